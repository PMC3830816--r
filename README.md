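# lssvmbdt

Three-class fetal-state classification from cardiotocogram (CTG) feature
tables in R: a least-squares support vector machine (LS-SVM) trained by one
linear solve, hyperparameters tuned by particle swarm optimization (PSO),
extended to multiple classes with a binary decision tree (BDT), and
evaluated with stratified cross-validation, confusion-ratio matrices and
cobweb misclassification plots.

## Who this is for

Cardiotocography records fetal heart rate and uterine activity; obstetric
screening software summarizes each recording into 21 numeric features (FHR
baseline, acceleration/deceleration rates, variability statistics,
histogram descriptors) plus a fetal-state label: **normal**, **suspect**,
or **pathologic** (the UCI `NSP` coding 1/2/3). This package is for anyone
who wants a reproducible, dependency-light implementation of the
LS-SVM + PSO + BDT pipeline for that kind of table — or for any
small-to-medium three-class (or R-class) numeric classification problem
with heavy class imbalance.

## The method

**Binary LS-SVM.** For labels `y_i ∈ ±1` the LS-SVM replaces the SVM's
inequality constraints and hinge loss with equality constraints and a
squared loss, so training reduces to the bordered linear (KKT) system

```
[ 0   −Yᵀ          ] [ b ]   [ 0 ]
[ Y   Ω + γ⁻¹ I    ] [ α ] = [ 1 ]     Ω_ij = y_i y_j K(x_i, x_j)
```

with the Gaussian kernel `K(x, z) = exp(−‖x−z‖² / 2σ²)`. The classifier is
`f(x) = sign(Σ_i y_i α_i K(x, x_i) + b)`.

**PSO tuning.** The penalty factor γ and kernel width σ² are searched in
log₂ space over `[2⁻⁴, 2¹²]²` by a 25-particle swarm (ω = 0.75,
c₁ = c₂ = 2, 50 iterations), maximizing stratified inner-CV accuracy.

**BDT multiclass.** R classes need R − 1 binary classifiers. The fixed
fetal-state tree first separates {pathologic, suspect} from {normal} (so a
single mistake cannot route an at-risk fetus to "normal"), then pathologic
from suspect. Arbitrary trees are supported via `partition_plan()`.

**Evaluation.** Stratified k-fold CV; a predicted × actual confusion
matrix; its column-normalized **confusion-ratio matrix** (diagonals =
per-class recall); one-vs-rest sensitivity/specificity; and the **cobweb
plot** — a radar chart of the R² − R off-diagonal misclassification rates
against the chance polygon at 1/R per axis.

## Worked example

```r
library(lssvmbdt)

# CTG-like synthetic table: 21 features, imbalanced classes, well separated
d  <- generate_ctg(n_per_class = c(330, 60, 36), separation = 4, seed = 11)
xy <- list(x = as.matrix(d[, 1:21]), y = d$state)

# full nested pipeline: per-fold, per-node PSO tuning (takes a few minutes)
res <- cross_validate(xy$x, xy$y, k = 10, seed = 42)
res
#> 10-fold stratified CV: mean accuracy 0.9883 (pooled 0.9883)
#> fold accuracies: 1.000 1.000 0.977 0.977 1.000 0.953 1.000 1.000 1.000 0.976

column_normalize(res$confusion)      # per-class recall on the diagonal
plot_cobweb(cobweb_coordinates(column_normalize(res$confusion)))
```

The mean accuracy is the average of the ten held-out fold accuracies (the
pooled-matrix accuracy is reported alongside; the two differ when folds are
unequal). On the published CTG confusion matrix the same tooling gives:

```r
t5 <- matrix(c(1604, 38, 13, 70, 208, 17, 12, 29, 135), 3,
             dimnames = list(ctg_classes, ctg_classes))
column_normalize(structure(t5, class = "confusion_matrix"))
#>            normal suspect pathologic
#> normal      0.969   0.237      0.068
#> suspect     0.023   0.705      0.165
#> pathologic  0.008   0.058      0.767
overall_accuracy(t5)
#> [1] 0.9158043
```

i.e. 96.9% of normal, 70.5% of suspect and 76.7% of pathologic records
correctly recalled.

## Command line

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "lssvmbdt", package = "lssvmbdt"))')
Rscript $CLI synth    --n 330,60,36 --seed 7 --out ctg.csv
Rscript $CLI crossval --data ctg.csv --k 10 --seed 7 --out results/
Rscript $CLI train    --data ctg.csv --seed 7 --out tree.json
Rscript $CLI predict  --model tree.json --data ctg.csv --out pred.csv
Rscript $CLI cobweb   --ratios results/confusion_ratio.csv --out cobweb.svg
```

`crossval` writes `metrics.json`, count and ratio matrices as CSV, and
cobweb figures (SVG + PNG); every command is reproducible from `--seed`.
Real UCI CTG data: export the `Raw Data` sheet of the UCI workbook to CSV
(21 feature columns + `NSP`) and pass it to `--data`.

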