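---
title: "Methods: LS-SVM with PSO tuning and a binary decision tree for fetal-state classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: LS-SVM with PSO tuning and a binary decision tree}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(lssvmbdt)
```

This vignette is the package's own account of the model it implements, the
choices that were genuinely open, and what the test suite does and does not
establish.

## 1. The model

### Binary LS-SVM

For training pairs $(x_i, y_i)$, $y_i \in \{\pm 1\}$, the least-squares SVM
minimizes $\tfrac12\|w\|^2 + \tfrac{\gamma}{2}\sum_i e_i^2$ subject to the
*equality* constraints $y_i(w^\top\varphi(x_i) + b) = 1 - e_i$. Eliminating
$w$ and $e$ from the Lagrangian optimality conditions leaves the bordered
linear system

$$
\begin{bmatrix} 0 & -Y^\top \\ Y & \Omega + \gamma^{-1} I \end{bmatrix}
\begin{bmatrix} b \\ \alpha \end{bmatrix} =
\begin{bmatrix} 0 \\ \mathbf{1} \end{bmatrix},
\qquad \Omega_{ij} = y_i y_j K(x_i, x_j),
$$

so training is one dense solve instead of a quadratic program. Two
consequences matter in practice: every training point gets a (possibly
negative) multiplier $\alpha_i$ — there is no sparsity — and the residuals
are recoverable as $e_i = \alpha_i / \gamma$, which the tests use to verify
the equality constraints ($\max_i |y_i f(x_i) - 1 + \alpha_i/\gamma| \le
10^{-6}$) after every fit.

**Relation to the classical SVM.** As $\gamma \to \infty$ the LS-SVM does
*not* become the hard-margin SVM: it forces $y_i f(x_i) = 1$ at *every*
training point (the kernel least-squares / Fisher-discriminant limit),
whereas the SVM constrains only its support vectors. The two boundaries
coincide exactly when the hard-margin active set spans the whole sample —
e.g. two symmetric parallel rows of points — and there the suite verifies
100% grid-sign agreement at $\gamma = 10^6$ against an independent SMO
solver of the classical dual (itself cross-checked against an external
implementation during development). On generic Gaussian-blob toy sets the
agreement away from the data is geometry-dependent, typically 95–98% of a
grid covering the data; this is a property of the two losses, not a solver
artifact.

The kernel is Gaussian, $K(x,z) = \exp(-\|x-z\|^2/2\sigma^2)$, and only
Gaussian: the kernel contract is narrow by design (`rbf_kernel`), and no
polynomial/sigmoid zoo is provided.

**Numerical path.** The first row of the bordered system appears with
$-Y^\top$; the symmetric variant flips that row's sign. Since the row's
right-hand side is zero, both systems have the *same* solution, so the
default solver uses block elimination with a Cholesky factorization of the
symmetric positive-definite block $A = \Omega + \gamma^{-1}I$:
$b = (Y^\top A^{-1}\mathbf 1)/(Y^\top A^{-1} Y)$,
$\alpha = A^{-1}(\mathbf 1 - bY)$. `solver = "lu"` performs the literal
partial-pivoting solve of the printed $(N+1)\times(N+1)$ matrix in either
sign convention; a unit test asserts the two paths agree to $10^{-8}$ and
that the Cholesky solution satisfies the printed system. At the intended
scale ($N \lesssim 2000$) no iterative solver is warranted.

**Ties.** A decision value of exactly zero predicts $+1$
(`sign(0) >= 0`), so prediction is deterministic.

**Feature scaling.** The RBF kernel is scale-sensitive and CTG features
span beats-per-minute to per-second rates, so z-score standardization is
fit on each node's training rows, stored in the model, and applied to
queries (`scale = FALSE` disables it for strict raw-feature behaviour).
Zero-variance features pass through centered but unscaled. Note that on
*synthetic* data whose informative axes already have unit within-class
variance, standardization slightly *shrinks* between-class separation
(the informative axis has inflated mixture variance); one evaluation test
therefore runs with `scale = FALSE` on the generator's raw scale. With PSO
tuning the kernel width absorbs this and the tuned pipeline is insensitive
to the choice.

### PSO hyperparameter search

Positions are $(\log_2\gamma, \log_2\sigma^2)$ over the box $[-4, 12]^2$,
i.e. $\gamma, \sigma^2 \in [2^{-4}, 2^{12}]$ — multiplicative parameters
are searched in log space, and the box endpoints are powers of two. The
update is the canonical

$$
V \leftarrow \omega V + c_1 r_1 (P - \lambda) + c_2 r_2 (G - \lambda),
\qquad \lambda \leftarrow \lambda + V,
$$

with $r_1, r_2$ drawn independently **per particle and per dimension** per
step (the common reading of the update; a scalar-draw variant would only
move particles along the line towards the attractors). Defaults: 25
particles, $\omega = 0.75$, $c_1 = c_2 = 2$, 50 iterations (the iteration
budget is not specified anywhere authoritative; 50 is enough for the
2-D search to stagnate in practice). Velocities are clamped to the box
width per dimension; positions leaving the box are clamped with the
velocity zeroed in that dimension.

Note that $c_1 + c_2 = 4$ sits at the classical stability boundary of the
PSO dynamics, so final precision on even a smooth quadratic is
seed-dependent: across 20 seeds roughly two thirds of runs land within
$10^{-2}$ of the argmax after 50 iterations, the rest within a few
$10^{-2}$. The convergence tests fix seeds, as any stochastic-optimizer
test must; this is a property of the published settings, not of the
implementation.

**Fitness.** Nothing authoritative defines the tuning objective, so the
package uses the mean accuracy of an internal stratified 5-fold CV on the
node's training rows — the standard leakage-free choice for SVM model
selection (training accuracy would drive $\gamma$ to interpolation). Folds
shrink automatically when the node's minority class is too small for 5
folds (at least 2 per fold), falling back to training accuracy with a
warning only when even 2-fold stratification is impossible. Exact fitness
ties prefer the smaller $\gamma$ (the simpler model), implemented as a
comparator hook in the best-update rather than a fitness perturbation.

**Nesting.** Tuning is re-run independently for every node of every outer
CV fold. Tuning once globally on all data would leak the held-out folds
into model selection; the nested reading is the only defensible one, and
its cost is contained by caching each inner fold's squared-distance matrix
once per node so that a hyperparameter evaluation costs one `exp()` and
one Cholesky solve per fold.

### Binary decision tree

R classes require R − 1 binary nodes. The fetal-state tree is fixed:

1. root: {pathologic, suspect} (+1) vs {normal} (−1);
2. second node: {pathologic} (+1) vs {suspect} (−1).

The root grouping is deliberately asymmetric in risk: separating the two
at-risk states from normal first means a record must be mis-ranked at the
root before an at-risk fetus can be labeled normal. The positive subset is
always the one listed first in the plan and maps to $+1$, recorded in the
serialized plan so stored trees are self-describing. Generic trees for any
R come from `partition_plan()`, which validates disjointness, coverage,
the R − 1 count, and that leaves are exactly the R singletons. No
automatic tree-structure learning is attempted.

## 2. Evaluation conventions

* **Stratified k-fold**: per class, a seeded shuffle then round-robin
  dealing, so per-class fold counts differ by at most one. With the real
  class totals (1655, 295, 176) and $k = 10$ the per-class fold sizes are
  {165, 166}, {29, 30}, {17, 18}.
* **Headline metric**: the mean of the k fold accuracies (the pooled
  confusion-matrix accuracy is reported alongside and labeled; the two
  differ when fold sizes differ).
* **Confusion matrices** are predicted × actual (rows × columns); the
  confusion-ratio matrix divides each column by its actual-class total, so
  columns sum to one exactly before the 3-decimal display rounding.
* **Cobweb axes**: the $R^2 - R$ off-diagonal ratios enumerated
  column-major — for each actual class in class order, the rates of being
  predicted as each other class — starting at the top of the radar plot
  and proceeding clockwise. No ordering is canonical in the literature;
  this one is recorded in the axis labels and the serialized polygon. The
  chance polygon sits at $1/R$ on every axis (a regular hexagon for
  $R = 3$).
* **ROC curves** are deliberately not implemented: with three classes the
  threshold-sweep space is six-dimensional, which is exactly what the
  cobweb representation replaces. Sensitivity/specificity at the operating
  point (one-vs-rest) plus the cobweb is the implemented surface.

## 3. The synthetic generator: what it emulates, what it does not

`generate_ctg()` draws each class from a spherical Gaussian in 21
dimensions, class $c$ centered at $\text{separation} \times
\text{within\_sd}$ along coordinate axis $c$. Defaults state the world the
package is tested in:

* `n_per_class = c(1655, 295, 176)` — the real CTG class imbalance
  (tests scale these down proportionally, e.g. (330, 60, 36), and say so);
* `dim = 21` — the CTG schema, reusing its feature names;
* `within_sd = 1`, `separation = 4` — class means 4 within-class standard
  deviations apart along distinct axes ($4\sqrt2 \approx 5.7\sigma$
  between means), i.e. nearly separable. This is what a scientist would
  call a clean benchmark for a kernel classifier: hard enough that wrong
  hyperparameters fail it (a fixed $\sigma^2$ far off scale drops accuracy
  to ~0.6), easy enough that a correctly tuned pipeline should exceed
  0.95.

What it does **not** emulate: real CTG features are correlated (no
covariances are published to copy), non-Gaussian, and the clinical classes
overlap heavily — the published per-class recalls (96.9/70.5/76.7%) are
far from the near-perfect recalls on the synthetic defaults. A green
synthetic test therefore establishes that the pipeline is wired correctly
and recovers structure it should recover, not that it reproduces clinical
difficulty. The published 91.62% 10-fold accuracy on the real table is
correspondingly *not* an acceptance target: it requires the external UCI
download and depends on tuning internals (PSO fitness, iteration budget,
fold seeds) that were never reported. With the real CSV supplied to the
CLI the pipeline is expected to land in the high-80s to low-90s.

## 4. Reproducibility and seeds

Every stochastic component (fold shuffles, swarm initialization and
updates, the generator) takes a seed; `cross_validate()` and the CLI
expand one master seed into per-component sub-seeds via a fixed integer
recurrence, so one integer reproduces a whole run byte-for-byte
(`metrics.json` is asserted identical across re-runs in the tests). PSO
keeps its RNG state inside the swarm object and restores the caller's
stream, so library calls do not perturb user code.

## 5. Known limitations

* No sparse/approximate LS-SVM variants or support-value pruning; memory
  is $O(N^2)$ and the dense solve $O(N^3)$ — fine to a few thousand rows.
* The CSV reader consumes the 21-feature + NSP/CLASS schema only; the UCI
  Excel workbook must be exported to CSV first. Rows with missing values
  are rejected, not imputed (no imputation is described for the original
  experiment).
* Config files are JSON (no YAML parser in the dependency footprint).
* The chance polygon is a reference line, not a statistical test; no
  significance machinery for comparing classifiers is provided.
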