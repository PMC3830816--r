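#' @title CTG feature schema
#' @description The 21 numeric features of the UCI cardiotocography table:
#' FHR baseline (LB), per-second event rates (AC accelerations, FM fetal
#' movements, UC uterine contractions, DL/DS/DP light/severe/prolonged
#' decelerations), short/long-term variability summaries (ASTV, MSTV, ALTV,
#' MLTV) and FHR-histogram descriptors (Width, Min, Max, N_max, N_zeros,
#' Mode, Mean, Median, Variance, Tendency).
#' @format Character vector of length 21.
#' @export
ctg_feature_names <- c(
  "LB", "AC", "FM", "UC", "DL", "DS", "DP", "ASTV", "MSTV", "ALTV", "MLTV",
  "Width", "Min", "Max", "N_max", "N_zeros", "Mode", "Mean", "Median",
  "Variance", "Tendency")

#' @title Fetal-state class labels
#' @description Class names in UCI NSP code order: 1 = normal, 2 = suspect,
#'   3 = pathologic.
#' @format Character vector of length 3.
#' @export
ctg_classes <- c("normal", "suspect", "pathologic")

norm_name <- function(x) toupper(gsub("[^A-Za-z0-9]", "", x))

#' Read a CTG feature table from delimited text
#'
#' Expects a header row containing the 21 features of [ctg_feature_names]
#' (case- and punctuation-insensitive, so `Nmax` matches `N_max`) plus a
#' label column named `NSP` or `CLASS` with values 1 (normal), 2 (suspect),
#' 3 (pathologic). The field separator (comma or semicolon) is sniffed from
#' the header. Rows with missing/non-numeric features or an invalid label
#' are rejected with a warning naming their line numbers.
#'
#' @param path Path to a UTF-8 CSV file.
#' @return A `data.frame` with the 21 canonical feature columns and a
#'   `state` factor with levels [ctg_classes]; attribute `"provenance"`
#'   records the source path and rejected line numbers.
#' @export
read_ctg <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  header <- readLines(path, n = 1L)
  sep <- if (lengths(regmatches(header, gregexpr(";", header))) >
             lengths(regmatches(header, gregexpr(",", header)))) ";" else ","
  df <- utils::read.csv(path, sep = sep, check.names = FALSE,
                        stringsAsFactors = FALSE)
  nm <- norm_name(names(df))
  want <- norm_name(ctg_feature_names)
  missing <- ctg_feature_names[!(want %in% nm)]
  if (length(missing))
    stopf("schema error: missing required column(s): %s",
          paste(missing, collapse = ", "))
  label_col <- which(nm %in% c("NSP", "CLASS"))[1L]
  if (is.na(label_col))
    stopf("schema error: missing label column NSP (or CLASS)")

  feat <- df[, match(want, nm), drop = FALSE]
  names(feat) <- ctg_feature_names
  for (j in seq_along(feat))
    feat[[j]] <- suppressWarnings(as.numeric(feat[[j]]))
  nsp <- suppressWarnings(as.numeric(df[[label_col]]))

  bad <- !stats::complete.cases(feat) | !is.finite(nsp) | !(nsp %in% 1:3)
  if (any(bad)) {
    # +1 for the header row: report file line numbers
    warning(sprintf("rejected %d row(s) at line(s): %s", sum(bad),
                    paste(which(bad) + 1L, collapse = ", ")),
            call. = FALSE)
    feat <- feat[!bad, , drop = FALSE]
    nsp <- nsp[!bad]
  }
  if (!nrow(feat)) stopf("empty dataset: no valid rows in %s", path)
  out <- feat
  out$state <- factor(ctg_classes[nsp], levels = ctg_classes)
  rownames(out) <- NULL
  attr(out, "provenance") <- list(source = "read", path = path,
                                  rejected_lines = which(bad) + 1L)
  out
}

#' Z-score standardization record
#'
#' `standardize_fit` computes per-feature mean and standard deviation on
#' training data; `standardize_apply` applies them to any matrix with the
#' same columns. Zero-variance features pass through unscaled (scale set to
#' 1) with a warning, so constant columns survive the round trip.
#'
#' @param x Numeric matrix or data frame of features (rows = points).
#' @return `standardize_fit`: an object of class `"standardizer"` with
#'   `center` and `scale` vectors. `standardize_apply`: the transformed
#'   matrix.
#' @export
standardize_fit <- function(x) {
  x <- as_feature_matrix(x)
  if (!nrow(x)) stopf("cannot standardize an empty matrix")
  center <- colMeans(x)
  scale <- apply(x, 2L, stats::sd)
  if (nrow(x) == 1L) scale[] <- NA_real_
  zero <- !is.finite(scale) | scale == 0
  if (any(zero)) {
    warning(sprintf("%d zero-variance feature(s) left unscaled", sum(zero)),
            call. = FALSE)
    scale[zero] <- 1
  }
  structure(list(center = center, scale = scale), class = "standardizer")
}

#' @rdname standardize_fit
#' @param stats A `"standardizer"` from `standardize_fit`.
#' @export
standardize_apply <- function(stats, x) {
  stopifnot(inherits(stats, "standardizer"))
  x <- as_feature_matrix(x)
  if (ncol(x) != length(stats$center))
    stopf("dimension mismatch: standardizer has %d features, x has %d",
          length(stats$center), ncol(x))
  sweep(sweep(x, 2L, stats$center, "-"), 2L, stats$scale, "/")
}

#' Generate a synthetic three-(or R-)class CTG-like feature table
#'
#' Draws each class from a spherical Gaussian in `dim` dimensions. Class
#' means sit at `separation * within_sd` along distinct coordinate axes, so
#' `separation` directly controls between-class separation in units of the
#' within-class standard deviation. The defaults emulate the real CTG
#' table's shape: 21 features, heavy 1655:295:176 class imbalance, and a
#' separation at which a well-tuned RBF classifier is near-perfect —
#' real CTG classes overlap far more, so accuracy on these defaults is an
#' upper bound, not an emulation of clinical difficulty.
#'
#' @param n_per_class Integer vector (length = number of classes, each
#'   >= 2) of per-class sample sizes.
#' @param dim Feature dimension; 21 mirrors the CTG schema and reuses its
#'   feature names.
#' @param class_means Optional R x dim matrix overriding the default means.
#' @param within_sd Within-class standard deviation (all features).
#' @param separation Mean spacing as a multiple of `within_sd` (> 0).
#' @param seed Integer seed; identical seeds give identical datasets.
#' @param classes Class names; defaults to [ctg_classes] for 3 classes.
#' @return A `data.frame` of features plus a `state` factor, with a
#'   `"provenance"` attribute recording the full generator spec.
#' @examples
#' d <- generate_ctg(n_per_class = c(100, 18, 11), seed = 42)
#' table(d$state)
#' @export
generate_ctg <- function(n_per_class = c(1655L, 295L, 176L), dim = 21L,
                         class_means = NULL, within_sd = 1, separation = 4,
                         seed = 1L, classes = NULL) {
  r <- length(n_per_class)
  if (r < 2L) stopf("need at least 2 classes")
  if (any(n_per_class < 2L)) stopf("each class needs n >= 2")
  if (separation <= 0 || within_sd <= 0)
    stopf("separation and within_sd must be > 0")
  if (dim < r) stopf("dim must be >= number of classes (distinct axes)")
  if (is.null(classes))
    classes <- if (r == 3L) ctg_classes else paste0("class", seq_len(r))
  if (is.null(class_means)) {
    class_means <- matrix(0, r, dim)
    for (c in seq_len(r)) class_means[c, c] <- separation * within_sd
  } else {
    class_means <- as.matrix(class_means)
    stopifnot(nrow(class_means) == r, ncol(class_means) == dim)
  }

  x <- with_seed(seed, {
    do.call(rbind, lapply(seq_len(r), function(c) {
      matrix(stats::rnorm(n_per_class[c] * dim, sd = within_sd),
             ncol = dim, byrow = TRUE) +
        matrix(class_means[c, ], n_per_class[c], dim, byrow = TRUE)
    }))
  })
  colnames(x) <- if (dim == 21L) ctg_feature_names else
    paste0("F", seq_len(dim))
  out <- as.data.frame(x)
  out$state <- factor(rep(classes, n_per_class), levels = classes)
  attr(out, "provenance") <- list(
    source = "synthetic", n_per_class = as.integer(n_per_class), dim = dim,
    within_sd = within_sd, separation = separation, seed = as.integer(seed))
  out
}

#' Write predictions next to their input records
#'
#' @param data Feature data frame (e.g. from [read_ctg()] or
#'   [generate_ctg()]).
#' @param predicted Vector of predicted class labels, one per row.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(data, predicted, path) {
  if (nrow(data) != length(predicted))
    stopf("length(predicted) = %d but data has %d rows",
          length(predicted), nrow(data))
  out <- cbind(data, predicted_state = as.character(predicted))
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stopf("cannot write predictions to %s", path)
  invisible(path)
}

# Split a CTG-style data frame into (features matrix, state factor).
split_xy <- function(data) {
  stopifnot("state" %in% names(data))
  x <- as_feature_matrix(data[, setdiff(names(data), "state"), drop = FALSE])
  list(x = x, y = data$state)
}
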