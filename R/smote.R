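## SMOTE oversampling: the data-generation step that turns the 60 original
## limb instances into a balanced, fully synthetic training set.

#' SMOTE interpolation within one class
#'
#' Each synthetic point is `x_i + u * (x_nn - x_i)` where `x_i` is a
#' uniformly drawn class member, `x_nn` one of its `k` nearest same-class
#' neighbors (Euclidean distance), and `u ~ Uniform(0, 1)`. All synthetic
#' points therefore lie on within-class segments, hence inside the class's
#' convex hull.
#'
#' @param points numeric matrix, one row per class member (>= 2 rows).
#' @param n_out number of synthetic points to generate.
#' @param k neighbor count; capped at `nrow(points) - 1` with a warning.
#' @param allow_degenerate if `TRUE` a single-point class is duplicated
#'   instead of raising an error.
#' @return numeric matrix with `n_out` rows. Draws come from the current RNG
#'   stream; seed externally (e.g. `set.seed`) for reproducibility.
#' @export
smote_class <- function(points, n_out, k = 5L, allow_degenerate = FALSE) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (n < 1L || n_out < 1L)
    stop_dg("need a non-empty class and n_out >= 1", class = "dg_invalid_input")
  if (n == 1L) {
    if (!allow_degenerate)
      stop_dg("single-point class cannot be interpolated",
              class = "dg_degenerate_class")
    return(points[rep(1L, n_out), , drop = FALSE])
  }
  if (k > n - 1L) {
    warn_dg("k = %d exceeds class size - 1; capped at %d", k, n - 1L,
            class = "dg_k_capped")
    k <- n - 1L
  }
  d2 <- as.matrix(stats::dist(points))^2
  diag(d2) <- Inf
  # k nearest neighbors per point, ties broken by row index
  nn_idx <- do.call(rbind, lapply(seq_len(n), function(i)
    order(d2[i, ])[seq_len(k)]))
  i <- sample.int(n, n_out, replace = TRUE)
  j <- nn_idx[cbind(i, sample.int(k, n_out, replace = TRUE))]
  u <- stats::runif(n_out)
  points[i, , drop = FALSE] + u * (points[j, , drop = FALSE] -
                                     points[i, , drop = FALSE])
}

#' Generate the balanced SMOTE training set for a grading task
#'
#' Every class is oversampled to exactly `n_per_class` synthetic instances
#' (the training set is fully synthetic), while the original table is kept
#' untouched as the hold-out test set. Neighbor search runs on standardized
#' features (z-score over the originals); interpolation is applied to the
#' raw feature values, which is equivalent up to the affine rescaling.
#'
#' @param table an [instance_table()] with labels for `task`.
#' @param task `"nihss"` (2 classes, default 120 per class) or `"mrc"`
#'   (3 classes, default 80 per class) — 240 training instances either way.
#' @param n_per_class synthetic instances per class; `NULL` for the task
#'   default.
#' @param k SMOTE neighbor count (default 5).
#' @param seed RNG seed.
#' @param include_demographics interpolate `age` and the sex indicator as
#'   continuous columns alongside the kinematic features.
#' @return object of class `train_test_bundle`: list with `train` and `test`
#'   instance tables, `task`, `n_classes`, `n_per_class`, `k`, `seed`.
#' @export
generate_training_set <- function(table, task = c("nihss", "mrc"),
                                  n_per_class = NULL, k = 5L, seed = 1L,
                                  include_demographics = FALSE) {
  task <- match.arg(task)
  if (is.null(n_per_class)) n_per_class <- if (task == "nihss") 120L else 80L
  fm <- to_feature_matrix(table, labels = task,
                          include_demographics = include_demographics,
                          standardize = FALSE)
  classes <- levels(fm$y)
  counts <- table(fm$y)
  if (any(counts < 2L))
    stop_dg("class '%s' has fewer than 2 instances",
            names(counts)[which.min(counts)], class = "dg_degenerate_class")
  scaler <- scaler_fit(fm$x)
  xs <- scaler_apply(fm$x, scaler)
  set.seed(seed)
  syn <- lapply(classes, function(cl) {
    z <- smote_class(xs[fm$y == cl, , drop = FALSE], n_per_class, k = k)
    scaler_invert(z, scaler)
  })
  raw <- do.call(rbind, syn)
  lab <- rep(as.integer(classes), each = n_per_class)
  df <- data.frame(
    subject_id = sprintf("syn_%s_%03d", task, seq_len(nrow(raw))),
    limb_id = NA_character_,
    mean = raw[, "mean"], max = raw[, "max"], osc = raw[, "osc"],
    nihss = if (task == "nihss") lab else NA_integer_,
    mrc = if (task == "mrc") lab else NA_integer_)
  if (include_demographics) {
    df$age <- raw[, "age"]
    df$sex <- NA_character_
    df$sex_m <- raw[, "sex_m"]
  }
  structure(list(train = instance_table(df), test = table, task = task,
                 n_classes = length(classes), n_per_class = n_per_class,
                 k = k, seed = seed),
            class = "train_test_bundle")
}

#' @export
print.train_test_bundle <- function(x, ...) {
  cat(sprintf(
    "<train_test_bundle> task %s: %d synthetic train (%d x %d classes), %d test\n",
    x$task, nrow(x$train), x$n_per_class, x$n_classes, nrow(x$test)))
  invisible(x)
}
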