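## Grading models: SVM and tree-ensemble families behind one fit/predict
## surface. The SVM wraps e1071/libsvm; the four ensemble methods (AdaBoost,
## gradient boosting, bagging, RUSBoost) are driven in R over the package's
## compiled depth-limited CART trees (src/trees.cpp), which keeps the
## 30-trial cross-validated search fast on small feature tables.

softmax_rows <- function(m) {
  m <- m - apply(m, 1L, max)
  e <- exp(m)
  e / rowSums(e)
}

## ---- SAMME boosting (AdaBoost / RUSBoost) ----------------------------------

samme_fit <- function(x, y, n_learners, learn_rate, max_depth,
                      undersample = FALSE) {
  n <- nrow(x)
  K <- nlevels(y)
  yi <- as.integer(y) - 1L
  w <- rep(1 / n, n)
  trees <- vector("list", n_learners)
  alpha <- numeric(n_learners)
  min_count <- min(table(y))
  class_idx <- split(seq_len(n), y)
  for (m in seq_len(n_learners)) {
    if (undersample) {
      # RUSBoost: every class undersampled to the minority size, sampling
      # probability proportional to the current boosting weights
      idx <- unlist(lapply(class_idx, function(pool) {
        if (length(pool) <= min_count) pool
        else sample(pool, min_count, prob = w[pool])
      }), use.names = FALSE)
      tree <- .cart_fit_cls(x[idx, , drop = FALSE], yi[idx],
                            w[idx] / sum(w[idx]), K, max_depth, 5L)
    } else {
      tree <- .cart_fit_cls(x, yi, w, K, max_depth, 5L)
    }
    pred <- .cart_predict_class(tree, x)
    miss <- pred != yi
    err <- min(max(sum(w * miss), 1e-10), 1 - 1e-10)
    a <- learn_rate * (log((1 - err) / err) + log(K - 1))
    if (a <= 0) a <- 0  # weak learner no better than chance: no vote
    trees[[m]] <- tree
    alpha[m] <- a
    if (a > 0) {
      w <- w * exp(a * miss)
      w <- w / sum(w)
    }
  }
  list(kind = "samme", trees = trees, alpha = alpha, n_classes = K)
}

samme_scores <- function(model, x) {
  n <- nrow(x)
  K <- model$n_classes
  votes <- matrix(0, n, K)
  for (m in seq_along(model$trees)) {
    if (model$alpha[m] == 0) next
    pred <- .cart_predict_class(model$trees[[m]], x)
    ij <- cbind(seq_len(n), pred + 1L)
    votes[ij] <- votes[ij] + model$alpha[m]
  }
  tot <- rowSums(votes)
  zero <- tot == 0
  votes[zero, ] <- 1 / K
  votes[!zero, ] <- votes[!zero, , drop = FALSE] / tot[!zero]
  votes
}

## ---- gradient boosting (softmax objective, second-order trees) -------------

gboost_fit <- function(x, y, n_learners, learn_rate, max_depth,
                       lambda = 1) {
  n <- nrow(x)
  K <- nlevels(y)
  ymat <- matrix(0, n, K)
  ymat[cbind(seq_len(n), as.integer(y))] <- 1
  margin <- matrix(0, n, K)
  trees <- vector("list", n_learners)
  for (m in seq_len(n_learners)) {
    p <- softmax_rows(margin)
    round_trees <- vector("list", K)
    for (k in seq_len(K)) {
      grad <- p[, k] - ymat[, k]
      hess <- pmax(2 * p[, k] * (1 - p[, k]), 1e-6)
      tree <- .cart_fit_reg(x, grad, hess, lambda, max_depth, 5L)
      round_trees[[k]] <- tree
      margin[, k] <- margin[, k] + learn_rate * .cart_predict(tree, x)[, 1L]
    }
    trees[[m]] <- round_trees
  }
  list(kind = "gboost", trees = trees, n_classes = K,
       learn_rate = learn_rate)
}

gboost_scores <- function(model, x) {
  K <- model$n_classes
  margin <- matrix(0, nrow(x), K)
  for (round_trees in model$trees)
    for (k in seq_len(K))
      margin[, k] <- margin[, k] +
        model$learn_rate * .cart_predict(round_trees[[k]], x)[, 1L]
  softmax_rows(margin)
}

## ---- bagging ----------------------------------------------------------------

bagging_fit <- function(x, y, n_learners, max_depth) {
  n <- nrow(x)
  K <- nlevels(y)
  yi <- as.integer(y) - 1L
  trees <- lapply(seq_len(n_learners), function(m) {
    # bootstrap resample expressed as multinomial case weights
    w <- as.numeric(stats::rmultinom(1L, n, rep(1 / n, n)))
    .cart_fit_cls(x, yi, w / n, K, max_depth, 5L)
  })
  list(kind = "bagging", trees = trees, n_classes = K)
}

bagging_scores <- function(model, x) {
  acc <- matrix(0, nrow(x), model$n_classes)
  for (tree in model$trees) acc <- acc + .cart_predict(tree, x)
  acc / length(model$trees)
}

## ---- family dispatch ---------------------------------------------------------

#' Fit a grading model with fixed hyperparameters
#'
#' Fits one model of the given family on a (standardized) feature matrix.
#' SVM hyperparameters: `kernel` (`"linear"`, `"radial"`, `"polynomial"`),
#' `cost` (box constraint), `gamma` (inverse kernel scale; for the
#' polynomial kernel values above 1 are clamped to 1 because the axis is
#' redundant with `cost` there and unbounded kernel magnitudes stall the
#' solver), `degree` (polynomial only). Ensemble hyperparameters: `method`
#' (`"adaboost"`, `"gradient_boost"`, `"bagging"`, `"rusboost"`),
#' `n_learners`, `learn_rate` (inactive for bagging), `max_depth`.
#' Multiclass SVM uses libsvm's one-vs-one decomposition; the ensembles are
#' natively multiclass.
#'
#' @param x numeric feature matrix.
#' @param y factor of class labels (>= 2 levels present).
#' @param hyperparameters named list as above.
#' @param family `"svm"` or `"ensemble"`.
#' @param seed seed for fit-time randomness (bagging bootstrap, RUSBoost
#'   undersampling).
#' @return object of class `grader_fit` with elements `family`,
#'   `hyperparameters`, `classes`, `feature_cols`, `fit`.
#' @export
train_final <- function(x, y, hyperparameters, family = c("svm", "ensemble"),
                        seed = 1L) {
  family <- match.arg(family)
  x <- as.matrix(x)
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2L)
    stop_dg("training data contains a single class", class = "dg_invalid_labels")
  hp <- hyperparameters
  set.seed(seed)
  fit <- if (family == "svm") {
    gamma <- if (hp$kernel == "polynomial") min(hp$gamma, 1) else hp$gamma
    e1071::svm(x, y, scale = FALSE, type = "C-classification",
               kernel = hp$kernel, cost = hp$cost,
               gamma = if (hp$kernel == "linear") 1 else gamma,
               degree = if (hp$kernel == "polynomial") hp$degree else 3,
               coef0 = if (hp$kernel == "polynomial") 1 else 0)
  } else {
    switch(hp$method,
      adaboost = samme_fit(x, y, hp$n_learners, hp$learn_rate, hp$max_depth),
      rusboost = samme_fit(x, y, hp$n_learners, hp$learn_rate, hp$max_depth,
                           undersample = TRUE),
      gradient_boost = gboost_fit(x, y, hp$n_learners, hp$learn_rate,
                                  hp$max_depth),
      bagging = bagging_fit(x, y, hp$n_learners, hp$max_depth),
      stop_dg("unknown ensemble method '%s'", hp$method,
              class = "dg_invalid_input"))
  }
  structure(list(family = family, hyperparameters = hp,
                 classes = levels(y), feature_cols = colnames(x), fit = fit),
            class = "grader_fit")
}

## per-class scores in [0,1] summing to 1 per row
grader_scores <- function(object, x) {
  x <- as.matrix(x)
  classes <- object$classes
  if (object$family == "svm") {
    pred <- predict(object$fit, x, decision.values = TRUE)
    dv <- attr(pred, "decision.values")
    agg <- matrix(0, nrow(x), length(classes),
                  dimnames = list(NULL, classes))
    for (j in seq_len(ncol(dv))) {
      pair <- strsplit(colnames(dv)[j], "/", fixed = TRUE)[[1L]]
      agg[, pair[1L]] <- agg[, pair[1L]] + dv[, j]
      agg[, pair[2L]] <- agg[, pair[2L]] - dv[, j]
    }
    # softmax over aggregated one-vs-one decision values
    softmax_rows(agg)
  } else {
    s <- switch(object$fit$kind,
                samme = samme_scores(object$fit, x),
                gboost = gboost_scores(object$fit, x),
                bagging = bagging_scores(object$fit, x))
    colnames(s) <- classes
    s
  }
}

#' Predict grades and class scores
#'
#' @param object a `grader_fit` from [train_final()] (or the `$fit` slot of a
#'   [train_grader()] model).
#' @param x numeric feature matrix on the same columns (and scaling) the
#'   model was trained on.
#' @param ... unused.
#' @return object of class `grading_result`: list with `grade` (factor) and
#'   `scores` (matrix, one column per class, rows summing to 1). The
#'   predicted grade is the score argmax; exact ties break toward the lower
#'   grade.
#' @export
predict.grader_fit <- function(object, x, ...) {
  x <- as.matrix(x)
  if (!is.null(object$feature_cols) && !is.null(colnames(x)) &&
      !identical(colnames(x), object$feature_cols))
    stop_dg("feature columns (%s) do not match model contract (%s)",
            paste(colnames(x), collapse = ","),
            paste(object$feature_cols, collapse = ","),
            class = "dg_feature_contract")
  bad <- which(rowSums(!is.finite(x)) > 0)
  if (length(bad))
    stop_dg("non-finite features in instance(s) %s",
            paste(utils::head(bad, 5L), collapse = ", "),
            class = "dg_invalid_input")
  scores <- grader_scores(object, x)
  grade <- factor(object$classes[max.col(scores, ties.method = "first")],
                  levels = object$classes)
  structure(list(grade = grade, scores = scores), class = "grading_result")
}

#' @export
print.grading_result <- function(x, ...) {
  cat(sprintf("<grading_result> %d instances over classes {%s}\n",
              length(x$grade), paste(colnames(x$scores), collapse = ", ")))
  print(table(predicted = x$grade))
  invisible(x)
}
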