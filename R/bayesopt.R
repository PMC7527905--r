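## Bayesian hyperparameter optimization: sequential model-based search with
## a Gaussian-process surrogate and expected-improvement acquisition, scored
## by stratified k-fold cross-validated misclassification. The evaluation
## budget (30 trials by default) is the contract; the surrogate is an
## implementation detail selectable between the GP and plain random search.

#' Hyperparameter search space for a model family
#'
#' Default axes: SVM — kernel in \{linear, radial, polynomial (degree 2-4)\},
#' box constraint `cost` and inverse kernel scale `gamma` log-uniform on
#' \[1e-3, 1e3\]; ensemble — method in \{adaboost, gradient_boost, bagging,
#' rusboost\}, learner count 10-500, learning rate log-uniform on
#' \[1e-3, 1\], tree depth 1-8.
#'
#' @param family `"svm"` or `"ensemble"`.
#' @return a `search_space`: list of axis descriptors (name, type, range or
#'   levels, log flag).
#' @export
search_space <- function(family = c("svm", "ensemble")) {
  family <- match.arg(family)
  axes <- if (family == "svm") {
    list(
      list(name = "kernel", type = "cat",
           levels = c("linear", "radial", "polynomial")),
      list(name = "degree", type = "int", lower = 2, upper = 4, log = FALSE),
      list(name = "cost",   type = "num", lower = 1e-3, upper = 1e3, log = TRUE),
      list(name = "gamma",  type = "num", lower = 1e-3, upper = 1e3, log = TRUE))
  } else {
    list(
      list(name = "method", type = "cat",
           levels = c("adaboost", "gradient_boost", "bagging", "rusboost")),
      list(name = "n_learners", type = "int", lower = 10, upper = 500,
           log = FALSE),
      list(name = "learn_rate", type = "num", lower = 1e-3, upper = 1,
           log = TRUE),
      list(name = "max_depth", type = "int", lower = 1, upper = 8,
           log = FALSE))
  }
  structure(list(family = family, axes = axes), class = "search_space")
}

sample_config <- function(space) {
  cfg <- lapply(space$axes, function(a) {
    switch(a$type,
      cat = sample(a$levels, 1L),
      int = {
        lo <- a$lower; hi <- a$upper
        if (isTRUE(a$log)) round(exp(stats::runif(1, log(lo), log(hi))))
        else sample(seq.int(lo, hi), 1L)
      },
      num = if (isTRUE(a$log)) exp(stats::runif(1, log(a$lower), log(a$upper)))
            else stats::runif(1, a$lower, a$upper))
  })
  names(cfg) <- vapply(space$axes, `[[`, "", "name")
  cfg
}

## encode a config as a numeric vector in [0,1]^d (one-hot categoricals,
## (log-)scaled numerics) for the GP kernel
encode_config <- function(cfg, space) {
  unlist(lapply(space$axes, function(a) {
    v <- cfg[[a$name]]
    if (a$type == "cat") as.numeric(a$levels == v)
    else {
      lo <- a$lower; hi <- a$upper
      if (isTRUE(a$log)) (log(v) - log(lo)) / (log(hi) - log(lo))
      else (v - lo) / (hi - lo)
    }
  }), use.names = FALSE)
}

#' Stratified cross-validation fold assignment
#'
#' @param y factor of labels.
#' @param k fold count.
#' @return integer fold index per instance; within every class the counts
#'   across folds differ by at most 1.
#' @export
stratified_folds <- function(y, k = 5L) {
  fold <- integer(length(y))
  for (cl in levels(y)) {
    idx <- which(y == cl)
    fold[sample(idx)] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

cv_misclassification <- function(x, y, fold, hyperparameters, family, seed) {
  k <- max(fold)
  wrong <- 0L
  for (f in seq_len(k)) {
    tr <- fold != f
    fit <- train_final(x[tr, , drop = FALSE], y[tr], hyperparameters,
                       family = family, seed = seed + f)
    pred <- predict(fit, x[!tr, , drop = FALSE])$grade
    wrong <- wrong + sum(as.character(pred) != as.character(y[!tr]))
  }
  wrong / length(y)
}

## GP posterior (squared-exponential kernel on encoded [0,1]^d points)
gp_posterior <- function(X, yv, Xcand, length_scale = 0.5, noise = 1e-4) {
  sqdist <- function(A, B) {
    an <- rowSums(A^2); bn <- rowSums(B^2)
    pmax(outer(an, bn, "+") - 2 * tcrossprod(A, B), 0)
  }
  mu0 <- mean(yv); sd0 <- stats::sd(yv)
  if (!is.finite(sd0) || sd0 < 1e-12) sd0 <- 1
  z <- (yv - mu0) / sd0
  K <- exp(-0.5 * sqdist(X, X) / length_scale^2)
  diag(K) <- diag(K) + noise + 1e-8
  L <- chol(K)
  alpha <- backsolve(L, backsolve(L, z, transpose = TRUE))
  Ks <- exp(-0.5 * sqdist(Xcand, X) / length_scale^2)
  mu <- drop(Ks %*% alpha)
  v <- backsolve(L, t(Ks), transpose = TRUE)
  s2 <- pmax(1 - colSums(v^2), 1e-12)
  list(mu = mu * sd0 + mu0, sd = sqrt(s2) * sd0)
}

expected_improvement <- function(mu, sd, best, xi = 0.01) {
  z <- (best - mu - xi) / sd
  (best - mu - xi) * stats::pnorm(z) + sd * stats::dnorm(z)
}

#' Bayesian hyperparameter optimization under a fixed evaluation budget
#'
#' Evaluates exactly `n_trials` hyperparameter configurations, each scored
#' by stratified `cv_folds`-fold cross-validated misclassification on the
#' training data. The first `n_init` configurations are a random design;
#' subsequent ones maximize expected improvement under a Gaussian-process
#' surrogate over a random candidate pool (`surrogate = "random"` falls back
#' to pure random search with the same budget and objective).
#'
#' @param x numeric feature matrix (standardized).
#' @param y factor of labels; every class must have at least `cv_folds`
#'   members.
#' @param family `"svm"` or `"ensemble"`.
#' @param n_trials evaluation budget (default 30).
#' @param cv_folds fold count (default 5).
#' @param seed RNG seed; identical seeds give identical histories.
#' @param space a [search_space()]; default for the family.
#' @param surrogate `"gp"` (default) or `"random"`.
#' @param n_init random initial design size (default 8, capped at
#'   `n_trials`).
#' @param n_candidates candidate pool per acquisition step (default 256).
#' @return list with `best_hyperparameters`, `best_objective`, `history`
#'   (data frame with per-trial objective) and `configs` (list of evaluated
#'   configurations).
#' @export
bayes_optimize <- function(x, y, family = c("svm", "ensemble"),
                           n_trials = 30L, cv_folds = 5L, seed = 1L,
                           space = NULL, surrogate = c("gp", "random"),
                           n_init = 8L, n_candidates = 256L) {
  family <- match.arg(family)
  surrogate <- match.arg(surrogate)
  space <- space %||% search_space(family)
  x <- as.matrix(x)
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2L)
    stop_dg("optimization needs at least 2 classes", class = "dg_invalid_labels")
  if (min(table(y)) < cv_folds)
    stop_dg("every class needs >= cv_folds (%d) instances", cv_folds,
            class = "dg_invalid_labels")
  set.seed(seed)
  fold <- stratified_folds(y, cv_folds)
  n_init <- min(n_init, n_trials)
  configs <- vector("list", n_trials)
  objective <- numeric(n_trials)
  for (i in seq_len(n_trials)) {
    cfg <- if (i <= n_init || surrogate == "random") {
      sample_config(space)
    } else {
      X <- t(vapply(configs[seq_len(i - 1L)], encode_config,
                    numeric(length(encode_config(configs[[1L]], space))),
                    space = space))
      cand <- replicate(n_candidates, sample_config(space), simplify = FALSE)
      Xc <- t(vapply(cand, encode_config, numeric(ncol(X)), space = space))
      post <- gp_posterior(X, objective[seq_len(i - 1L)], Xc)
      cand[[which.max(expected_improvement(
        post$mu, post$sd, min(objective[seq_len(i - 1L)])))]]
    }
    configs[[i]] <- cfg
    objective[i] <- cv_misclassification(x, y, fold, cfg, family,
                                         seed = seed + i * 1000L)
  }
  best <- which.min(objective)
  list(best_hyperparameters = configs[[best]],
       best_objective = objective[best],
       history = data.frame(trial = seq_len(n_trials), objective = objective),
       configs = configs)
}

#' Train a Bayes-optimized grader on an instance table
#'
#' End-to-end training for one task and model family: builds the
#' standardized feature matrix (storing the training-set scaler), runs
#' [bayes_optimize()] for `n_trials` cross-validated evaluations, and fits
#' the best configuration on the full training set.
#'
#' @param train an [instance_table()] (typically the synthetic SMOTE set
#'   from [generate_training_set()]) with labels for `task`.
#' @param task `"nihss"` or `"mrc"`.
#' @param family `"svm"` or `"ensemble"`.
#' @param n_trials,cv_folds,surrogate,space passed to [bayes_optimize()].
#' @param seed RNG seed for the whole training run.
#' @param include_demographics,include_limb_level feature flags (defaults
#'   `FALSE`, the reproduction configuration).
#' @return object of class `drift_grader`: list with the fitted `grader_fit`,
#'   `task`, `family`, `hyperparameters`, `cv_objective_history`, `scaler`
#'   and feature flags. Use [predict.drift_grader()] on new instance tables.
#' @export
train_grader <- function(train, task = c("nihss", "mrc"),
                         family = c("svm", "ensemble"),
                         n_trials = 30L, cv_folds = 5L, seed = 1L,
                         space = NULL, surrogate = "gp",
                         include_demographics = FALSE,
                         include_limb_level = FALSE) {
  task <- match.arg(task)
  family <- match.arg(family)
  fm <- to_feature_matrix(train, labels = task,
                          include_demographics = include_demographics,
                          include_limb_level = include_limb_level,
                          standardize = TRUE)
  opt <- bayes_optimize(fm$x, fm$y, family = family, n_trials = n_trials,
                        cv_folds = cv_folds, seed = seed, space = space,
                        surrogate = surrogate)
  fit <- train_final(fm$x, fm$y, opt$best_hyperparameters, family = family,
                     seed = seed)
  structure(list(fit = fit, task = task, family = family,
                 hyperparameters = opt$best_hyperparameters,
                 cv_objective_history = opt$history$objective,
                 best_cv_objective = opt$best_objective,
                 scaler = fm$scaler, classes = levels(fm$y),
                 include_demographics = include_demographics,
                 include_limb_level = include_limb_level, seed = seed),
            class = "drift_grader")
}

#' @export
print.drift_grader <- function(x, ...) {
  hp <- paste(names(x$hyperparameters),
              vapply(x$hyperparameters, function(v) format(v, digits = 3), ""),
              sep = "=", collapse = ", ")
  cat(sprintf("<drift_grader> task %s, family %s\n  best CV error %.3f over %d trials\n  %s\n",
              x$task, x$family, x$best_cv_objective,
              length(x$cv_objective_history), hp))
  invisible(x)
}

#' Grade limb instances with a trained model
#'
#' @param object a `drift_grader` from [train_grader()].
#' @param newdata an [instance_table()] (features are standardized with the
#'   stored training scaler) or a raw-unit numeric feature matrix.
#' @param ... unused.
#' @return a `grading_result` (see [predict.grader_fit()]).
#' @export
predict.drift_grader <- function(object, newdata, ...) {
  x <- if (inherits(newdata, "instance_table") || is.data.frame(newdata)) {
    to_feature_matrix(instance_table(newdata), labels = "none",
                      include_demographics = object$include_demographics,
                      include_limb_level = object$include_limb_level,
                      standardize = TRUE, scaler = object$scaler)$x
  } else {
    scaler_apply(as.matrix(newdata), object$scaler)
  }
  predict(object$fit, x)
}
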