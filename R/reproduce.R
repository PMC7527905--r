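## One-shot reproduction: SMOTE -> Bayes-optimized training -> hold-out
## evaluation on the 60 original limb instances, per task x family x seed.

#' Run one SMOTE + optimize + train + evaluate pipeline
#'
#' @param table labeled [instance_table()] (default the packaged clinical
#'   table).
#' @param task `"nihss"` or `"mrc"`.
#' @param family `"svm"` or `"ensemble"`.
#' @param seed seed controlling SMOTE and the optimizer/training run.
#' @param n_per_class,k SMOTE settings (task default 120/80 per class, k 5).
#' @param n_trials,cv_folds,surrogate optimizer settings (defaults 30, 5,
#'   `"gp"`).
#' @return list with the `model` (a `drift_grader`), the `bundle`
#'   (train/test split) and the hold-out `report` (an `evaluation_report`;
#'   binary reports use NIHSS 0 as the positive class).
#' @export
grade_pipeline <- function(table = table2_instances(),
                           task = c("nihss", "mrc"),
                           family = c("svm", "ensemble"), seed = 1L,
                           n_per_class = NULL, k = 5L, n_trials = 30L,
                           cv_folds = 5L, surrogate = "gp") {
  task <- match.arg(task)
  family <- match.arg(family)
  bundle <- generate_training_set(table, task = task,
                                  n_per_class = n_per_class, k = k,
                                  seed = seed)
  model <- train_grader(bundle$train, task = task, family = family,
                        n_trials = n_trials, cv_folds = cv_folds,
                        seed = seed, surrogate = surrogate)
  result <- predict(model, bundle$test)
  truth <- bundle$test[[task]]
  report <- evaluate_grading(result, truth)
  list(model = model, bundle = bundle, report = report)
}

report_row <- function(task, family, seed, pipe) {
  r <- pipe$report
  data.frame(task = task, family = family, seed = seed,
             train_n = nrow(pipe$bundle$train), test_n = nrow(pipe$bundle$test),
             accuracy = r$accuracy, sensitivity = r$sensitivity,
             specificity = r$specificity, precision = r$precision,
             f1 = r$f1, auc = r$auc)
}

#' Reproduce the grading study across seeds
#'
#' For every task in `tasks`, family in `families` and seed in `seeds`:
#' SMOTE-generate the balanced synthetic training set (120 per NIHSS class /
#' 80 per MRC class, 240 instances), Bayes-optimize hyperparameters over
#' `n_trials` cross-validated evaluations, fit the best configuration, and
#' evaluate on the 60 original hold-out instances. Single-run metrics
#' fluctuate with the SMOTE and search seeds, so the summary reports the
#' across-seed median of each metric.
#'
#' @param table labeled [instance_table()] (default the packaged clinical
#'   table).
#' @param tasks,families subsets of `c("nihss","mrc")` /
#'   `c("svm","ensemble")`.
#' @param seeds integer vector of seeds (one full pipeline run each).
#' @param n_trials,cv_folds,k,surrogate pipeline settings.
#' @param verbose print one line per completed run.
#' @return list with `per_seed` (one row per run: accuracy, sensitivity,
#'   specificity, precision, f1, auc) and `summary` (across-seed medians per
#'   task x family).
#' @export
run_reproduction <- function(table = table2_instances(),
                             tasks = c("nihss", "mrc"),
                             families = c("svm", "ensemble"),
                             seeds = 1:20, n_trials = 30L, cv_folds = 5L,
                             k = 5L, surrogate = "gp", verbose = FALSE) {
  rows <- list()
  for (task in tasks) for (family in families) for (seed in seeds) {
    pipe <- grade_pipeline(table, task = task, family = family, seed = seed,
                           k = k, n_trials = n_trials, cv_folds = cv_folds,
                           surrogate = surrogate)
    rows[[length(rows) + 1L]] <- report_row(task, family, seed, pipe)
    if (verbose)
      message(sprintf("%s/%s seed %d: accuracy %.3f, AUC %.3f",
                      task, family, seed,
                      pipe$report$accuracy, pipe$report$auc))
  }
  per_seed <- do.call(rbind, rows)
  metric_cols <- c("accuracy", "sensitivity", "specificity", "precision",
                   "f1", "auc")
  combos <- unique(per_seed[, c("task", "family")])
  summary <- do.call(rbind, lapply(seq_len(nrow(combos)), function(i) {
    sel <- per_seed$task == combos$task[i] & per_seed$family == combos$family[i]
    med <- vapply(metric_cols, function(mc) stats::median(per_seed[sel, mc]), 0)
    cbind(combos[i, ], n_seeds = sum(sel), as.data.frame(as.list(med)))
  }))
  rownames(summary) <- NULL
  list(per_seed = per_seed, summary = summary)
}
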