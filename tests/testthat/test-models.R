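# Bayes-optimized SVM / ensemble graders.

test_that("stratified folds balance every class to within one instance", {
  set.seed(2)
  y <- factor(rep(c("a", "b", "c"), c(120, 80, 40)))
  fold <- stratified_folds(y, 5)
  for (cl in levels(y)) {
    per_fold <- table(fold[y == cl])
    expect_lte(max(per_fold) - min(per_fold), 1)
  }
})

test_that("separable data is solved within 30 trials, matching a grid oracle", {
  d <- blob_data(n_per_class = 50, gap = 8, seed = 1)
  opt <- bayes_optimize(d$x, d$y, "svm", n_trials = 30, cv_folds = 5,
                        seed = 1)
  expect_equal(opt$best_objective, 0)

  # independent oracle: exhaustive coarse grid over the same space
  set.seed(99)
  fold <- stratified_folds(d$y, 5)
  grid_errors <- sapply(c("linear", "radial", "polynomial"), function(kern)
    sapply(c(0.1, 1, 10), function(cost)
      sapply(c(0.01, 0.1, 1), function(gamma)
        driftgrade:::cv_misclassification(
          d$x, d$y, fold, list(kernel = kern, cost = cost, gamma = gamma,
                               degree = 3), "svm", seed = 7))))
  expect_equal(min(grid_errors), 0)
  expect_lte(opt$best_objective, min(grid_errors))
})

test_that("a single trial yields a one-entry history equal to the best", {
  d <- blob_data(n_per_class = 20, seed = 2)
  opt <- bayes_optimize(d$x, d$y, "svm", n_trials = 1, seed = 3)
  expect_equal(nrow(opt$history), 1L)
  expect_equal(opt$best_objective, opt$history$objective[1])
})

test_that("optimization is deterministic under a fixed seed", {
  d <- blob_data(n_per_class = 15, gap = 3, seed = 4)
  o1 <- bayes_optimize(d$x, d$y, "svm", n_trials = 6, seed = 11)
  o2 <- bayes_optimize(d$x, d$y, "svm", n_trials = 6, seed = 11)
  expect_identical(o1$history, o2$history)
  expect_identical(o1$best_hyperparameters, o2$best_hyperparameters)
})

test_that("the returned best objective is the history minimum", {
  d <- blob_data(n_per_class = 15, gap = 2, seed = 5)
  for (fam in c("svm", "ensemble")) {
    opt <- bayes_optimize(d$x, d$y, fam, n_trials = 8, seed = 13)
    expect_equal(opt$best_objective, min(opt$history$objective))
    expect_equal(nrow(opt$history), 8L)
  }
})

test_that("every ensemble method interpolates separable training data", {
  d <- blob_data(n_per_class = 30, gap = 8, seed = 6)
  for (meth in c("adaboost", "gradient_boost", "bagging", "rusboost")) {
    hp <- list(method = meth, n_learners = 60, learn_rate = 0.3,
               max_depth = 4)
    fit <- train_final(d$x, d$y, hp, "ensemble", seed = 1)
    res <- predict(fit, d$x)
    expect_equal(mean(res$grade == d$y), 1, info = meth)
    expect_equal(unname(rowSums(res$scores)), rep(1, nrow(d$x)),
                 tolerance = 1e-9)
  }
})

test_that("the SVM fit interpolates separable data and scores sum to one", {
  d <- blob_data(n_per_class = 30, gap = 8, seed = 7)
  fit <- train_final(d$x, d$y, list(kernel = "radial", cost = 10, gamma = 0.1),
                     "svm", seed = 1)
  res <- predict(fit, d$x)
  expect_equal(mean(res$grade == d$y), 1)
  expect_equal(unname(rowSums(res$scores)), rep(1, nrow(d$x)),
               tolerance = 1e-9)
  expect_true(all(res$grade == colnames(res$scores)[max.col(res$scores)]))
})

test_that("single-class training data is rejected", {
  x <- matrix(stats::rnorm(30), ncol = 3)
  y <- factor(rep("a", 10))
  expect_error(train_final(x, y, list(kernel = "linear", cost = 1, gamma = 1),
                           "svm"), class = "dg_invalid_labels")
  expect_error(bayes_optimize(x, y, "svm"), class = "dg_invalid_labels")
})

test_that("prediction is equivariant to instance permutation", {
  d <- blob_data(n_per_class = 25, gap = 3, seed = 8)
  fit <- train_final(d$x, d$y,
                     list(method = "gradient_boost", n_learners = 40,
                          learn_rate = 0.2, max_depth = 3), "ensemble")
  perm <- sample(nrow(d$x))
  r1 <- predict(fit, d$x)
  r2 <- predict(fit, d$x[perm, ])
  expect_identical(as.character(r2$grade), as.character(r1$grade)[perm])
  expect_equal(r2$scores, r1$scores[perm, ])
})

test_that("feature-contract and non-finite inputs are rejected at predict time", {
  d <- blob_data(n_per_class = 10, gap = 8, seed = 9)
  fit <- train_final(d$x, d$y, list(kernel = "linear", cost = 1, gamma = 1),
                     "svm")
  wrong <- d$x; colnames(wrong) <- c("a", "b", "c")
  expect_error(predict(fit, wrong), class = "dg_feature_contract")
  nai <- d$x; nai[3, 2] <- NaN
  expect_error(predict(fit, nai), class = "dg_invalid_input")
})

test_that("classification trees agree with rpart on a clean split", {
  skip_if_not_installed("rpart")
  set.seed(10)
  x <- matrix(stats::runif(200), ncol = 2, dimnames = list(NULL, c("f1", "f2")))
  y <- factor(ifelse(x[, 1] > 0.5, "a", "b"))
  tree <- driftgrade:::.cart_fit_cls(x, as.integer(y) - 1L,
                                     rep(1 / 100, 100), 2L, 4L, 5L)
  ours <- driftgrade:::.cart_predict_class(tree, x)
  rp <- rpart::rpart(y ~ ., data.frame(y = y, x), method = "class",
                     control = rpart::rpart.control(maxdepth = 4, cp = 0,
                                                    xval = 0))
  theirs <- predict(rp, data.frame(x), type = "class")
  expect_equal(levels(y)[ours + 1L], as.character(theirs))
})

test_that("end-to-end grader predicts labels of the correct task", {
  tab <- table2_instances()
  b <- generate_training_set(tab, "nihss", seed = 2)
  model <- train_grader(b$train, "nihss", "svm", n_trials = 3, seed = 2)
  expect_s3_class(model, "drift_grader")
  expect_length(model$cv_objective_history, 3L)
  res <- predict(model, b$test)
  expect_setequal(levels(res$grade), c("0", "1"))
  expect_equal(length(res$grade), 60L)
  expect_equal(unname(rowSums(res$scores)), rep(1, 60), tolerance = 1e-9)
})
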