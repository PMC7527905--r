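# Confusion matrices, binary/macro metrics, ROC and AUC.

table3_cm <- function(tp, fn, fp, tn) {
  confusion(truth = rep(c("0", "1"), c(tp + fn, fp + tn)),
            predicted = c(rep("0", tp), rep("1", fn),
                          rep("0", fp), rep("1", tn)),
            classes = c("0", "1"))
}

test_that("confusion counts match hand tallies and respect class order", {
  cm <- confusion(c(0, 0, 1, 1), c(0, 1, 1, 1), classes = c(0, 1))
  expect_equal(unclass(unname(cm)), rbind(c(1L, 1L), c(0L, 2L)))
  expect_equal(sum(cm), 4L)

  perfect <- confusion(c("a", "b", "c"), c("a", "b", "c"))
  expect_true(all(perfect == diag(3)))
  expect_error(confusion(1:3, 1:2), class = "dg_invalid_input")
  expect_error(confusion(c("a", "z"), c("a", "a"), classes = c("a", "b")),
               class = "dg_invalid_input")
})

test_that("published binary metrics are recovered from their unique matrices", {
  # brute force: among all 2x2 matrices with row sums 40 (grade 0) and 20
  # (grade 1), exactly one reproduces each published metric row
  match_metrics <- function(target) {
    hits <- list()
    for (tp in 0:40) for (tn in 0:20) {
      m <- suppressWarnings(  # degenerate corners of the grid divide by zero
        binary_metrics(table3_cm(tp, 40 - tp, 20 - tn, tn), "0"))
      got <- round(unlist(m[c("accuracy", "sensitivity", "specificity",
                              "precision", "f1")]), 3)
      if (all(got == target)) hits[[length(hits) + 1]] <- c(tp = tp, tn = tn)
    }
    hits
  }
  svm_hits <- match_metrics(c(0.800, 0.825, 0.750, 0.868, 0.846))
  expect_length(svm_hits, 1L)
  expect_equal(svm_hits[[1]], c(tp = 33, tn = 15))

  ens_hits <- match_metrics(c(0.833, 0.875, 0.750, 0.875, 0.875))
  expect_length(ens_hits, 1L)
  expect_equal(ens_hits[[1]], c(tp = 35, tn = 15))
})

test_that("all-correct binary matrix scores 1 everywhere; 0/0 warns and gives 0", {
  m <- binary_metrics(table3_cm(40, 0, 0, 20), "0")
  expect_equal(unlist(m[1:5], use.names = FALSE), rep(1, 5))

  # no positive predictions: precision 0/0
  expect_warning(m0 <- binary_metrics(table3_cm(0, 40, 0, 20), "0"),
                 class = "dg_zero_division")
  expect_equal(m0$precision, 0)
  expect_equal(m0$f1, 0)
})

test_that("macro one-vs-rest metrics match a hand-computed 3-class matrix", {
  cm <- structure(rbind(c(10L, 3L, 0L), c(2L, 8L, 3L), c(0L, 2L, 32L)),
                  dimnames = list(truth = c("7", "8", "9"),
                                  predicted = c("7", "8", "9")),
                  class = c("confusion_matrix", "matrix"))
  m <- multiclass_metrics(cm)
  expect_equal(m$accuracy, 50 / 60)
  expect_equal(m$sensitivity, mean(c(10 / 13, 8 / 13, 32 / 34)))
  expect_equal(m$per_class$precision,
               c(10 / 12, 8 / 13, 32 / 35))

  perfect <- confusion(rep(c("7", "8", "9"), 5), rep(c("7", "8", "9"), 5))
  mp <- multiclass_metrics(perfect)
  expect_equal(c(mp$accuracy, mp$sensitivity, mp$specificity,
                 mp$precision, mp$f1), rep(1, 5))
})

test_that("uniform random predictions give macro sensitivity near 1/c", {
  set.seed(8)
  truth <- rep(c("a", "b", "c"), each = 200)
  sens <- replicate(50, {
    pred <- sample(c("a", "b", "c"), 600, replace = TRUE)
    multiclass_metrics(confusion(truth, pred))$sensitivity
  })
  expect_equal(mean(sens), 1 / 3, tolerance = 0.02)
})

test_that("accuracy is invariant to simultaneous class permutation", {
  set.seed(9)
  truth <- sample(c("7", "8", "9"), 60, replace = TRUE)
  pred <- sample(c("7", "8", "9"), 60, replace = TRUE)
  a1 <- multiclass_metrics(confusion(truth, pred, c("7", "8", "9")))$accuracy
  a2 <- multiclass_metrics(confusion(truth, pred, c("9", "7", "8")))$accuracy
  expect_equal(a1, a2)
})

test_that("ROC endpoints, separability and tie conventions hold", {
  roc <- roc_curve(c(0.9, 0.8, 0.2, 0.1), c("p", "p", "n", "n"), "p")
  expect_equal(roc$auc, 1)
  expect_equal(roc$fpr[1], 0); expect_equal(roc$tpr[1], 0)
  expect_equal(roc$fpr[length(roc$fpr)], 1)
  expect_equal(roc$tpr[length(roc$tpr)], 1)

  ties <- roc_curve(rep(0.5, 6), rep(c("p", "n"), 3), "p")
  expect_equal(ties$auc, 0.5)

  expect_error(roc_curve(1:4, rep("p", 4)), class = "dg_undefined_auc")
})

test_that("trapezoidal AUC equals the brute-force U-statistic on random instances", {
  set.seed(13)
  for (rep_i in 1:100) {
    n <- sample(4:20, 1)
    truth <- c("p", "n", sample(c("p", "n"), n - 2, replace = TRUE))
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # forces ties
    expect_equal(roc_curve(scores, truth, "p")$auc,
                 auc_ustat(scores, truth, "p"))
  }
})

test_that("AUC agrees with an independent implementation and is rank-invariant", {
  skip_if_not_installed("pROC")
  set.seed(14)
  truth <- sample(c("p", "n"), 40, replace = TRUE, prob = c(0.6, 0.4))
  scores <- stats::rnorm(40) + 1.2 * (truth == "p")
  ours <- roc_curve(scores, truth, "p")$auc
  theirs <- as.numeric(pROC::auc(pROC::roc(
    response = truth, predictor = scores, levels = c("n", "p"),
    direction = "<", quiet = TRUE)))
  expect_equal(ours, theirs, tolerance = 1e-12)
  # invariance under a strictly increasing transform
  expect_equal(roc_curve(exp(3 * scores), truth, "p")$auc, ours)
})

test_that("mean one-vs-rest AUC matches per-class binary oracles", {
  set.seed(15)
  truth <- rep(c("7", "8", "9"), each = 3)
  scores <- matrix(stats::runif(27), 9, 3, dimnames = list(NULL, c("7", "8", "9")))
  scores <- scores / rowSums(scores)
  got <- mean_ovr_auc(scores, truth)
  manual <- sapply(c("7", "8", "9"), function(cl)
    auc_ustat(scores[, cl], ifelse(truth == cl, "pos", "neg"), "pos"))
  expect_equal(unname(got$auc), unname(manual))
  expect_equal(got$mean_auc, mean(manual))

  perfect <- diag(3)[rep(1:3, each = 3), ]
  colnames(perfect) <- c("7", "8", "9")
  expect_equal(mean_ovr_auc(perfect, truth)$mean_auc, 1)
  const <- matrix(1 / 3, 9, 3, dimnames = list(NULL, c("7", "8", "9")))
  expect_equal(mean_ovr_auc(const, truth)$mean_auc, 0.5)

  expect_warning(
    m <- mean_ovr_auc(scores, rep(c("7", "8"), c(5, 4))),
    class = "dg_class_absent")
  expect_length(m$auc, 2L)
})
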