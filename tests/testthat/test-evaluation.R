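test_that("folds partition the data with preserved class ratio", {
  labs <- rep(c("HC", "ScZ"), each = 50)
  folds <- makeFolds(labs, k = 10, seed = 1)
  tests <- lapply(folds, `[[`, "test")
  expect_identical(sort(unlist(tests)), 1:100)
  expect_true(all(lengths(tests) == 10))
  for (f in folds) {
    expect_identical(sort(c(f$train, f$test)), 1:100)
    expect_length(intersect(f$train, f$test), 0)
  }
  # 60/40 imbalance: each fold holds 6 and 4 (+/- 1)
  labs2 <- rep(c("ScZ", "HC"), c(60, 40))
  folds2 <- makeFolds(labs2, k = 10, seed = 2)
  for (f in folds2) {
    expect_lte(abs(sum(labs2[f$test] == "ScZ") - 6), 1)
    expect_lte(abs(sum(labs2[f$test] == "HC") - 4), 1)
  }
  expect_error(makeFolds(rep(c("HC", "ScZ"), c(5, 95)), k = 10), "folds")
})

test_that("subject-unit folds never split a subject", {
  subj <- rep(sprintf("s%02d", 1:20), each = 15)
  labs <- rep(rep(c("HC", "ScZ"), each = 10), each = 15)
  folds <- makeFolds(labs, k = 5, unit = "subject", subjectIds = subj,
                     seed = 3)
  expect_identical(sort(unlist(lapply(folds, `[[`, "test"))),
                   seq_along(labs))
  for (f in folds)
    expect_length(intersect(subj[f$train], subj[f$test]), 0)
  expect_error(makeFolds(labs, k = 5, unit = "subject"), "subjectIds")
})

test_that("confusion metrics evaluate the standard formulas in percent", {
  truth <- rep(c("ScZ", "HC"), c(50, 50))
  pred <- c(rep("ScZ", 50), rep("HC", 40), rep("ScZ", 10))
  m <- confusionMetrics(truth, pred)
  expect_equal(unname(m["sensitivity"]), 100)
  expect_equal(unname(m["specificity"]), 80)
  expect_equal(unname(m["precision"]), 83.33, tolerance = 1e-4)
  expect_equal(unname(m["accuracy"]), 90)
  expect_equal(unname(m["f1"]), 90.91, tolerance = 1e-4)
  expect_equal(unname(m["fpr"]), 20)
  expect_identical(attr(m, "counts"),
                   c(TP = 50L, FP = 10L, TN = 40L, FN = 0L))
  # all correct
  perfect <- confusionMetrics(truth, truth)
  expect_equal(unname(perfect[c("sensitivity", "specificity", "precision",
                                "accuracy", "f1")]), rep(100, 5))
  expect_equal(unname(perfect["fpr"]), 0)
  expect_error(confusionMetrics(c("HC", "XX"), c("HC", "HC")), "unknown")
  expect_warning(confusionMetrics(rep("ScZ", 4), rep("ScZ", 4)),
                 "undefined")
})

test_that("metric identities hold over random confusion tables", {
  set.seed(11)
  for (i in 1:25) {
    n <- sample(20:200, 1)
    truth <- sample(c("HC", "ScZ"), n, replace = TRUE, prob = c(0.4, 0.6))
    pred <- ifelse(stats::runif(n) < 0.7, truth,
                   sample(c("HC", "ScZ"), n, replace = TRUE))
    if (length(unique(truth)) < 2 || length(unique(pred)) < 2) next
    m <- confusionMetrics(truth, pred)
    cts <- attr(m, "counts")
    # FPR = 100 - specificity
    expect_equal(unname(m["fpr"]), 100 - unname(m["specificity"]))
    # accuracy = prevalence-weighted sensitivity/specificity
    P <- cts["TP"] + cts["FN"]; N <- cts["TN"] + cts["FP"]
    expect_equal(unname(m["accuracy"]),
                 unname((m["sensitivity"] * P + m["specificity"] * N) /
                          (P + N)))
    # F1 lies between min and max of sensitivity and precision
    expect_gte(m["f1"], min(m["sensitivity"], m["precision"]) - 1e-9)
    expect_lte(m["f1"], max(m["sensitivity"], m["precision"]) + 1e-9)
    # label-swap symmetry: exchanging class roles swaps Sen and Spec
    flip <- function(x) ifelse(x == "ScZ", "HC", "ScZ")
    ms <- confusionMetrics(flip(truth), flip(pred))
    expect_equal(unname(ms["sensitivity"]), unname(m["specificity"]))
    expect_equal(unname(ms["specificity"]), unname(m["sensitivity"]))
  }
})

test_that("ROC curves behave at the extremes and against pROC", {
  truth <- rep(c("HC", "ScZ"), each = 20)
  sep <- c(stats::runif(20, 0, 0.4), stats::runif(20, 0.6, 1))
  r <- rocPoints(truth, sep)
  expect_equal(attr(r, "auc"), 1)
  expect_identical(c(r$fpr[1], r$tpr[1]), c(0, 0))
  expect_identical(c(tail(r$fpr, 1), tail(r$tpr, 1)), c(1, 1))
  # random scores: AUC near one half
  set.seed(13)
  truth2 <- rep(c("HC", "ScZ"), each = 100)
  rand <- stats::runif(200)
  expect_lt(abs(attr(rocPoints(truth2, rand), "auc") - 0.5), 0.1)
  # reversing scores flips the AUC
  a1 <- attr(rocPoints(truth2, rand), "auc")
  a2 <- attr(rocPoints(truth2, -rand), "auc")
  expect_equal(a1 + a2, 1, tolerance = 1e-9)
  expect_error(rocPoints(rep("ScZ", 5), stats::runif(5)), "both classes")
  # cross-check against an independent implementation
  skip_if_not_installed("pROC")
  scores <- stats::runif(100)
  truth3 <- sample(c("HC", "ScZ"), 100, replace = TRUE)
  ours <- attr(rocPoints(truth3, scores), "auc")
  theirs <- as.numeric(pROC::auc(pROC::roc(
    response = truth3, predictor = scores, levels = c("HC", "ScZ"),
    direction = "<", quiet = TRUE)))
  expect_equal(ours, theirs, tolerance = 1e-9)
})

test_that("fold aggregation computes mean and sample sd over folds", {
  mkReport <- function(i, acc) {
    truth <- rep(c("ScZ", "HC"), each = 50)
    wrong <- round((100 - acc))
    pred <- truth
    if (wrong > 0) pred[seq_len(wrong)] <- "HC"
    lobemel:::.foldReport(i, truth, pred, ifelse(pred == "ScZ", 0.9, 0.1))
  }
  reports <- list(mkReport(1, 90), mkReport(2, 92))
  rr <- aggregateFolds(reports, region = "frontal")
  s <- rr@summary
  expect_equal(s$mean[s$metric == "accuracy"], 91)
  expect_equal(s$sd[s$metric == "accuracy"], sd(c(90, 92)))
  # identical folds -> zero spread
  same <- aggregateFolds(list(mkReport(1, 90), mkReport(2, 90)))
  expect_true(all(same@summary$sd == 0))
  # equal-sized folds: mean of fold accuracies equals pooled accuracy
  pooledAcc <- 100 * (2 * 100 - 10 - 8) / 200
  expect_equal(s$mean[s$metric == "accuracy"], pooledAcc)
})

test_that("cross-validation scores every image exactly once out of fold", {
  toy <- toyImageSet(20, 16, seed = 5)
  res <- crossValidate(toy$images, toy$labels, config = cnnConfig(16),
                       k = 4, epochs = 3, batchSize = 8, seed = 9,
                       region = "toy")
  expect_s4_class(res, "RegionResult")
  expect_length(res@folds, 4)
  counts <- vapply(res@folds, function(f) sum(f@counts), 0)
  expect_identical(sum(counts), 20)          # every image scored once
  expect_true(all(counts >= 4 & counts <= 6)) # class ratio within +/- 1
  expect_true(is.finite(res@pooledAuc))
  expect_identical(res@region, "toy")
})
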