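test_that("one-vs-rest confusion counts enumerate correctly", {
  cc <- confusionCounts(c("A", "A", "B", "B"), c("A", "B", "B", "B"))
  a <- cc[cc$class == "A", ]
  expect_equal(c(a$TP, a$FN, a$FP, a$TN), c(1, 1, 0, 2))
  b <- cc[cc$class == "B", ]
  expect_equal(c(b$TP, b$FN, b$FP, b$TN), c(2, 0, 1, 1))

  perfect <- confusionCounts(c("x", "y"), c("x", "y"))
  expect_true(all(perfect$FP == 0) && all(perfect$FN == 0))

  allUnk <- confusionCounts(c("x", "y"), c("unknown", "unknown"))
  expect_true(all(allUnk$TP == 0) && all(allUnk$FP == 0))
  expect_true(all(allUnk$TP + allUnk$FP + allUnk$FN + allUnk$TN == 2))

  expect_error(confusionCounts(c("a", "b"), "a"), "length")
})

test_that("accuracy reduces to (TP+TN)/n and handles extremes", {
  # binary counts TP=3, TN=5, FP=1, FN=1 -> 0.8
  yTrue <- c(rep("pos", 4), rep("neg", 6))
  yPred <- c(rep("pos", 3), "neg", "pos", rep("neg", 5))
  expect_equal(accuracyScore(yTrue, yPred), 0.8)
  expect_equal(accuracyScore(c("a", "b"), c("a", "b")), 1)
  expect_equal(accuracyScore(c("a", "b"), c("b", "a")), 0)
  expect_error(accuracyScore(character(), character()), "empty")
})

test_that("precision/recall/F1 match hand arithmetic with safe zeros", {
  counts <- data.frame(class = "c1", TP = 2, FP = 1, FN = 2, TN = 5)
  r <- precisionRecallF1(counts)
  expect_equal(r$perClass$precision, 2 / 3)
  expect_equal(r$perClass$recall, 0.5)
  expect_equal(r$perClass$f1, 4 / 7)

  perfect <- precisionRecallF1(data.frame(class = "c", TP = 5, FP = 0,
                                          FN = 0, TN = 5))
  expect_equal(perfect$perClass$f1, 1)

  # P undefined (TP+FP = 0) reports 0 with a warning; F1 collapses to 0
  expect_warning(pr0 <- precisionRecallF1(
    data.frame(class = "c", TP = 0, FP = 0, FN = 3, TN = 5)),
    "zero denominator")
  expect_equal(pr0$perClass$precision, 0)
  expect_equal(pr0$perClass$f1, 0)

  two <- precisionRecallF1(
    data.frame(class = c("a", "b"), TP = c(2, 1), FP = c(1, 0),
               FN = c(2, 1), TN = c(5, 8)))
  expect_equal(unname(two$macro["f1"]),
               mean(c(4 / 7, 2 * (1 * 0.5) / 1.5)))
})

test_that("ARI agrees with the brute-force pair oracle", {
  a <- c(1, 1, 1, 2, 2, 2)
  b <- c(1, 1, 2, 1, 2, 2)  # contingency [[2,1],[1,2]]
  expect_equal(adjustedRandIndex(a, b), ariPairOracle(a, b),
               tolerance = 1e-12)

  expect_equal(adjustedRandIndex(c("x", "y", "x"), c("x", "y", "x")), 1)
  # symmetry and relabeling invariance
  expect_equal(adjustedRandIndex(a, b), adjustedRandIndex(b, a))
  expect_equal(adjustedRandIndex(a, b),
               adjustedRandIndex(c("q", "q", "q", "z", "z", "z"), b))

  set.seed(77)
  for (rep in 1:200) {
    n <- sample(4:12, 1)
    pa <- sample(1:3, n, replace = TRUE)
    pb <- sample(1:4, n, replace = TRUE)
    if (length(unique(pa)) == 1 && length(unique(pb)) == 1) next
    expect_equal(adjustedRandIndex(pa, pb), ariPairOracle(pa, pb),
                 tolerance = 1e-12)
  }
  expect_error(adjustedRandIndex("a", "a"), "at least two")
})

test_that("ARI agrees with an established implementation", {
  skip_if_not_installed("mclust")
  set.seed(5)
  for (rep in 1:25) {
    pa <- sample(1:4, 40, replace = TRUE)
    pb <- sample(1:3, 40, replace = TRUE)
    expect_equal(adjustedRandIndex(pa, pb),
                 unname(mclust::adjustedRandIndex(pa, pb)),
                 tolerance = 1e-12)
  }
})

test_that("independent labelings have ARI near zero on average", {
  set.seed(123)
  vals <- replicate(100, {
    adjustedRandIndex(sample(1:5, 500, replace = TRUE),
                      sample(1:5, 500, replace = TRUE))
  })
  expect_lt(abs(mean(vals)), 0.05)
})

test_that("trapezoid AUC equals the Mann-Whitney statistic", {
  r <- rocCurveAuc(c(0.9, 0.8, 0.4, 0.2), c(1, 1, 0, 0))
  expect_equal(r$auc, 1)
  expect_equal(rocCurveAuc(rep(0.5, 6), c(1, 0, 1, 0, 1, 0))$auc, 0.5)

  set.seed(9)
  for (rep in 1:20) {
    n <- sample(8:30, 1)
    scores <- sample(seq_len(1000), n) / 1000  # tie-free
    truth <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(truth) || all(truth)) next
    expect_equal(rocCurveAuc(scores, truth)$auc,
                 aucPairOracle(scores, truth))
  }
  expect_error(rocCurveAuc(c(0.1, 0.9), c(1, 1)), "positive and")
})

test_that("AUC agrees with an established implementation", {
  skip_if_not_installed("pROC")
  set.seed(13)
  scores <- runif(50)
  truth <- rbinom(50, 1, 0.4)
  expect_equal(rocCurveAuc(scores, truth)$auc,
               as.numeric(pROC::auc(pROC::roc(truth, scores,
                                              quiet = TRUE,
                                              direction = "<"))),
               tolerance = 1e-12)
})

test_that("precision-recall curves match exhaustive enumeration", {
  pr <- precisionRecallCurve(c(0.9, 0.8, 0.4, 0.2), c(1, 1, 0, 0))
  expect_equal(pr$precision[2], 1)
  expect_equal(pr$recall[2], 1)
  # perfect separation: precision 1 at recall 1
  expect_true(any(pr$precision == 1 & pr$recall == 1))

  allPos <- precisionRecallCurve(c(0.3, 0.6, 0.9), c(1, 1, 1))
  expect_true(all(allPos$precision == 1))

  scores <- c(0.9, 0.8, 0.4, 0.2); truth <- c(1, 0, 1, 0)
  pr2 <- precisionRecallCurve(scores, truth)
  for (i in seq_len(nrow(pr2))) {
    sel <- scores >= pr2$threshold[i]
    expect_equal(pr2$precision[i], sum(truth[sel]) / sum(sel))
    expect_equal(pr2$recall[i], sum(truth[sel]) / sum(truth))
  }
  expect_error(precisionRecallCurve(c(0.2, 0.4), c(0, 0)), "positive")
})

test_that("multiclass macro AUC averages one-vs-rest curves", {
  set.seed(3)
  probs <- softmaxRows(matrix(rnorm(60), 20, 3))
  colnames(probs) <- c("a", "b", "c")
  labels <- sample(colnames(probs), 20, replace = TRUE)
  r <- multiclassRocAuc(probs, labels)
  expect_length(r$perClass, 3)
  expect_equal(r$macroAuc,
               mean(vapply(colnames(probs), function(cl)
                 rocCurveAuc(probs[, cl], labels == cl)$auc, numeric(1))))
})
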