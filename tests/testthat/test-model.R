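test_that("valid convolution matches the nested-loop oracle", {
  I <- matrix(1:9, 3, byrow = TRUE)
  expect_equal(convolve2dValid(I, diag(2)),
               matrix(c(6, 8, 12, 14), 2, byrow = TRUE))
  expect_equal(convolve2dValid(I, matrix(1)), I)  # 1x1 identity kernel
  expect_equal(convolve2dValid(matrix(0, 4, 4), matrix(rnorm(4), 2)),
               matrix(0, 3, 3))

  set.seed(21)
  for (rep in 1:10) {
    I <- matrix(sample(-5:5, 64, replace = TRUE), 8, 8)
    km <- sample(1:4, 1); kn <- sample(1:4, 1)
    W <- matrix(sample(-3:3, km * kn, replace = TRUE), km, kn)
    expect_identical(convolve2dValid(I, W), convOracle(I, W))
    If <- matrix(rnorm(64), 8); Wf <- matrix(rnorm(km * kn), km, kn)
    expect_equal(convolve2dValid(If, Wf), convOracle(If, Wf),
                 tolerance = 1e-10)
  }
  expect_error(convolve2dValid(matrix(1, 2, 2), matrix(1, 3, 3)), "larger")
})

test_that("ReLU and max pooling behave per definition", {
  expect_equal(relu(-1), 0)
  expect_equal(relu(2), 2)
  expect_equal(relu(c(-3, 0, 5)), c(0, 0, 5))

  expect_equal(maxPool2d(matrix(1:4, 2), c(2, 2)), matrix(4))
  expect_equal(maxPool2d(matrix(7, 4, 4), c(2, 2)), matrix(7, 2, 2))
  m5 <- matrix(seq_len(25), 5, byrow = TRUE)
  expect_equal(dim(maxPool2d(m5, c(2, 2))), c(2L, 2L))  # row/col 5 dropped
  expect_equal(maxPool2d(m5, c(2, 2)), poolOracle(m5, 2, 2))
  set.seed(31)
  m <- matrix(rnorm(48), 6, 8)
  expect_equal(maxPool2d(m, c(3, 2)), poolOracle(m, 3, 2))
  expect_error(maxPool2d(matrix(1, 2, 2), c(3, 3)), "larger")
})

test_that("softmax is a shift-invariant probability over classes", {
  expect_equal(softmaxRows(c(0, 0)), matrix(0.5, 1, 2))
  set.seed(7)
  L <- matrix(rnorm(40) * 10, 8, 5)
  P <- softmaxRows(L)
  expect_equal(rowSums(P), rep(1, 8), tolerance = 1e-9)
  expect_true(all(P > 0))
  expect_equal(softmaxRows(L + 123.4), P, tolerance = 1e-9)
  # extreme logits stay finite thanks to max subtraction
  expect_false(anyNA(softmaxRows(matrix(c(1e4, 0), 1))))
})

test_that("categorical cross-entropy matches its closed forms", {
  y <- matrix(c(1, 0), 1)
  expect_equal(categoricalCrossEntropy(y, matrix(c(0.5, 0.5), 1)), log(2))
  expect_equal(categoricalCrossEntropy(y, y), 0, tolerance = 1e-6)
  k <- 7
  yk <- diag(k)
  expect_equal(categoricalCrossEntropy(yk, matrix(1 / k, k, k)), log(k))
  expect_gte(categoricalCrossEntropy(y, matrix(c(1e-12, 1), 1)), 0)
  expect_error(categoricalCrossEntropy(y, matrix(0.5, 1, 3)), "differ")
})

test_that("PCA equals the covariance eigendecomposition", {
  set.seed(12)
  X <- matrix(rnorm(200), 20, 10)
  p <- pcaFit(X, 3)
  ev <- eigen(cov(X))
  for (j in 1:3) {
    dotp <- abs(sum(p$rotation[, j] * ev$vectors[, j]))
    expect_equal(dotp, 1, tolerance = 1e-8)  # same axis up to sign
  }
  expect_equal(sort(p$sdev^2, decreasing = TRUE), p$sdev^2)
  # the training mean projects to the origin
  expect_equal(as.vector(pcaTransform(p, matrix(colMeans(X), 1))),
               rep(0, 3), tolerance = 1e-10)
  # collinear points: one component carries all variance
  line <- cbind(1:10, 2 * (1:10))
  pl <- pcaFit(line, 1)
  expect_equal(sum(pl$sdev^2) / sum(diag(cov(line))), 1, tolerance = 1e-12)
  expect_error(pcaFit(X, 50), "out of range")
})

test_that("model initialization respects ablation switches and the seed", {
  genes <- sprintf("g%02d", 1:64)
  pcaOnly <- buildModel(tinyModelConfig(enableConv = FALSE), genes,
                        c("a", "b"))
  expect_equal(nrow(pcaOnly@mlp[[1]]$W), 10L)  # pca_components only

  convOnly <- buildModel(tinyModelConfig(enablePca = FALSE), genes,
                         c("a", "b"))
  # branch A: 8x8 -> conv2x2 7x7 -> pool 3x3 -> pool 1x1 -> 1*8 filters
  # branch B: 8x8 -> conv3x3 6x6 -> pool 3x3 -> 9*6 filters
  expect_equal(nrow(convOnly@mlp[[1]]$W), 8L + 54L)

  m1 <- buildModel(tinyModelConfig(seed = 9L), genes, c("a", "b"))
  m2 <- buildModel(tinyModelConfig(seed = 9L), genes, c("a", "b"))
  expect_identical(m1@mlp, m2@mlp)
  expect_identical(m1@conv, m2@conv)
  m3 <- buildModel(tinyModelConfig(seed = 10L), genes, c("a", "b"))
  expect_false(identical(m1@mlp, m3@mlp))

  # impossible geometry reports the computed shapes
  bad <- modelConfig(convBranches = list(
    list(filters = 4L, kernel = c(2L, 2L),
         pools = list(c(9L, 9L)), dropout = 0)))
  expect_error(buildModel(bad, genes, c("a", "b")), "pooling window")
})

test_that("backprop gradients match finite differences", {
  cfg <- modelConfig(convBranches = list(
                       list(filters = 3L, kernel = c(2L, 2L),
                            pools = list(c(2L, 2L)), dropout = 0),
                       list(filters = 2L, kernel = c(3L, 3L),
                            pools = list(c(2L, 2L)), dropout = 0)),
                     pcaComponents = 4L, hiddenSizes = c(7L, 5L),
                     seed = 3L)
  genes <- sprintf("g%02d", 1:36)
  model <- buildModel(cfg, genes, c("A", "B", "C"))
  plan <- scTypeCNN:::.planFromConfig(cfg, 36, 3)
  params <- scTypeCNN:::.modelParams(model)
  set.seed(42)
  B <- 5
  flat <- matrix(abs(rnorm(B * 36)), B)
  pca <- matrix(rnorm(B * 4), B)
  Y <- scTypeCNN:::oneHot(sample(c("A", "B", "C"), B, TRUE),
                          c("A", "B", "C"))
  lg <- scTypeCNN:::nnLossGrad(plan, params, flat, pca, Y)
  h <- 1e-5
  numGrad <- function(mutate) {
    up <- scTypeCNN:::nnLossGrad(plan, mutate(params, h), flat, pca, Y)$loss
    dn <- scTypeCNN:::nnLossGrad(plan, mutate(params, -h), flat, pca, Y)$loss
    (up - dn) / (2 * h)
  }
  worst <- 0
  for (trial in 1:25) {
    kind <- sample(4, 1)
    if (kind == 1) {
      i <- sample(2, 1); r <- sample(length(params$conv[[i]]$K), 1)
      g <- lg$grads$conv[[i]]$K[r]
      nm <- numGrad(function(p, d) { p$conv[[i]]$K[r] <- p$conv[[i]]$K[r] + d; p })
    } else if (kind == 2) {
      i <- sample(2, 1); r <- sample(length(params$conv[[i]]$b), 1)
      g <- lg$grads$conv[[i]]$b[r]
      nm <- numGrad(function(p, d) { p$conv[[i]]$b[r] <- p$conv[[i]]$b[r] + d; p })
    } else if (kind == 3) {
      l <- sample(3, 1); r <- sample(length(params$mlp[[l]]$W), 1)
      g <- lg$grads$mlp[[l]]$W[r]
      nm <- numGrad(function(p, d) { p$mlp[[l]]$W[r] <- p$mlp[[l]]$W[r] + d; p })
    } else {
      l <- sample(3, 1); r <- sample(length(params$mlp[[l]]$b), 1)
      g <- lg$grads$mlp[[l]]$b[r]
      nm <- numGrad(function(p, d) { p$mlp[[l]]$b[r] <- p$mlp[[l]]$b[r] + d; p })
    }
    worst <- max(worst, abs(g - nm) / max(1e-8, abs(g) + abs(nm)))
  }
  expect_lt(worst, 1e-4)
})

test_that("training descends, is seed-reproducible, and degenerates safely", {
  fx <- tinyTrainedFixture()
  h <- trainingHistory(fx$model)
  expect_equal(nrow(h), 40L)
  expect_lt(h$train_loss[40], h$train_loss[1])

  # bit-identical rerun under the same seed
  d <- fx$data
  model2 <- buildModel(tinyModelConfig(), fx$filter$keptGeneIds,
                       sort(unique(d$labels[fx$split$train])))
  model2 <- trainModel(model2, fx$trainX, d$labels[fx$split$train],
                       epochs = 3L)
  model2b <- buildModel(tinyModelConfig(), fx$filter$keptGeneIds,
                        sort(unique(d$labels[fx$split$train])))
  model2b <- trainModel(model2b, fx$trainX, d$labels[fx$split$train],
                        epochs = 3L)
  expect_identical(trainingHistory(model2), trainingHistory(model2b))
  expect_identical(model2@mlp, model2b@mlp)

  # lr = 0 leaves the initial weights untouched
  frozenCfg <- tinyModelConfig(learningRate = 0)
  m0 <- buildModel(frozenCfg, fx$filter$keptGeneIds, c("acinar", "beta"))
  sub <- d$labels[fx$split$train] %in% c("acinar", "beta")
  xs <- ExpressionMatrix(exprValues(fx$trainX)[sub, , drop = FALSE],
                         normalized = TRUE)
  mT <- trainModel(m0, xs, d$labels[fx$split$train][sub], epochs = 2L)
  expect_identical(mT@mlp, m0@mlp)
  expect_identical(mT@conv, m0@conv)

  expect_error(trainModel(m0, xs, rep("acinar", nrow(exprValues(xs)))),
               "single class")
})

test_that("fine-tuning warm-starts and adapts the output layer", {
  fx <- tinyTrainedFixture()
  # no epochs, same classes: predictions unchanged
  same <- fineTune(fx$model, fx$testX, fx$testY, epochs = 0L)
  expect_identical(predictProba(same, fx$testX),
                   predictProba(fx$model, fx$testX))

  # new class set: output layer re-sized, earlier layers warm-started
  y2 <- ifelse(fx$testY == "beta", "beta", "notbeta")
  ft <- fineTune(fx$model, fx$testX, y2, epochs = 2L)
  expect_equal(classNames(ft), c("beta", "notbeta"))
  expect_equal(ncol(ft@mlp[[length(ft@mlp)]]$W), 2L)
  expect_error(fineTune(fx$model, fx$testX, character(0)), "non-empty")
})

test_that("fine-tuning on a shifted batch beats the unadapted model", {
  cfg <- tinySimConfig(seed = 23L)
  pair <- generateBatchPair(cfg, batchShift = 0.6)
  b1 <- pair$batch1; b2 <- pair$batch2
  filter <- fitGeneFilter(b1$matrix, 5)
  n1 <- normalizeCpmLog(applyGeneFilter(filter, b1$matrix))
  model <- buildModel(tinyModelConfig(seed = 2L), filter$keptGeneIds,
                      sort(unique(b1$labels)))
  model <- trainModel(model, n1, b1$labels, epochs = 30L)

  n2 <- normalizeCpmLog(applyGeneFilter(filter, b2$matrix))
  nTgt <- nrow(exprValues(n2))
  set.seed(91)
  tune <- sort(sample(nTgt, round(0.1 * nTgt)))
  rest <- setdiff(seq_len(nTgt), tune)
  subset2 <- function(idx) ExpressionMatrix(
    exprValues(n2)[idx, , drop = FALSE], normalized = TRUE)
  accOn <- function(m) {
    pr <- predictProba(m, subset2(rest))
    accuracyScore(b2$labels[rest],
                  colnames(pr)[max.col(pr, ties.method = "first")])
  }
  accBefore <- accOn(model)
  tuned <- fineTune(model, subset2(tune), b2$labels[tune], epochs = 15L)
  expect_gte(accOn(tuned), accBefore)
})

test_that("the compiled branch path equals composing the R primitives", {
  cfg <- modelConfig(convBranches = list(
                       list(filters = 4L, kernel = c(2L, 2L),
                            pools = list(c(2L, 2L), c(2L, 2L)),
                            dropout = 0),
                       list(filters = 3L, kernel = c(3L, 3L),
                            pools = list(c(2L, 2L)), dropout = 0)),
                     enablePca = FALSE, hiddenSizes = c(5L), seed = 2L)
  genes <- sprintf("g%02d", 1:81)  # 9x9 image
  model <- buildModel(cfg, genes, c("a", "b"))
  plan <- scTypeCNN:::.planFromConfig(cfg, 81, 2)
  params <- scTypeCNN:::.modelParams(model)
  set.seed(14)
  flat <- matrix(abs(rnorm(3 * 81)), 3)
  fwd <- scTypeCNN:::nnForward(plan, params, flat, NULL)

  manualBranch <- function(img, K, bias, kernel, pools) {
    feats <- lapply(seq_along(bias), function(f) {
      W <- matrix(K[, f], kernel[1], kernel[2], byrow = TRUE)
      A <- relu(convolve2dValid(img, W) + bias[f])
      for (w in pools) A <- maxPool2d(A, w)
      as.vector(t(A))  # row-major positions
    })
    unlist(feats)
  }
  for (b in 1:3) {
    img <- embedGeneImage(flat[b, ])$matrix
    want <- c(manualBranch(img, params$conv[[1]]$K, params$conv[[1]]$b,
                           c(2, 2), list(c(2, 2), c(2, 2))),
              manualBranch(img, params$conv[[2]]$K, params$conv[[2]]$b,
                           c(3, 3), list(c(2, 2))))
    # reconstruct the concatenated feature row the MLP saw
    X0 <- cbind(
      scTypeCNN:::.cppBranchForward(t(flat), plan$branches[[1]]$patchIdx0,
                                    params$conv[[1]]$K, params$conv[[1]]$b,
                                    plan$branches[[1]]$poolIdx0, 0, FALSE,
                                    0, FALSE)$feat,
      scTypeCNN:::.cppBranchForward(t(flat), plan$branches[[2]]$patchIdx0,
                                    params$conv[[2]]$K, params$conv[[2]]$b,
                                    plan$branches[[2]]$poolIdx0, 0, FALSE,
                                    0, FALSE)$feat)
    expect_equal(unname(X0[b, ]), want, tolerance = 1e-12)
  }
  expect_equal(rowSums(fwd$probs), rep(1, 3), tolerance = 1e-9)
})
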