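# Internal execution plan for the multi-scale network.
#
# Gene images are kept as flat row-major pixel vectors (one row per cell).
# The convolution/pooling branches run in compiled code (src/) as an
# im2col gather + GEMM per cell with fused ReLU/dropout/max-pooling; the
# MLP head runs as BLAS matmuls in R. All index matrices are precomputed
# once per model shape and passed down 0-based.

buildPlan <- function(side, branches, pcaComponents, hiddenSizes, nClasses) {
  br <- lapply(branches, function(b) {
    m <- as.integer(b$kernel[1]); n <- as.integer(b$kernel[2])
    if (m > side || n > side)
      stop("kernel (", m, "x", n, ") exceeds the ", side, "x", side,
           " gene image")
    if (length(b$pools) == 0L)
      stop("each convolution branch needs at least one pooling stage")
    convDims <- c(side - m + 1L, side - n + 1L)
    patchIdx0 <- .patchIndex(side, convDims, m, n)
    dims <- convDims
    poolIdx0 <- list()
    for (w in b$pools) {
      p <- as.integer(w[1]); q <- as.integer(w[2])
      outDims <- c(dims[1] %/% p, dims[2] %/% q)
      if (any(outDims < 1L))
        stop("pooling window (", p, "x", q, ") larger than its ",
             dims[1], "x", dims[2], " input map; reduce pooling or ",
             "kernel sizes for this image side (", side, ")")
      poolIdx0[[length(poolIdx0) + 1L]] <- .poolIndex(dims, outDims, p, q)
      dims <- outDims
    }
    list(filters = as.integer(b$filters), kernel = c(m, n),
         patchSize = m * n, dropout = b$dropout, convDims = convDims,
         convPos = prod(convDims), patchIdx0 = patchIdx0,
         poolIdx0 = poolIdx0, outPos = prod(dims),
         featWidth = as.integer(prod(dims) * b$filters))
  })
  convWidth <- sum(vapply(br, `[[`, integer(1), "featWidth"))
  inputWidth <- convWidth + as.integer(pcaComponents)
  if (inputWidth == 0L)
    stop("model has no features: enable at least one of the convolution ",
         "and PCA branches")
  list(side = side, branches = br, convWidth = convWidth,
       pcaComponents = as.integer(pcaComponents), inputWidth = inputWidth,
       layerSizes = c(inputWidth, hiddenSizes, nClasses))
}

# 0-based row-major pixel indices of each valid kernel placement
# (placements row-major over the conv output grid, kernel elements
# row-major within a placement).
.patchIndex <- function(side, convDims, m, n) {
  pos <- expand.grid(j = seq_len(convDims[2]), i = seq_len(convDims[1]))
  off <- expand.grid(dn = seq_len(n), dm = seq_len(m))
  idx <- matrix(0L, nrow(pos), nrow(off))
  for (e in seq_len(nrow(off)))
    idx[, e] <- (pos$i + off$dm[e] - 2L) * side + (pos$j + off$dn[e] - 2L)
  idx
}

# 0-based row-major map indices of each pooling window element.
.poolIndex <- function(inDims, outDims, p, q) {
  pos <- expand.grid(j = seq_len(outDims[2]), i = seq_len(outDims[1]))
  off <- expand.grid(dq = seq_len(q), dp = seq_len(p))
  idx <- matrix(0L, nrow(pos), nrow(off))
  for (e in seq_len(nrow(off)))
    idx[, e] <- ((pos$i - 1L) * p + off$dp[e] - 1L) * inDims[2] +
      (pos$j - 1L) * q + off$dq[e] - 1L
  idx
}

.addBias <- function(Z, b) Z + rep(b, each = nrow(Z))

# Full forward pass for a batch of cells. `training` enables dropout
# (masks drawn from a stream seeded off the current R RNG so runs are
# reproducible); with keepCache the intermediates needed by nnBackward are
# retained.
nnForward <- function(plan, params, flatB, pcaB, training = FALSE,
                      keepCache = FALSE) {
  B <- nrow(flatB)
  tflat <- t(flatB)
  feats <- vector("list", length(plan$branches))
  brCache <- vector("list", length(plan$branches))
  for (i in seq_along(plan$branches)) {
    br <- plan$branches[[i]]
    dropSeed <- if (training && br$dropout > 0)
      floor(stats::runif(1) * 2147483647) else 0
    res <- .cppBranchForward(tflat, br$patchIdx0, params$conv[[i]]$K,
                             params$conv[[i]]$b, br$poolIdx0, br$dropout,
                             training, dropSeed, keepCache)
    feats[[i]] <- res$feat
    if (keepCache)
      brCache[[i]] <- list(args = res$args,
                           invKeep = if (training && br$dropout > 0)
                             1 / (1 - br$dropout) else 1)
  }
  X0 <- do.call(cbind, c(feats, if (!is.null(pcaB)) list(pcaB)))
  As <- list(X0)
  Zs <- list()
  L <- length(params$mlp)
  for (l in seq_len(L)) {
    Z <- .addBias(As[[l]] %*% params$mlp[[l]]$W, params$mlp[[l]]$b)
    Zs[[l]] <- Z
    As[[l + 1L]] <- if (l < L) relu(Z) else Z
  }
  probs <- softmaxRows(As[[L + 1L]])
  res <- list(probs = probs, logits = As[[L + 1L]])
  if (keepCache)
    res$cache <- list(branches = brCache, As = As, Zs = Zs, B = B,
                      tflat = tflat)
  res
}

# Backpropagation for one batch: gradients of the mean categorical
# cross-entropy w.r.t. every trainable array. Gene images and PCA features
# are inputs, not parameters, so no gradient flows past the first conv /
# first MLP layer.
nnBackward <- function(plan, params, fwd, Y) {
  cache <- fwd$cache
  L <- length(params$mlp)
  grads <- list(conv = vector("list", length(plan$branches)),
                mlp = vector("list", L))
  d <- (fwd$probs - Y) / cache$B
  for (l in rev(seq_len(L))) {
    grads$mlp[[l]] <- list(W = crossprod(cache$As[[l]], d), b = colSums(d))
    if (l > 1L)
      d <- (d %*% t(params$mlp[[l]]$W)) * (cache$Zs[[l - 1L]] > 0)
    else
      d0 <- d %*% t(params$mlp[[1L]]$W)
  }
  colAt <- 0L
  for (i in seq_along(plan$branches)) {
    br <- plan$branches[[i]]
    bc <- cache$branches[[i]]
    g <- .cppBranchBackward(cache$tflat, br$patchIdx0,
                            d0[, colAt + seq_len(br$featWidth),
                               drop = FALSE],
                            bc$args, br$poolIdx0, br$filters, bc$invKeep)
    grads$conv[[i]] <- list(K = g$K, b = as.numeric(g$b))
    colAt <- colAt + br$featWidth
  }
  grads
}

# Loss and gradients in one call (dropout off); used by the finite-
# difference gradient check in the test suite.
nnLossGrad <- function(plan, params, flatB, pcaB, Y) {
  fwd <- nnForward(plan, params, flatB, pcaB, training = FALSE,
                   keepCache = TRUE)
  list(loss = categoricalCrossEntropy(Y, fwd$probs),
       grads = nnBackward(plan, params, fwd, Y))
}
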