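#' Model configuration
#'
#' Returns the resolved hyperparameter set of the classifier. The defaults
#' are the reference configuration: two parallel convolution branches (256
#' filters of 2x2 followed by two 2x2 max-pools; 128 filters of 5x5 followed
#' by one 3x3 max-pool), dropout 0.25 after each convolution, a 50-component
#' PCA branch, an MLP head with hidden sizes 128/128/64, plain SGD (no
#' momentum) at learning rate 1e-4, 300 epochs, batch size 32.
#'
#' @param convBranches list of branches, each a list with \code{filters},
#'   \code{kernel} (length-2), \code{pools} (list of length-2 windows) and
#'   \code{dropout}.
#' @param pcaComponents number of principal components concatenated with the
#'   convolutional features (0 disables the branch via \code{enablePca}).
#' @param hiddenSizes MLP hidden layer widths.
#' @param learningRate SGD learning rate.
#' @param epochs training epochs.
#' @param batchSize minibatch size.
#' @param seed integer seed controlling initialization, shuffling and
#'   dropout.
#' @param enableConv,enablePca ablation switches: drop the whole
#'   convolutional pooling branch set, or the PCA branch.
#' @return a \code{ModelConfig} list.
#' @export
modelConfig <- function(convBranches = list(
                          list(filters = 256L, kernel = c(2L, 2L),
                               pools = list(c(2L, 2L), c(2L, 2L)),
                               dropout = 0.25),
                          list(filters = 128L, kernel = c(5L, 5L),
                               pools = list(c(3L, 3L)),
                               dropout = 0.25)),
                        pcaComponents = 50L,
                        hiddenSizes = c(128L, 128L, 64L),
                        learningRate = 1e-4,
                        epochs = 300L,
                        batchSize = 32L,
                        seed = 1L,
                        enableConv = TRUE,
                        enablePca = TRUE) {
  for (b in convBranches) {
    stopifnot(length(b$kernel) == 2L, b$filters >= 1L)
    if (is.null(b$dropout)) stop("each conv branch needs a dropout fraction")
    assertScalarNumber(b$dropout, "dropout", 0, 1 - 1e-12)
  }
  if (any(hiddenSizes < 1L)) stop("hidden sizes must be positive")
  assertScalarNumber(learningRate, "learningRate", 0)
  assertScalarNumber(batchSize, "batchSize", 1)
  assertScalarNumber(epochs, "epochs", 0)
  if (enableConv && length(convBranches) == 0L)
    stop("enableConv = TRUE requires at least one branch")
  if (enablePca) assertScalarNumber(pcaComponents, "pcaComponents", 1)
  structure(list(convBranches = convBranches,
                 pcaComponents = as.integer(pcaComponents),
                 hiddenSizes = as.integer(hiddenSizes),
                 learningRate = learningRate, epochs = as.integer(epochs),
                 batchSize = as.integer(batchSize), seed = as.integer(seed),
                 enableConv = isTRUE(enableConv),
                 enablePca = isTRUE(enablePca)),
            class = "ModelConfig")
}

.activeBranches <- function(config)
  if (config$enableConv) config$convBranches else list()

.planFromConfig <- function(config, nGenes, nClasses) {
  side <- as.integer(ceiling(sqrt(nGenes)))
  buildPlan(side, .activeBranches(config),
            if (config$enablePca) config$pcaComponents else 0L,
            config$hiddenSizes, nClasses)
}

.glorot <- function(nin, nout, fanIn = nin, fanOut = nout) {
  lim <- sqrt(6 / (fanIn + fanOut))
  matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
}

#' Build an initialized (untrained) model
#'
#' Lays out the architecture for a given gene count and class set and draws
#' initial weights (Glorot uniform, zero biases) from the config seed; the
#' same seed gives bit-identical initial weights. The gene image side is
#' \code{ceiling(sqrt(nGenes))}.
#'
#' @param config a [modelConfig()].
#' @param geneIds ordered gene identifiers the model will expect.
#' @param classes ordered cell-type labels for the softmax head.
#' @return an untrained [CellTypeModel-class].
#' @export
buildModel <- function(config, geneIds, classes) {
  stopifnot(inherits(config, "ModelConfig"))
  geneIds <- as.character(geneIds)
  classes <- as.character(classes)
  if (length(classes) < 2L) stop("at least two classes are required")
  plan <- .planFromConfig(config, length(geneIds), length(classes))
  params <- withSeed(deriveSeed(config$seed, "init"),
                     .initParams(plan))
  new("CellTypeModel", config = unclass(config), geneIds = geneIds,
      classNames = classes, imageSide = plan$side,
      conv = params$conv, pca = list(), mlp = params$mlp,
      history = data.frame())
}

.initParams <- function(plan) {
  conv <- lapply(plan$branches, function(br) {
    list(K = .glorot(br$patchSize, br$filters,
                     fanIn = br$patchSize,
                     fanOut = br$patchSize * br$filters),
         b = rep(0, br$filters))
  })
  sizes <- plan$layerSizes
  mlp <- lapply(seq_len(length(sizes) - 1L), function(l) {
    list(W = .glorot(sizes[l], sizes[l + 1L]), b = rep(0, sizes[l + 1L]))
  })
  list(conv = conv, mlp = mlp)
}

.modelParams <- function(model) list(conv = model@conv, mlp = model@mlp)

# Normalized ExpressionMatrix -> list(flat images, pca features).
.modelInputs <- function(model, x, plan) {
  v <- if (is(x, "ExpressionMatrix")) {
    if (!isNormalized(x)) stop("input must be normalized (see normalizeCpmLog)")
    miss <- setdiff(model@geneIds, geneIds(x))
    if (length(miss))
      stop("input is missing model gene '", miss[1], "' (and ",
           length(miss) - 1L, " more); align and filter genes first")
    exprValues(x)[, model@geneIds, drop = FALSE]
  } else as.matrix(x)
  if (ncol(v) != length(model@geneIds))
    stop("input has ", ncol(v), " genes; model expects ",
         length(model@geneIds))
  flat <- imageMatrixFlat(v)$flat
  pcaB <- NULL
  if (model@config$enablePca) {
    if (!length(model@pca))
      stop("PCA branch enabled but not fitted; train the model first")
    # scores are standardized by the training-set component sd so that the
    # PCA branch enters the MLP on the same scale as the conv features
    pcaB <- sweep(pcaTransform(model@pca, v), 2L,
                  pmax(model@pca$sdev, 1e-8), "/")
    dimnames(pcaB) <- NULL
  }
  list(flat = flat, pca = pcaB, values = v)
}

#' Train the classifier with plain SGD
#'
#' Minimizes categorical cross-entropy with minibatch SGD (no momentum).
#' The PCA branch is fitted on the training cells at the start. Dropout is
#' active during training only. Per-epoch training loss, validation loss and
#' validation accuracy are recorded, and the weights from the epoch with the
#' best validation accuracy are returned (earliest epoch wins ties).
#' Shuffling, dropout and initialization are fully determined by the config
#' seed, so identical seeds and data give bit-identical histories.
#'
#' @param model an initialized [CellTypeModel-class] from [buildModel()].
#' @param x normalized training [ExpressionMatrix-class] (genes matching the
#'   model).
#' @param labels training cell-type labels.
#' @param valX,valLabels validation set (same preprocessing); when omitted,
#'   the training set doubles as validation set for checkpoint selection.
#' @param epochs override the config epoch count.
#' @return the trained [CellTypeModel-class]; its \code{history} slot holds
#'   the per-epoch metrics (see [trainingHistory()]).
#' @export
trainModel <- function(model, x, labels, valX = NULL, valLabels = NULL,
                       epochs = NULL) {
  stopifnot(is(model, "CellTypeModel"))
  config <- model@config
  epochs <- as.integer(epochs %||% config$epochs)
  labels <- as.character(labels)
  if (length(unique(labels)) < 2L)
    stop("training labels contain a single class; at least two are required")
  plan <- .planFromConfig(config, length(model@geneIds),
                          length(model@classNames))
  # fit the PCA branch on training cells only
  v <- if (is(x, "ExpressionMatrix")) exprValues(x)[, model@geneIds, drop = FALSE]
       else as.matrix(x)
  if (config$enablePca && !length(model@pca))
    model@pca <- pcaFit(v, config$pcaComponents)
  inp <- .modelInputs(model, x, plan)
  Y <- oneHot(labels, model@classNames)
  val <- NULL
  if (!is.null(valX)) {
    val <- .modelInputs(model, valX, plan)
    valY <- oneHot(as.character(valLabels), model@classNames)
  } else {
    val <- inp; valY <- Y
  }
  params <- .modelParams(model)
  n <- nrow(inp$flat)
  bs <- config$batchSize
  lr <- config$learningRate
  hist <- data.frame(epoch = integer(), train_loss = numeric(),
                     val_loss = numeric(), val_accuracy = numeric())
  best <- list(acc = -Inf, loss = Inf, params = params)
  withSeed(deriveSeed(config$seed, "shuffle"), {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      lossSum <- 0
      for (start in seq(1L, n, by = bs)) {
        rows <- ord[start:min(start + bs - 1L, n)]
        fwd <- nnForward(plan, params, inp$flat[rows, , drop = FALSE],
                         if (is.null(inp$pca)) NULL
                         else inp$pca[rows, , drop = FALSE],
                         training = TRUE, keepCache = TRUE)
        loss <- categoricalCrossEntropy(Y[rows, , drop = FALSE], fwd$probs)
        if (!is.finite(loss))
          stop("training diverged: non-finite loss at epoch ", ep,
               "; lower the learning rate")
        lossSum <- lossSum + loss * length(rows)
        grads <- nnBackward(plan, params, fwd, Y[rows, , drop = FALSE])
        params <- .sgdStep(params, grads, lr)
      }
      ev <- .evalParams(plan, params, val, valY)
      hist <- rbind(hist, data.frame(epoch = ep, train_loss = lossSum / n,
                                     val_loss = ev$loss,
                                     val_accuracy = ev$acc))
      if (ev$acc > best$acc)
        best <- list(acc = ev$acc, loss = ev$loss, params = params)
    }
  })
  model@conv <- best$params$conv
  model@mlp <- best$params$mlp
  model@history <- hist
  validObject(model)
  model
}

.sgdStep <- function(params, grads, lr) {
  for (i in seq_along(params$conv)) {
    params$conv[[i]]$K <- params$conv[[i]]$K - lr * grads$conv[[i]]$K
    params$conv[[i]]$b <- params$conv[[i]]$b - lr * grads$conv[[i]]$b
  }
  for (l in seq_along(params$mlp)) {
    params$mlp[[l]]$W <- params$mlp[[l]]$W - lr * grads$mlp[[l]]$W
    params$mlp[[l]]$b <- params$mlp[[l]]$b - lr * grads$mlp[[l]]$b
  }
  params
}

.evalParams <- function(plan, params, inp, Y) {
  fwd <- nnForward(plan, params, inp$flat, inp$pca, training = FALSE)
  pred <- max.col(fwd$probs, ties.method = "first")
  truth <- max.col(Y, ties.method = "first")
  list(loss = categoricalCrossEntropy(Y, fwd$probs),
       acc = mean(pred == truth))
}

#' Fine-tune a pretrained model on target data
#'
#' Continues SGD from the pretrained weights on a (typically small) labeled
#' subset of the target dataset. The target matrix must already be aligned
#' to the pretrained gene list ([alignGenes()] + [applyGeneFilter()] +
#' [normalizeCpmLog()]). When the target class set differs from the
#' pretrained one, the output layer is re-initialized for the target
#' classes; conv kernels, PCA and hidden layers are warm-started either way.
#'
#' @param pretrained a trained [CellTypeModel-class].
#' @param x normalized target [ExpressionMatrix-class].
#' @param labels target labels.
#' @param valX,valLabels optional validation data for checkpoint selection.
#' @param epochs fine-tuning epochs (default 30).
#' @return the fine-tuned [CellTypeModel-class].
#' @export
fineTune <- function(pretrained, x, labels, valX = NULL, valLabels = NULL,
                     epochs = 30L) {
  stopifnot(is(pretrained, "CellTypeModel"))
  labels <- as.character(labels)
  if (length(labels) == 0L) stop("fine-tuning requires a non-empty target set")
  targetClasses <- sort(unique(labels))
  model <- pretrained
  if (!identical(targetClasses, pretrained@classNames)) {
    config <- pretrained@config
    plan <- .planFromConfig(config, length(model@geneIds),
                            length(targetClasses))
    sizes <- plan$layerSizes
    L <- length(model@mlp)
    model@classNames <- targetClasses
    model@mlp[[L]] <- withSeed(deriveSeed(config$seed, "finetune"),
      list(W = .glorot(sizes[L], sizes[L + 1L]), b = rep(0, sizes[L + 1L])))
  }
  if (epochs == 0L) {
    validObject(model)
    return(model)
  }
  trainModel(model, x, labels, valX, valLabels, epochs = epochs)
}
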