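#' Class probabilities for new cells
#'
#' Deterministic forward pass (dropout disabled): repeated calls on the same
#' input return bit-identical matrices. The input must be normalized and
#' carry exactly the model's genes (use [alignGenes()], [applyGeneFilter()]
#' and [normalizeCpmLog()] on query data first).
#'
#' @param model a [CellTypeModel-class].
#' @param x normalized [ExpressionMatrix-class].
#' @return cells x classes probability matrix; rows sum to 1.
#' @export
predictProba <- function(model, x) {
  stopifnot(is(model, "CellTypeModel"))
  plan <- .planFromConfig(model@config, length(model@geneIds),
                          length(model@classNames))
  inp <- .modelInputs(model, x, plan)
  probs <- nnForward(plan, .modelParams(model), inp$flat, inp$pca)$probs
  dimnames(probs) <- list(
    if (is(x, "ExpressionMatrix")) cellIds(x) else rownames(inp$values),
    model@classNames)
  probs
}

#' Label cells with open-set rejection
#'
#' Assigns each cell the arg-max class when its maximum softmax probability
#' reaches \code{threshold}, and \code{"unknown"} otherwise, so cell types
#' absent from the reference are not forced into known classes. Comparison
#' is strict: \code{max < threshold} rejects, equality accepts. The compared
#' maximum is clipped to \code{1 - 1e-7} (a softmax is always below 1 in
#' exact arithmetic), so a threshold of 1 rejects every cell. Arg-max ties
#' are broken by the lowest class index.
#'
#' @param probabilities cells x classes probability matrix (from
#'   [predictProba()]), or a [CellTypeModel-class] together with \code{x}.
#' @param threshold rejection threshold in \[0, 1\] (default 0.97).
#' @param x when \code{probabilities} is a model: a normalized
#'   [ExpressionMatrix-class] to predict.
#' @return a [PredictionResult-class].
#' @export
predictWithRejection <- function(probabilities, threshold = 0.97, x = NULL) {
  if (is(probabilities, "CellTypeModel")) {
    if (is.null(x)) stop("supply the query data in x")
    probabilities <- predictProba(probabilities, x)
  }
  assertScalarNumber(threshold, "threshold", 0, 1)
  p <- as.matrix(probabilities)
  if (is.null(colnames(p)))
    colnames(p) <- paste0("class", seq_len(ncol(p)))
  if (is.null(rownames(p)))
    rownames(p) <- paste0("cell", seq_len(nrow(p)))
  mx <- pmin(apply(p, 1L, max), 1 - 1e-7)
  lab <- colnames(p)[max.col(p, ties.method = "first")]
  lab[mx < threshold] <- "unknown"
  new("PredictionResult", cellIds = rownames(p), probabilities = p,
      predictedLabels = lab, threshold = threshold)
}

#' Default rejection-threshold grid
#'
#' The standard sweep: 0.89 to 0.998 in steps of 0.002 (55 values).
#'
#' @param from,to,by grid limits and step.
#' @return numeric vector of thresholds.
#' @export
thresholdGrid <- function(from = 0.89, to = 0.998, by = 0.002) {
  g <- seq(from, to, by = by)
  if (g[length(g)] < to - 1e-12) g <- c(g, to)
  round(g, 10)
}

#' Accuracy across a grid of rejection thresholds
#'
#' Predicts once and scores the labeled evaluation set at each threshold.
#' Evaluation labels may include cell types the model was never trained on;
#' such cells are scored correct exactly when predicted \code{"unknown"}.
#' Cells of known types count as correct only when assigned their own type
#' (an \code{"unknown"} prediction for them is incorrect).
#'
#' @param model a [CellTypeModel-class].
#' @param x normalized evaluation [ExpressionMatrix-class].
#' @param labels true labels (may contain unseen types).
#' @param thresholds threshold vector (default [thresholdGrid()]).
#' @return data.frame with columns \code{threshold}, \code{accuracy} and
#'   \code{n_unknown}.
#' @export
sweepThreshold <- function(model, x, labels, thresholds = thresholdGrid()) {
  if (length(thresholds) == 0L) stop("thresholds must be non-empty")
  if (any(thresholds < 0 | thresholds > 1))
    stop("thresholds must lie in [0, 1]")
  probs <- predictProba(model, x)
  labels <- as.character(labels)
  if (length(labels) != nrow(probs))
    stop("labels length must match the number of cells")
  unseen <- !(labels %in% classNames(model))
  mx <- pmin(apply(probs, 1L, max), 1 - 1e-7)
  argmax <- colnames(probs)[max.col(probs, ties.method = "first")]
  res <- lapply(thresholds, function(th) {
    pred <- ifelse(mx < th, "unknown", argmax)
    correct <- ifelse(unseen, pred == "unknown", pred == labels)
    data.frame(threshold = th, accuracy = mean(correct),
               n_unknown = sum(pred == "unknown"))
  })
  do.call(rbind, res)
}
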