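#' @import methods
NULL

#' ExpressionMatrix: a cells x genes expression container
#'
#' Dense cells-as-rows expression matrix with unique cell and gene
#' identifiers carried as dimnames. Raw count matrices (the usual entry
#' point) are flagged \code{normalized = FALSE} and must be non-negative;
#' after CPM/log transformation the flag is set to \code{TRUE}.
#'
#' @slot values numeric matrix, cells in rows, genes in columns; dimnames
#'   hold cell ids (rows) and gene ids (columns).
#' @slot normalized logical scalar; \code{FALSE} for raw counts.
#'
#' @seealso [readExpressionMatrix()], [normalizeCpmLog()]
#' @export
setClass("ExpressionMatrix",
  representation(values = "matrix", normalized = "logical"))

setValidity("ExpressionMatrix", function(object) {
  v <- object@values
  msgs <- character()
  if (!is.numeric(v)) msgs <- c(msgs, "values must be a numeric matrix")
  if (is.null(rownames(v)) || is.null(colnames(v)))
    msgs <- c(msgs, "values must carry cell ids (rownames) and gene ids (colnames)")
  else {
    if (anyDuplicated(rownames(v))) {
      d <- unique(rownames(v)[duplicated(rownames(v))])
      msgs <- c(msgs, paste0("duplicate cell ids: ",
                             paste(utils::head(d, 5), collapse = ", ")))
    }
    if (anyDuplicated(colnames(v))) {
      d <- unique(colnames(v)[duplicated(colnames(v))])
      msgs <- c(msgs, paste0("duplicate gene ids: ",
                             paste(utils::head(d, 5), collapse = ", ")))
    }
  }
  if (length(object@normalized) != 1L || is.na(object@normalized))
    msgs <- c(msgs, "normalized must be TRUE or FALSE")
  else if (!object@normalized && is.numeric(v) && length(v) && min(v) < 0)
    msgs <- c(msgs, "raw count matrices must be non-negative")
  if (length(msgs)) msgs else TRUE
})

#' Construct an ExpressionMatrix
#'
#' @param values numeric matrix (cells x genes).
#' @param cellIds,geneIds optional id vectors; taken from dimnames when
#'   omitted.
#' @param normalized logical; \code{FALSE} for raw counts.
#' @return an [ExpressionMatrix-class] object.
#' @examples
#' m <- matrix(rpois(6, 5), 2, 3,
#'             dimnames = list(c("c1", "c2"), c("g1", "g2", "g3")))
#' ExpressionMatrix(m)
#' @export
ExpressionMatrix <- function(values, cellIds = rownames(values),
                             geneIds = colnames(values),
                             normalized = FALSE) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(cellIds)) stop("cell ids are required (rownames or cellIds)")
  if (is.null(geneIds)) stop("gene ids are required (colnames or geneIds)")
  dimnames(values) <- list(as.character(cellIds), as.character(geneIds))
  new("ExpressionMatrix", values = values, normalized = normalized)
}

#' @describeIn ExpressionMatrix-class the underlying cells x genes matrix
#' @param x an ExpressionMatrix.
#' @export
exprValues <- function(x) x@values

#' @describeIn ExpressionMatrix-class cell identifiers (row order)
#' @export
cellIds <- function(x) rownames(x@values)

#' @describeIn ExpressionMatrix-class gene identifiers (column order)
#' @export
geneIds <- function(x) colnames(x@values)

#' @describeIn ExpressionMatrix-class whether the matrix is normalized
#' @export
isNormalized <- function(x) x@normalized

#' @export
setMethod("dim", "ExpressionMatrix", function(x) dim(x@values))

setMethod("show", "ExpressionMatrix", function(object) {
  d <- dim(object@values)
  cat("ExpressionMatrix:", d[1], "cells x", d[2], "genes",
      if (object@normalized) "(normalized)" else "(raw counts)", "\n")
  frac0 <- if (length(object@values)) mean(object@values == 0) else NA
  cat(sprintf("  zero fraction: %.3f\n", frac0))
})

#' CellTypeModel: a trained multi-scale CNN cell-type classifier
#'
#' Holds everything needed for reproducible inference: the resolved
#' configuration, the gene list and image side used for embedding, the
#' convolution kernels and biases of each branch, the PCA centering/loadings,
#' the MLP weight matrices, and the ordered class names.
#'
#' @slot config resolved model configuration (see [modelConfig()]).
#' @slot geneIds ordered gene identifiers the model expects.
#' @slot classNames ordered cell-type labels; softmax columns follow this.
#' @slot imageSide side length of the square gene image.
#' @slot conv per-branch list with kernel matrix (patch x filters) and bias.
#' @slot pca list with center vector and rotation (genes x k), or empty.
#' @slot mlp list of layers, each with weight matrix W and bias b.
#' @slot history data.frame of per-epoch losses/accuracy (empty before
#'   training).
#' @export
setClass("CellTypeModel",
  representation(config = "list", geneIds = "character",
                 classNames = "character", imageSide = "integer",
                 conv = "list", pca = "ANY", mlp = "list",
                 history = "data.frame"))

setValidity("CellTypeModel", function(object) {
  msgs <- character()
  if (anyDuplicated(object@geneIds)) msgs <- c(msgs, "duplicate gene ids")
  if (anyDuplicated(object@classNames)) msgs <- c(msgs, "duplicate class names")
  nl <- length(object@mlp)
  if (nl > 0) {
    out <- object@mlp[[nl]]
    if (ncol(out$W) != length(object@classNames))
      msgs <- c(msgs, "output layer width must equal the number of classes")
  }
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "CellTypeModel", function(object) {
  cat("CellTypeModel:", length(object@classNames), "classes,",
      length(object@geneIds), "genes, image side", object@imageSide, "\n")
  pcaK <- if (isTRUE(object@config$enablePca)) object@config$pcaComponents
          else 0L
  cat("  conv branches:", length(object@conv),
      " | PCA components:", pcaK,
      if (isTRUE(object@config$enablePca) && !length(object@pca))
        "(not yet fitted)" else "", "\n")
  if (nrow(object@history))
    cat(sprintf("  trained %d epochs; best val accuracy %.4f\n",
                nrow(object@history), max(object@history$val_accuracy)))
  else cat("  (untrained: freshly initialized weights)\n")
})

#' @describeIn CellTypeModel-class ordered class labels of the softmax head
#' @param x a CellTypeModel.
#' @export
classNames <- function(x) x@classNames

#' @describeIn CellTypeModel-class per-epoch training history
#' @export
trainingHistory <- function(x) x@history

#' @describeIn CellTypeModel-class gene identifiers the model expects
#' @export
modelGeneIds <- function(x) x@geneIds

#' PredictionResult: per-cell class probabilities with open-set rejection
#'
#' @slot cellIds cell identifiers, one per row of \code{probabilities}.
#' @slot probabilities cells x classes softmax matrix (rows sum to 1).
#' @slot predictedLabels labels drawn from the model's classes or
#'   \code{"unknown"}.
#' @slot threshold rejection threshold used.
#' @export
setClass("PredictionResult",
  representation(cellIds = "character", probabilities = "matrix",
                 predictedLabels = "character", threshold = "numeric"))

setValidity("PredictionResult", function(object) {
  msgs <- character()
  n <- length(object@cellIds)
  if (nrow(object@probabilities) != n || length(object@predictedLabels) != n)
    msgs <- c(msgs, "cellIds, probabilities and predictedLabels must agree in length")
  if (n > 0) {
    rs <- rowSums(object@probabilities)
    if (max(abs(rs - 1)) > 1e-6)
      msgs <- c(msgs, "probability rows must sum to 1")
    mx <- pmin(apply(object@probabilities, 1, max), 1 - 1e-7)
    unk <- object@predictedLabels == "unknown"
    if (any(unk != (mx < object@threshold)))
      msgs <- c(msgs, "'unknown' must hold exactly when max probability < threshold")
  }
  if (length(object@threshold) != 1L || object@threshold < 0 || object@threshold > 1)
    msgs <- c(msgs, "threshold must be in [0, 1]")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "PredictionResult", function(object) {
  cat("PredictionResult:", length(object@cellIds), "cells,",
      ncol(object@probabilities), "classes, threshold", object@threshold, "\n")
  cat("  rejected as unknown:", sum(object@predictedLabels == "unknown"), "\n")
})

#' @describeIn PredictionResult-class predicted labels (with "unknown")
#' @param x a PredictionResult.
#' @export
predictedLabels <- function(x) x@predictedLabels

#' @describeIn PredictionResult-class the softmax probability matrix
#' @export
classProbabilities <- function(x) x@probabilities
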