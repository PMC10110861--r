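#' Read an expression matrix from disk
#'
#' Two on-disk layouts are supported. \code{"dense_delim"} is delimited text
#' (TSV or CSV, auto-detected) with a header row of gene ids and the first
#' column holding cell ids. \code{"mtx_triplet"} is Matrix Market coordinate
#' format with \code{genes.tsv} and \code{barcodes.tsv} sidecar files next to
#' the \code{.mtx} file (CellRanger-style). Matrices are oriented cells x
#' genes on return; a genes x cells MTX (the CellRanger convention) is
#' detected from the sidecar lengths and transposed.
#'
#' @param path file path (the \code{.mtx} file for \code{mtx_triplet}).
#' @param format \code{"dense_delim"} or \code{"mtx_triplet"}.
#' @return an [ExpressionMatrix-class] with \code{normalized = FALSE}.
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines(c("cell\tg1\tg2", "c1\t1\t0", "c2\t2\t3"), f)
#' readExpressionMatrix(f)
#' @export
readExpressionMatrix <- function(path, format = c("dense_delim", "mtx_triplet")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "dense_delim") {
    header <- readLines(path, n = 1L)
    if (!nzchar(header)) stop("malformed header: first line is empty in ", path)
    sep <- if (grepl("\t", header)) "\t" else ","
    df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1L,
                            check.names = FALSE, stringsAsFactors = FALSE)
    if (ncol(df) == 0L) stop("malformed header: no gene columns found in ", path)
    m <- as.matrix(df)
    if (!is.numeric(m)) stop("malformed matrix: non-numeric entries in ", path)
  } else {
    dir <- dirname(path)
    genesFile <- file.path(dir, "genes.tsv")
    cellsFile <- file.path(dir, "barcodes.tsv")
    if (!file.exists(genesFile) || !file.exists(cellsFile))
      stop("mtx_triplet requires genes.tsv and barcodes.tsv alongside ", path)
    sp <- Matrix::readMM(path)
    genes <- utils::read.table(genesFile, sep = "\t",
                               stringsAsFactors = FALSE)[[1]]
    cells <- utils::read.table(cellsFile, sep = "\t",
                               stringsAsFactors = FALSE)[[1]]
    m <- as.matrix(sp)
    if (nrow(m) == length(genes) && ncol(m) == length(cells)) {
      m <- t(m)  # genes x cells input: transpose to cells x genes
    } else if (!(nrow(m) == length(cells) && ncol(m) == length(genes))) {
      stop("mtx dimensions ", nrow(m), "x", ncol(m),
           " match neither sidecar orientation (", length(genes), " genes, ",
           length(cells), " cells)")
    }
    dimnames(m) <- list(cells, genes)
  }
  if (anyDuplicated(colnames(m))) {
    d <- unique(colnames(m)[duplicated(colnames(m))])
    stop("duplicate gene ids: ", paste(utils::head(d, 5), collapse = ", "))
  }
  if (min(m) < 0) stop("negative values found; raw counts must be non-negative")
  ExpressionMatrix(m, normalized = FALSE)
}

#' Write an expression matrix as dense delimited text
#'
#' Inverse of [readExpressionMatrix()] for the \code{dense_delim} layout;
#' write-then-read preserves ids and values.
#'
#' @param x an [ExpressionMatrix-class].
#' @param path output path.
#' @param sep field separator (default tab).
#' @return \code{path}, invisibly.
#' @export
writeExpressionMatrix <- function(x, path, sep = "\t") {
  stopifnot(is(x, "ExpressionMatrix"))
  df <- data.frame(cell_id = cellIds(x), exprValues(x),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("cell_id", geneIds(x))
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read per-cell labels
#'
#' Reads a two-column delimited file (cell id, cell-type label). Order is
#' preserved and labels are stripped of surrounding whitespace.
#'
#' @param path file path.
#' @return data.frame with columns \code{cell_id} and \code{label}.
#' @export
readLabels <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) stop("label file is empty (no cells): ", path)
  sep <- if (grepl("\t", first)) "\t" else ","
  hasHeader <- grepl("cell", strsplit(first, sep)[[1]][1], ignore.case = TRUE)
  df <- utils::read.table(path, header = hasHeader, sep = sep,
                          stringsAsFactors = FALSE,
                          colClasses = "character")
  if (nrow(df) == 0L) stop("label file is empty (no cells): ", path)
  if (ncol(df) < 2L) stop("label file must have two columns (cell_id, label)")
  data.frame(cell_id = trimws(df[[1]]), label = trimws(df[[2]]),
             stringsAsFactors = FALSE)
}

#' Match a label table to an expression matrix
#'
#' Joins labels to the matrix's cells (matrix row order); errors if any cell
#' is missing from the label table.
#'
#' @param x an [ExpressionMatrix-class].
#' @param labels data.frame from [readLabels()].
#' @return character vector of labels, one per matrix row.
#' @export
matchLabels <- function(x, labels) {
  idx <- match(cellIds(x), labels$cell_id)
  if (anyNA(idx)) {
    miss <- utils::head(cellIds(x)[is.na(idx)], 5)
    stop("cells absent from label file: ", paste(miss, collapse = ", "))
  }
  labels$label[idx]
}

#' Restrict two datasets to their shared genes
#'
#' Reference and query matrices are cut down to the intersection of their
#' gene ids, in the reference's gene order; cell rows are untouched. This is
#' how datasets from different platforms are integrated before training or
#' prediction.
#'
#' @param ref,query [ExpressionMatrix-class] objects.
#' @return list with elements \code{ref} and \code{query}.
#' @export
alignGenes <- function(ref, query) {
  shared <- intersect(geneIds(ref), geneIds(query))
  if (length(shared) == 0L)
    stop("the datasets share no genes; check that both use the same ",
         "gene identifier scheme")
  list(
    ref = ExpressionMatrix(exprValues(ref)[, shared, drop = FALSE],
                           normalized = isNormalized(ref)),
    query = ExpressionMatrix(exprValues(query)[, shared, drop = FALSE],
                             normalized = isNormalized(query))
  )
}

.CHECKPOINT_VERSION <- "sctypecnn-checkpoint-1"

#' Save / load a trained model checkpoint
#'
#' The checkpoint is a single-file archive holding the resolved config, gene
#' list, class names and every weight array; \code{loadModel(saveModel(m))}
#' reproduces predictions bit-identically.
#'
#' @param model a [CellTypeModel-class].
#' @param path checkpoint path.
#' @return \code{saveModel}: \code{path} invisibly; \code{loadModel}: the
#'   restored model.
#' @export
saveModel <- function(model, path) {
  stopifnot(is(model, "CellTypeModel"))
  payload <- list(version = .CHECKPOINT_VERSION,
                  config = model@config, geneIds = model@geneIds,
                  classNames = model@classNames, imageSide = model@imageSide,
                  conv = model@conv, pca = model@pca, mlp = model@mlp,
                  history = model@history)
  saveRDS(payload, path)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  if (!file.exists(path)) stop("checkpoint not found: ", path)
  payload <- tryCatch(readRDS(path), error = function(e)
    stop("incompatible or corrupted checkpoint (", conditionMessage(e), "): ",
         path, call. = FALSE))
  if (!is.list(payload) || !identical(payload$version, .CHECKPOINT_VERSION))
    stop("incompatible checkpoint: expected version ", .CHECKPOINT_VERSION,
         ", found ", if (is.list(payload)) payload$version %||% "<none>"
         else "<not a checkpoint>")
  new("CellTypeModel", config = payload$config, geneIds = payload$geneIds,
      classNames = payload$classNames, imageSide = payload$imageSide,
      conv = payload$conv, pca = payload$pca, mlp = payload$mlp,
      history = payload$history)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write predictions as TSV
#'
#' Emits one row per cell: cell id, predicted label, max probability, and one
#' column per class probability.
#'
#' @param pred a [PredictionResult-class].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writePredictions <- function(pred, path) {
  stopifnot(is(pred, "PredictionResult"))
  p <- pred@probabilities
  df <- data.frame(cell_id = pred@cellIds,
                   predicted_label = pred@predictedLabels,
                   max_probability = apply(p, 1, max),
                   p, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
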