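#' Fit a gene filter on raw counts
#'
#' Keeps genes observed (count > 0) in at least \code{minNonzeroCells} cells;
#' genes with fewer non-zero values are discarded. The filter is fit on the
#' reference/training data only and then applied to every partition and to
#' query data, so no information leaks from validation or test cells.
#'
#' @param x raw-count [ExpressionMatrix-class].
#' @param minNonzeroCells minimum number of cells with a non-zero count
#'   (default 200; "fewer than" is strict, so a gene seen in exactly
#'   \code{minNonzeroCells} cells is kept).
#' @return a \code{GeneFilter} list with \code{minNonzeroCells} and the
#'   ordered \code{keptGeneIds}.
#' @export
fitGeneFilter <- function(x, minNonzeroCells = 200) {
  stopifnot(is(x, "ExpressionMatrix"))
  if (isNormalized(x)) stop("gene filtering expects raw counts")
  assertScalarNumber(minNonzeroCells, "minNonzeroCells", 0)
  nz <- colSums(exprValues(x) > 0)
  keep <- nz >= minNonzeroCells
  if (!any(keep))
    stop("all ", length(nz), " genes have fewer than ", minNonzeroCells,
         " non-zero cells; lower minNonzeroCells")
  structure(list(minNonzeroCells = minNonzeroCells,
                 keptGeneIds = geneIds(x)[keep]),
            class = "GeneFilter")
}

#' Apply a fitted gene filter
#'
#' Restricts (and reorders) the columns of \code{x} to the filter's kept
#' genes. Apply after [alignGenes()] when the target is a query dataset.
#'
#' @param filter a \code{GeneFilter} from [fitGeneFilter()].
#' @param x an [ExpressionMatrix-class] containing every kept gene.
#' @return the restricted [ExpressionMatrix-class].
#' @export
applyGeneFilter <- function(filter, x) {
  stopifnot(inherits(filter, "GeneFilter"), is(x, "ExpressionMatrix"))
  missing <- setdiff(filter$keptGeneIds, geneIds(x))
  if (length(missing))
    stop("genes required by the filter are absent: ",
         paste(utils::head(missing, 5), collapse = ", "))
  ExpressionMatrix(exprValues(x)[, filter$keptGeneIds, drop = FALSE],
                   normalized = isNormalized(x))
}

#' CPM normalization with natural-log transform
#'
#' Per cell, each gene's count is divided by the cell's total count and
#' multiplied by \code{scale} (10,000 by default), so every cell's values sum
#' to exactly \code{scale} before the log step; then \code{log1p} is applied.
#' \code{log1p} rather than a bare log keeps zero counts at zero, which is
#' the only total choice for sparse count data.
#'
#' @param x raw-count [ExpressionMatrix-class].
#' @param scale per-cell target total before the log (default 10000).
#' @return a normalized [ExpressionMatrix-class].
#' @export
normalizeCpmLog <- function(x, scale = 10000) {
  stopifnot(is(x, "ExpressionMatrix"))
  if (isNormalized(x)) stop("matrix is already normalized")
  assertScalarNumber(scale, "scale", lo = 1e-12)
  v <- exprValues(x)
  totals <- rowSums(v)
  if (any(totals == 0)) {
    bad <- utils::head(cellIds(x)[totals == 0], 5)
    stop("cells with zero total count cannot be normalized: ",
         paste(bad, collapse = ", "))
  }
  out <- log1p(v / totals * scale)
  ExpressionMatrix(out, normalized = TRUE)
}

#' Split specification for train/validation/test partitioning
#'
#' @param fractions numeric length-3 vector (train, val, test) summing to 1;
#'   each fraction strictly inside (0, 1).
#' @param seed integer seed controlling the split.
#' @param stratified stratify by cell type (default TRUE) so rare types
#'   appear in every partition.
#' @return a \code{SplitSpec} list.
#' @export
splitSpec <- function(fractions = c(0.70, 0.15, 0.15), seed = 1L,
                      stratified = TRUE) {
  if (length(fractions) != 3L || any(fractions <= 0) || any(fractions >= 1))
    stop("fractions must be three values each in (0, 1)")
  if (abs(sum(fractions) - 1) > 1e-9)
    stop("fractions must sum to 1")
  structure(list(fractions = fractions, seed = as.integer(seed),
                 stratified = isTRUE(stratified)),
            class = "SplitSpec")
}

#' Split cells into train/validation/test index sets
#'
#' Index sets are disjoint and jointly cover all cells. Validation and test
#' sizes are \code{round(n * fraction)} with the remainder going to train.
#' Under stratification the same rule is applied within each cell type; a
#' type with fewer cells than partitions is placed wholly in train with a
#' warning. Identical seeds give identical splits.
#'
#' @param n number of cells, or an [ExpressionMatrix-class].
#' @param labels cell-type labels (required when \code{stratified}).
#' @param spec a [splitSpec()].
#' @return list of integer index vectors \code{train}, \code{val},
#'   \code{test}.
#' @export
splitDataset <- function(n, labels = NULL, spec = splitSpec()) {
  if (is(n, "ExpressionMatrix")) n <- nrow(exprValues(n))
  n <- as.integer(n)
  if (!is.null(labels) && length(labels) != n)
    stop("labels length (", length(labels), ") must match cell count (", n, ")")
  if (spec$stratified && is.null(labels))
    stop("stratified splitting requires labels")
  withSeed(deriveSeed(spec$seed, "split"), {
    if (!spec$stratified) {
      parts <- .splitIndices(sample.int(n), spec$fractions)
    } else {
      parts <- list(train = integer(), val = integer(), test = integer())
      for (cl in unique(labels)) {
        idx <- which(labels == cl)
        if (length(idx) < 3L) {
          warning("cell type '", cl, "' has only ", length(idx),
                  " cells; placing all of them in train")
          parts$train <- c(parts$train, idx)
        } else {
          p <- .splitIndices(idx[sample.int(length(idx))], spec$fractions)
          parts <- Map(c, parts, p)
        }
      }
      parts <- lapply(parts, sort)
    }
    parts
  })
}

# shuffledIdx is already randomly ordered; carve off val/test by rounding,
# remainder to train.
.splitIndices <- function(shuffledIdx, fractions) {
  n <- length(shuffledIdx)
  nVal <- round(n * fractions[2])
  nTest <- round(n * fractions[3])
  nTrain <- n - nVal - nTest
  list(train = shuffledIdx[seq_len(nTrain)],
       val = shuffledIdx[nTrain + seq_len(nVal)],
       test = shuffledIdx[nTrain + nVal + seq_len(nTest)])
}

#' Embed an expression vector as a square gene image
#'
#' A normalized per-cell expression vector of length F is reshaped row-major
#' into the smallest square matrix with side \code{ceiling(sqrt(F))}; the
#' trailing positions are zero-padded. Gene order is the stored (filtered)
#' gene order, so a given gene always occupies the same pixel.
#'
#' @param row numeric expression vector.
#' @param geneCount expected length F (defaults to \code{length(row)}); a
#'   mismatch is an error, which guards query data against the wrong gene
#'   list.
#' @return a \code{GeneImage} list with the square \code{matrix} and
#'   \code{sourceGeneCount}.
#' @examples
#' img <- embedGeneImage(1:10)
#' dim(img$matrix)  # 4 x 4, six zero pads
#' @export
embedGeneImage <- function(row, geneCount = length(row)) {
  f <- length(row)
  if (f < 1L) stop("expression vector must have at least one gene")
  if (f != geneCount)
    stop("expression vector has ", f, " genes but the model stores ",
         geneCount)
  s <- ceiling(sqrt(f))
  padded <- c(as.numeric(row), rep(0, s * s - f))
  structure(list(matrix = matrix(padded, nrow = s, byrow = TRUE),
                 sourceGeneCount = f),
            class = "GeneImage")
}

# All cells at once, kept flat in row-major order: row b of the result is
# cell b's padded image read row-by-row. The flat layout feeds the
# vectorized conv (see nn-plan.R); embedGeneImage() is the one-cell view.
imageMatrixFlat <- function(values) {
  f <- ncol(values)
  s <- ceiling(sqrt(f))
  if (s * s == f) return(list(flat = values, side = s))
  pad <- matrix(0, nrow(values), s * s - f)
  list(flat = cbind(values, pad, deparse.level = 0), side = s)
}
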