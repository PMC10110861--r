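#' Fit the PCA feature branch
#'
#' Centers the training matrix and keeps the top-\code{k} principal axes
#' (the leading eigenvectors of the training covariance, computed via SVD
#' through \code{stats::prcomp}). Fit on training cells only; validation,
#' test and query cells are projected with the stored center and loadings.
#'
#' @param x normalized cells x genes matrix (or [ExpressionMatrix-class]).
#' @param k number of components; must satisfy
#'   \code{k <= min(n_cells - 1, n_genes)}.
#' @return a \code{PCAModel} list with \code{center}, \code{rotation}
#'   (genes x k, orthonormal columns) and \code{sdev}.
#' @export
pcaFit <- function(x, k = 50L) {
  if (is(x, "ExpressionMatrix")) x <- exprValues(x)
  x <- as.matrix(x)
  k <- as.integer(k)
  kmax <- min(nrow(x) - 1L, ncol(x))
  if (k < 1L || k > kmax)
    stop("k = ", k, " out of range; need 1 <= k <= min(n_cells - 1, n_genes) = ",
         kmax)
  fit <- stats::prcomp(x, center = TRUE, scale. = FALSE, rank. = k)
  structure(list(center = fit$center,
                 rotation = fit$rotation[, seq_len(k), drop = FALSE],
                 sdev = fit$sdev[seq_len(k)]),
            class = "PCAModel")
}

#' Project data onto fitted principal axes
#'
#' \code{(x - center) \%*\% rotation}; projecting the training mean gives the
#' zero vector.
#'
#' @param pca a \code{PCAModel} from [pcaFit()].
#' @param x cells x genes matrix (or [ExpressionMatrix-class]) over the same
#'   genes, in the same order.
#' @return cells x k feature matrix.
#' @export
pcaTransform <- function(pca, x) {
  stopifnot(inherits(pca, "PCAModel"))
  if (is(x, "ExpressionMatrix")) x <- exprValues(x)
  x <- as.matrix(x)
  if (ncol(x) != length(pca$center))
    stop("gene count mismatch: data has ", ncol(x), ", PCA was fit on ",
         length(pca$center))
  sweep(x, 2L, pca$center) %*% pca$rotation
}
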