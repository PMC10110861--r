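# Network primitives. These are the building blocks of the classifier and
# are exported individually so each can be verified against independent
# oracles.

#' Valid 2D convolution (cross-correlation)
#'
#' Computes \code{S[i,j] = sum_m sum_n I[i+m-1, j+n-1] * W[m,n]} with no
#' padding, the form used throughout deep learning (no kernel flip). Output
#' shape is \code{(nrow(I)-m+1) x (ncol(I)-n+1)}.
#'
#' @param I numeric input matrix.
#' @param W numeric kernel, no larger than \code{I} in either dimension.
#' @return the feature map matrix.
#' @examples
#' convolve2dValid(matrix(1:9, 3, byrow = TRUE), diag(2)) # 2x2 map
#' @export
convolve2dValid <- function(I, W) {
  I <- as.matrix(I); W <- as.matrix(W)
  m <- nrow(W); n <- ncol(W)
  if (m > nrow(I) || n > ncol(I))
    stop("kernel (", m, "x", n, ") larger than input (",
         nrow(I), "x", ncol(I), ")")
  outR <- nrow(I) - m + 1L
  outC <- ncol(I) - n + 1L
  S <- matrix(0, outR, outC)
  for (dm in seq_len(m))
    for (dn in seq_len(n))
      S <- S + I[dm:(dm + outR - 1L), dn:(dn + outC - 1L), drop = FALSE] *
        W[dm, dn]
  S
}

#' Rectified linear activation
#'
#' Elementwise \code{max(0, x)}.
#'
#' @param x numeric scalar, vector, matrix or array.
#' @return same shape as \code{x}.
#' @export
relu <- function(x) {
  x[x < 0] <- 0
  x
}

#' Non-overlapping 2D max pooling
#'
#' Pools with stride equal to the window, so windows tile the map without
#' overlap; trailing rows/columns that do not fill a window are dropped
#' (floor division).
#'
#' @param x numeric matrix.
#' @param window integer length-2 window \code{(p, q)}.
#' @return pooled matrix of shape \code{floor(dim(x) / window)}.
#' @examples
#' maxPool2d(matrix(1:25, 5, byrow = TRUE), c(2, 2)) # 2x2, row/col 5 dropped
#' @export
maxPool2d <- function(x, window = c(2, 2)) {
  x <- as.matrix(x)
  p <- as.integer(window[1]); q <- as.integer(window[2])
  if (p > nrow(x) || q > ncol(x))
    stop("pooling window (", p, "x", q, ") larger than map (",
         nrow(x), "x", ncol(x), ")")
  outR <- nrow(x) %/% p
  outC <- ncol(x) %/% q
  out <- matrix(-Inf, outR, outC)
  for (dp in seq_len(p))
    for (dq in seq_len(q)) {
      rows <- (seq_len(outR) - 1L) * p + dp
      cols <- (seq_len(outC) - 1L) * q + dq
      out <- pmax(out, x[rows, cols, drop = FALSE])
    }
  out
}

#' Row-wise softmax
#'
#' \code{softmax(x)_j = exp(x_j) / sum_k exp(x_k)} applied to each row, with
#' the row maximum subtracted first for overflow safety (softmax is
#' shift-invariant, so the result is unchanged).
#'
#' @param logits numeric matrix (cells x classes) or vector.
#' @return matrix of probabilities; rows are positive and sum to 1.
#' @export
softmaxRows <- function(logits) {
  if (is.null(dim(logits))) logits <- matrix(logits, nrow = 1L)
  shifted <- logits - apply(logits, 1L, max)
  e <- exp(shifted)
  e / rowSums(e)
}

#' Categorical cross-entropy loss
#'
#' \code{J = -(1/n) sum_i sum_k y_ik * log(p_ik)} with predictions clipped
#' to \code{[eps, 1-eps]} so a confidently wrong probability of exactly zero
#' cannot produce an infinite loss.
#'
#' @param y one-hot truth matrix (n x k).
#' @param p probability matrix (n x k), rows summing to 1.
#' @param eps clipping constant (default 1e-7).
#' @return non-negative scalar loss.
#' @examples
#' categoricalCrossEntropy(matrix(c(1, 0), 1), matrix(c(0.5, 0.5), 1)) # log(2)
#' @export
categoricalCrossEntropy <- function(y, p, eps = 1e-7) {
  y <- as.matrix(y); p <- as.matrix(p)
  if (!all(dim(y) == dim(p)))
    stop("truth and prediction shapes differ: ",
         paste(dim(y), collapse = "x"), " vs ", paste(dim(p), collapse = "x"))
  p <- pmin(pmax(p, eps), 1 - eps)
  -sum(y * log(p)) / nrow(y)
}

# One-hot encode labels against a fixed class order.
oneHot <- function(labels, classes) {
  idx <- match(labels, classes)
  if (anyNA(idx))
    stop("labels outside the class set: ",
         paste(utils::head(unique(labels[is.na(idx)]), 5), collapse = ", "))
  Y <- matrix(0, length(labels), length(classes))
  Y[cbind(seq_along(labels), idx)] <- 1
  Y
}
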