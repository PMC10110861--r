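# Independent oracles used to verify the package's implementations.
# Each is written as directly as possible from first principles and shares
# no code with the implementation it checks.

# Valid cross-correlation by quadruple loop.
convOracle <- function(I, W) {
  m <- nrow(W); n <- ncol(W)
  out <- matrix(0, nrow(I) - m + 1, ncol(I) - n + 1)
  for (i in seq_len(nrow(out)))
    for (j in seq_len(ncol(out))) {
      acc <- 0
      for (a in seq_len(m))
        for (b in seq_len(n))
          acc <- acc + I[i + a - 1, j + b - 1] * W[a, b]
      out[i, j] <- acc
    }
  out
}

# Non-overlapping max pooling by explicit window extraction.
poolOracle <- function(x, p, q) {
  outR <- nrow(x) %/% p
  outC <- ncol(x) %/% q
  out <- matrix(0, outR, outC)
  for (i in seq_len(outR))
    for (j in seq_len(outC))
      out[i, j] <- max(x[((i - 1) * p + 1):(i * p), ((j - 1) * q + 1):(j * q)])
  out
}

# Adjusted Rand index by brute-force enumeration of all cell pairs.
ariPairOracle <- function(a, b) {
  n <- length(a)
  s11 <- sPairsA <- sPairsB <- 0
  for (i in seq_len(n - 1))
    for (j in (i + 1):n) {
      sa <- a[i] == a[j]
      sb <- b[i] == b[j]
      if (sa && sb) s11 <- s11 + 1
      if (sa) sPairsA <- sPairsA + 1
      if (sb) sPairsB <- sPairsB + 1
    }
  expected <- sPairsA * sPairsB / choose(n, 2)
  maxIndex <- (sPairsA + sPairsB) / 2
  if (maxIndex == expected) return(1)
  (s11 - expected) / (maxIndex - expected)
}

# AUC as the fraction of positive/negative pairs ranked correctly
# (Mann-Whitney U scaled by n+ * n-); ties count one half.
aucPairOracle <- function(scores, truth) {
  pos <- scores[as.logical(truth)]
  neg <- scores[!as.logical(truth)]
  cmp <- outer(pos, neg, ">") + 0.5 * outer(pos, neg, "==")
  mean(cmp)
}
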