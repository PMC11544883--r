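# independent brute-force pair-counting reference for the co-occurrence
# features, written against the definitions rather than the implementation
glcmOracle <- function(xsec, mask, qLow, qHigh, levels = 32L) {
  nA <- nrow(xsec); nZ <- ncol(xsec)
  bin1 <- function(x) {
    v <- (x - qLow) / (qHigh - qLow)
    v <- max(min(v, 1), 0)
    min(floor(v * levels), levels - 1L) + 1L
  }
  P <- matrix(0, levels, levels); n <- 0L
  for (a in seq_len(nA)) {
    a2 <- if (a == nA) 1L else a + 1L
    for (z in seq_len(nZ)) {
      if (mask[a, z] && mask[a2, z]) {
        i <- bin1(xsec[a, z]); j <- bin1(xsec[a2, z])
        P[i, j] <- P[i, j] + 1
        n <- n + 1L
      }
    }
  }
  P <- P / n
  contrast <- 0; energy <- 0; homog <- 0; entropy <- 0
  mi <- 0; mj <- 0
  for (i in 1:levels) for (j in 1:levels) {
    p <- P[i, j]
    contrast <- contrast + (i - j)^2 * p
    energy <- energy + p^2
    homog <- homog + p / (1 + abs(i - j))
    if (p > 0) entropy <- entropy - p * log2(p)
    mi <- mi + i * p; mj <- mj + j * p
  }
  si <- sqrt(sum(outer((1:levels - mi)^2, rep(1, levels)) * P))
  sj <- sqrt(sum(outer(rep(1, levels), (1:levels - mj)^2) * P))
  num <- sum(outer(1:levels - mi, 1:levels - mj) * P)
  corr <- if (si * sj > 0) num / (si * sj) else NA_real_
  list(contrast = contrast, correlation = corr, energy = energy,
       homogeneity = homog, entropy = entropy, nPairs = n)
}
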