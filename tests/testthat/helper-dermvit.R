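# Shared fixtures and independent oracles for the test suite.

# a 4-stage model small enough for fast unit tests (16 px input)
tinyConfig <- function(numClasses = 3L, seed = 1L, ...) {
  dermViTConfig(imageSize = 16, numClasses = numClasses,
                channels = c(8, 8, 16, 16), depths = c(1, 1, 1, 1),
                heads = c(1, 1, 2, 2), regionGrid = c(2, 2, 2, 1),
                topk = c(2, 4, 1, 1), strides = c(2, 2, 2, 2),
                scales = c(1, 2), seed = seed, ...)
}

# brute-force dense multi-head self-attention with the weights of a dhaLayer,
# written with explicit per-head loops (independent of the package's token
# plumbing apart from the input layout conversion)
denseMHSAOracle <- function(X, layer) {
  d <- dim(X)
  B <- d[1L]; C <- d[2L]; H <- d[3L]; W <- d[4L]
  T <- H * W
  p <- layer$params
  hd <- layer$d
  out <- array(0, dim(X))
  for (b in seq_len(B)) {
    tok <- matrix(0, T, C)
    for (h in seq_len(H)) for (w in seq_len(W))
      tok[(h - 1) * W + w, ] <- X[b, , h, w]
    Q <- tok %*% p$q$W + matrix(p$q$b, T, C, byrow = TRUE)
    K <- tok %*% p$k$W + matrix(p$k$b, T, C, byrow = TRUE)
    V <- tok %*% p$v$W + matrix(p$v$b, T, C, byrow = TRUE)
    O <- matrix(0, T, C)
    for (hh in seq_len(layer$heads)) {
      cols <- ((hh - 1) * hd + 1):(hh * hd)
      S <- Q[, cols] %*% t(K[, cols]) / sqrt(hd)
      A <- exp(S - apply(S, 1, max))
      A <- A / rowSums(A)
      O[, cols] <- A %*% V[, cols]
    }
    Y <- O %*% p$o$W + matrix(p$o$b, T, C, byrow = TRUE)
    for (h in seq_len(H)) for (w in seq_len(W))
      out[b, , h, w] <- Y[(h - 1) * W + w, ]
  }
  out
}

# Mann-Whitney rank AUC (ties handled by midranks); oracle for the
# pROC-backed implementation
rankAUC <- function(positive, scores) {
  r <- rank(scores)
  np <- sum(positive)
  nn <- sum(!positive)
  (sum(r[positive]) - np * (np + 1) / 2) / (np * nn)
}

# full-sort top-k oracle with lowest-index tie break
topkOracle <- function(row, k) {
  sort(order(-row)[seq_len(k)])
}

randomImage <- function(S = 16, seed = 1) {
  set.seed(seed)
  array(runif(S * S * 3), c(S, S, 3))
}
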