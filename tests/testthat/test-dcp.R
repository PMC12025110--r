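# Context pyramid: compression conv, pyramid pooling geometry and
# conservation, pyramid attention against a materialized-token oracle.

test_that("compression conv has the patch-merging contract", {
  layer <- compressLayer(3, 64, 4, seed = 1)
  expect_equal(countParameters(layer$params), 3 * 64 * 16 + 64) # 3136
  set.seed(1)
  X <- array(rnorm(3 * 224 * 224), c(1, 3, 224, 224))
  Y <- compress(X, layer)
  expect_equal(dim(Y), c(1, 64, 56, 56))

  # averaging kernel on constant input gives constant output
  avg <- layer
  avg$params$W <- matrix(1 / (3 * 16), 3 * 16, 64)
  avg$params$b <- numeric(64)
  Yc <- compress(array(2, c(1, 3, 8, 8)), avg)
  expect_equal(as.vector(Yc), rep(2, 64 * 4))

  expect_error(compress(array(0, c(1, 3, 9, 8)), layer), "divisible")
})

test_that("pyramid token counts follow the clamped closed form", {
  expect_equal(pyramidTokenCount(56, 56, c(1, 2, 4, 16)), 277)
  expect_equal(pyramidTokenCount(14, 14, c(1, 2, 4, 16)), 1 + 4 + 16 + 196)
  expect_equal(pyramidTokenCount(7, 7, c(1, 2, 4, 16)), 70)
  for (H in c(7, 14, 56)) {
    K <- array(rnorm(H * H * 2), c(1, 2, H, H))
    kv <- pyramidPoolKV(K, K, c(1, 2, 4, 16))
    expect_equal(kv$P, pyramidTokenCount(H, H, c(1, 2, 4, 16)))
    expect_equal(dim(kv$Kpsp), c(1, kv$P, 2))
  }
  # strictly fewer pooled tokens than pixels once the map exceeds all scales
  for (H in c(17, 32, 56)) {
    expect_lt(pyramidTokenCount(H, H, c(1, 2, 4, 16)), H * H)
  }
  expect_error(pyramidPoolKV(array(0, c(1, 2, 4, 4)),
                             array(0, c(1, 2, 4, 4)), integer(0)),
               "non-empty")
})

test_that("scale-1 pooling conserves the exact global mean", {
  set.seed(2)
  K <- array(rnorm(2 * 3 * 8 * 8), c(2, 3, 8, 8))
  kv <- pyramidPoolKV(K, K, c(1, 2, 4, 16))
  for (b in 1:2) for (ch in 1:3)
    expect_equal(kv$Kpsp[b, 1, ch], mean(K[b, ch, , ]), tolerance = 1e-12)
  # scales {1} yields exactly one token
  kv1 <- pyramidPoolKV(K, K, 1)
  expect_equal(kv1$P, 1)
})

test_that("pyramid attention matches a dense oracle over materialized tokens", {
  set.seed(3)
  Q <- array(rnorm(1 * 4 * 4 * 4), c(1, 4, 4, 4))
  K <- array(rnorm(1 * 4 * 4 * 4), c(1, 4, 4, 4))
  V <- array(rnorm(1 * 4 * 4 * 4), c(1, 4, 4, 4))
  kv <- pyramidPoolKV(K, V, c(1, 2))
  d <- 2 # two heads of width 2
  out <- pyramidAttention(Q, kv, d)
  qtok <- dermvit:::.toTokens(Q)
  otok <- matrix(0, 16, 4)
  for (h in 1:2) {
    cols <- ((h - 1) * d + 1):(h * d)
    Kp <- matrix(kv$Kpsp[1, , cols], 5)
    Vp <- matrix(kv$Vpsp[1, , cols], 5)
    S <- qtok[, cols] %*% t(Kp) / sqrt(d)
    A <- exp(S - apply(S, 1, max)); A <- A / rowSums(A)
    expect_equal(rowSums(A), rep(1, 16), tolerance = 1e-6)
    otok[, cols] <- A %*% Vp
  }
  oracle <- dermvit:::.fromTokens(otok, 1, 4, 4, 4)
  expect_lt(max(abs(out - oracle)), 1e-12)
})

test_that("pyramid attention degenerate cases", {
  set.seed(4)
  Q <- array(rnorm(32), c(1, 2, 4, 4))
  # single pooled token: every output equals that token's value
  kv <- pyramidPoolKV(array(rnorm(32), c(1, 2, 4, 4)),
                      array(rnorm(32), c(1, 2, 4, 4)), 1)
  out <- pyramidAttention(Q, kv, 2)
  for (ch in 1:2) expect_equal(as.vector(out[1, ch, , ]),
                               rep(kv$Vpsp[1, 1, ch], 16))
  # all pooled keys equal: output is the mean of pooled values
  K2 <- array(1, c(1, 2, 4, 4))
  V2 <- array(rnorm(32), c(1, 2, 4, 4))
  kv2 <- pyramidPoolKV(K2, V2, c(1, 2))
  out2 <- pyramidAttention(Q, kv2, 2)
  for (ch in 1:2) expect_equal(as.vector(out2[1, ch, , ]),
                               rep(mean(kv2$Vpsp[1, , ch]), 16),
                               tolerance = 1e-12)
  # Kpsp/Vpsp token-count mismatch
  kvBad <- kv2
  kvBad$Vpsp <- kvBad$Vpsp[, 1:3, , drop = FALSE]
  expect_error(pyramidAttention(Q, kvBad, 2), "differ")
})

test_that("dcpForward compresses and is deterministic", {
  layer <- dcpLayer(3, 8, 4, heads = 2, scales = c(1, 2, 4, 16), seed = 5)
  set.seed(5)
  X <- array(rnorm(2 * 3 * 32 * 32), c(2, 3, 32, 32))
  Y <- dcpForward(X, layer)
  expect_equal(dim(Y), c(2, 8, 8, 8))
  expect_identical(Y, dcpForward(X, layer))

  # scales {1}: attention over the single global-mean token makes the output
  # spatially constant
  l1 <- dcpLayer(3, 8, 4, heads = 2, scales = 1, seed = 5)
  Y1 <- dcpForward(X, l1)
  for (b in 1:2) for (ch in 1:8)
    expect_equal(max(Y1[b, ch, , ]) - min(Y1[b, ch, , ]), 0, tolerance = 1e-12)
})
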