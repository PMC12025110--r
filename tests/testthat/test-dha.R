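# Hierarchical routing attention: projection/partition geometry, region
# summaries, affinity scores, top-k routing, gathered attention, and the
# full block against a dense oracle.

test_that("projection partitions tokens by row-major tiles", {
  layer <- dhaLayer(channels = 64, heads = 2, regionGrid = 2, topk = 4, seed = 1)
  set.seed(1)
  X <- array(rnorm(64 * 64), c(1, 64, 8, 8))
  qkv <- projectAndPartition(X, layer)
  expect_equal(dim(qkv$Q), c(1, 2, 4, 16, 32)) # N=4 regions of 16 tokens, d=32

  # identity projection: tokens of Q equal the input pixels' channel vectors
  idLayer <- layer
  idLayer$params$q <- list(W = diag(64), b = numeric(64))
  qkvI <- projectAndPartition(X, idLayer)
  # pixel (row 0, col 7) on an 8x8 map with n=2 is token 8 of region 2 (1-based)
  g <- dermvit:::.regionGeom(8, 8, 2)
  expect_equal(g$reg[8], 2L)
  pos <- match(8L, g$tokens[[2]])
  expect_equal(as.vector(qkvI$Q[1, 1, 2, pos, ]), as.vector(X[1, 1:32, 1, 8]))
  expect_equal(as.vector(qkvI$Q[1, 2, 2, pos, ]), as.vector(X[1, 33:64, 1, 8]))

  expect_error(projectAndPartition(array(0, c(1, 64, 7, 8)), layer),
               "n=2")
})

test_that("region summaries are arithmetic means of region tokens", {
  mk <- function(vals) { # one region, two tokens, d = 2
    a <- array(0, c(1, 1, 1, 2, 2))
    a[1, 1, 1, , ] <- vals
    a
  }
  qkv <- list(Q = mk(rbind(c(1, 3), c(5, 7))), K = mk(matrix(0, 2, 2)),
              heads = 1L, d = 2L)
  s <- regionSummarize(qkv)
  expect_equal(as.vector(s$Qr[1, 1, 1, ]), c(3, 5))
  expect_equal(as.vector(s$Kr), c(0, 0))

  qkv$Q[1, 1, 1, 2, ] <- NA
  expect_error(regionSummarize(qkv), "NaN")

  # constant region: mean is that constant
  qkv2 <- list(Q = mk(rbind(c(2, -1), c(2, -1))), K = mk(matrix(1, 2, 2)),
               heads = 1L, d = 2L)
  expect_equal(as.vector(regionSummarize(qkv2)$Qr[1, 1, 1, ]), c(2, -1))
})

test_that("region affinity is an unnormalized dot-product matrix", {
  mk <- function(m) {
    a <- array(0, c(1, 1, nrow(m), ncol(m)))
    a[1, 1, , ] <- m
    a
  }
  s <- list(Qr = mk(rbind(c(1, 0), c(0, 2))), Kr = mk(rbind(c(1, 1), c(0, 1))))
  S <- regionAffinity(s)
  expect_equal(matrix(S[1, 1, , ], 2), rbind(c(1, 0), c(2, 2)))

  # orthogonal rows give a zero matrix, identity rows the identity
  s2 <- list(Qr = mk(rbind(c(1, 0), c(0, 1))), Kr = mk(rbind(c(0, 0), c(0, 0))))
  expect_true(all(regionAffinity(s2) == 0))
  s3 <- list(Qr = mk(diag(2)), Kr = mk(diag(2)))
  expect_equal(matrix(regionAffinity(s3)[1, 1, , ], 2), diag(2))

  s4 <- list(Qr = mk(diag(2)), Kr = array(0, c(1, 1, 3, 2)))
  expect_error(regionAffinity(s4), "differ")
})

test_that("top-k routing matches the full-sort oracle, ties break low", {
  expect_equal(routeTopk(matrix(c(0.2, 0.9, 0.5), 1), 1)[1, ], 2L)
  expect_equal(routeTopk(matrix(c(0.5, 0.5, 0.1), 1), 1)[1, ], 1L)
  expect_equal(routeTopk(matrix(runif(9), 3), 3),
               matrix(1:3, 3, 3, byrow = TRUE)) # k = N keeps every region
  expect_error(routeTopk(matrix(0, 2, 2), 3), "out of range")
  expect_error(routeTopk(matrix(0, 2, 2), 0), "out of range")

  set.seed(42)
  for (i in 1:100) {
    N <- sample(2:12, 1)
    row <- sample(round(runif(N, 0, 5), 1)) # coarse values force ties
    k <- sample(N, 1)
    expect_identical(as.integer(routeTopk(matrix(row, 1), k)[1, ]),
                     as.integer(topkOracle(row, k)))
  }

  # nesting: the retained set for k is a subset of that for k+1
  set.seed(7)
  S <- matrix(rnorm(64), 8)
  for (k in 1:7) {
    a <- routeTopk(S, k)
    b <- routeTopk(S, k + 1)
    for (i in 1:8) expect_true(all(a[i, ] %in% b[i, ]))
  }
})

test_that("gathered attention reproduces dense attention when k = N", {
  layer <- dhaLayer(channels = 64, heads = 2, regionGrid = 2, topk = 4, seed = 5)
  set.seed(9)
  X <- array(rnorm(64 * 64), c(1, 64, 8, 8))
  qkv <- projectAndPartition(X, layer)
  rt <- routeTopk(regionAffinity(regionSummarize(qkv)), 4)
  got <- gatherAndAttend(qkv, rt, returnWeights = TRUE)

  # weights: nonnegative, sum to 1 per query, attend exactly k*(HW/N) tokens
  for (i in 1:4) {
    A <- got$weights[[1]][[1]][[i]]
    expect_equal(ncol(A), 4 * 16)
    expect_true(all(A >= 0))
    expect_equal(rowSums(A), rep(1, 16), tolerance = 1e-12)
  }

  # against the hand-rolled dense oracle (pre-output-projection)
  oracleLayer <- layer
  oracleLayer$params$o <- list(W = diag(64), b = numeric(64))
  expect_lt(max(abs(got$Y - denseMHSAOracle(X, oracleLayer))), 1e-5)
})

test_that("gathered attention handles degenerate softmax cases", {
  # all gathered keys identical -> uniform weights -> mean of values
  mkq <- function(N, m, d, val) array(val, c(1, 1, N, m, d))
  V <- array(0, c(1, 1, 4, 1, 2)) # 2x2 grid on a 2x2 map: 1 token per region
  for (r in 1:4) V[1, 1, r, 1, ] <- c(2 * r - 1, 2 * r)
  qkv <- list(Q = mkq(4, 1, 2, 1), K = mkq(4, 1, 2, 1), V = V,
              H = 2, W = 2, n = 2, d = 2, heads = 1L)
  rt <- array(rep(1:4, each = 4), c(1, 1, 4, 4)) # every region keeps all 4
  Y <- gatherAndAttend(qkv, rt)
  expect_equal(as.vector(Y[1, 1, , ]), rep(4, 4)) # mean of 1,3,5,7
  expect_equal(as.vector(Y[1, 2, , ]), rep(5, 4)) # mean of 2,4,6,8

  # single region with a single token: softmax of one key is 1
  qkv1 <- list(Q = mkq(1, 1, 2, 0.3), K = mkq(1, 1, 2, -2),
               V = mkq(1, 1, 2, 0), H = 1, W = 1, n = 1, d = 2, heads = 1L)
  qkv1$V[1, 1, 1, 1, ] <- c(9, -3)
  rt1 <- array(1L, c(1, 1, 1, 1))
  expect_equal(as.vector(gatherAndAttend(qkv1, rt1)[1, , 1, 1]), c(9, -3))
})

test_that("dhaForward keeps shape, is deterministic, reduces to MHSA at n=1", {
  layer <- dhaLayer(channels = 16, heads = 2, regionGrid = 2, topk = 2, seed = 2)
  set.seed(3)
  X <- array(rnorm(2 * 16 * 8 * 8), c(2, 16, 8, 8))
  Y <- dhaForward(X, layer)
  expect_equal(dim(Y), dim(X))
  expect_identical(Y, dhaForward(X, layer))

  g1 <- dhaLayer(channels = 16, heads = 2, regionGrid = 1, topk = 1, seed = 2)
  expect_lt(max(abs(dhaForward(X, g1) - denseMHSAOracle(X, g1))), 1e-5)
})

test_that("fast routed path equals the reference op composition", {
  layer <- dhaLayer(channels = 16, heads = 2, regionGrid = 4, topk = 3, seed = 4)
  set.seed(8)
  X <- array(rnorm(2 * 16 * 8 * 8), c(2, 16, 8, 8))
  qkv <- projectAndPartition(X, layer)
  rt <- routeTopk(regionAffinity(regionSummarize(qkv)), 3)
  ref <- gatherAndAttend(qkv, rt)
  tk <- dermvit:::.toTokens(ref)
  p <- layer$params
  ref <- dermvit:::.fromTokens(
    tk %*% p$o$W + matrix(p$o$b, nrow(tk), 16, byrow = TRUE), 2, 16, 8, 8)
  expect_lt(max(abs(dhaForward(X, layer) - ref)), 1e-12)
})
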