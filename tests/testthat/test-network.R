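# Network assembly: forward contracts, determinism, ablation variants,
# parameter/MAC accounting, checkpointing.

test_that("forward contract: shape, determinism, batch independence", {
  m <- dermViT(tinyConfig(seed = 1))
  set.seed(2)
  X <- array(rnorm(3 * 3 * 16 * 16), c(3, 3, 16, 16))
  lg <- modelForward(m, X)
  expect_equal(dim(lg), c(3, 3))
  expect_true(all(is.finite(lg)))
  expect_identical(lg, modelForward(m, X))

  # permuting the batch permutes the logits identically
  perm <- c(3, 1, 2)
  expect_equal(modelForward(m, X[perm, , , , drop = FALSE]), lg[perm, ],
               tolerance = 1e-12)
})

test_that("logits stay finite over many seeded random inputs", {
  m <- dermViT(tinyConfig(seed = 3))
  for (s in 1:20) {
    set.seed(s)
    X <- array(rnorm(2 * 3 * 16 * 16, sd = 3), c(2, 3, 16, 16))
    expect_true(all(is.finite(modelForward(m, X))))
  }
})

test_that("parameter accounting: conservation and closed forms", {
  m <- dermViT(tinyConfig(seed = 1))
  total <- countParameters(m)
  bySub <- sum(vapply(m@params$stages, countParameters, numeric(1))) +
    countParameters(m@params$head)
  expect_equal(total, bySub)
  # rebuilding from the same config reproduces the same count
  expect_equal(countParameters(dermViT(tinyConfig(seed = 1))), total)

  expect_equal(countParameters(list(W = matrix(0, 4, 3), b = numeric(3))), 15)
  expect_equal(countParameters(list(w = array(0, c(8, 3, 3)),
                                    b = numeric(8))), 80) # depthwise 3x3
  expect_equal(countParameters(dfgLayer(64)$params), 26176)
})

test_that("MAC closed forms for elementary layers", {
  expect_equal(macsOf("linear", tokens = 7, din = 4, dout = 3), 84)
  expect_equal(macsOf("conv1x1", H = 8, W = 8, cin = 16, cout = 32),
               8 * 8 * 16 * 32)
  expect_equal(macsOf("patchconv", H = 8, W = 8, cin = 3, cout = 16,
                      stride = 4), 4 * 16 * 48)
  expect_equal(macsOf("dwconv", H = 5, W = 5, C = 8), 25 * 8 * 9)
  expect_equal(macsOf("attention", tokens = 16, d = 8), 2 * 256 * 8)
  expect_error(macsOf("fancy"), "unsupported layer type")
})

test_that("routed attention cheapens the stage MAC count whenever k < N", {
  sparse <- dermViT(dermViTConfig(
    imageSize = 32, numClasses = 4, channels = c(16, 32, 64, 128),
    depths = c(1, 1, 1, 1), heads = c(1, 2, 4, 8), regionGrid = c(4, 4, 2, 1),
    topk = c(2, 4, 2, 1), strides = c(4, 2, 2, 2), scales = c(1, 2), seed = 1))
  dense <- dermViT(dermViTConfig(
    imageSize = 32, numClasses = 4, channels = c(16, 32, 64, 128),
    depths = c(1, 1, 1, 1), heads = c(1, 2, 4, 8), regionGrid = c(4, 4, 2, 1),
    topk = c(16, 16, 4, 1), strides = c(4, 2, 2, 2), scales = c(1, 2), seed = 1))
  expect_lt(countMacs(sparse), countMacs(dense))
  expect_equal(countParameters(sparse), countParameters(dense))
})

test_that("ablation switches build the conventional variants", {
  base <- tinyConfig(seed = 4)
  vit <- dermViTConfig(imageSize = 16, numClasses = 3,
                       channels = c(8, 8, 16, 16), depths = c(1, 1, 1, 1),
                       heads = c(1, 1, 2, 2), regionGrid = c(2, 2, 2, 1),
                       topk = c(2, 4, 1, 1), strides = c(2, 2, 2, 2),
                       scales = c(1, 2), seed = 4,
                       useDHA = FALSE, useDCP = FALSE, useDFG = FALSE)
  mBase <- dermViT(base)
  mVit <- dermViT(vit)
  set.seed(5)
  X <- array(rnorm(2 * 3 * 16 * 16), c(2, 3, 16, 16))
  expect_true(all(is.finite(modelForward(mVit, X))))
  # dense-attention ablation collapses every region grid to 1
  for (s in 1:4) {
    expect_equal(mVit@geom$stages[[s]]$attn$n, 1L)
    expect_equal(mVit@geom$stages[[s]]$attn$k, 1L)
  }
  # FFN swap changes the parameter budget (4x FFN vs gated block)
  expect_false(countParameters(mVit) == countParameters(mBase))

  # with every switch on but k = N, the in-network attention equals dense
  # MHSA with the same weights
  cfgDense <- dermViTConfig(imageSize = 16, numClasses = 3,
                            channels = c(8, 8, 16, 16), depths = c(1, 1, 1, 1),
                            heads = c(1, 1, 2, 2), regionGrid = c(2, 2, 2, 1),
                            topk = c(4, 4, 4, 1), strides = c(2, 2, 2, 2),
                            scales = c(1, 2), seed = 4)
  mDense <- dermViT(cfgDense)
  g <- mDense@geom$stages[[1]]$attn
  bp <- mDense@params$stages[[1]]$blocks[[1]]$att
  set.seed(6)
  Xs <- array(rnorm(2 * 8 * 8 * 8), c(2, 8, 8, 8))
  fast <- dermvit:::.dhaCoreFwd(bp, dermvit:::.toTokens(Xs), g, 2)
  lyr <- dhaLayer(8, heads = 1, regionGrid = 1, topk = 1, seed = 1)
  lyr$params <- bp
  expect_lt(max(abs(dermvit:::.fromTokens(fast$y, 2, 8, 8, 8) -
                      denseMHSAOracle(Xs, lyr))), 1e-10)
})

test_that("checkpoints round-trip through a single file", {
  m <- dermViT(tinyConfig(seed = 7))
  path <- tempfile(fileext = ".rds")
  saveModel(m, path)
  m2 <- loadModel(path)
  set.seed(8)
  X <- array(rnorm(1 * 3 * 16 * 16), c(1, 3, 16, 16))
  expect_identical(modelForward(m, X), modelForward(m2, X))
  expect_equal(m2@config@imageSize, 16L)

  bad <- tempfile(fileext = ".rds")
  saveRDS(list(1), bad)
  expect_error(loadModel(bad), "DermViTModel")
  unlink(c(path, bad))
})

test_that("invalid configurations fail with descriptive errors", {
  expect_error(dermViTConfig(imageSize = 30), "divisible")
  expect_error(dermViTConfig(channels = c(10, 64, 128, 256),
                             heads = c(4, 2, 4, 8)), "divisible by heads")
  expect_error(dermViTConfig(topk = c(50, 4, 16, 49)), "exceeds")
})
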