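# Training protocol: splits, class weights, weighted cross-entropy, cosine
# schedule, augmentation, normalization, and the loop's determinism.

test_that("stratified split: exact arithmetic on balanced classes", {
  labels <- rep(1:4, each = 100)
  sp <- stratifiedSplit(labels, c(0.8, 0.05, 0.15), seed = 1)
  expect_equal(lengths(sp), c(train = 320L, val = 20L, test = 60L))
  for (cl in 1:4) {
    expect_equal(sum(labels[sp$train] == cl), 80)
    expect_equal(sum(labels[sp$val] == cl), 5)
    expect_equal(sum(labels[sp$test] == cl), 15)
  }
  # disjoint and exhaustive
  all <- c(sp$train, sp$val, sp$test)
  expect_equal(sort(all), 1:400)
  expect_equal(anyDuplicated(all), 0L)
})

test_that("stratified split: determinism, seed sensitivity, size errors", {
  labels <- sample(rep(1:3, c(50, 30, 40)))
  expect_identical(stratifiedSplit(labels, seed = 5),
                   stratifiedSplit(labels, seed = 5))
  s1 <- stratifiedSplit(labels, seed = 5)
  s2 <- stratifiedSplit(labels, seed = 6)
  expect_false(identical(s1$train, s2$train))
  # sums conserved for awkward n
  odd <- rep(1:3, c(17, 23, 31))
  so <- stratifiedSplit(odd, c(0.8, 0.05, 0.15), seed = 2)
  expect_equal(sum(lengths(so)), length(odd))
  expect_error(stratifiedSplit(c(1, 1, 1, 2), c(0.8, 0.05, 0.15), seed = 1),
               "too few")
})

test_that("inverse-frequency class weights", {
  expect_equal(classWeights(rep(1:2, c(50, 50))), c(1, 1))
  expect_equal(classWeights(rep(1:2, c(90, 10))), c(100 / 180, 5),
               tolerance = 1e-10)
  # sample-weighted mean is exactly 1
  set.seed(1)
  lab <- sample(1:5, 300, replace = TRUE, prob = c(0.5, 0.2, 0.1, 0.1, 0.1))
  w <- classWeights(lab)
  expect_equal(mean(w[lab]), 1, tolerance = 1e-12)
  expect_error(classWeights(rep(1L, 5), numClasses = 3), "absent")
})

test_that("weighted cross-entropy: hand values and identities", {
  expect_equal(weightedCrossEntropy(matrix(0, 1, 7), 1L), log(7),
               tolerance = 1e-12)
  # logits [[1,0],[0,1]], labels (1,2), weights (1,3): both sample losses are
  # -log(e/(e+1)), so the weighted mean equals it too
  lg <- rbind(c(1, 0), c(0, 1))
  l <- weightedCrossEntropy(lg, c(1L, 2L), c(1, 3))
  expect_equal(l, -log(exp(1) / (exp(1) + 1)), tolerance = 1e-10)
  expect_equal(round(l, 4), 0.3133)
  # unit weights equal the unweighted mean to 1e-7
  set.seed(2)
  lg2 <- matrix(rnorm(40), 10)
  y <- sample(1:4, 10, replace = TRUE)
  plain <- -mean(log(t(apply(lg2, 1, function(r) exp(r) / sum(exp(r))))[
    cbind(1:10, y)]))
  expect_equal(weightedCrossEntropy(lg2, y, rep(1, 4)), plain,
               tolerance = 1e-7)
  # correct-class logit -> +inf drives the loss to 0
  expect_lt(weightedCrossEntropy(rbind(c(50, 0)), 1L), 1e-10)
  expect_error(weightedCrossEntropy(lg, c(1L, 5L)), "out of range")
})

test_that("cosine schedule endpoints, midpoint and monotonicity", {
  cfg <- trainConfig()
  expect_equal(cosineLR(0, cfg), 2e-4, tolerance = 1e-12)
  expect_equal(cosineLR(100, cfg), 2e-6, tolerance = 1e-12)
  expect_equal(cosineLR(50, cfg), 1.01e-4, tolerance = 1e-10)
  lrs <- vapply(0:100, cosineLR, numeric(1), config = cfg)
  expect_true(all(diff(lrs) <= 0))
  expect_error(cosineLR(101, cfg), "out of range")
  expect_error(cosineLR(-1, cfg), "out of range")
})

test_that("augmentation: identities and dimension preservation", {
  img <- randomImage(17, seed = 1)
  expect_identical(augmentImage(img, FALSE, FALSE, 0), img)
  # double horizontal flip is the identity
  f <- augmentImage(img, TRUE, FALSE, 0)
  expect_identical(augmentImage(f, TRUE, FALSE, 0), img)
  # rotation preserves dimensions and the value range (reflect padding)
  r <- augmentImage(img, FALSE, FALSE, 23.7)
  expect_equal(dim(r), dim(img))
  expect_true(min(r) >= min(img) - 1e-12 && max(r) <= max(img) + 1e-12)
  set.seed(4)
  a1 <- augmentImage(img)
  set.seed(4)
  a2 <- augmentImage(img)
  expect_identical(a1, a2)
})

test_that("normalization hits the standard constants and inverts", {
  img <- array(0, c(4, 4, 3))
  img[, , 1] <- 0.485; img[, , 2] <- 0.456; img[, , 3] <- 0.406
  expect_equal(max(abs(normalizeImage(img))), 0, tolerance = 1e-12)
  one <- array(1, c(2, 2, 3))
  expect_equal(normalizeImage(one)[1, 1, 1], (1 - 0.485) / 0.229,
               tolerance = 1e-6)
  img2 <- randomImage(8, seed = 2)
  expect_equal(denormalizeImage(normalizeImage(img2)), img2,
               tolerance = 1e-6)
  expect_error(normalizeImage(array(0, c(4, 4, 2))), "H x W x 3")
})

test_that("the training loop is deterministic and records history", {
  gcfg <- generatorConfig(numClasses = 3, nImages = 30, imageSize = 16,
                          classProportions = rep(1 / 3, 3), seed = 2)
  ds <- generateDataset(gcfg)
  cfg <- dermViTConfig(imageSize = 16, numClasses = 3,
                       channels = c(8, 8, 16, 16), depths = c(1, 1, 1, 1),
                       heads = c(1, 1, 2, 2), regionGrid = c(2, 2, 2, 1),
                       topk = c(2, 4, 1, 1), strides = c(2, 2, 2, 2),
                       scales = c(1, 2), seed = 2)
  tc <- trainConfig(epochs = 2, batchSize = 8,
                    splitRatios = c(0.6, 0.2, 0.2), seed = 3)
  f1 <- trainModel(dermViT(cfg), ds, tc)
  f2 <- trainModel(dermViT(cfg), ds, tc)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$split, f2$split)
  expect_equal(nrow(f1$history), 2)
  expect_equal(colnames(f1$history),
               c("epoch", "lr", "train_loss", "val_loss", "train_acc",
                 "val_acc"))
  expect_true(all(is.finite(unlist(f1$history))))
  # best checkpoint predicts identically across the two runs
  set.seed(1)
  X <- array(runif(1 * 3 * 16 * 16), c(1, 3, 16, 16))
  expect_identical(predict(f1$model, X), predict(f2$model, X))
})
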