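# Training protocol: stratified splits, inverse-frequency class weighting,
# class-weighted cross-entropy, AdamW with per-epoch cosine annealing,
# flip/rotation augmentation and ImageNet channel normalization.

.IMNET_MEAN <- c(0.485, 0.456, 0.406)
.IMNET_STD <- c(0.229, 0.224, 0.225)

#' Build a training configuration
#'
#' @param lr0 initial learning rate (default 2e-4).
#' @param epochs total epochs of the cosine schedule (default 100).
#' @param finalLRFactor final/initial learning-rate ratio (default 0.01).
#' @param weightDecay decoupled AdamW weight decay (default 2e-4).
#' @param batchSize minibatch size (default 32).
#' @param splitRatios train/val/test fractions (default 0.8/0.05/0.15).
#' @param normMean,normStd per-channel normalization constants.
#' @param augment apply random flips and rotation to training images.
#' @param seed seed for splits, shuffling, augmentation and dropout.
#' @return a [TrainConfig-class].
#' @export
trainConfig <- function(lr0 = 2e-4, epochs = 100L, finalLRFactor = 0.01,
                        weightDecay = 2e-4, batchSize = 32L,
                        splitRatios = c(0.8, 0.05, 0.15),
                        normMean = .IMNET_MEAN, normStd = .IMNET_STD,
                        augment = TRUE, seed = 0L) {
  new("TrainConfig", lr0 = lr0, epochs = as.integer(epochs),
      finalLRFactor = finalLRFactor, weightDecay = weightDecay,
      batchSize = as.integer(batchSize), splitRatios = splitRatios,
      normMean = normMean, normStd = normStd, augment = augment,
      seed = as.integer(seed))
}

#' Stratified train/validation/test split
#'
#' Splits indices per class using largest-remainder rounding of the ratios,
#' so realized split sizes are as close to exact as integer counts allow
#' (balanced classes with compatible sizes split exactly). Errors if any
#' class would leave a split empty.
#'
#' @param labels integer or factor class labels.
#' @param ratios length-3 fractions summing to 1.
#' @param seed integer; permutation seed.
#' @return list with sorted integer index vectors `train`, `val`, `test`;
#'   disjoint and exhaustive.
#' @examples
#' sp <- stratifiedSplit(rep(1:4, each = 100), c(0.8, 0.05, 0.15), seed = 1)
#' lengths(sp) # 320 20 60
#' @export
stratifiedSplit <- function(labels, ratios = c(0.8, 0.05, 0.15), seed = 0L) {
  if (length(ratios) != 3L || abs(sum(ratios) - 1) > 1e-8)
    stop("ratios must be 3 fractions summing to 1")
  labels <- as.integer(as.factor(labels))
  set.seed(seed)
  out <- list(train = integer(), val = integer(), test = integer())
  for (cl in sort(unique(labels))) {
    idx <- sample(which(labels == cl))
    q <- length(idx) * ratios
    fl <- floor(q)
    rem <- length(idx) - sum(fl)
    if (rem > 0) {
      give <- order(-(q - fl))[seq_len(rem)] # ties -> earlier split
      fl[give] <- fl[give] + 1
    }
    if (any(fl < 1))
      stop(sprintf("class %d has too few samples (%d) for a non-empty split",
                   cl, length(idx)))
    b <- cumsum(fl)
    out$train <- c(out$train, idx[seq_len(b[1L])])
    out$val <- c(out$val, idx[(b[1L] + 1L):b[2L]])
    out$test <- c(out$test, idx[(b[2L] + 1L):b[3L]])
  }
  lapply(out, sort)
}

#' Inverse-frequency class weights
#'
#' `w_c = n / (K * n_c)`: balanced labels give unit weights, rare classes
#' get proportionally larger ones. The sample-weighted mean `sum(w[y]) / n`
#' is exactly 1.
#'
#' @param labels integer class labels (1-based).
#' @param numClasses K; defaults to `max(labels)`.
#' @return numeric weight vector of length K.
#' @examples
#' classWeights(rep(1:2, c(90, 10))) # 0.5556 5.0000
#' @export
classWeights <- function(labels, numClasses = max(labels)) {
  counts <- tabulate(labels, numClasses)
  if (any(counts == 0))
    stop(sprintf("class %s absent from the training labels",
                 paste(which(counts == 0), collapse = ", ")))
  length(labels) / (numClasses * counts)
}

#' Class-weighted cross-entropy loss
#'
#' Mean over the batch of `w[y_i] * (-log softmax(logits_i)[y_i])`,
#' normalized by the sum of sample weights (so unit weights reproduce the
#' plain mean cross-entropy exactly).
#'
#' @param logits B x K matrix.
#' @param labels integer vector of true classes, 1-based.
#' @param weights length-K class weights (default: unit).
#' @param gradient also return d loss / d logits.
#' @return scalar loss, or (with `gradient = TRUE`) a list with `loss` and
#'   the `B x K` gradient matrix.
#' @examples
#' weightedCrossEntropy(matrix(0, 1, 7), 1L) # log(7)
#' @export
weightedCrossEntropy <- function(logits, labels, weights = NULL,
                                 gradient = FALSE) {
  K <- ncol(logits)
  if (any(labels < 1L | labels > K)) stop("label out of range 1..K")
  if (is.null(weights)) weights <- rep(1, K)
  P <- .softmaxRows(logits)
  B <- nrow(logits)
  wi <- weights[labels]
  nll <- -log(P[cbind(seq_len(B), labels)])
  loss <- sum(wi * nll) / sum(wi)
  if (!gradient) return(loss)
  G <- P
  G[cbind(seq_len(B), labels)] <- G[cbind(seq_len(B), labels)] - 1
  list(loss = loss, gradient = G * (wi / sum(wi)))
}

#' Cosine-annealed learning rate
#'
#' `lr(e) = lr_min + (lr0 - lr_min) * (1 + cos(pi * e / epochs)) / 2` with
#' `lr_min = finalLRFactor * lr0`: starts at `lr0` and decays smoothly to
#' `finalLRFactor * lr0` at the last epoch.
#'
#' @param epoch epoch in `[0, epochs]`.
#' @param config a [trainConfig()].
#' @return numeric learning rate.
#' @examples
#' cosineLR(0, trainConfig())   # 2e-4
#' cosineLR(100, trainConfig()) # 2e-6
#' @export
cosineLR <- function(epoch, config = trainConfig()) {
  if (epoch < 0 || epoch > config@epochs)
    stop(sprintf("epoch %s out of range [0, %d]", epoch, config@epochs))
  lrMin <- config@finalLRFactor * config@lr0
  lrMin + (config@lr0 - lrMin) * (1 + cos(pi * epoch / config@epochs)) / 2
}

# ---- image transforms -------------------------------------------------------

.reflectIdx <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  j <- (i - 1L) %% (2L * n - 2L)
  j <- ifelse(j >= n, 2L * n - 2L - j, j)
  j + 1L
}

.rotateReflect <- function(img, angle) {
  d <- dim(img)
  H <- d[1L]; W <- d[2L]
  th <- angle * pi / 180
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  r <- rep(seq_len(H), times = W)
  cc <- rep(seq_len(W), each = H)
  dr <- r - cy; dc <- cc - cx
  sr <- cy + cos(th) * dr - sin(th) * dc
  sc <- cx + sin(th) * dr + cos(th) * dc
  r0 <- floor(sr); c0 <- floor(sc)
  fr <- sr - r0; fc <- sc - c0
  i00 <- cbind(.reflectIdx(r0, H), .reflectIdx(c0, W))
  i01 <- cbind(.reflectIdx(r0, H), .reflectIdx(c0 + 1, W))
  i10 <- cbind(.reflectIdx(r0 + 1, H), .reflectIdx(c0, W))
  i11 <- cbind(.reflectIdx(r0 + 1, H), .reflectIdx(c0 + 1, W))
  out <- img
  for (ch in seq_len(d[3L])) {
    pl <- img[, , ch]
    v <- (1 - fr) * (1 - fc) * pl[i00] + (1 - fr) * fc * pl[i01] +
      fr * (1 - fc) * pl[i10] + fr * fc * pl[i11]
    out[, , ch] <- matrix(v, H, W)
  }
  out
}

#' Randomly flip and rotate a training image
#'
#' Horizontal and vertical flips each with probability 1/2 and a rotation
#' uniform in +-`maxAngle` degrees (bilinear resampling with reflect-pad
#' fill, so output dimensions are preserved). Pass explicit values to force
#' a transform; `augmentImage(img, FALSE, FALSE, 0)` is the identity.
#'
#' @param image H x W x 3 array.
#' @param hflip,vflip logical or NULL (draw from the RNG).
#' @param angle rotation in degrees or NULL (draw uniform in +-`maxAngle`).
#' @param maxAngle rotation range bound (default 30 degrees).
#' @return transformed H x W x 3 array.
#' @export
augmentImage <- function(image, hflip = NULL, vflip = NULL, angle = NULL,
                         maxAngle = 30) {
  if (length(dim(image)) != 3L || dim(image)[3L] != 3L)
    stop("image must be an H x W x 3 array")
  if (is.null(hflip)) hflip <- stats::runif(1) < 0.5
  if (is.null(vflip)) vflip <- stats::runif(1) < 0.5
  if (is.null(angle)) angle <- stats::runif(1, -maxAngle, maxAngle)
  if (hflip) image <- image[, rev(seq_len(dim(image)[2L])), , drop = FALSE]
  if (vflip) image <- image[rev(seq_len(dim(image)[1L])), , , drop = FALSE]
  if (angle != 0) image <- .rotateReflect(image, angle)
  image
}

#' Channel normalization of images
#'
#' `(x - mean) / std` per channel for an H x W x 3 image in [0,1];
#' `denormalizeImage` inverts it.
#'
#' @param image H x W x 3 array.
#' @param mean,std length-3 channel constants.
#' @return normalized (resp. denormalized) array.
#' @export
normalizeImage <- function(image, mean = .IMNET_MEAN, std = .IMNET_STD) {
  if (length(dim(image)) != 3L || dim(image)[3L] != 3L)
    stop("image must be an H x W x 3 array")
  for (ch in 1:3) image[, , ch] <- (image[, , ch] - mean[ch]) / std[ch]
  image
}

#' @rdname normalizeImage
#' @export
denormalizeImage <- function(image, mean = .IMNET_MEAN, std = .IMNET_STD) {
  for (ch in 1:3) image[, , ch] <- image[, , ch] * std[ch] + mean[ch]
  image
}

# images: list of H x W x 3 arrays -> c(B, 3, H, W), optionally normalized
.imagesToBatch <- function(images, normalize = TRUE,
                           mean = .IMNET_MEAN, std = .IMNET_STD) {
  arr <- simplify2array(images) # H W 3 B
  if (length(dim(arr)) == 3L) dim(arr) <- c(dim(arr), 1L)
  if (normalize)
    for (ch in 1:3) arr[, , ch, ] <- (arr[, , ch, ] - mean[ch]) / std[ch]
  aperm(arr, c(4L, 3L, 1L, 2L))
}

.normalizeBatch <- function(X, mean = .IMNET_MEAN, std = .IMNET_STD) {
  for (ch in 1:3) X[, ch, , ] <- (X[, ch, , ] - mean[ch]) / std[ch]
  X
}

.datasetParts <- function(data) {
  if (is(data, "SyntheticDermData"))
    list(images = data@images, labels = data@labels, masks = data@masks)
  else list(images = data$images, labels = as.integer(data$labels),
            masks = data$masks)
}

# ---- training loop ----------------------------------------------------------

#' Train a model with AdamW and cosine annealing
#'
#' Runs the full protocol: stratified split (unless one is supplied),
#' inverse-frequency class weights from the training labels, per-epoch
#' cosine learning rate, flip/rotation augmentation, class-weighted
#' cross-entropy, and model selection by validation accuracy. Fully
#' deterministic given `config@seed`.
#'
#' @param model a [DermViTModel-class].
#' @param data a [SyntheticDermData-class] or a list with `images` (list of
#'   H x W x 3 arrays in [0,1]) and `labels` (1-based integers).
#' @param config a [trainConfig()].
#' @param split optional list of index vectors `train`, `val`, `test`.
#' @param stopTrainAcc optional early-stop threshold: training halts after
#'   the first epoch whose training accuracy reaches this value (useful for
#'   capacity/overfitting checks).
#' @param verbose print one line per epoch.
#' @return list of class `dermvitFit` with elements `model` (best validation
#'   accuracy checkpoint), `finalModel`, `history` (one row per epoch:
#'   epoch, lr, train_loss, val_loss, train_acc, val_acc), `split`,
#'   `classWeights`, `bestEpoch`.
#' @export
trainModel <- function(model, data, config = trainConfig(), split = NULL,
                       stopTrainAcc = NULL, verbose = FALSE) {
  parts <- .datasetParts(data)
  n <- length(parts$labels)
  if (is.null(split))
    split <- stratifiedSplit(parts$labels, config@splitRatios, config@seed)
  set.seed(config@seed)
  K <- model@config@numClasses
  w <- classWeights(parts$labels[split$train], K)
  valX <- .imagesToBatch(parts$images[split$val], TRUE,
                         config@normMean, config@normStd)
  valY <- parts$labels[split$val]
  st <- .adamInit()
  params <- model@params
  hist <- data.frame()
  best <- list(acc = -1, params = params, epoch = 0L)
  for (epoch in seq_len(config@epochs)) {
    lr <- cosineLR(epoch - 1, config)
    ord <- sample(split$train)
    nTrain <- length(ord)
    batches <- split(ord, ceiling(seq_along(ord) / config@batchSize))
    lossSum <- 0; corr <- 0
    for (bt in batches) {
      imgs <- parts$images[bt]
      if (config@augment) imgs <- lapply(imgs, augmentImage)
      X <- .imagesToBatch(imgs, TRUE, config@normMean, config@normStd)
      model@params <- params
      fw <- .modelFwd(model, X, training = TRUE)
      ce <- weightedCrossEntropy(fw$logits, parts$labels[bt], w,
                                 gradient = TRUE)
      if (!is.finite(ce$loss)) stop("training diverged: non-finite loss")
      bw <- .modelBwd(model, fw, ce$gradient)
      params <- .adamStep(params, bw$grads, st, lr, config@weightDecay)
      lossSum <- lossSum + ce$loss * length(bt)
      corr <- corr + sum(max.col(fw$logits, ties.method = "first") ==
                           parts$labels[bt])
    }
    model@params <- params
    vfw <- .modelFwd(model, valX, training = FALSE)
    vloss <- weightedCrossEntropy(vfw$logits, valY, w)
    vacc <- mean(max.col(vfw$logits, ties.method = "first") == valY)
    hist <- rbind(hist, data.frame(
      epoch = epoch, lr = lr, train_loss = lossSum / nTrain,
      val_loss = vloss, train_acc = corr / nTrain, val_acc = vacc))
    if (vacc > best$acc) best <- list(acc = vacc, params = params,
                                      epoch = epoch)
    if (verbose)
      message(sprintf(
        "epoch %3d lr %.2e train loss %.4f acc %.3f | val loss %.4f acc %.3f",
        epoch, lr, lossSum / nTrain, corr / nTrain, vloss, vacc))
    if (!is.null(stopTrainAcc) && corr / nTrain >= stopTrainAcc) break
  }
  bestModel <- model
  bestModel@params <- best$params
  structure(list(model = bestModel, finalModel = model, history = hist,
                 split = split, classWeights = w, bestEpoch = best$epoch),
            class = "dermvitFit")
}

#' Write a training history to CSV
#'
#' @param fit result of [trainModel()].
#' @param path output CSV path.
#' @export
writeHistory <- function(fit, path) {
  utils::write.csv(fit$history, path, row.names = FALSE)
  invisible(path)
}
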