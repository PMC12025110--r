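#' @import methods
NULL

#' Model configuration for a four-stage DermViT backbone
#'
#' Holds the per-stage hyperparameters (channels, block depth, attention
#' heads, region grid, routing top-k, pyramid scales, downsampling stride)
#' plus global settings (input size, number of classes, ablation switches,
#' dropout, initialization seed). Build one with [dermViTConfig()].
#'
#' @slot imageSize integer, square input resolution in pixels.
#' @slot numClasses integer, number of diagnosis classes.
#' @slot stages list of four per-stage parameter lists.
#' @slot useDHA,useDCP,useDFG logical ablation switches; turning a switch off
#'   replaces the block by its conventional counterpart (dense multi-head
#'   attention, plain strided convolution, 4x-expansion feed-forward).
#' @slot dropout numeric dropout rate used inside the feed-forward gate.
#' @slot seed integer seed for weight initialization.
#' @export
setClass("DermViTConfig", representation(
  imageSize = "integer", numClasses = "integer", stages = "list",
  useDHA = "logical", useDCP = "logical", useDFG = "logical",
  dropout = "numeric", seed = "integer"))

setValidity("DermViTConfig", function(object) {
  msg <- character()
  if (length(object@stages) != 4L) msg <- c(msg, "exactly 4 stages are required")
  strideProd <- 1L
  for (s in object@stages) {
    if (s$channels %% s$heads != 0)
      msg <- c(msg, sprintf("stage channels %d not divisible by heads %d",
                            s$channels, s$heads))
    if (s$topk > s$regionGrid^2)
      msg <- c(msg, sprintf("top-k %d exceeds region count %d",
                            s$topk, s$regionGrid^2))
    if (s$topk < 1L) msg <- c(msg, "top-k must be >= 1")
    if (length(s$scales) < 1L || any(diff(s$scales) <= 0) || any(s$scales < 1))
      msg <- c(msg, "pyramid scales must be strictly increasing positive integers")
    strideProd <- strideProd * s$stride
  }
  if (length(object@stages) == 4L && object@imageSize %% strideProd != 0)
    msg <- c(msg, sprintf("image size %d not divisible by total stride %d",
                          object@imageSize, strideProd))
  if (object@numClasses < 2L) msg <- c(msg, "need at least 2 classes")
  if (object@dropout < 0 || object@dropout >= 1) msg <- c(msg, "dropout must be in [0,1)")
  if (length(msg)) msg else TRUE
})

#' A built DermViT model
#'
#' Created by [dermViT()]. Carries the configuration, the parameter tree and
#' the precomputed per-stage geometry (map sizes, effective region grids,
#' routing/pooling index structures).
#'
#' @slot config a [DermViTConfig-class].
#' @slot params nested list of weight arrays.
#' @slot geom per-stage geometry list (internal).
#' @export
setClass("DermViTModel", representation(
  config = "DermViTConfig", params = "list", geom = "list"))

#' Training protocol configuration
#'
#' Defaults follow the training protocol used throughout: AdamW with initial
#' learning rate 2e-4 decayed by cosine annealing to 0.01 of its initial
#' value over 100 epochs, weight decay 2e-4, batch size 32, stratified
#' 0.8/0.05/0.15 splits, flip + rotation augmentation and ImageNet channel
#' normalization. Build one with [trainConfig()].
#'
#' @slot lr0,epochs,finalLRFactor,weightDecay,batchSize numeric core settings.
#' @slot splitRatios numeric(3) train/val/test fractions, summing to 1.
#' @slot normMean,normStd numeric(3) per-channel normalization constants.
#' @slot augment logical, apply random flips/rotation to training images.
#' @slot seed integer seed controlling splits, shuffling, augmentation, dropout.
#' @export
setClass("TrainConfig", representation(
  lr0 = "numeric", epochs = "integer", finalLRFactor = "numeric",
  weightDecay = "numeric", batchSize = "integer", splitRatios = "numeric",
  normMean = "numeric", normStd = "numeric", augment = "logical",
  seed = "integer"))

setValidity("TrainConfig", function(object) {
  msg <- character()
  if (object@lr0 <= 0) msg <- c(msg, "lr0 must be positive")
  if (abs(sum(object@splitRatios) - 1) > 1e-8)
    msg <- c(msg, "split ratios must sum to 1")
  if (length(object@splitRatios) != 3L) msg <- c(msg, "need 3 split ratios")
  if (length(msg)) msg else TRUE
})

#' Synthetic dermoscopy generator configuration
#'
#' Controls the class-conditional lesion simulator: number of classes and
#' images, resolution, (possibly imbalanced) class proportions, artifact
#' probabilities and lesion area bounds. Build one with [generatorConfig()].
#'
#' @slot numClasses,nImages,imageSize integers.
#' @slot classProportions numeric, summing to 1.
#' @slot pHair,pRuler,pBubble numeric artifact probabilities per image.
#' @slot areaBounds numeric(2) lesion area fraction bounds (0 < min < max < 1).
#' @slot seed integer.
#' @export
setClass("GeneratorConfig", representation(
  numClasses = "integer", nImages = "integer", imageSize = "integer",
  classProportions = "numeric", pHair = "numeric", pRuler = "numeric",
  pBubble = "numeric", areaBounds = "numeric", seed = "integer"))

setValidity("GeneratorConfig", function(object) {
  msg <- character()
  if (length(object@classProportions) != object@numClasses)
    msg <- c(msg, "classProportions length must equal numClasses")
  if (abs(sum(object@classProportions) - 1) > 1e-8)
    msg <- c(msg, "classProportions must sum to 1")
  ab <- object@areaBounds
  if (length(ab) != 2L || ab[1] <= 0 || ab[2] >= 1 || ab[1] >= ab[2])
    msg <- c(msg, "areaBounds must satisfy 0 < min < max < 1")
  for (p in c(object@pHair, object@pRuler, object@pBubble))
    if (p < 0 || p > 1) msg <- c(msg, "artifact probabilities must be in [0,1]")
  if (length(msg)) msg else TRUE
})

#' In-memory synthetic dermoscopy dataset
#'
#' Images are H x W x 3 arrays in [0,1] (8-bit quantized), labels are integer
#' class indices (1-based), masks are H x W binary lesion masks, and `meta`
#' records per-image artifact counts and lesion parameters. When written to
#' disk the object also carries the file paths and manifest location.
#'
#' @slot images,masks lists of arrays.
#' @slot labels integer vector.
#' @slot meta data.frame of per-image metadata.
#' @slot classNames character vector.
#' @slot files character vector of image paths ("" when in-memory only).
#' @slot manifest path of the CSV manifest ("" when in-memory only).
#' @export
setClass("SyntheticDermData", representation(
  images = "list", labels = "integer", masks = "list", meta = "data.frame",
  classNames = "character", files = "character", manifest = "character"))

#' Multiclass evaluation report
#'
#' Confusion matrix (rows = truth), accuracy, macro precision/recall/F1 and
#' macro one-vs-rest ROC AUC (MAUC), plus the per-class breakdown.
#'
#' @slot confusion K x K matrix, rows are true classes.
#' @slot accuracy,macroPrecision,macroRecall,macroF1,mauc numerics in [0,1]
#'   (`mauc` is NA when scores were not supplied).
#' @slot perClass data.frame with per-class precision/recall/F1/support/AUC.
#' @export
setClass("MetricsReport", representation(
  confusion = "matrix", accuracy = "numeric", macroPrecision = "numeric",
  macroRecall = "numeric", macroF1 = "numeric", mauc = "numeric",
  perClass = "data.frame"))

# ---- show methods ----------------------------------------------------------

#' @export
setMethod("show", "DermViTConfig", function(object) {
  cat(sprintf("DermViTConfig: %dpx input, %d classes, dropout %.2f\n",
              object@imageSize, object@numClasses, object@dropout))
  cat(sprintf("  ablation: DHA=%s DCP=%s DFG=%s\n",
              object@useDHA, object@useDCP, object@useDFG))
  for (i in seq_along(object@stages)) {
    s <- object@stages[[i]]
    cat(sprintf(
      "  stage %d: C=%d depth=%d heads=%d grid=%d k=%d stride=%d scales={%s}\n",
      i, s$channels, s$depth, s$heads, s$regionGrid, s$topk, s$stride,
      paste(s$scales, collapse = ",")))
  }
})

#' @export
setMethod("show", "DermViTModel", function(object) {
  cat(sprintf("DermViTModel: %s parameters\n",
              format(countParameters(object), big.mark = ",")))
  show(object@config)
})

#' @export
setMethod("show", "TrainConfig", function(object) {
  cat(sprintf(
    "TrainConfig: AdamW lr0=%g (cosine -> %g over %d epochs), wd=%g, batch=%d\n",
    object@lr0, object@lr0 * object@finalLRFactor, object@epochs,
    object@weightDecay, object@batchSize))
  cat(sprintf("  splits %s, augment=%s, seed=%d\n",
              paste(object@splitRatios, collapse = "/"), object@augment,
              object@seed))
})

#' @export
setMethod("show", "SyntheticDermData", function(object) {
  cat(sprintf("SyntheticDermData: %d images (%s), classes: %s\n",
              length(object@labels),
              if (nzchar(object@manifest)) object@manifest else "in memory",
              paste(sprintf("%s=%d", object@classNames,
                            tabulate(object@labels,
                                     length(object@classNames))),
                    collapse = " ")))
})

#' @export
setMethod("show", "MetricsReport", function(object) {
  cat(sprintf(
    "MetricsReport: accuracy %.4f | macro P %.4f R %.4f F1 %.4f | MAUC %s\n",
    object@accuracy, object@macroPrecision, object@macroRecall,
    object@macroF1,
    if (is.na(object@mauc)) "NA" else sprintf("%.4f", object@mauc)))
  print(object@confusion)
})

#' @export
setMethod("length", "SyntheticDermData", function(x) length(x@labels))
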