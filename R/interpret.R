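# Grad-CAM heatmaps and lesion-mask overlap scoring: channel gradients of a
# class logit at a chosen stage's output feature map weight the activations,
# followed by ReLU, bilinear upsampling to the image size and min-max
# normalization.

.resolveStage <- function(stage) {
  valid <- c("stage1", "stage2", "stage3", "stage4")
  if (is.numeric(stage)) stage <- paste0("stage", as.integer(stage))
  s <- match(stage, valid)
  if (is.na(s))
    stop(sprintf("unknown stage '%s'; valid stages: %s",
                 stage, paste(valid, collapse = ", ")))
  s
}

#' Grad-CAM heatmap for a class
#'
#' Computes the gradient of the target class logit with respect to the
#' chosen stage's output feature map, weights each channel by its spatially
#' averaged gradient, sums, rectifies, upsamples bilinearly to the input
#' size and min-max normalizes to [0,1]. A map whose rectified response is
#' identically zero is returned as zeros.
#'
#' @param model a [DermViTModel-class].
#' @param image raw H x W x 3 image in [0,1] (normalized internally).
#' @param targetClass 1-based class index; default: the predicted class.
#' @param stage `"stage1"`..`"stage4"` or 1..4; the feature map to explain.
#'   Default is the last stage's pre-head map.
#' @return H x W heatmap in [0,1].
#' @export
gradCam <- function(model, image, targetClass = NULL, stage = "stage4") {
  s <- .resolveStage(stage)
  X <- .imagesToBatch(list(image), TRUE)
  fw <- .modelFwd(model, X, training = FALSE)
  if (is.null(targetClass))
    targetClass <- max.col(fw$logits, ties.method = "first")[1L]
  dlog <- matrix(0, 1L, ncol(fw$logits))
  dlog[1L, targetClass] <- 1
  bw <- .modelBwd(model, fw, dlog)
  A <- fw$stageOut[[s]]
  dA <- bw$dStage[[s]]
  C <- dim(A)[2L]; Hs <- dim(A)[3L]; Ws <- dim(A)[4L]
  Am <- matrix(A[1L, , , ], C)
  dAm <- matrix(dA[1L, , , ], C)
  wts <- rowMeans(dAm)
  cam <- matrix(as.vector(wts %*% Am), Hs, Ws)
  cam[cam < 0] <- 0
  H0 <- dim(image)[1L]; W0 <- dim(image)[2L]
  up <- t(EBImage::resize(t(cam), w = W0, h = H0))
  up[up < 0] <- 0 # bilinear ringing guard
  mx <- max(up); mn <- min(up)
  if (mx <= 0) return(matrix(0, H0, W0))
  if (mx - mn < .Machine$double.eps) return(matrix(1, H0, W0))
  (up - mn) / (mx - mn)
}

#' Fraction of heatmap mass inside a lesion mask
#'
#' `sum(h[mask]) / sum(h)`; invariant to positive rescaling of the heatmap,
#' equal to the mask's area fraction for a uniform heatmap, defined as 0 for
#' an all-zero heatmap.
#'
#' @param heatmap H x W nonnegative array.
#' @param mask H x W binary (or logical) lesion mask.
#' @return overlap score in [0,1].
#' @examples
#' maskOverlap(matrix(c(1, 0, 3, 0), 2), matrix(c(1, 0, 0, 0), 2)) # 0.25
#' @export
maskOverlap <- function(heatmap, mask) {
  if (!identical(dim(heatmap), dim(mask)))
    stop("heatmap and mask shapes differ")
  tot <- sum(heatmap)
  if (tot == 0) return(0)
  sum(heatmap[mask > 0]) / tot
}

#' Export a heatmap overlay as PNG
#'
#' Blends the image with a blue-green-red colormap of the heatmap.
#'
#' @param image raw H x W x 3 image in [0,1].
#' @param heatmap H x W heatmap in [0,1] (e.g. from [gradCam()]).
#' @param path output PNG path.
#' @param alpha heatmap blend weight.
#' @export
writeCamOverlay <- function(image, heatmap, path, alpha = 0.45) {
  ramp <- grDevices::colorRamp(c("navy", "cyan", "yellow", "red"))
  cols <- ramp(as.vector(heatmap)) / 255
  d <- dim(image)
  overlay <- image
  for (ch in 1:3)
    overlay[, , ch] <- (1 - alpha) * image[, , ch] +
      alpha * matrix(cols[, ch], d[1L], d[2L])
  png::writePNG(overlay, path)
  invisible(path)
}
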