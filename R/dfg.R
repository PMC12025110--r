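# Dermoscopic Feature Gate (DFG): a GLU-style replacement for the
# transformer FFN. A 1x1 convolution expands the input and splits it into a
# content path and a gate path; the content path is refined by a 3x3
# depthwise convolution + ReLU and then multiplied by the gate before the
# 1x1 output projection (with dropout in training mode).

#' Construct a gated convolutional feed-forward layer
#'
#' @param channels input/output channels C.
#' @param hidden width h of each split half (default 2C); the expansion
#'   convolution produces 2h channels.
#' @param dropout dropout rate applied after the output projection during
#'   training.
#' @param seed integer seed for weight initialization.
#' @return a list of class `dfgLayer`.
#' @examples
#' countParameters(dfgLayer(64)$params) # 26176
#' @export
dfgLayer <- function(channels, hidden = 2L * channels, dropout = 0.1,
                     seed = 0L) {
  if (hidden < channels) stop("hidden width must be >= channels")
  if (dropout < 0 || dropout >= 1) stop("dropout must be in [0, 1)")
  set.seed(seed)
  params <- list(ex = .initLinear(channels, 2L * hidden),
                 dw = .initDW(hidden),
                 pr = .initLinear(hidden, channels))
  structure(list(channels = as.integer(channels), hidden = as.integer(hidden),
                 dropout = dropout, params = params),
            class = "dfgLayer")
}

#' Expand and split into content and gate paths
#'
#' 1x1 convolution C -> 2h followed by a channel split: the first h channels
#' form the content path X1, the last h the gate Vg.
#'
#' @param X feature map `c(B, C, H, W)`.
#' @param layer a [dfgLayer()].
#' @return list with feature maps `X1` and `Vg`, each `c(B, h, H, W)`.
#' @export
expandSplit <- function(X, layer) {
  .assertFeatureMap(X)
  d <- dim(X)
  if (d[2L] != layer$channels)
    stop(sprintf("input has %d channels, layer expects %d", d[2L], layer$channels))
  h <- layer$hidden
  z <- .linFwd(layer$params$ex, .toTokens(X))$y
  list(X1 = .fromTokens(z[, seq_len(h), drop = FALSE], d[1L], h, d[3L], d[4L]),
       Vg = .fromTokens(z[, h + seq_len(h), drop = FALSE], d[1L], h, d[3L], d[4L]))
}

#' Refine the content path and apply the gate
#'
#' `X2 = ReLU(DWConv3x3(X1))` (zero padding 1, spatial dims preserved), then
#' `Y = Dropout(Conv1x1(X2 * Vg))` projecting h -> C. Dropout is active only
#' with `training = TRUE`.
#'
#' @param X1,Vg feature maps of identical shape `c(B, h, H, W)`.
#' @param layer a [dfgLayer()].
#' @param training logical; enables dropout.
#' @return feature map `c(B, C, H, W)`.
#' @export
refineAndGate <- function(X1, Vg, layer, training = FALSE) {
  if (!identical(dim(X1), dim(Vg))) stop("X1 and Vg shapes differ")
  d <- dim(X1)
  dw <- .dwFwd(layer$params$dw, X1)
  x2 <- .toTokens(dw$y)
  x2 <- x2 * (x2 > 0)
  g <- x2 * .toTokens(Vg)
  y <- .linFwd(layer$params$pr, g)$y
  y <- .dropFwd(y, layer$dropout, training)$y
  .fromTokens(y, d[1L], layer$channels, d[3L], d[4L])
}

#' Gated feed-forward forward pass
#'
#' Composition of [expandSplit()] and [refineAndGate()]; output shape equals
#' input shape.
#'
#' @inheritParams expandSplit
#' @param training logical; enables dropout.
#' @return feature map shaped like `X`.
#' @export
dfgForward <- function(X, layer, training = FALSE) {
  sp <- expandSplit(X, layer)
  refineAndGate(sp$X1, sp$Vg, layer, training)
}

#' Closed-form parameter counts for the feed-forward alternatives
#'
#' `dfgParamCount` counts the gated block (1x1 expand C -> 2h, depthwise 3x3
#' on h, 1x1 project h -> C, all with bias); `ffnParamCount` counts the
#' standard 4x-expansion FFN (C -> 4C -> C) it replaces, `8C^2 + 5C`.
#'
#' @param C channels; `h` hidden width (default 2C).
#' @return numeric parameter count.
#' @export
dfgParamCount <- function(C, h = 2 * C) {
  (C * 2 * h + 2 * h) + (9 * h + h) + (h * C + C)
}

#' @rdname dfgParamCount
#' @export
ffnParamCount <- function(C) 8 * C^2 + 5 * C

# ---- fast core with backward -----------------------------------------------

.dfgFwd <- function(p, x, g, B, training, rate) {
  h <- g$h
  ex <- .linFwd(p$ex, x)
  x1 <- ex$y[, seq_len(h), drop = FALSE]
  vg <- ex$y[, h + seq_len(h), drop = FALSE]
  dw <- .dwFwd(p$dw, .fromTokens(x1, B, h, g$H, g$W))
  x2 <- .toTokens(dw$y)
  mask <- x2 > 0
  x2 <- x2 * mask
  gt <- x2 * vg
  pr <- .linFwd(p$pr, gt)
  dr <- .dropFwd(pr$y, rate, training)
  list(y = dr$y, ex = ex, dw = dw, mask = mask, x2 = x2, vg = vg, pr = pr,
       dr = dr)
}

.dfgBwd <- function(p, cache, g, B, dy) {
  h <- g$h
  dy <- .dropBwd(cache$dr, dy)
  prb <- .linBwd(p$pr, cache$pr, dy)
  dG <- prb$dx
  dX2 <- (dG * cache$vg) * cache$mask
  dVg <- dG * cache$x2
  dwb <- .dwBwd(p$dw, cache$dw, .fromTokens(dX2, B, h, g$H, g$W))
  dEx <- cbind(.toTokens(dwb$dx), dVg)
  exb <- .linBwd(p$ex, cache$ex, dEx)
  list(dx = exb$dx, dp = list(ex = exb$dp, dw = dwb$dp, pr = prb$dp))
}
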