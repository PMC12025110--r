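# Dermoscopic Context Pyramid (DCP): strided convolutional compression of the
# map followed by attention in which the keys/values are pyramid-pooled to a
# compact multi-scale token set while the queries keep their spatial
# coordinates.

# ---- pooling geometry ------------------------------------------------------

# concatenated token-level pooling matrix over all scales, each clamped
# independently in H and W
.pyramidMatrix <- function(H, W, scales) {
  if (length(scales) < 1L) stop("scales must be a non-empty increasing list")
  do.call(rbind, lapply(scales, function(s)
    kronecker(.poolMatrix1d(H, min(s, H)), .poolMatrix1d(W, min(s, W)))))
}

#' Pooled token count of a pyramid
#'
#' Closed form `sum(min(s_i, H) * min(s_i, W))` for pooling scales clamped to
#' the map size.
#'
#' @param H,W feature map size.
#' @param scales increasing positive integer pooling grid sizes.
#' @return integer token count.
#' @examples
#' pyramidTokenCount(56, 56, c(1, 2, 4, 16)) # 277
#' pyramidTokenCount(7, 7, c(1, 2, 4, 16))   # 70
#' @export
pyramidTokenCount <- function(H, W, scales) {
  sum(pmin(scales, H) * pmin(scales, W))
}

# ---- layer constructors -----------------------------------------------------

#' Construct a strided compression convolution
#'
#' Patch-merging style downsampler: a convolution whose kernel size equals
#' its stride, so each output pixel summarizes one non-overlapping patch.
#'
#' @param inChannels,outChannels channel counts.
#' @param stride downsample factor (also the kernel size).
#' @param seed integer seed for weight initialization.
#' @return a list of class `compressLayer`.
#' @export
compressLayer <- function(inChannels, outChannels, stride, seed = 0L) {
  if (stride < 1) stop("stride must be >= 1")
  set.seed(seed)
  structure(list(inChannels = as.integer(inChannels),
                 outChannels = as.integer(outChannels),
                 stride = as.integer(stride),
                 params = .initLinear(inChannels * stride^2, outChannels)),
            class = "compressLayer")
}

#' Spatially compress a feature map
#'
#' @param X feature map `c(B, C, H, W)`; H and W must be divisible by the
#'   layer stride.
#' @param layer a [compressLayer()].
#' @return feature map `c(B, outChannels, H/stride, W/stride)`.
#' @export
compress <- function(X, layer) {
  .assertFeatureMap(X)
  if (dim(X)[2L] != layer$inChannels)
    stop(sprintf("input has %d channels, layer expects %d",
                 dim(X)[2L], layer$inChannels))
  .pconvFwd(layer$params, X, layer$stride)$y
}

#' Construct a context-pyramid attention layer
#'
#' Compression convolution, layer norm, Q/K/V projections (all taken from
#' the compressed map), pyramid pooling of keys/values, multi-head attention
#' and an output projection.
#'
#' @param inChannels,outChannels channel counts (attention runs at
#'   `outChannels`).
#' @param stride downsample factor of the compression convolution.
#' @param heads attention heads; `outChannels` must be divisible by `heads`.
#' @param scales increasing pooling grid sizes; scales larger than the
#'   compressed map are clamped to the full map.
#' @param seed integer seed for weight initialization.
#' @return a list of class `dcpLayer`.
#' @export
dcpLayer <- function(inChannels, outChannels, stride, heads = 1L,
                     scales = c(1L, 2L, 4L, 16L), seed = 0L) {
  if (outChannels %% heads != 0)
    stop(sprintf("outChannels %d not divisible by heads %d", outChannels, heads))
  if (length(scales) < 1L || any(diff(scales) <= 0) || any(scales < 1))
    stop("scales must be strictly increasing positive integers")
  set.seed(seed)
  params <- list(pc = .initLinear(inChannels * stride^2, outChannels),
                 ln = .initLN(outChannels),
                 q = .initLinear(outChannels, outChannels),
                 k = .initLinear(outChannels, outChannels),
                 v = .initLinear(outChannels, outChannels),
                 o = .initLinear(outChannels, outChannels))
  structure(list(inChannels = as.integer(inChannels),
                 outChannels = as.integer(outChannels),
                 stride = as.integer(stride), heads = as.integer(heads),
                 d = as.integer(outChannels %/% heads),
                 scales = as.integer(scales), params = params),
            class = "dcpLayer")
}

# ---- reference operations --------------------------------------------------

#' Pyramid-pool keys and values
#'
#' Adaptive average pooling of the key and value maps to each grid size in
#' `scales` (clamped to the map size), flattened row-major and concatenated
#' in scale order.
#'
#' @param K,V feature maps `c(B, C, H, W)` with identical spatial dims.
#' @param scales increasing positive integer grid sizes.
#' @return list with `Kpsp`, `Vpsp` arrays `c(B, P, C)` where
#'   `P = pyramidTokenCount(H, W, scales)`, plus `scales` and `P`.
#' @export
pyramidPoolKV <- function(K, V, scales) {
  .assertFeatureMap(K, "K")
  .assertFeatureMap(V, "V")
  if (!identical(dim(K)[3:4], dim(V)[3:4]))
    stop("K and V spatial dimensions differ")
  d <- dim(K)
  Pmat <- .pyramidMatrix(d[3L], d[4L], scales)
  pool <- function(M) {
    tk <- .toTokens(M)
    out <- array(0, c(dim(M)[1L], nrow(Pmat), dim(M)[2L]))
    T <- d[3L] * d[4L]
    for (b in seq_len(dim(M)[1L]))
      out[b, , ] <- Pmat %*% tk[((b - 1L) * T + 1L):(b * T), , drop = FALSE]
    out
  }
  list(Kpsp = pool(K), Vpsp = pool(V), scales = scales, P = nrow(Pmat))
}

#' Attention of spatial queries over pyramid-pooled keys/values
#'
#' Standard scaled dot-product attention `softmax(Q Kpsp' / sqrt(d)) Vpsp`
#' per query token and head; queries keep their original spatial coordinates
#' so the output has the query map's shape.
#'
#' @param Q query feature map `c(B, C, H, W)`.
#' @param kv result of [pyramidPoolKV()] with channel count C.
#' @param d per-head feature dimension; C must be divisible by d.
#' @return feature map shaped like `Q`.
#' @export
pyramidAttention <- function(Q, kv, d) {
  .assertFeatureMap(Q, "Q")
  dq <- dim(Q)
  if (!identical(dim(kv$Kpsp), dim(kv$Vpsp)))
    stop("Kpsp and Vpsp token counts differ")
  if (dq[2L] %% d != 0) stop("channels not divisible by head dimension d")
  heads <- dq[2L] %/% d
  T <- dq[3L] * dq[4L]
  x <- .toTokens(Q)
  y <- matrix(0, nrow(x), dq[2L])
  scale <- 1 / sqrt(d)
  for (b in seq_len(dq[1L])) {
    rows <- ((b - 1L) * T + 1L):(b * T)
    for (h in seq_len(heads)) {
      cols <- ((h - 1L) * d + 1L):(h * d)
      at <- .sdpaFwd(x[rows, cols, drop = FALSE],
                     matrix(kv$Kpsp[b, , cols], kv$P),
                     matrix(kv$Vpsp[b, , cols], kv$P), scale)
      y[rows, cols] <- at$O
    }
  }
  .fromTokens(y, dq[1L], dq[2L], dq[3L], dq[4L])
}

#' Context-pyramid forward pass
#'
#' Compression convolution, layer norm, Q/K/V projection from the compressed
#' map, pyramid pooling of K/V, multi-head pyramid attention, output
#' projection. Output has the compressed spatial dims.
#'
#' @param X feature map `c(B, C, H, W)`.
#' @param layer a [dcpLayer()].
#' @return feature map `c(B, outChannels, H/stride, W/stride)`.
#' @export
dcpForward <- function(X, layer) {
  .assertFeatureMap(X)
  d <- dim(X)
  if (d[2L] != layer$inChannels)
    stop(sprintf("input has %d channels, layer expects %d", d[2L], layer$inChannels))
  g <- .dcpGeom(layer, d[3L], d[4L])
  .dcpFwd(layer$params, X, g, d[1L])$y
}

.dcpGeom <- function(layer, Hin, Win) {
  H <- Hin %/% layer$stride
  W <- Win %/% layer$stride
  list(s = layer$stride, C = layer$outChannels, heads = layer$heads,
       d = layer$d, H = H, W = W, T = H * W,
       Pmat = .pyramidMatrix(H, W, layer$scales),
       P = pyramidTokenCount(H, W, layer$scales))
}

# ---- fast core with backward -----------------------------------------------

.dcpFwd <- function(p, X, g, B, resid = FALSE) {
  pc <- .pconvFwd(p$pc, X, g$s)
  x <- .toTokens(pc$y)
  ln <- .lnFwd(p$ln, x)
  lq <- .linFwd(p$q, ln$y)
  lk <- .linFwd(p$k, ln$y)
  lv <- .linFwd(p$v, ln$y)
  O <- matrix(0, nrow(x), g$C)
  scale <- 1 / sqrt(g$d)
  att <- vector("list", B)
  kvp <- vector("list", B)
  for (b in seq_len(B)) {
    rows <- ((b - 1L) * g$T + 1L):(b * g$T)
    Kp <- g$Pmat %*% lk$y[rows, , drop = FALSE]
    Vp <- g$Pmat %*% lv$y[rows, , drop = FALSE]
    hc <- vector("list", g$heads)
    for (h in seq_len(g$heads)) {
      cols <- ((h - 1L) * g$d + 1L):(h * g$d)
      at <- .sdpaFwd(lq$y[rows, cols, drop = FALSE],
                     Kp[, cols, drop = FALSE], Vp[, cols, drop = FALSE], scale)
      O[rows, cols] <- at$O
      hc[[h]] <- at$A
    }
    att[[b]] <- hc
    kvp[[b]] <- list(Kp = Kp, Vp = Vp)
  }
  lo <- .linFwd(p$o, O)
  y <- if (resid) lo$y + x else lo$y
  list(y = .fromTokens(y, B, g$C, g$H, g$W),
       pc = pc, ln = ln, lq = lq, lk = lk, lv = lv, lo = lo,
       att = att, kvp = kvp, resid = resid)
}

.dcpBwd <- function(p, cache, g, B, dY) {
  dy <- .toTokens(dY)
  lo <- .linBwd(p$o, cache$lo, dy)
  dO <- lo$dx
  dQ <- matrix(0, nrow(dy), g$C)
  dKp <- matrix(0, g$P, g$C)
  dK <- matrix(0, nrow(dy), g$C)
  dV <- matrix(0, nrow(dy), g$C)
  scale <- 1 / sqrt(g$d)
  for (b in seq_len(B)) {
    rows <- ((b - 1L) * g$T + 1L):(b * g$T)
    dKp[] <- 0
    dVp <- matrix(0, g$P, g$C)
    for (h in seq_len(g$heads)) {
      cols <- ((h - 1L) * g$d + 1L):(h * g$d)
      sb <- .sdpaBwd(cache$lq$y[rows, cols, drop = FALSE],
                     cache$kvp[[b]]$Kp[, cols, drop = FALSE],
                     cache$kvp[[b]]$Vp[, cols, drop = FALSE],
                     cache$att[[b]][[h]], dO[rows, cols, drop = FALSE], scale)
      dQ[rows, cols] <- sb$dQ
      dKp[, cols] <- sb$dK
      dVp[, cols] <- sb$dV
    }
    dK[rows, ] <- crossprod(g$Pmat, dKp)
    dV[rows, ] <- crossprod(g$Pmat, dVp)
  }
  bq <- .linBwd(p$q, cache$lq, dQ)
  bk <- .linBwd(p$k, cache$lk, dK)
  bv <- .linBwd(p$v, cache$lv, dV)
  lnb <- .lnBwd(p$ln, cache$ln, bq$dx + bk$dx + bv$dx)
  dxc <- if (cache$resid) lnb$dx + dy else lnb$dx
  pcb <- .pconvBwd(p$pc, cache$pc, .fromTokens(dxc, B, g$C, g$H, g$W))
  list(dx = pcb$dx,
       dp = list(pc = pcb$dp, ln = lnb$dp, q = bq$dp, k = bk$dp, v = bv$dp,
                 o = lo$dp))
}
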