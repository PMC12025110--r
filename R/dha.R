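# Dermoscopic Hierarchical Attention (DHA): two-stage routed attention.
# Stage one scores coarse regions (mean-pooled queries/keys, unnormalized dot
# products) and keeps the top-k regions per query region; stage two runs
# ordinary scaled dot-product attention for each query token over the tokens
# of its retained regions only.

# ---- region geometry -------------------------------------------------------

.regionGeom <- function(H, W, n) {
  if (H %% n != 0 || W %% n != 0)
    stop(sprintf("region grid n=%d does not divide the %dx%d feature map (H=%d, W=%d)",
                 n, H, W, H, W))
  th <- H %/% n
  tw <- W %/% n
  hh <- rep(0:(H - 1L), each = W)
  ww <- rep(0:(W - 1L), times = H)
  reg <- (hh %/% th) * n + (ww %/% tw) + 1L # row-major tile order
  tokens <- split(seq_len(H * W), reg)      # row-major token order within tile
  Rm <- matrix(0, n * n, H * W)
  for (r in seq_len(n * n)) Rm[r, tokens[[r]]] <- 1 / length(tokens[[r]])
  list(N = n * n, m = th * tw, reg = reg, tokens = tokens, Rm = Rm)
}

.topkRows <- function(S, k) {
  N <- ncol(S)
  if (k < 1 || k > N) stop(sprintf("k=%d out of range [1, %d]", k, N))
  out <- matrix(0L, nrow(S), k)
  for (i in seq_len(nrow(S)))
    out[i, ] <- sort.int(order(-S[i, ])[seq_len(k)]) # stable: ties keep lowest index
  out
}

# ---- layer constructor ------------------------------------------------------

#' Construct a hierarchical routing-attention layer
#'
#' Creates the learnable parameters (Q/K/V projections and the output
#' projection after head concatenation) for a DHA layer. Routing is computed
#' independently per head and per image.
#'
#' @param channels feature channels C; must be divisible by `heads`.
#' @param heads number of attention heads (per-head dimension d = C/heads).
#' @param regionGrid n; the map is tiled into an n x n grid of N = n^2 regions.
#' @param topk number of regions each query region retains, 1 <= k <= n^2.
#' @param seed integer seed for weight initialization.
#' @return a list of class `dhaLayer`.
#' @examples
#' layer <- dhaLayer(channels = 16, heads = 2, regionGrid = 2, topk = 2)
#' X <- array(rnorm(16 * 64), c(1, 16, 8, 8))
#' dim(dhaForward(X, layer)) # same as input
#' @export
dhaLayer <- function(channels, heads = 1L, regionGrid = 2L, topk = regionGrid^2,
                     seed = 0L) {
  if (channels %% heads != 0)
    stop(sprintf("channels %d not divisible by heads %d", channels, heads))
  if (topk < 1 || topk > regionGrid^2)
    stop(sprintf("topk=%d out of range [1, %d]", topk, regionGrid^2))
  set.seed(seed)
  params <- list(q = .initLinear(channels, channels),
                 k = .initLinear(channels, channels),
                 v = .initLinear(channels, channels),
                 o = .initLinear(channels, channels))
  structure(list(channels = as.integer(channels), heads = as.integer(heads),
                 d = as.integer(channels %/% heads),
                 regionGrid = as.integer(regionGrid), topk = as.integer(topk),
                 params = params),
            class = "dhaLayer")
}

.dhaGeomFor <- function(layer, H, W) {
  rg <- .regionGeom(H, W, layer$regionGrid)
  c(rg, list(T = H * W, C = layer$channels, heads = layer$heads, d = layer$d,
             k = layer$topk, n = layer$regionGrid, H = H, W = W))
}

# ---- reference operations (spec-level semantics) ---------------------------

#' Project tokens to Q/K/V and partition them into regions
#'
#' Applies the layer's linear Q/K/V maps to every pixel token and arranges
#' the result by region: region r holds exactly the tokens of the r-th tile
#' of the n x n grid (row-major region order, row-major token order within a
#' tile).
#'
#' @param X feature map, array `c(B, C, H, W)`; H and W must be divisible by
#'   the layer's region grid.
#' @param layer a [dhaLayer()].
#' @return list with arrays `Q`, `K`, `V` of dim `c(B, heads, N, m, d)` where
#'   `N = n^2` and `m = H*W/N`, plus the geometry fields `H, W, n, d, heads`.
#' @export
projectAndPartition <- function(X, layer) {
  .assertFeatureMap(X)
  d <- dim(X)
  if (d[2L] != layer$channels)
    stop(sprintf("input has %d channels, layer expects %d", d[2L], layer$channels))
  g <- .dhaGeomFor(layer, d[3L], d[4L])
  x <- .toTokens(X)
  proj <- list(Q = .linFwd(layer$params$q, x)$y,
               K = .linFwd(layer$params$k, x)$y,
               V = .linFwd(layer$params$v, x)$y)
  B <- d[1L]
  arrange <- function(M) {
    out <- array(0, c(B, g$heads, g$N, g$m, g$d))
    ord <- unlist(g$tokens, use.names = FALSE)
    for (b in seq_len(B)) {
      rows <- ((b - 1L) * g$T + 1L):(b * g$T)
      for (h in seq_len(g$heads)) {
        cols <- ((h - 1L) * g$d + 1L):(h * g$d)
        A <- M[rows, cols, drop = FALSE][ord, , drop = FALSE]
        dim(A) <- c(g$m, g$N, g$d)
        out[b, h, , , ] <- aperm(A, c(2L, 1L, 3L))
      }
    }
    out
  }
  list(Q = arrange(proj$Q), K = arrange(proj$K), V = arrange(proj$V),
       H = g$H, W = g$W, n = g$n, d = g$d, heads = g$heads)
}

#' Mean-pool each region to region-level queries and keys
#'
#' @param qkv result of [projectAndPartition()].
#' @return list with `Qr`, `Kr` of dim `c(B, heads, N, d)`; row r is the
#'   arithmetic mean of region r's tokens.
#' @export
regionSummarize <- function(qkv) {
  if (anyNA(qkv$Q) || anyNA(qkv$K)) stop("NaN values in Q/K")
  list(Qr = apply(qkv$Q, c(1L, 2L, 3L, 5L), mean),
       Kr = apply(qkv$K, c(1L, 2L, 3L, 5L), mean),
       heads = qkv$heads, d = qkv$d)
}

#' Region-to-region affinity scores
#'
#' Plain dot products of region summaries, with no scaling or normalization:
#' `S[i, j] = Qr[i] . Kr[j]`.
#'
#' @param summary result of [regionSummarize()].
#' @return array `c(B, heads, N, N)`.
#' @export
regionAffinity <- function(summary) {
  dq <- dim(summary$Qr)
  dk <- dim(summary$Kr)
  if (!identical(dq, dk)) stop("Qr and Kr dimensions differ")
  B <- dq[1L]; heads <- dq[2L]; N <- dq[3L]
  S <- array(0, c(B, heads, N, N))
  for (b in seq_len(B)) for (h in seq_len(heads))
    S[b, h, , ] <- tcrossprod(
      matrix(summary$Qr[b, h, , ], N), matrix(summary$Kr[b, h, , ], N))
  S
}

#' Retain the top-k regions per query region
#'
#' Indices of the k largest entries per row of the affinity matrix, ties
#' broken toward the lowest index, returned sorted ascending.
#'
#' @param S an N x N affinity matrix or an array `c(B, heads, N, N)`.
#' @param k number of regions to retain, 1 <= k <= N.
#' @return an N x k integer matrix (or array `c(B, heads, N, k)`).
#' @examples
#' routeTopk(matrix(c(0.2, 0.9, 0.5), 1), 1) # region 2
#' @export
routeTopk <- function(S, k) {
  if (is.matrix(S)) return(.topkRows(S, k))
  d <- dim(S)
  if (length(d) != 4L) stop("S must be a matrix or a (B, heads, N, N) array")
  out <- array(0L, c(d[1L], d[2L], d[3L], k))
  for (b in seq_len(d[1L])) for (h in seq_len(d[2L]))
    out[b, h, , ] <- .topkRows(matrix(S[b, h, , ], d[3L]), k)
  out
}

#' Token-level attention over the retained regions
#'
#' For every query token, gathers the key/value tokens of its region's
#' retained regions (bit-identical copies, ascending region order) and
#' applies scaled dot-product attention `softmax(q Kt' / sqrt(d)) Vt`. The
#' result is reassembled into a feature map of the input's spatial size.
#'
#' @param qkv result of [projectAndPartition()].
#' @param routing result of [routeTopk()] (array form).
#' @param returnWeights also return the attention weight matrices.
#' @return feature map `c(B, heads*d, H, W)`; with `returnWeights = TRUE`, a
#'   list with elements `Y` and `weights` (nested per image/head/region).
#' @export
gatherAndAttend <- function(qkv, routing, returnWeights = FALSE) {
  dq <- dim(qkv$Q)
  B <- dq[1L]; heads <- dq[2L]; N <- dq[3L]; m <- dq[4L]; d <- dq[5L]
  if (!identical(dim(routing)[1:3], c(B, heads, N)))
    stop("routing inconsistent with qkv dimensions")
  H <- qkv$H; W <- qkv$W
  g <- .regionGeom(H, W, qkv$n)
  scale <- 1 / sqrt(d)
  y <- matrix(0, B * H * W, heads * d)
  weights <- if (returnWeights) vector("list", B)
  for (b in seq_len(B)) {
    wh <- if (returnWeights) vector("list", heads)
    for (h in seq_len(heads)) {
      wr <- if (returnWeights) vector("list", N)
      for (i in seq_len(N)) {
        ridx <- routing[b, h, i, ]
        Kt <- do.call(rbind, lapply(ridx, function(r) matrix(qkv$K[b, h, r, , ], m, d)))
        Vt <- do.call(rbind, lapply(ridx, function(r) matrix(qkv$V[b, h, r, , ], m, d)))
        at <- .sdpaFwd(matrix(qkv$Q[b, h, i, , ], m, d), Kt, Vt, scale)
        rows <- (b - 1L) * H * W + g$tokens[[i]]
        y[rows, ((h - 1L) * d + 1L):(h * d)] <- at$O
        if (returnWeights) wr[[i]] <- at$A
      }
      if (returnWeights) wh[[h]] <- wr
    }
    if (returnWeights) weights[[b]] <- wh
  }
  Y <- .fromTokens(y, B, heads * d, H, W)
  if (returnWeights) list(Y = Y, weights = weights) else Y
}

#' Hierarchical routing-attention forward pass
#'
#' Full DHA block: Q/K/V projection and region partition, region mean
#' pooling, affinity scoring, top-k routing, token-level attention within
#' the retained regions, head concatenation and output projection. Output
#' shape equals input shape. With a 1 x 1 region grid (N = k = 1) this is
#' exactly standard global multi-head self-attention.
#'
#' @param X feature map, array `c(B, C, H, W)`.
#' @param layer a [dhaLayer()].
#' @return feature map of the same shape as `X`.
#' @export
dhaForward <- function(X, layer) {
  .assertFeatureMap(X)
  d <- dim(X)
  if (d[2L] != layer$channels)
    stop(sprintf("input has %d channels, layer expects %d", d[2L], layer$channels))
  g <- .dhaGeomFor(layer, d[3L], d[4L])
  out <- .dhaCoreFwd(layer$params, .toTokens(X), g, d[1L])
  .fromTokens(out$y, d[1L], d[2L], d[3L], d[4L])
}

# ---- fast core used by the network -----------------------------------------
# Identical arithmetic to the reference composition above, organized as one
# pass over token matrices with a full fwd/bwd pair. Routing is discrete and
# carries no gradient; gradients flow through Q, K, V of the attended tokens.
#
# Three equivalent execution strategies per (image, head):
#   * k == N           : one dense attention over all tokens
#   * small maps       : dense scores with -Inf on non-retained region pairs
#                        (softmax weights of masked entries are exactly 0)
#   * large maps       : explicit per-query-region gather (memory-bounded)
.DHA_MASK_MAX_T <- 1024L

.dhaCoreFwd <- function(p, x, g, B) {
  lq <- .linFwd(p$q, x)
  lk <- .linFwd(p$k, x)
  lv <- .linFwd(p$v, x)
  O <- matrix(0, nrow(x), g$C)
  scale <- 1 / sqrt(g$d)
  dense <- g$k == g$N
  masked <- !dense && g$T <= .DHA_MASK_MAX_T
  cache <- vector("list", B)
  for (b in seq_len(B)) {
    rows <- ((b - 1L) * g$T + 1L):(b * g$T)
    hc <- vector("list", g$heads)
    for (h in seq_len(g$heads)) {
      cols <- ((h - 1L) * g$d + 1L):(h * g$d)
      Qh <- lq$y[rows, cols, drop = FALSE]
      Kh <- lk$y[rows, cols, drop = FALSE]
      Vh <- lv$y[rows, cols, drop = FALSE]
      if (dense) {
        at <- .sdpaFwd(Qh, Kh, Vh, scale)
        O[rows, cols] <- at$O
        hc[[h]] <- list(A = at$A)
        next
      }
      S <- tcrossprod(g$Rm %*% Qh, g$Rm %*% Kh)
      route <- .topkRows(S, g$k)
      if (masked) {
        allowReg <- matrix(FALSE, g$N, g$N)
        allowReg[cbind(rep(seq_len(g$N), g$k), as.vector(route))] <- TRUE
        St <- tcrossprod(Qh, Kh) * scale
        St[!allowReg[g$reg, g$reg]] <- -Inf
        A <- .softmaxRows(St)
        O[rows, cols] <- A %*% Vh
        hc[[h]] <- list(A = A)
      } else {
        regs <- vector("list", g$N)
        for (i in seq_len(g$N)) {
          qi <- g$tokens[[i]]
          gidx <- unlist(g$tokens[route[i, ]], use.names = FALSE)
          at <- .sdpaFwd(Qh[qi, , drop = FALSE], Kh[gidx, , drop = FALSE],
                         Vh[gidx, , drop = FALSE], scale)
          O[rows[qi], cols] <- at$O
          regs[[i]] <- list(A = at$A, gidx = gidx)
        }
        hc[[h]] <- regs
      }
    }
    cache[[b]] <- hc
  }
  lo <- .linFwd(p$o, O)
  list(y = lo$y, lq = lq, lk = lk, lv = lv, lo = lo, att = cache,
       full = dense || masked)
}

.dhaCoreBwd <- function(p, cache, g, B, dy) {
  lo <- .linBwd(p$o, cache$lo, dy)
  dO <- lo$dx
  dQ <- matrix(0, nrow(dy), g$C)
  dK <- matrix(0, nrow(dy), g$C)
  dV <- matrix(0, nrow(dy), g$C)
  scale <- 1 / sqrt(g$d)
  for (b in seq_len(B)) {
    rows <- ((b - 1L) * g$T + 1L):(b * g$T)
    for (h in seq_len(g$heads)) {
      cols <- ((h - 1L) * g$d + 1L):(h * g$d)
      Qh <- cache$lq$y[rows, cols, drop = FALSE]
      Kh <- cache$lk$y[rows, cols, drop = FALSE]
      Vh <- cache$lv$y[rows, cols, drop = FALSE]
      hcc <- cache$att[[b]][[h]]
      if (cache$full) {
        sb <- .sdpaBwd(Qh, Kh, Vh, hcc$A, dO[rows, cols, drop = FALSE], scale)
        dQ[rows, cols] <- sb$dQ
        dK[rows, cols] <- sb$dK
        dV[rows, cols] <- sb$dV
        next
      }
      for (i in seq_len(g$N)) {
        qi <- g$tokens[[i]]
        reg <- hcc[[i]]
        gidx <- reg$gidx
        sb <- .sdpaBwd(Qh[qi, , drop = FALSE], Kh[gidx, , drop = FALSE],
                       Vh[gidx, , drop = FALSE], reg$A,
                       dO[rows[qi], cols, drop = FALSE], scale)
        dQ[rows[qi], cols] <- dQ[rows[qi], cols] + sb$dQ
        dK[rows[gidx], cols] <- dK[rows[gidx], cols] + sb$dK
        dV[rows[gidx], cols] <- dV[rows[gidx], cols] + sb$dV
      }
    }
  }
  bq <- .linBwd(p$q, cache$lq, dQ)
  bk <- .linBwd(p$k, cache$lk, dK)
  bv <- .linBwd(p$v, cache$lv, dV)
  list(dx = bq$dx + bk$dx + bv$dx,
       dp = list(q = bq$dp, k = bk$dp, v = bv$dp, o = lo$dp))
}
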