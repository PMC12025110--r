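# Internal numeric kernels. All layers are implemented as fwd/bwd pairs on
# plain double arrays so the whole network is differentiable by hand-rolled
# reverse-mode composition.
#
# Conventions used throughout:
#   * feature map  : array dim c(B, C, H, W)
#   * token matrix : (B*H*W) x C, token order w fastest, then h, then image
#   * params       : nested named lists with array leaves; gradients mirror them

.EPS_LN <- 1e-5

# ---- feature map <-> token matrix ------------------------------------------

.toTokens <- function(X) {
  d <- dim(X)
  m <- aperm(X, c(4L, 3L, 1L, 2L)) # W H B C
  dim(m) <- c(d[4L] * d[3L] * d[1L], d[2L])
  m
}

.fromTokens <- function(m, B, C, H, W) {
  dim(m) <- c(W, H, B, C)
  aperm(m, c(3L, 4L, 2L, 1L))
}

.assertFeatureMap <- function(X, what = "X") {
  if (!is.array(X) || length(dim(X)) != 4L)
    stop(sprintf("%s must be a 4-D array (batch, channels, height, width)", what))
  if (!all(is.finite(X)))
    stop(sprintf("%s contains non-finite values", what))
  invisible(X)
}

# ---- broadcasting helpers ---------------------------------------------------

# add a length-ncol row vector to every row
.addRV <- function(m, v) m + rep(v, each = nrow(m))
# multiply every row elementwise by a length-ncol vector
.mulRV <- function(m, v) m * rep(v, each = nrow(m))

# ---- linear (== 1x1 convolution on tokens) ---------------------------------

.linFwd <- function(p, x) {
  list(y = .addRV(x %*% p$W, p$b), x = x)
}

.linBwd <- function(p, cache, dy) {
  list(dx = tcrossprod(dy, p$W),
       dp = list(W = crossprod(cache$x, dy), b = colSums(dy)))
}

# ---- layer norm over channels, per token -----------------------------------

.lnFwd <- function(p, x) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc * xc)
  inv <- 1 / sqrt(v + .EPS_LN)
  xhat <- xc * inv
  list(y = .addRV(.mulRV(xhat, p$g), p$b), xhat = xhat, inv = inv)
}

.lnBwd <- function(p, cache, dy) {
  xhat <- cache$xhat
  dxh <- .mulRV(dy, p$g)
  rm1 <- rowMeans(dxh)
  rm2 <- rowMeans(dxh * xhat)
  dx <- cache$inv * (dxh - rm1 - xhat * rm2)
  list(dx = dx, dp = list(g = colSums(dy * xhat), b = colSums(dy)))
}

# ---- relu / dropout --------------------------------------------------------

.reluFwd <- function(x) list(y = x * (x > 0), mask = x > 0)
.reluBwd <- function(cache, dy) dy * cache$mask

.dropFwd <- function(x, rate, training) {
  if (!training || rate <= 0) return(list(y = x, mask = NULL))
  mask <- (stats::runif(length(x)) >= rate) / (1 - rate)
  dim(mask) <- dim(x)
  list(y = x * mask, mask = mask)
}

.dropBwd <- function(cache, dy) if (is.null(cache$mask)) dy else dy * cache$mask

# ---- patch-merging convolution (kernel == stride) --------------------------
# Unfolds non-overlapping s x s patches and applies a linear map, so the
# weight layout is (Cin*s*s) x Cout with input-channel fastest, then patch
# row offset, then patch column offset.

.patchify <- function(X, s) {
  d <- dim(X) # B C H W
  Ho <- d[3L] %/% s; Wo <- d[4L] %/% s
  dim(X) <- c(d[1L], d[2L], s, Ho, s, Wo)
  Xp <- aperm(X, c(6L, 4L, 1L, 2L, 3L, 5L)) # Wo Ho B C sa sb
  dim(Xp) <- c(Wo * Ho * d[1L], d[2L] * s * s)
  Xp
}

.unpatchify <- function(dXp, B, C, H, W, s) {
  Ho <- H %/% s; Wo <- W %/% s
  dim(dXp) <- c(Wo, Ho, B, C, s, s)
  dX <- aperm(dXp, c(3L, 4L, 5L, 2L, 6L, 1L)) # B C sa Ho sb Wo
  dim(dX) <- c(B, C, H, W)
  dX
}

.pconvFwd <- function(p, X, s) {
  d <- dim(X)
  if (d[3L] %% s != 0 || d[4L] %% s != 0)
    stop(sprintf("spatial dims %dx%d not divisible by stride %d", d[3L], d[4L], s))
  Xp <- .patchify(X, s)
  lin <- .linFwd(p, Xp)
  list(y = .fromTokens(lin$y, d[1L], ncol(p$W), d[3L] %/% s, d[4L] %/% s),
       x = Xp, dims = d, s = s)
}

.pconvBwd <- function(p, cache, dY) {
  d <- cache$dims
  dy <- .toTokens(dY)
  lb <- .linBwd(p, cache, dy)
  list(dx = .unpatchify(lb$dx, d[1L], d[2L], d[3L], d[4L], cache$s), dp = lb$dp)
}

# ---- 3x3 depthwise convolution, zero padding 1 -----------------------------
# weights: array c(C, 3, 3); per-channel scaling uses first-two-dim recycling
# of a length B*C vector over a (B, C, H, W) slice.

# Internally the (B, C, H, W) map is viewed as a (B*C) x (H*W) matrix and the
# zero-padded neighborhoods are gathered by precomputed column indices; the
# per-channel kernel weights recycle down the B*C rows.

.dwOffsets <- function(H, W) {
  Hp <- H + 2L
  lapply(1:9, function(o) {
    a <- (o - 1L) %% 3L
    bb <- (o - 1L) %/% 3L
    as.vector(outer((a + 1L):(a + H), (bb + 1L):(bb + W),
                    function(r, cc) r + (cc - 1L) * Hp))
  })
}

.dwFwd <- function(p, X) {
  d <- dim(X)
  B <- d[1L]; C <- d[2L]; H <- d[3L]; W <- d[4L]
  off <- .dwOffsets(H, W)
  Mp <- matrix(0, B * C, (H + 2L) * (W + 2L))
  dim(X) <- c(B * C, H * W)
  Mp[, off[[5L]]] <- X # offset (0,0) is the center of the 3x3 window
  Y <- matrix(rep(p$b, each = B), B * C, H * W)
  for (o in 1:9) {
    wv <- rep(p$w[, (o - 1L) %% 3L + 1L, (o - 1L) %/% 3L + 1L], each = B)
    Y <- Y + Mp[, off[[o]], drop = FALSE] * wv
  }
  dim(Y) <- c(B, C, H, W)
  list(y = Y, mp = Mp, off = off, dims = d)
}

.dwBwd <- function(p, cache, dY) {
  d <- cache$dims
  B <- d[1L]; C <- d[2L]; H <- d[3L]; W <- d[4L]
  off <- cache$off
  dim(dY) <- c(B * C, H * W)
  dMp <- matrix(0, B * C, (H + 2L) * (W + 2L))
  dw <- array(0, c(C, 3L, 3L))
  for (o in 1:9) {
    a <- (o - 1L) %% 3L + 1L
    bb <- (o - 1L) %/% 3L + 1L
    wv <- rep(p$w[, a, bb], each = B)
    dMp[, off[[o]]] <- dMp[, off[[o]], drop = FALSE] + dY * wv
    sc <- rowSums(cache$mp[, off[[o]], drop = FALSE] * dY)
    dim(sc) <- c(B, C)
    dw[, a, bb] <- colSums(sc)
  }
  db <- rowSums(dY)
  dim(db) <- c(B, C)
  dx <- dMp[, off[[5L]], drop = FALSE]
  dim(dx) <- c(B, C, H, W)
  list(dx = dx, dp = list(w = dw, b = colSums(db)))
}

# ---- adaptive average pooling ----------------------------------------------
# Bin i of g over length L spans (floor((i-1)L/g), ceil(iL/g)] (0-based),
# matching the usual adaptive-pool convention; returns the g x L averaging
# matrix.

.poolMatrix1d <- function(L, g) {
  P <- matrix(0, g, L)
  for (i in seq_len(g)) {
    a <- floor((i - 1) * L / g) + 1L
    b <- ceiling(i * L / g)
    P[i, a:b] <- 1 / (b - a + 1L)
  }
  P
}

# token-level pooling matrix (g*g pooled tokens x H*W tokens), pooled tokens
# ordered row-major (column index fastest) like the token convention
.poolMatrix2d <- function(H, W, g) {
  kronecker(.poolMatrix1d(H, g), .poolMatrix1d(W, g))
}

# ---- scaled dot-product attention core -------------------------------------

.softmaxRows <- function(S) {
  n <- nrow(S)
  mx <- S[seq_len(n) + (max.col(S, ties.method = "first") - 1L) * n]
  E <- exp(S - mx)
  A <- E / rowSums(E)
  if (anyNA(A)) stop("softmax produced NaN attention weights (overflow?)")
  A
}

.sdpaFwd <- function(Q, K, V, scale) {
  A <- .softmaxRows(tcrossprod(Q, K) * scale)
  list(O = A %*% V, A = A)
}

.sdpaBwd <- function(Q, K, V, A, dO, scale) {
  dV <- crossprod(A, dO)
  dA <- tcrossprod(dO, V)
  dS <- A * (dA - rowSums(A * dA))
  list(dQ = (dS %*% K) * scale, dK = crossprod(dS, Q) * scale, dV = dV)
}

# ---- initializers (draw from the global RNG) -------------------------------

.initLinear <- function(din, dout) {
  l <- sqrt(6 / (din + dout))
  list(W = matrix(stats::runif(din * dout, -l, l), din, dout), b = numeric(dout))
}

.initDW <- function(C) {
  list(w = array(stats::rnorm(C * 9L, sd = sqrt(2 / 9)), c(C, 3L, 3L)),
       b = numeric(C))
}

.initLN <- function(C) list(g = rep(1, C), b = numeric(C))

# ---- parameter-tree utilities ----------------------------------------------

.treeMap <- function(f, p) {
  if (is.list(p)) lapply(p, function(e) .treeMap(f, e)) else f(p)
}

.treeMap2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (nm in names(a)) out[[nm]] <- .treeMap2(f, a[[nm]], b[[nm]])
    out
  } else f(a, b)
}

.zeroLike <- function(p) .treeMap(function(x) x * 0, p)
.treeAdd <- function(a, b) .treeMap2(`+`, a, b)

.treeLeaves <- function(p) {
  if (!is.list(p)) return(list(p))
  do.call(c, lapply(p, .treeLeaves))
}

.nParams <- function(p) sum(vapply(.treeLeaves(p), length, integer(1)))

# ---- AdamW ------------------------------------------------------------------
# Decoupled weight decay, applied to >=2-D weight arrays only (biases and
# norm scales are exempt, the usual transformer practice).

.adamInit <- function() {
  e <- new.env(parent = emptyenv())
  e$m <- list(); e$v <- list(); e$t <- 0L
  e
}

.adamStep <- function(p, g, st, lr, wd, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1L
  bc1 <- 1 - beta1^st$t
  bc2 <- 1 - beta2^st$t
  rec <- function(p, g, path) {
    if (is.list(p)) {
      for (nm in names(p)) p[[nm]] <- rec(p[[nm]], g[[nm]], paste0(path, ".", nm))
      return(p)
    }
    m <- st$m[[path]]; v <- st$v[[path]]
    if (is.null(m)) { m <- p * 0; v <- p * 0 }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    st$m[[path]] <- m; st$v[[path]] <- v
    upd <- (m / bc1) / (sqrt(v / bc2) + eps)
    if (!is.null(dim(p)) && length(dim(p)) >= 2L) upd <- upd + wd * p
    p - lr * upd
  }
  rec(p, g, "")
}
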