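# Four-stage cascade: each stage downsamples with a DCP unit (strided
# compression + pyramid attention), then runs `depth` residual pre-norm
# blocks of [DHA -> DFG]. Head: layer norm, global average pooling, linear
# classifier. Ablation switches swap each bespoke block for its conventional
# counterpart (dense MHSA / plain strided conv / 4x FFN).

#' Build a DermViT model configuration
#'
#' The default stage plan (strides 4,2,2,2; channels 64,128,256,512; depths
#' 2,2,6,2; heads = channels/32; 7x7 region grid with top-k 1,4,16,49;
#' pyramid scales 1,2,4,16) instantiates the full-size classifier: 11.8 M
#' parameters and about 2.2 G MACs at 224 px, the published model's budget
#' regime. Region grids are clamped at build time to the
#' largest divisor of the stage's map size, and top-k to the resulting
#' region count.
#'
#' @param imageSize square input resolution (default 224).
#' @param numClasses number of diagnosis classes (7 for ISIC2018-style data,
#'   9 for ISIC2019-style).
#' @param channels,depths,heads,regionGrid,topk,strides length-4 integer
#'   vectors of per-stage settings.
#' @param scales pyramid pooling grid sizes (shared across stages), or a
#'   list of four vectors.
#' @param useDHA,useDCP,useDFG ablation switches: `useDHA = FALSE` replaces
#'   routed attention by dense multi-head self-attention (region grid 1),
#'   `useDCP = FALSE` replaces the context pyramid by a plain strided
#'   convolution, `useDFG = FALSE` replaces the gated feed-forward by a
#'   standard 4x-expansion FFN.
#' @param dropout dropout rate in the feed-forward block.
#' @param seed integer weight-initialization seed.
#' @return a [DermViTConfig-class].
#' @examples
#' cfg <- dermViTConfig(imageSize = 32, channels = c(8, 16, 16, 32),
#'                      depths = c(1, 1, 1, 1), heads = c(1, 2, 2, 4),
#'                      numClasses = 4)
#' @export
dermViTConfig <- function(imageSize = 224L, numClasses = 7L,
                          channels = c(64L, 128L, 256L, 512L),
                          depths = c(2L, 2L, 6L, 2L),
                          heads = pmax(1L, channels %/% 32L),
                          regionGrid = c(7L, 7L, 7L, 7L),
                          topk = c(1L, 4L, 16L, 49L),
                          strides = c(4L, 2L, 2L, 2L),
                          scales = c(1L, 2L, 4L, 16L),
                          useDHA = TRUE, useDCP = TRUE, useDFG = TRUE,
                          dropout = 0.1, seed = 0L) {
  if (!is.list(scales)) scales <- rep(list(scales), 4L)
  stages <- lapply(seq_len(4L), function(i) list(
    channels = as.integer(channels[i]), depth = as.integer(depths[i]),
    heads = as.integer(heads[i]), regionGrid = as.integer(regionGrid[i]),
    topk = as.integer(topk[i]), stride = as.integer(strides[i]),
    scales = as.integer(scales[[i]])))
  new("DermViTConfig", imageSize = as.integer(imageSize),
      numClasses = as.integer(numClasses), stages = stages,
      useDHA = useDHA, useDCP = useDCP, useDFG = useDFG,
      dropout = dropout, seed = as.integer(seed))
}

# largest grid <= n dividing both H and W
.effGrid <- function(n, H, W) {
  for (m in seq.int(min(n, H, W), 1L)) if (H %% m == 0 && W %% m == 0) return(m)
  1L
}

#' Build a DermViT model from a configuration
#'
#' Initializes all weights (seeded) and precomputes per-stage geometry
#' (map sizes, effective region grids, routing/pooling structures).
#'
#' @param config a [dermViTConfig()].
#' @return a [DermViTModel-class].
#' @export
dermViT <- function(config) {
  validObject(config)
  set.seed(config@seed)
  H <- config@imageSize
  Cin <- 3L
  geomStages <- vector("list", 4L)
  paramStages <- vector("list", 4L)
  for (s in seq_len(4L)) {
    st <- config@stages[[s]]
    C <- st$channels
    Hs <- H %/% st$stride
    if (Hs < 1L)
      stop(sprintf("stage %d: stride %d collapses the %dx%d map", s, st$stride, H, H))
    if (H %% st$stride != 0)
      stop(sprintf("stage %d: map %dx%d not divisible by stride %d", s, H, H, st$stride))
    n <- if (config@useDHA) .effGrid(st$regionGrid, Hs, Hs) else 1L
    k <- min(st$topk, n^2)
    d <- C %/% st$heads
    dcpG <- list(s = st$stride, C = C, heads = st$heads, d = d,
                 H = Hs, W = Hs, T = Hs * Hs)
    if (config@useDCP) {
      dcpG$Pmat <- .pyramidMatrix(Hs, Hs, st$scales)
      dcpG$P <- pyramidTokenCount(Hs, Hs, st$scales)
    }
    attnG <- c(.regionGeom(Hs, Hs, n),
               list(T = Hs * Hs, C = C, heads = st$heads, d = d, k = k, n = n,
                    H = Hs, W = Hs))
    ffnG <- list(H = Hs, W = Hs, C = C, h = if (config@useDFG) 2L * C else 4L * C)
    geomStages[[s]] <- list(dcp = dcpG, attn = attnG, ffn = ffnG,
                            useDCP = config@useDCP, useDFG = config@useDFG,
                            C = C, H = Hs, W = Hs, depth = st$depth)
    pc <- .initLinear(Cin * st$stride^2, C)
    dcpP <- if (config@useDCP)
      list(pc = pc, ln = .initLN(C), q = .initLinear(C, C),
           k = .initLinear(C, C), v = .initLinear(C, C), o = .initLinear(C, C))
    else list(pc = pc)
    blocks <- vector("list", st$depth)
    for (b in seq_len(st$depth)) {
      att <- list(q = .initLinear(C, C), k = .initLinear(C, C),
                  v = .initLinear(C, C), o = .initLinear(C, C))
      ffn <- if (config@useDFG)
        list(ex = .initLinear(C, 4L * C), dw = .initDW(2L * C),
             pr = .initLinear(2L * C, C))
      else
        list(f1 = .initLinear(C, 4L * C), f2 = .initLinear(4L * C, C))
      blocks[[b]] <- list(ln1 = .initLN(C), att = att, ln2 = .initLN(C),
                          ffn = ffn)
    }
    paramStages[[s]] <- list(dcp = dcpP, blocks = blocks)
    Cin <- C
    H <- Hs
  }
  params <- list(stages = paramStages,
                 head = list(ln = .initLN(Cin),
                             fc = .initLinear(Cin, config@numClasses)))
  new("DermViTModel", config = config, params = params,
      geom = list(stages = geomStages, finalC = Cin, finalH = H))
}

# ---- full forward / backward -----------------------------------------------

.ffnFwd <- function(p, x, training, rate) {
  l1 <- .linFwd(p$f1, x)
  mask <- l1$y > 0
  h <- l1$y * mask
  l2 <- .linFwd(p$f2, h)
  dr <- .dropFwd(l2$y, rate, training)
  list(y = dr$y, l1 = l1, mask = mask, l2 = l2, dr = dr)
}

.ffnBwd <- function(p, cache, dy) {
  dy <- .dropBwd(cache$dr, dy)
  l2 <- .linBwd(p$f2, cache$l2, dy)
  l1 <- .linBwd(p$f1, cache$l1, l2$dx * cache$mask)
  list(dx = l1$dx, dp = list(f1 = l1$dp, f2 = l2$dp))
}

.modelFwd <- function(model, X, training = FALSE) {
  .assertFeatureMap(X)
  p <- model@params
  gm <- model@geom
  B <- dim(X)[1L]
  drop <- model@config@dropout
  stageCache <- vector("list", 4L)
  stageOut <- vector("list", 4L)
  cur <- X
  x <- NULL
  for (s in seq_len(4L)) {
    g <- gm$stages[[s]]
    if (g$useDCP) {
      dc <- .dcpFwd(p$stages[[s]]$dcp, cur, g$dcp, B, resid = TRUE)
    } else {
      dc <- .pconvFwd(p$stages[[s]]$dcp$pc, cur, g$dcp$s)
    }
    x <- .toTokens(dc$y)
    blocks <- vector("list", g$depth)
    for (bk in seq_len(g$depth)) {
      bp <- p$stages[[s]]$blocks[[bk]]
      ln1 <- .lnFwd(bp$ln1, x)
      at <- .dhaCoreFwd(bp$att, ln1$y, g$attn, B)
      x <- x + at$y
      ln2 <- .lnFwd(bp$ln2, x)
      ff <- if (g$useDFG) .dfgFwd(bp$ffn, ln2$y, g$ffn, B, training, drop)
            else .ffnFwd(bp$ffn, ln2$y, training, drop)
      x <- x + ff$y
      blocks[[bk]] <- list(ln1 = ln1, at = at, ln2 = ln2, ff = ff)
    }
    cur <- .fromTokens(x, B, g$C, g$H, g$W)
    stageOut[[s]] <- cur
    stageCache[[s]] <- list(dc = dc, blocks = blocks)
  }
  hln <- .lnFwd(p$head$ln, x)
  Tn <- gm$finalH^2
  pooled <- matrix(0, B, gm$finalC)
  for (b in seq_len(B))
    pooled[b, ] <- colMeans(hln$y[((b - 1L) * Tn + 1L):(b * Tn), , drop = FALSE])
  fc <- .linFwd(p$head$fc, pooled)
  if (!all(is.finite(fc$y))) stop("non-finite logits")
  list(logits = fc$y, stages = stageCache, stageOut = stageOut, hln = hln,
       fc = fc, B = B)
}

.modelBwd <- function(model, fw, dlogits) {
  p <- model@params
  gm <- model@geom
  B <- fw$B
  fcb <- .linBwd(p$head$fc, fw$fc, dlogits)
  Tn <- gm$finalH^2
  dtok <- matrix(0, B * Tn, gm$finalC)
  for (b in seq_len(B))
    dtok[((b - 1L) * Tn + 1L):(b * Tn), ] <-
      matrix(fcb$dx[b, ] / Tn, Tn, gm$finalC, byrow = TRUE)
  hlnb <- .lnBwd(p$head$ln, fw$hln, dtok)
  dx <- hlnb$dx
  dStage <- vector("list", 4L)
  gradStages <- vector("list", 4L)
  for (s in 4:1) {
    g <- gm$stages[[s]]
    if (s == 4L) dStage[[4L]] <- .fromTokens(dx, B, g$C, g$H, g$W)
    sc <- fw$stages[[s]]
    blockG <- vector("list", g$depth)
    for (bk in seq.int(g$depth, 1L)) {
      bc <- sc$blocks[[bk]]
      bp <- p$stages[[s]]$blocks[[bk]]
      ffb <- if (g$useDFG) .dfgBwd(bp$ffn, bc$ff, g$ffn, B, dx)
             else .ffnBwd(bp$ffn, bc$ff, dx)
      ln2b <- .lnBwd(bp$ln2, bc$ln2, ffb$dx)
      dx <- dx + ln2b$dx
      atb <- .dhaCoreBwd(bp$att, bc$at, g$attn, B, dx)
      ln1b <- .lnBwd(bp$ln1, bc$ln1, atb$dx)
      dx <- dx + ln1b$dx
      blockG[[bk]] <- list(ln1 = ln1b$dp, att = atb$dp, ln2 = ln2b$dp,
                           ffn = ffb$dp)
    }
    dMap <- .fromTokens(dx, B, g$C, g$H, g$W)
    if (g$useDCP) {
      dcb <- .dcpBwd(p$stages[[s]]$dcp, sc$dc, g$dcp, B, dMap)
      dcpG <- dcb$dp
    } else {
      dcb <- .pconvBwd(p$stages[[s]]$dcp$pc, sc$dc, dMap)
      dcpG <- list(pc = dcb$dp)
    }
    gradStages[[s]] <- list(dcp = dcpG, blocks = blockG)
    if (s > 1L) {
      dStage[[s - 1L]] <- dcb$dx
      dx <- .toTokens(dcb$dx)
    }
  }
  list(grads = list(stages = gradStages,
                    head = list(ln = hlnb$dp, fc = fcb$dp)),
       dStage = dStage, dInput = dcb$dx)
}

#' Forward pass to class logits
#'
#' @param model a [DermViTModel-class].
#' @param X input batch, array `c(B, 3, H, W)` of normalized images (see
#'   [normalizeImage()]).
#' @param training logical; enables dropout (draws from the global RNG).
#' @return logits matrix `B x numClasses`.
#' @export
modelForward <- function(model, X, training = FALSE) {
  .modelFwd(model, X, training)$logits
}

#' Predict classes or probabilities for raw images
#'
#' @param object a [DermViTModel-class].
#' @param newdata array `c(B, 3, H, W)` or `c(H, W, 3)` of raw images in
#'   [0,1]; normalized internally unless `normalize = FALSE`.
#' @param type one of `"prob"`, `"class"`, `"logits"`.
#' @param normalize apply the standard channel normalization first.
#' @param ... ignored.
#' @return probabilities matrix, integer class vector, or logits matrix.
#' @importFrom stats predict
#' @export
setMethod("predict", "DermViTModel",
          function(object, newdata, type = c("prob", "class", "logits"),
                   normalize = TRUE, ...) {
  type <- match.arg(type)
  if (length(dim(newdata)) == 3L) newdata <- .imagesToBatch(list(newdata), normalize)
  else if (normalize) newdata <- .normalizeBatch(newdata)
  lg <- modelForward(object, newdata)
  switch(type,
         logits = lg,
         prob = .softmaxRows(lg),
         class = max.col(lg, ties.method = "first"))
})

# ---- counting ---------------------------------------------------------------

#' @rdname countParameters
#' @export
setMethod("countParameters", "DermViTModel", function(object)
  .nParams(object@params))

#' Closed-form MAC counts for elementary layers
#'
#' Conventions: 1 MAC = 1 FLOP; only multiply-accumulates of matrix products
#' and convolutions are counted (elementwise activations, normalizations and
#' average pooling are not).
#'
#' @param kind one of `"linear"`, `"conv1x1"`, `"patchconv"`, `"dwconv"`,
#'   `"attention"` (dense attention over `tokens` tokens of width `d`:
#'   `2 * tokens^2 * d` for the score and value products).
#' @param tokens,din,dout,H,W,cin,cout,C,kernel,stride,d shape arguments as
#'   applicable to the layer kind.
#' @return numeric MAC count.
#' @examples
#' macsOf("linear", tokens = 10, din = 4, dout = 3) # 120
#' macsOf("attention", tokens = 16, d = 8)          # 4096
#' @export
macsOf <- function(kind, tokens = NULL, din = NULL, dout = NULL, H = NULL,
                   W = NULL, cin = NULL, cout = NULL, C = NULL, kernel = 3L,
                   stride = NULL, d = NULL) {
  switch(kind,
    linear = tokens * din * dout,
    conv1x1 = H * W * cin * cout,
    patchconv = (H %/% stride) * (W %/% stride) * cout * cin * stride^2,
    dwconv = H * W * C * kernel^2,
    attention = 2 * tokens^2 * d,
    stop("unsupported layer type: ", kind))
}

.stageMacs <- function(g) {
  C <- g$C
  T <- g$dcp$T
  total <- 0
  # downsampler
  total <- total + T * C * (g$dcp$cin * g$dcp$s^2)
  if (g$useDCP) {
    total <- total + 3 * T * C * C            # Q,K,V projections
    total <- total + 2 * T * g$dcp$P * C      # scores + value mix
    total <- total + T * C * C                # output projection
  }
  a <- g$attn
  for (bk in seq_len(g$depth)) {
    total <- total + 4 * T * C * C            # Q,K,V + output projections
    total <- total + a$N^2 * C                # region affinity scores
    total <- total + 2 * T * (a$k * a$m) * C  # routed token attention
    if (g$useDFG) {
      h <- g$ffn$h
      total <- total + T * C * 2 * h + 9 * h * T + T * h * C
    } else {
      total <- total + 2 * T * C * 4 * C
    }
  }
  total
}

#' @rdname countMacs
#' @export
setMethod("countMacs", "DermViTModel", function(model, inputShape = NULL) {
  if (is.null(inputShape))
    inputShape <- c(3L, model@config@imageSize, model@config@imageSize)
  if (inputShape[2L] != model@config@imageSize ||
      inputShape[3L] != model@config@imageSize)
    stop("inputShape spatial dims must match the configured image size")
  total <- 0
  cin <- inputShape[1L]
  for (s in seq_len(4L)) {
    g <- model@geom$stages[[s]]
    g$dcp$cin <- cin
    total <- total + .stageMacs(g)
    cin <- g$C
  }
  total + model@geom$finalC * model@config@numClasses
})

# ---- checkpointing ----------------------------------------------------------

#' Save / load a model checkpoint
#'
#' Single-file archive (RDS) with the configuration embedded.
#'
#' @param model a [DermViTModel-class].
#' @param path file path.
#' @return `loadModel` returns the restored [DermViTModel-class].
#' @export
saveModel <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  m <- readRDS(path)
  if (!is(m, "DermViTModel")) stop("file does not contain a DermViTModel")
  m
}
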