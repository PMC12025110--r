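# Synthetic dermoscopy generator: class-conditional elliptical lesions with
# radial Fourier border perturbation and color variegation on skin-toned
# backgrounds, plus the artifact repertoire typical of dermoscopic archives
# (hair strokes, ruler ticks, immersion bubbles), with per-image lesion
# masks and an ISIC-style one-hot CSV manifest.

.CLASS7 <- c("AKIEC", "BCC", "BKL", "DF", "NV", "MEL", "VASC")
.CLASS9 <- c("MEL", "NV", "BCC", "AK", "BKL", "DF", "VASC", "SCC", "UNK")
.CLASS_PICK <- c("NV", "MEL", "BKL", "VASC", "BCC", "DF", "AKIEC")

# ISIC2018-like class imbalance (HAM10000 frequencies)
.PROP7 <- c(AKIEC = 0.033, BCC = 0.051, BKL = 0.110, DF = 0.011,
            NV = 0.669, MEL = 0.111, VASC = 0.015)

.classNamesFor <- function(k) {
  if (k == 7L) .CLASS7
  else if (k == 9L) .CLASS9
  else .CLASS_PICK[seq_len(k)]
}

# per-class lesion morphology: base color, border irregularity amplitude
# range, variegation blob count range
.CLASS_STYLE <- list(
  NV    = list(col = c(0.45, 0.28, 0.18), irr = c(0.02, 0.08), nvar = 0:1),
  MEL   = list(col = c(0.22, 0.13, 0.10), irr = c(0.15, 0.35), nvar = 3:6),
  BKL   = list(col = c(0.64, 0.47, 0.30), irr = c(0.08, 0.18), nvar = 1:3),
  VASC  = list(col = c(0.62, 0.15, 0.20), irr = c(0.02, 0.06), nvar = 0:1),
  BCC   = list(col = c(0.72, 0.46, 0.42), irr = c(0.05, 0.15), nvar = 1:2),
  DF    = list(col = c(0.50, 0.32, 0.24), irr = c(0.03, 0.10), nvar = 0:1),
  AKIEC = list(col = c(0.70, 0.50, 0.40), irr = c(0.10, 0.20), nvar = 1:3),
  AK    = list(col = c(0.70, 0.50, 0.40), irr = c(0.10, 0.20), nvar = 1:3),
  SCC   = list(col = c(0.68, 0.42, 0.35), irr = c(0.12, 0.25), nvar = 2:4),
  UNK   = list(col = c(0.55, 0.38, 0.28), irr = c(0.05, 0.20), nvar = 0:3))

#' Build a synthetic-dermoscopy generator configuration
#'
#' Defaults emulate an ISIC2018-style archive: 7 classes with the archive's
#' strong class imbalance, 224 px images, lesion area between 5% and 40% of
#' the frame, and moderate artifact rates.
#'
#' @param numClasses 2..9 classes (7 = ISIC2018 names, 9 = ISIC2019 names).
#' @param nImages number of images to generate.
#' @param imageSize square image side in pixels.
#' @param classProportions sampling proportions per class (sum to 1);
#'   default: archive-like imbalance for 7 classes, uniform otherwise.
#' @param pHair,pRuler,pBubble per-image probabilities of each artifact type.
#' @param areaBounds lesion area fraction bounds `c(min, max)`.
#' @param seed integer master seed.
#' @return a [GeneratorConfig-class].
#' @export
generatorConfig <- function(numClasses = 7L, nImages = 100L, imageSize = 224L,
                            classProportions = NULL, pHair = 0.3,
                            pRuler = 0.2, pBubble = 0.2,
                            areaBounds = c(0.05, 0.4), seed = 0L) {
  if (numClasses < 2L || numClasses > 9L) stop("numClasses must be in 2..9")
  if (is.null(classProportions)) {
    classProportions <- if (numClasses == 7L) unname(.PROP7 / sum(.PROP7))
                        else rep(1 / numClasses, numClasses)
  }
  new("GeneratorConfig", numClasses = as.integer(numClasses),
      nImages = as.integer(nImages), imageSize = as.integer(imageSize),
      classProportions = classProportions, pHair = pHair, pRuler = pRuler,
      pBubble = pBubble, areaBounds = areaBounds, seed = as.integer(seed))
}

# cubic Bezier through 4 control points, n samples
.bezier <- function(P, n = 250L) {
  t <- seq(0, 1, length.out = n)
  b <- cbind((1 - t)^3, 3 * t * (1 - t)^2, 3 * t^2 * (1 - t), t^3)
  b %*% P
}

.paintStroke <- function(img, pts, thick, col) {
  H <- dim(img)[1L]; W <- dim(img)[2L]
  for (dy in -1:1) for (dx in -1:1) {
    r <- round(pts[, 1L]) + dy
    cc <- round(pts[, 2L]) + dx
    keep <- r >= 1 & r <= H & cc >= 1 & cc <= W
    if (!any(keep)) next
    d <- sqrt((pts[keep, 1L] - r[keep])^2 + (pts[keep, 2L] - cc[keep])^2)
    a <- pmax(0, pmin(1, thick + 0.5 - d))
    idx <- cbind(r[keep], cc[keep])
    for (ch in 1:3) {
      pl <- img[, , ch]
      pl[idx] <- pl[idx] * (1 - a) + col[ch] * a
      img[, , ch] <- pl
    }
  }
  img
}

#' Generate one synthetic dermoscopy sample
#'
#' Renders a skin-toned background, a class-conditional lesion (base hue,
#' border irregularity and color-variegation count drawn from class-specific
#' ranges), and artifact overlays. The binary mask marks lesion pixels only;
#' artifacts are excluded. Deterministic given `(classId, seed)`.
#'
#' @param classId 1-based class index.
#' @param cfg a [generatorConfig()].
#' @param seed integer seed for this sample.
#' @return list with `image` (H x W x 3 in [0,1], 8-bit quantized), `label`,
#'   `mask` (H x W 0/1 matrix), `meta` (lesion and artifact parameters).
#' @export
generateSample <- function(classId, cfg, seed = 0L) {
  if (classId < 1L || classId > cfg@numClasses)
    stop(sprintf("classId %d out of range 1..%d", classId, cfg@numClasses))
  set.seed(seed)
  S <- cfg@imageSize
  cn <- .classNamesFor(cfg@numClasses)[classId]
  style <- .CLASS_STYLE[[cn]]

  # background: skin tone with a gentle illumination gradient and fine noise
  base <- c(0.82, 0.64, 0.55) + stats::runif(3, -0.05, 0.05)
  gx <- stats::runif(1, -0.06, 0.06); gy <- stats::runif(1, -0.06, 0.06)
  xx <- matrix(rep(seq_len(S), each = S), S) / S  # column coordinate
  yy <- matrix(rep(seq_len(S), times = S), S) / S # row coordinate
  img <- array(0, c(S, S, 3L))
  for (ch in 1:3)
    img[, , ch] <- base[ch] + gx * (xx - 0.5) + gy * (yy - 0.5) +
      stats::rnorm(S * S, sd = 0.008)

  # lesion geometry: perturbed ellipse with class-conditional irregularity
  target <- stats::runif(1, cfg@areaBounds[1L], cfg@areaBounds[2L])
  cx <- stats::runif(1, 0.38, 0.62); cy <- stats::runif(1, 0.38, 0.62)
  ar <- stats::runif(1, 0.75, 1.3)
  thRot <- stats::runif(1, 0, pi)
  irr <- stats::runif(1, style$irr[1L], style$irr[2L])
  aj <- stats::rnorm(5); ph <- stats::runif(5, 0, 2 * pi)
  dx <- xx - cx; dy <- yy - cy
  p <- cos(thRot) * dx + sin(thRot) * dy
  q <- -sin(thRot) * dx + cos(thRot) * dy
  rho <- sqrt((p / ar)^2 + (q * ar)^2)
  phi <- atan2(q * ar, p / ar)
  shape <- 1
  for (j in 2:6) shape <- shape + irr * (aj[j - 1] / j) * cos(j * phi + ph[j - 1])
  shape <- pmax(shape, 0.3)
  r0 <- sqrt(target / pi)
  mask <- NULL
  for (try in seq_len(20L)) {
    mask <- (rho <= r0 * shape) + 0L
    area <- mean(mask)
    if (area >= cfg@areaBounds[1L] && area <= cfg@areaBounds[2L]) break
    r0 <- r0 * sqrt(target / max(area, 1e-6))
    if (try == 20L)
      stop("could not satisfy lesion area bounds after 20 attempts")
  }

  # lesion rendering: soft edge, radial darkening, class hue + jitter
  edge <- 1.5 / S
  alpha <- pmin(1, pmax(0, (r0 * shape - rho) / edge))
  lcol <- pmax(0, pmin(1, style$col + stats::runif(3, -0.05, 0.05)))
  depth <- 1 - 0.25 * pmin(1, rho / (r0 + 1e-9)) # darker toward the center
  for (ch in 1:3)
    img[, , ch] <- img[, , ch] * (1 - alpha) + (lcol[ch] * depth) * alpha

  # color variegation: darker blobs inside the lesion
  nVar <- if (length(style$nvar) == 1L) style$nvar else sample(style$nvar, 1L)
  for (v in seq_len(nVar)) {
    bphi <- stats::runif(1, 0, 2 * pi)
    brad <- stats::runif(1, 0, 0.55) * r0
    bcx <- cx + brad * cos(bphi); bcy <- cy + brad * sin(bphi)
    bsz <- stats::runif(1, 0.12, 0.3) * r0
    bcol <- pmax(0, lcol * stats::runif(1, 0.35, 0.7))
    ba <- exp(-((xx - bcx)^2 + (yy - bcy)^2) / (2 * bsz^2)) * alpha
    for (ch in 1:3) img[, , ch] <- img[, , ch] * (1 - ba) + bcol[ch] * ba
  }

  # artifacts (image only; the mask stays lesion-only)
  hairCount <- 0L
  if (stats::runif(1) < cfg@pHair) {
    hairCount <- sample(3:8, 1L)
    for (hr in seq_len(hairCount)) {
      P <- cbind(stats::runif(4, -0.1, 1.1) * S, stats::runif(4, -0.1, 1.1) * S)
      col <- rep(stats::runif(1, 0.05, 0.3), 3) * c(1, 0.85, 0.7)
      img <- .paintStroke(img, .bezier(P), stats::runif(1, 0.4, 0.9), col)
    }
  }
  ruler <- stats::runif(1) < cfg@pRuler
  if (ruler) {
    yr <- round(S * sample(c(stats::runif(1, 0.06, 0.14),
                             stats::runif(1, 0.86, 0.94)), 1L))
    x0 <- round(S * stats::runif(1, 0.05, 0.25))
    x1 <- round(S * stats::runif(1, 0.75, 0.95))
    img[yr + 0:1, x0:x1, ] <- 0.15
    step <- max(4L, round(S / 28))
    for (xt in seq(x0, x1, by = step))
      img[max(1, yr - round(S / 56)):(yr + 1), xt, ] <- 0.15
  }
  bubbleCount <- 0L
  if (stats::runif(1) < cfg@pBubble) {
    bubbleCount <- sample(2:6, 1L)
    for (bl in seq_len(bubbleCount)) {
      bcx <- stats::runif(1, 0.1, 0.9); bcy <- stats::runif(1, 0.1, 0.9)
      brad <- stats::runif(1, 0.02, 0.05)
      dd <- sqrt((xx - bcx)^2 + (yy - bcy)^2)
      ring <- pmax(0, 1 - abs(dd - brad) * S / 1.4)
      for (ch in 1:3)
        img[, , ch] <- img[, , ch] + 0.3 * (1 - img[, , ch]) * ring
    }
  }

  img[] <- round(pmin(pmax(img, 0), 1) * 255) / 255 # 8-bit quantization
  list(image = img, label = as.integer(classId), mask = mask,
       meta = list(class = cn, areaFrac = mean(mask), hairCount = hairCount,
                   ruler = as.integer(ruler), bubbleCount = bubbleCount,
                   irregularity = irr, nVariegation = nVar, seed = seed))
}

#' Generate a synthetic dermoscopy dataset
#'
#' Samples class labels from the configured proportions, renders each image
#' (deterministically from the master seed), and optionally writes PNG
#' images, PNG lesion masks and the one-hot CSV manifest in the ISIC
#' challenge ground-truth dialect.
#'
#' @param cfg a [generatorConfig()].
#' @param dir output directory; `NULL` keeps the dataset in memory only.
#' @return a [SyntheticDermData-class].
#' @export
generateDataset <- function(cfg, dir = NULL) {
  set.seed(cfg@seed)
  n <- cfg@nImages
  labels <- sample.int(cfg@numClasses, n, replace = TRUE,
                       prob = cfg@classProportions)
  seeds <- sample.int(.Machine$integer.max - 1L, n)
  cn <- .classNamesFor(cfg@numClasses)
  images <- vector("list", n); masks <- vector("list", n)
  meta <- vector("list", n)
  files <- character(n)
  if (!is.null(dir)) {
    ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE)
    if (!ok || file.access(dir, 2L) != 0L)
      stop(sprintf("output directory '%s' is not writable", dir))
    dir.create(file.path(dir, "masks"), showWarnings = FALSE)
  }
  for (i in seq_len(n)) {
    smp <- generateSample(labels[i], cfg, seeds[i])
    images[[i]] <- smp$image
    masks[[i]] <- smp$mask
    meta[[i]] <- as.data.frame(smp$meta)
    if (!is.null(dir)) {
      id <- sprintf("SYN_%07d", i)
      files[i] <- file.path(dir, paste0(id, ".png"))
      png::writePNG(smp$image, files[i])
      png::writePNG(smp$mask * 1, file.path(dir, "masks",
                                            paste0(id, "_mask.png")))
    }
  }
  meta <- do.call(rbind, meta)
  meta$image <- if (is.null(dir)) sprintf("SYN_%07d", seq_len(n))
                else sub("\\.png$", "", basename(files))
  manifest <- ""
  if (!is.null(dir)) {
    onehot <- matrix(0L, n, cfg@numClasses, dimnames = list(NULL, cn))
    onehot[cbind(seq_len(n), labels)] <- 1L
    man <- data.frame(image = meta$image, onehot, check.names = FALSE)
    manifest <- file.path(dir, "ground_truth.csv")
    utils::write.csv(man, manifest, row.names = FALSE)
  }
  new("SyntheticDermData", images = images, labels = as.integer(labels),
      masks = masks, meta = meta, classNames = cn, files = files,
      manifest = manifest)
}

#' Read an ISIC-style one-hot manifest
#'
#' Header-keyed parsing: the `image` column plus one column per class, each
#' row exactly one-hot. Column order does not affect the labels. Errors name
#' the offending row (bad one-hot) or image id (missing file).
#'
#' @param path manifest CSV path.
#' @param imageDir directory holding the images (default: the manifest's).
#' @param checkFiles verify that every image file exists.
#' @return data.frame with columns `image`, `file`, `className`, `label`
#'   (1-based, keyed to the package's canonical class order when the names
#'   match one, otherwise to the sorted column names).
#' @export
readManifest <- function(path, imageDir = dirname(path), checkFiles = TRUE) {
  if (!file.exists(path)) stop(sprintf("manifest '%s' not found", path))
  man <- utils::read.csv(path, check.names = FALSE)
  if (!"image" %in% colnames(man)) stop("manifest lacks an 'image' column")
  classCols <- setdiff(colnames(man), "image")
  oh <- as.matrix(man[, classCols, drop = FALSE])
  bad <- which(abs(rowSums(oh) - 1) > 1e-9 | apply(oh, 1, function(r)
    any(r != 0 & r != 1)))
  if (length(bad))
    stop(sprintf("manifest row %d is not one-hot", bad[1L]))
  className <- classCols[max.col(oh, ties.method = "first")]
  canon <- .classNamesFor(length(classCols))
  levels <- if (all(sort(classCols) == sort(canon))) canon else sort(classCols)
  files <- file.path(imageDir, paste0(man$image, ".png"))
  if (checkFiles) {
    miss <- which(!file.exists(files))
    if (length(miss))
      stop(sprintf("image file for id '%s' not found", man$image[miss[1L]]))
  }
  out <- data.frame(image = man$image, file = files, className = className,
                    label = match(className, levels), stringsAsFactors = FALSE)
  attr(out, "classes") <- levels
  out
}

#' Load a dataset written by [generateDataset()]
#'
#' Reads the manifest and the PNG images (and masks when present) back into
#' a [SyntheticDermData-class].
#'
#' @param manifestPath path of the ground-truth CSV.
#' @return a [SyntheticDermData-class].
#' @export
loadDataset <- function(manifestPath) {
  man <- readManifest(manifestPath)
  dirn <- dirname(manifestPath)
  images <- lapply(man$file, png::readPNG)
  masks <- lapply(man$image, function(id) {
    mp <- file.path(dirn, "masks", paste0(id, "_mask.png"))
    if (file.exists(mp)) round(png::readPNG(mp)) else NULL
  })
  new("SyntheticDermData", images = images, labels = as.integer(man$label),
      masks = masks, meta = data.frame(image = man$image),
      classNames = attr(man, "classes"), files = man$file,
      manifest = manifestPath)
}
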