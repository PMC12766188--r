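#' Drop the alpha channel
#'
#' 4-channel input keeps its first three channels; 1- and 3-channel input is
#' returned unchanged (transparency carries no information here).
#'
#' @param px numeric array (h, w[, channels]), 1-4 channels.
#' @return the array with at most 3 channels.
#' @export
omitAlpha <- function(px) {
  nc <- nChannels(px)
  stopifnot(nc >= 1L, nc <= 4L)
  if (nc == 4L) px[, , 1:3, drop = FALSE] else px
}

#' Pad an annotated image to a square frame
#'
#' Zero-padding is applied along the shorter axis only, split evenly between
#' the two borders with the odd pixel going to the far (bottom/right) border.
#' Masks are padded with background and boxes shifted by the pad offsets.
#'
#' @param ai an [AnnotatedImage-class].
#' @return list with `image` (square [AnnotatedImage-class]) and `record`, a
#'   list of the applied pads (`padLeft`, `padRight`, `padTop`, `padBottom`).
#' @export
padToSquare <- function(ai) {
  h <- imageHeight(ai); w <- imageWidth(ai)
  stopifnot(h > 0, w > 0)
  side <- max(h, w)
  padTop <- floor((side - h) / 2); padBottom <- side - h - padTop
  padLeft <- floor((side - w) / 2); padRight <- side - w - padLeft
  rec <- list(padLeft = padLeft, padRight = padRight,
              padTop = padTop, padBottom = padBottom)
  if (side == h && side == w) return(list(image = ai, record = rec))

  px <- pixels(ai)
  nc <- nChannels(px)
  out <- array(0, dim = c(side, side, nc))
  out[(padTop + 1):(padTop + h), (padLeft + 1):(padLeft + w), ] <-
    array(px, dim = c(h, w, nc))
  if (nc == 1L) out <- array(out[, , 1L], dim = c(side, side))

  insts <- lapply(instances(ai), function(inst) {
    m <- matrix(FALSE, side, side)
    m[(padTop + 1):(padTop + h), (padLeft + 1):(padLeft + w)] <- binMask(inst)
    b <- bbox(inst) + c(padLeft, padTop, 0, 0)
    Instance(m, box = b, classId = classId(inst), instanceId = instanceId(inst))
  })
  list(image = AnnotatedImage(out, imageId = imageId(ai), instances = insts),
       record = rec)
}

## Nearest-neighbour index mapping: target index t (1-based) reads source
## floor((t - 0.5) * S / T) + 1, the standard half-pixel-centre rule.
nnIndex <- function(target, source) {
  pmin(source, pmax(1L, floor((seq_len(target) - 0.5) * source / target) + 1L))
}

#' Resize an annotated image with bilinear interpolation
#'
#' Pixels are resampled bilinearly; masks with nearest-neighbour (bilinear
#' would de-binarise them); boxes are scaled analytically by the target/source
#' ratios rather than re-derived from the resampled masks, avoiding resampling
#' jitter.
#'
#' @param ai an [AnnotatedImage-class], square unless `allowNonSquare`.
#' @param targetSize output side in pixels.
#' @param allowNonSquare permit non-square input (then both axes are scaled to
#'   `targetSize`, distorting the aspect ratio).
#' @return list with `image` and `record` (`scaleX`, `scaleY`).
#' @export
resizeBilinear <- function(ai, targetSize = 1024L, allowNonSquare = FALSE) {
  h <- imageHeight(ai); w <- imageWidth(ai)
  if (h != w && !allowNonSquare)
    stop("input is not square (", w, " x ", h,
         "); pad first or set allowNonSquare = TRUE")
  sx <- targetSize / w; sy <- targetSize / h
  px <- fromEBImage(EBImage::resize(toEBImage(pixels(ai)), w = targetSize,
                                    h = targetSize, filter = "bilinear",
                                    antialias = FALSE))
  ri <- nnIndex(targetSize, h); ci <- nnIndex(targetSize, w)
  insts <- lapply(instances(ai), function(inst) {
    m <- binMask(inst)[ri, ci, drop = FALSE]
    b <- bbox(inst) * c(sx, sy, sx, sy)
    Instance(m, box = b, classId = classId(inst), instanceId = instanceId(inst))
  })
  list(image = AnnotatedImage(px, imageId = imageId(ai), instances = insts),
       record = list(scaleX = sx, scaleY = sy))
}

#' Duplicate a grayscale channel to three channels
#'
#' Pre-trained colour backbones expect 3 channels; the three outputs are
#' identical copies. A 3-channel input is returned unchanged with a warning.
#'
#' @param px numeric array (h, w) or (h, w, 1).
#' @return numeric array (h, w, 3).
#' @export
duplicateChannels <- function(px) {
  nc <- nChannels(px)
  if (nc == 3L) {
    warning("input already has 3 channels; returned unchanged")
    return(px)
  }
  stopifnot(nc == 1L)
  m <- if (length(dim(px)) == 3L) px[, , 1L] else px
  array(rep(m, 3L), dim = c(dim(m), 3L))
}

#' Per-channel z-score colour normalisation
#'
#' Computes `(x - mean_c) / std_c` per channel. Defaults are the ImageNet
#' backbone statistics used downstream: mean (0.485, 0.456, 0.406), std
#' (0.299, 0.224, 0.225).
#'
#' @param px numeric array (h, w, 3), intensities in [0, 1].
#' @param mean,std numeric(3).
#' @return the normalised array.
#' @export
normalizeColor <- function(px, mean = c(0.485, 0.456, 0.406),
                           std = c(0.299, 0.224, 0.225)) {
  stopifnot(nChannels(px) == 3L)
  if (any(std <= 0)) stop("std components must be > 0")
  for (k in 1:3) px[, , k] <- (px[, , k] - mean[k]) / std[k]
  px
}

#' Pooled pixel mean and variance of a training subset
#'
#' Population statistics over all pixels of all images (two-pass within a
#' streaming accumulation of sums and squared sums, so image sizes may differ).
#'
#' @param images non-empty list of [AnnotatedImage-class] or numeric arrays.
#' @return numeric(2) named `mean`, `var`.
#' @export
zscoreDatasetStats <- function(images) {
  if (length(images) == 0L) stop("need at least one image")
  s <- 0; s2 <- 0; n <- 0
  for (im in images) {
    px <- if (is(im, "AnnotatedImage")) pixels(im) else im
    s <- s + sum(px); s2 <- s2 + sum(px^2); n <- n + length(px)
  }
  m <- s / n
  c(mean = m, var = s2 / n - m^2)
}

#' Random annotation-aware flip
#'
#' With probability `p`, mirrors the image and all masks along the chosen axis
#' and remaps boxes (`horizontal`: x -> W - x - w; `vertical`: y -> H - y - h);
#' otherwise identity. Applying a certain flip twice restores the input.
#'
#' @param ai an [AnnotatedImage-class].
#' @param axis `"horizontal"` (left-right) or `"vertical"` (top-bottom).
#' @param p flip probability.
#' @param seed optional RNG seed.
#' @return the (possibly) flipped [AnnotatedImage-class].
#' @export
randomFlip <- function(ai, axis = c("vertical", "horizontal"), p = 0.5,
                       seed = NULL) {
  axis <- match.arg(axis)
  if (!withSeed(seed, stats::runif(1) < p)) return(ai)
  h <- imageHeight(ai); w <- imageWidth(ai)
  flipMat <- if (axis == "horizontal") function(m) m[, w:1, drop = FALSE]
             else function(m) m[h:1, , drop = FALSE]
  px <- perChannel(pixels(ai), flipMat)
  insts <- lapply(instances(ai), function(inst) {
    b <- bbox(inst)
    nb <- if (axis == "horizontal") c(w - b[1] - b[3], b[2], b[3], b[4])
          else c(b[1], h - b[2] - b[4], b[3], b[4])
    Instance(flipMat(binMask(inst)), box = nb, classId = classId(inst),
             instanceId = instanceId(inst))
  })
  AnnotatedImage(px, imageId = imageId(ai), instances = insts)
}

#' Additive Gaussian pixel noise
#'
#' Adds i.i.d. `N(0, scale^2)` noise per pixel; `scale` is the standard
#' deviation in [0, 1] intensity units (applied before colour normalisation).
#' Output is clipped back to [0, 1] unless `clip = FALSE`.
#'
#' @param px numeric array.
#' @param scale noise standard deviation (>= 0; 0 is the identity).
#' @param seed optional RNG seed.
#' @param clip clip output to [0, 1].
#' @return the noised array.
#' @export
gaussianNoise <- function(px, scale = 0.08, seed = NULL, clip = TRUE) {
  stopifnot(scale >= 0)
  if (scale == 0) return(px)
  out <- px + withSeed(seed, stats::rnorm(length(px), sd = scale))
  dim(out) <- dim(px)
  if (clip) out <- clip01(out)
  out
}

## Discrete 1-D Gaussian kernel, radius ceiling(4 * sigma), normalised.
gaussianKernel1d <- function(sigma) {
  rad <- max(1L, ceiling(4 * sigma))
  k <- exp(-((-rad:rad)^2) / (2 * sigma^2))
  k / sum(k)
}

## 1-D convolution along rows of a matrix with half-sample symmetric
## (reflective) padding; kernel assumed normalised and odd-length.
convolveRowsSym <- function(m, k) {
  rad <- (length(k) - 1L) / 2L
  n <- nrow(m)
  idx <- c(rad:1, 1:n, n:(n - rad + 1L))  # symmetric extension
  ext <- m[idx, , drop = FALSE]
  out <- matrix(0, n, ncol(m))
  for (j in seq_along(k)) out <- out + k[j] * ext[(j - 1L) + 1:n, , drop = FALSE]
  out
}

#' Gaussian blur with reflective boundaries
#'
#' Separable per-channel convolution with a normalised discrete Gaussian
#' (radius 4 sigma) under half-sample symmetric padding, which conserves the
#' global pixel sum exactly for the symmetric kernel. `sigma = 0` is the
#' identity.
#'
#' @param px numeric array (h, w[, channels]).
#' @param sigma blur standard deviation in pixels (>= 0).
#' @return the blurred array.
#' @export
gaussianBlur <- function(px, sigma = 1.0) {
  stopifnot(sigma >= 0)
  if (sigma == 0) return(px)
  k <- gaussianKernel1d(sigma)
  perChannel(px, function(m) t(convolveRowsSym(t(convolveRowsSym(m, k)), k)))
}

#' Full deterministic preprocessing chain
#'
#' Alpha removal, square padding, bilinear resize to `targetSize`, channel
#' duplication for grayscale input, and colour normalisation, with annotations
#' kept consistent throughout.
#'
#' @param ai an [AnnotatedImage-class].
#' @param config a [PreprocessConfig-class].
#' @return list with `image` (normalised, 3-channel, square) and `record`
#'   (pads and scales).
#' @export
applyPreprocess <- function(ai, config = PreprocessConfig()) {
  pixels(ai) <- omitAlpha(pixels(ai))
  padded <- padToSquare(ai)
  resized <- resizeBilinear(padded$image, targetSize = config@targetSize)
  ai <- resized$image
  if (nChannels(pixels(ai)) == 1L) pixels(ai) <- duplicateChannels(pixels(ai))
  pixels(ai) <- normalizeColor(pixels(ai), config@channelMean, config@channelStd)
  list(image = ai, record = c(padded$record, resized$record))
}

#' Common training-time augmentations
#'
#' Vertical flip, horizontal flip (each with probability `flipP`), Gaussian
#' noise and Gaussian blur (each applied with probability `noiseP` / `blurP`,
#' default always). Runs in raw intensity space, before the confusion-duplicate
#' and regional-drop operators and before colour normalisation.
#'
#' @param ai an [AnnotatedImage-class].
#' @param config a [PreprocessConfig-class].
#' @param seed optional RNG seed.
#' @return the augmented [AnnotatedImage-class].
#' @export
applyTrainingAugment <- function(ai, config = PreprocessConfig(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ai <- randomFlip(ai, "vertical", p = config@flipP)
  ai <- randomFlip(ai, "horizontal", p = config@flipP)
  if (stats::runif(1) < config@noiseP)
    pixels(ai) <- gaussianNoise(pixels(ai), config@noiseScale)
  if (stats::runif(1) < config@blurP)
    pixels(ai) <- gaussianBlur(pixels(ai), config@blurSigma)
  ai
}
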