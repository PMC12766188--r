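## Internal geometry / array helpers. Conventions: masks are logical h x w
## matrices indexed [row = y + 1, col = x + 1]; boxes are 0-based COCO
## [x, y, w, h].

asMask <- function(m) {
  if (!is.matrix(m)) stop("mask must be a matrix")
  if (!is.logical(m)) {
    m2 <- m != 0
    dim(m2) <- dim(m)
    m <- m2
  }
  m
}

#' Tight bounding box of a binary mask
#'
#' @param mask logical (or 0/1) matrix with at least one foreground pixel.
#' @return numeric(4) `[x, y, w, h]`, 0-based COCO convention.
#' @export
tightBox <- function(mask) {
  mask <- asMask(mask)
  rs <- range(which(rowSums(mask) > 0))
  cs <- range(which(colSums(mask) > 0))
  c(cs[1] - 1, rs[1] - 1, cs[2] - cs[1] + 1, rs[2] - rs[1] + 1)
}

clip01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

## Rectangle IoU on [x, y, w, h] boxes; zero-area union -> 0.
boxIoU <- function(a, b) {
  ix <- max(0, min(a[1] + a[3], b[1] + b[3]) - max(a[1], b[1]))
  iy <- max(0, min(a[2] + a[4], b[2] + b[4]) - max(a[2], b[2]))
  inter <- ix * iy
  un <- a[3] * a[4] + b[3] * b[4] - inter
  if (un <= 0) 0 else inter / un
}

## IoU between two full-frame logical masks.
maskIoU <- function(a, b) {
  inter <- sum(a & b)
  un <- sum(a) + sum(b) - inter
  if (un == 0) 0 else inter / un
}

## Crop a matrix / array to a 0-based [x, y, w, h] box.
cropToBox <- function(px, box) {
  rows <- (box[2] + 1):(box[2] + box[4])
  cols <- (box[1] + 1):(box[1] + box[3])
  if (length(dim(px)) == 3L) px[rows, cols, , drop = FALSE] else px[rows, cols, drop = FALSE]
}

## Embed a patch mask into a full h x w frame with its top-left at 0-based
## (x0, y0).
embedMask <- function(patch, h, w, x0, y0) {
  full <- matrix(FALSE, h, w)
  full[(y0 + 1):(y0 + nrow(patch)), (x0 + 1):(x0 + ncol(patch))] <- patch
  full
}

## Union of instance masks; all-FALSE frame when there are none.
gtUnionMask <- function(instList, h, w) {
  out <- matrix(FALSE, h, w)
  for (inst in instList) out <- out | binMask(inst)
  out
}

nChannels <- function(px) if (length(dim(px)) == 3L) dim(px)[3L] else 1L

## Apply f to every channel of a (h, w[, c]) array, preserving shape.
perChannel <- function(px, f) {
  if (length(dim(px)) == 2L) return(f(px))
  for (k in seq_len(dim(px)[3L])) px[, , k] <- f(px[, , k])
  px
}

## EBImage conversion: our arrays are (h, w[, c]); EBImage Images are
## (x = w, y = h[, c]).
toEBImage <- function(px) {
  if (length(dim(px)) == 2L) EBImage::Image(t(px))
  else EBImage::Image(aperm(px, c(2L, 1L, 3L)), colormode = "Color")
}

fromEBImage <- function(img) {
  a <- EBImage::imageData(img)
  d <- dim(a)
  if (length(d) == 2L) t(a) else aperm(a, c(2L, 1L, 3L))
}

withSeed <- function(seed, expr) {
  if (!is.null(seed)) set.seed(seed)
  expr
}

## Derive n child seeds (< 2^31) from the current RNG stream.
childSeeds <- function(n) sample.int(.Machine$integer.max - 1L, n)
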