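test_that("alpha channel handling keeps exactly the colour planes", {
  rgba <- array(runif(8 * 8 * 4), dim = c(8, 8, 4))
  out <- omitAlpha(rgba)
  expect_identical(dim(out), c(8L, 8L, 3L))
  expect_identical(out, rgba[, , 1:3])
  gray <- array(runif(64), dim = c(8, 8))
  expect_identical(omitAlpha(gray), gray)
  rgba[, , 4] <- 0
  expect_identical(omitAlpha(rgba)[, , 1:3], rgba[, , 1:3])
})

test_that("square padding splits evenly with the odd pixel to the far border", {
  # (w, h) = (100, 60): pad the vertical axis 20/20
  m <- helperDisk(60, 100, 12.5, 12.5, 2.6)
  ai <- AnnotatedImage(matrix(0.5, 60, 100), instances = list(
    Instance(m, box = c(10, 10, 5, 5))))
  res <- padToSquare(ai)
  expect_identical(dim(pixels(res$image))[1:2], c(100L, 100L))
  expect_identical(res$record[c("padTop", "padBottom")],
                   list(padTop = 20, padBottom = 20))
  expect_equal(bbox(instances(res$image)[[1]]), c(10, 30, 5, 5))

  # odd difference: extra pixel on the far border
  odd <- padToSquare(AnnotatedImage(matrix(0, 7, 10)))
  expect_identical(unlist(odd$record[c("padTop", "padBottom")]),
                   c(padTop = 1, padBottom = 2))

  sq <- AnnotatedImage(matrix(runif(25), 5, 5))
  res2 <- padToSquare(sq)
  expect_identical(pixels(res2$image), pixels(sq))
  expect_identical(unlist(res2$record), c(padLeft = 0, padRight = 0,
                                          padTop = 0, padBottom = 0))
})

test_that("bilinear resize scales boxes analytically and masks by nearest", {
  const <- AnnotatedImage(matrix(0.37, 64, 64))
  out <- resizeBilinear(const, 128L)$image
  expect_equal(range(pixels(out)), c(0.37, 0.37), tolerance = 1e-7)

  rect <- matrix(FALSE, 512, 512); rect[11:30, 11:30] <- TRUE
  ai <- AnnotatedImage(matrix(0.2, 512, 512),
                       instances = list(Instance(rect)))
  res <- resizeBilinear(ai, 1024L)
  expect_equal(bbox(instances(res$image)[[1]]), c(20, 20, 40, 40))
  # popcount of a nearest-neighbour 2x upscale ~ 4x the original
  expect_equal(sum(binMask(instances(res$image)[[1]])), 4 * sum(rect),
               tolerance = 0.15)

  expect_error(resizeBilinear(AnnotatedImage(matrix(0, 4, 6)), 8L),
               "not square")
})

test_that("channel duplication produces three identical planes", {
  v <- matrix(runif(16), 4, 4)
  out <- duplicateChannels(v)
  expect_identical(dim(out), c(4L, 4L, 3L))
  for (k in 1:3) expect_identical(out[, , k], v)
  expect_identical(out[, , 1], out[, , 3])
  expect_equal(apply(out, c(1, 2), mean), v)
  expect_warning(duplicateChannels(out), "already has 3 channels")
})

test_that("colour normalisation is an exact per-channel z-score", {
  atMean <- array(rep(c(0.485, 0.456, 0.406), each = 4), dim = c(2, 2, 3))
  expect_equal(max(abs(normalizeColor(atMean))), 0)
  x <- array(runif(2 * 2 * 3), dim = c(2, 2, 3))
  expect_equal(normalizeColor(x, mean = c(0, 0, 0), std = c(1, 1, 1)), x)
  ones <- array(1, dim = c(2, 2, 3))
  out <- normalizeColor(ones)
  expect_equal(out[1, 1, ], c((1 - 0.485) / 0.299, (1 - 0.456) / 0.224,
                              (1 - 0.406) / 0.225))
  expect_error(normalizeColor(x, std = c(1, 0, 1)), "std")
})

test_that("pooled dataset statistics match closed forms and a two-pass oracle", {
  expect_equal(zscoreDatasetStats(list(matrix(0.3, 4, 4))),
               c(mean = 0.3, var = 0))
  two <- list(matrix(0, 5, 5), matrix(1, 5, 5))
  expect_equal(zscoreDatasetStats(two), c(mean = 0.5, var = 0.25))
  set.seed(5)
  imgs <- lapply(1:4, function(i) matrix(runif(5 * sample(4:12, 1)), nrow = 5))
  pooled <- unlist(imgs)
  expect_equal(zscoreDatasetStats(imgs),
               c(mean = mean(pooled),
                 var = mean(pooled^2) - mean(pooled)^2), tolerance = 1e-12)
})

test_that("flips are annotation-aware involutions with the mirror formula", {
  ai <- helperDiskImage(40, rbind(c(12, 20, 5)))
  expect_identical(pixels(randomFlip(ai, "horizontal", p = 0)), pixels(ai))
  f2 <- randomFlip(randomFlip(ai, "horizontal", p = 1), "horizontal", p = 1)
  expect_identical(pixels(f2), pixels(ai))
  expect_identical(binMask(instances(f2)[[1]]), binMask(instances(ai)[[1]]))

  b <- bbox(instances(ai)[[1]])
  fh <- randomFlip(ai, "horizontal", p = 1)
  expect_equal(bbox(instances(fh)[[1]]), c(40 - b[1] - b[3], b[2], b[3], b[4]))
  fv <- randomFlip(ai, "vertical", p = 1)
  expect_equal(bbox(instances(fv)[[1]]), c(b[1], 40 - b[2] - b[4], b[3], b[4]))
})

test_that("gaussian noise has the configured standard deviation", {
  x <- matrix(0.5, 1000, 1000)
  expect_identical(gaussianNoise(x, 0), x)
  noised <- gaussianNoise(x, 0.08, seed = 2L, clip = FALSE)
  expect_equal(sd(noised - x), 0.08, tolerance = 0.001 / 0.08)
  expect_identical(gaussianNoise(x, 0.05, seed = 9L),
                   gaussianNoise(x, 0.05, seed = 9L))
})

test_that("gaussian blur conserves mass and matches the kernel closed form", {
  const <- matrix(0.42, 30, 30)
  expect_equal(gaussianBlur(const, 1.0), const, tolerance = 1e-12)
  set.seed(3)
  x <- matrix(runif(40 * 40), 40, 40)
  expect_equal(sum(gaussianBlur(x, 1.0)), sum(x), tolerance = 1e-6 / sum(x))
  # single bright pixel: centre value equals the 2-D kernel centre weight
  imp <- matrix(0, 21, 21); imp[11, 11] <- 1
  k <- exp(-((-4:4)^2) / 2); k <- k / sum(k)
  expect_equal(gaussianBlur(imp, 1.0)[11, 11], k[5]^2, tolerance = 1e-12)
  expect_identical(gaussianBlur(x, 0), x)
})

test_that("geometric ops keep boxes tight to masks within one pixel", {
  set.seed(17)
  for (rep in 1:6) {
    h <- sample(40:70, 1); w <- sample(40:70, 1)
    cx <- runif(1, 12, w - 12); cy <- runif(1, 12, h - 12)
    m <- helperDisk(h, w, cx, cy, runif(1, 4, 9))
    ai <- AnnotatedImage(matrix(0.4, h, w), instances = list(Instance(m)))

    padded <- padToSquare(ai)$image
    resized <- resizeBilinear(padded, 2L * max(h, w))$image
    flipped <- randomFlip(resized, sample(c("horizontal", "vertical"), 1), p = 1)
    for (stage in list(padded, resized, flipped)) {
      inst <- instances(stage)[[1]]
      expect_lte(max(abs(bbox(inst) - tightBox(binMask(inst)))), 1)
    }
  }
})

test_that("photometric ops never alter annotations", {
  ai <- helperDiskImage(40, rbind(c(20, 20, 6)))
  before <- instances(ai)
  pixels(ai) <- gaussianBlur(gaussianNoise(pixels(ai), 0.08, seed = 1L), 1.0)
  expect_identical(instances(ai), before)
})

test_that("the full preprocessing chain emits a normalised square 3-channel image", {
  ai <- helperDiskImage(50, rbind(c(20, 25, 7)))
  res <- applyPreprocess(ai, PreprocessConfig(targetSize = 100L))
  expect_identical(dim(pixels(res$image)), c(100L, 100L, 3L))
  inst <- instances(res$image)[[1]]
  expect_lte(max(abs(bbox(inst) - tightBox(binMask(inst)))), 1)
  # pad-then-resize at the original side is the identity on the mask
  sq <- padToSquare(ai)$image
  same <- resizeBilinear(sq, 50L)$image
  expect_identical(binMask(instances(same)[[1]]), binMask(instances(sq)[[1]]))
})
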