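smallScene <- function() SceneConfig(imageSize = 192L, cellsPerImage = c(1L, 3L),
                                     debrisPerImage = c(1L, 3L))

test_that("scene generation is deterministic and respects the cell count range", {
  cfg <- smallScene()
  a <- generateImage(cfg, seed = 12L)
  b <- generateImage(cfg, seed = 12L)
  expect_identical(pixels(a), pixels(b))
  expect_identical(lapply(instances(a), binMask), lapply(instances(b), binMask))
  expect_gte(length(instances(a)), 1L)
  expect_lte(length(instances(a)), 3L)

  none <- generateImage(SceneConfig(imageSize = 128L,
                                    cellsPerImage = c(0L, 0L)), seed = 1L)
  expect_length(instances(none), 0L)

  # masks span the full frame and every box is tight
  for (inst in instances(a)) {
    expect_identical(dim(binMask(inst)), c(192L, 192L))
    expect_equal(bbox(inst), tightBox(binMask(inst)))
  }
})

test_that("realised cell diameters track the 11 um / 0.212 um-per-px optics", {
  cfg <- SceneConfig()  # 512 px frames, ~52 px cells
  diams <- c()
  seed <- 1L
  while (length(diams) < 100) {
    ai <- generateImage(cfg, seed = seed)
    diams <- c(diams, vapply(instances(ai), function(i)
      2 * sqrt(sum(binMask(i)) / pi), numeric(1)))
    seed <- seed + 1L
  }
  expect_equal(mean(diams[1:100]), 11 / 0.212, tolerance = 3 / 52)
})

test_that("impossible packings fail with a clear error", {
  expect_error(generateImage(SceneConfig(imageSize = 128L,
                                         cellsPerImage = c(6L, 6L)), seed = 1L),
               "infeasible packing")
})

test_that("generated datasets round-trip through the COCO reader losslessly", {
  dir <- tempfile("synth")
  path <- generateDataset(5, smallScene(), dir, seed = 3L)
  expect_length(list.files(dir, pattern = "\\.png$"), 5L)
  expect_no_warning(back <- readCocoDataset(path, dir))
  expect_length(back, 5L)
  orig <- generateScenes(5, smallScene(), seed = 3L)
  for (k in 1:5) {
    expect_identical(length(instances(back[[k]])), length(instances(orig[[k]])))
    for (i in seq_along(instances(orig[[k]])))
      expect_identical(binMask(instances(back[[k]])[[i]]),
                       binMask(instances(orig[[k]])[[i]]))
  }
})

test_that("the mock predictor reproduces, misses and fabricates as configured", {
  ai <- generateImage(smallScene(), seed = 21L)
  perfect <- ErrorModel(missRate = 0, fpRate = 0, jitterPx = 0,
                        scoreCorrect = 1)
  preds <- mockPredict(ai, perfect, seed = 1L)
  expect_length(preds, length(instances(ai)))
  for (k in seq_along(preds)) {
    expect_identical(binMask(preds[[k]]), binMask(instances(ai)[[k]]))
    expect_identical(score(preds[[k]]), 1)
  }
  expect_identical(mapScore(preds, list(ai), "mask"), 1)

  blind <- ErrorModel(missRate = 1, fpRate = 0)
  expect_length(mockPredict(ai, blind, seed = 1L), 0L)
  expect_identical(mapScore(list(), list(ai), "mask"), 0)

  # miss decisions are Bernoulli(missRate)
  one <- helperDiskImage(64, rbind(c(32, 32, 10)))
  model <- ErrorModel(missRate = 0.3, fpRate = 0, jitterPx = 0)
  set.seed(77)
  hits <- sum(replicate(1e4, length(mockPredict(one, model))))
  expect_equal(hits / 1e4, 0.7, tolerance = 0.02 / 0.7)
})

test_that("a perfect detector leaves both zoos empty through a demo run", {
  scenes <- generateScenes(12, smallScene(), seed = 5L)
  res <- runDemoLoop(scenes, ErrorModel(0, 0, 0, scoreCorrect = 1),
                     nIters = 24L, seed = 2L)
  expect_identical(zooSize(res$eq1Zoo), 0L)
  expect_identical(zooSize(res$eq2Zoo), 0L)
  expect_identical(bboxMAP(res$report), 1)
  expect_identical(maskMAP(res$report), 1)
})

test_that("an error-prone detector saturates the eq2 zoo at its capacity", {
  scenes <- generateScenes(15, smallScene(), seed = 9L)
  res <- runDemoLoop(scenes, ErrorModel(missRate = 0.3, fpRate = 2,
                                        fpRadiusPx = 15),
                     nIters = 40L, seed = 4L)
  expect_identical(zooSize(res$eq2Zoo), 10L)
  firstFull <- match(10L, res$logs$eq2Size)
  expect_false(is.na(firstFull))
  expect_true(all(res$logs$eq2Size[firstFull:40] == 10L))  # stays saturated
})

test_that("demo runs are reproducible and log paste/instance bookkeeping", {
  scenes <- generateScenes(10, smallScene(), seed = 14L)
  args <- list(scenes, ErrorModel(missRate = 0.3, fpRate = 1.5,
                                  fpRadiusPx = 15),
               nIters = 25L, seed = 8L)
  r1 <- do.call(runDemoLoop, args)
  r2 <- do.call(runDemoLoop, args)
  expect_identical(r1$logs, r2$logs)
  expect_identical(bboxMAP(r1$report), bboxMAP(r2$report))

  # every labelled paste adds exactly one instance to the augmented stream
  baseCounts <- vapply(scenes, function(s) length(instances(s)), integer(1))
  ids <- vapply(scenes, imageId, integer(1))
  expect_identical(r1$logs$nInstances,
                   baseCounts[match(r1$logs$imageId, ids)] + r1$logs$pastesEq1)
  # zoo occupancy never exceeds capacity under realistic traffic
  expect_true(all(r1$logs$eq1Size <= 10L & r1$logs$eq2Size <= 10L))
})

test_that("adapter-contract violations are hard errors naming the violation", {
  scenes <- generateScenes(3, smallScene(), seed = 2L)
  badClass <- function(ai) list("not a prediction")
  expect_error(runDemoLoop(scenes, badClass, nIters = 1L, seed = 1L),
               "prediction contract violated.*not a Prediction")
  badDims <- function(ai) list(Prediction(matrix(TRUE, 4, 4), score = 0.5,
                                          imageId = imageId(ai)))
  expect_error(runDemoLoop(scenes, badDims, nIters = 1L, seed = 1L),
               "prediction contract violated.*dimensions")
})

test_that("the adaptive stub reports exposure-dependent effective rates", {
  stub <- adaptiveMockPredictor(ErrorModel(missRate = 0.4, fpRate = 2),
                                learnRate = 0.1)
  s0 <- stub$state()
  expect_identical(s0$eq1Seen, 0L)
  expect_equal(s0$missRate, 0.4)
  stub$notePastes(data.frame(zoo = c("eq1_zoo", "eq2_zoo", "eq1_zoo"),
                             accepted = c(TRUE, TRUE, FALSE)))
  s1 <- stub$state()
  expect_identical(s1$eq1Seen, 1L)
  expect_identical(s1$eq2Seen, 1L)
  expect_equal(s1$missRate, 0.4 * exp(-0.1))
  expect_equal(s1$fpRate, 2 * exp(-0.1))
})
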