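# The hand-worked single-image case: 2 ground-truth disks, 3 predictions
# processed correct / incorrect / correct, giving (1 + 2/3) / 2 = 5/6.
helperHandScene <- function() {
  ai <- helperDiskImage(64, rbind(c(16, 16, 7), c(46, 46, 7)))
  gt1 <- binMask(instances(ai)[[1]])
  gt2 <- binMask(instances(ai)[[2]])
  bg <- helperDisk(64, 64, 46, 16, 6)
  preds <- list(Prediction(gt1, score = 0.9, imageId = 1L),
                Prediction(bg, score = 0.8, imageId = 1L),
                Prediction(gt2, score = 0.7, imageId = 1L))
  list(image = ai, predictions = preds)
}

test_that("union-overlap ratio is IoU with a zero-union convention", {
  expect_identical(overlapUnionRatio(c(0, 0, 10, 10), c(0, 0, 10, 10)), 1)
  expect_identical(overlapUnionRatio(c(0, 0, 10, 10), c(20, 20, 5, 5)), 0)
  expect_equal(overlapUnionRatio(c(0, 0, 10, 10), c(5, 0, 10, 10)), 1 / 3)
  m1 <- matrix(FALSE, 4, 4); m2 <- m1
  expect_identical(overlapUnionRatio(m1, m2, mode = "mask"), 0)
  m1[1:2, 1:2] <- TRUE
  expect_identical(overlapUnionRatio(m1, m1, mode = "mask"), 1)
})

test_that("matching is greedy in score order and consumes ground truth", {
  sc <- helperHandScene()
  gt <- instances(sc$image)
  perfect <- list(Prediction(binMask(gt[[1]]), 1, imageId = 1L),
                  Prediction(binMask(gt[[2]]), 1, imageId = 1L))
  mr <- matchImage(perfect, gt, "mask")
  expect_true(all(mr$correct))
  expect_setequal(mr$matchedGt, c(1L, 2L))

  # two predictions on one GT: the higher-scored one takes it
  dup <- list(Prediction(binMask(gt[[1]]), 0.9, imageId = 1L),
              Prediction(binMask(gt[[1]]), 0.8, imageId = 1L))
  mr2 <- matchImage(dup, gt, "bbox")
  expect_identical(mr2$correct, c(TRUE, FALSE))
  expect_identical(mr2$matchedGt[1], 1L)

  expect_false(any(matchImage(dup, list(), "bbox")$correct))
})

test_that("the metric closes at 1 for perfect and 0 for absent predictions, 5/6 for the worked case", {
  sc <- helperHandScene()
  gt <- instances(sc$image)
  perfect <- lapply(gt, function(g) Prediction(binMask(g), 1, imageId = 1L))
  expect_identical(mapScore(perfect, list(sc$image), "bbox"), 1)
  expect_identical(mapScore(perfect, list(sc$image), "mask"), 1)
  expect_identical(mapScore(list(), list(sc$image), "bbox"), 0)
  expect_equal(mapScore(sc$predictions, list(sc$image), "mask"), 5 / 6)
  expect_equal(mapScore(sc$predictions, list(sc$image), "bbox"), 5 / 6)
  expect_equal(mapScoreBruteforce(sc$predictions, list(sc$image), "bbox"), 5 / 6)
})

test_that("optimised and brute-force evaluators agree to 1e-12 on random scenes", {
  for (seed in 1:30) {
    sc <- helperRandomEvalScene(seed)
    ds <- list(sc$image)
    expect_equal(mapScore(sc$predictions, ds, "bbox"),
                 mapScoreBruteforce(sc$predictions, ds, "bbox"),
                 tolerance = 1e-12)
  }
  for (seed in 31:40) {
    sc <- helperRandomEvalScene(seed)
    ds <- list(sc$image)
    expect_equal(mapScore(sc$predictions, ds, "mask"),
                 mapScoreBruteforce(sc$predictions, ds, "mask"),
                 tolerance = 1e-12)
  }
})

test_that("the score is permutation-invariant and in [0, 1], improves when a top incorrect prediction is dropped", {
  set.seed(55)
  for (rep in 1:8) {
    sc <- helperRandomEvalScene(rep + 100)
    if (length(sc$predictions) < 2) next
    ds <- list(sc$image)
    s0 <- mapScore(sc$predictions, ds, "bbox")
    expect_gte(s0, 0); expect_lte(s0, 1)
    shuf <- sample(sc$predictions)
    expect_identical(mapScore(shuf, ds, "bbox"), s0)
  }

  # removing an incorrect prediction never decreases the score
  sc <- helperHandScene()
  keep <- sc$predictions[c(1, 3)]
  expect_gte(mapScore(keep, list(sc$image), "bbox"),
             mapScore(sc$predictions, list(sc$image), "bbox"))
})

test_that("bbox and mask scores coincide when masks are filled boxes", {
  mkBoxMask <- function(x, y, w, h, side = 48) {
    m <- matrix(FALSE, side, side); m[(y + 1):(y + h), (x + 1):(x + w)] <- TRUE
    m
  }
  ai <- AnnotatedImage(matrix(0.2, 48, 48), imageId = 1L, instances = list(
    Instance(mkBoxMask(4, 4, 10, 12), instanceId = 1L),
    Instance(mkBoxMask(28, 20, 12, 9), instanceId = 2L)))
  preds <- list(Prediction(mkBoxMask(6, 5, 10, 12), 0.9, imageId = 1L),
                Prediction(mkBoxMask(28, 22, 12, 9), 0.8, imageId = 1L),
                Prediction(mkBoxMask(2, 30, 8, 8), 0.7, imageId = 1L))
  expect_identical(mapScore(preds, list(ai), "bbox"),
                   mapScore(preds, list(ai), "mask"))
})

test_that("degenerate images contribute zero terms but count in the average", {
  sc <- helperHandScene()
  gt <- instances(sc$image)
  perfect <- lapply(gt, function(g) Prediction(binMask(g), 1, imageId = 1L))
  emptyImg <- AnnotatedImage(matrix(0.2, 64, 64), imageId = 2L)
  # second image: no GT, no predictions -> term 0, N = 2
  expect_equal(mapScore(perfect, list(sc$image, emptyImg), "bbox"), 0.5)
  # prediction for an unknown image id is a hard error
  stray <- Prediction(binMask(gt[[1]]), 0.5, imageId = 77L)
  expect_error(mapScore(c(perfect, list(stray)), list(sc$image), "bbox"),
               "unknown image id")
  expect_error(mapScoreBruteforce(list(stray), list(sc$image), "bbox"),
               "unknown image id")
})

test_that("evaluateDataset assembles a coherent report and serialises it", {
  sc <- helperHandScene()
  rep <- evaluateDataset(sc$predictions, list(sc$image))
  expect_s4_class(rep, "EvalReport")
  expect_equal(bboxMAP(rep), 5 / 6)
  expect_equal(maskMAP(rep), 5 / 6)
  expect_identical(rep@nPredictions, 3L)
  expect_identical(rep@nGt, 2L)
  expect_equal(perImageTerms(rep, "bbox"), 5 / 6)
  path <- tempfile(fileext = ".json")
  writeEvalReport(rep, path)
  back <- jsonlite::fromJSON(path)
  expect_equal(back$bbox_map, 5 / 6)

  # the COCO-style alternative behaves sanely at the extremes
  gt <- instances(sc$image)
  perfect <- lapply(gt, function(g) Prediction(binMask(g), 1, imageId = 1L))
  expect_equal(cocoAveragePrecision(perfect, list(sc$image), "mask"), 1)
  expect_identical(cocoAveragePrecision(list(), list(sc$image), "mask"), 0)
})
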