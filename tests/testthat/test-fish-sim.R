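test_that("trajectories are reproducible for a fixed seed", {
  cfg <- simConfig(nFish = 8L, nFrames = 20L, seed = 12L)
  expect_identical(simulateSchool(cfg), simulateSchool(cfg))
  sc1 <- makeScene(simPreset("mf25-like", nFish = 8L, seed = 12L))
  sc2 <- makeScene(simPreset("mf25-like", nFish = 8L, seed = 12L))
  expect_identical(detTable(sc1), detTable(sc2))
})

test_that("without interactions or noise, motion is straight-line", {
  cfg <- simConfig(nFish = 4L, nFrames = 12L, schoolingStrength = 0,
                   headingNoiseSd = 0, tailBeatAmp = 0, seed = 21L)
  gt <- simulateSchool(cfg)
  for (id in unique(gt$id)) {
    g <- gt[gt$id == id, ]
    cx <- g$left + g$width / 2
    cy <- g$top + g$height / 2
    # ignore fish after wall contact or hard-core contact with another fish
    meanLen <- mean(tapply(gt$height, gt$id, max))
    inOpen <- cx > 2 * meanLen & cx < 1920 - 2 * meanLen &
      cy > 2 * meanLen & cy < 1080 - 2 * meanLen
    run <- which(cumsum(!inOpen) == 0)
    if (length(run) >= 3) {
      expect_equal(diff(diff(cx[run])), rep(0, length(run) - 2),
                   tolerance = 1e-9)
      expect_equal(diff(diff(cy[run])), rep(0, length(run) - 2),
                   tolerance = 1e-9)
    }
    # box height encodes the (constant) body length
    expect_equal(g$height, rep(g$height[1], nrow(g)))
  }
})

test_that("a full default school keeps every fish in frame every frame", {
  cfg <- simConfig(seed = 13L) # 75 fish, 25 frames, no exits
  gt <- simulateSchool(cfg)
  perFrame <- table(gt$frame)
  expect_equal(length(perFrame), 25L)
  expect_true(all(perFrame == 75L))
  expect_equal(length(unique(gt$id)), 75L)
  expect_true(all(gt$left >= 0 & gt$top >= 0))
  expect_true(all(gt$left + gt$width <= 1920))
  expect_true(all(gt$top + gt$height <= 1080))
  expect_true(all(gt$height >= 40 & gt$height <= 160))
})

test_that("identity corruption reproduces the ground truth", {
  cfg <- simConfig(nFish = 6L, nFrames = 10L, seed = 3L,
                   scoreOverlapPenalty = 0, scoreJitterPenalty = 0)
  gt <- simulateSchool(cfg)
  cor <- corruptDetections(gt, cfg)
  expect_equal(nrow(cor$detections), nrow(gt))
  expect_equal(cor$detections$left, gt$left)
  expect_equal(cor$detections$width, gt$width)
  expect_true(all(cor$detections$score == 1))
  expect_equal(nrow(cor$events), 0L)
})

test_that("certain occlusion hides exactly one of a fully overlapped pair", {
  gt <- do.call(rbind, lapply(1:6, function(f) data.frame(
    frame = f, id = c(1L, 2L),
    left = c(100, 102), top = c(100, 102),
    width = c(50, 40), height = c(50, 40))))
  cfg <- simConfig(nFish = 2L, occlusionDropProb = 1,
                   occlusionIouThreshold = 0.3, seed = 5L)
  cor <- corruptDetections(gt, cfg)
  perFrame <- table(cor$detections$frame)
  expect_true(all(perFrame == 1L))
  # the smaller box (id 2) is always the victim, and every drop is logged
  expect_true(all(cor$detections$sourceId == 1L))
  occ <- cor$events[cor$events$type == "occlusion_drop", ]
  expect_equal(nrow(occ), 6L)
  expect_true(all(occ$id == 2L))
  expect_true(all(occ$otherId == 1L))
})

test_that("clutter counts follow the Poisson mean", {
  gt <- data.frame(frame = 1:1000, id = 1L, left = 10, top = 10,
                   width = 40, height = 40)
  cfg <- simConfig(nFish = 1L, clutterRate = 2, seed = 8L)
  cor <- corruptDetections(gt, cfg)
  nClutter <- sum(is.na(cor$detections$sourceId))
  expect_lt(abs(nClutter - 2000), 3 * sqrt(2000))
  expect_equal(sum(cor$events$type == "clutter"), nClutter)
})

test_that("more occlusion pressure means weakly fewer detections", {
  rates <- sapply(c(0, 0.5, 1), function(p) {
    mean(sapply(1:5, function(s) {
      cfg <- simConfig(nFish = 30L, nFrames = 15L, occlusionDropProb = p,
                       schoolingStrength = 0.9, seed = s)
      nrow(corruptDetections(simulateSchool(cfg), cfg)$detections) / 15
    }))
  })
  expect_true(all(diff(rates) <= 1e-9))
})

test_that("every detection is linked to a source or logged as clutter", {
  sc <- makeScene(simPreset("mf25-like", nFish = 20L, seed = 7L))
  det <- detTable(sc)
  gtIds <- unique(gtTable(sc)$id)
  real <- det[!is.na(det$sourceId), ]
  expect_true(all(real$sourceId %in% gtIds))
  expect_equal(sum(is.na(det$sourceId)),
               sum(sceneEvents(sc)$type == "clutter"))
  perFrame <- table(factor(det$frame, levels = 1:25))
  clutterPerFrame <- table(factor(det$frame[is.na(det$sourceId)], levels = 1:25))
  expect_true(all(perFrame <= 20 + clutterPerFrame))
})

test_that("scene files replay byte-identically from the sidecar", {
  d1 <- withr::local_tempdir()
  sc <- makeScene(simPreset("mf25-like", nFish = 10L, seed = 14L), dir = d1)
  cfg2 <- loadSimConfig(file.path(d1, "scene.json"))
  d2 <- withr::local_tempdir()
  makeScene(cfg2, dir = d2)
  expect_identical(readLines(file.path(d1, "gt.txt")),
                   readLines(file.path(d2, "gt.txt")))
  expect_identical(readLines(file.path(d1, "det.txt")),
                   readLines(file.path(d2, "det.txt")))
  # gt parses back into one trajectory per fish
  g <- readGroundTruth(file.path(d1, "gt.txt"))
  expect_equal(length(unique(g$id)), 10L)
})
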