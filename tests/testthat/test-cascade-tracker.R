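det1 <- function(frame, box, score) {
  data.frame(frame = frame, left = box[1], top = box[2], width = box[3],
             height = box[4], score = score)
}

test_that("track birth follows the score threshold", {
  tk <- newTracker(trackerConfig())
  st <- trackStep(tk, det1(1L, c(0, 0, 40, 40), 0.9), 1L)
  expect_equal(nrow(st$records), 1L)
  expect_equal(st$records$id, 1L)

  tk <- newTracker(trackerConfig(preThresh = 0))
  st <- trackStep(tk, det1(1L, c(0, 0, 40, 40), 0.3), 1L)
  expect_equal(nrow(st$records), 0L)
  expect_length(st$tracker$tracks, 0L)

  # exactly at the threshold: ingested but not born (birth needs score > theta)
  tk <- newTracker(trackerConfig())
  st <- trackStep(tk, det1(1L, c(0, 0, 40, 40), 0.4), 1L)
  expect_equal(nrow(st$records), 0L)
})

test_that("a track missing more than maxAge consecutive frames is purged", {
  cfg <- trackerConfig(maxAge = 3L)
  tk <- newTracker(cfg)
  box <- c(100, 100, 40, 40)
  for (f in 1:2) {
    st <- trackStep(tk, det1(f, box, 0.9), f)
    tk <- st$tracker
  }
  # three missed frames: the track coasts and stays alive
  for (f in 3:5) {
    st <- trackStep(tk, NULL, f)
    tk <- st$tracker
    expect_equal(nrow(st$records), 1L)
    expect_true(st$records$coasted)
    expect_equal(st$records$id, 1L)
  }
  # a matching detection on the 4th frame revives the same identity
  st <- trackStep(tk, det1(6L, box, 0.9), 6L)
  expect_equal(st$records$id, 1L)
  expect_false(st$records$coasted)

  # with a 4th consecutive miss instead, the track is purged...
  tk2 <- newTracker(cfg)
  for (f in 1:2) tk2 <- trackStep(tk2, det1(f, box, 0.9), f)$tracker
  for (f in 3:5) tk2 <- trackStep(tk2, NULL, f)$tracker
  st <- trackStep(tk2, NULL, 6L)
  expect_equal(nrow(st$records), 0L)
  expect_length(st$tracker$tracks, 0L)
  # ...and the old identity never reappears
  st <- trackStep(st$tracker, det1(7L, box, 0.9), 7L)
  expect_equal(st$records$id, 2L)
})

test_that("score decay is multiplicative per missed frame", {
  cfg <- trackerConfig(decayFactor = 0.9)
  tr <- list(score = 0.8, misses = 0L)
  tr <- decayScore(tr, cfg)
  expect_equal(tr$score, 0.72)
  expect_equal(tr$misses, 1L)

  trSame <- decayScore(list(score = 0.6, misses = 0L),
                       trackerConfig(decayFactor = 1.0))
  expect_equal(trSame$score, 0.6)

  # k misses against the closed form
  tr <- list(score = 1, misses = 0L)
  for (k in 1:7) tr <- decayScore(tr, cfg)
  expect_equal(tr$score, 0.9^7, tolerance = 1e-12)
})

test_that("two separated constant-velocity targets keep their identities", {
  frames <- 1:10
  detA <- data.frame(frame = frames, left = 100 + 5 * (frames - 1),
                     top = 100, width = 40, height = 40, score = 1)
  detB <- data.frame(frame = frames, left = 900, top = 700 - 4 * (frames - 1),
                     width = 50, height = 50, score = 1)
  rec <- trackSequence(rbind(detA, detB), trackerConfig())
  live <- rec[!rec$coasted, ]
  expect_equal(length(unique(live$id)), 2L)
  # the reported boxes are the matched detections themselves
  a <- live[live$left < 500, ]
  expect_equal(sort(a$left), sort(detA$left), tolerance = 1e-9)
  expect_equal(unique(a$id), a$id[1])
})

test_that("a later stage recovers what the motion stage rejects", {
  cfg <- trackerConfig()
  s <- kfPredict(kfInit(c(0, 0, 40, 40)), cfg@posNoiseWeight, cfg@velNoiseWeight)
  # detection 1: far away (fails every gate); detection 2: overlapping but
  # squashed so its height innovation blows the chi-square motion gate
  dets <- rbind(c(5000, 5000, 40, 40),
                c(0, 10, 40, 15))
  expect_false(any(buildCostMatrix("motion", list(s), dets, cfg)$feasible[1, ]))
  m1 <- matchStage("motion", list(s), dets, integer(0), integer(0), cfg)
  expect_equal(nrow(m1), 0L)
  m2 <- matchStage("iou", list(s), dets,
                   m1[, 1], m1[, 2], cfg)
  expect_equal(nrow(m2), 1L)
  expect_equal(unname(m2[1, ]), c(1L, 2L))
})

test_that("stage matches never violate the stage gate", {
  set.seed(31)
  cfg <- trackerConfig()
  for (k in 1:20) {
    states <- lapply(1:4, function(i)
      kfPredict(kfInit(c(runif(1, 0, 400), runif(1, 0, 400),
                         runif(1, 20, 60), runif(1, 20, 60)))))
    dets <- cbind(runif(5, 0, 400), runif(5, 0, 400),
                  runif(5, 20, 60), runif(5, 20, 60))
    mt <- integer(0); md <- integer(0)
    for (st in c("motion", "iou", "distance")) {
      pr <- matchStage(st, states, dets, mt, md, cfg)
      if (nrow(pr)) {
        cm <- buildCostMatrix(st, states, dets, cfg)
        expect_true(all(cm$feasible[pr]))
        # a stage only touches yet-unmatched tracks and detections
        expect_length(intersect(pr[, 1], mt), 0L)
        expect_length(intersect(pr[, 2], md), 0L)
      }
      mt <- c(mt, pr[, 1]); md <- c(md, pr[, 2])
    }
  }
})

test_that("every detection and track takes exactly one lifecycle path", {
  sc <- makeScene(simPreset("mf25-like", nFish = 15L, seed = 9L))
  cfg <- trackerConfig()
  tk <- newTracker(cfg)
  perFrame <- splitByFrame(detTable(sc), seq_len(25))
  seen <- integer(0)
  for (f in seq_len(25)) {
    before <- vapply(tk$tracks, `[[`, integer(1), "id")
    st <- trackStep(tk, perFrame[[f]], f)
    tk <- st$tracker
    after <- vapply(tk$tracks, `[[`, integer(1), "id")
    rec <- st$records
    # no identity appears twice in one frame's output
    expect_false(any(duplicated(rec$id)))
    # records cover exactly the surviving tracks (matched, new, or coasting)
    expect_setequal(rec$id, after)
    # surviving tracks are previous tracks minus purges plus births
    expect_true(all(setdiff(before, after) %in% seen))   # purged ids existed
    expect_true(all(setdiff(after, before) > max(c(0L, seen)))) # fresh ids grow
    seen <- union(seen, after)
  }
})

test_that("identities are never reused and appear in contiguous frame runs", {
  sc <- makeScene(simPreset("severe-occlusion", nFish = 15L, seed = 4L))
  rec <- trackSequence(detTable(sc), trackerConfig(), frames = seq_len(25))
  for (id in unique(rec$id)) {
    fr <- sort(rec$frame[rec$id == id])
    expect_equal(fr, seq(min(fr), max(fr)))
  }
})

test_that("tracking is deterministic and rejects out-of-order frames", {
  sc <- makeScene(simPreset("mf25-like", nFish = 10L, seed = 2L))
  r1 <- trackSequence(detTable(sc), trackerConfig(), frames = seq_len(25))
  r2 <- trackSequence(detTable(sc), trackerConfig(), frames = seq_len(25))
  expect_identical(r1, r2)
  expect_equal(nrow(trackSequence(detTable(sc)[0, ], trackerConfig())), 0L)

  tk <- newTracker(trackerConfig())
  tk <- trackStep(tk, det1(2L, c(0, 0, 10, 10), 0.9), 2L)$tracker
  expect_error(trackStep(tk, det1(1L, c(0, 0, 10, 10), 0.9), 1L),
               "strictly increasing")
})

test_that("non-finite boxes are rejected with a warning", {
  tk <- newTracker(trackerConfig())
  d <- det1(1L, c(NaN, 0, 10, 10), 0.9)
  expect_warning(st <- trackStep(tk, d, 1L), "rejected")
  expect_equal(nrow(st$records), 0L)
})

test_that("a perfect detection stream is tracked perfectly", {
  sc <- makeScene(simConfig(nFish = 25L, seed = 6L))
  rec <- trackSequence(detTable(sc), trackerConfig(), frames = seq_len(25))
  rep <- evaluateTracking(gtTable(sc), rec)
  m <- reportMetrics(rep)
  expect_equal(m[["MOTA"]], 1)
  expect_equal(m[["IDF1"]], 1)
  expect_equal(unname(reportCounts(rep)[["IDSW"]]), 0)
})
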