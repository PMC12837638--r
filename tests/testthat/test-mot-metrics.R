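boxRow <- function(frame, id, x, y, w = 10, h = 10) {
  data.frame(frame = frame, id = id, left = x, top = y, width = w, height = h)
}

gridScene <- function(nObj, nFrames, spacing = 50) {
  do.call(rbind, lapply(seq_len(nObj), function(i)
    boxRow(seq_len(nFrames), i, spacing * i, 10 + seq_len(nFrames))))
}

test_that("CLEAR matching on perfect and empty predictions", {
  gt <- gridScene(3, 4)
  cm <- clearMatch(gt, gt)
  expect_equal(unname(cm$counts[c("FP", "FN", "IDSW")]), c(0L, 0L, 0L))
  expect_equal(cm$counts[["TP"]], cm$counts[["GT"]])
  expect_equal(unname(cm$coverage), rep(1, 3))

  cmEmpty <- clearMatch(gt, gt[0, ])
  expect_equal(cmEmpty$counts[["FN"]], nrow(gt))
  expect_equal(unname(cmEmpty$counts[c("FP", "IDSW", "TP")]), c(0L, 0L, 0L))
})

test_that("an identity handover is counted as one switch", {
  gt <- boxRow(1:4, 1, 100, 100)
  pred <- rbind(boxRow(1:2, 7, 100, 100), boxRow(3:4, 8, 100, 100))
  cm <- clearMatch(gt, pred)
  expect_equal(cm$counts[["IDSW"]], 1L)
  expect_equal(cm$counts[["TP"]], 4L)
  expect_equal(unname(cm$counts[c("FP", "FN")]), c(0L, 0L))
})

test_that("persisted correspondences survive a better-overlapping newcomer", {
  # gt 1 is matched to pred 7; a new pred box with higher IoU appears later,
  # but the existing valid pairing must persist (no switch, newcomer is FP)
  gt <- boxRow(1:3, 1, 100, 100)
  predOld <- boxRow(1:3, 7, 103, 100) # IoU = 7/13 >= 0.5 every frame
  predNew <- boxRow(2:3, 8, 100, 100) # perfect overlap, arrives at frame 2
  cm <- clearMatch(gt, rbind(predOld, predNew))
  expect_equal(cm$counts[["IDSW"]], 0L)
  expect_equal(cm$counts[["FP"]], 2L)
})

test_that("MOTA arithmetic including the negative regime", {
  expect_equal(mota(c(FN = 1, FP = 1, IDSW = 0, GT = 10)), 0.8)
  expect_equal(mota(c(FN = 0, FP = 0, IDSW = 0, GT = 10)), 1.0)
  expect_equal(mota(c(FN = 0, FP = 20, IDSW = 0, GT = 10)), -1.0)
  expect_error(mota(c(FN = 0, FP = 0, IDSW = 0, GT = 0)), "undefined")
})

test_that("MOTP is the mean 1 - IoU over matches", {
  gt <- boxRow(1, 1, 0, 0)
  pred <- boxRow(1, 5, 5, 5) # IoU 1/7 with a 10x10 at (0,0)... below 0.5
  cm <- clearMatch(gt, pred, iouThreshold = 0.1)
  expect_equal(motp(cm$distances), 6 / 7, tolerance = 1e-12)
  expect_error(motp(numeric(0)), "undefined")
  # invariant to frame ordering
  gt2 <- gridScene(2, 3)
  shuf <- gt2[sample(nrow(gt2)), ]
  expect_equal(motp(clearMatch(gt2, gt2)$distances),
               motp(clearMatch(gt2, shuf)$distances))
})

test_that("identity counts are exact for relabeled and empty predictions", {
  gt <- gridScene(3, 5)
  relabeled <- gt
  relabeled$id <- c(30, 10, 20)[gt$id]
  idc <- idGlobalAssignment(gt, relabeled)
  expect_equal(unname(idc), c(nrow(gt), 0, 0))
  idcEmpty <- idGlobalAssignment(gt, gt[0, ])
  expect_equal(unname(idcEmpty), c(0, 0, nrow(gt)))
})

test_that("identity assignment equals exhaustive bijection search on a toy", {
  gt <- rbind(boxRow(1:4, 1, 0, 0), boxRow(1:4, 2, 100, 0))
  # pred A covers gt1 fully; pred B covers gt2 on half its frames only
  pred <- rbind(boxRow(1:4, 10, 0, 0),
                boxRow(1:2, 11, 100, 0), boxRow(3:4, 11, 300, 0))
  idc <- idGlobalAssignment(gt, pred)
  oracle <- bruteIdCounts(gt, pred, 0.5)
  expect_equal(unname(idc), unname(oracle))
  expect_equal(idc[["IDTP"]], 6)
})

test_that("IDF1 family follows its closed forms", {
  r <- idf1Metrics(c(IDTP = 8, IDFP = 2, IDFN = 2))
  expect_equal(unname(r), c(0.8, 0.8, 0.8))
  perfect <- idf1Metrics(c(IDTP = 12, IDFP = 0, IDFN = 0))
  expect_equal(unname(perfect), c(1, 1, 1))
  set.seed(3)
  for (k in 1:30) {
    counts <- c(IDTP = sample(1:50, 1), IDFP = sample(0:30, 1),
                IDFN = sample(0:30, 1))
    r <- idf1Metrics(counts)
    expect_equal(r[["IDF1"]],
                 2 * r[["IDP"]] * r[["IDR"]] / (r[["IDP"]] + r[["IDR"]]),
                 tolerance = 1e-12)
  }
  w <- capture_warnings(z <- idf1Metrics(c(IDTP = 0, IDFP = 0, IDFN = 0)))
  expect_true(any(grepl("denominator", w)))
  expect_equal(unname(z), c(0, 0, 0))
})

test_that("MT/ML apply their lifespan thresholds inclusively/exclusively", {
  r <- mtMl(c(a = 1.0, b = 0.5, c = 0.1))
  expect_equal(r[["MT"]], 1 / 3)
  expect_equal(r[["ML"]], 1 / 3)
  expect_equal(unname(mtMl(c(1, 1))[c("MT", "ML")]), c(1, 0))
  boundary <- mtMl(c(x = 0.8, y = 0.2))
  expect_equal(boundary[["nMT"]], 1) # exactly 0.8 counts as mostly tracked
  expect_equal(boundary[["nML"]], 0) # exactly 0.2 is not mostly lost
  expect_error(mtMl(numeric(0)), "undefined")
})

test_that("HOTA decomposes correctly on perfect and split predictions", {
  gt <- gridScene(2, 6)
  perfect <- gt; perfect$id <- gt$id + 100
  h <- hotaMetrics(gt, perfect)
  expect_equal(h$HOTA, 1); expect_equal(h$DetA, 1); expect_equal(h$AssA, 1)

  # each gt split into two equal-length predicted identities
  split <- gt
  split$id <- gt$id * 10 + ifelse(split$frame <= 3, 0, 1)
  hs <- hotaMetrics(gt, split)
  expect_equal(hs$DetA, 1)
  expect_equal(hs$AssA, 0.5, tolerance = 1e-12)
  expect_equal(hs$HOTA, sqrt(0.5), tolerance = 1e-12)
})

test_that("HOTA is the geometric mean of DetA and AssA", {
  set.seed(17)
  for (k in 1:20) {
    sc <- randomMicroScene()
    h <- hotaMetrics(sc$gt, sc$pred)
    expect_equal(h$HOTA^2, h$DetA * h$AssA, tolerance = 1e-12)
    expect_true(all(c(h$HOTA, h$DetA, h$AssA) >= 0))
    expect_true(all(c(h$HOTA, h$DetA, h$AssA) <= 1))
  }
})

test_that("identity and CLEAR counts match brute force on random micro-scenes", {
  set.seed(29)
  for (k in 1:40) {
    sc <- randomMicroScene()
    idc <- idGlobalAssignment(sc$gt, sc$pred)
    expect_equal(unname(idc), unname(bruteIdCounts(sc$gt, sc$pred, 0.5)))
    cm <- clearMatch(sc$gt, sc$pred)
    oracle <- clearOracle(sc$gt, sc$pred, 0.5)
    expect_equal(cm$counts, oracle$counts)
    expect_equal(sum(cm$distances), oracle$totalDist, tolerance = 1e-9)
  }
})

test_that("metrics are invariant to relabeling and degrade with pure FPs", {
  set.seed(41)
  for (k in 1:10) {
    sc <- randomMicroScene()
    rep1 <- suppressWarnings(evaluateTracking(sc$gt, sc$pred))
    relab <- sc$pred
    ids <- unique(relab$id)
    relab$id <- (match(relab$id, ids) + 500L)
    rep2 <- suppressWarnings(evaluateTracking(sc$gt, relab))
    expect_equal(reportMetrics(rep1), reportMetrics(rep2), tolerance = 1e-12)

    fp <- boxRow(sort(unique(sc$gt$frame)), 999, 500, 500)
    rep3 <- suppressWarnings(evaluateTracking(sc$gt, rbind(sc$pred, fp)))
    m1 <- reportMetrics(rep1); m3 <- reportMetrics(rep3)
    expect_lte(m3[["MOTA"]], m1[["MOTA"]] + 1e-12)
    expect_lte(m3[["IDF1"]], m1[["IDF1"]] + 1e-12)
    expect_lte(m3[["HOTA"]], m1[["HOTA"]] + 1e-12)
  }
})

test_that("evaluateTracking reports a perfect score for relabeled truth", {
  gt <- gridScene(4, 6)
  pred <- gt; pred$id <- 5 - gt$id
  rep <- evaluateTracking(gt, pred)
  m <- reportMetrics(rep)
  expect_equal(m[["MOTA"]], 1); expect_equal(m[["IDF1"]], 1)
  expect_equal(m[["HOTA"]], 1); expect_equal(m[["MOTP"]], 0)
  expect_equal(m[["MT"]], 1);   expect_equal(m[["ML"]], 0)
  # determinism of the full report
  rep2 <- evaluateTracking(gt, pred)
  expect_identical(reportMetrics(rep), reportMetrics(rep2))
})

test_that("reports serialize to JSON and CSV", {
  gt <- gridScene(2, 3)
  rep <- evaluateTracking(gt, gt)
  j <- withr::local_tempfile(fileext = ".json")
  cv <- withr::local_tempfile(fileext = ".csv")
  writeReport(rep, j, cv)
  parsed <- jsonlite::read_json(j, simplifyVector = TRUE)
  expect_equal(parsed$metrics$MOTA, 1)
  expect_equal(parsed$schema, "1.0")
  df <- read.csv(cv)
  expect_true(all(c("MOTA", "IDF1", "HOTA", "IDSW") %in% df$quantity))
})
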