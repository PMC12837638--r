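# Multi-object tracking evaluation: CLEAR matching (FP/FN/IDSW -> MOTA,
# MOTP), identity metrics via a global trajectory assignment (IDF1/IDP/IDR),
# trajectory coverage (MT/ML), and single-threshold HOTA (DetA/AssA).

REPORT_SCHEMA <- "1.0"

frameTables <- function(d, frames) {
  idx <- split(seq_len(nrow(d)), factor(d$frame, levels = frames))
  lapply(idx, function(i) d[i, , drop = FALSE])
}

#' CLEAR-MOT correspondence and error counts
#'
#' Frame-by-frame matching between ground truth and predictions. Each frame,
#' correspondences from the most recent frames are persisted while still
#' valid (IoU at or above the threshold); the remaining boxes are then
#' optimally assigned by the Hungarian algorithm, maximising matches first
#' and total IoU second. An identity switch is counted whenever a
#' ground-truth object's matched predicted identity differs from its most
#' recent previous match.
#'
#' @param gt ground-truth data.frame (frame, id, left, top, width, height).
#' @param pred predicted data.frame in the same layout.
#' @param iouThreshold minimum IoU for a valid correspondence.
#' @return list with `counts` (named: FP, FN, IDSW, GT, TP), `distances`
#'   (1 - IoU per matched pair), and `coverage` (named per-gt-trajectory
#'   fraction of lifespan matched).
#' @export
clearMatch <- function(gt, pred, iouThreshold = 0.5) {
  frames <- sort(unique(c(gt$frame, pred$frame)))
  gtF <- frameTables(gt, frames)
  prF <- frameTables(pred, frames)
  corr <- character(0)        # gt id -> persisted pred id (as names/values)
  lastMatched <- character(0) # gt id -> most recent matched pred id
  FP <- FN <- IDSW <- TP <- 0L
  distances <- numeric(0)
  gtIds <- as.character(sort(unique(gt$id)))
  matchedFrames <- setNames(integer(length(gtIds)), gtIds)

  for (k in seq_along(frames)) {
    G <- gtF[[k]]; P <- prF[[k]]
    nG <- nrow(G); nP <- nrow(P)
    if (nG == 0 && nP == 0) next
    gBoxes <- as.matrix(G[, c("left", "top", "width", "height")])
    pBoxes <- as.matrix(P[, c("left", "top", "width", "height")])
    iou <- iouMatrix(gBoxes, pBoxes)
    usedG <- rep(FALSE, nG); usedP <- rep(FALSE, nP)
    pairs <- matrix(integer(0), 0, 2)
    # persist still-valid correspondences
    if (nG && nP) {
      gKeys <- as.character(G$id)
      pKeys <- as.character(P$id)
      for (gi in seq_len(nG)) {
        pid <- corr[gKeys[gi]]
        if (is.na(pid)) next
        pj <- match(pid, pKeys)
        if (!is.na(pj) && !usedP[pj] && iou[gi, pj] >= iouThreshold) {
          pairs <- rbind(pairs, c(gi, pj))
          usedG[gi] <- TRUE; usedP[pj] <- TRUE
        }
      }
      # optimal assignment of the remainder
      freeG <- which(!usedG); freeP <- which(!usedP)
      if (length(freeG) && length(freeP)) {
        sub <- iou[freeG, freeP, drop = FALSE]
        ms <- solveAssignment(list(values = 1 - sub,
                                   feasible = sub >= iouThreshold))
        if (nrow(ms$pairs)) {
          pairs <- rbind(pairs, cbind(freeG[ms$pairs[, 1]],
                                      freeP[ms$pairs[, 2]]))
        }
      }
    }
    nMatch <- nrow(pairs)
    if (nMatch) {
      for (r in seq_len(nMatch)) {
        gi <- pairs[r, 1]; pj <- pairs[r, 2]
        gid <- as.character(G$id[gi]); pid <- as.character(P$id[pj])
        prev <- lastMatched[gid]
        if (!is.na(prev) && prev != pid) IDSW <- IDSW + 1L
        lastMatched[gid] <- pid
        corr[gid] <- pid
        distances <- c(distances, 1 - iou[gi, pj])
        matchedFrames[gid] <- matchedFrames[gid] + 1L
      }
    }
    TP <- TP + nMatch
    FN <- FN + nG - nMatch
    FP <- FP + nP - nMatch
  }
  gtLen <- table(factor(as.character(gt$id), levels = gtIds))
  coverage <- as.numeric(matchedFrames) / as.numeric(gtLen)
  names(coverage) <- gtIds
  list(counts = c(FP = FP, FN = FN, IDSW = IDSW, GT = nrow(gt), TP = TP),
       distances = distances, coverage = coverage)
}

#' Multiple object tracking accuracy
#'
#' `MOTA = 1 - (FN + FP + IDSW) / GT`. Bounded above by 1; can be negative
#' when errors outnumber ground-truth boxes.
#'
#' @param counts named vector with FN, FP, IDSW, GT (e.g. from
#'   [clearMatch()]).
#' @return the MOTA score.
#' @export
mota <- function(counts) {
  if (counts[["GT"]] <= 0) stop("MOTA undefined: no ground-truth boxes")
  1 - (counts[["FN"]] + counts[["FP"]] + counts[["IDSW"]]) / counts[["GT"]]
}

#' Multiple object tracking precision
#'
#' Mean localisation error over matched pairs, here `1 - IoU` so 0 is perfect
#' overlap and lower is better.
#'
#' @param distances per-match `1 - IoU` values from [clearMatch()].
#' @return mean distance in \[0, 1\].
#' @export
motp <- function(distances) {
  if (!length(distances)) stop("MOTP undefined: no matched pairs")
  mean(distances)
}

#' Global identity assignment counts
#'
#' Bipartite minimum-cost matching between ground-truth and predicted
#' trajectories (dummy-augmented so every trajectory matches a real or dummy
#' partner). The cost of a real pair is the number of ground-truth frames not
#' co-located with the prediction plus the number of predicted frames not
#' co-located with the truth, where co-location means both boxes present in a
#' frame with IoU at or above the threshold. IDTP is the total number of
#' co-located frames over matched real pairs.
#'
#' @inheritParams clearMatch
#' @return named vector with IDTP, IDFP, IDFN.
#' @export
idGlobalAssignment <- function(gt, pred, iouThreshold = 0.5) {
  gIds <- sort(unique(gt$id)); pIds <- sort(unique(pred$id))
  nG <- length(gIds); nP <- length(pIds)
  totG <- nrow(gt); totP <- nrow(pred)
  if (nG == 0 || nP == 0) {
    return(c(IDTP = 0, IDFP = totP, IDFN = totG))
  }
  frames <- sort(unique(c(gt$frame, pred$frame)))
  gtF <- frameTables(gt, frames)
  prF <- frameTables(pred, frames)
  overlap <- matrix(0L, nG, nP)
  for (k in seq_along(frames)) {
    G <- gtF[[k]]; P <- prF[[k]]
    if (!nrow(G) || !nrow(P)) next
    iou <- iouMatrix(as.matrix(G[, c("left", "top", "width", "height")]),
                     as.matrix(P[, c("left", "top", "width", "height")]))
    hit <- which(iou >= iouThreshold, arr.ind = TRUE)
    if (nrow(hit)) {
      gi <- match(G$id[hit[, 1]], gIds)
      pj <- match(P$id[hit[, 2]], pIds)
      for (r in seq_along(gi)) overlap[gi[r], pj[r]] <- overlap[gi[r], pj[r]] + 1L
    }
  }
  lenG <- as.integer(table(factor(gt$id, levels = gIds)))
  lenP <- as.integer(table(factor(pred$id, levels = pIds)))
  n <- nG + nP
  cost <- matrix(BIG_COST, n, n)
  cost[seq_len(nG), seq_len(nP)] <- outer(lenG, lenP, "+") - 2 * overlap
  for (i in seq_len(nG)) cost[i, nP + i] <- lenG[i]
  for (j in seq_len(nP)) cost[nG + j, j] <- lenP[j]
  cost[nG + seq_len(nP), nP + seq_len(nG)] <- 0
  assign <- hungarian_solve(cost)
  idtp <- 0L
  for (i in seq_len(nG)) {
    j <- assign[i]
    if (j >= 1 && j <= nP) idtp <- idtp + overlap[i, j]
  }
  c(IDTP = idtp, IDFP = totP - idtp, IDFN = totG - idtp)
}

#' Identity precision, recall and F1
#'
#' `IDP = IDTP/(IDTP+IDFP)`, `IDR = IDTP/(IDTP+IDFN)`, and IDF1 their
#' harmonic mean `2 IDTP / (2 IDTP + IDFP + IDFN)`. A zero denominator yields
#' 0 with a warning so batch evaluation survives degenerate clips.
#'
#' @param idCounts named vector with IDTP, IDFP, IDFN (from
#'   [idGlobalAssignment()]).
#' @return named vector with IDF1, IDP, IDR.
#' @export
idf1Metrics <- function(idCounts) {
  idtp <- idCounts[["IDTP"]]; idfp <- idCounts[["IDFP"]]; idfn <- idCounts[["IDFN"]]
  safe <- function(num, den, what) {
    if (den <= 0) {
      warning(what, " denominator is zero; reporting 0")
      return(0)
    }
    num / den
  }
  c(IDF1 = safe(2 * idtp, 2 * idtp + idfp + idfn, "IDF1"),
    IDP = safe(idtp, idtp + idfp, "IDP"),
    IDR = safe(idtp, idtp + idfn, "IDR"))
}

#' Mostly-tracked and mostly-lost fractions
#'
#' A ground-truth trajectory counts as mostly tracked when matched for at
#' least 80% of its lifespan and mostly lost when matched for less than 20%.
#'
#' @param coverage per-trajectory matched fraction (from [clearMatch()]).
#' @return named vector with MT, ML (fractions of trajectories), and the
#'   underlying counts nMT, nML, nTraj.
#' @export
mtMl <- function(coverage) {
  if (!length(coverage)) stop("MT/ML undefined: no ground-truth trajectories")
  nMT <- sum(coverage >= 0.8)
  nML <- sum(coverage < 0.2)
  c(MT = nMT / length(coverage), ML = nML / length(coverage),
    nMT = nMT, nML = nML, nTraj = length(coverage))
}

hotaSingle <- function(gt, pred, alpha) {
  gIds <- sort(unique(gt$id)); pIds <- sort(unique(pred$id))
  nG <- length(gIds); nP <- length(pIds)
  totG <- nrow(gt); totP <- nrow(pred)
  if (nG == 0 || nP == 0) {
    det <- if (totG + totP > 0) 0 else 0
    return(list(HOTA = 0, DetA = det, AssA = 0,
                TP = 0L, FP = totP, FN = totG,
                assocScores = numeric(0)))
  }
  frames <- sort(unique(c(gt$frame, pred$frame)))
  gtF <- frameTables(gt, frames)
  prF <- frameTables(pred, frames)
  gtCount <- as.integer(table(factor(gt$id, levels = gIds)))
  prCount <- as.integer(table(factor(pred$id, levels = pIds)))
  ious <- vector("list", length(frames))
  potential <- matrix(0L, nG, nP)
  for (k in seq_along(frames)) {
    G <- gtF[[k]]; P <- prF[[k]]
    if (!nrow(G) || !nrow(P)) next
    iou <- iouMatrix(as.matrix(G[, c("left", "top", "width", "height")]),
                     as.matrix(P[, c("left", "top", "width", "height")]))
    ious[[k]] <- iou
    hit <- which(iou >= alpha, arr.ind = TRUE)
    if (nrow(hit)) {
      gi <- match(G$id[hit[, 1]], gIds)
      pj <- match(P$id[hit[, 2]], pIds)
      for (r in seq_along(gi)) potential[gi[r], pj[r]] <- potential[gi[r], pj[r]] + 1L
    }
  }
  denom <- outer(gtCount, prCount, "+") - potential
  galign <- ifelse(denom > 0, potential / denom, 0)
  # second pass: per-frame Hungarian on association-weighted similarity
  matches <- matrix(0L, nG, nP)
  TP <- FP <- FN <- 0L
  for (k in seq_along(frames)) {
    G <- gtF[[k]]; P <- prF[[k]]
    nGf <- nrow(G); nPf <- nrow(P)
    if (nGf == 0 && nPf == 0) next
    nMatch <- 0L
    if (nGf && nPf) {
      iou <- ious[[k]]
      gi <- match(G$id, gIds); pj <- match(P$id, pIds)
      score <- galign[gi, pj, drop = FALSE] * iou
      ms <- solveAssignment(list(values = max(score) - score + 1,
                                 feasible = iou >= alpha))
      if (nrow(ms$pairs)) {
        for (r in seq_len(nrow(ms$pairs))) {
          a <- gi[ms$pairs[r, 1]]; b <- pj[ms$pairs[r, 2]]
          matches[a, b] <- matches[a, b] + 1L
        }
        nMatch <- nrow(ms$pairs)
      }
    }
    TP <- TP + nMatch
    FN <- FN + nGf - nMatch
    FP <- FP + nPf - nMatch
  }
  unionCount <- outer(gtCount, prCount, "+") - matches
  assoc <- ifelse(matches > 0, matches / unionCount, 0)
  detA <- if (TP + FP + FN > 0) TP / (TP + FP + FN) else 0
  assA <- if (TP > 0) sum(matches * assoc) / TP else 0
  list(HOTA = sqrt(detA * assA), DetA = detA, AssA = assA,
       TP = TP, FP = FP, FN = FN, assocScores = assoc[matches > 0])
}

#' Higher-order tracking accuracy
#'
#' HOTA decomposes tracking quality into detection accuracy
#' `DetA = TP/(TP+FP+FN)` and association accuracy, the mean over true
#' positives of the per-detection association score
#' `A(c) = TPA/(TPA+FNA+FPA)`; `HOTA = sqrt(DetA * AssA)`. TPA counts
#' detections jointly matched to the same (gt id, pred id) pair across the
#' sequence, FNA/FPA the gt-only and pred-only matched detections of that
#' pair. Per-frame matching maximises association-weighted IoU (Hungarian),
#' accepting pairs with IoU at or above the localisation threshold.
#'
#' By default HOTA is computed at the single threshold `alphas = 0.5`; pass
#' the standard grid `seq(0.05, 0.95, by = 0.05)` to average over thresholds
#' for cross-paper comparability.
#'
#' @inheritParams clearMatch
#' @param alphas localisation threshold(s); components are averaged when more
#'   than one is given.
#' @return list with HOTA, DetA, AssA (averaged over `alphas`), the per-alpha
#'   table `perAlpha`, and for a single alpha the per-TP association scores.
#' @export
hotaMetrics <- function(gt, pred, alphas = 0.5) {
  res <- lapply(alphas, function(a) hotaSingle(gt, pred, a))
  perAlpha <- data.frame(
    alpha = alphas,
    HOTA = vapply(res, `[[`, numeric(1), "HOTA"),
    DetA = vapply(res, `[[`, numeric(1), "DetA"),
    AssA = vapply(res, `[[`, numeric(1), "AssA"),
    TP = vapply(res, function(r) as.numeric(r$TP), numeric(1)),
    FP = vapply(res, function(r) as.numeric(r$FP), numeric(1)),
    FN = vapply(res, function(r) as.numeric(r$FN), numeric(1))
  )
  out <- list(HOTA = mean(perAlpha$HOTA), DetA = mean(perAlpha$DetA),
              AssA = mean(perAlpha$AssA), perAlpha = perAlpha)
  if (length(alphas) == 1L) out$assocScores <- res[[1]]$assocScores
  out
}

#' Evaluate a tracking result against ground truth
#'
#' Runs the full metric suite: CLEAR matching (MOTA, MOTP, FP, FN, IDSW),
#' identity metrics after global trajectory assignment (IDF1, IDP, IDR),
#' trajectory coverage (MT, ML) and HOTA (DetA, AssA). Inputs may be file
#' paths (MOTChallenge dialect, read via [readGroundTruth()]) or data.frames.
#' A frame-range mismatch between the two inputs triggers a warning and
#' evaluation proceeds on the union of frames. Degenerate inputs (no
#' predictions, no matches) yield 0-valued metrics with warnings rather than
#' errors.
#'
#' @param gt ground truth: path or data.frame (frame, id, left, top, width,
#'   height).
#' @param pred tracking result: path or data.frame in the same layout.
#' @param iouThreshold localisation threshold for all matchers.
#' @param hotaAlphas threshold(s) for HOTA; defaults to `iouThreshold`.
#' @param includeCoasted if `pred` carries a `coasted` column, keep coasted
#'   records instead of dropping them.
#' @return a [MetricReport-class].
#' @export
evaluateTracking <- function(gt, pred, iouThreshold = 0.5, hotaAlphas = NULL,
                             includeCoasted = FALSE) {
  if (is.character(gt)) gt <- readGroundTruth(gt)
  if (is.character(pred)) pred <- readGroundTruth(pred)
  if ("coasted" %in% names(pred) && !includeCoasted) {
    pred <- pred[!pred$coasted, , drop = FALSE]
  }
  if (is.null(hotaAlphas)) hotaAlphas <- iouThreshold
  if (nrow(gt) && nrow(pred) &&
      (min(gt$frame) != min(pred$frame) || max(gt$frame) != max(pred$frame))) {
    warning("frame ranges of gt and prediction differ; evaluating on the union")
  }
  cm <- clearMatch(gt, pred, iouThreshold)
  motaV <- if (cm$counts[["GT"]] > 0) mota(cm$counts) else {
    warning("no ground-truth boxes; MOTA reported as 0")
    0
  }
  motpV <- if (length(cm$distances)) motp(cm$distances) else {
    warning("no matched pairs; MOTP reported as 0")
    0
  }
  idc <- idGlobalAssignment(gt, pred, iouThreshold)
  idm <- idf1Metrics(idc)
  cov <- mtMl(cm$coverage)
  ho <- hotaMetrics(gt, pred, hotaAlphas)
  metrics <- c(MOTA = motaV, MOTP = motpV,
               IDF1 = idm[["IDF1"]], IDP = idm[["IDP"]], IDR = idm[["IDR"]],
               HOTA = ho$HOTA, DetA = ho$DetA, AssA = ho$AssA,
               MT = cov[["MT"]], ML = cov[["ML"]])
  counts <- c(cm$counts, idc,
              nMT = cov[["nMT"]], nML = cov[["nML"]], nTraj = cov[["nTraj"]],
              nPred = nrow(pred))
  new("MetricReport", metrics = metrics, counts = counts,
      coverage = cm$coverage, iouThreshold = iouThreshold,
      schemaVersion = REPORT_SCHEMA)
}

#' Write a metric report to JSON and/or CSV
#'
#' The JSON schema is versioned (`schema` field) for downstream tooling; the
#' CSV holds one metric or count per row.
#'
#' @param report a [MetricReport-class].
#' @param jsonPath,csvPath output paths (either may be NULL).
#' @return invisible list of paths written.
#' @export
writeReport <- function(report, jsonPath = NULL, csvPath = NULL) {
  stopifnot(is(report, "MetricReport"))
  if (!is.null(jsonPath)) {
    payload <- list(schema = report@schemaVersion,
                    iouThreshold = report@iouThreshold,
                    metrics = as.list(report@metrics),
                    counts = as.list(report@counts),
                    coverage = as.list(report@coverage))
    jsonlite::write_json(payload, jsonPath, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  if (!is.null(csvPath)) {
    df <- data.frame(quantity = c(names(report@metrics), names(report@counts)),
                     value = c(unname(report@metrics), unname(report@counts)))
    utils::write.csv(df, csvPath, row.names = FALSE, quote = FALSE)
  }
  invisible(list(json = jsonPath, csv = csvPath))
}
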