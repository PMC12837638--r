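# Independent brute-force oracles and fixture builders shared across tests.
# These deliberately avoid the package's solvers: assignments are enumerated
# over permutations and trajectory matchings over injective maps.

permutationsOf <- function(n) {
  if (n == 0) return(matrix(integer(0), 1, 0))
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutationsOf(n - 1L)
  out <- vector("list", n)
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    out[[k]] <- cbind(k, matrix(rest[sub], nrow(sub), n - 1L))
  }
  do.call(rbind, out)
}

# Lexicographic optimum (max feasible matches, then min total cost) over all
# injective row->column maps of a masked cost matrix.
bruteAssignment <- function(values, feasible) {
  n <- nrow(values); m <- ncol(values)
  if (n == 0 || m == 0 || !any(feasible)) {
    return(list(count = 0L, cost = 0))
  }
  transposed <- n > m
  if (transposed) { values <- t(values); feasible <- t(feasible); tmp <- n; n <- m; m <- tmp }
  perms <- permutationsOf(m)
  bestCount <- -1L; bestCost <- Inf
  for (r in seq_len(nrow(perms))) {
    cols <- perms[r, seq_len(n)]
    feas <- feasible[cbind(seq_len(n), cols)]
    count <- sum(feas)
    cost <- sum(values[cbind(seq_len(n), cols)][feas])
    if (count > bestCount || (count == bestCount && cost < bestCost - 1e-12)) {
      bestCount <- count; bestCost <- cost
    }
  }
  list(count = bestCount, cost = bestCost)
}

# Frame-overlap counts between every gt and pred trajectory: number of frames
# where both are present and IoU >= thr.
overlapCounts <- function(gt, pred, thr) {
  gIds <- sort(unique(gt$id)); pIds <- sort(unique(pred$id))
  O <- matrix(0L, length(gIds), length(pIds),
              dimnames = list(as.character(gIds), as.character(pIds)))
  for (f in sort(unique(c(gt$frame, pred$frame)))) {
    G <- gt[gt$frame == f, , drop = FALSE]
    P <- pred[pred$frame == f, , drop = FALSE]
    if (!nrow(G) || !nrow(P)) next
    for (i in seq_len(nrow(G))) for (j in seq_len(nrow(P))) {
      v <- boxIoU(unlist(G[i, c("left", "top", "width", "height")]),
                  unlist(P[j, c("left", "top", "width", "height")]))
      if (v >= thr) {
        gi <- as.character(G$id[i]); pj <- as.character(P$id[j])
        O[gi, pj] <- O[gi, pj] + 1L
      }
    }
  }
  O
}

# Exhaustive search over injective gt->pred trajectory matchings maximizing
# total co-located frames; yields the identity counts.
bruteIdCounts <- function(gt, pred, thr) {
  O <- overlapCounts(gt, pred, thr)
  nG <- nrow(O); nP <- ncol(O)
  best <- 0L
  rec <- function(i, usedP, acc) {
    if (i > nG) { best <<- max(best, acc); return() }
    bound <- acc + sum(apply(O[i:nG, , drop = FALSE], 1, max, 0))
    if (bound < best) return()
    rec(i + 1L, usedP, acc) # gt i unmatched
    for (j in seq_len(nP)) {
      if (!usedP[j]) rec(i + 1L, replace(usedP, j, TRUE), acc + O[i, j])
    }
  }
  if (nG > 0 && nP > 0) rec(1L, rep(FALSE, nP), 0L)
  c(IDTP = best, IDFP = nrow(pred) - best, IDFN = nrow(gt) - best)
}

# Independent CLEAR accumulator: same persistence contract as the package
# (most recent correspondence kept while valid), but the per-frame optimal
# assignment is found by permutation brute force.
clearOracle <- function(gt, pred, thr) {
  frames <- sort(unique(c(gt$frame, pred$frame)))
  corr <- character(0); lastMatched <- character(0)
  FP <- FN <- IDSW <- TP <- 0L
  totalDist <- 0
  for (f in frames) {
    G <- gt[gt$frame == f, , drop = FALSE]
    P <- pred[pred$frame == f, , drop = FALSE]
    nG <- nrow(G); nP <- nrow(P)
    pairs <- matrix(integer(0), 0, 2)
    if (nG && nP) {
      iou <- iouMatrix(as.matrix(G[, c("left", "top", "width", "height")]),
                       as.matrix(P[, c("left", "top", "width", "height")]))
      usedG <- rep(FALSE, nG); usedP <- rep(FALSE, nP)
      for (gi in seq_len(nG)) {
        pid <- corr[as.character(G$id[gi])]
        if (is.na(pid)) next
        pj <- match(pid, as.character(P$id))
        if (!is.na(pj) && !usedP[pj] && iou[gi, pj] >= thr) {
          pairs <- rbind(pairs, c(gi, pj)); usedG[gi] <- TRUE; usedP[pj] <- TRUE
        }
      }
      freeG <- which(!usedG); freeP <- which(!usedP)
      if (length(freeG) && length(freeP)) {
        sub <- iou[freeG, freeP, drop = FALSE]
        # brute force: max matches then max total IoU over all injections
        nr <- nrow(sub); nc <- ncol(sub)
        tr <- nr > nc
        s2 <- if (tr) t(sub) else sub
        perms <- permutationsOf(ncol(s2))
        bestCount <- -1L; bestIoU <- -Inf; bestPairs <- NULL
        for (r in seq_len(nrow(perms))) {
          cols <- perms[r, seq_len(nrow(s2))]
          feas <- s2[cbind(seq_len(nrow(s2)), cols)] >= thr
          count <- sum(feas); tot <- sum(s2[cbind(seq_len(nrow(s2)), cols)][feas])
          if (count > bestCount || (count == bestCount && tot > bestIoU + 1e-12)) {
            bestCount <- count; bestIoU <- tot
            bp <- cbind(seq_len(nrow(s2))[feas], cols[feas])
            bestPairs <- if (tr) bp[, 2:1, drop = FALSE] else bp
          }
        }
        if (!is.null(bestPairs) && nrow(bestPairs)) {
          pairs <- rbind(pairs, cbind(freeG[bestPairs[, 1]], freeP[bestPairs[, 2]]))
        }
      }
      if (nrow(pairs)) {
        for (r in seq_len(nrow(pairs))) {
          gid <- as.character(G$id[pairs[r, 1]])
          pid <- as.character(P$id[pairs[r, 2]])
          prev <- lastMatched[gid]
          if (!is.na(prev) && prev != pid) IDSW <- IDSW + 1L
          lastMatched[gid] <- pid
          corr[gid] <- pid
          totalDist <- totalDist + (1 - iou[pairs[r, 1], pairs[r, 2]])
        }
      }
    }
    TP <- TP + nrow(pairs)
    FN <- FN + nG - nrow(pairs)
    FP <- FP + nP - nrow(pairs)
  }
  list(counts = c(FP = FP, FN = FN, IDSW = IDSW, GT = nrow(gt), TP = TP),
       totalDist = totalDist)
}

# Random micro-scene: a few short, possibly fragmented trajectories plus a
# perturbed/relabeled/dropped prediction of them.
randomMicroScene <- function(nObj = sample(1:4, 1), nFrames = sample(2:5, 1)) {
  gt <- list()
  for (id in seq_len(nObj)) {
    present <- sort(sample(seq_len(nFrames), sample(seq_len(nFrames), 1)))
    x <- runif(1, 0, 70); y <- runif(1, 0, 70)
    w <- runif(1, 10, 30); h <- runif(1, 10, 30)
    gt[[id]] <- data.frame(frame = present, id = id,
                           left = x + cumsum(runif(length(present), -3, 3)),
                           top = y + cumsum(runif(length(present), -3, 3)),
                           width = w, height = h)
  }
  gt <- do.call(rbind, gt)
  pred <- gt
  relab <- sample(nObj + 2, nObj) # may collide partially with new ids
  pred$id <- relab[pred$id]
  jit <- matrix(runif(2 * nrow(pred), -6, 6), ncol = 2)
  pred$left <- pred$left + jit[, 1]
  pred$top <- pred$top + jit[, 2]
  pred <- pred[runif(nrow(pred)) > 0.25, , drop = FALSE] # dropped detections
  nExtra <- sample(0:3, 1)
  if (nExtra) {
    pred <- rbind(pred, data.frame(
      frame = sample(seq_len(nFrames), nExtra, replace = TRUE),
      id = nObj + 10 + seq_len(nExtra),
      left = runif(nExtra, 0, 80), top = runif(nExtra, 0, 80),
      width = runif(nExtra, 10, 30), height = runif(nExtra, 10, 30)))
  }
  rownames(gt) <- rownames(pred) <- NULL
  list(gt = gt, pred = pred)
}

# Detection stream of one constant-velocity target with a visibility gap.
gapTrialDetections <- function(gap, seed, nVisible = 10L, nAfter = 5L) {
  set.seed(seed)
  x0 <- runif(1, 200, 1500); y0 <- runif(1, 200, 800)
  vx <- runif(1, -8, 8); vy <- runif(1, -8, 8)
  w <- runif(1, 40, 120); h <- runif(1, 40, 120)
  total <- nVisible + gap + nAfter
  frames <- seq_len(total)
  vis <- c(rep(TRUE, nVisible), rep(FALSE, gap), rep(TRUE, nAfter))
  list(det = data.frame(frame = frames[vis],
                        left = x0 + vx * (frames[vis] - 1),
                        top = y0 + vy * (frames[vis] - 1),
                        width = w, height = h, score = 0.9),
       frames = frames, lastVisible = nVisible, reappear = nVisible + gap + 1L)
}
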