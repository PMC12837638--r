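# Seeded fish-school simulator. Ground truth comes from a minimal zonal
# heading model (repulsion / alignment / attraction plus wall avoidance);
# boxes derive from body length, heading and a sinusoidal tail-beat aspect
# modulation. A separate corruption pass produces the detection stream:
# corner jitter, random dropout, occlusion-conditional dropout (the smaller
# box of a heavily overlapped pair is hidden, a simple depth proxy), Poisson
# clutter, and a penalty-based detection score.

# Box height encodes the fish's body length; width follows the heading (a
# side-on fish fills its length, a head-on fish only its body depth) with a
# sinusoidal tail-beat modulation on top.
fishBox <- function(cx, cy, len, heading, beat) {
  h <- len
  w <- pmax(len * (0.35 + 0.65 * abs(cos(heading))) * (1 + beat), 2)
  cbind(left = cx - w / 2, top = cy - h / 2, width = w, height = h)
}

wrapAngle <- function(a) atan2(sin(a), cos(a))

#' Simulate schooling ground-truth trajectories
#'
#' Generates per-fish trajectories under a zonal interaction model: a fish
#' steers away from neighbours closer than the repulsion radius, otherwise
#' blends alignment with neighbours' headings and attraction toward the local
#' centroid (both scaled by `schoolingStrength`), with wall avoidance near
#' the arena boundary. Heading changes are capped at `turnRateMax` per frame
#' and perturbed by Gaussian noise. The per-frame box follows the fish's
#' position and heading, with a sinusoidal tail-beat modulation of its
#' effective length. Deterministic for a fixed seed.
#'
#' With `schoolingStrength = 0`, `headingNoiseSd = 0` and `tailBeatAmp = 0`
#' the model degenerates to straight-line constant-velocity motion until wall
#' contact.
#'
#' @param config a [SimConfig-class].
#' @param seed RNG seed; defaults to `config@seed`.
#' @return ground-truth data.frame (frame, id, left, top, width, height) in
#'   internal 0-based coordinates.
#' @export
simulateSchool <- function(config = simConfig(), seed = config@seed) {
  stopifnot(is(config, "SimConfig"))
  withr::with_seed(seed, simulateSchoolImpl(config))
}

simulateSchoolImpl <- function(config) {
  n <- config@nFish
  W <- config@arenaWidth; H <- config@arenaHeight
  len <- runif(n, config@bodyLengthRange[1], config@bodyLengthRange[2])
  margin <- max(len) # keep initial boxes inside the arena
  # rejection-sample starting positions so solid bodies never coincide
  cx <- numeric(n); cy <- numeric(n)
  for (i in seq_len(n)) {
    for (attempt in 1:200) {
      px <- runif(1, margin, W - margin)
      py <- runif(1, margin, H - margin)
      if (i == 1L) break
      j <- seq_len(i - 1L)
      if (all(sqrt((px - cx[j])^2 + (py - cy[j])^2) >=
              0.4 * (len[i] + len[j]) / 2)) break
    }
    cx[i] <- px; cy[i] <- py
  }
  heading <- runif(n, -pi, pi)
  speed <- runif(n, config@speedRange[1], config@speedRange[2]) *
    len / config@fps # px per frame
  beatFreq <- runif(n, config@tailBeatFreqRange[1], config@tailBeatFreqRange[2])
  beatPhase <- runif(n, 0, 2 * pi)
  alive <- rep(TRUE, n)

  meanLen <- mean(len)
  rRep <- 1.2 * meanLen
  rAlign <- 4 * meanLen
  rAttract <- 8 * meanLen
  wallMargin <- 2 * meanLen

  out <- vector("list", config@nFrames)
  for (f in seq_len(config@nFrames)) {
    beat <- config@tailBeatAmp * sin(2 * pi * beatFreq * (f - 1) / config@fps +
                                     beatPhase)
    boxes <- fishBox(cx, cy, len, heading, beat)
    idx <- which(alive)
    out[[f]] <- data.frame(frame = f, id = idx,
                           left = boxes[idx, 1], top = boxes[idx, 2],
                           width = boxes[idx, 3], height = boxes[idx, 4])
    if (f == config@nFrames) break

    noise <- rnorm(n, 0, config@headingNoiseSd)
    dx <- outer(cx, cx, "-"); dy <- outer(cy, cy, "-")
    dist <- sqrt(dx^2 + dy^2); diag(dist) <- Inf
    desired <- heading
    for (i in which(alive)) {
      di <- dist[i, ]
      di[!alive] <- Inf
      nearest <- which.min(di)
      if (config@schoolingStrength > 0 && di[nearest] < rRep) {
        # steer directly away from the closest intruder
        desired[i] <- atan2(cy[i] - cy[nearest], cx[i] - cx[nearest])
      } else if (config@schoolingStrength > 0) {
        vx <- cos(heading[i]); vy <- sin(heading[i])
        nb <- which(di < rAlign)
        if (length(nb)) {
          vx <- vx + config@schoolingStrength * mean(cos(heading[nb]))
          vy <- vy + config@schoolingStrength * mean(sin(heading[nb]))
        }
        fa <- which(di < rAttract)
        if (length(fa)) {
          gx <- mean(cx[fa]) - cx[i]; gy <- mean(cy[fa]) - cy[i]
          gn <- sqrt(gx^2 + gy^2)
          if (gn > 0) {
            vx <- vx + 0.5 * config@schoolingStrength * gx / gn
            vy <- vy + 0.5 * config@schoolingStrength * gy / gn
          }
        }
        desired[i] <- atan2(vy, vx)
      }
      # wall avoidance dominates near the boundary
      nearWall <- cx[i] < wallMargin || cx[i] > W - wallMargin ||
        cy[i] < wallMargin || cy[i] > H - wallMargin
      if (nearWall && !config@allowExit) {
        desired[i] <- atan2(H / 2 - cy[i], W / 2 - cx[i])
      }
      turn <- wrapAngle(desired[i] - heading[i])
      turn <- max(min(turn, config@turnRateMax), -config@turnRateMax)
      heading[i] <- wrapAngle(heading[i] + turn + noise[i])
    }
    cx <- cx + speed * cos(heading) * alive
    cy <- cy + speed * sin(heading) * alive
    # hard-core repulsion: fish are solid bodies, so centres may not come
    # closer than a fraction of the pair's mean body length (their boxes can
    # and do still overlap, which is what produces occlusions)
    minSep <- 0.4 * outer(len, len, "+") / 2
    for (it in 1:3) {
      ddx <- outer(cx, cx, "-"); ddy <- outer(cy, cy, "-")
      dd <- sqrt(ddx^2 + ddy^2)
      dd[!alive, ] <- Inf; dd[, !alive] <- Inf; diag(dd) <- Inf
      viol <- which(dd < minSep & upper.tri(dd), arr.ind = TRUE)
      if (!nrow(viol)) break
      for (r in seq_len(nrow(viol))) {
        i <- viol[r, 1]; j <- viol[r, 2]
        d <- sqrt((cx[i] - cx[j])^2 + (cy[i] - cy[j])^2)
        ang <- if (d < 1e-9) heading[i] else atan2(cy[i] - cy[j], cx[i] - cx[j])
        push <- (minSep[i, j] - d) / 2
        cx[i] <- cx[i] + push * cos(ang); cy[i] <- cy[i] + push * sin(ang)
        cx[j] <- cx[j] - push * cos(ang); cy[j] <- cy[j] - push * sin(ang)
      }
    }
    if (config@allowExit) {
      gone <- cx < -len | cx > W + len | cy < -len | cy > H + len
      alive[gone] <- FALSE
    } else {
      halfMax <- len # generous clamp keeping boxes in frame
      cx <- pmin(pmax(cx, halfMax), W - halfMax)
      cy <- pmin(pmax(cy, halfMax), H - halfMax)
    }
  }
  gt <- do.call(rbind, out)
  rownames(gt) <- NULL
  gt
}

#' Corrupt ground truth into a detection stream
#'
#' Applies the detection corruption model: independent Gaussian jitter on
#' each box edge, random dropout with probability `dropProb`, additional
#' dropout of the smaller box of any pair overlapping above
#' `occlusionIouThreshold` with probability `occlusionDropProb` (the rear,
#' smaller-looking fish is the one hidden), and Poisson clutter boxes with
#' low scores. Each surviving detection's score is
#' `scoreBase - scoreJitterPenalty * relJitter - scoreOverlapPenalty * maxIoU`
#' clipped to \[0, 1\]. Deterministic per seed. With all corruption parameters
#' zero the detections reproduce the ground truth exactly with score
#' `scoreBase`.
#'
#' @param gt ground-truth data.frame from [simulateSchool()].
#' @param config a [SimConfig-class].
#' @param seed RNG seed; defaults to `config@seed + 1` so it is decoupled
#'   from the trajectory stream.
#' @return list with `detections` (frame, left, top, width, height, score,
#'   sourceId) and `events` (frame, type, id, otherId).
#' @export
corruptDetections <- function(gt, config = simConfig(),
                              seed = config@seed + 1L) {
  stopifnot(is(config, "SimConfig"))
  withr::with_seed(seed, corruptImpl(gt, config))
}

corruptImpl <- function(gt, config) {
  frames <- if (nrow(gt)) seq(min(gt$frame), max(gt$frame)) else integer(0)
  gtF <- frameTables(gt, frames)
  dets <- list()
  events <- list()
  logEvent <- function(frame, type, id, otherId = NA_integer_) {
    events[[length(events) + 1L]] <<- data.frame(
      frame = frame, type = type, id = id, otherId = otherId)
  }
  for (k in seq_along(frames)) {
    f <- frames[k]
    G <- gtF[[k]]
    n <- nrow(G)
    if (n) {
      boxes <- as.matrix(G[, c("left", "top", "width", "height")])
      iou <- iouMatrix(boxes, boxes); diag(iou) <- 0
      maxIou <- if (n > 1) apply(iou, 1, max) else rep(0, n)
      dropped <- runif(n) < config@dropProb
      for (i in which(dropped)) logEvent(f, "random_drop", G$id[i])
      # occlusion: the smaller box of an overlapped pair is at risk
      if (config@occlusionDropProb > 0 && n > 1) {
        pairs <- which(iou > config@occlusionIouThreshold, arr.ind = TRUE)
        pairs <- pairs[pairs[, 1] < pairs[, 2], , drop = FALSE]
        if (nrow(pairs)) {
          for (r in seq_len(nrow(pairs))) {
            i <- pairs[r, 1]; j <- pairs[r, 2]
            areas <- boxes[, 3] * boxes[, 4]
            victim <- if (areas[i] <= areas[j]) i else j
            other <- if (victim == i) j else i
            if (!dropped[victim] && runif(1) < config@occlusionDropProb) {
              dropped[victim] <- TRUE
              logEvent(f, "occlusion_drop", G$id[victim], G$id[other])
            }
          }
        }
      }
      keep <- which(!dropped)
      if (length(keep)) {
        kb <- boxes[keep, , drop = FALSE]
        relJitter <- rep(0, length(keep))
        if (config@jitterSd > 0) {
          jit <- matrix(rnorm(4 * length(keep), 0, config@jitterSd),
                        ncol = 4)
          right <- kb[, 1] + kb[, 3] + jit[, 3]
          bottom <- kb[, 2] + kb[, 4] + jit[, 4]
          kb[, 1] <- kb[, 1] + jit[, 1]
          kb[, 2] <- kb[, 2] + jit[, 2]
          kb[, 3] <- pmax(right - kb[, 1], 1)
          kb[, 4] <- pmax(bottom - kb[, 2], 1)
          relJitter <- rowMeans(abs(jit)) / boxes[keep, 4]
        }
        score <- pmin(pmax(config@scoreBase -
                             config@scoreJitterPenalty * relJitter -
                             config@scoreOverlapPenalty * maxIou[keep],
                           0), 1)
        dets[[length(dets) + 1L]] <- data.frame(
          frame = f, left = kb[, 1], top = kb[, 2], width = kb[, 3],
          height = kb[, 4], score = score, sourceId = G$id[keep])
      }
    }
    if (config@clutterRate > 0) {
      nClut <- rpois(1, config@clutterRate)
      if (nClut > 0) {
        cw <- runif(nClut, config@bodyLengthRange[1] / 2,
                    config@bodyLengthRange[2])
        chh <- runif(nClut, config@bodyLengthRange[1] / 2,
                     config@bodyLengthRange[2])
        dets[[length(dets) + 1L]] <- data.frame(
          frame = f,
          left = runif(nClut, 0, config@arenaWidth - cw),
          top = runif(nClut, 0, config@arenaHeight - chh),
          width = cw, height = chh,
          score = runif(nClut, 0.05, 0.5),
          sourceId = NA_integer_)
        for (i in seq_len(nClut)) logEvent(f, "clutter", NA_integer_)
      }
    }
  }
  detections <- if (length(dets)) do.call(rbind, dets) else data.frame(
    frame = integer(), left = numeric(), top = numeric(), width = numeric(),
    height = numeric(), score = numeric(), sourceId = integer())
  eventLog <- if (length(events)) do.call(rbind, events) else data.frame(
    frame = integer(), type = character(), id = integer(), otherId = integer())
  rownames(detections) <- NULL
  rownames(eventLog) <- NULL
  list(detections = detections, events = eventLog)
}

#' Generate a full simulated scene
#'
#' Runs [simulateSchool()] and [corruptDetections()] under the config's seed
#' and, when `dir` is given, writes `gt.txt` and `det.txt` in the
#' MOTChallenge dialects plus a `scene.json` sidecar holding the complete
#' configuration. Replaying the sidecar (via [loadSimConfig()]) reproduces
#' the files byte-identically.
#'
#' @param config a [SimConfig-class].
#' @param dir optional output directory (created if missing).
#' @return a [SimScene-class], invisibly carrying the written paths in
#'   attribute `paths` when `dir` was given.
#' @export
makeScene <- function(config = simConfig(), dir = NULL) {
  gt <- simulateSchool(config)
  cor <- corruptDetections(gt, config)
  scene <- new("SimScene", gt = gt, detections = cor$detections,
               events = cor$events, config = config)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    gtPath <- file.path(dir, "gt.txt")
    detPath <- file.path(dir, "det.txt")
    sidecar <- file.path(dir, "scene.json")
    gtOut <- gt
    gtOut$score <- 1
    writeTracks(gtOut, gtPath)
    det <- cor$detections
    lines <- sprintf("%d,-1,%.4f,%.4f,%.4f,%.4f,%.6f,-1,-1,-1",
                     as.integer(det$frame), det$left + 1, det$top + 1,
                     det$width, det$height, det$score)
    con <- file(detPath, open = "wb")
    if (length(lines)) writeLines(lines, con, sep = "\n")
    close(con)
    jsonlite::write_json(simConfigToList(config), sidecar, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    attr(scene, "paths") <- c(gt = gtPath, det = detPath, sidecar = sidecar)
  }
  scene
}

simConfigToList <- function(config) {
  nm <- slotNames("SimConfig")
  out <- lapply(nm, function(s) slot(config, s))
  names(out) <- nm
  out
}

#' Load a simulation configuration from a scene sidecar
#'
#' @param path path to a `scene.json` written by [makeScene()] or a YAML/JSON
#'   config file with the same field names.
#' @return a [SimConfig-class].
#' @export
loadSimConfig <- function(path) {
  vals <- if (grepl("[.]ya?ml$", path)) yaml::read_yaml(path)
          else jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(simConfig, vals[names(vals) %in% names(formals(simConfig))])
}

#' Scene presets
#'
#' Named corruption archetypes over the default tank geometry (75 fish,
#' 1920 x 1080 px, 30 FPS, 25 frames):
#' \describe{
#'   \item{mf25-like}{moderate jitter, dropout, occlusion loss and clutter —
#'     the general dense-tank operating point.}
#'   \item{normal}{light corruption.}
#'   \item{severe-occlusion}{aggressive occlusion-conditional dropout with
#'     strong schooling (dense overlaps).}
#'   \item{severely-deformed}{large tail-beat deformation and corner jitter.}
#'   \item{multi-density}{fewer fish with clutter, probing density contrast.}
#' }
#' Presets differ only in corruption/behaviour parameters and are qualitative
#' analogues of dense-tank recording conditions, not calibrated replicas.
#'
#' @param name preset name.
#' @param ... overrides forwarded to [simConfig()].
#' @return a [SimConfig-class].
#' @export
simPreset <- function(name = c("mf25-like", "normal", "severe-occlusion",
                               "severely-deformed", "multi-density"), ...) {
  name <- match.arg(name)
  base <- switch(name,
    "mf25-like" = list(jitterSd = 1.5, dropProb = 0.05,
                       occlusionDropProb = 0.5, occlusionIouThreshold = 0.3,
                       clutterRate = 0.5, scoreBase = 0.95),
    "normal" = list(jitterSd = 0.8, dropProb = 0.02,
                    occlusionDropProb = 0.2, clutterRate = 0.2,
                    scoreBase = 0.97),
    "severe-occlusion" = list(jitterSd = 1.5, dropProb = 0.05,
                              occlusionDropProb = 0.8,
                              occlusionIouThreshold = 0.2,
                              schoolingStrength = 0.9, clutterRate = 0.5,
                              scoreBase = 0.95),
    "severely-deformed" = list(jitterSd = 3, dropProb = 0.05,
                               occlusionDropProb = 0.4, tailBeatAmp = 0.35,
                               clutterRate = 0.5, scoreBase = 0.92),
    "multi-density" = list(nFish = 25L, jitterSd = 1.5, dropProb = 0.05,
                           occlusionDropProb = 0.4, clutterRate = 1,
                           scoreBase = 0.95)
  )
  over <- list(...)
  base[names(over)] <- over
  do.call(simConfig, base)
}
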