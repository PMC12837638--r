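# Three-stage cascade tracker. Per frame: predict every live track, run the
# motion -> IoU -> distance association cascade (each stage only sees pairs
# left unmatched by earlier stages), update matched tracks, spawn tracks from
# confident unmatched detections, coast unmatched tracks with score decay and
# purge those missing for more than maxAge consecutive frames.

#' Create a tracker
#'
#' @param config a [TrackerConfig-class].
#' @return an opaque tracker state for [trackStep()]; start with no live
#'   tracks and identity counter at 1.
#' @export
newTracker <- function(config = trackerConfig()) {
  list(tracks = list(), nextId = 1L, lastFrame = 0L, config = config)
}

newTrack <- function(id, box, score, config) {
  list(id = as.integer(id),
       state = kfInit(box, config@posNoiseWeight, config@velNoiseWeight),
       score = score, misses = 0L, age = 1L, lastBox = box)
}

#' Decay a coasting track's score
#'
#' Multiplies the track score by the configured decay factor and increments
#' its consecutive-miss counter. Applied once per unmatched frame.
#'
#' @param track a live track (as held inside a tracker).
#' @param config a [TrackerConfig-class].
#' @return the decayed track.
#' @export
decayScore <- function(track, config = trackerConfig()) {
  track$score <- track$score * config@decayFactor
  track$misses <- track$misses + 1L
  track
}

#' Run one cascade stage on the yet-unmatched tracks and detections
#'
#' Restricts the cost computation and Hungarian solve to tracks and
#' detections not claimed by earlier stages, then maps the stage-local pair
#' indices back to the full index space.
#'
#' @param stage one of "motion", "iou", "distance".
#' @param states list of predicted `kalmanState`s for all live tracks.
#' @param detBoxes m x 4 matrix of all detection boxes this frame.
#' @param matchedTracks,matchedDetections integer indices already matched by
#'   earlier stages.
#' @param config a [TrackerConfig-class].
#' @return k x 2 matrix of (track, detection) indices in the full index space;
#'   every returned pair satisfies the stage's gate.
#' @export
matchStage <- function(stage, states, detBoxes, matchedTracks,
                       matchedDetections, config = trackerConfig()) {
  freeT <- setdiff(seq_along(states), matchedTracks)
  m <- if (is.matrix(detBoxes)) nrow(detBoxes) else 0L
  freeD <- setdiff(seq_len(m), matchedDetections)
  empty <- matrix(integer(0), 0, 2,
                  dimnames = list(NULL, c("track", "detection")))
  if (!length(freeT) || !length(freeD)) return(empty)
  costs <- buildCostMatrix(stage, states[freeT],
                           detBoxes[freeD, , drop = FALSE], config)
  ms <- solveAssignment(costs)
  if (!nrow(ms$pairs)) return(empty)
  cbind(track = freeT[ms$pairs[, 1]], detection = freeD[ms$pairs[, 2]])
}

#' Advance the tracker by one frame
#'
#' Implements the per-frame step of the cascade tracker: all live tracks are
#' predicted one frame; the association cascade runs motion, IoU, then
#' distance stages over progressively fewer unmatched pairs; matched tracks
#' are Kalman-updated with their detection (score reset to the detection
#' score, miss counter cleared); unmatched detections scoring above
#' `thetaNew` spawn new tracks; unmatched tracks coast with decayed score and
#' are purged once their consecutive misses exceed `maxAge`. Matched and
#' newborn tracks report the detection box; coasting tracks report the
#' predicted box and are flagged `coasted`.
#'
#' Detections scoring below `preThresh` are discarded on ingest; boxes with
#' non-finite coordinates are rejected with a warning.
#'
#' @param tracker tracker state from [newTracker()] or a previous step.
#' @param detections data.frame with columns left, top, width, height, score
#'   (rows for one frame), or NULL/empty for a frame with no detections.
#' @param frame 1-based frame index, strictly greater than the previous
#'   frame's.
#' @return list with `tracker` (updated state) and `records` (data.frame
#'   frame, id, left, top, width, height, score, coasted).
#' @export
trackStep <- function(tracker, detections, frame) {
  config <- tracker$config
  frame <- as.integer(frame)
  if (frame <= tracker$lastFrame) {
    stop(sprintf("frames must be strictly increasing: got %d after %d",
                 frame, tracker$lastFrame))
  }
  if (is.null(detections) || !nrow(detections)) {
    detections <- data.frame(left = numeric(), top = numeric(),
                             width = numeric(), height = numeric(),
                             score = numeric())
  }
  boxes <- as.matrix(detections[, c("left", "top", "width", "height")])
  ok <- validBoxes(boxes)
  if (any(!ok)) {
    warning(sprintf("frame %d: %d detection(s) with non-finite or degenerate box rejected",
                    frame, sum(!ok)))
  }
  keep <- ok & detections$score >= config@preThresh
  boxes <- boxes[keep, , drop = FALSE]
  scores <- detections$score[keep]
  m <- nrow(boxes)

  # (i) predict all live tracks
  tracks <- lapply(tracker$tracks, function(tr) {
    tr$state <- kfPredict(tr$state, config@posNoiseWeight, config@velNoiseWeight)
    tr$age <- tr$age + 1L
    tr
  })
  states <- lapply(tracks, `[[`, "state")

  # (ii) cascade: motion -> iou -> distance over yet-unmatched pairs
  matchedT <- integer(0)
  matchedD <- integer(0)
  allPairs <- matrix(integer(0), 0, 2)
  for (stage in c("motion", "iou", "distance")) {
    pr <- matchStage(stage, states, boxes, matchedT, matchedD, config)
    if (nrow(pr)) {
      allPairs <- rbind(allPairs, pr)
      matchedT <- c(matchedT, pr[, 1])
      matchedD <- c(matchedD, pr[, 2])
    }
  }

  rec <- list()
  # (iii) matched tracks: update, reset misses, adopt detection score/box
  if (nrow(allPairs)) {
    for (k in seq_len(nrow(allPairs))) {
      i <- allPairs[k, 1]; j <- allPairs[k, 2]
      tr <- tracks[[i]]
      tr$state <- kfUpdate(tr$state, boxes[j, ], config@posNoiseWeight)
      tr$score <- scores[j]
      tr$misses <- 0L
      tr$lastBox <- boxes[j, ]
      tracks[[i]] <- tr
      rec[[length(rec) + 1L]] <- c(tr$id, boxes[j, ], scores[j], 0)
    }
  }

  # (iv) unmatched confident detections spawn new tracks
  nextId <- tracker$nextId
  for (j in setdiff(seq_len(m), matchedD)) {
    if (scores[j] > config@thetaNew) {
      tr <- newTrack(nextId, boxes[j, ], scores[j], config)
      nextId <- nextId + 1L
      tracks[[length(tracks) + 1L]] <- tr
      rec[[length(rec) + 1L]] <- c(tr$id, boxes[j, ], scores[j], 0)
    }
  }

  # (v) unmatched tracks coast with decayed score or are purged
  drop <- integer(0)
  for (i in setdiff(seq_along(states), matchedT)) {
    tr <- decayScore(tracks[[i]], config)
    if (tr$misses > config@maxAge) {
      drop <- c(drop, i)
    } else {
      tr$lastBox <- kfStateBox(tr$state)
      tracks[[i]] <- tr
      rec[[length(rec) + 1L]] <- c(tr$id, tr$lastBox, tr$score, 1)
    }
  }
  if (length(drop)) tracks <- tracks[-drop]

  records <- if (length(rec)) {
    rm <- do.call(rbind, rec)
    data.frame(frame = frame, id = as.integer(rm[, 1]), left = rm[, 2],
               top = rm[, 3], width = rm[, 4], height = rm[, 5],
               score = rm[, 6], coasted = rm[, 7] == 1)
  } else {
    data.frame(frame = integer(), id = integer(), left = numeric(),
               top = numeric(), width = numeric(), height = numeric(),
               score = numeric(), coasted = logical())
  }
  if (nrow(records)) records <- records[order(records$id), , drop = FALSE]
  rownames(records) <- NULL
  list(tracker = list(tracks = tracks, nextId = nextId, lastFrame = frame,
                      config = config),
       records = records)
}

#' Track a whole detection sequence
#'
#' Loops [trackStep()] over a detection table, visiting every frame in the
#' covered range (frames without detections still advance the tracker so
#' coasting and purging behave correctly). Deterministic: the same input and
#' configuration always produce identical output.
#'
#' @param detections data.frame with columns frame, left, top, width, height,
#'   score (e.g. from [readDetections()]).
#' @param config a [TrackerConfig-class].
#' @param frames frame range to process; defaults to
#'   `min(frame):max(frame)` of the detections.
#' @return data.frame of per-frame records (frame, id, left, top, width,
#'   height, score, coasted) for all frames.
#' @export
trackSequence <- function(detections, config = trackerConfig(), frames = NULL) {
  if (is.null(frames)) {
    if (!nrow(detections)) return(data.frame(
      frame = integer(), id = integer(), left = numeric(), top = numeric(),
      width = numeric(), height = numeric(), score = numeric(),
      coasted = logical()))
    frames <- seq(min(detections$frame), max(detections$frame))
  }
  perFrame <- splitByFrame(detections, frames)
  tracker <- newTracker(config)
  out <- vector("list", length(frames))
  for (k in seq_along(frames)) {
    st <- trackStep(tracker, perFrame[[k]], frames[k])
    tracker <- st$tracker
    out[[k]] <- st$records
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
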