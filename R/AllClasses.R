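#' @import methods
#' @importFrom stats qchisq rnorm runif rpois
#' @importFrom utils packageVersion
#' @useDynLib FishMOT, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

#' Tracker configuration
#'
#' Holds every tunable of the cascade tracker: birth/ingest score thresholds,
#' coasting lifetime, per-frame score decay, the three association-stage gates,
#' and the Kalman noise weights. All values are plain numbers so a
#' configuration can round-trip through YAML.
#'
#' @slot thetaNew score threshold above which an unmatched detection spawns a
#'   new track (the detector's track threshold).
#' @slot preThresh minimum detection score ingested at all; lower-scoring
#'   boxes are discarded before any association.
#' @slot maxAge maximum number of consecutive unmatched frames a track may
#'   coast; a track whose miss count exceeds `maxAge` is purged.
#' @slot decayFactor per-frame multiplicative score decay applied while a
#'   track coasts, in (0, 1].
#' @slot motionGate squared-Mahalanobis gate for the motion stage; default is
#'   the chi-square 95th percentile with 4 degrees of freedom.
#' @slot iouGate minimum IoU for a feasible pair in the IoU stage.
#' @slot distGateFactor centroid-distance gate expressed as a multiple of the
#'   mean of the two boxes' diagonals.
#' @slot posNoiseWeight Kalman position/size noise std as a fraction of box
#'   height.
#' @slot velNoiseWeight Kalman velocity noise std as a fraction of box height.
#' @slot suppressCoasted logical; drop coasted (propagated, unmatched) records
#'   when writing result files.
#' @seealso [trackerConfig()]
#' @export
setClass("TrackerConfig",
  representation(
    thetaNew = "numeric",
    preThresh = "numeric",
    maxAge = "integer",
    decayFactor = "numeric",
    motionGate = "numeric",
    iouGate = "numeric",
    distGateFactor = "numeric",
    posNoiseWeight = "numeric",
    velNoiseWeight = "numeric",
    suppressCoasted = "logical"
  )
)

setValidity("TrackerConfig", function(object) {
  msg <- character()
  if (object@thetaNew < 0 || object@thetaNew > 1)
    msg <- c(msg, "thetaNew must lie in [0, 1]")
  if (object@preThresh < 0 || object@preThresh > 1)
    msg <- c(msg, "preThresh must lie in [0, 1]")
  if (object@maxAge < 0L) msg <- c(msg, "maxAge must be >= 0")
  if (object@decayFactor <= 0 || object@decayFactor > 1)
    msg <- c(msg, "decayFactor must lie in (0, 1]")
  if (object@motionGate <= 0) msg <- c(msg, "motionGate must be positive")
  if (object@iouGate < 0 || object@iouGate > 1)
    msg <- c(msg, "iouGate must lie in [0, 1]")
  if (object@distGateFactor <= 0)
    msg <- c(msg, "distGateFactor must be positive")
  if (object@posNoiseWeight <= 0 || object@velNoiseWeight <= 0)
    msg <- c(msg, "noise weights must be positive")
  if (length(msg)) msg else TRUE
})

#' Create a tracker configuration
#'
#' Defaults follow the published operating point of the cascade tracker:
#' birth and ingest thresholds of 0.4 and purging of tracks unmatched for
#' more than 3 consecutive frames. The stage gates (chi-square 95% motion
#' gate, loose IoU gate tolerant of swimming deformation, diagonal-scaled
#' distance gate) and the noise weights are field-standard defaults, all
#' overridable here or from a YAML file via [loadTrackerConfig()].
#'
#' @param thetaNew,preThresh,maxAge,decayFactor,motionGate,iouGate,distGateFactor,posNoiseWeight,velNoiseWeight,suppressCoasted
#'   see the corresponding [TrackerConfig-class] slots.
#' @return a validated [TrackerConfig-class] object.
#' @examples
#' cfg <- trackerConfig(maxAge = 5L)
#' cfg
#' @export
trackerConfig <- function(thetaNew = 0.4,
                          preThresh = 0.4,
                          maxAge = 3L,
                          decayFactor = 0.9,
                          motionGate = stats::qchisq(0.95, df = 4),
                          iouGate = 0.1,
                          distGateFactor = 1.0,
                          posNoiseWeight = 1 / 20,
                          velNoiseWeight = 1 / 160,
                          suppressCoasted = TRUE) {
  new("TrackerConfig",
    thetaNew = as.numeric(thetaNew),
    preThresh = as.numeric(preThresh),
    maxAge = as.integer(maxAge),
    decayFactor = as.numeric(decayFactor),
    motionGate = as.numeric(motionGate),
    iouGate = as.numeric(iouGate),
    distGateFactor = as.numeric(distGateFactor),
    posNoiseWeight = as.numeric(posNoiseWeight),
    velNoiseWeight = as.numeric(velNoiseWeight),
    suppressCoasted = isTRUE(suppressCoasted)
  )
}

setMethod("show", "TrackerConfig", function(object) {
  cat("TrackerConfig\n")
  cat(sprintf("  birth threshold (thetaNew): %.3g   ingest floor (preThresh): %.3g\n",
    object@thetaNew, object@preThresh))
  cat(sprintf("  maxAge: %d frames   score decay: %.3g\n",
    object@maxAge, object@decayFactor))
  cat(sprintf("  gates: motion d2 <= %.4f, IoU >= %.3g, dist <= %.3g x mean diagonal\n",
    object@motionGate, object@iouGate, object@distGateFactor))
  cat(sprintf("  Kalman noise weights: pos %.4g, vel %.4g (x box height)\n",
    object@posNoiseWeight, object@velNoiseWeight))
  cat(sprintf("  suppress coasted output: %s\n", object@suppressCoasted))
  invisible(NULL)
})

#' Simulation configuration
#'
#' Parameters of the fish-school simulator: arena geometry, school size and
#' clip length, individual kinematics (body length, cruise speed in body
#' lengths per second, turn-rate cap), the zonal schooling interaction radii,
#' tail-beat box deformation, and the detection-corruption model (coordinate
#' jitter, random dropout, occlusion-conditional dropout, clutter, score
#' model).
#'
#' @slot nFish number of fish in the school.
#' @slot arenaWidth,arenaHeight arena size in pixels.
#' @slot fps recording frame rate (frames per second).
#' @slot nFrames clip length in frames.
#' @slot bodyLengthRange min/max fish body length in pixels.
#' @slot speedRange min/max cruise speed in body lengths per second.
#' @slot turnRateMax maximum heading change per frame, radians.
#' @slot headingNoiseSd per-frame heading noise std, radians.
#' @slot schoolingStrength 0 disables neighbour interactions; 1 is strong
#'   schooling.
#' @slot tailBeatAmp relative amplitude of the sinusoidal box-aspect
#'   modulation emulating tail beats.
#' @slot tailBeatFreqRange min/max tail-beat frequency, Hz.
#' @slot allowExit logical; when TRUE fish that swim fully out of frame are
#'   marked exited and produce no further ground-truth boxes.
#' @slot jitterSd Gaussian std (pixels) added independently to each box edge.
#' @slot dropProb base per-box detection dropout probability.
#' @slot occlusionIouThreshold pairwise IoU above which the smaller box is
#'   considered occluded.
#' @slot occlusionDropProb probability that an occluded box is dropped.
#' @slot clutterRate Poisson mean of false-positive clutter boxes per frame.
#' @slot scoreBase,scoreJitterPenalty,scoreOverlapPenalty detection-score
#'   model: `scoreBase - scoreJitterPenalty * relativeJitter -
#'   scoreOverlapPenalty * maxIoU`, clipped to \[0, 1\].
#' @slot seed integer seed making the scene fully reproducible.
#' @seealso [simConfig()], [simPreset()]
#' @export
setClass("SimConfig",
  representation(
    nFish = "integer",
    arenaWidth = "numeric",
    arenaHeight = "numeric",
    fps = "numeric",
    nFrames = "integer",
    bodyLengthRange = "numeric",
    speedRange = "numeric",
    turnRateMax = "numeric",
    headingNoiseSd = "numeric",
    schoolingStrength = "numeric",
    tailBeatAmp = "numeric",
    tailBeatFreqRange = "numeric",
    allowExit = "logical",
    jitterSd = "numeric",
    dropProb = "numeric",
    occlusionIouThreshold = "numeric",
    occlusionDropProb = "numeric",
    clutterRate = "numeric",
    scoreBase = "numeric",
    scoreJitterPenalty = "numeric",
    scoreOverlapPenalty = "numeric",
    seed = "integer"
  )
)

setValidity("SimConfig", function(object) {
  msg <- character()
  if (object@nFish < 1L) msg <- c(msg, "nFish must be >= 1")
  if (object@arenaWidth <= 0 || object@arenaHeight <= 0)
    msg <- c(msg, "arena dimensions must be positive")
  if (object@nFrames < 1L) msg <- c(msg, "nFrames must be >= 1")
  if (length(object@bodyLengthRange) != 2L ||
      any(object@bodyLengthRange <= 0) ||
      diff(object@bodyLengthRange) < 0)
    msg <- c(msg, "bodyLengthRange must be two positive non-decreasing values")
  if (length(object@speedRange) != 2L || any(object@speedRange < 0) ||
      diff(object@speedRange) < 0)
    msg <- c(msg, "speedRange must be two non-negative non-decreasing values")
  probs <- c(object@dropProb, object@occlusionDropProb,
             object@occlusionIouThreshold, object@scoreBase)
  if (any(probs < 0) || any(probs > 1))
    msg <- c(msg, "probabilities and scoreBase must lie in [0, 1]")
  if (object@clutterRate < 0) msg <- c(msg, "clutterRate must be >= 0")
  if (object@jitterSd < 0) msg <- c(msg, "jitterSd must be >= 0")
  if (object@schoolingStrength < 0 || object@schoolingStrength > 1)
    msg <- c(msg, "schoolingStrength must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Create a simulation configuration
#'
#' Defaults emulate the recording geometry of a dense aquaculture tank clip:
#' 75 fish in a 1920 x 1080 px arena at 30 FPS over 25 frames, body lengths
#' of 40-160 px (8-25 cm fish at a declared cm-to-pixel convenience mapping),
#' cruise speeds of 1-3 body lengths per second. The corruption channel is
#' off by default (ground truth passes through unchanged); use [simPreset()]
#' for corrupted-scene archetypes.
#'
#' @param nFish,arenaWidth,arenaHeight,fps,nFrames,bodyLengthRange,speedRange,turnRateMax,headingNoiseSd,schoolingStrength,tailBeatAmp,tailBeatFreqRange,allowExit,jitterSd,dropProb,occlusionIouThreshold,occlusionDropProb,clutterRate,scoreBase,scoreJitterPenalty,scoreOverlapPenalty,seed
#'   see the corresponding [SimConfig-class] slots.
#' @return a validated [SimConfig-class] object.
#' @examples
#' cfg <- simConfig(nFish = 10L, nFrames = 50L, seed = 7L)
#' @export
simConfig <- function(nFish = 75L,
                      arenaWidth = 1920,
                      arenaHeight = 1080,
                      fps = 30,
                      nFrames = 25L,
                      bodyLengthRange = c(40, 160),
                      speedRange = c(1, 3),
                      turnRateMax = 0.3,
                      headingNoiseSd = 0.08,
                      schoolingStrength = 0.5,
                      tailBeatAmp = 0.15,
                      tailBeatFreqRange = c(2, 4),
                      allowExit = FALSE,
                      jitterSd = 0,
                      dropProb = 0,
                      occlusionIouThreshold = 0.3,
                      occlusionDropProb = 0,
                      clutterRate = 0,
                      scoreBase = 1,
                      scoreJitterPenalty = 0.5,
                      scoreOverlapPenalty = 0.2,
                      seed = 1L) {
  new("SimConfig",
    nFish = as.integer(nFish),
    arenaWidth = as.numeric(arenaWidth),
    arenaHeight = as.numeric(arenaHeight),
    fps = as.numeric(fps),
    nFrames = as.integer(nFrames),
    bodyLengthRange = as.numeric(bodyLengthRange),
    speedRange = as.numeric(speedRange),
    turnRateMax = as.numeric(turnRateMax),
    headingNoiseSd = as.numeric(headingNoiseSd),
    schoolingStrength = as.numeric(schoolingStrength),
    tailBeatAmp = as.numeric(tailBeatAmp),
    tailBeatFreqRange = as.numeric(tailBeatFreqRange),
    allowExit = isTRUE(allowExit),
    jitterSd = as.numeric(jitterSd),
    dropProb = as.numeric(dropProb),
    occlusionIouThreshold = as.numeric(occlusionIouThreshold),
    occlusionDropProb = as.numeric(occlusionDropProb),
    clutterRate = as.numeric(clutterRate),
    scoreBase = as.numeric(scoreBase),
    scoreJitterPenalty = as.numeric(scoreJitterPenalty),
    scoreOverlapPenalty = as.numeric(scoreOverlapPenalty),
    seed = as.integer(seed)
  )
}

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig\n")
  cat(sprintf("  %d fish, %g x %g px arena, %g FPS, %d frames, seed %d\n",
    object@nFish, object@arenaWidth, object@arenaHeight, object@fps,
    object@nFrames, object@seed))
  cat(sprintf("  body length %g-%g px, speed %g-%g BL/s, schooling %.2g\n",
    object@bodyLengthRange[1], object@bodyLengthRange[2],
    object@speedRange[1], object@speedRange[2], object@schoolingStrength))
  cat(sprintf("  corruption: jitter sd %g px, dropout %g, occlusion drop %g (IoU > %g), clutter %g/frame\n",
    object@jitterSd, object@dropProb, object@occlusionDropProb,
    object@occlusionIouThreshold, object@clutterRate))
  invisible(NULL)
})

#' Simulated scene container
#'
#' Bundles the ground-truth trajectory table, the corrupted detection stream
#' derived from it, an event log (occlusion drops, random drops, clutter,
#' exits) and the generating [SimConfig-class]. Tables are plain data.frames
#' in the package's internal 0-based continuous coordinates.
#'
#' @slot gt data.frame with columns frame, id, left, top, width, height.
#' @slot detections data.frame with columns frame, left, top, width, height,
#'   score, sourceId (NA for clutter).
#' @slot events data.frame with columns frame, type, id, otherId.
#' @slot config the generating [SimConfig-class].
#' @seealso [makeScene()], [gtTable()], [detTable()], [sceneEvents()]
#' @export
setClass("SimScene",
  representation(
    gt = "data.frame",
    detections = "data.frame",
    events = "data.frame",
    config = "SimConfig"
  )
)

setValidity("SimScene", function(object) {
  msg <- character()
  need <- c("frame", "id", "left", "top", "width", "height")
  if (!all(need %in% names(object@gt)))
    msg <- c(msg, "gt must have frame/id/left/top/width/height columns")
  if (nrow(object@gt) && anyDuplicated(object@gt[, c("frame", "id")]))
    msg <- c(msg, "gt holds more than one box for some (frame, id)")
  if (nrow(object@detections) &&
      !all(c("frame", "score") %in% names(object@detections)))
    msg <- c(msg, "detections must carry frame and score columns")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SimScene", function(object) {
  cat("SimScene\n")
  cat(sprintf("  ground truth: %d boxes, %d trajectories, frames %d-%d\n",
    nrow(object@gt), length(unique(object@gt$id)),
    min(object@gt$frame), max(object@gt$frame)))
  nclut <- if (nrow(object@detections)) sum(is.na(object@detections$sourceId)) else 0L
  cat(sprintf("  detections: %d (%d clutter)\n", nrow(object@detections), nclut))
  cat(sprintf("  events logged: %d\n", nrow(object@events)))
  invisible(NULL)
})

#' @describeIn SimScene-class ground-truth trajectory table.
#' @param scene a [SimScene-class].
#' @export
gtTable <- function(scene) {
  stopifnot(is(scene, "SimScene"))
  scene@gt
}

#' @describeIn SimScene-class corrupted detection table.
#' @export
detTable <- function(scene) {
  stopifnot(is(scene, "SimScene"))
  scene@detections
}

#' @describeIn SimScene-class corruption event log.
#' @export
sceneEvents <- function(scene) {
  stopifnot(is(scene, "SimScene"))
  scene@events
}

#' @describeIn SimScene-class generating configuration.
#' @export
sceneConfig <- function(scene) {
  stopifnot(is(scene, "SimScene"))
  scene@config
}

#' Adaptive loss weights
#'
#' The focal/Dice weight pair (alpha, beta) plus the overall occlusion-loss
#' weight. `alpha + beta == 1` and both are floored at 1e-8 after any
#' adaptive update.
#'
#' @slot alpha focal-loss weight, in (0, 1).
#' @slot beta Dice-loss weight, in (0, 1).
#' @slot wBase overall occlusion-loss weight, positive.
#' @seealso [lossWeights()], [adaptWeights()], [totalLoss()]
#' @export
setClass("LossWeights",
  representation(alpha = "numeric", beta = "numeric", wBase = "numeric")
)

setValidity("LossWeights", function(object) {
  msg <- character()
  if (object@alpha <= 0 || object@beta <= 0)
    msg <- c(msg, "alpha and beta must be positive")
  if (abs(object@alpha + object@beta - 1) > 1e-9)
    msg <- c(msg, "alpha + beta must equal 1")
  if (object@wBase <= 0) msg <- c(msg, "wBase must be positive")
  if (length(msg)) msg else TRUE
})

#' Create a loss-weight object
#'
#' @param alpha focal-loss weight (beta is `1 - alpha`).
#' @param wBase overall occlusion-loss weight.
#' @return a validated [LossWeights-class].
#' @examples
#' lossWeights()
#' @export
lossWeights <- function(alpha = 0.5, wBase = 1) {
  new("LossWeights", alpha = as.numeric(alpha),
      beta = 1 - as.numeric(alpha), wBase = as.numeric(wBase))
}

setMethod("show", "LossWeights", function(object) {
  cat(sprintf("LossWeights: alpha = %.6g, beta = %.6g, wBase = %.6g\n",
    object@alpha, object@beta, object@wBase))
  invisible(NULL)
})

#' Tracking evaluation report
#'
#' The full metric suite computed by [evaluateTracking()]: CLEAR counts and
#' scores (MOTA, MOTP, FP, FN, IDSW), identity metrics after global
#' trajectory matching (IDF1, IDP, IDR and the IDTP/IDFP/IDFN counts),
#' trajectory-coverage fractions (MT, ML), and single-threshold HOTA with its
#' DetA/AssA decomposition.
#'
#' @slot metrics named numeric vector of all scalar metrics.
#' @slot counts named numeric vector of the underlying tallies.
#' @slot coverage per-ground-truth-trajectory tracked fraction of lifespan.
#' @slot iouThreshold localization threshold used throughout.
#' @slot schemaVersion report schema version string.
#' @seealso [evaluateTracking()], [writeReport()]
#' @export
setClass("MetricReport",
  representation(
    metrics = "numeric",
    counts = "numeric",
    coverage = "numeric",
    iouThreshold = "numeric",
    schemaVersion = "character"
  )
)

setMethod("show", "MetricReport", function(object) {
  m <- object@metrics
  cat(sprintf("MetricReport (IoU threshold %.2f)\n", object@iouThreshold))
  cat(sprintf("  MOTA %.4f  MOTP %.4f  IDSW %d  FP %d  FN %d\n",
    m[["MOTA"]], m[["MOTP"]], as.integer(object@counts[["IDSW"]]),
    as.integer(object@counts[["FP"]]), as.integer(object@counts[["FN"]])))
  cat(sprintf("  IDF1 %.4f  IDP %.4f  IDR %.4f\n",
    m[["IDF1"]], m[["IDP"]], m[["IDR"]]))
  cat(sprintf("  HOTA %.4f  DetA %.4f  AssA %.4f\n",
    m[["HOTA"]], m[["DetA"]], m[["AssA"]]))
  cat(sprintf("  MT %.4f  ML %.4f  (%d gt trajectories)\n",
    m[["MT"]], m[["ML"]], length(object@coverage)))
  invisible(NULL)
})

#' @describeIn MetricReport-class named vector of scalar metrics.
#' @param report a [MetricReport-class].
#' @export
reportMetrics <- function(report) {
  stopifnot(is(report, "MetricReport"))
  report@metrics
}

#' @describeIn MetricReport-class named vector of underlying tallies.
#' @export
reportCounts <- function(report) {
  stopifnot(is(report, "MetricReport"))
  report@counts
}
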