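# Stage-specific cost matrices and optimal assignment. Infeasible cells are
# masked with a large constant before the Hungarian solve and filtered from
# the returned pairs, so an infeasible pair is never reported as a match.

BIG_COST <- 1e12

#' Build a stage cost matrix
#'
#' Computes the tracks x detections cost matrix and feasibility mask for one
#' cascade stage:
#' \describe{
#'   \item{motion}{cost is the squared Mahalanobis gating distance of each
#'     detection under each track's predicted state; feasible while
#'     `d^2 <= motionGate` (chi-square 95%, 4 dof by default).}
#'   \item{iou}{cost is `1 - IoU` between the predicted state box and the
#'     detection box; feasible while `IoU >= iouGate`. Deliberately loose to
#'     tolerate the non-rigid deformation of swimming fish.}
#'   \item{distance}{cost is the Euclidean distance between the predicted
#'     centroid and the detection centroid; feasible while the distance is at
#'     most `distGateFactor` times the mean of the two boxes' diagonals.}
#' }
#'
#' @param stage one of "motion", "iou", "distance".
#' @param states list of predicted `kalmanState`s, one per track.
#' @param detBoxes m x 4 matrix of detection boxes.
#' @param config a [TrackerConfig-class].
#' @return list with `values` (n x m numeric) and `feasible` (n x m logical).
#' @export
buildCostMatrix <- function(stage, states, detBoxes, config = trackerConfig()) {
  stage <- match.arg(stage, c("motion", "iou", "distance"))
  n <- length(states)
  detBoxes <- if (is.null(detBoxes) || (is.matrix(detBoxes) && nrow(detBoxes) == 0)) {
    matrix(numeric(0), 0, 4)
  } else asBoxMatrix(detBoxes)
  m <- nrow(detBoxes)
  values <- matrix(0, n, m)
  feasible <- matrix(FALSE, n, m)
  if (n == 0 || m == 0) return(list(values = values, feasible = feasible))
  trackBoxes <- t(vapply(states, kfStateBox, numeric(4)))
  if (stage == "motion") {
    for (i in seq_len(n)) {
      d2 <- kfGatingDistance(states[[i]], detBoxes,
                             posWeight = config@posNoiseWeight)
      values[i, ] <- d2
      feasible[i, ] <- d2 <= config@motionGate
    }
  } else if (stage == "iou") {
    iou <- iouMatrix(trackBoxes, detBoxes)
    values <- 1 - iou
    feasible <- iou >= config@iouGate
  } else {
    tc <- boxCenters(trackBoxes)
    dc <- boxCenters(detBoxes)
    values <- sqrt(outer(tc[, 1], dc[, 1], "-")^2 +
                   outer(tc[, 2], dc[, 2], "-")^2)
    gate <- config@distGateFactor *
      outer(boxDiagonals(trackBoxes), boxDiagonals(detBoxes), "+") / 2
    feasible <- values <= gate
  }
  list(values = values, feasible = feasible)
}

#' Solve a masked linear assignment problem
#'
#' Minimum-total-cost one-to-one assignment over the feasible cells of a cost
#' matrix (Hungarian algorithm; infeasible cells can never enter the returned
#' match set). Among assignments the solver first maximises the number of
#' feasible matches, then minimises their total cost. Empty matrices in either
#' dimension yield an empty match set.
#'
#' @param costs list with `values` and `feasible` as returned by
#'   [buildCostMatrix()], or a plain numeric matrix (all cells feasible).
#' @return a match set: list with `pairs` (k x 2 matrix of track, detection
#'   indices), `unmatchedTracks`, `unmatchedDetections`.
#' @examples
#' solveAssignment(matrix(c(1, 2, 2, 1), 2, byrow = TRUE))$pairs
#' @export
solveAssignment <- function(costs) {
  if (is.matrix(costs)) costs <- list(values = costs,
                                      feasible = matrix(TRUE, nrow(costs), ncol(costs)))
  values <- costs$values
  feasible <- costs$feasible
  n <- nrow(values); m <- ncol(values)
  emptyPairs <- matrix(integer(0), 0, 2,
                       dimnames = list(NULL, c("track", "detection")))
  if (n == 0 || m == 0 || !any(feasible)) {
    return(list(pairs = emptyPairs, unmatchedTracks = seq_len(n),
                unmatchedDetections = seq_len(m)))
  }
  if (any(!is.finite(values[feasible]))) stop("feasible costs must be finite")
  work <- values
  work[!feasible] <- BIG_COST
  transposed <- n > m
  if (transposed) work <- t(work)
  assign <- hungarian_solve(work)
  rows <- which(assign > 0L)
  cols <- assign[rows]
  if (transposed) { tmp <- rows; rows <- cols; cols <- tmp }
  keep <- feasible[cbind(rows, cols)]
  pairs <- cbind(track = rows[keep], detection = cols[keep])
  o <- order(pairs[, 1])
  pairs <- pairs[o, , drop = FALSE]
  list(pairs = pairs,
       unmatchedTracks = setdiff(seq_len(n), pairs[, 1]),
       unmatchedDetections = setdiff(seq_len(m), pairs[, 2]))
}
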