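# Constant-velocity Kalman filter over box centre, aspect ratio and height.
# State: (cx, cy, a, h, vcx, vcy, va, vh); measurement: (cx, cy, a, h).
# Noise standard deviations scale with box height h, the established
# tracking-by-detection convention, so the filter is scale-aware.

KF_DIM <- 8L
KF_MEAS <- 4L

kfTransition <- function() {
  f <- diag(KF_DIM)
  f[cbind(1:4, 5:8)] <- 1
  f
}

kfMeasurementMatrix <- function() {
  h <- matrix(0, KF_MEAS, KF_DIM)
  h[cbind(1:4, 1:4)] <- 1
  h
}

boxToMeasurement <- function(box) {
  b <- asBoxMatrix(box)
  cbind(b[, 1] + b[, 3] / 2, b[, 2] + b[, 4] / 2, b[, 3] / b[, 4], b[, 4])
}

measurementToBox <- function(z) {
  w <- z[3] * z[4]
  c(z[1] - w / 2, z[2] - z[4] / 2, w, z[4])
}

symmetrize <- function(m) (m + t(m)) / 2

#' Initialise a Kalman track state from a box
#'
#' Positions are set to the box centre, aspect ratio and height; velocities
#' to zero. The initial covariance is diagonal with standard deviations
#' proportional to the box height (aspect components use small constants),
#' reflecting full uncertainty about velocity.
#'
#' @param box a `(left, top, width, height)` box.
#' @param posWeight position noise std as a fraction of height.
#' @param velWeight velocity noise std as a fraction of height.
#' @return a `kalmanState`: list with `mean` (length 8) and `cov` (8 x 8).
#' @examples
#' s <- kfInit(c(0, 0, 10, 20))
#' s$mean[1:4] # 5 10 0.5 20
#' @export
kfInit <- function(box, posWeight = 1 / 20, velWeight = 1 / 160) {
  if (!all(validBoxes(box))) stop("degenerate box: width and height must be positive and finite")
  z <- drop(boxToMeasurement(box))
  h <- z[4]
  std <- c(2 * posWeight * h, 2 * posWeight * h, 1e-2, 2 * posWeight * h,
           10 * velWeight * h, 10 * velWeight * h, 1e-5, 10 * velWeight * h)
  structure(list(mean = c(z, rep(0, 4)), cov = diag(std^2)),
            class = "kalmanState")
}

#' Advance a Kalman state one frame
#'
#' Applies the constant-velocity transition (time step of one frame) and
#' inflates the covariance with process noise scaled by the current height.
#'
#' @param state a `kalmanState` from [kfInit()].
#' @inheritParams kfInit
#' @return the predicted `kalmanState`.
#' @export
kfPredict <- function(state, posWeight = 1 / 20, velWeight = 1 / 160) {
  f <- kfTransition()
  h <- state$mean[4]
  std <- c(posWeight * h, posWeight * h, 1e-2, posWeight * h,
           velWeight * h, velWeight * h, 1e-5, velWeight * h)
  mean <- drop(f %*% state$mean)
  cov <- symmetrize(f %*% state$cov %*% t(f) + diag(std^2))
  structure(list(mean = mean, cov = cov), class = "kalmanState")
}

kfMeasurementNoise <- function(h, posWeight = 1 / 20) {
  std <- c(posWeight * h, posWeight * h, 1e-1, posWeight * h)
  diag(std^2)
}

kfProject <- function(state, posWeight = 1 / 20, measCov = NULL) {
  hm <- kfMeasurementMatrix()
  if (is.null(measCov)) measCov <- kfMeasurementNoise(state$mean[4], posWeight)
  zhat <- drop(hm %*% state$mean)
  s <- symmetrize(hm %*% state$cov %*% t(hm) + measCov)
  list(zhat = zhat, s = s, hm = hm, measCov = measCov)
}

#' Kalman measurement update
#'
#' Standard correction of the state against a box measurement
#' `(cx, cy, a, h)` using the Joseph-form covariance update, which keeps the
#' posterior covariance symmetric positive-semidefinite.
#'
#' @param state a `kalmanState`.
#' @param box the matched detection box.
#' @param posWeight measurement noise std as a fraction of height.
#' @param measCov optional explicit 4 x 4 measurement covariance, overriding
#'   the height-scaled default (useful for calibration and testing).
#' @return the posterior `kalmanState`.
#' @export
kfUpdate <- function(state, box, posWeight = 1 / 20, measCov = NULL) {
  if (!all(validBoxes(box))) stop("degenerate box: width and height must be positive and finite")
  z <- drop(boxToMeasurement(box))
  pr <- kfProject(state, posWeight, measCov)
  ch <- tryCatch(chol(pr$s), error = function(e) {
    stop("innovation covariance is not positive definite (collapsed state?): ",
         conditionMessage(e))
  })
  # K = P H' S^{-1}, via the Cholesky factor of S
  k <- t(backsolve(ch, forwardsolve(t(ch), pr$hm %*% state$cov)))
  mean <- state$mean + drop(k %*% (z - pr$zhat))
  ikh <- diag(KF_DIM) - k %*% pr$hm
  cov <- symmetrize(ikh %*% state$cov %*% t(ikh) + k %*% pr$measCov %*% t(k))
  structure(list(mean = mean, cov = cov), class = "kalmanState")
}

#' Squared Mahalanobis gating distance
#'
#' Distance between the state's projected measurement distribution and one or
#' more candidate boxes: `d^2 = (z - zhat)' S^{-1} (z - zhat)` with `S` the
#' innovation covariance. Used by the cascade's motion stage with a
#' chi-square gate (4 degrees of freedom).
#'
#' @param state a `kalmanState` (typically after [kfPredict()]).
#' @param boxes one box or an n x 4 matrix of boxes.
#' @inheritParams kfUpdate
#' @return numeric vector of squared distances, one per box.
#' @export
kfGatingDistance <- function(state, boxes, posWeight = 1 / 20, measCov = NULL) {
  z <- boxToMeasurement(boxes)
  pr <- kfProject(state, posWeight, measCov)
  ch <- tryCatch(chol(pr$s), error = function(e) {
    stop("singular innovation covariance: ", conditionMessage(e))
  })
  diff <- sweep(z, 2, pr$zhat)
  y <- forwardsolve(t(ch), t(diff))
  colSums(y^2)
}

#' Box implied by a Kalman state
#'
#' @param state a `kalmanState`.
#' @return a `(left, top, width, height)` vector.
#' @export
kfStateBox <- function(state) {
  measurementToBox(state$mean[1:4])
}
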