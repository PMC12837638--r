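# Box utilities. Boxes are (left, top, width, height) in continuous 0-based
# pixel coordinates; matrices carry one box per row.

asBoxMatrix <- function(b) {
  if (is.null(dim(b))) b <- matrix(b, nrow = 1)
  b <- as.matrix(b)
  if (ncol(b) != 4) stop("a box needs exactly 4 values: left, top, width, height")
  storage.mode(b) <- "double"
  b
}

boxCenters <- function(b) {
  b <- asBoxMatrix(b)
  cbind(b[, 1] + b[, 3] / 2, b[, 2] + b[, 4] / 2)
}

boxDiagonals <- function(b) {
  b <- asBoxMatrix(b)
  sqrt(b[, 3]^2 + b[, 4]^2)
}

#' Intersection-over-union of two boxes
#'
#' Overlap area divided by union area of two axis-aligned boxes given as
#' `(left, top, width, height)`. Accepts 4-vectors or n x 4 matrices of equal
#' row count (elementwise). Symmetric; 1 for identical boxes, 0 for disjoint
#' ones.
#'
#' @param a,b boxes as 4-vectors or n x 4 matrices.
#' @return numeric vector of IoU values in \[0, 1\].
#' @examples
#' boxIoU(c(0, 0, 10, 10), c(5, 5, 10, 10)) # 1/7
#' @export
boxIoU <- function(a, b) {
  a <- asBoxMatrix(a); b <- asBoxMatrix(b)
  stopifnot(nrow(a) == nrow(b))
  ix <- pmax(0, pmin(a[, 1] + a[, 3], b[, 1] + b[, 3]) - pmax(a[, 1], b[, 1]))
  iy <- pmax(0, pmin(a[, 2] + a[, 4], b[, 2] + b[, 4]) - pmax(a[, 2], b[, 2]))
  inter <- ix * iy
  union <- a[, 3] * a[, 4] + b[, 3] * b[, 4] - inter
  out <- ifelse(union > 0, pmin(inter / union, 1), 0)
  # identical boxes overlap exactly; avoid rounding noise from (l + w) - l
  out[rowSums(a != b) == 0] <- 1
  out
}

#' Pairwise IoU matrix
#'
#' @param a n x 4 box matrix.
#' @param b m x 4 box matrix.
#' @return n x m matrix of IoU values.
#' @export
iouMatrix <- function(a, b) {
  a <- asBoxMatrix(a); b <- asBoxMatrix(b)
  n <- nrow(a); m <- nrow(b)
  if (n == 0 || m == 0) return(matrix(numeric(0), n, m))
  ar <- a[rep(seq_len(n), times = m), , drop = FALSE]
  br <- b[rep(seq_len(m), each = n), , drop = FALSE]
  matrix(boxIoU(ar, br), n, m)
}

#' Euclidean distance between box centroids
#'
#' @param a,b boxes as 4-vectors or equal-row matrices.
#' @return numeric vector of centre distances in pixels.
#' @examples
#' centroidDistance(c(-1.5, -2, 3, 4), c(1.5, 2, 3, 4)) # 5
#' @export
centroidDistance <- function(a, b) {
  ca <- boxCenters(a); cb <- boxCenters(b)
  stopifnot(nrow(ca) == nrow(cb))
  sqrt(rowSums((ca - cb)^2))
}

validBoxes <- function(b) {
  b <- asBoxMatrix(b)
  rowSums(!is.finite(b)) == 0 & b[, 3] > 0 & b[, 4] > 0
}
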