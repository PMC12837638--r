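# MOTChallenge CSV dialects. Files store 1-based pixel coordinates
# "frame,id,bb_left,bb_top,bb_width,bb_height,conf,x,y,z"; internally the
# package works in 0-based continuous coordinates, so left/top are shifted by
# one at the boundary in both directions.

parseMotFile <- function(path, minFields = 7L) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    return(data.frame(frame = integer(), id = numeric(), left = numeric(),
                      top = numeric(), width = numeric(), height = numeric(),
                      conf = numeric()))
  }
  parts <- strsplit(lines, ",", fixed = TRUE)
  nf <- lengths(parts)
  bad <- which(nf < minFields)
  if (length(bad)) {
    stop(sprintf("malformed line %d in %s: expected >= %d comma-separated fields, got %d",
                 bad[1], path, minFields, nf[bad[1]]))
  }
  first7 <- t(vapply(parts, function(p) {
    v <- suppressWarnings(as.numeric(p[1:7]))
    if (length(p) < 7L) v[7] <- 1 # confidence column absent: all rows count
    v
  }, numeric(7)))
  badNum <- which(rowSums(is.na(first7)) > 0)
  if (length(badNum)) {
    stop(sprintf("malformed line %d in %s: non-numeric field", badNum[1], path))
  }
  data.frame(frame = as.integer(first7[, 1]), id = first7[, 2],
             left = first7[, 3] - 1, top = first7[, 4] - 1,
             width = first7[, 5], height = first7[, 6], conf = first7[, 7])
}

#' Read a MOTChallenge detection file
#'
#' Parses the detection dialect (`frame,id,left,top,width,height,conf,...`,
#' id conventionally -1). Coordinates are converted from the file's 1-based
#' convention to the package's 0-based continuous convention. Rows with
#' non-positive width or height are rejected with a warning stating how many
#' were dropped; a malformed line raises an error naming the line number.
#'
#' @param path path to a detection file.
#' @return data.frame with columns frame, left, top, width, height, score,
#'   ordered by frame then file order.
#' @export
readDetections <- function(path) {
  d <- parseMotFile(path)
  keep <- d$width > 0 & d$height > 0
  if (any(!keep)) {
    warning(sprintf("%d detection(s) with non-positive width/height rejected in %s",
                    sum(!keep), path))
    d <- d[keep, , drop = FALSE]
  }
  if (any(d$conf < 0 | d$conf > 1)) {
    stop("detection confidence outside [0, 1] in ", path)
  }
  if (any(d$frame < 1L)) stop("frame indices must be >= 1 in ", path)
  d <- d[order(d$frame), , drop = FALSE]
  out <- data.frame(frame = d$frame, left = d$left, top = d$top,
                    width = d$width, height = d$height, score = d$conf)
  rownames(out) <- NULL
  out
}

#' Read a MOTChallenge ground-truth or result file
#'
#' Parses the ground-truth/result dialect, in which field 2 carries a
#' positive trajectory identity. When the confidence field is present it is
#' treated as a consider flag: rows with `conf == 0` are dropped (MOT gt
#' convention); all other rows count. Duplicate (frame, id) rows raise an
#' integrity error.
#'
#' @param path path to a gt or result file.
#' @return data.frame with columns frame, id, left, top, width, height, score.
#' @export
readGroundTruth <- function(path) {
  d <- parseMotFile(path, minFields = 6L)
  if (any(d$id < 1 | d$id != floor(d$id))) {
    stop("ground-truth identities must be positive integers in ", path)
  }
  d <- d[d$conf != 0, , drop = FALSE]
  keep <- d$width > 0 & d$height > 0
  if (any(!keep)) {
    warning(sprintf("%d row(s) with non-positive width/height rejected in %s",
                    sum(!keep), path))
    d <- d[keep, , drop = FALSE]
  }
  dup <- duplicated(d[, c("frame", "id")])
  if (any(dup)) {
    stop(sprintf("duplicate (frame, id) pair (%d, %d) in %s",
                 d$frame[dup][1], as.integer(d$id[dup][1]), path))
  }
  d <- d[order(d$frame, d$id), , drop = FALSE]
  out <- data.frame(frame = d$frame, id = as.integer(d$id), left = d$left,
                    top = d$top, width = d$width, height = d$height,
                    score = d$conf)
  rownames(out) <- NULL
  out
}

#' Write tracker results in MOTChallenge format
#'
#' Emits the result dialect `frame,id,left,top,width,height,score,-1,-1,-1`,
#' rows sorted by frame then id, with fixed decimal formatting so a given
#' input always produces byte-identical output. Internal 0-based coordinates
#' are shifted back to the file's 1-based convention; the world-coordinate
#' fields are written as -1.
#'
#' @param tracks data.frame with columns frame, id, left, top, width, height
#'   and optionally score (default 1).
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeTracks <- function(tracks, path) {
  need <- c("frame", "id", "left", "top", "width", "height")
  if (!all(need %in% names(tracks))) {
    stop("tracks needs columns ", paste(need, collapse = ", "))
  }
  if (nrow(tracks)) {
    if (any(tracks$id < 1)) stop("identities must be positive")
    if (any(tracks$frame < 1)) stop("frames must be >= 1")
  }
  score <- if ("score" %in% names(tracks)) tracks$score else rep(1, nrow(tracks))
  o <- order(tracks$frame, tracks$id)
  lines <- sprintf("%d,%d,%.4f,%.4f,%.4f,%.4f,%.6f,-1,-1,-1",
                   as.integer(tracks$frame[o]), as.integer(tracks$id[o]),
                   tracks$left[o] + 1, tracks$top[o] + 1,
                   tracks$width[o], tracks$height[o], score[o])
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (length(lines)) writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Split a box table into per-frame lists
#'
#' @param d data.frame with a frame column.
#' @param frames frame range to cover (frames without rows yield empty
#'   entries). Defaults to `min(frame):max(frame)`.
#' @return named list of data.frames, one per frame.
#' @export
splitByFrame <- function(d, frames = NULL) {
  if (is.null(frames)) {
    if (!nrow(d)) return(list())
    frames <- seq(min(d$frame), max(d$frame))
  }
  idx <- split(seq_len(nrow(d)), factor(d$frame, levels = frames))
  lapply(idx, function(i) d[i, , drop = FALSE])
}
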