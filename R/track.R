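#' Hand keypoint naming and digit layout
#'
#' The 21-keypoint hand layout used throughout the package follows the
#' common pose-estimation convention: keypoint 0 is the wrist, keypoints
#' 1--4 are the thumb ray (CMC, MCP, IP, tip) and keypoints 5--20 are the
#' index, middle, ring and little rays (MCP, PIP, DIP, tip each).
#' Keypoint indices are 0-based in all user-facing tables; internally they
#' map to columns 1--21.
#'
#' @return `hand_keypoint_names()` returns the 21 keypoint names in order.
#' @export
hand_keypoint_names <- function() {
  c("wrist",
    "thumb_cmc", "thumb_mcp", "thumb_ip", "thumb_tip",
    "index_mcp", "index_pip", "index_dip", "index_tip",
    "middle_mcp", "middle_pip", "middle_dip", "middle_tip",
    "ring_mcp", "ring_pip", "ring_dip", "ring_tip",
    "little_mcp", "little_pip", "little_dip", "little_tip")
}

#' @rdname hand_keypoint_names
#' @return `hand_digits()` returns the five digit names.
#' @export
hand_digits <- function() {
  c("thumb", "index", "middle", "ring", "little")
}

#' @rdname hand_keypoint_names
#' @param digit Digit name, one of [hand_digits()].
#' @return `digit_keypoints()` returns the four 1-based column indices of
#'   the digit's keypoints, base to tip.
#' @export
digit_keypoints <- function(digit) {
  digit <- match.arg(digit, hand_digits())
  base <- switch(digit,
    thumb = 2L, index = 6L, middle = 10L, ring = 14L, little = 18L)
  base:(base + 3L)
}

#' Construct a 2D hand keypoint track
#'
#' A `hand_track` holds one hand's 2D keypoint stream: per-frame x/y pixel
#' coordinates and detection confidences for the 21 keypoints.  Missing
#' landmarks are encoded as `NA` coordinates with confidence 0 (the
#' on-disk pose-JSON dialect encodes them as `(0, 0, 0)` triplets).
#'
#' @param x,y Numeric matrices, frames x 21, pixel coordinates (`NA` =
#'   missing landmark).
#' @param conf Optional confidence matrix in `[0, 1]`; defaults to 1 where
#'   present and 0 where missing.
#' @param fps Frame rate in Hz (default 30).
#' @param hand_side `"left"` or `"right"`.
#' @param source `"markerless"` or `"projected_marker"`.
#' @return An object of class `hand_track`.
#' @export
hand_track <- function(x, y, conf = NULL, fps = 30,
                       hand_side = c("right", "left"),
                       source = c("markerless", "projected_marker")) {
  hand_side <- match.arg(hand_side)
  source <- match.arg(source)
  x <- as.matrix(x); y <- as.matrix(y)
  if (ncol(x) != 21L || ncol(y) != 21L)
    stop("hand_track requires exactly 21 keypoint columns")
  if (!identical(dim(x), dim(y)))
    stop("x and y must have identical dimensions")
  miss <- is.na(x) | is.na(y)
  x[miss] <- NA_real_; y[miss] <- NA_real_
  if (is.null(conf)) {
    conf <- matrix(1, nrow(x), 21L)
  } else {
    conf <- as.matrix(conf)
    if (!identical(dim(conf), dim(x)))
      stop("conf must match x/y dimensions")
    if (any(conf < 0 | conf > 1, na.rm = TRUE))
      stop("confidence values must lie in [0, 1]")
  }
  conf[miss] <- 0
  if (!is.numeric(fps) || length(fps) != 1L || fps <= 0)
    stop("fps must be a positive scalar")
  colnames(x) <- colnames(y) <- colnames(conf) <- hand_keypoint_names()
  structure(
    list(x = x, y = y, conf = conf, fps = fps,
         hand_side = hand_side, source = source),
    class = "hand_track")
}

#' @rdname hand_track
#' @param track A `hand_track`.
#' @return `n_frames()` returns the number of frames.
#' @export
n_frames <- function(track) {
  stopifnot(inherits(track, "hand_track"))
  nrow(track$x)
}

#' @rdname hand_track
#' @return `missing_landmarks()` returns a logical frames x 21 matrix,
#'   `TRUE` where a landmark is missing.
#' @export
missing_landmarks <- function(track) {
  stopifnot(inherits(track, "hand_track"))
  is.na(track$x) | is.na(track$y)
}

#' @export
print.hand_track <- function(x, ...) {
  miss <- sum(missing_landmarks(x))
  cat(sprintf(
    "<hand_track> %s hand, %s, %d frames @ %g Hz, %d missing landmark(s)\n",
    x$hand_side, x$source, n_frames(x), x$fps, miss))
  invisible(x)
}

#' Extract a frame range from a track
#'
#' @param track A `hand_track`.
#' @param start_frame,end_frame 0-based half-open frame interval
#'   `[start_frame, end_frame)`.
#' @return A `hand_track` with `end_frame - start_frame` frames.
#' @export
track_window <- function(track, start_frame, end_frame) {
  stopifnot(inherits(track, "hand_track"))
  n <- n_frames(track)
  if (start_frame < 0 || end_frame > n || start_frame >= end_frame)
    stop("frame window [", start_frame, ", ", end_frame,
         ") outside track of ", n, " frames")
  idx <- (start_frame + 1L):end_frame
  hand_track(track$x[idx, , drop = FALSE], track$y[idx, , drop = FALSE],
             track$conf[idx, , drop = FALSE], fps = track$fps,
             hand_side = track$hand_side, source = track$source)
}
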