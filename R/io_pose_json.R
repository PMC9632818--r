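#' Read per-frame hand keypoint JSON files into a track
#'
#' Reads a sequence of pose-JSON files (OpenPose v1.7-style dialect: a
#' top-level `"people"` array whose first entry carries
#' `"hand_left_keypoints_2d"` / `"hand_right_keypoints_2d"` as a flat list
#' of 63 numbers, 21 x \[x, y, confidence\]), one file per frame, in the
#' order given.  All-zero `(0, 0, 0)` triplets are the dialect's encoding
#' of an undetected landmark and are flagged missing.  A frame whose
#' `"people"` array is empty yields an all-missing frame.
#'
#' @param paths Character vector of JSON file paths, one per frame, in
#'   frame order.
#' @param hand_side `"left"` or `"right"`: which hand's keypoints to read.
#' @param fps Frame rate of the stream in Hz (default 30).
#' @return A [hand_track] with `source = "markerless"`.
#' @seealso [write_pose_json()]
#' @export
read_pose_json <- function(paths, hand_side = c("right", "left"), fps = 30) {
  hand_side <- match.arg(hand_side)
  if (length(paths) == 0L) stop("no pose-JSON files given")
  key <- paste0("hand_", hand_side, "_keypoints_2d")
  n <- length(paths)
  x <- matrix(NA_real_, n, 21L)
  y <- matrix(NA_real_, n, 21L)
  conf <- matrix(0, n, 21L)
  for (i in seq_len(n)) {
    obj <- tryCatch(
      jsonlite::fromJSON(paths[i], simplifyVector = TRUE),
      error = function(e) stop("malformed pose JSON in '", paths[i], "': ",
                               conditionMessage(e), call. = FALSE))
    people <- obj[["people"]]
    if (is.null(people) || length(people) == 0L) next  # no detection
    kp <- if (is.data.frame(people)) people[[key]][[1L]] else people[[1L]][[key]]
    if (is.null(kp))
      stop("pose JSON '", paths[i], "' lacks field '", key, "'")
    kp <- as.numeric(unlist(kp))
    if (length(kp) != 63L)
      stop("pose JSON '", paths[i], "' has ", length(kp) %/% 3,
           " keypoints; expected 21")
    m <- matrix(kp, ncol = 3L, byrow = TRUE)
    missing <- m[, 1L] == 0 & m[, 2L] == 0 & m[, 3L] == 0
    m[missing, ] <- NA_real_
    x[i, ] <- m[, 1L]
    y[i, ] <- m[, 2L]
    conf[i, ] <- ifelse(missing, 0, m[, 3L])
  }
  if (any(conf < 0 | conf > 1, na.rm = TRUE))
    stop("confidence values outside [0, 1] in pose JSON input")
  hand_track(x, y, conf, fps = fps, hand_side = hand_side,
             source = "markerless")
}

#' Write a track as per-frame pose-JSON files
#'
#' Emits one JSON file per frame in the dialect read by
#' [read_pose_json()].  Missing landmarks are written as `(0, 0, 0)`.
#'
#' @param track A [hand_track].
#' @param dir Output directory (created if absent).
#' @param prefix File name prefix; files are named
#'   `<prefix>_<frame 12 digits>_keypoints.json`.
#' @return Invisibly, the vector of written file paths in frame order.
#' @export
write_pose_json <- function(track, dir, prefix = "frame") {
  stopifnot(inherits(track, "hand_track"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  key <- paste0("hand_", track$hand_side, "_keypoints_2d")
  other <- paste0("hand_", setdiff(c("left", "right"), track$hand_side),
                  "_keypoints_2d")
  n <- n_frames(track)
  paths <- file.path(dir, sprintf("%s_%012d_keypoints.json", prefix,
                                  seq_len(n) - 1L))
  miss <- missing_landmarks(track)
  for (i in seq_len(n)) {
    m <- cbind(track$x[i, ], track$y[i, ], track$conf[i, ])
    m[miss[i, ], ] <- 0
    flat <- sprintf("%.6f", as.vector(t(m)))
    txt <- paste0(
      '{"version":1.3,"people":[{"person_id":[-1],',
      '"', key, '":[', paste(flat, collapse = ","), '],',
      '"', other, '":[]}]}')
    writeLines(txt, paths[i])
  }
  invisible(paths)
}
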