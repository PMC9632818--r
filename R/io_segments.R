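#' Activity vocabulary
#'
#' The four single-handed activities in the validation protocol:
#' finger abduction/adduction (`abd_add`), radial walking
#' (`radial_walking`), metacarpophalangeal flexion (`mcp_flexion`) and
#' thumb opposition (`thumb_opposition`).
#'
#' @return Character vector of the four activity codes.
#' @export
activity_levels <- function() {
  c("abd_add", "radial_walking", "mcp_flexion", "thumb_opposition")
}

#' Build a validated activity segment table
#'
#' Segments delimit one repetition of one activity within a continuous
#' recording.  Frames are 0-based and intervals half-open
#' `[start_frame, end_frame)`.
#'
#' @param df Data frame with columns `participant`, `hand`, `activity`,
#'   `repetition`, `start_frame`, `end_frame`.
#' @return The validated data frame, sorted by participant, hand,
#'   activity, repetition.
#' @export
activity_segments <- function(df) {
  need <- c("participant", "hand", "activity", "repetition",
            "start_frame", "end_frame")
  if (!all(need %in% names(df)))
    stop("segment table must have columns: ", paste(need, collapse = ", "))
  df <- df[need]
  df$participant <- as.character(df$participant)
  df$hand <- as.character(df$hand)
  df$activity <- as.character(df$activity)
  df$repetition <- as.integer(df$repetition)
  df$start_frame <- as.integer(df$start_frame)
  df$end_frame <- as.integer(df$end_frame)
  bad_act <- setdiff(unique(df$activity), activity_levels())
  if (length(bad_act))
    stop("unknown activity string(s): ", paste(bad_act, collapse = ", "))
  if (!all(df$hand %in% c("left", "right")))
    stop("hand must be 'left' or 'right'")
  if (any(df$repetition < 1L))
    stop("repetition must be >= 1")
  if (any(df$end_frame <= df$start_frame))
    stop("segments require start_frame < end_frame")
  # overlap check within each participant/hand recording
  for (key in split(df, paste(df$participant, df$hand))) {
    key <- key[order(key$start_frame), ]
    if (nrow(key) > 1L &&
        any(key$start_frame[-1L] < key$end_frame[-nrow(key)]))
      stop("overlapping segments for participant ", key$participant[1L],
           ", ", key$hand[1L], " hand")
  }
  df <- df[order(df$participant, df$hand,
                 match(df$activity, activity_levels()), df$repetition), ]
  rownames(df) <- NULL
  df
}

#' Read / write activity segment annotations (CSV)
#'
#' CSV header:
#' `participant,hand,activity,repetition,start_frame,end_frame`.
#'
#' @param path CSV file path.
#' @return `read_segments()`: a validated, sorted segment data frame.
#' @export
read_segments <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  activity_segments(df)
}

#' @rdname read_segments
#' @param segments Segment data frame (validated by [activity_segments()]).
#' @export
write_segments <- function(segments, path) {
  segments <- activity_segments(segments)
  utils::write.csv(segments, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write digit-swap annotations (CSV)
#'
#' Manual relabelling annotations for frames where the pose estimator
#' exchanged two digits.  CSV header:
#' `participant,hand,start_frame,end_frame,digit_a,digit_b`; frame ranges
#' are 0-based half-open.
#'
#' @param path CSV file path.
#' @return A data frame of swap events (zero rows if the file has only a
#'   header).
#' @export
read_swap_annotations <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant", "hand", "start_frame", "end_frame",
            "digit_a", "digit_b")
  if (!all(need %in% names(df)))
    stop("swap table must have columns: ", paste(need, collapse = ", "))
  df <- df[need]
  if (nrow(df)) {
    if (!all(df$digit_a %in% hand_digits()) ||
        !all(df$digit_b %in% hand_digits()))
      stop("swap digits must be digit names")
    if (any(df$digit_a == df$digit_b))
      stop("swap events require two distinct digits")
    if (any(df$end_frame <= df$start_frame))
      stop("swap events require start_frame < end_frame")
  }
  df
}

#' @rdname read_swap_annotations
#' @param swaps Swap-event data frame.
#' @export
write_swap_annotations <- function(swaps, path) {
  utils::write.csv(swaps, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
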