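#' Included angle at a joint
#'
#' The included angle at `p_vertex` between the chain segments towards
#' `p_proximal` and `p_distal`: the arccosine of the clamped normalised
#' dot product of the vectors vertex->proximal and vertex->distal, in
#' degrees within `[0, 180]`.  A fully extended (collinear) chain reads
#' 180 degrees.  All three arguments may be `n x 2` matrices for
#' frame-wise evaluation.  A zero-length segment or a missing coordinate
#' yields `NA` for that frame rather than an error.
#'
#' @param p_proximal,p_vertex,p_distal 2D points (length-2 vectors or
#'   `n x 2` matrices).
#' @return Angle(s) in degrees.
#' @export
included_angle <- function(p_proximal, p_vertex, p_distal) {
  p1 <- rbind2d(p_proximal); p2 <- rbind2d(p_vertex); p3 <- rbind2d(p_distal)
  u1 <- p1[, 1L] - p2[, 1L]; v1 <- p1[, 2L] - p2[, 2L]
  u2 <- p3[, 1L] - p2[, 1L]; v2 <- p3[, 2L] - p2[, 2L]
  deg <- vector_angle_deg(u1, v1, u2, v2)
  if (length(deg) == 1L) deg[[1L]] else deg
}

# angle between vectors (u1,v1) and (u2,v2) in [0, 180] degrees.
# atan2(|cross|, dot) is the numerically stable equivalent of the
# arccos of the clamped normalised dot product: well-conditioned near 0
# and 180 where acos loses half the significant digits.
vector_angle_deg <- function(u1, v1, u2, v2) {
  n1 <- sqrt(u1^2 + v1^2)
  n2 <- sqrt(u2^2 + v2^2)
  ang <- atan2(abs(u1 * v2 - v1 * u2), u1 * u2 + v1 * v2) * 180 / pi
  ang[!is.na(n1) & n1 == 0] <- NA_real_  # zero-length segment: undefined
  ang[!is.na(n2) & n2 == 0] <- NA_real_
  ang
}

rbind2d <- function(p) {
  if (is.matrix(p)) {
    if (ncol(p) != 2L) stop("points must have 2 columns")
    p
  } else {
    if (length(p) != 2L) stop("a point must have 2 coordinates")
    matrix(p, 1L, 2L)
  }
}

#' Angle between two digits' direction vectors
#'
#' The inter-digit angle is measured between the base->tip direction
#' vectors of the two digits: the base is the MCP keypoint for fingers
#' and the CMC keypoint for the thumb.  Parallel digits read 0 degrees.
#' With `vertex_at_wrist = TRUE` the directions are taken from the wrist
#' to each tip instead (alternative convention).
#'
#' @param track A [hand_track].
#' @param digit_a,digit_b Digit names.
#' @param vertex_at_wrist Use wrist->tip directions instead of base->tip.
#' @return Per-frame angle series in degrees, `[0, 180]`.
#' @export
inter_digit_angle <- function(track, digit_a, digit_b,
                              vertex_at_wrist = FALSE) {
  stopifnot(inherits(track, "hand_track"))
  if (digit_a == digit_b) stop("inter-digit angle needs two distinct digits")
  dir_of <- function(digit) {
    cols <- digit_keypoints(digit)
    base <- if (vertex_at_wrist) 1L else cols[1L]
    tip <- cols[4L]
    cbind(track$x[, tip] - track$x[, base],
          track$y[, tip] - track$y[, base])
  }
  da <- dir_of(digit_a)
  db <- dir_of(digit_b)
  vector_angle_deg(da[, 1L], da[, 2L], db[, 1L], db[, 2L])
}

#' Per-joint included angle series for one digit
#'
#' For a finger (chain wrist -> MCP -> PIP -> DIP -> tip): `alpha` is the
#' MCP included angle (vertex MCP, towards wrist and PIP), `beta` the PIP
#' angle, `gamma` the DIP angle.  For the thumb (chain wrist -> CMC ->
#' MCP -> IP -> tip) only `alpha` (MCP, vertex between CMC and IP) and
#' `beta` (IP, vertex between MCP and tip) are defined; `gamma` is all
#' missing.  Missing landmarks propagate to every angle they enter.
#'
#' @param track A [hand_track].
#' @param digit Digit name.
#' @return A list of numeric series `alpha`, `beta`, `gamma` (degrees).
#' @export
finger_joint_angles <- function(track, digit) {
  stopifnot(inherits(track, "hand_track"))
  digit <- match.arg(digit, hand_digits())
  pt <- function(col) cbind(track$x[, col], track$y[, col])
  cols <- digit_keypoints(digit)
  if (digit == "thumb") {
    # cols: CMC, MCP, IP, TIP
    alpha <- included_angle(pt(cols[1L]), pt(cols[2L]), pt(cols[3L]))
    beta <- included_angle(pt(cols[2L]), pt(cols[3L]), pt(cols[4L]))
    gamma <- rep(NA_real_, n_frames(track))
  } else {
    # cols: MCP, PIP, DIP, TIP; wrist is column 1
    alpha <- included_angle(pt(1L), pt(cols[1L]), pt(cols[2L]))
    beta <- included_angle(pt(cols[1L]), pt(cols[2L]), pt(cols[3L]))
    gamma <- included_angle(pt(cols[2L]), pt(cols[3L]), pt(cols[4L]))
  }
  list(alpha = alpha, beta = beta, gamma = gamma)
}

#' Per-activity angle catalog
#'
#' Returns the set of angle definitions measured for one activity and
#' hand:
#' * `abd_add`: 4 inter-digit angles against the middle-finger reference
#'   (thumb-middle, index-middle, ring-middle, little-middle);
#' * `radial_walking`: 4 adjacent-pair inter-digit angles (thumb-index,
#'   index-middle, middle-ring, ring-little);
#' * `mcp_flexion`: 5 MCP included angles (all five digits);
#' * `thumb_opposition`: 5 included angles (thumb IP and the PIP of
#'   index, middle, ring, little).
#' Across both hands the four activities yield 8 + 8 + 10 + 10 = 36
#' angle definitions per participant.
#'
#' @param activity One of [activity_levels()].
#' @param hand `"left"` or `"right"`.
#' @return Data frame with columns `name`, `kind` (`included_joint` /
#'   `inter_digit`), `activity`, `hand`, `digit_a`, `digit_b` (inter-digit
#'   only), `joint` (included only: `mcp`, `pip` or `ip`).
#' @export
build_angle_catalog <- function(activity, hand = c("right", "left")) {
  hand <- match.arg(hand)
  if (!activity %in% activity_levels())
    stop("unknown activity: ", activity)
  inter <- function(a, b) data.frame(
    name = paste0(a, "-", b), kind = "inter_digit", activity = activity,
    hand = hand, digit_a = a, digit_b = b, joint = NA_character_)
  incl <- function(d, joint) data.frame(
    name = paste0(d, "_", joint), kind = "included_joint",
    activity = activity, hand = hand, digit_a = d, digit_b = NA_character_,
    joint = joint)
  out <- switch(activity,
    abd_add = rbind(inter("thumb", "middle"), inter("index", "middle"),
                    inter("ring", "middle"), inter("little", "middle")),
    radial_walking = rbind(inter("thumb", "index"), inter("index", "middle"),
                           inter("middle", "ring"), inter("ring", "little")),
    mcp_flexion = do.call(rbind, lapply(hand_digits(), incl, joint = "mcp")),
    thumb_opposition = rbind(incl("thumb", "ip"), incl("index", "pip"),
                             incl("middle", "pip"), incl("ring", "pip"),
                             incl("little", "pip")))
  rownames(out) <- NULL
  out
}

#' @rdname build_angle_catalog
#' @return `full_angle_catalog()`: the 36-definition catalog across all
#'   four activities and both hands.
#' @export
full_angle_catalog <- function() {
  do.call(rbind, lapply(activity_levels(), function(act)
    rbind(build_angle_catalog(act, "right"),
          build_angle_catalog(act, "left"))))
}

#' Evaluate a catalog of angle definitions on a track
#'
#' @param track A [hand_track] (its `hand_side` should match the
#'   catalog's `hand`).
#' @param catalog Catalog data frame from [build_angle_catalog()].
#' @param vertex_at_wrist Passed to [inter_digit_angle()].
#' @return Numeric matrix, frames x definitions, colnames from
#'   `catalog$name`; values in degrees within `[0, 180]` or `NA`.
#' @export
compute_catalog_angles <- function(track, catalog, vertex_at_wrist = FALSE) {
  stopifnot(inherits(track, "hand_track"))
  out <- matrix(NA_real_, n_frames(track), nrow(catalog))
  colnames(out) <- catalog$name
  joints_cache <- list()
  for (j in seq_len(nrow(catalog))) {
    def <- catalog[j, ]
    if (def$kind == "inter_digit") {
      out[, j] <- inter_digit_angle(track, def$digit_a, def$digit_b,
                                    vertex_at_wrist = vertex_at_wrist)
    } else {
      d <- def$digit_a
      if (is.null(joints_cache[[d]]))
        joints_cache[[d]] <- finger_joint_angles(track, d)
      ja <- joints_cache[[d]]
      out[, j] <- switch(def$joint,
        mcp = ja$alpha,
        pip = ja$beta,
        ip = ja$beta,   # thumb interphalangeal
        dip = ja$gamma,
        stop("unknown joint: ", def$joint))
    }
  }
  out
}

#' Total Active Flexion of an angle series
#'
#' The maximum minus the minimum of the series over its non-missing
#' frames, in degrees.  Invariant under the convention swap
#' `theta -> 180 - theta`.  With fewer than two valid frames the TAF is
#' undefined and returned as `NA` with a warning.
#'
#' @param values Numeric angle series in degrees (one activity segment).
#' @return TAF in degrees (>= 0), or `NA`.
#' @export
total_active_flexion <- function(values) {
  v <- values[!is.na(values)]
  if (length(v) < 2L) {
    warning("fewer than 2 valid frames in segment; TAF undefined")
    return(NA_real_)
  }
  max(v) - min(v)
}

#' TAF of the repetition-averaged cycle
#'
#' Averages an angle series across equally long repetition segments into
#' one mean cycle and returns its Total Active Flexion.  Averaging
#' repetitions before taking the range suppresses frame noise that would
#' otherwise inflate a max-minus-min statistic, and mirrors the common
#' practice of summarising cyclic movements on the mean cycle.
#'
#' @param values Numeric angle series over the full activity stream
#'   (degrees).
#' @param segments Data frame of the activity's repetition segments
#'   (columns `start_frame`, `end_frame`, 0-based half-open); cycles are
#'   truncated to the shortest repetition.
#' @return TAF of the mean cycle in degrees.
#' @export
taf_of_average_cycle <- function(values, segments) {
  if (nrow(segments) == 0L) stop("no repetition segments given")
  len <- min(segments$end_frame - segments$start_frame)
  cyc <- rowMeans(vapply(seq_len(nrow(segments)), function(r)
    values[(segments$start_frame[r] + 1L):(segments$start_frame[r] + len)],
    numeric(len)), na.rm = TRUE)
  cyc[is.nan(cyc)] <- NA_real_
  total_active_flexion(cyc)
}
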