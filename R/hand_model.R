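#' Planar articulated hand geometry
#'
#' Segment lengths (mm) and neutral ray directions of a five-digit planar
#' hand used by the forward-kinematics simulator.  The hand lies in the
#' frontal plane facing the camera: the wrist is at the origin, digits
#' point towards +y, and +x is the radial (thumb) side; left-hand
#' geometry is mirrored about x = 0.  Fingers articulate about fixed
#' metacarpal heads; the thumb ray articulates about its carpometacarpal
#' joint.  Default lengths follow adult anthropometry (index finger
#' ~92 mm tip to metacarpal head).
#'
#' @param side `"right"` or `"left"`.
#' @return An object of class `hand_geometry`: per-digit list with
#'   `base_angle` (neutral ray direction, degrees from +y towards
#'   radial), `lengths` (phalanx lengths base to tip, mm) and, for
#'   fingers, `metacarpal` (wrist to MCP, mm); the thumb instead has
#'   `cmc_offset` (wrist to CMC polar offset, mm and degrees).
#' @export
hand_geometry <- function(side = c("right", "left")) {
  side <- match.arg(side)
  g <- list(
    side = side,
    thumb = list(base_angle = 50, cmc_offset = c(r = 35, angle = 40),
                 lengths = c(metacarpal = 45, proximal = 32, distal = 28)),
    index = list(base_angle = 15, metacarpal = 85,
                 lengths = c(proximal = 45, intermediate = 25, distal = 22)),
    middle = list(base_angle = 0, metacarpal = 88,
                  lengths = c(proximal = 50, intermediate = 30, distal = 24)),
    ring = list(base_angle = -12, metacarpal = 82,
                lengths = c(proximal = 45, intermediate = 27, distal = 23)),
    little = list(base_angle = -25, metacarpal = 72,
                  lengths = c(proximal = 35, intermediate = 22, distal = 20)))
  class(g) <- "hand_geometry"
  g
}

#' Synthetic capture scenario
#'
#' Describes one simulated recording of one activity: the motion command
#' (repetitions, cycle length, amplitude) and the corruption model of
#' the markerless stream (Gaussian keypoint jitter, spike outliers,
#' digit-swap events, occlusion windows).  Defaults mirror the
#' validation protocol: 30 Hz capture, four repetitions for
#' abduction/adduction and two for the other activities, and
#' convention amplitudes of 25 deg (abduction), 20 deg (radial walking),
#' 70 deg (MCP flexion) and 80 deg (opposition PIP flexion).
#'
#' @param activity One of [activity_levels()].
#' @param repetitions Number of repetitions (default per activity).
#' @param cycle_s Duration in seconds of one motion window (default 10,
#'   giving a ~240 s two-hand session consistent with continuous
#'   laboratory captures).
#' @param fps Frame rate in Hz (default 30).
#' @param amplitude Commanded joint excursion in degrees (default per
#'   activity).
#' @param jitter_sd Gaussian keypoint jitter SD in px (default 2).
#' @param outlier_rate Per landmark-frame spike probability (default
#'   0.02).
#' @param outlier_amp Spike displacement in px (default 16, i.e. 8 x the
#'   default jitter SD).
#' @param swap_events Optional data frame of digit-swap corruptions
#'   (`start_frame`, `end_frame`, `digit_a`, `digit_b`).
#' @param occlusion_windows Optional data frame of occlusion windows
#'   (`start_frame`, `end_frame`, `digit`).
#' @param marker_noise_sd Marker-based stream 3D noise SD in mm
#'   (default 0.2, the order of optical capture error).
#' @param px_per_mm Orthographic camera scale (default 1).
#' @param depth_mm Constant camera-axis depth of the hand plane (mm).
#' @param seed Optional integer seed; all randomness of the scenario
#'   flows from it.
#' @return An object of class `synthetic_scenario`.
#' @export
synthetic_scenario <- function(activity,
                               repetitions = NULL,
                               cycle_s = 10, fps = 30,
                               amplitude = NULL,
                               jitter_sd = 2,
                               outlier_rate = 0.02, outlier_amp = 16,
                               swap_events = NULL,
                               occlusion_windows = NULL,
                               marker_noise_sd = 0.2,
                               px_per_mm = 1, depth_mm = 500,
                               seed = NULL) {
  if (!activity %in% activity_levels())
    stop("unknown activity: ", activity)
  if (is.null(repetitions))
    repetitions <- switch(activity, abd_add = 4L, 2L)
  if (is.null(amplitude))
    amplitude <- switch(activity, abd_add = 25, radial_walking = 20,
                        mcp_flexion = 70, thumb_opposition = 80)
  if (outlier_rate < 0 || outlier_rate > 1)
    stop("outlier_rate must lie in [0, 1]")
  if (cycle_s * fps < 2) stop("scenario must span at least 2 frames")
  structure(list(activity = activity, repetitions = as.integer(repetitions),
                 cycle_s = cycle_s, fps = fps, amplitude = amplitude,
                 jitter_sd = jitter_sd, outlier_rate = outlier_rate,
                 outlier_amp = outlier_amp, swap_events = swap_events,
                 occlusion_windows = occlusion_windows,
                 marker_noise_sd = marker_noise_sd,
                 px_per_mm = px_per_mm, depth_mm = depth_mm, seed = seed),
            class = "synthetic_scenario")
}

# run code with a locally seeded RNG, restoring the caller's RNG state
with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  }
  set.seed(seed)
  code
}

# raised cosine 0 -> 1 -> 0 over u in [0, 1)
raised_cos <- function(u) (1 - cos(2 * pi * u)) / 2
# smooth ramp 0 -> 1 over u in [0, 1)
half_ramp <- function(u) (1 - cos(pi * pmin(1, pmax(0, u)))) / 2

# per-frame commanded abduction offsets (deg, towards radial) and flexion
# angles (deg) for all digits; returns list(theta = n x 5, flex = list of
# n x 3 per digit [base joint, middle joint, distal joint], windows)
command_trajectories <- function(scenario) {
  act <- scenario$activity
  fps <- scenario$fps
  reps <- scenario$repetitions
  n_windows <- switch(act, abd_add = 1L, radial_walking = 5L,
                      mcp_flexion = 1L, thumb_opposition = 4L)
  frames_per_window <- round(scenario$cycle_s * fps)
  frames_per_rep <- n_windows * frames_per_window
  n <- reps * frames_per_rep
  amp <- scenario$amplitude
  digits <- hand_digits()
  theta <- matrix(0, n, 5L, dimnames = list(NULL, digits))
  flex <- lapply(digits, function(d) matrix(0, n, 3L))
  names(flex) <- digits
  t_rep <- ((seq_len(n) - 1L) %% frames_per_rep)  # frame within repetition
  u_rep <- t_rep / frames_per_rep
  win <- t_rep %/% frames_per_window              # window within repetition
  u_win <- (t_rep %% frames_per_window) / frames_per_window
  # flex columns index the joints along each chain: fingers (MCP, PIP,
  # DIP), thumb (CMC, MCP, IP)
  if (act == "abd_add") {
    s <- raised_cos(u_rep)
    spread <- c(thumb = 1, index = 1, middle = 0, ring = -1, little = -1)
    for (d in digits) theta[, d] <- spread[[d]] * amp * s
  } else if (act == "radial_walking") {
    # windows 0..3: index..little slide radially and hold; window 4: reset
    sliders <- c("index", "middle", "ring", "little")
    for (k in seq_along(sliders)) {
      d <- sliders[k]
      g <- numeric(n)
      g[win == k - 1L] <- half_ramp(u_win[win == k - 1L])
      g[win > k - 1L & win < 4L] <- 1
      g[win == 4L] <- 1 - half_ramp(u_win[win == 4L])
      theta[, d] <- amp * g
    }
  } else if (act == "mcp_flexion") {
    s <- amp * raised_cos(u_rep)
    fingers <- setdiff(digits, "thumb")
    for (d in fingers) flex[[d]][, 1L] <- s   # finger MCP joints
    flex[["thumb"]][, 2L] <- s                # thumb MCP joint
  } else {  # thumb_opposition
    s <- amp * raised_cos(u_win)
    flex[["thumb"]][, 3L] <- s  # thumb IP flexes in every window
    fingers <- c("index", "middle", "ring", "little")
    for (k in seq_along(fingers)) {
      idx <- win == k - 1L
      flex[[fingers[k]]][idx, 2L] <- s[idx]  # that finger's PIP
    }
  }
  segments <- data.frame(
    repetition = seq_len(reps),
    start_frame = (seq_len(reps) - 1L) * frames_per_rep,
    end_frame = seq_len(reps) * frames_per_rep)
  list(theta = theta, flex = flex, n = n, segments = segments)
}

# analytic catalog angle series implied by the commanded trajectories
commanded_catalog_angles <- function(geometry, cmd, catalog) {
  digits <- hand_digits()
  base <- vapply(digits, function(d) geometry[[d]]$base_angle, numeric(1L))
  ray <- sweep(cmd$theta, 2L, base, "+")  # absolute ray direction per digit
  out <- matrix(NA_real_, cmd$n, nrow(catalog))
  colnames(out) <- catalog$name
  for (j in seq_len(nrow(catalog))) {
    def <- catalog[j, ]
    if (def$kind == "inter_digit") {
      out[, j] <- abs(ray[, def$digit_a] - ray[, def$digit_b])
    } else {
      joint_idx <- if (def$digit_a == "thumb")
        switch(def$joint, mcp = 2L, ip = 3L)
      else
        switch(def$joint, mcp = 1L, pip = 2L, dip = 3L)
      out[, j] <- 180 - cmd$flex[[def$digit_a]][, joint_idx]
    }
  }
  out
}

# forward kinematics: landmark positions (mm) for commanded trajectories.
# Each digit is a chain of three segments from its base (metacarpal head
# for fingers, CMC for the thumb); flexion at joint s rotates every more
# distal segment ulnarwards within the plane.
forward_kinematics <- function(geometry, cmd) {
  n <- cmd$n
  x <- matrix(NA_real_, n, 21L)
  y <- matrix(NA_real_, n, 21L)
  dirx <- function(a) sinpi(a / 180)
  diry <- function(a) cospi(a / 180)
  x[, 1L] <- 0; y[, 1L] <- 0  # wrist at origin
  for (d in hand_digits()) {
    gd <- geometry[[d]]
    cols <- digit_keypoints(d)
    ray <- gd$base_angle + cmd$theta[, d]
    fl <- cmd$flex[[d]]
    if (d == "thumb") {
      px <- rep(gd$cmc_offset[["r"]] * dirx(gd$cmc_offset[["angle"]]), n)
      py <- rep(gd$cmc_offset[["r"]] * diry(gd$cmc_offset[["angle"]]), n)
    } else {
      px <- rep(gd$metacarpal * dirx(gd$base_angle), n)
      py <- rep(gd$metacarpal * diry(gd$base_angle), n)
    }
    x[, cols[1L]] <- px  # digit base: CMC (thumb) / MCP (fingers)
    y[, cols[1L]] <- py
    segs <- if (d == "thumb") gd$lengths else gd$lengths
    ang <- ray
    for (s in seq_along(segs)) {
      ang <- ang - fl[, s]
      px <- px + segs[[s]] * dirx(ang)
      py <- py + segs[[s]] * diry(ang)
      x[, cols[s + 1L]] <- px
      y[, cols[s + 1L]] <- py
    }
  }
  if (geometry$side == "left") x <- -x
  list(x = x, y = y)
}

# confidence emulation: high when the realised displacement is within the
# jitter band, collapsing towards 0 for spike-sized displacements
confidence_model <- function(displacement, jitter_sd) {
  1 - stats::plogis((displacement - 3 * jitter_sd - 0.5) /
                      max(jitter_sd / 2, 0.25))
}

#' Simulate one activity capture
#'
#' Runs the planar forward-kinematics model for one scenario and emits
#' the three streams of a validation run: the ground truth (commanded
#' catalog angle series, clean landmark track, per-repetition segments
#' and TAF), the marker-based 3D stream (landmarks embedded at constant
#' depth plus reference markers, with optional small capture noise) and
#' the markerless 2D stream (projected landmarks with Gaussian jitter,
#' then any configured spike outliers, digit swaps and occlusions).
#' Deterministic given `scenario$seed`.
#'
#' @param geometry A [hand_geometry].
#' @param scenario A [synthetic_scenario].
#' @return List with elements `truth` (list: `angles` commanded matrix,
#'   `catalog`, `segments`, `taf`, `clean_track`), `markers` (a
#'   [marker_set]), `track` (the corrupted markerless [hand_track]) and
#'   `outliers` (data frame of injected spike positions).
#' @export
simulate_activity <- function(geometry, scenario) {
  stopifnot(inherits(geometry, "hand_geometry"),
            inherits(scenario, "synthetic_scenario"))
  with_local_seed(scenario$seed, {
    cmd <- command_trajectories(scenario)
    catalog <- build_angle_catalog(scenario$activity, geometry$side)
    angles <- commanded_catalog_angles(geometry, cmd, catalog)
    fk <- forward_kinematics(geometry, cmd)
    n <- cmd$n
    if (!is.null(scenario$occlusion_windows) &&
        nrow(scenario$occlusion_windows)) {
      ow <- scenario$occlusion_windows
      if (any(ow$start_frame < 0L) || any(ow$end_frame > n))
        stop("occlusion window outside simulated duration")
    }
    # clean 2D landmark track (px)
    s <- scenario$px_per_mm
    clean <- hand_track(fk$x * s, fk$y * s, fps = scenario$fps,
                        hand_side = geometry$side, source = "markerless")
    # 3D markers: mapped landmarks at constant depth + reference markers
    labels <- hawk_marker_labels()
    pos <- array(NA_real_, c(n, 3L, length(labels)))
    jm <- hawk_joint_map()
    for (lab in names(jm)) {
      col <- jm[[lab]] + 1L
      k <- match(lab, labels)
      pos[, 1L, k] <- fk$x[, col]
      pos[, 2L, k] <- fk$y[, col]
      pos[, 3L, k] <- scenario$depth_mm
    }
    ref_offsets <- list(FA_RAD = c(25, -60), FA_ULN = c(-25, -60),
                        WRIST_RAD = c(30, 5), WRIST_ULN = c(-30, 5),
                        HAND_DOR = c(5, 45))
    mirror <- if (geometry$side == "left") -1 else 1
    for (lab in names(ref_offsets)) {
      k <- match(lab, labels)
      pos[, 1L, k] <- mirror * ref_offsets[[lab]][1L]
      pos[, 2L, k] <- ref_offsets[[lab]][2L]
      pos[, 3L, k] <- scenario$depth_mm
    }
    if (scenario$marker_noise_sd > 0)
      pos <- pos + stats::rnorm(length(pos), 0, scenario$marker_noise_sd)
    markers <- marker_set(pos, labels, fps = scenario$fps)
    # markerless stream: jitter + corruption
    x <- clean$x; y <- clean$y
    if (scenario$jitter_sd > 0) {
      dx <- matrix(stats::rnorm(n * 21L, 0, scenario$jitter_sd), n, 21L)
      dy <- matrix(stats::rnorm(n * 21L, 0, scenario$jitter_sd), n, 21L)
    } else {
      dx <- dy <- matrix(0, n, 21L)
    }
    disp <- sqrt(dx^2 + dy^2)
    conf <- confidence_model(disp, scenario$jitter_sd)
    track <- hand_track(x + dx, y + dy, conf, fps = scenario$fps,
                        hand_side = geometry$side, source = "markerless")
    outliers <- data.frame(frame = integer(0), keypoint = integer(0))
    if (scenario$outlier_rate > 0) {
      oi <- inject_outliers(track, scenario$outlier_rate,
                            scenario$outlier_amp)
      track <- oi$track
      outliers <- oi$injected
    }
    if (!is.null(scenario$swap_events) && nrow(scenario$swap_events)) {
      for (j in seq_len(nrow(scenario$swap_events))) {
        ev <- scenario$swap_events[j, ]
        track <- inject_swap(track, ev$digit_a, ev$digit_b,
                             ev$start_frame, ev$end_frame)
      }
    }
    if (!is.null(scenario$occlusion_windows) &&
        nrow(scenario$occlusion_windows))
      track <- inject_occlusion(track, scenario$occlusion_windows)
    taf <- do.call(rbind, lapply(seq_len(nrow(cmd$segments)), function(r) {
      seg <- cmd$segments[r, ]
      idx <- (seg$start_frame + 1L):seg$end_frame
      data.frame(angle_name = catalog$name, repetition = seg$repetition,
                 taf = apply(angles[idx, , drop = FALSE], 2L,
                             total_active_flexion))
    }))
    rownames(taf) <- NULL
    list(truth = list(angles = angles, catalog = catalog,
                      segments = cmd$segments, taf = taf,
                      clean_track = clean),
         markers = markers, track = track, outliers = outliers)
  })
}

#' Inject spike outliers into a track
#'
#' Displaces each non-missing landmark-frame with probability `rate` by
#' `amp` px in a uniformly random direction, emulating keypoint
#' misidentification.  Confidence of displaced landmarks is capped at
#' 0.2.  The injected positions are returned so detector performance can
#' be scored against ground truth.
#'
#' @param track A [hand_track].
#' @param rate Per landmark-frame displacement probability.
#' @param amp Displacement magnitude in px.
#' @param seed Optional seed (otherwise the current RNG stream is used).
#' @return List with `track` and `injected` (data frame of 0-based
#'   `frame` and `keypoint` indices).
#' @export
inject_outliers <- function(track, rate, amp, seed = NULL) {
  stopifnot(inherits(track, "hand_track"))
  if (rate < 0 || rate > 1) stop("rate must lie in [0, 1]")
  with_local_seed(seed, {
    n <- n_frames(track)
    present <- !missing_landmarks(track)
    hit <- present & matrix(stats::runif(n * 21L) < rate, n, 21L)
    idx <- which(hit)
    if (length(idx)) {
      ang <- stats::runif(length(idx), 0, 2 * pi)
      track$x[idx] <- track$x[idx] + amp * cos(ang)
      track$y[idx] <- track$y[idx] + amp * sin(ang)
      track$conf[idx] <- pmin(track$conf[idx], 0.2)
    }
    injected <- data.frame(frame = (idx - 1L) %% n,
                           keypoint = (idx - 1L) %/% n)
    list(track = track, injected = injected[order(injected$frame,
                                                  injected$keypoint), ])
  })
}

#' Inject a digit-swap tracking error
#'
#' Exchanges two digits' keypoint blocks over a frame range — the exact
#' inverse of [apply_swap_correction()], so swapping and then correcting
#' restores the original track.
#'
#' @param track A [hand_track].
#' @param digit_a,digit_b Distinct digit names.
#' @param start_frame,end_frame 0-based half-open frame range.
#' @return The corrupted [hand_track].
#' @export
inject_swap <- function(track, digit_a, digit_b, start_frame, end_frame) {
  apply_swap_correction(track, data.frame(
    start_frame = start_frame, end_frame = end_frame,
    digit_a = digit_a, digit_b = digit_b))
}

#' Inject occlusion dropouts
#'
#' Within each window the targeted digit's keypoints are set missing
#' with probability `prob` per frame (default 1: deterministic dropout),
#' and the confidence of the frame's remaining landmarks is reduced by
#' 10%, floored at `confidence_floor`.
#'
#' @param track A [hand_track].
#' @param windows Data frame with columns `start_frame`, `end_frame`
#'   (0-based half-open) and `digit`.
#' @param prob Per-frame dropout probability within a window.
#' @param confidence_floor Lower bound applied when damping other
#'   landmarks' confidence.
#' @param seed Optional seed.
#' @return The corrupted [hand_track].
#' @export
inject_occlusion <- function(track, windows, prob = 1,
                             confidence_floor = 0.2, seed = NULL) {
  stopifnot(inherits(track, "hand_track"))
  if (is.null(windows) || nrow(windows) == 0L) return(track)
  n <- n_frames(track)
  if (any(windows$start_frame < 0L) || any(windows$end_frame > n) ||
      any(windows$start_frame >= windows$end_frame))
    stop("occlusion window outside track duration")
  with_local_seed(seed, {
    for (j in seq_len(nrow(windows))) {
      w <- windows[j, ]
      rows <- (w$start_frame + 1L):w$end_frame
      cols <- digit_keypoints(w$digit)
      drop <- if (prob >= 1) rep(TRUE, length(rows))
              else stats::runif(length(rows)) < prob
      r <- rows[drop]
      track$x[r, cols] <- NA_real_
      track$y[r, cols] <- NA_real_
      track$conf[r, cols] <- 0
      others <- setdiff(1:21, cols)
      track$conf[rows, others] <-
        pmax(track$conf[rows, others] * 0.9, confidence_floor)
    }
    track
  })
}

#' Simulate a full single-hand session
#'
#' Concatenates the four activities into one continuous recording for
#' one participant and hand, mirroring a laboratory session: per-activity
#' scenarios are simulated back to back, repetition segments are indexed
#' into the concatenated stream, and (optionally) one digit-swap
#' corruption is injected into the MCP flexion block and recorded in the
#' swap annotation table, emulating the manual relabelling workflow.
#'
#' @param participant Participant id (e.g. `"P01"`).
#' @param hand `"right"` or `"left"`.
#' @param seed Integer seed for the whole session.
#' @param cycle_s,jitter_sd,outlier_rate,outlier_amp,marker_noise_sd,px_per_mm
#'   Passed to every activity's [synthetic_scenario()].
#' @param inject_swaps Inject one ring/little swap into the MCP flexion
#'   block (recorded in the returned `swaps` table).
#' @param amplitude_cv Between-session range-of-motion variability:
#'   each activity's commanded amplitude is scaled by a factor drawn
#'   once per session from `Normal(1, amplitude_cv)` (truncated to
#'   `[0.7, 1.3]`), emulating individual differences in joint
#'   excursion; 0 disables it.
#' @return List with `track` (markerless [hand_track]), `markers`
#'   ([marker_set]), `segments`, `swaps`, and `truth` (per-activity list
#'   with commanded angles, clean track, per-repetition TAF and the
#'   activity's frame offset in the concatenated stream).
#' @export
simulate_session <- function(participant, hand, seed,
                             cycle_s = 10, jitter_sd = 2,
                             outlier_rate = 0.02, outlier_amp = 16,
                             marker_noise_sd = 0.2, px_per_mm = 1,
                             inject_swaps = TRUE, amplitude_cv = 0.1) {
  geometry <- hand_geometry(hand)
  amp_scale <- with_local_seed(seed, pmin(1.3, pmax(0.7,
    stats::rnorm(4L, 1, amplitude_cv))))
  xs <- list(); ys <- list(); cs <- list(); mpos <- list()
  truth <- list()
  seg_rows <- list()
  offset <- 0L
  for (k in seq_along(activity_levels())) {
    act <- activity_levels()[k]
    base_amp <- switch(act, abd_add = 25, radial_walking = 20,
                       mcp_flexion = 70, thumb_opposition = 80)
    sc <- synthetic_scenario(act, cycle_s = cycle_s, jitter_sd = jitter_sd,
                             amplitude = base_amp * amp_scale[k],
                             outlier_rate = outlier_rate,
                             outlier_amp = outlier_amp,
                             marker_noise_sd = marker_noise_sd,
                             px_per_mm = px_per_mm,
                             seed = seed + 101L * k)
    sim <- simulate_activity(geometry, sc)
    xs[[act]] <- sim$track$x; ys[[act]] <- sim$track$y
    cs[[act]] <- sim$track$conf
    mpos[[act]] <- sim$markers$positions
    seg <- sim$truth$segments
    seg_rows[[act]] <- data.frame(
      participant = participant, hand = hand, activity = act,
      repetition = seg$repetition,
      start_frame = seg$start_frame + offset,
      end_frame = seg$end_frame + offset)
    truth[[act]] <- list(angles = sim$truth$angles,
                         catalog = sim$truth$catalog,
                         taf = sim$truth$taf,
                         clean_track = sim$truth$clean_track,
                         frame_offset = offset)
    offset <- offset + n_frames(sim$track)
  }
  track <- hand_track(do.call(rbind, xs), do.call(rbind, ys),
                      do.call(rbind, cs), fps = 30, hand_side = hand,
                      source = "markerless")
  pos <- do.call(abind1, mpos)
  markers <- marker_set(pos, hawk_marker_labels(), fps = 30)
  segments <- activity_segments(do.call(rbind, seg_rows))
  swaps <- data.frame(participant = character(0), hand = character(0),
                      start_frame = integer(0), end_frame = integer(0),
                      digit_a = character(0), digit_b = character(0))
  if (inject_swaps) {
    mcp_seg <- seg_rows[["mcp_flexion"]]
    s0 <- mcp_seg$start_frame[1L] + 10L
    s1 <- s0 + 15L
    track <- inject_swap(track, "ring", "little", s0, s1)
    swaps <- data.frame(participant = participant, hand = hand,
                        start_frame = s0, end_frame = s1,
                        digit_a = "ring", digit_b = "little")
  }
  list(track = track, markers = markers, segments = segments,
       swaps = swaps, truth = truth)
}

# bind frames x 3 x markers arrays along the frame axis
abind1 <- function(...) {
  parts <- list(...)
  d <- dim(parts[[1L]])
  out <- array(NA_real_, c(sum(vapply(parts, function(p) dim(p)[1L],
                                      integer(1L))), d[2L], d[3L]))
  at <- 0L
  for (p in parts) {
    out[at + seq_len(dim(p)[1L]), , ] <- p
    at <- at + dim(p)[1L]
  }
  out
}
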