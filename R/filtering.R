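#' Per-stream filter configuration
#'
#' Bundles the cleaning parameters applied to a keypoint stream.  The
#' markerless defaults follow the validated pipeline settings: Hampel
#' outlier identifier with a half-window of 4 frames (9-sample centred
#' window) and a threshold of 1 robust SD, then a zero-phase 2nd-order
#' Butterworth low-pass at 3 Hz.  The marker-based stream uses a 5 Hz
#' cutoff and no Hampel step (`use_hampel = FALSE`).
#'
#' @param hampel_half_window Hampel half-window in frames (window =
#'   `2 * half_window + 1`); must be >= 1.
#' @param hampel_k Threshold in multiples of the robust SD (1.4826 * MAD).
#' @param butter_cutoff Low-pass cutoff in Hz; must satisfy
#'   `0 < cutoff < fps / 2`.
#' @param butter_order Butterworth order (>= 1).
#' @param sma_window Window for the simple-moving-average alternative.
#' @param fps Stream frame rate in Hz.
#' @param use_hampel Apply the Hampel step when filtering a track.
#' @param max_gap Longest run of missing frames bridged by linear
#'   interpolation before smoothing.
#' @param conf_min Low-confidence gate: landmarks detected with
#'   confidence below this value are treated as missing before
#'   filtering (0 disables the gate).
#' @return An object of class `filter_config`.
#' @export
filter_config <- function(hampel_half_window = 4L, hampel_k = 1,
                          butter_cutoff = 3, butter_order = 2L,
                          sma_window = 5L, fps = 30, use_hampel = TRUE,
                          max_gap = 10L, conf_min = 0.3) {
  if (hampel_half_window < 1L) stop("hampel_half_window must be >= 1")
  if (hampel_k < 0) stop("hampel_k must be non-negative")
  if (butter_order < 1L) stop("butter_order must be >= 1")
  if (fps <= 0) stop("fps must be positive")
  if (butter_cutoff <= 0 || butter_cutoff >= fps / 2)
    stop("butter_cutoff must lie in (0, fps/2)")
  structure(list(hampel_half_window = as.integer(hampel_half_window),
                 hampel_k = hampel_k, butter_cutoff = butter_cutoff,
                 butter_order = as.integer(butter_order),
                 sma_window = as.integer(sma_window), fps = fps,
                 use_hampel = isTRUE(use_hampel),
                 max_gap = as.integer(max_gap), conf_min = conf_min),
            class = "filter_config")
}

#' Hampel outlier filter
#'
#' Sliding-window outlier identifier: at each interior frame the median
#' `m` and the robust spread `sigma = 1.4826 * MAD` of the centred
#' window of `2 * half_window + 1` samples are computed (missing values
#' are excluded from the window statistics).  A sample with
#' `|x - m| > k * sigma` is replaced by the window median and flagged.
#' The leading and trailing `half_window` samples, where no full centred
#' window exists, pass through unflagged, as do missing samples.
#'
#' The robust spread is used in place of a raw SD because a plain SD
#' estimate is corrupted by the very outliers being sought.
#'
#' @param x Numeric series (may contain `NA`).
#' @param half_window Half-window in frames (default 4).
#' @param k Threshold in robust-SD multiples (default 1).
#' @return A list with `filtered` (the cleaned series), `flagged`
#'   (1-based indices of replaced samples) and `replacements` (data frame
#'   of `frame`, `original`, `replacement`; `frame` is 0-based).
#' @export
hampel_filter <- function(x, half_window = 4L, k = 1) {
  if (half_window < 1L) stop("half_window must be >= 1")
  n <- length(x)
  if (n <= 2L * half_window)
    stop("series length must exceed 2 * half_window")
  res <- hampel_core(as.numeric(x), as.integer(half_window), k)
  if (res$starved)
    warning("all-missing Hampel window; value(s) passed through ",
            "unfiltered")
  y <- res$filtered
  flagged <- as.integer(res$flagged)
  replacements <- data.frame(frame = flagged - 1L, original = x[flagged],
                             replacement = y[flagged])
  list(filtered = y, flagged = flagged, replacements = replacements)
}

#' Centred simple moving average
#'
#' Mean over a centred window of `window` samples; windows are truncated
#' at the edges (a window longer than the series yields the global mean).
#' For even `window` the window extends one sample further to the right.
#' Missing values are excluded from the mean; a missing centre sample
#' stays missing.
#'
#' @param x Numeric series.
#' @param window Window length in frames (>= 1).
#' @return Smoothed series of the same length.
#' @export
moving_average <- function(x, window = 5L) {
  if (window < 1L) stop("window must be >= 1")
  n <- length(x)
  left <- (window - 1L) %/% 2L
  right <- window %/% 2L
  vapply(seq_len(n), function(i) {
    if (is.na(x[i])) return(NA_real_)
    w <- x[max(1L, i - left):min(n, i + right)]
    mean(w, na.rm = TRUE)
  }, numeric(1L))
}

# steady-state-initialised single-pass IIR filter: output for a constant
# input equals dc_gain * input from the first sample
iir_filter_ss <- function(b, a, x) {
  g <- sum(b) / sum(a)
  signal::filter(b, a, x,
                 init.x = rep(x[1L], length(b) - 1L),
                 init = rep(x[1L] * g, length(a) - 1L))
}

# zero-phase forward-backward IIR filtering with odd-reflection padding
filtfilt_zero_phase <- function(b, a, x) {
  n <- length(x)
  npad <- 3L * (max(length(a), length(b)) - 1L)
  if (n <= npad + 1L)
    stop("series too short for zero-phase filtering (need > ",
         npad + 1L, " samples)")
  front <- 2 * x[1L] - x[(npad + 1L):2L]
  back <- 2 * x[n] - x[(n - 1L):(n - npad)]
  xp <- c(front, x, back)
  y <- iir_filter_ss(b, a, xp)
  y <- rev(iir_filter_ss(b, a, rev(y)))
  as.numeric(y[(npad + 1L):(npad + n)])
}

#' Zero-phase Butterworth low-pass filter
#'
#' Applies a Butterworth low-pass of the configured order and cutoff
#' forward and backward (squaring the magnitude response and cancelling
#' the phase), so the smoothed series stays frame-aligned with the raw
#' one.  Edge transients are suppressed by odd-reflection padding with
#' steady-state filter initialisation; DC gain is exactly 1.
#'
#' @param x Numeric series without missing values (interpolate gaps
#'   first, see [interpolate_gaps()]).
#' @param cutoff Cutoff frequency in Hz, `0 < cutoff < fps / 2`.
#' @param fps Sampling rate in Hz.
#' @param order Filter order (default 2).
#' @return Filtered series of the same length.
#' @export
butterworth_lowpass <- function(x, cutoff, fps, order = 2L) {
  if (cutoff <= 0 || cutoff >= fps / 2)
    stop("cutoff must lie strictly between 0 and the Nyquist frequency")
  if (anyNA(x))
    stop("series contains missing values; interpolate gaps first")
  bf <- signal::butter(order, cutoff / (fps / 2), type = "low")
  filtfilt_zero_phase(bf$b, bf$a, x)
}

#' Analytic forward-backward Butterworth magnitude response
#'
#' Magnitude gain of the zero-phase (forward-backward) digital
#' Butterworth low-pass at frequency `f`, from the closed form of the
#' bilinear-transformed design:
#' `1 / (1 + (tan(pi f / fps) / tan(pi cutoff / fps))^(2 * order))`.
#'
#' @param f Frequency in Hz (vectorised).
#' @inheritParams butterworth_lowpass
#' @return Amplitude gain in `[0, 1]`.
#' @export
butterworth_zero_phase_gain <- function(f, cutoff, fps, order = 2L) {
  u <- tan(pi * f / fps) / tan(pi * cutoff / fps)
  1 / (1 + u^(2 * order))
}

#' Data-driven cutoff selection by residual analysis
#'
#' Implements the residual-analysis procedure for choosing a low-pass
#' cutoff: for each candidate cutoff the RMS residual between the raw and
#' filtered series is computed; a straight line is fitted to the
#' noise-dominated high-frequency tail of the residual curve (top
#' `tail_frac` of the grid); its intercept at 0 Hz estimates the noise
#' floor.  The selected cutoff is the smallest grid value whose residual
#' does not exceed that noise level.  For near-noiseless signals the
#' intercept collapses towards zero, so the noise level is floored at
#' `rel_floor` times the RMS of the mean-removed raw series.
#'
#' @param x Numeric series without missing values.
#' @param fps Sampling rate in Hz.
#' @param cutoff_grid Strictly increasing candidate cutoffs in
#'   `(0, fps/2)` (default 0.5--10 Hz in 0.5 Hz steps).
#' @param order Butterworth order used for the trial filters.
#' @param tail_frac Fraction of the grid (from the top) used for the
#'   noise line fit (default 0.4).
#' @param rel_floor Relative noise-level floor (default 0.1).
#' @param default_cutoff Fallback cutoff returned with a warning when the
#'   residual tail is non-monotone (increasing fit slope) or no grid
#'   point reaches the noise level.
#' @return A list with `cutoff` (selected, Hz), `residuals` (data frame
#'   `cutoff`, `rms` for plotting), `noise_level`, `intercept`, `slope`.
#' @export
winter_residual_cutoff <- function(x, fps,
                                   cutoff_grid = seq(0.5, 10, by = 0.5),
                                   order = 2L, tail_frac = 0.4,
                                   rel_floor = 0.1, default_cutoff = 3) {
  if (is.unsorted(cutoff_grid, strictly = TRUE))
    stop("cutoff_grid must be strictly increasing")
  if (any(cutoff_grid <= 0 | cutoff_grid >= fps / 2))
    stop("cutoff_grid must lie within (0, Nyquist)")
  rms <- vapply(cutoff_grid, function(fc) {
    sqrt(mean((x - butterworth_lowpass(x, fc, fps, order))^2))
  }, numeric(1L))
  curve <- data.frame(cutoff = cutoff_grid, rms = rms)
  n_tail <- max(2L, ceiling(tail_frac * length(cutoff_grid)))
  tail_idx <- (length(cutoff_grid) - n_tail + 1L):length(cutoff_grid)
  fit <- stats::lm.fit(cbind(1, cutoff_grid[tail_idx]), rms[tail_idx])
  intercept <- fit$coefficients[[1L]]
  slope <- fit$coefficients[[2L]]
  noise_level <- max(intercept, rel_floor * sqrt(mean((x - mean(x))^2)))
  ok <- which(rms <= noise_level)
  if (slope > 0 || !length(ok)) {
    warning("residual curve tail unusable for noise-line fit; ",
            "falling back to default cutoff ", default_cutoff, " Hz")
    selected <- default_cutoff
  } else {
    selected <- cutoff_grid[ok[1L]]
  }
  list(cutoff = selected, residuals = curve, noise_level = noise_level,
       intercept = intercept, slope = slope)
}

#' Bridge short gaps by linear interpolation
#'
#' Linearly interpolates runs of missing samples of length `<= max_gap`.
#' Longer runs, and leading/trailing missing samples, remain missing;
#' smoothing is then applied per contiguous non-missing block.
#'
#' @param x Numeric series with `NA` gaps.
#' @param max_gap Longest gap (in frames) to bridge.
#' @return Series with short gaps filled.
#' @export
interpolate_gaps <- function(x, max_gap = 10L) {
  if (!anyNA(x)) return(x)
  as.numeric(zoo::na.approx(x, na.rm = FALSE, maxgap = max_gap))
}

#' Undo digit-swap tracking errors
#'
#' Exchanges the 4-keypoint blocks of two digits over a frame range,
#' mirroring a manual relabelling of frames where the pose estimator
#' swapped two fingers.  The operation is an involution: applying the
#' same event twice restores the input.
#'
#' @param track A [hand_track].
#' @param events Data frame with columns `start_frame`, `end_frame`
#'   (0-based half-open), `digit_a`, `digit_b`.  Extra columns (e.g.
#'   `participant`, `hand`) are ignored.
#' @return The corrected [hand_track].
#' @export
apply_swap_correction <- function(track, events) {
  stopifnot(inherits(track, "hand_track"))
  if (is.null(events) || nrow(events) == 0L) return(track)
  n <- n_frames(track)
  for (j in seq_len(nrow(events))) {
    ev <- events[j, ]
    if (ev$digit_a == ev$digit_b) stop("swap digits must be distinct")
    if (ev$start_frame < 0L || ev$end_frame > n ||
        ev$start_frame >= ev$end_frame)
      stop("swap event range [", ev$start_frame, ", ", ev$end_frame,
           ") outside track of ", n, " frames")
    rows <- (ev$start_frame + 1L):ev$end_frame
    ca <- digit_keypoints(ev$digit_a)
    cb <- digit_keypoints(ev$digit_b)
    for (field in c("x", "y", "conf")) {
      tmp <- track[[field]][rows, ca]
      track[[field]][rows, ca] <- track[[field]][rows, cb]
      track[[field]][rows, cb] <- tmp
    }
  }
  track
}

#' Clean every coordinate series of a track
#'
#' Applies the full per-coordinate cleaning chain to the x and y series
#' of all 21 keypoints: low-confidence gating (detections below
#' `conf_min` become missing), gap interpolation, optional Hampel
#' outlier removal, then zero-phase Butterworth smoothing.  Smoothing
#' runs per contiguous non-missing block; blocks too short for the
#' filter padding are left unsmoothed.  Frame count is never altered.
#'
#' @param track A [hand_track].
#' @param config A [filter_config].
#' @return A list with `track` (the cleaned [hand_track]) and `report`
#'   (list with `n_outliers` flagged by Hampel, `n_interpolated` gap
#'   samples filled, and per-keypoint outlier counts).
#' @export
filter_track <- function(track, config = filter_config()) {
  stopifnot(inherits(track, "hand_track"), inherits(config, "filter_config"))
  n_gated <- 0L
  if (!is.null(config$conf_min) && config$conf_min > 0) {
    gate <- !missing_landmarks(track) & track$conf < config$conf_min
    n_gated <- sum(gate)
    track$x[gate] <- NA_real_
    track$y[gate] <- NA_real_
    track$conf[gate] <- 0
  }
  n_out <- 0L
  n_interp <- 0L
  per_kp <- integer(21L)
  min_len <- 3L * config$butter_order + 2L
  for (kp in 1:21) {
    for (field in c("x", "y")) {
      s <- track[[field]][, kp]
      was_na <- is.na(s)
      if (all(was_na)) next
      s <- interpolate_gaps(s, config$max_gap)
      n_interp <- n_interp + sum(was_na & !is.na(s))
      if (config$use_hampel && sum(!is.na(s)) > 2L * config$hampel_half_window) {
        hf <- hampel_filter(s, config$hampel_half_window, config$hampel_k)
        s <- hf$filtered
        n_out <- n_out + length(hf$flagged)
        per_kp[kp] <- per_kp[kp] + length(hf$flagged)
      }
      runs <- contiguous_runs(!is.na(s))
      for (r in runs) {
        if (length(r) > min_len)
          s[r] <- butterworth_lowpass(s[r], config$butter_cutoff,
                                      config$fps, config$butter_order)
      }
      track[[field]][, kp] <- s
    }
  }
  list(track = track,
       report = list(n_outliers = n_out, n_interpolated = n_interp,
                     n_gated = n_gated, outliers_per_keypoint = per_kp))
}

# indices of maximal runs where flag is TRUE
contiguous_runs <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  lapply(which(r$values), function(i) starts[i]:ends[i])
}
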