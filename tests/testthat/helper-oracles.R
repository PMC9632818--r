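# Independent brute-force oracles used across the suite.  These
# deliberately re-derive results by a different route than the package
# (law of cosines instead of vector angles, explicit two-loop sliding
# windows instead of the production filter, closed-form hand arithmetic
# instead of vectorised code).

# vertex angle at p2 from the three side lengths (law of cosines)
law_of_cosines_angle <- function(p1, p2, p3) {
  a <- sqrt(sum((p3 - p1)^2))  # side opposite the vertex
  b <- sqrt(sum((p1 - p2)^2))
  c <- sqrt(sum((p3 - p2)^2))
  arg <- (b^2 + c^2 - a^2) / (2 * b * c)
  acos(pmin(1, pmax(-1, arg))) * 180 / pi
}

# naive two-loop Hampel: full centred windows over interior samples
# (edges pass through), NA-excluding median/MAD, replacement by the
# window median
naive_hampel <- function(x, half_window, k) {
  n <- length(x)
  y <- x
  flagged <- integer(0)
  if (n < 2 * half_window + 1) return(list(filtered = y, flagged = flagged))
  for (i in (half_window + 1):(n - half_window)) {
    if (is.na(x[i])) next
    w <- c()
    for (j in (i - half_window):(i + half_window))
      if (!is.na(x[j])) w <- c(w, x[j])
    if (length(w) <= 1) next
    m <- median(w)
    s <- 1.4826 * median(abs(w - m))
    if (abs(x[i] - m) > k * s) {
      y[i] <- m
      flagged <- c(flagged, i)
    }
  }
  list(filtered = y, flagged = flagged)
}

# random plausible hand track (no missing unless asked)
random_track <- function(n = 10, seed = 1, missing_frac = 0,
                         hand_side = "right") {
  set.seed(seed)
  x <- matrix(runif(n * 21, 0, 640), n, 21)
  y <- matrix(runif(n * 21, 0, 480), n, 21)
  conf <- matrix(runif(n * 21, 0.5, 1), n, 21)
  if (missing_frac > 0) {
    m <- matrix(runif(n * 21) < missing_frac, n, 21)
    x[m] <- NA; y[m] <- NA; conf[m] <- 0
  }
  hand_track(x, y, conf, fps = 30, hand_side = hand_side)
}

# noiseless scenario shorthand (short windows: structural checks only)
quiet_scenario <- function(activity, seed = 1, cycle_s = 2, ...) {
  synthetic_scenario(activity, cycle_s = cycle_s, jitter_sd = 0,
                     outlier_rate = 0, marker_noise_sd = 0, seed = seed,
                     ...)
}
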