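test_that("Hampel replaces an isolated spike in a constant series", {
  x <- c(5, 5, 5, 100, 5, 5, 5)
  hf <- hampel_filter(x, half_window = 3, k = 1)
  expect_equal(hf$filtered, rep(5, 7))
  expect_equal(hf$flagged, 4L)
  expect_equal(hf$replacements$frame, 3L)  # 0-based
  expect_equal(hf$replacements$original, 100)
})

test_that("Hampel passes a strictly linear ramp untouched", {
  x <- seq(0, 10, length.out = 50)
  hf <- hampel_filter(x, half_window = 4, k = 1)
  expect_equal(hf$filtered, x)
  expect_length(hf$flagged, 0L)
})

test_that("Hampel flags all 8-sigma spikes in a noisy sinusoid and
           matches the naive sliding-window oracle", {
  set.seed(42)
  n <- 497
  x <- 10 * sin(2 * pi * 0.5 * (0:(n - 1)) / 30) + rnorm(n, 0, 1)
  spikes <- sort(sample(10:(n - 10), 10))
  x[spikes] <- x[spikes] + 8 * sample(c(-1, 1), 10, replace = TRUE)
  hf <- hampel_filter(x, half_window = 4, k = 1)
  expect_true(all(spikes %in% hf$flagged))
  oracle <- naive_hampel(x, half_window = 4, k = 1)
  expect_identical(hf$filtered, oracle$filtered)
  expect_identical(hf$flagged, oracle$flagged)
})

test_that("Hampel equals the naive oracle on random series with gaps", {
  set.seed(99)
  for (i in 1:25) {
    n <- sample(20:80, 1)
    x <- cumsum(rnorm(n)) + rnorm(n, 0, 0.3)
    x[sample(n, n %/% 10)] <- NA
    w <- sample(1:5, 1); k <- runif(1, 0.5, 3)
    hf <- suppressWarnings(hampel_filter(x, w, k))
    oracle <- naive_hampel(x, w, k)
    expect_identical(hf$filtered, oracle$filtered)
    expect_identical(hf$flagged, oracle$flagged)
  }
})

test_that("Hampel is idempotent on spike-corrupted smooth series", {
  # after isolated spikes are replaced, a second pass finds nothing new
  x <- seq(0, 30, by = 0.25)
  x[c(20, 60, 100)] <- x[c(20, 60, 100)] + 50
  pass1 <- hampel_filter(x, 4, 1)
  pass2 <- hampel_filter(pass1$filtered, 4, 1)
  expect_length(pass2$flagged, 0L)
  expect_equal(pass2$filtered, pass1$filtered)
})

test_that("moving average: identity, constant, and convolution oracle", {
  x <- rnorm(40)
  expect_equal(moving_average(x, 1), x)
  expect_equal(moving_average(rep(3.3, 20), 7), rep(3.3, 20))
  sm <- moving_average(x, 5)
  for (i in seq_along(x)) {
    w <- x[max(1, i - 2):min(length(x), i + 2)]
    expect_equal(sm[i], sum(w) / length(w))
  }
  # window longer than the series: global mean everywhere
  expect_equal(moving_average(x[1:5], 99), rep(mean(x[1:5]), 5))
})

test_that("zero-phase Butterworth has unit DC gain and analytic
           attenuation at probe frequencies", {
  expect_equal(butterworth_lowpass(rep(7.5, 120), 3, 30), rep(7.5, 120),
               tolerance = 1e-9)
  t <- (0:499) / 30
  for (f in c(0.5, 3, 10)) {
    y <- butterworth_lowpass(sin(2 * pi * f * t), 3, 30, order = 2)
    idx <- 100:400
    X <- cbind(sin(2 * pi * f * t[idx]), cos(2 * pi * f * t[idx]))
    amp <- sqrt(sum(qr.solve(X, y[idx])^2))
    expect_equal(amp, butterworth_zero_phase_gain(f, 3, 30, 2),
                 tolerance = 0.02)
  }
  # 10 Hz is deep in the stop band
  y10 <- butterworth_lowpass(sin(2 * pi * 10 * t), 3, 30, order = 2)
  expect_lt(max(abs(y10[100:400])), 0.1)
})

test_that("smoothing is phase-free: the passband peak does not shift", {
  t <- (0:299) / 30
  s <- sin(2 * pi * 0.5 * t)
  y <- butterworth_lowpass(s, 3, 30)
  # peak of one interior cycle (frames 46..105 contain the peak at 76)
  expect_lte(abs(which.max(y[46:105]) - which.max(s[46:105])), 1L)
  expect_equal(max(y[46:105]), 1, tolerance = 0.02)
})

test_that("smoothing preserves the mean of a long stationary signal", {
  set.seed(8)
  x <- 50 + rnorm(2000, 0, 3)
  y <- butterworth_lowpass(x, 3, 30)
  expect_equal(mean(y), mean(x), tolerance = 0.005 * abs(mean(x)))
})

test_that("Butterworth rejects unusable configurations", {
  expect_error(butterworth_lowpass(rnorm(100), 15, 30), "Nyquist")
  expect_error(butterworth_lowpass(c(1, NA, 3), 3, 30), "missing")
  expect_error(filter_config(butter_cutoff = 20, fps = 30), "fps/2")
})

test_that("residual analysis selects the lowest cutoff for pure noise", {
  set.seed(31)
  x <- rnorm(600)
  res <- winter_residual_cutoff(x, 30)
  expect_equal(res$cutoff, 0.5)
  expect_equal(nrow(res$residuals), 20L)
  # residual curve decreases with cutoff
  expect_true(all(diff(res$residuals$rms) <= 1e-9))
})

test_that("residual analysis keeps the band of a clean sinusoid", {
  t <- (0:599) / 30
  x <- 10 * sin(2 * pi * 0.5 * t)
  res <- winter_residual_cutoff(x, 30)
  expect_lte(res$cutoff, 1)
})

test_that("residual analysis lands in a sane band for signal + noise", {
  t <- (0:599) / 30
  for (seed in 1:20) {
    set.seed(seed)
    x <- 10 * sin(2 * pi * 0.5 * t) + rnorm(600, 0, 1)
    res <- winter_residual_cutoff(x, 30)
    expect_gte(res$cutoff, 1)
    expect_lte(res$cutoff, 4)
  }
})

test_that("gap interpolation bridges short gaps only", {
  expect_equal(interpolate_gaps(c(2, NA, 4)), c(2, 3, 4))
  x <- c(NA, NA, 1, 2, NA, NA, NA, 6, 7)
  out <- interpolate_gaps(x, max_gap = 2)
  expect_true(all(is.na(out[1:2])))        # leading gap untouched
  expect_true(all(is.na(out[5:7])))        # gap of 3 > max_gap
  out2 <- interpolate_gaps(x, max_gap = 3)
  expect_equal(out2[5:7], c(3, 4, 5))
  # random masking of a linear series is restored exactly
  set.seed(4)
  lin <- seq(0, 99)
  mask <- sample(2:99, 20)
  lin_na <- lin; lin_na[mask] <- NA
  expect_equal(interpolate_gaps(lin_na, max_gap = 100), lin)
})

test_that("swap correction is an involution and restores ground truth", {
  tr <- random_track(30, seed = 13)
  expect_identical(apply_swap_correction(tr, NULL), tr)
  ev <- data.frame(start_frame = 5, end_frame = 15,
                   digit_a = "index", digit_b = "ring")
  swapped <- apply_swap_correction(tr, ev)
  expect_false(identical(swapped$x, tr$x))
  expect_identical(apply_swap_correction(swapped, ev), tr)
  # correction of an injected swap recovers the pre-injection track
  corrupted <- inject_swap(tr, "index", "ring", 5, 15)
  expect_identical(apply_swap_correction(corrupted, ev), tr)
})

test_that("swap events outside the track or with one digit are rejected", {
  tr <- random_track(10)
  expect_error(apply_swap_correction(tr, data.frame(
    start_frame = 0, end_frame = 11, digit_a = "index",
    digit_b = "ring")), "outside")
  expect_error(apply_swap_correction(tr, data.frame(
    start_frame = 0, end_frame = 5, digit_a = "index",
    digit_b = "index")), "distinct")
})

test_that("track filtering preserves frame count and gates low
           confidence", {
  set.seed(21)
  sim <- simulate_activity(hand_geometry("right"),
                           synthetic_scenario("abd_add", cycle_s = 2,
                                              seed = 77))
  ft <- filter_track(sim$track, filter_config())
  expect_equal(n_frames(ft$track), n_frames(sim$track))
  expect_gte(ft$report$n_gated, 1L)
  # injected spikes were gated or flagged rather than kept
  expect_gte(ft$report$n_gated + ft$report$n_outliers,
             nrow(sim$outliers))
})
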