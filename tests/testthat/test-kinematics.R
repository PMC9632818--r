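test_that("included angle: collinear chains read 180, right angles 90", {
  expect_equal(included_angle(c(0, 0), c(1, 0), c(2, 0)), 180)
  expect_equal(included_angle(c(0, 0), c(1, 0), c(1, 1)), 90)
  expect_true(is.na(included_angle(c(1, 1), c(1, 1), c(2, 2))))
})

test_that("included angle matches the law-of-cosines oracle", {
  set.seed(123)
  for (i in 1:1000) {
    p <- matrix(runif(6, -100, 100), 3, 2)
    expect_equal(included_angle(p[1, ], p[2, ], p[3, ]),
                 law_of_cosines_angle(p[1, ], p[2, ], p[3, ]),
                 tolerance = 1e-9)
  }
})

test_that("angles are invariant under rigid motion and uniform scale", {
  set.seed(9)
  tr <- random_track(8, seed = 9)
  cat36 <- build_angle_catalog("mcp_flexion", "right")
  a0 <- compute_catalog_angles(tr, cat36)
  th <- runif(1, 0, 2 * pi); sc <- runif(1, 0.2, 5)
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  tr2 <- tr
  tr2$x <- sc * (tr$x * R[1, 1] + tr$y * R[1, 2]) + 17
  tr2$y <- sc * (tr$x * R[2, 1] + tr$y * R[2, 2]) - 42
  expect_equal(compute_catalog_angles(tr2, cat36), a0, tolerance = 1e-9)
})

test_that("finger joint angles: extension, oracle equality, propagation", {
  # straight synthetic finger: all joints fully extended
  # all chains vertical through the wrist: fully extended digits
  n <- 4
  x <- matrix(0, n, 21); y <- matrix(0, n, 21)
  for (d in hand_digits()) {
    cols <- digit_keypoints(d)
    y[, cols] <- matrix(rep(c(10, 20, 30, 40), each = n), n, 4)
  }
  tr <- hand_track(x, y, fps = 30)
  for (d in c("index", "little")) {
    ja <- finger_joint_angles(tr, d)
    expect_equal(ja$alpha, rep(180, n), tolerance = 1e-9)
    expect_equal(ja$beta, rep(180, n), tolerance = 1e-9)
    expect_equal(ja$gamma, rep(180, n), tolerance = 1e-9)
  }
  # fabricated flexed pose equals manual per-joint included angles
  tr2 <- random_track(6, seed = 31)
  ja <- finger_joint_angles(tr2, "middle")
  cols <- digit_keypoints("middle")
  for (i in 1:6) {
    pw <- c(tr2$x[i, 1], tr2$y[i, 1])
    pm <- c(tr2$x[i, cols[1]], tr2$y[i, cols[1]])
    pp <- c(tr2$x[i, cols[2]], tr2$y[i, cols[2]])
    pd <- c(tr2$x[i, cols[3]], tr2$y[i, cols[3]])
    pt_ <- c(tr2$x[i, cols[4]], tr2$y[i, cols[4]])
    expect_equal(ja$alpha[i], included_angle(pw, pm, pp))
    expect_equal(ja$beta[i], included_angle(pm, pp, pd))
    expect_equal(ja$gamma[i], included_angle(pp, pd, pt_))
  }
  # a missing PIP wipes every angle that uses it at that frame
  tr3 <- random_track(10, seed = 5)
  pip <- digit_keypoints("index")[2]
  tr3$x[7, pip] <- NA; tr3$y[7, pip] <- NA
  ja3 <- finger_joint_angles(tr3, "index")
  expect_true(is.na(ja3$alpha[7]))
  expect_true(is.na(ja3$beta[7]))
  expect_true(is.na(ja3$gamma[7]))
  expect_false(anyNA(ja3$alpha[-7]))
})

test_that("thumb exposes MCP and IP angles only", {
  tr <- random_track(5, seed = 8)
  ja <- finger_joint_angles(tr, "thumb")
  expect_false(anyNA(ja$alpha))
  expect_false(anyNA(ja$beta))
  expect_true(all(is.na(ja$gamma)))
})

test_that("inter-digit angle: parallel 0, orthogonal 90, sweep range", {
  n <- 3
  x <- matrix(0, n, 21); y <- matrix(0, n, 21)
  ic <- digit_keypoints("index"); mc <- digit_keypoints("middle")
  x[, ic[1]] <- 10; x[, ic[4]] <- 10; y[, ic[1]] <- 0; y[, ic[4]] <- 50
  x[, mc[1]] <- 30; x[, mc[4]] <- 30; y[, mc[1]] <- 0; y[, mc[4]] <- 50
  tr <- hand_track(x, y, fps = 30)
  expect_equal(inter_digit_angle(tr, "index", "middle"), rep(0, n),
               tolerance = 1e-9)
  x[, mc[4]] <- 80; y[, mc[4]] <- 0  # middle now points along +x
  tr <- hand_track(x, y, fps = 30)
  expect_equal(inter_digit_angle(tr, "index", "middle"), rep(90, n),
               tolerance = 1e-9)
  # commanded 25 deg abduction sweep is recovered exactly without noise
  sim <- simulate_activity(hand_geometry("right"),
                           quiet_scenario("abd_add", cycle_s = 2))
  ang <- inter_digit_angle(sim$truth$clean_track, "index", "middle")
  expect_equal(max(ang) - min(ang), 25, tolerance = 1e-6)
})

test_that("angle catalogs have the published cardinalities", {
  for (hand in c("right", "left")) {
    expect_equal(nrow(build_angle_catalog("abd_add", hand)), 4L)
    expect_equal(nrow(build_angle_catalog("radial_walking", hand)), 4L)
    expect_equal(nrow(build_angle_catalog("mcp_flexion", hand)), 5L)
    expect_equal(nrow(build_angle_catalog("thumb_opposition", hand)), 5L)
  }
  expect_true(all(build_angle_catalog("abd_add", "right")$kind ==
                    "inter_digit"))
  expect_true(all(build_angle_catalog("abd_add", "right")$digit_b ==
                    "middle"))
  opp <- build_angle_catalog("thumb_opposition", "left")
  expect_true(all(opp$kind == "included_joint"))
  expect_equal(opp$joint, c("ip", "pip", "pip", "pip", "pip"))
  expect_equal(nrow(full_angle_catalog()), 36L)
  expect_error(build_angle_catalog("jazz_hands"), "unknown activity")
})

test_that("computed angles stay within [0, 180] or are missing", {
  tr <- random_track(50, seed = 77, missing_frac = 0.05)
  a <- compute_catalog_angles(tr, full_angle_catalog()[1:18, ])
  v <- a[!is.na(a)]
  expect_true(all(v >= 0 & v <= 180))
})

test_that("TAF arithmetic and its convention invariance", {
  expect_equal(total_active_flexion(rep(90, 10)), 0)
  expect_equal(total_active_flexion(c(170, 150, 110, 150, 170)), 60)
  s <- c(170, 150, 110, 150, 170)
  expect_equal(total_active_flexion(180 - s), total_active_flexion(s))
  expect_warning(out <- total_active_flexion(c(12, NA, NA)),
                 "TAF undefined")
  expect_true(is.na(out))
})

test_that("commanded MCP flexion range is recovered as TAF noiselessly", {
  sim <- simulate_activity(hand_geometry("right"),
                           quiet_scenario("mcp_flexion", cycle_s = 2))
  a <- compute_catalog_angles(sim$truth$clean_track, sim$truth$catalog)
  for (j in seq_len(ncol(a)))
    expect_equal(total_active_flexion(a[, j]), 70, tolerance = 1e-6)
})

test_that("TAF of the repetition-averaged cycle matches per-rep TAF on
           noiseless periodic data", {
  sim <- simulate_activity(hand_geometry("left"),
                           quiet_scenario("thumb_opposition", cycle_s = 2))
  a <- compute_catalog_angles(sim$truth$clean_track, sim$truth$catalog)
  segs <- sim$truth$segments
  for (j in seq_len(ncol(a)))
    expect_equal(taf_of_average_cycle(a[, j], segs), 80,
                 tolerance = 1e-6)
})
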