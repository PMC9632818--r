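test_that("zero amplitude and zero noise yield a static capture", {
  sc <- quiet_scenario("mcp_flexion", cycle_s = 1, amplitude = 0)
  sim <- simulate_activity(hand_geometry("right"), sc)
  n <- n_frames(sim$track)
  for (i in 2:n) {
    expect_identical(sim$track$x[i, ], sim$track$x[1, ])
    expect_identical(sim$track$y[i, ], sim$track$y[1, ])
  }
  expect_true(all(apply(sim$truth$angles, 2,
                        function(v) diff(range(v)) == 0)))
})

test_that("the same seed reproduces a simulation bit for bit", {
  sc <- synthetic_scenario("thumb_opposition", cycle_s = 1, seed = 314)
  geo <- hand_geometry("left")
  a <- simulate_activity(geo, sc)
  b <- simulate_activity(geo, sc)
  expect_identical(a$track, b$track)
  expect_identical(a$markers, b$markers)
  expect_identical(a$outliers, b$outliers)
})

test_that("noiseless generator -> kinematics round trip is exact to
           1e-6 degrees for every activity and hand", {
  for (hand in c("right", "left")) {
    geo <- hand_geometry(hand)
    for (act in activity_levels()) {
      sim <- simulate_activity(geo, quiet_scenario(act, cycle_s = 1))
      a <- compute_catalog_angles(sim$truth$clean_track,
                                  sim$truth$catalog)
      expect_lt(max(abs(a - sim$truth$angles)), 1e-6)
    }
  }
})

test_that("noiseless generator -> file dialects -> projection ->
           kinematics reproduces commanded angles", {
  geo <- hand_geometry("right")
  sim <- simulate_activity(geo, quiet_scenario("abd_add", cycle_s = 1))
  dir <- withr::local_tempdir()
  # markerless path through the pose-JSON dialect
  paths <- write_pose_json(sim$truth$clean_track, file.path(dir, "pose"))
  ml <- read_pose_json(paths, "right")
  a_ml <- compute_catalog_angles(ml, sim$truth$catalog)
  expect_lt(max(abs(a_ml - sim$truth$angles)), 1e-3)
  # marker path through the TSV dialect and orthographic projection
  write_marker_tsv(sim$markers, file.path(dir, "markers.tsv"))
  mk <- read_marker_tsv(file.path(dir, "markers.tsv"))
  tr <- project_markers(mk, projection(scale = 1))
  a_mk <- compute_catalog_angles(tr, sim$truth$catalog)
  expect_lt(max(abs(a_mk - sim$truth$angles)), 1e-3)
})

test_that("ground-truth TAF equals the commanded amplitude", {
  for (act in activity_levels()) {
    sim <- simulate_activity(hand_geometry("right"),
                             quiet_scenario(act, cycle_s = 1))
    amp <- switch(act, abd_add = 25, radial_walking = 20,
                  mcp_flexion = 70, thumb_opposition = 80)
    expect_equal(sim$truth$taf$taf, rep(amp, nrow(sim$truth$taf)),
                 tolerance = 1e-9)
  }
})

test_that("outlier injection obeys its rate and returns truth", {
  tr <- random_track(500, seed = 2)
  same <- inject_outliers(tr, 0, 16, seed = 5)
  expect_identical(same$track, tr)
  expect_equal(nrow(same$injected), 0L)
  one <- random_track(1, seed = 3)
  all_hit <- inject_outliers(one, 1, 16, seed = 6)
  expect_equal(nrow(all_hit$injected), 21L)
  disp <- sqrt((all_hit$track$x - one$x)^2 + (all_hit$track$y - one$y)^2)
  expect_equal(unname(disp[1, ]), rep(16, 21), tolerance = 1e-9)
  # binomial count within 3 sigma at rate 0.02 over 500 x 21 trials
  inj <- inject_outliers(tr, 0.02, 16, seed = 7)$injected
  ntrials <- 500 * 21
  expect_lt(abs(nrow(inj) - 0.02 * ntrials),
            3 * sqrt(ntrials * 0.02 * 0.98))
})

test_that("digit swap corruption: involution and angle signature", {
  # abduction moves index and middle differently, so a swap changes
  # per-digit angles while the symmetric pair angle is untouched
  sim <- simulate_activity(hand_geometry("right"),
                           quiet_scenario("abd_add", cycle_s = 1))
  tr <- sim$truth$clean_track
  sw <- inject_swap(tr, "index", "middle", 10, 20)
  expect_identical(inject_swap(sw, "index", "middle", 10, 20), tr)
  # the pairwise inter-digit angle is symmetric under the swap ...
  expect_equal(inter_digit_angle(sw, "index", "middle"),
               inter_digit_angle(tr, "index", "middle"), tolerance = 1e-12)
  # ... but per-digit angles differ wherever the digits differ
  a0 <- finger_joint_angles(tr, "index")$alpha
  a1 <- finger_joint_angles(sw, "index")$alpha
  expect_true(any(abs(a0[11:20] - a1[11:20]) > 1))
  expect_equal(a0[-(11:20)], a1[-(11:20)])
})

test_that("occlusion windows blank the targeted digit and propagate", {
  tr <- random_track(50, seed = 12)
  expect_identical(inject_occlusion(tr, NULL), tr)
  occ <- inject_occlusion(tr, data.frame(start_frame = 0, end_frame = 50,
                                         digit = "ring"))
  expect_true(all(missing_landmarks(occ)[, digit_keypoints("ring")]))
  # 20% window: exactly those frames go missing downstream
  occ2 <- inject_occlusion(tr, data.frame(start_frame = 10,
                                          end_frame = 20,
                                          digit = "index"))
  ja <- finger_joint_angles(occ2, "index")
  expect_true(all(is.na(ja$beta[11:20])))
  expect_false(anyNA(ja$beta[-(11:20)]))
  expect_error(
    inject_occlusion(tr, data.frame(start_frame = 40, end_frame = 60,
                                    digit = "index")), "outside")
})

test_that("a session stitches activities with consistent annotations", {
  ses <- simulate_session("P01", "right", seed = 99, cycle_s = 1)
  expect_equal(nrow(ses$segments), 4L + 2L + 2L + 2L)
  expect_equal(max(ses$segments$end_frame), n_frames(ses$track))
  expect_equal(dim(ses$markers$positions)[1], n_frames(ses$track))
  expect_equal(nrow(ses$swaps), 1L)
  # swap annotation points into the mcp_flexion block
  mcp <- ses$segments[ses$segments$activity == "mcp_flexion", ]
  expect_gte(ses$swaps$start_frame, min(mcp$start_frame))
  expect_lte(ses$swaps$end_frame, max(mcp$end_frame))
})
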