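test_that("toe height is the toe z minus the surface", {
  t <- c(0, 0.005)
  mts <- make_markers(t, list(R_TOE = c(0.3, -0.1, 0.02),
                              R_HEEL = c(0.1, -0.1, 0.02)))
  expect_equal(toe_height(mts)$toe_height, c(0.02, 0.02))
  expect_equal(toe_height(mts, surface = 0.01)$toe_height, c(0.01, 0.01))
  expect_error(toe_height(make_markers(t, list(R_HEEL = c(0, 0, 0)))),
               class = "gaitvar_schema_error")
})

test_that("synthetic swing peak matches the clearance template within 1 mm", {
  sim <- clean_sim()
  th <- toe_height(sim$markers)  # raw, zero noise
  expect_equal(max(th$toe_height), 0.122, tolerance = 0.001)
})

test_that("trunk angle geometry is correct", {
  t <- 0
  up <- make_markers(t, list(
    R_ACROMION = c(0, -0.17, 1.4), L_ACROMION = c(0, 0.17, 1.4),
    R_TROCHANTER = c(0, -0.10, 0.9), L_TROCHANTER = c(0, 0.10, 0.9)))
  expect_equal(trunk_angle(up)$trunk_angle, 0)
  lean <- make_markers(t, list(
    R_ACROMION = c(0.5, -0.17, 1.4), L_ACROMION = c(0.5, 0.17, 1.4),
    R_TROCHANTER = c(0, -0.10, 0.9), L_TROCHANTER = c(0, 0.10, 0.9)))
  expect_equal(suppressWarnings(trunk_angle(lean))$trunk_angle, 45)
  degen <- make_markers(t, list(
    R_ACROMION = c(0, -0.17, 0.9), L_ACROMION = c(0, 0.17, 0.9),
    R_TROCHANTER = c(0, -0.10, 0.9), L_TROCHANTER = c(0, 0.10, 0.9)))
  expect_error(trunk_angle(degen), class = "gaitvar_degenerate_geometry_error")
})

test_that("joint angles are zero on the standing reference itself", {
  sim <- clean_sim()
  ang <- joint_angles(sim$standing, sim$standing)
  expect_equal(unlist(ang[c("trunk", "hip", "knee", "ankle")]),
               c(trunk = 0, hip = 0, knee = 0, ankle = 0))
})

test_that("recovered knee curve matches the generator template", {
  sim <- cached_sim("pure-angles", n_strides = 6, seed = 3,
                    marker_noise_sd = 0, angle_amp_cv = 0, trunk_sway_sd = 0)
  ang <- joint_angles(sim$markers, sim$standing)
  cyc <- normalize_cycles(ang$knee, ang$time, sim$truth$events, "knee")
  mean_curve <- tapply(cyc$value, cyc$phase, mean)
  tpl <- angle_template(0:100, default_angle_coeffs()$knee)
  expect_lt(sqrt(mean((mean_curve - tpl)^2)), 0.5)
})

test_that("angles transform correctly under global rotation and translation", {
  sim <- clean_sim()
  stand <- sim$standing
  ref <- joint_angles(stand, stand)
  # translate all markers: nothing changes
  shifted <- tibble::as_tibble(stand)
  for (cc in setdiff(names(shifted), "time")) {
    shifted[[cc]] <- shifted[[cc]] +
      switch(substr(cc, nchar(cc), nchar(cc)), x = 1.5, y = -0.3, z = 0.2)
  }
  shifted <- gait_markers(shifted, frame_rate = 200, validate = FALSE)
  ang_t <- joint_angles(shifted, stand)
  expect_equal(unlist(ang_t[c("trunk", "hip", "knee", "ankle")]),
               unlist(ref[c("trunk", "hip", "knee", "ankle")]),
               tolerance = 1e-9)
  # rotate 10 degrees about y (sagittal plane): trunk picks up 10 degrees,
  # the inter-segment hip/knee/ankle angles do not move
  th <- 10 * pi / 180
  rot <- tibble::as_tibble(stand)
  nms <- marker_names(stand)
  for (nm in nms) {
    x <- rot[[paste0(nm, "_x")]]
    z <- rot[[paste0(nm, "_z")]]
    rot[[paste0(nm, "_x")]] <- x * cos(th) + z * sin(th)
    rot[[paste0(nm, "_z")]] <- -x * sin(th) + z * cos(th)
  }
  rot <- gait_markers(rot, frame_rate = 200, validate = FALSE)
  ang_r <- joint_angles(rot, stand)
  expect_equal(abs(ang_r$trunk), 10, tolerance = 1e-9)
  expect_equal(c(ang_r$hip, ang_r$knee, ang_r$ankle), c(0, 0, 0),
               tolerance = 1e-9)
})

test_that("time_normalize is exact on linear and constant signals", {
  t <- seq(0, 2, by = 0.005)
  row <- time_normalize(t, t, 0.4, 1.5)
  expect_equal(row, seq(0.4, 1.5, length.out = 101))
  expect_equal(time_normalize(rep(3, length(t)), t, 0.4, 1.5), rep(3, 101))
  expect_error(time_normalize(t, t, -0.5, 1.5), "span")
})

test_that("time_normalize resolves one period of a stride-locked sinusoid", {
  fs <- 200
  t <- seq(0, 3, by = 1 / fs)
  t0 <- 0.8; t1 <- 1.9
  x <- sin(2 * pi * (t - t0) / (t1 - t0))
  row <- time_normalize(x, t, t0, t1)
  ref <- sin(2 * pi * (0:100) / 100)
  expect_lt(max(abs(row - ref)), 1e-4)
})

test_that("normalized cycles have 101 points and stitch across strides", {
  sim <- clean_sim()
  th <- toe_height(sim$markers)
  cyc <- normalize_cycles(th$toe_height, th$time, sim$truth$events,
                          "toe_height")
  expect_true(all(table(cyc$stride) == 101))
  ends <- cyc$value[cyc$phase == 100]
  starts <- cyc$value[cyc$phase == 0]
  n <- length(ends)
  expect_equal(ends[-n], starts[-1], tolerance = 1e-9)
})

test_that("comparison grids are the protocol grids", {
  expect_equal(swing_grid(), seq(55L, 100L, by = 5L))
  expect_length(swing_grid(), 10)
  expect_equal(full_cycle_grid(), seq(10L, 100L, by = 10L))
  expect_length(full_cycle_grid(), 10)
})

test_that("extract_grid selects exactly the requested phases", {
  sim <- clean_sim()
  th <- toe_height(sim$markers)
  cyc <- normalize_cycles(th$toe_height, th$time, sim$truth$events, "toe")
  sub <- extract_grid(cyc, swing_grid())
  expect_setequal(unique(sub$phase), swing_grid())
  hs_col <- extract_grid(cyc, 0)
  expect_true(all(hs_col$phase == 0))
  expect_error(extract_grid(cyc, 62.5), "integer")
})
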