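test_that("generation is deterministic for a fixed seed", {
  a <- generate_gait(gait_params(n_strides = 4, seed = 11))
  b <- generate_gait(gait_params(n_strides = 4, seed = 11))
  expect_identical(a$markers, b$markers)
  expect_identical(a$truth$events, b$truth$events)
  c <- generate_gait(gait_params(n_strides = 4, seed = 12))
  expect_false(identical(a$markers, c$markers))
})

test_that("zero-variability generation gives identical normalized strides", {
  sim <- cached_sim("frozen6", n_strides = 6, seed = 5, marker_noise_sd = 0,
                    sd_cycle_duration = 0, sd_stride_length = 0,
                    angle_amp_cv = 0, trunk_sway_sd = 0)
  th <- toe_height(sim$markers)
  cyc <- normalize_cycles(th$toe_height, th$time, sim$truth$events,
                          signal = "toe_height")
  spread <- tapply(cyc$value, cyc$phase, function(v) max(v) - min(v))
  expect_lt(max(spread), 1e-9)
  prof <- mad_profile(cyc, grid = swing_grid())
  expect_lt(max(prof$mad), 1e-9)
})

test_that("injected toe deviations reproduce the target MAD at the source", {
  # Monte-Carlo oracle on the injected deviations themselves (no pipeline)
  prm <- gait_params(n_strides = 200, seed = 31,
                     toe_noise_spec = data.frame(phase = 90,
                                                 target_mad_m = 0.0088))
  sim <- generate_gait(prm)
  tm <- sim$truth$true_mad
  expect_equal(tm$true_mad_m[tm$phase == 90], 0.0088, tolerance = 0.10)
  # "expected" calibration draws sigma = target*sqrt(pi/2) without rescaling
  prm2 <- gait_params(n_strides = 200, seed = 31, calibrate = "expected",
                      toe_noise_spec = data.frame(phase = 90,
                                                  target_mad_m = 0.0088))
  sim2 <- generate_gait(prm2)
  tm2 <- sim2$truth$true_mad
  expect_equal(tm2$true_mad_m[tm2$phase == 90], 0.0088, tolerance = 0.10)
  # sample calibration is exact by construction
  expect_equal(tm$true_mad_m[tm$phase == 90], 0.0088, tolerance = 1e-9)
})

test_that("ground-truth cycle durations converge to the generator mean", {
  sim <- cached_sim("long500", n_strides = 500, seed = 8)
  durs <- sim$truth$events$cycle_duration
  sem <- 0.02 / sqrt(500)
  expect_lt(abs(mean(durs) - 1.10), 2 * sem)
})

test_that("toe height never penetrates the ground beyond 1 mm", {
  # the underlying trajectory cannot cross the surface; additive
  # measurement noise may dip below it by a few noise SDs at most
  z <- marker_xyz(clean_sim()$markers, "R_TOE")[, "z"]
  expect_gte(min(z), -0.001)
  zn <- marker_xyz(noisy_sim()$markers, "R_TOE")[, "z"]
  expect_gte(min(zn), -0.001 - 5 * 0.0005)
})

test_that("legs are half a cycle out of phase", {
  sim <- clean_sim()
  ev <- sim$truth$events
  left <- sim$truth$left_hs_times
  # exactly one left heel strike near the middle of every right stride
  for (k in seq_len(nrow(ev))) {
    inside <- left[left > ev$hs_time[k] & left < ev$next_hs_time[k]]
    expect_length(inside, 1)
    frac <- (inside - ev$hs_time[k]) / ev$cycle_duration[k]
    expect_lt(abs(frac - 0.5), 0.05)
  }
})

test_that("ground-truth toe-off phase is consistent with 60% stance", {
  sim <- clean_sim()
  expect_gt(sim$truth$toe_off_phase, 55)
  expect_lt(sim$truth$toe_off_phase, 70)
})

test_that("angle templates are periodic, smooth and shaped as documented", {
  co <- default_angle_coeffs()
  expect_equal(angle_template(0, co$knee), angle_template(100, co$knee))
  const <- list(a0 = 7, a = 0, b = 0)
  expect_equal(angle_template(c(0, 33, 100), const), rep(7, 3))
  expect_error(angle_template(101, co$hip), "0, 100")
  # knee swing-phase maximum in (60, 80)% of cycle
  g <- seq(0, 100, by = 0.1)
  peak <- g[which.max(angle_template(g, co$knee))]
  expect_gt(peak, 60)
  expect_lt(peak, 80)
})

test_that("forward_chain respects rigid-body geometry", {
  sl <- list(thigh = 0.41, shank = 0.41, trunk = 0.48)
  stand <- forward_chain(list(x = 0, z = 0.9, angle = 0),
                         list(hip = 0, knee = 0), sl)
  # all angles zero: leg markers vertically stacked under the trochanter
  expect_equal(stand$x, rep(0, 4), tolerance = 1e-12)
  expect_equal(stand$z[stand$marker == "KNEE"], 0.9 - 0.41)
  expect_equal(stand$z[stand$marker == "MALLEOLUS"], 0.9 - 0.82)
  # hip flexion 90 degrees: knee displaced horizontally by thigh length
  flex <- forward_chain(list(x = 0, z = 0.9, angle = 0),
                        list(hip = 90, knee = 0), sl)
  expect_equal(flex$x[flex$marker == "KNEE"], 0.41, tolerance = 1e-12)
  expect_equal(flex$z[flex$marker == "KNEE"], 0.9, tolerance = 1e-12)
  # random poses: segment lengths invariant to 1e-12
  set.seed(1)
  for (i in 1:20) {
    pose <- forward_chain(list(x = runif(1, -1, 1), z = runif(1, 0.5, 1.2),
                               angle = runif(1, -20, 20)),
                          list(hip = runif(1, -30, 90), knee = runif(1, 0, 120)),
                          sl)
    d <- function(a, b) {
      i1 <- pose$marker == a; i2 <- pose$marker == b
      sqrt((pose$x[i1] - pose$x[i2])^2 + (pose$z[i1] - pose$z[i2])^2)
    }
    expect_equal(d("TROCHANTER", "KNEE"), sl$thigh, tolerance = 1e-12)
    expect_equal(d("KNEE", "MALLEOLUS"), sl$shank, tolerance = 1e-12)
    expect_equal(d("TROCHANTER", "ACROMION"), sl$trunk, tolerance = 1e-12)
  }
  expect_error(forward_chain(list(x = 0, z = 1, angle = 0),
                             list(hip = 0, knee = 0),
                             list(thigh = -1, shank = 0.4, trunk = 0.5)),
               "> 0")
})

test_that("raised-cosine envelope peaks at 1 and vanishes off support", {
  expect_equal(raised_cosine_envelope(65, 65, width = 25), 1)
  expect_equal(raised_cosine_envelope(c(52.4, 77.6), 65, width = 25), c(0, 0))
  w <- raised_cosine_envelope(seq(0, 100, 0.5), 65, width = 25)
  expect_true(all(w >= 0 & w <= 1))
})

test_that("parameterization errors are raised", {
  expect_error(gait_params(toe_noise_spec = data.frame(phase = 120,
                                                       target_mad_m = 0.001)),
               class = "gaitvar_parameterization_error")
  expect_error(gait_params(noise_envelope_width = 0,
                           toe_noise_spec = data.frame(phase = 90,
                                                       target_mad_m = 0.001)),
               class = "gaitvar_parameterization_error")
  expect_error(gait_params(mean_cycle_duration = 0.05, frame_rate = 100),
               "frames per cycle")
  expect_error(gait_params(n_strides = 1), ">= 2")
})

test_that("condition presets differ only in variability", {
  off <- condition_params("OFF")
  on <- condition_params("ON")
  expect_equal(off$mean_cycle_duration, on$mean_cycle_duration)
  expect_equal(off$mean_stride_length, on$mean_stride_length)
  expect_true(all(on$toe_noise_spec$target_mad_m <
                    off$toe_noise_spec$target_mad_m))
  expect_lt(on$trunk_sway_sd, off$trunk_sway_sd)
})
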