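#' Synthetic treadmill-gait parameters
#'
#' Builds the parameter set for the synthetic treadmill-walking generator.
#' Defaults emulate the study conditions the package targets: belt speed
#' 1.1 m/s (4 km/h), mean cycle duration 1.10 s, mean stride length 1.22 m,
#' 200 Hz capture, segment lengths scaled from a 1.68 m stature with standard
#' anthropometric fractions (thigh 0.245 H, shank 0.246 H, foot 0.152 H,
#' trunk 0.288 H).
#'
#' Stride-to-stride randomness is injected three ways: cycle duration and
#' stride length are drawn independently Normal per stride; toe height
#' receives phase-localized deviations `a_s * w(phase)` per stride, where
#' `w` is a raised-cosine envelope centered on each `toe_noise_spec` phase
#' and `a_s` is Normal with scale calibrated so the MAD of the injected
#' deviations at the center phase equals the requested target (see
#' `calibrate`); and per-stride amplitude jitter multiplies the joint-angle
#' templates and offsets the trunk angle.
#'
#' @param belt_speed Treadmill belt speed, m/s.
#' @param mean_cycle_duration,sd_cycle_duration Per-stride cycle duration
#'   mean and SD, seconds.
#' @param mean_stride_length,sd_stride_length Per-stride stride length mean
#'   and SD, meters.
#' @param n_strides Number of complete strides to generate (>= 2).
#' @param frame_rate Sampling rate, Hz.
#' @param stance_fraction Nominal stance fraction of the cycle (toe-off
#'   near this phase).
#' @param height Stature in meters used to derive `segment_lengths`.
#' @param segment_lengths Named list `thigh`, `shank`, `foot`, `trunk` (m);
#'   derived from `height` when `NULL`.
#' @param angle_coeffs Fourier templates as from [default_angle_coeffs()].
#' @param angle_amp_cv Coefficient of variation of the per-stride amplitude
#'   multiplier applied to hip/knee/ankle templates.
#' @param trunk_sway_sd SD (degrees) of the per-stride trunk-angle offset.
#' @param toe_noise_spec Data frame with columns `phase` (percent of cycle)
#'   and `target_mad_m` (meters): target MAD of injected toe-height
#'   deviations at each phase. `NULL` or zero rows injects none.
#' @param noise_envelope_width Full support of the raised-cosine envelope,
#'   percent of cycle.
#' @param calibrate `"sample"` (default) rescales the drawn amplitudes so
#'   their realized sample MAD equals the target exactly; `"expected"` uses
#'   the closed-form scale `sigma = target * sqrt(pi/2)` so the target holds
#'   in expectation only.
#' @param marker_noise_sd White measurement noise SD added to every
#'   coordinate before any filtering, meters.
#' @param seed Integer seed; generation is bit-reproducible for a fixed seed.
#' @return A `gait_params` list.
#' @export
gait_params <- function(belt_speed = 1.1,
                        mean_cycle_duration = 1.10,
                        sd_cycle_duration = 0.02,
                        mean_stride_length = 1.22,
                        sd_stride_length = 0.02,
                        n_strides = 50,
                        frame_rate = 200,
                        stance_fraction = 0.60,
                        height = 1.68,
                        segment_lengths = NULL,
                        angle_coeffs = default_angle_coeffs(),
                        angle_amp_cv = 0.03,
                        trunk_sway_sd = 0.3,
                        toe_noise_spec = NULL,
                        noise_envelope_width = 25,
                        calibrate = c("sample", "expected"),
                        marker_noise_sd = 0.0005,
                        seed = 1L) {
  calibrate <- match.arg(calibrate)
  if (belt_speed < 0) abort("`belt_speed` must be >= 0.")
  if (mean_cycle_duration <= 0) abort("`mean_cycle_duration` must be > 0.")
  if (n_strides < 2) abort("`n_strides` must be >= 2.")
  if (sd_cycle_duration < 0 || sd_stride_length < 0 || angle_amp_cv < 0 ||
      trunk_sway_sd < 0 || marker_noise_sd < 0) {
    abort("SD parameters must be >= 0.")
  }
  if (mean_cycle_duration * frame_rate < 20) {
    abort("Stride too short for the frame rate: need >= 20 frames per cycle.")
  }
  if (stance_fraction <= 0.3 || stance_fraction >= 0.8) {
    abort("`stance_fraction` must lie in (0.3, 0.8).")
  }
  if (is.null(segment_lengths)) {
    segment_lengths <- list(thigh = 0.245 * height, shank = 0.246 * height,
                            foot = 0.152 * height, trunk = 0.288 * height)
  }
  if (any(unlist(segment_lengths) <= 0)) abort("Segment lengths must be > 0.")
  if (!is.null(toe_noise_spec)) {
    toe_noise_spec <- as_tibble(toe_noise_spec)
    stopifnot(all(c("phase", "target_mad_m") %in% names(toe_noise_spec)))
    if (noise_envelope_width <= 0) {
      abort("Requested toe-noise target with a zero-width envelope.",
            class = "gaitvar_parameterization_error")
    }
    if (any(toe_noise_spec$phase < 0 | toe_noise_spec$phase > 100)) {
      abort("`toe_noise_spec$phase` must lie in [0, 100].",
            class = "gaitvar_parameterization_error")
    }
    if (any(toe_noise_spec$target_mad_m < 0)) {
      abort("`target_mad_m` must be >= 0.")
    }
  }
  structure(list(
    belt_speed = belt_speed,
    mean_cycle_duration = mean_cycle_duration,
    sd_cycle_duration = sd_cycle_duration,
    mean_stride_length = mean_stride_length,
    sd_stride_length = sd_stride_length,
    n_strides = as.integer(n_strides),
    frame_rate = frame_rate,
    stance_fraction = stance_fraction,
    height = height,
    segment_lengths = segment_lengths,
    angle_coeffs = angle_coeffs,
    angle_amp_cv = angle_amp_cv,
    trunk_sway_sd = trunk_sway_sd,
    toe_noise_spec = toe_noise_spec,
    noise_envelope_width = noise_envelope_width,
    calibrate = calibrate,
    marker_noise_sd = marker_noise_sd,
    seed = as.integer(seed)
  ), class = "gait_params")
}

#' Condition presets for the two-condition design
#'
#' Returns [gait_params()] presets emulating the OFF (no vibration) and ON
#' (vibration) conditions: identical means everywhere, with the ON condition
#' differing only in smaller injected toe-height variability and smaller
#' trunk-sway variability. The preset toe-noise targets follow the reported
#' swing-phase MAD pattern (OFF 2.2/4.9/8.8/8.8 mm and ON 1.8/4.4/7.2/7.2 mm
#' at 65/70/90/95% of the cycle). Overlapping envelopes superpose, so with
#' several active bumps the realized per-point MAD exceeds each individual
#' target (in quadrature); use a single-entry `toe_noise_spec` when exact
#' per-point calibration is needed.
#'
#' @param condition `"OFF"` or `"ON"`.
#' @param ... Overrides passed on to [gait_params()].
#' @return A `gait_params` list.
#' @export
condition_params <- function(condition = c("OFF", "ON"), ...) {
  condition <- match.arg(condition)
  spec <- if (condition == "OFF") {
    tibble(phase = c(65, 70, 90, 95),
           target_mad_m = c(0.0022, 0.0049, 0.0088, 0.0088))
  } else {
    tibble(phase = c(65, 70, 90, 95),
           target_mad_m = c(0.0018, 0.0044, 0.0072, 0.0072))
  }
  sway <- if (condition == "OFF") 0.30 else 0.24
  gait_params(toe_noise_spec = spec, trunk_sway_sd = sway, ...)
}

#' Sagittal forward kinematic chain for one side
#'
#' Places trochanter, knee, malleolus and acromion in the sagittal (x-z)
#' plane from a trunk pose and joint angles. Angles are measured from the
#' vertical: `hip` is the thigh angle (flexion positive, thigh forward),
#' `knee` is knee flexion (shank angle = hip - knee), and the trunk segment
#' leans forward by `trunk_angle`.
#'
#' @param trunk_pose List with `x`, `z` (trochanter-midpoint position, m)
#'   and `angle` (trunk lean from vertical, degrees, forward positive).
#' @param joint_angles List with `hip` and `knee` in degrees.
#' @param segment_lengths List with `thigh`, `shank`, `trunk` in meters.
#' @return Tibble with columns `marker`, `x`, `z`.
#' @export
#' @examples
#' forward_chain(list(x = 0, z = 0.9, angle = 0),
#'               list(hip = 0, knee = 0),
#'               list(thigh = 0.41, shank = 0.41, trunk = 0.48))
forward_chain <- function(trunk_pose, joint_angles, segment_lengths) {
  sl <- segment_lengths
  if (any(unlist(sl[c("thigh", "shank", "trunk")]) <= 0)) {
    abort("Segment lengths must be > 0.")
  }
  stopifnot(all(is.finite(unlist(trunk_pose))), all(is.finite(unlist(joint_angles))))
  d2r <- pi / 180
  th_tr <- trunk_pose$angle * d2r
  th_h <- joint_angles$hip * d2r
  th_s <- (joint_angles$hip - joint_angles$knee) * d2r
  troch <- c(trunk_pose$x, trunk_pose$z)
  acrom <- troch + sl$trunk * c(sin(th_tr), cos(th_tr))
  knee <- troch + sl$thigh * c(sin(th_h), -cos(th_h))
  mall <- knee + sl$shank * c(sin(th_s), -cos(th_s))
  tibble(marker = c("TROCHANTER", "KNEE", "MALLEOLUS", "ACROMION"),
         x = c(troch[1], knee[1], mall[1], acrom[1]),
         z = c(troch[2], knee[2], mall[2], acrom[2]))
}

# quintic Hermite blend with zero end accelerations:
# X(0)=x1, X(1)=x2, X'(0)=m0, X'(1)=m1, X''(0)=X''(1)=0
quintic_blend <- function(tau, x1, x2, m0, m1) {
  h00 <- 1 - 10 * tau^3 + 15 * tau^4 - 6 * tau^5
  h01 <- 10 * tau^3 - 15 * tau^4 + 6 * tau^5
  h10 <- tau - 6 * tau^3 + 8 * tau^4 - 3 * tau^5
  h11 <- -4 * tau^3 + 7 * tau^4 - 3 * tau^5
  h00 * x1 + h01 * x2 + h10 * m0 + h11 * m1
}

#' Generate synthetic treadmill-walking marker trajectories
#'
#' Produces a full 14-marker trajectory set with known ground truth. Distal
#' markers (heel, toe, 5th metatarsal) are synthesized directly from
#' contact/clearance templates for exact control of event times and injected
#' variability; proximal markers (knee, trochanter, acromion, malleolus)
#' come from a rigid sagittal kinematic chain driven by the angle templates.
#' The two legs are half a cycle out of phase; horizontal positions include
#' the belt-induced backward drift during stance. Strict dynamic consistency
#' between the distal templates and the chain is not claimed.
#'
#' @param params A [gait_params()] list.
#' @return A list of class `gait_sim` with elements `markers` (a
#'   [gait_markers] tibble), `standing` (one-row [gait_markers] reference in
#'   the zero-angle pose) and `truth` (list with per-stride `events`
#'   — heel-strike/toe-off times, durations, stride lengths —, the injected
#'   toe deviations `deviations`, their exact per-phase MAD `true_mad`, left
#'   heel-strike times, and the parameters).
#' @export
#' @examples
#' sim <- generate_gait(gait_params(n_strides = 4, seed = 7))
#' sim$truth$events
generate_gait <- function(params) {
  stopifnot(inherits(params, "gait_params"))
  p <- params
  set.seed(p$seed)
  n <- p$n_strides
  fs <- p$frame_rate
  v <- p$belt_speed

  # per-stride draws
  Tn <- rnorm(n, p$mean_cycle_duration, p$sd_cycle_duration)
  Tn <- pmax(Tn, 0.5 * p$mean_cycle_duration)
  Ln <- rnorm(n, p$mean_stride_length, p$sd_stride_length)
  Ln <- pmax(Ln, 0.1 * p$mean_stride_length)

  # toe deviation amplitudes, one column per noise-spec entry
  spec <- p$toe_noise_spec
  n_spec <- if (is.null(spec)) 0L else nrow(spec)
  amp <- matrix(0, nrow = n, ncol = max(n_spec, 1L))
  if (n_spec > 0) {
    for (j in seq_len(n_spec)) {
      target <- spec$target_mad_m[j]
      a <- rnorm(n, 0, target * sqrt(pi / 2))
      if (p$calibrate == "sample" && target > 0) {
        m <- mean(abs(a - mean(a)))
        if (m > 0) a <- a * (target / m)
      }
      amp[, j] <- a
    }
  }
  amp_hip <- rnorm(n, 1, p$angle_amp_cv)
  amp_knee <- rnorm(n, 1, p$angle_amp_cv)
  amp_ankle <- rnorm(n, 1, p$angle_amp_cv)
  trunk_off <- rnorm(n, 0, p$trunk_sway_sd)

  # event times and contact positions (right foot), with one virtual stride
  # prepended/appended so the record has a lead-in and lead-out
  lead <- 0.25
  hs <- lead + c(0, cumsum(Tn))              # n + 1 right heel strikes
  ev <- c(hs[1] - Tn[1], hs, hs[n + 1] + Tn[n])
  xc <- c(0, cumsum(Ln - v * Tn))            # contact x at each hs
  xc_ext <- c(xc[1] - (Ln[1] - v * Tn[1]), xc, xc[n + 1] + (Ln[n] - v * Tn[n]))
  dur_ext <- diff(ev)                        # n + 2 stride durations
  amp_ext <- rbind(0, amp, 0)
  amp_hip_e <- c(amp_hip[1], amp_hip, amp_hip[n])
  amp_knee_e <- c(amp_knee[1], amp_knee, amp_knee[n])
  amp_ankle_e <- c(amp_ankle[1], amp_ankle, amp_ankle[n])
  trunk_off_e <- c(0, trunk_off, 0)

  t_end <- hs[n + 1] + lead
  time <- seq(0, t_end, by = 1 / fs)
  nf <- length(time)

  clear_tpl <- clearance_template_fun()
  heel_tpl <- heel_template_fun()

  sidx <- findInterval(time, ev)             # 1 .. n + 2
  sidx[sidx < 1] <- 1L
  sidx[sidx > n + 2] <- n + 2L
  t0 <- ev[sidx]
  D <- dur_ext[sidx]
  phase <- pmin(100 * (time - t0) / D, 100)
  xc_s <- xc_ext[sidx]
  xc_next <- xc_ext[sidx + 1]

  foot_len <- p$segment_lengths$foot

  right <- foot_track(time, phase, t0, D, xc_s, xc_next, v, foot_len,
                      clear_tpl, heel_tpl)
  # injected toe deviations
  if (n_spec > 0) {
    dev <- numeric(nf)
    for (j in seq_len(n_spec)) {
      dev <- dev + amp_ext[sidx, j] *
        raised_cosine_envelope(phase, spec$phase[j], p$noise_envelope_width)
    }
    right$toe_z <- right$toe_z + dev
  }

  # left foot: events at right mid-stride
  ev_l <- ev[-length(ev)] + dur_ext / 2
  ev_l <- c(ev_l[1] - dur_ext[1], ev_l, ev_l[length(ev_l)] + dur_ext[n + 2])
  xc_l <- (xc_ext + c(xc_ext[-1], xc_ext[n + 3] + (Ln[n] - v * Tn[n]))) / 2
  xc_l <- c(xc_l[1] - (Ln[1] - v * Tn[1]), xc_l)
  dur_l <- diff(ev_l)
  sidx_l <- findInterval(time, ev_l)
  sidx_l[sidx_l < 1] <- 1L
  sidx_l[sidx_l > length(dur_l)] <- length(dur_l)
  phase_l <- pmin(pmax(100 * (time - ev_l[sidx_l]) / dur_l[sidx_l], 0), 100)
  left <- foot_track(time, phase_l, ev_l[sidx_l], dur_l[sidx_l],
                     xc_l[sidx_l], xc_l[sidx_l + 1], v, foot_len,
                     clear_tpl, heel_tpl)

  # trunk / pelvis
  sl <- p$segment_lengths
  troch_z0 <- 0.06 + sl$shank + sl$thigh
  knots_t <- (ev[-length(ev)] + ev[-1]) / 2
  knots_x <- (xc_ext[-length(xc_ext)] + xc_ext[-1]) / 2
  pel_fun <- splinefun(knots_t, knots_x, method = "natural")
  pel_x <- pel_fun(time) + 0.005 * sin(4 * pi * phase / 100)
  pel_z <- troch_z0 - 0.010 + 0.012 * cos(4 * pi * (phase - 5) / 100)
  d2r <- pi / 180
  th_trunk <- (angle_template(phase, p$angle_coeffs$trunk) +
                 trunk_off_e[sidx]) * d2r
  acr_x <- pel_x + sl$trunk * sin(th_trunk)
  acr_z <- pel_z + sl$trunk * cos(th_trunk)

  # legs from the chain
  th_hip_r <- angle_template(phase, p$angle_coeffs$hip) * amp_hip_e[sidx] * d2r
  th_knee_r <- pmax(angle_template(phase, p$angle_coeffs$knee), 0) *
    amp_knee_e[sidx] * d2r
  th_shank_r <- th_hip_r - th_knee_r
  knee_rx <- pel_x + sl$thigh * sin(th_hip_r)
  knee_rz <- pel_z - sl$thigh * cos(th_hip_r)
  mall_rx <- knee_rx + sl$shank * sin(th_shank_r)
  mall_rz <- knee_rz - sl$shank * cos(th_shank_r)

  th_hip_l <- angle_template(phase_l, p$angle_coeffs$hip) * d2r
  th_knee_l <- pmax(angle_template(phase_l, p$angle_coeffs$knee), 0) * d2r
  th_shank_l <- th_hip_l - th_knee_l
  knee_lx <- pel_x + sl$thigh * sin(th_hip_l)
  knee_lz <- pel_z - sl$thigh * cos(th_hip_l)
  mall_lx <- knee_lx + sl$shank * sin(th_shank_l)
  mall_lz <- knee_lz - sl$shank * cos(th_shank_l)

  y_leg <- 0.10; y_sh <- 0.17
  mt5_frac <- 0.75
  df <- tibble(
    time = time,
    R_ACROMION_x = acr_x, R_ACROMION_y = -y_sh, R_ACROMION_z = acr_z,
    L_ACROMION_x = acr_x, L_ACROMION_y = y_sh, L_ACROMION_z = acr_z,
    R_TROCHANTER_x = pel_x, R_TROCHANTER_y = -y_leg, R_TROCHANTER_z = pel_z,
    L_TROCHANTER_x = pel_x, L_TROCHANTER_y = y_leg, L_TROCHANTER_z = pel_z,
    R_KNEE_x = knee_rx, R_KNEE_y = -y_leg, R_KNEE_z = knee_rz,
    L_KNEE_x = knee_lx, L_KNEE_y = y_leg, L_KNEE_z = knee_lz,
    R_MALLEOLUS_x = mall_rx, R_MALLEOLUS_y = -y_leg, R_MALLEOLUS_z = mall_rz,
    L_MALLEOLUS_x = mall_lx, L_MALLEOLUS_y = y_leg, L_MALLEOLUS_z = mall_lz,
    R_HEEL_x = right$heel_x, R_HEEL_y = -y_leg, R_HEEL_z = right$heel_z,
    L_HEEL_x = left$heel_x, L_HEEL_y = y_leg, L_HEEL_z = left$heel_z,
    R_TOE_x = right$toe_x, R_TOE_y = -y_leg, R_TOE_z = right$toe_z,
    L_TOE_x = left$toe_x, L_TOE_y = y_leg, L_TOE_z = left$toe_z
  )
  df$R_MT5_x <- df$R_HEEL_x + mt5_frac * (df$R_TOE_x - df$R_HEEL_x)
  df$R_MT5_y <- -y_leg
  df$R_MT5_z <- df$R_HEEL_z + mt5_frac * (df$R_TOE_z - df$R_HEEL_z)
  df$L_MT5_x <- df$L_HEEL_x + mt5_frac * (df$L_TOE_x - df$L_HEEL_x)
  df$L_MT5_y <- y_leg
  df$L_MT5_z <- df$L_HEEL_z + mt5_frac * (df$L_TOE_z - df$L_HEEL_z)

  if (p$marker_noise_sd > 0) {
    for (cc in setdiff(names(df), "time")) {
      df[[cc]] <- df[[cc]] + rnorm(nf, 0, p$marker_noise_sd)
    }
  }
  df <- df[c("time", unlist(lapply(canonical_markers(), function(nm)
    paste0(nm, c("_x", "_y", "_z")))))]
  markers <- gait_markers(df, frame_rate = fs)

  standing <- standing_pose(p)

  # ground truth
  to_phase <- toe_off_phase_template(clear_tpl)
  grid <- seq(0, 100, by = 5)
  if (n_spec > 0) {
    wmat <- vapply(seq_len(n_spec), function(j)
      raised_cosine_envelope(grid, spec$phase[j], p$noise_envelope_width),
      numeric(length(grid)))
    dev_grid <- amp %*% t(wmat)              # n x length(grid)
    true_mad <- vapply(seq_along(grid), function(g)
      mean(abs(dev_grid[, g] - mean(dev_grid[, g]))), numeric(1))
  } else {
    dev_grid <- matrix(0, n, length(grid))
    true_mad <- numeric(length(grid))
  }
  truth <- list(
    events = tibble(
      stride = seq_len(n),
      hs_time = hs[seq_len(n)],
      next_hs_time = hs[seq_len(n) + 1],
      toe_off_time = hs[seq_len(n)] + to_phase / 100 * Tn,
      cycle_duration = Tn,
      stride_length = Ln
    ),
    toe_off_phase = to_phase,
    deviations = tibble(
      stride = rep(seq_len(n), times = length(grid)),
      phase = rep(grid, each = n),
      deviation_m = as.numeric(dev_grid)
    ),
    true_mad = tibble(phase = grid, true_mad_m = true_mad),
    left_hs_times = ev_l[ev_l >= 0 & ev_l <= t_end],
    params = p
  )
  structure(list(markers = markers, standing = standing, truth = truth),
            class = "gait_sim")
}

# distal marker trajectories for one foot: belt-locked during stance,
# quintic swing with belt-matched end velocities
foot_track <- function(time, phase, t0, D, xc_s, xc_next, v, foot_len,
                       clear_tpl, heel_tpl) {
  heel_z <- heel_tpl(phase)
  toe_z <- clear_tpl(phase)

  heel_sw_start <- 55; toe_sw_start <- 58
  heel_x <- xc_s - v * (time - t0)
  sw <- phase >= heel_sw_start
  if (any(sw)) {
    frac <- 1 - heel_sw_start / 100
    tau <- (phase[sw] - heel_sw_start) / (100 - heel_sw_start)
    x1 <- xc_s[sw] - v * (heel_sw_start / 100) * D[sw]
    m <- -v * frac * D[sw]
    heel_x[sw] <- quintic_blend(tau, x1, xc_next[sw], m, m)
  }
  toe_x <- xc_s + foot_len - v * (time - t0)
  sw <- phase >= toe_sw_start
  if (any(sw)) {
    frac <- 1 - toe_sw_start / 100
    tau <- (phase[sw] - toe_sw_start) / (100 - toe_sw_start)
    x1 <- xc_s[sw] + foot_len - v * (toe_sw_start / 100) * D[sw]
    m <- -v * frac * D[sw]
    toe_x[sw] <- quintic_blend(tau, x1, xc_next[sw] + foot_len, m, m)
  }
  list(heel_x = heel_x, heel_z = heel_z, toe_x = toe_x, toe_z = toe_z)
}

# phase at which the noise-free clearance template first exceeds 10% of its
# swing peak -- the package's operational definition of toe-off
toe_off_phase_template <- function(clear_tpl) {
  g <- seq(55, 75, by = 0.01)
  zz <- clear_tpl(g)
  peak <- max(clear_tpl(seq(58, 100, by = 0.01)))
  thr <- 0.1 * peak
  i <- which(zz >= thr)[1]
  uniroot(function(ph) clear_tpl(ph) - thr,
          lower = g[max(i - 2, 1)], upper = g[i], tol = 1e-10)$root
}

# quiet-standing reference in the zero-angle pose
standing_pose <- function(p) {
  sl <- p$segment_lengths
  y_leg <- 0.10; y_sh <- 0.17
  mall_z <- 0.06
  knee_z <- mall_z + sl$shank
  troch_z <- knee_z + sl$thigh
  acr_z <- troch_z + sl$trunk
  heel_x <- -0.06; toe_x <- heel_x + sl$foot
  mt5_x <- heel_x + 0.75 * (toe_x - heel_x)
  one <- function(x, y, z) c(x = x, y = y, z = z)
  rows <- list(
    R_ACROMION = one(0, -y_sh, acr_z), L_ACROMION = one(0, y_sh, acr_z),
    R_TROCHANTER = one(0, -y_leg, troch_z), L_TROCHANTER = one(0, y_leg, troch_z),
    R_KNEE = one(0, -y_leg, knee_z), L_KNEE = one(0, y_leg, knee_z),
    R_MALLEOLUS = one(0, -y_leg, mall_z), L_MALLEOLUS = one(0, y_leg, mall_z),
    R_MT5 = one(mt5_x, -y_leg, 0.02), L_MT5 = one(mt5_x, y_leg, 0.02),
    R_HEEL = one(heel_x, -y_leg, 0.02), L_HEEL = one(heel_x, y_leg, 0.02),
    R_TOE = one(toe_x, -y_leg, 0.02), L_TOE = one(toe_x, y_leg, 0.02)
  )
  df <- tibble(time = 0)
  for (nm in canonical_markers()) {
    df[[paste0(nm, "_x")]] <- rows[[nm]][["x"]]
    df[[paste0(nm, "_y")]] <- rows[[nm]][["y"]]
    df[[paste0(nm, "_z")]] <- rows[[nm]][["z"]]
  }
  gait_markers(df, frame_rate = p$frame_rate, validate = FALSE)
}
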