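#' Toe height above the treadmill surface
#'
#' Foot trajectory is the height of the right toe marker above the treadmill
#' surface over time. The surface defaults to z = 0; alternatively it can be
#' calibrated as the 1st percentile of the heel height during the record
#' (`surface = "calibrate"`).
#'
#' @param mts A [gait_markers] tibble with an `R_TOE` marker.
#' @param surface Surface height in meters, or `"calibrate"`.
#' @return Tibble with columns `time` and `toe_height` (m, not clipped).
#' @export
toe_height <- function(mts, surface = 0) {
  z <- marker_xyz(mts, "R_TOE")[, "z"]
  if (identical(surface, "calibrate")) {
    heel_z <- marker_xyz(mts, "R_HEEL")[, "z"]
    surface <- as.numeric(stats::quantile(heel_z, 0.01)) - 0.02
  }
  tibble(time = mts$time, toe_height = z - surface)
}

# signed direction angle in the sagittal plane: 0 = vertical up,
# positive toward +x (anterior); input is an n x 3 coordinate matrix diff
sagittal_dir <- function(v) as.numeric(atan2(v[, 1], v[, 3])) * 180 / pi

wrap180 <- function(a) ((a + 180) %% 360) - 180

#' Trunk angle with respect to the vertical
#'
#' The trunk segment connects the midpoint of the left and right greater
#' trochanter markers to the midpoint of the acromion markers; its angle to
#' the vertical axis is measured in the sagittal (x-z) plane, positive for
#' forward lean.
#'
#' @param mts A [gait_markers] tibble with both acromion and trochanter
#'   markers.
#' @return Tibble with columns `time` and `trunk_angle` (degrees).
#' @export
trunk_angle <- function(mts) {
  acr <- (marker_xyz(mts, "R_ACROMION") + marker_xyz(mts, "L_ACROMION")) / 2
  tro <- (marker_xyz(mts, "R_TROCHANTER") + marker_xyz(mts, "L_TROCHANTER")) / 2
  d <- acr - tro
  if (any(sqrt(d[, 1]^2 + d[, 3]^2) < 1e-9)) {
    abort("Acromion and trochanter midpoints coincide in the sagittal plane.",
          class = "gaitvar_degenerate_geometry_error")
  }
  ang <- sagittal_dir(d)
  if (any(abs(ang) > 45)) {
    warn("Trunk angle outside (-45, 45) degrees; implausible for walking.")
  }
  tibble(time = mts$time, trunk_angle = ang)
}

#' Sagittal joint angles referenced to quiet standing
#'
#' Computes right-leg hip, knee and ankle angles and the trunk angle in the
#' sagittal plane, each minus its value in the quiet-standing reference so
#' that standing is 0 degrees by construction. Segment vectors: thigh
#' trochanter->knee, shank knee->malleolus, foot heel->5th metatarsal head,
#' trunk mid-trochanter->mid-acromion. Signs: hip flexion positive, knee
#' flexion positive, ankle dorsiflexion positive, trunk forward lean
#' positive. Being inter-segment angles, hip/knee/ankle are invariant to
#' global translation and to rotation in the sagittal plane; the trunk angle
#' shifts by the rotation.
#'
#' @param mts A [gait_markers] tibble with the right leg and trunk markers.
#' @param standing A one-row [gait_markers] quiet-standing reference.
#' @return Tibble with columns `time`, `trunk`, `hip`, `knee`, `ankle`
#'   (degrees).
#' @export
joint_angles <- function(mts, standing) {
  raw <- joint_angles_raw(mts)
  ref <- joint_angles_raw(standing)
  tibble(
    time = mts$time,
    trunk = wrap180(raw$trunk - ref$trunk[1]),
    hip = -wrap180(raw$hip - ref$hip[1]),
    knee = wrap180(raw$knee - ref$knee[1]),
    ankle = -wrap180(raw$ankle - ref$ankle[1])
  )
}

joint_angles_raw <- function(mts) {
  acr <- (marker_xyz(mts, "R_ACROMION") + marker_xyz(mts, "L_ACROMION")) / 2
  tro_m <- (marker_xyz(mts, "R_TROCHANTER") + marker_xyz(mts, "L_TROCHANTER")) / 2
  tro <- marker_xyz(mts, "R_TROCHANTER")
  knee <- marker_xyz(mts, "R_KNEE")
  mall <- marker_xyz(mts, "R_MALLEOLUS")
  heel <- marker_xyz(mts, "R_HEEL")
  mt5 <- marker_xyz(mts, "R_MT5")
  seglen <- function(v) sqrt(v[, 1]^2 + v[, 3]^2)
  thigh <- knee - tro
  shank <- mall - knee
  foot <- mt5 - heel
  trunk <- acr - tro_m
  if (any(c(seglen(thigh), seglen(shank), seglen(foot), seglen(trunk)) < 1e-9)) {
    abort("Zero-length segment in the sagittal plane.",
          class = "gaitvar_degenerate_geometry_error")
  }
  ang_thigh <- sagittal_dir(thigh)
  ang_shank <- sagittal_dir(shank)
  ang_shank_up <- sagittal_dir(-shank)
  ang_foot <- sagittal_dir(foot)
  ang_trunk_ext <- sagittal_dir(tro_m - acr)
  list(
    trunk = sagittal_dir(trunk),
    hip = wrap180(ang_thigh - ang_trunk_ext),
    knee = wrap180(ang_shank - ang_thigh),
    ankle = wrap180(ang_foot - ang_shank_up)
  )
}

#' Time-normalize a signal over one stride
#'
#' Resamples a signal onto 101 equally spaced phase points (0, 1, ..., 100%
#' of the cycle) between two heel strikes by linear interpolation; the
#' endpoints are sampled exactly at the (sub-frame) event times.
#'
#' @param values Signal samples.
#' @param time Time stamps (s).
#' @param t_start,t_end Heel-strike times bounding the stride (s).
#' @param n_points Number of phase samples (default 101).
#' @return Numeric vector of length `n_points`.
#' @export
time_normalize <- function(values, time, t_start, t_end, n_points = 101) {
  if (t_start < time[1] - 1e-9 || t_end > time[length(time)] + 1e-9 ||
      t_end <= t_start) {
    abort("Stride interval lies outside the recorded span.")
  }
  tq <- t_start + (seq_len(n_points) - 1) / (n_points - 1) * (t_end - t_start)
  approx(time, values, xout = tq, rule = 2)$y
}

#' Build the stride-by-phase matrix of a signal
#'
#' Time-normalizes a signal over every stride in an events table, returning
#' a tidy tibble (one row per stride per phase point).
#'
#' @param values Signal samples (e.g. toe height in meters or an angle in
#'   degrees).
#' @param time Time stamps (s).
#' @param events A [gait_events] tibble (or any tibble with `stride`,
#'   `hs_time`, `next_hs_time`).
#' @param signal Name stored in the `signal` column.
#' @return Tibble of class `gait_cycles` with columns `stride`, `signal`,
#'   `phase` (0:100) and `value`; exactly 101 phases per stride, no
#'   non-finite values.
#' @export
normalize_cycles <- function(values, time, events, signal = "signal") {
  rows <- purrr::pmap(
    list(events$stride, events$hs_time, events$next_hs_time),
    function(s, t0, t1) {
      tibble(stride = s, signal = signal, phase = 0:100,
             value = time_normalize(values, time, t0, t1))
    })
  out <- dplyr::bind_rows(rows)
  if (any(!is.finite(out$value))) {
    abort("Non-finite values produced during time normalization.")
  }
  structure(out, class = c("gait_cycles", class(out)))
}

#' Phase grids used for statistical comparison
#'
#' `swing_grid()` is the 10-point grid from 55 to 100% of the gait cycle
#' (every 5%), covering the swing phase, used for the foot trajectory.
#' `full_cycle_grid()` is the 10-point grid at every 10% of the entire cycle
#' (10, 20, ..., 100%), used for joint and trunk angles.
#'
#' @return Integer vector of 10 phase points.
#' @export
swing_grid <- function() seq(55L, 100L, by = 5L)

#' @rdname swing_grid
#' @export
full_cycle_grid <- function() seq(10L, 100L, by = 10L)

#' Select grid columns from normalized cycles
#'
#' @param cycles A `gait_cycles` tibble from [normalize_cycles()].
#' @param grid Integer phase points in `[0, 100]`.
#' @return The rows of `cycles` at the grid phases.
#' @export
extract_grid <- function(cycles, grid) {
  if (any(grid != round(grid)) || any(grid < 0 | grid > 100)) {
    abort("Grid points must be integers in [0, 100].")
  }
  dplyr::filter(cycles, .data$phase %in% as.integer(grid))
}
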