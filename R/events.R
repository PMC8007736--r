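#' Detect heel strikes from heel-marker height
#'
#' Finds one heel strike per gait cycle as the local minimum of the heel
#' height inside each excursion below a descending threshold
#' (`min + threshold_frac * range`), refined to sub-frame resolution by
#' fitting a parabola to the samples within 50 ms of the minimum (least
#' squares; a window longer than the low-pass filter's noise correlation
#' length averages out noise-induced tilt instead of trusting three
#' samples) and taking its vertex.
#' Events closer than `min_separation` are merged, keeping the lower
#' minimum. A pure local-minimum mode is available for sensitivity analysis.
#'
#' @param z Heel-marker height series in meters (filtered).
#' @param time Time stamps in seconds, same length as `z`.
#' @param threshold_frac Fraction of the signal range above the minimum used
#'   as the descending threshold.
#' @param min_separation Minimum time between events, seconds.
#' @param method `"threshold"` (default) or `"minimum"` (all separated local
#'   minima).
#' @return Numeric vector of heel-strike times (s), strictly increasing.
#' @export
detect_heel_strikes <- function(z, time, threshold_frac = 0.1,
                                min_separation = 0.4,
                                method = c("threshold", "minimum")) {
  method <- match.arg(method)
  stopifnot(length(z) == length(time))
  rng <- range(z)
  if (diff(rng) < 0.005) {
    abort("Heel-height signal is flat (range < 5 mm); no events detectable.",
          class = "gaitvar_no_events_error")
  }
  dt <- stats::median(diff(time))
  if (method == "threshold") {
    thr <- rng[1] + threshold_frac * diff(rng)
    below <- z < thr
    r <- rle(below)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    cand <- integer(0)
    for (k in which(r$values)) {
      seg <- starts[k]:ends[k]
      cand <- c(cand, seg[which.min(z[seg])])
    }
  } else {
    n <- length(z)
    cand <- which(z[2:(n - 1)] < z[1:(n - 2)] & z[2:(n - 1)] <= z[3:n]) + 1L
  }
  # drop candidates at the record edges (no parabolic neighbourhood)
  cand <- cand[cand > 1 & cand < length(z)]
  if (length(cand) > 1) {
    keep <- logical(length(cand))
    keep[1] <- TRUE
    last <- 1L
    for (i in seq_along(cand)[-1]) {
      if (time[cand[i]] - time[cand[last]] >= min_separation) {
        keep[i] <- TRUE
        last <- i
      } else if (z[cand[i]] < z[cand[last]]) {
        keep[last] <- FALSE
        keep[i] <- TRUE
        last <- i
      }
    }
    cand <- cand[keep]
  }
  if (length(cand) < 2) {
    abort("Fewer than 2 heel strikes detected; need >= 2 gait cycles.",
          class = "gaitvar_insufficient_data_error")
  }
  h <- max(1L, as.integer(round(0.05 / dt)))    # fit window: +/- 50 ms
  n <- length(z)
  vapply(cand, function(i) {
    lo <- max(1L, i - h)
    hi <- min(n, i + h)
    s <- seq.int(lo, hi) - i                     # frame offsets
    if (length(s) >= 3) {
      fit <- stats::lm.fit(cbind(1, s, s^2), z[seq.int(lo, hi)])
      a2 <- fit$coefficients[3]
      delta <- if (is.finite(a2) && a2 > 0) {
        -fit$coefficients[2] / (2 * a2)
      } else 0
    } else {
      delta <- 0
    }
    delta <- max(-h, min(h, delta))
    time[i] + delta * dt
  }, numeric(1))
}

#' Detect toe-offs from toe-marker height
#'
#' Within each stride (consecutive heel strikes), toe-off is the last time
#' the toe height rises through a threshold (stance baseline + 10% of the
#' swing peak above baseline) before the swing peak, linearly interpolated
#' to sub-frame resolution. Strides in which the toe never leaves the ground
#' (swing excursion < 10 mm) or with no threshold crossing are flagged with
#' `NA` and a warning.
#'
#' @param z Toe-marker height series in meters (filtered).
#' @param time Time stamps in seconds.
#' @param heel_strikes Heel-strike times from [detect_heel_strikes()].
#' @param threshold_frac Fraction of the swing excursion above baseline.
#' @return Numeric vector of length `length(heel_strikes) - 1`: toe-off time
#'   per stride, `NA` for flagged strides.
#' @export
detect_toe_offs <- function(z, time, heel_strikes, threshold_frac = 0.1) {
  n_strides <- length(heel_strikes) - 1
  if (n_strides < 1) {
    abort("Need at least 2 heel strikes.", class = "gaitvar_insufficient_data_error")
  }
  out <- rep(NA_real_, n_strides)
  for (k in seq_len(n_strides)) {
    idx <- which(time >= heel_strikes[k] & time <= heel_strikes[k + 1])
    if (length(idx) < 5) next
    zk <- z[idx]
    base <- min(zk)
    peak_i <- which.max(zk)
    if (zk[peak_i] - base < 0.010) next   # toe never leaves the ground
    thr <- base + threshold_frac * (zk[peak_i] - base)
    up <- which(zk[-1] >= thr & zk[-length(zk)] < thr)
    up <- up[up < peak_i]
    if (length(up) == 0) next
    i <- up[length(up)]
    t1 <- time[idx[i]]; t2 <- time[idx[i + 1]]
    out[k] <- t1 + (thr - zk[i]) / (zk[i + 1] - zk[i]) * (t2 - t1)
  }
  if (anyNA(out)) {
    warn(sprintf("%d stride(s) flagged: no toe-off detected.", sum(is.na(out))))
  }
  out
}

#' Cycle durations from heel-strike times
#'
#' @param heel_strikes Strictly increasing heel-strike times (s).
#' @return Durations `t[k+1] - t[k]` in seconds.
#' @export
#' @examples
#' cycle_durations(c(0, 1.1, 2.2))
cycle_durations <- function(heel_strikes) {
  if (length(heel_strikes) < 2) {
    abort("Need >= 2 heel strikes to compute cycle durations.",
          class = "gaitvar_insufficient_data_error")
  }
  diff(heel_strikes)
}

#' Belt-compensated stride lengths
#'
#' Stride length on a treadmill is the sagittally projected displacement of
#' the heel marker between consecutive heel strikes plus the belt travel
#' during the cycle: `L_k = x(t[k+1]) - x(t[k]) + belt_speed * T_k`. The lab
#' x axis points in the direction of progression and the belt carries the
#' stance foot backward, so for a walker holding station the displacement
#' term is near zero and the belt term dominates.
#'
#' @param x Heel-marker anterior position series (m).
#' @param time Time stamps (s).
#' @param heel_strikes Heel-strike times (s).
#' @param belt_speed Belt speed (m/s), `>= 0` (0 for overground data).
#' @return Stride lengths in meters, length `length(heel_strikes) - 1`.
#' @export
stride_lengths <- function(x, time, heel_strikes, belt_speed) {
  if (belt_speed < 0) abort("`belt_speed` must be >= 0.")
  if (length(heel_strikes) < 2) {
    abort("Need >= 2 heel strikes.", class = "gaitvar_insufficient_data_error")
  }
  x_at <- approx(time, x, xout = heel_strikes)$y
  len <- diff(x_at) + belt_speed * diff(heel_strikes)
  if (any(len <= 0, na.rm = TRUE)) {
    warn(sprintf("%d stride(s) flagged: non-positive computed length.",
                 sum(len <= 0, na.rm = TRUE)))
  }
  len
}

#' Detect and segment gait events for a recording
#'
#' Runs heel-strike and toe-off detection on the right foot, discards the
#' first and last detected strides (edge effects of filtering and padding),
#' and returns per-stride metrics. Left heel strikes are detected only to
#' validate the half-cycle phase offset. Strides whose toe-off fraction of
#' the cycle falls outside (0.4, 0.8) trigger a plausibility warning.
#'
#' @param mts A filtered [gait_markers] tibble with `R_HEEL`, `R_TOE` (and
#'   optionally `L_HEEL`) markers.
#' @param belt_speed Belt speed in m/s.
#' @param drop_edges Discard the first and last strides (default TRUE)?
#' @param method Heel-strike detection mode, see [detect_heel_strikes()].
#' @return A tibble of class `gait_events` with columns `stride`, `hs_time`,
#'   `next_hs_time`, `toe_off_time`, `cycle_duration`, `stride_length`;
#'   attributes `heel_strikes` (all kept right heel-strike times) and
#'   `left_hs_times`.
#' @export
gait_events <- function(mts, belt_speed, drop_edges = TRUE,
                        method = "threshold") {
  heel <- marker_xyz(mts, "R_HEEL")
  toe <- marker_xyz(mts, "R_TOE")
  hs <- detect_heel_strikes(heel[, "z"], mts$time, method = method)
  if (drop_edges) {
    if (length(hs) < 4) {
      abort("Too few strides to drop edge strides.",
            class = "gaitvar_insufficient_data_error")
    }
    hs <- hs[-c(1, length(hs))]
  }
  to <- detect_toe_offs(toe[, "z"], mts$time, hs)
  dur <- cycle_durations(hs)
  len <- stride_lengths(heel[, "x"], mts$time, hs, belt_speed)
  frac <- (to - hs[-length(hs)]) / dur
  bad <- !is.na(frac) & (frac <= 0.4 | frac >= 0.8)
  if (any(bad)) {
    warn(sprintf("%d stride(s) have a toe-off fraction outside (0.4, 0.8).",
                 sum(bad)))
  }
  left_hs <- tryCatch({
    lz <- marker_xyz(mts, "L_HEEL")[, "z"]
    detect_heel_strikes(lz, mts$time, method = method)
  }, error = function(e) numeric(0))
  out <- tibble(
    stride = seq_along(dur),
    hs_time = hs[-length(hs)],
    next_hs_time = hs[-1],
    toe_off_time = to,
    cycle_duration = dur,
    stride_length = len
  )
  structure(out, heel_strikes = hs, left_hs_times = left_hs,
            class = c("gait_events", class(out)))
}
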