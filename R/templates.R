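#' Within-cycle angle templates
#'
#' Joint and trunk angle patterns over the gait cycle are represented as
#' truncated Fourier series in percent of cycle, which makes them exactly
#' periodic (value and derivative match at 0% and 100%) and smooth. The
#' default coefficient sets describe a generic adult treadmill-walking
#' pattern: hip flexion peaking in terminal swing, knee flexion peaking at
#' ~72% of the cycle (swing), ankle plantarflexion around push-off, and a
#' small forward trunk lean with a twice-per-cycle bob.
#'
#' @param phase_percent Phase in percent of gait cycle, values in `[0, 100]`.
#' @param coeffs A list with components `a0` (scalar), `a`, `b` (harmonic
#'   cosine/sine coefficient vectors of equal length), angles in degrees.
#' @return Angle in degrees, same length as `phase_percent`.
#' @export
#' @examples
#' angle_template(c(0, 50, 100), default_angle_coeffs()$knee)
angle_template <- function(phase_percent, coeffs) {
  if (any(phase_percent < 0 | phase_percent > 100)) {
    abort("`phase_percent` must lie in [0, 100].")
  }
  stopifnot(is.list(coeffs), length(coeffs$a) == length(coeffs$b))
  th <- 2 * pi * phase_percent / 100
  val <- rep(coeffs$a0, length(phase_percent))
  for (k in seq_along(coeffs$a)) {
    val <- val + coeffs$a[k] * cos(k * th) + coeffs$b[k] * sin(k * th)
  }
  val
}

#' @rdname angle_template
#' @export
default_angle_coeffs <- function() {
  list(
    hip = list(
      a0 = 8.8985837,
      a = c(19.4279372, -2.4442623, -0.6331957, 0.1789013, -0.1586348, -0.0293427),
      b = c(-5.3200829, -2.0460377, 1.1219830, 0.0164259, 0.0242781, 0.0646692)),
    knee = list(
      a0 = 22.399015,
      a = c(-2.3815157, -13.7633915, -0.5238416, -0.0276636, -0.7104212, -0.2325314),
      b = c(-18.8834995, 9.0736147, 3.6290175, -1.0306707, -0.5117407, -0.0586596)),
    ankle = list(
      a0 = -1.4760527,
      a = c(-1.7667053, 4.2081605, -3.2063724, 2.3360794, -0.2398650, 0.0226666),
      b = c(5.4507999, -8.3567385, -0.1242425, 1.2039089, -1.1184226, 0.5037881)),
    trunk = list(
      a0 = 3.5243805,
      a = c(0.0511897, -0.4799844, -0.0228184, -0.0148470, -0.0090476, -0.0118028),
      b = c(0.0204211, 0.0566368, 0.0221229, 0.0070796, 0.0029325, 0.0020976))
  )
}

# ---- distal trajectory templates (meters, phase in % cycle) ----------------

# Toe-height template: zero during foot-flat stance, a cosine ramp to zero
# over early stance (the toe lowers after heel strike), then a swing curve
# with an early-swing clearance peak (~0.12 m near 70%) and a minimum toe
# clearance around 85% of the cycle. Waypoints interpolated with a natural
# cubic spline; tiny spline undershoots are clipped at zero.
clearance_template_fun <- function() {
  sw_phase <- c(55, 58, 61, 65, 70, 78, 85, 90, 95, 100)
  sw_z     <- c(0, 0.004, 0.018, 0.062, 0.120, 0.068, 0.045, 0.055, 0.055, 0.030)
  sf <- splinefun(sw_phase, sw_z, method = "natural")
  z_hs <- sw_z[length(sw_z)]
  function(phase) {
    z <- numeric(length(phase))
    early <- phase >= 0 & phase < 8
    z[early] <- z_hs * (1 + cos(pi * phase[early] / 8)) / 2
    swing <- phase >= 55 & phase <= 100
    z[swing] <- pmax(0, sf(phase[swing]))
    z
  }
}

# Heel-height template: two stance harmonics with a unique, well-curved
# minimum exactly at heel strike, plus a squared-raised-cosine swing bump
# (heel rise after heel-off peaking ~0.21 m near 66%). The squared (C3)
# bump ends at 92% of the cycle: its spectral content above the 7 Hz
# protocol cutoff is negligible, so zero-phase filtering neither rings nor
# displaces the heel-strike minimum.
heel_template_fun <- function() {
  function(phase) {
    base <- 0.02 + 0.018 * (1 - cos(2 * pi * phase / 100)) +
      0.012 * (1 - cos(4 * pi * phase / 100))
    bump <- numeric(length(phase))
    inb <- phase >= 40 & phase <= 92
    bump[inb] <- 0.21 * ((1 + cos(pi * (phase[inb] - 66) / 26)) / 2)^2
    base + bump
  }
}

#' Raised-cosine phase envelope
#'
#' Envelope used to localize injected toe-height variability around a target
#' phase: `0.5 * (1 + cos(pi * (phase - center) / half_width))` inside
#' `center +/- half_width`, zero outside, truncated to the stride's own
#' `[0, 100]` span. `width` is the full support in percent of cycle.
#'
#' @param phase Phase in percent of cycle.
#' @param center Envelope center (percent of cycle).
#' @param width Full support width (percent of cycle).
#' @return Envelope values in `[0, 1]` with `raised_cosine_envelope(center) == 1`.
#' @export
raised_cosine_envelope <- function(phase, center, width = 25) {
  hw <- width / 2
  w <- numeric(length(phase))
  inb <- abs(phase - center) <= hw & phase >= 0 & phase <= 100
  w[inb] <- 0.5 * (1 + cos(pi * (phase[inb] - center) / hw))
  w
}
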