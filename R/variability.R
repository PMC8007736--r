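#' Mean absolute deviation
#'
#' The package's variability statistic: the mean absolute deviation about
#' the sample mean, `(1/n) * sum(|x_i - mean(x)|)`. Unlike the standard
#' deviation it weighs deviations linearly, so every stride's contribution
#' is its own absolute deviation, and unlike the coefficient of variation it
#' keeps the signal's units. For Normal data its expectation is
#' `sigma * sqrt(2/pi)`.
#'
#' @param values Numeric vector, `n >= 2`, finite.
#' @return The MAD (same units as `values`), `>= 0`, zero iff all values
#'   are equal.
#' @export
#' @examples
#' mean_abs_dev(c(1, 2, 3, 4))  # 1
mean_abs_dev <- function(values) {
  if (length(values) < 2) {
    abort("Need at least 2 values to compute a MAD.",
          class = "gaitvar_insufficient_data_error")
  }
  if (any(!is.finite(values))) abort("`values` must be finite.")
  mean(abs(values - mean(values)))
}

#' MAD profile of normalized cycles
#'
#' Computes the across-stride mean and MAD of a normalized signal at each
#' phase grid point.
#'
#' @param cycles A `gait_cycles` tibble from [normalize_cycles()].
#' @param grid Integer phase points (default [swing_grid()]).
#' @param participant,condition Optional labels stored in the output.
#' @return Tibble with columns `participant`, `condition`, `signal`,
#'   `phase`, `mean`, `mad`, `n` (MAD and mean in the signal's own units).
#' @export
mad_profile <- function(cycles, grid = swing_grid(),
                        participant = NA_character_,
                        condition = NA_character_) {
  sub <- extract_grid(cycles, grid)
  out <- sub |>
    dplyr::group_by(.data$signal, .data$phase) |>
    dplyr::summarise(
      mean = mean(.data$value),
      mad = mean_abs_dev(.data$value),
      n = dplyr::n(),
      .groups = "drop"
    )
  dplyr::bind_cols(
    tibble(participant = rep(participant, nrow(out)),
           condition = rep(condition, nrow(out))),
    out
  )
}

#' MAD of the scalar stride metrics
#'
#' Applies the MAD statistic to the per-stride cycle durations and stride
#' lengths of an events table.
#'
#' @param events A [gait_events] tibble.
#' @return Tibble with one row per metric: `metric`, `mean`, `mad`, `n`
#'   (seconds for cycle duration, meters for stride length).
#' @export
scalar_variability <- function(events) {
  tibble(
    metric = c("cycle_duration", "stride_length"),
    mean = c(mean(events$cycle_duration), mean(events$stride_length)),
    mad = c(mean_abs_dev(events$cycle_duration),
            mean_abs_dev(events$stride_length)),
    n = nrow(events)
  )
}
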