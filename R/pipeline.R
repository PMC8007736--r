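#' Default analysis configuration
#'
#' Returns the pipeline configuration as a nested list. Keys mirror the
#' protocol: capture is windowed to the last `window_s` seconds of the
#' recording, channels are low-pass filtered (7 Hz second-order zero-phase
#' Butterworth) unless disabled, events come from the heel/toe marker
#' heights, the foot trajectory is compared on the 10-point swing grid and
#' angles on the 10-point full-cycle grid, and the statistical block uses a
#' MANOVA gate at `alpha` with one-tailed per-point tests at the Bonferroni
#' threshold.
#'
#' @return A named list; see the examples for its structure.
#' @export
#' @examples
#' str(default_config())
default_config <- function() {
  list(
    belt_speed = 1.1,
    window_s = 60,
    min_strides = 10,
    filter = list(enabled = TRUE, cutoff_hz = 7, order = 2),
    events = list(method = "threshold"),
    grids = list(trajectory = swing_grid(), angles = full_cycle_grid()),
    stats = list(alpha = 0.05, assumption_alpha = 0.05,
                 manova_mode = "two_group", tail = "less"),
    simulate = list(n_participants = 10, n_strides = 60,
                    between_participant_cv = 0.2, seed = 1L)
  )
}

validate_config <- function(config) {
  need <- c("belt_speed", "window_s", "min_strides", "filter", "events",
            "grids", "stats")
  missing <- setdiff(need, names(config))
  if (length(missing) > 0) {
    abort(paste0("Config is missing key(s): ", paste(missing, collapse = ", ")),
          class = "gaitvar_config_error")
  }
  if (!is.numeric(config$belt_speed)) {
    abort("Config key `belt_speed` must be numeric.",
          class = "gaitvar_config_error")
  }
  invisible(config)
}

#' Analyze one walking recording
#'
#' Applies the full single-recording pipeline in order: window selection
#' (default: the last 60 s), zero-phase low-pass filtering, event detection
#' and stride segmentation, toe-height and angle computation, per-stride
#' time normalization, and MAD profiling on the comparison grids.
#'
#' @param mts A [gait_markers] tibble (raw, unfiltered).
#' @param standing A one-row [gait_markers] quiet-standing reference.
#' @param config Configuration list from [default_config()].
#' @param participant,condition Labels carried into the profiles.
#' @return A list of class `gait_analysis`: `events` ([gait_events]),
#'   `metrics` (scalar means/MADs), `profiles` (tidy MAD profiles for toe
#'   height in meters and angles in degrees), `cycles` (tidy normalized
#'   curves), and `settings`.
#' @export
analyze_recording <- function(mts, standing, config = default_config(),
                              participant = NA_character_,
                              condition = NA_character_) {
  validate_config(config)
  span <- diff(range(mts$time))
  if (config$window_s > span + 1e-9) {
    abort(sprintf("Analysis window (%g s) exceeds the recording (%.3g s).",
                  config$window_s, span), class = "gaitvar_config_error")
  }
  t_max <- mts$time[nrow(mts)]
  win <- mts$time >= t_max - config$window_s - 1e-9
  mtw <- new_markers_like(mts, mts[win, ])

  if (isTRUE(config$filter$enabled)) {
    mtw <- lowpass_zero_phase(mtw, cutoff_hz = config$filter$cutoff_hz,
                              order = config$filter$order)
  }
  ev <- gait_events(mtw, belt_speed = config$belt_speed,
                    method = config$events$method)
  ev_ok <- ev[!is.na(ev$toe_off_time), ]
  if (nrow(ev_ok) < config$min_strides) {
    abort(sprintf("Only %d usable strides in the window; need >= %d.",
                  nrow(ev_ok), config$min_strides),
          class = "gaitvar_insufficient_data_error")
  }

  th <- toe_height(mtw)
  ang <- joint_angles(mtw, standing)

  cyc <- dplyr::bind_rows(
    normalize_cycles(th$toe_height, th$time, ev_ok, signal = "toe_height"),
    normalize_cycles(ang$trunk, ang$time, ev_ok, signal = "trunk"),
    normalize_cycles(ang$hip, ang$time, ev_ok, signal = "hip"),
    normalize_cycles(ang$knee, ang$time, ev_ok, signal = "knee"),
    normalize_cycles(ang$ankle, ang$time, ev_ok, signal = "ankle")
  )
  cyc <- structure(cyc, class = c("gait_cycles", class(tibble())))

  prof <- dplyr::bind_rows(
    mad_profile(dplyr::filter(cyc, .data$signal == "toe_height"),
                grid = config$grids$trajectory,
                participant = participant, condition = condition),
    mad_profile(dplyr::filter(cyc, .data$signal != "toe_height"),
                grid = config$grids$angles,
                participant = participant, condition = condition)
  )
  metrics <- dplyr::bind_cols(
    tibble(participant = rep(participant, 2), condition = rep(condition, 2)),
    scalar_variability(ev_ok)
  )
  structure(list(events = ev_ok, metrics = metrics, profiles = prof,
                 cycles = cyc,
                 settings = config[c("window_s", "filter", "events", "grids")]),
            class = "gait_analysis")
}

#' Simulate a two-condition cohort
#'
#' Generates paired recordings for `n_participants` under the OFF and ON
#' presets of [condition_params()]. Between-participant heterogeneity is
#' introduced as a shared lognormal multiplier on each participant's
#' toe-noise targets and trunk sway (the same multiplier in both
#' conditions, preserving the paired design); condition means are
#' identical by construction.
#'
#' @param n_participants Number of participants.
#' @param n_strides Strides generated per recording.
#' @param between_participant_cv CV of the participant-level variability
#'   multiplier.
#' @param seed Integer seed.
#' @param ... Further overrides for [gait_params()].
#' @return Tibble with columns `participant`, `condition`, `sim`
#'   (list column of `gait_sim` objects).
#' @export
simulate_cohort <- function(n_participants = 10, n_strides = 60,
                            between_participant_cv = 0.2, seed = 1L, ...) {
  set.seed(seed)
  mult <- exp(rnorm(n_participants, 0, between_participant_cv))
  seeds <- sample.int(.Machine$integer.max %/% 2, 2 * n_participants)
  rows <- purrr::map_dfr(seq_len(n_participants), function(i) {
    purrr::map_dfr(c("OFF", "ON"), function(cond) {
      base <- condition_params(cond, n_strides = n_strides, seed = 1L, ...)
      spec <- base$toe_noise_spec
      spec$target_mad_m <- spec$target_mad_m * mult[i]
      prm <- condition_params(
        cond, n_strides = n_strides,
        seed = seeds[2 * (i - 1) + match(cond, c("OFF", "ON"))],
        ...)
      prm$toe_noise_spec <- spec
      prm$trunk_sway_sd <- prm$trunk_sway_sd * mult[i]
      tibble(participant = sprintf("P%02d", i), condition = cond,
             sim = list(generate_gait(prm)))
    })
  })
  rows
}

#' Run the full simulate-analyze-compare pipeline
#'
#' Orchestrates the two-condition study flow on synthetic data: simulate a
#' paired cohort (OFF then ON), analyze every recording, and compare the
#' conditions — toe-trajectory MAD on the swing grid and each angle MAD on
#' the full-cycle grid through the MANOVA-gated protocol, and the scalar
#' cycle-duration / stride-length MADs with one-tailed paired t-tests
#' (Wilcoxon on assumption failure). Optionally writes tidy CSVs and a JSON
#' run manifest (config hash, seeds, package version, file checksums,
#' decision log) for reproducibility.
#'
#' @param config Configuration list from [default_config()].
#' @param out_dir Output directory for CSVs and the manifest, or `NULL`.
#' @return A list of class `gait_pipeline`: `profiles`, `metrics`,
#'   `comparisons` (named list of [compare_conditions()] results and the
#'   scalar test tibble), `manifest`.
#' @export
run_pipeline <- function(config = default_config(), out_dir = NULL) {
  validate_config(config)
  if (is.null(config$simulate)) {
    abort("Config is missing key(s): simulate", class = "gaitvar_config_error")
  }
  sim_cfg <- config$simulate
  cohort <- simulate_cohort(
    n_participants = sim_cfg$n_participants,
    n_strides = sim_cfg$n_strides,
    between_participant_cv = sim_cfg$between_participant_cv,
    seed = sim_cfg$seed
  )
  analyses <- purrr::pmap(cohort, function(participant, condition, sim) {
    analyze_recording(sim$markers, sim$standing, config,
                      participant = participant, condition = condition)
  })
  profiles <- dplyr::bind_rows(purrr::map(analyses, "profiles"))
  metrics <- dplyr::bind_rows(purrr::map(analyses, "metrics"))

  off <- dplyr::filter(profiles, .data$condition == "OFF")
  on <- dplyr::filter(profiles, .data$condition == "ON")
  tail <- config$stats$tail
  comparisons <- list()
  for (sig in unique(profiles$signal)) {
    comparisons[[paste0(sig, "_mad")]] <- compare_conditions(
      dplyr::filter(off, .data$signal == sig),
      dplyr::filter(on, .data$signal == sig),
      value = "mad", direction = tail,
      alpha = config$stats$alpha,
      assumption_alpha = config$stats$assumption_alpha,
      mode = config$stats$manova_mode
    )
  }
  comparisons$scalars <- compare_scalars(metrics, tail,
                                         config$stats$assumption_alpha)

  manifest <- list(
    package_version = as.character(utils::packageVersion("gaitvar")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    seed = sim_cfg$seed,
    config_hash = rlang::hash(config),
    decisions = list(
      filter = config$filter,
      event_method = config$events$method,
      grids = config$grids,
      stats = config$stats
    )
  )
  result <- structure(list(profiles = profiles, metrics = metrics,
                           comparisons = comparisons, manifest = manifest),
                      class = "gait_pipeline")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    files <- c(profiles = "profiles.csv", metrics = "metrics.csv",
               comparisons = "comparisons.csv")
    readr::write_csv(profiles, file.path(out_dir, files["profiles"]))
    readr::write_csv(metrics, file.path(out_dir, files["metrics"]))
    comp_tbl <- purrr::map_dfr(
      setdiff(names(comparisons), "scalars"),
      function(nm) dplyr::mutate(tidy(comparisons[[nm]]),
                                 comparison = nm, .before = 1))
    readr::write_csv(comp_tbl, file.path(out_dir, files["comparisons"]))
    readr::write_csv(comparisons$scalars, file.path(out_dir, "scalar_tests.csv"))
    sums <- tools::md5sum(file.path(out_dir, c(files, "scalar_tests.csv")))
    manifest$checksums <- as.list(setNames(unname(sums), basename(names(sums))))
    result$manifest <- manifest
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  result
}

compare_scalars <- function(metrics, tail, assumption_alpha) {
  purrr::map_dfr(unique(metrics$metric), function(met) {
    sub <- dplyr::filter(metrics, .data$metric == met) |>
      dplyr::arrange(.data$participant)
    a <- sub$mad[sub$condition == "OFF"]
    b <- sub$mad[sub$condition == "ON"]
    sw_a <- tryCatch(normality_check(a)$p, error = function(e) NA_real_)
    sw_b <- tryCatch(normality_check(b)$p, error = function(e) NA_real_)
    bt <- tryCatch(variance_check(a, b)$p, error = function(e) NA_real_)
    use_w <- isTRUE(sw_a < assumption_alpha) || isTRUE(sw_b < assumption_alpha) ||
      isTRUE(bt < assumption_alpha)
    if (use_w) {
      res <- wilcoxon_signed_rank(a, b, tail)
      tibble(metric = met, quantity = "mad", test = "wilcoxon",
             statistic = res$V, p = res$p)
    } else {
      res <- paired_t_one_tailed(a, b, tail)
      tibble(metric = met, quantity = "mad", test = "t",
             statistic = res$t, p = res$p)
    }
  })
}
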