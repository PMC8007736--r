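# Shared fixtures for the test suite. Simulations are cached per parameter
# key so several test files can reuse the same generated recording.

.sim_cache <- new.env(parent = emptyenv())

cached_sim <- function(key, ...) {
  if (is.null(.sim_cache[[key]])) {
    .sim_cache[[key]] <- generate_gait(gait_params(...))
  }
  .sim_cache[[key]]
}

# a clean (no marker noise) short walk used across files
clean_sim <- function() {
  cached_sim("clean8", n_strides = 8, seed = 42, marker_noise_sd = 0)
}

# a noisy short walk with default 0.5 mm marker noise
noisy_sim <- function() {
  cached_sim("noisy8", n_strides = 8, seed = 42)
}

# analysis config whose window covers (almost) the whole recording
config_for <- function(sim, ...) {
  cfg <- default_config()
  cfg$window_s <- floor(diff(range(sim$markers$time)))
  overrides <- list(...)
  for (nm in names(overrides)) cfg[[nm]] <- overrides[[nm]]
  cfg
}

# build a gait_markers tibble from a named list of n x 3 coordinate
# matrices (or length-3 vectors recycled over frames)
make_markers <- function(time, coords, frame_rate = 200) {
  df <- tibble::tibble(time = time)
  for (nm in names(coords)) {
    m <- coords[[nm]]
    if (is.null(dim(m))) m <- matrix(m, nrow = length(time), ncol = 3, byrow = TRUE)
    df[[paste0(nm, "_x")]] <- m[, 1]
    df[[paste0(nm, "_y")]] <- m[, 2]
    df[[paste0(nm, "_z")]] <- m[, 3]
  }
  gait_markers(df, frame_rate = frame_rate)
}

# synthetic tidy MAD profiles for compare_conditions(): one row per
# participant per phase, lognormal spread around per-phase level
make_profiles <- function(levels, phases = swing_grid(),
                          participants = sprintf("P%02d", 1:10),
                          condition = "X", sd_log = 0.15) {
  stopifnot(length(levels) == length(phases))
  grid <- expand.grid(participant = participants, phase = phases,
                      stringsAsFactors = FALSE)
  grid$condition <- condition
  grid$signal <- "toe_height"
  grid$mad <- levels[match(grid$phase, phases)] *
    exp(stats::rnorm(nrow(grid), 0, sd_log))
  grid$mean <- 0
  grid$n <- 60L
  tibble::as_tibble(grid)
}

# exact signed-rank reference: enumerate all 2^n sign patterns (no ties)
brute_force_signed_rank_p <- function(d, direction) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.numeric(signs %*% r)
  switch(direction,
         greater = mean(v_all >= v_obs),
         less = mean(v_all <= v_obs))
}
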