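#' Marker trajectory tables
#'
#' A marker trajectory set is a tibble with a `time` column (seconds) and
#' three columns `<NAME>_x`, `<NAME>_y`, `<NAME>_z` per marker (meters, lab
#' frame: x anterior in the direction of progression, y left, z vertical up),
#' carrying a `frame_rate` attribute (Hz). `gait_markers()` validates a data
#' frame and stamps the class; a single-row set serves as a quiet-standing
#' reference posture.
#'
#' @param data Data frame with `time` and `<NAME>_x/_y/_z` columns, in
#'   meters and seconds.
#' @param frame_rate Sampling rate in Hz. If `NULL`, inferred from the median
#'   time step.
#' @param validate Check invariants (constant time step, finite coordinates)?
#' @return A `gait_markers` tibble.
#' @export
#' @examples
#' df <- tibble::tibble(time = seq(0, 0.02, by = 0.005),
#'                      R_TOE_x = 0, R_TOE_y = 0, R_TOE_z = 0.02)
#' m <- gait_markers(df)
#' marker_names(m)
gait_markers <- function(data, frame_rate = NULL, validate = TRUE) {
  if (!is.data.frame(data)) abort("`data` must be a data frame.")
  data <- as_tibble(data)
  if (!"time" %in% names(data)) abort("`data` must have a `time` column.")
  coord_cols <- setdiff(names(data), "time")
  bad <- coord_cols[!grepl("_(x|y|z)$", coord_cols)]
  if (length(bad) > 0) {
    abort(paste0("Non-coordinate columns found: ", paste(bad, collapse = ", "),
                 ". Expected `<NAME>_x/_y/_z`."))
  }
  nms <- marker_names_from_cols(coord_cols)
  missing_axes <- unlist(lapply(nms, function(nm) {
    want <- paste0(nm, c("_x", "_y", "_z"))
    setdiff(want, coord_cols)
  }))
  if (length(missing_axes) > 0) {
    abort(paste0("Incomplete marker columns, missing: ",
                 paste(missing_axes, collapse = ", ")), class = "gaitvar_schema_error")
  }
  if (is.null(frame_rate)) {
    if (nrow(data) < 2) abort("Cannot infer `frame_rate` from < 2 frames.")
    frame_rate <- 1 / stats::median(diff(data$time))
  }
  out <- structure(data,
                   frame_rate = frame_rate,
                   class = c("gait_markers", class(data)))
  if (validate) validate_gait_markers(out)
  out
}

marker_names_from_cols <- function(cols) {
  unique(sub("_(x|y|z)$", "", cols))
}

validate_gait_markers <- function(x) {
  fr <- attr(x, "frame_rate")
  if (!is.numeric(fr) || fr <= 0) abort("`frame_rate` must be positive.")
  if (nrow(x) >= 2) {
    dt <- diff(x$time)
    if (any(dt <= 0)) abort("`time` must be strictly increasing.")
    if (max(abs(dt - 1 / fr)) > 1e-9) {
      abort(sprintf("`time` step is not constant at 1/%g s (tolerance 1e-9).", fr))
    }
  }
  vals <- as.matrix(x[setdiff(names(x), "time")])
  if (any(!is.finite(vals))) {
    abort("Non-finite coordinates present; fill gaps explicitly before use.",
          class = "gaitvar_gap_error")
  }
  invisible(x)
}

#' @rdname gait_markers
#' @param x A `gait_markers` tibble.
#' @export
marker_names <- function(x) {
  marker_names_from_cols(setdiff(names(x), "time"))
}

#' @rdname gait_markers
#' @export
frame_rate <- function(x) attr(x, "frame_rate")

#' Extract one marker's coordinates
#'
#' @param x A `gait_markers` tibble.
#' @param marker Canonical marker name, e.g. `"R_HEEL"`.
#' @return An `n_frames` x 3 numeric matrix with columns x, y, z (meters).
#' @export
marker_xyz <- function(x, marker) {
  cols <- paste0(marker, c("_x", "_y", "_z"))
  if (!all(cols %in% names(x))) {
    abort(paste0("Marker `", marker, "` not present."),
          class = "gaitvar_schema_error")
  }
  m <- as.matrix(x[cols])
  dimnames(m) <- list(NULL, c("x", "y", "z"))
  m
}

# keep attributes/class through dplyr-style subsetting of rows
new_markers_like <- function(template, data) {
  gait_markers(data, frame_rate = attr(template, "frame_rate"), validate = FALSE)
}

# Linear interpolation of interior NA runs up to max_gap frames; longer runs
# or NA at the record edges are an error. Used by the readers.
fill_marker_gaps <- function(data, max_gap = 10) {
  coord_cols <- setdiff(names(data), "time")
  n_filled <- 0L
  for (cc in coord_cols) {
    v <- data[[cc]]
    if (!anyNA(v)) next
    r <- rle(is.na(v))
    if (any(r$lengths[r$values] > max_gap)) {
      abort(sprintf("Column `%s` has a gap longer than %d frames.", cc, max_gap),
            class = "gaitvar_gap_error")
    }
    if (is.na(v[1]) || is.na(v[length(v)])) {
      abort(sprintf("Column `%s` has missing samples at the record edge.", cc),
            class = "gaitvar_gap_error")
    }
    idx <- which(!is.na(v))
    v <- approx(idx, v[idx], xout = seq_along(v))$y
    n_filled <- n_filled + sum(is.na(data[[cc]]))
    data[[cc]] <- v
  }
  if (n_filled > 0) {
    warn(sprintf("Linearly interpolated %d missing samples (gaps <= %d frames).",
                 n_filled, max_gap))
  }
  data
}
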