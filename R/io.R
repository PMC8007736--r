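#' Read a TRC marker-trajectory file
#'
#' Reads the tab-delimited TRC motion-capture text format (standard 5-line
#' header: `PathFileType`, field names, field values, marker-name row,
#' coordinate-label row). Coordinates are converted to meters according to
#' the header `Units` field, and marker names are mapped to the canonical
#' side-prefixed names via an alias table.
#'
#' @param path Path to a `.trc` file.
#' @param aliases Named character vector mapping vendor marker names to
#'   canonical names; canonical names always pass through unchanged.
#' @param require Character vector of marker names that must be present
#'   after mapping, or `NULL` to accept any set. Use `canonical_markers()`
#'   to demand the full 14-marker set.
#' @param max_gap Longest run of missing samples (frames) filled by linear
#'   interpolation; longer gaps raise an error.
#' @return A [gait_markers] tibble in meters and seconds.
#' @export
read_trc <- function(path, aliases = default_marker_aliases(),
                     require = NULL, max_gap = 10) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 6) {
    abort(paste0("`", path, "` is too short to be a TRC file."),
          class = "gaitvar_format_error")
  }
  keys <- strsplit(lines[2], "\t", fixed = TRUE)[[1]]
  vals <- strsplit(lines[3], "\t", fixed = TRUE)[[1]]
  need <- c("DataRate", "NumFrames", "NumMarkers", "Units")
  if (!all(need %in% keys)) {
    abort(paste0("TRC header of `", path, "` is missing field(s): ",
                 paste(setdiff(need, keys), collapse = ", ")),
          class = "gaitvar_format_error")
  }
  hdr <- setNames(vals[seq_along(keys)], keys)
  data_rate <- as.numeric(hdr[["DataRate"]])
  n_frames <- as.integer(hdr[["NumFrames"]])
  n_markers <- as.integer(hdr[["NumMarkers"]])
  units <- hdr[["Units"]]
  scale <- switch(units, mm = 1e-3, cm = 1e-2, m = 1,
                  abort(paste0("Unknown TRC Units `", units, "`."),
                        class = "gaitvar_format_error"))
  name_row <- strsplit(lines[4], "\t", fixed = TRUE)[[1]]
  raw_names <- name_row[seq(3, by = 3, length.out = n_markers)]
  raw_names <- trimws(raw_names)
  canon <- map_marker_names(raw_names, aliases, require)

  body <- lines[-(1:5)]
  body <- body[nzchar(trimws(body))]
  if (length(body) != n_frames) {
    abort(sprintf("TRC `%s`: header declares %d frames but %d data rows found.",
                  path, n_frames, length(body)), class = "gaitvar_format_error")
  }
  mat <- matrix(NA_real_, nrow = n_frames, ncol = 2 + 3 * n_markers)
  for (i in seq_len(n_frames)) {
    fields <- strsplit(body[i], "\t", fixed = TRUE)[[1]]
    v <- suppressWarnings(as.numeric(fields))
    if (length(v) < 2 + 3 * n_markers) {
      abort(sprintf("TRC `%s`: data row %d has %d fields, expected %d.",
                    path, i, length(v), 2 + 3 * n_markers),
            class = "gaitvar_format_error")
    }
    mat[i, ] <- v[seq_len(2 + 3 * n_markers)]
  }
  coords <- mat[, -(1:2), drop = FALSE] * scale
  df <- tibble(time = mat[, 2])
  for (j in seq_len(n_markers)) {
    df[[paste0(canon[j], "_x")]] <- coords[, 3 * j - 2]
    df[[paste0(canon[j], "_y")]] <- coords[, 3 * j - 1]
    df[[paste0(canon[j], "_z")]] <- coords[, 3 * j]
  }
  df <- fill_marker_gaps(df, max_gap = max_gap)
  gait_markers(df, frame_rate = data_rate)
}

map_marker_names <- function(raw, aliases, require) {
  canon <- ifelse(raw %in% names(aliases), unname(aliases[raw]), raw)
  if (anyDuplicated(canon)) {
    abort(paste0("Duplicate marker name(s) after aliasing: ",
                 paste(unique(canon[duplicated(canon)]), collapse = ", ")),
          class = "gaitvar_schema_error")
  }
  if (!is.null(require)) {
    missing <- setdiff(require, canon)
    if (length(missing) > 0) {
      abort(paste0("Required marker(s) not found: ",
                   paste(missing, collapse = ", ")),
            class = "gaitvar_schema_error")
    }
  }
  canon
}

#' Write a TRC marker-trajectory file
#'
#' Writes a [gait_markers] tibble in the tab-delimited TRC convention with
#' `Units` set to meters at 9 significant digits, so `read_trc()` round-trips
#' the values.
#'
#' @param mts A [gait_markers] tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trc <- function(mts, path) {
  nms <- marker_names(mts)
  if (length(nms) == 0) abort("Cannot write a TRC file with no markers.")
  fr <- frame_rate(mts)
  n <- nrow(mts)
  hdr1 <- paste("PathFileType", "4", "(X/Y/Z)", basename(path), sep = "\t")
  hdr2 <- paste("DataRate", "CameraRate", "NumFrames", "NumMarkers", "Units",
                "OrigDataRate", "OrigDataStartFrame", "OrigNumFrames", sep = "\t")
  hdr3 <- paste(format(fr, digits = 12), format(fr, digits = 12), n,
                length(nms), "m", format(fr, digits = 12), 1, n, sep = "\t")
  hdr4 <- paste(c("Frame#", "Time",
                  unlist(lapply(nms, function(nm) c(nm, "", "")))), collapse = "\t")
  hdr5 <- paste(c("", "",
                  unlist(lapply(seq_along(nms), function(j)
                    paste0(c("X", "Y", "Z"), j)))), collapse = "\t")
  cols <- unlist(lapply(nms, function(nm) paste0(nm, c("_x", "_y", "_z"))))
  body <- vapply(seq_len(n), function(i) {
    paste(c(i, sprintf("%.9g", mts$time[i]),
            sprintf("%.9g", as.numeric(mts[i, cols]))), collapse = "\t")
  }, character(1))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(hdr1, hdr2, hdr3, hdr4, hdr5, body), con)
  invisible(path)
}

#' Read / write the marker CSV dialect
#'
#' The CSV dialect is comma-separated UTF-8 with a header row
#' `time,<NAME>_x,<NAME>_y,<NAME>_z,...`, decimal point, meters and seconds.
#'
#' @inheritParams read_trc
#' @param frame_rate Sampling rate in Hz; inferred from `time` when `NULL`.
#' @return A [gait_markers] tibble.
#' @export
read_markers_csv <- function(path, frame_rate = NULL, require = NULL,
                             max_gap = 10) {
  df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_double()),
                        progress = FALSE)
  probs <- readr::problems(df)
  if (nrow(probs) > 0) {
    abort(sprintf("`%s`: non-numeric or malformed cell at row %d, column %d.",
                  path, probs$row[1], probs$col[1]),
          class = "gaitvar_format_error")
  }
  if (!"time" %in% names(df)) {
    abort(paste0("`", path, "` has no `time` column."),
          class = "gaitvar_format_error")
  }
  have <- marker_names_from_cols(setdiff(names(df), "time"))
  for (nm in have) {
    cols <- paste0(nm, c("_x", "_y", "_z"))
    lost <- setdiff(cols, names(df))
    if (length(lost) > 0) {
      abort(paste0("`", path, "`: marker ", nm, " is missing column(s) ",
                   paste(lost, collapse = ", "), "."),
            class = "gaitvar_schema_error")
    }
  }
  if (!is.null(require)) {
    missing <- setdiff(require, have)
    if (length(missing) > 0) {
      abort(paste0("Required marker(s) not found: ",
                   paste(missing, collapse = ", ")),
            class = "gaitvar_schema_error")
    }
  }
  df <- fill_marker_gaps(df, max_gap = max_gap)
  gait_markers(df, frame_rate = frame_rate)
}

#' @rdname read_markers_csv
#' @param mts A [gait_markers] tibble.
#' @export
write_markers_csv <- function(mts, path) {
  readr::write_csv(as_tibble(as.data.frame(mts)), path)
  invisible(path)
}
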