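# CSV readers/writers for the interchange schemas, plus flat key-value
# configs. CSV is the canonical format; the flow reader accepts a CSV
# fallback carrying the standard channel names.

read_csv_quiet <- function(path, ...) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE, ...)
}

#' Read a long-format colony-size table
#'
#' Expects columns `plate_id`, `condition`, `day`, `row`, `col` (or a `well`
#' column with A1-style labels), `strain`, `size_px`; optional `replicate`,
#' `status`, `flag`. Coordinates are normalized to 0-based integers.
#' Malformed input is rejected, never coerced: missing columns, duplicated
#' positions within a plate-day, and out-of-range coordinates all abort with
#' the offending row identified.
#'
#' @param path CSV file path.
#' @param format Optional plate format for coordinate range checking.
#' @return A validated tibble of colony observations.
#' @export
read_colony_table <- function(path, format = NULL) {
  data <- read_csv_quiet(path)
  if ("well" %in% names(data) && !all(c("row", "col") %in% names(data))) {
    rc <- well_to_rowcol(data$well)
    data$row <- rc$row; data$col <- rc$col
  }
  require_columns(data, c("plate_id", "condition", "day", "row", "col",
                          "strain", "size_px"), basename(path))
  data$row <- as.integer(data$row); data$col <- as.integer(data$col)
  key <- paste(data$plate_id, data$condition, data$day, data$row, data$col,
               sep = "\r")
  if (anyDuplicated(key)) {
    i <- which(duplicated(key))[[1L]]
    abort(sprintf(
      "Row %d duplicates position (plate %s, day %s, row %d, col %d).",
      i, data$plate_id[[i]], data$day[[i]], data$row[[i]], data$col[[i]]
    ))
  }
  if (!is.null(format)) {
    format <- as_plate_format(format)
    check_position(data$row, data$col, format)
  }
  if (any(!is.finite(data$size_px) | data$size_px < 0)) {
    i <- which(!is.finite(data$size_px) | data$size_px < 0)[[1L]]
    abort(sprintf("Row %d has an invalid size_px value.", i))
  }
  tibble::as_tibble(data)
}

#' @param data Colony table to write.
#' @param path Output CSV path.
#' @rdname read_colony_table
#' @export
write_colony_table <- function(data, path) {
  readr::write_csv(data, path)
  invisible(path)
}

#' Read/write a plate layout
#'
#' Layout CSVs carry `plate_id`, `row`, `col`, `well`, `strain`,
#' `replicate`, `layer`, `is_corner`; coordinates both 0-based and as
#' A1-style labels.
#'
#' @param layout Layout tibble from [make_snake_layout()].
#' @param path CSV path.
#' @param plate_id Plate id to stamp on export.
#' @return `write_layout()`: the path, invisibly. `read_layout()`: the
#'   layout tibble.
#' @export
write_layout <- function(layout, path, plate_id = "plate_1") {
  out <- dplyr::mutate(layout, plate_id = plate_id, .before = 1L)
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_layout
#' @export
read_layout <- function(path) {
  data <- read_csv_quiet(path)
  require_columns(data, c("row", "col", "strain"), basename(path))
  if (!"well" %in% names(data)) data$well <- rowcol_to_well(data$row, data$col)
  tibble::as_tibble(data)
}

#' Read plate-reader growth curves
#'
#' Accepts the long layout (`time`, `well`, `od`) or the wide layout (first
#' column time, one column per well), both in hours and OD600.
#'
#' @param path CSV path.
#' @param layout `"auto"` (default), `"long"` or `"wide"`.
#' @return Long tibble: `time`, `well`, `od`.
#' @export
read_growth_curves <- function(path, layout = c("auto", "long", "wide")) {
  layout <- match.arg(layout)
  data <- read_csv_quiet(path)
  is_long <- all(c("time", "well", "od") %in% names(data))
  if (layout == "auto") layout <- if (is_long) "long" else "wide"
  if (layout == "long") {
    require_columns(data, c("time", "well", "od"), basename(path))
    return(tibble::as_tibble(data[, c("time", "well", "od")]))
  }
  if (ncol(data) < 2L) abort("Wide growth-curve CSV needs time + >= 1 well.")
  names(data)[[1L]] <- "time"
  tidyr::pivot_longer(data, -"time", names_to = "well", values_to = "od")
}

#' Read flow-cytometry events from the CSV fallback
#'
#' One row per event with the standard channel names `FSC-A`, `SSC-A`,
#' `FSC-H`, `Width`, and the YFP area channel (`FL1-A` or `YFP-A`), plus
#' `day`, `replicate`, `sample_type` columns identifying the sample. A
#' `channel_map` can rename nonstandard headers. The matching `samples`
#' table (acquisition volumes) is read with [read_flow_samples()].
#'
#' @param path Events CSV path.
#' @param channel_map Named character vector mapping file headers to the
#'   canonical names `fsc_a`, `ssc_a`, `fsc_h`, `width`, `yfp_a`.
#' @return Event tibble with canonical channel columns.
#' @export
read_flow_csv <- function(path, channel_map = NULL) {
  data <- read_csv_quiet(path)
  default_map <- c("FSC-A" = "fsc_a", "SSC-A" = "ssc_a", "FSC-H" = "fsc_h",
                   "Width" = "width", "FL1-A" = "yfp_a", "YFP-A" = "yfp_a")
  map <- c(channel_map, default_map)
  hit <- names(data) %in% names(map)
  names(data)[hit] <- unname(map[names(data)[hit]])
  require_columns(data, c("day", "replicate", "sample_type", "fsc_a",
                          "ssc_a", "fsc_h", "width", "yfp_a"), basename(path))
  tibble::as_tibble(data)
}

#' @param path Samples CSV path (`day`, `replicate`, `sample_type`,
#'   `volume_ul`).
#' @rdname read_flow_csv
#' @export
read_flow_samples <- function(path) {
  data <- read_csv_quiet(path)
  require_columns(data, c("day", "replicate", "sample_type", "volume_ul"),
                  basename(path))
  tibble::as_tibble(data)
}

#' Read a flat key-value config
#'
#' Lines of `key = value` (or `key: value`); `#` comments and blank lines
#' ignored. Unknown keys are rejected (fail-fast), so a typo cannot silently
#' fall back to a default.
#'
#' @param path Config file path.
#' @param allowed Character vector of permitted keys.
#' @return Named list of values (numbers parsed as numeric).
#' @export
read_config <- function(path, allowed) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  m <- regmatches(lines, regexec("^([^=:]+)[=:](.*)$", lines))
  bad <- vapply(m, length, 0L) != 3L
  if (any(bad)) abort(sprintf("Malformed config line: '%s'",
                              lines[which(bad)[[1L]]]))
  keys <- trimws(vapply(m, `[[`, "", 2L))
  vals <- trimws(vapply(m, `[[`, "", 3L))
  unknown <- setdiff(keys, allowed)
  if (length(unknown) > 0L) {
    abort(sprintf("Unknown config key(s): %s", paste(unknown, collapse = ", ")),
          class = "colonyfit_unknown_config_key")
  }
  parsed <- lapply(vals, function(v) {
    n <- suppressWarnings(as.numeric(v))
    if (!is.na(n)) n else v
  })
  setNames(parsed, keys)
}

#' Serialize a calibration model to a key-value config (and back)
#'
#' @param model A `colony_calibration`.
#' @param path File path.
#' @return `write_calibration()`: the path, invisibly; `read_calibration()`:
#'   the model.
#' @export
write_calibration <- function(model, path) {
  writeLines(c(
    sprintf("slope = %.10g", model$slope),
    sprintf("intercept = %.10g", model$intercept),
    sprintf("r_squared = %.10g", model$r_squared),
    sprintf("day0_size = %.10g", model$day0_size)
  ), path)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  cfg <- read_config(path, c("slope", "intercept", "r_squared", "day0_size"))
  new_calibration(slope = cfg$slope, intercept = cfg$intercept,
                  r_squared = cfg$r_squared %||% NA_real_,
                  day0_size = cfg$day0_size %||% 57)
}
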