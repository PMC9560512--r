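# Colony size (pixels) -> cell number calibration and day-0 anchoring.

#' Fit the log-log size-to-cells calibration
#'
#' Colony area in pixels and colony cell number (from resuspension counts)
#' follow a power law; the calibration is an ordinary least-squares fit of
#' log10(cells) on log10(size). The fitted line converts imaged colony sizes
#' into population sizes so that growth can be expressed in generations.
#'
#' @param data A data frame with one row per calibration colony.
#' @param size,cells Columns holding colony size (pixels) and cell count;
#'   tidy-eval, defaults `size_px` and `cells`. All values must be > 0.
#' @param day0_size Mean pinned colony size in pixels, used as the day-0
#'   anchor for every trajectory. Default 57 px, the mean observed on 96- and
#'   384-density pins.
#'
#' @return A `colony_calibration` object with fields `slope`, `intercept`,
#'   `r_squared`, `day0_size`, `day0_cells`. Supports [tidy()], [glance()],
#'   [predict()].
#' @export
#'
#' @examples
#' d <- tibble::tibble(size_px = c(30, 57, 200, 1000),
#'                     cells = 10^(log10(size_px) * 1.46397 + 3.19251))
#' fit_calibration(d)
fit_calibration <- function(data, size = "size_px", cells = "cells",
                            day0_size = 57) {
  size_v <- if (is.character(size)) data[[size]] else
    dplyr::pull(data, {{ size }})
  cells_v <- if (is.character(cells)) data[[cells]] else
    dplyr::pull(data, {{ cells }})
  if (length(size_v) < 3L) {
    abort("Calibration needs at least 3 paired size/cell observations.")
  }
  if (any(!is.finite(size_v)) || any(!is.finite(cells_v)) ||
      any(size_v <= 0) || any(cells_v <= 0)) {
    abort("All calibration sizes and cell counts must be finite and > 0.")
  }
  fit <- lm(log10(cells_v) ~ log10(size_v))
  # summary.lm warns on exact fits (synthetic data); R^2 itself is fine
  r2 <- suppressWarnings(summary(fit)$r.squared)
  new_calibration(
    slope = unname(coef(fit)[[2L]]),
    intercept = unname(coef(fit)[[1L]]),
    r_squared = r2,
    day0_size = day0_size
  )
}

new_calibration <- function(slope, intercept, r_squared = NA_real_,
                            day0_size = 57) {
  if (!is.finite(slope) || slope <= 0) {
    abort("Calibration slope must be > 0: cells must increase with size.")
  }
  structure(
    list(
      slope = slope, intercept = intercept, r_squared = r_squared,
      day0_size = day0_size,
      day0_cells = 10^(log10(day0_size) * slope + intercept)
    ),
    class = "colony_calibration"
  )
}

#' The published default calibration
#'
#' The calibration fitted from hemacytometer counts of excised colonies:
#' log10(cells) = 1.46397 * log10(size) + 3.19251, anchored at a mean pinned
#' (day 0) size of 57 pixels, i.e. 579,506 cells per freshly pinned colony.
#' Ships as a named default so colony sizes can be converted without local
#' calibration data.
#'
#' @return A `colony_calibration` object.
#' @export
#'
#' @examples
#' size_to_cells(57, default_calibration())
default_calibration <- function() {
  new_calibration(slope = 1.46397, intercept = 3.19251, day0_size = 57)
}

#' @export
print.colony_calibration <- function(x, ...) {
  cat("<colony_calibration>\n")
  cat(sprintf("  log10(cells) = %.5f * log10(size_px) + %.5f\n", x$slope, x$intercept))
  if (is.finite(x$r_squared)) cat(sprintf("  R^2 = %.4f\n", x$r_squared))
  cat(sprintf("  day-0 anchor: %g px = %s cells\n", x$day0_size,
              format(round(x$day0_cells), big.mark = ",")))
  invisible(x)
}

#' @export
tidy.colony_calibration <- function(x, ...) {
  tibble::tibble(term = c("log10(size_px)", "(Intercept)"),
                 estimate = c(x$slope, x$intercept))
}

#' @export
glance.colony_calibration <- function(x, ...) {
  tibble::tibble(r.squared = x$r_squared, day0_size = x$day0_size,
                 day0_cells = x$day0_cells)
}

#' Convert colony sizes to cell numbers (and back)
#'
#' Evaluates the calibration line: `cells = 10^(log10(size) * slope +
#' intercept)`. `cells_to_size()` is the exact inverse on the same line, used
#' by the plate simulator.
#'
#' @param size Colony sizes in pixels, all > 0.
#' @param model A `colony_calibration`; defaults to [default_calibration()].
#' @return Numeric vector of cell numbers (not rounded).
#' @export
#'
#' @examples
#' size_to_cells(57)             # ~ 579,506 cells
#' cells_to_size(size_to_cells(200))  # 200
size_to_cells <- function(size, model = default_calibration()) {
  if (any(!is.finite(size)) || any(size <= 0)) {
    abort("`size` must be > 0; anchor or QC-flag zero-size records first.")
  }
  10^(log10(size) * model$slope + model$intercept)
}

#' @param cells Cell numbers, all > 0.
#' @rdname size_to_cells
#' @export
cells_to_size <- function(cells, model = default_calibration()) {
  if (any(!is.finite(cells)) || any(cells <= 0)) abort("`cells` must be > 0.")
  10^((log10(cells) - model$intercept) / model$slope)
}

#' @param object A `colony_calibration`.
#' @param newdata Optional data frame with a `size_px` column.
#' @param ... Unused.
#' @rdname size_to_cells
#' @export
predict.colony_calibration <- function(object, newdata, ...) {
  size_to_cells(newdata$size_px, object)
}

#' Anchor day-0 sizes and resolve zero-size QC flags
#'
#' Imaging software reports colonies smaller than the pinned footprint, or
#' with out-of-spec morphology (e.g. merged colonies), as size 0. Those
#' records must be adjudicated before fitness estimation: a record flagged as
#' a small-but-present colony is re-incorporated at the day-0 size; a record
#' flagged absent or morphologically complicated discards the whole colony
#' trajectory. Every day-0 record is set to the model's `day0_size` so all
#' trajectories start from the same anchored population (the mean number of
#' cells deposited by the pin).
#'
#' Adjudication is explicit: zero-size records must carry a `flag` column
#' with value `"present"` or `"absent"`; the software never guesses.
#'
#' @param data Long-format colony observations with columns `day`, `size_px`
#'   and (for any zero-size record) `flag`; typically also `plate_id`,
#'   `condition`, `row`, `col`, `strain`, `replicate`.
#' @param model A `colony_calibration` supplying `day0_size`.
#'
#' @return The tibble with anchored `size_px` and a `status` column: `"OK"`,
#'   `"RESET_TO_DAY0"` or `"DISCARD"`. `DISCARD` marks every record of the
#'   affected colony (identified by plate/row/col when present).
#' @export
anchor_day0 <- function(data, model = default_calibration()) {
  require_columns(data, c("day", "size_px"), "colony data")
  data <- tibble::as_tibble(data)
  if (!"status" %in% names(data)) data$status <- "OK"
  if (!"flag" %in% names(data)) data$flag <- NA_character_

  zero <- !is.na(data$size_px) & data$size_px == 0 & data$day > 0
  unflagged <- zero & !(data$flag %in% c("present", "absent"))
  if (any(unflagged)) {
    abort(sprintf(
      "%d zero-size record(s) lack a 'present'/'absent' flag; adjudicate them before anchoring.",
      sum(unflagged)
    ), class = "colonyfit_unflagged_zero")
  }
  bad_flag <- !zero & data$flag %in% c("absent")
  if (any(bad_flag & data$size_px > 0)) {
    abort("Conflicting flags: a record with size > 0 is flagged 'absent'.")
  }

  data$status[zero & data$flag == "present"] <- "RESET_TO_DAY0"
  data$size_px[zero & data$flag == "present"] <- model$day0_size

  # discard propagates to the colony's whole trajectory
  discard_rows <- zero & data$flag == "absent"
  key_cols <- intersect(c("plate_id", "condition", "row", "col"), names(data))
  if (any(discard_rows)) {
    if (length(key_cols) > 0L) {
      key <- do.call(paste, c(data[key_cols], sep = "\r"))
      data$status[key %in% key[discard_rows]] <- "DISCARD"
    } else {
      data$status[discard_rows] <- "DISCARD"
    }
  }

  day0 <- data$day == 0 & data$status != "DISCARD"
  data$size_px[day0] <- model$day0_size
  data$flag <- NULL
  data
}
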