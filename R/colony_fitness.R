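# Selection coefficients from colony-size trajectories: cells -> generations
# -> Malthusian slopes -> evolved-minus-ancestor slope differences.

#' Ancestor generations between two population sizes
#'
#' The number of doublings separating two cell counts, `log2(n_i / n_0)`.
#' Cumulative doublings of the ancestor population form the common "time"
#' axis against which all Malthusian slopes are taken, so that fitness is
#' expressed per ancestor generation.
#'
#' @param n_i,n_0 Cell counts, > 0 (vectorized).
#' @return Generations (dimensionless doublings).
#' @export
#'
#' @examples
#' generations(8, 1)                 # 3 doublings
#' generations(3.79e7, 579506)       # ~ 6 generations over four days
generations <- function(n_i, n_0) {
  if (any(!is.finite(n_i)) || any(!is.finite(n_0)) ||
      any(n_i <= 0) || any(n_0 <= 0)) {
    abort("Cell counts must be finite and > 0.")
  }
  log2(n_i / n_0)
}

colony_keys <- function(data) {
  intersect(c("plate_id", "condition", "row", "col"), names(data))
}

#' Build the ancestor-generation axis
#'
#' For each day, the mean over ancestor colonies of `log2(N_day / N_0)`,
#' pooling every replicate of both members of the ancestral pair. Each colony
#' must have a day-0 record (normally the anchored day-0 cell number).
#'
#' @param data Tibble of cell-count trajectories: columns `strain`, `day`,
#'   `cells`, plus colony identifiers (`plate_id`, `row`, `col` as
#'   available).
#' @param ancestors Character vector of ancestor strain ids.
#' @return A tibble with `day` and `g` (mean ancestor generations), plus an
#'   `ancestors` attribute.
#' @export
build_generation_axis <- function(data, ancestors) {
  require_columns(data, c("strain", "day", "cells"), "trajectory data")
  anc <- dplyr::filter(data, .data$strain %in% ancestors)
  if (nrow(anc) == 0L) {
    abort(sprintf("No trajectories found for ancestor strain(s) %s.",
                  paste(ancestors, collapse = ", ")))
  }
  keys <- setdiff(colony_keys(anc), "condition")
  axis <- anc |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(keys, "strain")))) |>
    dplyr::group_modify(function(d, key) {
      n0 <- d$cells[d$day == 0]
      if (length(n0) != 1L) {
        abort("Each ancestor colony needs exactly one day-0 record.")
      }
      tibble::tibble(day = d$day, g = generations(d$cells, n0))
    }) |>
    dplyr::ungroup() |>
    dplyr::group_by(.data$day) |>
    dplyr::summarise(g = mean(.data$g), .groups = "drop")
  if (dplyr::n_distinct(anc$day) < 2L) {
    abort("Ancestor trajectories need at least 2 days.")
  }
  attr(axis, "ancestors") <- unique(anc$strain)
  axis
}

log_fn <- function(base = c("ln", "log2")) {
  base <- match.arg(base)
  if (base == "ln") log else log2
}

#' Malthusian slope of a trajectory on the generation axis
#'
#' Ordinary least-squares slope of `log(cells)` against ancestor generations.
#' With `base = "ln"` an ancestor regressed on its own exact axis has slope
#' `ln 2` (~0.693); with `base = "log2"` it has slope 1. The slope is the
#' per-ancestor-generation Malthusian growth rate of the colony.
#'
#' @param cells Cell counts (> 0).
#' @param g Ancestor generations at the same days.
#' @param base Logarithm for the response: `"ln"` (default) or `"log2"`.
#' @return The OLS slope (per ancestor generation).
#' @export
malthusian_slope <- function(cells, g, base = c("ln", "log2")) {
  f <- log_fn(base)
  keep <- is.finite(cells) & is.finite(g)
  cells <- cells[keep]; g <- g[keep]
  if (length(unique(g)) < 2L) {
    abort("Generation axis is degenerate (fewer than 2 distinct values).",
          class = "colonyfit_degenerate_axis")
  }
  if (any(cells <= 0)) abort("Cell counts must be > 0.")
  y <- f(cells)
  sum((g - mean(g)) * (y - mean(y))) / sum((g - mean(g))^2)
}

#' Selection coefficient as an evolved-minus-ancestor slope difference
#'
#' @param evolved_slope Malthusian slope of one evolved replicate.
#' @param ancestor_slopes Slopes of the ancestor replicates on the same
#'   plate; their mean is subtracted.
#' @return The per-generation selection coefficient `s`.
#' @export
fitness_difference <- function(evolved_slope, ancestor_slopes) {
  stop_if_not_number(evolved_slope, "evolved_slope")
  if (length(ancestor_slopes) < 1L || any(!is.finite(ancestor_slopes))) {
    abort("`ancestor_slopes` must contain at least one finite slope.")
  }
  evolved_slope - mean(ancestor_slopes)
}

#' Per-replicate selection coefficients from cell-count trajectories
#'
#' The workhorse behind [estimate_colony_fitness()]: builds the ancestor
#' generation axis per plate/condition, fits each colony's Malthusian slope,
#' and reports for each evolved replicate the slope difference from the mean
#' ancestor slope on the same plate.
#'
#' @inheritParams build_generation_axis
#' @inheritParams malthusian_slope
#' @param last_day Restrict the regression to days `0..last_day` (default:
#'   all days present).
#' @return A tibble with one row per evolved replicate: `strain`,
#'   `condition`/`plate_id` when present, `replicate`, `s`, `evolved_slope`,
#'   `ancestor_mean_slope`, `days_used`, `log_base`.
#' @export
fitness_from_cells <- function(data, ancestors, base = c("ln", "log2"),
                               last_day = NULL) {
  base <- match.arg(base)
  require_columns(data, c("strain", "day", "cells"), "trajectory data")
  data <- tibble::as_tibble(data)
  if (!is.null(last_day)) data <- dplyr::filter(data, .data$day <= last_day)
  if (!"replicate" %in% names(data)) data$replicate <- NA_integer_

  group_keys <- intersect(c("plate_id", "condition"), names(data))
  data |>
    dplyr::group_by(dplyr::across(dplyr::all_of(group_keys))) |>
    dplyr::group_modify(function(d, key) {
      axis <- build_generation_axis(d, ancestors)
      d <- dplyr::left_join(d, axis, by = "day")
      pos_keys <- intersect(c("row", "col"), names(d))
      slopes <- d |>
        dplyr::group_by(dplyr::across(dplyr::all_of(
          c(pos_keys, "strain", "replicate")))) |>
        dplyr::summarise(
          slope = malthusian_slope(.data$cells, .data$g, base),
          days_used = dplyr::n_distinct(.data$day),
          .groups = "drop"
        )
      anc_mean <- mean(slopes$slope[slopes$strain %in% ancestors])
      slopes |>
        dplyr::filter(!(.data$strain %in% ancestors)) |>
        dplyr::transmute(
          strain = .data$strain, replicate = .data$replicate,
          s = .data$slope - anc_mean,
          evolved_slope = .data$slope,
          ancestor_mean_slope = anc_mean,
          days_used = .data$days_used,
          log_base = base
        )
    }) |>
    dplyr::ungroup()
}

#' Selection coefficients from a colony-size table
#'
#' The full plate pipeline: anchor day-0 sizes, normalize spatial (edge)
#' effects, convert sizes to cell numbers through the calibration, drop
#' corner and discarded colonies, and estimate each evolved replicate's
#' selection coefficient as the difference between its Malthusian slope and
#' the mean slope of the ancestor replicates on the same plate, all on the
#' ancestor-generation axis.
#'
#' @param data Long colony-size table: `day`, `row`, `col`, `strain`,
#'   `size_px`, optionally `plate_id`, `condition`, `replicate`, `status`,
#'   `is_corner`, `flag`.
#' @param ancestors Character vector of ancestor strain ids (the evolved
#'   strains' ancestral pair).
#' @param model Calibration; defaults to the published line.
#' @param base Log base for the slope regression: `"ln"` (default; comparable
#'   with the competitive assay's log-ratio slope) or `"log2"` (slopes in
#'   doublings per ancestor generation, so `s` is a per-generation doubling
#'   excess).
#' @param normalize Spatial correction applied per plate-day:
#'   `"rowcol"` (default), `"layer"` or `"none"`.
#' @param format Plate format (needed for corner flags and layer
#'   normalization when the table lacks `is_corner`/`layer` columns).
#' @param exclude_corners Drop the four plate corners. Default `TRUE`.
#' @inheritParams fitness_from_cells
#' @return A tibble of per-replicate estimates; see [fitness_from_cells()].
#' @export
estimate_colony_fitness <- function(data, ancestors,
                                    model = default_calibration(),
                                    base = c("ln", "log2"),
                                    normalize = c("rowcol", "layer", "none"),
                                    format = NULL,
                                    exclude_corners = TRUE,
                                    last_day = NULL) {
  base <- match.arg(base)
  normalize <- match.arg(normalize)
  require_columns(data, c("day", "row", "col", "strain", "size_px"),
                  "colony data")
  data <- tibble::as_tibble(data)
  if (!"is_corner" %in% names(data) && !is.null(format)) {
    data$is_corner <- is_plate_corner(data$row, data$col, format)
  }
  data <- anchor_day0(data, model)
  data <- switch(normalize,
    rowcol = rowcol_normalize(data, exclude_corners = exclude_corners),
    layer = layer_normalize(data, format = format,
                            exclude_corners = exclude_corners),
    none = data
  )
  drop <- data$status == "DISCARD"
  if (exclude_corners && "is_corner" %in% names(data)) {
    drop <- drop | data$is_corner
  }
  data <- data[!drop & data$size_px > 0, , drop = FALSE]
  data$cells <- size_to_cells(data$size_px, model)
  fitness_from_cells(data, ancestors, base = base, last_day = last_day)
}

#' Fitness estimates restricted to an early-day window
#'
#' Recomputes [estimate_colony_fitness()] using only days `0..last_day`, for
#' asking how many days of imaging are needed before estimates stabilize.
#'
#' @inheritParams estimate_colony_fitness
#' @param last_day Final imaging day to include (1..4 in a standard run).
#' @return As [estimate_colony_fitness()].
#' @export
fitness_by_day_window <- function(data, ancestors, last_day, ...) {
  estimate_colony_fitness(data, ancestors, last_day = last_day, ...)
}

#' Fitness versus log colony-size ratio
#'
#' The selection coefficient of a replicate and the log of its final colony
#' size relative to the mean ancestor colony size are deterministically
#' related on a shared generation axis; this fits that line per condition.
#' Conditions with fewer ancestor generations (stronger stress) give steeper
#' slopes, since the same size ratio then corresponds to fewer generations.
#'
#' @param estimates Per-replicate fitness table from
#'   [estimate_colony_fitness()] (needs `strain`, `replicate`, `s`, and
#'   `condition`/`plate_id` when present).
#' @param data The colony-size table the estimates came from.
#' @param ancestors Ancestor strain ids.
#' @param day Imaging day at which sizes are compared (default 4).
#' @return A tibble per condition: `slope`, `intercept`, `r_squared`, `n`.
#' @export
size_ratio_fitness_relation <- function(estimates, data, ancestors, day = 4) {
  require_columns(estimates, c("strain", "replicate", "s"), "estimates")
  require_columns(data, c("day", "strain", "size_px"), "colony data")
  day_n <- day
  sizes <- dplyr::filter(tibble::as_tibble(data), .data$day == day_n)
  if (!"replicate" %in% names(sizes)) sizes$replicate <- NA_integer_
  group_keys <- intersect(c("plate_id", "condition"), names(sizes))
  group_keys <- intersect(group_keys, names(estimates))

  joined <- sizes |>
    dplyr::group_by(dplyr::across(dplyr::all_of(group_keys))) |>
    dplyr::group_modify(function(d, key) {
      anc_size <- mean(d$size_px[d$strain %in% ancestors])
      d |>
        dplyr::filter(!(.data$strain %in% ancestors)) |>
        dplyr::transmute(strain = .data$strain, replicate = .data$replicate,
                         log_size_ratio = log(.data$size_px / anc_size))
    }) |>
    dplyr::ungroup() |>
    dplyr::inner_join(estimates, by = c(group_keys, "strain", "replicate"))

  cond_keys <- intersect("condition", names(joined))
  joined |>
    dplyr::group_by(dplyr::across(dplyr::all_of(cond_keys))) |>
    dplyr::group_modify(function(d, key) {
      if (nrow(d) < 3L) abort("Need >= 3 replicate points per condition.")
      if (var(d$log_size_ratio) == 0) {
        abort("Degenerate size ratios (zero spread); relation undefined.")
      }
      fit <- lm(s ~ log_size_ratio, data = d)
      tibble::tibble(
        slope = coef(fit)[[2L]], intercept = coef(fit)[[1L]],
        r_squared = summary(fit)$r.squared, n = nrow(d)
      )
    }) |>
    dplyr::ungroup()
}

#' Summarise fitness estimates per strain
#'
#' Per strain (and condition), the mean selection coefficient with a t-based
#' 95% confidence interval.
#'
#' @param estimates Per-replicate fitness table (`strain`, `s`, optionally
#'   `condition`).
#' @param conf_level Confidence level (default 0.95).
#' @return Tibble with `n`, `mean_s`, `sd_s`, `ci_lo`, `ci_hi`.
#' @export
summarise_fitness <- function(estimates, conf_level = 0.95) {
  require_columns(estimates, c("strain", "s"), "estimates")
  keys <- intersect(c("strain", "condition"), names(estimates))
  estimates |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_s = mean(.data$s),
      sd_s = sd(.data$s),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      half = qt(1 - (1 - conf_level) / 2, .data$n - 1) *
        .data$sd_s / sqrt(.data$n),
      ci_lo = .data$mean_s - .data$half,
      ci_hi = .data$mean_s + .data$half
    ) |>
    dplyr::select(-"half")
}

#' Plot per-strain fitness estimates
#'
#' @param estimates Per-replicate fitness table.
#' @return A ggplot: replicate points with mean and 95% CI per strain,
#'   faceted by condition when present.
#' @export
plot_fitness <- function(estimates) {
  summ <- summarise_fitness(estimates)
  p <- ggplot2::ggplot(estimates, ggplot2::aes(x = .data$strain, y = .data$s)) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.4, size = 0.8) +
    ggplot2::geom_pointrange(
      data = summ,
      ggplot2::aes(y = .data$mean_s, ymin = .data$ci_lo, ymax = .data$ci_hi),
      colour = "firebrick"
    ) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(x = NULL, y = "selection coefficient (per generation)") +
    ggplot2::theme_bw()
  if ("condition" %in% names(estimates)) {
    p <- p + ggplot2::facet_wrap(~condition)
  }
  p
}
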