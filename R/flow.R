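# Competitive fitness against a fluorescent reference: scatter/singlet
# ellipse gating, two-peak YFP threshold, false-negative correction of the
# marked-cell count, generations from cell concentration, and the selection
# coefficient from the log-ratio regression.

#' Fit and apply a covariance ellipse gate
#'
#' `fit_ellipse()` estimates the sample mean and covariance of two channels;
#' `in_ellipse()` keeps events whose squared Mahalanobis distance from the
#' center is within the chi-square (2 df) quantile at `level`, i.e. the
#' classical `level` probability ellipse. `ellipse_gate()` does both on the
#' same events. Gating is affine-invariant: rescaling either channel does not
#' change the mask.
#'
#' @param x,y Channel values (same length, >= 10 finite events).
#' @param level Coverage level in (0, 1), e.g. 0.99 for the scatter gate and
#'   0.95 for the singlet gate.
#' @return `fit_ellipse()`: a list with `center`, `cov`, `level`.
#'   `in_ellipse()`/`ellipse_gate()`: a logical keep-mask.
#' @export
fit_ellipse <- function(x, y, level) {
  if (length(x) != length(y)) abort("`x` and `y` must match in length.")
  keep <- is.finite(x) & is.finite(y)
  if (sum(keep) < 10L) abort("Ellipse gate needs at least 10 finite events.")
  if (level <= 0 || level >= 1) abort("`level` must be in (0, 1).")
  m <- cbind(x[keep], y[keep])
  sigma <- cov(m)
  if (!all(is.finite(sigma)) || det(sigma) <= .Machine$double.eps^2 ||
      any(diag(sigma) <= 0)) {
    abort("Channel covariance is singular; cannot fit an ellipse gate.",
          class = "colonyfit_singular_gate")
  }
  list(center = colMeans(m), cov = sigma, level = level)
}

#' @param ellipse A fitted ellipse from `fit_ellipse()`.
#' @rdname fit_ellipse
#' @export
in_ellipse <- function(x, y, ellipse) {
  d2 <- mahalanobis(cbind(x, y), ellipse$center, ellipse$cov)
  d2 <= qchisq(ellipse$level, df = 2)
}

#' @rdname fit_ellipse
#' @export
ellipse_gate <- function(x, y, level) {
  in_ellipse(x, y, fit_ellipse(x, y, level))
}

#' Fit the two-stage scatter/singlet gate set
#'
#' Stage 1 is a 99% ellipse on log10 SSC-A versus log10 FSC-A (removes
#' debris and off-scale events); stage 2 is a 95% ellipse on FSC-H versus
#' width, fitted to the stage-1 survivors (removes doublets/clumps). Gates
#' are normally fitted on the pooled events of one day and condition and
#' then applied to each sample of that pool.
#'
#' @param events Event tibble with columns `fsc_a`, `ssc_a`, `fsc_h`,
#'   `width` (linear instrument units, > 0).
#' @param scatter_level,singlet_level Ellipse coverage levels.
#' @return A `gate_set` list: `scatter` and `singlet` ellipses.
#' @export
fit_gates <- function(events, scatter_level = 0.99, singlet_level = 0.95) {
  require_columns(events, c("fsc_a", "ssc_a", "fsc_h", "width"), "events")
  if (any(events$fsc_a <= 0 | events$ssc_a <= 0)) {
    abort("Scatter areas must be > 0 for log10 gating.")
  }
  scatter <- fit_ellipse(log10(events$ssc_a), log10(events$fsc_a),
                         scatter_level)
  keep1 <- in_ellipse(log10(events$ssc_a), log10(events$fsc_a), scatter)
  singlet <- fit_ellipse(events$fsc_h[keep1], events$width[keep1],
                         singlet_level)
  structure(list(scatter = scatter, singlet = singlet), class = "gate_set")
}

#' @param gates A `gate_set` from [fit_gates()].
#' @rdname fit_gates
#' @return `apply_gates()`: the events surviving both ellipses.
#' @export
apply_gates <- function(events, gates) {
  keep <- in_ellipse(log10(events$ssc_a), log10(events$fsc_a), gates$scatter) &
    in_ellipse(events$fsc_h, events$width, gates$singlet)
  events[keep, , drop = FALSE]
}

#' Two-peak YFP threshold
#'
#' Locates the two largest modes of the log10 YFP-A histogram and places the
#' threshold at the midpoint of their bin centers -- the marked reference and
#' the unmarked strain form the two populations. The second peak must reach
#' at least `min_peak_frac` of the largest and the histogram must dip between
#' them (a valley below half the smaller peak); otherwise the distribution is
#' treated as unimodal and a manual threshold is required. In a multi-sample
#' experiment the threshold is set once, on pooled gated events, and held
#' constant.
#'
#' @param log_yfp log10 YFP-A values of gated events (>= 100).
#' @param bins Histogram bin count over the data range (default 256).
#' @param min_peak_frac Minimum height of the second peak relative to the
#'   first (default 0.05).
#' @return The threshold (log10 units).
#' @export
yfp_threshold <- function(log_yfp, bins = 256L, min_peak_frac = 0.05) {
  log_yfp <- log_yfp[is.finite(log_yfp)]
  if (length(log_yfp) < 100L) abort("Threshold detection needs >= 100 events.")
  breaks <- seq(min(log_yfp), max(log_yfp), length.out = bins + 1L)
  raw <- tabulate(findInterval(log_yfp, breaks, rightmost.closed = TRUE),
                  nbins = bins)
  centers <- (breaks[-1L] + breaks[-(bins + 1L)]) / 2
  # light running-mean smoothing so shot noise does not spawn fake modes
  counts <- as.vector(stats::filter(raw, rep(1 / 7, 7), sides = 2))
  counts[is.na(counts)] <- 0
  padded <- c(-1, counts, -1)
  is_peak <- counts > padded[seq_len(bins)] & counts >= padded[seq_len(bins) + 2L]
  peaks <- which(is_peak)
  if (length(peaks) >= 1L) {
    peaks <- peaks[order(counts[peaks], decreasing = TRUE)]
    p1 <- peaks[[1L]]
    rest <- peaks[abs(peaks - p1) > 1L &
                    counts[peaks] >= min_peak_frac * counts[p1]]
    for (p2 in rest) {
      lo <- min(p1, p2); hi <- max(p1, p2)
      valley <- min(counts[(lo + 1L):(hi - 1L)])
      if (valley < 0.5 * counts[[p2]]) {
        return((centers[[p1]] + centers[[p2]]) / 2)
      }
    }
  }
  abort("log10 YFP histogram looks unimodal; supply a manual threshold.",
        class = "colonyfit_needs_manual_threshold")
}

#' False-negative fraction of the marked reference
#'
#' Pure reference cultures contain cells whose fluorescence falls below the
#' YFP threshold; their fraction `f` (observed at 1-19% across controls) is
#' estimated from a gated reference-only control and used to correct the
#' marked-cell count in competitions.
#'
#' @param reference_events Gated events of a reference-only control.
#' @param threshold log10 YFP threshold.
#' @return `f`, the fraction of reference events below threshold. Values
#'   above 0.5 raise a warning (implausible control).
#' @export
false_negative_fraction <- function(reference_events, threshold) {
  require_columns(reference_events, "yfp_a", "reference events")
  n <- nrow(reference_events)
  if (n < 100L) abort("Reference-only control needs >= 100 gated events.")
  f <- mean(log10(reference_events$yfp_a) < threshold)
  if (f > 0.5) {
    warn(sprintf(
      "False-negative fraction %.2f > 0.5: implausible reference-only control.",
      f), class = "colonyfit_implausible_control")
  }
  f
}

#' Strain-to-reference ratio with false-negative correction
#'
#' The true number of marked reference cells among `total` gated events is
#' `p / (1 - f)`, where `p` is the YFP-positive count and `f` the
#' false-negative fraction of the marker; the unmarked-strain to reference
#' ratio is therefore `total * (1 - f) / p - 1`.
#'
#' @param total Total gated events (vectorized).
#' @param p YFP-positive events, `0 < p <= total`.
#' @param f False-negative fraction in `[0, 1)`.
#' @return The strain/reference ratio.
#' @export
#'
#' @examples
#' strain_ratio(10000, 4500, 0.1)  # 1.0
strain_ratio <- function(total, p, f) {
  if (any(p <= 0)) abort("`p` (YFP-positive count) must be > 0.")
  if (any(p > total)) abort("`p` cannot exceed `total`.")
  if (any(f < 0 | f >= 1)) abort("`f` must be in [0, 1).")
  ratio <- total * (1 - f) / p - 1
  if (any(ratio < 0)) {
    abort(paste(
      "Corrected reference count exceeds total events (p > (1 - f) * total):",
      "the false-negative control is inconsistent with this sample."
    ), class = "colonyfit_inconsistent_control")
  }
  ratio
}

#' Generations elapsed over one dilution cycle
#'
#' Each 24-h cycle starts with a `dilution` of the previous culture; the
#' doublings regrown are `log2(conc_end / (conc_prev_end * dilution))`.
#' Concentrations come from gated event counts over acquired volume. The
#' cumulative sum over cycles, taken from the ancestor strain's cultures,
#' forms the generation axis of the competition.
#'
#' @param conc_prev_end,conc_end Cell concentrations (events/uL) at the end
#'   of the previous and current cycle.
#' @param dilution Daily dilution factor (default 1/1000).
#' @return Generations (doublings) regrown in the cycle.
#' @export
#'
#' @examples
#' generations_elapsed(1000, 1000)  # log2(1000) = 9.97: full regrowth
generations_elapsed <- function(conc_prev_end, conc_end, dilution = 1 / 1000) {
  if (any(conc_prev_end <= 0) || any(conc_end <= 0)) {
    abort("Concentrations must be > 0.")
  }
  if (any(dilution <= 0 | dilution >= 1)) abort("`dilution` must be in (0, 1).")
  log2(conc_end / (conc_prev_end * dilution))
}

#' Selection coefficient from a log-ratio regression
#'
#' OLS slope of `ln(strain/reference)` against cumulative generations: the
#' per-generation selection coefficient of the unmarked strain relative to
#' the marked reference. An evolved strain's fitness difference is then its
#' `s` minus the mean `s` of its two ancestors measured against the same
#' reference.
#'
#' @param g Cumulative generations (>= 2 distinct values).
#' @param ratio Strain/reference ratios, > 0.
#' @return The slope (per generation).
#' @export
selection_coefficient <- function(g, ratio) {
  if (length(g) != length(ratio)) abort("`g` and `ratio` must match in length.")
  keep <- is.finite(g) & is.finite(ratio)
  g <- g[keep]; ratio <- ratio[keep]
  if (any(ratio <= 0)) abort("Ratios must be > 0 to take logs.")
  if (length(unique(g)) < 2L) {
    abort("Generation axis is degenerate (fewer than 2 distinct values).",
          class = "colonyfit_degenerate_axis")
  }
  y <- log(ratio)
  sum((g - mean(g)) * (y - mean(y))) / sum((g - mean(g))^2)
}

#' Full competitive-fitness pipeline
#'
#' From raw per-day event tables to per-replicate selection coefficients:
#' per day, gates are fitted on the pooled events of all samples (stage-1
#' scatter ellipse, stage-2 singlet ellipse) and applied per sample; the
#' log10 YFP threshold is detected once on pooled gated events (or supplied)
#' and held constant; the false-negative fraction comes from the same-day
#' reference-only control; ratios follow the corrected-count formula; each
#' replicate's generation axis accumulates `log2` regrowth of its own
#' culture across dilution cycles; and `s` is the slope of the log-ratio
#' regression.
#'
#' @param experiment A list with `events` (tibble: `day`, `replicate`,
#'   `sample_type` = "competition"/"reference_only", channel columns) and
#'   `samples` (tibble: `day`, `replicate`, `sample_type`, `volume_ul`), as
#'   produced by [simulate_flow_experiment()] or [read_flow_csv()].
#' @param threshold Optional manual log10 YFP threshold overriding
#'   detection.
#' @param dilution Daily dilution factor (default 1/1000).
#' @param scatter_level,singlet_level Gate coverage levels.
#' @return Tibble with one row per competition replicate: `replicate`, `s`,
#'   `n_days`. The per-day series (gated totals, `p`, `f`, ratio,
#'   concentration, cumulative generations) is attached as attribute
#'   `"series"`, and the threshold used as `"threshold"`.
#' @export
estimate_competitive_fitness <- function(experiment, threshold = NULL,
                                         dilution = 1 / 1000,
                                         scatter_level = 0.99,
                                         singlet_level = 0.95) {
  events <- experiment$events
  samples <- experiment$samples
  require_columns(events, c("day", "replicate", "sample_type", "fsc_a",
                            "ssc_a", "fsc_h", "width", "yfp_a"), "events")
  require_columns(samples, c("day", "replicate", "sample_type", "volume_ul"),
                  "samples")

  gated <- events |>
    dplyr::group_by(.data$day) |>
    dplyr::group_modify(function(d, key) apply_gates(d, fit_gates(
      d, scatter_level, singlet_level))) |>
    dplyr::ungroup()

  if (is.null(threshold)) {
    threshold <- yfp_threshold(
      log10(gated$yfp_a[gated$sample_type == "competition"]))
  }

  f_by_day <- gated |>
    dplyr::filter(.data$sample_type == "reference_only") |>
    dplyr::group_by(.data$day) |>
    dplyr::group_modify(function(d, key) {
      tibble::tibble(f = false_negative_fraction(d, threshold))
    }) |>
    dplyr::ungroup()

  series <- gated |>
    dplyr::filter(.data$sample_type == "competition") |>
    dplyr::group_by(.data$day, .data$replicate) |>
    dplyr::summarise(
      total = dplyr::n(),
      p = sum(log10(.data$yfp_a) > threshold),
      .groups = "drop"
    ) |>
    dplyr::left_join(f_by_day, by = "day") |>
    dplyr::left_join(
      dplyr::filter(samples, .data$sample_type == "competition"),
      by = c("day", "replicate")
    ) |>
    dplyr::mutate(
      ratio = strain_ratio(.data$total, .data$p, .data$f),
      concentration = .data$total / .data$volume_ul
    ) |>
    dplyr::arrange(.data$replicate, .data$day) |>
    dplyr::group_by(.data$replicate) |>
    dplyr::mutate(
      g_cycle = c(0, generations_elapsed(
        head(.data$concentration, -1L), tail(.data$concentration, -1L),
        dilution)),
      g = cumsum(.data$g_cycle)
    ) |>
    dplyr::ungroup()

  out <- series |>
    dplyr::group_by(.data$replicate) |>
    dplyr::summarise(
      s = selection_coefficient(.data$g, .data$ratio),
      n_days = dplyr::n(), .groups = "drop"
    )
  attr(out, "series") <- series
  attr(out, "threshold") <- threshold
  out
}

#' Plot a competition series
#'
#' @param fit Result of [estimate_competitive_fitness()].
#' @return A ggplot of log strain/reference ratio versus generations, one
#'   line per replicate.
#' @export
plot_competition <- function(fit) {
  series <- attr(fit, "series")
  if (is.null(series)) abort("`fit` carries no series attribute.")
  ggplot2::ggplot(series, ggplot2::aes(x = .data$g, y = log(.data$ratio),
                                       colour = factor(.data$replicate))) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::labs(x = "ancestor generations", y = "ln(strain / reference)",
                  colour = "replicate") +
    ggplot2::theme_bw()
}
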