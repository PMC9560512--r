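# Growth parameters from OD600 time series: maximum growth rate (sliding
# window), lag time, area under the log-OD curve, carrying capacity.

check_curve <- function(time, od, min_n = 2L) {
  if (length(time) != length(od)) abort("`time` and `od` must match in length.")
  if (length(time) < min_n) {
    abort(sprintf("Growth curve needs at least %d points.", min_n))
  }
  if (any(!is.finite(time)) || any(diff(time) <= 0)) {
    abort("`time` must be finite and strictly increasing.")
  }
  if (any(!is.finite(od)) || any(od <= 0)) {
    abort("`od` must be finite and > 0 (blank-corrected OD600).")
  }
  invisible(NULL)
}

# OLS slope/intercept in every contiguous window of w points, via rolling
# sums (a 24 h / 4 min series has ~346 windows; no per-window lm needed).
rolling_fits <- function(time, y, w) {
  n <- length(time)
  csum <- function(x) { c0 <- cumsum(x); c0[w:n] - c(0, c0[seq_len(n - w)]) }
  sx <- csum(time); sy <- csum(y)
  sxx <- csum(time^2); sxy <- csum(time * y)
  denom <- w * sxx - sx^2
  slope <- (w * sxy - sx * sy) / denom
  intercept <- (sy - slope * sx) / w
  tibble::tibble(start = seq_len(n - w + 1L), slope = slope,
                 intercept = intercept)
}

#' Maximum growth rate from a sliding window
#'
#' Fits an OLS line to `log(od)` versus time in every contiguous window of
#' `window` points (15 points = 1 h on a 4-min acquisition grid) and returns
#' the steepest slope -- the culture's maximum specific growth rate, in
#' h^-1 (natural-log units). Ties go to the earliest window.
#'
#' @param time Hours, strictly increasing.
#' @param od Blank-corrected OD600 values, > 0.
#' @param window Number of points per window (default 15).
#' @return A list: `rate` (h^-1), `window_start` (index of the first point of
#'   the maximizing window), `intercept` (of the max-rate line in log-OD).
#' @export
#'
#' @examples
#' t <- seq(0, 24, by = 4 / 60)
#' max_growth_rate(t, 0.05 * exp(0.4 * t))$rate  # 0.4
max_growth_rate <- function(time, od, window = 15L) {
  check_curve(time, od, min_n = window)
  fits <- rolling_fits(time, log(od), window)
  best <- which.max(fits$slope)  # which.max takes the earliest tie
  list(rate = fits$slope[[best]], window_start = fits$start[[best]],
       intercept = fits$intercept[[best]])
}

#' Lag time from the intersection of two fitted lines
#'
#' The lag is the time coordinate where the line fitted to the first
#' `window` log-OD points (the pre-growth baseline) crosses the maximum
#' growth rate line. If the two lines are close to parallel (slope difference
#' below `tol`), the lag is undefined -- e.g. a culture already growing
#' exponentially at t = 0 -- and `NA` is returned with a flag.
#'
#' @inheritParams max_growth_rate
#' @param tol Minimum slope difference (h^-1) below which the lag is
#'   declared undefined.
#' @return A list: `lag` (hours, or `NA`), `defined` (logical), `suspicious`
#'   (`TRUE` when the lag precedes the first time point by more than 1 h).
#' @export
lag_time <- function(time, od, window = 15L, tol = 1e-6) {
  check_curve(time, od, min_n = window)
  y <- log(od)
  first <- lm(y[seq_len(window)] ~ time[seq_len(window)])
  b1 <- coef(first)[[2L]]; a1 <- coef(first)[[1L]]
  mx <- max_growth_rate(time, od, window)
  if (abs(mx$rate - b1) < tol) {
    return(list(lag = NA_real_, defined = FALSE, suspicious = FALSE))
  }
  lag <- (a1 - mx$intercept) / (mx$rate - b1)
  list(lag = lag, defined = TRUE, suspicious = lag < time[[1L]] - 1)
}

#' Area under the log-OD curve
#'
#' Trapezoidal integral of `log(od)` over time with the rectangle under the
#' smallest measured log-OD removed, so a culture that never grows scores 0.
#' Units: log-OD x hours.
#'
#' @inheritParams max_growth_rate
#' @return Non-negative area.
#' @export
growth_auc <- function(time, od) {
  check_curve(time, od, min_n = 2L)
  y <- log(od)
  n <- length(y)
  trap <- sum(diff(time) * (y[-1L] + y[-n]) / 2)
  trap - min(y) * (time[[n]] - time[[1L]])
}

#' Carrying capacity
#'
#' The highest OD600 the culture reaches within the assay window.
#'
#' @inheritParams max_growth_rate
#' @return Maximum OD600.
#' @export
carrying_capacity <- function(time, od) {
  check_curve(time, od, min_n = 1L)
  max(od)
}

#' All four growth parameters for one or many wells
#'
#' Tidy wrapper: computes maximum growth rate, lag time, area under the
#' log-OD curve and carrying capacity per well.
#'
#' @param data Long tibble with columns `time` (hours) and `od`, plus an
#'   optional `well` column identifying curves.
#' @param window Sliding-window width in points (default 15).
#' @return One row per well: `max_rate`, `lag`, `lag_defined`,
#'   `lag_suspicious`, `auc`, `capacity`.
#' @export
#'
#' @examples
#' d <- simulate_growth_curve(lag = 3, rate = 0.35, K = 1.2, seed = 1)
#' growth_params(d)
growth_params <- function(data, window = 15L) {
  require_columns(data, c("time", "od"), "growth data")
  data <- tibble::as_tibble(data)
  if (!"well" %in% names(data)) data$well <- "well_1"
  data |>
    dplyr::group_by(.data$well) |>
    dplyr::group_modify(function(d, key) {
      d <- dplyr::arrange(d, .data$time)
      mx <- max_growth_rate(d$time, d$od, window)
      lg <- lag_time(d$time, d$od, window)
      tibble::tibble(
        max_rate = mx$rate,
        lag = lg$lag, lag_defined = lg$defined,
        lag_suspicious = lg$suspicious,
        auc = growth_auc(d$time, d$od),
        capacity = carrying_capacity(d$time, d$od)
      )
    }) |>
    dplyr::ungroup()
}

#' Plot growth curves with fitted lag and max-rate lines
#'
#' @param data Long tibble (`time`, `od`, optional `well`).
#' @param window Sliding-window width.
#' @return A ggplot of log OD600 versus time with the two fitted lines.
#' @export
plot_growth_curve <- function(data, window = 15L) {
  require_columns(data, c("time", "od"), "growth data")
  data <- tibble::as_tibble(data)
  if (!"well" %in% names(data)) data$well <- "well_1"
  params <- growth_params(data, window)
  p <- ggplot2::ggplot(data, ggplot2::aes(x = .data$time, y = log(.data$od))) +
    ggplot2::geom_point(size = 0.3, alpha = 0.5) +
    ggplot2::geom_vline(data = params, ggplot2::aes(xintercept = .data$lag),
                        linetype = 2, colour = "firebrick", na.rm = TRUE) +
    ggplot2::labs(x = "time (h)", y = "log OD600") +
    ggplot2::theme_bw()
  if (dplyr::n_distinct(data$well) > 1L) p <- p + ggplot2::facet_wrap(~well)
  p
}
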