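# Significance testing, FDR, error (RMSE) quantification, power analysis and
# cross-experiment reproducibility for fitness estimates.

#' One-sample t-test of fitness against zero
#'
#' Two-sided one-sample t-test with the null mean at 0, applied to a group of
#' replicate selection coefficients.
#'
#' @param values Replicate `s` values (n >= 2, nonzero variance).
#' @return The two-sided p-value.
#' @export
#'
#' @examples
#' one_sample_test(c(1, 2, 3, 4, 5))  # ~ 0.0132
one_sample_test <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 2L) abort("Need at least 2 replicate values.")
  if (var(values) == 0) {
    abort("Replicate values have zero variance; t-test undefined.")
  }
  t.test(values, mu = 0)$p.value
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment across a family of tests (wraps
#' `stats::p.adjust(method = "BH")` after range validation).
#'
#' @param pvals p-values in `[0, 1]`.
#' @return q-values, monotone non-decreasing in p.
#' @export
bh_fdr <- function(pvals) {
  if (any(!is.finite(pvals)) || any(pvals < 0 | pvals > 1)) {
    abort("p-values must lie in [0, 1].")
  }
  p.adjust(pvals, method = "BH")
}

#' Per-group fitness tests with FDR correction
#'
#' For each strain (x condition) group: mean `s`, t-based confidence
#' interval, one-sample t-test against 0, and BH q-values across the whole
#' family of groups. FDR is corrected within one assay's table -- never
#' across assays.
#'
#' @param estimates Per-replicate fitness table (`strain`, `s`, optional
#'   `condition`).
#' @param alpha FDR threshold for the `significant` flag (default 0.05).
#' @param conf_level Confidence level for the interval (default 0.95).
#' @return One row per group: summary columns plus `p_value`, `q_value`,
#'   `significant`.
#' @export
fitness_tests <- function(estimates, alpha = 0.05, conf_level = 0.95) {
  summ <- summarise_fitness(estimates, conf_level)
  keys <- intersect(c("strain", "condition"), names(estimates))
  pvals <- estimates |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(p_value = one_sample_test(.data$s), .groups = "drop")
  out <- dplyr::left_join(summ, pvals, by = keys)
  out$q_value <- bh_fdr(out$p_value)
  out$significant <- out$q_value < alpha
  out
}

#' Assay error scale: RMSE of the fitness-by-strain ANOVA
#'
#' Fits `s ~ strain` (one-way ANOVA) per condition and reports the root mean
#' square of the residuals -- the assay's empirical per-replicate error.
#' The default denominator is the total n (mean squared residual); set
#' `use_df = TRUE` for the residual-degrees-of-freedom variant.
#'
#' @param estimates Per-replicate fitness table (`strain`, `s`, optional
#'   `condition`).
#' @param use_df Divide by residual df instead of n.
#' @return Tibble per condition: `rmse`, `r_squared` (variance in fitness
#'   explained by strain), `n`.
#' @export
rmse_by_strain <- function(estimates, use_df = FALSE) {
  require_columns(estimates, c("strain", "s"), "estimates")
  keys <- intersect("condition", names(estimates))
  estimates |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::group_modify(function(d, key) {
      if (dplyr::n_distinct(d$strain) < 2L) {
        abort("RMSE needs at least 2 strains per condition.")
      }
      fit <- aov(s ~ strain, data = d)
      res <- residuals(fit)
      denom <- if (use_df) fit$df.residual else length(res)
      tibble::tibble(
        rmse = sqrt(sum(res^2) / denom),
        r_squared = variance_explained(d$s, d$strain),
        n = nrow(d)
      )
    }) |>
    dplyr::ungroup()
}

#' Power of the two-sided one-sample t-test
#'
#' Exact power from the noncentral t distribution, with noncentrality
#' `(effect / sd) * sqrt(n)`.
#'
#' @param effect True fitness difference to detect.
#' @param n Replicates.
#' @param sd Per-replicate error (e.g. the assay RMSE).
#' @param alpha Two-sided significance level (default 0.05).
#' @return Power in `[0, 1]`.
#' @export
power_one_sample_t <- function(effect, n, sd, alpha = 0.05) {
  if (n < 2) abort("Power needs n >= 2.")
  stop_if_not_number(sd, "sd", positive = TRUE)
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must be in (0, 1).")
  df <- n - 1
  tcrit <- qt(1 - alpha / 2, df)
  ncp <- (effect / sd) * sqrt(n)
  1 - pt(tcrit, df, ncp = ncp) + pt(-tcrit, df, ncp = ncp)
}

#' Minimum detectable fitness difference
#'
#' Inverts the one-sample t power function: the smallest true fitness
#' difference detectable with the given replication, per-replicate error and
#' significance level at the target power.
#'
#' @inheritParams power_one_sample_t
#' @param power Target power (default 0.80).
#' @return The minimum detectable difference, on the scale of `sd`.
#' @export
#'
#' @examples
#' power_min_detectable(n = 32, sd = 0.0176)  # ~ 0.009: a < 1% difference
power_min_detectable <- function(n, sd, alpha = 0.05, power = 0.80) {
  if (power <= alpha || power >= 1) {
    abort("`power` must be in (alpha, 1).")
  }
  fn <- function(effect) power_one_sample_t(effect, n, sd, alpha) - power
  upper <- sd * 100
  if (fn(upper) < 0) {
    abort("No finite effect reaches the target power within bounds.",
          class = "colonyfit_power_unattainable")
  }
  uniroot(fn, c(1e-12, upper), tol = 1e-12)$root
}

#' Reproducibility between two fitness experiments
#'
#' Pearson correlation of strain (x condition) mean selection coefficients
#' between two independently measured tables.
#'
#' @param set_a,set_b Per-replicate fitness tables sharing at least 3
#'   strain x condition groups.
#' @return A list: `r` (Pearson correlation of group means), `n_groups`,
#'   and the paired means tibble (`means`).
#' @export
compare_experiments <- function(set_a, set_b) {
  keys <- intersect(intersect(c("strain", "condition"), names(set_a)),
                    names(set_b))
  mean_of <- function(d) {
    d |>
      dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
      dplyr::summarise(mean_s = mean(.data$s), .groups = "drop")
  }
  paired <- dplyr::inner_join(mean_of(set_a), mean_of(set_b), by = keys,
                              suffix = c("_a", "_b"))
  if (nrow(paired) < 3L) {
    abort("Need at least 3 shared strain x condition groups.")
  }
  list(r = cor(paired$mean_s_a, paired$mean_s_b), n_groups = nrow(paired),
       means = paired)
}

#' Assay summary table
#'
#' One row per condition with the quantities used to judge an assay: RMSE,
#' variance in fitness explained by strain, and the minimum detectable
#' fitness difference at the stated power and significance.
#'
#' @inheritParams rmse_by_strain
#' @param n Replicates per group used in the power calculation; defaults to
#'   the median group size in the table.
#' @param alpha,power Significance level and target power.
#' @return Tibble: `condition` (if present), `rmse`, `r_squared`,
#'   `min_detectable`, `n_power`.
#' @export
assay_summary <- function(estimates, n = NULL, alpha = 0.05, power = 0.80) {
  base <- rmse_by_strain(estimates)
  keys <- intersect(c("strain", "condition"), names(estimates))
  if (is.null(n)) {
    n <- estimates |>
      dplyr::count(dplyr::across(dplyr::all_of(keys))) |>
      dplyr::pull(.data$n) |>
      median()
  }
  base$min_detectable <- vapply(
    base$rmse, function(sd) power_min_detectable(n, sd, alpha, power), 0
  )
  base$n_power <- n
  base
}
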