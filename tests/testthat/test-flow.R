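test_that("the 99% ellipse keeps 99% of a bivariate normal", {
  withr::with_seed(10, {
    x <- rnorm(1e5); y <- 0.6 * x + rnorm(1e5, 0, 0.8)
  })
  keep <- ellipse_gate(x, y, 0.99)
  expect_equal(mean(keep), 0.990, tolerance = 0.003)
  keep95 <- ellipse_gate(x, y, 0.95)
  expect_equal(mean(keep95), 0.950, tolerance = 0.005)
})

test_that("degenerate channels cannot be gated", {
  withr::with_seed(1, x <- rnorm(1000))
  expect_error(ellipse_gate(x, x * 2 + 3, 0.99),
               class = "colonyfit_singular_gate")
  expect_error(ellipse_gate(rep(1, 1000) + 1e-300 * rnorm(1000), rnorm(1000),
                            0.99), class = "colonyfit_singular_gate")
  expect_error(ellipse_gate(rnorm(5), rnorm(5), 0.99), "10")
})

test_that("ellipse masks are invariant to affine channel rescaling", {
  withr::with_seed(11, {
    x <- rnorm(5000, 5, 0.3); y <- rnorm(5000, 4, 0.2) + 0.3 * x
  })
  m1 <- ellipse_gate(x, y, 0.95)
  m2 <- ellipse_gate(100 * x - 7, 0.01 * y + 3, 0.95)
  expect_identical(m1, m2)
})

test_that("the YFP threshold lands midway between two populations", {
  withr::with_seed(12, {
    bal <- c(rnorm(5000, 2, 0.1), rnorm(5000, 4, 0.1))
    skew <- c(rnorm(9000, 2, 0.1), rnorm(1000, 4, 0.1))
    uni <- rnorm(10000, 3, 0.3)
  })
  expect_lt(abs(yfp_threshold(bal) - 3.0), 0.1)
  # peak locations do not move with a 90/10 imbalance
  expect_lt(abs(yfp_threshold(skew) - 3.0), 0.15)
  expect_error(yfp_threshold(uni),
               class = "colonyfit_needs_manual_threshold")
  expect_error(yfp_threshold(rnorm(50)), "100")
})

test_that("the false-negative fraction recovers the simulated dim rate", {
  withr::with_seed(13, {
    n <- 20000
    dim <- runif(n) < 0.05
    ref <- tibble::tibble(yfp_a = 10^ifelse(dim, rnorm(n, 2, 0.15),
                                            rnorm(n, 4, 0.15)))
  })
  expect_lt(abs(false_negative_fraction(ref, 3.0) - 0.05), 0.01)
  bright <- tibble::tibble(yfp_a = 10^rnorm(500, 4, 0.1))
  expect_equal(false_negative_fraction(bright, 3.0), 0)
  dim_only <- tibble::tibble(yfp_a = 10^rnorm(500, 2, 0.1))
  expect_warning(false_negative_fraction(dim_only, 3.0),
                 class = "colonyfit_implausible_control")
})

test_that("the corrected ratio follows the published count algebra", {
  expect_equal(strain_ratio(10000, 5000, 0), 1.0)
  expect_equal(strain_ratio(10000, 4500, 0.1), 1.0)
  # a pure-reference sample: p equals the corrected total
  expect_equal(strain_ratio(10000, 9000, 0.1), 0.0)
  expect_error(strain_ratio(100, 0, 0), "> 0")
  expect_error(strain_ratio(100, 99, 0.1),
               class = "colonyfit_inconsistent_control")
  expect_error(strain_ratio(100, 50, 1), "\\[0, 1\\)")
})

test_that("Eq-1 style correction is unbiased where the raw count is not", {
  # simulated mixture with known truth: strain:reference = 1.5, f = 0.19
  withr::with_seed(14, {
    n <- 1e5
    truth_ratio <- 1.5
    is_strain <- runif(n) < truth_ratio / (1 + truth_ratio)
    dim <- !is_strain & runif(n) < 0.19
    p <- sum(!is_strain & !dim)
  })
  corrected <- strain_ratio(n, p, 0.19)
  expect_equal(corrected, truth_ratio, tolerance = 0.01 * truth_ratio)
  # ignoring f inflates the apparent strain fraction by 1/(1-f)
  uncorrected <- n / p - 1
  predicted_bias <- (1 + truth_ratio) / (1 - 0.19) - 1
  expect_equal(uncorrected, predicted_bias, tolerance = 0.01 * predicted_bias)
})

test_that("generations per cycle come from the dilution-adjusted regrowth", {
  expect_equal(generations_elapsed(1000, 1000), log2(1000), tolerance = 1e-12)
  expect_equal(generations_elapsed(1000, 1000), 9.9658, tolerance = 1e-4)
  expect_equal(generations_elapsed(1000, 1), 0)  # 1/1000 with no regrowth
  # a ratio definition: concentrations scale with 1/volume
  expect_equal(generations_elapsed(5e4 / 14, 5e4 / 7), log2(2000),
               tolerance = 1e-12)
  expect_error(generations_elapsed(0, 10), "> 0")
})

test_that("the log-ratio slope recovers exact selection coefficients", {
  g <- c(0, 10, 20, 30)
  expect_equal(selection_coefficient(g, rep(2, 4)), 0)
  expect_equal(selection_coefficient(g, exp(0.02 * g)), 0.02,
               tolerance = 1e-9)
  expect_error(selection_coefficient(rep(5, 3), c(1, 2, 3)),
               class = "colonyfit_degenerate_axis")
  expect_error(selection_coefficient(g, c(-1, 1, 1, 1)), "> 0")
})

test_that("s from the full pipeline is invariant to concentration rescaling", {
  ex <- simulate_flow_experiment(s = 0.04, replicates = 3, n_events = 8000,
                                 seed = 21)
  f1 <- estimate_competitive_fitness(ex)
  ex$samples$volume_ul <- ex$samples$volume_ul * 5  # conc / 5 everywhere
  f2 <- estimate_competitive_fitness(ex)
  expect_equal(f1$s, f2$s, tolerance = 1e-12)
})

test_that("gating keeps most well-behaved events and strips the rest", {
  ex <- simulate_flow_experiment(s = 0, replicates = 2, n_events = 20000,
                                 seed = 22)
  day0 <- dplyr::filter(ex$events, day == 0)
  gates <- fit_gates(day0)
  gated <- apply_gates(day0, gates)
  singlets <- !is.na(day0$truth_strain)
  retention <- sum(!is.na(gated$truth_strain)) / sum(singlets)
  expect_gt(retention, 0.85)
  expect_lt(retention, 0.999)
  # the gated pool is purer than the raw pool
  expect_gt(mean(!is.na(gated$truth_strain)), mean(singlets))
})

test_that("simulated experiments are deterministic in their seed", {
  a <- simulate_flow_experiment(replicates = 1, n_events = 500, seed = 5)
  b <- simulate_flow_experiment(replicates = 1, n_events = 500, seed = 5)
  expect_identical(a$events, b$events)
  c <- simulate_flow_experiment(replicates = 1, n_events = 500, seed = 6)
  expect_false(identical(a$events$yfp_a, c$events$yfp_a))
})
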