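test_that("generations follow the log2 ratio of cell counts", {
  expect_equal(generations(579506, 579506), 0)
  expect_equal(generations(8 * 579506, 579506), 3)
  # four days of growth in the published worked numbers: ~6 doublings
  expect_equal(generations(3.79e7, 579506), 6.03123, tolerance = 1e-5)
  expect_error(generations(0, 10), "> 0")
  expect_error(generations(10, -1), "> 0")
})

test_that("the generation axis averages ancestor replicate doublings", {
  # single ancestor doubling daily
  anc <- exact_trajectory(0, days = 0:4, g_per_day = 1, strain = "anc1")
  axis <- build_generation_axis(anc, "anc1")
  expect_equal(axis$g, c(0, 1, 2, 3, 4))

  # two ancestors reaching 5.8 and 6.2 generations at day 4 -> mean 6.0
  a1 <- exact_trajectory(0, days = c(0, 4), g_per_day = 5.8 / 4,
                         strain = "anc1", row = 0)
  a2 <- exact_trajectory(0, days = c(0, 4), g_per_day = 6.2 / 4,
                         strain = "anc2", row = 1)
  axis2 <- build_generation_axis(dplyr::bind_rows(a1, a2), c("anc1", "anc2"))
  expect_equal(axis2$g[axis2$day == 4], 6.0, tolerance = 1e-12)

  expect_error(build_generation_axis(a1, "missing_strain"), "No trajectories")
})

test_that("a non-growing ancestor gives a degenerate axis that is rejected", {
  anc <- exact_trajectory(0, g_per_day = 0, strain = "anc1")
  axis <- build_generation_axis(anc, "anc1")
  expect_true(all(axis$g == 0))
  expect_error(malthusian_slope(anc$cells, axis$g),
               class = "colonyfit_degenerate_axis")
})

test_that("Malthusian slopes hit the closed forms on exact trajectories", {
  anc <- exact_trajectory(0)
  axis <- build_generation_axis(anc, "ev")
  expect_equal(malthusian_slope(anc$cells, axis$g, base = "log2"), 1,
               tolerance = 1e-12)
  expect_equal(malthusian_slope(anc$cells, axis$g, base = "ln"), log(2),
               tolerance = 1e-12)
  # strain growing 2^1.05 per ancestor generation
  ev <- exact_trajectory(0.05)
  expect_equal(malthusian_slope(ev$cells, axis$g, base = "ln"), 1.05 * log(2),
               tolerance = 1e-12)
  expect_equal(malthusian_slope(ev$cells, axis$g, base = "ln"), 0.727805,
               tolerance = 1e-4)
})

test_that("fitness differences are slope differences in the chosen base", {
  d <- exact_trajectories(c(anc1 = 0, anc2 = 0, ev = 0.05))
  fit_ln <- fitness_from_cells(d, c("anc1", "anc2"), base = "ln")
  fit_l2 <- fitness_from_cells(d, c("anc1", "anc2"), base = "log2")
  expect_identical(nrow(fit_ln), 1L)
  expect_equal(fit_ln$s, 0.05 * log(2), tolerance = 1e-12)
  expect_equal(fit_ln$s, 0.034657, tolerance = 1e-4)
  expect_equal(fit_l2$s, 0.05, tolerance = 1e-12)
  # the two bases differ by exactly ln 2
  expect_equal(fit_ln$s / fit_l2$s, log(2), tolerance = 1e-12)
  expect_equal(fit_ln$s,
               fitness_difference(fit_ln$evolved_slope,
                                  fit_ln$ancestor_mean_slope))
  # an evolved strain identical to the ancestors scores zero
  d0 <- exact_trajectories(c(anc1 = 0, anc2 = 0, twin = 0))
  expect_equal(fitness_from_cells(d0, c("anc1", "anc2"))$s, 0,
               tolerance = 1e-12)
})

test_that("s is invariant to a common rescaling of all cell counts", {
  d <- exact_trajectories(c(anc1 = 0, anc2 = 0, ev = 0.07))
  s1 <- fitness_from_cells(d, c("anc1", "anc2"))$s
  d$cells <- d$cells * 3.7
  s2 <- fitness_from_cells(d, c("anc1", "anc2"))$s
  expect_equal(s1, s2, tolerance = 1e-12)
})

test_that("day windows agree exactly on noiseless data", {
  strain_s <- c(anc1 = 0, anc2 = 0, ev = 0.08)
  d <- simulate_plate(strain_s, format = 96, sigma = 0, profile = "flat",
                      seed = 3)
  full <- estimate_colony_fitness(d, c("anc1", "anc2"), normalize = "none")
  for (last in 1:4) {
    win <- fitness_by_day_window(d, c("anc1", "anc2"), last_day = last,
                                 normalize = "none")
    expect_equal(sort(win$s), sort(full$s), tolerance = 1e-9,
                 label = sprintf("window day %d", last))
  }
})

test_that("longer day windows tighten noisy estimates", {
  strain_s <- c(anc1 = 0, anc2 = 0, ev = 0.05)
  spread <- vapply(c(1L, 4L), function(last) {
    reps <- vapply(1:100, function(seed) {
      d <- simulate_plate(strain_s, format = 96, sigma = 0.1,
                          profile = "flat", seed = seed)
      fit <- fitness_by_day_window(d, c("anc1", "anc2"), last_day = last,
                                   normalize = "none", base = "log2")
      mean(fit$s)
    }, 0)
    sd(reps)
  }, 0)
  expect_gt(spread[[1]], spread[[2]])
})

test_that("fitness tracks the log colony-size ratio, steeper under low g", {
  # noiseless: fitness and the day-4 size ratio are two views of one number
  strain_s <- c(anc1 = 0, anc2 = 0, ev1 = 0.02, ev2 = 0.05, ev3 = 0.10)
  d6 <- simulate_plate(strain_s, format = 96, sigma = 1e-4, profile = "flat",
                       g_per_day = 1.5, seed = 5, condition = "low_stress")
  f6 <- estimate_colony_fitness(d6, c("anc1", "anc2"), normalize = "none")
  rel6 <- size_ratio_fitness_relation(f6, d6, c("anc1", "anc2"))
  expect_gt(rel6$r_squared, 0.99)

  # halving ancestor generations (stress) steepens the slope
  d3 <- simulate_plate(strain_s, format = 96, sigma = 1e-4, profile = "flat",
                       g_per_day = 0.75, seed = 6, condition = "high_stress")
  f3 <- estimate_colony_fitness(d3, c("anc1", "anc2"), normalize = "none")
  rel3 <- size_ratio_fitness_relation(f3, d3, c("anc1", "anc2"))
  expect_gt(rel3$slope, rel6$slope)

  # identical trajectories have no spread to regress on
  flat <- simulate_plate(c(anc1 = 0, anc2 = 0, ev = 0), format = 96,
                         sigma = 0, profile = "flat", seed = 7)
  ffit <- estimate_colony_fitness(flat, c("anc1", "anc2"), normalize = "none")
  expect_error(size_ratio_fitness_relation(ffit, flat, c("anc1", "anc2")),
               "Degenerate|zero spread")
})

test_that("discarded trajectories yield no fitness estimate", {
  strain_s <- c(anc1 = 0, anc2 = 0, ev = 0.05)
  d <- simulate_plate(strain_s, format = 96, sigma = 0, profile = "flat",
                      seed = 9)
  # flag one evolved colony absent at day 2
  target <- which(d$strain == "ev" & d$replicate == 1 & d$day == 2)
  d$size_px[target] <- 0
  d$flag <- NA_character_
  d$flag[target] <- "absent"
  fit <- estimate_colony_fitness(d, c("anc1", "anc2"), normalize = "none")
  expect_false(any(fit$strain == "ev" & fit$replicate == 1))
  expect_true(any(fit$strain == "ev" & fit$replicate == 2))
})

test_that("per-strain summaries carry t-based confidence intervals", {
  withr::with_seed(17, {
    est <- tibble::tibble(strain = rep(c("a", "b"), each = 20),
                          s = rnorm(40, rep(c(0.02, 0.05), each = 20), 0.01))
  })
  summ <- summarise_fitness(est)
  expect_identical(nrow(summ), 2L)
  a <- est$s[est$strain == "a"]
  ci <- mean(a) + c(-1, 1) * qt(0.975, 19) * sd(a) / sqrt(20)
  expect_equal(c(summ$ci_lo[[1]], summ$ci_hi[[1]]), ci, tolerance = 1e-12)
})
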