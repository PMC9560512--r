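test_that("constant plates pass through every normalization unchanged", {
  d <- plate_table(96, function(r, c) rep(100, length(r)))
  for (out in list(rowcol_normalize(d), rowcol_normalize(d, stat = "median"),
                   layer_normalize(d, 96))) {
    expect_equal(out$size_px, d$size_px)
  }
})

test_that("rank-1 row x column structure flattens to the grand mean", {
  withr::with_seed(4, {
    v <- runif(4, 1, 3); w <- runif(6, 1, 2)
  })
  d <- tibble::tibble(row = rep(0:3, each = 6), col = rep(0:5, 4))
  d$size_px <- v[d$row + 1] * w[d$col + 1]
  out <- rowcol_normalize(d, exclude_corners = FALSE)
  expect_equal(out$size_px, rep(mean(d$size_px), 24), tolerance = 1e-12)
})

test_that("the row pass equalizes a doubled row's mean", {
  d <- tibble::tibble(row = rep(0:3, each = 6), col = rep(0:5, 4))
  withr::with_seed(8, d$size_px <- runif(24, 80, 120))
  d$size_px[d$row == 2] <- 2 * d$size_px[d$row == 2]
  out <- rowcol_normalize(d, exclude_corners = FALSE)
  row_means <- as.vector(tapply(out$size_px, out$row, mean))
  col_means <- as.vector(tapply(out$size_px, out$col, mean))
  # column means are exactly the grand mean after the second pass
  expect_equal(col_means, rep(mean(out$size_px), 6), tolerance = 1e-12)
  # the doubled row no longer stands out
  expect_lt(diff(range(row_means)) / mean(out$size_px), 0.05)
  # grand mean preserved
  expect_equal(mean(out$size_px), mean(d$size_px), tolerance = 1e-12)
})

test_that("mean normalization is a fixed point on separable plates and
          contracts otherwise", {
  # exactly separable row x column structure: one application reaches the
  # fixed point, a second changes nothing
  d <- plate_table(96, function(r, c) 100 * (1 + 0.1 * r) * (1 - 0.05 * c))
  once <- rowcol_normalize(d, exclude_corners = FALSE)
  twice <- rowcol_normalize(once, exclude_corners = FALSE)
  expect_equal(twice$size_px, once$size_px, tolerance = 1e-9)

  # with non-separable residual variation, re-application moves values far
  # less than the first application did (Sinkhorn-style contraction)
  withr::with_seed(6, {
    n <- plate_table(96, function(r, c) {
      100 * (1 + 0.1 * r) * (1 - 0.05 * c) * exp(rnorm(length(r), 0, 0.05))
    })
  })
  n1 <- rowcol_normalize(n, exclude_corners = FALSE)
  n2 <- rowcol_normalize(n1, exclude_corners = FALSE)
  step1 <- mean(abs(n1$size_px - n$size_px))
  step2 <- mean(abs(n2$size_px - n1$size_px))
  expect_lt(step2, 0.05 * step1)
})

test_that("injected row/column effects are removed below 1e-6 residual R2", {
  # strain effects laid out balanced within every row and column (diagonal
  # stripes), multiplied by injected row and column trends
  withr::with_seed(21, {
    row_eff <- runif(16, 0.7, 1.4)
    col_eff <- rep(runif(6, 0.8, 1.3), each = 4)  # block trends across cols
    strain_eff <- c(1, 1.1, 1.25, 1.4)
  })
  d <- plate_table(384, function(r, c) {
    200 * strain_eff[(r + c) %% 4 + 1] * row_eff[r + 1] * col_eff[c + 1]
  })
  d$strain <- paste0("s", (d$row + d$col) %% 4 + 1)
  before_row <- variance_explained(d$size_px, d$row)
  expect_gt(before_row, 0.05)
  out <- rowcol_normalize(d, exclude_corners = FALSE)
  expect_lt(variance_explained(out$size_px, out$row), before_row * 1e-6)
  expect_lt(variance_explained(out$size_px, out$col),
            variance_explained(d$size_px, d$col) * 1e-6)
  # the strain signal survives untouched
  expect_gt(variance_explained(out$size_px, out$strain), 0.99)
})

test_that("layer normalization equalizes layer means and keeps the grand mean", {
  d <- plate_table(384, function(r, c) rep(100, length(r)))
  d$size_px <- d$size_px * ifelse(d$layer == 0, 2, 1)
  out <- layer_normalize(d, 384, exclude_corners = FALSE)
  layer_means <- as.vector(tapply(out$size_px, out$layer, mean))
  expect_equal(layer_means, rep(mean(out$size_px), 8), tolerance = 1e-9)
  expect_equal(mean(out$size_px), mean(d$size_px), tolerance = 1e-9)
})

test_that("masked rows and columns are diagnosed by name", {
  d <- plate_table(96, function(r, c) 100 + r)
  d$mask <- d$row == 3
  expect_error(rowcol_normalize(d), class = "colonyfit_empty_group")
})

test_that("additive normalization removes additive row effects", {
  d <- tibble::tibble(row = rep(0:3, each = 6), col = rep(0:5, 4))
  d$size_px <- 100 + 10 * d$row + 2 * d$col
  out <- rowcol_normalize(d, method = "additive", exclude_corners = FALSE)
  expect_lt(var(out$size_px), 1e-18)
})

test_that("variance explained matches the hand-computed ANOVA R2", {
  expect_equal(variance_explained(c(1, 2, 3, 4), c("A", "A", "B", "B")), 0.8)
  # identical within-group values, distinct means: all variance explained
  expect_equal(variance_explained(c(5, 5, 9, 9), c("A", "A", "B", "B")), 1)
  # random labels explain almost nothing
  withr::with_seed(13, {
    x <- rnorm(1000)
    lab <- sample(letters[1:4], 1000, replace = TRUE)
  })
  expect_lt(variance_explained(x, lab), 0.05)
  expect_error(variance_explained(c(1, 2), c("A", "A")), "2 groups")
  expect_error(variance_explained(c(1, 1, 1, 1), c("A", "A", "B", "B")),
               "zero")
})

test_that("variance_explained equals the aov sum-of-squares ratio", {
  withr::with_seed(31, {
    x <- rnorm(60, rep(c(0, 0.5, 1.2), each = 20))
    lab <- rep(c("a", "b", "c"), each = 20)
  })
  fit <- summary(aov(x ~ lab))[[1]]
  expect_equal(variance_explained(x, lab),
               fit$`Sum Sq`[[1]] / sum(fit$`Sum Sq`), tolerance = 1e-12)
})

test_that("an extreme outer-layer shift is flagged against the center", {
  withr::with_seed(5, {
    d <- plate_table(384, function(r, c) rnorm(length(r), 100, 2))
  })
  d$size_px[d$layer == 0] <- d$size_px[d$layer == 0] + 20  # +10 SD
  res <- layer_effect_test(d)
  expect_true(res$flagged[res$layer == 0])
  expect_true(all(res$testable))
})

test_that("layer tests hold their false-positive rate under the null", {
  flagged <- vapply(1:100, function(seed) {
    withr::with_seed(seed, {
      d <- plate_table(96, function(r, c) rnorm(length(r), 100, 5))
    })
    res <- layer_effect_test(d)
    c(sum(res$flagged), nrow(res))
  }, c(0, 0))
  rate <- sum(flagged[1, ]) / sum(flagged[2, ])
  expect_lt(rate, 0.075)  # <= ~1.5x the nominal 5% FDR
})

test_that("a constant plate cannot be layer-tested", {
  d <- plate_table(96, function(r, c) rep(7, length(r)))
  expect_error(layer_effect_test(d), "zero variance")
})
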