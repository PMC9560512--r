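# Seeded generators for the three assay input kinds, with known ground
# truth: pinned-plate colony sizes (edge effects + strain fitness), OD600
# growth curves, and flow-cytometry competition events.

#' Edge-effect multiplier profiles
#'
#' Edge effects enlarge perimeter colonies, grow stronger with incubation
#' time, and reach about 4 layers into the plate; agar trimming dramatically
#' reduces (but does not eliminate) them. Profiles are multiplicative on
#' cell number: layer `l` on day `d` gets
#' `1 + (strength - 1) * max(0, 1 - l/depth) * d/max(day)`.
#'
#' @param profile `"trimmed"` (layer-0 strength 1.15), `"intact"` (2.0) or
#'   `"flat"` (no effect), or a single numeric layer-0 strength.
#' @param depth Layers affected (default 4).
#' @return A function `(layer, day, max_day) -> multiplier`.
#' @export
edge_profile <- function(profile = c("trimmed", "intact", "flat"), depth = 4) {
  strength <- if (is.numeric(profile)) {
    profile[[1L]]
  } else {
    switch(match.arg(profile), trimmed = 1.15, intact = 2.0, flat = 1.0)
  }
  if (strength <= 0) abort("Edge multipliers must be > 0.")
  function(layer, day, max_day) {
    frac <- pmax(0, 1 - layer / depth) * (if (max_day > 0) day / max_day else 0)
    1 + (strength - 1) * frac
  }
}

#' Simulate a pinned-plate colony-size time course
#'
#' Generates a snake-randomized layout and, per colony and day, a cell count
#' `day0_cells * 2^(g(day) * (1 + s_strain)) * edge_multiplier(layer, day) *
#' lognormal(sigma)`, converted to a colony size in pixels by the inverse
#' calibration. Ancestor strains (s = 0 unless stated otherwise) define the
#' generation axis `g(day) = g_per_day * day`. Day-0 records are emitted at
#' the anchored day-0 size. Deterministic given `seed`.
#'
#' @param strain_s Named numeric vector: true selection coefficient per
#'   strain (per ancestor generation). Must include the `ancestors`.
#' @param ancestors Ancestor strain ids (default `c("anc1", "anc2")`).
#' @param format Plate format (default 384).
#' @param days Imaging days (default `0:4`).
#' @param g_per_day Ancestor generations accumulated per day (default 1.5,
#'   i.e. ~6 generations over the 4-day time course).
#' @param sigma Lognormal noise on cells, sdlog in natural-log units
#'   (default 0.05).
#' @param profile Edge-effect profile; see [edge_profile()]. Default
#'   `"trimmed"`.
#' @param model Calibration used for the inverse size mapping.
#' @param condition Condition label stamped on the records.
#' @param plate_id Plate id stamped on the records.
#' @param seed Integer seed.
#' @return Long colony table: `plate_id`, `condition`, `day`, `row`, `col`,
#'   `layer`, `is_corner`, `strain`, `replicate`, `size_px`, `status`; the
#'   true parameters are attached as attribute `"truth"`.
#' @export
#'
#' @examples
#' d <- simulate_plate(c(anc1 = 0, anc2 = 0, ev1 = 0.05), seed = 1)
simulate_plate <- function(strain_s,
                           ancestors = c("anc1", "anc2"),
                           format = 384,
                           days = 0:4,
                           g_per_day = 1.5,
                           sigma = 0.05,
                           profile = "trimmed",
                           model = default_calibration(),
                           condition = "CM",
                           plate_id = "plate_1",
                           seed = 1L) {
  if (is.null(names(strain_s)) || any(names(strain_s) == "")) {
    abort("`strain_s` must be a named vector of per-strain fitness values.")
  }
  missing_anc <- setdiff(ancestors, names(strain_s))
  if (length(missing_anc) > 0L) {
    abort(sprintf("Ancestor strain(s) %s missing from `strain_s`.",
                  paste(missing_anc, collapse = ", ")))
  }
  if (sigma < 0) abort("`sigma` must be >= 0.")
  mult <- edge_profile(profile)
  format <- as_plate_format(format)
  max_day <- max(days)

  withr::with_seed(seed, {
    layout <- make_snake_layout(names(strain_s), format, seed = seed)
    grid <- tidyr::expand_grid(layout, day = days)
    g <- g_per_day * grid$day
    s <- strain_s[grid$strain]
    cells <- model$day0_cells * 2^(g * (1 + s)) *
      mult(grid$layer, grid$day, max_day) *
      exp(rnorm(nrow(grid), 0, sigma))
    size <- unname(cells_to_size(cells, model))
    size[grid$day == 0] <- model$day0_size
    out <- tibble::tibble(
      plate_id = plate_id, condition = condition, day = grid$day,
      row = grid$row, col = grid$col, layer = grid$layer,
      is_corner = grid$is_corner, strain = grid$strain,
      replicate = grid$replicate, size_px = size, status = "OK"
    )
    attr(out, "truth") <- list(strain_s = strain_s, ancestors = ancestors,
                               g_per_day = g_per_day, sigma = sigma,
                               seed = seed)
    out
  })
}

#' Simulate a lag / exponential / saturation growth curve
#'
#' OD600 stays at `od0` until `lag`, then follows a logistic approach to the
#' carrying capacity `K` whose maximum log-slope equals `rate`; Gaussian
#' measurement noise is added on the OD scale. Samples on a 4-minute grid
#' over 24 h by default.
#'
#' @param lag Lag time in hours (>= 0).
#' @param rate Maximum specific growth rate, h^-1 (> 0).
#' @param K Carrying capacity in OD600 (> `od0`; `K = od0` gives a flat
#'   curve).
#' @param od0 Starting OD600 (default 0.1, a back-diluted inoculum the reader resolves well above its noise floor).
#' @param noise_sd Gaussian noise SD on OD (default 0.002).
#' @param dt Sampling interval in hours (default 4/60).
#' @param t_max Assay length in hours (default 24).
#' @param seed Integer seed.
#' @return Tibble with `time` (h) and `od`; truth in attribute `"truth"`.
#' @export
simulate_growth_curve <- function(lag, rate, K, od0 = 0.1,
                                  noise_sd = 0.002, dt = 4 / 60,
                                  t_max = 24, seed = 1L) {
  if (rate <= 0 || od0 <= 0 || K < od0 || lag < 0) {
    abort("Need rate > 0, od0 > 0, K >= od0 and lag >= 0.")
  }
  time <- seq(0, t_max, by = dt)
  if (K == od0) {
    od <- rep(od0, length(time))
  } else {
    # internal logistic rate chosen so the initial ln-slope equals `rate`
    r <- rate / (1 - od0 / K)
    od <- ifelse(
      time < lag, od0,
      K / (1 + (K / od0 - 1) * exp(-r * (time - lag)))
    )
  }
  withr::with_seed(seed, {
    od <- od + rnorm(length(od), 0, noise_sd)
  })
  out <- tibble::tibble(time = time, od = pmax(od, 1e-6))
  attr(out, "truth") <- list(lag = lag, rate = rate, K = K, od0 = od0,
                             noise_sd = noise_sd, seed = seed)
  out
}

mvn2 <- function(n, mu1, mu2, sd1, sd2, rho = 0) {
  z1 <- rnorm(n); z2 <- rnorm(n)
  cbind(mu1 + sd1 * z1,
        mu2 + sd2 * (rho * z1 + sqrt(1 - rho^2) * z2))
}

flow_events_for <- function(n, p_strain, f_dim, debris_frac, doublet_frac) {
  kind <- sample(c("cell", "debris", "doublet"), n, replace = TRUE,
                 prob = c(1 - debris_frac - doublet_frac, debris_frac,
                          doublet_frac))
  n_cell <- sum(kind == "cell"); n_deb <- sum(kind == "debris")
  n_dbl <- sum(kind == "doublet")

  # singlet cells: tight scatter cluster, width ~ 60
  sc <- mvn2(n_cell, 4.5, 5.0, 0.06, 0.06, rho = 0.5)
  cell <- tibble::tibble(
    ssc_a = 10^sc[, 1L], fsc_a = 10^sc[, 2L],
    fsc_h = 10^(sc[, 2L] - 0.11 + rnorm(n_cell, 0, 0.02)),
    width = rnorm(n_cell, 60, 4)
  )
  is_strain <- runif(n_cell) < p_strain
  dim_ref <- !is_strain & (runif(n_cell) < f_dim)
  log_yfp <- ifelse(is_strain | dim_ref, rnorm(n_cell, 2, 0.15),
                    rnorm(n_cell, 4, 0.15))
  cell$yfp_a <- 10^log_yfp
  cell$truth_strain <- is_strain

  # debris: low, diffuse scatter
  scd <- mvn2(n_deb, 3.0, 3.5, 0.3, 0.3)
  debris <- tibble::tibble(
    ssc_a = 10^scd[, 1L], fsc_a = 10^scd[, 2L],
    fsc_h = 10^(scd[, 2L] - 0.11 + rnorm(n_deb, 0, 0.1)),
    width = rnorm(n_deb, 55, 6),
    yfp_a = 10^rnorm(n_deb, 2, 0.5),
    truth_strain = NA
  )

  # doublets: cell-like scatter area but double width and lower height/area
  scb <- mvn2(n_dbl, 4.7, 5.2, 0.08, 0.08, rho = 0.5)
  doublet <- tibble::tibble(
    ssc_a = 10^scb[, 1L], fsc_a = 10^scb[, 2L],
    fsc_h = 10^(scb[, 2L] - 0.25 + rnorm(n_dbl, 0, 0.05)),
    width = rnorm(n_dbl, 120, 8),
    yfp_a = 10^rnorm(n_dbl, 3, 0.8),
    truth_strain = NA
  )
  dplyr::bind_rows(cell, debris, doublet)
}

#' Simulate a flow-cytometry competition experiment
#'
#' Per day and replicate, draws ungated events from three clusters (singlet
#' cells, debris, doublets) with the strain:reference proportion following a
#' true selection coefficient on a ~`gen_per_day`-generations-per-day axis:
#' `ratio(day) = ratio0 * exp(s * g(day))`, with lognormal day-to-day
#' jitter. A fraction `f_true` of reference cells is dim (below the YFP
#' threshold), which the analysis must correct for. A reference-only control
#' is generated per day. Acquisition volumes are set so measured event
#' concentrations track the culture's true concentration through the daily
#' 1/1000 dilution cycles.
#'
#' @param s True per-generation selection coefficient of the strain versus
#'   the reference (default 0.05).
#' @param replicates Number of competition replicates (default 7).
#' @param days Sampling days (default `0:3`: the initial mix plus 3 growth
#'   cycles).
#' @param n_events Ungated events acquired per sample (default 20000).
#' @param ratio0 Initial strain/reference ratio (default 1).
#' @param f_true True dim fraction of the reference (default 0.10, inside
#'   the 1-19% band seen in real controls).
#' @param gen_per_day Generations regrown per cycle (default 10).
#' @param dilution Daily dilution (default 1/1000).
#' @param day_noise_sd Lognormal sd of day-to-day ratio jitter (default
#'   0.05).
#' @param debris_frac,doublet_frac Fractions of non-cell events (default
#'   0.05 each).
#' @param conc0 Day-0 culture concentration, events/uL (default 1000).
#' @param seed Integer seed.
#' @return A list with `events`, `samples` (see
#'   [estimate_competitive_fitness()]) and `truth`.
#' @export
simulate_flow_experiment <- function(s = 0.05, replicates = 7, days = 0:3,
                                     n_events = 20000, ratio0 = 1,
                                     f_true = 0.10, gen_per_day = 10,
                                     dilution = 1 / 1000,
                                     day_noise_sd = 0.05,
                                     debris_frac = 0.05, doublet_frac = 0.05,
                                     conc0 = 1000, seed = 1L) {
  if (f_true < 0 || f_true >= 1) abort("`f_true` must be in [0, 1).")
  if (ratio0 < 0) abort("`ratio0` must be >= 0.")
  withr::with_seed(seed, {
    day_index <- seq_along(days) - 1L
    conc <- conc0 * (2^gen_per_day * dilution)^day_index
    vol <- n_events / conc

    grids <- tidyr::crossing(day = days, replicate = seq_len(replicates))
    events <- purrr::pmap_dfr(grids, function(day, replicate) {
      g_true <- gen_per_day * which(days == day)[[1L]] - gen_per_day
      ratio <- ratio0 * exp(s * g_true) * exp(rnorm(1, 0, day_noise_sd))
      e <- flow_events_for(n_events, p_strain = ratio / (1 + ratio),
                           f_dim = f_true, debris_frac, doublet_frac)
      e$day <- day; e$replicate <- replicate; e$sample_type <- "competition"
      e
    })
    controls <- purrr::map_dfr(days, function(day) {
      e <- flow_events_for(n_events, p_strain = 0, f_dim = f_true,
                           debris_frac, doublet_frac)
      e$day <- day; e$replicate <- 0L; e$sample_type <- "reference_only"
      e
    })
    samples <- tidyr::crossing(day = days,
                               replicate = c(0L, seq_len(replicates)))
    samples$sample_type <- ifelse(samples$replicate == 0L, "reference_only",
                                  "competition")
    samples$volume_ul <- vol[match(samples$day, days)]

    list(
      events = dplyr::bind_rows(events, controls),
      samples = samples,
      truth = list(s = s, f_true = f_true, gen_per_day = gen_per_day,
                   ratio0 = ratio0, seed = seed)
    )
  })
}
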