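# Shared builders for in-code fixtures.

# A full plate of sizes from a function of (row, col); long-format tibble.
plate_table <- function(format, f, day = 4, plate_id = "p1",
                        condition = "CM") {
  fmt <- plate_format(format)
  d <- tidyr::expand_grid(row = 0:(fmt$n_rows - 1), col = 0:(fmt$n_cols - 1))
  tibble::tibble(
    plate_id = plate_id, condition = condition, day = day,
    row = d$row, col = d$col,
    layer = layer_index(d$row, d$col, fmt),
    is_corner = is_plate_corner(d$row, d$col, fmt),
    strain = "s1", replicate = seq_len(nrow(d)),
    size_px = f(d$row, d$col), status = "OK"
  )
}

# Exact cell trajectory: cells = n0 * 2^(g_per_day * day * (1 + s)).
exact_trajectory <- function(s, days = 0:4, g_per_day = 1.5, n0 = 579506,
                             strain = "ev", row = 0, col = 0) {
  tibble::tibble(
    plate_id = "p1", condition = "CM", row = row, col = col,
    strain = strain, replicate = 1L, day = days,
    cells = n0 * 2^(g_per_day * days * (1 + s))
  )
}

# Several exact trajectories stacked, one per (strain, s) pair.
exact_trajectories <- function(strain_s, ...) {
  purrr::imap_dfr(strain_s, function(s, nm) {
    i <- match(nm, names(strain_s))
    exact_trajectory(s, strain = nm, row = i, col = i, ...)
  })
}
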