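# Plate geometry: formats, concentric layers, corners, snake-randomized layouts.

#' Supported pinning formats
#'
#' A pinned plate has one of three standard densities: 96 (8 x 12),
#' 384 (16 x 24) or 1536 (32 x 48) positions. Coordinates are 0-based and
#' row-major throughout the package; A1-style well labels appear only at the
#' I/O boundary (see [rowcol_to_well()]).
#'
#' @param format Plate density as a number or string: 96, 384 or 1536.
#'
#' @return A `plate_format` object: a list with `name`, `n_rows`, `n_cols`.
#' @export
#'
#' @examples
#' plate_format(384)
plate_format <- function(format) {
  name <- as.character(format)
  dims <- switch(name,
    "96"   = c(8L, 12L),
    "384"  = c(16L, 24L),
    "1536" = c(32L, 48L),
    abort(sprintf("Unknown plate format '%s' (supported: 96, 384, 1536).", name))
  )
  structure(
    list(name = name, n_rows = dims[[1L]], n_cols = dims[[2L]]),
    class = "plate_format"
  )
}

#' @export
print.plate_format <- function(x, ...) {
  cat(sprintf("<plate_format %s: %d rows x %d cols>\n", x$name, x$n_rows, x$n_cols))
  invisible(x)
}

as_plate_format <- function(format) {
  if (inherits(format, "plate_format")) format else plate_format(format)
}

check_position <- function(row, col, format) {
  bad <- row < 0L | row >= format$n_rows | col < 0L | col >= format$n_cols |
    !is.finite(row) | !is.finite(col)
  if (any(bad)) {
    i <- which(bad)[[1L]]
    abort(sprintf(
      "Position (%s, %s) is outside the %s-format plate (0..%d rows, 0..%d cols).",
      row[[i]], col[[i]], format$name, format$n_rows - 1L, format$n_cols - 1L
    ), class = "colonyfit_position_out_of_range")
  }
  invisible(NULL)
}

#' Concentric layer of a plate position
#'
#' Positions on a pinned plate are grouped into concentric rectangular rings
#' ("layers") by their minimum distance to the plate boundary: layer 0 is the
#' outermost ring, and the innermost layer of an `n_rows x n_cols` plate is
#' `n_rows/2 - 1` (rows are always the shorter axis). Layers are the unit at
#' which edge effects -- the systematic enlargement of perimeter colonies --
#' are quantified and corrected.
#'
#' @param row,col 0-based position indices (vectorized).
#' @param format A [plate_format()] or something coercible to one.
#'
#' @return Integer vector of 0-based layer indices.
#' @export
#'
#' @examples
#' layer_index(0, 0, 384)   # outermost ring
#' layer_index(7, 11, 384)  # innermost ring of a 16 x 24 plate
layer_index <- function(row, col, format) {
  format <- as_plate_format(format)
  row <- as.integer(row); col <- as.integer(col)
  check_position(row, col, format)
  pmin(row, col, format$n_rows - 1L - row, format$n_cols - 1L - col)
}

#' Is a position one of the four plate corners?
#'
#' Corner colonies show pronounced variance (especially on agar-trimmed
#' plates) and are excluded from downstream statistics by default.
#'
#' @inheritParams layer_index
#' @return Logical vector.
#' @export
is_plate_corner <- function(row, col, format) {
  format <- as_plate_format(format)
  row <- as.integer(row); col <- as.integer(col)
  check_position(row, col, format)
  (row == 0L | row == format$n_rows - 1L) & (col == 0L | col == format$n_cols - 1L)
}

# Ring-by-ring enumeration of all positions, outermost first, clockwise from
# the ring's top-left position. Returns a tibble ordered along the snake path.
snake_path <- function(format) {
  format <- as_plate_format(format)
  nr <- format$n_rows; nc <- format$n_cols
  rings <- lapply(seq_len(nr %/% 2L) - 1L, function(l) {
    r0 <- l; r1 <- nr - 1L - l; c0 <- l; c1 <- nc - 1L - l
    if (r0 == r1) {
      rows <- rep(r0, c1 - c0 + 1L); cols <- c0:c1
    } else {
      rows <- c(rep(r0, c1 - c0 + 1L), (r0 + 1L):r1,
                rep(r1, c1 - c0), if (r1 - 1L >= r0 + 1L) (r1 - 1L):(r0 + 1L))
      cols <- c(c0:c1, rep(c1, r1 - r0), (c1 - 1L):c0,
                if (r1 - 1L >= r0 + 1L) rep(c0, r1 - r0 - 1L))
    }
    tibble::tibble(row = as.integer(rows), col = as.integer(cols), layer = l)
  })
  dplyr::bind_rows(rings)
}

#' Snake-randomized strain layout
#'
#' Assigns strain replicates to plate positions by walking the plate's
#' concentric rings from the outermost ring inward (clockwise from the
#' top-left of each ring) and laying down a seeded random strain order,
#' cycling until the plate is full. Each strain therefore gets equal
#' representation overall (counts differ by at most 1) and appears in every
#' sufficiently large layer, which randomizes both neighbours and
#' edge-proximity across replicates.
#'
#' @param strains Character vector of strain ids (at least one).
#' @param format Plate format; see [plate_format()].
#' @param seed Integer seed; the same seed reproduces the same layout.
#' @param trimmed Logical metadata flag: was excess agar trimmed from the
#'   plate edge after pinning? Carried through to outputs, not used here.
#'
#' @return A tibble with one row per position, ordered along the snake path:
#'   columns `row`, `col`, `layer`, `is_corner`, `well`, `strain`,
#'   `replicate`, plus attributes `format`, `seed`, `trimmed`.
#' @export
#'
#' @examples
#' layout <- make_snake_layout(paste0("s", 1:12), 384, seed = 1)
#' dplyr::count(layout, strain)  # 32 replicates each
make_snake_layout <- function(strains, format, seed, trimmed = TRUE) {
  format <- as_plate_format(format)
  strains <- as.character(strains)
  if (length(strains) < 1L) abort("`strains` must contain at least one id.")
  if (anyDuplicated(strains)) abort("`strains` must be unique ids.")
  n_pos <- format$n_rows * format$n_cols
  if (length(strains) > n_pos) {
    abort(sprintf("%d strains exceed the %d positions of a %s plate.",
                  length(strains), n_pos, format$name))
  }
  path <- snake_path(format)
  order <- withr::with_seed(seed, sample(strains))
  assignment <- rep_len(order, n_pos)
  layout <- path
  layout$is_corner <- is_plate_corner(layout$row, layout$col, format)
  layout$well <- rowcol_to_well(layout$row, layout$col)
  layout$strain <- assignment
  layout$replicate <- stats::ave(seq_len(n_pos), assignment, FUN = seq_along)
  attr(layout, "format") <- format
  attr(layout, "seed") <- seed
  attr(layout, "trimmed") <- trimmed
  layout
}

#' Convert between 0-based coordinates and A1-style well labels
#'
#' Rows map to letters A, B, ... Z, AA, AB, ... (1536-format plates have 32
#' rows, A through AF); columns map to 1-based numbers.
#'
#' @param row,col 0-based indices.
#' @return `rowcol_to_well()`: character labels. `well_to_rowcol()`: a tibble
#'   with 0-based `row` and `col`.
#' @export
#'
#' @examples
#' rowcol_to_well(0, 0)       # "A1"
#' well_to_rowcol("AF48")     # row 31, col 47
rowcol_to_well <- function(row, col) {
  row <- as.integer(row); col <- as.integer(col)
  if (any(row < 0L | col < 0L)) abort("Coordinates must be >= 0.")
  letter <- ifelse(row < 26L, LETTERS[row + 1L],
                   paste0(LETTERS[row %/% 26L], LETTERS[row %% 26L + 1L]))
  paste0(letter, col + 1L)
}

#' @param well Character well labels like "A1" or "AF48".
#' @rdname rowcol_to_well
#' @export
well_to_rowcol <- function(well) {
  well <- toupper(trimws(as.character(well)))
  m <- regmatches(well, regexec("^([A-Z]{1,2})([0-9]+)$", well))
  bad <- vapply(m, length, 0L) != 3L
  if (any(bad)) {
    abort(sprintf("Malformed well label: '%s'", well[which(bad)[[1L]]]))
  }
  letters_part <- vapply(m, `[[`, "", 2L)
  num_part <- as.integer(vapply(m, `[[`, "", 3L))
  row <- vapply(letters_part, function(s) {
    chars <- match(strsplit(s, "")[[1L]], LETTERS)
    if (length(chars) == 1L) chars[[1L]] - 1L else (chars[[1L]] * 26L + chars[[2L]]) - 1L
  }, 0L, USE.NAMES = FALSE)
  if (any(num_part < 1L)) abort("Well column numbers are 1-based.")
  tibble::tibble(row = row, col = num_part - 1L)
}

#' Plot a plate layout
#'
#' @param layout A layout tibble from [make_snake_layout()].
#' @return A ggplot: one tile per position, coloured by strain, corners marked.
#' @export
plot_layout <- function(layout) {
  require_columns(layout, c("row", "col", "strain"), "layout")
  ggplot2::ggplot(layout, ggplot2::aes(x = .data$col, y = .data$row, fill = .data$strain)) +
    ggplot2::geom_tile(colour = "grey30", linewidth = 0.2) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "column (0-based)", y = "row (0-based)", fill = "strain") +
    ggplot2::theme_minimal()
}
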