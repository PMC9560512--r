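# Spatial (edge-effect) normalization of plate colony sizes and diagnostics.

norm_group_keys <- function(data) {
  intersect(c("plate_id", "condition", "day"), names(data))
}

# Positions excluded from all statistics: plate corners, discarded
# trajectories, and anything the caller masked explicitly.
norm_mask <- function(data, exclude_corners) {
  masked <- rep(FALSE, nrow(data))
  if ("status" %in% names(data)) masked <- masked | data$status == "DISCARD"
  if ("mask" %in% names(data)) masked <- masked | as.logical(data$mask)
  if (exclude_corners && "is_corner" %in% names(data)) {
    masked <- masked | as.logical(data$is_corner)
  }
  masked | is.na(data$size_px)
}

group_stat <- function(stat) {
  switch(stat,
    mean = function(x) mean(x),
    median = function(x) median(x),
    abort("`stat` must be 'mean' or 'median'.")
  )
}

#' Row/column normalization of colony sizes
#'
#' Corrects plate-wide spatial trends by scaling each colony to its row and
#' column summary: first every value is multiplied by (grand stat / its row
#' stat), then -- with statistics recomputed -- by (grand stat / its column
#' stat). With `stat = "mean"`, the output column means all equal the output
#' grand mean exactly, and the grand mean is preserved. An additive variant
#' (value + grand - row stat, then + grand - column stat) is available via
#' `method = "additive"`.
#'
#' Masked positions (plate corners, `status == "DISCARD"`, a logical `mask`
#' column, or `NA` sizes) are excluded from every statistic but still
#' rescaled, so they stay on the plate for bookkeeping. When `plate_id`,
#' `condition` or `day` columns are present, each plate-day is normalized
#' independently.
#'
#' @param data Long-format colony table with `row`, `col`, `size_px` columns.
#' @param stat Row/column summary: `"mean"` (default) or `"median"` (even
#'   counts use the midpoint sample median).
#' @param method `"multiplicative"` (default) or `"additive"`.
#' @param exclude_corners Exclude the four plate corners from statistics
#'   (requires an `is_corner` column to act on). Default `TRUE`.
#'
#' @return The tibble with `size_px` replaced by normalized values; the
#'   method used is recorded in the `"normalization"` attribute.
#' @export
rowcol_normalize <- function(data, stat = c("mean", "median"),
                             method = c("multiplicative", "additive"),
                             exclude_corners = TRUE) {
  stat <- match.arg(stat)
  method <- match.arg(method)
  require_columns(data, c("row", "col", "size_px"), "colony data")
  data <- tibble::as_tibble(data)
  keys <- norm_group_keys(data)
  fn <- group_stat(stat)

  out <- data |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::group_modify(function(d, key) {
      masked <- norm_mask(d, exclude_corners)
      d$size_px <- normalize_pass(d$size_px, d$row, masked, fn, method,
                                  axis = "row", key = key)
      d$size_px <- normalize_pass(d$size_px, d$col, masked, fn, method,
                                  axis = "column", key = key)
      d
    }) |>
    dplyr::ungroup()
  attr(out, "normalization") <- paste0("rowcol_", stat, "_", method)
  out
}

normalize_pass <- function(values, index, masked, fn, method, axis, key) {
  ok <- !masked
  if (!any(ok)) abort("All positions are masked; nothing to normalize.")
  grand <- fn(values[ok])
  stats <- tapply(values[ok], index[ok], fn)
  levels_all <- unique(index)
  missing <- setdiff(as.character(levels_all), names(stats))
  if (length(missing) > 0L) {
    abort(sprintf("%s %s has no unmasked entries; cannot normalize.",
                  axis, missing[[1L]]), class = "colonyfit_empty_group")
  }
  if (method == "multiplicative" && any(stats <= 0)) {
    bad <- names(stats)[stats <= 0][[1L]]
    abort(sprintf("%s %s has a nonpositive %s; cannot scale.", axis, bad,
                  "summary"), class = "colonyfit_zero_stat")
  }
  s <- unname(stats[as.character(index)])
  out <- if (method == "multiplicative") values * grand / s else
    values + grand - s
  as.vector(out)
}

#' Layer normalization of colony sizes
#'
#' Scales each colony by (grand mean / its concentric layer's mean),
#' flattening the average edge-effect profile. Grouping and masking follow
#' [rowcol_normalize()].
#'
#' @inheritParams rowcol_normalize
#' @param format Plate format, needed to derive layers when the table has no
#'   `layer` column.
#' @return The tibble with `size_px` replaced by layer-normalized values.
#' @export
layer_normalize <- function(data, format = NULL, exclude_corners = TRUE) {
  require_columns(data, c("row", "col", "size_px"), "colony data")
  data <- tibble::as_tibble(data)
  if (!"layer" %in% names(data)) {
    if (is.null(format)) abort("Provide `format` or a `layer` column.")
    data$layer <- layer_index(data$row, data$col, format)
  }
  keys <- norm_group_keys(data)
  out <- data |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::group_modify(function(d, key) {
      masked <- norm_mask(d, exclude_corners)
      d$size_px <- normalize_pass(d$size_px, d$layer, masked, mean,
                                  "multiplicative", axis = "layer", key = key)
      d
    }) |>
    dplyr::ungroup()
  attr(out, "normalization") <- "layer_mean"
  out
}

#' Fraction of variance explained by a grouping
#'
#' One-way ANOVA R-squared: between-group sum of squares over total sum of
#' squares. Used to quantify how much colony-size variance is attributable to
#' strain identity, plate layer, row or column, before and after
#' normalization.
#'
#' @param values Numeric vector.
#' @param labels Grouping labels, same length.
#' @return A fraction in `[0, 1]`.
#' @export
#'
#' @examples
#' variance_explained(c(1, 2, 3, 4), c("A", "A", "B", "B"))  # 0.8
variance_explained <- function(values, labels) {
  keep <- is.finite(values) & !is.na(labels)
  values <- values[keep]; labels <- as.character(labels[keep])
  if (length(unique(labels)) < 2L) {
    abort("Need at least 2 groups to partition variance.")
  }
  grand <- mean(values)
  sst <- sum((values - grand)^2)
  if (sst <= 0) abort("Total variance is zero; R^2 undefined.")
  group_means <- tapply(values, labels, mean)
  group_n <- tapply(values, labels, length)
  ssb <- sum(group_n * (group_means - grand)^2)
  ssb / sst
}

#' Test each plate layer against the plate center
#'
#' Edge effects show up as layers whose colony sizes differ from the plate's
#' innermost layer. Each outer layer is compared to the center layer with a
#' two-sample t-test and the p-values are adjusted across layers by
#' Benjamini-Hochberg FDR; layers with q < `alpha` are flagged.
#'
#' @inheritParams layer_normalize
#' @param alpha FDR threshold for flagging a layer (default 0.05).
#' @return A tibble with one row per non-center layer: `layer`, `n`,
#'   `center_n`, `mean_ratio` (layer mean / center mean), `p_value`,
#'   `q_value`, `flagged`, `testable`. Untestable layers (fewer than 2
#'   values) are reported, not dropped.
#' @export
layer_effect_test <- function(data, format = NULL, exclude_corners = TRUE,
                              alpha = 0.05) {
  require_columns(data, c("row", "col", "size_px"), "colony data")
  data <- tibble::as_tibble(data)
  if (!"layer" %in% names(data)) {
    if (is.null(format)) abort("Provide `format` or a `layer` column.")
    data$layer <- layer_index(data$row, data$col, format)
  }
  masked <- norm_mask(data, exclude_corners)
  d <- data[!masked, c("layer", "size_px")]
  if (var(d$size_px) == 0) {
    abort("Colony sizes have zero variance; layer test undefined.")
  }
  center <- max(d$layer)
  center_vals <- d$size_px[d$layer == center]
  if (length(center_vals) < 2L) {
    abort("Center layer has fewer than 2 unmasked values.")
  }
  layers <- sort(setdiff(unique(d$layer), center))
  res <- purrr::map_dfr(layers, function(l) {
    vals <- d$size_px[d$layer == l]
    testable <- length(vals) >= 2L &&
      (var(vals) > 0 || var(center_vals) > 0)
    p <- if (testable) t.test(vals, center_vals)$p.value else NA_real_
    tibble::tibble(
      layer = l, n = length(vals), center_n = length(center_vals),
      mean_ratio = mean(vals) / mean(center_vals),
      p_value = p, testable = testable
    )
  })
  res$q_value <- NA_real_
  res$q_value[res$testable] <- bh_fdr(res$p_value[res$testable])
  res$flagged <- !is.na(res$q_value) & res$q_value < alpha
  res[, c("layer", "n", "center_n", "mean_ratio", "p_value", "q_value",
          "flagged", "testable")]
}

#' Heatmap of a plate-day
#'
#' @param data Long colony table for one plate-day (`row`, `col`, `size_px`).
#' @return A ggplot tile map of colony sizes.
#' @export
plot_plate <- function(data) {
  require_columns(data, c("row", "col", "size_px"), "colony data")
  ggplot2::ggplot(data, ggplot2::aes(x = .data$col, y = .data$row,
                                     fill = .data$size_px)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = "size (px)") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "column", y = "row") +
    ggplot2::theme_minimal()
}
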