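#' Form factor (solidity) of a cell region
#'
#' The form factor is the cell area divided by the convex-hull area. Compact
#' amoeboid microglia score close to 1; ramified microglia with long thin
#' processes score low, because the processes enlarge the hull far more than
#' the cell area.
#'
#' Under the pixel-corner hull convention the value is exactly 1 for filled
#' axis-aligned rectangles and biased low by roughly `0.7/r` on a rasterized
#' disk of radius `r` pixels (about 3.5% at r = 20, under 1% at r = 80).
#'
#' @param region A [region_mask()].
#' @return Dimensionless ratio in (0, 1].
#' @examples
#' sq <- region_mask(as.matrix(expand.grid(1:10, 1:10)), 1)
#' form_factor(sq)  # exactly 1
#' @export
form_factor <- function(region) {
  stopifnot(inherits(region, "RegionMask"))
  region$area_um2 / region$convex_area_um2
}

#' Score every cell in a microglia channel
#'
#' Segments the image at the configured threshold and computes the form
#' factor of each cell. Cells touching the image border are excluded by
#' default: their hulls are truncated by the field of view, which biases the
#' form factor.
#'
#' @param image Microglia-channel [image_plane()] (typically Iba-1).
#' @param group Condition label attached to every record.
#' @param low,high Inclusive segmentation thresholds (default 30--255).
#' @param min_area_px Minimum cell size in pixels (default 30).
#' @param exclude_border Drop cells touching the image border (default TRUE).
#' @return Data frame of `MorphRecord` rows: `cell_id`, `group`, `area_um2`,
#'   `convex_area_um2`, `form_factor`.
#' @export
score_scene <- function(image, group, low = 30, high = 255,
                        min_area_px = 30, exclude_border = TRUE) {
  regions <- segment(image, low = low, high = high, min_area_px = min_area_px)
  if (exclude_border) {
    dims <- dim(image$pixels)
    regions <- Filter(function(r) !touches_border(r, dims), regions)
  }
  if (length(regions) == 0)
    return(data.frame(cell_id = integer(), group = character(),
                      area_um2 = numeric(), convex_area_um2 = numeric(),
                      form_factor = numeric()))
  do.call(rbind, lapply(regions, function(r) data.frame(
    cell_id = r$label, group = group, area_um2 = r$area_um2,
    convex_area_um2 = r$convex_area_um2, form_factor = form_factor(r),
    row.names = NULL)))
}

#' Per-group summary and pairwise comparison of morphometry records
#'
#' Summarises a numeric readout (by default the form factor) per group
#' (mean, SD, SEM, n) and, when at least two groups each contribute two or
#' more cells, runs a one-way ANOVA followed by Tukey's honest significant
#' difference test for all pairwise contrasts at alpha = 0.05.
#'
#' @param records Data frame with a `group` column and the `value_col`
#'   column (default `"form_factor"`).
#' @param value_col Name of the numeric column to summarise.
#' @return List with `summary` (per-group data frame), `comparisons`
#'   (pairwise data frame: `contrast`, `diff`, `lwr`, `upr`, `p_adj`,
#'   `significant`; empty for a single group), and `degenerate` (TRUE when
#'   the pooled variance is zero, in which case no test is run).
#' @export
summarize_groups <- function(records, value_col = "form_factor") {
  stopifnot(is.data.frame(records), value_col %in% names(records),
            "group" %in% names(records))
  v <- records[[value_col]]
  g <- factor(records$group)
  summ <- do.call(rbind, lapply(levels(g), function(lev) {
    x <- v[g == lev]
    data.frame(group = lev, n = length(x), mean = mean(x),
               sd = stats::sd(x), sem = stats::sd(x) / sqrt(length(x)))
  }))
  empty_cmp <- data.frame(contrast = character(), diff = numeric(),
                          lwr = numeric(), upr = numeric(),
                          p_adj = numeric(), significant = logical())
  if (nlevels(g) < 2 || any(table(g) < 2))
    return(list(summary = summ, comparisons = empty_cmp, degenerate = FALSE))
  if (stats::var(v) == 0)
    return(list(summary = summ, comparisons = empty_cmp, degenerate = TRUE))
  fit <- stats::aov(v ~ g)
  tk <- stats::TukeyHSD(fit)$g
  cmp <- data.frame(contrast = rownames(tk), diff = tk[, "diff"],
                    lwr = tk[, "lwr"], upr = tk[, "upr"],
                    p_adj = tk[, "p adj"],
                    significant = tk[, "p adj"] < 0.05, row.names = NULL)
  list(summary = summ, comparisons = cmp, degenerate = FALSE)
}
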