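#' Detect amyloid plaques in a plaque channel
#'
#' Segments the plaque channel (Thioflavin S or Amylo Glo) at the inclusive
#' intensity interval `[low, 255]` and measures each plaque's area, Feret
#' diameter and centroid. Each plaque is assigned a circular neighborhood of
#' diameter 8x its Feret diameter (radius `4 * feret_um`) within which
#' plaque-associated glial activation is scored.
#'
#' @param plaque_channel An [image_plane()] of the plaque stain.
#' @param low Lower inclusive intensity threshold (default 20).
#' @param min_area_px Minimum plaque size in pixels (default 20).
#' @return Data frame of `PlaqueRecord` rows: `plaque_id`, `area_um2`,
#'   `feret_um`, `centroid_row`, `centroid_col` (pixel-center coordinates),
#'   `neighborhood_radius_um` (= 4 x Feret), `excluded` (all FALSE here;
#'   see [exclude_overlaps()]).
#' @export
detect_plaques <- function(plaque_channel, low = 20, min_area_px = 20) {
  regions <- segment(plaque_channel, low = low, high = 255,
                     min_area_px = min_area_px)
  tab <- regions_table(regions)
  data.frame(plaque_id = tab$label, area_um2 = tab$area_um2,
             feret_um = tab$feret_um, centroid_row = tab$centroid_row,
             centroid_col = tab$centroid_col,
             neighborhood_radius_um = 4 * tab$feret_um,
             excluded = logical(nrow(tab)))
}

#' Flag plaques with overlapping neighborhoods
#'
#' Any pair of plaques whose neighborhood disks intersect (centroid distance
#' at most the sum of the two neighborhood radii) has *both* members flagged
#' `excluded`. The operation is symmetric, idempotent and independent of the
#' record order. Flagged plaques carry no halo intensity downstream.
#'
#' With `mode = "mask"` the looser criterion of overlapping plaque masks is
#' approximated by testing whether the centroid distance is below the sum of
#' the plaques' Feret radii (`feret_um / 2`).
#'
#' @param plaques Data frame from [detect_plaques()], all from one scene.
#' @param pixel_size_um Pixel calibration used to convert centroid pixel
#'   coordinates to micrometres (default 1).
#' @param mode `"neighborhood"` (default) or `"mask"`.
#' @return The input data frame with the `excluded` flag set.
#' @export
exclude_overlaps <- function(plaques, pixel_size_um = 1,
                             mode = c("neighborhood", "mask")) {
  mode <- match.arg(mode)
  n <- nrow(plaques)
  if (n < 2) return(plaques)
  rad <- switch(mode,
                neighborhood = plaques$neighborhood_radius_um,
                mask = plaques$feret_um / 2)
  cy <- plaques$centroid_row * pixel_size_um
  cx <- plaques$centroid_col * pixel_size_um
  d <- as.matrix(stats::dist(cbind(cy, cx)))
  lim <- outer(rad, rad, `+`)
  hit <- d <= lim
  diag(hit) <- FALSE
  plaques$excluded <- plaques$excluded | apply(hit, 1, any)
  plaques
}

# logical mask of pixels whose centers lie within `radius_um` of the
# centroid (pixel-center coordinates, inclusive boundary)
disk_mask <- function(dim_px, center_row, center_col, radius_um,
                      pixel_size_um) {
  ys <- (seq_len(dim_px[1]) - 0.5 - center_row) * pixel_size_um
  xs <- (seq_len(dim_px[2]) - 0.5 - center_col) * pixel_size_um
  outer(ys^2, xs^2, `+`) <= radius_um^2
}

#' Default background region for halo quantification
#'
#' The non-plaque-associated reference region: the complement of the union
#' of all plaque neighborhood disks, eroded by `erode_px` pixels (each disk
#' radius is enlarged by `erode_px` before taking the complement).
#'
#' @param image Glial-channel [image_plane()] (defines geometry).
#' @param plaques Data frame from [detect_plaques()].
#' @param erode_px Erosion margin in pixels (default 5).
#' @return Logical matrix, TRUE on background pixels.
#' @export
background_mask <- function(image, plaques, erode_px = 5) {
  dims <- dim(image$pixels)
  bg <- matrix(TRUE, dims[1], dims[2])
  for (i in seq_len(nrow(plaques))) {
    bg <- bg & !disk_mask(dims, plaques$centroid_row[i],
                          plaques$centroid_col[i],
                          plaques$neighborhood_radius_um[i] +
                            erode_px * image$pixel_size_um,
                          image$pixel_size_um)
  }
  bg
}

#' Background-corrected glial halo intensity around one plaque
#'
#' Integrates the glial signal inside the plaque's neighborhood disk:
#' pixels with intensity in the inclusive interval `[low, 255]` contribute
#' `max(value - background_mean, 0)`, where `background_mean` is the mean
#' intensity (unthresholded) of the supplied background region.
#'
#' @param glial_channel Glial-channel [image_plane()] (GFAP or Iba-1).
#' @param plaque One-row data frame (or list) with `centroid_row`,
#'   `centroid_col`, `neighborhood_radius_um` and `excluded`.
#' @param background Logical matrix (e.g. from [background_mask()]) or a
#'   [region_mask()] defining the reference region; must be nonempty.
#' @param low Lower inclusive intensity threshold for contributing pixels
#'   (default 30).
#' @return Integrated background-corrected intensity (arbitrary units,
#'   nonnegative).
#' @export
halo_intensity <- function(glial_channel, plaque, background, low = 30) {
  if (isTRUE(plaque$excluded))
    stop("plaque ", plaque$plaque_id, " is excluded (overlapping neighborhood)")
  if (inherits(background, "RegionMask")) {
    m <- matrix(FALSE, nrow(glial_channel$pixels), ncol(glial_channel$pixels))
    m[background$coords] <- TRUE
    background <- m
  }
  if (!any(background)) stop("background region is empty")
  bg_mean <- mean(glial_channel$pixels[background])
  disk <- disk_mask(dim(glial_channel$pixels), plaque$centroid_row,
                    plaque$centroid_col, plaque$neighborhood_radius_um,
                    glial_channel$pixel_size_um)
  v <- glial_channel$pixels[disk]
  v <- v[v >= low & v <= 255]
  sum(pmax(v - bg_mean, 0))
}

#' Measure halo intensities for all usable plaques in a scene
#'
#' Convenience wrapper: detects plaques, flags overlapping neighborhoods,
#' builds the default background region and integrates the glial halo of
#' every non-excluded plaque.
#'
#' @param plaque_channel,glial_channel Co-registered [image_plane()]s.
#' @param plaque_low Plaque segmentation threshold (default 20).
#' @param glial_low Glial intensity threshold (default 30).
#' @param min_area_px Minimum plaque size in pixels (default 20).
#' @return Data frame: plaque records with a `halo_intensity` column (NA for
#'   excluded plaques).
#' @export
measure_halos <- function(plaque_channel, glial_channel, plaque_low = 20,
                          glial_low = 30, min_area_px = 20) {
  if (!identical(dim(plaque_channel$pixels), dim(glial_channel$pixels)))
    stop("plaque and glial channels have mismatched dimensions")
  pl <- detect_plaques(plaque_channel, low = plaque_low,
                       min_area_px = min_area_px)
  pl <- exclude_overlaps(pl, pixel_size_um = plaque_channel$pixel_size_um)
  pl$halo_intensity <- NA_real_
  keep <- which(!pl$excluded)
  if (length(keep) > 0) {
    bg <- background_mask(glial_channel, pl)
    for (i in keep)
      pl$halo_intensity[i] <- halo_intensity(glial_channel, pl[i, ], bg,
                                             low = glial_low)
  }
  pl
}

#' Ordinary least squares of halo intensity on plaque area
#'
#' @param records Data frame with columns `area_um2` and `halo_intensity`
#'   (excluded/NA rows are dropped); at least 3 usable rows with nonzero
#'   variance in area.
#' @return `RegressionFit`: list with `slope`, `intercept`, `r_squared`,
#'   `n`, and the underlying `lm` fit.
#' @export
regress_intensity_on_area <- function(records) {
  d <- records[stats::complete.cases(records[, c("area_um2",
                                                 "halo_intensity")]), ]
  if (nrow(d) < 3) stop("need at least 3 plaques for regression")
  if (stats::var(d$area_um2) == 0) stop("zero variance in plaque area")
  fit <- stats::lm(halo_intensity ~ area_um2, data = d)
  # constant response: define R^2 = 0 rather than the 0/0 of summary.lm;
  # noiseless scenes fit exactly, so silence summary.lm's perfect-fit warning
  r2 <- if (stats::var(d$halo_intensity) == 0) 0 else
    suppressWarnings(summary(fit)$r.squared)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2, n = nrow(d), fit = fit),
            class = "RegressionFit")
}

#' @export
print.RegressionFit <- function(x, ...) {
  cat(sprintf("y = %.4gx + %.6g, R2 = %.3f, n = %d\n",
              x$slope, x$intercept, x$r_squared, x$n))
  invisible(x)
}

#' Compare halo-vs-area regression slopes between groups
#'
#' Fits the pooled interaction model
#' `halo_intensity ~ area_um2 * group` with the reference group as the
#' baseline level, and tests each non-reference group's interaction
#' coefficient (its slope difference from the reference) with a t-test.
#' This is the classical test of equality of regression slopes.
#'
#' @param records Data frame with columns `group`, `area_um2`,
#'   `halo_intensity`; every group needs at least 3 usable rows.
#' @param reference Name of the reference group.
#' @return Data frame of `SlopeComparison` rows: `group`,
#'   `slope_difference` (group slope minus reference slope), `p_value`.
#' @export
compare_slopes <- function(records, reference) {
  d <- records[stats::complete.cases(records[, c("area_um2",
                                                 "halo_intensity")]), ]
  if (!reference %in% d$group) stop("reference group not present: ", reference)
  cnt <- table(d$group)
  if (any(cnt < 3)) stop("every group needs at least 3 records")
  d$group <- stats::relevel(factor(d$group), ref = reference)
  fit <- stats::lm(halo_intensity ~ area_um2 * group, data = d)
  cf <- summary(fit)$coefficients
  others <- setdiff(levels(d$group), reference)
  rows <- lapply(others, function(gr) {
    nm <- paste0("area_um2:group", gr)
    data.frame(group = gr, slope_difference = cf[nm, "Estimate"],
               p_value = cf[nm, "Pr(>|t|)"])
  })
  do.call(rbind, rows)
}

#' Count plaques and plaque-associated glial clusters
#'
#' Counts plaques in the plaque channel and, in each glial channel, the
#' number of glial clusters (regions segmented at `[glial_low, 255]` of at
#' least `glial_min_area_px` pixels) whose centroid lies inside some
#' plaque's neighborhood disk.
#'
#' @param plaque_channel,gfap_channel,iba1_channel Co-registered
#'   [image_plane()]s.
#' @param plaque_low,glial_low Segmentation thresholds (defaults 20, 30).
#' @param min_area_px,glial_min_area_px Minimum region sizes (defaults 20,
#'   30).
#' @return Named list: `plaques`, `gfap_clusters`, `iba1_clusters`.
#' @export
count_plaques_and_clusters <- function(plaque_channel, gfap_channel,
                                       iba1_channel, plaque_low = 20,
                                       glial_low = 30, min_area_px = 20,
                                       glial_min_area_px = 30) {
  dims <- dim(plaque_channel$pixels)
  if (!identical(dims, dim(gfap_channel$pixels)) ||
      !identical(dims, dim(iba1_channel$pixels)))
    stop("channel dimensions do not match")
  pl <- detect_plaques(plaque_channel, low = plaque_low,
                       min_area_px = min_area_px)
  count_clusters <- function(channel) {
    regs <- segment(channel, low = glial_low, high = 255,
                    min_area_px = glial_min_area_px)
    if (length(regs) == 0 || nrow(pl) == 0) return(0L)
    tab <- regions_table(regs)
    px <- channel$pixel_size_um
    inside <- vapply(seq_len(nrow(tab)), function(i) {
      dy <- (tab$centroid_row[i] - pl$centroid_row) * px
      dx <- (tab$centroid_col[i] - pl$centroid_col) * px
      any(sqrt(dy^2 + dx^2) <= pl$neighborhood_radius_um)
    }, logical(1))
    sum(inside)
  }
  list(plaques = nrow(pl), gfap_clusters = count_clusters(gfap_channel),
       iba1_clusters = count_clusters(iba1_channel))
}
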