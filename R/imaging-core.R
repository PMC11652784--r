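#' Construct an image plane
#'
#' An `ImagePlane` is one 8-bit grayscale channel of a fluorescence scene,
#' stored as a matrix of intensities in 0..255 together with the physical
#' pixel calibration in micrometres.
#'
#' @param pixels Numeric matrix of intensities; all values must lie in
#'   \[0, 255\]. Rows index image rows (y), columns index image columns (x).
#' @param pixel_size_um Physical edge length of one pixel in micrometres
#'   (> 0).
#' @param channel_name Free-text channel label, e.g. `"Iba1"`, `"GFAP"`,
#'   `"ThS"`, `"AmyloGlo"`, `"DCX"`, `"BrdU"`.
#' @return An object of class `ImagePlane`: a list with elements `pixels`,
#'   `pixel_size_um` and `channel_name`.
#' @examples
#' img <- image_plane(matrix(0, 64, 64), pixel_size_um = 1)
#' dim(img$pixels)
#' @export
image_plane <- function(pixels, pixel_size_um, channel_name = "") {
  if (!is.matrix(pixels)) stop("'pixels' must be a matrix")
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255)
    stop("pixel intensities must lie in [0, 255]")
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1 ||
      is.na(pixel_size_um) || pixel_size_um <= 0)
    stop("'pixel_size_um' must be a single positive number")
  structure(
    list(pixels = pixels, pixel_size_um = pixel_size_um,
         channel_name = channel_name),
    class = "ImagePlane"
  )
}

#' @export
print.ImagePlane <- function(x, ...) {
  cat(sprintf("ImagePlane '%s': %d x %d px, %.4g um/px, range [%g, %g]\n",
              x$channel_name, nrow(x$pixels), ncol(x$pixels),
              x$pixel_size_um, min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' Read a grayscale TIFF page as an image plane
#'
#' Reads one page of a grayscale TIFF file. Inputs with bit depth other than
#' 8 are linearly rescaled to 0--255 with a warning.
#'
#' @param path Path to a TIFF file.
#' @param pixel_size_um Pixel calibration in micrometres per pixel (> 0).
#' @param channel_name Channel label stored on the returned plane.
#' @param page Page index for multi-page files (default 1).
#' @return An [image_plane()].
#' @export
read_image <- function(path, pixel_size_um, channel_name = "", page = 1L) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (!is.numeric(pixel_size_um) || pixel_size_um <= 0)
    stop("'pixel_size_um' must be positive")
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE),
                    error = function(e) stop("not a readable TIFF: ", path))
  if (page < 1 || page > length(pages))
    stop("page ", page, " out of range (file has ", length(pages), ")")
  px <- pages[[page]]
  if (length(dim(px)) == 3) stop("multi-channel (colour) TIFF not supported")
  px <- as.matrix(px)
  if (max(px) > 255) {
    warning("input is not 8-bit; rescaling intensities to 0-255")
    bits <- ceiling(log2(max(px) + 1))
    px <- round(px / (2^bits - 1) * 255)
  }
  image_plane(px, pixel_size_um, channel_name)
}

#' Write an image plane as an 8-bit grayscale TIFF
#'
#' @param image An [image_plane()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  stopifnot(inherits(image, "ImagePlane"))
  tiff::writeTIFF(round(image$pixels) / 255, path, bits.per.sample = 8L)
  invisible(path)
}

# --- geometry on pixel masks -------------------------------------------------
#
# Convention: pixel (r, c) occupies the unit square with corners
# (x, y) in {c-1, c} x {r-1, r}. Hulls are taken over the pixel-corner
# cloud so a single pixel has hull area 1 and convex rasterized shapes
# score solidity ~1; a 1xN bar has corner-caliper Feret sqrt(N^2 + 1).

pixel_corners <- function(coords) {
  r <- coords[, 1]; c <- coords[, 2]
  pts <- cbind(x = c(c - 1, c, c - 1, c), y = c(r - 1, r - 1, r, r))
  unique(pts)
}

polygon_area <- function(poly) {
  # shoelace formula; poly is an n x 2 matrix of vertices in order
  x <- poly[, 1]; y <- poly[, 2]
  n <- nrow(poly)
  j <- c(2:n, 1)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

#' Construct a region mask from pixel coordinates
#'
#' A `RegionMask` is one labeled connected pixel region together with its
#' derived geometry: pixel and physical area, the convex hull of the
#' pixel-corner cloud (shoelace area), and the maximum-caliper Feret
#' diameter of the hull.
#'
#' @param coords Two-column integer matrix of (row, col) pixel coordinates.
#' @param pixel_size_um Pixel calibration in micrometres (> 0).
#' @param label Positive integer region label.
#' @return An object of class `RegionMask` with fields `label`, `coords`,
#'   `area_px`, `area_um2`, `hull_vertices` (x, y in pixel-corner
#'   coordinates), `convex_area_um2`, `feret_um`, `centroid` (row, col of
#'   the pixel-center centroid) and `pixel_size_um`.
#' @export
region_mask <- function(coords, pixel_size_um, label = 1L) {
  coords <- as.matrix(coords)
  if (nrow(coords) == 0) stop("region must contain at least one pixel")
  if (pixel_size_um <= 0) stop("'pixel_size_um' must be positive")
  pts <- pixel_corners(coords)
  h <- grDevices::chull(pts[, 1], pts[, 2])
  hull <- pts[h, , drop = FALSE]
  hull_area_px2 <- polygon_area(hull)
  feret_px <- if (nrow(hull) == 1) 0 else max(stats::dist(hull))
  area_px <- nrow(coords)
  structure(
    list(
      label = as.integer(label),
      coords = coords,
      area_px = area_px,
      area_um2 = area_px * pixel_size_um^2,
      hull_vertices = hull,
      convex_area_um2 = hull_area_px2 * pixel_size_um^2,
      feret_um = feret_px * pixel_size_um,
      centroid = c(row = mean(coords[, 1]) - 0.5,
                   col = mean(coords[, 2]) - 0.5),
      pixel_size_um = pixel_size_um
    ),
    class = "RegionMask"
  )
}

#' @export
print.RegionMask <- function(x, ...) {
  cat(sprintf(
    "RegionMask %d: %d px (%.4g um2), hull %.4g um2, Feret %.4g um\n",
    x$label, x$area_px, x$area_um2, x$convex_area_um2, x$feret_um))
  invisible(x)
}

#' Convex hull of a region's pixel-corner cloud
#'
#' Each pixel contributes its four corner points; the hull polygon is
#' returned with its shoelace area scaled by the pixel calibration. By this
#' convention a single pixel yields a unit-square hull.
#'
#' @param region A [region_mask()].
#' @return List with `hull_vertices` (n x 2 matrix, x/y pixel-corner
#'   coordinates) and `convex_area_um2`.
#' @export
convex_hull <- function(region) {
  stopifnot(inherits(region, "RegionMask"))
  list(hull_vertices = region$hull_vertices,
       convex_area_um2 = region$convex_area_um2)
}

#' Maximum-caliper (Feret) diameter of a region
#'
#' Maximum pairwise distance over the convex-hull vertices of the
#' pixel-corner cloud, scaled to micrometres. A 1x10 bar at 1 um/px scores
#' sqrt(10^2 + 1) ~ 10.0499 um (corner-to-corner caliper).
#'
#' @param region A [region_mask()].
#' @return Feret diameter in micrometres.
#' @export
feret_diameter <- function(region) {
  stopifnot(inherits(region, "RegionMask"))
  region$feret_um
}

# shift a matrix by (dr, dc), padding with `fill`
shift_matrix <- function(m, dr, dc, fill = Inf) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rows <- max(1, 1 + dr):min(nr, nr + dr)
  cols <- max(1, 1 + dc):min(nc, nc + dc)
  if (length(rows) > 0 && length(cols) > 0)
    out[rows, cols] <- m[rows - dr, cols - dc, drop = FALSE]
  out
}

# 8-connected component labeling by iterative min-label propagation.
# Returns an integer matrix: 0 background, components labeled 1..k in
# raster order (row-major) of each component's first pixel.
label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  if (!any(mask)) return(matrix(0L, nr, nc))
  rowmajor <- t(matrix(seq_len(nr * nc), nc, nr))  # row-major scan index
  lab <- matrix(Inf, nr, nc)
  lab[mask] <- rowmajor[mask]
  offs <- cbind(dr = rep(-1:1, each = 3), dc = rep(-1:1, 3))
  offs <- offs[!(offs[, 1] == 0 & offs[, 2] == 0), ]
  repeat {
    nxt <- lab
    for (k in seq_len(nrow(offs)))
      nxt <- pmin(nxt, shift_matrix(lab, offs[k, 1], offs[k, 2]))
    nxt[!mask] <- Inf
    if (identical(nxt, lab)) break
    lab <- nxt
  }
  roots <- sort(unique(lab[mask]))          # sorted = raster order of minima
  out <- matrix(0L, nr, nc)
  out[mask] <- match(lab[mask], roots)
  out
}

#' Threshold segmentation into connected regions
#'
#' Foreground pixels are those with intensity in the inclusive interval
#' `[low, high]`; no shade (flat-field) correction is applied beforehand.
#' Foreground is split into 8-connected components; components smaller than
#' `min_area_px` are discarded. Labels are assigned in raster order
#' (row-major) of each component's first pixel, so segmentation is
#' deterministic.
#'
#' @param image An [image_plane()].
#' @param low,high Inclusive intensity bounds in 0..255 (`low <= high`).
#' @param min_area_px Minimum component size in pixels; smaller components
#'   are dropped.
#' @return List of [region_mask()] objects (possibly empty), labeled
#'   `1..k`.
#' @examples
#' px <- matrix(0, 32, 32); px[5:10, 5:10] <- 200
#' regs <- segment(image_plane(px, 1), low = 30, high = 255, min_area_px = 10)
#' length(regs)
#' @export
segment <- function(image, low, high = 255, min_area_px = 1) {
  stopifnot(inherits(image, "ImagePlane"))
  if (low > high) stop("'low' must not exceed 'high'")
  if (low < 0 || high > 255) stop("thresholds must lie in 0..255")
  mask <- image$pixels >= low & image$pixels <= high
  lab <- label_components(mask)
  k <- max(lab)
  if (k == 0) return(list())
  regions <- list()
  nxt <- 1L
  for (i in seq_len(k)) {
    coords <- which(lab == i, arr.ind = TRUE)
    if (nrow(coords) < min_area_px) next
    # order pixels in raster order within the region, for reproducible output
    coords <- coords[order(coords[, 1], coords[, 2]), , drop = FALSE]
    regions[[nxt]] <- region_mask(coords, image$pixel_size_um, label = nxt)
    nxt <- nxt + 1L
  }
  regions
}

#' Tabulate segmented regions
#'
#' @param regions List of [region_mask()] objects, e.g. from [segment()].
#' @return Data frame with one row per region: `label`, `area_px`,
#'   `area_um2`, `convex_area_um2`, `feret_um`, `centroid_row`,
#'   `centroid_col`.
#' @export
regions_table <- function(regions) {
  if (length(regions) == 0)
    return(data.frame(label = integer(), area_px = integer(),
                      area_um2 = numeric(), convex_area_um2 = numeric(),
                      feret_um = numeric(), centroid_row = numeric(),
                      centroid_col = numeric()))
  do.call(rbind, lapply(regions, function(r) data.frame(
    label = r$label, area_px = r$area_px, area_um2 = r$area_um2,
    convex_area_um2 = r$convex_area_um2, feret_um = r$feret_um,
    centroid_row = r$centroid["row"], centroid_col = r$centroid["col"],
    row.names = NULL)))
}

# does a region touch the image border?
touches_border <- function(region, dim_px) {
  any(region$coords[, 1] %in% c(1L, dim_px[1])) ||
    any(region$coords[, 2] %in% c(1L, dim_px[2]))
}
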