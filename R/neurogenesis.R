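# Polylines are n x 2 matrices of (row, col) points in pixel coordinates.

polyline_arc_length <- function(polyline) {
  p <- as.matrix(polyline)
  if (nrow(p) < 2) stop("polyline needs at least 2 points")
  sum(sqrt(rowSums((p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2)))
}

# minimum distance from each point (rows of pts) to a polyline, in pixels
dist_to_polyline <- function(pts, polyline) {
  pts <- as.matrix(pts); p <- as.matrix(polyline)
  a <- p[-nrow(p), , drop = FALSE]; b <- p[-1, , drop = FALSE]
  ab <- b - a
  len2 <- rowSums(ab^2)
  apply(pts, 1, function(q) {
    t <- ((q[1] - a[, 1]) * ab[, 1] + (q[2] - a[, 2]) * ab[, 2]) /
      pmax(len2, .Machine$double.eps)
    t <- pmin(pmax(t, 0), 1)
    proj <- a + ab * t
    sqrt(min((q[1] - proj[, 1])^2 + (q[2] - proj[, 2])^2))
  })
}

# robust proper/improper segment intersection (endpoints touching count)
orient <- function(p, q, r) {
  v <- (q[1] - p[1]) * (r[2] - p[2]) - (q[2] - p[2]) * (r[1] - p[1])
  sign(v)
}

on_segment <- function(p, q, r) {
  min(p[1], q[1]) <= r[1] && r[1] <= max(p[1], q[1]) &&
    min(p[2], q[2]) <= r[2] && r[2] <= max(p[2], q[2])
}

segments_intersect <- function(p1, p2, q1, q2) {
  o1 <- orient(p1, p2, q1); o2 <- orient(p1, p2, q2)
  o3 <- orient(q1, q2, p1); o4 <- orient(q1, q2, p2)
  if (o1 != o2 && o3 != o4) return(TRUE)
  (o1 == 0 && on_segment(p1, p2, q1)) ||
    (o2 == 0 && on_segment(p1, p2, q2)) ||
    (o3 == 0 && on_segment(q1, q2, p1)) ||
    (o4 == 0 && on_segment(q1, q2, p2))
}

# does a path (polyline) cross a line (polyline) at least once?
path_crosses_line <- function(path, line) {
  path <- as.matrix(path); line <- as.matrix(line)
  for (i in seq_len(nrow(path) - 1)) {
    for (j in seq_len(nrow(line) - 1)) {
      if (segments_intersect(path[i, ], path[i + 1, ],
                             line[j, ], line[j + 1, ])) return(TRUE)
    }
  }
  FALSE
}

#' Construct a subgranular-zone scene annotation
#'
#' Vector annotations of one dentate-gyrus field: the SGZ trace, the
#' mid-granular-cell-layer and outer-granular-cell-layer reference lines,
#' marker-positive soma positions, and tagged dendrite paths. The
#' annotations are produced by the generator or by external manual tracing;
#' no automatic dendrite tracing from pixels is attempted.
#'
#' @param polyline SGZ trace, n x 2 matrix of (row, col) points (n >= 2).
#' @param mid_gcl_line,outer_gcl_line Reference polylines (n >= 2 each).
#' @param soma_positions Named list of m x 2 matrices of soma positions per
#'   marker (e.g. `DCX`, `BrdU`).
#' @param dendrite_paths List of dendrite annotations, each a list with
#'   `path` (n x 2 matrix), `soma_id` and `order` (`"primary"` or
#'   `"secondary"`).
#' @param pixel_size_um Pixel calibration in micrometres.
#' @return An object of class `SgzScene`.
#' @export
sgz_scene <- function(polyline, mid_gcl_line, outer_gcl_line,
                      soma_positions = list(), dendrite_paths = list(),
                      pixel_size_um = 1) {
  for (ln in list(polyline, mid_gcl_line, outer_gcl_line))
    if (nrow(as.matrix(ln)) < 2) stop("polylines need at least 2 points")
  if (polyline_arc_length(polyline) <= 0) stop("SGZ trace has zero length")
  structure(list(polyline = as.matrix(polyline),
                 mid_gcl_line = as.matrix(mid_gcl_line),
                 outer_gcl_line = as.matrix(outer_gcl_line),
                 soma_positions = lapply(soma_positions, as.matrix),
                 dendrite_paths = dendrite_paths,
                 pixel_size_um = pixel_size_um),
            class = "SgzScene")
}

#' Linear density of labeled cells along the SGZ
#'
#' Counts the positions lying within `band_um` of the SGZ trace and divides
#' by the trace arc length in millimetres, giving cells per mm of SGZ.
#'
#' @param positions m x 2 matrix of (row, col) cell positions in pixels
#'   (may have zero rows).
#' @param polyline SGZ trace, n x 2 matrix in pixels.
#' @param pixel_size_um Pixel calibration in micrometres.
#' @param band_um Maximum distance from the trace for a cell to count as
#'   SGZ-resident (default 20 um).
#' @return Cells per millimetre of SGZ.
#' @export
linear_density <- function(positions, polyline, pixel_size_um,
                           band_um = 20) {
  len_mm <- polyline_arc_length(polyline) * pixel_size_um / 1000
  if (len_mm <= 0) stop("SGZ trace has zero length")
  positions <- as.matrix(positions)
  if (length(positions) == 0 || nrow(positions) == 0) return(0)
  d_um <- dist_to_polyline(positions, polyline) * pixel_size_um
  sum(d_um <= band_um) / len_mm
}

#' Laminar counts of somata and dendrite crossings
#'
#' Counts (a) DCX-positive cell bodies, (b) primary dendrite paths crossing
#' the mid-GCL line at least once, and (c) secondary dendrite paths crossing
#' the outer-GCL line at least once. A path that crosses a line several
#' times counts once. Crossings are detected by exact segment-intersection
#' tests between the path and line polylines.
#'
#' @param scene An [sgz_scene()].
#' @return `LaminarCounts`: list with integer `a`, `b`, `c`.
#' @export
laminar_counts <- function(scene) {
  stopifnot(inherits(scene, "SgzScene"))
  dcx <- scene$soma_positions$DCX
  a <- if (is.null(dcx)) 0L else nrow(dcx)
  b <- 0L; c_ <- 0L
  for (d in scene$dendrite_paths) {
    if (identical(d$order, "primary") &&
        path_crosses_line(d$path, scene$mid_gcl_line)) b <- b + 1L
    if (identical(d$order, "secondary") &&
        path_crosses_line(d$path, scene$outer_gcl_line)) c_ <- c_ + 1L
  }
  structure(list(a = as.integer(a), b = b, c = c_), class = "LaminarCounts")
}

#' Dendrite sprouting and branching ratios
#'
#' Sprouting is the number of mid-GCL-crossing primary dendrites per soma
#' (b/a); branching is the number of outer-GCL-crossing secondary dendrites
#' per primary dendrite (c/b). A ratio with zero denominator is undefined
#' and returned as `NA` (never coerced to 0).
#'
#' @param counts A `LaminarCounts` object or list with `a`, `b`, `c`.
#' @return List with `sprouting` (b/a) and `branching` (c/b), `NA` where the
#'   denominator is zero.
#' @examples
#' dendrite_ratios(list(a = 10, b = 20, c = 30))  # 2.0, 1.5
#' @export
dendrite_ratios <- function(counts) {
  list(sprouting = if (counts$a > 0) counts$b / counts$a else NA_real_,
       branching = if (counts$b > 0) counts$c / counts$b else NA_real_)
}

#' Write / read SGZ scene annotations as JSON
#'
#' @param scene An [sgz_scene()].
#' @param path Output (input) JSON file path.
#' @return `path` invisibly; `read_sgz_scene` returns the scene.
#' @export
write_sgz_scene <- function(scene, path) {
  stopifnot(inherits(scene, "SgzScene"))
  obj <- list(
    polyline = unclass(scene$polyline),
    mid_gcl_line = unclass(scene$mid_gcl_line),
    outer_gcl_line = unclass(scene$outer_gcl_line),
    soma_positions = lapply(scene$soma_positions, unclass),
    dendrite_paths = lapply(scene$dendrite_paths, function(d)
      list(path = unclass(d$path), soma_id = d$soma_id, order = d$order)),
    pixel_size_um = scene$pixel_size_um
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_sgz_scene
#' @export
read_sgz_scene <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  dend <- obj$dendrite_paths
  if (is.data.frame(dend))
    dend <- lapply(seq_len(nrow(dend)), function(i)
      list(path = dend$path[[i]], soma_id = dend$soma_id[i],
           order = dend$order[i]))
  sgz_scene(obj$polyline, obj$mid_gcl_line, obj$outer_gcl_line,
            lapply(obj$soma_positions, as.matrix), dend, obj$pixel_size_um)
}
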