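# Seeded synthetic-scene generation. One integer seed drives one named
# pseudorandom stream per scene component (seed_stream), so adding a
# component never perturbs the draws of existing ones.

seed_stream <- function(seed, component) {
  h <- sum(utf8ToInt(component) * seq_along(utf8ToInt(component)))
  as.integer((abs(seed) * 48271 + h * 7919) %% 2147483647)
}

# stamp value onto pixels whose centers lie within radius of (r0, c0)
stamp_disk <- function(px, r0, c0, radius, value) {
  nr <- nrow(px); nc <- ncol(px)
  rs <- max(1, floor(r0 - radius)):min(nr, ceiling(r0 + radius) + 1)
  cs <- max(1, floor(c0 - radius)):min(nc, ceiling(c0 + radius) + 1)
  dy <- (rs - 0.5 - r0)^2
  dx <- (cs - 0.5 - c0)^2
  hit <- outer(dy, dx, `+`) <= radius^2
  block <- px[rs, cs, drop = FALSE]
  block[hit] <- value
  px[rs, cs] <- block
  px
}

# jittered-grid placement: deterministic feasibility, seeded assignment
place_on_grid <- function(n, image_size_px, reach_px, jitter_px = 2) {
  pitch <- 2 * reach_px + 2 * jitter_px + 2
  margin <- reach_px + jitter_px + 1
  span <- image_size_px - 2 * margin
  k <- floor(span / pitch) + 1
  if (k < 1 || k * k < n)
    stop("infeasible packing: ", n, " cells of reach ", reach_px,
         " px do not fit a ", image_size_px, " px canvas")
  nodes <- expand.grid(row = margin + (0:(k - 1)) * pitch,
                       col = margin + (0:(k - 1)) * pitch)
  pick <- sample(nrow(nodes), n)
  cbind(row = nodes$row[pick] + stats::runif(n, -jitter_px, jitter_px),
        col = nodes$col[pick] + stats::runif(n, -jitter_px, jitter_px))
}

#' Generate a synthetic microglia scene with ground truth
#'
#' Cells are rasterized as a soma disk plus `n_branches` random-walk
#' processes of the requested length and width, painted at a fixed intensity
#' above the segmentation threshold. `activation` retracts branches (the
#' rasterized branch length is `branch_length_um * (1 - activation)`),
#' emulating the amoeboid shift of activated microglia: higher activation
#' gives higher form factors, while longer branches give lower ones. Cells
#' are placed on a seeded jittered grid so they can never touch; an
#' infeasible request (too many cells for the canvas) is an error.
#'
#' @param seed Integer seed; identical seed and parameters give bit-identical
#'   scenes.
#' @param n_cells Number of cells.
#' @param image_size_px Square canvas size in pixels.
#' @param pixel_size_um Pixel calibration (default 1 um/px).
#' @param soma_radius_um Soma radius.
#' @param n_branches Branches per cell.
#' @param branch_length_um Nominal branch length before retraction.
#' @param branch_width_um Branch thickness.
#' @param activation Branch-retraction fraction in \[0, 1\].
#' @param intensity Paint intensity (default 200; segmentation threshold 30).
#' @return List with `image` (an [image_plane()], channel `"Iba1"`) and
#'   `truth` (data frame: `cell_id`, `center_row`, `center_col`,
#'   `n_branches`, `branch_length_um`, `morph_class`).
#' @export
generate_microglia_scene <- function(seed, n_cells = 9, image_size_px = 512,
                                     pixel_size_um = 1, soma_radius_um = 8,
                                     n_branches = 4, branch_length_um = 30,
                                     branch_width_um = 2, activation = 0,
                                     intensity = 200) {
  stopifnot(activation >= 0, activation <= 1, n_cells >= 0)
  soma_px <- soma_radius_um / pixel_size_um
  eff_len <- branch_length_um * (1 - activation) / pixel_size_um
  if (n_branches == 0) eff_len <- 0
  reach <- ceiling(soma_px + eff_len + branch_width_um / pixel_size_um + 1)
  px <- matrix(0, image_size_px, image_size_px)
  truth <- data.frame(cell_id = integer(), center_row = numeric(),
                      center_col = numeric(), n_branches = integer(),
                      branch_length_um = numeric(), morph_class = character())
  if (n_cells > 0) {
    withr::with_seed(seed_stream(seed, "microglia"), {
      centers <- place_on_grid(n_cells, image_size_px, reach)
      half_w <- max(branch_width_um / pixel_size_um / 2, 0.71)
      for (i in seq_len(n_cells)) {
        r0 <- centers[i, 1]; c0 <- centers[i, 2]
        px <- stamp_disk(px, r0, c0, soma_px, intensity)
        if (eff_len > 0) {
          for (b in seq_len(n_branches)) {
            theta <- stats::runif(1, 0, 2 * pi)
            pos <- c(r0, c0)
            steps <- round(eff_len)
            for (s in seq_len(steps)) {
              theta <- theta + stats::rnorm(1, 0, 0.25)
              step <- c(sin(theta), cos(theta))
              nxt <- pos + step
              # confine the walk to the cell's reach so cells stay disjoint
              if (sqrt(sum((nxt - c(r0, c0))^2)) > eff_len + soma_px - 1)
                break
              pos <- nxt
              px <- stamp_disk(px, pos[1], pos[2], half_w, intensity)
            }
          }
        }
      }
      truth <- data.frame(
        cell_id = seq_len(n_cells), center_row = centers[, 1],
        center_col = centers[, 2], n_branches = n_branches,
        branch_length_um = branch_length_um * (1 - activation),
        morph_class = if (n_branches == 0 || eff_len * pixel_size_um < 10)
          "amoeboid" else "ramified")
    })
  }
  list(image = image_plane(px, pixel_size_um, "Iba1"), truth = truth)
}

# Gaussian noise sd giving an expected R^2 for y = b1 * x + e given x values
sigma_for_r2 <- function(beta1, x, r2) {
  abs(beta1) * stats::sd(x) * sqrt((1 - r2) / r2)
}

# paint `n_px` glial pixels (plus an exact remainder) inside a disk so the
# thresholded, background-corrected sum over the disk equals `target`
paint_halo <- function(px, center, radius, target, n_seeds, background,
                       halo_value) {
  excess <- halo_value - background
  dims <- dim(px)
  rs <- max(1, floor(center[1] - radius)):min(dims[1], ceiling(center[1] + radius))
  cs <- max(1, floor(center[2] - radius)):min(dims[2], ceiling(center[2] + radius))
  grid <- expand.grid(row = rs, col = cs)
  d2 <- (grid$row - 0.5 - center[1])^2 + (grid$col - 0.5 - center[2])^2
  # keep a safety margin off the rim so sub-pixel centroid differences
  # between generation and measurement cannot drop painted pixels
  grid <- grid[d2 <= (radius - 1.5)^2, ]
  target <- max(target, 20)
  n <- min(floor(target / excess), nrow(grid) - 1)
  rem <- target - n * excess
  seeds <- grid[sample(nrow(grid), n_seeds), , drop = FALSE]
  dmin <- rep(Inf, nrow(grid))
  for (s in seq_len(n_seeds))
    dmin <- pmin(dmin, (grid$row - seeds$row[s])^2 +
                   (grid$col - seeds$col[s])^2)
  ord <- order(dmin)
  chosen <- grid[ord[seq_len(n)], ]
  px[cbind(chosen$row, chosen$col)] <- halo_value
  if (rem > 0) {
    if (rem >= 30 - background) {
      extra <- grid[ord[n + 1], ]
      px[extra$row, extra$col] <- background + rem
    } else if (n > 0) {
      last <- grid[ord[n], ]
      px[last$row, last$col] <- halo_value + rem
    }
  }
  px
}

#' Generate a synthetic plaque scene with glial halos and ground truth
#'
#' Plaques are radial-falloff blobs (intensity 255 at the center falling to
#' the detection threshold at the rim) placed on a seeded grid so that their
#' 8x-Feret neighborhood disks never overlap. Each glial channel paints,
#' inside each plaque's neighborhood disk, clustered blobs whose thresholded
#' background-corrected integrated intensity equals
#' `beta1 * area_um2 + beta0 + N(0, sigma)` exactly (up to 8-bit rounding of
#' a single remainder pixel). The rest of the channel sits at a uniform
#' background level, so the default background region recovers the true
#' background mean.
#'
#' @param seed Integer seed.
#' @param n_plaques Number of plaques.
#' @param image_size_px Square canvas size (default 1024).
#' @param pixel_size_um Pixel calibration (default 1 um/px).
#' @param radius_um_range Min/max plaque radius in micrometres.
#' @param beta1,beta0 Halo linear model: intensity on plaque area (um^2).
#'   Defaults parameterize a strong positive area dependence typical of
#'   plaque-associated microgliosis.
#' @param sigma Gaussian noise SD on the halo target; `NULL` (default)
#'   calibrates it so the expected R^2 of intensity on area is `target_r2`.
#' @param target_r2 Used only when `sigma` is NULL (default 0.6).
#' @param background Glial background intensity (default 10, below the
#'   glial threshold of 30).
#' @param halo_value Paint intensity of halo pixels (default 210).
#' @param n_seeds Cluster blobs per neighborhood disk (default 3).
#' @param channels Glial channel names to synthesize (default `"Iba1"`;
#'   add `"GFAP"` for cluster-count scenes).
#' @param centers Optional n x 2 matrix of plaque centers (row, col) in
#'   pixels, overriding grid placement (e.g. to force overlapping
#'   neighborhoods).
#' @return List with `plaque` ([image_plane()]), one [image_plane()] per
#'   requested glial channel (named `iba1` / `gfap`), and `truth` (data
#'   frame per plaque: center, radius, measured `area_um2`, `feret_um`,
#'   `neighborhood_radius_um`, noiseless `expected_halo` and realized
#'   `target_halo`; attributes `beta1`, `beta0`, `sigma`).
#' @export
generate_plaque_scene <- function(seed, n_plaques = 8, image_size_px = 1024,
                                  pixel_size_um = 1,
                                  radius_um_range = c(4, 10), beta1 = 633.8,
                                  beta0 = 276179, sigma = NULL,
                                  target_r2 = 0.6, background = 10,
                                  halo_value = 210, n_seeds = 3,
                                  channels = "Iba1", centers = NULL) {
  stopifnot(n_plaques >= 1, background < 30, halo_value <= 255)
  plaque_px <- matrix(0, image_size_px, image_size_px)
  r_max_px <- radius_um_range[2] / pixel_size_um
  # neighborhood radius is 4 x Feret ~ 8 x plaque radius; keep disks apart
  reach <- ceiling(8 * (r_max_px + 1) + 4)
  radii <- withr::with_seed(seed_stream(seed, "plaque-geometry"), {
    if (is.null(centers))
      centers <- place_on_grid(n_plaques, image_size_px, reach)
    stats::runif(n_plaques, radius_um_range[1], radius_um_range[2]) /
      pixel_size_um
  })
  for (i in seq_len(n_plaques)) {
    # radial falloff: 255 at center, crossing the threshold (20) at the rim
    r <- radii[i]
    rs <- max(1, floor(centers[i, 1] - r)):min(image_size_px,
                                               ceiling(centers[i, 1] + r))
    cs <- max(1, floor(centers[i, 2] - r)):min(image_size_px,
                                               ceiling(centers[i, 2] + r))
    dy <- (rs - 0.5 - centers[i, 1])^2
    dx <- (cs - 0.5 - centers[i, 2])^2
    d <- sqrt(outer(dy, dx, `+`))
    block <- plaque_px[rs, cs, drop = FALSE]
    inside <- d <= r
    block[inside] <- pmax(block[inside], round(255 - (255 - 20) * d[inside] / r))
    plaque_px[rs, cs] <- block
  }
  plaque <- image_plane(plaque_px, pixel_size_um, "ThS")
  detected <- detect_plaques(plaque)
  if (nrow(detected) != n_plaques)
    stop("plaque rasterization produced ", nrow(detected), " regions for ",
         n_plaques, " plaques")
  # match detected records to generator centers
  ord <- vapply(seq_len(n_plaques), function(i)
    which.min((detected$centroid_row - centers[i, 1])^2 +
                (detected$centroid_col - centers[i, 2])^2), integer(1))
  detected <- detected[ord, ]
  if (is.null(sigma))
    sigma <- sigma_for_r2(beta1, detected$area_um2, target_r2)
  expected <- beta1 * detected$area_um2 + beta0
  target <- withr::with_seed(seed_stream(seed, "halo-noise"),
                             expected + stats::rnorm(n_plaques, 0, sigma))
  target <- round(pmax(target, 20))
  out <- list(plaque = plaque)
  for (ch in channels) {
    gp <- matrix(background, image_size_px, image_size_px)
    gp <- withr::with_seed(seed_stream(seed, paste0("halo-", ch)), {
      for (i in seq_len(n_plaques)) {
        gp <- paint_halo(gp, c(detected$centroid_row[i],
                               detected$centroid_col[i]),
                         detected$neighborhood_radius_um[i] / pixel_size_um,
                         target[i], n_seeds, background, halo_value)
      }
      gp
    })
    out[[tolower(ch)]] <- image_plane(gp, pixel_size_um, ch)
  }
  truth <- data.frame(plaque_id = seq_len(n_plaques),
                      center_row = centers[, 1], center_col = centers[, 2],
                      radius_px = radii, area_um2 = detected$area_um2,
                      feret_um = detected$feret_um,
                      neighborhood_radius_um = detected$neighborhood_radius_um,
                      expected_halo = expected, target_halo = target)
  attr(truth, "beta1") <- beta1
  attr(truth, "beta0") <- beta0
  attr(truth, "sigma") <- sigma
  out$truth <- truth
  out
}

#' Generate tabular halo-regression data (no rasterization)
#'
#' Draws plaque areas and halo intensities straight from the linear halo
#' model, for simulation studies of the regression and slope-comparison
#' stages where rasterizing full scenes would add nothing.
#'
#' @param seed Integer seed.
#' @param n Number of plaques.
#' @param beta1,beta0 Linear model parameters.
#' @param sigma Noise SD; `NULL` calibrates to `target_r2`.
#' @param target_r2 Expected R^2 when `sigma` is NULL (default 0.6).
#' @param area_range Uniform range of plaque areas in um^2.
#' @param group Group label attached to the records.
#' @return Data frame `group`, `area_um2`, `halo_intensity`; attribute
#'   `sigma`.
#' @export
generate_halo_records <- function(seed, n = 60, beta1 = 633.8,
                                  beta0 = 276179, sigma = NULL,
                                  target_r2 = 0.6,
                                  area_range = c(50, 1500),
                                  group = "Veh") {
  withr::with_seed(seed_stream(seed, paste0("halo-records-", group)), {
    area <- stats::runif(n, area_range[1], area_range[2])
    if (is.null(sigma)) sigma <- sigma_for_r2(beta1, area, target_r2)
    y <- beta1 * area + beta0 + stats::rnorm(n, 0, sigma)
    d <- data.frame(group = group, area_um2 = area, halo_intensity = y)
    attr(d, "sigma") <- sigma
    d
  })
}

#' Generate a synthetic subgranular-zone scene with known counts
#'
#' Lays out an SGZ trace of the requested length, places DCX and BrdU somata
#' along it at the requested linear densities (within the SGZ band), and
#' constructs primary dendrites that cross the mid-GCL line and secondary
#' dendrites that cross the outer-GCL line, so the true laminar counts
#' (a, b, c) are known by construction.
#'
#' @param seed Integer seed.
#' @param length_mm SGZ trace length (default 2 mm).
#' @param pixel_size_um Pixel calibration (default 1 um/px).
#' @param amplitude_px Sine amplitude of the trace (0 gives a straight
#'   trace of exactly `length_mm`).
#' @param dcx_per_mm,brdu_per_mm Target linear densities.
#' @param primary_per_soma Primary dendrites per DCX soma (each crosses the
#'   mid-GCL line).
#' @param secondary_per_primary Secondary dendrites per primary (each
#'   crosses the outer-GCL line).
#' @return List with `scene` (an [sgz_scene()]) and `truth` (list: `a`,
#'   `b`, `c`, `dcx_density`, `brdu_density`, `arc_length_mm`).
#' @export
generate_sgz_scene <- function(seed, length_mm = 2, pixel_size_um = 1,
                               amplitude_px = 20, dcx_per_mm = 8,
                               brdu_per_mm = 4, primary_per_soma = 1,
                               secondary_per_primary = 2) {
  len_px <- length_mm * 1000 / pixel_size_um
  xs <- seq(0, len_px, by = 25)
  base_row <- 200
  if (amplitude_px > 0) {
    rows <- base_row + amplitude_px * sin(xs / 300)
    poly <- cbind(rows, 100 + xs)
    # rescale x-spacing so the arc length matches len_px
    raw_len <- polyline_arc_length(poly)
    poly[, 2] <- 100 + (poly[, 2] - 100) * (len_px / raw_len)
    # one more correction pass (sine row term unchanged)
    poly[, 2] <- 100 + (poly[, 2] - 100) *
      (len_px / polyline_arc_length(poly))
  } else {
    poly <- cbind(rep(base_row, length(xs)), 100 + xs)
  }
  mid <- poly; mid[, 1] <- mid[, 1] - 30 / pixel_size_um
  outer_l <- poly; outer_l[, 1] <- outer_l[, 1] - 60 / pixel_size_um
  arc_mm <- polyline_arc_length(poly) * pixel_size_um / 1000
  n_dcx <- round(dcx_per_mm * arc_mm)
  n_brdu <- round(brdu_per_mm * arc_mm)
  place_somata <- function(n, jitter_um) {
    if (n == 0) return(matrix(numeric(0), 0, 2))
    # arc-length-uniform stations along the trace
    seglen <- sqrt(rowSums((poly[-1, ] - poly[-nrow(poly), ])^2))
    cum <- c(0, cumsum(seglen))
    st <- (seq_len(n) - 0.5) / n * cum[length(cum)]
    t(vapply(st, function(s) {
      j <- findInterval(s, cum, rightmost.closed = TRUE)
      frac <- (s - cum[j]) / seglen[j]
      p <- poly[j, ] + frac * (poly[j + 1, ] - poly[j, ])
      p + c(stats::runif(1, -jitter_um, jitter_um) / pixel_size_um, 0)
    }, numeric(2)))
  }
  withr::with_seed(seed_stream(seed, "sgz"), {
    dcx <- place_somata(n_dcx, 5)
    brdu <- place_somata(n_brdu, 5)
    dendrites <- list()
    if (n_dcx > 0 && primary_per_soma > 0) {
      for (i in seq_len(n_dcx)) {
        for (p in seq_len(primary_per_soma)) {
          dx <- stats::runif(1, -8, 8)
          tip <- c(dcx[i, 1] - 42 / pixel_size_um, dcx[i, 2] + dx)
          dendrites[[length(dendrites) + 1]] <-
            list(path = rbind(dcx[i, ], tip), soma_id = i, order = "primary")
          if (secondary_per_primary > 0) {
            for (s in seq_len(secondary_per_primary)) {
              dx2 <- stats::runif(1, -12, 12)
              tip2 <- c(tip[1] - 33 / pixel_size_um, tip[2] + dx2)
              dendrites[[length(dendrites) + 1]] <-
                list(path = rbind(tip, tip2), soma_id = i,
                     order = "secondary")
            }
          }
        }
      }
    }
    scene <- sgz_scene(poly, mid, outer_l,
                       soma_positions = list(DCX = dcx, BrdU = brdu),
                       dendrite_paths = dendrites,
                       pixel_size_um = pixel_size_um)
    truth <- list(a = n_dcx, b = n_dcx * primary_per_soma,
                  c = n_dcx * primary_per_soma * secondary_per_primary,
                  dcx_density = n_dcx / arc_mm,
                  brdu_density = n_brdu / arc_mm, arc_length_mm = arc_mm)
    list(scene = scene, truth = truth)
  })
}

#' Rasterize an SGZ scene for visual QC
#'
#' Paints somata as small disks and dendrites/reference lines as thin
#' strokes into an 8-bit plane. Intended for eyeballing generated scenes;
#' quantification always runs on the vector annotations.
#'
#' @param scene An [sgz_scene()].
#' @param dims Canvas dimensions (rows, cols); default covers the scene.
#' @return An [image_plane()].
#' @export
rasterize_sgz_scene <- function(scene, dims = NULL) {
  pts <- rbind(scene$polyline, scene$mid_gcl_line, scene$outer_gcl_line)
  if (is.null(dims))
    dims <- c(ceiling(max(pts[, 1]) + 50), ceiling(max(pts[, 2]) + 50))
  px <- matrix(0, dims[1], dims[2])
  draw_line <- function(px, path, value) {
    for (i in seq_len(nrow(path) - 1)) {
      a <- path[i, ]; b <- path[i + 1, ]
      n <- max(2, ceiling(sqrt(sum((b - a)^2))))
      for (t in seq(0, 1, length.out = n)) {
        p <- round(a + t * (b - a))
        if (p[1] >= 1 && p[1] <= dims[1] && p[2] >= 1 && p[2] <= dims[2])
          px[p[1], p[2]] <- value
      }
    }
    px
  }
  px <- draw_line(px, scene$polyline, 60)
  px <- draw_line(px, scene$mid_gcl_line, 80)
  px <- draw_line(px, scene$outer_gcl_line, 100)
  for (d in scene$dendrite_paths) px <- draw_line(px, d$path, 150)
  for (m in names(scene$soma_positions)) {
    pos <- scene$soma_positions[[m]]
    for (i in seq_len(nrow(pos)))
      px <- stamp_disk(px, pos[i, 1], pos[i, 2], 3, 255)
  }
  image_plane(px, scene$pixel_size_um, "QC")
}

#' Generate gene fold and perturbagen score tables with known set structure
#'
#' Draws a long gene fold table (one row per gene and group) whose up/down
#' membership follows a designed Venn-region structure, plus a perturbagen
#' score table with known counts above any threshold.
#'
#' @param seed Integer seed.
#' @param groups Group labels (default D4, A1, S1, C1).
#' @param n_genes Total genes (must cover the designs).
#' @param up_design,down_design Named integer vectors: names are Venn region
#'   keys (group names joined by `&`), values are region sizes. Defaults
#'   mirror a screen with 6 triple-shared upregulated and 10 triple-shared
#'   downregulated genes among the treated groups.
#' @param n_scores Perturbagen entries per group and kind.
#' @return List with `folds` (data frame `gene`, `group`, `fold`), `scores`
#'   (data frame `name`, `kind`, `group`, `score`) and `truth` (list:
#'   `up_sets`, `down_sets` per group, `up_design`, `down_design`).
#' @export
generate_signature_tables <- function(
    seed, groups = c("D4", "A1", "S1", "C1"), n_genes = 200,
    up_design = c("D4" = 8, "A1" = 4, "S1" = 3, "C1" = 2, "D4&A1" = 3,
                  "D4&S1" = 2, "D4&C1" = 2, "D4&A1&S1" = 2, "D4&A1&C1" = 5,
                  "D4&S1&C1" = 2, "D4&A1&S1&C1" = 6),
    down_design = c("D4" = 5, "A1" = 2, "S1" = 2, "C1" = 2, "D4&A1" = 2,
                    "D4&S1" = 1, "D4&C1" = 1, "D4&A1&C1" = 2,
                    "D4&A1&S1&C1" = 10),
    n_scores = 25) {
  n_design <- sum(up_design) + sum(down_design)
  if (n_genes < n_design)
    stop("n_genes must cover the designed regions (need >= ", n_design, ")")
  genes <- sprintf("gene%04d", seq_len(n_genes))
  membership_up <- stats::setNames(vector("list", length(groups)), groups)
  membership_down <- membership_up
  idx <- 1
  assign_regions <- function(design, membership) {
    for (key in names(design)) {
      member_groups <- strsplit(key, "&", fixed = TRUE)[[1]]
      take <- genes[idx:(idx + design[[key]] - 1)]
      idx <<- idx + design[[key]]
      for (g in member_groups)
        membership[[g]] <- c(membership[[g]], take)
    }
    membership
  }
  membership_up <- assign_regions(up_design, membership_up)
  membership_down <- assign_regions(down_design, membership_down)
  withr::with_seed(seed_stream(seed, "signatures"), {
    folds <- do.call(rbind, lapply(groups, function(g) {
      fold <- stats::runif(n_genes, -1.9, 1.9)
      up <- genes %in% membership_up[[g]]
      dn <- genes %in% membership_down[[g]]
      fold[up] <- stats::runif(sum(up), 2, 4)
      fold[dn] <- -stats::runif(sum(dn), 2, 4)
      data.frame(gene = genes, group = g, fold = round(fold, 2))
    }))
    scores <- do.call(rbind, lapply(groups, function(g)
      do.call(rbind, lapply(c("PCL", "PC"), function(k)
        data.frame(name = sprintf("%s_%s_%02d", k, g, seq_len(n_scores)),
                   kind = k, group = g,
                   score = round(stats::runif(n_scores, -100, 100), 2))))))
    list(folds = folds, scores = scores,
         truth = list(up_sets = lapply(membership_up, sort),
                      down_sets = lapply(membership_down, sort),
                      up_design = up_design, down_design = down_design))
  })
}

#' Generate a synthetic metabolic cohort with ground truth
#'
#' Per-animal fasting glucose and insulin draws plus oral glucose tolerance
#' curves: glucose rises from baseline to a peak at 30 min and then decays
#' exponentially back toward baseline at a group-specific rate. A decay rate
#' of 0 emulates the impaired tolerance of metabolically stressed animals
#' (no return to baseline over the sampled window).
#'
#' @param seed Integer seed.
#' @param n_per_group Animals per group (default 6).
#' @param params Named list (one entry per group) of lists with
#'   `glucose_mean`, `glucose_sd`, `insulin_mean`, `insulin_sd`,
#'   `ogtt_peak`, `decay` (per-minute rate after the 30-min peak). The
#'   default design contrasts a normal-chow group with metabolically
#'   stressed groups that show elevated fasting values and no glycemic
#'   return to baseline.
#' @param times_min OGTT sampling times (default 0, 30, ..., 120).
#' @param noise_sd Measurement noise on OGTT points (default 0.4 mM).
#' @return List with `cohort` (data frame: `animal_id`, `group`,
#'   `fasting_glucose_mM`, `fasting_insulin_UmL`, `ogtt_<t>` columns) and
#'   `truth` (the parameter list).
#' @export
generate_metabolic_cohort <- function(
    seed, n_per_group = 6,
    params = list(
      NCD = list(glucose_mean = 5.5, glucose_sd = 0.5, insulin_mean = 4.5,
                 insulin_sd = 0.8, ogtt_peak = 14, decay = 0.035),
      HFSTZ = list(glucose_mean = 15, glucose_sd = 2, insulin_mean = 13,
                   insulin_sd = 2, ogtt_peak = 28, decay = 0)),
    times_min = seq(0, 120, by = 30), noise_sd = 0.4) {
  withr::with_seed(seed_stream(seed, "metabolic"), {
    rows <- list()
    for (g in names(params)) {
      p <- params[[g]]
      for (i in seq_len(n_per_group)) {
        glu <- max(stats::rnorm(1, p$glucose_mean, p$glucose_sd), 0.5)
        ins <- max(stats::rnorm(1, p$insulin_mean, p$insulin_sd), 0.1)
        curve <- vapply(times_min, function(t) {
          v <- if (t <= 30) glu + (p$ogtt_peak - glu) * t / 30
               else glu + (p$ogtt_peak - glu) * exp(-p$decay * (t - 30))
          max(v + stats::rnorm(1, 0, noise_sd), 0.5)
        }, numeric(1))
        row <- data.frame(animal_id = sprintf("%s_%02d", g, i), group = g,
                          fasting_glucose_mM = glu,
                          fasting_insulin_UmL = ins)
        row[paste0("ogtt_", times_min)] <- as.list(curve)
        rows[[length(rows) + 1]] <- row
      }
    }
    list(cohort = do.call(rbind, rows), truth = params)
  })
}
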