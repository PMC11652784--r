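# Independent geometry oracles used to cross-check the package's hull and
# Feret computations. These deliberately use different algorithms than the
# implementation (gift wrapping vs chull; all-corner brute force and
# rotating calipers vs all-pairs on hull vertices).

all_pixel_corners <- function(coords) {
  r <- coords[, 1]; c <- coords[, 2]
  unique(cbind(x = c(c - 1, c, c - 1, c), y = c(r - 1, r - 1, r, r)))
}

# brute-force Feret: max pairwise distance over every pixel corner
oracle_feret_bruteforce <- function(coords) {
  pts <- all_pixel_corners(coords)
  if (nrow(pts) < 2) return(0)
  max(dist(pts))
}

# Jarvis-march (gift wrapping) convex hull, counter-clockwise
oracle_gift_wrap_hull <- function(pts) {
  pts <- unique(pts)
  n <- nrow(pts)
  if (n < 3) return(pts)
  cross <- function(o, a, b)
    (a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1])
  start <- which.min(pts[, 1] + pts[, 2] * 1e-9)
  hull <- integer(0)
  p <- start
  repeat {
    hull <- c(hull, p)
    q <- if (p == n) 1L else p + 1L
    for (i in seq_len(n)) {
      cr <- cross(pts[p, ], pts[i, ], pts[q, ])
      if (cr < 0 ||
          (cr == 0 && sum((pts[i, ] - pts[p, ])^2) >
             sum((pts[q, ] - pts[p, ])^2))) q <- i
    }
    p <- q
    if (p == start) break
  }
  pts[hull, , drop = FALSE]
}

oracle_hull_area <- function(coords) {
  hull <- oracle_gift_wrap_hull(all_pixel_corners(coords))
  x <- hull[, 1]; y <- hull[, 2]
  n <- nrow(hull); j <- c(2:n, 1)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

# rotating-calipers diameter of a convex polygon (antipodal pairs)
rotating_calipers_feret <- function(hull) {
  p <- unique(hull)
  n <- nrow(p)
  if (n < 2) return(0)
  if (n == 2) return(sqrt(sum((p[1, ] - p[2, ])^2)))
  # ensure counter-clockwise order
  x <- p[, 1]; y <- p[, 2]; j <- c(2:n, 1)
  if (sum(x * y[j] - x[j] * y) < 0) p <- p[n:1, , drop = FALSE]
  area2 <- function(a, b, c)
    abs((b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1]))
  d2 <- function(a, b) sum((a - b)^2)
  k <- 2L
  best <- 0
  for (i in seq_len(n)) {
    jj <- i %% n + 1L
    repeat {
      knext <- k %% n + 1L
      if (area2(p[i, ], p[jj, ], p[knext, ]) >
          area2(p[i, ], p[jj, ], p[k, ])) k <- knext else break
    }
    best <- max(best, d2(p[i, ], p[k, ]), d2(p[jj, ], p[k, ]))
  }
  sqrt(best)
}

# connected random blob mask: pixels visited by a seeded random walk
random_walk_coords <- function(n_steps, size = 40) {
  pos <- c(size %/% 2, size %/% 2)
  coords <- matrix(pos, 1, 2)
  for (i in seq_len(n_steps)) {
    step <- sample(list(c(0, 1), c(0, -1), c(1, 0), c(-1, 0),
                        c(1, 1), c(-1, -1), c(1, -1), c(-1, 1)), 1)[[1]]
    pos <- pmin(pmax(pos + step, 2), size - 1)
    coords <- rbind(coords, pos)
  }
  unique(coords)
}

disk_coords <- function(r) {
  n <- 2 * r + 4
  g <- expand.grid(row = 1:n, col = 1:n)
  c0 <- r + 2
  as.matrix(g[(g$row - 0.5 - c0)^2 + (g$col - 0.5 - c0)^2 <= r^2, ])
}

rect_coords <- function(h, w, r0 = 3, c0 = 3) {
  as.matrix(expand.grid(row = r0:(r0 + h - 1), col = c0:(c0 + w - 1)))
}

plus_sign_coords <- function() {
  # two 21x3 bars crossing at the center (117 px)
  horiz <- expand.grid(row = 11:13, col = 2:22)
  vert <- expand.grid(row = 2:22, col = 11:13)
  as.matrix(unique(rbind(horiz, vert)))
}

# independent segment-intersection primitive: parametric 2x2 solve
oracle_segments_intersect <- function(p1, p2, q1, q2, tol = 1e-12) {
  d1 <- p2 - p1; d2 <- q2 - q1
  den <- d1[1] * d2[2] - d1[2] * d2[1]
  if (abs(den) < tol) {
    # parallel: check collinear overlap by projection
    cr <- (q1[1] - p1[1]) * d1[2] - (q1[2] - p1[2]) * d1[1]
    if (abs(cr) > tol) return(FALSE)
    L <- sum(d1^2)
    if (L < tol) return(all(abs(p1 - q1) < tol))
    t1 <- sum((q1 - p1) * d1) / L
    t2 <- sum((q2 - p1) * d1) / L
    return(max(min(t1, t2), 0) <= min(max(t1, t2), 1))
  }
  t <- ((q1[1] - p1[1]) * d2[2] - (q1[2] - p1[2]) * d2[1]) / den
  u <- ((q1[1] - p1[1]) * d1[2] - (q1[2] - p1[2]) * d1[1]) / den
  t >= -tol && t <= 1 + tol && u >= -tol && u <= 1 + tol
}

oracle_path_crosses <- function(path, line) {
  for (i in seq_len(nrow(path) - 1))
    for (j in seq_len(nrow(line) - 1))
      if (oracle_segments_intersect(path[i, ], path[i + 1, ],
                                    line[j, ], line[j + 1, ])) return(TRUE)
  FALSE
}
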