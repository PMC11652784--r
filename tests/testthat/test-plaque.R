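test_that("plaque detection assigns 8x-Feret neighborhoods", {
  blank <- image_plane(matrix(0, 64, 64), 1)
  expect_equal(nrow(detect_plaques(blank)), 0)

  px <- matrix(0, 100, 100)
  px[40:49, 40:49] <- 200
  pl <- detect_plaques(image_plane(px, 1))
  expect_equal(nrow(pl), 1)
  expect_equal(pl$feret_um, 10 * sqrt(2), tolerance = 1e-12)
  expect_equal(pl$neighborhood_radius_um, 4 * 10 * sqrt(2), tolerance = 1e-12)
  expect_equal(pl$area_um2, 100)
})

test_that("plaque threshold boundary at 20 is inclusive", {
  px <- matrix(0, 40, 40)
  px[5:10, 5:10] <- 20
  px[25:30, 25:30] <- 19
  pl <- detect_plaques(image_plane(px, 1), low = 20)
  expect_equal(nrow(pl), 1)
})

test_that("overlap exclusion flags both members, symmetrically", {
  mk <- function(r1, c1, r2, c2, feret = 10) data.frame(
    plaque_id = 1:2, area_um2 = 100, feret_um = feret,
    centroid_row = c(r1, r2), centroid_col = c(c1, c2),
    neighborhood_radius_um = 4 * feret, excluded = FALSE)

  far <- exclude_overlaps(mk(10, 10, 10, 200))
  expect_false(any(far$excluded))

  coincident <- exclude_overlaps(mk(50, 50, 50, 50))
  expect_true(all(coincident$excluded))
})

test_that("exclusion is idempotent, order-independent, and survivors are disjoint", {
  withr::with_seed(23, {
    for (rep in 1:20) {
      n <- sample(3:12, 1)
      pl <- data.frame(plaque_id = seq_len(n), area_um2 = 100,
                       feret_um = stats::runif(n, 5, 20),
                       centroid_row = stats::runif(n, 0, 400),
                       centroid_col = stats::runif(n, 0, 400),
                       excluded = FALSE)
      pl$neighborhood_radius_um <- 4 * pl$feret_um
      once <- exclude_overlaps(pl)
      twice <- exclude_overlaps(once)
      expect_identical(once$excluded, twice$excluded)

      perm <- sample(n)
      shuffled <- exclude_overlaps(pl[perm, ])
      expect_identical(shuffled$excluded[order(perm)], once$excluded)

      surv <- once[!once$excluded, ]
      if (nrow(surv) >= 2) {
        for (i in 1:(nrow(surv) - 1)) for (j in (i + 1):nrow(surv)) {
          d <- sqrt((surv$centroid_row[i] - surv$centroid_row[j])^2 +
                      (surv$centroid_col[i] - surv$centroid_col[j])^2)
          expect_gt(d, surv$neighborhood_radius_um[i] +
                      surv$neighborhood_radius_um[j])
        }
      }
    }
  })
})

test_that("halo intensity does the documented arithmetic", {
  pl <- data.frame(plaque_id = 1, centroid_row = 50, centroid_col = 50,
                   neighborhood_radius_um = 20, excluded = FALSE)
  bg_region <- matrix(FALSE, 100, 100); bg_region[90:99, 90:99] <- TRUE

  # channel uniformly at the background mean: nothing above background
  uni <- image_plane(matrix(130, 100, 100), 1)
  expect_equal(halo_intensity(uni, pl, bg_region), 0)

  # disk at 130, background at 30: 100 per disk pixel
  disk <- disk_mask(c(100, 100), 50, 50, 20, 1)
  px <- matrix(30, 100, 100); px[disk] <- 130
  expect_equal(halo_intensity(image_plane(px, 1), pl, bg_region),
               100 * sum(disk))

  # pixels below the intensity threshold never contribute
  px2 <- matrix(0, 100, 100); px2[disk] <- 29
  expect_equal(halo_intensity(image_plane(px2, 1), pl, bg_region), 0)

  pl_ex <- pl; pl_ex$excluded <- TRUE
  expect_error(halo_intensity(uni, pl_ex, bg_region), "excluded")
  expect_error(halo_intensity(uni, pl, matrix(FALSE, 100, 100)), "empty")
})

test_that("halo intensity is monotone in pixel intensity", {
  pl <- data.frame(plaque_id = 1, centroid_row = 30, centroid_col = 30,
                   neighborhood_radius_um = 10, excluded = FALSE)
  bg <- matrix(FALSE, 60, 60); bg[55:59, 55:59] <- TRUE
  px <- matrix(10, 60, 60)
  px[25:35, 25:35] <- 120
  base <- halo_intensity(image_plane(px, 1), pl, bg)
  px[30, 30] <- 200
  expect_gt(halo_intensity(image_plane(px, 1), pl, bg), base)
})

test_that("neighborhood disk area matches pi (4 Feret)^2 within 2%", {
  for (feret in c(8, 15, 30)) {
    r <- 4 * feret
    m <- disk_mask(c(400, 400), 200, 200, r, 1)
    expect_lt(abs(sum(m) - pi * r^2) / (pi * r^2), 0.02)
  }
})

test_that("regression on exact and degenerate inputs behaves", {
  d <- data.frame(area_um2 = c(1, 2, 3, 4), halo_intensity = c(7, 9, 11, 13))
  fit <- regress_intensity_on_area(d)
  expect_equal(fit$slope, 2)
  expect_equal(fit$intercept, 5)
  expect_equal(fit$r_squared, 1)

  const <- data.frame(area_um2 = 1:5, halo_intensity = 3)
  fit0 <- regress_intensity_on_area(const)
  expect_equal(fit0$slope, 0)
  expect_equal(fit0$r_squared, 0)

  expect_error(regress_intensity_on_area(d[1:2, ]), "at least 3")
  expect_error(regress_intensity_on_area(
    data.frame(area_um2 = rep(2, 5), halo_intensity = 1:5)), "variance")
})

test_that("slope comparison is exact on duplicated groups and well powered", {
  a <- generate_halo_records(301, group = "Veh")
  dup <- a; dup$group <- "Copy"
  cmp <- compare_slopes(rbind(a, dup), reference = "Veh")
  expect_equal(cmp$slope_difference, 0)

  expect_error(compare_slopes(a, reference = "HE"), "reference")

  # strong slope contrast (633.8 vs 191.5) detected at p < 0.01 in >= 90%
  hits <- vapply(1:100, function(i) {
    v <- generate_halo_records(3000 + i, group = "Veh")
    h <- generate_halo_records(70000 + i, group = "HE", beta1 = 191.5,
                               beta0 = 105632, sigma = attr(v, "sigma"))
    compare_slopes(rbind(v, h), reference = "Veh")$p_value < 0.01
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("fitted slope bias stays small under moderate noise", {
  # moderate noise: sigma = 0.25 * beta1 * sd(area) (expected R^2 ~ 0.94)
  bias <- vapply(1:100, function(i) {
    d <- generate_halo_records(4000 + i, sigma = 0.25 * 633.8 * 420)
    abs(regress_intensity_on_area(d)$slope - 633.8) / 633.8
  }, numeric(1))
  expect_lt(mean(bias), 0.05)
})

test_that("plaque and glial cluster counting respects neighborhoods", {
  blankset <- lapply(c("ThS", "GFAP", "Iba1"), function(ch)
    image_plane(matrix(0, 64, 64), 1, ch))
  out <- count_plaques_and_clusters(blankset[[1]], blankset[[2]],
                                    blankset[[3]])
  expect_equal(unlist(out, use.names = FALSE), c(0, 0, 0))

  # one plaque, one glial blob inside its disk, one far outside
  pp <- matrix(0, 200, 200); pp[95:104, 95:104] <- 200
  gf <- matrix(0, 200, 200)
  gf[110:117, 110:117] <- 200    # inside the ~56 um neighborhood
  gf[5:12, 180:187] <- 200       # outside every neighborhood
  out2 <- count_plaques_and_clusters(
    image_plane(pp, 1, "ThS"), image_plane(gf, 1, "GFAP"),
    image_plane(gf, 1, "Iba1"))
  expect_equal(out2$plaques, 1)
  expect_equal(out2$gfap_clusters, 1)
  expect_equal(out2$iba1_clusters, 1)

  expect_error(count_plaques_and_clusters(
    image_plane(pp, 1), image_plane(matrix(0, 10, 10), 1),
    image_plane(gf, 1)), "dimensions")
})
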