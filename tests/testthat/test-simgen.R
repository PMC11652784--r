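test_that("generators are deterministic given a seed", {
  a <- generate_microglia_scene(3, n_cells = 4)
  b <- generate_microglia_scene(3, n_cells = 4)
  expect_identical(a$image$pixels, b$image$pixels)
  expect_identical(a$truth, b$truth)
  expect_false(identical(
    generate_microglia_scene(4, n_cells = 4)$image$pixels, a$image$pixels))

  s1 <- generate_signature_tables(5)
  s2 <- generate_signature_tables(5)
  expect_identical(s1$folds, s2$folds)

  m1 <- generate_metabolic_cohort(5)
  m2 <- generate_metabolic_cohort(5)
  expect_identical(m1$cohort, m2$cohort)
})

test_that("microglia scenes segment into the designed number of cells", {
  sc <- generate_microglia_scene(19, n_cells = 6)
  recs <- score_scene(sc$image, "g")
  expect_equal(nrow(recs), 6)

  # soma-only mode yields compact, near-convex cells
  sc0 <- generate_microglia_scene(19, n_cells = 6, n_branches = 0)
  r0 <- score_scene(sc0$image, "g")
  expect_equal(nrow(r0), 6)
  expect_gt(min(r0$form_factor), 0.9)
  expect_gt(mean(r0$form_factor), mean(recs$form_factor))
})

test_that("infeasible packings error out explicitly", {
  expect_error(generate_microglia_scene(1, n_cells = 100,
                                        image_size_px = 128),
               "infeasible packing")
})

test_that("branch growth lowers and activation raises the form factor", {
  ffs <- vapply(c(10, 30, 60), function(L) {
    sc <- generate_microglia_scene(7, n_cells = 5, image_size_px = 1024,
                                   branch_length_um = L)
    mean(score_scene(sc$image, "g")$form_factor)
  }, numeric(1))
  expect_true(all(diff(ffs) < 0))

  rest <- generate_microglia_scene(8, n_cells = 5, image_size_px = 1024,
                                   branch_length_um = 40)
  act <- generate_microglia_scene(8, n_cells = 5, image_size_px = 1024,
                                  branch_length_um = 40, activation = 0.75)
  expect_gt(mean(score_scene(act$image, "g")$form_factor),
            mean(score_scene(rest$image, "g")$form_factor))
})

test_that("noiseless plaque scenes store self-consistent truth", {
  sc <- generate_plaque_scene(13, n_plaques = 5, sigma = 0)
  expect_equal(sc$truth$expected_halo,
               633.8 * sc$truth$area_um2 + 276179)
  halos <- measure_halos(sc$plaque, sc$iba1)
  expect_equal(nrow(halos), 5)
  expect_false(any(halos$excluded))
  # match measured plaques to truth by centroid
  ord <- vapply(seq_len(5), function(i)
    which.min((halos$centroid_row - sc$truth$center_row[i])^2 +
                (halos$centroid_col - sc$truth$center_col[i])^2), integer(1))
  m <- halos[ord, ]
  expect_equal(m$area_um2, sc$truth$area_um2)
  # painted halo equals the target up to the 8-bit remainder pixel
  expect_lt(max(abs(m$halo_intensity - sc$truth$target_halo)), 2)
  expect_gt(stats::cor(m$halo_intensity, sc$truth$target_halo), 0.95)
})

test_that("plaques forced together are flagged by the exclusion rule", {
  centers <- rbind(c(300, 300), c(300, 360), c(300, 800))
  sc <- generate_plaque_scene(17, n_plaques = 3, sigma = 0,
                              centers = centers)
  pl <- exclude_overlaps(detect_plaques(sc$plaque))
  expect_equal(sum(pl$excluded), 2)
})

test_that("a zero-slope halo law is not mistaken for area dependence", {
  hits <- vapply(1:200, function(i) {
    d <- generate_halo_records(5000 + i, beta1 = 0, beta0 = 276179,
                               sigma = 30000)
    ci <- stats::confint(regress_intensity_on_area(d)$fit)["area_um2", ]
    ci[1] <= 0 && 0 <= ci[2]
  }, logical(1))
  expect_gt(mean(hits), 0.9)
  expect_lt(mean(hits), 1)
})

test_that("SGZ scenes recover their designed counts and densities", {
  g <- generate_sgz_scene(23, dcx_per_mm = 12, brdu_per_mm = 4,
                          primary_per_soma = 1, secondary_per_primary = 2)
  lc <- laminar_counts(g$scene)
  expect_equal(c(lc$a, lc$b, lc$c), c(g$truth$a, g$truth$b, g$truth$c))
  expect_equal(dendrite_ratios(lc)$sprouting, 1)
  expect_equal(dendrite_ratios(lc)$branching, 2)

  # straight trace of exactly 2 mm: densities are exact
  flat <- generate_sgz_scene(29, amplitude_px = 0, dcx_per_mm = 5)
  expect_equal(flat$truth$arc_length_mm, 2)
  expect_equal(nrow(flat$scene$soma_positions$DCX), 10)
  expect_equal(linear_density(flat$scene$soma_positions$DCX,
                              flat$scene$polyline, 1), 5)

  none <- generate_sgz_scene(31, primary_per_soma = 0)
  lc0 <- laminar_counts(none$scene)
  expect_equal(c(lc0$b, lc0$c), c(0L, 0L))

  qc <- rasterize_sgz_scene(g$scene)
  expect_s3_class(qc, "ImagePlane")
  expect_gt(max(qc$pixels), 0)
})

test_that("signature tables realize their designed set structure", {
  st <- generate_signature_tables(37)
  out <- filter_by_fold(st$folds)
  expect_identical(out$up, st$truth$up_sets)
  expect_identical(out$down, st$truth$down_sets)

  venn <- intersect_sets(out$up)
  expect_equal(intersection_size(venn, c("A1", "S1", "C1")),
               unname(st$truth$up_design["D4&A1&S1&C1"]))

  # all folds inside (-2, 2): nothing passes
  quiet <- st$folds
  quiet$fold <- pmin(pmax(quiet$fold, -1.9), 1.9)
  empty <- filter_by_fold(quiet)
  expect_true(all(lengths(empty$up) == 0))
  expect_true(all(lengths(empty$down) == 0))

  # threshold sweep on the score table is monotone against truth
  prev <- Inf
  for (thr in c(-100, -50, 0, 50, 90, 100)) {
    n <- nrow(filter_scores(st$scores, thr)$entries)
    expect_equal(n, sum(st$scores$score > thr))
    expect_lte(n, prev)
    prev <- n
  }
})

test_that("metabolic cohorts reflect their generating parameters", {
  mc <- generate_metabolic_cohort(43)
  sm <- summarize_metabolic(mc$cohort)

  # cohort-mean HOMA-IR is consistent with the true group parameters
  for (g in names(mc$truth)) {
    p <- mc$truth[[g]]
    expected <- homa_ir(p$glucose_mean, p$insulin_mean)
    row <- sm$groups[sm$groups$group == g, ]
    expect_lt(abs(row$homa_ir_mean - expected),
              4 * row$homa_ir_sem + 0.5)
  }

  # zero decay: terminal glucose stays near the peak (no return to baseline)
  ogtt_cols <- grep("^ogtt_", names(mc$cohort), value = TRUE)
  hf <- mc$cohort[mc$cohort$group == "HFSTZ", ]
  expect_gt(mean(hf[[ogtt_cols[length(ogtt_cols)]]]),
            0.9 * mc$truth$HFSTZ$ogtt_peak)
  ncd <- mc$cohort[mc$cohort$group == "NCD", ]
  expect_lt(mean(ncd[[ogtt_cols[length(ogtt_cols)]]]),
            0.6 * mc$truth$NCD$ogtt_peak)
})
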