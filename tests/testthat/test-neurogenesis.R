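test_that("linear density counts banded cells per mm of trace", {
  trace <- cbind(rep(100, 2), c(0, 2000))          # straight 2 mm at 1 um/px
  cells <- cbind(rep(102, 10), seq(100, 1900, length.out = 10))
  expect_equal(linear_density(cells, trace, 1), 5.0)
  expect_equal(linear_density(matrix(numeric(0), 0, 2), trace, 1), 0)

  # cells beyond the band are not counted
  far <- rbind(cells, c(160, 1000))
  expect_equal(linear_density(far, trace, 1, band_um = 20), 5.0)
  expect_equal(linear_density(far, trace, 1, band_um = 100), 5.5)

  expect_error(linear_density(cells, cbind(c(1, 1), c(5, 5)), 1), "zero")
})

test_that("linear density is invariant to trace re-parameterization", {
  trace <- cbind(c(50, 80, 60), c(0, 800, 2000))
  withr::with_seed(31, {
    cells <- cbind(stats::runif(20, 40, 90), stats::runif(20, 0, 2000))
  })
  dense <- do.call(rbind, lapply(seq_len(nrow(trace) - 1), function(i) {
    t <- seq(0, 1, length.out = 9)[-9]
    outer(t, trace[i + 1, ] - trace[i, ]) + rep(1, 8) %o% trace[i, ]
  }))
  dense <- rbind(dense, trace[nrow(trace), ])
  expect_equal(linear_density(cells, trace, 1),
               linear_density(cells, dense, 1))
})

test_that("laminar counts follow the a/b/c crossing rules", {
  mid <- cbind(c(70, 70), c(0, 500))
  outer_l <- cbind(c(40, 40), c(0, 500))
  sgz <- cbind(c(100, 100), c(0, 500))
  somata <- cbind(rep(95, 10), seq(50, 450, length.out = 10))
  dend <- list()
  for (i in 1:10) {
    tip <- c(60, somata[i, 2])
    dend[[length(dend) + 1]] <- list(path = rbind(somata[i, ], tip),
                                     soma_id = i, order = "primary")
    for (s in 1:2)
      dend[[length(dend) + 1]] <- list(
        path = rbind(tip, c(30, somata[i, 2] + 5 * s)),
        soma_id = i, order = "secondary")
  }
  scene <- sgz_scene(sgz, mid, outer_l, list(DCX = somata), dend)
  lc <- laminar_counts(scene)
  expect_equal(c(lc$a, lc$b, lc$c), c(10L, 10L, 20L))
  rat <- dendrite_ratios(lc)
  expect_equal(rat$sprouting, 1.0)
  expect_equal(rat$branching, 2.0)

  # no dendrites: b = c = 0, branching undefined
  bare <- sgz_scene(sgz, mid, outer_l, list(DCX = somata), list())
  lc0 <- laminar_counts(bare)
  expect_equal(c(lc0$a, lc0$b, lc0$c), c(10L, 0L, 0L))
  expect_equal(dendrite_ratios(lc0)$sprouting, 0)
  expect_true(is.na(dendrite_ratios(lc0)$branching))
})

test_that("a path crossing a line several times still counts once", {
  mid <- cbind(c(50, 50), c(0, 100))
  zigzag <- cbind(c(60, 40, 60, 40), c(10, 20, 30, 40))
  scene <- sgz_scene(cbind(c(80, 80), c(0, 100)), mid,
                     cbind(c(20, 20), c(0, 100)),
                     list(DCX = cbind(60, 10)),
                     list(list(path = zigzag, soma_id = 1,
                               order = "primary")))
  expect_equal(laminar_counts(scene)$b, 1L)
})

test_that("counts are invariant to path direction reversal", {
  g <- generate_sgz_scene(41, dcx_per_mm = 5)
  lc <- laminar_counts(g$scene)
  rev_scene <- g$scene
  rev_scene$dendrite_paths <- lapply(rev_scene$dendrite_paths, function(d) {
    d$path <- d$path[nrow(d$path):1, , drop = FALSE]
    d
  })
  lc_rev <- laminar_counts(rev_scene)
  expect_equal(lc, lc_rev)
})

test_that("crossing detection agrees with an independent intersection oracle", {
  withr::with_seed(53, {
    for (i in 1:200) {
      line <- cbind(stats::runif(3, 0, 100), c(0, 50, 100))
      path <- cbind(stats::runif(4, 0, 100), sort(stats::runif(4, 0, 100)))
      expect_equal(path_crosses_line(path, line),
                   oracle_path_crosses(path, line))
    }
  })
})

test_that("dendrite ratios are exact rationals with undefined-denominator guards", {
  expect_equal(unlist(dendrite_ratios(list(a = 10, b = 20, c = 30))),
               c(sprouting = 2.0, branching = 1.5))
  expect_equal(unlist(dendrite_ratios(list(a = 5, b = 5, c = 5))),
               c(sprouting = 1.0, branching = 1.0))
  und <- dendrite_ratios(list(a = 0, b = 0, c = 0))
  expect_true(is.na(und$sprouting))
  expect_true(is.na(und$branching))
})

test_that("doubling every structure doubles counts and preserves ratios", {
  g <- generate_sgz_scene(61, dcx_per_mm = 6)
  lc <- laminar_counts(g$scene)
  doubled <- g$scene
  shift <- function(m, dr) {
    m[, 1] <- m[, 1] + dr
    m
  }
  doubled$soma_positions$DCX <- rbind(doubled$soma_positions$DCX,
                                      shift(doubled$soma_positions$DCX, 1))
  doubled$dendrite_paths <- c(
    doubled$dendrite_paths,
    lapply(doubled$dendrite_paths, function(d) {
      d$path <- shift(d$path, 1)
      d
    }))
  lc2 <- laminar_counts(doubled)
  expect_equal(c(lc2$a, lc2$b, lc2$c), 2 * c(lc$a, lc$b, lc$c))
  expect_equal(dendrite_ratios(lc2), dendrite_ratios(lc))
})

test_that("scene JSON round trip preserves quantification", {
  g <- generate_sgz_scene(71)
  f <- withr::local_tempfile(fileext = ".json")
  write_sgz_scene(g$scene, f)
  back <- read_sgz_scene(f)
  expect_equal(laminar_counts(back), laminar_counts(g$scene))
  expect_equal(
    linear_density(back$soma_positions$DCX, back$polyline, 1),
    linear_density(g$scene$soma_positions$DCX, g$scene$polyline, 1))
})
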