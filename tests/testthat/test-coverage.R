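test_that("point-in-window tests follow the half-open m/z convention", {
  full <- build_scheme(c(300, 1200), scan_area(0.9, 0.9, 1.1, 1.1), 1, 1)
  inside <- data.frame(mz = c(300, 700, 1200), im = c(0.6, 1.0, 1.5))
  expect_true(all(is_covered(inside, full)))
  expect_false(is_covered(data.frame(mz = 250, im = 1.0), full))
  expect_false(is_covered(data.frame(mz = 700, im = 1.6), full))

  # hand-computed 2-scan x 2-window scheme (flat area, midline at 1.0):
  # windows: scan1 {[1000,1200) x [1.0,1.5], [600,800) x [0.6,1.0]}
  #          scan2 {[800,1000) x [1.0,1.5], [400,600) x [0.6,1.0]}
  s <- build_scheme(c(400, 600, 800, 1000, 1200),
                    scan_area(0.7, 0.7, 1.3, 1.3), 2, 2,
                    im_range = c(0.6, 1.5))
  pts <- data.frame(
    mz = c(1100, 1100, 650, 450, 1200),
    im = c(1.2, 0.8, 0.8, 1.2, 1.5)
  )
  expect_equal(is_covered(pts, s), c(TRUE, FALSE, TRUE, FALSE, TRUE))

  # a precursor on a shared interior edge belongs to the higher bin, once
  edge_pt <- data.frame(mz = 800, im = 1.2, charge = 2L,
                        intensity = 1, sequence = NA, is_phospho = FALSE)
  rep <- coverage_report(new_spectral_library(edge_pt), s)
  expect_equal(rep$covered_fraction, 1)
  expect_equal(sum(rep$per_window_counts), 1L)
  hit <- which(rep$per_window_counts == 1L)
  expect_equal(s$windows$mz_start[hit], 800)
})

test_that("coverage reports count fractions, windows and uncovered marginals", {
  one_window <- build_scheme(c(500, 700), scan_area(0.9, 0.9, 1.1, 1.1), 1, 1,
                             im_range = c(0.8, 1.2))
  inside <- new_spectral_library(data.frame(
    mz = runif(50, 510, 690), im = runif(50, 0.85, 1.15),
    charge = rep(2:4, length.out = 50)
  ))
  r <- coverage_report(inside, one_window)
  expect_equal(r$covered_fraction, 1.0)
  expect_equal(r$per_window_counts, 50L)
  expect_true(all(r$per_charge_fraction == 1))

  # shrink the window's IM interval above every precursor: nothing covered
  narrow <- one_window
  narrow$windows$im_low <- 1.16
  outside <- new_spectral_library(data.frame(
    mz = runif(30, 510, 690), im = runif(30, 0.85, 1.15), charge = 2L
  ))
  r2 <- coverage_report(outside, narrow)
  expect_equal(r2$covered_fraction, 0)
  expect_equal(sum(r2$uncovered_mz_histogram$count), r2$n_precursors)
  expect_equal(sum(r2$uncovered_im_histogram$count), r2$n_precursors)

  empty <- new_spectral_library(data.frame(
    mz = numeric(0), im = numeric(0), charge = integer(0)
  ))
  expect_error(coverage_report(empty, one_window), "empty library")
})

test_that("vectorized coverage equals the naive per-record loop", {
  set.seed(3)
  fixtures <- list(
    list(lib = proteome_library(500, seed = 2),
         scheme = build_scheme(equidistant_bin_edges(c(300, 1200), 24),
                               recovery_area(), 12, 2)),
    list(lib = proteome_library(400, seed = 3),
         scheme = build_scheme(equidistant_bin_edges(c(300, 1200), 8),
                               scan_area(0.6, 0.6, 1.5, 1.5), 8, 1)),
    list(lib = recovery_library(300, seed = 4),
         scheme = build_scheme(c(300, 500, 800, 1000, 1100, 1150, 1200),
                               scan_area(0.7, 0.9, 1.0, 1.4), 3, 2)),
    list(lib = generate_library(cloud_model(phospho = TRUE, seed = 5), 300),
         scheme = build_scheme(equidistant_bin_edges(c(400, 1400), 16),
                               scan_area(0.8, 1.0, 1.1, 1.4), 8, 2,
                               im_range = c(0.6, 1.5))),
    list(lib = new_spectral_library(data.frame(
           mz = c(300, 600, 600.0001, 900, 1200), im = c(0.6, 1.0, 1.0, 1.2, 1.5),
           charge = 2L)),
         scheme = build_scheme(c(300, 600, 900, 1200),
                               scan_area(0.7, 0.8, 1.2, 1.3), 3, 1))
  )
  for (f in fixtures) {
    expect_identical(is_covered(f$lib, f$scheme), naive_covered(f$lib, f$scheme))
  }
})

test_that("enlarging a window's IM interval never decreases coverage", {
  lib <- proteome_library(800, seed = 12)
  scheme <- build_scheme(equidistant_bin_edges(c(300, 1200), 12),
                         scan_area(0.8, 1.0, 1.0, 1.2), 6, 2)
  base <- mean(is_covered(lib, scheme))
  set.seed(9)
  for (i in 1:10) {
    grown <- scheme
    j <- sample(nrow(grown$windows), 1)
    grown$windows$im_low[j] <- max(0.6, grown$windows$im_low[j] - runif(1, 0, 0.2))
    grown$windows$im_high[j] <- min(1.5, grown$windows$im_high[j] + runif(1, 0, 0.2))
    expect_gte(mean(is_covered(lib, grown)), base)
  }
})

test_that("per-window balance summarizes count spread", {
  mk <- function(counts) {
    structure(list(per_window_counts = counts), class = "coverage_report")
  }
  expect_equal(per_window_balance(mk(c(2, 2, 2, 2)))$max_over_mean, 1.0)
  expect_equal(per_window_balance(mk(c(0, 4)))$max_over_mean, 2.0)

  # equal-density windows spread counts far more evenly than equidistant
  lib <- proteome_library(10000, seed = 1)
  flib <- filter_precursors(lib)
  full <- scan_area(0.6, 0.6, 1.5, 1.5)
  dens <- build_scheme(equal_density_bin_edges(flib, 24, c(300, 1200)),
                       full, 24, 1)
  dist <- build_scheme(equidistant_bin_edges(c(300, 1200), 24), full, 24, 1)
  b_dens <- per_window_balance(coverage_report(flib, dens))
  b_dist <- per_window_balance(coverage_report(flib, dist))
  expect_lte(b_dens$max - b_dens$min, 1L)
  expect_lt(b_dens$max - b_dens$min, b_dist$max - b_dist$min)
})

test_that("coverage reports export as flat TSV", {
  lib <- proteome_library(300, seed = 2)
  s <- build_scheme(equidistant_bin_edges(c(300, 1200), 8),
                    scan_area(0.6, 0.6, 1.5, 1.5), 8, 1)
  r <- coverage_report(lib, s, intensity_weighted = TRUE)
  path <- tempfile(fileext = ".tsv")
  write_coverage_report(r, path)
  tab <- read.delim(path, header = FALSE)
  expect_equal(as.numeric(tab$V2[tab$V1 == "covered_fraction"]),
               r$covered_fraction, tolerance = 1e-6)
  expect_equal(sum(as.integer(tab$V2[grepl("^window_", tab$V1)])),
               sum(r$per_window_counts))
})
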