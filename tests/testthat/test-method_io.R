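test_that("method files carry one pasef row per window and ms1 rows per cycle", {
  lib <- proteome_library(2000, seed = 1)
  flib <- filter_precursors(lib)
  scheme <- build_scheme(equal_density_bin_edges(flib, 24, c(300, 1200)),
                         recovery_area(), 12, 2)
  path <- tempfile(fileext = ".txt")
  write_method_file(scheme, path)
  lines <- readLines(path)
  body <- lines[!grepl("^#", lines)][-1]
  expect_equal(sum(grepl("^pasef,", body)), 24)
  expect_equal(sum(grepl("^ms1,", body)), 1)

  empty <- scheme
  empty$windows <- empty$windows[0, ]
  expect_error(write_method_file(empty, tempfile()), "empty scheme")
})

test_that("method files round-trip at the printed precision", {
  lib <- proteome_library(2000, seed = 1)
  flib <- filter_precursors(lib)
  schemes <- list(
    build_scheme(equal_density_bin_edges(flib, 24, c(300, 1200)),
                 recovery_area(), 12, 2),
    build_scheme(equidistant_bin_edges(c(300, 1200), 24),
                 scan_area(0.6, 0.6, 1.5, 1.5), 8, 3),
    build_scheme(equidistant_bin_edges(c(400, 1400), 8),
                 scan_area(0.8, 1.0, 1.2, 1.4), 8, 1)
  )
  for (s in schemes) {
    path <- tempfile(fileext = ".txt")
    write_method_file(s, path)
    back <- read_method_file(path)
    expect_equal(back$n_scans, s$n_scans)
    expect_equal(back$windows_per_scan, s$windows_per_scan)
    expect_equal(back$windows$mz_start, s$windows$mz_start, tolerance = 0.005 + 1e-9)
    expect_equal(back$windows$mz_end, s$windows$mz_end, tolerance = 0.005 + 1e-9)
    expect_equal(back$windows$im_low, s$windows$im_low, tolerance = 5e-5 + 1e-9)
    expect_equal(back$windows$im_high, s$windows$im_high, tolerance = 5e-5 + 1e-9)
    # and a second write of the re-read scheme is byte-identical in body
    path2 <- tempfile(fileext = ".txt")
    write_method_file(back, path2)
    strip <- function(p) grep("^#", readLines(p), invert = TRUE, value = TRUE)
    expect_identical(strip(path), strip(path2))
  }
})

test_that("the reader accepts comments, synonyms and flexible column order", {
  txt <- c(
    "# hand-written method",
    "MS Type,Start Mass,End Mass,Start IM,End IM,Cycle Id,CE [eV]",
    "ms1,-,-,-,-,0,-",
    "pasef,400.00,1200.00,1.3000,0.7000,1,-"
  )
  path <- tempfile(fileext = ".txt")
  writeLines(txt, path)
  s <- read_method_file(path)
  expect_equal(s$n_scans, 1)
  expect_equal(s$windows_per_scan, 1)
  expect_equal(s$windows$mz_start, 400)
  expect_equal(s$windows$im_high, 1.3)
  expect_equal(s$ms1_frames_per_cycle, 1L)

  bad <- c("type,cycle id,start IM [1/K0],end IM [1/K0],start mass [m/z],end mass [m/z],CE [eV]",
           "pasef,1,0.7000,1.3000,400.00,1200.00,-")
  path_bad <- tempfile(fileext = ".txt")
  writeLines(bad, path_bad)
  expect_error(read_method_file(path_bad), "line")

  path_nocol <- tempfile(fileext = ".txt")
  writeLines(c("foo,bar", "1,2"), path_nocol)
  expect_error(read_method_file(path_nocol), "column")
})

test_that("an externally defined equidistant window table evaluates unchanged", {
  # 8 scans x 3 windows over the full IM rectangle, as in the original
  # equidistant scheme geometry
  scheme <- build_scheme(equidistant_bin_edges(c(300, 1200), 24),
                         scan_area(0.6, 0.6, 1.5, 1.5), 8, 3)
  path <- tempfile(fileext = ".txt")
  write_method_file(scheme, path)
  lib <- proteome_library(3000, seed = 2)
  lib_path <- tempfile(fileext = ".tsv")
  write_library(lib, lib_path)
  rep <- run_evaluate(path, lib_path)
  direct <- coverage_report(filter_precursors(lib), read_method_file(path),
                            restrict_to_ranges = FALSE)
  expect_equal(rep$covered_fraction, direct$covered_fraction)
  expect_length(rep$per_window_counts, 24)
})

test_that("run_evaluate reports full and zero coverage at the extremes", {
  lib <- proteome_library(500, seed = 8)
  lib_path <- tempfile(fileext = ".tsv")
  write_library(lib, lib_path)

  full <- build_scheme(c(300, 1200), scan_area(0.9, 0.9, 1.1, 1.1), 1, 1)
  p_full <- tempfile(fileext = ".txt")
  write_method_file(full, p_full)
  r_full <- run_evaluate(p_full, lib_path)
  expect_equal(r_full$covered_fraction, 1)
  expect_true(all(r_full$per_charge_fraction == 1))

  # method windows disjoint in m/z from the whole library
  disjoint <- build_scheme(c(300, 310), scan_area(0.9, 0.9, 1.1, 1.1), 1, 1)
  lib_hi <- new_spectral_library(data.frame(
    mz = runif(100, 900, 1100), im = runif(100, 0.8, 1.2), charge = 2L
  ))
  p_dis <- tempfile(fileext = ".txt")
  lib_hi_path <- tempfile(fileext = ".tsv")
  write_method_file(disjoint, p_dis)
  write_library(lib_hi, lib_hi_path)
  expect_equal(run_evaluate(p_dis, lib_hi_path)$covered_fraction, 0)
})

test_that("run_create executes the pipeline end-to-end from a config", {
  lib <- proteome_library(4000, seed = 1)
  out <- withr::local_tempdir()
  cfg <- run_config(preset = "spd60", mode = "optimal", n_trials = 25,
                    n_initial_random = 10, seed = 42, output_dir = out)
  res <- suppressMessages(run_create(cfg, lib = lib))
  expect_equal(nrow(res$scheme$windows), 24)
  expect_equal(round(res$cycle_time_s, 2), 1.38)
  expect_true(file.exists(res$paths$method))
  expect_true(file.exists(res$paths$report))
  expect_true(file.exists(res$paths$history))

  # equidistant mode: equal window widths, preset scan count
  cfg_eq <- run_config(preset = "spd100", mode = "equidistant",
                       output_dir = out)
  res_eq <- suppressMessages(run_create(cfg_eq, lib = lib))
  widths <- res_eq$scheme$windows$mz_end - res_eq$scheme$windows$mz_start
  expect_equal(res_eq$scheme$n_scans, 8)
  expect_true(all(abs(widths - widths[1]) < 1e-9))

  # reproducibility: same config and seed give identical method files
  cfg2 <- run_config(preset = "spd60", mode = "optimal", n_trials = 25,
                     n_initial_random = 10, seed = 42,
                     output_dir = withr::local_tempdir())
  res2 <- suppressMessages(run_create(cfg2, lib = lib))
  expect_identical(readLines(res2$paths$method), readLines(res$paths$method))
  expect_identical(res2$optimization$history, res$optimization$history)
})

test_that("run configurations round-trip through YAML with presets expanded", {
  cfg <- run_config(preset = "spd30", mode = "equidistant",
                    mz_range = c(400, 1400), seed = 9)
  expect_equal(cfg$n_scans, 25L)
  path <- tempfile(fileext = ".yaml")
  save_run_config(cfg, path)
  back <- load_run_config(path)
  expect_equal(back[names(back) != "output_dir"],
               cfg[names(cfg) != "output_dir"])
  writeLines("n_scans: 5\nbogus_key: 1", path)
  expect_error(load_run_config(path), "unknown config key")
})

test_that("density overlays render for proteome and phospho clouds", {
  lib <- proteome_library(400, seed = 3)
  scheme <- build_scheme(equidistant_bin_edges(c(300, 1200), 8),
                         scan_area(0.7, 0.9, 1.0, 1.3), 4, 2)
  path <- tempfile(fileext = ".png")
  p <- plot_scheme_density(lib, scheme, path)
  expect_s3_class(p, "ggplot")
  expect_true(file.exists(path) && file.size(path) > 0)

  phos <- generate_library(cloud_model(phospho = TRUE, seed = 4), 400)
  p2 <- plot_scheme_density(phos, scheme = NULL)
  expect_s3_class(p2, "ggplot")
})
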