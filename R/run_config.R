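#' End-to-end run configuration
#'
#' Bundles all parameters of a method-design run. The throughput
#' presets expand to the standard Evosep gradients: `spd100` = 8
#' dia-PASEF scans (11 min), `spd60` = 12 scans (21 min), `spd30` = 25
#' scans (44 min), all with two ion-mobility windows per scan, m/z
#' 300-1200 Th and 1/K0 0.6-1.5.
#'
#' @param library_path Path to the input spectral library (may be
#'   `NULL` when a library object is passed to [run_create()]).
#' @param library_format Library dialect, see [read_library()].
#' @param preset One of `"spd100"`, `"spd60"`, `"spd30"`, `"custom"`.
#' @param mode `"optimal"` (equal-density bins + scan-area
#'   optimization) or `"equidistant"` (fixed-width bins over the full
#'   ion-mobility range).
#' @param mz_range,im_range Method ranges; phosphoproteomics methods
#'   typically use `mz_range = c(400, 1400)`.
#' @param n_scans,windows_per_scan Scheme geometry; `n_scans` is taken
#'   from the preset unless `preset = "custom"`.
#' @param ramp_time,frame_overhead,ms1_frames_per_cycle Timing.
#' @param charges Evaluation/optimization population charges.
#' @param n_trials,n_initial_random,seed Optimizer settings.
#' @param output_dir Directory for method file, report and figure.
#' @param plot If `TRUE`, [run_create()] writes a density/scheme
#'   overlay figure.
#' @return A `run_config`.
#' @export
run_config <- function(library_path = NULL, library_format = "auto",
                       preset = c("spd60", "spd100", "spd30", "custom"),
                       mode = c("optimal", "equidistant"),
                       mz_range = c(300, 1200), im_range = c(0.6, 1.5),
                       n_scans = NULL, windows_per_scan = 2L,
                       ramp_time = 0.100, frame_overhead = 0.00615,
                       ms1_frames_per_cycle = 1L, charges = 2:4,
                       n_trials = 200L, n_initial_random = 20L,
                       seed = 42L, output_dir = ".", plot = FALSE) {
  preset <- match.arg(preset)
  mode <- match.arg(mode)
  preset_scans <- c(spd100 = 8L, spd60 = 12L, spd30 = 25L)
  if (preset != "custom") {
    n_scans <- preset_scans[[preset]]
  } else if (is.null(n_scans)) {
    stop("preset 'custom' requires n_scans")
  }
  structure(
    list(library_path = library_path, library_format = library_format,
         preset = preset, mode = mode,
         mz_range = as.numeric(mz_range), im_range = as.numeric(im_range),
         n_scans = as.integer(n_scans),
         windows_per_scan = as.integer(windows_per_scan),
         ramp_time = ramp_time, frame_overhead = frame_overhead,
         ms1_frames_per_cycle = as.integer(ms1_frames_per_cycle),
         charges = as.integer(charges),
         n_trials = as.integer(n_trials),
         n_initial_random = as.integer(n_initial_random),
         seed = as.integer(seed), output_dir = output_dir,
         plot = isTRUE(plot)),
    class = "run_config"
  )
}

#' Read or write a run configuration as YAML
#'
#' @param path YAML file path.
#' @return For `load_run_config()`, a `run_config`.
#' @export
load_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  do.call(run_config, vals)
}

#' @rdname load_run_config
#' @param cfg A `run_config`.
#' @export
save_run_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Design a dia-PASEF method end-to-end
#'
#' Reads (or accepts) a spectral library, filters it to the configured
#' ranges and charges, bins the m/z axis, optimizes the scan area (or
#' uses the full ion-mobility rectangle with equidistant bins in
#' equidistant mode), builds the scheme, evaluates its coverage, and
#' writes the method window table plus a coverage report (and
#' optionally a figure) into `cfg$output_dir`.
#'
#' @param cfg A [run_config()].
#' @param lib Optional `spectral_library`; when `NULL` the library is
#'   read from `cfg$library_path`.
#' @return Invisibly, a list with `scheme`, `report`, `optimization`
#'   (NULL in equidistant mode), `cycle_time_s` and output `paths`.
#' @export
run_create <- function(cfg, lib = NULL) {
  stopifnot(inherits(cfg, "run_config"))
  if (is.null(lib)) {
    if (is.null(cfg$library_path)) stop("config stage: no library given")
    lib <- read_library(cfg$library_path, cfg$library_format)
  }
  flib <- filter_precursors(lib, cfg$mz_range, cfg$im_range, cfg$charges)
  if (nrow(flib$records) == 0) stop("filter stage: no precursors retained")
  n_windows <- cfg$n_scans * cfg$windows_per_scan

  opt <- NULL
  if (cfg$mode == "optimal") {
    opt <- optimize_scan_area(
      flib,
      optimization_config(n_trials = cfg$n_trials,
                          n_initial_random = cfg$n_initial_random,
                          seed = cfg$seed),
      n_scans = cfg$n_scans, windows_per_scan = cfg$windows_per_scan,
      mz_range = cfg$mz_range, im_range = cfg$im_range,
      charges = cfg$charges
    )
    edges <- opt$bin_edges
    area <- opt$best_area
  } else {
    edges <- equidistant_bin_edges(cfg$mz_range, n_windows)
    area <- scan_area(cfg$im_range[1], cfg$im_range[1],
                      cfg$im_range[2], cfg$im_range[2])
  }
  scheme <- build_scheme(edges, area, cfg$n_scans, cfg$windows_per_scan,
                         cfg$im_range, cfg$ramp_time, cfg$frame_overhead,
                         cfg$ms1_frames_per_cycle)
  report <- coverage_report(flib, scheme, charges = cfg$charges)

  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    method = file.path(cfg$output_dir,
                       sprintf("diapasef_%s_%s.txt", cfg$preset, cfg$mode)),
    report = file.path(cfg$output_dir,
                       sprintf("coverage_%s_%s.tsv", cfg$preset, cfg$mode))
  )
  write_method_file(scheme, paths$method)
  write_coverage_report(report, paths$report)
  if (!is.null(opt)) {
    paths$history <- file.path(cfg$output_dir,
                               sprintf("trials_%s.tsv", cfg$preset))
    write_optimization_history(opt, paths$history)
  }
  if (cfg$plot) {
    paths$figure <- file.path(cfg$output_dir,
                              sprintf("scheme_%s_%s.png", cfg$preset, cfg$mode))
    plot_scheme_density(flib, scheme, paths$figure)
  }
  message(sprintf(
    "scheme: %d windows; cycle time %.2f s; coverage %.1f%% (seed %d, %s mode)",
    nrow(scheme$windows), cycle_time(scheme),
    100 * report$covered_fraction, cfg$seed, cfg$mode))
  invisible(list(scheme = scheme, report = report, optimization = opt,
                 cycle_time_s = cycle_time(scheme), paths = paths))
}

#' Evaluate an existing method against a library
#'
#' Re-imports a method window table and reports how much of the
#' library it covers (overall and per charge), the per-window
#' precursor counts, and the uncovered-population marginals.
#'
#' @param method_path Method window table, see [read_method_file()].
#' @param library_path Spectral library file.
#' @param cfg Optional [run_config()] supplying ranges, charges and
#'   library dialect; defaults are used when `NULL`.
#' @return A `coverage_report`.
#' @export
run_evaluate <- function(method_path, library_path, cfg = NULL) {
  if (is.null(cfg)) cfg <- run_config()
  scheme <- read_method_file(method_path, cfg$ramp_time,
                             cfg$frame_overhead)
  lib <- read_library(library_path, cfg$library_format)
  flib <- filter_precursors(lib, cfg$mz_range, cfg$im_range, cfg$charges)
  coverage_report(flib, scheme, charges = cfg$charges,
                  restrict_to_ranges = FALSE)
}
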