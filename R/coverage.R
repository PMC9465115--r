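#' Point-in-window test for precursors against a scheme
#'
#' A precursor is covered when some isolation window satisfies
#' `mz_start <= mz < mz_end` (the window carrying the highest m/z bin is
#' closed on the right so the upper range limit is not lost) and
#' `im_low <= im <= im_high`. With the default zero-overlap geometry the
#' windows partition the scanned region, so each covered precursor falls
#' in exactly one window.
#'
#' @param precursors A `spectral_library` or a data frame with columns
#'   `mz` and `im`.
#' @param scheme An `acquisition_scheme`.
#' @return Logical vector, one element per precursor.
#' @export
is_covered <- function(precursors, scheme) {
  rec <- if (inherits(precursors, "spectral_library")) {
    precursors$records
  } else {
    as.data.frame(precursors)
  }
  stopifnot(inherits(scheme, "acquisition_scheme"),
            all(c("mz", "im") %in% names(rec)))
  .window_index(rec, scheme) > 0L
}

# index of the covering window per precursor (0 = uncovered); with zero
# overlap the covering window is unique, otherwise the lowest-index
# (highest-mobility-first) window wins
.window_index <- function(rec, scheme) {
  w <- scheme$windows
  last_edge <- max(w$mz_end)
  idx <- integer(nrow(rec))
  for (i in seq_len(nrow(w))) {
    closed_right <- w$mz_end[i] >= last_edge - 1e-9
    in_mz <- rec$mz >= w$mz_start[i] &
      (rec$mz < w$mz_end[i] | (closed_right & rec$mz <= w$mz_end[i]))
    hit <- idx == 0L & in_mz &
      rec$im >= w$im_low[i] & rec$im <= w$im_high[i]
    idx[hit] <- i
  }
  idx
}

#' Coverage of a precursor population by an acquisition scheme
#'
#' Evaluates which precursors of the library fall inside at least one
#' isolation window. The default evaluation population comprises
#' records with charge 2-4 whose coordinates lie inside the scheme's
#' configured m/z and ion-mobility ranges; per-charge fractions are
#' reported over the records of each charge.
#'
#' @param lib A non-empty `spectral_library`.
#' @param scheme An `acquisition_scheme`.
#' @param histogram_bins Number of bins for the uncovered-population
#'   m/z and ion-mobility histograms.
#' @param charges Charge states forming the evaluation population.
#' @param restrict_to_ranges If `TRUE` (default), restrict the
#'   population to the scheme's m/z and ion-mobility ranges.
#' @param intensity_weighted If `TRUE`, also report the
#'   intensity-weighted covered fraction.
#' @return A `coverage_report` with fields `n_precursors`,
#'   `covered_fraction`, `per_charge_fraction`, `per_window_counts`
#'   (aligned to `scheme$windows`), `uncovered_mz_histogram` and
#'   `uncovered_im_histogram` (data frames of bin mids and counts), and
#'   optionally `intensity_weighted_fraction`.
#' @export
coverage_report <- function(lib, scheme, histogram_bins = 25L,
                            charges = 2:4, restrict_to_ranges = TRUE,
                            intensity_weighted = FALSE) {
  stopifnot(inherits(lib, "spectral_library"),
            inherits(scheme, "acquisition_scheme"))
  rec <- lib$records
  if (nrow(rec) == 0) stop("empty library")
  keep <- rec$charge %in% charges
  if (restrict_to_ranges) {
    keep <- keep &
      rec$mz >= scheme$mz_range[1] & rec$mz <= scheme$mz_range[2] &
      rec$im >= scheme$im_range[1] & rec$im <= scheme$im_range[2]
  }
  rec <- rec[keep, , drop = FALSE]
  if (nrow(rec) == 0) {
    stop("no precursors in the evaluation population (charges ",
         paste(charges, collapse = ","), " within the scheme ranges)")
  }

  idx <- .window_index(rec, scheme)
  covered <- idx > 0L
  per_charge <- vapply(
    sort(unique(rec$charge)),
    function(z) mean(covered[rec$charge == z]),
    numeric(1)
  )
  names(per_charge) <- sort(unique(rec$charge))
  per_window <- tabulate(idx[covered], nbins = nrow(scheme$windows))

  hist_df <- function(x, range, nb) {
    breaks <- seq(range[1], range[2], length.out = nb + 1)
    cnt <- if (length(x)) {
      tabulate(pmin(pmax(findInterval(x, breaks, rightmost.closed = TRUE),
                         1L), nb), nbins = nb)
    } else integer(nb)
    data.frame(mid = (breaks[-1] + breaks[-(nb + 1)]) / 2, count = cnt)
  }
  unc <- rec[!covered, , drop = FALSE]

  report <- list(
    n_precursors = nrow(rec),
    covered_fraction = mean(covered),
    per_charge_fraction = per_charge,
    per_window_counts = per_window,
    uncovered_mz_histogram = hist_df(unc$mz, scheme$mz_range, histogram_bins),
    uncovered_im_histogram = hist_df(unc$im, scheme$im_range, histogram_bins)
  )
  if (intensity_weighted) {
    report$intensity_weighted_fraction <-
      sum(rec$intensity[covered]) / sum(rec$intensity)
  }
  structure(report, class = "coverage_report")
}

#' @export
print.coverage_report <- function(x, ...) {
  cat(sprintf("Coverage: %.1f%% of %d precursors\n",
              100 * x$covered_fraction, x$n_precursors))
  for (z in names(x$per_charge_fraction)) {
    cat(sprintf("  charge %s: %.1f%%\n", z,
                100 * x$per_charge_fraction[[z]]))
  }
  b <- per_window_balance(x)
  cat(sprintf("  per-window counts: min %d, max %d, max/mean %.2f\n",
              b$min, b$max, b$max_over_mean))
  invisible(x)
}

#' Per-window precursor balance
#'
#' Summarizes how evenly the covered precursors distribute over the
#' isolation windows; equal-density binning targets a max/mean ratio
#' near 1, whereas equidistant windows concentrate precursors in the
#' dense mid-m/z windows.
#'
#' @param report A `coverage_report`.
#' @return List with `min`, `max`, `mean` and `max_over_mean` of the
#'   per-window counts.
#' @export
per_window_balance <- function(report) {
  stopifnot(inherits(report, "coverage_report"))
  counts <- report$per_window_counts
  list(min = min(counts), max = max(counts), mean = mean(counts),
       max_over_mean = if (mean(counts) > 0) max(counts) / mean(counts)
                       else NA_real_)
}

#' Export a coverage report as a flat table
#'
#' @param report A `coverage_report`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_coverage_report <- function(report, path) {
  stopifnot(inherits(report, "coverage_report"))
  lines <- c(
    sprintf("n_precursors\t%d", report$n_precursors),
    sprintf("covered_fraction\t%.6f", report$covered_fraction),
    sprintf("covered_fraction_charge%s\t%.6f",
            names(report$per_charge_fraction),
            report$per_charge_fraction),
    if (!is.null(report$intensity_weighted_fraction)) {
      sprintf("intensity_weighted_fraction\t%.6f",
              report$intensity_weighted_fraction)
    },
    sprintf("window_%d_count\t%d",
            seq_along(report$per_window_counts), report$per_window_counts)
  )
  writeLines(lines, path)
  invisible(path)
}
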