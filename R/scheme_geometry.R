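#' Trapezoidal scan area
#'
#' The region of the m/z - ion mobility plane swept by a dia-PASEF
#' scheme is modeled as a trapezoid whose lower and upper edges are
#' linear in m/z. The four parameters are the 1/K0 values of the bottom
#' and top edges evaluated at the m/z range limits; these corners are
#' what the optimizer searches.
#'
#' @param im_bottom_left,im_bottom_right 1/K0 of the lower edge at the
#'   lower / upper end of the m/z range.
#' @param im_top_left,im_top_right 1/K0 of the upper edge at the lower /
#'   upper end of the m/z range.
#' @return A `scan_area` object.
#' @export
scan_area <- function(im_bottom_left, im_bottom_right,
                      im_top_left, im_top_right) {
  stopifnot(is.finite(im_bottom_left), is.finite(im_bottom_right),
            is.finite(im_top_left), is.finite(im_top_right))
  if (im_top_left <= im_bottom_left || im_top_right <= im_bottom_right) {
    stop("invalid scan area: top edge must lie above bottom edge at ",
         "both ends of the m/z range")
  }
  structure(
    list(im_bottom_left = im_bottom_left, im_bottom_right = im_bottom_right,
         im_top_left = im_top_left, im_top_right = im_top_right),
    class = "scan_area"
  )
}

#' @export
print.scan_area <- function(x, ...) {
  cat(sprintf(
    "Scan area (1/K0): bottom %.3f -> %.3f, top %.3f -> %.3f\n",
    x$im_bottom_left, x$im_bottom_right, x$im_top_left, x$im_top_right))
  invisible(x)
}

#' Interpolate an internal boundary line of the scan area
#'
#' Both trapezoid edges are linear in m/z; the line at height
#' `strip_fraction` interpolates between the bottom edge (fraction 0)
#' and the top edge (fraction 1). Used to place the quadrupole
#' transition points that split each TIMS ramp into ion-mobility
#' windows.
#'
#' @param area A [scan_area()].
#' @param strip_fraction Number in `[0, 1]`.
#' @param mz m/z value(s) at which to evaluate the line.
#' @param mz_range The m/z interval over which the corners are defined.
#' @return 1/K0 value(s), vectorized over `mz`.
#' @export
strip_boundary_im <- function(area, strip_fraction, mz, mz_range) {
  stopifnot(inherits(area, "scan_area"),
            strip_fraction >= 0, strip_fraction <= 1,
            mz_range[1] < mz_range[2])
  t <- (mz - mz_range[1]) / (mz_range[2] - mz_range[1])
  bottom <- area$im_bottom_left + t * (area$im_bottom_right - area$im_bottom_left)
  top <- area$im_top_left + t * (area$im_top_right - area$im_top_left)
  bottom + strip_fraction * (top - bottom)
}

#' Equal-density m/z bin edges
#'
#' Splits the m/z axis into `n_bins` bins holding (up to ties) equal
#' numbers of library precursors. Interior edges are empirical quantiles
#' at probabilities i/n_bins, placed midway between the adjacent order
#' statistics so that per-bin counts differ by at most one for
#' continuous data; outer edges are the `mz_range` limits.
#'
#' @param lib A `spectral_library` already filtered to `mz_range`.
#' @param n_bins Number of bins (>= 1); the library must hold at least
#'   `n_bins` records.
#' @param mz_range Ordered m/z interval (Th).
#' @return Strictly increasing numeric vector of `n_bins + 1` edges.
#' @export
equal_density_bin_edges <- function(lib, n_bins, mz_range) {
  stopifnot(inherits(lib, "spectral_library"), n_bins >= 1,
            mz_range[1] < mz_range[2])
  x <- lib$records$mz
  if (any(x < mz_range[1] | x > mz_range[2])) {
    stop("library contains precursors outside mz_range; apply ",
         "filter_precursors() first")
  }
  n <- length(x)
  if (n < n_bins) stop("fewer records (", n, ") than bins (", n_bins, ")")
  if (n_bins == 1) return(as.numeric(mz_range))
  x <- sort(x)
  idx <- seq_len(n_bins - 1) * n / n_bins
  lo <- pmin(floor(idx), n - 1)
  interior <- (x[lo] + x[lo + 1]) / 2
  edges <- c(mz_range[1], interior, mz_range[2])
  if (any(diff(edges) <= 0)) {
    bad <- which(diff(edges) <= 0)
    stop("tied m/z values collapse quantile edges at probabilities ",
         paste(sprintf("%d/%d", bad, n_bins), collapse = ", "),
         " (edge value ", sprintf("%.4f", edges[bad[1] + 1]), ")")
  }
  edges
}

#' Equidistant m/z bin edges
#'
#' @param mz_range Ordered m/z interval (Th).
#' @param n_bins Number of bins (>= 1).
#' @return Arithmetic progression of `n_bins + 1` edges.
#' @export
equidistant_bin_edges <- function(mz_range, n_bins) {
  stopifnot(n_bins >= 1, mz_range[1] < mz_range[2])
  seq(mz_range[1], mz_range[2], length.out = n_bins + 1)
}

#' Build a dia-PASEF acquisition scheme
#'
#' Assigns the m/z bins diagonally to `n_scans` TIMS ramps with
#' `windows_per_scan` ion-mobility windows each, following the cloud's
#' m/z-mobility correlation: scan 1 starts at the highest-m/z bin in the
#' top mobility strip, and each subsequent scan's starting window is
#' offset one bin lower. With bins indexed 1..W from low m/z, scan j
#' carries bin `W - (s-1)*n_scans - (j-1)` in strip s (strip 1 = highest
#' mobility). The quadrupole transition between strips s and s+1 of a
#' scan lies on the scan-area line at height `(k-s)/k`, evaluated at the
#' mean of the two adjacent bins' m/z centers; the top and bottom strips
#' are extended to the instrument ion-mobility limits so no mobility
#' range is left unscanned.
#'
#' @param bin_edges Strictly increasing m/z edges; `length(bin_edges) -
#'   1` must equal `n_scans * windows_per_scan`.
#' @param area A [scan_area()] lying inside `im_range`.
#' @param n_scans Number of dia-PASEF scans per cycle.
#' @param windows_per_scan Ion-mobility windows per scan (k).
#' @param im_range Instrument 1/K0 range.
#' @param ramp_time TIMS accumulation/ramp time in seconds per frame.
#' @param frame_overhead Per-frame transfer overhead in seconds.
#' @param ms1_frames_per_cycle Number of MS1 frames per cycle.
#' @param overlap Symmetric m/z widening of each window (Th); default 0.
#' @return An `acquisition_scheme` whose `$windows` data frame has one
#'   row per isolation window (columns `scan`, `strip`, `mz_start`,
#'   `mz_end`, `im_low`, `im_high`), ordered within each scan from high
#'   to low ion mobility.
#' @export
build_scheme <- function(bin_edges, area, n_scans, windows_per_scan,
                         im_range = c(0.6, 1.5),
                         ramp_time = 0.100, frame_overhead = 0.00615,
                         ms1_frames_per_cycle = 1L, overlap = 0) {
  stopifnot(inherits(area, "scan_area"), n_scans >= 1,
            windows_per_scan >= 1, im_range[1] < im_range[2],
            all(diff(bin_edges) > 0))
  k <- windows_per_scan
  W <- length(bin_edges) - 1
  if (W != n_scans * k) {
    stop("bin count (", W, ") must equal n_scans * windows_per_scan (",
         n_scans * k, ")")
  }
  corners <- unlist(area)
  if (any(corners < im_range[1] - 1e-9 | corners > im_range[2] + 1e-9)) {
    stop("scan area corners fall outside im_range")
  }
  mz_range <- c(bin_edges[1], bin_edges[W + 1])
  centers <- (bin_edges[-1] + bin_edges[-(W + 1)]) / 2

  rows <- vector("list", n_scans)
  for (j in seq_len(n_scans)) {
    bins <- W - (seq_len(k) - 1) * n_scans - (j - 1)  # strip 1..k
    # mobility boundaries from the top limit down to the bottom limit,
    # one quadrupole jump per interior boundary
    bounds <- numeric(k + 1)
    bounds[1] <- im_range[2]
    bounds[k + 1] <- im_range[1]
    if (k > 1) {
      for (s in seq_len(k - 1)) {
        eval_mz <- mean(centers[bins[c(s, s + 1)]])
        b <- strip_boundary_im(area, (k - s) / k, eval_mz, mz_range)
        if (b < im_range[1] || b > im_range[2]) {
          warning("transition 1/K0 ", sprintf("%.3f", b),
                  " outside im_range; clamped")
          b <- min(max(b, im_range[1]), im_range[2])
        }
        bounds[s + 1] <- b
      }
    }
    if (any(diff(bounds) >= 0)) {
      stop("non-monotone ion-mobility boundaries in scan ", j,
           "; scan area is too distorted for ", k, " windows per scan")
    }
    rows[[j]] <- data.frame(
      scan = j, strip = seq_len(k),
      mz_start = bin_edges[bins] - overlap / 2,
      mz_end = bin_edges[bins + 1] + overlap / 2,
      im_low = bounds[-1], im_high = bounds[-(k + 1)]
    )
  }
  windows <- do.call(rbind, rows)
  rownames(windows) <- NULL
  structure(
    list(windows = windows, n_scans = n_scans, windows_per_scan = k,
         ms1_frames_per_cycle = as.integer(ms1_frames_per_cycle),
         ramp_time = ramp_time, frame_overhead = frame_overhead,
         mz_range = mz_range, im_range = as.numeric(im_range)),
    class = "acquisition_scheme"
  )
}

#' @export
print.acquisition_scheme <- function(x, ...) {
  cat(sprintf(
    "dia-PASEF scheme: %d scans x %d IM windows (%d isolation windows)\n",
    x$n_scans, x$windows_per_scan, nrow(x$windows)))
  cat(sprintf("  m/z %.1f-%.1f Th, 1/K0 %.2f-%.2f, cycle time %.2f s\n",
              x$mz_range[1], x$mz_range[2], x$im_range[1], x$im_range[2],
              cycle_time(x)))
  invisible(x)
}

#' Acquisition cycle time
#'
#' One cycle comprises all dia-PASEF frames plus the MS1 frame(s), each
#' lasting the TIMS ramp time plus a fixed per-frame transfer overhead:
#' `(n_scans + ms1_frames) * (ramp_time + frame_overhead)`.
#'
#' @param scheme An `acquisition_scheme`.
#' @return Cycle time in seconds.
#' @export
cycle_time <- function(scheme) {
  stopifnot(inherits(scheme, "acquisition_scheme"))
  frame_cycle_time(scheme$n_scans, scheme$ms1_frames_per_cycle,
                   scheme$ramp_time, scheme$frame_overhead)
}

#' @rdname cycle_time
#' @param n_scans Number of dia-PASEF frames per cycle (may be 0).
#' @param ms1_frames_per_cycle Number of MS1 frames per cycle.
#' @param ramp_time,frame_overhead Seconds per frame: TIMS ramp and
#'   transfer overhead.
#' @export
frame_cycle_time <- function(n_scans, ms1_frames_per_cycle = 1L,
                             ramp_time = 0.100, frame_overhead = 0.00615) {
  stopifnot(n_scans >= 0, ms1_frames_per_cycle >= 0)
  (n_scans + ms1_frames_per_cycle) * (ramp_time + frame_overhead)
}
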