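#' Method-file dialect for dia-PASEF window tables
#'
#' Schemes are serialized as plain CSV window tables, one row per
#' isolation window plus one `ms1` row per cycle. The header names the
#' columns `type, cycle id, start IM [1/K0], end IM [1/K0],
#' start mass [m/z], end mass [m/z], CE [eV]`; lines starting with `#`
#' are comments. For `pasef` rows the ion-mobility start is the high
#' end of the window (TIMS ramps elute from high to low 1/K0), so
#' `start IM > end IM` while `start mass < end mass`. Ion mobilities
#' are printed with four decimals and masses with two, and
#' [read_method_file()] reproduces the windows exactly at that printed
#' precision. The collision-energy column is a passthrough placeholder:
#' CE ramping is instrument configuration, not window geometry.
#'
#' @name method_file_dialect
NULL

.method_header <- paste("type,cycle id,start IM [1/K0],end IM [1/K0],",
                        "start mass [m/z],end mass [m/z],CE [eV]", sep = "")

#' Write an acquisition scheme as a method window table
#'
#' @param scheme A non-empty `acquisition_scheme`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @seealso [method_file_dialect]
#' @export
write_method_file <- function(scheme, path) {
  stopifnot(inherits(scheme, "acquisition_scheme"))
  w <- scheme$windows
  if (nrow(w) == 0) stop("cannot write an empty scheme")
  lines <- c(
    sprintf("# dia-PASEF window table: %d scans x %d IM windows, cycle time %.4f s",
            scheme$n_scans, scheme$windows_per_scan, cycle_time(scheme)),
    .method_header,
    sprintf("ms1,%d,-,-,-,-,-", seq_len(scheme$ms1_frames_per_cycle) - 1L)
  )
  ord <- order(w$scan, w$strip)
  w <- w[ord, , drop = FALSE]
  lines <- c(lines, sprintf(
    "pasef,%d,%.4f,%.4f,%.2f,%.2f,-",
    w$scan, w$im_high, w$im_low, w$mz_start, w$mz_end
  ))
  writeLines(lines, path)
  invisible(path)
}

.normalize_header <- function(x) {
  x <- tolower(x)
  x <- gsub("\\[[^]]*\\]", "", x)   # strip unit annotations
  gsub("[^a-z0-9]", "", x)
}

# accepted synonyms per internal column, after normalization
.method_col_syn <- list(
  type = c("type", "mstype"),
  cycle_id = c("cycleid", "cycle"),
  im_start = c("startim", "imstart", "onekzerostart"),
  im_end = c("endim", "imend", "onekzeroend"),
  mz_start = c("startmass", "massstart", "startmz", "mzstart"),
  mz_end = c("endmass", "massend", "endmz", "mzend")
)

#' Read a method window table into an acquisition scheme
#'
#' Accepts the dialect written by [write_method_file()] and permissive
#' variants: `#` comment lines, flexible column order, and common
#' header synonyms (e.g. `MS Type`, `Start IM`, `Start Mass`). Scans
#' are reconstructed by grouping `pasef` rows on the cycle id with
#' windows ordered from high to low ion mobility; timing parameters are
#' not stored in the file and are taken from the arguments.
#'
#' @param path Method file path.
#' @param ramp_time,frame_overhead,ms1_frames_per_cycle Timing; the
#'   MS1 frame count defaults to the number of `ms1` rows in the file
#'   (or 1 if none).
#' @return An `acquisition_scheme`.
#' @export
read_method_file <- function(path, ramp_time = 0.100,
                             frame_overhead = 0.00615,
                             ms1_frames_per_cycle = NULL) {
  if (!file.exists(path)) stop("method file not found: ", path)
  raw <- readLines(path)
  keep <- !grepl("^\\s*#", raw) & nzchar(trimws(raw))
  body <- raw[keep]
  row_numbers <- which(keep)
  if (length(body) < 2) stop("method file has no data rows: ", path)
  dt <- data.table::fread(text = body, sep = ",", header = TRUE,
                          colClasses = "character", data.table = FALSE)
  norm <- .normalize_header(names(dt))
  col_of <- function(key) {
    hit <- which(norm %in% .method_col_syn[[key]])
    if (length(hit) == 0) {
      stop("method file lacks a recognizable '", key, "' column; header: ",
           paste(names(dt), collapse = ", "))
    }
    hit[1]
  }
  type <- tolower(trimws(dt[[col_of("type")]]))
  cycle <- suppressWarnings(as.integer(dt[[col_of("cycle_id")]]))
  num <- function(key) suppressWarnings(as.numeric(dt[[col_of(key)]]))
  im_start <- num("im_start"); im_end <- num("im_end")
  mz_start <- num("mz_start"); mz_end <- num("mz_end")

  is_pasef <- type == "pasef"
  n_ms1 <- sum(type == "ms1")
  if (!any(is_pasef)) stop("method file contains no pasef rows")
  bad <- which(is_pasef & (is.na(im_start) | is.na(im_end) |
                             is.na(mz_start) | is.na(mz_end) |
                             im_start <= im_end | mz_start >= mz_end))
  if (length(bad) > 0) {
    stop("inconsistent pasef row geometry (need start IM > end IM and ",
         "start mass < end mass) at file line(s) ",
         paste(row_numbers[bad + 1L], collapse = ", "))
  }

  p <- data.frame(cycle = cycle[is_pasef],
                  im_high = im_start[is_pasef], im_low = im_end[is_pasef],
                  mz_start = mz_start[is_pasef], mz_end = mz_end[is_pasef])
  p <- p[order(p$cycle, -p$im_high), , drop = FALSE]
  scans <- unique(p$cycle)
  per_scan <- table(p$cycle)
  k <- as.integer(per_scan[1])
  if (!all(per_scan == k)) {
    stop("scans carry unequal window counts: ",
         paste(sprintf("cycle %s: %d", names(per_scan), per_scan),
               collapse = "; "))
  }
  windows <- data.frame(
    scan = match(p$cycle, scans),
    strip = as.integer(stats::ave(p$im_high, p$cycle,
                                  FUN = function(x) seq_along(x))),
    mz_start = p$mz_start, mz_end = p$mz_end,
    im_low = p$im_low, im_high = p$im_high
  )
  rownames(windows) <- NULL
  structure(
    list(windows = windows, n_scans = length(scans), windows_per_scan = k,
         ms1_frames_per_cycle = as.integer(
           if (!is.null(ms1_frames_per_cycle)) ms1_frames_per_cycle
           else max(n_ms1, 1L)),
         ramp_time = ramp_time, frame_overhead = frame_overhead,
         mz_range = c(min(windows$mz_start), max(windows$mz_end)),
         im_range = c(min(windows$im_low), max(windows$im_high))),
    class = "acquisition_scheme"
  )
}

#' Overlay an acquisition scheme on the precursor density
#'
#' Renders a two-dimensional kernel-density estimate of the library's
#' (m/z, 1/K0) coordinates with the isolation windows drawn as
#' rectangles. Diagnostic only; no numeric result depends on figures.
#'
#' @param lib A non-empty `spectral_library`.
#' @param scheme An `acquisition_scheme`, or `NULL` for a density-only
#'   figure.
#' @param path Optional output file (png/pdf/svg by extension).
#' @return The ggplot object, invisibly.
#' @export
plot_scheme_density <- function(lib, scheme = NULL, path = NULL) {
  stopifnot(inherits(lib, "spectral_library"))
  rec <- lib$records
  if (nrow(rec) == 0) stop("empty library")
  p <- ggplot2::ggplot(rec, ggplot2::aes(x = .data$mz, y = .data$im)) +
    ggplot2::stat_density_2d(
      ggplot2::aes(fill = ggplot2::after_stat(.data$density)),
      geom = "raster", contour = FALSE, n = 120
    ) +
    ggplot2::scale_fill_viridis_c(name = "density") +
    ggplot2::labs(x = "m/z [Th]", y = expression("1/K"[0] ~ "[V s/cm"^2 * "]")) +
    ggplot2::theme_minimal()
  if (!is.null(scheme)) {
    p <- p + ggplot2::geom_rect(
      data = scheme$windows,
      ggplot2::aes(xmin = .data$mz_start, xmax = .data$mz_end,
                   ymin = .data$im_low, ymax = .data$im_high),
      inherit.aes = FALSE, fill = NA, colour = "white", linewidth = 0.3
    )
  }
  if (!is.null(path)) {
    ok <- tryCatch({
      ggplot2::ggsave(path, p, width = 7, height = 5, dpi = 150)
      TRUE
    }, error = function(e) {
      warning("could not write figure to ", path, ": ", conditionMessage(e))
      FALSE
    })
  }
  invisible(p)
}
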