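#' Spectral-library containers and text I/O
#'
#' A `spectral_library` holds one row per precursor with columns `mz`
#' (Th), `im` (reduced ion mobility 1/K0, V s/cm^2), `charge` (integer
#' >= 1), `intensity` (arbitrary units, 1 when absent from the source),
#' `sequence` (modified-peptide string or NA) and `is_phospho` (TRUE iff
#' the sequence carries a phosphorylation annotation).
#'
#' @name spectral_library
NULL

.record_cols <- c("mz", "im", "charge", "intensity", "sequence", "is_phospho")

# column maps from source dialects to the internal names; the DIA-NN /
# FragPipe and Spectronaut library exports share these headers
.dialect_maps <- list(
  generic = c(
    mz = "mz", im = "im", charge = "charge",
    intensity = "intensity", sequence = "sequence"
  ),
  diann_fragpipe = c(
    mz = "PrecursorMz", im = "IonMobility", charge = "PrecursorCharge",
    intensity = "LibraryIntensity", sequence = "ModifiedPeptide"
  ),
  spectronaut = c(
    mz = "PrecursorMz", im = "IonMobility", charge = "PrecursorCharge",
    intensity = "LibraryIntensity", sequence = "ModifiedPeptide"
  )
)

#' Construct a spectral library from a precursor data frame
#'
#' Low-level constructor: wraps a data frame with at least `mz`, `im`
#' and `charge` columns (optional `intensity`, `sequence`,
#' `is_phospho`, defaulted when absent) into a `spectral_library`.
#' No filtering or deduplication is applied; see [read_library()] for
#' parsing files.
#'
#' @param records Data frame of precursors.
#' @param source_format Label recorded on the library.
#' @param filters_applied,parse_report Optional provenance records.
#' @return A `spectral_library`.
#' @export
new_spectral_library <- function(records, source_format = "generic",
                                 filters_applied = NULL,
                                 parse_report = NULL) {
  records <- as.data.frame(records)
  for (col in .record_cols) {
    if (!col %in% names(records)) {
      records[[col]] <- switch(col,
        intensity = rep(1, nrow(records)),
        sequence = rep(NA_character_, nrow(records)),
        is_phospho = rep(FALSE, nrow(records)),
        stop("missing required column: ", col)
      )
    }
  }
  records <- records[, .record_cols, drop = FALSE]
  rownames(records) <- NULL
  structure(
    list(
      records = records,
      source_format = source_format,
      filters_applied = filters_applied,
      parse_report = parse_report
    ),
    class = "spectral_library"
  )
}

#' @export
print.spectral_library <- function(x, ...) {
  cat("Spectral library:", nrow(x$records), "precursors",
      sprintf("(source: %s)\n", x$source_format))
  if (nrow(x$records) > 0) {
    cat(sprintf("  m/z %.2f-%.2f Th, 1/K0 %.3f-%.3f, charges: %s\n",
                min(x$records$mz), max(x$records$mz),
                min(x$records$im), max(x$records$im),
                paste(sort(unique(x$records$charge)), collapse = ", ")))
  }
  if (!is.null(x$filters_applied)) {
    f <- x$filters_applied
    cat(sprintf("  filters: m/z [%g, %g], 1/K0 [%g, %g], charges {%s}\n",
                f$mz_range[1], f$mz_range[2], f$im_range[1], f$im_range[2],
                paste(f$charges, collapse = ",")))
  }
  invisible(x)
}

#' Number of precursors in a spectral library
#'
#' @param lib A `spectral_library`.
#' @return Integer record count.
#' @export
n_precursors <- function(lib) {
  stopifnot(inherits(lib, "spectral_library"))
  nrow(lib$records)
}

.detect_phospho <- function(sequence) {
  !is.na(sequence) &
    (grepl("Phospho", sequence, fixed = TRUE) |
       grepl("UniMod:21", sequence, fixed = TRUE))
}

.resolve_dialect <- function(header) {
  has_generic <- all(c("mz", "im", "charge") %in% header)
  has_tool <- all(c("PrecursorMz", "IonMobility", "PrecursorCharge") %in% header)
  if (has_generic && has_tool) {
    stop("ambiguous library dialect: header contains both generic ",
         "(mz/im/charge) and tool (PrecursorMz/IonMobility/PrecursorCharge) ",
         "columns; pass `format` explicitly")
  }
  if (has_generic) return("generic")
  if (has_tool) return("diann_fragpipe")
  stop("cannot determine library dialect from header: ",
       paste(utils::head(header, 12), collapse = ", "))
}

#' Read a spectral-library precursor table
#'
#' Reads tab- or comma-separated precursor tables (delimiter detected
#' from the file; gzip accepted by extension) in either the generic
#' dialect (columns `mz`, `im`, `charge`, optional `intensity`,
#' `sequence`) or the DIA-NN/FragPipe and Spectronaut library dialects
#' (`PrecursorMz`, `IonMobility`, `PrecursorCharge`, optional
#' `LibraryIntensity`, `ModifiedPeptide`). Rows with missing or
#' non-numeric m/z, ion mobility, or charge (or values violating mz > 0,
#' im > 0, charge >= 1) are dropped and counted in the parse report.
#' Records are deduplicated on (sequence, charge) when a sequence column
#' is present, otherwise on (mz, im, charge); the first occurrence wins,
#' and row order otherwise follows the file.
#'
#' @param path Path to the library file.
#' @param format One of `"auto"`, `"generic"`, `"diann_fragpipe"`,
#'   `"spectronaut"`. `"auto"` resolves the dialect by header inspection
#'   and fails on ambiguity.
#' @return A `spectral_library`. The parse report (`$parse_report`)
#'   records rows read, dropped, and deduplicated.
#' @export
read_library <- function(path, format = c("auto", "generic",
                                          "diann_fragpipe", "spectronaut")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("library file not found: ", path)
  dt <- if (grepl("\\.gz$", path)) {
    con <- gzfile(path, "rt")
    on.exit(close(con), add = TRUE)
    data.table::fread(text = readLines(con), sep = "auto", header = TRUE,
                      colClasses = "character", showProgress = FALSE)
  } else {
    data.table::fread(path, sep = "auto", header = TRUE,
                      colClasses = "character", showProgress = FALSE)
  }
  if (format == "auto") format <- .resolve_dialect(names(dt))
  map <- .dialect_maps[[format]]
  required <- map[c("mz", "im", "charge")]
  missing_cols <- setdiff(required, names(dt))
  if (length(missing_cols) > 0) {
    stop("library file lacks required column(s) for dialect '", format,
         "': ", paste(missing_cols, collapse = ", "))
  }
  n_rows <- nrow(dt)
  rec <- data.frame(
    mz = suppressWarnings(as.numeric(dt[[map[["mz"]]]])),
    im = suppressWarnings(as.numeric(dt[[map[["im"]]]])),
    charge = suppressWarnings(as.integer(dt[[map[["charge"]]]]))
  )
  has_sequence <- map[["sequence"]] %in% names(dt)
  rec$intensity <- if (map[["intensity"]] %in% names(dt)) {
    ints <- suppressWarnings(as.numeric(dt[[map[["intensity"]]]]))
    ifelse(is.na(ints) | ints < 0, 1, ints)
  } else rep(1, n_rows)
  rec$sequence <- if (has_sequence) {
    s <- dt[[map[["sequence"]]]]
    ifelse(is.na(s) | s == "", NA_character_, s)
  } else rep(NA_character_, n_rows)
  rec$is_phospho <- .detect_phospho(rec$sequence)

  valid <- !is.na(rec$mz) & !is.na(rec$im) & !is.na(rec$charge) &
    rec$mz > 0 & rec$im > 0 & rec$charge >= 1L
  n_dropped <- sum(!valid)
  rec <- rec[valid, , drop = FALSE]

  key <- if (has_sequence && any(!is.na(rec$sequence))) {
    paste(rec$sequence, rec$charge, sep = "\r")
  } else {
    paste(rec$mz, rec$im, rec$charge, sep = "\r")
  }
  dup <- duplicated(key)
  n_duplicates <- sum(dup)
  rec <- rec[!dup, , drop = FALSE]

  if (nrow(rec) == 0) stop("no valid precursor records in ", path)
  new_spectral_library(
    rec, source_format = format,
    parse_report = list(n_rows = n_rows, n_dropped = n_dropped,
                        n_duplicates_removed = n_duplicates,
                        n_records = nrow(rec))
  )
}

#' Write a spectral library in the generic dialect
#'
#' Writes tab-separated columns `mz`, `im`, `charge`, `intensity`,
#' `sequence`. Numeric fields are printed with enough digits to
#' round-trip doubles exactly.
#'
#' @param lib A `spectral_library`.
#' @param path Output path (`.gz` extension compresses).
#' @return `path`, invisibly.
#' @export
write_library <- function(lib, path) {
  stopifnot(inherits(lib, "spectral_library"))
  rec <- lib$records
  out <- data.frame(
    mz = sprintf("%.17g", rec$mz),
    im = sprintf("%.17g", rec$im),
    charge = rec$charge,
    intensity = sprintf("%.17g", rec$intensity),
    sequence = ifelse(is.na(rec$sequence), "", rec$sequence)
  )
  data.table::fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Filter precursors by m/z, ion mobility and charge
#'
#' Retains records with `mz_range[1] <= mz <= mz_range[2]`,
#' `im_range[1] <= im <= im_range[2]` and charge in `charges`. An empty
#' result is returned with a warning, not an error. The applied filters
#' are recorded in `$filters_applied`.
#'
#' @param lib A `spectral_library`.
#' @param mz_range Ordered numeric interval (Th).
#' @param im_range Ordered numeric interval (1/K0).
#' @param charges Non-empty integer vector of charge states to keep.
#' @return Filtered `spectral_library`.
#' @export
filter_precursors <- function(lib, mz_range = c(300, 1200),
                              im_range = c(0.6, 1.5), charges = 2:4) {
  stopifnot(inherits(lib, "spectral_library"),
            length(mz_range) == 2, mz_range[1] <= mz_range[2],
            length(im_range) == 2, im_range[1] <= im_range[2],
            length(charges) >= 1)
  rec <- lib$records
  keep <- rec$mz >= mz_range[1] & rec$mz <= mz_range[2] &
    rec$im >= im_range[1] & rec$im <= im_range[2] &
    rec$charge %in% charges
  out <- rec[keep, , drop = FALSE]
  if (nrow(out) == 0) warning("no precursors pass the filters")
  new_spectral_library(
    out, source_format = lib$source_format,
    filters_applied = list(mz_range = mz_range, im_range = im_range,
                           charges = sort(unique(as.integer(charges)))),
    parse_report = lib$parse_report
  )
}

#' Summarize a spectral library
#'
#' @param lib A `spectral_library`.
#' @return A list with `n_records`, `per_charge` (named counts),
#'   `mz_range`, `im_range` (NA for an empty library) and
#'   `phospho_fraction`.
#' @export
library_summary <- function(lib) {
  stopifnot(inherits(lib, "spectral_library"))
  rec <- lib$records
  if (nrow(rec) == 0) {
    return(list(n_records = 0L, per_charge = integer(0),
                mz_range = c(NA_real_, NA_real_),
                im_range = c(NA_real_, NA_real_),
                phospho_fraction = NA_real_))
  }
  tab <- table(rec$charge)
  list(
    n_records = nrow(rec),
    per_charge = setNames(as.integer(tab), names(tab)),
    mz_range = range(rec$mz),
    im_range = range(rec$im),
    phospho_fraction = mean(rec$is_phospho)
  )
}
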