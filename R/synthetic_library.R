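#' Synthetic precursor clouds in the m/z - ion mobility plane
#'
#' Tryptic peptide precursors of a given charge form diagonal bands in
#' the m/z-1/K0 plane: ion mobility rises roughly linearly with m/z, and
#' higher charges sit on lower, flatter bands. `cloud_model()` captures
#' this as a per-charge mixture of linear im-on-mz trends with Gaussian
#' residuals over a truncated lognormal m/z marginal, and a phospho mode
#' that shifts the whole cloud towards higher m/z (the ~80 Da
#' phosphogroup at charge >= 2) and higher ion mobility.
#'
#' @param charge_weights Named mixture weights for charges 2..4; must
#'   sum to 1.
#' @param im_intercept,im_slope Named per-charge linear trend of 1/K0 on
#'   m/z.
#' @param im_sd Gaussian residual standard deviation around the trend
#'   (1/K0 units).
#' @param mz_meanlog,mz_sdlog Lognormal m/z marginal (median
#'   `exp(mz_meanlog)` Th).
#' @param mz_range,im_range Truncation bounds; generated records are
#'   rejection-sampled into these.
#' @param phospho If `TRUE`, apply `phospho_shift` and mark records as
#'   phosphopeptides.
#' @param phospho_shift Additive `(mz, im)` shift applied in phospho
#'   mode.
#' @param seed Integer seed; generation is reproducible bit-for-bit.
#' @return A `cloud_model` list.
#' @export
cloud_model <- function(charge_weights = c(`2` = 0.66, `3` = 0.27, `4` = 0.07),
                        im_intercept = c(`2` = 0.40, `3` = 0.30, `4` = 0.28),
                        im_slope = c(`2` = 0.00090, `3` = 0.00080, `4` = 0.00075),
                        im_sd = 0.045,
                        mz_meanlog = log(700), mz_sdlog = 0.30,
                        mz_range = if (phospho) c(400, 1400) else c(300, 1200),
                        im_range = c(0.6, 1.5),
                        phospho = FALSE,
                        phospho_shift = c(mz = 80, im = 0.03),
                        seed = 1L) {
  stopifnot(abs(sum(charge_weights) - 1) < 1e-8,
            all(names(charge_weights) %in% names(im_intercept)),
            all(names(charge_weights) %in% names(im_slope)),
            im_sd >= 0, mz_range[1] < mz_range[2], im_range[1] < im_range[2])
  structure(
    list(charge_weights = charge_weights, im_intercept = im_intercept,
         im_slope = im_slope, im_sd = im_sd,
         mz_meanlog = mz_meanlog, mz_sdlog = mz_sdlog,
         mz_range = mz_range, im_range = im_range,
         phospho = phospho, phospho_shift = phospho_shift,
         seed = as.integer(seed)),
    class = "cloud_model"
  )
}

#' Generate a synthetic spectral library from a cloud model
#'
#' Draws exactly `n` precursors from the model by rejection sampling
#' into the model's m/z and ion-mobility bounds. Identical seeds yield
#' identical libraries. In phospho mode every record is flagged
#' `is_phospho = TRUE`.
#'
#' @param model A [cloud_model()].
#' @param n Number of precursors (>= 1).
#' @return A `spectral_library`.
#' @export
generate_library <- function(model, n) {
  stopifnot(inherits(model, "cloud_model"), n >= 1)
  set.seed(model$seed)
  charges <- as.integer(names(model$charge_weights))
  shift_mz <- if (model$phospho) model$phospho_shift[["mz"]] else 0
  shift_im <- if (model$phospho) model$phospho_shift[["im"]] else 0

  out <- vector("list", 0)
  n_kept <- 0L
  n_drawn <- 0L
  while (n_kept < n) {
    batch <- max(1000L, ceiling((n - n_kept) * 1.5))
    z <- charges[sample.int(length(charges), batch, replace = TRUE,
                            prob = model$charge_weights)]
    # the phospho cloud is the proteome cloud translated by the
    # configured (mz, im) offsets: the trend is evaluated on the
    # unshifted mass
    mz_base <- rlnorm(batch, model$mz_meanlog, model$mz_sdlog)
    mz <- mz_base + shift_mz
    key <- as.character(z)
    im <- model$im_intercept[key] + model$im_slope[key] * mz_base +
      rnorm(batch, 0, model$im_sd) + shift_im
    ok <- mz >= model$mz_range[1] & mz <= model$mz_range[2] &
      im >= model$im_range[1] & im <= model$im_range[2]
    n_drawn <- n_drawn + batch
    if (any(ok)) {
      out[[length(out) + 1L]] <-
        data.frame(mz = mz[ok], im = im[ok], charge = z[ok])
      n_kept <- n_kept + sum(ok)
    }
    if (n_drawn >= 10000L && n_kept / n_drawn < 0.02) {
      stop("infeasible truncation: acceptance rate ",
           sprintf("%.3f", n_kept / n_drawn),
           " below 0.02; widen mz_range/im_range or adjust the trends")
    }
  }
  rec <- do.call(rbind, out)[seq_len(n), , drop = FALSE]
  rec$intensity <- 1
  rec$sequence <- NA_character_
  rec$is_phospho <- model$phospho
  new_spectral_library(rec, source_format = "generic",
                       parse_report = list(n_rows = n, n_dropped = 0L,
                                           n_duplicates_removed = 0L,
                                           n_records = n))
}

#' Generate precursors strictly inside a trapezoidal scan area
#'
#' Samples m/z uniformly over `mz_range` and ion mobility uniformly
#' between the trapezoid's bottom and top edges at that m/z, so every
#' record lies in the open interior of the trapezoid. Charges are 2 or 3
#' with equal probability. Used as an optimizer-recovery fixture: a
#' scheme tiling the same trapezoid covers this cloud completely.
#'
#' @param area A [scan_area()]; must have positive height at both ends.
#' @param mz_range Ordered m/z interval (Th).
#' @param n Number of precursors (>= 1).
#' @param seed Integer seed.
#' @return A `spectral_library`.
#' @export
generate_within_trapezoid <- function(area, mz_range, n, seed = 1L) {
  stopifnot(inherits(area, "scan_area"), n >= 1,
            length(mz_range) == 2, mz_range[1] < mz_range[2])
  if (area$im_top_left <= area$im_bottom_left ||
      area$im_top_right <= area$im_bottom_right) {
    stop("degenerate trapezoid: top edge does not lie above bottom edge")
  }
  set.seed(as.integer(seed))
  mz <- runif(n, mz_range[1], mz_range[2])
  lo <- strip_boundary_im(area, 0, mz, mz_range)
  hi <- strip_boundary_im(area, 1, mz, mz_range)
  im <- lo + runif(n) * (hi - lo)
  rec <- data.frame(mz = mz, im = im,
                    charge = sample(2:3, n, replace = TRUE),
                    intensity = 1, sequence = NA_character_,
                    is_phospho = FALSE)
  new_spectral_library(rec, source_format = "generic")
}
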