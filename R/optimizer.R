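#' Configuration for scan-area optimization
#'
#' @param n_trials Total number of objective evaluations (default 200,
#'   which in practice suffices for the four-corner search to settle).
#' @param n_initial_random Random evaluations before the surrogate
#'   model takes over.
#' @param seed Integer seed; the whole search is reproducible.
#' @param bounds Per-corner search interval (1/K0); defaults to the
#'   instrument ion-mobility range at build time.
#' @param initial_points Optional list of numeric length-4 vectors
#'   (bottom-left, bottom-right, top-left, top-right corners) evaluated
#'   first, counting towards `n_trials`.
#' @param proposer `"gp"` for Gaussian-process expected-improvement
#'   proposals, `"random"` for pure random search. Any function with
#'   signature `(bounds_matrix, X_history, y_history)` returning the
#'   next length-4 corner vector is also accepted.
#' @return An `optimization_config`.
#' @export
optimization_config <- function(n_trials = 200L, n_initial_random = 20L,
                                seed = 42L, bounds = NULL,
                                initial_points = NULL, proposer = "gp") {
  stopifnot(n_trials >= 1, n_initial_random >= 1,
            n_initial_random <= n_trials)
  structure(
    list(n_trials = as.integer(n_trials),
         n_initial_random = as.integer(n_initial_random),
         seed = as.integer(seed), bounds = bounds,
         initial_points = initial_points, proposer = proposer),
    class = "optimization_config"
  )
}

#' Coverage objective for a candidate set of trapezoid corners
#'
#' Builds the scheme for the candidate corners over fixed equal-density
#' bin edges and returns the covered fraction of the default evaluation
#' population. Geometrically invalid candidates (top edge at or below
#' the bottom edge at either end) score 0 instead of raising, so the
#' optimizer can search the full box.
#'
#' @param params Numeric length-4: `(im_bottom_left, im_bottom_right,
#'   im_top_left, im_top_right)`.
#' @param lib A `spectral_library`.
#' @param bin_edges Precomputed m/z bin edges (computed once per
#'   library; they do not depend on the scan area).
#' @param n_scans,windows_per_scan,im_range Scheme geometry, as in
#'   [build_scheme()].
#' @param charges Evaluation population charges.
#' @return Covered fraction in `[0, 1]`.
#' @export
coverage_objective <- function(params, lib, bin_edges, n_scans,
                               windows_per_scan, im_range = c(0.6, 1.5),
                               charges = 2:4) {
  stopifnot(length(params) == 4)
  if (params[3] <= params[1] || params[4] <= params[2]) return(0)
  area <- scan_area(params[1], params[2], params[3], params[4])
  scheme <- tryCatch(
    suppressWarnings(
      build_scheme(bin_edges, area, n_scans, windows_per_scan, im_range)
    ),
    error = function(e) NULL
  )
  if (is.null(scheme)) return(0)
  rec <- lib$records
  keep <- rec$charge %in% charges &
    rec$mz >= scheme$mz_range[1] & rec$mz <= scheme$mz_range[2] &
    rec$im >= im_range[1] & rec$im <= im_range[2]
  if (!any(keep)) return(0)
  mean(is_covered(rec[keep, , drop = FALSE], scheme))
}

# --- Gaussian-process surrogate -------------------------------------
# Zero-mean GP on inputs scaled to [0,1]^4, squared-exponential kernel,
# small nugget; the next candidate maximizes expected improvement over
# a random candidate pool. This mirrors the usual gp_minimize-style
# loop while staying dependency-free.

.gp_fit <- function(X, y, lengthscale = 0.25, nugget = 1e-6) {
  mu <- mean(y)
  yc <- y - mu
  s2 <- max(var(y), 1e-12)
  d2 <- as.matrix(stats::dist(X))^2
  K <- s2 * exp(-d2 / (2 * lengthscale^2)) + diag(nugget + 1e-10, nrow(X))
  L <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(L)) {
    K <- K + diag(1e-4, nrow(X))
    L <- chol(K)
  }
  alpha <- backsolve(L, forwardsolve(t(L), yc))
  list(X = X, L = L, alpha = alpha, mu = mu, s2 = s2,
       lengthscale = lengthscale)
}

.gp_predict <- function(fit, Xnew) {
  d2 <- outer(rowSums(Xnew^2), rowSums(fit$X^2), "+") -
    2 * Xnew %*% t(fit$X)
  d2[d2 < 0] <- 0
  Ks <- fit$s2 * exp(-d2 / (2 * fit$lengthscale^2))
  mean_pred <- as.numeric(Ks %*% fit$alpha) + fit$mu
  v <- forwardsolve(t(fit$L), t(Ks))
  var_pred <- pmax(fit$s2 - colSums(v^2), 1e-12)
  list(mean = mean_pred, sd = sqrt(var_pred))
}

.expected_improvement <- function(pred, y_best, xi = 0.01) {
  z <- (pred$mean - y_best - xi) / pred$sd
  (pred$mean - y_best - xi) * pnorm(z) + pred$sd * dnorm(z)
}

# propose the next corner vector (in original units)
.gp_propose <- function(bounds, X, y, n_candidates = 1000L) {
  lo <- bounds[, 1]
  span <- bounds[, 2] - bounds[, 1]
  scale01 <- function(M) sweep(sweep(M, 2, lo), 2, span, "/")
  if (length(unique(round(y, 12))) < 2) {
    return(lo + runif(4) * span)  # flat history: no gradient to exploit
  }
  fit <- .gp_fit(scale01(X), y)
  cand <- matrix(runif(n_candidates * 4), ncol = 4)
  # mix in local perturbations of the incumbent
  best <- scale01(X)[which.max(y), , drop = FALSE]
  local <- matrix(rnorm(200 * 4, mean = rep(best, each = 200), sd = 0.05),
                  ncol = 4)
  cand <- rbind(cand, pmin(pmax(local, 0), 1))
  ei <- .expected_improvement(.gp_predict(fit, cand), max(y))
  x <- cand[which.max(ei), ]
  lo + x * span
}

#' Optimize the scan-area corners for maximum precursor coverage
#'
#' Runs `n_initial_random` random corner draws (after any seeded
#' `initial_points`), then surrogate-guided proposals until `n_trials`
#' evaluations, maximizing [coverage_objective()]. The m/z bin edges
#' are computed once from the library and held fixed; only the
#' ion-mobility geometry is searched. A fixed seed makes the full trial
#' history reproducible.
#'
#' @param lib A non-empty `spectral_library`.
#' @param cfg An [optimization_config()].
#' @param n_scans,windows_per_scan,im_range,charges As in
#'   [coverage_objective()].
#' @param mz_range m/z interval used for the equal-density binning.
#' @return An `optimization_result` with `best_area`, `best_value`, the
#'   full `history` data frame (trial, four corners, value) and the
#'   seed.
#' @export
optimize_scan_area <- function(lib, cfg = optimization_config(),
                               n_scans = 12L, windows_per_scan = 2L,
                               mz_range = c(300, 1200),
                               im_range = c(0.6, 1.5), charges = 2:4) {
  stopifnot(inherits(lib, "spectral_library"),
            inherits(cfg, "optimization_config"))
  if (nrow(lib$records) == 0) stop("empty library")
  flib <- filter_precursors(lib, mz_range, im_range, charges)
  if (nrow(flib$records) == 0) stop("no precursors in the search population")
  edges <- equal_density_bin_edges(flib, n_scans * windows_per_scan, mz_range)

  bounds <- cfg$bounds
  if (is.null(bounds)) bounds <- im_range
  if (!is.matrix(bounds)) {
    stopifnot(length(bounds) == 2, bounds[1] < bounds[2])
    bounds <- matrix(rep(as.numeric(bounds), each = 4), ncol = 2)
  }
  stopifnot(nrow(bounds) == 4, ncol(bounds) == 2)

  obj <- function(p) {
    coverage_objective(p, flib, edges, n_scans, windows_per_scan,
                       im_range, charges)
  }

  set.seed(cfg$seed)
  n_init_pts <- length(cfg$initial_points)
  X <- matrix(NA_real_, nrow = cfg$n_trials, ncol = 4)
  y <- numeric(cfg$n_trials)
  kind <- character(cfg$n_trials)
  proposer <- cfg$proposer
  for (t in seq_len(cfg$n_trials)) {
    if (t <= n_init_pts) {
      x <- as.numeric(cfg$initial_points[[t]])
      kind[t] <- "seeded"
    } else if (t <= n_init_pts + cfg$n_initial_random) {
      x <- bounds[, 1] + runif(4) * (bounds[, 2] - bounds[, 1])
      kind[t] <- "random"
    } else if (is.function(proposer)) {
      x <- as.numeric(proposer(bounds, X[seq_len(t - 1), , drop = FALSE],
                               y[seq_len(t - 1)]))
      kind[t] <- "custom"
    } else if (identical(proposer, "random")) {
      x <- bounds[, 1] + runif(4) * (bounds[, 2] - bounds[, 1])
      kind[t] <- "random"
    } else {
      x <- .gp_propose(bounds, X[seq_len(t - 1), , drop = FALSE],
                       y[seq_len(t - 1)])
      kind[t] <- "gp"
    }
    X[t, ] <- x
    y[t] <- obj(x)
  }
  if (all(y == 0)) {
    stop("all ", cfg$n_trials, " trials were geometrically invalid or ",
         "covered no precursors; check bounds and library ranges")
  }
  best <- which.max(y)
  history <- data.frame(
    trial = seq_len(cfg$n_trials),
    im_bottom_left = X[, 1], im_bottom_right = X[, 2],
    im_top_left = X[, 3], im_top_right = X[, 4],
    value = y, proposal = kind
  )
  structure(
    list(best_area = scan_area(X[best, 1], X[best, 2], X[best, 3],
                               X[best, 4]),
         best_value = y[best], history = history, seed = cfg$seed,
         bin_edges = edges),
    class = "optimization_result"
  )
}

#' @export
print.optimization_result <- function(x, ...) {
  cat(sprintf(
    "Scan-area optimization: best coverage %.3f after %d trials (seed %d)\n",
    x$best_value, nrow(x$history), x$seed))
  print(x$best_area)
  invisible(x)
}

#' Exhaustive grid search over the scan-area corners
#'
#' Evaluates every combination of `resolution` equispaced values per
#' corner over the ion-mobility range (invalid geometries score 0).
#' Deterministic; serves as an independent check on the surrogate
#' search.
#'
#' @inheritParams optimize_scan_area
#' @param resolution Grid points per corner dimension (>= 2).
#' @return An `optimization_result` (`history` holds all grid points).
#' @export
grid_search_oracle <- function(lib, resolution = 7L, n_scans = 12L,
                               windows_per_scan = 2L,
                               mz_range = c(300, 1200),
                               im_range = c(0.6, 1.5), charges = 2:4) {
  stopifnot(inherits(lib, "spectral_library"), resolution >= 2)
  flib <- filter_precursors(lib, mz_range, im_range, charges)
  edges <- equal_density_bin_edges(flib, n_scans * windows_per_scan, mz_range)
  vals <- seq(im_range[1], im_range[2], length.out = resolution)
  grid <- as.matrix(expand.grid(bl = vals, br = vals, tl = vals, tr = vals))
  y <- apply(grid, 1, function(p) {
    coverage_objective(p, flib, edges, n_scans, windows_per_scan,
                       im_range, charges)
  })
  best <- which.max(y)
  history <- data.frame(
    trial = seq_len(nrow(grid)),
    im_bottom_left = grid[, 1], im_bottom_right = grid[, 2],
    im_top_left = grid[, 3], im_top_right = grid[, 4],
    value = y, proposal = "grid"
  )
  structure(
    list(best_area = scan_area(grid[best, 1], grid[best, 2],
                               grid[best, 3], grid[best, 4]),
         best_value = y[best], history = history, seed = NA_integer_,
         bin_edges = edges),
    class = "optimization_result"
  )
}

#' Export an optimization history as TSV
#'
#' @param result An `optimization_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_optimization_history <- function(result, path) {
  stopifnot(inherits(result, "optimization_result"))
  data.table::fwrite(result$history, path, sep = "\t")
  invisible(path)
}
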