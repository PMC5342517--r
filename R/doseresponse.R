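# Viability curves and the four response measures.
#
# Two routes from counts to response summaries:
#   * piecewise-linear: per-replicate trapezoid AUC and segment-interpolated
#     IC50, summarized by the replicate median;
#   * model-based: AUC and IC50 of the fitted hormetic curve, estimated on
#     all replicate points jointly (see fit.R).

#' Validate a dose grid
#'
#' A dose grid is a strictly increasing concentration vector (µM) whose first
#' element is 0 (the vehicle control) with at least 3 points.
#'
#' @param conc Numeric vector of concentrations.
#' @return The validated grid, invisibly usable as-is.
#' @export
dose_grid <- function(conc) {
  conc <- as.numeric(conc)
  if (length(conc) < 3L) stop("dose grid needs at least 3 concentrations")
  if (anyNA(conc)) stop("dose grid contains NA")
  if (conc[1] != 0) stop("dose grid must start at 0 (vehicle control)")
  if (any(diff(conc) <= 0)) stop("dose grid must be strictly increasing")
  conc
}

#' Convert raw counts to a control-normalized viability curve
#'
#' Each replicate is normalized to its own untreated-control well, so
#' viability is exactly 1 at dose 0.
#'
#' @param counts Nonnegative cell counts, aligned to `grid`.
#' @param grid A [dose_grid()].
#' @param sample,replicate Identifiers carried through for reporting.
#' @return An object of class `"viability_curve"`: a list with `sample`,
#'   `replicate`, `conc` and `viability`.
#' @export
normalize_counts <- function(counts, grid, sample = NA_character_,
                             replicate = NA_integer_) {
  grid <- dose_grid(grid)
  counts <- as.numeric(counts)
  if (length(counts) != length(grid))
    stop("counts and dose grid lengths differ")
  if (anyNA(counts) || any(counts < 0))
    stop(sprintf("negative or missing count for sample %s replicate %s",
                 sample, replicate))
  if (counts[1] <= 0)
    stop(sprintf("control (dose 0) count is not positive for sample %s replicate %s",
                 sample, replicate))
  structure(list(sample = sample, replicate = replicate, conc = grid,
                 viability = counts / counts[1]),
            class = "viability_curve")
}

viability_curve <- function(conc, viability, sample = NA_character_,
                            replicate = NA_integer_) {
  conc <- dose_grid(conc)
  viability <- as.numeric(viability)
  if (length(viability) != length(conc))
    stop("viability and dose grid lengths differ")
  if (anyNA(viability) || any(viability < 0))
    stop("viability must be nonnegative")
  if (viability[1] != 1) stop("viability at dose 0 must be exactly 1")
  structure(list(sample = sample, replicate = replicate, conc = conc,
                 viability = viability),
            class = "viability_curve")
}

#' Trapezoidal area under a viability curve
#'
#' @param curve A `"viability_curve"` from [normalize_counts()].
#' @return Area in µM x viability units over the observed grid.
#' @export
trapezoid_auc <- function(curve) {
  x <- curve$conc; y <- curve$viability
  if (length(x) != length(y)) stop("grid/viability length mismatch")
  sum(diff(x) * (y[-length(y)] + y[-1]) / 2)
}

#' Interpolated IC50 of a piecewise-linear viability curve
#'
#' Scans segments in order of increasing concentration and linearly
#' interpolates to viability 0.5 within the first segment whose endpoints
#' bracket 0.5 with a downward crossing. Curves that never reach 0.5 are
#' censored at the maximum tested concentration.
#'
#' @param curve A `"viability_curve"`.
#' @return A list with `ic50` (µM) and `censored` (logical).
#' @export
interpolate_ic50 <- function(curve) {
  x <- curve$conc; y <- curve$viability
  for (i in seq_len(length(x) - 1L)) {
    if (y[i] >= 0.5 && y[i + 1L] <= 0.5 && y[i] > y[i + 1L]) {
      ic50 <- x[i] + (y[i] - 0.5) / (y[i] - y[i + 1L]) * (x[i + 1L] - x[i])
      return(list(ic50 = ic50, censored = FALSE))
    }
  }
  list(ic50 = max(x), censored = TRUE)
}

#' Replicate-median response summaries
#'
#' The piecewise-linear AUC and IC50 are computed per replicate and the
#' component-wise median is reported. Censored replicate IC50s contribute
#' their censoring value (the maximum concentration); the summary is flagged
#' censored when at least half of the replicates are censored.
#'
#' @param aucs Numeric vector of per-replicate trapezoid AUCs.
#' @param ic50s Numeric vector of per-replicate IC50s (censored ones at the
#'   maximum concentration).
#' @param censored Logical vector aligned to `ic50s`.
#' @return A list with `auc_trap`, `ic50_trap` and `ic50_censored`.
#' @export
median_measures <- function(aucs, ic50s, censored = rep(FALSE, length(ic50s))) {
  if (length(aucs) < 1L || length(ic50s) < 1L)
    stop("at least one replicate is required")
  if (length(ic50s) != length(censored))
    stop("ic50s and censored lengths differ")
  list(auc_trap = stats::median(aucs),
       ic50_trap = stats::median(ic50s),
       ic50_censored = mean(censored) >= 0.5)
}

#' Area under the fitted hormetic curve
#'
#' Integrates the fitted model over `[0, cmax]` by adaptive quadrature.
#'
#' @param fit A `"hormetic_fit"` (or bare [hormetic_params()]).
#' @param cmax Upper end of the concentration range (µM, > 0).
#' @return The fitted AUC.
#' @export
fitted_auc <- function(fit, cmax) {
  if (!is.numeric(cmax) || length(cmax) != 1L || !is.finite(cmax) || cmax <= 0)
    stop("cmax must be a single positive concentration")
  p <- if (inherits(fit, "hormetic_fit")) fit$params else as_hormetic_params(fit)
  stats::integrate(function(c) hormetic_model(c, p), 0, cmax,
                   rel.tol = 1e-10, abs.tol = 1e-12,
                   subdivisions = 500L)$value
}

#' IC50 of the fitted hormetic curve
#'
#' Finds the smallest concentration in `[0, cmax]` where the fitted curve
#' crosses viability 0.5 downwards, by bracketing on a 1000-point grid
#' followed by bisection to 1e-8 µM. Curves that never cross are censored at
#' `cmax`.
#'
#' @inheritParams fitted_auc
#' @return A list with `ic50` and `censored`.
#' @export
fitted_ic50 <- function(fit, cmax) {
  if (!is.numeric(cmax) || length(cmax) != 1L || !is.finite(cmax) || cmax <= 0)
    stop("cmax must be a single positive concentration")
  p <- if (inherits(fit, "hormetic_fit")) fit$params else as_hormetic_params(fit)
  grid <- seq(0, cmax, length.out = 1000L)
  v <- hormetic_model(grid, p)
  for (i in seq_len(length(grid) - 1L)) {
    if (v[i] >= 0.5 && v[i + 1L] <= 0.5 && v[i] > v[i + 1L]) {
      if (v[i] == 0.5) return(list(ic50 = grid[i], censored = FALSE))
      root <- stats::uniroot(function(c) hormetic_model(c, p) - 0.5,
                             lower = grid[i], upper = grid[i + 1L],
                             tol = 1e-10)$root
      return(list(ic50 = root, censored = FALSE))
    }
  }
  list(ic50 = cmax, censored = TRUE)
}
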