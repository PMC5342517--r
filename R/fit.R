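# Nonlinear least-squares estimation of the five hormetic parameters.
#
# Primary path: bounded L-BFGS-B from a small set of deterministic heuristic
# starts. The fit is declared converged when the optimizer reports success,
# the RSS is finite, and no shape-critical parameter is pinned to a sampling
# bound (a bound-pinned slope is the signature of step-like fast responders,
# for which the logistic is not steep enough at zero concentration under any
# interior parametrization). Non-converged fits fall back to the minimum-RSS
# solution over `n_samplings` random parameter draws.

hm_bounds <- function(cmax) {
  list(lower = c(mu = 0, sigma = 1e-3, shift = -cmax / 2, slope = 1e-3,
                 amp = 0),
       upper = c(mu = cmax, sigma = cmax / 2, shift = 2 * cmax, slope = 20,
                 amp = 5))
}

hm_rss <- function(par, conc, viability) {
  r <- viability - hormetic_model(conc, hm_par_unchecked(par))
  sum(r * r)
}

# Internal fast path: skip constructor validation inside the optimizer loop.
hm_par_unchecked <- function(p) {
  structure(c(mu = p[[1]], sigma = p[[2]], shift = p[[3]], slope = p[[4]],
              amp = p[[5]]), class = "hormetic_params")
}

# analytic gradient of the residual sum of squares
hm_rss_grad <- function(par, conc, viability) {
  mu <- par[[1]]; sg <- par[[2]]; sh <- par[[3]]; sl <- par[[4]]; am <- par[[5]]
  s <- stats::plogis(-sl * (conc - sh))
  phi <- stats::dnorm(conc, mu, sg)
  r <- viability - (s + am * phi)
  sp <- s * (1 - s)
  z <- (conc - mu) / sg
  -2 * c(mu = sum(r * am * phi * z / sg),
         sigma = sum(r * am * phi * (z * z - 1) / sg),
         shift = sum(r * sp * sl),
         slope = -sum(r * sp * (conc - sh)),
         amp = sum(r * phi))
}

hm_optim <- function(start, conc, viability, bounds, maxit = 1000L,
                     factr = 1e4) {
  o <- try(stats::optim(start, hm_rss, gr = hm_rss_grad, conc = conc,
                        viability = viability, method = "L-BFGS-B",
                        lower = bounds$lower, upper = bounds$upper,
                        control = list(maxit = maxit, factr = factr)),
           silent = TRUE)
  if (inherits(o, "try-error")) return(NULL)
  o
}

# Deterministic heuristic starts: peak position from the empirical maximum,
# logistic midpoint from the empirical half-viability dose, plus two generic
# fallback shapes.
hm_starts <- function(conc, viability, cmax) {
  imax <- which.max(viability)
  half <- conc[which.min(abs(viability - 0.5))]
  list(
    c(mu = min(conc[imax], cmax), sigma = cmax / 10, shift = half, slope = 1,
      amp = max(0.05, (max(viability) - 1) * cmax / 8)),
    c(mu = cmax / 8, sigma = cmax / 16, shift = cmax / 2, slope = 2,
      amp = 0.01),
    c(mu = cmax / 4, sigma = cmax / 5, shift = 0.6 * cmax, slope = 0.7,
      amp = 1)
  )
}

hm_converged <- function(o, bounds, tol = 1e-6) {
  if (is.null(o) || o$convergence != 0L || !is.finite(o$value)) return(FALSE)
  p <- o$par
  # slope pinned to its ceiling means the optimizer ran out of steepness,
  # not that it found a stationary point
  if (p[[4]] >= bounds$upper[["slope"]] - tol) return(FALSE)
  # with a material peak component (height > 2% of control viability), a
  # bound-pinned sigma or amp ceiling is equally non-stationary; amp = 0
  # and negligible peaks are legitimate boundary solutions
  peak_height <- p[[5]] / (p[[2]] * sqrt(2 * pi))
  if (is.finite(peak_height) && peak_height > 0.02) {
    if (p[[2]] <= bounds$lower[["sigma"]] + tol ||
        p[[2]] >= bounds$upper[["sigma"]] - tol) return(FALSE)
    if (p[[5]] >= bounds$upper[["amp"]] - tol) return(FALSE)
  }
  TRUE
}

hm_fit_obj <- function(o, method, converged, n_points) {
  structure(list(params = hm_par_unchecked(o$par), rss = o$value,
                 converged = converged, method = method,
                 n_points = n_points),
            class = "hormetic_fit")
}

#' Fit the five-parameter hormetic model to one sample
#'
#' All replicate (concentration, viability) points of a sample enter the
#' estimation jointly. Minimizes the residual sum of squares under bound
#' constraints (`sigma`, `slope` > 0, `amp` >= 0). When the primary bounded
#' fit does not converge to an interior optimum -- typical for step-like
#' fast responders -- the minimum-RSS solution over [random_restart_fit()]
#' is returned with `method = "random_restart"`.
#'
#' @param conc Concentrations (µM), one entry per replicate point.
#' @param viability Control-normalized viabilities aligned to `conc`.
#' @param n_samplings Number of random parameter draws in the fallback.
#' @param polish If `TRUE` each random draw seeds a bounded local
#'   minimization; if `FALSE` draws are evaluated directly.
#' @param seed Optional integer; when given, the fallback's draws are made
#'   reproducible without touching the caller's RNG stream.
#' @return A `"hormetic_fit"`: `params`, `rss`, `converged`, `method`
#'   (`"nls"` or `"random_restart"`) and `n_points`.
#' @export
fit_hormetic <- function(conc, viability, n_samplings = 500L, polish = TRUE,
                         seed = NULL) {
  conc <- as.numeric(conc); viability <- as.numeric(viability)
  if (length(conc) != length(viability))
    stop("conc and viability lengths differ")
  if (length(conc) < 6L)
    stop("at least 6 points are required to estimate 5 parameters")
  cmax <- max(conc)
  bounds <- hm_bounds(cmax)
  fits <- Filter(Negate(is.null),
                 lapply(hm_starts(conc, viability, cmax), hm_optim,
                        conc = conc, viability = viability, bounds = bounds))
  if (length(fits)) {
    best <- fits[[which.min(vapply(fits, `[[`, 0, "value"))]]
    if (hm_converged(best, bounds))
      return(hm_fit_obj(best, "nls", TRUE, length(conc)))
  }
  incumbent <- if (length(fits))
    fits[[which.min(vapply(fits, `[[`, 0, "value"))]]$par else NULL
  fb <- random_restart_fit(conc, viability, n_samplings = n_samplings,
                           polish = polish, seed = seed,
                           extra_starts = incumbent)
  fb$converged <- FALSE  # records that the primary path failed
  fb
}

#' Random-restart fallback fit
#'
#' Draws `n_samplings` parameter vectors uniformly from the sampling ranges
#' (`mu` in \[0, cmax\], `sigma` in (0, cmax/2\], `shift` in
#' \[-cmax/2, 2 cmax\], `slope` in (0, 20\], `amp` in \[0, 5\]), optionally
#' polishes each by bounded local minimization, and returns the minimum-RSS
#' solution.
#'
#' @inheritParams fit_hormetic
#' @param starts Optional matrix (one row per start, columns mu, sigma,
#'   shift, slope, amp) replacing the random draws, e.g. to restart from
#'   known parameter vectors.
#' @param extra_starts Optional additional start vector(s) always included
#'   among the polished candidates (used by [fit_hormetic()] to carry its
#'   primary-path incumbent, so the returned RSS never exceeds it).
#' @param n_polish Number of lowest-RSS draws seeding local minimization
#'   when `polish = TRUE`.
#' @export
random_restart_fit <- function(conc, viability, n_samplings = 500L,
                               polish = TRUE, seed = NULL, starts = NULL,
                               extra_starts = NULL, n_polish = 20L) {
  conc <- as.numeric(conc); viability <- as.numeric(viability)
  if (length(conc) != length(viability))
    stop("conc and viability lengths differ")
  if (length(conc) < 6L)
    stop("at least 6 points are required to estimate 5 parameters")
  if (n_samplings < 1L) stop("n_samplings must be >= 1")
  cmax <- max(conc)
  bounds <- hm_bounds(cmax)
  pnames <- c("mu", "sigma", "shift", "slope", "amp")
  run <- function() {
    if (is.null(starts)) {
      draws <- matrix(stats::runif(5L * n_samplings,
                                   min = rep(bounds$lower, each = n_samplings),
                                   max = rep(bounds$upper, each = n_samplings)),
                      ncol = 5L, dimnames = list(NULL, pnames))
    } else {
      draws <- matrix(as.numeric(starts), ncol = 5L,
                      dimnames = list(NULL, pnames))
    }
    if (!is.null(extra_starts))
      draws <- rbind(draws, matrix(as.numeric(extra_starts), ncol = 5L,
                                   dimnames = list(NULL, pnames)))
    rss_raw <- apply(draws, 1L, hm_rss, conc = conc, viability = viability)
    best_i <- which.min(rss_raw)
    best <- list(par = draws[best_i, ], value = rss_raw[best_i],
                 convergence = 0L)
    if (polish) {
      for (i in utils::head(order(rss_raw), n_polish)) {
        o <- hm_optim(draws[i, ], conc, viability, bounds, maxit = 200L,
                      factr = 1e7)
        if (!is.null(o) && is.finite(o$value) && o$value < best$value)
          best <- o
      }
    }
    # final tight polish of the incumbent
    ofin <- hm_optim(best$par, conc, viability, bounds)
    if (!is.null(ofin) && ofin$value <= best$value) best <- ofin
    best
  }
  best <- if (is.null(seed)) run() else with_private_seed(seed, run())
  hm_fit_obj(best, "random_restart",
             converged = best$convergence == 0L && is.finite(best$value),
             n_points = length(conc))
}
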