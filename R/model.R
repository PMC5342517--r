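# Five-parameter hormetic dose-response model:
#   v(c) = 1 / (1 + exp(slope * (c - shift))) + amp * dnorm(c, mu, sigma)
# The logistic term (asymptotes fixed at 1 and 0 on control-normalized
# viability) carries the monotone decline; the scaled normal density carries
# an optional low-dose growth peak.

#' Construct and validate hormetic model parameters
#'
#' @param mu Mean of the normal-density peak component (µM).
#' @param sigma Standard deviation of the peak component (µM, > 0).
#' @param shift Midpoint of the logistic decline (µM); for `amp = 0` the
#'   fitted IC50 equals `shift` exactly.
#' @param slope Steepness of the logistic decline (1/µM, > 0; larger is
#'   steeper).
#' @param amp Nonnegative proportionality coefficient scaling the
#'   normal-density contribution. `amp = 0` reduces the model to the
#'   two-parameter sigmoid.
#'
#' @return A named numeric vector of class `"hormetic_params"`.
#' @export
#' @examples
#' p <- hormetic_params(mu = 1, sigma = 0.5, shift = 4, slope = 2, amp = 0.8)
#' hormetic_model(c(0, 1, 4, 8), p)
hormetic_params <- function(mu, sigma, shift, slope, amp) {
  p <- c(mu = as.numeric(mu), sigma = as.numeric(sigma),
         shift = as.numeric(shift), slope = as.numeric(slope),
         amp = as.numeric(amp))
  if (anyNA(p) || any(!is.finite(p))) stop("hormetic parameters must be finite")
  if (p[["sigma"]] <= 0) stop("sigma must be > 0")
  if (p[["slope"]] <= 0) stop("slope must be > 0")
  if (p[["amp"]] < 0) stop("amp must be >= 0")
  structure(p, class = "hormetic_params")
}

as_hormetic_params <- function(p) {
  if (inherits(p, "hormetic_params")) return(p)
  if (is.list(p)) p <- unlist(p)
  hormetic_params(p[["mu"]], p[["sigma"]], p[["shift"]], p[["slope"]],
                  p[["amp"]])
}

#' Evaluate the hormetic dose-response model
#'
#' @param conc Numeric vector of concentrations (µM).
#' @param params A [hormetic_params()] object (or coercible named vector).
#' @return Predicted viabilities (dimensionless, 1 = untreated control).
#' @export
hormetic_model <- function(conc, params) {
  p <- as_hormetic_params(params)
  # logistic written via plogis for numerical stability at extreme slopes
  stats::plogis(-p[["slope"]] * (conc - p[["shift"]])) +
    p[["amp"]] * stats::dnorm(conc, p[["mu"]], p[["sigma"]])
}

# Exact integral of the model over [0, cmax]: logistic antiderivative plus
# amp-scaled normal CDF difference.  Used internally for planting synthetic
# ground truth; the user-facing fitted_auc() integrates numerically.
hormetic_auc_exact <- function(params, cmax) {
  p <- as_hormetic_params(params)
  s <- p[["slope"]]; h <- p[["shift"]]
  logistic_part <- (log1pexp(s * h) - log1pexp(-s * (cmax - h))) / s
  peak_part <- p[["amp"]] *
    (stats::pnorm(cmax, p[["mu"]], p[["sigma"]]) -
       stats::pnorm(0, p[["mu"]], p[["sigma"]]))
  logistic_part + peak_part
}
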