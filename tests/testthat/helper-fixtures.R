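# Shared fixtures: everything is generated in code at test time.

DEFAULT_GRID <- c(0, 0.5, 1, 2, 3, 4, 6, 8)

make_curve <- function(viability, conc = NULL) {
  if (is.null(conc)) conc <- DEFAULT_GRID[seq_along(viability)]
  hormetrics:::viability_curve(conc, viability)
}

# random monotone-ish viability curve on an n-point grid, viability[1] = 1
random_curve <- function(n = 8, cmax = 8) {
  conc <- c(0, sort(runif(n - 1, 0.1, cmax)))
  v <- c(1, runif(n - 1, 0, 1.6))
  make_curve(v, conc)
}

random_params <- function() {
  hormetic_params(mu = runif(1, 0, 8), sigma = runif(1, 0.1, 4),
                  shift = runif(1, -4, 16), slope = runif(1, 0.05, 15),
                  amp = runif(1, 0, 5))
}

# independent closed-form AUC oracle: logistic antiderivative + normal CDF
closed_form_auc <- function(p, cmax) {
  s <- p[["slope"]]; h <- p[["shift"]]
  l1p <- function(x) ifelse(x > 30, x, log1p(exp(x)))
  (l1p(s * h) - l1p(-s * (cmax - h))) / s +
    p[["amp"]] * (pnorm(cmax, p[["mu"]], p[["sigma"]]) -
                    pnorm(0, p[["mu"]], p[["sigma"]]))
}

# small, fast cohort for pipeline-level tests
quick_config <- function(seed = 1L, ...) {
  cohort_config(n_samples = 10L, n_genes_mutation = 30L,
                n_genes_expression = 200L, n_drugs = 10L,
                n_hypermutants = 3L, n_collinear_groups = 2L,
                rng_seed = seed, ...)
}

# brute-force O(genes^2) collinearity oracle: pairwise column comparison
brute_force_collinear <- function(mat) {
  g <- ncol(mat)
  assigned <- rep(NA_integer_, g)
  gid <- 0L
  for (i in seq_len(g)) {
    if (!is.na(assigned[i])) next
    gid <- gid + 1L
    assigned[i] <- gid
    if (i < g) for (j in (i + 1L):g)
      if (is.na(assigned[j]) && all(mat[, i] == mat[, j])) assigned[j] <- gid
  }
  split(colnames(mat), assigned)
}
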