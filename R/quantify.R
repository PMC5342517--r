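# Cohort-level quantification: long-format count table in, one row of the
# four response measures (plus fit diagnostics) per sample out.

#' Compute the four viability measures for every sample of a cohort
#'
#' Per replicate, counts are control-normalized and summarized by trapezoid
#' AUC and interpolated IC50 (replicate medians). Per sample, the hormetic
#' model is fitted to all replicate points jointly and integrated/inverted
#' for the fitted AUC and IC50 on `[0, cmax]`.
#'
#' @param counts Long data frame: `sample`, `replicate`, `dose_uM`, `count`.
#' @param grid Optional [dose_grid()]; defaults to the sorted unique doses.
#' @param n_samplings Random restarts for non-converging fits.
#' @param polish Polish random restarts by local minimization.
#' @param seed Optional integer; per-sample fallback seeds are derived from
#'   it so single samples can be re-fit reproducibly.
#' @return A list with `measures` (data frame: sample, the four measures,
#'   censor flags, fit parameters, rss, converged, method) and `fits`
#'   (named list of `"hormetic_fit"`).
#' @export
quantify_cohort <- function(counts, grid = NULL, n_samplings = 500L,
                            polish = TRUE, seed = NULL) {
  need <- c("sample", "replicate", "dose_uM", "count")
  if (!all(need %in% names(counts)))
    stop("counts table lacks column(s): ",
         paste(setdiff(need, names(counts)), collapse = ", "))
  if (is.null(grid)) grid <- sort(unique(counts$dose_uM))
  grid <- dose_grid(grid)
  cmax <- max(grid)
  samples <- unique(counts$sample)
  fits <- list()
  rows <- vector("list", length(samples))
  for (si in seq_along(samples)) {
    s <- samples[si]
    sub <- counts[counts$sample == s, , drop = FALSE]
    reps <- unique(sub$replicate)
    aucs <- numeric(0); ic50s <- numeric(0); cens <- logical(0)
    all_c <- numeric(0); all_v <- numeric(0)
    for (r in reps) {
      rsub <- sub[sub$replicate == r, , drop = FALSE]
      rsub <- rsub[order(rsub$dose_uM), , drop = FALSE]
      if (!isTRUE(all.equal(rsub$dose_uM, grid)))
        stop(sprintf("sample %s replicate %s does not cover the dose grid",
                     s, r))
      curve <- normalize_counts(rsub$count, grid, sample = s, replicate = r)
      aucs <- c(aucs, trapezoid_auc(curve))
      ic <- interpolate_ic50(curve)
      ic50s <- c(ic50s, ic$ic50); cens <- c(cens, ic$censored)
      all_c <- c(all_c, curve$conc); all_v <- c(all_v, curve$viability)
    }
    med <- median_measures(aucs, ic50s, cens)
    fit_seed <- if (is.null(seed)) NULL else as.integer((seed + 977L * si) %%
                                                          2147483647L)
    fit <- fit_hormetic(all_c, all_v, n_samplings = n_samplings,
                        polish = polish, seed = fit_seed)
    fits[[s]] <- fit
    fauc <- fitted_auc(fit, cmax)
    fic <- fitted_ic50(fit, cmax)
    p <- fit$params
    c1 <- min(grid[grid > 0])
    rows[[si]] <- data.frame(
      sample = s, auc_trap = med$auc_trap, ic50_trap = med$ic50_trap,
      auc_fit = fauc, ic50_fit = fic$ic50,
      ic50_trap_censored = med$ic50_censored,
      ic50_fit_censored = fic$censored,
      v_lowest = hormetic_model(c1, p),
      mu = p[["mu"]], sigma = p[["sigma"]], shift = p[["shift"]],
      slope = p[["slope"]], amp = p[["amp"]], rss = fit$rss,
      converged = fit$converged, method = fit$method,
      stringsAsFactors = FALSE)
  }
  measures <- do.call(rbind, rows)
  rownames(measures) <- NULL
  list(measures = measures, fits = fits)
}
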