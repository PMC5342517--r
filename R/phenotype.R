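# Monotonicity classification and the monotonous vs non-monotonous group
# comparison: per-mutation chi-square tests and an empirical-Bayes moderated
# two-group comparison of expression (variance shrinkage toward a common
# prior, needed at the tiny group sizes organoid panels produce).

#' Classify a sample as monotonous or non-monotonous responder
#'
#' A sample is a non-monotonous (hormetic) responder when its fitted curve
#' at the lowest nonzero tested concentration is at least 1.5 times the
#' untreated control (inclusive threshold).
#'
#' @param fit A `"hormetic_fit"` for the sample.
#' @param grid The [dose_grid()] the sample was tested on.
#' @param threshold Viability ratio defining non-monotonicity.
#' @param sample Optional sample id carried through.
#' @return A list with `sample`, `v_lowest` (fitted viability at the lowest
#'   nonzero dose) and `label` (`"monotonous"` or `"non_monotonous"`).
#' @export
classify_monotonicity <- function(fit, grid, threshold = 1.5,
                                  sample = NA_character_) {
  grid <- dose_grid(grid)
  c1 <- min(grid[grid > 0])
  p <- if (inherits(fit, "hormetic_fit")) fit$params else as_hormetic_params(fit)
  v1 <- hormetic_model(c1, p)
  list(sample = sample, v_lowest = v1,
       label = if (v1 >= threshold) "non_monotonous" else "monotonous")
}

#' Per-mutation chi-square test between two sample groups
#'
#' For each gene, tests independence of mutation status and group membership
#' in the 2x2 contingency table, without continuity correction (df = 1).
#' Genes with a zero marginal (never or always mutated, or an empty group)
#' are degenerate and reported with statistic 0 and p = 1.
#'
#' @param mat Binary mutation matrix (samples x genes).
#' @param labels Two-level factor/character vector aligned to rows.
#' @return Data frame: `gene`, `statistic`, `p`, `degenerate`.
#' @export
chisq_per_mutation <- function(mat, labels) {
  labels <- as.factor(labels)
  if (nlevels(labels) != 2L)
    stop("labels must have exactly two levels")
  if (length(labels) != nrow(mat))
    stop("labels length must match matrix rows")
  g2 <- labels == levels(labels)[2]
  n <- nrow(mat)
  small_expected <- 0L
  res <- lapply(colnames(mat), function(gene) {
    x <- mat[, gene]
    a <- sum(x == 1 & !g2); b <- sum(x == 1 & g2)
    c_ <- sum(x == 0 & !g2); d <- sum(x == 0 & g2)
    r1 <- a + b; r2 <- c_ + d; c1 <- a + c_; c2 <- b + d
    if (r1 == 0L || r2 == 0L || c1 == 0L || c2 == 0L)
      return(data.frame(gene = gene, statistic = 0, p = 1,
                        degenerate = TRUE))
    expected <- outer(c(r1, r2), c(c1, c2)) / n
    if (any(expected < 5)) small_expected <<- small_expected + 1L
    stat <- n * (a * d - b * c_)^2 / (r1 * r2 * c1 * c2)
    data.frame(gene = gene, statistic = stat,
               p = stats::pchisq(stat, df = 1L, lower.tail = FALSE),
               degenerate = FALSE)
  })
  if (small_expected > 0L)
    warning(sprintf("%d gene(s) have expected cell counts below 5; chi-square p-values are approximate",
                    small_expected))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

# Newton solve of trigamma(y) = x for y > 0 (monotone decreasing).
trigamma_inverse <- function(x) {
  vapply(x, function(xi) {
    if (!is.finite(xi) || xi <= 0) return(Inf)
    if (xi > 1e7) return(1 / sqrt(xi))
    if (xi < 1e-6) return(1 / xi)
    y <- 0.5 + 1 / xi
    for (iter in 1:50) {
      tri <- trigamma(y)
      dif <- tri * (1 - tri / xi) / psigamma(y, deriv = 2L)
      y <- y + dif
      if (abs(dif) < 1e-10 * y) break
    }
    y
  }, 0)
}

# Empirical-Bayes squeeze of per-gene variances toward a common prior:
# moment estimation of (d0, s0^2) from the distribution of log sample
# variances, following the scaled inverse-chi-square hierarchical model.
squeeze_variances <- function(s2, df) {
  ok <- is.finite(s2) & s2 > 0
  if (sum(ok) < 2L) return(list(df_prior = 0, s2_prior = NA_real_,
                                s2_post = s2))
  z <- log(s2[ok])
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- stats::var(e) - trigamma(df / 2)
  if (is.finite(evar) && evar > 0) {
    df_prior <- 2 * trigamma_inverse(evar)
    s2_prior <- exp(emean + digamma(df_prior / 2) - log(df_prior / 2))
  } else {
    df_prior <- Inf
    s2_prior <- exp(emean)
  }
  s2_post <- if (is.infinite(df_prior)) rep(s2_prior, length(s2)) else
    (df_prior * s2_prior + df * s2) / (df_prior + df)
  list(df_prior = df_prior, s2_prior = s2_prior, s2_post = s2_post)
}

#' Moderated two-group differential expression
#'
#' Per-gene two-group comparison with empirical-Bayes variance moderation:
#' residual (pooled) variances are shrunk toward a common prior whose
#' degrees of freedom and scale are estimated from the across-gene variance
#' distribution; the moderated t-statistic uses the shrunken variance with
#' augmented degrees of freedom. With `prior_df = 0` the statistic reduces
#' to the ordinary pooled-variance two-sample t.
#'
#' @param expr Numeric matrix, genes x samples.
#' @param labels Two-level factor/character vector over samples; the
#'   reported difference is mean(level 2) - mean(level 1).
#' @param prior_df Optional override of the estimated prior degrees of
#'   freedom (`0` disables shrinkage, `Inf` shrinks fully).
#' @return Data frame: `gene`, `diff`, `t`, `df`, `p`, `p_adj` (BH), plus
#'   `s2` and `s2_post`.
#' @export
moderated_de <- function(expr, labels, prior_df = NULL) {
  labels <- as.factor(labels)
  if (nlevels(labels) != 2L) stop("labels must have exactly two levels")
  if (length(labels) != ncol(expr))
    stop("labels length must match matrix columns")
  i1 <- labels == levels(labels)[1]; i2 <- !i1
  n1 <- sum(i1); n2 <- sum(i2)
  if (n1 < 2L || n2 < 2L) stop("each group needs at least 2 samples")
  m1 <- rowMeans(expr[, i1, drop = FALSE])
  m2 <- rowMeans(expr[, i2, drop = FALSE])
  v1 <- apply(expr[, i1, drop = FALSE], 1L, stats::var)
  v2 <- apply(expr[, i2, drop = FALSE], 1L, stats::var)
  df_resid <- n1 + n2 - 2L
  s2 <- ((n1 - 1L) * v1 + (n2 - 1L) * v2) / df_resid
  if (is.null(prior_df)) {
    sq <- squeeze_variances(s2, df_resid)
  } else if (prior_df == 0) {
    sq <- list(df_prior = 0, s2_prior = NA_real_, s2_post = s2)
  } else if (is.infinite(prior_df)) {
    sq0 <- squeeze_variances(s2, df_resid)
    s2p <- sq0$s2_prior %||% mean(s2)
    if (!is.finite(s2p)) s2p <- mean(s2)
    sq <- list(df_prior = Inf, s2_prior = s2p,
               s2_post = rep(s2p, length(s2)))
  } else {
    sq0 <- squeeze_variances(s2, df_resid)
    s2p <- if (is.finite(sq0$s2_prior)) sq0$s2_prior else mean(s2)
    sq <- list(df_prior = prior_df, s2_prior = s2p,
               s2_post = (prior_df * s2p + df_resid * s2) /
                 (prior_df + df_resid))
  }
  se <- sqrt(sq$s2_post * (1 / n1 + 1 / n2))
  diff <- m2 - m1
  tstat <- ifelse(se > 0, diff / se, ifelse(diff == 0, 0, Inf * sign(diff)))
  df_total <- df_resid + sq$df_prior
  p <- 2 * stats::pt(-abs(tstat), df = df_total)
  p[tstat == 0] <- 1
  data.frame(gene = rownames(expr) %||% as.character(seq_len(nrow(expr))),
             diff = diff, t = tstat, df = df_total, p = p,
             p_adj = stats::p.adjust(p, method = "BH"),
             s2 = s2, s2_post = sq$s2_post, row.names = NULL)
}
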