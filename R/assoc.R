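# Feature-response association: Welch t-tests of the four viability
# measures between mutant and wild-type samples (Benjamini-Hochberg adjusted
# per measure), a Pearson correlation screen for expression, scalar group
# tests, subtype ANOVA, the pairwise-complete drug-correlation panel, and
# the two-of-four-measures robustness rule.

MEASURE_NAMES <- c("auc_trap", "ic50_trap", "auc_fit", "ic50_fit")

check_measures <- function(measures, measure_cols) {
  missing_cols <- setdiff(c("sample", measure_cols), names(measures))
  if (length(missing_cols))
    stop("measures table lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  cens <- intersect(c("ic50_trap_censored", "ic50_fit_censored"),
                    names(measures))
  n_cens <- sum(vapply(cens, function(cl) sum(measures[[cl]]), 0L))
  if (n_cens > 0L)
    warning(sprintf("%d censored IC50 value(s) enter the tests at the maximum tested concentration",
                    n_cens))
  invisible(measures)
}

#' Associate collinear mutation groups with the viability measures
#'
#' For each group and each of the four measures, a two-sided Welch t-test of
#' the measure in mutant vs wild-type samples; p-values are
#' Benjamini-Hochberg adjusted per measure across all tested groups. Groups
#' with fewer than `min_group` samples in either arm are skipped and listed
#' in the `"skipped"` attribute. Direction is `"sensitizing"` when mutants
#' have the lower mean (lower viability measure = more sensitive).
#'
#' @param measures Data frame with `sample` plus the four measure columns.
#' @param groups List of collinear groups from [group_collinear()].
#' @param p_cutoff Adjusted-p significance cutoff (FDR).
#' @param min_group Minimum samples per arm for a group to be testable.
#' @param pooled Use pooled-variance t-tests instead of Welch.
#' @param measure_cols Measure columns to test.
#' @return Data frame of association records: `feature`, `kind`, `measure`,
#'   `direction`, `statistic`, `p`, `p_adj`, `significant`, plus group flags
#'   (`hypermutant_only`, `large_group`, `n_mutant`, `genes`).
#' @export
mutation_association <- function(measures, groups, p_cutoff = 0.25,
                                 min_group = 2L, pooled = FALSE,
                                 measure_cols = MEASURE_NAMES) {
  check_measures(measures, measure_cols)
  rows <- list(); skipped <- character(0)
  for (grp in groups) {
    mutant <- names(grp$pattern)[grp$pattern == 1L]
    is_mut <- measures$sample %in% mutant
    if (sum(is_mut) < min_group || sum(!is_mut) < min_group) {
      skipped <- c(skipped, grp$id)
      next
    }
    for (m in measure_cols) {
      x <- measures[[m]][is_mut]; y <- measures[[m]][!is_mut]
      # zero-variance arms (e.g. all-censored IC50s) break t.test; report
      # the limiting values instead of erroring
      tt <- tryCatch(stats::t.test(x, y, var.equal = pooled),
                     error = function(e) {
                       eq <- isTRUE(all.equal(mean(x), mean(y)))
                       list(statistic = c(t = if (eq) 0 else
                         sign(mean(x) - mean(y)) * Inf),
                         p.value = if (eq) 1 else 0)
                     })
      rows[[length(rows) + 1L]] <- data.frame(
        feature = grp$id, kind = "mutation_group", measure = m,
        direction = if (mean(x) < mean(y)) "sensitizing" else "resistance",
        statistic = unname(tt$statistic), p = tt$p.value, p_adj = NA_real_,
        significant = NA,
        hypermutant_only = grp$hypermutant_only,
        large_group = grp$large_group, n_mutant = grp$n_mutant,
        genes = paste(grp$genes, collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(feature = character(0), kind = character(0),
               measure = character(0), direction = character(0),
               statistic = numeric(0), p = numeric(0), p_adj = numeric(0),
               significant = logical(0), hypermutant_only = logical(0),
               large_group = logical(0), n_mutant = integer(0),
               genes = character(0))
  for (m in unique(out$measure)) {
    i <- out$measure == m
    out$p_adj[i] <- stats::p.adjust(out$p[i], method = "BH")
  }
  out$significant <- out$p_adj < p_cutoff
  attr(out, "skipped") <- skipped
  out
}

#' Correlate gene expression with the viability measures
#'
#' Per gene and measure, the Pearson correlation of (filtered, centered)
#' expression with the measure; a gene-measure pair is significant when
#' `|r| >= r_cutoff` (inclusive). Zero-variance genes are skipped with a
#' flag rather than erroring. BH-adjusted correlation-test p-values are
#' reported alongside for reference.
#'
#' @param measures Data frame with `sample` plus the measure columns.
#' @param expr Expression matrix, genes x samples (already variance-filtered
#'   and mean-centered).
#' @param r_cutoff Absolute-correlation significance cutoff.
#' @param measure_cols Measure columns to test.
#' @return Data frame of association records (statistic = Pearson r), with
#'   a `"skipped"` attribute naming zero-variance genes.
#' @export
expression_association <- function(measures, expr, r_cutoff = 0.5,
                                   measure_cols = MEASURE_NAMES) {
  check_measures(measures, measure_cols)
  common <- intersect(measures$sample, colnames(expr))
  if (length(common) < 3L)
    stop("fewer than 3 samples shared between measures and expression")
  expr <- expr[, common, drop = FALSE]
  mtab <- measures[match(common, measures$sample), , drop = FALSE]
  sds <- apply(expr, 1L, stats::sd)
  skipped <- rownames(expr)[sds == 0]
  expr <- expr[sds > 0, , drop = FALSE]
  rows <- list()
  for (m in measure_cols) {
    y <- mtab[[m]]
    r <- as.numeric(stats::cor(t(expr), y))
    nuse <- length(y)
    tstat <- r * sqrt(nuse - 2) / sqrt(pmax(1 - r^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tstat), df = nuse - 2)
    rows[[m]] <- data.frame(
      feature = rownames(expr), kind = "expression_gene", measure = m,
      direction = ifelse(r < 0, "sensitizing", "resistance"),
      statistic = r, p = p,
      p_adj = stats::p.adjust(p, method = "BH"),
      significant = abs(r) >= r_cutoff,
      hypermutant_only = FALSE, large_group = FALSE,
      n_mutant = NA_integer_, genes = rownames(expr),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' Apply the robustness rule across viability measures
#'
#' Retains features whose association is significant for at least
#' `min_measures` of the four viability measures, propagating the collinear
#' group flags.
#'
#' @param records Association records from [mutation_association()] and/or
#'   [expression_association()].
#' @param min_measures Required number of significant measures (inclusive).
#' @return Data frame: `feature`, `kind`, `n_significant_measures`,
#'   `hypermutant_only`, `large_group`, `genes`.
#' @export
robustness_filter <- function(records, min_measures = 2L) {
  if (nrow(records) == 0L)
    return(data.frame(feature = character(0), kind = character(0),
                      n_significant_measures = integer(0),
                      hypermutant_only = logical(0),
                      large_group = logical(0), genes = character(0)))
  counts <- stats::aggregate(significant ~ feature + kind +
                               hypermutant_only + large_group + genes,
                             data = records, FUN = sum)
  names(counts)[names(counts) == "significant"] <- "n_significant_measures"
  out <- counts[counts$n_significant_measures >= min_measures, , drop = FALSE]
  out <- out[order(-out$n_significant_measures, out$feature), ,
             drop = FALSE]
  rownames(out) <- NULL
  out[, c("feature", "kind", "n_significant_measures", "hypermutant_only",
          "large_group", "genes")]
}

#' Two-group scalar test of one viability measure
#'
#' Two-sided t-test (Welch by default) of a measure between two label
#' groups, e.g. hypermutant vs non-hypermutant status.
#'
#' @param x Numeric measure vector.
#' @param labels Two-level grouping aligned to `x`.
#' @param pooled Use the pooled-variance (classical) t-test.
#' @return A list with `statistic` and `p`.
#' @export
group_scalar_test <- function(x, labels, pooled = FALSE) {
  labels <- as.factor(labels)
  if (nlevels(labels) != 2L) stop("labels must have exactly two levels")
  if (any(table(labels) < 2L)) stop("each group needs at least 2 samples")
  tt <- stats::t.test(x ~ labels, var.equal = pooled)
  list(statistic = unname(tt$statistic), p = tt$p.value)
}

#' Subtype association by one-way ANOVA
#'
#' F-test of a viability measure across subtype levels. Levels with fewer
#' than `min_per_level` samples are merged into `"other"` with a warning.
#'
#' @param x Numeric measure vector.
#' @param labels Subtype labels aligned to `x`.
#' @param min_per_level Minimum samples for a level to stand alone.
#' @return A list with `statistic` (F), `df`, and `p`.
#' @export
subtype_association <- function(x, labels, min_per_level = 2L) {
  labels <- as.character(labels)
  tab <- table(labels)
  small <- names(tab)[tab < min_per_level]
  if (length(small)) {
    warning("merging sparse subtype level(s) into 'other': ",
            paste(small, collapse = ", "))
    labels[labels %in% small] <- "other"
  }
  labels <- as.factor(labels)
  usable <- table(labels) >= min_per_level
  if (sum(usable) < 2L) stop("fewer than 2 usable subtype levels")
  keep <- labels %in% names(which(usable))
  x <- x[keep]; labels <- droplevels(labels[keep])
  ft <- stats::oneway.test(x ~ labels, var.equal = TRUE)
  list(statistic = unname(ft$statistic),
       df = unname(ft$parameter), p = ft$p.value)
}

#' Pairwise-complete drug-response correlation panel
#'
#' Pearson correlations between all drug pairs using pairwise-complete
#' samples; pairs with fewer than `min_pairs` complete observations are
#' reported as `NA`. Also returns the panel ranked by correlation with the
#' focal drug (focal drug excluded from its own ranking).
#'
#' @param drug_mat Numeric matrix, samples x drugs (AUCs; may contain NA).
#' @param focal Column name of the focal drug.
#' @param min_pairs Minimum pairwise-complete samples per pair.
#' @return A list with `matrix` (symmetric, unit diagonal) and `ranking`
#'   (data frame `drug`, `r`, `n`, sorted by `r` descending, NAs last).
#' @export
drug_correlations <- function(drug_mat, focal = "EZH2i", min_pairs = 3L) {
  if (!focal %in% colnames(drug_mat))
    stop(sprintf("focal drug '%s' absent from the panel", focal))
  nd <- ncol(drug_mat)
  cm <- matrix(NA_real_, nd, nd,
               dimnames = list(colnames(drug_mat), colnames(drug_mat)))
  npairs <- matrix(0L, nd, nd, dimnames = dimnames(cm))
  for (i in seq_len(nd)) {
    cm[i, i] <- 1
    npairs[i, i] <- sum(is.finite(drug_mat[, i]))
    for (j in if (i < nd) (i + 1L):nd else integer(0)) {
      ok <- stats::complete.cases(drug_mat[, c(i, j)])
      npairs[i, j] <- npairs[j, i] <- sum(ok)
      if (sum(ok) >= min_pairs) {
        r <- stats::cor(drug_mat[ok, i], drug_mat[ok, j])
        cm[i, j] <- cm[j, i] <- r
      }
    }
  }
  others <- setdiff(colnames(drug_mat), focal)
  ranking <- data.frame(drug = others, r = cm[focal, others],
                        n = npairs[focal, others], stringsAsFactors = FALSE)
  ranking <- ranking[order(-ranking$r, ranking$drug, na.last = TRUE), ,
                     drop = FALSE]
  rownames(ranking) <- NULL
  list(matrix = cm, ranking = ranking)
}
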