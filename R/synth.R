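# Seeded synthetic-cohort generator with planted, recorded ground truth.
#
# The generator emulates a ~20-line tumor-organoid panel screened against a
# focal drug on an 8-point dose grid with 3-4 replicates: sigmoid responders
# with an optional low-dose growth peak, a binary somatic-mutation matrix
# containing collinear groups and hypermutated samples, mean-offset
# expression with a minority of high-variance genes, and a multi-drug AUC
# panel with one drug strongly correlated to the focal drug. Every planted
# signal is recorded in the returned `truth` object.

#' Configuration for a synthetic cohort
#'
#' Defaults describe the emulated screen: 20 samples, an 8-point grid from 0
#' to 8 µM, 3 replicates of 2000 seeded cells, 15% hormetic responders
#' (3/20), 6 hypermutants, a mutation effect of 2 within-group AUC standard
#' deviations, a planted expression gene at correlation -0.7 with response,
#' and an 84-drug panel with one drug planted at correlation 0.8 with the
#' focal drug.
#'
#' @param n_samples Number of organoid lines.
#' @param dose_grid Concentrations (µM), strictly increasing from 0.
#' @param n_replicates Replicates per line (3 or 4).
#' @param seed_count Cells seeded per well.
#' @param noise_sd Multiplicative log-scale noise SD on counts.
#' @param frac_hormetic Fraction of lines with a planted low-dose peak
#'   reaching at least 1.5x control at the lowest nonzero dose.
#' @param n_genes_mutation Number of mutation genes.
#' @param n_collinear_groups Number of planted collinear mutation groups.
#' @param n_hypermutants Number of hypermutated lines (5x background rate).
#' @param planted_mut_effect Mean AUC shift between mutant and wild-type
#'   lines for the planted gene, in units of the within-group AUC SD.
#' @param n_genes_expression Number of expression genes.
#' @param sd_high SD of the high-variance gene minority (11% of genes).
#' @param planted_expr_corr Target Pearson correlation of the planted gene
#'   with true AUC (negative = higher expression, more sensitive).
#' @param n_drugs Number of drugs in the panel, including the focal drug.
#' @param planted_drug_corr Target correlation of the planted drug's AUC
#'   with the focal drug's.
#' @param rng_seed Integer seed; identical configs and seeds reproduce
#'   byte-identical cohorts.
#' @return A validated list of class `"cohort_config"`.
#' @export
cohort_config <- function(n_samples = 20L,
                          dose_grid = c(0, 0.5, 1, 2, 3, 4, 6, 8),
                          n_replicates = 3L,
                          seed_count = 2000L,
                          noise_sd = 0.05,
                          frac_hormetic = 0.15,
                          n_genes_mutation = 80L,
                          n_collinear_groups = 3L,
                          n_hypermutants = 6L,
                          planted_mut_effect = 2,
                          n_genes_expression = 2000L,
                          sd_high = 1,
                          planted_expr_corr = -0.7,
                          n_drugs = 84L,
                          planted_drug_corr = 0.8,
                          rng_seed = 1L) {
  cfg <- list(n_samples = as.integer(n_samples), dose_grid = dose_grid,
              n_replicates = as.integer(n_replicates),
              seed_count = as.integer(seed_count), noise_sd = noise_sd,
              frac_hormetic = frac_hormetic,
              n_genes_mutation = as.integer(n_genes_mutation),
              n_collinear_groups = as.integer(n_collinear_groups),
              n_hypermutants = as.integer(n_hypermutants),
              planted_mut_effect = planted_mut_effect,
              n_genes_expression = as.integer(n_genes_expression),
              sd_high = sd_high, planted_expr_corr = planted_expr_corr,
              n_drugs = as.integer(n_drugs),
              planted_drug_corr = planted_drug_corr,
              rng_seed = as.integer(rng_seed))
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  bad <- function(field, why) stop(sprintf("invalid config field '%s': %s",
                                           field, why), call. = FALSE)
  if (cfg$n_samples < 4L) bad("n_samples", "need at least 4 samples")
  dg <- cfg$dose_grid
  if (length(dg) < 3L || dg[1] != 0 || any(diff(dg) <= 0))
    bad("dose_grid", "must be strictly increasing and start at 0")
  if (!cfg$n_replicates %in% 3:4) bad("n_replicates", "must be 3 or 4")
  if (cfg$seed_count <= 0L) bad("seed_count", "must be positive")
  if (cfg$noise_sd < 0) bad("noise_sd", "must be nonnegative")
  if (cfg$frac_hormetic < 0 || cfg$frac_hormetic > 1)
    bad("frac_hormetic", "must lie in [0, 1]")
  if (cfg$n_genes_mutation < 1L) bad("n_genes_mutation", "must be >= 1")
  if (cfg$n_collinear_groups < 0L) bad("n_collinear_groups", "must be >= 0")
  if (cfg$n_hypermutants < 0L || cfg$n_hypermutants > cfg$n_samples)
    bad("n_hypermutants", "must lie in [0, n_samples]")
  if (cfg$n_genes_expression < 1L) bad("n_genes_expression", "must be >= 1")
  if (cfg$sd_high <= 0) bad("sd_high", "must be positive")
  if (abs(cfg$planted_expr_corr) > 1)
    bad("planted_expr_corr", "must lie in [-1, 1]")
  if (cfg$n_drugs < 2L) bad("n_drugs", "need the focal drug plus >= 1 other")
  if (abs(cfg$planted_drug_corr) > 1)
    bad("planted_drug_corr", "must lie in [-1, 1]")
  invisible(cfg)
}

# Rescale a noise vector against an anchor so the sample correlation equals
# `r` exactly (anchor-orthogonalized construction).
plant_correlated <- function(anchor, r, noise) {
  z <- as.numeric(scale(anchor))
  e <- noise - z * sum(noise * z) / sum(z * z)
  e <- as.numeric(scale(e))
  out <- r * z + sqrt(1 - r^2) * e
  as.numeric(scale(out))  # unit sample SD, exact sample correlation r
}

#' Generate a complete synthetic cohort
#'
#' @param config A [cohort_config()].
#' @return A list with `counts` (long data frame: sample, replicate,
#'   dose_uM, count), `mutations` (records: sample, gene, class, variant_id),
#'   `expression` (genes x samples matrix), `drugs` (samples x drugs AUC
#'   matrix, focal drug in column `"EZH2i"`), `annotations` (sample,
#'   subtype, hypermutant) and `truth` (planted ground truth).
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) config <- do.call(cohort_config, config)
  validate_cohort_config(config)
  with_private_seed(config$rng_seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(cfg) {
  n <- cfg$n_samples
  samples <- sprintf("S%02d", seq_len(n))
  grid <- cfg$dose_grid
  cmax <- max(grid)
  c1 <- min(grid[grid > 0])

  ## --- true dose-response parameters ---------------------------------
  shift <- stats::runif(n, 2.5, 6.5)
  slope <- stats::runif(n, 0.8, 2.5)
  n_h <- round(cfg$frac_hormetic * n)
  hormetic_idx <- if (n_h > 0) sort(sample.int(n, n_h)) else integer(0)
  mu <- sigma <- amp <- peak_target <- numeric(n)

  ## --- planted mutation gene ------------------------------------------
  # mutants get their true (logistic) AUC lowered by exactly
  # planted_mut_effect within-group AUC standard deviations, realized by
  # solving for the logistic midpoint that hits the target area
  mut_gene <- "G_PLANT_MUT"
  n_mut <- max(2L, round(0.35 * n))
  mut_carriers <- sort(sample.int(n, n_mut))
  logistic_auc <- function(sh, sl)
    (log1pexp(sl * sh) - log1pexp(-sl * (cmax - sh))) / sl
  if (cfg$planted_mut_effect != 0) {
    A0 <- mapply(logistic_auc, shift, slope)
    delta <- cfg$planted_mut_effect * stats::sd(A0)
    for (i in mut_carriers) {
      floor_auc <- logistic_auc(-cmax / 2, slope[i]) + 1e-3
      target <- max(A0[i] - delta, floor_auc)
      shift[i] <- stats::uniroot(function(s)
        logistic_auc(s, slope[i]) - target,
        lower = -cmax / 2, upper = 2 * cmax, tol = 1e-10)$root
    }
  }

  # hormetic peaks: amp chosen so the true curve hits a target 1.5-1.9x
  # control at the lowest nonzero dose. Peaks are kept narrow (mu at least
  # 3.5 sigma above zero) so the normal density contributes nothing at the
  # control dose and viability stays exactly 1 there after normalization.
  for (i in hormetic_idx) {
    mu[i] <- c1 * stats::runif(1, 1.0, 1.3)
    sigma[i] <- mu[i] / stats::runif(1, 3.5, 4.5)
    peak_target[i] <- stats::runif(1, 1.55, 1.9)
    sig_c1 <- stats::plogis(-slope[i] * (c1 - shift[i]))
    amp[i] <- (peak_target[i] - sig_c1) / stats::dnorm(c1, mu[i], sigma[i])
  }
  # inactive peak components still need valid (unused) mu/sigma
  mono <- setdiff(seq_len(n), hormetic_idx)
  mu[mono] <- c1
  sigma[mono] <- c1

  params <- data.frame(sample = samples, mu = mu, sigma = sigma,
                       shift = shift, slope = slope, amp = amp,
                       hormetic = seq_len(n) %in% hormetic_idx,
                       stringsAsFactors = FALSE)
  true_auc <- vapply(seq_len(n), function(i)
    hormetic_auc_exact(hm_par_unchecked(c(mu[i], sigma[i], shift[i],
                                          slope[i], amp[i])), cmax), 0)
  true_v_c1 <- vapply(seq_len(n), function(i)
    hormetic_model(c1, hm_par_unchecked(c(mu[i], sigma[i], shift[i],
                                          slope[i], amp[i]))), 0)

  ## --- counts ----------------------------------------------------------
  counts <- expand.grid(dose_uM = grid, replicate = seq_len(cfg$n_replicates),
                        sample = samples, stringsAsFactors = FALSE)
  counts <- counts[, c("sample", "replicate", "dose_uM")]
  v_true <- vapply(seq_len(nrow(counts)), function(k) {
    i <- match(counts$sample[k], samples)
    hormetic_model(counts$dose_uM[k],
                   hm_par_unchecked(c(mu[i], sigma[i], shift[i], slope[i],
                                      amp[i])))
  }, 0)
  noise <- if (cfg$noise_sd > 0)
    exp(stats::rnorm(nrow(counts), 0, cfg$noise_sd)) else 1
  counts$count <- pmax(0, round(cfg$seed_count * v_true * noise))

  ## --- mutations -------------------------------------------------------
  genes <- sprintf("G%04d", seq_len(cfg$n_genes_mutation))
  hyper_idx <- if (cfg$n_hypermutants > 0)
    sort(sample.int(n, cfg$n_hypermutants)) else integer(0)
  p_bg <- 0.12
  rate <- rep(p_bg, n)
  rate[hyper_idx] <- min(0.6, 5 * p_bg)
  mut <- matrix(0L, n, cfg$n_genes_mutation,
                dimnames = list(samples, genes))
  for (j in seq_len(cfg$n_genes_mutation))
    mut[, j] <- stats::rbinom(n, 1L, rate)

  # planted collinear groups: identical columns copied to k member genes
  reserved <- integer(0)
  collinear <- list()
  if (cfg$n_collinear_groups > 0) {
    avail <- seq_len(cfg$n_genes_mutation)
    for (g in seq_len(cfg$n_collinear_groups)) {
      k <- sample(2:8, 1L)
      if (length(avail) < k + 1L) break
      cols <- avail[seq_len(k)]
      avail <- setdiff(avail, cols)
      pattern <- stats::rbinom(n, 1L, 0.2)
      while (sum(pattern) < 2L) pattern <- stats::rbinom(n, 1L, 0.2)
      mut[, cols] <- pattern
      collinear[[g]] <- list(genes = genes[cols], pattern = pattern)
      reserved <- c(reserved, cols)
    }
  }

  # planted associated gene gets a dedicated column (not in any collinear
  # reservation)
  free <- setdiff(seq_len(cfg$n_genes_mutation), reserved)
  plant_col <- free[length(free)]
  plant_vec <- integer(n)
  plant_vec[mut_carriers] <- 1L
  mut[, plant_col] <- plant_vec
  genes[plant_col] <- mut_gene
  colnames(mut) <- genes

  # emit one record per mutated cell (coding classes) plus excluded-class
  # decoy records that the feature filter must remove
  idx <- which(mut == 1L, arr.ind = TRUE)
  keep_classes <- c("missense", "nonsense", "frameshift", "splice")
  records <- data.frame(
    sample = samples[idx[, 1]],
    gene = genes[idx[, 2]],
    class = sample(keep_classes, nrow(idx), replace = TRUE,
                   prob = c(0.7, 0.15, 0.1, 0.05)),
    variant_id = sprintf("v%05d", seq_len(nrow(idx))),
    stringsAsFactors = FALSE)
  n_decoy <- max(1L, round(0.25 * nrow(idx)))
  decoys <- data.frame(
    sample = samples[sample.int(n, n_decoy, replace = TRUE)],
    gene = genes[sample.int(cfg$n_genes_mutation, n_decoy, replace = TRUE)],
    class = sample(c("silent", "intron", "utr", "flank", "intergenic",
                     "noncoding"), n_decoy, replace = TRUE),
    variant_id = sprintf("d%05d", seq_len(n_decoy)),
    stringsAsFactors = FALSE)
  records <- rbind(records, decoys)
  records <- records[order(records$sample, records$gene), ]
  rownames(records) <- NULL

  ## --- expression ------------------------------------------------------
  egenes <- sprintf("E%05d", seq_len(cfg$n_genes_expression))
  n_hi <- max(1L, round(0.11 * cfg$n_genes_expression))
  hi_idx <- seq_len(n_hi)  # leading block is high-variance
  gsd <- rep(0.3, cfg$n_genes_expression)
  gsd[hi_idx] <- cfg$sd_high
  base_mean <- stats::rnorm(cfg$n_genes_expression, 0, 2)
  expr <- matrix(stats::rnorm(cfg$n_genes_expression * n), ncol = n,
                 dimnames = list(egenes, samples)) * gsd + base_mean
  expr_gene <- "E_PLANT_BIK"
  rownames(expr)[1] <- expr_gene
  if (abs(cfg$planted_expr_corr) > 0) {
    g <- plant_correlated(true_auc, cfg$planted_expr_corr, stats::rnorm(n))
    expr[1, ] <- g * cfg$sd_high + base_mean[1]
  }

  ## --- drug panel ------------------------------------------------------
  dnames <- c("EZH2i", "D_PLANT_CORR",
              sprintf("D%03d", seq_len(cfg$n_drugs - 2L)))
  drugs <- matrix(NA_real_, n, cfg$n_drugs,
                  dimnames = list(samples, dnames))
  drugs[, "EZH2i"] <- true_auc
  auc_sd <- stats::sd(true_auc)
  if (cfg$n_drugs >= 3L)
    for (j in 3:cfg$n_drugs)
      drugs[, j] <- mean(true_auc) + stats::rnorm(n) * auc_sd
  if (abs(cfg$planted_drug_corr) > 0) {
    d <- plant_correlated(true_auc, cfg$planted_drug_corr, stats::rnorm(n))
    drugs[, "D_PLANT_CORR"] <- mean(true_auc) + d * auc_sd
  } else {
    drugs[, "D_PLANT_CORR"] <- mean(true_auc) + stats::rnorm(n) * auc_sd
  }

  ## --- annotations & truth --------------------------------------------
  annotations <- data.frame(
    sample = samples,
    subtype = sample(paste0("CMS", 1:4), n, replace = TRUE),
    hypermutant = seq_len(n) %in% hyper_idx,
    stringsAsFactors = FALSE)

  truth <- list(params = params,
                true_auc = stats::setNames(true_auc, samples),
                true_viability_lowest_dose = stats::setNames(true_v_c1,
                                                             samples),
                hormetic_samples = samples[hormetic_idx],
                hypermutant_samples = samples[hyper_idx],
                mutation_gene = mut_gene,
                mutation_carriers = samples[mut_carriers],
                expression_gene = expr_gene,
                correlated_drug = "D_PLANT_CORR",
                collinear_groups = collinear,
                binary_mutations = mut)

  list(counts = counts, mutations = records, expression = expr,
       drugs = drugs, annotations = annotations, truth = truth,
       config = cfg)
}

#' Write a synthetic cohort to TSV files plus truth.json
#'
#' @param cohort Result of [generate_cohort()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the vector of written paths.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  hdr <- output_header(cohort$config)
  paths <- c(
    counts = file.path(dir, "counts.tsv"),
    mutations = file.path(dir, "mutations.tsv"),
    expression = file.path(dir, "expression.tsv"),
    drugs = file.path(dir, "drugs.tsv"),
    annotations = file.path(dir, "annotations.tsv"),
    truth = file.path(dir, "truth.json"))
  write_tsv_hdr(cohort$counts, paths["counts"], hdr)
  write_tsv_hdr(cohort$mutations, paths["mutations"], hdr)
  write_matrix_tsv(cohort$expression, paths["expression"], hdr, "gene")
  write_matrix_tsv(t(cohort$drugs), paths["drugs"], hdr, "drug")
  write_tsv_hdr(cohort$annotations, paths["annotations"], hdr)
  truth <- cohort$truth
  truth$binary_mutations <- NULL  # large and reconstructible; keep JSON lean
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(paths)
}
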