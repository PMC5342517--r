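# End-to-end orchestration: simulate (or read) -> quantify -> phenotype ->
# features -> associate, with one global seed fanned out to per-stage
# derived seeds and a machine-readable summary.

#' Pipeline configuration
#'
#' Collects every numeric threshold of the analysis (defaults as used
#' throughout: FDR cutoff 0.25, |r| cutoff 0.5, robustness rule 2 of 4
#' measures, expression SD cutoff 0.7, mutation recurrence minimum 2,
#' large-group threshold 5, monotonicity threshold 1.5, 500 random
#' restarts) plus the cohort definition and the global seed.
#'
#' @param out_dir Output directory.
#' @param cohort A [cohort_config()] used when `input_dir` is `NULL`.
#' @param input_dir Optional directory of pre-existing cohort TSVs (as
#'   written by [write_cohort()]); when given, simulation is skipped.
#' @param p_cutoff Adjusted-p (FDR) cutoff for mutation associations.
#' @param r_cutoff Absolute-correlation cutoff for expression associations.
#' @param min_measures Robustness rule: required significant measures.
#' @param sd_cutoff Expression SD filter threshold.
#' @param recurrence_min Minimum mutated samples per retained gene.
#' @param large_threshold Collinear-group size flagged as large.
#' @param monotonicity_threshold Fitted-viability ratio defining
#'   non-monotonous response.
#' @param n_samplings Random restarts for non-converging fits.
#' @param gene_list Optional curated gene subset for a second mutation pass.
#' @param overrides Optional data frame (`sample`, `gene`) of forced
#'   mutation calls.
#' @param focal_drug Focal drug column in the drug panel.
#' @param rng_seed Global seed; per-stage seeds are derived from it.
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(out_dir,
                            cohort = cohort_config(),
                            input_dir = NULL,
                            p_cutoff = 0.25,
                            r_cutoff = 0.5,
                            min_measures = 2L,
                            sd_cutoff = 0.7,
                            recurrence_min = 2L,
                            large_threshold = 5L,
                            monotonicity_threshold = 1.5,
                            n_samplings = 500L,
                            gene_list = NULL,
                            overrides = NULL,
                            focal_drug = "EZH2i",
                            rng_seed = 1L) {
  thr <- c(p_cutoff, r_cutoff, min_measures, sd_cutoff, recurrence_min,
           large_threshold, monotonicity_threshold, n_samplings)
  if (any(!is.finite(thr)) || any(thr <= 0))
    stop("all thresholds must be positive")
  structure(list(out_dir = out_dir, cohort = cohort, input_dir = input_dir,
                 p_cutoff = p_cutoff, r_cutoff = r_cutoff,
                 min_measures = as.integer(min_measures),
                 sd_cutoff = sd_cutoff,
                 recurrence_min = as.integer(recurrence_min),
                 large_threshold = as.integer(large_threshold),
                 monotonicity_threshold = monotonicity_threshold,
                 n_samplings = as.integer(n_samplings),
                 gene_list = gene_list, overrides = overrides,
                 focal_drug = focal_drug,
                 rng_seed = as.integer(rng_seed)),
            class = "pipeline_config")
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir Directory containing counts.tsv, mutations.tsv,
#'   expression.tsv, drugs.tsv and annotations.tsv.
#' @return A cohort list (without `truth`).
#' @export
read_cohort <- function(dir) {
  ann <- read_tsv(file.path(dir, "annotations.tsv"))
  ann$hypermutant <- as.logical(ann$hypermutant)
  list(counts = read_tsv(file.path(dir, "counts.tsv")),
       mutations = read_tsv(file.path(dir, "mutations.tsv")),
       expression = read_matrix_tsv(file.path(dir, "expression.tsv")),
       drugs = t(read_matrix_tsv(file.path(dir, "drugs.tsv"))),
       annotations = ann, truth = NULL)
}

#' Run the full analysis pipeline
#'
#' Simulates (or reads) a cohort, quantifies the four viability measures,
#' classifies monotonicity and compares responder groups, builds the
#' mutation/expression feature matrices, runs all association analyses with
#' the robustness rule, and writes every stage artifact plus `summary.json`
#' under `config$out_dir`. Identical config and seed reproduce identical
#' outputs.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with all in-memory stage results (`cohort`,
#'   `measures`, `fits`, `monotonicity`, `phenotype`, `features`,
#'   `associations`, `robust`, `drug`, `summary`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  hdr <- output_header(config, seed = config$rng_seed)

  ## stage 1: cohort -----------------------------------------------------
  cohort <- if (is.null(config$input_dir)) {
    cc <- config$cohort
    cc$rng_seed <- derive_seed(config$rng_seed, 1L)
    generate_cohort(do.call(cohort_config, unclass(cc)))
  } else read_cohort(config$input_dir)
  write_cohort(cohort, file.path(out, "cohort"))
  samples <- unique(cohort$counts$sample)

  ## stage 2: quantify ---------------------------------------------------
  q <- quantify_cohort(cohort$counts, n_samplings = config$n_samplings,
                       seed = derive_seed(config$rng_seed, 2L))
  write_tsv_hdr(q$measures, file.path(out, "measures.tsv"), hdr)
  grid <- dose_grid(sort(unique(cohort$counts$dose_uM)))

  ## stage 3: phenotype --------------------------------------------------
  mono <- do.call(rbind, lapply(names(q$fits), function(s) {
    cl <- classify_monotonicity(q$fits[[s]], grid,
                                threshold = config$monotonicity_threshold,
                                sample = s)
    data.frame(sample = s, v_lowest = cl$v_lowest, label = cl$label,
               stringsAsFactors = FALSE)
  }))
  write_tsv_hdr(mono, file.path(out, "monotonicity.tsv"), hdr)

  ## stage 4: features ---------------------------------------------------
  binmat <- filter_and_binarize(cohort$mutations, samples)
  binmat <- apply_overrides(binmat, config$overrides)
  binmat <- recurrence_filter(binmat, config$recurrence_min)
  hyper <- cohort$annotations$sample[cohort$annotations$hypermutant]
  groups <- group_collinear(binmat, hyper, config$large_threshold)
  write_matrix_tsv(binmat, file.path(out, "binary_mutations.tsv"), hdr,
                   "sample")
  groups_df <- do.call(rbind, lapply(groups, function(g) data.frame(
    group_id = g$id, genes = paste(g$genes, collapse = ","),
    pattern = paste(g$pattern, collapse = ""), n_mutant = g$n_mutant,
    hypermutant_only = g$hypermutant_only, large_group = g$large_group,
    stringsAsFactors = FALSE)))
  if (is.null(groups_df)) groups_df <- data.frame()
  write_tsv_hdr(groups_df, file.path(out, "collinear_groups.tsv"), hdr)

  expr_filtered <- variance_filter(mean_center(cohort$expression),
                                   "sd_threshold", config$sd_cutoff)

  # responder-group comparisons need both labels present with >= 2 samples
  phenotype <- list(mutations = NULL, expression = NULL)
  lab <- stats::setNames(mono$label, mono$sample)[samples]
  if (all(table(factor(lab, levels = c("monotonous", "non_monotonous"))) >= 2L) &&
      nrow(expr_filtered) > 0L) {
    phenotype$mutations <- suppressWarnings(chisq_per_mutation(binmat, lab))
    phenotype$expression <- moderated_de(expr_filtered[, samples,
                                                       drop = FALSE], lab)
    write_tsv_hdr(phenotype$mutations,
                  file.path(out, "phenotype_mutations.tsv"), hdr)
    write_tsv_hdr(phenotype$expression,
                  file.path(out, "phenotype_expression.tsv"), hdr)
  }

  ## stage 5: associations ----------------------------------------------
  mut_assoc <- mutation_association(q$measures, groups,
                                    p_cutoff = config$p_cutoff)
  expr_assoc <- expression_association(q$measures, expr_filtered,
                                       r_cutoff = config$r_cutoff)
  records <- rbind(mut_assoc, expr_assoc)
  write_tsv_hdr(records, file.path(out, "associations.tsv"), hdr)
  robust <- robustness_filter(records, config$min_measures)
  write_tsv_hdr(robust, file.path(out, "robust_features.tsv"), hdr)

  # optional second mutation pass restricted to a curated gene list
  if (!is.null(config$gene_list)) {
    binmat_subset <- subset_genes(binmat, config$gene_list)
    groups_subset <- group_collinear(binmat_subset, hyper,
                                     config$large_threshold)
    mut_subset <- mutation_association(q$measures, groups_subset,
                                       p_cutoff = config$p_cutoff)
    robust_subset <- robustness_filter(mut_subset, config$min_measures)
    write_tsv_hdr(robust_subset,
                  file.path(out, "robust_features_genelist.tsv"), hdr)
  }

  ann <- cohort$annotations[match(q$measures$sample,
                                  cohort$annotations$sample), ]
  scalar_tests <- list()
  if (length(unique(ann$hypermutant)) == 2L &&
      all(table(ann$hypermutant) >= 2L))
    scalar_tests$hypermutant <- lapply(
      stats::setNames(MEASURE_NAMES, MEASURE_NAMES),
      function(m) group_scalar_test(q$measures[[m]], ann$hypermutant))
  subtype_tests <- tryCatch(
    lapply(stats::setNames(MEASURE_NAMES, MEASURE_NAMES),
           function(m) suppressWarnings(
             subtype_association(q$measures[[m]], ann$subtype))),
    error = function(e) NULL)

  drug <- drug_correlations(cohort$drugs, focal = config$focal_drug)
  write_matrix_tsv(drug$matrix, file.path(out, "drug_correlation_matrix.tsv"),
                   hdr, "drug")
  write_tsv_hdr(drug$ranking, file.path(out, "drug_ranking.tsv"), hdr)

  ## stage 6: summary ----------------------------------------------------
  summary <- list(
    seed = config$rng_seed,
    config_hash = config_fingerprint(config),
    thresholds = list(p_cutoff = config$p_cutoff,
                      r_cutoff = config$r_cutoff,
                      min_measures = config$min_measures,
                      sd_cutoff = config$sd_cutoff,
                      recurrence_min = config$recurrence_min,
                      large_threshold = config$large_threshold,
                      monotonicity_threshold = config$monotonicity_threshold,
                      n_samplings = config$n_samplings),
    n_samples = length(samples),
    monotonicity = stats::setNames(as.list(mono$label), mono$sample),
    robust_features = robust,
    hypermutant_tests = scalar_tests$hypermutant,
    subtype_tests = subtype_tests,
    top_drug_correlations = utils::head(drug$ranking, 10L))
  jsonlite::write_json(summary, file.path(out, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  writeLines(c(hdr, sprintf("R %s, hormetrics %s", getRversion(),
                            utils::packageVersion("hormetrics"))),
             file.path(out, "run_log.txt"))

  invisible(list(cohort = cohort, measures = q$measures, fits = q$fits,
                 monotonicity = mono, phenotype = phenotype,
                 features = list(matrix = binmat, groups = groups,
                                 expression = expr_filtered),
                 associations = records, robust = robust, drug = drug,
                 summary = summary))
}

# Deterministic per-stage seed derivation, kept below 2^31
derive_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 48271 + stage * 961748927) %% 2147483647)
}
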