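# Mutation and expression feature preparation: class filtering and
# binarization, germline override injection, recurrence filtering, collinear
# grouping, gene-list subsetting, mean-centering and variance filtering.

# Canonical variant classes and a normalization table for common annotation
# spellings (MAF-style and Sequence Ontology). Unmapped spellings error
# rather than silently pass.
VARIANT_CLASSES <- c("missense", "nonsense", "frameshift", "splice",
                     "silent", "intron", "intergenic", "noncoding", "utr",
                     "flank", "other")

# classes excluded from binarization (non-coding or silent)
EXCLUDED_CLASSES <- c("silent", "intron", "intergenic", "noncoding", "utr",
                      "flank")

VARIANT_CLASS_MAP <- c(
  missense = "missense", missense_mutation = "missense",
  missense_variant = "missense",
  nonsense = "nonsense", nonsense_mutation = "nonsense",
  stop_gained = "nonsense", nonstop_mutation = "nonsense",
  frameshift = "frameshift", frame_shift_del = "frameshift",
  frame_shift_ins = "frameshift", frameshift_variant = "frameshift",
  in_frame_del = "other", in_frame_ins = "other",
  splice = "splice", splice_site = "splice", splice_region = "splice",
  silent = "silent", synonymous = "silent", synonymous_variant = "silent",
  intron = "intron", intronic = "intron",
  intergenic = "intergenic", igr = "intergenic",
  noncoding = "noncoding", rna = "noncoding", lincrna = "noncoding",
  utr = "utr", `3'utr` = "utr", `5'utr` = "utr", utr3 = "utr", utr5 = "utr",
  flank = "flank", `3'flank` = "flank", `5'flank` = "flank",
  other = "other", translation_start_site = "other")

normalize_variant_class <- function(class) {
  key <- tolower(trimws(as.character(class)))
  mapped <- VARIANT_CLASS_MAP[key]
  if (anyNA(mapped)) {
    bad <- unique(key[is.na(mapped)])
    stop(sprintf("unknown variant class(es): %s", paste(bad, collapse = ", ")))
  }
  unname(mapped)
}

#' Filter mutation records and binarize per gene
#'
#' Retains only coding, non-silent variant classes (drops silent, intron,
#' intergenic, non-coding, UTR and flank records), then marks a
#' (sample, gene) cell 1 when at least one retained record exists; no
#' distinction is made between different types of mutation in the same gene.
#'
#' @param records Data frame with columns `sample`, `gene`, `class` (and
#'   optionally `variant_id`).
#' @param samples Character vector of all cohort samples (matrix rows).
#' @return A samples x genes binary integer matrix; genes with no retained
#'   record are absent.
#' @export
filter_and_binarize <- function(records, samples) {
  stopifnot(all(c("sample", "gene", "class") %in% names(records)))
  if (!all(records$sample %in% samples))
    stop("mutation records reference samples outside the cohort: ",
         paste(setdiff(unique(records$sample), samples), collapse = ", "))
  cls <- normalize_variant_class(records$class)
  keep <- !(cls %in% EXCLUDED_CLASSES)
  kept <- records[keep, , drop = FALSE]
  genes <- sort(unique(kept$gene))
  mat <- matrix(0L, length(samples), length(genes),
                dimnames = list(samples, genes))
  if (nrow(kept))
    mat[cbind(match(kept$sample, samples), match(kept$gene, genes))] <- 1L
  mat
}

#' Force-include specific (sample, gene) mutations
#'
#' Applies a curated override list (e.g. pathogenic germline variants found
#' outside the somatic pipeline) by setting the named cells to 1. Genes not
#' yet present are added as new columns.
#'
#' @param mat Binary mutation matrix (samples x genes).
#' @param overrides Data frame with columns `sample` and `gene`.
#' @return The updated matrix.
#' @export
apply_overrides <- function(mat, overrides) {
  if (is.null(overrides) || nrow(overrides) == 0L) return(mat)
  stopifnot(all(c("sample", "gene") %in% names(overrides)))
  unknown <- setdiff(unique(overrides$sample), rownames(mat))
  if (length(unknown))
    stop("override references unknown sample(s): ",
         paste(unknown, collapse = ", "))
  new_genes <- setdiff(unique(overrides$gene), colnames(mat))
  if (length(new_genes)) {
    add <- matrix(0L, nrow(mat), length(new_genes),
                  dimnames = list(rownames(mat), new_genes))
    mat <- cbind(mat, add)
  }
  mat[cbind(match(overrides$sample, rownames(mat)),
            match(overrides$gene, colnames(mat)))] <- 1L
  mat
}

#' Drop genes mutated in fewer than `min_samples` samples
#'
#' @param mat Binary mutation matrix.
#' @param min_samples Minimum number of mutated samples (inclusive).
#' @return The filtered matrix.
#' @export
recurrence_filter <- function(mat, min_samples = 2L) {
  if (min_samples < 1L) stop("min_samples must be >= 1")
  mat[, colSums(mat) >= min_samples, drop = FALSE]
}

#' Group collinear mutations
#'
#' Partitions genes by identical mutation pattern across samples (mutations
#' present in exactly the same set of lines are statistically
#' indistinguishable and tested as one feature). Groups whose mutant samples
#' are all hypermutants are flagged as likely passengers; groups with at
#' least `large_threshold` member genes are flagged because no single driver
#' can be pinpointed.
#'
#' @param mat Binary mutation matrix (samples x genes).
#' @param hypermutants Character vector of hypermutated sample ids.
#' @param large_threshold Member-gene count at which a group is flagged
#'   large.
#' @return A list of `"collinear_group"` objects: `id`, `genes`, `pattern`
#'   (named 0/1 vector over samples), `n_mutant`, `hypermutant_only`,
#'   `large_group`.
#' @export
group_collinear <- function(mat, hypermutants = character(0),
                            large_threshold = 5L) {
  if (ncol(mat) == 0L) return(list())
  keys <- apply(mat, 2L, paste, collapse = "")
  split_genes <- split(colnames(mat), keys)
  # deterministic order: by first appearance of the pattern in the matrix
  first_col <- vapply(split_genes, function(g) match(g[1], colnames(mat)), 0L)
  split_genes <- split_genes[order(first_col)]
  out <- vector("list", length(split_genes))
  for (i in seq_along(split_genes)) {
    genes <- split_genes[[i]]
    pattern <- mat[, genes[1]]
    mutants <- rownames(mat)[pattern == 1L]
    out[[i]] <- structure(list(
      id = sprintf("CG%03d", i),
      genes = genes,
      pattern = pattern,
      n_mutant = length(mutants),
      hypermutant_only = length(mutants) > 0L &&
        all(mutants %in% hypermutants),
      large_group = length(genes) >= large_threshold),
      class = "collinear_group")
  }
  out
}

#' Subset a mutation matrix to a curated gene list
#'
#' @param mat Binary mutation matrix.
#' @param gene_list Character vector of gene symbols (case-sensitive).
#' @return The matrix restricted to listed genes, matrix column order
#'   preserved; empty intersection returns an empty matrix with a warning.
#' @export
subset_genes <- function(mat, gene_list) {
  if (length(gene_list) == 0L) stop("gene_list must be nonempty")
  keep <- colnames(mat) %in% gene_list
  if (!any(keep))
    warning("no matrix gene matches the gene list; returning empty matrix")
  mat[, keep, drop = FALSE]
}

#' Row/gene mean-center an expression matrix
#'
#' @param expr Numeric matrix, genes x samples.
#' @return The centered matrix (every gene row has mean 0).
#' @export
mean_center <- function(expr) {
  expr - rowMeans(expr)
}

#' Keep high-variance genes
#'
#' Either keeps genes whose sample standard deviation strictly exceeds a
#' threshold (`sd_threshold` mode), or the top `ceiling(fraction * n_genes)`
#' genes by SD (`top_fraction` mode, ties broken by gene id).
#'
#' @param expr Numeric matrix, genes x samples.
#' @param mode `"sd_threshold"` or `"top_fraction"`.
#' @param value Threshold SD or fraction, > 0.
#' @return The filtered matrix.
#' @export
variance_filter <- function(expr, mode = c("sd_threshold", "top_fraction"),
                            value = 0.7) {
  mode <- match.arg(mode)
  if (value <= 0) stop("value must be positive")
  sds <- apply(expr, 1L, stats::sd)
  if (mode == "sd_threshold") {
    expr[sds > value, , drop = FALSE]
  } else {
    # zero-variance genes carry no signal and are never kept
    k <- min(sum(sds > 0), ceiling(value * nrow(expr)))
    ord <- order(-sds, rownames(expr))
    expr[sort(ord[seq_len(k)]), , drop = FALSE]
  }
}
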