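test_that("filter_and_binarize drops non-coding classes and collapses records", {
  samples <- c("S1", "S2", "S3")
  rec <- data.frame(
    sample = c("S1", "S2", "S2", "S3", "S3", "S3"),
    gene = c("TP53", "TP53", "TP53", "KRAS", "KRAS", "KRAS"),
    class = c("silent", "missense", "missense", "intron", "utr", "flank"))
  mat <- filter_and_binarize(rec, samples)
  # TP53: only S2 has retained records; S1's silent one is filtered
  expect_identical(unname(mat[, "TP53"]), c(0L, 1L, 0L))
  # KRAS: all records excluded -> gene column absent entirely
  expect_false("KRAS" %in% colnames(mat))
  # two missense records in the same cell give a single 1
  expect_identical(sum(mat[, "TP53"]), 1L)
  expect_error(filter_and_binarize(
    data.frame(sample = "S1", gene = "X", class = "weird"), samples),
    "unknown variant class.*weird")
  expect_error(filter_and_binarize(
    data.frame(sample = "S9", gene = "X", class = "missense"), samples),
    "outside the cohort")
})

test_that("common annotation spellings are normalized", {
  expect_identical(
    hormetrics:::normalize_variant_class(
      c("Missense_Mutation", "Silent", "3'UTR", "Frame_Shift_Del", "IGR")),
    c("missense", "silent", "utr", "frameshift", "intergenic"))
})

test_that("apply_overrides writes exactly the named cells, idempotently", {
  mat <- matrix(0L, 3, 2, dimnames = list(c("S1", "S2", "S3"),
                                          c("APC", "MUTYH")))
  ov <- data.frame(sample = "S3", gene = "MUTYH")
  m1 <- apply_overrides(mat, ov)
  expect_identical(sum(m1), 1L)
  expect_identical(m1["S3", "MUTYH"], 1L)
  expect_identical(apply_overrides(m1, ov), m1)          # idempotent
  expect_identical(apply_overrides(mat, NULL), mat)      # empty = identity
  # unknown gene becomes a new column; unknown sample errors
  m2 <- apply_overrides(mat, data.frame(sample = "S1", gene = "POLE"))
  expect_identical(m2["S1", "POLE"], 1L)
  expect_error(apply_overrides(mat, data.frame(sample = "SX", gene = "APC")),
               "unknown sample")
})

test_that("recurrence_filter keeps genes mutated in >= min_samples", {
  mat <- cbind(one = c(1L, 0L, 0L, 0L), two = c(1L, 1L, 0L, 0L),
               zero = c(0L, 0L, 0L, 0L))
  rownames(mat) <- paste0("S", 1:4)
  out <- recurrence_filter(mat, 2L)
  expect_identical(colnames(out), "two")
  expect_error(recurrence_filter(mat, 0L), "min_samples")
})

test_that("group_collinear partitions genes by exact pattern with flags", {
  mat <- cbind(a = c(1L, 1L, 0L, 0L), b = c(1L, 1L, 0L, 0L),
               c = c(0L, 1L, 1L, 0L),
               d = c(1L, 0L, 0L, 0L), e = c(1L, 0L, 0L, 0L),
               f = c(1L, 0L, 0L, 0L), g = c(1L, 0L, 0L, 0L),
               h = c(1L, 0L, 0L, 0L))
  rownames(mat) <- paste0("S", 1:4)
  groups <- group_collinear(mat, hypermutants = c("S1", "S2"),
                            large_threshold = 5L)
  sizes <- vapply(groups, function(g) length(g$genes), 0L)
  expect_setequal(sizes, c(2L, 1L, 5L))
  big <- groups[[which(sizes == 5L)]]
  expect_true(big$large_group)
  expect_true(big$hypermutant_only)       # only S1 mutant, S1 is hypermutant
  ab <- groups[[which(sizes == 2L)]]
  expect_true(ab$hypermutant_only)        # S1+S2 both hypermutant
  expect_false(ab$large_group)
  cg <- groups[[which(sizes == 1L)]]
  expect_false(cg$hypermutant_only)       # S3 mutant, not hypermutant
})

test_that("group_collinear matches the brute-force oracle on random matrices", {
  set.seed(31)
  for (i in 1:10) {
    mat <- matrix(rbinom(12 * 40, 1L, 0.25), 12, 40,
                  dimnames = list(sprintf("S%02d", 1:12),
                                  sprintf("G%02d", 1:40)))
    groups <- group_collinear(mat)
    oracle <- brute_force_collinear(mat)
    got <- lapply(groups, `[[`, "genes")
    norm <- function(l) unname(sort(vapply(l, function(g)
      paste(sort(g), collapse = "|"), "")))
    expect_identical(norm(got), norm(oracle))
    # partition property: groups cover every gene exactly once
    expect_setequal(unlist(got), colnames(mat))
    expect_identical(length(unlist(got)), ncol(mat))
  }
})

test_that("group_collinear is invariant to gene input order", {
  set.seed(32)
  mat <- matrix(rbinom(10 * 30, 1L, 0.3), 10, 30,
                dimnames = list(paste0("S", 1:10), paste0("G", 1:30)))
  g1 <- group_collinear(mat)
  g2 <- group_collinear(mat[, sample(30)])
  norm <- function(gs) sort(vapply(gs, function(g)
    paste(sort(g$genes), collapse = "|"), ""))
  expect_identical(norm(g1), norm(g2))
})

test_that("subset_genes keeps listed columns in matrix order", {
  mat <- matrix(0L, 2, 4, dimnames = list(c("S1", "S2"),
                                          c("A", "B", "C", "D")))
  expect_identical(colnames(subset_genes(mat, c("D", "B"))), c("B", "D"))
  expect_identical(subset_genes(mat, colnames(mat)), mat)
  expect_warning(out <- subset_genes(mat, "ZZZ"), "no matrix gene")
  expect_identical(ncol(out), 0L)
  expect_error(subset_genes(mat, character(0)), "nonempty")
})

test_that("mean_center zeroes every gene mean and is idempotent", {
  set.seed(33)
  expr <- matrix(rnorm(50, mean = 3), 5, 10,
                 dimnames = list(paste0("g", 1:5), paste0("S", 1:10)))
  cen <- mean_center(expr)
  expect_true(all(abs(rowMeans(cen)) < 1e-12))
  expect_equal(mean_center(cen), cen)
  expect_equal(unname(mean_center(matrix(5, 1, 4))[1, ]), rep(0, 4))
  # explicit recomputation oracle
  expect_equal(cen[2, ], expr[2, ] - mean(expr[2, ]))
})

test_that("variance_filter applies strict SD threshold and top-fraction", {
  set.seed(34)
  n <- 1000; ns <- 12
  sds <- rep(0.3, n); sds[1:112] <- 1.5
  expr <- matrix(rnorm(n * ns), n, ns) * sds
  rownames(expr) <- sprintf("g%04d", 1:n)
  # scale rows to EXACT sample SD so the boundary is sharp
  expr <- expr / apply(expr, 1, sd) * sds
  kept <- variance_filter(expr, "top_fraction", 0.112)
  expect_identical(nrow(kept), 112L)
  expect_identical(rownames(kept), sprintf("g%04d", 1:112))
  # strict inequality: SD exactly at the threshold is dropped
  one <- matrix(rnorm(8), 1, 8, dimnames = list("gx", NULL))
  one <- one / sd(one) * 0.7
  expect_identical(nrow(variance_filter(one, "sd_threshold", 0.7)), 0L)
  expect_identical(nrow(variance_filter(one, "sd_threshold", 0.69)), 1L)
  # constant genes never survive either mode
  const <- rbind(flat = rep(2, 8), vary = rnorm(8))
  expect_identical(rownames(variance_filter(const, "sd_threshold", 0.01)),
                   "vary")
  expect_identical(rownames(variance_filter(const, "top_fraction", 1)),
                   "vary")
  expect_error(variance_filter(const, "sd_threshold", 0), "positive")
})

test_that("binarize -> recurrence -> collinear preserves the partition", {
  coh <- generate_cohort(quick_config(12))
  mat <- filter_and_binarize(coh$mutations,
                             unique(coh$annotations$sample))
  mat <- recurrence_filter(mat, 2L)
  groups <- group_collinear(mat)
  expect_identical(sum(vapply(groups, function(g) length(g$genes), 0L)),
                   ncol(mat))
})
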