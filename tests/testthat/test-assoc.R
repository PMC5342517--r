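# helpers to build measures tables and groups in code
fake_measures <- function(values, samples = sprintf("S%02d", seq_along(values))) {
  data.frame(sample = samples, auc_trap = values, ic50_trap = values,
             auc_fit = values, ic50_fit = values)
}

fake_group <- function(pattern, samples, id = "CG001", genes = "GENE1",
                       hyper_only = FALSE, large = FALSE) {
  structure(list(id = id, genes = genes,
                 pattern = stats::setNames(pattern, samples),
                 n_mutant = sum(pattern), hypermutant_only = hyper_only,
                 large_group = large),
            class = "collinear_group")
}

test_that("Benjamini-Hochberg matches the hand-computed worked example", {
  # min over j >= i of m * p_(j) / j: [0.01, 0.02, 0.03] -> all 0.03
  expect_equal(p.adjust(c(0.01, 0.02, 0.03), method = "BH"),
               c(0.03, 0.03, 0.03))
  # the adjustment the association path applies is exactly this
  set.seed(51)
  vals <- c(rnorm(6, 0), rnorm(6, -3))
  samples <- sprintf("S%02d", 1:12)
  groups <- list(fake_group(rep(c(1L, 0L), each = 6), samples, "CG001"),
                 fake_group(rep(c(0L, 1L, 0L, 1L), 3), samples, "CG002"),
                 fake_group(c(rep(1L, 3), rep(0L, 9)), samples, "CG003"))
  rec <- mutation_association(fake_measures(vals, samples), groups)
  for (m in unique(rec$measure)) {
    i <- rec$measure == m
    expect_equal(rec$p_adj[i], p.adjust(rec$p[i], method = "BH"))
  }
})

test_that("BH is monotone in rank and never below the raw p", {
  set.seed(52)
  for (i in 1:50) {
    p <- runif(sample(3:40, 1))
    adj <- p.adjust(p, method = "BH")
    expect_true(all(adj >= p - 1e-15))
    ord <- order(p)
    expect_true(all(diff(adj[ord]) >= -1e-15))
    expect_true(all(adj <= 1))
  }
})

test_that("mutation_association tests groups with Welch t and flags", {
  samples <- sprintf("S%02d", 1:10)
  vals <- c(1, 1.1, 0.9, 1.05, 0.95, 3, 3.2, 2.8, 3.1, 2.9)
  grp <- fake_group(rep(c(1L, 0L), each = 5), samples,
                    genes = c("A", "B"), hyper_only = TRUE)
  rec <- mutation_association(fake_measures(vals, samples), list(grp))
  expect_identical(nrow(rec), 4L)
  expect_true(all(rec$direction == "sensitizing"))  # mutants lower
  expect_true(all(rec$significant))
  expect_true(all(rec$hypermutant_only))
  tt <- t.test(vals[1:5], vals[6:10])
  expect_equal(rec$statistic[rec$measure == "auc_trap"],
               unname(tt$statistic))
  # identical value sets in both arms: t = 0, p = 1, not significant
  same <- c(1, 2, 3, 4, 5, 1, 2, 3, 4, 5)
  g2 <- fake_group(rep(c(1L, 0L), each = 5), samples)
  rec2 <- mutation_association(fake_measures(same, samples), list(g2))
  expect_equal(rec2$statistic, rep(0, 4))
  expect_equal(rec2$p, rep(1, 4))
  expect_false(any(rec2$significant))
  # under-sized arms are skipped, not tested
  g3 <- fake_group(c(1L, rep(0L, 9)), samples, id = "CGskip")
  rec3 <- mutation_association(fake_measures(vals, samples), list(grp, g3))
  expect_identical(attr(rec3, "skipped"), "CGskip")
  expect_false("CGskip" %in% rec3$feature)
  expect_error(mutation_association(fake_measures(vals)[, -2], list(grp)),
               "lacks column")
})

test_that("expression_association screens by |r| >= 0.5 inclusive", {
  samples <- sprintf("S%02d", 1:10)
  set.seed(53)
  y <- rnorm(10)
  expr <- rbind(self = y, anti = -y, flat = rep(1, 10),
                noise = rnorm(10))
  colnames(expr) <- samples
  meas <- fake_measures(y, samples)
  rec <- expression_association(meas, expr)
  expect_identical(attr(rec, "skipped"), "flat")
  self_rec <- rec[rec$feature == "self" & rec$measure == "auc_trap", ]
  expect_equal(self_rec$statistic, 1)
  expect_true(self_rec$significant)
  expect_identical(self_rec$direction, "resistance")
  anti_rec <- rec[rec$feature == "anti" & rec$measure == "auc_trap", ]
  expect_equal(anti_rec$statistic, -1)
  expect_identical(anti_rec$direction, "sensitizing")
  expect_error(expression_association(fake_measures(y[1:2], samples[1:2]),
                                      expr[, 1:2]), "fewer than 3")
})

test_that("robustness_filter applies the inclusive >= 2-of-4 rule", {
  rec <- data.frame(
    feature = rep(c("f1", "f2", "f3"), each = 4),
    kind = "mutation_group",
    measure = rep(c("auc_trap", "ic50_trap", "auc_fit", "ic50_fit"), 3),
    significant = c(TRUE, TRUE, FALSE, FALSE,   # f1: 2 -> kept
                    TRUE, FALSE, FALSE, FALSE,  # f2: 1 -> dropped
                    TRUE, TRUE, TRUE, TRUE),    # f3: 4 -> kept
    hypermutant_only = rep(c(TRUE, FALSE, FALSE), each = 4),
    large_group = FALSE,
    genes = rep(c("A", "B", "C"), each = 4))
  out <- robustness_filter(rec)
  expect_setequal(out$feature, c("f1", "f3"))
  expect_identical(out$n_significant_measures[out$feature == "f3"], 4L)
  expect_identical(out$n_significant_measures[out$feature == "f1"], 2L)
  # flags survive the filter
  expect_true(out$hypermutant_only[out$feature == "f1"])
  expect_false(out$hypermutant_only[out$feature == "f3"])
  expect_identical(nrow(robustness_filter(rec, min_measures = 5)), 0L)
})

test_that("group_scalar_test is a two-sided t-test with the F identity", {
  x <- c(1, 2, 3, 4, 1.5, 2.5, 3.5, 4.5)
  labels <- rep(c("A", "B"), each = 4)
  same <- group_scalar_test(c(1, 2, 3, 1, 2, 3), rep(c("A", "B"), each = 3))
  expect_equal(same$p, 1)
  # pooled t^2 equals the classical one-way F on the same split
  set.seed(54)
  y <- rnorm(12); lab <- rep(c("A", "B"), each = 6)
  tt <- group_scalar_test(y, lab, pooled = TRUE)
  ft <- oneway.test(y ~ lab, var.equal = TRUE)
  expect_equal(tt$statistic^2, unname(ft$statistic))
  expect_equal(tt$p, ft$p.value)
  expect_error(group_scalar_test(y, rep("A", 12)), "two levels")
  expect_error(group_scalar_test(y, c("A", rep("B", 11))), "at least 2")
})

test_that("subtype_association runs one-way ANOVA with level merging", {
  set.seed(55)
  # balanced equal-mean case: F near 0 against the direct formula oracle
  y <- rep(c(-1, 1), 6)
  lab <- rep(c("CMS1", "CMS2", "CMS3"), each = 4)
  r <- subtype_association(y, lab)
  k <- 3; n <- 12
  means <- tapply(y, lab, mean); gm <- mean(y)
  ssb <- sum(table(lab) * (means - gm)^2) / (k - 1)
  ssw <- sum((y - means[lab])^2) / (n - k)
  expect_equal(r$statistic, unname(ssb / ssw))
  expect_equal(r$statistic, 0)
  # two levels: F equals the squared pooled t
  y2 <- rnorm(10); lab2 <- rep(c("CMS1", "CMS2"), each = 5)
  r2 <- subtype_association(y2, lab2)
  t2 <- group_scalar_test(y2, lab2, pooled = TRUE)
  expect_equal(r2$statistic, t2$statistic^2)
  # sparse levels are merged with a warning
  expect_warning(r3 <- subtype_association(c(y2, 5), c(lab2, "CMS4")),
                 "CMS4")
  expect_error(suppressWarnings(subtype_association(y2[1:3],
                                                    c("A", "B", "C"))),
               "usable subtype levels")
  # a level shifted far out is detected
  y4 <- c(rnorm(8), rnorm(4, 10)); lab4 <- rep(c("CMS1", "CMS2", "CMS3"),
                                               c(4, 4, 4))
  expect_lt(subtype_association(y4, lab4)$p, 0.01)
})

test_that("drug_correlations uses pairwise-complete samples", {
  set.seed(56)
  n <- 12
  base <- rnorm(n)
  mat <- cbind(EZH2i = base, dup = base, other = rnorm(n),
               sparse = c(rnorm(2), rep(NA, n - 2)))
  rownames(mat) <- sprintf("S%02d", 1:n)
  mat[1:3, "other"] <- NA
  dc <- drug_correlations(mat)
  expect_equal(dc$matrix["EZH2i", "dup"], 1)
  expect_equal(diag(dc$matrix), rep(1, 4), ignore_attr = TRUE)
  expect_true(isSymmetric(dc$matrix))
  # pairwise-complete oracle: explicit subset per pair
  ok <- complete.cases(mat[, c("EZH2i", "other")])
  expect_equal(dc$matrix["EZH2i", "other"],
               cor(mat[ok, "EZH2i"], mat[ok, "other"]))
  # below min_pairs -> NA
  expect_true(is.na(dc$matrix["EZH2i", "sparse"]))
  # ranking excludes the focal drug, descending, NAs last
  expect_identical(dc$ranking$drug[1], "dup")
  expect_identical(dc$ranking$drug[3], "sparse")
  expect_error(drug_correlations(mat[, 2:4]), "focal")
})

test_that("association outputs are invariant to sample ordering", {
  coh <- generate_cohort(quick_config(57))
  q <- quantify_cohort(coh$counts, seed = 57)
  mat <- recurrence_filter(
    filter_and_binarize(coh$mutations, coh$annotations$sample), 2L)
  groups <- group_collinear(mat)
  rec1 <- suppressWarnings(mutation_association(q$measures, groups))
  perm <- sample(nrow(q$measures))
  rec2 <- suppressWarnings(mutation_association(q$measures[perm, ], groups))
  expect_equal(rec1$p, rec2$p)
  expect_equal(rec1$statistic, rec2$statistic)
  expr <- variance_filter(mean_center(coh$expression), "sd_threshold", 0.7)
  e1 <- expression_association(q$measures, expr)
  e2 <- expression_association(q$measures[perm, ], expr)
  expect_equal(e1$statistic, e2$statistic)
})

test_that("planted features are recovered in a single effect cohort", {
  coh <- generate_cohort(cohort_config(rng_seed = 58))
  q <- quantify_cohort(coh$counts, seed = 58)
  mat <- recurrence_filter(
    filter_and_binarize(coh$mutations, coh$annotations$sample), 2L)
  groups <- group_collinear(mat,
                            coh$annotations$sample[coh$annotations$hypermutant])
  rec <- suppressWarnings(mutation_association(q$measures, groups))
  expr <- variance_filter(mean_center(coh$expression), "sd_threshold", 0.7)
  rec <- rbind(rec, expression_association(q$measures, expr))
  robust <- robustness_filter(rec)
  hits <- unlist(strsplit(robust$genes, ","))
  expect_true(coh$truth$mutation_gene %in% hits)
  expect_true(coh$truth$expression_gene %in% robust$feature)
  dc <- drug_correlations(coh$drugs)
  expect_identical(dc$ranking$drug[1], coh$truth$correlated_drug)
})
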