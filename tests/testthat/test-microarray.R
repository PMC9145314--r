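# Microarray pipeline: reliability filtering, quantile normalization,
# symbol collapse, differential expression, DEG union, FDR, PCA, heatmap.

mini_features <- function(n, symbol = sprintf("G%02d", seq_len(n))) {
  data.frame(feature_id = sprintf("F%02d", seq_len(n)), symbol = symbol,
             above_noise = TRUE, below_saturation = TRUE,
             population_outlier = FALSE, uniform_spot = TRUE,
             is_control = FALSE, stringsAsFactors = FALSE)
}

mini_samples <- function(k) {
  data.frame(sample = sprintf("s%d", seq_len(k)), cell_line = "WT",
             exposure = "control", replicate = seq_len(k))
}

test_that("reliability filter keeps exactly the features passing all five criteria", {
  f <- mini_features(10)
  f$above_noise[1] <- FALSE
  f$population_outlier[2] <- TRUE
  f$is_control[3] <- TRUE
  tab <- feature_table(f, matrix(2^8, 10, 2), mini_samples(2))
  kept <- filter_reliable(tab)
  expect_equal(nrow(kept$features), 7)
  expect_false(any(kept$features$feature_id %in% c("F01", "F02", "F03")))
  # empty table stays empty
  empty <- feature_table(f[0, ], matrix(0, 0, 2), mini_samples(2))
  expect_equal(nrow(filter_reliable(empty)$features), 0)
  # missing flag column is a schema error naming the column
  expect_error(feature_table(f[, -3], matrix(1, 10, 2), mini_samples(2)),
               "above_noise")
})

test_that("quantile normalization matches hand arithmetic and equalizes distributions", {
  # hand-computed 3 x 2 case: sorted-column row means are (2.5, 4, 5.5)
  m <- 2^matrix(c(1, 2, 3, 6, 4, 8), nrow = 3)
  em <- log2_quantile_normalize(m)
  expect_equal(em$values[, 1], c(2.5, 4, 5.5), ignore_attr = TRUE)
  expect_equal(em$values[, 2], c(4, 2.5, 5.5), ignore_attr = TRUE)
  # identical samples are unchanged
  mm <- 2^matrix(c(5, 1, 3, 5, 1, 3), nrow = 3)
  expect_equal(log2_quantile_normalize(mm)$values, log2(mm),
               ignore_attr = TRUE)
  # sorted columns identical; within-sample rank order preserved
  set.seed(42)
  r <- matrix(rexp(200, 0.1) + 0.5, 40, 5)
  v <- log2_quantile_normalize(r)$values
  for (j in 2:5) expect_equal(sort(v[, j]), sort(v[, 1]))
  for (j in 1:5) expect_equal(order(v[, j]), order(r[, j]))
  expect_error(log2_quantile_normalize(matrix(c(1, 0, 2, 3), 2)),
               "non-positive")
})

test_that("symbol collapse takes per-sample medians and drops empty symbols", {
  f <- mini_features(12, symbol = c(rep("A", 3), rep("B", 2), "C", "D", "E",
                                    rep("E", 2), "", "E"))
  vals <- matrix(2^(1:12), 12, 2)
  em <- log2_quantile_normalize(feature_table(f, vals, mini_samples(2)))
  col <- collapse_by_symbol(em)
  expect_equal(nrow(col$values), 5)  # A B C D E
  expect_equal(attr(col, "n_dropped"), 1)
  expect_equal(unname(col$values["A", 1]), 2)        # median of log2 values 1,2,3
  expect_equal(unname(col$values["B", 1]), 4.5)      # median of 4,5
  expect_equal(unname(col$values["C", 1]), 6)        # single feature unchanged
  expect_equal(unname(col$values["E", 1]), median(c(8, 9, 10, 12)))
  # pipeline is idempotent once collapsed (filter/normalize/collapse again)
  again <- collapse_by_symbol(log2_quantile_normalize(2^col$values))
  expect_equal(again$values, col$values, tolerance = 1e-12)
})

test_that("per-gene t-tests match stats::t.test and obey label symmetry", {
  set.seed(3)
  v <- matrix(rnorm(60, 8, 1), 10, 6,
              dimnames = list(sprintf("G%02d", 1:10), sprintf("s%d", 1:6)))
  em <- structure(list(values = v,
                       rows = data.frame(symbol = rownames(v)),
                       samples = data.frame(sample = colnames(v),
                                            grp = rep(c("a", "b"), each = 3))),
                  class = "expression_matrix")
  r <- differential_expression(em, em$samples$grp == "a",
                               em$samples$grp == "b", label = "toy")
  for (g in 1:10) {
    tt <- t.test(v[g, 1:3], v[g, 4:6], var.equal = TRUE)
    expect_equal(r$t[g], unname(tt$statistic), tolerance = 1e-12)
    expect_equal(r$p[g], tt$p.value, tolerance = 1e-12)
    expect_equal(r$log2fc[g], mean(v[g, 1:3]) - mean(v[g, 4:6]),
                 tolerance = 1e-12)
  }
  # swapping group labels negates the fold change, keeps the p-value
  rs <- differential_expression(em, em$samples$grp == "b",
                                em$samples$grp == "a")
  expect_equal(rs$log2fc, -r$log2fc)
  expect_equal(rs$p, r$p)
  # identical groups: log2FC 0, p 1
  em$values[, 4:6] <- em$values[, 1:3]
  ri <- differential_expression(em, em$samples$grp == "a",
                                em$samples$grp == "b")
  expect_true(all(ri$log2fc == 0) && all(ri$p == 1))
  expect_error(differential_expression(em, em$samples$sample == "s1",
                                       em$samples$grp == "b"),
               ">= 2 replicates")
})

fake_comparison <- function(genes, sig, label) {
  r <- data.frame(gene = genes, log2fc = 0, t = 0,
                  p = ifelse(genes %in% sig, 1e-5, 0.5))
  attr(r, "label") <- label
  class(r) <- c("comparison_result", "data.frame")
  r
}

test_that("DEG union accounting matches brute-force set arithmetic", {
  genes <- sprintf("G%03d", 1:500)
  sets <- list(a = genes[1:6], b = genes[7:15], c = genes[16:30],
               d = genes[31:65], e = c(genes[66:103], genes[10], genes[40]))
  cmp <- mapply(fake_comparison, sig = sets, label = names(sets),
                MoreArgs = list(genes = genes), SIMPLIFY = FALSE)
  degs <- select_degs(cmp, alpha = 0.001)
  expect_equal(degs$per_comparison,
               c(a = 6L, b = 9L, c = 15L, d = 35L, e = 40L))
  expect_equal(length(degs$genes), length(unique(unlist(sets))))
  expect_equal(length(degs$genes), 103)  # 105 calls, 2 overlapping genes
  expect_equal(degs$total_calls, 105)
  expect_equal(degs$overlap["b", "e"], 1L)
  expect_equal(degs$overlap["d", "e"], 1L)
  # disjoint sets: union is the plain sum; identical sets: single set size
  dis <- select_degs(cmp[1:2])
  expect_equal(length(dis$genes), 15)
  same <- select_degs(list(cmp$a, cmp$a))
  expect_equal(length(same$genes), 6)
  expect_error(select_degs(list(cmp$a, fake_comparison(genes[-1], sets$a, "x"))),
               "inconsistent gene universes")
})

test_that("FDR estimate is expected false positives over observed calls", {
  calls <- 6 + 9 + 15 + 35 + 40 + 332 + 219
  fdr <- estimate_fdr(calls, n_genes = 10246, n_comparisons = 7, alpha = 0.001)
  expect_equal(round(fdr * 100), 11)
  # calls equal to the expectation: FDR 100%
  expect_equal(estimate_fdr(50, n_genes = 1000, n_comparisons = 1,
                            alpha = 0.05), 1)
  expect_equal(estimate_fdr(100, 1000, 5, alpha = 0), 0)
  expect_warning(f0 <- estimate_fdr(0, 1000, 5), "not available")
  expect_true(is.na(f0))
})

test_that("PCA scores separate constructed clusters and report variance fractions", {
  set.seed(9)
  v <- cbind(matrix(rnorm(50 * 4, 0, 0.3), 50, 4),
             matrix(rnorm(50 * 4, 3, 0.3), 50, 4))
  rownames(v) <- sprintf("G%02d", 1:50)
  colnames(v) <- sprintf("s%d", 1:8)
  em <- structure(list(values = v, rows = data.frame(symbol = rownames(v)),
                       samples = data.frame(sample = colnames(v))),
                  class = "expression_matrix")
  pc <- pca_scores(em)
  expect_true(all(diff(pc$variance_fraction) <= 1e-12))
  expect_lte(sum(pc$variance_fraction), 1 + 1e-9)
  expect_gt(min(abs(pc$scores[1:4, 1] - mean(pc$scores[, 1]))) +
            min(abs(pc$scores[5:8, 1] - mean(pc$scores[, 1]))), 0)
  expect_true(max(pc$scores[1:4, 1]) < min(pc$scores[5:8, 1]) ||
              min(pc$scores[1:4, 1]) > max(pc$scores[5:8, 1]))
  # a duplicated sample gets identical scores
  em$values <- cbind(em$values, em$values[, 1, drop = FALSE])
  em$samples <- rbind(em$samples, data.frame(sample = "dup"))
  pc2 <- pca_scores(em)
  expect_equal(pc2$scores[1, ], pc2$scores[9, ], ignore_attr = TRUE)
  em$values[] <- 1
  expect_error(pca_scores(em), "no variance")
})

test_that("log2FC heatmap clustering matches a naive agglomeration oracle", {
  # construct an expression matrix whose per-comparison log2FCs are known
  genes <- sprintf("G%d", 1:5)
  fc_truth <- c(0, 0.1, 1.0, 1.1, 5)
  v <- rbind(outer(fc_truth, c(1, 1, 1, 0, 0, 0)))
  v <- v + 6
  rownames(v) <- genes
  colnames(v) <- sprintf("s%d", 1:6)
  em <- structure(list(values = v, rows = data.frame(symbol = genes),
                       samples = data.frame(sample = colnames(v),
                                            grp = rep(c("g", "c"), each = 3))),
                  class = "expression_matrix")
  cmp <- list(one = list(group = em$samples$grp == "g",
                         control = em$samples$grp == "c"))
  hm <- log2fc_heatmap(em, cmp, c(genes, "ABSENT"))
  expect_equal(hm$skipped, "ABSENT")
  expect_equal(sort(hm$log2fc[, "one"]), sort(fc_truth), ignore_attr = TRUE)
  # oracle: naive average-linkage agglomeration on the same distances
  or <- oracle_average_linkage(dist(matrix(fc_truth)))
  expect_equal(sort(hm$hclust$height), sort(or$heights), tolerance = 1e-12)
  for (k in c(2, 3, 4)) {
    naive <- partition_signature(or$partitions[[5 - k]], 5)
    expect_equal(hclust_signature(hm$hclust, k, 5), naive,
                 info = paste("k =", k))
  }
  # identical rows merge at zero height and sit on adjacent leaves
  v2 <- v; v2["G2", ] <- v2["G1", ]
  em$values <- v2
  hm2 <- log2fc_heatmap(em, cmp, genes)
  expect_equal(min(hm2$hclust$height), 0)
  pos <- match(c("G1", "G2"), rownames(hm2$log2fc))
  expect_equal(abs(diff(pos)), 1)
  # single gene: trivial one-leaf result
  hm1 <- log2fc_heatmap(em, cmp, "G5")
  expect_null(hm1$hclust)
  expect_equal(nrow(hm1$log2fc), 1)
})

test_that("feature tables survive a TSV round trip", {
  tab <- gen_expression(n_genes = 40, probes_per_gene = 2,
                        flag_fail_rate = 0.1, control_fraction = 0.05,
                        seed = 4)
  dir <- tempfile()
  write_feature_tables(tab, dir)
  back <- read_feature_tables(file.path(dir, "samples.tsv"))
  expect_equal(back$features$feature_id, tab$features$feature_id)
  expect_equal(back$features$is_control, tab$features$is_control)
  expect_equal(unname(back$intensity), unname(tab$intensity),
               tolerance = 1e-6)
  expect_equal(back$samples$sample, tab$samples$sample)
  expect_true(file.exists(file.path(dir, "truth.json")))
})
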