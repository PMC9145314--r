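#!/usr/bin/env Rscript
# Microarray pipeline on the generated feature tables: reliability filter,
# log2 + quantile normalization, gene-symbol collapse, per-comparison
# t-tests (p < 0.001), DEG union with FDR estimate, PCA, clustered log2FC
# heatmap.

suppressPackageStartupMessages(library(npinflam))

out <- "results/microarray"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

tab <- read_feature_tables("results/data/expression/samples.tsv")
message(sprintf("loaded %d features x %d samples", nrow(tab$features),
                ncol(tab$intensity)))
em <- collapse_by_symbol(log2_quantile_normalize(filter_reliable(tab)))
message(sprintf("gene-level matrix: %d genes x %d samples",
                nrow(em$values), ncol(em$values)))
write.table(round(em$values, 5), file.path(out, "normalized_matrix.tsv"),
            sep = "\t", quote = FALSE)

comparisons <- list(
  star_WT = list(group = list(cell_line = "WT", exposure = "GNP-1"),
                 control = list(cell_line = "WT", exposure = "control")),
  sphere_WT = list(group = list(cell_line = "WT", exposure = "GNP-4"),
                   control = list(cell_line = "WT", exposure = "control")),
  rod_WT = list(group = list(cell_line = "WT", exposure = "GNP-6"),
                control = list(cell_line = "WT", exposure = "control")),
  rod_ASC = list(group = list(cell_line = "ASC-def", exposure = "GNP-6"),
                 control = list(cell_line = "ASC-def", exposure = "control")),
  rod_NLRP3 = list(group = list(cell_line = "NLRP3-def", exposure = "GNP-6"),
                   control = list(cell_line = "NLRP3-def", exposure = "control")),
  ASC_base = list(group = list(cell_line = "ASC-def", exposure = "control"),
                  control = list(cell_line = "WT", exposure = "control")),
  NLRP3_base = list(group = list(cell_line = "NLRP3-def", exposure = "control"),
                    control = list(cell_line = "WT", exposure = "control")))

res <- lapply(names(comparisons), function(nm) {
  r <- differential_expression(em, comparisons[[nm]]$group,
                               comparisons[[nm]]$control, label = nm)
  write.table(r, file.path(out, paste0("comparison_", nm, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  r
})
names(res) <- names(comparisons)

degs <- select_degs(res, alpha = 0.001)
fdr <- estimate_fdr(degs, n_genes = nrow(em$values),
                    n_comparisons = length(res), alpha = 0.001)
message(sprintf("DEGs per comparison: %s",
                paste(sprintf("%s=%d", names(degs$per_comparison),
                              degs$per_comparison), collapse = ", ")))
message(sprintf("union %d genes (%d calls); FDR estimate %.0f%%",
                length(degs$genes), degs$total_calls, 100 * fdr))
write.table(data.frame(gene = degs$genes), file.path(out, "deg_set.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
jsonlite::write_json(list(per_comparison = as.list(degs$per_comparison),
                          union = length(degs$genes),
                          total_calls = degs$total_calls, fdr = fdr),
                     file.path(out, "deg_summary.json"),
                     auto_unbox = TRUE, digits = NA)

# PCA of the samples in the DEG space; treatment comparisons drive the heatmap
pca <- pca_scores(em, degs$genes)
message(sprintf("PCA: PC1 %.0f%%, PC2 %.1f%% of variance",
                100 * pca$variance_fraction[1], 100 * pca$variance_fraction[2]))
write.table(cbind(em$samples, round(pca$scores[, 1:4], 5)),
            file.path(out, "pca_scores.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)

hm <- log2fc_heatmap(em, comparisons[1:5], degs$genes)
write.table(round(hm$log2fc, 5), file.path(out, "heatmap_log2fc.tsv"),
            sep = "\t", quote = FALSE)
if (requireNamespace("pheatmap", quietly = TRUE)) {
  pheatmap::pheatmap(hm$log2fc, cluster_rows = hm$hclust, cluster_cols = FALSE,
                     show_rownames = nrow(hm$log2fc) <= 60,
                     main = "log2FC of union DEGs per comparison",
                     filename = file.path(out, "heatmap_log2fc.png"),
                     width = 6, height = 9)
  message("wrote clustered heatmap PNG")
}
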