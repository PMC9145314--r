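#!/usr/bin/env Rscript
# Gene set enrichment per comparison: rank genes by signed t-statistic,
# weighted running-sum ES with a gene-label permutation null, BH q-values,
# and a summary grid of sets that are repeatedly significant or top-ranked.

suppressPackageStartupMessages(library(npinflam))

out <- "results/gsea"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

sets <- read_gmt("results/data/gene_sets.gmt")
message(sprintf("loaded %d gene sets", length(sets)))

cmp_files <- list.files("results/microarray", pattern = "^comparison_.*\\.tsv$",
                        full.names = TRUE)
enr <- list()
for (f in cmp_files) {
  nm <- sub("^comparison_(.*)\\.tsv$", "\\1", basename(f))
  cmp <- read.delim(f)
  ranked <- rank_genes(cmp)
  e <- permutation_significance(ranked, sets, n_perm = 1000, seed = 17)
  write.table(e, file.path(out, paste0("gsea_", nm, ".tsv")), sep = "\t",
              quote = FALSE, row.names = FALSE)
  for (i in seq_len(nrow(e))) {
    message(sprintf("%-12s %-32s ES %+.2f NES %+.2f p %.4g (%s)",
                    nm, e$set[i], e$es[i], e$nes[i], e$p[i], e$direction[i]))
  }
  enr[[nm]] <- e
}

grid <- enrichment_summary_grid(enr, p_cut = 0.05, top_n = 20, min_times = 2)
write.table(grid, file.path(out, "summary_grid.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message(sprintf("summary grid: %d sets repeatedly significant/top-ranked",
                nrow(grid)))
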