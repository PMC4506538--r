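#!/usr/bin/env Rscript
# Stage 5: tissue-specificity rank analysis across the 81-tissue atlas.
#
# Ranks every gene's cerebral-cortex expression among all tissues
# (1 = lowest anywhere, 81 = highest anywhere), tests the planted
# neural-enriched set for a right skew with the one-sided KS statistic,
# repeats the scan for every tissue, and compares neural vs non-neural
# p-values with a one-sided Wilcoxon rank-sum test.
suppressPackageStartupMessages(library(areutr))

data_dir <- "results/data"
m <- read_matrix_tsv(file.path(data_dir, "atlas.tsv"))
lab <- read.delim(file.path(data_dir, "labels.tsv"), header = FALSE,
                  col.names = c("tissue", "class"))
labels <- setNames(lab$class, lab$tissue)
gene_set <- readLines(file.path(data_dir, "atlas_planted_genes.txt"))

rd_all <- rank_distribution(m$values, "cerebral_cortex", "all")
rd_set <- rank_distribution(m$values, "cerebral_cortex", gene_set)
write.table(data.frame(rank = seq_along(rd_all$counts),
                       all_genes = rd_all$counts,
                       gene_set = rd_set$counts),
            "results/cortex_rank_histogram.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

rk <- tissue_rank_matrix(m$values)[, "cerebral_cortex"]
skew <- ks_right_skew(rk[gene_set], rk)
message(sprintf(
  "cortex rank right skew of the gene set: D+ = %.3f, one-sided p = %.3g",
  skew$D_plus, skew$p))

scan <- per_tissue_scan(m$values, gene_set)
write.table(scan, "results/tissue_scan.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
top <- scan[order(scan$p), ][1:5, ]
message("smallest skew p-values: ",
        paste(sprintf("%s (p=%.2g)", top$tissue, top$p), collapse = ", "))

nn <- neural_vs_nonneural(scan, labels)
write.table(data.frame(stat = names(unlist(nn)), value = unlist(nn)),
            "results/neural_vs_nonneural.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
message(sprintf(
  "neural vs non-neural skew p-values: Wilcoxon one-sided p = %.3g (medians %.2g vs %.2g)",
  nn$wilcoxon_p, nn$neural_median_p, nn$nonneural_median_p))
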