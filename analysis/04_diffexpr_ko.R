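#!/usr/bin/env Rscript
# Stage 4: KO vs WT differential expression.
#
# Selects probe sets with > 10-fold, BH-adjusted p < 0.05, direction-
# consistent changes between the KO and WT replicate groups; collapses them
# to genes; and summarizes where the upregulated set sits relative to the
# transcriptome median in each genotype.
suppressPackageStartupMessages(library(areutr))

data_dir <- "results/data"
m <- read_matrix_tsv(file.path(data_dir, "ko_matrix.tsv"))
ko_cols <- grep("^KO_", colnames(m$values), value = TRUE)
wt_cols <- grep("^WT_", colnames(m$values), value = TRUE)

hits <- select_hits(m$values, ko_cols, wt_cols,
                    fold_threshold = 10, alpha = 0.05)
write.table(hits, "results/diffexpr_hits.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
message(nrow(hits), " probe-set hits (",
        sum(hits$direction == "up"), " up, ",
        sum(hits$direction == "down"), " down)")

truth <- read.delim(file.path(data_dir, "ko_truth.tsv"))
up_truth <- truth$probe_id[truth$direction == "up"]
sens <- mean(up_truth %in% hits$probe_id[hits$direction == "up"])
message(sprintf("sensitivity on planted up rows: %.1f%%", 100 * sens))

probe2gene <- setNames(sub("^p", "g", hits$probe_id), hits$probe_id)
genes <- collapse_to_genes(hits, probe2gene)
writeLines(genes$up_genes, "results/ko_up_genes.txt")
message(length(genes$up_genes), " upregulated genes / ",
        genes$up_probes, " probes; ",
        length(genes$down_genes), " downregulated genes / ",
        genes$down_probes, " probes")

if (length(genes$up_genes) > 0) {
  up_probes <- hits$probe_id[hits$direction == "up"]
  ms <- median_position_summary(m$values, up_probes, wt_cols, ko_cols)
  message(sprintf(
    "upregulated set median: WT %.2f (transcriptome %.2f), KO %.2f (transcriptome %.2f)",
    ms[["median_a"]], ms[["transcriptome_median_a"]],
    ms[["median_b"]], ms[["transcriptome_median_b"]]))
  write.table(data.frame(stat = names(ms), value = unname(ms)),
              "results/median_position.tsv",
              sep = "\t", quote = FALSE, row.names = FALSE)
}
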