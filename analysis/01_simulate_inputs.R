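#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study inputs with planted ground truth.
#
# Produces, under results/data/:
#   utrs.fa / utrs.bed      3' UTRs with planted AUUUA/UAUUUAU content
#   sample_diff.sam         3' end reads, ARE-rich genes upregulated
#   sample_undiff.sam       baseline 3' end reads
#   truth_counts.tsv        planted per-gene PASS counts, both samples
#   ko_matrix.tsv           log2 KO/WT replicate matrix (planted 16-fold)
#   ko_truth.tsv            planted up/down probe sets
#   atlas.tsv / labels.tsv  81-tissue atlas with planted neural set
suppressPackageStartupMessages(library(areutr))

out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 20L

cfg <- sim_config(seed = seed)
message("motif plan: ", paste(names(cfg$motif_plan), collapse = ", "))

utrs <- gen_utrs(cfg)
bed <- make_utr_bed(utrs)
write_utr_fasta(utrs, file.path(out, "utrs.fa"))
write_bed6(bed, file.path(out, "utrs.bed"))
write.table(utrs[, c("utr_id", "gene_id", "group")],
            file.path(out, "utr_groups.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
message("UTRs: ", nrow(utrs), " across ", length(unique(utrs$group)),
        " motif groups")

# plant motif-dependent fold changes into the differentiated sample counts
ann <- annotate_ares(utrs)
fc_true <- gen_fold_changes(cfg, ann)
set.seed(seed + 1L)
truth_undiff <- setNames(
  sample(cfg$reads_per_gene_range[1]:cfg$reads_per_gene_range[2],
         nrow(bed), replace = TRUE), bed$name)
truth_diff <- setNames(
  pmax(1L, as.integer(round(truth_undiff * 2^fc_true[names(truth_undiff)]))),
  names(truth_undiff))
gen_sam_3reads(cfg, bed, file.path(out, "sample_diff.sam"),
               truth = truth_diff)
gen_sam_3reads(sim_config(seed = seed + 2L), bed,
               file.path(out, "sample_undiff.sam"), truth = truth_undiff)
write.table(data.frame(gene_id = names(truth_undiff),
                       pass_diff = unname(truth_diff),
                       pass_undiff = unname(truth_undiff),
                       log2fc_planted = unname(fc_true[names(truth_undiff)])),
            file.path(out, "truth_counts.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
message("planted PASS reads: ", sum(truth_diff), " (differentiated) / ",
        sum(truth_undiff), " (undifferentiated)")

ko <- gen_ko_matrix(cfg)
write_matrix_tsv(ko$values, file.path(out, "ko_matrix.tsv"),
                 id_col = "probe_id")
write.table(data.frame(probe_id = c(ko$truth_up, ko$truth_down),
                       direction = rep(c("up", "down"),
                                       c(length(ko$truth_up),
                                         length(ko$truth_down)))),
            file.path(out, "ko_truth.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
message("KO matrix: ", nrow(ko$values), " probe sets, planted ",
        length(ko$truth_up), " up / ", length(ko$truth_down), " down at ",
        cfg$ko_plan$fold, "-fold")

atlas <- gen_atlas(cfg)
write_matrix_tsv(atlas$values, file.path(out, "atlas.tsv"),
                 id_col = "gene_id")
write.table(data.frame(tissue = names(atlas$neural_labels),
                       class = unname(atlas$neural_labels)),
            file.path(out, "labels.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
writeLines(atlas$planted_genes, file.path(out, "atlas_planted_genes.txt"))
message("atlas: ", nrow(atlas$values), " genes x ", ncol(atlas$values),
        " tissues (", sum(atlas$neural_labels == "neural"),
        " neural), planted neural set of ", length(atlas$planted_genes))
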