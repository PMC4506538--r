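#!/usr/bin/env Rscript
# Stage 2: ARE annotation of the 3' UTRs and pentamer enrichment.
#
# Annotates AUUUA / UAUUUAU content (with the >= 12 nt AU-run clustered
# class), bins genes by pentamer count, and asks which pentamers are
# over-represented in the ARE-rich UTRs relative to the ARE-less ones.
suppressPackageStartupMessages(library(areutr))

data_dir <- "results/data"
dir.create("results", showWarnings = FALSE)

utrs <- read_utr_fasta(file.path(data_dir, "utrs.fa"))
ann <- annotate_ares(utrs, min_run = 12L)
write.table(ann, "results/are_annotation.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

groups <- group_by_pentamer_count(ann)
message("pentamer-count groups: ",
        paste(sprintf("%s: %d", names(groups), lengths(groups)),
              collapse = ", "))
message("clustered heptamers found in ",
        sum(ann$n_clustered > 0), " UTRs")

fg <- utrs[ann$n_pentamer >= 6, ]
bg <- utrs[ann$n_pentamer == 0, ]
enr <- pentamer_enrichment(fg, bg, k = 5L, n_perm = 999L, seed = 30L)
write.table(enr, "results/pentamer_enrichment.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
message("top 5 enriched pentamers in ARE-rich UTRs: ",
        paste(enr$kmer[1:5], collapse = ", "))
core <- match(c("UAUUU", "UUUAU", "AUUUA"), enr$kmer)
message("ranks of the ARE core pentamers UAUUU/UUUAU/AUUUA: ",
        paste(core, collapse = ", "))
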