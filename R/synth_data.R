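## Seeded synthetic-data generators. Each generator is a pure function of
## the simulation config: the same seed yields byte-identical output. Every
## dataset is emitted together with its ground truth so recovery can be
## asserted exactly.

## Evaluate expr under a fixed seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  expr
}

#' Simulation configuration
#'
#' Bundles every tunable of the synthetic-data generators with defaults that
#' emulate the study conditions of the analyses: a four-bin AUUUA motif plan
#' (0, 1-2, 3-5, >= 6 pentamers, the top bin in a clustered >= 12 nt AU-run
#' context), motif-count-dependent log2 fold-change shifts, 3' end reads
#' with >= 2 non-genomic A's at planted polyadenylation sites plus decoy
#' classes, an 81-tissue atlas with a planted neural-enriched gene set, and
#' replicate KO/WT matrices with planted 16-fold hits.
#'
#' @param seed base RNG seed; generators derive per-stage seeds from it.
#' @param n_genes number of genes for the atlas and KO matrix generators.
#' @param utr_length_range min/max simulated 3' UTR length (nt).
#' @param gc_bg background GC fraction of UTR filler sequence.
#' @param motif_plan named list of per-group plans: `n` UTRs, `target`
#'   AUUUA pentamer count, `clustered` flag (plant one UAUUUAU inside a
#'   >= 12 nt AU run).
#' @param fc_effect per-bin log2 fold-change shift (monotone in bin order).
#' @param fc_noise_sd standard deviation of per-gene log2 fold-change noise.
#' @param reads_per_gene_range min/max planted PASS reads per gene.
#' @param frac_pass fraction of simulated reads that are PASS (the rest are
#'   split equally across low-MAPQ, non-PASS-clip and outside-UTR decoys).
#' @param n_tissues number of atlas tissues (81, the published atlas size).
#' @param neural_tissues names of the neural tissue class.
#' @param n_planted size of the planted neural-enriched gene set.
#' @param neural_shift_sd shift (in noise SDs) added to planted genes in
#'   every neural tissue.
#' @param ko_plan list: `n_up`/`n_down` planted rows, linear `fold`,
#'   `n_reps` per group.
#' @param ko_noise_sd within-group SD of the KO/WT matrix (log2 units).
#' @param ... overrides merged over the defaults.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 2000L,
                       utr_length_range = c(150L, 400L),
                       gc_bg = 0.5,
                       motif_plan = list(
                         "0"    = list(n = 100L, target = 0L, clustered = FALSE),
                         "1-2"  = list(n = 100L, target = 2L, clustered = FALSE),
                         "3-5"  = list(n = 100L, target = 4L, clustered = FALSE),
                         ">=6"  = list(n = 100L, target = 7L, clustered = TRUE)),
                       fc_effect = 0.5,
                       fc_noise_sd = 1.0,
                       reads_per_gene_range = c(50L, 200L),
                       frac_pass = 0.8,
                       n_tissues = 81L,
                       neural_tissues = c("cerebral_cortex", "cerebellum",
                                          "hippocampus", "olfactory_bulb",
                                          "spinal_cord", "amygdala",
                                          "hypothalamus", "dorsal_striatum",
                                          "retina", "dorsal_root_ganglion"),
                       n_planted = 80L,
                       neural_shift_sd = 2,
                       ko_plan = list(n_up = 50L, n_down = 50L,
                                      fold = 16, n_reps = 4L),
                       ko_noise_sd = 0.25,
                       ...) {
  cfg <- list(seed = seed, n_genes = n_genes,
              utr_length_range = utr_length_range, gc_bg = gc_bg,
              motif_plan = motif_plan, fc_effect = fc_effect,
              fc_noise_sd = fc_noise_sd,
              reads_per_gene_range = reads_per_gene_range,
              frac_pass = frac_pass, n_tissues = n_tissues,
              neural_tissues = neural_tissues, n_planted = n_planted,
              neural_shift_sd = neural_shift_sd, ko_plan = ko_plan,
              ko_noise_sd = ko_noise_sd)
  dots <- list(...)
  cfg[names(dots)] <- dots
  stopifnot(cfg$frac_pass > 0, cfg$frac_pass <= 1,
            cfg$n_tissues >= 2L, length(cfg$neural_tissues) >= 1L)
  class(cfg) <- "sim_config"
  cfg
}

## Random filler sequence free of AUUUA (and hence of UAUUUAU).
bg_segment <- function(len, gc) {
  if (len <= 0L) return("")
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, U = (1 - gc) / 2)
  repeat {
    s <- paste(sample(names(probs), len, replace = TRUE, prob = probs),
               collapse = "")
    if (!grepl("AUUUA", s, fixed = TRUE)) return(s)
  }
}

## Motif blocks are C-flanked so that no AUUUA can span a block boundary
## and AU runs cannot extend into the filler.
block_clustered <- "CUAUUUAUUUUUUC"   # 1 pentamer, 1 heptamer in a 12 nt run
block_isolated  <- "CUAUUUAUC"        # 1 pentamer, 1 heptamer in a 7 nt run
block_pentamer  <- "CAUUUAC"          # 1 pentamer, no heptamer

#' Generate 3' UTR sequences with exact planted motif counts
#'
#' Each UTR of a motif-plan group carries exactly `target` AUUUA pentamers:
#' C-flanked motif blocks (one clustered or isolated UAUUUAU block when
#' `target > 0`, pentamer-only blocks for the rest) interleaved with
#' AUUUA-free background filler. Generated sequences are verified against
#' [annotate_ares()] so annotation tests have integer ground truth.
#'
#' @param cfg a [sim_config()].
#' @return data.frame with `utr_id`, `gene_id`, `sequence`, `group`.
#' @export
gen_utrs <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed + 101L, {
    rows <- list()
    idx <- 0L
    for (lab in names(cfg$motif_plan)) {
      plan <- cfg$motif_plan[[lab]]
      for (i in seq_len(plan$n)) {
        idx <- idx + 1L
        gid <- sprintf("g%05d", idx)
        blocks <- character(0)
        if (plan$target > 0L) {
          blocks <- c(if (isTRUE(plan$clustered)) block_clustered
                      else block_isolated,
                      rep(block_pentamer, plan$target - 1L))
        }
        block_len <- sum(nchar(blocks))
        len <- sample(cfg$utr_length_range[1]:cfg$utr_length_range[2], 1L)
        if (block_len + length(blocks) + 1L > len)
          stop("gen_utrs: motif plan for group '", lab,
               "' infeasible within utr_length_range")
        seq <- NULL
        for (try in seq_len(100L)) {
          filler_total <- len - block_len
          n_gaps <- length(blocks) + 1L
          cuts <- sort(sample.int(filler_total + 1L, n_gaps - 1L,
                                  replace = TRUE) - 1L)
          gap_len <- diff(c(0L, cuts, filler_total))
          pieces <- character(2L * length(blocks) + 1L)
          pieces[seq(1L, length(pieces), by = 2L)] <-
            vapply(gap_len, bg_segment, character(1), gc = cfg$gc_bg)
          if (length(blocks) > 0L)
            pieces[seq(2L, length(pieces) - 1L, by = 2L)] <- blocks
          cand <- paste(pieces, collapse = "")
          ann <- annotate_ares(data.frame(utr_id = gid, gene_id = gid,
                                          sequence = cand), min_run = 12L)
          ok <- ann$n_pentamer == plan$target &&
            (plan$target == 0L ||
               (isTRUE(plan$clustered) == (ann$n_clustered >= 1L)))
          if (ok) { seq <- cand; break }
        }
        if (is.null(seq))
          stop("gen_utrs: failed to plant exact motif counts for '",
               gid, "'")
        rows[[idx]] <- data.frame(utr_id = paste0("u", substring(gid, 2)),
                                  gene_id = gid, sequence = seq,
                                  group = lab, stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  })
}

#' Per-gene log2 fold changes whose location shifts with motif count
#'
#' `log2fc = fc_effect * bin_index + Normal(0, fc_noise_sd)`, with bin index
#' 0, 1, 2, ... over the pentamer-count bins, so the group effect is
#' non-decreasing in bin order whenever `fc_effect > 0`.
#'
#' @param cfg a [sim_config()].
#' @param annotations data.frame from [annotate_ares()].
#' @param boundaries pentamer-count bin boundaries.
#' @return named numeric vector of log2 fold changes, one per gene.
#' @export
gen_fold_changes <- function(cfg, annotations, boundaries = c(1L, 3L, 6L)) {
  stopifnot(inherits(cfg, "sim_config"))
  groups <- group_by_pentamer_count(annotations, boundaries)
  with_seed(cfg$seed + 202L, {
    fc <- numeric(0)
    for (i in seq_along(groups)) {
      g <- groups[[i]]
      if (length(g) == 0L) next
      fc <- c(fc, stats::setNames(
        cfg$fc_effect * (i - 1L) + stats::rnorm(length(g),
                                                sd = cfg$fc_noise_sd), g))
    }
    fc
  })
}

#' BED6 intervals for simulated UTRs
#'
#' Lays the UTRs along one chromosome with 2 kb spacing, alternating
#' strands; `name` carries the gene id.
#'
#' @param utrs data.frame from [gen_utrs()].
#' @param chrom chromosome name.
#' @return BED6 data.frame.
#' @export
make_utr_bed <- function(utrs, chrom = "chr1") {
  n <- nrow(utrs)
  start <- 2000L * seq_len(n)
  data.frame(chrom = chrom,
             start = start,
             end = start + nchar(utrs$sequence),
             name = utrs$gene_id,
             score = 0,
             strand = rep(c("+", "-"), length.out = n),
             stringsAsFactors = FALSE)
}

random_dna <- function(n, len) {
  if (n == 0L) return(character(0))
  m <- matrix(sample(c("A", "C", "G", "T"), n * len, replace = TRUE),
              nrow = n)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

sam_line <- function(qname, flag, chrom, pos1, mapq, cigar, seq) {
  paste(qname, flag, chrom, pos1, mapq, cigar, "*", 0, 0, seq,
        strrep("I", nchar(seq)), sep = "\t")
}

#' Generate 3' end sequencing alignments with planted PASS truth
#'
#' For every gene of the truth table, plants `pass_count` reads whose 3'
#' ends fall inside the gene's UTR and whose soft-clips begin with >= 2
#' non-genomic A's (in mRNA sense; reverse-strand alignments store the
#' reverse complement with a leading soft-clip). Decoy reads are added in
#' three labelled classes: `:lowmapq` (MAPQ < 10), `:nonpass` (leading A run
#' of length < 2) and `:outside` (PASS-like clip but 3' end outside every
#' UTR), sized so PASS reads make up `frac_pass` of the total.
#'
#' @param cfg a [sim_config()].
#' @param utr_bed BED6 data.frame of UTRs ([make_utr_bed()]).
#' @param path output SAM file.
#' @param truth optional named integer vector gene -> planted PASS count;
#'   drawn from `reads_per_gene_range` when NULL.
#' @return invisibly, a list with `path`, `truth` and the per-class decoy
#'   counts.
#' @export
gen_sam_3reads <- function(cfg, utr_bed, path, truth = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  M <- 20L  # genome-matched bases per read
  with_seed(cfg$seed + 303L, {
    if (is.null(truth)) {
      truth <- stats::setNames(
        sample(cfg$reads_per_gene_range[1]:cfg$reads_per_gene_range[2],
               nrow(utr_bed), replace = TRUE),
        utr_bed$name)
    }
    stopifnot(all(names(truth) %in% utr_bed$name))
    chrom_len <- max(utr_bed$end) + 5000L
    header <- c("@HD\tVN:1.6\tSO:unknown",
                paste0("@SQ\tSN:", utr_bed$chrom[1], "\tLN:", chrom_len))

    make_reads <- function(gene, n, mapq_pool, min_lead_a, tag) {
      if (n <= 0L) return(character(0))
      u <- utr_bed[utr_bed$name == gene, , drop = FALSE][1, ]
      end3 <- sample(u$start:(u$end - 1L), n, replace = TRUE)
      if (min_lead_a >= 2L) {
        # leading run of >= 2 non-genomic A's, sometimes with extra tail
        lead <- strrep("A", sample(2:8, n, replace = TRUE))
        clips <- paste0(lead, ifelse(stats::runif(n) < 0.2,
                                     random_dna(n, 2L), ""))
      } else {
        clips <- sample(c("", "A", "GAA", "CAA"), n, replace = TRUE)
      }
      mapq <- sample(mapq_pool, n, replace = TRUE)
      bodies <- random_dna(n, M)
      qn <- paste0("r_", gene, "_", tag, seq_len(n))
      ncl <- nchar(clips)
      clip_op <- ifelse(ncl > 0L, paste0(ncl, "S"), "")
      if (u$strand == "+") {
        sam_line(qn, 0L, u$chrom, end3 - M + 2L, mapq,
                 paste0(M, "M", clip_op), paste0(bodies, clips))
      } else {
        rc <- revcomp_chr(clips)
        sam_line(qn, 16L, u$chrom, end3 + 1L, mapq,
                 paste0(clip_op, M, "M"), paste0(rc, bodies))
      }
    }

    lines <- unlist(lapply(names(truth), function(gene)
      make_reads(gene, truth[[gene]], 30:42, 2L, "pass")))
    n_pass <- sum(truth)
    n_decoy <- max(0L, round(n_pass * (1 - cfg$frac_pass) / cfg$frac_pass))
    n_low <- n_decoy %/% 3L
    n_non <- n_decoy %/% 3L
    n_out <- n_decoy - n_low - n_non

    genes <- utr_bed$name
    if (n_low > 0L) {
      tab <- table(sample(genes, n_low, replace = TRUE))
      lines <- c(lines, unlist(lapply(names(tab), function(g)
        make_reads(g, tab[[g]], 0:9, 2L, "lowmapq:"))))
    }
    if (n_non > 0L) {
      tab <- table(sample(genes, n_non, replace = TRUE))
      lines <- c(lines, unlist(lapply(names(tab), function(g)
        make_reads(g, tab[[g]], 30:42, 0L, "nonpass:"))))
    }
    if (n_out > 0L) {
      # PASS-like reads whose 3' ends sit in the inter-UTR gaps
      end3 <- sample(utr_bed$start - 1000L, n_out, replace = TRUE)
      clips <- strrep("A", sample(2:8, n_out, replace = TRUE))
      lines <- c(lines, sam_line(
        paste0("r_none_outside:", seq_len(n_out)), 0L, utr_bed$chrom[1],
        end3 - M + 2L, sample(30:42, n_out, replace = TRUE),
        paste0(M, "M", nchar(clips), "S"),
        paste0(random_dna(n_out, M), clips)))
    }
    writeLines(c(header, lines), path)
    invisible(list(path = path, truth = truth,
                   n_decoys = c(lowmapq = n_low, nonpass = n_non,
                                outside = n_out)))
  })
}

#' Generate a multi-tissue expression atlas with a planted neural set
#'
#' Background expression is i.i.d. Normal(0, 1) per gene and tissue, which
#' makes the null tissue-rank distribution provably uniform. The first
#' `n_planted` genes get `+neural_shift_sd` added in every neural tissue.
#'
#' @param cfg a [sim_config()].
#' @return list with `values` (genes x tissues matrix), `neural_labels`
#'   (named vector tissue -> class) and `planted_genes`.
#' @export
gen_atlas <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"),
            length(cfg$neural_tissues) < cfg$n_tissues)
  n_other <- cfg$n_tissues - length(cfg$neural_tissues)
  tissues <- c(cfg$neural_tissues,
               sprintf("tissue_%02d", seq_len(n_other)))
  genes <- sprintf("g%05d", seq_len(cfg$n_genes))
  with_seed(cfg$seed + 404L, {
    vals <- matrix(stats::rnorm(cfg$n_genes * cfg$n_tissues),
                   nrow = cfg$n_genes,
                   dimnames = list(genes, tissues))
    planted <- genes[seq_len(min(cfg$n_planted, cfg$n_genes))]
    vals[planted, cfg$neural_tissues] <-
      vals[planted, cfg$neural_tissues] + cfg$neural_shift_sd
    labels <- stats::setNames(
      ifelse(tissues %in% cfg$neural_tissues, "neural", "non-neural"),
      tissues)
    list(values = vals, neural_labels = labels, planted_genes = planted)
  })
}

#' Generate a replicate KO/WT expression matrix with planted hits
#'
#' Log2-scale matrix with per-gene baselines Normal(7, 1.5) and within-group
#' noise Normal(0, `ko_noise_sd`); the planted up rows are shifted by
#' `+log2(fold)` in every KO column, the down rows by `-log2(fold)`.
#'
#' @param cfg a [sim_config()].
#' @return list with `values` (probes x samples), `groups` (named vector
#'   column -> "KO"/"WT"), `truth_up`, `truth_down` (probe ids) and
#'   `probe2gene`.
#' @export
gen_ko_matrix <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  plan <- cfg$ko_plan
  stopifnot(plan$n_reps >= 2L,
            plan$n_up + plan$n_down <= cfg$n_genes)
  probes <- sprintf("p%05d", seq_len(cfg$n_genes))
  cols <- c(sprintf("WT_%d", seq_len(plan$n_reps)),
            sprintf("KO_%d", seq_len(plan$n_reps)))
  with_seed(cfg$seed + 505L, {
    baseline <- stats::rnorm(cfg$n_genes, mean = 7, sd = 1.5)
    vals <- baseline + matrix(stats::rnorm(cfg$n_genes * length(cols),
                                           sd = cfg$ko_noise_sd),
                              nrow = cfg$n_genes)
    dimnames(vals) <- list(probes, cols)
    ko_cols <- grepl("^KO_", cols)
    up <- if (plan$n_up > 0L) probes[seq_len(plan$n_up)] else character(0)
    down <- if (plan$n_down > 0L)
      probes[plan$n_up + seq_len(plan$n_down)] else character(0)
    if (plan$fold != 1) {
      vals[up, ko_cols] <- vals[up, ko_cols] + log2(plan$fold)
      vals[down, ko_cols] <- vals[down, ko_cols] - log2(plan$fold)
    }
    groups <- stats::setNames(ifelse(ko_cols, "KO", "WT"), cols)
    probe2gene <- stats::setNames(sub("^p", "g", probes), probes)
    list(values = vals, groups = groups,
         truth_up = up, truth_down = down, probe2gene = probe2gene)
  })
}
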