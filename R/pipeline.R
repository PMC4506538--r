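## End-to-end orchestration: simulate (optional) -> ARE annotation ->
## PASS quantification -> between-condition log2 ratios -> motif-group KS
## comparison -> KO/WT hit selection -> tissue-rank scan. Every stage
## boundary is a TSV; each run writes a JSON manifest with the config hash,
## seed, input checksums and package version.

#' @importFrom tools md5sum
#' @importFrom utils packageVersion
NULL

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

default_pipeline_config <- function() {
  list(seed = 7L,
       simulate = TRUE,
       min_run = 12L,
       min_mapq = 10L,
       min_a = 2L,
       pseudo = 1.0,
       fold_threshold = 10,
       alpha = 0.05,
       boundaries = c(1L, 3L, 6L),
       sim = list())
}

#' Run the full analysis pipeline
#'
#' With `simulate = TRUE` (the default demo mode) all inputs are generated
#' by the seeded synthetic-data module; otherwise the config must name
#' `utr_fasta`, `utr_bed`, `sam_a`, `sam_b`, `ko_matrix`, `atlas` and
#' `labels` files. Stages run in order and write their tables under
#' `outdir`; a `manifest.json` records provenance. Any stage error aborts
#' the run with the stage name.
#'
#' @param config a list of options, or the path of a YAML file holding one;
#'   unset keys fall back to the demo defaults.
#' @param outdir output directory (created if needed).
#' @return invisibly, a named list of output file paths.
#' @export
run_pipeline <- function(config = list(), outdir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- default_pipeline_config()
  cfg[names(config)] <- config
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  outputs <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  inputs <- character(0)
  if (isTRUE(cfg$simulate)) {
    sim <- do.call(sim_config, c(list(seed = cfg$seed), cfg$sim))
    utrs <- stage("simulate", gen_utrs(sim))
    utr_bed <- make_utr_bed(utrs)
    fasta <- file.path(outdir, "utrs.fa")
    write_utr_fasta(utrs, fasta)
    bed <- file.path(outdir, "utrs.bed")
    write_bed6(utr_bed, bed)
    sam_a <- file.path(outdir, "sample_diff.sam")
    sam_b <- file.path(outdir, "sample_undiff.sam")
    # plant motif-count-dependent fold changes into the read counts so the
    # differentiated sample upregulates ARE-rich genes over the baseline
    stage("simulate", {
      ann0 <- annotate_ares(utrs, min_run = cfg$min_run)
      fc_true <- gen_fold_changes(sim, ann0, cfg$boundaries)
      truth_b <- with_seed(sim$seed + 42L, stats::setNames(
        sample(sim$reads_per_gene_range[1]:sim$reads_per_gene_range[2],
               nrow(utr_bed), replace = TRUE), utr_bed$name))
      truth_a <- stats::setNames(
        pmax(1L, as.integer(round(truth_b * 2^fc_true[names(truth_b)]))),
        names(truth_b))
      gen_sam_3reads(sim, utr_bed, sam_a, truth = truth_a)
      sim_b <- do.call(sim_config, c(list(seed = cfg$seed + 1L), cfg$sim))
      gen_sam_3reads(sim_b, utr_bed, sam_b, truth = truth_b)
    })
    ko <- stage("simulate", gen_ko_matrix(sim))
    atlas <- stage("simulate", gen_atlas(sim))
    inputs <- c(fasta, bed, sam_a, sam_b)
  } else {
    needed <- c("utr_fasta", "utr_bed", "sam_a", "sam_b", "ko_matrix",
                "atlas", "labels")
    missing_key <- setdiff(needed, names(cfg))
    if (length(missing_key) > 0L)
      stop("run_pipeline: config key '", missing_key[1], "' is missing")
    utrs <- stage("read", read_utr_fasta(cfg$utr_fasta))
    utr_bed <- stage("read", read_bed6(cfg$utr_bed))
    fasta <- cfg$utr_fasta; bed <- cfg$utr_bed
    sam_a <- cfg$sam_a; sam_b <- cfg$sam_b
    ko_m <- stage("read", read_matrix_tsv(cfg$ko_matrix))
    ko <- list(values = ko_m$values,
               groups = stats::setNames(
                 ifelse(grepl("^KO", colnames(ko_m$values)), "KO", "WT"),
                 colnames(ko_m$values)))
    at_m <- stage("read", read_matrix_tsv(cfg$atlas))
    lab <- utils::read.table(cfg$labels, sep = "\t", header = FALSE,
                             col.names = c("tissue", "class"),
                             stringsAsFactors = FALSE)
    atlas <- list(values = at_m$values,
                  neural_labels = stats::setNames(lab$class, lab$tissue))
    inputs <- c(fasta, bed, sam_a, sam_b, cfg$ko_matrix, cfg$atlas)
  }

  # ARE annotation
  ann <- stage("annotate-ares", annotate_ares(utrs, min_run = cfg$min_run))
  outputs$annotation <- write_tsv(ann, file.path(outdir, "are_annotation.tsv"))

  # PASS quantification of both conditions
  reads_a <- stage("quantify-3reads", read_sam_3p(sam_a))
  reads_b <- stage("quantify-3reads", read_sam_3p(sam_b))
  qa <- stage("quantify-3reads",
              quantify_3reads(reads_a, utr_bed, cfg$min_mapq, cfg$min_a))
  qb <- stage("quantify-3reads",
              quantify_3reads(reads_b, utr_bed, cfg$min_mapq, cfg$min_a))
  message("quantify-3reads A: ",
          paste(names(qa$accounting), qa$accounting, collapse = ", "))
  message("quantify-3reads B: ",
          paste(names(qb$accounting), qb$accounting, collapse = ", "))
  outputs$quant_a <- write_tsv(qa$quant, file.path(outdir, "quant_a.tsv"))
  outputs$quant_b <- write_tsv(qb$quant, file.path(outdir, "quant_b.tsv"))

  # log2 ratios and motif-group comparison
  fc <- stage("compare-3reads",
              log2_rpm_ratio(qa$quant, qb$quant, pseudo = cfg$pseudo))
  outputs$log2fc <- write_tsv(
    data.frame(gene_id = names(fc), log2fc = unname(fc)),
    file.path(outdir, "log2fc.tsv"))
  groups <- stage("compare-motif-groups",
                  group_by_pentamer_count(ann, cfg$boundaries))
  cmp <- stage("compare-motif-groups", compare_motif_groups(fc, groups))
  outputs$group_ks <- write_tsv(cmp, file.path(outdir, "motif_group_ks.tsv"))

  # KO/WT differential expression
  hits <- stage("diffexpr",
                select_hits(ko$values,
                            ko_cols = names(ko$groups)[ko$groups == "KO"],
                            wt_cols = names(ko$groups)[ko$groups == "WT"],
                            fold_threshold = cfg$fold_threshold,
                            alpha = cfg$alpha))
  outputs$diffexpr <- write_tsv(hits, file.path(outdir, "diffexpr_hits.tsv"))

  # tissue-rank scan of the upregulated genes (planted set in demo mode)
  up_ids <- hits$probe_id[hits$direction == "up"]
  scan_set <- if (isTRUE(cfg$simulate))
    intersect(sub("^p", "g", up_ids), rownames(atlas$values)) else up_ids
  scan <- stage("tissue-rank-scan", {
    if (length(scan_set) >= 2L) per_tissue_scan(atlas$values, scan_set)
    else per_tissue_scan(atlas$values,
                         rownames(atlas$values)[seq_len(50L)])
  })
  outputs$tissue_scan <- write_tsv(scan, file.path(outdir, "tissue_scan.tsv"))

  manifest <- list(
    tool = "areutr",
    version = as.character(utils::packageVersion("areutr")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = cfg$seed,
    config_hash = tools::md5sum(
      local({
        f <- tempfile(); saveRDS(cfg, f); f
      }))[[1]],
    inputs = as.list(tools::md5sum(inputs))
  )
  manifest_path <- file.path(outdir, "manifest.json")
  writeLines(minimal_json(manifest), manifest_path)
  outputs$manifest <- manifest_path
  invisible(outputs)
}

## Small JSON writer for the manifest (strings/numbers/named lists only),
## so the package itself does not depend on a JSON library.
minimal_json <- function(x, indent = 0) {
  pad <- strrep("  ", indent)
  if (is.list(x)) {
    items <- vapply(names(x), function(nm)
      paste0(pad, "  \"", nm, "\": ", minimal_json(x[[nm]], indent + 1)),
      character(1))
    paste0("{\n", paste(items, collapse = ",\n"), "\n", pad, "}")
  } else if (is.character(x)) {
    paste0("\"", gsub("\"", "\\\\\"", x), "\"")
  } else {
    as.character(x)
  }
}
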