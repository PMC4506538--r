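## Differential expression between KO and WT sample groups on a log2-scale
## matrix: row-wise Welch t-tests, Benjamini-Hochberg control over the
## variance-filtered family, a linear fold-change threshold, and a
## consistency requirement that every KO column deviates from the WT group
## mean in the same direction.

#' Row-wise Welch t-tests
#'
#' Two-sided Welch (unequal-variance) t-test of group A against group B for
#' every matrix row, with Welch-Satterthwaite degrees of freedom. Rows where
#' both groups are constant return p = 1 when the means are equal and p = 0
#' (infinite t, flagged by `degenerate`) when they differ.
#'
#' @param mat numeric matrix, log2 scale, columns = samples.
#' @param cols_a,cols_b column names or indices of the two groups (>= 2
#'   each).
#' @return data.frame with `t`, `df`, `p_raw`, `mean_a`, `mean_b`,
#'   `degenerate`; rownames follow `mat`.
#' @export
welch_t_rows <- function(mat, cols_a, cols_b) {
  a <- mat[, cols_a, drop = FALSE]
  b <- mat[, cols_b, drop = FALSE]
  na <- ncol(a); nb <- ncol(b)
  if (na < 2L || nb < 2L)
    stop("welch_t_rows: each group needs >= 2 columns")
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- rowSums((a - ma)^2) / (na - 1L)
  vb <- rowSums((b - mb)^2) / (nb - 1L)
  se2 <- va / na + vb / nb
  diff <- ma - mb
  t_stat <- ifelse(se2 > 0, diff / sqrt(se2),
                   ifelse(diff == 0, 0, sign(diff) * Inf))
  df <- ifelse(se2 > 0,
               se2^2 / ((va / na)^2 / (na - 1L) + (vb / nb)^2 / (nb - 1L)),
               NA_real_)
  p <- ifelse(se2 > 0, 2 * stats::pt(-abs(t_stat), df),
              ifelse(diff == 0, 1, 0))
  data.frame(t = t_stat, df = df, p_raw = p, mean_a = ma, mean_b = mb,
             degenerate = se2 == 0 & diff != 0,
             row.names = rownames(mat))
}

#' Select strong, consistent differential-expression hits
#'
#' A probe set is a hit when (i) the absolute group-mean difference exceeds
#' `log2(fold_threshold)`, (ii) its Benjamini-Hochberg adjusted Welch p
#' (family = all rows surviving a zero-variance filter) is below `alpha`,
#' and (iii) the change is consistent: every KO column deviates from the WT
#' group mean in the direction of the overall fold change.
#'
#' @param mat numeric matrix, log2 scale; rows = probe sets.
#' @param ko_cols,wt_cols column names/indices of the KO and WT groups.
#' @param fold_threshold linear fold-change threshold (default 10).
#' @param alpha BH-adjusted significance level (default 0.05).
#' @return data.frame of hits: `probe_id`, `log2fc` (KO minus WT), `t`,
#'   `p_raw`, `p_adj`, `direction`, `consistent`. The full tested table is
#'   attached as attribute `"tested"`.
#' @export
select_hits <- function(mat, ko_cols, wt_cols, fold_threshold = 10,
                        alpha = 0.05) {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)))
  # BH family: rows with non-zero overall variance
  v <- apply(mat[, c(ko_cols, wt_cols), drop = FALSE], 1L, stats::var)
  tested <- mat[v > 0, , drop = FALSE]
  if (nrow(tested) == 0L)
    stop("select_hits: no rows with non-zero variance")
  tt <- welch_t_rows(tested, ko_cols, wt_cols)
  log2fc <- tt$mean_a - tt$mean_b
  p_adj <- bh_adjust(tt$p_raw)

  ko <- tested[, ko_cols, drop = FALSE]
  wt_mean <- rowMeans(tested[, wt_cols, drop = FALSE])
  dev <- ko - wt_mean
  consistent <- vapply(seq_len(nrow(tested)), function(i) {
    all(sign(dev[i, ]) == sign(log2fc[i])) && log2fc[i] != 0
  }, logical(1))

  full <- data.frame(probe_id = rownames(tested),
                     log2fc = log2fc, t = tt$t, p_raw = tt$p_raw,
                     p_adj = p_adj,
                     direction = ifelse(log2fc > 0, "up", "down"),
                     consistent = consistent,
                     stringsAsFactors = FALSE)
  rownames(full) <- NULL
  is_hit <- abs(full$log2fc) > log2(fold_threshold) &
    full$p_adj < alpha & full$consistent
  hits <- full[is_hit, , drop = FALSE]
  rownames(hits) <- NULL
  attr(hits, "tested") <- full
  hits
}

#' Collapse probe-set hits to gene sets
#'
#' A gene is upregulated when at least one of its probe sets is an up hit
#' (and none is a down hit); genes with probes in both directions are set
#' aside as discordant and reported separately.
#'
#' @param hits data.frame from [select_hits()].
#' @param probe2gene named character vector: probe id -> gene id.
#' @return list with `up_genes`, `down_genes` (character vectors),
#'   `up_probes`, `down_probes` (counts), `discordant_genes`.
#' @export
collapse_to_genes <- function(hits, probe2gene) {
  if (nrow(hits) == 0L)
    return(list(up_genes = character(), down_genes = character(),
                up_probes = 0L, down_probes = 0L,
                discordant_genes = character()))
  unmapped <- setdiff(hits$probe_id, names(probe2gene))
  if (length(unmapped) > 0L)
    stop("collapse_to_genes: probe '", unmapped[1], "' has no gene mapping")
  gene <- unname(probe2gene[hits$probe_id])
  up <- unique(gene[hits$direction == "up"])
  down <- unique(gene[hits$direction == "down"])
  discordant <- intersect(up, down)
  if (length(discordant) > 0L)
    message("collapse_to_genes: ", length(discordant),
            " discordant gene(s) excluded")
  list(up_genes = setdiff(up, discordant),
       down_genes = setdiff(down, discordant),
       up_probes = sum(hits$direction == "up"),
       down_probes = sum(hits$direction == "down"),
       discordant_genes = discordant)
}

#' Median expression position of a gene set
#'
#' Summarizes where a gene set sits relative to the whole transcriptome in
#' each sample group: per gene, the mean over group columns; per set, the
#' median over genes; transcriptome medians computed the same way over all
#' rows. Used to show sets expressed below the transcriptome median in WT
#' that reach the median in KO.
#'
#' @param mat numeric matrix (log2 scale).
#' @param gene_set character vector of row ids (non-empty, subset of rows).
#' @param cols_a,cols_b the two sample groups.
#' @return named numeric vector: `median_a`, `median_b`,
#'   `transcriptome_median_a`, `transcriptome_median_b`.
#' @export
median_position_summary <- function(mat, gene_set, cols_a, cols_b) {
  if (length(gene_set) == 0L)
    stop("median_position_summary: empty gene set")
  missing_rows <- setdiff(gene_set, rownames(mat))
  if (length(missing_rows) > 0L)
    stop("median_position_summary: gene '", missing_rows[1],
         "' not in matrix")
  ga <- rowMeans(mat[, cols_a, drop = FALSE])
  gb <- rowMeans(mat[, cols_b, drop = FALSE])
  c(median_a = stats::median(ga[gene_set]),
    median_b = stats::median(gb[gene_set]),
    transcriptome_median_a = stats::median(ga),
    transcriptome_median_b = stats::median(gb))
}
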