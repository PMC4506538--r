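## Tissue-specific expression ranks. For a gene and a focal tissue, the rank
## is the position of the focal tissue in the list of atlas tissues arranged
## in increasing expression order: 1 = expressed lower in the focal tissue
## than anywhere else, T = higher than anywhere else. Ties are broken by
## atlas column order (stable sort), keeping ranks integral in 1..T.
## Right skew of a gene set's rank distribution relative to the whole-atlas
## background is measured with a one-sided KS statistic.

#' Tissue rank of one expression row
#'
#' @param expr_row numeric vector of expression over the atlas tissues.
#' @param focal_index column index or name of the focal tissue.
#' @return integer rank in 1..T.
#' @export
rank_tissue <- function(expr_row, focal_index) {
  if (is.character(focal_index)) {
    if (is.null(names(expr_row)) || !(focal_index %in% names(expr_row)))
      stop("rank_tissue: focal tissue '", focal_index, "' absent")
    focal_index <- match(focal_index, names(expr_row))
  }
  if (focal_index < 1L || focal_index > length(expr_row))
    stop("rank_tissue: focal index out of range")
  if (any(!is.finite(expr_row))) stop("rank_tissue: non-finite expression")
  unname(rank(expr_row, ties.method = "first")[focal_index])
}

#' Tissue-rank matrix of an atlas
#'
#' Ranks every gene's expression row across tissues (ties by column order),
#' yielding for each gene the rank of every tissue at once.
#'
#' @param atlas_values numeric matrix, genes x tissues.
#' @return integer matrix of the same shape; entry (g, t) is the rank of
#'   tissue t for gene g.
#' @export
tissue_rank_matrix <- function(atlas_values) {
  stopifnot(is.matrix(atlas_values))
  if (any(!is.finite(atlas_values)))
    stop("tissue_rank_matrix: non-finite expression values")
  t(apply(atlas_values, 1L, rank, ties.method = "first"))
}

#' Rank histogram of a gene set for a focal tissue
#'
#' @param atlas_values numeric matrix, genes x tissues, with rownames.
#' @param focal focal tissue (column name or index).
#' @param gene_set character vector of gene ids, or `"all"`.
#' @return list with `counts` (integer vector over ranks 1..T), `n_genes`,
#'   `n_dropped` (genes absent from the atlas).
#' @export
rank_distribution <- function(atlas_values, focal, gene_set = "all") {
  T_ <- ncol(atlas_values)
  if (is.character(focal)) {
    if (!(focal %in% colnames(atlas_values)))
      stop("rank_distribution: focal tissue '", focal, "' absent")
    focal <- match(focal, colnames(atlas_values))
  }
  if (identical(gene_set, "all")) {
    rows <- seq_len(nrow(atlas_values))
    n_dropped <- 0L
  } else {
    present <- intersect(gene_set, rownames(atlas_values))
    n_dropped <- length(gene_set) - length(present)
    if (length(present) == 0L)
      stop("rank_distribution: no gene of the set is in the atlas")
    rows <- match(present, rownames(atlas_values))
  }
  ranks <- apply(atlas_values[rows, , drop = FALSE], 1L, function(r)
    rank(r, ties.method = "first")[focal])
  list(counts = tabulate(ranks, nbins = T_),
       n_genes = length(rows), n_dropped = n_dropped)
}

#' One-sided KS right-skew test on rank multisets
#'
#' `D+ = sup(ECDF_background - ECDF_set)`: positive when the set's ranks sit
#' to the right (higher ranks, i.e. focal-tissue-enriched expression) of the
#' background. One-sided p from the asymptotic exponential bound.
#'
#' @param set_ranks,background_ranks integer multisets of ranks (>= 2 each).
#' @return list with `D_plus` and `p`.
#' @export
ks_right_skew <- function(set_ranks, background_ranks) {
  res <- ks_one_sided(set_ranks, background_ranks)
  list(D_plus = res$D_plus, p = res$p)
}

#' Per-tissue rank-skew scan
#'
#' For every tissue of the atlas: rank all genes with that tissue as focal,
#' then test the gene set's ranks against the whole-atlas background with
#' the one-sided KS statistic. A set of genes specifically expressed in a
#' tissue class (e.g. neural) yields its smallest p-values there.
#'
#' @param atlas_values numeric matrix, genes x tissues, with dimnames.
#' @param gene_set character vector of gene ids (genes absent from the atlas
#'   are dropped with a message).
#' @return data.frame with `tissue`, `n_set`, `D_plus`, `p`, `neg_log10_p`.
#' @export
per_tissue_scan <- function(atlas_values, gene_set) {
  present <- intersect(gene_set, rownames(atlas_values))
  if (length(present) < 2L)
    stop("per_tissue_scan: need >= 2 set genes present in the atlas")
  if (length(present) < length(gene_set))
    message("per_tissue_scan: dropped ", length(gene_set) - length(present),
            " gene(s) absent from the atlas")
  rk <- tissue_rank_matrix(atlas_values)
  set_rows <- match(present, rownames(atlas_values))
  out <- lapply(seq_len(ncol(atlas_values)), function(j) {
    res <- ks_one_sided(rk[set_rows, j], rk[, j])
    data.frame(tissue = colnames(atlas_values)[j],
               n_set = length(set_rows),
               D_plus = res$D_plus, p = res$p,
               neg_log10_p = -log10(res$p),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Neural vs non-neural comparison of scan p-values
#'
#' One-sided Wilcoxon rank-sum test of whether the per-tissue skew p-values
#' of the neural tissue class are smaller than those of the non-neural
#' class.
#'
#' @param scan data.frame from [per_tissue_scan()].
#' @param labels named character vector tissue -> "neural"/"non-neural";
#'   every scanned tissue must be labelled.
#' @return list with `wilcoxon_p`, `neural_median_p`, `nonneural_median_p`,
#'   `n_neural`, `n_nonneural`.
#' @export
neural_vs_nonneural <- function(scan, labels) {
  missing_lab <- setdiff(scan$tissue, names(labels))
  if (length(missing_lab) > 0L)
    stop("neural_vs_nonneural: unlabelled tissue '", missing_lab[1], "'")
  lab <- labels[scan$tissue]
  neural_p <- scan$p[lab == "neural"]
  other_p <- scan$p[lab == "non-neural"]
  if (length(neural_p) == 0L || length(other_p) == 0L)
    stop("neural_vs_nonneural: both tissue classes must be non-empty")
  w <- wilcoxon_rank_sum(neural_p, other_p, alternative = "less")
  list(wilcoxon_p = w$p,
       neural_median_p = stats::median(neural_p),
       nonneural_median_p = stats::median(other_p),
       n_neural = length(neural_p),
       n_nonneural = length(other_p))
}
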