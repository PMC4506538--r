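## ARE annotation: AUUUA pentamer / UAUUUAU heptamer content of 3' UTRs,
## with heptamers classified by their AU-run context. A heptamer lying
## entirely inside a maximal A/U run of >= min_run nt (default 12) is
## "clustered" (the bona fide ARE configuration); any other heptamer is
## "isolated". Motif occurrences are counted overlapping, because tandem
## arrays such as UAUUUAUUUAU contain overlapping heptamers.

ARE_PENTAMER <- "AUUUA"
ARE_HEPTAMER <- "UAUUUAU"

check_rna <- function(x, what = "sequence") {
  x <- chartr("Tt", "Uu", toupper(x))
  if (any(grepl("[^ACGU]", x)))
    stop(what, " must be over the {A,C,G,U} alphabet")
  x
}

#' Count overlapping motif occurrences
#'
#' All occurrence start positions are counted, including overlapping ones.
#' Input T/t is treated as U.
#'
#' @param sequence character vector of RNA (or DNA) sequences.
#' @param motif a single non-empty RNA string.
#' @return integer vector of counts, one per sequence.
#' @export
count_motif <- function(sequence, motif) {
  if (length(motif) != 1L || !nzchar(motif)) stop("count_motif: empty motif")
  motif <- check_rna(motif, "motif")
  sequence <- check_rna(sequence)
  m <- nchar(motif)
  vapply(sequence, function(s) {
    n <- nchar(s)
    if (n < m) return(0L)
    starts <- seq_len(n - m + 1L)
    sum(substring(s, starts, starts + m - 1L) == motif)
  }, integer(1), USE.NAMES = FALSE)
}

#' Find maximal A/U runs in a sequence
#'
#' Returns the maximal runs of consecutive A or U bases, left to right, as
#' 0-based half-open intervals in sequence coordinates.
#'
#' @param sequence a single RNA string.
#' @return data.frame with columns `start`, `end`, `length`.
#' @export
find_au_runs <- function(sequence) {
  stopifnot(length(sequence) == 1L)
  sequence <- check_rna(sequence)
  empty <- data.frame(start = integer(), end = integer(), length = integer())
  if (!nzchar(sequence)) return(empty)
  m <- gregexpr("[AU]+", sequence)[[1]]
  if (m[1] == -1L) return(empty)
  start <- as.integer(m) - 1L
  len <- attr(m, "match.length")
  data.frame(start = start, end = start + len, length = len)
}

motif_starts <- function(sequence, motif) {
  n <- nchar(sequence); m <- nchar(motif)
  if (n < m) return(integer())
  starts <- seq_len(n - m + 1L)
  starts[substring(sequence, starts, starts + m - 1L) == motif] - 1L
}

#' Annotate ARE content of 3' UTRs
#'
#' For each UTR, counts overlapping AUUUA pentamers and UAUUUAU heptamers and
#' classifies every heptamer as clustered (its 7 nt lie inside a maximal A/U
#' run of length >= `min_run`) or isolated. Because every UAUUUAU contains an
#' AUUUA, `n_heptamer <= n_pentamer` always holds.
#'
#' @param utrs data.frame with columns `utr_id`, `gene_id`, `sequence` (as
#'   returned by [read_utr_fasta()] or [gen_utrs()]).
#' @param min_run minimum A/U run length for the clustered class (nt).
#' @return data.frame with one row per UTR: `utr_id`, `gene_id`,
#'   `n_pentamer`, `n_heptamer`, `n_clustered`, `n_isolated`, `n_runs`,
#'   `max_run`, `utr_length`.
#' @export
annotate_ares <- function(utrs, min_run = 12L) {
  stopifnot(all(c("utr_id", "gene_id", "sequence") %in% names(utrs)),
            min_run >= 1L)
  seqs <- check_rna(utrs$sequence)
  one <- function(s) {
    runs <- find_au_runs(s)
    hept <- motif_starts(s, ARE_HEPTAMER)
    n_hept <- length(hept)
    n_clust <- 0L
    if (n_hept > 0L && nrow(runs) > 0L) {
      big <- runs[runs$length >= min_run, , drop = FALSE]
      if (nrow(big) > 0L) {
        n_clust <- sum(vapply(hept, function(h) {
          any(big$start <= h & h + 7L <= big$end)
        }, logical(1)))
      }
    }
    c(n_pentamer = length(motif_starts(s, ARE_PENTAMER)),
      n_heptamer = n_hept,
      n_clustered = n_clust,
      n_isolated = n_hept - n_clust,
      n_runs = nrow(runs),
      max_run = if (nrow(runs)) max(runs$length) else 0L)
  }
  stats_mat <- t(vapply(seqs, one, numeric(6), USE.NAMES = FALSE))
  colnames(stats_mat) <- c("n_pentamer", "n_heptamer", "n_clustered",
                           "n_isolated", "n_runs", "max_run")
  out <- data.frame(utr_id = utrs$utr_id, gene_id = utrs$gene_id,
                    stats_mat, utr_length = nchar(seqs),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

pentamer_group_labels <- function(boundaries) {
  b <- as.integer(boundaries)
  labs <- "0"
  for (i in seq_along(b)) {
    lo <- b[i]
    hi <- if (i < length(b)) b[i + 1L] - 1L else NA_integer_
    labs <- c(labs, if (is.na(hi)) paste0(">=", lo)
              else if (lo == hi) as.character(lo)
              else paste0(lo, "-", hi))
  }
  labs
}

#' Group genes by AUUUA pentamer count
#'
#' Partitions annotated UTRs into motif-count bins. With the default
#' boundaries `c(1, 3, 6)` the bins are 0, 1-2, 3-5 and >= 6 pentamers; the
#' top bin mirrors the observation that expression shifts are most
#' pronounced for mRNAs with six or more AUUUA motifs.
#'
#' @param annotations data.frame from [annotate_ares()].
#' @param boundaries strictly increasing integer vector starting at 1.
#' @return named list of character vectors of gene ids, one per bin, in bin
#'   order.
#' @export
group_by_pentamer_count <- function(annotations, boundaries = c(1L, 3L, 6L)) {
  b <- as.integer(boundaries)
  if (length(b) < 1L || b[1] != 1L || is.unsorted(b, strictly = TRUE))
    stop("group_by_pentamer_count: boundaries must be strictly increasing and start at 1")
  labs <- pentamer_group_labels(b)
  cuts <- c(0L, b, Inf)
  idx <- findInterval(annotations$n_pentamer, cuts)
  out <- lapply(seq_along(labs), function(i)
    unique(annotations$gene_id[idx == i]))
  names(out) <- labs
  out
}

#' Compare expression changes across motif-count groups
#'
#' Two-sided KS comparison of per-gene log2 fold changes between every pair
#' of motif-count groups. Pairs where either group has fewer than two genes
#' with a fold-change value are skipped with a warning.
#'
#' @param log2fc named numeric vector of per-gene log2 fold changes.
#' @param groups named list of gene-id vectors (from
#'   [group_by_pentamer_count()]).
#' @return data.frame with columns `group_a`, `group_b`, `n_a`, `n_b`, `D`,
#'   `p`.
#' @export
compare_motif_groups <- function(log2fc, groups) {
  stopifnot(!is.null(names(log2fc)), length(groups) >= 2L)
  vals <- lapply(groups, function(g) log2fc[intersect(g, names(log2fc))])
  labs <- names(groups)
  pairs <- utils::combn(seq_along(groups), 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    a <- vals[[i1]]; b <- vals[[i2]]
    if (length(a) < 2L || length(b) < 2L) {
      warning("compare_motif_groups: skipping pair ", labs[i1], " vs ",
              labs[i2], " (group with < 2 values)")
      return(NULL)
    }
    ks <- ks_two_sided(a, b)
    data.frame(group_a = labs[i1], group_b = labs[i2],
               n_a = length(a), n_b = length(b),
               D = ks$D, p = ks$p, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
}

#' Pentamer (k-mer) enrichment by label permutation
#'
#' Scores every k-mer by the difference in mean per-UTR occurrence rate
#' (count / (length - k + 1)) between a foreground and a background UTR set,
#' against a null built by permuting the set labels. Reported are a z-score
#' against the permutation null and a one-sided permutation p-value
#' `(1 + #\{null >= observed\}) / (n_perm + 1)`. K-mers are counted on the
#' given (sense) strand only.
#'
#' @param foreground,background UTR data.frames (columns `utr_id`,
#'   `sequence`).
#' @param k k-mer length (default 5, the pentamer scale of ARE cores).
#' @param n_perm number of label permutations (>= 100).
#' @param seed RNG seed for the permutations.
#' @return data.frame sorted by decreasing z: `kmer`, `fg_rate`, `bg_rate`,
#'   `diff`, `z`, `p_perm`.
#' @export
pentamer_enrichment <- function(foreground, background, k = 5L,
                                n_perm = 999L, seed = 1L) {
  if (nrow(foreground) == 0L || nrow(background) == 0L)
    stop("pentamer_enrichment: both UTR sets must be non-empty")
  if (k < 1L) stop("pentamer_enrichment: k must be >= 1")
  if (n_perm < 100L) stop("pentamer_enrichment: n_perm must be >= 100")
  seqs <- check_rna(c(foreground$sequence, background$sequence))
  long_enough <- nchar(seqs) >= k
  if (!any(long_enough)) stop("pentamer_enrichment: all UTRs shorter than k")
  is_fg <- c(rep(TRUE, nrow(foreground)), rep(FALSE, nrow(background)))
  if (any(!long_enough)) {
    warning("pentamer_enrichment: dropping ", sum(!long_enough),
            " UTR(s) shorter than k")
    seqs <- seqs[long_enough]
    is_fg <- is_fg[long_enough]
  }
  if (!any(is_fg) || all(is_fg))
    stop("pentamer_enrichment: one set has no UTR of length >= k")
  set <- Biostrings::RNAStringSet(seqs)
  counts <- Biostrings::oligonucleotideFrequency(set, width = k)
  rates <- counts / (nchar(seqs) - k + 1L)

  n_fg <- sum(is_fg); n_bg <- sum(!is_fg); n <- length(is_fg)
  contrast <- function(fg_mask) {
    colMeans(rates[fg_mask, , drop = FALSE]) -
      colMeans(rates[!fg_mask, , drop = FALSE])
  }
  obs <- contrast(is_fg)

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()), add = TRUE)
  set.seed(seed)
  null_mat <- vapply(seq_len(n_perm), function(i) {
    contrast(seq_len(n) %in% sample.int(n, n_fg))
  }, numeric(ncol(rates)))

  null_mean <- rowMeans(null_mat)
  null_sd <- apply(null_mat, 1L, stats::sd)
  z <- ifelse(null_sd > 0, (obs - null_mean) / null_sd, 0)
  p_perm <- (1 + rowSums(null_mat >= obs)) / (n_perm + 1)

  out <- data.frame(kmer = colnames(rates),
                    fg_rate = colMeans(rates[is_fg, , drop = FALSE]),
                    bg_rate = colMeans(rates[!is_fg, , drop = FALSE]),
                    diff = obs, z = z, p_perm = p_perm,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$z), ]
  rownames(out) <- NULL
  out
}
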