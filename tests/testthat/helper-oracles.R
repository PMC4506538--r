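# Independent brute-force oracles used to validate the implementation.
# These deliberately share no code with the package: everything is done by
# naive enumeration.

random_rna <- function(len, probs = c(A = .25, C = .25, G = .25, U = .25)) {
  paste(sample(names(probs), len, replace = TRUE, prob = probs),
        collapse = "")
}

# all-positions sliding-window motif count
brute_count_motif <- function(s, motif) {
  n <- nchar(s); m <- nchar(motif)
  if (n < m) return(0L)
  hits <- 0L
  for (i in seq_len(n - m + 1L)) {
    if (substr(s, i, i + m - 1L) == motif) hits <- hits + 1L
  }
  hits
}

# 0-based start positions of a motif
brute_motif_starts <- function(s, motif) {
  n <- nchar(s); m <- nchar(motif)
  out <- integer(0)
  if (n >= m) {
    for (i in seq_len(n - m + 1L)) {
      if (substr(s, i, i + m - 1L) == motif) out <- c(out, i - 1L)
    }
  }
  out
}

# maximal A/U runs by character scan; 0-based half-open
brute_au_runs <- function(s) {
  chars <- strsplit(s, "")[[1]]
  runs <- NULL
  start <- NA
  for (i in seq_along(chars)) {
    if (chars[i] %in% c("A", "U")) {
      if (is.na(start)) start <- i - 1L
    } else if (!is.na(start)) {
      runs <- rbind(runs, c(start, i - 1L))
      start <- NA
    }
  }
  if (!is.na(start)) runs <- rbind(runs, c(start, length(chars)))
  if (is.null(runs)) matrix(integer(0), ncol = 2) else runs
}

# clustered/isolated heptamer classification by enumeration
brute_heptamer_classes <- function(s, min_run = 12L) {
  hept <- brute_motif_starts(s, "UAUUUAU")
  runs <- brute_au_runs(s)
  clustered <- 0L
  for (h in hept) {
    inside <- FALSE
    if (nrow(runs) > 0) {
      for (r in seq_len(nrow(runs))) {
        if (runs[r, 2] - runs[r, 1] >= min_run &&
            runs[r, 1] <= h && h + 7L <= runs[r, 2]) inside <- TRUE
      }
    }
    if (inside) clustered <- clustered + 1L
  }
  c(n_heptamer = length(hept), n_clustered = clustered,
    n_isolated = length(hept) - clustered)
}

# KS statistics by evaluating both ECDFs on a dense grid of breakpoints
brute_ks <- function(a, b) {
  grid <- sort(c(a, b))
  fa <- sapply(grid, function(x) mean(a <= x))
  fb <- sapply(grid, function(x) mean(b <= x))
  list(D = max(abs(fa - fb)), D_plus_b_minus_a = max(c(0, fb - fa)))
}

# exact two-sided Wilcoxon rank-sum p by enumerating all label assignments
brute_wilcoxon_two_sided <- function(x, y) {
  pooled <- c(x, y)
  n <- length(pooled); nx <- length(x)
  u_obs <- sum(outer(x, y, ">"))
  combos <- combn(n, nx)
  u_all <- apply(combos, 2, function(idx) {
    xx <- pooled[idx]; yy <- pooled[-idx]
    sum(outer(xx, yy, ">"))
  })
  d_obs <- abs(u_obs - length(x) * length(y) / 2)
  mean(abs(u_all - length(x) * length(y) / 2) >= d_obs - 1e-9)
}

# small SAM writer for fixtures
write_test_sam <- function(path, lines, chrom = "chr1", len = 100000L) {
  writeLines(c("@HD\tVN:1.6\tSO:unknown",
               paste0("@SQ\tSN:", chrom, "\tLN:", len),
               lines), path)
}

sam_record <- function(qname, flag, chrom, pos, mapq, cigar, seq) {
  paste(qname, flag, chrom, pos, mapq, cigar, "*", 0, 0, seq,
        strrep("I", nchar(seq)), sep = "\t")
}
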