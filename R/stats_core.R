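#' @importFrom stats p.adjust wilcox.test cor pt ecdf setNames rnorm runif
NULL

#' Empirical cumulative distribution function
#'
#' Right-continuous step function `F(x) = #\{v <= x\} / n`, as plotted for
#' expression-change distributions of motif-count groups.
#'
#' @param values numeric vector, at least one finite value.
#' @return a function of class `ecdf`.
#' @export
ecdf_step <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 1L) stop("ecdf_step: need at least one finite value")
  stats::ecdf(values)
}

## Shared ECDF-sweep kernel: evaluates F_a - F_b over the pooled breakpoints
## and returns the signed differences. D = max |diff|, D+ = max(diff, 0).
ecdf_diff_sweep <- function(a, b) {
  stopifnot(is.numeric(a), is.numeric(b))
  pooled <- sort(unique(c(a, b)))
  na <- length(a)
  nb <- length(b)
  fa <- vapply(pooled, function(x) sum(a <= x), numeric(1)) / na
  fb <- vapply(pooled, function(x) sum(b <= x), numeric(1)) / nb
  fa - fb
}

## Asymptotic two-sided Kolmogorov tail: Q(t) = 2 * sum (-1)^(k-1) exp(-2 k^2 t^2)
kolmogorov_tail <- function(t) {
  if (t <= 0) return(1)
  k <- seq_len(100L)
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * t^2))
  min(max(p, 0), 1)
}

#' Two-sided two-sample Kolmogorov-Smirnov test
#'
#' D is the supremum of |F_a - F_b| over the pooled sample breakpoints; the
#' p-value uses the asymptotic Kolmogorov series with effective sample size
#' `n = |a||b| / (|a| + |b|)`. Used to compare expression-change
#' distributions between groups of transcripts with different AUUUA motif
#' counts.
#'
#' @param a,b numeric vectors of length >= 2.
#' @return list with elements `D` and `p`.
#' @export
ks_two_sided <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2L || length(b) < 2L)
    stop("ks_two_sided: both samples need >= 2 values")
  if (anyNA(a) || anyNA(b)) stop("ks_two_sided: missing values not allowed")
  d <- max(abs(ecdf_diff_sweep(a, b)))
  ne <- length(a) * length(b) / (length(a) + length(b))
  list(D = d, p = kolmogorov_tail(sqrt(ne) * d))
}

#' One-sided Kolmogorov-Smirnov test for a right shift
#'
#' Tests whether `a_set` is shifted towards larger values relative to
#' `b_background`: `D+ = sup(F_background - F_set)` over pooled breakpoints,
#' with the one-sided asymptotic p-value `exp(-2 D+^2 nm/(n+m))` clipped to
#' (0, 1]. This is the kernel of the tissue-rank skew statistic.
#'
#' @param a_set numeric vector (the gene set), length >= 2.
#' @param b_background numeric vector (the background), length >= 2.
#' @return list with elements `D_plus` and `p`.
#' @export
ks_one_sided <- function(a_set, b_background) {
  a <- as.numeric(a_set); b <- as.numeric(b_background)
  if (length(a) < 2L || length(b) < 2L)
    stop("ks_one_sided: both samples need >= 2 values")
  if (anyNA(a) || anyNA(b)) stop("ks_one_sided: missing values not allowed")
  d_plus <- max(c(0, ecdf_diff_sweep(b, a)))
  ne <- length(a) * length(b) / (length(a) + length(b))
  p <- exp(-2 * d_plus^2 * ne)
  list(D_plus = d_plus, p = min(max(p, .Machine$double.xmin), 1))
}

#' Wilcoxon rank-sum test
#'
#' Exact enumeration when the pooled sample size is <= 20 and there are no
#' ties; otherwise the normal approximation with tie and continuity
#' correction.
#'
#' @param x,y numeric vectors, non-empty.
#' @param alternative one of "two.sided", "less", "greater" ("less" means x
#'   tends to be smaller than y).
#' @return list with elements `U` (number of (x, y) pairs with x > y) and `p`.
#' @export
wilcoxon_rank_sum <- function(x, y,
                              alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 1L || length(y) < 1L)
    stop("wilcoxon_rank_sum: both samples must be non-empty")
  ties <- any(duplicated(c(x, y)))
  use_exact <- (length(x) + length(y) <= 20L) && !ties
  res <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = alternative,
                       exact = use_exact, correct = TRUE)
  )
  list(U = unname(res$statistic), p = res$p.value, exact = use_exact)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR-adjusted p-values, capped at 1.
#'
#' @param p numeric vector of raw p-values in \[0, 1\].
#' @return numeric vector of adjusted p-values, same order as input.
#' @export
bh_adjust <- function(p) {
  p <- as.numeric(p)
  if (anyNA(p) || any(p < 0 | p > 1))
    stop("bh_adjust: p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Pearson correlation coefficient
#'
#' @param x,y numeric vectors of equal length >= 3, both non-constant.
#' @return sample correlation in \[-1, 1\].
#' @export
pearson_r <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y) || length(x) < 3L)
    stop("pearson_r: need equal-length vectors with >= 3 values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("pearson_r: constant vector")
  stats::cor(x, y, method = "pearson")
}
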