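## 3' end sequencing quantification. A read qualifies as polyadenylation
## site-supporting (PASS) when the soft-clip beyond its genome-matched 3'
## end starts with >= 2 consecutive A's in mRNA-sense orientation: the
## non-genomic A's immediately following the genome-encoded part evidence a
## poly(A) junction. PASS reads falling inside annotated 3' UTRs are counted
## per gene and scaled to reads per million (RPM) of *total* PASS reads.

#' @importFrom GenomicRanges GRanges findOverlaps
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors queryHits subjectHits
NULL

#' Filter alignments by mapping quality
#'
#' @param reads data.frame from [read_sam_3p()].
#' @param min_mapq inclusive threshold (default 10).
#' @return the reads with `mapq >= min_mapq`, order preserved.
#' @export
filter_mapq <- function(reads, min_mapq = 10L) {
  reads[reads$mapq >= min_mapq, , drop = FALSE]
}

#' Leading non-genomic A count of the 3' soft-clip
#' @param clip3p character vector of sense-orientation soft-clips.
#' @return integer vector: length of the leading A run of each clip.
#' @export
leading_a_count <- function(clip3p) {
  m <- regexpr("^A+", clip3p)
  ifelse(m == 1L, attr(m, "match.length"), 0L)
}

#' PASS qualification of reads
#'
#' TRUE iff the soft-clip starts with at least `min_a` consecutive A's.
#' Later non-A bases (e.g. sequencing errors deep in the tail) do not
#' disqualify a read, but a non-A base immediately after the genome-encoded
#' part does.
#'
#' @param reads data.frame with a `clip3p` column, sense orientation.
#' @param min_a minimum number of leading non-genomic A's (default 2).
#' @return logical vector.
#' @export
qualify_pass <- function(reads, min_a = 2L) {
  leading_a_count(reads$clip3p) >= min_a
}

#' Assign read 3' ends to annotated 3' UTRs
#'
#' A read is assigned to the gene whose 3' UTR interval (0-based half-open)
#' contains its `genome_end3p` on the same chromosome and strand. When the
#' 3' end falls into several overlapping UTRs, the gene whose annotated 3'
#' terminus is nearest wins; exact ties go to the lexicographically smaller
#' gene id. The number of ambiguous assignments is recorded in the
#' `"n_ambiguous"` attribute so users can audit them.
#'
#' @param reads data.frame with `chrom`, `strand`, `genome_end3p`.
#' @param utrs BED6 data.frame ([read_bed6()]); `name` is the gene id.
#' @return character vector of gene ids (NA where unassigned), with
#'   attribute `n_ambiguous`.
#' @export
assign_to_utr <- function(reads, utrs) {
  if (nrow(reads) == 0L) {
    out <- character(0)
    attr(out, "n_ambiguous") <- 0L
    return(out)
  }
  # half-open [start, end) BED -> IRanges [start+1, end] on 1-based closed
  q <- GenomicRanges::GRanges(reads$chrom,
                              IRanges::IRanges(reads$genome_end3p + 1L,
                                               width = 1L),
                              strand = reads$strand)
  s <- GenomicRanges::GRanges(utrs$chrom,
                              IRanges::IRanges(utrs$start + 1L, utrs$end),
                              strand = utrs$strand)
  hits <- GenomicRanges::findOverlaps(q, s, ignore.strand = FALSE)
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)

  # annotated 3' terminus of each UTR (0-based coordinate of last UTR base
  # on the mRNA side): end-1 on '+', start on '-'
  term3 <- ifelse(utrs$strand == "+", utrs$end - 1L, utrs$start)
  assigned <- rep(NA_character_, nrow(reads))
  n_ambiguous <- 0L
  if (length(qh) > 0L) {
    dist <- abs(reads$genome_end3p[qh] - term3[sh])
    gene <- utrs$name[sh]
    ord <- order(qh, dist, gene)
    qh_o <- qh[ord]; gene_o <- gene[ord]
    first <- !duplicated(qh_o)
    assigned[qh_o[first]] <- gene_o[first]
    multi <- table(qh)
    n_ambiguous <- sum(multi > 1L)
  }
  attr(assigned, "n_ambiguous") <- n_ambiguous
  assigned
}

#' Per-gene RPM from PASS counts
#'
#' `rpm = pass_count / total_pass * 1e6`. The denominator is the total
#' number of PASS reads in the sample, including those outside annotated
#' 3' UTRs, so per-gene counts may sum to less than `total_pass`.
#'
#' @param counts named integer vector of per-gene PASS counts.
#' @param total_pass total PASS reads in the sample (> 0).
#' @return data.frame with `gene_id`, `pass_count`, `rpm`.
#' @export
quantify_rpm <- function(counts, total_pass) {
  if (total_pass <= 0L) stop("quantify_rpm: total_pass must be > 0")
  if (sum(counts) > total_pass)
    stop("quantify_rpm: per-gene counts exceed total_pass")
  data.frame(gene_id = names(counts),
             pass_count = as.integer(counts),
             rpm = as.numeric(counts) / total_pass * 1e6,
             stringsAsFactors = FALSE)
}

#' Between-condition log2 RPM ratios
#'
#' For every gene present in either condition (absent genes get RPM 0):
#' `log2((rpm_a + pseudo) / (rpm_b + pseudo))`. The symmetric pseudocount
#' (default 1 RPM) keeps zero-expression genes defined and unbiased at
#' equality.
#'
#' @param quant_a,quant_b data.frames from [quantify_rpm()] (e.g.
#'   differentiated vs undifferentiated).
#' @param pseudo pseudocount in RPM units (> 0).
#' @return named numeric vector of log2 ratios (a over b).
#' @export
log2_rpm_ratio <- function(quant_a, quant_b, pseudo = 1.0) {
  if (pseudo <= 0) stop("log2_rpm_ratio: pseudo must be > 0")
  genes <- union(quant_a$gene_id, quant_b$gene_id)
  rpm_a <- stats::setNames(rep(0, length(genes)), genes)
  rpm_b <- rpm_a
  rpm_a[quant_a$gene_id] <- quant_a$rpm
  rpm_b[quant_b$gene_id] <- quant_b$rpm
  log2((rpm_a + pseudo) / (rpm_b + pseudo))
}

#' Full PASS quantification of one sample
#'
#' Applies the MAPQ filter, PASS qualification and UTR assignment, and
#' returns per-gene quantities together with a read-conservation accounting:
#' every input read is exactly one of low-MAPQ, non-PASS, PASS-unassigned or
#' PASS-assigned.
#'
#' @param reads data.frame from [read_sam_3p()].
#' @param utrs BED6 data.frame of 3' UTRs.
#' @param min_mapq MAPQ threshold (inclusive, default 10).
#' @param min_a minimum leading non-genomic A's for PASS (default 2).
#' @return list with `quant` (per-gene data.frame including all UTR genes,
#'   zero-count genes included), `total_pass`, and `accounting` (named
#'   integer vector: n_input, n_low_mapq, n_non_pass, n_pass_unassigned,
#'   n_pass_assigned, n_ambiguous).
#' @export
quantify_3reads <- function(reads, utrs, min_mapq = 10L, min_a = 2L) {
  n_input <- nrow(reads)
  kept <- filter_mapq(reads, min_mapq)
  n_low <- n_input - nrow(kept)
  is_pass <- qualify_pass(kept, min_a)
  pass <- kept[is_pass, , drop = FALSE]
  n_nonpass <- nrow(kept) - nrow(pass)
  total_pass <- nrow(pass)

  genes <- sort(unique(utrs$name))
  counts <- stats::setNames(integer(length(genes)), genes)
  n_ambiguous <- 0L
  if (total_pass > 0L) {
    gene_hit <- assign_to_utr(pass, utrs)
    n_ambiguous <- attr(gene_hit, "n_ambiguous")
    tab <- table(gene_hit[!is.na(gene_hit)])
    counts[names(tab)] <- as.integer(tab)
  }
  n_assigned <- sum(counts)
  n_unassigned <- total_pass - n_assigned

  quant <- if (total_pass > 0L) quantify_rpm(counts, total_pass) else
    data.frame(gene_id = genes, pass_count = 0L, rpm = 0,
               stringsAsFactors = FALSE)
  list(quant = quant,
       total_pass = total_pass,
       accounting = c(n_input = n_input,
                      n_low_mapq = n_low,
                      n_non_pass = n_nonpass,
                      n_pass_unassigned = n_unassigned,
                      n_pass_assigned = n_assigned,
                      n_ambiguous = n_ambiguous))
}
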