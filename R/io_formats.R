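## File-format layer. Conventions used throughout the package:
##  - all genomic intervals are 0-based half-open internally (BED native;
##    SAM POS converted from 1-based on load);
##  - sequences are held in the RNA alphabet (input T mapped to U), matching
##    the UAUUUAU spelling of the motifs being annotated.

#' @importFrom Biostrings readBStringSet writeXStringSet BStringSet
#'   DNAString DNAStringSet reverseComplement oligonucleotideFrequency
#'   RNAStringSet
#' @importFrom utils read.table write.table
NULL

normalize_rna <- function(seqs, ids = NULL) {
  up <- toupper(seqs)
  up <- chartr("T", "U", up)
  bad <- grepl("[^ACGU]", up)
  if (any(bad)) {
    which_bad <- if (is.null(ids)) which(bad)[1] else ids[bad][1]
    stop("non-ACGTU character in sequence record '", which_bad, "'")
  }
  up
}

#' Read 3' UTR sequences from FASTA
#'
#' Headers are parsed as `"utr_id gene_id"`; when no gene id is given the
#' UTR id is reused. Sequences are normalized to the RNA alphabet
#' (case-folded, T -> U); any other character is an error naming the record.
#'
#' @param path FASTA file.
#' @return data.frame with columns `utr_id`, `gene_id`, `sequence`.
#' @export
read_utr_fasta <- function(path) {
  if (!file.exists(path)) stop("read_utr_fasta: no such file: ", path)
  set <- Biostrings::readBStringSet(path)
  headers <- names(set)
  if (is.null(headers) || any(!nzchar(headers)))
    stop("read_utr_fasta: malformed FASTA (empty header) in ", path)
  fields <- strsplit(headers, "\\s+")
  utr_id <- vapply(fields, `[[`, character(1), 1L)
  gene_id <- vapply(fields, function(f) if (length(f) >= 2L) f[[2L]] else f[[1L]],
                    character(1))
  seqs <- normalize_rna(as.character(set), ids = utr_id)
  data.frame(utr_id = utr_id, gene_id = gene_id, sequence = unname(seqs),
             stringsAsFactors = FALSE)
}

#' Write 3' UTR records to FASTA
#'
#' @param utrs data.frame as returned by [read_utr_fasta()].
#' @param path output file.
#' @export
write_utr_fasta <- function(utrs, path) {
  stopifnot(all(c("utr_id", "gene_id", "sequence") %in% names(utrs)))
  set <- Biostrings::BStringSet(utrs$sequence)
  names(set) <- paste(utrs$utr_id, utrs$gene_id)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a BED6 file of 3' UTR intervals
#'
#' Intervals are kept 0-based half-open (BED native). Strand must be `+` or
#' `-`; the unstranded `.` is rejected because read-to-UTR assignment is
#' strand-aware.
#'
#' @param path BED file with >= 6 tab-separated columns.
#' @return data.frame with columns `chrom`, `start`, `end`, `name`, `score`,
#'   `strand`.
#' @export
read_bed6 <- function(path) {
  if (!file.exists(path)) stop("read_bed6: no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 6L))
    stop("read_bed6: line ", which(nf < 6L)[1], " has fewer than 6 columns")
  bed <- data.frame(
    chrom  = vapply(fields, `[[`, character(1), 1L),
    start  = as.integer(vapply(fields, `[[`, character(1), 2L)),
    end    = as.integer(vapply(fields, `[[`, character(1), 3L)),
    name   = vapply(fields, `[[`, character(1), 4L),
    score  = as.numeric(vapply(fields, `[[`, character(1), 5L)),
    strand = vapply(fields, `[[`, character(1), 6L),
    stringsAsFactors = FALSE
  )
  if (anyNA(bed$start) || anyNA(bed$end))
    stop("read_bed6: non-integer start/end coordinate")
  if (any(bed$start < 0L)) stop("read_bed6: negative start coordinate")
  if (any(bed$start >= bed$end)) {
    i <- which(bed$start >= bed$end)[1]
    stop("read_bed6: start >= end at line ", i, " (", bed$name[i], ")")
  }
  if (any(!bed$strand %in% c("+", "-"))) {
    i <- which(!bed$strand %in% c("+", "-"))[1]
    stop("read_bed6: strand must be '+' or '-' (got '", bed$strand[i],
         "' at line ", i, "); '.' is not usable for stranded 3' UTRs")
  }
  bed
}

#' Write BED6 intervals
#' @param bed data.frame as returned by [read_bed6()].
#' @param path output file.
#' @export
write_bed6 <- function(bed, path) {
  stopifnot(all(c("chrom", "start", "end", "name", "score", "strand")
                %in% names(bed)))
  utils::write.table(bed[, c("chrom", "start", "end", "name", "score",
                             "strand")],
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read 3' end sequencing alignments from SAM
#'
#' Parses a headered SAM file and extracts, for every mapped read, the
#' mRNA-sense 3' end and the 3'-terminal soft-clip:
#' \itemize{
#'   \item forward alignments (FLAG bit 16 unset): the mRNA 3' side is the
#'     right (high-coordinate) end; the trailing `S` CIGAR op supplies the
#'     clip, already in sense orientation;
#'   \item reverse alignments (bit 16 set): the mRNA 3' side is the left end;
#'     the leading `S` op supplies the clip, which is reverse-complemented
#'     back to sense orientation.
#' }
#' `genome_end3p` is the 0-based coordinate of the last genome-matched base
#' on the mRNA 3' side. Unmapped reads are skipped. Clips are reported in
#' the RNA alphabet.
#'
#' @param path SAM file with header.
#' @return data.frame with columns `read_id`, `chrom`, `strand`,
#'   `genome_end3p`, `mapq`, `clip3p`.
#' @export
read_sam_3p <- function(path) {
  if (!file.exists(path)) stop("read_sam_3p: no such file: ", path)
  bam <- Rsamtools::asBam(path,
                          destination = tempfile(fileext = ""),
                          overwrite = TRUE, indexDestination = FALSE)
  on.exit(unlink(bam), add = TRUE)
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq"),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE)
  )
  rec <- Rsamtools::scanBam(bam, param = param)[[1]]
  n <- length(rec$qname)
  if (n == 0L) {
    return(data.frame(read_id = character(), chrom = character(),
                      strand = character(), genome_end3p = integer(),
                      mapq = integer(), clip3p = character(),
                      stringsAsFactors = FALSE))
  }
  cigars <- rec$cigar
  if (anyNA(cigars)) {
    stop("read_sam_3p: missing CIGAR for mapped read '",
         rec$qname[which(is.na(cigars))[1]], "'")
  }
  ops <- GenomicAlignments::explodeCigarOps(cigars)
  lens <- GenomicAlignments::explodeCigarOpLengths(cigars)
  ref_w <- GenomicAlignments::cigarWidthAlongReferenceSpace(cigars)
  is_rev <- bitwAnd(rec$flag, 16L) > 0L
  seqs <- as.character(rec$seq)

  clip_len <- integer(n)
  for (i in seq_len(n)) {
    o <- ops[[i]]; l <- lens[[i]]
    keep <- o != "H"           # hard clips carry no sequence
    o <- o[keep]; l <- l[keep]
    if (length(o) == 0L) stop("read_sam_3p: empty CIGAR for read '",
                              rec$qname[i], "'")
    if (is_rev[i]) {
      clip_len[i] <- if (o[1L] == "S") l[1L] else 0L
    } else {
      k <- length(o)
      clip_len[i] <- if (o[k] == "S") l[k] else 0L
    }
  }

  clip3p <- character(n)
  has_clip <- clip_len > 0L
  if (any(has_clip)) {
    fwd <- has_clip & !is_rev
    if (any(fwd)) {
      w <- nchar(seqs[fwd])
      clip3p[fwd] <- substr(seqs[fwd], w - clip_len[fwd] + 1L, w)
    }
    rev <- has_clip & is_rev
    if (any(rev)) {
      raw <- substr(seqs[rev], 1L, clip_len[rev])
      clip3p[rev] <- as.character(
        Biostrings::reverseComplement(Biostrings::DNAStringSet(raw)))
    }
  }
  clip3p <- chartr("Tt", "Uu", toupper(clip3p))

  data.frame(
    read_id = rec$qname,
    chrom = as.character(rec$rname),
    strand = ifelse(is_rev, "-", "+"),
    genome_end3p = ifelse(is_rev, rec$pos - 1L, rec$pos - 1L + ref_w - 1L),
    mapq = rec$mapq,
    clip3p = clip3p,
    stringsAsFactors = FALSE
  )
}

#' Read an expression matrix from TSV
#'
#' First row holds column ids, first column row ids. Rows containing any
#' non-numeric or missing cell are dropped (the downstream analyses assume
#' complete matrices); the drop count is recorded.
#'
#' @param path TSV file.
#' @param groups optional named character vector mapping column id to a group
#'   label; checked against the file's columns.
#' @return list with `values` (numeric matrix with dimnames), `groups`, and
#'   `n_dropped`.
#' @export
read_matrix_tsv <- function(path, groups = NULL) {
  if (!file.exists(path)) stop("read_matrix_tsv: no such file: ", path)
  raw <- utils::read.table(path, sep = "\t", header = TRUE, row.names = NULL,
                           check.names = FALSE, colClasses = "character",
                           quote = "", comment.char = "")
  if (ncol(raw) < 2L) stop("read_matrix_tsv: need row ids plus >= 1 column")
  row_ids <- raw[[1]]
  if (anyDuplicated(row_ids))
    stop("read_matrix_tsv: duplicate row id '",
         row_ids[duplicated(row_ids)][1], "'")
  col_ids <- colnames(raw)[-1]
  if (anyDuplicated(col_ids))
    stop("read_matrix_tsv: duplicate column id '",
         col_ids[duplicated(col_ids)][1], "'")
  vals <- suppressWarnings(
    vapply(raw[-1], as.numeric, numeric(nrow(raw))))
  vals <- matrix(vals, nrow = nrow(raw),
                 dimnames = list(row_ids, col_ids))
  ok <- apply(vals, 1L, function(r) all(is.finite(r)))
  n_dropped <- sum(!ok)
  vals <- vals[ok, , drop = FALSE]
  if (!is.null(groups)) {
    missing_cols <- setdiff(col_ids, names(groups))
    if (length(missing_cols) > 0L)
      stop("read_matrix_tsv: no group label for column '",
           missing_cols[1], "'")
    groups <- groups[col_ids]
  }
  list(values = vals, groups = groups, n_dropped = n_dropped)
}

#' Write an expression matrix to TSV
#'
#' Values are written with full precision (\code{format(..., digits = 17)}
#' via \code{write.table} default formatting), so a read/write round trip is
#' value-exact for finite doubles.
#'
#' @param values numeric matrix with dimnames.
#' @param path output file.
#' @param id_col name of the leading id column.
#' @export
write_matrix_tsv <- function(values, path, id_col = "id") {
  stopifnot(is.matrix(values), !is.null(rownames(values)),
            !is.null(colnames(values)))
  df <- data.frame(rownames(values),
                   format(values, digits = 17, trim = TRUE,
                          scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c(id_col, colnames(values))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
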