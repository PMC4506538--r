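make_reads_df <- function(...) {
  df <- data.frame(..., stringsAsFactors = FALSE)
  if (!"read_id" %in% names(df)) df$read_id <- paste0("r", seq_len(nrow(df)))
  df
}

test_that("MAPQ filter is inclusive at the threshold", {
  reads <- make_reads_df(mapq = c(10L, 9L, 42L, 0L))
  kept <- filter_mapq(reads, 10L)
  expect_equal(kept$mapq, c(10L, 42L))
  expect_equal(nrow(filter_mapq(reads[0, ], 10L)), 0L)
})

test_that("PASS qualification reads the leading non-genomic A run", {
  reads <- make_reads_df(clip3p = c("AA", "A", "GAA", "AAG", "", "AAAAA"))
  expect_equal(qualify_pass(reads),
               c(TRUE, FALSE, FALSE, TRUE, FALSE, TRUE))
  # monotone in min_a: raising the threshold never adds PASS reads
  set.seed(8)
  clips <- replicate(200, paste(sample(c("A", "C", "G", "U"),
                                       sample(0:6, 1), replace = TRUE),
                                collapse = ""))
  rd <- make_reads_df(clip3p = clips)
  prev <- qualify_pass(rd, 0L)
  for (k in 1:5) {
    cur <- qualify_pass(rd, k)
    expect_true(all(prev | !cur))
    prev <- cur
  }
})

test_that("UTR assignment respects half-open bounds, strand and tie-break", {
  utrs <- data.frame(chrom = "chr1", start = 10L, end = 20L, name = "g1",
                     score = 0, strand = "+", stringsAsFactors = FALSE)
  inside <- make_reads_df(chrom = "chr1", strand = "+", genome_end3p = 15L)
  expect_equal(as.vector(assign_to_utr(inside, utrs)), "g1")
  at_end <- make_reads_df(chrom = "chr1", strand = "+", genome_end3p = 20L)
  expect_true(is.na(assign_to_utr(at_end, utrs)))
  wrong_strand <- make_reads_df(chrom = "chr1", strand = "-",
                                genome_end3p = 15L)
  expect_true(is.na(assign_to_utr(wrong_strand, utrs)))

  # overlapping UTRs: nearer annotated 3' terminus wins
  over <- data.frame(chrom = "chr1", start = c(0L, 10L), end = c(30L, 22L),
                     name = c("gFar", "gNear"), score = 0, strand = "+",
                     stringsAsFactors = FALSE)
  read <- make_reads_df(chrom = "chr1", strand = "+", genome_end3p = 20L)
  res <- assign_to_utr(read, over)
  expect_equal(as.vector(res), "gNear")   # |20-21| = 1 < |20-29| = 9
  expect_equal(attr(res, "n_ambiguous"), 1L)

  # exact distance tie -> lexicographically smaller gene id
  tie <- data.frame(chrom = "chr1", start = c(0L, 5L), end = c(21L, 21L),
                    name = c("gB", "gA"), score = 0, strand = "+",
                    stringsAsFactors = FALSE)
  expect_equal(as.vector(assign_to_utr(read, tie)), "gA")
})

test_that("RPM scaling and log2 ratios follow the definitions", {
  q <- quantify_rpm(c(g1 = 5L, g2 = 15L), 20L)
  expect_equal(q$rpm, c(250000, 750000))
  expect_equal(quantify_rpm(c(g1 = 7L), 7L)$rpm, 1e6)
  expect_error(quantify_rpm(integer(0), 0L), "> 0")

  qa <- data.frame(gene_id = "g1", pass_count = 1L, rpm = 200)
  qb <- data.frame(gene_id = "g1", pass_count = 1L, rpm = 100)
  expect_equal(unname(log2_rpm_ratio(qa, qb, pseudo = 1e-9)), 1,
               tolerance = 1e-7)
  expect_equal(unname(log2_rpm_ratio(qa, qa)), 0)
  # gene absent from both -> pseudocount keeps the ratio at 0
  zero <- data.frame(gene_id = "gX", pass_count = 0L, rpm = 0)
  expect_equal(unname(log2_rpm_ratio(zero, zero, pseudo = 1)), 0)
  expect_error(log2_rpm_ratio(qa, qb, pseudo = 0), "pseudo")
})

test_that("synthetic alignments round-trip to exact planted counts", {
  cfg <- sim_config(seed = 31, reads_per_gene_range = c(10L, 30L),
                    motif_plan = list(
                      "0" = list(n = 8L, target = 0L, clustered = FALSE),
                      ">=6" = list(n = 8L, target = 6L, clustered = TRUE)))
  utrs <- gen_utrs(cfg)
  bed <- make_utr_bed(utrs)
  sam <- tempfile(fileext = ".sam")
  truth <- gen_sam_3reads(cfg, bed, sam)$truth
  reads <- read_sam_3p(sam)
  res <- quantify_3reads(reads, bed)
  expect_equal(res$quant$pass_count,
               unname(truth[res$quant$gene_id]))
  acc <- res$accounting
  expect_equal(unname(acc["n_input"]),
               unname(acc["n_low_mapq"] + acc["n_non_pass"] +
                        acc["n_pass_unassigned"] + acc["n_pass_assigned"]))
  # decoy classes are excluded by the right gate
  expect_equal(unname(acc["n_low_mapq"]),
               sum(grepl("lowmapq", reads$read_id)))
  expect_equal(unname(acc["n_pass_unassigned"]),
               sum(grepl("outside", reads$read_id)))
})

test_that("log2 ratios recover planted fold changes within pseudocount bias", {
  # two samples with known counts >= 50: bias bound |log2((x+1)/(y+1)) -
  # log2(x/y)| is tiny at this depth
  x <- c(g1 = 100L, g2 = 400L, g3 = 50L)
  y <- c(g1 = 50L, g2 = 100L, g3 = 200L)
  qa <- quantify_rpm(x, sum(x))
  qb <- quantify_rpm(y, sum(y))
  obs <- log2_rpm_ratio(qa, qb, pseudo = 1)
  expected <- log2((x / sum(x)) / (y / sum(y)))
  bound <- abs(log2((x + 1) / (y + 1)) - log2(x / y)) + 1e-6
  expect_true(all(abs(obs[names(x)] - expected) <=
                    pmax(bound, 2e-5)))
})
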