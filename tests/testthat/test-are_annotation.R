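test_that("count_motif counts overlapping occurrences", {
  expect_equal(count_motif("AUUUA", "AUUUA"), 1L)
  expect_equal(count_motif("AUUUAUUUA", "AUUUA"), 2L)
  expect_equal(count_motif("GCGCGC", "AUUUA"), 0L)
  expect_equal(count_motif("atttattta", "AUUUA"), 2L)   # case + T/U
  expect_error(count_motif("AUUUA", ""), "empty motif")
})

test_that("find_au_runs returns maximal runs, left to right", {
  runs <- find_au_runs("GGAUUUAUGG")
  expect_equal(runs$start, 2L)
  expect_equal(runs$end, 8L)
  expect_equal(nrow(find_au_runs("")), 0L)
  whole <- find_au_runs("AUAU")
  expect_equal(whole$start, 0L)
  expect_equal(whole$end, 4L)
})

test_that("annotate_ares classifies clustered vs isolated heptamers", {
  ann <- annotate_ares(data.frame(utr_id = "u", gene_id = "g",
                                  sequence = "UAUUUAUAUUUAU"))
  expect_equal(ann$n_heptamer, 2)
  expect_equal(ann$n_clustered, 2)   # whole 13 nt sequence is one AU run
  expect_equal(ann$n_isolated, 0)

  ann <- annotate_ares(data.frame(utr_id = "u", gene_id = "g",
                                  sequence = "GGUAUUUAUGG"))
  expect_equal(ann$n_heptamer, 1)
  expect_equal(ann$n_clustered, 0)   # run length 7 < 12
  expect_equal(ann$n_isolated, 1)

  empty <- annotate_ares(data.frame(utr_id = "u", gene_id = "g",
                                    sequence = ""))
  expect_equal(empty$n_pentamer, 0)
  expect_equal(empty$n_heptamer, 0)

  # min_run is a real parameter: with min_run = 7 the isolated case flips
  ann7 <- annotate_ares(data.frame(utr_id = "u", gene_id = "g",
                                   sequence = "GGUAUUUAUGG"), min_run = 7L)
  expect_equal(ann7$n_clustered, 1)
})

test_that("motif counting and ARE annotation match brute-force enumeration", {
  set.seed(99)
  for (i in 1:300) {
    # AU-biased alphabet so motifs and long runs actually occur
    s <- random_rna(sample(0:100, 1),
                    probs = c(A = .35, C = .15, G = .15, U = .35))
    expect_identical(count_motif(s, "AUUUA"), brute_count_motif(s, "AUUUA"))
    ann <- annotate_ares(data.frame(utr_id = "u", gene_id = "g",
                                    sequence = s))
    oracle <- brute_heptamer_classes(s)
    expect_equal(ann$n_pentamer, brute_count_motif(s, "AUUUA"))
    expect_equal(ann$n_heptamer, unname(oracle["n_heptamer"]))
    expect_equal(ann$n_clustered, unname(oracle["n_clustered"]))
    expect_equal(ann$n_isolated, unname(oracle["n_isolated"]))
    # type invariants
    expect_lte(ann$n_heptamer, ann$n_pentamer)
    expect_equal(ann$n_clustered + ann$n_isolated, ann$n_heptamer)
    # runs are maximal and match the scan oracle
    runs <- find_au_runs(s)
    expect_equal(unname(as.matrix(runs[, c("start", "end")])),
                 unname(brute_au_runs(s)),
                 ignore_attr = TRUE)
  }
})

test_that("annotation is invariant to T/U spelling", {
  s <- "GGTATTTATTTATGGAAATTTAAA"
  a1 <- annotate_ares(data.frame(utr_id = "u", gene_id = "g", sequence = s))
  a2 <- annotate_ares(data.frame(utr_id = "u", gene_id = "g",
                                 sequence = chartr("T", "U", s)))
  expect_equal(a1, a2)
})

test_that("pentamer-count grouping bins genes as specified", {
  ann <- data.frame(utr_id = c("u1", "u2", "u3"),
                    gene_id = c("g1", "g2", "g3"),
                    n_pentamer = c(0, 7, 1))
  g <- group_by_pentamer_count(ann)
  expect_equal(names(g), c("0", "1-2", "3-5", ">=6"))
  expect_equal(g[["0"]], "g1")
  expect_equal(g[[">=6"]], "g2")
  expect_equal(g[["1-2"]], "g3")
  empty <- group_by_pentamer_count(ann[0, ])
  expect_true(all(lengths(empty) == 0))
  expect_error(group_by_pentamer_count(ann, boundaries = c(3, 1)),
               "strictly increasing")
})

test_that("motif-group KS comparison handles degenerate and derived cases", {
  fc <- c(g1 = 0, g2 = 0, g3 = 1, g4 = 1,
          g5 = 1, g6 = 2, g7 = 3, g8 = 4,
          g9 = 3, g10 = 4, g11 = 5, g12 = 6)
  groups <- list("0" = paste0("g", 1:4), "low" = paste0("g", 5:8),
                 "high" = paste0("g", 9:12))
  res <- compare_motif_groups(fc, groups)
  expect_equal(nrow(res), 3L)
  lo_hi <- res[res$group_a == "low" & res$group_b == "high", ]
  expect_equal(lo_hi$D, 0.5)  # {1,2,3,4} vs {3,4,5,6}, derived by sweep
  ident <- compare_motif_groups(c(a = 1, b = 2, c = 1, d = 2),
                                list(x = c("a", "b"), y = c("c", "d")))
  expect_equal(ident$D, 0)
  expect_equal(ident$p, 1)
  expect_warning(
    compare_motif_groups(fc, list("0" = "g1", rest = paste0("g", 2:8))),
    "skipping")
})

test_that("pentamer enrichment recovers planted ARE pentamers", {
  set.seed(21)
  fg <- data.frame(
    utr_id = paste0("f", 1:25), gene_id = paste0("f", 1:25),
    sequence = vapply(1:25, function(i)
      paste(c(random_rna(60, c(A = .2, C = .3, G = .3, U = .2)),
              strrep("UAUUUAU", 4)), collapse = ""), character(1)))
  bg <- data.frame(
    utr_id = paste0("b", 1:25), gene_id = paste0("b", 1:25),
    sequence = vapply(1:25, function(i)
      random_rna(88, c(A = .1, C = .4, G = .4, U = .1)), character(1)))
  enr <- pentamer_enrichment(fg, bg, n_perm = 199, seed = 3)
  expect_equal(nrow(enr), 4^5)
  top10 <- enr$kmer[1:10]
  expect_true(all(c("UAUUU", "UUUAU", "AUUUA") %in% top10))
  # seeded determinism
  enr2 <- pentamer_enrichment(fg, bg, n_perm = 199, seed = 3)
  expect_identical(enr, enr2)
})

test_that("pentamer enrichment is null under label exchange", {
  set.seed(22)
  pool <- data.frame(
    utr_id = paste0("u", 1:40), gene_id = paste0("u", 1:40),
    sequence = vapply(1:40, function(i) random_rna(80), character(1)))
  fg <- pool[1:20, ]
  bg <- pool[21:40, ]
  enr <- pentamer_enrichment(fg, bg, n_perm = 199, seed = 4)
  expect_gte(min(enr$p_perm), 1 / 200)
  alpha <- 0.05
  expect_lte(mean(enr$p_perm < alpha), alpha + 3 * sqrt(alpha / 1024))
  # identical sets: the contrast is exactly zero
  same <- pentamer_enrichment(fg, fg, n_perm = 199, seed = 5)
  expect_true(all(abs(same$diff) < 1e-15))
  expect_true(all(same$p_perm >= 1 / 200))
})

test_that("enrichment handles a single-base k-mer universe", {
  fg <- data.frame(utr_id = "f", gene_id = "f", sequence = "AAAAUUUU")
  bg <- data.frame(utr_id = "b", gene_id = "b", sequence = "GGGGCCCC")
  enr <- pentamer_enrichment(fg, bg, k = 1, n_perm = 100, seed = 1)
  expect_equal(nrow(enr), 4L)
  expect_true(all(is.finite(enr$z)))
  expect_error(pentamer_enrichment(
    data.frame(utr_id = "f", gene_id = "f", sequence = "AU"),
    data.frame(utr_id = "b", gene_id = "b", sequence = "GC"),
    k = 5, n_perm = 100, seed = 1), "shorter than k")
})
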