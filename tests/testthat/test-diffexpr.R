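test_that("row-wise Welch t matches stats::t.test", {
  set.seed(17)
  mat <- matrix(rnorm(40 * 8, mean = 7), 40, 8,
                dimnames = list(paste0("p", 1:40), paste0("s", 1:8)))
  res <- welch_t_rows(mat, paste0("s", 1:4), paste0("s", 5:8))
  for (i in c(1, 7, 23, 40)) {
    ref <- stats::t.test(mat[i, 1:4], mat[i, 5:8], var.equal = FALSE)
    expect_equal(res$t[i], unname(ref$statistic), tolerance = 1e-10)
    expect_equal(res$df[i], unname(ref$parameter), tolerance = 1e-10)
    expect_equal(res$p_raw[i], ref$p.value, tolerance = 1e-10)
  }
})

test_that("Welch degenerate rows behave as documented", {
  mat <- rbind(equal = c(1, 1, 1, 2, 2, 2) * 0 + 5,
               shifted = c(0, 0, 0, 1, 1, 1) + c(0, 0, 0, 1e-9, -1e-9, 0))
  colnames(mat) <- paste0("s", 1:6)
  res <- welch_t_rows(mat, paste0("s", 1:3), paste0("s", 4:6))
  expect_equal(res["equal", "t"], 0)
  expect_equal(res["equal", "p_raw"], 1)
  expect_lt(res["shifted", "p_raw"], 1e-6)
  # both groups constant but different means: flagged, p -> 0
  const <- rbind(x = c(0, 0, 0, 1, 1, 1))
  colnames(const) <- paste0("s", 1:6)
  res2 <- welch_t_rows(const, paste0("s", 1:3), paste0("s", 4:6))
  expect_true(res2$degenerate)
  expect_equal(res2$p_raw, 0)
  expect_error(welch_t_rows(mat, "s1", paste0("s", 4:6)), ">= 2")
})

test_that("hit selection applies fold, BH and consistency filters", {
  set.seed(23)
  n <- 200
  mat <- matrix(rnorm(n * 8, mean = 7, sd = 0.2), n, 8,
                dimnames = list(sprintf("p%03d", 1:n),
                                c(paste0("WT_", 1:4), paste0("KO_", 1:4))))
  ko <- paste0("KO_", 1:4); wt <- paste0("WT_", 1:4)
  # p001: ~15-fold up, consistent -> hit
  mat["p001", ko] <- mat["p001", ko] + log2(15)
  # p002: 8-fold only -> no hit regardless of p
  mat["p002", ko] <- mat["p002", ko] + log2(8)
  # p003: 20-fold on average but one KO column below the WT mean
  mat["p003", ko] <- mat["p003", ko] + log2(20)
  mat["p003", "KO_4"] <- mean(mat["p003", wt]) - 1
  hits <- select_hits(mat, ko, wt)
  expect_true("p001" %in% hits$probe_id)
  expect_equal(hits$direction[hits$probe_id == "p001"], "up")
  expect_false("p002" %in% hits$probe_id)
  expect_false("p003" %in% hits$probe_id)
  tested <- attr(hits, "tested")
  expect_true(all(tested$p_adj >= tested$p_raw))
})

test_that("hit selection is monotone in both thresholds", {
  cfg <- sim_config(seed = 41, n_genes = 300,
                    ko_plan = list(n_up = 10L, n_down = 10L, fold = 12,
                                   n_reps = 3L),
                    ko_noise_sd = 0.8)
  ko <- gen_ko_matrix(cfg)
  kc <- names(ko$groups)[ko$groups == "KO"]
  wc <- names(ko$groups)[ko$groups == "WT"]
  strict <- select_hits(ko$values, kc, wc, fold_threshold = 10,
                        alpha = 0.05)
  loose_fold <- select_hits(ko$values, kc, wc, fold_threshold = 5,
                            alpha = 0.05)
  loose_alpha <- select_hits(ko$values, kc, wc, fold_threshold = 10,
                             alpha = 0.2)
  expect_true(all(strict$probe_id %in% loose_fold$probe_id))
  expect_true(all(strict$probe_id %in% loose_alpha$probe_id))
})

test_that("planted strong hits are recovered with high sensitivity", {
  cfg <- sim_config(seed = 51, n_genes = 1000,
                    ko_plan = list(n_up = 50L, n_down = 0L, fold = 16,
                                   n_reps = 4L))
  ko <- gen_ko_matrix(cfg)
  hits <- select_hits(ko$values,
                      names(ko$groups)[ko$groups == "KO"],
                      names(ko$groups)[ko$groups == "WT"])
  up_hits <- hits$probe_id[hits$direction == "up"]
  expect_gte(mean(ko$truth_up %in% up_hits), 0.9)
  # no planted row is called in the wrong direction
  expect_equal(
    length(intersect(ko$truth_up, hits$probe_id[hits$direction == "down"])),
    0L)
})

test_that("gene collapsing separates concordant and discordant genes", {
  hits <- data.frame(probe_id = c("p1", "p2", "p3", "p4"),
                     log2fc = c(4, 4, 4, -4),
                     t = 1, p_raw = 0.001, p_adj = 0.01,
                     direction = c("up", "up", "up", "down"),
                     consistent = TRUE, stringsAsFactors = FALSE)
  map <- c(p1 = "gA", p2 = "gA", p3 = "gB", p4 = "gB")
  res <- suppressMessages(collapse_to_genes(hits, map))
  expect_equal(res$up_genes, "gA")
  expect_equal(res$discordant_genes, "gB")
  expect_equal(res$up_probes, 3L)
  expect_equal(res$down_probes, 1L)
  empty <- collapse_to_genes(hits[0, ], map)
  expect_equal(length(empty$up_genes), 0L)
  expect_error(collapse_to_genes(hits, map[-1]), "p1")
})

test_that("median position summary locates a set against the transcriptome", {
  set.seed(61)
  mat <- matrix(rnorm(100 * 6, mean = 7), 100, 6,
                dimnames = list(sprintf("g%03d", 1:100),
                                c(paste0("WT_", 1:3), paste0("KO_", 1:3))))
  wt <- paste0("WT_", 1:3); ko <- paste0("KO_", 1:3)
  all_rows <- median_position_summary(mat, rownames(mat), wt, ko)
  expect_equal(all_rows[["median_a"]], all_rows[["transcriptome_median_a"]])
  one <- median_position_summary(mat, "g001", wt, ko)
  expect_equal(one[["median_a"]], mean(mat["g001", wt]))
  # planted: low in WT, at the transcriptome median in KO
  low_set <- sprintf("g%03d", 1:10)
  mat2 <- mat
  mat2[low_set, wt] <- mat2[low_set, wt] - 4
  mat2[low_set, ko] <- median(rowMeans(mat2[, ko])) +
    rnorm(length(low_set) * 3, sd = 0.1)
  res <- median_position_summary(mat2, low_set, wt, ko)
  expect_lt(res[["median_a"]], res[["transcriptome_median_a"]])
  expect_lt(abs(res[["median_b"]] - res[["transcriptome_median_b"]]), 0.5)
  expect_error(median_position_summary(mat, character(0), wt, ko), "empty")
})
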