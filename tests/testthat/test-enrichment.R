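paper_gene_table <- function() {
  # reconstructs the printed summary counts as a flagged gene table:
  # 30973 genes, 270 channels, 1374 DEGs of which 31 channels
  n <- 30973; n_ch <- 270; n_deg <- 1374; n_ch_deg <- 31
  is_channel <- c(rep(TRUE, n_ch), rep(FALSE, n - n_ch))
  is_deg <- rep(FALSE, n)
  is_deg[seq_len(n_ch_deg)] <- TRUE                      # channel DEGs
  is_deg[(n_ch + 1):(n_ch + n_deg - n_ch_deg)] <- TRUE   # non-channel DEGs
  data.frame(gene_id = sprintf("g%05d", seq_len(n)),
             is_channel = is_channel,
             channel_class = ifelse(is_channel, "intrinsic", "none"),
             is_deg = is_deg)
}

test_that("contingency table partitions the gene list disjointly", {
  g <- paper_gene_table()
  tab <- build_table(g, function(x) x$is_deg, function(x) x$is_channel)
  expect_equal(c(tab$a, tab$b, tab$c, tab$d), c(31, 1343, 239, 29360))
  expect_equal(tab$a + tab$b + tab$c + tab$d, nrow(g))
  # no annotated genes
  tab0 <- build_table(g, function(x) x$is_deg, function(x) rep(FALSE, nrow(x)))
  expect_equal(c(tab0$a, tab0$c), c(0, 0))
  expect_equal(tab0$b, 1374)
  expect_error(build_table(g[0, ], function(x) x$is_deg,
                           function(x) x$is_channel), "non-empty")
})

test_that("synthetic tables match a brute-force recount", {
  g <- gen_transcriptome(synth_transcriptome_params(
    n_genes = 2000, n_channel_genes = 100, n_intrinsic = 60, seed = 3))
  tab <- build_table(g, function(x) x$is_deg, function(x) x$is_channel)
  # recount oracle: plain table() on the two flags
  tt <- table(set = g$is_deg, annot = g$is_channel)
  expect_equal(tab$a, unname(tt["TRUE", "TRUE"]))
  expect_equal(tab$b, unname(tt["TRUE", "FALSE"]))
  expect_equal(tab$c, unname(tt["FALSE", "TRUE"]))
  expect_equal(tab$d, unname(tt["FALSE", "FALSE"]))
})

test_that("fold enrichment reproduces the printed 2.79 and its conventions", {
  tab <- contingency_table(31, 1343, 239, 29360)
  expect_equal(round(fold_enrichment(tab), 2), 2.79)
  # equal proportions give exactly 1
  expect_equal(fold_enrichment(contingency_table(10, 90, 50, 450)), 1)
  # arithmetic oracle on an arbitrary table
  t2 <- contingency_table(10, 307, 174, 30482)
  expect_equal(fold_enrichment(t2), (10 / 317) / (174 / 30656))
  expect_error(fold_enrichment(contingency_table(5, 10, 0, 100)), "infinite")
})

test_that("exact test reproduces the printed P = 1.41E-6", {
  tab <- contingency_table(31, 1343, 239, 29360)
  p <- fisher_exact_two_sided(tab)
  expect_equal(signif(p, 3), 1.41e-6)
  # and agrees with the independent implementation in stats
  m <- matrix(c(31, 1343, 239, 29360), 2, byrow = TRUE)
  expect_equal(p, stats::fisher.test(m)$p.value, tolerance = 1e-10)
})

test_that("a table at its independence expectation has p = 1", {
  # margins 10/20 x 6/24: expected a = 2 is the modal table
  expect_equal(fisher_exact_two_sided(contingency_table(2, 8, 4, 16)), 1)
})

test_that("exact test matches hypergeometric enumeration on small tables", {
  # subset here; the exhaustive margin sweep runs in the acceptance suite
  set.seed(99)
  for (i in 1:200) {
    a <- sample(0:8, 1); b <- sample(0:8, 1)
    c <- sample(0:8, 1); d <- sample(0:8, 1)
    if (a + c == 0 || b + d == 0 || a + b == 0 || c + d == 0) next
    tab <- contingency_table(a, b, c, d)
    expect_equal(fisher_exact_two_sided(tab),
                 fisher_enum_oracle(a, b, c, d), tolerance = 1e-12)
  }
  # row/column swap invariance of p
  expect_equal(fisher_exact_two_sided(contingency_table(3, 9, 5, 2)),
               fisher_exact_two_sided(contingency_table(3, 5, 9, 2)),
               tolerance = 1e-12)
})

test_that("doubling convention is available and bounded by 1", {
  tab <- contingency_table(3, 9, 5, 2)
  p_min <- fisher_exact_two_sided(tab)
  p_dbl <- fisher_exact_two_sided(tab, method = "doubling")
  expect_lte(p_dbl, 1)
  expect_gte(p_dbl, p_min / 2)
})

test_that("the paired enrichment analyses run from a flagged table", {
  g <- gen_transcriptome(synth_transcriptome_params(
    n_genes = 10000, n_channel_genes = 150, n_intrinsic = 90,
    deg_odds_channels = 4, rescue_odds_intrinsic = 4, seed = 8))
  res <- run_paper_enrichments(g)
  expect_length(res, 2)
  expect_equal(res[[1]]$annotation_name, "ion channel genes")
  expect_equal(res[[2]]$set_name, "rescued DEGs")
  expect_true(all(vapply(res, function(r) r$p_two_sided >= 0 &&
                           r$p_two_sided <= 1, logical(1L))))
  # missing rescue flags: analysis 2 skipped with a warning
  expect_warning(res1 <- run_paper_enrichments(g[, 1:4]), "rescued")
  expect_length(res1, 1)
})

test_that("null transcriptomes are calibrated and planted odds recoverable", {
  # scaled-down calibration (full 500-seed run in the acceptance suite)
  ps <- vapply(1:100, function(s) {
    g <- gen_transcriptome(synth_transcriptome_params(
      n_genes = 8000, n_channel_genes = 120, n_intrinsic = 60,
      deg_odds_channels = 1, rescue_odds_intrinsic = 1, seed = s))
    fisher_exact_two_sided(
      build_table(g, function(x) x$is_deg, function(x) x$is_channel))
  }, numeric(1L))
  expect_lte(mean(ps < 0.05), 0.08)
  folds <- vapply(1:60, function(s) {
    g <- gen_transcriptome(synth_transcriptome_params(
      deg_odds_channels = 3, seed = s))
    fold_enrichment(
      build_table(g, function(x) x$is_deg, function(x) x$is_channel))
  }, numeric(1L))
  expect_gte(stats::median(folds), 2.5)
  expect_lte(stats::median(folds), 3.5)
})

test_that("gene tables round-trip through TSV", {
  g <- gen_transcriptome(synth_transcriptome_params(
    n_genes = 500, n_channel_genes = 40, n_intrinsic = 20, seed = 4))
  path <- tempfile(fileext = ".tsv")
  write_gene_table(g, path)
  back <- read_gene_table(path)
  expect_equal(back, g)
  unlink(path)
})
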