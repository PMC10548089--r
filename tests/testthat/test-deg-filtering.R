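test_that("cpm matches hand arithmetic", {
  counts <- tibble::tibble(
    gene = c("g1", "g2", "g3"),
    a = c(1, 5, 0),
    b = c(0, 999995, 0)
  )
  # library a total 6, library b total 999995
  out <- cpm(counts)
  expect_equal(out$a, c(1, 5, 0) * 1e6 / 6)
  expect_equal(out$b[3], 0)

  big <- tibble::tibble(gene = c("g1", "rest"), lib = c(5, 2e6 - 5))
  expect_equal(cpm(big)$lib[1], 2.5)  # 5 in a 2e6 library

  zero <- tibble::tibble(gene = "g1", a = 1, b = 0)
  expect_error(cpm(zero), "zero total.*b")
})

test_that("cpm_filter removes a gene iff CPM < threshold in >= min_libraries", {
  # 6 libraries, equal totals; g_edge is below threshold in exactly 1 library
  mk <- function(rows) {
    tb <- tibble::as_tibble(rows)
    tb$gene <- paste0("g", seq_len(nrow(tb)))
    dplyr::relocate(tb, "gene")
  }
  filler <- rep(1e6, 6)  # keeps totals ~1e6 so CPM ~ counts
  counts <- mk(as.data.frame(rbind(
    filler,
    c(0, 1e6, 1e6, 1e6, 1e6, 1e6),   # low in exactly 1 library -> retained
    c(0, 0, 1e6, 1e6, 1e6, 1e6),     # low in exactly 2 -> removed
    rep(0, 6)                         # all-zero -> removed
  )))
  out <- cpm_filter(counts)
  expect_equal(out$retained, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(out$n_low_libraries, c(0L, 1L, 2L, 6L))

  # brute-force check of the rule on a random toy matrix
  set.seed(11)
  toy <- mk(as.data.frame(matrix(rpois(30, 3), nrow = 5)))
  got <- cpm_filter(toy, threshold = 1, min_libraries = 2)
  cpm_mat <- as.matrix(cpm(toy)[-1])
  expect_equal(got$retained, rowSums(cpm_mat < 1) < 2, ignore_attr = TRUE)

  expect_error(cpm_filter(counts, min_libraries = 7), "exceeds")
})

test_that("cpm_filter limits: threshold 0 removes nothing, threshold -> Inf removes all", {
  u <- simulate_universe(60, zero_gene_fraction = 0.3, seed = 5)
  zero <- cpm_filter(u$counts, threshold = 0)
  expect_true(all(zero$retained))  # no CPM is ever strictly below 0
  # any strictly positive threshold removes genes at CPM 0 in >= 2 libraries
  tiny <- cpm_filter(u$counts, threshold = 1e-12)
  n_zero_libs <- rowSums(as.matrix(u$counts[-1]) == 0)
  expect_equal(tiny$retained, unname(n_zero_libs < 2))
  high <- cpm_filter(u$counts, threshold = 1e12)
  expect_false(any(high$retained))
})

test_that("benjamini_hochberg reproduces the step-up recurrence", {
  expect_equal(benjamini_hochberg(0.03), 0.03)
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04)),
               rep(0.04, 4))
  p <- c(0.001, 0.008, 0.039, 0.041, 0.042, 0.06, 0.074, 0.205)
  perm <- sample(seq_along(p))
  expect_equal(benjamini_hochberg(p)[perm], benjamini_hochberg(p[perm]))
  expect_error(benjamini_hochberg(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("call_degs applies the intersection rule with literal thresholds", {
  t1 <- tibble::tibble(gene = c("a", "b", "c", "d", "e"),
                       log2fc = c(1.2, 2, 1.5, 1, -1.2),
                       padj = c(0.04, 0.04, 0.2, 0.05, 0.01))
  t2 <- tibble::tibble(gene = c("a", "b", "c", "d", "e"),
                       log2fc = c(1.1, 2, 1.5, 1, -1.3),
                       padj = c(0.01, 0.04, 0.01, 0.049, 0.02))
  d <- call_degs(list(m1 = t1, m2 = t2))
  # a: passes both; b: passes both; c: significant in one table only;
  # d: padj == 0.05 in one table (strict <) -> excluded there;
  # e: |log2fc| == 1.2 >= 1 in both, down
  expect_setequal(d$gene, c("a", "b", "e"))
  expect_equal(d$direction[d$gene == "e"], "down")
  expect_equal(attr(d, "n_down"), 1L)

  # boundary: |log2FC| = 1 exactly is included; padj = 0.05 exactly is not
  tb <- tibble::tibble(gene = "x", log2fc = 1, padj = 0.049)
  expect_equal(call_degs(list(a = tb, b = tb))$gene, "x")
  tb2 <- tibble::tibble(gene = "x", log2fc = 1, padj = 0.05)
  expect_equal(nrow(call_degs(list(a = tb2, b = tb2))), 0L)
})

test_that("call_degs excludes discordant signs and is monotone in thresholds", {
  t1 <- tibble::tibble(gene = "a", log2fc = 2, padj = 0.01)
  t2 <- tibble::tibble(gene = "a", log2fc = -2, padj = 0.01)
  expect_message(d <- call_degs(list(m1 = t1, m2 = t2)), "discordant")
  expect_equal(nrow(d), 0L)
  expect_equal(attr(d, "discordant"), "a")

  sim <- simulate_de_tables(paste0("g", 1:300), paste0("g", 1:40), seed = 9)
  loose <- call_degs(sim$tables, fdr = 0.05, fc = 2)
  for (cfg in list(c(0.01, 2), c(0.05, 4), c(0.01, 4))) {
    tight <- call_degs(sim$tables, fdr = cfg[1], fc = cfg[2])
    expect_true(all(tight$gene %in% loose$gene))
  }
})

test_that("NA adjusted p-values become 1 with a warning; missing genes are not DEGs", {
  t1 <- tibble::tibble(gene = c("a", "b"), log2fc = c(2, 2), padj = c(0.01, NA))
  t2 <- tibble::tibble(gene = "a", log2fc = 2, padj = 0.01)
  expect_warning(d <- call_degs(list(m1 = t1, m2 = t2)), "NA")
  expect_equal(d$gene, "a")
})

test_that("linear fold-change columns are auto-detected", {
  lin <- tibble::tibble(gene = "a", fc = 4, padj = 0.01)
  lg <- tibble::tibble(gene = "a", log2fc = 2, padj = 0.01)
  expect_equal(call_degs(list(x = lin, y = lg))$mean_log2fc, 2)
})
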