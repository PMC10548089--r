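test_that("simulate_universe plants the background truth exactly", {
  u <- simulate_universe(1000, zero_gene_fraction = 0.1, seed = 2)
  f <- cpm_filter(u$counts)
  expect_equal(sum(f$retained), 900L)
  expect_identical(f$retained, u$truth$expressed)

  u0 <- simulate_universe(200, zero_gene_fraction = 0, seed = 2)
  expect_true(all(cpm_filter(u0$counts)$retained))

  expect_error(simulate_universe(2e7, n_libraries = 10), "1e8")
  expect_error(simulate_universe(100, zero_gene_fraction = 1), "\\[0, 1\\)")
})

test_that("plant_enrichment yields the exact requested overlap", {
  bg <- paste0("g", 1:20)
  pe <- plant_enrichment(bg, k = 5, n = 4, x_target = 1, seed = 1)
  expect_length(pe$target, 5L)
  expect_length(pe$degs, 4L)
  expect_equal(length(intersect(pe$target, pe$degs)), 1L)

  # property: exact overlap across random feasible specs
  set.seed(99)
  for (i in 1:25) {
    b <- sample(10:200, 1)
    k <- sample.int(b, 1)
    n <- sample.int(b, 1)
    x <- sample(max(0, n + k - b):min(n, k), 1)
    pe <- plant_enrichment(paste0("g", 1:b), k, n, x, seed = i)
    expect_equal(length(intersect(pe$target, pe$degs)), x)
  }

  # degenerate: everything equal
  pe_all <- plant_enrichment(bg, 20, 20, 20, seed = 1)
  expect_setequal(pe_all$target, bg)
  expect_setequal(pe_all$degs, bg)

  expect_error(plant_enrichment(bg, 5, 4, 5, seed = 1), "feasible range")
  expect_error(plant_enrichment(bg, 19, 19, 17, seed = 1), "feasible range")
})

test_that("simulate_marker_table draws unique markers with requested sizes", {
  bg <- paste0("g", 1:5000)
  sizes <- setNames(c(300, 500, 120, 80, 200, 150, 100, 90, 240, 160, 110, 118),
                    as.character(1:12))
  sim <- simulate_marker_table(bg, sizes, seed = 4)
  expect_equal(nrow(sim$markers), sum(sizes))
  expect_false(anyDuplicated(sim$markers$gene) > 0)
  expect_equal(as.integer(table(sim$markers$cluster)[as.character(1:12)]),
               unname(sizes))

  empty <- simulate_marker_table(bg, c(a = 0), seed = 1)
  expect_equal(nrow(empty$markers), 0L)
  expect_error(simulate_marker_table(paste0("g", 1:10), c(a = 11)),
               "only 10")
})

test_that("simulate_de_tables truth is exactly recovered by call_degs", {
  bg <- paste0("g", 1:500)
  degs <- sample(bg, 60)
  sim <- simulate_de_tables(bg, degs, prop_down = 0.8, seed = 6)
  called <- call_degs(sim$tables)
  expect_setequal(called$gene, degs)
  truth_dir <- sim$truth[sim$truth$is_deg, ]
  expect_equal(called$direction[match(truth_dir$gene, called$gene)],
               truth_dir$direction)
})

test_that("planted site classes carry their nominal expectation scores", {
  sim <- simulate_transcripts_with_sites(test_mirna(), seed = 10)
  by_class <- setNames(sim$truth$expectation, sim$truth$class)
  expect_equal(by_class[["perfect"]], 0)
  expect_equal(by_class[["gu_nonseed"]], 0.5)
  expect_equal(by_class[["seed_mismatch"]], 1.5)
  expect_equal(by_class[["bulge"]], 2.0)
  expect_equal(by_class[["decoy"]], 4.5)
  expect_equal(sim$truth$emitted, c(TRUE, TRUE, TRUE, TRUE, FALSE))
  expect_error(
    simulate_transcripts_with_sites(test_mirna(), transcript_length = 30),
    "too short")
  expect_error(
    simulate_transcripts_with_sites("ACGUACGUACGUACGU"), "19-24")
})

test_that("simulate_qpcr truth is recovered by ddct at zero noise", {
  s1 <- simulate_qpcr(effect = 1, noise_sd = 0, replicates = 3, seed = 1)
  r1 <- tidy(ddct(s1$ct_table, "reference"))
  expect_equal(r1$rq, rep(1, 6))

  s2 <- simulate_qpcr(effect = 0.25, noise_sd = 0, replicates = 3, seed = 1)
  r2 <- glance(ddct(s2$ct_table, "reference"))
  expect_equal(r2$mean_rq[r2$condition == "treatment"], 0.25)

  expect_error(simulate_qpcr(effect = 0.5, replicates = 1), ">= 2")
  expect_error(simulate_qpcr(effect = -1), "effect")
})

test_that("noisy qPCR recovery is unbiased within Monte-Carlo tolerance", {
  rec <- vapply(1:60, function(i) {
    s <- simulate_qpcr(effect = 0.25, noise_sd = 0.3, replicates = 3,
                       seed = 4000 + i)
    g <- glance(ddct(s$ct_table, "reference"))
    g$mean_rq[g$condition == "treatment"]
  }, numeric(1))
  expect_lt(abs(mean(rec) - 0.25) / 0.25, 0.15)
})
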