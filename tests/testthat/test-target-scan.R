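test_that("score_duplex reproduces the penalty table by hand", {
  mir <- test_mirna()                      # 21 nt
  perfect <- comp_rna_row <- chartr("ACGU", "UGCA", mir)
  sc <- score_duplex(mir, perfect)
  expect_equal(sc$expectation, 0)
  expect_equal(sc$seed_mismatches, 0L)

  # single G:U at miRNA position 15 (outside seed): mir[15] = G, target U
  tc <- strsplit(perfect, "")[[1]]
  expect_equal(substr(mir, 15, 15), "G")
  tc[15] <- "U"
  sc_gu <- score_duplex(mir, paste(tc, collapse = ""))
  expect_equal(sc_gu$expectation, 0.5)
  expect_equal(sc_gu$seed_mismatches, 0L)

  # single non-GU mismatch at position 5 (in seed): 1 * 1.5
  tc <- strsplit(perfect, "")[[1]]
  mc5 <- substr(mir, 5, 5)
  tc[5] <- setdiff(c("A", "C", "G", "U"),
                   c(chartr("ACGU", "UGCA", mc5),
                     c(G = "U", U = "G")[mc5]))[1]
  sc_mm <- score_duplex(mir, paste(tc, collapse = ""))
  expect_equal(sc_mm$expectation, 1.5)
  expect_equal(sc_mm$seed_mismatches, 1L)

  # two seed mismatches: 3.0 (scored, but above the emission boundary)
  tc[7] <- setdiff(c("A", "C", "G", "U"),
                   c(chartr("ACGU", "UGCA", substr(mir, 7, 7)),
                     c(G = "U", U = "G")[substr(mir, 7, 7)]))[1]
  expect_equal(score_duplex(mir, paste(tc, collapse = ""))$expectation, 3.0)

  # one-nt target bulge outside the seed: gap_open = 2.0 exactly
  mrow <- paste0(substr(mir, 1, 15), "-", substr(mir, 16, 21))
  trow <- paste0(substr(perfect, 1, 15), "A", substr(perfect, 16, 21))
  sc_gap <- score_duplex(mrow, trow)
  expect_equal(sc_gap$expectation, 2.0)

  # gap run: open + extend = 2.5
  mrow2 <- paste0(substr(mir, 1, 15), "--", substr(mir, 16, 21))
  trow2 <- paste0(substr(perfect, 1, 15), "AA", substr(perfect, 16, 21))
  expect_equal(score_duplex(mrow2, trow2)$expectation, 2.5)

  expect_error(score_duplex("A-G", "U-C"), "gap in both")
  expect_error(score_duplex("AXG", "UGC"), "Illegal character")
})

test_that("adding a mismatch never decreases the expectation", {
  mir <- test_mirna()
  tc0 <- strsplit(chartr("ACGU", "UGCA", mir), "")[[1]]
  base0 <- score_duplex(mir, paste(tc0, collapse = ""))$expectation
  for (p in c(1, 3, 8, 13, 14, 21)) {
    for (b in setdiff(c("A", "C", "G", "U"), tc0[p])) {
      tc <- tc0
      tc[p] <- b
      expect_gte(score_duplex(mir, paste(tc, collapse = ""))$expectation,
                 base0)
    }
  }
})

test_that("an embedded perfect complement is found once with expectation 0", {
  mir <- test_mirna()
  set.seed(31)
  sim <- simulate_transcripts_with_sites(mir,
                                         site_classes = c(perfect = 1),
                                         transcript_length = 150, seed = 31)
  hits <- scan_targets(c(mir = mir), sim$transcripts)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$expectation, 0)
  expect_equal(hits$start, sim$truth$start)
  expect_equal(hits$end, sim$truth$end)
  # coordinates really address the site: the transcript substring at
  # [start, end] must read as the reverse of the degapped target row
  sub <- substr(sim$transcripts$seq, hits$start, hits$end)
  expect_equal(sub, revcomp_rna(mir))
})

test_that("hit expectations re-score identically through score_duplex", {
  mir <- test_mirna()
  sim <- simulate_transcripts_with_sites(mir, seed = 17)
  hits <- scan_targets(c(mir = mir), sim$transcripts)
  for (k in seq_len(nrow(hits))) {
    rows <- strsplit(hits$alignment[k], "\n")[[1]]
    # printed rows are miRNA 3'->5' and target 5'->3'; reverse into the
    # scoring register
    rev_str <- function(s) paste(rev(strsplit(s, "")[[1]]), collapse = "")
    sc <- score_duplex(rev_str(rows[1]), rev_str(rows[3]))
    expect_equal(sc$expectation, hits$expectation[k])
    expect_equal(sc$seed_mismatches, hits$seed_mismatches[k])
  }
})

test_that("scanner optimum matches the brute-force alignment oracle on short toys", {
  mir <- test_mirna()
  set.seed(55)
  params <- scan_params()
  n_checked <- 0
  for (i in 1:30) {
    # toys: a site with a random single defect in random short flanks
    cls <- sample(c("perfect", "gu_nonseed", "seed_mismatch", "bulge"), 1)
    sim <- simulate_transcripts_with_sites(
      mir, site_classes = setNames(1L, cls),
      transcript_length = 30 + nchar(mir), seed = 1000 + i)
    tx <- sim$transcripts$seq[1]
    oracle <- brute_force_min_expectation(mir, tx, params)
    hits <- scan_targets(c(m = mir), c(t = tx), params)
    expect_gt(nrow(hits), 0)
    best <- min(hits$expectation)
    if (max(hits$gaps) <= 1) {
      expect_equal(best, oracle)
      n_checked <- n_checked + 1
    } else {
      expect_lte(best, oracle)
    }
  }
  expect_gt(n_checked, 20)
})

test_that("a site at expectation exactly max_expectation is emitted", {
  mir <- test_mirna()
  sim <- simulate_transcripts_with_sites(mir, site_classes = c(bulge = 1),
                                         transcript_length = 150, seed = 3)
  hits <- scan_targets(c(m = mir), sim$transcripts)
  expect_equal(hits$expectation, 2.0)
  expect_equal(hits$gaps, 1L)
})

test_that("hit order and content are deterministic across runs", {
  mir <- test_mirna()
  sim <- simulate_transcripts_with_sites(mir, seed = 77)
  h1 <- scan_targets(c(m = mir), sim$transcripts)
  h2 <- scan_targets(c(m = mir), sim$transcripts)
  expect_identical(h1, h2)
})

test_that("scanner input contracts are enforced", {
  expect_error(scan_targets(character(0), c(t = "ACGU")), "no sequences")
  expect_error(scan_targets(c(m = "ACGUACGUACGU"), c(t = "ACGU")),
               "shorter than hsp_size")
  long_mir <- test_mirna()
  expect_error(scan_targets(c(m = long_mir), c(t = "ACXGU")),
               "Illegal character")
})

test_that("best_per_transcript keeps one minimal-expectation hit per transcript", {
  mir <- test_mirna()
  sim <- simulate_transcripts_with_sites(
    mir, site_classes = c(perfect = 1, gu_nonseed = 1),
    n_transcripts = 1, transcript_length = 200, seed = 12)
  all_hits <- scan_targets(c(m = mir), sim$transcripts)
  expect_equal(nrow(all_hits), 2L)
  best <- scan_targets(c(m = mir), sim$transcripts, best_per_transcript = TRUE)
  expect_equal(nrow(best), 1L)
  expect_equal(best$expectation, 0)
})
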