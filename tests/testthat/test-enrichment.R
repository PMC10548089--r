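test_that("observed_overlap counts intersections", {
  expect_equal(observed_overlap(c("a", "b"), c("c", "d")), 0L)
  expect_equal(observed_overlap(c("a", "b"), c("a", "b", "c")), 2L)
  expect_equal(observed_overlap(character(0), c("a")), 0L)
})

test_that("hypergeometric moments and tails match hand combinatorics", {
  expect_equal(hypergeometric_mean(4, 5, 20), 1)
  expect_equal(hypergeometric_tail(1, 4, 5, 20), 1 - 1365 / 4845)
  # K = B: the whole background is the target
  expect_equal(hypergeometric_mean(7, 30, 30), 7)
  expect_equal(hypergeometric_tail(7, 7, 30, 30), 1)
  # K = 0
  expect_equal(hypergeometric_mean(7, 0, 30), 0)
  expect_equal(hypergeometric_tail(1, 7, 0, 30), 0)
  # infeasible x falls back to tail conventions
  expect_equal(hypergeometric_tail(10, 4, 5, 20), 0)
  expect_equal(hypergeometric_tail(-1, 4, 5, 20), 1)
  # log-space stability at large B
  expect_gt(hypergeometric_tail(500, 1000, 5e5, 1e6), 0)
})

test_that("the lattice-DP enumeration oracle agrees with literal combn enumeration", {
  for (cfg in list(c(6, 3, 2), c(8, 5, 4), c(10, 2, 7))) {
    expect_equal(overlap_distribution_dp(cfg[1], cfg[2], cfg[3]),
                 overlap_distribution_combn(cfg[1], cfg[2], cfg[3]))
  }
})

test_that("permutation null matches the exact overlap distribution on a small universe", {
  bg <- paste0("g", 1:20)
  pe <- plant_enrichment(bg, k = 5, n = 4, x_target = 1, seed = 3)
  res <- permutation_overlap_test(pe$degs, pe$target, bg, r = 50000, seed = 4)
  # exact enumeration over all C(20,4) = 4845 subsets
  pmf <- overlap_distribution_dp(20, 5, 4)
  expect_equal(res$hypergeometric_mean, 1.0)
  sigma <- sqrt(sum((0:4)^2 * pmf) - 1)
  expect_lt(abs(res$null_mean - 1.0), 3 * sigma / sqrt(res$r))
  emp <- tabulate(res$null_overlaps + 1L, nbins = 5) / res$r
  expect_lt(sum(abs(emp - pmf)) / 2, 0.02)  # total variation
})

test_that("p_raw, p_pseudo and the hypergeometric tail are coherent", {
  bg <- paste0("g", 1:200)
  pe <- plant_enrichment(bg, k = 40, n = 30, x_target = 12, seed = 5)
  res <- permutation_overlap_test(pe$degs, pe$target, bg, r = 5000, seed = 6)
  expect_equal(res$observed_overlap, 12L)
  expect_gte(res$p_pseudo, 1 / (res$r + 1))
  expect_lte(res$p_raw, res$p_pseudo + 1 / (res$r + 1))
  expect_lt(abs(res$p_raw - res$hypergeometric_p), 0.02)
  # monotonicity of the empirical tail in x for the same null
  tails <- vapply(0:30, function(x) mean(res$null_overlaps >= x), numeric(1))
  expect_true(all(diff(tails) <= 0))
})

test_that("degenerate targets and out-of-background queries are handled", {
  bg <- paste0("g", 1:30)
  # target = background: every overlap equals n
  res <- permutation_overlap_test(bg[1:6], bg, bg, r = 200, seed = 1)
  expect_equal(res$observed_overlap, 6L)
  expect_true(all(res$null_overlaps == 6L))
  expect_equal(res$p_raw, 1)

  expect_warning(
    res2 <- permutation_overlap_test(c(bg[1:5], "zz"), bg[1:10], bg,
                                     r = 100, seed = 1),
    "outside the background")
  expect_equal(res2$n, 5L)

  expect_error(
    permutation_overlap_test(bg[1:5], "not_here", bg, r = 10),
    "empty after intersection")
})

test_that("identical seeds give byte-identical permutation results", {
  bg <- paste0("g", 1:100)
  a <- permutation_overlap_test(bg[1:10], bg[1:30], bg, r = 500, seed = 42)
  b <- permutation_overlap_test(bg[1:10], bg[1:30], bg, r = 500, seed = 42)
  expect_identical(a$null_overlaps, b$null_overlaps)
})

test_that("tidy/glance/autoplot expose the null histogram and summary", {
  bg <- paste0("g", 1:50)
  res <- permutation_overlap_test(bg[1:8], bg[1:20], bg, r = 300, seed = 2)
  td <- tidy(res)
  expect_equal(sum(td$count), res$r)
  gl <- glance(res)
  expect_equal(gl$observed_overlap, res$observed_overlap)
  expect_s3_class(autoplot(res), "ggplot")
})
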