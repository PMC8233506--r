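test_that("plating efficiency is the co-plating colony ratio with guarded edges", {
  expect_equal(plating_efficiency(50, 100)$p_eff, 0.5)
  expect_equal(plating_efficiency(100, 100)$p_eff, 1)
  expect_error(plating_efficiency(0, 100), "uncorrectable")
  expect_error(plating_efficiency(10, 0), "integer")
  expect_warning(pe <- plating_efficiency(120, 100), "clamping")
  expect_equal(pe$p_eff, 1)
})

test_that("count correction scales by 1/p_eff and rounds ties to even", {
  expect_identical(correct_counts(c(5, 9, 0), 1), c(5L, 9L, 0L))
  expect_identical(correct_counts(c(2, 4), 0.5), c(4L, 8L))
  expect_identical(correct_counts(3, 0.4), 8L)   # 7.5 rounds to even -> 8
  expect_identical(correct_counts(1, 0.4), 2L)   # 2.5 rounds to even -> 2
  expect_error(correct_counts(c(1, 2), 0), "p_eff")
  expect_error(correct_counts(c(1, 2), 1.2), "p_eff")
})

test_that("MSS recursion equals brute-force compound-Poisson convolution", {
  for (m in c(0.3, 0.8, 2)) {
    mss <- ld_pmf(m, 20)
    brute <- brute_ld_pmf(m, 20)
    expect_lt(max(abs(log(mss) - log(brute))), 1e-6)
  }
})

test_that("the maximum-likelihood m is permutation-invariant and p0-consistent", {
  counts <- c(0, 0, 0, 0, 0, 1, 1, 2, 4, 9)
  e1 <- estimate_rate(fluctuation_assay(counts, 1e7), ci = FALSE)
  e2 <- estimate_rate(fluctuation_assay(rev(counts), 1e7), ci = FALSE)
  expect_equal(e1$m_hat, e2$m_hat, tolerance = 1e-9)
  # half the cultures mutant-free: p0 method gives m ~= ln 2
  expect_lt(abs(e1$m_hat / log(2) - 1), 0.15)
  # adding a culture at the (rounded) median count moves m_hat only modestly
  med <- as.integer(round(stats::median(counts)))
  e3 <- estimate_rate(fluctuation_assay(c(counts, med), 1e7), ci = FALSE)
  expect_lt(abs(e3$m_hat - e1$m_hat) / e1$m_hat, 0.3)
})

test_that("an all-zero assay is a boundary estimate with an upper bound only", {
  e <- estimate_rate(fluctuation_assay(rep(0, 10), 1e7))
  expect_true(e$boundary)
  expect_equal(e$rate, 0)
  expect_equal(e$ci_low, 0)
  # upper bound: 1.92 log-lik units along exp(-n m)
  expect_equal(e$ci_high, 1.92 / 10 / 1e7, tolerance = 1e-3)
})

test_that("profile-likelihood interval brackets the estimate", {
  cts <- gen_fluctuation_counts(5e-7, 1e7, 12, seed = 3)
  e <- estimate_rate(fluctuation_assay(cts, 1e7))
  expect_lt(e$ci_low, e$rate)
  expect_gt(e$ci_high, e$rate)
  expect_equal(e$rate, e$m_hat / 1e7)
})

test_that("plating a culture fraction is handled by likelihood thinning", {
  # thinned pmf matches direct binomial thinning of the full distribution
  m <- 2; z <- 0.3
  full <- ld_pmf(m, 4000)
  direct <- vapply(0:6, function(k) {
    sum(full * stats::dbinom(k, 0:4000, z))
  }, numeric(1))
  expect_equal(epistasim:::ld_pmf_thinned(m, 6, z), direct, tolerance = 1e-8)

  # recovery when only 20% of each culture is plated
  rates <- vapply(1:40, function(i) {
    cts <- gen_fluctuation_counts(5e-7, 1e7, 10, seed = i)
    pl <- withr::with_seed(5000 + i, stats::rbinom(length(cts), cts, 0.2))
    estimate_rate(fluctuation_assay(pl, 2e6, volume_fraction = 0.2),
                  ci = FALSE)$rate
  }, numeric(1))
  expect_lt(abs(stats::median(rates) / 5e-7 - 1), 0.25)
})

test_that("the published pipeline order corrects counts before estimation", {
  cts <- gen_fluctuation_counts(5e-7, 1e7, 10, seed = 11)
  # imperfect plating: thin counts to 80%, then correct back
  observed <- withr::with_seed(99, stats::rbinom(length(cts), cts, 0.8))
  a <- fluctuation_assay(observed, 1e7)
  e_corr <- estimate_rate(a, p_eff = 0.8, ci = FALSE)
  e_manual <- estimate_rate(fluctuation_assay(correct_counts(observed, 0.8), 1e7),
                            ci = FALSE)
  expect_equal(e_corr$m_hat, e_manual$m_hat, tolerance = 1e-9)
  # the likelihood-thinning alternative gives a similar rate
  e_thin <- estimate_rate(a, p_eff = 0.8, method = "thin-likelihood", ci = FALSE)
  expect_lt(abs(e_thin$rate / e_corr$rate - 1), 0.35)
})
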