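test_that("joint HWD test is zero at equilibrium and matches the multinomial oracle", {
  # counts exactly at Hardy-Weinberg proportions
  tt <- lrt_hwd_joint(c(216, 432, 288, 64))
  expect_lt(tt$statistic, 1e-8)
  expect_equal(tt$df, 2)

  # independent oracle via dmultinom under the two hypotheses
  nk <- c(296, 332, 248, 124)
  tt <- lrt_hwd_joint(nk)
  phat <- (3 * 296 + 2 * 332 + 248) / 3000
  P0 <- c(phat^3, 3 * phat^2 * (1 - phat), 3 * phat * (1 - phat)^2,
          (1 - phat)^3)
  oracle <- 2 * (dmultinom(nk, prob = nk / 1000, log = TRUE) -
                 dmultinom(nk, prob = P0, log = TRUE))
  expect_equal(tt$statistic, oracle, tolerance = 1e-8)
  expect_gt(tt$statistic, 0)
  expect_lt(tt$p_value, 0.05)
})

test_that("single-coefficient HWD tests respect their nulls", {
  # exact equilibrium proportions: both single tests are null-true
  P <- genotype_freqs(popgen_params(0.55))
  counts <- round(P * 1e5)
  expect_lt(lrt_hwd_single(counts, "D1")$statistic, 1e-4)
  expect_lt(lrt_hwd_single(counts, "D2")$statistic, 1e-4)

  # D1 = 0 but D2 != 0: the D1 null fits exactly, the D2 null cannot
  P <- genotype_freqs(popgen_params(0.6, 0, 0.05))
  counts <- round(P * 1e5)
  s1 <- lrt_hwd_single(counts, "D1")$statistic
  s2 <- lrt_hwd_single(counts, "D2")$statistic
  expect_lt(s1, 1)
  expect_gt(s2, 100)

  # on noiseless disequilibrium input each single statistic is bounded by
  # the joint statistic (nested nulls)
  counts <- round(genotype_freqs(ref_pop()) * 1e5)
  joint <- lrt_hwd_joint(counts)$statistic
  expect_lte(lrt_hwd_single(counts, "D1")$statistic, joint + 1e-6)
  expect_lte(lrt_hwd_single(counts, "D2")$statistic, joint + 1e-6)
})

test_that("association test detects strong genetic effects", {
  sim <- simulate_sample(ref_scenario(n = 800, h2 = 0.2, seed = 5))
  tt <- suppressWarnings(lrt_association(sim$sample, seed = 5, n_starts = 2))
  expect_equal(tt$df, 7)
  expect_lt(tt$p_value, 0.01)
  expect_gt(tt$statistic, 0)
})

test_that("permutation calibration yields a valid p-value", {
  sim <- simulate_sample(ref_scenario(n = 100, seed = 31))
  tt <- suppressWarnings(
    lrt_association(sim$sample, calibration = "permutation", n_perm = 15,
                    seed = 31, n_starts = 1, max_iter = 300))
  expect_equal(tt$calibration, "permutation")
  expect_gte(tt$p_value, 1 / 16)
  expect_lte(tt$p_value, 1)
  expect_true(is.na(tt$df))
})

test_that("effect tests are nonnegative, nested, and sized by the constraint", {
  sim <- simulate_sample(ref_scenario(n = 300, seed = 17))
  t1 <- suppressWarnings(lrt_effects(sim$sample, "lambda", seed = 17,
                                     n_starts = 1))
  t4 <- suppressWarnings(lrt_effects(sim$sample,
                                     c("lambda", "i_a", "i_d", "i_dprime"),
                                     seed = 17, n_starts = 1))
  ta <- suppressWarnings(lrt_effects(sim$sample, "a", seed = 17,
                                     n_starts = 1))
  for (tt in list(t1, t4, ta)) {
    expect_gte(tt$statistic, 0)
    expect_gte(tt$p_value, 0)
    expect_lte(tt$p_value, 1)
  }
  expect_equal(t1$df, 1)
  expect_equal(t4$df, 4)
  expect_error(lrt_effects(sim$sample, "mu"))
  expect_error(lrt_effects(sim$sample, character(0)))
})

test_that("duplication-rate tests use the right reference distribution", {
  sim <- simulate_sample(ref_scenario(n = 300, seed = 23))
  ti <- suppressWarnings(lrt_duplication(sim$sample, "u", 0.5, seed = 23,
                                         n_starts = 1))
  expect_equal(ti$df, 1)
  expect_equal(ti$calibration, "chi2")
  expect_gte(ti$statistic, 0)

  tb <- suppressWarnings(lrt_duplication(sim$sample, "v", 1, seed = 23,
                                         n_starts = 1))
  expect_equal(tb$calibration, "chi2_boundary_mixture")
  # boundary p-value never exceeds the chi2 p-value halved (for stat > 0)
  if (tb$statistic > 1e-12)
    expect_equal(tb$p_value,
                 0.5 * pchisq(tb$statistic, 1, lower.tail = FALSE),
                 tolerance = 1e-12)
  else expect_equal(tb$p_value, 1)
})
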