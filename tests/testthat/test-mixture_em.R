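test_that("mixture log-likelihood matches per-subject brute force", {
  s <- phenotype_sample(c(1, 2, 4), c(0.7, -0.2, 1.4))
  rates <- duplication_rates(0.3, 0.4)
  model <- config_model(matrix(c(1, -1, 0.5, -0.5, 0.2, -0.2, 0, -2),
                               4, 2, byrow = TRUE), sigma2 = 1.7)
  # oracle: direct density summation, subject by subject
  w <- rbind(c(0.3, 0.7), c(0.3, 0.7), c(0.4, 0.6), c(0.4, 0.6))
  oracle <- 0
  for (i in 1:3) {
    k <- s$genotype[i]
    oracle <- oracle + log(
      w[k, 1] * dnorm(s$phenotype[i], model$means[k, 1], sqrt(1.7)) +
      w[k, 2] * dnorm(s$phenotype[i], model$means[k, 2], sqrt(1.7)))
  }
  expect_equal(mixture_loglik(s, rates, model), oracle, tolerance = 1e-12)

  # single-component collapse at u = v = 1
  r1 <- duplication_rates(1, 1)
  expect_equal(mixture_loglik(s, r1, model),
               sum(dnorm(s$phenotype,
                         model$means[cbind(s$genotype, 1)],
                         sqrt(1.7), log = TRUE)), tolerance = 1e-12)

  # identical component means make the weights irrelevant
  meq <- config_model(matrix(rep(c(1, 0.5, 0.2, 0), 2), 4, 2), 1.3)
  expect_equal(mixture_loglik(s, duplication_rates(0.2, 0.9), meq),
               mixture_loglik(s, duplication_rates(0.7, 0.1), meq),
               tolerance = 1e-12)

  expect_error(config_model(matrix(0, 4, 2), sigma2 = 0))
})

test_that("E-step posteriors behave at the degenerate and symmetric cases", {
  model <- config_model(matrix(c(2, -2, 1, -1, 1, -1, 0.5, -0.5),
                               4, 2, byrow = TRUE), 1)

  # degenerate prior: an AAA subject with u = 1 is surely maternal
  s1 <- phenotype_sample(1, 0.3)
  om <- e_step(s1, duplication_rates(1, 0.5), model)
  expect_equal(unname(om[1, ]), c(1, 0))

  # equal means: posterior equals the prior
  meq <- config_model(matrix(rep(c(1, 0.5, 0.2, 0), 2), 4, 2), 1)
  s2 <- phenotype_sample(c(1, 3), c(0.4, -0.9))
  om <- e_step(s2, duplication_rates(0.3, 0.4), meq)
  expect_equal(unname(om[, 1]), c(0.3, 0.4), tolerance = 1e-12)

  # midpoint + even prior: perfectly ambiguous
  s3 <- phenotype_sample(1, 0)
  om <- e_step(s3, duplication_rates(0.5, 0.5), model)
  expect_equal(unname(om[1, ]), c(0.5, 0.5), tolerance = 1e-12)

  # rows always sum to one
  set.seed(5)
  s4 <- phenotype_sample(sample(1:4, 30, TRUE), rnorm(30))
  om <- e_step(s4, duplication_rates(0.25, 0.8), model)
  expect_equal(unname(rowSums(om)), rep(1, 30), tolerance = 1e-12)
})

test_that("M-step reproduces hand-computed weighted means", {
  # six subjects, two per stratum 1/2, one each in 3/4
  s <- phenotype_sample(c(1, 1, 2, 2, 3, 4), c(2.0, 1.0, 0.5, -0.5, 0.3, -1.2))
  om <- rbind(c(0.9, 0.1), c(0.2, 0.8), c(0.6, 0.4), c(0.5, 0.5),
              c(0.3, 0.7), c(1.0, 0.0))

  up <- m_step(s, om)

  # spreadsheet-style oracle for stratum 1
  expect_equal(up$model$means[1, 1],
               (0.9 * 2.0 + 0.2 * 1.0) / (0.9 + 0.2), tolerance = 1e-12)
  expect_equal(up$model$means[1, 2],
               (0.1 * 2.0 + 0.8 * 1.0) / (0.1 + 0.8), tolerance = 1e-12)
  expect_equal(up$rates$u, (0.9 + 0.2 + 0.6 + 0.5) / 4, tolerance = 1e-12)
  expect_equal(up$rates$v, (0.3 + 1.0) / 2, tolerance = 1e-12)

  # residual-variance oracle
  ss <- 0
  for (i in 1:6) for (j in 1:2)
    ss <- ss + om[i, j] * (s$phenotype[i] - up$model$means[s$genotype[i], j])^2
  expect_equal(up$model$sigma2, ss / 6, tolerance = 1e-12)

  # hard assignment: stratum means and u = v = 1
  om_hard <- cbind(rep(1, 6), rep(0, 6))
  up <- m_step(s, om_hard)
  expect_equal(up$rates$u, 1)
  expect_equal(up$model$means[1, 1], 1.5, tolerance = 1e-12)

  # symmetric posteriors collapse both means onto the stratum mean
  om_sym <- matrix(0.5, 6, 2)
  up <- m_step(s, om_sym)
  expect_equal(up$model$means[1, 1], up$model$means[1, 2])
  expect_equal(up$model$means[1, 1], 1.5, tolerance = 1e-12)
})

test_that("EM fit recovers well-separated single-configuration data", {
  # u = v = 1: every subject is maternal, so the fit collapses to
  # per-genotype normal MLE
  set.seed(61)
  sc <- simulation_scenario(pop = ref_pop(),
                            rates = duplication_rates(1, 1),
                            effects = ref_effects(), h2 = 0.9, n = 2000,
                            seed = 61)
  sim <- simulate_sample(sc)
  fit <- suppressWarnings(fit_mixture(sim$sample, n_starts = 2, seed = 1,
                                      canonicalize = FALSE))
  # oracle: per-genotype normal MLE (the true model has one component
  # per stratum, so the mixture fit must match it, possibly with the
  # weight parameter left anywhere along the collapsed ridge)
  oracle <- 0
  for (k in 1:4) {
    stratum <- sim$sample$phenotype[sim$sample$genotype == k]
    # each stratum's fitted mean (prior-weighted over configurations)
    # reproduces the stratum sample mean
    wk <- if (k <= 2) fit$rates$u else fit$rates$v
    expect_equal(wk * fit$model$means[k, 1] +
                   (1 - wk) * fit$model$means[k, 2],
                 mean(stratum), tolerance = 0.02)
  }
  ll_oracle <- 0
  for (k in 1:4) {
    stratum <- sim$sample$phenotype[sim$sample$genotype == k]
    s2k <- mean((stratum - mean(stratum))^2)
    ll_oracle <- ll_oracle + sum(dnorm(stratum, mean(stratum),
                                       sqrt(s2k), log = TRUE))
  }
  # shared-variance mixture with 11 parameters cannot do much better or
  # worse than the 8-parameter per-stratum normal MLE on one-component
  # data
  expect_gt(fit$loglik, ll_oracle - 10)
  expect_lt(fit$loglik, ll_oracle + 10)
})

test_that("EM trace is monotone and constrained fits never win", {
  set.seed(71)
  for (r in 1:4) {
    sim <- simulate_sample(ref_scenario(n = 300, seed = 700 + r))
    fit <- suppressWarnings(fit_mixture(sim$sample, n_starts = 2, seed = r))
    expect_true(all(diff(fit$trace) >= -1e-8 * (1 + abs(fit$loglik))))

    for (cons in list("lambda", c("a", "d"), c("lambda", "i_a", "i_d",
                                               "i_dprime"))) {
      nul <- suppressWarnings(
        fit_mixture(sim$sample, fix_effects = cons, n_starts = 2, seed = r,
                    init_means = list(fit$model$means)))
      expect_true(all(diff(nul$trace) >= -1e-8 * (1 + abs(nul$loglik))))
      expect_lte(nul$loglik, fit$loglik + 1e-6 * (1 + abs(fit$loglik)))
      expect_equal(unname(unclass(nul$effects)[cons]),
                   rep(0, length(cons)), tolerance = 1e-10)
    }
  }
})

test_that("unconstrained fits are reported in the canonical labeling", {
  set.seed(81)
  sim <- simulate_sample(ref_scenario(n = 500, seed = 81))
  fit <- suppressWarnings(fit_mixture(sim$sample, n_starts = 2, seed = 2))
  expect_lte(fit$rates$u + fit$rates$v, 1 + 1e-9)
})

test_that("an empty genotype stratum leaves the effects undefined", {
  set.seed(91)
  s <- phenotype_sample(sample(1:3, 120, TRUE), rnorm(120))
  expect_warning(fit <- fit_mixture(s, n_starts = 1), "empty genotype stratum")
  expect_true(all(is.na(fit$effects)))
  expect_true(is.finite(fit$loglik))
})

test_that("constant phenotypes are rejected", {
  s <- phenotype_sample(c(1, 2, 3, 4), rep(1.5, 4))
  expect_error(fit_mixture(s), "constant")
})
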