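test_that("effects and means are exact mutual inverses", {
  # frozen worked example: reference effect vector -> cell means
  m <- effects_to_means(ref_effects())
  expect_equal(as.vector(t(m)),
               c(1.7, -0.1, 1.5, -0.5, 1.2, -0.4, -0.3, -1.3))

  # the closed-form inverse agrees with solving the linear system
  e_solve <- solve(effect_design_matrix(), as.vector(t(m)))
  expect_equal(unname(unclass(means_to_effects(m))), unname(e_solve),
               tolerance = 1e-12)

  # identity case: only an overall mean
  expect_true(all(effects_to_means(genetic_effects(mu = 3.25)) == 3.25))
  e0 <- means_to_effects(matrix(5, 4, 2))
  expect_equal(e0[["mu"]], 5)
  expect_equal(unname(unclass(e0)[-1]), rep(0, 7))

  # round trips at machine precision for arbitrary vectors
  set.seed(101)
  for (i in 1:25) {
    x <- rnorm(8, sd = 3)
    eff <- do.call(genetic_effects, as.list(x))
    expect_equal(unclass(means_to_effects(effects_to_means(eff))),
                 unclass(eff), tolerance = 1e-13)
    m <- matrix(rnorm(8, sd = 5), 4, 2)
    expect_equal(unname(effects_to_means(means_to_effects(m))),
                 unname(m), tolerance = 1e-13)
  }
})

test_that("configuration weights follow the duplication rates", {
  w <- configuration_weights(duplication_rates(0.3, 0.4))
  expect_equal(unname(w["AAA", ]), c(0.3, 0.7))
  expect_equal(unname(w["AAa", ]), c(0.3, 0.7))
  expect_equal(unname(w["aaa", ]), c(0.4, 0.6))

  expect_true(all(configuration_weights(duplication_rates(1, 1))[, 1] == 1))
  expect_true(all(configuration_weights(duplication_rates(0.5, 0.5)) == 0.5))

  set.seed(7)
  for (i in 1:10) {
    w <- configuration_weights(duplication_rates(runif(1), runif(1)))
    expect_equal(unname(rowSums(w)), rep(1, 4))
  }
})

test_that("genetic variance matches brute-force cell enumeration", {
  pop <- ref_pop(); rates <- ref_rates()
  means <- effects_to_means(ref_effects())

  # independent oracle: loop over the eight cells explicitly
  P <- genotype_freqs(pop)
  uv <- c(rates$u, rates$v)
  acc1 <- 0; acc2 <- 0
  for (k in 1:4) for (j in 1:2) {
    pij <- if (j == 1) uv[(k > 2) + 1] else 1 - uv[(k > 2) + 1]
    wkj <- P[[k]] * pij
    acc1 <- acc1 + wkj * means[k, j]
    acc2 <- acc2 + wkj * means[k, j]^2
  }
  expect_equal(genetic_variance(pop, rates, means), acc2 - acc1^2,
               tolerance = 1e-12)

  # constant means have zero variance; translation invariance;
  # quadratic scaling
  expect_equal(genetic_variance(pop, rates, matrix(2.5, 4, 2)), 0)
  v0 <- genetic_variance(pop, rates, means)
  expect_equal(genetic_variance(pop, rates, means + 11.3), v0,
               tolerance = 1e-9)
  expect_equal(genetic_variance(pop, rates, 3 * means), 9 * v0,
               tolerance = 1e-9)

  # two equiprobable cells at +/-1, all other cells carry no weight
  m2 <- matrix(0, 4, 2); m2[1, ] <- c(1, -1)
  expect_equal(genetic_variance(popgen_params(1, 0, 0),
                                duplication_rates(0.5, 0.5), m2), 1)
})

test_that("genotype coding helpers validate their inputs", {
  expect_equal(copies_A(1:4), c(3L, 2L, 1L, 0L))
  expect_error(copies_A(5))
  expect_error(duplication_rates(-0.1, 0.5))
  expect_error(genetic_effects(mu = NA_real_))
})
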