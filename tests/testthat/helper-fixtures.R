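# Shared fixtures for the test suite. The reference scenario is the
# generating model used throughout the Monte-Carlo experiments.

ref_effects <- function() {
  genetic_effects(mu = 0, a = 0.8, d = 0.5, d_prime = 0.4, lambda = 0.5,
                  i_a = 0.4, i_d = 0.5, i_dprime = 0.3)
}

ref_pop <- function() popgen_params(0.6, 0.08, 0.06)

ref_rates <- function() duplication_rates(0.3, 0.4)

ref_scenario <- function(n = 400, h2 = 0.2, seed = NULL) {
  simulation_scenario(pop = ref_pop(), rates = ref_rates(),
                      effects = ref_effects(), h2 = h2, n = n, seed = seed)
}

# draw a random valid (p, D1, D2) triple by rejection
random_popgen <- function() {
  repeat {
    p <- runif(1, 0.1, 0.9)
    D1 <- runif(1, -0.05, 0.1)
    D2 <- runif(1, -0.05, 0.1)
    x <- tryCatch(popgen_params(p, D1, D2), error = function(e) NULL)
    if (!is.null(x)) return(x)
  }
}
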