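# Seeded simulator for the generating model: multinomial triploid
# genotypes from (p, D1, D2), Bernoulli parent-of-origin configurations
# from (u, v), Gaussian phenotypes around the configuration means with
# residual variance set by a target heritability.

#' Simulation scenario
#'
#' Bundles the generating parameters of one simulated cancer population.
#' The defaults are the reference study conditions used throughout the
#' package's Monte-Carlo experiments: allele frequency 0.6 with
#' disequilibria D1 = 0.08 and D2 = 0.06, parental duplication rates
#' u = 0.3 and v = 0.4, genetic effects
#' (a, d, d', lambda, I_a, I_d, I_d') = (0.8, 0.5, 0.4, 0.5, 0.4, 0.5,
#' 0.3) around an overall mean of zero, heritability 0.2, and 400
#' subjects.
#'
#' @param pop a [popgen_params()] object.
#' @param rates a [duplication_rates()] object.
#' @param effects a [genetic_effects()] vector.
#' @param h2 broad-sense heritability in (0, 1): the fraction of total
#'   phenotypic variance contributed by the configuration means.
#' @param n number of subjects.
#' @param seed optional integer seed.
#' @return An object of class `"simulation_scenario"`.
#' @export
simulation_scenario <- function(pop = popgen_params(0.6, 0.08, 0.06),
                                rates = duplication_rates(0.3, 0.4),
                                effects = genetic_effects(
                                  mu = 0, a = 0.8, d = 0.5, d_prime = 0.4,
                                  lambda = 0.5, i_a = 0.4, i_d = 0.5,
                                  i_dprime = 0.3),
                                h2 = 0.2, n = 400, seed = NULL) {
  stopifnot(inherits(pop, "popgen_params"),
            inherits(rates, "duplication_rates"),
            length(h2) == 1, h2 > 0, h2 < 1, n >= 1)
  structure(list(pop = pop, rates = rates, effects = effects,
                 h2 = h2, n = as.integer(n), seed = seed),
            class = "simulation_scenario")
}

#' Simulate a triploid genotype/phenotype sample
#'
#' Genotypes are multinomial with probabilities [genotype_freqs()];
#' conditional on genotype, the configuration is maternal with
#' probability `u` (AAA, AAa) or `v` (Aaa, aaa); the phenotype is the
#' configuration mean plus Gaussian noise with variance
#' `genetic_variance * (1 - h2) / h2`, so the configuration means explain
#' a fraction `h2` of the total variance in expectation.
#'
#' @param scenario a [simulation_scenario()].
#' @return An object of class `"simulated_sample"`: components `sample`
#'   (a [phenotype_sample()]), `latent` (true configuration index per
#'   subject), `sigma2_used`, and `scenario`.
#' @export
simulate_sample <- function(scenario) {
  stopifnot(inherits(scenario, "simulation_scenario"))
  if (!is.null(scenario$seed)) set.seed(scenario$seed)
  n <- scenario$n
  P <- genotype_freqs(scenario$pop)
  means <- effects_to_means(scenario$effects)
  vg <- genetic_variance(scenario$pop, scenario$rates, means)
  if (vg <= 0)
    stop("zero genetic variance: heritability scaling is undefined ",
         "(all configuration means coincide)")
  sigma2 <- vg * (1 - scenario$h2) / scenario$h2
  k <- sample.int(4, n, replace = TRUE, prob = P)
  p_maternal <- ifelse(k <= 2, scenario$rates$u, scenario$rates$v)
  j <- ifelse(runif(n) < p_maternal, 1L, 2L)
  y <- means[cbind(k, j)] + rnorm(n, 0, sqrt(sigma2))
  structure(list(sample = phenotype_sample(k, y), latent = j,
                 sigma2_used = sigma2, scenario = scenario),
            class = "simulated_sample")
}

#' Simulate under a null generating model
#'
#' `"no_effect"` sets all eight configuration means to the overall mean;
#' `"no_imprinting"` zeroes the imprinting effect and its three
#' interactions (so the two configurations of every genotype share a
#' mean). In both cases the residual variance is anchored to the
#' alternative scenario's value, so null and power runs are directly
#' comparable.
#'
#' @param scenario a [simulation_scenario()] (the alternative whose noise
#'   level is retained).
#' @param null `"no_effect"` or `"no_imprinting"`.
#' @return An object of class `"simulated_sample"`.
#' @export
simulate_null_sample <- function(scenario,
                                 null = c("no_effect", "no_imprinting")) {
  null <- match.arg(null)
  stopifnot(inherits(scenario, "simulation_scenario"))
  means_alt <- effects_to_means(scenario$effects)
  vg_alt <- genetic_variance(scenario$pop, scenario$rates, means_alt)
  if (vg_alt <= 0)
    stop("zero genetic variance in the anchoring alternative scenario")
  sigma2 <- vg_alt * (1 - scenario$h2) / scenario$h2

  eff0 <- scenario$effects
  if (null == "no_effect") {
    eff0[setdiff(EFFECT_NAMES, "mu")] <- 0
  } else {
    eff0[c("lambda", "i_a", "i_d", "i_dprime")] <- 0
  }
  means0 <- effects_to_means(eff0)

  if (!is.null(scenario$seed)) set.seed(scenario$seed)
  n <- scenario$n
  P <- genotype_freqs(scenario$pop)
  k <- sample.int(4, n, replace = TRUE, prob = P)
  p_maternal <- ifelse(k <= 2, scenario$rates$u, scenario$rates$v)
  j <- ifelse(runif(n) < p_maternal, 1L, 2L)
  y <- means0[cbind(k, j)] + rnorm(n, 0, sqrt(sigma2))
  sc0 <- scenario; sc0$effects <- eff0
  structure(list(sample = phenotype_sample(k, y), latent = j,
                 sigma2_used = sigma2, scenario = sc0, null = null),
            class = "simulated_sample")
}
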