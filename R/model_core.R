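# Genotype / configuration coding and the effect <-> mean linear system.
#
# Triploid genotype classes are indexed k = 1..4 for AAA, AAa, Aaa, aaa
# (so the number of copies of allele A is 4 - k). Each genotype hides two
# parent-of-origin configurations j = 1 (duplicated allele is maternal)
# and j = 2 (paternal). The 4 x 2 table of configuration means mu_kj is an
# invertible linear transform of eight genetic effects.

GENOTYPE_LABELS <- c("AAA", "AAa", "Aaa", "aaa")
CONFIG_LABELS <- c("M", "P")
EFFECT_NAMES <- c("mu", "a", "d", "d_prime", "lambda", "i_a", "i_d", "i_dprime")

cell_labels <- function() {
  as.vector(t(outer(GENOTYPE_LABELS, CONFIG_LABELS, paste, sep = ".")))
}

#' Number of copies of allele A in a triploid genotype class
#'
#' @param k integer genotype class in `1:4` (AAA, AAa, Aaa, aaa).
#' @return Integer vector of A-allele copy numbers (3, 2, 1, 0).
#' @export
copies_A <- function(k) {
  stopifnot(all(k %in% 1:4))
  4L - as.integer(k)
}

#' Parent-specific chromosome duplication rates
#'
#' `u` is the probability that the duplicated copy of allele A is of
#' maternal origin; `v` is the same probability for allele a. These are the
#' mixture weights of the maternal configuration within each genotype
#' stratum.
#'
#' @param u,v probabilities in `[0, 1]`.
#' @return An object of class `"duplication_rates"`.
#' @export
duplication_rates <- function(u, v) {
  stopifnot(length(u) == 1, length(v) == 1, is.finite(u), is.finite(v),
            u >= 0, u <= 1, v >= 0, v <= 1)
  structure(list(u = u, v = v), class = "duplication_rates")
}

#' @export
print.duplication_rates <- function(x, ...) {
  cat(sprintf("Parental duplication rates: u = %.4f (allele A maternal), v = %.4f (allele a maternal)\n",
              x$u, x$v))
  invisible(x)
}

#' Quantitative-genetic effect vector
#'
#' The eight-parameter decomposition of the configuration means: overall
#' mean `mu`, additive effect `a`, dominance of AA over a (`d`), dominance
#' of A over aa (`d_prime`), imprinting effect `lambda`, and the
#' interactions of the imprinting effect with the additive and the two
#' dominance effects (`i_a`, `i_d`, `i_dprime`). All in phenotype units.
#'
#' @param mu,a,d,d_prime,lambda,i_a,i_d,i_dprime finite numeric scalars.
#' @return A named numeric vector of class `"genetic_effects"`.
#' @export
genetic_effects <- function(mu = 0, a = 0, d = 0, d_prime = 0, lambda = 0,
                            i_a = 0, i_d = 0, i_dprime = 0) {
  x <- c(mu = mu, a = a, d = d, d_prime = d_prime, lambda = lambda,
         i_a = i_a, i_d = i_d, i_dprime = i_dprime)
  stopifnot(all(is.finite(x)))
  structure(x, class = "genetic_effects")
}

#' Design matrix mapping genetic effects to configuration means
#'
#' Rows are the eight (genotype, configuration) cells in the order
#' AAA.M, AAA.P, AAa.M, AAa.P, Aaa.M, Aaa.P, aaa.M, aaa.P; columns are the
#' eight effects. The parameterization carries mu, a, d, d_prime on the
#' within-genotype pair sums, lambda plus one interaction on each
#' parent-of-origin half-difference, and identifies lambda alone from the
#' aaa half-difference, making the matrix full rank.
#'
#' @return An 8 x 8 numeric matrix.
#' @export
effect_design_matrix <- function() {
  X <- rbind(
    c(1,  1, 0, 0,  1,  1,  0,  0),   # AAA maternal
    c(1,  1, 0, 0, -1, -1,  0,  0),   # AAA paternal
    c(1,  0, 1, 0,  1,  0,  1,  0),   # AAa maternal
    c(1,  0, 1, 0, -1,  0, -1,  0),   # AAa paternal
    c(1,  0, 0, 1,  1,  0,  0,  1),   # Aaa maternal
    c(1,  0, 0, 1, -1,  0,  0, -1),   # Aaa paternal
    c(1, -1, 0, 0,  1,  0,  0,  0),   # aaa maternal
    c(1, -1, 0, 0, -1,  0,  0,  0))   # aaa paternal
  dimnames(X) <- list(cell_labels(), EFFECT_NAMES)
  X
}

as_mean_matrix <- function(m) {
  # accepts a 4 x 2 matrix or a length-8 vector in cell order
  if (is.matrix(m)) {
    stopifnot(nrow(m) == 4, ncol(m) == 2)
  } else {
    stopifnot(length(m) == 8)
    m <- matrix(m, nrow = 4, ncol = 2, byrow = TRUE)
  }
  dimnames(m) <- list(GENOTYPE_LABELS, CONFIG_LABELS)
  stopifnot(all(is.finite(m)))
  m
}

#' Configuration means implied by a genetic-effect vector
#'
#' @param effects a [genetic_effects()] vector (or any named length-8
#'   numeric with the same component order).
#' @return A 4 x 2 matrix of configuration means, rows AAA..aaa, columns
#'   maternal/paternal.
#' @export
effects_to_means <- function(effects) {
  stopifnot(length(effects) == 8, all(is.finite(effects)))
  as_mean_matrix(as.vector(effect_design_matrix() %*% unclass(effects)))
}

#' Genetic effects implied by a table of configuration means
#'
#' Exact inverse of [effects_to_means()], obtained by solving the linear
#' system row by row: pair means identify mu, a, d, d_prime; the aaa
#' half-difference identifies lambda; the remaining half-differences give
#' the interactions.
#'
#' @param means 4 x 2 matrix of configuration means (or length-8 vector in
#'   cell order).
#' @return A [genetic_effects()] vector.
#' @export
means_to_effects <- function(means) {
  m <- as_mean_matrix(means)
  mu <- (m[1, 1] + m[1, 2] + m[4, 1] + m[4, 2]) / 4
  a <- (m[1, 1] + m[1, 2] - m[4, 1] - m[4, 2]) / 4
  d <- (m[2, 1] + m[2, 2]) / 2 - mu
  d_prime <- (m[3, 1] + m[3, 2]) / 2 - mu
  lambda <- (m[4, 1] - m[4, 2]) / 2
  i_a <- (m[1, 1] - m[1, 2]) / 2 - lambda
  i_d <- (m[2, 1] - m[2, 2]) / 2 - lambda
  i_dprime <- (m[3, 1] - m[3, 2]) / 2 - lambda
  genetic_effects(mu, a, d, d_prime, lambda, i_a, i_d, i_dprime)
}

#' Mixture weights of the parent-of-origin configurations
#'
#' Genotypes AAA and AAa arise by duplication of allele A, so their
#' maternal-configuration weight is `u`; Aaa and aaa arise by duplication
#' of allele a, with maternal weight `v`.
#'
#' @param rates a [duplication_rates()] object.
#' @return A 4 x 2 matrix of weights; every row sums to 1.
#' @export
configuration_weights <- function(rates) {
  stopifnot(inherits(rates, "duplication_rates"))
  w <- rbind(c(rates$u, 1 - rates$u),
             c(rates$u, 1 - rates$u),
             c(rates$v, 1 - rates$v),
             c(rates$v, 1 - rates$v))
  dimnames(w) <- list(GENOTYPE_LABELS, CONFIG_LABELS)
  w
}

#' Genetic variance over the eight (genotype, configuration) cells
#'
#' Variance of the configuration mean across subjects: each cell (k, j)
#' has probability `P_k * pi_kj` and value `mu_kj`. Used to set the
#' residual variance from a target heritability when simulating.
#'
#' @param pop a [popgen_params()] object.
#' @param rates a [duplication_rates()] object.
#' @param means 4 x 2 matrix of configuration means.
#' @return Nonnegative scalar variance.
#' @export
genetic_variance <- function(pop, rates, means) {
  m <- as_mean_matrix(means)
  w <- genotype_freqs(pop) * configuration_weights(rates)
  mbar <- sum(w * m)
  max(sum(w * m^2) - mbar^2, 0)
}
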