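# Likelihood-ratio tests: Hardy-Weinberg disequilibrium (joint and
# single-coefficient), overall genotype-phenotype association, individual
# or joint genetic effects, and parent-specific duplication rates.

new_test_result <- function(name, statistic, df, p_value, calibration,
                            null_fit = NULL, alt_fit = NULL) {
  stopifnot(statistic >= -1e-6, p_value >= 0, p_value <= 1)
  structure(list(name = name, statistic = max(statistic, 0), df = df,
                 p_value = p_value, calibration = calibration,
                 null_fit = null_fit, alt_fit = alt_fit),
            class = "aneu_lrt")
}

#' @export
print.aneu_lrt <- function(x, ...) {
  cat(sprintf("Likelihood-ratio test: %s\n", x$name))
  df_txt <- if (is.na(x$df)) "" else sprintf(", df = %g", x$df)
  cat(sprintf("  LR statistic = %.4f%s, p = %.4g  [%s]\n",
              x$statistic, df_txt, x$p_value, x$calibration))
  invisible(x)
}

multinom_loglik <- function(nk, P) {
  # 0 * log 0 = 0 convention
  use <- nk > 0
  sum(nk[use] * log(pmax(P[use], 1e-300)))
}

#' Joint test of Hardy-Weinberg disequilibrium (D1 = D2 = 0)
#'
#' Compares the saturated multinomial fit of the four genotype counts with
#' the equilibrium model in which the genotype frequencies are the
#' Hardy-Weinberg cubes of the allele-counting frequency estimate. The
#' statistic is referred to a chi-square distribution with 2 degrees of
#' freedom.
#'
#' @param counts a [genotype_counts()] object or length-4 count vector.
#' @return An object of class `"aneu_lrt"`.
#' @export
lrt_hwd_joint <- function(counts) {
  counts <- as_genotype_counts(counts)
  if (counts$n == 0) stop("no observations")
  nk <- counts$counts
  ll_alt <- multinom_loglik(nk, nk / counts$n)
  pg0 <- estimate_popgen(counts)
  P0 <- genotype_freqs(popgen_params(pg0$p, 0, 0))
  ll_null <- multinom_loglik(nk, P0)
  stat <- 2 * (ll_alt - ll_null)
  new_test_result("HWD joint (D1 = D2 = 0)", stat, 2,
                  pchisq(max(stat, 0), 2, lower.tail = FALSE), "chi2",
                  null_fit = list(p = pg0$p, P = P0),
                  alt_fit = list(P = nk / counts$n))
}

#' Test of a single Hardy-Weinberg disequilibrium coefficient
#'
#' Null model fixes `D1 = 0` (equivalently `P(AAA) = p^3`) or `D2 = 0`
#' (`P(aaa) = q^3`) while profiling the remaining free parameters by
#' bounded numerical maximization of the multinomial likelihood; 1 degree
#' of freedom.
#'
#' @param counts a [genotype_counts()] object or length-4 count vector.
#' @param which `"D1"` or `"D2"`.
#' @return An object of class `"aneu_lrt"`.
#' @export
lrt_hwd_single <- function(counts, which = c("D1", "D2")) {
  which <- match.arg(which)
  counts <- as_genotype_counts(counts)
  if (counts$n == 0) stop("no observations")
  nk <- counts$counts
  ll_alt <- multinom_loglik(nk, nk / counts$n)
  pg <- estimate_popgen(counts)

  negll <- function(theta) {
    p <- theta[1]; Dfree <- theta[2]
    pars <- if (which == "D1") c(0, Dfree) else c(Dfree, 0)
    P <- tryCatch(genotype_freqs(popgen_params(p, pars[1], pars[2])),
                  error = function(e) NULL)
    if (is.null(P)) return(1e10)
    -multinom_loglik(nk, P)
  }
  init_free <- if (which == "D1") min(max(pg$D2, -pg$q^3 + 1e-6),
                                      1 - pg$q^3 - 1e-6)
               else min(max(pg$D1, -pg$p^3 + 1e-6), 1 - pg$p^3 - 1e-6)
  opt <- nlminb(c(min(max(pg$p, 1e-4), 1 - 1e-4), init_free), negll,
                lower = c(1e-6, -1), upper = c(1 - 1e-6, 1))
  if (opt$convergence != 0 && !is.finite(opt$objective))
    stop("profile optimization for the ", which, " = 0 null failed: ",
         opt$message)
  ll_null <- -opt$objective
  stat <- 2 * (ll_alt - ll_null)
  new_test_result(paste0("HWD single (", which, " = 0)"), stat, 1,
                  pchisq(max(stat, 0), 1, lower.tail = FALSE), "chi2",
                  null_fit = list(p = opt$par[1], D_free = opt$par[2]))
}

# single-normal MLE log-likelihood (the association null: all
# configuration means equal, so (u, v) drop out of the likelihood)
flat_loglik <- function(y) {
  mu <- mean(y)
  s2 <- mean((y - mu)^2)
  sum(dnorm(y, mu, sqrt(s2), log = TRUE))
}

#' Overall association test (all configuration means equal)
#'
#' Tests whether the locus is associated with the phenotype at all:
#' the null collapses all eight configuration means to a single mean
#' (under which the duplication rates drop out of the likelihood), the
#' alternative is the full mixture fit. The default chi-square reference
#' uses 7 degrees of freedom (eight means reduce to one; the duplication
#' rates are unidentified under the null, a Davies-type nonregularity, so
#' a permutation calibration is offered as well).
#'
#' @param sample a [phenotype_sample()].
#' @param calibration `"chi2"` or `"permutation"`.
#' @param n_perm number of phenotype permutations.
#' @param seed optional seed (permutations and EM starts).
#' @param ... further arguments passed to [fit_mixture()].
#' @return An object of class `"aneu_lrt"`.
#' @export
lrt_association <- function(sample, calibration = c("chi2", "permutation"),
                            n_perm = 500, seed = NULL, ...) {
  calibration <- match.arg(calibration)
  alt <- fit_mixture(sample, seed = seed, ...)
  ll_null <- flat_loglik(sample$phenotype)
  stat <- 2 * (alt$loglik - ll_null)
  if (calibration == "chi2") {
    p <- pchisq(max(stat, 0), 7, lower.tail = FALSE)
    df <- 7
  } else {
    if (!is.null(seed)) set.seed(seed)
    exceed <- 0L
    perm_args <- list(...)
    perm_args$n_starts <- 1  # one EM start per permutation keeps cost linear
    for (b in seq_len(n_perm)) {
      ys <- sample(sample$phenotype)
      sp <- phenotype_sample(sample$genotype, ys)
      ab <- do.call(fit_mixture, c(list(sample = sp), perm_args))
      stat_b <- 2 * (ab$loglik - flat_loglik(ys))
      if (stat_b >= stat) exceed <- exceed + 1L
    }
    p <- (1 + exceed) / (n_perm + 1)
    df <- NA_real_
  }
  new_test_result("overall association (mu_kj identical)", stat, df, p,
                  calibration, alt_fit = alt)
}

#' Test of one or several genetic effects
#'
#' Likelihood-ratio test of `H0:` the named effects are zero, against the
#' unconstrained mixture model. The null fit constrains the effects to
#' zero inside the EM M-step; degrees of freedom equal the number of
#' constrained effects. To keep the statistic nonnegative despite
#' possible local optima, the null fit receives an extra EM start at the
#' alternative solution projected into the constraint space (and, if the
#' statistic still comes out negative, the alternative is refitted from
#' the null solution).
#'
#' @param sample a [phenotype_sample()].
#' @param which nonempty subset of
#'   `c("a","d","d_prime","lambda","i_a","i_d","i_dprime")`.
#' @param seed optional seed for the jittered EM starts.
#' @param ... further arguments passed to [fit_mixture()].
#' @return An object of class `"aneu_lrt"`.
#' @export
lrt_effects <- function(sample, which, seed = NULL, ...) {
  stopifnot(length(which) >= 1,
            all(which %in% setdiff(EFFECT_NAMES, "mu")))
  alt <- fit_mixture(sample, seed = seed, ...)
  null <- fit_mixture(sample, fix_effects = which, seed = seed,
                      init_means = list(alt$model$means), ...)
  stat <- 2 * (alt$loglik - null$loglik)
  if (stat < -1e-6) {
    alt2 <- fit_mixture(sample, seed = seed,
                        init_means = list(null$model$means), ...)
    if (alt2$loglik > alt$loglik) alt <- alt2
    stat <- 2 * (alt$loglik - null$loglik)
  }
  df <- length(which)
  new_test_result(paste0("effects (", paste(which, collapse = ", "),
                         " = 0)"),
                  max(stat, 0), df,
                  pchisq(max(stat, 0), df, lower.tail = FALSE), "chi2",
                  null_fit = null, alt_fit = alt)
}

#' Test of a parent-specific duplication rate
#'
#' Tests `H0: u = null_value` (or `v`). An interior null value (for
#' example 0.5, no parental bias) uses the usual 1-df chi-square
#' reference; the boundary nulls 0 and 1 use the 50:50 mixture of a point
#' mass at zero and a 1-df chi-square.
#'
#' @param sample a [phenotype_sample()].
#' @param which `"u"` or `"v"`.
#' @param null_value hypothesized rate in `[0, 1]`.
#' @param seed optional seed for the jittered EM starts.
#' @param ... further arguments passed to [fit_mixture()].
#' @return An object of class `"aneu_lrt"`.
#' @export
lrt_duplication <- function(sample, which = c("u", "v"), null_value = 0.5,
                            seed = NULL, ...) {
  which <- match.arg(which)
  stopifnot(length(null_value) == 1, null_value >= 0, null_value <= 1)
  alt <- fit_mixture(sample, seed = seed, canonicalize = FALSE, ...)
  null <- fit_mixture(sample, fix_rates = setNames(null_value, which),
                      seed = seed, init_means = list(alt$model$means), ...)
  stat <- 2 * (alt$loglik - null$loglik)
  if (stat < -1e-6) {
    alt2 <- fit_mixture(sample, seed = seed, canonicalize = FALSE,
                        init_means = list(null$model$means), ...)
    if (alt2$loglik > alt$loglik) alt <- alt2
    stat <- 2 * (alt$loglik - null$loglik)
  }
  stat <- max(stat, 0)
  boundary <- null_value %in% c(0, 1)
  p <- if (boundary) {
    if (stat <= 1e-12) 1 else 0.5 * pchisq(stat, 1, lower.tail = FALSE)
  } else pchisq(stat, 1, lower.tail = FALSE)
  new_test_result(sprintf("duplication rate (%s = %g)", which, null_value),
                  stat, 1, p,
                  if (boundary) "chi2_boundary_mixture" else "chi2",
                  null_fit = null, alt_fit = alt)
}
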