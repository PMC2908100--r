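# Phenotype likelihood: a four-stratum, two-component normal mixture with
# shared residual variance. Within genotype stratum k the phenotype is
# mu_k1 (maternal duplication, prior weight u or v) or mu_k2 (paternal),
# plus N(0, sigma2) noise. EM alternates configuration posteriors with
# weighted-mean updates; constrained fits solve the posterior-weighted
# least-squares problem in effect space with the named effects fixed at 0.

#' Per-subject genotype/phenotype sample
#'
#' @param genotype integer genotype classes in `1:4`, or labels among
#'   `"AAA","AAa","Aaa","aaa"`, or A-copy counts coded as characters
#'   `"3","2","1","0"`.
#' @param phenotype finite numeric phenotype values, same length.
#' @param sample_id optional unique subject identifiers.
#' @return A data frame of class `"phenotype_sample"` with integer column
#'   `genotype` and numeric column `phenotype`.
#' @export
phenotype_sample <- function(genotype, phenotype, sample_id = NULL) {
  k <- parse_genotype(genotype)
  stopifnot(length(k) == length(phenotype), length(k) >= 1,
            all(is.finite(phenotype)))
  if (is.null(sample_id)) sample_id <- paste0("S", seq_along(k))
  stopifnot(!anyDuplicated(sample_id))
  structure(data.frame(sample_id = as.character(sample_id),
                       genotype = k, phenotype = as.numeric(phenotype),
                       stringsAsFactors = FALSE),
            class = c("phenotype_sample", "data.frame"))
}

parse_genotype <- function(genotype) {
  if (is.numeric(genotype)) {
    k <- as.integer(genotype)
    if (!all(k %in% 1:4))
      stop("numeric genotype must be a class index in 1:4")
    return(k)
  }
  g <- as.character(genotype)
  k <- match(g, GENOTYPE_LABELS)
  copies <- match(g, c("3", "2", "1", "0"))
  k[is.na(k)] <- copies[is.na(k)]
  if (anyNA(k)) {
    bad <- which(is.na(k))[1]
    stop("unknown genotype token '", g[bad], "' at row ", bad,
         "; accepted: ", paste(GENOTYPE_LABELS, collapse = ", "),
         " or A-copy counts 3/2/1/0")
  }
  k
}

#' Configuration-mean model
#'
#' The 4 x 2 table of configuration means together with the shared
#' residual variance; the component parameters of the phenotype mixture.
#'
#' @param means 4 x 2 matrix of configuration means (rows AAA..aaa,
#'   columns maternal/paternal) or length-8 vector in cell order.
#' @param sigma2 residual variance, strictly positive.
#' @return An object of class `"config_model"`.
#' @export
config_model <- function(means, sigma2) {
  stopifnot(length(sigma2) == 1, is.finite(sigma2), sigma2 > 0)
  structure(list(means = as_mean_matrix(means), sigma2 = sigma2),
            class = "config_model")
}

# per-subject component log-densities (n x 2), with prior weights folded in
component_logdens <- function(y, k, rates, model) {
  w <- configuration_weights(rates)
  s <- sqrt(model$sigma2)
  l1 <- log(w[k, 1]) + dnorm(y, model$means[k, 1], s, log = TRUE)
  l2 <- log(w[k, 2]) + dnorm(y, model$means[k, 2], s, log = TRUE)
  cbind(l1, l2)
}

#' Mixture log-likelihood of a phenotype sample
#'
#' Each subject contributes the log of a two-component normal mixture:
#' the two configuration means of its genotype stratum, weighted by the
#' duplication rates.
#'
#' @param sample a [phenotype_sample()].
#' @param rates a [duplication_rates()].
#' @param model a [config_model()].
#' @return Scalar log-likelihood.
#' @export
mixture_loglik <- function(sample, rates, model) {
  ll <- component_logdens(sample$phenotype, sample$genotype, rates, model)
  m <- pmax(ll[, 1], ll[, 2])
  # guard the -Inf/-Inf cell (both prior weights zero cannot happen: rows
  # of the weight table sum to 1)
  sum(m + log(exp(ll[, 1] - m) + exp(ll[, 2] - m)))
}

#' E-step: posterior configuration probabilities
#'
#' @inheritParams mixture_loglik
#' @return An `n x 2` matrix; row i gives the posterior probability that
#'   subject i carries the maternal / paternal configuration. Rows sum
#'   to 1. If both component densities underflow to zero the prior
#'   weights are assigned.
#' @export
e_step <- function(sample, rates, model) {
  ll <- component_logdens(sample$phenotype, sample$genotype, rates, model)
  m <- pmax(ll[, 1], ll[, 2])
  p1 <- exp(ll[, 1] - m)
  p2 <- exp(ll[, 2] - m)
  tot <- p1 + p2
  dead <- !is.finite(tot) | tot == 0
  if (any(dead)) {
    w <- configuration_weights(rates)
    p1[dead] <- w[sample$genotype[dead], 1]
    p2[dead] <- w[sample$genotype[dead], 2]
    tot[dead] <- p1[dead] + p2[dead]
  }
  om <- cbind(p1 / tot, p2 / tot)
  colnames(om) <- CONFIG_LABELS
  om
}

# posterior cell masses W[k, j] and weighted sums S[k, j]
cell_moments <- function(y, k, omega) {
  W <- rbind(rowsum_by(omega[, 1], k), rowsum_by(omega[, 2], k))
  S <- rbind(rowsum_by(omega[, 1] * y, k), rowsum_by(omega[, 2] * y, k))
  list(W = t(W), S = t(S))  # 4 x 2
}

rowsum_by <- function(x, k) {
  out <- numeric(4)
  s <- rowsum(x, k)
  out[as.integer(rownames(s))] <- s
  out
}

#' M-step: update duplication rates, configuration means, and variance
#'
#' Closed-form posterior-weighted updates: `u` is the mean maternal
#' posterior over the AAA/AAa strata, `v` over Aaa/aaa; each cell mean is
#' the posterior-weighted phenotype mean; `sigma2` is the posterior-
#' weighted mean squared residual.
#'
#' @param sample a [phenotype_sample()].
#' @param posterior an `n x 2` posterior matrix from [e_step()].
#' @param prev previous [config_model()]; cells with no posterior mass
#'   keep their previous mean.
#' @param fix_rates optional named numeric fixing `u` and/or `v`.
#' @param free_effects effect names estimated freely; the rest are held
#'   at zero through a weighted least-squares update in effect space.
#' @return A list with components `rates` and `model`.
#' @export
m_step <- function(sample, posterior, prev = NULL, fix_rates = NULL,
                   free_effects = EFFECT_NAMES) {
  y <- sample$phenotype
  k <- sample$genotype
  n <- length(y)
  mom <- cell_moments(y, k, posterior)
  W <- mom$W; S <- mom$S
  nk <- rowsum_by(rep(1, n), k)

  u <- if (!is.null(fix_rates) && "u" %in% names(fix_rates)) fix_rates[["u"]]
       else if (nk[1] + nk[2] > 0) (W[1, 1] + W[2, 1]) / (nk[1] + nk[2]) else 0.5
  v <- if (!is.null(fix_rates) && "v" %in% names(fix_rates)) fix_rates[["v"]]
       else if (nk[3] + nk[4] > 0) (W[3, 1] + W[4, 1]) / (nk[3] + nk[4]) else 0.5
  rates <- duplication_rates(min(max(u, 0), 1), min(max(v, 0), 1))

  prev_means <- if (!is.null(prev)) prev$means else matrix(0, 4, 2)
  if (identical(sort(free_effects), sort(EFFECT_NAMES))) {
    # saturated: per-cell weighted means; empty cells keep their previous
    # value (they carry no posterior mass and do not affect the fit)
    means <- ifelse(W > 1e-10, S / pmax(W, 1e-300), prev_means)
  } else {
    means <- constrained_mean_update(W, S, free_effects, prev_means)
  }
  means <- as_mean_matrix(means)

  ss <- sum(posterior[, 1] * (y - means[k, 1])^2 +
            posterior[, 2] * (y - means[k, 2])^2)
  sigma2 <- ss / n
  floor2 <- 1e-12 * max(var(y), .Machine$double.eps)
  if (sigma2 < floor2) sigma2 <- floor2
  list(rates = rates, model = config_model(means, sigma2))
}

# weighted least squares in effect space with the non-free effects fixed
# at zero; cells with (numerically) zero posterior mass are dropped
constrained_mean_update <- function(W, S, free_effects, prev_means) {
  X <- effect_design_matrix()
  free <- match(free_effects, EFFECT_NAMES)
  stopifnot(!anyNA(free))
  w <- as.vector(t(W))           # cell order AAA.M, AAA.P, ...
  s <- as.vector(t(S))
  use <- w > 1e-10
  ybar <- ifelse(use, s / pmax(w, 1e-300), 0)
  Xf <- X[use, free, drop = FALSE]
  sw <- sqrt(w[use])
  fit <- qr(sw * Xf)
  if (fit$rank < length(free))
    stop("constrained M-step is rank deficient: an effect is not ",
         "identifiable from the occupied genotype strata")
  beta <- qr.coef(fit, sw * ybar[use])
  mvec <- as.vector(X[, free, drop = FALSE] %*% beta)
  matrix(mvec, 4, 2, byrow = TRUE)
}

#' Fit the parent-of-origin phenotype mixture by EM
#'
#' Estimates duplication rates (u, v), the eight configuration means, and
#' the shared residual variance by maximum likelihood. Optional
#' constraints fix named genetic effects at zero (the M-step then solves
#' a posterior-weighted least-squares problem in effect space) and/or fix
#' a duplication rate at a given value; these supply the null fits of the
#' likelihood-ratio tests.
#'
#' Initialization sets u = v = 0.5, each stratum's two means to the
#' stratum mean plus/minus half the stratum standard deviation, and
#' sigma2 to the pooled within-stratum variance; additional starts jitter
#' the means to guard against local optima. The model is invariant to
#' globally swapping the two configuration labels (u, v, means columns);
#' unconstrained fits are reported in the canonical labeling with
#' `u + v <= 1`.
#'
#' @param sample a [phenotype_sample()].
#' @param fix_effects character vector of effect names (subset of
#'   `"a","d","d_prime","lambda","i_a","i_d","i_dprime"`) constrained to
#'   zero, or `NULL` for the unconstrained fit.
#' @param fix_rates named numeric vector fixing `u` and/or `v`, or `NULL`.
#' @param tol relative log-likelihood convergence threshold.
#' @param max_iter maximum EM iterations per start.
#' @param n_starts number of EM starts (first deterministic, rest
#'   jittered).
#' @param seed optional seed for the jittered starts.
#' @param init_means optional list of extra 4 x 2 starting mean matrices.
#' @param canonicalize swap configuration labels so that `u + v <= 1`;
#'   defaults to `TRUE` only for fully unconstrained fits.
#' @return An object of class `"mixture_fit"`: components `rates`,
#'   `model`, `effects`, `loglik`, `trace`, `converged`, `n_starts_used`,
#'   `empty_strata`.
#' @export
fit_mixture <- function(sample, fix_effects = NULL, fix_rates = NULL,
                        tol = 1e-8, max_iter = 2000, n_starts = 5,
                        seed = NULL, init_means = NULL,
                        canonicalize = is.null(fix_effects) &&
                          is.null(fix_rates)) {
  stopifnot(inherits(sample, "phenotype_sample"), n_starts >= 1)
  y <- sample$phenotype
  k <- sample$genotype
  n <- length(y)
  if (var(y) < .Machine$double.eps)
    stop("all phenotypes are (numerically) constant; sigma2 is degenerate")
  if (!is.null(fix_effects)) {
    stopifnot(all(fix_effects %in% setdiff(EFFECT_NAMES, "mu")))
    free_effects <- setdiff(EFFECT_NAMES, fix_effects)
  } else free_effects <- EFFECT_NAMES

  nk <- rowsum_by(rep(1, n), k)
  empty <- which(nk == 0)

  # deterministic moment-based start
  gm <- gs <- numeric(4)
  pooled_ss <- 0
  for (kk in 1:4) {
    yk <- y[k == kk]
    gm[kk] <- if (length(yk)) mean(yk) else mean(y)
    gs[kk] <- if (length(yk) > 1) sd(yk) else sd(y)
    if (length(yk) > 1) pooled_ss <- pooled_ss + sum((yk - mean(yk))^2)
  }
  gs[gs < 1e-8] <- max(sd(y), 1e-8)
  sigma2_0 <- max(pooled_ss / n, 1e-8 * var(y))
  base_means <- cbind(gm + 0.5 * gs, gm - 0.5 * gs)

  project <- function(m) {
    # force a starting mean table into the constraint space
    if (is.null(fix_effects)) return(as_mean_matrix(m))
    e <- means_to_effects(m)
    e[fix_effects] <- 0
    effects_to_means(e)
  }

  starts <- list(project(base_means))
  if (!is.null(init_means))
    starts <- c(starts, lapply(init_means, project))
  n_random <- max(n_starts - 1, 0)
  if (n_random > 0) {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv), add = TRUE)
      set.seed(seed)
    }
    jit_scale <- 0.25 * sqrt(sigma2_0)
    for (b in seq_len(n_random))
      starts <- c(starts, list(project(base_means +
        matrix(rnorm(8, 0, jit_scale), 4, 2))))
  }

  u0 <- if (!is.null(fix_rates) && "u" %in% names(fix_rates)) fix_rates[["u"]] else 0.5
  v0 <- if (!is.null(fix_rates) && "v" %in% names(fix_rates)) fix_rates[["v"]] else 0.5

  # precomputed quantities for the lean inner loop
  idx <- split(seq_len(n), factor(k, levels = 1:4))
  k12 <- k <= 2L
  u_fixed <- !is.null(fix_rates) && "u" %in% names(fix_rates)
  v_fixed <- !is.null(fix_rates) && "v" %in% names(fix_rates)
  saturated <- length(free_effects) == 8L
  X <- effect_design_matrix()
  free_idx <- match(free_effects, EFFECT_NAMES)
  Xfree <- X[, free_idx, drop = FALSE]
  floor2 <- 1e-12 * max(var(y), .Machine$double.eps)
  stratum_sums <- function(x) vapply(idx, function(i) sum(x[i]), 0.0)

  best <- NULL
  for (st in starts) {
    u <- u0; v <- v0
    means <- st
    s2 <- sigma2_0
    trace <- numeric(max_iter)
    ll_old <- -Inf
    converged <- FALSE
    it <- 0L
    while (it < max_iter) {
      it <- it + 1L
      # component log-densities serve both the likelihood evaluation and
      # the E-step posteriors
      pri1 <- ifelse(k12, u, v)
      s <- sqrt(s2)
      l1 <- log(pri1) + dnorm(y, means[k, 1], s, log = TRUE)
      l2 <- log(1 - pri1) + dnorm(y, means[k, 2], s, log = TRUE)
      mx <- pmax(l1, l2)
      e1 <- exp(l1 - mx); e2 <- exp(l2 - mx)
      tot <- e1 + e2
      ll <- sum(mx + log(tot))
      trace[it] <- ll
      if (is.finite(ll_old) && ll < ll_old - 1e-6 * (1 + abs(ll)))
        warning(sprintf("EM log-likelihood decreased at iteration %d (%.3g)",
                        it, ll_old - ll))
      if (is.finite(ll_old) && abs(ll - ll_old) < tol * (1 + abs(ll))) {
        converged <- TRUE
        break
      }
      ll_old <- ll
      dead <- !is.finite(tot) | tot == 0
      if (any(dead)) {
        e1[dead] <- pri1[dead]; e2[dead] <- 1 - pri1[dead]
        tot[dead] <- 1
      }
      om1 <- e1 / tot
      # M-step
      W1 <- stratum_sums(om1); W2 <- nk - W1
      S1 <- stratum_sums(om1 * y); S2 <- stratum_sums(y) - S1
      if (!u_fixed && nk[1] + nk[2] > 0)
        u <- min(max((W1[1] + W1[2]) / (nk[1] + nk[2]), 0), 1)
      if (!v_fixed && nk[3] + nk[4] > 0)
        v <- min(max((W1[3] + W1[4]) / (nk[3] + nk[4]), 0), 1)
      W <- cbind(W1, W2); S <- cbind(S1, S2)
      if (saturated) {
        means <- ifelse(W > 1e-10, S / pmax(W, 1e-300), means)
      } else {
        means <- constrained_mean_update(W, S, free_effects, means)
      }
      s2 <- max(sum(om1 * (y - means[k, 1])^2 +
                      (1 - om1) * (y - means[k, 2])^2) / n, floor2)
    }
    cand <- list(rates = duplication_rates(u, v),
                 model = config_model(as_mean_matrix(means), s2),
                 trace = trace[seq_len(it)], converged = converged)
    # on convergence the loop breaks before the M-step, so ll matches the
    # returned parameters; otherwise the extra M-step requires a fresh
    # evaluation
    cand$loglik <- if (converged) ll else
      mixture_loglik(sample, cand$rates, cand$model)
    if (is.null(best) || cand$loglik > best$loglik) best <- cand
  }

  if (canonicalize && best$rates$u + best$rates$v > 1) {
    best$rates <- duplication_rates(1 - best$rates$u, 1 - best$rates$v)
    best$model$means <- best$model$means[, 2:1]
    colnames(best$model$means) <- CONFIG_LABELS
  }

  effects <- means_to_effects(best$model$means)
  if (length(empty)) {
    warning("empty genotype stratum (", paste(GENOTYPE_LABELS[empty],
            collapse = ", "), "): genetic effects are not identifiable")
    effects[] <- NA_real_
  }
  if (!best$converged)
    warning("EM did not converge within ", max_iter,
            " iterations; best iterate returned")

  structure(list(rates = best$rates, model = best$model, effects = effects,
                 loglik = best$loglik, trace = best$trace,
                 converged = best$converged, n_starts_used = length(starts),
                 empty_strata = empty, n = n,
                 fix_effects = fix_effects, fix_rates = fix_rates),
            class = "mixture_fit")
}

#' @export
print.mixture_fit <- function(x, digits = 4, ...) {
  cat("Parent-of-origin mixture fit (EM)\n")
  cat(sprintf("  n = %d subjects, log-likelihood = %.*f, converged: %s\n",
              x$n, digits, x$loglik, x$converged))
  cat(sprintf("  duplication rates: u = %.*f, v = %.*f\n",
              digits, x$rates$u, digits, x$rates$v))
  cat(sprintf("  residual variance: sigma2 = %.*f\n", digits, x$model$sigma2))
  cat("  configuration means:\n")
  print(round(x$model$means, digits))
  cat("  genetic effects:\n")
  print(round(unclass(x$effects), digits))
  if (!is.null(x$fix_effects))
    cat("  constrained to zero:", paste(x$fix_effects, collapse = ", "), "\n")
  if (!is.null(x$fix_rates))
    cat("  fixed rates:", paste(names(x$fix_rates), "=", x$fix_rates,
                                collapse = ", "), "\n")
  invisible(x)
}
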