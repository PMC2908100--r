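# Monte-Carlo study harness: parameter-recovery grids over sample size
# and heritability, plus power / type-I-error runs for the
# likelihood-ratio tests.

#' Monte-Carlo study grid
#'
#' @param sample_sizes sample sizes per cell.
#' @param heritabilities heritabilities per cell.
#' @param n_replicates replicates per cell.
#' @param alpha test level for power runs.
#' @param master_seed integer; per-replicate seeds are derived from it.
#' @param scenario a [simulation_scenario()] supplying all parameters
#'   except `n`, `h2` and `seed`.
#' @param fit_control list of arguments passed on to [fit_mixture()].
#'   The study default uses the single deterministic moment-based EM
#'   start (null fits inside the tests are additionally warm-started
#'   from the projected alternative), which keeps replicate cost low;
#'   pass `n_starts = 5` to reproduce the interactive default.
#' @return An object of class `"study_grid"`.
#' @export
study_grid <- function(sample_sizes = c(400, 800, 2000),
                       heritabilities = c(0.05, 0.1, 0.2),
                       n_replicates = 200, alpha = 0.05,
                       master_seed = 1,
                       scenario = simulation_scenario(),
                       fit_control = list(n_starts = 1, tol = 1e-8,
                                          max_iter = 2000)) {
  stopifnot(n_replicates >= 1, alpha > 0, alpha < 1,
            inherits(scenario, "simulation_scenario"))
  structure(list(sample_sizes = sample_sizes,
                 heritabilities = heritabilities,
                 n_replicates = n_replicates, alpha = alpha,
                 master_seed = as.integer(master_seed),
                 scenario = scenario, fit_control = fit_control),
            class = "study_grid")
}

#' Derive a replicate-level seed from a master seed
#'
#' Deterministic, collision-resistant mapping kept below 2^31 so each
#' replicate of each grid cell has its own reproducible stream.
#'
#' @param master_seed integer master seed.
#' @param cell integer cell index.
#' @param replicate integer replicate index.
#' @return An integer seed.
#' @export
derive_seed <- function(master_seed, cell, replicate) {
  as.integer((as.numeric(master_seed) * 7919 + cell * 104729 +
                replicate * 13) %% 2147483629)
}

cell_table <- function(grid) {
  expand.grid(n = grid$sample_sizes, h2 = grid$heritabilities,
              KEEP.OUT.ATTRS = FALSE)
}

replicate_scenario <- function(grid, n, h2, seed) {
  sc <- grid$scenario
  sc$n <- as.integer(n)
  sc$h2 <- h2
  sc$seed <- seed
  sc
}

fit_with_control <- function(sample, grid, ...) {
  do.call(fit_mixture, c(list(sample = sample), grid$fit_control,
                         list(...)))
}

#' Parameter-recovery study
#'
#' For every (sample size, heritability) cell, simulates `n_replicates`
#' datasets from the grid's scenario, estimates the population-genetic
#' parameters from the genotype counts and the duplication rates plus
#' genetic effects from the mixture EM, and tabulates per-cell means,
#' standard deviations across replicates, and standard errors of the
#' mean. Replicates whose fit fails are excluded and counted.
#'
#' @param grid a [study_grid()].
#' @param verbose print per-cell progress.
#' @return An object of class `"aneu_study"`: `summary` (one row per
#'   cell x parameter with mean/sd/se), `raw` (replicate-level
#'   estimates), `excluded` (failures per cell).
#' @export
run_recovery_study <- function(grid, verbose = FALSE) {
  stopifnot(inherits(grid, "study_grid"))
  cells <- cell_table(grid)
  par_names <- c("p", "u", "v", "a", "d", "d_prime", "lambda",
                 "i_a", "i_d", "i_dprime")
  raw <- list()
  summ <- list()
  excluded <- integer(nrow(cells))
  for (ci in seq_len(nrow(cells))) {
    n <- cells$n[ci]; h2 <- cells$h2[ci]
    est <- matrix(NA_real_, grid$n_replicates, length(par_names),
                  dimnames = list(NULL, par_names))
    for (r in seq_len(grid$n_replicates)) {
      seed <- derive_seed(grid$master_seed, ci, r)
      sc <- replicate_scenario(grid, n, h2, seed)
      res <- tryCatch(suppressWarnings({
        sim <- simulate_sample(sc)
        counts <- tabulate(sim$sample$genotype, 4)
        pg <- estimate_popgen(counts)
        fit <- fit_with_control(sim$sample, grid, seed = seed + 1L)
        c(p = pg$p, u = fit$rates$u, v = fit$rates$v,
          unclass(fit$effects)[setdiff(EFFECT_NAMES, "mu")])
      }), error = function(e) NULL)
      if (is.null(res) || anyNA(res)) excluded[ci] <- excluded[ci] + 1L
      else est[r, ] <- res[par_names]
    }
    ok <- stats::complete.cases(est)
    m <- colMeans(est[ok, , drop = FALSE])
    s <- apply(est[ok, , drop = FALSE], 2, sd)
    summ[[ci]] <- data.frame(n = n, h2 = h2, parameter = par_names,
                             mean = m, sd = s, se = s / sqrt(sum(ok)),
                             n_used = sum(ok), row.names = NULL)
    raw[[ci]] <- data.frame(n = n, h2 = h2,
                            replicate = seq_len(grid$n_replicates), est)
    if (verbose)
      message(sprintf("cell n=%d h2=%.2f done (%d/%d replicates used)",
                      n, h2, sum(ok), grid$n_replicates))
  }
  structure(list(summary = do.call(rbind, summ),
                 raw = do.call(rbind, raw),
                 excluded = data.frame(cells, excluded),
                 grid = grid),
            class = "aneu_study")
}

#' @export
print.aneu_study <- function(x, digits = 4, ...) {
  cat("Monte-Carlo parameter-recovery study\n")
  s <- x$summary
  for (cell in unique(paste(s$n, s$h2))) {
    sub <- s[paste(s$n, s$h2) == cell, ]
    cat(sprintf("\nn = %d, H2 = %.2f (replicates used: %d)\n",
                sub$n[1], sub$h2[1], sub$n_used[1]))
    print(data.frame(parameter = sub$parameter,
                     mean = round(sub$mean, digits),
                     sd = round(sub$sd, digits),
                     se = round(sub$se, digits)), row.names = FALSE)
  }
  invisible(x)
}

power_test_registry <- function(name) {
  switch(name,
    association = list(
      run = function(sample, grid, seed)
        do.call(lrt_association,
                c(list(sample = sample, seed = seed), grid$fit_control)),
      null = "no_effect"),
    imprinting = list(
      run = function(sample, grid, seed)
        do.call(lrt_effects,
                c(list(sample = sample, which = "lambda", seed = seed),
                  grid$fit_control)),
      null = "no_imprinting"),
    imprinting_joint = list(
      run = function(sample, grid, seed)
        do.call(lrt_effects,
                c(list(sample = sample,
                       which = c("lambda", "i_a", "i_d", "i_dprime"),
                       seed = seed), grid$fit_control)),
      null = "no_imprinting"),
    stop("unknown test '", name,
         "'; available: association, imprinting, imprinting_joint"))
}

#' Power / type-I-error study
#'
#' Per grid cell, simulates replicates under the alternative scenario
#' (power) or the test's matched null generator (type-I error), runs the
#' named likelihood-ratio test, and reports the rejection fraction at
#' the grid's `alpha`.
#'
#' @param grid a [study_grid()].
#' @param test `"association"` (overall test, null generator
#'   `"no_effect"`), `"imprinting"` (lambda-only test, null generator
#'   `"no_imprinting"`), or `"imprinting_joint"` (lambda and its three
#'   interactions jointly, df = 4, same null generator).
#' @param generator `"alternative"` or `"null"`.
#' @param verbose print per-cell progress.
#' @return A data frame with one row per cell: `n`, `h2`, `rejections`,
#'   `n_used`, `rate`, `mc_se` (binomial Monte-Carlo standard error).
#' @export
run_power_study <- function(grid, test = c("association", "imprinting",
                                           "imprinting_joint"),
                            generator = c("alternative", "null"),
                            verbose = FALSE) {
  stopifnot(inherits(grid, "study_grid"))
  test <- match.arg(test)
  generator <- match.arg(generator)
  entry <- power_test_registry(test)
  cells <- cell_table(grid)
  out <- cells
  out$rejections <- 0L; out$n_used <- 0L
  for (ci in seq_len(nrow(cells))) {
    for (r in seq_len(grid$n_replicates)) {
      seed <- derive_seed(grid$master_seed, ci + 1000L, r)
      sc <- replicate_scenario(grid, cells$n[ci], cells$h2[ci], seed)
      res <- tryCatch(suppressWarnings({
        sim <- if (generator == "alternative") simulate_sample(sc)
               else simulate_null_sample(sc, entry$null)
        entry$run(sim$sample, grid, seed + 1L)$p_value
      }), error = function(e) NA_real_)
      if (!is.na(res)) {
        out$n_used[ci] <- out$n_used[ci] + 1L
        if (res < grid$alpha) out$rejections[ci] <- out$rejections[ci] + 1L
      }
    }
    if (verbose)
      message(sprintf("cell n=%d h2=%.2f: %d/%d rejections",
                      cells$n[ci], cells$h2[ci], out$rejections[ci],
                      out$n_used[ci]))
  }
  out$rate <- out$rejections / pmax(out$n_used, 1)
  out$mc_se <- sqrt(out$rate * (1 - out$rate) / pmax(out$n_used, 1))
  attr(out, "test") <- test
  attr(out, "generator") <- generator
  out
}

#' Bonferroni-adjusted p-values for multi-locus batches
#'
#' Convenience wrapper around [stats::p.adjust()] for users running the
#' single-locus tests across many loci.
#'
#' @param p numeric vector of p-values.
#' @param method adjustment method, default `"bonferroni"`.
#' @return Adjusted p-values.
#' @export
adjust_pvalues <- function(p, method = "bonferroni") {
  stats::p.adjust(p, method = method)
}
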