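# Population genetics of a duplicated (triploid) locus: genotype
# frequencies under Hardy-Weinberg disequilibrium, the diploid-to-triploid
# duplication model, and estimation of (p, D1, D2) from genotype counts.

#' Population-genetic parameters of a triploid locus
#'
#' Allele-A frequency `p` and the two Hardy-Weinberg disequilibrium (HWD)
#' coefficients: `D1` is the excess frequency of genotype AAA over `p^3`,
#' `D2` the excess of aaa over `q^3`. The remaining two genotype
#' frequencies are closed so that the four frequencies sum to one and
#' allele counting returns `p` (see [genotype_freqs()]).
#'
#' @param p allele-A frequency in `[0, 1]`.
#' @param D1,D2 HWD coefficients.
#' @return An object of class `"popgen_params"` with components `p`, `q`,
#'   `D1`, `D2`.
#' @export
popgen_params <- function(p, D1 = 0, D2 = 0) {
  stopifnot(length(p) == 1, is.finite(p), p >= 0, p <= 1,
            is.finite(D1), is.finite(D2))
  x <- structure(list(p = p, q = 1 - p, D1 = D1, D2 = D2),
                 class = "popgen_params")
  genotype_freqs(x)  # errors if the implied frequencies are invalid
  x
}

#' @export
print.popgen_params <- function(x, ...) {
  cat(sprintf("Triploid locus: p = %.4f, D1 = %.4f, D2 = %.4f\n",
              x$p, x$D1, x$D2))
  P <- genotype_freqs(x)
  cat(sprintf("Genotype frequencies: %s\n",
              paste(sprintf("%s = %.4f", names(P), P), collapse = ", ")))
  invisible(x)
}

#' Triploid genotype frequencies under Hardy-Weinberg disequilibrium
#'
#' `P(AAA) = p^3 + D1`, `P(aaa) = q^3 + D2`; the heterozygote frequencies
#' are the unique closure `P(AAa) = 3 p^2 q - 2 D1 + D2` and
#' `P(Aaa) = 3 p q^2 + D1 - 2 D2` that preserves both the sum-to-one
#' constraint and allele-frequency consistency
#' `(3 P1 + 2 P2 + P3) / 3 = p`.
#'
#' @param pop a [popgen_params()] object.
#' @return Named numeric vector `(AAA, AAa, Aaa, aaa)` summing to 1.
#' @export
genotype_freqs <- function(pop) {
  stopifnot(inherits(pop, "popgen_params"))
  p <- pop$p; q <- pop$q
  P <- c(p^3 + pop$D1,
         3 * p^2 * q - 2 * pop$D1 + pop$D2,
         3 * p * q^2 + pop$D1 - 2 * pop$D2,
         q^3 + pop$D2)
  names(P) <- GENOTYPE_LABELS
  if (any(P < -1e-12) || any(P > 1 + 1e-12))
    stop("parameters imply genotype frequencies outside [0, 1]: ",
         paste(sprintf("%.4f", P), collapse = ", "))
  pmin(pmax(P, 0), 1)
}

#' Observed triploid genotype counts
#'
#' @param n1,n2,n3,n4 nonnegative integer counts of genotypes AAA, AAa,
#'   Aaa, aaa, or a single length-4 vector passed as `n1`.
#' @return An object of class `"genotype_counts"`.
#' @export
genotype_counts <- function(n1, n2 = NULL, n3 = NULL, n4 = NULL) {
  n <- if (is.null(n2)) n1 else c(n1, n2, n3, n4)
  stopifnot(length(n) == 4, all(is.finite(n)), all(n >= 0),
            all(abs(n - round(n)) < 1e-8))
  n <- as.integer(round(n))
  names(n) <- GENOTYPE_LABELS
  structure(list(counts = n, n = sum(n)), class = "genotype_counts")
}

as_genotype_counts <- function(x) {
  if (inherits(x, "genotype_counts")) return(x)
  genotype_counts(x)
}

#' Multinomial MLE of the four genotype frequencies
#'
#' @param counts a [genotype_counts()] object or length-4 count vector.
#' @return Named frequency vector `counts / n`.
#' @export
estimate_genotype_freqs <- function(counts) {
  counts <- as_genotype_counts(counts)
  if (counts$n == 0) stop("no observations: total genotype count is zero")
  counts$counts / counts$n
}

#' Estimate allele frequency and HWD coefficients from genotype counts
#'
#' `closed_form` uses allele counting, `p = (3 n1 + 2 n2 + n3) / (3 n)`,
#' and subtraction, `D1 = n1/n - p^3`, `D2 = n4/n - q^3`. `em` iterates
#' the allele-proportion E-step (each genotype class contributes its known
#' A-allele dosage out of three copies) with the frequency M-step until
#' the parameter change falls below `tol`; because the three-parameter
#' model is saturated for the four counts, the EM fixed point coincides
#' with the closed form.
#'
#' @param counts a [genotype_counts()] object or length-4 count vector.
#' @param method `"closed_form"` or `"em"`.
#' @param tol convergence threshold on the parameter change (EM only).
#' @param max_iter iteration cap (EM only).
#' @return A [popgen_params()] object with attributes `clipped` (logical)
#'   and, for EM, `iterations`.
#' @export
estimate_popgen <- function(counts, method = c("closed_form", "em"),
                            tol = 1e-10, max_iter = 10000) {
  method <- match.arg(method)
  counts <- as_genotype_counts(counts)
  if (counts$n == 0) stop("no observations: total genotype count is zero")
  nk <- counts$counts
  n <- counts$n
  Phat <- nk / n

  closed <- function() {
    p <- (3 * nk[[1]] + 2 * nk[[2]] + nk[[3]]) / (3 * n)
    c(p = p, D1 = Phat[[1]] - p^3, D2 = Phat[[4]] - (1 - p)^3)
  }

  if (method == "closed_form") {
    est <- closed()
    iters <- NA_integer_
  } else {
    theta <- c(p = 0.5, D1 = 0, D2 = 0)
    dosage <- copies_A(1:4) / 3
    iters <- 0L
    repeat {
      iters <- iters + 1L
      # E: proportion of allele A carried by each genotype class;
      # M: allele frequency by weighted counting, disequilibria by
      # subtracting the Hardy-Weinberg cubes from the observed P1, P4.
      p_new <- sum(nk * dosage) / n
      theta_new <- c(p = p_new,
                     D1 = Phat[[1]] - p_new^3,
                     D2 = Phat[[4]] - (1 - p_new)^3)
      if (max(abs(theta_new - theta)) < tol) { theta <- theta_new; break }
      theta <- theta_new
      if (iters >= max_iter)
        stop("EM for (p, D1, D2) failed to converge in ", max_iter,
             " iterations; last estimate: ",
             paste(sprintf("%.6g", theta), collapse = ", "))
    }
    est <- theta
  }

  # clip to the valid frequency region (rarely needed: count-based
  # estimates are valid by construction)
  p <- min(max(est[["p"]], 0), 1)
  D1 <- est[["D1"]]; D2 <- est[["D2"]]
  clipped <- FALSE
  out <- tryCatch(popgen_params(p, D1, D2), error = function(e) NULL)
  if (is.null(out)) {
    clipped <- TRUE
    D1 <- min(max(D1, -p^3), 1 - p^3)
    D2 <- min(max(D2, -(1 - p)^3), 1 - (1 - p)^3)
    out <- popgen_params(p, D1, D2)
  }
  attr(out, "clipped") <- clipped
  attr(out, "iterations") <- iters
  out
}

#' Triploid genotype frequencies after duplicating a diploid population
#'
#' In a diploid source population at Hardy-Weinberg equilibrium with
#' allele-A frequency `p`, a proportion `g` of A alleles and `h` of a
#' alleles is duplicated: AA becomes AAA with probability `g`, aa becomes
#' aaa with probability `h`, and Aa becomes AAa (probability `g`) or Aaa
#' (probability `h`). Conditioning on the duplicated (triploid) subset
#' yields the returned frequencies, which in general carry nonzero
#' disequilibria even though the source was in equilibrium.
#'
#' @param p diploid allele-A frequency.
#' @param g,h duplication proportions for alleles A and a, each in
#'   `[0, 1]`, not both zero. (Conditioning on the triploid subset makes
#'   the frequencies well defined even when `g + h > 1`, in which case
#'   `g` and `h` act as relative duplication propensities of the two
#'   heterozygote routes.)
#' @return Named frequency vector `(AAA, AAa, Aaa, aaa)` among triploids.
#' @export
duplicate_population <- function(p, g, h) {
  stopifnot(length(p) == 1, p >= 0, p <= 1,
            length(g) == 1, g >= 0, g <= 1,
            length(h) == 1, h >= 0, h <= 1)
  if (g == 0 && h == 0)
    stop("g = h = 0: no duplication occurs, the triploid population is empty")
  q <- 1 - p
  mass <- c(g * p^2, 2 * p * q * g, 2 * p * q * h, h * q^2)
  P <- mass / sum(mass)
  names(P) <- GENOTYPE_LABELS
  P
}
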