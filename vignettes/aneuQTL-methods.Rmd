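---
title: "Modeling the genetic control of cancer at triploid aneuploid loci"
author: "aneuQTL authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling the genetic control of cancer at triploid aneuploid loci}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aneuQTL)
```

## The problem

Cancer genomes are frequently aneuploid: a chromosomal segment is
present in an abnormal number of copies. aneuQTL models the simplest
case, a biallelic locus carried in **three** copies by every sampled
cancer patient. A triploid patient carries one of four observable
genotypes — AAA, AAa, Aaa, aaa — but each genotype hides two
*parent-of-origin configurations*, depending on whether the duplicated
chromosome was maternal or paternal. The configuration is not
observable with ordinary genotyping, yet it can carry phenotypic
information (genomic imprinting). The package estimates, from triploid
genotype calls and a quantitative cancer phenotype:

* the allele frequency and two Hardy-Weinberg disequilibrium (HWD)
  coefficients of the triploid population,
* the parent-specific duplication rates `u` (probability that a
  duplicated A allele is maternal) and `v` (same for a),
* eight quantitative-genetic effects decomposing the configuration
  means, and
* likelihood-ratio tests for disequilibrium, overall association,
  individual effects, and duplication rates.

## Population genetics of the duplicated locus

Genotype frequencies are parameterized as

$$P_{AAA} = p^3 + D_1,\qquad P_{aaa} = q^3 + D_2,$$
$$P_{AAa} = 3p^2q - 2D_1 + D_2,\qquad P_{Aaa} = 3pq^2 + D_1 - 2D_2,$$

the unique closure of the two disequilibrium coefficients that
preserves both $\sum_k P_k = 1$ and allele-counting consistency
$(3P_1 + 2P_2 + P_3)/3 = p$. With three free parameters against three
degrees of freedom in the four genotype proportions the model is
saturated, so the maximum-likelihood estimator has closed form
(`estimate_popgen(..., "closed_form")`): allele counting for $\hat p$
and subtraction of the Hardy-Weinberg cubes for $\hat D_1, \hat D_2$.
The EM variant iterates the allele-dosage E-step with the frequency
M-step and converges to the same fixed point; both routes are exposed
because the agreement is a useful self-check and the EM form
generalizes to data with missing genotype classes.

Duplication itself creates disequilibrium: `duplicate_population()`
implements the diploid-to-triploid model in which proportions `g` and
`h` of A and a alleles are duplicated. Conditioning on the triploid
subset yields frequencies that generically violate Hardy-Weinberg
equilibrium even when the diploid source population obeyed it — e.g.
`duplicate_population(0.5, 1, 1)` gives (1/6, 1/3, 1/3, 1/6), an
implied $D_1 = 1/6 - 1/8 \approx 0.042$. This is why the association
model must carry free disequilibrium parameters rather than assuming
equilibrium. The estimation of `g` and `h` themselves from triploid
counts is out of scope: the four counts identify only three parameters,
and the model never needs them.

## The configuration mixture

The phenotype model is a four-stratum, two-component normal mixture.
Within genotype stratum $k$ the phenotype is distributed as

$$y \sim \pi_{k1}\,N(\mu_{k1}, \sigma^2) + \pi_{k2}\,N(\mu_{k2},
\sigma^2),$$

with maternal weight $\pi_{k1} = u$ for the strata arising from
duplication of A (AAA, AAa) and $\pi_{k1} = v$ for those arising from a
(Aaa, aaa). A single residual variance is shared by all eight
components. The EM algorithm (`fit_mixture()`) alternates posterior
configuration probabilities with weighted-mean updates; all updates are
closed-form.

The eight configuration means are an invertible linear transform of
eight genetic effects: overall mean $\mu$, additive effect $a$,
dominance of AA over a ($d$) and of A over aa ($d'$), imprinting effect
$\lambda$, and three imprinting interactions $I_{a\lambda}, I_{d\lambda},
I_{d'\lambda}$:

$$\mu_{11} = \mu + a + \lambda + I_{a\lambda},\quad
  \mu_{12} = \mu + a - \lambda - I_{a\lambda},$$
$$\mu_{21} = \mu + d + \lambda + I_{d\lambda},\quad
  \mu_{22} = \mu + d - \lambda - I_{d\lambda},$$
$$\mu_{31} = \mu + d' + \lambda + I_{d'\lambda},\quad
  \mu_{32} = \mu + d' - \lambda - I_{d'\lambda},$$
$$\mu_{41} = \mu - a + \lambda,\quad
  \mu_{42} = \mu - a - \lambda.$$

Within-genotype pair sums carry $\mu, a, d, d'$; each parent-of-origin
half-difference carries $\lambda$ plus one interaction; the aaa
half-difference identifies $\lambda$ alone, which makes the system full
rank and gives `means_to_effects()` as its exact closed-form inverse.
This coding was a genuinely open design choice: we also evaluated the
orthodox factorial alternative in which $\lambda$ is the *average*
half-difference and the interactions are sum-to-zero deviations. Both
are full-rank reparameterizations of the same saturated mean structure
— fits, association tests and joint imprinting tests are identical
under either — and they differ only in which single contrast the
one-degree-of-freedom $\lambda$ test pins down. We kept the coding
above because it keeps every effect attached to a named genotype
contrast, matching the verbal effect definitions.

### Numerical choices

* **Initialization.** `u = v = 0.5`; stratum means at the stratum
  sample mean $\pm$ half the stratum standard deviation; $\sigma^2$ at
  the pooled within-stratum variance. `n_starts = 5` by default for
  interactive fits, with seeded jitter of the starting means, because
  mixture likelihoods are multimodal. The Monte-Carlo harness uses the
  single deterministic start (and warm-starts null fits from the
  projected alternative), which we found to change likelihood values
  negligibly on this model while keeping a 200-replicate study within
  minutes.
* **Convergence.** Relative log-likelihood change below `1e-8`, at most
  2000 iterations; the trace is retained and checked for monotonicity
  (an EM guarantee) to `1e-8` slack.
* **Constrained fits.** Null hypotheses fix named effects at zero. The
  M-step then solves the posterior-weighted least-squares problem in
  effect space restricted to the free coordinates; cells with no
  posterior mass are dropped from the solve.
* **Degenerate inputs.** A variance floor of `1e-12` times the
  phenotype variance blocks spike solutions; all-constant phenotypes
  are rejected; an empty genotype stratum leaves the effect vector
  `NA` with a warning, since four of the eight means are then
  unidentifiable.
* **Label switching.** The likelihood is invariant to globally swapping
  the two configuration labels (mapping $(u, v)$ to $(1-u, 1-v)$ and
  exchanging the mean columns). Unconstrained fits are therefore
  reported in the canonical labeling with $u + v \le 1$; constrained
  fits are left untouched so fixed rates keep their stated values. The
  swap leaves $\mu, a, d, d'$ and every test statistic unchanged; only
  the signs of the imprinting block and the orientation of $(u, v)$
  are conventions.

## Hypothesis tests

All tests are likelihood-ratio tests between nested fits:

* **HWD**, joint ($D_1 = D_2 = 0$, df 2) and single-coefficient
  (df 1, with the remaining parameters profiled by bounded numerical
  maximization of the multinomial likelihood).
* **Overall association** ($\mu_{kj} \equiv \mu$, df 7 by parameter
  counting of the mean structure). The duplication rates are
  unidentified under this null — a Davies-type nonregularity — so a
  phenotype-permutation calibration is available alongside the default
  $\chi^2_7$ reference.
* **Effects**: any subset of $\{a, d, d', \lambda, I_{a\lambda},
  I_{d\lambda}, I_{d'\lambda}\}$ fixed at zero, df equal to the subset
  size. `run_power_study()` exposes the $\lambda$-only test
  (`"imprinting"`) and the joint parent-of-origin test
  (`"imprinting_joint"`, df 4), whose null is exactly the generator
  that equalizes the two configurations of every genotype.
* **Duplication rates**: $u$ or $v$ fixed at an interior value
  ($\chi^2_1$) or at the boundary values 0/1, where the reference is
  the 50:50 mixture of a point mass at zero and $\chi^2_1$. Both the
  literal boundary null ($u = 1$: duplication always maternal) and the
  no-parental-bias null ($u = 1/2$) are supported; the caller must
  choose explicitly.

## The simulator and what it does (not) emulate

`simulate_sample()` draws genotypes from the multinomial implied by
$(p, D_1, D_2)$, assigns configurations by Bernoulli draws with
maternal probability `u` or `v`, and adds Gaussian noise around the
configuration means. The residual variance is set from a target
broad-sense heritability $H^2$ as
$\sigma^2 = V_G (1 - H^2)/H^2$, where $V_G$ is the variance of the
configuration means over the eight (genotype, configuration) cells
(`genetic_variance()`). Broad-sense heritability is the only variance
decomposition available in this model, and it reproduces the expected
qualitative behavior: estimator spread scales like
$\sqrt{(1-H^2)/H^2}$ across heritability levels.

The reference scenario used as the default everywhere is: $p = 0.6$,
$D_1 = 0.08$, $D_2 = 0.06$ (genotype frequencies 0.296, 0.332, 0.248,
0.124), $u = 0.3$, $v = 0.4$, effects
$(a, d, d', \lambda, I_{a\lambda}, I_{d\lambda}, I_{d'\lambda}) =
(0.8, 0.5, 0.4, 0.5, 0.4, 0.5, 0.3)$ with $\mu = 0$, sample sizes 400,
800 or 2000, and $H^2 \in \{0.05, 0.1, 0.2\}$. The overall mean is not
separately specified by the study design; translation leaves every
other effect's recovery unchanged, so $\mu = 0$ throughout.

Null generators (`simulate_null_sample()`) either flatten all eight
means (`"no_effect"`) or zero the imprinting block
(`"no_imprinting"`), keeping the noise variance anchored to the
alternative so that power and false-positive runs are directly
comparable.

What the simulator does **not** emulate: the ancestral diploid cohort
and its exposure dynamics, measurement error structure beyond a single
Gaussian term, covariates (sex, ancestry, lifestyle), multi-locus
association, and higher-order polyploidy. Passing tests therefore
certify the internal statistical machinery, not robustness to the ways
real cancer cohorts violate these assumptions.

## The Monte-Carlo harness and its problem sizes

`run_recovery_study()` and `run_power_study()` orchestrate the grid of
(sample size, heritability) cells. Per-replicate seeds are derived
deterministically from a master seed so every cell is reproducible and
parallelizable. Default replicate count is 200; recovery summaries
report both the across-replicate standard deviation and the standard
error of the mean, since either may be wanted as a precision measure.
The package's own acceptance experiments use 200 replicates for power
and recovery and 500 for false-positive rates, sizes at which the
binomial Monte-Carlo error of a rate near 0.05-0.2 is about 0.01-0.03.

## Known limitations

* **Information, not bias, limits imprinting inference at realistic
  heritabilities.** At $H^2 = 0.2$ the within-stratum component
  separations are 0.5-1.0 residual standard deviations. Two-component
  normal mixtures this overlapped carry very little likelihood
  information: numerically, truth-initialized fits at $n = 20{,}000$
  show a per-subject log-likelihood-ratio of about 0.002 for the joint
  parent-of-origin test and essentially zero for the $\lambda$-only
  contrast. At $n = 400$ this translates into single-digit
  noncentrality and low power for imprinting detection (we measure
  about 0.13-0.19 for the $\lambda$ test and about 0.18-0.27 for the
  joint test at $H^2 = 0.2$), and into duplication-rate and imprinting
  estimates whose spread remains large even at $n = 2000$ (e.g.
  across-replicate standard deviations around 0.15-0.18 for $u, v$ and
  0.7 for $\lambda$ in the recovery study). Users
  should regard $u$, $v$, $\lambda$ and the interaction estimates as
  reliable only for strongly heritable traits or very large samples;
  the genotype-level quantities ($p$, $D_1$, $D_2$, $a$, $d$, $d'$,
  overall association) are well identified at ordinary sizes.
* **Chi-square calibration of the mixture-structure tests is
  anti-conservative.** Testing effects that live in the within-stratum
  half-differences (the imprinting block) against a $\chi^2$ reference
  is a normal-mixture homogeneity problem: under the null the component
  separation and the weights are unidentified, and the LRT's null
  distribution is heavier than chi-square. In our null studies at
  $n = 400$ the $\lambda$ test rejects about 23% of the time at nominal
  $\alpha = 0.05$ and the overall association test about 12%, despite
  conservative safeguards (the null fit is warm-started from the
  projected alternative). The permutation calibration of
  `lrt_association()` is the honest alternative when compute permits;
  p-values of the imprinting-block tests under chi-square calibration
  should be treated as anti-conservative screening values.
* Reported likelihood-based intervals are not provided; the package's
  uncertainty statements come from Monte-Carlo replication.
* The canonical $u + v \le 1$ labeling is a convention; if the true
  maternal duplication rates sum above one, the reported orientation
  is mirrored (with the imprinting block's signs flipped).

## Reproducing the headline numbers

`scripts/acceptance.R` in the source repository reruns the headline
experiment from scratch — 200 simulated replicates of the reference
scenario at $n = 400$, $H^2 = 0.2$, each fitted and tested for
$\lambda = 0$ at $\alpha = 0.05$ — and writes the empirical power to a
JSON file. The test suite additionally recomputes the false-positive
envelope, the $n = 2000$ recovery of $p$ and $a$, and the model-level
properties (inverse maps, estimator agreement, EM monotonicity,
disequilibrium emergence, test calibration).
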