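---
title: "Models and methods: chance versus contingency for a recurrent beneficial mutation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: chance versus contingency for a recurrent beneficial mutation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epistasim)
```

## The question the package answers

Replicate bacterial populations evolving in lactose-containing environments
often substitute loss-of-function mutations in the *lacI* repressor: the
mutation recurs at a high rate and shortens the lag phase after transfer to
fresh medium, a substantial benefit under daily serial transfer. Yet a fraction
of populations never substitute it. Two explanations compete. Under the
*chance* hypothesis the mutation simply has not arisen and fixed yet; under the
*historical contingency* hypothesis earlier substitutions change the mutation's
fitness effect (epistasis), closing that path. Distinguishing the two requires
quantitative machinery, not more sequencing: a simulator for what chance alone
predicts, estimators for the mutation rate and fitness effects that
parameterize it, and exact statistics for the contingency tables that the
sequenced clones produce. This package implements that machinery end to end,
with a synthetic-data module standing in for every laboratory input so the
whole analysis runs, and is tested, without laboratory data.

## Wright–Fisher simulation of the focal allele

`run_replicate()` simulates a haploid population of constant size $N$ under a
Wright–Fisher regime. Per generation:

1. background mutations arrive Poisson($NU$) population-wide ($U$ per
   individual per generation), each at a new site, with a selection
   coefficient drawn from a discrete distribution of fitness effects (DFE);
2. focal mutations convert focal-wild-type individuals at rate $\mu$ per cell
   per generation (one way; no back-mutation);
3. the next generation is a multinomial draw with weights proportional to
   lineage count times fitness; fitness is multiplicative across carried
   mutations, the focal allele contributing $1 + s$.

A replicate ends when the focal frequency exceeds the fixation threshold
(default 0.95) or at the horizon (default 8,000 generations). Internally the
population is a set of *lineage classes* (count, fitness, focal flag) rather
than individual records; the update law is identical at the distribution level
and makes $N = 10^5$ over thousands of generations tractable in plain R. Tests
verify the one-generation transition law against the explicit multinomial
distribution (total-variation distance $< 0.01$ at $10^5$ draws) and the whole
engine against Kimura's diffusion fixation probability
$\pi = (1 - e^{-2s}) / (1 - e^{-2Ns})$ in the interference-free case.

Default parameter values are the conditions of the serial-transfer system the
package models: $U = 7 \times 10^{-4}$, $\mu = 1.72 \times 10^{-7}$,
$s = 0.0831$ in lactose (0.0405 in the daily glucose/lactose alternation),
fixation above 95%, 8,000 generations. The default DFE
(`default_dfe()`) is three deleterious classes ($-0.1, -0.03, -0.01$; 30%
each) and three beneficial classes ($+0.01, +0.03, +0.08$; 5%, 3%, 2%). The
deleterious side is conventional; the beneficial side is a deliberately simple
placeholder that preserves a 3 + 3 class structure, and it implies a *strong*
clonal-interference regime at large $N$: at $N = 10^5$, $+0.08$ mutations
alone arrive 1.4 times per generation. Any empirically calibrated class table
should be substituted through `dfe_classes()` before quantitative comparison
with a particular experiment; with the placeholder, the short-epoch arm below
is heavily suppressed, and the combined substitution frequency at $N = 10^5$
computed by `scripts/acceptance.R` sits far below what a weak-interference
DFE would give.

### Fluctuating regimes and the combined frequency

Two of the three lactose-containing selection regimes alternate 2,000
generation epochs of lactose and glucose. Glucose epochs are not simulated;
the package adopts the assumption that focal mutations segregating (not yet
fixed) when lactose selection ends are lost during glucose selection, so a
regime with two lactose epochs obeys
$f_s = f_{2k} + f_{2k}(1 - f_{2k})$ (`extrapolate_fluctuating()`), where
$f_{2k}$ is the single-epoch fixation probability. Both fluctuating regimes
contain exactly two lactose epochs and use the same formula. The combined
frequency across the three regimes (`combined_fs()`) is the unweighted mean of
the constant-lactose value and two copies of the extrapolated value, because
each regime contributed equal population counts in the design this mirrors;
the combination rule is a package decision, as no canonical rule exists for
pooling regimes.

`substitution_frequency()` summarizes replicates as the fixed proportion with
a 1,000-resample bootstrap percentile interval, and
`reproduce_substitution_sweep()` runs the constant and epoch arms across
population sizes from one master seed.

## Fluctuation-test mutation rate

`estimate_rate()` implements maximum likelihood under the Lea–Coulson form of
the Luria–Delbrück law: mutations arrive Poisson($m$) per culture during
expansion and a clone founded at relative size $x$ of the final culture grows
to $\sim 1/x$ cells, giving clone-size pmf $1/(j(j+1))$ and the
Ma–Sandri–Sarkar recursion $p_0 = e^{-m}$,
$p_r = (m/r)\sum_{j<r} p_j/(r-j+1)$ for the mutant-count distribution. Three
practical layers sit on top:

* **plating efficiency** — observed counts are multiplied by $1/p_{\mathrm{eff}}$
  (`correct_counts()`, rounding ties-to-even) *before* estimation, mirroring
  the published pipeline order; folding the efficiency into the likelihood as
  thinning is available (`method = "thin-likelihood"`) but off by default;
* **partial plating** — when a volume fraction $z < 1$ of each culture is
  plated, the likelihood uses the binomially thinned count distribution
  (convolution of the whole-culture pmf with the thinning kernel, truncated
  where the kernel mass on the observed range is negligible);
* **jackpots** — counts above a cap (default 1,000) enter as right-censored
  tail probabilities, so a single early mutation cannot force an unbounded
  pmf support.

The rate is $\hat m$ divided by the whole-culture cell number
$n_{\mathrm{final}}/z$; the 95% interval comes from the profile likelihood at
a 1.92 log-likelihood-unit drop. An all-zero assay is reported as a boundary
estimate (rate 0, upper bound only). The recursion is verified against a
brute-force compound-Poisson convolution (log-likelihood agreement to
$10^{-6}$), and parameter recovery on synthetic assays (median within 10% of
truth over 500 assays of 10 cultures at $m \approx 5$) is part of the test
suite. The synthetic generator uses discrete doublings with deterministic
clone growth, which shares the $e^{-m}$ zero class and $1/x$ tail with the
continuous model but is not identical to it; the few-percent downward bias
this induces in $\hat m$ is visible in, and bounded by, the recovery test.

## Serial-transfer competition fitness

Absolute (Malthusian) fitness over a $d$-day competition with daily
$D$-fold dilution is $w = \ln(D^d\, N_f/N_i)$ (`absolute_fitness()`; $D$
defaults to 100). Relative fitness is the ratio $w_a/w_b$ and the selection
coefficient $s = w_a/w_b - 1$ (`relative_fitness()`), so swapping competitor
labels inverts the ratio exactly. Only within-competitor count ratios enter,
so raw colony counts and dilution-adjusted densities are interchangeable as
long as each replicate uses one convention. The two-day
glucose-then-lactose structure of the daily-alternating environment enters
only through $d = 2$. `batch_fitness()` averages replicates per strain pair
with a $t$-based 95% interval (the interval family is a package choice),
excluding and logging replicates with an extinct competitor.

## Baranyi–Roberts growth and virtual competitions

Single-strain growth follows
$\mathrm{d}N/\mathrm{d}t = r\,\alpha(t)\,N\,(1 - (N/k)^\nu)$ with adjustment
function $\alpha(t) = q_0/(q_0 + e^{-vt})$: $r$ is the maximum specific
growth rate (per hour), $k$ the carrying capacity (OD units), $\nu$ the
deceleration exponent, and $q_0, v$ the initial physiological state and its
recovery rate, which jointly set the lag. The substitution $w = (k/N)^\nu$
linearizes the ODE, so `br_trajectory()` evaluates the exact solution
$$N(t) = k\left[1 + ((k/y_0)^\nu - 1)\,e^{-\nu r A(t)}\right]^{-1/\nu},
\qquad A(t) = t + \tfrac{1}{v}\ln\frac{q_0 + e^{-vt}}{1 + q_0},$$
and numerical integration appears only as an independent oracle in the tests.
Lag is reported analytically as $\ln(1 + 1/q_0)/v$ — standard for this model
and free of tangent-construction ambiguity — with the geometric
(tangent-based) lag as a secondary output. `fit_growth()` estimates all six
parameters by Levenberg–Marquardt least squares from a fixed multi-start grid
(three $\nu$ values, two adjustment rates, three lag scales, data-driven
centers), on log-transformed parameters with the capacity parameterized as
$y_0$ plus a positive gap; fits are therefore deterministic. Flat,
non-saturating or non-monotone curves return a flagged failure object rather
than an error. The $q_0$–$v$ pair is weakly identified under noise, but their
lag combination is robust; the tests require exact (<1%) recovery on
noiseless curves and recovery of a 1.13 h lag contrast within 0.2 h from
fifty 0.005-OD-noise curves per strain.

`virtual_competition()` couples two strains through a shared nutrient pool:
each strain grows at its own rate and adjustment state but saturates against
the *combined* density scaled by its own capacity,
$\mathrm{d}N_i/\mathrm{d}t = r_i \alpha_i N_i \max(0, 1 - ((N_a+N_b)/k_i)^{\nu_i})$
— the simplest coupling consistent with independent use of a common pool, and
one that keeps densities non-decreasing. This system has no closed form and
is integrated with `deSolve::lsoda` (rtol $10^{-8}$). Virtual relative
fitness is the ratio of realized log growth,
$\ln(N_a(T)/N_a(0)) / \ln(N_b(T)/N_b(0))$ — the same Malthusian-ratio form as
direct competitions, chosen so the two are commensurable (a difference form
would not be). Defaults: 1:1 initial mixing and a 24 h horizon, matching one
serial-transfer cycle. Identical competitors give exactly 1 by symmetry;
zero-net-growth horizons are flagged rather than divided through.

## Mutation-set parallelism

`dice()` computes Sørensen–Dice similarity $2|A \cap B|/(|A| + |B|)$ between
clones' mutated-locus sets; two empty sets are undefined (`NA` with a
warning), not 0 or 1. Locus identity is whatever granularity the profiles
carry — gene-level labels make two different substitutions in the same gene
count as shared, which is the intended default; supplying position-level
identifiers switches the matching. `group_mean_similarity()` averages all
unordered pairs within each group and across groups;
`permutation_test()` reassigns clones to labels (preserving group sizes) and
reports, for each statistic, the two-sided p-value by absolute deviation from
the permutation mean, with the add-one correction
$p = (1 + \#\{|t_b - \bar t| \ge |t_{\mathrm{obs}} - \bar t|\})/(1 + B)$.
Two-sidedness is the package's choice where no direction is pre-registered.
Under the exchangeable null generator the p-values are uniform
(Kolmogorov–Smirnov check over 500 simulated datasets in the test suite).

## Exact statistics

The contingency claims rest on three small-sample procedures, all built on
explicit enumeration with log binomial coefficients: `wilson_ci()` (the
Wilson score interval — among the standard candidates it is the one that
reproduces the published 31.4–68.6% interval for 12/24, which is why it is
the package's interval), `binomial_test()` (exact tail sums;
minimum-likelihood two-sided convention), and `fisher_exact()` (full
hypergeometric enumeration over tables with fixed margins; two-tailed sums
tables with point probability at or below the observed, the dominant
convention, verified to reproduce the published 0.026 and 0.119). Degenerate
margins return p = 1 with a flag. p-values are kept at full precision;
rounding happens only at presentation.

## The synthetic-data module

`gen_growth_curve()`, `gen_fluctuation_counts()`, `gen_competition_counts()`
and `gen_mutation_profiles()` emulate, respectively, 5-minute plate-reader OD
series (exact trajectory plus additive Gaussian noise truncated at zero —
plate-reader noise is approximately scale-free at these densities and
truncation keeps readings physical; the default 0.005 OD is a fixture choice,
as no instrument noise magnitude is inherent to the model), Luria–Delbrück
mutant counts (per-doubling binomial seeding with deterministic clone
doubling — exact at desk scale with no special-function evaluation),
competition plate counts (multinomial or Poisson sampling around frequencies
obtained by inverting the fitness estimator, so the estimator's expectation
is the target fitness), and clone-by-locus incidence tables (two signature
locus pools carried at `p_within` by the own group and `p_shared` by the
other, plus private loci; the within-minus-between expected shared-locus rate
is $(p_{\mathrm{within}} - p_{\mathrm{shared}})^2 \ge 0$, with equality —
full exchangeability — at the null). Every generator takes an explicit seed,
never touches the global RNG state, and is bit-reproducible;
`write_synthetic()` attaches a JSON sidecar recording parameters and seed.

What the generators deliberately do not emulate: diauxic two-sugar dynamics,
OD-to-CFU calibration, sequencing reads or variant calling, mutation-rate
heterogeneity among cultures, and differential growth of mutants during
culture expansion. Passing tests therefore show that the estimators recover
truth under the stated models, not that real plate readers or real genomes
satisfy those models.

## Problem sizes and numerical choices

The test suite and acceptance script run, as package choices: the
population-size sweep at $N = 10^3$ and $10^4$ with 50 replicates per arm
and the headline at $N = 10^5$ with 20 per arm; the diffusion-oracle check
at $N = 200$ with 500 replicates; rate recovery over 500 ten-culture assays;
lag-contrast recovery over 50 noisy curves per strain; and permutation
uniformity over 500 datasets at 199 permutations. Other numerical defaults:
fixation threshold 0.95; bootstrap 1,000 resamples, percentile 2.5/97.5;
MSS likelihood cap 1,000 with censoring; profile-likelihood drop 1.92;
ODE tolerances rtol $10^{-8}$/atol $10^{-12}$; ties-to-even rounding in
count correction.

## Known limitations

* The default DFE's beneficial supply is a placeholder; quantitative
  substitution-frequency comparisons for a specific experiment require its
  calibrated class table (see above).
* The simulator assumes a plain per-generation Wright–Fisher update; daily
  bottleneck/regrowth structure within transfers is not modeled.
* The fluctuation generator's doubling construction biases $\hat m$ downward
  by a few percent relative to the continuous-model likelihood at desk
  scales.
* Virtual competitions are in OD units, growth-only, without death, diauxie
  or secretion-mediated interactions; they test whether measured growth
  parameters *suffice* to predict competitive outcomes, not mechanism.
* Permutation p-values are lower-bounded at $1/(B+1)$; group designs more
  unbalanced than the generators produce were not studied.
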