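---
title: "Twin-design ACE models in twinace: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Twin-design ACE models in twinace: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(twinace)
```

## The model

The classical twin design decomposes the variance of a phenotype into
additive genetic (A), shared environmental (C), and non-shared
environmental (E) components by exploiting the known genetic relatedness
of twin types: monozygotic (MZ) pairs share all segregating genes
(relatedness coefficient γ = 1), dizygotic (DZ) pairs half on average
(γ = ½). Shared environment is, by definition, fully correlated within a
pair regardless of zygosity; non-shared environment (which also absorbs
measurement error) is uncorrelated. Writing the phenotype of each twin
as y = aA + cC + eE with standardized, unit-variance latent scores, a
pair's phenotypes are bivariate normal with common mean μ, common
variance a² + c² + e², and cross-twin covariance γa² + c². The implied
twin correlations are rMZ = a² + c² and rDZ = ½a² + c², which gives the
Falconer moment estimator a² = 2(rMZ − rDZ) implemented in
`falconer_decomposition()` (out-of-range values are flagged, never
silently truncated, so the user sees when the correlations are
incompatible with the model).

Key assumptions inherited from the design: purely additive gene action
(no dominance component is fitted — with twins reared together A, C, D
are not jointly identified, and this package deliberately fits ACE
only), equal shared environments for MZ and DZ pairs, no assortative
mating, and no gene–environment interaction. The synthetic-data
generator makes exactly the same assumptions, which is what makes
parameter recovery a meaningful test of the estimators.

`fit_ace_ml()` maximizes the exact bivariate-normal likelihood over the
MZ and DZ strata jointly. Two implementation details matter:

* **Sufficient statistics.** With a common mean and variance per
  stratum, the log-likelihood depends on the data only through per-group
  sums (n, Σx, Σx², Σx₁x₂). These are accumulated once; each likelihood
  evaluation is then O(1), which is what makes the 300-cohort coverage
  study and the 400-replicate calibration study in the test suite run in
  seconds rather than hours.
* **Nonnegative path parameterization.** The optimizer works on
  (μ, a, c, e) with a, c, e ≥ 0 (box constraints under L-BFGS-B), so the
  standardized components a², c², e² are automatically in [0, 1] and sum
  to one. Five deterministic starting points spanning the variance
  simplex guard against local optima; ties are broken toward the lowest
  a² for reproducibility.

## Binary choices: liability threshold and tetrachoric correlation

A binary choice is modelled as a thresholded latent liability: choice
= 1 when a standard-normal liability exceeds t, so a population
prevalence K corresponds to t = Φ⁻¹(1 − K). A twin pair's choices follow
a bivariate normal cut at (t, t) with correlation γa² + c²; the four
concordance-cell probabilities are orthant masses of that distribution.

`bvn_cell_probabilities()` computes the upper orthant by a
one-dimensional quadrature of φ(x)·Φ((rx − t₂)/√(1 − r²)) over x > t₁
(`stats::integrate`, absolute tolerance 1e−10), with exact expressions at
r = ±1; the other cells follow from the margins. The closed-form check
P(both above 0 | r = ½) = ¼ + arcsin(½)/2π = ⅓ holds to 1e−8 and is
asserted in the tests.

`fit_tetrachoric()` inverts a single 2×2 table by maximizing the
multinomial likelihood over (r, t₁, t₂), searching on the Fisher-z scale
for r so the optimum stays interior; a boundary flag is raised when |r̂|
reaches 1 (e.g. a perfectly concordant table). Zero cells need no
continuity correction — the likelihood stays finite as long as both
margins are positive. `fit_liability_ace()` fits all groups jointly with
a single threshold (zygosity should not shift prevalence; a per-group
threshold would absorb sampling noise into the margins) and reports
standardized components with profile CIs. The test suite checks that the
joint fit's implied group correlations agree with independent per-group
tetrachoric fits, and that tables constructed from exact orthant
probabilities at N = 10⁶ are inverted to |r̂ − r| ≤ 0.01 across
r ∈ [−0.8, 0.8] and thresholds ∈ {−0.5, 0, 0.5}.

## Profile-likelihood intervals and likelihood-ratio tests

All interval estimates are profile-likelihood CIs: the bound for a
standardized component p is the value where the profile log-likelihood
(all other parameters re-optimized, with the component's share held at
p via a scale-and-split reparameterization) drops by χ²₁(0.95)/2 =
1.92 from the maximum, located by bisection. This mirrors the intervals
produced by mainstream SEM engines for twin models and respects the
[0, 1] boundary, unlike Wald intervals. The coverage study in the test
suite (300 cohorts of 500 MZ + 500 DZ pairs at a² = 0.6) checks the
nominal rate within ±3 percentage points.

Nested models are compared by likelihood-ratio tests. When the reduced
model pins a variance component at its zero boundary (ACE → AE, AE → E,
…), the usual χ²_df reference is conservative; `likelihood_ratio_test()`
reports, alongside the naive p, the standard 50:50 mixture of χ²_df and
χ²_{df−1}. The calibration study (400 cohorts generated under an AE
truth) checks that the mixture-corrected test of C = 0 rejects at
5% ± 3pp. Equality constraints that are interior (the sex-limitation
chain) use the naive χ² reference.

## Sex limitation

With five zygosity groups (MZm, MZf, DZm, DZf, DZos),
`fit_sex_limitation()` fits the nested chain:

1. **full** — sex-specific paths and means (continuous) or thresholds
   (liability), with the DZ opposite-sex cross-twin covariance
   rg·aₘ·a_f + rc·cₘ·c_f and exactly one of rg/rc free;
2. **qualitative_constrained** — rg fixed at 0.5 (or rc at 1.0), the
   values expected when the *same* genetic (shared-environmental)
   factors operate in both sexes;
3. **quantitative_equal** — male and female components additionally
   equated (testing differences in *magnitude*);
4. **homogeneous** — means/thresholds equated too; for continuous traits
   this submodel is exactly the pooled univariate model, and the test
   suite asserts that its maximized likelihood matches `fit_ace_ml()`.

Here rg is the DZos additive-genetic correlation itself, bounded in
[0, 1] with 0.5 as its no-qualitative-difference value — the convention
used by the major SEM twin-modelling tools. (An alternative convention
scales a relative attenuation factor onto the DZ value of ½; we chose
the direct-correlation form because the constrained values 0.5/1.0 then
read off immediately.) rg and rc cannot both be freed: with one
opposite-sex covariance observation per pair they are not jointly
identified, so the full model frees rg with rc = 1 by default and the
`free = "rc"` option swaps the roles. Sex-specific E correlations are
ruled out by definition (E is within-individual).

Because rg enters only through the DZos covariance and is bounded, the
qualitative test is conservative in moderate samples (its observed
type-I rate in our simulations is below nominal); the quantitative test,
an interior equality constraint, is calibrated at its nominal rate — the
suite verifies 5% ± 3pp over 200 homogeneous cohorts.

## The synthetic cohort generator

`sim_config()` defaults encode the study conditions the package is
built to emulate: 6584 twin pairs (2318 MZ, 2146 DZ same-sex, 2120 DZ
opposite-sex, with the published MZ and DZss totals split evenly by sex
since only the three totals are published), choice prevalence 0.5,
choice-liability ACE of (0.44, 0.47, 0.09), achievement ACE of
(0.59, 0.07, 0.34), grades on a 1–6 scale with mean 3.9 and SD 1.16,
and ages in a narrow band around 18. Latent scores are drawn directly
with the required cross-twin correlations (γ for A, 1 for C, rg/rc in
the DZos group) and combined through per-sex paths, so every population
moment is available in closed form for the property tests.

Three generator decisions were genuinely open:

* **Selection into achievement.** The mechanism linking choice and
  subsequent achievement is not published. We use the *same* liability
  draw to decide choice and to gate the observation of grades, so
  missingness is familial (concordant-chooser pairs are a selected set),
  while the grade phenotype itself is an independent ACE draw. This
  reproduces the observable structure — achievement available for about
  half the sample, restricted to choosers — without asserting an
  unverifiable cross-trait correlation. Under this scheme selection is
  ignorable for the grade trait, which is what makes end-to-end
  parameter recovery a valid check of the fitting code.
* **Grade discretization.** Continuous achievement is rounded to the
  nearest integer in [1, 6] after scaling to the configured mean/SD,
  reproducing the mild ceiling effects of real grade distributions.
* **Seeding.** One pseudo-random stream per run, restored afterwards
  (`withr::with_seed`), so identical configs give bit-identical cohorts
  and every simulation in the test suite is reproducible.

## Preprocessing

`apply_corrections()` follows the order exclusions → age/sex OLS
residualization → van der Waerden transform → restandardization.
Corrections are computed on individuals pooled across twins: age is
pair-constant and MZ pairs are always same-sex, so uncorrected age/sex
mean effects would masquerade as shared environment, and per-twin-slot
fits would be rank-deficient. The van der Waerden transform maps the
value with rank r among n non-missing entries to Φ⁻¹(r/(n+1)), ties
receiving the average-rank quantile (the symmetric choice that preserves
the mean-zero property); missing values stay missing throughout, and
standardization is computed within the analysis sample actually fitted.

One consequence worth knowing: on *coarse* bounded scales (six grade
levels with a ceiling), the normal-scores transform is a non-linear
relabelling of a handful of categories, and it perturbs the MZ and DZ
correlations slightly in opposite directions. In the default synthetic
cohort this shows up as a small downward bias in the recovered shared
environment for achievement (a few percentage points, with a matching
upward shift in heritability) relative to the latent generating values —
the raw-grade Falconer estimate sits close to truth, while the
post-transform estimate gives most of c² away to a². The recovery is
still comfortably inside the ±0.07 end-to-end tolerance, but this is a
genuine property of inverse-normal transforms applied to coarse data,
not an estimator defect, and it applies to real analyses that use the
same recipe.

## Descriptive statistics

Because co-twins are not independent observations, descriptive tests use
one randomly selected twin per pair (`chisq_one_per_pair()` — Pearson
chi-square without continuity correction on the 2×2 sex-by-choice
table — and `anova_sex_zygosity()` — two-way fixed-effects ANOVA with
sequential type-I sums of squares in the order sex, zygosity,
interaction, the deterministic classical convention for unbalanced
data). The selection seed is an explicit argument, so published numbers
of this kind are reproducible only jointly with their seed; the suite
verifies determinism and the nominal type-I rate of the chi-square under
sex-independent choice. Chooser shares are reported with explicit
denominators: shares by sex or zygosity group are percentages *of
choosers*, the overall rate a percentage of all individuals with a
non-missing indicator.

## Problem sizes and runtime

The replication sizes used by the test suite are chosen to make Monte
Carlo noise small relative to each tolerance while keeping the full
suite around two minutes on one core: recovery checks average 5 cohorts
of 10,000 pairs (continuous) and 3 cohorts of 6,000 pairs (liability);
the coverage study uses 300 cohorts of 1,000 pairs; calibration studies
use 200–400 replicates; the power examples use 60–100 replicates of
500–2,000 pairs. The sufficient-statistic likelihood makes the
continuous-model studies essentially free; liability fits are dominated
by the orthant quadrature (a few milliseconds per fit).

## Known limitations

* Complete pairs only: singleton twins are rejected by the reader and
  excluded from likelihoods, matching pair-based published analyses; a
  marginal-likelihood treatment of singletons is out of scope.
* No dominance (ADE), no ordinal multi-threshold traits, no
  multivariate or longitudinal models, no assortative mating or
  gene–environment interaction — in either the estimators or the
  generator.
* The generator's realism is limited to what the fitted models assume
  (normal liabilities, linear mean effects, ignorable selection given
  choice). Passing recovery tests therefore demonstrates the
  correctness of the estimators under the model, not robustness of the
  twin design to violations of its assumptions in real data.
* Published chi-squares and ANOVAs that depend on an unpublished random
  one-twin-per-pair selection cannot be reproduced exactly, only
  distributionally.
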