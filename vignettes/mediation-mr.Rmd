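---
title: "Two-step mediation Mendelian randomization with medmr: models, design choices, and what the simulations show"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-step mediation MR: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(medmr)
```

## The scientific problem

An exposure (here the motivating case is circulating selenium) has an
estimated causal effect on an outcome (estimated glomerular filtration
rate, eGFR), and the question is how much of that effect travels through
intermediate molecular traits — a panel of plasma proteins. With only GWAS
summary statistics from three non-overlapping studies (exposure, protein
panel, outcome), the two-sample, two-step mediation MR design answers this
in three stages:

1. **Total effect** `theta`: MR of exposure on outcome.
2. **Two steps**: MR of exposure on each mediator (effect `a`, using the
   exposure's instruments) and MR of each mediator on the outcome (effect
   `b`, using the mediator's own instruments, typically pQTLs selected at
   the suggestive tier).
3. **Mediation**: the indirect effect is the product `a*b`; the mediation
   proportion is `a*b / theta`. A mediator is a *partial* mediator when
   both steps are significant and `a*b` has the sign of `theta`; when the
   signs oppose, the mediator works against the total effect and is
   flagged *inconsistent* rather than partial. Discovered mediators are
   then tested for gene-set over-representation.

All effects are carried as betas on the per-1-SD scale; report tables
exponentiate them into "OR" columns because that is how mediation-MR
results are conventionally printed even for continuous outcomes, and
`render_mediation_table()` reproduces that layout.

## The structural model behind the generator

`truth_config()` + `simulate_study()` encode the minimal linear structural
model consistent with the product decomposition:

```
X  = sum_j gamma_j g_j + e_X
M_k = alpha_k X + sum_j delta_kj g_j + e_k
Y  = c' X + sum_k b_k M_k + e_Y
```

so a SNP's true marginal effects are `gamma_j` on the exposure,
`alpha_k gamma_j (+ delta_kj)` on mediator k, and
`theta gamma_j + sum_k b_k delta_kj` on the outcome, with
`theta = c' + sum_k alpha_k b_k`. Observed coefficients are drawn
`Normal(true, se^2)` with `se = 1/sqrt(n * 2 f (1-f))` — the standard
error of a standardized-trait, per-allele regression — and two-sided
normal p-values. Default sample sizes (4,162 / 3,301 / 1,201,909) mirror
the exposure GWAS, plasma-proteome panel, and eGFR meta-analysis that
motivate the package; the default total effect is `-0.003` SD per SD, the
scale reported for selenium on eGFR.

Deliberate realism features, each exercised by tests:

* **Mediator QTLs** (`n_qtl = 5`, `delta_qtl = 0.3`): without them a
  mediator has no instruments of its own and step 2 is impossible. Five
  strong, independent QTLs emulate the cis-pQTL architecture of plasma
  proteins.
* **Allele-orientation scrambling** (`swap_prob = 0.3`) and per-study
  binomial EAF noise, so harmonization genuinely has work to do.
* **Pleiotropy** (`pleio_mode`): balanced (mean zero) or directional
  (nonzero mean; the Egger intercept estimates exactly this mean).
* **Reverse-causal SNPs** (`gamma_rev = 0.15`, `theta_rev = 0.7`): a true
  outcome variant whose induced exposure association is detectable at the
  suggestive tier yet explains clearly less variance in the exposure —
  the case the Steiger filter exists for.
* **Planted outliers** (`outlier_mult` outcome SEs added to an
  instrument), the MR-PRESSO target.
* An optional **LD-block mode** that expands each instrument into a block
  of correlated proxies and emits the matching LD matrix, so clumping is
  testable. Observed noise is drawn independently per proxy — adequate
  for testing the greedy clump, not a full LD-aware noise model.

What the generator does *not* emulate: individual-level data,
case-control traits, covariate adjustment, fine-scale LD, correlated
mediator residuals (mediators are independent given X by default, which
makes the `sum a*b` decomposition exact), and winner's-curse conditioning
beyond what thresholding induces naturally. Passing tests therefore
demonstrate correctness of the estimators and the pipeline logic under a
faithful summary-statistics noise model, not robustness to every
pathology of real GWAS meta-analyses.

Instrument-strength defaults (|gamma| 0.15–0.30, MAF 0.2–0.5) give
single-SNP F-statistics of roughly 30–190 at n = 4,162, matching a
published selenium instrument set in which no instrument was weak.

## The selection cascade

`select_instruments()` runs, in fixed order: p-value threshold (5e-8
genome-wide, 1e-5 suggestive) → greedy LD clumping (keep the smallest
p-value, drop neighbours with r² > 0.001 within 10 Mb; ties broken by
p-value then SNP id, so the cascade is deterministic) → allele
harmonization → single-SNP F ≥ 10 → MR-PRESSO outlier removal → Steiger
directionality filter → blocklist exclusion (the offline stand-in for
PhenoScanner-style confounder lookups) → Bonferroni exclusion of SNPs
with outcome p < alpha/m.

Choices worth knowing about:

* **Palindromic SNPs are dropped by default.** The stricter reading of
  "palindromic SNPs were excluded" is drop-all; the frequency-rescue rule
  (keep when both EAFs sit outside (0.42, 0.58), orienting by which side
  of 0.5 they fall on) is available as `palindrome = "rescue"`.
* **The Bonferroni outcome filter cannot tell direct from mediated
  outcome association.** When the true total effect is large, or in step
  2 where a real mediator makes its own QTLs outcome-associated, the
  filter removes precisely the valid instruments. It therefore defaults
  on in the total-effect cascade (where the motivating exposure has a
  tiny effect, `-0.003`, and the filter only catches genuinely direct
  variants) and **off** in `screen_mediators()` step 2
  (`step2_bonferroni_m = NA`); both are configurable.
* **Clumping parameters** (r² 0.001, 10 Mb) are the common two-sample-MR
  convention; the source analyses do not state theirs.

## Estimators and their reference distributions

* `mr_ivw()` fixed-effect is exactly zero-intercept weighted least
  squares with weights `1/se_Gamma^2` (tested against an independent WLS
  solve to 1e-12). The random-effects form multiplies the SE by
  `max(1, sqrt(Q/(n-1)))` (multiplicative overdispersion, floored).
  **The random-effects interval and p-value use a t reference with n-1
  degrees of freedom**, not the normal: the overdispersion factor is
  estimated from the same handful of instruments, and with n = 8 and the
  heterogeneity that exposure-side measurement error induces at large
  |theta|, normal quantiles cover near 91% instead of 95%. The
  fixed-effect form keeps the normal reference, so its null rejection
  rate is exactly nominal.
* `mr_egger()` orients all SNPs to non-negative exposure effects,
  fits a weighted regression with free intercept, floors the residual
  scale at 1, and uses t(n-2). The intercept estimates mean directional
  pleiotropy. Two pathologies are documented rather than hidden: with a
  narrow spread of instrument strengths the slope (and hence intercept)
  is weakly identified, and regression dilution from exposure-side noise
  leaks a `(1-lambda)*theta*mean(gamma)`-sized bias into the intercept
  when |theta| is large. Tests that target the intercept use a wide
  gamma spread and a small theta for exactly this reason.
* `mr_weighted_median()` interpolates the ratio at centred cumulative
  weight 0.5 and bootstraps its SE parametrically (default 1000 draws,
  seeded). It is consistent while valid instruments hold a majority of
  the weight; with 40% contamination it retains a finite-sample shift of
  order one ratio-SD, which is why the robustness claim is "closer to
  the truth than IVW", not "unbiased".
* `mr_raps()` solves the robust adjusted profile score equation (Huber
  psi, c = 1.345, by default) with an optional overdispersion variance
  `tau2` solved from the second-moment condition and floored at zero;
  SEs come from the M-estimation sandwich. The profile score is not
  monotone in beta, so the solver walks a fine grid outward from the
  IVW, weighted-median, and zero starts and takes the sign change
  nearest the start — deterministic by construction.
* `mr_presso()` implements the residual-sum-of-squares global test,
  per-SNP outlier test (empirical p, Bonferroni-corrected), and
  distortion test. The null simulations resample **both** the
  SNP-exposure and SNP-outcome effects: resampling only the outcome side
  makes exposure-side measurement error masquerade as pleiotropy and
  flags every SNP once |theta| is non-trivial. Empirical p-values use
  the `(1 + #exceedances)/(n_sim + 1)` form, so `global_p >=
  1/(n_sim+1)` always.
* `cochran_q()`, `leave_one_out()`, `steiger_direction()` (strict
  inequality: a tie is *not* evidence for the assumed direction), and
  `mr_power()` (two-sided normal approximation for a continuous
  standardized outcome) complete the diagnostic suite.

The Egger fallback rule — prefer the Egger slope when its intercept test
is significant at 0.05 — is applied by `total_effect()` and per step in
`screen_mediators()`. Note its cost: on an equal-strength QTL panel the
intercept test still fires at its nominal 5% rate while the Egger slope
is nearly unidentified, so roughly one screen in twenty replaces a good
IVW estimate with a noisy Egger one. Median-based summaries absorb this;
single fixed-seed analyses can tighten `egger_alpha` when the instrument
panel has no strength spread.

## Mediation arithmetic

`mediation_effect(a, b) = a*b` exactly; `mediation_ratio(a, b, theta) =
a*b/theta`, errors on `theta = 0`, and is deliberately unconstrained —
opposing mediators legitimately produce ratios below 0 or above 1. The
delta-method SE `sqrt(a^2 se_b^2 + b^2 se_a^2)` (optionally with the
exact-product `se_a^2 se_b^2` term) is an addition of this package; the
published screen format reports no interval for mediation effects.
Classification is a pure function of the two step p-values and the three
signs, so it is exactly reproducible from any printed table — which is
what the acceptance checks on the bundled 35-protein screen do.

## Problem sizes and numerical choices in the test suite

Simulation-backed tests use: 2000 replicates for null calibration of IVW
and Cochran's Q (both exact-nominal constructions, band 0.035–0.065);
1000 replicates for 95% CI coverage of the random-effects IVW at
study-scale sample sizes and theta = -0.3 (≥ 93%); 300 replicates for
recovery of a true mediation proportion of 0.25 (median within ±0.05);
200 seeds each for the PRESSO outlier flag (≥ 95%), Steiger reverse-SNP
removal (≥ 95%), and weighted-median-beats-IVW under 40% contamination
(≥ 80%). Oracle-equivalence tests (IVW vs WLS, interceptless Egger vs
IVW, hypergeometric tail vs exhaustive enumeration at N ≤ 25) run on 100
random fixtures each at 1e-12. These sizes keep the whole suite under a
few minutes while leaving comfortable Monte-Carlo margins around every
bound.

Root-finding tolerances are 1e-12 (RAPS beta) and 1e-14 (tau2);
empirical p-values never return exactly zero; degenerate inputs
(single-instrument sets, zero total effect, mediators with no surviving
instruments, empty post-cascade sets) degrade to defined results or
flagged rows rather than errors, except where the spec of the method
makes an error the honest answer (Wald ratio at gamma = 0, ratio at
theta = 0).

## Enrichment

`hypergeom_enrich()` is plain upper-tail hypergeometric
over-representation with BH adjustment by default. The universe defaults
to the screened mediator panel — the correct background for a panel
screen, not the genome. It does not emulate any pathway database's
reaction/entity coverage semantics; results are set over-representation,
nothing more.

## Known limitations

Step 2 is univariable per mediator: no adjustment for the exposure or
for sibling mediators, so a mediator correlated with a true mediator can
screen positive. The decomposition `sum(a*b) + direct = theta` is exact
only for mediators independent given the exposure (the generator's
default; a correlated-mediator option exists for exploration). When the
exposure drives a mediator strongly, the exposure's instruments become
genuine mediator-GWAS hits and contaminate step 2 with ratio
`theta/alpha`; PRESSO and Steiger remove most of this, but it is the
main reason step-2 estimates should be read alongside their selection
reports. I²-style weak-instrument corrections for Egger and multivariable
MR are out of scope.
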