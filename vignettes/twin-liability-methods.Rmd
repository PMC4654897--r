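---
title: "Liability-threshold heritability for a censored age-at-onset trait: models, weighting and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Liability-threshold heritability for a censored age-at-onset trait}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twinliab)
```

## The problem

Total hip arthroplasty (THA) for primary hip osteoarthritis is a rare,
strongly age-dependent, clinically unambiguous endpoint. A nationwide twin
register linked to an arthroplasty register observes it only through a
finite calendar window: twins enter follow-up at whatever age they have
reached when the arthroplasty register opens, leave it at operation, death,
emigration or the administrative close, and any operation performed before
the window opened is invisible. The classical twin design asks how much of
the population variance in the liability to this endpoint is explained by
additive genetic effects (A), non-additive genetic effects (D), shared
environment (C) and unique environment (E). `twinliab` implements the full
chain: a generative model of such a cohort, registry linkage, concordance
and tetrachoric correlation estimation, weighted bivariate-probit variance
component fits, competing-risk cumulative incidence, and age-resolved
versions of all of it.

## The liability-threshold model

A binary trait is modelled as the dichotomisation of a latent standard
normal liability \(L\): an individual is affected by age \(t\) when
\(L > \tau(t)\), with \(\tau\) strictly decreasing so that cumulative
incidence rises with age. With prevalence \(q\) at some horizon,
\(\tau = \Phi^{-1}(1-q)\). Twin pairs share a bivariate normal liability
with correlation \(r_{MZ} = a^2 + d^2 + c^2\) in monozygotic and
\(r_{DZ} = a^2/2 + d^2/4 + c^2\) in dizygotic pairs. The saturated model
frees one correlation per zygosity class; the ACE/ADE/AE/CE submodels
constrain them through the variance components, which live on the unit
simplex (ACDE is not identifiable from MZ/DZ data and is rejected).
Broad-sense heritability is \(H^2 = a^2 + d^2\); for a saturated fit the
moment version \(2(r_{MZ} - r_{DZ})\) is reported and labelled as such.

Pair outcomes enter through the bivariate probit likelihood. For a pair
with outcomes \((y_1, y_2)\), sex-specific thresholds \(z_{s_1}, z_{s_2}\)
and zygosity correlation \(r\), the cell probabilities are orthant
probabilities of the bivariate normal; the log likelihood is the weighted
sum over pairs. Because outcomes are binary, the data collapse to weighted
counts per (zygosity, sex pattern, outcome pattern) cell, so one likelihood
evaluation costs a handful of orthant evaluations regardless of cohort
size. "Sex-adjusted" fits share components across sexes with sex-specific
thresholds and keep opposite-sex pairs (mixed-threshold term);
"sex-stratified" fits use same-sex pairs of one sex only, since an
opposite-sex pair has no single sex.

The tetrachoric correlation of a concordance table is the ML fit of this
same bivariate-normal model to a single 2×2 table under twin
exchangeability: double entry, a single threshold shared by both members,
and the discordant mass split evenly across the two off-diagonal cells.
The test suite checks the ML fit against an independent oracle that
grid-searches the correlation (step 1e-3, refined to 1e-5) and computes
orthant probabilities by one-dimensional numerical integration.

## Censoring, competing death, and IPCW

Death is a competing outcome, not censoring: a twin who dies without THA is
a fully observed non-case (the illness--death view of the trajectory).
Censoring means administrative window close or emigration only. The
cumulative incidence of THA is estimated by the Aalen--Johansen estimator
on the age scale with delayed entry at each twin's age at the window start
(`estimate_cif()`, via the multi-state machinery of the survival package),
which conserves probability: survival plus both cause-specific cumulative
incidences is 1 at every age.

For the variance-component fits, the binary outcome is "case by horizon
age \(h\)". `censoring_weights()` estimates the censoring survivor function
\(\hat G\) by a delayed-entry Kaplan--Meier of the censoring distribution
and gives each individual who is fully observed to \(h\) (case or death
before \(h\), or under observation at \(h\)) the weight
\(\hat G(\text{entry}-) / \hat G(\min(\text{exit}, h)-)\) — the inverse of
the conditional probability of escaping censoring from that individual's
own entry. Censored-before-horizon individuals get weight 0, as do
individuals who entered follow-up at or after \(h\): they were never under
observation for this outcome, since any qualifying operation would predate
the registry. A pair enters the weighted likelihood only when both members
are fully observed; its weight is the product of the member weights (the
simplest consistent pair-level rule; it is a swappable policy). Weights are
capped at 20 by default and capped counts are logged.

Two properties of this construction deserve emphasis:

* Under *random* censoring (e.g. emigration) the weights are classic IPCW:
  they sum to about the cohort size and the weighted outcome mean is an
  unbiased estimate of the cumulative onset probability. The test suite
  verifies both on an emigration-censored cohort.
* Under *administrative* censoring the close-out age is deterministic given
  entry age, so an individual entering at age \(e\) can never be observed
  in-study at \(h > e + \text{window}\). Positivity fails for that
  subgroup, no weighting can represent it, and the weight sum is not the
  cohort size. The weighted fit then estimates the liability correlation of
  the *observable* population — harmless when, as in the generative model,
  the correlation structure does not depend on birth cohort, but it is the
  reason the analysis horizon must sit within the support of the entry
  distribution.

## The registry blind spot

Operations before the window opening are invisible; affected individuals
appear as non-cases. For an individual entering at age \(e\), the observed
"case by \(h\)" indicator is therefore 1 only when the liability lies in a
*band*: above the threshold at \(\min(\text{death}, h)\) but below the
threshold at \(e\). The erased upper tail is shared within a pair (twins
enter together), and its mass grows with entry age. Band dichotomisation
is not threshold dichotomisation: the ML tetrachoric of banded outcomes is
attenuated, and more so for MZ than DZ pairs, because at high correlation
the pairs erased together are exactly the concordant-affected ones. The
estimated components inherit the distortion (a² down, c² up). This is a
property of the registry design itself, not of the estimator, and the real
study inherits the same limitation; the generator exposes it via
`emit_prevalent = TRUE`, which makes pre-window onsets visible and restores
near-unbiased recovery in simulation.

The default analysis horizon is **60 years**: under the calibrated onset
curve the erased onset mass is then at most a few percent of the horizon
onset mass for the oldest in-study entrants, while enough affected pairs
remain for the fit.
Higher horizons buy affected pairs at the price of rapidly growing
blind-spot attenuation; the replicate experiment in
`scripts/acceptance.R` quantifies what remains at 60.

## The synthetic cohort generator

`sim_params()` encodes the study conditions; `simulate_cohort()` draws the
cohort. Defaults:

* **Zygosity mix** 21.6% MZ / 37.6% same-sex DZ / 40.8% opposite-sex DZ
  (individual counts 20,327 / 35,363 / 38,373 of 94,063 rescaled to pair
  proportions); same-sex pairs are male with probability 1/2.
* **Components** \((a^2, d^2, c^2, e^2) = (0.47, 0, 0.21, 0.32)\), giving
  \(r_{MZ} = 0.68\), \(r_{DZ} = 0.445\).
* **Onset**: lifetime liability-scale prevalence 0.06 by age 100, with a
  Gaussian-shaped cumulative onset curve of location 69 and scale 9.5
  years. A single Gaussian shape cannot match every descriptive statistic
  of the source cohort at once; this location/scale balances three of them
  — a mean observed age at operation near 66 years, an observed case
  fraction near 0.9% under the 15.66-year window, and a cumulative
  incidence rising roughly four- to five-fold between ages 60 and 85 —
  landing at 65.0 years, 0.9% and 5–6-fold respectively. Onset
  probability is negligible before age 45 and rises sharply after 50.
* **Mortality**: Gompertz hazards \(3.5\times10^{-5} e^{0.094t}\) (men) and
  \(1.8\times10^{-5} e^{0.099t}\) (women) — standard Nordic actuarial
  levels, giving roughly 10% in-window deaths.
* **Calendar mechanics**: window 1995-01-01 to 2010-08-31; birth years
  1900–1975. The register's birth-year distribution is not published, so
  the default samples the range with weights equal to the probability that
  both pair members survive to the window start (the cohort is conditioned
  on being alive then) times an exponential ascertainment tilt
  \(e^{0.03(y - 1900)}\) standing in for growing twin ascertainment and
  birth numbers across the century. The tilt rate was set so in-window
  deaths land near the observed 11% and censoring in the observed 84–91%
  band. Emigration is independent exponential censoring at 0.002/year.
* **Mechanism**: a single time-invariant liability per person, assembled
  from A/D/C/E factor scores shared within pairs at the biometric
  correlations; onset age is the deterministic inverse of the threshold
  curve at the liability. The optional `age_effect` schedule re-weights
  the same factor scores with age-dependent loadings (liability then varies
  with age and onset is the first threshold crossing, found by a 0.5-year
  grid scan); constant loadings are the default.
* Pre-window onsets are emitted as non-cases unless `emit_prevalent`.

What the generator does *not* emulate: zygosity misclassification,
diagnosis coding error, liability-dependent mortality, secular trends in
surgery rates, or any difference in age structure between zygosity groups
(the real cohort's opposite-sex twins were younger, hence their higher
censored fraction; the simulator uses one birth distribution for all). A
passing recovery test therefore shows the estimator chain is correct under
this idealised data-generating process, not that the real study's
estimates are unbiased.

## Numerical choices

* Orthant probabilities via `mvtnorm::pmvnorm`; likelihood cells are
  clamped away from 0 and the optimiser objective returns a large finite
  value outside the feasible region.
* Optimisation: BFGS on unconstrained transforms (thresholds raw,
  correlations through atanh, simplex components through multinomial
  logit), relative tolerance 1e-12, up to five jittered restarts when the
  gradient check (max |g| below 1e-3 relative to the log likelihood)
  fails; non-converged fits are flagged, never silent.
* Confidence intervals: delta method on the transformed scale (Fisher-z
  for correlations, logit for components), truncated to the unit interval.
  Components estimated at the simplex boundary are reported as 0.00 with a
  one-sided (0, 1) interval.
* Likelihood-ratio tests use the plain chi-square reference without a
  boundary mixture correction, matching the df/p convention of standard
  biometric software output.
* Ages are exact day differences divided by 365.25. Ties between an
  operation and death or censoring on the same day go to the operation (a
  recorded operation implies the patient was alive). Zero-length
  at-risk intervals are nudged by 1e-3 years before survival fits.
* The saturated model frees, by default, separate same-sex and
  opposite-sex DZ correlations (`pool_dz = FALSE` — whether the original
  analysis pooled them is not stated); its free-parameter count is
  thresholds + correlations, which fixes the AIC convention.
* Age-resolved curves re-fit thresholds and components at every grid age
  (default 40–90 by 5 years); bootstrap CIs for concordance curves use
  B = 200 pair resamples with weights treated as fixed. Ages with no
  affected probands, or fewer affected pairs than `min_affected_pairs`,
  are flagged undefined rather than estimated.

## Problem sizes

Simulation experiments in the tests and the acceptance script use cohorts
of 45,000 pairs — the scale of the study base after exclusions — with 25
replicate seeds for the recovery experiment; unit tests use 2,000–45,000
pairs as the property demands. At these sizes a single ACE fit costs a few
seconds because the likelihood aggregates to cell counts.

## Known limitations

* The IPCW binary-outcome formulation identifies correlations of the
  observable population only; with purely administrative censoring, late
  horizons are unreachable (see above). A hazard-scale bivariate model
  (estimating the dependence from cumulative-incidence risk sets) would
  use the data more efficiently and escape the horizon restriction; it is
  out of scope here.
* The registry blind spot biases component estimates even at the default
  horizon; the recovery experiment measures the residual rather than
  pretending it away. Per-replicate sampling noise in a rare-trait ACE fit
  is large (the study's own a² interval spanned 12–79%), so 25-replicate
  means carry Monte-Carlo error of several percentage points.
* The ML tetrachoric applied to the published raw complete-pair counts
  reproduces the printed correlations for the male strata exactly but not
  for the MZ-female and opposite-sex strata, whose printed values appear
  to come from the weighted model-based fit rather than the raw tables;
  the raw-count estimates are reported as computed.
* No ascertainment correction beyond complete pairs; no sex-limitation
  models with distinct male/female components; no probabilistic record
  linkage (person identifiers are exact).
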