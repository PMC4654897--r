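# twinliab

Classical twin-design heritability analysis for a rare, late-onset binary
trait observed through registry linkage — motivated by primary hip
osteoarthritis severe enough to end in total hip arthroplasty (THA). The
package is written for genetic epidemiologists working with register-based
twin cohorts where the outcome is right-censored by a finite observation
window, death competes with the outcome, and twins enter follow-up at
whatever age they have reached when the registry opens.

## The model

A binary trait is the dichotomisation of a latent standard-normal liability
*L*: an individual is affected by age *t* when *L* > τ(*t*), with τ
strictly decreasing (incidence accumulates with age) and
τ = Φ⁻¹(1 − *q*) at prevalence *q*. Twin pairs share bivariate-normal
liabilities with correlation

  r_MZ = a² + d² + c²,  r_DZ = a²/2 + d²/4 + c²,

where a², d², c², e² are the additive-genetic, dominance, shared- and
unique-environment proportions of liability variance (broad-sense
heritability H² = a² + d²). The package fits the saturated model (free
correlation per zygosity group) and the ACE/ADE/AE/CE submodels by
maximising the weighted bivariate-probit likelihood of pair outcomes
"case by horizon age *h*", with inverse-probability-of-censoring weights
(IPCW) built from a delayed-entry Kaplan–Meier of the censoring
distribution. Death before *h* without THA is a fully observed non-case
(illness–death view), and the cumulative incidence of THA under competing
mortality is estimated by the Aalen–Johansen estimator. Pairwise /
proband-wise concordance, maximum-likelihood tetrachoric correlations,
model-based case-wise concordance Φ₂(z, z; ρ)/q, likelihood-ratio tests and
AIC, and age-resolved concordance and component curves complete the
pipeline. A synthetic twin-register generator with correlated liabilities,
age-dependent onset, competing Gompertz mortality and window censoring
makes every stage testable without register access.

## Worked example

```r
library(twinliab)

# a registry-style cohort at the default study conditions
cohort <- simulate_cohort(sim_params(n_pairs = 45000, seed = 20250901))
table(cohort$exit_cause) / nrow(cohort)
#>      case  censored     death
#> 0.0077000 0.8914444 0.1008556

# ML tetrachoric correlation from a published complete-pair table:
# 10 concordant-affected, 57 discordant, 4558 concordant-unaffected
tetrachoric(pair_table(10, 57, 4558, stratum = "MZM"))
#> Tetrachoric [MZM]: rho = 0.704 (95% CI 0.543 to 0.815), threshold = 2.394, logLik = -417.970

concordance_rates(pair_table(10, 57, 4558))$probandwise   # 2*10 / (2*10 + 57)
#> [1] 0.2597403

# case-wise concordance implied by the liability model at rho = 0.80, q = 6%
model_casewise(0.80, 0.06)
#> [1] 0.5116345

# IPCW ACE fit at the 60-year horizon
w   <- censoring_weights(cohort, 60)
fit <- fit_components(twin_pairs(cohort, weights = w), "ACE")
round(fit$components, 2)
#>   a2   d2   c2   e2
#> 0.45 0.00 0.32 0.23
```

The tetrachoric 0.70 says that monozygotic male pairs' latent liabilities
correlate at 0.70; the proband-wise concordance 0.26 is the probability a
twin undergoes THA given an affected co-twin; the case-wise value 0.51 is
the same probability implied by the fitted liability model at lifetime
scale. The ACE fit decomposes liability variance: here roughly half
additive-genetic with the balance environmental (the generating values
were 0.47 / 0.21 / 0.32; with fewer than two hundred affected pairs per
replicate, a single 45,000-pair cohort carries sampling noise of ten or
more points on each component, which is why the recovery experiment
averages 25 replicates).

The `analysis/` directory holds the full workflow as numbered scripts —
`01_simulate_cohort.R` through `05_age_dynamics.R` (cohort generation,
concordance tables, biometric models, competing-risk cumulative incidence,
age-resolved curves). Each is a thin driver over the package functions,
prints what it finds, and writes its tables under `results/`.

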