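#' Simulation parameters for a synthetic twin cohort
#'
#' Bundles everything the cohort generator needs: the liability variance
#' decomposition, the age-dependent onset threshold, sex-specific competing
#' mortality, the registry observation window, and the zygosity mix.
#'
#' The defaults describe a Danish-register-style study population: a
#' zygosity mix matching a nationwide twin cohort of 94,063 individuals
#' (21.6\% MZ, 37.6\% same-sex DZ, 40.8\% opposite-sex DZ), a lifetime
#' liability-scale prevalence of 6\% for the case-defining operation, onset
#' probability rising sharply after age 50, variance components
#' (a2, d2, c2, e2) = (0.47, 0, 0.21, 0.32), and a 15.66-year observation
#' window (1995-01-01 to 2010-08-31) yielding roughly 0.9\% observed cases
#' and 84--91\% right censoring.
#'
#' @param a2,d2,c2,e2 Proportions of liability variance from additive
#'   genetic, non-additive (dominance) genetic, common-environment and
#'   unique-environment sources. Must be non-negative and sum to 1.
#' @param n_pairs Number of twin pairs to simulate (pairs retained are those
#'   with both members alive at the window start).
#' @param prevalence Lifetime liability-scale prevalence: the probability of
#'   onset by `ref_age` in the absence of death and censoring.
#' @param onset_mean,onset_sd Location/scale (years) of the Gaussian shape of
#'   the cumulative onset curve; together with `prevalence` and `ref_age`
#'   they define the monotone decreasing probit threshold `tau(t)`.
#' @param ref_age Reference age (years) at which the cumulative onset
#'   probability equals `prevalence`.
#' @param mortality List with elements `male` and `female`, each
#'   `c(rate = , shape = )` for a Gompertz hazard `rate * exp(shape * age)`
#'   (per year). `NULL` disables mortality.
#' @param window_start,window_end Calendar dates (ISO-8601 strings or Dates)
#'   delimiting the registry observation window.
#' @param birth_range Two-element numeric vector of birth years. The range
#'   is an arbitrary but documented default (registries do not publish the
#'   cohort's birth-year distribution).
#' @param birth_tilt Exponential growth rate (per year) of the birth-cohort
#'   sampling weight across `birth_range`, emulating growing twin
#'   ascertainment and birth numbers across the century; sampling weights
#'   are additionally thinned by the probability that both pair members
#'   survive to the window start, since the cohort is conditioned on being
#'   alive then. `0` gives uniform births.
#' @param zygosity_mix Named proportions for `MZ`, `DZSS`, `DZOS` pairs;
#'   must sum to 1.
#' @param emigration_rate Rate (per year) of an independent exponential
#'   censoring process standing in for emigration/loss to follow-up.
#' @param age_effect Optional age-varying loading schedule: a list with
#'   elements `ages` (grid, years) and `a2`, `c2`, `e2` (and optionally
#'   `d2`) giving variance proportions at each grid age (each row summing
#'   to 1). Liability is then a weighted sum of fixed person-level A/D/C/E
#'   factor scores with age-dependent loadings. `NULL` means constant
#'   loadings.
#' @param emit_prevalent If `TRUE`, individuals whose onset precedes study
#'   entry are still emitted as cases (with onset age as exit); the default
#'   `FALSE` mirrors a registry that opens at the window start and silently
#'   converts pre-window onsets to non-cases.
#' @param seed Integer seed; the generator is deterministic given the seed.
#'
#' @return An object of class `sim_params` (a validated list).
#' @examples
#' p <- sim_params(n_pairs = 500, seed = 1)
#' p$zygosity_mix
#' @export
sim_params <- function(a2 = 0.47, d2 = 0, c2 = 0.21, e2 = 0.32,
                       n_pairs = 45000,
                       prevalence = 0.06,
                       onset_mean = 69, onset_sd = 9.5, ref_age = 100,
                       mortality = list(male   = c(rate = 3.5e-5, shape = 0.094),
                                        female = c(rate = 1.8e-5, shape = 0.099)),
                       window_start = "1995-01-01", window_end = "2010-08-31",
                       birth_range = c(1900, 1975),
                       birth_tilt = 0.03,
                       zygosity_mix = c(MZ = 20327, DZSS = 35363, DZOS = 38373) / 94063,
                       emigration_rate = 0.002,
                       age_effect = NULL,
                       emit_prevalent = FALSE,
                       seed = NULL) {
  comp <- c(a2 = a2, d2 = d2, c2 = c2, e2 = e2)
  if (any(!is.finite(comp)) || any(comp < 0) || any(comp > 1))
    stop("variance proportions must lie in [0, 1]")
  if (abs(sum(comp) - 1) > 1e-12)
    stop("variance proportions must sum to 1 (got ", format(sum(comp), digits = 15), ")")
  if (!is.numeric(n_pairs) || length(n_pairs) != 1 || n_pairs <= 0)
    stop("n_pairs must be a positive count")
  if (prevalence <= 0 || prevalence >= 1) stop("prevalence must be in (0, 1)")
  if (onset_sd <= 0) stop("onset_sd must be positive")
  zygosity_mix <- zygosity_mix[c("MZ", "DZSS", "DZOS")]
  if (anyNA(zygosity_mix) || abs(sum(zygosity_mix) - 1) > 1e-8)
    stop("zygosity_mix must contain MZ, DZSS, DZOS and sum to 1")
  window_start <- as.Date(window_start); window_end <- as.Date(window_end)
  if (!(window_start < window_end)) stop("window_start must precede window_end")
  if (length(birth_range) != 2 || birth_range[1] > birth_range[2])
    stop("birth_range must be an increasing pair of years")
  if (!is.null(mortality)) {
    for (s in c("male", "female")) {
      m <- mortality[[s]]
      if (is.null(m) || any(!is.finite(m[c("rate", "shape")])) || any(m[c("rate", "shape")] < 0))
        stop("mortality must supply non-negative rate and shape for each sex")
    }
  }
  if (!is.null(age_effect)) age_effect <- validate_age_effect(age_effect, d2)
  p <- list(a2 = a2, d2 = d2, c2 = c2, e2 = e2, n_pairs = as.integer(n_pairs),
            prevalence = prevalence, onset_mean = onset_mean, onset_sd = onset_sd,
            ref_age = ref_age, mortality = mortality,
            window_start = window_start, window_end = window_end,
            birth_range = as.numeric(birth_range), birth_tilt = birth_tilt,
            zygosity_mix = zygosity_mix,
            emigration_rate = emigration_rate, age_effect = age_effect,
            emit_prevalent = isTRUE(emit_prevalent), seed = seed)
  class(p) <- "sim_params"
  p
}

validate_age_effect <- function(age_effect, d2) {
  need <- c("ages", "a2", "c2", "e2")
  if (!all(need %in% names(age_effect)))
    stop("age_effect needs elements ages, a2, c2, e2 (optionally d2)")
  n <- length(age_effect$ages)
  if (is.unsorted(age_effect$ages, strictly = TRUE))
    stop("age_effect$ages must be strictly increasing")
  if (is.null(age_effect$d2)) age_effect$d2 <- rep(0, n)
  tot <- age_effect$a2 + age_effect$d2 + age_effect$c2 + age_effect$e2
  if (any(lengths(age_effect[c("a2", "d2", "c2", "e2")]) != n))
    stop("age_effect loading vectors must match length(ages)")
  if (any(abs(tot - 1) > 1e-8))
    stop("age_effect proportions must sum to 1 at every grid age")
  age_effect
}

#' @export
print.sim_params <- function(x, ...) {
  cat("Twin-cohort simulation parameters\n")
  cat(sprintf("  components  a2=%.3f d2=%.3f c2=%.3f e2=%.3f  (rMZ=%.3f, rDZ=%.3f)\n",
              x$a2, x$d2, x$c2, x$e2, x$a2 + x$d2 + x$c2,
              0.5 * x$a2 + 0.25 * x$d2 + x$c2))
  cat(sprintf("  pairs       %d  (MZ %.3f / DZSS %.3f / DZOS %.3f)\n",
              x$n_pairs, x$zygosity_mix["MZ"], x$zygosity_mix["DZSS"], x$zygosity_mix["DZOS"]))
  cat(sprintf("  onset       lifetime prevalence %.3f by age %g; shape N(%g, %g)\n",
              x$prevalence, x$ref_age, x$onset_mean, x$onset_sd))
  cat(sprintf("  window      %s to %s; births %g-%g\n",
              format(x$window_start), format(x$window_end),
              x$birth_range[1], x$birth_range[2]))
  invisible(x)
}

#' Age-dependent liability threshold
#'
#' The cumulative onset probability by age `t` (ignoring death and
#' censoring) is `F(t) = prevalence * pnorm(t, onset_mean, onset_sd) /
#' pnorm(ref_age, onset_mean, onset_sd)`; the probit threshold is
#' `tau(t) = qnorm(1 - F(t))`, strictly decreasing in age so that incidence
#' accumulates.
#'
#' @param age Ages in years (vectorised).
#' @param params A [sim_params()] object.
#' @return `liability_threshold`: threshold values (probit units).
#' @export
liability_threshold <- function(age, params) {
  stats::qnorm(1 - cumulative_onset(age, params))
}

#' @rdname liability_threshold
#' @return `cumulative_onset`: the latent cumulative onset probability
#'   `F(age)` (no death, no censoring).
#' @export
cumulative_onset <- function(age, params) {
  params$prevalence *
    stats::pnorm(age, params$onset_mean, params$onset_sd) /
    stats::pnorm(params$ref_age, params$onset_mean, params$onset_sd)
}

#' Onset age implied by a liability value
#'
#' Inverts the threshold curve: onset occurs at the age where the (constant)
#' liability first exceeds `tau(t)`; liabilities that never cross the
#' threshold by `ref_age` yield `Inf`.
#'
#' @param liability Standard-normal liability values.
#' @param params A [sim_params()] object.
#' @return Onset ages in years (`Inf` when onset never occurs).
#' @export
onset_age <- function(liability, params) {
  zmax <- stats::pnorm(params$ref_age, params$onset_mean, params$onset_sd)
  p <- stats::pnorm(liability, lower.tail = FALSE)          # survivor mass above liability
  frac <- p * zmax / params$prevalence                      # pnorm((T - mean)/sd) at onset
  out <- rep(Inf, length(liability))
  hit <- p < params$prevalence                              # crosses the threshold by ref_age
  out[hit] <- params$onset_mean + params$onset_sd * stats::qnorm(frac[hit])
  out
}
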