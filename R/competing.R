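#' Cumulative incidence under competing risks (Aalen-Johansen)
#'
#' Estimates the cause-specific cumulative incidence of the case event with
#' death as a competing risk, on the age scale with delayed entry at each
#' twin's age at study start, via the Aalen-Johansen estimator
#' ([survival::survfit()] multi-state machinery). Standard errors use the
#' standard infinitesimal-jackknife variance.
#'
#' @param cohort A `twin_cohort`.
#' @param by_sex Estimate separate curves per sex.
#' @param grid Age grid (years) on which curves are evaluated; default: 1-year
#'   steps spanning the observed exit ages.
#' @return A `cif_curve` data.frame with columns `sex` (or `"pooled"`),
#'   `age`, `cause` (`case`/`death`), `cif`, `se`, `n_risk`, plus the overall
#'   survival column `surv` satisfying `surv + sum(cif) = 1` at every age.
#' @export
estimate_cif <- function(cohort, by_sex = FALSE, grid = NULL) {
  d <- as.data.frame(cohort)
  if (all(d$exit_cause == "censored"))
    warning("all observations censored; cumulative incidence is identically zero")
  # survfit needs strictly positive sojourn: nudge zero-length intervals
  eps <- 1e-3
  same <- d$exit_age <= d$entry_age
  d$exit_age[same] <- d$entry_age[same] + eps
  d$state <- factor(d$exit_cause, levels = c("censored", "case", "death"))
  if (is.null(grid)) {
    grid <- seq(floor(min(d$entry_age)), ceiling(max(d$exit_age)), by = 1)
  }
  one <- function(dd, label) {
    fit <- survival::survfit(survival::Surv(entry_age, exit_age, state) ~ 1,
                             data = dd, id = person_id)
    s <- summary(fit, times = grid, extend = TRUE)
    states <- s$states
    ic <- which(states == "case"); id_ <- which(states == "death")
    i0 <- which(states == "(s0)")
    nrisk <- cbind(s$n.risk)[, i0]
    data.frame(sex = label,
               age = rep(grid, 2),
               cause = rep(c("case", "death"), each = length(grid)),
               cif = c(s$pstate[, ic], s$pstate[, id_]),
               se = c(s$std.err[, ic], s$std.err[, id_]),
               n_risk = rep(nrisk, 2),
               surv = rep(s$pstate[, i0], 2),
               stringsAsFactors = FALSE)
  }
  out <- if (by_sex) {
    do.call(rbind, lapply(split(d, d$sex), function(dd) one(dd, dd$sex[1])))
  } else {
    one(d, "pooled")
  }
  rownames(out) <- NULL
  class(out) <- c("cif_curve", "data.frame")
  out
}

# left-continuous censoring survivor function G(t-) from a delayed-entry
# Kaplan-Meier of the censoring distribution
censoring_km <- function(d) {
  eps <- 1e-3
  same <- d$exit_age <= d$entry_age
  d$exit_age[same] <- d$entry_age[same] + eps
  cens <- as.integer(d$exit_cause == "censored")
  fit <- survival::survfit(survival::Surv(entry_age, exit_age, cens) ~ 1, data = d)
  times <- fit$time[fit$n.event > 0]
  surv <- fit$surv[fit$n.event > 0]
  function(t) {
    pos <- findInterval(t - 1e-9, times)
    c(1, surv)[pos + 1]
  }
}

#' Inverse-probability-of-censoring weights for a horizon outcome
#'
#' Builds the per-individual weighted binary outcome "case by
#' `horizon_age`". The censoring distribution `G` is estimated by
#' Kaplan-Meier on the age scale with delayed entry, treating administrative
#' end of window and emigration as censoring; death is an outcome state, so
#' a death before the horizon without the case event is a fully observed
#' non-case, not a censoring. An individual fully observed to the horizon
#' (case or death before it, or still under observation at it) receives
#' weight `G(entry_age-) / G(min(exit_age, horizon)-)` -- the inverse of the
#' conditional probability of escaping censoring from their own delayed
#' entry, so that weights self-normalise to the eligible cohort size; an
#' individual censored before the horizon receives weight 0. Individuals
#' who entered at or after the horizon are not under observation for the
#' outcome and are excluded (weight 0, not fully observed).
#'
#' @param cohort A `twin_cohort`.
#' @param horizon_age Outcome horizon in years.
#' @param stratify_by_sex Estimate `G` separately per sex.
#' @param cap Upper bound on weights; capped individuals are counted in
#'   attribute `n_capped`.
#' @return A data.frame (`person_id`, `pair_id`, `sex`, `zygosity`,
#'   `response`, `weight`, `fully_observed`) of class `weighted_outcome`.
#' @export
censoring_weights <- function(cohort, horizon_age, stratify_by_sex = FALSE, cap = 20) {
  d <- as.data.frame(cohort)
  Gfun <- if (stratify_by_sex) {
    fns <- lapply(split(d, d$sex), censoring_km)
    function(t, sex) {
      out <- numeric(length(t))
      for (s in names(fns)) out[sex == s] <- fns[[s]](t[sex == s])
      out
    }
  } else {
    fn <- censoring_km(d)
    function(t, sex) fn(t)
  }
  # delayed entry: an individual who entered at or after the horizon was
  # never under observation for "case by horizon" (any such onset predates
  # the registry window) and cannot contribute at this horizon
  eligible <- d$entry_age < horizon_age
  is_case <- eligible & d$exit_cause == "case" & d$exit_age <= horizon_age
  is_death <- eligible & d$exit_cause == "death" & d$exit_age <= horizon_age
  in_study <- eligible & d$exit_age >= horizon_age
  fully <- is_case | is_death | in_study
  tstar <- pmin(d$exit_age, horizon_age)
  G <- Gfun(tstar, d$sex)
  Gentry <- Gfun(d$entry_age, d$sex)
  if (any(fully & G <= 0))
    stop("censoring survivor function reaches 0 before the horizon; ",
         "use a lower horizon_age or rely on the weight cap at an earlier age")
  w <- ifelse(fully, Gentry / G, 0)
  n_capped <- sum(w > cap)
  w <- pmin(w, cap)
  out <- data.frame(person_id = d$person_id, pair_id = d$pair_id,
                    sex = d$sex, zygosity = d$zygosity,
                    horizon_age = horizon_age,
                    response = as.integer(is_case),
                    weight = w, fully_observed = fully,
                    stringsAsFactors = FALSE)
  attr(out, "n_capped") <- n_capped
  class(out) <- c("weighted_outcome", "data.frame")
  out
}
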