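#' Simulate a registry-style twin cohort
#'
#' Generates twin pairs with correlated standard-normal liabilities
#' (`rMZ = a2 + d2 + c2`, `rDZ = a2/2 + d2/4 + c2`), converts each
#' liability to an onset age through the monotone age threshold, draws
#' sex-specific Gompertz death ages conditional on both members being alive
#' at the window start, and applies administrative end-of-window and
#' independent emigration censoring. Onsets that precede study entry are
#' unobservable to the registry and are emitted as non-cases unless
#' `emit_prevalent` is set.
#'
#' Liability is assembled from person-level factor scores (A shared fully
#' in MZ pairs, with correlation 1/2 in DZ pairs; D shared fully in MZ,
#' correlation 1/4 in DZ; C shared fully in all pairs; E independent), so an
#' `age_effect` schedule can re-weight the same scores at different ages.
#'
#' @param params A [sim_params()] object.
#' @return A `data.frame` with one row per twin: `person_id`, `pair_id`,
#'   `member_index`, `sex`, `zygosity` (`MZ`/`DZSS`/`DZOS`), `birth_date`,
#'   `entry_age`, `exit_age`, `exit_cause` (`case`/`death`/`censored`),
#'   `diagnosis_code` (ICD-10, cases only). Attribute `truth` holds the
#'   latent per-person liability, onset age and death age; attribute
#'   `params` the generating parameters. The same seed reproduces the same
#'   cohort exactly.
#' @examples
#' coh <- simulate_cohort(sim_params(n_pairs = 2000, seed = 42))
#' table(coh$exit_cause)
#' @export
simulate_cohort <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  if (!is.null(params$seed)) set.seed(params$seed)
  n <- params$n_pairs

  zyg <- sample(c("MZ", "DZSS", "DZOS"), n, replace = TRUE, prob = params$zygosity_mix)
  # sexes: same-sex pairs are male with prob 1/2; OS pairs get one of each,
  # member order randomised
  ss_male <- stats::runif(n) < 0.5
  sex1 <- ifelse(zyg == "DZOS", NA, ifelse(ss_male, "male", "female"))
  os_first_male <- stats::runif(n) < 0.5
  sex1[zyg == "DZOS"] <- ifelse(os_first_male[zyg == "DZOS"], "male", "female")
  sex2 <- ifelse(zyg == "DZOS", ifelse(sex1 == "male", "female", "male"), sex1)

  # factor scores; sharing by zygosity
  mz <- zyg == "MZ"
  shareA <- ifelse(mz, 1, 0.5)
  shareD <- ifelse(mz, 1, 0.25)
  A <- shared_factor(n, shareA)
  D <- shared_factor(n, shareD)
  Cs <- stats::rnorm(n); C1 <- Cs; C2 <- Cs
  E1 <- stats::rnorm(n); E2 <- stats::rnorm(n)

  birth_year <- draw_birth_years(n, sex1, sex2, params)
  birth_date <- as.Date("1970-01-01") + round((birth_year - 1970) * 365.25)
  entry_age <- pmax(0, as.numeric(params$window_start - birth_date) / 365.25)

  onset1 <- onset_from_factors(A$f1, D$f1, C1, E1, params)
  onset2 <- onset_from_factors(A$f2, D$f2, C2, E2, params)

  death1 <- draw_death_age(sex1, entry_age, params)
  death2 <- draw_death_age(sex2, entry_age, params)

  emi1 <- draw_emigration(entry_age, params)
  emi2 <- draw_emigration(entry_age, params)
  admin <- as.numeric(params$window_end - birth_date) / 365.25  # age at window close

  rec <- function(member, sexm, onset, death, emi) {
    obs_onset <- onset
    if (!params$emit_prevalent) obs_onset[onset <= entry_age] <- Inf
    cens <- pmin(admin, emi)
    exit <- pmin(obs_onset, death, cens)
    # tie rule: a recorded operation implies alive at operation, so the case
    # wins an exact tie with death or censoring
    cause <- ifelse(obs_onset <= exit, "case",
                    ifelse(death <= exit, "death", "censored"))
    data.frame(
      person_id = sprintf("P%07d", (seq_len(n) - 1L) * 2L + member),
      pair_id = sprintf("T%06d", seq_len(n)),
      member_index = member,
      sex = sexm,
      zygosity = zyg,
      birth_date = birth_date,
      entry_age = entry_age,
      exit_age = pmax(exit, entry_age),
      exit_cause = cause,
      diagnosis_code = ifelse(obs_onset <= exit,
                              sample(c("M16.0", "M16.1"), n, replace = TRUE, prob = c(0.8, 0.2)),
                              NA_character_),
      stringsAsFactors = FALSE
    )
  }
  out <- rbind(rec(1L, sex1, onset1, death1, emi1),
               rec(2L, sex2, onset2, death2, emi2))
  out <- out[order(out$pair_id, out$member_index), ]
  rownames(out) <- NULL

  lia1 <- constant_liability(A$f1, D$f1, C1, E1, params)
  lia2 <- constant_liability(A$f2, D$f2, C2, E2, params)
  truth <- data.frame(
    person_id = c(sprintf("P%07d", (seq_len(n) - 1L) * 2L + 1L),
                  sprintf("P%07d", (seq_len(n) - 1L) * 2L + 2L)),
    pair_id = rep(sprintf("T%06d", seq_len(n)), 2),
    liability = c(lia1, lia2),
    onset_age = c(onset1, onset2),
    death_age = c(death1, death2),
    stringsAsFactors = FALSE
  )
  truth <- truth[order(truth$pair_id, truth$person_id), ]
  rownames(truth) <- NULL
  attr(out, "truth") <- truth
  attr(out, "params") <- params
  class(out) <- c("twin_cohort", "data.frame")
  out
}

# Birth years over the range, weighted by the probability that both pair
# members survive to the window start under the Gompertz model: a register
# cohort alive at study entry is mortality-thinned, so old birth cohorts
# contribute few pairs. Uniform when mortality is disabled.
draw_birth_years <- function(n, sex1, sex2, params) {
  lo <- params$birth_range[1]; hi <- params$birth_range[2]
  tilt <- params$birth_tilt %||% 0
  if (is.null(params$mortality) && tilt == 0) return(stats::runif(n, lo, hi))
  yrs <- seq(lo, hi, by = 0.25)
  entry <- pmax(0, as.numeric(params$window_start - as.Date("1970-01-01")) / 365.25 - (yrs - 1970))
  Sg <- function(t, m) exp(-m[["rate"]] / m[["shape"]] * (exp(m[["shape"]] * t) - 1))
  Sm <- if (is.null(params$mortality)) rep(1, length(entry)) else Sg(entry, params$mortality$male)
  Sf <- if (is.null(params$mortality)) rep(1, length(entry)) else Sg(entry, params$mortality$female)
  ramp <- exp(tilt * (yrs - lo))
  Sm <- Sm * sqrt(ramp); Sf <- Sf * sqrt(ramp)
  pick <- function(w, k) {
    if (k == 0) return(numeric(0))
    cw <- cumsum(w / sum(w))
    yrs[findInterval(stats::runif(k), cw) + 1] + stats::runif(k, 0, 0.25)
  }
  out <- numeric(n)
  mm <- sex1 == "male" & sex2 == "male"
  ff <- sex1 == "female" & sex2 == "female"
  os <- !mm & !ff
  out[mm] <- pick(Sm * Sm, sum(mm))
  out[ff] <- pick(Sf * Sf, sum(ff))
  out[os] <- pick(Sm * Sf, sum(os))
  out
}

# bivariate standard normal with correlation `share` per pair
shared_factor <- function(n, share) {
  z0 <- stats::rnorm(n); z1 <- stats::rnorm(n); z2 <- stats::rnorm(n)
  s <- sqrt(share)
  u <- sqrt(1 - share)
  list(f1 = s * z0 + u * z1, f2 = s * z0 + u * z2)
}

constant_liability <- function(A, D, C, E, params) {
  sqrt(params$a2) * A + sqrt(params$d2) * D + sqrt(params$c2) * C + sqrt(params$e2) * E
}

# onset age given factor scores; closed form for constant loadings, grid
# scan of the age-varying liability when an age_effect schedule is present
onset_from_factors <- function(A, D, C, E, params) {
  ae <- params$age_effect
  if (is.null(ae)) return(onset_age(constant_liability(A, D, C, E, params), params))
  grid <- seq(max(1, min(ae$ages)), params$ref_age, by = 0.5)
  wa <- sqrt(stats::approx(ae$ages, ae$a2, grid, rule = 2)$y)
  wd <- sqrt(stats::approx(ae$ages, ae$d2, grid, rule = 2)$y)
  wc <- sqrt(stats::approx(ae$ages, ae$c2, grid, rule = 2)$y)
  we <- sqrt(stats::approx(ae$ages, ae$e2, grid, rule = 2)$y)
  tau <- liability_threshold(grid, params)
  out <- rep(Inf, length(A))
  # chunk to bound the individuals x ages matrix
  idx <- split(seq_along(A), ceiling(seq_along(A) / 20000))
  for (ii in idx) {
    L <- outer(A[ii], wa) + outer(D[ii], wd) + outer(C[ii], wc) + outer(E[ii], we)
    crossed <- sweep(L, 2, tau, ">")
    first <- apply(crossed, 1, function(z) if (any(z)) which(z)[1] else NA_integer_)
    out[ii][!is.na(first)] <- grid[first[!is.na(first)]]
  }
  out
}

# Gompertz death age conditional on surviving to the entry age (pairs are
# retained only when both members are alive at the window start; sampling
# conditionally is the equivalent efficient construction)
draw_death_age <- function(sex, entry_age, params) {
  if (is.null(params$mortality)) return(rep(Inf, length(sex)))
  rate <- ifelse(sex == "male", params$mortality$male["rate"], params$mortality$female["rate"])
  shape <- ifelse(sex == "male", params$mortality$male["shape"], params$mortality$female["shape"])
  u <- stats::runif(length(sex))
  ifelse(shape <= 0 | rate <= 0, Inf,
         log(exp(shape * entry_age) - (shape / rate) * log(u)) / shape)
}

draw_emigration <- function(entry_age, params) {
  if (is.null(params$emigration_rate) || params$emigration_rate <= 0)
    return(rep(Inf, length(entry_age)))
  entry_age + stats::rexp(length(entry_age), params$emigration_rate)
}

#' Write a simulated cohort as registry-style delimited files
#'
#' Emits the two files the linkage pipeline consumes plus a truth file for
#' recovery experiments: `twins.csv` (person id, pair id, sex, zygosity,
#' birth date, death/emigration dates), `events.csv` (person id, operation
#' date, ICD-10 diagnosis code, one row per operation) and `truth.csv`
#' (latent liability, onset age, death age, generating components).
#'
#' @param cohort Output of [simulate_cohort()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the three file paths.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "twin_cohort"))
  params <- attr(cohort, "params")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  age_to_date <- function(birth, age) birth + round(age * 365.25)

  # censoring before the administrative window close is emigration; record
  # it so the linkage round-trip reproduces the same exit ages
  admin_age <- as.numeric(params$window_end - cohort$birth_date) / 365.25
  emigrated <- cohort$exit_cause == "censored" & cohort$exit_age < admin_age - 1e-6
  twins <- data.frame(
    person_id = cohort$person_id,
    pair_id = cohort$pair_id,
    sex = cohort$sex,
    zygosity = cohort$zygosity,
    birth_date = format(cohort$birth_date),
    death_date = ifelse(cohort$exit_cause == "death",
                        format(age_to_date(cohort$birth_date, cohort$exit_age)), ""),
    emigration_date = ifelse(emigrated,
                             format(age_to_date(cohort$birth_date, cohort$exit_age)), ""),
    stringsAsFactors = FALSE
  )
  events <- cohort[cohort$exit_cause == "case", ]
  events <- data.frame(
    person_id = events$person_id,
    operation_date = format(age_to_date(events$birth_date, events$exit_age)),
    diagnosis_code = events$diagnosis_code,
    stringsAsFactors = FALSE
  )
  truth <- attr(cohort, "truth")
  truth$a2 <- params$a2; truth$d2 <- params$d2
  truth$c2 <- params$c2; truth$e2 <- params$e2

  paths <- file.path(dir, c("twins.csv", "events.csv", "truth.csv"))
  data.table::fwrite(twins, paths[1])
  data.table::fwrite(events, paths[2])
  data.table::fwrite(truth, paths[3])
  invisible(paths)
}
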