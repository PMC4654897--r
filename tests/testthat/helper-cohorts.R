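# Shared simulated cohorts, built once per test run and reused across files.

.sim_cache <- new.env(parent = emptyenv())

cached_cohort <- function(key, params) {
  if (!exists(key, envir = .sim_cache)) {
    assign(key, simulate_cohort(params), envir = .sim_cache)
  }
  get(key, envir = .sim_cache)
}

# register-style cohort at study defaults
default_cohort <- function(n_pairs = 45000, seed = 20250901) {
  cached_cohort(sprintf("default_%d_%d", n_pairs, seed),
                sim_params(n_pairs = n_pairs, seed = seed))
}

# fully observed lifetime cohort: no death, no emigration, entry at ~0,
# window long enough to cover every onset
lifetime_params <- function(n_pairs, seed, emigration_rate = 0, ...) {
  sim_params(n_pairs = n_pairs, seed = seed, mortality = NULL,
             emigration_rate = emigration_rate,
             birth_range = c(1993, 1994), birth_tilt = 0,
             window_start = "1995-01-01", window_end = "2120-01-01", ...)
}

lifetime_cohort <- function(n_pairs = 45000, seed = 915) {
  cached_cohort(sprintf("lifetime_%d_%d", n_pairs, seed),
                lifetime_params(n_pairs, seed))
}

# small hand-written registry fixture: 3 clean pairs by default
write_twin_fixture <- function(dir = withr::local_tempdir(),
                               rows = NULL) {
  if (is.null(rows)) {
    rows <- data.frame(
      person_id = c("A1", "A2", "B1", "B2", "C1", "C2"),
      pair_id = c("pA", "pA", "pB", "pB", "pC", "pC"),
      sex = c("male", "male", "female", "female", "male", "female"),
      zygosity = c("MZ", "MZ", "DZSS", "DZSS", "DZOS", "DZOS"),
      birth_date = c("1940-05-01", "1940-05-01", "1930-11-12", "1930-11-12",
                     "1955-02-28", "1955-02-28"),
      death_date = c("", "", "", "2001-03-15", "", ""),
      emigration_date = "",
      stringsAsFactors = FALSE
    )
  }
  path <- file.path(dir, "twins.csv")
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  path
}

write_event_fixture <- function(dir = withr::local_tempdir(), rows = NULL) {
  if (is.null(rows)) {
    rows <- data.frame(
      person_id = c("A1", "A1", "C2"),
      operation_date = c("2000-06-01", "2002-07-01", "2005-01-20"),
      diagnosis_code = c("M16.0", "M161", "M16.1"),
      stringsAsFactors = FALSE
    )
  }
  path <- file.path(dir, "events.csv")
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  path
}

toy_cif_cohort <- function() {
  # 8 individuals, entry 0: censored 50, case 55, death 60, case 62,
  # censored 65, case 70, death 72, censored 80
  data.frame(
    person_id = sprintf("I%d", 1:8),
    pair_id = sprintf("p%d", rep(1:4, each = 2)),
    member_index = rep(1:2, 4),
    sex = rep("male", 8),
    zygosity = rep("MZ", 8),
    birth_date = as.Date("1930-01-01"),
    entry_age = 0,
    exit_age = c(50, 55, 60, 62, 65, 70, 72, 80),
    exit_cause = c("censored", "case", "death", "case", "censored", "case", "death", "censored"),
    diagnosis_code = NA_character_,
    stringsAsFactors = FALSE
  )
}
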