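test_that("clean registry fixtures load as-is", {
  dir <- withr::local_tempdir()
  tw <- load_twin_register(write_twin_fixture(dir))
  expect_identical(nrow(tw), 6L)
  expect_identical(length(unique(tw$pair_id)), 3L)
  ev <- load_event_register(write_event_fixture(dir))
  expect_identical(nrow(ev), 3L)   # bilateral rows both retained at this stage
  expect_s3_class(ev$operation_date, "Date")
})

test_that("loader validation: singletons, bad dates, sex/zygosity conflicts", {
  dir <- withr::local_tempdir()
  rows <- data.frame(person_id = c("A1", "A2", "B1"),
                     pair_id = c("pA", "pA", "pB"),
                     sex = c("male", "male", "female"),
                     zygosity = c("MZ", "MZ", "MZ"),
                     birth_date = c("1940-05-01", "1940-05-01", "1950-01-01"),
                     stringsAsFactors = FALSE)
  expect_warning(tw <- load_twin_register(write_twin_fixture(dir, rows)), "pB")
  expect_identical(nrow(tw), 2L)

  rows2 <- rows[1:2, ]; rows2$sex <- c("male", "female")
  expect_error(suppressWarnings(load_twin_register(write_twin_fixture(dir, rows2))), "pA")

  rows3 <- rows[1:2, ]; rows3$person_id <- c("A1", "A1")
  expect_error(load_twin_register(write_twin_fixture(dir, rows3)), "duplicate")

  rows4 <- rows[1:2, ]; rows4$birth_date <- c("1940-05-01", "05/01/1940")
  expect_error(load_twin_register(write_twin_fixture(dir, rows4)), "birth_date")

  expect_error(load_twin_register(file.path(dir, "nope.csv")), "not found")

  evrows <- data.frame(person_id = "A1", operation_date = "June 2000",
                       diagnosis_code = "M16.0", stringsAsFactors = FALSE)
  expect_error(load_event_register(write_event_fixture(dir, evrows)), "row")

  # empty event register is fine
  empty <- data.frame(person_id = character(), operation_date = character(),
                      diagnosis_code = character())
  expect_identical(nrow(load_event_register(write_event_fixture(dir, empty))), 0L)
})

test_that("cohort assembly applies whitelist, dedupe and tie rules", {
  dir <- withr::local_tempdir()
  tw <- load_twin_register(write_twin_fixture(dir))
  # A1 has two qualifying ops (dotted + undotted codes): first defines exit;
  # C2 has one; B2 died in 2001
  ev <- load_event_register(write_event_fixture(dir))
  coh <- build_analysis_cohort(tw, ev)
  a1 <- coh[coh$person_id == "A1", ]
  expect_identical(a1$exit_cause, "case")
  expect_equal(a1$exit_age, as.numeric(as.Date("2000-06-01") - as.Date("1940-05-01")) / 365.25)
  expect_identical(coh$exit_cause[coh$person_id == "C2"], "case")
  expect_identical(coh$exit_cause[coh$person_id == "B2"], "death")
  expect_identical(coh$exit_cause[coh$person_id == "B1"], "censored")
  # non-whitelist code is a non-case
  ev2 <- load_event_register(write_event_fixture(dir, data.frame(
    person_id = "B1", operation_date = "2003-01-01", diagnosis_code = "M16.2")))
  coh2 <- build_analysis_cohort(tw, ev2)
  expect_identical(coh2$exit_cause[coh2$person_id == "B1"], "censored")
  # event for unknown person is dropped with a message
  ev3 <- load_event_register(write_event_fixture(dir, data.frame(
    person_id = "ZZ", operation_date = "2003-01-01", diagnosis_code = "M16.0")))
  expect_message(coh3 <- build_analysis_cohort(tw, ev3), "dropped")
  expect_identical(attr(coh3, "dropped_events"), 1L)
})

test_that("ICD-10 dialects normalise to the same code", {
  expect_identical(normalize_icd10(c("M16.0", "m160", " M16.1 ")),
                   c("M160", "M160", "M161"))
})

test_that("exclusion ledger reconciles with input size", {
  dir <- withr::local_tempdir()
  rows <- data.frame(
    person_id = sprintf("P%02d", 1:12),
    pair_id = rep(sprintf("p%02d", 1:6), each = 2),
    sex = rep(c("male", "male"), 6),
    zygosity = rep(c("MZ", "UZ", "DZSS", "UZ", "MZ", "MZ"), each = 2),
    birth_date = "1940-05-01",
    death_date = c(rep("", 10), "1990-01-01", ""),   # p06 has a pre-window death
    stringsAsFactors = FALSE
  )
  tw <- load_twin_register(write_twin_fixture(dir, rows))
  coh <- build_analysis_cohort(tw, load_event_register(write_event_fixture(
    dir, data.frame(person_id = character(), operation_date = character(),
                    diagnosis_code = character()))))
  led <- exclusion_ledger(coh)
  expect_identical(unname(led["zygosity_excluded"]), 4L)
  expect_identical(unname(led["pair_not_alive_at_start"]), 2L)
  expect_identical(nrow(coh) + sum(led), 12L)
  # idempotence: rebuilding from the already-built cohort's survivors changes nothing
  coh2 <- build_analysis_cohort(tw, load_event_register(write_event_fixture(
    dir, data.frame(person_id = character(), operation_date = character(),
                    diagnosis_code = character()))))
  expect_identical(as.data.frame(coh), as.data.frame(coh2))
})
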