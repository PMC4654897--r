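test_that("Aalen-Johansen matches the hand-computed fixture value", {
  # hand calculation: CIF_case(75) = 1/7 + 1/7 + 4/21 = 10/21,
  # CIF_death(75) = 1/7 + 4/21 = 7/21, survival = 4/21
  cif <- estimate_cif(toy_cif_cohort(), grid = c(50, 75))
  at75 <- cif[cif$age == 75, ]
  expect_equal(at75$cif[at75$cause == "case"], 10 / 21, tolerance = 1e-10)
  expect_equal(at75$cif[at75$cause == "death"], 7 / 21, tolerance = 1e-10)
  expect_equal(at75$surv[1], 4 / 21, tolerance = 1e-10)
})

test_that("with a single cause the CIF reduces to 1 - Kaplan-Meier", {
  coh <- default_cohort(5000, seed = 404)
  coh <- as.data.frame(coh)
  coh$exit_cause[coh$exit_cause == "death"] <- "censored"  # remove competing cause
  class(coh) <- c("twin_cohort", "data.frame")
  grid <- seq(40, 80, by = 5)
  cif <- estimate_cif(coh, grid = grid)
  km <- survival::survfit(survival::Surv(entry_age, pmax(exit_age, entry_age + 1e-6),
                                         exit_cause == "case") ~ 1, data = coh)
  skm <- summary(km, times = grid, extend = TRUE)$surv
  got <- cif$cif[cif$cause == "case"]
  expect_equal(got, 1 - skm, tolerance = 1e-8)
})

test_that("CIF curves are monotone, non-negative and conserve probability", {
  cif <- estimate_cif(default_cohort(8000, seed = 11), by_sex = TRUE,
                      grid = seq(30, 95, by = 1))
  expect_true(all(cif$cif >= 0))
  for (sx in unique(cif$sex)) for (cs in c("case", "death")) {
    v <- cif$cif[cif$sex == sx & cif$cause == cs]
    expect_true(all(diff(v) >= -1e-12))
  }
  # conservation: surv + case + death = 1 at every grid age
  one <- cif[cif$cause == "case", ]
  other <- cif[cif$cause == "death", ]
  expect_equal(one$surv + one$cif + other$cif, rep(1, nrow(one)), tolerance = 1e-10)
})

test_that("without death or censoring the CIF equals the empirical onset curve", {
  coh <- lifetime_cohort(8000, seed = 21)
  grid <- c(50, 60, 70, 80, 90)
  cif <- estimate_cif(coh, grid = grid)
  emp <- vapply(grid, function(a) mean(coh$exit_cause == "case" & coh$exit_age <= a),
                numeric(1))
  got <- cif$cif[cif$cause == "case"]
  expect_equal(got, emp, tolerance = 1e-8)
})

test_that("incidence rises four- to five-fold between 60 and 85 in both sexes", {
  cif <- estimate_cif(default_cohort(), by_sex = TRUE, grid = c(60, 85))
  for (sx in c("male", "female")) {
    k <- cif[cif$sex == sx & cif$cause == "case", ]
    fold <- k$cif[k$age == 85] / k$cif[k$age == 60]
    expect_gt(fold, 3); expect_lt(fold, 6)
  }
})

test_that("half-sample CIF curves agree within pointwise Monte Carlo error", {
  coh <- default_cohort()
  ids <- unique(coh$pair_id)
  set.seed(1)
  half <- sample(ids, length(ids) %/% 2)
  g <- seq(50, 85, by = 5)
  c1 <- estimate_cif(coh[coh$pair_id %in% half, ], grid = g)
  c2 <- estimate_cif(coh[!coh$pair_id %in% half, ], grid = g)
  k1 <- c1[c1$cause == "case", ]; k2 <- c2[c2$cause == "case", ]
  pooled_se <- sqrt(k1$se^2 + k2$se^2)
  expect_true(all(abs(k1$cif - k2$cif) <= 3.5 * pooled_se + 1e-8))
})

test_that("censoring weights reproduce the hand-computed toy values", {
  # 4 individuals, entry 0: case@60, censored@65, death@70, admin-censored@80;
  # horizon 75. Censoring KM drops to 2/3 after the event at 65, so
  # weights are 1 (case), 0 (censored before horizon), 1.5, 1.5.
  toy <- data.frame(
    person_id = sprintf("I%d", 1:4), pair_id = sprintf("p%d", c(1, 1, 2, 2)),
    member_index = c(1, 2, 1, 2), sex = "female", zygosity = "MZ",
    birth_date = as.Date("1930-01-01"), entry_age = 0,
    exit_age = c(60, 65, 70, 80),
    exit_cause = c("case", "censored", "death", "censored"),
    diagnosis_code = NA_character_, stringsAsFactors = FALSE
  )
  w <- censoring_weights(toy, 75)
  expect_equal(w$weight, c(1, 0, 1.5, 1.5), tolerance = 1e-12)
  expect_identical(w$response, c(1L, 0L, 0L, 0L))
  expect_identical(w$fully_observed, c(TRUE, FALSE, TRUE, TRUE))
})

test_that("zero censoring gives unit weights for all fully observed", {
  coh <- lifetime_cohort(3000, seed = 17)
  w <- censoring_weights(coh, 90)
  expect_true(all(w$weight[w$fully_observed] == 1))
  expect_true(all(w$fully_observed))
})

test_that("weights self-normalise and de-bias under random censoring", {
  # random (emigration-style) censoring, no death, entry at ~0: the classic
  # IPCW regime where positivity holds at every age
  coh <- cached_cohort("rand_cens",
                       lifetime_params(20000, seed = 314, emigration_rate = 0.02))
  h <- 75
  w <- censoring_weights(coh, h)
  n <- nrow(coh)
  expect_lt(abs(sum(w$weight) / n - 1), 0.05)
  p <- attr(coh, "params")
  truth <- cumulative_onset(h, p)
  weighted <- sum(w$weight * w$response) / sum(w$weight)
  naive <- mean(w$response)
  # the raw fraction of observed cases underestimates the onset
  # probability; the weighted mean recovers it
  expect_lt(naive, truth - 3 * sqrt(truth * (1 - truth) / n))
  expect_lt(abs(weighted - truth), 3 * sqrt(truth * (1 - truth) / sum(w$weight > 0)) + 0.005)
})

test_that("death before the horizon is an observed non-case, not censoring", {
  toy <- data.frame(
    person_id = c("I1", "I2"), pair_id = c("p1", "p1"), member_index = 1:2,
    sex = "male", zygosity = "MZ", birth_date = as.Date("1940-01-01"),
    entry_age = 0, exit_age = c(55, 70), exit_cause = c("death", "censored"),
    diagnosis_code = NA_character_, stringsAsFactors = FALSE
  )
  w <- censoring_weights(toy, 65)
  expect_true(w$fully_observed[1])
  expect_identical(w$response[1], 0L)
  expect_gt(w$weight[1], 0)
})
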