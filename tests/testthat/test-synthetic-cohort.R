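test_that("parameter validation rejects non-simplex components and bad inputs", {
  expect_error(sim_params(a2 = 0.6, c2 = 0.6, e2 = 0.2, d2 = 0), "sum to 1")
  expect_error(sim_params(a2 = -0.1, d2 = 0, c2 = 0.5, e2 = 0.6), "\\[0, 1\\]")
  expect_error(sim_params(n_pairs = 0), "positive")
  expect_error(sim_params(prevalence = 1.2), "prevalence")
  expect_error(sim_params(zygosity_mix = c(MZ = 0.5, DZSS = 0.2, DZOS = 0.2)), "sum to 1")
  expect_error(sim_params(age_effect = list(ages = c(40, 60), a2 = c(0.5, 0.6),
                                            c2 = c(0.2, 0.2), e2 = c(0.3, 0.3))),
               "sum to 1")
})

test_that("threshold curve is strictly decreasing and inverts exactly", {
  p <- sim_params(n_pairs = 10, seed = 1)
  ages <- seq(30, 99, by = 0.5)
  tau <- liability_threshold(ages, p)
  expect_true(all(diff(tau) < 0))
  # onset_age is the exact inverse of the threshold curve
  lia <- c(1.6, 2.0, 2.4)
  t_on <- onset_age(lia, p)
  expect_equal(liability_threshold(t_on, p), lia, tolerance = 1e-9)
  # liabilities below the ref-age threshold never onset
  expect_identical(onset_age(qnorm(1 - p$prevalence) - 0.2, p), Inf)
})

test_that("same seed gives byte-identical cohorts", {
  p <- sim_params(n_pairs = 300, seed = 99)
  c1 <- simulate_cohort(p)
  c2 <- simulate_cohort(p)
  expect_identical(as.data.frame(c1), as.data.frame(c2))
  expect_identical(attr(c1, "truth"), attr(c2, "truth"))
})

test_that("perfect heritability makes MZ pairs fully concordant in onset", {
  p <- lifetime_params(2000, seed = 5, a2 = 1, d2 = 0, c2 = 0, e2 = 0,
                       zygosity_mix = c(MZ = 1, DZSS = 0, DZOS = 0))
  coh <- simulate_cohort(p)
  tr <- attr(coh, "truth")
  i1 <- seq(1, nrow(tr), by = 2); i2 <- i1 + 1
  expect_gt(cor(tr$liability[i1], tr$liability[i2]), 0.999)
  # both members onset (or neither) at any horizon
  tab <- pair_contingency(coh, "MZ", horizon_age = 80)
  expect_identical(tab$n_cd, 0L)
})

test_that("pair liability correlations converge to rMZ and rDZ", {
  coh <- lifetime_cohort()
  tr <- attr(coh, "truth")
  i1 <- seq(1, nrow(tr), by = 2); i2 <- i1 + 1
  zyg <- coh$zygosity[match(tr$person_id[i1], coh$person_id)]
  r_mz <- cor(tr$liability[i1][zyg == "MZ"], tr$liability[i2][zyg == "MZ"])
  r_dz <- cor(tr$liability[i1][zyg != "MZ"], tr$liability[i2][zyg != "MZ"])
  n_mz <- sum(zyg == "MZ"); n_dz <- sum(zyg != "MZ")
  se <- function(r, n) (1 - r^2) / sqrt(n - 3)
  expect_lt(abs(r_mz - 0.68), 3 * se(0.68, n_mz))
  expect_lt(abs(r_dz - 0.445), 3 * se(0.445, n_dz))
})

test_that("lifetime prevalence matches the target without death or censoring", {
  coh <- lifetime_cohort()
  frac <- mean(coh$exit_cause == "case")
  n <- nrow(coh)
  expect_lt(abs(frac - 0.06), 3 * sqrt(0.06 * 0.94 / n) + 0.002)
  # cumulative onset curve matches the latent curve pointwise
  p <- attr(coh, "params")
  for (a in c(55, 65, 75, 85)) {
    emp <- mean(coh$exit_cause == "case" & coh$exit_age <= a)
    theo <- cumulative_onset(a, p)
    expect_lt(abs(emp - theo), 3 * sqrt(theo * (1 - theo) / n) + 0.002)
  }
})

test_that("MZ and DZ twins share the same marginal onset probability", {
  coh <- default_cohort()
  mz <- coh$zygosity == "MZ"
  p1 <- mean(coh$exit_cause[mz] == "case")
  p2 <- mean(coh$exit_cause[!mz] == "case")
  tst <- prop.test(c(sum(coh$exit_cause[mz] == "case"), sum(coh$exit_cause[!mz] == "case")),
                   c(sum(mz), sum(!mz)))
  expect_gt(tst$p.value, 0.001)
  expect_lt(abs(p1 - p2), 0.005)
})

test_that("defaults reproduce the study conditions", {
  p <- sim_params()
  expect_equal(p$a2 + p$d2 + p$c2 + p$e2, 1, tolerance = 1e-12)
  expect_equal(unname(p$zygosity_mix["MZ"]), 20327 / 94063, tolerance = 1e-10)
  coh <- default_cohort()
  cens <- mean(coh$exit_cause == "censored")
  expect_gt(cens, 0.84); expect_lt(cens, 0.91)
  raw_cases <- mean(coh$exit_cause == "case")
  expect_gt(raw_cases, 0.005); expect_lt(raw_cases, 0.015)
  # zygosity mix realised
  expect_equal(mean(coh$zygosity == "MZ"), 0.216, tolerance = 0.02)
})

test_that("pair structure invariants hold on simulator output", {
  coh <- simulate_cohort(sim_params(n_pairs = 2000, seed = 77))
  expect_true(all(coh$exit_age >= coh$entry_age))
  expect_true(all(coh$entry_age >= 0))
  i1 <- seq(1, nrow(coh), by = 2); i2 <- i1 + 1
  expect_identical(coh$pair_id[i1], coh$pair_id[i2])
  expect_identical(coh$birth_date[i1], coh$birth_date[i2])
  expect_identical(coh$zygosity[i1], coh$zygosity[i2])
  os <- coh$zygosity[i1] == "DZOS"
  expect_true(all(coh$sex[i1][os] != coh$sex[i2][os]))
  expect_true(all(coh$sex[i1][!os] == coh$sex[i2][!os]))
})

test_that("written register files round-trip through the loaders", {
  coh <- simulate_cohort(sim_params(n_pairs = 500, seed = 123))
  dir <- withr::local_tempdir()
  paths <- write_cohort(coh, dir)
  tw <- load_twin_register(paths[1])
  ev <- load_event_register(paths[2])
  expect_identical(nrow(tw), nrow(coh))
  expect_identical(nrow(ev), sum(coh$exit_cause == "case"))
  built <- build_analysis_cohort(tw, ev)
  expect_identical(sort(built$person_id[built$exit_cause == "case"]),
                   sort(coh$person_id[coh$exit_cause == "case"]))
  # exit ages agree to date-rounding precision
  m <- match(coh$person_id, built$person_id)
  expect_lt(max(abs(built$exit_age[m] - coh$exit_age)), 0.01)
})
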