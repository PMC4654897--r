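complete_pairs <- function(n_pairs = 20000, seed = 303, ...) {
  coh <- cached_cohort(sprintf("life_fit_%d_%d", n_pairs, seed),
                       lifetime_params(n_pairs, seed, ...))
  twin_pairs(coh)
}

test_that("saturated per-stratum correlations equal the tetrachoric ML", {
  pr <- complete_pairs(6000, seed = 55)
  fit <- fit_saturated(pr, sex = "male")
  # same-sex male MZ pairs as a plain contingency table
  mz <- pr[pr$zyg == "MZ" & pr$s1 == "male" & pr$s2 == "male", ]
  tab <- pair_table(sum(mz$y1 & mz$y2), sum(xor(mz$y1, mz$y2)), sum(!mz$y1 & !mz$y2))
  te <- tetrachoric(tab)
  expect_lt(abs(fit$correlations[["MZ"]] - te$rho), 1e-3)
  # likelihood decomposes: the stratified fit cannot beat per-table ML
  dz <- pr[pr$zyg == "DZSS" & pr$s1 == "male", ]
  tabdz <- pair_table(sum(dz$y1 & dz$y2), sum(xor(dz$y1, dz$y2)), sum(!dz$y1 & !dz$y2))
  tedz <- tetrachoric(tabdz)
  expect_lt(abs(fit$loglik - (te$loglik + tedz$loglik)), 1e-4)
})

test_that("unit weights reproduce the unweighted fit exactly", {
  pr <- complete_pairs(6000, seed = 55)
  pr_w <- pr
  pr_w$w <- 1
  attr(pr_w, "weight_scheme_id") <- "unweighted"
  f1 <- fit_saturated(pr, sex = "both")
  f2 <- fit_saturated(pr_w, sex = "both")
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-9)
  expect_equal(f1$correlations, f2$correlations, tolerance = 1e-7)
})

test_that("ACE recovery on complete data is within Monte Carlo error", {
  pr <- complete_pairs()
  fit <- fit_components(pr, "ACE")
  expect_true(fit$converged)
  se <- fit$component_se
  expect_lt(abs(fit$components[["a2"]] - 0.47), 3 * se[["a2"]])
  expect_lt(abs(fit$components[["c2"]] - 0.21), 3 * se[["c2"]])
  expect_lt(abs(fit$components[["e2"]] - 0.32), 3 * se[["e2"]])
  expect_equal(sum(fit$components), 1, tolerance = 1e-8)
  # implied correlations are consistent and inside [-1, 1]
  expect_equal(unname(fit$correlations[["rMZ"]]),
               fit$components[["a2"]] + fit$components[["c2"]], tolerance = 1e-12)
  expect_true(all(abs(fit$correlations) <= 1))
})

test_that("pure-additive data pushes the ACE shared environment to zero", {
  coh <- cached_cohort("pureA", lifetime_params(15000, seed = 61, a2 = 0.6,
                                                d2 = 0, c2 = 0, e2 = 0.4))
  fit <- fit_components(twin_pairs(coh), "ACE")
  expect_lt(fit$components[["c2"]], 0.05)
  expect_lt(abs(fit$components[["a2"]] - 0.6), 3 * fit$component_se[["a2"]] + 0.05)
})

test_that("AE overestimates a2 relative to ACE when shared environment exists", {
  pr <- complete_pairs()
  ace <- fit_components(pr, "ACE")
  ae <- fit_components(pr, "AE")
  expect_gt(ae$components[["a2"]], ace$components[["a2"]])
  # and AE absorbs roughly a2 + c2
  expect_lt(abs(ae$components[["a2"]] - (ace$components[["a2"]] + ace$components[["c2"]])), 0.12)
})

test_that("likelihood-ratio machinery: identical fits, nesting, AIC identity", {
  pr <- complete_pairs(6000, seed = 55)
  sat <- fit_saturated(pr)
  ace <- fit_components(pr, "ACE")
  ae <- fit_components(pr, "AE")
  expect_equal(sat$aic, 2 * sat$n_free - 2 * sat$loglik, tolerance = 1e-10)
  expect_equal(ace$aic, 2 * ace$n_free - 2 * ace$loglik, tolerance = 1e-10)
  same <- compare_models(ace, ace)
  expect_equal(same$chi2, 0, tolerance = 1e-8)
  lrt <- compare_models(ae, sat)
  expect_gte(lrt$chi2, 0)
  expect_identical(lrt$df, sat$n_free - ae$n_free)
  expect_true(lrt$p >= 0 && lrt$p <= 1)
  expect_error(compare_models(ae, fit_saturated(pr, sex = "male")), "different data")
  expect_error(fit_components(pr, "ACDE"), "not identifiable")
})

test_that("equal-prevalence assumption holds on simulator output", {
  pr <- complete_pairs()
  # per-zygosity-class empirical prevalence
  q_mz <- with(pr[pr$zyg == "MZ", ], sum(y1 + y2) / (2 * length(y1)))
  q_dz <- with(pr[pr$zyg != "MZ", ], sum(y1 + y2) / (2 * length(y1)))
  n_mz <- 2 * sum(pr$zyg == "MZ"); n_dz <- 2 * sum(pr$zyg != "MZ")
  se <- sqrt(q_mz * (1 - q_mz) / n_mz + q_dz * (1 - q_dz) / n_dz)
  expect_lt(abs(q_mz - q_dz), 3 * se)
})

test_that("heritability accessor covers model-based and moment-based paths", {
  pr <- complete_pairs()
  ace <- fit_components(pr, "ACE")
  h <- heritability(ace)
  expect_identical(h$method, "model")
  expect_equal(h$h2, ace$components[["a2"]], tolerance = 1e-12)
  expect_true(h$ci95[1] <= h$h2 && h$h2 <= h$ci95[2])
  sat <- fit_saturated(pr)
  hs <- heritability(sat)
  expect_identical(hs$method, "moment-based")
  dzn <- setdiff(names(sat$correlations), "MZ")
  rdz <- mean(sat$correlations[dzn])
  expect_equal(hs$h2, 2 * (sat$correlations[["MZ"]] - rdz), tolerance = 1e-10)
})

test_that("moment identities reproduce the printed sex-adjusted decomposition", {
  # saturated correlations rMZ = 0.68, rDZ = 0.45 imply a2 = 2(rMZ - rDZ),
  # c2 = 2 rDZ - rMZ, matching the printed ACE row to rounding
  a2 <- 2 * (0.68 - 0.45)
  c2 <- 2 * 0.45 - 0.68
  expect_equal(a2, 0.46, tolerance = 1e-12)
  expect_equal(c2, 0.22, tolerance = 1e-12)
  expect_equal(round(1 - a2 - c2, 2), 0.32)
})
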