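#' Proband-wise concordance by age
#'
#' At each grid age `t`, computes IPCW-weighted joint and marginal
#' probabilities of "case by `t`" for MZ and (pooled same-sex plus
#' opposite-sex) DZ pairs; the proband-wise concordance is their ratio
#' `P(both affected) / P(affected)`, and the marginal curve is the weighted
#' cumulative incidence across all fully observed individuals. Pointwise
#' percentile confidence intervals come from a weighted bootstrap over pairs
#' (weights treated as fixed).
#'
#' @param cohort A `twin_cohort`.
#' @param grid Age grid in years (default 40 to 90 by 5).
#' @param B Bootstrap replicates for pointwise CIs (0 disables).
#' @param cap Weight cap passed to [censoring_weights()].
#' @param conf.level Confidence level.
#' @return A data.frame of class `age_curve` with columns `age`, `label`
#'   (`MZ_concordance`, `DZ_concordance`, `marginal`), `value`, `lo`, `hi`,
#'   `defined`. Grid ages with no affected probands are flagged undefined.
#' @export
concordance_by_age <- function(cohort, grid = seq(40, 90, by = 5), B = 200,
                               cap = 20, conf.level = 0.95) {
  stopifnot(!is.unsorted(grid, strictly = TRUE))
  per_age <- lapply(grid, function(t) {
    w <- censoring_weights(cohort, t, cap = cap)
    pr <- twin_pairs(cohort, weights = w)
    ind <- w[w$fully_observed & w$weight > 0, ]
    list(pairs = pr, ind = ind)
  })
  all_ids <- unique(cohort$pair_id)
  stat_one <- function(pa, cnt = NULL) {
    pr <- pa$pairs; ind <- pa$ind
    mp <- if (is.null(cnt)) rep(1, nrow(pr)) else cnt[match(pr$pair_id, all_ids)]
    mi <- if (is.null(cnt)) rep(1, nrow(ind)) else cnt[match(ind$pair_id, all_ids)]
    res <- c(MZ_concordance = NA_real_, DZ_concordance = NA_real_, marginal = NA_real_)
    sw <- sum(mi * ind$weight)
    if (sw > 0) res["marginal"] <- sum(mi * ind$weight * ind$response) / sw
    for (lab in c("MZ", "DZ")) {
      sel <- if (lab == "MZ") pr$zyg == "MZ" else pr$zyg %in% c("DZSS", "DZOS")
      wz <- mp[sel] * pr$w[sel]
      if (sum(wz) == 0) next
      joint <- sum(wz * pr$y1[sel] * pr$y2[sel]) / sum(wz)
      marg <- sum(wz * (pr$y1[sel] + pr$y2[sel]) / 2) / sum(wz)
      if (marg > 0) res[paste0(lab, "_concordance")] <- joint / marg
    }
    res
  }
  est <- t(vapply(per_age, stat_one, numeric(3)))
  lo <- hi <- matrix(NA_real_, nrow(est), ncol(est))
  if (B > 0) {
    n_ids <- length(all_ids)
    boot <- array(NA_real_, c(B, length(grid), 3))
    for (b in seq_len(B)) {
      cnt <- tabulate(sample.int(n_ids, n_ids, replace = TRUE), nbins = n_ids)
      for (i in seq_along(grid)) boot[b, i, ] <- stat_one(per_age[[i]], cnt)
    }
    alpha <- (1 - conf.level) / 2
    for (i in seq_along(grid)) for (j in 1:3) {
      v <- boot[, i, j]
      if (any(is.finite(v))) {
        qs <- stats::quantile(v, c(alpha, 1 - alpha), na.rm = TRUE, names = FALSE)
        lo[i, j] <- qs[1]; hi[i, j] <- qs[2]
      }
    }
  }
  labs <- c("MZ_concordance", "DZ_concordance", "marginal")
  out <- data.frame(age = rep(grid, 3),
                    label = rep(labs, each = length(grid)),
                    value = c(est[, 1], est[, 2], est[, 3]),
                    lo = c(lo[, 1], lo[, 2], lo[, 3]),
                    hi = c(hi[, 1], hi[, 2], hi[, 3]),
                    stringsAsFactors = FALSE)
  out$defined <- is.finite(out$value)
  class(out) <- c("age_curve", "data.frame")
  out
}

#' Variance components by age
#'
#' Refits the liability model at each grid age on the outcome "case by `t`"
#' with IPCW weights at that horizon (thresholds and components both re-fit
#' per age), assembling age curves of a2/c2 (or d2)/e2 and broad-sense
#' heritability with delta-method CIs. Ages with too few affected pairs, or
#' where the optimiser fails, are flagged rather than estimated.
#'
#' @param cohort A `twin_cohort`.
#' @param grid Age grid in years.
#' @param model_tag `"ACE"` or `"AE"`.
#' @param sex `"both"` for the sex-adjusted fit, else `"male"`/`"female"`.
#' @param min_affected_pairs Minimum number of observed pairs with at least
#'   one affected member required to attempt a fit at a grid age.
#' @param cap Weight cap passed to [censoring_weights()].
#' @return A data.frame of class `age_curve` with columns `age`, `label`
#'   (`a2`, `c2`/`d2`, `e2`, `h2`), `value`, `lo`, `hi`, `defined`,
#'   `converged`.
#' @export
components_by_age <- function(cohort, grid = seq(40, 90, by = 5),
                              model_tag = c("ACE", "AE"), sex = "both",
                              min_affected_pairs = 5, cap = 20) {
  model_tag <- match.arg(model_tag)
  free <- setdiff(model_components(model_tag), "e2")
  labs <- c(free, "e2", "h2")
  rows <- list()
  for (t in grid) {
    w <- censoring_weights(cohort, t, cap = cap)
    pr <- twin_pairs(cohort, weights = w)
    pr <- restrict_sex(pr, if (sex == "both") "both" else sex)
    n_aff <- sum((pr$y1 + pr$y2) > 0)
    if (n_aff < min_affected_pairs) {
      rows[[length(rows) + 1]] <- data.frame(age = t, label = labs, value = NA_real_,
                                             lo = NA_real_, hi = NA_real_,
                                             defined = FALSE, converged = FALSE)
      next
    }
    fit <- tryCatch(fit_components(pr, model_tag, sex = sex), error = function(e) NULL)
    if (is.null(fit)) {
      rows[[length(rows) + 1]] <- data.frame(age = t, label = labs, value = NA_real_,
                                             lo = NA_real_, hi = NA_real_,
                                             defined = FALSE, converged = FALSE)
      next
    }
    val <- c(fit$components[free], e2 = unname(fit$components[["e2"]]), h2 = fit$h2_broad)
    lo <- c(vapply(free, function(k) fit$component_ci[[k]][1], 0),
            fit$component_ci[["e2"]][1], fit$h2_ci[1])
    hi <- c(vapply(free, function(k) fit$component_ci[[k]][2], 0),
            fit$component_ci[["e2"]][2], fit$h2_ci[2])
    rows[[length(rows) + 1]] <- data.frame(age = t, label = labs, value = unname(val),
                                           lo = unname(lo), hi = unname(hi),
                                           defined = TRUE, converged = fit$converged)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("age_curve", "data.frame")
  out
}
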