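#' Pair-level outcomes for the bivariate probit likelihood
#'
#' Reshapes a cohort into one row per complete twin pair with binary
#' outcomes. Unweighted, the outcome is "case by `horizon_age`" and every
#' pair has weight 1. With a [censoring_weights()] frame, only pairs with
#' both members fully observed to the horizon enter, the pair weight is the
#' product of the member weights, and responses are taken from the weight
#' frame.
#'
#' @param cohort A `twin_cohort`.
#' @param horizon_age Affection horizon (default `Inf`), ignored when
#'   `weights` is supplied (the weights carry their own horizon).
#' @param weights Optional [censoring_weights()] output.
#' @return A data.frame `pair_id`, `zyg`, `s1`, `s2`, `y1`, `y2`, `w` with
#'   opposite-sex pairs ordered male first; attribute `weight_scheme_id`
#'   identifies the weighting.
#' @export
twin_pairs <- function(cohort, horizon_age = Inf, weights = NULL) {
  d <- as.data.frame(cohort)[, c("person_id", "pair_id", "member_index",
                                 "sex", "zygosity", "exit_cause", "exit_age")]
  if (is.null(weights)) {
    d$y <- as.integer(d$exit_cause == "case" & d$exit_age <= horizon_age)
    d$w <- 1
    d$obs <- TRUE
    scheme <- "unweighted"
  } else {
    m <- match(d$person_id, weights$person_id)
    if (anyNA(m)) stop("weights do not cover every person in the cohort")
    d$y <- weights$response[m]
    d$w <- weights$weight[m]
    d$obs <- weights$fully_observed[m]
    scheme <- sprintf("ipcw:h=%g", weights$horizon_age[1])
  }
  d <- d[order(d$pair_id, d$member_index), ]
  n2 <- ave(seq_len(nrow(d)), d$pair_id, FUN = length)
  d <- d[n2 == 2, , drop = FALSE]
  i1 <- seq(1, nrow(d), by = 2); i2 <- i1 + 1
  # order OS pairs male first so s1/s2 are canonical
  swap <- d$sex[i1] == "female" & d$sex[i2] == "male"
  a <- ifelse(swap, i2, i1); b <- ifelse(swap, i1, i2)
  out <- data.frame(pair_id = d$pair_id[a],
                    zyg = d$zygosity[a],
                    s1 = d$sex[a], s2 = d$sex[b],
                    y1 = d$y[a], y2 = d$y[b],
                    w = d$w[a] * d$w[b],
                    stringsAsFactors = FALSE)
  keep <- d$obs[a] & d$obs[b] & out$w > 0
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "weight_scheme_id") <- scheme
  out
}

# weighted cell counts by (zyg, s1, s2, y1, y2)
aggregate_pairs <- function(pairs) {
  key <- interaction(pairs$zyg, pairs$s1, pairs$s2, pairs$y1, pairs$y2, drop = TRUE)
  w <- tapply(pairs$w, key, sum)
  parts <- do.call(rbind, strsplit(names(w), ".", fixed = TRUE))
  data.frame(zyg = parts[, 1], s1 = parts[, 2], s2 = parts[, 3],
             y1 = as.integer(parts[, 4]), y2 = as.integer(parts[, 5]),
             w = as.numeric(w), stringsAsFactors = FALSE)
}

# cell log-probabilities for every row of an aggregated table given
# thresholds (keyed by sex, or by zygosity stratum in stratified saturated
# fits) and per-zygosity-class correlations
agg_loglik <- function(agg, z, rho_by_class, thr_by = "sex") {
  if (any(!is.finite(unlist(z))) || any(!is.finite(unlist(rho_by_class)))) return(-Inf)
  combos <- unique(agg[, c("zyg", "s1", "s2")])
  ll <- 0
  for (k in seq_len(nrow(combos))) {
    zy <- combos$zyg[k]; s1 <- combos$s1[k]; s2 <- combos$s2[k]
    if (thr_by == "zyg") { t1 <- z[[zy]]; t2 <- z[[zy]] } else { t1 <- z[[s1]]; t2 <- z[[s2]] }
    r <- rho_by_class[[zy]]
    if (abs(r) >= 0.9999) r <- sign(r) * 0.9999
    p11 <- bvn_upper(t1, t2, r)
    pu1 <- stats::pnorm(t1, lower.tail = FALSE)
    pu2 <- stats::pnorm(t2, lower.tail = FALSE)
    p10 <- pu1 - p11; p01 <- pu2 - p11
    p00 <- 1 - pu1 - pu2 + p11
    p <- c(`0.0` = p00, `1.0` = p10, `0.1` = p01, `1.1` = p11)
    if (any(!is.finite(p)) || any(p <= 0)) return(-Inf)
    rows <- agg$zyg == zy & agg$s1 == s1 & agg$s2 == s2
    cell <- paste(agg$y1[rows], agg$y2[rows], sep = ".")
    ll <- ll + sum(agg$w[rows] * log(p[cell]))
  }
  ll
}

model_components <- function(model_tag) {
  switch(model_tag,
         ACE = c("a2", "c2", "e2"),
         ADE = c("a2", "d2", "e2"),
         AE  = c("a2", "e2"),
         CE  = c("c2", "e2"),
         stop("unknown model_tag: ", model_tag))
}

# unconstrained parameters -> simplex of the model's free components
par_to_components <- function(x, model_tag) {
  free <- model_components(model_tag)
  e <- exp(c(x, 0))
  p <- e / sum(e)
  comp <- c(a2 = 0, d2 = 0, c2 = 0, e2 = 0)
  comp[free] <- p
  comp
}

implied_correlations <- function(comp) {
  c(rMZ = comp[["a2"]] + comp[["d2"]] + comp[["c2"]],
    rDZ = 0.5 * comp[["a2"]] + 0.25 * comp[["d2"]] + comp[["c2"]])
}

numeric_jacobian <- function(f, x, eps = 1e-6) {
  f0 <- f(x)
  J <- matrix(NA_real_, length(f0), length(x))
  for (j in seq_along(x)) {
    xp <- x; xm <- x
    xp[j] <- xp[j] + eps; xm[j] <- xm[j] - eps
    J[, j] <- (f(xp) - f(xm)) / (2 * eps)
  }
  J
}

run_optim <- function(start, nll, restarts = 5) {
  best <- stats::optim(start, nll, method = "BFGS",
                       control = list(maxit = 1000, reltol = 1e-12))
  tries <- 0
  grad_ok <- function(o) {
    g <- numeric_jacobian(function(p) nll(p), o$par, eps = 1e-5)
    max(abs(g)) < 1e-3 * max(1, abs(o$value))
  }
  while ((best$convergence != 0 || !grad_ok(best)) && tries < restarts) {
    tries <- tries + 1
    jit <- start + stats::rnorm(length(start), sd = 0.3)
    cand <- tryCatch(stats::optim(jit, nll, method = "BFGS",
                                  control = list(maxit = 1000, reltol = 1e-12)),
                     error = function(e) NULL)
    if (!is.null(cand) && cand$value < best$value) best <- cand
  }
  best$grad_converged <- grad_ok(best)
  best
}

threshold_setup <- function(agg, sex, thr_by = "sex") {
  keys <- if (thr_by == "zyg") {
    sort(unique(agg$zyg))
  } else if (sex == "both") {
    sort(unique(c(agg$s1, agg$s2)))
  } else {
    sex
  }
  # weighted prevalence per threshold group for starting values
  q <- vapply(keys, function(k) {
    sel1 <- if (thr_by == "zyg") agg$zyg == k else agg$s1 == k
    sel2 <- if (thr_by == "zyg") agg$zyg == k else agg$s2 == k
    num <- sum(agg$w[sel1] * agg$y1[sel1]) + sum(agg$w[sel2] * agg$y2[sel2])
    den <- sum(agg$w[sel1]) + sum(agg$w[sel2])
    max(min(num / den, 0.99), 1e-4)
  }, numeric(1))
  list(sexes = keys, z_start = stats::qnorm(1 - q))
}

restrict_sex <- function(pairs, sex) {
  if (sex == "both") return(pairs)
  pairs[pairs$s1 == sex & pairs$s2 == sex, , drop = FALSE]
}

new_liability_fit <- function(...) structure(list(...), class = "liability_fit")

#' Fit the saturated bivariate-probit twin model
#'
#' Maximises the (optionally IPCW-weighted) sum over twin pairs of the log
#' bivariate-probit likelihood with a free tetrachoric correlation per
#' zygosity class. With `sex = "both"` (sex-adjusted mode) thresholds are
#' sex-specific, shared across zygosity groups, and opposite-sex pairs
#' contribute a mixed-threshold term; with `sex = "male"`/`"female"`
#' (sex-stratified mode) only same-sex pairs of that sex enter and one
#' threshold is fitted per zygosity stratum, so each stratum's correlation
#' coincides with the ML tetrachoric of its own table.
#'
#' @param pairs Output of [twin_pairs()].
#' @param sex `"both"`, `"male"` or `"female"`.
#' @param pool_dz Pool same-sex and opposite-sex DZ pairs into a single DZ
#'   correlation (default `FALSE`: separate correlations).
#' @param conf.level Confidence level for delta-method intervals.
#' @return A `liability_fit` with correlations, thresholds/prevalences,
#'   log likelihood, AIC and a convergence flag.
#' @export
fit_saturated <- function(pairs, sex = c("both", "male", "female"),
                          pool_dz = FALSE, conf.level = 0.95) {
  sex <- match.arg(sex)
  pairs <- restrict_sex(pairs, sex)
  if (nrow(pairs) == 0) stop("no pairs to fit")
  agg <- aggregate_pairs(pairs)
  # sex-adjusted mode: one threshold per sex shared across zygosity groups;
  # stratified mode: one threshold per zygosity stratum (so each stratum's
  # correlation coincides with the ML tetrachoric of its own table)
  thr_by <- if (sex == "both") "sex" else "zyg"
  ts <- threshold_setup(agg, sex, thr_by)
  classes <- intersect(c("MZ", "DZSS", "DZOS"), unique(agg$zyg))
  rho_groups <- if (pool_dz) {
    stats::setNames(ifelse(classes == "MZ", "MZ", "DZ"), classes)
  } else {
    stats::setNames(classes, classes)
  }
  groups <- unique(unname(rho_groups))
  npar_z <- length(ts$sexes)
  make_inputs <- function(par) {
    z <- as.list(stats::setNames(par[seq_len(npar_z)], ts$sexes))
    rg <- tanh(par[npar_z + seq_along(groups)])
    names(rg) <- groups
    list(z = z, rho = as.list(stats::setNames(rg[rho_groups], names(rho_groups))))
  }
  nll <- function(par) {
    if (any(!is.finite(par))) return(1e10)
    inp <- make_inputs(par)
    v <- -agg_loglik(agg, inp$z, inp$rho, thr_by)
    if (!is.finite(v)) 1e10 else v
  }
  start <- c(ts$z_start, atanh(ifelse(groups == "MZ", 0.5, 0.25)))
  opt <- run_optim(start, nll)
  inp <- make_inputs(opt$par)
  H <- stats::optimHess(opt$par, nll)
  V <- tryCatch(solve(H), error = function(e) matrix(NA_real_, length(start), length(start)))
  rho_hat <- unlist(inp$rho)
  zc <- stats::qnorm(1 - (1 - conf.level) / 2)
  ci <- lapply(seq_along(groups), function(g) {
    se <- sqrt(V[npar_z + g, npar_z + g])
    tanh(atanh(tanh(opt$par[npar_z + g])) + c(-1, 1) * zc * se)
  })
  names(ci) <- groups
  thresholds <- unlist(inp$z)
  new_liability_fit(
    model_tag = "saturated", sex = sex,
    loglik = -opt$value,
    n_free = length(start),
    aic = 2 * length(start) + 2 * opt$value,
    thresholds = thresholds,
    prevalences = stats::pnorm(thresholds, lower.tail = FALSE),
    correlations = rho_hat,
    correlation_ci = ci,
    components = NULL, component_ci = NULL,
    h2_broad = NULL,
    par = opt$par, vcov = V,
    converged = opt$convergence == 0 && isTRUE(opt$grad_converged),
    weight_scheme_id = attr(pairs, "weight_scheme_id") %||% "unweighted",
    n_pairs = nrow(pairs), pool_dz = pool_dz
  )
}

#' Fit an ACE/ADE/AE/CE liability-threshold model
#'
#' Same weighted bivariate-probit likelihood as [fit_saturated()] with the
#' zygosity correlations constrained to `rMZ = a2 + d2 + c2`,
#' `rDZ = a2/2 + d2/4 + c2` and the model's absent components fixed at 0.
#' Free components are parameterised on the unit simplex through a
#' multinomial-logit transform; confidence intervals are delta-method on the
#' logit of each component, truncated to [0, 1]. A component estimated at
#' the 0 boundary is reported as 0.00 with a one-sided (0, 1) interval.
#'
#' The ACDE decomposition is rejected: with MZ and DZ pairs only it is not
#' identifiable.
#'
#' @inheritParams fit_saturated
#' @param model_tag One of `"ACE"`, `"ADE"`, `"AE"`, `"CE"`.
#' @return A `liability_fit` with `components`, implied `correlations`,
#'   `h2_broad` (= a2 + d2) and per-component CIs.
#' @export
fit_components <- function(pairs, model_tag, sex = c("both", "male", "female"),
                           conf.level = 0.95) {
  if (identical(model_tag, "ACDE"))
    stop("ACDE is not identifiable in the classical twin design")
  free <- model_components(model_tag)
  sex <- match.arg(sex)
  pairs <- restrict_sex(pairs, sex)
  if (nrow(pairs) == 0) stop("no pairs to fit")
  agg <- aggregate_pairs(pairs)
  ts <- threshold_setup(agg, sex)
  npar_z <- length(ts$sexes)
  npar_c <- length(free) - 1
  classes <- unique(agg$zyg)
  make_inputs <- function(par) {
    z <- as.list(stats::setNames(par[seq_len(npar_z)], ts$sexes))
    comp <- par_to_components(par[npar_z + seq_len(npar_c)], model_tag)
    r <- implied_correlations(comp)
    rho <- lapply(stats::setNames(classes, classes),
                  function(cl) if (cl == "MZ") r[["rMZ"]] else r[["rDZ"]])
    list(z = z, comp = comp, rho = rho)
  }
  nll <- function(par) {
    if (any(!is.finite(par))) return(1e10)
    inp <- make_inputs(par)
    v <- -agg_loglik(agg, inp$z, inp$rho)
    if (!is.finite(v)) 1e10 else v
  }
  start_comp <- stats::setNames(rep(1 / length(free), length(free)), free)
  start <- c(ts$z_start, log(start_comp[-length(free)] / start_comp[length(free)]))
  opt <- run_optim(start, nll)
  inp <- make_inputs(opt$par)
  H <- stats::optimHess(opt$par, nll)
  V <- tryCatch(solve(H), error = function(e) matrix(NA_real_, length(start), length(start)))
  comp <- inp$comp
  # delta-method SEs of the component vector
  Jc <- numeric_jacobian(function(p) par_to_components(p[npar_z + seq_len(npar_c)], model_tag), opt$par)
  Vc <- Jc %*% V %*% t(Jc)
  se <- sqrt(pmax(diag(Vc), 0))
  names(se) <- names(comp)
  zc <- stats::qnorm(1 - (1 - conf.level) / 2)
  ci <- lapply(names(comp), function(nm) {
    cval <- comp[[nm]]
    if (!nm %in% free) return(c(0, 0))
    if (cval < 1e-4 || cval > 1 - 1e-4) return(c(0, 1))        # boundary, one-sided style
    se_logit <- se[[nm]] / (cval * (1 - cval))
    pmin(pmax(stats::plogis(stats::qlogis(cval) + c(-1, 1) * zc * se_logit), 0), 1)
  })
  names(ci) <- names(comp)
  rimp <- implied_correlations(comp)
  h2 <- comp[["a2"]] + comp[["d2"]]
  se_h2 <- {
    Jh <- numeric_jacobian(function(p) {
      cp <- par_to_components(p[npar_z + seq_len(npar_c)], model_tag)
      cp[["a2"]] + cp[["d2"]]
    }, opt$par)
    sqrt(max(Jh %*% V %*% t(Jh), 0))
  }
  thresholds <- unlist(inp$z)
  new_liability_fit(
    model_tag = model_tag, sex = sex,
    loglik = -opt$value,
    n_free = length(start),
    aic = 2 * length(start) + 2 * opt$value,
    thresholds = thresholds,
    prevalences = stats::pnorm(thresholds, lower.tail = FALSE),
    correlations = rimp,
    correlation_ci = NULL,
    components = comp, component_ci = ci, component_se = se,
    h2_broad = h2, h2_se = se_h2,
    h2_ci = pmin(pmax(h2 + c(-1, 1) * zc * se_h2, 0), 1),
    par = opt$par, vcov = V,
    converged = opt$convergence == 0 && isTRUE(opt$grad_converged),
    weight_scheme_id = attr(pairs, "weight_scheme_id") %||% "unweighted",
    n_pairs = nrow(pairs)
  )
}

#' @export
print.liability_fit <- function(x, ...) {
  cat(sprintf("%s liability fit (%s, %s)\n", x$model_tag, x$sex, x$weight_scheme_id))
  cat(sprintf("  logLik %.3f  AIC %.3f  free params %d  pairs %d%s\n",
              x$loglik, x$aic, x$n_free, x$n_pairs,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  cat("  prevalences:", paste(sprintf("%s=%.4f", names(x$prevalences), x$prevalences), collapse = " "), "\n")
  if (!is.null(x$components)) {
    cat("  components:",
        paste(sprintf("%s=%.3f", names(x$components), x$components), collapse = " "),
        sprintf(" (h2 broad = %.3f)\n", x$h2_broad))
  }
  cat("  correlations:", paste(sprintf("%s=%.3f", names(x$correlations), x$correlations), collapse = " "), "\n")
  invisible(x)
}

#' Likelihood-ratio comparison of nested liability fits
#'
#' `chi2 = 2 (LL_general - LL_restricted)` with degrees of freedom equal to
#' the difference in free parameters and a plain chi-square p value (no
#' boundary mixture correction), plus the AIC difference for non-nested
#' comparison.
#'
#' @param fit_restricted,fit_general `liability_fit` objects on the same
#'   data and weight scheme.
#' @return List `chi2`, `df`, `p`, `aic_restricted`, `aic_general`,
#'   `delta_aic`.
#' @export
compare_models <- function(fit_restricted, fit_general) {
  stopifnot(inherits(fit_restricted, "liability_fit"), inherits(fit_general, "liability_fit"))
  if (!identical(fit_restricted$weight_scheme_id, fit_general$weight_scheme_id))
    stop("fits use different weight schemes; refit on a common scheme")
  if (!identical(fit_restricted$n_pairs, fit_general$n_pairs))
    stop("fits use different data (pair counts differ)")
  chi2 <- max(0, 2 * (fit_general$loglik - fit_restricted$loglik))
  df <- fit_general$n_free - fit_restricted$n_free
  p <- if (df > 0) stats::pchisq(chi2, df, lower.tail = FALSE) else NA_real_
  list(chi2 = chi2, df = df, p = p,
       aic_restricted = fit_restricted$aic, aic_general = fit_general$aic,
       delta_aic = fit_restricted$aic - fit_general$aic)
}

#' Broad-sense heritability of a liability fit
#'
#' For component fits, `H2 = a2 + d2` with its delta-method CI (equal to
#' `a2` for ACE/AE). For a saturated fit, where no decomposition exists, the
#' moment-based `2 (rMZ - rDZ)` is returned and labelled as such; `rDZ` is
#' the pair-count-weighted mean of the fitted DZ correlations when same-sex
#' and opposite-sex DZ correlations were freed separately.
#'
#' @param fit A `liability_fit`.
#' @param dz_weights Optional named weights for averaging DZ correlations in
#'   the saturated case (defaults to equal weights).
#' @return List `h2`, `ci95`, `method` (`"model"` or `"moment-based"`).
#' @export
heritability <- function(fit, dz_weights = NULL) {
  stopifnot(inherits(fit, "liability_fit"))
  if (!fit$converged) warning("fit did not converge; heritability may be unreliable")
  if (!is.null(fit$components)) {
    return(list(h2 = fit$h2_broad, ci95 = fit$h2_ci, method = "model"))
  }
  rho <- fit$correlations
  rmz <- rho[["MZ"]]
  dzn <- setdiff(names(rho), "MZ")
  wts <- if (is.null(dz_weights)) stats::setNames(rep(1, length(dzn)), dzn) else dz_weights[dzn]
  rdz <- sum(rho[dzn] * wts) / sum(wts)
  h2 <- 2 * (rmz - rdz)
  # delta method through the stored parameter covariance
  npar_z <- length(fit$thresholds)
  groups <- if (isTRUE(fit$pool_dz)) unique(ifelse(names(rho) == "MZ", "MZ", "DZ")) else names(rho)
  g <- numeric(length(fit$par))
  for (i in seq_along(groups)) {
    r <- tanh(fit$par[npar_z + i])
    drho <- 1 - r^2
    gw <- if (groups[i] == "MZ") 2 else -2 * (if (isTRUE(fit$pool_dz)) 1 else wts[[groups[i]]] / sum(wts))
    g[npar_z + i] <- gw * drho
  }
  se <- sqrt(max(0, t(g) %*% fit$vcov %*% g))
  list(h2 = h2, ci95 = h2 + c(-1, 1) * 1.96 * se, method = "moment-based")
}
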