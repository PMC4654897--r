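#' Upper-orthant probability of the standard bivariate normal
#'
#' `P(X > a, Y > b)` for standard normal margins with correlation `rho`.
#' Thin vectorised wrapper around [mvtnorm::pmvnorm()].
#'
#' @param a,b Lower bounds (probit units).
#' @param rho Correlation in (-1, 1).
#' @return Probabilities.
#' @keywords internal
bvn_upper <- function(a, b, rho) {
  n <- max(length(a), length(b), length(rho))
  a <- rep_len(a, n); b <- rep_len(b, n); rho <- rep_len(rho, n)
  vapply(seq_len(n), function(i) {
    if (!is.finite(a[i]) && a[i] > 0) return(0)
    if (!is.finite(b[i]) && b[i] > 0) return(0)
    as.numeric(mvtnorm::pmvnorm(lower = c(a[i], b[i]), upper = c(Inf, Inf),
                                corr = matrix(c(1, rho[i], rho[i], 1), 2)))
  }, numeric(1))
}

#' Construct a pair contingency table from counts
#'
#' A 2x2 concordance table of complete twin pairs collapsed to its three
#' distinguishable cells: both affected, discordant, neither affected.
#'
#' @param n_cc Pairs with both members affected.
#' @param n_cd Discordant pairs.
#' @param n_dd Pairs with neither member affected.
#' @param stratum Optional label, e.g. `"MZM"`.
#' @return An object of class `pair_contingency`.
#' @examples
#' pair_table(10, 57, 4558, stratum = "MZM")
#' @export
pair_table <- function(n_cc, n_cd, n_dd, stratum = NULL) {
  counts <- c(n_cc = n_cc, n_cd = n_cd, n_dd = n_dd)
  if (any(counts < 0) || any(!is.finite(counts))) stop("counts must be non-negative")
  total <- n_cc + n_cd + n_dd
  structure(list(n_cc = n_cc, n_cd = n_cd, n_dd = n_dd, total = total,
                 q = if (total > 0) (2 * n_cc + n_cd) / (2 * total) else NA_real_,
                 stratum = stratum %||% "pooled",
                 complete_pairs_only = NA),
            class = "pair_contingency")
}

#' @export
print.pair_contingency <- function(x, ...) {
  cat(sprintf("Pair contingency [%s]: both %d / discordant %d / neither %d (total %d, q = %.4g)\n",
              x$stratum, x$n_cc, x$n_cd, x$n_dd, x$total, x$q))
  invisible(x)
}

#' Tabulate pair concordance for a zygosity/sex stratum
#'
#' Counts concordant-affected, discordant and concordant-unaffected complete
#' pairs, where "affected" means a case event by `horizon_age` (default: by
#' end of follow-up). With `complete_pairs_only` (the convention for
#' concordance tables restricted to pairs alive at follow-up), pairs with a
#' member whose follow-up ended in death are dropped.
#'
#' @param cohort A `twin_cohort`.
#' @param zygosity Zygosity codes to include, e.g. `"MZ"` or
#'   `c("DZSS", "DZOS")`; `NULL` pools all.
#' @param sex `"male"`, `"female"` or `"pooled"`; a sex restriction keeps
#'   pairs whose members are both of that sex.
#' @param horizon_age Affection horizon in years (default `Inf`).
#' @param complete_pairs_only Drop pairs with a member dead at end of
#'   follow-up (default `TRUE`).
#' @return A `pair_contingency`.
#' @export
pair_contingency <- function(cohort, zygosity = NULL, sex = "pooled",
                             horizon_age = Inf, complete_pairs_only = TRUE) {
  sex <- match.arg(sex, c("pooled", "male", "female"))
  known <- unique(cohort$zygosity)
  if (!is.null(zygosity) && !all(zygosity %in% c("MZ", "DZSS", "DZOS", known)))
    stop("unknown stratum: ", paste(setdiff(zygosity, known), collapse = ", "))
  keep <- if (is.null(zygosity)) rep(TRUE, nrow(cohort)) else cohort$zygosity %in% zygosity
  d <- cohort[keep, , drop = FALSE]
  d <- d[order(d$pair_id, d$member_index), ]
  n2 <- ave(seq_len(nrow(d)), d$pair_id, FUN = length)
  d <- d[n2 == 2, , drop = FALSE]
  if (nrow(d) == 0) {
    return(pair_table(0, 0, 0, stratum = paste(c(zygosity %||% "all", sex), collapse = "/")))
  }
  i1 <- seq(1, nrow(d), by = 2); i2 <- i1 + 1
  if (sex != "pooled") {
    ok <- d$sex[i1] == sex & d$sex[i2] == sex
    i1 <- i1[ok]; i2 <- i2[ok]
  }
  if (complete_pairs_only) {
    dead <- d$exit_cause == "death"
    ok <- !(dead[i1] | dead[i2])
    i1 <- i1[ok]; i2 <- i2[ok]
  }
  aff <- d$exit_cause == "case" & d$exit_age <= horizon_age
  y1 <- aff[i1]; y2 <- aff[i2]
  tab <- pair_table(sum(y1 & y2), sum(xor(y1, y2)), sum(!y1 & !y2),
                    stratum = paste(c(zygosity %||% "all", sex), collapse = "/"))
  tab$complete_pairs_only <- complete_pairs_only
  tab
}

#' Pairwise and proband-wise concordance rates
#'
#' Pairwise concordance is `n_cc / (n_cc + n_cd)`; proband-wise concordance
#' under complete ascertainment is `2 n_cc / (2 n_cc + n_cd)` -- the
#' probability that a twin is affected given an affected co-twin.
#'
#' @param tab A `pair_contingency`.
#' @return List with `pairwise`, `probandwise` and `defined` (FALSE when no
#'   pair has an affected member, in which case the rates are `NA`).
#' @examples
#' concordance_rates(pair_table(10, 57, 4558))
#' @export
concordance_rates <- function(tab) {
  stopifnot(inherits(tab, "pair_contingency"))
  if (tab$total == 0) stop("empty table")
  den <- tab$n_cc + tab$n_cd
  if (den == 0) {
    return(list(pairwise = NA_real_, probandwise = NA_real_, defined = FALSE))
  }
  list(pairwise = tab$n_cc / den,
       probandwise = 2 * tab$n_cc / (2 * tab$n_cc + tab$n_cd),
       defined = TRUE)
}

# symmetric double-entered log likelihood, up to the constant ncd*log(2):
# cells p11 = P(both above), p10 = P(above, below) (discordant mass split
# evenly across the two off-diagonal cells), p00 = remainder
tetra_loglik <- function(rho, tau, n_cc, n_cd, n_dd) {
  p11 <- bvn_upper(tau, tau, rho)
  pu <- stats::pnorm(tau, lower.tail = FALSE)
  p10 <- pu - p11
  p00 <- 1 - 2 * pu + p11
  if (p11 <= 0 || p10 <= 0 || p00 <= 0) return(-Inf)
  n_cc * log(p11) + n_cd * log(p10) + n_dd * log(p00)
}

#' Maximum-likelihood tetrachoric correlation of a twin pair table
#'
#' Maximises the symmetric double-entered bivariate-normal likelihood of the
#' pair table with a single threshold shared by both members (twins within a
#' stratum are exchangeable). Returns the ML correlation, the threshold, the
#' maximised log likelihood and a delta-method 95% CI computed on the
#' Fisher-z scale.
#'
#' @param tab A `pair_contingency`.
#' @param correction Add 0.5 to every cell before fitting (off by default);
#'   useful for tables with an empty concordant-affected cell.
#' @param conf.level Confidence level for the CI.
#' @return An object of class `tetrachoric_estimate` with elements `rho`,
#'   `threshold`, `ci95`, `loglik`, `se`, `boundary`, `converged`. Tables
#'   with a degenerate margin (no affected or no unaffected individuals)
#'   return `boundary = TRUE` and no estimate.
#' @examples
#' tetrachoric(pair_table(10, 57, 4558, "MZM"))
#' @export
tetrachoric <- function(tab, correction = FALSE, conf.level = 0.95) {
  stopifnot(inherits(tab, "pair_contingency"))
  n_cc <- tab$n_cc; n_cd <- tab$n_cd; n_dd <- tab$n_dd
  if (correction) { n_cc <- n_cc + 0.5; n_cd <- n_cd + 0.5; n_dd <- n_dd + 0.5 }
  n_aff <- 2 * n_cc + n_cd
  n_un <- 2 * n_dd + n_cd
  if (n_aff == 0 || n_un == 0) {
    return(structure(list(rho = NA_real_, threshold = NA_real_, ci95 = c(NA_real_, NA_real_),
                          loglik = NA_real_, se = NA_real_, boundary = TRUE, converged = FALSE,
                          stratum = tab$stratum),
                     class = "tetrachoric_estimate"))
  }
  q <- n_aff / (2 * (n_cc + n_cd + n_dd))
  nll <- function(par) {
    if (any(!is.finite(par))) return(1e10)
    v <- -tetra_loglik(tanh(par[1]), par[2], n_cc, n_cd, n_dd)
    if (!is.finite(v)) 1e10 else v
  }
  start <- c(atanh(0.3), stats::qnorm(1 - q))
  opt <- stats::optim(start, nll, method = "BFGS", control = list(maxit = 500))
  if (opt$convergence != 0) {
    for (s in c(0, 0.6, -0.3)) {
      alt <- stats::optim(c(atanh(s * 0.99), stats::qnorm(1 - q)), nll,
                          method = "Nelder-Mead", control = list(maxit = 2000))
      if (alt$value < opt$value) opt <- alt
    }
  }
  h <- stats::optimHess(opt$par, nll)
  se_z <- tryCatch(sqrt(solve(h)[1, 1]), error = function(e) NA_real_)
  zhat <- opt$par[1]
  zcrit <- stats::qnorm(1 - (1 - conf.level) / 2)
  ci <- if (is.na(se_z)) c(NA_real_, NA_real_) else tanh(zhat + c(-1, 1) * zcrit * se_z)
  rho <- tanh(zhat)
  structure(list(rho = rho, threshold = opt$par[2], ci95 = ci,
                 loglik = -opt$value,
                 se = if (is.na(se_z)) NA_real_ else se_z * (1 - rho^2),
                 boundary = FALSE, converged = opt$convergence == 0,
                 stratum = tab$stratum),
            class = "tetrachoric_estimate")
}

#' @export
print.tetrachoric_estimate <- function(x, ...) {
  if (isTRUE(x$boundary)) {
    cat(sprintf("Tetrachoric [%s]: degenerate margin, no estimate\n", x$stratum))
  } else {
    cat(sprintf("Tetrachoric [%s]: rho = %.3f (95%% CI %.3f to %.3f), threshold = %.3f, logLik = %.3f\n",
                x$stratum, x$rho, x$ci95[1], x$ci95[2], x$threshold, x$loglik))
  }
  invisible(x)
}

#' Model-based case-wise concordance
#'
#' Probability that a twin is affected given an affected co-twin, implied by
#' the liability model: `P2(z, z; rho) / q`, where `z = qnorm(1 - q)` and
#' `P2` is the bivariate standard-normal upper-orthant probability.
#'
#' @param rho Liability correlation in (-1, 1).
#' @param q Prevalence in (0, 1).
#' @return Case-wise concordance (vectorised over `rho`/`q`).
#' @examples
#' model_casewise(0.80, 0.06)  # ~0.51
#' @export
model_casewise <- function(rho, q) {
  if (any(q <= 0 | q >= 1)) stop("q must be in (0, 1)")
  if (any(abs(rho) >= 1)) stop("rho must be in (-1, 1)")
  z <- stats::qnorm(1 - q)
  bvn_upper(z, z, rho) / q
}
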