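# Independent oracle for the tetrachoric likelihood: upper-orthant
# probabilities by 1-D numerical integration (no mvtnorm, no optim over
# rho), and the maximum located by a two-stage grid search over rho with a
# 1-D profile optimisation of the threshold.

oracle_orthant <- function(a, b, rho) {
  if (abs(rho) < 1e-12) return(pnorm(a, lower.tail = FALSE) * pnorm(b, lower.tail = FALSE))
  f <- function(x) dnorm(x) * pnorm((b - rho * x) / sqrt(1 - rho^2), lower.tail = FALSE)
  integrate(f, lower = a, upper = Inf, rel.tol = 1e-12, abs.tol = 1e-14)$value
}

oracle_pair_loglik <- function(rho, tau, n_cc, n_cd, n_dd) {
  p11 <- oracle_orthant(tau, tau, rho)
  pu <- pnorm(tau, lower.tail = FALSE)
  p10 <- pu - p11
  p00 <- 1 - 2 * pu + p11
  if (p11 <= 0 || p10 <= 0 || p00 <= 0) return(-1e12)   # keep optimize() finite
  n_cc * log(p11) + n_cd * log(p10) + n_dd * log(p00)
}

# two-stage grid over rho (coarse 1e-3 step, then 1e-5 refinement around the
# coarse optimum); the threshold is profiled out by optimize()
oracle_tetrachoric <- function(n_cc, n_cd, n_dd) {
  q <- (2 * n_cc + n_cd) / (2 * (n_cc + n_cd + n_dd))
  tau0 <- qnorm(1 - q)
  prof <- function(rho) {
    o <- optimize(function(tau) -oracle_pair_loglik(rho, tau, n_cc, n_cd, n_dd),
                  interval = tau0 + c(-1, 1))
    -o$objective
  }
  coarse <- seq(-0.999, 0.999, by = 1e-3)
  ll1 <- vapply(coarse, prof, numeric(1))
  r1 <- coarse[which.max(ll1)]
  fine <- seq(max(-0.9999, r1 - 2e-3), min(0.9999, r1 + 2e-3), by = 1e-5)
  ll2 <- vapply(fine, prof, numeric(1))
  list(rho = fine[which.max(ll2)], loglik = max(ll2))
}
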