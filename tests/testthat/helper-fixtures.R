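# Shared test fixtures: all built in code, no stored data.

# A tiny deterministic trial: 3/10 events in the active arm, 5/10 in the
# comparator arm, one balanced binary covariate.
tiny_trial <- function() {
  t <- rep(c(1, 0), each = 10)
  y <- c(rep(1, 3), rep(0, 7), rep(1, 5), rep(0, 5))
  x <- rep(c(0, 1), 10)
  ipd_trial(y, t, matrix(x, ncol = 1, dimnames = list(NULL, "x1")))
}

# An ALD summary whose B and C arms have equal odds (log-OR exactly 0).
null_ald <- function(means = 0.5, sds = 0.3) {
  ald_summary(cov_means = means, cov_sds = sds, n_B = 100, n_C = 100,
              events_B = 50, events_C = 50)
}

# Degenerate posterior: every draw identical, for closed-form checks of
# the marginalization step.
fake_posterior <- function(beta0 = 0, beta_t = 0, beta_pf = 0,
                           beta_em = 0, L = 50) {
  K <- length(beta_pf)
  stopifnot(length(beta_em) == K)
  draws <- matrix(rep(c(beta0, beta_t, beta_pf, beta_em), each = L), L)
  colnames(draws) <- c("(Intercept)", "t", paste0("x", 1:K),
                       paste0("x", 1:K, ":t"))
  structure(
    list(L = L, beta0 = draws[, 1], beta_t = draws[, 2],
         beta_pf = draws[, 2 + seq_len(K), drop = FALSE],
         beta_em = draws[, 2 + K + seq_len(K), drop = FALSE],
         draws = draws,
         diagnostics = list(table = NULL, acceptance = NA),
         method = "degenerate", prior_sd = Inf,
         covariate_names = paste0("x", 1:K)),
    class = "posterior_sample")
}

# Simulate a two-arm trial directly from coefficients over a given
# covariate matrix (bypasses scenario plumbing for focused tests).
sim_outcomes <- function(X, beta0, beta_t, beta_pf, beta_em) {
  n <- nrow(X)
  t <- rep(c(1, 0), length.out = n)
  eta <- beta0 + beta_t * t + drop(X %*% beta_pf) + t * drop(X %*% beta_em)
  ipd_trial(stats::rbinom(n, 1, stats::plogis(eta)), t, X)
}

# 1-D quadrature of E[expit(a + b * X)] for X ~ N(m, s^2): the
# independent oracle for marginal probabilities under a normal covariate.
expit_normal_mean <- function(a, b, m, s) {
  stats::integrate(function(x) stats::plogis(a + b * x) * stats::dnorm(x, m, s),
                   m - 10 * s, m + 10 * s, rel.tol = 1e-10)$value
}
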