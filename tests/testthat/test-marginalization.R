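test_that("ALD-side log-OR matches textbook 2x2 arithmetic", {
  ald <- ald_summary(0.5, 0.3, n_B = 100, n_C = 100,
                     events_B = 30, events_C = 50)
  res <- ald_log_or(ald)
  expect_equal(res$estimate, log(3 / 7), tolerance = 1e-12)
  expect_equal(res$se, sqrt(1 / 30 + 1 / 70 + 1 / 50 + 1 / 50),
               tolerance = 1e-12)
  expect_false(res$continuity_corrected)

  # equal odds -> zero
  expect_equal(ald_log_or(null_ald())$estimate, 0)

  # zero cell -> 0.5 correction on every cell, finite output, flagged
  ald0 <- ald_summary(0.5, 0.3, n_B = 50, n_C = 50,
                      events_B = 10, events_C = 0)
  res0 <- ald_log_or(ald0)
  expect_true(res0$continuity_corrected)
  expect_true(is.finite(res0$estimate) && is.finite(res0$se))
  expect_equal(res0$estimate, log((10.5 / 40.5) / (0.5 / 50.5)),
               tolerance = 1e-12)
})

test_that("Bucher arithmetic identities", {
  b <- bucher(list(estimate = -1.0, se = 0.3), list(estimate = -0.5, se = 0.4))
  expect_equal(b$point, -0.5)
  expect_equal(b$se, 0.5)
  expect_equal(b$ci_low, -0.5 - 1.96 * 0.5)
  expect_equal(bucher(c(-0.7, 0.2), c(-0.7, 0.1))$point, 0)
  expect_equal(bucher(c(0, 0), c(0, 0.37))$se, 0.37)
})

test_that("Dirichlet draws have the right support, sum and mean", {
  set.seed(51)
  w <- c(0.4, 0.3, 0.2, 0.1)
  P <- rdirichlet(1e4, 20 * w)
  expect_equal(rowSums(P), rep(1, 1e4), tolerance = 1e-12)
  expect_true(all(P >= 0))
  # E[pi] = w; SE of the mean = sqrt(w(1-w)/(a0+1))/sqrt(n)
  mc_se <- sqrt(w * (1 - w) / 21) / sqrt(1e4)
  expect_true(all(abs(colMeans(P) - w) < 3 * mc_se + 1e-4))
})

test_that("G-computation collapses correctly for degenerate posteriors", {
  ald <- ald_summary(c(0.5, 0.8), c(0.2, 0.3), n_B = 100, n_C = 100,
                     events_B = 30, events_C = 50)
  anchor <- ald_log_or(ald)

  # all-zero coefficients: every contrast is 0, point = -anchor
  post0 <- fake_posterior(0, 0, c(0, 0), c(0, 0), L = 40)
  g0 <- gcomp_parametric(post0, ald, "mvn", diag(2), n_star = 200)
  expect_equal(g0$point, -anchor$estimate, tolerance = 1e-12)
  expect_equal(unname(g0$draws), rep(0, 40))
  expect_equal(g0$se, anchor$se, tolerance = 1e-12)

  # covariates inert: contrast equals beta_t exactly (collapsible)
  postc <- fake_posterior(-0.3, 0.9, c(0, 0), c(0, 0), L = 25)
  gc <- gcomp_parametric(postc, ald, "mvgamma", diag(2), n_star = 200)
  expect_equal(unname(gc$draws), rep(0.9, 25), tolerance = 1e-12)
  expect_equal(gc$point, 0.9 - anchor$estimate, tolerance = 1e-12)
})

test_that("G-computation matches a 1-D quadrature oracle", {
  set.seed(52)
  b0 <- -0.4; bt <- -1.1; bpf <- 0.8; bem <- 0.6
  m <- 0.5; s <- 0.25
  ald <- ald_summary(m, s, n_B = 200, n_C = 200,
                     events_B = 70, events_C = 90)
  post <- fake_posterior(b0, bt, bpf, bem, L = 10)
  g <- gcomp_parametric(post, ald, "mvn", matrix(1), n_star = 1e5)
  mu1 <- expit_normal_mean(b0 + bt, bpf + bem, m, s)
  mu0 <- expit_normal_mean(b0, bpf, m, s)
  oracle <- qlogis(mu1) - qlogis(mu0)
  expect_equal(unname(g$draws[1]), oracle, tolerance = 0.03)
  expect_equal(g$point, oracle - ald_log_or(ald)$estimate, tolerance = 0.03)
})

test_that("simulated ALD populations match the published moments", {
  set.seed(53)
  ald <- ald_summary(c(0.6, 1.5), c(0.2, 0.5), n_B = 100, n_C = 100,
                     events_B = 30, events_C = 40)
  corr <- matrix(c(1, 0.3, 0.3, 1), 2)
  for (fam in c("mvn", "mvgamma")) {
    X <- simulate_ald_population(ald, fam, corr, n_star = 5e4)
    expect_equal(unname(colMeans(X)), c(0.6, 1.5), tolerance = 0.02)
    expect_equal(unname(apply(X, 2, sd)), c(0.2, 0.5), tolerance = 0.02)
    expect_equal(cor(X)[1, 2], 0.3, tolerance = 0.05)
  }
  # gamma family is right-skewed, normal is not
  Xg <- simulate_ald_population(ald, "mvgamma", corr, n_star = 5e4)
  skew <- mean(((Xg[, 2] - mean(Xg[, 2])) / sd(Xg[, 2]))^3)
  expect_gt(skew, 0.3)
})

test_that("G-MAIC reduces to empirical G-computation in the large-concentration limit", {
  set.seed(54)
  X <- matrix(rnorm(120, 0.5, 0.3), ncol = 1)
  tr <- sim_outcomes(X, -0.4, 0.7, 0.6, 0.5)
  w <- estimate_weights(tr$X, mean(tr$X))  # uniform weights
  post <- fake_posterior(-0.4, 0.7, 0.6, 0.5, L = 30)
  g <- gmaic(post, tr, w, null_ald(), .concentration_scale = 1e6)
  p1 <- predict_prob(1, post, tr$X, 1)
  p0 <- predict_prob(1, post, tr$X, 0)
  emp <- qlogis(mean(p1)) - qlogis(mean(p0))
  expect_true(all(abs(g$draws - emp) < 1e-3))
})

test_that("G-MAIC degenerate cases", {
  set.seed(55)
  X <- matrix(rnorm(40, 0.5, 0.3), ncol = 1)
  tr <- sim_outcomes(X, 0.2, 0.5, 0.3, 0.1)
  w <- estimate_weights(tr$X, mean(tr$X))

  # zero coefficients: contrast 0 regardless of the Dirichlet draw
  post0 <- fake_posterior(0, 0, 0, 0, L = 20)
  g0 <- gmaic(post0, tr, w, null_ald())
  expect_equal(unname(g0$draws), rep(0, 20), tolerance = 1e-12)

  # n = 1: the simplex is a point, contrast is that profile's logit diff
  tr1 <- ipd_trial(1, 1, matrix(0.4))
  w1 <- structure(list(alpha = 0, w = 1, w_norm = 1, ess = 1,
                       converged = TRUE, balance_residual = 0),
                  class = "maic_weights")
  post1 <- fake_posterior(-0.2, 0.8, 0.5, 0.3, L = 10)
  g1 <- gmaic(post1, tr1, w1, null_ald())
  d_prof <- (-0.2 + 0.8 + 0.4 * (0.5 + 0.3)) - (-0.2 + 0.4 * 0.5)
  expect_equal(unname(g1$draws), rep(d_prof, 10), tolerance = 1e-12)

  # unconverged weights: flagged invalid, not an error
  wbad <- structure(list(converged = FALSE), class = "maic_weights")
  gbad <- gmaic(post1, tr1, wbad, null_ald())
  expect_false(gbad$valid)
})

test_that("every estimator reconstructs the adjusted A-vs-C contrast when unanchored", {
  set.seed(56)
  cfg <- scenario_config(n_ipd = 200, overlap = "high", structure = "normal")
  ac <- simulate_trial(cfg, "AC")
  ald <- aggregate_ipd(simulate_trial(cfg, "BC"))
  anchor <- ald_log_or(ald)
  w <- estimate_weights(ac$X, ald$cov_means)
  post <- fit_outcome_model(ac, L = 300, method = "laplace")

  g <- gmaic(post, ac, w, ald)
  expect_equal(g$point + anchor$estimate, mean(g$draws), tolerance = 1e-12)
  gc <- gcomp_parametric(post, ald, "mvn", cor(ac$X), n_star = 500)
  expect_equal(gc$point + anchor$estimate, mean(gc$draws), tolerance = 1e-12)
  m <- maic(ac, ald, n_boot = 50)
  expect_equal(m$point + anchor$estimate,
               gmaic:::.weighted_logor_t(ac$y, ac$t, m$weights$w_norm),
               tolerance = 1e-12)
  b <- bucher(ipd_log_or(ac), ald)
  expect_equal(b$point + anchor$estimate, ipd_log_or(ac)$estimate,
               tolerance = 1e-12)
})

test_that("G-MAIC agrees with G-computation when the ALD is the aggregated IPD", {
  set.seed(57)
  cfg <- scenario_config(n_ipd = 300, overlap = "high", structure = "normal")
  agree <- replicate(60, {
    tr <- simulate_trial(cfg, "BC")   # serves as both IPD and ALD source
    tr$t <- tr$t                      # active arm treated as "A"
    ald <- aggregate_ipd(tr)
    w <- estimate_weights(tr$X, ald$cov_means)
    post <- fit_outcome_model(tr, L = 300, method = "laplace")
    g1 <- gmaic(post, tr, w, ald)
    g2 <- gcomp_parametric(post, ald, "mvn", cor(tr$X), n_star = 500)
    abs(g1$point - g2$point) < 3 * sqrt(g1$se^2 + g2$se^2)
  })
  expect_gt(mean(agree), 0.95)
})

test_that("tempering spreads the concentration and inflates propagated variance", {
  set.seed(58)
  cfg <- scenario_config(n_ipd = 150, overlap = "poor", structure = "normal")
  # the Bayesian-bootstrap variance component is isolated by holding the
  # outcome-model draw fixed: all Delta variation then comes from the
  # Dirichlet weights whose concentration tempering spreads out
  post <- fake_posterior(-0.5, 0.4, rep(0.5, 5), rep(1, 5), L = 3000)
  sd_ratio <- replicate(10, {
    tr <- simulate_trial(cfg, "AC")
    ald <- aggregate_ipd(simulate_trial(cfg, "BC"))
    w <- estimate_weights(tr$X, ald$cov_means)
    if (!w$converged) return(NA)
    n <- length(tr$y)
    ess_full <- ess(n * w$w_norm)
    ess_temp <- ess(n * w$w_norm^0.5 / sum(w$w_norm^0.5))
    expect_gt(ess_temp, ess_full)  # deterministic part of the property
    g1 <- gmaic(post, tr, w, ald, temper = 1)
    g05 <- gmaic(post, tr, w, ald, temper = 0.5)
    sd(g05$draws) / sd(g1$draws)
  })
  expect_gt(mean(sd_ratio, na.rm = TRUE), 1)
})

test_that("marginal_estimate methods behave", {
  est <- marginal_estimate(point = 0.2, se = 0.1, method = "bucher")
  expect_equal(unname(coef(est)), 0.2)
  ci <- confint(est)
  z <- qnorm(0.975)
  expect_equal(unname(ci[1, ]), c(0.2 - z * 0.1, 0.2 + z * 0.1),
               tolerance = 1e-10)
  expect_true(est$ci_low <= est$point && est$point <= est$ci_high)
  s <- summary(est)
  expect_equal(s$estimate, 0.2)
  expect_output(print(est), "Bucher")
  bad <- marginal_estimate(NA_real_, NA_real_, method = "maic",
                           valid = TRUE, notes = "boom")
  expect_false(bad$valid)  # non-finite forces invalid
})
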