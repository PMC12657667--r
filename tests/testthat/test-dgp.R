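test_that("normal covariate simulation honours its moments", {
  set.seed(21)
  cm <- covariate_model("normal", means = c(1, 2, 3), sds = c(1, 1, 1),
                        correlation = diag(3))
  X <- simulate_covariates(cm, 1e5)
  expect_true(max(abs(cor(X) - diag(3))) < 0.02)
  expect_true(max(abs(colMeans(X) - c(1, 2, 3))) < 0.02)

  tight <- covariate_model("normal", means = rep(1, 2), sds = rep(1e-8, 2),
                           correlation = diag(2))
  Xt <- simulate_covariates(tight, 100)
  expect_true(max(abs(Xt - 1)) < 1e-6)

  bad <- matrix(c(1, 0.9, 0.9, 0.9, 1, -0.9, 0.9, -0.9, 1), 3)
  expect_error(covariate_model("normal", means = rep(0, 3), sds = rep(1, 3),
                               correlation = bad), "positive definite")
})

test_that("nonnormal covariates hit their closed-form marginals", {
  set.seed(22)
  cm <- covariate_model("nonnormal", means = c(0.6, 0.6, 0.6, 0.5, 0.3),
                        correlation = {
                          m <- matrix(0.2, 3, 3); diag(m) <- 1; m
                        })
  X <- simulate_covariates(cm, 1e5)
  # binary columns: marginal probabilities from the quadrature threshold
  expect_lt(abs(mean(X[, 4]) - 0.5), 0.01)
  expect_lt(abs(mean(X[, 5]) - 0.3), 0.01)
  expect_true(all(X[, 4:5] %in% c(0, 1)))
  # gamma marginals: mean matched, sd = mean/sqrt(shape)
  expect_true(max(abs(colMeans(X[, 1:3]) - 0.6)) < 0.01)
  expect_true(max(abs(apply(X[, 1:3], 2, sd) - 0.6 / sqrt(2))) < 0.01)
  # dependence of the binaries on x1 is non-monotone (quadratic): weak
  # linear correlation but clear association across x1 terciles
  terc <- cut(X[, 1], quantile(X[, 1], c(0, 1/3, 2/3, 1)),
              include.lowest = TRUE)
  rates <- tapply(X[, 4], terc, mean)
  expect_gt(max(rates) - min(rates), 0.05)
})

test_that("scenario grid is the 18-element factorial product", {
  sc <- make_scenarios()
  expect_length(sc, 18)
  triples <- vapply(sc, function(s)
    paste(s$n_ipd, s$overlap, s$structure), "")
  expect_equal(anyDuplicated(triples), 0L)
  expect_length(make_scenarios(n_ipd_values = 100), 6)
})

test_that("simulated trials obey the outcome model", {
  set.seed(23)
  cfg <- scenario_config(n_ipd = 2e4, overlap = "high", structure = "normal",
                         outcome_coeffs = outcome_coefficients(
                           beta0 = 0, beta_t = 0,
                           beta_pf = rep(0, 5), beta_em = rep(0, 5)))
  tr <- simulate_trial(cfg, "AC")
  expect_equal(sum(tr$t), 1e4)  # exact 1:1 blocks
  expect_lt(abs(mean(tr$y) - 0.5), 0.02)

  # forcing limit: hugely negative treatment effect, no modification
  cfg2 <- scenario_config(n_ipd = 2000, overlap = "high",
                          structure = "normal",
                          outcome_coeffs = outcome_coefficients(
                            beta0 = 0, beta_t = -1e6,
                            beta_pf = rep(0.5, 5), beta_em = rep(0, 5)))
  tr2 <- simulate_trial(cfg2, "AC")
  expect_equal(sum(tr2$y[tr2$t == 1]), 0)

  # comparator-arm rate matches the calibrated control event rate
  set.seed(24)
  cfg3 <- scenario_config(n_ipd = 100, n_ald = 1e5, overlap = "moderate",
                          structure = "normal")
  bc <- simulate_trial(cfg3, "BC")
  rate_C <- mean(bc$y[bc$t == 0])
  expect_lt(abs(rate_C - 0.35), 3 * sqrt(0.35 * 0.65 / 5e4) + 0.005)
})

test_that("same seed gives bit-identical trials", {
  cfg <- scenario_config(n_ipd = 100, overlap = "poor",
                         structure = "nonnormal")
  set.seed(99); a <- simulate_trial(cfg, "AC")
  set.seed(99); b <- simulate_trial(cfg, "AC")
  expect_identical(a, b)
})

test_that("design truth is zero under shared effects and matches a quadrature oracle otherwise", {
  set.seed(25)
  cfg <- scenario_config(n_ipd = 100, overlap = "high", structure = "normal")
  d0 <- true_marginal_effect(cfg, n_large = 1e5)
  expect_equal(as.numeric(d0), 0)  # identical coefficients: exact zero

  # no effect modification, different treatment effects: oracle by 1-D
  # quadrature over the normal linear predictor
  co <- outcome_coefficients(beta0 = -0.5, beta_t = -1, beta_t_B = -0.4,
                             beta_pf = rep(0.5, 5), beta_em = rep(0, 5))
  cfg2 <- scenario_config(n_ipd = 100, overlap = "high",
                          structure = "normal", outcome_coeffs = co)
  bc <- cfg2$covariate_models$bc
  Sig <- diag(bc$sds) %*% bc$correlation %*% diag(bc$sds)
  m <- sum(co$beta_pf * bc$means)
  s <- sqrt(drop(t(co$beta_pf) %*% Sig %*% co$beta_pf))
  muA <- expit_normal_mean(co$beta0 + co$beta_t, 1, m, s)
  muB <- expit_normal_mean(co$beta0 + co$beta_t_B, 1, m, s)
  oracle <- qlogis(muA) - qlogis(muB)
  d <- true_marginal_effect(cfg2, n_large = 4e5)
  expect_lt(abs(as.numeric(d) - oracle), 4 * attr(d, "mcse") + 0.002)

  # collapsible case: no covariate effects at all
  co3 <- outcome_coefficients(beta0 = -0.2, beta_t = -1, beta_t_B = -0.4,
                              beta_pf = rep(0, 5), beta_em = rep(0, 5))
  cfg3 <- scenario_config(n_ipd = 100, overlap = "high",
                          structure = "normal", outcome_coeffs = co3)
  d3 <- true_marginal_effect(cfg3, n_large = 1e5)
  expect_equal(as.numeric(d3), -1 - (-0.4), tolerance = 1e-9)
})

test_that("the odds ratio is non-collapsible under prognostic effects", {
  set.seed(26)
  cfg <- scenario_config(n_ipd = 2e5, overlap = "high", structure = "normal")
  ac <- simulate_trial(cfg, "AC")
  marg <- ipd_log_or(ac)$estimate
  co <- cfg$outcome_coeffs
  cond_at_mean <- co$beta_t +
    sum(cfg$covariate_models$ac$means * co$beta_em)
  # marginal and conditional-at-the-mean log-ORs differ materially
  # (attenuation of the marginal OR under strong prognostic heterogeneity)
  expect_gt(abs(marg - cond_at_mean), 0.05)
  expect_lt(abs(marg), abs(cond_at_mean))
})

test_that("overlap levels deliver the target mean ESS reductions", {
  set.seed(27)
  targets <- c(high = 0.31, moderate = 0.55, poor = 0.827)
  for (ov in names(targets)) {
    cms <- default_covariate_models("normal", ov)
    reds <- replicate(200, {
      X <- simulate_covariates(cms$ac, 600)
      w <- estimate_weights(X, cms$bc$means)
      if (w$converged) 1 - w$ess / 600 else NA
    })
    expect_lt(abs(mean(reds, na.rm = TRUE) - targets[[ov]]), 0.10)
  }
  targets_nn <- c(high = 0.327, poor = 0.81)
  for (ov in names(targets_nn)) {
    cms <- default_covariate_models("nonnormal", ov)
    reds <- replicate(100, {
      X <- simulate_covariates(cms$ac, 600)
      w <- estimate_weights(X, cms$bc$means)
      if (w$converged) 1 - w$ess / 600 else NA
    })
    expect_lt(abs(mean(reds, na.rm = TRUE) - targets_nn[[ov]]), 0.10)
  }
})
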