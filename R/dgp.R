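## Synthetic two-trial anchored networks: covariate models, outcome model,
## scenario grid, and the design-implied true marginal effect.

#' Outcome-model coefficients for the binary-outcome logistic DGP
#'
#' The event probability for a participant with covariates x under
#' treatment t is expit(beta0 + beta_t * t + x' beta_pf + t * x' beta_em):
#' every covariate is both prognostic (\code{beta_pf}) and an effect
#' modifier (\code{beta_em}), and the interaction coefficients are shared
#' between the two active treatments (shared effect modifiers).
#'
#' @param beta0 baseline log-odds.  \code{NA} means "calibrate from the
#'   control event rate" (done by \code{\link{scenario_config}}).
#' @param beta_t conditional treatment log-odds-ratio of active treatment
#'   A versus the common comparator.
#' @param beta_pf numeric vector of prognostic log-odds-ratios.
#' @param beta_em numeric vector of effect-modifier interaction
#'   log-odds-ratios (same length as \code{beta_pf}).
#' @param beta_t_B conditional log-OR of active treatment B versus the
#'   comparator; defaults to \code{beta_t} (equal effects, so the design
#'   truth for A vs B is zero).
#' @return An object of class \code{outcome_coefficients}.
#' @export
outcome_coefficients <- function(beta0 = NA_real_,
                                 beta_t = log(0.25),
                                 beta_pf = rep(0.5, 5),
                                 beta_em = rep(1.0, 5),
                                 beta_t_B = beta_t) {
  beta_pf <- as.numeric(beta_pf)
  beta_em <- as.numeric(beta_em)
  if (length(beta_em) != length(beta_pf))
    stop("beta_pf and beta_em must have the same length")
  stopifnot(is.finite(beta_t), is.finite(beta_t_B),
            all(is.finite(beta_pf)), all(is.finite(beta_em)))
  structure(list(beta0 = beta0, beta_t = beta_t, beta_t_B = beta_t_B,
                 beta_pf = beta_pf, beta_em = beta_em),
            class = "outcome_coefficients")
}

#' Covariate model for one trial population
#'
#' Two structures are supported.  \code{"normal"}: a multivariate normal
#' with the given means, SDs and correlation.  \code{"nonnormal"}: the
#' first \code{K - n_binary} covariates are continuous with Gamma
#' marginals (fixed shape, scale set by the target mean) joined by a
#' Gaussian copula, and the remaining covariates are binary indicators
#' obtained by thresholding a noisy quadratic function of the first
#' covariate -- a non-linear dependence structure that a log-linear trial
#' assignment model cannot represent.
#'
#' @param structure \code{"normal"} or \code{"nonnormal"}.
#' @param means target covariate means (for binary covariates, marginal
#'   probabilities).
#' @param sds SDs of the continuous covariates (normal structure only;
#'   under the nonnormal structure the Gamma shape fixes the SD).
#' @param correlation correlation matrix of the continuous block (used as
#'   the Gaussian-copula correlation under the nonnormal structure).
#' @param gamma_shape Gamma shape of the skewed continuous marginals.
#' @param n_binary number of trailing binary covariates (nonnormal only).
#' @param binary_noise_sd SD of the Gaussian noise added to the quadratic
#'   score before thresholding.
#' @return An object of class \code{covariate_model}.
#' @export
covariate_model <- function(structure = c("normal", "nonnormal"),
                            means, sds = NULL, correlation = NULL,
                            gamma_shape = 2, n_binary = 2,
                            binary_noise_sd = 1) {
  structure <- match.arg(structure)
  means <- as.numeric(means)
  K <- length(means)
  if (structure == "normal") {
    n_cont <- K
    n_binary <- 0L
  } else {
    n_binary <- as.integer(n_binary)
    n_cont <- K - n_binary
    if (n_cont < 1L) stop("need at least one continuous covariate")
    pb <- means[(n_cont + 1L):K]
    if (any(pb < 0 | pb > 1))
      stop("binary covariate means must lie in [0, 1]")
  }
  if (is.null(correlation)) correlation <- diag(n_cont)
  correlation <- as.matrix(correlation)
  if (nrow(correlation) != n_cont || ncol(correlation) != n_cont)
    stop("correlation must be ", n_cont, "x", n_cont,
         " (continuous block only)")
  if (max(abs(correlation - t(correlation))) > 1e-10 ||
      max(abs(diag(correlation) - 1)) > 1e-10)
    stop("correlation must be symmetric with unit diagonal")
  ev <- eigen(correlation, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-12)
    stop("correlation matrix is not positive definite")
  if (structure == "normal") {
    if (is.null(sds)) stop("sds required for the normal structure")
    sds <- as.numeric(sds)
    if (length(sds) != K) stop("sds must match means in length")
    if (any(sds <= 0)) stop("continuous covariate SDs must be > 0")
    obj <- list(structure = structure, means = means, sds = sds,
                correlation = correlation, n_binary = 0L)
  } else {
    cont_means <- means[seq_len(n_cont)]
    if (any(cont_means <= 0))
      stop("Gamma-marginal covariates need strictly positive means")
    scales <- cont_means / gamma_shape
    cont_sds <- sqrt(gamma_shape) * scales
    pb <- means[(n_cont + 1L):K]
    thr <- vapply(pb, function(p)
      .quadratic_score_threshold(p, gamma_shape, binary_noise_sd), 0)
    obj <- list(structure = structure, means = means,
                sds = c(cont_sds, sqrt(pb * (1 - pb))),
                correlation = correlation,
                gamma_shape = gamma_shape, gamma_scales = scales,
                n_binary = n_binary, binary_probs = pb,
                binary_noise_sd = binary_noise_sd,
                binary_thresholds = thr)
  }
  class(obj) <- "covariate_model"
  obj
}

## Threshold q with P(Z^2 + eps > q) = p, where Z is a standardized
## Gamma(shape) variate and eps ~ N(0, noise_sd): solved by 1-D quadrature
## over the Gamma density so the binary marginals have a known closed form.
.quadratic_score_threshold <- function(p, shape, noise_sd) {
  stopifnot(p > 0, p < 1)
  ## work on the unit-scale gamma; standardization removes the scale anyway
  prob_exceed <- function(q) {
    f <- function(x) {
      z <- (x - shape) / sqrt(shape)
      stats::pnorm((z^2 - q) / noise_sd) * stats::dgamma(x, shape = shape)
    }
    stats::integrate(f, 0, Inf, rel.tol = 1e-9)$value
  }
  stats::uniroot(function(q) prob_exceed(q) - p,
                 lower = -8, upper = 60, tol = 1e-9)$root
}

#' Simulate covariates from a covariate model
#'
#' Uses the R global random number generator; call \code{set.seed} for
#' reproducibility.
#'
#' @param model a \code{\link{covariate_model}}.
#' @param n number of rows to draw.
#' @return an \code{n x K} numeric matrix.
#' @export
simulate_covariates <- function(model, n) {
  stopifnot(inherits(model, "covariate_model"), n >= 1)
  K <- length(model$means)
  if (model$structure == "normal") {
    D <- diag(model$sds, K)
    Sigma <- D %*% model$correlation %*% D
    X <- MASS::mvrnorm(n, mu = model$means, Sigma = Sigma)
    if (n == 1L) X <- matrix(X, nrow = 1L)
  } else {
    n_cont <- K - model$n_binary
    Z <- MASS::mvrnorm(n, mu = rep(0, n_cont), Sigma = model$correlation)
    if (n == 1L) Z <- matrix(Z, nrow = 1L)
    U <- stats::pnorm(Z)
    Xc <- vapply(seq_len(n_cont), function(j)
      stats::qgamma(U[, j], shape = model$gamma_shape,
                    scale = model$gamma_scales[j]),
      numeric(n))
    if (n == 1L) Xc <- matrix(Xc, nrow = 1L)
    ## binary covariates: noisy quadratic in the (standardized) first
    ## continuous covariate, thresholded at the precomputed quantile
    z1 <- (Xc[, 1] / model$gamma_scales[1] - model$gamma_shape) /
      sqrt(model$gamma_shape)
    Xb <- vapply(seq_len(model$n_binary), function(j) {
      u <- z1^2 + stats::rnorm(n, 0, model$binary_noise_sd)
      as.numeric(u > model$binary_thresholds[j])
    }, numeric(n))
    if (n == 1L) Xb <- matrix(Xb, nrow = 1L)
    X <- cbind(Xc, Xb)
  }
  colnames(X) <- paste0("x", seq_len(K))
  X
}

## Per-overlap downward shift of the AC-trial covariate means relative to
## the BC trial.  Calibrated (once, by stochastic root-finding at n = 600)
## so that the average MAIC effective-sample-size reduction hits the
## design targets: normal 31/55/82.7%, nonnormal 32.7/55/81%.
.overlap_offsets <- list(
  normal    = c(high = 0.0723, moderate = 0.1079, poor = 0.1671),
  nonnormal = c(high = 0.1296, moderate = 0.1767, poor = 0.2439)
)

#' Default covariate models for both trials of a scenario
#'
#' The BC (aggregate-level) trial population has five covariates centred
#' at 0.6; the AC (IPD) trial population is shifted downward by a
#' per-overlap offset calibrated so that the mean MAIC ESS reduction at
#' n = 600 matches the design targets (roughly 31\%, 55\% and 83\% for
#' high, moderate and poor overlap under the normal structure).
#'
#' @param structure \code{"normal"} or \code{"nonnormal"}.
#' @param overlap \code{"high"}, \code{"moderate"} or \code{"poor"}.
#' @param K number of covariates.
#' @return list with \code{ac} and \code{bc} \code{\link{covariate_model}}s.
#' @export
default_covariate_models <- function(structure = c("normal", "nonnormal"),
                                     overlap = c("high", "moderate", "poor"),
                                     K = 5) {
  structure <- match.arg(structure)
  overlap <- match.arg(overlap)
  delta <- .overlap_offsets[[structure]][[overlap]]
  if (structure == "normal") {
    corr <- matrix(0.2, K, K); diag(corr) <- 1
    bc <- covariate_model("normal", means = rep(0.6, K),
                          sds = rep(0.2, K), correlation = corr)
    ac <- covariate_model("normal", means = rep(0.6 - delta, K),
                          sds = rep(0.2, K), correlation = corr)
  } else {
    n_cont <- K - 2L
    corr <- matrix(0.2, n_cont, n_cont); diag(corr) <- 1
    bc <- covariate_model("nonnormal",
                          means = c(rep(0.6, n_cont), 0.5, 0.5),
                          correlation = corr)
    ac <- covariate_model("nonnormal",
                          means = c(rep(0.6 - delta, n_cont),
                                    0.5 - delta, 0.5 - delta),
                          correlation = corr)
  }
  list(ac = ac, bc = bc)
}

#' Scenario configuration for the simulation study
#'
#' Bundles the trial sizes, overlap level, covariate structure, outcome
#' coefficients and covariate models of one simulation scenario.  When
#' \code{outcome_coeffs$beta0} is \code{NA} the intercept is calibrated so
#' that the comparator-arm event rate in the BC population equals
#' \code{control_event_rate}.
#'
#' @param n_ipd size of the AC (IPD) trial.
#' @param n_ald size of the BC (aggregate) trial.
#' @param overlap population overlap level.
#' @param structure covariate structure.
#' @param outcome_coeffs an \code{\link{outcome_coefficients}}.
#' @param control_event_rate target marginal event rate in the comparator
#'   arm of the BC population, used to calibrate the intercept.
#' @param covariate_models optional list \code{(ac, bc)} overriding
#'   \code{\link{default_covariate_models}}.
#' @return An object of class \code{scenario_config}.
#' @export
scenario_config <- function(n_ipd = 200, n_ald = 600,
                            overlap = c("high", "moderate", "poor"),
                            structure = c("normal", "nonnormal"),
                            outcome_coeffs = outcome_coefficients(),
                            control_event_rate = 0.35,
                            covariate_models = NULL) {
  overlap <- match.arg(overlap)
  structure <- match.arg(structure)
  stopifnot(n_ipd >= 2, n_ald >= 2,
            inherits(outcome_coeffs, "outcome_coefficients"))
  if (n_ipd %% 2 != 0 || n_ald %% 2 != 0)
    stop("trial sizes must be even for 1:1 block randomization")
  if (is.null(covariate_models))
    covariate_models <- default_covariate_models(
      structure, overlap, K = length(outcome_coeffs$beta_pf))
  if (is.na(outcome_coeffs$beta0))
    outcome_coeffs$beta0 <- calibrate_intercept(
      covariate_models$bc, outcome_coeffs, control_event_rate)
  structure(list(n_ipd = as.integer(n_ipd), n_ald = as.integer(n_ald),
                 overlap = overlap, structure = structure,
                 outcome_coeffs = outcome_coeffs,
                 control_event_rate = control_event_rate,
                 covariate_models = covariate_models,
                 label = sprintf("%s/%s/n%d", structure, overlap, n_ipd)),
            class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("scenario ", x$label, ": n_ipd = ", x$n_ipd, ", n_ald = ", x$n_ald,
      ", overlap = ", x$overlap, ", structure = ", x$structure, "\n",
      sep = "")
  invisible(x)
}

## Evaluate an expression with the global RNG saved and restored, seeded
## locally -- used for deterministic internal calibrations that must not
## perturb the caller's random stream.
.with_local_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Calibrate the outcome-model intercept from a control event rate
#'
#' Solves E_X[expit(beta0 + X' beta_pf)] = rate over the given covariate
#' model by root-finding on a large fixed Monte Carlo sample (deterministic;
#' does not disturb the caller's RNG state).
#'
#' @param cov_model the covariate model of the population in which the
#'   rate is defined (the BC trial population by default).
#' @param coeffs an \code{\link{outcome_coefficients}} (only
#'   \code{beta_pf} is used).
#' @param rate target comparator-arm event rate.
#' @param n_mc Monte Carlo sample size.
#' @return the calibrated intercept (scalar).
#' @export
calibrate_intercept <- function(cov_model, coeffs, rate, n_mc = 2e5) {
  stopifnot(rate > 0, rate < 1)
  X <- .with_local_seed(104729L, simulate_covariates(cov_model, n_mc))
  eta <- drop(X %*% coeffs$beta_pf)
  stats::uniroot(function(b0) mean(stats::plogis(b0 + eta)) - rate,
                 lower = -30, upper = 30, tol = 1e-10)$root
}

#' Simulate one trial of a scenario
#'
#' Draws covariates from the trial's population model, assigns treatment
#' 1:1 by block randomization, and draws binary outcomes from the logistic
#' outcome model.  For the AC trial the active treatment is A
#' (\code{beta_t}); for the BC trial it is B (\code{beta_t_B}).
#'
#' @param config a \code{\link{scenario_config}}.
#' @param trial \code{"AC"} (IPD trial, size \code{n_ipd}) or \code{"BC"}
#'   (aggregate trial, size \code{n_ald}).
#' @return An \code{\link{ipd_trial}}.
#' @export
simulate_trial <- function(config, trial = c("AC", "BC")) {
  stopifnot(inherits(config, "scenario_config"))
  trial <- match.arg(trial)
  co <- config$outcome_coeffs
  if (trial == "AC") {
    n <- config$n_ipd
    cm <- config$covariate_models$ac
    bt <- co$beta_t
  } else {
    n <- config$n_ald
    cm <- config$covariate_models$bc
    bt <- co$beta_t_B
  }
  X <- simulate_covariates(cm, n)
  t <- sample(rep(c(1, 0), each = n / 2))
  eta <- co$beta0 + bt * t + drop(X %*% co$beta_pf) +
    t * drop(X %*% co$beta_em)
  y <- stats::rbinom(n, 1, stats::plogis(eta))
  ipd_trial(y, t, X, trial_label = trial)
}

#' The full factorial scenario grid
#'
#' Cartesian product of IPD sizes, overlap levels and covariate
#' structures, in deterministic order (structure slowest, then overlap,
#' then size), yielding 18 scenarios under the defaults.
#'
#' @param n_ipd_values IPD trial sizes.
#' @param overlaps overlap levels.
#' @param structures covariate structures.
#' @param ... further arguments passed to \code{\link{scenario_config}}.
#' @return list of \code{\link{scenario_config}} objects.
#' @export
make_scenarios <- function(n_ipd_values = c(100, 200, 600),
                           overlaps = c("high", "moderate", "poor"),
                           structures = c("normal", "nonnormal"),
                           ...) {
  grid <- expand.grid(n_ipd = n_ipd_values, overlap = overlaps,
                      structure = structures,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(grid)), function(i)
    scenario_config(n_ipd = grid$n_ipd[i], overlap = grid$overlap[i],
                    structure = grid$structure[i], ...))
}

#' Design-implied true marginal A-vs-B effect in the BC population
#'
#' Simulates a large cohort from the BC covariate model and contrasts the
#' marginal event probabilities under hypothetical assignment of everyone
#' to A and to B, using the shared-coefficient outcome model:
#' logit(mu_A) - logit(mu_B).  Under equal treatment effects
#' (\code{beta_t_B == beta_t}) this is exactly zero.  A delta-method Monte
#' Carlo standard error is attached as attribute \code{"mcse"}.
#'
#' @param config a \code{\link{scenario_config}}.
#' @param n_large cohort size (at least 1e6 recommended).
#' @return the marginal log odds ratio (scalar) with attribute
#'   \code{"mcse"}.
#' @export
true_marginal_effect <- function(config, n_large = 1e6) {
  stopifnot(inherits(config, "scenario_config"), n_large >= 1)
  co <- config$outcome_coeffs
  X <- simulate_covariates(config$covariate_models$bc, n_large)
  base <- co$beta0 + drop(X %*% co$beta_pf)
  mod <- drop(X %*% co$beta_em)
  pA <- stats::plogis(base + co$beta_t + mod)
  pB <- stats::plogis(base + co$beta_t_B + mod)
  muA <- mean(pA); muB <- mean(pB)
  if (muA %in% c(0, 1) || muB %in% c(0, 1))
    stop("degenerate configuration: marginal probability of 0 or 1")
  est <- stats::qlogis(muA) - stats::qlogis(muB)
  ## delta method on the paired means (same covariate draw for both arms)
  infl <- pA / (muA * (1 - muA)) - pB / (muB * (1 - muB))
  attr(est, "mcse") <- stats::sd(infl) / sqrt(n_large)
  est
}
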