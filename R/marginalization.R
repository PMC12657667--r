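## Marginal anchored estimators: ALD-side log-OR, Bucher's unadjusted
## contrast, Bayesian parametric G-computation over a simulated target
## population, and G-MAIC (Bayesian-bootstrap marginalization over the
## MAIC-reweighted IPD).  All return a `marginal_estimate`.

#' Construct a marginal treatment-effect estimate
#'
#' Classed container for an anchored A-vs-B log odds ratio with its
#' standard error, Wald 95\% confidence interval, optional per-draw
#' posterior contrasts, and validity flag.  Users normally obtain these
#' from \code{\link{maic}}, \code{\link{bucher}},
#' \code{\link{gcomp_parametric}} or \code{\link{gmaic}}.
#'
#' @param point log odds ratio point estimate.
#' @param se standard error (>= 0).
#' @param method estimator label, one of \code{"bucher"}, \code{"maic"},
#'   \code{"gcomp"}, \code{"gcomp_misspec"}, \code{"gmaic"}.
#' @param draws optional vector of per-draw (unanchored) contrasts.
#' @param valid logical; invalid estimates carry a reason in
#'   \code{notes}.
#' @param notes character vector of diagnostic notes.
#' @param ald_logor optional list \code{(estimate, se)} of the B-vs-C
#'   anchor used.
#' @param conf_z Wald multiplier (1.96 for 95\%).
#' @param extras named list of method-specific fields stored on the
#'   object.
#' @return An object of class \code{marginal_estimate}.
#' @export
marginal_estimate <- function(point, se, method, draws = NULL,
                              valid = TRUE, notes = character(),
                              ald_logor = NULL, conf_z = 1.96,
                              extras = list()) {
  if (isTRUE(valid) && (!is.finite(point) || !is.finite(se)))
    valid <- FALSE
  obj <- list(point = point, se = se,
              ci_low = point - conf_z * se,
              ci_high = point + conf_z * se,
              draws = draws, method = method, valid = isTRUE(valid),
              notes = as.character(notes), ald_logor = ald_logor,
              conf_z = conf_z)
  obj[names(extras)] <- extras
  class(obj) <- "marginal_estimate"
  obj
}

#' @export
print.marginal_estimate <- function(x, ...) {
  lab <- c(bucher = "Bucher (unadjusted anchored contrast)",
           maic = "MAIC (moment-matching weights, bootstrap SE)",
           gcomp = "Bayesian parametric G-computation",
           gcomp_misspec = "Bayesian parametric G-computation (mis-specified covariate model)",
           gmaic = "G-MAIC (Bayesian-bootstrap marginalization)")[x$method]
  if (is.na(lab)) lab <- x$method
  cat(lab, "\n")
  if (!x$valid) {
    cat("  estimate INVALID:", paste(x$notes, collapse = "; "), "\n")
  } else {
    cat(sprintf("  A vs B log-OR: %.4f (SE %.4f), 95%% CI [%.4f, %.4f]\n",
                x$point, x$se, x$ci_low, x$ci_high))
    if (!is.null(x$ess))
      cat(sprintf("  ESS: %.1f (%.1f%% reduction)\n",
                  x$ess, 100 * x$ess_reduction))
    if (length(x$notes)) cat("  note:", paste(x$notes, collapse = "; "), "\n")
  }
  invisible(x)
}

#' @export
summary.marginal_estimate <- function(object, ...) {
  out <- data.frame(method = object$method, estimate = object$point,
                    se = object$se, ci_low = object$ci_low,
                    ci_high = object$ci_high, valid = object$valid)
  if (!is.null(object$draws)) {
    out$n_draws <- length(object$draws)
    out$draw_sd <- stats::sd(object$draws)
  }
  out
}

#' @export
coef.marginal_estimate <- function(object, ...) {
  stats::setNames(object$point, "logOR_AB")
}

#' @export
confint.marginal_estimate <- function(object, parm, level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  m <- matrix(c(object$point - z * object$se,
                object$point + z * object$se), 1, 2,
              dimnames = list("logOR_AB",
                              sprintf("%.1f %%", c((1 - level) / 2,
                                                   1 - (1 - level) / 2) * 100)))
  m
}

#' @export
plot.marginal_estimate <- function(x, ...) {
  if (is.null(x$draws) || !length(x$draws)) {
    stop("no per-draw contrasts stored for this estimate")
  }
  graphics::hist(x$draws, breaks = 40, freq = FALSE,
                 main = paste("Posterior contrasts:", x$method),
                 xlab = "unanchored A vs C log-OR draw", ...)
  graphics::abline(v = mean(x$draws), lwd = 2)
  invisible(x)
}

#' B-vs-C log odds ratio from aggregate event counts
#'
#' Standard 2x2 log-OR with SE = sqrt of the summed reciprocal cell
#' counts.  If any cell is zero, a 0.5 continuity correction is applied
#' to all four cells and flagged in the result.
#'
#' @param ald an \code{\link{ald_summary}}.
#' @return list with \code{estimate}, \code{se},
#'   \code{continuity_corrected}.
#' @export
ald_log_or <- function(ald) {
  stopifnot(inherits(ald, "ald_summary"))
  a <- ald$events_B; b <- ald$n_B - ald$events_B
  c <- ald$events_C; d <- ald$n_C - ald$events_C
  corrected <- min(a, b, c, d) == 0
  if (corrected) { a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5 }
  list(estimate = log((a / b) / (c / d)),
       se = sqrt(1 / a + 1 / b + 1 / c + 1 / d),
       continuity_corrected = corrected)
}

#' A-vs-C log odds ratio from the IPD 2x2 table
#'
#' Crude (unweighted) marginal contrast of the IPD trial, with the same
#' continuity-correction rule as \code{\link{ald_log_or}}.
#'
#' @param trial an \code{\link{ipd_trial}}.
#' @return list with \code{estimate}, \code{se},
#'   \code{continuity_corrected}.
#' @export
ipd_log_or <- function(trial) {
  stopifnot(inherits(trial, "ipd_trial"))
  ald_log_or(aggregate_ipd(trial))
}

.as_contrast <- function(x) {
  if (inherits(x, "ald_summary")) return(ald_log_or(x))
  if (inherits(x, "ipd_trial")) return(ipd_log_or(x))
  if (is.list(x)) return(list(estimate = x$estimate, se = x$se))
  if (is.numeric(x) && length(x) == 2) return(list(estimate = x[1], se = x[2]))
  stop("cannot interpret contrast input")
}

#' Bucher's method: unadjusted anchored indirect comparison
#'
#' d_AB = d_AC - d_BC with variances summed; no population adjustment.
#'
#' @param d_AC the A-vs-C contrast: a list \code{(estimate, se)}, a
#'   length-2 numeric, or an \code{\link{ipd_trial}} (crude 2x2 log-OR).
#' @param d_BC the B-vs-C contrast: same forms, or an
#'   \code{\link{ald_summary}}.
#' @return A \code{\link{marginal_estimate}} with
#'   \code{method = "bucher"}.
#' @export
bucher <- function(d_AC, d_BC) {
  ac <- .as_contrast(d_AC)
  bc <- .as_contrast(d_BC)
  stopifnot(is.finite(ac$estimate), is.finite(bc$estimate),
            is.finite(ac$se), is.finite(bc$se))
  marginal_estimate(point = ac$estimate - bc$estimate,
                    se = sqrt(ac$se^2 + bc$se^2),
                    method = "bucher", ald_logor = bc)
}

#' Draw Dirichlet-distributed weight vectors
#'
#' @param n number of draws.
#' @param alpha concentration vector (non-negative, not all zero).
#' @return an \code{n x length(alpha)} matrix; rows sum to 1.
#' @export
rdirichlet <- function(n, alpha) {
  alpha <- as.numeric(alpha)
  stopifnot(n >= 1, all(alpha >= 0), sum(alpha) > 0)
  k <- length(alpha)
  G <- matrix(stats::rgamma(n * k, shape = rep(alpha, each = n)), n, k)
  G / rowSums(G)
}

#' Simulate a covariate population matching ALD summaries
#'
#' Draws \code{n_star} covariate profiles whose marginal means and SDs
#' match the aggregate summaries, under either a multivariate normal or a
#' Gaussian-copula multivariate Gamma family, with the supplied
#' correlation (typically borrowed from the IPD sample, since the ALD
#' reports none).
#'
#' @param ald an \code{\link{ald_summary}} with SDs for every covariate.
#' @param cov_model \code{"mvn"} or \code{"mvgamma"}.
#' @param correlation K x K correlation matrix.
#' @param n_star population size.
#' @return an \code{n_star x K} matrix.
#' @export
simulate_ald_population <- function(ald, cov_model = c("mvn", "mvgamma"),
                                    correlation, n_star = 1000) {
  stopifnot(inherits(ald, "ald_summary"), n_star >= 1)
  cov_model <- match.arg(cov_model)
  m <- as.numeric(ald$cov_means)
  s <- as.numeric(ald$cov_sds)
  K <- length(m)
  if (anyNA(s))
    stop("simulate_ald_population needs an SD for every covariate")
  correlation <- as.matrix(correlation)
  stopifnot(nrow(correlation) == K, ncol(correlation) == K)
  if (cov_model == "mvn") {
    D <- diag(s, K)
    X <- MASS::mvrnorm(n_star, mu = m, Sigma = D %*% correlation %*% D)
  } else {
    if (any(m <= 0))
      stop("Gamma marginals require strictly positive means")
    Z <- MASS::mvrnorm(n_star, mu = rep(0, K), Sigma = correlation)
    if (n_star == 1L) Z <- matrix(Z, nrow = 1L)
    U <- stats::pnorm(Z)
    shape <- (m / s)^2
    scale <- s^2 / m
    X <- vapply(seq_len(K), function(j)
      stats::qgamma(U[, j], shape = shape[j], scale = scale[j]),
      numeric(n_star))
  }
  if (n_star == 1L) X <- matrix(X, nrow = 1L)
  colnames(X) <- ald$covariate_names
  X
}

## Shared tail of the Bayesian marginal estimators: per-draw contrasts on
## the logit scale, dropping draws whose average probability is exactly 0
## or 1 (infinite after the logit transform).
.contrast_from_mu <- function(mu1, mu0, anchor, method, extras) {
  degenerate <- mu1 %in% c(0, 1) | mu0 %in% c(0, 1)
  delta <- stats::qlogis(mu1[!degenerate]) - stats::qlogis(mu0[!degenerate])
  n_deg <- sum(degenerate)
  notes <- character()
  if (n_deg > 0)
    notes <- sprintf("%d draw(s) with degenerate mean probability dropped",
                     n_deg)
  if (length(delta) < 2) {
    return(marginal_estimate(
      point = NA_real_, se = NA_real_, method = method, valid = FALSE,
      notes = c(notes, "all posterior draws degenerate"),
      ald_logor = anchor,
      extras = c(extras, list(degenerate_draws = n_deg))))
  }
  marginal_estimate(
    point = mean(delta) - anchor$estimate,
    se = sqrt(stats::var(delta) + anchor$se^2),
    method = method, draws = delta, notes = notes, ald_logor = anchor,
    extras = c(extras, list(degenerate_draws = n_deg)))
}

#' Bayesian parametric G-computation for anchored comparison
#'
#' Simulates one fixed pseudo-population of \code{n_star} covariate
#' profiles from a parametric family matched to the aggregate summaries,
#' then, for every posterior draw of the outcome model, averages
#' predicted probabilities over that population under each treatment
#' condition and contrasts them on the logit scale.  The posterior mean
#' of the per-draw contrasts, anchored by the B-vs-C log-OR, is the point
#' estimate; the SE combines the posterior SD with the anchor's sampling
#' error (sum of variances).
#'
#' @param posterior a \code{\link[=fit_outcome_model]{posterior_sample}}.
#' @param ald an \code{\link{ald_summary}} (means, SDs, event counts).
#' @param cov_model covariate family for the simulated population:
#'   \code{"mvn"} or \code{"mvgamma"} (Gaussian copula with
#'   moment-matched Gamma marginals).
#' @param correlation K x K correlation for the simulated population,
#'   typically the IPD sample correlation.
#' @param n_star size of the simulated population (default 1000).
#' @param ald_logor optional precomputed anchor \code{(estimate, se)};
#'   defaults to \code{ald_log_or(ald)}.
#' @param method label stored on the result (\code{"gcomp"} by default;
#'   use \code{"gcomp_misspec"} for a deliberately mis-specified family).
#' @return A \code{\link{marginal_estimate}} carrying the per-draw
#'   contrasts and a count of dropped degenerate draws.
#' @export
gcomp_parametric <- function(posterior, ald, cov_model = c("mvn", "mvgamma"),
                             correlation, n_star = 1000,
                             ald_logor = NULL, method = "gcomp") {
  stopifnot(inherits(posterior, "posterior_sample"))
  cov_model <- match.arg(cov_model)
  anchor <- if (is.null(ald_logor)) ald_log_or(ald) else
    .as_contrast(ald_logor)
  X0 <- simulate_ald_population(ald, cov_model, correlation, n_star)
  if (ncol(X0) != ncol(posterior$beta_pf))
    stop("covariate dimension mismatch between posterior and population")
  mu1 <- colMeans(.posterior_prob_matrix(posterior, X0, 1))
  mu0 <- colMeans(.posterior_prob_matrix(posterior, X0, 0))
  .contrast_from_mu(mu1, mu0, anchor, method,
                    extras = list(cov_model = cov_model, n_star = n_star))
}

#' G-MAIC: Bayesian-bootstrap marginalization with MAIC weights
#'
#' Approximates the aggregate-trial covariate distribution by the
#' MAIC-reweighted empirical distribution of the IPD, treating the
#' normalized weights as pseudo-frequencies: the Bayesian-bootstrap
#' posterior for the population weights is Dirichlet with concentration
#' a_i = n * w_i (total concentration n, reducing to Rubin's Bayesian
#' bootstrap under uniform weights).  For each posterior draw of the
#' outcome model a fresh Dirichlet weight vector is drawn and predicted
#' probabilities are weight-averaged under each treatment condition; the
#' logit-scale contrasts are anchored and summarized as in
#' \code{\link{gcomp_parametric}}.
#'
#' Optional weight tempering (\code{temper} < 1) raises the normalized
#' weights to a power below one before forming the concentration vector,
#' spreading the Dirichlet mass and inflating the propagated variance
#' under extreme weight concentration.
#'
#' @param posterior a \code{\link[=fit_outcome_model]{posterior_sample}}.
#' @param trial the IPD trial the posterior was fitted on.
#' @param weights converged \code{\link{maic_weights}} for the trial.
#' @param ald the aggregate trial: an \code{\link{ald_summary}}, or a
#'   precomputed anchor \code{(estimate, se)}.
#' @param temper tempering exponent in (0, 1]; 1 disables tempering.
#' @param .concentration_scale multiplier on the concentration vector;
#'   the default 1 is the Bayesian bootstrap.  Large values collapse the
#'   Dirichlet draws onto the weighted empirical distribution (useful for
#'   limit checks), so this is an expert/testing knob, not an analysis
#'   choice.
#' @return A \code{\link{marginal_estimate}} with
#'   \code{method = "gmaic"}.
#' @export
gmaic <- function(posterior, trial, weights, ald, temper = 1,
                  .concentration_scale = 1) {
  stopifnot(inherits(posterior, "posterior_sample"),
            inherits(trial, "ipd_trial"),
            inherits(weights, "maic_weights"),
            temper > 0, temper <= 1)
  if (!weights$converged)
    return(marginal_estimate(
      point = NA_real_, se = NA_real_, method = "gmaic", valid = FALSE,
      notes = "MAIC weights did not converge"))
  anchor <- .as_contrast(ald)
  n <- length(trial$y)
  wt <- weights$w_norm^temper
  a <- .concentration_scale * n * wt / sum(wt)
  P1 <- .posterior_prob_matrix(posterior, trial$X, 1)
  P0 <- .posterior_prob_matrix(posterior, trial$X, 0)
  L <- posterior$L
  ## one fresh Dirichlet draw per posterior draw, shared across arms
  G <- matrix(stats::rgamma(n * L, shape = a), n, L)
  Pi <- sweep(G, 2, colSums(G), "/")
  mu1 <- colSums(Pi * P1)
  mu0 <- colSums(Pi * P0)
  .contrast_from_mu(mu1, mu0, anchor, "gmaic",
                    extras = list(ess = weights$ess,
                                  ess_reduction = 1 - weights$ess / n,
                                  temper = temper))
}

#' One-call G-MAIC from raw trial data
#'
#' Convenience pipeline: estimate MAIC weights against the aggregate
#' covariate means, fit the Bayesian outcome model on the IPD, and
#' marginalize with \code{\link{gmaic}}.
#'
#' @param ipd an \code{\link{ipd_trial}}.
#' @param ald an \code{\link{ald_summary}}.
#' @param temper tempering exponent (see \code{\link{gmaic}}).
#' @param prior_sd,L,method passed to \code{\link{fit_outcome_model}}.
#' @return A \code{\link{marginal_estimate}}.
#' @export
gmaic_estimate <- function(ipd, ald, temper = 1, prior_sd = 10, L = 1000,
                           method = c("mcmc", "laplace")) {
  method <- match.arg(method)
  w <- estimate_weights(ipd$X, ald$cov_means)
  post <- fit_outcome_model(ipd, prior_sd = prior_sd, L = L, method = method)
  gmaic(post, ipd, w, ald, temper = temper)
}

#' One-call parametric G-computation from raw trial data
#'
#' Convenience pipeline: fit the Bayesian outcome model on the IPD,
#' borrow the IPD sample correlation for the simulated population, and
#' marginalize with \code{\link{gcomp_parametric}}.
#'
#' @param ipd an \code{\link{ipd_trial}}.
#' @param ald an \code{\link{ald_summary}}.
#' @param cov_model covariate family (\code{"mvn"} or \code{"mvgamma"}).
#' @param n_star simulated population size.
#' @param prior_sd,L,method passed to \code{\link{fit_outcome_model}}.
#' @return A \code{\link{marginal_estimate}}.
#' @export
gcomp_estimate <- function(ipd, ald, cov_model = c("mvn", "mvgamma"),
                           n_star = 1000, prior_sd = 10, L = 1000,
                           method = c("mcmc", "laplace")) {
  cov_model <- match.arg(cov_model)
  method <- match.arg(method)
  post <- fit_outcome_model(ipd, prior_sd = prior_sd, L = L, method = method)
  gcomp_parametric(post, ald, cov_model = cov_model,
                   correlation = stats::cor(ipd$X), n_star = n_star)
}
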