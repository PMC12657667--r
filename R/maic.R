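## MAIC weight estimation by moment matching, Kish ESS diagnostics, and
## the classical MAIC estimator with non-parametric bootstrap variance.

#' Estimate MAIC weights by moment matching
#'
#' Solves the mean-balancing problem for matching-adjusted indirect
#' comparison: weights w_i = exp(alpha' x_i) such that the weighted
#' covariate means equal the target (aggregate-trial) means.  The
#' coefficients minimize the convex objective
#' Q(alpha) = sum_i exp(alpha' (x_i - xbar_target)), whose gradient is the
#' weighted-mean balance residual, so the first-order condition is exactly
#' the moment constraint.  Covariates are centred at the target means and
#' standardized internally; optimization is quasi-Newton (BFGS) on
#' log Q with analytic gradient, started at alpha = 0.
#'
#' Failure to converge (including an infeasible target outside the convex
#' hull of the data) is reported through \code{converged = FALSE}, never
#' an error, so that simulation and bootstrap loops can count failures.
#'
#' @param X numeric matrix of matched covariates (one row per IPD
#'   participant).
#' @param target_means numeric vector of target means, one per column.
#' @param tol balance tolerance on the standardized scale: convergence
#'   requires every standardized weighted-mean residual below \code{tol}.
#' @return An object of class \code{maic_weights}: list with
#'   \code{alpha} (on the original covariate scale), \code{w} (raw
#'   weights, shift-invariant parameterization exp(alpha'(x - target))),
#'   \code{w_norm} (normalized to sum 1), \code{ess}, \code{converged},
#'   and \code{balance_residual} (weighted mean minus target, original
#'   scale).
#' @export
estimate_weights <- function(X, target_means, tol = 1e-6) {
  X <- as.matrix(X)
  n <- nrow(X); K <- ncol(X)
  target_means <- as.numeric(target_means)
  if (length(target_means) != K)
    stop("target_means must have one entry per column of X")
  if (!all(is.finite(X)) || !all(is.finite(target_means)))
    stop("non-finite values in covariates or targets")

  fail <- function(note) {
    w <- rep(NA_real_, n)
    structure(list(alpha = rep(NA_real_, K), w = w, w_norm = w,
                   ess = NA_real_, converged = FALSE,
                   balance_residual = rep(NA_real_, K), note = note),
              class = "maic_weights")
  }

  ## constant columns carry no information for tilting: drop them if they
  ## already match their target, otherwise the problem is infeasible
  sds <- apply(X, 2, stats::sd)
  keep <- sds > 0
  if (any(!keep)) {
    mism <- !keep & abs(colMeans(X) - target_means) > 1e-8
    if (any(mism))
      return(fail(paste("constant covariate(s) not matching target:",
                        paste(which(mism), collapse = ", "))))
    warning("dropping constant covariate column(s) already at target: ",
            paste(which(!keep), collapse = ", "))
  }
  if (!any(keep)) {
    ## everything constant and matching: uniform weights solve the problem
    w <- rep(1, n)
    return(structure(list(alpha = rep(0, K), w = w, w_norm = w / n,
                          ess = n, converged = TRUE,
                          balance_residual = colMeans(X) - target_means),
                     class = "maic_weights"))
  }

  Z <- sweep(X[, keep, drop = FALSE], 2, target_means[keep])
  Z <- sweep(Z, 2, sds[keep], "/")
  ## minimize log Q(a) = log sum_i exp(z_i' a); grad = weighted mean of z,
  ## i.e. the standardized balance residual
  fn <- function(a) {
    eta <- drop(Z %*% a)
    m <- max(eta)
    m + log(sum(exp(eta - m)))
  }
  gr <- function(a) {
    eta <- drop(Z %*% a)
    w <- exp(eta - max(eta))
    drop(crossprod(Z, w)) / sum(w)
  }
  opt <- tryCatch(
    stats::optim(rep(0, sum(keep)), fn, gr, method = "BFGS",
                 control = list(maxit = 1000, reltol = 1e-14)),
    error = function(e) NULL)
  if (is.null(opt) || !all(is.finite(opt$par)))
    return(fail("optimizer failure"))
  a <- opt$par
  eta <- drop(Z %*% a)
  w <- exp(eta - max(eta))
  if (!all(is.finite(w)) || sum(w) <= 0)
    return(fail("non-finite weights"))
  w_norm <- w / sum(w)
  resid_std <- drop(crossprod(Z, w_norm))
  converged <- max(abs(resid_std)) < tol
  alpha <- rep(0, K)
  alpha[keep] <- a / sds[keep]
  structure(
    list(alpha = alpha,
         w = w, w_norm = w_norm,
         ess = ess(w), converged = converged,
         balance_residual = drop(crossprod(X, w_norm)) - target_means,
         note = if (converged) NULL else
           sprintf("balance residual %.3g exceeds tol %.3g (target may lie outside the convex hull)",
                   max(abs(resid_std)), tol)),
    class = "maic_weights")
}

#' @export
print.maic_weights <- function(x, ...) {
  if (!x$converged) {
    cat("MAIC weights: NOT converged",
        if (!is.null(x$note)) paste0(" (", x$note, ")"), "\n", sep = "")
  } else {
    n <- length(x$w)
    cat(sprintf(
      "MAIC weights: n = %d, ESS = %.1f (%.1f%% reduction), max |balance residual| = %.2g\n",
      n, x$ess, 100 * (1 - x$ess / n), max(abs(x$balance_residual))))
  }
  invisible(x)
}

#' Kish effective sample size of a weight vector
#'
#' ESS = (sum w)^2 / sum w^2; scale-invariant, between 1 and n.
#'
#' @param w non-negative weights, not all zero.
#' @return scalar ESS.
#' @export
ess <- function(w) {
  w <- as.numeric(w)
  if (any(!is.finite(w)) || any(w < 0)) stop("weights must be finite and >= 0")
  s <- sum(w)
  if (s <= 0) stop("weights must not be all zero")
  s^2 / sum(w^2)
}

## Weighted marginal log-OR of t in (y, t): the MLE of a weighted logistic
## regression of y on an intercept and t, available in closed form from
## the weighted 2x2 cell sums.  Returns NA under weighted separation.
.weighted_logor_t <- function(y, t, w) {
  a <- sum(w * y * t);        b <- sum(w * (1 - y) * t)
  c <- sum(w * y * (1 - t));  d <- sum(w * (1 - y) * (1 - t))
  if (min(a, b, c, d) <= 0) return(NA_real_)
  log((a / b) / (c / d))
}

#' MAIC point estimate of the anchored A-vs-B contrast
#'
#' Fits the weighted marginal regression of outcome on treatment in the
#' IPD (equivalently, the weighted 2x2 log odds ratio), giving the A-vs-C
#' effect transported to the aggregate-trial population, and anchors it by
#' subtracting the B-vs-C log odds ratio from the aggregate event counts.
#'
#' @param trial an \code{\link{ipd_trial}}.
#' @param weights a converged \code{\link{maic_weights}}.
#' @param ald an \code{\link{ald_summary}}.
#' @return the anchored log odds ratio; \code{NA} (with attribute
#'   \code{"note"}) under weighted separation.  The transported A-vs-C
#'   contrast is attached as attribute \code{"d_AC"}.
#' @export
maic_point_estimate <- function(trial, weights, ald) {
  stopifnot(inherits(trial, "ipd_trial"), inherits(weights, "maic_weights"),
            inherits(ald, "ald_summary"))
  if (!weights$converged) stop("weights did not converge")
  d_AC <- .weighted_logor_t(trial$y, trial$t, weights$w_norm)
  d_BC <- ald_log_or(ald)$estimate
  if (is.na(d_AC)) {
    out <- NA_real_
    attr(out, "note") <- "weighted separation: all weighted events in one arm"
    return(out)
  }
  out <- d_AC - d_BC
  attr(out, "d_AC") <- d_AC
  out
}

#' Matching-adjusted indirect comparison (MAIC)
#'
#' The classical anchored MAIC estimator: moment-matching weights
#' (\code{\link{estimate_weights}}) transport the IPD trial's marginal
#' A-vs-C effect to the aggregate-trial population; the B-vs-C contrast
#' from the aggregate event counts anchors the comparison; the standard
#' error is the SD of non-parametric bootstrap replicates, each of which
#' resamples IPD rows with replacement and re-estimates both the weights
#' (against the fixed aggregate means) and the weighted regression.
#' Replicates whose weight estimation fails, or whose weighted table is
#' separated, are dropped and counted.
#'
#' @param ipd an \code{\link{ipd_trial}}.
#' @param ald an \code{\link{ald_summary}}.
#' @param n_boot number of bootstrap replicates (default 1000).
#' @param match_sds also match the continuous covariates' second moments
#'   by augmenting with squared covariates (default \code{FALSE}: means
#'   only).
#' @param tol balance tolerance passed to \code{\link{estimate_weights}}.
#' @return A \code{\link{marginal_estimate}} with \code{method = "maic"};
#'   extras: \code{weights} (the full-sample \code{maic_weights}),
#'   \code{ess}, \code{ess_reduction}, \code{boot_failures},
#'   \code{n_boot}.
#' @export
maic <- function(ipd, ald, n_boot = 1000, match_sds = FALSE, tol = 1e-6) {
  stopifnot(inherits(ipd, "ipd_trial"), inherits(ald, "ald_summary"),
            n_boot >= 2)
  mm <- .maic_match_matrix(ipd, ald, match_sds)
  d_BC <- ald_log_or(ald)
  full <- estimate_weights(mm$X, mm$targets, tol = tol)
  n <- length(ipd$y)

  if (!full$converged) {
    return(marginal_estimate(
      point = NA_real_, se = NA_real_, method = "maic", valid = FALSE,
      notes = paste("full-sample weight estimation failed:",
                    if (is.null(full$note)) "" else full$note),
      extras = list(weights = full, ess = NA_real_, ess_reduction = NA_real_,
                    boot_failures = NA_integer_, n_boot = n_boot)))
  }
  point <- maic_point_estimate(ipd, full, ald)
  if (is.na(point)) {
    return(marginal_estimate(
      point = NA_real_, se = NA_real_, method = "maic", valid = FALSE,
      notes = attr(point, "note"),
      extras = list(weights = full, ess = full$ess,
                    ess_reduction = 1 - full$ess / n,
                    boot_failures = NA_integer_, n_boot = n_boot)))
  }

  reps <- numeric(n_boot)
  failures <- 0L
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    wb <- estimate_weights(mm$X[idx, , drop = FALSE], mm$targets, tol = tol)
    est <- NA_real_
    if (wb$converged)
      est <- .weighted_logor_t(ipd$y[idx], ipd$t[idx], wb$w_norm)
    if (is.na(est)) failures <- failures + 1L
    reps[b] <- est
  }
  ok <- !is.na(reps)
  se <- if (sum(ok) >= 2) stats::sd(reps[ok]) else NA_real_
  notes <- character()
  if (failures > 0)
    notes <- sprintf("%d of %d bootstrap replicates failed", failures, n_boot)
  if (failures > n_boot / 2)
    notes <- c(notes, "more than half of bootstrap replicates failed; SE unreliable")
  marginal_estimate(
    point = as.numeric(point), se = se, method = "maic",
    valid = TRUE, notes = notes, ald_logor = d_BC,
    extras = list(weights = full, ess = full$ess,
                  ess_reduction = 1 - full$ess / n,
                  boot_failures = failures, n_boot = n_boot))
}

## Build the matching design: covariate columns (plus squared continuous
## columns when matching second moments) and their target means.
.maic_match_matrix <- function(ipd, ald, match_sds = FALSE) {
  X <- ipd$X
  targets <- as.numeric(ald$cov_means)
  if (match_sds) {
    cont <- which(!is.na(ald$cov_sds) &
                    apply(X, 2, function(v) !all(v %in% c(0, 1))))
    if (length(cont)) {
      X2 <- X[, cont, drop = FALSE]^2
      colnames(X2) <- paste0(colnames(X)[cont], "^2")
      ## E[X^2] = Var + mean^2, with the published SD as sqrt(Var)
      t2 <- ald$cov_sds[cont]^2 + ald$cov_means[cont]^2
      X <- cbind(X, X2)
      targets <- c(targets, as.numeric(t2))
    }
  }
  list(X = X, targets = targets)
}
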