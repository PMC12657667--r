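## Bayesian logistic outcome regression on the IPD:
##   logit P(y=1 | t, x) = beta0 + beta_t t + x' beta_pf + t x' beta_em
## with independent Normal(0, prior_sd^2) priors on every coefficient.
## Two posterior engines: an asymptotically exact independence
## Metropolis-Hastings sampler with a multivariate-t proposal built from
## the Laplace approximation (default), and the Laplace normal
## approximation itself as a fast flag for large simulation runs.

.outcome_design <- function(t, X) {
  cbind(`(Intercept)` = 1, t = t, X, X * t)
}

## Penalized (MAP) Newton-Raphson for the logistic model with a Gaussian
## ridge prior; returns the mode and the negative-Hessian at the mode.
.logistic_map <- function(D, y, prior_sd, maxit = 100, tol = 1e-10) {
  p <- ncol(D)
  lambda <- 1 / prior_sd^2
  beta <- rep(0, p)
  log_post <- function(b) {
    eta <- drop(D %*% b)
    sum(y * eta - log1p(exp(eta))) - 0.5 * lambda * sum(b^2)
  }
  lp <- log_post(beta)
  for (it in seq_len(maxit)) {
    eta <- drop(D %*% beta)
    mu <- stats::plogis(eta)
    g <- drop(crossprod(D, y - mu)) - lambda * beta
    W <- mu * (1 - mu)
    H <- crossprod(D, D * W) + diag(lambda, p)
    step <- solve(H, g)
    ## step-halving for global convergence
    s <- 1
    repeat {
      cand <- beta + s * step
      lpc <- log_post(cand)
      if (is.finite(lpc) && lpc >= lp - 1e-12) break
      s <- s / 2
      if (s < 1e-8) break
    }
    beta <- beta + s * step
    lpn <- log_post(beta)
    if (abs(lpn - lp) < tol && max(abs(g)) < 1e-6) { lp <- lpn; break }
    lp <- lpn
  }
  eta <- drop(D %*% beta)
  mu <- stats::plogis(eta)
  H <- crossprod(D, D * (mu * (1 - mu))) + diag(lambda, p)
  list(mode = beta, neg_hessian = H, log_post = lp,
       log_post_fun = log_post)
}

## Split-chain potential scale reduction factor (rank-plain version).
.split_rhat <- function(draws_by_chain) {
  halves <- list()
  for (ch in draws_by_chain) {
    m <- length(ch) %/% 2
    halves <- c(halves, list(ch[seq_len(m)], ch[m + seq_len(m)]))
  }
  m <- length(halves); n <- length(halves[[1]])
  means <- vapply(halves, mean, 0)
  vars <- vapply(halves, stats::var, 0)
  B <- n * stats::var(means)
  W <- mean(vars)
  if (W <= 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Fit the Bayesian logistic outcome model
#'
#' Samples the joint posterior of all coefficients of the logistic model
#' with treatment, prognostic and treatment-by-covariate interaction
#' terms, under independent Normal(0, \code{prior_sd}^2) priors.
#'
#' \code{method = "mcmc"} (default) runs an independence
#' Metropolis-Hastings sampler whose proposal is a multivariate t
#' (7 degrees of freedom) centred at the posterior mode with the
#' inverse negative-Hessian as scale -- asymptotically exact, with
#' split-chain scale-reduction diagnostics; the fit aborts if any
#' parameter has Rhat above 1.05.  \code{method = "laplace"} draws from
#' the multivariate-normal (Laplace) approximation at the mode; it is an
#' approximation, intended for large simulation runs where thousands of
#' model fits are needed.
#'
#' @param trial an \code{\link{ipd_trial}}.
#' @param prior_sd prior standard deviation (default 10: weakly
#'   informative on the log-odds scale).
#' @param L number of retained posterior draws (total across chains).
#' @param chains number of chains (\code{method = "mcmc"} only).
#' @param method \code{"mcmc"} or \code{"laplace"}.
#' @param burn burn-in iterations per chain (\code{"mcmc"} only).
#' @return An object of class \code{posterior_sample}: list with
#'   \code{L}, \code{beta0}, \code{beta_t} (L-vectors), \code{beta_pf},
#'   \code{beta_em} (L x K matrices), \code{draws} (L x p matrix of all
#'   coefficients), \code{diagnostics} (per-parameter Rhat and
#'   acceptance rate), \code{method}, \code{covariate_names}.
#' @export
fit_outcome_model <- function(trial, prior_sd = 10, L = 1000, chains = 2,
                              method = c("mcmc", "laplace"), burn = 250) {
  stopifnot(inherits(trial, "ipd_trial"), L >= 1, prior_sd > 0)
  method <- match.arg(method)
  K <- ncol(trial$X)
  D <- .outcome_design(trial$t, trial$X)
  if (!all(is.finite(D))) stop("non-finite design matrix")
  flat <- vapply(c(0, 1), function(arm) {
    ya <- trial$y[trial$t == arm]
    length(ya) > 0 && (all(ya == 0) || all(ya == 1))
  }, NA)
  if (any(flat))
    warning("arm(s) t=", paste(c(0, 1)[flat], collapse = ","),
            " have no outcome variation; ",
            "posterior relies on the prior for identification")
  p <- ncol(D)
  map <- .logistic_map(D, trial$y, prior_sd)
  Sig <- solve(map$neg_hessian)
  Sig <- (Sig + t(Sig)) / 2
  R <- chol(Sig)

  if (method == "laplace") {
    Zs <- matrix(stats::rnorm(L * p), L, p)
    draws <- sweep(Zs %*% R, 2, map$mode, "+")
    diag_tab <- data.frame(parameter = colnames(D),
                           rhat = rep(1, p), row.names = NULL)
    accept <- NA_real_
  } else {
    draws <- .run_independence_mh(map, R, L, chains, burn, p,
                                  df = 7, scale = 1)
    if (is.null(draws))  # heavy-tailed retry for awkward posteriors
      draws <- .run_independence_mh(map, R, L, chains, burn, p,
                                    df = 4, scale = 1.6)
    if (is.null(draws))
      stop("posterior sampler did not converge: split-Rhat above 1.05 ",
           "after proposal-scale retry")
    diag_tab <- data.frame(parameter = colnames(D),
                           rhat = attr(draws, "rhat"), row.names = NULL)
    accept <- attr(draws, "acceptance")
    attr(draws, "rhat") <- NULL
    attr(draws, "acceptance") <- NULL
  }
  colnames(draws) <- colnames(D)
  structure(
    list(L = nrow(draws),
         beta0 = draws[, 1],
         beta_t = draws[, 2],
         beta_pf = draws[, 2 + seq_len(K), drop = FALSE],
         beta_em = draws[, 2 + K + seq_len(K), drop = FALSE],
         draws = draws,
         diagnostics = list(table = diag_tab, acceptance = accept,
                            map = map$mode),
         method = method, prior_sd = prior_sd,
         covariate_names = trial$covariate_names),
    class = "posterior_sample")
}

## Independence MH with a multivariate-t proposal at the mode; returns
## NULL when split-Rhat exceeds 1.05 so the caller can retry.
.run_independence_mh <- function(map, R0, L, chains, burn, p,
                                 df = 7, scale = 1) {
    R <- R0 * scale
    log_post <- map$log_post_fun
    ldet <- sum(log(diag(R)))
    log_prop <- function(b) {
      u <- backsolve(R, b - map$mode, transpose = TRUE)
      -ldet - (df + p) / 2 * log1p(sum(u^2) / df)
    }
    per_chain <- ceiling(L / chains)
    chains_draws <- vector("list", chains)
    acc_n <- 0L; tot_n <- 0L
    for (ch in seq_len(chains)) {
      iters <- per_chain + burn
      ## proposals drawn in a block: multivariate t at the mode
      Zs <- matrix(stats::rnorm(iters * p), iters, p)
      g <- stats::rchisq(iters, df) / df
      props <- sweep((Zs / sqrt(g)) %*% R, 2, map$mode, "+")
      lp_prop <- apply(props, 1, log_post)
      lq_prop <- apply(props, 1, log_prop)
      cur <- map$mode
      lp_cur <- log_post(cur); lq_cur <- log_prop(cur)
      out <- matrix(NA_real_, iters, p)
      us <- stats::runif(iters)
      for (i in seq_len(iters)) {
        if (log(us[i]) < (lp_prop[i] - lq_prop[i]) - (lp_cur - lq_cur)) {
          cur <- props[i, ]; lp_cur <- lp_prop[i]; lq_cur <- lq_prop[i]
          acc_n <- acc_n + 1L
        }
        tot_n <- tot_n + 1L
        out[i, ] <- cur
      }
      chains_draws[[ch]] <- out[(burn + 1):iters, , drop = FALSE]
    }
    rhat <- vapply(seq_len(p), function(j)
      .split_rhat(lapply(chains_draws, function(m) m[, j])), 0)
    if (any(rhat > 1.05)) return(NULL)
    draws <- do.call(rbind, chains_draws)[seq_len(L), , drop = FALSE]
    attr(draws, "rhat") <- rhat
    attr(draws, "acceptance") <- acc_n / tot_n
    draws
}

#' @export
print.posterior_sample <- function(x, ...) {
  cat("posterior sample: L = ", x$L, " draws (", x$method, "), ",
      ncol(x$draws), " coefficients\n", sep = "")
  s <- data.frame(mean = colMeans(x$draws),
                  sd = apply(x$draws, 2, stats::sd))
  if (!is.null(x$diagnostics$table$rhat))
    s$rhat <- x$diagnostics$table$rhat
  print(round(s, 3))
  invisible(x)
}

#' Predicted event probabilities for one posterior draw
#'
#' Evaluates expit(beta0 + beta_t t + X beta_pf + t X beta_em) at draw
#' \code{draw_index} for every row of \code{X} under treatment condition
#' \code{t}; with \code{t = 0} the treatment and interaction coefficients
#' do not enter.
#'
#' @param draw_index draw number, between 1 and \code{posterior$L}.
#' @param posterior a \code{\link[=fit_outcome_model]{posterior_sample}}.
#' @param X covariate matrix (columns in model order).
#' @param t treatment condition, 0 or 1 (scalar).
#' @return vector of probabilities in (0, 1), one per row of \code{X}.
#' @export
predict_prob <- function(draw_index, posterior, X, t) {
  stopifnot(inherits(posterior, "posterior_sample"),
            draw_index >= 1, draw_index <= posterior$L,
            t %in% c(0, 1))
  X <- as.matrix(X)
  l <- draw_index
  eta <- posterior$beta0[l] + posterior$beta_t[l] * t +
    drop(X %*% posterior$beta_pf[l, ]) +
    t * drop(X %*% posterior$beta_em[l, ])
  stats::plogis(eta)
}

## All-draw probability matrix (m profiles x L draws) for marginalization.
.posterior_prob_matrix <- function(posterior, X, t) {
  X <- as.matrix(X)
  D <- .outcome_design(rep(t, nrow(X)), X)
  stats::plogis(D %*% t(posterior$draws))
}
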