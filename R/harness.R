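## ADEMP simulation engine: replicated two-trial datasets per scenario,
## all estimators applied, missing-estimate accounting, and performance
## measures (bias, empirical SE, model-average SE, coverage) with Monte
## Carlo standard errors.

## Independent reproducible sub-streams (L'Ecuyer-CMRG), one per
## replicate, so results do not depend on execution order.
.rng_substreams <- function(seed, n) {
  old_kind <- RNGkind()
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old_seed <- get(".Random.seed", envir = globalenv())
  on.exit({
    RNGkind(old_kind[1], old_kind[2], old_kind[3])
    if (has) assign(".Random.seed", old_seed, envir = globalenv())
  })
  RNGkind("L'Ecuyer-CMRG")
  set.seed(seed)
  s <- get(".Random.seed", envir = globalenv())
  streams <- vector("list", n)
  for (i in seq_len(n)) {
    streams[[i]] <- s
    s <- parallel::nextRNGStream(s)
  }
  streams
}

.method_choices <- c("bucher", "maic", "gcomp", "gcomp_misspec", "gmaic")

#' Run one simulation scenario
#'
#' For each replicate: simulate a fresh AC (IPD) trial and BC trial,
#' aggregate the BC trial to ALD, and apply every requested estimator.
#' Estimates that are invalid (failed weight estimation, degenerate or
#' infinite logits) are recorded with a status and treated as missing by
#' \code{\link{performance}}.  Each replicate runs on its own RNG
#' sub-stream derived from \code{seed}, so the table is reproducible and
#' independent of execution order.
#'
#' @param config a \code{\link{scenario_config}}.
#' @param methods subset of
#'   \code{c("bucher", "maic", "gcomp", "gcomp_misspec", "gmaic")}.
#'   Under the normal covariate structure the correctly specified
#'   G-computation family is multivariate normal and the mis-specified
#'   one multivariate Gamma; under the nonnormal structure the roles
#'   swap.
#' @param n_sim number of replicates (>= 2).
#' @param seed integer seed.
#' @param n_boot MAIC bootstrap replicates per dataset.
#' @param L posterior draws for the Bayesian methods.
#' @param posterior_method \code{"laplace"} (fast, default for
#'   simulation runs) or \code{"mcmc"}.
#' @param n_star simulated population size for G-computation.
#' @param temper G-MAIC tempering exponent.
#' @return data.frame, one row per replicate x method, with columns
#'   \code{scenario}, \code{rep}, \code{method}, \code{estimate},
#'   \code{se}, \code{ci_low}, \code{ci_high}, \code{valid},
#'   \code{status}, \code{boot_failures}, \code{ess}.
#' @export
run_scenario <- function(config, methods = .method_choices, n_sim = 100,
                         seed = 1, n_boot = 1000, L = 1000,
                         posterior_method = c("laplace", "mcmc"),
                         n_star = 1000, temper = 1) {
  stopifnot(inherits(config, "scenario_config"), n_sim >= 2)
  posterior_method <- match.arg(posterior_method)
  if (!length(methods)) stop("methods must not be empty")
  methods <- match.arg(methods, .method_choices, several.ok = TRUE)
  streams <- .rng_substreams(seed, n_sim)
  old_kind <- RNGkind()
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old_seed <- get(".Random.seed", envir = globalenv())
  on.exit({
    RNGkind(old_kind[1], old_kind[2], old_kind[3])
    if (has) assign(".Random.seed", old_seed, envir = globalenv())
  })
  RNGkind("L'Ecuyer-CMRG")

  correct_family <- if (config$structure == "normal") "mvn" else "mvgamma"
  wrong_family <- setdiff(c("mvn", "mvgamma"), correct_family)
  need_post <- any(c("gcomp", "gcomp_misspec", "gmaic") %in% methods)
  need_w <- any(c("maic", "gmaic") %in% methods)

  rows <- vector("list", n_sim)
  for (r in seq_len(n_sim)) {
    assign(".Random.seed", streams[[r]], envir = globalenv())
    ac <- simulate_trial(config, "AC")
    bc <- simulate_trial(config, "BC")
    ald <- aggregate_ipd(bc)
    anchor <- ald_log_or(ald)
    corr_ipd <- stats::cor(ac$X)

    post <- NULL
    if (need_post)
      post <- tryCatch(
        fit_outcome_model(ac, L = L, method = posterior_method),
        error = function(e) e, warning = function(w)
          suppressWarnings(fit_outcome_model(ac, L = L,
                                             method = posterior_method)))
    w <- if (need_w) estimate_weights(ac$X, ald$cov_means) else NULL

    ests <- lapply(methods, function(m) {
      switch(m,
        bucher = bucher(ipd_log_or(ac), anchor),
        maic = maic(ac, ald, n_boot = n_boot),
        gcomp = , gcomp_misspec = {
          fam <- if (m == "gcomp") correct_family else wrong_family
          if (inherits(post, "error"))
            marginal_estimate(NA_real_, NA_real_, method = m,
                              valid = FALSE, notes = conditionMessage(post))
          else
            gcomp_parametric(post, ald, cov_model = fam,
                             correlation = corr_ipd, n_star = n_star,
                             ald_logor = anchor, method = m)
        },
        gmaic = {
          if (inherits(post, "error"))
            marginal_estimate(NA_real_, NA_real_, method = "gmaic",
                              valid = FALSE, notes = conditionMessage(post))
          else
            gmaic(post, ac, w, anchor, temper = temper)
        })
    })

    rows[[r]] <- do.call(rbind, lapply(seq_along(methods), function(i) {
      e <- ests[[i]]
      ok <- e$valid && is.finite(e$point) && is.finite(e$se)
      status <- if (ok) "ok"
        else if (methods[i] %in% c("maic", "gmaic") &&
                 any(grepl("weight", e$notes))) "weight_failure"
        else "infinite"
      data.frame(scenario = config$label, rep = r, method = methods[i],
                 estimate = if (ok) e$point else NA_real_,
                 se = if (ok) e$se else NA_real_,
                 ci_low = if (ok) e$ci_low else NA_real_,
                 ci_high = if (ok) e$ci_high else NA_real_,
                 valid = ok, status = status,
                 boot_failures = if (!is.null(e$boot_failures))
                   e$boot_failures else NA_integer_,
                 ess = if (!is.null(e$ess)) e$ess else NA_real_,
                 stringsAsFactors = FALSE)
    }))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Performance measures with Monte Carlo standard errors
#'
#' Complete-case (within method) summaries of a replicate table against
#' the true effect: bias = mean(est) - true_d; empirical SE = SD of the
#' estimates; model-average SE = mean of the reported SEs (or
#' root-mean-variance with \code{mod_se_type = "rms"}); coverage =
#' proportion of Wald 95\% intervals containing \code{true_d}.  MCSEs use
#' the standard forms: bias EmpSE/sqrt(n), EmpSE itself
#' EmpSE/sqrt(2(n-1)), coverage sqrt(c(1-c)/n).
#'
#' @param estimates a replicate table from \code{\link{run_scenario}}.
#' @param true_d true A-vs-B marginal log odds ratio (0 under the default
#'   shared-effect design).
#' @param mod_se_type \code{"mean"} or \code{"rms"}.
#' @return data.frame, one row per method: \code{n_valid},
#'   \code{failure_count}, \code{infinite_count}, \code{bias},
#'   \code{bias_mcse}, \code{emp_se}, \code{emp_se_mcse}, \code{mod_se},
#'   \code{coverage}, \code{coverage_mcse}.
#' @export
performance <- function(estimates, true_d = 0,
                        mod_se_type = c("mean", "rms")) {
  mod_se_type <- match.arg(mod_se_type)
  stopifnot(all(c("method", "estimate", "se", "valid") %in%
                  names(estimates)))
  out <- lapply(split(estimates, estimates$method), function(d) {
    ok <- d$valid & is.finite(d$estimate)
    n_valid <- sum(ok)
    n_fail <- sum(!ok & d$status == "weight_failure")
    n_inf <- sum(!ok) - n_fail
    row <- data.frame(
      scenario = d$scenario[1], method = d$method[1],
      n_sim = nrow(d), n_valid = n_valid,
      failure_count = n_fail, infinite_count = n_inf,
      bias = NA_real_, bias_mcse = NA_real_,
      emp_se = NA_real_, emp_se_mcse = NA_real_,
      mod_se = NA_real_, coverage = NA_real_, coverage_mcse = NA_real_,
      stringsAsFactors = FALSE)
    if (n_valid < 2) return(row)
    est <- d$estimate[ok]; se <- d$se[ok]
    emp <- stats::sd(est)
    cov <- mean(d$ci_low[ok] <= true_d & true_d <= d$ci_high[ok])
    row$bias <- mean(est) - true_d
    row$bias_mcse <- emp / sqrt(n_valid)
    row$emp_se <- emp
    row$emp_se_mcse <- emp / sqrt(2 * (n_valid - 1))
    row$mod_se <- if (mod_se_type == "mean") mean(se) else
      sqrt(mean(se^2))
    row$coverage <- cov
    row$coverage_mcse <- sqrt(cov * (1 - cov) / n_valid)
    row
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Run a full simulation study over a scenario grid
#'
#' Runs \code{\link{run_scenario}} for every configuration (each on a
#' seed offset by its grid position), verifies the design-implied truth
#' with \code{\link{true_marginal_effect}}, and assembles replicate and
#' performance tables.  When \code{out_dir} is given, writes
#' \code{estimates.csv}, \code{performance.csv}, \code{truths.csv} and a
#' YAML manifest recording the seed, replication count and failure
#' totals.
#'
#' @param configs list of \code{\link{scenario_config}}s, e.g. from
#'   \code{\link{make_scenarios}}.
#' @param n_sim replicates per scenario.
#' @param methods estimators to run (see \code{\link{run_scenario}}).
#' @param seed integer master seed.
#' @param out_dir optional output directory.
#' @param true_d true effect; the design implies 0, verified against
#'   \code{\link{true_marginal_effect}} at \code{n_true} draws.
#' @param n_true cohort size for the truth verification.
#' @param ... further arguments passed to \code{\link{run_scenario}}.
#' @return list with \code{estimates}, \code{performance} and
#'   \code{truths} data.frames, invisibly classed
#'   \code{simulation_study}.
#' @export
run_study <- function(configs, n_sim = 100, methods = .method_choices,
                      seed = 1, out_dir = NULL, true_d = 0,
                      n_true = 5e5, ...) {
  stopifnot(length(configs) >= 1)
  if (!length(methods)) stop("methods must not be empty")
  methods <- match.arg(methods, .method_choices, several.ok = TRUE)
  old_kind <- RNGkind()
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old_seed <- get(".Random.seed", envir = globalenv())
  on.exit({
    RNGkind(old_kind[1], old_kind[2], old_kind[3])
    if (has) assign(".Random.seed", old_seed, envir = globalenv())
  })
  truth_streams <- .rng_substreams(seed + 777L, length(configs))
  est_list <- vector("list", length(configs))
  truth_list <- vector("list", length(configs))
  for (i in seq_along(configs)) {
    cfg <- configs[[i]]
    assign(".Random.seed", truth_streams[[i]], envir = globalenv())
    td <- true_marginal_effect(cfg, n_large = n_true)
    truth_list[[i]] <- data.frame(scenario = cfg$label,
                                  true_effect = as.numeric(td),
                                  mcse = attr(td, "mcse"))
    est_list[[i]] <- run_scenario(cfg, methods = methods, n_sim = n_sim,
                                  seed = seed + i, ...)
  }
  estimates <- do.call(rbind, est_list)
  truths <- do.call(rbind, truth_list)
  perf <- do.call(rbind, lapply(est_list, performance, true_d = true_d))
  rownames(perf) <- NULL
  res <- structure(list(estimates = estimates, performance = perf,
                        truths = truths, seed = seed, n_sim = n_sim,
                        methods = methods),
                   class = "simulation_study")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(estimates, file.path(out_dir, "estimates.csv"),
                     row.names = FALSE)
    utils::write.csv(perf, file.path(out_dir, "performance.csv"),
                     row.names = FALSE)
    utils::write.csv(truths, file.path(out_dir, "truths.csv"),
                     row.names = FALSE)
    yaml::write_yaml(
      list(package_version = as.character(utils::packageVersion("gmaic")),
           r_version = R.version.string,
           seed = seed, n_sim = n_sim, methods = methods,
           scenarios = vapply(configs, `[[`, "", "label"),
           failure_counts = stats::aggregate(
             !estimates$valid, by = list(method = estimates$method),
             FUN = sum)$x),
      file.path(out_dir, "manifest.yaml"))
  }
  res
}

#' @export
print.simulation_study <- function(x, ...) {
  cat("simulation study: ", length(unique(x$performance$scenario)),
      " scenario(s) x ", x$n_sim, " replicates, methods: ",
      paste(x$methods, collapse = ", "), "\n", sep = "")
  print(x$performance, digits = 3)
  invisible(x)
}

#' Nested-loop style summary plot of a performance table
#'
#' Plots one performance measure across the scenario grid, one line per
#' method, scenarios ordered as supplied (the nested-loop layout of
#' factorial simulation reports).
#'
#' @param perf a performance table from \code{\link{performance}} or
#'   \code{\link{run_study}}.
#' @param measure column to plot (default \code{"bias"}).
#' @param ref reference horizontal line (0 for bias, 0.95 for coverage).
#' @return invisibly, the reshaped matrix of plotted values.
#' @export
plot_performance <- function(perf, measure = "bias",
                             ref = if (measure == "coverage") 0.95 else 0) {
  stopifnot(measure %in% names(perf))
  scen <- unique(perf$scenario)
  meths <- unique(perf$method)
  m <- sapply(meths, function(mm)
    perf[[measure]][match(paste(scen, mm),
                          paste(perf$scenario, perf$method))])
  m <- matrix(m, nrow = length(scen),
              dimnames = list(scen, meths))
  graphics::matplot(m, type = "b", pch = seq_along(meths), lty = 1,
                    xaxt = "n", xlab = "scenario", ylab = measure,
                    main = paste("Simulation performance:", measure))
  graphics::axis(1, at = seq_along(scen), labels = scen, las = 2,
                 cex.axis = 0.7)
  graphics::abline(h = ref, lty = 3)
  graphics::legend("topleft", legend = meths, pch = seq_along(meths),
                   col = seq_along(meths), lty = 1, bty = "n", cex = 0.8)
  invisible(m)
}
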