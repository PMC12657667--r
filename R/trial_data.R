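#' Construct an individual-participant-data (IPD) trial object
#'
#' Container for one two-arm trial with row-level records: a binary
#' outcome, a binary treatment indicator (1 = active treatment, 0 = common
#' comparator) and a numeric covariate matrix.  All downstream estimators
#' (\code{\link{maic}}, \code{\link{gcomp_parametric}}, \code{\link{gmaic}})
#' consume this class.
#'
#' @param y integer/numeric vector of binary outcomes (0/1).
#' @param t integer/numeric vector of binary treatment indicators
#'   (1 = active arm, 0 = common comparator).
#' @param X numeric matrix (or data frame) of covariates, one row per
#'   participant.  Binary covariates are coded 0/1.
#' @param covariate_names optional character vector of covariate labels;
#'   defaults to the column names of \code{X} or \code{x1..xK}.
#' @param trial_label short label for the trial, e.g. \code{"AC"}.
#'
#' @return An object of class \code{ipd_trial}: a list with elements
#'   \code{y}, \code{t}, \code{X} (numeric matrix with column names),
#'   \code{covariate_names}, \code{trial_label}.
#' @export
ipd_trial <- function(y, t, X, covariate_names = NULL, trial_label = "AC") {
  y <- as.numeric(y)
  t <- as.numeric(t)
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  n <- length(y)
  if (length(t) != n || nrow(X) != n)
    stop("y, t and X must describe the same participants: lengths differ (",
         n, ", ", length(t), ", ", nrow(X), ")")
  if (n < 1L) stop("trial must contain at least one participant")
  if (ncol(X) < 1L) stop("at least one covariate is required")
  if (anyNA(y) || anyNA(t) || anyNA(X))
    stop("missing values are not supported in IPD")
  if (!all(y %in% c(0, 1))) stop("outcome y must be coded 0/1")
  if (!all(t %in% c(0, 1))) stop("treatment t must be coded 0/1")
  if (is.null(covariate_names)) {
    covariate_names <- colnames(X)
    if (is.null(covariate_names))
      covariate_names <- paste0("x", seq_len(ncol(X)))
  }
  if (length(covariate_names) != ncol(X))
    stop("covariate_names must have one entry per column of X")
  colnames(X) <- covariate_names
  structure(
    list(y = y, t = t, X = X,
         covariate_names = covariate_names,
         trial_label = as.character(trial_label)),
    class = "ipd_trial")
}

#' @export
print.ipd_trial <- function(x, ...) {
  cat("IPD trial ", x$trial_label, ": n = ", length(x$y),
      " (active ", sum(x$t == 1), " / comparator ", sum(x$t == 0), "), ",
      ncol(x$X), " covariates [",
      paste(x$covariate_names, collapse = ", "), "]\n", sep = "")
  cat("events: active ", sum(x$y[x$t == 1]), ", comparator ",
      sum(x$y[x$t == 0]), "\n", sep = "")
  invisible(x)
}

#' Construct an aggregate-level-data (ALD) trial summary
#'
#' Published-style summary of the comparator trial: pooled covariate means
#' (proportions for binary covariates), pooled covariate standard
#' deviations, and per-arm sample sizes and event counts for the active
#' arm (B) and the common comparator arm (C).
#'
#' @param cov_means numeric vector of covariate means.
#' @param cov_sds numeric vector of covariate SDs; \code{NA} entries are
#'   allowed for binary covariates, whose SDs no consumer uses.
#' @param n_B,n_C arm sample sizes.
#' @param events_B,events_C arm event counts.
#' @param covariate_names optional labels, recycled from names of
#'   \code{cov_means} when present.
#' @param trial_label short label, e.g. \code{"BC"}.
#'
#' @return An object of class \code{ald_summary}.
#' @export
ald_summary <- function(cov_means, cov_sds = NULL, n_B, n_C,
                        events_B, events_C,
                        covariate_names = NULL, trial_label = "BC") {
  cov_means <- as.numeric(cov_means)
  K <- length(cov_means)
  if (K < 1L) stop("at least one covariate mean is required")
  if (is.null(cov_sds)) cov_sds <- rep(NA_real_, K)
  cov_sds <- as.numeric(cov_sds)
  if (length(cov_sds) != K)
    stop("cov_sds must match cov_means in length")
  if (any(cov_sds < 0, na.rm = TRUE)) stop("covariate SDs must be >= 0")
  for (nm in c("n_B", "n_C", "events_B", "events_C")) {
    v <- get(nm)
    if (length(v) != 1L || is.na(v) || v < 0 || v != round(v))
      stop(nm, " must be a single non-negative integer")
  }
  if (n_B < 1 || n_C < 1) stop("both arms must contain participants")
  if (events_B > n_B) stop("events_B (", events_B, ") exceeds n_B (", n_B, ")")
  if (events_C > n_C) stop("events_C (", events_C, ") exceeds n_C (", n_C, ")")
  if (is.null(covariate_names)) {
    covariate_names <- names(cov_means)
    if (is.null(covariate_names))
      covariate_names <- paste0("x", seq_len(K))
  }
  structure(
    list(cov_means = stats::setNames(cov_means, covariate_names),
         cov_sds = stats::setNames(cov_sds, covariate_names),
         n_B = as.integer(n_B), n_C = as.integer(n_C),
         events_B = as.integer(events_B), events_C = as.integer(events_C),
         covariate_names = covariate_names,
         trial_label = as.character(trial_label)),
    class = "ald_summary")
}

#' @export
print.ald_summary <- function(x, ...) {
  cat("ALD trial ", x$trial_label, ": B ", x$events_B, "/", x$n_B,
      " events, C ", x$events_C, "/", x$n_C, " events\n", sep = "")
  m <- rbind(mean = x$cov_means, sd = x$cov_sds)
  print(round(m, 4))
  invisible(x)
}

#' Read an IPD trial from CSV
#'
#' Expects a header row with columns \code{y}, \code{t} and \code{x1..xK}
#' (any column other than \code{y}/\code{t} is taken as a covariate, in
#' file order).
#'
#' @param path path to a comma-separated file.
#' @param trial_label label for the resulting trial.
#' @return An \code{\link{ipd_trial}}.
#' @export
read_ipd <- function(path, trial_label = "AC") {
  if (!file.exists(path)) stop("IPD file not found: ", path)
  d <- utils::read.csv(path, check.names = FALSE)
  for (nm in c("y", "t"))
    if (!nm %in% names(d))
      stop("IPD file ", path, " is missing required column '", nm, "'")
  covs <- setdiff(names(d), c("y", "t"))
  if (length(covs) == 0L)
    stop("IPD file ", path, " contains no covariate columns")
  ipd_trial(d$y, d$t, as.matrix(d[covs]), covariate_names = covs,
            trial_label = trial_label)
}

#' Write an IPD trial to CSV
#'
#' @param trial an \code{\link{ipd_trial}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_ipd <- function(trial, path) {
  stopifnot(inherits(trial, "ipd_trial"))
  d <- data.frame(y = trial$y, t = trial$t, check.names = FALSE)
  d[trial$covariate_names] <- as.data.frame(trial$X)
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an ALD summary from YAML
#'
#' The file holds keys \code{cov_means}, optional \code{cov_sds} (YAML
#' \code{.na} or \code{~} for binary covariates), \code{n_B}, \code{n_C},
#' \code{events_B}, \code{events_C}, optional \code{covariate_names} and
#' \code{trial_label}.
#'
#' @param path path to a YAML file.
#' @return An \code{\link{ald_summary}}.
#' @export
read_ald <- function(path) {
  if (!file.exists(path)) stop("ALD file not found: ", path)
  d <- yaml::read_yaml(path)
  for (nm in c("cov_means", "n_B", "n_C", "events_B", "events_C"))
    if (is.null(d[[nm]]))
      stop("ALD file ", path, " is missing required key '", nm, "'")
  ald_summary(cov_means = unlist(d$cov_means),
              cov_sds = if (is.null(d$cov_sds)) NULL else
                as.numeric(unlist(d$cov_sds)),
              n_B = d$n_B, n_C = d$n_C,
              events_B = d$events_B, events_C = d$events_C,
              covariate_names = if (is.null(d$covariate_names)) NULL else
                unlist(d$covariate_names),
              trial_label = if (is.null(d$trial_label)) "BC" else
                d$trial_label)
}

#' Write an ALD summary to YAML
#'
#' @param ald an \code{\link{ald_summary}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_ald <- function(ald, path) {
  stopifnot(inherits(ald, "ald_summary"))
  yaml::write_yaml(
    list(trial_label = ald$trial_label,
         covariate_names = as.list(ald$covariate_names),
         cov_means = as.list(unname(ald$cov_means)),
         cov_sds = as.list(unname(ald$cov_sds)),
         n_B = ald$n_B, n_C = ald$n_C,
         events_B = ald$events_B, events_C = ald$events_C),
    path)
  invisible(path)
}

#' Aggregate an IPD trial into an ALD summary
#'
#' Pools covariates across arms (means and sample SDs) and tabulates
#' per-arm sample sizes and event counts, mimicking how a published trial
#' reports baseline characteristics and outcomes.  The active arm maps to
#' arm B and the comparator arm to arm C of the summary.
#'
#' @param trial an \code{\link{ipd_trial}}.
#' @param trial_label label for the resulting summary.
#' @return An \code{\link{ald_summary}}.
#' @export
aggregate_ipd <- function(trial, trial_label = trial$trial_label) {
  stopifnot(inherits(trial, "ipd_trial"))
  active <- trial$t == 1
  if (!any(active) || !any(!active))
    stop("cannot aggregate a trial with an empty arm")
  ald_summary(
    cov_means = colMeans(trial$X),
    cov_sds = apply(trial$X, 2, stats::sd),
    n_B = sum(active), n_C = sum(!active),
    events_B = sum(trial$y[active]), events_C = sum(trial$y[!active]),
    covariate_names = trial$covariate_names,
    trial_label = trial_label)
}
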