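#' @rdname fit_full_mle
#' @export
fit_mstate <- function(data, model, estimator = c("mle", "ignorev",
                                                  "earlycensor", "directml",
                                                  "mcem"), ...) {
  estimator <- match.arg(estimator)
  switch(estimator,
         mle = fit_full_mle(data, model, ...),
         ignorev = fit_ignorev(data, model, ...),
         earlycensor = fit_earlycensor(data, model, ...),
         directml = fit_directml(data, model, ...),
         mcem = fit_mcem(data, model, ...))
}

msm_fit_result <- function(estimator, model, theta, vcov, loglik, converged,
                           iterations, notes = character(0), level = 0.95,
                           extra = list()) {
  theta <- stats::setNames(as.numeric(theta), model$par_names)
  dimnames(vcov) <- list(model$par_names, model$par_names)
  out <- structure(c(list(estimator = estimator, theta = theta, vcov = vcov,
                          loglik = loglik, converged = converged,
                          iterations = iterations, notes = notes), extra),
                   class = "msm_fit")
  wald_ci(out, level)
}

#' Wald confidence intervals for a fit
#'
#' Symmetric normal-quantile intervals `theta_hat +/- z * SE` with the
#' standard errors taken from the square root of the covariance diagonal
#' (the inverse observed information at convergence). Negative variance
#' entries (non-positive-semidefinite covariance, e.g. from a saddle point)
#' are flagged and yield `NA` intervals.
#'
#' @param fit an `msm_fit` object.
#' @param level confidence level, default 0.95.
#' @return the fit with `se`, `ci_lower`, `ci_upper` and `level` fields
#'   updated.
#' @export
wald_ci <- function(fit, level = 0.95) {
  v <- diag(fit$vcov)
  bad <- !is.finite(v) | v < 0
  if (any(bad))
    fit$notes <- union(fit$notes, "covariance not positive semi-definite; some CIs unavailable")
  se <- ifelse(bad, NA_real_, sqrt(pmax(v, 0)))
  z <- stats::qnorm(1 - (1 - level) / 2)
  fit$se <- stats::setNames(se, names(fit$theta))
  fit$ci_lower <- fit$theta - z * se
  fit$ci_upper <- fit$theta + z * se
  fit$level <- level
  fit
}

#' @export
print.msm_fit <- function(x, ...) {
  cat("Fit (", x$estimator, "), log-likelihood ", format(x$loglik),
      if (!x$converged) "  [NOT CONVERGED]", "\n", sep = "")
  print(data.frame(estimate = x$theta, se = x$se,
                   lower = x$ci_lower, upper = x$ci_upper))
  if (length(x$notes)) cat("notes:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}

## shared machinery: Newton MLE on fully observed sequences
fit_mnl_sequences <- function(model, tau, ev_mat, len, init, estimator,
                              extra = list()) {
  cells <- compile_cells(model, tau)
  C <- tabulate_counts(model, cells, ev_mat, len)
  fn <- function(theta) mnl_objective(model, cells, theta, C)
  res <- newton_max(fn, init)
  vc <- invert_information(-res$hess)
  msm_fit_result(estimator, model, res$theta, vc$vcov, res$loglik,
                 res$converged && vc$ok, res$iterations,
                 notes = vc$notes, extra = extra)
}

invert_information <- function(info) {
  v <- tryCatch(solve(info), error = function(e) NULL)
  if (!is.null(v)) return(list(vcov = (v + t(v)) / 2, ok = TRUE,
                               notes = character(0)))
  # singular information: pseudo-inverse, flagged
  eg <- eigen(info, symmetric = TRUE)
  pos <- eg$values > max(eg$values) * 1e-12
  v <- eg$vectors[, pos, drop = FALSE] %*%
    (t(eg$vectors[, pos, drop = FALSE]) / eg$values[pos])
  list(vcov = (v + t(v)) / 2, ok = FALSE,
       notes = "singular observed information; pseudo-inverse used")
}

#' Fit the discrete hazard model: five estimation strategies
#'
#' All fitters maximize a (weighted) log-likelihood by Newton's method with
#' analytic score and Hessian, step-halving line search, gradient tolerance
#' `1e-8`, and return the inverse observed information at convergence as the
#' covariance with 95% Wald intervals.
#'
#' * `fit_full_mle()` -- the full-data MLE ("MLE*"), computed from latent
#'   paths before any coarsening (or from fully observed records).
#' * `fit_ignorev()` -- ignores the coarsening: every ambiguous time (more
#'   than one event indicated in `Yobs`) is recoded as the reference event 0
#'   and the full-data MLE is run on the modified data. Requires every
#'   ambiguous group to contain event 0. The modified data is returned in
#'   field `modified` for auditability; inputs are never mutated.
#' * `fit_earlycensor()` -- artificially right-censors each subject at the
#'   first observed time where some non-reference event is coarsened into
#'   group 0, then runs the full-data MLE on the truncated records. Field
#'   `modified` holds the truncation times.
#' * `fit_directml()` -- direct maximum likelihood on the ignorable
#'   likelihood: all compatible latent paths are enumerated once per
#'   distinct record before optimization, and score/information come from
#'   exact finite-mixture identities ([score_info()]).
#' * `fit_mcem()` -- Monte Carlo EM with importance sampling; see
#'   [mcem_fit()].
#'
#' @param paths a `latent_paths` object ([simulate_paths()]).
#' @param records an `observed_records` object ([apply_coarsening()]).
#' @param model an [mstate_model()].
#' @param init optional initial parameter vector (default all zero).
#' @param max_paths per-subject cap on compatible paths (DirectML).
#' @param ... passed through by [fit_mstate()].
#' @return an object of class `msm_fit`.
#' @export
fit_full_mle <- function(paths, model, init = NULL) {
  init <- if (is.null(init)) rep(0, model$p) else as_theta(model, init)
  if (inherits(paths, "observed_records")) {
    sq <- records_to_sequences(paths)
    return(fit_mnl_sequences(model, paths$tau, sq$ev, sq$len, init, "MLE"))
  }
  stopifnot(inherits(paths, "latent_paths"))
  fit_mnl_sequences(model, paths$tau, paths$events,
                    pmin(paths$T1, paths$tau), init, "MLE")
}

records_to_sequences <- function(records, allow_recode = FALSE) {
  model <- records$model
  N <- length(records$records)
  ev <- matrix(NA_integer_, N, records$tau)
  len <- integer(N)
  recoded <- 0L
  for (i in seq_len(N)) {
    r <- records$records[[i]]
    len[i] <- r$tobs
    for (t in seq_len(r$tobs)) {
      occ <- which(r$Yobs[, t] == 1L) - 1L
      if (length(occ) == 1L) ev[i, t] <- occ
      else if (allow_recode) {
        if (!0L %in% occ)
          stop("ambiguous group without the reference event at subject ", i,
               ", t = ", t, "; IgnoreV is not applicable")
        ev[i, t] <- 0L
        recoded <- recoded + 1L
      } else stop("record ", i, " has an ambiguous time (t = ", t,
                  "); a fully observed dataset is required")
    }
  }
  list(ev = ev, len = len, recoded = recoded)
}

#' @rdname fit_full_mle
#' @export
fit_ignorev <- function(records, model, init = NULL) {
  stopifnot(inherits(records, "observed_records"))
  init <- if (is.null(init)) rep(0, model$p) else as_theta(model, init)
  sq <- records_to_sequences(records, allow_recode = TRUE)
  mod <- data.frame(subject_id = rep(seq_along(sq$len), sq$len),
                    t = sequence(sq$len),
                    event = as.integer(t(sq$ev))[as.vector(t(col(sq$ev) <= sq$len))])
  fit_mnl_sequences(model, records$tau, sq$ev, sq$len, init, "IgnoreV",
                    extra = list(modified = mod))
}

#' @rdname fit_full_mle
#' @export
fit_earlycensor <- function(records, model, init = NULL) {
  stopifnot(inherits(records, "observed_records"))
  init <- if (is.null(init)) rep(0, model$p) else as_theta(model, init)
  N <- length(records$records)
  ev <- matrix(NA_integer_, N, records$tau)
  len <- integer(N)
  cens_at <- rep(NA_integer_, N)
  for (i in seq_len(N)) {
    r <- records$records[[i]]
    tobs <- r$tobs
    # first observed time where some non-reference event sits in group 0
    trig <- which(colSums(r$Vobs[-1, seq_len(tobs), drop = FALSE] == 0L) > 0)
    if (length(trig)) {
      cens_at[i] <- min(trig)
      tobs <- min(trig) - 1L
    }
    len[i] <- tobs
    for (t in seq_len(tobs)) {
      occ <- which(r$Yobs[, t] == 1L) - 1L
      if (length(occ) != 1L)
        stop("ambiguity remains after early censoring at subject ", i,
             " (non reference-grouped coarsening)")
      ev[i, t] <- occ
    }
  }
  if (all(len == 0L))
    stop("early censoring truncated every subject to length 0")
  fit_mnl_sequences(model, records$tau, ev, len, init, "EarlyCensor",
                    extra = list(modified = data.frame(
                      subject_id = seq_len(N), censored_at = cens_at)))
}

#' @rdname fit_full_mle
#' @export
fit_directml <- function(records, model, init = NULL, max_paths = 1e5) {
  stopifnot(inherits(records, "observed_records"))
  init <- if (is.null(init)) rep(0, model$p) else as_theta(model, init)
  cells <- compile_cells(model, records$tau)
  fl <- flatten_records(model, cells, records, max_paths)
  fn <- function(theta) mixture_objective(model, cells, fl, theta)
  res <- newton_max(fn, init)
  vc <- invert_information(-res$hess)
  msm_fit_result("DirectML", model, res$theta, vc$vcov, res$loglik,
                 res$converged && vc$ok, res$iterations, notes = vc$notes,
                 extra = list(n_paths = fl$n_paths, n_distinct = fl$n_recs))
}
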