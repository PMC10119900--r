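#' Simulation-study performance measures
#'
#' Aggregates repeated estimates into per (estimator, N, parameter) bias,
#' empirical standard error and confidence-interval coverage, each with its
#' Monte Carlo standard error:
#' `bias = mean(theta_hat) - theta`, `empse = sd(theta_hat)`,
#' `mcse_bias = empse / sqrt(nsim)`,
#' `mcse_empse = empse / sqrt(2 (nsim - 1))`,
#' `coverage = mean(ci_lower <= theta <= ci_upper)` (closed interval),
#' `mcse_coverage = sqrt(coverage (1 - coverage) / nsim)`.
#' Non-converged repetitions are excluded from the measures and counted in
#' `n_excluded`.
#'
#' @param estimates data frame with columns `estimator`, `N`, `rep`,
#'   `parameter`, `estimate`, `ci_lower`, `ci_upper`, `converged`.
#' @param truth named true parameter vector.
#' @return data frame of class `performance_table`.
#' @export
performance_metrics <- function(estimates, truth) {
  need <- c("estimator", "N", "rep", "parameter", "estimate",
            "ci_lower", "ci_upper", "converged")
  stopifnot(all(need %in% names(estimates)))
  if (!all(estimates$parameter %in% names(truth)))
    stop("truth is missing parameters: ",
         paste(setdiff(unique(estimates$parameter), names(truth)), collapse = ", "))
  key <- interaction(estimates$estimator, estimates$N, estimates$parameter,
                     drop = TRUE, sep = "\r")
  rows <- lapply(levels(key), function(k) {
    sub <- estimates[key == k, , drop = FALSE]
    th <- truth[[sub$parameter[1]]]
    ok <- sub$converged
    est <- sub$estimate[ok]
    nsim <- length(est)
    if (nsim < 2) stop("fewer than 2 converged estimates for ", k)
    empse <- stats::sd(est)
    cov <- mean(sub$ci_lower[ok] <= th & th <= sub$ci_upper[ok])
    data.frame(estimator = sub$estimator[1], N = sub$N[1],
               parameter = sub$parameter[1], truth = th,
               nsim = nsim, n_excluded = sum(!ok),
               bias = mean(est) - th, mcse_bias = empse / sqrt(nsim),
               empse = empse, mcse_empse = empse / sqrt(2 * (nsim - 1)),
               coverage = cov,
               mcse_coverage = sqrt(cov * (1 - cov) / nsim))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("performance_table", class(out))
  out
}

#' Configure and run a simulation study
#'
#' For each sample size `N` and repetition: simulate latent paths from the
#' model at the true parameter, fit the full-data MLE ("MLE*") before
#' coarsening, coarsen the paths under the scenario, and fit each requested
#' estimator on the observed records. Per-repetition seeds are drawn up
#' front from the root seed, so the whole study is a deterministic function
#' of `(config, seed)` and independent of scheduling.
#'
#' @param model an [mstate_model()] (with a `"truth"` attribute, or pass
#'   `truth`).
#' @param scenario a [scenario_spec()].
#' @param N vector of sample sizes.
#' @param nsim number of repetitions (>= 2).
#' @param estimators subset of `c("mle", "ignorev", "earlycensor",
#'   "directml", "mcem")`.
#' @param truth true parameter vector (default `true_theta(model)`).
#' @param seed root seed.
#' @param mcem an [mcem_control()] for the MCEM estimator.
#' @param max_paths compatible-path cap for DirectML.
#' @param verbose print per-repetition progress.
#' @return list of class `sim_study` with `estimates` (raw per-repetition
#'   results), `performance` (a [performance_metrics()] table), `truth` and
#'   the settings.
#' @export
run_study <- function(model, scenario, N, nsim, estimators = c("mle", "ignorev",
                                                               "earlycensor",
                                                               "directml"),
                      truth = NULL, seed = 1L, mcem = mcem_control(),
                      max_paths = 1e5, verbose = FALSE) {
  stopifnot(nsim >= 2)
  estimators <- match.arg(estimators, c("mle", "ignorev", "earlycensor",
                                        "directml", "mcem"),
                          several.ok = TRUE)
  if (is.null(truth)) truth <- true_theta(model)
  truth <- as_theta(model, truth)
  set.seed(seed)
  rep_seeds <- matrix(sample.int(2147483646L, length(N) * nsim),
                      nsim, length(N))
  all_rows <- list()
  for (iN in seq_along(N)) {
    for (rep in seq_len(nsim)) {
      s <- rep_seeds[rep, iN]
      rows <- run_one_rep(model, scenario, N[iN], truth, s, estimators,
                          mcem, max_paths)
      rows$rep <- rep
      all_rows[[length(all_rows) + 1L]] <- rows
      if (verbose)
        message("N = ", N[iN], " rep ", rep, "/", nsim, " done")
    }
  }
  estimates <- do.call(rbind, all_rows)
  structure(list(estimates = estimates,
                 performance = performance_metrics(estimates, truth),
                 truth = truth, N = N, nsim = nsim,
                 estimators = estimators, seed = seed),
            class = "sim_study")
}

run_one_rep <- function(model, scenario, N, truth, s, estimators, mcem,
                        max_paths) {
  paths <- simulate_paths(model, truth, N, scenario$tau, seed = s)
  schedules <- make_scenario_schedules(scenario, model, N, seed = s + 1L)
  records <- apply_coarsening(paths, schedules)
  fits <- list()
  for (est in estimators) {
    fit <- tryCatch(switch(est,
      mle = fit_full_mle(paths, model),
      ignorev = fit_ignorev(records, model),
      earlycensor = fit_earlycensor(records, model),
      directml = fit_directml(records, model, max_paths = max_paths),
      mcem = {
        ctl <- mcem
        ctl$seed <- as.integer((as.double(s) + 2L) %% 2147483629)
        fit_mcem(records, model, ctl)
      }), error = function(e) e)
    fits[[est]] <- fit
  }
  do.call(rbind, lapply(names(fits), function(est) {
    f <- fits[[est]]
    lab <- c(mle = "MLE", ignorev = "IgnoreV", earlycensor = "EarlyCensor",
             directml = "DirectML", mcem = "MCEM")[[est]]
    if (inherits(f, "error"))
      return(data.frame(estimator = lab, N = N, parameter = model$par_names,
                        estimate = NA_real_, ci_lower = NA_real_,
                        ci_upper = NA_real_, converged = FALSE))
    data.frame(estimator = lab, N = N, parameter = names(f$theta),
               estimate = unname(f$theta), ci_lower = unname(f$ci_lower),
               ci_upper = unname(f$ci_upper),
               converged = f$converged & !is.na(f$ci_lower))
  }))
}

#' @export
print.sim_study <- function(x, ...) {
  cat("Simulation study:", x$nsim, "repetitions, N =",
      paste(x$N, collapse = ", "), "\n")
  print(format_performance(x$performance))
  invisible(x)
}

#' Format a performance table in the conventional layout
#'
#' Rows are estimator-by-N, columns are parameters, each cell shows
#' "bias (MC-SE)" (or another measure).
#'
#' @param perf a [performance_metrics()] table.
#' @param measure one of `"bias"`, `"empse"`, `"coverage"`.
#' @param digits rounding for the displayed values.
#' @return a data frame ready for printing.
#' @export
format_performance <- function(perf, measure = "bias", digits = 3) {
  mcse <- paste0("mcse_", measure)
  pars <- unique(perf$parameter)
  keys <- unique(perf[, c("estimator", "N")])
  out <- keys
  for (pp in pars) {
    cellv <- character(nrow(keys))
    for (i in seq_len(nrow(keys))) {
      row <- perf[perf$estimator == keys$estimator[i] & perf$N == keys$N[i] &
                    perf$parameter == pp, ]
      cellv[i] <- sprintf("%.*f (%.*f)", digits, row[[measure]],
                          digits, row[[mcse]])
    }
    out[[pp]] <- cellv
  }
  out
}

#' Write a small deterministic demonstration study to a directory
#'
#' Generates a micro study (prostate model, scenario-1-type coarsening at
#' reduced follow-up, N = 300) and writes the latent CSV, observed CSV,
#' per-estimator fit table and performance table. All output is a pure
#' function of `seed`.
#'
#' @param dir output directory (created if needed).
#' @param seed integer seed.
#' @return invisibly, the paths of the written files.
#' @export
write_demo_study <- function(dir, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  model <- model_prostate()
  truth <- true_theta(model)
  scen <- scenario_spec(tau = 6, blackout_times = 3:5,
                        patterns = list(list(c(0L, 2L))), pattern_probs = 1,
                        subject_prob = 0.5)
  paths <- simulate_paths(model, truth, 300, scen$tau, seed = seed)
  schedules <- make_scenario_schedules(scen, model, 300, seed = seed + 1L)
  records <- apply_coarsening(paths, schedules)
  f1 <- file.path(dir, "latent.csv"); write_paths_csv(paths, f1)
  f2 <- file.path(dir, "observed.csv"); write_records_csv(records, f2)
  fits <- list(MLE = fit_full_mle(paths, model),
               IgnoreV = fit_ignorev(records, model),
               EarlyCensor = fit_earlycensor(records, model),
               DirectML = fit_directml(records, model))
  tab <- do.call(rbind, lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    data.frame(estimator = nm, parameter = names(f$theta),
               estimate = unname(f$theta), se = unname(f$se),
               ci_lower = unname(f$ci_lower), ci_upper = unname(f$ci_upper),
               converged = f$converged)
  }))
  f3 <- file.path(dir, "fits.csv")
  utils::write.csv(format(tab, digits = 10), f3, row.names = FALSE,
                   quote = FALSE)
  invisible(c(f1, f2, f3))
}
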