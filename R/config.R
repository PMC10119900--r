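#' Read a study configuration file
#'
#' A single YAML document describes a complete study: a `model` section
#' (either `preset: prostate | onset_late | onset_early` or a full custom
#' specification with `events`, `absorbing`, `kill_sets`, `contexts`,
#' `ctx_init`, `ctx_trans`, a `feasible` (event, context) table for
#' intercept + time terms and optional `indicators`), an optional `truth`
#' mapping (required for custom models), a `scenario` section (`id: 1|2|3`
#' or custom `tau` / `blackout_times` / `patterns` / `pattern_probs` /
#' `subject_prob`), a `study` section (`N`, `nsim`, `estimators`, `seed`)
#' and an optional `mcem` section ([mcem_control()] fields). Validation
#' errors name the offending field.
#'
#' @param file path to a YAML configuration file.
#' @return list with `model`, `truth`, `scenario`, `study`, `mcem`.
#' @export
read_study_config <- function(file) {
  cfg <- yaml::read_yaml(file)
  if (is.null(cfg$model)) stop("config: missing 'model' section")
  model <- model_from_config(cfg$model)
  truth <- if (!is.null(cfg$truth)) {
    as_theta(model, unlist(cfg$truth))
  } else {
    tr <- attr(model, "truth")
    if (is.null(tr)) stop("config: custom model requires a 'truth' section")
    tr
  }
  if (is.null(cfg$scenario)) stop("config: missing 'scenario' section")
  scenario <- scenario_from_config(cfg$scenario)
  st <- cfg$study
  # YAML 1.1 reads a bare key `N` as boolean FALSE; accept either spelling
  if (!is.null(st) && is.null(st$N) && "FALSE" %in% names(st))
    st$N <- st[["FALSE"]]
  if (is.null(st) || is.null(st$N) || is.null(st$nsim))
    stop("config: 'study' section must give N and nsim")
  study <- list(N = as.integer(unlist(st$N)), nsim = as.integer(st$nsim),
                estimators = if (is.null(st$estimators))
                  c("mle", "ignorev", "earlycensor", "directml")
                else unlist(st$estimators),
                seed = if (is.null(st$seed)) 1L else as.integer(st$seed))
  mcem <- do.call(mcem_control, if (is.null(cfg$mcem)) list() else cfg$mcem)
  list(model = model, truth = truth, scenario = scenario, study = study,
       mcem = mcem)
}

model_from_config <- function(mc) {
  if (!is.null(mc$preset))
    return(switch(mc$preset,
                  prostate = model_prostate(),
                  onset_late = model_onset_late(),
                  onset_early = model_onset_early(),
                  stop("config: unknown model preset '", mc$preset, "'")))
  need <- c("events", "absorbing", "contexts", "ctx_init", "ctx_trans",
            "feasible")
  miss <- setdiff(need, names(mc))
  if (length(miss)) stop("config: model section missing ",
                         paste(miss, collapse = ", "))
  trans <- do.call(rbind, mc$ctx_trans[mc$contexts])
  feas <- do.call(rbind, lapply(mc$feasible, as.data.frame))
  terms <- state_time_terms(feas)
  if (!is.null(mc$indicators))
    terms <- c(terms, lapply(mc$indicators, function(x)
      term_intercept(x$name, x$event, unlist(x$contexts))))
  ks <- if (is.null(mc$kill_sets)) list() else lapply(mc$kill_sets, unlist)
  mstate_model(unlist(mc$events), unlist(mc$absorbing), ks,
               unlist(mc$contexts), mc$ctx_init, trans, terms)
}

scenario_from_config <- function(sc) {
  if (!is.null(sc$id)) return(scenario_spec(id = sc$id))
  patterns <- lapply(sc$patterns, function(p) lapply(p, as.integer))
  scenario_spec(tau = sc$tau, blackout_times = unlist(sc$blackout_times),
                patterns = patterns,
                pattern_probs = if (is.null(sc$pattern_probs)) NULL
                                else unlist(sc$pattern_probs),
                subject_prob = if (is.null(sc$subject_prob)) 1
                               else sc$subject_prob,
                per_subject = if (is.null(sc$per_subject)) TRUE
                              else isTRUE(sc$per_subject))
}

#' Run a full study from a configuration file
#'
#' Convenience wrapper: [read_study_config()] then [run_study()], writing
#' the raw estimates and the performance table as CSV files into `out_dir`.
#'
#' @param file YAML configuration path.
#' @param out_dir output directory.
#' @param verbose print progress.
#' @return the `sim_study` object, invisibly.
#' @export
run_study_config <- function(file, out_dir = ".", verbose = TRUE) {
  cfg <- read_study_config(file)
  study <- run_study(cfg$model, cfg$scenario, cfg$study$N, cfg$study$nsim,
                     estimators = cfg$study$estimators, truth = cfg$truth,
                     seed = cfg$study$seed, mcem = cfg$mcem,
                     verbose = verbose)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(study$estimates, file.path(out_dir, "estimates.csv"),
                   row.names = FALSE)
  utils::write.csv(study$performance, file.path(out_dir, "performance.csv"),
                   row.names = FALSE)
  invisible(study)
}
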