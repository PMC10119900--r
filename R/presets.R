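#' Bundled data-generating models
#'
#' Three progressive multi-state models used throughout the package's
#' simulation studies, each a baseline-category discrete hazard model with
#' per (event, state) intercept and time slope.
#'
#' `model_prostate()` mimics palliative treatment of advanced prostate
#' cancer: events 0 = Alive (reference), 1 = AA (anti-androgen
#' prescription), 2 = GnRH (gonadotropin-releasing hormone prescription),
#' 3 = Death (absorbing). States are S0 (untreated), S1 (has received AA),
#' S2 (has received GnRH); a prescription of AA never follows a prior GnRH
#' (GnRH removes AA from the risk set), and within S2 an extra indicator
#' coefficient (`GnRH:S2:hadS1`) distinguishes men who reached GnRH after
#' AA. Time is measured in 90-day windows over a follow-up of up to
#' `tau = 50`.
#'
#' `model_onset_late()` and `model_onset_early()` are three-event
#' illness-death-type models (0 = Alive, 1 = Treatment, 2 = Death) with one
#' transient state: in the late-onset model (designed for `tau = 50`)
#' treatment initiation is infrequent but increases with time, repeat
#' treatment is infrequent and decreases with time, and mortality differs
#' sharply between treated and untreated; in the early-onset model
#' (designed for `tau = 10`) treatment starts early, repeat treatment is
#' frequent among the treated especially at early times, and the risk of
#' death rises rapidly towards the end of follow-up.
#'
#' Four coefficients of the prostate model (`GnRH:S1:intercept = -1.62`,
#' `GnRH:S1:time = -0.039`, `Death:S0:intercept = -4.66`,
#' `Death:S0:time = -0.023`) are register-calibrated reference values; the
#' remaining coefficients of all three models are a synthetic calibration
#' chosen to reproduce the qualitative dynamics described above (see the
#' methods vignette). The full truth vector used by the study harness is
#' attached as attribute `"truth"` and returned by [true_theta()].
#'
#' @return an [mstate_model()] with a `"truth"` attribute.
#' @export
model_prostate <- function() {
  events <- c("Alive", "AA", "GnRH", "Death")
  contexts <- c("S0", "S1", "S2", "S2hadS1")
  trans <- rbind(
    S0      = c("S0", "S1", "S2",      "S0"),
    S1      = c("S1", "S1", "S2hadS1", "S1"),
    S2      = c("S2", "S2", "S2",      "S2"),
    S2hadS1 = c("S2hadS1", "S2hadS1", "S2hadS1", "S2hadS1"))
  feas <- data.frame(
    event   = c("AA", "AA", "GnRH", "GnRH", "GnRH", "GnRH",
                "Death", "Death", "Death", "Death"),
    context = c("S0", "S1", "S0", "S1", "S2", "S2hadS1",
                "S0", "S1", "S2", "S2hadS1"),
    label   = c("S0", "S1", "S0", "S1", "S2", "S2",
                "S0", "S1", "S2", "S2"))
  terms <- c(state_time_terms(feas),
             list(term_intercept("GnRH:S2:hadS1", "GnRH", "S2hadS1")))
  m <- mstate_model(events, absorbing = "Death",
                    kill_sets = list(GnRH = "AA"),
                    contexts = contexts, ctx_init = "S0",
                    ctx_trans = trans, terms = terms)
  truth <- c(
    "AA:S0:intercept"    = -1.10, "AA:S0:time"    = -0.150,
    "AA:S1:intercept"    = -0.70, "AA:S1:time"    = -0.050,
    "GnRH:S0:intercept"  = -1.40, "GnRH:S0:time"  = -0.050,
    "GnRH:S1:intercept"  = -1.62, "GnRH:S1:time"  = -0.039,
    "GnRH:S2:intercept"  = -0.40, "GnRH:S2:time"  = -0.010,
    "Death:S0:intercept" = -4.66, "Death:S0:time" = -0.023,
    "Death:S1:intercept" = -3.60, "Death:S1:time" =  0.020,
    "Death:S2:intercept" = -2.80, "Death:S2:time" =  0.030,
    "GnRH:S2:hadS1"      =  0.30)
  attr(m, "truth") <- as_theta(m, truth)
  m
}

#' @rdname model_prostate
#' @export
model_onset_late <- function() {
  m <- illness_death_model()
  truth <- c(
    "Trt:S0:intercept"   = -4.50, "Trt:S0:time"   =  0.060,
    "Trt:S1:intercept"   = -3.00, "Trt:S1:time"   = -0.050,
    "Death:S0:intercept" = -5.00, "Death:S0:time" =  0.020,
    "Death:S1:intercept" = -3.00, "Death:S1:time" =  0.020)
  attr(m, "truth") <- as_theta(m, truth)
  m
}

#' @rdname model_prostate
#' @export
model_onset_early <- function() {
  m <- illness_death_model()
  truth <- c(
    "Trt:S0:intercept"   = -2.50, "Trt:S0:time"   =  0.050,
    "Trt:S1:intercept"   =  0.50, "Trt:S1:time"   = -0.250,
    "Death:S0:intercept" = -5.00, "Death:S0:time" =  0.350,
    "Death:S1:intercept" = -4.50, "Death:S1:time" =  0.350)
  attr(m, "truth") <- as_theta(m, truth)
  m
}

illness_death_model <- function() {
  events <- c("Alive", "Trt", "Death")
  trans <- rbind(S0 = c("S0", "S1", "S0"),
                 S1 = c("S1", "S1", "S1"))
  feas <- data.frame(event = c("Trt", "Trt", "Death", "Death"),
                     context = c("S0", "S1", "S0", "S1"))
  mstate_model(events, absorbing = "Death", kill_sets = list(),
               contexts = c("S0", "S1"), ctx_init = "S0",
               ctx_trans = trans, terms = state_time_terms(feas))
}

#' True parameter vector of a bundled model
#'
#' @param model a model carrying a `"truth"` attribute
#'   ([model_prostate()] and friends).
#' @return named numeric vector.
#' @export
true_theta <- function(model) {
  tr <- attr(model, "truth")
  if (is.null(tr)) stop("model carries no truth attribute")
  tr
}

#' Default coarsening scenario for the illness-death models
#'
#' Blackout of the treatment register (events 0 and 1 merged) with
#' per-subject probability 0.5: at times 1--10 for the late-onset model
#' (`tau = 50`), at times 3--6 for the early-onset model (`tau = 10`).
#'
#' @param which `"late"` or `"early"`.
#' @return a [scenario_spec()].
#' @export
onset_scenario <- function(which = c("late", "early")) {
  which <- match.arg(which)
  if (which == "late")
    scenario_spec(tau = 50, blackout_times = 1:10,
                  patterns = list(list(c(0L, 1L))), pattern_probs = 1,
                  subject_prob = 0.5)
  else
    scenario_spec(tau = 10, blackout_times = 3:6,
                  patterns = list(list(c(0L, 1L))), pattern_probs = 1,
                  subject_prob = 0.5)
}
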