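---
title: "Estimating discrete-time multi-state models from coarsened event histories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating discrete-time multi-state models from coarsened event histories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coarsemsm)
```

## The problem

Register-based longitudinal studies often observe *which kind* of event
happened only during parts of the follow-up. A prescription register may
start collecting data mid-study, lose coverage during a calendar window, or
distinguish event subtypes only after a definition change; a cause of death
may be missing for recent deaths. At such times one knows only that *some
event in a group* occurred — the data are *coarsened*, a notion that
subsumes missingness and censoring. Because the history of past events
feeds back into future event probabilities (a man who already switched to a
second-line drug has different hazards than an untreated one), coarsening
simultaneously corrupts the outcome and the history-derived covariates, and
naive work-arounds can be badly biased.

`coarsemsm` provides, in one package: a simulator for discrete-time
multivariate event histories; a representation of coarsening processes and
the induced observed data; maximum likelihood estimation under independent,
non-informative coarsening by direct marginalization over compatible latent
paths; a Monte Carlo EM (MCEM) alternative based on importance sampling;
the two naive comparators used as baselines; and a simulation-study harness
with the standard performance measures.

## The latent model

Time is discrete, `t = 1, ..., tau` (1-based throughout, matching the
notation of discrete-time event-history analysis). Events are indexed
`0, ..., n`: event 0 is the reference ("nothing happened"), events
`1..n_na` are non-absorbing, the last `n_a` are absorbing. Exactly one
event occurs per step until absorption; the latent local response `Y` is
the `(1+n) x tau` indicator matrix of these events, and `T1` the absorption
time (`tau + 1` if none).

Conditional on the history, event probabilities follow a baseline-category
(multinomial logit) model. Each non-reference event at risk has a linear
predictor `eta_{j,t}` and

    Pr(Y[j,t] = 1 | past) = b[j,t] * exp(eta[j,t]) / (1 + sum_k b[k,t] * exp(eta[k,t]))

with the reference taking the remaining mass. The at-risk indicators
`b[j,t]` are generated by *kill sets*: after event `e` occurs, every event
in `kill_sets[[e]]` is permanently out of risk (absorbing events kill
everything, the reference is never killed). Support is therefore monotone
non-increasing — the structural restriction under which the fast support
computation and the importance-sampling proposal below are valid. `b_t` is
a deterministic function of the history through `t - 1`, so it is known one
step ahead.

### Contexts instead of raw histories

The package requires the linear predictors to depend on the history only
through a finite *context* label updated event-by-event (plus time itself).
A context is typically a treatment state — S0 untreated, S1 on first-line
drug, S2 on second-line — possibly enriched with indicators such as "S2
reached via S1". This is not a practical restriction for the model family
targeted here (every coefficient is of the form event:state:intercept,
event:state:time, or event:state:indicator), and it buys a decisive
computational property: the hazard vector depends on the past only through
the cell `(t, context, set-of-occurred-events)`. All likelihoods, scores
and Hessians in the package reduce to weighted sums over a few thousand
such cells, which is what makes a pure-R implementation practical at
`N = 10,000` subjects. Discrete external or time-fixed covariates can be
folded into the context label space; continuous external covariate
processes are out of scope.

## Coarsening and the observed data

The coarsening process is a `(1+n) x tau` matrix `V` of group labels:
events sharing `V[., t]` are indistinguishable at `t`, and each group is
labelled by its lowest member index. Absorbing and non-absorbing events are
never grouped together — whether the subject is still under follow-up is
always known — except that right censoring at `t2` is encoded as all-zero
columns from `t2` on. The observed local response is

    Yobs[j,t] = sum_g Y[g,t] * I(V[g,t] = V[j,t]),

so an ambiguous time shows a whole group of 1's. With `T2` the censoring
time, `D = min(T1, T2)`, `Delta = I(D = T2)` and `C_t = I(D - Delta >= t)`,
the observables are `Yobs`, `Vobs = C_t * V` and the follow-up summaries —
all recoverable from `Yobs` and `Vobs` alone, which the file reader uses as
a consistency check.

Crucially, a coarsened time need not stay ambiguous: if AA can never follow
GnRH and AA is observed *after* a time where {AA, GnRH} were merged, the
merged event must have been AA. The enumeration and support machinery
exploit exactly this.

## The ignorable likelihood and DirectML

Under conditional independence of `V` and `Y` (given external covariates)
and non-informativeness, the observed-data likelihood is proportional to
the *ignorable likelihood*: the latent likelihood summed over every latent
path of length `D - Delta` that agrees with the observed groups, the
unambiguous events, and the at-risk process. `enumerate_compatible()`
performs an exact depth-first enumeration over the ambiguous times, pruning
events that are out of risk, absorb too early, or would kill an event
observed later; it is verified against a brute-force sweep of all `(1+n)^t`
sequences in the test suite. The enumeration is performed once per distinct
record before optimization.

The score and observed information are computed through exact
finite-mixture identities over the compatible set: with posterior path
weights `pi_c` proportional to the latent likelihoods,

    grad = sum_c pi_c s_c
    hess = sum_c pi_c (H_c + s_c s_c') - grad grad'

where `s_c, H_c` are the standard multinomial-logit per-path score and
Hessian. This route was chosen over transcribing closed-form derivative
expressions symbol-by-symbol because the identities hold exactly for any
finite mixture and can be validated independently against central finite
differences (the tests require relative agreement of 1e-5 for the score
and 1e-4 for the Hessian). `fit_directml()` maximizes the summed ignorable
log-likelihood by Newton's method on these derivatives.

`enumerate_compatible()` refuses to expand more than `max_paths` (default
100,000) paths per subject and fails loudly instead of truncating: the path
count grows exponentially with the number of ambiguous times, and a
silently truncated likelihood would no longer be a likelihood.

## MCEM with importance sampling

When enumeration is too expensive, `fit_mcem()` maximizes the same
likelihood by Monte Carlo EM. The E-step expectation of the latent
log-likelihood given the observed data is approximated by self-normalized
importance sampling. The proposal is built from the *support matrix* `J`:
`J[j+1, t] = 1` iff some compatible path has event `j` at `t`. In the
restricted class (kill-set dynamics; only non-absorbing events merged with
the reference) `J` has a fast observable-data rule — in the occurred group,
at risk under the unambiguous past, killing no later-observed event — which
the tests verify against the enumeration oracle. Sampling proceeds
sequentially: at each time the proposal column is `Q_t = (J_t * P_t) /
(J_t' P_t)` with `P_t` the current-history hazards; ambiguous times are
drawn from `Q_t`, observed times are kept; the raw weight is
`w = prod P_t' y_t / prod Q_t' y_t`. Because the proposal support equals
the posterior support in the restricted class, every sampled path is
compatible and every weight is strictly positive (asserted in tests).

The EM loop runs a fixed 10 iterations with sample-size schedule
`m_r = min(10 + 5(r-1), m_max)`, `m_max = 25` by default (40 is
recommended when many times are coarsened over a long follow-up, where the
path posterior is more diffuse). Initialization is the EarlyCensor
estimate. Each iteration maximizes the weighted surrogate — a weighted
multinomial-logit log-likelihood, solved by the same Newton core — and the
running estimate is the cumulative sample-size-weighted average
`theta_r = (m_r that_r + sum_{j<r} m_j that_j) / sum_{j<=r} m_j`, which
damps the Monte Carlo noise of the later iterations. Design choices made
where the procedure is underdetermined, recorded here deliberately:

* fresh samples are drawn every iteration (no sample recycling), keeping
  iterations conditionally independent;
* subjects without any ambiguous time bypass sampling entirely and
  contribute exact terms, reducing both cost and variance;
* per-subject, per-iteration sampler seeds are derived deterministically
  from the control seed, so results do not depend on the number of
  subjects processed or on processing order;
* the covariance is a Louis-type observed information at the final
  estimate, computed from a fresh importance sample of `var_m` draws per
  coarsened subject via the same weighted mixture identity (negated), plus
  the exact information of the fully observed subjects. The standard-error
  construction for MCEM is an interpretation — the loop itself only
  defines the point estimate — and is documented as such.

## Naive comparators

`fit_ignorev()` acts as if nothing happened at ambiguous times: every time
with more than one indicated event is recoded to the reference event and
the full-data MLE is run on the modified copy (inputs are never mutated;
the modified data ship with the fit for audit). This misclassifies both
outcomes and history-derived covariates, correlated over consecutive
coarsened times. `fit_earlycensor()` instead right-censors each subject at
the first observed time where a non-reference event is merged into group 0;
under independent coarsening this is unbiased but discards all later
information. Both require only the full-data machinery.

All fitters share one Newton core: analytic score and Hessian,
step-halving line search with Levenberg damping for non-concave stretches,
gradient tolerance `1e-8`, at most 200 iterations. Singular information at
convergence is flagged (pseudo-inverse, `converged = FALSE`) rather than
hidden. Wald intervals are `theta_hat +/- z * SE` at level 0.95 by default.

## Bundled data-generating models and their calibration

`model_prostate()` is a four-event pathway for palliative prostate-cancer
treatment (Alive, AA, GnRH, Death; states S0/S1/S2 with a "had S1"
indicator inside S2; GnRH removes AA from risk), with time measured in
90-day windows. Four of its 17 coefficients are register-calibrated
reference values carried as-is:

* `GnRH:S1:intercept = -1.62`, `GnRH:S1:time = -0.039`
* `Death:S0:intercept = -4.66`, `Death:S0:time = -0.023`

The other 13 coefficients — and all 8 coefficients of each illness-death
model — are a **synthetic calibration**, chosen once from the qualitative
description of the intended dynamics and not revisited: treatment
initiation from S0 is common early (intercepts around -1.1 to -1.4 with
mildly negative time slopes, so most subjects start a drug within the
first four windows), repeat doses of the current drug are frequent
(intercepts -0.7 in S1, -0.4 in S2), and mortality rises with treatment
line (-4.66, -3.6, -2.8 for S0/S1/S2). `model_onset_late()` makes
treatment initiation rare but increasing over a long follow-up
(`tau = 50`) with sharply different mortality for treated and untreated;
`model_onset_early()` compresses everything into `tau = 10` with frequent
early repeat treatment and steeply increasing mortality. The late-onset
model's design follow-up is fixed at `tau = 50`.

Two readings of the scenario randomization are possible: one blackout
draw (and one pattern draw) per subject applied to all blackout times, or
independent redraws per subject-time. The per-subject reading is the
default — a register outage affects all its times for a given subject —
and the per-time variant is available via `per_subject = FALSE`.
Time-dependent coefficients use calendar time `t`; time since state entry
can be expressed with a `term_covariate()` if needed.

### What the generator does and does not emulate

The simulator reproduces the structure the estimators rely on: feedback of
the event history on hazards, monotone risk sets, independent
non-informative coarsening, register-style blackout windows, and
administrative censoring. It does *not* include measured covariates,
unobserved heterogeneity (frailty), coarsening that depends on the
latent path, left-censoring, or time-discretization error from an
underlying continuous process. Passing tests therefore demonstrate
correctness of the estimators under the stated assumptions — not
robustness to their violation; in particular, when coarsening depends on
the outcome process, even EarlyCensor and DirectML lose their
justification.

## Performance measures and problem sizes

`run_study()` repeats simulate → fit-before-coarsening → coarsen →
fit-after-coarsening, with per-repetition seeds fixed up front, and
aggregates bias, empirical SE and coverage with Monte Carlo standard
errors (`mcse_bias = empse / sqrt(nsim)`,
`mcse_empse = empse / sqrt(2 (nsim - 1))`,
`mcse_coverage = sqrt(cov (1 - cov) / nsim)`). Coverage counts closed
intervals; non-convergent repetitions are excluded and reported, never
resampled. The test suite exercises the full designs at desk scale — for
example the recovery/coverage study uses `tau = 6`, `N = 5,000`,
`nsim = 200`, and the structural-bias comparisons use `N = 2,000` with
`nsim = 20-60` — sizes chosen so the whole suite runs comfortably on a
laptop while keeping every Monte Carlo check at 3-sigma strength.

## Known limitations

* Likelihood ridges: when an (event, state) pair is essentially unobserved
  in a small sample, its intercept/slope pair is unidentified and Newton
  stops somewhere along a flat ridge with a singular-information flag;
  estimates of other coordinates are unaffected but the flagged CIs are
  meaningless.
* DirectML's cost is exponential in the number of ambiguous times per
  subject; the `max_paths` guard makes this explicit. MCEM is the intended
  fallback, at the price of Monte Carlo noise and a slight residual bias
  at small `m`.
* The coarsening law itself (`psi`) is never estimated — it is ignorable
  by assumption, and scenario generators realize it implicitly.
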