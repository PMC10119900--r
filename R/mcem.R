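#' Support matrix of the latent path posterior
#'
#' `J[j+1, t] = 1` iff some latent path compatible with the observed record
#' has event `j` at time `t`. For the restricted model class -- monotone
#' (kill-set) at-risk dynamics and coarsening that only merges non-absorbing
#' events with the reference event -- a fast rule applies: `j` is feasible
#' at `t` iff it lies in the group observed to contain the event at `t`, is
#' at risk given the unambiguously observed events before `t`, and no event
#' observed unambiguously after `t` is killed by `j`. Outside the
#' restricted class the fast rule is unavailable and the marginal support is
#' computed from the full compatible-path enumeration (`method = "oracle"`);
#' within it the two agree.
#'
#' @param record one element of `observed_records$records`.
#' @param model an [mstate_model()].
#' @param method `"fast"` (restricted class, default) or `"oracle"`.
#' @param max_paths cap for the oracle enumeration.
#' @return binary matrix `(1+n) x tobs`.
#' @export
support_matrix <- function(record, model, method = c("fast", "oracle"),
                           max_paths = 1e5) {
  method <- match.arg(method)
  tobs <- record$tobs
  J <- matrix(0L, model$n + 1L, tobs, dimnames = list(model$events, NULL))
  if (tobs == 0L) return(J)
  if (method == "oracle") {
    paths <- enumerate_compatible(record, model, max_paths)
    for (t in seq_len(tobs)) J[unique(paths[, t]) + 1L, t] <- 1L
    return(J)
  }
  check_restricted(record, model)
  groups <- record_groups(record)
  unamb <- vapply(groups, function(g) if (length(g) == 1L) g else NA_integer_,
                  integer(1))
  K <- kill_lookup(model)
  # mask of unambiguously observed events before t
  mask <- 0L
  future <- vector("list", tobs)
  seen <- integer(0)
  for (t in tobs:1) {
    future[[t]] <- seen
    if (!is.na(unamb[t]) && unamb[t] > 0L) seen <- union(seen, unamb[t])
  }
  for (t in seq_len(tobs)) {
    for (e in groups[[t]]) {
      ok <- TRUE
      if (e > 0L) {
        if (!model$risk_table[mask + 1L, e]) ok <- FALSE
        else if (e %in% model$absorbing_idx && t < tobs) ok <- FALSE
        else if (length(future[[t]]) && any(K[e + 1L, future[[t]]])) ok <- FALSE
      }
      if (ok) J[e + 1L, t] <- 1L
    }
    if (!is.na(unamb[t]) && unamb[t] > 0L)
      mask <- bitwOr(mask, model$event_bit[unamb[t] + 1L])
  }
  J
}

check_restricted <- function(record, model) {
  for (t in seq_len(record$tobs)) {
    occ <- which(record$Yobs[, t] == 1L) - 1L
    if (length(occ) > 1L) {
      if (!0L %in% occ || any(occ %in% model$absorbing_idx))
        stop("record outside the restricted class (ambiguous group must ",
             "contain the reference event and no absorbing event); ",
             "use method = \"oracle\"")
    }
  }
  invisible(TRUE)
}

## compact per-record view used by the samplers
compact_record <- function(record) {
  groups <- record_groups(record)
  obs <- vapply(groups, function(g) if (length(g) == 1L) g else NA_integer_,
                integer(1))
  list(tobs = record$tobs, obs = obs, groups = groups,
       ambiguous = anyNA(obs))
}

#' Sample a latent path from the importance-sampling proposal
#'
#' Sequential proposal over `t = 1, ..., D - Delta`: at each time the
#' current history determines the hazard vector `P_t`; the proposal column
#' is `Q_t = (J_t * P_t) / (J_t' P_t)`. At unambiguous times the observed
#' event is kept (`Q_t` is a unit vector there); at ambiguous times the
#' event is drawn from `Q_t`. The raw importance weight is
#' `w = p(y) / q(y)` with `p(y) = prod_t P_t' y_t` and
#' `q(y) = prod_t Q_t' y_t`. In the restricted class every sampled path is
#' compatible with the record, so `w > 0` always.
#'
#' @param model an [mstate_model()].
#' @param theta parameter vector.
#' @param record one element of `observed_records$records`.
#' @param J support matrix from [support_matrix()].
#' @param seed optional integer seed.
#' @return list with `events` (the sampled path), `logw` (log raw weight),
#'   `logp` and `logq`.
#' @export
propose_path <- function(model, theta, record, J, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  theta <- as_theta(model, theta)
  cells <- compile_cells(model, record$tobs)
  haz <- cell_hazards(model, cells, theta, want_ex = FALSE)
  propose_path_(model, cells, haz, compact_record(record), J)
}

propose_path_ <- function(model, cells, haz, cr, J) {
  tobs <- cr$tobs
  ev <- integer(tobs)
  logp <- 0; logq <- 0
  ctx <- model$ctx_init_idx; mask <- 0L
  for (t in seq_len(tobs)) {
    cid <- cell_id(cells, t, ctx, mask)
    a <- haz$alpha[cid, ]
    if (is.na(cr$obs[t])) {
      cand <- cr$groups[[t]][J[cr$groups[[t]] + 1L, t] == 1L]
      pc <- a[cand + 1L]
      s <- sum(pc)
      if (s <= 0) stop("degenerate proposal (J'P = 0) at t = ", t)
      e <- cand[findInterval(stats::runif(1), cumsum(pc / s)) + 1L]
      logq <- logq + log(a[e + 1L] / s)
    } else {
      e <- cr$obs[t]
    }
    if (a[e + 1L] <= 0)
      stop("sampled/observed event has zero probability at t = ", t)
    logp <- logp + log(a[e + 1L])
    ev[t] <- e
    if (e > 0L) {
      mask <- bitwOr(mask, model$event_bit[e + 1L])
      ctx <- model$trans_idx[ctx, e + 1L]
    }
  }
  list(events = ev, logw = logp - logq, logp = logp, logq = logq)
}

#' Control settings for the Monte Carlo EM fitter
#'
#' The sample-size schedule follows `m_r = min(10 + 5 (r - 1), m_max)` over
#' `iterations` EM iterations; `m_max = 25` is the default, with 40
#' recommended for long follow-up with many coarsened times. `var_m` sets
#' the size of the final importance sample used for the Louis-type observed
#' information.
#'
#' @param m_max cap on Monte Carlo samples per subject and iteration.
#' @param iterations number of EM iterations (fixed, no stopping rule).
#' @param seed integer seed for the sampler.
#' @param var_m sample size for the final variance estimate.
#' @param tol,maxit Newton settings for the inner M-step.
#' @return list of class `mcem_control`.
#' @export
mcem_control <- function(m_max = 25L, iterations = 10L, seed = 1L,
                         var_m = m_max, tol = 1e-8, maxit = 200L) {
  stopifnot(iterations >= 1, m_max >= 1)
  structure(list(m_max = as.integer(m_max), iterations = as.integer(iterations),
                 seed = as.integer(seed), var_m = as.integer(var_m),
                 tol = tol, maxit = maxit), class = "mcem_control")
}

#' Monte Carlo EM with importance sampling
#'
#' Implements the MCEM loop: initialize at the EarlyCensor estimate; at
#' iteration `r` draw `m_r = min(10 + 5 (r - 1), m_max)` importance samples
#' per subject with coarsened data at the current parameter, form the
#' importance-sampling approximation of the EM surrogate
#' `Q(theta | theta_{r-1})` (a weighted latent log-likelihood, i.e. a
#' weighted multinomial-logit objective), maximize it by Newton's method,
#' and update the running estimate by the cumulative
#' sample-size-weighted average
#' `theta_r = (m_r theta_hat_r + sum_{j<r} m_j theta_hat_j) / sum_{j<=r} m_j`
#' (iteration 1 initializes the average). Subjects without any ambiguous
#' time contribute their exact latent log-likelihood instead of samples.
#' Fresh samples are drawn every iteration; per-subject seeds are derived
#' from `(seed, iteration, subject)` so results do not depend on sample
#' size or processing order.
#'
#' The covariance is a Louis-type observed information evaluated at the
#' final estimate from a fresh importance sample of size `var_m` per
#' coarsened subject: the self-normalized weighted mixture identity
#' `sum w (H_c + s_c s_c') - (sum w s_c)(sum w s_c)'`, negated and combined
#' with the exact information of the fully observed subjects.
#'
#' @param records an `observed_records` object.
#' @param model an [mstate_model()].
#' @param control an [mcem_control()].
#' @param init optional initial value; default is the EarlyCensor fit.
#' @return an `msm_fit` with a per-iteration `trace` data frame
#'   (`iteration`, `m_r`, surrogate value, per-parameter `theta_hat` and
#'   running average).
#' @export
mcem_fit <- function(records, model, control = mcem_control(), init = NULL) {
  stopifnot(inherits(records, "observed_records"))
  if (is.null(init)) {
    ec <- fit_earlycensor(records, model)
    init <- ec$theta
  } else init <- as_theta(model, init)

  cells <- compile_cells(model, records$tau)
  crs <- lapply(records$records, compact_record)
  amb <- which(vapply(crs, `[[`, logical(1), "ambiguous"))
  Js <- lapply(amb, function(i) support_matrix(records$records[[i]], model))

  # exact contribution of fully observed subjects
  n <- model$n
  C_exact <- matrix(0, cells$n_cells, n + 1L)
  unamb <- setdiff(seq_along(crs), amb)
  if (length(unamb)) {
    lens <- vapply(crs[unamb], `[[`, integer(1), "tobs")
    evm <- matrix(NA_integer_, length(unamb), records$tau)
    for (k in seq_along(unamb))
      if (lens[k] > 0) evm[k, seq_len(lens[k])] <- crs[[unamb[k]]]$obs
    C_exact <- tabulate_counts(model, cells, evm, lens)
  }

  theta_prev <- init
  m_hist <- numeric(0)
  that_hist <- NULL
  trace <- NULL
  theta_avg <- init
  for (r in seq_len(control$iterations)) {
    m_r <- min(10L + 5L * (r - 1L), control$m_max)
    C <- C_exact
    if (length(amb)) {
      haz <- cell_hazards(model, cells, theta_prev, want_ex = FALSE)
      sampled <- sample_weighted_counts(model, cells, haz, crs[amb], Js,
                                        m_r, control$seed, r, amb)
      C <- C + sampled
    }
    fn <- function(theta) mnl_objective(model, cells, theta, C)
    res <- newton_max(fn, theta_prev, tol = control$tol, maxit = control$maxit)
    that <- res$theta
    m_hist <- c(m_hist, m_r)
    that_hist <- rbind(that_hist, that)
    theta_avg <- drop(crossprod(that_hist, m_hist)) / sum(m_hist)
    trace <- rbind(trace, data.frame(iteration = r, m_r = m_r,
                                     surrogate = res$loglik,
                                     converged = res$converged,
                                     t(stats::setNames(that, paste0("hat.", model$par_names))),
                                     t(stats::setNames(theta_avg, paste0("avg.", model$par_names)))))
    theta_prev <- theta_avg
  }

  # Louis-type observed information at the final estimate
  info <- louis_information(model, cells, records, crs, amb, Js, C_exact,
                            theta_avg, control)
  vc <- invert_information(info$information)
  msm_fit_result("MCEM", model, theta_avg, vc$vcov, info$loglik_exact,
                 all(trace$converged) && vc$ok,
                 control$iterations, notes = vc$notes,
                 extra = list(trace = trace))
}

#' @rdname fit_full_mle
#' @param control an [mcem_control()].
#' @export
fit_mcem <- function(records, model, control = mcem_control(), init = NULL)
  mcem_fit(records, model, control, init)

## draw m samples per ambiguous subject and return the weighted count
## matrix over cells x events (weights self-normalized per subject)
sample_weighted_counts <- function(model, cells, haz, crs, Js, m, seed, r,
                                   subject_ids) {
  n_cells <- cells$n_cells
  idx_all <- integer(0); wt_all <- numeric(0)
  for (k in seq_along(crs)) {
    cr <- crs[[k]]; J <- Js[[k]]
    set.seed(subject_seed(seed, r, subject_ids[k]))
    logw <- numeric(m)
    idx <- vector("list", m)
    for (s in seq_len(m)) {
      smp <- propose_path_(model, cells, haz, cr, J)
      logw[s] <- smp$logw
      cid <- path_cells(model, cells, smp$events, cr$tobs)
      idx[[s]] <- smp$events * n_cells + cid
    }
    w <- exp(logw - logsumexp(logw))             # normalized weights
    idx_all <- c(idx_all, unlist(idx))
    wt_all <- c(wt_all, rep(w, each = cr$tobs))
  }
  counts <- numeric(n_cells * (model$n + 1L))
  if (length(idx_all)) {
    agg <- rowsum(wt_all, idx_all)
    counts[as.integer(rownames(agg))] <- agg
  }
  matrix(counts, n_cells, model$n + 1L)
}

subject_seed <- function(seed, r, i)
  as.integer((as.double(seed) * 48271 + r * 1299721 + i * 7919) %% 2147483629)

louis_information <- function(model, cells, records, crs, amb, Js, C_exact,
                              theta, control) {
  haz <- cell_hazards(model, cells, theta)
  ex <- mnl_objective(model, cells, theta, C_exact, haz)
  info <- -ex$hess
  if (length(amb)) {
    n_cells <- cells$n_cells
    sc <- list(); se <- list(); sp <- list(); wts <- numeric(0)
    n_paths <- 0L; path_rec <- integer(0)
    m <- control$var_m
    for (k in seq_along(amb)) {
      cr <- crs[[amb[k]]]
      set.seed(subject_seed(control$seed, control$iterations + 1L, amb[k]))
      logw <- numeric(m)
      for (s in seq_len(m)) {
        smp <- propose_path_(model, cells, haz, cr, Js[[k]])
        logw[s] <- smp$logw
        cid <- path_cells(model, cells, smp$events, cr$tobs)
        sc[[n_paths + s]] <- cid
        se[[n_paths + s]] <- smp$events
        sp[[n_paths + s]] <- rep(n_paths + s, cr$tobs)
      }
      wts <- c(wts, exp(logw - logsumexp(logw)))
      path_rec <- c(path_rec, rep(k, m))
      n_paths <- n_paths + m
    }
    fl <- list(step_cell = unlist(sc), step_event = unlist(se),
               step_path = unlist(sp), path_rec = path_rec,
               n_paths = n_paths, n_recs = length(amb),
               w_rec = rep(1, length(amb)))
    ob <- mixture_objective(model, cells, fl, theta, haz = haz,
                            fixed_w = wts)
    info <- info + (-ob$hess)
  }
  list(information = info, loglik_exact = ex$loglik)
}
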