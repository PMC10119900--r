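# Shared fixtures and independent brute-force oracles.
#
# The oracles deliberately avoid the package's enumeration, support and
# mixture machinery: they work by exhausting all event sequences and
# scoring each with latent_loglik (itself pinned by hand-computed values),
# so they can arbitrate enumerate_compatible, ignorable_loglik,
# support_matrix and score_info.

# small model without kill interactions: events 0..n_na non-absorbing plus
# optionally one absorbing, one context, intercept + time per event
toy_model <- function(n_na = 2, absorbing = FALSE) {
  ev <- c("E0", paste0("E", seq_len(n_na)), if (absorbing) "X")
  trans <- matrix("S", 1, length(ev), dimnames = list("S", ev))
  feas <- data.frame(event = setdiff(ev, "E0"), context = "S")
  mstate_model(ev, absorbing = if (absorbing) "X" else character(0),
               kill_sets = list(), contexts = "S", ctx_init = "S",
               ctx_trans = trans, terms = state_time_terms(feas))
}

rand_theta <- function(model, sd = 0.6) {
  stats::setNames(stats::rnorm(model$p, 0, sd), model$par_names)
}

# all complete latent paths of length tau (absorption truncates), with their
# latent log-likelihoods; recursion over raw event codes, no package
# enumeration involved
oracle_paths <- function(model, tau) {
  out <- list()
  rec <- function(prefix) {
    t <- length(prefix)
    if (t == tau || (t > 0 && prefix[t] %in% model$absorbing_idx)) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible())
    }
    for (e in 0:model$n) rec(c(prefix, e))
  }
  rec(integer(0))
  out
}

oracle_total_prob <- function(model, theta, tau) {
  sum(vapply(oracle_paths(model, tau),
             function(ev) exp(latent_loglik(model, theta, ev)), numeric(1)))
}

# latent_paths object from hand-written event sequences (list of integer
# vectors, absorbing event terminating each)
manual_paths <- function(model, seqs, tau) {
  N <- length(seqs)
  evm <- matrix(NA_integer_, N, tau)
  T1 <- rep.int(tau + 1L, N)
  for (i in seq_len(N)) {
    s <- seqs[[i]]
    evm[i, seq_along(s)] <- s
    hit <- which(s %in% model$absorbing_idx)
    if (length(hit)) T1[i] <- min(hit)
  }
  structure(list(events = evm, T1 = T1, tau = tau, model = model),
            class = "latent_paths")
}

# does a full latent path coarsen to the given record under schedule V?
oracle_compatible <- function(model, ev_full, T1, V, record) {
  cand <- coarsemsm:::coarsen_one(model, ev_full, T1, V, ncol(V))
  identical(cand$Yobs, record$Yobs) && cand$D == record$D &&
    cand$Delta == record$Delta
}

# brute-force ignorable likelihood: sum of path probabilities over all
# complete latent paths that coarsen to the record under its schedule
oracle_ignorable <- function(model, theta, record, V, tau) {
  tot <- 0
  for (ev in oracle_paths(model, tau)) {
    T1 <- {
      hit <- which(ev %in% model$absorbing_idx)
      if (length(hit)) min(hit) else tau + 1L
    }
    if (oracle_compatible(model, c(ev, rep(NA_integer_, tau - length(ev))),
                          T1, V, record))
      tot <- tot + exp(latent_loglik(model, theta, ev))
  }
  log(tot)
}

# brute-force compatible paths (as a set of event-code strings)
oracle_compatible_set <- function(model, record, V, tau) {
  keep <- character(0)
  for (ev in oracle_paths(model, tau)) {
    T1 <- {
      hit <- which(ev %in% model$absorbing_idx)
      if (length(hit)) min(hit) else tau + 1L
    }
    if (is.finite(latent_loglik(model, rep(0, model$p), ev)) &&
        oracle_compatible(model, c(ev, rep(NA_integer_, tau - length(ev))),
                          T1, V, record))
      keep <- c(keep, paste(ev[seq_len(record$tobs)], collapse = "."))
  }
  sort(unique(keep))
}

# numeric derivatives of the summed ignorable log-likelihood
fd_score <- function(model, theta, records, h = 1e-5) {
  f <- function(th) sum(vapply(records$records, function(r)
    ignorable_loglik(model, th, r), numeric(1)))
  vapply(seq_along(theta), function(k) {
    e <- replace(numeric(length(theta)), k, h)
    (f(theta + e) - f(theta - e)) / (2 * h)
  }, numeric(1))
}

fd_hessian <- function(model, theta, records, h = 1e-4) {
  g <- function(th) fd_score(model, th, records, h = 1e-5)
  p <- length(theta)
  H <- matrix(0, p, p)
  for (k in seq_len(p)) {
    e <- replace(numeric(p), k, h)
    H[, k] <- (g(theta + e) - g(theta - e)) / (2 * h)
  }
  (H + t(H)) / 2
}

# random restricted coarsening schedule: merges a random subset of
# non-absorbing events with the reference at random times
rand_restricted_schedule <- function(model, tau) {
  V <- identity_schedule(model, tau)
  nna <- model$n_na
  for (t in seq_len(tau)) {
    if (stats::runif(1) < 0.5 && nna >= 1) {
      grp <- sample(seq_len(nna), sample.int(nna, 1))
      V[c(1L, grp + 1L), t] <- 0L
    }
  }
  V
}
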