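#' Latent log-likelihood of one event path
#'
#' The log of the latent likelihood contribution
#' \deqn{L_{\mathrm{latent}}(\theta) = \prod_{t \le d-\delta} \prod_j
#'   \{\alpha_\theta(j, t \mid h_{t-1}) b_{j,t}\}^{y_{j,t}},}
#' i.e. the sum over observed steps of the log discrete hazard of the event
#' that occurred. A path that selects an event with zero probability (not
#' at risk, or any event after absorption) yields `-Inf` rather than an
#' error.
#'
#' @param model an [mstate_model()].
#' @param theta parameter vector.
#' @param events integer vector of event codes; the path to evaluate.
#' @param upto evaluate the first `upto` steps (default: all); this is
#'   `d - delta` for a censored record.
#' @return scalar log-likelihood.
#' @export
latent_loglik <- function(model, theta, events, upto = length(events)) {
  theta <- as_theta(model, theta)
  stopifnot(upto <= length(events))
  ll <- 0
  hist <- integer(0)
  for (t in seq_len(upto)) {
    e <- events[t]
    b <- at_risk(model, hist)
    if (b[1] == 0 || b[e + 1L] == 0) return(-Inf)   # absorbed or not at risk
    p <- hazard_probs(linear_predictors(model, theta, hist, t), b)
    if (p[e + 1L] <= 0) return(-Inf)
    ll <- ll + log(unname(p[e + 1L]))
    hist <- c(hist, e)
  }
  ll
}

record_groups <- function(record) {
  lapply(seq_len(record$tobs), function(t) which(record$Yobs[, t] == 1L) - 1L)
}

#' Enumerate latent paths compatible with an observed record
#'
#' Depth-first enumeration of every complete latent event sequence of
#' length `D - Delta` that agrees with the observed record: at each time
#' the path's event lies in the group observed to have occurred (the
#' observed event itself when unambiguous) and is at risk given the path's
#' own history. Branches are pruned when the chosen event would remove from
#' the risk set an event observed unambiguously later, or would absorb the
#' subject before the end of observed follow-up. The enumeration is exact,
#' complete and deterministic (events tried in index order).
#'
#' @param record one element of `observed_records$records`.
#' @param model an [mstate_model()].
#' @param max_paths hard cap on the number of compatible paths; exceeding
#'   it raises an error (the count grows exponentially in the number of
#'   ambiguous times).
#' @return integer matrix with one row per compatible path, `D - Delta`
#'   columns.
#' @export
enumerate_compatible <- function(record, model, max_paths = 1e5) {
  tobs <- record$tobs
  if (tobs == 0L) return(matrix(integer(0), 1L, 0L))
  groups <- record_groups(record)
  # events observed unambiguously at times > t, for kill-pruning
  unamb <- vapply(groups, function(g) if (length(g) == 1L) g else NA_integer_,
                  integer(1))
  future <- vector("list", tobs)
  seen <- integer(0)
  for (t in tobs:1) {
    future[[t]] <- seen
    if (!is.na(unamb[t]) && unamb[t] > 0L) seen <- union(seen, unamb[t])
  }
  K <- kill_lookup(model)
  abs_codes <- model$absorbing_idx
  out <- vector("list", 64L); n_out <- 0L
  path <- integer(tobs)
  count_env <- new.env(); count_env$n <- 0L

  rec_dfs <- function(t, ctx, mask) {
    if (t > tobs) {
      count_env$n <- count_env$n + 1L
      if (count_env$n > max_paths)
        stop("more than max_paths = ", max_paths, " compatible paths")
      n_out <<- n_out + 1L
      if (n_out > length(out)) length(out) <<- 2L * length(out)
      out[[n_out]] <<- path[seq_len(tobs)]
      return(invisible())
    }
    for (e in groups[[t]]) {
      if (e > 0L) {
        if (!model$risk_table[mask + 1L, e]) next
        if (e %in% abs_codes && t < tobs) next
        if (length(future[[t]]) && any(K[e + 1L, future[[t]]])) next
      }
      path[t] <<- e
      rec_dfs(t + 1L,
              model$trans_idx[ctx, e + 1L],
              bitwOr(mask, model$event_bit[e + 1L]))
    }
  }
  rec_dfs(1L, model$ctx_init_idx, 0L)
  if (n_out == 0L)
    stop("no compatible path: record is inconsistent with the model")
  do.call(rbind, out[seq_len(n_out)])
}

kill_lookup <- function(model) {
  n <- model$n
  K <- matrix(FALSE, n + 1L, n)
  for (e in names(model$kill_sets))
    K[match(e, model$events),
      match(model$kill_sets[[e]], model$events) - 1L] <- TRUE
  if (model$n_a > 0) K[model$absorbing_idx + 1L, ] <- TRUE
  K
}

#' Ignorable log-likelihood of an observed record
#'
#' The log observed-data likelihood under independent, non-informative
#' coarsening: the log-sum-exp over all compatible latent paths of their
#' latent log-likelihoods. Equals [latent_loglik()] when the record is
#' fully observed.
#'
#' @param model an [mstate_model()].
#' @param theta parameter vector.
#' @param record one element of `observed_records$records`.
#' @param max_paths passed to [enumerate_compatible()].
#' @return scalar log-likelihood.
#' @export
ignorable_loglik <- function(model, theta, record, max_paths = 1e5) {
  paths <- enumerate_compatible(record, model, max_paths)
  if (ncol(paths) == 0L) return(0)
  lls <- apply(paths, 1, function(ev) latent_loglik(model, theta, ev))
  logsumexp(lls)
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

## ---- vectorized engines -------------------------------------------------

## counts over cells x events from complete sequences (rows of ev_mat,
## evaluated up to len[i]); returns n_cells x (n+1) matrix
tabulate_counts <- function(model, cells, ev_mat, len) {
  N <- nrow(ev_mat)
  n <- model$n; n_cells <- cells$n_cells
  counts <- numeric(n_cells * (n + 1L))
  ctx <- rep.int(model$ctx_init_idx, N)
  mask <- integer(N)
  tmax <- if (length(len)) max(len) else 0L
  for (t in seq_len(tmax)) {
    act <- which(len >= t)
    if (!length(act)) break
    e <- ev_mat[act, t]
    if (anyNA(e)) stop("NA event inside observed follow-up")
    cid <- cell_id(cells, t, ctx[act], mask[act])
    counts <- counts + tabulate((e) * n_cells + cid, nbins = n_cells * (n + 1L))
    nz <- e > 0L
    if (any(nz)) {
      inz <- act[nz]
      mask[inz] <- bitwOr(mask[inz], model$event_bit[e[nz] + 1L])
      ctx[inz] <- model$trans_idx[cbind(ctx[inz], e[nz] + 1L)]
    }
  }
  matrix(counts, n_cells, n + 1L)
}

## steps of one path: cell id per time
path_cells <- function(model, cells, ev, len) {
  cid <- integer(len)
  ctx <- model$ctx_init_idx; mask <- 0L
  for (t in seq_len(len)) {
    cid[t] <- cell_id(cells, t, ctx, mask)
    e <- ev[t]
    if (e > 0L) {
      mask <- bitwOr(mask, model$event_bit[e + 1L])
      ctx <- model$trans_idx[ctx, e + 1L]
    }
  }
  cid
}

## Flatten a set of observed records into global step arrays over the
## compatible paths of the distinct records. Used by DirectML and the
## score/information computation.
flatten_records <- function(model, cells, records, max_paths = 1e5) {
  keys <- vapply(records$records, function(r)
    paste(r$D, r$Delta,
          paste(apply(r$Yobs[, seq_len(r$tobs), drop = FALSE], 2,
                      function(col) paste(which(col == 1L) - 1L, collapse = ".")),
                collapse = "|"), sep = ";"), character(1))
  ug <- match(keys, unique(keys))
  w_rec <- as.numeric(tabulate(ug, nbins = max(ug)))
  first <- match(seq_len(max(ug)), ug)

  sc <- list(); se <- list(); sp <- list(); pr <- list()
  n_paths <- 0L
  for (k in seq_along(first)) {
    r <- records$records[[first[k]]]
    paths <- enumerate_compatible(r, model, max_paths)
    np <- nrow(paths); tb <- ncol(paths)
    if (tb == 0L) { pr[[k]] <- n_paths + 1L; n_paths <- n_paths + 1L
                    sc[[k]] <- integer(0); se[[k]] <- integer(0)
                    sp[[k]] <- integer(0); next }
    cids <- t(apply(paths, 1, path_cells, model = model, cells = cells, len = tb))
    if (np == 1L) cids <- matrix(cids, 1L)
    sc[[k]] <- as.integer(t(cids))
    se[[k]] <- as.integer(t(paths))
    sp[[k]] <- rep(n_paths + seq_len(np), each = tb)
    pr[[k]] <- n_paths + seq_len(np)
    n_paths <- n_paths + np
  }
  path_rec <- integer(n_paths)
  for (k in seq_along(pr)) path_rec[pr[[k]]] <- k
  list(step_cell = unlist(sc), step_event = unlist(se),
       step_path = unlist(sp), path_rec = path_rec,
       n_paths = n_paths, n_recs = length(first), w_rec = w_rec)
}

## log-likelihood, score and Hessian of the total ignorable log-likelihood
## from flattened records, via exact finite-mixture identities:
##   grad_rec  = sum_c pi_c s_c
##   hess_rec  = sum_c pi_c (H_c + s_c s_c') - grad_rec grad_rec'
## with pi_c the posterior path weights at theta.
mixture_objective <- function(model, cells, fl, theta, haz = NULL,
                              fixed_w = NULL) {
  if (is.null(haz)) haz <- cell_hazards(model, cells, theta)
  n <- cells$n; n_cells <- cells$n_cells; p <- cells$p
  step_ll <- haz$logalpha[cbind(fl$step_cell, fl$step_event + 1L)]
  path_ll <- numeric(fl$n_paths)
  agg <- rowsum(step_ll, fl$step_path)
  path_ll[as.integer(rownames(agg))] <- agg

  if (is.null(fixed_w)) {
    Mrec <- vapply(split(path_ll, fl$path_rec), max, numeric(1))
    Mrec <- Mrec[as.character(seq_len(fl$n_recs))]
    ex <- exp(path_ll - Mrec[fl$path_rec])
    Srec <- drop(rowsum(ex, fl$path_rec))
    ll_rec <- Mrec + log(Srec)
    pi_path <- ex / Srec[fl$path_rec]
  } else {
    # externally supplied normalized per-path weights (importance sampling)
    pi_path <- fixed_w
    ll_rec <- drop(rowsum(pi_path * path_ll, fl$path_rec))
  }
  ll <- sum(fl$w_rec * ll_rec)
  pw <- pi_path * fl$w_rec[fl$path_rec]

  # per-step score contributions
  S <- -haz$Ex[fl$step_cell, , drop = FALSE]
  pos <- fl$step_event > 0L
  if (any(pos)) {
    xrow <- (fl$step_event[pos] - 1L) * n_cells + fl$step_cell[pos]
    S[pos, ] <- S[pos, , drop = FALSE] + cells$Xflat[xrow, , drop = FALSE]
  }
  G <- matrix(0, fl$n_paths, p)
  agg <- rowsum(S, fl$step_path)
  G[as.integer(rownames(agg)), ] <- agg
  grad <- drop(crossprod(G, pw))

  # sum_rec w sum_c pi_c H_c: depends on cells only through weighted counts
  cellw <- drop(rowsum(pw[fl$step_path], fl$step_cell))
  cw <- numeric(n_cells)
  cw[as.integer(names(cellw))] <- cellw
  H1 <- matrix(0, p, p)
  for (j in seq_len(n)) {
    rows <- (j - 1L) * n_cells + seq_len(n_cells)
    Xj <- cells$Xflat[rows, , drop = FALSE]
    H1 <- H1 + crossprod(Xj, (cw * haz$alpha[, j + 1L]) * Xj)
  }
  H1 <- -(H1 - crossprod(haz$Ex, cw * haz$Ex))

  H2 <- crossprod(sqrt(pw) * G)                    # sum w pi g g'
  Gbar <- rowsum(pi_path * G, fl$path_rec)
  H3 <- crossprod(sqrt(fl$w_rec) * Gbar)           # sum w gbar gbar'
  hess <- H1 + H2 - H3
  list(loglik = ll, grad = grad, hess = hess, ll_rec = ll_rec,
       pi_path = pi_path)
}

#' Score and observed information of the ignorable log-likelihood
#'
#' Computes the gradient and the observed information (negative Hessian)
#' of the summed ignorable log-likelihood over a set of observed records,
#' through exact finite-mixture identities over the compatible path sets:
#' the score is the posterior-weighted average of per-path scores, and the
#' Hessian combines posterior-weighted per-path Hessians with the
#' between-path score covariance. No approximation is involved.
#'
#' @param model an [mstate_model()].
#' @param theta parameter vector.
#' @param records an `observed_records` object.
#' @param max_paths per-subject compatible-path cap.
#' @return list with `loglik`, `score` (length p) and `information`
#'   (p x p observed information).
#' @export
score_info <- function(model, theta, records, max_paths = 1e5) {
  theta <- as_theta(model, theta)
  cells <- compile_cells(model, records$tau)
  fl <- flatten_records(model, cells, records, max_paths)
  ob <- mixture_objective(model, cells, fl, theta)
  if (any(!is.finite(ob$grad)) || any(!is.finite(ob$hess)))
    stop("non-finite score/information")
  list(loglik = ob$loglik, score = stats::setNames(ob$grad, model$par_names),
       information = -ob$hess)
}

## ---- Newton maximizer ---------------------------------------------------
## fn(theta) -> list(loglik, grad, hess); maximizes with damped Newton steps
## and step-halving; hess is of the log-likelihood (negative definite near
## the optimum).
newton_max <- function(fn, init, tol = 1e-8, maxit = 200L) {
  theta <- init
  ob <- fn(theta)
  if (!is.finite(ob$loglik)) stop("objective not finite at the initial value")
  converged <- FALSE
  iter <- 0L
  while (iter < maxit) {
    iter <- iter + 1L
    if (max(abs(ob$grad)) < tol) { converged <- TRUE; break }
    A <- -ob$hess
    lambda <- 0
    repeat {
      dir <- tryCatch(solve(A + lambda * diag(nrow(A)), ob$grad),
                      error = function(e) NULL)
      if (!is.null(dir) && sum(dir * ob$grad) > 0) break
      lambda <- if (lambda == 0) 1e-6 * (1 + max(abs(diag(A)))) else 10 * lambda
      if (lambda > 1e12) { dir <- ob$grad; break }   # gradient fallback
    }
    step <- 1
    repeat {
      cand <- theta + step * dir
      obc <- fn(cand)
      if (is.finite(obc$loglik) && obc$loglik >= ob$loglik - 1e-12) break
      step <- step / 2
      if (step < 1e-10) { obc <- ob; cand <- theta; break }
    }
    if (identical(cand, theta) && max(abs(ob$grad)) >= tol) break
    theta <- cand; ob <- obc
  }
  if (max(abs(ob$grad)) < tol) converged <- TRUE
  list(theta = theta, loglik = ob$loglik, grad = ob$grad, hess = ob$hess,
       converged = converged, iterations = iter)
}
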