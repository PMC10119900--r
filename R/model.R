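#' Define a discrete-time multi-state event model
#'
#' Constructs the data-generating model for a discrete-time multivariate
#' event history. Time runs over integer steps `t = 1, ..., tau`. At every
#' step exactly one of the events `0, ..., n` occurs, where event 0 is the
#' reference ("nothing happened", e.g. the subject stayed alive), events
#' `1, ..., n_na` are non-absorbing and the remaining events are absorbing
#' (terminal). After an absorbing event nothing further occurs.
#'
#' The conditional event probabilities (discrete hazards) follow a
#' baseline-category multinomial logit model: each non-reference event `j`
#' that is at risk at time `t` has a linear predictor `eta_j(t)` and
#' \deqn{\Pr(Y_{j,t}=1 \mid \mathrm{past}) =
#'   \frac{b_{j,t} e^{\eta_{j,t}}}{1 + \sum_k b_{k,t} e^{\eta_{k,t}}},}
#' with event 0 taking the remaining probability mass. The at-risk
#' indicators `b_{j,t}` are driven by *kill sets*: once event `e` has
#' occurred, every event in `kill_sets[[e]]` is permanently removed from
#' the risk set (absorbing events remove all events). Support is therefore
#' monotone: an event that has left the risk set never re-enters it.
#'
#' History enters the linear predictors through a finite *context*: a label
#' (such as a treatment state "S0"/"S1"/"S2") that is updated
#' deterministically after each event via `ctx_trans`. The context, possibly
#' enriched with history indicators (e.g. "S2+hadS1" for subjects who
#' reached S2 via S1), must carry all history information the linear
#' predictors use. Model terms then attach coefficients to
#' (event, context) pairs; see [term_intercept()], [term_time()] and
#' [term_covariate()]. Discrete external or time-fixed covariates can be
#' represented by extending the context label space.
#'
#' @param events character vector of event names; the first element is the
#'   reference event (index 0).
#' @param absorbing character vector naming the absorbing events; these must
#'   be the last elements of `events`.
#' @param kill_sets named list mapping an event name to the event names no
#'   longer at risk once it has occurred. The reference event can never be
#'   killed. Absorbing events implicitly kill everything.
#' @param contexts character vector of context labels.
#' @param ctx_init label of the initial context (before any event).
#' @param ctx_trans character matrix with `length(contexts)` rows and
#'   `length(events)` columns: entry `[s, j]` is the context after event
#'   `j-1` occurs in context `s`. Entries for absorbing events are ignored.
#'   Dimnames, if present, must match `contexts` and `events`.
#' @param terms list of model terms built with [term_intercept()],
#'   [term_time()] or [term_covariate()]. Their order defines the parameter
#'   layout.
#'
#' @return An object of class `mstate_model` with elements `events`, `n`,
#'   `n_na`, `n_a`, `kill_sets`, `contexts`, `ctx_init`, `ctx_trans`,
#'   `terms`, `par_names` (length `p`), and internal lookup tables.
#' @seealso [simulate_paths()], [model_prostate()], [hazard_probs()]
#' @export
mstate_model <- function(events, absorbing, kill_sets = list(),
                         contexts, ctx_init, ctx_trans, terms) {
  stopifnot(is.character(events), length(events) >= 2, !anyDuplicated(events))
  n <- length(events) - 1L
  if (!all(absorbing %in% events) || events[1] %in% absorbing)
    stop("absorbing events must be non-reference members of 'events'")
  n_a <- length(absorbing)
  n_na <- n - n_a
  if (n_a > 0 && !identical(sort(match(absorbing, events)),
                            as.integer((n - n_a + 2):(n + 1))))
    stop("absorbing events must be the last elements of 'events'")

  if (length(kill_sets)) {
    if (is.null(names(kill_sets)) || !all(names(kill_sets) %in% events))
      stop("kill_sets must be named by event")
    bad <- vapply(kill_sets, function(k) events[1] %in% k, logical(1))
    if (any(bad)) stop("the reference event can never be killed")
  }

  stopifnot(is.character(contexts), !anyDuplicated(contexts),
            ctx_init %in% contexts)
  ctx_trans <- as.matrix(ctx_trans)
  if (nrow(ctx_trans) != length(contexts) || ncol(ctx_trans) != n + 1L)
    stop("ctx_trans must be length(contexts) x length(events)")
  if (!all(ctx_trans %in% contexts))
    stop("ctx_trans entries must be context labels")

  if (!length(terms) || !all(vapply(terms, inherits, logical(1), "msm_term")))
    stop("terms must be a non-empty list of model terms")
  par_names <- vapply(terms, `[[`, character(1), "name")
  if (anyDuplicated(par_names)) stop("duplicate parameter names in terms")
  for (tm in terms) {
    if (!tm$event %in% events || tm$event == events[1])
      stop("term '", tm$name, "' refers to unknown or reference event")
    if (!is.null(tm$contexts) && !all(tm$contexts %in% contexts))
      stop("term '", tm$name, "' refers to unknown context")
  }

  # kill matrix: K[e+1, j] TRUE if occurrence of event e removes event j
  # (j = 1..n) from the risk set; absorbing events remove everything.
  K <- matrix(FALSE, n + 1L, n)
  for (e in names(kill_sets))
    K[match(e, events), match(kill_sets[[e]], events) - 1L] <- TRUE
  if (n_a > 0) K[(n - n_a + 2):(n + 1), ] <- TRUE

  # occurred-event bitmask lookup (events 1..n): risk[m+1, j] = at risk of j
  n_mask <- 2L^n
  risk <- matrix(TRUE, n_mask, n)
  for (m in seq_len(n_mask) - 1L) {
    occ <- which(bitwAnd(m, bitwShiftL(1L, 0:(n - 1L))) != 0L)  # events occurred
    if (length(occ)) {
      killed <- apply(K[occ + 1L, , drop = FALSE], 2, any)
      risk[m + 1L, killed] <- FALSE
    }
  }

  trans_idx <- matrix(match(ctx_trans, contexts), nrow(ctx_trans))

  structure(list(
    events = events, n = n, n_na = n_na, n_a = n_a,
    absorbing = absorbing, kill_sets = kill_sets,
    contexts = contexts, ctx_init = ctx_init,
    ctx_init_idx = match(ctx_init, contexts),
    ctx_trans = ctx_trans, trans_idx = trans_idx,
    terms = terms, par_names = par_names, p = length(par_names),
    risk_table = risk, event_bit = c(0L, bitwShiftL(1L, 0:(n - 1L))),
    absorbing_idx = if (n_a > 0) (n - n_a + 1L):n else integer(0)
  ), class = "mstate_model")
}

msm_term <- function(name, event, contexts, value_fun) {
  structure(list(name = name, event = event, contexts = contexts,
                 value_fun = value_fun), class = "msm_term")
}

#' Model terms for the baseline-category hazard model
#'
#' Each term binds one coefficient to an event and a set of contexts, with a
#' covariate value that may depend on the context label and on time.
#' `term_intercept()` contributes 1 whenever the subject's context is in
#' `contexts`, `term_time()` contributes the current time `t`, and
#' `term_covariate()` contributes `value_fun(context, t)` (for history
#' indicators such as "had state S1", encode the indicator in the context
#' label and use an intercept-like term restricted to the enriched labels).
#'
#' @param name coefficient name, conventionally `"event:context:covariate"`.
#' @param event event name the linear predictor belongs to.
#' @param contexts context labels in which the term is active; `NULL` means
#'   all contexts.
#' @param value_fun function `(context, t) -> numeric` giving the covariate
#'   value.
#' @return An object of class `msm_term`.
#' @export
term_intercept <- function(name, event, contexts = NULL)
  msm_term(name, event, contexts, function(ctx, t) 1)

#' @rdname term_intercept
#' @export
term_time <- function(name, event, contexts = NULL)
  msm_term(name, event, contexts, function(ctx, t) t)

#' @rdname term_intercept
#' @export
term_covariate <- function(name, event, contexts = NULL, value_fun)
  msm_term(name, event, contexts, value_fun)

#' Build intercept + time terms for a table of feasible (event, context) pairs
#'
#' Convenience builder for the common model family in which every feasible
#' (event, state) combination gets its own intercept and time slope, the form
#' of all coefficients in the bundled data-generating models.
#'
#' @param feasible data frame with columns `event` and `context`; one row per
#'   feasible combination. An optional column `label` overrides the context
#'   part of the coefficient names (several enriched contexts can share one
#'   coefficient by repeating rows with the same `label`).
#' @return list of terms suitable for [mstate_model()].
#' @export
state_time_terms <- function(feasible) {
  stopifnot(all(c("event", "context") %in% names(feasible)))
  lab <- if ("label" %in% names(feasible)) feasible$label else feasible$context
  out <- list()
  for (key in unique(paste(feasible$event, lab, sep = ":"))) {
    rows <- which(paste(feasible$event, lab, sep = ":") == key)
    ev <- feasible$event[rows[1]]
    ctxs <- unique(feasible$context[rows])
    out <- c(out, list(
      term_intercept(paste0(key, ":intercept"), ev, ctxs),
      term_time(paste0(key, ":time"), ev, ctxs)))
  }
  out
}

#' @export
print.mstate_model <- function(x, ...) {
  cat("Discrete-time multi-state model\n")
  cat("  events:", paste0(seq_along(x$events) - 1L, "=", x$events,
                          ifelse(x$events %in% x$absorbing, "*", "")),
      "(* absorbing)\n")
  cat("  contexts:", paste(x$contexts, collapse = ", "), "\n")
  cat("  parameters (p =", x$p, "):",
      paste(utils::head(x$par_names, 6), collapse = ", "),
      if (x$p > 6) "...", "\n")
  invisible(x)
}

#' Validate and name a parameter vector for a model
#'
#' @param model an [mstate_model()].
#' @param theta numeric vector of length `model$p`, optionally named; if
#'   named, entries are matched to the model's parameter layout by name.
#' @return named numeric vector in layout order.
#' @export
as_theta <- function(model, theta) {
  if (length(theta) != model$p)
    stop("theta has length ", length(theta), " but the model has p = ",
         model$p, " parameters")
  if (!is.null(names(theta))) {
    if (!setequal(names(theta), model$par_names))
      stop("theta names do not match the model's parameter layout")
    theta <- theta[model$par_names]
  } else names(theta) <- model$par_names
  theta
}

## ---- compiled cell machinery -------------------------------------------
## A "cell" is a (t, context, occurred-mask) combination. The design row of
## every event, the risk set, and hence the hazard vector depend on the
## history only through the cell, so likelihoods, scores and Hessians for
## whole samples reduce to weighted sums over cells. Cells are enumerated
## eagerly; for the bundled models this is a few thousand entries.

compile_cells <- function(model, tau) {
  n <- model$n; p <- model$p
  n_ctx <- length(model$contexts); n_mask <- nrow(model$risk_table)
  n_cells <- tau * n_ctx * n_mask
  # cell id = ((t-1)*n_ctx + (ctx-1))*n_mask + mask + 1
  tt <- rep(seq_len(tau), each = n_ctx * n_mask)
  cc <- rep(rep(seq_len(n_ctx), each = n_mask), times = tau)
  mm <- rep(seq_len(n_mask) - 1L, times = tau * n_ctx)

  riskmat <- model$risk_table[mm + 1L, , drop = FALSE]  # n_cells x n

  # design: Xflat[(j-1)*n_cells + cell, ] = x_{j}(ctx, t)
  Xflat <- matrix(0, n_cells * n, p)
  ctx_lab <- model$contexts[cc]
  for (k in seq_len(p)) {
    tm <- model$terms[[k]]
    j <- match(tm$event, model$events) - 1L
    act <- if (is.null(tm$contexts)) rep(TRUE, n_cells) else ctx_lab %in% tm$contexts
    if (!any(act)) next
    vals <- mapply(tm$value_fun, ctx_lab[act], tt[act])
    Xflat[(j - 1L) * n_cells + which(act), k] <- vals
  }

  list(tau = tau, n = n, p = p, n_ctx = n_ctx, n_mask = n_mask,
       n_cells = n_cells, t = tt, ctx = cc, mask = mm,
       riskmat = riskmat, Xflat = Xflat)
}

cell_id <- function(cells, t, ctx, mask)
  ((t - 1L) * cells$n_ctx + (ctx - 1L)) * cells$n_mask + mask + 1L

## hazards on all cells for a parameter vector; returns log alpha
## (n_cells x (n+1), column 1 = event 0), alpha, and Ex = E[x | cell]
## (n_cells x p). Log-sum-exp guarded.
cell_hazards <- function(model, cells, theta, want_ex = TRUE) {
  n <- cells$n; n_cells <- cells$n_cells
  eta <- matrix(cells$Xflat %*% theta, n_cells, n)
  eta[!cells$riskmat] <- -Inf
  M <- pmax(0, apply(eta, 1, max))
  M[!is.finite(M)] <- 0
  lse <- M + log(exp(-M) + rowSums(exp(eta - M)))
  logalpha <- cbind(-lse, eta - lse)
  alpha <- exp(logalpha)
  Ex <- NULL
  if (want_ex) {
    Ex <- matrix(0, n_cells, cells$p)
    for (j in seq_len(n)) {
      rows <- (j - 1L) * n_cells + seq_len(n_cells)
      Ex <- Ex + alpha[, j + 1L] * cells$Xflat[rows, , drop = FALSE]
    }
  }
  list(eta = eta, logalpha = logalpha, alpha = alpha, Ex = Ex)
}

## weighted multinomial-logit objective over cells.
## C: counts matrix n_cells x (n+1) (may be fractional). Returns loglik,
## gradient and Hessian of sum_cells sum_j C[cell, j] * log alpha_j(cell).
mnl_objective <- function(model, cells, theta, C, haz = NULL) {
  if (is.null(haz)) haz <- cell_hazards(model, cells, theta)
  n <- cells$n; n_cells <- cells$n_cells
  use <- C != 0
  ll <- sum(C[use] * haz$logalpha[use])
  rowTot <- rowSums(C)
  obsvec <- as.vector(C[, -1, drop = FALSE])       # (j-1)*n_cells + cell order
  grad <- drop(crossprod(cells$Xflat, obsvec)) - drop(crossprod(haz$Ex, rowTot))
  H <- matrix(0, cells$p, cells$p)
  for (j in seq_len(n)) {
    rows <- (j - 1L) * n_cells + seq_len(n_cells)
    Xj <- cells$Xflat[rows, , drop = FALSE]
    H <- H + crossprod(Xj, (rowTot * haz$alpha[, j + 1L]) * Xj)
  }
  H <- H - crossprod(haz$Ex, rowTot * haz$Ex)
  list(loglik = ll, grad = grad, hess = -H)  # hess of the log-likelihood
}
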