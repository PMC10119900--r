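#' History summaries: context, occurred events, at-risk indicators
#'
#' A subject's history up to time `t - 1` is the integer vector of event
#' codes (0..n) observed so far. `history_context()` returns the context
#' label after that history, and `at_risk()` the vector of at-risk
#' indicators `b_t` for events 0..n at the next step: an event is at risk
#' unless some earlier event's kill set removed it or an absorbing event has
#' occurred. The reference event is always at risk before absorption. Since
#' the at-risk vector depends only on events up to `t - 1`, it is known one
#' step ahead.
#'
#' @param model an [mstate_model()].
#' @param history integer vector of past event codes (possibly empty).
#' @return `history_context()`: a context label; `at_risk()`: named 0/1
#'   integer vector of length `n + 1`.
#' @export
history_context <- function(model, history) {
  ci <- model$ctx_init_idx
  for (e in history) ci <- model$trans_idx[ci, e + 1L]
  model$contexts[ci]
}

#' @rdname history_context
#' @export
at_risk <- function(model, history) {
  history <- as.integer(history)
  if (any(history < 0L | history > model$n)) stop("invalid event code in history")
  mask <- 0L
  for (e in history) mask <- bitwOr(mask, model$event_bit[e + 1L])
  absorbed <- length(model$absorbing_idx) > 0 &&
    any(history %in% model$absorbing_idx)
  b <- c(if (absorbed) 0L else 1L,
         if (absorbed) rep(0L, model$n) else as.integer(model$risk_table[mask + 1L, ]))
  names(b) <- model$events
  b
}

#' Linear predictors of the baseline-category hazard model
#'
#' Computes `eta_{j,t}` for the non-reference events `j = 1..n` given the
#' history through `t - 1`; the reference event's predictor is identically
#' zero. Each coefficient contributes `theta_k * value_k(context, t)` to the
#' predictor of its event when the current context activates it.
#'
#' @param model an [mstate_model()].
#' @param theta parameter vector (see [as_theta()]).
#' @param history integer vector of past event codes.
#' @param t current time step (1-based).
#' @return named numeric vector of length `n`.
#' @export
linear_predictors <- function(model, theta, history, t) {
  theta <- as_theta(model, theta)
  ctx <- history_context(model, history)
  eta <- numeric(model$n)
  names(eta) <- model$events[-1]
  for (k in seq_len(model$p)) {
    tm <- model$terms[[k]]
    if (is.null(tm$contexts) || ctx %in% tm$contexts) {
      j <- match(tm$event, model$events) - 1L
      eta[j] <- eta[j] + theta[k] * tm$value_fun(ctx, t)
    }
  }
  eta
}

#' Discrete hazard probabilities
#'
#' Maps linear predictors and at-risk indicators to the conditional event
#' probabilities \eqn{\Pr(Y_{j,t} = 1 \mid \mathrm{past})} for events
#' `0..n`:
#' \deqn{\alpha_j = \frac{b_j e^{\eta_j}}{1 + \sum_k b_k e^{\eta_k}},}
#' with \eqn{\eta_0 = 0}. Events not at risk get probability exactly 0, and
#' the probabilities sum to 1. Evaluated in log space (log-sum-exp) so large
#' predictors cannot overflow.
#'
#' @param eta numeric vector of length `n` of linear predictors for events
#'   `1..n`.
#' @param b at-risk 0/1 vector of length `n + 1` (including event 0, which
#'   must be at risk).
#' @return numeric probability vector of length `n + 1` (events 0..n).
#' @export
hazard_probs <- function(eta, b) {
  n <- length(eta)
  if (length(b) != n + 1L) stop("b must have length length(eta) + 1")
  if (b[1] != 1) stop("invalid state: the reference event is not at risk")
  if (!all(is.finite(eta))) stop("non-finite linear predictor")
  e <- c(0, eta)
  e[b == 0] <- -Inf
  M <- max(0, e)
  p <- exp(e - M) / sum(exp(e - M))
  p[b == 0] <- 0
  p
}

#' @rdname hazard_probs
#' @param model an [mstate_model()].
#' @param theta parameter vector.
#' @param history integer vector of past event codes.
#' @param t current time step.
#' @export
event_probs <- function(model, theta, history, t)
  hazard_probs(linear_predictors(model, theta, history, t),
               at_risk(model, history))
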