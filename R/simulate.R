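#' Simulate latent event-history paths
#'
#' Draws `N` complete latent paths from the model by sequential sampling of
#' the discrete hazards at `t = 1, ..., tau`, updating each subject's
#' context and risk set after every event. Subjects that experience an
#' absorbing event at time `T1` have no events afterwards.
#'
#' The simulation is vectorized over subjects: at each step subjects are
#' grouped by their (context, occurred-events) cell and one uniform draw per
#' subject selects the event from the cell's hazard vector. One uniform is
#' drawn per subject per step in fixed subject order, so with a fixed seed
#' subject `k`'s path does not depend on how many further subjects are
#' simulated.
#'
#' @param model an [mstate_model()].
#' @param theta parameter vector (see [as_theta()]).
#' @param N number of subjects.
#' @param tau end of follow-up (number of time steps).
#' @param seed integer seed; the result is reproducible given `(seed, model,
#'   theta, tau)`.
#' @return An object of class `latent_paths`: list with `events` (`N x tau`
#'   integer matrix of event codes, `NA` after absorption), `T1` (length-`N`
#'   absorption times, `tau + 1` if none), `tau`, and the `model`.
#' @export
simulate_paths <- function(model, theta, N, tau, seed = NULL) {
  stopifnot(N >= 1, tau >= 1)
  theta <- as_theta(model, theta)
  if (!is.null(seed)) set.seed(seed)
  cells <- compile_cells(model, tau)
  haz <- cell_hazards(model, cells, theta, want_ex = FALSE)
  if (any(!is.finite(haz$alpha)))
    stop("non-finite hazard encountered during simulation")

  ev <- matrix(NA_integer_, N, tau)
  T1 <- rep.int(tau + 1L, N)
  ctx <- rep.int(model$ctx_init_idx, N)
  mask <- integer(N)
  alive <- rep.int(TRUE, N)
  abs_codes <- model$absorbing_idx
  # subject-major uniforms: subject k consumes draws (k-1)*tau + 1 .. k*tau,
  # so its path is invariant to the total number of subjects simulated
  U <- matrix(stats::runif(N * tau), N, tau, byrow = TRUE)

  for (t in seq_len(tau)) {
    u <- U[, t]
    idx <- which(alive)
    if (!length(idx)) next
    cid <- cell_id(cells, t, ctx[idx], mask[idx])
    for (c in unique(cid)) {
      sub <- idx[cid == c]
      cp <- cumsum(haz$alpha[c, ])            # events 0..n
      ev[sub, t] <- findInterval(u[sub], cp[seq_len(model$n)])
    }
    e <- ev[idx, t]
    nz <- e > 0L
    if (any(nz)) {
      inz <- idx[nz]
      mask[inz] <- bitwOr(mask[inz], model$event_bit[e[nz] + 1L])
      ctx[inz] <- model$trans_idx[cbind(ctx[inz], e[nz] + 1L)]
      dead <- inz[e[nz] %in% abs_codes]
      if (length(dead)) {
        T1[dead] <- t
        alive[dead] <- FALSE
      }
    }
  }
  structure(list(events = ev, T1 = T1, tau = tau, model = model),
            class = "latent_paths")
}

#' @export
print.latent_paths <- function(x, ...) {
  cat("Latent paths:", nrow(x$events), "subjects,", x$tau, "time steps;",
      sum(x$T1 <= x$tau), "absorbed\n")
  invisible(x)
}

#' Convert latent paths to/from long-format data frames
#'
#' The long format has one row per subject and time step up to
#' `min(T1, tau)` with columns `subject_id`, `t` and `event` (integer code
#' 0..n). [paths_from_df()] is the exact inverse of [as.data.frame()] on a
#' `latent_paths` object.
#'
#' @param x a `latent_paths` object.
#' @param ... unused.
#' @return a `data.frame` in long format.
#' @export
as.data.frame.latent_paths <- function(x, ...) {
  len <- pmin(x$T1, x$tau)
  data.frame(
    subject_id = rep(seq_along(x$T1), len),
    t = sequence(len),
    event = as.integer(t(x$events))[as.vector(t(col(x$events) <= len))]
  )
}

#' @rdname as.data.frame.latent_paths
#' @param df long-format data frame with columns `subject_id`, `t`, `event`.
#' @param model the [mstate_model()] the paths belong to.
#' @param tau end of follow-up.
#' @export
paths_from_df <- function(df, model, tau) {
  stopifnot(all(c("subject_id", "t", "event") %in% names(df)))
  ids <- unique(df$subject_id)
  N <- length(ids)
  ev <- matrix(NA_integer_, N, tau)
  ev[cbind(match(df$subject_id, ids), df$t)] <- as.integer(df$event)
  if (any(df$event < 0 | df$event > model$n))
    stop("event codes outside 0..n")
  T1 <- rep.int(tau + 1L, N)
  for (a in model$absorbing_idx) {
    hit <- which(ev == a, arr.ind = TRUE)
    if (nrow(hit)) {
      agg <- tapply(hit[, 2], hit[, 1], min)
      T1[as.integer(names(agg))] <- pmin(T1[as.integer(names(agg))],
                                         as.integer(agg))
    }
  }
  # absorption must terminate the path, and rows must be contiguous
  len <- pmin(T1, tau)
  if (any(!is.na(ev)[col(ev) > len[row(ev)]]))
    stop("events recorded after absorption")
  if (any(is.na(ev)[col(ev) <= len[row(ev)]]))
    stop("missing (subject, t) rows before absorption/end of follow-up")
  structure(list(events = ev, T1 = T1, tau = tau, model = model),
            class = "latent_paths")
}

#' Read and write latent path CSV files
#'
#' Plain CSV in the long format of [as.data.frame.latent_paths()]. The
#' writer/reader pair round-trips exactly.
#'
#' @param paths a `latent_paths` object.
#' @param file path to a CSV file.
#' @export
write_paths_csv <- function(paths, file) {
  utils::write.csv(as.data.frame(paths), file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname write_paths_csv
#' @param model the [mstate_model()].
#' @param tau end of follow-up.
#' @export
read_paths_csv <- function(file, model, tau) {
  df <- utils::read.csv(file)
  paths_from_df(df, model, tau)
}
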