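#' Coarsening schedules
#'
#' A coarsening schedule for one subject is a `(1+n) x tau` integer matrix
#' `V`: `V[j+1, t]` is the group label of event `j` at time `t`. Events
#' sharing a label at a time are indistinguishable when one of them occurs;
#' the label of a group is the lowest event index in it. Absorbing and
#' non-absorbing events never share a group, except that right censoring at
#' time `t2` is encoded by all-zero columns for every `s >= t2`.
#'
#' `identity_schedule()` leaves every event in its own group (no
#' coarsening). `blackout_schedule()` merges the events in `group` (which
#' must contain the reference event 0 for the restricted model class used by
#' the fast support computation) at the given `times`, emulating a register
#' that does not record those events during a blackout window.
#' `schedule_censor()` adds right censoring at `t2`.
#'
#' @param model an [mstate_model()].
#' @param tau number of time steps.
#' @return integer matrix `(1+n) x tau`.
#' @export
identity_schedule <- function(model, tau) {
  V <- matrix(rep(0:model$n, tau), model$n + 1L, tau)
  rownames(V) <- model$events
  V
}

#' @rdname identity_schedule
#' @param times integer vector of blackout times.
#' @param group integer vector of event codes coarsened together.
#' @export
blackout_schedule <- function(model, tau, times, group) {
  stopifnot(all(times >= 1), all(times <= tau),
            all(group %in% 0:model$n))
  V <- identity_schedule(model, tau)
  V[group + 1L, times] <- min(group)
  V
}

#' @rdname identity_schedule
#' @param V a schedule matrix.
#' @param t2 right-censoring time (all events coarsened to group 0 from
#'   `t2` on).
#' @export
schedule_censor <- function(V, t2) {
  stopifnot(t2 >= 1, t2 <= ncol(V))
  V[, t2:ncol(V)] <- 0L
  V
}

## canonicalize labels (min event index per group, per column) and validate
canonicalize_schedule <- function(model, V) {
  n <- model$n
  if (!is.matrix(V) || nrow(V) != n + 1L) stop("schedule has wrong dimension")
  for (t in seq_len(ncol(V))) {
    col <- V[, t]
    if (all(col == 0L)) next                      # censoring column
    for (g in unique(col)) {
      members <- which(col == g) - 1L
      V[members + 1L, t] <- min(members)
    }
    col <- V[, t]
    if (length(model$absorbing_idx)) {
      for (g in unique(col)) {
        members <- which(col == g) - 1L
        isabs <- members %in% model$absorbing_idx
        if (any(isabs) && !all(isabs))
          stop("absorbing and non-absorbing events share a group at t = ", t)
      }
    }
  }
  # all-zero columns must be terminal (right censoring)
  allzero <- which(colSums(V != 0L) == 0L)
  if (length(allzero) && !identical(allzero, min(allzero):ncol(V)))
    stop("all-zero (censoring) columns must form a terminal block")
  V
}

#' Scenario specifications for study coarsening processes
#'
#' Describes a randomly assigned per-subject coarsening process: during the
#' `blackout_times`, a subject drawn (with probability `subject_prob`) to be
#' coarsened has one of the `patterns` applied; each pattern is a list of
#' event groups merged during the blackout. By default one Bernoulli draw
#' and one pattern draw are made per subject and applied to all blackout
#' times (`per_subject = TRUE`); with `per_subject = FALSE` both are redrawn
#' independently at every blackout time.
#'
#' The three bundled scenarios act on the prostate-treatment model
#' ([model_prostate()]): scenario 1 (`tau = 10`) and scenario 2
#' (`tau = 50`) hide GnRH prescriptions (group \{0, 2\}) with probability
#' 0.5, at times 3--6 and at times 5, 6, 20--29 respectively; scenario 3
#' (`tau = 10`, times 3--6) draws one of four patterns -- \{0, 1\} merged,
#' \{0, 2\} merged, \{0, 1, 2\} merged, or no merging -- each with
#' probability 0.25.
#'
#' @param id scenario id 1, 2 or 3 for the bundled presets.
#' @param tau,blackout_times,patterns,pattern_probs,subject_prob,per_subject
#'   fields for a custom scenario (see Details).
#' @return an object of class `scenario_spec`.
#' @export
scenario_spec <- function(id = NULL, tau = NULL, blackout_times = NULL,
                          patterns = NULL, pattern_probs = NULL,
                          subject_prob = 1, per_subject = TRUE) {
  if (!is.null(id)) {
    return(switch(as.character(id),
      "1" = scenario_spec(tau = 10, blackout_times = 3:6,
                          patterns = list(list(c(0L, 2L))),
                          pattern_probs = 1, subject_prob = 0.5),
      "2" = scenario_spec(tau = 50, blackout_times = c(5:6, 20:29),
                          patterns = list(list(c(0L, 2L))),
                          pattern_probs = 1, subject_prob = 0.5),
      "3" = scenario_spec(tau = 10, blackout_times = 3:6,
                          patterns = list(list(c(0L, 1L)), list(c(0L, 2L)),
                                          list(c(0L, 1L, 2L)), list()),
                          pattern_probs = rep(0.25, 4), subject_prob = 1),
      stop("unknown scenario id: ", id)))
  }
  stopifnot(!is.null(tau), !is.null(blackout_times), !is.null(patterns))
  if (is.null(pattern_probs))
    pattern_probs <- rep(1 / length(patterns), length(patterns))
  stopifnot(length(pattern_probs) == length(patterns),
            abs(sum(pattern_probs) - 1) < 1e-8,
            all(blackout_times >= 1), all(blackout_times <= tau))
  structure(list(tau = tau, blackout_times = sort(unique(blackout_times)),
                 patterns = patterns, pattern_probs = pattern_probs,
                 subject_prob = subject_prob, per_subject = per_subject),
            class = "scenario_spec")
}

#' Generate per-subject coarsening schedules for a scenario
#'
#' @param scenario a [scenario_spec()].
#' @param model an [mstate_model()]; grouped events must be valid for it.
#' @param N number of subjects.
#' @param seed integer seed.
#' @return list of `N` schedule matrices; attribute `"pattern"` holds the
#'   per-subject pattern index (0 = not coarsened) when
#'   `per_subject = TRUE`.
#' @export
make_scenario_schedules <- function(scenario, model, N, seed = NULL) {
  stopifnot(inherits(scenario, "scenario_spec"))
  if (!is.null(seed)) set.seed(seed)
  tau <- scenario$tau
  base <- identity_schedule(model, tau)
  pat_of <- function(k) scenario$patterns[[k]]
  out <- vector("list", N)
  pattern_drawn <- integer(N)
  for (i in seq_len(N)) {
    V <- base
    if (scenario$per_subject) {
      if (stats::runif(1) < scenario$subject_prob) {
        k <- sample.int(length(scenario$patterns), 1,
                        prob = scenario$pattern_probs)
        pattern_drawn[i] <- k
        for (grp in pat_of(k))
          V[grp + 1L, scenario$blackout_times] <- min(grp)
      }
    } else {
      for (t in scenario$blackout_times) {
        if (stats::runif(1) < scenario$subject_prob) {
          k <- sample.int(length(scenario$patterns), 1,
                          prob = scenario$pattern_probs)
          for (grp in pat_of(k)) V[grp + 1L, t] <- min(grp)
        }
      }
    }
    out[[i]] <- V
  }
  attr(out, "pattern") <- pattern_drawn
  out
}

#' Apply a coarsening process to latent paths
#'
#' Produces the observed data from latent paths and per-subject coarsening
#' schedules. For each subject, the observed local response is
#' `Yobs[j, t] = sum_g Y[g, t] * I(V[g, t] = V[j, t])` (1 if an event in
#' event `j`'s group occurred), `T2` is the first time with an all-zero
#' schedule column (`tau + 1` if none), `D = min(T1, T2)`,
#' `Delta = I(D = T2)`, and `C_t = I(D - Delta >= t)` flags the observed
#' follow-up. Entries after the last observed time `D - Delta` are masked
#' (zero).
#'
#' @param paths a `latent_paths` object from [simulate_paths()].
#' @param schedules list of schedule matrices (length `N`), or one matrix
#'   recycled for all subjects.
#' @return An object of class `observed_records`: list with `records` (one
#'   list per subject with `Yobs`, `Vobs`, `D`, `Delta`, `C`, `tobs`),
#'   `model` and `tau`.
#' @export
apply_coarsening <- function(paths, schedules) {
  stopifnot(inherits(paths, "latent_paths"))
  model <- paths$model; tau <- paths$tau
  N <- nrow(paths$events)
  if (is.matrix(schedules)) schedules <- rep(list(schedules), N)
  stopifnot(length(schedules) == N)
  # schedules are usually drawn from a handful of patterns: canonicalize
  # and validate each distinct matrix once
  keys <- vapply(schedules, function(V) paste(V, collapse = ","), character(1))
  uk <- match(keys, unique(keys))
  canon <- lapply(schedules[match(seq_len(max(uk)), uk)], function(V) {
    V <- canonicalize_schedule(model, V)
    if (ncol(V) != tau) stop("schedule has ", ncol(V), " columns, expected ", tau)
    V
  })
  recs <- vector("list", N)
  for (i in seq_len(N))
    recs[[i]] <- coarsen_one(model, paths$events[i, ], paths$T1[i],
                             canon[[uk[i]]], tau)
  structure(list(records = recs, model = model, tau = tau),
            class = "observed_records")
}

coarsen_one <- function(model, ev, T1, V, tau) {
  n <- model$n
  zero_cols <- which(colSums(V != 0L) == 0L)
  T2 <- if (length(zero_cols)) min(zero_cols) else tau + 1L
  D <- as.integer(min(T1, T2))
  Delta <- as.integer(D == T2)
  tobs <- D - Delta
  C <- as.integer(seq_len(tau) <= tobs)
  Yobs <- matrix(0L, n + 1L, tau, dimnames = list(model$events, NULL))
  for (t in seq_len(tobs)) {
    g <- ev[t]
    Yobs[V[, t] == V[g + 1L, t], t] <- 1L
  }
  Vobs <- V * rep(C, each = n + 1L)
  list(Yobs = Yobs, Vobs = Vobs, D = D, Delta = Delta, C = C, tobs = tobs)
}

#' @export
print.observed_records <- function(x, ...) {
  nz <- vapply(x$records, function(r)
    any(colSums(r$Yobs[, seq_len(r$tobs), drop = FALSE]) > 1), logical(1))
  cat("Observed records:", length(x$records), "subjects,", x$tau,
      "time steps;", sum(nz), "with ambiguous times\n")
  invisible(x)
}

#' Recover follow-up summaries from the observables
#'
#' Recomputes `(D, Delta, C)` from `Yobs` and `Vobs` alone: absorption is
#' visible as an absorbing event's group occurring (absorbing events are
#' never grouped with non-absorbing ones), and right censoring as the first
#' all-zero column of `Vobs` not explained by earlier absorption. Used as a
#' consistency check when reading observed data from files.
#'
#' @param Yobs,Vobs observed matrices `(1+n) x tau`.
#' @param model an [mstate_model()].
#' @return list with `D`, `Delta`, `C`.
#' @export
derive_times <- function(Yobs, Vobs, model) {
  tau <- ncol(Yobs)
  abs_rows <- model$absorbing_idx + 1L
  t_abs <- if (length(abs_rows)) {
    hit <- which(colSums(Yobs[abs_rows, , drop = FALSE] == 1L) > 0)
    if (length(hit)) min(hit) else tau + 1L
  } else tau + 1L
  if (t_abs <= tau) {
    D <- t_abs; Delta <- 0L
  } else {
    zero_cols <- which(colSums(Vobs != 0L) == 0L)
    first0 <- if (length(zero_cols)) min(zero_cols) else tau + 1L
    if (first0 <= tau) {
      D <- first0; Delta <- 1L
    } else {
      D <- tau + 1L; Delta <- 1L
    }
  }
  list(D = D, Delta = Delta, C = as.integer(seq_len(tau) <= D - Delta))
}

#' Read and write observed-record CSV files
#'
#' One row per subject and observed time `t <= D - Delta`, with columns
#' `subject_id`, `t`, group labels `v_0 .. v_n` and indicators
#' `yobs_0 .. yobs_n`. The reader canonicalizes group labels, recomputes
#' `(D, Delta, C)` via [derive_times()] and validates the record structure.
#'
#' @param records an `observed_records` object.
#' @param file CSV file path.
#' @export
write_records_csv <- function(records, file) {
  model <- records$model
  n <- model$n
  rows <- lapply(seq_along(records$records), function(i) {
    r <- records$records[[i]]
    if (r$tobs == 0L) return(NULL)
    ts <- seq_len(r$tobs)
    cbind(subject_id = i, t = ts,
          t(r$Vobs[, ts, drop = FALSE]), t(r$Yobs[, ts, drop = FALSE]))
  })
  m <- do.call(rbind, rows)
  colnames(m) <- c("subject_id", "t", paste0("v_", 0:n), paste0("yobs_", 0:n))
  utils::write.csv(as.data.frame(m), file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname write_records_csv
#' @param model an [mstate_model()].
#' @param tau end of follow-up.
#' @export
read_records_csv <- function(file, model, tau) {
  df <- utils::read.csv(file)
  n <- model$n
  need <- c("subject_id", "t", paste0("v_", 0:n), paste0("yobs_", 0:n))
  if (!all(need %in% names(df))) stop("observed CSV is missing columns")
  ids <- unique(df$subject_id)
  recs <- vector("list", length(ids))
  vcols <- paste0("v_", 0:n); ycols <- paste0("yobs_", 0:n)
  for (k in seq_along(ids)) {
    sub <- df[df$subject_id == ids[k], , drop = FALSE]
    sub <- sub[order(sub$t), , drop = FALSE]
    tobs <- nrow(sub)
    if (!identical(as.integer(sub$t), seq_len(tobs)))
      stop("subject ", ids[k], ": times must be contiguous from 1")
    Yobs <- matrix(0L, n + 1L, tau, dimnames = list(model$events, NULL))
    Vraw <- identity_schedule(model, tau)
    Vraw[, seq_len(tobs)] <- t(as.matrix(sub[, vcols]))
    if (tobs < tau) Vraw[, (tobs + 1L):tau] <- 0L
    Vraw <- canonicalize_schedule(model, Vraw)
    Yobs[, seq_len(tobs)] <- t(as.matrix(sub[, ycols]))
    dd <- derive_times(Yobs, Vraw, model)
    if (dd$D - dd$Delta != tobs)
      stop("subject ", ids[k], ": rows after apparent censoring/absorption")
    # occurred group must match the labels
    for (t in seq_len(tobs)) {
      occ <- which(Yobs[, t] == 1L) - 1L
      if (!length(occ)) stop("subject ", ids[k], ": no event indicated at t = ", t)
      lab <- unique(Vraw[occ + 1L, t])
      if (length(lab) != 1L ||
          !setequal(occ, which(Vraw[, t] == lab) - 1L))
        stop("subject ", ids[k], ": yobs does not mark one whole group at t = ", t)
    }
    Vobs <- Vraw * rep(dd$C, each = n + 1L)
    recs[[k]] <- list(Yobs = Yobs, Vobs = Vobs, D = dd$D, Delta = dd$Delta,
                      C = dd$C, tobs = tobs)
  }
  structure(list(records = recs, model = model, tau = tau),
            class = "observed_records")
}
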