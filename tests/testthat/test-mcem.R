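test_that("support matrix: fast rule equals the enumeration oracle", {
  set.seed(404)
  m <- toy_model(n_na = 2, absorbing = TRUE)
  mp <- model_prostate()
  for (rep in 1:40) {
    model <- if (rep %% 2) m else mp
    tau <- sample(2:4, 1)
    paths <- simulate_paths(model, rand_theta(model), 1, tau, seed = 900 + rep)
    V <- rand_restricted_schedule(model, tau)
    rec <- apply_coarsening(paths, V)$records[[1]]
    expect_identical(support_matrix(rec, model, "fast"),
                     support_matrix(rec, model, "oracle"))
  }
})

test_that("support columns are unit vectors at fully observed times", {
  m <- model_prostate()
  p <- manual_paths(m, list(c(1L, 0L, 2L, 0L)), 4)
  V <- blackout_schedule(m, 4, 2L, c(0L, 2L))
  rec <- apply_coarsening(p, V)$records[[1]]
  J <- support_matrix(rec, m)
  expect_equal(unname(J[, 1]), c(0L, 1L, 0L, 0L))
  expect_equal(unname(J[, 3]), c(0L, 0L, 1L, 0L))
  expect_equal(unname(J[, 2]), c(1L, 0L, 1L, 0L))   # ambiguous {0, 2}
})

test_that("support uses information after t: killed events are infeasible", {
  # events {1,2} merged at t = 1, AA observed at t = 2; since AA cannot
  # follow GnRH, GnRH is infeasible at t = 1 (unrestricted grouping, so
  # only the oracle applies)
  m <- model_prostate()
  V <- identity_schedule(m, 2)
  V[2:3, 1] <- 1L
  p <- manual_paths(m, list(c(1L, 1L)), 2)
  rec <- apply_coarsening(p, V)$records[[1]]
  expect_error(support_matrix(rec, m, "fast"), "restricted")
  J <- support_matrix(rec, m, "oracle")
  expect_equal(unname(J[, 1]), c(0L, 1L, 0L, 0L))
})

test_that("proposal with no ambiguity returns the observed path, q = 1", {
  m <- model_prostate()
  th <- true_theta(m)
  p <- manual_paths(m, list(c(0L, 1L, 3L)), 3)
  rec <- apply_coarsening(p, identity_schedule(m, 3))$records[[1]]
  J <- support_matrix(rec, m)
  smp <- propose_path(m, th, rec, J, seed = 1)
  expect_identical(smp$events, c(0L, 1L, 3L))
  expect_equal(smp$logq, 0)
  expect_equal(smp$logw, latent_loglik(m, th, c(0L, 1L, 3L)))
})

test_that("sampled paths are always compatible with positive weight", {
  m <- model_prostate()
  th <- true_theta(m)
  p <- simulate_paths(m, th, 30, 6, seed = 61)
  sch <- make_scenario_schedules(
    scenario_spec(tau = 6, blackout_times = 2:5,
                  patterns = list(list(c(0L, 2L))), subject_prob = 1),
    m, 30, seed = 62)
  recs <- apply_coarsening(p, sch)
  set.seed(9)
  for (i in 1:30) {
    rec <- recs$records[[i]]
    if (rec$tobs == 0) next
    J <- support_matrix(rec, m)
    compat <- apply(enumerate_compatible(rec, m), 1, paste, collapse = ".")
    for (s in 1:20) {
      smp <- propose_path(m, th, rec, J)
      expect_true(paste(smp$events, collapse = ".") %in% compat)
      expect_true(is.finite(smp$logw))
    }
  }
})

test_that("self-normalized IS expectations match the enumeration posterior", {
  # toy record with several compatible paths: the weighted frequency of
  # each path must match its exact posterior probability within 3 MC-SEs
  m <- model_prostate()
  th <- true_theta(m)
  p <- manual_paths(m, list(c(0L, 2L, 0L, 2L)), 4)
  V <- blackout_schedule(m, 4, 2:4, c(0L, 2L))
  rec <- apply_coarsening(p, V)$records[[1]]
  paths <- enumerate_compatible(rec, m)
  lls <- apply(paths, 1, function(ev) latent_loglik(m, th, ev))
  post <- exp(lls - max(lls)); post <- post / sum(post)
  keys <- apply(paths, 1, paste, collapse = ".")

  J <- support_matrix(rec, m)
  mth <- 10000
  set.seed(33)
  draws <- character(mth); logw <- numeric(mth)
  for (s in seq_len(mth)) {
    smp <- propose_path(m, th, rec, J)
    draws[s] <- paste(smp$events, collapse = ".")
    logw[s] <- smp$logw
  }
  w <- exp(logw - max(logw)); w <- w / sum(w)
  for (k in seq_along(keys)) {
    ind <- as.numeric(draws == keys[k])
    est <- sum(w * ind)
    # MC-SE of a self-normalized IS estimate (delta method)
    mcse <- sqrt(sum(w^2 * (ind - est)^2))
    expect_lt(abs(est - post[k]), 3 * mcse + 1e-6)
  }
})

test_that("MCEM is deterministic and matches the full MLE when exact", {
  m <- model_prostate()
  th <- true_theta(m)
  p <- simulate_paths(m, th, 250, 6, seed = 71)
  recs <- apply_coarsening(p, identity_schedule(m, 6))
  mle <- fit_full_mle(p, m)
  mc <- fit_mcem(recs, m, mcem_control(seed = 5))
  # no ambiguity: every iteration maximizes the exact latent likelihood
  expect_equal(mc$theta, mle$theta, tolerance = 1e-6)
  mc2 <- fit_mcem(recs, m, mcem_control(seed = 5))
  expect_identical(mc$theta, mc2$theta)
  expect_equal(mc$trace$m_r, pmin(10 + 5 * (0:9), 25))
})

test_that("exact-E-step EM increases the ignorable log-likelihood", {
  # replacing the importance weights by exact enumeration posteriors turns
  # the loop into plain EM, whose ascent property must hold numerically
  m <- model_prostate()
  th <- true_theta(m)
  p <- simulate_paths(m, th, 150, 5, seed = 81)
  sch <- make_scenario_schedules(
    scenario_spec(tau = 5, blackout_times = 2:4,
                  patterns = list(list(c(0L, 2L))), subject_prob = 0.5),
    m, 150, seed = 82)
  recs <- apply_coarsening(p, sch)
  cells <- coarsemsm:::compile_cells(m, 5)
  fl <- coarsemsm:::flatten_records(m, cells, recs)
  theta <- rep(0, m$p)
  prev <- -Inf
  for (it in 1:30) {
    ob <- coarsemsm:::mixture_objective(m, cells, fl, theta)
    expect_gte(ob$loglik, prev - 1e-10)
    prev <- ob$loglik
    # E-step: exact posterior path weights -> weighted cell counts
    pw <- ob$pi_path * fl$w_rec[fl$path_rec]
    wstep <- pw[fl$step_path]
    idx <- fl$step_event * cells$n_cells + fl$step_cell
    agg <- rowsum(wstep, idx)
    C <- numeric(cells$n_cells * (m$n + 1L))
    C[as.integer(rownames(agg))] <- agg
    C <- matrix(C, cells$n_cells, m$n + 1L)
    # M-step
    theta <- coarsemsm:::newton_max(function(t.)
      coarsemsm:::mnl_objective(m, cells, t., C), theta)$theta
  }
  # EM fixed point is a stationary point of the ignorable likelihood and
  # attains the DirectML optimum value (parameters may differ along flat
  # ridges when an (event, state) pair is rarely observed)
  si <- score_info(m, theta, recs)
  dml <- fit_directml(recs, m)
  expect_lt(max(abs(si$score)), 0.05)
  expect_equal(si$loglik, dml$loglik, tolerance = 1e-6)
})
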