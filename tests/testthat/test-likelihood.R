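test_that("latent log-likelihood matches the stepwise hazards", {
  # tau = 1, n = 3, theta = 0: every event has probability 1/4
  m <- toy_model(n_na = 3)
  expect_equal(latent_loglik(m, rep(0, m$p), 0L), log(1 / 4))
  # exp(latent_loglik) equals the product of hazard entries along the path
  mp <- model_prostate()
  th <- true_theta(mp)
  ev <- c(0L, 1L, 1L, 2L, 0L, 3L)
  prod_haz <- 1
  for (t in seq_along(ev))
    prod_haz <- prod_haz * event_probs(mp, th, ev[seq_len(t - 1L)], t)[ev[t] + 1]
  expect_equal(latent_loglik(mp, th, ev), log(unname(prod_haz)))
  # paths violating the at-risk process get -Inf, not an error
  expect_equal(latent_loglik(mp, th, c(2L, 1L)), -Inf)   # AA after GnRH
  expect_equal(latent_loglik(mp, th, c(3L, 0L)), -Inf)   # event after death
})

test_that("complete path probabilities sum to one", {
  set.seed(7)
  m1 <- toy_model(n_na = 2, absorbing = TRUE)
  m2 <- model_prostate()
  for (rep in 1:5) {
    expect_equal(oracle_total_prob(m1, rand_theta(m1), 3), 1,
                 tolerance = 1e-10)
    expect_equal(oracle_total_prob(m2, rand_theta(m2), 3), 1,
                 tolerance = 1e-10)
  }
})

test_that("compatible-path enumeration is exact on hand-checked cases", {
  m <- model_prostate()
  tau <- 4
  # fully observed record: exactly one path, the record itself
  p <- manual_paths(m, list(c(0L, 1L, 2L, 0L)), tau)
  r <- apply_coarsening(p, identity_schedule(m, tau))$records[[1]]
  expect_identical(enumerate_compatible(r, m),
                   matrix(c(0L, 1L, 2L, 0L), 1))

  # group {0,2} ambiguous at t in {2,3}: GnRH can repeat, so 4 paths
  V <- blackout_schedule(m, tau, 2:3, c(0L, 2L))
  p2 <- manual_paths(m, list(c(0L, 0L, 2L, 0L)), tau)
  r2 <- apply_coarsening(p2, V)$records[[1]]
  paths <- enumerate_compatible(r2, m)
  expect_equal(nrow(paths), 4)
  expect_setequal(apply(paths, 1, paste, collapse = "."),
                  c("0.0.0.0", "0.0.2.0", "0.2.0.0", "0.2.2.0"))

  # the at-risk process can disambiguate: events {1,2} grouped at t = 1,
  # AA observed at t = 2, and AA can never follow GnRH, so the t = 1 event
  # must have been AA
  V3 <- identity_schedule(m, 2)
  V3[2:3, 1] <- 1L
  p3 <- manual_paths(m, list(c(1L, 1L)), 2)
  r3 <- apply_coarsening(p3, V3)$records[[1]]
  expect_identical(enumerate_compatible(r3, m), matrix(c(1L, 1L), 1))

  # max_paths guard fails loudly
  V4 <- blackout_schedule(m, tau, 1:4, c(0L, 2L))
  p4 <- manual_paths(m, list(c(2L, 2L, 2L, 2L)), tau)
  r4 <- apply_coarsening(p4, V4)$records[[1]]
  expect_error(enumerate_compatible(r4, m, max_paths = 3), "max_paths")
})

test_that("enumeration and ignorable likelihood match brute force", {
  # randomized property: small models, random restricted schedules and
  # random paths; the brute-force oracle exhausts all event sequences
  set.seed(202)
  m <- toy_model(n_na = 2, absorbing = TRUE)
  mp <- model_prostate()
  for (rep in 1:30) {
    model <- if (rep %% 2) m else mp
    tau <- sample(2:4, 1)
    th <- rand_theta(model)
    paths <- simulate_paths(model, th, 1, tau,
                            seed = 5000 + rep)
    V <- rand_restricted_schedule(model, tau)
    rec <- apply_coarsening(paths, V)$records[[1]]
    # enumerated set == brute-force compatible set
    enum <- enumerate_compatible(rec, model)
    got <- sort(apply(enum, 1, paste, collapse = "."))
    want <- oracle_compatible_set(model, rec, V, tau)
    expect_identical(got, want)
    # ignorable log-likelihood == brute-force marginalization
    expect_equal(ignorable_loglik(model, th, rec),
                 oracle_ignorable(model, th, rec, V, tau),
                 tolerance = 1e-10)
    # invariance to group relabeling
    V2 <- V
    for (t in seq_len(tau)) {
      col <- V2[, t]
      if (any(col == 0L) && sum(col == 0L) > 1) {
        grp <- which(col == 0L) - 1L
        V2[grp + 1L, t] <- max(grp)   # arbitrary consistent label
      }
    }
    rec2 <- apply_coarsening(paths, V2)$records[[1]]
    expect_equal(ignorable_loglik(model, th, rec2),
                 ignorable_loglik(model, th, rec), tolerance = 1e-12)
  }
})

test_that("score and observed information match numerical derivatives", {
  set.seed(31)
  m <- toy_model(n_na = 2, absorbing = TRUE)
  th <- rand_theta(m, sd = 0.4)
  paths <- simulate_paths(m, th, 12, 4, seed = 88)
  sch <- lapply(1:12, function(i) rand_restricted_schedule(m, 4))
  recs <- apply_coarsening(paths, sch)
  si <- score_info(m, th, recs)
  expect_equal(si$loglik,
               sum(vapply(recs$records, function(r)
                 ignorable_loglik(m, th, r), numeric(1))),
               tolerance = 1e-10)
  g_fd <- fd_score(m, th, recs)
  expect_equal(unname(si$score), g_fd, tolerance = 1e-5)
  H_fd <- fd_hessian(m, th, recs)
  expect_equal(unname(-si$information), H_fd, tolerance = 1e-4)
})

test_that("score reduces to the logistic form in a two-event model", {
  # events {0, absorbing}, intercept only: score = sum(y - e^t/(1+e^t))
  ev <- c("Alive", "Death")
  tr <- matrix("S", 1, 2, dimnames = list("S", ev))
  m <- mstate_model(ev, absorbing = "Death", kill_sets = list(),
                    contexts = "S", ctx_init = "S", ctx_trans = tr,
                    terms = list(term_intercept("Death:intercept", "Death")))
  p <- simulate_paths(m, -0.4, 300, 5, seed = 17)
  recs <- apply_coarsening(p, identity_schedule(m, 5))
  for (theta in c(-1, -0.4, 0.3)) {
    si <- score_info(m, theta, recs)
    n_death <- sum(p$T1 <= 5)
    n_steps <- sum(pmin(p$T1, 5))
    pr <- exp(theta) / (1 + exp(theta))
    expect_equal(unname(si$score), n_death - n_steps * pr, tolerance = 1e-9)
    expect_equal(unname(si$information[1, 1]), n_steps * pr * (1 - pr),
                 tolerance = 1e-9)
  }
})

test_that("empty compatible sets and inconsistent records fail loudly", {
  m <- model_prostate()
  # record claiming AA after GnRH with everything fully observed
  p <- manual_paths(m, list(c(2L, 0L)), 2)
  r <- apply_coarsening(p, identity_schedule(m, 2))$records[[1]]
  r$Yobs[, 2] <- c(0L, 1L, 0L, 0L)     # forge an impossible AA
  expect_error(enumerate_compatible(r, m), "no compatible path")
})
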