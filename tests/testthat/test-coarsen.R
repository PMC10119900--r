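test_that("a register blackout hides the event type but not its timing", {
  # drug registers stop recording events 0,1,2 from t = 4; the subject
  # receives drug 1 at t = 4 and dies at t = 6: the t = 4 event is observed
  # only as "some event in {0,1,2}", while the death stays fully observed
  m <- model_prostate()
  tau <- 10
  p <- manual_paths(m, list(c(0L, 0L, 0L, 1L, 0L, 3L)), tau)
  V <- blackout_schedule(m, tau, times = 4:10, group = 0:2)
  r <- apply_coarsening(p, V)$records[[1]]
  expect_equal(r$D, 6L)
  expect_equal(r$Delta, 0L)
  expect_equal(unname(r$Yobs[, 4]), c(1L, 1L, 1L, 0L))
  expect_equal(unname(r$Yobs[, 6]), c(0L, 0L, 0L, 1L))
  # had he died at t = 4 all events would have been observed
  p2 <- manual_paths(m, list(c(0L, 0L, 0L, 3L)), tau)
  r2 <- apply_coarsening(p2, V)$records[[1]]
  expect_equal(unname(r2$Yobs[, 4]), c(0L, 0L, 0L, 1L))
})

test_that("the identity schedule changes nothing", {
  m <- model_prostate()
  p <- simulate_paths(m, true_theta(m), 50, 8, seed = 2)
  r <- apply_coarsening(p, identity_schedule(m, 8))
  for (i in 1:50) {
    rec <- r$records[[i]]
    expect_equal(rec$D, min(p$T1[i], 9L))
    expect_equal(rec$Delta, as.integer(p$T1[i] > 8))
    for (t in seq_len(rec$tobs))
      expect_equal(unname(which(rec$Yobs[, t] == 1L)) - 1L, p$events[i, t])
  }
})

test_that("right censoring truncates the observed record", {
  # latent death at t = 10 but the process is censored at T2 = 9:
  # D = 9, Delta = 1, last observed time 8
  m <- model_prostate()
  tau <- 10
  p <- manual_paths(m, list(c(1L, 0L, 0L, 0L, 2L, 0L, 0L, 0L, 0L, 3L)), tau)
  V <- schedule_censor(identity_schedule(m, tau), 9)
  r <- apply_coarsening(p, V)$records[[1]]
  expect_equal(r$D, 9L)
  expect_equal(r$Delta, 1L)
  expect_equal(r$tobs, 8L)
  expect_equal(unname(r$C), c(rep(1L, 8), 0L, 0L))
  expect_true(all(r$Yobs[, 9:10] == 0L))
  expect_true(all(r$Vobs[, 9:10] == 0L))
})

test_that("derive_times recovers (D, Delta, C) from the observables", {
  m <- model_prostate()
  tau <- 6
  # no absorption, no censoring
  p <- manual_paths(m, list(c(0L, 1L, 0L, 2L, 0L, 0L)), tau)
  r <- apply_coarsening(p, identity_schedule(m, tau))$records[[1]]
  expect_equal(r$D, 7L); expect_equal(r$Delta, 1L)
  d <- derive_times(r$Yobs, r$Vobs, m)
  expect_equal(d, list(D = 7L, Delta = 1L, C = rep(1L, 6)))
  # censoring from t = 5
  V <- schedule_censor(identity_schedule(m, tau), 5)
  r2 <- apply_coarsening(p, V)$records[[1]]
  d2 <- derive_times(r2$Yobs, r2$Vobs, m)
  expect_equal(d2$D, 5L); expect_equal(d2$Delta, 1L)
  # randomized consistency across many coarsened subjects
  paths <- simulate_paths(m, true_theta(m), 100, 10, seed = 8)
  sch <- make_scenario_schedules(scenario_spec(3), m, 100, seed = 9)
  recs <- apply_coarsening(paths, sch)
  for (rec in recs$records) {
    dd <- derive_times(rec$Yobs, rec$Vobs, m)
    expect_equal(dd$D, rec$D)
    expect_equal(dd$Delta, rec$Delta)
    expect_equal(dd$C, rec$C)
  }
})

test_that("coarsening never changes D when the record ends in absorption", {
  m <- model_prostate()
  p <- simulate_paths(m, true_theta(m), 200, 10, seed = 31)
  sch <- make_scenario_schedules(scenario_spec(1), m, 200, seed = 32)
  r <- apply_coarsening(p, sch)
  for (i in 1:200) {
    rec <- r$records[[i]]
    if (rec$Delta == 0L) expect_equal(rec$D, p$T1[i])
  }
})

test_that("scenario generators reproduce the stated designs", {
  m <- model_prostate()
  s1 <- scenario_spec(1)
  expect_equal(s1$tau, 10); expect_equal(s1$blackout_times, 3:6)
  s2 <- scenario_spec(2)
  expect_equal(s2$tau, 50); expect_equal(s2$blackout_times, c(5:6, 20:29))
  s3 <- scenario_spec(3)
  expect_equal(length(s3$patterns), 4)

  N <- 10000
  sch <- make_scenario_schedules(s1, m, N, seed = 77)
  frac <- mean(attr(sch, "pattern") > 0)
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / N))
  # uncoarsened subjects carry the identity schedule
  id0 <- which(attr(sch, "pattern") == 0)[1]
  expect_identical(sch[[id0]], identity_schedule(m, 10))
  # coarsened subjects merge {0, 2} exactly at the blackout times
  id1 <- which(attr(sch, "pattern") == 1)[1]
  expect_identical(sch[[id1]],
                   blackout_schedule(m, 10, times = 3:6, group = c(0L, 2L)))

  sch3 <- make_scenario_schedules(s3, m, N, seed = 78)
  pat <- attr(sch3, "pattern")
  for (k in 1:4)
    expect_lt(abs(mean(pat == k) - 0.25), 3 * sqrt(0.25 * 0.75 / N))
})

test_that("schedule validation enforces the grouping rules", {
  m <- model_prostate()
  V <- identity_schedule(m, 4)
  V[c(1, 4), 2] <- 0L                         # death grouped with reference
  p <- manual_paths(m, list(c(0L, 0L, 0L, 0L)), 4)
  expect_error(apply_coarsening(p, V), "absorbing")
  # arbitrary consistent labels are canonicalized to the min-index rule
  V2 <- identity_schedule(m, 4)
  V2[c(1, 3), 2] <- 2L                        # {0, 2} labelled "2"
  r <- apply_coarsening(manual_paths(m, list(c(0L, 2L, 0L, 0L)), 4), V2)
  expect_equal(unname(r$records[[1]]$Vobs[c(1, 3), 2]), c(0L, 0L))
})

test_that("observed-record CSV round-trips and is validated", {
  m <- model_prostate()
  p <- simulate_paths(m, true_theta(m), 60, 10, seed = 21)
  sch <- make_scenario_schedules(scenario_spec(3), m, 60, seed = 22)
  r <- apply_coarsening(p, sch)
  f <- withr::local_tempfile(fileext = ".csv")
  write_records_csv(r, f)
  r2 <- read_records_csv(f, m, 10)
  expect_equal(length(r2$records), sum(vapply(r$records, function(x)
    x$tobs > 0, logical(1))))
  kept <- which(vapply(r$records, function(x) x$tobs > 0, logical(1)))
  for (k in seq_along(kept)) {
    a <- r$records[[kept[k]]]; b <- r2$records[[k]]
    expect_identical(a$Yobs, b$Yobs)
    expect_identical(a$Vobs, b$Vobs)
    expect_equal(a$D, b$D); expect_equal(a$Delta, b$Delta)
  }
  # corrupted file: event indicated outside its group
  df <- utils::read.csv(f)
  df$yobs_1[1] <- 1 - df$yobs_1[1]
  f2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df, f2, row.names = FALSE)
  expect_error(read_records_csv(f2, m, 10), "subject 1")
})

test_that("coarsening partitions path space: record likelihoods sum to 1", {
  # fixed schedule, all complete latent paths coarsened and grouped by
  # record; the package's ignorable likelihood per distinct record must
  # match the group mass, and the masses must total 1
  m <- toy_model(n_na = 2, absorbing = TRUE)
  tau <- 3
  set.seed(42)
  for (rep in 1:3) {
    th <- rand_theta(m)
    V <- rand_restricted_schedule(m, tau)
    paths <- oracle_paths(m, tau)
    keys <- character(0); mass <- numeric(0); rec_of <- list()
    for (ev in paths) {
      pr <- exp(latent_loglik(m, th, ev))
      if (pr == 0) next
      T1 <- { h <- which(ev %in% m$absorbing_idx); if (length(h)) min(h) else tau + 1L }
      rec <- coarsemsm:::coarsen_one(m, c(ev, rep(NA_integer_, tau - length(ev))),
                                     T1, V, tau)
      key <- paste(rec$D, rec$Delta,
                   paste(rec$Yobs[, seq_len(rec$tobs)], collapse = ""),
                   sep = "|")
      i <- match(key, keys)
      if (is.na(key %in% keys) || is.na(i)) {
        keys <- c(keys, key); mass <- c(mass, pr)
        rec_of[[length(keys)]] <- rec
      } else mass[i] <- mass[i] + pr
    }
    expect_equal(sum(mass), 1, tolerance = 1e-10)
    for (i in seq_along(keys))
      expect_equal(ignorable_loglik(m, th, rec_of[[i]]), log(mass[i]),
                   tolerance = 1e-8)
  }
})
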