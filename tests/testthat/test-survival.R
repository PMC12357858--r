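test_that("Kaplan-Meier estimates match the hand product-limit oracle", {
  # all censored: flat curve at 1
  crv <- km_curve(c(1, 2, 3), c(0, 0, 0))
  expect_true(all(crv$survival == 1))

  # n = 4, events at 1 and 2, censored at 1.5 and 3
  times <- c(1, 1.5, 2, 3)
  events <- c(1, 0, 1, 0)
  crv <- km_curve(times, events)
  at_events <- crv[crv$n_event > 0, ]
  expect_equal(at_events$survival[at_events$time == 1], 0.75,
               tolerance = 1e-12)
  expect_equal(at_events$survival[at_events$time == 2], 0.375,
               tolerance = 1e-12)
  orc <- oracle_km(times, events)
  expect_equal(at_events$survival, orc$survival, tolerance = 1e-12)

  # no censoring, distinct times: S after k-th event = (n - k)/n
  n <- 7
  crv <- km_curve(seq_len(n), rep(1, n))
  expect_equal(crv$survival, (n - seq_len(n)) / n)
  expect_true(all(diff(crv$survival) <= 0))
  expect_error(km_curve(numeric(), numeric()), "empty")
})

test_that("log-rank agrees with survdiff and the risk-table oracle", {
  # identical groups carry no signal
  t0 <- c(1, 2, 3, 4); e0 <- c(1, 0, 1, 1)
  same <- logrank_test(t0, e0, t0, e0)
  expect_equal(same$chisq, 0)
  expect_equal(same$p, 1)

  # frozen 8-patient interleaved toy, from the independent risk-table oracle
  tA <- c(1, 3, 5, 7); eA <- c(1, 1, 0, 1)
  tB <- c(2, 4, 6, 8); eB <- c(1, 0, 1, 1)
  lr <- logrank_test(tA, eA, tB, eB)
  expect_equal(lr$chisq, 0.44760130414531912, tolerance = 1e-10)
  expect_equal(lr$p, 0.50347626329530348, tolerance = 1e-10)

  # a censored-only patient acts through risk sets alone
  lr2 <- logrank_test(c(tA, 2.5), c(eA, 0), tB, eB)
  orc2 <- oracle_logrank(c(tA, 2.5, tB), c(eA, 0, eB),
                         c(rep(TRUE, 5), rep(FALSE, 4)))
  expect_equal(lr2$chisq, orc2$chisq, tolerance = 1e-10)
  expect_false(lr2$chisq == lr$chisq)

  # random cohorts (with ties) against survdiff and the oracle
  set.seed(31)
  for (i in 1:20) {
    na <- sample(8:30, 1); nb <- sample(8:30, 1)
    ta <- round(rexp(na, 0.3), 1) + 0.1
    tb <- round(rexp(nb, 0.5), 1) + 0.1
    ea <- rbinom(na, 1, 0.7); eb <- rbinom(nb, 1, 0.7)
    if (sum(ea) + sum(eb) == 0) next
    got <- logrank_test(ta, ea, tb, eb)
    sd <- survival::survdiff(
      survival::Surv(c(ta, tb), c(ea, eb)) ~ rep(1:2, c(na, nb))
    )
    expect_equal(got$chisq, unname(sd$chisq), tolerance = 1e-10)
    orc <- oracle_logrank(c(ta, tb), c(ea, eb), rep(c(TRUE, FALSE), c(na, nb)))
    expect_equal(got$chisq, orc$chisq, tolerance = 1e-10)
    expect_equal(got$p, orc$p, tolerance = 1e-10)
  }

  expect_message(z <- logrank_test(c(1, 2), c(0, 0), c(3, 4), c(0, 0)),
                 "zero events")
  expect_equal(z$p, 1)
})

test_that("log-rank and Cox are invariant to a common time rescale", {
  set.seed(5)
  t1 <- rexp(40); e1 <- rbinom(40, 1, 0.6)
  t2 <- rexp(40, 1.7); e2 <- rbinom(40, 1, 0.6)
  a <- logrank_test(t1, e1, t2, e2)
  b <- logrank_test(t1 * 37, e1, t2 * 37, e2)
  expect_equal(a, b, tolerance = 1e-12)
  g <- rep(c(1, 0), each = 40)
  ca <- cox_hazard_ratio(g, c(t1, t2), c(e1, e2))
  cb <- cox_hazard_ratio(g, c(t1, t2) * 37, c(e1, e2))
  expect_equal(ca$hazard_ratio, cb$hazard_ratio, tolerance = 1e-8)
})

test_that("Cox hazard ratio maximizes the Breslow partial likelihood", {
  # symmetric duplicated data: HR exactly 1
  tt <- c(1, 2, 3, 4); ee <- c(1, 0, 1, 1)
  sym <- cox_hazard_ratio(rep(c(1, 0), each = 4), c(tt, tt), c(ee, ee))
  expect_equal(sym$hazard_ratio, 1, tolerance = 1e-6)

  # 6-patient toy: frozen beta from the grid/optimize oracle
  tt6 <- c(1, 2, 3, 4, 5, 6); ee6 <- c(1, 1, 0, 1, 1, 0)
  z6 <- c(1, 0, 1, 0, 1, 0)
  fit <- cox_hazard_ratio(z6, tt6, ee6)
  expect_equal(fit$log_hr, 0.27394782091007874, tolerance = 1e-6)
  expect_equal(fit$log_hr, oracle_cox_beta(tt6, ee6, z6), tolerance = 1e-6)

  # random cohorts against the written-out partial likelihood
  set.seed(13)
  for (i in 1:10) {
    n <- 40
    z <- rbinom(n, 1, 0.5)
    tt <- rexp(n, 0.1 * exp(0.7 * z))
    ee <- rbinom(n, 1, 0.8)
    if (sum(ee[z == 1]) == 0 || sum(ee[z == 0]) == 0) next
    fit <- cox_hazard_ratio(z, tt, ee)
    expect_equal(fit$log_hr, oracle_cox_beta(tt, ee, z), tolerance = 1e-6)
  }

  # monotone likelihood: one group's events all precede the other's
  mono <- cox_hazard_ratio(rep(c(1, 0), each = 4),
                           c(1, 2, 3, 4, 10, 11, 12, 13),
                           c(1, 1, 1, 0, 1, 1, 1, 0))
  expect_false(mono$estimable)
  expect_true(is.na(mono$hazard_ratio))
})

test_that("best-cutoff scan equals exhaustive brute force and flags degenerate input", {
  expect_error(best_cutoff_scan(rep(2, 30), rexp(30) + 0.1, rbinom(30, 1, 0.5)),
               class = "oncorank_no_valid_cutoff")
  expect_error(
    best_cutoff_scan(1:20, rexp(20) + 0.1, rbinom(20, 1, 0.5),
                     min_group = 15),
    class = "oncorank_no_valid_cutoff"
  )

  set.seed(77)
  for (i in 1:10) {
    n <- sample(40:120, 1)
    expr <- round(rlnorm(n, 2, 0.7), sample(c(0, 1, 2), 1))
    tt <- rexp(n, 0.05 * exp(0.5 * (expr > median(expr))))
    cens <- runif(n, 0, 40)
    times <- pmin(tt, cens); events <- as.numeric(tt <= cens)
    if (sum(events) < 3) next
    got <- best_cutoff_scan(expr, times, events)
    orc <- oracle_best_cutoff(expr, times, events)
    expect_identical(got$cutoff, orc$cutoff)
    expect_identical(got$n_high, orc$n_high)
    expect_equal(got$p_logrank, orc$p, tolerance = 1e-12)
    # scan table covers exactly the admissible cutoffs
    expect_true(all(tidy(got)$n_high >= 5 & tidy(got)$n_low >= 5))
  }
})

test_that("the scan finds a planted bimodal cutpoint", {
  hits <- 0
  for (i in 1:100) {
    set.seed(1000 + i)
    n <- 200
    expr <- rbinom(n, 1, 0.5)
    tt <- rexp(n, 0.05 * ifelse(expr == 1, 4, 1))
    cens <- runif(n, 0, 60)
    times <- pmin(tt, cens); events <- as.numeric(tt <= cens)
    scan <- best_cutoff_scan(expr, times, events)
    if (scan$cutoff == 0 && scan$p_logrank < 1e-3) hits <- hits + 1
  }
  expect_gte(hits, 95)
})

test_that("cohort association ranks a planted driver ahead and penalizes protective fits", {
  set.seed(400)
  n <- 150
  driver <- rlnorm(n, 1, 0.5)
  noise <- rlnorm(n, 1, 0.5)
  tt <- rexp(n, 0.04 * ifelse(driver > median(driver), 3.5, 1))
  cens <- runif(n, 0, 60)
  cohort <- survival_cohort(
    tibble::tibble(patient_id = paste0("p", 1:n),
                   time = pmin(tt, cens),
                   event = as.numeric(tt <= cens),
                   DRIVER = driver, NOISE = noise,
                   EMPTY = NA_real_),
    cohort_id = "test"
  )
  expect_message(out <- cohort_association(cohort), "not estimable")
  expect_identical(
    out$results$status[out$results$symbol == "EMPTY"], "all_missing"
  )
  comp <- out$components
  p_comp <- comp[comp$metric_name == "p_logrank", ]
  expect_false("EMPTY" %in% p_comp$symbol)
  expect_lt(p_comp$value[p_comp$symbol == "DRIVER"],
            p_comp$value[p_comp$symbol == "NOISE"])
  hr_comp <- comp[comp$metric_name == "hazard_ratio", ]
  expect_gt(hr_comp$value[hr_comp$symbol == "DRIVER"], 1)

  # shuffling patients changes nothing
  perm <- sample(n)
  cohort2 <- survival_cohort(as_tibble(cohort)[perm, ], cohort_id = "test")
  out2 <- suppressMessages(cohort_association(cohort2))
  expect_equal(out2$results, out$results)
})

test_that("null-calibrated log-rank at a fixed median split", {
  # reduced-size version of the calibration claim; the full 2,000-replicate
  # check runs in the acceptance suite
  set.seed(9)
  rejected <- 0; n_sim <- 300
  for (i in seq_len(n_sim)) {
    co <- simulate_survival_cohort(n = 100, hr_true = 1, seed = 50000 + i)
    expr <- co$SIM1
    high <- expr > median(expr)
    p <- logrank_test(co$time[high], co$event[high],
                      co$time[!high], co$event[!high])$p
    if (p < 0.05) rejected <- rejected + 1
  }
  expect_gte(rejected / n_sim, 0.02)
  expect_lte(rejected / n_sim, 0.09)
})
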