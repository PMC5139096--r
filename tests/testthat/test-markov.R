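test_that("an absorbing Well cohort reproduces the discounted annuity", {
  H <- 20
  sched <- build_schedule(rep(0, H), rep(0, H), rep(0, H), screened = FALSE,
                          n_screens = 0)
  pay <- toy_payoffs("none")
  res <- run_cohort(sched, pay, econ_settings(horizon = H))
  annuity <- sum((1 + 0.035)^-(1:H))
  expect_equal(res$qaly, pay$utility_well * annuity, tolerance = 1e-12)
  expect_equal(res$life_years, H)
  expect_equal(res$cost, 0)
  expect_equal(res$oc_deaths, 0)
})

test_that("occupancy is conserved over 40 cycles", {
  sched <- toy_schedule(seed = 41)
  res <- run_cohort(sched, toy_payoffs(), econ_settings())
  expect_lt(res$max_drift, 1e-10)
  # death states never lose mass
  expect_true(all(diff(res$trace[, "dead_oc"]) >= -1e-15))
  expect_true(all(diff(res$trace[, "dead_other"]) >= -1e-15))
})

test_that("row-sum violations are reported with cycle and state", {
  sched <- toy_schedule(seed = 42)
  sched$P[5, 3, 4] <- sched$P[5, 3, 4] + 0.01
  expect_error(run_cohort(sched, toy_payoffs(), econ_settings()),
               "cycle 5, state oc_year1")
})

test_that("discounted QALYs are bounded by life years times max utility", {
  for (seed in 43:47) {
    sched <- toy_schedule(seed = seed)
    pay <- toy_payoffs()
    res <- run_cohort(sched, pay, econ_settings())
    expect_lte(res$qaly, res$life_years * pay$utility_well + 1e-9)
  }
})

test_that("null screening effect and zero screening costs equalise strategies", {
  H <- 40
  oc <- 0.0005 * seq_len(H) / H
  inc <- rep(0.002, H)
  oth <- rep(0.006, H)
  res <- lapply(c("none", "MMS", "USS"), function(s) {
    pay <- build_payoffs(s, parameter_means(),
                         options = model_options(fp_enabled = FALSE))
    pay$cost_screen <- 0; pay$cost_invitation <- 0
    sched <- build_schedule(oc, inc, oth, screened = s != "none",
                            n_screens = 7)
    run_cohort(sched, pay, econ_settings())
  })
  expect_equal(res[[1]]$cost, res[[2]]$cost, tolerance = 1e-12)
  expect_equal(res[[1]]$qaly, res[[3]]$qaly, tolerance = 1e-12)
  expect_equal(res[[2]]$oc_deaths, res[[3]]$oc_deaths, tolerance = 1e-12)
})

test_that("screening cost stream matches the per-woman arithmetic", {
  pay <- toy_payoffs("MMS", completion_frac = 1)
  pay$cost_screen <- 61; pay$cost_invitation <- 0
  s <- screening_cost_stream("MMS", pay, n_screens = 7, horizon = 40)
  expect_equal(sum(s), 427) # 7 annual screens at £61
  expect_equal(sum(screening_cost_stream("MMS", pay, n_screens = 0,
                                         horizon = 40)), 0)
  expect_equal(sum(screening_cost_stream("none", pay, n_screens = 7,
                                         horizon = 40)), 0)
  expect_error(screening_cost_stream("foo", pay, 7, 40), "unknown strategy")
  expect_error(screening_cost_stream("MMS", pay, 50, 40), "horizon")
})

test_that("false-positive load scales with the per-cancer ratio", {
  pay <- toy_payoffs("MMS")
  expect_equal(false_positive_load(100, 0, pay)$n_fp, 0)
  fp <- false_positive_load(100, 2.302, pay)
  expect_equal(fp$n_fp, 230.2)
  expect_equal(fp$cost, 230.2 * pay$fp_cost)
  expect_equal(fp$qaly_loss, 230.2 * pay$fp_disutility)
  expect_error(false_positive_load(100, -1, pay), ">= 0")
})

test_that("the engine matches an individual-level microsimulation", {
  sched <- toy_schedule(seed = 48)
  pay <- toy_payoffs("MMS")
  setts <- econ_settings()
  engine <- run_cohort(sched, pay, setts)
  sim <- microsim_oracle(sched, pay, setts, n = 40000, seed = 49)
  for (m in c("cost", "qaly", "life_years", "oc_deaths")) {
    expect_lt(abs(engine[[m]] - sim[[m]]), 3 * sim$se[[m]] + 1e-12)
  }
})

test_that("the schedule calibration reproduces arm-level mortality", {
  H <- 40
  oc <- c(rep(1e-5, 3), seq(5e-5, 8e-4, length.out = 37))
  inc <- rep(0.004, H)
  oth <- rep(0.006, H)
  sched <- build_schedule(oc, inc, oth, screened = FALSE)
  pay <- build_payoffs("none", parameter_means())
  res <- run_cohort(sched, pay, econ_settings())
  # expected cohort-level deaths from the marginal trajectory
  alive <- 1; target <- 0
  for (t in seq_len(H)) {
    target <- target + alive * oc[t]
    alive <- alive * (1 - oc[t]) * (1 - oth[t])
  }
  expect_equal(res$oc_deaths, target, tolerance = 0.02)
})
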