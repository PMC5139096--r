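test_that("pooled other-cause rate is deaths over exposure", {
  expect_equal(other_cause_rate(13296, 2194447), 13296 / 2194447)
  expect_equal(round(100 * other_cause_rate(13296, 2194447), 2), 0.61)
  expect_equal(other_cause_rate(0, 1000), 0)
  expect_equal(other_cause_rate(10, 1000), 0.01)
  expect_error(other_cause_rate(-1, 10), "non-negative")
  expect_error(other_cause_rate(1, 0), "positive")
})

test_that("other-cause probabilities switch to the life table at age 72", {
  lt <- synthetic_life_table()
  r <- 0.006
  p <- build_other_cause(r, entry_age = 60, trial_years = 12, table = lt,
                         horizon = 40)
  expect_equal(p[1:12], rep(1 - exp(-r), 12)) # rate-to-probability
  expect_equal(p[13], lt$qx[lt$age == 72])
  expect_equal(p[40], lt$qx[lt$age == 99])
  # flat life table equal to the trial probability: continuous sequence
  flat <- data.frame(age = 50:105, qx = 1 - exp(-r))
  pf <- build_other_cause(r, table = flat, horizon = 40)
  expect_equal(pf, rep(1 - exp(-r), 40))
  short <- data.frame(age = 60:80, qx = 0.01)
  expect_error(build_other_cause(r, table = short, horizon = 40), "age 81")
})

test_that("parametric extrapolation has the family's hazard shape", {
  d <- data.frame(time = rexp(4000, 0.1), event = 1)
  fe <- fit_parametric(d, "exponential")
  tr <- extrapolate_parametric(fe, 40)
  expect_equal(tr$hazard, rep(tr$hazard[1], 40), tolerance = 1e-9)
  set.seed(33)
  dw <- data.frame(time = rweibull(4000, 1.6, 15), event = 1)
  fw <- fit_parametric(dw, "weibull")
  trw <- extrapolate_parametric(fw, 40)
  expect_true(all(diff(trw$hazard) > 0)) # shape > 1: increasing hazard
  expect_true(all(trw$hazard >= 0))
  expect_equal(nrow(trw), 40)
})

test_that("discrepancy attenuation follows the stated arithmetic", {
  hr <- c(rep(0.9, 11), rep(0.8, 9))
  # no attenuation, no noise: identity
  same <- apply_discrepancy(hr, discrepancy_spec(0, 0), trial_years = 11)
  expect_equal(same, hr)
  # mean 5%/year, sd 0: effect 0.2 becomes 0.2 * 0.95^2 after 2 years
  out <- apply_discrepancy(hr, discrepancy_spec(0.05, 0), trial_years = 11)
  expect_equal(out[1:11], hr[1:11])             # within-trial untouched
  expect_equal(out[13], 1 - 0.2 * 0.95^2)       # = 0.8195
  expect_equal(out[12], 1 - 0.2 * 0.95)
  # log-HR scale
  outl <- apply_discrepancy(hr, discrepancy_spec(0.05, 0, scale = "log-HR"),
                            trial_years = 11)
  expect_equal(outl[13], exp(log(0.8) * 0.95^2))
  expect_error(discrepancy_spec(scale = "wrong"))
  expect_error(discrepancy_spec(annual_attenuation_mean = 1.2), "\\[0, 1\\]")
  # random multipliers have the right first two moments
  set.seed(34)
  m <- rdiscrepancy_multipliers(discrepancy_spec(0.05, 0.05), 20000)
  expect_equal(mean(m), 0.95, tolerance = 0.005)
  expect_equal(sd(m), 0.05, tolerance = 0.01)
})

test_that("smoothing extrapolation extends and floors properly", {
  h <- c(1e-4, 2e-4, 3e-4, 4e-4, 5e-4, 5.5e-4, 6e-4, 6.2e-4, 6.3e-4, 6.4e-4,
         6.4e-4)
  tr <- extrapolate_smoothing(h, 40)
  expect_equal(tr$hazard[1:11], h)
  expect_true(all(tr$hazard > 0))
  expect_equal(nrow(tr), 40)
  expect_warning(extrapolate_smoothing(c(0, h[-1]), 40), "floored")
  # constant series stays constant through the smoothing pipeline
  trc <- extrapolate_smoothing(rep(2e-4, 11), 40)
  expect_equal(trc$hazard, rep(2e-4, 40), tolerance = 1e-12)
})

test_that("all regimes keep a constant hazard constant", {
  # a constant within-trial hazard extrapolates to (nearly) the same
  # constant under smoothing and under the memoryless parametric family
  h <- rep(4e-4, 11)
  expect_equal(extrapolate_smoothing(h, 40)$hazard, rep(4e-4, 40))
  set.seed(35)
  d <- data.frame(time = pmin(rexp(30000, 4e-4), 11),
                  event = as.integer(rexp(30000, 4e-4) <= 11))
  d$event <- as.integer(d$time < 11)
  fe <- fit_parametric(d, "exponential")
  tre <- extrapolate_parametric(fe, 40)
  expect_equal(tre$hazard, rep(tre$hazard[1], 40), tolerance = 1e-9)
  expect_equal(tre$hazard[1], 4e-4, tolerance = 0.15)
})

test_that("deterministic discrepancy equals base case when switched off", {
  inp <- small_inputs()
  base <- build_trajectories(inp, "smoothing", 40)
  off <- build_trajectories(inp, "discrepancy", 40,
                            discrepancy = discrepancy_spec(0, 0))
  expect_identical(base$oc_hazard, off$oc_hazard)
  expect_identical(base$hr, off$hr)
})
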