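test_that("scenario calibration hits the trial-scale event fractions", {
  sc <- trial_scenario()
  fr <- scenario_event_fractions(sc)
  expect_equal(unname(fr$oc_death["none"]), 0.0034, tolerance = 1e-6)
  expect_equal(unname(fr$diagnosed[c("none", "MMS", "USS")]),
               c(0.0062, 0.0067, 0.0062), tolerance = 1e-4)
  # delayed effect: no benefit early, 23% reduction in the late trial years
  expect_equal(sc$hr_funs$MMS[1:7], rep(1, 7))
  expect_equal(sc$hr_funs$MMS[9:11], rep(0.77, 3))
})

test_that("scenario validation rejects malformed inputs", {
  expect_error(trial_scenario(arm_sizes = c(none = 0, MMS = 10, USS = 10)),
               "positive")
  sc <- small_scenario()
  sc$baseline_oc_mortality_hazard[3] <- -1
  expect_error(ovascreen:::validate_scenario(sc), "year 3")
  sc2 <- small_scenario()
  sc2$incidence_hazard$MMS[2] <- NaN
  expect_error(ovascreen:::validate_scenario(sc2), "arm MMS")
  sc3 <- small_scenario()
  sc3$stage_mix$USS <- c(borderline = 0.5, I = 0.1, II = 0.1, III = 0.1,
                         IV = 0.1)
  expect_error(ovascreen:::validate_scenario(sc3), "sum to 1")
})

test_that("all-zero hazards censor every subject at end of follow-up", {
  sc <- small_scenario()
  sc$baseline_oc_mortality_hazard[] <- 0
  sc$incidence_hazard <- lapply(sc$incidence_hazard, function(x) x * 0)
  sc$other_cause_hazard <- 0
  ipd <- generate_ipd(sc, seed = 1)
  expect_true(all(ipd$event == "censored"))
  expect_true(all(ipd$time == sc$followup_years))
})

test_that("constant-hazard survival matches the exponential closed form", {
  sc <- trial_scenario(arm_sizes = c(none = 50000, MMS = 10, USS = 10),
                       baseline_oc_mortality_hazard = rep(0.02, 11),
                       hr_profiles = list(MMS = rep(1, 11), USS = rep(1, 11)),
                       incidence_hazard = list(none = rep(0, 11),
                                               MMS = rep(0, 11),
                                               USS = rep(0, 11)),
                       other_cause_hazard = 0, stage_mix = NULL, seed = 2)
  ipd <- generate_ipd(sc)
  km <- km_estimate(
    data.frame(time = ipd$time[ipd$arm == "none"],
               event = as.integer(ipd$event[ipd$arm == "none"] == "oc_death")),
    grid = c(2, 5, 10))
  expected <- exp(-0.02 * c(2, 5, 10))
  mc_se <- sqrt(expected * (1 - expected) / 50000)
  expect_true(all(abs(km$survival - expected) < 3 * mc_se + 1e-9))
})

test_that("empirical event fractions converge to the analytic values", {
  sc <- trial_scenario(arm_sizes = c(none = 50000, MMS = 50000, USS = 50000))
  ipd <- generate_ipd(sc, seed = 3)
  fr <- scenario_event_fractions(sc)
  for (a in c("none", "MMS", "USS")) {
    d <- ipd[ipd$arm == a, ]
    for (m in c("oc_death", "diagnosed")) {
      p <- fr[[m]][[a]]
      obs <- if (m == "oc_death") mean(d$event == "oc_death") else
        mean(!is.na(d$diag_time))
      se <- sqrt(p * (1 - p) / nrow(d))
      expect_lt(abs(obs - p), 3 * se + 1e-9)
    }
    expect_true(all(is.na(d$diag_time) | d$diag_time <= d$time + 1e-12))
  }
})

test_that("generation is reproducible under a fixed seed", {
  sc <- small_scenario()
  a <- generate_ipd(sc, seed = 99)
  b <- generate_ipd(sc, seed = 99)
  expect_identical(a, b)
})

test_that("scenario round-trips through structured text", {
  sc <- small_scenario()
  path <- tempfile(fileext = ".yaml")
  write_scenario(sc, path)
  sc2 <- read_scenario(path)
  expect_equal(sc2$baseline_oc_mortality_hazard,
               sc$baseline_oc_mortality_hazard)
  expect_equal(sc2$arm_sizes, sc$arm_sizes)
  expect_equal(sc2$stage_mix, sc$stage_mix)
  unlink(path)
})
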