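test_that("run configuration validates and round-trips through YAML", {
  cfg <- run_config(regime = "discrepancy", horizon = "11-year",
                    n_draws = 10, seed = 3)
  expect_equal(cfg$regime, "discrepancy")
  expect_error(run_config(regime = "quadratic"))
  expect_error(run_config(n_draws = 0), "n_draws")
  path <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(regime = "smoothing", horizon = "11-year",
                        n_draws = 25, seed = 9, roca_cost = 20), path)
  cfg2 <- read_run_config(path)
  expect_equal(cfg2$n_draws, 25)
  expect_equal(cfg2$roca_cost, 20)
  unlink(path)
})

config_hash_of <- function(cfg) ovascreen:::config_hash(cfg)

test_that("experiments are reproducible and fully logged", {
  cfg <- run_config(n_draws = 8, seed = 5, scenario = small_scenario())
  inp <- small_inputs()
  r1 <- run_experiment(cfg, inputs = inp)
  r2 <- run_experiment(cfg, inputs = inp)
  expect_identical(r1$psa$cost, r2$psa$cost)
  expect_identical(r1$summary$table, r2$summary$table)
  expect_equal(r1$log$config_hash, r2$log$config_hash)
  expect_match(r1$log$config_hash, "^[0-9a-f]{32}$")
  # different config, different hash
  cfg2 <- run_config(n_draws = 8, seed = 6, scenario = small_scenario())
  expect_false(config_hash_of(cfg) == config_hash_of(cfg2))
})

test_that("a single-draw degenerate run produces a deterministic report", {
  cfg <- run_config(n_draws = 1, seed = 7, scenario = small_scenario(),
                    wtp_grid = seq(0, 30000, 10000))
  rpt <- run_experiment(cfg, inputs = small_inputs())
  tab <- rpt$summary$table
  expect_equal(tab$mean, tab$ci_low)
  dir <- tempfile()
  write_report(rpt, dir)
  expect_true(all(file.exists(file.path(dir, c("strategy_results.csv",
                                               "frontier.csv", "ceac.csv",
                                               "evpi.csv",
                                               "run_log.yaml")))))
  unlink(dir, recursive = TRUE)
})

test_that("11-year validation table compares model and trial fractions", {
  cfg <- run_config(horizon = "11-year", n_draws = 2, seed = 8,
                    scenario = small_scenario())
  rpt <- run_experiment(cfg, inputs = small_inputs())
  # identical inputs: differences are exactly zero
  self_ref <- data.frame(
    measure = c("oc_deaths", "cancers"), strategy = c("MMS", "none"),
    value = c(rpt$deterministic$MMS$oc_deaths,
              rpt$deterministic$none$cancers))
  cmp <- compare_to_trial(rpt, self_ref)
  expect_equal(cmp$diff_pp, c(0, 0))
  # lifetime runs are rejected
  cfg_l <- run_config(horizon = "lifetime", n_draws = 2, seed = 8,
                      scenario = small_scenario())
  rpt_l <- run_experiment(cfg_l, inputs = small_inputs())
  expect_error(compare_to_trial(rpt_l), "11-year")
})

test_that("extending the horizon past age 100 barely moves the base case", {
  # discounting and late-age mortality make cycles beyond age 100 nearly
  # irrelevant for QALYs; absolute costs move slightly more (the fitted
  # incidence keeps rising at very old ages), so incremental results are
  # held to 1%
  inp <- small_inputs()
  tr40 <- build_trajectories(inp, "smoothing", 40)
  tr45 <- build_trajectories(inp, "smoothing", 45)
  r40 <- evaluate_strategies(tr40, settings = econ_settings(horizon = 40))
  r45 <- evaluate_strategies(tr45, settings = econ_settings(horizon = 45))
  for (s in c("none", "MMS")) {
    expect_lt(abs(r45[[s]]$qaly - r40[[s]]$qaly) / r40[[s]]$qaly, 0.0025)
  }
  d40 <- r40$MMS$cost - r40$none$cost
  d45 <- r45$MMS$cost - r45$none$cost
  expect_lt(abs(d45 - d40) / abs(d40), 0.01)
  q40 <- r40$MMS$qaly - r40$none$qaly
  q45 <- r45$MMS$qaly - r45$none$qaly
  expect_lt(abs(q45 - q40) / abs(q40), 0.01)
})
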