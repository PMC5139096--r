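sim_surv <- function(n, rdist, cens_range = c(5, 25), seed = 1) {
  set.seed(seed)
  t <- rdist(n)
  cn <- runif(n, cens_range[1], cens_range[2])
  data.frame(time = pmin(t, cn), event = as.integer(t <= cn))
}

test_that("weibull fit on exponential data recovers shape 1", {
  d <- sim_surv(10000, function(n) rexp(n, 0.08), seed = 21)
  ft <- fit_parametric(d, "weibull")
  se <- sqrt(diag(ft$vcov_t))[1] # log-shape scale
  expect_lt(abs(log(ft$params[["shape"]])), 1.96 * se)
})

test_that("weibull parameters are recovered within 5% at n = 10,000", {
  d <- sim_surv(10000, function(n) rweibull(n, 1.3, 20), seed = 22)
  ft <- fit_parametric(d, "weibull")
  expect_lt(abs(ft$params[["shape"]] - 1.3) / 1.3, 0.05)
  expect_lt(abs(ft$params[["scale"]] - 20) / 20, 0.05)
  expect_true(is.finite(ft$loglik))
  expect_equal(ft$bic, 2 * log(10000) - 2 * ft$loglik)
})

test_that("all five families fit and satisfy survival invariants", {
  d <- sim_surv(3000, function(n) rlnorm(n, 2.5, 0.8), seed = 23)
  for (fam in c("exponential", "weibull", "gompertz", "log-logistic",
                "log-normal")) {
    ft <- fit_parametric(d, fam)
    H <- ovascreen:::cumhaz_parametric(ft, c(0, 1, 2, 5, 10, 20))
    expect_true(all(diff(H) >= 0))        # cumulative hazard non-decreasing
    expect_equal(H[1], 0)                 # survival(0) = 1
    expect_true(all(is.finite(ft$params)))
  }
  expect_error(fit_parametric(data.frame(time = c(1, 2), event = c(1, 0)),
                              "weibull"), "2 events")
})

test_that("BIC selection minimises within the chosen regime", {
  mk <- function(bic) structure(list(bic = bic), class = "ova_parfit")
  fits <- list(arm1 = list(A = mk(100), B = mk(101)))
  sel <- select_family(fits, "separate")
  expect_equal(unname(sel$chosen["arm1"]), "A")
  # combined: A best in 2 arms by 1, B best in third by 10 -> B iff summed lower
  fits3 <- list(a1 = list(A = mk(100), B = mk(101)),
                a2 = list(A = mk(100), B = mk(101)),
                a3 = list(A = mk(110), B = mk(100)))
  sel_c <- select_family(fits3, "combined")
  expect_equal(unname(sel_c$chosen), rep("B", 3))  # 310 vs 302
  sel_s <- select_family(fits3, "separate")
  expect_equal(unname(sel_s$chosen), c("A", "A", "B"))
  # failed fits excluded with a warning; all-failed errors
  fits_na <- list(a1 = list(A = NULL, B = mk(90)))
  expect_warning(sel_na <- select_family(fits_na, "separate"), "excluded")
  expect_equal(unname(sel_na$chosen["a1"]), "B")
  expect_error(suppressWarnings(select_family(list(a1 = list(A = NULL)),
                                              "separate")), "failed")
})

test_that("spline fit without time-varying terms gives a constant HR", {
  sc <- small_scenario()
  ipd <- generate_ipd(sc, seed = 24)
  d <- data.frame(time = ipd$time,
                  event = as.integer(ipd$event == "oc_death"), arm = ipd$arm)
  ph <- fit_spline_hr(d, n_internal_knots = 2, tv = FALSE)
  tab <- spline_hazard_table(ph, 1:11)
  hr <- tab$hr$MMS
  expect_lt(diff(range(hr)) / mean(hr), 1e-6)
  # time-varying model must not lose likelihood against its nested PH version
  tv <- fit_spline_hr(d, n_internal_knots = 2, tv = TRUE)
  expect_gte(tv$loglik, ph$loglik - 1e-6)
})

test_that("a delayed effect is recovered as a declining fitted HR", {
  # known truth: HR 1 before year 7, 0.7 after
  sc <- trial_scenario(
    arm_sizes = c(none = 60000, MMS = 60000, USS = 1000),
    baseline_oc_mortality_hazard = rep(0.004, 11),
    hr_profiles = list(MMS = c(rep(1, 7), rep(0.7, 4)),
                       USS = rep(1, 11)),
    incidence_hazard = list(none = rep(1e-4, 11), MMS = rep(1e-4, 11),
                            USS = rep(1e-4, 11)))
  ipd <- generate_ipd(sc, seed = 25)
  d <- data.frame(time = ipd$time,
                  event = as.integer(ipd$event == "oc_death"), arm = ipd$arm)
  fit <- fit_spline_hr(d, n_internal_knots = 2)
  hr <- spline_hazard_table(fit, 1:11)$hr$MMS
  expect_lt(mean(hr[8:11]), mean(hr[1:7]))
  expect_true(all(hr > 0))
})

test_that("spline hazards satisfy the survival invariants", {
  inp <- small_inputs()
  fit <- inp$spline_fit
  for (a in fit$arms) {
    H <- ovascreen:::spline_cumhaz(fit, seq(0.25, 11, by = 0.25), a)
    expect_true(all(diff(H) >= -1e-12))
    expect_true(all(H >= 0))
  }
})
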