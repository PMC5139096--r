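# Lifetime extrapolation: pooled other-cause mortality spliced onto a life
# table, smoothing / parametric extension of within-trial hazards and hazard
# ratios, and the model-discrepancy adjustment for structural uncertainty.

#' Pooled annual other-cause mortality rate
#'
#' @param deaths number of deaths from causes other than ovarian cancer.
#' @param women_years total exposure in women-years.
#' @return annual rate (deaths per woman-year).
#' @export
other_cause_rate <- function(deaths, women_years) {
  if (deaths < 0 || women_years < 0) stop("inputs must be non-negative")
  if (women_years == 0) stop("exposure must be positive")
  deaths / women_years
}

#' Synthetic national life table (female, Gompertz-Makeham)
#'
#' A synthetic stand-in for a national female life table, generated from a
#' Gompertz-Makeham hazard \eqn{\mu(x) = A + B e^{\theta (x - 60)}} with
#' parameters chosen to resemble contemporary UK female mortality (annual
#' death probability about 0.5% at 60, 7% at 85, 20% at 95). Shipped as
#' plain CSV in `extdata/life_table_synthetic.csv`; this function regenerates
#' it from code.
#'
#' @param ages ages covered (default 50 to 105).
#' @param A,B,theta Gompertz-Makeham parameters.
#' @return `data.frame(age, qx)` with `qx` the annual death probability.
#' @export
synthetic_life_table <- function(ages = 50:105, A = 5e-4, B = 4.5e-3,
                                 theta = 0.108) {
  mu <- A + B * exp(theta * (ages - 60))
  data.frame(age = ages, qx = 1 - exp(-mu))
}

#' Read a life table from CSV
#' @param path CSV with columns `age` and `qx`.
#' @return validated `data.frame(age, qx)`.
#' @export
read_life_table <- function(path) {
  x <- utils::read.csv(path)
  stopifnot(all(c("age", "qx") %in% names(x)))
  if (any(x$qx < 0 | x$qx > 1)) stop("life-table qx must lie in [0, 1]")
  if (any(diff(x$age) != 1)) stop("life-table ages must be contiguous")
  x
}

#' Per-cycle other-cause death probabilities
#'
#' Uses the pooled within-trial rate (converted to an annual probability via
#' `1 - exp(-rate)`) for the trial years, then switches to life-table
#' probabilities at the attained age: with entry at 60 and a 12-year trial
#' window, the life table takes over at age 72. By default the life table is
#' used as published (no rescaling at the splice, so a healthy-volunteer jump
#' is possible); `rescale = TRUE` scales the life-table section to be
#' continuous at the switch.
#'
#' @param rate pooled annual other-cause mortality rate.
#' @param entry_age average age at model entry.
#' @param trial_years number of initial cycles using the pooled trial rate.
#' @param table life table (`data.frame(age, qx)`).
#' @param horizon total number of model cycles.
#' @param rescale rescale the life-table section for continuity at the
#'   switch.
#' @return numeric vector of length `horizon` of annual death probabilities.
#' @export
build_other_cause <- function(rate, entry_age = 60, trial_years = 12,
                              table = synthetic_life_table(),
                              horizon = 40, rescale = FALSE) {
  if (rate < 0) stop("rate must be non-negative")
  p_trial <- 1 - exp(-rate)
  out <- numeric(horizon)
  nt <- min(trial_years, horizon)
  out[seq_len(nt)] <- p_trial
  if (horizon > trial_years) {
    cycles <- (trial_years + 1):horizon
    ages <- entry_age + cycles - 1
    idx <- match(ages, table$age)
    if (any(is.na(idx))) {
      stop(sprintf("life table does not cover age %d",
                   ages[which(is.na(idx))[1]]))
    }
    q <- table$qx[idx]
    if (rescale) {
      q0 <- table$qx[match(entry_age + trial_years, table$age)]
      if (is.na(q0) || q0 <= 0) stop("cannot rescale: switch age missing")
      q <- q * (p_trial / q0)
    }
    out[cycles] <- pmin(q, 1)
  }
  out
}

# --- hazard / HR trajectories ------------------------------------------------

new_trajectory <- function(hazard, source) {
  structure(data.frame(year = seq_along(hazard), hazard = hazard,
                       source = source),
            class = c("hazard_trajectory", "data.frame"))
}

#' Lifetime annual hazards from a fitted parametric or spline model
#'
#' Evaluates annual hazard increments (differences of the fitted cumulative
#' hazard) across the full model horizon. For spline fits the
#' log-cumulative-hazard spline is linear in log time beyond the boundary
#' knots, so extrapolation is the natural linear extension of the basis.
#' Negative increments (possible for an improper tail, e.g. a negative-rate
#' Gompertz plateau) are floored at zero and flagged.
#'
#' @param fit an `ova_parfit` or `ova_splinefit`.
#' @param horizon number of model years.
#' @param arm arm label (spline fits only).
#' @param params,coefs optional replacement parameters/coefficients (PSA
#'   draws).
#' @return a `hazard_trajectory` data frame (`year`, `hazard` as annual
#'   cumulative-hazard increments, `source`).
#' @export
extrapolate_parametric <- function(fit, horizon, arm = NULL, params = NULL,
                                   coefs = NULL) {
  if (inherits(fit, "ova_parfit")) {
    H <- cumhaz_parametric(fit, 0:horizon, params)
    dh <- diff(H)
    src <- paste0("parametric:", fit$family)
  } else if (inherits(fit, "ova_splinefit")) {
    if (is.null(arm)) arm <- fit$arms[1]
    dh <- spline_annual_hazards(fit, seq_len(horizon), arm, coefs)
    src <- "spline"
  } else stop("fit must be an ova_parfit or ova_splinefit")
  flagged <- any(dh < 0 | !is.finite(dh))
  dh[!is.finite(dh)] <- 0
  tr <- new_trajectory(pmax(dh, 0), src)
  attr(tr, "floored") <- flagged
  tr
}

#' Smoothing-based lifetime hazard trajectory
#'
#' Keeps the within-trial annual hazards and extends them by a damped-trend
#' exponential-smoothing forecast on the log-hazard scale. Non-positive
#' within-trial hazards are floored at a small positive value (with a
#' warning) before taking logs. A standard-normal `z` reproduces the
#' forecast's uncertainty for PSA propagation: the whole extrapolated path is
#' shifted by `z` forecast standard deviations (a single draw, so sampled
#' paths stay smooth).
#'
#' @param within_hazards annual hazards for the trial years.
#' @param horizon total model years.
#' @param settings smoothing settings, see [forecast_smoothing()].
#' @param z optional standard-normal deviate for uncertainty propagation.
#' @return a `hazard_trajectory`.
#' @export
extrapolate_smoothing <- function(within_hazards, horizon,
                                  settings = list(trend = "damped"), z = 0) {
  h <- as.numeric(within_hazards)
  if (any(h <= 0)) {
    warning("non-positive hazards floored before log transform")
    h <- pmax(h, 1e-10)
  }
  fc <- forecast_smoothing(log(h), horizon - length(h), settings)
  ext <- exp(fc$mean + z * fc$sd)
  new_trajectory(c(h, ext), "smoothing")
}

#' Smoothing-based lifetime hazard-ratio trajectory
#'
#' As [extrapolate_smoothing()], but operating on the log hazard-ratio
#' series of a screening arm.
#'
#' @param within_hr annual hazard ratios for the trial years.
#' @param horizon total model years.
#' @param settings smoothing settings.
#' @param z optional standard-normal deviate.
#' @return numeric vector of annual hazard ratios, length `horizon`.
#' @export
extrapolate_hr_smoothing <- function(within_hr, horizon,
                                     settings = list(trend = "damped"),
                                     z = 0) {
  r <- pmax(as.numeric(within_hr), 1e-6)
  fc <- forecast_smoothing(log(r), horizon - length(r), settings)
  pmax(c(r, exp(fc$mean + z * fc$sd)), 1e-6)
}

#' Model-discrepancy specification
#'
#' Structural-uncertainty adjustment for extrapolated screening effects: in
#' each extrapolated year the screening effect is attenuated by a random
#' multiplier with mean `1 - annual_attenuation_mean` and standard deviation
#' `attenuation_sd`, so after `t` extrapolated years the cumulative
#' attenuation has mean `(1 - annual_attenuation_mean)^t` (the base case uses
#' a 5% cumulative annual decrease with standard deviation 0.05).
#'
#' @param annual_attenuation_mean mean annual fractional decrease of the
#'   effect (in \[0, 1\]).
#' @param attenuation_sd standard deviation of the annual multiplier.
#' @param scale `"effect-size"` (attenuate `1 - HR`) or `"log-HR"`.
#' @return list of class `discrepancy_spec`.
#' @export
discrepancy_spec <- function(annual_attenuation_mean = 0.05,
                             attenuation_sd = 0.05,
                             scale = c("effect-size", "log-HR")) {
  if (annual_attenuation_mean < 0 || annual_attenuation_mean > 1) {
    stop("annual_attenuation_mean must lie in [0, 1]")
  }
  if (attenuation_sd < 0) stop("attenuation_sd must be >= 0")
  scale <- match.arg(scale)
  structure(list(annual_attenuation_mean = annual_attenuation_mean,
                 attenuation_sd = attenuation_sd, scale = scale),
            class = "discrepancy_spec")
}

#' Apply model discrepancy to an extrapolated hazard-ratio trajectory
#'
#' Within-trial years are untouched. For extrapolated year `t` (counting from
#' the end of the trial), the screening effect (on the configured scale) is
#' multiplied by the cumulative product of `t` independent annual multipliers
#' with mean `1 - annual_attenuation_mean` and the configured standard
#' deviation (log-normal; degenerate when the sd is 0).
#'
#' @param hr annual hazard-ratio vector over the full horizon.
#' @param spec a [discrepancy_spec()].
#' @param trial_years number of within-trial years (left untouched).
#' @param seed optional seed for the multipliers (use the PSA stream
#'   otherwise).
#' @param multipliers optional pre-drawn annual multipliers (length
#'   `horizon - trial_years`), e.g. from the PSA random stream.
#' @return adjusted hazard-ratio vector.
#' @export
apply_discrepancy <- function(hr, spec = discrepancy_spec(), trial_years,
                              seed = NULL, multipliers = NULL) {
  if (!inherits(spec, "discrepancy_spec")) stop("spec must be a discrepancy_spec")
  horizon <- length(hr)
  if (horizon <= trial_years) return(hr)
  n_ext <- horizon - trial_years
  m_mean <- 1 - spec$annual_attenuation_mean
  if (!is.null(multipliers)) {
    stopifnot(length(multipliers) == n_ext)
    m <- multipliers
  } else if (spec$attenuation_sd == 0) {
    m <- rep(m_mean, n_ext)
  } else {
    if (!is.null(seed)) set.seed(seed)
    sdlog2 <- log(1 + (spec$attenuation_sd / m_mean)^2)
    m <- stats::rlnorm(n_ext, log(m_mean) - sdlog2 / 2, sqrt(sdlog2))
  }
  cm <- cumprod(m)
  idx <- (trial_years + 1):horizon
  if (spec$scale == "effect-size") {
    eff <- (1 - hr[idx]) * cm
    hr[idx] <- 1 - eff
  } else {
    hr[idx] <- exp(log(hr[idx]) * cm)
  }
  pmax(hr, 1e-6)
}

#' Draw annual discrepancy multipliers
#' @param spec a [discrepancy_spec()].
#' @param n number of extrapolated years.
#' @return vector of `n` multipliers (log-normal, mean
#'   `1 - annual_attenuation_mean`, sd `attenuation_sd`).
#' @export
rdiscrepancy_multipliers <- function(spec, n) {
  m_mean <- 1 - spec$annual_attenuation_mean
  if (spec$attenuation_sd == 0) return(rep(m_mean, n))
  sdlog2 <- log(1 + (spec$attenuation_sd / m_mean)^2)
  stats::rlnorm(n, log(m_mean) - sdlog2 / 2, sqrt(sdlog2))
}

#' Write a hazard / HR trajectory as CSV
#' @param traj a `hazard_trajectory` (or any data frame with `year` and value
#'   columns).
#' @param path CSV path.
#' @export
write_trajectory_csv <- function(traj, path) {
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE)
  invisible(path)
}
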