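# End-to-end pipeline: from (synthetic or supplied) trial data through curve
# digitization, pseudo-IPD reconstruction and survival fitting, to the
# annual hazard / hazard-ratio trajectories and per-strategy cohort results.

ARMS <- c("none", "MMS", "USS")
EXTRAP_REGIMES <- c("smoothing", "separate-parametric", "same-parametric",
                    "discrepancy")

#' Build all model inputs from a trial scenario
#'
#' Runs the evidence-synthesis half of the pipeline: generates synthetic IPD,
#' digitizes per-arm mortality and diagnosis Kaplan-Meier curves with
#' numbers-at-risk tables, reconstructs pseudo-IPD by the Guyot algorithm,
#' fits the Royston-Parmar spline model with time-varying arm effects
#' (mortality), fits the five parametric families per arm for mortality
#' (structural-uncertainty regimes) and for incidence (BIC-selected per arm,
#' used in all regimes), and pools the other-cause mortality rate from the
#' generated cohort.
#'
#' @param scenario a [trial_scenario()].
#' @param n_internal_knots spline knots for the mortality model.
#' @param noise_sd digitization noise (survival-probability units).
#' @param seed seed for data generation (defaults to the scenario's).
#' @param life_table life table for other-cause extrapolation.
#' @return object of class `ova_inputs`.
#' @export
build_model_inputs <- function(scenario = trial_scenario(),
                               n_internal_knots = 2, noise_sd = 0,
                               seed = NULL, life_table = synthetic_life_table()) {
  ipd <- generate_ipd(scenario, seed)
  fy <- scenario$followup_years
  recon_mort <- recon_inc <- list()
  for (a in ARMS) {
    dg <- digitize_curve(ipd, a, endpoint = "oc_death", noise_sd = noise_sd)
    recon_mort[[a]] <- reconstruct_ipd(dg$curve, dg$risk)
    dgi <- digitize_curve(ipd, a, endpoint = "diagnosis", noise_sd = noise_sd)
    recon_inc[[a]] <- reconstruct_ipd(dgi$curve, dgi$risk)
  }
  mort_all <- do.call(rbind, lapply(ARMS, function(a) {
    data.frame(time = recon_mort[[a]]$time, event = recon_mort[[a]]$event,
               arm = a)
  }))
  mort_all$arm <- factor(mort_all$arm, levels = ARMS)
  spline_fit <- fit_spline_hr(mort_all, n_internal_knots)

  fit_grid <- function(recon) {
    lapply(recon, function(d) {
      fits <- lapply(PAR_FAMILIES, function(f) {
        tryCatch(fit_parametric(d, f), error = function(e) NULL)
      })
      stats::setNames(fits, PAR_FAMILIES)
    })
  }
  fits_mort <- fit_grid(recon_mort)
  fits_inc <- fit_grid(recon_inc)
  # same family across arms for incidence: keeps the three arms' lifetime
  # diagnosis extrapolations structurally comparable (and diagnoses ahead of
  # the arm-level mortality they must support)
  inc_sel <- select_family(fits_inc, "combined")

  oc_rate <- other_cause_rate(sum(ipd$event == "other_death"), sum(ipd$time))

  structure(list(scenario = scenario, ipd_summary = summary(ipd$event),
                 recon_mort = recon_mort, recon_inc = recon_inc,
                 spline_fit = spline_fit, fits_mort = fits_mort,
                 fits_inc = fits_inc, inc_sel = inc_sel,
                 other_cause_rate = oc_rate, trial_years = fy,
                 entry_age = scenario$entry_age, life_table = life_table),
            class = "ova_inputs")
}

#' @export
print.ova_inputs <- function(x, ...) {
  cat("Model inputs built from reconstructed pseudo-IPD\n")
  cat(sprintf("  trial years: %d; pooled other-cause rate: %.4f%% / year\n",
              x$trial_years, 100 * x$other_cause_rate))
  cat(sprintf("  incidence families: %s\n",
              paste(names(x$inc_sel$chosen), x$inc_sel$chosen, sep = "=",
                    collapse = ", ")))
  print(x$spline_fit)
  invisible(x)
}

#' Annual hazard and hazard-ratio trajectories over the model horizon
#'
#' Turns fitted within-trial models into lifetime annual trajectories under
#' one of four regimes: `"smoothing"` (base case: spline hazards and HRs
#' within trial, damped-trend exponential smoothing beyond),
#' `"separate-parametric"` and `"same-parametric"` (BIC-selected parametric
#' families per arm, evaluated across the whole horizon), and
#' `"discrepancy"` (the smoothing base case with the model-discrepancy
#' attenuation of the extrapolated screening effect).
#'
#' @param inputs an `ova_inputs` from [build_model_inputs()].
#' @param regime one of `"smoothing"`, `"separate-parametric"`,
#'   `"same-parametric"`, `"discrepancy"`.
#' @param horizon model years (default 40).
#' @param draw optional PSA draw (see [run_psa()]); `NULL` gives the
#'   deterministic trajectories (point estimates; the discrepancy
#'   attenuation at its mean).
#' @param discrepancy a [discrepancy_spec()] for the discrepancy regime.
#' @return list of class `ova_trajectories` with per-arm OC mortality
#'   hazards, screening-arm HRs, per-arm incidence hazards and other-cause
#'   probabilities.
#' @export
build_trajectories <- function(inputs, regime = "smoothing", horizon = 40,
                               draw = NULL, discrepancy = discrepancy_spec()) {
  regime <- match.arg(regime, EXTRAP_REGIMES)
  fy <- inputs$trial_years
  sp_tab <- spline_hazard_table(inputs$spline_fit, seq_len(fy),
                                coefs = draw$spline_coefs)
  oc_hazard <- list(); hr <- list()
  if (regime %in% c("smoothing", "discrepancy")) {
    h0 <- extrapolate_smoothing(sp_tab$hazard$none, horizon,
                                z = draw$z_h %||% 0)$hazard
    for (a in c("MMS", "USS")) {
      hr[[a]] <- extrapolate_hr_smoothing(sp_tab$hr[[a]], horizon,
                                          z = (draw$z_hr %||% c(MMS = 0, USS = 0))[[a]])
      if (regime == "discrepancy") {
        mult <- draw$disc_m[[a]] %||%
          rep(1 - discrepancy$annual_attenuation_mean, horizon - fy)
        hr[[a]] <- apply_discrepancy(hr[[a]], discrepancy, fy,
                                     multipliers = mult)
      }
    }
    oc_hazard <- list(none = h0, MMS = h0 * hr$MMS, USS = h0 * hr$USS)
  } else {
    sel <- select_family(inputs$fits_mort,
                         if (regime == "separate-parametric") "separate"
                         else "combined")
    for (a in ARMS) {
      fit <- inputs$fits_mort[[a]][[sel$chosen[[a]]]]
      params <- if (!is.null(draw$mort_coefs[[a]])) {
        par_from_transformed(fit$family, draw$mort_coefs[[a]])
      } else NULL
      oc_hazard[[a]] <- extrapolate_parametric(fit, horizon,
                                               params = params)$hazard
    }
    for (a in c("MMS", "USS")) {
      hr[[a]] <- oc_hazard[[a]] / pmax(oc_hazard$none, 1e-300)
    }
  }
  incidence <- list()
  for (a in ARMS) {
    fit <- inputs$fits_inc[[a]][[inputs$inc_sel$chosen[[a]]]]
    params <- if (!is.null(draw$inc_coefs[[a]])) {
      par_from_transformed(fit$family, draw$inc_coefs[[a]])
    } else NULL
    incidence[[a]] <- extrapolate_parametric(fit, horizon,
                                             params = params)$hazard
  }
  other_cause <- build_other_cause(inputs$other_cause_rate,
                                   entry_age = inputs$entry_age,
                                   trial_years = fy + 1,
                                   table = inputs$life_table,
                                   horizon = horizon)
  structure(list(oc_hazard = oc_hazard, hr = hr, incidence = incidence,
                 other_cause = other_cause, trial_years = fy,
                 horizon = horizon, regime = regime),
            class = "ova_trajectories")
}

#' Evaluate the three strategies for one parameter realisation
#'
#' @param traj an `ova_trajectories`.
#' @param params named parameter vector (draw or means).
#' @param stage_mix named list of per-strategy stage mixes (defaults to the
#'   scenario placeholders).
#' @param settings an [econ_settings()].
#' @param options a [model_options()].
#' @return named list of `ova_ce` results (`none`, `MMS`, `USS`).
#' @export
evaluate_strategies <- function(traj, params = parameter_means(),
                                stage_mix = NULL,
                                settings = econ_settings(),
                                options = model_options()) {
  H <- min(traj$horizon, settings$horizon)
  if (is.null(stage_mix)) {
    stage_mix <- list(
      none = stats::setNames(c(0.10, 0.20, 0.10, 0.40, 0.20), STAGES),
      MMS = stats::setNames(c(0.15, 0.30, 0.12, 0.32, 0.11), STAGES),
      USS = stats::setNames(c(0.13, 0.27, 0.12, 0.35, 0.13), STAGES))
  }
  out <- list()
  for (s in ARMS) {
    payoffs <- build_payoffs(s, params, stage_mix[[s]], options)
    sched <- build_schedule(
      oc_death_prob = 1 - exp(-traj$oc_hazard[[s]][seq_len(H)]),
      incidence_prob = 1 - exp(-traj$incidence[[s]][seq_len(H)]),
      other_cause_prob = traj$other_cause[seq_len(H)],
      screened = s != "none", n_screens = options$n_screens)
    out[[s]] <- run_cohort(sched, payoffs, settings)
  }
  out
}
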