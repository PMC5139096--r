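# Synthetic cohort generation: competing piecewise-exponential event times
# plus a latent diagnosis clock, and Kaplan-Meier "digitization" emulating
# coordinates read off a published figure.

# vectorised piecewise-exponential sampler; rates are annual hazards on
# consecutive unit-length intervals starting at 0, constant after the last.
rpexp_vec <- function(n, rates) {
  breaks <- seq_len(length(rates)) # right edges of the yearly bins
  H <- c(0, cumsum(rates))         # cumulative hazard at 0:length(rates)
  e <- stats::rexp(n)
  out <- rep(Inf, n)
  idx <- findInterval(e, H, left.open = FALSE)
  inside <- e < H[length(H)]
  i <- idx[inside]
  out[inside] <- (i - 1) + (e[inside] - H[i]) / rates[i]
  # beyond the table: continue at the final rate if positive
  last <- rates[length(rates)]
  if (last > 0) {
    beyond <- !inside
    out[beyond] <- length(rates) + (e[beyond] - H[length(H)]) / last
  }
  out
}

#' Generate synthetic individual-patient data for a screening trial
#'
#' Draws per-subject event histories from the competing piecewise-exponential
#' mechanism of a [trial_scenario()]: an ovarian-cancer death clock (baseline
#' hazard times the arm's time-varying hazard ratio), an other-cause death
#' clock, optional random censoring, and administrative censoring at the end
#' of follow-up. A latent diagnosis clock runs in parallel; a woman who dies
#' of ovarian cancer is recorded as diagnosed no later than her death (the
#' cohort-level mortality law is specified directly, as in arm-level trial
#' reporting, so diagnosis does not gate death).
#'
#' Ties between latent clocks are broken in favour of ovarian-cancer death
#' (the rarest event), then other-cause death, then censoring.
#'
#' @param scenario a [trial_scenario()].
#' @param seed overrides the scenario's stored seed when non-`NULL`.
#' @return a `data.frame` of class `synthetic_ipd` with columns `arm`,
#'   `time` (years), `event` (factor: `oc_death`, `other_death`, `censored`),
#'   `diag_time` (`NA` if never diagnosed) and `stage` (`NA` if undiagnosed).
#' @export
generate_ipd <- function(scenario, seed = NULL) {
  validate_scenario(scenario)
  fy <- scenario$followup_years
  if (is.null(seed)) seed <- scenario$seed
  set.seed(seed)
  res <- vector("list", length(scenario$arm_sizes))
  names(res) <- names(scenario$arm_sizes)
  for (a in names(scenario$arm_sizes)) {
    n <- scenario$arm_sizes[[a]]
    h_oc <- scenario$baseline_oc_mortality_hazard * scenario$hr_funs[[a]]
    t_oc <- rpexp_vec(n, c(h_oc, 0))           # no OC deaths beyond follow-up
    t_ot <- if (scenario$other_cause_hazard > 0) {
      stats::rexp(n, scenario$other_cause_hazard)
    } else rep(Inf, n)
    t_cn <- if (scenario$random_censoring_rate > 0) {
      stats::rexp(n, scenario$random_censoring_rate)
    } else rep(Inf, n)
    t_adm <- rep(fy, n)
    tmat <- cbind(oc_death = t_oc, other_death = t_ot, censored = pmin(t_cn, t_adm))
    time <- pmin(tmat[, 1], tmat[, 2], tmat[, 3])
    # tie-break order = column order (max.col with ties.method "first" on -t)
    event <- c("oc_death", "other_death", "censored")[
      max.col(-tmat, ties.method = "first")]
    d_lat <- rpexp_vec(n, c(scenario$incidence_hazard[[a]], 0))
    diag_time <- ifelse(d_lat < time, d_lat,
                        ifelse(event == "oc_death", time, NA_real_))
    stage <- rep(NA_character_, n)
    has_dx <- !is.na(diag_time)
    if (any(has_dx)) {
      stage[has_dx] <- sample(names(scenario$stage_mix[[a]]), sum(has_dx),
                              replace = TRUE, prob = scenario$stage_mix[[a]])
    }
    res[[a]] <- data.frame(arm = a, time = time, event = event,
                           diag_time = diag_time, stage = stage,
                           stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out$arm <- factor(out$arm, levels = names(scenario$arm_sizes))
  out$event <- factor(out$event, levels = c("oc_death", "other_death", "censored"))
  class(out) <- c("synthetic_ipd", "data.frame")
  attr(out, "followup_years") <- fy
  out
}

# time/status pair for a given endpoint, treating competing events as censoring
endpoint_surv <- function(ipd, arm, endpoint = c("oc_death", "diagnosis")) {
  endpoint <- match.arg(endpoint)
  d <- ipd[ipd$arm == arm, , drop = FALSE]
  if (nrow(d) == 0) stop(sprintf("arm '%s' has no subjects", arm))
  if (endpoint == "oc_death") {
    data.frame(time = d$time, status = as.integer(d$event == "oc_death"))
  } else {
    dx <- !is.na(d$diag_time)
    data.frame(time = ifelse(dx, d$diag_time, d$time),
               status = as.integer(dx))
  }
}

#' Emulate digitized Kaplan-Meier coordinates and a numbers-at-risk table
#'
#' Evaluates the exact Kaplan-Meier estimator for one arm and endpoint on a
#' time grid, optionally perturbs the coordinates with additive Gaussian noise
#' (emulating manual curve digitization), re-monotonises the noisy curve by a
#' decreasing isotonic projection, and tabulates the numbers at risk at the
#' stated times.
#'
#' @param ipd a `synthetic_ipd` from [generate_ipd()].
#' @param arm arm label.
#' @param grid time points (years) at which curve coordinates are read;
#'   defaults to a monthly grid over follow-up.
#' @param noise_sd standard deviation of the digitization noise, in survival
#'   probability units.
#' @param endpoint `"oc_death"` (mortality curve; other deaths censored) or
#'   `"diagnosis"` (diagnosis-free survival).
#' @param risk_times times for the numbers-at-risk table (default: whole
#'   years).
#' @param seed optional seed for the noise draw.
#' @return list with `curve` (`data.frame(time, survival)`) and `risk`
#'   (`data.frame(time, n_at_risk)`).
#' @export
digitize_curve <- function(ipd, arm, grid = NULL, noise_sd = 0,
                           endpoint = c("oc_death", "diagnosis"),
                           risk_times = NULL, seed = NULL) {
  endpoint <- match.arg(endpoint)
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  ts <- endpoint_surv(ipd, arm, endpoint)
  fy <- attr(ipd, "followup_years")
  if (is.null(fy)) fy <- max(ipd$time)
  if (is.null(grid)) grid <- seq(0, fy, by = 1 / 12)
  if (any(grid < 0) || any(grid > fy + 1e-9)) {
    stop("grid must lie within follow-up")
  }
  if (is.null(risk_times)) risk_times <- 0:floor(fy)
  km <- km_curve(ts$time, ts$status, grid)
  s <- km$survival
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    s <- s + stats::rnorm(length(s), 0, noise_sd)
    s[grid == 0] <- 1
    s <- iso_decreasing(s)
    s <- pmin(pmax(s, 0), 1)
  }
  n_at_risk <- vapply(risk_times, function(tt) sum(ts$time >= tt - 1e-12), 0L)
  list(curve = data.frame(time = grid, survival = s),
       risk = data.frame(time = risk_times, n_at_risk = n_at_risk))
}

# decreasing isotonic projection (least squares), via isoreg on the negated
# series
iso_decreasing <- function(y) {
  -stats::isoreg(seq_along(y), -y)$yf
}

#' Write synthetic IPD and digitized curves to CSV
#' @param x object to write (`synthetic_ipd`, or the list returned by
#'   [digitize_curve()]).
#' @param path for IPD, a file path; for a digitized curve, a base path to
#'   which `_curve.csv` and `_risk.csv` are appended.
#' @return written path(s), invisibly.
#' @export
write_ipd_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ipd_csv
#' @export
write_curve_csv <- function(x, path) {
  p1 <- paste0(path, "_curve.csv"); p2 <- paste0(path, "_risk.csv")
  utils::write.csv(x$curve, p1, row.names = FALSE)
  utils::write.csv(x$risk, p2, row.names = FALSE)
  invisible(c(p1, p2))
}
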