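# Survival fitting: the five standard parametric families (via flexsurv)
# with BIC selection under two regimes, and Royston-Parmar spline models with
# time-varying arm effects for the hazard-ratio analysis.

PAR_FAMILIES <- c("exponential", "weibull", "gompertz", "log-logistic", "log-normal")
.flexsurv_dist <- c(exponential = "exp", weibull = "weibull", gompertz = "gompertz",
                    `log-logistic` = "llogis", `log-normal` = "lnorm")

# collapse tied (time, status) rows into weights; reconstructed IPD places
# events on the digitized grid and censorings at a handful of times, so this
# turns ~1e5 rows into a few hundred and makes repeated ML fits cheap
aggregate_surv <- function(time, status) {
  key <- paste(time, status)
  agg <- stats::aggregate(list(w = rep(1L, length(time))),
                          by = list(time = time, status = status), FUN = sum)
  agg
}

#' Fit a standard parametric survival model
#'
#' Maximum-likelihood fit of one of the five standard families (exponential,
#' Weibull, Gompertz, log-logistic, log-normal) to right-censored IPD, via
#' [flexsurv::flexsurvreg()]. Tied observations are aggregated into case
#' weights before fitting. BIC is computed as `k * log(n) - 2 * logLik` with
#' `n` the number of subjects.
#'
#' @param ipd `data.frame` with columns `time` and `event` (1/0).
#' @param family one of `"exponential"`, `"weibull"`, `"gompertz"`,
#'   `"log-logistic"`, `"log-normal"`.
#' @return object of class `ova_parfit`: family, natural-scale parameters,
#'   transformed-scale estimates with covariance (for PSA draws),
#'   log-likelihood, BIC, `n`.
#' @export
fit_parametric <- function(ipd, family = PAR_FAMILIES) {
  family <- match.arg(family)
  ev <- if (is.numeric(ipd$event)) ipd$event else as.integer(ipd$event == 1)
  if (sum(ev) < 2) stop("need at least 2 events to fit a parametric model")
  agg <- aggregate_surv(ipd$time, ev)
  agg$time <- pmax(agg$time, 1e-8) # parametric likelihoods need t > 0
  fit <- tryCatch(
    flexsurv::flexsurvreg(survival::Surv(time, status) ~ 1, data = agg,
                          weights = w, dist = .flexsurv_dist[[family]]),
    error = function(e) e, warning = function(w) w
  )
  if (inherits(fit, "condition") || !is.finite(fit$loglik)) {
    msg <- if (inherits(fit, "condition")) conditionMessage(fit) else "non-finite log-likelihood"
    stop(sprintf("%s fit failed to converge: %s", family, msg))
  }
  n <- sum(agg$w)
  k <- nrow(fit$res)
  out <- list(family = family,
              params = stats::setNames(fit$res[, "est"], rownames(fit$res)),
              coef_t = stats::setNames(fit$res.t[, "est"], rownames(fit$res.t)),
              vcov_t = fit$cov,
              loglik = fit$loglik,
              bic = k * log(n) - 2 * fit$loglik,
              n = n, n_events = sum(agg$w * agg$status), k = k)
  class(out) <- "ova_parfit"
  out
}

#' @export
print.ova_parfit <- function(x, ...) {
  cat(sprintf("%s fit: n = %d (%d events), logLik = %.2f, BIC = %.2f\n",
              x$family, x$n, x$n_events, x$loglik, x$bic))
  print(round(x$params, 6))
  invisible(x)
}

# natural-scale parameters from a transformed-scale draw
par_from_transformed <- function(family, coef_t) {
  switch(family,
    exponential = c(rate = exp(coef_t[[1]])),
    weibull = c(shape = exp(coef_t[[1]]), scale = exp(coef_t[[2]])),
    gompertz = c(shape = coef_t[[1]], rate = exp(coef_t[[2]])),
    `log-logistic` = c(shape = exp(coef_t[[1]]), scale = exp(coef_t[[2]])),
    `log-normal` = c(meanlog = coef_t[[1]], sdlog = exp(coef_t[[2]]))
  )
}

# cumulative hazard of a fitted family at times t (optionally with replaced
# natural-scale parameters, e.g. a PSA draw)
cumhaz_parametric <- function(fit, t, params = NULL) {
  p <- if (is.null(params)) fit$params else params
  H <- switch(fit$family,
    exponential = p[["rate"]] * t,
    weibull = (t / p[["scale"]])^p[["shape"]],
    gompertz = {
      a <- p[["shape"]]; b <- p[["rate"]]
      if (abs(a) < 1e-12) b * t else b / a * (exp(a * t) - 1)
    },
    `log-logistic` = log1p((t / p[["scale"]])^p[["shape"]]),
    `log-normal` = -stats::plnorm(t, p[["meanlog"]], p[["sdlog"]],
                                  lower.tail = FALSE, log.p = TRUE)
  )
  pmax(H, 0)
}

#' Select a parametric family by BIC
#'
#' Given a grid of fitted families per arm, picks the BIC-minimising family
#' either separately per arm or as a single family shared across arms
#' (minimising the summed BIC).
#'
#' @param fits nested list `fits[[arm]][[family]]` of [fit_parametric()]
#'   results; failed fits may be `NULL` and are excluded with a warning.
#' @param regime `"separate"` (per-arm winner) or `"combined"` (shared
#'   winner by summed BIC).
#' @return object of class `ova_selection`: `regime`, named `chosen` family
#'   per arm, and the full `bic_table` (arms x families).
#' @export
select_family <- function(fits, regime = c("separate", "combined")) {
  regime <- match.arg(regime)
  arms <- names(fits)
  fams <- unique(unlist(lapply(fits, names)))
  bic <- matrix(NA_real_, length(arms), length(fams),
                dimnames = list(arms, fams))
  for (a in arms) for (f in names(fits[[a]])) {
    if (!is.null(fits[[a]][[f]])) bic[a, f] <- fits[[a]][[f]]$bic
  }
  if (any(is.na(bic))) {
    warning("some fits failed and were excluded from selection")
  }
  if (all(is.na(bic))) stop("all parametric fits failed")
  if (regime == "separate") {
    chosen <- apply(bic, 1, function(r) colnames(bic)[which.min(r)])
  } else {
    tot <- colSums(bic) # NA propagates: a family must fit in every arm
    if (all(is.na(tot))) stop("no family fitted successfully in all arms")
    chosen <- stats::setNames(rep(names(which.min(tot)), length(arms)), arms)
  }
  structure(list(regime = regime, chosen = chosen, bic_table = bic),
            class = "ova_selection")
}

#' @export
print.ova_selection <- function(x, ...) {
  cat(sprintf("BIC model selection (%s regime)\n", x$regime))
  print(round(x$bic_table, 2))
  cat("chosen:", paste(names(x$chosen), x$chosen, sep = " = ", collapse = ", "), "\n")
  invisible(x)
}

#' Royston-Parmar spline model with time-varying arm effects
#'
#' Fits a flexible parametric model in which the log cumulative hazard is a
#' restricted cubic spline in log time, the baseline arm enters the intercept
#' and, when `tv = TRUE`, the screening arms also shift the linear log-time
#' coefficient, yielding time-varying log hazard ratios (the model used by
#' the trial analysts for delayed screening effects). Fitting is delegated to
#' [flexsurv::flexsurvspline()] on weight-aggregated data.
#'
#' @param ipd `data.frame` with columns `time`, `event` (1/0) and `arm`
#'   (factor; first level is the baseline/no-screening arm).
#' @param n_internal_knots number of internal knots on log time (default 2,
#'   placed at tertiles of uncensored log event times).
#' @param tv allow time-varying arm effects (`FALSE` gives proportional
#'   hazards on the log-cumulative-hazard scale).
#' @return object of class `ova_splinefit` with coefficients, covariance,
#'   knots and bookkeeping needed to evaluate per-arm cumulative hazards.
#' @export
fit_spline_hr <- function(ipd, n_internal_knots = 2, tv = TRUE) {
  ev <- if (is.numeric(ipd$event)) ipd$event else as.integer(ipd$event == 1)
  arm <- droplevels(as.factor(ipd$arm))
  agg <- stats::aggregate(list(w = rep(1L, nrow(ipd))),
                          by = list(time = pmax(ipd$time, 1e-8), status = ev,
                                    arm = arm), FUN = sum)
  fml <- if (tv) Surv(time, status) ~ arm + gamma1(arm) else
    Surv(time, status) ~ arm
  fit <- tryCatch(
    flexsurv::flexsurvspline(fml, data = agg, weights = w,
                             k = n_internal_knots, scale = "hazard"),
    error = function(e) e
  )
  if (inherits(fit, "error")) {
    stop(sprintf(paste0("spline fit failed (%s); with few events try fewer ",
                        "internal knots"), conditionMessage(fit)))
  }
  out <- list(knots = fit$knots,
              coef = fit$res.t[, "est"],
              vcov = fit$cov,
              loglik = fit$loglik,
              n = sum(agg$w),
              n_events = sum(agg$w * agg$status),
              arms = levels(arm), tv = tv, k = n_internal_knots)
  class(out) <- "ova_splinefit"
  out
}

#' @export
print.ova_splinefit <- function(x, ...) {
  cat(sprintf(paste0("Royston-Parmar spline fit: %d internal knots, arms %s\n",
                     "  n = %d (%d events), logLik = %.2f, time-varying effects: %s\n"),
              x$k, paste(x$arms, collapse = "/"), x$n, x$n_events, x$loglik,
              x$tv))
  invisible(x)
}

# restricted cubic spline basis on log time (natural spline form used by
# flexsurv: s(x) = g0 + g1 x + sum_j g_{j+1} v_j(x))
rp_basis <- function(knots, x) {
  kmin <- knots[1]; kmax <- knots[length(knots)]
  B <- cbind(1, x)
  if (length(knots) > 2) {
    for (j in 2:(length(knots) - 1)) {
      kj <- knots[j]
      lam <- (kmax - kj) / (kmax - kmin)
      B <- cbind(B, pmax(x - kj, 0)^3 - lam * pmax(x - kmin, 0)^3 -
                   (1 - lam) * pmax(x - kmax, 0)^3)
    }
  }
  B
}

# per-arm log cumulative hazard evaluated at times t from a (possibly drawn)
# coefficient vector
spline_cumhaz <- function(fit, t, arm, coefs = NULL) {
  if (is.null(coefs)) coefs <- fit$coef
  ng <- fit$k + 2
  x <- log(pmax(t, 1e-12))
  B <- rp_basis(fit$knots, x)
  gam <- coefs[seq_len(ng)]
  if (arm != fit$arms[1]) {
    g0nm <- paste0("arm", arm)
    gam[1] <- gam[1] + coefs[[g0nm]]
    g1nm <- paste0("gamma1(arm", arm, ")")
    if (g1nm %in% names(coefs)) gam[2] <- gam[2] + coefs[[g1nm]]
  }
  exp(as.vector(B %*% gam))
}

# annual hazard increments (cumulative-hazard differences) per model year
spline_annual_hazards <- function(fit, years, arm, coefs = NULL) {
  H <- spline_cumhaz(fit, c(1e-8, years), arm, coefs)
  pmax(diff(H), 0)
}

#' Annual hazards and hazard ratios from a spline fit
#'
#' Evaluates per-arm annual hazards (cumulative-hazard increments over model
#' years) and screening-arm hazard ratios relative to the baseline arm.
#'
#' @param fit an `ova_splinefit`.
#' @param years vector of whole model years (e.g. `1:11`).
#' @param coefs optional replacement coefficient vector (PSA draw).
#' @return list with `hazard` (named list of per-arm annual hazards) and
#'   `hr` (named list per screening arm).
#' @export
spline_hazard_table <- function(fit, years, coefs = NULL) {
  hz <- lapply(fit$arms, function(a) spline_annual_hazards(fit, years, a, coefs))
  names(hz) <- fit$arms
  base <- hz[[fit$arms[1]]]
  hr <- lapply(fit$arms[-1], function(a) {
    r <- hz[[a]] / pmax(base, 1e-300)
    pmax(r, 1e-6)
  })
  names(hr) <- fit$arms[-1]
  list(hazard = hz, hr = hr)
}

#' Export fit summaries as CSV
#' @param fits nested list `fits[[arm]][[family]]` of `ova_parfit` objects.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_fit_summary_csv <- function(fits, path) {
  rows <- list()
  for (a in names(fits)) for (f in names(fits[[a]])) {
    ft <- fits[[a]][[f]]
    if (is.null(ft)) next
    rows[[length(rows) + 1]] <- data.frame(
      arm = a, family = f,
      params = paste(sprintf("%s=%.6g", names(ft$params), ft$params),
                     collapse = ";"),
      loglik = ft$loglik, bic = ft$bic, n = ft$n)
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
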