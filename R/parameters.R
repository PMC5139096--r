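# Cost, utility and false-positive-rate parameters: the key model input
# table, distribution fitting from (mean, 95% CI) summaries, and assembly of
# the payoff map consumed by the Markov engine.

#' The key model input table
#'
#' Costs (2013/14 GBP), utilities/disutilities and false positives per cancer
#' identified, each with a distribution family and 95% confidence interval,
#' as used by the probabilistic analysis. Shipped as plain CSV in
#' `extdata/parameters.csv`.
#'
#' @param path optional alternative CSV (columns `name`, `mean`, `family`,
#'   `ci_low`, `ci_high`).
#' @return `data.frame` of parameter rows.
#' @export
parameter_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "parameters.csv", package = "ovascreen")
  }
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("name", "mean", "family", "ci_low", "ci_high") %in% names(x)))
  x
}

#' Named vector of parameter means
#' @param table a [parameter_table()].
#' @return named numeric vector.
#' @export
parameter_means <- function(table = parameter_table()) {
  stats::setNames(table$mean, table$name)
}

# scale-free squared error on the two target percentiles
ci_loss <- function(q, ci) {
  sum(((q - ci) / pmax(abs(ci), 1e-12))^2)
}

#' Fit a sampling distribution to a (mean, 95% CI) summary
#'
#' Finds distribution parameters that match the published mean exactly and
#' minimise the squared error of the 2.5th/97.5th percentiles against the
#' published interval. Families: `gamma` (shape free, rate fixed by the
#' mean); `beta` (precision free; values with support outside \[0,1\], such
#' as false positives per cancer, are modelled as a scaled beta on
#' \[0, 2 x mean\]); `hybrid` (equal-mean mixture of a gamma and a scaled
#' beta with jointly fitted shape parameters and mixture weight — an
#' approximation, since the source's exact construction is not public). A
#' degenerate interval equal to the mean gives a point mass.
#'
#' @param mean published mean.
#' @param ci length-2 vector (lower, upper).
#' @param family `"gamma"`, `"beta"` or `"hybrid"`.
#' @param name label used in error messages.
#' @return object of class `param_dist` with elements `r` (sampler
#'   `function(n)`), `q` (quantile function), `achieved` (mean and
#'   percentiles of the fitted distribution) and `ok` flags for the
#'   mean-within-0.5% / CI-within-2% checks.
#' @export
fit_distribution <- function(mean, ci, family = c("gamma", "beta", "hybrid"),
                             name = "parameter") {
  family <- match.arg(family)
  lo <- ci[1]; hi <- ci[2]
  if (lo == mean && hi == mean) {
    out <- list(family = "point", mean = mean, ci = ci, pars = NULL,
                r = function(n) rep(mean, n),
                q = function(p) rep(mean, length(p)),
                achieved = c(mean = mean, q025 = mean, q975 = mean),
                ok = c(mean = TRUE, ci = TRUE))
    class(out) <- "param_dist"
    return(out)
  }
  if (!(lo < mean && mean < hi)) {
    stop(sprintf("infeasible summary for '%s': mean must lie inside the CI",
                 name))
  }
  if (family == "gamma") {
    qf <- function(k) stats::qgamma(c(0.025, 0.975), shape = k, rate = k / mean)
    op <- stats::optimize(function(lk) ci_loss(qf(exp(lk)), ci), c(-5, 15))
    k <- exp(op$minimum)
    pars <- c(shape = k, rate = k / mean)
    r <- function(n) stats::rgamma(n, pars[["shape"]], pars[["rate"]])
    q <- function(p) stats::qgamma(p, pars[["shape"]], pars[["rate"]])
  } else if (family == "beta") {
    if (mean < 1 && hi <= 1 && lo >= 0) {
      m <- mean; scale <- 1
    } else {
      scale <- 2 * mean; m <- 0.5 # scaled support [0, 2*mean]
    }
    qf <- function(v) scale * stats::qbeta(c(0.025, 0.975),
                                           (mean / scale) * v,
                                           (1 - mean / scale) * v)
    op <- stats::optimize(function(lv) ci_loss(qf(exp(lv)), ci), c(-5, 20))
    v <- exp(op$minimum)
    pars <- c(alpha = (mean / scale) * v, beta = (1 - mean / scale) * v,
              scale = scale)
    r <- function(n) pars[["scale"]] *
      stats::rbeta(n, pars[["alpha"]], pars[["beta"]])
    q <- function(p) pars[["scale"]] *
      stats::qbeta(p, pars[["alpha"]], pars[["beta"]])
  } else {
    # hybrid: mixture of a gamma and a scaled beta on the cost scale; both
    # component means are pinned at the target mean (the beta through its
    # fitted support), so the mixture mean is exact for any weight
    mix_q <- function(p, k, a, U, w) {
      b <- a * (U - mean) / mean
      vapply(p, function(pp) {
        f <- function(x) w * stats::pgamma(x, k, k / mean) +
          (1 - w) * stats::pbeta(pmin(x / U, 1), a, b) - pp
        stats::uniroot(f, c(1e-9, mean * 50), extendInt = "upX",
                       tol = 1e-9)$root
      }, 0)
    }
    obj <- function(p) {
      k <- exp(p[1]); a <- exp(p[2])
      U <- mean * (1 + exp(p[3])); w <- stats::plogis(p[4])
      ci_loss(mix_q(c(0.025, 0.975), k, a, U, w), ci)
    }
    op <- list(value = Inf)
    for (start in list(c(3, 1, 0, 0), c(2, 2, 1, 1), c(4, 0.5, -0.5, -1))) {
      cand <- stats::optim(start, obj,
                           control = list(maxit = 2000, reltol = 1e-12))
      if (cand$value < op$value) op <- cand
    }
    k <- exp(op$par[1]); a <- exp(op$par[2])
    U <- mean * (1 + exp(op$par[3])); w <- stats::plogis(op$par[4])
    b <- a * (U - mean) / mean
    pars <- c(shape = k, rate = k / mean, alpha = a, beta = b, upper = U,
              weight = w)
    r <- function(n) {
      g <- stats::runif(n) < w
      out <- numeric(n)
      out[g] <- stats::rgamma(sum(g), k, k / mean)
      out[!g] <- U * stats::rbeta(sum(!g), a, b)
      out
    }
    q <- function(p) mix_q(p, k, a, U, w)
  }
  qs <- q(c(0.025, 0.975))
  # fitted mean: analytic for all three constructions (components match the
  # target mean by design)
  achieved <- c(mean = mean, q025 = qs[1], q975 = qs[2])
  ok <- c(mean = TRUE,
          ci = all(abs(qs - ci) / pmax(abs(ci), 1e-12) <= 0.02))
  out <- list(family = family, mean = mean, ci = ci, pars = pars, r = r,
              q = q, achieved = achieved, ok = ok, name = name)
  class(out) <- "param_dist"
  out
}

#' @export
print.param_dist <- function(x, ...) {
  cat(sprintf("%s ~ %s: mean %.4g, fitted 95%% interval (%.4g, %.4g), target (%.4g, %.4g)\n",
              x$name %||% "parameter", x$family, x$mean,
              x$achieved[["q025"]], x$achieved[["q975"]], x$ci[1], x$ci[2]))
  invisible(x)
}

#' Fit all distributions in a parameter table
#' @param table a [parameter_table()].
#' @return named list of `param_dist` objects.
#' @export
fit_all_distributions <- function(table = parameter_table()) {
  out <- lapply(seq_len(nrow(table)), function(i) {
    fit_distribution(table$mean[i], c(table$ci_low[i], table$ci_high[i]),
                     table$family[i], table$name[i])
  })
  names(out) <- table$name
  out
}

#' Sample parameter sets
#'
#' One row per PSA draw, one column per parameter; uses the current RNG
#' stream (set the seed outside for reproducibility).
#'
#' @param dists named list from [fit_all_distributions()].
#' @param n number of draws.
#' @return numeric matrix `n` x parameters.
#' @export
sample_parameters <- function(dists, n) {
  m <- vapply(dists, function(d) d$r(n), numeric(n))
  if (n == 1) m <- matrix(m, nrow = 1, dimnames = list(NULL, names(dists)))
  m
}

#' Model options and sensitivity toggles
#'
#' @param n_screens annual screening rounds costed (default 7, consistent
#'   with a per-woman screening cost of roughly £400).
#' @param completion_frac fraction of invited women completing each screen
#'   (the remainder incur the drop-out cost).
#' @param screening_disutility annual utility decrement while being screened
#'   (0 in the base case; 0.01 or 0.005 in sensitivity analyses).
#' @param roca_cost additional per-screen cost of the risk-algorithm test for
#'   MMS (0 in the base case; the sensitivity analysis uses a placeholder
#'   £20, the source's value not being public).
#' @param mms_cost_variant `"base"`, `"high"` or `"low"`: replaces the mean
#'   complete-screen MMS cost by the corresponding CI bound.
#' @param primary_care_fp apply the MMS false-positive rate to diagnoses in
#'   the no-screening arm (diagnosis through primary care).
#' @param fp_enabled include the false-positive load at all.
#' @param screen_detected_frac fraction of diagnoses during the screening
#'   period attributed to screening (drives the false-positive count).
#' @return list of class `model_options`.
#' @export
model_options <- function(n_screens = 7, completion_frac = 0.8,
                          screening_disutility = 0, roca_cost = 0,
                          mms_cost_variant = c("base", "high", "low"),
                          primary_care_fp = FALSE, fp_enabled = TRUE,
                          screen_detected_frac = 1) {
  structure(list(n_screens = n_screens, completion_frac = completion_frac,
                 screening_disutility = screening_disutility,
                 roca_cost = roca_cost,
                 mms_cost_variant = match.arg(mms_cost_variant),
                 primary_care_fp = primary_care_fp, fp_enabled = fp_enabled,
                 screen_detected_frac = screen_detected_frac),
            class = "model_options")
}

STAGES <- c("borderline", "I", "II", "III", "IV")

#' Assemble the payoff map for one strategy
#'
#' Maps one parameter realisation (one PSA draw, or the table means) plus a
#' per-strategy stage mix at diagnosis into the per-state utilities and
#' one-off costs consumed by [run_cohort()]. Diagnosis and treatment costs
#' and the first-year disutility are stage-mix weighted; borderline tumours
#' carry the Stage-1 disutility (a documented placeholder). A false positive
#' costs one Stage-1 treatment and one year of Stage-1 disutility.
#'
#' @param strategy `"none"`, `"MMS"` or `"USS"`.
#' @param params named numeric vector (one draw or [parameter_means()]).
#' @param stage_mix probability vector over `borderline, I, II, III, IV`.
#' @param options a [model_options()].
#' @return list of class `payoff_map`.
#' @export
build_payoffs <- function(strategy, params = parameter_means(),
                          stage_mix = NULL, options = model_options()) {
  if (!strategy %in% c("none", "MMS", "USS")) {
    stop(sprintf("unknown strategy '%s'", strategy))
  }
  if (is.null(stage_mix)) {
    stage_mix <- stats::setNames(c(0.10, 0.20, 0.10, 0.40, 0.20), STAGES)
  }
  stopifnot(abs(sum(stage_mix) - 1) < 1e-8)
  p <- params
  diag_costs <- c(p[["cost_diag_borderline"]], p[["cost_diag_stage1"]],
                  p[["cost_diag_stage2"]], p[["cost_diag_stage3"]],
                  p[["cost_diag_stage4"]])
  treat_costs <- c(p[["cost_treat_borderline"]], p[["cost_treat_stage1"]],
                   p[["cost_treat_stage2"]], p[["cost_treat_stage3"]],
                   p[["cost_treat_stage4"]])
  disutil <- c(p[["disutility_stage1_or_fp"]], p[["disutility_stage1_or_fp"]],
               p[["disutility_stage2"]], p[["disutility_stage3"]],
               p[["disutility_stage4"]])
  mms_complete <- switch(options$mms_cost_variant,
                         base = p[["cost_screen_mms_complete"]],
                         high = 83, low = 37)
  cost_screen <- switch(strategy,
    none = 0,
    MMS = options$completion_frac * (mms_complete + options$roca_cost) +
      (1 - options$completion_frac) * p[["cost_screen_mms_dropout"]],
    USS = options$completion_frac * p[["cost_screen_uss_complete"]] +
      (1 - options$completion_frac) * p[["cost_screen_uss_dropout"]])
  fp_ratio <- if (!options$fp_enabled) 0 else switch(strategy,
    none = if (options$primary_care_fp) p[["fp_per_cancer_mms"]] else 0,
    MMS = p[["fp_per_cancer_mms"]],
    USS = p[["fp_per_cancer_uss"]])
  out <- list(strategy = strategy,
              utility_well = min(p[["utility_cancer_free"]], 1),
              disutility_first_year = sum(stage_mix * disutil),
              cost_diag = sum(stage_mix * diag_costs),
              cost_treat = sum(stage_mix * treat_costs),
              cost_eol = p[["cost_end_of_life"]],
              cost_screen = cost_screen,
              cost_invitation = if (strategy == "none") 0 else
                p[["cost_invitation"]],
              fp_ratio = fp_ratio,
              fp_cost = p[["cost_treat_stage1"]],
              fp_disutility = p[["disutility_stage1_or_fp"]],
              fp_in_unscreened = options$primary_care_fp,
              screen_disutility = options$screening_disutility,
              screen_detected_frac = options$screen_detected_frac,
              n_screens = options$n_screens)
  class(out) <- "payoff_map"
  out
}
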