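# Value-of-information analysis: expected value of perfect information from
# the PSA net-benefit matrix, and regression-based expected value of partial
# perfect information (nonparametric regression of net benefit on parameter
# subsets, per Strong and colleagues' single-loop estimator).

#' Net-benefit matrix at a willingness-to-pay value
#' @param psa an `ova_psa`.
#' @param lambda willingness to pay (£/QALY).
#' @return draws x strategies matrix of net benefit `lambda*QALY - cost`.
#' @export
net_benefit <- function(psa, lambda) {
  lambda * psa$qaly - psa$cost
}

#' Per-person expected value of perfect information
#'
#' Mean over draws of the per-draw maximum net benefit, minus the maximum
#' over strategies of the mean net benefit.
#'
#' @param nb draws x strategies net-benefit matrix.
#' @return per-person EVPI (same monetary units as `nb`).
#' @export
evpi <- function(nb) {
  nb <- as.matrix(nb)
  if (ncol(nb) < 2) stop("need at least 2 strategies")
  if (any(!is.finite(nb))) stop("net benefits must be finite")
  mean(apply(nb, 1, max)) - max(colMeans(nb))
}

#' Population settings for value-of-information scaling
#'
#' @param eligible annual number of women in the eligible age range
#'   (default 7,121,000).
#' @param affected number affected by the funding decision after adjusting
#'   for uptake and compliance (default 1,045,914).
#' @param horizon_years decision horizon (default 1; the population figure
#'   implicitly covers the relevant years).
#' @return list of class `population_settings`.
#' @export
population_settings <- function(eligible = 7121000, affected = 1045914,
                                horizon_years = 1) {
  if (affected > eligible) stop("affected population cannot exceed eligible")
  structure(list(eligible = eligible, affected = affected,
                 horizon_years = horizon_years),
            class = "population_settings")
}

#' Scale a per-person value to the population
#' @param per_person per-person value (>= 0).
#' @param pop a [population_settings()].
#' @return population value.
#' @export
population_scale <- function(per_person, pop = population_settings()) {
  if (any(per_person < 0)) stop("per-person value must be >= 0")
  per_person * pop$affected * pop$horizon_years
}

#' EVPI across a willingness-to-pay grid
#' @param psa an `ova_psa`.
#' @param wtp willingness-to-pay grid.
#' @param pop optional [population_settings()]; when supplied a population
#'   EVPI column is added.
#' @return `data.frame(wtp, evpi[, evpi_pop])`.
#' @export
evpi_curve <- function(psa, wtp = seq(0, 40000, by = 500), pop = NULL) {
  ev <- vapply(wtp, function(l) evpi(net_benefit(psa, l)), 0)
  out <- data.frame(wtp = wtp, evpi = ev)
  if (!is.null(pop)) out$evpi_pop <- population_scale(ev, pop)
  out
}

#' Regression-based EVPPI for a parameter subset
#'
#' Estimates the expected value of perfect information about a subset of
#' parameters by regressing each strategy's net benefit on the subset with a
#' penalized smooth (a generalized additive model): the fitted values
#' estimate the conditional expectation of net benefit given the subset, and
#' EVPPI = mean of the per-draw maximum fitted value minus the maximum of
#' the mean fitted values. A Monte Carlo standard error is attached by
#' resampling rows of the fitted values.
#'
#' @param nb draws x strategies net-benefit matrix.
#' @param params draws x parameters matrix (e.g. `psa$params`).
#' @param group character vector of column names (1 to 4 parameters; larger
#'   groups need dimension reduction first).
#' @param n_boot bootstrap resamples for the standard error.
#' @return list of class `ova_evppi`: `evppi`, `se`, `group`.
#' @export
evppi_regression <- function(nb, params, group, n_boot = 200) {
  nb <- as.matrix(nb)
  if (nrow(nb) < 500) stop("need at least 500 draws for EVPPI regression")
  if (!length(group)) stop("parameter group must be non-empty")
  if (!all(group %in% colnames(params))) {
    stop("unknown parameter(s): ",
         paste(setdiff(group, colnames(params)), collapse = ", "))
  }
  d <- length(group)
  if (d > 4) stop("EVPPI regression supports groups of up to 4 parameters")
  X <- as.data.frame(params[, group, drop = FALSE])
  names(X) <- paste0("x", seq_len(d))
  degen <- vapply(X, function(v) stats::var(v) < 1e-24, TRUE)
  if (all(degen)) return(structure(list(evppi = 0, se = 0, group = group),
                                   class = "ova_evppi"))
  X <- X[, !degen, drop = FALSE]
  d <- ncol(X)
  rhs <- if (d == 1) "s(x1, k = 10)" else {
    kk <- c(`2` = 6, `3` = 5, `4` = 4)[[as.character(d)]]
    sprintf("te(%s, k = %d)", paste(names(X), collapse = ", "), kk)
  }
  fitted <- matrix(NA_real_, nrow(nb), ncol(nb))
  for (j in seq_len(ncol(nb))) {
    dat <- cbind(y = nb[, j], X)
    fit <- tryCatch(
      mgcv::gam(stats::as.formula(paste("y ~", rhs)), data = dat),
      error = function(e) {
        stop("EVPPI regression failed for strategy ", j, ": ",
             conditionMessage(e))
      })
    fitted[, j] <- stats::fitted(fit)
  }
  est <- mean(apply(fitted, 1, max)) - max(colMeans(fitted))
  bs <- vapply(seq_len(n_boot), function(b) {
    idx <- sample.int(nrow(fitted), replace = TRUE)
    fb <- fitted[idx, , drop = FALSE]
    mean(apply(fb, 1, max)) - max(colMeans(fb))
  }, 0)
  structure(list(evppi = est, se = stats::sd(bs), group = group),
            class = "ova_evppi")
}

#' @export
print.ova_evppi <- function(x, ...) {
  cat(sprintf("EVPPI[%s] = %.4f (MC se %.4f)\n",
              paste(x$group, collapse = ", "), x$evppi, x$se))
  invisible(x)
}

#' Grouped EVPPI decomposition of decision uncertainty
#'
#' Computes EVPPI at one willingness-to-pay value for named parameter
#' groups and reports each group's share of the EVPI.
#'
#' @param psa an `ova_psa`.
#' @param groups named list of character vectors of parameter names.
#' @param lambda willingness to pay (default £20,000).
#' @return `data.frame(group, evppi, se, share_of_evpi)`.
#' @export
evppi_groups <- function(psa, groups, lambda = 20000) {
  nb <- net_benefit(psa, lambda)
  total <- evpi(nb)
  rows <- lapply(names(groups), function(g) {
    e <- evppi_regression(nb, psa$params, groups[[g]])
    data.frame(group = g, evppi = e$evppi, se = e$se,
               share_of_evpi = if (total > 0) e$evppi / total else NA_real_)
  })
  out <- do.call(rbind, rows)
  attr(out, "evpi") <- total
  out[order(-out$evppi), ]
}
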