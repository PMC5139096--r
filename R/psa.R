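# Probabilistic sensitivity analysis: joint sampling of cost/utility/FP
# parameters (Table-1 distributions) and effectiveness uncertainty (survival
# coefficient draws plus forecast noise), incremental analysis with the
# efficiency frontier, and cost-effectiveness acceptability curves.

chol_safe <- function(V) {
  V <- (V + t(V)) / 2
  for (j in 0:8) {
    L <- tryCatch(chol(V + diag(10^(-12 + j), nrow(V))), error = function(e) NULL)
    if (!is.null(L)) return(t(L))
  }
  stop("covariance matrix is not positive definite")
}

draw_coefs <- function(coef, L, z = NULL) {
  if (is.null(z)) z <- stats::rnorm(length(coef))
  stats::setNames(coef + as.vector(L %*% z), names(coef))
}

#' Run the probabilistic sensitivity analysis
#'
#' Draws `n_draws` parameter sets (every Table-1 cost, utility and
#' false-positive parameter from its fitted distribution; survival and
#' forecast uncertainty through multivariate-normal coefficient draws and
#' standard-normal forecast deviates; discrepancy multipliers where the
#' regime uses them), rebuilds the hazard trajectories for each draw and
#' runs the cohort model for all three strategies. Draws producing
#' non-finite results are rejected and resampled (count reported).
#'
#' @param inputs an `ova_inputs` from [build_model_inputs()].
#' @param n_draws Monte Carlo samples (5000 in the base case).
#' @param seed RNG seed; the run is deterministic given the seed.
#' @param regime extrapolation regime, see [build_trajectories()].
#' @param settings an [econ_settings()].
#' @param options a [model_options()].
#' @param dists fitted parameter distributions
#'   ([fit_all_distributions()]).
#' @param stage_mix optional per-strategy stage mixes.
#' @param discrepancy a [discrepancy_spec()] (discrepancy regime only).
#' @param effectiveness_uncertainty draw survival-coefficient and forecast
#'   uncertainty (`TRUE` in the base case); `FALSE` holds effectiveness at
#'   its point estimates so only the Table-1 parameters vary.
#' @return object of class `ova_psa`: matrices `cost`, `qaly`, `life_years`,
#'   `oc_deaths` (draws x strategies), the parameter draw matrix augmented
#'   with derived effectiveness summaries, and bookkeeping.
#' @export
run_psa <- function(inputs, n_draws = 5000, seed = 1, regime = "smoothing",
                    settings = econ_settings(), options = model_options(),
                    dists = fit_all_distributions(), stage_mix = NULL,
                    discrepancy = discrepancy_spec(),
                    effectiveness_uncertainty = TRUE) {
  regime <- match.arg(regime, EXTRAP_REGIMES)
  set.seed(seed)
  H <- settings$horizon
  fy <- inputs$trial_years
  L_spline <- chol_safe(inputs$spline_fit$vcov)
  sel_mort <- if (regime %in% c("separate-parametric", "same-parametric")) {
    select_family(inputs$fits_mort,
                  if (regime == "separate-parametric") "separate" else "combined")
  } else NULL
  L_mort <- if (!is.null(sel_mort)) {
    lapply(ARMS, function(a) {
      chol_safe(inputs$fits_mort[[a]][[sel_mort$chosen[[a]]]]$vcov_t)
    })
  } else NULL
  if (!is.null(L_mort)) names(L_mort) <- ARMS
  L_inc <- lapply(ARMS, function(a) {
    chol_safe(inputs$fits_inc[[a]][[inputs$inc_sel$chosen[[a]]]]$vcov_t)
  })
  names(L_inc) <- ARMS

  res <- list(cost = matrix(NA_real_, n_draws, 3),
              qaly = matrix(NA_real_, n_draws, 3),
              life_years = matrix(NA_real_, n_draws, 3),
              oc_deaths = matrix(NA_real_, n_draws, 3),
              cancers = matrix(NA_real_, n_draws, 3))
  for (nm in names(res)) colnames(res[[nm]]) <- ARMS
  pmat <- NULL
  n_rejected <- 0L

  i <- 1L
  while (i <= n_draws) {
    params <- drop(sample_parameters(dists, 1))
    draw <- if (effectiveness_uncertainty) {
      dr <- list(
        spline_coefs = draw_coefs(inputs$spline_fit$coef, L_spline),
        z_h = stats::rnorm(1),
        z_hr = c(MMS = stats::rnorm(1), USS = stats::rnorm(1))
      )
      if (!is.null(sel_mort)) {
        dr$mort_coefs <- lapply(ARMS, function(a) {
          draw_coefs(inputs$fits_mort[[a]][[sel_mort$chosen[[a]]]]$coef_t,
                     L_mort[[a]])
        })
        names(dr$mort_coefs) <- ARMS
      }
      dr$inc_coefs <- lapply(ARMS, function(a) {
        draw_coefs(inputs$fits_inc[[a]][[inputs$inc_sel$chosen[[a]]]]$coef_t,
                   L_inc[[a]])
      })
      names(dr$inc_coefs) <- ARMS
      if (regime == "discrepancy") {
        dr$disc_m <- list(MMS = rdiscrepancy_multipliers(discrepancy, H - fy),
                          USS = rdiscrepancy_multipliers(discrepancy, H - fy))
      }
      dr
    } else NULL
    out <- tryCatch({
      traj <- build_trajectories(inputs, regime, H, draw, discrepancy)
      ce <- evaluate_strategies(traj, params, stage_mix, settings, options)
      list(traj = traj, ce = ce)
    }, error = function(e) NULL)
    ok <- !is.null(out) &&
      all(is.finite(vapply(out$ce, function(r) r$cost + r$qaly, 0)))
    if (!ok) { n_rejected <- n_rejected + 1L
               if (n_rejected > 50 * n_draws) stop("too many rejected draws")
               next }
    for (s in ARMS) {
      r <- out$ce[[s]]
      res$cost[i, s] <- r$cost; res$qaly[i, s] <- r$qaly
      res$life_years[i, s] <- r$life_years
      res$oc_deaths[i, s] <- r$oc_deaths
      res$cancers[i, s] <- r$cancers
    }
    eff <- c(
      eff_longterm_mms = mean(out$traj$hr$MMS[(fy + 1):H]),
      eff_longterm_uss = mean(out$traj$hr$USS[(fy + 1):H]),
      eff_within_mms = mean(out$traj$hr$MMS[seq_len(fy)]),
      eff_within_uss = mean(out$traj$hr$USS[seq_len(fy)]),
      base_oc_mortality = sum(out$traj$oc_hazard$none)
    )
    row <- c(params, eff)
    if (is.null(pmat)) {
      pmat <- matrix(NA_real_, n_draws, length(row),
                     dimnames = list(NULL, names(row)))
    }
    pmat[i, ] <- row
    i <- i + 1L
  }
  structure(list(cost = res$cost, qaly = res$qaly,
                 life_years = res$life_years, oc_deaths = res$oc_deaths,
                 cancers = res$cancers, params = pmat,
                 strategies = ARMS, n_draws = n_draws, seed = seed,
                 regime = regime, settings = settings,
                 n_rejected = n_rejected),
            class = "ova_psa")
}

pctl <- function(x) stats::quantile(x, c(0.025, 0.975), names = FALSE)

#' @export
summary.ova_psa <- function(object, ...) {
  s <- lapply(c("cost", "qaly", "life_years", "oc_deaths"), function(nm) {
    m <- object[[nm]]
    data.frame(measure = nm, strategy = colnames(m), mean = colMeans(m),
               ci_low = apply(m, 2, function(x) pctl(x)[1]),
               ci_high = apply(m, 2, function(x) pctl(x)[2]))
  })
  tab <- do.call(rbind, s)
  rownames(tab) <- NULL
  inc <- incremental_analysis(object)
  structure(list(table = tab, incremental = inc,
                 n_rejected = object$n_rejected, regime = object$regime),
            class = "summary.ova_psa")
}

#' @export
print.summary.ova_psa <- function(x, ...) {
  cat(sprintf("PSA summary (%s regime; %d rejected draws)\n", x$regime,
              x$n_rejected))
  tab <- x$table
  tab$mean <- signif(tab$mean, 6)
  tab$ci_low <- signif(tab$ci_low, 6); tab$ci_high <- signif(tab$ci_high, 6)
  print(tab, row.names = FALSE)
  print(x$incremental)
  invisible(x)
}

#' @export
print.ova_psa <- function(x, ...) {
  cat(sprintf("PSA: %d draws, %s regime, seed %d (%d rejected)\n",
              x$n_draws, x$regime, x$seed, x$n_rejected))
  print(summary(x))
  invisible(x)
}

#' Efficiency frontier with dominance labels
#'
#' Standard incremental analysis: strategies sorted by mean cost; strictly
#' dominated strategies (another strategy no more costly and no less
#' effective, strictly better on one) are excluded first, then extendedly
#' dominated strategies (ICER exceeding that of a more effective strategy)
#' are removed iteratively; ICERs are reported along the frontier.
#'
#' @param ce `data.frame` with columns `strategy`, `cost`, `qaly` (means),
#'   or an `ova_psa` (means and draw-wise CIs are used).
#' @return object of class `ova_frontier`: the input table augmented with
#'   `label` (`frontier`, `dominated`, `extendedly dominated`), `icer`
#'   (vs the previous frontier strategy) and, for PSA input, draw-wise
#'   incremental CIs vs the least costly strategy.
#' @export
incremental_analysis <- function(ce) {
  psa <- NULL
  if (inherits(ce, "ova_psa")) {
    psa <- ce
    ce <- data.frame(strategy = psa$strategies, cost = colMeans(psa$cost),
                     qaly = colMeans(psa$qaly))
  }
  stopifnot(all(c("strategy", "cost", "qaly") %in% names(ce)))
  if (nrow(ce) < 2) stop("need at least 2 strategies")
  df <- ce[order(ce$cost, -ce$qaly), , drop = FALSE]
  n <- nrow(df)
  label <- rep("frontier", n)
  dominated_by <- character(0)
  # strict dominance
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (df$cost[j] <= df$cost[i] && df$qaly[j] >= df$qaly[i] &&
          (df$cost[j] < df$cost[i] || df$qaly[j] > df$qaly[i])) {
        label[i] <- "dominated"
        dominated_by[df$strategy[i]] <- df$strategy[j]
        break
      }
    }
  }
  # extended dominance: ICERs along the candidate frontier must increase
  repeat {
    idx <- which(label == "frontier")
    if (length(idx) < 3) break
    co <- df$cost[idx]; qa <- df$qaly[idx]
    icers <- diff(co) / diff(qa)
    drop <- which(diff(icers) < 0)
    if (!length(drop)) break
    label[idx[drop[1] + 1]] <- "extendedly dominated"
  }
  idx <- which(label == "frontier")
  icer <- rep(NA_real_, n)
  if (length(idx) > 1) {
    icer[idx[-1]] <- diff(df$cost[idx]) / diff(df$qaly[idx])
  }
  df$label <- label
  df$icer <- icer
  out <- list(table = df, dominated_by = dominated_by)
  if (!is.null(psa)) {
    ref <- df$strategy[1]
    inc <- lapply(setdiff(psa$strategies, ref), function(s) {
      dc <- psa$cost[, s] - psa$cost[, ref]
      de <- psa$qaly[, s] - psa$qaly[, ref]
      # draw-wise ICER percentile CI: draws with no QALY gain count as
      # dominated (ranked worst)
      ratio <- ifelse(de > 0, dc / de, Inf)
      qs <- stats::quantile(ratio, c(0.025, 0.975), names = FALSE, type = 1)
      data.frame(strategy = s, ref = ref,
                 d_cost = mean(dc), d_cost_lo = pctl(dc)[1],
                 d_cost_hi = pctl(dc)[2],
                 d_qaly = mean(de), d_qaly_lo = pctl(de)[1],
                 d_qaly_hi = pctl(de)[2],
                 icer_lo = qs[1], icer_hi = qs[2])
    })
    out$incremental_vs_ref <- do.call(rbind, inc)
  }
  class(out) <- "ova_frontier"
  out
}

#' @export
print.ova_frontier <- function(x, ...) {
  cat("Incremental analysis (mean costs and QALYs)\n")
  df <- x$table
  df$cost <- round(df$cost); df$qaly <- round(df$qaly, 3)
  df$icer <- ifelse(is.na(df$icer), "-", paste0("£", round(df$icer)))
  print(df, row.names = FALSE)
  if (!is.null(x$incremental_vs_ref)) {
    cat("Incrementals vs", x$incremental_vs_ref$ref[1], "(percentile 95% CIs):\n")
    inc <- x$incremental_vs_ref
    for (i in seq_len(nrow(inc))) {
      hi <- if (is.finite(inc$icer_hi[i])) sprintf("£%.0f", inc$icer_hi[i]) else "dominated"
      lo <- if (is.finite(inc$icer_lo[i])) sprintf("£%.0f", inc$icer_lo[i]) else "dominant"
      cat(sprintf("  %s: ΔC £%.0f (%.0f to %.0f), ΔQ %.3f (%.3f to %.3f), ICER CI %s to %s\n",
                  inc$strategy[i], inc$d_cost[i], inc$d_cost_lo[i],
                  inc$d_cost_hi[i], inc$d_qaly[i], inc$d_qaly_lo[i],
                  inc$d_qaly_hi[i], lo, hi))
    }
  }
  invisible(x)
}

#' Cost-effectiveness acceptability curves
#'
#' At each willingness-to-pay value, the probability that each strategy has
#' the highest net benefit (`lambda * QALY - cost`) across the PSA draws;
#' exact ties are split equally.
#'
#' @param psa an `ova_psa`.
#' @param wtp willingness-to-pay grid (default £0-£40,000 in £500 steps).
#' @return object of class `ova_ceac`: `data.frame` with `wtp` and one
#'   probability column per strategy.
#' @export
ceac <- function(psa, wtp = seq(0, 40000, by = 500)) {
  if (!length(wtp)) stop("willingness-to-pay grid must be non-empty")
  out <- matrix(0, length(wtp), length(psa$strategies),
                dimnames = list(NULL, psa$strategies))
  for (k in seq_along(wtp)) {
    nb <- wtp[k] * psa$qaly - psa$cost
    mx <- nb == apply(nb, 1, max)
    w <- mx / rowSums(mx)
    out[k, ] <- colMeans(w)
  }
  res <- data.frame(wtp = wtp, out, check.names = FALSE)
  class(res) <- c("ova_ceac", "data.frame")
  res
}

#' @export
plot.ova_ceac <- function(x, ...) {
  strat <- setdiff(names(x), "wtp")
  graphics::matplot(x$wtp, as.matrix(x[strat]), type = "l", lty = 1, lwd = 2,
                    xlab = "Willingness to pay (£/QALY)",
                    ylab = "Probability cost-effective", ylim = c(0, 1), ...)
  graphics::legend("right", legend = strat, col = seq_along(strat), lty = 1,
                   lwd = 2, bty = "n")
  invisible(x)
}

#' Export PSA draws as CSV (parameters plus per-strategy outcomes)
#' @param psa an `ova_psa`.
#' @param path CSV path.
#' @export
write_psa_csv <- function(psa, path) {
  df <- data.frame(psa$params,
                   stats::setNames(as.data.frame(psa$cost),
                                   paste0("cost_", colnames(psa$cost))),
                   stats::setNames(as.data.frame(psa$qaly),
                                   paste0("qaly_", colnames(psa$qaly))))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
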