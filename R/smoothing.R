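# State-space exponential smoothing (simple, and additive damped trend) with
# maximum-likelihood weights, used to extrapolate annual log hazards and
# log hazard ratios beyond the trial window.

ets_filter <- function(y, alpha, beta, phi, l0, b0) {
  n <- length(y)
  l <- l0; b <- b0
  fitted <- numeric(n); e <- numeric(n)
  for (t in seq_len(n)) {
    f <- l + phi * b
    e[t] <- y[t] - f
    fitted[t] <- f
    l <- l + phi * b + alpha * e[t]
    b <- phi * b + beta * e[t]
  }
  list(fitted = fitted, resid = e, level = l, trend = b, sse = sum(e^2))
}

#' Exponential-smoothing forecast of an annual series
#'
#' Fits a state-space exponential-smoothing model -- simple exponential
#' smoothing (`trend = "none"`) or additive damped trend (`trend = "damped"`,
#' the default) -- by minimising the one-step squared error, and returns the
#' h-step forecast mean together with its standard deviation from the
#' innovations state-space forecast variance. Used on log hazards and on log
#' hazard ratios, so that forecast uncertainty can be propagated through the
#' probabilistic sensitivity analysis.
#'
#' @param series observed annual values (at least 3).
#' @param horizon number of steps ahead to forecast.
#' @param settings list: `trend` (`"damped"` or `"none"`), optional fixed
#'   `alpha`, `beta`, `phi`; bounds follow common practice
#'   (`alpha` in \[0.01, 1\], `beta` in \[0, alpha\], `phi` in \[0.8, 0.98\]).
#' @return list of class `ova_forecast`: `mean`, `sd` (length `horizon`),
#'   fitted smoothing parameters and in-sample sigma.
#' @export
forecast_smoothing <- function(series, horizon,
                               settings = list(trend = "damped")) {
  y <- as.numeric(series)
  if (length(y) < 3) stop("need at least 3 observed values")
  if (any(!is.finite(y))) stop("series must be finite")
  trend <- if (is.null(settings$trend)) "damped" else settings$trend
  trend <- match.arg(trend, c("damped", "none"))
  fixed <- settings[intersect(names(settings), c("alpha", "beta", "phi"))]

  if (stats::var(y) < 1e-18) {
    # constant series: the forecast is that constant under any weights
    out <- list(mean = rep(y[1], horizon), sd = rep(0, horizon),
                alpha = fixed$alpha %||% 1, beta = 0, phi = 1, sigma = 0,
                trend = trend, level = y[1], slope = 0)
    class(out) <- "ova_forecast"
    return(out)
  }

  if (trend == "none") {
    obj <- function(p) {
      a <- fixed$alpha %||% stats::plogis(p[1]) * 0.99 + 0.01
      l0 <- p[length(p)]
      ets_filter(y, a, 0, 1, l0, 0)$sse
    }
    init <- if (is.null(fixed$alpha)) c(0, y[1]) else c(y[1])
    op <- stats::optim(init, obj,
                       method = if (length(init) == 1) "BFGS" else "Nelder-Mead",
                       control = list(maxit = 2000))
    a <- fixed$alpha %||% (stats::plogis(op$par[1]) * 0.99 + 0.01)
    fl <- ets_filter(y, a, 0, 1, op$par[length(op$par)], 0)
    sigma2 <- fl$sse / length(y)
    mean_f <- rep(fl$level, horizon)
    cj <- rep(a, horizon)
    var_f <- sigma2 * (1 + c(0, cumsum(cj^2))[seq_len(horizon)])
    out <- list(mean = mean_f, sd = sqrt(var_f), alpha = a, beta = 0, phi = 1,
                sigma = sqrt(sigma2), trend = trend, level = fl$level, slope = 0)
  } else {
    obj <- function(p) {
      a <- fixed$alpha %||% (stats::plogis(p[1]) * 0.99 + 0.01)
      b <- (fixed$beta %||% (stats::plogis(p[2]) * a))
      ph <- fixed$phi %||% (0.8 + 0.18 * stats::plogis(p[3]))
      l0 <- p[4]; b0 <- p[5]
      ets_filter(y, a, b, ph, l0, b0)$sse
    }
    init <- c(0, -1, 0, y[1], (y[length(y)] - y[1]) / (length(y) - 1))
    op <- stats::optim(init, obj, method = "Nelder-Mead",
                       control = list(maxit = 5000, reltol = 1e-12))
    a <- fixed$alpha %||% (stats::plogis(op$par[1]) * 0.99 + 0.01)
    b <- fixed$beta %||% (stats::plogis(op$par[2]) * a)
    ph <- fixed$phi %||% (0.8 + 0.18 * stats::plogis(op$par[3]))
    fl <- ets_filter(y, a, b, ph, op$par[4], op$par[5])
    sigma2 <- fl$sse / length(y)
    phj <- cumsum(ph^(seq_len(horizon)))           # phi + phi^2 + ... + phi^h
    mean_f <- fl$level + phj * fl$trend
    cj <- a + b * phj                              # c_j for j = 1..h-1
    var_f <- sigma2 * (1 + c(0, cumsum(cj^2))[seq_len(horizon)])
    out <- list(mean = mean_f, sd = sqrt(var_f), alpha = a, beta = b, phi = ph,
                sigma = sqrt(sigma2), trend = trend,
                level = fl$level, slope = fl$trend)
  }
  class(out) <- "ova_forecast"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.ova_forecast <- function(x, ...) {
  cat(sprintf("exponential smoothing (%s trend): alpha=%.3f beta=%.3f phi=%.3f sigma=%.4f\n",
              x$trend, x$alpha, x$beta, x$phi, x$sigma))
  cat(sprintf("  %d-step forecast: %s ...\n", length(x$mean),
              paste(round(utils::head(x$mean, 5), 4), collapse = ", ")))
  invisible(x)
}
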