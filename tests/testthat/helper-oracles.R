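# Independent oracles used to cross-check the implementation. These are kept
# deliberately naive (textbook loops, brute force) and share no code with the
# package internals they check.

# textbook product-limit estimator: loop over distinct event times
km_oracle <- function(time, status, grid) {
  ord <- order(time)
  time <- time[ord]; status <- status[ord]
  ev_times <- sort(unique(time[status == 1]))
  s <- 1
  surv_at <- function(tt) {
    s <- 1
    for (et in ev_times) {
      if (et > tt) break
      n_risk <- sum(time >= et)
      d <- sum(time == et & status == 1)
      s <- s * (1 - d / n_risk)
    }
    s
  }
  vapply(grid, surv_at, 0)
}

# individual-level microsimulation through a transition schedule, with
# per-woman payoff accrual (same economic definitions, independent code
# path); returns means and Monte Carlo standard errors
microsim_oracle <- function(schedule, payoffs, settings, n = 100000,
                            seed = 1) {
  set.seed(seed)
  H <- min(schedule$horizon, settings$horizon)
  P <- schedule$P
  state <- rep(if (schedule$screened) 1L else 2L, n)
  v <- (1 + settings$discount_rate)^-(seq_len(H))
  u_oc1 <- max(payoffs$utility_well - payoffs$disutility_first_year, 0)
  state_u <- c(payoffs$utility_well, payoffs$utility_well, u_oc1,
               payoffs$utility_well, 0, 0)
  scr <- screening_cost_stream(if (schedule$screened) payoffs$strategy else
    "none", payoffs, schedule$n_screens, H)
  cost_i <- qaly_i <- ly_i <- numeric(n)
  for (t in seq_len(H)) {
    prev <- state
    nxt <- integer(n)
    for (s in 1:6) {
      idx <- which(prev == s)
      if (!length(idx)) next
      nxt[idx] <- sample.int(6, length(idx), replace = TRUE,
                             prob = P[t, s, ])
    }
    state <- nxt
    ubar_i <- if (settings$half_cycle) {
      (state_u[prev] + state_u[state]) / 2
    } else state_u[prev]
    dx_i <- (prev <= 2 & state == 3)
    dth_i <- (prev %in% c(3, 4) & state == 5)
    fp_active <- payoffs$fp_ratio > 0 &&
      ((schedule$screened && t <= schedule$n_screens) ||
         (!schedule$screened && payoffs$fp_in_unscreened))
    fp_i <- if (fp_active) {
      dx_i * payoffs$screen_detected_frac * payoffs$fp_ratio
    } else 0
    sdu_i <- if (t <= schedule$n_screens) {
      payoffs$screen_disutility * ((prev == 1) + (state == 1)) / 2
    } else 0
    qaly_i <- qaly_i + v[t] * (ubar_i - fp_i * payoffs$fp_disutility - sdu_i)
    ly_i <- ly_i + if (settings$half_cycle) {
      ((prev <= 4) + (state <= 4)) / 2
    } else as.numeric(prev <= 4)
    cost_i <- cost_i + v[t] * (scr[t] * (prev == 1) +
                                 dx_i * (payoffs$cost_diag + payoffs$cost_treat) +
                                 fp_i * payoffs$fp_cost +
                                 dth_i * payoffs$cost_eol)
  }
  dead_oc <- as.numeric(state == 5)
  list(cost = mean(cost_i), qaly = mean(qaly_i), life_years = mean(ly_i),
       oc_deaths = mean(dead_oc),
       se = c(cost = sd(cost_i), qaly = sd(qaly_i),
              life_years = sd(ly_i), oc_deaths = sd(dead_oc)) / sqrt(n),
       n = n)
}

# literal recursion for additive damped-trend exponential smoothing
damped_trend_oracle <- function(y, alpha, beta, phi, l0, b0, h) {
  l <- l0; b <- b0
  for (t in seq_along(y)) {
    f <- l + phi * b
    e <- y[t] - f
    l <- l + phi * b + alpha * e
    b <- phi * b + beta * e
  }
  out <- numeric(h)
  for (j in seq_len(h)) {
    out[j] <- l + sum(phi^(1:j)) * b
  }
  out
}

# brute-force dominance labels for a set of strategies: a strategy is on the
# frontier iff it maximises net benefit for some willingness to pay >= 0;
# strictly dominated strategies are labelled first, the rest of the excluded
# ones are extendedly dominated
frontier_oracle <- function(cost, qaly) {
  n <- length(cost)
  label <- rep("frontier", n)
  for (i in seq_len(n)) {
    dom <- any(cost <= cost[i] & qaly >= qaly[i] &
                 (cost < cost[i] | qaly > qaly[i]))
    if (dom) label[i] <- "dominated"
  }
  # candidate willingness-to-pay values: all pairwise crossings plus extremes
  lams <- c(0, 1e12)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (qaly[i] != qaly[j]) {
      l <- (cost[i] - cost[j]) / (qaly[i] - qaly[j])
      if (is.finite(l) && l > 0) lams <- c(lams, l * c(0.999, 1, 1.001))
    }
  }
  optimal_somewhere <- rep(FALSE, n)
  for (l in lams) {
    nb <- l * qaly - cost
    optimal_somewhere[nb >= max(nb) - 1e-9] <- TRUE
  }
  label[!optimal_somewhere & label == "frontier"] <- "extendedly dominated"
  label
}

# two-level nested Monte Carlo EVPPI oracle for the two-parameter toy
# decision model NB1 = 0, NB2 = theta1 + theta2
nested_mc_evppi <- function(mu1, sd1, mu2, sd2, n_outer = 5000,
                            n_inner = 5000, seed = 1) {
  set.seed(seed)
  th1 <- rnorm(n_outer, mu1, sd1)
  # outer loop: perfect knowledge of theta1; inner loop: expectation over
  # theta2 given theta1 (independent here)
  val <- vapply(th1, function(t1) {
    max(0, mean(t1 + rnorm(n_inner, mu2, sd2)))
  }, 0)
  # current-information value: best decision on the overall mean
  nb2_mc <- mean(rnorm(n_outer, mu1, sd1) + rnorm(n_outer, mu2, sd2))
  mean(val) - max(0, nb2_mc)
}
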