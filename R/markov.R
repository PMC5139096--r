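# Six-state annual-cycle cohort Markov engine: Well (screened / unscreened),
# ovarian cancer in the first / later years after diagnosis, and death from
# ovarian cancer or other causes. Computes lifetime discounted costs, QALYs,
# undiscounted life years and the fraction dying of ovarian cancer.

MODEL_STATES <- c("well_screened", "well_unscreened", "oc_year1", "oc_later",
                  "dead_oc", "dead_other")

#' Economic evaluation settings
#'
#' @param discount_rate annual discount rate applied to both costs and QALYs
#'   (default 3.5%).
#' @param horizon number of annual cycles (default 40: entry at 60, model to
#'   age 100).
#' @param half_cycle use the half-cycle correction (trapezoidal average of
#'   start- and end-of-cycle occupancy) for state payoffs.
#' @param price_year label for the cost base year.
#' @return list of class `econ_settings`.
#' @export
econ_settings <- function(discount_rate = 0.035, horizon = 40,
                          half_cycle = TRUE, price_year = "2013/14") {
  if (discount_rate < 0) stop("discount rate must be >= 0")
  if (horizon < 1) stop("horizon must be >= 1 cycle")
  structure(list(discount_rate = discount_rate, horizon = as.integer(horizon),
                 half_cycle = half_cycle, cycle_length = 1,
                 price_year = price_year),
            class = "econ_settings")
}

# conditional OC-death probability solving
#   (1 - exp(-(h + h_oth))) * h / (h + h_oth) = f
solve_cause_hazard <- function(f, h_oth) {
  if (f <= 0) return(0)
  f <- min(f, 0.98)
  g <- function(h) (1 - exp(-(h + h_oth))) * h / (h + h_oth) - f
  stats::uniroot(g, c(1e-12, 60), tol = 1e-12)$root
}

#' Build the per-cycle transition schedule for one strategy
#'
#' Assembles the cycle-by-cycle 6x6 transition matrices from annual
#' cohort-level inputs. Incidence and other-cause death compete as constant
#' hazards within the cycle. The OC-death transition is calibrated so that
#' the cohort-level ovarian-cancer deaths per cycle match the arm-level
#' mortality trajectory (the trial reports mortality at arm level, not
#' conditional on diagnosis): a deterministic forward pass solves the
#' conditional probability from the diagnosed-state occupancy each cycle.
#' At the end of the screening programme the surviving screened population
#' moves to the unscreened well state.
#'
#' @param oc_death_prob annual cohort-level probabilities of OC death (per
#'   person alive), length `horizon`.
#' @param incidence_prob annual probabilities of OC diagnosis (per person
#'   without diagnosis), length `horizon`.
#' @param other_cause_prob annual other-cause death probabilities, length
#'   `horizon`.
#' @param screened does the strategy screen (cohort starts in the
#'   well-screened state)?
#' @param n_screens number of annual screening rounds.
#' @return object of class `ova_schedule`: array `P` (`horizon` x 6 x 6) plus
#'   metadata.
#' @export
build_schedule <- function(oc_death_prob, incidence_prob, other_cause_prob,
                           screened = TRUE, n_screens = 7) {
  H <- length(oc_death_prob)
  stopifnot(length(incidence_prob) == H, length(other_cause_prob) == H)
  if (any(oc_death_prob < 0 | incidence_prob < 0 | incidence_prob > 1 |
          other_cause_prob < 0 | other_cause_prob > 1)) {
    stop("annual probabilities must lie in [0, 1]")
  }
  P <- array(0, dim = c(H, 6, 6),
             dimnames = list(NULL, MODEL_STATES, MODEL_STATES))
  u <- c(if (screened) c(1, 0) else c(0, 1), 0, 0, 0, 0)
  capped <- 0L
  for (t in seq_len(H)) {
    h_inc <- -log(1 - min(incidence_prob[t], 0.999999))
    h_oth <- -log(1 - min(other_cause_prob[t], 0.999999))
    he <- h_inc + h_oth
    p_exit <- 1 - exp(-he)
    p_w_oc <- if (he > 0) p_exit * h_inc / he else 0
    p_w_do <- if (he > 0) p_exit * h_oth / he else 0
    p_w_stay <- 1 - p_w_oc - p_w_do

    alive <- sum(u[1:4])
    occ_oc <- u[3] + u[4]
    target <- oc_death_prob[t] * alive
    f <- if (occ_oc > 1e-12) target / occ_oc else 0
    if (f > 0.98) capped <- capped + 1L
    h_oc <- solve_cause_hazard(f, h_oth)
    hd <- h_oc + h_oth
    p_d_exit <- 1 - exp(-hd)
    p_oc_doc <- if (hd > 0) p_d_exit * h_oc / hd else 0
    p_oc_do <- if (hd > 0) p_d_exit * h_oth / hd else 0
    p_oc_stay <- 1 - p_oc_doc - p_oc_do

    M <- matrix(0, 6, 6)
    # well states
    for (w in 1:2) {
      M[w, 3] <- p_w_oc; M[w, 6] <- p_w_do; M[w, w] <- p_w_stay
    }
    # end of the screening programme: survivors leave the screened state
    if (screened && t == n_screens) {
      M[1, 2] <- M[1, 1]; M[1, 1] <- 0
    }
    # cancer states: first-year survivors move to the later-years state
    M[3, 5] <- p_oc_doc; M[3, 6] <- p_oc_do; M[3, 4] <- p_oc_stay
    M[4, 5] <- p_oc_doc; M[4, 6] <- p_oc_do; M[4, 4] <- p_oc_stay
    M[5, 5] <- 1; M[6, 6] <- 1
    P[t, , ] <- M
    u <- as.vector(u %*% M)
  }
  structure(list(P = P, horizon = H, screened = screened,
                 n_screens = n_screens, oc_death_prob = oc_death_prob,
                 incidence_prob = incidence_prob,
                 other_cause_prob = other_cause_prob, n_capped = capped),
            class = "ova_schedule")
}

#' Per-cycle screening cost stream
#'
#' Annual cost of the screening programme per woman occupying the
#' well-screened state: invitation plus the completion-mix screen cost,
#' during the screening period only. The no-screening comparator has an
#' identically zero stream.
#'
#' @param strategy `"none"`, `"MMS"` or `"USS"`.
#' @param payoffs a payoff map from [build_payoffs()].
#' @param n_screens screening rounds (default from the payoff map).
#' @param horizon number of cycles.
#' @return numeric vector of per-cycle (undiscounted) costs.
#' @export
screening_cost_stream <- function(strategy, payoffs, n_screens = NULL,
                                  horizon = 40) {
  if (!strategy %in% c("none", "MMS", "USS")) {
    stop(sprintf("unknown strategy '%s'", strategy))
  }
  if (is.null(n_screens)) n_screens <- payoffs$n_screens
  if (n_screens > horizon) stop("screening duration exceeds the horizon")
  out <- numeric(horizon)
  if (strategy != "none" && n_screens > 0) {
    out[seq_len(n_screens)] <- payoffs$cost_invitation + payoffs$cost_screen
  }
  out
}

#' False-positive load per cycle
#'
#' Number of false positives generated per screen-detected cancer, with the
#' associated one-off treatment cost and one year of Stage-1 disutility per
#' false positive.
#'
#' @param cancers_detected fraction (or count) of screen-detected cancers.
#' @param fp_per_cancer false positives per cancer identified.
#' @param payoffs payoff map (uses `fp_cost` and `fp_disutility`).
#' @return list: `n_fp`, `cost`, `qaly_loss` (one year, undiscounted).
#' @export
false_positive_load <- function(cancers_detected, fp_per_cancer, payoffs) {
  if (fp_per_cancer < 0) stop("fp_per_cancer must be >= 0")
  n_fp <- cancers_detected * fp_per_cancer
  list(n_fp = n_fp, cost = n_fp * payoffs$fp_cost,
       qaly_loss = n_fp * payoffs$fp_disutility)
}

#' Run the cohort model for one strategy
#'
#' Forward-propagates the cohort trace through the transition schedule and
#' accrues discounted costs and QALYs (half-cycle-corrected state payoffs;
#' one-off costs applied to transition flows, uncorrected), undiscounted life
#' years, and the fraction dying of ovarian cancer. The discount factor for
#' cycle `t` is `(1 + r)^-t`.
#'
#' @param schedule an `ova_schedule` from [build_schedule()].
#' @param payoffs a payoff map from [build_payoffs()].
#' @param settings an [econ_settings()].
#' @return object of class `ova_ce` with totals, a cost breakdown, the
#'   occupancy trace and per-cycle flows.
#' @export
run_cohort <- function(schedule, payoffs, settings = econ_settings()) {
  H <- min(schedule$horizon, settings$horizon)
  P <- schedule$P
  # row-sum validation
  for (t in seq_len(H)) {
    rs <- rowSums(P[t, , ])
    bad <- which(abs(rs - 1) > 1e-12)
    if (length(bad)) {
      stop(sprintf("transition rows must sum to 1: cycle %d, state %s",
                   t, MODEL_STATES[bad[1]]))
    }
    if (any(P[t, , ] < -1e-15) || any(P[t, , ] > 1 + 1e-15)) {
      stop(sprintf("transition probabilities outside [0,1] at cycle %d", t))
    }
  }
  v <- (1 + settings$discount_rate)^-(seq_len(H))
  U <- matrix(0, H + 1, 6, dimnames = list(NULL, MODEL_STATES))
  U[1, ] <- c(if (schedule$screened) c(1, 0) else c(0, 1), 0, 0, 0, 0)

  scr_stream <- screening_cost_stream(
    if (schedule$screened) payoffs$strategy else "none", payoffs,
    schedule$n_screens, H)

  cost_comp <- c(screening = 0, diagnosis = 0, treatment = 0,
                 false_positive = 0, end_of_life = 0)
  qaly <- 0; ly <- 0
  new_dx <- oc_deaths_flow <- numeric(H)
  u_oc1 <- max(payoffs$utility_well - payoffs$disutility_first_year, 0)
  state_u <- c(payoffs$utility_well, payoffs$utility_well, u_oc1,
               payoffs$utility_well, 0, 0)

  for (t in seq_len(H)) {
    u0 <- U[t, ]
    M <- P[t, , ]
    u1 <- as.vector(u0 %*% M)
    U[t + 1, ] <- u1
    ubar <- if (settings$half_cycle) (u0 + u1) / 2 else u0

    dx <- u0[1] * M[1, 3] + u0[2] * M[2, 3]
    dth <- u0[3] * M[3, 5] + u0[4] * M[4, 5]
    new_dx[t] <- dx; oc_deaths_flow[t] <- dth

    # false positives arise from screens during the programme
    fp_active <- payoffs$fp_ratio > 0 &&
      ((schedule$screened && t <= schedule$n_screens) ||
         (!schedule$screened && payoffs$fp_in_unscreened))
    fp <- if (fp_active) {
      false_positive_load(dx * payoffs$screen_detected_frac,
                          payoffs$fp_ratio, payoffs)
    } else list(n_fp = 0, cost = 0, qaly_loss = 0)

    screening_du <- if (t <= schedule$n_screens) {
      payoffs$screen_disutility * ubar[1]
    } else 0

    qaly <- qaly + v[t] * (sum(ubar * state_u) - fp$qaly_loss - screening_du)
    ly <- ly + sum(ubar[1:4])

    cost_comp["screening"] <- cost_comp["screening"] +
      v[t] * scr_stream[t] * u0[1]
    cost_comp["diagnosis"] <- cost_comp["diagnosis"] +
      v[t] * dx * payoffs$cost_diag
    cost_comp["treatment"] <- cost_comp["treatment"] +
      v[t] * dx * payoffs$cost_treat
    cost_comp["false_positive"] <- cost_comp["false_positive"] +
      v[t] * fp$cost
    cost_comp["end_of_life"] <- cost_comp["end_of_life"] +
      v[t] * dth * payoffs$cost_eol
  }
  drift <- abs(rowSums(U) - 1)
  out <- list(strategy = payoffs$strategy,
              cost = sum(cost_comp), qaly = qaly, life_years = ly,
              oc_deaths = unname(U[H + 1, "dead_oc"]),
              cancers = sum(new_dx),
              cost_components = cost_comp,
              trace = U, new_diagnoses = new_dx,
              oc_death_flow = oc_deaths_flow,
              horizon = H, settings = settings,
              max_drift = max(drift))
  class(out) <- "ova_ce"
  out
}

#' @export
print.ova_ce <- function(x, ...) {
  cat(sprintf("Strategy %s over %d cycles (discount %.1f%%)\n", x$strategy,
              x$horizon, 100 * x$settings$discount_rate))
  cat(sprintf("  cost  = £%.2f   QALYs = %.3f   life years = %.3f\n",
              x$cost, x$qaly, x$life_years))
  cat(sprintf("  OC deaths = %.3f%%   cancers diagnosed = %.3f%%\n",
              100 * x$oc_deaths, 100 * x$cancers))
  invisible(x)
}
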