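# Kaplan-Meier estimation (via the survival package) and reconstruction of
# pseudo individual-patient data from digitized curve coordinates plus a
# numbers-at-risk table, following the iterative algorithm of Guyot et al.

# product-limit estimate evaluated on an arbitrary grid (1 before the first
# event; flat extension beyond the last observed time)
km_curve <- function(time, status, grid) {
  sf <- survival::survfit(survival::Surv(time, status) ~ 1)
  s <- summary(sf, times = grid, extend = TRUE)$surv
  data.frame(time = grid, survival = s)
}

#' Kaplan-Meier estimate on a time grid
#'
#' Product-limit estimator for reconstructed (or any) single-arm IPD,
#' evaluated at the requested time points. Equals 1 before the first event
#' and extends flat beyond the last observed time.
#'
#' @param ipd `data.frame` with columns `time` and `event` (1 = event,
#'   0 = censored).
#' @param grid time points at which to evaluate the curve.
#' @return `data.frame(time, survival)`.
#' @export
km_estimate <- function(ipd, grid) {
  if (nrow(ipd) == 0) stop("empty IPD")
  ev <- if (is.numeric(ipd$event)) ipd$event else as.integer(ipd$event == 1)
  km_curve(ipd$time, ev, grid)
}

#' Reconstruct pseudo individual-patient data from a digitized KM curve
#'
#' Implements the iterative reconstruction algorithm of Guyot et al.: within
#' each numbers-at-risk interval, censoring counts are adjusted until the
#' implied number at risk at the next risk-table time matches the published
#' count, with event counts at each digitized step recovered from the
#' published survival ratios. Censoring times are spread evenly within each
#' interval; event times sit at the digitized step locations. Subjects
#' remaining after the last risk-table time are censored at the end of the
#' curve, unless `total_events` is supplied, in which case events in the tail
#' are topped up to match the reported total.
#'
#' @param curve `data.frame(time, survival)`: ordered digitized coordinates,
#'   starting at (0, 1). Non-monotone survival (digitization noise) is
#'   repaired by a decreasing isotonic projection; survival above 1 + 1e-6 is
#'   a validation error.
#' @param risk `data.frame(time, n_at_risk)`: non-increasing counts at
#'   stated times; the first entry fixes the number of subjects.
#' @param total_events optional reported total number of events; the default
#'   `NULL` uses the risk-table-only variant of the algorithm (all that is
#'   observable from a published figure).
#' @return `data.frame(time, event)` of class `reconstructed_ipd` with
#'   exactly `risk$n_at_risk[1]` rows.
#' @references Guyot P, Ades AE, Ouwens MJNM, Welton NJ. Enhanced secondary
#'   analysis of survival data: reconstructing the data from published
#'   Kaplan-Meier survival curves. BMC Med Res Methodol 2012;12:9.
#' @export
reconstruct_ipd <- function(curve, risk, total_events = NULL) {
  t_s <- curve$time; s <- curve$survival
  if (is.unsorted(t_s)) stop("curve times must be ordered")
  if (any(s > 1 + 1e-6) || any(s < -1e-6)) {
    stop("survival coordinates must lie in [0, 1]")
  }
  if (any(diff(risk$n_at_risk) > 0)) {
    stop("numbers at risk must be non-increasing")
  }
  if (risk$n_at_risk[1] <= 0) stop("initial number at risk must be positive")
  if (min(risk$time) < min(t_s) - 1e-9 || max(risk$time) > max(t_s) + 1e-9) {
    stop("risk table and curve must cover a common time range")
  }
  s <- pmin(pmax(s, 0), 1)
  if (any(diff(s) > 1e-12)) s <- iso_decreasing(s)
  if (abs(t_s[1]) < 1e-12) s[1] <- 1

  trisk <- risk$time; nrisk <- risk$n_at_risk
  nint <- length(trisk)
  K <- length(t_s)
  # click index ranges per interval [trisk_i, trisk_{i+1})
  lower <- vapply(trisk, function(tt) which(t_s >= tt - 1e-9)[1], 0L)
  upper <- c(lower[-1] - 1L, K)

  n_hat <- rep(NA_real_, K + 1)
  km_hat <- rep(1, K)
  d <- integer(K)
  cens_times <- list()
  n_hat[1] <- nrisk[1]
  last_event <- 0L # index of last click with an event (0 = none, KM = 1)

  process_clicks <- function(kset, cen_t, n_start, km_prev, last_ev) {
    # walk clicks in kset given censor times cen_t within the interval
    d_loc <- integer(length(kset)); n_loc <- numeric(length(kset) + 1)
    n_loc[1] <- n_start
    km_loc <- numeric(length(kset))
    for (j in seq_along(kset)) {
      k <- kset[j]
      km_ref <- if (last_ev > 0) km_hat[last_ev] else km_prev
      dk <- 0L
      if (km_ref > 0 && n_loc[j] > 0) {
        dk <- round(n_loc[j] * (1 - s[k] / km_ref))
        dk <- max(0L, min(dk, floor(n_loc[j])))
      }
      d_loc[j] <- dk
      km_loc[j] <- if (dk > 0) km_ref * (1 - dk / n_loc[j]) else km_ref
      if (dk > 0) { km_hat[k] <<- km_loc[j]; last_ev <- k } else km_hat[k] <<- km_ref
      # censorings between this click and the next
      t_next <- if (j < length(kset)) t_s[kset[j + 1]] else Inf
      ck <- sum(cen_t >= t_s[k] & cen_t < t_next)
      n_loc[j + 1] <- n_loc[j] - dk - ck
    }
    list(d = d_loc, n_end = n_loc[length(n_loc)], last_ev = last_ev)
  }

  for (i in seq_len(nint - 1L)) {
    kset <- seq(lower[i], upper[i])
    if (length(kset) == 0 || lower[i] > upper[i]) { cens_times[[i]] <- numeric(0); next }
    n_start <- n_hat[lower[i]]
    km_prev <- if (last_event > 0) km_hat[last_event] else 1
    # initial censoring guess from the KM identity (Guyot et al. eq. for
    # n.censor): drop implied by the survival ratio, minus the published drop
    guess <- if (s[lower[i]] > 0) {
      round(n_start * s[lower[i + 1L]] / s[lower[i]]) - nrisk[i + 1L]
    } else n_start - nrisk[i + 1L]
    if (!is.finite(guess)) guess <- n_start - nrisk[i + 1L]
    ncen <- max(0L, min(as.integer(guess), as.integer(n_start)))
    t_lo <- t_s[lower[i]]; t_hi <- trisk[i + 1L]
    best <- NULL
    for (iter in 1:40) {
      cen_t <- if (ncen > 0) {
        t_lo + seq_len(ncen) * (t_hi - t_lo) / (ncen + 1)
      } else numeric(0)
      km_save <- km_hat
      res <- process_clicks(kset, cen_t, n_start, km_prev, last_event)
      mismatch <- res$n_end - nrisk[i + 1L]
      if (is.null(best) || abs(mismatch) < abs(best$mismatch)) {
        best <- list(ncen = ncen, mismatch = mismatch, res = res,
                     cen_t = cen_t, km = km_hat)
      }
      km_hat <- km_save
      if (mismatch == 0) break
      ncen_new <- ncen + as.integer(mismatch)
      ncen_new <- max(0L, min(ncen_new, as.integer(n_start)))
      if (ncen_new == ncen) break
      ncen <- ncen_new
    }
    km_hat <- best$km
    # re-run the best configuration to fix state
    res <- process_clicks(kset, best$cen_t, n_start, km_prev, last_event)
    d[kset] <- res$d
    last_event <- res$last_ev
    cens_times[[i]] <- best$cen_t
    n_hat[upper[i] + 1L] <- res$n_end
    # propagate start-of-interval counts for the clicks
    nn <- n_start
    for (j in seq_along(kset)) {
      k <- kset[j]
      n_hat[k] <- nn
      t_next <- if (j < length(kset)) t_s[kset[j + 1]] else Inf
      nn <- nn - d[k] - sum(best$cen_t >= t_s[k] & best$cen_t < t_next)
    }
  }

  # final interval: clicks at/after the last risk time; no further risk
  # anchors, so events come from the curve and the remainder is censored at
  # the end of the curve (or topped up to total_events when reported)
  kset <- seq(lower[nint], K)
  n_start <- nrisk[nint]
  km_prev <- if (last_event > 0) km_hat[last_event] else 1
  res <- process_clicks(kset, numeric(0), n_start, km_prev, last_event)
  d[kset] <- res$d
  if (!is.null(total_events)) {
    short <- total_events - sum(d)
    if (short != 0) {
      k_end <- K
      d[k_end] <- max(0L, d[k_end] + as.integer(short))
      res$n_end <- n_start - sum(d[kset])
    }
  }
  n_left <- max(0, res$n_end)

  times <- c(rep(t_s, d), unlist(cens_times), rep(t_s[K], n_left))
  event <- c(rep(1L, sum(d)), rep(0L, length(unlist(cens_times)) + n_left))
  out <- data.frame(time = times, event = event)
  out <- out[order(out$time, -out$event), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("reconstructed_ipd", "data.frame")
  out
}

#' Read/write reconstruction inputs and outputs as CSV
#' @param path CSV path.
#' @return the object read, or `path` invisibly when writing.
#' @export
read_curve_csv <- function(path) {
  x <- utils::read.csv(path)
  stopifnot(all(c("time", "survival") %in% names(x)))
  x
}

#' @rdname read_curve_csv
#' @export
read_risk_csv <- function(path) {
  x <- utils::read.csv(path)
  stopifnot(all(c("time", "n_at_risk") %in% names(x)))
  x
}

#' @rdname read_curve_csv
#' @param ipd a `reconstructed_ipd`.
#' @export
write_recon_csv <- function(ipd, path) {
  utils::write.csv(as.data.frame(ipd), path, row.names = FALSE)
  invisible(path)
}
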