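#' Resting membrane potential from the zero-current segment
#'
#' For file-based data the break-in potential is usually not recorded with
#' the sweep, so the resting potential is taken as the mean voltage over the
#' absolute-zero-current segment appended at the sweep end.
#'
#' @param trace a [voltage_trace()].
#' @return resting potential, mV.
#' @export
resting_potential <- function(trace) {
  seg <- protocol_segments(trace$protocol)
  if (trace$protocol$zero_current_dur <= 0)
    stopf("protocol has no zero-current segment")
  idx <- segment_idx(trace, seg$zero[1], seg$zero[2])
  if (!length(idx)) stopf("no samples in the zero-current segment")
  mean(trace$voltage[idx])
}

# Model basis for the passive step response over times t (ms from onset):
# columns 1, Ra-component, Rin-component (both in mV per unit resistance).
passive_basis <- function(t_ms, i_inj, tau_p, tau_m) {
  cbind(1,
        i_inj * MV_PER_PA_MOHM * (1 - exp(-t_ms / tau_p)),
        i_inj * MV_PER_PA_MOHM * (1 - exp(-t_ms / tau_m)))
}

#' Fit passive membrane properties to the hyperpolarizing probe
#'
#' Fits the double-exponential charging model
#' `V(t) = V_offset + I (R_a (1 - exp(-t/tau_p)) + R_in (1 - exp(-t/tau_m)))`
#' to the probe-step segment of the smoothed trace by Nelder-Mead
#' minimization of the sum of squared errors. The two components are ordered
#' by time constant: the fast one (`tau_p`, constrained below 10 ms via a
#' logistic transform) is the pipette/series component, the slow one the
#' membrane. Amplitudes and offset are profiled out by linear least squares
#' at each step of the search, and the model prediction is passed through
#' the same smoothing operator as the data so the estimator is unbiased for
#' noiseless signals. Three starts (a method-of-moments seed and two
#' perturbations) guard against local minima; non-convergence is flagged,
#' not raised.
#'
#' @param trace a raw [voltage_trace()] containing the hyperpolarizing step.
#' @param i_inj injected probe current, pA (defaults to the protocol value).
#' @param smooth_window smoothing window, ms.
#' @return list of class `passive_fit`: `v_offset`, `r_a`, `tau_p`, `r_in`,
#'   `tau_m`, `sse`, `converged`, `rmp`.
#' @export
fit_passive <- function(trace, i_inj = trace$protocol$hyper_step_amp,
                        smooth_window = 1) {
  validate_trace(trace)
  seg <- protocol_segments(trace$protocol)
  fs <- trace$protocol$sampling_rate
  if (trace$protocol$hyper_step_dur < 5)
    stopf("probe step (%g ms) shorter than 5 x the pipette time-constant guess",
          trace$protocol$hyper_step_dur)
  sm <- smooth_trace(trace, smooth_window)

  pad <- 2 # ms of pre-onset context given to the model smoothing
  guard <- 1 # ms dropped before the step offset (smoothing edge)
  ext_idx <- segment_idx(sm, seg$hyper[1] - pad, seg$hyper[2])
  fit_sel <- {
    t_ext <- sm$time[ext_idx] * 1000
    t_ext >= seg$hyper[1] - 1e-9 & t_ext < seg$hyper[2] - guard
  }
  y <- sm$voltage[ext_idx][fit_sel]
  t_rel <- sm$time[ext_idx] * 1000 - seg$hyper[1] # ms from onset, <0 in pad

  sse_of <- function(theta) {
    tau_p <- 10 * stats::plogis(theta[1])
    tau_m <- tau_p * (1 + exp(theta[2]))
    X_ext <- passive_basis(pmax(t_rel, 0), i_inj, tau_p, tau_m)
    X_ext[t_rel < 0, 2:3] <- 0
    Xs <- apply(X_ext, 2, smooth_vector, fs = fs, window = smooth_window)
    X <- Xs[fit_sel, , drop = FALSE]
    beta <- tryCatch(qr.coef(qr(X), y), error = function(e) rep(NA_real_, 3))
    if (anyNA(beta)) return(list(sse = Inf, beta = beta, tau = c(tau_p, tau_m)))
    if (beta[2] < 0) { # series resistance cannot be negative
      X2 <- X[, c(1, 3)]
      b2 <- qr.coef(qr(X2), y)
      beta <- c(b2[1], 0, b2[2])
      r <- y - X2 %*% b2
    } else {
      r <- y - X %*% beta
    }
    list(sse = sum(r^2), beta = beta, tau = c(tau_p, tau_m))
  }
  obj <- function(theta) sse_of(theta)$sse

  # method-of-moments seed for tau_m from the 63% crossing of the deflection
  v_off0 <- mean(y[t_rel[fit_sel] < 0.5])
  dv_ss <- mean(y[t_rel[fit_sel] > 0.75 * trace$protocol$hyper_step_dur]) - v_off0
  t63 <- {
    d <- (y - v_off0) / dv_ss
    i63 <- which(d >= 0.63)[1]
    if (is.na(i63)) trace$protocol$hyper_step_dur / 4 else t_rel[fit_sel][i63]
  }
  tau_m0 <- max(2, min(t63, trace$protocol$hyper_step_dur / 2))
  inv <- function(tau_p, tau_m) c(stats::qlogis(min(max(tau_p / 10, 1e-4), 1 - 1e-4)),
                                  log(max(tau_m / tau_p - 1, 1e-3)))
  starts <- list(inv(1, tau_m0), inv(0.5, tau_m0 * 1.5), inv(2, tau_m0 * 0.7))

  best <- NULL
  conv <- FALSE
  for (s in starts) {
    o <- optim(s, obj, method = "Nelder-Mead",
               control = list(reltol = 1e-12, maxit = 2000))
    if (is.null(best) || o$value < best$value) { best <- o }
  }
  # polish from the best point
  o2 <- optim(best$par, obj, method = "Nelder-Mead",
              control = list(reltol = 1e-12, maxit = 2000))
  if (o2$value <= best$value) best <- o2
  conv <- best$convergence == 0
  fin <- sse_of(best$par)
  rmp <- tryCatch(resting_potential(trace), error = function(e) NA_real_)
  out <- list(v_offset = unname(fin$beta[1]), r_a = unname(fin$beta[2]),
              tau_p = fin$tau[1], r_in = unname(fin$beta[3]),
              tau_m = fin$tau[2], sse = fin$sse, converged = conv, rmp = rmp)
  class(out) <- "passive_fit"
  out
}

#' Direct input- and series-resistance estimates from the raw step
#'
#' Model-light cross-check of [fit_passive()]: the total resistance comes
#' from the steady-state deflection divided by the injected current; the
#' membrane component from a log-linear regression of the remaining charging
#' deficit (after the fast series component has settled), whose intercept
#' gives `R_in` and whose slope gives `tau_m`; the series resistance is the
#' remainder. Valid when `tau_p` is much faster than `tau_m` and the step
#' reaches steady state; if the step is shorter than five estimated membrane
#' time constants the result carries a `steady_state` warning flag.
#'
#' @param trace a raw [voltage_trace()].
#' @param smooth_window smoothing window, ms.
#' @return list with `r_in`, `r_a` (Mohm), `tau_m` (ms) and
#'   `steady_state` (logical flag).
#' @export
direct_resistance_estimate <- function(trace, smooth_window = 1) {
  seg <- protocol_segments(trace$protocol)
  i_inj <- trace$protocol$hyper_step_amp
  sm <- smooth_trace(trace, smooth_window)
  idx <- segment_idx(sm, seg$hyper[1], seg$hyper[2] - 1)
  t_rel <- sm$time[idx] * 1000 - seg$hyper[1]
  v <- sm$voltage[idx]
  v_off <- baseline_mean(sm, seg$hyper[1], dur_ms = 50)
  dur <- trace$protocol$hyper_step_dur
  dv_ss <- mean(v[t_rel > 0.75 * dur]) - v_off
  r_tot <- dv_ss / (i_inj * MV_PER_PA_MOHM)
  # crude tau_m from the 63% crossing, then refine on the log-deficit
  frac <- (v - v_off) / dv_ss
  i63 <- which(frac >= 0.63)[1]
  t63 <- if (is.na(i63)) dur / 4 else t_rel[i63]
  lo <- max(5, 0.25 * t63)
  hi <- min(0.9 * dur, max(2.5 * t63, lo + 5))
  sel <- t_rel >= lo & t_rel <= hi
  # charging deficit in Mohm: deflection(t) - steady = -I (R_in e^{-t/tau_m}
  # + R_a e^{-t/tau_p}), so divide by -I to get a positive resistance scale
  d <- (v[sel] - dv_ss - v_off) / (-i_inj * MV_PER_PA_MOHM)
  ok <- d > 0
  fit <- lm(log(d[ok]) ~ t_rel[sel][ok])
  tau_m <- -1 / coef(fit)[2]
  r_in <- exp(coef(fit)[1])
  # the "steady-state" window still carries a small residue of the membrane
  # charge; correct the total-resistance estimate for it
  t_ss <- t_rel[t_rel > 0.75 * dur]
  r_tot <- r_tot + r_in * mean(exp(-t_ss / tau_m))
  r_a <- max(0, r_tot - r_in)
  list(r_in = unname(r_in), r_a = unname(r_a), tau_m = unname(tau_m),
       steady_state = dur >= 5 * tau_m)
}

#' Input-resistance inclusion filter
#'
#' Keeps cells whose fitted input resistance lies between 100 and 450 Mohm
#' (inclusive at both ends), the standard pyramidal-cell inclusion window;
#' cells outside the window most likely belong to a different cell class.
#'
#' @param passive_table data.frame with columns `cell_id` and `r_in`.
#' @param lower,upper inclusion bounds, Mohm.
#' @return list with `kept` (filtered data.frame) and `report` (data.frame of
#'   exclusions with reasons; zero rows when nothing was excluded).
#' @export
qc_filter <- function(passive_table, lower = 100, upper = 450) {
  stopifnot(all(c("cell_id", "r_in") %in% names(passive_table)))
  keep <- passive_table$r_in >= lower & passive_table$r_in <= upper
  keep[is.na(keep)] <- FALSE
  excl <- passive_table[!keep, , drop = FALSE]
  report <- data.frame(
    cell_id = excl$cell_id,
    r_in = excl$r_in,
    reason = ifelse(is.na(excl$r_in), "r_in not estimable",
                    ifelse(excl$r_in < lower,
                           sprintf("r_in below %g Mohm", lower),
                           sprintf("r_in above %g Mohm", upper))),
    stringsAsFactors = FALSE)
  list(kept = passive_table[keep, , drop = FALSE], report = report)
}
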