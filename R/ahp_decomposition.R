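#' Locate the AHP peak after the depolarizing step
#'
#' The most negative excursion relative to the pre-step baseline within the
#' first 100 ms after the step offset. The baseline is the mean over the
#' 100 ms preceding the hyperpolarizing probe (shared with the spike
#' analysis). If the trace never drops below baseline there, the peak
#' amplitude is 0 and downstream fitting is skipped.
#'
#' @param trace a smoothed (and possibly decimated) [voltage_trace()].
#' @param search_window window after the step offset to search, ms.
#' @param guard dead time after the step offset excluded from the search,
#'   ms (default 2): the smoothing window smears the offset discontinuity
#'   over about 1 ms and those transition samples belong to neither the step
#'   nor the decay.
#' @return list with `peak_amp` (mV, <= 0), `t_peak` (ms from sweep start)
#'   and `baseline` (mV).
#' @export
ahp_peak <- function(trace, search_window = 100, guard = 2) {
  seg <- protocol_segments(trace$protocol)
  baseline <- baseline_mean(trace, seg$hyper[1])
  idx <- segment_idx(trace, seg$depol[2] + guard, seg$depol[2] + search_window)
  dv <- trace$voltage[idx] - baseline
  i_min <- which.min(dv)
  if (dv[i_min] >= 0)
    return(list(peak_amp = 0, t_peak = NA_real_, baseline = baseline))
  list(peak_amp = dv[i_min], t_peak = trace$time[idx[i_min]] * 1000,
       baseline = baseline)
}

# tau transforms onto their bound intervals: medium (0, 400], slow
# (400, 8000] ms.
tau_med_of <- function(a) 400 * stats::plogis(a)
tau_slow_of <- function(a) 400 + 7600 * stats::plogis(a)
tau_med_inv <- function(tau) stats::qlogis(min(max(tau / 400, 1e-6), 1 - 1e-6))
tau_slow_inv <- function(tau) stats::qlogis(min(max((tau - 400) / 7600, 1e-6), 1 - 1e-6))

# Linear least-squares amplitudes for fixed decay constants; returns the
# amplitudes and the SSE. Used for multi-start scoring and by the oracle in
# the tests.
ahp_linear_amplitudes <- function(t_ms, y, tau_med, tau_slow) {
  X <- cbind(exp(-t_ms / tau_med), exp(-t_ms / tau_slow))
  beta <- tryCatch(qr.coef(qr(X), y), error = function(e) c(NA_real_, NA_real_))
  if (anyNA(beta)) return(list(v = beta, sse = Inf))
  r <- y - X %*% beta
  list(v = as.numeric(beta), sse = sum(r^2))
}

#' Bi-exponential decomposition of the AHP decay
#'
#' Fits `V(t) = V_med exp(-t/tau_med) + V_slow exp(-t/tau_slow)` to the
#' baseline-subtracted decay from the AHP peak to the end of the recorded
#' window, by Nelder-Mead minimization of the sum of squared errors with the
#' decay constants constrained (via logistic transforms) to 0-400 ms for the
#' medium and 400 ms - 8 s for the slow component. Components are labeled by
#' the bound interval their decay constant occupies, never by amplitude. The
#' trace is smoothed and then decimated by block averaging (default to
#' 1 kHz) before fitting: block means are unbiased for decays this slow and,
#' unlike an IIR anti-alias filter, do not ring at the step-offset
#' discontinuity; the decimation leaves the optimum unchanged while making
#' the 8-s tail affordable.
#'
#' Initialization scores a 3 x 3 grid of decay-constant pairs (50/150/350 ms
#' by 1/3/6 s) with linear least-squares amplitudes, starts Nelder-Mead from
#' the best pair (ties broken toward the smaller slow decay), and polishes
#' with a restart.
#'
#' @param trace a raw [voltage_trace()].
#' @param decimate_hz sampling rate used for the fit (default 1000).
#' @param smooth_window smoothing window, ms.
#' @return list of class `ahp_fit`: `v_med`, `tau_med`, `v_slow`, `tau_slow`,
#'   `r2`, `sse`, `peak_amp`, `t_fit_start`, `converged` and `n_fit` (points
#'   in the window). `converged` is `"ok"`, `"at_bound"` (a decay constant
#'   pinned at its interval edge), `"ill_conditioned"` (decay constants
#'   within a factor of two of each other, where the two components are not
#'   separable), `"no_ahp"` or `"failed"`.
#' @export
fit_ahp <- function(trace, decimate_hz = 1000, smooth_window = 1) {
  validate_trace(trace)
  sm <- smooth_trace(trace, smooth_window)
  if (trace$protocol$sampling_rate > decimate_hz)
    sm <- block_decimate_trace(sm, decimate_hz)
  pk <- ahp_peak(sm)
  out <- list(v_med = 0, tau_med = NA_real_, v_slow = 0, tau_slow = NA_real_,
              r2 = NA_real_, sse = NA_real_, peak_amp = pk$peak_amp,
              t_fit_start = pk$t_peak, converged = "no_ahp", n_fit = 0L)
  class(out) <- "ahp_fit"
  if (pk$peak_amp >= 0) return(out)

  seg <- protocol_segments(trace$protocol)
  idx <- segment_idx(sm, pk$t_peak, seg$tail[2])
  t_ms <- sm$time[idx] * 1000 - pk$t_peak
  y <- sm$voltage[idx] - pk$baseline
  out$n_fit <- length(idx)

  starts <- expand.grid(tau_med = c(50, 150, 350),
                        tau_slow = c(1000, 3000, 6000))
  starts$sse <- NA_real_
  amps <- vector("list", nrow(starts))
  for (i in seq_len(nrow(starts))) {
    a <- ahp_linear_amplitudes(t_ms, y, starts$tau_med[i], starts$tau_slow[i])
    starts$sse[i] <- a$sse
    amps[[i]] <- a$v
  }
  ord <- order(starts$sse, starts$tau_slow) # ties -> smaller tau_slow
  i0 <- ord[1]
  theta0 <- c(amps[[i0]][1], amps[[i0]][2],
              tau_med_inv(starts$tau_med[i0]), tau_slow_inv(starts$tau_slow[i0]))

  obj <- function(theta) {
    pred <- theta[1] * exp(-t_ms / tau_med_of(theta[3])) +
      theta[2] * exp(-t_ms / tau_slow_of(theta[4]))
    sum((y - pred)^2)
  }
  o <- optim(theta0, obj, method = "Nelder-Mead",
             control = list(reltol = 1e-12, maxit = 5000))
  o2 <- optim(o$par, obj, method = "Nelder-Mead",
              control = list(reltol = 1e-12, maxit = 5000))
  if (o2$value <= o$value) o <- o2

  tau_med <- tau_med_of(o$par[3])
  tau_slow <- tau_slow_of(o$par[4])
  at_bound <- tau_med > 0.995 * 400 || tau_med < 1e-3 ||
    tau_slow > 400 + 0.995 * 7600 || tau_slow < 400 + 0.005 * 7600
  pred <- o$par[1] * exp(-t_ms / tau_med) + o$par[2] * exp(-t_ms / tau_slow)
  r2 <- if (sd(y) == 0 || sd(pred) == 0) NA_real_ else cor(y, pred)^2

  out$v_med <- o$par[1]
  out$v_slow <- o$par[2]
  out$tau_med <- tau_med
  out$tau_slow <- tau_slow
  out$sse <- o$value
  out$r2 <- r2
  out$converged <- if (o$convergence != 0) "failed"
    else if (at_bound) "at_bound"
    else if (tau_slow / tau_med < 2) "ill_conditioned"
    else "ok"
  out
}

#' Goodness of fit of an AHP decomposition
#'
#' The squared Pearson correlation between the fitted bi-exponential curve
#' and the smoothed, decimated data over the fit window.
#'
#' @param fit an [fit_ahp()] result.
#' @param trace the [voltage_trace()] it was fitted to.
#' @param decimate_hz,smooth_window as used for the fit.
#' @return `r2`, or `NA` for zero-variance data.
#' @export
fit_quality <- function(fit, trace, decimate_hz = 1000, smooth_window = 1) {
  if (is.na(fit$t_fit_start)) return(NA_real_)
  sm <- smooth_trace(trace, smooth_window)
  if (trace$protocol$sampling_rate > decimate_hz)
    sm <- block_decimate_trace(sm, decimate_hz)
  seg <- protocol_segments(trace$protocol)
  baseline <- baseline_mean(sm, seg$hyper[1])
  idx <- segment_idx(sm, fit$t_fit_start, seg$tail[2])
  t_ms <- sm$time[idx] * 1000 - fit$t_fit_start
  y <- sm$voltage[idx] - baseline
  pred <- fit$v_med * exp(-t_ms / fit$tau_med) +
    fit$v_slow * exp(-t_ms / fit$tau_slow)
  if (sd(y) == 0 || sd(pred) == 0) return(NA_real_)
  cor(y, pred)^2
}

#' Medium/slow AHP change across an ablation pair
#'
#' Percent change of the mean fitted medium and slow amplitudes across a
#' range of current steps, as used for pharmacological validation (amplitudes
#' averaged over the 325-450 pA steps).
#'
#' @param fits_before,fits_after named lists (by step, pA) of [fit_ahp()]
#'   results covering the step range.
#' @param step_range inclusive range of steps to average, pA.
#' @return list with `mahp_change_pct` and `sahp_change_pct`.
#' @export
ablation_contrast <- function(fits_before, fits_after,
                              step_range = c(325, 450)) {
  pick <- function(fits) {
    s <- as.numeric(names(fits))
    sel <- s >= step_range[1] & s <= step_range[2]
    if (!any(sel)) stopf("no fits inside the step range %g-%g pA",
                         step_range[1], step_range[2])
    fits[sel]
  }
  fb <- pick(fits_before); fa <- pick(fits_after)
  mean_of <- function(fits, f) mean(vapply(fits, `[[`, numeric(1), f))
  pct <- function(before, after) 100 * (after / before - 1)
  list(
    mahp_change_pct = pct(mean_of(fb, "v_med"), mean_of(fa, "v_med")),
    sahp_change_pct = pct(mean_of(fb, "v_slow"), mean_of(fa, "v_slow")))
}

#' Per-step AHP table for one cell
#'
#' Fits every sweep of a cell and assembles the long-format feature table
#' consumed by the cohort statistics.
#'
#' @param cell a cell record (list with `cell_id`, `group_label`, `sweeps`).
#' @param ... passed to [fit_ahp()].
#' @return data.frame with one row per sweep: `cell_id`, `group`, `step`,
#'   `v_med`, `tau_med`, `v_slow`, `tau_slow`, `r2`, `peak_amp`,
#'   `converged`.
#' @export
ahp_by_step <- function(cell, ...) {
  rows <- lapply(names(cell$sweeps), function(sid) {
    f <- fit_ahp(cell$sweeps[[sid]], ...)
    data.frame(cell_id = cell$cell_id, group = cell$group_label,
               step = as.numeric(sid), v_med = f$v_med, tau_med = f$tau_med,
               v_slow = f$v_slow, tau_slow = f$tau_slow, r2 = f$r2,
               peak_amp = f$peak_amp, converged = f$converged,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$step), , drop = FALSE]
}
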