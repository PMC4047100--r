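#' A single current-clamp voltage sweep
#'
#' Container for one uniformly sampled membrane-potential recording plus its
#' stimulus protocol. Time is in seconds, 0-based at sweep start; voltage is
#' in mV. The time grid must be uniform (to within 1 ppm) and consistent with
#' the protocol's sampling rate.
#'
#' @param time numeric vector of sample times (s), strictly increasing.
#' @param voltage numeric vector of membrane potential (mV), same length.
#' @param protocol a [current_protocol()].
#' @param cell_id,sweep_id identifiers; `sweep_id` defaults to the step
#'   amplitude in pA.
#' @param group_label one of `"vehicle"`, `"treated"`, `"unknown"`.
#' @param ground_truth optional list of generative parameters (attached by
#'   the synthetic generator; `NULL` for real data).
#' @return object of class `voltage_trace`.
#' @export
voltage_trace <- function(time, voltage, protocol,
                          cell_id = "cell1",
                          sweep_id = as.character(protocol$depol_step_amp),
                          group_label = "unknown",
                          ground_truth = NULL) {
  tr <- structure(
    list(time = as.numeric(time), voltage = as.numeric(voltage),
         protocol = protocol, cell_id = as.character(cell_id),
         sweep_id = as.character(sweep_id),
         group_label = match.arg(group_label, c("vehicle", "treated", "unknown")),
         ground_truth = ground_truth),
    class = "voltage_trace")
  validate_trace(tr)
  tr
}

validate_trace <- function(tr) {
  stopifnot(inherits(tr, "voltage_trace"))
  n <- length(tr$time)
  if (n < 2L) stopf("trace must have at least 2 samples")
  if (length(tr$voltage) != n)
    stopf("time and voltage lengths differ (%d vs %d)", n, length(tr$voltage))
  dt <- diff(tr$time)
  if (any(dt <= 0)) stopf("time must be strictly increasing")
  dt0 <- (tr$time[n] - tr$time[1]) / (n - 1)
  if (max(abs(dt - dt0)) > 1e-6 * dt0)
    stopf("time grid is not uniform to within 1 ppm")
  fs <- 1 / dt0
  if (abs(fs - tr$protocol$sampling_rate) > 1e-6 * tr$protocol$sampling_rate)
    stopf("sampling rate in metadata (%g Hz) does not match time grid (%g Hz)",
          tr$protocol$sampling_rate, fs)
  invisible(tr)
}

# Index range (inclusive) of samples with t in [from, to) ms from sweep start.
segment_idx <- function(tr, from_ms, to_ms) {
  t_ms <- tr$time * 1000
  which(t_ms >= from_ms - 1e-9 & t_ms < to_ms - 1e-9)
}

# Mean voltage over the `dur_ms` immediately preceding `at_ms`. Baselines for
# the spike-detection criterion and AHP amplitudes are defined this way.
baseline_mean <- function(tr, at_ms, dur_ms = 100) {
  idx <- segment_idx(tr, max(0, at_ms - dur_ms), at_ms)
  if (!length(idx)) stopf("no samples in baseline window before %g ms", at_ms)
  mean(tr$voltage[idx])
}

#' @export
print.voltage_trace <- function(x, ...) {
  cat(sprintf(
    "<voltage_trace> cell %s sweep %s (%s): %d samples @ %g kHz, %.1f s\n",
    x$cell_id, x$sweep_id, x$group_label, length(x$time),
    x$protocol$sampling_rate / 1000, max(x$time)))
  invisible(x)
}
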