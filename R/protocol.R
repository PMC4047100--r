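#' Current-injection protocol for one sweep
#'
#' Describes the stimulus timeline of a single current-clamp sweep: a steady
#' holding current, a small hyperpolarizing probe step (to measure passive
#' membrane properties and series resistance), a depolarizing step that evokes
#' the spike train and the after-hyperpolarization, a long post-step recording
#' window, and a zero-current segment appended at the sweep end to check the
#' membrane potential. A sweep family steps the depolarizing amplitude from
#' 150 to 450 pA in 25-pA increments (13 sweeps).
#'
#' @param depol_step_amp depolarizing step amplitude in pA; must lie on the
#'   13-value grid `seq(150, 450, by = 25)`.
#' @param holding_current steady holding current in pA. The synthetic cells
#'   rest at the target baseline by construction, so the default is 0.
#' @param hyper_step_amp hyperpolarizing probe amplitude in pA, relative to
#'   the holding current (default -20).
#' @param hyper_step_dur duration of the probe step in ms (default 200).
#' @param depol_step_dur duration of the depolarizing step in ms (default 600).
#' @param record_dur total recorded duration in ms, from sweep start through
#'   the post-step AHP window (default 8000).
#' @param zero_current_dur duration of the absolute-zero-current segment
#'   appended after `record_dur`, in ms (default 200).
#' @param hyper_onset,depol_onset onset times of the two steps in ms from
#'   sweep start (defaults 100 and 500; at least 100 ms of baseline precedes
#'   each step so baselines can be measured).
#' @param inter_sweep_interval interval between successive sweeps in seconds
#'   (metadata only; default 30).
#' @param sampling_rate acquisition rate in Hz (default 50000).
#'
#' @return an object of class `current_protocol`.
#' @seealso [protocol_family()] for the full 13-step family,
#'   [generate_trace()] for simulation.
#' @export
current_protocol <- function(depol_step_amp,
                             holding_current = 0,
                             hyper_step_amp = -20,
                             hyper_step_dur = 200,
                             depol_step_dur = 600,
                             record_dur = 8000,
                             zero_current_dur = 200,
                             hyper_onset = 100,
                             depol_onset = 500,
                             inter_sweep_interval = 30,
                             sampling_rate = 50000) {
  p <- list(
    depol_step_amp = depol_step_amp,
    holding_current = holding_current,
    hyper_step_amp = hyper_step_amp,
    hyper_step_dur = hyper_step_dur,
    depol_step_dur = depol_step_dur,
    record_dur = record_dur,
    zero_current_dur = zero_current_dur,
    hyper_onset = hyper_onset,
    depol_onset = depol_onset,
    inter_sweep_interval = inter_sweep_interval,
    sampling_rate = sampling_rate
  )
  class(p) <- "current_protocol"
  validate_protocol(p)
  p
}

#' The 13-value depolarizing-step grid (pA)
#' @return numeric vector `seq(150, 450, by = 25)`.
#' @export
step_grid <- function() seq(150, 450, by = 25)

validate_protocol <- function(p) {
  stopifnot(inherits(p, "current_protocol"))
  num <- c("depol_step_amp", "holding_current", "hyper_step_amp",
           "hyper_step_dur", "depol_step_dur", "record_dur",
           "zero_current_dur", "hyper_onset", "depol_onset",
           "inter_sweep_interval", "sampling_rate")
  for (f in num) if (!is_number(p[[f]])) stopf("protocol field '%s' must be a single finite number", f)
  if (!p$depol_step_amp %in% step_grid())
    stopf("depol_step_amp must be one of %s pA (got %g)",
          paste(range(step_grid()), collapse = "-"), p$depol_step_amp)
  if (p$sampling_rate <= 0) stopf("sampling_rate must be positive")
  if (p$hyper_step_dur <= 0 || p$depol_step_dur <= 0)
    stopf("step durations must be positive")
  # segments must be disjoint and lie inside the recorded window
  h0 <- p$hyper_onset; h1 <- h0 + p$hyper_step_dur
  d0 <- p$depol_onset; d1 <- d0 + p$depol_step_dur
  if (h0 < 0 || h1 > d0)
    stopf("hyperpolarizing step [%g, %g] ms must precede the depolarizing step onset (%g ms)", h0, h1, d0)
  if (d1 >= p$record_dur)
    stopf("depolarizing step must end before record_dur so the AHP tail is recorded")
  invisible(p)
}

#' Build the standard 13-sweep protocol family
#'
#' @param ... arguments passed to [current_protocol()] other than
#'   `depol_step_amp`.
#' @param steps depolarizing amplitudes to include (default all 13).
#' @return a named list of `current_protocol` objects keyed by step amplitude.
#' @export
protocol_family <- function(..., steps = step_grid()) {
  stopifnot(all(steps %in% step_grid()))
  out <- lapply(steps, function(s) current_protocol(depol_step_amp = s, ...))
  names(out) <- as.character(steps)
  out
}

# Segment boundaries in ms from sweep start, used by the generator and the
# feature extractors alike.
protocol_segments <- function(p) {
  list(
    hyper = c(p$hyper_onset, p$hyper_onset + p$hyper_step_dur),
    depol = c(p$depol_onset, p$depol_onset + p$depol_step_dur),
    tail = c(p$depol_onset + p$depol_step_dur, p$record_dur),
    zero = c(p$record_dur, p$record_dur + p$zero_current_dur),
    total = c(0, p$record_dur + p$zero_current_dur)
  )
}

#' @export
print.current_protocol <- function(x, ...) {
  seg <- protocol_segments(x)
  cat(sprintf(
    "<current_protocol> depol %g pA [%g-%g ms], hyper %g pA [%g-%g ms], %g kHz, %g ms total\n",
    x$depol_step_amp, seg$depol[1], seg$depol[2],
    x$hyper_step_amp, seg$hyper[1], seg$hyper[2],
    x$sampling_rate / 1000, seg$total[2]))
  invisible(x)
}
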