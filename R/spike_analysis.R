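#' Smooth a trace by local linear least squares
#'
#' Each sample is replaced by the value at the window center of a linear
#' least-squares fit over a centered window (a first-order Savitzky-Golay
#' filter, [signal::sgolayfilt()] with `p = 1`). Constant and linear signals
#' pass through unchanged. All downstream feature extraction operates on
#' smoothed traces.
#'
#' @param trace a [voltage_trace()].
#' @param window window length in ms (default 1).
#' @return the smoothed [voltage_trace()].
#' @export
smooth_trace <- function(trace, window = 1) {
  validate_trace(trace)
  fs <- trace$protocol$sampling_rate
  n_w <- round(window * fs / 1000)
  if (n_w %% 2 == 0) n_w <- n_w + 1
  n_w <- max(n_w, 3)
  if (n_w > length(trace$voltage)) stopf("smoothing window longer than trace")
  out <- trace
  out$voltage <- as.numeric(signal::sgolayfilt(trace$voltage, p = 1, n = n_w))
  attr(out, "smoothed") <- TRUE
  out
}

# The linear smoothing operator as applied by smooth_trace, for use on model
# predictions so that fits in "smoothed space" stay unbiased (see
# fit_passive). For a degree-1 fit the central Savitzky-Golay response is a
# centered running mean, which cumsum computes in O(n); the first and last
# half-windows differ from sgolayfilt's edge fits, so callers must keep
# edges out of their fit windows.
smooth_vector <- function(v, fs, window = 1) {
  n_w <- round(window * fs / 1000)
  if (n_w %% 2 == 0) n_w <- n_w + 1
  n_w <- max(n_w, 3)
  h <- (n_w - 1L) %/% 2L
  n <- length(v)
  cs <- cumsum(c(0, v))
  out <- v
  core <- (h + 1L):(n - h)
  out[core] <- (cs[core + h + 1L] - cs[core - h]) / n_w
  out
}

#' Detect spikes in the depolarizing-step window
#'
#' Local maxima of the (smoothed) trace whose amplitude exceeds the baseline
#' membrane voltage by more than 40 mV count as spikes. The baseline is the
#' mean over the 100 ms immediately preceding the depolarizing step. Peaks
#' closer than a 2-ms refractory separation are merged, keeping the higher
#' one.
#'
#' @param trace a smoothed [voltage_trace()].
#' @param baseline baseline membrane voltage in mV; computed from the
#'   pre-step segment when `NULL`.
#' @param min_height detection criterion in mV above baseline (default 40).
#' @param refractory minimum inter-peak separation in ms (default 2).
#' @return numeric vector of spike peak times in ms from sweep start (empty
#'   when no spikes).
#' @export
detect_spikes <- function(trace, baseline = NULL, min_height = 40,
                          refractory = 2) {
  seg <- protocol_segments(trace$protocol)
  if (is.null(baseline)) baseline <- baseline_mean(trace, seg$depol[1])
  idx <- segment_idx(trace, seg$depol[1], seg$depol[2])
  v <- trace$voltage[idx]
  t_ms <- trace$time[idx] * 1000
  if (length(v) < 3) return(numeric(0))
  core <- 2:(length(v) - 1)
  is_peak <- v[core] >= v[core - 1] & v[core] > v[core + 1] &
    (v[core] - baseline) > min_height
  cand <- core[is_peak]
  if (!length(cand)) return(numeric(0))
  # non-maximum suppression within the refractory separation
  ord <- cand[order(v[cand], decreasing = TRUE)]
  keep <- logical(0)
  kept_t <- numeric(0)
  for (i in ord) {
    if (!length(kept_t) || min(abs(t_ms[i] - kept_t)) >= refractory)
      kept_t <- c(kept_t, t_ms[i])
  }
  sort(kept_t)
}

#' Spike threshold from the differentiated trace
#'
#' The threshold is the earliest point of the rising phase where the slope of
#' the (smoothed) voltage trace surpasses 20 mV/ms, found by scanning
#' backward from the spike peak: walking back from the peak, the first sample
#' whose centered-difference dV/dt drops below the criterion marks the start
#' of the suprathreshold run, and the sample after it is the threshold.
#'
#' @param trace a smoothed [voltage_trace()].
#' @param spike_time spike peak time in ms (from [detect_spikes()]).
#' @param slope_crit slope criterion in mV/ms (default 20).
#' @param lookback maximum search window before the peak, ms (default 10).
#' @return list with `threshold_v` (mV) and `threshold_t` (ms), or both `NA`
#'   when the slope never reaches the criterion.
#' @export
spike_threshold <- function(trace, spike_time, slope_crit = 20, lookback = 10) {
  fs <- trace$protocol$sampling_rate
  dt_ms <- 1000 / fs
  i_pk <- which.min(abs(trace$time * 1000 - spike_time))
  i_lo <- max(2L, i_pk - as.integer(round(lookback / dt_ms)))
  v <- trace$voltage
  dvdt <- (v[(i_lo + 1):(i_pk + 1)] - v[(i_lo - 1):(i_pk - 1)]) / (2 * dt_ms)
  # dvdt[k] is the slope at sample (i_lo - 1 + k)
  above <- dvdt >= slope_crit
  if (!any(above)) return(list(threshold_v = NA_real_, threshold_t = NA_real_))
  k_pk <- length(dvdt)
  # scan backward from the peak to the start of the contiguous run
  k <- k_pk
  while (k > 1 && above[k - 1]) k <- k - 1
  if (!above[k]) {
    # peak sample itself below criterion (flat top): use last run before peak
    runs <- rle(above)
    ends <- cumsum(runs$lengths)
    last_true <- max(which(runs$values))
    k <- ends[last_true] - runs$lengths[last_true] + 1
  }
  i_th <- i_lo - 1 + k
  list(threshold_v = v[i_th], threshold_t = trace$time[i_th] * 1000)
}

# First time v crosses `level`, moving forward over samples idx (linear
# interpolation between samples). direction +1: upward crossing, -1 downward.
crossing_time <- function(t_ms, v, level, direction = 1) {
  d <- direction * (v - level)
  hit <- which(d[-1] >= 0 & d[-length(d)] < 0)
  if (!length(hit)) return(NA_real_)
  i <- hit[1]
  frac <- (level - v[i]) / (v[i + 1] - v[i])
  t_ms[i] + frac * (t_ms[i + 1] - t_ms[i])
}

#' Waveform features of a single spike
#'
#' Measures, on the smoothed trace: peak potential, threshold (see
#' [spike_threshold()]), amplitude (peak minus threshold), 20-80% rise time
#' (time between crossings of 20% and 80% of the threshold-to-peak
#' difference, sub-sample by linear interpolation), rising slope (the 80-20%
#' voltage difference divided by the rise time) and width at half maximum
#' (between the rising and falling crossings of threshold + amplitude/2).
#'
#' @param trace a smoothed [voltage_trace()].
#' @param spike_time spike peak time, ms.
#' @param window_end latest time (ms) the falling phase may extend to
#'   (defaults to 10 ms after the peak); if the half-height re-crossing is
#'   not found before it, `half_width` is `NA`.
#' @return list of class `spike_features`: `t_peak`, `v_peak`,
#'   `threshold_v`, `threshold_t`, `amplitude`, `rise_time_20_80` (us),
#'   `rising_slope` (mV/ms), `half_width` (ms).
#' @export
spike_waveform_features <- function(trace, spike_time, window_end = NULL) {
  t_ms <- trace$time * 1000
  i_pk <- which.min(abs(t_ms - spike_time))
  v_peak <- trace$voltage[i_pk]
  t_peak <- t_ms[i_pk]
  th <- spike_threshold(trace, spike_time)
  feats <- list(t_peak = t_peak, v_peak = v_peak,
                threshold_v = th$threshold_v, threshold_t = th$threshold_t,
                amplitude = NA_real_, rise_time_20_80 = NA_real_,
                rising_slope = NA_real_, half_width = NA_real_)
  class(feats) <- "spike_features"
  if (is.na(th$threshold_v)) return(feats)
  amp <- v_peak - th$threshold_v
  feats$amplitude <- amp
  i_th <- which.min(abs(t_ms - th$threshold_t))
  rise_idx <- i_th:i_pk
  t20 <- crossing_time(t_ms[rise_idx], trace$voltage[rise_idx],
                       th$threshold_v + 0.2 * amp)
  t80 <- crossing_time(t_ms[rise_idx], trace$voltage[rise_idx],
                       th$threshold_v + 0.8 * amp)
  if (!is.na(t20) && !is.na(t80) && t80 > t20) {
    feats$rise_time_20_80 <- (t80 - t20) * 1000 # us
    feats$rising_slope <- (0.6 * amp) / (t80 - t20) # mV/ms
  }
  half <- th$threshold_v + 0.5 * amp
  t_half_up <- crossing_time(t_ms[rise_idx], trace$voltage[rise_idx], half)
  if (is.null(window_end)) window_end <- t_peak + 10
  fall_idx <- i_pk:min(length(t_ms), which.min(abs(t_ms - window_end)))
  t_half_dn <- crossing_time(t_ms[fall_idx], trace$voltage[fall_idx], half,
                             direction = -1)
  if (!is.na(t_half_up) && !is.na(t_half_dn))
    feats$half_width <- t_half_dn - t_half_up
  feats
}

#' Interval statistics of a spike train
#'
#' Interspike intervals and the accommodation index: 100 times the ratio of
#' the final interspike interval to the first. With fewer than three spikes
#' the first and last interval coincide (or do not exist) and the index is
#' reported missing.
#'
#' @param spike_times numeric vector of spike times, ms.
#' @return list of class `spike_train_stats`: `n_spikes`, `spike_times`,
#'   `isis`, `mean_isi`, `first_isi`, `last_isi`, `accommodation_pct`.
#' @export
train_stats <- function(spike_times) {
  spike_times <- sort(spike_times)
  n <- length(spike_times)
  isis <- if (n >= 2) diff(spike_times) else numeric(0)
  out <- list(
    n_spikes = n, spike_times = spike_times, isis = isis,
    mean_isi = if (length(isis)) mean(isis) else NA_real_,
    first_isi = if (length(isis)) isis[1] else NA_real_,
    last_isi = if (length(isis)) isis[length(isis)] else NA_real_,
    accommodation_pct = if (n >= 3) 100 * isis[length(isis)] / isis[1] else NA_real_)
  class(out) <- "spike_train_stats"
  out
}

#' All spike measurements for one sweep
#'
#' Smooths the sweep, detects spikes, and returns per-spike waveform
#' features together with the train statistics. The falling-phase search of
#' each spike is limited by the next spike's peak.
#'
#' @param trace a raw [voltage_trace()].
#' @param smooth_window smoothing window, ms.
#' @return list with `spikes` (list of [spike_waveform_features()] results),
#'   `train` (a [train_stats()] result) and `baseline` (mV).
#' @export
sweep_spike_features <- function(trace, smooth_window = 1) {
  sm <- smooth_trace(trace, smooth_window)
  seg <- protocol_segments(trace$protocol)
  baseline <- baseline_mean(sm, seg$depol[1])
  times <- detect_spikes(sm, baseline = baseline)
  feats <- vector("list", length(times))
  for (i in seq_along(times)) {
    w_end <- if (i < length(times)) times[i + 1] else times[i] + 10
    feats[[i]] <- spike_waveform_features(sm, times[i], window_end = w_end)
  }
  list(spikes = feats, train = train_stats(times), baseline = baseline)
}

#' Average first-spike features across current steps for one cell
#'
#' Active membrane properties are measured on the first action potential of
#' each sweep and averaged feature-wise across the sweeps of the cell.
#'
#' @param step_features named list (by step) of [sweep_spike_features()]
#'   results, or a data.frame of first-spike features with one row per step.
#' @return a one-row data.frame of averaged first-spike features (all `NA`
#'   when no sweep has a spike).
#' @export
first_spike_cell_average <- function(step_features) {
  if (is.data.frame(step_features)) {
    tab <- step_features
  } else {
    rows <- lapply(step_features, function(sf) {
      if (!length(sf$spikes)) return(NULL)
      as.data.frame(unclass(sf$spikes[[1]]))
    })
    rows <- Filter(Negate(is.null), rows)
    if (!length(rows)) {
      tab <- as.data.frame(setNames(as.list(rep(NA_real_, 8)),
        c("t_peak", "v_peak", "threshold_v", "threshold_t", "amplitude",
          "rise_time_20_80", "rising_slope", "half_width")))
      return(tab)
    }
    tab <- do.call(rbind, rows)
  }
  as.data.frame(lapply(tab, function(col) mean(col, na.rm = TRUE)))
}
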