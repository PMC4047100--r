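#' Generative parameters for a single synthetic sweep
#'
#' Ground-truth parameters of the synthetic-trace forward model. The model
#' is: resting potential, plus the passive double-exponential response to the
#' hyperpolarizing probe (series + membrane components, the same equation the
#' passive fitter inverts), plus a capped subthreshold depolarization during
#' the spiking step, plus stereotyped spike templates at generated spike
#' times, plus a post-step AHP that is exactly the sum of a medium and a slow
#' exponential, plus band-limited Gaussian noise.
#'
#' Defaults are patterned on whole-cell recordings from pyramidal neurons:
#' resting potential near -70 mV, input resistance 230 Mohm, membrane time
#' constant 30 ms, series resistance 30 Mohm, spike half-widths near 1 ms,
#' and AHP amplitudes of a few mV decaying over hundreds of ms (medium) and
#' seconds (slow).
#'
#' @param rmp resting membrane potential, mV.
#' @param r_in_true input resistance, Mohm.
#' @param tau_m_true membrane time constant, ms.
#' @param r_a_true series (access) resistance, Mohm.
#' @param tau_p_true pipette/series time constant, ms (fast component).
#' @param v_med_true,tau_med_true medium-AHP amplitude (mV, <= 0) and decay
#'   (ms, in (0, 400]).
#' @param v_slow_true,tau_slow_true slow-AHP amplitude (mV, <= 0) and decay
#'   (ms, in (400, 8000]).
#' @param spike_gain spikes per pA above the 125-pA offset; the generated
#'   count at step amplitude I is `round(spike_gain * (I - 125))`.
#' @param isi_adaptation generative last-ISI/first-ISI ratio (>= 1);
#'   interspike intervals are geometrically stretched to realize it.
#' @param spike_shape list with `peak_height` (mV above rmp, > 40 so spikes
#'   are detectable by design), `rise_tau` and `fall_tau` (ms) of the
#'   difference-of-exponentials template, and `threshold` (mV, absolute).
#' @param noise_sd standard deviation of the band-limited noise, mV.
#' @param noise_bandwidth low-pass corner of the noise, Hz (default 2000,
#'   matching a 0-2 kHz acquisition bandwidth).
#' @param seed integer seed for the noise draw, or `NULL`.
#' @return object of class `trace_gen_params`.
#' @export
trace_gen_params <- function(rmp = -70,
                             r_in_true = 230, tau_m_true = 30,
                             r_a_true = 30, tau_p_true = 1,
                             v_med_true = -3.5, tau_med_true = 120,
                             v_slow_true = -1.4, tau_slow_true = 6000,
                             spike_gain = 0.04, isi_adaptation = 2,
                             spike_shape = list(peak_height = 80,
                                                rise_tau = 0.15,
                                                fall_tau = 1.0,
                                                threshold = -50),
                             noise_sd = 0.2, noise_bandwidth = 2000,
                             seed = NULL) {
  p <- list(rmp = rmp, r_in_true = r_in_true, tau_m_true = tau_m_true,
            r_a_true = r_a_true, tau_p_true = tau_p_true,
            v_med_true = v_med_true, tau_med_true = tau_med_true,
            v_slow_true = v_slow_true, tau_slow_true = tau_slow_true,
            spike_gain = spike_gain, isi_adaptation = isi_adaptation,
            spike_shape = spike_shape, noise_sd = noise_sd,
            noise_bandwidth = noise_bandwidth, seed = seed)
  class(p) <- "trace_gen_params"
  validate_gen_params(p)
  p
}

validate_gen_params <- function(p) {
  stopifnot(inherits(p, "trace_gen_params"))
  if (p$tau_m_true <= 0 || p$tau_p_true <= 0)
    stopf("passive time constants must be positive")
  if (p$tau_med_true <= 0 || p$tau_med_true > 400)
    stopf("tau_med_true must lie in (0, 400] ms")
  if (p$tau_slow_true <= 400 || p$tau_slow_true > 8000)
    stopf("tau_slow_true must lie in (400, 8000] ms")
  if (p$v_med_true > 0 || p$v_slow_true > 0)
    stopf("AHP amplitudes are hyperpolarizing and must be <= 0")
  if (p$noise_sd < 0) stopf("noise_sd must be >= 0")
  if (p$r_in_true <= 0 || p$r_a_true < 0) stopf("r_in_true > 0 and r_a_true >= 0 required")
  if (p$isi_adaptation < 1) stopf("isi_adaptation must be >= 1")
  ss <- p$spike_shape
  if (!all(c("peak_height", "rise_tau", "fall_tau", "threshold") %in% names(ss)))
    stopf("spike_shape needs peak_height, rise_tau, fall_tau, threshold")
  if (ss$peak_height <= 40)
    stopf("spike peak_height must exceed 40 mV above rmp so spikes are detectable")
  if (ss$rise_tau <= 0 || ss$fall_tau <= ss$rise_tau)
    stopf("need 0 < rise_tau < fall_tau")
  invisible(p)
}

# Saturating double-exponential response to a current step of amplitude I
# (pA), evaluated at t (ms) >= 0 after onset; result in mV. This is the
# forward counterpart of the passive-fit model.
passive_step_response <- function(t_ms, i_pA, r_a, tau_p, r_in, tau_m) {
  i_pA * MV_PER_PA_MOHM *
    (r_a * (1 - exp(-t_ms / tau_p)) + r_in * (1 - exp(-t_ms / tau_m)))
}

# Spike template: difference of exponentials normalized to unit peak.
# Returns values for t_ms >= 0 after template onset (the threshold kink).
spike_template <- function(t_ms, rise_tau, fall_tau) {
  g <- exp(-t_ms / fall_tau) - exp(-t_ms / rise_tau)
  t_pk <- log(fall_tau / rise_tau) * rise_tau * fall_tau / (fall_tau - rise_tau)
  g / (exp(-t_pk / fall_tau) - exp(-t_pk / rise_tau))
}

spike_template_peak_delay <- function(rise_tau, fall_tau) {
  log(fall_tau / rise_tau) * rise_tau * fall_tau / (fall_tau - rise_tau)
}

# Generated spike onset times (ms from depolarizing-step onset). Spikes span
# [t_first, depol_dur - 20] with geometrically stretched ISIs so that
# last/first ISI equals isi_adaptation (defined for n >= 3).
generate_spike_times <- function(n_spikes, depol_dur, isi_adaptation,
                                 t_first = 20, t_guard = 20) {
  if (n_spikes <= 0) return(numeric(0))
  if (n_spikes == 1) return(t_first)
  span <- depol_dur - t_first - t_guard
  n_isi <- n_spikes - 1
  if (n_isi == 1) {
    isis <- span
  } else if (isi_adaptation == 1) {
    isis <- rep(span / n_isi, n_isi)
  } else {
    r <- isi_adaptation^(1 / (n_isi - 1))
    isi1 <- span * (r - 1) / (r^n_isi - 1)
    isis <- isi1 * r^(seq_len(n_isi) - 1)
  }
  if (min(isis) < 5)
    stopf("spike train exceeds the depolarizing window: %d spikes need a minimum ISI below 5 ms", n_spikes)
  cumsum(c(t_first, isis))
}

# Band-limited Gaussian noise: white noise brick-wall low-passed in the
# frequency domain (zero phase), rescaled so the delivered sd equals
# noise_sd. Deterministic given the RNG state.
bandlimited_noise <- function(n, fs, sd_mV, bandwidth_hz) {
  if (sd_mV == 0) return(numeric(n))
  w <- rnorm(n)
  if (bandwidth_hz < fs / 2) {
    W <- fft(w)
    f <- (seq_len(n) - 1) * fs / n
    f <- pmin(f, fs - f) # two-sided frequency axis
    W[f > bandwidth_hz] <- 0
    w <- Re(fft(W, inverse = TRUE)) / n
  }
  s <- sd(w)
  if (s == 0) return(numeric(n))
  w * (sd_mV / s)
}

#' Generate one synthetic current-clamp sweep
#'
#' Builds a voltage trace from the documented forward model (see
#' [trace_gen_params()]) and attaches the exact ground truth. The
#' subthreshold depolarization during the spiking step charges (with an
#' effective 5-ms time constant under strong drive) toward the spike
#' threshold rather than toward `I * R_in`, so the inter-spike envelope stays
#' below the baseline + 40 mV detection criterion; the post-step signal is
#' exactly baseline + medium/slow AHP + noise, which keeps the AHP ground
#' truth exact. The last spike ends at least 20 ms before the step offset so
#' spike waveforms never overlap the AHP window.
#'
#' @param protocol a [current_protocol()].
#' @param params a [trace_gen_params()].
#' @return a [voltage_trace()] with a `ground_truth` list carrying the
#'   generative parameters, spike onset/peak times, the spike count and the
#'   noise-free trace components.
#' @export
generate_trace <- function(protocol, params) {
  validate_protocol(protocol)
  validate_gen_params(params)
  seg <- protocol_segments(protocol)
  fs <- protocol$sampling_rate
  n <- round((seg$total[2] / 1000) * fs)
  t_ms <- (seq_len(n) - 1) / fs * 1000

  v <- rep(params$rmp, n)

  # hyperpolarizing probe: superposed charge (at onset) and discharge (at
  # offset) of the double-exponential passive model
  resp <- function(t0) {
    out <- numeric(n)
    idx <- t_ms >= t0
    out[idx] <- passive_step_response(t_ms[idx] - t0, protocol$hyper_step_amp,
                                      params$r_a_true, params$tau_p_true,
                                      params$r_in_true, params$tau_m_true)
    out
  }
  v <- v + resp(seg$hyper[1]) - resp(seg$hyper[2])

  # depolarizing step: capped subthreshold envelope, window-limited
  cap_lin <- protocol$depol_step_amp * MV_PER_PA_MOHM *
    (params$r_a_true + params$r_in_true)
  cap <- min(cap_lin, params$spike_shape$threshold - params$rmp)
  tau_eff <- 5 # ms; effective charge time under suprathreshold drive
  didx <- t_ms >= seg$depol[1] & t_ms < seg$depol[2]
  envelope <- numeric(n)
  envelope[didx] <- cap * (1 - exp(-(t_ms[didx] - seg$depol[1]) / tau_eff))
  v <- v + envelope

  # spikes
  n_spk <- max(0L, as.integer(round(params$spike_gain *
                                      (protocol$depol_step_amp - 125))))
  onsets <- generate_spike_times(n_spk, protocol$depol_step_dur,
                                 params$isi_adaptation)
  ss <- params$spike_shape
  template_amp <- ss$peak_height - (ss$threshold - params$rmp)
  spikes <- numeric(n)
  for (t0 in onsets) {
    t_abs <- seg$depol[1] + t0
    jdx <- which(t_ms >= t_abs & t_ms < t_abs + 10 * ss$fall_tau)
    spikes[jdx] <- spikes[jdx] +
      template_amp * spike_template(t_ms[jdx] - t_abs, ss$rise_tau, ss$fall_tau)
  }
  v <- v + spikes

  # post-step AHP: exact two-exponential sum relative to baseline, from the
  # first sample at/after the step offset through the end of the sweep
  aidx <- t_ms >= seg$depol[2]
  ahp <- numeric(n)
  ahp[aidx] <- params$v_med_true * exp(-(t_ms[aidx] - seg$depol[2]) / params$tau_med_true) +
    params$v_slow_true * exp(-(t_ms[aidx] - seg$depol[2]) / params$tau_slow_true)
  v <- v + ahp

  noise <- with_seed(params$seed,
                     bandlimited_noise(n, fs, params$noise_sd,
                                       params$noise_bandwidth))
  gt <- list(
    params = params, protocol = protocol,
    n_spikes = n_spk,
    spike_onset_ms = seg$depol[1] + onsets,
    spike_peak_ms = seg$depol[1] + onsets +
      spike_template_peak_delay(ss$rise_tau, ss$fall_tau),
    depol_envelope_mV = cap, tau_envelope_ms = tau_eff,
    components = list(passive_and_envelope = v - spikes - ahp,
                      spikes = spikes, ahp = ahp)
  )
  voltage_trace(time = t_ms / 1000, voltage = v + noise, protocol = protocol,
                ground_truth = gt)
}

#' Generate a pharmacological-ablation sweep pair
#'
#' Emulates a bath-application control in which the slow AHP is selectively
#' suppressed (as Forskolin does) while the medium AHP is spared: the second
#' sweep is generated with `v_slow_true * sahp_scale` and
#' `v_med_true * mahp_scale`, all other parameters identical.
#'
#' @param protocol,params as in [generate_trace()].
#' @param sahp_scale,mahp_scale multipliers in \[0, 1\] applied to the slow
#'   and medium amplitudes of the second sweep.
#' @param seed_after seed for the second sweep's noise draw; defaults to the
#'   same seed as the first (so scales of 1 reproduce the first sweep
#'   exactly). Pass a different seed for an independent noise realization.
#' @return list with elements `before` and `after` (two [voltage_trace()]s).
#' @export
generate_ablation_pair <- function(protocol, params, sahp_scale, mahp_scale = 1,
                                   seed_after = params$seed) {
  stopifnot(sahp_scale >= 0, sahp_scale <= 1, mahp_scale >= 0, mahp_scale <= 1)
  before <- generate_trace(protocol, params)
  p2 <- params
  p2$v_slow_true <- params$v_slow_true * sahp_scale
  p2$v_med_true <- params$v_med_true * mahp_scale
  p2$seed <- seed_after
  after <- generate_trace(protocol, p2)
  list(before = before, after = after)
}

#' Generative parameters for a two-group cohort
#'
#' Defines the group-level generative model for the slow-AHP amplitude used
#' by [generate_cohort()]: for cell i in group g at current step I (pA),
#'
#'   |v_slow|(i, I) = a0 + u_i + (b_g + b_i) (I - 300) + e_{iI}
#'
#' with `b_g = sahp_base_slope` for vehicle cells and
#' `sahp_base_slope + sahp_interaction_slope` for treated cells,
#' `u_i ~ N(0, random_intercept_sd^2)`, `b_i ~ N(0, random_slope_sd^2)` and
#' `e ~ N(0, residual_sd^2)`. The treatment thus acts as an extra per-pA
#' growth of the slow AHP (the generative analogue of a treatment-by-current
#' interaction). The medium AHP grows with current identically in both
#' groups. Observations go missing completely at random with probability
#' `missing_frac`, and a fraction `outlier_frac` is displaced by
#' `outlier_scale * residual_sd` (random sign).
#'
#' Default cohort sizes (20 vehicle / 15 treated) and amplitude scales are
#' patterned on published whole-cell cohorts of this design.
#'
#' @param n_vehicle,n_treated cells per group.
#' @param sahp_ref_amp baseline |v_slow| at the 300-pA reference step, mV.
#' @param sahp_base_slope common |v_slow| growth, mV per pA.
#' @param sahp_interaction_slope extra growth in the treated group, mV/pA.
#' @param mahp_ref_amp,mahp_slope medium-AHP magnitude at 300 pA and growth.
#' @param random_intercept_sd,random_slope_sd,residual_sd sds of the cell
#'   intercept (mV), cell slope (mV/pA) and observation noise (mV).
#' @param missing_frac MCAR missingness proportion in \[0, 0.5\].
#' @param outlier_frac,outlier_scale outlier proportion and displacement in
#'   multiples of `residual_sd`.
#' @param seed integer seed.
#' @return object of class `cohort_gen_params`.
#' @export
cohort_gen_params <- function(n_vehicle = 20, n_treated = 15,
                              sahp_ref_amp = 1.0,
                              sahp_base_slope = 0.004,
                              sahp_interaction_slope = 0.0014,
                              mahp_ref_amp = 3.5, mahp_slope = 0.004,
                              random_intercept_sd = 0.3,
                              random_slope_sd = 0.001,
                              residual_sd = 0.25,
                              missing_frac = 0.03,
                              outlier_frac = 0, outlier_scale = 6,
                              seed = NULL) {
  p <- list(n_vehicle = n_vehicle, n_treated = n_treated,
            sahp_ref_amp = sahp_ref_amp, sahp_base_slope = sahp_base_slope,
            sahp_interaction_slope = sahp_interaction_slope,
            mahp_ref_amp = mahp_ref_amp, mahp_slope = mahp_slope,
            random_intercept_sd = random_intercept_sd,
            random_slope_sd = random_slope_sd, residual_sd = residual_sd,
            missing_frac = missing_frac, outlier_frac = outlier_frac,
            outlier_scale = outlier_scale, seed = seed)
  class(p) <- "cohort_gen_params"
  validate_cohort_params(p)
  p
}

validate_cohort_params <- function(p) {
  stopifnot(inherits(p, "cohort_gen_params"))
  if (p$random_intercept_sd < 0 || p$random_slope_sd < 0 || p$residual_sd < 0)
    stopf("all sds must be >= 0")
  if (p$missing_frac < 0 || p$missing_frac > 0.5)
    stopf("missing_frac must lie in [0, 0.5]")
  if (p$outlier_frac < 0 || p$missing_frac + p$outlier_frac >= 1)
    stopf("missing_frac + outlier_frac must be < 1")
  if (p$n_vehicle < 1 || p$n_treated < 1) stopf("need at least one cell per group")
  invisible(p)
}

#' Simulate the per-sweep ground-truth response table of a cohort
#'
#' Draws the generative slow- and medium-AHP amplitudes for every (cell,
#' step) pair of a two-group cohort without synthesizing any voltage traces.
#' This is the table-level arm of the generator: [generate_cohort()] uses
#' exactly these values as per-sweep ground truth when it does synthesize
#' traces, and the statistical calibration and power machinery simulate from
#' it directly.
#'
#' @param cohort a [cohort_gen_params()].
#' @param steps current steps to include (default the 13-value grid).
#' @return data.frame with columns `cell_id`, `group`, `step`, `v_slow`,
#'   `v_med` (signed, mV), `missing`, `outlier`, plus per-cell truth columns
#'   `u_cell` and `b_cell`.
#' @export
simulate_response_table <- function(cohort, steps = step_grid()) {
  validate_cohort_params(cohort)
  with_seed(cohort$seed, {
    n_cells <- cohort$n_vehicle + cohort$n_treated
    groups <- rep(c("vehicle", "treated"), c(cohort$n_vehicle, cohort$n_treated))
    cell_ids <- sprintf("%s_%02d", ifelse(groups == "vehicle", "veh", "trt"),
                        unlist(lapply(c(cohort$n_vehicle, cohort$n_treated), seq_len)))
    u <- rnorm(n_cells, 0, cohort$random_intercept_sd)
    b <- rnorm(n_cells, 0, cohort$random_slope_sd)
    rows <- vector("list", n_cells)
    for (i in seq_len(n_cells)) {
      slope <- cohort$sahp_base_slope + b[i] +
        if (groups[i] == "treated") cohort$sahp_interaction_slope else 0
      x <- steps - 300
      e <- rnorm(length(steps), 0, cohort$residual_sd)
      # magnitudes are left unclipped here so the table follows the linear
      # mixed model exactly; trace synthesis clips at 0 (an AHP cannot be
      # depolarizing) when it consumes these values
      sahp_mag <- cohort$sahp_ref_amp + u[i] + slope * x + e
      e2 <- rnorm(length(steps), 0, cohort$residual_sd)
      mahp_mag <- cohort$mahp_ref_amp + cohort$mahp_slope * x + e2
      rows[[i]] <- data.frame(
        cell_id = cell_ids[i], group = groups[i], step = steps,
        v_slow = -sahp_mag, v_med = -mahp_mag,
        missing = FALSE, outlier = FALSE,
        u_cell = u[i], b_cell = b[i], stringsAsFactors = FALSE)
    }
    tab <- do.call(rbind, rows)
    n_obs <- nrow(tab)
    if (cohort$outlier_frac > 0) {
      out <- runif(n_obs) < cohort$outlier_frac
      shift <- cohort$outlier_scale * cohort$residual_sd *
        sample(c(-1, 1), n_obs, replace = TRUE)
      tab$v_slow[out] <- tab$v_slow[out] + shift[out]
      tab$outlier <- out
    }
    if (cohort$missing_frac > 0)
      tab$missing <- runif(n_obs) < cohort$missing_frac
    tab
  })
}

#' Generate a full synthetic two-group cohort of sweep families
#'
#' For every cell, draws the per-sweep ground-truth AHP amplitudes from the
#' cohort model ([simulate_response_table()]) and synthesizes one sweep per
#' current step with those amplitudes ([generate_trace()]). Missing
#' observations are realized as absent sweeps.
#'
#' @param cohort a [cohort_gen_params()].
#' @param trace_params_base a [trace_gen_params()] supplying everything the
#'   cohort model does not vary (passive properties, spike shape, noise).
#' @param protocol_args named list of overrides passed to
#'   [protocol_family()] (e.g. a reduced `sampling_rate` for large runs).
#' @param steps current steps to simulate (default all 13).
#' @param traces if `FALSE`, return only the ground-truth table (fast path
#'   used by the statistical simulations).
#' @return list with `truth` (the response table), `cells` (per cell: list of
#'   [voltage_trace()] keyed by step; `NULL` when `traces = FALSE`) and
#'   `params`.
#' @export
generate_cohort <- function(cohort,
                            trace_params_base = trace_gen_params(),
                            protocol_args = list(),
                            steps = step_grid(),
                            traces = TRUE) {
  truth <- simulate_response_table(cohort, steps = steps)
  cells <- NULL
  if (traces) {
    protos <- do.call(protocol_family, c(list(steps = steps), protocol_args))
    ids <- unique(truth$cell_id)
    cells <- vector("list", length(ids))
    names(cells) <- ids
    for (ci in seq_along(ids)) {
      rows <- truth[truth$cell_id == ids[ci], ]
      grp <- rows$group[1]
      sweeps <- list()
      for (k in seq_len(nrow(rows))) {
        if (rows$missing[k]) next
        p <- trace_params_base
        p$v_slow_true <- min(0, rows$v_slow[k])
        p$v_med_true <- min(0, rows$v_med[k])
        p$seed <- seed_child(cohort$seed %||% trace_params_base$seed,
                             ci * 1000 + k)
        tr <- generate_trace(protos[[as.character(rows$step[k])]], p)
        tr$cell_id <- ids[ci]
        tr$group_label <- grp
        sweeps[[as.character(rows$step[k])]] <- tr
      }
      cells[[ci]] <- list(cell_id = ids[ci], group_label = grp, sweeps = sweeps)
    }
  }
  list(truth = truth, cells = cells, params = cohort)
}
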