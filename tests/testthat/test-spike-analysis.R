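# Smoothing, spike detection, waveform features, train statistics.

# bare trace builder: arbitrary voltage vector on a protocol grid
bare_trace <- function(v, fs = 50000, proto = current_protocol(300, record_dur = 1300, sampling_rate = fs)) {
  n <- round((proto$record_dur + proto$zero_current_dur) / 1000 * fs)
  stopifnot(length(v) == n)
  voltage_trace(time = (seq_len(n) - 1) / fs, voltage = v, protocol = proto)
}

test_that("local-linear smoothing passes constants and ramps unchanged", {
  fs <- 10000
  proto <- current_protocol(300, record_dur = 1300, sampling_rate = fs)
  n <- round(1.5 * fs)
  const <- voltage_trace((seq_len(n) - 1) / fs, rep(-70, n), proto)
  expect_equal(smooth_trace(const)$voltage, rep(-70, n))
  ramp <- voltage_trace((seq_len(n) - 1) / fs, seq(-70, -60, length.out = n), proto)
  sm <- smooth_trace(ramp)
  core <- 100:(n - 100)
  expect_equal(sm$voltage[core], ramp$voltage[core], tolerance = 1e-10)
})

test_that("smoothed white noise has the variance of a per-window OLS midpoint", {
  fs <- 10000
  n_w <- 11 # 1 ms at 10 kHz, forced odd
  set.seed(8)
  n <- round(1.5 * fs)
  v <- rnorm(n)
  proto <- current_protocol(300, record_dur = 1300, sampling_rate = fs)
  sm <- smooth_trace(voltage_trace((seq_len(n) - 1) / fs, v, proto))$voltage
  # brute-force OLS per window at a handful of positions
  idx <- seq(2000, 12000, by = 500)
  for (i in idx) {
    w <- (i - 5):(i + 5)
    fit <- lm(v[w] ~ w)
    expect_equal(sm[i], unname(predict(fit)[6]), tolerance = 1e-8)
  }
  # variance of the midpoint of an OLS line over w iid points is sigma^2/w
  core <- sm[1000:(n - 1000)]
  expect_equal(var(core), 1 / n_w, tolerance = 0.1)
})

test_that("flat traces yield no spikes and tall templates are all found", {
  fs <- 20000
  proto <- current_protocol(300, record_dur = 1300, sampling_rate = fs)
  n <- round(1.5 * fs)
  flat <- voltage_trace((seq_len(n) - 1) / fs, rep(-70, n), proto)
  expect_identical(detect_spikes(flat), numeric(0))
  # 3 spikes of +50 mV and 1 of +30 mV above baseline inside the step window
  t_ms <- (seq_len(n) - 1) / fs * 1000
  v <- rep(-70, n)
  put <- function(at, height) {
    jdx <- which(t_ms >= at & t_ms < at + 10)
    v[jdx] <<- v[jdx] + height * sahpkit:::spike_template(t_ms[jdx] - at, 0.15, 1.0)
  }
  for (at in c(550, 700, 850)) put(at, 50)
  put(1000, 30)
  tr <- voltage_trace((seq_len(n) - 1) / fs, v, proto)
  pk <- detect_spikes(tr, baseline = -70)
  expect_length(pk, 3)
  delay <- sahpkit:::spike_template_peak_delay(0.15, 1.0)
  expect_equal(pk, c(550, 700, 850) + delay, tolerance = 1000 / fs)
})

test_that("every generated spike is detected with no spurious extras", {
  # exhaustive over the step family at moderate noise
  p <- trace_gen_params(noise_sd = 0.3, seed = 41)
  for (s in step_grid()[c(1, 4, 7, 10, 13)]) {
    tr <- generate_trace(short_protocol(s, 20000), p)
    sf <- sweep_spike_features(tr)
    expect_identical(sf$train$n_spikes, tr$ground_truth$n_spikes)
  }
})

test_that("threshold lands on an exact piecewise-linear slope breakpoint", {
  fs <- 50000
  proto <- current_protocol(300, record_dur = 1300, sampling_rate = fs)
  n <- round(1.5 * fs)
  t_ms <- (seq_len(n) - 1) / fs * 1000
  v <- rep(-70, n)
  # 10 mV/ms pre-ramp from 600 ms, then 25 mV/ms from exactly 610 ms
  ramp1 <- t_ms >= 600 & t_ms < 610
  v[ramp1] <- -70 + 10 * (t_ms[ramp1] - 600)
  ramp2 <- t_ms >= 610 & t_ms < 612
  v[ramp2] <- -70 + 100 + 25 * (t_ms[ramp2] - 610)
  after <- t_ms >= 612
  v[after] <- v[which(ramp2)[sum(ramp2)]]
  tr <- voltage_trace((seq_len(n) - 1) / fs, v, proto)
  th <- spike_threshold(tr, spike_time = 612, lookback = 15)
  expect_equal(th$threshold_t, 610, tolerance = 1.5 * 1000 / fs)
  expect_equal(th$threshold_v, 30, tolerance = 0.1)
})

test_that("idealized triangular spike has closed-form waveform features", {
  fs <- 50000
  proto <- current_protocol(300, record_dur = 1300, sampling_rate = fs)
  n <- round(1.5 * fs)
  t_ms <- (seq_len(n) - 1) / fs * 1000
  v <- numeric(n) # threshold level 0
  rise <- t_ms >= 600 & t_ms < 601
  v[rise] <- 100 * (t_ms[rise] - 600)
  fall <- t_ms >= 601 & t_ms < 603
  v[fall] <- 100 * (1 - (t_ms[fall] - 601) / 2)
  tr <- voltage_trace((seq_len(n) - 1) / fs, v, proto)
  f <- spike_waveform_features(tr, spike_time = 601)
  dt_us <- 1e6 / fs
  expect_equal(f$rise_time_20_80, 600, tolerance = dt_us)
  expect_equal(f$rising_slope, 100, tolerance = 1)
  expect_equal(f$half_width, 1.5, tolerance = 2 / fs * 1000)
  expect_equal(f$amplitude, 100, tolerance = 0.5)
})

test_that("template spike features match the brute-force sample-scan oracle", {
  p <- trace_gen_params(noise_sd = 0.1, seed = 17)
  tr <- generate_trace(short_protocol(350, 50000), p)
  sm <- smooth_trace(tr)
  pks <- detect_spikes(sm)
  expect_gt(length(pks), 2)
  dt_ms <- 1000 / 50000
  for (k in seq_along(pks)) {
    f <- spike_waveform_features(sm, pks[k])
    o <- spike_scan_oracle(sm, pks[k])
    expect_equal(f$threshold_t, o$threshold_t, tolerance = dt_ms)
    expect_equal(f$threshold_v, o$threshold_v, tolerance = 0.5)
    expect_equal(f$rise_time_20_80, o$rise_time_20_80, tolerance = dt_ms * 1000)
    expect_equal(f$half_width, o$half_width, tolerance = dt_ms)
  }
})

test_that("generated threshold parameter is recovered within 1 mV", {
  for (s in c(200, 300, 450)) {
    tr <- generate_trace(short_protocol(s, 50000),
                         trace_gen_params(noise_sd = 0, seed = 1))
    sf <- sweep_spike_features(tr)
    ths <- vapply(sf$spikes[-1], `[[`, numeric(1), "threshold_v")
    expect_lt(max(abs(ths + 50)), 1)
  }
})

test_that("feature extraction shifts with a constant offset only where it must", {
  p <- trace_gen_params(noise_sd = 0.1, seed = 23)
  tr <- generate_trace(short_protocol(300, 20000), p)
  tr2 <- tr
  tr2$voltage <- tr$voltage + 7
  sm <- smooth_trace(tr); sm2 <- smooth_trace(tr2)
  pk <- detect_spikes(sm); pk2 <- detect_spikes(sm2)
  expect_equal(pk, pk2)
  f <- spike_waveform_features(sm, pk[1])
  f2 <- spike_waveform_features(sm2, pk2[1])
  expect_equal(f2$v_peak, f$v_peak + 7)
  expect_equal(f2$threshold_v, f$threshold_v + 7)
  expect_equal(f2$amplitude, f$amplitude)
  expect_equal(f2$half_width, f$half_width)
  expect_equal(f2$rise_time_20_80, f$rise_time_20_80)
  expect_equal(f2$rising_slope, f$rising_slope)
})

test_that("train statistics follow the interval arithmetic", {
  s <- train_stats(c(0, 10, 20, 30))
  expect_equal(s$isis, c(10, 10, 10))
  expect_equal(s$accommodation_pct, 100)
  s2 <- train_stats(c(0, 10, 25, 45))
  expect_equal(s2$first_isi, 10)
  expect_equal(s2$last_isi, 20)
  expect_equal(s2$accommodation_pct, 200)
  expect_true(is.na(train_stats(c(0, 10))$accommodation_pct)) # 2 spikes
  expect_identical(train_stats(numeric(0))$n_spikes, 0L)
})

test_that("measured accommodation recovers the generative ratio within 5%", {
  p <- trace_gen_params(noise_sd = 0.1, isi_adaptation = 2, seed = 31)
  for (s in c(275, 350, 450)) { # n_spikes >= 6
    sf <- sweep_spike_features(generate_trace(short_protocol(s, 20000), p))
    expect_gte(sf$train$n_spikes, 4)
    expect_lt(abs(sf$train$accommodation_pct / 200 - 1), 0.05)
  }
})

test_that("first-spike cell averages are feature-wise means across steps", {
  tab <- data.frame(rise_time_20_80 = c(150, 170), half_width = c(1.2, 1.4),
                    amplitude = c(60, 62))
  avg <- first_spike_cell_average(tab)
  expect_equal(avg$rise_time_20_80, 160)
  expect_equal(avg$half_width, 1.3)
  # no spikes anywhere -> all-missing record
  empty <- first_spike_cell_average(list())
  expect_true(all(is.na(unlist(empty))))
})
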