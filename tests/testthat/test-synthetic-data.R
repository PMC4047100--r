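# Synthetic-trace and cohort generator.

test_that("quiet sweep equals the analytic passive forward model exactly", {
  proto <- tail_protocol(300, sampling_rate = 5000)
  p <- quiet_params()
  tr <- generate_trace(proto, p)
  expect_equal(max(abs(tr$voltage - analytic_quiet_sweep(proto, p))), 0)
})

test_that("post-step tail matches the closed-form two-exponential sum", {
  proto <- tail_protocol(300, sampling_rate = 5000)
  p <- trace_gen_params(noise_sd = 0, spike_gain = 0,
                        v_med_true = -3.5, tau_med_true = 150,
                        v_slow_true = -1.4, tau_slow_true = 6000)
  tr <- generate_trace(proto, p)
  offset <- proto$depol_onset + proto$depol_step_dur
  at <- function(t_ms) tr$voltage[which.min(abs(tr$time * 1000 - (offset + t_ms)))]
  for (t_ms in c(400, 1000, 3000)) {
    expected <- p$rmp - 3.5 * exp(-t_ms / 150) - 1.4 * exp(-t_ms / 6000)
    expect_equal(at(t_ms), expected, tolerance = 1e-6)
  }
})

test_that("default sweeps sit near -70 mV and the family spans 150-450 pA", {
  protos <- protocol_family(sampling_rate = 2000)
  expect_equal(as.numeric(names(protos)), seq(150, 450, by = 25))
  tr <- generate_trace(protos[["150"]], trace_gen_params(seed = 3))
  bl <- sahpkit:::baseline_mean(tr, 100)
  expect_lt(abs(bl + 70), 3 * 0.2 / sqrt(100 * 2)) # CLT bound on the segment mean
})

test_that("trace generation is bit-deterministic under a seed", {
  proto <- short_protocol(250, sampling_rate = 10000)
  p <- trace_gen_params(seed = 99)
  expect_identical(generate_trace(proto, p)$voltage,
                   generate_trace(proto, p)$voltage)
})

test_that("trace minus ground-truth components equals the noise draw", {
  proto <- tail_protocol(300, sampling_rate = 5000)
  p <- trace_gen_params(seed = 5)
  tr <- generate_trace(proto, p)
  gt <- tr$ground_truth
  resid <- tr$voltage - (gt$components$passive_and_envelope +
                           gt$components$spikes + gt$components$ahp)
  p0 <- p; p0$noise_sd <- 0
  noise <- tr$voltage - generate_trace(proto, p0)$voltage
  expect_equal(resid, noise, tolerance = 1e-12)
  expect_equal(sd(resid), 0.2, tolerance = 0.05)
})

test_that("generated spike count is non-decreasing in step amplitude", {
  p <- trace_gen_params(seed = 1)
  counts <- vapply(step_grid(), function(s) {
    generate_trace(short_protocol(s, 2000), p)$ground_truth$n_spikes
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
  expect_gt(counts[13], counts[1])
})

test_that("overfull spike trains raise a parameter error", {
  expect_error(generate_trace(short_protocol(450, 10000),
                              trace_gen_params(spike_gain = 0.4)),
               "exceeds the depolarizing window")
})

test_that("ablation pair with unit scales and shared seed is identical", {
  proto <- tail_protocol(400, 2000)
  p <- trace_gen_params(seed = 12)
  pair <- generate_ablation_pair(proto, p, sahp_scale = 1, mahp_scale = 1)
  expect_identical(pair$before$voltage, pair$after$voltage)
})

test_that("full ablation leaves a fitted slow amplitude near zero", {
  proto <- tail_protocol(350, 5000)
  p <- trace_gen_params(noise_sd = 0.1, seed = 21)
  pair <- generate_ablation_pair(proto, p, sahp_scale = 0, seed_after = 22)
  f <- fit_ahp(pair$after)
  expect_lt(abs(f$v_slow), 3 * 0.1) # indistinguishable from 0 at this noise
})

test_that("null cohort has identical generative group means at every step", {
  cp <- cohort_gen_params(n_vehicle = 5, n_treated = 5,
                          sahp_interaction_slope = 0,
                          random_intercept_sd = 0, random_slope_sd = 0,
                          residual_sd = 0, missing_frac = 0, seed = 1)
  tab <- simulate_response_table(cp)
  m <- tapply(tab$v_slow, list(tab$group, tab$step), mean)
  expect_equal(unname(m["vehicle", ]), unname(m["treated", ]))
})

test_that("MCAR deletion count is binomially plausible and bookkept", {
  n_tot <- 13 * 35 * 20
  miss <- sum(vapply(1:20, function(s) {
    sum(simulate_response_table(cohort_gen_params(missing_frac = 0.03,
                                                  seed = s))$missing)
  }, numeric(1)))
  expect_lt(abs(miss - 0.03 * n_tot), 4 * sqrt(n_tot * 0.03 * 0.97))
})

test_that("generative slow-AHP magnitude grows with current under a positive slope", {
  cp <- cohort_gen_params(n_vehicle = 6, n_treated = 6, residual_sd = 0,
                          random_slope_sd = 0, missing_frac = 0, seed = 4)
  tab <- simulate_response_table(cp)
  for (g in c("vehicle", "treated")) {
    m <- tapply(-tab$v_slow[tab$group == g], tab$step[tab$group == g], mean)
    expect_true(all(diff(m) >= 0))
  }
})

test_that("cohorts with traces honor the per-sweep ground-truth amplitudes", {
  cp <- cohort_gen_params(n_vehicle = 2, n_treated = 2, missing_frac = 0.1,
                          seed = 8)
  co <- generate_cohort(cp, trace_gen_params(noise_sd = 0),
                        protocol_args = list(sampling_rate = 2000),
                        steps = c(150, 300, 450))
  expect_identical(names(co$cells), unique(co$truth$cell_id))
  for (cid in names(co$cells)) {
    rows <- co$truth[co$truth$cell_id == cid, ]
    expect_setequal(names(co$cells[[cid]]$sweeps),
                    as.character(rows$step[!rows$missing]))
    for (k in which(!rows$missing)) {
      tr <- co$cells[[cid]]$sweeps[[as.character(rows$step[k])]]
      expect_equal(tr$ground_truth$params$v_slow_true, min(0, rows$v_slow[k]))
    }
  }
})
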