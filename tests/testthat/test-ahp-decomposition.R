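# Bi-exponential AHP decomposition.

test_that("AHP peak follows the closed-form tail value and trivial cases", {
  proto <- tail_protocol(300, 5000)
  # trace returning exactly to baseline -> no AHP
  tr0 <- generate_trace(proto, quiet_params())
  pk0 <- ahp_peak(smooth_trace(tr0))
  expect_equal(pk0$peak_amp, 0)
  f0 <- fit_ahp(tr0)
  expect_identical(f0$converged, "no_ahp")
  expect_equal(f0$v_med, 0)
  # two-exponential tail: peak equals the closed form at the detected time
  p <- quiet_params(v_med_true = -3.5, tau_med_true = 150,
                    v_slow_true = -1.4, tau_slow_true = 6000)
  tr <- generate_trace(proto, p)
  pk <- ahp_peak(smooth_trace(tr))
  offset <- proto$depol_onset + proto$depol_step_dur
  t_rel <- pk$t_peak - offset
  expect_lt(t_rel, 10) # found right after the step
  expected <- -3.5 * exp(-t_rel / 150) - 1.4 * exp(-t_rel / 6000)
  expect_equal(pk$peak_amp, expected, tolerance = 0.02)
  # single-component tail: peak is the medium amplitude alone
  pm <- quiet_params(v_med_true = -3.5, tau_med_true = 150)
  pkm <- ahp_peak(smooth_trace(generate_trace(proto, pm)))
  expect_equal(pkm$peak_amp, -3.5 * exp(-(pkm$t_peak - offset) / 150),
               tolerance = 0.02)
})

test_that("a noiseless single slow exponential is recovered degenerately", {
  p <- quiet_params(v_med_true = 0, v_slow_true = -2, tau_slow_true = 2000)
  f <- fit_ahp(generate_trace(tail_protocol(300, 5000), p))
  expect_equal(f$tau_slow, 2000, tolerance = 1 / 2000)
  t_rel <- f$t_fit_start - 1100
  expect_equal(f$v_slow, -2 * exp(-t_rel / 2000), tolerance = 1e-3)
  expect_lt(abs(f$v_med), 0.01)
})

test_that("noiseless two-component tails match the dense grid oracle within 1%", {
  cases <- expand.grid(v_med = c(-3.5, -1), tau_med = c(80, 250),
                       v_slow = c(-1.4, -0.6), tau_slow = c(1500, 6000))
  proto <- tail_protocol(300, 5000)
  for (i in seq_len(nrow(cases))) {
    cs <- cases[i, ]
    p <- quiet_params(v_med_true = cs$v_med, tau_med_true = cs$tau_med,
                      v_slow_true = cs$v_slow, tau_slow_true = cs$tau_slow)
    tr <- generate_trace(proto, p)
    f <- fit_ahp(tr)
    w <- ahp_fit_window(tr)
    o <- ahp_grid_oracle(w$t_ms, w$y)
    expect_lt(abs(f$v_med / o$v_med - 1), 0.01)
    expect_lt(abs(f$tau_med / o$tau_med - 1), 0.01)
    expect_lt(abs(f$v_slow / o$v_slow - 1), 0.01)
    expect_lt(abs(f$tau_slow / o$tau_slow - 1), 0.01)
  }
})

test_that("decay-constant bounds are always respected under noise", {
  proto <- tail_protocol(300, 5000)
  for (s in 1:10) {
    f <- fit_ahp(generate_trace(proto, trace_gen_params(noise_sd = 0.2, seed = s)))
    expect_gt(f$tau_med, 0); expect_lte(f$tau_med, 400)
    expect_gt(f$tau_slow, 400); expect_lte(f$tau_slow, 8000)
  }
})

test_that("goodness of fit is 1 for noiseless data and favors the true model", {
  proto <- tail_protocol(300, 5000)
  p <- quiet_params(v_med_true = -3.5, tau_med_true = 100,
                    v_slow_true = -2.5, tau_slow_true = 5000)
  tr <- generate_trace(proto, p)
  f <- fit_ahp(tr)
  expect_equal(f$r2, 1, tolerance = 1e-6)
  expect_equal(fit_quality(f, tr), f$r2, tolerance = 1e-9)
  # a forced single exponential on well-separated two-component data fits
  # strictly worse
  w <- ahp_fit_window(tr)
  single_sse <- function(tau) {
    X <- exp(-w$t_ms / tau)
    b <- sum(X * w$y) / sum(X * X)
    pred <- b * X
    cor(w$y, pred)^2
  }
  best_single_r2 <- max(vapply(exp(seq(log(50), log(8000), length.out = 200)),
                               single_sse, numeric(1)))
  expect_gt(f$r2, best_single_r2)
})

test_that("fitted amplitudes are linear in the generative amplitudes", {
  proto <- tail_protocol(300, 5000)
  base <- quiet_params(v_med_true = -2, tau_med_true = 120,
                       v_slow_true = -1, tau_slow_true = 4000)
  f1 <- fit_ahp(generate_trace(proto, base))
  scaled <- quiet_params(v_med_true = -2 * 1.8, tau_med_true = 120,
                         v_slow_true = -1 * 1.8, tau_slow_true = 4000)
  f2 <- fit_ahp(generate_trace(proto, scaled))
  expect_equal(f2$v_med / f1$v_med, 1.8, tolerance = 0.01)
  expect_equal(f2$v_slow / f1$v_slow, 1.8, tolerance = 0.01)
  expect_equal(f2$tau_med, f1$tau_med, tolerance = 0.01)
  expect_equal(f2$tau_slow, f1$tau_slow, tolerance = 0.01)
})

test_that("components are labeled by bound interval, not amplitude order", {
  # slow component much larger than medium: labels must still follow tau
  p <- quiet_params(v_med_true = -0.6, tau_med_true = 100,
                    v_slow_true = -4, tau_slow_true = 5000)
  f <- fit_ahp(generate_trace(tail_protocol(300, 5000), p))
  expect_lt(f$tau_med, 400)
  expect_gt(f$tau_slow, 400)
  expect_equal(f$v_med, -0.6 * exp(-(f$t_fit_start - 1100) / 100),
               tolerance = 0.05)
})

test_that("near-degenerate decay constants trip the identifiability flag", {
  proto <- tail_protocol(300, 5000)
  flags <- vapply(1:8, function(s) {
    p <- trace_gen_params(tau_med_true = 350, tau_slow_true = 450,
                          v_med_true = -2.5, v_slow_true = -2,
                          noise_sd = 0.2, seed = s)
    fit_ahp(generate_trace(proto, p))$converged
  }, character(1))
  expect_gte(mean(flags %in% c("at_bound", "ill_conditioned")), 0.5)
})

test_that("ablation contrast is null for identical fits and exact for scales", {
  fits <- lapply(setNames(seq(325, 450, 25), seq(325, 450, 25)), function(s)
    structure(list(v_med = -3.5, v_slow = -1.4), class = "ahp_fit"))
  ident <- ablation_contrast(fits, fits)
  expect_equal(ident$mahp_change_pct, 0)
  expect_equal(ident$sahp_change_pct, 0)
  scaled <- lapply(fits, function(f) { f$v_slow <- f$v_slow * 0.3; f })
  expect_equal(ablation_contrast(fits, scaled)$sahp_change_pct, -70)
  expect_error(ablation_contrast(fits["325"], fits["325"],
                                 step_range = c(440, 450)), "no fits")
})

test_that("per-cell AHP tables repeat the per-sweep fits without drift", {
  cp <- cohort_gen_params(n_vehicle = 2, n_treated = 1, missing_frac = 0, seed = 3)
  co <- generate_cohort(cp, trace_gen_params(noise_sd = 0.1),
                        protocol_args = list(sampling_rate = 2000),
                        steps = c(150, 250, 350, 450))
  cell <- co$cells[[1]]
  tab <- ahp_by_step(cell)
  expect_identical(nrow(tab), 4L)
  expect_identical(tab$step, c(150, 250, 350, 450))
  f300 <- fit_ahp(cell$sweeps[["350"]])
  expect_identical(tab$v_slow[tab$step == 350], f300$v_slow)
  expect_identical(tab$tau_slow[tab$step == 350], f300$tau_slow)
})

test_that("fitted slow amplitude tracks a monotone generative trend", {
  cp <- cohort_gen_params(n_vehicle = 2, n_treated = 1, missing_frac = 0,
                          residual_sd = 0.05, random_slope_sd = 0, seed = 6)
  co <- generate_cohort(cp, trace_gen_params(noise_sd = 0.05),
                        protocol_args = list(sampling_rate = 2000),
                        steps = c(150, 250, 350, 450))
  tab <- ahp_by_step(co$cells[[1]])
  truth <- co$truth[co$truth$cell_id == tab$cell_id[1], ]
  # fitted magnitudes correlate strongly with the generative ones
  expect_gt(cor(-tab$v_slow, -truth$v_slow), 0.95)
})
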