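# Long-table assembly, mixed models, influence, imputation, pooling,
# correlation.

sim_table <- function(..., seed = 1) {
  cp <- cohort_gen_params(..., seed = seed)
  tr <- simulate_response_table(cp)
  build_long_table(data.frame(cell_id = tr$cell_id, group = tr$group,
                              step = tr$step,
                              v_slow = ifelse(tr$missing, NA, tr$v_slow)),
                   "v_slow")
}

test_that("long tables have one flagged row per (cell, step)", {
  tab <- sim_table(n_vehicle = 2, n_treated = 2, missing_frac = 0)
  expect_identical(nrow(tab), 4L * 13L)
  expect_false(any(tab$missing))
  # a corrupted step stays as a flagged row, not a dropped one
  feats <- data.frame(cell_id = rep(c("a", "b"), each = 13),
                      group = rep(c("vehicle", "treated"), each = 13),
                      step = rep(step_grid(), 2),
                      v_slow = -runif(26))
  feats$v_slow[5] <- NA
  tab2 <- build_long_table(feats, "v_slow")
  expect_identical(nrow(tab2), 26L)
  expect_identical(sum(tab2$missing), 1L)
  # duplicates are rejected
  expect_error(build_long_table(rbind(feats, feats[1, ]), "v_slow"),
               "duplicate")
})

test_that("missing-row bookkeeping matches the generator's deletions", {
  cp <- cohort_gen_params(missing_frac = 0.1, seed = 3)
  tr <- simulate_response_table(cp)
  tab <- build_long_table(data.frame(cell_id = tr$cell_id, group = tr$group,
                                     step = tr$step,
                                     v_slow = ifelse(tr$missing, NA, tr$v_slow)),
                          "v_slow")
  expect_identical(sum(tab$missing), sum(tr$missing))
})

test_that("with zero random variation the LME equals ordinary least squares", {
  tab <- sim_table(random_intercept_sd = 0, random_slope_sd = 0,
                   missing_frac = 0, seed = 2)
  f <- fit_lme(tab)
  d <- as.data.frame(tab)
  d$step_c <- (d$step - 300) / 100
  d$group <- factor(d$group, c("vehicle", "treated"))
  ols <- lm(response ~ group * step_c, data = d)
  expect_equal(f$fixed$estimate, unname(coef(ols)), tolerance = 1e-6)
})

test_that("the interaction test has one degree of freedom under continuous coding", {
  tab <- sim_table(n_vehicle = 5, n_treated = 5, missing_frac = 0)
  ti <- test_interaction(tab)
  expect_equal(ti$test$df, 1)
  expect_gte(ti$test$chi_square, 0)
  # factor coding gives the 12-df version
  full_f <- fit_lme(tab, "full", step_coding = "factor")
  red_f <- fit_lme(tab, "no_interaction", step_coding = "factor")
  expect_equal(lrt(full_f, red_f)$df, 12)
})

test_that("identical models give a guarded zero-df test with p = 1", {
  tab <- sim_table(n_vehicle = 3, n_treated = 3, missing_frac = 0)
  f <- fit_lme(tab)
  out <- lrt(f, f)
  expect_identical(out$chi_square, 0)
  expect_identical(out$p_value, 1)
  red <- fit_lme(tab, "no_interaction")
  expect_error(lrt(red, f), "not nested")
})

test_that("interaction estimates recover the generative slope", {
  est <- vapply(1:30, function(s) {
    tab <- sim_table(missing_frac = 0, seed = s)
    f <- fit_lme(tab)
    f$fixed$estimate_per_pa[f$fixed$term == "grouptreated:step_c"]
  }, numeric(1))
  # response is the signed (negative) amplitude: slope flips sign
  expect_lt(abs(mean(est) / (-0.0014) - 1), 0.15)
})

test_that("Cook's screen tracks the brute-force deletion oracle", {
  tab <- sim_table(n_vehicle = 2, n_treated = 2, missing_frac = 0, seed = 9)
  f <- fit_lme(tab)
  rep <- cooks_screen(tab, f)
  expect_identical(rep$n, 52L)
  expect_equal(rep$cutoff, 4 / 52)
  oracle <- cooks_deletion_oracle(tab)
  expect_gt(cor(rep$distances, oracle, method = "spearman"), 0.95)
})

test_that("a grossly displaced observation attains the maximum distance", {
  tab <- sim_table(n_vehicle = 3, n_treated = 3, missing_frac = 0, seed = 5)
  i <- 20
  tab$response[i] <- tab$response[i] + 20 * 0.25 # 20 residual sds
  rep <- cooks_screen(tab)
  expect_equal(which.max(rep$distances), i)
  expect_true(i %in% rep$flagged)
  # clean null data: flagged fraction stays small
  rep0 <- cooks_screen(sim_table(n_vehicle = 5, n_treated = 5,
                                 missing_frac = 0, seed = 7))
  expect_lt(length(rep0$flagged) / rep0$n, 0.12)
})

test_that("imputation is an identity without missing data and deterministic", {
  tab <- sim_table(n_vehicle = 3, n_treated = 3, missing_frac = 0)
  imps <- impute_cohort(tab, m = 3, seed = 1)
  expect_length(imps, 3)
  for (im in imps) expect_equal(im$response, tab$response)
  tabm <- sim_table(n_vehicle = 5, n_treated = 5, missing_frac = 0.1, seed = 11)
  a <- impute_cohort(tabm, m = 2, seed = 7)
  b <- impute_cohort(tabm, m = 2, seed = 7)
  expect_identical(a, b)
  c2 <- impute_cohort(tabm, m = 2, seed = 8)
  expect_false(identical(a, c2))
})

test_that("imputed values stay within the observed response range", {
  tabm <- sim_table(n_vehicle = 8, n_treated = 8, missing_frac = 0.15, seed = 13)
  obs <- tabm$response[!tabm$missing]
  imps <- impute_cohort(tabm, m = 5, seed = 2)
  for (im in imps) {
    filled <- im$response[im$imputed]
    expect_true(all(filled > min(obs) - 3 * sd(obs)))
    expect_true(all(filled < max(obs) + 3 * sd(obs)))
  }
})

test_that("cells with all steps missing are dropped with a warning", {
  tab <- sim_table(n_vehicle = 3, n_treated = 3, missing_frac = 0)
  tab$response[tab$cell_id == "veh_01"] <- NA
  tab$missing[tab$cell_id == "veh_01"] <- TRUE
  expect_warning(imps <- impute_cohort(tab, m = 2, seed = 1), "all steps missing")
  expect_false("veh_01" %in% imps[[1]]$cell_id)
})

test_that("pooling identical fits reproduces the single fit and inflates SEs", {
  tab <- sim_table(n_vehicle = 4, n_treated = 4, missing_frac = 0)
  f <- fit_lme(tab)
  pooled <- pool_estimates(list(f, f, f))
  expect_equal(pooled$estimate, f$fixed$estimate)
  expect_equal(pooled$se, f$fixed$se) # no between-imputation variance
  # with real imputations the pooled SE is at least the within-imputation SE
  tabm <- sim_table(n_vehicle = 6, n_treated = 6, missing_frac = 0.1, seed = 4)
  fits <- lapply(impute_cohort(tabm, m = 5, seed = 3), fit_lme)
  pooled2 <- pool_estimates(fits)
  expect_true(all(pooled2$se >= sqrt(pooled2$within) - 1e-12))
  # heterogeneous model specs are rejected
  expect_error(pool_estimates(list(f, fit_lme(tab, "no_interaction"))),
               "heterogeneous")
})

test_that("pooled LRT of identical statistics reduces to the single test", {
  tab <- sim_table(n_vehicle = 4, n_treated = 4, missing_frac = 0)
  ti <- test_interaction(tab)
  pooled <- pool_lrt(list(ti$test, ti$test, ti$test))
  expect_equal(pooled$chi_square, ti$test$chi_square)
  # no between-imputation variance: F reference equals the chi-square test
  expect_equal(pooled$p_value, ti$test$p_value, tolerance = 1e-6)
})

test_that("correlation is exact on a linear relation and null under permutation", {
  steps <- step_grid()
  feats <- data.frame(cell_id = "c", group = "vehicle", step = steps,
                      v_slow = -0.2 - 0.01 * (steps - 150),
                      n_spikes = 1 + 0.04 * (steps - 125))
  out <- correlate_sahp_spikes(feats)
  expect_equal(out$vehicle$r, -1, tolerance = 1e-12)
  expect_identical(out$vehicle$n_points, 13L)
  set.seed(3)
  rs <- replicate(50, {
    f2 <- feats
    f2$n_spikes <- sample(f2$n_spikes)
    correlate_sahp_spikes(f2)$vehicle$r
  })
  expect_lt(abs(mean(rs)), 0.15)
  expect_lt(mean(abs(rs) > 0.55), 0.1) # |r| large only rarely
  expect_error(correlate_sahp_spikes(feats[1:2, ]), "fewer than 3")
})

test_that("groups with stronger generative coupling show stronger correlation", {
  set.seed(12)
  reps <- replicate(20, {
    steps <- step_grid()
    mk <- function(gain_sd) {
      n <- 1 + 0.04 * (steps - 125) + rnorm(13, 0, 1)
      v <- -0.2 - 0.004 * (steps - 150) + rnorm(13, 0, gain_sd)
      list(n = n, v = v)
    }
    tight <- mk(0.1); loose <- mk(1.2)
    feats <- rbind(
      data.frame(cell_id = "t", group = "treated", step = steps,
                 v_slow = tight$v, n_spikes = tight$n),
      data.frame(cell_id = "v", group = "vehicle", step = steps,
                 v_slow = loose$v, n_spikes = loose$n))
    out <- correlate_sahp_spikes(feats)
    abs(out$treated$r) > abs(out$vehicle$r)
  })
  expect_gt(mean(reps), 0.8)
})
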