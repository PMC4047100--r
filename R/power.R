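# Simulation-based power analysis for the treatment-by-current interaction.

#' Effect specification for power simulation
#'
#' Bundles the generative quantities that determine the distribution of the
#' interaction likelihood-ratio statistic: the interaction slope (extra
#' slow-AHP growth per pA of current in the treated group), the random-effect
#' and residual standard deviations, and the baseline amplitude/slope the
#' simulated cohorts share. Either constructed from generator ground truth
#' ([effect_spec_from_params()]) or from a fitted model
#' ([effect_spec_from_lme()]), in which case the interaction slope may carry
#' its estimation uncertainty (`interaction_se`) for posterior-style
#' parameter draws during simulation.
#'
#' @param interaction_slope extra treated-group growth, mV/pA (magnitude).
#' @param ref_amp,base_slope shared amplitude at 300 pA (mV) and common
#'   growth (mV/pA).
#' @param random_intercept_sd,random_slope_sd,residual_sd as in
#'   [cohort_gen_params()].
#' @param interaction_se optional standard error of `interaction_slope`
#'   (mV/pA); when positive, each simulated cohort draws its true slope from
#'   `N(interaction_slope, interaction_se^2)`.
#' @return list of class `effect_spec`.
#' @export
effect_spec <- function(interaction_slope, ref_amp = 1.0, base_slope = 0.004,
                        random_intercept_sd = 0.3, random_slope_sd = 0.001,
                        residual_sd = 0.25, interaction_se = 0) {
  if (random_intercept_sd < 0 || random_slope_sd < 0 || residual_sd <= 0)
    stopf("effect_spec variances must be non-negative (residual_sd positive)")
  out <- list(interaction_slope = interaction_slope, ref_amp = ref_amp,
              base_slope = base_slope,
              random_intercept_sd = random_intercept_sd,
              random_slope_sd = random_slope_sd, residual_sd = residual_sd,
              interaction_se = interaction_se)
  class(out) <- "effect_spec"
  out
}

#' @rdname effect_spec
#' @param cohort a [cohort_gen_params()].
#' @export
effect_spec_from_params <- function(cohort) {
  effect_spec(interaction_slope = cohort$sahp_interaction_slope,
              ref_amp = cohort$sahp_ref_amp,
              base_slope = cohort$sahp_base_slope,
              random_intercept_sd = cohort$random_intercept_sd,
              random_slope_sd = cohort$random_slope_sd,
              residual_sd = cohort$residual_sd)
}

#' @rdname effect_spec
#' @param fit a full-model [fit_lme()] result on a slow-AHP table (signed
#'   responses; the magnitude model is recovered by sign flips).
#' @param uncertainty include the interaction slope's standard error so the
#'   simulation integrates over parameter uncertainty (default `TRUE`).
#' @export
effect_spec_from_lme <- function(fit, uncertainty = TRUE) {
  stopifnot(inherits(fit, "sahp_lme"))
  fx <- fit$fixed
  pick <- function(term) {
    i <- match(term, fx$term)
    if (is.na(i)) stopf("term '%s' absent from the fitted model", term)
    i
  }
  i_int <- pick("grouptreated:step_c")
  i_step <- pick("step_c")
  i_ref <- pick("(Intercept)")
  sds <- fit$ranef_sd
  get_sd <- function(name) {
    i <- grep(name, names(sds), fixed = TRUE)
    if (!length(i)) 0 else max(sds[i])
  }
  effect_spec(
    interaction_slope = abs(fx$estimate_per_pa[i_int]),
    ref_amp = abs(fx$estimate[i_ref]),
    base_slope = abs(fx$estimate_per_pa[i_step]),
    random_intercept_sd = get_sd("(Intercept):NA"),
    random_slope_sd = get_sd("step_c:NA") / 100,
    residual_sd = fit$sigma,
    interaction_se = if (uncertainty) fx$se[i_int] / 100 else 0)
}

# One simulated interaction LRT p-value on a prebuilt design, using
# lme4::refit for speed. `design` is the data.frame of the template fit.
sim_lrt_p <- function(full0, red0, design, spec, slope_draw) {
  cells <- unique(design[, c("cell_id", "group")])
  n_cells <- nrow(cells)
  u <- rnorm(n_cells, 0, spec$random_intercept_sd)
  b <- rnorm(n_cells, 0, spec$random_slope_sd)
  names(u) <- names(b) <- cells$cell_id
  slope <- spec$base_slope + b[design$cell_id] +
    ifelse(design$group == "treated", slope_draw, 0)
  mag <- spec$ref_amp + u[design$cell_id] + slope * (design$step - 300) +
    rnorm(nrow(design), 0, spec$residual_sd)
  y <- -mag
  f2 <- suppressWarnings(suppressMessages(lme4::refit(full0, y)))
  r2 <- suppressWarnings(suppressMessages(lme4::refit(red0, y)))
  chi <- max(0, 2 * (as.numeric(logLik(f2)) - as.numeric(logLik(r2))))
  pchisq(chi, 1, lower.tail = FALSE)
}

# Template design and fitted model pair for a given cohort size.
power_template <- function(n_vehicle, n_treated, spec) {
  cp <- cohort_gen_params(
    n_vehicle = n_vehicle, n_treated = n_treated,
    sahp_ref_amp = spec$ref_amp, sahp_base_slope = spec$base_slope,
    sahp_interaction_slope = spec$interaction_slope,
    random_intercept_sd = spec$random_intercept_sd,
    random_slope_sd = spec$random_slope_sd, residual_sd = spec$residual_sd,
    missing_frac = 0, seed = 1)
  truth <- simulate_response_table(cp)
  tab <- build_long_table(
    data.frame(cell_id = truth$cell_id, group = truth$group,
               step = truth$step, v_slow = truth$v_slow), "v_slow")
  full <- fit_lme(tab, "full")
  red <- fit_lme(tab, "no_interaction")
  design <- as.data.frame(tab[!tab$missing, c("cell_id", "group", "step")])
  list(full = full$model, red = red$model, design = design)
}

#' Monte-Carlo rejection rate of the interaction test at one design
#'
#' Simulates cohorts of fixed group sizes from an effect specification and
#' returns the fraction on which the interaction likelihood-ratio test
#' rejects at level `alpha`. With `interaction_slope = 0` this estimates the
#' type-I error. The design matrix and both models are constructed once and
#' refitted to each simulated response vector.
#'
#' @param spec an [effect_spec()].
#' @param n_vehicle,n_treated cells per group.
#' @param alpha test level.
#' @param n_sim number of simulated cohorts.
#' @param seed integer seed.
#' @return list with `rate`, `mc_se`, `n_sim`, `p_values`.
#' @export
interaction_rejection_rate <- function(spec, n_vehicle, n_treated,
                                       alpha = 0.05, n_sim = 500,
                                       seed = NULL) {
  tmpl <- power_template(n_vehicle, n_treated, spec)
  pv <- with_seed(seed, {
    vapply(seq_len(n_sim), function(s) {
      slope_draw <- if (spec$interaction_se > 0)
        rnorm(1, spec$interaction_slope, spec$interaction_se)
      else spec$interaction_slope
      sim_lrt_p(tmpl$full, tmpl$red, tmpl$design, spec, slope_draw)
    }, numeric(1))
  })
  rate <- mean(pv < alpha)
  list(rate = rate, mc_se = sqrt(rate * (1 - rate) / n_sim),
       n_sim = n_sim, p_values = pv)
}

#' Monte-Carlo power of the interaction test versus sample size
#'
#' For each total cell count on the grid, simulates cohorts from the effect
#' specification (cells split as evenly as possible between groups), runs
#' the full-versus-reduced interaction likelihood-ratio test on each, and
#' records the rejection fraction at level `alpha` with its Monte-Carlo
#' standard error. When the effect specification carries
#' `interaction_se > 0`, each simulated cohort draws its interaction slope
#' from the corresponding normal distribution, integrating over parameter
#' uncertainty the way posterior-simulation power analyses do.
#'
#' @param spec an [effect_spec()].
#' @param n_grid integer vector of total cell counts.
#' @param alpha test level (default 0.05).
#' @param n_sim simulated cohorts per grid point (default 1000).
#' @param seed integer seed.
#' @return data.frame of class `power_curve`: `n_total`, `n_vehicle`,
#'   `n_treated`, `power`, `mc_se`, plus `alpha`, `n_sim` and the spec as
#'   attributes.
#' @export
power_curve <- function(spec, n_grid, alpha = 0.05, n_sim = 1000,
                        seed = NULL) {
  stopifnot(inherits(spec, "effect_spec"), all(n_grid >= 4))
  rows <- vector("list", length(n_grid))
  for (gi in seq_along(n_grid)) {
    N <- n_grid[gi]
    n_v <- ceiling(N / 2); n_t <- N - n_v
    rr <- interaction_rejection_rate(spec, n_v, n_t, alpha = alpha,
                                     n_sim = n_sim,
                                     seed = seed_child(seed, gi))
    rows[[gi]] <- data.frame(n_total = N, n_vehicle = n_v, n_treated = n_t,
                             power = rr$rate, mc_se = rr$mc_se)
  }
  out <- do.call(rbind, rows)
  attr(out, "alpha") <- alpha
  attr(out, "n_sim") <- n_sim
  attr(out, "spec") <- spec
  class(out) <- c("power_curve", class(out))
  out
}

#' Closed-form power of the 1-df interaction test
#'
#' Noncentral-chi-square approximation: the interaction estimate in the
#' balanced continuous-coding design has variance
#' `(1/n_v + 1/n_t) (sigma_b^2 + sigma_e^2 / S_xx)` with `S_xx` the per-cell
#' sum of squares of the centered current covariate, giving noncentrality
#' `lambda = slope^2 / Var` and power
#' `P(chisq_1(lambda) > qchisq(1 - alpha, 1))`.
#'
#' @param spec an [effect_spec()] (its `interaction_se` is ignored).
#' @param n_total total cell count(s).
#' @param alpha test level.
#' @param steps current-step grid, pA.
#' @return numeric vector of power values.
#' @export
power_closed_form <- function(spec, n_total, alpha = 0.05,
                              steps = step_grid()) {
  s_xx <- sum((steps - 300)^2)
  vapply(n_total, function(N) {
    n_v <- ceiling(N / 2); n_t <- N - n_v
    v_slope <- (1 / n_v + 1 / n_t) *
      (spec$random_slope_sd^2 + spec$residual_sd^2 / s_xx)
    lambda <- spec$interaction_slope^2 / v_slope
    pchisq(qchisq(1 - alpha, 1), 1, ncp = lambda, lower.tail = FALSE)
  }, numeric(1))
}
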