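#' Assemble the long-format cohort table
#'
#' One row per (cell, step) with the chosen response; rows whose response is
#' unobserved are flagged missing, not dropped, so that imputation and
#' bookkeeping can see them.
#'
#' @param features long data.frame of per-sweep features (must contain
#'   `cell_id`, `group`, `step` and the response column); absent (cell, step)
#'   combinations are filled in as missing rows.
#' @param response_name name of the response column (e.g. `"v_slow"`).
#' @param steps the step grid the table must cover.
#' @return data.frame of class `cohort_table` with columns `cell_id`,
#'   `group`, `step`, `response`, `missing`.
#' @export
build_long_table <- function(features, response_name, steps = step_grid()) {
  need <- c("cell_id", "group", "step", response_name)
  if (!all(need %in% names(features)))
    stopf("features table lacks columns: %s",
          paste(setdiff(need, names(features)), collapse = ", "))
  if (anyDuplicated(features[, c("cell_id", "step")]))
    stopf("duplicate (cell, step) rows in the features table")
  cells <- unique(features[, c("cell_id", "group")])
  grid <- merge(cells, data.frame(step = steps), by = NULL)
  tab <- merge(grid, features[, need], by = c("cell_id", "group", "step"),
               all.x = TRUE)
  tab$response <- tab[[response_name]]
  tab[[response_name]] <- NULL
  tab$missing <- is.na(tab$response)
  tab <- tab[order(tab$cell_id, tab$step), c("cell_id", "group", "step",
                                             "response", "missing")]
  rownames(tab) <- NULL
  attr(tab, "response_name") <- response_name
  class(tab) <- c("cohort_table", class(tab))
  tab
}

# Centered, rescaled current covariate: (step - 300)/100, i.e. units of
# 100 pA. Rescaling keeps the random-slope variance O(0.01) instead of
# O(1e-6), which the mixed-model optimizer handles far better; coefficients
# are reported on both scales.
step_covariate <- function(step) (step - 300) / 100

#' Fit the linear mixed-effects model of a cohort table
#'
#' Fixed effects: treatment group, injected current (centered, by default as
#' a continuous covariate so the treatment-by-current interaction is a
#' single-df trend test) and their interaction. Random effects: per-cell
#' intercept and current slope. Estimation is by maximum likelihood (not
#' REML) so that likelihood-ratio tests between fixed-effect structures are
#' valid. A singular random-effects covariance triggers a refit with a
#' diagonal (uncorrelated) structure, which is flagged.
#'
#' @param table a [build_long_table()] result (missing rows are dropped from
#'   the fit but retained in the table).
#' @param formula_terms which fixed effects to include: `"full"`
#'   (group * current), `"no_interaction"`, or `"no_group"` (current only).
#' @param step_coding `"continuous"` (default, 1-df interaction) or
#'   `"factor"` (13-level factor, 12-df interaction).
#' @return list of class `sahp_lme`: `model` (the merMod), `fixed`
#'   (coefficient table with per-pA rescalings), `ranef_sd`, `sigma`,
#'   `loglik`, `df`, `converged`, `singular`, `formula_id`, `n_obs`.
#' @export
fit_lme <- function(table, formula_terms = c("full", "no_interaction", "no_group"),
                    step_coding = c("continuous", "factor")) {
  formula_terms <- match.arg(formula_terms)
  step_coding <- match.arg(step_coding)
  d <- as.data.frame(table)
  d <- d[!d$missing & !is.na(d$response), , drop = FALSE]
  if (length(unique(d$cell_id[d$group == "vehicle"])) < 2 ||
      length(unique(d$cell_id[d$group == "treated"])) < 2)
    stopf("need at least 2 cells per group")
  d$step_c <- step_covariate(d$step)
  d$step_f <- factor(d$step)
  d$group <- factor(d$group, levels = c("vehicle", "treated"))
  xterm <- if (step_coding == "continuous") "step_c" else "step_f"
  fixed <- switch(formula_terms,
    full = sprintf("response ~ group * %s", xterm),
    no_interaction = sprintf("response ~ group + %s", xterm),
    no_group = sprintf("response ~ %s", xterm))
  form <- as.formula(paste(fixed, "+ (1 + step_c | cell_id)"))
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore",
                            calc.derivs = FALSE)
  fit <- suppressWarnings(suppressMessages(
    lme4::lmer(form, data = d, REML = FALSE, control = ctrl)))
  singular <- lme4::isSingular(fit, tol = 1e-4)
  if (singular) {
    form2 <- as.formula(paste(fixed, "+ (1 + step_c || cell_id)"))
    fit2 <- suppressWarnings(suppressMessages(
      lme4::lmer(form2, data = d, REML = FALSE, control = ctrl)))
    if (logLik(fit2) >= logLik(fit) - 1e-6) fit <- fit2
  }
  sf <- summary(fit)$coefficients
  fixedtab <- data.frame(term = rownames(sf), estimate = sf[, "Estimate"],
                         se = sf[, "Std. Error"], stringsAsFactors = FALSE,
                         row.names = NULL)
  # per-pA rescaling of current terms (the covariate is per 100 pA)
  per_pa <- fixedtab$estimate / ifelse(grepl("step_c", fixedtab$term), 100, 1)
  fixedtab$estimate_per_pa <- per_pa
  vc <- as.data.frame(lme4::VarCorr(fit))
  out <- list(
    model = fit, fixed = fixedtab,
    ranef_sd = setNames(vc$sdcor, paste(vc$var1, vc$var2, sep = ":")),
    sigma = sigma(fit), loglik = as.numeric(logLik(fit)),
    df = attr(logLik(fit), "df"),
    converged = length(fit@optinfo$conv$lme4) == 0,
    singular = singular, formula_id = paste(formula_terms, step_coding),
    n_obs = nrow(d))
  class(out) <- "sahp_lme"
  out
}

#' Likelihood-ratio test between nested mixed models
#'
#' `chi_square = 2 (loglik_full - loglik_reduced)` referred to a chi-square
#' with degrees of freedom equal to the parameter-count difference. Both
#' models must be ML fits of nested fixed-effect structures on the same
#' observations.
#'
#' @param full,reduced [fit_lme()] results.
#' @return list of class `sahp_lrt`: `chi_square`, `df`, `p_value`,
#'   `full_model_id`, `reduced_model_id`.
#' @export
lrt <- function(full, reduced) {
  stopifnot(inherits(full, "sahp_lme"), inherits(reduced, "sahp_lme"))
  if (full$n_obs != reduced$n_obs)
    stopf("models were fitted to different numbers of observations")
  df <- full$df - reduced$df
  if (df < 0) stopf("models are not nested: the full model has fewer parameters")
  chi <- 2 * (full$loglik - reduced$loglik)
  if (chi < -1e-6)
    stopf("negative likelihood-ratio statistic (%.3g): convergence failure", chi)
  chi <- max(chi, 0)
  p <- if (df == 0) 1 else pchisq(chi, df, lower.tail = FALSE)
  out <- list(chi_square = chi, df = df, p_value = p,
              full_model_id = full$formula_id,
              reduced_model_id = reduced$formula_id)
  class(out) <- "sahp_lrt"
  out
}

#' Interaction likelihood-ratio test for a cohort table
#'
#' Convenience wrapper fitting the full model and the model without the
#' treatment-by-current interaction and comparing them with [lrt()].
#'
#' @param table a [build_long_table()] result.
#' @param step_coding passed to [fit_lme()].
#' @return list with `full`, `reduced` and `test`.
#' @export
test_interaction <- function(table, step_coding = "continuous") {
  full <- fit_lme(table, "full", step_coding)
  reduced <- fit_lme(table, "no_interaction", step_coding)
  list(full = full, reduced = reduced, test = lrt(full, reduced))
}

#' Cook's-distance influence screen
#'
#' Observation-level Cook's distances for the fixed effects of the mixed
#' model, flagged against the 4/n cutoff where n is the number of
#' observation points in the fit. The marginal covariance implied by the
#' fitted random effects (block diagonal by cell) is used to whiten the
#' data, after which the ordinary case-deletion identity
#' `D_i = r_i^2 h_ii / (p s^2 (1 - h_ii)^2)` applies; this closed form
#' tracks brute-force leave-one-observation-out refitting closely (verified
#' in the test suite) at a fraction of the cost.
#'
#' @param table a [build_long_table()] result.
#' @param model optional [fit_lme()] result for `table` (fitted fresh when
#'   `NULL`).
#' @return list of class `influence_report`: `distances` (per observed row
#'   of `table`, `NA` for missing rows), `cutoff`, `flagged` (row indices of
#'   `table`), `n`.
#' @export
cooks_screen <- function(table, model = NULL) {
  if (is.null(model)) model <- fit_lme(table, "full")
  fit <- model$model
  fr <- fit@frame
  X <- model.matrix(stats::terms(fit), fr)
  y <- stats::model.response(fr)
  s2_eps <- sigma(fit)^2
  vc <- lme4::VarCorr(fit)
  G <- Reduce(`+`, lapply(vc, function(m) {
    out <- matrix(0, 2, 2,
                  dimnames = list(c("(Intercept)", "step_c"),
                                  c("(Intercept)", "step_c")))
    out[rownames(m), colnames(m)] <- m
    out
  }))
  # whiten per cell: V_cell = Z G Z' + sigma^2 I with Z = [1, step_c]
  n <- nrow(X)
  yw <- numeric(n)
  Xw <- matrix(0, n, ncol(X))
  for (cid in unique(fr$cell_id)) {
    idx <- which(fr$cell_id == cid)
    Z <- cbind(1, fr$step_c[idx])
    V <- Z %*% G %*% t(Z) + s2_eps * diag(length(idx))
    L <- chol(V)
    yw[idx] <- backsolve(L, y[idx], transpose = TRUE)
    Xw[idx, ] <- backsolve(L, X[idx, , drop = FALSE], transpose = TRUE)
  }
  qrX <- qr(Xw)
  h <- rowSums(qr.Q(qrX)^2)
  r <- yw - Xw %*% qr.coef(qrX, yw)
  p <- ncol(X)
  s2 <- sum(r^2) / (n - p)
  d <- as.numeric(r)^2 * h / (p * s2 * (1 - h)^2)
  obs_rows <- which(!table$missing & !is.na(table$response))
  if (length(obs_rows) != n)
    stopf("model was not fitted to this table (%d vs %d observations)",
          n, length(obs_rows))
  if (n <= p) stopf("fewer observations than parameters")
  distances <- rep(NA_real_, nrow(table))
  distances[obs_rows] <- d
  cutoff <- 4 / n
  out <- list(distances = distances, cutoff = cutoff,
              flagged = which(!is.na(distances) & distances > cutoff), n = n)
  class(out) <- "influence_report"
  out
}

#' Per-group correlation of sAHP amplitude with spike count
#'
#' For each treatment group, the per-step group means of the slow-AHP
#' amplitude are correlated (Pearson, two-sided) with the per-step group
#' means of the spike count - 13 points per group on the full grid.
#'
#' @param features long data.frame with `cell_id`, `group`, `step`,
#'   `v_slow` and `n_spikes`.
#' @return named list (per group) of lists with `r`, `p`, `n_points`.
#' @export
correlate_sahp_spikes <- function(features) {
  stopifnot(all(c("group", "step", "v_slow", "n_spikes") %in% names(features)))
  out <- list()
  for (g in unique(features$group)) {
    sub <- features[features$group == g, ]
    agg <- aggregate(cbind(v_slow, n_spikes) ~ step, data = sub,
                     FUN = mean, na.rm = TRUE)
    if (nrow(agg) < 3) stopf("fewer than 3 step points for group %s", g)
    ct <- cor.test(agg$v_slow, agg$n_spikes, method = "pearson")
    out[[g]] <- list(r = unname(ct$estimate), p = ct$p.value,
                     n_points = nrow(agg))
  }
  out
}
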