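# Multiple imputation by expectation-maximization with bootstrapping, and
# the combining rules for estimates and likelihood-ratio statistics.

# EM for a multivariate-normal model of the cells x steps response matrix
# with group-specific means and a pooled covariance. The covariance is
# shrunk toward its own diagonal with adaptive weight p/(n + p) to keep the
# 13-dimensional estimate well-conditioned at cohort-scale n.
em_mvn <- function(Y, groups, max_iter = 200, tol = 1e-6) {
  n <- nrow(Y); p <- ncol(Y)
  glev <- unique(groups)
  M <- matrix(0, length(glev), p, dimnames = list(glev, NULL))
  for (g in glev)
    M[g, ] <- apply(Y[groups == g, , drop = FALSE], 2, mean, na.rm = TRUE)
  M[is.na(M)] <- mean(Y, na.rm = TRUE)
  Yc <- Y
  for (g in glev) Yc[groups == g, ] <- sweep(Y[groups == g, , drop = FALSE], 2, M[g, ])
  S <- stats::cov(Yc, use = "pairwise.complete.obs")
  S[is.na(S)] <- 0
  diag(S)[diag(S) <= 0] <- stats::var(as.numeric(Y), na.rm = TRUE)
  alpha <- p / (n + p)
  v_floor <- max(stats::var(as.numeric(Y), na.rm = TRUE), 1e-8) * 1e-4
  shrink <- function(S) {
    S2 <- (1 - alpha) * S + alpha * diag(diag(S), p)
    # variance floor: tiny bootstrap resamples can make a column degenerate
    diag(S2) <- pmax(diag(S2), v_floor)
    S2
  }
  S <- shrink(S)
  mis_pat <- is.na(Y)

  for (iter in seq_len(max_iter)) {
    Yhat <- Y
    Cacc <- matrix(0, p, p)
    for (i in seq_len(n)) {
      mis <- mis_pat[i, ]
      if (!any(mis)) next
      mu <- M[groups[i], ]
      if (all(mis)) {
        Yhat[i, ] <- mu
        Cacc <- Cacc + S
        next
      }
      Soo <- S[!mis, !mis, drop = FALSE]
      Smo <- S[mis, !mis, drop = FALSE]
      K <- Smo %*% solve(Soo)
      Yhat[i, mis] <- mu[mis] + K %*% (Y[i, !mis] - mu[!mis])
      Cm <- S[mis, mis, drop = FALSE] - K %*% t(Smo)
      Cacc[mis, mis] <- Cacc[mis, mis] + Cm
    }
    M_new <- M
    for (g in glev)
      M_new[g, ] <- colMeans(Yhat[groups == g, , drop = FALSE])
    Yc <- Yhat
    for (g in glev)
      Yc[groups == g, ] <- sweep(Yhat[groups == g, , drop = FALSE], 2, M_new[g, ])
    S_new <- shrink((crossprod(Yc) + Cacc) / n)
    delta <- max(abs(M_new - M), abs(S_new - S))
    M <- M_new; S <- S_new
    if (delta < tol) break
  }
  list(mean = M, cov = S, iters = iter)
}

# Conditional-normal draw of the missing entries of one row.
draw_missing <- function(y, mu, S) {
  mis <- is.na(y)
  if (!any(mis)) return(y)
  if (all(mis)) {
    y[] <- MASS::mvrnorm(1, mu, S)
    return(y)
  }
  Soo <- S[!mis, !mis, drop = FALSE]
  Smo <- S[mis, !mis, drop = FALSE]
  K <- Smo %*% solve(Soo)
  cm <- mu[mis] + as.numeric(K %*% (y[!mis] - mu[!mis]))
  Cm <- S[mis, mis, drop = FALSE] - K %*% t(Smo)
  Cm <- (Cm + t(Cm)) / 2
  y[mis] <- MASS::mvrnorm(1, cm, Cm)
  y
}

#' Multiple imputation of a cohort table by EM with bootstrapping
#'
#' Missing (cell, step) responses are imputed under a multivariate-normal
#' model of the 13-step response vector per cell, with group-specific means
#' and a pooled, diagonal-shrunk covariance. For each of the `m`
#' imputations, the model is estimated by expectation-maximization on a
#' bootstrap resample of cells (drawn within group, preserving group sizes)
#' - the bootstrap propagates parameter uncertainty into the imputations -
#' and the missing entries of the original table are then drawn from their
#' conditional normal distribution. Cells with all steps missing cannot
#' inform the model and are dropped with a warning.
#'
#' @param table a [build_long_table()] result with `missing` flagged.
#' @param m number of imputations (default 20).
#' @param seed integer seed; imputation is deterministic given it.
#' @return list of `m` completed `cohort_table`s (an extra logical column
#'   `imputed` marks filled rows). With no missing data, `m` identical
#'   copies of the input are returned.
#' @export
impute_cohort <- function(table, m = 20, seed = NULL) {
  stopifnot(nrow(table) > 0)
  if (mean(table$missing) >= 0.5)
    stopf("more than half of the observations are missing")
  if (!any(table$missing)) {
    tab <- table
    tab$imputed <- FALSE
    return(replicate(m, tab, simplify = FALSE))
  }
  steps <- sort(unique(table$step))
  cells <- unique(table[, c("cell_id", "group")])
  Y <- matrix(NA_real_, nrow(cells), length(steps),
              dimnames = list(cells$cell_id, as.character(steps)))
  for (k in seq_len(nrow(table))) {
    if (!table$missing[k])
      Y[table$cell_id[k], as.character(table$step[k])] <- table$response[k]
  }
  all_mis <- rowSums(!is.na(Y)) == 0
  if (any(all_mis)) {
    warnf("dropping %d cell(s) with all steps missing: %s", sum(all_mis),
          paste(rownames(Y)[all_mis], collapse = ", "))
    Y <- Y[!all_mis, , drop = FALSE]
    cells <- cells[!all_mis, , drop = FALSE]
    table <- table[table$cell_id %in% cells$cell_id, , drop = FALSE]
  }
  groups <- cells$group

  with_seed(seed, {
    out <- vector("list", m)
    for (j in seq_len(m)) {
      idx <- unlist(lapply(unique(groups), function(g) {
        gi <- which(groups == g)
        sample(gi, length(gi), replace = TRUE)
      }))
      fit <- em_mvn(Y[idx, , drop = FALSE], groups[idx])
      Yj <- Y
      for (i in seq_len(nrow(Y)))
        Yj[i, ] <- draw_missing(Y[i, ], fit$mean[groups[i], ], fit$cov)
      tab <- table
      tab$imputed <- tab$missing
      for (k in which(tab$missing)) {
        tab$response[k] <- Yj[tab$cell_id[k], as.character(tab$step[k])]
        tab$missing[k] <- FALSE
      }
      out[[j]] <- tab
    }
    out
  })
}

#' Pool mixed-model estimates across imputations (Rubin's rules)
#'
#' Point estimates are averaged; the total variance combines the
#' within-imputation variance `W` and the between-imputation variance `B` as
#' `T = W + (1 + 1/m) B`, with Rubin's degrees of freedom for the t
#' reference.
#'
#' @param fits list of [fit_lme()] results from the same model on `m`
#'   imputed tables.
#' @return data.frame with one row per fixed-effect term: `estimate`, `se`,
#'   `df`, `p_value`, and the variance components `within`, `between`.
#' @export
pool_estimates <- function(fits) {
  stopifnot(length(fits) >= 1, all(vapply(fits, inherits, TRUE, "sahp_lme")))
  ids <- vapply(fits, `[[`, "", "formula_id")
  if (length(unique(ids)) != 1) stopf("imputation fits have heterogeneous model specs")
  m <- length(fits)
  terms <- fits[[1]]$fixed$term
  est <- sapply(fits, function(f) f$fixed$estimate)
  ses <- sapply(fits, function(f) f$fixed$se)
  if (m == 1) { est <- cbind(est); ses <- cbind(ses) }
  qbar <- rowMeans(est)
  W <- rowMeans(ses^2)
  B <- if (m > 1) apply(est, 1, var) else 0 * qbar
  Tv <- W + (1 + 1 / m) * B
  df <- ifelse(B > 0, (m - 1) * (1 + W / ((1 + 1 / m) * B))^2, Inf)
  tstat <- qbar / sqrt(Tv)
  p <- 2 * pt(-abs(tstat), df)
  data.frame(term = terms, estimate = qbar, se = sqrt(Tv), df = df,
             p_value = p, within = W, between = B,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Pool likelihood-ratio statistics across imputations (D2)
#'
#' Combines the per-imputation chi-square statistics by the standard
#' multiple-imputation chi-square combination (the D2 statistic of Li, Meng,
#' Raghunathan and Rubin), referred to an F distribution.
#'
#' @param lrts list of [lrt()] results from the same comparison on `m`
#'   imputed tables.
#' @return list with `chi_square` (mean statistic), `D2`, `df1`, `df2`,
#'   `p_value`, `m`.
#' @export
pool_lrt <- function(lrts) {
  stopifnot(length(lrts) >= 1, all(vapply(lrts, inherits, TRUE, "sahp_lrt")))
  k <- unique(vapply(lrts, `[[`, numeric(1), "df"))
  if (length(k) != 1) stopf("heterogeneous degrees of freedom across imputations")
  d <- vapply(lrts, `[[`, numeric(1), "chi_square")
  m <- length(d)
  if (m == 1) {
    return(list(chi_square = d, D2 = d / k, df1 = k, df2 = Inf,
                p_value = pchisq(d, k, lower.tail = FALSE), m = 1))
  }
  r <- (1 + 1 / m) * var(sqrt(d))
  D2 <- max(0, (mean(d) / k - (m + 1) / (m - 1) * r) / (1 + r))
  df2 <- if (r > 0) k^(-3 / m) * (m - 1) * (1 + 1 / r)^2 else Inf
  list(chi_square = mean(d), D2 = D2, df1 = k, df2 = df2,
       p_value = pf(D2, k, df2, lower.tail = FALSE), m = m)
}
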