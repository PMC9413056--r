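#' Conditional direct and indirect effects over a moderator grid
#'
#' Product-of-paths effects of amyloid on each growth factor, evaluated at
#' each moderator value `w`:
#' `B_AT = (a1 + a1w w)(b1 + b1w w)`,
#' `B_ATN = (a1 + a1w w)(d21 + d21w w)(b2 + b2w w)`,
#' `B_AN = (a2 + a2w w)(b2 + b2w w)`, direct `c' = c + cw w`, and
#' `total = direct + B_AT + B_ATN + B_AN` (an identity of the recursive
#' linear system).
#'
#' @param fit a [fit_growth_mediation()] result.
#' @param w_grid moderator values (default -1, 0, +1 SD).
#' @return data frame of class `effect_estimates`: one row per
#'   (outcome, w) with the effect decomposition.
#' @export
indirect_effects <- function(fit, w_grid = c(-1, 0, 1)) {
  out <- do.call(rbind, lapply(c("intercept", "slope"), function(oc) {
    sfx <- if (oc == "intercept") "I" else "S"
    a1 <- path_coef(fit, "a1"); a1w <- path_coef(fit, "a1w")
    a2 <- path_coef(fit, "a2"); a2w <- path_coef(fit, "a2w")
    d21 <- path_coef(fit, "d21"); d21w <- path_coef(fit, "d21w")
    b1 <- path_coef(fit, paste0("b1_", sfx))
    b1w <- path_coef(fit, paste0("b1w_", sfx))
    b2 <- path_coef(fit, paste0("b2_", sfx))
    b2w <- path_coef(fit, paste0("b2w_", sfx))
    cc <- path_coef(fit, paste0("c_", sfx))
    cw <- path_coef(fit, paste0("cw_", sfx))
    data.frame(
      outcome = oc, w = w_grid,
      direct = cc + cw * w_grid,
      b_at = (a1 + a1w * w_grid) * (b1 + b1w * w_grid),
      b_atn = (a1 + a1w * w_grid) * (d21 + d21w * w_grid) *
        (b2 + b2w * w_grid),
      b_an = (a2 + a2w * w_grid) * (b2 + b2w * w_grid))
  }))
  out$indirect_total <- out$b_at + out$b_atn + out$b_an
  out$total <- out$direct + out$indirect_total
  class(out) <- c("effect_estimates", "data.frame")
  out
}

#' Index of moderated mediation
#'
#' Analytic derivative of the conditional indirect effect with respect to
#' the moderator, evaluated at `at_w`.  When a single path on the pathway is
#' moderated the derivative is constant in `w` and reduces to the familiar
#' product (e.g. `a2w * b2` for the amyloid -> FDG -> EF pathway); with more
#' than one moderated path the conditional effect is curved in `w` and the
#' derivative at a stated `w` is reported.
#'
#' @param fit a [fit_growth_mediation()] result.
#' @param pathway one of `"AT"`, `"ATN"`, `"AN"`.
#' @param outcome `"intercept"` or `"slope"`.
#' @param at_w moderator value at which the derivative is taken (default 0,
#'   the moderator mean).
#' @return scalar IMM.
#' @export
index_of_moderated_mediation <- function(fit, pathway = c("AN", "AT", "ATN"),
                                         outcome = c("intercept", "slope"),
                                         at_w = 0) {
  if (!pathway[1L] %in% c("AT", "ATN", "AN")) {
    stop("index_of_moderated_mediation: unknown pathway '", pathway[1L],
         "' (use AT, ATN or AN)")
  }
  pathway <- match.arg(pathway)
  outcome <- match.arg(outcome)
  sfx <- if (outcome == "intercept") "I" else "S"
  a1 <- path_coef(fit, "a1"); a1w <- path_coef(fit, "a1w")
  a2 <- path_coef(fit, "a2"); a2w <- path_coef(fit, "a2w")
  d21 <- path_coef(fit, "d21"); d21w <- path_coef(fit, "d21w")
  b1 <- path_coef(fit, paste0("b1_", sfx))
  b1w <- path_coef(fit, paste0("b1w_", sfx))
  b2 <- path_coef(fit, paste0("b2_", sfx))
  b2w <- path_coef(fit, paste0("b2w_", sfx))
  w <- at_w
  switch(pathway,
    AT = a1w * (b1 + b1w * w) + b1w * (a1 + a1w * w),
    AN = a2w * (b2 + b2w * w) + b2w * (a2 + a2w * w),
    ATN = a1w * (d21 + d21w * w) * (b2 + b2w * w) +
      d21w * (a1 + a1w * w) * (b2 + b2w * w) +
      b2w * (a1 + a1w * w) * (d21 + d21w * w))
}

# bias-corrected interval from a bootstrap sample (half-count z0 convention)
bc_interval <- function(boot, theta_hat, alpha = 0.05) {
  boot <- boot[is.finite(boot)]
  B <- length(boot)
  if (B == 0L || max(boot) - min(boot) < 1e-300) {
    c0 <- if (B) boot[1L] else theta_hat
    warning("bc_interval: degenerate bootstrap distribution")
    return(c(lower = c0, upper = c0, z0 = 0))
  }
  p0 <- (sum(boot < theta_hat) + 0.5 * sum(boot == theta_hat)) / B
  p0 <- min(max(p0, 0.5 / B), 1 - 0.5 / B)
  z0 <- stats::qnorm(p0)
  za <- stats::qnorm(1 - alpha / 2)
  lo <- stats::pnorm(2 * z0 - za)
  hi <- stats::pnorm(2 * z0 + za)
  q <- stats::quantile(boot, c(lo, hi), names = FALSE, type = 6)
  c(lower = q[1L], upper = q[2L], z0 = z0)
}

#' Bias-corrected bootstrap confidence intervals
#'
#' Case (subject) resampling with replacement; the estimator is refitted on
#' every resample.  Bias correction shifts the percentile levels by the
#' probit of the bootstrap distribution's position relative to the point
#' estimate (half-count convention for ties); with `z0 = 0` the interval
#' reduces exactly to the percentile method on the same resamples.
#'
#' @param design an object with `n` subjects, subsettable by the estimator.
#' @param estimator `function(design, idx)` returning a named numeric
#'   vector of quantities for the subjects in `idx`.
#' @param B number of resamples (>= 100).
#' @param alpha 1 - confidence level.
#' @param seed integer seed (resampling is deterministic given it).
#' @return matrix with rows per quantity and columns `estimate`, `lower`,
#'   `upper`, `z0`; bootstrap draws in attribute `boot`, failed-resample
#'   count in `n_failed`.
#' @export
bc_bootstrap <- function(design, estimator, B = 2000L, alpha = 0.05,
                         seed = 1L) {
  if (B < 100L) stop("bc_bootstrap: B must be at least 100")
  n <- design$n %||% nrow(design)
  theta_hat <- estimator(design, seq_len(n))
  set.seed(derive_seed(seed, 11L))
  boot <- matrix(NA_real_, B, length(theta_hat),
                 dimnames = list(NULL, names(theta_hat)))
  n_failed <- 0L
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    est <- tryCatch(estimator(design, idx), error = function(e) NULL)
    if (is.null(est)) n_failed <- n_failed + 1L else boot[b, ] <- est
  }
  if (n_failed > 0.05 * B) {
    stop(sprintf("bc_bootstrap: %d of %d resamples failed (> 5%%)",
                 n_failed, B))
  }
  out <- t(vapply(seq_along(theta_hat), function(j) {
    bc_interval(boot[, j], theta_hat[j], alpha)
  }, numeric(3)))
  out <- cbind(estimate = theta_hat, out)
  rownames(out) <- names(theta_hat)
  attr(out, "boot") <- boot
  attr(out, "n_failed") <- n_failed
  out
}

#' Rubin's-rules pooling across imputations
#'
#' Combines per-imputation estimates and standard errors: pooled estimate is
#' the mean, total variance is the mean squared SE plus `(1 + 1/M)` times
#' the between-imputation variance, degrees of freedom follow
#' Barnard-Rubin when a complete-data df is supplied (otherwise the classic
#' large-sample formula), and the CI uses t quantiles.
#'
#' @param estimates M x p matrix of per-imputation estimates.
#' @param ses M x p matrix of per-imputation standard errors.
#' @param df_com complete-data degrees of freedom (default `Inf`).
#' @param alpha 1 - confidence level.
#' @return data frame of class `pooled_estimate` with `qbar`, `ubar`, `b`,
#'   `t`, `se`, `df`, `lower`, `upper`, one row per quantity.
#' @export
pool_rubin <- function(estimates, ses, df_com = Inf, alpha = 0.05) {
  estimates <- as.matrix(estimates)
  ses <- as.matrix(ses)
  M <- nrow(estimates)
  if (M < 2L) stop("pool_rubin: pooling undefined for M = 1")
  if (!all(is.finite(estimates)) || !all(is.finite(ses))) {
    stop("pool_rubin: non-finite estimates or standard errors")
  }
  qbar <- colMeans(estimates)
  b <- apply(estimates, 2L, stats::var)
  ubar <- colMeans(ses^2)
  t_var <- ubar + (1 + 1 / M) * b
  riv <- (1 + 1 / M) * b / ubar
  df_old <- ifelse(b > 0, (M - 1) * (1 + 1 / riv)^2, Inf)
  if (is.finite(df_com)) {
    lam <- (1 + 1 / M) * b / t_var
    df_obs <- (df_com + 1) / (df_com + 3) * df_com * (1 - lam)
    df <- 1 / (1 / df_old + 1 / df_obs)
  } else {
    df <- df_old
  }
  se <- sqrt(t_var)
  tq <- ifelse(is.finite(df), stats::qt(1 - alpha / 2, df),
               stats::qnorm(1 - alpha / 2))
  out <- data.frame(qbar = qbar, ubar = ubar, b = b, t = t_var, se = se,
                    df = df, lower = qbar - tq * se, upper = qbar + tq * se)
  rownames(out) <- colnames(estimates)
  class(out) <- c("pooled_estimate", "data.frame")
  out
}

#' Multiple-imputation inference for the moderated mediation model
#'
#' Two-track inference mirroring the analysis design: (1) the mediation
#' model is fitted once per plausible-value imputation (the moderator column
#' replaced by each draw) and coefficients are pooled by Rubin's rules;
#' (2) bias-corrected bootstrap confidence intervals for the conditional
#' indirect effects and the indices of moderated mediation are obtained from
#' a model using the per-subject average plausible value as moderator.
#'
#' @param plausible a [draw_plausible_values()] result (rows aligned with
#'   `table`).
#' @param table cohort table.
#' @param spec a [mediation_spec()]; `spec$w` names the moderator column to
#'   fill with the plausible values.
#' @param w_grid moderator grid for conditional effects.
#' @param B bootstrap resamples (`0` skips the bootstrap track).
#' @param alpha 1 - confidence level.
#' @param seed integer seed.
#' @return list of class `mi_inference`: `pooled` (coefficients), `effects`
#'   (conditional-effect table from the average-value fit), `imm`,
#'   `boot_ci`, `fit_avg`, `n_used`, `M`.
#' @export
run_mi_inference <- function(plausible, table, spec = mediation_spec(),
                             w_grid = c(-1, 0, 1), B = 2000L, alpha = 0.05,
                             seed = 1L) {
  vals <- plausible$values
  if (nrow(vals) != nrow(table)) {
    stop("run_mi_inference: plausible values and table are not row-aligned")
  }
  M <- ncol(vals)
  est <- se <- NULL
  n_mi <- NA_integer_
  for (m in seq_len(M)) {
    tbl_m <- table
    tbl_m[[spec$w]] <- vals[, m]
    fit_m <- tryCatch({
      fit_growth_mediation(build_design(tbl_m, spec))
    }, error = function(e) {
      stop("run_mi_inference: fit failed for imputation column im", m, ": ",
           conditionMessage(e))
    })
    if (is.null(est)) {
      est <- matrix(NA_real_, M, length(fit_m$coef),
                    dimnames = list(NULL, names(fit_m$coef)))
      se <- est
    }
    est[m, ] <- fit_m$coef
    se[m, ] <- fit_m$se
    n_mi <- fit_m$n_used
  }
  # Barnard-Rubin small-sample df with the analysis sample's complete-data df
  pooled <- pool_rubin(est, se, df_com = max(n_mi - ncol(est), 3L),
                       alpha = alpha)

  tbl_avg <- table
  tbl_avg[[spec$w]] <- rowMeans(vals)
  design_avg <- build_design(tbl_avg, spec)
  fit_avg <- fit_growth_mediation(design_avg)
  eff <- indirect_effects(fit_avg, w_grid)
  imm <- c(
    imm_an_intercept = index_of_moderated_mediation(fit_avg, "AN",
                                                    "intercept"),
    imm_an_slope = index_of_moderated_mediation(fit_avg, "AN", "slope"),
    imm_at_intercept = index_of_moderated_mediation(fit_avg, "AT",
                                                    "intercept"),
    imm_at_slope = index_of_moderated_mediation(fit_avg, "AT", "slope"),
    imm_atn_intercept = index_of_moderated_mediation(fit_avg, "ATN",
                                                     "intercept"),
    imm_atn_slope = index_of_moderated_mediation(fit_avg, "ATN", "slope"))
  boot_ci <- NULL
  if (B > 0L) {
    pc <- growth_precond(fit_avg)
    estimator <- function(design, idx) {
      wts <- resample_weights(design, idx)
      f <- fit_growth_mediation(design, weights = wts, se = FALSE,
                                precond = pc)
      e <- indirect_effects(f, w_grid)
      v <- c(e$b_at, e$b_atn, e$b_an)
      names(v) <- paste(rep(c("b_at", "b_atn", "b_an"), each = nrow(e)),
                        rep(e$outcome, times = 3),
                        rep(e$w, times = 3), sep = "_")
      c(v,
        imm_an_intercept = index_of_moderated_mediation(f, "AN", "intercept"),
        imm_an_slope = index_of_moderated_mediation(f, "AN", "slope"))
    }
    boot_ci <- bc_bootstrap(design_avg, estimator, B = B, alpha = alpha,
                            seed = seed)
  }
  structure(list(pooled = pooled, estimates = est, ses = se,
                 effects = eff, imm = imm, boot_ci = boot_ci,
                 fit_avg = fit_avg, n_used = design_avg$n, M = M),
            class = "mi_inference")
}
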