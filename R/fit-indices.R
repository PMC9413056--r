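# chi-square based fit indices and residual-based SRMR for the
# likelihood-ratio comparisons used by the decomposition and mediation fits.

ncp_solve <- function(chisq, df, prob) {
  # largest noncentrality with pchisq(chisq, df, ncp) >= prob is found by
  # root-finding; pchisq is decreasing in ncp.
  if (stats::pchisq(chisq, df) < prob) return(0)
  f <- function(l) stats::pchisq(chisq, df, ncp = l) - prob
  hi <- max(2 * chisq, 1)
  while (f(hi) > 0) hi <- hi * 2
  stats::uniroot(f, c(0, hi), tol = 1e-8)$root
}

#' Likelihood-ratio fit indices (chi-square, RMSEA, CFI, TLI)
#'
#' Computes the usual structural-equation fit summary from the log-likelihoods
#' of a target model (H0), the saturated model (H1) and a baseline
#' (independence) model.  The RMSEA 90% confidence interval is obtained by
#' inverting the noncentral chi-square distribution.
#'
#' @param loglik_h0,nparam_h0 log-likelihood and parameter count of the model.
#' @param loglik_h1,nparam_h1 log-likelihood and parameter count of the
#'   saturated comparison model.
#' @param loglik_base,nparam_base log-likelihood and parameter count of the
#'   baseline model.
#' @param n sample size.
#' @param rmsea_denominator `"n-1"` (classic Steiger formula, default) or
#'   `"n"`; software conventions differ.
#' @return list of class `fit_indices` with `chisq`, `df`, `rmsea`,
#'   `rmsea_ci90`, `cfi`, `tli`, `n_used`, plus the baseline chi-square.
#' @export
fit_indices <- function(loglik_h0, nparam_h0, loglik_h1, nparam_h1,
                        loglik_base, nparam_base, n,
                        rmsea_denominator = c("n-1", "n")) {
  rmsea_denominator <- match.arg(rmsea_denominator)
  if (n < 2L) stop("fit_indices: n must be at least 2")
  if (loglik_h1 < loglik_h0 - 1e-6) {
    stop("fit_indices: saturated log-likelihood is below the model's")
  }
  df <- nparam_h1 - nparam_h0
  if (df <= 0L) stop("saturated model: fit indices undefined (df = 0)")
  chisq <- max(2 * (loglik_h1 - loglik_h0), 0)
  nd <- if (rmsea_denominator == "n-1") n - 1 else n
  rmsea <- sqrt(max(chisq - df, 0) / (df * nd))
  lo <- sqrt(ncp_solve(chisq, df, 0.95) / (df * nd))
  hi <- sqrt(ncp_solve(chisq, df, 0.05) / (df * nd))
  ci <- c(min(lo, rmsea), max(hi, rmsea))

  chisq_base <- max(2 * (loglik_h1 - loglik_base), 0)
  df_base <- nparam_h1 - nparam_base
  num <- max(chisq - df, 0)
  den <- max(chisq_base - df_base, chisq - df, 0)
  cfi <- if (den == 0) 1 else 1 - num / den
  cfi <- min(max(cfi, 0), 1)
  rb <- chisq_base / df_base
  tli <- if (abs(rb - 1) < 1e-12) 1 else (rb - chisq / df) / (rb - 1)

  structure(list(chisq = chisq, df = df, rmsea = rmsea, rmsea_ci90 = ci,
                 cfi = cfi, tli = tli, srmr = NA_real_, n_used = n,
                 chisq_base = chisq_base, df_base = df_base),
            class = "fit_indices")
}

#' @export
print.fit_indices <- function(x, ...) {
  cat(sprintf("chi-square(%d) = %.3f\n", x$df, x$chisq))
  cat(sprintf("RMSEA = %.3f, 90%% CI (%.3f, %.3f)\n",
              x$rmsea, x$rmsea_ci90[1], x$rmsea_ci90[2]))
  cat(sprintf("CFI = %.3f; TLI = %.3f", x$cfi, x$tli))
  if (!is.na(x$srmr)) cat(sprintf("; SRMR = %.3f", x$srmr))
  cat(sprintf("\nn = %d\n", x$n_used))
  invisible(x)
}

#' Standardized root mean square residual
#'
#' Root mean square of the standardized differences between observed and
#' model-implied covariances, over the unique (lower-triangle including
#' diagonal) entries.  Residuals are standardized by the observed standard
#' deviations.  Mean residuals are excluded by default.
#'
#' @param observed,implied [mvn_model()] objects with identical labels.
#' @param include_means if `TRUE`, standardized mean residuals enter the pool.
#' @return nonnegative scalar.
#' @export
srmr <- function(observed, implied, include_means = FALSE) {
  if (!identical(observed$labels, implied$labels)) {
    stop("srmr: observed and implied models must share labels and ordering")
  }
  sdo <- sqrt(diag(observed$cov))
  if (any(sdo <= 0)) {
    stop(sprintf("degenerate scale: zero observed variance for %s",
                 paste(observed$labels[sdo <= 0], collapse = ", ")))
  }
  D <- outer(sdo, sdo)
  R <- (observed$cov - implied$cov) / D
  vals <- R[lower.tri(R, diag = TRUE)]
  if (include_means) {
    vals <- c(vals, (observed$mean - implied$mean) / sdo)
  }
  sqrt(mean(vals^2))
}

#' Standard errors from the observed information matrix
#'
#' Central-difference Hessian of a log-likelihood at its maximum; standard
#' errors are the square roots of the diagonal of the negative inverse
#' Hessian.  Directions in which the information matrix is singular get `NA`
#' standard errors (with a warning) instead of failing.
#'
#' @param loglik_fn function mapping a parameter vector to a log-likelihood.
#' @param theta_hat parameter vector at the maximum.
#' @param step relative finite-difference step.
#' @return numeric vector of standard errors (`NA` where the information is
#'   singular), with the Hessian attached as attribute `hessian`.
#' @export
observed_info_se <- function(loglik_fn, theta_hat, step = 1e-4) {
  p <- length(theta_hat)
  h <- step * pmax(abs(theta_hat), 1)
  f0 <- loglik_fn(theta_hat)
  H <- matrix(NA_real_, p, p)
  for (i in seq_len(p)) {
    ei <- replace(numeric(p), i, h[i])
    H[i, i] <- (loglik_fn(theta_hat + ei) - 2 * f0 +
                  loglik_fn(theta_hat - ei)) / h[i]^2
  }
  if (p > 1L) {
    for (i in seq_len(p - 1L)) {
      for (j in seq((i + 1L), p)) {
        ei <- replace(numeric(p), i, h[i])
        ej <- replace(numeric(p), j, h[j])
        H[i, j] <- H[j, i] <-
          (loglik_fn(theta_hat + ei + ej) - loglik_fn(theta_hat + ei - ej) -
             loglik_fn(theta_hat - ei + ej) +
             loglik_fn(theta_hat - ei - ej)) / (4 * h[i] * h[j])
      }
    }
  }
  info <- -H
  scale <- max(abs(info), 1)
  if (any(diag(info) < -1e-6 * scale)) {
    warning("observed_info_se: positive curvature at the claimed maximum")
  }
  e <- eigen(info, symmetric = TRUE)
  tolv <- max(abs(e$values)) * 1e-10
  ok <- e$values > tolv
  se <- rep(NA_real_, p)
  if (any(ok)) {
    Vp <- e$vectors[, ok, drop = FALSE] %*%
      (t(e$vectors[, ok, drop = FALSE]) / e$values[ok])
    flat <- rowSums(e$vectors[, !ok, drop = FALSE]^2) > 1e-8
    se <- sqrt(pmax(diag(Vp), 0))
    se[flat] <- NA_real_
  }
  if (anyNA(se)) {
    warning("observed_info_se: information matrix singular; NA standard ",
            "errors flagged")
  }
  names(se) <- names(theta_hat)
  attr(se, "hessian") <- H
  se
}
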