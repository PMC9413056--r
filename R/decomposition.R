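#' Specification of the memory decomposition model
#'
#' The decomposition regresses the baseline memory composite on demographic
#' and brain-integrity predictors, splits the residual variance into a latent
#' residual reserve component (MEMR, uncorrelated with every predictor by
#' construction) and a fixed measurement-error variance, and optionally
#' constrains selected predictor covariances to zero.
#'
#' @param predictors ordered predictor column names.
#' @param memory memory composite column name.
#' @param fixed_error_variance measurement-error variance of the memory
#'   composite, fixed (not estimated); default 0.161.
#' @param zero_cov list of predictor-name pairs whose covariance is fixed to
#'   zero (affects fit indices through the added degrees of freedom).
#' @param drop predictors removed for parsimony (e.g. race/ethnicity).
#' @return list of class `decomposition_spec`.
#' @export
decomposition_spec <- function(predictors = c("age", "sex", "education",
                                              "apoe4", "race", "ethnicity",
                                              "hcv_adj", "wbv_adj", "log_wmh",
                                              "abeta_ratio", "ptau_t0",
                                              "fdg_t0"),
                               memory = "mem_t0",
                               fixed_error_variance = 0.161,
                               zero_cov = NULL, drop = NULL) {
  if (fixed_error_variance <= 0) {
    stop("decomposition_spec: fixed_error_variance must be positive")
  }
  predictors <- setdiff(predictors, drop)
  if (!is.null(zero_cov)) {
    for (pr in zero_cov) {
      if (length(pr) != 2L || !all(pr %in% predictors)) {
        stop("decomposition_spec: zero_cov must pair retained predictors")
      }
    }
  }
  structure(list(predictors = predictors, memory = memory,
                 fixed_error_variance = fixed_error_variance,
                 zero_cov = zero_cov),
            class = "decomposition_spec")
}

#' Maximum-likelihood fit of the decomposition model
#'
#' Estimates the joint (predictors, memory) moments by EM over missingness
#' patterns (full-information ML), extracts the regression of memory on the
#' predictors, and splits the residual variance as
#' `psi_hat = max(residual - theta, 0)` with the measurement-error variance
#' `theta` fixed by the spec.  When zero-covariance constraints are present,
#' fit indices are computed against the unconstrained saturated model; the
#' unconstrained decomposition is itself saturated, so the indices are then
#' undefined and omitted.
#'
#' @param table cohort table (typically after [preprocess_cohort()]).
#' @param spec a [decomposition_spec()].
#' @param se compute observed-information standard errors (default `TRUE`).
#' @return list of class `decomposition_fit`: coefficients (`beta`, with
#'   intercept `(Intercept)`), `psi_hat`, `theta`, `se`, `std_beta`,
#'   `moments` (constrained saturated joint), `loglik`, `fit`
#'   (a [fit_indices()] object or `NULL`), `srmr`, `n_used`, `boundary`.
#' @export
fit_decomposition_ml <- function(table, spec = decomposition_spec(),
                                 se = TRUE) {
  vars <- c(spec$predictors, spec$memory)
  missing_cols <- setdiff(vars, names(table))
  if (length(missing_cols)) {
    stop("fit_decomposition_ml: missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  x <- as.matrix(table[vars])
  keep <- rowSums(!is.na(x)) > 0L
  x <- x[keep, , drop = FALSE]
  n <- nrow(x)
  p <- length(spec$predictors)

  # collinearity pre-check on pairwise-complete correlations
  suppressWarnings(
    cr0 <- stats::cor(x[, spec$predictors, drop = FALSE],
                      use = "pairwise.complete.obs"))
  if (!anyNA(cr0)) {
    kap0 <- kappa(cr0, exact = TRUE)
    if (!is.finite(kap0) || kap0 > 1e10) {
      ev <- eigen(cr0, symmetric = TRUE)
      dep <- spec$predictors[abs(ev$vectors[, p]) > 0.3]
      stop("fit_decomposition_ml: collinear predictors: ",
           paste(dep, collapse = ", "))
    }
  }

  sat <- em_saturated(x)  # unconstrained H1
  constrained <- length(spec$zero_cov %||% list()) > 0L
  h0_mom <- if (constrained) {
    em_saturated(x, zero_cov = spec$zero_cov)
  } else sat

  sxx <- h0_mom$cov[spec$predictors, spec$predictors, drop = FALSE]
  sxy <- h0_mom$cov[spec$predictors, spec$memory]
  syy <- h0_mom$cov[spec$memory, spec$memory]
  kap <- kappa(stats::cov2cor(sxx), exact = TRUE)
  if (!is.finite(kap) || kap > 1e10) {
    ev <- eigen(stats::cov2cor(sxx), symmetric = TRUE)
    dep <- spec$predictors[abs(ev$vectors[, p]) > 0.3]
    stop("fit_decomposition_ml: collinear predictors: ",
         paste(dep, collapse = ", "))
  }
  beta <- solve(sxx, sxy)
  names(beta) <- spec$predictors
  b0 <- h0_mom$mean[spec$memory] -
    sum(h0_mom$mean[spec$predictors] * beta)
  resid_var <- max(syy - sum(beta * sxy), 0)
  theta <- spec$fixed_error_variance
  boundary <- resid_var < theta
  psi_hat <- max(resid_var - theta, 0)
  if (boundary) {
    warning("fit_decomposition_ml: residual variance below the fixed error ",
            "variance; psi_hat clipped to 0 (boundary)")
  }

  implied <- decomposition_implied(h0_mom, spec, c(b0, beta), psi_hat, theta)
  ll_h0 <- mvn_loglik_missing(x, implied)
  ll_h1 <- attr(sat, "loglik")

  fit <- NULL
  srmr_val <- NA_real_
  if (constrained || boundary) {
    base <- em_saturated(x, zero_cov = all_pairs(vars))
    df_con <- length(spec$zero_cov %||% list())
    np_h1 <- n_par_saturated(p + 1L)
    np_h0 <- np_h1 - df_con - as.integer(boundary)
    fit <- fit_indices(ll_h0, np_h0, ll_h1, np_h1,
                       attr(base, "loglik"), 2L * (p + 1L), n)
    srmr_val <- srmr(sat, implied)
    fit$srmr <- srmr_val
  }

  se_vec <- NULL
  if (se) {
    # differentiate in SD units so the numeric Hessian is well conditioned
    # across raw predictor scales (e.g. mm^3 volumes vs year counts)
    sdy0 <- sqrt(syy)
    scl <- c(sdy0, sdy0 / sqrt(diag(sxx)), syy)
    ll_fn <- function(phi) {
      par <- phi * scl
      psi <- par[p + 2L]
      if (psi < 0) return(-Inf)
      m <- decomposition_implied(h0_mom, spec, par[seq_len(p + 1L)], psi,
                                 theta)
      mvn_loglik_missing(x, m)
    }
    par_hat <- c(b0, beta, psi_hat)
    se_vec <- suppressWarnings(observed_info_se(ll_fn, par_hat / scl)) * scl
    names(se_vec) <- c("(Intercept)", spec$predictors, "psi")
    if (boundary) se_vec["psi"] <- NA_real_
  }

  sdx <- sqrt(diag(sxx))
  sdy <- sqrt(syy)
  std_beta <- beta * sdx / sdy

  structure(list(
    beta = stats::setNames(c(b0, beta), c("(Intercept)", spec$predictors)),
    psi_hat = psi_hat, theta = theta, resid_var = resid_var,
    boundary = boundary, se = se_vec, std_beta = std_beta,
    moments = h0_mom, saturated = sat, implied = implied,
    loglik = ll_h0, loglik_saturated = ll_h1,
    fit = fit, srmr = srmr_val, n_used = n, spec = spec),
    class = "decomposition_fit")
}

# model-implied joint moments of (predictors, memory) given regression
# parameters and the (constrained) predictor moments
decomposition_implied <- function(mom, spec, par, psi, theta) {
  p <- length(spec$predictors)
  b0 <- par[1L]
  beta <- par[seq(2L, p + 1L)]
  sxx <- mom$cov[spec$predictors, spec$predictors, drop = FALSE]
  mux <- mom$mean[spec$predictors]
  sxy <- drop(sxx %*% beta)
  syy <- sum(beta * sxy) + psi + theta
  cv <- rbind(cbind(sxx, sxy), c(sxy, syy))
  mvn_model(c(mux, b0 + sum(mux * beta)), cv,
            labels = c(spec$predictors, spec$memory))
}

all_pairs <- function(vars) {
  idx <- utils::combn(vars, 2L, simplify = FALSE)
  idx
}

#' @export
print.decomposition_fit <- function(x, ...) {
  cat("Memory decomposition (FIML), n =", x$n_used, "\n")
  tab <- data.frame(estimate = x$beta,
                    se = if (is.null(x$se)) NA_real_ else
                      x$se[seq_along(x$beta)])
  print(round(tab, 4))
  cat(sprintf("psi (residual reserve variance) = %.4f%s; theta = %.4f\n",
              x$psi_hat, if (x$boundary) " [boundary]" else "", x$theta))
  if (!is.null(x$fit)) print(x$fit)
  invisible(x)
}

#' Regression-method factor scores for the residual reserve index
#'
#' Shrunken residual `(psi/(psi+theta)) * (mem - linear predictor)`.  For
#' rows with missing predictors the linear predictor is replaced by its
#' conditional expectation given the observed predictors under the saturated
#' predictor moments; rows with missing memory get `NA`.
#'
#' @param fit a [fit_decomposition_ml()] result.
#' @param table cohort table (same columns as used for the fit).
#' @return numeric vector of per-subject reserve scores.
#' @export
factor_scores <- function(fit, table) {
  spec <- fit$spec
  x <- as.matrix(table[spec$predictors])
  mem <- table[[spec$memory]]
  p <- length(spec$predictors)
  b0 <- fit$beta[1L]
  beta <- fit$beta[-1L]
  mux <- fit$moments$mean[spec$predictors]
  sxx <- fit$moments$cov[spec$predictors, spec$predictors, drop = FALSE]
  lp <- rep(NA_real_, nrow(x))
  obs <- !is.na(x)
  for (pat in missing_patterns(obs)) {
    o <- pat$obs
    m <- setdiff(seq_len(p), o)
    if (length(m) == 0L) {
      lp[pat$rows] <- b0 + drop(x[pat$rows, , drop = FALSE] %*% beta)
    } else if (length(o) == 0L) {
      lp[pat$rows] <- b0 + sum(mux * beta)
    } else {
      B <- sxx[m, o, drop = FALSE] %*% solve(sxx[o, o, drop = FALSE])
      dev <- sweep(x[pat$rows, o, drop = FALSE], 2L, mux[o])
      ex_m <- rep(mux[m], each = length(pat$rows)) + dev %*% t(B)
      lp[pat$rows] <- b0 +
        drop(x[pat$rows, o, drop = FALSE] %*% beta[o]) +
        drop(ex_m %*% beta[m])
    }
  }
  r <- fit$psi_hat / (fit$psi_hat + fit$theta)
  score <- r * (mem - lp)
  score[is.na(mem)] <- NA_real_
  score
}

#' Standardized decomposition coefficients
#'
#' `beta_j * SD(x_j) / SD(memory)` with standard deviations taken from the
#' fitted saturated moments.
#'
#' @param fit a [fit_decomposition_ml()] result.
#' @return named numeric vector (no intercept).
#' @export
standardize_estimates <- function(fit) {
  sdx <- sqrt(diag(fit$moments$cov[fit$spec$predictors, fit$spec$predictors,
                                   drop = FALSE]))
  if (any(sdx <= 0)) {
    stop("degenerate scale: zero-variance predictor ",
         paste(fit$spec$predictors[sdx <= 0], collapse = ", "))
  }
  sdy <- sqrt(fit$moments$cov[fit$spec$memory, fit$spec$memory])
  fit$beta[-1L] * sdx / sdy
}

#' Data-driven zero-covariance constraints
#'
#' Flags predictor pairs whose saturated correlation is not significant at
#' the given level (normal approximation with pairwise-complete n), mirroring
#' the practice of fixing non-significant covariances to zero to aid
#' convergence.
#'
#' @param table cohort table.
#' @param spec a [decomposition_spec()].
#' @param z critical value (default 1.96).
#' @return list of predictor-name pairs suitable for
#'   `decomposition_spec(zero_cov = ...)`.
#' @export
auto_zero_cov <- function(table, spec = decomposition_spec(), z = 1.96) {
  x <- as.matrix(table[spec$predictors])
  sat <- em_saturated(x)
  cr <- stats::cov2cor(sat$cov)
  out <- list()
  for (pair in all_pairs(spec$predictors)) {
    n_pair <- sum(stats::complete.cases(x[, pair]))
    r <- cr[pair[1L], pair[2L]]
    if (n_pair > 3L && abs(atanh(r)) * sqrt(n_pair - 3) < z) {
      out[[length(out) + 1L]] <- pair
    }
  }
  out
}
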