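#' Specification of the moderated sequential mediation model
#'
#' Variable roles follow the AT(N) cascade: X = CSF amyloid ratio (higher =
#' less pathology), M1 = plasma p-tau181 at T1, M2 = FDG metabolism at T2
#' (higher = less neurodegeneration), W = the residual reserve index as
#' moderator of every mediation path, and a latent linear growth model for
#' the EF series with the intercept centred at the third annual follow-up.
#'
#' @param x,w,m1,m2 column names for the amyloid ratio, moderator, tau and
#'   FDG variables.
#' @param ef EF column names in visit order.
#' @param covariates covariates of the growth factors (intercept and slope
#'   equations only).
#' @param interactions which of the nine moderated paths are active
#'   (default all, the full moderated model).
#' @param loadings slope loadings per visit (default `t - 3`, centring the
#'   intercept at T3).
#' @param ef_variance `"shared"` (one EF residual variance) or `"by_time"`.
#' @param standardize z-score X, W, M1, M2 by their sample moments when the
#'   design is built.
#' @return list of class `mediation_spec`.
#' @export
mediation_spec <- function(x = "abeta_ratio", w = "memr", m1 = "ptau_t1",
                           m2 = "fdg_t2", ef = paste0("ef_t", 0:7),
                           covariates = c("age", "sex", "education"),
                           interactions = c("a1w", "a2w", "d21w", "b1w_I",
                                            "b1w_S", "b2w_I", "b2w_S",
                                            "cw_I", "cw_S"),
                           loadings = (0:7) - 3,
                           ef_variance = c("shared", "by_time"),
                           standardize = TRUE) {
  ef_variance <- match.arg(ef_variance)
  if (length(loadings) != length(ef)) {
    stop("mediation_spec: loadings must have one entry per EF visit")
  }
  known <- c("a1w", "a2w", "d21w", "b1w_I", "b1w_S", "b2w_I", "b2w_S",
             "cw_I", "cw_S")
  if (!all(interactions %in% known)) {
    stop("mediation_spec: unknown interaction label(s): ",
         paste(setdiff(interactions, known), collapse = ", "))
  }
  structure(list(x = x, w = w, m1 = m1, m2 = m2, ef = ef,
                 covariates = covariates, interactions = interactions,
                 loadings = loadings, ef_variance = ef_variance,
                 standardize = standardize),
            class = "mediation_spec")
}

#' Build the mediation analysis dataset
#'
#' Restricts to subjects with complete X, W, M1, M2 and covariates (the EF
#' series keeps its missingness for marginal-likelihood integration),
#' optionally z-scores the biomarkers and moderator, and constructs the
#' product columns for the moderated paths.
#'
#' @param table (preprocessed) cohort table.
#' @param spec a [mediation_spec()].
#' @return list of class `mediation_design` with vectors `x`, `w`, `m1`,
#'   `m2`, products, covariate matrix `cov`, EF matrix `ef`, and `n`.
#' @export
build_design <- function(table, spec = mediation_spec()) {
  need <- c(spec$x, spec$w, spec$m1, spec$m2, spec$covariates, spec$ef)
  missing_cols <- setdiff(need, names(table))
  if (length(missing_cols)) {
    stop("build_design: missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  core <- table[c(spec$x, spec$w, spec$m1, spec$m2, spec$covariates)]
  keep <- stats::complete.cases(core)
  if (!any(keep)) stop("build_design: zero analyzable subjects")
  zs <- function(v) if (spec$standardize) (v - mean(v)) / stats::sd(v) else v
  x <- zs(table[[spec$x]][keep])
  w <- zs(table[[spec$w]][keep])
  m1 <- zs(table[[spec$m1]][keep])
  m2 <- zs(table[[spec$m2]][keep])
  cov <- as.matrix(table[keep, spec$covariates, drop = FALSE])
  ef <- as.matrix(table[keep, spec$ef, drop = FALSE])
  obs <- !is.na(ef)
  any_obs <- rowSums(obs) > 0L
  rows_map <- which(any_obs)
  pats <- lapply(missing_patterns(obs[any_obs, , drop = FALSE]),
                 function(p) list(rows = rows_map[p$rows], obs = p$obs))
  out <- structure(list(x = x, w = w, m1 = m1, m2 = m2,
                        xw = x * w, m1w = m1 * w, m2w = m2 * w,
                        cov = cov, ef = ef, ef_patterns = pats,
                        n = sum(keep), keep = which(keep),
                        spec = spec),
                   class = "mediation_design")
  out$blocks <- mediation_blocks(out)
  out
}

subset_design <- function(design, idx) {
  out <- design
  for (f in c("x", "w", "m1", "m2", "xw", "m1w", "m2w")) {
    out[[f]] <- design[[f]][idx]
  }
  out$cov <- design$cov[idx, , drop = FALSE]
  out$ef <- design$ef[idx, , drop = FALSE]
  out$ef_patterns <- NULL
  out$blocks <- NULL
  out$n <- length(idx)
  out$blocks <- mediation_blocks(out)
  out
}

# bootstrap resample as multinomial case weights (equivalent to refitting on
# the resampled rows, but reuses the design's cached pattern grouping)
resample_weights <- function(design, idx) {
  tabulate(idx, nbins = design$n)
}

# equation design matrices with coefficient names (cached on the design)
mediation_blocks <- function(design) {
  if (!is.null(design$blocks)) return(design$blocks)
  spec <- design$spec
  act <- spec$interactions
  d1 <- cbind(a0 = 1, a1 = design$x, g_tau = design$w)
  if ("a1w" %in% act) d1 <- cbind(d1, a1w = design$xw)
  d2 <- cbind(n0 = 1, a2 = design$x, d21 = design$m1, g_fdg = design$w)
  if ("a2w" %in% act) d2 <- cbind(d2, a2w = design$xw)
  if ("d21w" %in% act) d2 <- cbind(d2, d21w = design$m1w)
  d3 <- function(sfx) {
    m <- cbind(1, design$x, design$m1, design$m2, design$w)
    colnames(m) <- paste0(c("int0_", "c_", "b1_", "b2_", "g_"), sfx)
    colnames(m)[1] <- if (sfx == "I") "i0" else "s0"
    for (nm in c("cw", "b1w", "b2w")) {
      lab <- paste0(nm, "_", sfx)
      if (lab %in% act) {
        col <- switch(nm, cw = design$xw, b1w = design$m1w, b2w = design$m2w)
        m <- cbind(m, col)
        colnames(m)[ncol(m)] <- lab
      }
    }
    cv <- design$cov
    colnames(cv) <- paste0(colnames(cv), "_", sfx)
    cbind(m, cv)
  }
  list(tau = d1, fdg = d2, eta_i = d3("I"), eta_s = d3("S"))
}

# weighted ML linear regression from sufficient statistics
ols_ml <- function(X, y, wts = NULL) {
  if (is.null(wts)) {
    XtX <- crossprod(X)
    Xty <- crossprod(X, y)
    yty <- sum(y^2)
    n <- length(y)
  } else {
    XtX <- crossprod(X, wts * X)
    Xty <- crossprod(X, wts * y)
    yty <- sum(wts * y^2)
    n <- sum(wts)
  }
  R <- chol(XtX)
  beta <- backsolve(R, backsolve(R, Xty, transpose = TRUE))
  rss <- max(yty - sum(beta * Xty), 0)
  sigma2 <- rss / n
  vc <- chol2inv(R) * sigma2
  ll <- -n / 2 * (log(2 * pi * sigma2) + 1)
  list(beta = stats::setNames(drop(beta), colnames(X)),
       se = stats::setNames(sqrt(diag(vc)), colnames(X)),
       sigma2 = sigma2, loglik = ll, vcov = vc, n = n)
}

# sufficient statistics for the growth block, grouped by EF missingness
# pattern.  XI and XS are the intercept/slope equation designs (possibly
# different column sets); stats are the pattern-level cross products needed
# for the profiled GLS solution.
growth_suffstats <- function(XI, XS, Y, wts = NULL, loadings,
                             patterns = NULL) {
  if (is.null(patterns)) {
    obs <- !is.na(Y)
    any_obs <- rowSums(obs) > 0L
    rows_map <- which(any_obs)
    patterns <- lapply(missing_patterns(obs[any_obs, , drop = FALSE]),
                       function(p) list(rows = rows_map[p$rows],
                                        obs = p$obs))
  }
  lapply(patterns, function(pat) {
    rows <- pat$rows
    o <- pat$obs
    Xi <- XI[rows, , drop = FALSE]
    Xs <- XS[rows, , drop = FALSE]
    Yp <- Y[rows, o, drop = FALSE]
    C <- cbind(1, loadings[o])
    if (is.null(wts)) {
      list(S_ii = crossprod(Xi), S_is = crossprod(Xi, Xs),
           S_ss = crossprod(Xs),
           T_i = crossprod(Xi, Yp), T_s = crossprod(Xs, Yp),
           G = crossprod(Yp), n = length(rows), obs = o, C = C)
    } else {
      wp <- wts[rows]
      list(S_ii = crossprod(Xi, wp * Xi), S_is = crossprod(Xi, wp * Xs),
           S_ss = crossprod(Xs, wp * Xs),
           T_i = crossprod(Xi, wp * Yp), T_s = crossprod(Xs, wp * Yp),
           G = crossprod(Yp, wp * Yp), n = sum(wp), obs = o, C = C)
    }
  })
}

# profiled negative log-likelihood of the latent growth block.
# varpar = (log-chol of Psi_eta: l11, l21, l22; log residual variance(s)).
# Returns the profiled GLS solution as attributes when requested.
growth_objective <- function(varpar, stats_list, loadings, p_i, p_s, n_theta,
                             want_beta = FALSE) {
  Lc <- matrix(c(exp(varpar[1L]), varpar[2L], 0, exp(varpar[3L])), 2, 2)
  psi <- Lc %*% t(Lc)
  thv <- exp(varpar[3L + seq_len(n_theta)])
  A <- matrix(0, p_i + p_s, p_i + p_s)
  r <- numeric(p_i + p_s)
  ii <- seq_len(p_i)
  is_ <- p_i + seq_len(p_s)
  q <- 0
  ld <- 0
  n_cells <- 0
  for (st in stats_list) {
    k <- length(st$obs)
    C <- st$C
    th <- if (n_theta == 1L) rep(thv, k) else thv[st$obs]
    # V = C Psi C' + Theta is positive definite by construction (theta > 0)
    V <- C %*% psi %*% t(C) + diag(th, k)
    R <- chol(V)
    Vi <- chol2inv(R)
    D <- Vi %*% C                      # k x 2
    W2 <- crossprod(C, D)              # 2 x 2
    A[ii, ii] <- A[ii, ii] + W2[1L, 1L] * st$S_ii
    A[ii, is_] <- A[ii, is_] + W2[1L, 2L] * st$S_is
    A[is_, is_] <- A[is_, is_] + W2[2L, 2L] * st$S_ss
    r[ii] <- r[ii] + drop(st$T_i %*% D[, 1L])
    r[is_] <- r[is_] + drop(st$T_s %*% D[, 2L])
    q <- q + sum(Vi * st$G)
    ld <- ld + st$n * 2 * sum(log(diag(R)))
    n_cells <- n_cells + st$n * k
  }
  A[is_, ii] <- t(A[ii, is_])
  Ra <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(Ra)) return(1e10)
  beta <- backsolve(Ra, backsolve(Ra, r, transpose = TRUE))
  nll <- 0.5 * (ld + q - sum(beta * r) + n_cells * log(2 * pi))
  if (want_beta) {
    attr(nll, "beta") <- drop(beta)
    attr(nll, "vcov_beta") <- chol2inv(Ra)
    attr(nll, "psi") <- psi
    attr(nll, "theta") <- thv
  }
  nll
}

# analytic gradient of the profiled growth objective with respect to the
# variance parameters (envelope theorem: the profiled mean solution is a
# stationary point, so only the explicit dependence on V contributes)
growth_gradient <- function(varpar, stats_list, p_i, p_s, n_theta) {
  a <- varpar[1L]; b <- varpar[2L]; cc <- varpar[3L]
  Lc <- matrix(c(exp(a), b, 0, exp(cc)), 2, 2)
  psi <- Lc %*% t(Lc)
  thv <- exp(varpar[3L + seq_len(n_theta)])
  ii <- seq_len(p_i)
  is_ <- p_i + seq_len(p_s)

  # pass 1: profiled mean solution (same assembly as the objective)
  A <- matrix(0, p_i + p_s, p_i + p_s)
  r <- numeric(p_i + p_s)
  pre <- vector("list", length(stats_list))
  for (j in seq_along(stats_list)) {
    st <- stats_list[[j]]
    k <- length(st$obs)
    th <- if (n_theta == 1L) rep(thv, k) else thv[st$obs]
    V <- st$C %*% psi %*% t(st$C) + diag(th, k)
    R <- chol(V)
    Vi <- chol2inv(R)
    D <- Vi %*% st$C
    W2 <- crossprod(st$C, D)
    A[ii, ii] <- A[ii, ii] + W2[1L, 1L] * st$S_ii
    A[ii, is_] <- A[ii, is_] + W2[1L, 2L] * st$S_is
    A[is_, is_] <- A[is_, is_] + W2[2L, 2L] * st$S_ss
    r[ii] <- r[ii] + drop(st$T_i %*% D[, 1L])
    r[is_] <- r[is_] + drop(st$T_s %*% D[, 2L])
    pre[[j]] <- list(Vi = Vi)
  }
  A[is_, ii] <- t(A[ii, is_])
  beta <- solve(A, r)
  bI <- beta[ii]
  bS <- beta[is_]

  # d Psi / d (a, b, c) through the log-Cholesky factor
  dL <- list(matrix(c(exp(a), 0, 0, 0), 2, 2),
             matrix(c(0, 1, 0, 0), 2, 2),
             matrix(c(0, 0, 0, exp(cc)), 2, 2))
  dPsi <- lapply(dL, function(d) d %*% t(Lc) + Lc %*% t(d))

  g <- numeric(3L + n_theta)
  for (j in seq_along(stats_list)) {
    st <- stats_list[[j]]
    Vi <- pre[[j]]$Vi
    k <- length(st$obs)
    # residual second-moment matrix E = G - U - U' + W at the profiled mean
    N <- rbind(drop(bI %*% st$T_i), drop(bS %*% st$T_s))   # 2 x k
    U <- st$C %*% N
    h12 <- drop(bI %*% st$S_is %*% bS)
    H <- matrix(c(drop(bI %*% st$S_ii %*% bI), h12,
                  h12, drop(bS %*% st$S_ss %*% bS)), 2, 2)
    E <- st$G - U - t(U) + st$C %*% H %*% t(st$C)
    Q <- st$n * Vi - Vi %*% E %*% Vi
    P <- crossprod(st$C, Q %*% st$C)   # 2 x 2
    for (v in 1:3) g[v] <- g[v] + 0.5 * sum(P * dPsi[[v]])
    if (n_theta == 1L) {
      g[4L] <- g[4L] + 0.5 * sum(diag(Q)) * thv
    } else {
      g[3L + st$obs] <- g[3L + st$obs] + 0.5 * diag(Q) * thv[st$obs]
    }
  }
  g
}

# preconditioner for bootstrap refits: whitening transform of the variance
# parameters from the full-data Hessian (finite differences of the analytic
# gradient)
growth_precond <- function(fit) {
  design <- fit$design
  spec <- fit$spec
  blocks <- mediation_blocks(design)
  p_i <- ncol(blocks$eta_i)
  p_s <- ncol(blocks$eta_s)
  n_theta <- length(fit$varpar) - 3L
  ss <- growth_suffstats(blocks$eta_i, blocks$eta_s, design$ef, NULL,
                         spec$loadings, design$ef_patterns)
  vp <- fit$varpar
  q <- length(vp)
  H <- matrix(0, q, q)
  h <- 1e-4
  for (j in seq_len(q)) {
    e <- replace(numeric(q), j, h)
    H[, j] <- (growth_gradient(vp + e, ss, p_i, p_s, n_theta) -
                 growth_gradient(vp - e, ss, p_i, p_s, n_theta)) / (2 * h)
  }
  H <- (H + t(H)) / 2
  ev <- eigen(H, symmetric = TRUE)
  vals <- pmax(ev$values, max(ev$values) * 1e-6)
  B <- ev$vectors %*% diag(1 / sqrt(vals), q) %*% t(ev$vectors)
  list(center = vp, B = B)
}

#' Fit the moderated sequential mediation model
#'
#' The joint likelihood factorises along the recursion
#' `f(M1 | X, W) f(M2 | X, M1, W) f(EF series | X, M1, M2, W, covariates)`:
#' the mediator blocks are normal linear regressions (ML), and the growth
#' block maximises the marginal normal likelihood of each subject's observed
#' EF values with mean given by the intercept/slope equations and covariance
#' `Z Psi Z' + Theta` (random intercept and slope, `Z = [1, t - 3]`).
#' Product terms are fixed regressors.  The growth covariance is
#' parameterised by its log-Cholesky factor so it cannot leave the positive
#' semi-definite cone.
#'
#' @param design a [build_design()] result.
#' @param weights optional nonnegative case weights (bootstrap machinery).
#' @param start optional warm-start variance parameters from a previous fit.
#' @param se compute standard errors (skipped inside bootstrap refits).
#' @param precond optional whitening transform of the variance parameters
#'   (`list(center, B)` from the full-data fit) used to accelerate
#'   warm-started bootstrap refits; point estimates only.
#' @return list of class `mediation_fit`: `coef` (all structural
#'   coefficients, named), `se`, `psi_eta`, `theta_ef`, `sigma2_tau`,
#'   `sigma2_fdg`, per-block and total log-likelihoods, `nparam`, `n_used`,
#'   `converged`, `varpar`.
#' @export
fit_growth_mediation <- function(design, weights = NULL, start = NULL,
                                 se = TRUE, precond = NULL) {
  spec <- design$spec
  blocks <- mediation_blocks(design)
  f1 <- ols_ml(blocks$tau, design$m1, weights)
  f2 <- ols_ml(blocks$fdg, design$m2, weights)

  p_i <- ncol(blocks$eta_i)
  p_s <- ncol(blocks$eta_s)
  n_theta <- if (spec$ef_variance == "shared") 1L else length(spec$ef)
  ss <- growth_suffstats(blocks$eta_i, blocks$eta_s, design$ef, weights,
                         spec$loadings, design$ef_patterns)
  obj <- function(vp) growth_objective(vp, ss, spec$loadings, p_i, p_s,
                                       n_theta)
  grd <- function(vp) growth_gradient(vp, ss, p_i, p_s, n_theta)

  # optional preconditioning (bootstrap refits): optimize in the whitened
  # space u, vp = center + B u, where B'HB ~ I for the full-data Hessian H
  if (!is.null(precond)) {
    center <- precond$center
    B <- precond$B
    obj_u <- function(u) obj(center + drop(B %*% u))
    grd_u <- function(u) drop(crossprod(B, grd(center + drop(B %*% u))))
    op <- stats::nlminb(numeric(length(center)), obj_u,
                        gradient = grd_u,
                        control = list(iter.max = 100L, eval.max = 200L,
                                       rel.tol = 1e-8))
    vp_hat <- center + drop(B %*% op$par)
    sol <- growth_objective(vp_hat, ss, spec$loadings, p_i, p_s, n_theta,
                            want_beta = TRUE)
    beta3 <- attr(sol, "beta")
    names(beta3) <- c(colnames(blocks$eta_i), colnames(blocks$eta_s))
    coef_all <- c(f1$beta, f2$beta, beta3)
    se_all <- rep(NA_real_, length(coef_all))
    names(se_all) <- names(coef_all)
    return(structure(list(
      coef = coef_all, se = se_all,
      psi_eta = attr(sol, "psi"), theta_ef = attr(sol, "theta"),
      sigma2_tau = f1$sigma2, sigma2_fdg = f2$sigma2,
      loglik_blocks = c(tau = f1$loglik, fdg = f2$loglik,
                        growth = -as.numeric(sol)),
      loglik = f1$loglik + f2$loglik - as.numeric(sol),
      vcov_blocks = NULL, varpar = vp_hat, varpar_se = NULL,
      nparam = length(coef_all) + 2L + 3L + n_theta,
      n_used = design$n, converged = op$convergence == 0L,
      spec = spec, design = design),
      class = "mediation_fit"))
  }

  if (is.null(start)) {
    # moment start from per-subject OLS growth curves
    Z <- cbind(1, spec$loadings)
    cases <- stats::complete.cases(design$ef)
    if (sum(cases) >= 10L) {
      cf <- t(qr.solve(Z, t(design$ef[cases, , drop = FALSE])))
      vi <- max(stats::var(cf[, 1L]) / 2, 1e-3)
      vs <- max(stats::var(cf[, 2L]) / 2, 1e-4)
    } else {
      vi <- max(stats::var(design$ef[, 1L], na.rm = TRUE) / 2, 1e-3)
      vs <- 1e-2
    }
    resv <- max(mean(apply(design$ef, 2L, stats::var, na.rm = TRUE)) / 3,
                1e-3)
    start <- c(log(sqrt(vi)), 0, log(sqrt(vs)), rep(log(resv), n_theta))
  }
  lower <- c(-8, -10, -8, rep(-10, n_theta))
  upper <- c(5, 10, 5, rep(5, n_theta))
  # the profiled mean parameters are insensitive to the last digits of the
  # variance parameters, so bootstrap refits (se = FALSE) use a looser
  # optimizer tolerance
  ctrl <- list(iter.max = 200L, eval.max = 400L,
               rel.tol = if (se) 1e-10 else 1e-8)
  opt <- stats::nlminb(start, obj, gradient = grd, lower = lower,
                       upper = upper, control = ctrl)
  converged <- opt$convergence == 0L
  if (!converged) {
    # random restarts around the moment start
    best <- opt
    for (r in seq_len(5L)) {
      st <- start + stats::rnorm(length(start), 0, 0.5)
      o2 <- stats::nlminb(st, obj, gradient = grd, lower = lower,
                          upper = upper, control = ctrl)
      if (o2$objective < best$objective) best <- o2
    }
    opt <- best
    converged <- opt$convergence == 0L
  }
  sol <- growth_objective(opt$par, ss, spec$loadings, p_i, p_s, n_theta,
                          want_beta = TRUE)
  beta3 <- attr(sol, "beta")
  names(beta3) <- c(colnames(blocks$eta_i), colnames(blocks$eta_s))
  vcov3 <- attr(sol, "vcov_beta")
  ll3 <- -as.numeric(sol)

  coef_all <- c(f1$beta, f2$beta, beta3)
  se_all <- rep(NA_real_, length(coef_all))
  names(se_all) <- names(coef_all)
  varpar_se <- NULL
  if (se) {
    se_all[names(f1$se)] <- f1$se
    se_all[names(f2$se)] <- f2$se
    se_all[names(beta3)] <- sqrt(pmax(diag(vcov3), 0))
    varpar_se <- tryCatch(
      suppressWarnings(observed_info_se(function(vp) -obj(vp), opt$par,
                                        step = 1e-4)),
      error = function(e) NULL)
  }
  # free parameters: means + two mediator residual variances + Psi (3) + Theta
  nparam <- length(coef_all) + 2L + 3L + n_theta
  structure(list(
    coef = coef_all, se = se_all,
    psi_eta = attr(sol, "psi"), theta_ef = attr(sol, "theta"),
    sigma2_tau = f1$sigma2, sigma2_fdg = f2$sigma2,
    loglik_blocks = c(tau = f1$loglik, fdg = f2$loglik, growth = ll3),
    loglik = f1$loglik + f2$loglik + ll3,
    vcov_blocks = list(tau = f1$vcov, fdg = f2$vcov, growth = vcov3),
    varpar = opt$par, varpar_se = varpar_se,
    nparam = nparam, n_used = design$n, converged = converged,
    spec = spec, design = design),
    class = "mediation_fit")
}

#' @export
print.mediation_fit <- function(x, ...) {
  cat("Moderated sequential mediation fit, n =", x$n_used, "\n")
  tab <- data.frame(estimate = x$coef, se = x$se,
                    z = x$coef / x$se)
  tab$p <- 2 * stats::pnorm(-abs(tab$z))
  print(round(tab, 4))
  cat(sprintf("log-likelihood: %.3f (tau %.3f, fdg %.3f, growth %.3f)\n",
              x$loglik, x$loglik_blocks[1], x$loglik_blocks[2],
              x$loglik_blocks[3]))
  invisible(x)
}

# coefficient accessor with 0 for inactive paths
path_coef <- function(fit, name) {
  if (name %in% names(fit$coef)) unname(fit$coef[name]) else 0
}

# EM for the unrestricted multivariate regression of the endogenous block on
# the exogenous columns with unstructured residual covariance (the H1 model
# for the mediation fit indices), under response missingness
em_mvreg <- function(Y, Z, tol = 1e-8, max_iter = 500L) {
  n <- nrow(Y)
  q <- ncol(Y)
  obs <- !is.na(Y)
  pats <- missing_patterns(obs)
  ZtZ <- crossprod(Z)
  R <- chol(ZtZ)
  # start: complete-case-ish per-column OLS with mean fill
  Yf <- Y
  for (j in seq_len(q)) {
    Yf[is.na(Y[, j]), j] <- mean(Y[, j], na.rm = TRUE)
  }
  B <- backsolve(R, backsolve(R, crossprod(Z, Yf), transpose = TRUE))
  E <- Yf - Z %*% B
  sigma <- crossprod(E) / n + diag(1e-6, q)
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    mu_fit <- Z %*% B
    resid <- Y - mu_fit
    filled <- resid
    cc <- matrix(0, q, q)
    ll <- 0
    for (pat in pats) {
      o <- pat$obs
      m <- setdiff(seq_len(q), o)
      if (length(o) == 0L) {
        filled[pat$rows, ] <- 0
        cc[m, m] <- cc[m, m] + length(pat$rows) * sigma[m, m]
        next
      }
      Soo <- sigma[o, o, drop = FALSE]
      Ro <- chol(Soo)
      ro <- resid[pat$rows, o, drop = FALSE]
      z <- backsolve(Ro, t(ro), transpose = TRUE)
      ll <- ll + sum(-0.5 * (length(o) * log(2 * pi) +
                               2 * sum(log(diag(Ro))) + colSums(z^2)))
      if (length(m)) {
        Bc <- sigma[m, o, drop = FALSE] %*% chol2inv(Ro)
        filled[pat$rows, m] <- ro %*% t(Bc)
        cmm <- sigma[m, m, drop = FALSE] - Bc %*% sigma[o, m, drop = FALSE]
        cc[m, m] <- cc[m, m] + length(pat$rows) * cmm
      }
    }
    if (is.finite(ll_old) && abs(ll - ll_old) < tol) {
      converged <- TRUE
      break
    }
    ll_old <- ll
    Yhat <- mu_fit + filled
    B <- backsolve(R, backsolve(R, crossprod(Z, Yhat), transpose = TRUE))
    E <- Yhat - Z %*% B
    sigma <- (crossprod(E) + cc) / n
    sigma <- (sigma + t(sigma)) / 2
  }
  list(B = B, sigma = sigma, loglik = ll, converged = converged,
       nparam = length(B) + q * (q + 1L) / 2L)
}

#' Fit indices for the mediation model
#'
#' Compares the fitted model (H0) with the unrestricted multivariate
#' regression of (M1, M2, EF series) on the exogenous columns with
#' unstructured residual covariance (H1, estimated by EM under EF
#' missingness), and with a baseline of means and variances only (zero
#' covariances and zero slopes).  SRMR is computed on the residual moments
#' of the endogenous block, with the model-implied covariance evaluated at
#' the sample moderator mean.
#'
#' @param fit a [fit_growth_mediation()] result.
#' @param design the matching [build_design()] dataset.
#' @return a [fit_indices()] object with `srmr` filled in.
#' @export
model_fit_indices <- function(fit, design = fit$design) {
  spec <- fit$spec
  Y <- cbind(m1 = design$m1, m2 = design$m2, design$ef)
  Z <- cbind(1, x = design$x, w = design$w, xw = design$xw, design$cov)
  q <- ncol(Y)
  h1 <- tryCatch(em_mvreg(Y, Z), error = function(e) NULL)
  fallback <- FALSE
  if (is.null(h1) || !h1$converged) {
    fallback <- TRUE
    warning("model_fit_indices: H1 EM did not converge; complete-case ",
            "fallback used")
    cases <- stats::complete.cases(Y)
    h1 <- em_mvreg(Y[cases, , drop = FALSE], Z[cases, , drop = FALSE])
  }
  # baseline: per-variable mean and variance on observed cells
  ll_base <- 0
  for (j in seq_len(q)) {
    v <- Y[, j][!is.na(Y[, j])]
    s2 <- stats::var(v) * (length(v) - 1) / length(v)
    ll_base <- ll_base + sum(stats::dnorm(v, mean(v), sqrt(s2), log = TRUE))
  }
  out <- fit_indices(fit$loglik, fit$nparam, h1$loglik, h1$nparam,
                     ll_base, 2L * q, design$n)
  # SRMR: observed H1 residual moments vs model-implied at the mean moderator
  labels <- c("m1", "m2", spec$ef)
  obs_mod <- mvn_model(rep(0, q), h1$sigma, labels)
  imp_mod <- mvn_model(rep(0, q),
                       implied_endogenous_cov(fit, mean(design$w)), labels)
  out$srmr <- srmr(obs_mod, imp_mod)
  attr(out, "h1_fallback") <- fallback
  out
}

# model-implied residual covariance of (M1, M2, EF series) at moderator w
implied_endogenous_cov <- function(fit, w = 0) {
  spec <- fit$spec
  k1 <- path_coef(fit, "d21") + path_coef(fit, "d21w") * w
  s1 <- fit$sigma2_tau
  s2 <- fit$sigma2_fdg
  # shocks: e1 (tau), e2 (fdg); M1 = e1; M2 = k1 e1 + e2 (conditional on Z)
  p1_I <- path_coef(fit, "b1_I") + path_coef(fit, "b1w_I") * w
  p2_I <- path_coef(fit, "b2_I") + path_coef(fit, "b2w_I") * w
  p1_S <- path_coef(fit, "b1_S") + path_coef(fit, "b1w_S") * w
  p2_S <- path_coef(fit, "b2_S") + path_coef(fit, "b2w_S") * w
  # loading of (eta_I, eta_S) residuals on (e1, e2, uI, uS)
  li <- c(p1_I + p2_I * k1, p2_I, 1, 0)
  ls <- c(p1_S + p2_S * k1, p2_S, 0, 1)
  shock_cov <- diag(c(s1, s2, 0, 0))
  shock_cov[3:4, 3:4] <- fit$psi_eta
  nt <- length(spec$ef)
  out <- matrix(0, 2L + nt, 2L + nt)
  m1v <- c(1, 0, 0, 0)
  m2v <- c(k1, 1, 0, 0)
  lam <- spec$loadings
  rows <- rbind(m1v, m2v,
                t(sapply(seq_len(nt),
                         function(t) li + lam[t] * ls)))
  out <- rows %*% shock_cov %*% t(rows)
  thv <- if (length(fit$theta_ef) == 1L) rep(fit$theta_ef, nt) else
    fit$theta_ef
  diag(out)[2L + seq_len(nt)] <- diag(out)[2L + seq_len(nt)] + thv
  out
}

#' Model-implied mediator and EF trajectories over an (X, W) grid
#'
#' Propagates the structural equations at covariate means: implied tau and
#' FDG from the mediator equations, implied growth factors from the
#' intercept/slope equations, and `EF(t) = intercept + (t - 3) * slope`.
#'
#' @param fit a [fit_growth_mediation()] result.
#' @param x_levels,w_levels grid of amyloid / moderator values (SD units
#'   when the design was standardized).
#' @param times visit indices.
#' @return tidy data frame: one row per (x, w, time) with implied `m1`,
#'   `m2`, `intercept`, `slope`, `ef`.
#' @export
predict_trajectories <- function(fit, x_levels = c(-1, 0, 1),
                                 w_levels = c(-1, 0, 1), times = NULL) {
  spec <- fit$spec
  times <- times %||% seq_along(spec$ef) - 1L
  if (any(abs(c(x_levels, w_levels)) > 4)) {
    warning("predict_trajectories: grid point beyond 4 SD; extrapolating")
  }
  cov_means <- colMeans(fit$design$cov)
  grid <- expand.grid(x = x_levels, w = w_levels)
  out <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    x <- grid$x[i]; w <- grid$w[i]
    m1 <- path_coef(fit, "a0") + path_coef(fit, "a1") * x +
      path_coef(fit, "g_tau") * w + path_coef(fit, "a1w") * x * w
    m2 <- path_coef(fit, "n0") + path_coef(fit, "a2") * x +
      path_coef(fit, "d21") * m1 + path_coef(fit, "g_fdg") * w +
      path_coef(fit, "a2w") * x * w + path_coef(fit, "d21w") * m1 * w
    eta <- function(sfx, const) {
      path_coef(fit, const) + path_coef(fit, paste0("c_", sfx)) * x +
        path_coef(fit, paste0("b1_", sfx)) * m1 +
        path_coef(fit, paste0("b2_", sfx)) * m2 +
        path_coef(fit, paste0("g_", sfx)) * w +
        path_coef(fit, paste0("cw_", sfx)) * x * w +
        path_coef(fit, paste0("b1w_", sfx)) * m1 * w +
        path_coef(fit, paste0("b2w_", sfx)) * m2 * w +
        sum(vapply(names(cov_means), function(cn) {
          path_coef(fit, paste0(cn, "_", sfx)) * cov_means[[cn]]
        }, numeric(1)))
    }
    eta_i <- eta("I", "i0")
    eta_s <- eta("S", "s0")
    data.frame(x = x, w = w, time = times,
               m1 = m1, m2 = m2, intercept = eta_i, slope = eta_s,
               ef = eta_i + (times - 3) * eta_s)
  }))
  rownames(out) <- NULL
  out
}
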