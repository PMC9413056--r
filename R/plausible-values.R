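#' MCMC settings for the Bayesian decomposition model
#'
#' Priors follow the Bayesian re-estimation of the decomposition: the memory
#' error variance gets a highly informative Normal(0.161, 0.00002) prior
#' truncated to the positives (honoured literally via a Metropolis step),
#' regression coefficients get diffuse normal priors, and the reserve
#' variance a diffuse inverse-gamma prior.
#'
#' @param n_chains number of chains (default 2).
#' @param iterations iterations per chain (default 2000).
#' @param burn_fraction fraction discarded as burn-in (default 0.5).
#' @param thin thinning interval for stored draws.
#' @param seed integer seed.
#' @param prior_theta_mean,prior_theta_var truncated-normal prior for the
#'   fixed-in-ML error variance.
#' @param prior_beta_var variance of the diffuse normal coefficient prior.
#' @param prior_psi_shape,prior_psi_rate inverse-gamma prior for the reserve
#'   variance.
#' @return list of class `mcmc_config`.
#' @export
mcmc_config <- function(n_chains = 2L, iterations = 2000L,
                        burn_fraction = 0.5, thin = 1L, seed = 1L,
                        prior_theta_mean = 0.161, prior_theta_var = 2e-5,
                        prior_beta_var = 1e6,
                        prior_psi_shape = 0.001, prior_psi_rate = 0.001) {
  if (prior_theta_var <= 0 || prior_beta_var <= 0) {
    stop("mcmc_config: prior variances must be positive")
  }
  if (burn_fraction <= 0 || burn_fraction >= 1) {
    stop("mcmc_config: burn_fraction must be in (0, 1)")
  }
  structure(list(n_chains = as.integer(n_chains),
                 iterations = as.integer(iterations),
                 burn_fraction = burn_fraction, thin = as.integer(thin),
                 seed = as.integer(seed),
                 prior_theta_mean = prior_theta_mean,
                 prior_theta_var = prior_theta_var,
                 prior_beta_var = prior_beta_var,
                 prior_psi_shape = prior_psi_shape,
                 prior_psi_rate = prior_psi_rate),
            class = "mcmc_config")
}

#' Gibbs sampler for the decomposition model
#'
#' Bayesian re-estimation of the fitted decomposition with the latent
#' residual reserve drawn explicitly.  Each sweep updates (i) the per-subject
#' latent reserve from its conditional normal, (ii) the regression
#' coefficients from their conjugate normal, (iii) the reserve variance from
#' its conjugate inverse-gamma, (iv) the error variance by a random-walk
#' Metropolis step targeting the truncated-normal prior times the
#' likelihood, and (v) missing predictor cells from their conditional
#' normals under the ML saturated predictor model.  Chains start from the ML
#' estimates and are seed-deterministic.
#'
#' @param table cohort table.
#' @param spec a [decomposition_spec()].
#' @param mcmc an [mcmc_config()].
#' @param fix_theta,fix_psi hold the error/reserve variance at its starting
#'   value (diagnostic use).
#' @return list of class `mcmc_chains`: per-chain parameter draws
#'   (iterations x parameters), retained latent-reserve draws, acceptance
#'   rates, the ML fit, and the configuration.
#' @export
gibbs_decomposition <- function(table, spec = decomposition_spec(),
                                mcmc = mcmc_config(),
                                fix_theta = FALSE, fix_psi = FALSE) {
  ml <- fit_decomposition_ml(table, spec, se = FALSE)
  vars <- c(spec$predictors, spec$memory)
  x_all <- as.matrix(table[vars])
  keep <- rowSums(!is.na(x_all)) > 0L
  x_all <- x_all[keep, , drop = FALSE]
  n <- nrow(x_all)
  p <- length(spec$predictors)
  xm <- x_all[, spec$predictors, drop = FALSE]
  mem <- x_all[, spec$memory]
  mem_obs <- !is.na(mem)
  n_y <- sum(mem_obs)

  mux <- ml$saturated$mean[spec$predictors]
  sxx <- ml$saturated$cov[spec$predictors, spec$predictors, drop = FALSE]
  obs <- !is.na(xm)
  pats <- missing_patterns(obs)
  # conditional draw machinery per pattern (fixed saturated predictor model)
  pat_draw <- lapply(pats, function(pat) {
    o <- pat$obs
    m <- setdiff(seq_len(p), o)
    if (length(m) == 0L) return(NULL)
    if (length(o) == 0L) {
      Cmm <- sxx + diag(1e-10, p)
    } else {
      Soo <- sxx[o, o, drop = FALSE]
      B <- sxx[m, o, drop = FALSE] %*% solve(Soo)
      Cmm <- sxx[m, m, drop = FALSE] - B %*% sxx[o, m, drop = FALSE]
      Cmm <- (Cmm + t(Cmm)) / 2 + diag(1e-10, length(m))
    }
    Rm <- chol(Cmm)
    list(rows = pat$rows, m = m, o = o,
         B = if (length(o)) B else NULL, Cinv = chol2inv(Rm), Lp = t(Rm),
         mem_obs = pat$rows[mem_obs[pat$rows]],
         mem_mis = pat$rows[!mem_obs[pat$rows]])
  })
  pat_draw <- Filter(Negate(is.null), pat_draw)

  iters <- mcmc$iterations
  burn <- floor(mcmc$burn_fraction * iters)
  retained_idx <- seq(burn + 1L, iters, by = mcmc$thin)
  par_names <- c("(Intercept)", spec$predictors, "psi", "theta")
  prior_prec <- 1 / mcmc$prior_beta_var
  a0 <- mcmc$prior_psi_shape
  r0 <- mcmc$prior_psi_rate
  th_m <- mcmc$prior_theta_mean
  th_sd <- sqrt(mcmc$prior_theta_var)
  prop_sd <- max(1.5 * min(th_sd, th_m * sqrt(2 / max(n_y, 2))), 1e-4)

  chains <- vector("list", mcmc$n_chains)
  for (ch in seq_len(mcmc$n_chains)) {
    set.seed(derive_seed(mcmc$seed, 100L + ch))
    beta <- ml$beta
    psi <- max(ml$psi_hat, 1e-3)
    theta <- spec$fixed_error_variance
    xw <- xm
    cond_mean <- function(pd) {  # prior conditional mean of the missing cells
      if (is.null(pd$B)) {
        matrix(mux[pd$m], length(pd$rows), length(pd$m), byrow = TRUE)
      } else {
        dev <- sweep(xm[pd$rows, pd$o, drop = FALSE], 2L, mux[pd$o])
        rep(mux[pd$m], each = length(pd$rows)) + dev %*% t(pd$B)
      }
    }
    for (pd in pat_draw) xw[pd$rows, pd$m] <- cond_mean(pd)
    memr_state <- numeric(n)  # current latent-reserve state for step (v)
    draws <- matrix(NA_real_, iters, length(par_names),
                    dimnames = list(NULL, par_names))
    memr_keep <- matrix(NA_real_, length(retained_idx), n)
    acc <- 0L
    for (it in seq_len(iters)) {
      # (v) missing predictor cells from their full conditional: the
      # saturated predictor model acts as the prior, and rows with observed
      # memory also condition on the current memory residual (a rank-one
      # precision update), which keeps the kernel a valid Gibbs step
      for (pd in pat_draw) {
        k <- length(pd$m)
        M0 <- cond_mean(pd)
        if (length(pd$mem_mis)) {
          ridx <- match(pd$mem_mis, pd$rows)
          z <- matrix(stats::rnorm(length(ridx) * k), k)
          xw[pd$mem_mis, pd$m] <- M0[ridx, , drop = FALSE] + t(pd$Lp %*% z)
        }
        if (length(pd$mem_obs)) {
          ridx <- match(pd$mem_obs, pd$rows)
          bm <- beta[1L + pd$m]
          b_oth <- beta[1L + pd$o]
          lp_obs <- beta[1L] +
            (if (length(pd$o))
               drop(xm[pd$mem_obs, pd$o, drop = FALSE] %*% b_oth) else 0)
          r <- mem[pd$mem_obs] - memr_state[pd$mem_obs] - lp_obs
          P <- pd$Cinv + tcrossprod(bm) / theta
          Rp <- chol(P)
          rhs <- M0[ridx, , drop = FALSE] %*% pd$Cinv + outer(r, bm) / theta
          mu_post <- t(backsolve(Rp, backsolve(Rp, t(rhs),
                                               transpose = TRUE)))
          z <- matrix(stats::rnorm(length(ridx) * k), k)
          xw[pd$mem_obs, pd$m] <- mu_post + t(backsolve(Rp, z))
        }
      }
      X <- cbind(1, xw)
      lp <- drop(X %*% beta)
      # (i) latent reserve
      r <- psi / (psi + theta)
      memr <- numeric(n)
      memr[mem_obs] <- r * (mem[mem_obs] - lp[mem_obs]) +
        stats::rnorm(n_y, 0, sqrt(r * theta))
      if (any(!mem_obs)) {
        memr[!mem_obs] <- stats::rnorm(sum(!mem_obs), 0, sqrt(psi))
      }
      memr_state <- memr
      # (ii) coefficients
      yb <- (mem - memr)[mem_obs]
      Xo <- X[mem_obs, , drop = FALSE]
      prec <- crossprod(Xo) / theta + diag(prior_prec, p + 1L)
      ch_prec <- chol(prec)
      mu_b <- backsolve(ch_prec,
                        backsolve(ch_prec, crossprod(Xo, yb) / theta,
                                  transpose = TRUE))
      beta <- drop(mu_b + backsolve(ch_prec, stats::rnorm(p + 1L)))
      lp <- drop(X %*% beta)
      # (iii) reserve variance
      if (!fix_psi) {
        psi <- 1 / stats::rgamma(1L, a0 + n / 2, r0 + sum(memr^2) / 2)
      }
      # (iv) error variance: Metropolis on the truncated-normal prior
      if (!fix_theta) {
        rss <- sum((mem[mem_obs] - lp[mem_obs] - memr[mem_obs])^2)
        log_post <- function(th) {
          if (th <= 0) return(-Inf)
          -n_y / 2 * log(th) - rss / (2 * th) +
            stats::dnorm(th, th_m, th_sd, log = TRUE)
        }
        th_prop <- theta + stats::rnorm(1L, 0, prop_sd)
        lr <- log_post(th_prop) - log_post(theta)
        if (is.finite(lr) && log(stats::runif(1L)) < lr) {
          theta <- th_prop
          acc <- acc + 1L
        }
      }
      if (!is.finite(psi) || !is.finite(theta) || any(!is.finite(beta))) {
        stop("gibbs_decomposition: non-finite posterior state at iteration ",
             it)
      }
      draws[it, ] <- c(beta, psi, theta)
      k_ret <- match(it, retained_idx)
      if (!is.na(k_ret)) memr_keep[k_ret, ] <- memr
    }
    chains[[ch]] <- list(params = draws, memr = memr_keep,
                         accept_theta = acc / iters)
  }
  structure(list(chains = chains, retained = retained_idx,
                 par_names = par_names, ml = ml, spec = spec, mcmc = mcmc,
                 n = n, data = x_all),
            class = "mcmc_chains")
}

#' Potential scale reduction factor (Gelman-Rubin R-hat)
#'
#' Computed per parameter from the second 50% of iterations by default,
#' matching the convergence criterion of R-hat below 1.1 over the second
#' half of the run.  With `split = TRUE` each chain is first split in half.
#'
#' @param chains an `mcmc_chains` object, or a list of numeric vectors (one
#'   per chain) for a single parameter.
#' @param split split each chain in two before computing R-hat.
#' @param second_half restrict to the second 50% of iterations.
#' @return named numeric vector of R-hat values.
#' @export
psrf <- function(chains, split = FALSE, second_half = TRUE) {
  if (inherits(chains, "mcmc_chains")) {
    out <- vapply(chains$par_names, function(pn) {
      psrf(lapply(chains$chains, function(ch) ch$params[, pn]),
           split = split, second_half = second_half)
    }, numeric(1))
    return(out)
  }
  draws <- lapply(chains, as.numeric)
  if (second_half) {
    draws <- lapply(draws, function(d) d[seq(floor(length(d) / 2) + 1L,
                                             length(d))])
  }
  if (split) {
    draws <- do.call(c, lapply(draws, function(d) {
      h <- floor(length(d) / 2)
      list(d[seq_len(h)], d[seq(h + 1L, length(d))])
    }))
  }
  m <- length(draws)
  if (m < 2L) stop("psrf: need at least 2 chains (or split-chain mode)")
  len <- min(lengths(draws))
  if (len < 10L) stop("psrf: need at least 10 retained draws per chain")
  draws <- vapply(draws, function(d) d[seq_len(len)], numeric(len))
  W <- mean(apply(draws, 2L, stats::var))
  B <- len * stats::var(colMeans(draws))
  if (W < 1e-300) return(1)  # constant-parameter convention
  sqrt((len - 1) / len + B / (len * W))
}

# draw memory from its conditional normal given observed predictor cells
draw_memory_conditional <- function(x, model, spec) {
  p <- length(spec$predictors)
  xm <- x[, spec$predictors, drop = FALSE]
  obs <- !is.na(xm)
  out <- numeric(nrow(x))
  mu <- model$mean
  sg <- model$cov
  for (pat in missing_patterns(obs)) {
    o <- pat$obs
    if (length(o) == 0L) {
      out[pat$rows] <- stats::rnorm(length(pat$rows), mu[p + 1L],
                                    sqrt(sg[p + 1L, p + 1L]))
      next
    }
    Soo <- sg[o, o, drop = FALSE]
    byx <- solve(Soo, sg[o, p + 1L])
    cv <- max(sg[p + 1L, p + 1L] - sum(sg[o, p + 1L] * byx), 1e-12)
    dev <- sweep(xm[pat$rows, o, drop = FALSE], 2L, mu[o])
    out[pat$rows] <- mu[p + 1L] + drop(dev %*% byx) +
      stats::rnorm(length(pat$rows), 0, sqrt(cv))
  }
  out
}

# likelihood-ratio discrepancy of a dataset against model-implied moments;
# `start` warm-starts the saturated EM (replicates sit near their generating
# moments, so this shortens the EM path without changing its fixed point)
lr_discrepancy <- function(data, model, ll_sat = NULL, start = NULL) {
  if (is.null(ll_sat)) {
    ll_sat <- attr(em_saturated(data, start = start), "loglik")
  }
  2 * (ll_sat - mvn_loglik_missing(data, model))
}

#' Posterior predictive p-value for the decomposition model
#'
#' For each retained draw, a replicate dataset with the observed sample size
#' and missingness pattern is simulated from the draw's model-implied
#' moments; the discrepancy is the likelihood-ratio distance between a
#' dataset's saturated moments and the draw's implied moments.  The PPP is
#' the proportion of draws in which the replicated discrepancy is at least
#' the observed one; values near 0 indicate misfit.
#'
#' @param chains an `mcmc_chains` object from [gibbs_decomposition()].
#' @param n_draws number of (thinned) posterior draws to use.
#' @param seed seed for the replicate simulations.
#' @return scalar in `[0, 1]` with attribute `discrepancies`.
#' @export
ppp <- function(chains, n_draws = 100L, seed = 1L) {
  spec <- chains$spec
  x <- chains$data
  p <- length(spec$predictors)
  mask <- is.na(x)
  sat <- em_saturated(x)
  ll_sat_obs <- attr(sat, "loglik")
  ret <- chains$retained
  per_chain <- max(1L, floor(n_draws / length(chains$chains)))
  if (per_chain * length(chains$chains) < 50L) {
    warning("ppp: fewer than 50 retained draws; p-value is imprecise")
  }
  set.seed(derive_seed(seed, 7L))
  d_obs <- d_rep <- numeric(0)
  mux <- chains$ml$saturated$mean[spec$predictors]
  sxx <- chains$ml$saturated$cov[spec$predictors, spec$predictors,
                                 drop = FALSE]
  for (ch in chains$chains) {
    idx <- unique(round(seq(1L, length(ret), length.out = per_chain)))
    for (i in idx) {
      par <- ch$params[ret[i], ]
      model <- decomposition_implied(
        mvn_model(c(mux, 0), rbind(cbind(sxx, 0), 0),
                  labels = c(spec$predictors, spec$memory)),
        spec, par[seq_len(p + 1L)], par["psi"], par["theta"])
      f_obs <- 2 * (ll_sat_obs - mvn_loglik_missing(x, model))
      # replicate: predictors kept as observed, memory redrawn from its
      # conditional normal given the observed predictor cells, so observed
      # and replicated discrepancies are on the same footing
      rep_x <- x
      rep_x[, spec$memory] <- draw_memory_conditional(x, model, spec)
      rep_x[mask] <- NA_real_
      f_rep <- lr_discrepancy(rep_x, model, start = model)
      d_obs <- c(d_obs, f_obs)
      d_rep <- c(d_rep, f_rep)
    }
  }
  out <- mean(d_rep >= d_obs)
  attr(out, "discrepancies") <- cbind(observed = d_obs, replicated = d_rep)
  out
}

#' Draw plausible values for the residual reserve index
#'
#' Saves `M` stored latent-reserve vectors at equally spaced post-burn-in
#' iterations, alternating across chains to reduce autocorrelation.  The
#' result carries the convergence (R-hat) table and the ICC(2,k) reliability
#' of the imputations.
#'
#' @param chains an `mcmc_chains` object.
#' @param M number of imputations (default 30).
#' @return list of class `plausible_values`: `values` (subjects x M),
#'   `psrf`, `icc`, `M`.
#' @export
draw_plausible_values <- function(chains, M = 30L) {
  ret_len <- length(chains$retained)
  n_chains <- length(chains$chains)
  total <- ret_len * n_chains
  if (total < M) {
    stop(sprintf(
      "draw_plausible_values: %d retained draws < M = %d; run at least %d iterations",
      total, M, ceiling(M / n_chains) * 2L * chains$mcmc$thin))
  }
  # order retained draws alternating across chains, then take M equally spaced
  order_idx <- cbind(rep(seq_len(ret_len), each = n_chains),
                     rep(seq_len(n_chains), times = ret_len))
  pick <- unique(round(seq(1L, total, length.out = M)))
  j <- 1L
  while (length(pick) < M) {  # guard against rounding collisions
    extra <- setdiff(seq_len(total), pick)
    pick <- sort(c(pick, extra[j])); j <- j + 1L
  }
  vals <- sapply(pick, function(k) {
    chains$chains[[order_idx[k, 2L]]]$memr[order_idx[k, 1L], ]
  })
  colnames(vals) <- paste0("im", seq_len(M))
  icc <- tryCatch(icc2k(vals), error = function(e) NULL)
  structure(list(values = vals, psrf = psrf(chains), icc = icc, M = M,
                 iterations = chains$retained[order_idx[pick, 1L]],
                 retained_row = order_idx[pick, 1L],
                 chain = order_idx[pick, 2L]),
            class = "plausible_values")
}

#' ICC(2,k): two-way random effects, absolute agreement, average of k ratings
#'
#' Reliability of the mean over `k` imputations from the two-way ANOVA mean
#' squares (rows = subjects, columns = imputations):
#' `(MSR - MSE) / (MSR + (MSC - MSE)/n)`.  The confidence interval follows
#' the F-based construction of McGraw & Wong, obtained for the
#' single-rating coefficient and transformed with the Spearman-Brown step.
#'
#' @param values numeric matrix, subjects x imputations, no missing cells.
#' @param alpha confidence level complement (default 0.05).
#' @return list of class `icc2k`: `icc`, `ci`, mean squares, `n`, `k`.
#' @export
icc2k <- function(values, alpha = 0.05) {
  values <- as.matrix(values)
  n <- nrow(values)
  k <- ncol(values)
  if (k < 2L || n < 3L) stop("icc2k: need >= 3 rows and >= 2 columns")
  if (anyNA(values)) stop("icc2k: missing cells are not allowed")
  gm <- mean(values)
  rm_ <- rowMeans(values)
  cm <- colMeans(values)
  ssr <- k * sum((rm_ - gm)^2)
  ssc <- n * sum((cm - gm)^2)
  sse <- sum((values - outer(rm_, rep(1, k)) -
                outer(rep(1, n), cm) + gm)^2)
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  if (msr < 1e-300) {
    stop("icc2k: zero between-subject variance; ICC undefined")
  }
  icc_k <- (msr - mse) / (msr + (msc - mse) / n)
  icc_1 <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  # McGraw & Wong F-based interval for ICC(A,1), Spearman-Brown to (A,k)
  a <- k * icc_1 / (n * (1 - icc_1))
  b <- 1 + k * icc_1 * (n - 1) / (n * (1 - icc_1))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  f_l <- stats::qf(1 - alpha / 2, n - 1, v)
  f_u <- stats::qf(1 - alpha / 2, v, n - 1)
  lo1 <- n * (msr - f_l * mse) /
    (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
  up1 <- n * (f_u * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * f_u * msr)
  sb <- function(r) r * k / (1 + (k - 1) * r)
  structure(list(icc = icc_k, ci = c(sb(lo1), sb(up1)),
                 msr = msr, msc = msc, mse = mse, n = n, k = k),
            class = "icc2k")
}

#' @export
print.icc2k <- function(x, ...) {
  cat(sprintf("ICC(2,%d) = %.3f, 95%% CI (%.3f, %.3f); n = %d\n",
              x$k, x$icc, x$ci[1], x$ci[2], x$n))
  invisible(x)
}
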