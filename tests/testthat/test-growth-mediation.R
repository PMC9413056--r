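test_that("design construction builds products and restricts to complete
          biomarker cases", {
  tb <- recovery_table(200, seed = 61)
  sp <- recovery_spec()
  d <- build_design(tb, sp)
  expect_equal(d$xw, d$x * d$w)
  expect_equal(d$m1w, d$m1 * d$w)
  expect_equal(d$n, 200L)

  # W identically zero makes every product column zero
  tb0 <- tb
  tb0$memr <- 0
  d0 <- build_design(tb0, sp)
  expect_true(all(d0$xw == 0) && all(d0$m1w == 0) && all(d0$m2w == 0))

  # complete-biomarker fraction 0.33 at n = 1000: analyzed n ~ Binomial
  cc <- cohort_config(n_subjects = 1000, seed = 62,
                      complete_fraction = 0.33)
  tbm <- apply_missingness(generate_cohort(cc, true_params()), cc)
  tbm$memr <- tbm$w_true
  dm <- build_design(tbm, recovery_spec())
  expect_lt(abs(dm$n - 330), 3 * sqrt(1000 * 0.33 * 0.67) + 1)

  # no analyzable subjects is an error
  tb_na <- tb
  tb_na$ptau_t1 <- NA_real_
  expect_error(build_design(tb_na, sp), "zero analyzable")
})

test_that("mediator blocks equal closed-form OLS on complete data", {
  tb <- recovery_table(350, seed = 63)
  d <- build_design(tb, recovery_spec())
  f <- fit_growth_mediation(d, se = TRUE)
  o1 <- lm(d$m1 ~ d$x + d$w + d$xw)
  o2 <- lm(d$m2 ~ d$x + d$m1 + d$w + d$xw + d$m1w)
  expect_equal(unname(f$coef[c("a0", "a1", "g_tau", "a1w")]),
               unname(coef(o1)), tolerance = 1e-8)
  expect_equal(unname(f$coef[c("n0", "a2", "d21", "g_fdg", "a2w", "d21w")]),
               unname(coef(o2)), tolerance = 1e-8)
})

test_that("growth estimates on complete balanced data cannot be improved by
          a brute-force maximizer of the joint likelihood", {
  tb <- recovery_table(150, seed = 64)
  sp <- recovery_spec()
  d <- build_design(tb, sp)
  f <- fit_growth_mediation(d)
  blocks <- reservemed:::mediation_blocks(d)
  XI <- blocks$eta_i
  XS <- blocks$eta_s
  pI <- ncol(XI)
  Y <- d$ef
  lam <- sp$loadings
  # independent objective: direct 8-variate normal density, no profiling
  nll_full <- function(par) {
    bI <- par[seq_len(pI)]
    bS <- par[pI + seq_len(pI)]
    L <- matrix(c(exp(par[2 * pI + 1]), par[2 * pI + 2], 0,
                  exp(par[2 * pI + 3])), 2, 2)
    psi <- L %*% t(L)
    th <- exp(par[2 * pI + 4])
    Z <- cbind(1, lam)
    V <- Z %*% psi %*% t(Z) + diag(th, 8)
    mu <- outer(drop(XI %*% bI), rep(1, 8)) +
      outer(drop(XS %*% bS), lam)
    R <- chol(V)
    dev <- Y - mu
    z <- backsolve(R, t(dev), transpose = TRUE)
    0.5 * (nrow(Y) * (8 * log(2 * pi) + 2 * sum(log(diag(R)))) +
             sum(z^2))
  }
  par_hat <- c(f$coef[colnames(XI)], f$coef[colnames(XS)], f$varpar)
  expect_equal(-nll_full(par_hat), f$loglik_blocks[["growth"]],
               tolerance = 1e-8)
  op <- optim(par_hat, nll_full, method = "BFGS",
              control = list(maxit = 2000, reltol = 1e-15))
  # brute force cannot improve on the profiled fit, and does not move
  expect_lt(nll_full(par_hat) - op$value, 1e-4)
  expect_lt(max(abs(op$par - par_hat)), 1e-4)
})

test_that("interaction estimates are unbiased under a null moderator", {
  tp0 <- true_params(a2w = 0)
  reps <- 25
  ests <- matrix(NA_real_, reps, 9)
  colnames(ests) <- c("a1w", "a2w", "d21w", "b1w_I", "b2w_I", "cw_I",
                      "b1w_S", "b2w_S", "cw_S")
  for (r in seq_len(reps)) {
    tb <- recovery_table(332, seed = 700 + r, truth = tp0)
    f <- fit_growth_mediation(build_design(tb, recovery_spec()), se = FALSE)
    ests[r, ] <- f$coef[colnames(ests)]
  }
  mc_se <- apply(ests, 2, sd) / sqrt(reps)
  expect_true(all(abs(colMeans(ests)) < 3 * mc_se + 1e-8))
})

test_that("re-centring the intercept at T0 shifts intercept coefficients by
          -3 times the slope coefficients and leaves slopes unchanged", {
  tb <- recovery_table(250, seed = 65)
  sp3 <- recovery_spec()
  sp0 <- recovery_spec(loadings = 0:7)
  f3 <- fit_growth_mediation(build_design(tb, sp3))
  f0 <- fit_growth_mediation(build_design(tb, sp0))
  nI <- grep("_I$|^i0$", names(f3$coef), value = TRUE)
  nS <- sub("i0", "s0", sub("_I$", "_S", nI))
  expect_equal(unname(f0$coef[nI]),
               unname(f3$coef[nI] - 3 * f3$coef[nS]), tolerance = 1e-5)
  expect_equal(unname(f0$coef[nS]), unname(f3$coef[nS]), tolerance = 1e-5)
})

test_that("block log-likelihoods sum to the joint and weights replicate
          row duplication", {
  tb <- recovery_table(120, seed = 66)
  d <- build_design(tb, recovery_spec())
  f <- fit_growth_mediation(d)
  expect_equal(unname(sum(f$loglik_blocks)), f$loglik, tolerance = 1e-10)
  # doubling all case weights leaves estimates unchanged
  f2 <- fit_growth_mediation(d, weights = rep(2, d$n))
  expect_equal(f2$coef, f$coef, tolerance = 1e-6)
})

test_that("fit indices are calibrated for the true model and flag a
          quadratic trend fitted as linear", {
  ok <- 0L
  for (r in 1:3) {
    tb <- recovery_table(1000, seed = 670 + r, complete = FALSE)
    d <- build_design(tb, recovery_spec())
    fi <- model_fit_indices(fit_growth_mediation(d), d)
    if (fi$rmsea < 0.05) ok <- ok + 1L
    expect_gt(fi$cfi, 0.9)
  }
  expect_gte(ok, 2L)

  # strong quadratic time trend, linear growth model: poor fit
  tb <- recovery_table(1000, seed = 68)
  qt <- 0.12 * ((0:7) - 3)^2
  for (j in 0:7) {
    tb[[paste0("ef_t", j)]] <- tb[[paste0("ef_t", j)]] +
      qt[j + 1] * (1 + tb$w_true^2)
  }
  d <- build_design(tb, recovery_spec())
  fi_bad <- model_fit_indices(fit_growth_mediation(d), d)
  expect_gt(fi_bad$rmsea, 0.08)
})

test_that("per-time EF residual variances are estimable", {
  tb <- recovery_table(400, seed = 69)
  d <- build_design(tb, recovery_spec(ef_variance = "by_time"))
  f <- fit_growth_mediation(d)
  expect_length(f$theta_ef, 8L)
  expect_true(all(f$theta_ef > 0.05 & f$theta_ef < 0.5))
})

test_that("trajectory prediction propagates the structural algebra", {
  tb <- recovery_table(150, seed = 70)
  d <- build_design(tb, recovery_spec())
  f <- fit_growth_mediation(d)

  # hand-set coefficients: implied M2 difference between W = +-1 at X = 1
  f2 <- f
  f2$coef[] <- 0
  f2$coef["a2"] <- 0.3; f2$coef["a2w"] <- -0.15; f2$coef["b2_I"] <- 0.4
  tr <- predict_trajectories(f2, x_levels = 1, w_levels = c(-1, 1))
  m2_hi <- unique(tr$m2[tr$w == 1])
  m2_lo <- unique(tr$m2[tr$w == -1])
  expect_equal(m2_hi - m2_lo, 2 * (-0.15), tolerance = 1e-12)

  # all paths zero: EF curves are flat and equal to the intercept constant
  f0 <- f
  f0$coef[] <- 0
  f0$coef["i0"] <- 0.7
  f0$design$cov[] <- 0
  tr0 <- predict_trajectories(f0)
  expect_true(all(abs(tr0$ef - 0.7) < 1e-12))

  # grid beyond 4 SD warns about extrapolation
  expect_warning(predict_trajectories(f, x_levels = 5), "extrapolat")
})
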