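# small decomposition problem shared across the MCMC tests
pv_fixture <- function(n = 300, seed = 51, psi = 0.25) {
  tp <- true_params(psi_true = psi)
  cc <- cohort_config(n_subjects = n, seed = seed, complete_fraction = 1)
  tb <- preprocess_cohort(generate_cohort(cc, tp))
  list(table = tb, truth = tp,
       spec = decomposition_spec(drop = c("race", "ethnicity")))
}

test_that("Gibbs chains are seed-deterministic and agree with ML under
          diffuse priors", {
  fx <- pv_fixture(n = 350, seed = 52)
  mc <- mcmc_config(iterations = 800, seed = 99)
  ch1 <- gibbs_decomposition(fx$table, fx$spec, mc)
  ch2 <- gibbs_decomposition(fx$table, fx$spec, mc)
  expect_identical(ch1$chains[[1]]$params, ch2$chains[[1]]$params)

  # posterior means of coefficients within 2 posterior SDs of ML
  ml <- ch1$ml
  ret <- ch1$retained
  post <- do.call(rbind, lapply(ch1$chains, function(c) c$params[ret, ]))
  for (nm in names(ml$beta)) {
    expect_lt(abs(mean(post[, nm]) - ml$beta[[nm]]), 2 * sd(post[, nm]))
  }
  # theta wanders only within its tight prior
  expect_lt(abs(mean(post[, "theta"]) - 0.161), 0.02)
})

test_that("coefficient draws stay centred on the FIML solution when
          predictors are missing", {
  tp <- true_params()
  cc <- cohort_config(n_subjects = 500, seed = 58)
  tb <- preprocess_cohort(apply_missingness(generate_cohort(cc, tp), cc))
  sp <- decomposition_spec(drop = c("race", "ethnicity"))
  ch <- suppressWarnings(
    gibbs_decomposition(tb, sp, mcmc_config(iterations = 900, seed = 13)))
  ml <- ch$ml
  post <- do.call(rbind, lapply(ch$chains,
                                function(c) c$params[ch$retained, ]))
  for (nm in names(ml$beta)) {
    expect_lt(abs(mean(post[, nm]) - ml$beta[[nm]]),
              3 * sd(post[, nm]) + 1e-8)
  }
})

test_that("a near-degenerate error-variance prior pins theta at its mean", {
  fx <- pv_fixture(n = 200, seed = 53)
  mc <- mcmc_config(iterations = 500, seed = 3, prior_theta_var = 1e-10)
  ch <- gibbs_decomposition(fx$table, fx$spec, mc)
  th <- ch$chains[[1]]$params[ch$retained, "theta"]
  expect_lt(sd(th), 0.01)
  expect_lt(abs(mean(th) - 0.161), 0.005)
})

test_that("with variances fixed at truth the Gibbs posterior mean of the
          coefficients matches the marginal GLS value", {
  fx <- pv_fixture(n = 250, seed = 54)
  sp <- fx$spec
  mc <- mcmc_config(iterations = 6000, seed = 7, n_chains = 1)
  ch <- gibbs_decomposition(fx$table, sp, mc, fix_theta = TRUE,
                            fix_psi = TRUE)
  # marginalising the latent reserve: mem ~ N(X b, psi + theta), so the
  # posterior mean of b under a flat-ish prior is the OLS/GLS solution
  X <- cbind(1, as.matrix(fx$table[sp$predictors]))
  y <- fx$table$mem_t0
  b_gls <- qr.solve(X, y)
  post <- colMeans(ch$chains[[1]]$params[ch$retained, seq_len(ncol(X))])
  expect_equal(unname(post), unname(b_gls), tolerance = 2e-2)
})

test_that("the potential scale reduction factor separates mixed from
          unmixed chains", {
  expect_equal(psrf(list(rep(1, 100), rep(1, 100))), 1)
  set.seed(11)
  expect_lt(psrf(list(rnorm(10000), rnorm(10000))), 1.02)
  expect_gte(psrf(list(rnorm(10000), rnorm(10000))), 0.99)
  expect_gt(psrf(list(rnorm(2000), rnorm(2000, 5))), 1.1)
  # split-chain mode detects a trend within one chain
  drift <- seq(0, 5, length.out = 2000) + rnorm(2000, 0, 0.1)
  expect_gt(psrf(list(drift, drift), split = TRUE), 1.1)
  expect_error(psrf(list(rnorm(100))), "2 chains")
})

test_that("likelihood-ratio discrepancy of a dataset against its own
          saturated moments is zero", {
  x <- mvn_toy(60, c(0, 1), matrix(c(1, 0.3, 0.3, 1), 2), seed = 4)
  sat <- em_saturated(x)
  expect_equal(reservemed:::lr_discrepancy(x, sat), 0, tolerance = 1e-6)
})

test_that("posterior predictive p-value is moderate for well-specified data
          and extreme under gross misspecification", {
  fx <- pv_fixture(n = 300, seed = 55)
  mc <- mcmc_config(iterations = 600, seed = 5)
  ch <- gibbs_decomposition(fx$table, fx$spec, mc)
  p_ok <- ppp(ch, n_draws = 80, seed = 1)
  expect_gt(p_ok, 0.05)
  expect_lt(p_ok, 0.95)

  # gross misspecification: the error-variance prior pins theta far above
  # the true memory noise, so the implied residual variance cannot shrink
  # to the observed one (psi is bounded below by zero)
  tb_bad <- fx$table
  set.seed(77)
  X <- as.matrix(tb_bad[fx$spec$predictors])
  tb_bad$mem_t0 <- drop(scale(X[, "abeta_ratio"])) * 0.5 +
    rnorm(nrow(tb_bad), 0, 0.05)
  mc2 <- mcmc_config(iterations = 600, seed = 6, prior_theta_var = 1e-8,
                     prior_theta_mean = 0.5)
  # the ML starting fit legitimately clips psi at the boundary here
  ch_bad <- suppressWarnings(gibbs_decomposition(tb_bad, fx$spec, mc2))
  suppressWarnings(p_bad <- ppp(ch_bad, n_draws = 40, seed = 2))
  expect_lt(p_bad, 0.05)
})

test_that("plausible values have the documented shape, reproduce the ML
          factor scores on average, and decompose variance correctly", {
  fx <- pv_fixture(n = 400, seed = 56)
  mc <- mcmc_config(iterations = 1200, seed = 21)
  ch <- gibbs_decomposition(fx$table, fx$spec, mc)
  pv <- draw_plausible_values(ch, M = 30)
  expect_equal(dim(pv$values), c(400L, 30L))
  expect_equal(colnames(pv$values), paste0("im", 1:30))
  expect_true(all(pv$psrf < 1.1))

  # M = 1 returns exactly one stored latent vector
  pv1 <- draw_plausible_values(ch, M = 1)
  k <- pv1$retained_row[1]; cidx <- pv1$chain[1]
  expect_equal(unname(pv1$values[, 1]),
               unname(ch$chains[[cidx]]$memr[k, ]))

  # mean over many draws approximates the regression factor score
  pv200 <- draw_plausible_values(ch, M = 200)
  sc <- factor_scores(ch$ml, fx$table)
  expect_gt(cor(rowMeans(pv200$values), sc), 0.99)

  # across-subject variance ~ psi; within-subject across-imputation
  # variance ~ psi*theta/(psi+theta)
  expect_lt(abs(var(as.vector(pv200$values)) - fx$truth$psi_true),
            0.15 * fx$truth$psi_true)
  within <- mean(apply(pv200$values, 1, var))
  cond_var <- fx$truth$psi_true * fx$truth$theta_true /
    (fx$truth$psi_true + fx$truth$theta_true)
  expect_lt(abs(within - cond_var), 0.15 * cond_var)

  # requesting more imputations than retained draws errors with the count
  mc_small <- mcmc_config(iterations = 40, seed = 1)
  ch_small <- gibbs_decomposition(fx$table, fx$spec, mc_small)
  expect_error(draw_plausible_values(ch_small, M = 200), "retained draws")
})

test_that("ICC(2,k) matches a direct two-way ANOVA oracle and behaves at the
          extremes", {
  # worked 4 x 3 matrix against independent sums-of-squares computation
  m <- matrix(c(9, 2, 5, 8,
                6, 1, 3, 2,
                8, 4, 6, 8), 4, 3)
  r <- icc2k(m)
  n <- 4; k <- 3
  gm <- mean(m)
  ssr <- k * sum((rowMeans(m) - gm)^2)
  ssc <- n * sum((colMeans(m) - gm)^2)
  sst <- sum((m - gm)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1); msc <- ssc / (k - 1); mse <- sse / ((n - 1) * (k - 1))
  expect_equal(r$icc, (msr - mse) / (msr + (msc - mse) / n),
               tolerance = 1e-10)
  expect_true(r$ci[1] <= r$icc && r$icc <= r$ci[2])

  # identical columns, subjects differ: perfect reliability
  v <- cbind(1:10, 1:10, 1:10)
  expect_equal(icc2k(v)$icc, 1)

  # pure noise columns: near-zero reliability
  set.seed(9)
  noise <- matrix(rnorm(1000 * 30), 1000, 30)
  expect_lt(abs(icc2k(noise)$icc), 0.05)

  # constant matrix is undefined
  expect_error(icc2k(matrix(1, 5, 3)), "undefined")
})
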