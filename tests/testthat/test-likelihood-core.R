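test_that("marginal MVN log-likelihood matches the standard normal density and
          per-row oracle under missingness", {
  # single standard-normal observation at zero
  expect_equal(mvn_loglik_missing(matrix(0, 1, 1), mvn_model(0, matrix(1))),
               -0.5 * log(2 * pi), tolerance = 1e-12)

  # a row with all cells missing contributes exactly zero
  m <- mvn_model(c(0, 0), diag(2))
  x <- rbind(c(1, 2), c(NA, NA))
  expect_equal(mvn_loglik_missing(x, m),
               mvn_loglik_missing(rbind(c(1, 2)), m), tolerance = 1e-12)

  # pattern-grouped computation equals explicit per-row sub-matrix extraction
  set.seed(42)
  sg <- crossprod(matrix(rnorm(9), 3)) + diag(3) * 0.5
  mu <- rnorm(3)
  mdl <- mvn_model(mu, sg)
  x <- mvn_toy(7, mu, sg, seed = 9, holes = 5)
  expect_equal(mvn_loglik_missing(x, mdl), oracle_mvn_loglik(x, mu, sg),
               tolerance = 1e-10)

  # complete data: equals the closed-form joint density
  xc <- mvn_toy(20, mu, sg, seed = 10)
  expect_equal(mvn_loglik_missing(xc, mdl), oracle_mvn_loglik(xc, mu, sg),
               tolerance = 1e-10)

  # singular observed sub-block names the pattern
  bad <- mvn_model(c(0, 0), matrix(c(1, 1, 1, 1), 2), labels = c("p", "q"))
  expect_error(mvn_loglik_missing(rbind(c(0, 0)), bad), "p, q")
})

test_that("EM for the saturated model recovers ML moments and maximizes the
          missing-data likelihood", {
  set.seed(7)
  x <- mvn_toy(40, c(1, -1), matrix(c(2, 0.8, 0.8, 1), 2), seed = 3)
  m <- em_saturated(x)
  ctr <- sweep(x, 2, colMeans(x))
  expect_equal(unname(m$mean), unname(colMeans(x)), tolerance = 1e-10)
  expect_equal(unname(m$cov), unname(crossprod(ctr) / nrow(x)),
               tolerance = 1e-10)

  # 5-row bivariate toy with one missing cell vs generic-optimizer oracle
  x5 <- rbind(c(0.3, 1.1), c(-0.5, 0.2), c(1.4, NA), c(0.1, -0.8),
              c(-1.0, 0.5))
  colnames(x5) <- c("v1", "v2")
  m5 <- em_saturated(x5, tol = 1e-12)
  nll <- function(par) {
    sg <- matrix(c(exp(par[3]), par[5], par[5], exp(par[4])), 2)
    if (min(eigen(sg, symmetric = TRUE, only.values = TRUE)$values) <= 1e-10)
      return(1e10)
    -mvn_loglik_missing(x5, mvn_model(par[1:2], sg, c("v1", "v2")))
  }
  st <- c(m5$mean, log(diag(m5$cov)), m5$cov[1, 2])
  op <- optim(st + 0.3, nll, method = "BFGS",
              control = list(maxit = 500, reltol = 1e-14))
  expect_equal(-op$value, attr(m5, "loglik"), tolerance = 1e-6)
  expect_equal(unname(op$par[1:2]), unname(m5$mean), tolerance = 1e-4)

  # likelihood is invariant to duplicating every row
  m5d <- em_saturated(rbind(x5, x5), tol = 1e-12)
  expect_equal(m5d$mean, m5$mean, tolerance = 1e-5)
  expect_equal(m5d$cov, m5$cov, tolerance = 1e-5)

  # monotone non-decreasing log-likelihood trace
  x_h <- mvn_toy(60, c(0, 0, 0), diag(3) + 0.5, seed = 5, holes = 40)
  tr <- attr(em_saturated(x_h), "loglik_trace")
  expect_true(all(diff(tr) > -1e-8))

  # never-observed variable errors by name
  x_bad <- cbind(a = rnorm(5), b = NA_real_)
  expect_error(em_saturated(x_bad), "never observed.*b")
})

test_that("zero-covariance constrained EM is exact ML under the constraint", {
  set.seed(21)
  sg <- matrix(c(1, 0.5, 0.2, 0.5, 1, 0.4, 0.2, 0.4, 1), 3)
  x <- mvn_toy(200, c(0, 0, 0), sg, seed = 21)
  mC <- em_saturated(x, zero_cov = list(c("v1", "v3")), tol = 1e-12)
  expect_equal(mC$cov["v1", "v3"], 0)
  # oracle: direct optimization over the free covariance entries
  nll <- function(par) {
    sg0 <- diag(exp(par[4:6]))
    sg0[1, 2] <- sg0[2, 1] <- par[7]
    sg0[2, 3] <- sg0[3, 2] <- par[8]
    if (min(eigen(sg0, symmetric = TRUE, only.values = TRUE)$values) <= 1e-8)
      return(1e10)
    -mvn_loglik_missing(x, mvn_model(par[1:3], sg0, colnames(x)))
  }
  st <- c(mC$mean, log(diag(mC$cov)), mC$cov[1, 2], mC$cov[2, 3])
  op <- optim(st + 0.1, nll, method = "BFGS",
              control = list(maxit = 1000, reltol = 1e-14))
  expect_equal(attr(mC, "loglik"), -op$value, tolerance = 1e-6)
})

test_that("fit indices reproduce hand-computed RMSEA and CFI and their
          invariances", {
  # perfect fit
  fi0 <- fit_indices(-100, 5, -100, 10, -150, 3, n = 50)
  expect_equal(fi0$chisq, 0)
  expect_equal(fi0$rmsea, 0)
  expect_equal(fi0$cfi, 1)

  # chisq 50, df 10, n 101 -> rmsea sqrt(40/1000) = 0.2; baseline 200/15
  fi <- fit_indices(-125, 5, -100, 15, -200, 0, n = 101)
  expect_equal(fi$chisq, 50)
  expect_equal(fi$df, 10)
  expect_equal(fi$rmsea, 0.2, tolerance = 1e-12)
  expect_equal(fi$cfi, 1 - 40 / 185, tolerance = 1e-12)
  expect_true(fi$rmsea_ci90[1] <= fi$rmsea && fi$rmsea <= fi$rmsea_ci90[2])

  # invariance to adding a constant to every log-likelihood
  fi_shift <- fit_indices(-125 + 7, 5, -100 + 7, 15, -200 + 7, 0, n = 101)
  expect_equal(fi_shift$rmsea, fi$rmsea)
  expect_equal(fi_shift$cfi, fi$cfi)

  # df = 0 is a saturated-model error
  expect_error(fit_indices(-100, 10, -100, 10, -150, 3, n = 50),
               "saturated")
})

test_that("SRMR matches hand computation and is scale-invariant", {
  obs <- mvn_model(c(0, 0), matrix(c(1, 0.5, 0.5, 1), 2), c("a", "b"))
  imp <- mvn_model(c(0, 0), diag(2), c("a", "b"))
  expect_equal(srmr(obs, obs), 0)
  expect_equal(srmr(obs, imp), sqrt(0.25 / 3), tolerance = 1e-12)

  # rescaling both models by a common diagonal leaves SRMR unchanged
  d <- diag(c(2, 0.5))
  obs2 <- mvn_model(c(0, 0), d %*% obs$cov %*% d, c("a", "b"))
  imp2 <- mvn_model(c(0, 0), d %*% imp$cov %*% d, c("a", "b"))
  expect_equal(srmr(obs2, imp2), srmr(obs, imp), tolerance = 1e-12)

  # zero observed variance is a degenerate-scale error
  degen <- mvn_model(c(0, 0), diag(c(0, 1)), c("a", "b"))
  expect_error(srmr(degen, imp), "degenerate")
})

test_that("observed-information SEs match closed forms and flag flat
          directions", {
  # iid normal mean with known variance: SE = sigma/sqrt(n)
  set.seed(2)
  y <- rnorm(40, 1, 2)
  se1 <- observed_info_se(function(th) sum(dnorm(y, th, 2, log = TRUE)), 1)
  expect_equal(unname(se1[1]), 2 / sqrt(40), tolerance = 1e-6)

  # linear regression vs (X'X)^-1 sigma^2
  set.seed(3)
  X <- cbind(1, rnorm(60), rnorm(60))
  beta <- c(0.5, -1, 2)
  y <- drop(X %*% beta) + rnorm(60, 0, 1.5)
  bh <- qr.solve(X, y)
  ll <- function(b) sum(dnorm(y, drop(X %*% b), 1.5, log = TRUE))
  se <- observed_info_se(ll, bh)
  expect_equal(as.numeric(se), sqrt(diag(solve(crossprod(X)) * 1.5^2)),
               tolerance = 1e-5)

  # duplicated parameter (flat direction) is flagged NA, not an error
  ll_flat <- function(b) sum(dnorm(y, drop(X[, 1:2] %*% b[1:2]) +
                                     0 * b[3], 1.5, log = TRUE))
  expect_warning(se_f <- observed_info_se(ll_flat, c(bh[1:2], 0)),
                 "singular")
  expect_true(is.na(se_f[3]))
  expect_false(anyNA(se_f[1:2]))
})
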