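dec_spec <- function(...) decomposition_spec(drop = c("race", "ethnicity"),
                                             ...)

test_that("decomposition coefficients equal OLS on complete data", {
  cc <- cohort_config(n_subjects = 400, seed = 31, complete_fraction = 1)
  tb <- preprocess_cohort(generate_cohort(cc, true_params()))
  sp <- dec_spec()
  fit <- fit_decomposition_ml(tb, sp, se = FALSE)
  ols <- lm(reformulate(sp$predictors, sp$memory), data = tb)
  expect_equal(unname(fit$beta), unname(coef(ols)), tolerance = 1e-8)
  # residual variance bookkeeping: explained + psi + theta = total implied
  sxx <- fit$moments$cov[sp$predictors, sp$predictors]
  b <- fit$beta[-1]
  expect_equal(drop(t(b) %*% sxx %*% b) + fit$psi_hat + fit$theta,
               fit$implied$cov[sp$memory, sp$memory], tolerance = 1e-8)
})

test_that("psi is clipped at zero with a boundary warning when the memory
          residual is below the fixed error variance", {
  set.seed(5)
  n <- 80
  tb <- data.frame(p1 = rnorm(n))
  # near-noiseless: residual variance ~1e-4, far below theta = 0.161
  tb$mem_t0 <- 2 * tb$p1 + rnorm(n, 0, 0.01)
  sp <- decomposition_spec(predictors = "p1")
  expect_warning(fit <- fit_decomposition_ml(tb, sp, se = FALSE),
                 "boundary")
  expect_equal(fit$psi_hat, 0)
  expect_true(fit$boundary)
})

test_that("decomposition recovers generator coefficients and reserve
          variance at n = 5000", {
  tp <- true_params()
  cc <- cohort_config(n_subjects = 5000, seed = 33, complete_fraction = 1)
  tb <- preprocess_cohort(generate_cohort(cc, tp))
  fit <- fit_decomposition_ml(tb, dec_spec())
  # age effects routed through volumes/WMH are carried by those predictors
  truth <- c(age = tp$decomp[["age"]],
             sex = tp$decomp[["sex"]], education = tp$decomp[["education"]],
             apoe4 = tp$decomp[["apoe4"]], hcv_adj = tp$decomp[["hcv"]],
             wbv_adj = tp$decomp[["wbv"]], log_wmh = tp$decomp[["log_wmh"]],
             abeta_ratio = tp$decomp[["abeta_ratio"]],
             ptau_t0 = tp$decomp[["ptau_t0"]],
             fdg_t0 = tp$decomp[["fdg_t0"]])
  est <- fit$beta[names(truth)]
  se <- fit$se[names(truth)]
  expect_true(all(abs(est - truth) < 3 * se))
  expect_lt(abs(fit$psi_hat - tp$psi_true), 0.1 * tp$psi_true)
})

test_that("FIML handles missing predictors and psi_true = 0 drives psi_hat
          to (near) the boundary", {
  tp0 <- true_params(psi_true = 1e-8)
  hits_small <- 0L
  hits_boundary <- 0L
  for (r in 1:20) {
    cc <- cohort_config(n_subjects = 500, seed = 400 + r,
                        complete_fraction = 1)
    tb <- preprocess_cohort(generate_cohort(cc, tp0))
    fit <- suppressWarnings(fit_decomposition_ml(tb, dec_spec(), se = FALSE))
    if (fit$psi_hat < 0.05) hits_small <- hits_small + 1L
    if (fit$boundary) hits_boundary <- hits_boundary + 1L
  }
  expect_gte(hits_small, 19L)       # psi_hat is near zero essentially always
  expect_gte(hits_boundary, 3L)     # the hard clip fires in a real share
})

test_that("factor scores implement the shrinkage formula, including the
          conditional-expectation path for missing predictors", {
  # hand toy: 3 subjects, 1 predictor, stated beta/psi/theta
  fit <- list(beta = c("(Intercept)" = 1, p1 = 2), psi_hat = 0.3,
              theta = 0.1,
              moments = mvn_model(c(0, 0), diag(2), c("p1", "mem")),
              spec = decomposition_spec(predictors = "p1", memory = "mem",
                                        fixed_error_variance = 0.1))
  class(fit) <- "decomposition_fit"
  tb <- data.frame(p1 = c(0, 1, -1), mem = c(1, 4, 0))
  raw <- tb$mem - (1 + 2 * tb$p1)
  expect_equal(factor_scores(fit, tb), 0.75 * raw)

  # psi = theta gives shrinkage one half; theta -> 0 gives the raw residual
  fit$psi_hat <- 0.1
  expect_equal(factor_scores(fit, tb), raw / 2)
  fit$psi_hat <- 0.1; fit$theta <- 1e-12
  expect_equal(factor_scores(fit, tb), raw, tolerance = 1e-6)

  # missing predictor: conditional expectation through the saturated moments
  fit$psi_hat <- 0.3; fit$theta <- 0.1
  fit$moments <- mvn_model(c(0.5, 0), matrix(c(1, 0, 0, 1), 2),
                           c("p1", "mem"))
  tb2 <- data.frame(p1 = c(NA, 1), mem = c(1, 4))
  sc <- factor_scores(fit, tb2)
  expect_equal(sc[1], 0.75 * (1 - (1 + 2 * 0.5)))  # E[p1] = 0.5
  # missing memory gives a missing score
  tb3 <- data.frame(p1 = c(1, 1), mem = c(NA, 4))
  expect_true(is.na(factor_scores(fit, tb3)[1]))
})

test_that("scores are uncorrelated with fitted values on complete data", {
  cc <- cohort_config(n_subjects = 600, seed = 35, complete_fraction = 1)
  tb <- preprocess_cohort(generate_cohort(cc, true_params()))
  sp <- dec_spec()
  fit <- fit_decomposition_ml(tb, sp, se = FALSE)
  sc <- factor_scores(fit, tb)
  fitted_vals <- as.matrix(tb[sp$predictors]) %*% fit$beta[-1]
  expect_lt(abs(cor(sc, fitted_vals)), 1e-8)
})

test_that("standardized estimates rescale by the SD ratio", {
  fit <- list(beta = c("(Intercept)" = 0, p1 = 1), psi_hat = 0.3,
              theta = 0.1,
              moments = mvn_model(c(0, 0), diag(c(4, 16)), c("p1", "mem")),
              spec = decomposition_spec(predictors = "p1", memory = "mem",
                                        fixed_error_variance = 0.1))
  class(fit) <- "decomposition_fit"
  expect_equal(unname(standardize_estimates(fit)), 0.5)  # 1 * 2 / 4
  fit$beta["p1"] <- 0
  expect_equal(unname(standardize_estimates(fit)), 0)
  # pre-standardized data: standardized equals raw
  fit$moments <- mvn_model(c(0, 0), diag(2), c("p1", "mem"))
  fit$beta["p1"] <- 0.37
  expect_equal(unname(standardize_estimates(fit)), 0.37)
})

test_that("zero-covariance constraints add degrees of freedom and yield
          sane fit indices", {
  cc <- cohort_config(n_subjects = 800, seed = 36, complete_fraction = 1)
  tb <- preprocess_cohort(generate_cohort(cc, true_params()))
  # volume residuals and log WMH share only a weak age dependence, so the
  # zero-covariance constraint is nearly satisfied in the generator
  sp <- dec_spec(zero_cov = list(c("hcv_adj", "log_wmh"),
                                 c("wbv_adj", "log_wmh")))
  fit <- fit_decomposition_ml(tb, sp, se = FALSE)
  expect_equal(fit$fit$df, 2L)
  expect_gte(fit$fit$chisq, 0)
  expect_lt(fit$fit$rmsea, 0.06)   # constraints hold in the generator
  expect_gt(fit$fit$cfi, 0.95)
  expect_equal(fit$moments$cov["hcv_adj", "log_wmh"], 0)
  expect_lt(fit$srmr, 0.05)
})

test_that("collinear predictors are rejected with their names", {
  cc <- cohort_config(n_subjects = 300, seed = 37, complete_fraction = 1)
  tb <- preprocess_cohort(generate_cohort(cc, true_params()))
  tb$dup <- tb$age
  sp <- decomposition_spec(predictors = c("age", "dup", "sex"))
  expect_error(fit_decomposition_ml(tb, sp), "collinear")
})
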