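# Shared fixtures: all data are generated in code at test time.

# Analysis table on the generator's own z scale, with the true latent
# moderator, for parameter-recovery experiments (standardization by the
# known population moments removes sample-rescaling noise from the
# truth/estimate comparison).
recovery_table <- function(n, seed, truth = true_params(),
                           complete = TRUE) {
  cc <- cohort_config(n_subjects = n, seed = seed,
                      complete_fraction = 1)
  tb <- generate_cohort(cc, truth)
  if (!complete) tb <- apply_missingness(tb, cc)
  am <- attr(tb, "abeta_moments")
  tb$abeta_ratio <- (tb$abeta_ratio - am[["mean"]]) / am[["sd"]]
  tb$ptau_t1 <- (tb$ptau_t1 - cc$ptau_t1_mean) / cc$ptau_t1_sd
  tb$fdg_t2 <- (tb$fdg_t2 - cc$fdg_t2_mean) / cc$fdg_t2_sd
  tb$memr <- tb$w_true
  tb$age <- tb$age - cc$age_mean
  tb$education <- tb$education - 12
  tb
}

recovery_spec <- function(...) mediation_spec(standardize = FALSE, ...)

# truth vector on the recovery-table scale, named like the fitted
# coefficients (structural paths only)
structural_truth <- function(tp = true_params()) {
  c(a1 = tp$a1, g_tau = tp$g_tau, a1w = tp$a1w,
    a2 = tp$a2, d21 = tp$d21, g_fdg = tp$g_fdg, a2w = tp$a2w,
    d21w = tp$d21w,
    c_I = tp$c_I, b1_I = tp$b1_I, b2_I = tp$b2_I, g_I = tp$g_I,
    cw_I = tp$cw_I, b1w_I = tp$b1w_I, b2w_I = tp$b2w_I,
    c_S = tp$c_S, b1_S = tp$b1_S, b2_S = tp$b2_S, g_S = tp$g_S,
    cw_S = tp$cw_S, b1w_S = tp$b1w_S, b2w_S = tp$b2w_S)
}

# small complete multivariate-normal dataset with optional punched holes
mvn_toy <- function(n, mu, sigma, seed = 1, holes = 0) {
  set.seed(seed)
  x <- rmvn(n, mu, sigma)
  colnames(x) <- paste0("v", seq_along(mu))
  if (holes > 0) {
    idx <- sample(length(x), holes)
    x[idx] <- NA_real_
  }
  x
}

# hand-rolled complete-data MVN log density (oracle, independent of the
# pattern-grouped implementation)
oracle_mvn_loglik <- function(x, mu, sigma) {
  ll <- 0
  for (i in seq_len(nrow(x))) {
    o <- which(!is.na(x[i, ]))
    if (!length(o)) next
    xo <- x[i, o]
    mo <- mu[o]
    So <- sigma[o, o, drop = FALSE]
    k <- length(o)
    ll <- ll - 0.5 * (k * log(2 * pi) + determinant(So)$modulus[1] +
                        drop(t(xo - mo) %*% solve(So) %*% (xo - mo)))
  }
  ll
}

# a mediation fit with arbitrary hand-set path coefficients
fake_fit <- function(coef) {
  structure(list(coef = coef, spec = recovery_spec()),
            class = "mediation_fit")
}

random_paths <- function(seed) {
  set.seed(seed)
  v <- rnorm(22, 0, 0.3)
  names(v) <- c("a1", "g_tau", "a1w", "a2", "d21", "g_fdg", "a2w", "d21w",
                "c_I", "b1_I", "b2_I", "g_I", "cw_I", "b1w_I", "b2w_I",
                "c_S", "b1_S", "b2_S", "g_S", "cw_S", "b1w_S", "b2w_S")
  v
}
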