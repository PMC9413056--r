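#' Ground-truth parameters of the full structural model
#'
#' Defaults calibrate a generative model whose recursive structure mirrors the
#' analysis pipeline: a memory composite decomposed into demographic and
#' brain-integrity components plus a latent residual reserve (MEMR), an
#' amyloid -> tau -> FDG-metabolism cascade moderated by the standardized
#' reserve, and a latent linear growth model for executive function (EF).
#'
#' Structural coefficients are expressed on z-score scales: amyloid ratio,
#' tau and FDG enter as z-scores of their raw marginals, and the moderator is
#' the latent reserve divided by its true standard deviation, so paths are
#' per-SD effects.  The default interaction structure has a single active
#' moderated path (`a2w < 0`, amyloid-by-reserve on FDG), which produces the
#' crossover pattern in which higher reserve predicts lower metabolism at low
#' amyloid pathology but higher metabolism (and better downstream EF) at high
#' amyloid pathology.
#'
#' @param ... named overrides of any default component.
#' @return list of class `true_params`.
#' @export
true_params <- function(...) {
  p <- list(
    # decomposition: memory composite units per raw predictor unit
    decomp = c(age = -0.02, sex = -0.15, education = 0.04, apoe4 = -0.15,
               race = 0, ethnicity = 0,
               hcv = 2.2e-4, wbv = 1.5e-6, log_wmh = -0.08,
               abeta_ratio = 2.5, ptau_t0 = -0.008, fdg_t0 = 1.0),
    mem_mean = 0.31,          # marginal mean of the memory composite
    psi_true = 0.25,          # latent reserve variance
    theta_true = 0.161,       # memory measurement-error variance
    # structural paths (z-scored biomarkers, standardized reserve w)
    a1 = -0.33, a2 = 0.27, d21 = -0.20,
    b1_I = -0.10, b1_S = -0.010,
    b2_I = 0.40, b2_S = 0.050,
    c_I = 0.20, c_S = 0.020,
    g_tau = 0, g_fdg = 0, g_I = 0.12, g_S = 0.005,
    a1w = 0, a2w = -0.15, d21w = 0,
    b1w_I = 0, b1w_S = 0, b2w_I = 0, b2w_S = 0, cw_I = 0, cw_S = 0,
    # covariate effects on the growth factors (raw covariate units)
    cov_age_I = -0.015, cov_sex_I = -0.10, cov_edu_I = 0.03,
    cov_age_S = -0.0015, cov_sex_S = 0, cov_edu_S = 0.001,
    # growth-factor intercepts and residual structure
    mu_I = 0.24, mu_S = -0.05,
    psi_eta = matrix(c(0.25, 0.010, 0.010, 0.004), 2, 2),
    theta_ef = 0.15,
    # equation residual variances (z scale)
    sigma_tau2 = 0.85, sigma_fdg2 = 0.80,
    # T0 companion biomarkers correlate 0.8 with their analysis-time copies
    companion_cor = 0.8
  )
  ov <- list(...)
  unknown <- setdiff(names(ov), names(p))
  if (length(unknown)) {
    stop("true_params: unknown component(s): ", paste(unknown, collapse = ", "))
  }
  p[names(ov)] <- ov
  vs <- c(p$psi_true, p$theta_true, p$sigma_tau2, p$sigma_fdg2)
  if (any(vs <= 0)) stop("true_params: all variances must be positive")
  ev <- eigen(p$psi_eta, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev < -1e-12)) {
    stop("true_params: psi_eta must be positive semi-definite")
  }
  if (p$theta_ef < 0) stop("true_params: theta_ef must be nonnegative")
  class(p) <- "true_params"
  p
}

#' Cohort generation settings
#'
#' Marginal moments default to the descriptive statistics of the ADNI1/GO/2
#' total sample the generator emulates (age 73.10 (7.27) years, 52.9% male,
#' 16.06 (2.75) years of education, the APOE e4 allele distribution, MRI
#' volume and CSF/plasma/PET biomarker marginals), together with the
#' missingness architecture: a subsample with complete mediation biomarkers
#' and monotone logistic dropout of the EF series.
#'
#' @param n_subjects number of subjects.
#' @param seed integer seed; generation is deterministic given
#'   `config` + `truth` + `seed`.
#' @param complete_fraction fraction of subjects with complete amyloid, tau
#'   and FDG mediation biomarkers (default 332/2351).
#' @param dropout list with `intercept` (logit per-visit hazard), `slope_ef`
#'   and `slope_age` coefficients of the monotone EF dropout model.
#' @param ... named overrides of marginal-moment defaults.
#' @return list of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 2351L, seed = 1L,
                          complete_fraction = 332 / 2351,
                          dropout = list(intercept = stats::qlogis(0.08),
                                         slope_ef = -0.3, slope_age = 0.03),
                          ...) {
  cfg <- list(
    n_subjects = as.integer(n_subjects), seed = as.integer(seed),
    complete_fraction = complete_fraction, dropout = dropout,
    age_mean = 73.10, age_sd = 7.27,
    p_male = 0.529, edu_mean = 16.06, edu_sd = 2.75,
    p_apoe4 = c(0.53, 0.37, 0.10),     # 0, 1, 2 alleles
    p_race = 0.058, p_ethnicity = 0.045,
    tiv_mean = 1514968.61, tiv_sd = 164049.96,
    hcv_mean = 6989.14, hcv_sd = 1130.00, hcv_tiv_cor = 0.40,
    wbv_mean = 910437, wbv_sd = 98483.23, wbv_tiv_cor = 0.70,
    hcv_age_slope = -35, wbv_age_slope = -2500,  # mm^3 per year
    wmh_logmean = 1.175, wmh_logsd = 1.114, wmh_age_slope = 0.04,
    abeta_mean = 0.165, abeta_apoe_slope = -0.022, abeta_sd = 0.055,
    ptau_t1_mean = 18.59, ptau_t1_sd = 11.56,
    ptau_t0_mean = 18.48, ptau_t0_sd = 12.32,
    fdg_t2_mean = 1.21, fdg_t2_sd = 0.17,
    fdg_t0_mean = 1.23, fdg_t0_sd = 0.15,
    ef_times = 0:7,
    # per-variable missingness among subjects outside the complete-biomarker
    # subsample (decomposition-stage predictors)
    predictor_missing = c(hcv = 0.34, wbv = 0.34, tiv = 0.34, wmh = 0.39,
                          ptau_t0 = 0.60, fdg_t0 = 0.55),
    mediation_missing = c(abeta_ratio = 0.55, ptau_t1 = 0.40, fdg_t2 = 0.45)
  )
  ov <- list(...)
  unknown <- setdiff(names(ov), names(cfg))
  if (length(unknown)) {
    stop("cohort_config: unknown option(s): ", paste(unknown, collapse = ", "))
  }
  cfg[names(ov)] <- ov
  if (cfg$n_subjects < 2L) stop("cohort_config: n_subjects must be >= 2")
  if (cfg$complete_fraction <= 0 || cfg$complete_fraction > 1) {
    stop("cohort_config: complete_fraction must be in (0, 1]")
  }
  class(cfg) <- "cohort_config"
  cfg
}

#' Generate a synthetic cohort from known ground truth
#'
#' Draws a complete (no missingness) wide-format cohort table from the
#' recursive structural model in `truth`, with marginal moments from
#' `config`.  Hidden truth columns (`memr_true`, `w_true`, `eta_i_true`,
#' `eta_s_true`) carry the latent reserve and growth factors for parameter
#' recovery studies; estimation functions never consume them.
#'
#' @param config a [cohort_config()].
#' @param truth a [true_params()].
#' @return data frame of class `cohort_table`, one row per subject.
#' @export
generate_cohort <- function(config = cohort_config(), truth = true_params()) {
  stopifnot(inherits(config, "cohort_config"), inherits(truth, "true_params"))
  set.seed(config$seed)
  n <- config$n_subjects

  age <- stats::rnorm(n, config$age_mean, config$age_sd)
  sex <- stats::rbinom(n, 1L, config$p_male)
  education <- stats::rnorm(n, config$edu_mean, config$edu_sd)
  apoe4 <- sample(0:2, n, replace = TRUE, prob = config$p_apoe4)
  race <- stats::rbinom(n, 1L, config$p_race)
  ethnicity <- stats::rbinom(n, 1L, config$p_ethnicity)

  age_c <- age - config$age_mean
  tiv <- stats::rnorm(n, config$tiv_mean, config$tiv_sd)
  b_hcv <- config$hcv_tiv_cor * config$hcv_sd / config$tiv_sd
  hcv_res <- stats::rnorm(n, 0, config$hcv_sd * sqrt(1 - config$hcv_tiv_cor^2))
  hcv <- config$hcv_mean + b_hcv * (tiv - config$tiv_mean) +
    config$hcv_age_slope * age_c + hcv_res
  b_wbv <- config$wbv_tiv_cor * config$wbv_sd / config$tiv_sd
  wbv_res <- stats::rnorm(n, 0, config$wbv_sd * sqrt(1 - config$wbv_tiv_cor^2))
  wbv <- config$wbv_mean + b_wbv * (tiv - config$tiv_mean) +
    config$wbv_age_slope * age_c + wbv_res
  wmh <- exp(stats::rnorm(n, config$wmh_logmean + config$wmh_age_slope * age_c,
                          config$wmh_logsd))

  # amyloid: APOE4-dependent mean; lower ratio = more pathology
  abeta_ratio <- config$abeta_mean + config$abeta_apoe_slope * apoe4 +
    stats::rnorm(n, 0, config$abeta_sd)
  mu_a <- config$abeta_mean + config$abeta_apoe_slope *
    sum((0:2) * config$p_apoe4)
  sd_a <- sqrt(config$abeta_sd^2 + config$abeta_apoe_slope^2 *
                 (sum((0:2)^2 * config$p_apoe4) -
                    sum((0:2) * config$p_apoe4)^2))
  x <- (abeta_ratio - mu_a) / sd_a

  # latent reserve: w is the unit-variance moderator, memr its raw-scale copy
  w <- stats::rnorm(n)
  memr <- sqrt(truth$psi_true) * w

  # tau equation (T1 analysis-time measurement) on the z scale
  m1 <- truth$a1 * x + truth$g_tau * w + truth$a1w * x * w +
    stats::rnorm(n, 0, sqrt(truth$sigma_tau2))
  ptau_t1 <- config$ptau_t1_mean + config$ptau_t1_sd * m1
  rho <- truth$companion_cor
  m1_t0 <- rho * m1 + sqrt(1 - rho^2) * stats::rnorm(n)
  ptau_t0 <- config$ptau_t0_mean + config$ptau_t0_sd * m1_t0

  # FDG equation (T2), including the amyloid-by-reserve moderation
  m2 <- truth$a2 * x + truth$d21 * m1 + truth$g_fdg * w +
    truth$a2w * x * w + truth$d21w * m1 * w +
    stats::rnorm(n, 0, sqrt(truth$sigma_fdg2))
  fdg_t2 <- config$fdg_t2_mean + config$fdg_t2_sd * m2
  m2_t0 <- rho * m2 + sqrt(1 - rho^2) * stats::rnorm(n)
  fdg_t0 <- config$fdg_t0_mean + config$fdg_t0_sd * m2_t0

  # memory composite: decomposition linear predictor + reserve + error
  bd <- truth$decomp
  hcv_dev <- hcv - (config$hcv_mean + b_hcv * (tiv - config$tiv_mean))
  wbv_dev <- wbv - (config$wbv_mean + b_wbv * (tiv - config$tiv_mean))
  lp <- bd["age"] * age_c + bd["sex"] * sex +
    bd["education"] * (education - config$edu_mean) +
    bd["apoe4"] * apoe4 + bd["race"] * race + bd["ethnicity"] * ethnicity +
    bd["hcv"] * hcv_dev + bd["wbv"] * wbv_dev +
    bd["log_wmh"] * (log(wmh) - config$wmh_logmean) +
    bd["abeta_ratio"] * (abeta_ratio - mu_a) +
    bd["ptau_t0"] * (ptau_t0 - config$ptau_t0_mean) +
    bd["fdg_t0"] * (fdg_t0 - config$fdg_t0_mean)
  mem_t0 <- truth$mem_mean + lp + memr +
    stats::rnorm(n, 0, sqrt(truth$theta_true))

  # growth factors and the EF series (intercept centered at T3)
  edu_c <- education - 12
  eta_lin_i <- truth$mu_I + truth$c_I * x + truth$b1_I * m1 +
    truth$b2_I * m2 + truth$g_I * w + truth$cw_I * x * w +
    truth$b1w_I * m1 * w + truth$b2w_I * m2 * w +
    truth$cov_age_I * age_c + truth$cov_sex_I * sex + truth$cov_edu_I * edu_c
  eta_lin_s <- truth$mu_S + truth$c_S * x + truth$b1_S * m1 +
    truth$b2_S * m2 + truth$g_S * w + truth$cw_S * x * w +
    truth$b1w_S * m1 * w + truth$b2w_S * m2 * w +
    truth$cov_age_S * age_c + truth$cov_sex_S * sex + truth$cov_edu_S * edu_c
  u <- rmvn(n, c(0, 0), truth$psi_eta)
  eta_i <- eta_lin_i + u[, 1L]
  eta_s <- eta_lin_s + u[, 2L]
  times <- config$ef_times
  ef <- sapply(times, function(t) {
    eta_i + (t - 3) * eta_s + stats::rnorm(n, 0, sqrt(truth$theta_ef))
  })
  colnames(ef) <- paste0("ef_t", times)

  out <- data.frame(
    id = seq_len(n), age = age, sex = sex, education = education,
    apoe4 = apoe4, race = race, ethnicity = ethnicity,
    hcv = hcv, wbv = wbv, wmh = wmh, tiv = tiv,
    abeta_ratio = abeta_ratio, ptau_t0 = ptau_t0, ptau_t1 = ptau_t1,
    fdg_t0 = fdg_t0, fdg_t2 = fdg_t2, mem_t0 = mem_t0, ef,
    memr_true = memr, w_true = w, eta_i_true = eta_i, eta_s_true = eta_s
  )
  attr(out, "abeta_moments") <- c(mean = mu_a, sd = sd_a)
  class(out) <- c("cohort_table", "data.frame")
  out
}

#' Impose the study missingness structure on a complete cohort
#'
#' A random subsample of the configured fraction keeps complete mediation
#' biomarkers (amyloid ratio, T1 tau, T2 FDG); the remaining subjects lose at
#' least one of them.  Decomposition-stage predictors are missing at the
#' configured per-variable rates outside the complete subsample.  The EF
#' series follows monotone dropout with a per-visit logistic hazard in the
#' previous EF value and baseline age.
#'
#' @param table a complete [generate_cohort()] table (no missing cells).
#' @param config the [cohort_config()] used to generate it.
#' @return the table with `NA` missingness imposed.
#' @export
apply_missingness <- function(table, config) {
  med_vars <- c("abeta_ratio", "ptau_t1", "fdg_t2")
  ef_cols <- paste0("ef_t", config$ef_times)
  if (anyNA(table[c(med_vars, ef_cols)])) {
    stop("apply_missingness: table already has missingness flags set")
  }
  if (config$complete_fraction <= 0 || config$complete_fraction > 1) {
    stop("apply_missingness: complete_fraction must be in (0, 1]")
  }
  set.seed(derive_seed(config$seed, 2L))
  n <- nrow(table)
  n_complete <- round(config$complete_fraction * n)
  complete_idx <- sample.int(n, n_complete)
  incomplete <- setdiff(seq_len(n), complete_idx)

  for (v in med_vars) {
    rate <- config$mediation_missing[[v]]
    drop <- incomplete[stats::runif(length(incomplete)) < rate]
    table[drop, v] <- NA_real_
  }
  # guarantee the complement really is incomplete on the mediation biomarkers
  still <- incomplete[!is.na(table$abeta_ratio[incomplete]) &
                        !is.na(table$ptau_t1[incomplete]) &
                        !is.na(table$fdg_t2[incomplete])]
  if (length(still)) {
    pick <- med_vars[sample.int(3L, length(still), replace = TRUE)]
    for (v in med_vars) table[still[pick == v], v] <- NA_real_
  }
  pm <- config$predictor_missing
  # volumes are acquired together: one MRI-missing indicator for hcv/wbv/tiv
  mri_miss <- incomplete[stats::runif(length(incomplete)) < pm[["hcv"]]]
  table[mri_miss, c("hcv", "wbv", "tiv")] <- NA_real_
  for (v in c("wmh", "ptau_t0", "fdg_t0")) {
    drop <- incomplete[stats::runif(length(incomplete)) < pm[[v]]]
    table[drop, v] <- NA_real_
  }

  # monotone EF dropout: MAR through the previous observed EF value
  dz <- config$dropout
  age_c <- table$age - config$age_mean
  active <- rep(TRUE, n)
  for (j in seq_along(ef_cols)[-1L]) {
    prev <- table[[ef_cols[j - 1L]]]
    eta <- dz$intercept + dz$slope_ef * ifelse(active, prev, 0) +
      dz$slope_age * age_c
    p_drop <- if (is.finite(dz$intercept)) stats::plogis(eta) else
      rep(0, n)
    gone <- active & (stats::runif(n) < p_drop)
    active <- active & !gone
    table[!active, ef_cols[j]] <- NA_real_
  }
  table
}

#' Preprocess a cohort table for analysis
#'
#' Applies the standard transformations: natural-log white-matter
#' hyperintensity volume, head-size correction of hippocampal and whole-brain
#' volumes (residuals from a regression on total intracranial volume),
#' standardization of the EF series by the T0 mean and SD of the analysis
#' sample, centering of education on 12 years and age on the cohort mean,
#' and optional z-scoring of the biomarkers.  A provenance attribute guards
#' against double application.
#'
#' @param table a cohort table (raw scale).
#' @param options list; any of `log_wmh`, `adjust_volumes`, `standardize_ef`,
#'   `center_education` (constant), `center_age` (constant), `z_biomarkers`.
#' @return the transformed table with a `preprocessed` attribute recording
#'   the transformations and the moments used.
#' @export
preprocess_cohort <- function(table, options = list()) {
  if (!is.null(attr(table, "preprocessed"))) {
    stop("preprocess_cohort: table is already preprocessed (provenance flag)")
  }
  opt <- utils::modifyList(
    list(log_wmh = TRUE, adjust_volumes = TRUE, standardize_ef = TRUE,
         center_education = 12, center_age = 73.10, z_biomarkers = FALSE),
    options)
  prov <- list(options = opt)

  if (opt$log_wmh && "wmh" %in% names(table)) {
    bad <- which(!is.na(table$wmh) & table$wmh <= 0)
    if (length(bad)) {
      stop("preprocess_cohort: wmh <= 0 in row(s) ",
           paste(utils::head(bad, 10L), collapse = ", "))
    }
    table$log_wmh <- log(table$wmh)
  }
  if (opt$adjust_volumes && all(c("hcv", "wbv", "tiv") %in% names(table))) {
    for (v in c("hcv", "wbv")) {
      ok <- !is.na(table[[v]]) & !is.na(table$tiv)
      fit <- stats::lm.fit(cbind(1, table$tiv[ok]), table[[v]][ok])
      adj <- rep(NA_real_, nrow(table))
      adj[ok] <- fit$residuals
      table[[paste0(v, "_adj")]] <- adj
      prov[[paste0(v, "_tiv_coef")]] <- fit$coefficients
    }
  }
  ef_cols <- grep("^ef_t[0-9]+$", names(table), value = TRUE)
  if (opt$standardize_ef && length(ef_cols)) {
    m0 <- mean(table$ef_t0, na.rm = TRUE)
    s0 <- stats::sd(table$ef_t0, na.rm = TRUE)
    for (v in ef_cols) table[[v]] <- (table[[v]] - m0) / s0
    prov$ef_t0_moments <- c(mean = m0, sd = s0)
  }
  if (!is.null(opt$center_education)) {
    table$education <- table$education - opt$center_education
  }
  if (!is.null(opt$center_age)) {
    table$age <- table$age - opt$center_age
  }
  if (opt$z_biomarkers) {
    zv <- intersect(c("abeta_ratio", "ptau_t0", "ptau_t1", "fdg_t0", "fdg_t2"),
                    names(table))
    prov$biomarker_moments <- list()
    for (v in zv) {
      m <- mean(table[[v]], na.rm = TRUE)
      s <- stats::sd(table[[v]], na.rm = TRUE)
      table[[v]] <- (table[[v]] - m) / s
      prov$biomarker_moments[[v]] <- c(mean = m, sd = s)
    }
  }
  attr(table, "preprocessed") <- prov
  table
}
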