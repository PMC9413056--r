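# Exact moments of the generative structural model.
#
# Every generated variable is a polynomial in independent basis variables
# (Gaussian shocks plus the Bernoulli sex indicator), so means and
# covariances follow exactly from per-variable moments of monomials
# (Isserlis-type bookkeeping).  Used to check the simulated covariance
# structure against algebra rather than against another simulation.

poly_const <- function(c) if (c == 0) list() else
  list(list(c = c, pow = integer(0)))

poly_var <- function(name) list(list(c = 1, pow = stats::setNames(1L, name)))

pow_key <- function(pow) {
  if (!length(pow)) return("")
  pow <- pow[order(names(pow))]
  paste(names(pow), pow, sep = "^", collapse = "*")
}

poly_collapse <- function(p) {
  if (!length(p)) return(list())
  keys <- vapply(p, function(t) pow_key(t$pow), character(1))
  out <- list()
  for (k in unique(keys)) {
    terms <- p[keys == k]
    c_sum <- sum(vapply(terms, `[[`, numeric(1), "c"))
    if (abs(c_sum) > 0) out[[length(out) + 1L]] <-
        list(c = c_sum, pow = terms[[1L]]$pow)
  }
  out
}

poly_add <- function(...) poly_collapse(do.call(c, list(...)))

poly_scale <- function(p, s) {
  if (s == 0) return(list())
  lapply(p, function(t) list(c = t$c * s, pow = t$pow))
}

poly_mul <- function(p1, p2) {
  if (!length(p1) || !length(p2)) return(list())
  out <- list()
  for (t1 in p1) for (t2 in p2) {
    pow <- t1$pow
    for (nm in names(t2$pow)) {
      pow[nm] <- (if (nm %in% names(pow)) pow[nm] else 0L) + t2$pow[nm]
    }
    out[[length(out) + 1L]] <- list(c = t1$c * t2$c, pow = pow)
  }
  poly_collapse(out)
}

poly_mean <- function(p, moment) {
  if (!length(p)) return(0)
  sum(vapply(p, function(t) {
    if (!length(t$pow)) return(t$c)
    t$c * prod(mapply(moment, names(t$pow), t$pow))
  }, numeric(1)))
}

normal_moment <- function(sd, k) {
  if (k %% 2L == 1L) return(0)
  sd^k * prod(seq(k - 1L, 1L, by = -2L))
}

#' Model-implied moments of the mediation-stage variables
#'
#' Exact means and covariances of (z-scale tau, z-scale FDG, EF at each
#' visit) under the generative model, computed by symbolic expansion over the
#' independent shocks.  The latent growth factors' moments are returned as
#' well.
#'
#' @param truth a [true_params()].
#' @param config a [cohort_config()] (supplies covariate marginals).
#' @return list with `mean`, `cov`, `labels` for (m1, m2, ef_t*) and a
#'   `growth` block for the latent intercept/slope.
#' @export
implied_growth_moments <- function(truth, config = cohort_config()) {
  L <- tryCatch(t(chol(truth$psi_eta)), error = function(e) {
    e <- eigen(truth$psi_eta, symmetric = TRUE)
    e$vectors %*% diag(sqrt(pmax(e$values, 0)), 2)
  })
  moment <- function(name, k) {
    switch(name,
      x = , w = , zI = , zS = normal_moment(1, k),
      e1 = normal_moment(sqrt(truth$sigma_tau2), k),
      e2 = normal_moment(sqrt(truth$sigma_fdg2), k),
      age = normal_moment(config$age_sd, k),
      edu = normal_moment(config$edu_sd, k),
      sex = config$p_male,
      if (startsWith(name, "eps")) normal_moment(sqrt(truth$theta_ef), k)
      else stop("unknown basis variable: ", name))
  }
  x <- poly_var("x"); w <- poly_var("w")
  xw <- poly_mul(x, w)
  m1 <- poly_add(poly_scale(x, truth$a1), poly_scale(w, truth$g_tau),
                 poly_scale(xw, truth$a1w), poly_var("e1"))
  m1w <- poly_mul(m1, w)
  m2 <- poly_add(poly_scale(x, truth$a2), poly_scale(m1, truth$d21),
                 poly_scale(w, truth$g_fdg), poly_scale(xw, truth$a2w),
                 poly_scale(m1w, truth$d21w), poly_var("e2"))
  m2w <- poly_mul(m2, w)
  edu_shift <- config$edu_mean - 12
  eta_i <- poly_add(
    poly_const(truth$mu_I), poly_scale(x, truth$c_I),
    poly_scale(m1, truth$b1_I), poly_scale(m2, truth$b2_I),
    poly_scale(w, truth$g_I), poly_scale(xw, truth$cw_I),
    poly_scale(m1w, truth$b1w_I), poly_scale(m2w, truth$b2w_I),
    poly_scale(poly_var("age"), truth$cov_age_I),
    poly_scale(poly_var("sex"), truth$cov_sex_I),
    poly_scale(poly_add(poly_const(edu_shift), poly_var("edu")),
               truth$cov_edu_I),
    poly_scale(poly_var("zI"), L[1, 1]))
  eta_s <- poly_add(
    poly_const(truth$mu_S), poly_scale(x, truth$c_S),
    poly_scale(m1, truth$b1_S), poly_scale(m2, truth$b2_S),
    poly_scale(w, truth$g_S), poly_scale(xw, truth$cw_S),
    poly_scale(m1w, truth$b1w_S), poly_scale(m2w, truth$b2w_S),
    poly_scale(poly_var("age"), truth$cov_age_S),
    poly_scale(poly_var("sex"), truth$cov_sex_S),
    poly_scale(poly_add(poly_const(edu_shift), poly_var("edu")),
               truth$cov_edu_S),
    poly_scale(poly_var("zI"), L[2, 1]), poly_scale(poly_var("zS"), L[2, 2]))

  times <- config$ef_times
  vars <- c(list(m1 = m1, m2 = m2),
            stats::setNames(lapply(times, function(t) {
              poly_add(eta_i, poly_scale(eta_s, t - 3),
                       poly_var(paste0("eps", t)))
            }), paste0("ef_t", times)))
  labels <- names(vars)
  k <- length(vars)
  mu <- vapply(vars, poly_mean, numeric(1), moment = moment)
  covm <- matrix(0, k, k, dimnames = list(labels, labels))
  for (i in seq_len(k)) for (j in i:k) {
    e2m <- poly_mean(poly_mul(vars[[i]], vars[[j]]), moment)
    covm[i, j] <- covm[j, i] <- e2m - mu[i] * mu[j]
  }
  g_mu <- c(I = poly_mean(eta_i, moment), S = poly_mean(eta_s, moment))
  g_cov <- matrix(c(
    poly_mean(poly_mul(eta_i, eta_i), moment) - g_mu[1]^2,
    poly_mean(poly_mul(eta_i, eta_s), moment) - g_mu[1] * g_mu[2],
    poly_mean(poly_mul(eta_i, eta_s), moment) - g_mu[1] * g_mu[2],
    poly_mean(poly_mul(eta_s, eta_s), moment) - g_mu[2]^2), 2, 2,
    dimnames = list(c("I", "S"), c("I", "S")))
  list(mean = mu, cov = covm, labels = labels,
       growth = list(mean = g_mu, cov = g_cov))
}
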