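#' Model-implied multivariate normal moments
#'
#' Container for the mean vector and covariance matrix implied by a model,
#' together with the variable ordering.  All full-information likelihood
#' computations in the package are expressed against this container.
#'
#' @param mean numeric vector of model-implied means.
#' @param cov symmetric positive semi-definite covariance matrix.
#' @param labels variable names; defaults to the column names of `cov`.
#' @return an object of class `mvn_model` with elements `mean`, `cov`,
#'   `labels`.
#' @export
mvn_model <- function(mean, cov, labels = NULL) {
  mean <- as.numeric(mean)
  cov <- as.matrix(cov)
  p <- length(mean)
  labels <- labels %||% colnames(cov) %||% paste0("v", seq_len(p))
  if (nrow(cov) != p || ncol(cov) != p || length(labels) != p) {
    stop("mvn_model: mean, cov and labels dimensions do not match")
  }
  scale <- max(1, max(abs(cov)))
  if (max(abs(cov - t(cov))) > 1e-8 * scale) {
    stop("mvn_model: covariance matrix is not symmetric")
  }
  cov <- (cov + t(cov)) / 2
  ev <- eigen(cov, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10 * scale) {
    stop("mvn_model: covariance matrix is not positive semi-definite")
  }
  dimnames(cov) <- list(labels, labels)
  structure(list(mean = stats::setNames(mean, labels), cov = cov,
                 labels = labels),
            class = "mvn_model")
}

#' @export
print.mvn_model <- function(x, ...) {
  cat("Multivariate normal model for", length(x$labels), "variables:\n")
  print(round(x$mean, 4))
  invisible(x)
}

# group rows of a matrix by missingness pattern; returns list of
# list(rows, obs) with obs an integer index of observed columns
missing_patterns <- function(obs) {
  key <- apply(obs, 1L, function(z) paste(as.integer(z), collapse = ""))
  idx <- split(seq_len(nrow(obs)), key)
  lapply(idx, function(rows) list(rows = rows, obs = which(obs[rows[1L], ])))
}

align_data <- function(data, labels) {
  x <- as.matrix(data)
  if (!is.null(colnames(x)) && all(labels %in% colnames(x))) {
    x <- x[, labels, drop = FALSE]
  } else if (ncol(x) != length(labels)) {
    stop("data columns do not match model labels")
  }
  storage.mode(x) <- "double"
  x
}

#' Multivariate normal log-likelihood under arbitrary missingness
#'
#' Each row contributes the log-density of its observed sub-vector under the
#' marginal normal implied by `model` (the full-information likelihood).
#' Rows with no observed cells contribute zero.
#'
#' @param data matrix or data frame; `NA` marks a missing cell.
#' @param model an [mvn_model()].
#' @return the total log-likelihood (scalar).
#' @export
mvn_loglik_missing <- function(data, model) {
  x <- align_data(data, model$labels)
  obs <- !is.na(x)
  ll <- 0
  for (pat in missing_patterns(obs)) {
    o <- pat$obs
    if (length(o) == 0L) next
    k <- length(o)
    S <- model$cov[o, o, drop = FALSE]
    R <- tryCatch(chol(S), error = function(e) NULL)
    if (is.null(R) || any(diag(R) < 1e-12)) {
      stop(sprintf(
        "singular model covariance for observed pattern {%s}",
        paste(model$labels[o], collapse = ", ")))
    }
    ctr <- sweep(x[pat$rows, o, drop = FALSE], 2L, model$mean[o])
    z <- backsolve(R, t(ctr), transpose = TRUE)
    quad <- colSums(z^2)
    ll <- ll + sum(-0.5 * (k * log(2 * pi) + 2 * sum(log(diag(R))) + quad))
  }
  ll
}

# Iterative conditional fitting for a covariance matrix with zero constraints
# (updates against complete-data sufficient statistics S = ML covariance).
# zero: logical p x p matrix, TRUE where sigma_jk is constrained to 0.
icf_zero_cov <- function(S, zero, sigma0 = NULL, max_sweeps = 100L,
                         tol = 1e-10) {
  p <- ncol(S)
  sigma <- sigma0 %||% {
    s <- S
    s[zero] <- 0
    s
  }
  # ensure a positive definite start
  w <- 1
  while (min(eigen(sigma, symmetric = TRUE, only.values = TRUE)$values) <
         1e-10 * max(diag(S)) && w > 1e-4) {
    w <- w / 2
    s0 <- S
    s0[zero] <- 0
    sigma <- w * s0 + (1 - w) * diag(diag(S), p)
  }
  for (sweep_i in seq_len(max_sweeps)) {
    old <- sigma
    for (j in seq_len(p)) {
      mj <- setdiff(seq_len(p), j)
      free <- mj[!zero[j, mj]]
      A <- sigma[mj, mj, drop = FALSE]
      Ainv <- solve(A)
      if (length(free) == 0L) {
        sigma[j, mj] <- 0
        sigma[mj, j] <- 0
        sigma[j, j] <- S[j, j]
        next
      }
      H <- Ainv[match(free, mj), , drop = FALSE]
      ZtZ <- H %*% S[mj, mj, drop = FALSE] %*% t(H)
      Zty <- H %*% S[mj, j]
      beta <- solve(ZtZ, Zty)
      lambda <- max(S[j, j] - 2 * sum(beta * Zty) +
                      drop(crossprod(beta, ZtZ %*% beta)), 1e-12)
      b <- numeric(length(mj))
      b[match(free, mj)] <- beta
      sigma[j, mj] <- b
      sigma[mj, j] <- b
      sigma[j, j] <- lambda +
        drop(crossprod(beta, Ainv[match(free, mj), match(free, mj),
                                  drop = FALSE] %*% beta))
    }
    if (max(abs(sigma - old)) < tol * max(1, max(abs(S)))) break
  }
  sigma
}

#' EM estimation of the saturated multivariate normal model
#'
#' Maximum-likelihood mean and covariance (ML divisor `n`) for incomplete
#' multivariate normal data, by expectation-maximisation over missingness
#' patterns.  Optionally a set of covariance entries can be constrained to
#' zero, in which case the M-step uses iterative conditional fitting so the
#' constrained estimate is still exact ML.
#'
#' @param data matrix or data frame with `NA` for missing cells.
#' @param tol convergence tolerance on the log-likelihood change.
#' @param max_iter maximum EM iterations; reaching it sets a `converged = FALSE`
#'   flag on the result rather than failing.
#' @param zero_cov optional list of length-2 character or integer vectors
#'   naming variable pairs whose covariance is fixed to zero.
#' @param start optional [mvn_model()] used as starting values (e.g. the
#'   moments a replicate dataset was simulated from), which shortens the EM
#'   path without changing the fixed point.
#' @return an [mvn_model()] with attributes `loglik`, `iterations`,
#'   `converged`, `n`, `loglik_trace`.
#' @export
em_saturated <- function(data, tol = 1e-8, max_iter = 500L, zero_cov = NULL,
                         start = NULL) {
  x <- as.matrix(data)
  storage.mode(x) <- "double"
  labels <- colnames(x) %||% paste0("v", seq_len(ncol(x)))
  colnames(x) <- labels
  n <- nrow(x)
  p <- ncol(x)
  if (n < 2L) stop("em_saturated: need at least 2 rows")
  obs <- !is.na(x)
  nobs <- colSums(obs)
  if (any(nobs == 0L)) {
    stop(sprintf("unidentifiable variable(s) never observed: %s",
                 paste(labels[nobs == 0L], collapse = ", ")))
  }
  if (any(nobs < 2L)) {
    stop(sprintf("variable(s) observed for fewer than 2 rows: %s",
                 paste(labels[nobs < 2L], collapse = ", ")))
  }
  zero <- matrix(FALSE, p, p, dimnames = list(labels, labels))
  if (!is.null(zero_cov)) {
    for (pr in zero_cov) {
      j <- if (is.character(pr)) match(pr, labels) else as.integer(pr)
      if (anyNA(j) || length(j) != 2L) {
        stop("zero_cov entries must be pairs of known variable names")
      }
      zero[j[1L], j[2L]] <- TRUE
      zero[j[2L], j[1L]] <- TRUE
    }
  }
  constrained <- any(zero)

  if (!is.null(start)) {
    mu <- start$mean[labels]
    sigma <- start$cov[labels, labels]
  } else {
    mu <- colMeans(x, na.rm = TRUE)
    v <- apply(x, 2L, stats::var, na.rm = TRUE) * (nobs - 1L) / nobs
    v[!is.finite(v) | v <= 0] <- 1e-6
    sigma <- diag(v, p)
    dimnames(sigma) <- list(labels, labels)
  }

  pats <- missing_patterns(obs)
  complete <- all(obs)
  ll_old <- -Inf
  trace <- numeric(0)
  converged <- FALSE
  iter <- 0L

  repeat {
    iter <- iter + 1L
    if (complete) {
      mu <- colMeans(x)
      ctr <- sweep(x, 2L, mu)
      S <- crossprod(ctr) / n
      sigma <- if (constrained) icf_zero_cov(S, zero, sigma0 = NULL) else S
    } else {
      filled <- x
      cc <- matrix(0, p, p)
      for (pat in pats) {
        o <- pat$obs
        m <- setdiff(seq_len(p), o)
        if (length(m) == 0L) next
        if (length(o) == 0L) {
          filled[pat$rows, ] <- rep(mu, each = length(pat$rows))
          cc[m, m] <- cc[m, m] + length(pat$rows) * sigma[m, m]
          next
        }
        Soo <- sigma[o, o, drop = FALSE]
        B <- sigma[m, o, drop = FALSE] %*% solve(Soo)
        dev <- sweep(x[pat$rows, o, drop = FALSE], 2L, mu[o])
        filled[pat$rows, m] <- rep(mu[m], each = length(pat$rows)) +
          dev %*% t(B)
        cmm <- sigma[m, m, drop = FALSE] - B %*% sigma[o, m, drop = FALSE]
        cc[m, m] <- cc[m, m] + length(pat$rows) * cmm
      }
      mu <- colMeans(filled)
      ctr <- sweep(filled, 2L, mu)
      S <- (crossprod(ctr) + cc) / n
      S <- (S + t(S)) / 2
      sigma <- if (constrained) {
        icf_zero_cov(S, zero, sigma0 = if (iter == 1L) NULL else sigma)
      } else S
    }
    model <- mvn_model(mu, sigma, labels)
    ll <- mvn_loglik_missing(x, model)
    trace <- c(trace, ll)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol) {
      converged <- TRUE
      break
    }
    if (complete && !constrained) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) {
      warning("em_saturated: maximum iterations reached without convergence")
      break
    }
    ll_old <- ll
  }
  attr(model, "loglik") <- ll
  attr(model, "iterations") <- iter
  attr(model, "converged") <- converged
  attr(model, "n") <- n
  attr(model, "loglik_trace") <- trace
  attr(model, "n_constraints") <- sum(zero[upper.tri(zero)])
  model
}

# number of free parameters of a (possibly constrained) saturated MVN model
n_par_saturated <- function(p, n_constraints = 0L) {
  p + p * (p + 1L) / 2L - n_constraints
}
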