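#' Multiple imputation by chained equations
#'
#' Fills missing covariate values by iterated conditional draws: for each
#' incomplete covariate in turn, a regression on all other covariates, the
#' marker score (when complete) and the outcome is fit on the observed rows,
#' model parameters are drawn from their approximate posterior, and the
#' missing cells are replaced by draws from the predictive distribution
#' (Bayesian linear regression for continuous fields, logistic draws for
#' binary fields).  The outcome and marker score are never imputed.
#'
#' @param cohort Cohort data frame; `outcome` must be fully observed.
#' @param m Number of imputed datasets (>= 2; `m = 1` returns the single
#'   completed dataset).
#' @param iterations Chained-equation sweeps per imputation (default 10).
#' @param seed Integer seed; each imputation uses a derived substream.
#' @return List of `m` completed cohorts; observed cells are identical
#'   across them and to the input.
#' @export
impute_chained <- function(cohort, m = 5L, iterations = 10L, seed = 1L) {
  stopifnot(m >= 1L, iterations >= 1L)
  if (anyNA(cohort$outcome)) {
    stop("outcome must be fully observed", call. = FALSE)
  }
  covs <- covariate_columns(cohort)
  incomplete <- covs[vapply(covs, function(v) anyNA(cohort[[v]]), logical(1))]
  if (length(incomplete) == 0L) {
    return(replicate(m, cohort, simplify = FALSE))
  }
  for (v in incomplete) {
    if (all(is.na(cohort[[v]]))) {
      stop(sprintf("covariate '%s' has no observed values to impute from", v),
           call. = FALSE)
    }
  }
  use_marker <- !is.null(cohort$marker_score) && !anyNA(cohort$marker_score)
  predictors <- function(v) {
    c(setdiff(covs, v), if (use_marker) "marker_score", "outcome")
  }
  is_binary <- vapply(incomplete, function(v) {
    all(cohort[[v]][!is.na(cohort[[v]])] %in% c(0, 1))
  }, logical(1))
  names(is_binary) <- incomplete

  lapply(seq_len(m), function(k) {
    set.seed(derive_seed(seed, paste0("mice-", k)))
    comp <- cohort
    # initialize by draws from the observed marginals
    for (v in incomplete) {
      mis <- is.na(comp[[v]])
      comp[[v]][mis] <- sample(comp[[v]][!mis], sum(mis), replace = TRUE)
    }
    for (it in seq_len(iterations)) {
      for (v in incomplete) {
        mis <- is.na(cohort[[v]])
        X <- model.matrix(~ ., data = comp[, predictors(v), drop = FALSE])
        comp[[v]][mis] <- if (is_binary[[v]]) {
          draw_logistic(cohort[[v]][!mis], X[!mis, , drop = FALSE],
                        X[mis, , drop = FALSE])
        } else {
          draw_normal(cohort[[v]][!mis], X[!mis, , drop = FALSE],
                      X[mis, , drop = FALSE])
        }
      }
    }
    comp
  })
}

# Bayesian linear-regression predictive draw: sigma^2 from the scaled
# inverse chi-square, beta from N(betahat, sigma^2 (X'X)^-1), then y from
# N(X beta, sigma).
draw_normal <- function(y_obs, X_obs, X_mis) {
  keep <- usable_columns(X_obs)
  X_obs <- X_obs[, keep, drop = FALSE]
  X_mis <- X_mis[, keep, drop = FALSE]
  qrX <- qr(X_obs)
  betahat <- qr.coef(qrX, y_obs)
  betahat[is.na(betahat)] <- 0
  res <- y_obs - drop(X_obs %*% betahat)
  df <- max(1L, length(y_obs) - qrX$rank)
  sigma2 <- sum(res^2) / rchisq(1L, df)
  R <- qr.R(qrX)[seq_len(qrX$rank), seq_len(qrX$rank), drop = FALSE]
  piv <- qrX$pivot[seq_len(qrX$rank)]
  z <- rnorm(qrX$rank)
  beta <- betahat
  beta[piv] <- beta[piv] + sqrt(sigma2) * backsolve(R, z)
  drop(X_mis %*% beta) + rnorm(nrow(X_mis), 0, sqrt(sigma2))
}

# Logistic draw: beta from N(betahat, vcov), then Bernoulli(plogis(X beta)).
draw_logistic <- function(y_obs, X_obs, X_mis) {
  keep <- usable_columns(X_obs)
  X_obs <- X_obs[, keep, drop = FALSE]
  X_mis <- X_mis[, keep, drop = FALSE]
  fit <- suppressWarnings(
    glm.fit(X_obs, y_obs, family = binomial(), intercept = FALSE)
  )
  betahat <- coef(fit)
  betahat[is.na(betahat)] <- 0
  # approximate posterior covariance from the Fisher information
  w <- fit$weights
  info <- crossprod(X_obs * sqrt(pmax(w, 1e-10)))
  V <- tryCatch(chol2inv(chol(info)), error = function(e) {
    diag(1e-6, ncol(X_obs))
  })
  beta <- betahat + drop(chol(V + diag(1e-12, ncol(V))) %*%
                           rnorm(ncol(X_obs)))
  rbinom(nrow(X_mis), 1L, plogis(drop(X_mis %*% beta)))
}

# Drop constant (non-intercept) columns that would make the design singular.
usable_columns <- function(X) {
  keep <- rep(TRUE, ncol(X))
  for (j in seq_len(ncol(X))) {
    if (colnames(X)[j] != "(Intercept)" && length(unique(X[, j])) == 1L) {
      keep[j] <- FALSE
    }
  }
  keep
}

#' Pool estimates across imputations with Rubin's rules
#'
#' Given per-imputation point estimates \eqn{\hat q_j} and within-imputation
#' variances \eqn{u_j}: pooled estimate \eqn{\bar q}, within-variance
#' \eqn{\bar u}, between-variance \eqn{b = var(\hat q_j)}, total variance
#' \eqn{T = \bar u + (1 + 1/m) b}, classical degrees of freedom
#' \eqn{(m-1)\left(1 + \bar u / ((1+1/m) b)\right)^2} (infinite when
#' b = 0), with t-based 95% CI and two-sided p-value for H0: estimate = 0.
#'
#' @param estimates Numeric vector of per-imputation estimates.
#' @param within_variances Positive per-imputation variances (SE squared).
#' @param conf_level Confidence level (default 0.95).
#' @return Object of class `pooled_estimate` with fields `m`, `q_bar`,
#'   `u_bar`, `b`, `total_variance`, `standard_error`, `df`, `ci_low`,
#'   `ci_high`, `p_value`.
#' @export
rubins_pool <- function(estimates, within_variances, conf_level = 0.95) {
  m <- length(estimates)
  stopifnot(m >= 1L, length(within_variances) == m)
  if (anyNA(estimates) || anyNA(within_variances) ||
      any(within_variances <= 0)) {
    stop("within-imputation variances must be positive and non-missing",
         call. = FALSE)
  }
  q_bar <- mean(estimates)
  u_bar <- mean(within_variances)
  b <- if (m > 1L) var(estimates) else 0
  total <- u_bar + (1 + 1 / m) * b
  df <- if (b > 0) (m - 1) * (1 + u_bar / ((1 + 1 / m) * b))^2 else Inf
  se <- sqrt(total)
  alpha <- 1 - conf_level
  tcrit <- qt(1 - alpha / 2, df)
  p <- 2 * pt(-abs(q_bar / se), df)
  structure(list(m = m, q_bar = q_bar, u_bar = u_bar, b = b,
                 total_variance = total, standard_error = se, df = df,
                 ci_low = q_bar - tcrit * se, ci_high = q_bar + tcrit * se,
                 p_value = p),
            class = "pooled_estimate")
}

#' @export
print.pooled_estimate <- function(x, ...) {
  cat(sprintf(
    "pooled estimate = %.4f (SE %.4f, 95%% CI %.4f to %.4f, p = %.4g)\n  m = %d, within = %.6f, between = %.6f, df = %.1f\n",
    x$q_bar, x$standard_error, x$ci_low, x$ci_high, x$p_value,
    x$m, x$u_bar, x$b, x$df))
  invisible(x)
}
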