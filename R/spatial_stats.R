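# spatial_stats: covariate correlation filtering, Moran's I with a
# permutation null, OLS baseline, and maximum-likelihood spatial-lag
# regression with likelihood-ratio test and AIC.

#' Greedy correlation filter for covariates
#'
#' Scans the variables in the given order and drops any variable whose
#' absolute Pearson correlation with an already-retained variable is at or
#' above the cutoff, so the retained set is mutually below-cutoff.
#'
#' @param X Data frame or matrix of numeric covariates.
#' @param cutoff Absolute correlation threshold (default 0.70).
#' @return Character vector of retained variable names.
#' @export
correlation_filter <- function(X, cutoff = 0.70) {
  X <- as.data.frame(X)
  if (ncol(X) < 2L) stopf("need at least two variables")
  sds <- vapply(X, stats::sd, numeric(1))
  if (any(sds == 0))
    stopf("constant column(s): %s (correlation undefined)",
          paste(names(X)[sds == 0], collapse = ", "))
  retained <- character(0)
  for (v in names(X)) {
    if (!length(retained)) { retained <- v; next }
    r <- abs(stats::cor(X[[v]], X[, retained, drop = FALSE]))
    if (all(r < cutoff)) retained <- c(retained, v)
  }
  retained
}

#' Moran's I with permutation inference
#'
#' Global spatial autocorrelation `I = (n / S0) * sum_ij w_ij z_i z_j /
#' sum_i z_i^2` with `z` the centred values and `S0` the total weight.
#' Significance comes from random relabelling of the values across locations
#' (two-sided), which is reliable at the moderate n of area-level analyses
#' where the analytic null can mislead.
#'
#' @param y Numeric vector (non-constant).
#' @param W A `spatial_weights` object.
#' @param n_perm Number of permutations (default 999).
#' @param seed Seed for the permutation draws (required for reproducibility).
#' @return Object of class `moran_result`: `i_value`, `expected`
#'   (`-1/(n-1)`), `p_perm`, `n_perm`.
#' @export
morans_i <- function(y, W, n_perm = 999, seed = NULL) {
  stopifnot(inherits(W, "spatial_weights"))
  n <- W$n
  if (length(y) != n) stopf("length(y) != number of observations in W")
  z <- y - mean(y)
  denom <- sum(z^2)
  if (denom == 0) stopf("`y` is constant; Moran's I undefined")
  tr <- weights_triplets(W)
  s0 <- sum(tr$w)
  if (s0 == 0) stopf("all spatial weights are zero")
  i_stat <- function(zz) (n / s0) * sum(tr$w * zz[tr$i] * zz[tr$j]) / denom
  i_obs <- i_stat(z)
  perm <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) i_stat(z[sample.int(n)]), numeric(1))
  })
  p_hi <- (1 + sum(perm >= i_obs)) / (n_perm + 1)
  p_lo <- (1 + sum(perm <= i_obs)) / (n_perm + 1)
  structure(list(i_value = i_obs, expected = -1 / (n - 1),
                 p_perm = min(1, 2 * min(p_hi, p_lo)), n_perm = n_perm),
            class = "moran_result")
}

#' @export
print.moran_result <- function(x, ...) {
  cat(sprintf("Moran's I = %.4f (E[I] = %.4f), permutation p = %.4g (%d perms)\n",
              x$i_value, x$expected, x$p_perm, x$n_perm))
  invisible(x)
}

design_matrix <- function(X) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- sprintf("x%d", seq_len(ncol(X)))
  cbind(`(Intercept)` = 1, X)
}

#' Ordinary least squares baseline
#'
#' Least-squares fit of `y` on the covariates (intercept added), exposing the
#' residuals for spatial autocorrelation checks and the Gaussian
#' log-likelihood for comparison with the spatial-lag model.
#'
#' @param y Response vector.
#' @param X Covariate matrix or data frame (no intercept column).
#' @return Object of class `ols_fit`: `coefficients`, `se`, `residuals`,
#'   `fitted`, `sigma2` (ML), `loglik`, `aic`, `n`.
#' @export
fit_ols <- function(y, X) {
  Xd <- design_matrix(X)
  n <- length(y)
  p <- ncol(Xd)
  if (n <= p) stopf("need n > number of parameters")
  qx <- qr(Xd)
  if (qx$rank < p) stopf("design matrix is rank deficient")
  beta <- qr.coef(qx, y)
  res <- qr.resid(qx, y)
  rss <- sum(res^2)
  sigma2_ml <- rss / n
  se <- sqrt(diag(chol2inv(qr.R(qx))) * rss / (n - p))
  ll <- -n / 2 * (log(2 * pi) + log(sigma2_ml) + 1)
  structure(list(coefficients = beta, se = se, residuals = res,
                 fitted = y - res, sigma2 = sigma2_ml, loglik = ll,
                 aic = -2 * ll + 2 * (p + 1), n = n, qr = qx, p = p),
            class = "ols_fit")
}

#' @export
print.ols_fit <- function(x, ...) {
  cat("OLS fit\n")
  print(data.frame(Estimate = x$coefficients, `Std. Error` = x$se,
                   check.names = FALSE))
  cat(sprintf("logLik: %.3f  AIC: %.1f\n", x$loglik, x$aic))
  invisible(x)
}

#' Maximum-likelihood spatial-lag regression
#'
#' Fits `y = rho * W y + X beta + e` by maximizing the concentrated
#' log-likelihood over the spatial autoregressive coefficient `rho`, with the
#' log-determinant `log|I - rho W|` computed from the eigenvalues of the
#' row-standardized weights matrix. `rho` is searched over
#' `(1/lambda_min, 1/lambda_max)` by bounded scalar optimization. Asymptotic
#' standard errors come from the information matrix of `(beta, rho, sigma2)`;
#' the model is compared to OLS with a 1-df likelihood-ratio test and AIC.
#'
#' @param y Response vector.
#' @param X Covariate matrix or data frame (no intercept column).
#' @param W A `spatial_weights` object.
#' @param se Compute asymptotic standard errors (disable in tight
#'   simulation loops).
#' @param optim_tol Tolerance of the 1-D likelihood optimization.
#' @return Object of class `spatial_lag_fit`: `rho`, `coefficients`, `se`,
#'   `z`, `p_value`, `rho_se`, `rho_z`, `rho_p`, `sigma2`, `loglik`,
#'   `lr_stat`, `lr_p`, `aic`, and the nested `ols` fit.
#' @export
fit_spatial_lag <- function(y, X, W, se = TRUE, optim_tol = 1e-8) {
  stopifnot(inherits(W, "spatial_weights"))
  n <- length(y)
  if (n != W$n) stopf("length(y) != number of observations in W")
  Xd <- design_matrix(X)
  p <- ncol(Xd)
  if (n <= p + 2L) stopf("need n > number of parameters")
  ols <- fit_ols(y, X)
  Wm <- weights_matrix(W)
  Wy <- as.vector(Wm %*% y)
  if (all(Wy == 0) && all(Wm == 0)) {
    # degenerate weights: the model collapses to OLS
    fit <- list(rho = 0, coefficients = ols$coefficients, sigma2 = ols$sigma2,
                loglik = ols$loglik)
  } else {
    ev <- eigen(Wm, only.values = TRUE)$values
    if (is.complex(ev)) {
      if (max(abs(Im(ev))) > 1e-8)
        stopf("weights matrix has genuinely complex eigenvalues; use a symmetric neighbour structure")
      ev <- Re(ev)
    }
    lo <- if (min(ev) < 0) 1 / min(ev) + 1e-6 else -1 + 1e-6
    hi <- if (max(ev) > 0) 1 / max(ev) - 1e-6 else 1 - 1e-6
    qx <- ols$qr
    e0 <- ols$residuals
    ed <- qr.resid(qx, Wy)
    conc_ll <- function(rho) {
      u <- e0 - rho * ed
      dets <- 1 - rho * ev
      if (any(dets <= 0)) return(-Inf)
      -n / 2 * (log(2 * pi) + 1) - n / 2 * log(sum(u^2) / n) + sum(log(dets))
    }
    opt <- stats::optimize(conc_ll, c(lo, hi), maximum = TRUE,
                           tol = optim_tol)
    rho <- opt$maximum
    if (!is.finite(opt$objective))
      stopf("spatial-lag likelihood optimization failed to converge (interval %.4f..%.4f)",
            lo, hi)
    beta <- qr.coef(qx, y - rho * Wy)
    u <- e0 - rho * ed
    fit <- list(rho = rho, coefficients = beta, sigma2 = sum(u^2) / n,
                loglik = opt$objective)
  }
  lr_stat <- max(0, 2 * (fit$loglik - ols$loglik))
  out <- list(rho = fit$rho, coefficients = fit$coefficients,
              sigma2 = fit$sigma2, loglik = fit$loglik,
              lr_stat = lr_stat,
              lr_p = stats::pchisq(lr_stat, df = 1, lower.tail = FALSE),
              aic = -2 * fit$loglik + 2 * (p + 2), ols = ols, n = n)
  if (se) {
    info <- lag_information(y, Xd, Wm, fit$rho, fit$coefficients, fit$sigma2)
    vc <- tryCatch(solve(info), error = function(e) NULL)
    if (!is.null(vc)) {
      sds <- sqrt(pmax(0, diag(vc)))
      out$se <- stats::setNames(sds[seq_len(p)], names(fit$coefficients))
      out$z <- fit$coefficients / out$se
      out$p_value <- 2 * stats::pnorm(-abs(out$z))
      out$rho_se <- sds[p + 1L]
      out$rho_z <- fit$rho / out$rho_se
      out$rho_p <- 2 * stats::pnorm(-abs(out$rho_z))
    }
  }
  structure(out, class = "spatial_lag_fit")
}

# Information matrix of the spatial-lag ML estimator, parameter order
# (beta, rho, sigma2); standard asymptotic blocks.
lag_information <- function(y, Xd, Wm, rho, beta, sigma2) {
  n <- length(y)
  p <- ncol(Xd)
  A <- diag(n) - rho * Wm
  C <- Wm %*% solve(A)
  term <- as.vector(C %*% (Xd %*% beta))
  info <- matrix(0, p + 2L, p + 2L)
  info[seq_len(p), seq_len(p)] <- crossprod(Xd) / sigma2
  ibr <- as.vector(crossprod(Xd, term)) / sigma2
  info[seq_len(p), p + 1L] <- ibr
  info[p + 1L, seq_len(p)] <- ibr
  info[p + 1L, p + 1L] <- sum(C * t(C)) + sum(C^2) +
    sum(term^2) / sigma2
  trC <- sum(diag(C))
  info[p + 1L, p + 2L] <- trC / sigma2
  info[p + 2L, p + 1L] <- trC / sigma2
  info[p + 2L, p + 2L] <- n / (2 * sigma2^2)
  info
}

#' @export
print.spatial_lag_fit <- function(x, ...) {
  cat("Spatial-lag model (ML)\n")
  if (!is.null(x$se)) {
    print(data.frame(Estimate = x$coefficients, `Std. Error` = x$se,
                     `z-Value` = x$z, `p-Value` = x$p_value,
                     check.names = FALSE))
    cat(sprintf("Rho: %.5f (se %.5f), LR test value: %.2f, p-value: %.4g\n",
                x$rho, x$rho_se, x$lr_stat, x$lr_p))
  } else {
    cat(sprintf("Rho: %.5f, LR test value: %.2f, p-value: %.4g\n",
                x$rho, x$lr_stat, x$lr_p))
  }
  cat(sprintf("AIC: %.1f (OLS AIC: %.1f)\n", x$aic, x$ols$aic))
  invisible(x)
}

#' Simulate a spatial autoregressive response
#'
#' Draws `y = (I - rho W)^{-1} (X beta + e)` with `e ~ N(0, sigma^2)`,
#' providing ground truth for spatial-lag recovery experiments.
#'
#' @param W A `spatial_weights` object.
#' @param rho Spatial autoregressive coefficient, `|rho| < 1`.
#' @param beta Coefficient vector matching `ncol(X)`.
#' @param sigma Error standard deviation.
#' @param X Design matrix (include an intercept column yourself if wanted).
#' @param seed RNG seed.
#' @return Numeric response vector.
#' @export
simulate_sar <- function(W, rho, beta, sigma, X, seed = NULL) {
  stopifnot(inherits(W, "spatial_weights"))
  if (abs(rho) >= 1) stopf("|rho| must be < 1")
  X <- as.matrix(X)
  if (length(beta) != ncol(X)) stopf("length(beta) != ncol(X)")
  n <- W$n
  eps <- with_seed(seed, stats::rnorm(n, 0, sigma))
  xb <- as.vector(X %*% beta) + eps
  if (rho == 0) return(xb)
  Wm <- weights_matrix(W)
  out <- tryCatch(solve(diag(n) - rho * Wm, xb), error = function(e)
    stopf("(I - rho W) is singular at rho = %g", rho))
  as.vector(out)
}
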