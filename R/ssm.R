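#' Specify a univariate annual-biomass state-space model
#'
#' Observation equation `y_t = x_t + v_t`, `v_t ~ N(0, obs_var_t)` with the
#' per-year observation variances fixed at the squared standard errors of
#' the annual estimates; process equation `x_t = phi x_{t-1} + Z_t beta +
#' w_t`, `w_t ~ N(0, sigma2_proc)`; initial state `x_1 ~ N(y_1, obs_var_1)`
#' (pinned at the first observation, so it contributes no free parameters).
#'
#' @param y centered log-scale annual biomass estimates; `NA` marks gap
#'   years.  The first year must be observed.
#' @param obs_var per-year observation variances (> 0 wherever `y` is
#'   observed).
#' @param Z covariate matrix with one row per year: column 1 the z-scored
#'   trend, optional column 2 a z-scored environmental covariate.  Rows
#'   must be complete.
#' @param years optional integer year labels.
#' @return object of class `ssm_spec`.
#' @export
ssm_spec <- function(y, obs_var, Z, years = NULL) {
  n <- length(y)
  Z <- as.matrix(Z)
  stopifnot(length(obs_var) == n, nrow(Z) == n, !anyNA(Z))
  if (is.na(y[1])) stop("the first year must be observed")
  obs <- !is.na(y)
  if (any(obs_var[obs] <= 0) || any(!is.finite(obs_var[obs])))
    stop("obs_var must be positive and finite wherever y is observed")
  structure(list(y = as.numeric(y), obs_var = as.numeric(obs_var),
                 Z = Z, n = n,
                 years = if (is.null(years)) seq_len(n) else as.integer(years)),
            class = "ssm_spec")
}

#' State-space model parameters
#'
#' @param phi autoregressive coefficient (density dependence when
#'   `phi < 1`; a random walk when `phi = 1` — not constrained).
#' @param beta covariate effects (trend first, optional environmental
#'   covariate second), on the z-score scale.
#' @param sigma2_proc process variance (>= 0).
#' @return object of class `ssm_params`.
#' @export
ssm_params <- function(phi, beta, sigma2_proc) {
  stopifnot(is.finite(phi), all(is.finite(beta)), is.finite(sigma2_proc),
            sigma2_proc >= 0)
  structure(list(phi = phi, beta = as.numeric(beta),
                 sigma2_proc = sigma2_proc), class = "ssm_params")
}

# y with NA encoded as NaN for the C++ kernel
ssm_y_cpp <- function(spec) {
  y <- spec$y
  y[is.na(y)] <- NaN
  y
}

#' Exact Gaussian log-likelihood by Kalman filtering
#'
#' Forward filtering with the data-pinned initial condition; missing years
#' are handled by prediction-only steps.  Returns the sum of the log
#' predictive densities of the observed `y_t` (for `n = 1` this is
#' `-0.5 * log(2 * pi * 2 * obs_var_1)` because the prior is centered at
#' the observation).
#'
#' @param spec an [ssm_spec].
#' @param params an [ssm_params] (its `beta` must match `ncol(spec$Z)`).
#' @return log-likelihood (scalar).
#' @export
kalman_loglik <- function(spec, params) {
  stopifnot(inherits(spec, "ssm_spec"), length(params$beta) == ncol(spec$Z))
  zb <- as.numeric(spec$Z %*% params$beta)
  ll <- .kalman_loglik_cpp(ssm_y_cpp(spec), spec$obs_var, zb,
                           params$phi, params$sigma2_proc)
  if (!is.finite(ll) && ll > 0) stop("non-finite prediction variance")
  ll
}

# smoothed states and lag-one covariances at given parameters
kalman_smooth <- function(spec, params) {
  zb <- as.numeric(spec$Z %*% params$beta)
  .kalman_smoother_cpp(ssm_y_cpp(spec), spec$obs_var, zb,
                       params$phi, params$sigma2_proc)
}

# dispersed random starting values for the multi-start searches
draw_starts <- function(n_starts, k) {
  data.frame(phi = runif(n_starts, -0.9, 0.9),
             matrix(rnorm(n_starts * k), n_starts, k,
                    dimnames = list(NULL, paste0("beta", seq_len(k)))),
             sigma2 = exp(runif(n_starts, log(0.01), log(2))))
}

#' Fit the state-space model by multi-start EM
#'
#' Expectation-maximization with closed-form M-steps from Kalman-smoother
#' sufficient statistics for `(phi, beta, sigma2_proc)`.  The search is
#' repeated from `n_starts` randomized initial parameter sets (dispersed
#' over `phi ~ U(-0.9, 0.9)`, `beta ~ N(0, 1)`,
#' `sigma2_proc ~ logU(0.01, 2)`) plus one data-driven start from the
#' lagged regression of `y`; the best log-likelihood is retained.  The
#' per-iteration log-likelihood trace of the winning start is kept so the
#' EM ascent property can be verified.
#'
#' @param spec an [ssm_spec] with at least 5 observed years.
#' @param n_starts number of random starts (default 100).
#' @param tol relative log-likelihood convergence tolerance (default 1e-8).
#' @param max_iter EM iteration cap per start (default 2000).
#' @param seed integer seed for the start draws.
#' @return object of class `ssm_fit`: `params` ([ssm_params]), `loglik`,
#'   `states` (smoothed means and variances), `trace`, `convergence`
#'   (list with `n_starts`, `best_start`, `iterations`, `converged`,
#'   `boundary`), and the `spec`.
#' @export
fit_em <- function(spec, n_starts = 100, tol = 1e-8, max_iter = 2000,
                   seed = NULL) {
  stopifnot(inherits(spec, "ssm_spec"))
  if (sum(!is.na(spec$y)) < 5) stop("need at least 5 observed years")
  if (!is.null(seed)) set.seed(seed)
  k <- ncol(spec$Z)
  y <- ssm_y_cpp(spec)

  starts <- draw_starts(n_starts, k)
  # data-driven start: OLS of y_t on (y_{t-1}, Z_t)
  yy <- spec$y
  ok <- which(!is.na(yy[-1]) & !is.na(yy[-spec$n])) + 1L
  if (length(ok) > k + 2) {
    Xd <- cbind(yy[ok - 1L], spec$Z[ok, , drop = FALSE])
    cf <- tryCatch(qr.coef(qr(Xd), yy[ok]), error = function(e) NULL)
    if (!is.null(cf) && all(is.finite(cf))) {
      res <- yy[ok] - Xd %*% cf
      starts <- rbind(starts,
                      c(max(min(cf[1], 0.95), -0.95), cf[-1],
                        max(var(as.numeric(res)) / 2, 0.01)))
    }
  }

  best <- NULL
  best_i <- NA_integer_
  for (i in seq_len(nrow(starts))) {
    st <- as.numeric(starts[i, ])
    r <- .kalman_em_cpp(y, spec$obs_var, spec$Z,
                        st[1], st[2:(1 + k)], st[2 + k],
                        tol, max_iter, 1e-10)
    if (!is.finite(r$loglik)) next
    if (is.null(best) || r$loglik > best$loglik) {
      best <- r
      best_i <- i
    }
  }
  if (is.null(best))
    stop("convergence failure: all EM starts failed")
  boundary <- best$sigma2_proc <= 1e-8
  params <- ssm_params(best$phi, best$beta, best$sigma2_proc)
  sm <- kalman_smooth(spec, params)
  structure(list(params = params, loglik = best$loglik,
                 states = data.frame(year = spec$years,
                                     xhat = as.numeric(sm$xs),
                                     var = as.numeric(sm$Ps)),
                 trace = as.numeric(best$trace),
                 convergence = list(n_starts = nrow(starts),
                                    best_start = best_i,
                                    iterations = best$iterations,
                                    converged = isTRUE(best$converged),
                                    boundary = boundary),
                 spec = spec, method = "em"),
            class = "ssm_fit")
}

#' Fit the state-space model by direct numerical maximum likelihood
#'
#' Quasi-Newton (BFGS) maximization of [kalman_loglik()] over
#' `(phi, beta, log sigma2_proc)`, multi-started like [fit_em()].  Used as
#' the dual estimator for cross-validation of the EM fit and for fast
#' bootstrap refits.
#'
#' @inheritParams fit_em
#' @return an `ssm_fit` (see [fit_em()]).
#' @export
fit_ml <- function(spec, n_starts = 20, seed = NULL) {
  stopifnot(inherits(spec, "ssm_spec"))
  if (!is.null(seed)) set.seed(seed)
  k <- ncol(spec$Z)
  y <- ssm_y_cpp(spec)
  negll <- function(par) {
    ll <- .kalman_loglik_cpp(y, spec$obs_var,
                             as.numeric(spec$Z %*% par[2:(1 + k)]),
                             par[1], exp(par[2 + k]))
    if (!is.finite(ll)) 1e10 else -ll
  }
  starts <- draw_starts(n_starts, k)
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    st <- as.numeric(starts[i, ])
    st[2 + k] <- log(st[2 + k])
    o <- tryCatch(optim(st, negll, method = "BFGS",
                        control = list(maxit = 500)),
                  error = function(e) NULL)
    if (is.null(o) || !is.finite(o$value)) next
    if (is.null(best) || o$value < best$value) best <- o
  }
  if (is.null(best)) stop("convergence failure: all ML starts failed")
  par <- best$par
  params <- ssm_params(par[1], par[2:(1 + k)], exp(par[2 + k]))
  sm <- kalman_smooth(spec, params)
  structure(list(params = params, loglik = -best$value,
                 states = data.frame(year = spec$years,
                                     xhat = as.numeric(sm$xs),
                                     var = as.numeric(sm$Ps)),
                 trace = numeric(0),
                 convergence = list(n_starts = n_starts, best_start = NA,
                                    iterations = best$counts[1],
                                    converged = best$convergence == 0,
                                    boundary = exp(par[2 + k]) <= 1e-8),
                 spec = spec, method = "ml"),
            class = "ssm_fit")
}

#' @export
print.ssm_fit <- function(x, ...) {
  p <- x$params
  cat(sprintf("State-space fit (%s): phi = %.3f, beta = (%s), sigma2_proc = %.4f\n",
              x$method, p$phi, paste(sprintf("%.3f", p$beta), collapse = ", "),
              p$sigma2_proc))
  cat(sprintf("  logL = %.4f; converged: %s%s\n", x$loglik,
              x$convergence$converged,
              if (x$convergence$boundary) " (variance at boundary)" else ""))
  invisible(x)
}

# parameter vector view of a fit: (phi, beta..., sigma2_proc)
par_vector <- function(fit) {
  c(phi = fit$params$phi,
    setNames(fit$params$beta, paste0("beta", seq_along(fit$params$beta))),
    sigma2_proc = fit$params$sigma2_proc)
}

#' Parametric bootstrap uncertainty for a state-space fit
#'
#' Simulates `n_boot` replicate series from the fitted parameters with the
#' observed per-year variances and missingness pattern (initial state drawn
#' from the data-pinned prior), refits each replicate by EM (warm-started
#' at the fitted parameters plus a few dispersed starts), and returns
#' bootstrap SEs together with basic ("unbiased") 95% intervals
#' `2*theta_hat - q_{97.5/2.5}`.  The lower interval end for the process
#' variance is clamped at zero.  Non-converging replicates are dropped and
#' counted; a warning is attached when more than 20% fail.
#'
#' @param spec an [ssm_spec].
#' @param fit an `ssm_fit` for `spec`.
#' @param n_boot number of replicates (default 1000).
#' @param seed integer seed.
#' @param n_starts EM starts per replicate refit (first one warm).
#' @param ci_type `"basic"` (default) or `"percentile"`.
#' @return list with `se`, `ci95` (matrix with rows `lower`/`upper`),
#'   `estimates` (replicate parameter matrix), `n_failed`, `provenance`.
#' @export
bootstrap_uncertainty <- function(spec, fit, n_boot = 1000, seed = NULL,
                                  n_starts = 5, ci_type = c("basic", "percentile")) {
  ci_type <- match.arg(ci_type)
  stopifnot(inherits(spec, "ssm_spec"), inherits(fit, "ssm_fit"))
  if (!is.null(seed)) set.seed(seed)
  k <- ncol(spec$Z)
  p0 <- fit$params
  zb <- as.numeric(spec$Z %*% p0$beta)
  obs <- !is.na(spec$y)
  theta_hat <- par_vector(fit)
  est <- matrix(NA_real_, n_boot, length(theta_hat),
                dimnames = list(NULL, names(theta_hat)))
  warm <- rbind(c(p0$phi, p0$beta, max(p0$sigma2_proc, 0.01)))
  for (b in seq_len(n_boot)) {
    eps <- rnorm(2 * spec$n)
    yb <- .kalman_simulate_cpp(spec$y[1], spec$obs_var, zb, p0$phi,
                               p0$sigma2_proc, obs, eps)
    yb <- as.numeric(yb)
    yb[!obs] <- NaN
    starts <- rbind(warm, as.matrix(draw_starts(n_starts - 1, k)))
    bb <- NULL
    for (i in seq_len(nrow(starts))) {
      st <- as.numeric(starts[i, ])
      r <- .kalman_em_cpp(yb, spec$obs_var, spec$Z, st[1], st[2:(1 + k)],
                          st[2 + k], 1e-7, 2000, 1e-10)
      if (!is.finite(r$loglik)) next
      if (is.null(bb) || r$loglik > bb$loglik) bb <- r
    }
    # refits that merely hit the iteration cap (EM crawls near the variance
    # boundary) are kept: dropping them would censor small-sigma2 replicates
    if (!is.null(bb))
      est[b, ] <- c(bb$phi, bb$beta, bb$sigma2_proc)
  }
  okb <- stats::complete.cases(est)
  n_failed <- sum(!okb)
  if (n_failed > 0.2 * n_boot)
    warning(sprintf("bootstrap: %d of %d replicates failed to converge",
                    n_failed, n_boot))
  est_ok <- est[okb, , drop = FALSE]
  se <- apply(est_ok, 2, sd)
  qs <- apply(est_ok, 2, quantile, probs = c(0.975, 0.025))
  ci <- if (ci_type == "basic") {
    rbind(lower = 2 * theta_hat - qs[1, ], upper = 2 * theta_hat - qs[2, ])
  } else {
    rbind(lower = qs[2, ], upper = qs[1, ])
  }
  ci["lower", "sigma2_proc"] <- max(ci["lower", "sigma2_proc"], 0)
  list(se = se, ci95 = ci, estimates = est_ok, n_failed = n_failed,
       provenance = "bootstrap")
}

#' Standard errors from the observed information (Hessian)
#'
#' Central-difference Hessian of the negative log-likelihood at the
#' estimate, inverted to give asymptotic SEs.  A subset of parameters can
#' be profiled with the others held fixed (`which`).  Returns `NA` SEs with
#' a flag when the Hessian is not positive definite (boundary or singular
#' fits).
#'
#' @param spec an [ssm_spec].
#' @param fit an `ssm_fit`.
#' @param which indices into `(phi, beta..., sigma2_proc)` to differentiate
#'   (default: all).
#' @return list with `se` (named), `ok` (logical), `provenance`.
#' @export
hessian_se <- function(spec, fit, which = NULL) {
  stopifnot(inherits(spec, "ssm_spec"), inherits(fit, "ssm_fit"))
  k <- ncol(spec$Z)
  theta <- par_vector(fit)
  if (is.null(which)) which <- seq_along(theta)
  y <- ssm_y_cpp(spec)
  negll <- function(sub) {
    th <- theta
    th[which] <- sub
    if (th[length(th)] < 0) return(1e10)
    ll <- .kalman_loglik_cpp(y, spec$obs_var,
                             as.numeric(spec$Z %*% th[2:(1 + k)]),
                             th[1], th[length(th)])
    if (!is.finite(ll)) 1e10 else -ll
  }
  H <- tryCatch(optimHess(theta[which], negll), error = function(e) NULL)
  se <- rep(NA_real_, length(which))
  names(se) <- names(theta)[which]
  ok <- FALSE
  if (!is.null(H)) {
    ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
    if (all(ev > 0)) {
      se <- sqrt(diag(solve(H)))
      names(se) <- names(theta)[which]
      ok <- TRUE
    }
  }
  list(se = se, ok = ok, provenance = "hessian")
}

#' Standardized residuals of a state-space fit
#'
#' Observation residuals `(y_t - xhat_t) / sd`, with the model-implied
#' variance `obs_var_t - var(xhat_t)` of the smoothed discrepancy; process
#' residuals `(xhat_t - phi xhat_{t-1} - Z_t beta) / sd` with variance
#' `sigma2_proc` minus the smoothed-moment correction.  Lag 1-5
#' autocorrelations are attached for diagnostics.
#'
#' @param spec an [ssm_spec].
#' @param fit an `ssm_fit`.
#' @return list with `obs_residuals`, `proc_residuals` (standardized),
#'   `obs_raw`, `proc_raw` (unstandardized discrepancies), `acf_obs`,
#'   `acf_proc`.
#' @export
ssm_residuals <- function(spec, fit) {
  stopifnot(inherits(spec, "ssm_spec"), inherits(fit, "ssm_fit"))
  p <- fit$params
  sm <- kalman_smooth(spec, p)
  xs <- as.numeric(sm$xs)
  Ps <- as.numeric(sm$Ps)
  Pc <- as.numeric(sm$Pcross)
  n <- spec$n
  v_obs <- pmax(spec$obs_var - Ps, 1e-12)
  obs_res <- (spec$y - xs) / sqrt(v_obs)
  zb <- as.numeric(spec$Z %*% p$beta)
  idx <- 2:n
  e <- xs[idx] - p$phi * xs[idx - 1] - zb[idx]
  v_proc <- pmax(p$sigma2_proc -
                   (Ps[idx] + p$phi^2 * Ps[idx - 1] - 2 * p$phi * Pc[idx]),
                 1e-12)
  proc_res <- e / sqrt(v_proc)
  acf_safe <- function(r) {
    r <- r[is.finite(r)]
    if (length(r) < 6 || sd(r) == 0) return(rep(NA_real_, 5))
    as.numeric(acf(r, lag.max = 5, plot = FALSE)$acf)[-1]
  }
  list(obs_residuals = as.numeric(obs_res),
       proc_residuals = as.numeric(proc_res),
       obs_raw = as.numeric(spec$y - xs), proc_raw = as.numeric(e),
       acf_obs = acf_safe(obs_res), acf_proc = acf_safe(proc_res))
}
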