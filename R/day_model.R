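#' Control parameters for the day-level observation model
#'
#' @param k basis dimension of the cyclic cubic phenology spline
#'   (period 366, knots evenly spaced over days 1-366).
#' @param p_grid grid over which the Tweedie power parameter is profiled;
#'   at each grid point the dispersion is set by mean Pearson-residual
#'   scaling and the smoothing parameters re-selected.
#' @param lambda_s_grid,lambda_u_grid initial coarse grids (log10) for the
#'   spline smoothing parameter and the location ridge parameter.
#' @param optim_maxit Nelder-Mead iterations when polishing the smoothing
#'   parameters around the best grid point.
#' @param pirls_maxit,pirls_tol penalized IRLS iteration cap and relative
#'   penalized-deviance tolerance.
#' @return list of class `day_model_control`.
#' @export
day_model_control <- function(k = 10,
                              p_grid = seq(1.05, 1.95, by = 0.05),
                              lambda_s_grid = 10^seq(-2, 5),
                              lambda_u_grid = 10^seq(0, 3),
                              optim_maxit = 25,
                              pirls_maxit = 40, pirls_tol = 1e-8) {
  stopifnot(k >= 4, all(p_grid > 1), all(p_grid < 2))
  structure(list(k = k, p_grid = p_grid,
                 lambda_s_grid = lambda_s_grid,
                 lambda_u_grid = lambda_u_grid,
                 optim_maxit = optim_maxit,
                 pirls_maxit = pirls_maxit, pirls_tol = pirls_tol),
            class = "day_model_control")
}

#' Select taxa with sufficient monitoring coverage
#'
#' A year qualifies for a taxon when it contains at least
#' `min_nonzero_per_year` non-zero biomass records; taxa are retained when
#' they have at least `min_years` qualifying years.
#'
#' @param samples long-format sample table with columns `taxon`, `year`
#'   (or `date`), `biomass`.
#' @param min_years minimum number of qualifying years (default 20).
#' @param min_nonzero_per_year minimum non-zero records per qualifying year
#'   (default 3).
#' @return character vector of retained taxa (possibly empty).
#' @export
select_taxa <- function(samples, min_years = 20, min_nonzero_per_year = 3) {
  if (nrow(samples) == 0L) return(character(0))
  if (is.null(samples$year)) samples$year <- as.integer(format(as.Date(samples$date), "%Y"))
  keep <- vapply(split(samples, samples$taxon), function(d) {
    nz <- tapply(d$biomass > 0, d$year, sum)
    sum(nz >= min_nonzero_per_year) >= min_years
  }, logical(1))
  names(keep)[keep]
}

# ---- internal: design matrix assembly -------------------------------------

build_day_design <- function(data, k) {
  sm <- mgcv::smoothCon(mgcv::s(julian_day, bs = "cc", k = k),
                        data = data,
                        knots = list(julian_day = seq(1, 366, length.out = k)),
                        absorb.cons = TRUE)[[1]]
  Xs <- sm$X
  Ss <- sm$S[[1]]
  yf <- factor(data$year)
  Xy <- stats::model.matrix(~ 0 + yf)
  wind_z <- as.numeric(scale(data$wind))
  is_int <- as.numeric(data$method == "integrated")
  Xf <- cbind(wind = wind_z, integrated = is_int, wind_int = wind_z * is_int)
  lf <- factor(data$location)
  Xu <- if (nlevels(lf) > 1) stats::model.matrix(~ 0 + lf) else NULL
  X <- cbind(Xs, Xy, Xf, Xu)
  ns <- ncol(Xs); ny <- ncol(Xy); nu <- if (is.null(Xu)) 0L else ncol(Xu)
  list(X = X, S_spline = Ss, smooth = sm,
       idx_s = seq_len(ns),
       idx_y = ns + seq_len(ny),
       idx_f = ns + ny + 1:3,
       idx_u = if (nu > 0) ns + ny + 3L + seq_len(nu) else integer(0),
       years = as.integer(levels(yf)), locations = levels(lf),
       wind_center = mean(data$wind), wind_scale = sd(data$wind))
}

# Tweedie unit deviance, 1 < p < 2, y >= 0
tweedie_deviance <- function(y, mu, p) {
  2 * (pmax(y, 0)^(2 - p) / ((1 - p) * (2 - p)) -
         y * mu^(1 - p) / (1 - p) + mu^(2 - p) / (2 - p))
}

# Penalized IRLS for fixed (p, lambda_s, lambda_u).  Returns the fit or a
# non-converged shell; the penalized deviance is forced non-increasing by
# step halving.
pirls_fit <- function(y, des, p, lambda_s, lambda_u, control, beta0 = NULL) {
  X <- des$X
  n <- length(y)
  np <- ncol(X)
  Sp <- matrix(0, np, np)
  Sp[des$idx_s, des$idx_s] <- lambda_s * des$S_spline
  if (length(des$idx_u))
    Sp[cbind(des$idx_u, des$idx_u)] <- lambda_u
  if (is.null(beta0)) {
    mu <- y + mean(y[y > 0]) / 2
    eta <- log(mu)
    beta <- NULL
  } else {
    beta <- beta0
    eta <- as.numeric(X %*% beta)
    mu <- exp(eta)
  }
  pdev_old <- Inf
  converged <- FALSE
  for (it in seq_len(control$pirls_maxit)) {
    w <- mu^(2 - p)
    z <- eta + (y - mu) / mu
    XtW <- t(X * w)
    A <- XtW %*% X + Sp
    bnew <- tryCatch(solve(A, XtW %*% z), error = function(e) NULL)
    if (is.null(bnew) || any(!is.finite(bnew))) return(NULL)
    bnew <- as.numeric(bnew)
    # step-halving on the penalized deviance
    step <- 1
    repeat {
      btry <- if (is.null(beta)) bnew else beta + step * (bnew - beta)
      etat <- as.numeric(X %*% btry)
      if (max(abs(etat)) < 50) {
        mut <- exp(etat)
        pdev <- sum(tweedie_deviance(y, mut, p)) +
          as.numeric(t(btry) %*% Sp %*% btry)
        if (is.finite(pdev) && (pdev <= pdev_old + 1e-10 || is.null(beta))) break
      }
      step <- step / 2
      if (step < 1e-8) return(NULL)
    }
    beta <- btry; eta <- etat; mu <- mut
    if (abs(pdev_old - pdev) < control$pirls_tol * (abs(pdev) + 0.1)) {
      converged <- TRUE
      pdev_old <- pdev
      break
    }
    pdev_old <- pdev
  }
  w <- mu^(2 - p)
  XtW <- t(X * w)
  XtWX <- XtW %*% X
  A <- XtWX + Sp
  H <- tryCatch(solve(A, XtWX), error = function(e) NULL)
  if (is.null(H)) return(NULL)
  edf <- sum(diag(H))
  dev <- sum(tweedie_deviance(y, mu, p))
  pearson <- sum((y - mu)^2 / mu^p)
  list(beta = beta, mu = mu, eta = eta, A = A, XtWX = XtWX, Sp = Sp,
       edf = edf, dev = dev, pearson = pearson,
       gcv = n * dev / (n - edf)^2, converged = converged,
       pdev = pdev_old)
}

# smoothing-parameter selection by GCV for one p (coarse grid + polish)
select_lambdas <- function(y, des, p, control, start = NULL, beta0 = NULL) {
  has_u <- length(des$idx_u) > 0
  gcv_of <- function(lpar) {
    ls <- exp(lpar[1])
    lu <- if (has_u) exp(lpar[2]) else 0
    f <- pirls_fit(y, des, p, ls, lu, control, beta0 = beta0)
    if (is.null(f)) return(1e10)
    f$gcv
  }
  if (is.null(start)) {
    grid <- if (has_u)
      expand.grid(ls = log(control$lambda_s_grid), lu = log(control$lambda_u_grid))
    else data.frame(ls = log(control$lambda_s_grid))
    scores <- apply(grid, 1, gcv_of)
    start <- as.numeric(grid[which.min(scores), ])
  }
  opt <- optim(start, gcv_of, method = "Nelder-Mead",
               control = list(maxit = control$optim_maxit, reltol = 1e-3))
  list(par = opt$par,
       lambda_s = exp(opt$par[1]),
       lambda_u = if (has_u) exp(opt$par[2]) else 0)
}

#' Fit the day-level Tweedie observation model for one taxon
#'
#' Maximizes a penalized Tweedie log-likelihood (log link) for
#' `log mu = s(julian_day) + alpha_year + gamma_w * wind_z +
#' gamma_m * [integrated] + gamma_wm * wind_z * [integrated] + u_location`.
#' The phenology spline `s` is a cyclic penalized cubic regression spline
#' (period 366) shared by all years; year effects are fitted without a
#' global intercept so every year gets its own estimate and standard error;
#' location intercepts are ridge-penalized (the mixed-model-as-penalty
#' equivalence of i.i.d. normal random intercepts); wind is z-scored with
#' the sample mean/SD of the supplied daily wind; ferrybox is the reference
#' method level.  Smoothing and ridge parameters minimize a GCV score on
#' the working model, and the Tweedie power parameter is profiled over
#' `control$p_grid` with the dispersion set by mean Pearson-residual
#' scaling at each grid point.
#'
#' Years in which every sample is zero are removed before fitting (their
#' log-scale estimate would diverge).  Non-convergence is reported through
#' the `converged` flag rather than an error so that a community-level run
#' can route failed taxa around the downstream analysis.
#'
#' @param samples day-level samples for one taxon: columns `year` (or
#'   `date`), `julian_day`, `location`, `method`
#'   (`"integrated"`/`"ferrybox"`), `wind`, `biomass`.
#' @param control a [day_model_control].
#' @return object of class `day_model_fit` with elements `coefficients`,
#'   `Vb` (coefficient covariance), `p`, `dispersion`, `lambda_s`,
#'   `lambda_u`, `edf`, `mu` (fitted means), `design`, `years`,
#'   `dropped_years`, `alpha` (per-year log-scale estimates), `alpha_se`,
#'   `wind` (per-method slopes, offset, interaction with SEs and p-values),
#'   `sigma2_loc`, `loglik`, `converged`, `taxon`, `data`.
#' @export
fit_day_model <- function(samples, control = day_model_control()) {
  d <- as.data.frame(samples)
  if (is.null(d$year)) d$year <- as.integer(format(as.Date(d$date), "%Y"))
  if (is.null(d$julian_day)) d$julian_day <- as.integer(format(as.Date(d$date), "%j"))
  stopifnot(all(d$biomass >= 0), all(is.finite(d$biomass)))
  if (length(unique(d$year)) < 2 || nrow(d) < 30)
    stop("need at least 2 years and 30 samples to fit the day-level model")
  all_zero <- tapply(d$biomass, d$year, function(b) all(b == 0))
  dropped <- as.integer(names(all_zero)[all_zero])
  d <- d[!(d$year %in% dropped), , drop = FALSE]

  des <- build_day_design(d, control$k)
  y <- d$biomass
  n <- length(y)

  best <- NULL
  lam_start <- NULL
  beta_warm <- NULL
  for (p in control$p_grid) {
    lam <- select_lambdas(y, des, p, control, start = lam_start, beta0 = beta_warm)
    f <- pirls_fit(y, des, p, lam$lambda_s, lam$lambda_u, control,
                   beta0 = beta_warm)
    lam_start <- lam$par
    if (is.null(f)) next
    beta_warm <- f$beta
    disp <- f$pearson / (n - f$edf)
    ll <- sum(dtweedie_log(y, f$mu, p, disp))
    if (is.null(best) || ll > best$loglik) {
      best <- list(p = p, lambda_s = lam$lambda_s, lambda_u = lam$lambda_u,
                   fit = f, dispersion = disp, loglik = ll)
    }
  }
  if (is.null(best) || !best$fit$converged) {
    return(structure(list(taxon = d$taxon[1], converged = FALSE,
                          dropped_years = dropped,
                          reason = "penalized IRLS did not converge"),
                     class = "day_model_fit"))
  }
  f <- best$fit
  Vb <- solve(f$A) * best$dispersion
  alpha <- f$beta[des$idx_y]
  alpha_se <- sqrt(diag(Vb)[des$idx_y])
  names(alpha) <- names(alpha_se) <- des$years

  cf <- f$beta[des$idx_f]
  vf <- Vb[des$idx_f, des$idx_f]
  slope_ferry <- cf[1]
  slope_int <- cf[1] + cf[3]
  se_ferry <- sqrt(vf[1, 1])
  se_int <- sqrt(vf[1, 1] + vf[3, 3] + 2 * vf[1, 3])
  wind_tab <- data.frame(
    term = c("wind_ferrybox", "wind_integrated", "method_offset_integrated",
             "wind_x_method"),
    estimate = c(slope_ferry, slope_int, cf[2], cf[3]),
    se = c(se_ferry, se_int, sqrt(vf[2, 2]), sqrt(vf[3, 3])))
  wind_tab$p_value <- 2 * pnorm(-abs(wind_tab$estimate / wind_tab$se))

  structure(list(
    taxon = if (!is.null(d$taxon)) as.character(d$taxon[1]) else NA_character_,
    coefficients = f$beta, Vb = Vb, p = best$p, dispersion = best$dispersion,
    lambda_s = best$lambda_s, lambda_u = best$lambda_u, edf = f$edf,
    mu = f$mu, eta = f$eta, design = des, years = des$years,
    dropped_years = dropped, alpha = alpha, alpha_se = alpha_se,
    wind = wind_tab,
    sigma2_loc = if (best$lambda_u > 0) best$dispersion / best$lambda_u else 0,
    loglik = best$loglik, converged = TRUE, data = d),
    class = "day_model_fit")
}

#' @export
print.day_model_fit <- function(x, ...) {
  if (!x$converged) {
    cat(sprintf("Day-level model for '%s': NOT CONVERGED (%s)\n",
                x$taxon, x$reason))
    return(invisible(x))
  }
  cat(sprintf("Day-level Tweedie model for '%s'\n", x$taxon))
  cat(sprintf("  n = %d samples, %d years; p = %.2f, dispersion = %.3g, edf = %.1f\n",
              nrow(x$data), length(x$years), x$p, x$dispersion, x$edf))
  cat(sprintf("  log-likelihood %.2f; median-biomass day %d\n",
              x$loglik, median_biomass_day(x)))
  invisible(x)
}

#' Centered annual log-biomass series from a day-level fit
#'
#' `y_t = alpha_t - mean(alpha)`; the standard error of each year's
#' estimate is taken directly from the coefficient covariance (the year
#' effects are parameterized without a reference level).  The squared SEs
#' are the fixed observation variances of the dynamic model.
#'
#' @param fit converged [fit_day_model()] result.
#' @return object of class `annual_series`: data frame with columns
#'   `year`, `y`, `se`, plus attributes `taxon` and `n_years`.
#' @export
annual_series <- function(fit) {
  stopifnot(inherits(fit, "day_model_fit"))
  if (!fit$converged) stop("cannot extract annual series from a non-converged fit")
  if (any(!is.finite(fit$alpha_se))) stop("non-finite annual standard error")
  out <- data.frame(year = fit$years,
                    y = as.numeric(fit$alpha - mean(fit$alpha)),
                    se = as.numeric(fit$alpha_se))
  structure(out, taxon = fit$taxon, n_years = nrow(out),
            class = c("annual_series", "data.frame"))
}

#' Median-biomass day of the fitted phenology
#'
#' Smallest Julian day `d` at which the fitted seasonal curve accumulates
#' half of its annual mass: `sum_{j <= d} exp(s(j)) >= 0.5 * sum_j
#' exp(s(j))`, evaluated on the integer day grid 1-366 with year, wind,
#' method and location terms at reference values (they cancel from the
#' ratio).
#'
#' @param fit converged [fit_day_model()] result.
#' @return integer Julian day.
#' @export
median_biomass_day <- function(fit) {
  stopifnot(inherits(fit, "day_model_fit"), fit$converged)
  grid <- data.frame(julian_day = 1:366)
  Xp <- mgcv::PredictMat(fit$design$smooth, grid)
  s <- as.numeric(Xp %*% fit$coefficients[fit$design$idx_s])
  cum <- cumsum(exp(s))
  as.integer(which(cum >= 0.5 * cum[length(cum)])[1])
}

#' Fitted seasonal (phenology) curve
#'
#' Evaluates the fitted cyclic spline `s(julian_day)` on a day grid, on the
#' log-biomass scale (centered by the basis constraint; year, wind, method
#' and location terms are excluded).
#'
#' @param fit converged [fit_day_model()] result.
#' @param days Julian days at which to evaluate (default the full cycle).
#' @return numeric vector of log-scale seasonal effects.
#' @export
phenology_curve <- function(fit, days = 1:366) {
  Xp <- mgcv::PredictMat(fit$design$smooth, data.frame(julian_day = days))
  as.numeric(Xp %*% fit$coefficients[fit$design$idx_s])
}

#' Randomized quantile (Dunn-Smyth) residuals
#'
#' `r_i = qnorm(u_i)` with `u_i = F(y_i)` for positive observations and
#' `u_i` uniform on the zero atom `[0, F(0)]` for exact zeros, where `F` is
#' the fitted Tweedie CDF at each observation's mean.  Under a correctly
#' specified model the residuals are standard normal.  Randomization is
#' seeded for reproducibility.
#'
#' @param fit converged [fit_day_model()] result.
#' @param seed integer seed for the atom randomization.
#' @return numeric residual vector aligned with `fit$data`.
#' @export
dunn_smyth_residuals <- function(fit, seed = 1L) {
  stopifnot(inherits(fit, "day_model_fit"), fit$converged)
  if (!is.null(seed)) set.seed(seed)
  y <- fit$data$biomass
  u <- ptweedie(y, fit$mu, fit$p, fit$dispersion)
  zero <- y == 0
  if (any(zero)) {
    F0 <- exp(-fit$mu[zero]^(2 - fit$p) / (fit$dispersion * (2 - fit$p)))
    u[zero] <- runif(sum(zero), 0, F0)
  }
  qnorm(pmin(pmax(u, 1e-12), 1 - 1e-12))
}

#' Temporal drift of extreme positive residuals (phenology-shift check)
#'
#' Pearson correlation between Julian day and year among observations whose
#' residual exceeds `threshold`.  A negative correlation means the extreme
#' positive outliers occur ever earlier in the season — evidence that the
#' (year-constant) fitted phenology has advanced over the study period.
#'
#' @param residuals Dunn-Smyth residual vector.
#' @param samples the sample table the residuals are aligned to (needs
#'   `julian_day` and `year`).
#' @param threshold residual cutoff defining "extreme positive" (default 2).
#' @return list with `correlation`, `p_value`, `n_outliers` (`correlation`
#'   and `p_value` are `NA` when fewer than 3 outliers exist).
#' @export
phenology_shift_check <- function(residuals, samples, threshold = 2) {
  stopifnot(length(residuals) == nrow(samples))
  sel <- residuals > threshold
  n_out <- sum(sel)
  if (n_out < 3) {
    return(list(correlation = NA_real_, p_value = NA_real_,
                n_outliers = n_out))
  }
  ct <- cor.test(samples$julian_day[sel], samples$year[sel])
  list(correlation = unname(ct$estimate), p_value = ct$p.value,
       n_outliers = n_out)
}
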