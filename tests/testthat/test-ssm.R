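test_that("single-year likelihood matches the hand-derived closed form", {
  # prior centered at y1 with variance r1 => y1 ~ N(y1, 2 r1), innovation 0
  sp <- ssm_spec(0.3, 0.04, matrix(0, 1, 1))
  expect_equal(kalman_loglik(sp, ssm_params(0.7, 0, 0.5)),
               -0.5 * log(2 * pi * 0.08), tolerance = 1e-12)
  # value does not depend on phi/beta/q with a single year
  expect_equal(kalman_loglik(sp, ssm_params(-0.2, 3, 0.01)),
               -0.5 * log(2 * pi * 0.08), tolerance = 1e-12)
})

test_that("filter equals the brute-force multivariate-normal oracle", {
  set.seed(42)
  for (i in 1:80) {
    n <- sample(2:10, 1)
    y <- rnorm(n)
    if (n > 2) y[sample(2:n, sample(0:1, 1))] <- NA
    r <- runif(n, 0.01, 0.3)
    Z <- cbind(rnorm(n), rnorm(n))
    phi <- runif(1, -0.95, 0.95)
    beta <- rnorm(2)
    q <- runif(1, 0.01, 1)
    sp <- ssm_spec(y, r, Z)
    expect_lt(abs(kalman_loglik(sp, ssm_params(phi, beta, q)) -
                    oracle_mvn_loglik(y, r, Z, phi, beta, q)), 1e-8)
  }
})

test_that("likelihood is exactly equivariant under rescaling the series", {
  # y -> c y with obs_var -> c^2 obs_var, beta -> c beta, q -> c^2 q is a
  # pure change of units: logL drops by n_obs * log(c)
  fx <- make_ssm_fixture(0.5, 0.2, 0.5, 0.2, n = 15, seed = 3)
  sp <- fx$spec
  pars <- ssm_params(0.4, c(0.1, 0.3), 0.15)
  cc <- 2.7
  sp_sc <- ssm_spec(cc * sp$y, cc^2 * sp$obs_var, sp$Z)
  pars_sc <- ssm_params(0.4, cc * c(0.1, 0.3), cc^2 * 0.15)
  expect_equal(kalman_loglik(sp_sc, pars_sc),
               kalman_loglik(sp, pars) - sp$n * log(cc), tolerance = 1e-9)
})

test_that("diffuse process variance sends the likelihood to -Inf", {
  fx <- make_ssm_fixture(0.5, 0.2, 0.5, 0.2, n = 12, seed = 4)
  lls <- vapply(c(1, 1e2, 1e4, 1e6, 1e8), function(q)
    kalman_loglik(fx$spec, ssm_params(0.5, c(0.2, 0.5), q)), numeric(1))
  expect_true(all(diff(lls) < 0))
})

test_that("EM ascends monotonically and agrees with direct ML", {
  for (s in 1:10) {
    fx <- make_ssm_fixture(runif(1, -0.6, 0.6), rnorm(1, 0, 0.3),
                           rnorm(1, 0, 0.5), runif(1, 0.05, 0.5),
                           n = 24, seed = 100 + s)
    fe <- fit_em(fx$spec, n_starts = 15, seed = s)
    expect_true(all(diff(fe$trace) > -1e-9))
    fm <- fit_ml(fx$spec, n_starts = 10, seed = s)
    expect_lt(abs(fe$loglik - fm$loglik), 1e-4)
  }
})

test_that("EM recovers dynamics parameters at study dimensions", {
  # truth phi=0.5, beta=(0.2, 0.5), q=0.2, n=24; reduced replicate count
  errs <- t(vapply(1:40, function(i) {
    fx <- make_ssm_fixture(0.5, 0.2, 0.5, 0.2, n = 24, seed = 2000 + i)
    f <- fit_em(fx$spec, n_starts = 15, seed = i)
    abs(c(f$params$phi, f$params$beta, f$params$sigma2_proc) - fx$truth)
  }, numeric(4)))
  med <- apply(errs, 2, median)
  expect_lt(med[1], 0.25)  # phi
  expect_lt(med[3], 0.15)  # beta2
})

test_that("missing years are handled by prediction-only steps", {
  fx <- make_ssm_fixture(0.5, 0.2, 0.5, 0.2, n = 20, seed = 5)
  y <- fx$spec$y
  y[c(7, 13)] <- NA
  sp <- ssm_spec(y, fx$spec$obs_var, fx$spec$Z)
  f <- fit_em(sp, n_starts = 15, seed = 6)
  expect_true(is.finite(f$loglik))
  expect_true(all(is.finite(f$states$xhat)))  # smoothed states fill gaps
  expect_lt(abs(kalman_loglik(sp, f$params) -
                  oracle_mvn_loglik(y, sp$obs_var, sp$Z, f$params$phi,
                                    f$params$beta, f$params$sigma2_proc)),
            1e-8)
})

test_that("Hessian SE matches the weighted-mean closed form", {
  # phi = 0 and sigma2 held fixed, Z a column of ones: for t >= 2 the
  # observations are independent N(beta, q + r_t); the first-year term
  # carries no information about beta
  set.seed(9)
  n <- 15
  r <- runif(n, 0.02, 0.2)
  q <- 0.1
  y <- rnorm(n, 1.3, sqrt(q + r))
  sp <- ssm_spec(y, r, matrix(1, n, 1))
  bhat <- sum(y[-1] / (q + r[-1])) / sum(1 / (q + r[-1]))
  fake <- structure(list(params = ssm_params(0, bhat, q)), class = "ssm_fit")
  h <- hessian_se(sp, fake, which = 2)
  se_closed <- 1 / sqrt(sum(1 / (q + r[-1])))
  expect_true(h$ok)
  expect_equal(unname(h$se), se_closed, tolerance = 1e-6)
})

test_that("Hessian flags singular information (collinear covariates)", {
  set.seed(10)
  n <- 20
  z <- zscore(rnorm(n))
  Z <- cbind(z, z)  # perfectly collinear
  x <- simulate_latent_states(taxon_truth("x", phi = 0.3, sigma2_proc = 0.2),
                              NULL, n, seed = 11)
  r <- rep(0.04, n)
  sp <- ssm_spec(x + rnorm(n, 0, 0.2), r, Z)
  fake <- structure(list(params = ssm_params(0.3, c(0.2, 0.2), 0.2)),
                    class = "ssm_fit")
  h <- hessian_se(sp, fake)
  expect_false(h$ok)
  expect_true(all(is.na(h$se)))
})

test_that("bootstrap is reproducible, clamps the variance CI at zero, and
          broadly agrees with the Hessian on a well-behaved fixture", {
  fx <- make_ssm_fixture(0.4, 0.2, 0.5, 0.3, n = 24, seed = 12)
  f <- fit_em(fx$spec, n_starts = 15, seed = 13)
  b1 <- bootstrap_uncertainty(fx$spec, f, n_boot = 150, seed = 14)
  b2 <- bootstrap_uncertainty(fx$spec, f, n_boot = 150, seed = 14)
  expect_identical(b1$estimates, b2$estimates)
  expect_true(all(b1$se > 0))
  h <- hessian_se(fx$spec, f)
  expect_true(h$ok)
  for (nm in c("phi", "beta2")) {
    expect_lt(abs(b1$se[nm] - h$se[nm]) / h$se[nm], 0.3)
  }

  # near-zero process variance: replicate estimates pile at the boundary
  fx0 <- make_ssm_fixture(0.3, 0.1, 0.3, 0.005, n = 24, seed = 15)
  f0 <- fit_em(fx0$spec, n_starts = 15, seed = 16)
  b0 <- bootstrap_uncertainty(fx0$spec, f0, n_boot = 150, seed = 17)
  expect_gte(b0$ci95["lower", "sigma2_proc"], 0)
})

test_that("residuals are centered and white for a correctly specified model", {
  acf1_obs <- acf1_proc <- mobs <- numeric(60)
  for (i in 1:60) {
    fx <- make_ssm_fixture(0.5, 0.2, 0.5, 0.2, n = 24, seed = 3000 + i)
    fake <- structure(list(params = ssm_params(0.5, c(0.2, 0.5), 0.2)),
                      class = "ssm_fit")
    rs <- ssm_residuals(fx$spec, fake)
    acf1_obs[i] <- rs$acf_obs[1]
    acf1_proc[i] <- rs$acf_proc[1]
    mobs[i] <- mean(rs$obs_residuals)
  }
  lim <- 2 / sqrt(24)
  # process residuals behave like white noise under the true model
  expect_gte(mean(abs(acf1_proc) < lim), 0.85)
  # smoothed observation residuals carry intrinsic negative lag-1
  # autocorrelation (the smoother splits each year's noise between
  # neighbouring states); check the magnitude, not whiteness
  expect_lt(median(acf1_obs), 0)
  expect_gt(median(acf1_obs), -0.6)
  expect_lt(median(abs(mobs)), 0.3)
})

test_that("zero process noise gives vanishing process residuals", {
  set.seed(18)
  n <- 18
  Z <- cbind(zscore(seq_len(n)))
  x <- numeric(n)
  for (t in 2:n) x[t] <- 0.5 * x[t - 1] + 0.3 * Z[t, 1]  # q = 0 exactly
  sp <- ssm_spec(x + rnorm(n, 0, 0.05), rep(0.0025, n), Z)
  fake <- structure(list(params = ssm_params(0.5, 0.3, 1e-8)),
                    class = "ssm_fit")
  rs <- ssm_residuals(sp, fake)
  # smoothed states obey the deterministic recursion almost exactly
  expect_lt(max(abs(rs$proc_raw)), 1e-3)
})

test_that("spec constructor validates its inputs", {
  expect_error(ssm_spec(c(NA, 1, 2), rep(0.1, 3), matrix(0, 3, 1)),
               "first year")
  expect_error(ssm_spec(c(1, 2), c(0.1, 0), matrix(0, 2, 1)), "positive")
  expect_error(ssm_spec(c(1, 2), c(0.1, 0.1), matrix(c(1, NA), 2, 1)))
})
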