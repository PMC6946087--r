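# Independent oracles used across tests.

# Brute-force joint multivariate-normal log-density of the observed y for
# the annual state-space model: the state covariance is assembled explicitly
# from the AR recursion (prior x1 ~ N(y1, r1)), never via the Kalman filter.
oracle_mvn_loglik <- function(y, r, Z, phi, beta, q) {
  n <- length(y)
  zb <- as.numeric(Z %*% beta)
  m <- numeric(n)
  V <- matrix(0, n, n)
  m[1] <- y[1]
  V[1, 1] <- r[1]
  for (t in 2:n) {
    m[t] <- phi * m[t - 1] + zb[t]
    for (s in 1:(t - 1)) {
      V[t, s] <- phi * V[t - 1, s]
      V[s, t] <- V[t, s]
    }
    V[t, t] <- phi^2 * V[t - 1, t - 1] + q
  }
  obs <- !is.na(y)
  Vy <- V[obs, obs, drop = FALSE] + diag(r[obs], sum(obs))
  yo <- y[obs] - m[obs]
  as.numeric(-0.5 * (sum(obs) * log(2 * pi) +
                       determinant(Vy)$modulus + t(yo) %*% solve(Vy, yo)))
}

# Trapezoid-rule oracle for the median-biomass day: cumulative integral of
# exp(s) over a fine day grid, first crossing of half the total mass.
oracle_median_day <- function(s_fun, step = 0.05) {
  g <- seq(1, 366, by = step)
  f <- exp(s_fun(g))
  cum <- cumsum((f[-1] + f[-length(f)]) / 2 * step)
  g[-1][which(cum >= 0.5 * cum[length(cum)])[1]]
}

# Simulated state-space dataset at given truth, with observation SEs drawn
# from the range typical of the day-level model output.
make_ssm_fixture <- function(phi, beta_trend, beta_env, sigma2, n, seed,
                             obs_var_range = c(0.01, 0.09)) {
  set.seed(seed)
  Z <- cbind(zscore(seq_len(n)), zscore(rnorm(n)))
  tr <- taxon_truth("fixture", phi = phi, beta_trend = beta_trend,
                    beta_env = beta_env, sigma2_proc = sigma2)
  x <- simulate_latent_states(tr, Z, n, seed = NULL)
  obs_var <- runif(n, obs_var_range[1], obs_var_range[2])
  list(spec = ssm_spec(x + rnorm(n, 0, sqrt(obs_var)), obs_var, Z),
       truth = c(phi = phi, beta1 = beta_trend, beta2 = beta_env,
                 sigma2_proc = sigma2),
       states = x)
}

# Day-level fixture: one taxon with known phenology, wind and method biases.
make_day_fixture <- function(seed = 11, n_years = 24,
                             peak_day = 150, peak_width = 30,
                             wind_int = 0.2, wind_ferry = -0.2,
                             method_offset = 0.3, p = 1.6, disp = 1.2,
                             samples_per_year = 45) {
  cfg <- sim_config(n_years = n_years, samples_per_year = samples_per_year)
  tr <- taxon_truth("Fixture sp.", phi = 0.4, sigma2_proc = 0.3,
                    peak_day = peak_day, peak_width = peak_width,
                    wind_effect_integrated = wind_int,
                    wind_effect_ferrybox = wind_ferry,
                    method_offset = method_offset,
                    tweedie_p = p, tweedie_phi = disp, location_sd = 0.25)
  x <- simulate_latent_states(tr, NULL, n_years, seed = seed)
  d <- simulate_day_samples(tr, x, cfg, seed = seed + 1)
  list(truth = tr, states = x, samples = d, config = cfg)
}

# coarse day-model control used where many fits are needed
fast_day_control <- function() {
  day_model_control(p_grid = seq(1.2, 1.8, by = 0.15), optim_maxit = 20)
}
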