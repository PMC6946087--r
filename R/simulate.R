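#' Simulation configuration for synthetic monitoring data
#'
#' Defines the study conditions the generator emulates: a multi-decadal
#' coastal monitoring program with ~45 day-level samples per year drawn from
#' an uneven seasonal density, two sampling methods (depth-integrated
#' bottle sampling and ferrybox flow-through sampling), several locations,
#' windy-day observation bias, and a seasonally stratified brackish water
#' column.  Defaults mirror a 24-year program with roughly 1089 samples in
#' total and daily mean wind 5.4 m/s (SD 2.1 m/s).
#'
#' @param n_years number of study years (>= 3).
#' @param start_year first calendar year.
#' @param samples_per_year expected number of sampling days per year
#'   (per-year counts are Poisson around this mean).
#' @param n_locations number of sampling locations.
#' @param frac_integrated fraction of samples taken with the integrated
#'   method (the rest are ferrybox); in `[0, 1]`.
#' @param wind_mean,wind_sd daily mean wind speed moments (m/s); wind is
#'   drawn from a gamma distribution with these moments.
#' @param season_peak,season_width peak Julian day and width (days) of the
#'   Gaussian seasonal sampling density; `season_floor` adds uniform
#'   off-season coverage.
#' @param hydro list of hydrography parameters: `cast_interval` (days
#'   between casts), `depths`, `temp_base`, `temp_seasonal` (seasonal
#'   swing of the deep layer), `strat_amp` (summer surface warming, drives
#'   stratification), `temp_year_sd` (inter-annual temperature anomaly SD),
#'   `temp_trend` (deg C/year), `sal_surface`, `sal_gradient` (increase
#'   from surface to 20 m), `sal_year_sd`, `sal_trend`, `noise_sd`
#'   (within-cast measurement noise).
#' @param nutrients list: `n_per_winter` (mean winter records), `din_mean`,
#'   `dip_mean`, `si_mean`, `year_cv` (inter-annual CV), `within_cv`.
#' @param ice list: `mean_days`, `sd_days` for annual ice-day counts.
#' @param rng_seed integer seed recorded in the config.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_years = 24, start_year = 1993,
                       samples_per_year = 45, n_locations = 6,
                       frac_integrated = 0.6,
                       wind_mean = 5.4, wind_sd = 2.1,
                       season_peak = 200, season_width = 70,
                       season_floor = 0.15,
                       hydro = list(cast_interval = 7,
                                    depths = c(0, 5, 10, 15, 20),
                                    temp_base = 3, temp_seasonal = 2,
                                    strat_amp = 12, temp_year_sd = 0.8,
                                    temp_trend = 0.04,
                                    sal_surface = 5.5, sal_gradient = 0.25,
                                    sal_year_sd = 0.12, sal_trend = -0.005,
                                    noise_sd = 0.25),
                       nutrients = list(n_per_winter = 7, din_mean = 6,
                                        dip_mean = 0.7, si_mean = 12,
                                        year_cv = 0.25, within_cv = 0.3),
                       ice = list(mean_days = 36, sd_days = 30),
                       rng_seed = 1L) {
  stopifnot(n_years >= 3, wind_sd >= 0, samples_per_year > 0,
            frac_integrated >= 0, frac_integrated <= 1)
  structure(list(n_years = n_years, start_year = start_year,
                 samples_per_year = samples_per_year,
                 n_locations = n_locations,
                 frac_integrated = frac_integrated,
                 wind_mean = wind_mean, wind_sd = wind_sd,
                 season_peak = season_peak, season_width = season_width,
                 season_floor = season_floor,
                 hydro = hydro, nutrients = nutrients, ice = ice,
                 rng_seed = as.integer(rng_seed)),
            class = "sim_config")
}

#' True parameters for one simulated taxon
#'
#' Ground truth for the full two-stage data-generating process: the latent
#' AR(1) annual dynamics (`phi`, `beta_trend`, `beta_env`, `sigma2_proc`),
#' the seasonal phenology curve (log-scale Gaussian bump with cyclic
#' distance, period 366), method- and wind-dependent observation bias, and
#' the Tweedie observation noise.
#'
#' @param name taxon label.
#' @param phi autoregressive coefficient of annual log biomass
#'   (`|phi| < 1` for stationary scenarios).
#' @param beta_trend,beta_env effects of the z-scored trend and (optional)
#'   environmental covariate on the latent state.
#' @param env_name which covariate carries `beta_env`
#'   (`"temp"`, `"sal"`, `"strat"`, `"DIN"`, `"DIP"`, `"silicate"`, `"ice"`),
#'   or `NA` for none.
#' @param sigma2_proc process variance (>= 0).
#' @param peak_day,peak_width,phen_amp phenology: peak Julian day, Gaussian
#'   width in days, and log-scale amplitude of the seasonal curve.
#' @param log_level baseline log biomass (log ug/L) at the phenology peak
#'   year-average.
#' @param wind_effect_integrated,wind_effect_ferrybox log-scale biomass
#'   change per SD of wind, by sampling method.
#' @param method_offset log-scale offset of integrated relative to ferrybox
#'   sampling.
#' @param tweedie_p Tweedie power in (1, 2) (exact zeros occur).
#' @param tweedie_phi Tweedie dispersion (> 0).
#' @param location_sd SD of location random intercepts (log scale, >= 0).
#' @param is_diatom flag used by the covariate candidacy rules.
#' @return list of class `taxon_truth`.
#' @export
taxon_truth <- function(name, phi = 0.4, beta_trend = 0, beta_env = 0,
                        env_name = NA_character_, sigma2_proc = 0.2,
                        peak_day = 180, peak_width = 40, phen_amp = 2.5,
                        log_level = log(5),
                        wind_effect_integrated = 0, wind_effect_ferrybox = 0,
                        method_offset = 0,
                        tweedie_p = 1.5, tweedie_phi = 1, location_sd = 0.2,
                        is_diatom = FALSE) {
  stopifnot(is.finite(phi), is.finite(beta_trend), is.finite(beta_env),
            sigma2_proc >= 0, tweedie_p > 1, tweedie_p < 2, tweedie_phi > 0,
            location_sd >= 0, peak_day >= 1, peak_day <= 366, peak_width > 0)
  structure(as.list(environment()), class = "taxon_truth")
}

#' Simulate latent annual log-biomass states
#'
#' AR(1) recursion `x_t = phi * x_{t-1} + Z_t beta + w_t`,
#' `w_t ~ N(0, sigma2_proc)`.  The initial state is drawn from the
#' stationary marginal `N(0, sigma2_proc / (1 - phi^2))` when `|phi| < 1`,
#' otherwise from `N(0, sigma2_proc)`.
#'
#' @param truth a [taxon_truth].
#' @param Z matrix of z-scored annual covariates (`n_years` rows); its
#'   columns are multiplied by `c(beta_trend, beta_env)` (as many as
#'   provided columns).
#' @param n_years number of years.
#' @param seed optional integer seed.
#' @return numeric vector `x` of length `n_years`.
#' @export
simulate_latent_states <- function(truth, Z = NULL, n_years, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  phi <- truth$phi
  q <- truth$sigma2_proc
  if (!all(is.finite(c(phi, q)))) stop("non-finite parameters")
  beta <- c(truth$beta_trend, truth$beta_env)
  if (is.null(Z)) {
    zb <- numeric(n_years)
  } else {
    Z <- as.matrix(Z)
    stopifnot(nrow(Z) == n_years)
    beta <- beta[seq_len(ncol(Z))]
    zb <- as.numeric(Z %*% beta)
  }
  x <- numeric(n_years)
  v1 <- if (abs(phi) < 1) q / (1 - phi^2) else q
  x[1] <- rnorm(1, 0, sqrt(v1))
  for (t in seq_len(n_years)[-1])
    x[t] <- phi * x[t - 1] + zb[t] + rnorm(1, 0, sqrt(q))
  x
}

# cyclic distance between Julian days (period 366)
circ_dist <- function(d, peak, period = 366) {
  dd <- abs(d - peak) %% period
  pmin(dd, period - dd)
}

# log-scale phenology curve of a simulated taxon
truth_phenology <- function(truth, days) {
  truth$phen_amp * exp(-0.5 * (circ_dist(days, truth$peak_day) /
                                 truth$peak_width)^2)
}

#' Simulate day-level biomass samples for one taxon
#'
#' For each sampled day the expected biomass is
#' `mu = exp(log_level + x_year + s(julian) + wind_z * slope(method) +
#' method_offset * [integrated] + u_location)` and the observed biomass is
#' drawn from a Tweedie distribution (compound Poisson-gamma), so exact
#' zeros occur.  Sampling days follow the seasonal sampling density of the
#' config; per-year sample counts are Poisson.  Location random intercepts
#' are drawn once and held constant across years.
#'
#' @param truth a [taxon_truth].
#' @param states latent annual states (one per year).
#' @param config a [sim_config].
#' @param seed optional integer seed.
#' @return data frame with columns `taxon`, `date`, `year`, `julian_day`,
#'   `location`, `method`, `wind`, `biomass`.
#' @export
simulate_day_samples <- function(truth, states, config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(length(states) == config$n_years)
  years <- config$start_year + seq_len(config$n_years) - 1L
  u_loc <- rnorm(config$n_locations, 0, truth$location_sd)
  # seasonal sampling density over days 1..365 (day 366 only in leap years)
  dens_of <- function(days) {
    exp(-0.5 * (circ_dist(days, config$season_peak) / config$season_width)^2) +
      config$season_floor
  }
  # gamma wind with the configured mean/SD
  wshape <- (config$wind_mean / config$wind_sd)^2
  wscale <- config$wind_sd^2 / config$wind_mean
  out <- vector("list", config$n_years)
  for (i in seq_len(config$n_years)) {
    yr <- years[i]
    ndays <- 365L + as.integer(format(as.Date(sprintf("%d-12-31", yr)), "%j") == "366")
    n_s <- max(1L, rpois(1, config$samples_per_year))
    dens <- dens_of(seq_len(ndays))
    jd <- sort(sample.int(ndays, n_s, replace = TRUE, prob = dens))
    loc <- sample.int(config$n_locations, n_s, replace = TRUE)
    integrated <- rbinom(n_s, 1, config$frac_integrated) == 1
    wind <- rgamma(n_s, shape = wshape, scale = wscale)
    wind_z <- (wind - config$wind_mean) / config$wind_sd
    slope <- ifelse(integrated, truth$wind_effect_integrated,
                    truth$wind_effect_ferrybox)
    eta <- truth$log_level + states[i] + truth_phenology(truth, jd) +
      wind_z * slope + truth$method_offset * integrated + u_loc[loc]
    biomass <- rtweedie(n_s, mu = exp(eta), p = truth$tweedie_p,
                        phi = truth$tweedie_phi)
    out[[i]] <- data.frame(
      taxon = truth$name,
      date = as.Date(sprintf("%d-01-01", yr)) + jd - 1L,
      year = yr, julian_day = jd,
      location = paste0("L", loc),
      method = ifelse(integrated, "integrated", "ferrybox"),
      wind = wind, biomass = biomass)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Simulate environmental monitoring data
#'
#' Generates hydrographic casts (seasonally stratified temperature with
#' depth attenuation, salinity with a weak halocline and inter-annual
#' drift), winter nutrient records (November-March), annual ice-day counts
#' and daily mean wind, with the statistical structure the covariate module
#' expects: summer casts are density-stratified, midwinter casts are nearly
#' homogeneous.
#'
#' @param config a [sim_config].
#' @param seed optional integer seed.
#' @return list with data frames `hydro` (`date`, `location`, `depth`,
#'   `temperature`, `salinity`), `nutrients` (`date`, `no3`, `no2`, `nh4`,
#'   `po4`, `sio4`), `ice` (`year`, `ice_days`), `wind` (`date`, `wind`),
#'   and `year_anomaly` (the true annual temperature/salinity anomalies,
#'   for recovery tests).
#' @export
simulate_environment <- function(config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  h <- config$hydro
  years <- config$start_year + seq_len(config$n_years) - 1L
  temp_anom <- rnorm(config$n_years, 0, h$temp_year_sd) +
    h$temp_trend * (seq_len(config$n_years) - (config$n_years + 1) / 2)
  sal_anom <- rnorm(config$n_years, 0, h$sal_year_sd) +
    h$sal_trend * (seq_len(config$n_years) - (config$n_years + 1) / 2)

  hydro <- vector("list", config$n_years)
  for (i in seq_len(config$n_years)) {
    yr <- years[i]
    jd <- seq(3, 363, by = h$cast_interval)
    # seasonal shape: deep layer swings gently, surface warming only in the
    # warm season so that midwinter columns are thermally homogeneous
    seas <- cos(2 * pi * (jd - config$season_peak) / 366)
    t_deep <- pmax(h$temp_base + h$temp_seasonal * seas + 0.5 * temp_anom[i], 0.2)
    dT <- pmax(h$strat_amp * seas, 0) + temp_anom[i] * (seas > 0)
    grid <- expand.grid(jd = jd, depth = h$depths)
    idx <- match(grid$jd, jd)
    temp <- t_deep[idx] + pmax(dT[idx], 0) * exp(-grid$depth / 6) +
      rnorm(nrow(grid), 0, h$noise_sd)
    sal <- h$sal_surface + sal_anom[i] + h$sal_gradient * grid$depth / 20 +
      rnorm(nrow(grid), 0, h$noise_sd / 4)
    hydro[[i]] <- data.frame(
      date = as.Date(sprintf("%d-01-01", yr)) + grid$jd - 1L,
      location = "H1", depth = grid$depth,
      temperature = pmax(temp, -0.4), salinity = pmax(sal, 0.5))
  }
  hydro <- do.call(rbind, hydro)

  nu <- config$nutrients
  nut <- vector("list", config$n_years)
  for (i in seq_len(config$n_years)) {
    yr <- years[i]
    n_rec <- max(1L, rpois(1, nu$n_per_winter))
    # winter of target year yr: Nov-Dec of yr-1 and Jan-Mar of yr
    offs <- sample.int(151, n_rec, replace = TRUE)  # days from Nov 1
    dates <- as.Date(sprintf("%d-11-01", yr - 1L)) + offs - 1L
    ymul <- exp(rnorm(1, 0, nu$year_cv))
    wmul <- exp(rnorm(n_rec, 0, nu$within_cv))
    din <- nu$din_mean * ymul * wmul
    nut[[i]] <- data.frame(
      date = dates,
      no3 = 0.7 * din, no2 = 0.05 * din, nh4 = 0.25 * din,
      po4 = nu$dip_mean * ymul * exp(rnorm(n_rec, 0, nu$within_cv)),
      sio4 = nu$si_mean * ymul * exp(rnorm(n_rec, 0, nu$within_cv)))
  }
  nutrients <- do.call(rbind, nut)

  ice <- data.frame(
    year = years,
    ice_days = pmax(0L, as.integer(round(rnorm(config$n_years,
                                               config$ice$mean_days,
                                               config$ice$sd_days)))))

  all_dates <- seq(as.Date(sprintf("%d-01-01", years[1])),
                   as.Date(sprintf("%d-12-31", years[config$n_years])), by = 1)
  wshape <- (config$wind_mean / config$wind_sd)^2
  wind <- data.frame(date = all_dates,
                     wind = rgamma(length(all_dates), shape = wshape,
                                   scale = config$wind_sd^2 / config$wind_mean))

  list(hydro = hydro, nutrients = nutrients, ice = ice, wind = wind,
       year_anomaly = data.frame(year = years, temp = temp_anom,
                                 sal = sal_anom))
}

#' Simulate a complete synthetic monitoring dataset
#'
#' Ties the generator together: simulates the environment, derives the true
#' z-scored covariate series for each taxon with the covariate module (so
#' covariate effects act on the same series the analysis pipeline will
#' reconstruct), simulates latent annual states and day-level samples, and
#' returns everything together with a truth sidecar.
#'
#' @param config a [sim_config].
#' @param truths list of [taxon_truth] objects.
#' @param seed integer seed (defaults to `config$rng_seed`); identical
#'   config + seed reproduce the dataset exactly.
#' @return list with `samples` (all taxa stacked), `environment`
#'   (see [simulate_environment]), `states` (matrix years x taxa),
#'   `covariates` (named list of [covariate_series]), `truths`, `config`.
#' @export
simulate_dataset <- function(config, truths, seed = config$rng_seed) {
  set.seed(seed)
  env <- simulate_environment(config, seed = NULL)
  years <- config$start_year + seq_len(config$n_years) - 1L
  trend_z <- zscore(as.numeric(years))

  # one covariate series per distinct env_name used by any taxon
  env_names <- unique(na.omit(vapply(truths, `[[`, character(1), "env_name")))
  covs <- list()
  for (nm in env_names) {
    covs[[nm]] <- switch(nm,
      temp = , sal = , strat = NULL,  # taxon-specific, built per taxon below
      DIN = winter_nutrient_series(env$nutrients, "DIN", years),
      DIP = winter_nutrient_series(env$nutrients, "DIP", years),
      silicate = winter_nutrient_series(env$nutrients, "silicate", years),
      ice = annual_covariate(env$ice$ice_days, years, "ice"))
  }

  states <- matrix(NA_real_, config$n_years, length(truths),
                   dimnames = list(years, vapply(truths, `[[`, character(1), "name")))
  samples <- vector("list", length(truths))
  taxon_covs <- vector("list", length(truths))
  for (j in seq_along(truths)) {
    tr <- truths[[j]]
    Z <- matrix(trend_z, ncol = 1)
    cs <- NULL
    if (!is.na(tr$env_name) && tr$beta_env != 0) {
      cs <- if (tr$env_name %in% c("temp", "sal", "strat")) {
        taxon_anomaly_series(env$hydro, tr$env_name,
                             median_day = tr$peak_day, years = years)
      } else covs[[tr$env_name]]
      zc <- cs$z_values
      zc[is.na(zc)] <- 0  # truth uses mean conditions in gap years
      Z <- cbind(Z, zc)
    }
    x <- simulate_latent_states(tr, Z, config$n_years, seed = NULL)
    states[, j] <- x
    samples[[j]] <- simulate_day_samples(tr, x, config, seed = NULL)
    taxon_covs[j] <- list(cs)  # may be NULL; keep the slot
  }
  names(taxon_covs) <- colnames(states)

  list(samples = do.call(rbind, samples), environment = env, states = states,
       covariates = c(covs[!vapply(covs, is.null, logical(1))]),
       taxon_covariates = taxon_covs, truths = truths, config = config)
}

#' Write a synthetic dataset as delimited text + truth sidecar
#'
#' Writes the same CSV schemas the pipeline reads (`samples.csv`,
#' `hydro.csv`, `nutrients.csv`, `ice.csv`, `wind.csv`) plus
#' `truth.json` recording every true parameter, for recovery tests.
#'
#' @param dataset result of [simulate_dataset()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  env <- dataset$environment
  write.csv(dataset$samples, file.path(dir, "samples.csv"), row.names = FALSE)
  write.csv(env$hydro, file.path(dir, "hydro.csv"), row.names = FALSE)
  write.csv(env$nutrients, file.path(dir, "nutrients.csv"), row.names = FALSE)
  write.csv(env$ice, file.path(dir, "ice.csv"), row.names = FALSE)
  write.csv(env$wind, file.path(dir, "wind.csv"), row.names = FALSE)
  truth <- list(config = unclass(dataset$config),
                taxa = lapply(dataset$truths, unclass),
                states = as.data.frame(dataset$states))
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
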