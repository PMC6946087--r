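test_that("taxon selection applies the qualifying-year rule", {
  # community-scale fixture: 31 taxa built to pass, 5 built to fail
  mk_taxon <- function(name, n_years, nonzero_per_year) {
    do.call(rbind, lapply(seq_len(n_years), function(i) {
      data.frame(taxon = name, year = 1993 + i - 1,
                 biomass = c(rep(1, nonzero_per_year),
                             rep(0, 5 - min(nonzero_per_year, 5))))
    }))
  }
  pass <- do.call(rbind, lapply(sprintf("good%02d", 1:31), mk_taxon,
                                n_years = 24, nonzero_per_year = 5))
  fail <- rbind(
    mk_taxon("bad_19years", 19, 5),          # one year short
    mk_taxon("bad_2nonzero", 24, 2),         # too few non-zero records
    mk_taxon("bad_10years", 10, 5),
    mk_taxon("bad_zero", 24, 0),
    mk_taxon("bad_edge", 19, 3))
  got <- select_taxa(rbind(pass, fail), min_years = 20,
                     min_nonzero_per_year = 3)
  expect_setequal(got, sprintf("good%02d", 1:31))
  # boundary: exactly 20 qualifying years is retained
  expect_identical(select_taxa(mk_taxon("edge", 20, 3)), "edge")
  expect_identical(select_taxa(pass[0, ]), character(0))
})

fixture <- make_day_fixture(seed = 11)
fit <- fit_day_model(fixture$samples)

test_that("day-level model recovers year effects, phenology and biases", {
  expect_true(fit$converged)
  expect_gt(cor(fit$alpha, fixture$states), 0.9)
  # phenology peak within a week of the true peak (day 150)
  s <- phenology_curve(fit)
  peak_est <- which.max(s)
  expect_lte(min(abs(peak_est - 150), 366 - abs(peak_est - 150)), 7)
  # wind slopes (truth +0.2 integrated, -0.2 ferrybox) within 2 SE,
  # interaction significant
  w <- fit$wind
  est <- setNames(w$estimate, w$term)
  se <- setNames(w$se, w$term)
  expect_lt(abs(est["wind_integrated"] - 0.2), 2 * se["wind_integrated"])
  expect_lt(abs(est["wind_ferrybox"] + 0.2), 2 * se["wind_ferrybox"])
  expect_lt(w$p_value[w$term == "wind_x_method"], 0.05)
  # estimated Tweedie power near the generating value
  expect_lt(abs(fit$p - 1.6), 0.15)
})

test_that("fitted phenology is cyclic at the period boundary", {
  s <- phenology_curve(fit, c(1, 366))
  expect_lt(abs(s[1] - s[2]), 1e-8)
})

test_that("annual series is centered with positive SEs; all-zero years drop", {
  ser <- annual_series(fit)
  expect_equal(mean(ser$y), 0, tolerance = 1e-10)
  expect_true(all(ser$se > 0))
  expect_true(!is.unsorted(ser$year))

  # force an all-zero year and check it is absent downstream
  d <- fixture$samples
  d$biomass[d$year == 2000] <- 0
  f0 <- fit_day_model(d, fast_day_control())
  expect_identical(f0$dropped_years, 2000L)
  expect_false(2000 %in% annual_series(f0)$year)
})

test_that("annual estimates agree with an independent mgcv fit", {
  suppressMessages(library(mgcv))  # tw() profiling needs the attached namespace
  d <- fixture$samples
  d$wind_z <- as.numeric(scale(d$wind))
  d$fyear <- factor(d$year)
  d$floc <- factor(d$location)
  d$int <- as.numeric(d$method == "integrated")
  g <- mgcv::gam(biomass ~ 0 + s(julian_day, bs = "cc", k = 10) + fyear +
                   wind_z + int + wind_z:int + s(floc, bs = "re"),
                 knots = list(julian_day = seq(1, 366, length.out = 10)),
                 family = mgcv::tw(), data = d, method = "REML")
  am <- coef(g)[grep("fyear", names(coef(g)))]
  expect_gt(cor(fit$alpha, am), 0.999)
  expect_lt(max(abs((fit$alpha - mean(fit$alpha)) - (am - mean(am)))), 0.05)
  expect_lt(abs(fit$wind$estimate[1] - unname(coef(g)["wind_z"])), 0.02)
})

test_that("log-link scale equivariance: doubling biomass shifts year effects", {
  ctl <- day_model_control(p_grid = 1.6)
  f1 <- fit_day_model(fixture$samples, ctl)
  d2 <- fixture$samples
  d2$biomass <- 2 * d2$biomass
  f2 <- fit_day_model(d2, ctl)
  expect_equal(unname(f2$alpha - f1$alpha), rep(log(2), length(f1$alpha)),
               tolerance = 0.01)
  expect_equal(annual_series(f1)$y, annual_series(f2)$y, tolerance = 0.01)
})

test_that("annual estimates are invariant to location relabeling", {
  d <- fixture$samples
  # reversed labels so the factor-level (and design-column) order changes
  d$location <- rev(LETTERS[1:6])[match(d$location, sort(unique(d$location)))]
  f2 <- fit_day_model(d, fast_day_control())
  f1 <- fit_day_model(fixture$samples, fast_day_control())
  expect_equal(f1$alpha, f2$alpha, tolerance = 1e-6)
})

test_that("median-biomass day: uniform mass gives day 183, oracle agrees", {
  # flat phenology: zero out the spline block of a real fit
  flat <- fit
  flat$coefficients[flat$design$idx_s] <- 0
  expect_identical(median_biomass_day(flat), 183L)

  # trapezoid oracle on the fitted curve
  md <- median_biomass_day(fit)
  oracle <- oracle_median_day(function(g) phenology_curve(fit, g))
  expect_lt(abs(md - oracle), 1.5)
})

test_that("a narrow symmetric phenology puts the median day at its peak", {
  fx <- make_day_fixture(seed = 31, peak_day = 150, peak_width = 12,
                         wind_int = 0, wind_ferry = 0, method_offset = 0)
  fx$truth$phen_amp <- 6  # peak dominates the off-season baseline mass
  x <- simulate_latent_states(fx$truth, NULL, 24, seed = 31)
  d <- simulate_day_samples(fx$truth, x, fx$config, seed = 32)
  f <- fit_day_model(d, fast_day_control())
  expect_lte(abs(median_biomass_day(f) - 150), 3)
})

test_that("Dunn-Smyth residuals are seeded, normal under the model, and
          map zeros into the atom", {
  r1 <- dunn_smyth_residuals(fit, seed = 5)
  r2 <- dunn_smyth_residuals(fit, seed = 5)
  expect_identical(r1, r2)
  expect_gt(stats::ks.test(r1, "pnorm")$p.value, 0.01)
  zero <- fit$data$biomass == 0
  if (any(zero)) {
    F0 <- exp(-fit$mu[zero]^(2 - fit$p) / (fit$dispersion * (2 - fit$p)))
    expect_true(all(r1[zero] <= qnorm(F0) + 1e-8))
  }
})

test_that("phenology-shift check flags an advancing season", {
  # peak advances 1.5 days/year while the fitted curve is year-constant
  set.seed(41)
  cfg <- sim_config(n_years = 24, samples_per_year = 60)
  tr <- taxon_truth("Shift sp.", phi = 0, sigma2_proc = 0.05,
                    peak_day = 200, peak_width = 25, phen_amp = 3)
  x <- simulate_latent_states(tr, NULL, 24, seed = 42)
  pieces <- lapply(seq_len(24), function(i) {
    tri <- tr
    tri$peak_day <- 200 - 1.5 * (i - 1)
    xi <- rep(0, 24); xi[i] <- x[i]
    d <- simulate_day_samples(tri, xi, cfg, seed = 420 + i)
    d[d$year == cfg$start_year + i - 1, ]
  })
  d <- do.call(rbind, pieces)
  f <- fit_day_model(d, fast_day_control())
  res <- dunn_smyth_residuals(f, seed = 43)
  chk <- phenology_shift_check(res, f$data)
  expect_lt(chk$correlation, 0)
  expect_lt(chk$p_value, 0.05)

  # fewer than 3 outliers: undefined result
  few <- phenology_shift_check(c(3, 3, rep(0, nrow(f$data) - 2)), f$data)
  expect_true(is.na(few$correlation))
  expect_identical(few$n_outliers, 2L)
})

test_that("inadequate data is rejected up front", {
  d <- fixture$samples[1:25, ]
  expect_error(fit_day_model(d), "at least 2 years")
})
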