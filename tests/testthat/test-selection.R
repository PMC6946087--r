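test_that("candidate sets follow the timing, nutrient and silicate rules", {
  # early-season diatom: everything including silicate
  cs <- candidate_set("Thalassiosira baltica", 116, is_diatom = TRUE)
  expect_setequal(cs$candidates,
                  c("null", "temp", "sal", "strat", "DIN", "DIP", "ice",
                    "silicate"))
  # late-season non-diatom: hydrography only
  cs <- candidate_set("Late sp.", 208)
  expect_setequal(cs$candidates, c("null", "temp", "sal", "strat"))
  # Ebria tripartita keeps silicate despite median day 203 >= 166
  cs <- candidate_set("Ebria tripartita", 203, is_ebria = TRUE)
  expect_setequal(cs$candidates,
                  c("null", "temp", "sal", "strat", "silicate"))
  # boundary: day 166 itself is "not before 15 June"
  cs <- candidate_set("Edge sp.", 166)
  expect_false(any(c("DIN", "DIP", "ice") %in% cs$candidates))
  expect_true("null" %in% cs$candidates)
})

test_that("AICc matches the small-sample formula", {
  expect_equal(aicc(0, 2, 10), 4 + 12 / 7)
  # arithmetic on a published-scale input: logL -12.59, K 4, n 24
  expect_equal(aicc(-12.59, 4, 24), 25.18 + 8 + 40 / 19, tolerance = 1e-12)
  expect_error(aicc(0, 9, 10), "undefined")
  expect_error(aicc(0, 10, 10), "undefined")
})

test_that("support classification is the deterministic AICc-difference rule", {
  expect_identical(classify_support(10, 12.59)$support, "relevant")
  expect_equal(classify_support(10, 12.59)$delta, 2.59)
  expect_identical(classify_support(10, 10.86)$support, "indicative")
  expect_identical(classify_support(10, 9.5)$support, "none")
  expect_identical(classify_support(10, 10)$support, "none")
  expect_identical(classify_support(10, 12)$support, "relevant")
  # property: definition holds over random deltas
  set.seed(1)
  for (d in runif(50, -5, 5)) {
    got <- classify_support(100 - d, 100)
    expect_equal(got$delta, d)
    expect_identical(got$support,
                     if (d >= 2) "relevant" else if (d > 0) "indicative"
                     else "none")
  }
})

test_that("selection detects a strong covariate effect and ranks models", {
  set.seed(7)
  n <- 24
  covs <- list(temp = zscore(rnorm(n)), sal = zscore(rnorm(n)),
               strat = zscore(rnorm(n)))
  Z <- cbind(zscore(seq_len(n)), covs$temp)
  tr <- taxon_truth("x", phi = -0.04, beta_trend = -0.23, beta_env = 0.69,
                    sigma2_proc = 0.07)
  x <- simulate_latent_states(tr, Z, n, seed = 8)
  obs_var <- runif(n, 0.01, 0.09)
  ser <- data.frame(year = 1993:2016, y = x + rnorm(n, 0, sqrt(obs_var)),
                    se = sqrt(obs_var))
  res <- run_selection(ser, covs, candidate_set("x", 187),
                       n_starts = 20, n_boot = 100, seed = 9)
  expect_identical(res$best, "temp")
  expect_identical(res$support, "relevant")
  expect_equal(res$table$delta_aicc[res$table$covariate == "null"], 0)
  expect_true(!is.unsorted(res$table$aicc))
  # bootstrap attached to the winning model, Hessian to the null
  expect_identical(res$uncertainty$temp$provenance, "bootstrap")
  expect_identical(res$uncertainty$null$provenance, "hessian")
  # the true effect is inside the winning model's bootstrap CI
  ci <- res$uncertainty$temp$ci95
  expect_gt(0.69, ci["lower", "beta2"])
  expect_lt(0.69, ci["upper", "beta2"])
})

test_that("a null-only candidate set yields 'none' with no bootstrap", {
  set.seed(11)
  n <- 20
  x <- simulate_latent_states(taxon_truth("x", phi = 0.3, sigma2_proc = 0.1),
                              NULL, n, seed = 12)
  ser <- data.frame(year = seq_len(n), y = x + rnorm(n, 0, 0.1),
                    se = rep(0.1, n))
  cs <- candidate_set("x", 200)
  cs$candidates <- "null"
  res <- run_selection(ser, list(), cs, n_starts = 15, n_boot = 100,
                       seed = 13)
  expect_identical(res$best, "null")
  expect_identical(res$support, "none")
  expect_identical(res$uncertainty$null$provenance, "hessian")
})

test_that("gap years in a covariate are dropped pairwise for that candidate", {
  set.seed(14)
  n <- 24
  z <- zscore(rnorm(n))
  cs_gap <- covariate_series("temp", seq_len(n),
                             replace(rnorm(n), c(3, 17), NA))
  x <- simulate_latent_states(taxon_truth("x", phi = 0.3, sigma2_proc = 0.1),
                              cbind(zscore(seq_len(n))), n, seed = 15)
  ser <- data.frame(year = seq_len(n), y = x + rnorm(n, 0, 0.1),
                    se = rep(0.1, n))
  cands <- candidate_set("x", 200)
  cands$candidates <- c("null", "temp")
  res <- run_selection(ser, list(temp = cs_gap), cands,
                       n_starts = 15, n_boot = 0, seed = 16)
  tab <- res$table
  expect_equal(tab$n[tab$covariate == "temp"], n - 2)
  expect_equal(tab$n[tab$covariate == "null"], n)
})

test_that("AICc ranking is invariant to the biomass unit of measurement", {
  set.seed(17)
  n <- 24
  covs <- list(temp = zscore(rnorm(n)), sal = zscore(rnorm(n)))
  x <- simulate_latent_states(taxon_truth("x", phi = 0.4, beta_env = 0.5,
                                          env_name = "temp",
                                          sigma2_proc = 0.15),
                              cbind(zscore(seq_len(n)), covs$temp), n,
                              seed = 18)
  obs_var <- runif(n, 0.01, 0.09)
  y <- x + rnorm(n, 0, sqrt(obs_var))
  cands <- candidate_set("x", 200)
  cands$candidates <- c("null", "temp", "sal")
  r1 <- run_selection(data.frame(year = seq_len(n), y = y, se = sqrt(obs_var)),
                      covs, cands, n_starts = 15, n_boot = 0, seed = 19)
  # a common rescaling of y and se (changing the unit of log biomass)
  # shifts every candidate's logL by the same Jacobian term, so the AICc
  # differences and the ranking are preserved
  cc <- 3
  r2 <- run_selection(data.frame(year = seq_len(n), y = cc * y,
                                 se = cc * sqrt(obs_var)),
                      covs, cands, n_starts = 15, n_boot = 0, seed = 19)
  expect_identical(r1$table$covariate, r2$table$covariate)
  expect_equal(r1$table$delta_aicc, r2$table$delta_aicc, tolerance = 1e-4)
  expect_equal(r2$table$aicc - r1$table$aicc,
               rep(2 * n * log(cc), nrow(r1$table)), tolerance = 1e-4)
})
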