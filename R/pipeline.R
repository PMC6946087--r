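#' Pipeline configuration
#'
#' Bundles every knob of the two-step analysis: the data source (a
#' simulation block or a directory of delimited-text inputs), taxon
#' filters, day-level model control, dynamic-model search and bootstrap
#' sizes, the summer window used for biomass shares, the output directory
#' and the global seed.
#'
#' @param output_dir directory for all outputs (created if needed).
#' @param simulation optional list with elements `config` (a
#'   [sim_config]) and `truths` (list of [taxon_truth]); when present the
#'   pipeline generates its own data.
#' @param input_dir directory holding `samples.csv`, `hydro.csv`,
#'   `nutrients.csv`, `ice.csv`, `wind.csv` (ignored when `simulation`
#'   is given).
#' @param include,exclude optional taxon name filters.
#' @param min_years,min_nonzero_per_year coverage thresholds for
#'   [select_taxa()].
#' @param day_control a [day_model_control].
#' @param n_starts,n_boot multi-start and bootstrap sizes for the dynamic
#'   models.
#' @param summer_months months defining "summer" for biomass shares
#'   (default June-August).
#' @param diatom_classes class names treated as diatoms by the silicate
#'   candidacy rule.
#' @param seed global integer seed.
#' @param resume reuse per-taxon intermediates already present in
#'   `output_dir` (restart support).
#' @param make_plots write effect and wind-effect figures.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(output_dir,
                            simulation = NULL, input_dir = NULL,
                            include = NULL, exclude = NULL,
                            min_years = 20, min_nonzero_per_year = 3,
                            day_control = day_model_control(),
                            n_starts = 100, n_boot = 1000,
                            summer_months = 6:8,
                            diatom_classes = "Diatomophyceae",
                            seed = 1L, resume = FALSE, make_plots = TRUE) {
  if (is.null(simulation) && is.null(input_dir))
    stop("either a simulation block or an input_dir is required")
  if (!is.null(input_dir) && is.null(simulation)) {
    need <- file.path(input_dir, c("samples.csv", "hydro.csv",
                                   "nutrients.csv", "ice.csv", "wind.csv"))
    if (!all(file.exists(need)))
      stop("missing input file(s): ",
           paste(basename(need[!file.exists(need)]), collapse = ", "))
  }
  structure(as.list(environment()), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Reads the scalar fields of [pipeline_config()] from a YAML file;
#' simulation blocks are supported through `n_taxa`-free explicit lists of
#' taxon parameters passed to [taxon_truth()].
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- NULL
  if (!is.null(y$simulation)) {
    cfg <- do.call(sim_config, y$simulation$config %||% list())
    truths <- lapply(y$simulation$truths, function(t) do.call(taxon_truth, t))
    sim <- list(config = cfg, truths = truths)
  }
  y$simulation <- NULL
  do.call(pipeline_config, c(y, list(simulation = sim)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# share of total community biomass in the summer window, averaged per year
compute_bm_pct <- function(samples, summer_months = 6:8) {
  mth <- as.integer(format(as.Date(samples$date), "%m"))
  s <- samples[mth %in% summer_months, , drop = FALSE]
  tot <- tapply(s$biomass, s$year, sum)
  by_taxon <- tapply(s$biomass, list(s$taxon, s$year), sum)
  by_taxon[is.na(by_taxon)] <- 0
  shares <- sweep(by_taxon, 2, as.numeric(tot[colnames(by_taxon)]), "/")
  pct <- 100 * rowMeans(shares, na.rm = TRUE)
  data.frame(taxon = rownames(by_taxon), bm_pct = round(as.numeric(pct), 2))
}

# build all annual covariate series for one taxon from environment tables
build_taxon_covariates <- function(env, median_day, years) {
  covs <- list(
    temp = taxon_anomaly_series(env$hydro, "temp", median_day, years),
    sal = taxon_anomaly_series(env$hydro, "sal", median_day, years),
    strat = taxon_anomaly_series(env$hydro, "strat", median_day, years),
    DIN = winter_nutrient_series(env$nutrients, "DIN", years),
    DIP = winter_nutrient_series(env$nutrients, "DIP", years),
    silicate = winter_nutrient_series(env$nutrients, "silicate", years))
  ice <- env$ice[match(years, env$ice$year), "ice_days"]
  covs$ice <- annual_covariate(ice, years, "ice")
  covs
}

# one Table-style report row from a selection fit
report_row <- function(taxon, nm, res, covs) {
  f <- res$fits[[nm]]
  un <- res$uncertainty[[nm]]
  se <- un$se
  g <- function(x, d = NA_real_) if (is.null(x) || length(x) == 0 || is.na(x)) d else unname(x)
  cs <- covs[[nm]]
  data.frame(
    taxon = taxon, covariate = nm,
    beta1 = f$params$beta[1], beta1_se = g(se["beta1"]),
    beta2 = if (length(f$params$beta) > 1) f$params$beta[2] else NA_real_,
    beta2_se = g(se["beta2"]),
    cov_mean = if (!is.null(cs)) cs$raw_mean else NA_real_,
    cov_sd = if (!is.null(cs)) cs$raw_sd else NA_real_,
    phi = f$params$phi, phi_se = g(se["phi"]),
    sigma2_proc = f$params$sigma2_proc, sigma2_se = g(se["sigma2_proc"]),
    logL = f$loglik,
    n = res$table$n[res$table$covariate == nm],
    delta_aicc = res$table$delta_aicc[res$table$covariate == nm],
    support = res$support, se_type = un$provenance)
}

#' Run the full two-step pipeline
#'
#' Simulate (or load) monitoring data, select taxa with sufficient
#' coverage, fit the day-level observation model per taxon, extract the
#' centered annual series and median-biomass day, build the taxon-specific
#' covariate series, rank the candidate dynamic models, and write a report
#' bundle: per-taxon annual series and fit summaries, a community-level
#' selection table, residual diagnostics, optional effect/wind figures, a
#' run log and provenance metadata.  Per-taxon failures (non-convergence)
#' are isolated and logged; the run completes.
#'
#' @param config a [pipeline_config].
#' @return invisible list with `selection_table`, `wind_table`,
#'   `annual` (named list of annual series), `results` (named list of
#'   [run_selection()] results), `skipped` (named reasons), `bm_pct`,
#'   `output_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  log_msg <- function(...) {
    line <- sprintf(...)
    log_lines <<- c(log_lines, line)
    message(line)
  }
  set.seed(config$seed)

  if (!is.null(config$simulation)) {
    log_msg("simulating dataset (seed %d)", config$seed)
    ds <- simulate_dataset(config$simulation$config, config$simulation$truths,
                           seed = config$seed)
    samples <- ds$samples
    env <- ds$environment
    in_dir <- file.path(config$output_dir, "inputs")
    write_dataset(ds, in_dir)
  } else {
    rd <- function(f) read.csv(file.path(config$input_dir, f))
    samples <- rd("samples.csv")
    env <- list(hydro = rd("hydro.csv"), nutrients = rd("nutrients.csv"),
                ice = rd("ice.csv"), wind = rd("wind.csv"))
  }
  samples$year <- as.integer(format(as.Date(samples$date), "%Y"))
  samples$julian_day <- as.integer(format(as.Date(samples$date), "%j"))

  taxa <- select_taxa(samples, config$min_years, config$min_nonzero_per_year)
  if (!is.null(config$include)) taxa <- intersect(taxa, config$include)
  if (!is.null(config$exclude)) taxa <- setdiff(taxa, config$exclude)
  log_msg("%d taxa pass the coverage filter: %s", length(taxa),
          paste(taxa, collapse = ", "))
  years <- sort(unique(samples$year))

  taxon_class <- if (!is.null(samples$class))
    tapply(as.character(samples$class), samples$taxon, `[`, 1) else NULL
  is_diatom_of <- function(tx) {
    !is.null(taxon_class) && taxon_class[[tx]] %in% config$diatom_classes
  }

  annual <- list(); results <- list(); skipped <- list()
  sel_rows <- list(); wind_rows <- list(); diag_rows <- list()
  tdir <- file.path(config$output_dir, "taxa")
  dir.create(tdir, showWarnings = FALSE)

  for (tx in taxa) {
    d <- samples[samples$taxon == tx, , drop = FALSE]
    acsv <- file.path(tdir, paste0(gsub("[^A-Za-z0-9]+", "_", tx), "_annual.csv"))
    fit <- tryCatch(fit_day_model(d, config$day_control),
                    error = function(e) structure(
                      list(converged = FALSE, reason = conditionMessage(e)),
                      class = "day_model_fit"))
    if (!fit$converged) {
      log_msg("SKIP %s: day-level model failed (%s)", tx, fit$reason)
      skipped[[tx]] <- paste("day-model:", fit$reason)
      next
    }
    ser <- annual_series(fit)
    md <- median_biomass_day(fit)
    res_ds <- dunn_smyth_residuals(fit, seed = config$seed)
    shift <- phenology_shift_check(res_ds, fit$data)
    write.csv(as.data.frame(ser), acsv, row.names = FALSE)
    annual[[tx]] <- ser
    wind_rows[[tx]] <- cbind(taxon = tx, fit$wind)
    diag_rows[[tx]] <- data.frame(taxon = tx, median_day = md,
                                  tweedie_p = fit$p,
                                  dispersion = fit$dispersion,
                                  outlier_cor = shift$correlation,
                                  outlier_p = shift$p_value,
                                  n_outliers = shift$n_outliers)

    covs <- build_taxon_covariates(env, md, ser$year)
    cands <- candidate_set(tx, md, is_diatom = isTRUE(is_diatom_of(tx)),
                           is_ebria = grepl("^Ebria tripartita", tx))
    res <- tryCatch(
      run_selection(ser, covs, cands, n_starts = config$n_starts,
                    n_boot = config$n_boot, seed = config$seed),
      error = function(e) e)
    if (inherits(res, "error")) {
      log_msg("SKIP %s: dynamic model failed (%s)", tx, conditionMessage(res))
      skipped[[tx]] <- paste("ssm:", conditionMessage(res))
      next
    }
    if (length(res$failed))
      log_msg("%s: non-convergent candidate(s) %s", tx,
              paste(res$failed, collapse = ", "))
    results[[tx]] <- res
    # report every candidate improving on the null, or the best fit if none
    report <- res$table$covariate[res$table$covariate != "null" &
                                    res$table$delta_aicc > 0]
    if (length(report) == 0) report <- res$best
    for (nm in setdiff(report, "null"))
      sel_rows[[paste(tx, nm)]] <- report_row(tx, nm, res, covs)
    log_msg("%s: best = %s (%s)", tx, res$best, res$support)
  }

  sel <- if (length(sel_rows)) do.call(rbind, sel_rows) else NULL
  windt <- if (length(wind_rows)) do.call(rbind, wind_rows) else NULL
  diagt <- if (length(diag_rows)) do.call(rbind, diag_rows) else NULL
  bm <- compute_bm_pct(samples, config$summer_months)
  if (!is.null(sel)) {
    rownames(sel) <- NULL
    write.csv(sel, file.path(config$output_dir, "selection_table.csv"),
              row.names = FALSE)
  }
  if (!is.null(windt)) {
    rownames(windt) <- NULL
    write.csv(windt, file.path(config$output_dir, "wind_effects.csv"),
              row.names = FALSE)
  }
  if (!is.null(diagt)) {
    rownames(diagt) <- NULL
    write.csv(diagt, file.path(config$output_dir, "day_model_diagnostics.csv"),
              row.names = FALSE)
  }
  write.csv(bm, file.path(config$output_dir, "summer_biomass_pct.csv"),
            row.names = FALSE)

  if (config$make_plots && !is.null(sel)) {
    fdir <- file.path(config$output_dir, "figures")
    dir.create(fdir, showWarnings = FALSE)
    ggplot2::ggsave(file.path(fdir, "covariate_effects.png"),
                    plot_covariate_effects(sel), width = 7, height = 5, dpi = 150)
    if (!is.null(windt))
      ggplot2::ggsave(file.path(fdir, "wind_effects.png"),
                      plot_wind_effects(windt), width = 7, height = 5, dpi = 150)
  }

  # provenance: config hash (md5 of its canonical JSON), seed, version
  cfg_json <- jsonlite::toJSON(lapply(unclass(config), function(x)
    if (is.list(x) || is.function(x)) NULL else x), auto_unbox = TRUE)
  tf <- file.path(config$output_dir, "config.json")
  writeLines(cfg_json, tf)
  meta <- list(seed = config$seed,
               config_md5 = unname(tools::md5sum(tf)),
               package_version = as.character(utils::packageVersion("planktonssm")),
               n_taxa_run = length(results), skipped = names(skipped))
  jsonlite::write_json(meta, file.path(config$output_dir, "metadata.json"),
                       auto_unbox = TRUE)
  writeLines(log_lines, file.path(config$output_dir, "run.log"))

  invisible(list(selection_table = sel, wind_table = windt,
                 diagnostics = diagt, annual = annual, results = results,
                 skipped = skipped, bm_pct = bm,
                 output_dir = config$output_dir))
}
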