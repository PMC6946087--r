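#' Bundled Baltic plankton community summary table
#'
#' A 31-taxon summary of a Gulf of Finland nano- and microplankton
#' monitoring community: taxonomic class, percentage contribution to total
#' summer biomass (`bm_pct`), day-level sample size, median-biomass Julian
#' day, and the mean (with uncertainty) temperature, salinity and
#' stratification index experienced over the 60 days before median biomass.
#' Used as the reference community for worked examples, for the
#' summer-biomass-share arithmetic and for building realistic simulation
#' scenarios.
#'
#' @return data frame with columns `class`, `taxon`, `bm_pct`, `n`,
#'   `median_day`, `temp_mean`, `temp_se`, `sal_mean`, `sal_se`,
#'   `strat_mean`, `strat_se`.
#' @export
community_table <- function() {
  read.csv(system.file("extdata", "community_table.csv",
                       package = "planktonssm"),
           check.names = FALSE)
}

#' Bundled reference dynamic-model parameter scenarios
#'
#' Fitted annual-dynamics parameters (trend effect `beta1`, covariate
#' effect `beta2`, density dependence `phi`, process variance
#' `sigma2_proc`, with SEs, log-likelihood, series length and AICc
#' improvement over the trend-only null) for the best-supported covariate
#' models of the reference community.  These rows double as realistic
#' ground-truth scenarios for the simulation-based validation of the
#' estimators.
#'
#' @return data frame, one row per taxon-covariate model.
#' @export
reference_fits <- function() {
  read.csv(system.file("extdata", "reference_fits.csv",
                       package = "planktonssm"),
           check.names = FALSE)
}

#' Summer biomass share of a taxon subset
#'
#' Sums the percentage contributions to total summer biomass (`bm_pct`)
#' over a subset of taxa and reports the result rounded to one decimal,
#' together with the largest single contribution.
#'
#' @param biomass_table data frame with columns `taxon` and `bm_pct`
#'   (defaults to [community_table()]).
#' @param taxa character vector of taxon names; unknown names are an error.
#' @return list with `share` (percent, 1 decimal), `top_taxon`,
#'   `top_share`.
#' @export
summer_biomass_share <- function(taxa, biomass_table = community_table()) {
  if (length(taxa) == 0)
    return(list(share = 0.0, top_taxon = NA_character_, top_share = NA_real_))
  idx <- match(taxa, biomass_table$taxon)
  if (anyNA(idx))
    stop("unknown taxon: ", paste(taxa[is.na(idx)], collapse = ", "))
  bm <- biomass_table$bm_pct[idx]
  list(share = round(sum(bm), 1),
       top_taxon = taxa[which.max(bm)],
       top_share = max(bm))
}

#' Translate a standardized effect into a scenario change
#'
#' Helpers for interpreting z-scored effect sizes in natural units: a
#' projected change of `delta_raw` units of a covariate with inter-annual
#' SD `raw_sd` equals `delta_raw / raw_sd` standard deviations, and a
#' per-SD log-scale effect `beta` applied to `delta_sd` standard deviations
#' multiplies biomass by `exp(beta * delta_sd)`.
#'
#' @param delta_raw projected change in natural units.
#' @param raw_sd inter-annual SD of the covariate in natural units.
#' @return `scenario_sd_change()`: the change expressed in SD units.
#' @export
scenario_sd_change <- function(delta_raw, raw_sd) delta_raw / raw_sd

#' @rdname scenario_sd_change
#' @param beta standardized (per-SD) effect on log biomass.
#' @param delta_sd change in SD units.
#' @return `scenario_biomass_change()`: the multiplicative biomass change.
#' @export
scenario_biomass_change <- function(beta, delta_sd) exp(beta * delta_sd)
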