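#' Build the taxon-specific candidate covariate set
#'
#' Every taxon is tested against its temperature, salinity and
#' stratification anomaly series.  Taxa reaching median biomass before
#' 15 June (Julian day 166) additionally get the winter nutrient measures
#' DIN and DIP and the number of ice days (their winter signal plausibly
#' precedes an early bloom).  Winter silicate is considered only for
#' diatoms and for the silica-skeleton flagellate *Ebria tripartita*,
#' regardless of timing.  The null model (trend only) is always included,
#' and no candidate carries more than one environmental covariate.
#'
#' @param taxon taxon name.
#' @param median_day median-biomass Julian day from the day-level model.
#' @param is_diatom is the taxon a diatom?
#' @param is_ebria is the taxon *Ebria tripartita*?
#' @return object of class `candidate_set`: list with `taxon`,
#'   `median_day`, `candidates` (character vector starting with `"null"`).
#' @export
candidate_set <- function(taxon, median_day, is_diatom = FALSE,
                          is_ebria = FALSE) {
  cands <- c("temp", "sal", "strat")
  if (median_day < 166) cands <- c(cands, "DIN", "DIP", "ice")
  if (is_diatom || is_ebria) cands <- c(cands, "silicate")
  structure(list(taxon = taxon, median_day = median_day,
                 is_diatom_or_ebria = is_diatom || is_ebria,
                 candidates = c("null", cands)),
            class = "candidate_set")
}

#' Small-sample Akaike information criterion
#'
#' `AICc = -2 logL + 2K + 2K(K + 1) / (n - K - 1)`, with the number of
#' years as the sample size.  The null dynamic model has `K = 3`
#' (`phi`, `beta1`, `sigma2_proc`); adding one covariate gives `K = 4`
#' (the data-pinned initial state carries no parameters).
#'
#' @param logL maximized log-likelihood.
#' @param K number of estimated parameters.
#' @param n sample size (number of years); must exceed `K + 1`.
#' @return AICc value.
#' @export
aicc <- function(logL, K, n) {
  if (n <= K + 1) stop("AICc undefined: n must exceed K + 1")
  -2 * logL + 2 * K + 2 * K * (K + 1) / (n - K - 1)
}

#' Classify covariate support from an AICc comparison
#'
#' With `delta = aicc_null - aicc_candidate` (positive = the covariate
#' model improves on the trend-only null): `delta >= 2` is "relevant"
#' (clear evidence), `0 < delta < 2` is "indicative" (weak evidence),
#' `delta <= 0` is "none".
#'
#' @param aicc_candidate,aicc_null AICc of the covariate model and the
#'   null model.
#' @return list with `support` (one of `"relevant"`, `"indicative"`,
#'   `"none"`) and `delta`.
#' @export
classify_support <- function(aicc_candidate, aicc_null) {
  stopifnot(is.finite(aicc_candidate), is.finite(aicc_null))
  delta <- aicc_null - aicc_candidate
  support <- if (delta >= 2) "relevant" else if (delta > 0) "indicative" else "none"
  list(support = support, delta = delta)
}

#' Rank candidate dynamic models for one taxon
#'
#' Fits the trend-only null model and one state-space model per candidate
#' covariate via [fit_em()], ranks them by [aicc()] (ties broken toward the
#' simpler model), classifies the support of the best non-null candidate
#' with [classify_support()], and attaches uncertainty: parametric
#' bootstrap for candidates that beat the null (when `n_boot > 0`),
#' Hessian SEs otherwise.  Years missing from a candidate covariate are
#' dropped pairwise for that candidate.
#'
#' @param series an [annual_series()] (or data frame with `year`, `y`,
#'   `se`).
#' @param covariates named list of [covariate_series] (or plain z-scored
#'   vectors aligned to the series years), one per candidate name.
#' @param candidates a [candidate_set].
#' @param n_starts,n_boot,seed control for [fit_em()] and
#'   [bootstrap_uncertainty()]; `n_boot = 0` skips the bootstrap.
#' @return object of class `selection_result`: `taxon`, `table` (one row
#'   per converged candidate: `covariate`, `K`, `n`, `logL`, `aicc`,
#'   `delta_aicc`), `best`, `support`, `fits`, `uncertainty`, `failed`.
#' @export
run_selection <- function(series, covariates, candidates,
                          n_starts = 100, n_boot = 1000, seed = 1L) {
  stopifnot(inherits(candidates, "candidate_set"))
  taxon <- candidates$taxon
  years <- series$year
  y <- series$y
  se <- series$se

  cov_z <- function(nm) {
    cv <- covariates[[nm]]
    if (is.null(cv)) return(NULL)
    if (inherits(cv, "covariate_series")) {
      z <- cv$z_values[match(years, cv$years)]
    } else {
      stopifnot(length(cv) == length(years))
      z <- as.numeric(cv)
    }
    z
  }

  fits <- list()
  rows <- list()
  failed <- character(0)
  for (nm in candidates$candidates) {
    if (nm == "null") {
      yrs_keep <- rep(TRUE, length(years))
      Z <- cbind(trend = zscore(as.numeric(years)))
    } else {
      z <- cov_z(nm)
      if (is.null(z)) next
      yrs_keep <- !is.na(z)
      if (sum(yrs_keep) < 5) {
        failed <- c(failed, nm)
        next
      }
      Z <- cbind(trend = zscore(as.numeric(years[yrs_keep])),
                 cov = z[yrs_keep])
    }
    sp <- ssm_spec(y[yrs_keep], se[yrs_keep]^2, Z, years = years[yrs_keep])
    f <- tryCatch(fit_em(sp, n_starts = n_starts, seed = seed),
                  error = function(e) NULL)
    # a fit that merely hit the EM iteration cap away from the boundary is
    # numerically settled; only degenerate boundary non-convergence fails
    if (is.null(f) ||
        (!f$convergence$converged && f$convergence$boundary)) {
      failed <- c(failed, nm)
      next
    }
    K <- 2 + ncol(Z)  # phi, sigma2_proc + one beta per column
    n_eff <- sum(!is.na(sp$y))
    fits[[nm]] <- f
    rows[[nm]] <- data.frame(covariate = nm, K = K, n = n_eff,
                             logL = f$loglik, aicc = aicc(f$loglik, K, n_eff))
  }
  if (is.null(fits[["null"]]))
    stop(sprintf("null model did not converge for taxon '%s'", taxon))
  tab <- do.call(rbind, rows)
  tab$delta_aicc <- tab$aicc[tab$covariate == "null"] - tab$aicc
  # rank by AICc; ties toward the simpler model (fewer parameters)
  tab <- tab[order(tab$aicc, tab$K), ]
  rownames(tab) <- NULL

  non_null <- tab[tab$covariate != "null", , drop = FALSE]
  if (nrow(non_null) > 0) {
    cls <- classify_support(min(non_null$aicc),
                            tab$aicc[tab$covariate == "null"])
    best <- if (cls$delta > 0) non_null$covariate[which.min(non_null$aicc)] else "null"
    support <- cls$support
  } else {
    best <- "null"
    support <- "none"
  }

  uncertainty <- list()
  for (nm in names(fits)) {
    f <- fits[[nm]]
    beats_null <- nm != "null" &&
      tab$delta_aicc[tab$covariate == nm] > 0
    sp <- f$spec
    uncertainty[[nm]] <- if (beats_null && n_boot > 0) {
      bootstrap_uncertainty(sp, f, n_boot = n_boot, seed = seed)
    } else {
      hessian_se(sp, f)
    }
  }

  structure(list(taxon = taxon, table = tab, best = best, support = support,
                 fits = fits, uncertainty = uncertainty, failed = failed),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("Model selection for '%s': best = %s (%s)\n",
              x$taxon, x$best, x$support))
  print(x$table, digits = 4)
  if (length(x$failed))
    cat("non-convergent candidates:", paste(x$failed, collapse = ", "), "\n")
  invisible(x)
}
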