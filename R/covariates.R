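#' Seawater density anomaly (sigma-t, EOS-80)
#'
#' Computes the density anomaly `sigma_t = rho(S, T, p = 0) - 1000` kg/m3
#' from practical salinity and temperature (ITS-68 scale assumed close
#' enough to ITS-90 at the precision used here) using the EOS-80 /
#' UNESCO 1983 one-atmosphere equation of state (Millero & Poisson
#' polynomial).  Valid for `S` in 0-42 and `T` in -2 to 40 degrees C.
#'
#' @param salinity practical salinity (dimensionless, >= 0).
#' @param temperature temperature, degrees C, in `[-2, 40]`.
#' @return density anomaly in kg/m3.
#' @examples
#' sigma_t(35, 5)   # open-ocean reference value 27.675
#' sigma_t(5.5, 16) # brackish summer surface water
#' @export
sigma_t <- function(salinity, temperature) {
  if (any(!is.finite(salinity)) || any(!is.finite(temperature)))
    stop("salinity and temperature must be finite")
  if (any(salinity < 0) || any(salinity > 42))
    stop("salinity outside EOS-80 validity range [0, 42]")
  if (any(temperature < -2) || any(temperature > 40))
    stop("temperature outside EOS-80 validity range [-2, 40] degrees C")
  T <- temperature
  S <- salinity
  rho_w <- 999.842594 + 6.793952e-2 * T - 9.095290e-3 * T^2 +
    1.001685e-4 * T^3 - 1.120083e-6 * T^4 + 6.536332e-9 * T^5
  A <- 8.24493e-1 - 4.0899e-3 * T + 7.6438e-5 * T^2 -
    8.2467e-7 * T^3 + 5.3875e-9 * T^4
  B <- -5.72466e-3 + 1.0227e-4 * T - 1.6546e-6 * T^2
  C <- 4.8314e-4
  rho_w + A * S + B * S^1.5 + C * S^2 - 1000
}

#' Density stratification index between surface and 20 m
#'
#' `E = sigma_t(20 m) - sigma_t(surface)`.  Larger values indicate stronger
#' density stratification of the water column; a homogeneous column gives 0.
#'
#' @param sal_surface,temp_surface salinity and temperature at the surface.
#' @param sal_deep,temp_deep salinity and temperature at ~20 m depth.
#' @return stratification index in kg/m3 (vectorized).
#' @export
stratification_index <- function(sal_surface, temp_surface, sal_deep, temp_deep) {
  sigma_t(sal_deep, temp_deep) - sigma_t(sal_surface, temp_surface)
}

#' Per-cast stratification index from a hydrographic profile table
#'
#' Groups profile rows into casts by `(date, location)`, takes the
#' shallowest record (depth <= `surface_max`) as the surface layer and the
#' record closest to 20 m (within `deep_range`) as the deep layer, and
#' returns one stratification index per cast.  Casts missing either layer
#' are skipped with a warning.
#'
#' @param profiles data frame with columns `date`, `location`, `depth`,
#'   `temperature`, `salinity`.
#' @param surface_max maximum depth (m) accepted as "surface" (default 5).
#' @param deep_range acceptable depth interval for the ~20 m layer.
#' @return data frame with columns `date`, `location`, `strat`.
#' @export
cast_stratification <- function(profiles, surface_max = 5,
                                deep_range = c(15, 25)) {
  stopifnot(all(c("date", "location", "depth", "temperature", "salinity")
                %in% names(profiles)))
  key <- interaction(profiles$date, profiles$location, drop = TRUE)
  pieces <- split(profiles, key)
  out <- lapply(pieces, function(d) {
    surf <- d[d$depth <= surface_max, , drop = FALSE]
    deep <- d[d$depth >= deep_range[1] & d$depth <= deep_range[2], , drop = FALSE]
    if (nrow(surf) == 0L || nrow(deep) == 0L) return(NULL)
    surf <- surf[which.min(surf$depth), ]
    deep <- deep[which.min(abs(deep$depth - 20)), ]
    data.frame(date = surf$date, location = surf$location,
               strat = stratification_index(surf$salinity, surf$temperature,
                                            deep$salinity, deep$temperature))
  })
  skipped <- sum(vapply(out, is.null, logical(1)))
  if (skipped > 0)
    warning(sprintf("%d cast(s) skipped: missing surface or 20 m layer", skipped))
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  rownames(res) <- NULL
  res
}

#' z-score a numeric vector (sample mean 0, sample SD 1)
#'
#' Missing entries are excluded from the mean/SD and stay missing in the
#' output.  Errors on degenerate input (fewer than two non-missing values
#' or zero sample SD), because a z-scored covariate with no variance is
#' meaningless in the dynamic model.
#'
#' @param x numeric vector.
#' @return z-scored vector with attributes `raw_mean` and `raw_sd`.
#' @export
zscore <- function(x) {
  ok <- !is.na(x)
  if (sum(ok) < 2L) stop("zscore needs at least 2 non-missing values")
  m <- mean(x[ok])
  s <- sd(x[ok])
  if (s == 0) stop("degenerate covariate: sample SD is zero")
  z <- (x - m) / s
  attr(z, "raw_mean") <- m
  attr(z, "raw_sd") <- s
  z
}

#' Construct an annual covariate series
#'
#' Container for one z-scored annual environmental driver, retaining the raw
#' values and their mean/SD so that standardized effects can be translated
#' back to natural units in reports.
#'
#' @param name covariate name (e.g. `"temp"`, `"sal"`, `"strat"`, `"DIN"`,
#'   `"DIP"`, `"silicate"`, `"ice"`, `"trend"`).
#' @param years ordered integer years (one value per year, gaps as `NA` in
#'   `raw_values`).
#' @param raw_values raw annual values aligned with `years`.
#' @return object of class `covariate_series` with elements `name`, `years`,
#'   `raw_values`, `z_values`, `raw_mean`, `raw_sd`.
#' @export
covariate_series <- function(name, years, raw_values) {
  stopifnot(length(years) == length(raw_values), !is.unsorted(years))
  z <- zscore(raw_values)
  structure(list(name = name, years = as.integer(years),
                 raw_values = as.numeric(raw_values),
                 z_values = as.numeric(z),
                 raw_mean = attr(z, "raw_mean"), raw_sd = attr(z, "raw_sd")),
            class = "covariate_series")
}

#' @export
print.covariate_series <- function(x, ...) {
  cat(sprintf("Annual covariate '%s': %d years (%d-%d), raw mean %.3g (SD %.3g), %d missing\n",
              x$name, length(x$years), min(x$years), max(x$years),
              x$raw_mean, x$raw_sd, sum(is.na(x$raw_values))))
  invisible(x)
}

#' @export
as.data.frame.covariate_series <- function(x, ...) {
  data.frame(year = x$years, raw = x$raw_values, z = x$z_values)
}

#' Taxon-specific annual anomaly series over a pre-bloom window
#'
#' For each year, averages all observations of one hydrographic variable
#' whose Julian day falls in the 60-day window `[median_day - 59,
#' median_day]` (lags 0-59 before the taxon's median-biomass day; windows
#' crossing the year boundary truncate at day 1), subtracts the across-year
#' mean of those annual means (the anomaly), and z-scores the result.
#'
#' @param profiles hydrographic table: `date`, `location`, `depth`,
#'   `temperature`, `salinity`.
#' @param variable one of `"temp"`, `"sal"`, `"strat"`.
#' @param median_day taxon's median-biomass Julian day in `[1, 366]`.
#' @param years integer vector of target years.
#' @param max_depth for `"temp"`/`"sal"`, observations deeper than this are
#'   ignored (default 10 m, the sampled layer).
#' @return a [covariate_series] (years with an empty window are `NA`).
#' @export
taxon_anomaly_series <- function(profiles, variable = c("temp", "sal", "strat"),
                                 median_day, years, max_depth = 10) {
  variable <- match.arg(variable)
  stopifnot(median_day >= 1, median_day <= 366)
  if (variable == "strat") {
    casts <- cast_stratification(profiles)
    dates <- as.Date(casts$date)
    vals <- casts$strat
  } else {
    keep <- profiles$depth <= max_depth
    dates <- as.Date(profiles$date[keep])
    vals <- if (variable == "temp") profiles$temperature[keep]
            else profiles$salinity[keep]
  }
  jd <- as.integer(format(dates, "%j"))
  yr <- as.integer(format(dates, "%Y"))
  lo <- max(1, median_day - 59)
  in_window <- jd >= lo & jd <= median_day
  ann <- vapply(years, function(y) {
    sel <- in_window & yr == y
    if (!any(sel)) NA_real_ else mean(vals[sel])
  }, numeric(1))
  n_ok <- sum(!is.na(ann))
  if (n_ok < 0.8 * length(years))
    warning(sprintf("anomaly window has data in only %d of %d years",
                    n_ok, length(years)))
  anom <- ann - mean(ann, na.rm = TRUE)
  covariate_series(variable, years, anom)
}

#' Winter nutrient covariate series
#'
#' Averages nutrient records from the winter preceding the growing season:
#' for target year `y`, records dated November-December of `y - 1` and
#' January-March of `y`.  DIN is the per-record sum of nitrate, nitrite and
#' ammonium; DIP is phosphate; silicate is taken as provided.  Records are
#' assumed depth-averaged over 0-10 m, in micromolar.
#'
#' @param nutrients data frame with columns `date`, `no3`, `no2`, `nh4`,
#'   `po4`, `sio4` (micromolar).
#' @param kind `"DIN"`, `"DIP"` or `"silicate"`.
#' @param years target years.
#' @return a [covariate_series]; years without winter records are `NA` with
#'   a warning.
#' @export
winter_nutrient_series <- function(nutrients, kind = c("DIN", "DIP", "silicate"),
                                   years) {
  kind <- match.arg(kind)
  d <- as.Date(nutrients$date)
  mth <- as.integer(format(d, "%m"))
  yr <- as.integer(format(d, "%Y"))
  target <- ifelse(mth >= 11, yr + 1L, ifelse(mth <= 3, yr, NA_integer_))
  value <- switch(kind,
                  DIN = nutrients$no3 + nutrients$no2 + nutrients$nh4,
                  DIP = nutrients$po4,
                  silicate = nutrients$sio4)
  ann <- vapply(years, function(y) {
    sel <- !is.na(target) & target == y
    if (!any(sel)) NA_real_ else mean(value[sel])
  }, numeric(1))
  if (anyNA(ann))
    warning(sprintf("no winter nutrient records for year(s): %s",
                    paste(years[is.na(ann)], collapse = ", ")))
  covariate_series(kind, years, ann)
}

#' Annual count covariate (e.g. ice days) or linear trend
#'
#' Wraps already-annual values (such as the number of days with more than
#' 10% ice cover) as a z-scored [covariate_series].  `trend_series()` builds
#' the z-scored study-year covariate used as the uniform temporal trend in
#' every dynamic model.
#'
#' @param values annual values aligned with `years`.
#' @param years integer years.
#' @param name covariate name (default `"ice"`).
#' @return a [covariate_series].
#' @export
annual_covariate <- function(values, years, name = "ice") {
  covariate_series(name, years, values)
}

#' @rdname annual_covariate
#' @export
trend_series <- function(years) {
  covariate_series("trend", years, as.numeric(years))
}
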