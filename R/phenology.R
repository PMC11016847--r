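#' Aggregate hourly logger temperatures to daily climate
#'
#' Collapses an hourly air-temperature series to per-day mean, minimum,
#' maximum and within-day standard deviation, plus the number of hours in the
#' chilling band (used by the dormancy trajectory generator). Days with fewer
#' than 20 hourly readings are retained but marked incomplete; no gap
#' imputation is performed.
#'
#' @param temps Data frame with columns `site`, `datetime` (POSIXct or
#'   ISO-8601 string) and `temp_c`. Timestamps must be strictly increasing
#'   within a site; temperatures outside \[-50, 50\] degrees C are rejected.
#' @param chill_band Numeric length-2: temperature band (degrees C, inclusive)
#'   within which an hour counts as a chilling hour. Default \[0, 10\].
#' @return Data frame with one row per site x date: `site`, `date`, `mean_c`,
#'   `min_c`, `max_c`, `sd_c`, `n_hours`, `chill_hours`, `complete`.
#' @export
aggregate_daily <- function(temps, chill_band = c(0, 10)) {
  if (is.null(temps) || nrow(temps) == 0) stop("empty temperature series", call. = FALSE)
  stopifnot(all(c("site", "datetime", "temp_c") %in% names(temps)))
  if (!inherits(temps$datetime, "POSIXct")) {
    temps$datetime <- as.POSIXct(temps$datetime, tz = "UTC")
  }
  if (any(is.na(temps$datetime))) stop("unparseable datetimes in temperature series", call. = FALSE)
  bad <- which(temps$temp_c < -50 | temps$temp_c > 50)
  if (length(bad)) {
    stop("temperature outside the [-50, 50] C sanity band at rows ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  for (s in unique(temps$site)) {
    ts <- temps$datetime[temps$site == s]
    if (is.unsorted(ts, strictly = TRUE)) {
      stop("timestamps not strictly increasing for site '", s, "'", call. = FALSE)
    }
  }
  temps$date <- as.Date(temps$datetime, tz = "UTC")
  sp <- split(temps, list(temps$site, temps$date), drop = TRUE)
  rows <- lapply(sp, function(d) {
    n <- nrow(d)
    data.frame(
      site = d$site[1], date = d$date[1],
      mean_c = mean(d$temp_c), min_c = min(d$temp_c), max_c = max(d$temp_c),
      sd_c = if (n > 1) stats::sd(d$temp_c) else 0,
      n_hours = n,
      chill_hours = sum(d$temp_c >= chill_band[1] & d$temp_c <= chill_band[2]),
      complete = n >= 20
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$site, out$date), ]
  rownames(out) <- NULL
  out
}

#' Period climate summary
#'
#' Mean of daily mean temperatures and mean of within-day standard deviations
#' over a date range, per site — the "period mean +/- average daily sd" way of
#' characterising a site's winter.
#'
#' @param daily Output of [aggregate_daily()].
#' @param from,to Optional date range (inclusive); defaults to the full span.
#' @return Data frame with `site`, `mean_of_daily_means_c`,
#'   `mean_of_daily_sds_c`, `n_days`.
#' @export
climate_period_summary <- function(daily, from = NULL, to = NULL) {
  if (!is.null(from)) daily <- daily[daily$date >= as.Date(from), ]
  if (!is.null(to)) daily <- daily[daily$date <= as.Date(to), ]
  if (nrow(daily) == 0) stop("no days in the requested period", call. = FALSE)
  sp <- split(daily, daily$site)
  out <- do.call(rbind, lapply(sp, function(d) data.frame(
    site = d$site[1],
    mean_of_daily_means_c = mean(d$mean_c),
    mean_of_daily_sds_c = mean(d$sd_c),
    n_days = nrow(d)
  )))
  rownames(out) <- NULL
  out
}

#' First frost date
#'
#' Earliest date on which the daily minimum (or daily mean) temperature drops
#' below 0 degrees C. The first-frost date is used to restrict the
#' dormancy-depth model to campaigns after dormancy induction.
#'
#' @param daily Output of [aggregate_daily()] (one site, or pre-filtered).
#' @param mode `"min_below_0"` (default) or `"mean_below_0"`.
#' @return A `Date`, or `NA` if no day qualifies.
#' @export
first_frost_date <- function(daily, mode = c("min_below_0", "mean_below_0")) {
  mode <- match.arg(mode)
  if (nrow(daily) == 0) stop("empty daily series", call. = FALSE)
  daily <- daily[order(daily$date), ]
  hit <- if (mode == "min_below_0") daily$min_c < 0 else daily$mean_c < 0
  if (!any(hit)) return(as.Date(NA))
  daily$date[which(hit)[1]]
}

#' Budburst success fraction
#'
#' Fraction of a twig's buds that reached at least the budburst stage
#' (stage 2 on the 0-4 phenological scale), assessed two weeks after the
#' earliest bud reached stage 4 (or at experiment end).
#'
#' @param n_buds_ge_stage2 Count of buds at stage >= 2.
#' @param n_buds_total Total bud count (must be >= 1).
#' @return Proportion in \[0, 1\] (vectorized).
#' @export
budburst_success <- function(n_buds_ge_stage2, n_buds_total) {
  if (any(n_buds_total < 1)) stop("n_buds_total must be >= 1", call. = FALSE)
  if (any(n_buds_ge_stage2 < 0 | n_buds_ge_stage2 > n_buds_total)) {
    stop("n_buds_ge_stage2 must lie in [0, n_buds_total]", call. = FALSE)
  }
  n_buds_ge_stage2 / n_buds_total
}

#' Thermal time to budburst under constant forcing
#'
#' Converts per-twig stage-transition calendars into budburst outcomes. Under
#' a constant forcing temperature the thermal time (degree-days above the base
#' temperature) accumulated until the first bud reaches stage 2 measures the
#' twig's dormancy depth: deeply dormant twigs need many degree-days, released
#' ones few. Twigs that never reach stage 2 are censored: they carry a success
#' fraction but no thermal time.
#'
#' @param phenology Data frame with one row per twig: columns `twig_id`,
#'   `tree_id`, `species`, `site`, `campaign_date`, `forcing_start_date`,
#'   `stage2_date` (`NA` when never reached), `n_buds_total`,
#'   `n_buds_ge_stage2`. Date columns may be `Date` or ISO-8601 strings.
#' @param forcing_temp_c Constant forcing temperature (degrees C, default 20).
#' @param base_temp_c Base temperature for degree-day accumulation (default 0,
#'   so thermal time is simply days x forcing temperature).
#' @return Data frame of budburst outcomes: the identifying columns plus
#'   `success_fraction`, `days_to_stage2`, `thermal_time_dd`, `censored` and
#'   `suspicious_zero_days` (stage 2 recorded on the forcing start day).
#' @export
thermal_time_to_budburst <- function(phenology, forcing_temp_c = 20,
                                     base_temp_c = 0) {
  if (forcing_temp_c <= base_temp_c) {
    stop("forcing_temp_c must exceed base_temp_c", call. = FALSE)
  }
  ph <- phenology
  for (col in c("campaign_date", "forcing_start_date", "stage2_date")) {
    if (!inherits(ph[[col]], "Date")) ph[[col]] <- as.Date(ph[[col]])
  }
  if (any(ph$forcing_start_date < ph$campaign_date, na.rm = TRUE)) {
    stop("forcing_start_date before campaign_date", call. = FALSE)
  }
  early <- which(!is.na(ph$stage2_date) & ph$stage2_date < ph$forcing_start_date)
  if (length(early)) {
    stop("stage-2 date before forcing start for twig(s): ",
         paste(utils::head(ph$twig_id[early], 5), collapse = ", "), call. = FALSE)
  }
  days <- as.numeric(ph$stage2_date - ph$forcing_start_date)
  censored <- is.na(ph$stage2_date)
  data.frame(
    twig_id = ph$twig_id, tree_id = ph$tree_id, species = ph$species,
    site = ph$site, campaign_date = ph$campaign_date,
    success_fraction = budburst_success(ph$n_buds_ge_stage2, ph$n_buds_total),
    n_buds_total = ph$n_buds_total, n_buds_ge_stage2 = ph$n_buds_ge_stage2,
    days_to_stage2 = ifelse(censored, NA_real_, days),
    thermal_time_dd = ifelse(censored, NA_real_,
                             days * (forcing_temp_c - base_temp_c)),
    censored = censored,
    suspicious_zero_days = !censored & days == 0
  )
}

#' Bud water content from fresh and dry masses
#'
#' Water content of a bud weighed before (`fresh`) and after (`dry`) complete
#' water extraction. The default fresh-mass basis, `100 * (fresh - dry) /
#' fresh`, keeps values in \[0, 100) consistent with the ~40-57% range typical
#' of temperate-tree winter buds; a dry-mass basis is available.
#'
#' @param fresh_mass_mg,dry_mass_mg Masses in mg; `0 < dry <= fresh` required.
#' @param basis `"fresh"` (default) or `"dry"`.
#' @param sample_id Optional identifiers for error messages.
#' @return Water content percentage (vectorized).
#' @export
bud_water_content <- function(fresh_mass_mg, dry_mass_mg,
                              basis = c("fresh", "dry"), sample_id = NULL) {
  basis <- match.arg(basis)
  bad <- which(dry_mass_mg <= 0 | dry_mass_mg > fresh_mass_mg)
  if (length(bad)) {
    who <- if (!is.null(sample_id)) paste(sample_id[bad], collapse = ", ")
           else paste("positions", paste(bad, collapse = ", "))
    stop("invalid masses (need 0 < dry <= fresh) for ", who, call. = FALSE)
  }
  denom <- if (basis == "fresh") fresh_mass_mg else dry_mass_mg
  100 * (fresh_mass_mg - dry_mass_mg) / denom
}
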