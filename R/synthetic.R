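#' Site parameters for the temperature generator
#'
#' Describes one site's climate: an annual seasonal sinusoid, a diurnal
#' sinusoid and AR(1) hour-to-hour noise. The default pair of sites (see
#' [default_sites()]) differs by 2.3 degrees C, emulating a low-elevation /
#' high-elevation contrast of roughly 500 m.
#'
#' @param name Site label.
#' @param annual_mean_c Annual mean air temperature (degrees C).
#' @param seasonal_amplitude_c Amplitude of the annual sinusoid (degrees C).
#' @param diurnal_amplitude_c Amplitude of the day-night sinusoid (degrees C).
#' @param ar1_coefficient AR(1) coefficient of the hourly noise, in \[0, 1).
#' @param noise_sd_c Stationary standard deviation of the hourly noise.
#' @param site_offset_c Additive offset applied to the whole series.
#' @return An object of class `site_params`.
#' @export
site_params <- function(name, annual_mean_c, seasonal_amplitude_c = 8.5,
                        diurnal_amplitude_c = 3, ar1_coefficient = 0.8,
                        noise_sd_c = 2, site_offset_c = 0) {
  stopifnot(seasonal_amplitude_c >= 0, diurnal_amplitude_c >= 0,
            ar1_coefficient >= 0, ar1_coefficient < 1, noise_sd_c >= 0)
  structure(list(name = name, annual_mean_c = annual_mean_c,
                 seasonal_amplitude_c = seasonal_amplitude_c,
                 diurnal_amplitude_c = diurnal_amplitude_c,
                 ar1_coefficient = ar1_coefficient, noise_sd_c = noise_sd_c,
                 site_offset_c = site_offset_c),
            class = "site_params")
}

#' Default site pair
#'
#' A milder lowland site and a highland site 2.3 degrees C colder, the
#' elevational contrast typical of paired phenology sites ~500 m apart in
#' altitude.
#'
#' @return Named list of two [site_params()].
#' @export
default_sites <- function() {
  list(
    lowland = site_params("lowland", annual_mean_c = 10.9),
    highland = site_params("highland", annual_mean_c = 8.6)
  )
}

#' Species parameters for the dormancy generator
#'
#' Encodes one species' chilling-forcing behaviour and seasonal trajectories:
#' chilling hours needed to release endodormancy, degree-day requirement once
#' released, the exponential decline of dormancy depth with chilling, budburst
#' success limits, the senescence-time uptake peak and winter floor, the
#' natural-abundance isotope line (slope below the meteoric water line, as
#' evaporative enrichment produces), and the autumn/winter/spring water
#' content plateaus with a pre-budburst rise.
#'
#' @param name Species label.
#' @param chill_requirement_h Chilling hours (in the chilling band) releasing
#'   endodormancy.
#' @param forcing_requirement_dd Degree-days to budburst once fully released.
#' @param initial_depth_dd Autumn dormancy depth (degree-days) before any
#'   chilling.
#' @param depth_decay_rate Per-chilling-hour decline rate of log dormancy
#'   depth.
#' @param base_success,max_success Budburst success probability before any /
#'   after full chilling.
#' @param senescence_window Length-2 `Date` (or string) range of leaf
#'   senescence; the uptake peak sits at its midpoint.
#' @param background_beta0,background_beta1 Intercept (per mil) and slope of
#'   the species' natural-abundance d18O -> d2H line; slope must be in (0, 8].
#' @param d18O_mean Mean natural-abundance d18O of bud water (per mil).
#' @param uptake_peak_pct,uptake_floor_pct Senescence peak and winter floor of
#'   short-term uptake (percent).
#' @param prebudburst_uptake_rise_pct Extra uptake at campaigns within a month
#'   of natural budburst (0 for species without a spring rise).
#' @param wc_autumn_pct,wc_winter_pct,wc_spring_pct Water-content plateaus.
#' @param wc_rise_lead_days Lead of the water-content rise before natural
#'   budburst (default 45 d, i.e. about 6-8 weeks).
#' @param natural_budburst_doy Day-of-year of natural budburst in spring.
#' @return An object of class `species_params`.
#' @export
species_params <- function(name, chill_requirement_h, forcing_requirement_dd,
                           initial_depth_dd, depth_decay_rate,
                           base_success, max_success,
                           senescence_window,
                           background_beta0, background_beta1, d18O_mean,
                           uptake_peak_pct, uptake_floor_pct,
                           prebudburst_uptake_rise_pct = 0,
                           wc_autumn_pct, wc_winter_pct, wc_spring_pct,
                           wc_rise_lead_days = 45,
                           natural_budburst_doy = 110) {
  stopifnot(base_success >= 0, base_success <= max_success, max_success <= 1,
            uptake_floor_pct < uptake_peak_pct,
            background_beta1 > 0, background_beta1 <= 8,
            initial_depth_dd >= forcing_requirement_dd)
  structure(list(
    name = name, chill_requirement_h = chill_requirement_h,
    forcing_requirement_dd = forcing_requirement_dd,
    initial_depth_dd = initial_depth_dd, depth_decay_rate = depth_decay_rate,
    base_success = base_success, max_success = max_success,
    senescence_window = as.Date(senescence_window),
    background_beta0 = background_beta0, background_beta1 = background_beta1,
    d18O_mean = d18O_mean,
    uptake_peak_pct = uptake_peak_pct, uptake_floor_pct = uptake_floor_pct,
    prebudburst_uptake_rise_pct = prebudburst_uptake_rise_pct,
    wc_autumn_pct = wc_autumn_pct, wc_winter_pct = wc_winter_pct,
    wc_spring_pct = wc_spring_pct, wc_rise_lead_days = wc_rise_lead_days,
    natural_budburst_doy = natural_budburst_doy
  ), class = "species_params")
}

#' Default five-species set
#'
#' Five deciduous broadleaf species with contrasting chilling requirements and
#' dormancy behaviour: two low-chill species able to burst throughout winter
#' (beech- and oak-like), two high-chill species with near-zero autumn success
#' (maple- and lime-like) and one intermediate species with a fast decline in
#' dormancy depth and an elevated winter uptake floor (hornbeam-like). Water
#' content plateaus span the ~40 percent (oak) to ~57 percent (lime) winter
#' range; isotope line slopes sit between 5 and 6.5, below the meteoric water
#' line slope of 8. Only the beech- and lime-like species get a pre-budburst
#' uptake rise.
#'
#' @return Named list of five [species_params()].
#' @export
default_species <- function() {
  list(
    maple = species_params(
      "maple", chill_requirement_h = 2400, forcing_requirement_dd = 260,
      initial_depth_dd = 1400, depth_decay_rate = 5.6e-4,
      base_success = 0.05, max_success = 0.70,
      senescence_window = c("2019-10-18", "2019-11-10"),
      background_beta0 = -22, background_beta1 = 5.5, d18O_mean = -10,
      uptake_peak_pct = 50, uptake_floor_pct = 1.5,
      wc_autumn_pct = 52, wc_winter_pct = 48, wc_spring_pct = 58,
      natural_budburst_doy = 118),
    hornbeam = species_params(
      "hornbeam", chill_requirement_h = 1800, forcing_requirement_dd = 140,
      initial_depth_dd = 1000, depth_decay_rate = 9e-4,
      base_success = 0.30, max_success = 0.90,
      senescence_window = c("2019-10-22", "2019-11-12"),
      background_beta0 = -28, background_beta1 = 6.0, d18O_mean = -9.5,
      uptake_peak_pct = 70, uptake_floor_pct = 4,
      wc_autumn_pct = 53, wc_winter_pct = 49, wc_spring_pct = 60,
      natural_budburst_doy = 105),
    beech = species_params(
      "beech", chill_requirement_h = 800, forcing_requirement_dd = 240,
      initial_depth_dd = 1300, depth_decay_rate = 5.3e-4,
      base_success = 0.50, max_success = 0.95,
      senescence_window = c("2019-10-25", "2019-11-15"),
      background_beta0 = -25, background_beta1 = 5.2, d18O_mean = -10.5,
      uptake_peak_pct = 45, uptake_floor_pct = 1.5,
      prebudburst_uptake_rise_pct = 12,
      wc_autumn_pct = 48, wc_winter_pct = 43, wc_spring_pct = 55,
      natural_budburst_doy = 112),
    oak = species_params(
      "oak", chill_requirement_h = 900, forcing_requirement_dd = 180,
      initial_depth_dd = 900, depth_decay_rate = 5.4e-4,
      base_success = 0.15, max_success = 0.50,
      senescence_window = c("2019-10-24", "2019-11-14"),
      background_beta0 = -30, background_beta1 = 6.4, d18O_mean = -9,
      uptake_peak_pct = 40, uptake_floor_pct = 1.5,
      wc_autumn_pct = 43, wc_winter_pct = 40, wc_spring_pct = 50,
      natural_budburst_doy = 120),
    lime = species_params(
      "lime", chill_requirement_h = 2200, forcing_requirement_dd = 150,
      initial_depth_dd = 1100, depth_decay_rate = 7.1e-4,
      base_success = 0.02, max_success = 0.80,
      senescence_window = c("2019-10-20", "2019-11-08"),
      background_beta0 = -26, background_beta1 = 5.8, d18O_mean = -10,
      uptake_peak_pct = 55, uptake_floor_pct = 2,
      prebudburst_uptake_rise_pct = 12,
      wc_autumn_pct = 59, wc_winter_pct = 57, wc_spring_pct = 66,
      natural_budburst_doy = 108)
  )
}

#' Default campaign calendar
#'
#' Twelve main sampling campaigns, roughly fortnightly from mid-October to the
#' start of April, plus three extra mid-winter campaigns (uptake and water
#' content only) giving 15 campaigns in total; the ninth falls on 24 January.
#'
#' @return List with `main` (12 dates), `extra` (3 dates) and `background`
#'   (3 natural-abundance dates in the following winter).
#' @export
default_campaigns <- function() {
  list(
    main = as.Date(c("2019-10-10", "2019-10-23", "2019-11-06", "2019-11-27",
                     "2019-12-11", "2019-12-27", "2020-01-10", "2020-01-24",
                     "2020-02-07", "2020-02-21", "2020-03-06", "2020-04-01")),
    extra = as.Date(c("2020-01-17", "2020-01-31", "2020-02-14")),
    background = as.Date(c("2021-01-21", "2021-02-10", "2021-03-04"))
  )
}

#' Synthetic experiment configuration
#'
#' Bundles every generator parameter: sites, species, campaign calendar,
#' per-site tree count, instrument and biological noise levels, the label
#' specification and isotope constants, and the master seed. The defaults
#' describe the emulated study design: 2 sites, 5 species, 5 trees per
#' species and site, 12 + 3 campaigns, IRMS precision 1 per mil (d2H) and
#' 0.2 per mil (d18O).
#'
#' @param seed Integer master seed; recorded in all outputs.
#' @param n_trees_per_species_site Trees per species at each site (default 5).
#' @param campaigns Campaign calendar as from [default_campaigns()].
#' @param sites Named list of [site_params()].
#' @param species Named list of [species_params()].
#' @param noise Named list: `d2H_sd` (1 per mil), `d18O_sd` (0.2 per mil),
#'   `wc_sd_pct`, `uptake_sd_pct`, `tt_sd_log` (lognormal sd of thermal time),
#'   `d18O_bio_sd` (biological spread of natural-abundance d18O, not an
#'   instrument term and therefore never zeroed by "noise-free" runs of the
#'   instrument noise).
#' @param label A [label_spec()].
#' @param constants An [isotope_constants()].
#' @param chill_band Chilling band in degrees C (default c(0, 10)).
#' @param forcing_temp_c,base_temp_c Forcing assay temperatures.
#' @param season Length-2 date range the temperature loggers cover.
#' @param n_buds_range Range of bud counts per twig.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       n_trees_per_species_site = 5,
                       campaigns = default_campaigns(),
                       sites = default_sites(),
                       species = default_species(),
                       noise = list(d2H_sd = 1, d18O_sd = 0.2,
                                    wc_sd_pct = 2, uptake_sd_pct = 3,
                                    tt_sd_log = 0.15, d18O_bio_sd = 1.2),
                       label = label_spec(),
                       constants = isotope_constants(),
                       chill_band = c(0, 10),
                       forcing_temp_c = 20, base_temp_c = 0,
                       season = c("2019-10-01", "2020-04-30"),
                       n_buds_range = c(8, 14)) {
  all_dates <- sort(c(campaigns$main, campaigns$extra))
  if (any(duplicated(all_dates)) || is.unsorted(all_dates, strictly = TRUE)) {
    stop("campaign dates must be strictly increasing and unique", call. = FALSE)
  }
  structure(list(
    seed = as.integer(seed),
    n_trees_per_species_site = n_trees_per_species_site,
    campaigns = campaigns, sites = sites, species = species, noise = noise,
    label = label, constants = constants, chill_band = chill_band,
    forcing_temp_c = forcing_temp_c, base_temp_c = base_temp_c,
    season = as.Date(season), n_buds_range = n_buds_range
  ), class = "sim_config")
}

#' Simulate an hourly site temperature series
#'
#' Hourly air temperature as annual sinusoid (coldest in mid-January) plus
#' diurnal sinusoid (warmest mid-afternoon) plus stationary AR(1) noise.
#'
#' @param site A [site_params()].
#' @param start,end Date range (inclusive), at least 30 days.
#' @param seed Optional seed; when `NULL` the ambient RNG stream is used (as
#'   [simulate_experiment()] does under its master seed).
#' @return Data frame with `site`, `datetime` (POSIXct UTC), `temp_c`.
#' @export
simulate_temperatures <- function(site, start, end, seed = NULL) {
  stopifnot(inherits(site, "site_params"))
  start <- as.Date(start); end <- as.Date(end)
  if (as.numeric(end - start) < 30) stop("date range must span >= 30 days", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  dt <- seq(as.POSIXct(paste(start, "00:00:00"), tz = "UTC"),
            as.POSIXct(paste(end, "23:00:00"), tz = "UTC"), by = "hour")
  doy <- as.numeric(strftime(dt, "%j", tz = "UTC")) +
    as.numeric(strftime(dt, "%H", tz = "UTC")) / 24
  hour <- as.numeric(strftime(dt, "%H", tz = "UTC"))
  seasonal <- site$seasonal_amplitude_c * cos(2 * pi * (doy - 205) / 365.25)
  diurnal <- site$diurnal_amplitude_c * sin(2 * pi * (hour - 9) / 24)
  n <- length(dt)
  innov_sd <- site$noise_sd_c * sqrt(1 - site$ar1_coefficient^2)
  noise <- as.numeric(stats::filter(stats::rnorm(n, 0, innov_sd),
                                    site$ar1_coefficient, method = "recursive"))
  data.frame(site = site$name, datetime = dt,
             temp_c = site$annual_mean_c + site$site_offset_c + seasonal +
               diurnal + noise)
}

#' Latent dormancy trajectory of a species at a site
#'
#' Accumulates chilling hours (hours within the chilling band, carried by the
#' `chill_hours` column of [aggregate_daily()] output) and derives, at each
#' campaign date, the latent dormancy state: log dormancy depth declines
#' linearly with accumulated chilling from the autumn level towards the
#' forcing requirement, endodormancy is released once the chilling requirement
#' is met, and budburst success probability rises from its base to its maximum
#' in proportion to chilling progress. Deterministic given the climate.
#'
#' @param species A [species_params()].
#' @param daily Daily climate for one site from [aggregate_daily()] (must
#'   carry `chill_hours`).
#' @param campaign_dates Campaign dates (must be covered by `daily`).
#' @return Data frame with `campaign_date`, `chill_accum_h`,
#'   `dormancy_depth_dd`, `released`, `p_success`.
#' @export
simulate_dormancy_trajectory <- function(species, daily, campaign_dates) {
  stopifnot(inherits(species, "species_params"),
            "chill_hours" %in% names(daily))
  campaign_dates <- as.Date(campaign_dates)
  if (max(campaign_dates) > max(daily$date) + 1) {
    stop("daily climate does not cover all campaigns", call. = FALSE)
  }
  daily <- daily[order(daily$date), ]
  chill <- vapply(campaign_dates, function(d) {
    sum(daily$chill_hours[daily$date < d])
  }, numeric(1))
  depth <- pmax(species$forcing_requirement_dd,
                species$initial_depth_dd * exp(-species$depth_decay_rate * chill))
  # success tracks the decline of dormancy depth itself: shallower dormancy,
  # higher fraction of buds able to burst
  progress <- (species$initial_depth_dd - depth) /
    (species$initial_depth_dd - species$forcing_requirement_dd)
  data.frame(
    campaign_date = campaign_dates,
    chill_accum_h = chill,
    dormancy_depth_dd = depth,
    released = chill >= species$chill_requirement_h,
    p_success = species$base_success +
      (species$max_success - species$base_success) * progress
  )
}

# Seasonal truth curves ---------------------------------------------------

.uptake_truth <- function(species, date) {
  date <- as.Date(date)
  sw <- species$senescence_window
  peak_date <- sw[1] + as.numeric(sw[2] - sw[1]) / 2
  sd_days <- as.numeric(sw[2] - sw[1]) / 3
  u <- species$uptake_floor_pct +
    (species$uptake_peak_pct - species$uptake_floor_pct) *
    exp(-0.5 * ((as.numeric(date - peak_date)) / sd_days)^2)
  bb <- as.Date(sprintf("2020-01-01")) + species$natural_budburst_doy - 1
  rise <- ifelse(date >= bb - 30 & date < bb,
                 species$prebudburst_uptake_rise_pct, 0)
  u + rise
}

.wc_truth <- function(species, date) {
  date <- as.Date(date)
  sen_end <- species$senescence_window[2]
  bb <- as.Date("2020-01-01") + species$natural_budburst_doy - 1
  rise_start <- bb - species$wc_rise_lead_days
  decline_len <- 21
  w <- numeric(length(date))
  for (i in seq_along(date)) {
    d <- date[i]
    if (d <= sen_end) {
      w[i] <- species$wc_autumn_pct
    } else if (d <= sen_end + decline_len) {
      f <- as.numeric(d - sen_end) / decline_len
      w[i] <- species$wc_autumn_pct +
        f * (species$wc_winter_pct - species$wc_autumn_pct)
    } else if (d < rise_start) {
      # slow creep through winter (deacclimation), up to 35% of the spring gain
      f <- 0.35 * as.numeric(d - (sen_end + decline_len)) /
        max(1, as.numeric(rise_start - (sen_end + decline_len)))
      w[i] <- species$wc_winter_pct +
        f * (species$wc_spring_pct - species$wc_winter_pct)
    } else {
      f <- 0.35 + 0.65 * min(1, as.numeric(d - rise_start) /
                               species$wc_rise_lead_days)
      w[i] <- species$wc_winter_pct +
        f * (species$wc_spring_pct - species$wc_winter_pct)
    }
  }
  w
}

# Natural-abundance sample generator; draws from the ambient RNG stream.
.background_samples <- function(config) {
  rows <- list()
  drift <- c(0, 5, 10)  # d18O enrichment across the three winter campaigns
  for (sp_name in names(config$species)) {
    sp <- config$species[[sp_name]]
    for (site_name in names(config$sites)) {
      for (tree in seq_len(config$n_trees_per_species_site)) {
        tree_id <- sprintf("%s_%s_T%02d", site_name, sp_name, tree)
        for (ci in seq_along(config$campaigns$background)) {
          d18_true <- sp$d18O_mean + drift[ci] +
            stats::rnorm(1, 0, config$noise$d18O_bio_sd)
          d2_true <- sp$background_beta0 + sp$background_beta1 * d18_true
          rows[[length(rows) + 1]] <- data.frame(
            sample_id = sprintf("NA_%s_C%d", tree_id, ci),
            species = sp_name, site = site_name, tree_id = tree_id,
            campaign_date = config$campaigns$background[ci],
            tissue = "bud",
            d2H = d2_true + stats::rnorm(1, 0, config$noise$d2H_sd),
            d18O = d18_true + stats::rnorm(1, 0, config$noise$d18O_sd),
            is_labelled = FALSE,
            d2H_true = d2_true, d18O_true = d18_true
          )
        }
      }
    }
  }
  do.call(rbind, rows)
}

#' Simulate natural-abundance background samples only
#'
#' Generates the three-winter-campaign natural-abundance isotope dataset (the
#' input to [fit_background_lines()]) without the rest of the experiment;
#' used for background-line parameter-recovery studies.
#'
#' @param config A [sim_config()].
#' @param seed Optional seed overriding `config$seed`.
#' @return Isotope table including the latent `d2H_true`, `d18O_true` columns.
#' @export
simulate_background_samples <- function(config = sim_config(), seed = NULL) {
  set.seed(if (is.null(seed)) config$seed else seed)
  .background_samples(config)
}

#' Simulate a complete labelling experiment
#'
#' Generates the full synthetic dataset bundle: hourly temperatures for both
#' sites, per-twig forcing-assay phenology at the 12 main campaigns, bud
#' fresh/dry masses, labelled-bud (all 15 campaigns) and labelled-twig-tissue
#' (campaign 9) isotope samples, natural-abundance background samples, and a
#' truth table recording every latent per-sample value for recovery tests.
#'
#' Labelled deltas are constructed on the atom-fraction scale — the latent
#' per-sample uptake mixes the background and label atom percents, and the
#' mixture is inverted back to a delta before instrument noise is added — so
#' the excess-label arithmetic applied to noise-free data recovers the
#' programmed uptake exactly.
#'
#' @param config A [sim_config()].
#' @return A list of class `isobud_simulation`: `temps`, `phenology`, `mass`,
#'   `isotopes`, `truth`, `trajectories`, `config`.
#' @export
simulate_experiment <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  cs <- config$campaigns
  all_dates <- sort(c(cs$main, cs$extra))
  campaign_index <- stats::setNames(seq_along(all_dates), as.character(all_dates))
  r2h <- config$constants$r_standard_2h
  ap_label <- delta_to_atom_percent(config$label$d2h_label, r2h)
  dd_per_day <- config$forcing_temp_c - config$base_temp_c
  # twice-weekly monitoring grid (days since forcing start)
  monitor_days <- sort(c(seq(0, 133, by = 7), seq(3, 133, by = 7)))
  max_forcing_days <- max(monitor_days)

  temps <- do.call(rbind, lapply(config$sites, function(st) {
    simulate_temperatures(st, config$season[1], config$season[2])
  }))
  rownames(temps) <- NULL
  daily <- aggregate_daily(temps, chill_band = config$chill_band)

  traj <- list()
  for (sp_name in names(config$species)) {
    for (site_name in names(config$sites)) {
      tr <- simulate_dormancy_trajectory(
        config$species[[sp_name]], daily[daily$site == site_name, ], all_dates)
      tr$species <- sp_name
      tr$site <- site_name
      traj[[paste(sp_name, site_name)]] <- tr
    }
  }

  phen <- list(); mass <- list(); iso <- list(); truth <- list()
  for (sp_name in names(config$species)) {
    sp <- config$species[[sp_name]]
    for (site_name in names(config$sites)) {
      tr <- traj[[paste(sp_name, site_name)]]
      for (tree in seq_len(config$n_trees_per_species_site)) {
        tree_id <- sprintf("%s_%s_T%02d", site_name, sp_name, tree)
        # tree-level biology, shared across that tree's campaigns
        tree_log_depth <- stats::rnorm(1, 0, 0.08)
        tree_logit_succ <- stats::rnorm(1, 0, 0.4)
        tree_wc <- stats::rnorm(1, 0, 1.2)
        tree_uptake <- stats::rnorm(1, 0, 1.5)
        for (cd in as.character(all_dates)) {
          date <- as.Date(cd)
          ci <- campaign_index[[cd]]
          row_tr <- tr[tr$campaign_date == date, ]
          is_main <- date %in% cs$main

          if (is_main) {
            twig_id <- sprintf("%s_C%02d_tw", tree_id, ci)
            tt_true <- row_tr$dormancy_depth_dd *
              exp(tree_log_depth + stats::rnorm(1, 0, config$noise$tt_sd_log))
            days_true <- tt_true / dd_per_day
            p <- stats::plogis(stats::qlogis(
              pmin(pmax(row_tr$p_success, 1e-3), 1 - 1e-3)) + tree_logit_succ)
            n_buds <- sample(seq(config$n_buds_range[1],
                                 config$n_buds_range[2]), 1)
            n_ge2 <- stats::rbinom(1, n_buds, p)
            overrun <- days_true > max_forcing_days
            censored <- n_ge2 == 0 || overrun
            if (overrun) n_ge2 <- 0
            forcing_start <- date + 1
            if (!censored) {
              obs_day <- monitor_days[which(monitor_days >= days_true)[1]]
              s2 <- forcing_start + obs_day
              s1 <- s2 - 3; s3 <- s2 + 6; s4 <- s2 + 12
            } else {
              s1 <- s2 <- s3 <- s4 <- as.Date(NA)
            }
            phen[[length(phen) + 1]] <- data.frame(
              twig_id = twig_id, tree_id = tree_id, species = sp_name,
              site = site_name, campaign_date = date,
              forcing_start_date = forcing_start,
              stage1_date = s1, stage2_date = s2, stage3_date = s3,
              stage4_date = s4,
              n_buds_total = n_buds, n_buds_ge_stage2 = n_ge2
            )
          }

          # labelled bud sample (all 15 campaigns)
          sample_id <- sprintf("%s_C%02d_bud", tree_id, ci)
          u_true <- .uptake_truth(sp, date) + tree_uptake +
            stats::rnorm(1, 0, config$noise$uptake_sd_pct)
          u_true <- min(max(u_true, 0), 100)
          d18_true <- sp$d18O_mean + 3 * pmax(0, as.numeric(date - cs$main[1])) / 180 +
            stats::rnorm(1, 0, config$noise$d18O_bio_sd)
          d2_bg_true <- sp$background_beta0 + sp$background_beta1 * d18_true
          ap_bg <- delta_to_atom_percent(d2_bg_true, r2h)
          ap_s <- ap_bg + u_true / 100 * (ap_label - ap_bg)
          d2_s_true <- atom_percent_to_delta(ap_s, r2h)
          iso[[length(iso) + 1]] <- data.frame(
            sample_id = sample_id, species = sp_name, site = site_name,
            tree_id = tree_id, campaign_date = date, tissue = "bud",
            d2H = d2_s_true + stats::rnorm(1, 0, config$noise$d2H_sd),
            d18O = d18_true + stats::rnorm(1, 0, config$noise$d18O_sd),
            is_labelled = TRUE, d2H_true = d2_s_true, d18O_true = d18_true
          )
          wc_true <- .wc_truth(sp, date) + tree_wc +
            stats::rnorm(1, 0, config$noise$wc_sd_pct)
          wc_true <- min(max(wc_true, 1), 99)
          fresh <- max(8, stats::rnorm(1, 30, 5))
          mass[[length(mass) + 1]] <- data.frame(
            sample_id = sample_id, species = sp_name, site = site_name,
            tree_id = tree_id, campaign_date = date,
            fresh_mass_mg = fresh, dry_mass_mg = fresh * (1 - wc_true / 100)
          )
          truth[[length(truth) + 1]] <- data.frame(
            sample_id = sample_id, species = sp_name, site = site_name,
            tree_id = tree_id, campaign_date = date, campaign_index = ci,
            tissue = "bud", uptake_true_pct = u_true, wc_true_pct = wc_true,
            dormancy_depth_dd = row_tr$dormancy_depth_dd,
            chill_accum_h = row_tr$chill_accum_h, released = row_tr$released
          )

          # twig-tissue labelled sample at campaign 9 (coldest mid-winter date)
          if (ci == 9) {
            tsample <- sprintf("%s_C%02d_twigtissue", tree_id, ci)
            u_twig <- min(max(.uptake_truth(sp, date) + 10 + tree_uptake +
                                stats::rnorm(1, 0, config$noise$uptake_sd_pct),
                              0), 100)
            d18_tw <- d18_true + stats::rnorm(1, 0, 0.5)
            d2_bg_tw <- sp$background_beta0 + sp$background_beta1 * d18_tw
            ap_bg_tw <- delta_to_atom_percent(d2_bg_tw, r2h)
            d2_tw <- atom_percent_to_delta(
              ap_bg_tw + u_twig / 100 * (ap_label - ap_bg_tw), r2h)
            iso[[length(iso) + 1]] <- data.frame(
              sample_id = tsample, species = sp_name, site = site_name,
              tree_id = tree_id, campaign_date = date, tissue = "twig",
              d2H = d2_tw + stats::rnorm(1, 0, config$noise$d2H_sd),
              d18O = d18_tw + stats::rnorm(1, 0, config$noise$d18O_sd),
              is_labelled = TRUE, d2H_true = d2_tw, d18O_true = d18_tw
            )
            truth[[length(truth) + 1]] <- data.frame(
              sample_id = tsample, species = sp_name, site = site_name,
              tree_id = tree_id, campaign_date = date, campaign_index = ci,
              tissue = "twig", uptake_true_pct = u_twig, wc_true_pct = NA_real_,
              dormancy_depth_dd = row_tr$dormancy_depth_dd,
              chill_accum_h = row_tr$chill_accum_h, released = row_tr$released
            )
          }
        }
      }
    }
  }

  isotopes <- rbind(do.call(rbind, iso), .background_samples(config))
  rownames(isotopes) <- NULL
  structure(list(
    temps = temps,
    phenology = do.call(rbind, phen),
    mass = do.call(rbind, mass),
    isotopes = isotopes,
    truth = do.call(rbind, truth),
    trajectories = do.call(rbind, traj),
    config = config
  ), class = "isobud_simulation")
}

#' Write a simulated experiment to CSV files
#'
#' Emits `temps.csv`, `phenology.csv`, `mass.csv`, `isotopes.csv`,
#' `truth.csv` and a `manifest.json` carrying the seed and a content
#' fingerprint of the configuration. The latent `*_true` columns are kept out
#' of `isotopes.csv` (they live in `truth.csv`), so the written files are
#' exactly what a real campaign would provide.
#'
#' @param sim An `isobud_simulation`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "isobud_simulation"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  iso_out <- sim$isotopes[, c("sample_id", "species", "site", "tree_id",
                              "campaign_date", "tissue", "d2H", "d18O",
                              "is_labelled")]
  names(iso_out)[names(iso_out) == "d2H"] <- "d2H_permil"
  names(iso_out)[names(iso_out) == "d18O"] <- "d18O_permil"
  paths <- c(
    temps = file.path(dir, "temps.csv"),
    phenology = file.path(dir, "phenology.csv"),
    mass = file.path(dir, "mass.csv"),
    isotopes = file.path(dir, "isotopes.csv"),
    truth = file.path(dir, "truth.csv")
  )
  temps_out <- sim$temps
  temps_out$datetime <- format(temps_out$datetime, "%Y-%m-%d %H:%M:%S",
                               tz = "UTC")
  utils::write.csv(temps_out, paths["temps"], row.names = FALSE)
  utils::write.csv(sim$phenology, paths["phenology"], row.names = FALSE)
  utils::write.csv(sim$mass, paths["mass"], row.names = FALSE)
  utils::write.csv(iso_out, paths["isotopes"], row.names = FALSE)
  utils::write.csv(sim$truth, paths["truth"], row.names = FALSE)
  manifest <- list(seed = sim$config$seed,
                   config_hash = config_fingerprint(sim$config),
                   files = basename(unname(paths)))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(c(paths, manifest = file.path(dir, "manifest.json")))
}

# Focused generators for model-stage power and calibration studies ---------

#' Simulate a budburst-success table with known fixed effects
#'
#' Small focused generator for power and type-I studies of
#' [fit_success_model()]: per-twig binomial bud counts whose logit success is
#' linear in sampling date, with optional species/site main effects,
#' species-specific date slopes and a random tree intercept.
#'
#' @param n_trees Trees per species x site.
#' @param n_campaigns Number of fortnightly campaigns from 10 October 2019.
#' @param intercept Logit-scale intercept.
#' @param beta_date Logit slope per month of sampling date.
#' @param species_sd SD of species main effects (0 = none).
#' @param site_effect Additive logit effect of the second site.
#' @param species_slope_sd SD of species-specific date slopes (0 = none).
#' @param tree_sd SD of the random tree intercept.
#' @param n_buds Buds per twig.
#' @param n_species,n_sites Factor sizes.
#' @param seed Optional seed.
#' @return Analysis-table-shaped data frame for [fit_success_model()].
#' @export
simulate_success_table <- function(n_trees = 3, n_campaigns = 8,
                                   intercept = -1, beta_date = 0,
                                   species_sd = 0, site_effect = 0,
                                   species_slope_sd = 0, tree_sd = 0.3,
                                   n_buds = 10, n_species = 5, n_sites = 2,
                                   seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  dates <- as.Date("2019-10-10") + 14 * (seq_len(n_campaigns) - 1)
  months <- as.numeric(dates - dates[1]) / 30
  sp_eff <- stats::rnorm(n_species, 0, species_sd)
  sp_slope <- stats::rnorm(n_species, 0, species_slope_sd)
  rows <- list()
  for (sp in seq_len(n_species)) {
    for (si in seq_len(n_sites)) {
      for (tr in seq_len(n_trees)) {
        tree_id <- sprintf("s%d_sp%d_t%d", si, sp, tr)
        tree_eff <- stats::rnorm(1, 0, tree_sd)
        eta <- intercept + (beta_date + sp_slope[sp]) * months + sp_eff[sp] +
          (si == 2) * site_effect + tree_eff
        n2 <- stats::rbinom(n_campaigns, n_buds, stats::plogis(eta))
        rows[[length(rows) + 1]] <- data.frame(
          species = paste0("sp", sp), site = paste0("site", si),
          tree_id = tree_id, campaign_date = dates,
          campaign_index = seq_len(n_campaigns),
          n_buds_total = n_buds, n_buds_ge_stage2 = n2
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  out$success_fraction <- out$n_buds_ge_stage2 / out$n_buds_total
  out
}

#' Simulate a dormancy-depth table with known fixed effects
#'
#' Focused generator for [fit_dormancy_depth_model()]: log thermal time linear
#' (and optionally quadratic) in date, with optional site offset, species
#' effects and a random tree intercept.
#'
#' @param n_trees,n_campaigns,n_species,n_sites,seed As in
#'   [simulate_success_table()].
#' @param intercept Log thermal time at the first campaign.
#' @param beta_date,beta_date2 Linear / quadratic coefficients per month.
#' @param species_sd,site_effect,tree_sd,resid_sd Effect and noise scales on
#'   the log scale.
#' @return Analysis-table-shaped data frame with `thermal_time_dd`,
#'   `censored = FALSE`.
#' @export
simulate_depth_table <- function(n_trees = 3, n_campaigns = 8,
                                 intercept = log(800), beta_date = 0,
                                 beta_date2 = 0, species_sd = 0,
                                 site_effect = 0, tree_sd = 0.05,
                                 resid_sd = 0.15, n_species = 5, n_sites = 2,
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  dates <- as.Date("2019-11-27") + 14 * (seq_len(n_campaigns) - 1)
  months <- as.numeric(dates - dates[1]) / 30
  sp_eff <- stats::rnorm(n_species, 0, species_sd)
  rows <- list()
  for (sp in seq_len(n_species)) {
    for (si in seq_len(n_sites)) {
      for (tr in seq_len(n_trees)) {
        tree_id <- sprintf("s%d_sp%d_t%d", si, sp, tr)
        tree_eff <- stats::rnorm(1, 0, tree_sd)
        ln_tt <- intercept + beta_date * months + beta_date2 * months^2 +
          sp_eff[sp] + (si == 2) * site_effect + tree_eff +
          stats::rnorm(n_campaigns, 0, resid_sd)
        rows[[length(rows) + 1]] <- data.frame(
          species = paste0("sp", sp), site = paste0("site", si),
          tree_id = tree_id, campaign_date = dates,
          campaign_index = seq_len(n_campaigns),
          thermal_time_dd = exp(ln_tt), censored = FALSE
        )
      }
    }
  }
  do.call(rbind, rows)
}

#' Simulate a campaign-response table with known structure
#'
#' Focused generator for [fit_campaign_model()]: a Gaussian percent-scale
#' response (water content or uptake) that is flat by default, with an
#' optional step at a given campaign restricted to one species (a
#' campaign-by-species interaction) and a random tree intercept.
#'
#' @param n_trees,n_campaigns,n_species,n_sites,seed As in
#'   [simulate_success_table()].
#' @param baseline Response level (percent).
#' @param step_campaign,step_species,step_size Campaign index, species index
#'   and size of the injected step (`NULL`/0 for a null table).
#' @param tree_sd,resid_sd Noise scales (percent).
#' @param response Name of the response column to fill
#'   (`"water_content_pct"` or `"uptake_pct"`).
#' @return Analysis-table-shaped data frame.
#' @export
simulate_campaign_table <- function(n_trees = 3, n_campaigns = 8,
                                    baseline = 45, step_campaign = NULL,
                                    step_species = 1, step_size = 0,
                                    tree_sd = 1, resid_sd = 2,
                                    n_species = 5, n_sites = 2,
                                    response = "water_content_pct",
                                    seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  dates <- as.Date("2019-10-10") + 14 * (seq_len(n_campaigns) - 1)
  rows <- list()
  for (sp in seq_len(n_species)) {
    for (si in seq_len(n_sites)) {
      for (tr in seq_len(n_trees)) {
        tree_id <- sprintf("s%d_sp%d_t%d", si, sp, tr)
        mu <- rep(baseline, n_campaigns) + stats::rnorm(1, 0, tree_sd)
        if (!is.null(step_campaign) && sp == step_species) {
          mu[seq_len(n_campaigns) >= step_campaign] <-
            mu[seq_len(n_campaigns) >= step_campaign] + step_size
        }
        y <- mu + stats::rnorm(n_campaigns, 0, resid_sd)
        row <- data.frame(
          species = paste0("sp", sp), site = paste0("site", si),
          tree_id = tree_id, campaign_date = dates,
          campaign_index = seq_len(n_campaigns)
        )
        row[[response]] <- y
        rows[[length(rows) + 1]] <- row
      }
    }
  }
  do.call(rbind, rows)
}
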