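#' Pipeline configuration
#'
#' All tunable parameters of the end-to-end analysis in one serializable
#' object. Defaults mirror the standard assay: 20 degrees C constant forcing
#' over a 0 degree base, fresh-mass water content, species-pooled background
#' lines, a 2000 per mil label, correlations excluding the three autumn
#' campaigns, a 0.1 peak-fraction onset threshold, and the dormancy-depth
#' model restricted to campaigns after the first frost.
#'
#' @param forcing_temp_c,base_temp_c Forcing assay temperatures (degrees C).
#' @param water_content_basis `"fresh"` or `"dry"`.
#' @param line_scope `"species"` (pool sites) or `"species_site"`.
#' @param guard_permil Ill-conditioned-label guard (per mil).
#' @param label A [label_spec()].
#' @param constants An [isotope_constants()].
#' @param exclude_campaigns Campaign indices dropped from the correlations.
#' @param onset_threshold Peak fraction defining uptake collapse.
#' @param onset_autumn_end Last date eligible as the uptake peak (the autumn
#'   search window for [detect_endodormancy_onset()]).
#' @param after_first_frost Restrict the dormancy-depth model to campaigns on
#'   or after the first frost date.
#' @param frost_mode Frost definition, see [first_frost_date()].
#' @param model_method `"auto"`, `"mixed"` or `"fixed"` (see
#'   [fit_success_model()]).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(forcing_temp_c = 20, base_temp_c = 0,
                            water_content_basis = "fresh",
                            line_scope = "species",
                            guard_permil = 100,
                            label = label_spec(),
                            constants = isotope_constants(),
                            exclude_campaigns = 1:3,
                            onset_threshold = 0.1,
                            onset_autumn_end = "2020-01-01",
                            after_first_frost = TRUE,
                            frost_mode = "min_below_0",
                            model_method = "auto") {
  structure(list(
    forcing_temp_c = forcing_temp_c, base_temp_c = base_temp_c,
    water_content_basis = water_content_basis, line_scope = line_scope,
    guard_permil = guard_permil, label = label, constants = constants,
    exclude_campaigns = exclude_campaigns, onset_threshold = onset_threshold,
    onset_autumn_end = as.Date(onset_autumn_end),
    after_first_frost = after_first_frost, frost_mode = frost_mode,
    model_method = model_method
  ), class = "pipeline_config")
}

#' Content fingerprint of a configuration
#'
#' Deterministic 31-bit fingerprint (a simple polynomial rolling hash over the
#' deparsed object) used to stamp output files so a reader can tell whether
#' two outputs came from the same configuration. Not cryptographic.
#'
#' @param x Any R object.
#' @return Fingerprint as an 8-character hex string.
#' @export
config_fingerprint <- function(x) {
  s <- paste(deparse(x), collapse = "")
  bytes <- utf8ToInt(s)
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

# CSV schema validation ----------------------------------------------------

.read_checked <- function(path, numeric_cols, required_cols, date_cols = character(),
                          logical_cols = character()) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                        colClasses = "character")
  missing <- setdiff(required_cols, names(df))
  if (length(missing)) {
    stop(basename(path), ": missing column(s) ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  for (col in numeric_cols) {
    raw <- df[[col]]
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(val) & !(is.na(raw) | raw %in% c("", "NA")))
    if (length(bad)) {
      stop(basename(path), ": non-numeric value in column '", col,
           "' at data row(s) ", paste(utils::head(bad, 5), collapse = ", "),
           " (e.g. '", raw[bad[1]], "')", call. = FALSE)
    }
    df[[col]] <- val
  }
  for (col in date_cols) {
    raw <- df[[col]]
    val <- as.Date(raw, format = "%Y-%m-%d")
    bad <- which(is.na(val) & !(is.na(raw) | raw %in% c("", "NA")))
    if (length(bad)) {
      stop(basename(path), ": unparseable ISO-8601 date in column '", col,
           "' at data row(s) ", paste(utils::head(bad, 5), collapse = ", "),
           call. = FALSE)
    }
    df[[col]] <- val
  }
  for (col in logical_cols) {
    df[[col]] <- as.logical(df[[col]])
    if (any(is.na(df[[col]]))) {
      stop(basename(path), ": column '", col, "' must be TRUE/FALSE",
           call. = FALSE)
    }
  }
  df
}

#' Read an isotope measurement CSV
#'
#' Schema: `sample_id, species, site, tree_id, campaign_date, tissue,
#' d2H_permil, d18O_permil, is_labelled`. Violations are reported with row
#' numbers. The returned table uses the internal column names `d2H` / `d18O`.
#'
#' @param path CSV path.
#' @return Validated isotope table.
#' @export
read_isotopes <- function(path) {
  df <- .read_checked(
    path,
    numeric_cols = c("d2H_permil", "d18O_permil"),
    required_cols = c("sample_id", "species", "site", "tree_id",
                      "campaign_date", "tissue", "d2H_permil", "d18O_permil",
                      "is_labelled"),
    date_cols = "campaign_date", logical_cols = "is_labelled")
  names(df)[names(df) == "d2H_permil"] <- "d2H"
  names(df)[names(df) == "d18O_permil"] <- "d18O"
  if (!all(df$tissue %in% c("bud", "twig"))) {
    stop(basename(path), ": tissue must be 'bud' or 'twig'", call. = FALSE)
  }
  low <- which(df$d2H <= -1000 | df$d18O <= -1000)
  if (length(low)) {
    stop(basename(path), ": delta at or below -1000 per mil at data row(s) ",
         paste(utils::head(low, 5), collapse = ", "), call. = FALSE)
  }
  df
}

#' Read an hourly temperature CSV
#'
#' Schema: `site, datetime, temp_c`.
#'
#' @param path CSV path.
#' @return Validated temperature table.
#' @export
read_temps <- function(path) {
  df <- .read_checked(path, numeric_cols = "temp_c",
                      required_cols = c("site", "datetime", "temp_c"))
  df$datetime <- as.POSIXct(df$datetime, tz = "UTC",
                            tryFormats = c("%Y-%m-%d %H:%M:%S",
                                           "%Y-%m-%dT%H:%M:%S", "%Y-%m-%d"))
  if (any(is.na(df$datetime))) {
    stop(basename(path), ": unparseable datetime values", call. = FALSE)
  }
  df
}

#' Read a phenology CSV
#'
#' Wide schema, one row per forced twig: `twig_id, tree_id, species, site,
#' campaign_date, forcing_start_date, stage1_date, stage2_date, stage3_date,
#' stage4_date, n_buds_total, n_buds_ge_stage2`; stage dates may be empty when
#' the stage was never reached and must be weakly increasing with stage.
#'
#' @param path CSV path.
#' @return Validated phenology table.
#' @export
read_phenology <- function(path) {
  df <- .read_checked(
    path,
    numeric_cols = c("n_buds_total", "n_buds_ge_stage2"),
    required_cols = c("twig_id", "tree_id", "species", "site", "campaign_date",
                      "forcing_start_date", "stage2_date", "n_buds_total",
                      "n_buds_ge_stage2"),
    date_cols = intersect(c("campaign_date", "forcing_start_date",
                            "stage1_date", "stage2_date", "stage3_date",
                            "stage4_date"),
                          names(utils::read.csv(path, comment.char = "#",
                                                nrows = 1))))
  stage_cols <- intersect(paste0("stage", 1:4, "_date"), names(df))
  if (length(stage_cols) > 1) {
    m <- as.matrix(as.data.frame(lapply(df[stage_cols], as.numeric)))
    bad <- which(apply(m, 1, function(r) {
      r <- r[!is.na(r)]
      length(r) > 1 && is.unsorted(r)
    }))
    if (length(bad)) {
      stop(basename(path), ": stage dates not weakly increasing at data row(s) ",
           paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
    }
  }
  if (any(df$n_buds_ge_stage2 > df$n_buds_total)) {
    stop(basename(path), ": n_buds_ge_stage2 exceeds n_buds_total", call. = FALSE)
  }
  df
}

#' Read a bud mass CSV
#'
#' Schema: `sample_id, species, site, tree_id, campaign_date, fresh_mass_mg,
#' dry_mass_mg` with `0 < dry <= fresh`.
#'
#' @param path CSV path.
#' @return Validated mass table.
#' @export
read_mass <- function(path) {
  df <- .read_checked(
    path, numeric_cols = c("fresh_mass_mg", "dry_mass_mg"),
    required_cols = c("sample_id", "species", "site", "tree_id",
                      "campaign_date", "fresh_mass_mg", "dry_mass_mg"),
    date_cols = "campaign_date")
  bad <- which(df$dry_mass_mg <= 0 | df$dry_mass_mg > df$fresh_mass_mg)
  if (length(bad)) {
    stop(basename(path), ": invalid masses (need 0 < dry <= fresh) at data ",
         "row(s) ", paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  df
}

.write_output_csv <- function(df, path, hash) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("# isobud schema 1 config_hash=%s", hash), con)
  utils::write.csv(df, con, row.names = FALSE)
}

#' Run the full dormancy analysis pipeline
#'
#' Executes the three analysis stages in order on one experiment's data:
#' isotopes (background lines, meteoric-line diagnostics, per-sample label
#' uptake), phenology (daily climate, frost dates, budburst outcomes, water
#' content), and models (the four response models, Tukey species contrasts,
#' campaign-filtered correlations, per-species endodormancy onset). All
#' analysis stages are deterministic; randomness lives only in the generator.
#'
#' @param data Either a directory containing `temps.csv`, `phenology.csv`,
#'   `mass.csv`, `isotopes.csv`, an `isobud_simulation`, or a named list with
#'   elements `temps`, `phenology`, `mass`, `isotopes` (data frames).
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory; when given, writes
#'   `uptake.csv`, `outcomes.csv`, `water_content.csv`, `daily_climate.csv`,
#'   `model_<response>.csv`, `correlations.csv`, `onset.csv`, `report.txt`
#'   and `manifest.json`. Partial outputs are removed if any stage fails.
#' @return An object of class `isobud_report` (a list of all stage results).
#' @export
run_pipeline <- function(data, config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (inherits(data, "isobud_simulation")) {
    data <- list(temps = data$temps, phenology = data$phenology,
                 mass = data$mass, isotopes = data$isotopes)
  } else if (is.character(data) && length(data) == 1) {
    data <- list(
      temps = read_temps(file.path(data, "temps.csv")),
      phenology = read_phenology(file.path(data, "phenology.csv")),
      mass = read_mass(file.path(data, "mass.csv")),
      isotopes = read_isotopes(file.path(data, "isotopes.csv"))
    )
  }
  stopifnot(all(c("temps", "phenology", "mass", "isotopes") %in% names(data)))

  # stage 1: climate
  daily <- aggregate_daily(data$temps)
  climate <- climate_period_summary(daily)
  frost <- do.call(rbind, lapply(split(daily, daily$site), function(d) {
    data.frame(site = d$site[1],
               first_frost_min = first_frost_date(d, "min_below_0"),
               first_frost_mean = first_frost_date(d, "mean_below_0"))
  }))
  rownames(frost) <- NULL

  # stage 2: isotopes
  isotopes <- screen_natural_abundance(data$isotopes)
  lines <- fit_background_lines(isotopes, scope = config$line_scope)
  gmwl <- do.call(rbind, lapply(names(lines), function(nm) {
    ln <- lines[[nm]]
    dg <- line_vs_gmwl(ln, config$constants)
    data.frame(line = nm, species = ln$species, beta0 = ln$beta0,
               beta1 = ln$beta1, se_beta0 = ln$se_beta0,
               se_beta1 = ln$se_beta1, n = ln$n,
               residual_sd = ln$residual_sd,
               slope_deficit = dg$slope_deficit,
               evaporative_flag = dg$evaporative_flag)
  }))
  uptake <- compute_uptake(isotopes, lines, label = config$label,
                           constants = config$constants,
                           guard_permil = config$guard_permil,
                           line_scope = config$line_scope)

  # stage 3: phenology outcomes and water content
  outcomes <- thermal_time_to_budburst(data$phenology,
                                       forcing_temp_c = config$forcing_temp_c,
                                       base_temp_c = config$base_temp_c)
  wc <- data$mass
  wc$water_content_pct <- bud_water_content(wc$fresh_mass_mg, wc$dry_mass_mg,
                                            basis = config$water_content_basis,
                                            sample_id = wc$sample_id)

  # stage 4: models
  tab <- build_analysis_table(outcomes, uptake, wc)
  after_date <- if (config$after_first_frost) {
    fr <- if (config$frost_mode == "min_below_0") frost$first_frost_min
          else frost$first_frost_mean
    if (all(is.na(fr))) min(tab$campaign_date) else min(fr, na.rm = TRUE)
  } else min(tab$campaign_date)

  models <- list(
    success = fit_success_model(tab, method = config$model_method),
    depth = fit_dormancy_depth_model(tab, after_date = after_date,
                                     method = config$model_method),
    water_content = fit_campaign_model(tab, "water_content",
                                       method = config$model_method),
    uptake = fit_campaign_model(tab, "uptake", method = config$model_method)
  )
  species_contrasts <- lapply(models, function(m) {
    tryCatch(tukey_contrasts(m, "species"), error = function(e) NULL)
  })
  correlations <- dormancy_correlations(
    tab, exclude_campaigns = config$exclude_campaigns)

  all_campaigns <- sort(unique(tab$campaign_date))
  autumn_idx <- which(all_campaigns <= config$onset_autumn_end)
  onset <- lapply(sort(unique(as.character(tab$species))), function(sp) {
    d <- tab[tab$species == sp & !is.na(tab$uptake_pct), ]
    mu <- stats::aggregate(uptake_pct ~ campaign_index, data = d, FUN = mean)
    detect_endodormancy_onset(mu$uptake_pct, mu$campaign_index,
                              threshold_fraction = config$onset_threshold,
                              peak_window = autumn_idx, species = sp)
  })
  names(onset) <- sort(unique(as.character(tab$species)))
  onset_df <- do.call(rbind, lapply(onset, function(o) data.frame(
    species = o$species, site_scope = o$site_scope,
    onset_campaign_index = o$onset_campaign_index,
    peak_campaign_index = o$peak_campaign_index,
    peak_uptake_pct = o$peak_uptake_pct,
    post_drop_mean_pct = o$post_drop_mean_pct,
    threshold_fraction = o$threshold_fraction, detected = o$detected)))
  rownames(onset_df) <- NULL

  report <- structure(list(
    daily = daily, climate = climate, frost = frost,
    background_lines = lines, gmwl_diagnostics = gmwl, uptake = uptake,
    outcomes = outcomes, water_content = wc, analysis_table = tab,
    after_date = after_date, models = models,
    species_contrasts = species_contrasts,
    correlations = correlations, onset = onset, onset_table = onset_df,
    config = config
  ), class = "isobud_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    hash <- config_fingerprint(config)
    written <- character(0)
    ok <- FALSE
    on.exit(if (!ok) unlink(written), add = TRUE)
    emit <- function(df, name) {
      p <- file.path(out_dir, name)
      .write_output_csv(df, p, hash)
      written <<- c(written, p)
    }
    emit(uptake[, setdiff(names(uptake), c("d2H_true", "d18O_true",
                                           "screen_flag"))], "uptake.csv")
    emit(outcomes, "outcomes.csv")
    emit(wc, "water_content.csv")
    emit(daily, "daily_climate.csv")
    emit(gmwl, "background_lines.csv")
    for (nm in names(models)) {
      m <- models[[nm]]
      emit(cbind(part = "anova", m$anova[, c("term", "chisq", "df", "p")]),
           sprintf("model_%s.csv", nm))
    }
    emit(correlations, "correlations.csv")
    emit(onset_df, "onset.csv")
    rp <- file.path(out_dir, "report.txt")
    writeLines(format_report(report), rp)
    written <- c(written, rp)
    mp <- file.path(out_dir, "manifest.json")
    jsonlite::write_json(
      list(schema_version = 1, config_hash = hash,
           package_version = as.character(utils::packageVersion("isobud")),
           n_analysis_rows = nrow(tab)),
      mp, auto_unbox = TRUE, pretty = TRUE)
    written <- c(written, mp)
    ok <- TRUE
  }
  report
}

#' Format a pipeline report as plain text
#'
#' Human-readable summary mirroring the canonical result layout: one ANOVA
#' table per response (chi-square, df, p), the species-level correlation
#' table, and the per-species endodormancy onsets.
#'
#' @param report An `isobud_report`.
#' @return Character vector of report lines.
#' @export
format_report <- function(report) {
  stopifnot(inherits(report, "isobud_report"))
  fmt_p <- function(p) ifelse(p < 0.001, "<0.001", sprintf("%.3f", p))
  out <- c("isobud dormancy analysis report",
           "================================", "")
  out <- c(out, "Site climate (period mean of daily means +/- mean daily sd):")
  for (i in seq_len(nrow(report$climate))) {
    cl <- report$climate[i, ]
    fr <- report$frost[report$frost$site == cl$site, ]
    out <- c(out, sprintf("  %-10s %5.1f +/- %.1f C; first frost (min<0): %s",
                          cl$site, cl$mean_of_daily_means_c,
                          cl$mean_of_daily_sds_c,
                          format(fr$first_frost_min)))
  }
  out <- c(out, "", "Background lines vs global meteoric water line:")
  for (i in seq_len(nrow(report$gmwl_diagnostics))) {
    g <- report$gmwl_diagnostics[i, ]
    out <- c(out, sprintf(
      "  %-10s d2H = %6.1f + %.2f d18O (n=%d); slope deficit %.2f%s",
      g$line, g$beta0, g$beta1, g$n, g$slope_deficit,
      if (g$evaporative_flag) " [evaporative]" else ""))
  }
  for (nm in names(report$models)) {
    m <- report$models[[nm]]
    out <- c(out, "", sprintf("Model: %s (%s fit, type %s ANOVA, n = %d)",
                              m$response, m$method, m$anova_type, m$n),
             sprintf("  %-28s %9s %4s %8s", "term", "chisq", "df", "P"))
    for (i in seq_len(nrow(m$anova))) {
      a <- m$anova[i, ]
      out <- c(out, sprintf("  %-28s %9.2f %4d %8s", a$term, a$chisq, a$df,
                            fmt_p(a$p)))
    }
  }
  out <- c(out, "", "Species-specific Pearson correlations (campaigns ",
           paste0("  excluded: ",
                  paste(report$config$exclude_campaigns, collapse = ", "), "):"),
           sprintf("  %-10s %-14s %-14s %7s %8s %5s", "species", "var1",
                   "var2", "r", "P", "n"))
  for (i in seq_len(nrow(report$correlations))) {
    cr <- report$correlations[i, ]
    out <- c(out, if (cr$computable) {
      sprintf("  %-10s %-14s %-14s %7.3f %8s %5d", cr$species, cr$var1,
              cr$var2, cr$r, fmt_p(cr$p), cr$n)
    } else {
      sprintf("  %-10s %-14s %-14s %7s %8s %5d", cr$species, cr$var1,
              cr$var2, "NC", "NC", cr$n)
    })
  }
  out <- c(out, "", "Endodormancy onset (uptake collapse):")
  for (o in report$onset) {
    out <- c(out, if (o$detected) {
      sprintf("  %-10s onset at campaign %d (peak %.1f%% at campaign %d)",
              o$species, o$onset_campaign_index, o$peak_uptake_pct,
              o$peak_campaign_index)
    } else {
      sprintf("  %-10s no onset detected", o$species)
    })
  }
  out
}

#' @export
print.isobud_report <- function(x, ...) {
  cat(format_report(x), sep = "\n")
  invisible(x)
}
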