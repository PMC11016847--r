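#' Isotope reference constants
#'
#' Bundles the isotope-ratio reference values and meteoric-water-line
#' parameters used throughout the labelling arithmetic. The defaults are the
#' community-standard VSMOW isotope amount ratios (2H/1H and 18O/16O) and the
#' global meteoric water line (GMWL) slope 8 / intercept 10 per mil.
#'
#' @param r_standard_2h VSMOW 2H/1H isotope amount ratio.
#' @param r_standard_18o VSMOW 18O/16O isotope amount ratio.
#' @param gmwl_slope Slope of the global meteoric water line (dimensionless).
#' @param gmwl_intercept Intercept of the global meteoric water line (per mil).
#' @return An object of class `isotope_constants`.
#' @export
#' @examples
#' isotope_constants()
isotope_constants <- function(r_standard_2h = 1.5576e-4,
                              r_standard_18o = 2.0052e-3,
                              gmwl_slope = 8,
                              gmwl_intercept = 10) {
  stopifnot(r_standard_2h > 0, r_standard_18o > 0, gmwl_slope > 0)
  structure(
    list(r_standard_2h = r_standard_2h, r_standard_18o = r_standard_18o,
         gmwl_slope = gmwl_slope, gmwl_intercept = gmwl_intercept),
    class = "isotope_constants"
  )
}

#' Label water specification
#'
#' Describes the deuterium-enriched incubation water. The default of
#' 2000 per mil corresponds to the strongly 2H-enriched water used in
#' twig-cutting labelling assays.
#'
#' @param d2h_label delta-2H of the label water (per mil vs VSMOW).
#' @return An object of class `label_spec`.
#' @export
label_spec <- function(d2h_label = 2000) {
  stopifnot(is.numeric(d2h_label), length(d2h_label) == 1, d2h_label > -1000)
  structure(list(d2h_label = d2h_label), class = "label_spec")
}

#' Convert delta notation to atom percent
#'
#' Converts a delta value (per mil vs a reference standard) to the heavy-isotope
#' atom percent:
#' `atom% = 100 * R_std * (delta/1000 + 1) / (1 + R_std * (delta/1000 + 1))`.
#'
#' @param delta Numeric vector of delta values (per mil). Must be > -1000:
#'   -1000 per mil is the zero-heavy-isotope lower bound of the delta scale.
#' @param r_standard Isotope amount ratio of the reference standard (> 0).
#' @param sample_id Optional identifiers used to name offending samples in
#'   error messages.
#' @return Numeric vector of atom percent values in (0, 100); strictly
#'   increasing in `delta`.
#' @export
#' @examples
#' delta_to_atom_percent(0, 1.5576e-4)     # VSMOW itself
#' delta_to_atom_percent(2000, 1.5576e-4)  # 3x the VSMOW ratio
delta_to_atom_percent <- function(delta, r_standard, sample_id = NULL) {
  stopifnot(is.numeric(delta), is.numeric(r_standard), all(r_standard > 0))
  bad <- which(!is.na(delta) & delta <= -1000)
  if (length(bad)) {
    who <- if (!is.null(sample_id)) paste(sample_id[bad], collapse = ", ")
           else paste("positions", paste(bad, collapse = ", "))
    stop("delta values at or below -1000 per mil are outside the delta scale (",
         who, ")", call. = FALSE)
  }
  r_sample <- r_standard * (delta / 1000 + 1)
  100 * r_sample / (1 + r_sample)
}

#' Convert atom percent back to delta notation
#'
#' Algebraic inverse of [delta_to_atom_percent()].
#'
#' @param ap Numeric vector of atom percent values, strictly inside (0, 100).
#' @param r_standard Isotope amount ratio of the reference standard (> 0).
#' @return Numeric vector of delta values (per mil).
#' @export
atom_percent_to_delta <- function(ap, r_standard) {
  stopifnot(is.numeric(ap), is.numeric(r_standard), all(r_standard > 0))
  bad <- which(!is.na(ap) & (ap <= 0 | ap >= 100))
  if (length(bad)) {
    stop("atom percent outside (0, 100) at positions ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  r_sample <- ap / (100 - ap)
  (r_sample / r_standard - 1) * 1000
}

#' Fit a species natural-abundance background line
#'
#' Ordinary least squares of delta-2H on delta-18O across a species'
#' natural-abundance (unlabelled) samples. The fitted line predicts the
#' expected background delta-2H of any sample from its measured delta-18O,
#' which is the reference level against which label uptake is scored. Bud
#' water lines typically fall below the global meteoric water line (slope 8)
#' because cuticular evaporation enriches 18O relative to 2H (Rayleigh
#' fractionation).
#'
#' @param samples Data frame of isotope measurements with at least columns
#'   `d2H`, `d18O` and (if `species` is given) `species` and `is_labelled`.
#' @param species Optional species name; if supplied, `samples` is filtered to
#'   unlabelled rows of that species before fitting.
#' @return An object of class `background_line` with elements `species`,
#'   `beta0` (intercept, per mil), `beta1` (slope), `n`, `residual_sd`,
#'   `se_beta0`, `se_beta1`.
#' @export
fit_background_line <- function(samples, species = NULL) {
  if (!is.null(species)) {
    keep <- samples$species == species & !samples$is_labelled
    samples <- samples[keep, , drop = FALSE]
  }
  n <- nrow(samples)
  if (n < 3) {
    stop("need at least 3 natural-abundance samples to fit a background line",
         if (!is.null(species)) paste0(" for species '", species, "'"),
         " (got ", n, ")", call. = FALSE)
  }
  if (stats::sd(samples$d18O) == 0) {
    stop("degenerate predictor: d18O has zero variance",
         if (!is.null(species)) paste0(" for species '", species, "'"),
         call. = FALSE)
  }
  fit <- stats::lm(d2H ~ d18O, data = samples)
  cf <- summary(fit)$coefficients
  structure(
    list(
      species = if (is.null(species)) NA_character_ else species,
      beta0 = unname(cf[1, 1]), beta1 = unname(cf[2, 1]),
      n = n,
      residual_sd = summary(fit)$sigma,
      se_beta0 = unname(cf[1, 2]), se_beta1 = unname(cf[2, 2])
    ),
    class = "background_line"
  )
}

#' Fit background lines for every species in a measurement table
#'
#' @param isotopes Isotope measurement table (see [read_isotopes()] for the
#'   schema). Only unlabelled rows are used.
#' @param scope Either `"species"` (pool both sites, the default) or
#'   `"species_site"` (fit one line per species x site combination).
#' @return A named list of `background_line` objects; for
#'   `scope = "species_site"` names are `"<species>.<site>"`.
#' @export
fit_background_lines <- function(isotopes, scope = c("species", "species_site")) {
  scope <- match.arg(scope)
  nat <- isotopes[!isotopes$is_labelled, , drop = FALSE]
  if (scope == "species") {
    sp <- sort(unique(nat$species))
    out <- lapply(sp, function(s) fit_background_line(nat, species = s))
    names(out) <- sp
  } else {
    grp <- interaction(nat$species, nat$site, drop = TRUE)
    out <- lapply(levels(grp), function(g) {
      sub <- nat[grp == g, , drop = FALSE]
      ln <- fit_background_line(sub[!sub$is_labelled, ])
      ln$species <- sub$species[1]
      ln
    })
    names(out) <- levels(grp)
  }
  out
}

#' @export
print.background_line <- function(x, ...) {
  cat(sprintf(
    "Background line%s: d2H = %.3f + %.4f * d18O  (n = %d, residual sd = %.3f)\n",
    if (is.na(x$species)) "" else paste0(" [", x$species, "]"),
    x$beta0, x$beta1, x$n, x$residual_sd))
  invisible(x)
}

#' Predict natural-abundance background delta-2H
#'
#' Evaluates a fitted background line at a sample's measured delta-18O:
#' `d2H_background = beta0 + beta1 * d18O`.
#'
#' @param line A `background_line` object.
#' @param d18O_sample Numeric vector of delta-18O values (per mil).
#' @return Predicted background delta-2H (per mil).
#' @export
predict_background_d2h <- function(line, d18O_sample) {
  stopifnot(inherits(line, "background_line"), is.numeric(d18O_sample))
  line$beta0 + line$beta1 * d18O_sample
}

#' Short-term uptake of labelled water
#'
#' Scores the excess deuterium a labelled sample carries over its
#' natural-abundance background, as a percentage of the label end member:
#' `uptake% = (atom%_sample - atom%_background) / (atom%_label - atom%_background) * 100`.
#' All three atom percent terms are computed with [delta_to_atom_percent()];
#' the background delta-2H is predicted from the sample's own delta-18O via
#' [predict_background_d2h()]. Values may be slightly negative under
#' measurement noise and are deliberately not clipped (clipping would bias
#' campaign means toward zero); values outside [-5, 105] are flagged via the
#' `"qc_flag"` attribute, not rejected.
#'
#' @param d2H_sample,d18O_sample Measured deltas of the labelled sample (per mil).
#' @param line Fitted `background_line` for the sample's species.
#' @param label A [label_spec()].
#' @param constants An [isotope_constants()].
#' @param guard_permil Minimum excess of the label delta-2H over the predicted
#'   background required for a well-conditioned denominator (default 100 per
#'   mil, roughly 30x typical IRMS precision).
#' @param sample_id Optional identifiers for error messages.
#' @return Numeric vector of uptake percentages with attribute `qc_flag`
#'   (character: `"ok"` or `"outside_range"`).
#' @export
label_uptake_percent <- function(d2H_sample, d18O_sample, line,
                                 label = label_spec(),
                                 constants = isotope_constants(),
                                 guard_permil = 100,
                                 sample_id = NULL) {
  stopifnot(inherits(line, "background_line"), inherits(label, "label_spec"),
            inherits(constants, "isotope_constants"))
  d2h_bg <- predict_background_d2h(line, d18O_sample)
  bad <- which(label$d2h_label - d2h_bg < guard_permil)
  if (length(bad)) {
    who <- if (!is.null(sample_id)) paste(sample_id[bad], collapse = ", ")
           else paste("positions", paste(bad, collapse = ", "))
    stop("ill-conditioned label: label d2H (", label$d2h_label,
         " per mil) exceeds the predicted background by less than ",
         guard_permil, " per mil for ", who, call. = FALSE)
  }
  r <- constants$r_standard_2h
  ap_sample <- delta_to_atom_percent(d2H_sample, r, sample_id = sample_id)
  ap_bg <- delta_to_atom_percent(d2h_bg, r)
  ap_label <- delta_to_atom_percent(label$d2h_label, r)
  uptake <- (ap_sample - ap_bg) / (ap_label - ap_bg) * 100
  flag <- ifelse(uptake < -5 | uptake > 105, "outside_range", "ok")
  attr(uptake, "qc_flag") <- flag
  uptake
}

#' Compute label uptake for a table of labelled samples
#'
#' Applies [label_uptake_percent()] row-wise using each sample's
#' species-specific background line, producing the per-sample uptake table.
#' Twig-tissue samples reuse the bud line of the same species by default
#' (`twig_uses_bud_line = TRUE`), since the twig and bud natural-abundance
#' slopes are closely similar.
#'
#' @param isotopes Isotope table; only `is_labelled == TRUE` rows are scored.
#' @param lines Named list of `background_line` objects as returned by
#'   [fit_background_lines()].
#' @param label,constants,guard_permil See [label_uptake_percent()].
#' @param line_scope `"species"` or `"species_site"`; must match how `lines`
#'   was built.
#' @param twig_uses_bud_line Kept for interface clarity; when lines are fitted
#'   from bud tissue only, twig samples are scored against the same line.
#' @return Data frame with the input metadata plus `d2H_background_permil`,
#'   `atom_pct_sample`, `atom_pct_background`, `atom_pct_label`, `uptake_pct`
#'   and `qc_flag`.
#' @export
compute_uptake <- function(isotopes, lines,
                           label = label_spec(),
                           constants = isotope_constants(),
                           guard_permil = 100,
                           line_scope = c("species", "species_site"),
                           twig_uses_bud_line = TRUE) {
  line_scope <- match.arg(line_scope)
  lab <- isotopes[isotopes$is_labelled, , drop = FALSE]
  if (nrow(lab) == 0) stop("no labelled samples to score", call. = FALSE)
  key <- if (line_scope == "species") lab$species
         else paste(lab$species, lab$site, sep = ".")
  missing_line <- setdiff(unique(key), names(lines))
  if (length(missing_line)) {
    stop("no background line available for: ",
         paste(missing_line, collapse = ", "), call. = FALSE)
  }
  r <- constants$r_standard_2h
  out <- lab
  out$d2H_background_permil <- NA_real_
  out$uptake_pct <- NA_real_
  out$qc_flag <- NA_character_
  for (k in unique(key)) {
    idx <- which(key == k)
    ln <- lines[[k]]
    u <- label_uptake_percent(lab$d2H[idx], lab$d18O[idx], ln,
                              label = label, constants = constants,
                              guard_permil = guard_permil,
                              sample_id = lab$sample_id[idx])
    out$d2H_background_permil[idx] <- predict_background_d2h(ln, lab$d18O[idx])
    out$uptake_pct[idx] <- as.numeric(u)
    out$qc_flag[idx] <- attr(u, "qc_flag")
  }
  out$atom_pct_sample <- delta_to_atom_percent(out$d2H, r)
  out$atom_pct_background <- delta_to_atom_percent(out$d2H_background_permil, r)
  out$atom_pct_label <- delta_to_atom_percent(label$d2h_label, r)
  out
}

#' Compare a background line with the global meteoric water line
#'
#' A slope below the GMWL slope of 8 indicates Rayleigh-type evaporative
#' enrichment of the tissue water (preferential retention of 18O over 2H),
#' as expected when buds lose water through the cuticle over winter.
#'
#' @param line A `background_line`.
#' @param constants An [isotope_constants()].
#' @return List with `slope_deficit` (GMWL slope minus fitted slope) and
#'   `evaporative_flag` (`TRUE` when the fitted slope is below the GMWL slope
#'   by more than two standard errors).
#' @export
line_vs_gmwl <- function(line, constants = isotope_constants()) {
  stopifnot(inherits(line, "background_line"))
  deficit <- constants$gmwl_slope - line$beta1
  list(
    slope_deficit = deficit,
    evaporative_flag = (line$beta1 + 2 * line$se_beta1) < constants$gmwl_slope
  )
}

#' Screen natural-abundance measurements for implausible values
#'
#' Warn-level quality screen: unlabelled samples with d2H above 0 per mil or
#' d18O above 10 per mil are unusual for mid-latitude tissue water and are
#' flagged, not rejected. Labelled samples may legitimately exceed
#' natural-abundance ranges.
#'
#' @param isotopes Isotope measurement table.
#' @return The table with a logical `screen_flag` column; warns when any
#'   unlabelled sample is flagged.
#' @export
screen_natural_abundance <- function(isotopes) {
  flag <- !isotopes$is_labelled & (isotopes$d2H > 0 | isotopes$d18O > 10)
  if (any(flag)) {
    warning(sum(flag), " natural-abundance sample(s) outside the expected ",
            "range (d2H > 0 or d18O > 10 per mil): ",
            paste(utils::head(isotopes$sample_id[flag], 5), collapse = ", "),
            call. = FALSE)
  }
  isotopes$screen_flag <- flag
  isotopes
}
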