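#' Assemble the twig/bud analysis table
#'
#' Joins budburst outcomes (twig assay), bud water content and label uptake
#' (bud assay) at the tree x campaign level into the single table the model
#' stage consumes. Campaign indices are assigned 1-based in calendar order of
#' the distinct campaign dates present.
#'
#' @param outcomes Output of [thermal_time_to_budburst()]; may be `NULL`.
#' @param uptake Output of [compute_uptake()] restricted to bud tissue; may be
#'   `NULL`.
#' @param water_content Data frame with `sample_id`, `tree_id`, `species`,
#'   `site`, `campaign_date`, `water_content_pct`; may be `NULL`.
#' @param campaign_dates Optional full vector of campaign dates used to fix
#'   the index mapping (useful when a subset of campaigns appears in the data).
#' @return Data frame with one row per tree x campaign x assay join, columns
#'   `species`, `site`, `tree_id`, `campaign_date`, `campaign_index` plus the
#'   available response columns (`success_fraction`, `thermal_time_dd`,
#'   `censored`, `n_buds_total`, `n_buds_ge_stage2`, `water_content_pct`,
#'   `uptake_pct`, `twig_id`).
#' @export
build_analysis_table <- function(outcomes = NULL, uptake = NULL,
                                 water_content = NULL, campaign_dates = NULL) {
  key <- c("species", "site", "tree_id", "campaign_date")
  norm_date <- function(d) { d$campaign_date <- as.Date(d$campaign_date); d }
  tabs <- list()
  if (!is.null(outcomes)) {
    tabs$twig <- norm_date(outcomes[, c(key, "twig_id", "success_fraction",
                                        "n_buds_total", "n_buds_ge_stage2",
                                        "days_to_stage2", "thermal_time_dd",
                                        "censored")])
  }
  bud <- NULL
  if (!is.null(uptake)) {
    bud <- norm_date(uptake[uptake$tissue == "bud",
                            c(key, "sample_id", "uptake_pct", "qc_flag")])
  }
  if (!is.null(water_content)) {
    wc <- norm_date(water_content[, c(key, "sample_id", "water_content_pct")])
    bud <- if (is.null(bud)) wc else merge(bud, wc, by = c(key, "sample_id"),
                                           all = TRUE)
  }
  if (!is.null(bud)) tabs$bud <- bud
  if (length(tabs) == 0) stop("nothing to assemble", call. = FALSE)
  tab <- if (length(tabs) == 2) merge(tabs$twig, tabs$bud, by = key, all = TRUE)
         else tabs[[1]]
  if (is.null(campaign_dates)) campaign_dates <- sort(unique(tab$campaign_date))
  campaign_dates <- sort(unique(as.Date(campaign_dates)))
  tab$campaign_index <- match(tab$campaign_date, campaign_dates)
  if (any(is.na(tab$campaign_index))) {
    stop("campaign_date not covered by campaign_dates mapping", call. = FALSE)
  }
  tab <- tab[order(tab$campaign_index, tab$species, tab$site, tab$tree_id), ]
  rownames(tab) <- NULL
  tab
}

# Shared fitting machinery -----------------------------------------------

# days since first campaign, in months, keeps the optimizer well scaled
.date_num <- function(campaign_date) {
  d <- as.Date(campaign_date)
  as.numeric(d - min(d)) / 30
}

.prep_factors <- function(d, sum_contrasts = FALSE) {
  for (col in c("species", "site", "tree_id", "campaign")) {
    if (col %in% names(d)) {
      d[[col]] <- factor(d[[col]])
      if (sum_contrasts && col != "tree_id" && nlevels(d[[col]]) > 1) {
        stats::contrasts(d[[col]]) <- stats::contr.sum(nlevels(d[[col]]))
      }
    }
  }
  d
}

.check_levels <- function(d, cols) {
  for (col in cols) {
    if (length(unique(d[[col]])) < 2) {
      stop("factor '", col, "' needs >= 2 observed levels", call. = FALSE)
    }
  }
}

.converged <- function(fit) {
  isTRUE(fit$fit$convergence == 0) && isTRUE(fit$sdr$pdHess)
}

.ranef_var <- function(fit) {
  v <- tryCatch(glmmTMB::VarCorr(fit)$cond$tree_id[1, 1],
                error = function(e) NA_real_)
  as.numeric(v)
}

.coef_table <- function(fit, robust_vcov = NULL) {
  if (inherits(fit, "glmmTMB")) {
    cf <- summary(fit)$coefficients$cond
    data.frame(term = rownames(cf), estimate = cf[, 1], se = cf[, 2],
               statistic = cf[, 3], p = cf[, 4], row.names = NULL)
  } else {
    ct <- lmtest::coeftest(fit, vcov. = robust_vcov)
    data.frame(term = rownames(ct), estimate = ct[, 1], se = ct[, 2],
               statistic = ct[, 3], p = ct[, 4], row.names = NULL)
  }
}

.anova_table <- function(fit, type, robust_vcov = NULL) {
  a <- if (is.null(robust_vcov)) {
    car::Anova(fit, type = type)
  } else if (inherits(fit, "glm")) {
    car::Anova(fit, type = type, vcov. = robust_vcov, test.statistic = "Wald")
  } else {
    car::Anova(fit, type = type, vcov. = robust_vcov)
  }
  chisq_col <- intersect(c("Chisq", "F"), colnames(a))[1]
  p_col <- grep("^Pr", colnames(a), value = TRUE)[1]
  out <- data.frame(term = rownames(a), chisq = a[[chisq_col]],
                    df = a[["Df"]], p = a[[p_col]],
                    anova_type = if (type == 2) "II" else "III",
                    row.names = NULL)
  out[!is.na(out$df) & out$df >= 1 | out$term == "(Intercept)", , drop = FALSE]
}

.new_model_result <- function(response, fit, method, anova_type, n,
                              robust_vcov = NULL, note = NULL) {
  type_num <- if (anova_type == "II") 2 else 3
  anova <- if (is.null(robust_vcov)) {
    .anova_table(fit, type = type_num)
  } else {
    # a (near-)singular robust vcov cannot support the Wald hypotheses;
    # degrade to the model-based covariance rather than failing the stage
    tryCatch(.anova_table(fit, type = type_num, robust_vcov = robust_vcov),
             error = function(e) {
               note <<- paste(c(note, "robust vcov singular; ANOVA uses model-based vcov"),
                              collapse = "; ")
               .anova_table(fit, type = type_num)
             })
  }
  structure(
    list(
      response = response,
      method = method,
      fit = fit,
      coefficients = .coef_table(fit, robust_vcov),
      anova = anova,
      anova_type = anova_type,
      ranef_var = if (inherits(fit, "glmmTMB")) .ranef_var(fit) else NA_real_,
      converged = if (inherits(fit, "glmmTMB")) .converged(fit) else TRUE,
      n = n,
      note = note
    ),
    class = "dormancy_model"
  )
}

#' @export
print.dormancy_model <- function(x, ...) {
  cat(sprintf("Dormancy response model: %s (%s fit, type %s ANOVA, n = %d)\n",
              x$response, x$method, x$anova_type, x$n))
  if (!is.null(x$note)) cat("note:", x$note, "\n")
  print(x$anova, digits = 4)
  invisible(x)
}

# Fit a glmmTMB mixed model, falling back to a fixed-effects model with
# cluster-robust (by tree) errors when the mixed fit errors or fails to
# converge. Returns the pieces .new_model_result needs.
.fit_with_fallback <- function(mixed_formula, fixed_formula, data, family,
                               method, anova_type, response) {
  method <- match.arg(method, c("auto", "mixed", "fixed"))
  if (method %in% c("auto", "mixed")) {
    fit <- tryCatch(
      suppressWarnings(glmmTMB::glmmTMB(mixed_formula, data = data,
                                        family = family)),
      error = function(e) e
    )
    ok <- !inherits(fit, "error") && .converged(fit)
    if (ok) {
      return(.new_model_result(response, fit, "mixed", anova_type,
                               n = nrow(data)))
    }
    if (method == "mixed") {
      msg <- if (inherits(fit, "error")) conditionMessage(fit)
             else "mixed fit did not converge"
      stop("mixed model failed for response '", response, "': ", msg,
           call. = FALSE)
    }
    note <- "mixed fit unavailable; fixed-effects fit with cluster-robust (tree) errors"
  } else {
    note <- "fixed-effects fit with cluster-robust (tree) errors (requested)"
  }
  fit <- if (identical(family, "gaussian")) {
    stats::lm(fixed_formula, data = data)
  } else {
    stats::glm(fixed_formula, data = data, family = family)
  }
  if (!is.null(fit$rank) && fit$rank < length(stats::coef(fit))) {
    alias <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient design for response '", response, "'; aliased terms: ",
         paste(alias, collapse = ", "), call. = FALSE)
  }
  n_clusters <- length(unique(data$tree_id))
  n_coef <- sum(!is.na(stats::coef(fit)))
  vc <- tryCatch(sandwich::vcovCL(fit, cluster = data$tree_id),
                 error = function(e) NULL)
  if (is.null(vc) || n_clusters <= n_coef) {
    # too few tree clusters to support a cluster-robust covariance of this
    # dimension; use heteroscedasticity-robust errors instead
    vc <- sandwich::vcovHC(fit, type = "HC1")
    note <- paste(note, "(HC1 errors: fewer tree clusters than coefficients)")
  }
  .new_model_result(response, fit, "fixed_cluster_robust", anova_type,
                    n = nrow(data), robust_vcov = vc, note = note)
}

#' Binomial mixed model of budburst success
#'
#' Models per-twig budburst counts (buds at stage >= 2 out of total buds) with
#' a logit-link binomial mixed model: sampling date (continuous), species and
#' site plus every two-way interaction as fixed effects and a random intercept
#' per donor tree. Fixed terms are evaluated with a type II Wald ANOVA. When
#' the mixed fit fails to converge the function falls back to a fixed-effects
#' binomial GLM with cluster-robust standard errors by tree, recorded in the
#' result's `note`.
#'
#' @param table Analysis table from [build_analysis_table()] with twig rows
#'   (`n_buds_ge_stage2`, `n_buds_total` present).
#' @param method `"auto"` (default: mixed with fallback), `"mixed"` or
#'   `"fixed"`.
#' @param interactions Include the two-way interactions (default `TRUE`).
#' @return A `dormancy_model` object.
#' @export
fit_success_model <- function(table, method = "auto", interactions = TRUE) {
  d <- table[!is.na(table$n_buds_ge_stage2) & !is.na(table$n_buds_total), ]
  .check_levels(d, c("species", "site"))
  d <- .prep_factors(d)
  d$date_num <- .date_num(d$campaign_date)
  d$n_fail <- d$n_buds_total - d$n_buds_ge_stage2
  rhs <- if (interactions) "(date_num + species + site)^2"
         else "date_num + species + site"
  .fit_with_fallback(
    stats::as.formula(paste("cbind(n_buds_ge_stage2, n_fail) ~", rhs,
                            "+ (1 | tree_id)")),
    stats::as.formula(paste("cbind(n_buds_ge_stage2, n_fail) ~", rhs)),
    data = d, family = stats::binomial(), method = method,
    anova_type = "II", response = "budburst_success"
  )
}

#' Polynomial mixed model of dormancy depth
#'
#' Models log thermal time to budburst with a Gaussian mixed model: a
#' second-order orthogonal polynomial of sampling date, species and site and
#' all two-way interactions (both polynomial orders interact with species and
#' site) as fixed effects, random intercept per tree, type III Wald ANOVA
#' under sum-to-zero contrasts. Only uncensored twigs sampled on or after
#' `after_date` — conventionally the first frost, after which dormancy depth
#' declines smoothly — enter the fit; the log transform normalizes the
#' strongly right-skewed degree-day requirements.
#'
#' @param table Analysis table with `thermal_time_dd` and `censored`.
#' @param after_date Earliest campaign date retained (Date or string).
#' @param method,interactions See [fit_success_model()].
#' @return A `dormancy_model` object.
#' @export
fit_dormancy_depth_model <- function(table, after_date, method = "auto",
                                     interactions = TRUE) {
  d <- table[!is.na(table$thermal_time_dd) & !table$censored &
               as.Date(table$campaign_date) >= as.Date(after_date), ]
  if (length(unique(d$campaign_date)) <= 1) {
    stop("insufficient data: <= 1 campaign on or after ", after_date,
         call. = FALSE)
  }
  if (any(d$thermal_time_dd <= 0)) {
    d <- d[d$thermal_time_dd > 0, ]
  }
  .check_levels(d, c("species", "site"))
  d <- .prep_factors(d, sum_contrasts = TRUE)
  d$date_num <- .date_num(d$campaign_date)
  d$ln_tt <- log(d$thermal_time_dd)
  rhs <- if (interactions) "(poly(date_num, 2) + species + site)^2"
         else "poly(date_num, 2) + species + site"
  .fit_with_fallback(
    stats::as.formula(paste("ln_tt ~", rhs, "+ (1 | tree_id)")),
    stats::as.formula(paste("ln_tt ~", rhs)),
    data = d, family = "gaussian", method = method,
    anova_type = "III", response = "dormancy_depth_ln_thermal_time"
  )
}

#' Campaign-factor mixed model of water content or uptake
#'
#' Models bud water content or short-term label uptake with sampling campaign
#' as a categorical factor (so non-linear seasonal trajectories are free of
#' functional-form assumptions and individual campaigns are comparable),
#' species, site and all two-way interactions as fixed effects, random
#' intercept per tree, type III Wald ANOVA under sum-to-zero contrasts.
#' Responses are Gaussian on the percent scale; water content may optionally
#' be logit-transformed first.
#'
#' @param table Analysis table with `water_content_pct` / `uptake_pct`.
#' @param response `"water_content"` or `"uptake"`.
#' @param method,interactions See [fit_success_model()].
#' @param logit_water Logit-transform water content (default `FALSE`).
#' @return A `dormancy_model` object.
#' @export
fit_campaign_model <- function(table, response = c("water_content", "uptake"),
                               method = "auto", interactions = TRUE,
                               logit_water = FALSE) {
  response <- match.arg(response)
  col <- if (response == "water_content") "water_content_pct" else "uptake_pct"
  d <- table[!is.na(table[[col]]), ]
  if (length(unique(d$campaign_index)) < 2) {
    stop("need data from >= 2 campaigns", call. = FALSE)
  }
  .check_levels(d, c("species", "site"))
  d$campaign <- d$campaign_index
  d <- .prep_factors(d, sum_contrasts = TRUE)
  d$y <- d[[col]]
  if (response == "water_content" && logit_water) {
    d$y <- stats::qlogis(pmin(pmax(d$y / 100, 1e-6), 1 - 1e-6))
  }
  if (interactions) {
    cells <- base::table(d$campaign, d$species)
    if (any(cells == 0)) {
      warning("empty campaign x species cells; their interaction contrasts ",
              "are not estimable", call. = FALSE)
    }
  }
  rhs <- if (interactions) "(campaign + species + site)^2"
         else "campaign + species + site"
  .fit_with_fallback(
    stats::as.formula(paste("y ~", rhs, "+ (1 | tree_id)")),
    stats::as.formula(paste("y ~", rhs)),
    data = d, family = "gaussian", method = method,
    anova_type = "III", response = response
  )
}

#' Tukey HSD post-hoc contrasts
#'
#' All pairwise level contrasts of a factor in a fitted dormancy model, with
#' Tukey family-wise adjustment of p-values (via estimated marginal means).
#'
#' @param model A `dormancy_model`.
#' @param factor Name of a factor in the model (`"species"`, `"site"`,
#'   `"campaign"`).
#' @return Data frame of contrasts: `contrast`, `estimate`, `se`, `df`,
#'   `statistic`, `p_adjusted`.
#' @export
tukey_contrasts <- function(model, factor) {
  stopifnot(inherits(model, "dormancy_model"))
  terms_used <- all.vars(stats::formula(model$fit))
  if (!factor %in% terms_used) {
    stop("factor '", factor, "' is not a term of the ", model$response,
         " model", call. = FALSE)
  }
  emm <- suppressMessages(emmeans::emmeans(model$fit, specs = factor))
  pr <- summary(emmeans::contrast(emm, method = "pairwise", adjust = "tukey"))
  stat_col <- intersect(c("z.ratio", "t.ratio"), names(pr))[1]
  data.frame(contrast = as.character(pr$contrast), estimate = pr$estimate,
             se = pr$SE, df = pr$df, statistic = pr[[stat_col]],
             p_adjusted = pr$p.value, row.names = NULL)
}

#' Species-specific Pearson correlations between dormancy proxies
#'
#' Pearson correlations between budburst success, dormancy depth (thermal
#' time), bud water content and short-term label uptake, computed per species
#' across (tree, campaign) pairs. Early autumn campaigns — when leaves are
#' still attached and photosynthetically active — are excluded by default
#' (campaigns 1-3) so the correlations reflect bud-internal dormancy.
#'
#' @param table Analysis table from [build_analysis_table()].
#' @param exclude_campaigns Campaign indices to drop (default `1:3`; use
#'   `integer(0)` for none).
#' @param pairing `"tree_campaign"` (default: average twig/bud values per tree
#'   and campaign before correlating) or `"row"` (raw row-level pairing).
#' @param min_pairs Minimum complete pairs needed per species x variable pair
#'   (default 4); sparser entries are returned with `computable = FALSE`
#'   rather than dropped.
#' @return Data frame: `species`, `var1`, `var2`, `r`, `p`, `n`, `computable`.
#' @export
dormancy_correlations <- function(table, exclude_campaigns = 1:3,
                                  pairing = c("tree_campaign", "row"),
                                  min_pairs = 4) {
  pairing <- match.arg(pairing)
  vars <- c(success = "success_fraction", depth = "thermal_time_dd",
            water_content = "water_content_pct", uptake = "uptake_pct")
  d <- table[!table$campaign_index %in% exclude_campaigns, ]
  if (pairing == "tree_campaign") {
    agg <- stats::aggregate(
      d[intersect(names(d), vars)],
      by = list(species = d$species, site = d$site, tree_id = d$tree_id,
                campaign_index = d$campaign_index),
      FUN = function(x) mean(x, na.rm = TRUE)
    )
    d <- agg
  }
  pairs_idx <- utils::combn(names(vars), 2, simplify = FALSE)
  out <- list()
  for (sp in sort(unique(as.character(d$species)))) {
    ds <- d[d$species == sp, ]
    for (pv in pairs_idx) {
      c1 <- vars[[pv[1]]]; c2 <- vars[[pv[2]]]
      x <- if (c1 %in% names(ds)) ds[[c1]] else rep(NA_real_, nrow(ds))
      y <- if (c2 %in% names(ds)) ds[[c2]] else rep(NA_real_, nrow(ds))
      ok <- is.finite(x) & is.finite(y)
      n <- sum(ok)
      if (n >= min_pairs && stats::sd(x[ok]) > 0 && stats::sd(y[ok]) > 0) {
        ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
        row <- data.frame(species = sp, var1 = pv[1], var2 = pv[2],
                          r = unname(ct$estimate), p = ct$p.value, n = n,
                          computable = TRUE)
      } else {
        row <- data.frame(species = sp, var1 = pv[1], var2 = pv[2],
                          r = NA_real_, p = NA_real_, n = n,
                          computable = FALSE)
      }
      out[[length(out) + 1]] <- row
    }
  }
  do.call(rbind, out)
}

#' Detect the onset of endodormancy from an uptake trajectory
#'
#' Change-point rule for the characteristic autumn pattern of short-term
#' labelled-water uptake: a senescence-time peak followed by a collapse to
#' near zero when symplastic isolation of the bud sets in. The onset is the
#' first campaign after the peak whose mean uptake falls below
#' `threshold_fraction` x peak and stays below it at the following campaign
#' (one-campaign persistence, so a single noisy dip does not trigger). The
#' rule is invariant to uniform rescaling of the series.
#'
#' @param uptake_mean Numeric vector of per-campaign mean uptake (percent).
#' @param campaign_index Campaign indices (default `seq_along(uptake_mean)`).
#' @param threshold_fraction Fraction of the peak defining "collapsed"
#'   (default 0.1).
#' @param peak_window Optional subset of `campaign_index` within which the
#'   peak is searched (e.g. autumn campaigns only); default all.
#' @param species,site_scope Metadata echoed into the result.
#' @return An `onset_estimate`: `species`, `site_scope`,
#'   `onset_campaign_index` (`NA` when no campaign satisfies persistence,
#'   with `detected = FALSE`), `peak_campaign_index`, `peak_uptake_pct`,
#'   `post_drop_mean_pct`, `threshold_fraction`.
#' @export
detect_endodormancy_onset <- function(uptake_mean,
                                      campaign_index = seq_along(uptake_mean),
                                      threshold_fraction = 0.1,
                                      peak_window = NULL,
                                      species = NA_character_,
                                      site_scope = "pooled") {
  stopifnot(length(uptake_mean) == length(campaign_index),
            threshold_fraction > 0, threshold_fraction < 1)
  ord <- order(campaign_index)
  uptake_mean <- uptake_mean[ord]
  campaign_index <- campaign_index[ord]
  if (length(uptake_mean) < 4) {
    stop("need >= 4 campaigns to detect an onset", call. = FALSE)
  }
  if (!any(uptake_mean > 0, na.rm = TRUE)) {
    stop("all campaign means are <= 0; no uptake signal", call. = FALSE)
  }
  in_window <- if (is.null(peak_window)) rep(TRUE, length(campaign_index))
               else campaign_index %in% peak_window
  peak_pos <- which(in_window)[which.max(uptake_mean[in_window])]
  peak <- uptake_mean[peak_pos]
  cut <- threshold_fraction * peak
  onset_pos <- NA_integer_
  if (peak_pos < length(uptake_mean) - 1) {
    for (i in (peak_pos + 1):(length(uptake_mean) - 1)) {
      if (!is.na(uptake_mean[i]) && uptake_mean[i] < cut &&
          !is.na(uptake_mean[i + 1]) && uptake_mean[i + 1] < cut) {
        onset_pos <- i
        break
      }
    }
  }
  detected <- !is.na(onset_pos)
  structure(
    list(
      species = species, site_scope = site_scope,
      onset_campaign_index = if (detected) campaign_index[onset_pos] else NA_integer_,
      peak_campaign_index = campaign_index[peak_pos],
      peak_uptake_pct = peak,
      post_drop_mean_pct = if (detected) mean(uptake_mean[onset_pos:length(uptake_mean)])
                           else NA_real_,
      threshold_fraction = threshold_fraction,
      detected = detected
    ),
    class = "onset_estimate"
  )
}

#' @export
print.onset_estimate <- function(x, ...) {
  if (x$detected) {
    cat(sprintf(
      "Endodormancy onset%s: campaign %d (peak %.1f%% at campaign %d, post-drop mean %.2f%%)\n",
      if (is.na(x$species)) "" else paste0(" [", x$species, "]"),
      x$onset_campaign_index, x$peak_uptake_pct, x$peak_campaign_index,
      x$post_drop_mean_pct))
  } else {
    cat("No endodormancy onset detected (persistence rule unmet)\n")
  }
  invisible(x)
}
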