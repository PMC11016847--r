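p_of <- function(model, term) {
  a <- model$anova
  a$p[a$term == term]
}

test_that("analysis table joins assays at tree x campaign and indexes campaigns", {
  sim <- default_sim_cached()
  rep <- default_report_cached()
  tab <- rep$analysis_table
  expect_true(all(c("species", "site", "tree_id", "campaign_date",
                    "campaign_index", "success_fraction", "thermal_time_dd",
                    "water_content_pct", "uptake_pct") %in% names(tab)))
  # campaign index consistent with date order
  ord <- order(tab$campaign_date)
  expect_true(all(diff(tab$campaign_index[ord]) >= 0))
  expect_equal(sort(unique(tab$campaign_index)), 1:15)
  # extra campaigns carry no twig assay
  extra <- tab[tab$campaign_index %in% c(8, 10, 12), ]
  expect_true(all(is.na(extra$thermal_time_dd)))
  expect_true(all(!is.na(extra$uptake_pct)))
  # no duplicated twig rows
  tw <- tab$twig_id[!is.na(tab$twig_id)]
  expect_false(any(duplicated(tw)))
})

test_that("success model finds a programmed date effect with the right sign", {
  tab <- simulate_success_table(beta_date = 0.8, seed = 101)
  m <- fit_success_model(tab)
  expect_s3_class(m, "dormancy_model")
  expect_equal(m$anova_type, "II")
  expect_lt(p_of(m, "date_num"), 0.05)
  expect_gt(m$coefficients$estimate[m$coefficients$term == "date_num"], 0)
  expect_true(all(m$anova$p >= 0 & m$anova$p <= 1))
  expect_equal(m$n, nrow(tab))
})

test_that("success model stays quiet on null data", {
  tab <- simulate_success_table(beta_date = 0, seed = 202)
  m <- fit_success_model(tab)
  expect_gt(p_of(m, "date_num"), 0.05)
  # near-zero slope estimate
  est <- m$coefficients$estimate[m$coefficients$term == "date_num"]
  se <- m$coefficients$se[m$coefficients$term == "date_num"]
  expect_lt(abs(est) / se, 3)
})

test_that("species-specific slopes surface as a date x species interaction", {
  hits <- vapply(1:5, function(s) {
    tab <- simulate_success_table(beta_date = 0.3, species_slope_sd = 0.5,
                                  seed = 300 + s)
    m <- fit_success_model(tab)
    p_of(m, "date_num:species") < 0.05
  }, logical(1))
  expect_gte(sum(hits), 3)
})

test_that("fallback fixed-effects fit reproduces mixed-model signs", {
  tab <- simulate_success_table(beta_date = 0.8, species_sd = 0.8, seed = 404)
  m_mixed <- fit_success_model(tab, method = "mixed")
  m_fixed <- fit_success_model(tab, method = "fixed")
  expect_equal(m_fixed$method, "fixed_cluster_robust")
  shared <- intersect(m_mixed$coefficients$term, m_fixed$coefficients$term)
  s1 <- sign(m_mixed$coefficients$estimate[match(shared, m_mixed$coefficients$term)])
  s2 <- sign(m_fixed$coefficients$estimate[match(shared, m_fixed$coefficients$term)])
  expect_equal(s1, s2)
})

test_that("depth model detects a linear decline without inventing curvature", {
  tab <- simulate_depth_table(beta_date = -0.4, seed = 77)
  m <- fit_dormancy_depth_model(tab, after_date = "2019-11-27")
  expect_equal(m$anova_type, "III")
  expect_lt(p_of(m, "poly(date_num, 2)"), 0.05)
  # quadratic coefficient itself not significant on linear truth
  cf <- m$coefficients
  p_quad <- cf$p[cf$term == "poly(date_num, 2)2"]
  expect_gt(p_quad, 0.05)

  # null: constant thermal time
  tab0 <- simulate_depth_table(beta_date = 0, seed = 78)
  m0 <- fit_dormancy_depth_model(tab0, after_date = "2019-11-27")
  for (term in c("poly(date_num, 2)", "species", "site")) {
    expect_gt(p_of(m0, term), 0.05)
  }

  # site offset detected
  tab_s <- simulate_depth_table(beta_date = -0.2, site_effect = -0.3, seed = 79)
  m_s <- fit_dormancy_depth_model(tab_s, after_date = "2019-11-27")
  expect_lt(p_of(m_s, "site"), 0.05)
})

test_that("depth model enforces its campaign filter", {
  tab <- simulate_depth_table(seed = 80)
  expect_error(fit_dormancy_depth_model(tab, after_date = max(tab$campaign_date)),
               "insufficient data")
  # censored twigs are excluded
  tab$censored[1:10] <- TRUE
  m <- fit_dormancy_depth_model(tab, after_date = "2019-11-27")
  expect_equal(m$n, nrow(tab) - 10)
})

test_that("campaign model reads categorical campaign structure", {
  # null: flat response, two identical sites
  tab0 <- simulate_campaign_table(seed = 90)
  m0 <- fit_campaign_model(tab0, "water_content")
  expect_gt(p_of(m0, "campaign"), 0.05)
  expect_gt(p_of(m0, "site"), 0.05)

  # step at campaign 5 in species 2 only -> campaign x species interaction
  tab1 <- simulate_campaign_table(step_campaign = 5, step_species = 2,
                                  step_size = 8, seed = 91)
  m1 <- fit_campaign_model(tab1, "water_content")
  expect_lt(p_of(m1, "campaign:species"), 0.05)

  # uptake response column is honoured
  tab2 <- simulate_campaign_table(response = "uptake_pct", seed = 92)
  m2 <- fit_campaign_model(tab2, "uptake")
  expect_equal(m2$response, "uptake")
})

test_that("type II and III agree on a balanced design without interactions", {
  tab <- simulate_campaign_table(seed = 93)
  m <- fit_campaign_model(tab, "water_content", interactions = FALSE,
                          method = "fixed")
  a2 <- isobud:::.anova_table(m$fit, type = 2,
                              robust_vcov = sandwich::vcovCL(m$fit, cluster = NULL))
  a3 <- isobud:::.anova_table(m$fit, type = 3,
                              robust_vcov = sandwich::vcovCL(m$fit, cluster = NULL))
  shared <- intersect(a2$term, a3$term)
  shared <- setdiff(shared, "(Intercept)")
  expect_equal(a2$chisq[match(shared, a2$term)],
               a3$chisq[match(shared, a3$term)], tolerance = 1e-8)
})

test_that("Tukey contrasts cover all level pairs and respect nulls", {
  # two-level factor: single contrast, adjustment is a no-op
  tab <- simulate_campaign_table(seed = 94)
  m <- fit_campaign_model(tab, "water_content", interactions = FALSE)
  ct_site <- tukey_contrasts(m, "site")
  expect_equal(nrow(ct_site), 1)
  raw <- summary(emmeans::contrast(
    suppressMessages(emmeans::emmeans(m$fit, "site")), "pairwise",
    adjust = "none"))
  expect_equal(ct_site$p_adjusted, raw$p.value, tolerance = 1e-8)

  # five identical species levels: nothing significant
  ct_sp <- tukey_contrasts(m, "species")
  expect_equal(nrow(ct_sp), choose(5, 2))
  expect_true(all(ct_sp$p_adjusted > 0.05))

  # one species shifted far: its contrasts dominate
  tab2 <- simulate_campaign_table(step_campaign = 1, step_species = 3,
                                  step_size = 10, seed = 95)
  m2 <- fit_campaign_model(tab2, "water_content", interactions = FALSE)
  ct2 <- tukey_contrasts(m2, "species")
  involving <- grepl("sp3", ct2$contrast)
  expect_true(all(ct2$p_adjusted[involving] < 0.05))
  expect_error(tukey_contrasts(m2, "elevation"), "not a term")
})

test_that("correlation stage matches a hand-rolled Pearson oracle", {
  rep <- default_report_cached()
  tab <- rep$analysis_table
  cors <- dormancy_correlations(tab, exclude_campaigns = 1:3)
  # recompute one entry with explicit formulas
  agg <- stats::aggregate(
    cbind(thermal_time_dd, water_content_pct) ~ species + site + tree_id +
      campaign_index,
    data = tab[!tab$campaign_index %in% 1:3, ], FUN = mean, na.action = stats::na.pass)
  for (sp in unique(tab$species)) {
    d <- agg[agg$species == sp, ]
    ok <- is.finite(d$thermal_time_dd) & is.finite(d$water_content_pct)
    x <- d$thermal_time_dd[ok]; y <- d$water_content_pct[ok]
    r_oracle <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    row <- cors[cors$species == sp & cors$var1 == "depth" &
                  cors$var2 == "water_content", ]
    expect_equal(row$r, r_oracle, tolerance = 1e-10)
    expect_equal(row$n, sum(ok))
  }
})

test_that("correlations handle perfect association and sparse cells", {
  tab <- simulate_depth_table(n_species = 1, seed = 96)
  tab$water_content_pct <- 80 - 0.02 * tab$thermal_time_dd # exact affine
  cors <- dormancy_correlations(tab, exclude_campaigns = integer(0))
  row <- cors[cors$var1 == "depth" & cors$var2 == "water_content", ]
  expect_equal(row$r, -1, tolerance = 1e-12)
  # insufficient pairs flagged, not dropped
  tab$water_content_pct[-(1:3)] <- NA
  cors2 <- dormancy_correlations(tab, exclude_campaigns = integer(0))
  row2 <- cors2[cors2$var1 == "depth" & cors2$var2 == "water_content", ]
  expect_false(row2$computable)
  expect_true(is.na(row2$r))
  expect_equal(nrow(cors2), nrow(cors))
})

test_that("campaign exclusion attenuates the senescence-driven uptake-depth link", {
  rep <- default_report_cached()
  tab <- rep$analysis_table
  full <- dormancy_correlations(tab, exclude_campaigns = integer(0))
  filt <- dormancy_correlations(tab, exclude_campaigns = 1:3)
  f_r <- full$r[full$var1 == "depth" & full$var2 == "uptake"]
  g_r <- filt$r[filt$var1 == "depth" & filt$var2 == "uptake"]
  # dropping the senescence peak weakens the association on average
  expect_lt(mean(abs(g_r), na.rm = TRUE), mean(abs(f_r), na.rm = TRUE))
})

test_that("onset detection follows the peak-collapse-persistence rule", {
  o <- detect_endodormancy_onset(c(0.5, 8, 9, 0.3, 0.2, 0.2),
                                 threshold_fraction = 0.1)
  expect_true(o$detected)
  expect_equal(o$onset_campaign_index, 4)
  expect_equal(o$peak_campaign_index, 3)
  expect_equal(o$peak_uptake_pct, 9)
  expect_lte(o$post_drop_mean_pct, o$peak_uptake_pct)

  # monotone increasing: no onset
  o2 <- detect_endodormancy_onset(c(1, 2, 3, 4, 5))
  expect_false(o2$detected)
  expect_true(is.na(o2$onset_campaign_index))

  # a single dip does not satisfy persistence
  o3 <- detect_endodormancy_onset(c(1, 9, 0.1, 5, 6, 7))
  expect_false(o3$detected)

  # rescale invariance
  x <- c(0.5, 8, 9, 0.3, 0.2, 0.2)
  o4 <- detect_endodormancy_onset(1000 * x, threshold_fraction = 0.1)
  expect_equal(o4$onset_campaign_index, o$onset_campaign_index)
  expect_equal(o4$peak_campaign_index, o$peak_campaign_index)

  expect_error(detect_endodormancy_onset(c(1, 2, 3)), ">= 4")
  expect_error(detect_endodormancy_onset(c(0, 0, 0, 0)), "no uptake signal")
})
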