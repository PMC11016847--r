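test_that("temperature generator degenerates to a constant and is seeded", {
  st <- site_params("flat", annual_mean_c = 6, seasonal_amplitude_c = 0,
                    diurnal_amplitude_c = 0, noise_sd_c = 0)
  tp <- simulate_temperatures(st, "2019-11-01", "2019-12-15")
  expect_true(all(tp$temp_c == 6))

  st2 <- default_sites()$lowland
  a <- simulate_temperatures(st2, "2019-11-01", "2019-12-15", seed = 9)
  b <- simulate_temperatures(st2, "2019-11-01", "2019-12-15", seed = 9)
  expect_identical(a, b)
  expect_error(simulate_temperatures(st2, "2019-11-01", "2019-11-10"),
               ">= 30 days")
})

test_that("the two default sites differ by about their programmed offset", {
  sites <- default_sites()
  a <- simulate_temperatures(sites$lowland, "2019-10-11", "2020-04-01", seed = 3)
  b <- simulate_temperatures(sites$highland, "2019-10-11", "2020-04-01", seed = 4)
  diff_c <- mean(a$temp_c) - mean(b$temp_c)
  expect_equal(diff_c,
               sites$lowland$annual_mean_c - sites$highland$annual_mean_c,
               tolerance = 0.5)
})

test_that("dormancy trajectory accumulates chilling hours as constructed", {
  sp <- default_species()$beech
  # all days warm: no chill, depth pinned at its autumn level
  warm <- data.frame(site = "A", date = as.Date("2019-10-01") + 0:180,
                     mean_c = 20, min_c = 18, max_c = 22, sd_c = 1,
                     n_hours = 24, chill_hours = 0, complete = TRUE)
  camps <- as.Date(c("2019-10-10", "2019-12-01", "2020-02-01", "2020-03-25"))
  tr <- simulate_dormancy_trajectory(sp, warm, camps)
  expect_true(all(tr$chill_accum_h == 0))
  expect_true(all(tr$dormancy_depth_dd == sp$initial_depth_dd))
  expect_true(all(!tr$released))

  # all days at 5 C: 24 chilling hours per day, release when the requirement
  # is met
  cold <- warm
  cold$mean_c <- 5; cold$min_c <- 5; cold$max_c <- 5; cold$chill_hours <- 24
  tr2 <- simulate_dormancy_trajectory(sp, cold, camps)
  days_before <- as.numeric(camps - as.Date("2019-10-01"))
  expect_equal(tr2$chill_accum_h, 24 * days_before)
  expect_equal(tr2$released, 24 * days_before >= sp$chill_requirement_h)

  # depth is non-increasing across campaigns
  expect_true(all(diff(tr2$dormancy_depth_dd) <= 0))
  expect_true(all(tr2$dormancy_depth_dd >= sp$forcing_requirement_dd))
  expect_true(all(tr2$p_success >= sp$base_success &
                    tr2$p_success <= sp$max_success))
})

test_that("noise-free experiment is exactly invertible by the pipeline", {
  sim <- simulate_experiment(noiseless_config(seed = 7))
  rep <- run_pipeline(sim)
  m <- merge(rep$uptake, sim$truth, by = "sample_id")
  expect_gt(nrow(m), 100)
  expect_lt(max(abs(m$uptake_pct - m$uptake_true_pct)), 1e-6)
  w <- merge(rep$water_content, sim$truth, by = "sample_id")
  expect_lt(max(abs(w$water_content_pct - w$wc_true_pct), na.rm = TRUE), 1e-9)
})

test_that("generated data respect their physical bounds", {
  sim <- default_sim_cached()
  wc <- bud_water_content(sim$mass$fresh_mass_mg, sim$mass$dry_mass_mg)
  expect_true(all(wc > 0 & wc < 100))
  succ <- sim$phenology$n_buds_ge_stage2 / sim$phenology$n_buds_total
  expect_true(all(succ >= 0 & succ <= 1))
  lab <- sim$isotopes[sim$isotopes$is_labelled, ]
  expect_true(all(lab$d2H <= sim$config$label$d2h_label + 5))
  expect_true(all(sim$isotopes$d2H > -1000 & sim$isotopes$d18O > -1000))
  expect_true(all(sim$truth$uptake_true_pct >= 0 &
                    sim$truth$uptake_true_pct <= 100))
  # twig-tissue samples exist only at campaign 9 and show extra uptake there
  tw <- sim$truth[sim$truth$tissue == "twig", ]
  expect_true(all(tw$campaign_index == 9))
  bud9 <- sim$truth[sim$truth$tissue == "bud" & sim$truth$campaign_index == 9, ]
  expect_gt(mean(tw$uptake_true_pct), mean(bud9$uptake_true_pct))
})

test_that("simulation output files are byte-identical under a fixed seed", {
  d1 <- file.path(tempdir(), "simA"); d2 <- file.path(tempdir(), "simB")
  write_simulation(simulate_experiment(sim_config(seed = 31)), d1)
  write_simulation(simulate_experiment(sim_config(seed = 31)), d2)
  for (f in c("temps.csv", "phenology.csv", "mass.csv", "isotopes.csv",
              "truth.csv")) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))), label = f)
  }
  # a different seed changes the data
  d3 <- file.path(tempdir(), "simC")
  write_simulation(simulate_experiment(sim_config(seed = 32)), d3)
  expect_false(identical(unname(tools::md5sum(file.path(d1, "isotopes.csv"))),
                         unname(tools::md5sum(file.path(d3, "isotopes.csv")))))
  unlink(c(d1, d2, d3), recursive = TRUE)
})

test_that("fitted background lines recover the generator's species lines", {
  sim <- default_sim_cached()
  lines <- fit_background_lines(sim$isotopes)
  for (sp_name in names(sim$config$species)) {
    sp <- sim$config$species[[sp_name]]
    ln <- lines[[sp_name]]
    expect_lt(abs(ln$beta1 - sp$background_beta1), 4 * ln$se_beta1)
    expect_lt(abs(ln$beta0 - sp$background_beta0), 4 * ln$se_beta0)
    expect_true(line_vs_gmwl(ln)$evaporative_flag)
  }
})

test_that("focused model-stage generators honour their programmed effects", {
  tab <- simulate_success_table(beta_date = 2, n_campaigns = 6, seed = 5)
  agg <- stats::aggregate(success_fraction ~ campaign_index, tab, mean)
  expect_gt(stats::cor(agg$campaign_index, agg$success_fraction), 0.8)

  tab2 <- simulate_depth_table(beta_date = -0.5, seed = 6)
  agg2 <- stats::aggregate(thermal_time_dd ~ campaign_index, tab2, mean)
  expect_true(all(diff(log(agg2$thermal_time_dd)) < 0))

  tab3 <- simulate_campaign_table(step_campaign = 4, step_species = 2,
                                  step_size = 10, resid_sd = 0.5, seed = 8)
  sp2 <- tab3[tab3$species == "sp2", ]
  expect_gt(mean(sp2$water_content_pct[sp2$campaign_index >= 4]) -
              mean(sp2$water_content_pct[sp2$campaign_index < 4]), 5)
})
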