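# Shared fixtures. Everything is built in code; the default-seed experiment
# and its pipeline report are computed once per test run and reused.

.fixture_env <- new.env(parent = emptyenv())

default_sim_cached <- function(seed = 1) {
  key <- paste0("sim_", seed)
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- simulate_experiment(sim_config(seed = seed))
  }
  .fixture_env[[key]]
}

default_report_cached <- function(seed = 1) {
  key <- paste0("report_", seed)
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- run_pipeline(default_sim_cached(seed))
  }
  .fixture_env[[key]]
}

# a background_line with chosen coefficients, bypassing the fitter
make_line <- function(beta0, beta1, n = 10, residual_sd = 0,
                      se_beta0 = 0, se_beta1 = 0, species = "testsp") {
  structure(list(species = species, beta0 = beta0, beta1 = beta1, n = n,
                 residual_sd = residual_sd, se_beta0 = se_beta0,
                 se_beta1 = se_beta1),
            class = "background_line")
}

# exact points on a line, as an isotope table
line_points <- function(beta0, beta1, d18O, species = "testsp") {
  data.frame(sample_id = paste0("s", seq_along(d18O)), species = species,
             site = "A", tree_id = "t1", campaign_date = as.Date("2021-01-21"),
             tissue = "bud", d2H = beta0 + beta1 * d18O, d18O = d18O,
             is_labelled = FALSE)
}

# a configuration with all instrument/assay noise terms zeroed (biological
# spread in d18O is retained so the background lines stay identifiable)
noiseless_config <- function(seed = 7, n_trees = 2) {
  sim_config(seed = seed, n_trees_per_species_site = n_trees,
             noise = list(d2H_sd = 0, d18O_sd = 0, wc_sd_pct = 0,
                          uptake_sd_pct = 0, tt_sd_log = 0, d18O_bio_sd = 1.2))
}
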