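test_that("delta to atom percent matches closed-form evaluation", {
  r <- 1.5576e-4
  # independent closed-form oracle: atom% = 100*Rs/(1+Rs), Rs = r*(d/1000+1)
  oracle <- function(d) {
    rs <- r * (d / 1000 + 1)
    100 * rs / (1 + rs)
  }
  expect_equal(delta_to_atom_percent(0, r), oracle(0), tolerance = 1e-12)
  expect_equal(delta_to_atom_percent(0, r), 0.015574, tolerance = 1e-4)
  expect_equal(delta_to_atom_percent(2000, r), oracle(2000), tolerance = 1e-12)
  expect_equal(delta_to_atom_percent(2000, r), 0.046706, tolerance = 1e-4)
  # zero heavy-isotope limit
  expect_lt(delta_to_atom_percent(-1000 + 1e-9, r), 1e-12)
  # vectorized
  expect_equal(delta_to_atom_percent(c(0, 2000), r),
               c(oracle(0), oracle(2000)))
})

test_that("delta scale lower bound is enforced, naming the sample", {
  expect_error(delta_to_atom_percent(-1000, 1.5576e-4), "-1000")
  expect_error(delta_to_atom_percent(c(5, -1200), 1.5576e-4,
                                     sample_id = c("a", "bud17")),
               "bud17")
})

test_that("atom percent conversion is strictly monotone and invertible", {
  r <- 1.5576e-4
  set.seed(11)
  deltas <- sort(stats::runif(200, -900, 10000))
  ap <- delta_to_atom_percent(deltas, r)
  expect_true(all(diff(ap) > 0))
  expect_true(all(ap > 0 & ap < 100))
  back <- atom_percent_to_delta(ap, r)
  rel_err <- abs(back - deltas) / pmax(abs(deltas), 1)
  expect_lt(max(rel_err), 1e-10)
  # closed-form inverse at the reference point
  expect_equal(atom_percent_to_delta(100 * r / (1 + r), r), 0,
               tolerance = 1e-10)
  expect_error(atom_percent_to_delta(0, r), "outside")
  expect_error(atom_percent_to_delta(100, r), "outside")
})

test_that("background line fitting recovers exact lines", {
  pts <- line_points(10, 8, d18O = c(-15, -10, -5, 0, 5))
  ln <- fit_background_line(pts, species = "testsp")
  expect_equal(ln$beta1, 8, tolerance = 1e-10)
  expect_equal(ln$beta0, 10, tolerance = 1e-10)
  expect_equal(ln$residual_sd, 0, tolerance = 1e-8)
  expect_equal(ln$n, 5)

  ln2 <- fit_background_line(line_points(-4, 5, d18O = c(-12, -8, -3)))
  expect_equal(ln2$beta1, 5, tolerance = 1e-10)
  expect_equal(ln2$beta0, -4, tolerance = 1e-10)
})

test_that("background line fit equals the closed-form OLS oracle", {
  set.seed(21)
  for (i in 1:5) {
    n <- sample(5:30, 1)
    x <- stats::rnorm(n, -10, 3)
    y <- 2 + 5.5 * x + stats::rnorm(n, 0, 2)
    pts <- line_points(0, 0, d18O = x)
    pts$d2H <- y
    ln <- fit_background_line(pts)
    # sums-of-squares formulas, independent of lm()
    b1 <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
    b0 <- mean(y) - b1 * mean(x)
    expect_equal(ln$beta1, b1, tolerance = 1e-8)
    expect_equal(ln$beta0, b0, tolerance = 1e-8)
    # permutation invariance
    perm <- sample(n)
    ln_p <- fit_background_line(pts[perm, ])
    expect_equal(ln_p$beta1, ln$beta1, tolerance = 1e-12)
    expect_equal(ln_p$beta0, ln$beta0, tolerance = 1e-12)
  }
})

test_that("background line fitting rejects degenerate inputs", {
  expect_error(fit_background_line(line_points(1, 2, d18O = c(-5, -4))),
               "at least 3")
  expect_error(fit_background_line(line_points(1, 2, d18O = c(-5, -5, -5))),
               "degenerate")
  # labelled samples never enter a species fit
  pts <- line_points(10, 8, d18O = c(-5, -4, -3, -2))
  pts$is_labelled <- c(FALSE, FALSE, TRUE, TRUE)
  expect_error(fit_background_line(pts, species = "testsp"), "at least 3")
})

test_that("background prediction is the line evaluated at the sample d18O", {
  expect_equal(predict_background_d2h(make_line(10, 5), -10), -40)
  expect_equal(predict_background_d2h(make_line(0, 0), 123), 0)
  expect_equal(predict_background_d2h(make_line(10, 8), 0), 10)
  expect_equal(predict_background_d2h(make_line(10, 8), c(0, -10)), c(10, -70))
})

test_that("label uptake spans the background-to-label mixing line", {
  ln <- make_line(-25, 5.5)
  lab <- label_spec(2000)
  cst <- isotope_constants()
  d18 <- -10
  bg <- predict_background_d2h(ln, d18)
  expect_equal(as.numeric(label_uptake_percent(bg, d18, ln, lab, cst)), 0,
               tolerance = 1e-10)
  expect_equal(as.numeric(label_uptake_percent(2000, d18, ln, lab, cst)), 100,
               tolerance = 1e-10)
  # strictly increasing in sample d2H
  u <- as.numeric(label_uptake_percent(seq(bg, 2000, length.out = 25),
                                       rep(d18, 25), ln, lab, cst))
  expect_true(all(diff(u) > 0))
})

test_that("uptake arithmetic reproduces stated atom-percent ratios", {
  cst <- isotope_constants()
  r <- cst$r_standard_2h
  # construct deltas whose atom percents are exactly 0.015, 0.020, 0.060
  d_bg <- atom_percent_to_delta(0.015, r)
  d_s <- atom_percent_to_delta(0.020, r)
  d_lab <- atom_percent_to_delta(0.060, r)
  ln <- make_line(d_bg, 0) # flat line: background independent of d18O
  u <- label_uptake_percent(d_s, 0, ln, label_spec(d_lab), cst)
  expect_equal(as.numeric(u), (0.020 - 0.015) / (0.060 - 0.015) * 100,
               tolerance = 1e-9)
  expect_equal(as.numeric(u), 11.1111, tolerance = 1e-4)
})

test_that("uptake values are flagged, not clipped, and the guard trips", {
  ln <- make_line(-25, 5.5)
  cst <- isotope_constants()
  bg <- predict_background_d2h(ln, -10)
  u <- label_uptake_percent(bg - 150, -10, ln, label_spec(2000), cst)
  expect_lt(as.numeric(u), -5)
  expect_equal(attr(u, "qc_flag"), "outside_range")
  expect_error(
    label_uptake_percent(0, -10, ln, label_spec(bg + 50), cst,
                         sample_id = "s9"),
    "ill-conditioned"
  )
})

test_that("meteoric-line comparison flags evaporative slopes", {
  d1 <- line_vs_gmwl(make_line(10, 8, se_beta1 = 0.01))
  expect_equal(d1$slope_deficit, 0)
  expect_false(d1$evaporative_flag)
  d2 <- line_vs_gmwl(make_line(0, 5, se_beta1 = 0.5))
  expect_equal(d2$slope_deficit, 3)
  expect_true(d2$evaporative_flag)
  d3 <- line_vs_gmwl(make_line(0, 7.9, se_beta1 = 1.0))
  expect_false(d3$evaporative_flag)
})

test_that("natural-abundance screen warns but keeps rows", {
  pts <- line_points(10, 8, d18O = c(-5, -4, 12))
  expect_warning(out <- screen_natural_abundance(pts), "outside the expected")
  expect_equal(nrow(out), 3)
  expect_equal(out$screen_flag, c(FALSE, FALSE, TRUE))
})

test_that("per-species line fitting pools sites by default and can split", {
  sim <- default_sim_cached()
  lines <- fit_background_lines(sim$isotopes, scope = "species")
  expect_setequal(names(lines), names(sim$config$species))
  expect_true(all(vapply(lines, function(l) l$n, numeric(1)) >= 3))
  by_site <- fit_background_lines(sim$isotopes, scope = "species_site")
  expect_equal(length(by_site), 10)
})
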