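test_that("a degenerate all-zero-rate cell shows no activity", {
  cfg <- sim_config(kinetics = kinetic_params(gamma0 = 0,
                                              rebinding_rate = 0,
                                              koff = 0, delta = 0),
                    mrna_decay = 0, protein_per_mrna = 0,
                    dilution_rate = 0, extrinsic_cv = 0, dcas9_cv = 0,
                    n_cells = 1, seed = 1)
  rec <- run_cell(cfg, seed = 1)
  expect_identical(rec$protein_level, 0)
  expect_identical(rec$transcripts_made, 0)
  expect_identical(rec$occupancy_fraction, 0)
})

test_that("simulation is deterministic given the master seed", {
  cfg <- fixed_population(r = 0.3, rebinding = 10, n_cells = 20, seed = 99)
  a <- simulate_population(cfg)
  b <- simulate_population(cfg)
  expect_identical(a$cells, b$cells)
  # per-cell streams are counter-based: the first cells do not change when
  # more cells are appended
  cfg2 <- cfg
  cfg2$n_cells <- 10L
  expect_identical(simulate_population(cfg2)$cells,
                   a$cells[1:10, ])
})

test_that("a non-targeting guide recovers the unrepressed control", {
  cfg <- sim_config(guide = guide_spec("NT", r = 1),
                    extrinsic_cv = 0, dcas9_cv = 0, n_cells = 400,
                    seed = 31)
  s <- simulate_population(cfg)$summary
  expect_equal(s$mean_expression, 1, tolerance = 3 * s$se_mean_expression +
                 .Machine$double.eps)
})

test_that("saturating dCas9 leaves the residual passage rate r", {
  # transcripts per unit time approach r * gamma0 at full occupancy
  cfg <- fixed_population(r = 0.026, rebinding = 2000, n_cells = 400,
                          seed = 32)
  res <- simulate_population(cfg)
  window <- cfg$t_end - cfg$burn_in
  rate <- mean(res$cells$transcripts_made) / window
  se <- sd(res$cells$transcripts_made) / sqrt(nrow(res$cells)) / window
  expect_equal(rate, 0.026 * 20, tolerance = 3 * se / (0.026 * 20))
  expect_gt(res$summary$mean_occupancy, 0.999)
})

test_that("time-averaged occupancy matches the two-state formula", {
  # intermediate dCas9: kout = delta r gamma0 = 2, rebinding = 3
  cfg <- fixed_population(r = 0.1, rebinding = 3, n_cells = 500, seed = 33)
  res <- simulate_population(cfg)
  occ <- res$cells$occupancy_fraction
  p_expect <- occupancy(cfg$kinetics,
                        kout_rate(cfg$kinetics, cfg$guide))
  se <- sd(occ) / sqrt(length(occ))
  expect_equal(mean(occ), p_expect, tolerance = 3 * se / p_expect)
})

test_that("population mean matches the analytic steady state", {
  # one non-saturating condition checked here at small n; the full sweep
  # lives in the acceptance suite
  cfg <- fixed_population(r = 0.026, rebinding = 20, n_cells = 500,
                          seed = 34)
  s <- simulate_population(cfg)$summary
  g_expect <- relative_expression(
    dimensionless_point(lambda_ = 20 / 20, alpha = 0, r = 0.026))
  expect_equal(s$mean_expression, g_expect,
               tolerance = 3 * s$se_mean_expression / g_expect)
})

test_that("population_summary handles edge cases", {
  rec <- data.frame(protein_level = rep(5, 10),
                    occupancy_fraction = rep(0.5, 10))
  s <- population_summary(rec, control_mean = 10)
  expect_identical(s$mean_expression, 0.5)
  expect_identical(s$noise_cv, 0)
  expect_identical(s$mean_occupancy, 0.5)
  expect_error(population_summary(rec, control_mean = 0),
               class = "kickout_normalization_error")
  # single cell: summary collapses to that cell
  s1 <- population_summary(rec[1, ], control_mean = 10)
  expect_identical(s1$mean_expression, 0.5)
  expect_true(is.na(s1$noise_cv))
  # sampling oracle: lognormal with CV 0.3
  set.seed(8)
  v <- rlnorm(10000, 0, sqrt(log(1.09)))
  s2 <- population_summary(data.frame(protein_level = v), control_mean = 1)
  expect_equal(s2$noise_cv, 0.30, tolerance = 0.04)
})

test_that("decoy arrays dilute the active complex pool", {
  expect_identical(active_dcas9_fraction(0), 1)
  expect_identical(active_dcas9_fraction(1), 0.5)
  expect_identical(active_dcas9_fraction(3), 0.25)
})

test_that("aTc induction is a monotone Hill response", {
  expect_identical(atc_induction(0, vmax = 2, km = 10, hill = 2,
                                 basal = 0.1), 0.1)
  expect_equal(atc_induction(1e9, vmax = 2, km = 10, hill = 2, basal = 0.1),
               2.1, tolerance = 1e-6)
  expect_equal(atc_induction(10, vmax = 2, km = 10, hill = 2, basal = 0.1),
               1.1, tolerance = 1e-12)
  x <- atc_induction(seq(0, 100, by = 5), vmax = 1, km = 20, hill = 2)
  expect_true(all(diff(x) >= 0))
})
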