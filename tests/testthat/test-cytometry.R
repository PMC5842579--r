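test_that("trim_outliers applies the single-pass three-sigma rule", {
  set.seed(1)
  base <- rnorm(1000)
  base <- (base - mean(base)) / sd(base)      # exact mean 0, sd 1
  base <- base[abs(base) < 2.5]               # no outliers by construction
  s <- population_sample("a", base)
  expect_identical(attr(trim_outliers(s), "n_removed"), 0L)

  # a single injected 5-sigma point is removed, and only that point
  spiked <- population_sample("b", c(base, 5))
  tr <- trim_outliers(spiked)
  expect_identical(attr(tr, "n_removed"), 1L)
  expect_identical(sort(tr$values), sort(base))

  # idempotent on its own output
  tr2 <- trim_outliers(tr)
  expect_identical(tr2$values, tr$values)

  # normal-tail oracle: about 0.27% of a large Gaussian sample is cut
  set.seed(2)
  big <- population_sample("c", rnorm(100000))
  frac <- attr(trim_outliers(big), "n_removed") / 100000
  expect_equal(frac, 0.0027, tolerance = 0.25)
})

test_that("noise_cv corrects for autofluorescence", {
  flat <- function(id, mu, s, n = 1000) {
    v <- rnorm(n)
    population_sample(id, mu + s * (v - mean(v)) / sd(v))
  }
  set.seed(3)
  samp <- flat("s", mu = 2, s = 0.5)
  blank0 <- flat("b", mu = 1, s = 1e-12)
  ns <- noise_cv(samp, blank0)
  expect_equal(ns$noise, 0.5, tolerance = 1e-6)

  # 3-4-5 construction: sd_sample 0.5, sd_blank 0.3, mu 1 -> sigma 0.4
  blank <- flat("b", mu = 1, s = 0.3)
  ns <- noise_cv(samp, blank)
  expect_equal(ns$sigma, 0.4, tolerance = 1e-9)
  expect_equal(ns$noise, 0.4, tolerance = 1e-9)
  # linear-subtraction variant kept for exact replication
  expect_equal(noise_cv(samp, blank, method = "linear")$noise, 0.2,
               tolerance = 1e-9)

  expect_error(noise_cv(flat("s", 2, 0.1), flat("b", 1, 0.3)),
               class = "kickout_negative_variance")
  expect_error(noise_cv(flat("s", 1, 0.5), flat("b", 2, 0.3)),
               class = "kickout_below_background")
})

test_that("synthetic constitutive noise sits at the 0.3 plateau", {
  pops <- gen_population(generator_config(true_relative_levels = 1,
                                          autofluorescence_mean = 5,
                                          autofluorescence_sd = 0.05,
                                          n_cells = 20000, seed = 4))
  ns <- noise_cv(pops[["level_1"]], pops[["blank"]])
  expect_equal(ns$noise, 0.30, tolerance = 0.03)
})

test_that("relative_expression_table normalizes to the control", {
  # blank sd is kept small relative to the faintest level so that the
  # mean-correction error, not blank noise, dominates the comparison
  cfg <- generator_config(true_relative_levels = c(1, 0.32, 0.026),
                          autofluorescence_mean = 10,
                          autofluorescence_sd = 0.05,
                          n_cells = 10000, seed = 5)
  pops <- gen_population(cfg)
  tab <- relative_expression_table(pops, control_id = "level_1",
                                   blank_id = "blank")
  rel <- tab$relative_mean[match(c("level_1", "level_0.32", "level_0.026",
                                   "blank"), tab$sample_id)]
  expect_identical(rel[1], 1)
  expect_equal(rel[2], 0.32, tolerance = 0.02)
  expect_equal(rel[3], 0.026, tolerance = 0.05)
  expect_equal(rel[4], 0, tolerance = 0.01)

  # invariant under a common multiplicative gain
  gained <- lapply(pops, function(p) {
    p$values <- p$values * 7.3
    p
  })
  tab2 <- relative_expression_table(gained, "level_1", "blank")
  expect_equal(tab2$relative_mean, tab$relative_mean, tolerance = 1e-12)

  expect_error(relative_expression_table(pops, control_id = "blank",
                                         blank_id = "level_1"),
               class = "kickout_normalization_error")
})

test_that("log t-test applies the Bonferroni threshold", {
  same <- c(2, 2, 2)
  res <- log_t_test(same, same, n_comparisons = 3)
  expect_identical(res$p_value, 1)
  expect_false(res$significant)
  expect_equal(res$threshold, 0.017, tolerance = 0.02)

  set.seed(6)
  a <- rlnorm(3, log(10), 0.05)
  b <- rlnorm(3, log(1), 0.05)
  res <- log_t_test(a, b, n_comparisons = 3)
  expect_true(res$significant)
  expect_error(log_t_test(c(1, -1), c(1, 2)), class = "kickout_domain_error")
})

test_that("doubling_time fits exponential growth", {
  t <- seq(0, 120, by = 10)
  od <- 0.01 * 2^(t / 30)
  expect_equal(as.numeric(doubling_time(t, od)), 30, tolerance = 1e-9)

  # regression oracle: 2% multiplicative noise keeps the fit within a
  # minute over seeded repetitions
  for (s in 1:10) {
    set.seed(s)
    odn <- od * rlnorm(length(od), 0, 0.02)
    expect_equal(as.numeric(doubling_time(t, odn)), 30, tolerance = 1 / 30)
  }

  expect_error(doubling_time(t, rep(0.5, length(t))),
               class = "kickout_no_growth")
})
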