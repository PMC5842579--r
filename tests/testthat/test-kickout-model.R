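test_that("relative_expression reproduces the reference inferences", {
  # round-trip of the published P127 inference: lambda*r = 0.4324 gives 0.32
  expect_equal(relative_expression(dimensionless_point(lambda_r = 0.4324,
                                                       r = 0.026)),
               0.32, tolerance = 1e-3)
  # stronger-promoter point: lambda*r = 1.124 gives 0.5415
  expect_equal(relative_expression(dimensionless_point(lambda_r = 1.1241,
                                                       r = 0.026)),
               0.5415, tolerance = 1e-3)
  # saturated limit gamma* = r
  expect_identical(relative_expression(dimensionless_point(lambda_ = 0,
                                                           r = 0.5)), 0.5)
})

test_that("dimensionless_point validates its invariants", {
  expect_error(dimensionless_point(lambda_ = -1, r = 0.5), "lambda_")
  expect_error(dimensionless_point(lambda_ = 1, r = 1.5), "r must")
  expect_error(dimensionless_point(lambda_ = 1, alpha = -0.1, r = 0.5),
               "alpha")
})

test_that("occupancy follows simple two-state kinetics", {
  kp <- function(reb) kinetic_params(rebinding_rate = reb)
  expect_identical(occupancy(kp(1), kout = 0), 1)
  expect_identical(occupancy(kp(1), kout = 1), 0.5)
  expect_equal(occupancy(kp(1), kout = 0.43), 1 / 1.43, tolerance = 1e-12)
  expect_error(occupancy(kp(0), kout = 0),
               class = "kickout_undefined_occupancy")
})

test_that("kout_rate combines collision ejection and spontaneous unbinding", {
  g <- function(r) guide_spec("g", r = r)
  expect_identical(
    kout_rate(kinetic_params(gamma0 = 5, delta = 0, koff = 0.1), g(0.5)),
    0.1)
  expect_equal(
    kout_rate(kinetic_params(gamma0 = 20, delta = 1, koff = 0), g(0.026)),
    0.52, tolerance = 1e-12)
  expect_equal(
    kout_rate(kinetic_params(gamma0 = 10, delta = 1, koff = 0.1), g(1)),
    10.1, tolerance = 1e-12)
})

test_that("infer_lambda_r inverts the steady state", {
  expect_equal(infer_lambda_r(0.32, guide20()), 0.4324, tolerance = 1e-3)
  expect_identical(infer_lambda_r(0.026, guide20()), 0)
  expect_equal(infer_lambda_r(0.5, guide_spec("g", r = 0.1), alpha = 0.1),
               0.70, tolerance = 1e-12)
  expect_error(infer_lambda_r(1, guide20()),
               class = "kickout_divergent_inference")
  expect_error(infer_lambda_r(0.01, guide20()),
               class = "kickout_inconsistent_inputs")
})

test_that("inference and prediction are mutual inverses (property)", {
  set.seed(42)
  for (i in 1:200) {
    r <- runif(1, 0, 0.9)
    alpha <- runif(1, 0, 2)
    # admissible observation: above the floor reached as lambda*r -> 0
    floor_ <- (r + alpha) / (1 + alpha)
    g_obs <- runif(1, floor_, 0.999)
    lr <- infer_lambda_r(g_obs, guide_spec("g", r = r), alpha = alpha)
    back <- relative_expression(dimensionless_point(lambda_r = lr,
                                                    alpha = alpha, r = r))
    expect_equal(back, g_obs, tolerance = 1e-12)
  }
})

test_that("gamma* limits and monotonicity hold (property)", {
  set.seed(7)
  for (i in 1:50) {
    r <- runif(1)
    alpha <- runif(1, 0, 1)
    lr <- 10^runif(1, -3, 2)
    g <- relative_expression(dimensionless_point(lambda_r = lr,
                                                 alpha = alpha, r = r))
    expect_gte(g, r)
    expect_lte(g, 1)
    # strictly increasing in lambda*r and in alpha
    expect_gt(relative_expression(dimensionless_point(lambda_r = lr * 1.1,
                                                      alpha = alpha, r = r)),
              g)
    expect_gt(relative_expression(dimensionless_point(lambda_r = lr,
                                                      alpha = alpha + 0.1,
                                                      r = r)),
              g)
  }
  # saturated and runaway limits
  expect_equal(relative_expression(dimensionless_point(lambda_r = 1e9,
                                                       r = 0.1)),
               1, tolerance = 1e-8)
  expect_identical(relative_expression(dimensionless_point(lambda_ = 0,
                                                           r = 0.1)), 0.1)
})

test_that("predict_promoter matches the published chained inference", {
  expect_equal(predict_promoter(pair127(), guide20()), 0.5415,
               tolerance = 1e-3)
  # identity at fold 1
  p1 <- promoter_pair("a", "b", strength_fold = 1, gamma_star_ref = 0.32)
  expect_equal(predict_promoter(p1, guide20()), 0.32, tolerance = 1e-12)
  # finite unbinding lowers the prediction
  expect_equal(predict_promoter(pair127(), guide20(), alpha = 0.14),
               oracle_predict(0.32, 2.6, 0.026, 0.14), tolerance = 1e-12)
  expect_equal(predict_promoter(pair127(), guide20(), alpha = 0.14), 0.487,
               tolerance = 1e-3)
})

test_that("predict_promoter is monotone in fold and alpha (property)", {
  g <- guide20()
  folds <- c(0.5, 1, 1.5, 2.6, 5)
  preds <- vapply(folds, function(f) {
    predict_promoter(promoter_pair("a", "b", f, 0.32), g)
  }, numeric(1))
  expect_true(all(diff(preds) > 0))
  alphas <- seq(0, 0.4, by = 0.05)
  pa <- vapply(alphas, function(a) predict_promoter(pair127(), g, a),
               numeric(1))
  expect_true(all(diff(pa) < 0))
})

test_that("alpha_crossing finds the unbinding threshold", {
  # full complementarity: bound chosen at the alpha = 0.14 prediction
  bound <- oracle_predict(0.32, 2.6, 0.026, 0.14)
  expect_equal(alpha_crossing(pair127(), guide20(), bound),
               oracle_alpha_crossing(0.32, 2.6, 0.026, bound),
               tolerance = 1e-6)
  expect_equal(alpha_crossing(pair127(), guide20(), bound), 0.14,
               tolerance = 0.01)
  # trivial: bound at the alpha = 0 prediction
  expect_equal(alpha_crossing(pair127(), guide20(),
                              predict_promoter(pair127(), guide20())),
               0, tolerance = 1e-7)
  # 6-mismatch guide round trip at alpha = 0.35
  b6 <- predict_promoter(pair127(), guide14(), alpha = 0.35)
  expect_equal(alpha_crossing(pair127(), guide14(), b6), 0.35,
               tolerance = 1e-6)
  expect_error(alpha_crossing(pair127(), guide20(), 0.2),
               class = "kickout_no_crossing")
})

test_that("koff bound and lifetime bound reproduce the printed estimates", {
  lr <- infer_lambda_r(0.32, guide20())
  lambda_ <- lr / 0.026
  coef <- koff_upper_bound(0.14, lambda_, gamma0 = 1)
  expect_equal(coef, 8e-3, tolerance = 0.08)          # approx 8.4e-3
  expect_identical(koff_upper_bound(0, lambda_, 20), 0)
  expect_equal(koff_upper_bound(0.14, lambda_, 20), 0.168, tolerance = 1e-2)
  expect_error(koff_upper_bound(0.14, 0, 20),
               class = "kickout_division_error")

  expect_equal(lifetime_bound(2, 1 / 6), 12, tolerance = 1e-12)
  expect_identical(lifetime_bound(1, 1), 1)
  expect_equal(lifetime_bound(2, 1 / 2.4), 4.8, tolerance = 1e-12)
  expect_identical(lifetime_bound(2, 0), Inf)

  # composition: rounded coefficient, gamma0 = 20/min, two gene copies
  koff_rounded <- signif(coef, 1) * 20
  expect_equal(koff_rounded, 0.16, tolerance = 1e-12)
  expect_gte(lifetime_bound(2, koff_rounded), 12)
})

test_that("gene_copy_number follows the replication-overlap exponent", {
  expect_identical(gene_copy_number(copy_number_params(tC = 0, tD = 0,
                                                       td = 30, phi = 0.2)),
                   1)
  expect_equal(gene_copy_number(copy_number_params(60, 20, 30, 0.66)),
               2^((60 * 0.34 + 20) / 30), tolerance = 1e-12)
  expect_equal(gene_copy_number(copy_number_params(60, 20, 30, 1)),
               2^(2 / 3), tolerance = 1e-12)
})
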