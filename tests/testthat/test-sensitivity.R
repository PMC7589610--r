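test_that("the perturbation grid reproduces the published eight-level table", {
  grid <- build_grid(reference_predictor_summary())
  published <- rbind(
    c(49.2,  22.4,  4.8,  395.4, 1176.8),
    c(56,    29,    7.7,  483,   1408),
    c(62.8,  35.6,  10.6, 570.6, 1639.2),
    c(69.6,  42.2,  13.5, 658.2, 1870.4),
    c(76.4,  48.8,  16.4, 745.8, 2101.6),
    c(83.2,  55.4,  19.3, 833.4, 2332.8),
    c(90,    62,    22.2, 921,   2564),
    c(96.8,  68.6,  25.1, 1008.6, 2795.2))
  expect_equal(unname(grid$levels), published, tolerance = 1e-12)
  # endpoints hit the observed extremes to machine precision
  ref <- reference_predictor_summary()
  expect_equal(unname(grid$levels[2, ]), unname(ref$x_min), tolerance = 1e-14)
  expect_equal(unname(grid$levels[7, ]), unname(ref$x_max), tolerance = 1e-14)
  # strictly increasing levels for every non-degenerate predictor
  expect_true(all(apply(grid$levels, 2, function(v) all(diff(v) > 0))))
})

test_that("a unit-range predictor maps the grid onto the coefficients themselves", {
  s <- predictor_summary(x_ave = 0.5, x_max = 1, x_min = 0)
  g <- build_grid(s)
  expect_equal(unname(g$levels[, 1]), g$coefficients, tolerance = 1e-14)
})

test_that("perturbation curves are affine with the exact coefficient step", {
  ds <- generate_dataset(synthetic_config(seed = 31))
  summ <- compute_summary(ds)
  fit <- fit_plsr(ds, h = 2)
  curves <- perturb_predict(fit, summ, quiet = TRUE)
  for (j in 1:5) {
    cj <- curves[[j]]
    # adjacent levels differ by exactly 0.2 * x_dif_j * B[j, ]
    step <- 0.2 * summ$x_dif[[j]] * fit$B[j, ]
    for (k in 2:8) {
      expect_equal(unname(cj[k, ] - cj[k - 1, ]), unname(step),
                   tolerance = 1e-9)
    }
    # second differences vanish: the curve is exactly affine in the level
    d2 <- diff(cj, differences = 2)
    expect_lt(max(abs(d2)), 1e-9 * max(abs(cj)))
  }
})

test_that("a predictor with zero coefficients produces a flat curve at the baseline", {
  ds <- generate_dataset(synthetic_config(seed = 32))
  summ <- compute_summary(ds)
  fit <- fit_plsr(ds, h = 2)
  fit$B[3, ] <- 0  # null out body-fat's effect
  curves <- perturb_predict(fit, summ, quiet = TRUE)
  base <- drop(predict(fit, matrix(summ$x_ave, 1)))
  expect_equal(unname(curves[[3]]),
               matrix(base, 8, 7, byrow = TRUE), tolerance = 1e-12,
               ignore_attr = TRUE)
  trends <- classify_trends(curves)
  expect_true(all(trends[3, ] == "negligible"))
})

test_that("curves equal the closed-form evaluation from the coefficients", {
  ds <- generate_dataset(synthetic_config(seed = 33))
  summ <- compute_summary(ds)
  fit <- fit_plsr(ds, h = 3)
  grid <- build_grid(summ)
  curves <- perturb_predict(fit, summ, grid, quiet = TRUE)
  base_row <- summ$x_ave
  for (j in 1:5) {
    for (k in c(1, 5, 8)) {
      closed <- fit$b0 + drop(base_row %*% fit$B) +
        (grid$levels[k, j] - base_row[[j]]) * fit$B[j, ]
      expect_equal(unname(curves[[j]][k, ]), unname(closed), tolerance = 1e-10)
    }
  }
})

test_that("trend labels follow the sign pattern of the true coefficient map", {
  cfg <- synthetic_config(n = 20, latent_rank = 2,
                          noise_sd_x = 0, noise_sd_y = 0, seed = 34)
  ds <- generate_dataset(cfg)
  summ <- compute_summary(ds)
  fit <- fit_plsr(ds, h = 2)
  curves <- perturb_predict(fit, summ, quiet = TRUE)
  trends <- classify_trends(curves, flat_tol = 0)  # pure slope signs
  # the affine range maps preserve predictor orientation and response
  # orientation, so fitted signs must match the generator's true map
  B_true <- true_linear_map(cfg)
  expect_identical(unname(trends),
                   matrix(ifelse(B_true > 0, "increasing", "decreasing"),
                          5, 7))
})

test_that("trend classification is invariant to positive response rescaling", {
  ds <- generate_dataset(synthetic_config(seed = 35))
  summ <- compute_summary(ds)
  t1 <- classify_trends(perturb_predict(fit_plsr(ds, h = 2), summ, quiet = TRUE))
  ds2 <- ds
  ds2$Y <- ds$Y * 12.5
  t2 <- classify_trends(perturb_predict(fit_plsr(ds2$X, ds2$Y, h = 2), summ,
                                        quiet = TRUE))
  expect_identical(t1, t2)
})

test_that("extrapolating grid rows trigger a notice, not a refusal", {
  ds <- generate_dataset(synthetic_config(seed = 36))
  summ <- compute_summary(ds)
  fit <- fit_plsr(ds, h = 2)
  expect_message(perturb_predict(fit, summ), "extrapolate")
})
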