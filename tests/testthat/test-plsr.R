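test_that("standardization centers, scales, is idempotent and rejects constants", {
  set.seed(1)
  M <- matrix(rnorm(60, mean = 5, sd = 3), 12, 5)
  s <- standardize(M)
  # independent mean/sd recomputation
  for (j in 1:5) {
    expect_equal(mean(s$x[, j]), 0, tolerance = 1e-12)
    expect_equal(sqrt(sum((s$x[, j] - mean(s$x[, j]))^2) / 11), 1, tolerance = 1e-12)
  }
  s2 <- standardize(s$x)
  expect_equal(s2$x, s$x, tolerance = 1e-10)
  expect_equal(s2$center, rep(0, 5), tolerance = 1e-12)
  expect_equal(s2$scale, rep(1, 5), tolerance = 1e-12)

  # supplied parameters are applied, never re-estimated
  s3 <- standardize(M[1:3, ], center = s$center, scale = s$scale)
  expect_equal(s3$x, s$x[1:3, ], tolerance = 1e-12)

  M_const <- cbind(M[, 1:2], 4, M[, 4:5])
  colnames(M_const) <- paste0("V", 1:5)
  expect_error(standardize(M_const), "zero-variance column: V3")
})

test_that("extracted component matches a power-iteration + projection oracle", {
  set.seed(7)
  for (rep in 1:10) {
    E <- matrix(rnorm(24), 8, 3)
    F <- matrix(rnorm(16), 8, 2)
    cmp <- extract_component(E, F)
    w_ref <- oracle_weight(crossprod(E, F))
    expect_equal(cmp$w, w_ref, tolerance = 1e-8)
    expect_equal(sum(cmp$w^2), 1, tolerance = 1e-12)
    t_ref <- drop(E %*% w_ref)
    # explicit least-squares projections of each block on the score
    expect_equal(cmp$alpha, drop(crossprod(E, t_ref)) / sum(t_ref^2),
                 tolerance = 1e-8)
    expect_equal(cmp$beta, drop(crossprod(F, t_ref)) / sum(t_ref^2),
                 tolerance = 1e-8)
  }
})

test_that("single-response weight reduces to the classical one-block form", {
  set.seed(2)
  E <- matrix(rnorm(30), 10, 3)
  F <- matrix(rnorm(10), 10, 1)
  cmp <- extract_component(E, F)
  w_ref <- drop(crossprod(E, F))
  w_ref <- w_ref / sqrt(sum(w_ref^2))
  if (w_ref[which.max(abs(w_ref))] < 0) w_ref <- -w_ref
  expect_equal(cmp$w, w_ref, tolerance = 1e-10)
})

test_that("a single latent direction is recovered exactly without noise", {
  set.seed(3)
  t_true <- rnorm(9)
  E <- tcrossprod(t_true, c(1, -2, 0.5))
  F <- tcrossprod(t_true, c(0.3, 1.2))
  cmp <- extract_component(E, F)
  resid <- F - tcrossprod(cmp$t, cmp$beta)
  expect_lt(max(abs(resid)), 1e-10)
})

test_that("extraction refuses blocks with no predictor-response association", {
  E <- matrix(rnorm(20), 10, 2)
  F <- matrix(0, 10, 3)
  expect_error(extract_component(E, F), "no extractable component")
})

test_that("deflation orthogonalizes, annihilates rank-one blocks and reconstructs", {
  set.seed(4)
  E <- scale(matrix(rnorm(50), 10, 5))
  F <- scale(matrix(rnorm(30), 10, 3))
  cmp <- extract_component(E, F)
  dfl <- deflate(E, F, cmp$t, cmp$alpha, cmp$beta)
  expect_lt(max(abs(crossprod(dfl$E, cmp$t))),
            1e-10 * sqrt(sum(E^2)) * sqrt(sum(cmp$t^2)))

  E1 <- tcrossprod(cmp$t, cmp$alpha)
  dfl1 <- deflate(E1, F, cmp$t, cmp$alpha, cmp$beta)
  expect_lt(max(abs(dfl1$E)), 1e-10)
})

test_that("component accumulation reconstructs the standardized predictors", {
  set.seed(5)
  X <- matrix(rnorm(60, 10), 12, 5)
  Y <- matrix(rnorm(36, 10), 12, 3)
  fit <- fit_plsr(X, Y, h = 5)
  Xs <- standardize(X)$x
  recon <- matrix(0, 12, 5)
  E <- Xs; F <- standardize(Y)$x
  for (a in seq_len(fit$h)) {
    recon <- recon + tcrossprod(fit$scores[, a], fit$x_loadings[, a])
    d <- deflate(E, F, fit$scores[, a], fit$x_loadings[, a], fit$y_loadings[, a])
    E <- d$E; F <- d$F
  }
  expect_lt(max(abs(recon + E - Xs)), 1e-10)
})

test_that("fitted models satisfy the score and coefficient identities", {
  set.seed(6)
  for (rep in 1:8) {
    n <- sample(8:30, 1)
    inst <- random_instance(n, 5, 4, rank = 3, noise = 0.5)
    h <- sample(1:4, 1)
    fit <- fit_plsr(inst$X, inst$Y, h = h)
    # unit-norm weights, orthogonal scores
    expect_equal(colSums(fit$W^2), rep(1, h), tolerance = 1e-10)
    G <- crossprod(fit$scores)
    off <- G - diag(diag(G), h)
    expect_lt(max(abs(off)), 1e-8 * max(diag(G)))
    # component-path and coefficient-path predictions agree
    Ys_hat <- fit$scores %*% t(fit$y_loadings)
    via_components <- sweep(sweep(Ys_hat, 2, fit$y_scale, "*"), 2, fit$y_center, "+")
    expect_lt(max(abs(via_components - fit$fitted)),
              1e-10 * max(abs(fit$fitted)))
  }
})

test_that("PLS with all components reproduces ordinary least squares", {
  set.seed(8)
  for (rep in 1:5) {
    X <- matrix(rnorm(16 * 4, 10), 16, 4)
    Y <- matrix(rnorm(16 * 3, 50, 5), 16, 3)
    fit <- fit_plsr(X, Y, h = 4)
    ols <- oracle_ols_predict(X, Y)
    expect_lt(max(abs(fit$fitted - ols)) / max(abs(ols)), 1e-8)
  }
})

test_that("prediction obeys the centering and finite-difference identities", {
  ds <- positive_dataset(n = 15, seed = 10)
  fit <- fit_plsr(ds, h = 3)
  # mean row predicts mean responses exactly
  expect_equal(drop(predict(fit, matrix(colMeans(ds$X), 1))),
               colMeans(ds$Y), tolerance = 1e-12, ignore_attr = TRUE)
  # training rows reproduce stored fits
  expect_equal(predict(fit, ds$X), fit$fitted, tolerance = 1e-12,
               ignore_attr = TRUE)
  # bumping predictor j by delta moves predictions by delta * B[j, ]
  x0 <- ds$X[1, ]
  for (j in 1:5) {
    x1 <- x0; x1[j] <- x1[j] + 0.37
    diff <- drop(predict(fit, matrix(x1, 1)) - predict(fit, matrix(x0, 1)))
    expect_equal(diff, 0.37 * fit$B[j, ], tolerance = 1e-9, ignore_attr = TRUE)
  }
  expect_error(predict(fit, matrix(1, 2, 3)), "expects 5")
})

test_that("h outside the admissible range is rejected", {
  ds <- positive_dataset(n = 6, seed = 11)
  expect_error(fit_plsr(ds, h = 0), "must be in 1")
  expect_error(fit_plsr(ds, h = 6), "must be in 1")
})

test_that("the NIPALS core agrees with an independent reference implementation", {
  skip_if_not_installed("mixOmics")
  set.seed(12)
  for (rep in 1:10) {
    n <- sample(10:20, 1)
    m <- sample(3:5, 1)
    p <- sample(2:4, 1)
    h <- sample(1:min(3, m), 1)
    inst <- random_instance(n, m, p, rank = min(m, p), noise = 0.4)
    X <- inst$X; Y <- inst$Y
    colnames(X) <- paste0("x", seq_len(m))
    colnames(Y) <- paste0("y", seq_len(p))
    fit <- fit_plsr(X, Y, h = h)
    ref <- mixOmics::pls(X, Y, ncomp = h, mode = "regression", scale = TRUE)
    pred_ref <- predict(ref, X)$predict[, , h]
    expect_lt(max(abs(fit$fitted - pred_ref)) / max(abs(pred_ref)), 1e-6)
  }
})

test_that("model serialization round-trips and preserves predictions", {
  ds <- positive_dataset(n = 12, seed = 13)
  fit <- fit_plsr(ds, h = 2)
  path <- withr::local_tempfile(fileext = ".txt")
  write_pls_model(fit, path)
  back <- read_pls_model(path)
  expect_identical(back$h, fit$h)
  expect_identical(back$B, fit$B)
  expect_identical(back$b0, fit$b0)
  expect_equal(predict(back, ds$X), fit$fitted, ignore_attr = TRUE)
})
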