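test_that("ridge solves the penalized normal equations", {
  # identity design, no penalty -> OLS
  m <- fit_ridge(diag(2), matrix(c(1, 2), 2, 1), 0)
  expect_equal(unname(m$weights), matrix(c(1, 2), 2, 1))
  # infinite-penalty limit
  m2 <- fit_ridge(matrix(1), matrix(1), 1e12)
  expect_lt(abs(m2$weights[1, 1]), 1e-6)
  # worked value from the closed form (X'X + lam I)^{-1} X'Y
  m3 <- fit_ridge(matrix(c(1, 0, 1, 0, 1, 1), 3, 2),
                  matrix(c(1, 2, 3), 3, 1), 1)
  expect_equal(unname(m3$weights), matrix(c(0.875, 1.375), 2, 1))
  # normal-equation residual on random problems
  set.seed(5)
  for (lam in c(0, 0.1, 10, 1e4)) {
    X <- matrix(rnorm(60), 12, 5); Y <- matrix(rnorm(36), 12, 3)
    W <- fit_ridge(X, Y, lam)$weights
    lhs <- (crossprod(X) + diag(lam, 5)) %*% W
    rhs <- crossprod(X, Y)
    expect_lt(norm(lhs - rhs, "F"), 1e-10 * norm(rhs, "F"))
  }
  expect_error(fit_ridge(matrix(c(1, 1, 2, 2), 2, 2), matrix(1:2), 0),
               "rank deficient")
})

test_that("lasso matches soft-thresholding on orthonormal designs", {
  # OLS limit at lam = 0
  m <- fit_lasso(diag(3), matrix(c(1, -2, 3), 3, 1), 0)
  expect_equal(unname(m$weights), matrix(c(1, -2, 3), 3, 1))
  # worked soft-threshold value
  m2 <- fit_lasso(diag(2), matrix(c(3, -1), 2, 1), 1)
  expect_equal(unname(m2$weights), matrix(c(2, 0), 2, 1))
  # exact soft-thresholding for random orthonormal X (Q from QR)
  set.seed(8)
  X <- qr.Q(qr(matrix(rnorm(49), 7, 7)))
  Y <- matrix(rnorm(14), 7, 2)
  for (lam in c(0.05, 0.3, 1)) {
    W <- fit_lasso(X, Y, lam)$weights
    z <- crossprod(X, Y)
    expect_equal(W, sign(z) * pmax(abs(z) - lam, 0), tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
  # null threshold: lam >= max|X'Y| zeroes everything exactly
  z <- crossprod(X, Y)
  W0 <- fit_lasso(X, Y, max(abs(z)))$weights
  expect_true(all(W0 == 0))
})

test_that("lasso agrees with OLS at lam = 0 and obeys KKT on general designs", {
  set.seed(9)
  X <- matrix(rnorm(48), 12, 4)
  Y <- matrix(rnorm(24), 12, 2)
  W_ols <- solve(crossprod(X), crossprod(X, Y))
  expect_equal(fit_lasso(X, Y, 0)$weights, W_ols, tolerance = 1e-8,
               ignore_attr = TRUE)
  lam <- 0.7
  W <- fit_lasso(X, Y, lam, tol = 1e-10)$weights
  grad <- crossprod(X) %*% W - crossprod(X, Y)
  viol <- ifelse(W != 0, abs(grad + lam * sign(W)),
                 pmax(abs(grad) - lam, 0))
  expect_lt(max(viol), 1e-10)
})

test_that("lasso L1 norm is nonincreasing in the penalty", {
  set.seed(10)
  X <- matrix(rnorm(80), 16, 5)
  Y <- matrix(rnorm(32), 16, 2)
  lams <- c(0, 0.2, 0.5, 1, 2, 5, 10)
  l1 <- vapply(lams, function(l) sum(abs(fit_lasso(X, Y, l)$weights)),
               numeric(1))
  expect_true(all(diff(l1) <= 1e-9))
})

test_that("lasso solution matches glmnet under its rescaled objective", {
  skip_if_not_installed("glmnet")
  set.seed(12)
  N <- 20
  X <- matrix(rnorm(N * 6), N, 6)
  y <- matrix(rnorm(N), N, 1)
  lam <- 1.5  # our objective: 0.5*||y-Xw||^2 + lam*||w||_1
  ours <- fit_lasso(X, y, lam, tol = 1e-12)$weights[, 1]
  g <- glmnet::glmnet(X, y, alpha = 1, lambda = lam / N,
                      intercept = FALSE, standardize = FALSE,
                      thresh = 1e-14)
  expect_equal(ours, as.numeric(g$beta), tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("prediction is the linear map X_new W", {
  set.seed(13)
  X <- matrix(rnorm(30), 6, 5)
  Y <- matrix(rnorm(18), 6, 3)
  m <- fit_ridge(X, Y, 0.5)
  expect_equal(predict_cerebellum(m, matrix(0, 2, 5)), matrix(0, 2, 3),
               ignore_attr = TRUE)
  A <- matrix(rnorm(10), 2, 5); B <- matrix(rnorm(10), 2, 5)
  expect_equal(predict_cerebellum(m, 2 * A + 3 * B),
               2 * predict_cerebellum(m, A) + 3 * predict_cerebellum(m, B))
  # identity fit reproduces training data at lam = 0
  mi <- fit_ridge(diag(3), Y[1:3, ], 0)
  expect_equal(predict_cerebellum(mi, diag(3)), Y[1:3, ],
               ignore_attr = TRUE)
  Xn <- matrix(rnorm(10), 2, 5,
               dimnames = list(NULL, paste0("q", 1:5)))
  m_named <- fit_ridge(matrix(rnorm(30), 6, 5,
                              dimnames = list(NULL, paste0("p", 1:5))),
                       Y, 1)
  expect_error(predict_cerebellum(m_named, Xn), "parcel mismatch")
  expect_error(predict_cerebellum(m, matrix(0, 2, 4)), "expects 5")
})

test_that("voxelwise accuracy is per-column Pearson r with skips counted", {
  set.seed(14)
  Y <- matrix(rnorm(20), 5, 4)
  ev <- evaluate_voxelwise(Y, Y)
  expect_equal(ev$per_unit_r, rep(1, 4))
  # affine invariance
  expect_equal(evaluate_voxelwise(2 * Y + 7, Y)$mean_r, 1)
  expect_equal(
    evaluate_voxelwise(matrix(c(3, 2, 1), 3, 1),
                       matrix(c(1, 2, 3), 3, 1))$per_unit_r, -1)
  # degenerate column skipped and counted
  Yh <- Y; Yh[, 2] <- 5
  ev2 <- evaluate_voxelwise(Yh, Y)
  expect_equal(ev2$n_skipped, 1L)
  expect_true(is.na(ev2$per_unit_r[2]))
  expect_error(evaluate_voxelwise(matrix(1, 3, 2), matrix(1, 3, 2)),
               "degenerate")
  expect_error(evaluate_voxelwise(Y[1:2, ], Y[1:2, ]), "3 condition")
})

test_that("cross-validation picks the accuracy-maximizing penalty", {
  set.seed(15)
  X <- matrix(rnorm(25 * 6), 25, 6)
  W <- matrix(rnorm(18), 6, 3)
  Y_clean <- X %*% W
  # single-value grid
  cv1 <- crossval_tune(X, Y_clean, "ridge", lambda_grid = 2, seed = 1)
  expect_equal(cv1$chosen_lambda, 2)
  # determinism
  cv_a <- crossval_tune(X, Y_clean + 0.1 * matrix(rnorm(75), 25, 3),
                        "ridge", c(0.1, 1, 10), seed = 99)
  set.seed(1234)  # must not influence the fold shuffle
  cv_b <- crossval_tune(X, Y_clean + 0.1 * matrix(rnorm(75), 25, 3),
                        "ridge", c(0.1, 1, 10), seed = 99)
  expect_identical(cv_a$fold_of_row, cv_b$fold_of_row)
  # noiseless data favor the weak penalty
  cv2 <- crossval_tune(X, Y_clean, "ridge", c(1e-6, 1e6), seed = 3)
  expect_equal(cv2$chosen_lambda, 1e-6)
  expect_error(crossval_tune(X[1:8, ], Y_clean[1:8, ], "ridge", 1, k = 5),
               "3 rows")
})

test_that("model averaging is the unweighted elementwise mean", {
  m1 <- connectivity_model(matrix(1), "ridge", 1,
                           parcel_ids = "p1", target_unit_ids = "v1")
  m3 <- connectivity_model(matrix(3), "ridge", 2,
                           parcel_ids = "p1", target_unit_ids = "v1")
  expect_equal(average_models(list(m1))$weights, m1$weights)
  avg <- average_models(list(m1, m3))
  expect_equal(avg$weights[1, 1], 2)
  expect_equal(avg$lam, c(1, 2))
  mneg <- connectivity_model(-m1$weights, "ridge", 1, "p1", "v1")
  expect_equal(average_models(list(m1, mneg))$weights[1, 1], 0)
  m_other <- connectivity_model(matrix(1), "ridge", 1, "pX", "v1")
  expect_error(average_models(list(m1, m_other)), "mismatched parcel")
  m_lasso <- connectivity_model(matrix(1), "lasso", 1, "p1", "v1")
  expect_error(average_models(list(m1, m_lasso)), "mismatched methods")
})

test_that("connectivity model files round-trip", {
  set.seed(16)
  m <- fit_ridge(matrix(rnorm(30), 6, 5,
                        dimnames = list(NULL, paste0("p", 1:5))),
                 matrix(rnorm(12), 6, 2,
                        dimnames = list(NULL, paste0("v", 1:2))),
                 lam = 3, training_meta = list(dataset = "sim"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_connectivity_model(m, path)
  back <- read_connectivity_model(path)
  expect_equal(back$weights, m$weights, tolerance = 1e-12)
  expect_identical(back$method, "ridge")
  expect_equal(back$lam, 3)
  expect_equal(back$training_meta$dataset, "sim")
})
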