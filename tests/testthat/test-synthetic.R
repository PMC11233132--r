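test_that("simulation is a pure function of its config", {
  cfg <- simulation_config(n_subjects = 3L, n_conditions_train = 8L,
                           n_conditions_test = 5L, n_parcels = 6L,
                           n_voxels = 4L, gating_gain = 0.3, seed = 42L)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(d1$W_true, d2$W_true)
  expect_identical(lapply(d1$cerebellum_test, unclass),
                   lapply(d2$cerebellum_test, unclass))
  expect_identical(d1$roi$unit_ids, d2$roi$unit_ids)
})

test_that("noiseless, ungated transmission is exactly Y = X W", {
  cfg <- simulation_config(n_subjects = 2L, n_conditions_train = 6L,
                           n_conditions_test = 4L, n_parcels = 5L,
                           n_voxels = 3L, noise_sd_cortex = 0,
                           noise_sd_cerebellum = 0, gating_gain = 0,
                           seed = 43L)
  ds <- simulate_dataset(cfg)
  for (s in 1:2) {
    expect_equal(unclass(ds$cerebellum_test[[s]]),
                 unclass(ds$cortex_test[[s]]) %*% ds$W_true,
                 ignore_attr = TRUE)
    expect_equal(unclass(ds$cerebellum_train[[s]]),
                 unclass(ds$cortex_train[[s]]) %*% ds$W_true,
                 ignore_attr = TRUE)
  }
})

test_that("gating touches only gated-condition rows of ROI voxels", {
  base <- list(n_subjects = 2L, n_conditions_train = 6L,
               n_conditions_test = 5L, n_parcels = 5L, n_voxels = 4L,
               noise_sd_cortex = 0, noise_sd_cerebellum = 0,
               roi_fraction = 0.5, seed = 44L)
  d0 <- simulate_dataset(do.call(simulation_config,
                                 c(base, gating_gain = 0)))
  d1 <- simulate_dataset(do.call(simulation_config,
                                 c(base, gating_gain = 0.6)))
  gated <- d1$config$gated_conditions
  roi <- d1$roi$unit_ids
  for (s in 1:2) {
    y0 <- unclass(d0$cerebellum_test[[s]])
    y1 <- unclass(d1$cerebellum_test[[s]])
    other_rows <- setdiff(rownames(y0), gated)
    other_cols <- setdiff(colnames(y0), roi)
    expect_equal(y1[other_rows, ], y0[other_rows, ])
    expect_equal(y1[, other_cols], y0[, other_cols])
    expect_equal(y1[gated, roi], 1.6 * y0[gated, roi], tolerance = 1e-12)
  }
  # training data are never gated
  expect_identical(unclass(d1$cerebellum_train[[1]]),
                   unclass(d0$cerebellum_train[[1]]))
})

test_that("config validation names the offending field", {
  expect_error(simulation_config(n_parcels = 0), "n_parcels")
  expect_error(simulation_config(gating_gain = -1), "gating_gain")
  expect_error(simulation_config(connectivity_sparsity = 1),
               "connectivity_sparsity")
  expect_error(simulation_config(roi_fraction = 0), "roi_fraction")
  expect_error(simulation_config(gated_conditions = "nope"),
               "gated_conditions")
  expect_error(simulation_config(noise_sd_cortex = -0.1), "noise sds")
})

test_that("true weights are nonnegative with the configured sparsity", {
  cfg <- simulation_config(n_parcels = 60L, n_voxels = 40L,
                           connectivity_sparsity = 0.7, seed = 45L)
  ds <- simulate_dataset(cfg)
  expect_true(all(ds$W_true >= 0))
  frac_zero <- mean(ds$W_true == 0)
  expect_gt(frac_zero, 0.65); expect_lt(frac_zero, 0.75)
})

test_that("trivial calibration levels are exact and reps are deterministic", {
  cfg <- simulation_config(n_subjects = 4L, n_conditions_test = 5L,
                           n_parcels = 8L, n_voxels = 6L,
                           n_conditions_train = 6L, seed = 46L)
  cal1 <- suppressWarnings(calibration_experiment(cfg, n_reps = 20L,
                                                  alpha = 1))
  expect_equal(cal1$rate_anova, 1)
  cal0 <- suppressWarnings(calibration_experiment(cfg, n_reps = 20L,
                                                  alpha = 0))
  expect_equal(cal0$rate_anova, 0)
  a <- suppressWarnings(calibration_experiment(cfg, n_reps = 30L))
  b <- suppressWarnings(calibration_experiment(cfg, n_reps = 30L))
  expect_identical(a$rate_anova, b$rate_anova)
  expect_identical(a$mean_residual_by_condition,
                   b$mean_residual_by_condition)
  expect_error(calibration_experiment(
    simulation_config(gating_gain = 0.2)), "gating_gain = 0")
  expect_warning(calibration_experiment(cfg, n_reps = 5L), "n_reps")
})

test_that("with no gating the signed residuals are centered at zero", {
  cfg <- simulation_config(n_subjects = 6L, n_conditions_test = 6L,
                           n_parcels = 10L, n_voxels = 8L,
                           n_conditions_train = 8L, seed = 47L)
  cal <- calibration_experiment(cfg, n_reps = 300L)
  # each residual's SD is about the ROI-mean noise (noise_sd / sqrt(4 roi
  # voxels) = 0.05); over 300 reps x 6 subjects the mean's SE is ~1.2e-3,
  # so 4 SEs is a generous zero-centering bound
  se <- cfg$noise_sd_cerebellum / sqrt(4) / sqrt(300 * cfg$n_subjects)
  expect_true(all(abs(cal$mean_residual_by_condition) < 4 * se))
})

test_that("gated-condition mean residual grows with the gating gain", {
  mean_gated <- vapply(c(0, 0.2, 0.5), function(g) {
    reps <- vapply(1:40, function(r) {
      cfg <- simulation_config(n_subjects = 6L, n_conditions_test = 6L,
                               n_parcels = 10L, n_voxels = 8L,
                               n_conditions_train = 8L, gating_gain = g,
                               seed = 48L + 1000L * r)
      ds <- simulate_dataset(cfg)
      res <- run_recruitment_analysis(ds$cortex_test, ds$cerebellum_test,
                                      ds$true_model, ds$roi, ds$design)
      mean(test_residuals(res$residual_table)[, cfg$gated_conditions])
    }, numeric(1))
    mean(reps)
  }, numeric(1))
  expect_true(all(diff(mean_gated) > 0))
})

test_that("recovery collapses when condition labels are shuffled", {
  # scaled-down recovery: the shuffled-control correlation sits near zero
  cfg <- simulation_config(n_subjects = 4L, seed = 49L)
  rec <- recovery_experiment(cfg, lambda_grid = c(0.3, 1))
  expect_lt(abs(rec$shuffled_weight_corr), 0.2)
  expect_gt(rec$weight_corr, rec$shuffled_weight_corr + 0.5)
  expect_gt(rec$heldout_r, rec$shuffled_r + 0.5)
})
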