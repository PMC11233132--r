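#' Parameter-recovery experiment
#'
#' Validates connectivity estimation against known ground truth: simulates
#' a dataset, tunes the penalty per subject by cross-validation on the
#' training conditions, fits per-subject models at the chosen penalties,
#' averages them into a group model, and reports (i) the correlation
#' between estimated and true weights and (ii) held-out voxelwise accuracy
#' on the test conditions, against a label-shuffled control in which each
#' subject's training cerebellar rows are randomly permuted before fitting
#' (destroying the cortex-cerebellum correspondence).
#'
#' The default method is the lasso: the true weights are sparse, and with
#' fewer training conditions than parcels only the sparsity-exploiting
#' estimator can recover weight components outside the subspace spanned by
#' the task activity (ridge caps well below full recovery there).
#'
#' @param config a [simulation_config] (gating gain 0 recommended: recovery
#'   targets the task-invariant transmission itself).
#' @param lambda_grid candidate penalties for [crossval_tune()]; `NULL`
#'   picks a default grid per method.
#' @param method `"lasso"` (default) or `"ridge"`.
#' @param fit_tol KKT tolerance for the lasso fits; slightly looser than
#'   [fit_lasso()]'s default because near-singular training designs
#'   (30 conditions, 40 parcels) slow the tail of coordinate descent, and
#'   a 1e-6 KKT gap perturbs the recovered weights by orders of magnitude
#'   less than the quantities compared here.
#' @return list: `weight_corr` (mean per-voxel correlation of group weights
#'   with truth), `weight_corr_overall` (single correlation over all
#'   entries), `heldout_r`, `shuffled_r`, `shuffled_weight_corr`,
#'   `chosen_lambdas`, `cv_reports`, `group_model`.
#' @export
recovery_experiment <- function(config, lambda_grid = NULL,
                                method = c("lasso", "ridge"),
                                fit_tol = 1e-6) {
  stopifnot(inherits(config, "simulation_config"))
  method <- match.arg(method)
  if (is.null(lambda_grid)) {
    lambda_grid <- if (method == "lasso") c(0.1, 0.3, 1, 3)
                   else exp(seq(-2, 6, by = 1))
  }
  ds <- simulate_dataset(config)
  S <- config$n_subjects

  fit_subject <- function(X, Y, seed) {
    # fold fits only rank the penalties, so they may run at a looser
    # tolerance than the final fit
    cv_extra <- if (method == "lasso") list(tol = max(fit_tol, 1e-4))
                else list()
    extra <- if (method == "lasso") list(tol = fit_tol) else list()
    cv <- do.call(crossval_tune,
                  c(list(X, Y, method = method, lambda_grid = lambda_grid,
                         k = 5L, seed = seed), cv_extra))
    fit_fun <- if (method == "ridge") fit_ridge else fit_lasso
    list(cv = cv,
         model = do.call(fit_fun, c(list(X, Y, cv$chosen_lambda), extra)))
  }

  fits <- lapply(seq_len(S), function(s) {
    fit_subject(unclass(ds$cortex_train[[s]]),
                unclass(ds$cerebellum_train[[s]]),
                seed = config$seed + s)
  })
  group <- average_models(lapply(fits, `[[`, "model"))

  per_voxel_corr <- function(W_hat, W_true) {
    r <- vapply(seq_len(ncol(W_true)), function(q) {
      if (stats::sd(W_hat[, q]) == 0) return(NA_real_)
      stats::cor(W_hat[, q], W_true[, q])
    }, numeric(1L))
    mean(r, na.rm = TRUE)
  }
  heldout <- mean(vapply(seq_len(S), function(s) {
    evaluate_voxelwise(
      predict_cerebellum(group, unclass(ds$cortex_test[[s]])),
      unclass(ds$cerebellum_test[[s]]))$mean_r
  }, numeric(1L)))

  # control: permute training condition labels of Y per subject, refit with
  # the same estimator settings (the subject's chosen penalty) so that only
  # the cortex-cerebellum correspondence differs
  fit_fun <- if (method == "ridge") fit_ridge else fit_lasso
  shuffled <- lapply(seq_len(S), function(s) {
    set.seed(config$seed + 10000L + s)
    Y <- unclass(ds$cerebellum_train[[s]])
    Y_perm <- Y[sample(nrow(Y)), , drop = FALSE]
    rownames(Y_perm) <- rownames(Y)
    lam_s <- fits[[s]]$cv$chosen_lambda
    extra <- if (method == "lasso") list(tol = fit_tol) else list()
    do.call(fit_fun, c(list(unclass(ds$cortex_train[[s]]), Y_perm, lam_s),
                       extra))
  })
  group_shuffled <- average_models(shuffled)
  shuffled_r <- mean(vapply(seq_len(S), function(s) {
    evaluate_voxelwise(
      predict_cerebellum(group_shuffled, unclass(ds$cortex_test[[s]])),
      unclass(ds$cerebellum_test[[s]]))$mean_r
  }, numeric(1L)))

  list(weight_corr = per_voxel_corr(group$weights, ds$W_true),
       weight_corr_overall = stats::cor(as.vector(group$weights),
                                        as.vector(ds$W_true)),
       heldout_r = heldout,
       shuffled_r = shuffled_r,
       shuffled_weight_corr = per_voxel_corr(group_shuffled$weights,
                                             ds$W_true),
       chosen_lambdas = vapply(fits, function(f) f$cv$chosen_lambda,
                               numeric(1L)),
       cv_reports = lapply(fits, `[[`, "cv"),
       group_model = group)
}

# One null/alternative replicate of the residual pipeline on a fresh
# synthetic dataset: predict with the true weights, rescale per subject,
# return the test p-values.
pipeline_replicate <- function(config, rep_seed, gating_gain = NULL) {
  args <- unclass(config)
  args$seed <- rep_seed
  if (!is.null(gating_gain)) args$gating_gain <- gating_gain
  args$connectivity_scale <- NULL  # rederive defaults deterministically
  cfg <- do.call(simulation_config, args[names(args) %in%
                                           names(formals(simulation_config))])
  ds <- simulate_dataset(cfg)
  gated <- cfg$gated_conditions
  nongated <- setdiff(ds$design$condition_labels, gated)
  res <- run_recruitment_analysis(
    ds$cortex_test, ds$cerebellum_test, ds$true_model, ds$roi, ds$design,
    contrasts = list(gated_vs_rest = list(a = gated, b = nongated)))
  list(p_anova = res$anova_oneway$p_value,
       p_contrast = res$posthoc$gated_vs_rest$p_value,
       mean_residuals = colMeans(test_residuals(res$residual_table)))
}

binom_ci <- function(k, n, level = 0.95) {
  ci <- stats::binom.test(k, n)$conf.int
  c(lower = ci[1L], upper = ci[2L])
}

#' Type-I-error calibration of the residual pipeline
#'
#' Runs the full selective-recruitment pipeline on `n_reps` independent
#' synthetic datasets generated with gating gain 0 (the task-invariant
#' null), predicting with the true connectivity weights, and reports the
#' fraction of repetitions in which each test rejects at `alpha`, with an
#' exact binomial confidence interval. Replicate seeds are derived from the
#' config seed by a fixed offset.
#'
#' @param config a [simulation_config] with `gating_gain = 0`.
#' @param n_reps number of Monte Carlo repetitions (>= 100 recommended).
#' @param alpha nominal test level.
#' @return list: `rate_anova`, `ci_anova`, `rate_contrast`, `ci_contrast`,
#'   `n_reps`, `alpha`, `mean_residual_by_condition`.
#' @export
calibration_experiment <- function(config, n_reps = 2000L, alpha = 0.05) {
  stopifnot(inherits(config, "simulation_config"))
  if (config$gating_gain != 0) {
    stop("calibration requires gating_gain = 0")
  }
  if (n_reps < 100L) {
    warning("n_reps < 100 gives a very imprecise type-I estimate")
  }
  reps <- lapply(seq_len(n_reps), function(r) {
    pipeline_replicate(config, rep_seed = (config$seed + 104729L * r) %%
                         .Machine$integer.max)
  })
  p_anova <- vapply(reps, `[[`, numeric(1L), "p_anova")
  p_contrast <- vapply(reps, `[[`, numeric(1L), "p_contrast")
  mean_res <- colMeans(do.call(rbind, lapply(reps, `[[`, "mean_residuals")))
  k1 <- sum(p_anova < alpha); k2 <- sum(p_contrast < alpha)
  list(rate_anova = k1 / n_reps, ci_anova = binom_ci(k1, n_reps),
       rate_contrast = k2 / n_reps, ci_contrast = binom_ci(k2, n_reps),
       n_reps = n_reps, alpha = alpha,
       mean_residual_by_condition = mean_res)
}

#' Power of the residual pipeline across gating gains
#'
#' For each gain, runs the pipeline on `n_reps` fresh synthetic datasets
#' with that gating gain injected on the gated conditions and reports the
#' rejection rate of the one-way repeated-measures ANOVA and of the
#' one-sided gated-versus-nongated contrast at `alpha`. The first gain
#' should be 0, where the rejection rate reduces to the type-I rate.
#'
#' @param config a [simulation_config] (its `gating_gain` is overridden).
#' @param gains ascending gains, first entry 0.
#' @param n_reps repetitions per gain.
#' @param alpha nominal test level.
#' @return data.frame: `gain`, `power_anova`, `power_contrast`, `n_reps`,
#'   with binomial standard errors.
#' @export
power_experiment <- function(config, gains = c(0, 0.1, 0.25, 0.5),
                             n_reps = 500L, alpha = 0.05) {
  stopifnot(inherits(config, "simulation_config"))
  if (is.unsorted(gains) || gains[1L] != 0) {
    stop("gains must be ascending with first entry 0")
  }
  rows <- lapply(seq_along(gains), function(i) {
    g <- gains[i]
    reps <- lapply(seq_len(n_reps), function(r) {
      pipeline_replicate(
        config,
        rep_seed = (config$seed + 104729L * r + 524287L * i) %%
          .Machine$integer.max,
        gating_gain = g)
    })
    pa <- mean(vapply(reps, `[[`, numeric(1L), "p_anova") < alpha)
    pc <- mean(vapply(reps, `[[`, numeric(1L), "p_contrast") < alpha)
    data.frame(gain = g, power_anova = pa, power_contrast = pc,
               se_anova = sqrt(pa * (1 - pa) / n_reps),
               se_contrast = sqrt(pc * (1 - pc) / n_reps),
               n_reps = n_reps)
  })
  do.call(rbind, rows)
}
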