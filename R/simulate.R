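#' Simulation configuration
#'
#' Full generative specification for synthetic cortico-cerebellar task
#' activity with known connectivity and injectable input gating. Cortical
#' activity has low-rank task structure shared across subjects (with
#' per-subject jitter); cerebellar activity is the cortical activity
#' transmitted through a fixed sparse nonnegative weight matrix, optionally
#' amplified by `(1 + gating_gain)` for the gated conditions on the ROI
#' voxels; independent Gaussian noise is added to both sides.
#'
#' Signal scalings are chosen so cortical and cerebellar signal entries
#' have variance close to 1; `snr` (signal variance over noise variance)
#' then determines the default noise standard deviations
#' `1 / sqrt(snr)`.
#'
#' @param n_subjects number of subjects S.
#' @param n_conditions_train,n_conditions_test conditions in the training
#'   and (disjoint) test sets.
#' @param n_parcels,n_voxels predictor parcels P and target voxels Q.
#' @param task_rank number of latent task dimensions in the shared
#'   condition x parcel structure. `NULL` (default) uses
#'   `n_conditions_train`: a well-designed multi-domain battery aims for
#'   conditions that span as many distinct activity dimensions as possible.
#'   Smaller values emulate redundant batteries; note that connectivity
#'   weights are then only identifiable within the spanned subspace, so
#'   weight recovery degrades by construction.
#' @param connectivity_sparsity fraction of zero entries in the true
#'   weights, in [0, 1).
#' @param connectivity_scale scale of nonzero weights; `NULL` picks
#'   `1 / sqrt(P * (1 - sparsity))` so transmitted signal has unit
#'   variance.
#' @param gated_conditions labels of test conditions receiving gating;
#'   `NULL` defaults to the first three test conditions.
#' @param gating_gain multiplicative gain g >= 0 on transmitted input for
#'   gated conditions (0 = task-invariant transmission, the null).
#' @param noise_sd_cortex,noise_sd_cerebellum Gaussian noise SDs; `NULL`
#'   derives them from `snr`.
#' @param snr signal-to-noise amplitude ratio (signal SD over noise SD, the
#'   tSNR-style convention) used for default noise SDs: with unit-variance
#'   signal, `noise_sd = 1 / snr`.
#' @param subject_jitter_sd SD of per-subject jitter on the shared task
#'   loadings.
#' @param task_activation_mean mean cortical activation of task conditions
#'   above the resting baseline (normalized-activity units). Task
#'   conditions engage cortex, so their activity — and hence the
#'   transmitted cerebellar prediction — sits above rest on average; this
#'   is what anchors the through-origin rescaling and gives gating a
#'   consistent (positive) direction.
#' @param roi_fraction fraction of voxels in the gated ROI.
#' @param seed integer seed; the dataset is a pure function of the config.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(n_subjects = 8L,
                              n_conditions_train = 30L,
                              n_conditions_test = 10L,
                              n_parcels = 40L,
                              n_voxels = 20L,
                              task_rank = NULL,
                              connectivity_sparsity = 0.7,
                              connectivity_scale = NULL,
                              gated_conditions = NULL,
                              gating_gain = 0,
                              noise_sd_cortex = NULL,
                              noise_sd_cerebellum = NULL,
                              snr = 10,
                              subject_jitter_sd = 0.2,
                              task_activation_mean = 1,
                              roi_fraction = 0.5,
                              seed = 7L) {
  cfg <- list(n_subjects = as.integer(n_subjects),
              n_conditions_train = as.integer(n_conditions_train),
              n_conditions_test = as.integer(n_conditions_test),
              n_parcels = as.integer(n_parcels),
              n_voxels = as.integer(n_voxels),
              task_rank = if (is.null(task_rank)) as.integer(n_conditions_train)
                          else as.integer(task_rank),
              connectivity_sparsity = connectivity_sparsity,
              connectivity_scale = connectivity_scale,
              gated_conditions = gated_conditions,
              gating_gain = gating_gain,
              noise_sd_cortex = noise_sd_cortex,
              noise_sd_cerebellum = noise_sd_cerebellum,
              snr = snr,
              subject_jitter_sd = subject_jitter_sd,
              task_activation_mean = task_activation_mean,
              roi_fraction = roi_fraction,
              seed = as.integer(seed))
  for (f in c("n_subjects", "n_conditions_train", "n_conditions_test",
              "n_parcels", "n_voxels", "task_rank")) {
    if (is.na(cfg[[f]]) || cfg[[f]] < 1L) stop("invalid config field: ", f)
  }
  if (cfg$connectivity_sparsity < 0 || cfg$connectivity_sparsity >= 1) {
    stop("invalid config field: connectivity_sparsity")
  }
  if (cfg$gating_gain < 0) stop("invalid config field: gating_gain")
  if (cfg$snr <= 0) stop("invalid config field: snr")
  if (cfg$roi_fraction <= 0 || cfg$roi_fraction > 1) {
    stop("invalid config field: roi_fraction")
  }
  if (is.null(cfg$connectivity_scale)) {
    cfg$connectivity_scale <-
      1 / sqrt(cfg$n_parcels * (1 - cfg$connectivity_sparsity))
  }
  if (is.null(cfg$noise_sd_cortex)) cfg$noise_sd_cortex <- 1 / cfg$snr
  if (is.null(cfg$noise_sd_cerebellum)) {
    cfg$noise_sd_cerebellum <- 1 / cfg$snr
  }
  test_labels <- sprintf("test%02d", seq_len(cfg$n_conditions_test))
  if (is.null(cfg$gated_conditions)) {
    cfg$gated_conditions <- test_labels[seq_len(min(3L,
                                                    cfg$n_conditions_test))]
  }
  if (!all(cfg$gated_conditions %in% test_labels)) {
    stop("invalid config field: gated_conditions (must be test conditions)")
  }
  if (any(c(cfg$noise_sd_cortex, cfg$noise_sd_cerebellum) < 0)) {
    stop("invalid config field: noise sds must be nonnegative")
  }
  structure(cfg, class = "simulation_config")
}

#' Simulate a multi-subject cortico-cerebellar dataset
#'
#' Draws shared task loadings `T` (conditions x rank) and parcel loadings
#' `B` (rank x parcels), a sparse nonnegative true weight matrix `W_true`,
#' and per subject `X_s = (T + jitter_s) B + noise` and
#' `Y_s = gate * (X_s W_true) + noise`, where `gate = 1 + g` on gated
#' condition rows restricted to the ROI voxels and 1 elsewhere. Training
#' conditions are never gated (they emulate the independent multi-task
#' training battery); the test set is a disjoint condition set. Rest is not
#' included as a row: the analysis pipeline appends it as exact zeros.
#'
#' @param config a [simulation_config].
#' @return list of class `synthetic_dataset`: per-subject lists
#'   `cortex_train`, `cerebellum_train`, `cortex_test`, `cerebellum_test`
#'   of [activity_table]s; `W_true`; `true_model` (a [connectivity_model]
#'   wrapping `W_true`); `roi` ([roi_mask] of the gated voxels); `design`
#'   ([condition_design] of the test conditions); `config`.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  c_ <- config
  set.seed(c_$seed)
  P <- c_$n_parcels; Q <- c_$n_voxels; R <- c_$task_rank
  parcel_ids <- sprintf("p%03d", seq_len(P))
  voxel_ids <- sprintf("v%03d", seq_len(Q))
  train_labels <- sprintf("train%02d", seq_len(c_$n_conditions_train))
  test_labels <- sprintf("test%02d", seq_len(c_$n_conditions_test))

  B <- matrix(stats::rnorm(R * P), R, P) / sqrt(R)
  T_train <- matrix(stats::rnorm(c_$n_conditions_train * R),
                    c_$n_conditions_train, R)
  T_test <- matrix(stats::rnorm(c_$n_conditions_test * R),
                   c_$n_conditions_test, R)
  mask <- matrix(stats::runif(P * Q) >= c_$connectivity_sparsity, P, Q)
  W_true <- matrix(abs(stats::rnorm(P * Q)), P, Q) * mask *
    c_$connectivity_scale
  dimnames(W_true) <- list(parcel_ids, voxel_ids)

  n_roi <- max(1L, round(c_$roi_fraction * Q))
  roi_voxels <- voxel_ids[seq_len(n_roi)]
  gate_row <- test_labels %in% c_$gated_conditions
  gate_col <- voxel_ids %in% roi_voxels

  make_pair <- function(T_shared, labels, subject, gated) {
    N <- nrow(T_shared)
    T_s <- T_shared + c_$subject_jitter_sd * matrix(stats::rnorm(N * R), N, R)
    X <- c_$task_activation_mean + T_s %*% B +
      c_$noise_sd_cortex * matrix(stats::rnorm(N * P), N, P)
    signal <- X %*% W_true
    if (gated && c_$gating_gain > 0) {
      amp <- 1 + c_$gating_gain * outer(gate_row, gate_col)
      signal <- signal * amp
    }
    Y <- signal + c_$noise_sd_cerebellum * matrix(stats::rnorm(N * Q), N, Q)
    list(cortex = activity_table(X, labels, parcel_ids, subject,
                                 space = "cortex_parcel"),
         cerebellum = activity_table(Y, labels, voxel_ids, subject,
                                     space = "cerebellum_voxel"))
  }

  cortex_train <- cerebellum_train <- vector("list", c_$n_subjects)
  cortex_test <- cerebellum_test <- vector("list", c_$n_subjects)
  subject_ids <- sprintf("s%02d", seq_len(c_$n_subjects))
  for (s in seq_len(c_$n_subjects)) {
    tr <- make_pair(T_train, train_labels, subject_ids[s], gated = FALSE)
    te <- make_pair(T_test, test_labels, subject_ids[s], gated = TRUE)
    cortex_train[[s]] <- tr$cortex; cerebellum_train[[s]] <- tr$cerebellum
    cortex_test[[s]] <- te$cortex; cerebellum_test[[s]] <- te$cerebellum
  }
  names(cortex_train) <- names(cerebellum_train) <- subject_ids
  names(cortex_test) <- names(cerebellum_test) <- subject_ids

  structure(list(
    cortex_train = cortex_train, cerebellum_train = cerebellum_train,
    cortex_test = cortex_test, cerebellum_test = cerebellum_test,
    W_true = W_true,
    true_model = connectivity_model(W_true, "ridge", lam = 0,
                                    parcel_ids = parcel_ids,
                                    target_unit_ids = voxel_ids,
                                    training_meta = list(source = "true")),
    roi = roi_mask("gated_roi", roi_voxels),
    design = condition_design(test_labels, rest_label = "rest"),
    config = config),
    class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  c_ <- x$config
  cat(sprintf(paste0("<synthetic_dataset> S = %d, train %d / test %d ",
                     "conditions, P = %d, Q = %d, gain = %g\n"),
              c_$n_subjects, c_$n_conditions_train, c_$n_conditions_test,
              c_$n_parcels, c_$n_voxels, c_$gating_gain))
  invisible(x)
}
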