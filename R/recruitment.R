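#' Per-subject scale fit between predicted and observed ROI activity
#'
#' Connectivity weights estimated on other subjects and datasets predict
#' regional activity only up to a scale factor (signal-to-noise differs
#' between datasets). A simple linear regression of observed on predicted
#' activity absorbs that difference; its residuals are the selective-
#' recruitment statistic. By default the regression passes through the
#' origin (the resting baseline sits at (0, 0) and is included as a data
#' point), so `slope = sum(pred * obs) / sum(pred^2)`. A free-intercept
#' variant is available.
#'
#' @param pred,obs numeric vectors of predicted and observed ROI activity,
#'   one value per condition (length >= 2 before rest augmentation).
#' @param include_rest append the rest anchor point (0, 0) before fitting.
#' @param free_intercept if `TRUE`, fit an ordinary regression with
#'   intercept instead of the through-origin fit.
#' @param subject_id stored on the result.
#' @return list of class `scale_fit`: `slope`, `intercept`, `r_squared`
#'   (uncentered for the through-origin fit, centered otherwise),
#'   `n_points`, `residuals` (per input condition, rest anchor excluded),
#'   `rest_residual`, `nonpositive_slope` flag.
#' @export
fit_scale <- function(pred, obs, include_rest = TRUE, free_intercept = FALSE,
                      subject_id = NA_character_) {
  stopifnot(length(pred) == length(obs), length(pred) >= 2L,
            all(is.finite(pred)), all(is.finite(obs)))
  labels <- names(pred)
  x <- as.numeric(pred); y <- as.numeric(obs)
  if (include_rest) { x <- c(x, 0); y <- c(y, 0) }
  if (free_intercept) {
    if (stats::sd(x) == 0) stop("predictions are constant; slope undefined")
    fit <- stats::lm.fit(cbind(1, x), y)
    intercept <- fit$coefficients[1L]
    slope <- fit$coefficients[2L]
    ss_res <- sum(fit$residuals^2)
    ss_tot <- sum((y - mean(y))^2)
  } else {
    if (sum(x^2) == 0) stop("predictions are all zero; slope undefined")
    slope <- sum(x * y) / sum(x^2)
    intercept <- 0
    ss_res <- sum((y - slope * x)^2)
    ss_tot <- sum(y^2)  # uncentered: through-origin fit
  }
  resid_all <- y - intercept - slope * x
  resid <- resid_all[seq_along(pred)]
  names(resid) <- labels
  structure(list(subject_id = subject_id,
                 slope = unname(slope), intercept = unname(intercept),
                 r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
                 n_points = length(x),
                 residuals = resid,
                 rest_residual = if (include_rest) unname(resid_all[length(x)])
                                 else NA_real_,
                 nonpositive_slope = slope <= 0),
            class = "scale_fit")
}

#' Signed residual table across subjects
#'
#' Applies [fit_scale()] to each subject's predicted/observed ROI profile
#' and collects the signed residuals `obs - slope * pred` into a subjects x
#' conditions matrix — the quantity submitted to repeated-measures tests.
#' With the default through-origin fit (rest anchor included) each
#' subject's residuals are orthogonal to that subject's predictions.
#'
#' @param pred_profiles,obs_profiles lists (one element per subject) of
#'   named numeric vectors sharing the same condition labels.
#' @param subject_ids subject identifiers.
#' @inheritParams fit_scale
#' @return list of class `residual_table`: `residuals` (S x N matrix),
#'   `pred`/`obs` matrices, `scale_fits`, `subject_ids`,
#'   `condition_labels`.
#' @export
signed_residuals <- function(pred_profiles, obs_profiles,
                             subject_ids = names(pred_profiles),
                             include_rest = TRUE, free_intercept = FALSE) {
  S <- length(pred_profiles)
  stopifnot(S >= 1L, length(obs_profiles) == S)
  if (is.null(subject_ids)) subject_ids <- paste0("s", seq_len(S))
  labels <- names(pred_profiles[[1L]])
  fits <- vector("list", S)
  for (s in seq_len(S)) {
    if (!identical(names(pred_profiles[[s]]), labels) ||
        !identical(names(obs_profiles[[s]]), labels)) {
      stop("subject ", subject_ids[s],
           ": condition labels differ across subjects")
    }
    fits[[s]] <- tryCatch(
      fit_scale(pred_profiles[[s]], obs_profiles[[s]],
                include_rest = include_rest, free_intercept = free_intercept,
                subject_id = subject_ids[s]),
      error = function(e) stop("scale fit failed for subject ",
                               subject_ids[s], ": ", conditionMessage(e)))
  }
  residuals <- do.call(rbind, lapply(fits, `[[`, "residuals"))
  dimnames(residuals) <- list(subject_ids, labels)
  structure(list(residuals = residuals,
                 pred = do.call(rbind, pred_profiles),
                 obs = do.call(rbind, obs_profiles),
                 scale_fits = fits,
                 subject_ids = subject_ids,
                 condition_labels = labels),
            class = "residual_table")
}

#' @export
print.residual_table <- function(x, ...) {
  cat(sprintf("<residual_table> %d subjects x %d conditions\n",
              nrow(x$residuals), ncol(x$residuals)))
  print(round(x$residuals, 4), ...)
  invisible(x)
}

#' Residuals for the conditions under test
#'
#' Drops the rest baseline column (if present): rest anchors the scale fit
#' but is excluded from the residual ANOVA.
#'
#' @param rt a `residual_table`.
#' @param rest_label rest condition label, or `NULL` to keep all columns.
#' @return S x N numeric matrix.
#' @export
test_residuals <- function(rt, rest_label = "rest") {
  stopifnot(inherits(rt, "residual_table"))
  r <- rt$residuals
  if (!is.null(rest_label) && rest_label %in% colnames(r)) {
    r <- r[, colnames(r) != rest_label, drop = FALSE]
  }
  r
}

#' End-to-end selective-recruitment analysis
#'
#' Runs the full pipeline for one dataset: append the resting baseline to
#' the cortical and cerebellar tables, predict cerebellar activity from the
#' cortical data with a (group) connectivity model, average observed and
#' predicted activity over the ROI, rescale predictions per subject, and
#' test the signed residuals. Inference is a one-way repeated-measures
#' ANOVA over conditions, a factorial repeated-measures ANOVA when the
#' design declares more than one factor, and one-sided paired t-tests for
#' any declared contrasts.
#'
#' @param cortex_tables,cerebellum_tables lists of [activity_table]s (one
#'   per subject, same order) holding the test conditions without a rest
#'   row.
#' @param model a [connectivity_model] (typically group-averaged weights
#'   estimated on independent subjects).
#' @param roi a [roi_mask] over the cerebellar units.
#' @param design a [condition_design]; its `rest_label` (default "rest")
#'   names the appended baseline.
#' @param contrasts named list of contrasts, each
#'   `list(a = <labels>, b = <labels>)`; condition-set means are compared
#'   with a paired one-sided t-test (a > b).
#' @param include_rest,free_intercept passed to [fit_scale()].
#' @param tail tail for the contrast t-tests.
#' @return list of class `recruitment_result`: `residual_table`,
#'   `anova_oneway`, `anova_factorial` (or NULL), `posthoc`,
#'   `mean_r_squared`, `condition_means` (mean residual and SEM per
#'   condition).
#' @export
run_recruitment_analysis <- function(cortex_tables, cerebellum_tables, model,
                                     roi, design, contrasts = list(),
                                     include_rest = TRUE,
                                     free_intercept = FALSE,
                                     tail = "greater") {
  S <- length(cortex_tables)
  stopifnot(S >= 2L, length(cerebellum_tables) == S,
            inherits(model, "connectivity_model"),
            inherits(roi, "roi_mask"), inherits(design, "condition_design"))
  rest <- if (is.null(design$rest_label)) "rest" else design$rest_label
  subject_ids <- vapply(cortex_tables, attr, character(1L), "subject_id")

  stage <- function(what, expr) {
    tryCatch(expr, error = function(e) {
      stop("[", what, "] ", conditionMessage(e), call. = FALSE)
    })
  }
  pred_profiles <- vector("list", S)
  obs_profiles <- vector("list", S)
  for (s in seq_len(S)) {
    ctx <- stage("align", align_to_design(cortex_tables[[s]], design))
    crb <- stage("align", align_to_design(cerebellum_tables[[s]], design))
    ctx <- stage("rest-augmentation", append_rest_baseline(ctx, rest))
    crb <- stage("rest-augmentation", append_rest_baseline(crb, rest))
    yhat <- stage("prediction", predict_cerebellum(model, unclass(ctx)))
    yhat_tab <- retable(yhat, crb, unit_ids = colnames(yhat),
                        space = "cerebellum_voxel")
    pred_profiles[[s]] <- stage("roi-extraction",
                                extract_roi_profile(yhat_tab, roi))
    obs_profiles[[s]] <- stage("roi-extraction",
                               extract_roi_profile(crb, roi))
  }
  rt <- stage("scale-fit",
              signed_residuals(pred_profiles, obs_profiles,
                               subject_ids = subject_ids,
                               include_rest = include_rest,
                               free_intercept = free_intercept))
  res_test <- test_residuals(rt, rest)
  anova1 <- stage("anova", rm_anova_oneway(res_test))
  anovaf <- NULL
  if (!is.null(design$factor_levels) && ncol(design$factor_levels) > 1L) {
    anovaf <- stage("anova", rm_anova_factorial(res_test, design))
  }
  posthoc <- lapply(contrasts, function(ct) {
    a <- rowMeans(res_test[, ct$a, drop = FALSE])
    b <- rowMeans(res_test[, ct$b, drop = FALSE])
    stage("posthoc", paired_ttest(a, b, tail = tail))
  })
  cm <- colMeans(res_test)
  sem <- apply(res_test, 2L, stats::sd) / sqrt(S)
  structure(list(residual_table = rt,
                 anova_oneway = anova1,
                 anova_factorial = anovaf,
                 posthoc = posthoc,
                 mean_r_squared = mean(vapply(rt$scale_fits, `[[`,
                                              numeric(1L), "r_squared")),
                 condition_means = data.frame(condition = names(cm),
                                              mean_residual = unname(cm),
                                              sem = unname(sem))),
            class = "recruitment_result")
}

#' @export
print.recruitment_result <- function(x, ...) {
  cat("Selective recruitment analysis\n")
  cat(sprintf("  subjects: %d, conditions tested: %d, mean R^2 = %.3f\n",
              nrow(x$residual_table$residuals),
              nrow(x$condition_means), x$mean_r_squared))
  cat("  one-way RM-ANOVA on signed residuals: ")
  print(x$anova_oneway)
  if (!is.null(x$anova_factorial)) {
    cat("  factorial RM-ANOVA:\n")
    print(as.data.frame(x$anova_factorial)[, c("effect", "df_num", "df_den",
                                               "f_value", "p_value")],
          row.names = FALSE)
  }
  for (nm in names(x$posthoc)) {
    cat("  contrast ", nm, ": ", sep = "")
    print(x$posthoc[[nm]])
  }
  invisible(x)
}

#' Serialize a recruitment result to JSON
#' @param result a `recruitment_result`.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_recruitment_report <- function(result, path) {
  stopifnot(inherits(result, "recruitment_result"))
  a1 <- result$anova_oneway
  obj <- list(
    mean_r_squared = result$mean_r_squared,
    anova_oneway = list(df_num = a1$df_num, df_den = a1$df_den,
                        f_value = a1$f_value, p_value = a1$p_value),
    condition_means = result$condition_means,
    residuals = as.data.frame(result$residual_table$residuals))
  if (!is.null(result$anova_factorial)) {
    obj$anova_factorial <- as.data.frame(result$anova_factorial)
  }
  if (length(result$posthoc)) {
    obj$posthoc <- lapply(result$posthoc, function(t) {
      list(t_value = t$t_value, df = t$df, p_value = t$p_value,
           tail = t$tail)
    })
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "columns")
  invisible(path)
}
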