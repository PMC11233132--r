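#' Task-invariant connectivity model
#'
#' A fixed linear mapping from cortical parcel activity to cerebellar voxel
#' activity: `Y = X W`, with W estimated by regularized regression on
#' task-activity matrices. No intercept is fitted anywhere: the resting
#' baseline, appended as a row of zeros to both X and Y, anchors the model
#' at the origin.
#'
#' @param weights P x Q numeric matrix of connectivity weights.
#' @param method `"ridge"` or `"lasso"`.
#' @param lam penalty value(s); a vector when the model is an average of
#'   models fitted at different penalties.
#' @param parcel_ids,target_unit_ids row/column identifiers of `weights`.
#' @param training_meta free-form list (dataset tag, conditions, subjects).
#' @return list of class `connectivity_model`.
#' @export
connectivity_model <- function(weights, method = c("ridge", "lasso"),
                               lam = NA_real_,
                               parcel_ids = rownames(weights),
                               target_unit_ids = colnames(weights),
                               training_meta = list()) {
  method <- match.arg(method)
  weights <- as.matrix(weights)
  if (!all(is.finite(weights))) stop("connectivity weights must be finite")
  if (is.null(parcel_ids)) parcel_ids <- paste0("p", seq_len(nrow(weights)))
  if (is.null(target_unit_ids)) {
    target_unit_ids <- paste0("v", seq_len(ncol(weights)))
  }
  stopifnot(length(parcel_ids) == nrow(weights),
            length(target_unit_ids) == ncol(weights),
            all(lam >= 0 | is.na(lam)))
  dimnames(weights) <- list(parcel_ids, target_unit_ids)
  structure(list(weights = weights, method = method, lam = lam,
                 parcel_ids = as.character(parcel_ids),
                 target_unit_ids = as.character(target_unit_ids),
                 training_meta = training_meta),
            class = "connectivity_model")
}

#' @export
print.connectivity_model <- function(x, ...) {
  cat(sprintf("<connectivity_model> %s, lambda = %s: %d parcels -> %d targets\n",
              x$method, paste(signif(x$lam, 4), collapse = ", "),
              nrow(x$weights), ncol(x$weights)))
  invisible(x)
}

check_xy <- function(X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) stop("X and Y must have the same number of rows")
  if (nrow(X) < 1L) stop("need at least one condition row")
  if (!all(is.finite(X)) || !all(is.finite(Y))) stop("X and Y must be finite")
  list(X = X, Y = Y)
}

#' Fit a ridge connectivity model
#'
#' Minimizes `||Y - X W||_F^2 + lam * ||W||_F^2` (no intercept), solving the
#' normal equations `(X'X + lam I) W = X'Y` directly. At `lam = 0` this is
#' ordinary least squares and requires X to have full column rank.
#'
#' @param X N x P cortical activity matrix (conditions x parcels).
#' @param Y N x Q cerebellar activity matrix (conditions x voxels).
#' @param lam nonnegative ridge penalty.
#' @param training_meta optional metadata stored on the model.
#' @return a [connectivity_model].
#' @export
fit_ridge <- function(X, Y, lam, training_meta = list()) {
  d <- check_xy(X, Y); X <- d$X; Y <- d$Y
  stopifnot(is.numeric(lam), length(lam) == 1L, lam >= 0)
  A <- crossprod(X) + diag(lam, ncol(X))
  if (lam == 0) {
    qrx <- qr(X)
    if (qrx$rank < ncol(X)) {
      stop("X is rank deficient (rank ", qrx$rank, " < ", ncol(X),
           " columns); ridge with lam = 0 is not identified")
    }
  }
  W <- solve(A, crossprod(X, Y))
  connectivity_model(W, "ridge", lam,
                     parcel_ids = colnames(X), target_unit_ids = colnames(Y),
                     training_meta = training_meta)
}

soft_threshold <- function(z, g) sign(z) * pmax(abs(z) - g, 0)

lasso_kkt_worst <- function(XtX, xty, w, lam) {
  grad <- as.numeric(XtX %*% w) - xty
  max(ifelse(w != 0, abs(grad + lam * sign(w)),
             pmax(abs(grad) - lam, 0)))
}

# Active-set polish for coordinate descent on degenerate (singular-Gram)
# problems: fix the sign pattern s of the current active set A and solve
# the stationarity system XtX[A,A] w_A = xty[A] - lam * s exactly
# (minimum-norm via SVD when singular). Coordinates whose solved sign
# disagrees with s are dropped, and when the system is inconsistent (the
# sign pattern admits no stationary point, e.g. more active coordinates
# than the data rank) the smallest-magnitude coordinate is dropped; the
# solve then repeats.
lasso_polish <- function(XtX, xty, w, lam, tol) {
  seen <- character(0)  # signed-support patterns already visited
  for (pass in 1:300) {
    act <- which(w != 0)
    if (length(act) == 0L) return(w)
    s <- sign(w[act])
    key <- paste(act * s, collapse = ",")
    cycling <- key %in% seen
    seen <- c(seen, key)
    A <- XtX[act, act, drop = FALSE]
    b <- xty[act] - lam * s
    sv <- svd(A)
    pos <- sv$d > max(sv$d[1L], 1) * 1e-12
    w_act <- as.numeric(sv$v[, pos, drop = FALSE] %*%
      ((crossprod(sv$u[, pos, drop = FALSE], b)) / sv$d[pos]))
    flipped <- sign(w_act) != s & w_act != 0
    if (any(flipped)) {
      w[] <- 0
      keep <- !flipped & w_act != 0
      w[act[keep]] <- w_act[keep]
      next
    }
    resid <- as.numeric(A %*% w_act) - b
    if (max(abs(resid)) > tol && length(act) > 1L) {
      # inconsistent stationarity system: retire the weakest coordinate
      # (or, when revisiting a pattern, progressively stronger ones)
      ord <- order(abs(w_act))
      drop <- act[ord[min(if (cycling) 2L else 1L, length(ord))]]
      w[] <- 0
      w[act] <- w_act
      w[drop] <- 0
      next
    }
    w[] <- 0
    w[act] <- w_act
    # full KKT: admit the worst violating inactive coordinate, if any
    grad <- as.numeric(XtX %*% w) - xty
    inact_viol <- pmax(abs(grad) - lam, 0)
    inact_viol[act] <- 0
    j <- which.max(inact_viol)
    if (inact_viol[j] <= tol) return(w)
    w[j] <- -sign(grad[j]) * tol  # enter with an infinitesimal step
  }
  w
}

# CD with fallbacks for one target column: coordinate descent from the
# warm start, then active-set polish, then a cold restart (degenerate
# problems occasionally trap a warm-started sweep in a bad support).
# Returns w = NULL when the KKT tolerance cannot be met.
lasso_solve_column <- function(XtX, xty, lam, tol, max_iter, w0 = NULL) {
  worst_seen <- Inf
  starts <- if (is.null(w0)) list(NULL) else list(w0, NULL)
  for (w_start in starts) {
    sol <- .lasso_cd_column(XtX, xty, lam, tol, as.integer(max_iter),
                            w_start)
    w <- sol$w
    if (sol$converged) return(list(w = w, worst = sol$worst_kkt))
    worst_seen <- min(worst_seen, sol$worst_kkt)
    # alternate exact active-set solves with short CD refinements
    for (round in 1:5) {
      w_p <- lasso_polish(XtX, xty, w, lam, tol)
      worst <- lasso_kkt_worst(XtX, xty, w_p, lam)
      if (worst <= tol) return(list(w = w_p, worst = worst))
      if (worst < worst_seen) { worst_seen <- worst; w <- w_p }
      sol <- .lasso_cd_column(XtX, xty, lam, tol, 2000L, w)
      w <- sol$w
      if (sol$converged) return(list(w = w, worst = sol$worst_kkt))
      worst_seen <- min(worst_seen, sol$worst_kkt)
    }
  }
  list(w = NULL, worst = worst_seen)
}

#' Fit a lasso connectivity model by coordinate descent
#'
#' Minimizes `0.5 * ||Y - X W||_F^2 + lam * ||W||_1` (no intercept),
#' solving each target column independently by cyclic coordinate descent
#' with soft-thresholding updates (compiled inner loop working on the Gram
#' matrix). Convergence is declared when every coordinate satisfies its
#' Karush-Kuhn-Tucker condition to within `tol`.
#'
#' @inheritParams fit_ridge
#' @param lam nonnegative L1 penalty.
#' @param tol per-coordinate KKT tolerance.
#' @param max_iter maximum number of full coordinate sweeps per target.
#' @return a [connectivity_model].
#' @export
fit_lasso <- function(X, Y, lam, tol = 1e-8, max_iter = 100000L,
                      training_meta = list()) {
  d <- check_xy(X, Y); X <- d$X; Y <- d$Y
  stopifnot(is.numeric(lam), length(lam) == 1L, lam >= 0)
  P <- ncol(X)
  XtX <- crossprod(X)
  XtY <- crossprod(X, Y)
  if (any(diag(XtX) == 0) && lam == 0) {
    stop("X has an all-zero column; lasso with lam = 0 is not identified")
  }
  W <- matrix(0, P, ncol(Y))
  for (q in seq_len(ncol(Y))) {
    # pathwise continuation: start at lam_max (where w = 0 is optimal) and
    # descend geometrically to the target penalty, warm-starting each step
    lam_max <- max(abs(XtY[, q]))
    w0 <- NULL
    if (lam > 0 && lam < lam_max) {
      path <- exp(seq(log(lam_max), log(lam), length.out = 6L))[-c(1L, 6L)]
      for (l in path) {
        # loose, capped warm-up solves: only the final solve needs tol
        sol <- .lasso_cd_column(XtX, XtY[, q], l, max(tol, 1e-4), 500L, w0)
        w0 <- sol$w
      }
    }
    sol <- lasso_solve_column(XtX, XtY[, q], lam, tol, max_iter, w0)
    if (is.null(sol$w)) {
      stop("lasso coordinate descent did not converge for target ", q,
           " within ", max_iter, " sweeps (worst KKT violation ",
           format(sol$worst, digits = 3), ")")
    }
    W[, q] <- sol$w
  }
  connectivity_model(W, "lasso", lam,
                     parcel_ids = colnames(X), target_unit_ids = colnames(Y),
                     training_meta = training_meta)
}

#' Predict cerebellar activity from cortical activity
#'
#' Multiplies new cortical activity patterns with the model weights:
#' `Y_hat = X_new W`. The prediction is linear and maps rest (a zero row)
#' to rest.
#'
#' @param model a [connectivity_model].
#' @param X_new N' x P matrix whose columns match the model's parcels. When
#'   `X_new` has column names they must equal the model's `parcel_ids`.
#' @return N' x Q matrix of predicted activity.
#' @export
predict_cerebellum <- function(model, X_new) {
  stopifnot(inherits(model, "connectivity_model"))
  X_new <- as.matrix(X_new)
  if (ncol(X_new) != nrow(model$weights)) {
    stop("X_new has ", ncol(X_new), " parcels but the model expects ",
         nrow(model$weights))
  }
  if (!is.null(colnames(X_new)) &&
      !identical(colnames(X_new), model$parcel_ids)) {
    missing <- setdiff(model$parcel_ids, colnames(X_new))
    extra <- setdiff(colnames(X_new), model$parcel_ids)
    stop("parcel mismatch; missing: ",
         paste(missing, collapse = ", "), "; extra: ",
         paste(extra, collapse = ", "))
  }
  Y_hat <- X_new %*% model$weights
  colnames(Y_hat) <- model$target_unit_ids
  Y_hat
}

#' Voxelwise predictive accuracy
#'
#' Predictive accuracy of a connectivity model is the Pearson correlation
#' between the observed and predicted response profile of each target unit
#' across conditions, summarized by the mean over units. Units whose
#' observed or predicted profile has zero variance are skipped and counted.
#'
#' @param Y_hat,Y_obs matrices of identical shape (>= 3 condition rows).
#' @return list with `per_unit_r` (NA where skipped), `mean_r`, and
#'   `n_skipped`.
#' @export
evaluate_voxelwise <- function(Y_hat, Y_obs) {
  Y_hat <- as.matrix(Y_hat); Y_obs <- as.matrix(Y_obs)
  if (!identical(dim(Y_hat), dim(Y_obs))) stop("shape mismatch")
  if (nrow(Y_obs) < 3L) stop("need at least 3 condition rows for correlation")
  r <- vapply(seq_len(ncol(Y_obs)), function(q) {
    if (stats::sd(Y_hat[, q]) == 0 || stats::sd(Y_obs[, q]) == 0) {
      return(NA_real_)
    }
    stats::cor(Y_hat[, q], Y_obs[, q])
  }, numeric(1L))
  if (all(is.na(r))) stop("all target units are degenerate (zero variance)")
  list(per_unit_r = r, mean_r = mean(r, na.rm = TRUE),
       n_skipped = sum(is.na(r)))
}

#' Tune the penalty by k-fold cross-validation over conditions
#'
#' Condition rows are partitioned into k folds by a seeded shuffle. For each
#' penalty in the grid, the model is fitted on k-1 folds and evaluated on
#' the held-out rows with [evaluate_voxelwise()]; the reported accuracy per
#' penalty is the mean over folds. The chosen penalty maximizes mean
#' accuracy, with ties broken toward the larger penalty (more
#' regularization).
#'
#' @inheritParams fit_ridge
#' @param method `"ridge"` or `"lasso"`.
#' @param lambda_grid nonempty vector of candidate penalties.
#' @param k number of folds (each fold must get >= 3 rows).
#' @param seed integer seed for the fold shuffle.
#' @param ... further arguments passed to the fitter (e.g. `tol` for
#'   [fit_lasso()]).
#' @return list of class `cv_report`: `lambda_grid`,
#'   `mean_accuracy_per_lambda`, `chosen_lambda`, `k`, `fold_of_row`.
#' @export
crossval_tune <- function(X, Y, method = c("ridge", "lasso"), lambda_grid,
                          k = 5L, seed = 1L, ...) {
  method <- match.arg(method)
  d <- check_xy(X, Y); X <- d$X; Y <- d$Y
  if (length(lambda_grid) == 0L) stop("lambda_grid is empty")
  N <- nrow(X)
  if (k < 2L || N < k) stop("need 2 <= k <= N")
  fold_sizes <- tabulate(rep_len(seq_len(k), N), nbins = k)
  if (min(fold_sizes) < 3L) {
    stop("fold with ", min(fold_sizes),
         " rows; correlation-based accuracy needs >= 3 rows per fold")
  }
  fold_of_row <- local({
    set.seed(seed)
    sample(rep_len(seq_len(k), N))
  })
  fit_fun <- if (method == "ridge") fit_ridge else fit_lasso
  acc <- vapply(lambda_grid, function(lam) {
    fold_acc <- vapply(seq_len(k), function(f) {
      hold <- fold_of_row == f
      m <- fit_fun(X[!hold, , drop = FALSE], Y[!hold, , drop = FALSE], lam,
                   ...)
      evaluate_voxelwise(predict_cerebellum(m, X[hold, , drop = FALSE]),
                         Y[hold, , drop = FALSE])$mean_r
    }, numeric(1L))
    mean(fold_acc)
  }, numeric(1L))
  best <- max(acc)
  chosen <- max(lambda_grid[acc >= best - 1e-12])  # ties toward larger lambda
  structure(list(lambda_grid = lambda_grid, mean_accuracy_per_lambda = acc,
                 chosen_lambda = chosen, k = k, fold_of_row = fold_of_row),
            class = "cv_report")
}

#' Average connectivity models across subjects
#'
#' The group (or "fusion") model is the unweighted elementwise mean of
#' subject-level weight matrices. All models must share method, parcel ids,
#' and target ids; the penalties of the source models are recorded.
#'
#' @param models list of [connectivity_model]s.
#' @return a [connectivity_model] with averaged weights.
#' @export
average_models <- function(models) {
  stopifnot(length(models) >= 1L,
            all(vapply(models, inherits, logical(1L), "connectivity_model")))
  ref <- models[[1L]]
  for (m in models[-1L]) {
    if (!identical(m$parcel_ids, ref$parcel_ids) ||
        !identical(m$target_unit_ids, ref$target_unit_ids)) {
      stop("models have mismatched parcel or target ids")
    }
    if (!identical(m$method, ref$method)) {
      stop("models have mismatched methods")
    }
  }
  W <- Reduce(`+`, lapply(models, `[[`, "weights")) / length(models)
  connectivity_model(W, ref$method,
                     lam = unlist(lapply(models, `[[`, "lam")),
                     parcel_ids = ref$parcel_ids,
                     target_unit_ids = ref$target_unit_ids,
                     training_meta = list(n_models = length(models)))
}

#' Read/write a connectivity model (weights TSV + JSON sidecar)
#'
#' Weights go to `<path>` as a TSV with parcel ids in the first column and
#' target unit ids in the header; method, penalty and metadata go to
#' `<path>.json`.
#'
#' @param model a [connectivity_model].
#' @param path path of the weights TSV.
#' @return `path` (write) or a [connectivity_model] (read).
#' @export
write_connectivity_model <- function(model, path) {
  stopifnot(inherits(model, "connectivity_model"))
  header <- paste(c("parcel", model$target_unit_ids), collapse = "\t")
  rows <- vapply(seq_len(nrow(model$weights)), function(i) {
    paste(c(model$parcel_ids[i],
            formatC(model$weights[i, ], format = "g", digits = 17)),
          collapse = "\t")
  }, character(1L))
  writeLines(c(header, rows), path)
  jsonlite::write_json(list(method = model$method, lam = model$lam,
                            training_meta = model$training_meta),
                       paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_connectivity_model
#' @export
read_connectivity_model <- function(path) {
  tab <- read_activity_table(path)  # same TSV layout: labels x ids
  W <- matrix(unclass(tab), nrow(tab), ncol(tab), dimnames = dimnames(tab))
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  connectivity_model(W, meta$method, lam = meta$lam,
                     parcel_ids = rownames(tab),
                     target_unit_ids = colnames(tab),
                     training_meta = as.list(meta$training_meta))
}
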