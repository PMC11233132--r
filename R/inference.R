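#' Repeated-measures statistics for residual tables
#'
#' Within-subject ANOVA on balanced condition tables (one observation per
#' subject and condition), as used to test whether signed residuals differ
#' systematically across conditions. Each effect is tested against its own
#' effect-by-subject interaction error term; no sphericity correction is
#' applied, so the degrees of freedom are the classical uncorrected ones.
#'
#' @name rm_anova
NULL

anova_result <- function(effect, ss_effect, df_num, ss_error, df_den) {
  ms_effect <- ss_effect / df_num
  ms_error <- ss_error / df_den
  degenerate <- ss_error <= 0
  f <- if (degenerate) {
    if (ss_effect <= 0) 0 else Inf
  } else {
    ms_effect / ms_error
  }
  p <- if (is.infinite(f)) 0 else stats::pf(f, df_num, df_den,
                                            lower.tail = FALSE)
  structure(list(effect = effect, df_num = as.integer(df_num),
                 df_den = as.integer(df_den), f_value = f, p_value = p,
                 ss_effect = ss_effect, ss_error = ss_error,
                 ms_effect = ms_effect, ms_error = ms_error,
                 degenerate = degenerate),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("%s: F(%d, %d) = %.4g, p = %.4g%s\n", x$effect, x$df_num,
              x$df_den, x$f_value, x$p_value,
              if (x$degenerate) " [degenerate: zero error SS]" else ""))
  invisible(x)
}

check_rm_table <- function(y) {
  y <- as.matrix(y)
  if (nrow(y) < 2L) stop("need at least 2 subjects (rows)")
  if (ncol(y) < 2L) stop("need at least 2 conditions (columns)")
  if (!all(is.finite(y))) stop("table must be complete and finite")
  y
}

#' One-way repeated-measures ANOVA
#'
#' Partitions the total sum of squares of a subjects x conditions table into
#' subject, condition, and subject-by-condition (error) components;
#' `F = MS_condition / MS_error` with `(N-1, (N-1)(S-1))` degrees of
#' freedom. A zero error SS yields `F = Inf`, `p = 0` and a degeneracy flag.
#'
#' @param table numeric S x N matrix: one row per subject, one column per
#'   condition (e.g. the test conditions of a [signed_residuals()] table).
#' @return an `anova_result` with fields `effect`, `df_num`, `df_den`,
#'   `f_value`, `p_value`, `ss_effect`, `ss_error`; the full SS partition is
#'   in attribute `"partition"`.
#' @export
rm_anova_oneway <- function(table) {
  y <- check_rm_table(table)
  S <- nrow(y); N <- ncol(y)
  grand <- mean(y)
  subj_means <- rowMeans(y)
  cond_means <- colMeans(y)
  ss_subject <- N * sum((subj_means - grand)^2)
  ss_cond <- S * sum((cond_means - grand)^2)
  ss_total <- sum((y - grand)^2)
  ss_error <- ss_total - ss_subject - ss_cond
  res <- anova_result("condition", ss_cond, N - 1L, ss_error,
                      (N - 1L) * (S - 1L))
  attr(res, "partition") <- c(ss_total = ss_total, ss_subject = ss_subject,
                              ss_condition = ss_cond, ss_error = ss_error)
  res
}

# Marginal-mean smoother: for each condition column, the mean of `v` over
# the conditions sharing its levels on the factors in `subset` (grand mean
# for the empty subset).
margin_means <- function(v, groups, subset) {
  if (length(subset) == 0L) return(rep(mean(v), length(v)))
  g <- interaction(groups[subset], drop = TRUE)
  stats::ave(v, g)
}

#' Fully-within-subject factorial repeated-measures ANOVA
#'
#' For a complete factorial crossing with one observation per subject and
#' cell, computes every main effect and interaction. Effect estimates are
#' formed by inclusion-exclusion over marginal means; each effect's error
#' term is its interaction with subjects, so
#' `df_den = df_num * (S - 1)` per effect.
#'
#' @param table numeric S x N matrix (subjects x conditions), columns in the
#'   design's condition order.
#' @param design a [condition_design] with `factor_levels` covering the
#'   table's columns (the rest condition, if any, must already be excluded).
#' @return data.frame of class `anova_table`, one row per effect, with the
#'   `anova_result` fields as columns; SS conservation terms in attribute
#'   `"partition"`.
#' @export
rm_anova_factorial <- function(table, design) {
  stopifnot(inherits(design, "condition_design"))
  y <- check_rm_table(table)
  fl <- design$factor_levels
  if (is.null(fl)) {
    fl <- data.frame(condition = design$condition_labels)
  }
  if (!is.null(colnames(y))) {
    if (!setequal(colnames(y), design$condition_labels)) {
      stop("table conditions do not match the design")
    }
    y <- y[, design$condition_labels, drop = FALSE]
  } else if (ncol(y) != length(design$condition_labels)) {
    stop("table has ", ncol(y), " columns but the design declares ",
         length(design$condition_labels), " conditions")
  }
  S <- nrow(y); N <- ncol(y)
  n_levels <- vapply(fl, function(f) length(unique(f)), integer(1L))
  cells <- interaction(fl, drop = FALSE)
  if (N != prod(n_levels) || anyDuplicated(as.character(cells))) {
    missing <- setdiff(levels(cells), as.character(unique(cells)))
    stop("design is not a complete one-observation-per-cell crossing",
         if (length(missing)) paste0("; missing cells: ",
                                     paste(missing, collapse = ", ")))
  }
  factors <- names(fl)
  grand <- mean(y)
  cond_means <- colMeans(y)
  subj_means <- rowMeans(y)

  # all nonempty factor subsets, ordered by interaction order
  subsets <- unlist(lapply(seq_along(factors), function(m) {
    utils::combn(factors, m, simplify = FALSE)
  }), recursive = FALSE)

  effect_terms <- function(v, subset) {
    # inclusion-exclusion over sub-subsets: the pure effect per condition
    out <- numeric(length(v))
    for (m in 0:length(subset)) {
      for (sub in utils::combn(subset, m, simplify = FALSE)) {
        out <- out + (-1)^(length(subset) - m) * margin_means(v, fl, sub)
      }
    }
    out
  }

  results <- lapply(subsets, function(subset) {
    eff <- effect_terms(cond_means, subset)
    ss_eff <- S * sum(eff^2)
    # effect x subject error: same contrast within each subject, centered
    # on that subject's mean profile, minus the group-level effect
    ss_err <- 0
    for (s in seq_len(S)) {
      eff_s <- effect_terms(y[s, ] - subj_means[s] + grand, subset)
      ss_err <- ss_err + sum((eff_s - eff)^2)
    }
    df_num <- prod(n_levels[subset] - 1L)
    anova_result(paste(subset, collapse = ":"), ss_eff, df_num, ss_err,
                 df_num * (S - 1L))
  })
  out <- do.call(rbind, lapply(results, function(r) {
    data.frame(effect = r$effect, df_num = r$df_num, df_den = r$df_den,
               f_value = r$f_value, p_value = r$p_value,
               ss_effect = r$ss_effect, ss_error = r$ss_error,
               degenerate = r$degenerate, stringsAsFactors = FALSE)
  }))
  class(out) <- c("anova_table", "data.frame")
  ss_subject <- N * sum((subj_means - grand)^2)
  attr(out, "partition") <- c(ss_total = sum((y - grand)^2),
                              ss_subject = ss_subject)
  out
}

#' Paired t-test between two within-subject condition profiles
#'
#' Classical paired t on the subject-wise differences `d = a - b`, with
#' `df = S - 1`. The default tail is one-sided ("greater"): selective
#' recruitment predicts a positive residual difference for the gated
#' condition, and a one-sided test is what the printed t/p statistics of
#' this analysis correspond to. When `sd(d) = 0` the test is degenerate:
#' `t = 0, p = 1` (two-sided) if the mean difference is also 0, otherwise
#' `t = +/-Inf` with a flag.
#'
#' @param a,b numeric vectors of equal length S (paired by subject).
#' @param tail `"greater"` (one-sided, a > b) or `"two.sided"`.
#' @return list of class `ttest_result`: `t_value`, `df`, `p_value`,
#'   `tail`, `mean_diff`, `degenerate`.
#' @export
paired_ttest <- function(a, b, tail = c("greater", "two.sided")) {
  tail <- match.arg(tail)
  stopifnot(length(a) == length(b), length(a) >= 2L)
  d <- a - b
  S <- length(d)
  if (stats::sd(d) == 0) {
    if (mean(d) == 0) {
      t <- 0
      p <- if (tail == "greater") 0.5 else 1
    } else {
      t <- sign(mean(d)) * Inf
      p <- if (t > 0 || tail == "two.sided") 0 else 1
    }
    res <- list(t_value = t, df = S - 1L, p_value = p, tail = tail,
                mean_diff = mean(d), degenerate = TRUE)
  } else {
    ht <- stats::t.test(a, b, paired = TRUE, alternative = tail)
    res <- list(t_value = unname(ht$statistic), df = unname(ht$parameter),
                p_value = ht$p.value, tail = tail,
                mean_diff = unname(ht$estimate), degenerate = FALSE)
  }
  structure(res, class = "ttest_result")
}

#' @export
print.ttest_result <- function(x, ...) {
  cat(sprintf("paired t(%d) = %.4g, p = %.4g (%s)%s\n", x$df, x$t_value,
              x$p_value, x$tail,
              if (x$degenerate) " [degenerate: zero-variance differences]"
              else ""))
  invisible(x)
}
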