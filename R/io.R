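#' Read an activity table from TSV
#'
#' Expected layout: UTF-8 TSV, header row of unit ids preceded by a label
#' column name, then one row per condition with the condition label in the
#' first column and numeric activity values in the remaining columns.
#'
#' @param path file path.
#' @param subject_id,space metadata for the returned table (not stored in
#'   the TSV itself).
#' @return an [activity_table].
#' @export
read_activity_table <- function(path, subject_id = "s01",
                                space = "cortex_parcel") {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) {
    stop("'", path, "': expected a header line and at least one data row")
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  width <- length(fields[[1L]])
  ragged <- which(lengths(fields) != width)
  if (length(ragged)) {
    stop("'", path, "': ragged row at line ", ragged[1L],
         " (expected ", width, " fields, found ", lengths(fields)[ragged[1L]], ")")
  }
  ids <- fields[[1L]][-1L]
  labels <- vapply(fields[-1L], `[[`, character(1L), 1L)
  values <- matrix(NA_real_, length(labels), length(ids))
  for (i in seq_along(labels)) {
    row <- suppressWarnings(as.numeric(fields[[i + 1L]][-1L]))
    if (anyNA(row)) {
      stop("'", path, "': non-numeric cell at line ", i + 1L)
    }
    values[i, ] <- row
  }
  if (anyDuplicated(labels)) {
    stop("'", path, "': duplicate condition label '",
         labels[duplicated(labels)][1L], "'")
  }
  activity_table(values, labels, ids, subject_id = subject_id, space = space)
}

#' Write an activity table to TSV
#'
#' Values are written with full double precision (17 significant digits), so
#' a write/read round trip reproduces the table to within 1e-12.
#'
#' @param table an [activity_table].
#' @param path destination file path.
#' @return `path`, invisibly.
#' @export
write_activity_table <- function(table, path) {
  stopifnot(inherits(table, "activity_table"))
  header <- paste(c("condition", unit_ids(table)), collapse = "\t")
  rows <- vapply(seq_len(nrow(table)), function(i) {
    paste(c(condition_labels(table)[i],
            formatC(unclass(table)[i, ], format = "g", digits = 17)),
          collapse = "\t")
  }, character(1L))
  writeLines(c(header, rows), path, useBytes = FALSE)
  invisible(path)
}

#' Read/write a parcel assignment (two-column TSV: unit_id, parcel_id)
#' @param path file path.
#' @return a [parcel_assignment].
#' @export
read_parcel_assignment <- function(path) {
  df <- utils::read.delim(path, colClasses = c("character", "integer"))
  parcel_assignment(df[[1L]], df[[2L]])
}

#' @rdname read_parcel_assignment
#' @param assignment a [parcel_assignment] to write.
#' @export
write_parcel_assignment <- function(assignment, path) {
  stopifnot(inherits(assignment, "parcel_assignment"))
  utils::write.table(
    data.frame(unit_id = assignment$unit_ids,
               parcel_id = assignment$parcel_id_per_unit),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read/write an ROI mask (one member unit id per line)
#' @param path file path.
#' @param roi_name region name (defaults to the file name stem on read).
#' @return a [roi_mask].
#' @export
read_roi_mask <- function(path, roi_name = sub("\\.[^.]*$", "", basename(path))) {
  members <- readLines(path, encoding = "UTF-8")
  roi_mask(roi_name, members[nzchar(members)])
}

#' @rdname read_roi_mask
#' @param roi a [roi_mask] to write.
#' @export
write_roi_mask <- function(roi, path) {
  stopifnot(inherits(roi, "roi_mask"))
  writeLines(roi$unit_ids, path)
  invisible(path)
}

#' Condition design
#'
#' Declares the experimental conditions, their factor structure, and
#' (optionally) the label used for the appended resting baseline. The
#' condition order in the design is authoritative: activity tables are
#' reordered to match it on load.
#'
#' @param condition_labels character vector of condition labels.
#' @param factor_levels `NULL` for a one-factor design (the condition itself
#'   is the factor), or a data.frame with one row per condition and one
#'   column per factor giving each condition's level.
#' @param rest_label optional label for the resting baseline row; must not
#'   collide with a condition label.
#' @return list of class `condition_design`.
#' @export
condition_design <- function(condition_labels, factor_levels = NULL,
                             rest_label = NULL) {
  condition_labels <- as.character(condition_labels)
  if (anyDuplicated(condition_labels)) stop("duplicate condition labels")
  if (!is.null(factor_levels)) {
    factor_levels <- as.data.frame(factor_levels)
    if (nrow(factor_levels) != length(condition_labels)) {
      stop("factor_levels must have one row per condition")
    }
    if (anyNA(factor_levels)) {
      stop("every condition needs a complete factor assignment")
    }
    factor_levels[] <- lapply(factor_levels, as.character)
    rownames(factor_levels) <- condition_labels
  }
  if (!is.null(rest_label) && rest_label %in% condition_labels) {
    stop("rest_label collides with a condition label")
  }
  structure(list(condition_labels = condition_labels,
                 factor_levels = factor_levels,
                 rest_label = rest_label),
            class = "condition_design")
}

#' Read/write a condition design as JSON
#' @param path file path.
#' @return a [condition_design].
#' @export
read_condition_design <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  fl <- obj$factor_levels
  if (!is.null(fl)) fl <- as.data.frame(fl)
  condition_design(obj$condition_labels, fl, obj$rest_label)
}

#' @rdname read_condition_design
#' @param design a [condition_design] to write.
#' @export
write_condition_design <- function(design, path) {
  stopifnot(inherits(design, "condition_design"))
  obj <- list(condition_labels = design$condition_labels)
  if (!is.null(design$factor_levels)) {
    obj$factor_levels <- as.list(design$factor_levels)
  }
  if (!is.null(design$rest_label)) obj$rest_label <- design$rest_label
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Reorder a table's conditions to match the design
#' @param table an [activity_table].
#' @param design a [condition_design] whose labels the table must contain.
#' @return the table with rows in design order.
#' @export
align_to_design <- function(table, design) {
  stopifnot(inherits(table, "activity_table"),
            inherits(design, "condition_design"))
  missing <- setdiff(design$condition_labels, condition_labels(table))
  if (length(missing)) {
    stop("table is missing design condition(s): ",
         paste(missing, collapse = ", "))
  }
  retable(unclass(table)[design$condition_labels, , drop = FALSE], table)
}
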