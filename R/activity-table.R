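#' Condition-by-unit activity table
#'
#' Container for one subject's task-activity estimates: a numeric matrix with
#' conditions in rows and measurement units (neocortical parcels, surface
#' vertices, or cerebellar voxels) in columns. Values are normalized GLM
#' activity estimates (beta weights divided by the residual RMS), so they are
#' unitless and comparable across units.
#'
#' @param values numeric matrix, conditions x units, all finite.
#' @param condition_labels character vector of unique row labels.
#' @param unit_ids character vector of unique column ids.
#' @param subject_id subject identifier.
#' @param space one of `"cortex_parcel"`, `"cortex_vertex"`,
#'   `"cerebellum_voxel"`.
#'
#' @return An object of class `activity_table`: the values matrix with
#'   dimnames set and `subject_id` / `space` attributes.
#' @export
activity_table <- function(values, condition_labels, unit_ids,
                           subject_id = "s01",
                           space = c("cortex_parcel", "cortex_vertex",
                                     "cerebellum_voxel")) {
  space <- match.arg(space)
  values <- as.matrix(values)
  if (!is.numeric(values) || !all(is.finite(values))) {
    stop("activity values must be finite numerics")
  }
  condition_labels <- as.character(condition_labels)
  unit_ids <- as.character(unit_ids)
  if (nrow(values) != length(condition_labels)) {
    stop("row count (", nrow(values), ") does not match number of condition ",
         "labels (", length(condition_labels), ")")
  }
  if (ncol(values) != length(unit_ids)) {
    stop("column count (", ncol(values), ") does not match number of unit ",
         "ids (", length(unit_ids), ")")
  }
  if (anyDuplicated(condition_labels)) {
    stop("duplicate condition labels: ",
         paste(unique(condition_labels[duplicated(condition_labels)]),
               collapse = ", "))
  }
  if (anyDuplicated(unit_ids)) {
    stop("duplicate unit ids: ",
         paste(unique(unit_ids[duplicated(unit_ids)]), collapse = ", "))
  }
  dimnames(values) <- list(condition_labels, unit_ids)
  structure(values,
            subject_id = as.character(subject_id),
            space = space,
            class = c("activity_table", "matrix", "array"))
}

#' @export
print.activity_table <- function(x, ...) {
  cat(sprintf("<activity_table> subject %s, space %s: %d conditions x %d units\n",
              attr(x, "subject_id"), attr(x, "space"), nrow(x), ncol(x)))
  print(utils::head(unclass(x)[, seq_len(min(6L, ncol(x))), drop = FALSE]), ...)
  invisible(x)
}

condition_labels <- function(table) rownames(table)
unit_ids <- function(table) colnames(table)

# rebuild an activity_table around a new values matrix, keeping metadata
retable <- function(values, template, unit_ids = colnames(values),
                    condition_labels = rownames(values),
                    space = attr(template, "space")) {
  activity_table(values, condition_labels, unit_ids,
                 subject_id = attr(template, "subject_id"), space = space)
}

#' Normalize beta estimates by the residual RMS
#'
#' Divides each unit's (column's) beta estimates by that unit's residual
#' root-mean-square from the first-level GLM, turning raw betas into
#' noise-normalized activity estimates. The RMS values must be strictly
#' positive and finite; zero or negative entries are rejected (mask such
#' units out beforehand rather than silently dropping them).
#'
#' @param beta numeric matrix, conditions x units.
#' @param residual_rms positive numeric vector, one entry per column of
#'   `beta` (the per-unit residual standard deviation; divide by it directly).
#' @return matrix of the same shape, `beta[, j] / residual_rms[j]`.
#' @export
normalize_betas <- function(beta, residual_rms) {
  beta <- as.matrix(beta)
  if (length(residual_rms) != ncol(beta)) {
    stop("residual_rms length (", length(residual_rms),
         ") does not match number of units (", ncol(beta), ")")
  }
  bad <- !is.finite(residual_rms) | residual_rms <= 0
  if (any(bad)) {
    ids <- colnames(beta)
    if (is.null(ids)) ids <- as.character(seq_len(ncol(beta)))
    stop("non-positive or non-finite residual RMS for unit(s): ",
         paste(ids[bad], collapse = ", "))
  }
  sweep(beta, 2L, residual_rms, "/")
}

#' Parcel assignment of surface units
#'
#' Maps each surface unit (vertex) to an integer parcel id. Parcel id 0 is
#' reserved for unassigned units (e.g. the medial wall) and is always
#' excluded from parcel averages.
#'
#' @param unit_ids character vector of unit ids.
#' @param parcel_id_per_unit integer vector of nonnegative parcel ids,
#'   parallel to `unit_ids`.
#' @return list of class `parcel_assignment`.
#' @export
parcel_assignment <- function(unit_ids, parcel_id_per_unit) {
  unit_ids <- as.character(unit_ids)
  parcel_id_per_unit <- as.integer(parcel_id_per_unit)
  if (length(unit_ids) != length(parcel_id_per_unit)) {
    stop("unit_ids and parcel_id_per_unit lengths differ")
  }
  if (anyNA(parcel_id_per_unit) || any(parcel_id_per_unit < 0L)) {
    stop("parcel ids must be nonnegative integers (0 = unassigned)")
  }
  structure(list(unit_ids = unit_ids,
                 parcel_id_per_unit = parcel_id_per_unit),
            class = "parcel_assignment")
}

#' Average vertex-level activity into parcels
#'
#' Replaces each parcel's member columns by their arithmetic mean, producing
#' a condition x parcel table ordered by ascending parcel id. Units assigned
#' to parcel 0 are excluded.
#'
#' @param table an [activity_table] in vertex (or voxel) space.
#' @param assignment a [parcel_assignment] covering the table's units.
#' @return an [activity_table] in `cortex_parcel` space with unit ids
#'   `"p<id>"`.
#' @export
average_into_parcels <- function(table, assignment) {
  stopifnot(inherits(table, "activity_table"),
            inherits(assignment, "parcel_assignment"))
  idx <- match(unit_ids(table), assignment$unit_ids)
  parcel_of <- assignment$parcel_id_per_unit[idx]   # NA where unit unknown
  keep <- !is.na(parcel_of) & parcel_of > 0L
  if (!any(keep)) {
    stop("no table unit has a nonzero parcel assignment")
  }
  parcels <- sort(unique(parcel_of[keep]))
  means <- vapply(parcels, function(p) {
    rowMeans(table[, keep & parcel_of == p, drop = FALSE])
  }, numeric(nrow(table)))
  means <- matrix(means, nrow = nrow(table),
                  dimnames = list(rownames(table), paste0("p", parcels)))
  retable(means, table, space = "cortex_parcel")
}

#' Append the resting baseline as a row of zeros
#'
#' Rest is not modeled explicitly in first-level analyses; it enters the
#' connectivity analysis as an implicit zero-activity condition, appended as
#' a row of zeros to both cortical and cerebellar tables. This anchors the
#' prediction-to-observation regression at the origin.
#'
#' @param table an [activity_table].
#' @param rest_label label for the appended row (must not already exist).
#' @return the table with one extra all-zero row.
#' @seealso [remove_rest_baseline()]
#' @export
append_rest_baseline <- function(table, rest_label = "rest") {
  stopifnot(inherits(table, "activity_table"))
  if (rest_label %in% condition_labels(table)) {
    stop("condition label '", rest_label, "' already present")
  }
  values <- rbind(unclass(table), matrix(0, 1L, ncol(table)))
  retable(values, table,
          condition_labels = c(condition_labels(table), rest_label))
}

#' Drop a previously appended rest row
#' @param table an [activity_table].
#' @param rest_label label of the row to drop.
#' @return the table without that row.
#' @export
remove_rest_baseline <- function(table, rest_label = "rest") {
  stopifnot(inherits(table, "activity_table"))
  i <- match(rest_label, condition_labels(table))
  if (is.na(i)) stop("no condition labelled '", rest_label, "'")
  retable(unclass(table)[-i, , drop = FALSE], table)
}

#' Cerebellar region-of-interest mask
#'
#' @param roi_name name of the region (e.g. `"M3_right"`, `"D3_right"`).
#' @param unit_ids character vector of member unit ids (unique, nonempty).
#' @return list of class `roi_mask`.
#' @export
roi_mask <- function(roi_name, unit_ids) {
  unit_ids <- as.character(unit_ids)
  if (length(unit_ids) == 0L) stop("ROI '", roi_name, "' has no members")
  if (anyDuplicated(unit_ids)) stop("ROI members must be unique")
  structure(list(roi_name = as.character(roi_name), unit_ids = unit_ids),
            class = "roi_mask")
}

#' Mean activity profile over an ROI
#'
#' Averages the table's columns over the ROI members, giving one value per
#' condition: the observed (or predicted) regional activity profile.
#'
#' @param table an [activity_table] whose units cover the ROI.
#' @param roi a [roi_mask].
#' @return named numeric vector, one mean per condition.
#' @export
extract_roi_profile <- function(table, roi) {
  stopifnot(inherits(table, "activity_table"), inherits(roi, "roi_mask"))
  missing <- setdiff(roi$unit_ids, unit_ids(table))
  if (length(missing)) {
    stop("ROI '", roi$roi_name, "' members missing from table: ",
         paste(missing, collapse = ", "))
  }
  rowMeans(table[, roi$unit_ids, drop = FALSE])
}
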