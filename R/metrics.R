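check_geometry <- function(pred, gt) {
  stopifnot(inherits(pred, "binary_mask"), inherits(gt, "binary_mask"))
  if (!identical(dim(pred$voxels), dim(gt$voxels)))
    stop_segrank("segrank_geometry_error",
                 paste0("mask shapes differ: ",
                        paste(dim(pred$voxels), collapse = "x"), " vs ",
                        paste(dim(gt$voxels), collapse = "x")))
  if (!spacing_equal(pred$spacing, gt$spacing))
    stop_segrank("segrank_geometry_error",
                 paste0("mask spacings differ: ",
                        paste(format(pred$spacing), collapse = "x"), " vs ",
                        paste(format(gt$spacing), collapse = "x")))
  invisible(TRUE)
}

#' Dice similarity coefficient on 3D masks
#'
#' Computes `2|P n G| / (|P| + |G|)`. When both masks are empty the value
#' is undefined (0/0) and, following the benchmark's rule, 0 is returned.
#'
#' @param pred,gt [binary_mask] objects with identical shape and spacing.
#' @return A number in \[0, 1\].
#' @examples
#' a <- binary_mask(array(TRUE, c(2, 2, 2)))
#' dice_coefficient(a, a)
#' @export
dice_coefficient <- function(pred, gt) {
  check_geometry(pred, gt)
  np <- sum(pred$voxels)
  ng <- sum(gt$voxels)
  if (np + ng == 0L) return(0)
  2 * sum(pred$voxels & gt$voxels) / (np + ng)
}

# Logical array marking mask voxels with at least one 6-neighbour outside
# the mask; the grid border counts as background.
boundary_array <- function(m) {
  d <- dim(m)
  inside <- m
  for (ax in 1:3) {
    n <- d[ax]
    idx_lo <- c(1L, seq_len(n - 1L))   # neighbour at -1 (replicate edge -> fix below)
    idx_hi <- c(seq_len(n - 1L) + 1L, n)
    lo <- slice_index(m, ax, idx_lo)
    hi <- slice_index(m, ax, idx_hi)
    # out-of-grid is background: force the border slices to FALSE neighbours
    lo <- set_border_false(lo, ax, 1L)
    hi <- set_border_false(hi, ax, n)
    inside <- inside & lo & hi
  }
  m & !inside
}

slice_index <- function(m, ax, idx) {
  switch(ax, m[idx, , , drop = FALSE], m[, idx, , drop = FALSE],
         m[, , idx, drop = FALSE])
}

set_border_false <- function(m, ax, at) {
  switch(ax,
         { m[at, , ] <- FALSE; m },
         { m[, at, ] <- FALSE; m },
         { m[, , at] <- FALSE; m })
}

#' Boundary voxels of a binary mask
#'
#' A mask voxel is a boundary voxel when at least one of its six
#' face-neighbours lies outside the mask; voxels on the grid edge count as
#' boundary (outside the grid is background).
#'
#' @param mask a [binary_mask].
#' @return Integer matrix of voxel coordinates (one row per boundary voxel,
#'   columns x/y/z); zero rows for an empty mask.
#' @export
boundary_voxels <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  which(boundary_array(mask$voxels), arr.ind = TRUE)
}

# Squared Euclidean distance (mm^2) from every voxel centre to the nearest
# TRUE voxel centre of `feature`, with anisotropic spacing.
distance_sq_to <- function(feature, spacing) {
  .edt3d_sq(as.logical(feature), as.integer(dim(feature)), as.numeric(spacing))
}

#' Normalized surface dice (NSD) with tolerance
#'
#' The boundary voxel sets of prediction and ground truth are compared:
#' the NSD is the fraction of boundary voxels of either mask lying within
#' `tolerance_mm` (Euclidean distance between voxel centres, scaled by the
#' voxel spacing) of the other mask's boundary,
#' `(|{p : d(p, S_G) <= t}| + |{g : d(g, S_P) <= t}|) / (|S_P| + |S_G|)`.
#' The tolerance expresses the clinically acceptable boundary error. If
#' both boundaries are empty the value is undefined and 0 is returned; if
#' exactly one is empty no surface can be matched and the value is 0.
#'
#' Surfaces are represented as boundary voxel centres (6-connectivity),
#' not area-weighted mesh elements; distances come from an exact
#' anisotropic Euclidean distance transform and are compared to the
#' tolerance on squared values, so results are reproducible to the last
#' bit against a brute-force pairwise computation.
#'
#' @param pred,gt [binary_mask] objects with identical shape and spacing.
#' @param tolerance_mm non-negative tolerance in mm.
#' @return A number in \[0, 1\].
#' @examples
#' cube <- array(FALSE, c(4, 4, 4)); cube[1:2, 1:2, 1:2] <- TRUE
#' shifted <- array(FALSE, c(4, 4, 4)); shifted[2:3, 1:2, 1:2] <- TRUE
#' surface_dice(binary_mask(cube), binary_mask(shifted), tolerance_mm = 1)
#' surface_dice(binary_mask(cube), binary_mask(shifted), tolerance_mm = 0.5)
#' @export
surface_dice <- function(pred, gt, tolerance_mm) {
  check_geometry(pred, gt)
  tolerance_mm <- as.numeric(tolerance_mm)
  if (length(tolerance_mm) != 1L || !is.finite(tolerance_mm) || tolerance_mm < 0)
    stop_segrank("segrank_config_error", "tolerance_mm must be a single number >= 0")
  bp <- boundary_array(pred$voxels)
  bg <- boundary_array(gt$voxels)
  np <- sum(bp)
  ng <- sum(bg)
  if (np == 0L && ng == 0L) return(0)
  if (np == 0L || ng == 0L) return(0)
  tol2 <- tolerance_mm^2
  dg <- distance_sq_to(bg, gt$spacing)
  dp <- distance_sq_to(bp, pred$spacing)
  (sum(dg[bp] <= tol2) + sum(dp[bg] <= tol2)) / (np + ng)
}

#' Evaluate one case: all ROIs, both metrics
#'
#' For every ROI in the task specification, computes DSC and NSD (at the
#' task's tolerance) between the predicted and ground-truth label volumes,
#' yielding `2 * length(rois)` records. ROIs absent from both volumes get
#' value 0 for both metrics (the undefined-metric rule); geometry
#' mismatches are an error rather than a silent zero, since silently
#' zeroed cases would corrupt downstream rankings.
#'
#' @param pred,gt [label_volume] objects sharing shape and spacing.
#' @param spec a [task_spec].
#' @param team,case identifiers recorded in the output.
#' @return A `data.frame` with columns `team`, `task`, `case`, `roi`,
#'   `metric`, `value`.
#' @export
evaluate_case <- function(pred, gt, spec, team, case) {
  stopifnot(inherits(pred, "label_volume"), inherits(gt, "label_volume"),
            inherits(spec, "task_spec"))
  if (!identical(dim(pred$voxels), dim(gt$voxels)) ||
      !spacing_equal(pred$spacing, gt$spacing))
    stop_segrank("segrank_geometry_error",
                 paste0("case '", case, "' (team '", team,
                        "'): prediction and ground truth geometry differ"))
  rows <- lapply(seq_along(spec$rois), function(i) {
    lab <- spec$rois[[i]]
    roi <- names(spec$rois)[i]
    pm <- extract_roi_mask(pred, lab)
    gm <- extract_roi_mask(gt, lab)
    data.frame(team = team, task = spec$name, case = case, roi = roi,
               metric = c("DSC", "NSD"),
               value = c(dice_coefficient(pm, gm),
                         surface_dice(pm, gm, spec$tolerance_mm)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Per-case metric tables
#'
#' Validates a data frame of per-case metric records (columns `team`,
#' `task`, `case`, `roi`, `metric`, `value`) as a complete block design:
#' every team must have exactly one value for every (task, case, roi,
#' metric) combination present in the table, as required for paired
#' significance testing.
#'
#' @param records data frame of metric records.
#' @return The validated table, classed `metric_table`.
#' @export
metric_table <- function(records) {
  need <- c("team", "task", "case", "roi", "metric", "value")
  if (!is.data.frame(records) || !all(need %in% names(records)))
    stop_segrank("segrank_format_error",
                 paste0("metric table needs columns: ", paste(need, collapse = ", ")))
  records <- as.data.frame(records)[need]
  for (col in need[1:5]) records[[col]] <- as.character(records[[col]])
  records$value <- as.numeric(records$value)
  if (any(!is.finite(records$value)) ||
      any(records$value < -1e-12) || any(records$value > 1 + 1e-12))
    stop_segrank("segrank_format_error", "metric values must lie in [0, 1]")
  records$value <- pmin(pmax(records$value, 0), 1)
  unit <- paste(records$task, records$case, records$roi, records$metric, sep = "\r")
  key <- paste(records$team, unit, sep = "\r")
  if (anyDuplicated(key))
    stop_segrank("segrank_format_error",
                 "duplicate (team, task, case, roi, metric) records")
  teams <- unique(records$team)
  tab <- table(unit)
  if (any(tab != length(teams))) {
    bad <- names(tab)[tab != length(teams)]
    miss <- vapply(bad[seq_len(min(5L, length(bad)))],
                   function(u) gsub("\r", "/", u), character(1))
    stop_segrank("segrank_data_error",
                 paste0("incomplete block: not every team scored on every ",
                        "(task, case, roi, metric); e.g. ",
                        paste(miss, collapse = "; ")))
  }
  records <- records[order(records$team, records$task, records$case,
                           records$roi, records$metric), , drop = FALSE]
  rownames(records) <- NULL
  class(records) <- c("metric_table", "data.frame")
  records
}

#' @export
print.metric_table <- function(x, ...) {
  cat("<metric_table> ", length(unique(x$team)), " teams, ",
      length(unique(x$task)), " tasks, ", nrow(x), " records\n", sep = "")
  NextMethod()
}

#' Write / read a metric table CSV
#'
#' Rows are sorted team, task, case, roi, metric so output is
#' deterministic; values use `'.'` as the decimal separator.
#'
#' @param table a [metric_table].
#' @param path CSV path.
#' @return `path` (write) or the validated [metric_table] (read).
#' @export
write_metric_table <- function(table, path) {
  table <- metric_table(table)
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_metric_table
#' @export
read_metric_table <- function(path) {
  if (!file.exists(path))
    stop_segrank("segrank_data_error", paste0("metric table not found: ", path))
  metric_table(utils::read.csv(path, stringsAsFactors = FALSE,
                               colClasses = c(value = "numeric")))
}
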