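#' Label volumes
#'
#' A label volume is a 3D grid of non-negative integer label IDs together
#' with the physical edge lengths of a voxel in mm. Volumes read from disk
#' are reoriented (by axis permutation and flips only, never resampling)
#' into the closest right-anterior-superior (RAS) frame, so that voxel
#' grids from different files are comparable.
#'
#' @param voxels 3D array of non-negative integers (label IDs; 0 = background).
#' @param spacing numeric triple, voxel edge lengths in mm (all > 0).
#' @return An object of class `label_volume` with elements `voxels`
#'   (integer 3D array), `spacing` and `orientation` (always `"RAS"`).
#' @examples
#' v <- label_volume(array(0L, c(4, 4, 4)), spacing = c(1, 1, 2))
#' dim(v$voxels)
#' @export
label_volume <- function(voxels, spacing = c(1, 1, 1)) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop_segrank("segrank_format_error", "voxels must be a 3D array")
  if (any(dim(voxels) < 1L))
    stop_segrank("segrank_format_error", "volume must have at least one voxel per axis")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop_segrank("segrank_format_error", "spacing must be three positive values (mm)")
  voxels <- check_integer_labels(voxels)
  structure(list(voxels = voxels, spacing = spacing, orientation = "RAS"),
            class = "label_volume")
}

# Values within 1e-6 of an integer are rounded; anything else is rejected
# (guards against lossy-compressed or interpolated label maps).
check_integer_labels <- function(voxels, tol = 1e-6) {
  v <- as.numeric(voxels)
  r <- round(v)
  if (any(!is.finite(v)) || any(abs(v - r) > tol))
    stop_segrank("segrank_format_error",
                 "volume contains non-integer voxel values; not a label map")
  if (any(r < 0))
    stop_segrank("segrank_format_error", "label values must be >= 0")
  out <- array(as.integer(r), dim(voxels))
  out
}

#' @export
print.label_volume <- function(x, ...) {
  labs <- sort(unique(as.vector(x$voxels)))
  cat("<label_volume> ", paste(dim(x$voxels), collapse = "x"),
      " voxels, spacing ", paste(format(x$spacing), collapse = "x"),
      " mm (", x$orientation, ")\n", sep = "")
  cat("  labels present:", paste(labs, collapse = ", "), "\n")
  invisible(x)
}

#' Read a NIfTI label volume, reoriented to RAS
#'
#' Reads a `.nii`/`.nii.gz` file and reorders the data grid into the
#' closest-to-RAS frame determined from the dominant direction cosines of
#' the image affine. Reorientation is a pure axis permutation plus flips;
#' the data are never resampled, so label counts are preserved exactly.
#' Voxel spacing is taken from the affine and reported in the RAS axis
#' order.
#'
#' @param path path to a NIfTI file with integer-valued data.
#' @return A [label_volume].
#' @export
read_label_volume <- function(path) {
  if (!file.exists(path))
    stop_segrank("segrank_data_error", paste0("file not found: ", path))
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) > 3L) {
    if (all(d[-(1:3)] == 1L)) {
      dim(img) <- d[1:3]
      img <- RNifti::asNifti(img)
    } else {
      stop_segrank("segrank_format_error",
                   paste0("expected a 3D volume, got dims ",
                          paste(d, collapse = "x"), ": ", path))
    }
  }
  ori <- RNifti::orientation(img)
  ch <- strsplit(ori, "")[[1]]
  valid <- length(ch) == 3L && any(ch %in% c("R", "L")) &&
    any(ch %in% c("A", "P")) && any(ch %in% c("S", "I"))
  if (!valid)
    stop_segrank("segrank_orientation_error",
                 paste0("missing or degenerate affine (orientation '", ori,
                        "'): ", path))
  if (ori != "RAS") RNifti::orientation(img) <- "RAS"
  xf <- RNifti::xform(img)
  spacing <- sqrt(colSums(xf[1:3, 1:3]^2))
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop_segrank("segrank_orientation_error",
                 paste0("degenerate affine (zero-length axis): ", path))
  label_volume(as.array(img), spacing = spacing)
}

#' Write a label volume to NIfTI
#'
#' @param volume a [label_volume].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_label_volume <- function(volume, path) {
  stopifnot(inherits(volume, "label_volume"))
  img <- RNifti::asNifti(volume$voxels)
  RNifti::pixdim(img) <- volume$spacing
  RNifti::writeNifti(img, path, datatype = "int16")
  invisible(path)
}

#' Binary region-of-interest masks
#'
#' @param voxels 3D logical array.
#' @param spacing numeric triple in mm.
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(voxels, spacing = c(1, 1, 1)) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop_segrank("segrank_format_error", "mask voxels must be a 3D array")
  storage.mode(voxels) <- "logical"
  if (any(is.na(voxels)))
    stop_segrank("segrank_format_error", "mask contains missing values")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop_segrank("segrank_format_error", "spacing must be three positive values (mm)")
  structure(list(voxels = voxels, spacing = spacing), class = "binary_mask")
}

#' Extract the binary mask of one ROI label
#'
#' @param volume a [label_volume].
#' @param label integer label ID (>= 1; the background label 0 is refused
#'   unless `allow_background = TRUE`).
#' @param allow_background permit extracting the background (label 0) mask.
#' @return A [binary_mask] with the same shape and spacing as `volume`.
#'   An absent label yields a legal all-`FALSE` mask.
#' @export
extract_roi_mask <- function(volume, label, allow_background = FALSE) {
  stopifnot(inherits(volume, "label_volume"))
  label <- as.integer(label)
  if (length(label) != 1L || is.na(label) || label < 0L)
    stop_segrank("segrank_config_error", "label must be a single non-negative integer")
  if (label == 0L && !allow_background)
    stop_segrank("segrank_config_error",
                 "label 0 is background; set allow_background = TRUE to extract it")
  binary_mask(volume$voxels == label, volume$spacing)
}

#' Robust min-max intensity scaling
#'
#' Clips an image to the `lower_pct`/`upper_pct` percentiles and affinely
#' maps that range to \[0, 1\]. Used to bring non-quantitative modalities
#' (e.g. MRI) to a common range; percentile defaults are configurable.
#'
#' @param image numeric array (any shape).
#' @param lower_pct,upper_pct percentiles in \[0, 100\], `upper_pct > lower_pct`.
#' @return Array of the same shape with values in \[0, 1\].
#' @export
robust_minmax_scale <- function(image, lower_pct = 0.5, upper_pct = 99.5) {
  if (!is.numeric(image))
    stop_segrank("segrank_format_error", "image must be numeric")
  if (!(upper_pct > lower_pct))
    stop_segrank("segrank_config_error", "upper_pct must exceed lower_pct")
  qs <- stats::quantile(image, c(lower_pct, upper_pct) / 100,
                        names = FALSE, type = 7, na.rm = FALSE)
  if (qs[2] - qs[1] <= 0)
    stop_segrank("segrank_format_error",
                 "degenerate intensity range (constant image?)")
  out <- (pmin(pmax(image, qs[1]), qs[2]) - qs[1]) / (qs[2] - qs[1])
  if (!is.null(dim(image))) dim(out) <- dim(image)
  out
}

#' Task specifications
#'
#' A task couples a named set of ROI labels with the task-level NSD
#' tolerance (mm) chosen by the annotating clinicians as the acceptable
#' boundary error, and the challenge phase the task belongs to.
#'
#' @param name task identifier.
#' @param phase `"development"` or `"mystery"`.
#' @param rois named integer vector: values are label IDs (> 0, distinct),
#'   names are ROI names (1-3 entries).
#' @param tolerance_mm positive NSD tolerance in mm (single value per task).
#' @return An object of class `task_spec`.
#' @examples
#' task_spec("Spleen", "mystery", c(spleen = 1), tolerance_mm = 3)
#' @export
task_spec <- function(name, phase, rois, tolerance_mm) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop_segrank("segrank_config_error", "task name must be a non-empty string")
  if (!phase %in% c("development", "mystery"))
    stop_segrank("segrank_config_error",
                 paste0("task '", name, "': phase must be 'development' or 'mystery'"))
  rois <- structure(as.integer(rois), names = names(rois))
  if (length(rois) < 1L || is.null(names(rois)) || any(!nzchar(names(rois))))
    stop_segrank("segrank_config_error",
                 paste0("task '", name, "': rois must be a non-empty named vector"))
  if (any(is.na(rois)) || any(rois <= 0L) || anyDuplicated(rois))
    stop_segrank("segrank_config_error",
                 paste0("task '", name, "': ROI label IDs must be distinct positive integers"))
  tolerance_mm <- as.numeric(tolerance_mm)
  if (length(tolerance_mm) != 1L || !is.finite(tolerance_mm) || tolerance_mm <= 0)
    stop_segrank("segrank_config_error",
                 paste0("task '", name, "': tolerance_mm must be a single positive number"))
  structure(list(name = name, phase = phase, rois = rois,
                 tolerance_mm = tolerance_mm),
            class = "task_spec")
}

#' @export
print.task_spec <- function(x, ...) {
  cat("<task_spec> ", x$name, " (", x$phase, "), NSD tolerance ",
      x$tolerance_mm, " mm\n  ROIs: ",
      paste0(names(x$rois), " (label ", x$rois, ")", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Load task specifications from a YAML or JSON config file
#'
#' The config is a list of entries with fields `name`, `phase`,
#' `tolerance_mm` and `rois` (a list of `{label, name}` pairs). Files
#' ending in `.json` are parsed as JSON, anything else as YAML.
#'
#' @param path config file path.
#' @return A named list of [task_spec] objects (names = task names).
#' @seealso [benchmark_task_specs()] for the packaged ten-task default.
#' @export
load_task_config <- function(path) {
  if (!file.exists(path))
    stop_segrank("segrank_config_error", paste0("config file not found: ", path))
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.null(raw$tasks)) raw <- raw$tasks
  if (!is.list(raw) || length(raw) == 0L)
    stop_segrank("segrank_config_error",
                 paste0(path, ": expected a non-empty list of tasks"))
  specs <- lapply(seq_along(raw), function(i) {
    entry <- raw[[i]]
    where <- paste0(path, ": tasks[", i, "]")
    for (fld in c("name", "phase", "rois", "tolerance_mm"))
      if (is.null(entry[[fld]]))
        stop_segrank("segrank_config_error", paste0(where, ": missing field '", fld, "'"))
    rois <- entry$rois
    labels <- vapply(rois, function(r) {
      if (is.null(r$label) || is.null(r$name))
        stop_segrank("segrank_config_error",
                     paste0(where, ".rois: each ROI needs 'label' and 'name'"))
      as.integer(r$label)
    }, integer(1))
    names(labels) <- vapply(rois, function(r) as.character(r$name), character(1))
    task_spec(entry$name, entry$phase, labels, entry$tolerance_mm)
  })
  names(specs) <- vapply(specs, function(s) s$name, character(1))
  if (anyDuplicated(names(specs)))
    stop_segrank("segrank_config_error",
                 paste0(path, ": duplicate task names: ",
                        paste(unique(names(specs)[duplicated(names(specs))]),
                              collapse = ", ")))
  specs
}

#' The ten-task benchmark configuration
#'
#' Packaged defaults for the ten-task multi-organ benchmark: seven
#' development-phase tasks (brain, heart, hippocampus, liver, lung,
#' pancreas, prostate) and three mystery-phase tasks (colon, hepatic
#' vessel, spleen), with the clinician-chosen NSD tolerances in mm
#' (Brain 5, Heart 4, Hippocampus 1, Liver 7, Lung 2, Prostate 4,
#' Pancreas 5, Colon 4, Hepatic vessel 3, Spleen 3).
#'
#' @return A named list of [task_spec] objects.
#' @examples
#' benchmark_task_specs()[["Spleen"]]
#' @export
benchmark_task_specs <- function() {
  load_task_config(system.file("extdata", "benchmark_tasks.yaml",
                               package = "segrank", mustWork = TRUE))
}

# phase lookup (task name -> phase) from a spec list, or NULL
task_phase_map <- function(task_specs) {
  if (is.null(task_specs)) return(NULL)
  structure(vapply(task_specs, function(s) s$phase, character(1)),
            names = vapply(task_specs, function(s) s$name, character(1)))
}
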