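#' Team quality profiles for synthetic cohorts
#'
#' A profile controls both volume-space degradation (applied by
#' [perturb_prediction()]) and direct metric simulation (used by
#' [simulate_metric_table()]): positive `dilate_erode_radius` dilates the
#' predicted ROI, negative erodes; `shift_voxels` translates it;
#' `boundary_flip_prob` randomly toggles voxels on either side of the ROI
#' boundary; `miss_prob` drops the ROI entirely; `beta_mean`/`beta_sd`
#' parameterise the Beta distribution of directly simulated per-case
#' metric values (higher mean = better team).
#'
#' @param team team identifier.
#' @param dilate_erode_radius signed radius in voxels (+ dilate, - erode).
#' @param shift_voxels integer triple, translation in voxels.
#' @param boundary_flip_prob,miss_prob probabilities in \[0, 1\].
#' @param beta_mean mean of simulated metric values, in (0, 1).
#' @param beta_sd standard deviation; capped at the feasibility bound
#'   `sqrt(mean * (1 - mean))` of the Beta family.
#' @return An object of class `team_profile`.
#' @export
team_profile <- function(team, dilate_erode_radius = 0,
                         shift_voxels = c(0L, 0L, 0L),
                         boundary_flip_prob = 0, miss_prob = 0,
                         beta_mean = 0.8, beta_sd = 0.1) {
  if (!is.character(team) || length(team) != 1L || !nzchar(team))
    stop_segrank("segrank_config_error", "team must be a non-empty string")
  shift_voxels <- as.integer(shift_voxels)
  if (length(shift_voxels) != 3L || any(is.na(shift_voxels)))
    stop_segrank("segrank_config_error", "shift_voxels must be an integer triple")
  for (p in c(boundary_flip_prob, miss_prob))
    if (!is.finite(p) || p < 0 || p > 1)
      stop_segrank("segrank_config_error", "probabilities must lie in [0, 1]")
  if (!is.finite(beta_mean) || beta_mean <= 0 || beta_mean >= 1)
    stop_segrank("segrank_config_error", "beta_mean must lie in (0, 1)")
  if (!is.finite(beta_sd) || beta_sd <= 0)
    stop_segrank("segrank_config_error", "beta_sd must be positive")
  structure(list(team = team,
                 dilate_erode_radius = as.numeric(dilate_erode_radius),
                 shift_voxels = shift_voxels,
                 boundary_flip_prob = boundary_flip_prob,
                 miss_prob = miss_prob,
                 beta_mean = beta_mean, beta_sd = beta_sd),
            class = "team_profile")
}

# Beta(mean, sd) -> shape parameters, with sd capped just inside the
# feasibility bound sd^2 < mean*(1-mean).
beta_shapes <- function(mean, sd) {
  bound <- sqrt(mean * (1 - mean))
  sd <- min(sd, 0.95 * bound)
  v <- sd^2
  k <- mean * (1 - mean) / v - 1
  c(shape1 = mean * k, shape2 = (1 - mean) * k)
}

#' Synthetic cohort configuration
#'
#' @param tasks list of [task_spec] objects.
#' @param n_cases cases per task (single value or one per task).
#' @param teams list of [team_profile] objects (>= 2, distinct names).
#' @param seed integer seed driving all generation.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(tasks, n_cases, teams, seed) {
  if (!is.list(tasks) || length(tasks) < 1L ||
      !all(vapply(tasks, inherits, logical(1), "task_spec")))
    stop_segrank("segrank_config_error", "tasks must be a list of task_spec objects")
  names(tasks) <- vapply(tasks, function(t) t$name, character(1))
  if (anyDuplicated(names(tasks)))
    stop_segrank("segrank_config_error", "duplicate task names")
  n_cases <- as.integer(rep(n_cases, length.out = length(tasks)))
  if (any(is.na(n_cases)) || any(n_cases < 1L))
    stop_segrank("segrank_config_error", "n_cases must be >= 1")
  if (!is.list(teams) || length(teams) < 2L ||
      !all(vapply(teams, inherits, logical(1), "team_profile")))
    stop_segrank("segrank_config_error",
                 "teams must be a list of >= 2 team_profile objects")
  names(teams) <- vapply(teams, function(t) t$team, character(1))
  if (anyDuplicated(names(teams)))
    stop_segrank("segrank_config_error", "team identifiers must be distinct")
  structure(list(tasks = tasks, n_cases = n_cases, teams = teams,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

# ellipsoid mask centred at `centre` with semi-axes `radii` (voxel units)
ellipsoid_mask <- function(shape, centre, radii) {
  x <- (seq_len(shape[1]) - centre[1]) / radii[1]
  y <- (seq_len(shape[2]) - centre[2]) / radii[2]
  z <- (seq_len(shape[3]) - centre[3]) / radii[3]
  outer(outer(x^2, y^2, `+`), z^2, `+`) <= 1
}

#' Generate a phantom ground-truth label volume
#'
#' Places one randomly sized and positioned ellipsoid per ROI of the task
#' specification, pairwise non-overlapping, on an empty grid. Phantoms
#' carry none of the intensity or anatomical structure of real scans:
#' the evaluation pipeline consumes only label overlaps and surfaces, so
#' ellipsoids exercise exactly the code paths that matter.
#'
#' @param shape integer triple, grid size (each axis >= 12 recommended).
#' @param spacing voxel spacing in mm.
#' @param spec a [task_spec]; one ellipsoid per entry of `spec$rois`.
#' @param seed integer seed (same seed, same volume).
#' @param max_retries placement attempts per ROI before giving up.
#' @return A [label_volume].
#' @export
generate_phantom_gt <- function(shape, spacing, spec, seed, max_retries = 200L) {
  stopifnot(inherits(spec, "task_spec"))
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 8L))
    stop_segrank("segrank_config_error", "shape must be an integer triple, each >= 8")
  local_seed(seed, {
    vox <- array(0L, shape)
    for (i in seq_along(spec$rois)) {
      lab <- spec$rois[[i]]
      placed <- FALSE
      for (try in seq_len(max_retries)) {
        radii <- pmax(2, stats::runif(3, shape / 10, shape / 5))
        lo <- radii + 1
        hi <- shape - radii
        if (any(hi <= lo)) next
        centre <- stats::runif(3, lo, hi)
        mask <- ellipsoid_mask(shape, centre, radii)
        if (!any(mask & vox != 0L)) {
          vox[mask] <- lab
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stop_segrank("segrank_placement_error",
                     paste0("could not place non-overlapping ROI '",
                            names(spec$rois)[i], "' after ", max_retries,
                            " attempts; enlarge the grid"))
    }
    label_volume(vox, spacing)
  })
}

# morphological dilation/erosion by Euclidean radius r (voxel units)
dilate_mask <- function(m, r) {
  if (!any(m)) return(m)
  d2 <- .edt3d_sq(as.logical(m), as.integer(dim(m)), c(1, 1, 1))
  array(d2 <= r^2, dim(m))
}
erode_mask <- function(m, r) {
  if (!any(m)) return(m)
  d2 <- .edt3d_sq(as.logical(!m), as.integer(dim(m)), c(1, 1, 1))
  array(m & d2 > r^2, dim(m))
}

shift_mask <- function(m, shift) {
  out <- array(FALSE, dim(m))
  d <- dim(m)
  src <- dst <- vector("list", 3)
  for (ax in 1:3) {
    s <- shift[ax]
    src[[ax]] <- seq_len(d[ax]) - s
    keep <- src[[ax]] >= 1L & src[[ax]] <= d[ax]
    dst[[ax]] <- seq_len(d[ax])[keep]
    src[[ax]] <- src[[ax]][keep]
    if (length(src[[ax]]) == 0L) return(out)
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- m[src[[1]], src[[2]], src[[3]]]
  out
}

#' Degrade a ground truth into a simulated team prediction
#'
#' Applies the profile's perturbations per ROI: with probability
#' `miss_prob` the ROI is dropped entirely; otherwise it is translated by
#' `shift_voxels`, dilated (radius > 0) or eroded (radius < 0), and
#' voxels on the inner/outer boundary are flipped with
#' `boundary_flip_prob`. Perturbed ROIs are written back in label order
#' (later labels overwrite earlier ones where perturbations collide).
#' Deterministic in `seed`.
#'
#' @param gt a [label_volume] ground truth.
#' @param profile a [team_profile].
#' @param seed integer seed.
#' @return A [label_volume] prediction with the same geometry.
#' @export
perturb_prediction <- function(gt, profile, seed) {
  stopifnot(inherits(gt, "label_volume"), inherits(profile, "team_profile"))
  local_seed(seed, {
    labs <- sort(setdiff(unique(as.vector(gt$voxels)), 0L))
    out <- array(0L, dim(gt$voxels))
    for (lab in labs) {
      if (stats::runif(1) < profile$miss_prob) next
      m <- gt$voxels == lab
      if (any(profile$shift_voxels != 0L))
        m <- shift_mask(m, profile$shift_voxels)
      r <- profile$dilate_erode_radius
      if (r > 0) m <- dilate_mask(m, r)
      if (r < 0) m <- erode_mask(m, abs(r))
      p <- profile$boundary_flip_prob
      if (p > 0 && any(m)) {
        inner <- boundary_array(m)
        outer_shell <- dilate_mask(m, 1) & !m
        drop <- inner & array(stats::runif(length(m)) < p, dim(m))
        add <- outer_shell & array(stats::runif(length(m)) < p, dim(m))
        m <- (m & !drop) | add
      }
      out[m] <- lab
    }
    label_volume(out, gt$spacing)
  })
}

#' Simulate a per-case metric table with known quality ordering
#'
#' Bypasses volumes entirely: every (team, task, case, ROI, metric) value
#' is drawn independently from a Beta distribution with the team's
#' `beta_mean`/`beta_sd`, so the true quality ordering is the descending
#' order of `beta_mean`. Always yields a complete block; deterministic in
#' the config's seed.
#'
#' @param config a [cohort_config].
#' @param metrics metric names to simulate (default DSC and NSD).
#' @return A [metric_table].
#' @export
simulate_metric_table <- function(config, metrics = c("DSC", "NSD")) {
  stopifnot(inherits(config, "cohort_config"))
  local_seed(config$seed, {
    rows <- list()
    for (ti in seq_along(config$tasks)) {
      spec <- config$tasks[[ti]]
      cases <- sprintf("case%03d", seq_len(config$n_cases[ti]))
      for (team in names(config$teams)) {
        pr <- config$teams[[team]]
        sh <- beta_shapes(pr$beta_mean, pr$beta_sd)
        n <- length(cases) * length(spec$rois) * length(metrics)
        vals <- stats::rbeta(n, sh[1], sh[2])
        grid <- expand.grid(metric = metrics, roi = names(spec$rois),
                            case = cases, stringsAsFactors = FALSE)
        rows[[length(rows) + 1L]] <-
          data.frame(team = team, task = spec$name, case = grid$case,
                     roi = grid$roi, metric = grid$metric,
                     value = pmin(pmax(vals, 0), 1),
                     stringsAsFactors = FALSE)
      }
    }
    metric_table(do.call(rbind, rows))
  })
}

#' Write a synthetic cohort of NIfTI volumes to disk
#'
#' Generates phantom ground truths and per-team perturbed predictions and
#' writes them in the directory layout the batch evaluator reads:
#' `<out_dir>/gt/<task>/<case>.nii.gz` and
#' `<out_dir>/submissions/<team>/<task>/<case>.nii.gz`, plus the cohort
#' parameters as `cohort.yaml`.
#'
#' @param config a [cohort_config].
#' @param out_dir output directory (created if needed).
#' @param shape,spacing phantom grid size and voxel spacing.
#' @return Invisibly, a list with `gt_dir`, `pred_dir` and `config_path`.
#' @export
simulate_cohort <- function(config, out_dir, shape = c(24L, 24L, 24L),
                            spacing = c(1, 1, 1)) {
  stopifnot(inherits(config, "cohort_config"))
  gt_dir <- file.path(out_dir, "gt")
  pred_dir <- file.path(out_dir, "submissions")
  for (ti in seq_along(config$tasks)) {
    spec <- config$tasks[[ti]]
    dir.create(file.path(gt_dir, spec$name), recursive = TRUE,
               showWarnings = FALSE)
    for (ci in seq_len(config$n_cases[ti])) {
      case <- sprintf("case%03d", ci)
      gt_seed <- (config$seed + 1000L * ti + ci) %% .Machine$integer.max
      gt <- generate_phantom_gt(shape, spacing, spec, seed = gt_seed)
      write_label_volume(gt, file.path(gt_dir, spec$name,
                                       paste0(case, ".nii.gz")))
      for (mi in seq_along(config$teams)) {
        pr <- config$teams[[mi]]
        d <- file.path(pred_dir, pr$team, spec$name)
        dir.create(d, recursive = TRUE, showWarnings = FALSE)
        p_seed <- (gt_seed + 7919L * mi) %% .Machine$integer.max
        pred <- perturb_prediction(gt, pr, seed = p_seed)
        write_label_volume(pred, file.path(d, paste0(case, ".nii.gz")))
      }
    }
  }
  cfg <- list(
    seed = config$seed,
    tasks = lapply(unname(config$tasks), function(s)
      list(name = s$name, phase = s$phase, tolerance_mm = s$tolerance_mm,
           rois = lapply(seq_along(s$rois), function(i)
             list(label = unname(s$rois[[i]]), name = names(s$rois)[i])))),
    n_cases = as.list(config$n_cases),
    teams = lapply(unname(config$teams), unclass)
  )
  config_path <- file.path(out_dir, "cohort.yaml")
  yaml::write_yaml(cfg, config_path)
  invisible(list(gt_dir = gt_dir, pred_dir = pred_dir,
                 config_path = config_path))
}
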