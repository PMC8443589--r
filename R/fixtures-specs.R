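#' Synthetic-fixture specifications
#'
#' Constructors for the seeded generator specs.  Each constructor validates
#' its invariants eagerly and errors with the offending field name, so a bad
#' configuration never reaches a generator.  Defaults encode the imaging and
#' dosing protocol the package models: 8 regions of interest per scaffold,
#' 8-12 microtissues per field of view, 120 um z-stacks at a 5 um interval
#' (25 planes), 48 h drug washout from 1 uM.
#'
#' @param grid_rows,grid_cols Tile grid dimensions of the low-magnification
#'   slide scan.
#' @param tile_size_px Side length of each square tile, pixels.
#' @param overlap_frac Fractional overlap between neighbouring tiles, in
#'   `[0, 0.5)`.
#' @param scaffold_centers List of `c(row_px, col_px)` scaffold centres in
#'   mosaic coordinates (0-based pixels).
#' @param scaffold_radius_px Scaffold radius in pixels.
#' @param rois_per_scaffold Number of regions of interest per scaffold.
#' @param roi_template List of `c(d_row, d_col)` pixel offsets from the
#'   scaffold centre, one per ROI.  Default: `rois_per_scaffold` points
#'   equally spaced on a circle at 55% of the scaffold radius.
#' @param fovs_per_scaffold Fields of view imaged per scaffold (one per ROI
#'   by default).
#' @param microtissues_per_fov_range Inclusive `c(min, max)` count of
#'   microtissues rendered per field of view.
#' @param microtissue_radius_px_range Inclusive `c(min, max)` microtissue
#'   core radius, pixels.
#' @param channel_names Ordered channel names.
#' @param background_level Constant background intensity.
#' @param seed Integer seed; identical specs give bit-identical fixtures.
#' @return An object of class `slide_spec`.
#' @seealso [gen_slide()]
#' @export
slide_spec <- function(grid_rows = 2L, grid_cols = 2L, tile_size_px = 192L,
                       overlap_frac = 0.1,
                       scaffold_centers = NULL,
                       scaffold_radius_px = 60,
                       rois_per_scaffold = 8L,
                       roi_template = NULL,
                       fovs_per_scaffold = NULL,
                       microtissues_per_fov_range = c(8L, 12L),
                       microtissue_radius_px_range = c(6, 9),
                       channel_names = c("nuclei", "cytoskeleton",
                                         "asma", "collagen1"),
                       background_level = 200,
                       seed = 1L) {
  if (!is_count(grid_rows) || grid_rows < 1) abort_config("grid_rows", "must be a positive integer")
  if (!is_count(grid_cols) || grid_cols < 1) abort_config("grid_cols", "must be a positive integer")
  if (!is_count(tile_size_px) || tile_size_px < 8) abort_config("tile_size_px", "must be an integer >= 8")
  if (!is_number(overlap_frac) || overlap_frac < 0 || overlap_frac >= 0.5)
    abort_config("overlap_frac", "must lie in [0, 0.5)")
  if (!is_count(rois_per_scaffold) || rois_per_scaffold < 1)
    abort_config("rois_per_scaffold", "must be a positive integer")
  if (is.null(roi_template)) {
    ang <- 2 * pi * (seq_len(rois_per_scaffold) - 1) / rois_per_scaffold
    r <- 0.55 * scaffold_radius_px
    roi_template <- lapply(seq_along(ang),
                           function(i) c(r * sin(ang[i]), r * cos(ang[i])))
  }
  if (length(roi_template) != rois_per_scaffold)
    abort_config("roi_template", sprintf(
      "length (%d) must equal rois_per_scaffold (%d)",
      length(roi_template), rois_per_scaffold))
  fovs_per_scaffold <- fovs_per_scaffold %||% rois_per_scaffold
  rng <- microtissues_per_fov_range
  if (length(rng) != 2L || rng[1] > rng[2])
    abort_config("microtissues_per_fov_range", "must be c(min, max) with min <= max")
  rrng <- microtissue_radius_px_range
  if (length(rrng) != 2L || rrng[1] > rrng[2] || rrng[1] <= 0)
    abort_config("microtissue_radius_px_range", "must be positive c(min, max) with min <= max")
  stride <- round((1 - overlap_frac) * tile_size_px)
  mosaic_dim <- c(stride * (grid_rows - 1) + tile_size_px,
                  stride * (grid_cols - 1) + tile_size_px)
  scaffold_centers <- scaffold_centers %||% list()
  for (i in seq_along(scaffold_centers)) {
    ctr <- scaffold_centers[[i]]
    if (length(ctr) != 2L) abort_config("scaffold_centers", "entries must be c(row_px, col_px)")
    if (any(ctr - scaffold_radius_px < 0) ||
        ctr[1] + scaffold_radius_px > mosaic_dim[1] ||
        ctr[2] + scaffold_radius_px > mosaic_dim[2])
      abort_config("scaffold_centers", sprintf(
        "scaffold %d does not fit inside the %dx%d mosaic", i,
        mosaic_dim[1], mosaic_dim[2]))
  }
  structure(list(
    grid_rows = as.integer(grid_rows), grid_cols = as.integer(grid_cols),
    tile_size_px = as.integer(tile_size_px), overlap_frac = overlap_frac,
    scaffold_centers = scaffold_centers,
    scaffold_radius_px = scaffold_radius_px,
    rois_per_scaffold = as.integer(rois_per_scaffold),
    roi_template = roi_template,
    fovs_per_scaffold = as.integer(fovs_per_scaffold),
    microtissues_per_fov_range = as.integer(round(rng)),
    microtissue_radius_px_range = rrng,
    channel_names = channel_names,
    background_level = background_level,
    stride_px = as.integer(stride),
    mosaic_dim = as.integer(mosaic_dim),
    seed = as.integer(seed)), class = "slide_spec")
}

#' @param n_planes Number of z planes; must satisfy
#'   `(n_planes - 1) * z_step_um == depth_um`.
#' @param z_step_um Slice interval, micrometres.
#' @param depth_um Total stack depth, micrometres.
#' @param in_focus_plane 0-based index of the sharp plane.
#' @param defocus_sigma_per_plane_px Gaussian blur sigma added per plane of
#'   defocus (sigma = rate * |plane - in_focus_plane|).
#' @param condition_fold Named per-channel intensity multiplier applied to
#'   every microtissue (e.g. `c(collagen1 = 8, asma = 6)` for a fibrotic
#'   condition); unnamed channels default to 1.
#' @param base_amplitude Peak per-pixel intensity of an average microtissue
#'   before fold scaling.
#' @param noise_cv Coefficient of variation of multiplicative per-pixel
#'   lognormal noise.
#' @param fov_size_px Side length of the rendered field of view.
#' @rdname slide_spec
#' @return An object of class `stack_spec`.
#' @seealso [gen_zstack()]
#' @export
stack_spec <- function(n_planes = 25L, z_step_um = 5, depth_um = 120,
                       in_focus_plane = 12L,
                       defocus_sigma_per_plane_px = 0.6,
                       condition_fold = c(nuclei = 1),
                       background_level = 200,
                       base_amplitude = 3000,
                       noise_cv = 0.05,
                       fov_size_px = 176L,
                       microtissues_per_fov_range = c(8L, 12L),
                       microtissue_radius_px_range = c(6, 9),
                       channel_names = c("nuclei", "cytoskeleton",
                                         "asma", "collagen1"),
                       seed = 1L) {
  if (!is_count(n_planes) || n_planes < 1) abort_config("n_planes", "must be a positive integer")
  if ((n_planes - 1) * z_step_um != depth_um)
    abort_config("depth_um", sprintf(
      "inconsistent geometry: (n_planes - 1) * z_step_um = %g != depth_um = %g",
      (n_planes - 1) * z_step_um, depth_um))
  if (!is_count(in_focus_plane) || in_focus_plane >= n_planes)
    abort_config("in_focus_plane", sprintf("must lie in [0, %d)", n_planes))
  fold <- setNames(rep(1, length(channel_names)), channel_names)
  if (length(condition_fold)) {
    if (is.null(names(condition_fold)) ||
        !all(names(condition_fold) %in% channel_names))
      abort_config("condition_fold", "must be named by channels present in channel_names")
    if (any(condition_fold <= 0)) abort_config("condition_fold", "must be > 0")
    fold[names(condition_fold)] <- condition_fold
  }
  if (!is_number(noise_cv) || noise_cv < 0) abort_config("noise_cv", "must be >= 0")
  structure(list(
    n_planes = as.integer(n_planes), z_step_um = z_step_um,
    depth_um = depth_um, in_focus_plane = as.integer(in_focus_plane),
    defocus_sigma_per_plane_px = defocus_sigma_per_plane_px,
    condition_fold = fold, background_level = background_level,
    base_amplitude = base_amplitude, noise_cv = noise_cv,
    fov_size_px = as.integer(fov_size_px),
    microtissues_per_fov_range = as.integer(round(microtissues_per_fov_range)),
    microtissue_radius_px_range = microtissue_radius_px_range,
    channel_names = channel_names, seed = as.integer(seed)),
    class = "stack_spec")
}

#' @param c0_uM Starting concentration, micromolar.
#' @param k_per_h First-order elimination rate, per hour.  Exactly one of
#'   `k_per_h` and `t_half_h` must be given (`t_half = ln 2 / k`).
#' @param t_half_h Elimination half-life, hours.
#' @param sample_times_h Strictly increasing, non-negative sampling times.
#' @rdname slide_spec
#' @return An object of class `decay_spec`.
#' @seealso [gen_decay()]
#' @export
decay_spec <- function(c0_uM = 1, k_per_h = NULL, t_half_h = NULL,
                       sample_times_h = seq(0, 48, by = 6),
                       noise_cv = 0.05, analyte = "compound", seed = 1L) {
  if (!is_number(c0_uM) || c0_uM <= 0) abort_config("c0_uM", "must be > 0")
  if (is.null(k_per_h) && is.null(t_half_h))
    abort_config("k_per_h", "or t_half_h must be supplied")
  if (is.null(k_per_h)) {
    if (!is_number(t_half_h) || t_half_h <= 0) abort_config("t_half_h", "must be > 0")
    k_per_h <- log(2) / t_half_h
  }
  if (!is_number(k_per_h) || k_per_h < 0) abort_config("k_per_h", "must be >= 0")
  t_half_h <- if (k_per_h > 0) log(2) / k_per_h else Inf
  if (any(sample_times_h < 0) || is.unsorted(sample_times_h, strictly = TRUE))
    abort_config("sample_times_h", "must be non-negative and strictly increasing")
  if (!is_number(noise_cv) || noise_cv < 0) abort_config("noise_cv", "must be >= 0")
  structure(list(c0_uM = c0_uM, k_per_h = k_per_h, t_half_h = t_half_h,
                 sample_times_h = sample_times_h, noise_cv = noise_cv,
                 analyte = analyte, seed = as.integer(seed)),
            class = "decay_spec")
}

#' @param n_genes Number of genes in the simulated expression matrix.
#' @param n_reps_per_group Replicates per group.
#' @param groups Group labels; the first is the reference.
#' @param de_genes Named numeric vector of true log2 fold-changes (non-zero;
#'   sign gives direction) applied to the non-reference group(s).
#' @param batch_assignment Optional character vector of plate labels, one per
#'   sample (samples ordered group-major).  Default alternates two plates.
#' @param batch_sd,residual_sd Log2-scale standard deviations of the plate
#'   effect and residual noise.
#' @rdname slide_spec
#' @return An object of class `expr_spec`.
#' @seealso [gen_expression()]
#' @export
expr_spec <- function(n_genes = 1000L, n_reps_per_group = 3L,
                      groups = c("control", "nash"),
                      de_genes = NULL,
                      batch_assignment = NULL,
                      batch_sd = 0.1, residual_sd = 0.5, seed = 1L) {
  if (!is_count(n_genes) || n_genes < 1) abort_config("n_genes", "must be a positive integer")
  if (!is_count(n_reps_per_group) || n_reps_per_group < 2)
    abort_config("n_reps_per_group", "must be an integer >= 2")
  if (length(groups) < 2) abort_config("groups", "needs at least two labels")
  genes <- sprintf("G%05d", seq_len(n_genes))
  de_genes <- de_genes %||% setNames(numeric(0), character(0))
  if (length(de_genes) && !all(names(de_genes) %in% genes))
    abort_config("de_genes", "contains genes outside the simulated universe (G00001..)")
  n_samples <- length(groups) * n_reps_per_group
  batch_assignment <- batch_assignment %||%
    rep(c("plateA", "plateB"), length.out = n_samples)
  if (length(batch_assignment) != n_samples)
    abort_config("batch_assignment", sprintf("must have one plate per sample (%d)", n_samples))
  if (batch_sd < 0) abort_config("batch_sd", "must be >= 0")
  if (residual_sd < 0) abort_config("residual_sd", "must be >= 0")
  structure(list(n_genes = as.integer(n_genes), genes = genes,
                 n_reps_per_group = as.integer(n_reps_per_group),
                 groups = groups, de_genes = de_genes,
                 batch_assignment = batch_assignment,
                 batch_sd = batch_sd, residual_sd = residual_sd,
                 seed = as.integer(seed)), class = "expr_spec")
}

#' @param analytes Character vector of analyte names.
#' @param group_means Matrix of mean concentrations, `analytes` x groups
#'   (column names are the condition labels).
#' @param detection_limit Named numeric lower limit of detection per analyte
#'   (unnamed scalar recycles to all analytes).
#' @param n_reps Replicates per group.
#' @param days Optional vector of sampling days, one per group column, kept
#'   in the sample annotation.
#' @rdname slide_spec
#' @return An object of class `panel_spec`.
#' @seealso [gen_panel()]
#' @export
panel_spec <- function(analytes, group_means, detection_limit = 0,
                       noise_cv = 0.1, n_reps = 3L, days = NULL, seed = 1L) {
  group_means <- as.matrix(group_means)
  if (nrow(group_means) != length(analytes))
    abort_config("group_means", "must have one row per analyte")
  if (is.null(colnames(group_means)))
    abort_config("group_means", "must carry group labels as column names")
  if (any(group_means < 0)) abort_config("group_means", "must be >= 0")
  if (length(detection_limit) == 1L && is.null(names(detection_limit)))
    detection_limit <- setNames(rep(detection_limit, length(analytes)), analytes)
  if (!all(analytes %in% names(detection_limit)))
    abort_config("detection_limit", "must name every analyte")
  if (any(detection_limit < 0)) abort_config("detection_limit", "must be >= 0")
  if (!is_number(noise_cv) || noise_cv < 0) abort_config("noise_cv", "must be >= 0")
  if (!is.null(days) && length(days) != ncol(group_means))
    abort_config("days", "must have one entry per group column")
  rownames(group_means) <- analytes
  structure(list(analytes = analytes, group_means = group_means,
                 detection_limit = detection_limit[analytes],
                 noise_cv = noise_cv, n_reps = as.integer(n_reps),
                 days = days, seed = as.integer(seed)),
            class = "panel_spec")
}
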