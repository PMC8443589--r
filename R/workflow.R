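#' Orchestration and reproducible end-to-end runs
#'
#' Glue binding the fixture generators to the imaging, PK, omics and panel
#' analytics: a demo-experiment builder, the full imaging quantification
#' pipeline, and a config-driven `run_pipeline()` that writes result
#' tables plus a run manifest (seed, config hash, file list, wall time,
#' warnings).
#'
#' @name workflow
NULL

#' Build a complete synthetic imaging experiment
#'
#' Generates one slide per condition (identical scaffold geometry, seeds
#' derived from `seed`) and renders a z-stack for every ROI/FOV with the
#' condition's per-channel intensity folds.  The returned maps feed
#' [run_imaging_pipeline()] directly.
#'
#' @param seed Master seed.
#' @param conditions Named list: condition -> named per-channel fold
#'   vector (e.g. `list(control = c(), nash = c(asma = 6, collagen1 = 8))`).
#'   The first entry is the reference.
#' @param scaffolds_per_condition Scaffolds rendered per condition.
#' @param fovs_per_scaffold Fields of view (ROIs imaged) per scaffold.
#' @param n_planes,z_step_um Stack geometry; depth is implied.
#' @param noise_cv Pixel noise CV for the stacks.
#' @param tile_size_px,overlap_frac,scaffold_radius_px Slide geometry.
#' @return List: `tiles` (reference condition's slide), `truth`, `stacks`
#'   (list of `gen_zstack()` results across all conditions), `fov_scaffold`,
#'   `scaffold_condition`, `conditions`.
#' @export
build_demo_experiment <- function(seed = 1L,
                                  conditions = list(
                                    control = c(),
                                    nash = c(asma = 6, collagen1 = 8)),
                                  scaffolds_per_condition = 2L,
                                  fovs_per_scaffold = 8L,
                                  n_planes = 3L, z_step_um = 5,
                                  noise_cv = 0.05,
                                  tile_size_px = 192L, overlap_frac = 0.1,
                                  scaffold_radius_px = 55) {
  stopifnot(length(conditions) >= 1, !is.null(names(conditions)))
  n_scaf <- scaffolds_per_condition
  # scaffold centres on a row of 2x1 tile grids: one 2-scaffold slide per
  # condition keeps mosaics small; conditions are separate slides anyway.
  stacks <- list()
  fov_scaffold <- character(0)
  scaffold_condition <- character(0)
  tiles_ref <- NULL
  truth_ref <- NULL
  scaf_global <- 0L
  fov_global <- 0L
  for (ci in seq_along(conditions)) {
    cond <- names(conditions)[ci]
    stride <- round((1 - overlap_frac) * tile_size_px)
    mosaic_w <- stride * (n_scaf - 1) + tile_size_px
    centres <- lapply(seq_len(n_scaf), function(s)
      c((stride + tile_size_px) / 2,
        (s - 0.5) * mosaic_w / n_scaf))
    sl <- slide_spec(grid_rows = 2L, grid_cols = n_scaf,
                     tile_size_px = tile_size_px,
                     overlap_frac = overlap_frac,
                     scaffold_centers = centres,
                     scaffold_radius_px = scaffold_radius_px,
                     fovs_per_scaffold = fovs_per_scaffold,
                     # same slide seed for every condition: scaffold layouts
                     # and microtissue geometry are paired across conditions,
                     # so truth intensity ratios equal the folds exactly
                     seed = child_seed(seed, "slide"))
    slide <- gen_slide(sl)
    if (ci == 1L) {
      tiles_ref <- slide$tiles
      truth_ref <- slide$truth
    }
    for (lay in slide$truth$fov_layouts) {
      fov_global <- fov_global + 1L
      scaf_id <- scaf_global + lay$scaffold_id
      sp <- stack_spec(n_planes = n_planes, z_step_um = z_step_um,
                       depth_um = (n_planes - 1) * z_step_um,
                       in_focus_plane = (n_planes - 1L) %/% 2L,
                       condition_fold = conditions[[ci]],
                       noise_cv = noise_cv,
                       # condition label deliberately absent from the seed
                       # stream: base amplitudes match across conditions
                       seed = child_seed(seed, paste0("fov_", lay$fov_id)))
      lay$fov_id <- fov_global
      stacks[[fov_global]] <- gen_zstack(sp, lay)
      fov_scaffold[as.character(fov_global)] <- as.character(scaf_id)
    }
    for (s in seq_len(n_scaf))
      scaffold_condition[as.character(scaf_global + s)] <- cond
    scaf_global <- scaf_global + n_scaf
  }
  list(tiles = tiles_ref, truth = truth_ref, stacks = stacks,
       fov_scaffold = fov_scaffold,
       scaffold_condition = scaffold_condition,
       conditions = conditions, overlap_frac = overlap_frac,
       scaffold_radius_px = scaffold_radius_px)
}

#' Run the full imaging quantification pipeline
#'
#' Stitch -> detect scaffolds -> place ROIs -> per-FOV focus selection,
#' segmentation and intensity measurement -> per-FOV/per-scaffold
#' aggregation -> condition comparison.
#'
#' @param experiment Output of [build_demo_experiment()] (or a list with
#'   the same fields).
#' @param reference_condition Reference for fold-changes (default: first
#'   condition).
#' @param min_area_px,seg_sigma Segmentation parameters.
#' @param channels Channels quantified per microtissue.
#' @return List: `mosaic`, `detections`, `roi_sets`, `records`,
#'   `summaries`, `comparison`.
#' @export
run_imaging_pipeline <- function(experiment,
                                 reference_condition = NULL,
                                 min_area_px = 100, seg_sigma = 2,
                                 channels = c("asma", "collagen1")) {
  ex <- experiment
  reference_condition <- reference_condition %||% names(ex$conditions)[1]
  mosaic <- stitch_tiles(ex$tiles, ex$overlap_frac)
  dets <- detect_scaffolds(mosaic, ex$scaffold_radius_px)
  template <- ex$truth$spec$roi_template
  roi_sets <- lapply(seq_along(dets), function(i)
    place_rois(dets[[i]], template, roi_size_px = 64,
               mosaic_dim = dim(mosaic$pixels), scaffold_id = i))
  records <- list()
  for (st in ex$stacks) {
    foc <- select_focus(st$stack)
    seg <- segment_microtissues(st$stack$pixels$nuclei[foc$plane_idx + 1L, , ],
                                min_area_px = min_area_px,
                                sigma = seg_sigma,
                                fov_id = st$stack$fov_id)
    if (nrow(seg$records) == 0L) next
    records[[length(records) + 1L]] <-
      measure_intensity(seg$labels, seg$records, st$stack, foc,
                        channels = channels)
  }
  records <- do.call(rbind, records)
  summaries <- summarize_microtissues(records, ex$fov_scaffold,
                                      ex$scaffold_condition)
  comparison <- compare_conditions(summaries$scaffold_summaries,
                                   reference_condition)
  list(mosaic = mosaic, detections = dets, roi_sets = roi_sets,
       records = records, summaries = summaries, comparison = comparison)
}

# Stable 32-bit FNV-1a hash of a config list via its canonical JSON form.
# The output location is excluded: two runs of the same analysis into
# different directories are the same run.
config_hash <- function(config) {
  config$out_dir <- NULL
  js <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                         force = TRUE)
  sprintf("%08x", child_seed(0L, as.character(js)))
}

#' Run a configured end-to-end analysis and write outputs
#'
#' Validates the configuration (reporting every problem, not just the
#' first), executes the requested stages in dependency order and writes
#' result tables plus a JSON run manifest.  Reruns with an identical
#' (config, seed) pair produce byte-identical tables.
#'
#' Config keys: `seed` (integer), `out_dir` (path), `modules` (subset of
#' `"fixtures"`, `"imaging"`), and an optional `experiment` list of
#' overrides passed to [build_demo_experiment()].
#'
#' @param config A list, or path to a JSON file holding one.
#' @return The run manifest (invisibly also written to
#'   `manifest.json`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  t0 <- proc.time()[["elapsed"]]
  problems <- character(0)
  if (is.null(config$seed) || !is_count(config$seed))
    problems <- c(problems, "seed: must be a non-negative integer")
  if (is.null(config$out_dir) || !is.character(config$out_dir))
    problems <- c(problems, "out_dir: must be a path")
  modules <- config$modules %||% c("fixtures", "imaging")
  bad <- setdiff(modules, c("fixtures", "imaging"))
  if (length(bad))
    problems <- c(problems, paste0("modules: unknown stage(s) ",
                                   paste(bad, collapse = ", ")))
  if (length(problems))
    abort_input("configuration invalid:\n  %s",
                paste(problems, collapse = "\n  "))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  warnings_log <- character(0)
  files <- character(0)
  put <- function(df, name) {
    path <- file.path(config$out_dir, name)
    write.csv(df, path, row.names = FALSE)
    files <<- c(files, name)
    path
  }
  ex_args <- config$experiment %||% list()
  ex_args$seed <- as.integer(config$seed)
  ex <- withCallingHandlers(
    do.call(build_demo_experiment, ex_args),
    warning = function(w) {
      warnings_log <<- c(warnings_log, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  truth_mt <- do.call(rbind, lapply(ex$stacks, function(st)
    data.frame(fov_id = st$truth$fov_id, n = nrow(st$truth$centres))))
  put(truth_mt, "fixture_fov_truth.csv")
  manifest <- list(config_hash = config_hash(config),
                   seed = as.integer(config$seed),
                   package_version = as.character(
                     utils::packageVersion("mpskit")),
                   stages = modules)
  if ("imaging" %in% modules) {
    res <- withCallingHandlers(
      run_imaging_pipeline(ex),
      warning = function(w) {
        warnings_log <<- c(warnings_log, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    roi_df <- do.call(rbind, lapply(res$roi_sets, function(rs)
      data.frame(scaffold_id = rs$scaffold_id,
                 roi_idx = seq_len(nrow(rs$centres)),
                 row_px = rs$centres[, 1], col_px = rs$centres[, 2])))
    put(roi_df, "roi_coordinates.csv")
    put(res$records, "microtissues.csv")
    put(res$summaries$scaffold_summaries, "scaffold_summaries.csv")
    put(res$comparison, "condition_comparison.csv")
    message(sprintf(
      "imaging: %d scaffold(s), %d microtissue record(s), %d comparison row(s)",
      length(res$detections), nrow(res$records), nrow(res$comparison)))
  }
  manifest$files <- files
  manifest$warnings <- warnings_log
  manifest$wall_time_s <- round(proc.time()[["elapsed"]] - t0, 2)
  jsonlite::write_json(manifest,
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
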