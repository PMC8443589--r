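#' Seeded fixture generators
#'
#' Generators producing every input the analysis modules consume, together
#' with exhaustive machine-readable ground truth (`truth`) for recovery
#' tests: exact tile offsets, scaffold and ROI centres, and per-microtissue
#' rendered integrated intensities.  Identical (spec, seed) pairs give
#' bit-identical output; no global RNG state is touched.
#'
#' Microtissues are rendered as Gaussian-tapered disks (flat core of the
#' stated radius, soft edge), so defocus blur and focus metrics respond
#' smoothly.  Intensities are single-precision-style values in
#' `[0, 65535]`, quantised to integers like 16-bit confocal data.
#'
#' @name fixtures
NULL

# Edge softness of the rendered disks, px.
.TAPER_SIGMA <- 1.2

# Additive rendering of one tapered disk onto `img`; returns the updated
# image plus the exact rendered (pre-noise, pre-quantisation) sum, which is
# what ground truth records.
render_disk <- function(img, centre, radius, amplitude) {
  n <- nrow(img); m <- ncol(img)
  ext <- ceiling(radius + 4 * .TAPER_SIGMA)
  r0 <- max(1L, floor(centre[1] + 1 - ext)); r1 <- min(n, ceiling(centre[1] + 1 + ext))
  c0 <- max(1L, floor(centre[2] + 1 - ext)); c1 <- min(m, ceiling(centre[2] + 1 + ext))
  if (r0 > r1 || c0 > c1) return(list(img = img, sum = 0))
  rr <- r0:r1; cc <- c0:c1
  d <- sqrt(outer((rr - 1 - centre[1])^2, (cc - 1 - centre[2])^2, `+`))
  prof <- ifelse(d <= radius, 1, exp(-(d - radius)^2 / (2 * .TAPER_SIGMA^2)))
  patch <- amplitude * prof
  img[rr, cc] <- img[rr, cc] + patch
  list(img = img, sum = sum(patch))
}

quantize16 <- function(img) pmin(pmax(round(img), 0), 65535)

# Deterministic jittered-grid layout of non-touching microtissues inside a
# square field of view.  A grid guarantees a minimum centre separation (no
# merged objects), the jitter removes the regular-lattice look.
gen_fov_layout <- function(n, radius_range, fov_size_px) {
  rmax <- max(radius_range)
  margin <- ceiling(rmax + 4 * .TAPER_SIGMA + 4)
  span <- fov_size_px - 2 * margin
  g <- ceiling(sqrt(n))
  cell <- span / g
  jit <- max(0, min(cell / 2 - rmax - 3, 5))
  cells <- sample.int(g * g, n)
  centres <- matrix(0, n, 2)
  radii <- runif(n, radius_range[1], radius_range[2])
  for (i in seq_len(n)) {
    gr <- (cells[i] - 1) %/% g
    gc <- (cells[i] - 1) %% g
    centres[i, ] <- c(margin + (gr + 0.5) * cell + runif(1, -jit, jit),
                      margin + (gc + 0.5) * cell + runif(1, -jit, jit))
  }
  ord <- order(centres[, 1], centres[, 2])
  list(centres = centres[ord, , drop = FALSE], radii = radii[ord])
}

#' Generate a low-magnification slide mosaic as tiles plus ground truth
#'
#' Renders the nuclei-channel slide scan: a background field carrying one
#' tapered bright disk per scaffold (plus speckle texture inside it, which
#' gives the stitcher something to lock onto), cut into an overlapping tile
#' grid.  Ground truth records the exact tile offsets, scaffold centres and
#' the fixed ROI array of every scaffold, and the sampled per-FOV
#' microtissue layouts consumed later by [gen_zstack()].
#'
#' @param spec A [slide_spec()].
#' @return A list with `tiles` (each a list with `pixels`, 0-based
#'   `grid_pos`, `channel`) and `truth` (tile offsets, scaffolds, ROI
#'   centres, FOV layouts, echoed spec).
#' @export
gen_slide <- function(spec) {
  stopifnot(inherits(spec, "slide_spec"))
  with_seed(spec$seed, {
    dims <- spec$mosaic_dim
    canvas <- matrix(spec$background_level, dims[1], dims[2])
    scaffolds <- list()
    roi_centers <- list()
    fov_layouts <- list()
    fov_id <- 0L
    for (s in seq_along(spec$scaffold_centers)) {
      ctr <- spec$scaffold_centers[[s]]
      res <- render_disk(canvas, ctr, spec$scaffold_radius_px, 400)
      canvas <- res$img
      # nuclei speckle inside the scaffold: stitching/detection texture
      n_spk <- 120L
      ang <- runif(n_spk, 0, 2 * pi)
      rad <- spec$scaffold_radius_px * sqrt(runif(n_spk)) * 0.95
      for (k in seq_len(n_spk)) {
        pos <- ctr + rad[k] * c(cos(ang[k]), sin(ang[k]))
        canvas <- render_disk(canvas, pos, runif(1, 1.2, 2.2),
                              runif(1, 300, 900))$img
      }
      scaffolds[[s]] <- list(centre = ctr, radius_px = spec$scaffold_radius_px)
      rc <- t(vapply(spec$roi_template, function(d) ctr + d, numeric(2)))
      roi_centers[[s]] <- rc
      n_rng <- spec$microtissues_per_fov_range
      for (j in seq_len(spec$fovs_per_scaffold)) {
        fov_id <- fov_id + 1L
        n_mt <- sample(seq(n_rng[1], n_rng[2]), 1L)
        lay <- gen_fov_layout(n_mt, spec$microtissue_radius_px_range, 176L)
        fov_layouts[[fov_id]] <- list(
          fov_id = fov_id, scaffold_id = s, roi_idx = j,
          centres = lay$centres, radii = lay$radii)
      }
    }
    canvas <- quantize16(canvas)
    tiles <- list()
    offsets <- matrix(0L, spec$grid_rows * spec$grid_cols, 2)
    k <- 0L
    for (i in seq_len(spec$grid_rows) - 1L) {
      for (j in seq_len(spec$grid_cols) - 1L) {
        k <- k + 1L
        off <- c(i, j) * spec$stride_px
        offsets[k, ] <- off
        tiles[[k]] <- list(
          pixels = canvas[off[1] + seq_len(spec$tile_size_px),
                          off[2] + seq_len(spec$tile_size_px), drop = FALSE],
          grid_pos = c(i, j), channel = "nuclei")
      }
    }
    truth <- list(tile_offsets = offsets, mosaic_dim = dims,
                  scaffolds = scaffolds, roi_centers = roi_centers,
                  fov_layouts = fov_layouts,
                  microtissues = list(), spec = spec)
    list(tiles = tiles, truth = truth, mosaic = canvas)
  })
}

#' Generate a defocused multi-channel z-stack for one field of view
#'
#' Renders the in-focus image of every channel (background plus
#' Gaussian-tapered microtissue disks, per-channel amplitudes scaled by the
#' spec's `condition_fold`), then produces each plane by blurring with
#' sigma proportional to the distance from the in-focus plane and applying
#' multiplicative lognormal pixel noise.  Base amplitudes are drawn from a
#' seed sub-stream independent of the noise stream, so two specs that
#' differ only in `condition_fold` assign identical base intensities and
#' their truth means differ by exactly the fold.
#'
#' @param spec A [stack_spec()].
#' @param fov_truth Optional FOV layout (one element of
#'   `gen_slide()$truth$fov_layouts`); when `NULL`, a layout is sampled
#'   from the spec's own count and radius ranges.
#' @return A list with `stack` (class `zstack`: `pixels[[channel]]` a
#'   plane x row x col array, `z_step_um`, `channel_names`) and `truth`
#'   (per-microtissue centres, radii and exact per-channel rendered
#'   integrated intensities).
#' @export
gen_zstack <- function(spec, fov_truth = NULL) {
  stopifnot(inherits(spec, "stack_spec"))
  if (is.null(fov_truth)) {
    fov_truth <- with_seed(child_seed(spec$seed, "layout"), {
      rng <- spec$microtissues_per_fov_range
      n_mt <- sample(seq(rng[1], rng[2]), 1L)
      lay <- gen_fov_layout(n_mt, spec$microtissue_radius_px_range,
                            spec$fov_size_px)
      list(fov_id = 1L, scaffold_id = 1L, roi_idx = 1L,
           centres = lay$centres, radii = lay$radii)
    })
  }
  centres <- fov_truth$centres
  radii <- fov_truth$radii
  n_mt <- nrow(centres)
  nch <- length(spec$channel_names)
  # base amplitudes: lognormal scatter about base_amplitude, shared stream
  base <- with_seed(child_seed(spec$seed, "intensity"),
                    matrix(spec$base_amplitude *
                             rlnorm(n_mt * nch, -0.02, 0.2), n_mt, nch))
  amp <- sweep(base, 2, spec$condition_fold[spec$channel_names], `*`)
  sz <- spec$fov_size_px
  infocus <- list()
  truth_int <- matrix(0, n_mt, nch,
                      dimnames = list(NULL, spec$channel_names))
  for (ch in seq_len(nch)) {
    img <- matrix(spec$background_level, sz, sz)
    for (i in seq_len(n_mt)) {
      res <- render_disk(img, centres[i, ], radii[i], amp[i, ch])
      img <- res$img
      truth_int[i, ch] <- res$sum
    }
    infocus[[spec$channel_names[ch]]] <- img
  }
  pixels <- with_seed(child_seed(spec$seed, "noise"), {
    out <- list()
    for (ch in spec$channel_names) {
      arr <- array(0, dim = c(spec$n_planes, sz, sz))
      for (p in seq_len(spec$n_planes) - 1L) {
        sigma <- spec$defocus_sigma_per_plane_px * abs(p - spec$in_focus_plane)
        plane <- blur2d(infocus[[ch]], sigma)
        plane <- plane * matrix(lognormal_noise(sz * sz, spec$noise_cv), sz, sz)
        arr[p + 1L, , ] <- quantize16(plane)
      }
      out[[ch]] <- arr
    }
    out
  })
  stack <- structure(list(pixels = pixels, z_step_um = spec$z_step_um,
                          channel_names = spec$channel_names,
                          fov_id = fov_truth$fov_id), class = "zstack")
  truth <- list(fov_id = fov_truth$fov_id,
                scaffold_id = fov_truth$scaffold_id,
                centres = centres, radii = radii,
                intensity = truth_int,
                in_focus_plane = spec$in_focus_plane, spec = spec)
  list(stack = stack, truth = truth)
}

#' Generate a first-order drug-decay concentration time-course
#'
#' `c(t) = c0 * exp(-k t) * eps` with `eps` lognormal of unit mean and
#' coefficient of variation `noise_cv`.
#'
#' @param spec A [decay_spec()].
#' @return A [conc_series()] with attribute `true_k_per_h`.
#' @export
gen_decay <- function(spec) {
  stopifnot(inherits(spec, "decay_spec"))
  conc <- with_seed(spec$seed, {
    mu <- spec$c0_uM * exp(-spec$k_per_h * spec$sample_times_h)
    mu * lognormal_noise(length(mu), spec$noise_cv)
  })
  out <- conc_series(analyte = spec$analyte, times_h = spec$sample_times_h,
                     conc_uM = conc, input_conc_uM = spec$c0_uM)
  attr(out, "true_k_per_h") <- spec$k_per_h
  out
}

#' Generate a log2-scale expression matrix with batch structure
#'
#' Model per gene g, sample s: `baseline_g + effect_{g,group(s)} +
#' plate_{plate(s)} + N(0, residual_sd)`.  The non-reference groups carry
#' the spec's true log2 fold-changes.  Plate offsets are drawn once per
#' plate and shared across genes, mimicking plate-level batch effects.
#'
#' @param spec An [expr_spec()].
#' @return List: `matrix` (genes x samples, log2 scale), `sample_info`
#'   (sample, group, plate), `truth` ([deg_table()]-shaped data frame of
#'   true log2 fold-changes, `de` flag set for spec'd genes).
#' @export
gen_expression <- function(spec) {
  stopifnot(inherits(spec, "expr_spec"))
  with_seed(spec$seed, {
    n_samples <- length(spec$groups) * spec$n_reps_per_group
    group <- rep(spec$groups, each = spec$n_reps_per_group)
    sample_id <- sprintf("S%02d_%s", seq_len(n_samples), group)
    baseline <- rnorm(spec$n_genes, 8, 2)
    plates <- unique(spec$batch_assignment)
    plate_off <- setNames(rnorm(length(plates), 0, spec$batch_sd), plates)
    eff <- matrix(0, spec$n_genes, n_samples,
                  dimnames = list(spec$genes, sample_id))
    if (length(spec$de_genes)) {
      idx <- match(names(spec$de_genes), spec$genes)
      eff[idx, group != spec$groups[1]] <- spec$de_genes
    }
    resid <- matrix(rnorm(spec$n_genes * n_samples, 0, spec$residual_sd),
                    spec$n_genes, n_samples)
    mat <- baseline + eff +
      matrix(plate_off[spec$batch_assignment], spec$n_genes, n_samples,
             byrow = TRUE) + resid
    dimnames(mat) <- list(spec$genes, sample_id)
    truth <- data.frame(gene = spec$genes,
                        log2fc = ifelse(spec$genes %in% names(spec$de_genes),
                                        spec$de_genes[spec$genes], 0),
                        de = spec$genes %in% names(spec$de_genes),
                        row.names = NULL)
    list(matrix = mat,
         sample_info = data.frame(sample = sample_id, group = group,
                                  plate = spec$batch_assignment),
         truth = truth)
  })
}

#' Generate a biomarker panel with detection limits
#'
#' Concentrations are `group_mean * eps` (lognormal, CV `noise_cv`); cells
#' below the analyte's detection limit are flagged undetected.
#'
#' @param spec A [panel_spec()].
#' @return A [panel_matrix()].
#' @export
gen_panel <- function(spec) {
  stopifnot(inherits(spec, "panel_spec"))
  with_seed(spec$seed, {
    groups <- colnames(spec$group_means)
    n_a <- length(spec$analytes)
    cols <- list(); conds <- character(0); days <- numeric(0)
    for (g in seq_along(groups)) {
      for (r in seq_len(spec$n_reps)) {
        mu <- spec$group_means[, g]
        cols[[length(cols) + 1L]] <- mu * lognormal_noise(n_a, spec$noise_cv)
        conds <- c(conds, groups[g])
        days <- c(days, if (is.null(spec$days)) NA_real_ else spec$days[g])
      }
    }
    conc <- do.call(cbind, cols)
    dimnames(conc) <- list(spec$analytes,
                           sprintf("%s_r%d", conds,
                                   rep(seq_len(spec$n_reps), length(groups))))
    detected <- conc >= matrix(spec$detection_limit, n_a, ncol(conc))
    panel_matrix(conc, detected,
                 data.frame(sample = colnames(conc), condition = conds,
                            day = days))
  })
}
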