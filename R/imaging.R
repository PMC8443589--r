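#' Automated microtissue fibrosis quantification
#'
#' The unbiased imaging workflow: stitch low-magnification nuclei tiles into
#' a slide mosaic, locate scaffolds, place the fixed ROI array, pick the
#' in-focus plane of each ROI z-stack on the nuclei channel, segment
#' microtissues, measure background-subtracted total marker intensity per
#' microtissue, and aggregate per FOV and per scaffold.  All coordinates
#' are 0-based `(row, col)` pixels; tie-breaks are always lowest index.
#'
#' @name imaging
NULL

#' Stitch a rectangular grid of single-channel tiles into a mosaic
#'
#' Nominal grid offsets (`round((1 - overlap_frac) * tile_size)` strides)
#' are refined by maximising normalised cross-correlation with the already
#' placed neighbour over the overlap strip, searching a window of +/-10% of
#' the tile size.  Overlaps are blended by linear feathering.  Constant
#' (featureless) overlap strips, or a zero overlap, fall back to the
#' nominal offsets.
#'
#' @param tiles List of tiles as produced by [gen_slide()]: each a list
#'   with `pixels` (matrix), `grid_pos` (`c(row_idx, col_idx)`, 0-based)
#'   and `channel`.
#' @param overlap_frac Fractional tile overlap in `[0, 0.5)`.
#' @param refine Refine offsets by cross-correlation (default `TRUE`).
#' @return A `slide_mosaic`: list with `pixels`, `tile_offsets` (matrix of
#'   0-based `(row, col)` offsets in tile order), `tile_grid`.
#' @export
stitch_tiles <- function(tiles, overlap_frac, refine = TRUE) {
  if (length(tiles) == 0L) abort_input("no tiles supplied")
  ch <- unique(vapply(tiles, function(t) t$channel, character(1)))
  if (length(ch) != 1L) abort_input("tiles span multiple channels: %s",
                                    paste(ch, collapse = ", "))
  gp <- t(vapply(tiles, function(t) as.integer(t$grid_pos), integer(2)))
  nr <- max(gp[, 1]) + 1L; nc <- max(gp[, 2]) + 1L
  want <- expand.grid(r = seq_len(nr) - 1L, c = seq_len(nc) - 1L)
  have <- paste(gp[, 1], gp[, 2])
  missing <- setdiff(paste(want$r, want$c), have)
  if (length(missing))
    abort_input("incomplete tile grid; missing cell(s): %s",
                paste(missing, collapse = "; "))
  if (anyDuplicated(have)) abort_input("duplicate tile grid positions")
  tile_size <- nrow(tiles[[1]]$pixels)
  stride <- round((1 - overlap_frac) * tile_size)
  ov_px <- tile_size - stride
  if (refine && ov_px <= 0) {
    warning("zero overlap: cross-correlation refinement skipped, ",
            "using nominal offsets")
    refine <- FALSE
  }
  win <- max(1L, round(0.1 * tile_size))
  ord <- order(gp[, 1], gp[, 2])
  offsets <- matrix(NA_integer_, length(tiles), 2)
  for (t_i in ord) {
    i <- gp[t_i, 1]; j <- gp[t_i, 2]
    if (i == 0L && j == 0L) {
      offsets[t_i, ] <- c(0L, 0L)
      next
    }
    # anchor on the left neighbour when present, else the one above
    if (j > 0L) {
      nb <- which(gp[, 1] == i & gp[, 2] == j - 1L)
      delta <- c(0L, stride)
    } else {
      nb <- which(gp[, 1] == i - 1L & gp[, 2] == j)
      delta <- c(stride, 0L)
    }
    nominal <- offsets[nb, ] + delta
    offsets[t_i, ] <- if (refine) {
      refine_offset(tiles[[nb]]$pixels, offsets[nb, ], tiles[[t_i]]$pixels,
                    nominal, win)
    } else nominal
  }
  storage.mode(offsets) <- "integer"
  dims <- c(max(offsets[, 1]) + tile_size, max(offsets[, 2]) + tile_size)
  acc <- matrix(0, dims[1], dims[2])
  wacc <- matrix(0, dims[1], dims[2])
  cap <- max(1L, ov_px)
  ramp <- pmin(seq_len(tile_size), tile_size + 1L - seq_len(tile_size), cap) / cap
  w <- outer(ramp, ramp)
  for (t_i in seq_along(tiles)) {
    rs <- offsets[t_i, 1] + seq_len(tile_size)
    cs <- offsets[t_i, 2] + seq_len(tile_size)
    acc[rs, cs] <- acc[rs, cs] + w * tiles[[t_i]]$pixels
    wacc[rs, cs] <- wacc[rs, cs] + w
  }
  structure(list(pixels = acc / wacc, tile_offsets = offsets,
                 tile_grid = gp, channel = ch), class = "slide_mosaic")
}

# Best (row, col) offset for tile `b` given an already placed neighbour `a`,
# maximising Pearson correlation over the overlap; NA correlations (flat
# strips) leave the nominal offset in place.
refine_offset <- function(a, off_a, b, nominal, win) {
  ts <- nrow(a)
  best <- nominal
  best_cc <- -Inf
  for (dr in seq(-win, win)) {
    for (dc in seq(-win, win)) {
      off_b <- nominal + c(dr, dc)
      r0 <- max(off_a[1], off_b[1]); r1 <- min(off_a[1], off_b[1]) + ts - 1L
      c0 <- max(off_a[2], off_b[2]); c1 <- min(off_a[2], off_b[2]) + ts - 1L
      if (r1 - r0 < 4L || c1 - c0 < 4L) next
      pa <- a[(r0 - off_a[1] + 1L):(r1 - off_a[1] + 1L),
              (c0 - off_a[2] + 1L):(c1 - off_a[2] + 1L)]
      pb <- b[(r0 - off_b[1] + 1L):(r1 - off_b[1] + 1L),
              (c0 - off_b[2] + 1L):(c1 - off_b[2] + 1L)]
      cc <- patch_ncc(pa, pb)
      if (!is.na(cc) && cc > best_cc + 1e-12) {
        best_cc <- cc
        best <- off_b
      }
    }
  }
  if (!is.finite(best_cc)) nominal else best
}

#' Detect circular scaffolds in a nuclei-channel mosaic
#'
#' Heavy Gaussian smoothing (sigma = radius / 4) followed by Otsu
#' thresholding yields candidate blobs; blobs of implausible size relative
#' to the expected scaffold area are dropped, centres are refined by
#' circular-template matching (small shift search maximising in-disk
#' foreground), and the radius is re-estimated from the half-height
#' crossing of the azimuthally averaged radial intensity profile.
#' Detections are returned row-major by centre; a featureless mosaic
#' returns an empty list.
#'
#' @param mosaic A `slide_mosaic` (or plain matrix).
#' @param expected_radius_px Approximate scaffold radius, pixels.
#' @return List of detections: `centre` (0-based), `radius_px`, `score`.
#' @export
detect_scaffolds <- function(mosaic, expected_radius_px) {
  img <- if (inherits(mosaic, "slide_mosaic")) mosaic$pixels else mosaic
  if (expected_radius_px <= 0) abort_input("expected_radius_px must be > 0")
  sm <- blur2d(img, expected_radius_px / 4)
  thr <- otsu_threshold(sm)
  if (is.na(thr)) return(list())
  mask <- sm > thr
  lab <- label_components(mask)
  n_lab <- max(lab)
  if (n_lab == 0L) return(list())
  area0 <- pi * expected_radius_px^2
  # radius read-out uses a lightly smoothed image: the heavy detection blur
  # would spread the scaffold edge and bias the half-height crossing
  sm_fine <- blur2d(img, expected_radius_px / 16)
  dets <- list()
  for (i in seq_len(n_lab)) {
    w <- which(lab == i, arr.ind = TRUE)
    if (nrow(w) < 0.25 * area0 || nrow(w) > 4 * area0) next
    ctr <- c(mean(w[, 1]) - 1, mean(w[, 2]) - 1)
    ctr <- refine_centre_disk(mask, ctr, expected_radius_px)
    rad <- radial_halfheight_radius(sm_fine, ctr, expected_radius_px)
    dets[[length(dets) + 1L]] <- list(
      centre = ctr, radius_px = rad,
      score = mean(sm[w]) - thr)
  }
  if (length(dets) == 0L) return(list())
  ctrs <- t(vapply(dets, function(d) d$centre, numeric(2)))
  dets[order(ctrs[, 1], ctrs[, 2])]
}

refine_centre_disk <- function(mask, ctr, radius) {
  n <- nrow(mask); m <- ncol(mask)
  score <- function(c0) {
    rr <- max(1, floor(c0[1] + 1 - radius)):min(n, ceiling(c0[1] + 1 + radius))
    cc <- max(1, floor(c0[2] + 1 - radius)):min(m, ceiling(c0[2] + 1 + radius))
    d2 <- outer((rr - 1 - c0[1])^2, (cc - 1 - c0[2])^2, `+`)
    sum(mask[rr, cc][d2 <= radius^2])
  }
  best <- ctr; best_s <- score(ctr)
  for (dr in -3:3) for (dc in -3:3) {
    if (dr == 0 && dc == 0) next
    s <- score(ctr + c(dr, dc))
    if (s > best_s) { best_s <- s; best <- ctr + c(dr, dc) }
  }
  best
}

# Radius from the half-height crossing of the radial mean profile.
radial_halfheight_radius <- function(img, ctr, r_guess) {
  r_max <- round(2 * r_guess)
  n <- nrow(img); m <- ncol(img)
  rr <- max(1, floor(ctr[1] + 1 - r_max)):min(n, ceiling(ctr[1] + 1 + r_max))
  cc <- max(1, floor(ctr[2] + 1 - r_max)):min(m, ceiling(ctr[2] + 1 + r_max))
  d <- sqrt(outer((rr - 1 - ctr[1])^2, (cc - 1 - ctr[2])^2, `+`))
  bins <- pmin(r_max, floor(d)) + 1L
  vals <- img[rr, cc]
  prof <- vapply(seq_len(r_max), function(b) mean(vals[bins == b]), numeric(1))
  prof[!is.finite(prof)] <- min(vals)
  peak <- mean(prof[seq_len(max(1L, round(r_guess / 3)))])
  base <- min(prof)
  half <- base + 0.5 * (peak - base)
  below <- which(prof < half)
  below <- below[below > 1L]
  if (length(below) == 0L) return(r_guess)
  i <- below[1]
  # linear interpolation between the bracketing bins (bin centres i - 0.5)
  frac <- (prof[i - 1] - half) / (prof[i - 1] - prof[i])
  (i - 1.5) + frac
}

#' Place the fixed ROI array on a detected scaffold
#'
#' @param det A detection from [detect_scaffolds()] (or a list with
#'   `centre`).
#' @param template List of `c(d_row, d_col)` offsets from the scaffold
#'   centre, one per ROI.
#' @param roi_size_px ROI box side length; boxes are half-open
#'   `[centre - size/2, centre + size/2)`.
#' @param mosaic_dim `c(rows, cols)` of the mosaic, to validate bounds.
#' @param scaffold_id Identifier carried into the output.
#' @return An `roi_set`: `scaffold_id`, `centres` (matrix, 0-based),
#'   `roi_size_px`.
#' @export
place_rois <- function(det, template, roi_size_px, mosaic_dim,
                       scaffold_id = 1L) {
  if (length(template) == 0L) abort_input("empty ROI template")
  centres <- t(vapply(template, function(d) det$centre + d, numeric(2)))
  half <- roi_size_px / 2
  for (i in seq_len(nrow(centres))) {
    lo <- centres[i, ] - half
    hi <- centres[i, ] + half
    if (any(lo < 0) || hi[1] > mosaic_dim[1] || hi[2] > mosaic_dim[2])
      abort_input("ROI %d exceeds mosaic bounds", i)
  }
  structure(list(scaffold_id = scaffold_id, centres = centres,
                 roi_size_px = roi_size_px), class = "roi_set")
}

#' Select the in-focus plane of a z-stack
#'
#' Per-plane sharpness is the variance of the 4-neighbour Laplacian of the
#' stated channel (nuclei by default); the selected plane is the argmax,
#' ties broken toward the lowest index.  An all-constant stack returns
#' plane 0 with zero scores and `degenerate = TRUE`.
#'
#' @param stack A `zstack` from [gen_zstack()] (or a list with `pixels`
#'   holding per-channel plane x row x col arrays).
#' @param channel Channel used for scoring.
#' @return A `focus_selection`: `plane_idx` (0-based), `focus_scores`,
#'   `degenerate`.
#' @export
select_focus <- function(stack, channel = "nuclei") {
  if (!channel %in% names(stack$pixels))
    abort_input("channel '%s' not present in stack", channel)
  arr <- stack$pixels[[channel]]
  n_planes <- dim(arr)[1]
  scores <- vapply(seq_len(n_planes),
                   function(p) laplacian_var(arr[p, , ]), numeric(1))
  degenerate <- !any(scores > 0) || diff(range(scores)) == 0
  plane <- if (degenerate) 0L else which.max(scores) - 1L
  structure(list(plane_idx = plane, focus_scores = scores,
                 degenerate = degenerate), class = "focus_selection")
}

#' Segment microtissues in an in-focus plane image
#'
#' Gaussian smoothing (sigma 2 px), Otsu threshold, 4-connected components,
#' minimum-area filter; labels are numbered row-major by centroid.
#'
#' @param img Detection-channel image (matrix), normally the in-focus
#'   nuclei plane.
#' @param min_area_px Minimum object area, pixels.
#' @param sigma Smoothing sigma, pixels.
#' @param fov_id Identifier carried into the records.
#' @return List: `labels` (integer matrix) and `records`, a data frame of
#'   skeleton microtissue records (fov_id, label, area_px, centroid).
#' @export
segment_microtissues <- function(img, min_area_px = 100, sigma = 2,
                                 fov_id = 1L) {
  empty <- list(labels = matrix(0L, nrow(img), ncol(img)),
                records = data.frame(fov_id = integer(0), label = integer(0),
                                     area_px = integer(0),
                                     centroid_row = numeric(0),
                                     centroid_col = numeric(0)))
  sm <- blur2d(img, sigma)
  thr <- otsu_threshold(sm)
  if (is.na(thr)) return(empty)
  lab <- label_components(sm > thr)
  if (max(lab) == 0L) return(empty)
  keep <- which(tabulate(lab[lab > 0L]) >= min_area_px)
  lab[!(lab %in% keep)] <- 0L
  lab <- relabel_rowmajor(lab)
  n <- max(lab)
  if (n == 0L) return(empty)
  rec <- do.call(rbind, lapply(seq_len(n), function(i) {
    w <- which(lab == i, arr.ind = TRUE)
    data.frame(fov_id = fov_id, label = i, area_px = nrow(w),
               centroid_row = mean(w[, 1]) - 1,
               centroid_col = mean(w[, 2]) - 1)
  }))
  list(labels = lab, records = rec)
}

#' Measure background-subtracted total intensity per microtissue
#'
#' For every labelled object and requested channel, the total intensity is
#' the pixel sum inside the (slightly dilated) object mask at the selected
#' in-focus plane minus `area * background`, where the background is the
#' median of pixels outside all masks dilated by a guard band.  The mask
#' dilation recovers the soft tapered edge of the objects; pixels claimed
#' by two dilated masks are excluded from both.  Negative totals are
#' clamped to zero and flagged.  `mode = "stack"` sums the measurement
#' over all planes instead of the single selected plane.
#'
#' @param labels Label matrix from [segment_microtissues()].
#' @param records Matching records data frame.
#' @param stack The `zstack` the labels came from.
#' @param focus A `focus_selection` for the stack.
#' @param channels Channels to quantify.
#' @param measure_dilate_px Mask dilation radius for measurement.
#' @param guard_px Extra guard band excluded from the background estimate.
#' @param mode `"plane"` (default) or `"stack"`.
#' @return `records` extended with one `total_<channel>` column per channel
#'   and a `clamped` flag.
#' @export
measure_intensity <- function(labels, records, stack, focus,
                              channels = c("asma", "collagen1"),
                              measure_dilate_px = 3L, guard_px = 3L,
                              mode = c("plane", "stack")) {
  mode <- match.arg(mode)
  missing_ch <- setdiff(channels, names(stack$pixels))
  if (length(missing_ch))
    abort_input("channel(s) missing from stack: %s",
                paste(missing_ch, collapse = ", "))
  n <- max(labels)
  planes <- if (mode == "plane") focus$plane_idx + 1L
            else seq_len(dim(stack$pixels[[channels[1]]])[1])
  masks <- lapply(seq_len(n), function(i)
    dilate_mask(labels == i, measure_dilate_px))
  claim <- Reduce(`+`, lapply(masks, function(m) m * 1L),
                  matrix(0L, nrow(labels), ncol(labels)))
  bg_excl <- dilate_mask(claim > 0L, guard_px)
  records$clamped <- FALSE
  for (ch in channels) {
    totals <- numeric(n)
    for (p in planes) {
      img <- stack$pixels[[ch]][p, , ]
      bg <- if (any(!bg_excl)) median(img[!bg_excl]) else 0
      for (i in seq_len(n)) {
        m <- masks[[i]] & claim == 1L
        totals[i] <- totals[i] + sum(img[m]) - sum(m) * bg
      }
    }
    clamp <- totals < 0
    records$clamped <- records$clamped | clamp
    totals[clamp] <- 0
    records[[paste0("total_", ch)]] <- totals
  }
  records
}

#' Aggregate microtissue records per FOV and per scaffold
#'
#' FOV summaries are per-channel means over the FOV's microtissues; the
#' scaffold summary is the unweighted mean of its FOV means (per-FOV
#' averaging first, so unevenly populated FOVs carry equal weight).  FOVs
#' listed in the map but carrying zero records are excluded from the
#' scaffold mean and reported in `empty_fovs`.
#'
#' @param records Measured records ([measure_intensity()] output, possibly
#'   concatenated across FOVs).
#' @param fov_scaffold Named map (or data frame `fov_id`/`scaffold_id`)
#'   from FOV to scaffold.
#' @param scaffold_condition Named map from scaffold id to condition label.
#' @return List: `fov_summaries`, `scaffold_summaries` (data frames),
#'   `empty_fovs`.
#' @export
summarize_microtissues <- function(records, fov_scaffold,
                                   scaffold_condition) {
  if (is.data.frame(fov_scaffold))
    fov_scaffold <- setNames(fov_scaffold$scaffold_id,
                             fov_scaffold$fov_id)
  chans <- grep("^total_", names(records), value = TRUE)
  if (nrow(records) > 0 &&
      !all(as.character(records$fov_id) %in% names(fov_scaffold)))
    abort_input("records reference FOVs absent from the fov -> scaffold map")
  fov_ids <- names(fov_scaffold)
  fs <- do.call(rbind, lapply(fov_ids, function(f) {
    sub <- records[as.character(records$fov_id) == f, , drop = FALSE]
    if (nrow(sub) == 0L) return(NULL)
    out <- data.frame(fov_id = f,
                      scaffold_id = as.character(fov_scaffold[[f]]),
                      n_microtissues = nrow(sub))
    for (ch in chans) out[[ch]] <- mean(sub[[ch]])
    out
  }))
  empty <- setdiff(fov_ids, if (is.null(fs)) character(0) else fs$fov_id)
  if (length(empty))
    message("excluding ", length(empty),
            " FOV(s) with zero microtissues: ", paste(empty, collapse = ", "))
  if (is.null(fs))
    return(list(fov_summaries = NULL, scaffold_summaries = NULL,
                empty_fovs = empty))
  ss <- do.call(rbind, lapply(unique(fs$scaffold_id), function(s) {
    sub <- fs[fs$scaffold_id == s, , drop = FALSE]
    out <- data.frame(scaffold_id = s,
                      condition = as.character(scaffold_condition[[s]]),
                      n_fovs = nrow(sub),
                      n_microtissues = sum(sub$n_microtissues))
    for (ch in chans) out[[ch]] <- mean(sub[[ch]])
    out
  }))
  list(fov_summaries = fs, scaffold_summaries = ss, empty_fovs = empty)
}

#' Compare per-scaffold marker means between conditions
#'
#' Fold-change is the ratio of condition means of scaffold summaries to the
#' reference condition's mean; percent change is `(1 - cond/ref) * 100`
#' (positive = reduction under treatment).  A zero reference mean yields a
#' flagged `NA` fold rather than an error.  A two-sided Welch t-test
#' p-value across scaffolds is attached when both groups have >= 2
#' scaffolds.
#'
#' @param scaffold_summaries From [summarize_microtissues()].
#' @param reference_condition Label of the reference condition.
#' @return Data frame: channel, condition, fold_change, percent_change,
#'   p_value, n_scaffolds, undefined_fold flag.
#' @export
compare_conditions <- function(scaffold_summaries, reference_condition) {
  ss <- scaffold_summaries
  if (!reference_condition %in% ss$condition)
    abort_input("reference condition '%s' absent", reference_condition)
  chans <- grep("^total_", names(ss), value = TRUE)
  conds <- setdiff(unique(ss$condition), reference_condition)
  out <- list()
  for (ch in chans) {
    ref_vals <- ss[[ch]][ss$condition == reference_condition]
    for (cond in conds) {
      vals <- ss[[ch]][ss$condition == cond]
      undef <- mean(ref_vals) == 0
      fold <- if (undef) NA_real_ else mean(vals) / mean(ref_vals)
      pct <- if (undef) NA_real_ else (1 - mean(vals) / mean(ref_vals)) * 100
      p <- if (length(vals) >= 2 && length(ref_vals) >= 2 &&
               (sd(vals) > 0 || sd(ref_vals) > 0))
        stats::t.test(vals, ref_vals)$p.value else NA_real_
      out[[length(out) + 1L]] <- data.frame(
        channel = sub("^total_", "", ch), condition = cond,
        fold_change = fold, percent_change = pct, p_value = p,
        n_scaffolds = length(vals), undefined_fold = undef)
    }
  }
  do.call(rbind, out)
}
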