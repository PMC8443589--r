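# Shared small fixture: 2x2 slide with two scaffolds, used by several blocks.
slide <- gen_slide(slide_spec(grid_rows = 2, grid_cols = 2,
                              overlap_frac = 0.1,
                              scaffold_centers = list(c(120, 120),
                                                      c(240, 240)),
                              scaffold_radius_px = 55, seed = 3))

test_that("stitch_tiles recovers generator offsets and validates its input", {
  # single tile: identity
  one <- list(list(pixels = matrix(1:9, 3), grid_pos = c(0L, 0L),
                   channel = "nuclei"))
  m1 <- stitch_tiles(one, overlap_frac = 0, refine = FALSE)
  expect_equal(m1$pixels, one[[1]]$pixels)
  expect_equal(m1$tile_offsets, matrix(0L, 1, 2))

  # noise-free fixture: refined offsets equal truth exactly, dims match
  mo <- stitch_tiles(slide$tiles, 0.1)
  expect_identical(mo$tile_offsets, slide$truth$tile_offsets)
  expect_equal(dim(mo$pixels), slide$truth$mosaic_dim)
  # blended mosaic reproduces the generator's canvas where truth is known
  expect_lt(max(abs(mo$pixels - slide$mosaic)), 1e-9)

  # missing grid cell is an input error naming the gap
  expect_error(stitch_tiles(slide$tiles[-2], 0.1), "missing cell")
  # zero overlap with refinement requested: warning + nominal offsets
  t0 <- list(list(pixels = matrix(runif(64), 8), grid_pos = c(0L, 0L),
                  channel = "n"),
             list(pixels = matrix(runif(64), 8), grid_pos = c(0L, 1L),
                  channel = "n"))
  expect_warning(m0 <- stitch_tiles(t0, 0), "nominal")
  expect_equal(m0$tile_offsets[2, ], c(0L, 8L))
})

test_that("detect_scaffolds finds fixture scaffolds accurately, in row-major order", {
  expect_length(detect_scaffolds(matrix(100, 64, 64), 20), 0L)
  mo <- stitch_tiles(slide$tiles, 0.1)
  dets <- detect_scaffolds(mo, 55)
  expect_length(dets, 2L)
  for (i in 1:2) {
    truth <- slide$truth$scaffolds[[i]]
    expect_lt(max(abs(dets[[i]]$centre - truth$centre)), 2)
    expect_lt(abs(dets[[i]]$radius_px - truth$radius) / truth$radius, 0.05)
  }
  # row-major ordering by centre
  expect_lt(dets[[1]]$centre[1], dets[[2]]$centre[1])
})

test_that("place_rois applies the template with translation equivariance", {
  det <- list(centre = c(100, 100))
  template <- slide$truth$spec$roi_template
  rs <- place_rois(det, template, roi_size_px = 20, mosaic_dim = c(400, 400))
  expect_equal(nrow(rs$centres), 8L)
  # translated scaffold: every ROI centre translated by the same vector
  rs2 <- place_rois(list(centre = c(130, 80)), template, 20, c(400, 400))
  expect_equal(rs2$centres, rs$centres +
                 matrix(rep(c(30, -20), each = 8), ncol = 2))
  # single-offset template at the origin-side centre
  rs3 <- place_rois(list(centre = c(50, 50)), list(c(0, 0)), 10, c(100, 100))
  expect_equal(rs3$centres, matrix(c(50, 50), 1))
  # out-of-bounds ROI errors with its index
  expect_error(place_rois(list(centre = c(5, 5)), list(c(0, 0), c(-10, 0)),
                          20, c(400, 400)), "ROI 1")
})

test_that("select_focus maximises variance-of-Laplacian with stated tie-breaks", {
  sp <- stack_spec(in_focus_plane = 12L, noise_cv = 0.02, seed = 9)
  zs <- gen_zstack(sp)
  foc <- select_focus(zs$stack)
  expect_equal(foc$plane_idx, 12L)
  expect_false(foc$degenerate)
  # invariance under positive affine intensity rescaling
  resc <- zs$stack
  resc$pixels$nuclei <- resc$pixels$nuclei * 3.7 + 50
  expect_equal(select_focus(resc)$plane_idx, 12L)
  # single plane
  s1 <- list(pixels = list(nuclei = array(runif(64), c(1, 8, 8))))
  expect_equal(select_focus(s1)$plane_idx, 0L)
  # constant stack: plane 0, flagged
  sc <- list(pixels = list(nuclei = array(5, c(4, 8, 8))))
  fc <- select_focus(sc)
  expect_equal(fc$plane_idx, 0L)
  expect_true(fc$degenerate)
  expect_error(select_focus(zs$stack, channel = "nope"), "nope")
})

test_that("segmentation recovers exact object counts on noise-free FOVs", {
  expect_equal(nrow(segment_microtissues(matrix(7, 50, 50))$records), 0L)
  for (seed in c(7, 8, 9)) {
    sp <- stack_spec(n_planes = 3, z_step_um = 5, depth_um = 10,
                     in_focus_plane = 1, noise_cv = 0, seed = seed)
    zs <- gen_zstack(sp)
    seg <- segment_microtissues(zs$stack$pixels$nuclei[2, , ])
    expect_equal(nrow(seg$records), nrow(zs$truth$centres))
    expect_true(all(seg$records$area_px >= 100))
  }
})

test_that("measure_intensity is background-subtracted and truth-accurate", {
  sp <- stack_spec(n_planes = 3, z_step_um = 5, depth_um = 10,
                   in_focus_plane = 1, noise_cv = 0, seed = 7)
  zs <- gen_zstack(sp)
  foc <- select_focus(zs$stack)
  seg <- segment_microtissues(zs$stack$pixels$nuclei[2, , ])
  rec <- measure_intensity(seg$labels, seg$records, zs$stack, foc,
                           channels = c("nuclei", "asma", "collagen1"))
  # truth centres are row-major sorted, matching label order
  for (ch in c("nuclei", "asma", "collagen1")) {
    rel <- abs(rec[[paste0("total_", ch)]] - zs$truth$intensity[, ch]) /
      zs$truth$intensity[, ch]
    expect_lt(max(rel), 0.01)
  }
  expect_false(any(rec$clamped))
  # uniform image with any mask: total ~ 0 after background subtraction
  flat <- list(pixels = list(x = array(123, c(1, 40, 40))))
  lab <- matrix(0L, 40, 40); lab[5:15, 5:15] <- 1L
  r0 <- segment_microtissues(matrix(0, 40, 40))$records  # empty skeleton
  rec0 <- measure_intensity(lab, data.frame(fov_id = 1, label = 1,
                                            area_px = 121,
                                            centroid_row = 9,
                                            centroid_col = 9),
                            flat, list(plane_idx = 0L), channels = "x")
  expect_equal(rec0$total_x, 0)
  expect_error(measure_intensity(lab, r0, flat, list(plane_idx = 0L),
                                 channels = "missing"), "missing")
})

test_that("two objects with a known truth ratio are measured within 5%", {
  # paired stacks differing only in one channel's fold: measured ratio of
  # matched objects must track the construction
  a <- gen_zstack(stack_spec(n_planes = 3, z_step_um = 5, depth_um = 10,
                             in_focus_plane = 1, noise_cv = 0, seed = 31))
  b <- gen_zstack(stack_spec(n_planes = 3, z_step_um = 5, depth_um = 10,
                             in_focus_plane = 1, noise_cv = 0, seed = 31,
                             condition_fold = c(asma = 3)))
  fa <- select_focus(a$stack); fb <- select_focus(b$stack)
  sa <- segment_microtissues(a$stack$pixels$nuclei[2, , ])
  sb <- segment_microtissues(b$stack$pixels$nuclei[2, , ])
  ra <- measure_intensity(sa$labels, sa$records, a$stack, fa, "asma")
  rb <- measure_intensity(sb$labels, sb$records, b$stack, fb, "asma")
  ratio <- rb$total_asma / ra$total_asma
  expect_true(all(abs(ratio - 3) / 3 < 0.05))
})

test_that("summaries average per FOV then unweighted per scaffold", {
  rec <- data.frame(fov_id = c(1, 2, 2, 2), label = 1:4, area_px = 100,
                    centroid_row = 0, centroid_col = 0,
                    total_asma = c(2, 4, 4, 4))
  fs <- setNames(c("s1", "s1"), c("1", "2"))
  cond <- c(s1 = "nash")
  sm <- summarize_microtissues(rec, fs, cond)
  expect_equal(sm$fov_summaries$total_asma, c(2, 4))
  # unweighted mean of FOV means, not of pooled microtissues
  expect_equal(sm$scaffold_summaries$total_asma, 3)
  expect_equal(sm$scaffold_summaries$n_microtissues, 4)
  # an empty FOV is excluded and reported
  fs3 <- setNames(c("s1", "s1", "s1"), c("1", "2", "3"))
  expect_message(sm3 <- summarize_microtissues(rec, fs3, cond), "zero microtissues")
  expect_equal(sm3$empty_fovs, "3")
  expect_equal(sm3$scaffold_summaries$total_asma, 3)
})

test_that("compare_conditions computes folds, percent change and flags", {
  ss <- data.frame(scaffold_id = c("a", "b", "c", "d"),
                   condition = c("ctrl", "ctrl", "trt", "trt"),
                   n_fovs = 2, n_microtissues = 10,
                   total_asma = c(10, 10, 5, 5))
  cmp <- compare_conditions(ss, "ctrl")
  expect_equal(cmp$fold_change, 0.5)
  expect_equal(cmp$percent_change, 50)  # treated = half of control
  # identical conditions: fold exactly 1
  ss$total_asma <- 7
  expect_equal(compare_conditions(ss, "ctrl")$fold_change, 1)
  # zero reference mean: flagged, not a number
  ss$total_asma <- c(0, 0, 5, 5)
  cmp0 <- compare_conditions(ss, "ctrl")
  expect_true(cmp0$undefined_fold)
  expect_true(is.na(cmp0$fold_change))
  expect_error(compare_conditions(ss, "nope"), "nope")
})

test_that("spatial translation shifts coordinates, not intensities", {
  sp <- stack_spec(n_planes = 1, z_step_um = 5, depth_um = 0,
                   in_focus_plane = 0, noise_cv = 0, seed = 13)
  zs <- gen_zstack(sp)
  shift <- c(6, -4)
  lay2 <- list(fov_id = 1L, scaffold_id = 1L, roi_idx = 1L,
               centres = sweep(zs$truth$centres, 2, -shift),
               radii = zs$truth$radii)
  zs2 <- gen_zstack(sp, lay2)
  seg1 <- segment_microtissues(zs$stack$pixels$nuclei[1, , ])
  seg2 <- segment_microtissues(zs2$stack$pixels$nuclei[1, , ])
  foc <- list(plane_idx = 0L)
  r1 <- measure_intensity(seg1$labels, seg1$records, zs$stack, foc, "asma")
  r2 <- measure_intensity(seg2$labels, seg2$records, zs2$stack, foc, "asma")
  # order can change (row-major by centroid): match objects by position
  key1 <- order(r1$centroid_row, r1$centroid_col)
  m2 <- r2[order(r2$centroid_row, r2$centroid_col), ]
  m1 <- r1[key1, ]
  expect_equal(m2$centroid_row, m1$centroid_row + shift[1], tolerance = 0.1)
  expect_equal(m2$centroid_col, m1$centroid_col + shift[2], tolerance = 0.1)
  expect_equal(m2$total_asma, m1$total_asma, tolerance = 0.01)
})
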