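test_that("clean phantom slices segment with high fidelity against ground truth", {
  ph <- std_phantom()
  seg <- std_slice_seg()
  z <- 3
  expect_gte(dice(seg$wall_mask, ph$truth$masks$wall[, , z]), 0.98)
  expect_gte(dice(seg$media_mask, ph$truth$masks$media[, , z]), 0.98)
  tr <- ph$truth$per_slice
  ctr <- attr(seg$lumen_contour, "center")
  expect_lt(abs(ctr[1] - tr$center_row[z]), 0.5)
  expect_lt(abs(ctr[2] - tr$center_col[z]), 0.5)
  # lamellar pixel recovery within 5% of the true ring pixel count
  expect_lt(abs(sum(seg$lamellae_mask) / sum(ph$truth$masks$lamellae[, , z]) - 1),
            0.05)
})

test_that("segmentation set invariants hold on every slice, both paths", {
  ph <- std_phantom()
  cfg <- std_config()
  for (z in 1:2) {
    seg <- segment_slice(ph$grid$data[, , z], cfg)
    expect_true(check_segmentation_invariants(seg))
    # exact pixel-count partition of the wall
    expect_identical(sum(seg$media_mask) + sum(seg$adventitia_mask),
                     sum(seg$wall_mask))
  }
  fb <- segment_dilated_fallback(ph$grid$data[, , 1], cfg)
  expect_false(any(fb$lumen_mask & fb$wall_mask))
})

test_that("degenerate slices raise empty-slice / no-contrast errors", {
  cfg <- std_config()
  expect_error(segment_wall(matrix(100, 64, 64), cfg),
               class = "aortamorph_empty_slice")
  img <- std_phantom()$grid$data[, , 1]
  media <- std_slice_seg()$media_mask
  expect_error(segment_lamellae(matrix(42, nrow(img), ncol(img)), media, cfg),
               class = "aortamorph_no_contrast")
})

test_that("exclusion masks neutralise artefacts outside the vessel", {
  ph <- std_phantom()
  cfg <- std_config()
  img <- ph$grid$data[, , 3]
  clean_wall <- segment_wall(img, cfg)
  dirty <- img
  dirty[10:30, 10:30] <- 230  # bright dust speck far from the vessel
  excl <- matrix(FALSE, nrow(img), ncol(img))
  excl[5:35, 5:35] <- TRUE
  expect_identical(segment_wall(dirty, cfg, exclusion_mask = excl), clean_wall)
})

test_that("segmentation is invariant to affine intensity rescaling", {
  ph <- std_phantom()
  cfg <- std_config()
  img <- ph$grid$data[, , 2]
  a <- segment_slice(img, cfg)
  b <- segment_slice(img * 3.7 + 1200, cfg)
  expect_identical(a$wall_mask, b$wall_mask)
  expect_identical(a$media_mask, b$media_mask)
  expect_identical(a$lamellae_mask, b$lamellae_mask)
})

test_that("open walls are detected and signal the fallback", {
  ph <- std_phantom()
  img <- ph$grid$data[, , 1]
  wall <- segment_wall(img, std_config())
  # cut a 10-px gap through the wall (upper half of a 10-column swath)
  ctr <- round(dim(wall) / 2)
  gap <- wall
  gap[1:ctr[1], ctr[2]:(ctr[2] + 9)] <- FALSE
  expect_error(segment_lumen(img, gap), class = "aortamorph_open_wall")
})

test_that("the media-adventitia rule reproduces closed-form expectations", {
  cfg <- std_config()
  ann <- ideal_annulus(c(320, 320), r_in = 100, r_out = 140)
  res <- media_adventitia_limit(ann$wall, ann$lumen, cfg)
  expect_equal(res$min_wall_thickness_px, 40, tolerance = 0.05)
  # media outer radius = 100 + 20 + round(0.35 * 40) = 134, within 1 px
  expect_equal(mean(res$contour$r), 134, tolerance = 1)
  expect_true(all(res$media_mask[ann$wall == FALSE] == FALSE))
  expect_gt(sum(res$adventitia_mask), 0)
})

test_that("circumferentially varying walls use the minimum thickness", {
  # outer boundary is an ellipse: thickness varies ~40..60 around the ring
  dims <- c(360, 360); ctr <- (dims + 1) / 2
  rows <- matrix(seq_len(dims[1]), dims[1], dims[2])
  cols <- matrix(seq_len(dims[2]), dims[1], dims[2], byrow = TRUE)
  r <- sqrt((rows - ctr[1])^2 + (cols - ctr[2])^2)
  th <- atan2(rows - ctr[1], cols - ctr[2])
  r_out <- 100 + 40 + 20 * cos(th)^2
  wall <- r >= 100 & r <= r_out
  lumen <- r < 100
  res <- media_adventitia_limit(wall, lumen, std_config())
  expect_equal(res$min_wall_thickness_px, 40, tolerance = 0.6)
  # dilation radius = round(0.35 * min) = 14 everywhere: at the thin angle the
  # media radius is 100 + 20 + 14 = 134 within discretisation
  thin <- abs(aortamorph:::angle_diff(res$contour$theta, pi / 2)) < 0.1
  expect_equal(mean(res$contour$r[thin]), 134, tolerance = 1.2)
  expect_error(media_adventitia_limit(ideal_annulus(c(64, 64), 20, 22)$wall,
                                      ideal_annulus(c(64, 64), 20, 22)$lumen,
                                      std_config()),
               class = "aortamorph_wall_too_thin")
})

test_that("the watershed fallback closes dilated and damaged vessels", {
  cfg <- std_config()
  ph <- std_phantom()
  img <- ph$grid$data[, , 3]
  std <- segment_slice(img, cfg)
  fb <- segment_dilated_fallback(img, cfg)
  # path consistency on a circular slice
  expect_gte(dice(fb$lumen_mask, std$lumen_mask), 0.98)
  expect_lt(abs(sum(fb$lumen_mask) / (pi * 50^2) - 1), 0.03)
  # a wall broken over > 90 degrees is unclosable
  dims <- dim(img)
  rows <- matrix(seq_len(dims[1]), dims[1], dims[2])
  cols <- matrix(seq_len(dims[2]), dims[1], dims[2], byrow = TRUE)
  th <- atan2(rows - (dims[1] + 1) / 2, cols - (dims[2] + 1) / 2)
  broken <- img
  broken[abs(th) < pi / 3.5] <- 40
  expect_error(segment_dilated_fallback(broken, cfg),
               class = "aortamorph_fallback_failed")
})

test_that("limit overrides anchor the axial smoothing spline", {
  ph <- cached("override_ph", generate_phantom(
    phantom_spec(n_slices = 12, slice_shape = c(192, 192), lumen_radius_px = 40,
                 wall_thickness_px = 20, n_lamellae = 3, lamella_thickness_px = 2.5,
                 voxel_size_um = 1), include_masks = FALSE))
  cfg <- pipeline_config(voxel_size_um = 1, central_window_n_slices = 12,
                         angular_samples = 180)
  seg <- cached("override_seg", segment_stack(ph$grid, cfg))
  # fixed point: overriding with the automatic contour changes nothing
  seg_fp <- apply_limit_override(seg, 6, seg$slices[[6]]$media_adventitia_contour)
  for (z in c(2, 6, 10)) {
    expect_equal(seg_fp$slices[[z]]$media_adventitia_contour$r,
                 seg$slices[[z]]$media_adventitia_contour$r, tolerance = 1e-8)
  }
  # pushing slice 6 outward by 5 px shifts neighbours with decaying magnitude
  ov <- seg$slices[[6]]$media_adventitia_contour
  ov$r <- ov$r + 5
  attr(ov, "center") <- attr(seg$slices[[6]]$media_adventitia_contour, "center")
  seg2 <- apply_limit_override(seg, 6, ov)
  shift <- vapply(1:12, function(z)
    mean(seg2$slices[[z]]$media_adventitia_contour$r -
           seg$slices[[z]]$media_adventitia_contour$r), numeric(1))
  expect_equal(shift[6], 5, tolerance = 0.3)
  expect_true(abs(shift[7]) < shift[6])
  expect_true(abs(shift[9]) < abs(shift[7]))
  expect_identical(seg2$slices[[6]]$provenance, "override")
  # an override that does not enclose the lumen is rejected
  bad <- seg$slices[[6]]$lumen_contour
  bad$r <- bad$r * 0.5
  attr(bad, "center") <- attr(seg$slices[[6]]$lumen_contour, "center")
  expect_error(apply_limit_override(seg, 6, bad),
               class = "aortamorph_invalid_override")
})
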