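break_spec <- function(...) {
  phantom_spec(n_slices = 24, slice_shape = c(224, 224), lumen_radius_px = 45,
               wall_thickness_px = 28, n_lamellae = 3, lamella_thickness_px = 2.5,
               voxel_size_um = 1, ...)
}

iel_cfg <- function(...) {
  pipeline_config(voxel_size_um = 1, central_window_n_slices = 24,
                  reslice = FALSE, ...)
}

broken_run <- function() cached("iel_broken", {
  sp <- break_spec(breaks = list(
    list(slice_start = 5, slice_end = 10, theta_start_deg = 30,
         theta_end_deg = 60, lamellae = 1:2),
    list(slice_start = 14, slice_end = 21, theta_start_deg = 200,
         theta_end_deg = 245, lamellae = 1L)))
  run_iel(sp, iel_cfg())
})

test_that("the IEL shell hugs the lumen border with the configured extent", {
  ph <- std_phantom()
  cfg <- std_config()
  seg <- segment_stack(ph$grid, cfg)
  shell <- extract_iel(seg, iel_dilation_px = 7)
  z <- 3
  expect_true(all(shell[, , z][!seg$slices[[z]]$wall_mask] == FALSE))
  # radial extent of the shell along a ray: about 7-8 px beyond the border
  ctr <- attr(seg$slices[[z]]$lumen_contour, "center")
  idx <- which(shell[, , z], arr.ind = TRUE)
  rr <- sqrt((idx[, 1] - ctr[1])^2 + (idx[, 2] - ctr[2])^2)
  expect_lt(max(rr) - min(rr), 9.5)
  expect_gt(max(rr) - min(rr), 6.5)
  # dilation 0 keeps just the 1-px border
  shell0 <- extract_iel(seg, iel_dilation_px = 0)
  expect_lt(mean(apply(shell0, 3, sum)), mean(apply(shell, 3, sum)) / 4)
  expect_gt(sum(shell0[, , z]), 0)
})

test_that("the en-face projection of an intact IEL is uniformly bright", {
  sp <- break_spec()
  run <- cached("iel_intact", run_iel(sp, iel_cfg()))
  expect_true(all(run$surface$valid))
  lv <- sp$intensity
  expect_gt(stats::median(run$surface$image), lv$interlamellar)
  expect_equal(nrow(run$breaks), 0L)
  expect_equal(run$pct, 0)
})

test_that("IEL holes appear at their true en-face coordinates", {
  run <- broken_run()
  expect_equal(nrow(run$breaks), 2L)
  b <- run$breaks[order(run$breaks$slice_min), ]
  expect_true(b$slice_min[1] >= 4 && b$slice_max[1] <= 11)
  expect_true(b$theta_min_deg[1] >= 25 && b$theta_max_deg[1] <= 65)
  expect_true(b$slice_min[2] >= 13 && b$slice_max[2] <= 22)
  expect_true(b$theta_min_deg[2] >= 195 && b$theta_max_deg[2] <= 250)
  # total detected area within 10% of the analytic truth
  tr <- run$truth$breaks
  expect_lt(abs(sum(run$breaks$area_um2) / sum(tr$enface_area_um2) - 1), 0.1)
})

test_that("enlarging a hole strictly increases the detected break fraction", {
  small <- cached("iel_small_hole", run_iel(break_spec(breaks = list(
    list(slice_start = 8, slice_end = 14, theta_start_deg = 100,
         theta_end_deg = 130, lamellae = 1L))), iel_cfg()))
  big <- cached("iel_big_hole", run_iel(break_spec(breaks = list(
    list(slice_start = 6, slice_end = 16, theta_start_deg = 90,
         theta_end_deg = 150, lamellae = 1L))), iel_cfg()))
  expect_gt(big$pct, small$pct)
  expect_gt(small$pct, 0)
})

test_that("manual break masks bypass detection with exact pass-through", {
  run <- cached("iel_intact", run_iel(break_spec(), iel_cfg()))
  surf <- run$surface
  # force a uniform arc pitch so a 5% pixel mask is exactly 5% of the area
  surf$arc_pitch_um <- rep(mean(surf$arc_pitch_um), length(surf$arc_pitch_um))
  manual <- matrix(FALSE, nrow(surf$image), ncol(surf$image))
  manual[, 1:18] <- TRUE  # 18 of 360 columns = 5%
  qb <- quantify_breaks(surf, pipeline_config(min_break_area_um2 = 0),
                        manual_mask = manual)
  expect_equal(qb$pct, 5, tolerance = 1e-9)
})

test_that("surfaces dominated by breaks are flagged but still quantified", {
  run <- cached("iel_intact", run_iel(break_spec(), iel_cfg()))
  manual <- matrix(TRUE, nrow(run$surface$image), ncol(run$surface$image))
  expect_warning(qb <- quantify_breaks(run$surface,
                                       pipeline_config(min_break_area_um2 = 0),
                                       manual_mask = manual),
                 "dominated")
  expect_true(qb$dominated)
  expect_equal(qb$pct, 100, tolerance = 1e-9)
})
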