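test_that("the distance transform is exactly Euclidean", {
  # single foreground pixel: distance 1 to the adjacent background
  m <- matrix(0, 9, 9); m[5, 5] <- 1
  expect_equal(euclidean_distance_transform(m)[5, 5], 1)
  expect_true(all(euclidean_distance_transform(matrix(0, 6, 6)) == 0))
  # solid disk: centre distance equals the inradius
  ann <- ideal_annulus(c(101, 101), r_in = 0, r_out = 40)
  d <- euclidean_distance_transform(ann$r <= 40)
  expect_equal(max(d), 40, tolerance = 0.5)
  # random masks match the brute-force oracle exactly
  set.seed(31)
  for (i in 1:20) {
    m <- matrix(runif(32 * 32) > 0.6, 32, 32)
    expect_equal(euclidean_distance_transform(m), edt_brute_force(m),
                 tolerance = 1e-12)
  }
})

test_that("thickness along normals recovers analytic band heights", {
  # 34-px band at 1.1 um voxels: fitted mean 37.4 um, negligible SD
  lum <- circle_contour(100, center = c(200, 200), n_theta = 360)
  med <- circle_contour(134, center = c(200, 200), n_theta = 360)
  td <- media_thickness(lum, med, voxel_size_um = 1.1)
  expect_equal(td$mean_um, 37.4, tolerance = 0.6)
  expect_lt(td$sd_um, 0.6)
  expect_equal(td$n_samples, 360)
  expect_equal(td$n_dropped, 0)

  # sinusoidally varying 30..50 px: mean ~ 40, samples bracket the extremes
  med2 <- circle_contour(100, center = c(200, 200), n_theta = 360,
                         r_fun = function(th) 140 + 10 * sin(4 * th))
  lum2 <- circle_contour(100, center = c(200, 200), n_theta = 360)
  td2 <- media_thickness(lum2, med2, voxel_size_um = 1)
  expect_equal(td2$sample_mean_um, 40, tolerance = 1)
  expect_lte(min(td2$samples$thickness_um), 31)
  expect_gte(max(td2$samples$thickness_um), 49)

  # degenerate: all samples identical -> SD bounded by the bin width
  g <- glance(td)
  expect_s3_class(g, "tbl_df")
  expect_equal(nrow(tidy(td)), 360)
})

test_that("areas and fractions are exact pixel arithmetic", {
  m <- matrix(FALSE, 50, 50); m[1:40, 1:25] <- TRUE  # 1000 px
  expect_equal(cross_sectional_area(m, 1.1), 1210)
  expect_equal(cross_sectional_area(matrix(FALSE, 5, 5), 1.1), 0)

  media <- matrix(FALSE, 30, 30); media[5:24, 5:24] <- TRUE
  lam <- media & row(media) < 10
  fr <- lamellae_fraction(lam, media, 1)
  expect_equal(fr$lamellae_area_um2 + fr$interlamellar_area_um2,
               fr$media_area_um2)
  expect_equal(fr$lamellae_pct, 100 * sum(lam) / sum(media))
  expect_equal(lamellae_fraction(media, media, 1)$lamellae_pct, 100)
  empty <- lamellae_fraction(media & FALSE, media, 1)
  expect_equal(empty$lamellae_pct, 0)
  expect_equal(empty$interlamellar_area_um2, empty$media_area_um2)
  bad <- media; bad[1, 1] <- TRUE
  expect_error(lamellae_fraction(bad, media, 1),
               class = "aortamorph_invariant_violation")
})

test_that("ellipse-mean-axes diameter matches closed forms", {
  ct <- circle_contour(100, center = c(150, 150), n_theta = 180)
  expect_equal(lumen_diameter(ct, 1)$diameter_um, 200, tolerance = 0.5)
  # true ellipse with semi-axes 100 / 60: diameter (200 + 120) / 2
  th <- seq(0, 2 * pi, length.out = 91)[-91]
  ell <- tibble::tibble(theta = th, r = NA,
                        row = 150 + 60 * sin(th), col = 150 + 100 * cos(th))
  attr(ell, "center") <- c(150, 150)
  class(ell) <- c("vessel_contour", class(ell))
  d <- lumen_diameter(ell, 1)
  expect_equal(d$diameter_um, 160, tolerance = 0.5)
  expect_equal(d$major_axis_um, 200, tolerance = 0.5)
  # wrinkles average out in the fit
  wr <- circle_contour(100, center = c(150, 150), n_theta = 360,
                       r_fun = function(t) 100 + 5 * sin(12 * t))
  expect_equal(lumen_diameter(wr, 1)$diameter_um, 200, tolerance = 4)
})

test_that("physical outputs are scale-equivariant in the voxel size", {
  seg <- std_slice_seg()
  a <- measure_slice(seg, voxel_size_um = 1.1)$record
  b <- measure_slice(seg, voxel_size_um = 2.2)$record
  expect_equal(b$lumen_diameter_um, 2 * a$lumen_diameter_um, tolerance = 1e-9)
  expect_equal(b$media_area_um2, 4 * a$media_area_um2, tolerance = 1e-9)
  expect_equal(b$lamellae_pct, a$lamellae_pct, tolerance = 1e-9)
  expect_equal(b$media_thickness_um, 2 * a$media_thickness_um, tolerance = 0.02)
})

test_that("stack summaries aggregate records as documented", {
  rec <- measure_slice(std_slice_seg(), slice = 1, voxel_size_um = 1)$record
  recs <- dplyr::bind_rows(rec, rec, rec)
  recs$slice <- 1:3
  s <- summarize_stack(recs)
  expect_true(all(s$summary$sd == 0))
  expect_equal(s$summary$mean[s$summary$parameter == "lumen_diameter_um"],
               rec$lumen_diameter_um)
  # single-slice window: mean = value, SD = 0 by convention
  s1 <- summarize_stack(rec)
  expect_true(all(s1$summary$sd == 0))
  expect_equal(s1$summary$n[1], 1)
})
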