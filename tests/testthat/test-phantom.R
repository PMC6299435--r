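test_that("phantom generation is deterministic for identical spec and seed", {
  sp <- phantom_spec(n_slices = 3, slice_shape = c(96, 96), lumen_radius_px = 20,
                     wall_thickness_px = 10, n_lamellae = 2, lamella_thickness_px = 2,
                     voxel_size_um = 1, noise_sigma = 8, seed = 42L)
  a <- generate_phantom(sp, include_masks = FALSE)
  b <- generate_phantom(sp, include_masks = FALSE)
  expect_identical(a$grid$data, b$grid$data)
  # different seed changes the noise
  sp2 <- phantom_spec(n_slices = 3, slice_shape = c(96, 96), lumen_radius_px = 20,
                      wall_thickness_px = 10, n_lamellae = 2, lamella_thickness_px = 2,
                      voxel_size_um = 1, noise_sigma = 8, seed = 43L)
  expect_false(identical(a$grid$data,
                         generate_phantom(sp2, include_masks = FALSE)$grid$data))
})

test_that("noise-free rendering respects the contrast ordering everywhere", {
  ph <- std_phantom()
  lv <- std_spec()$intensity
  expect_gte(min(ph$grid$data), lv$paraffin)
  expect_lte(max(ph$grid$data), lv$lamella)
  # lamellar mask pixels are brighter than interlamellar matrix pixels
  z <- 3
  img <- ph$grid$data[, , z]
  lam <- ph$truth$masks$lamellae[, , z]
  matrix_px <- ph$truth$masks$media[, , z] & !lam
  # compare the interior (fully covered) pixels, away from antialiased edges
  expect_gt(stats::median(img[lam]), stats::median(img[matrix_px]))
})

test_that("spec invariants are enforced", {
  expect_error(phantom_spec(wall_thickness_px = 5, n_lamellae = 3,
                            lamella_thickness_px = 4),
               class = "aortamorph_invalid_spec")
  expect_error(phantom_spec(slice_shape = c(128, 128), lumen_radius_px = 100),
               class = "aortamorph_invalid_spec")
  expect_error(phantom_spec(intensity = list(paraffin = 200, interlamellar = 120,
                                             lamella = 250, adventitia = 100)),
               class = "aortamorph_invalid_spec")
})

test_that("ground-truth diameters follow the generating geometry", {
  sp <- phantom_spec(n_slices = 64, slice_shape = c(320, 320),
                     lumen_radius_px = 100, wall_thickness_px = 40,
                     n_lamellae = 3, lamella_thickness_px = 4, voxel_size_um = 1)
  tr <- analytic_morphometry(sp)
  expect_equal(tr$per_slice$diameter_um, rep(200, 64))
  spd <- phantom_spec(n_slices = 64, slice_shape = c(480, 480),
                      lumen_radius_px = 100, wall_thickness_px = 40,
                      n_lamellae = 3, lamella_thickness_px = 4, voxel_size_um = 1,
                      dilation = list(start_slice = 40, end_slice = 60,
                                      max_scale = 1.5))
  trd <- analytic_morphometry(spd)
  expect_equal(max(trd$per_slice$diameter_um), 300, tolerance = 1e-6)
  expect_equal(min(trd$per_slice$diameter_um), 200, tolerance = 1e-6)
})

test_that("rendered wrinkled boundary tracks the generating radius function", {
  ph <- wrinkled_phantom(5)
  seg <- segment_slice(ph$grid$data[, , 1], std_config())
  ct <- seg$lumen_contour
  r_true <- 100 + 5 * sin(12 * ct$theta)
  expect_lt(sqrt(mean((ct$r - r_true)^2)), 1)
})

test_that("analytic areas: quadrature equals closed forms and partitions exactly", {
  # degenerate (zero-amplitude wrinkle): quadrature equals the annulus formula
  sp <- std_spec()
  tr <- analytic_morphometry(sp)
  Tm <- sp$media_thickness_px
  closed <- pi * ((50 + Tm)^2 - 50^2)
  expect_equal(tr$per_slice$media_area_um2[1], closed, tolerance = 1e-6)
  # exact partition and bounded fraction
  expect_equal(tr$per_slice$lamellae_area_um2 + tr$per_slice$interlamellar_area_um2,
               tr$per_slice$media_area_um2, tolerance = 1e-9)
  expect_true(all(tr$per_slice$lamellae_pct >= 0 & tr$per_slice$lamellae_pct <= 100))
  # symmetric ring placement: fraction is exactly n t / T
  expect_equal(tr$per_slice$lamellae_pct[1], 100 * 3 * 3 / Tm, tolerance = 1e-6)
  # wrinkles do not change the fraction (uniform radial shift of all rings)
  spw <- std_spec(wrinkle = list(amplitude_px = 4, frequency = 9))
  trw <- analytic_morphometry(spw)
  expect_equal(trw$per_slice$lamellae_pct[1], 100 * 3 * 3 / Tm, tolerance = 1e-5)
})

test_that("three 4-px lamellae spread over a 40-px media occupy exactly 30%", {
  expect_equal(ring_area_fraction(100, 40, 3, 4), 30, tolerance = 1e-12)
})

test_that("rendered mask mass matches analytic area within the perimeter bound", {
  ph <- std_phantom()
  sp <- std_spec()
  tr <- ph$truth$per_slice
  for (z in c(1, 4)) {
    px <- sum(ph$truth$masks$media[, , z])
    perim <- 2 * pi * (2 * 50 + sp$media_thickness_px)  # both circumferences
    expect_lt(abs(px - tr$media_area_um2[z]), perim)
  }
})

test_that("phantom specs round-trip through YAML config files", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("n_slices: 4", "slice_shape: [128, 128]", "lumen_radius_px: 30",
               "wall_thickness_px: 12", "n_lamellae: 2", "lamella_thickness_px: 2",
               "voxel_size_um: 1.1", "seed: 9"), f)
  sp <- read_phantom_spec(f)
  expect_s3_class(sp, "phantom_spec")
  expect_equal(sp$n_slices, 4L)
  expect_equal(sp$lumen_radius_px, 30)
  writeLines("not_a_key: 1", f)
  expect_error(read_phantom_spec(f), class = "aortamorph_invalid_spec")
})

test_that("phantoms write to disk and read back losslessly", {
  d <- withr::local_tempdir()
  ph <- generate_phantom(phantom_spec(n_slices = 2, slice_shape = c(96, 96),
                                      lumen_radius_px = 20, wall_thickness_px = 10,
                                      n_lamellae = 2, lamella_thickness_px = 2,
                                      voxel_size_um = 1))
  paths <- write_phantom(ph, d)
  expect_true(all(file.exists(paths)))
  back <- read_stack(paths[["stack"]], 1)
  expect_equal(back$data, round(ph$grid$data), ignore_attr = TRUE)
})
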