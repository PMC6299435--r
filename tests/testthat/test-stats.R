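test_that("the KS statistic equals the maximal CDF gap", {
  x <- c(1, 2, 3); y <- c(4, 5, 6)
  expect_equal(ks_two_sample(x, y)$D, 1)       # disjoint supports
  id <- ks_two_sample(c(1.1, 2.2, 3.3), c(1.1, 2.2, 3.3))
  expect_equal(id$D, 0)
  expect_equal(id$p, 1)
  expect_error(ks_two_sample(numeric(), 1:3),
               class = "aortamorph_invalid_sample")
})

test_that("small-sample KS p values equal the exhaustive permutation tail", {
  set.seed(17)
  for (i in 1:10) {
    x <- round(stats::rnorm(5), 3)
    y <- round(stats::rnorm(5, mean = 0.6), 3)
    ks <- ks_two_sample(x, y)
    expect_equal(ks$D, ks_D_brute_force(x, y), tolerance = 1e-12)
    expect_equal(ks$p, ks_p_permutation(x, y), tolerance = 1e-9)
    expect_identical(ks$method, "exact")
  }
})

test_that("asymptotic and exact KS p values agree closely at n = m = 5", {
  set.seed(23)
  diffs <- replicate(100, {
    x <- stats::rnorm(5); y <- stats::rnorm(5, 0.3)
    exact <- ks_two_sample(x, y)$p
    asym <- suppressWarnings(stats::ks.test(x, y, exact = FALSE)$p.value)
    abs(exact - min(1, asym))
  })
  # the asymptotic formula is conservative at tiny n; agreement is coarse but
  # bounded, and the exact route is the one used at these sizes
  expect_lt(stats::median(diffs), 0.1)
})

test_that("KS is invariant under strictly monotone transforms", {
  set.seed(5)
  x <- stats::rnorm(8); y <- stats::rnorm(8, 1)
  a <- ks_two_sample(x, y)
  b <- ks_two_sample(exp(x), exp(y))
  expect_equal(a$D, b$D, tolerance = 1e-12)
  expect_equal(a$p, b$p, tolerance = 1e-9)
})

test_that("the dispersion F-test matches hand-computed examples", {
  ft <- f_test_dispersion(c(0, 2, 4), c(0, 1, 2))
  expect_equal(ft$F, 4)            # variances 4 and 1
  expect_equal(ft$df1, 2)
  expect_equal(ft$df2, 2)
  # cross-check the two-sided p against var.test
  vt <- stats::var.test(c(0, 2, 4), c(0, 1, 2))
  expect_equal(ft$p, vt$p.value, tolerance = 1e-12)
  # equal variances: F = 1, p = 1
  ft2 <- f_test_dispersion(c(1, 2, 3), c(11, 12, 13))
  expect_equal(ft2$F, 1)
  expect_equal(ft2$p, 1)
  # scale-free under common scaling
  set.seed(2)
  x <- stats::rnorm(6); y <- stats::rnorm(6, 0, 2)
  expect_equal(f_test_dispersion(x, y)$F, f_test_dispersion(7 * x, 7 * y)$F,
               tolerance = 1e-12)
  # degenerate cases
  expect_error(f_test_dispersion(c(1, 1, 1), c(2, 2)),
               class = "aortamorph_invalid_sample")
  zf <- f_test_dispersion(c(1, 1, 1), c(0, 1, 2))
  expect_identical(zf$F, Inf)
  expect_equal(zf$p, 0)
})

test_that("significance flags honour the boundary conventions", {
  expect_identical(flag_significance(c(0.0009, 0.001, 0.01, 0.05, 0.0501,
                                       0.06, 0.08, 0.081, 0.9)),
                   c("***", "***", "**", "*", "#", "#", "#", "ns", "ns"))
  expect_error(flag_significance(1.2))
})

test_that("group comparisons cover all pairs and flag both tests", {
  set.seed(8)
  dat <- tidyr::expand_grid(group = c("a", "b", "c"), sample = 1:5)
  dat$parameter <- "thickness"
  dat$value <- stats::rnorm(nrow(dat), mean = match(dat$group, letters))
  cmp <- run_group_comparison(dat)
  expect_equal(nrow(cmp), 3)   # 3 pairs x 1 parameter
  expect_equal(attr(cmp, "n_comparisons"), 3)
  expect_true(all(cmp$D >= 0 & cmp$D <= 1))
  expect_true(all(cmp$F > 0))
  expect_true(all(cmp$ks_flag %in% c("***", "**", "*", "#", "ns")))
  # identical groups: p = 1 and no significance
  dup <- dplyr::bind_rows(
    tibble::tibble(group = "g1", sample = paste0("s", 1:5),
                   parameter = "v", value = c(1, 2, 3, 4, 5)),
    tibble::tibble(group = "g2", sample = paste0("t", 1:5),
                   parameter = "v", value = c(1, 2, 3, 4, 5)))
  cmp2 <- run_group_comparison(dup)
  expect_equal(cmp2$ks_p, 1)
  expect_identical(cmp2$ks_flag, "ns")
  expect_equal(cmp2$F, 1)
  # removing one sample still leaves n = 4: no error
  expect_s3_class(run_group_comparison(dplyr::filter(dup, .data$sample != "s1" |
                                                       .data$group != "g1")),
                  "group_comparison")
  # group size < 2 rejected
  tiny <- dplyr::bind_rows(
    tibble::tibble(group = "g1", sample = "s1", parameter = "v", value = 1),
    tibble::tibble(group = "g2", sample = paste0("t", 1:3),
                   parameter = "v", value = 1:3))
  expect_error(run_group_comparison(tiny), class = "aortamorph_invalid_sample")
})
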