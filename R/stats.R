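#' Two-sample Kolmogorov-Smirnov test
#'
#' D is the supremum gap between the two empirical CDFs over the pooled
#' support. The p value is exact (small-sample permutation distribution) when
#' both samples have at most 10 values, asymptotic otherwise — matching how
#' the test is applied to per-animal group means (n = 5 per group).
#'
#' @param x,y numeric samples (nonempty).
#' @return tibble with `D`, `p`, `n_x`, `n_y`, `method`.
#' @export
ks_two_sample <- function(x, y) {
  if (length(x) == 0 || length(y) == 0)
    abort("both samples must be nonempty", class = "aortamorph_invalid_sample")
  exact <- length(x) <= 10 && length(y) <= 10
  kt <- suppressWarnings(stats::ks.test(x, y, exact = exact))
  tibble(D = unname(kt$statistic), p = min(1, kt$p.value),
         n_x = length(x), n_y = length(y),
         method = if (exact) "exact" else "asymptotic")
}

#' F-test of dispersion
#'
#' Variance-ratio test used to compare data dispersion between groups instead
#' of their means (informative for heterogeneous groups, e.g. when dilations
#' appear in only some animals). F is the larger sample variance over the
#' smaller; the two-sided p doubles the upper tail, capped at 1. Assumes
#' normality — fragile at n = 5, reported as-is by design.
#'
#' @param x,y numeric samples with at least 2 values each.
#' @return tibble with `F`, `p`, `df1`, `df2` (numerator, denominator df).
#' @export
f_test_dispersion <- function(x, y) {
  if (length(x) < 2 || length(y) < 2)
    abort("both samples need >= 2 values", class = "aortamorph_invalid_sample")
  vx <- stats::var(x); vy <- stats::var(y)
  if (vx == 0 && vy == 0)
    abort("both samples have zero variance: F undefined",
          class = "aortamorph_invalid_sample")
  if (vy == 0 || vx == 0) {
    swap <- vx == 0
    return(tibble(F = Inf, p = 0,
                  df1 = length(if (swap) y else x) - 1,
                  df2 = length(if (swap) x else y) - 1))
  }
  swap <- vy > vx
  f <- if (swap) vy / vx else vx / vy
  df1 <- (if (swap) length(y) else length(x)) - 1
  df2 <- (if (swap) length(x) else length(y)) - 1
  p <- min(1, 2 * stats::pf(f, df1, df2, lower.tail = FALSE))
  tibble(F = f, p = p, df1 = df1, df2 = df2)
}

#' Significance flag for a p value
#'
#' `***` for p <= 0.001, `**` for p <= 0.01, `*` for p <= 0.05 (boundaries
#' inclusive), `#` for the trend band (0.05, 0.08], `ns` otherwise.
#'
#' @param p p value(s) in \[0, 1\].
#' @param levels decreasing thresholds for `*`, `**`, `***`.
#' @param trend_band interval flagged as a trend.
#' @return character vector of flags.
#' @export
flag_significance <- function(p, levels = c(0.05, 0.01, 0.001),
                              trend_band = c(0.05, 0.08)) {
  stopifnot(all(p >= 0 & p <= 1))
  dplyr::case_when(
    p <= levels[3] ~ "***",
    p <= levels[2] ~ "**",
    p <= levels[1] ~ "*",
    p > trend_band[1] & p <= trend_band[2] ~ "#",
    TRUE ~ "ns"
  )
}

#' Pairwise group comparisons of per-sample summary values
#'
#' One value per animal/stack (e.g. the per-sample mean of a morphometric
#' parameter). For every parameter and every group pair, runs the two-sample
#' KS test on the values and the F-test on their dispersion, and flags both p
#' values. No multiple-testing correction is applied; the number of
#' comparisons made is reported alongside.
#'
#' @param data tibble with columns `group`, `sample`, `parameter`, `value`
#'   (long format; `parameter` optional when only one parameter is present).
#' @param config a [pipeline_config()] (significance levels and trend band).
#' @return object of class `group_comparison`: tibble with one row per
#'   (parameter, group pair) carrying `D`, `ks_p`, `ks_flag`, `F`, `f_p`,
#'   `f_flag`, group sizes; attribute `n_comparisons`.
#' @export
run_group_comparison <- function(data, config = pipeline_config()) {
  if (!"parameter" %in% names(data)) data$parameter <- "value"
  groups <- unique(data$group)
  if (length(groups) < 2) abort("need >= 2 groups", class = "aortamorph_invalid_sample")
  sizes <- data |> dplyr::distinct(.data$group, .data$sample) |>
    dplyr::count(.data$group)
  if (any(sizes$n < 2)) abort("every group needs >= 2 samples",
                              class = "aortamorph_invalid_sample")
  pairs <- utils::combn(as.character(groups), 2, simplify = FALSE)
  out <- purrr::map(unique(data$parameter), function(par) {
    purrr::map(pairs, function(pr) {
      x <- data$value[data$group == pr[1] & data$parameter == par]
      y <- data$value[data$group == pr[2] & data$parameter == par]
      ks <- ks_two_sample(x, y)
      ft <- f_test_dispersion(x, y)
      tibble(parameter = par, group_1 = pr[1], group_2 = pr[2],
             n_1 = length(x), n_2 = length(y),
             mean_1 = mean(x), mean_2 = mean(y),
             sd_1 = stats::sd(x), sd_2 = stats::sd(y),
             D = ks$D, ks_p = ks$p,
             ks_flag = flag_significance(ks$p, config$significance_levels,
                                         config$trend_band),
             F = ft$F, f_p = ft$p,
             f_flag = flag_significance(ft$p, config$significance_levels,
                                        config$trend_band))
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
  attr(out, "n_comparisons") <- nrow(out)
  class(out) <- c("group_comparison", class(out))
  out
}
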