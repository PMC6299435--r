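#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a thickness distribution into its per-angle samples
#' @param x a `thickness_distribution`.
#' @param ... unused.
#' @return tibble with `theta`, `thickness_um`.
#' @export
tidy.thickness_distribution <- function(x, ...) x$samples

#' One-row summary of a thickness distribution's Gaussian fit
#' @param x a `thickness_distribution`.
#' @param ... unused.
#' @export
glance.thickness_distribution <- function(x, ...) {
  tibble(mean_um = x$mean_um, sd_um = x$sd_um,
         sample_mean_um = x$sample_mean_um, sample_sd_um = x$sample_sd_um,
         fit_residual = x$fit_residual,
         n_samples = x$n_samples, n_dropped = x$n_dropped,
         high_drop_flag = x$high_drop_flag)
}

#' Per-slice records of a morphometry run
#' @param x a `morphometry_run`.
#' @param ... unused.
#' @export
tidy.morphometry_run <- function(x, ...) x$records

#' Stack-level summary of a morphometry run, one row per parameter
#' @param x a `morphometry_run`.
#' @param ... unused.
#' @export
glance.morphometry_run <- function(x, ...) x$summary$summary

#' Lumen centroids of a segmentation stack
#' @param x a `segmentation_stack`.
#' @param ... unused.
#' @return tibble with `slice`, `row`, `col`, `provenance`.
#' @export
tidy.segmentation_stack <- function(x, ...) {
  ok <- which(!vapply(x$slices, is.null, logical(1)))
  tibble(
    slice = ok,
    row = vapply(ok, function(z) contour_center(x$slices[[z]]$lumen_contour)[1], numeric(1)),
    col = vapply(ok, function(z) contour_center(x$slices[[z]]$lumen_contour)[2], numeric(1)),
    provenance = vapply(ok, function(z) x$slices[[z]]$provenance, character(1))
  )
}

#' Evaluated centreline points
#' @param x a `centerline`.
#' @param ... unused.
#' @export
tidy.centerline <- function(x, ...) {
  centerline_at(x, seq(x$range[1], x$range[2]))
}

#' Break table of an IEL run
#' @param x an `iel_run`.
#' @param ... unused.
#' @export
tidy.iel_run <- function(x, ...) x$breaks

#' One-row summary of an IEL run
#' @param x an `iel_run`.
#' @param ... unused.
#' @export
glance.iel_run <- function(x, ...) {
  tibble(n_breaks = nrow(x$breaks), break_pct = x$pct,
         threshold = x$threshold,
         valid_frac = mean(x$surface$valid))
}
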