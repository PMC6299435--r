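#' @importFrom ggplot2 ggplot aes autoplot geom_line geom_col geom_raster
#'   geom_point geom_jitter geom_errorbar facet_wrap labs theme_minimal
#'   scale_fill_viridis_c stat_function position_jitter
#' @export
ggplot2::autoplot

#' Plot per-slice morphometry traces
#'
#' One panel per parameter, slice index on the x axis — the per-slice view of
#' diameter, thickness, areas and lamellar fraction along the analysed window.
#' @param object a `morphometry_run`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.morphometry_run <- function(object, ...) {
  long <- object$records |>
    dplyr::select("slice", "lumen_diameter_um", "media_thickness_um",
                  "media_area_um2", "lamellae_pct") |>
    tidyr::pivot_longer(-"slice", names_to = "parameter")
  ggplot(long, aes(x = .data$slice, y = .data$value)) +
    geom_line(colour = "steelblue") +
    facet_wrap(~parameter, scales = "free_y") +
    labs(x = "slice", y = NULL,
         title = "Per-slice aortic wall morphometry") +
    theme_minimal()
}

#' Plot a thickness histogram with its Gaussian fit
#' @param object a `thickness_distribution`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.thickness_distribution <- function(object, ...) {
  h <- object$histogram
  amp <- max(h$count)
  mu <- object$mean_um; sd <- max(object$sd_um, 1e-9)
  ggplot(h, aes(x = .data$mid, y = .data$count)) +
    geom_col(fill = "grey70", width = diff(h$mid[1:2] %||% c(0, 1))) +
    stat_function(fun = function(x) amp * exp(-(x - mu)^2 / (2 * sd^2)),
                  colour = "firebrick") +
    labs(x = "media thickness (um)", y = "count",
         title = sprintf("Thickness distribution: %.1f +/- %.1f um", mu, sd)) +
    theme_minimal()
}

#' Plot the en-face IEL surface
#'
#' Axial position against circumferential angle; breaks appear as dark
#' regions.
#' @param object an `iel_surface` or `iel_run`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.iel_surface <- function(object, ...) {
  img <- object$image
  img[!object$valid] <- NA
  df <- tibble(
    slice = rep(seq_len(nrow(img)), times = ncol(img)),
    angle_deg = rep((seq_len(ncol(img)) - 1) / ncol(img) * 360, each = nrow(img)),
    intensity = as.vector(img)
  )
  ggplot(df, aes(x = .data$angle_deg, y = .data$slice, fill = .data$intensity)) +
    geom_raster() +
    scale_fill_viridis_c(na.value = "white") +
    labs(x = "circumferential angle (deg)", y = "axial slice",
         title = "En-face IEL luminal surface") +
    theme_minimal()
}

#' @export
autoplot.iel_run <- function(object, ...) autoplot(object$surface, ...)

#' Plot per-sample group values with group mean and SD
#'
#' The cohort view: one point per animal/stack, group mean +/- SD overlaid,
#' one panel per parameter.
#' @param data long tibble with `group`, `sample`, `parameter`, `value` (as
#'   consumed by [run_group_comparison()]).
#' @return a ggplot.
#' @export
plot_group_values <- function(data) {
  if (!"parameter" %in% names(data)) data$parameter <- "value"
  summ <- data |>
    dplyr::group_by(.data$group, .data$parameter) |>
    dplyr::summarise(mean = mean(.data$value), sd = stats::sd(.data$value),
                     .groups = "drop")
  ggplot(data, aes(x = .data$group, y = .data$value)) +
    geom_jitter(width = 0.08, alpha = 0.7, colour = "steelblue") +
    geom_point(data = summ, aes(y = .data$mean), size = 3) +
    geom_errorbar(data = summ,
                  aes(y = .data$mean, ymin = .data$mean - .data$sd,
                      ymax = .data$mean + .data$sd), width = 0.2) +
    facet_wrap(~parameter, scales = "free_y") +
    labs(x = NULL, y = NULL, title = "Per-sample group values (mean +/- SD)") +
    theme_minimal()
}
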