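#' Exact Euclidean distance transform
#'
#' Per-pixel Euclidean distance (in pixels) to the nearest background pixel;
#' exact, not a chamfer approximation. An all-background mask yields a zero
#' map.
#'
#' @param mask binary matrix.
#' @return numeric matrix of distances.
#' @export
euclidean_distance_transform <- function(mask) {
  m <- matrix(as.numeric(mask != 0), nrow(mask), ncol(mask))
  if (!any(m > 0)) return(m)
  matrix(as.numeric(EBImage::distmap(m)), nrow(m), ncol(m))
}

#' Media thickness distribution of one slice
#'
#' At each angular sample, the thickness is the Euclidean distance from the
#' lumen-wall contour point to the media-adventitia limit along the local
#' normal, converted to um. The distribution of all values in the slice is
#' binned (Freedman-Diaconis) and fitted to a Gaussian by least squares on the
#' histogram, initialised at the sample mean and SD; fitted mean and SD are
#' the primary thickness statistics, sample moments are reported alongside.
#'
#' @param lumen_contour,media_contour contour tibbles (same angular grid
#'   recommended).
#' @param voxel_size_um voxel size, um.
#' @param max_depth_px longest ray considered, px.
#' @return object of class `thickness_distribution`: `samples` tibble
#'   (`theta`, `thickness_um`), `mean_um`, `sd_um` (Gaussian fit),
#'   `sample_mean_um`, `sample_sd_um`, `fit_residual`, `n_samples`,
#'   `n_dropped`, `high_drop_flag`, `histogram`.
#' @export
media_thickness <- function(lumen_contour, media_contour, voxel_size_um = 1.1,
                            max_depth_px = NULL) {
  K <- nrow(lumen_contour)
  nrm <- contour_normals(lumen_contour)
  max_depth_px <- max_depth_px %||% (max(media_contour$r) - min(lumen_contour$r) + 10)
  ctr <- contour_center(lumen_contour)
  mctr <- contour_center(media_contour)
  step <- 0.25
  s <- seq(0, max_depth_px, by = step)
  rows <- outer(lumen_contour$row, rep(1, length(s))) + outer(nrm[, "row"], s)
  cols <- outer(lumen_contour$col, rep(1, length(s))) + outer(nrm[, "col"], s)
  dy <- rows - mctr[1]; dx <- cols - mctr[2]
  rr <- sqrt(dx^2 + dy^2)
  th <- wrap_angle(atan2(dy, dx))
  r_lim <- matrix(contour_r_at(media_contour, as.vector(th)), K, length(s))
  inside <- rr <= r_lim
  thick_px <- vapply(seq_len(K), function(k) {
    v <- inside[k, ]
    if (!v[1]) return(NA_real_)      # ray starts outside the media limit
    i <- which(!v)
    if (length(i) == 0) return(NA_real_)  # never exits: pathological
    i <- i[1]
    # refine the crossing between samples i-1 and i
    f0 <- rr[k, i - 1] - r_lim[k, i - 1]
    f1 <- rr[k, i] - r_lim[k, i]
    s[i - 1] + step * (0 - f0) / max(f1 - f0, 1e-9)
  }, numeric(1))
  dropped <- sum(is.na(thick_px))
  thick <- thick_px[!is.na(thick_px)] * voxel_size_um
  theta_ok <- lumen_contour$theta[!is.na(thick_px)]
  if (length(thick) == 0) abort("no thickness sample succeeded", class = "aortamorph_thickness_failed")
  gf <- fit_gaussian_hist(thick)
  structure(list(
    samples = tibble(theta = theta_ok, thickness_um = thick),
    mean_um = gf$mean, sd_um = gf$sd,
    sample_mean_um = mean(thick), sample_sd_um = stats::sd(thick),
    fit_residual = gf$residual, histogram = gf$histogram,
    n_samples = K, n_dropped = dropped,
    high_drop_flag = dropped > 0.1 * K
  ), class = "thickness_distribution")
}

# Least-squares Gaussian fit to a Freedman-Diaconis histogram. Degenerate
# distributions (fewer than 4 occupied bins) fall back to sample moments with
# the SD capped by the bin width.
fit_gaussian_hist <- function(x) {
  h <- graphics::hist(x, breaks = "FD", plot = FALSE)
  mids <- h$mids; counts <- h$counts
  bw <- diff(h$breaks[1:2])
  mu0 <- mean(x); sd0 <- max(stats::sd(x), bw / 4, 1e-9)
  hist_tb <- tibble(mid = mids, count = counts)
  if (sum(counts > 0) < 4 || length(x) < 8) {
    return(list(mean = mu0, sd = min(stats::sd(x), bw), residual = NA_real_,
                histogram = hist_tb))
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(count ~ A * exp(-(mid - mu)^2 / (2 * sigma^2)),
                      data = data.frame(mid = mids, count = counts),
                      start = list(A = max(counts), mu = mu0, sigma = sd0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(list(mean = mu0, sd = stats::sd(x), residual = NA_real_,
                histogram = hist_tb))
  }
  cf <- stats::coef(fit)
  list(mean = unname(cf["mu"]), sd = abs(unname(cf["sigma"])),
       residual = sqrt(mean(stats::resid(fit)^2)), histogram = hist_tb)
}

#' Cross-sectional area of a mask
#'
#' Pixel count times the squared voxel size.
#' @param mask binary matrix.
#' @param voxel_size_um voxel size, um.
#' @return area in um^2.
#' @export
cross_sectional_area <- function(mask, voxel_size_um = 1.1) {
  sum(mask != 0) * voxel_size_um^2
}

#' Medial fraction occupied by lamellae
#'
#' Lamellar pixel count divided by the media pixel count (percent); the
#' interlamellar area follows by subtraction, so the three areas partition
#' exactly.
#'
#' @param lamellae_mask,media_mask binary masks with
#'   `lamellae_mask` a subset of `media_mask`.
#' @param voxel_size_um voxel size, um.
#' @return tibble with `lamellae_pct`, `lamellae_area_um2`,
#'   `interlamellar_area_um2`, `media_area_um2`.
#' @export
lamellae_fraction <- function(lamellae_mask, media_mask, voxel_size_um = 1.1) {
  lam <- lamellae_mask != 0; med <- media_mask != 0
  if (any(lam & !med))
    abort("lamellae mask is not a subset of the media mask (upstream bug)",
          class = "aortamorph_invariant_violation")
  if (!any(med)) abort("empty media mask", class = "aortamorph_invariant_violation")
  n_lam <- sum(lam); n_med <- sum(med)
  v2 <- voxel_size_um^2
  tibble(lamellae_pct = 100 * n_lam / n_med,
         lamellae_area_um2 = n_lam * v2,
         interlamellar_area_um2 = (n_med - n_lam) * v2,
         media_area_um2 = n_med * v2)
}

#' Lumen diameter by ellipse approximation
#'
#' Fits the vessel internal circumference with a direct least-squares ellipse
#' and averages its major and minor axes, mirroring how aortic diameter is
#' assessed by echocardiography.
#'
#' @param lumen_contour contour tibble (>= 6 points).
#' @param voxel_size_um voxel size, um.
#' @return tibble with `diameter_um`, `major_axis_um`, `minor_axis_um`,
#'   `center_row`, `center_col`, `angle`.
#' @export
lumen_diameter <- function(lumen_contour, voxel_size_um = 1.1) {
  e <- fit_ellipse(lumen_contour$row, lumen_contour$col)
  major <- 2 * e$axes[1] * voxel_size_um
  minor <- 2 * e$axes[2] * voxel_size_um
  tibble(diameter_um = (major + minor) / 2,
         major_axis_um = major, minor_axis_um = minor,
         center_row = unname(e$center["row"]), center_col = unname(e$center["col"]),
         angle = e$angle)
}

#' Morphometry of one segmented slice
#'
#' @param seg a `slice_segmentation`.
#' @param slice slice index recorded in the output.
#' @param voxel_size_um voxel size, um.
#' @return list with `record` (one-row tibble: diameter, thickness mean/SD,
#'   areas, lamellar fraction, provenance) and `thickness` (a
#'   `thickness_distribution`, `NULL` on fallback slices).
#' @export
measure_slice <- function(seg, slice = 1L, voxel_size_um = 1.1) {
  dia <- lumen_diameter(seg$lumen_contour, voxel_size_um)
  frac <- lamellae_fraction(seg$lamellae_mask, seg$media_mask, voxel_size_um)
  thick <- NULL
  if (identical(seg$provenance, "fallback") || is.null(seg$media_adventitia_contour)) {
    th_mean <- NA_real_; th_sd <- NA_real_
  } else {
    thick <- media_thickness(seg$lumen_contour, seg$media_adventitia_contour,
                             voxel_size_um)
    th_mean <- thick$mean_um; th_sd <- thick$sd_um
  }
  rec <- tibble(
    slice = slice,
    lumen_diameter_um = dia$diameter_um,
    media_thickness_um = th_mean,
    media_thickness_sd_um = th_sd,
    media_area_um2 = frac$media_area_um2,
    lamellae_area_um2 = frac$lamellae_area_um2,
    interlamellar_area_um2 = frac$interlamellar_area_um2,
    lamellae_pct = frac$lamellae_pct,
    provenance = seg$provenance
  )
  list(record = rec, thickness = thick)
}

#' Stack-level summary of per-slice morphometry
#'
#' Means and SDs over the analysis window for every quantity, plus the pooled
#' per-angle thickness samples for distribution plots. SD is 0 by convention
#' for a single-slice window.
#'
#' @param records tibble of per-slice records (from [measure_slice()] /
#'   [run_morphometry()]).
#' @param thickness_samples optional pooled tibble (`slice`, `theta`,
#'   `thickness_um`).
#' @return object of class `stack_summary`: `summary` tibble (parameter,
#'   mean, sd, n) and `thickness_samples`.
#' @export
summarize_stack <- function(records, thickness_samples = NULL) {
  if (nrow(records) < 1) abort("no records to summarise")
  params <- c("lumen_diameter_um", "media_thickness_um", "media_area_um2",
              "lamellae_area_um2", "interlamellar_area_um2", "lamellae_pct")
  summ <- purrr::map(params, function(p) {
    v <- records[[p]]
    v <- v[!is.na(v)]
    tibble(parameter = p,
           mean = if (length(v)) mean(v) else NA_real_,
           sd = if (length(v) > 1) stats::sd(v) else 0,
           n = length(v))
  }) |> dplyr::bind_rows()
  structure(list(summary = summ, n_slices = nrow(records),
                 thickness_samples = thickness_samples),
            class = "stack_summary")
}

#' @export
print.stack_summary <- function(x, ...) {
  cat(sprintf("<stack_summary> %d slices\n", x$n_slices))
  print(x$summary)
  invisible(x)
}
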