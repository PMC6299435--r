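#' Extract the internal elastic lamina as a 3D shell
#'
#' Per slice, the 1-px lumen-wall border (the IEL location) is dilated by a
#' disk of radius `iel_dilation_px` (default 7 px, which captures the entire
#' IEL at 1.1 um voxels) and intersected with the wall; the per-slice shells
#' are stacked.
#'
#' @param seg a [segment_stack()] result.
#' @param iel_dilation_px dilation radius in pixels.
#' @return logical 3D array `[row, col, slice]`.
#' @export
extract_iel <- function(seg, iel_dilation_px = 7) {
  missing <- which(vapply(seg$slices, is.null, logical(1)))
  if (length(missing))
    abort(paste("missing lumen contour on slices:", paste(missing, collapse = ", ")),
          class = "aortamorph_missing_slices")
  dims <- seg$dims
  shell <- array(FALSE, dim = dims)
  brush <- disk_brush(iel_dilation_px)
  for (z in seq_len(dims[3])) {
    sl <- seg$slices[[z]]
    lum <- matrix(as.numeric(sl$lumen_mask), dims[1], dims[2])
    border <- (matrix(as.numeric(EBImage::dilate(lum, disk_brush(1.5))),
                      dims[1], dims[2]) > 0.5) & sl$wall_mask
    if (iel_dilation_px > 0) {
      b <- EBImage::dilate(matrix(as.numeric(border), dims[1], dims[2]), brush)
      border <- (matrix(as.numeric(b), dims[1], dims[2]) > 0.5) & sl$wall_mask
    }
    shell[, , z] <- border
  }
  shell
}

#' En-face maximal projection of the IEL shell
#'
#' Reslices the IEL to the en-face perspective: for each (slice, angle), the
#' maximal original intensity over shell voxels along the outward normal ray
#' from the lumen-wall limit. Columns are angles (the unwrapping geometry),
#' rows are slices. The circumferential pixel pitch is recorded per slice as
#' `2 pi x mean lumen radius / K x voxel`, since the lumen radius varies
#' axially.
#'
#' @param grid the intensity [voxel_grid()] the segmentation came from.
#' @param shell [extract_iel()] result.
#' @param seg the matching [segment_stack()].
#' @param max_depth_px radial extent scanned along each ray.
#' @return object of class `iel_surface`: `image` (n_slices x K), `valid`
#'   logical matrix (empty shell columns are invalid, not interpolated),
#'   `arc_pitch_um` (per slice), `axial_pitch_um`.
#' @export
enface_projection <- function(grid, shell, seg, max_depth_px = NULL) {
  dims <- seg$dims
  K <- nrow(seg$slices[[1]]$lumen_contour)
  n <- dims[3]
  img_out <- matrix(NA_real_, n, K)
  valid <- matrix(FALSE, n, K)
  arc_pitch <- numeric(n)
  v <- grid$voxel_size_um
  for (z in seq_len(n)) {
    sl <- seg$slices[[z]]
    ct <- sl$lumen_contour
    nrm <- contour_normals(ct)
    depth_max <- max_depth_px %||% 20
    s <- seq(-1, depth_max, by = 0.5)
    rows <- outer(ct$row, rep(1, length(s))) + outer(nrm[, "row"], s)
    cols <- outer(ct$col, rep(1, length(s))) + outer(nrm[, "col"], s)
    ri <- clamp(round(rows), 1, dims[1]); ci <- clamp(round(cols), 1, dims[2])
    sh <- matrix(shell[, , z][cbind(as.vector(ri), as.vector(ci))], K, length(s))
    inten <- matrix(bilinear(get_slice(grid, z), as.vector(rows), as.vector(cols)),
                    K, length(s))
    inten[!sh] <- -Inf
    mx <- apply(inten, 1, max)
    ok <- is.finite(mx)
    img_out[z, ok] <- mx[ok]
    valid[z, ] <- ok
    arc_pitch[z] <- 2 * pi * mean(ct$r) / K * v
  }
  structure(list(image = img_out, valid = valid,
                 arc_pitch_um = arc_pitch, axial_pitch_um = v),
            class = "iel_surface")
}

#' @export
print.iel_surface <- function(x, ...) {
  cat(sprintf("<iel_surface> %d slices x %d angular samples (%.1f%% valid)\n",
              nrow(x$image), ncol(x$image), 100 * mean(x$valid)))
  invisible(x)
}

#' Quantify IEL surface breaks
#'
#' Breaks appear as dark discontinuities on the en-face surface. Detection is
#' automated: pixels below the threshold (a fixed grey value from the config,
#' or Otsu over the valid surface) are grouped into 8-connected components;
#' components at least `min_break_area_um2` large are reported. Areas use the
#' per-slice circumferential pitch, so axially varying lumen radii are
#' honoured. An externally supplied manual break mask replaces detection for
#' parity with manual contouring.
#'
#' @param surface an [enface_projection()] result.
#' @param config a [pipeline_config()] (threshold and minimum area).
#' @param manual_mask optional logical matrix of the surface shape; when
#'   given, detection is bypassed.
#' @return list with `breaks` (tibble: id, area_um2, slice/angle bounding box,
#'   centroid), `pct` (percent of valid surface occupied), `threshold`,
#'   `dominated` (TRUE with a warning when > 50% of the surface is dark).
#' @export
quantify_breaks <- function(surface, config = pipeline_config(), manual_mask = NULL) {
  img <- surface$image
  valid <- surface$valid
  px_area <- matrix(surface$arc_pitch_um * surface$axial_pitch_um,
                    nrow(img), ncol(img))  # recycles per-slice pitch down rows
  total_area <- sum(px_area[valid])
  if (is.null(manual_mask)) {
    vals <- img[valid]
    thr <- config$break_threshold
    if (is.null(thr)) {
      if (diff(range(vals)) < 1e-9) {
        thr <- min(vals) - 1  # uniform: intact surface
      } else {
        thr <- auto_threshold(vals, config$threshold_method)
        # an intact surface has no dark mode: only accept an automatic
        # threshold when the two classes are separated by a real contrast gap
        sep <- mean(vals[vals >= thr]) - mean(vals[vals < thr])
        if (!is.finite(sep) || sep < config$break_min_contrast) thr <- min(vals) - 1
      }
    }
    dark <- valid & !is.na(img) & img < thr
  } else {
    thr <- NA_real_
    dark <- valid & (manual_mask != 0)
  }
  dominated <- FALSE
  if (sum(px_area[dark]) > 0.5 * total_area) {
    dominated <- TRUE
    warn("surface dominated by breaks (> 50% dark)")
  }
  lab <- label_components(dark, 8)
  breaks <- tibble(id = integer(), area_um2 = numeric(),
                   slice_min = integer(), slice_max = integer(),
                   theta_min_deg = numeric(), theta_max_deg = numeric(),
                   centroid_slice = numeric(), centroid_theta_deg = numeric())
  if (max(lab) > 0) {
    K <- ncol(img)
    rowsl <- matrix(seq_len(nrow(img)), nrow(img), K)
    colth <- matrix(seq_len(K), nrow(img), K, byrow = TRUE)
    breaks <- purrr::map(seq_len(max(lab)), function(l) {
      sel <- lab == l
      a <- sum(px_area[sel])
      tibble(id = l, area_um2 = a,
             slice_min = min(rowsl[sel]), slice_max = max(rowsl[sel]),
             theta_min_deg = (min(colth[sel]) - 1) / K * 360,
             theta_max_deg = (max(colth[sel]) - 1) / K * 360,
             centroid_slice = mean(rowsl[sel]),
             centroid_theta_deg = mean((colth[sel] - 1) / K * 360))
    }) |> dplyr::bind_rows() |>
      dplyr::filter(.data$area_um2 >= config$min_break_area_um2) |>
      dplyr::mutate(id = dplyr::row_number())
  }
  pct <- if (total_area > 0) 100 * sum(breaks$area_um2) / total_area else 0
  list(breaks = breaks, pct = pct, threshold = thr, dominated = dominated,
       valid_area_um2 = total_area)
}
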