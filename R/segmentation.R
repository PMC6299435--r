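#' Per-slice wall segmentation
#'
#' Binarises a transverse slice to separate the aortic wall from the
#' surrounding paraffin: Otsu threshold on the (affinely rescaled) intensities,
#' morphological closing then opening with a disk, hole filling restricted to
#' holes smaller than the lumen candidate, and selection of the largest bright
#' connected component. An optional exclusion mask (the reproducible
#' replacement for manual artefact painting) forces pixels to background
#' before any morphology.
#'
#' @param img numeric matrix (one slice).
#' @param config a [pipeline_config()].
#' @param exclusion_mask optional logical matrix; `TRUE` pixels are excluded.
#' @return logical wall mask.
#' @export
segment_wall <- function(img, config = pipeline_config(), exclusion_mask = NULL) {
  rng <- range(img)
  if (diff(rng) <= 0)
    abort("empty slice: uniform intensity, no threshold possible",
          class = "aortamorph_empty_slice")
  vals <- if (is.null(exclusion_mask)) as.vector(img) else img[exclusion_mask == 0]
  thr <- tryCatch(auto_threshold(vals, config$threshold_method),
                  aortamorph_no_contrast = function(e)
                    abort("empty slice: uniform intensity, no threshold possible",
                          class = "aortamorph_empty_slice"))
  bw <- img > thr
  if (!is.null(exclusion_mask)) bw[exclusion_mask != 0] <- FALSE
  if (!any(bw))
    abort(sprintf("empty slice: nothing above Otsu threshold %.4g", thr),
          class = "aortamorph_empty_slice")
  brush <- disk_brush(config$smooth_disk_px)
  m <- matrix(as.numeric(bw), nrow(bw), ncol(bw))
  m <- EBImage::opening(EBImage::closing(m, brush), brush)
  m <- matrix(as.numeric(m) > 0.5, nrow(bw), ncol(bw))
  lab <- label_components(m, 8)
  if (max(lab) == 0)
    abort(sprintf("empty slice: morphology removed all foreground (threshold %.4g)", thr),
          class = "aortamorph_empty_slice")
  sizes <- tabulate(lab[lab > 0])
  wall <- lab == which.max(sizes)
  # fill holes smaller than the lumen candidate (= largest enclosed hole)
  bg <- label_components(!wall, 4)
  border_labels <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
  hole_labels <- setdiff(unique(bg[bg > 0]), border_labels)
  if (length(hole_labels) > 1) {
    hole_sizes <- vapply(hole_labels, function(l) sum(bg == l), numeric(1))
    lumen_candidate <- hole_labels[which.max(hole_sizes)]
    for (l in setdiff(hole_labels, lumen_candidate)) wall[bg == l] <- TRUE
  }
  if (!is.null(exclusion_mask)) wall[exclusion_mask != 0] <- FALSE
  wall
}

#' Lumen segmentation
#'
#' The lumen is the background region fully enclosed by the wall, located by
#' flood fill from the wall centroid (which lies inside the annulus). Its
#' subpixel boundary contour, ordered counter-clockwise from angle 0 about the
#' lumen centroid, marks the lumen-wall limit (the IEL location, since the
#' intima gives no phase contrast).
#'
#' @param img numeric matrix (unused by the geometry, kept for interface
#'   symmetry and provenance).
#' @param wall_mask logical wall mask.
#' @param n_theta angular samples of the returned contour.
#' @return list with `lumen_mask`, `contour`, `centroid`.
#' @export
segment_lumen <- function(img, wall_mask, n_theta = 360) {
  wall <- wall_mask != 0
  idx <- which(wall, arr.ind = TRUE)
  if (nrow(idx) == 0) abort("empty wall mask", class = "aortamorph_empty_slice")
  ctr <- round(c(mean(idx[, 1]), mean(idx[, 2])))
  if (wall[ctr[1], ctr[2]])
    abort("wall centroid lies on the wall: no enclosed cavity",
          class = "aortamorph_open_wall")
  bg <- label_components(!wall, 4)
  lumen_label <- bg[ctr[1], ctr[2]]
  border_labels <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
  if (lumen_label %in% border_labels)
    abort("open wall: lumen leaks to the image border",
          class = "aortamorph_open_wall")
  lumen <- bg == lumen_label
  lidx <- which(lumen, arr.ind = TRUE)
  centroid <- c(mean(lidx[, 1]), mean(lidx[, 2]))
  contour <- trace_contour(lumen, center = centroid, n_theta = n_theta)
  contour <- refine_contour_halfmax(img, contour)
  list(lumen_mask = lumen, contour = contour, centroid = centroid)
}

#' Media-adventitia delineation
#'
#' Realises the half-wall + dilation rule: Euclidean distance maps are taken
#' from every wall pixel to the lumen (`d_in`) and to the outer paraffin
#' (`d_out`); the mid-wall line is the band where `|d_in - d_out| <= 0.5` px
#' (an exact-equality set is empty on a grid), and divides the wall into two
#' halves. The minimum wall thickness is the minimum of `d_in + d_out` on that
#' line. The media is the inner half dilated by a disk of radius
#' `round(media_dilation_factor x minimum thickness)`, intersected with the
#' wall; its outer contour is then smoothed as a periodic spline in polar
#' coordinates about the lumen centroid and the mask regenerated from the
#' smoothed contour.
#'
#' @param wall_mask,lumen_mask logical masks.
#' @param config a [pipeline_config()].
#' @param lumen_contour optional precomputed lumen contour (for the centre).
#' @return list with `media_mask`, `adventitia_mask`, `contour` (smoothed
#'   media-adventitia limit), `min_wall_thickness_px`.
#' @export
media_adventitia_limit <- function(wall_mask, lumen_mask, config = pipeline_config(),
                                   lumen_contour = NULL) {
  wall <- wall_mask != 0; lumen <- lumen_mask != 0
  if (!any(lumen)) abort("empty lumen mask", class = "aortamorph_open_wall")
  outside <- !(wall | lumen)
  d_in <- EBImage::distmap(matrix(as.numeric(!lumen), nrow(wall), ncol(wall)))
  d_out <- EBImage::distmap(matrix(as.numeric(!outside), nrow(wall), ncol(wall)))
  d_in <- matrix(as.numeric(d_in), nrow(wall), ncol(wall))
  d_out <- matrix(as.numeric(d_out), nrow(wall), ncol(wall))
  midline <- wall & abs(d_in - d_out) <= 0.5
  if (!any(midline))
    abort("non-annular wall topology: no mid-wall line", class = "aortamorph_open_wall")
  min_thick <- min(d_in[midline] + d_out[midline])
  if (min_thick < 3)
    abort(sprintf("wall too thin: minimum thickness %.2f px", min_thick),
          class = "aortamorph_wall_too_thin")
  inner <- wall & (d_in < d_out | midline)
  rad <- round(config$media_dilation_factor * min_thick)
  media <- EBImage::dilate(matrix(as.numeric(inner), nrow(wall), ncol(wall)),
                           disk_brush(rad))
  media <- (matrix(as.numeric(media), nrow(wall), ncol(wall)) > 0.5) & wall
  lidx <- which(lumen, arr.ind = TRUE)
  centroid <- if (!is.null(lumen_contour)) contour_center(lumen_contour)
              else c(mean(lidx[, 1]), mean(lidx[, 2]))
  contour <- trace_contour(media, center = centroid,
                           n_theta = config$angular_samples)
  contour <- smooth_contour(contour, sp = config$contour_spline_sp)
  media <- mask_from_contour(contour, dim(wall)) & wall
  list(media_mask = media, adventitia_mask = wall & !media,
       contour = contour, min_wall_thickness_px = min_thick)
}

#' Lamellae segmentation within the media
#'
#' The high-contrast lamellae are brighter than the interlamellar matrix, so
#' an Otsu threshold computed over the media pixels only separates them.
#' Components smaller than `min_lamella_px` are removed.
#'
#' @param img numeric slice.
#' @param media_mask logical media mask.
#' @param config a [pipeline_config()].
#' @return logical lamellae mask (subset of the media).
#' @export
segment_lamellae <- function(img, media_mask, config = pipeline_config()) {
  media <- media_mask != 0
  if (!any(media)) abort("empty media mask", class = "aortamorph_empty_slice")
  vals <- img[media]
  if (diff(range(vals)) < 1e-9)
    abort("no contrast within the media: degenerate histogram",
          class = "aortamorph_no_contrast")
  thr_grey <- auto_threshold(vals, config$threshold_method)
  lam <- media & img > thr_grey
  lab <- label_components(lam, 8)
  if (max(lab) > 0) {
    sizes <- tabulate(lab[lab > 0])
    keep <- which(sizes >= config$min_lamella_px)
    lam <- lab %in% keep & lam
    dim(lam) <- dim(media)
  }
  lam
}

#' Fallback segmentation for non-circular (dilated) vessels
#'
#' Used when the standard path raises an open-wall error. The brightest
#' fraction of the slice (mainly lamellae) is thresholded; the watershed
#' transform of the Euclidean distance map of the complement partitions the
#' slice into basins whose ridge lines close the tube across small gaps; the
#' lumen is the basin containing the seed point, grown as an enclosed region
#' (a reproducible replacement for interactive lumen carving). Thickness is
#' not computed on fallback slices downstream (areas and diameter only).
#'
#' @param img numeric slice.
#' @param config a [pipeline_config()].
#' @param seed_point `c(row, col)` inside the lumen; defaults to the centroid
#'   of the bright structure (valid for tubes centred on their lumen), and in
#'   pipeline runs to the lumen centroid of the nearest successfully
#'   segmented slice.
#' @return list with `wall_mask`, `lumen_mask`, `contour`, `centroid`,
#'   `provenance = "fallback"`.
#' @export
segment_dilated_fallback <- function(img, config = pipeline_config(), seed_point = NULL) {
  # brightest fraction of the tissue (pixels above the wall binarisation
  # threshold): mainly lamellae, even when paraffin dominates the slice
  fg <- img[img > auto_threshold(as.vector(img), config$threshold_method)]
  if (length(fg) == 0)
    abort("fallback failed: manual mask required (no foreground)",
          class = "aortamorph_fallback_failed")
  thr <- stats::quantile(fg, 1 - config$fallback_bright_quantile)
  bright <- img >= thr
  lab <- label_components(bright, 8)
  if (max(lab) > 0) {
    sizes <- tabulate(lab[lab > 0])
    bright <- (lab > 0) & (sizes[pmax(lab, 1)] >= config$min_lamella_px)
    dim(bright) <- dim(img)
  }
  if (is.null(seed_point)) {
    idx <- which(bright, arr.ind = TRUE)
    seed_point <- round(c(mean(idx[, 1]), mean(idx[, 2])))
  }
  D <- EBImage::distmap(matrix(as.numeric(!bright), nrow(img), ncol(img)))
  ws <- EBImage::watershed(D)
  ws <- matrix(as.integer(ws), nrow(img), ncol(img))
  lumen_label <- ws[seed_point[1], seed_point[2]]
  if (lumen_label == 0)
    abort("fallback failed: manual mask required (seed on watershed line)",
          class = "aortamorph_fallback_failed")
  lumen <- ws == lumen_label & !bright
  lab <- label_components(lumen, 4)
  if (max(lab) > 0) {
    sl <- lab[seed_point[1], seed_point[2]]
    if (sl == 0) { sizes <- tabulate(lab[lab > 0]); sl <- which.max(sizes) }
    lumen <- lab == sl
  }
  touches_border <- any(lumen[1, ]) || any(lumen[nrow(lumen), ]) ||
    any(lumen[, 1]) || any(lumen[, ncol(lumen)])
  if (!any(lumen) || touches_border)
    abort("fallback failed: manual mask required (lumen not enclosed)",
          class = "aortamorph_fallback_failed")
  # closure quality: most of the lumen outline must be backed by bright wall
  # structure nearby, otherwise the watershed ridge is a geometric artefact
  # spanning a genuinely open wall
  lidx0 <- which(lumen, arr.ind = TRUE)
  outline <- trace_contour(lumen, center = c(mean(lidx0[, 1]), mean(lidx0[, 2])),
                           n_theta = 180)
  d_bright <- matrix(as.numeric(EBImage::distmap(
    matrix(as.numeric(!bright), nrow(img), ncol(img)))), nrow(img), ncol(img))
  pos <- cbind(clamp(round(outline$row), 1, nrow(img)),
               clamp(round(outline$col), 1, ncol(img)))
  support <- mean(d_bright[pos] <= 5)
  if (support < 0.75)
    abort(sprintf(
      "fallback failed: manual mask required (only %.0f%% of the lumen outline is backed by wall)",
      100 * support), class = "aortamorph_fallback_failed")
  # closed tube: bright structure plus the watershed ridge lines, hole-filled;
  # a light opening shaves off the 1-px ridge spokes radiating outward
  tube <- bright | (ws == 0)
  filled <- matrix(as.numeric(EBImage::fillHull(
    matrix(as.numeric(tube), nrow(img), ncol(img)))), nrow(img), ncol(img)) > 0.5
  wall <- filled & !lumen
  wall <- matrix(as.numeric(EBImage::opening(
    matrix(as.numeric(wall), nrow(img), ncol(img)), disk_brush(1.5))),
    nrow(img), ncol(img)) > 0.5
  ring <- EBImage::dilate(matrix(as.numeric(lumen), nrow(img), ncol(img)),
                          disk_brush(1.5))
  ring <- (matrix(as.numeric(ring), nrow(img), ncol(img)) > 0.5) & !lumen
  wall <- (wall | ring) & !lumen
  lidx <- which(lumen, arr.ind = TRUE)
  centroid <- c(mean(lidx[, 1]), mean(lidx[, 2]))
  contour <- trace_contour(lumen, center = centroid, n_theta = config$angular_samples)
  contour <- refine_contour_halfmax(img, contour)
  list(wall_mask = wall, lumen_mask = lumen, contour = contour,
       centroid = centroid, provenance = "fallback")
}

#' Segment one slice end to end
#'
#' Standard path (wall, lumen, media-adventitia limit, lamellae); on an
#' open-wall or non-annular failure the dilated-vessel fallback is used, on
#' which only areas are measured downstream.
#'
#' @param img numeric slice.
#' @param config a [pipeline_config()].
#' @param exclusion_mask optional exclusion mask.
#' @param fallback_seed optional lumen seed for the fallback path.
#' @return object of class `slice_segmentation`: masks, contours,
#'   `min_wall_thickness_px` (NA on fallback), `provenance`.
#' @export
segment_slice <- function(img, config = pipeline_config(), exclusion_mask = NULL,
                          fallback_seed = NULL) {
  res <- tryCatch({
    wall <- segment_wall(img, config, exclusion_mask)
    lum <- segment_lumen(img, wall, n_theta = config$angular_samples)
    mal <- media_adventitia_limit(wall, lum$lumen_mask, config, lum$contour)
    lam <- segment_lamellae(img, mal$media_mask, config)
    list(wall_mask = wall, lumen_mask = lum$lumen_mask,
         media_mask = mal$media_mask, adventitia_mask = mal$adventitia_mask,
         lamellae_mask = lam, lumen_contour = lum$contour,
         media_adventitia_contour = mal$contour,
         min_wall_thickness_px = mal$min_wall_thickness_px,
         provenance = "auto")
  }, aortamorph_open_wall = function(e) e, aortamorph_wall_too_thin = function(e) e)
  if (inherits(res, "condition")) {
    fb <- segment_dilated_fallback(img, config, seed_point = fallback_seed)
    media <- fb$wall_mask  # media-adventitia limit requires external input on
                           # fallback slices; whole wall reported as media
    lam <- tryCatch(segment_lamellae(img, media, config),
                    aortamorph_no_contrast = function(e) media & FALSE)
    res <- list(wall_mask = fb$wall_mask, lumen_mask = fb$lumen_mask,
                media_mask = media, adventitia_mask = fb$wall_mask & !media,
                lamellae_mask = lam, lumen_contour = fb$contour,
                media_adventitia_contour = NULL,
                min_wall_thickness_px = NA_real_,
                provenance = "fallback")
  }
  structure(res, class = "slice_segmentation")
}

#' Segment every slice of a stack
#'
#' @param grid a [voxel_grid()].
#' @param config a [pipeline_config()].
#' @param exclusion_masks optional list of per-slice exclusion masks (or NULL
#'   entries).
#' @return object of class `segmentation_stack`: list of
#'   [segment_slice()] results plus `config` and a `failed` tibble.
#' @export
segment_stack <- function(grid, config = pipeline_config(), exclusion_masks = NULL) {
  n <- n_slices(grid)
  slices <- vector("list", n)
  failed <- list()
  last_centroid <- NULL
  for (z in seq_len(n)) {
    ex <- if (!is.null(exclusion_masks)) exclusion_masks[[z]] else NULL
    slices[[z]] <- tryCatch(
      segment_slice(get_slice(grid, z), config, ex, fallback_seed =
                      if (!is.null(last_centroid)) round(last_centroid) else NULL),
      error = function(e) e
    )
    if (inherits(slices[[z]], "slice_segmentation")) {
      last_centroid <- contour_center(slices[[z]]$lumen_contour)
    } else {
      failed[[length(failed) + 1]] <- tibble(slice = z,
                                             error = conditionMessage(slices[[z]]))
      slices[[z]] <- NULL
    }
  }
  failed <- if (length(failed)) dplyr::bind_rows(failed) else
    tibble(slice = integer(), error = character())
  if (nrow(failed) > config$max_failed_slice_frac * n)
    abort(paste0("segmentation failed on ", nrow(failed), "/", n, " slices:\n",
                 paste(sprintf("  slice %d: %s", failed$slice, failed$error),
                       collapse = "\n")),
          class = "aortamorph_run_failed")
  structure(list(slices = slices, config = config, failed = failed,
                 dims = dim(grid$data)),
            class = "segmentation_stack")
}

#' Override the media-adventitia limit on a slice and propagate
#'
#' Replaces the named slice's media-adventitia contour and re-smooths the
#' per-slice polar radius profiles of all slices along the axial direction
#' with a weighted smoothing spline anchored at override slices, mirroring the
#' way a manual correction on one image readjusts its neighbours. Override
#' slices are marked `provenance = "override"`.
#'
#' @param seg a [segment_stack()] result.
#' @param slice_index slice to override (may be vector-recycled over a list of
#'   contours).
#' @param override_contour a contour tibble enclosing that slice's lumen.
#' @param anchor_weight spline weight of anchored slices relative to the rest.
#' @return updated `segmentation_stack`.
#' @export
apply_limit_override <- function(seg, slice_index, override_contour,
                                 anchor_weight = 1000) {
  sl <- seg$slices[[slice_index]]
  if (is.null(sl)) abort("cannot override a failed slice", class = "aortamorph_invalid_override")
  lum_r <- sl$lumen_contour$r
  ov_r <- contour_r_at(override_contour, sl$lumen_contour$theta)
  if (any(ov_r <= lum_r))
    abort("override contour does not enclose the lumen", class = "aortamorph_invalid_override")
  ok <- which(!vapply(seg$slices, is.null, logical(1)))
  ok <- ok[vapply(ok, function(z) !is.null(seg$slices[[z]]$media_adventitia_contour), logical(1))]
  if (!(slice_index %in% ok)) abort("slice has no media-adventitia contour (fallback slice)",
                                    class = "aortamorph_invalid_override")
  theta <- seg$slices[[ok[1]]]$media_adventitia_contour$theta
  R <- vapply(ok, function(z) seg$slices[[z]]$media_adventitia_contour$r,
              numeric(length(theta)))  # [theta x slice]
  R[, ok == slice_index] <- contour_r_at(override_contour, theta)
  w <- rep(1, length(ok)); w[ok == slice_index] <- anchor_weight
  if (length(ok) >= 4) {
    for (i in seq_along(theta)) {
      fit <- stats::smooth.spline(ok, R[i, ], w = w)
      R[i, ] <- stats::predict(fit, ok)$y
    }
  }
  prov <- seg$slices[[slice_index]]$provenance
  for (j in seq_along(ok)) {
    z <- ok[j]
    ctr <- contour_center(seg$slices[[z]]$media_adventitia_contour)
    newc <- new_contour(theta, R[, j], ctr)
    seg$slices[[z]]$media_adventitia_contour <- newc
    wall <- seg$slices[[z]]$wall_mask
    media <- mask_from_contour(newc, dim(wall)) & wall
    seg$slices[[z]]$media_mask <- media
    seg$slices[[z]]$adventitia_mask <- wall & !media
  }
  seg$slices[[slice_index]]$provenance <- "override"
  seg
}

#' Check the set invariants of a slice segmentation
#'
#' Lumen and wall are disjoint; media is a subset of the wall; lamellae are a
#' subset of the media; adventitia is exactly wall minus media; the lumen is a
#' single 4-connected component.
#' @param seg a `slice_segmentation`.
#' @return TRUE invisibly, or an error describing the violated invariant.
#' @export
check_segmentation_invariants <- function(seg) {
  stopifnot(inherits(seg, "slice_segmentation"))
  if (any(seg$lumen_mask & seg$wall_mask)) abort("lumen and wall overlap")
  if (any(seg$media_mask & !seg$wall_mask)) abort("media not a subset of wall")
  if (any(seg$lamellae_mask & !seg$media_mask)) abort("lamellae not a subset of media")
  if (!identical(which(seg$adventitia_mask), which(seg$wall_mask & !seg$media_mask)))
    abort("adventitia != wall \\ media")
  lab <- label_components(seg$lumen_mask, 4)
  if (max(lab) != 1) abort("lumen is not a single 4-connected component")
  invisible(TRUE)
}
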