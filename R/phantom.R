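#' Specify a synthetic aorta phantom
#'
#' Defines a paraffin-embedded vessel as it appears in transverse
#' phase-contrast microCT slices: a roughly circular wall (bright relative to
#' paraffin) containing concentric bright elastic lamellae in a darker
#' interlamellar matrix, an adventitial rim, and paraffin-level grey inside
#' the lumen and outside the wall. The tube axis may be tilted and wavy, the
#' luminal boundary corrugated (wrinkles from loss of intra-luminal pressure),
#' focal dilations bulge the tube, and lamellar breaks carve dark holes across
#' contiguous slices.
#'
#' All geometry is analytic, so every downstream measurement has a closed-form
#' (or quadrature-exact) ground truth; see [analytic_morphometry()].
#'
#' @param n_slices number of slices.
#' @param slice_shape `c(rows, cols)` in pixels.
#' @param voxel_size_um isotropic voxel size (default 1.1 um).
#' @param lumen_radius_px base lumen radius.
#' @param wall_thickness_px radial wall thickness (lumen-wall limit to
#'   adventitia-paraffin limit).
#' @param n_lamellae number of concentric lamellae within the media.
#' @param lamella_thickness_px radial thickness of each lamella.
#' @param media_thickness_px radial thickness of the tunica media band; the
#'   default places the media-adventitia limit where the half-wall +
#'   0.35 x minimum-thickness delineation rule puts it, so that pipeline
#'   recovery error is attributable to the pipeline and not the phantom.
#' @param axis_tilt_deg tilt of the tube axis versus the stack axis (applied
#'   along the column direction).
#' @param axis_waviness list `(amplitude_px, period_slices)`: sinusoidal
#'   centreline displacement along the row direction.
#' @param wrinkle list `(amplitude_px, frequency)`: luminal-boundary
#'   corrugation `r(theta) = R + A sin(f theta)`.
#' @param dilation optional list `(start_slice, end_slice, max_scale)`: smooth
#'   (sin^2 ramp) radial scaling of the vessel, peaking mid-window.
#' @param breaks optional list of lamellar holes, each a list
#'   `(slice_start, slice_end, theta_start_deg, theta_end_deg, lamellae)`
#'   where `lamellae` are the affected ring indices (1 = innermost, the IEL).
#'   Holes show the interlamellar grey, with ~2 px smooth circumferential
#'   edges and crisp axial extent.
#' @param wall_gaps optional list of occlusion artefacts, each a list
#'   `(slice_start, slice_end, theta_start_deg, theta_end_deg)`: the whole
#'   wall sector is rendered at paraffin grey (contrast dropout), which breaks
#'   the wall's annular topology on those slices and exercises the
#'   dilated-vessel fallback. The analytic ground truth still describes the
#'   underlying (occluded) vessel.
#' @param intensity named list of grey levels: `paraffin`, `interlamellar`,
#'   `lamella`, `adventitia`. Must satisfy lamella > interlamellar > paraffin
#'   (phase-contrast appearance). The lamella/matrix separation is deliberately
#'   a free parameter.
#' @param noise_sigma additive Gaussian noise scale (grey levels).
#' @param seed RNG seed; identical spec + seed gives a bit-identical stack.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(n_slices = 64,
                         slice_shape = c(512, 512),
                         voxel_size_um = 1.1,
                         lumen_radius_px = 100,
                         wall_thickness_px = 40,
                         n_lamellae = 3,
                         lamella_thickness_px = 4,
                         media_thickness_px = NULL,
                         axis_tilt_deg = 0,
                         axis_waviness = list(amplitude_px = 0, period_slices = 200),
                         wrinkle = list(amplitude_px = 0, frequency = 12),
                         dilation = NULL,
                         breaks = NULL,
                         wall_gaps = NULL,
                         intensity = list(paraffin = 40, interlamellar = 120,
                                          lamella = 200, adventitia = 100),
                         noise_sigma = 0,
                         seed = 1L) {
  media_thickness_px <- media_thickness_px %||%
    (wall_thickness_px / 2 + round(0.35 * wall_thickness_px))
  spec <- structure(list(
    n_slices = as.integer(n_slices), slice_shape = as.integer(slice_shape),
    voxel_size_um = voxel_size_um, lumen_radius_px = lumen_radius_px,
    wall_thickness_px = wall_thickness_px, n_lamellae = as.integer(n_lamellae),
    lamella_thickness_px = lamella_thickness_px,
    media_thickness_px = media_thickness_px,
    axis_tilt_deg = axis_tilt_deg, axis_waviness = axis_waviness,
    wrinkle = wrinkle, dilation = dilation, breaks = breaks,
    wall_gaps = wall_gaps,
    intensity = intensity, noise_sigma = noise_sigma, seed = as.integer(seed)
  ), class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  s <- spec
  if (s$n_slices < 1) abort("n_slices must be >= 1", class = "aortamorph_invalid_spec")
  if (s$lumen_radius_px <= 0) abort("lumen_radius_px must be > 0", class = "aortamorph_invalid_spec")
  if (s$wall_thickness_px < s$n_lamellae * s$lamella_thickness_px)
    abort("wall thinner than the lamellar stack", class = "aortamorph_invalid_spec")
  if (s$media_thickness_px > s$wall_thickness_px)
    abort("media_thickness_px cannot exceed wall_thickness_px", class = "aortamorph_invalid_spec")
  if (s$media_thickness_px < s$n_lamellae * s$lamella_thickness_px)
    abort("media thinner than the lamellar stack", class = "aortamorph_invalid_spec")
  lv <- s$intensity
  if (!(lv$lamella > lv$interlamellar && lv$interlamellar > lv$paraffin))
    abort("intensity ordering must be lamella > interlamellar > paraffin",
          class = "aortamorph_invalid_spec")
  # vessel must fit in every slice
  geo <- phantom_geometry(s)
  max_r <- max(vapply(seq_len(s$n_slices), function(z) {
    geo$scale(z) * s$lumen_radius_px + abs(s$wrinkle$amplitude_px) + s$wall_thickness_px
  }, numeric(1)))
  margins <- vapply(seq_len(s$n_slices), function(z) {
    ctr <- geo$center(z)
    min(ctr[1] - 1, s$slice_shape[1] - ctr[1], ctr[2] - 1, s$slice_shape[2] - ctr[2])
  }, numeric(1))
  if (any(margins < max_r + 2))
    abort("vessel exceeds slice bounds", class = "aortamorph_invalid_spec")
  invisible(spec)
}

# Analytic geometry shared by the renderer and the ground-truth computation.
phantom_geometry <- function(spec) {
  s <- spec
  z_mid <- (s$n_slices + 1) / 2
  c0 <- (s$slice_shape + 1) / 2
  tilt <- tan(s$axis_tilt_deg * pi / 180)
  wav <- s$axis_waviness
  center <- function(z) {
    row <- c0[1] + if (wav$amplitude_px != 0)
      wav$amplitude_px * sin(2 * pi * (z - 1) / wav$period_slices) else 0
    col <- c0[2] + tilt * (z - z_mid)
    c(row, col)
  }
  scale_at <- function(z) {
    d <- s$dilation
    if (is.null(d)) return(rep(1, length(z)))
    t <- (z - d$start_slice) / (d$end_slice - d$start_slice)
    w <- ifelse(t >= 0 & t <= 1, sin(pi * t)^2, 0)
    1 + (d$max_scale - 1) * w
  }
  r_in <- function(theta, z) {
    scale_at(z) * s$lumen_radius_px +
      s$wrinkle$amplitude_px * sin(s$wrinkle$frequency * theta)
  }
  # fractional coverage removed by breaks for lamella ring i at (theta, z)
  break_cov <- function(theta, z, ring) {
    if (is.null(s$breaks)) return(rep(0, length(theta)))
    cov <- rep(0, length(theta))
    r_ring <- scale_at(z) * s$lumen_radius_px  # edge width scale
    for (b in s$breaks) {
      if (!(ring %in% b$lamellae)) next
      # crisp axial extent (breaks begin/end between sections); smooth ~2 px
      # edges circumferentially only
      cz <- as.numeric(z >= b$slice_start & z <= b$slice_end)
      if (cz <= 0) next
      th0 <- b$theta_start_deg * pi / 180
      th1 <- b$theta_end_deg * pi / 180
      mid <- (th0 + th1) / 2
      half <- (th1 - th0) / 2
      edge <- 2 / max(r_ring, 1)
      depth <- half - abs(angle_diff(theta, mid))
      cth <- clamp(depth / edge, 0, 1)
      cov <- pmax(cov, cth * cz)
    }
    cov
  }
  # lamella ring i: radial band [r_in + c_i - t/2, r_in + c_i + t/2].
  # Ring 1 (the IEL) starts exactly at the lumen border; the remaining rings
  # span the media evenly. Offsets are symmetric about the media midline, so
  # the lamellar area fraction is exactly n t / T_media (n >= 2).
  ring_offset <- function(i) {
    t2 <- s$lamella_thickness_px / 2
    if (s$n_lamellae == 1) return(t2)
    t2 + (s$media_thickness_px - s$lamella_thickness_px) *
      (i - 1) / (s$n_lamellae - 1)
  }
  list(center = center, scale = scale_at, r_in = r_in,
       break_cov = break_cov, ring_offset = ring_offset)
}

#' Generate a synthetic aorta stack with ground truth
#'
#' Renders the phantom described by `spec` with analytic antialiasing: each
#' radial boundary gets 1-px linear coverage blending on the radial signed
#' distance, which is the exact box-filter average for radially varying
#' regions and gives subpixel-accurate boundaries.
#'
#' @param spec a [phantom_spec()].
#' @param include_masks also render per-slice ground-truth masks (wall, media,
#'   lamellae) as logical arrays; switch off for large stacks where only the
#'   analytic table is needed.
#' @return list with `grid` (a [voxel_grid()]) and `truth`
#'   (see [analytic_morphometry()], plus `masks` when requested).
#' @export
generate_phantom <- function(spec, include_masks = TRUE) {
  validate_phantom_spec(spec)
  s <- spec
  geo <- phantom_geometry(s)
  nr <- s$slice_shape[1]; nc <- s$slice_shape[2]
  lv <- s$intensity
  t2 <- s$lamella_thickness_px / 2
  data <- array(0, dim = c(nr, nc, s$n_slices))
  masks <- if (include_masks) list(
    wall = array(FALSE, dim(data)), media = array(FALSE, dim(data)),
    lamellae = array(FALSE, dim(data))
  ) else NULL
  band <- function(r, lo, hi) clamp(pmin(r - lo, hi - r) + 0.5, 0, 1)
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  # in-plane coordinates are mapped to true distance-from-axis: for a tilted
  # cylinder the transverse cut is an ellipse with major axis R / cos(tilt),
  # which sqrt((dx cos_t)^2 + dy^2) <= R reproduces exactly
  cos_t <- cos(s$axis_tilt_deg * pi / 180)
  for (z in seq_len(s$n_slices)) {
    ctr <- geo$center(z)
    dy <- rows - ctr[1]; dx <- (cols - ctr[2]) * cos_t
    r <- sqrt(dx^2 + dy^2)
    th <- wrap_angle(atan2(dy, dx))
    rin <- geo$r_in(th, z)
    rout <- rin + s$wall_thickness_px
    rmed <- rin + s$media_thickness_px
    img <- lv$paraffin +
      (lv$interlamellar - lv$paraffin) * band(r, rin, rout) +
      (lv$adventitia - lv$interlamellar) * band(r, rmed, rout)
    lam_cov <- 0
    for (i in seq_len(s$n_lamellae)) {
      ci <- geo$ring_offset(i)
      cov_i <- band(r, rin + ci - t2, rin + ci + t2) *
        (1 - geo$break_cov(th, z, i))
      lam_cov <- lam_cov + cov_i
    }
    img <- img + (lv$lamella - lv$interlamellar) * pmin(lam_cov, 1)
    if (!is.null(s$wall_gaps)) {
      for (g in s$wall_gaps) {
        if (z < g$slice_start || z > g$slice_end) next
        mid <- (g$theta_start_deg + g$theta_end_deg) / 2 * pi / 180
        half <- (g$theta_end_deg - g$theta_start_deg) / 2 * pi / 180
        sel <- abs(angle_diff(th, mid)) <= half & r >= rin - 2 & r <= rout + 2
        img[sel] <- lv$paraffin
      }
    }
    data[, , z] <- img
    if (include_masks) {
      masks$wall[, , z] <- r >= rin & r <= rout
      masks$media[, , z] <- r >= rin & r <= rmed
      lam <- matrix(FALSE, nr, nc)
      for (i in seq_len(s$n_lamellae)) {
        ci <- geo$ring_offset(i)
        lam <- lam | (r >= rin + ci - t2 & r <= rin + ci + t2 &
                        geo$break_cov(th, z, i) < 0.5)
      }
      masks$lamellae[, , z] <- lam
    }
  }
  if (s$noise_sigma > 0) {
    withr::with_seed(s$seed, {
      data <- data + stats::rnorm(length(data), 0, s$noise_sigma)
    })
    data <- clamp(data, 0, 65535)
  }
  truth <- analytic_morphometry(s)
  if (include_masks) truth$masks <- masks
  list(grid = voxel_grid(data, s$voxel_size_um, source_depth = "synthetic"),
       truth = truth)
}

#' Closed-form per-slice ground truth of a phantom
#'
#' Diameter, media thickness, compartment areas and lamellar fraction computed
#' from the generating radius functions, not from rendered pixels. Areas of
#' wrinkled annuli are computed by adaptive quadrature of
#' `(r_out(theta)^2 - r_in(theta)^2) / 2` (relative error < 1e-6); lamellar
#' rings affected by breaks have the removed angular coverage integrated with
#' the same coverage function the renderer uses.
#'
#' @param spec a [phantom_spec()].
#' @return list with `per_slice` (tibble: slice, centre, scale, diameter_um,
#'   media_thickness_um, media_area_um2, lamellae_area_um2,
#'   interlamellar_area_um2, lamellae_pct), `centerline` (tibble: slice, row,
#'   col) and `breaks` (tibble with analytic en-face areas, um^2).
#' @export
analytic_morphometry <- function(spec) {
  validate_phantom_spec(spec)
  s <- spec
  geo <- phantom_geometry(s)
  v <- s$voxel_size_um
  t_l <- s$lamella_thickness_px
  quad <- function(f) stats::integrate(f, 0, 2 * pi, rel.tol = 1e-9,
                                       subdivisions = 400L)$value
  per <- purrr::map(seq_len(s$n_slices), function(z) {
    ctr <- geo$center(z)
    sc <- geo$scale(z)
    # media band area by quadrature of the generating radii
    media_px2 <- quad(function(th) {
      rin <- geo$r_in(th, z)
      ((rin + s$media_thickness_px)^2 - rin^2) / 2
    })
    lam_px2 <- sum(vapply(seq_len(s$n_lamellae), function(i) {
      ci <- geo$ring_offset(i)
      quad(function(th) {
        rin <- geo$r_in(th, z)
        ((rin + ci + t_l / 2)^2 - (rin + ci - t_l / 2)^2) / 2 *
          (1 - geo$break_cov(th, z, i))
      })
    }, numeric(1)))
    tibble(
      slice = z, center_row = ctr[1], center_col = ctr[2], scale = sc,
      lumen_radius_px = sc * s$lumen_radius_px,
      diameter_um = 2 * sc * s$lumen_radius_px * v,
      media_thickness_um = s$media_thickness_px * v,
      media_area_um2 = media_px2 * v^2,
      lamellae_area_um2 = lam_px2 * v^2,
      interlamellar_area_um2 = (media_px2 - lam_px2) * v^2,
      lamellae_pct = 100 * lam_px2 / media_px2
    )
  }) |> dplyr::bind_rows()
  centerline <- tibble(
    slice = seq_len(s$n_slices),
    row = vapply(seq_len(s$n_slices), function(z) geo$center(z)[1], numeric(1)),
    col = vapply(seq_len(s$n_slices), function(z) geo$center(z)[2], numeric(1))
  )
  brk <- if (is.null(s$breaks)) {
    tibble(id = integer(), slice_start = integer(), slice_end = integer(),
           theta_start_deg = numeric(), theta_end_deg = numeric(),
           enface_area_um2 = numeric())
  } else {
    purrr::imap(s$breaks, function(b, i) {
      # en-face area on the IEL surface: arc length removed at the lumen
      # radius, integrated over the affected slices (only holes reaching the
      # innermost lamella are visible on the IEL surface)
      area <- sum(vapply(seq(b$slice_start, b$slice_end), function(z) {
        if (!(1L %in% b$lamellae)) return(0)
        r_l <- geo$scale(z) * s$lumen_radius_px
        quad(function(th) geo$break_cov(th, z, 1L) * r_l)
      }, numeric(1))) * v^2
      tibble(id = i, slice_start = b$slice_start, slice_end = b$slice_end,
             theta_start_deg = b$theta_start_deg, theta_end_deg = b$theta_end_deg,
             enface_area_um2 = area)
    }) |> dplyr::bind_rows()
  }
  list(per_slice = per, centerline = centerline, breaks = brk)
}

#' Exact lamellar area fraction of concentric rings in an annular media
#'
#' Ratio of summed ring areas to the area of the annulus
#' `[r_in, r_in + media_thickness]`, in percent. Ring offsets follow the
#' generator's placement (innermost ring flush with the lumen border, rings
#' evenly spanning the media); offsets are symmetric about the media midline,
#' so for `n >= 2` the ratio reduces exactly to
#' `100 * n * t / media_thickness`.
#' @param r_in inner (lumen) radius, px.
#' @param media_thickness media band thickness, px.
#' @param n_lamellae,lamella_thickness ring count and thickness, px.
#' @return percentage in \[0, 100\].
#' @export
ring_area_fraction <- function(r_in, media_thickness, n_lamellae, lamella_thickness) {
  offs <- if (n_lamellae == 1) lamella_thickness / 2 else
    lamella_thickness / 2 + (media_thickness - lamella_thickness) *
      (seq_len(n_lamellae) - 1) / (n_lamellae - 1)
  ring <- sum(pi * ((r_in + offs + lamella_thickness / 2)^2 -
                      (r_in + offs - lamella_thickness / 2)^2))
  annulus <- pi * ((r_in + media_thickness)^2 - r_in^2)
  100 * ring / annulus
}

#' Write a phantom to disk
#'
#' Stack as 16-bit multi-page TIFF, ground truth as CSV, masks (if present) as
#' 8-bit TIFF stacks.
#' @param phantom result of [generate_phantom()].
#' @param dir output directory (created if needed).
#' @return invisibly, the written file paths.
#' @export
write_phantom <- function(phantom, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(stack = file.path(dir, "phantom.tif"),
             truth = file.path(dir, "ground_truth.csv"))
  write_stack(phantom$grid, paths[["stack"]])
  utils::write.csv(phantom$truth$per_slice, paths[["truth"]], row.names = FALSE)
  if (!is.null(phantom$truth$masks)) {
    for (nm in names(phantom$truth$masks)) {
      p <- file.path(dir, paste0("mask_", nm, ".tif"))
      write_stack(phantom$truth$masks[[nm]], p)
      paths[nm] <- p
    }
  }
  invisible(paths)
}

#' Read a phantom spec from a YAML/JSON config file
#'
#' Keys match the arguments of [phantom_spec()]; absent keys take defaults.
#' @param path config file.
#' @return a `phantom_spec`.
#' @export
read_phantom_spec <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(phantom_spec))
  bad <- setdiff(names(raw), known)
  if (length(bad)) abort(paste("unknown phantom spec keys:", paste(bad, collapse = ", ")),
                         class = "aortamorph_invalid_spec")
  do.call(phantom_spec, raw)
}
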