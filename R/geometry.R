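#' Vessel centreline from per-slice lumen centroids
#'
#' Cubic smoothing splines (one per in-plane coordinate, parameterised by
#' slice index) through the lumen centroids of all segmented slices.
#'
#' @param centroids tibble with columns `slice`, `row`, `col` (as produced by
#'   [tidy.segmentation_stack()] or the phantom ground truth), or a
#'   `segmentation_stack`.
#' @param spar smoothing parameter of [stats::smooth.spline()]; `NULL` lets
#'   generalised cross-validation choose it.
#' @return object of class `centerline`.
#' @export
compute_centerline <- function(centroids, spar = NULL) {
  if (inherits(centroids, "segmentation_stack")) {
    ok <- which(!vapply(centroids$slices, is.null, logical(1)))
    centroids <- tibble(
      slice = ok,
      row = vapply(ok, function(z) contour_center(centroids$slices[[z]]$lumen_contour)[1], numeric(1)),
      col = vapply(ok, function(z) contour_center(centroids$slices[[z]]$lumen_contour)[2], numeric(1))
    )
  }
  if (nrow(centroids) < 4)
    abort("centreline needs at least 4 slices with valid lumina",
          class = "aortamorph_too_few_slices")
  fit <- function(y) {
    if (is.null(spar)) stats::smooth.spline(centroids$slice, y)
    else stats::smooth.spline(centroids$slice, y, spar = spar)
  }
  structure(list(fit_row = fit(centroids$row), fit_col = fit(centroids$col),
                 range = range(centroids$slice), centroids = centroids),
            class = "centerline")
}

#' Evaluate a centreline
#'
#' @param centerline a [compute_centerline()] result.
#' @param s axial positions (slice units) within the fitted range.
#' @return tibble with `slice`, `row`, `col` and unit tangent components
#'   `t_row`, `t_col`, `t_slice`.
#' @export
centerline_at <- function(centerline, s) {
  row <- stats::predict(centerline$fit_row, s)$y
  col <- stats::predict(centerline$fit_col, s)$y
  dr <- stats::predict(centerline$fit_row, s, deriv = 1)$y
  dc <- stats::predict(centerline$fit_col, s, deriv = 1)$y
  len <- sqrt(dr^2 + dc^2 + 1)
  if (any(!is.finite(len)) || any(len <= 0))
    abort("degenerate centreline tangent", class = "aortamorph_degenerate_centerline")
  tibble(slice = s, row = row, col = col,
         t_row = dr / len, t_col = dc / len, t_slice = 1 / len)
}

#' @export
print.centerline <- function(x, ...) {
  cat(sprintf("<centerline> fitted on %d slices (%g..%g)\n",
              nrow(x$centroids), x$range[1], x$range[2]))
  invisible(x)
}

#' Reslice a stack orthogonal to the vessel axis
#'
#' Resamples the stack on planes orthogonal to the local centreline tangent
#' (trilinear interpolation, plane spacing = voxel size), yielding transverse
#' virtual cuts of the tube. In-plane frames are carried along the axis by
#' parallel transport of an initial basis, so no spurious axial twist is
#' introduced. Each output slice is centred on the centreline.
#'
#' @param grid a [voxel_grid()].
#' @param centerline a [compute_centerline()] result.
#' @param out_shape `c(rows, cols)` of the output slices (default: input
#'   shape).
#' @param fill value for samples outside the input volume edges (edge clamp).
#' @return a [voxel_grid()] with the same voxel size.
#' @export
reslice_orthogonal <- function(grid, centerline, out_shape = NULL) {
  d <- dim(grid$data)
  out_shape <- out_shape %||% d[1:2]
  n <- d[3]
  cl <- centerline_at(centerline, seq_len(n))
  # initial in-plane basis orthogonal to the first tangent
  tangents <- cbind(cl$t_row, cl$t_col, cl$t_slice)  # (row, col, slice) comps
  U <- matrix(0, n, 3); V <- matrix(0, n, 3)
  t1 <- tangents[1, ]
  u <- c(1, 0, 0) - sum(c(1, 0, 0) * t1) * t1
  if (sqrt(sum(u^2)) < 1e-6) u <- c(0, 1, 0) - sum(c(0, 1, 0) * t1) * t1
  u <- u / sqrt(sum(u^2))
  v <- c(t1[2] * u[3] - t1[3] * u[2],
         t1[3] * u[1] - t1[1] * u[3],
         t1[1] * u[2] - t1[2] * u[1])
  U[1, ] <- u; V[1, ] <- v
  for (i in seq_len(n)[-1]) {
    tv <- tangents[i, ]
    u <- U[i - 1, ] - sum(U[i - 1, ] * tv) * tv
    u <- u / sqrt(sum(u^2))
    v <- c(tv[2] * u[3] - tv[3] * u[2],
           tv[3] * u[1] - tv[1] * u[3],
           tv[1] * u[2] - tv[2] * u[1])
    U[i, ] <- u; V[i, ] <- v
  }
  ctr <- (out_shape + 1) / 2
  rr <- matrix(seq_len(out_shape[1]), out_shape[1], out_shape[2]) - ctr[1]
  cc <- matrix(seq_len(out_shape[2]), out_shape[1], out_shape[2], byrow = TRUE) - ctr[2]
  out <- array(0, dim = c(out_shape, n))
  for (i in seq_len(n)) {
    p0 <- c(cl$row[i], cl$col[i], cl$slice[i])
    pr <- p0[1] + rr * U[i, 1] + cc * V[i, 1]
    pc <- p0[2] + rr * U[i, 2] + cc * V[i, 2]
    ps <- p0[3] + rr * U[i, 3] + cc * V[i, 3]
    out[, , i] <- matrix(trilinear(grid$data, as.vector(pr), as.vector(pc),
                                   as.vector(ps)), out_shape[1], out_shape[2])
  }
  voxel_grid(out, grid$voxel_size_um, source_depth = grid$source_depth)
}

#' Virtually open a slice: local Cartesian-to-polar unwrap
#'
#' For each of K contour points, a ray is cast outward along the local normal
#' of the lumen-wall limit; intensities are sampled bilinearly at unit-pixel
#' radial steps. Each point of the limit acts as a local centre, so the
#' annular wall is converted into a straight band whose depth-0 edge is the
#' lumen-wall limit at every angle.
#'
#' @param img numeric slice.
#' @param lumen_contour lumen contour tibble (K points).
#' @param n_depth radial depth samples.
#' @return object of class `unwrapped_slice`: `image` (K x n_depth matrix,
#'   row k = profile along ray k), `contour`, `depth_step` (1 px),
#'   `angular_step` (radians).
#' @export
unwrap_polar <- function(img, lumen_contour, n_depth = 80) {
  K <- nrow(lumen_contour)
  nrm <- contour_normals(lumen_contour)
  depths <- seq(0, n_depth - 1)
  rows <- outer(lumen_contour$row, rep(1, n_depth)) + outer(nrm[, "row"], depths)
  cols <- outer(lumen_contour$col, rep(1, n_depth)) + outer(nrm[, "col"], depths)
  # reject self-intersecting ray fans: adjacent rays crossing within the band
  # manifest as non-monotone angular ordering of mid-depth samples
  ctr <- contour_center(lumen_contour)
  vals <- matrix(bilinear(img, as.vector(rows), as.vector(cols)), K, n_depth)
  structure(list(image = vals, contour = lumen_contour, normals = nrm,
                 depth_step = 1, angular_step = 2 * pi / K,
                 dims = dim(img)),
            class = "unwrapped_slice")
}

#' Map an unwrapped band back to Cartesian pixel space
#'
#' Inverse of [unwrap_polar()] for binary bands: each Cartesian pixel near the
#' wall is assigned the band value at its nearest contour point and its signed
#' depth along that point's normal.
#'
#' @param band K x n_depth matrix (e.g. a thresholded unwrapped mask).
#' @param unwrapped the [unwrap_polar()] result the band came from.
#' @return logical matrix of the original slice shape.
#' @export
rewrap_band <- function(band, unwrapped) {
  ct <- unwrapped$contour
  ctr <- contour_center(ct)
  K <- nrow(ct); n_depth <- ncol(band)
  dims <- unwrapped$dims
  r_max <- max(ct$r) + n_depth + 2
  rows <- matrix(seq_len(dims[1]), dims[1], dims[2])
  cols <- matrix(seq_len(dims[2]), dims[1], dims[2], byrow = TRUE)
  dy <- rows - ctr[1]; dx <- cols - ctr[2]
  rr <- sqrt(dx^2 + dy^2)
  cand <- which(rr <= r_max & rr >= max(min(ct$r) - 2, 0))
  th <- wrap_angle(atan2(dy[cand], dx[cand]))
  k0 <- round(th / unwrapped$angular_step)
  # the ray through a pixel is not exactly the ray at its polar angle when the
  # contour is wrinkled: among neighbouring rays, take the one whose normal
  # line passes closest to the pixel
  best_k <- rep(1L, length(cand)); best_depth <- rep(0, length(cand))
  best_lat <- rep(Inf, length(cand))
  for (off in -3:3) {
    k <- ((k0 + off) %% K) + 1
    ddy <- rows[cand] - ct$row[k]; ddx <- cols[cand] - ct$col[k]
    nr <- unwrapped$normals[k, "row"]; nc <- unwrapped$normals[k, "col"]
    depth <- ddy * nr + ddx * nc
    lat <- abs(ddy * nc - ddx * nr)
    better <- lat < best_lat
    best_k[better] <- k[better]
    best_depth[better] <- depth[better]
    best_lat[better] <- lat[better]
  }
  di <- best_depth + 1
  ok <- di >= 0.5 & di <= n_depth + 0.499
  out <- matrix(FALSE, dims[1], dims[2])
  # bilinear lookup along the depth axis of the band
  d0 <- clamp(floor(di[ok]), 1, n_depth - 1)
  fd <- clamp(di[ok] - d0, 0, 1)
  v <- (1 - fd) * band[cbind(best_k[ok], d0)] + fd * band[cbind(best_k[ok], d0 + 1)]
  out[cand[ok]] <- v >= 0.5
  out
}

#' Select the central analysis window of a stack
#'
#' A contiguous range of `n` slices centred on the stack midpoint (floor
#' division for odd remainders), as used for the per-sample morphometry
#' window.
#'
#' @param n_total total slices available (or a [voxel_grid()]).
#' @param n window length.
#' @return integer vector of slice indices (1-based).
#' @export
select_central_window <- function(n_total, n) {
  if (inherits(n_total, "voxel_grid")) n_total <- n_slices(n_total)
  if (n_total < n)
    abort(sprintf("stack too short: %d slices available, %d required", n_total, n),
          class = "aortamorph_stack_too_short")
  start <- floor((n_total - n) / 2) + 1L
  seq.int(start, start + n - 1L)
}
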