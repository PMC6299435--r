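#' Contours
#'
#' Boundary contours (lumen-wall and media-adventitia limits) are represented
#' as tibbles with one row per angular sample: `theta` (radians, in \[0, 2pi)
#' measured from the +col axis towards +row), `r` (radius in pixels from the
#' contour centre) and the corresponding subpixel `row`, `col` positions.
#' The centre is carried in the `center` attribute as `c(row, col)`.
#'
#' @name contours
NULL

new_contour <- function(theta, r, center) {
  out <- tibble(
    theta = wrap_angle(theta),
    r = r,
    row = center[1] + r * sin(theta),
    col = center[2] + r * cos(theta)
  )
  attr(out, "center") <- center
  class(out) <- c("vessel_contour", class(out))
  out
}

contour_center <- function(contour) attr(contour, "center")

#' Trace the outer boundary of a star-shaped mask at subpixel precision
#'
#' Casts `n_theta` rays from the centre and finds the outermost radius at which
#' the bilinearly interpolated mask crosses 0.5. For a solid region this is its
#' boundary; for an annulus it is the outer limit.
#'
#' @param mask binary matrix.
#' @param center `c(row, col)`; default the mask centroid.
#' @param n_theta number of angular samples (contour is ordered
#'   counter-clockwise starting at angle 0).
#' @param r_step radial sampling step in pixels.
#' @return a contour tibble (see [contours]).
#' @export
trace_contour <- function(mask, center = NULL, n_theta = 360, r_step = 0.25) {
  m <- matrix(as.numeric(mask != 0), nrow(mask), ncol(mask))
  if (sum(m) == 0) abort("cannot trace contour of an empty mask", class = "aortamorph_empty_mask")
  if (is.null(center)) {
    idx <- which(m > 0, arr.ind = TRUE)
    center <- c(mean(idx[, 1]), mean(idx[, 2]))
  }
  theta <- 2 * pi * (seq_len(n_theta) - 1) / n_theta
  r_max <- sqrt(nrow(m)^2 + ncol(m)^2)
  rs <- seq(0, r_max, by = r_step)
  ct <- cos(theta); st <- sin(theta)
  # sample all rays at once: matrix [n_theta x length(rs)]
  rows <- center[1] + outer(st, rs)
  cols <- center[2] + outer(ct, rs)
  vals <- matrix(bilinear(m, as.vector(rows), as.vector(cols)), n_theta, length(rs))
  r_out <- vapply(seq_len(n_theta), function(k) {
    v <- vals[k, ]
    inside <- which(v >= 0.5)
    if (length(inside) == 0) return(NA_real_)
    i <- max(inside)
    if (i == length(v)) return(rs[i])
    # linear interpolation of the 0.5 crossing between samples i and i+1
    v0 <- v[i]; v1 <- v[i + 1]
    rs[i] + r_step * (v0 - 0.5) / max(v0 - v1, 1e-9)
  }, numeric(1))
  if (anyNA(r_out)) abort("mask not visible from centre on some rays", class = "aortamorph_trace_failed")
  new_contour(theta, r_out, center)
}

#' Refine a contour to the half-maximum edge of the intensity image
#'
#' For each ray, the intensity profile is sampled radially around the initial
#' boundary estimate; the boundary is relocated to the crossing of the local
#' half-maximum level (midpoint of the inner and outer plateau intensities).
#' This removes the threshold-placement bias of mask-derived boundaries and
#' stays unbiased when interpolation has smoothed the edge.
#'
#' @param img numeric slice.
#' @param contour initial contour tibble.
#' @param halfwidth radial search half-window, px.
#' @return refined contour.
#' @export
refine_contour_halfmax <- function(img, contour, halfwidth = 3) {
  ctr <- contour_center(contour)
  s <- seq(-halfwidth, halfwidth, by = 0.25)
  K <- nrow(contour)
  # radial offsets along each ray direction
  rows <- outer(contour$row, rep(1, length(s))) + outer(sin(contour$theta), s)
  cols <- outer(contour$col, rep(1, length(s))) + outer(cos(contour$theta), s)
  f <- matrix(bilinear(img, as.vector(rows), as.vector(cols)), K, length(s))
  n_edge <- sum(s <= -halfwidth + 1)
  inner <- rowMeans(f[, seq_len(n_edge), drop = FALSE])
  outer_ <- rowMeans(f[, ncol(f) - seq_len(n_edge) + 1, drop = FALSE])
  lev <- (inner + outer_) / 2
  r_new <- vapply(seq_len(K), function(k) {
    v <- f[k, ]
    cr <- if (outer_[k] >= inner[k]) which(v >= lev[k]) else which(v <= lev[k])
    if (length(cr) == 0 || cr[1] == 1) return(contour$r[k])
    i <- cr[1]
    frac <- (lev[k] - v[i - 1]) / (v[i] - v[i - 1] + 1e-12)
    contour$r[k] + s[i - 1] + 0.25 * clamp(frac, 0, 1)
  }, numeric(1))
  new_contour(contour$theta, r_new, ctr)
}

#' Smooth a contour's radius function with a periodic spline
#'
#' Fits `r(theta)` with a cyclic cubic regression spline (period 2*pi) and
#' replaces the radii by the fitted values.
#'
#' @param contour a contour tibble.
#' @param sp smoothing parameter passed to [mgcv::gam()]; `NULL` lets GCV
#'   choose it.
#' @param k basis dimension of the cyclic spline.
#' @return smoothed contour.
#' @export
smooth_contour <- function(contour, sp = NULL, k = 40) {
  k <- min(k, nrow(contour) - 1)
  dat <- data.frame(theta = contour$theta, r = contour$r)
  fit <- mgcv::gam(r ~ s(theta, bs = "cc", k = k), data = dat,
                   knots = list(theta = c(0, 2 * pi)), sp = sp)
  new_contour(contour$theta, as.numeric(stats::predict(fit, dat)), contour_center(contour))
}

#' Periodic linear interpolation of a contour radius function
#' @keywords internal
contour_r_at <- function(contour, theta) {
  th <- contour$theta; r <- contour$r
  o <- order(th); th <- th[o]; r <- r[o]
  th_ext <- c(th[length(th)] - 2 * pi, th, th[1] + 2 * pi)
  r_ext <- c(r[length(r)], r, r[1])
  stats::approx(th_ext, r_ext, xout = wrap_angle(theta), rule = 2)$y
}

#' Outward unit normals of a contour
#'
#' Computed from the polar parameterisation via periodic central differences of
#' r(theta); returned as a two-column matrix of (d_row, d_col) components.
#' @keywords internal
contour_normals <- function(contour) {
  th <- contour$theta; r <- contour$r
  n <- length(th)
  ip <- c(2:n, 1); im <- c(n, 1:(n - 1))
  dth <- wrap_angle(th[ip] - th[im]); dth[dth == 0] <- 2 * pi / n
  drdth <- (r[ip] - r[im]) / dth
  # tangent d/dtheta of c + r (cos, sin): x=col, y=row
  tx <- drdth * cos(th) - r * sin(th)
  ty <- drdth * sin(th) + r * cos(th)
  nx <- ty; ny <- -tx
  # orient outward (positive radial component)
  s <- sign(nx * cos(th) + ny * sin(th)); s[s == 0] <- 1
  nx <- nx * s; ny <- ny * s
  len <- sqrt(nx^2 + ny^2)
  cbind(row = ny / len, col = nx / len)
}

#' Rasterise the region enclosed by a star-shaped contour
#'
#' A pixel is inside when its radius about the contour centre does not exceed
#' the interpolated contour radius at its angle.
#' @param contour contour tibble.
#' @param dims `c(nrow, ncol)` of the output mask.
#' @return logical matrix.
#' @export
mask_from_contour <- function(contour, dims) {
  center <- contour_center(contour)
  rows <- matrix(seq_len(dims[1]), dims[1], dims[2])
  cols <- matrix(seq_len(dims[2]), dims[1], dims[2], byrow = TRUE)
  dy <- rows - center[1]; dx <- cols - center[2]
  r <- sqrt(dx^2 + dy^2)
  th <- wrap_angle(atan2(dy, dx))
  r <= matrix(contour_r_at(contour, as.vector(th)), dims[1], dims[2])
}

#' Direct least-squares ellipse fit
#'
#' Fitzgibbon's ellipse-specific conic fit. Used to approximate the vessel
#' internal circumference, whose mean axis length defines the lumen diameter
#' (mirroring the echocardiographic convention).
#'
#' @param row,col point coordinates (>= 6 points).
#' @return list with `center` (row, col), `axes` (major, minor semi-axes, px)
#'   and `angle` (radians, major axis from +col).
#' @export
fit_ellipse <- function(row, col) {
  if (length(row) < 6) abort("ellipse fit needs at least 6 points", class = "aortamorph_degenerate_fit")
  x <- col - mean(col); y <- row - mean(row)
  D1 <- cbind(x^2, x * y, y^2)
  D2 <- cbind(x, y, 1)
  S1 <- crossprod(D1); S2 <- crossprod(D1, D2); S3 <- crossprod(D2)
  T1 <- tryCatch(-solve(S3, t(S2)), error = function(e) NULL)
  if (is.null(T1)) abort("degenerate ellipse fit (collinear points)", class = "aortamorph_degenerate_fit")
  M <- S1 + S2 %*% T1
  M <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
  ev <- eigen(M)
  a1 <- Re(ev$vectors)
  cond <- 4 * a1[1, ] * a1[3, ] - a1[2, ]^2
  i <- which(cond > 0)
  if (length(i) == 0) abort("degenerate ellipse fit", class = "aortamorph_degenerate_fit")
  a1 <- a1[, i[1]]
  a <- c(a1, as.numeric(T1 %*% a1))  # A B C D E F on centred coords
  A <- a[1]; B <- a[2] / 2; C <- a[3]; D <- a[4] / 2; E <- a[5] / 2; F <- a[6]
  den <- B^2 - A * C
  cx <- (C * D - B * E) / den
  cy <- (A * E - B * D) / den
  num <- 2 * (A * E^2 + C * D^2 + F * B^2 - 2 * B * D * E - A * C * F)
  s <- sqrt((A - C)^2 + 4 * B^2)
  ax1 <- sqrt(num / (den * (s - (A + C))))
  ax2 <- sqrt(num / (den * (-s - (A + C))))
  axes <- sort(c(ax1, ax2), decreasing = TRUE)
  ang <- if (abs(B) < 1e-12 && A <= C) 0 else atan2(2 * B, A - C) / 2
  list(
    center = c(row = cy + mean(row), col = cx + mean(col)),
    axes = axes,
    angle = ang
  )
}
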