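#' @importFrom rlang %||% abort warn
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom purrr map map_dbl map_int map2 imap
NULL

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Discrete disk structuring element
#'
#' Pixels whose centre lies within `radius` of the element centre. Radius 0
#' gives a single pixel.
#' @param radius disk radius in pixels (non-negative; rounded to integer grid).
#' @return binary matrix of odd size.
#' @keywords internal
disk_brush <- function(radius) {
  r <- max(0L, as.integer(round(radius)))
  if (r == 0L) return(matrix(1, 1, 1))
  n <- 2L * r + 1L
  idx <- seq_len(n) - r - 1L
  d2 <- outer(idx^2, idx^2, "+")
  matrix(as.numeric(d2 <= radius^2 + 1e-9), n, n)
}

#' Connected-component labelling with selectable connectivity
#'
#' EBImage's `bwlabel()` is 4-connected; foreground objects in this package are
#' 8-connected, so diagonal-touching labels are merged with a union-find pass.
#' @param mask binary matrix.
#' @param connectivity 4 or 8.
#' @return integer label matrix (0 = background).
#' @keywords internal
label_components <- function(mask, connectivity = 8) {
  m <- matrix(as.numeric(mask != 0), nrow(mask), ncol(mask))
  lab <- EBImage::bwlabel(m)
  lab <- matrix(as.integer(lab), nrow(m), ncol(m))
  if (connectivity == 4 || max(lab) <= 1L) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  parent <- seq_len(max(lab))
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  union_ <- function(a, b) { ra <- find(a); rb <- find(b); if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb) }
  pair_up <- function(a, b) {
    sel <- a > 0L & b > 0L & a != b
    if (any(sel)) {
      u <- unique(cbind(a[sel], b[sel]))
      for (k in seq_len(nrow(u))) union_(u[k, 1], u[k, 2])
    }
  }
  # diagonal neighbours only; orthogonal ones already share labels
  pair_up(lab[-nr, -nc], lab[-1, -1])
  pair_up(lab[-nr, -1], lab[-1, -nc])
  root <- vapply(seq_along(parent), find, integer(1))
  root <- match(root, sort(unique(root)))  # compact labels
  out <- lab
  out[lab > 0L] <- root[lab[lab > 0L]]
  out
}

#' Bilinear interpolation into a 2D image
#'
#' Coordinates are 1-based (row, col) pixel centres; samples outside the image
#' are clamped to the border.
#' @keywords internal
bilinear <- function(img, row, col) {
  nr <- nrow(img); nc <- ncol(img)
  r <- clamp(row, 1, nr); c <- clamp(col, 1, nc)
  r0 <- clamp(floor(r), 1, nr - 1); c0 <- clamp(floor(c), 1, nc - 1)
  fr <- r - r0; fc <- c - c0
  i00 <- img[cbind(r0, c0)]; i10 <- img[cbind(r0 + 1, c0)]
  i01 <- img[cbind(r0, c0 + 1)]; i11 <- img[cbind(r0 + 1, c0 + 1)]
  (1 - fr) * (1 - fc) * i00 + fr * (1 - fc) * i10 + (1 - fr) * fc * i01 + fr * fc * i11
}

#' Trilinear interpolation into a 3D array (row, col, slice), clamped at edges
#' @keywords internal
trilinear <- function(arr, row, col, slice) {
  d <- dim(arr)
  r <- clamp(row, 1, d[1]); c <- clamp(col, 1, d[2]); s <- clamp(slice, 1, d[3])
  r0 <- clamp(floor(r), 1, d[1] - 1); c0 <- clamp(floor(c), 1, d[2] - 1)
  s0 <- if (d[3] > 1) clamp(floor(s), 1, d[3] - 1) else rep(1, length(s))
  fr <- r - r0; fc <- c - c0; fs <- if (d[3] > 1) s - s0 else rep(0, length(s))
  s1 <- pmin(s0 + 1, d[3])
  g <- function(ri, ci, si) arr[cbind(ri, ci, si)]
  v0 <- (1 - fr) * (1 - fc) * g(r0, c0, s0) + fr * (1 - fc) * g(r0 + 1, c0, s0) +
    (1 - fr) * fc * g(r0, c0 + 1, s0) + fr * fc * g(r0 + 1, c0 + 1, s0)
  v1 <- (1 - fr) * (1 - fc) * g(r0, c0, s1) + fr * (1 - fc) * g(r0 + 1, c0, s1) +
    (1 - fr) * fc * g(r0, c0 + 1, s1) + fr * fc * g(r0 + 1, c0 + 1, s1)
  (1 - fs) * v0 + fs * v1
}

#' Natural (numeric-aware) sort of file names
#'
#' Orders `img_2.tif` before `img_10.tif`.
#' @keywords internal
natural_sort <- function(x) {
  if (length(x) <= 1) return(x)
  keys <- lapply(x, function(s) {
    parts <- regmatches(s, gregexpr("[0-9]+|[^0-9]+", s))[[1]]
    parts
  })
  maxlen <- max(lengths(keys))
  pad <- function(parts) {
    out <- character(maxlen)
    for (i in seq_len(maxlen)) {
      p <- if (i <= length(parts)) parts[i] else ""
      out[i] <- if (grepl("^[0-9]+$", p)) sprintf("%020d", as.numeric(p)) else p
    }
    paste(out, collapse = "")
  }
  x[order(vapply(keys, pad, character(1)), method = "radix")]
}

#' Dice similarity coefficient between two binary masks
#' @param a,b binary matrices or arrays of identical dimension.
#' @return Dice coefficient in \[0, 1\]; 1 when both masks are empty.
#' @export
dice <- function(a, b) {
  a <- a != 0; b <- b != 0
  s <- sum(a) + sum(b)
  if (s == 0) return(1)
  2 * sum(a & b) / s
}

wrap_angle <- function(theta) theta %% (2 * pi)

# shortest signed angular distance a - b in (-pi, pi]
angle_diff <- function(a, b) {
  d <- (a - b) %% (2 * pi)
  d[d > pi] <- d[d > pi] - 2 * pi
  d
}

# smoothstep ramp 0..1 over [0, 1]
smoothstep <- function(t) {
  t <- clamp(t, 0, 1)
  t * t * (3 - 2 * t)
}

#' Automatic threshold of a grey-value sample
#'
#' `"isodata"` (Ridler-Calvard, the ImageJ default): iterate the threshold to
#' the midpoint of the two class means. Because the midpoint rule is symmetric
#' in the two classes, the binarised boundary of an antialiased edge falls at
#' ~50% coverage, i.e. at the true subpixel boundary, even when one class has
#' a long bright tail (lamellae). `"otsu"` maximises between-class variance
#' (via EBImage). Both are invariant to affine intensity rescaling.
#'
#' @param vals numeric vector of intensities.
#' @param method "isodata" or "otsu".
#' @return threshold on the scale of `vals`.
#' @export
auto_threshold <- function(vals, method = c("isodata", "otsu")) {
  method <- match.arg(method)
  rng <- range(vals)
  if (diff(rng) <= 0) abort("degenerate histogram: single grey value",
                            class = "aortamorph_no_contrast")
  if (method == "otsu") {
    norm <- (vals - rng[1]) / diff(rng)
    thr <- EBImage::otsu(EBImage::Image(matrix(norm, length(norm), 1)),
                         range = c(0, 1))
    return(rng[1] + as.numeric(thr) * diff(rng))
  }
  t_old <- mean(rng)
  for (i in 1:100) {
    lo <- vals[vals < t_old]; hi <- vals[vals >= t_old]
    if (!length(lo) || !length(hi)) break
    t_new <- (mean(lo) + mean(hi)) / 2
    if (abs(t_new - t_old) < 1e-7 * diff(rng)) { t_old <- t_new; break }
    t_old <- t_new
  }
  t_old
}
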