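# Shared phantom fixtures, built in code and cached per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# mid-size clean vessel: wall thick enough that the 0.35 rule is stable
std_spec <- function(...) {
  phantom_spec(n_slices = 6, slice_shape = c(224, 224), lumen_radius_px = 50,
               wall_thickness_px = 24, n_lamellae = 3, lamella_thickness_px = 3,
               voxel_size_um = 1, ...)
}

std_phantom <- function() cached("std", generate_phantom(std_spec()))

std_config <- function(...) {
  pipeline_config(voxel_size_um = 1, central_window_n_slices = 6,
                  angular_samples = 360, ...)
}

std_slice_seg <- function() {
  cached("std_seg", segment_slice(std_phantom()$grid$data[, , 3], std_config()))
}

# large wrinkle-capable vessel used for contour / unwrap checks
wrinkled_phantom <- function(amplitude = 5) {
  cached(paste0("wrk", amplitude), generate_phantom(
    phantom_spec(n_slices = 2, slice_shape = c(288, 288), lumen_radius_px = 100,
                 wall_thickness_px = 24, n_lamellae = 3, lamella_thickness_px = 3,
                 voxel_size_um = 1,
                 wrinkle = list(amplitude_px = amplitude, frequency = 12))))
}

# ideal (analytic, not rendered) annulus masks for rule checks
ideal_annulus <- function(dims = c(320, 320), r_in = 100, r_out = 140,
                          center = (dims + 1) / 2) {
  rows <- matrix(seq_len(dims[1]), dims[1], dims[2])
  cols <- matrix(seq_len(dims[2]), dims[1], dims[2], byrow = TRUE)
  r <- sqrt((rows - center[1])^2 + (cols - center[2])^2)
  list(wall = r >= r_in & r <= r_out, lumen = r < r_in, r = r,
       center = center)
}

# brute-force Euclidean distance transform (independent oracle)
edt_brute_force <- function(mask) {
  m <- mask != 0
  out <- matrix(0, nrow(m), ncol(m))
  bg <- which(!m, arr.ind = TRUE)
  fg <- which(m, arr.ind = TRUE)
  if (nrow(bg) == 0 || nrow(fg) == 0) return(out)
  for (i in seq_len(nrow(fg))) {
    out[fg[i, 1], fg[i, 2]] <-
      sqrt(min((bg[, 1] - fg[i, 1])^2 + (bg[, 2] - fg[i, 2])^2))
  }
  out
}

# brute-force two-sample KS statistic (max CDF gap over pooled points)
ks_D_brute_force <- function(x, y) {
  pooled <- c(x, y)
  max(vapply(pooled, function(t) abs(mean(x <= t) - mean(y <= t)), numeric(1)))
}

# exhaustive permutation tail probability of the KS statistic
ks_p_permutation <- function(x, y) {
  pooled <- c(x, y)
  n <- length(x)
  D_obs <- ks_D_brute_force(x, y)
  splits <- utils::combn(length(pooled), n)
  Ds <- apply(splits, 2, function(ix)
    ks_D_brute_force(pooled[ix], pooled[-ix]))
  mean(Ds >= D_obs - 1e-12)
}

# analytic circle contour for tests that need contours without images
circle_contour <- function(r, center = c(0, 0), n_theta = 360,
                           r_fun = function(theta) rep(r, length(theta))) {
  theta <- 2 * pi * (seq_len(n_theta) - 1) / n_theta
  rr <- r_fun(theta)
  out <- tibble::tibble(theta = theta, r = rr,
                        row = center[1] + rr * sin(theta),
                        col = center[2] + rr * cos(theta))
  attr(out, "center") <- center
  class(out) <- c("vessel_contour", class(out))
  out
}
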