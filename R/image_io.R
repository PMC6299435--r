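#' 3D voxel grid
#'
#' A greyscale stack with isotropic physical voxel size. Data are held as a
#' numeric (float) array indexed `[row, col, slice]`, 1-based, regardless of
#' the source bit depth; the source depth is recorded. All physical outputs
#' downstream are in um / um^2 via `voxel_size_um`.
#'
#' @param data 3D numeric array `[row, col, slice]` (a matrix is promoted to a
#'   single-slice stack).
#' @param voxel_size_um isotropic voxel size, um (> 0).
#' @param source_depth note on the source bit depth ("8-bit", "16-bit",
#'   "float", "synthetic", ...).
#' @return object of class `voxel_grid`.
#' @export
voxel_grid <- function(data, voxel_size_um, source_depth = "float") {
  if (is.matrix(data)) data <- array(data, dim = c(dim(data), 1))
  stopifnot(length(dim(data)) == 3)
  if (!is.numeric(voxel_size_um) || voxel_size_um <= 0)
    abort("voxel_size_um must be a positive scalar", class = "aortamorph_invalid_grid")
  if (any(dim(data) < 1)) abort("all dimensions must be >= 1", class = "aortamorph_invalid_grid")
  structure(list(data = data, voxel_size_um = voxel_size_um,
                 source_depth = source_depth),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<voxel_grid> %d slices of %d x %d px, voxel %.3g um (%s source)\n",
              d[3], d[1], d[2], x$voxel_size_um, x$source_depth))
  invisible(x)
}

#' @export
dim.voxel_grid <- function(x) dim(x$data)

n_slices <- function(grid) dim(grid$data)[3]

get_slice <- function(grid, z) grid$data[, , z]

#' Read an image stack from TIFF
#'
#' Accepts a multi-page TIFF or a directory of single-page TIFFs, which are
#' ordered by natural (numeric-aware) sort of their file names, so `img_2.tif`
#' precedes `img_10.tif`. Integer sources are read at their native integer
#' values (0..2^bits-1) into a float array.
#'
#' @param path file or directory.
#' @param voxel_size_um isotropic voxel size of the scan, um.
#' @return a [voxel_grid()].
#' @export
read_stack <- function(path, voxel_size_um) {
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.tiff?$", ignore.case = TRUE,
                        full.names = TRUE)
    if (length(files) == 0) abort("no TIFF files in directory", class = "aortamorph_io_error")
    files <- files[order(match(basename(files), natural_sort(basename(files))))]
    pages <- lapply(files, function(f) tiff::readTIFF(f, as.is = TRUE, all = FALSE))
  } else {
    if (!file.exists(path)) abort(paste("no such file:", path), class = "aortamorph_io_error")
    pages <- tiff::readTIFF(path, as.is = TRUE, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
  }
  if (length(pages) == 0) abort("stack has zero slices", class = "aortamorph_io_error")
  pages <- lapply(pages, function(p) if (length(dim(p)) == 3) p[, , 1] else p)
  shp <- dim(pages[[1]])
  for (i in seq_along(pages)) {
    if (!identical(dim(pages[[i]]), shp))
      abort(sprintf("slice %d has shape %s, expected %s", i,
                    paste(dim(pages[[i]]), collapse = "x"),
                    paste(shp, collapse = "x")),
            class = "aortamorph_io_error")
  }
  depth <- attr(pages[[1]], "bits.per.sample") %||% NA
  is_float <- max(vapply(pages, max, numeric(1))) <= 1 && !is.integer(pages[[1]])
  data <- array(0, dim = c(shp[1], shp[2], length(pages)))
  for (i in seq_along(pages)) data[, , i] <- as.numeric(pages[[i]])
  voxel_grid(data, voxel_size_um,
             source_depth = if (is_float) "float" else sprintf("%s-bit", depth %||% "integer"))
}

#' Write a stack (or mask stack) to a multi-page TIFF
#'
#' Greyscale data are rounded to the integer grid and written 16-bit; logical
#' (mask) data are written 8-bit as 0/255. Integer-valued greyscale stacks
#' round-trip bit-identically through [read_stack()].
#'
#' @param x a [voxel_grid()], a 3D array, or a logical mask array/matrix.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_stack <- function(x, path) {
  data <- if (inherits(x, "voxel_grid")) x$data else x
  if (is.matrix(data)) data <- array(data, dim = c(dim(data), 1))
  is_mask <- is.logical(data) || all(data %in% c(0, 1))
  pages <- lapply(seq_len(dim(data)[3]), function(z) {
    sl <- data[, , z]
    if (is_mask) matrix(as.numeric(sl != 0), nrow(sl), ncol(sl))
    else clamp(round(sl), 0, 65535) / 65535
  })
  ok <- tryCatch(tiff::writeTIFF(pages, path,
                                 bits.per.sample = if (is_mask) 8L else 16L),
                 error = function(e) abort(paste("cannot write", path, ":", conditionMessage(e)),
                                           class = "aortamorph_io_error"))
  invisible(path)
}

#' Pipeline configuration
#'
#' Houses the method's constants: the central analysis window (200 slices),
#' the media-adventitia delineation factor (0.35 x minimum wall thickness),
#' the IEL dilation radius (7 px), unwrapping resolution, smoothing and
#' thresholding parameters, and the significance levels used for flagging
#' (0.05 / 0.01 / 0.001, with a 0.05-0.08 trend band).
#'
#' @param voxel_size_um isotropic voxel size, um.
#' @param central_window_n_slices slices analysed around the stack midpoint.
#' @param media_dilation_factor fraction of the minimum wall thickness used to
#'   dilate the inner wall half towards the media-adventitia limit; validated
#'   for this phantom family and C57B/6-like geometry, exposed because its
#'   suitability elsewhere is unknown.
#' @param iel_dilation_px binary dilation radius of the lumen-wall border used
#'   to capture the internal elastic lamina.
#' @param angular_samples rays per slice for unwrapping / thickness sampling.
#' @param smooth_disk_px structuring-element radius for mask smoothing.
#' @param min_lamella_px minimum lamellar component size kept, px.
#' @param contour_spline_sp smoothing parameter of the periodic
#'   media-adventitia contour spline (`NULL` = GCV).
#' @param centerline_spar `spar` of the centreline smoothing spline
#'   (`NULL` = GCV).
#' @param fallback_bright_quantile brightest fraction thresholded by the
#'   dilated-vessel fallback.
#' @param threshold_method automatic binarisation method, "isodata" (ImageJ
#'   default; boundary falls at ~50% edge coverage) or "otsu"; see
#'   [auto_threshold()].
#' @param min_break_area_um2 smallest IEL break reported.
#' @param break_threshold fixed grey threshold for break detection, or `NULL`
#'   for an automatic threshold on the en-face surface.
#' @param break_min_contrast minimum grey-level separation between the dark
#'   and bright surface classes for an automatic break threshold to be
#'   accepted (guards intact surfaces against spurious splits).
#' @param reslice run the orthogonal reslicing stage.
#' @param significance_levels decreasing p thresholds for `*`, `**`, `***`.
#' @param trend_band p interval flagged `#` (trend).
#' @param max_failed_slice_frac tolerated fraction of failed slices per run.
#' @param seed RNG seed recorded in the manifest.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(voxel_size_um = 1.1,
                            central_window_n_slices = 200L,
                            media_dilation_factor = 0.35,
                            iel_dilation_px = 7L,
                            threshold_method = "isodata",
                            angular_samples = 360L,
                            smooth_disk_px = 3L,
                            min_lamella_px = 10L,
                            contour_spline_sp = NULL,
                            centerline_spar = NULL,
                            fallback_bright_quantile = 0.15,
                            min_break_area_um2 = 20,
                            break_threshold = NULL,
                            break_min_contrast = 10,
                            reslice = TRUE,
                            significance_levels = c(0.05, 0.01, 0.001),
                            trend_band = c(0.05, 0.08),
                            max_failed_slice_frac = 0.2,
                            seed = 1L) {
  cfg <- structure(as.list(environment()), class = "pipeline_config")
  validate_pipeline_config(cfg)
  cfg
}

validate_pipeline_config <- function(cfg) {
  check <- function(ok, key, msg) {
    if (!ok) abort(sprintf("config key '%s': %s", key, msg),
                   class = "aortamorph_invalid_config")
  }
  check(cfg$voxel_size_um > 0, "voxel_size_um", "must be > 0")
  check(cfg$media_dilation_factor > 0 && cfg$media_dilation_factor < 1,
        "media_dilation_factor", "must lie in (0, 1)")
  check(cfg$central_window_n_slices >= 1, "central_window_n_slices", "must be >= 1")
  check(cfg$iel_dilation_px >= 0, "iel_dilation_px", "must be >= 0")
  check(cfg$threshold_method %in% c("isodata", "otsu"), "threshold_method",
        "must be 'isodata' or 'otsu'")
  check(cfg$angular_samples >= 8, "angular_samples", "must be >= 8")
  check(cfg$fallback_bright_quantile > 0 && cfg$fallback_bright_quantile < 1,
        "fallback_bright_quantile", "must lie in (0, 1)")
  check(all(diff(cfg$significance_levels) < 0), "significance_levels",
        "must be strictly decreasing")
  check(length(cfg$trend_band) == 2 && cfg$trend_band[1] < cfg$trend_band[2],
        "trend_band", "must be an increasing pair")
  invisible(cfg)
}

#' Load a pipeline configuration from YAML/JSON
#'
#' Absent keys take the defaults of [pipeline_config()]; unknown keys and
#' invariant violations are rejected naming the key.
#' @param path config file (YAML; JSON is a YAML subset).
#' @return a `pipeline_config`.
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(raw), known)
  if (length(bad)) abort(paste("unknown config keys:", paste(bad, collapse = ", ")),
                         class = "aortamorph_invalid_config")
  do.call(pipeline_config, raw)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    cat(sprintf("  %-26s %s\n", nm,
                if (is.null(v)) "NULL" else paste(format(v), collapse = ", ")))
  }
  invisible(x)
}

# md5 of an arbitrary R object via a temporary serialisation
object_checksum <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f)
  unname(tools::md5sum(f))
}

# plain-text run log: effective config + input checksums
write_run_log <- function(path, config, inputs = character(), extra = character()) {
  lines <- c(
    sprintf("aortamorph run log  (%s)", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    "== effective config ==",
    vapply(names(config), function(nm) {
      v <- config[[nm]]
      sprintf("%s: %s", nm, if (is.null(v)) "NULL" else paste(format(v), collapse = ", "))
    }, character(1)),
    "== inputs ==",
    if (length(inputs)) sprintf("%s: %s", names(inputs), inputs) else "(none)",
    extra
  )
  writeLines(lines, path)
  invisible(path)
}
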