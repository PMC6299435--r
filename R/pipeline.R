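resolve_input <- function(input, config, include_masks = FALSE) {
  if (inherits(input, "phantom_spec")) {
    ph <- generate_phantom(input, include_masks = include_masks)
    list(grid = ph$grid, truth = ph$truth,
         checksum = c(phantom_spec = object_checksum(unclass(input))))
  } else if (inherits(input, "voxel_grid")) {
    list(grid = input, truth = NULL,
         checksum = c(grid = object_checksum(input$data)))
  } else if (is.character(input)) {
    g <- read_stack(input, config$voxel_size_um)
    cs <- if (dir.exists(input)) c(dir = unname(object_checksum(input)))
          else c(stack = unname(tools::md5sum(input)))
    list(grid = g, truth = NULL, checksum = cs)
  } else {
    abort("input must be a phantom_spec, voxel_grid or path")
  }
}

# first-pass lumen centroids on the raw stack (wall + lumen only), used to fit
# the centreline before orthogonal reslicing
stack_centroids <- function(grid, config) {
  n <- n_slices(grid)
  rows <- purrr::map(seq_len(n), function(z) {
    res <- tryCatch({
      img <- get_slice(grid, z)
      wall <- segment_wall(img, config)
      lum <- segment_lumen(img, wall, n_theta = 90)
      tibble(slice = z, row = lum$centroid[1], col = lum$centroid[2])
    }, error = function(e) NULL)
    res
  })
  dplyr::bind_rows(rows)
}

#' Run the full morphometry pipeline
#'
#' Orchestrates the workflow end to end: load or generate the stack, estimate
#' the centreline from per-slice lumen centroids, reslice orthogonal to the
#' vessel axis, select the central analysis window, segment every window
#' slice (standard path with dilated-vessel fallback), and measure diameter,
#' media thickness, areas and lamellar fraction per slice plus stack-level
#' summaries. Fallback slices contribute areas and diameter but no thickness.
#'
#' @param input a [phantom_spec()], a [voxel_grid()], or a path to a TIFF
#'   stack/directory.
#' @param config a [pipeline_config()]; `central_window_n_slices` must not
#'   exceed the stack length.
#' @param output_dir optional directory for CSV tables, the run log and mask
#'   exports.
#' @param exclusion_masks optional per-slice exclusion masks (raw-stack
#'   indexing; only honoured when reslicing is disabled).
#' @return object of class `morphometry_run`: `records` (per-slice tibble),
#'   `summary` ([summarize_stack()]), `thickness_samples` (long tibble),
#'   `segmentation`, `centerline`, `window`, `manifest`.
#' @export
run_morphometry <- function(input, config = pipeline_config(), output_dir = NULL,
                            exclusion_masks = NULL) {
  t0 <- proc.time()[["elapsed"]]
  timings <- list()
  tick <- function(stage, t_start) {
    timings[[stage]] <<- proc.time()[["elapsed"]] - t_start
    proc.time()[["elapsed"]]
  }
  inp <- resolve_input(input, config)
  grid <- inp$grid
  t1 <- tick("input", t0)
  cl <- NULL
  if (isTRUE(config$reslice)) {
    cent <- stack_centroids(grid, config)
    cl <- compute_centerline(cent, spar = config$centerline_spar)
    grid <- reslice_orthogonal(grid, cl)
    exclusion_masks <- NULL  # raw-stack masks do not map to resliced frames
  }
  t1 <- tick("reslice", t1)
  window <- select_central_window(n_slices(grid), config$central_window_n_slices)
  wgrid <- voxel_grid(grid$data[, , window, drop = FALSE], grid$voxel_size_um,
                      grid$source_depth)
  seg <- segment_stack(wgrid, config,
                       if (!is.null(exclusion_masks)) exclusion_masks[window] else NULL)
  t1 <- tick("segmentation", t1)
  ok <- which(!vapply(seg$slices, is.null, logical(1)))
  meas <- purrr::map(ok, function(z)
    measure_slice(seg$slices[[z]], slice = window[z], voxel_size_um = config$voxel_size_um))
  records <- dplyr::bind_rows(purrr::map(meas, "record"))
  thick_samples <- dplyr::bind_rows(purrr::map2(meas, records$slice, function(m, sl) {
    if (is.null(m$thickness)) return(NULL)
    dplyr::mutate(m$thickness$samples, slice = sl, .before = 1)
  }))
  summary <- summarize_stack(records, thick_samples)
  t1 <- tick("morphometry", t1)
  manifest <- list(
    config = config, input_checksums = inp$checksum, seed = config$seed,
    window = range(window), n_slices_analysed = length(ok),
    failed_slices = seg$failed,
    provenance = tibble(slice = records$slice, provenance = records$provenance),
    timings = tibble(stage = names(timings), seconds = unlist(timings)),
    outputs = character()
  )
  run <- structure(list(records = records, summary = summary,
                        thickness_samples = thick_samples, segmentation = seg,
                        centerline = cl, window = window, truth = inp$truth,
                        manifest = manifest),
                   class = "morphometry_run")
  if (!is.null(output_dir)) run <- write_morphometry_run(run, output_dir)
  run
}

write_morphometry_run <- function(run, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(records = file.path(output_dir, "records.csv"),
             summary = file.path(output_dir, "summary.csv"),
             thickness = file.path(output_dir, "thickness_samples.csv"),
             log = file.path(output_dir, "run.log"))
  utils::write.csv(run$records, paths[["records"]], row.names = FALSE)
  utils::write.csv(run$summary$summary, paths[["summary"]], row.names = FALSE)
  utils::write.csv(run$thickness_samples, paths[["thickness"]], row.names = FALSE)
  write_run_log(paths[["log"]], run$manifest$config, run$manifest$input_checksums,
                extra = c("== provenance ==",
                          sprintf("slice %d: %s", run$manifest$provenance$slice,
                                  run$manifest$provenance$provenance)))
  run$manifest$outputs <- paths
  run
}

#' @export
print.morphometry_run <- function(x, ...) {
  cat(sprintf("<morphometry_run> %d slices (window %d..%d), %d fallback, %d failed\n",
              nrow(x$records), x$manifest$window[1], x$manifest$window[2],
              sum(x$records$provenance == "fallback"), nrow(x$manifest$failed_slices)))
  print(x$summary$summary)
  invisible(x)
}

#' Run the IEL surface pipeline
#'
#' Segments the whole analysed region (no central-window cropping: the IEL is
#' scored over the full ascending-aorta stack), extracts the IEL shell,
#' projects it en face and quantifies surface breaks.
#'
#' @param input as in [run_morphometry()].
#' @param config a [pipeline_config()].
#' @param output_dir optional directory for the en-face TIFF and break table.
#' @param manual_breaks optional logical matrix (slices x angular samples)
#'   replacing automated break detection.
#' @return object of class `iel_run`: `surface`, `breaks`, `pct`,
#'   `threshold`, `segmentation`, `manifest`.
#' @export
run_iel <- function(input, config = pipeline_config(), output_dir = NULL,
                    manual_breaks = NULL) {
  t0 <- proc.time()[["elapsed"]]
  inp <- resolve_input(input, config)
  grid <- inp$grid
  cl <- NULL
  if (isTRUE(config$reslice)) {
    cent <- stack_centroids(grid, config)
    cl <- compute_centerline(cent, spar = config$centerline_spar)
    grid <- reslice_orthogonal(grid, cl)
  }
  seg <- segment_stack(grid, config)
  shell <- extract_iel(seg, config$iel_dilation_px)
  surface <- enface_projection(grid, shell, seg,
                               max_depth_px = config$iel_dilation_px + 4)
  qb <- quantify_breaks(surface, config, manual_mask = manual_breaks)
  manifest <- list(config = config, input_checksums = inp$checksum,
                   seed = config$seed,
                   elapsed_s = proc.time()[["elapsed"]] - t0,
                   outputs = character())
  run <- structure(list(surface = surface, breaks = qb$breaks, pct = qb$pct,
                        threshold = qb$threshold, segmentation = seg,
                        centerline = cl, truth = inp$truth, manifest = manifest),
                   class = "iel_run")
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- c(surface = file.path(output_dir, "iel_surface.tif"),
               breaks = file.path(output_dir, "breaks.csv"),
               log = file.path(output_dir, "run.log"))
    img <- surface$image
    img[!surface$valid] <- 0
    write_stack(array(img, dim = c(dim(img), 1)), paths[["surface"]])
    utils::write.csv(run$breaks, paths[["breaks"]], row.names = FALSE)
    write_run_log(paths[["log"]], config, inp$checksum,
                  extra = sprintf("break pct: %.4f", run$pct))
    run$manifest$outputs <- paths
  }
  run
}

#' @export
print.iel_run <- function(x, ...) {
  cat(sprintf("<iel_run> %d breaks, %.2f%% of IEL surface\n",
              nrow(x$breaks), x$pct))
  invisible(x)
}

#' Simulate a multi-group phantom cohort and summarise each sample
#'
#' Generates one phantom per sample with the group's wall thickness (jittered
#' across samples to emulate between-animal variability), runs the full
#' morphometry pipeline on each, and returns the per-sample parameter means in
#' the long format [run_group_comparison()] consumes, plus the pooled per-angle
#' thickness samples per group (for distribution comparisons across the
#' cohort).
#'
#' Defaults are scaled-down study conditions: 3 age groups of 5 samples with
#' monotonically increasing wall thickness, mirroring the design of an ageing
#' cohort at desk scale.
#'
#' @param wall_thickness_px_by_group named numeric vector: group label ->
#'   mean wall thickness, px.
#' @param n_per_group samples (animals) per group.
#' @param jitter_sd_px between-sample SD of the wall thickness, px.
#' @param spec_args named list of [phantom_spec()] arguments shared by all
#'   samples.
#' @param config a [pipeline_config()] (its `central_window_n_slices` should
#'   match the phantom length).
#' @param seed cohort seed; each sample derives its own phantom seed from it.
#' @return list with `samples` (long tibble: group, sample, parameter, value),
#'   `pooled_thickness` (group, sample, slice, thickness_um) and `runs`.
#' @export
simulate_cohort <- function(wall_thickness_px_by_group = c(`3mo` = 18, `6mo` = 20, `9mo` = 22),
                            n_per_group = 5,
                            jitter_sd_px = 0.8,
                            spec_args = list(n_slices = 12, slice_shape = c(192, 192),
                                             lumen_radius_px = 40, n_lamellae = 3,
                                             lamella_thickness_px = 2),
                            config = pipeline_config(central_window_n_slices = 12),
                            seed = 1L) {
  groups <- names(wall_thickness_px_by_group)
  walls <- withr::with_seed(seed, {
    lapply(seq_along(groups), function(g)
      pmax(wall_thickness_px_by_group[g] +
             stats::rnorm(n_per_group, 0, jitter_sd_px),
           6))
  })
  runs <- list(); samples <- list(); pooled <- list()
  for (g in seq_along(groups)) {
    for (i in seq_len(n_per_group)) {
      sp <- do.call(phantom_spec, c(spec_args, list(
        wall_thickness_px = walls[[g]][i],
        seed = seed * 1000L + g * 100L + i
      )))
      run <- run_morphometry(sp, config)
      id <- sprintf("%s_s%d", groups[g], i)
      runs[[id]] <- run
      sm <- run$summary$summary
      samples[[id]] <- tibble(group = groups[g], sample = id,
                              parameter = sm$parameter, value = sm$mean)
      pooled[[id]] <- dplyr::mutate(run$thickness_samples,
                                    group = groups[g], sample = id, .before = 1)
    }
  }
  list(samples = dplyr::bind_rows(samples),
       pooled_thickness = dplyr::bind_rows(pooled),
       runs = runs)
}
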