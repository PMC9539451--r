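#' Pipeline configuration
#'
#' Bundles every option of the region -> cycle -> tile processing graph.
#' Cycles are the parallel unit: each cycle is processed independently
#' given the reference-cycle geometry, so outputs are identical for any
#' worker count and any cycle ordering.
#'
#' @param root Raw experiment root (readable by [discover_layout()]).
#' @param out Output root; caches, diagnostics and hyperstacks go here.
#' @param regions Region subset (default all).
#' @param cycles Cycle subset (default all available).
#' @param deconv Run deconvolution (`TRUE`) or pass raw focal planes.
#' @param deconv_opts A [deconv_params()].
#' @param bp_opts A [back_projector_params()].
#' @param af A [af_params()].
#' @param focus_metric One of `focus_metrics`.
#' @param register_mode `"translation"` or `"similarity"`.
#' @param upsample Sub-pixel registration factor.
#' @param blend Mosaic blending, `"linear"` or `"none"`.
#' @param workers Worker processes for cycle-level parallelism.
#' @param seed Seed recorded in the run manifest (processing is
#'   deterministic; the seed covers any future stochastic extension).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(root, out, regions = NULL, cycles = NULL,
                            deconv = TRUE, deconv_opts = deconv_params(),
                            bp_opts = back_projector_params(),
                            af = af_params(), focus_metric = "tenengrad",
                            register_mode = "translation", upsample = 20L,
                            blend = "linear", workers = 1L, seed = 1L) {
  stopifnot(workers >= 1)
  structure(list(root = root, out = out, regions = regions, cycles = cycles,
                 deconv = isTRUE(deconv), deconv_params = deconv_opts,
                 bp_params = bp_opts, af = af,
                 focus_metric = focus_metric,
                 register_mode = register_mode,
                 upsample = as.integer(upsample), blend = blend,
                 workers = as.integer(workers), seed = as.integer(seed)),
            class = "pipeline_config")
}

config_hash <- function(config) {
  x <- config[setdiff(names(config), c("out", "workers"))]
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, force = TRUE,
                              digits = NA), tf)
  unname(tools::md5sum(tf))
}

region_dir <- function(config, region)
  file.path(config$out, sprintf("region_%03d", region))

cache_mosaic_path <- function(config, region, cycle, channel)
  file.path(region_dir(config, region), "cache",
            sprintf("mosaic_c%03d_ch%d.tif", cycle, channel))

# Cached intermediates are stored as 32-bit float pages on the sensor
# scale (clipped to [0, 65535], which the final 16-bit output enforces
# anyway), preserving sub-integer precision across pipeline stages.
write_float_tiff <- function(mat, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  tiff::writeTIFF(pmin(pmax(mat, 0), 65535) / 65535, path,
                  bits.per.sample = 32L, compression = "none",
                  reduce = FALSE)
  invisible(path)
}

read_float_tiff <- function(path) {
  tiff::readTIFF(path) * 65535
}

log_event <- function(config, region, record) {
  path <- file.path(region_dir(config, region), "log.jsonl")
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  cat(jsonlite::toJSON(record, auto_unbox = TRUE, digits = NA), "\n",
      file = path, append = TRUE, sep = "")
}

# Process one cycle of one region: per tile and channel, read the stack,
# select the best-focus plane, deconvolve, register against the reference
# cycle, and compose one registered mosaic per channel at the shared tile
# positions. Returns focus and transform diagnostics; mosaics go to the
# cache.
process_cycle <- function(config, layout, optics, region, cycle, psfs,
                          ref_planes, positions) {
  nch <- length(layout$channels)
  nt <- n_tiles(layout)
  ref_ch <- layout$reference_channel
  focus_rows <- list()
  planes <- lapply(seq_len(nch), function(ch) vector("list", nt))
  for (tile in seq_len(nt)) {
    for (ch in seq_len(nch)) {
      stack <- read_tile(config$root, layout, region, cycle, tile, ch)
      sel <- select_best_plane(stack, config$focus_metric)
      if (config$deconv) {
        dec <- deconvolve(stack, psfs[[ch]], params = config$deconv_params,
                          bp_params = config$bp_params)
        plane <- dec[, , sel$z]
      } else {
        plane <- stack[, , sel$z] * 1.0
      }
      planes[[ch]][[tile]] <- plane
      focus_rows[[length(focus_rows) + 1L]] <-
        c(tile = tile, channel = ch, cycle = cycle, z = sel$z, sel$scores)
    }
  }
  if (cycle == layout$reference_cycle) {
    transforms <- replicate(nt, drift_transform(0, 0, 0, 1, 1),
                            simplify = FALSE)
  } else {
    transforms <- register_cycle_tiles(
      ref_planes, planes[[ref_ch]],
      mode = config$register_mode, upsample = config$upsample)
    for (ch in seq_len(nch)) for (tile in seq_len(nt))
      planes[[ch]][[tile]] <- apply_transform(
        planes[[ch]][[tile]], invert_transform(transforms[[tile]]))
  }
  for (ch in seq_len(nch)) {
    mosaic <- compose_mosaic(planes[[ch]], positions, blend = config$blend,
                             layout = layout)
    write_float_tiff(mosaic, cache_mosaic_path(config, region, cycle, ch))
  }
  focus <- as.data.frame(do.call(rbind, focus_rows))
  names(focus) <- c("tile", "channel", "cycle", "z",
                    paste0("score_z", seq_len(layout$n_z)))
  list(cycle = cycle, focus = focus, transforms = transforms)
}

#' Assemble the final hyperstack of a region from cached mosaics
#'
#' Applies exposure-scaled blank-cycle background subtraction to the
#' marker (non-nuclear) channels of stained cycles, detects high-intensity
#' autofluorescent objects on the first blank cycle's artifact channel,
#' zeroes them across all marker planes, and stacks all cycle-channel
#' mosaics into one [hyperstack()] sharing the reference pixel grid.
#'
#' @param config A [pipeline_config()].
#' @param layout The (possibly partial) [experiment_layout()].
#' @param region Region index.
#' @param cycles Cycles with cached mosaics, in ascending order.
#' @return A [hyperstack()].
#' @export
assemble_region <- function(config, layout, region, cycles) {
  nch <- length(layout$channels)
  nuclear <- vapply(layout$channels, function(c) c$is_nuclear, logical(1))
  blanks <- intersect(layout$blank_cycles, cycles)
  mosaics <- list()
  for (cycle in cycles) for (ch in seq_len(nch))
    mosaics[[paste(cycle, ch)]] <-
      read_float_tiff(cache_mosaic_path(config, region, cycle, ch))
  # blank subtraction on marker channels of stained cycles
  if (length(blanks)) {
    b1 <- min(blanks)
    for (cycle in setdiff(cycles, layout$blank_cycles))
      for (ch in which(!nuclear)) {
        mosaics[[paste(cycle, ch)]] <- subtract_background(
          mosaics[[paste(cycle, ch)]], mosaics[[paste(b1, ch)]],
          exposure_for(layout, ch, cycle), exposure_for(layout, ch, b1))
      }
    # artifact mask from the first blank cycle
    art_ch <- config$af$artifact_channel
    if (is.null(art_ch)) art_ch <- which(!nuclear)[1]
    if (!is.na(art_ch) && length(art_ch)) {
      nuc_ch <- which(nuclear)[1]
      nuc_plane <- if (!is.na(nuc_ch))
        mosaics[[paste(layout$reference_cycle, nuc_ch)]]
      else matrix(0, nrow(mosaics[[1]]), ncol(mosaics[[1]]))
      mask <- detect_artifacts(mosaics[[paste(b1, art_ch)]], nuc_plane,
                               config$af)
      for (cycle in cycles) for (ch in which(!nuclear))
        mosaics[[paste(cycle, ch)]] <-
          remove_artifacts(mosaics[[paste(cycle, ch)]], mask)
      mask_csv <- file.path(region_dir(config, region), "artifacts.csv")
      utils::write.csv(mask$objects, mask_csv, row.names = FALSE)
    }
  }
  keys <- expand.grid(channel = seq_len(nch), cycle = cycles)
  hyperstack(
    planes = lapply(seq_len(nrow(keys)), function(i)
      mosaics[[paste(keys$cycle[i], keys$channel[i])]]),
    cycle = keys$cycle, channel = keys$channel,
    channel_names = vapply(keys$channel,
                           function(ch) layout$channels[[ch]]$name,
                           character(1)))
}

#' Process one region end to end
#'
#' Runs the full chain on one region: per-cycle read -> best-focus
#' selection -> deconvolution -> between-cycle registration, stitching
#' geometry computed once from the reference cycle, blank-cycle background
#' subtraction, autofluorescence artifact masking, and hyperstack
#' assembly. Per-cycle work runs under `config$workers` forked workers;
#' results are identical for any worker count. Intermediate registered
#' mosaics, diagnostics CSVs (focus, transforms, positions, artifacts), a
#' JSON-lines log and a run manifest are written under the region's
#' output directory.
#'
#' @param config A [pipeline_config()].
#' @param region Region index.
#' @param cycles Cycle subset to process (default: all available; must
#'   contain the reference cycle unless its geometry is already cached).
#' @return Invisibly, a list with `hyperstack` (also written to
#'   `hyperstack.tif`), `manifest`, and the diagnostics.
#' @export
process_region <- function(config, region = 1L, cycles = NULL) {
  t_start <- Sys.time()
  disc <- discover_layout(config$root)
  layout <- disc$layout
  optics <- disc$optics
  avail <- disc$cycles_present
  if (is.null(cycles)) cycles <- config$cycles
  if (is.null(cycles)) cycles <- avail
  cycles <- sort(intersect(cycles, avail))
  if (!length(cycles)) stop("no requested cycle is available on disk")
  rdir <- region_dir(config, region)
  dir.create(file.path(rdir, "cache"), recursive = TRUE,
             showWarnings = FALSE)

  pos_path <- file.path(rdir, "positions.csv")
  ref_dir <- file.path(rdir, "cache", "ref_planes")
  status <- data.frame(cycle = cycles, status = "pending",
                       seconds = NA_real_)

  psfs <- if (config$deconv) {
    lapply(layout$channels, function(ch)
      generate_psf(ch$emission_wavelength, optics, layout$n_z))
  } else NULL

  # ---- reference geometry (computed once, reused for every cycle) ------
  if (!file.exists(pos_path) || !dir.exists(ref_dir)) {
    if (!(layout$reference_cycle %in% cycles))
      stop("reference cycle absent from selection and no cached geometry")
    ref_ch <- layout$reference_channel
    ref_planes <- lapply(seq_len(n_tiles(layout)), function(tile) {
      stack <- read_tile(config$root, layout, region, layout$reference_cycle,
                         tile, ref_ch)
      sel <- select_best_plane(stack, config$focus_metric)
      if (config$deconv) {
        dec <- deconvolve(stack, psfs[[ref_ch]],
                          params = config$deconv_params,
                          bp_params = config$bp_params)
        dec[, , sel$z]
      } else stack[, , sel$z] * 1.0
    })
    pairs <- pairwise_translations(ref_planes, layout)
    model <- fit_stage_model(pairs, layout)
    positions <- solve_positions(model, layout)
    write_positions_csv(positions, pos_path)
    utils::write.csv(model$pairs, file.path(rdir, "pairwise.csv"),
                     row.names = FALSE)
    dir.create(ref_dir, recursive = TRUE, showWarnings = FALSE)
    for (tile in seq_along(ref_planes))
      write_float_tiff(ref_planes[[tile]],
                       file.path(ref_dir, sprintf("tile_%03d.tif", tile)))
    log_event(config, region, list(stage = "geometry", region = region,
                                   n_pairs = nrow(pairs)))
  } else {
    positions <- read_positions_csv(pos_path)
    ref_planes <- lapply(seq_len(n_tiles(layout)), function(tile)
      read_float_tiff(file.path(ref_dir, sprintf("tile_%03d.tif", tile))))
  }

  # ---- per-cycle processing (parallel unit: cycle) ---------------------
  todo <- cycles[!vapply(cycles, function(cyc)
    all(file.exists(vapply(seq_along(layout$channels), function(ch)
      cache_mosaic_path(config, region, cyc, ch), character(1)))),
    logical(1))]
  status$status[!(status$cycle %in% todo)] <- "skipped"
  run_one <- function(cyc) {
    t0 <- Sys.time()
    res <- process_cycle(config, layout, optics, region, cyc, psfs,
                         ref_planes, positions)
    res$seconds <- as.numeric(Sys.time() - t0, units = "secs")
    res
  }
  results <- if (config$workers > 1L && length(todo) > 1L) {
    parallel::mclapply(todo, run_one, mc.cores = config$workers,
                       mc.preschedule = FALSE)
  } else {
    lapply(todo, run_one)
  }
  for (res in results) {
    if (inherits(res, "try-error") || is.null(res$cycle)) {
      stop("cycle processing failed: ", paste(res, collapse = " "))
    }
    i <- match(res$cycle, status$cycle)
    status$status[i] <- "done"
    status$seconds[i] <- res$seconds
    log_event(config, region, list(stage = "cycle", region = region,
                                   cycle = res$cycle,
                                   seconds = res$seconds))
  }

  # diagnostics: merge new focus/transform rows with cached ones
  focus_path <- file.path(rdir, "focus.csv")
  done_cycles <- unlist(lapply(results, `[[`, "cycle"))
  old_focus <- if (file.exists(focus_path)) {
    prev <- utils::read.csv(focus_path)
    prev[!(prev$cycle %in% done_cycles), ]
  } else NULL
  focus_all <- do.call(rbind, c(list(old_focus),
                               lapply(results, `[[`, "focus")))
  if (!is.null(focus_all) && nrow(focus_all)) {
    focus_all <- focus_all[order(focus_all$cycle, focus_all$tile,
                                 focus_all$channel), ]
    utils::write.csv(focus_all, focus_path, row.names = FALSE)
  }
  tf_path <- file.path(rdir, "transforms.csv")
  transforms <- if (file.exists(tf_path)) read_transforms_csv(tf_path)
  else list()
  for (res in results) transforms[[res$cycle]] <- res$transforms
  write_transforms_csv(transforms, tf_path)

  # ---- assembly --------------------------------------------------------
  cached <- sort(unique(c(cycles, previously_cached_cycles(config, region,
                                                           layout))))
  hs <- assemble_region(config, layout, region, cached)
  write_hyperstack(hs, file.path(rdir, "hyperstack.tif"))

  manifest <- list(config_hash = config_hash(config),
                   version = tryCatch(
                     as.character(utils::packageVersion("codexpp")),
                     error = function(e) "dev"),
                   region = region, cycles = cycles,
                   status = status,
                   seconds_total = as.numeric(Sys.time() - t_start,
                                              units = "secs"))
  jsonlite::write_json(manifest, file.path(rdir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(list(hyperstack = hs, manifest = manifest,
                 positions = positions, transforms = transforms))
}

previously_cached_cycles <- function(config, region, layout) {
  files <- list.files(file.path(region_dir(config, region), "cache"),
                      pattern = "^mosaic_c\\d+_ch\\d+\\.tif$")
  if (!length(files)) return(integer())
  cyc <- as.integer(sub("^mosaic_c(\\d+)_ch.*$", "\\1", files))
  cnt <- table(cyc)
  as.integer(names(cnt)[cnt == length(layout$channels)])
}

#' Process newly available cycles incrementally
#'
#' Adds cycles to an existing run: the stored reference geometry and all
#' previously computed per-cycle mosaics are reused untouched, only the
#' new cycles are processed, and the hyperstack is re-assembled from the
#' full cache (so a late-arriving blank cycle updates the
#' background-subtracted marker planes without recomputing geometry).
#' Re-submitted cycles are skipped and marked as such in the run manifest.
#'
#' @param config A [pipeline_config()].
#' @param new_cycles Integer cycles now available.
#' @param region Region index.
#' @return As [process_region()].
#' @export
process_incremental <- function(config, new_cycles, region = 1L) {
  rdir <- region_dir(config, region)
  have_geometry <- file.exists(file.path(rdir, "positions.csv"))
  disc <- discover_layout(config$root)
  if (!have_geometry &&
      !(disc$layout$reference_cycle %in% new_cycles))
    stop("reference cycle neither cached nor in the new selection")
  process_region(config, region = region, cycles = new_cycles)
}
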