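# Synthetic raw-experiment generator. Emits a complete TIFF tree that the
# reader discovers exactly, containing every degradation the pipeline
# corrects -- axial focal-plane drift, between-cycle lateral drift,
# per-tile stage jitter, optical blur, shot and read noise, and bright
# erythrocyte-like autofluorescent blobs -- together with a ground-truth
# manifest that serves as the oracle for every stage.

#' Degradation specification for the synthetic generator
#'
#' @param drift_max Maximum between-cycle lateral drift, px (integer,
#'   uniform in `[-drift_max, drift_max]`; cycle 1 has zero drift).
#' @param focal_drift_max Maximum axial focal-plane drift in planes.
#' @param jitter_max Maximum per-tile stage jitter, px.
#' @param n_rbc Number of erythrocyte-like bright blobs per region.
#' @param rbc_bleed Range of the cycle-dependent factor by which blob
#'   autofluorescence carries into marker channels of non-blank cycles.
#'   Erythrocyte autofluorescence varies between imaging cycles, sometimes
#'   exceeding the blank-cycle intensity, which is exactly why plain blank
#'   subtraction leaves residual artifacts; the default range straddles 1
#'   to reproduce that behavior.
#' @param background Per-channel background offset, DN.
#' @param poisson Apply Poisson (shot) noise.
#' @param read_noise_sd Gaussian read noise standard deviation, DN.
#' @param cell_density Cells per pixel of canvas area.
#' @return An object of class `degradation_spec`.
#' @export
degradation_spec <- function(drift_max = 8L, focal_drift_max = 2L,
                             jitter_max = 3L, n_rbc = 12L,
                             rbc_bleed = c(0.85, 1.25), background = 500,
                             poisson = TRUE, read_noise_sd = 30,
                             cell_density = 1 / 1500) {
  structure(list(drift_max = as.integer(drift_max),
                 focal_drift_max = as.integer(focal_drift_max),
                 jitter_max = as.integer(jitter_max),
                 n_rbc = as.integer(n_rbc), rbc_bleed = rbc_bleed,
                 background = background, poisson = isTRUE(poisson),
                 read_noise_sd = read_noise_sd,
                 cell_density = cell_density),
            class = "degradation_spec")
}

#' Degradation presets
#' @param name `"clean"` (no drift, jitter or blobs), `"drifty"`
#'   (defaults), or `"rbc-heavy"` (many bright blobs).
#' @return A [degradation_spec()].
#' @export
synth_preset <- function(name = c("drifty", "clean", "rbc-heavy")) {
  switch(match.arg(name),
         clean = degradation_spec(drift_max = 0L, focal_drift_max = 0L,
                                  jitter_max = 0L, n_rbc = 0L),
         drifty = degradation_spec(),
         `rbc-heavy` = degradation_spec(n_rbc = 30L))
}

#' Default synthetic experiment layout
#'
#' A compact acquisition that exercises every pipeline stage: 2x2 tile
#' grid of 256x256 px, 6 z planes, nuclear (DAPI-like) plus one Cy3-like
#' marker channel, and 4 cycles of which the first is a blank
#' (autofluorescence background) cycle.
#'
#' @param n_cycles Total cycles including the blank.
#' @param tile_px Tile height/width in pixels.
#' @return An [experiment_layout()].
#' @export
default_synth_layout <- function(n_cycles = 4L, tile_px = 256L) {
  experiment_layout(
    grid_rows = 2L, grid_cols = 2L, n_z = 6L,
    channels = list(
      channel_spec("DAPI", 425, exposure_time = 100, is_nuclear = TRUE),
      channel_spec("Cy3", 595, exposure_time = 200)),
    n_cycles = n_cycles, blank_cycles = 1L,
    overlap_fraction = 0.15, tile_shape = c(tile_px, tile_px),
    reference_cycle = 1L)
}

#' Default synthetic optics
#'
#' The acquisition optics of a 20x/0.75 NA air objective system
#' (377.44 nm pixels, 1500 nm z-step); the PSF support is kept at 31 px
#' laterally, which contains the blur of all defocus levels the generator
#' renders.
#'
#' @return An [optical_config()].
#' @export
default_synth_optics <- function() {
  optical_config(numerical_aperture = 0.75, pixel_size_xy = 377.44,
                 z_step = 1500, psf_size_xy = 31L, refractive_index = 1.0)
}

disk_mask <- function(nr, nc, cy, cx, r) {
  yy <- matrix(seq_len(nr), nr, nc)
  xx <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  (yy - cy)^2 + (xx - cx)^2 <= r^2
}

#' Generate a synthetic raw experiment
#'
#' Renders a scene of random non-overlapping disk "cells" (nuclear stain
#' in every cell, markers in random subsets) per region, blurs each z
#' plane with the matching defocus plane of the channel's Born-Wolf PSF,
#' applies per-cycle lateral drift, per-(cycle, tile) stage jitter and
#' per-cycle focal-plane drift, adds Poisson and Gaussian read noise, and
#' writes the tile tree plus `experiment.yaml` and a ground-truth
#' `manifest.json` under `out`. Blank cycles carry only background and
#' bright erythrocyte-like blobs in the marker channels (the blobs also
#' bleed, with a cycle-dependent factor, into the marker channels of
#' stained cycles); the nuclear channel is stained in every cycle.
#'
#' @param out Output directory (created; must not already contain tiles).
#' @param layout An [experiment_layout()].
#' @param optics An [optical_config()].
#' @param degradations A [degradation_spec()].
#' @param seed Integer seed; identical seeds produce byte-identical trees.
#' @return The ground-truth manifest (list), invisibly; also written to
#'   `out/manifest.json`.
#' @export
simulate_experiment <- function(out, layout = default_synth_layout(),
                                optics = default_synth_optics(),
                                degradations = degradation_spec(),
                                seed = 1L) {
  set.seed(seed)
  th <- layout$tile_shape[1]; tw <- layout$tile_shape[2]
  step_y <- round(th * (1 - layout$overlap_fraction))
  step_x <- round(tw * (1 - layout$overlap_fraction))
  margin <- degradations$drift_max + degradations$jitter_max + 4L
  if (margin >= min(step_y, step_x))
    stop("infeasible degradations: drift + jitter exceed the tile step")
  Hc <- (layout$grid_rows - 1L) * step_y + th + 2L * margin
  Wc <- (layout$grid_cols - 1L) * step_x + tw + 2L * margin
  nz <- layout$n_z
  zc <- focal_plane_index(nz)
  n_ch <- length(layout$channels)
  nuclear_ch <- which(vapply(layout$channels, function(c) c$is_nuclear,
                             logical(1)))[1]

  # ---- scene: cells ----------------------------------------------------
  n_cells <- max(3L, round(Hc * Wc * degradations$cell_density))
  cells <- data.frame(id = integer(), y = numeric(), x = numeric(),
                      r = numeric(), nuclear_intensity = numeric())
  marker_members <- matrix(FALSE, 0, n_ch)
  tries <- 0L
  while (nrow(cells) < n_cells && tries < n_cells * 60L) {
    tries <- tries + 1L
    r <- stats::runif(1, 4, 8)
    cy <- stats::runif(1, r + 1, Hc - r); cx <- stats::runif(1, r + 1, Wc - r)
    if (nrow(cells) &&
        any((cells$y - cy)^2 + (cells$x - cx)^2 < (cells$r + r + 2)^2)) next
    cells <- rbind(cells, data.frame(
      id = nrow(cells) + 1L, y = cy, x = cx, r = r,
      nuclear_intensity = stats::runif(1, 15000, 30000)))
    marker_members <- rbind(marker_members,
                            stats::runif(n_ch) < 0.5)
  }
  marker_members[, nuclear_ch] <- TRUE

  nuclear_canvas <- matrix(0, Hc, Wc)
  marker_canvas <- lapply(seq_len(n_ch), function(i) matrix(0, Hc, Wc))
  for (i in seq_len(nrow(cells))) {
    m <- disk_mask(Hc, Wc, cells$y[i], cells$x[i], cells$r[i])
    nuclear_canvas[m] <- nuclear_canvas[m] + cells$nuclear_intensity[i]
    for (ch in seq_len(n_ch)) {
      if (ch == nuclear_ch || !marker_members[i, ch]) next
      marker_canvas[[ch]][m] <- marker_canvas[[ch]][m] +
        stats::runif(1, 8000, 20000)
    }
  }
  marker_canvas[[nuclear_ch]] <- nuclear_canvas

  # ---- scene: erythrocyte-like blobs ----------------------------------
  rbc_canvas <- matrix(0, Hc, Wc)
  artifacts <- data.frame(id = integer(), y = numeric(), x = numeric(),
                          r = numeric(), intensity = numeric(),
                          area = integer(), nuclear_overlap = logical())
  for (i in seq_len(degradations$n_rbc)) {
    r <- stats::runif(1, 3, 6)
    # keep blobs inside the area every stitched mosaic covers, so the
    # manifest truth is observable regardless of drift and jitter
    pad <- margin + r + degradations$jitter_max + 2
    cy <- stats::runif(1, pad, Hc - pad); cx <- stats::runif(1, pad, Wc - pad)
    val <- stats::runif(1, 25000, 50000)
    m <- disk_mask(Hc, Wc, cy, cx, r)
    rbc_canvas[m] <- pmax(rbc_canvas[m], val)
    overlap <- any(nuclear_canvas[m] > 0)
    artifacts <- rbind(artifacts, data.frame(
      id = i, y = cy, x = cx, r = r, intensity = val, area = sum(m),
      nuclear_overlap = overlap))
  }

  # ---- per-cycle degradations -----------------------------------------
  rnd_int <- function(n, a) {
    if (a > 0) sample(seq(-a, a), n, replace = TRUE) else rep(0L, n)
  }
  drift <- data.frame(cycle = seq_len(layout$n_cycles),
                      dy = rnd_int(layout$n_cycles, degradations$drift_max),
                      dx = rnd_int(layout$n_cycles, degradations$drift_max),
                      rotation = 0, scale = 1)
  drift$dy[layout$reference_cycle] <- 0L
  drift$dx[layout$reference_cycle] <- 0L
  focal <- data.frame(cycle = seq_len(layout$n_cycles),
                      z = pmin(pmax(zc + rnd_int(layout$n_cycles,
                                                 degradations$focal_drift_max),
                                    1L), nz))
  focal$z[layout$reference_cycle] <- zc
  nt <- n_tiles(layout)
  jitter <- expand.grid(tile = seq_len(nt), cycle = seq_len(layout$n_cycles))
  jitter$dy <- rnd_int(nrow(jitter), degradations$jitter_max)
  jitter$dx <- rnd_int(nrow(jitter), degradations$jitter_max)
  bleed <- stats::runif(layout$n_cycles, degradations$rbc_bleed[1],
                        degradations$rbc_bleed[2])
  bleed[layout$blank_cycles] <- 1

  # ---- blur stacks per channel content --------------------------------
  # 2-D blur of the canvas with the |defocus|-offset plane of the
  # channel's PSF; blur(a + f b) = blur(a) + f blur(b), so the channel,
  # marker and blob canvases are blurred once per defocus level and
  # combined per cycle.
  psf_big <- lapply(seq_len(n_ch), function(ch)
    generate_psf(layout$channels[[ch]]$emission_wavelength, optics,
                 2L * nz - 1L))
  blur_levels <- function(canvas, psf3) {
    lapply(0:(nz - 1L), function(off) {
      plane <- psf3[, , focal_plane_index(dim(psf3)[3]) + off]
      plane <- plane / sum(plane)
      k <- array(plane, c(dim(plane), 1L))
      out <- fft_convolve(array(canvas, c(dim(canvas), 1L)),
                          psf_otf(k, c(dim(canvas), 1L)))
      matrix(out, nrow(canvas), ncol(canvas))
    })
  }
  marker_blur <- lapply(seq_len(n_ch), function(ch)
    blur_levels(marker_canvas[[ch]], psf_big[[ch]]))
  rbc_blur <- lapply(seq_len(n_ch), function(ch) {
    if (ch == nuclear_ch || degradations$n_rbc == 0L) NULL
    else blur_levels(rbc_canvas, psf_big[[ch]])
  })

  # ---- write tiles -----------------------------------------------------
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  for (region in seq_len(layout$n_regions)) {
    for (cycle in seq_len(layout$n_cycles)) {
      is_blank <- cycle %in% layout$blank_cycles
      for (tile in seq_len(nt)) {
        rc <- tile_row_col(layout, tile)
        j <- jitter[jitter$tile == tile & jitter$cycle == cycle, ]
        y0 <- margin + (rc["row"] - 1L) * step_y + drift$dy[cycle] + j$dy
        x0 <- margin + (rc["col"] - 1L) * step_x + drift$dx[cycle] + j$dx
        for (channel in seq_len(n_ch)) {
          for (z in seq_len(nz)) {
            off <- abs(z - focal$z[cycle]) + 1L
            plane <- matrix(degradations$background, th, tw)
            if (channel == nuclear_ch || !is_blank) {
              src <- marker_blur[[channel]][[off]]
              plane <- plane + src[y0 + seq_len(th), x0 + seq_len(tw)]
            }
            if (channel != nuclear_ch && !is.null(rbc_blur[[channel]])) {
              src <- rbc_blur[[channel]][[off]]
              plane <- plane + bleed[cycle] *
                src[y0 + seq_len(th), x0 + seq_len(tw)]
            }
            if (degradations$poisson)
              plane <- matrix(stats::rpois(length(plane), plane),
                              th, tw)
            if (degradations$read_noise_sd > 0)
              plane <- plane + stats::rnorm(length(plane), 0,
                                            degradations$read_noise_sd)
            write_plane(plane, tile_path(out, region, cycle, tile, z,
                                         channel))
          }
        }
      }
    }
  }
  write_experiment_config(layout, optics, file.path(out, "experiment.yaml"))

  # ---- manifest --------------------------------------------------------
  focal_full <- expand.grid(tile = seq_len(nt), channel = seq_len(n_ch),
                            cycle = seq_len(layout$n_cycles))
  focal_full$z <- focal$z[focal_full$cycle]
  ref_j <- jitter[jitter$cycle == layout$reference_cycle, ]
  pos <- t(vapply(seq_len(nt), function(tile) {
    rc <- tile_row_col(layout, tile)
    jr <- ref_j[ref_j$tile == tile, ]
    c((rc["row"] - 1L) * step_y + jr$dy, (rc["col"] - 1L) * step_x + jr$dx)
  }, numeric(2)))
  mins <- apply(pos, 2, min)
  pos <- sweep(pos, 2, mins)
  # scene coordinates of the stitched reference mosaic origin
  origin <- c(margin, margin) + mins
  manifest <- list(
    seed = seed,
    layout = layout_to_list(layout, optics),
    degradations = unclass(degradations),
    focal = focal_full,
    drift = drift,
    jitter = jitter,
    bleed = data.frame(cycle = seq_len(layout$n_cycles), factor = bleed),
    positions = data.frame(tile = seq_len(nt), y = pos[, 1], x = pos[, 2]),
    scene_origin = as.numeric(origin),
    cells = cbind(cells, stats::setNames(
      as.data.frame(marker_members),
      paste0("marker_", vapply(layout$channels, function(c) c$name,
                               character(1))))),
    artifacts = artifacts)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(manifest)
}

#' Read a ground-truth manifest
#' @param root Experiment root written by [simulate_experiment()].
#' @return Manifest list with data-frame components restored.
#' @export
read_manifest <- function(root) {
  m <- jsonlite::read_json(file.path(root, "manifest.json"),
                           simplifyVector = TRUE)
  for (f in c("focal", "drift", "jitter", "bleed", "positions", "cells",
              "artifacts"))
    if (!is.null(m[[f]])) m[[f]] <- as.data.frame(m[[f]])
  m
}
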