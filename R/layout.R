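#' Channel specification
#'
#' Describes one imaging filter channel of a cyclic multiplexed acquisition.
#'
#' @param name Text label, e.g. `"DAPI"` or `"Cy3"`.
#' @param emission_wavelength Emission wavelength in nanometres.
#' @param exposure_time Exposure time in milliseconds. Either a single value
#'   used for every cycle or a vector with one entry per cycle.
#' @param is_nuclear Logical flag marking the nuclear counterstain channel.
#'
#' @return An object of class `channel_spec`.
#' @export
channel_spec <- function(name, emission_wavelength, exposure_time = 100,
                         is_nuclear = FALSE) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(emission_wavelength) || any(emission_wavelength <= 0))
    stop("emission_wavelength must be > 0")
  if (!is.numeric(exposure_time) || any(exposure_time <= 0))
    stop("exposure_time must be > 0")
  structure(
    list(name = name,
         emission_wavelength = as.numeric(emission_wavelength),
         exposure_time = as.numeric(exposure_time),
         is_nuclear = isTRUE(is_nuclear)),
    class = "channel_spec")
}

#' Optical configuration of the microscope
#'
#' Parameters of the widefield optical train used both for point-spread
#' function synthesis and for the back-projector cutoff frequencies.
#'
#' @param numerical_aperture Objective numerical aperture (dimensionless).
#' @param pixel_size_xy Lateral pixel size in nanometres.
#' @param z_step Axial plane spacing in nanometres.
#' @param psf_size_xy Lateral extent of synthesized PSFs in pixels (odd).
#' @param refractive_index Immersion refractive index (1.0 for air objectives).
#'
#' @return An object of class `optical_config`.
#' @export
optical_config <- function(numerical_aperture = 0.75, pixel_size_xy = 377.44,
                           z_step = 1500, psf_size_xy = 255,
                           refractive_index = 1.0) {
  if (!(numerical_aperture > 0 && numerical_aperture < refractive_index))
    stop("require 0 < numerical_aperture < refractive_index")
  if (pixel_size_xy <= 0 || z_step <= 0) stop("pixel_size_xy and z_step must be > 0")
  psf_size_xy <- as.integer(psf_size_xy)
  if (psf_size_xy < 1L || psf_size_xy %% 2L == 0L)
    stop("psf_size_xy must be a positive odd integer")
  structure(
    list(numerical_aperture = numerical_aperture,
         pixel_size_xy = pixel_size_xy,
         z_step = z_step,
         psf_size_xy = psf_size_xy,
         refractive_index = refractive_index),
    class = "optical_config")
}

#' Experiment layout
#'
#' The (region, cycle, tile, z, channel) grid of a cyclic acquisition plus
#' the addressing conventions shared by the reader, writer and simulator.
#' Tiles are indexed row-major over the grid (serpentine order available via
#' `serpentine = TRUE`); all indices are 1-based.
#'
#' @param grid_rows,grid_cols Tile grid dimensions per region.
#' @param n_z Number of z planes per stack.
#' @param channels List of [channel_spec()] objects (1 to 4).
#' @param n_cycles Number of imaging cycles.
#' @param n_regions Number of tissue regions.
#' @param blank_cycles Integer cycle indices that carry no marker stain
#'   (autofluorescence background cycles).
#' @param overlap_fraction Nominal tile overlap as a fraction of the tile
#'   dimension, in `[0, 0.5)`.
#' @param tile_shape Integer `(height, width)` of a tile in pixels.
#' @param reference_cycle Cycle used as registration/stitching reference.
#' @param reference_channel Channel index used as registration reference
#'   (defaults to the first nuclear channel).
#' @param serpentine Logical; if `TRUE`, even grid rows run right-to-left.
#' @param partial Logical flag marking a layout restricted to a subset of an
#'   acquisition (set by [discover_layout()]).
#'
#' @return An object of class `experiment_layout`.
#' @export
experiment_layout <- function(grid_rows, grid_cols, n_z, channels, n_cycles,
                              n_regions = 1L, blank_cycles = integer(),
                              overlap_fraction = 0.15,
                              tile_shape = c(256L, 256L),
                              reference_cycle = 1L, reference_channel = NULL,
                              serpentine = FALSE, partial = FALSE) {
  if (inherits(channels, "channel_spec")) channels <- list(channels)
  stopifnot(grid_rows >= 1, grid_cols >= 1, n_z >= 1, n_cycles >= 1,
            n_regions >= 1)
  if (length(channels) < 1L || length(channels) > 4L)
    stop("between 1 and 4 channels are supported")
  if (!all(vapply(channels, inherits, logical(1), "channel_spec")))
    stop("channels must be a list of channel_spec objects")
  if (!(overlap_fraction >= 0 && overlap_fraction < 0.5))
    stop("overlap_fraction must lie in [0, 0.5)")
  blank_cycles <- as.integer(blank_cycles)
  if (length(blank_cycles) && any(blank_cycles < 1L | blank_cycles > n_cycles))
    stop("blank_cycles must be cycle indices in [1, n_cycles]")
  tile_shape <- as.integer(tile_shape)
  stopifnot(length(tile_shape) == 2L, all(tile_shape >= 1L))
  if (is.null(reference_channel)) {
    nuc <- which(vapply(channels, function(ch) ch$is_nuclear, logical(1)))
    reference_channel <- if (length(nuc)) nuc[1L] else 1L
  }
  reference_cycle <- as.integer(reference_cycle)
  reference_channel <- as.integer(reference_channel)
  if (reference_cycle < 1L || reference_cycle > n_cycles)
    stop("reference_cycle out of range")
  if (reference_channel < 1L || reference_channel > length(channels))
    stop("reference_channel out of range")
  structure(
    list(n_regions = as.integer(n_regions),
         grid_rows = as.integer(grid_rows), grid_cols = as.integer(grid_cols),
         n_z = as.integer(n_z), channels = channels,
         n_cycles = as.integer(n_cycles), blank_cycles = blank_cycles,
         overlap_fraction = overlap_fraction, tile_shape = tile_shape,
         reference_cycle = reference_cycle,
         reference_channel = reference_channel,
         serpentine = isTRUE(serpentine), partial = isTRUE(partial)),
    class = "experiment_layout")
}

#' @export
print.experiment_layout <- function(x, ...) {
  cat(sprintf(paste0("<experiment_layout> %d region(s), %dx%d tile grid, ",
                     "%d z, %d channel(s), %d cycle(s)%s\n"),
              x$n_regions, x$grid_rows, x$grid_cols, x$n_z,
              length(x$channels), x$n_cycles,
              if (x$partial) " [partial]" else ""))
  cat(sprintf("  tiles %dx%d px, overlap %.0f%%, blank cycles: %s\n",
              x$tile_shape[1], x$tile_shape[2], 100 * x$overlap_fraction,
              if (length(x$blank_cycles)) paste(x$blank_cycles, collapse = ",")
              else "none"))
  cat(sprintf("  reference: cycle %d, channel %d (%s)\n", x$reference_cycle,
              x$reference_channel, x$channels[[x$reference_channel]]$name))
  invisible(x)
}

#' Number of tiles per region
#' @param layout An [experiment_layout()].
#' @return Integer tile count.
#' @export
n_tiles <- function(layout) layout$grid_rows * layout$grid_cols

#' Map a tile index to its grid row and column
#'
#' Tiles are numbered 1..`n_tiles(layout)` row-major; with
#' `layout$serpentine` even rows run right-to-left.
#'
#' @param layout An [experiment_layout()].
#' @param tile 1-based tile index.
#' @return Integer vector `c(row, col)` (1-based).
#' @export
tile_row_col <- function(layout, tile) {
  tile <- as.integer(tile)
  stopifnot(tile >= 1L, tile <= n_tiles(layout))
  row <- (tile - 1L) %/% layout$grid_cols + 1L
  col <- (tile - 1L) %% layout$grid_cols + 1L
  if (layout$serpentine && row %% 2L == 0L) col <- layout$grid_cols + 1L - col
  c(row = row, col = col)
}

#' Exposure time for a channel in a given cycle
#' @param layout An [experiment_layout()].
#' @param channel Channel index.
#' @param cycle Cycle index.
#' @return Exposure time in ms.
#' @export
exposure_for <- function(layout, channel, cycle) {
  e <- layout$channels[[channel]]$exposure_time
  if (length(e) == 1L) e else e[[cycle]]
}

# ---- file addressing ---------------------------------------------------

#' Canonical tile file path
#'
#' The canonical on-disk pattern is
#' `root/region_RRR/cycle_CCC/tile_TTT_z_ZZ_ch_K.tif`, a bijection between
#' addresses and paths for a given layout. Alternative acquisition naming
#' schemes can be supported by supplying a different `formatter` to the
#' readers.
#'
#' @param root Experiment root directory.
#' @param region,cycle,tile,z,channel 1-based address components.
#' @return File path (character).
#' @export
tile_path <- function(root, region, cycle, tile, z, channel) {
  file.path(root, sprintf("region_%03d", region), sprintf("cycle_%03d", cycle),
            sprintf("tile_%03d_z_%02d_ch_%d.tif", tile, z, channel))
}

#' Parse a canonical tile filename into its address
#' @param path Path or filename following the canonical pattern.
#' @return Named integer vector `(region, cycle, tile, z, channel)`, with
#'   `NA` for components absent from a bare filename.
#' @export
parse_tile_path <- function(path) {
  fn <- basename(path)
  m <- regmatches(fn, regexec("^tile_(\\d+)_z_(\\d+)_ch_(\\d+)\\.tif$", fn))[[1]]
  if (length(m) != 4L) stop("not a canonical tile filename: ", fn)
  dirs <- strsplit(dirname(path), "/", fixed = TRUE)[[1]]
  reg <- grep("^region_\\d+$", dirs, value = TRUE)
  cyc <- grep("^cycle_\\d+$", dirs, value = TRUE)
  c(region = if (length(reg)) as.integer(sub("region_", "", reg[length(reg)])) else NA_integer_,
    cycle = if (length(cyc)) as.integer(sub("cycle_", "", cyc[length(cyc)])) else NA_integer_,
    tile = as.integer(m[2]), z = as.integer(m[3]), channel = as.integer(m[4]))
}

# ---- configuration serialization --------------------------------------

layout_to_list <- function(layout, optics = NULL) {
  cfg <- list(
    n_regions = layout$n_regions,
    grid_rows = layout$grid_rows, grid_cols = layout$grid_cols,
    n_z = layout$n_z, n_cycles = layout$n_cycles,
    blank_cycles = as.integer(layout$blank_cycles),
    overlap_fraction = layout$overlap_fraction,
    tile_shape = as.integer(layout$tile_shape),
    reference_cycle = layout$reference_cycle,
    reference_channel = layout$reference_channel,
    serpentine = layout$serpentine,
    channels = lapply(layout$channels, function(ch)
      list(name = ch$name, emission_wavelength = ch$emission_wavelength,
           exposure_time = ch$exposure_time, is_nuclear = ch$is_nuclear)))
  if (!is.null(optics))
    cfg$optics <- list(numerical_aperture = optics$numerical_aperture,
                       pixel_size_xy = optics$pixel_size_xy,
                       z_step = optics$z_step, psf_size_xy = optics$psf_size_xy,
                       refractive_index = optics$refractive_index)
  cfg
}

list_to_layout <- function(cfg) {
  chans <- lapply(cfg$channels, function(ch)
    channel_spec(ch$name, ch$emission_wavelength,
                 unlist(ch$exposure_time), isTRUE(ch$is_nuclear)))
  experiment_layout(
    grid_rows = cfg$grid_rows, grid_cols = cfg$grid_cols, n_z = cfg$n_z,
    channels = chans, n_cycles = cfg$n_cycles,
    n_regions = if (is.null(cfg$n_regions)) 1L else cfg$n_regions,
    blank_cycles = unlist(cfg$blank_cycles),
    overlap_fraction = cfg$overlap_fraction,
    tile_shape = unlist(cfg$tile_shape),
    reference_cycle = if (is.null(cfg$reference_cycle)) 1L else cfg$reference_cycle,
    reference_channel = cfg$reference_channel,
    serpentine = isTRUE(cfg$serpentine))
}

list_to_optics <- function(cfg) {
  if (is.null(cfg$optics)) return(optical_config())
  o <- cfg$optics
  optical_config(o$numerical_aperture, o$pixel_size_xy, o$z_step,
                 o$psf_size_xy, o$refractive_index)
}

#' Write an experiment configuration file
#' @param layout An [experiment_layout()].
#' @param optics An [optical_config()] or `NULL`.
#' @param path Destination; `experiment.yaml` under the root by convention.
#' @return `path`, invisibly.
#' @export
write_experiment_config <- function(layout, optics, path) {
  yaml::write_yaml(layout_to_list(layout, optics), path)
  invisible(path)
}

#' Read an experiment configuration file
#' @param path Path to a YAML configuration.
#' @return List with elements `layout` and `optics`.
#' @export
read_experiment_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  list(layout = list_to_layout(cfg), optics = list_to_optics(cfg))
}

#' Discover the layout of an experiment directory
#'
#' Reads `experiment.yaml` at the root and reconciles it with the directory
#' tree. Cycles declared in the configuration but not yet present on disk
#' are dropped and the layout is flagged `partial`, so that any acquired
#' portion of an experiment can be processed while imaging continues. A
#' region count that contradicts the directory tree is an error.
#'
#' @param root Experiment root directory.
#' @return List with elements `layout` (possibly partial), `optics`, and
#'   `cycles_present` (integer vector of cycles available on disk).
#' @export
discover_layout <- function(root) {
  cfg_path <- file.path(root, "experiment.yaml")
  if (!file.exists(cfg_path))
    stop("unresolvable layout: no experiment.yaml under ", root)
  cfg <- read_experiment_config(cfg_path)
  layout <- cfg$layout
  regions <- sort(list.files(root, pattern = "^region_\\d+$"))
  if (length(regions) && length(regions) != layout$n_regions)
    stop(sprintf("unresolvable layout: config declares %d region(s), found %d",
                 layout$n_regions, length(regions)))
  cycles_present <- seq_len(layout$n_cycles)
  if (length(regions)) {
    per_region <- lapply(regions, function(r)
      as.integer(sub("cycle_", "",
                     list.files(file.path(root, r), pattern = "^cycle_\\d+$"))))
    cycles_present <- sort(Reduce(intersect, per_region))
    if (!length(cycles_present))
      stop("unresolvable layout: no complete cycle present in every region")
  }
  if (!setequal(cycles_present, seq_len(layout$n_cycles))) {
    layout$partial <- TRUE
    layout$blank_cycles <- intersect(layout$blank_cycles, cycles_present)
  }
  list(layout = layout, optics = cfg$optics, cycles_present = cycles_present)
}
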