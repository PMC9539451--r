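#' Read a single-plane 16-bit grayscale TIFF
#' @param path File path.
#' @return Integer matrix (rows = y, cols = x) on the native 0..65535 scale.
#' @export
read_plane <- function(path) {
  if (!file.exists(path)) stop("addressed file not found: ", path)
  img <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  storage.mode(img) <- "integer"
  img
}

#' Write a single-plane 16-bit grayscale TIFF
#'
#' Values are clipped to `[0, 65535]` and rounded; the round trip through
#' [read_plane()] is then bit-exact.
#'
#' @param img Numeric matrix.
#' @param path Destination path (directories are created as needed).
#' @return `path`, invisibly.
#' @export
write_plane <- function(img, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  img <- round(pmin(pmax(img, 0), 65535))
  tiff::writeTIFF(img / 65535, path, bits.per.sample = 16L,
                  compression = "none")
  invisible(path)
}

#' Read one tile's z-stack for a channel and cycle
#'
#' @param root Experiment root directory.
#' @param layout An [experiment_layout()].
#' @param region,cycle,tile,channel 1-based address components.
#' @return A `tile_stack`: numeric array `(y, x, z)` ordered by ascending z,
#'   native 16-bit values untouched, with the address attached.
#' @export
read_tile <- function(root, layout, region, cycle, tile, channel) {
  planes <- lapply(seq_len(layout$n_z), function(z) {
    p <- tile_path(root, region, cycle, tile, z, channel)
    read_plane(p)
  })
  shapes <- vapply(planes, dim, integer(2))
  if (any(shapes[1, ] != shapes[1, 1]) || any(shapes[2, ] != shapes[2, 1]))
    stop("layout mismatch: z planes of one stack differ in shape")
  if (any(shapes[, 1] != layout$tile_shape))
    stop(sprintf("layout mismatch: plane shape %dx%d, layout declares %dx%d",
                 shapes[1, 1], shapes[2, 1],
                 layout$tile_shape[1], layout$tile_shape[2]))
  data <- array(unlist(planes), dim = c(dim(planes[[1]]), layout$n_z))
  structure(data,
            address = c(region = region, cycle = cycle, tile = tile,
                        channel = channel),
            class = c("tile_stack", "array"))
}

#' Write one tile's z-stack as single-plane TIFF files
#' @param stack Numeric array `(y, x, z)`.
#' @param root,region,cycle,tile,channel Address; see [tile_path()].
#' @return Invisibly, the written file paths.
#' @export
write_tile <- function(stack, root, region, cycle, tile, channel) {
  nz <- dim(stack)[3]
  paths <- vapply(seq_len(nz), function(z) {
    write_plane(stack[, , z], tile_path(root, region, cycle, tile, z, channel))
  }, character(1))
  invisible(paths)
}

#' Construct a hyperstack
#'
#' A hyperstack is the aligned (y, x, channel, cycle) output of processing
#' one region: one mosaic plane per cycle-channel pair, all sharing one
#' registered pixel grid.
#'
#' @param planes List of numeric matrices, one per cycle-channel pair, all
#'   of identical shape.
#' @param cycle,channel Integer vectors parallel to `planes`.
#' @param channel_names Character vector parallel to `planes`.
#' @return An object of class `hyperstack`.
#' @export
hyperstack <- function(planes, cycle, channel, channel_names) {
  if (!length(planes)) stop("empty hyperstack: no planes")
  d <- dim(planes[[1]])
  if (!all(vapply(planes, function(p) identical(dim(p), d), logical(1))))
    stop("hyperstack planes must share one mosaic shape")
  stopifnot(length(cycle) == length(planes),
            length(channel) == length(planes),
            length(channel_names) == length(planes))
  structure(list(planes = planes, cycle = as.integer(cycle),
                 channel = as.integer(channel),
                 channel_names = as.character(channel_names)),
            class = "hyperstack")
}

#' @export
print.hyperstack <- function(x, ...) {
  d <- dim(x$planes[[1]])
  cat(sprintf("<hyperstack> %d plane(s) of %dx%d px (%d cycle(s) x %d channel(s))\n",
              length(x$planes), d[1], d[2],
              length(unique(x$cycle)), length(unique(x$channel))))
  invisible(x)
}

#' Write a hyperstack as a multi-page 16-bit TIFF
#'
#' Planes are clipped to `[0, 65535]` and stored as 16-bit pages in
#' cycle-major order. Axis metadata (cycle and channel of every page) is
#' written to a JSON sidecar at `<path>.json` so that [read_hyperstack()]
#' restores the object losslessly.
#'
#' @param hs A [hyperstack()].
#' @param path Destination `.tif` path.
#' @return `path`, invisibly.
#' @export
write_hyperstack <- function(hs, path) {
  stopifnot(inherits(hs, "hyperstack"))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  pages <- lapply(hs$planes, function(p) round(pmin(pmax(p, 0), 65535)) / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  meta <- list(cycle = hs$cycle, channel = hs$channel,
               channel_names = hs$channel_names,
               shape = dim(hs$planes[[1]]))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = FALSE)
  invisible(path)
}

#' Read a hyperstack written by [write_hyperstack()]
#' @param path Path to the multi-page TIFF.
#' @return A [hyperstack()].
#' @export
read_hyperstack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  pages <- lapply(pages, function(p) {
    storage.mode(p) <- "integer"; p
  })
  meta_path <- paste0(path, ".json")
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    hyperstack(pages, meta$cycle, meta$channel, meta$channel_names)
  } else {
    hyperstack(pages, rep(1L, length(pages)), seq_along(pages),
               paste0("page", seq_along(pages)))
  }
}
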