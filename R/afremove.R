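#' Autofluorescence-removal parameters
#'
#' @param min_object_px Minimum connected-component area; smaller bright
#'   objects are treated as noise (default 10 px).
#' @param mean_intensity_fraction Fraction of the 16-bit ceiling (65535) a
#'   retained object's mean intensity on the original blank image must
#'   reach (default 0.20, i.e. 13107).
#' @param otsu_levels Number of classes for multilevel Otsu thresholding of
#'   the enhanced blank image; the topmost class is "bright" (default 3:
#'   background / moderate / intense autofluorescence).
#' @param clahe_clip CLAHE clip limit.
#' @param clahe_tiles CLAHE tile grid `(ny, nx)`.
#' @param artifact_channel Channel used for detection; by default the
#'   Cy3-like channel of the first blank cycle, where erythrocyte
#'   autofluorescence is strongest.
#' @return An object of class `af_params`.
#' @export
af_params <- function(min_object_px = 10L, mean_intensity_fraction = 0.20,
                      otsu_levels = 3L, clahe_clip = 0.02,
                      clahe_tiles = c(8L, 8L), artifact_channel = NULL) {
  stopifnot(min_object_px >= 1, mean_intensity_fraction > 0,
            mean_intensity_fraction < 1 + 1e-9, otsu_levels >= 2)
  structure(list(min_object_px = as.integer(min_object_px),
                 mean_intensity_fraction = mean_intensity_fraction,
                 otsu_levels = as.integer(otsu_levels),
                 clahe_clip = clahe_clip,
                 clahe_tiles = as.integer(clahe_tiles),
                 artifact_channel = artifact_channel),
            class = "af_params")
}

#' Subtract aligned blank-cycle background from a marker image
#'
#' The blank image is scaled by the exposure-time ratio before
#' subtraction so that background acquired at a different exposure is
#' comparable; negative results clip to zero.
#'
#' @param marker,blank Numeric matrices of identical shape, blank
#'   registered to the marker's frame.
#' @param exposure_marker,exposure_blank Exposure times in ms (> 0).
#' @return Floating-point background-subtracted image.
#' @export
subtract_background <- function(marker, blank, exposure_marker = 1,
                                exposure_blank = 1) {
  if (exposure_marker <= 0 || exposure_blank <= 0)
    stop("exposure times must be > 0")
  stopifnot(identical(dim(marker), dim(blank)))
  pmax(marker - blank * (exposure_marker / exposure_blank), 0)
}

#' Normalize and enhance a blank image
#'
#' Min-max normalization to `[0, 1]` followed by contrast-limited adaptive
#' histogram equalization, preparing the blank autofluorescence image for
#' thresholding.
#'
#' @param blank Numeric matrix.
#' @param params An [af_params()].
#' @return Matrix in `[0, 1]`; a constant input returns zeros with a
#'   warning.
#' @export
enhance_blank <- function(blank, params = af_params()) {
  rng <- range(blank)
  if (rng[1] == rng[2]) {
    warning("constant blank image; returning zeros")
    return(matrix(0, nrow(blank), ncol(blank)))
  }
  norm <- (blank - rng[1]) / (rng[2] - rng[1])
  # the equalizer requires dimensions divisible by the tile grid:
  # reflect-pad to the next multiple and crop back afterwards
  nx <- params$clahe_tiles[2]; ny <- params$clahe_tiles[1]
  pr <- (ny - nrow(norm) %% ny) %% ny
  pc <- (nx - ncol(norm) %% nx) %% nx
  padded <- norm[c(seq_len(nrow(norm)), nrow(norm) + 1L - seq_len(pr)), ,
                 drop = FALSE]
  padded <- padded[, c(seq_len(ncol(norm)), ncol(norm) + 1L - seq_len(pc)),
                   drop = FALSE]
  # EBImage operates column-major (x, y); planes here are (y, x) matrices
  eq <- EBImage::clahe(t(padded), nx = nx, ny = ny,
                       limit = params$clahe_clip * 256)
  out <- t(as.matrix(eq))[seq_len(nrow(norm)), seq_len(ncol(norm))]
  pmin(pmax(out, 0), 1)
}

#' Multilevel Otsu thresholds
#'
#' Exhaustive search for the `levels - 1` thresholds of a 256-bin
#' histogram that maximize the between-class variance (Otsu's criterion
#' generalized to several classes).
#'
#' @param img Numeric matrix with values in `[0, 1]`.
#' @param levels Number of classes (2 or 3 supported).
#' @return Numeric vector of `levels - 1` ascending thresholds on the
#'   `[0, 1]` scale.
#' @export
multi_otsu <- function(img, levels = 3L) {
  nbins <- 256L
  h <- tabulate(pmin(pmax(floor(img * nbins) + 1L, 1L), nbins), nbins)
  p <- h / sum(h)
  mids <- (seq_len(nbins) - 0.5) / nbins
  cw <- cumsum(p); cm <- cumsum(p * mids)
  class_stat <- function(i, j) {
    # between-class contribution of bins (i, j]
    w <- cw[j] - if (i > 0) cw[i] else 0
    if (w <= 0) return(0)
    m <- cm[j] - if (i > 0) cm[i] else 0
    m^2 / w
  }
  if (levels == 2L) {
    best <- -Inf; t1 <- 1L
    for (i in 1:(nbins - 1L)) {
      s <- class_stat(0L, i) + class_stat(i, nbins)
      if (s > best) { best <- s; t1 <- i }
    }
    return(t1 / nbins)
  }
  if (levels != 3L) stop("otsu_levels of 2 or 3 are supported")
  best <- -Inf; th <- c(1L, 2L)
  for (i in 1:(nbins - 2L)) {
    si <- class_stat(0L, i)
    for (j in (i + 1L):(nbins - 1L)) {
      s <- si + class_stat(i, j) + class_stat(j, nbins)
      if (s > best) { best <- s; th <- c(i, j) }
    }
  }
  th / nbins
}

# 8-connected labeling: EBImage::bwlabel is 4-connected, so labels that
# touch diagonally are merged by union-find over the label adjacency.
label_components8 <- function(mask) {
  lab <- EBImage::bwlabel(t(mask))     # EBImage is (x, y)
  lab <- t(as.matrix(lab))
  n <- max(lab)
  if (n <= 1) return(lab)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  nr <- nrow(lab); nc <- ncol(lab)
  merge_pairs <- function(a, b) {
    sel <- a > 0 & b > 0 & a != b
    unique(cbind(a[sel], b[sel]))
  }
  d1 <- merge_pairs(lab[-nr, -nc], lab[-1, -1])     # down-right diagonal
  d2 <- merge_pairs(lab[-nr, -1], lab[-1, -nc])     # down-left diagonal
  for (pr in list(d1, d2)) {
    if (!nrow(pr)) next
    for (i in seq_len(nrow(pr))) {
      ra <- find(pr[i, 1]); rb <- find(pr[i, 2])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  relabel <- match(roots, sort(unique(roots)))
  out <- lab
  out[lab > 0] <- relabel[lab[lab > 0]]
  out
}

#' Detect high-intensity autofluorescent artifacts
#'
#' Implements the normalize -> enhance -> threshold -> filter -> rescue
#' chain on a blank-cycle image, in this exact order: (1) min-max
#' normalization + CLAHE ([enhance_blank()]); (2) multilevel Otsu
#' thresholding of the enhanced image, keeping the topmost (brightest)
#' class as a binary mask; (3) removal of connected components smaller
#' than `min_object_px` (8-connectivity); (4) removal of objects whose
#' mean intensity measured on the original, un-enhanced blank falls below
#' `mean_intensity_fraction * 65535`; (5) removal of objects overlapping
#' the nuclear-stain mask (single-level Otsu on the registered nuclear
#' plane), so autofluorescent nucleated cells are not lost.
#'
#' @param blank Numeric matrix: the artifact-detection channel of the
#'   first blank cycle, on the native 16-bit scale, aligned to the mosaic.
#' @param nuclear Numeric matrix: registered nuclear-stain plane of the
#'   same shape.
#' @param params An [af_params()].
#' @return An `artifact_mask`: list with `mask` (logical matrix), `labels`
#'   (integer matrix), and `objects` (data frame: label, area,
#'   mean_intensity, dropped stage bookkeeping of retained objects).
#' @export
detect_artifacts <- function(blank, nuclear, params = af_params()) {
  stopifnot(identical(dim(blank), dim(nuclear)))
  enhanced <- enhance_blank(blank, params)
  th <- multi_otsu(enhanced, params$otsu_levels)
  bright <- enhanced > th[length(th)]
  labels <- label_components8(bright)
  keep <- integer(0)
  objects <- list()
  if (max(labels) > 0) {
    areas <- tabulate(labels[labels > 0], max(labels))
    nuc_mask <- if (max(nuclear) > min(nuclear))
      nuclear > EBImage::otsu(t(nuclear) / 65535, range = c(0, 1)) * 65535
    else matrix(FALSE, nrow(nuclear), ncol(nuclear))
    for (l in seq_len(max(labels))) {
      if (areas[l] == 0) next
      sel <- labels == l
      if (areas[l] < params$min_object_px) next        # (3) small objects
      mi <- mean(blank[sel])
      if (mi < params$mean_intensity_fraction * 65535) next  # (4) dim
      if (any(nuc_mask[sel])) next                     # (5) nuclear rescue
      keep <- c(keep, l)
      objects[[length(objects) + 1L]] <- data.frame(
        label = l, area = areas[l], mean_intensity = mi)
    }
  }
  mask <- labels %in% keep
  dim(mask) <- dim(labels)
  out_labels <- labels
  out_labels[!mask] <- 0L
  out_labels[mask] <- match(out_labels[mask], keep)
  structure(list(mask = mask, labels = out_labels,
                 objects = if (length(objects)) do.call(rbind, objects)
                 else data.frame(label = integer(), area = integer(),
                                 mean_intensity = numeric()),
                 params = params),
            class = "artifact_mask")
}

#' @export
print.artifact_mask <- function(x, ...) {
  cat(sprintf("<artifact_mask> %d object(s), %d px masked of %d\n",
              nrow(x$objects), sum(x$mask), length(x$mask)))
  invisible(x)
}

#' Zero masked artifact pixels in every plane
#'
#' Sets every pixel of the artifact mask to exactly zero in each supplied
#' (background-subtracted) cycle-channel plane; unmasked pixels are
#' untouched. Idempotent.
#'
#' @param planes List of numeric matrices matching the mask shape (or a
#'   single matrix).
#' @param mask An `artifact_mask` from [detect_artifacts()] (or a logical
#'   matrix).
#' @return The planes with masked pixels zeroed (same structure as input).
#' @export
remove_artifacts <- function(planes, mask) {
  m <- if (inherits(mask, "artifact_mask")) mask$mask else mask
  one <- function(p) {
    if (!identical(dim(p), dim(m))) stop("plane and mask shapes differ")
    p[m] <- 0
    p
  }
  if (is.matrix(planes)) one(planes) else lapply(planes, one)
}

#' Erythrocyte QC mask by H&E color deconvolution
#'
#' Optional quality-control utility: separates an RGB H&E image into
#' hematoxylin and eosin stain densities via the Beer-Lambert optical
#' density transform and the pseudo-inverse of the standard H&E stain
#' matrix, then thresholds eosin-dominant dense regions (erythrocytes
#' appear as bright eosin-pink patches) for visual comparison with
#' [detect_artifacts()] output.
#'
#' @param rgb_he Numeric array `(y, x, 3)` with values in `[0, 1]` or
#'   `[0, 255]`.
#' @param eosin_threshold Eosin optical density threshold (default 0.25).
#' @return Logical matrix marking erythrocyte-like regions.
#' @export
colordeconv_rbc_qc <- function(rgb_he, eosin_threshold = 0.25) {
  if (length(dim(rgb_he)) != 3L || dim(rgb_he)[3] != 3L)
    stop("rgb_he must be a (y, x, 3) array")
  if (max(rgb_he) > 1) rgb_he <- rgb_he / 255
  # standard H&E stain vectors (unit RGB absorbance directions)
  stains <- rbind(hematoxylin = c(0.650, 0.704, 0.286),
                  eosin = c(0.072, 0.990, 0.105))
  stains <- stains / sqrt(rowSums(stains^2))
  od <- -log10(pmax(rgb_he, 1 / 256))         # optical density per channel
  odm <- matrix(od, ncol = 3L)
  dens <- odm %*% MASS::ginv(stains)          # per-pixel stain densities
  eos <- matrix(dens[, 2], dim(rgb_he)[1], dim(rgb_he)[2])
  hem <- matrix(dens[, 1], dim(rgb_he)[1], dim(rgb_he)[2])
  eos > eosin_threshold & eos > hem
}
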