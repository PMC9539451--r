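# Born-Wolf widefield point-spread function.
#
# The Born-Wolf model describes the 3-D diffraction pattern of an aberration-
# free widefield microscope focused into a medium of refractive index n_i.
# The amplitude at lateral radius r and defocus z is the pupil integral
#
#   U(r, z) = int_0^1 J0(k NA r rho) exp(-i k z NA^2 rho^2 / (2 n_i)) rho drho
#
# with k = 2 pi / lambda, and the intensity PSF is |U|^2. The integral is
# evaluated per voxel by composite Simpson quadrature over rho; lateral
# radial symmetry is exploited by computing a fine radial profile per z
# plane and interpolating onto the pixel grid.

born_wolf_profile <- function(radii, z, wavelength, na, n_i, n_rho = 257L) {
  k <- 2 * pi / wavelength
  rho <- seq(0, 1, length.out = n_rho)
  # Simpson weights (n_rho odd)
  w <- rep(c(4, 2), length.out = n_rho - 2L)
  w <- c(1, w, 1) * (rho[2] - rho[1]) / 3
  defocus <- exp(-1i * k * z * na^2 * rho^2 / (2 * n_i)) * rho * w
  vapply(radii, function(r) {
    u <- sum(besselJ(k * na * r * rho, 0) * defocus)
    Re(u * Conj(u))
  }, numeric(1))
}

# 1-based index of the focal (z = 0) plane of an n_z-plane stack.
focal_plane_index <- function(n_z) as.integer((n_z - 1L) %/% 2L + 1L)

#' Synthesize a Born-Wolf point-spread function
#'
#' Numerically integrates the Born-Wolf pupil integral per voxel to produce
#' the widefield PSF sampled at the acquisition's lateral pixel size and
#' axial z-step. The volume is `psf_size_xy x psf_size_xy x n_z`, normalized
#' to unit sum, with the focal plane at z index `(n_z - 1) %/% 2 + 1` and
#' the lateral maximum at the central pixel.
#'
#' @param wavelength Emission wavelength in nanometres.
#' @param optics An [optical_config()].
#' @param n_z Number of z planes.
#' @param oversample Integer lateral oversampling factor for the radial
#'   quadrature grid (used by validation oracles; 1 evaluates exactly at
#'   pixel radii).
#' @return A `psf_model`: numeric array `(y, x, z)` of unit sum with
#'   attributes `wavelength` and `optics`.
#' @export
generate_psf <- function(wavelength, optics, n_z, oversample = 1L) {
  stopifnot(wavelength > 0, n_z >= 1)
  p <- optics$psf_size_xy
  if (p %% 2L == 0L) stop("psf_size_xy must be odd")
  c0 <- (p + 1L) %/% 2L
  xy <- seq_len(p) - c0
  r_px <- sqrt(outer(xy^2, xy^2, "+"))          # radius in pixels
  zc <- focal_plane_index(n_z)
  z_off <- (seq_len(n_z) - zc) * optics$z_step  # nm
  r_max <- max(r_px) * optics$pixel_size_xy
  # fine radial grid; linear interpolation onto pixel radii
  n_r <- max(256L, oversample * 4L * c0)
  r_grid <- seq(0, r_max, length.out = n_r)
  psf <- array(0, dim = c(p, p, n_z))
  for (iz in seq_len(n_z)) {
    prof <- born_wolf_profile(r_grid, z_off[iz], wavelength,
                              optics$numerical_aperture,
                              optics$refractive_index)
    psf[, , iz] <- matrix(stats::approx(r_grid, prof,
                                        xout = r_px * optics$pixel_size_xy,
                                        rule = 2)$y, p, p)
  }
  psf <- psf / sum(psf)
  structure(psf, wavelength = wavelength, optics = optics,
            focal_plane = zc, class = c("psf_model", "array"))
}

#' Full width at half maximum of a 1-D profile
#'
#' Locates the maximum and the two half-maximum crossings by linear
#' interpolation between samples; `spacing` converts the result to physical
#' units.
#'
#' @param profile Numeric vector.
#' @param spacing Sample spacing (default 1, i.e. pixels).
#' @return FWHM in units of `spacing`, or `NA` if no crossing exists.
#' @export
measure_fwhm <- function(profile, spacing = 1) {
  profile <- as.numeric(profile)
  i0 <- which.max(profile)
  half <- profile[i0] / 2
  left <- NA_real_
  for (i in seq.int(i0, 2L)) {
    if (profile[i - 1L] < half) {
      left <- (i - 1L) + (half - profile[i - 1L]) / (profile[i] - profile[i - 1L])
      break
    }
  }
  right <- NA_real_
  n <- length(profile)
  if (i0 < n) for (i in seq.int(i0, n - 1L)) {
    if (profile[i + 1L] < half) {
      right <- i + (profile[i] - half) / (profile[i] - profile[i + 1L])
      break
    }
  }
  (right - left) * spacing
}

#' Lateral FWHM of a 3-D stack at its brightest plane
#'
#' Extracts the row and column profiles through the global intensity
#' maximum and returns the mean of their FWHMs.
#'
#' @param stack Numeric array `(y, x, z)`.
#' @param spacing Lateral pixel size.
#' @return FWHM in units of `spacing`.
#' @export
lateral_fwhm <- function(stack, spacing = 1) {
  d <- dim(stack)
  i <- arrayInd(which.max(stack), d)
  mean(c(measure_fwhm(stack[, i[2], i[3]], spacing),
         measure_fwhm(stack[i[1], , i[3]], spacing)), na.rm = TRUE)
}

#' Export a PSF volume as a multi-page TIFF
#'
#' The volume is stored as 32-bit float pages so externally generated PSFs
#' can be exchanged losslessly.
#'
#' @param psf A `psf_model` or plain numeric array `(y, x, z)`.
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_psf <- function(psf, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  pages <- lapply(seq_len(dim(psf)[3]), function(z) psf[, , z])
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none",
                  reduce = FALSE)
  invisible(path)
}

#' Import a PSF volume from a multi-page TIFF
#' @param path Path written by [write_psf()] or an external generator.
#' @param optics,wavelength Optional metadata to attach.
#' @return A `psf_model` normalized to unit sum.
#' @export
read_psf <- function(path, optics = NULL, wavelength = NA_real_) {
  pages <- tiff::readTIFF(path, all = TRUE)
  psf <- array(unlist(pages), dim = c(dim(pages[[1]]), length(pages)))
  psf <- psf / sum(psf)
  structure(psf, wavelength = wavelength, optics = optics,
            focal_plane = focal_plane_index(dim(psf)[3]),
            class = c("psf_model", "array"))
}
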