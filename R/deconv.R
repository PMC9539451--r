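#' Wiener-Butterworth back-projector parameters
#'
#' @param alpha Wiener regularization; a small positive value that keeps the
#'   inversion of the forward projector away from division by zero.
#' @param beta Spectral amplitude of the Butterworth factor at the cutoff
#'   frequency (the optical resolution limit), in (0, 1).
#' @param n Butterworth filter order setting the transition slope at the
#'   cutoff.
#' @return An object of class `back_projector_params`.
#' @export
back_projector_params <- function(alpha = 0.05, beta = 0.1, n = 20L) {
  stopifnot(alpha > 0, beta > 0, beta < 1, n >= 1)
  structure(list(alpha = alpha, beta = beta, n = as.integer(n)),
            class = "back_projector_params")
}

#' Deconvolution parameters
#'
#' @param iterations Richardson-Lucy iteration count (the unmatched
#'   back projector is designed to converge in a single iteration).
#' @param pad_mode Boundary handling: `"reflect"` pads by the PSF half-width
#'   before the FFT and crops after; `"periodic"` uses circular convolution
#'   on the raw extent.
#' @param backend `"cpu"` (the only compute backend provided; the flag is
#'   kept so configurations remain portable across implementations).
#' @return An object of class `deconv_params`.
#' @export
deconv_params <- function(iterations = 1L, pad_mode = c("reflect", "periodic"),
                          backend = c("cpu", "gpu")) {
  stopifnot(iterations >= 1)
  backend <- match.arg(backend)
  if (backend == "gpu") {
    message("gpu backend not available; using cpu")
    backend <- "cpu"
  }
  structure(list(iterations = as.integer(iterations),
                 pad_mode = match.arg(pad_mode), backend = backend),
            class = "deconv_params")
}

# Butterworth amplitude at normalized radial frequency rho (rho = 1 at the
# cutoff), parameterized so that the amplitude equals beta at rho = 1 and 1
# at rho = 0: B(rho) = 1 / sqrt(1 + eps^2 rho^(2n)), eps^2 = 1/beta^2 - 1.
butterworth_amplitude <- function(rho, beta, n) {
  eps2 <- 1 / beta^2 - 1
  1 / sqrt(1 + eps2 * rho^(2 * n))
}

#' Build the Wiener-Butterworth unmatched back projector
#'
#' The back projector replaces the flipped PSF in the Richardson-Lucy
#' update. Its transfer function is the product `W(k) * B(k)` of the Wiener
#' inverse of the PSF's optical transfer function,
#' `W = conj(H) / (|H|^2 + alpha)`, and an n-th order Butterworth low-pass
#' whose cutoff is the optical resolution limit (laterally `2 NA / lambda`,
#' axially `NA^2 / (2 n_i lambda)`) and whose amplitude at the cutoff is
#' `beta`. By construction the combined amplitude at the cutoff equals
#' `beta` times the Wiener amplitude there.
#'
#' @param psf A `psf_model` from [generate_psf()] (carries the optics).
#' @param params A [back_projector_params()].
#' @param target_shape Integer shape `(ny, nx, nz)` of the (padded) stack
#'   the projector will be applied to; must not be smaller than the PSF.
#' @return A `back_projector`: list with the complex `transfer` array, the
#'   `params`, and the per-axis `cutoff` frequencies (cycles/nm).
#' @export
build_back_projector <- function(psf, params = back_projector_params(),
                                 target_shape) {
  target_shape <- as.integer(target_shape)
  if (any(dim(psf) > target_shape))
    stop("psf larger than target shape in at least one axis")
  optics <- attr(psf, "optics")
  wavelength <- attr(psf, "wavelength")
  if (is.null(optics) || !is.numeric(wavelength) || is.na(wavelength))
    stop("psf must carry optics and wavelength metadata")
  otf <- psf_otf(unclass(psf), target_shape,
                 center = c((dim(psf)[1] + 1L) %/% 2L,
                            (dim(psf)[2] + 1L) %/% 2L,
                            attr(psf, "focal_plane")))
  wiener <- Conj(otf) / (Mod(otf)^2 + params$alpha)
  kc_xy <- 2 * optics$numerical_aperture / wavelength
  kc_z <- optics$numerical_aperture^2 /
    (2 * optics$refractive_index * wavelength)
  ky <- fft_freqs(target_shape[1], optics$pixel_size_xy)
  kx <- fft_freqs(target_shape[2], optics$pixel_size_xy)
  kz <- fft_freqs(target_shape[3], optics$z_step)
  rho2 <- outer(outer((ky / kc_xy)^2, (kx / kc_xy)^2, "+"), (kz / kc_z)^2, "+")
  bw <- butterworth_amplitude(sqrt(rho2), params$beta, params$n)
  structure(list(transfer = wiener * bw, params = params,
                 cutoff = c(y = kc_xy, x = kc_xy, z = kc_z),
                 shape = target_shape),
            class = "back_projector")
}

#' Richardson-Lucy deconvolution with an unmatched back projector
#'
#' Runs the multiplicative Richardson-Lucy update
#' `e_{k+1} = e_k * BP (x) ( raw / (PSF (x) e_k) )` with the Wiener-
#' Butterworth back projector `BP` in place of the flipped PSF, starting
#' from `e_0 = raw`. With the default single iteration this matches the
#' accelerated scheme used for cyclic multiplexed data. No intensity
#' rescaling is applied; the output stays on the input scale as
#' floating-point values, clipped to be non-negative.
#'
#' @param stack Numeric array `(y, x, z)` (a [read_tile()] stack).
#' @param psf A `psf_model` sharing the stack's optics.
#' @param bp Optional [build_back_projector()] result matching the padded
#'   stack shape; built on the fly when `NULL`.
#' @param params A [deconv_params()].
#' @param bp_params A [back_projector_params()] used when `bp` is `NULL`.
#' @return Deconvolved numeric array of the stack's shape (attributes
#'   preserved).
#' @export
deconvolve <- function(stack, psf, bp = NULL, params = deconv_params(),
                       bp_params = back_projector_params()) {
  x <- unclass(stack)
  d <- dim(x)
  if (max(x) <= 0) {
    warning("all-zero stack; returned unchanged")
    return(stack)
  }
  if (params$pad_mode == "reflect") {
    pads <- pmin((dim(psf) - 1L) %/% 2L, d - 1L)
  } else {
    pads <- c(0L, 0L, 0L)
  }
  xp <- if (any(pads > 0L)) pad_reflect3(x, pads) else x
  shape <- dim(xp)
  if (is.null(bp) || !identical(as.integer(bp$shape), as.integer(shape)))
    bp <- build_back_projector(psf, bp_params, shape)
  otf <- psf_otf(unclass(psf), shape,
                 center = c((dim(psf)[1] + 1L) %/% 2L,
                            (dim(psf)[2] + 1L) %/% 2L,
                            attr(psf, "focal_plane")))
  eps <- 1e-6 * max(xp)
  est <- xp
  for (it in seq_len(params$iterations)) {
    blurred <- fft_convolve(est, otf)
    ratio <- xp / pmax(blurred, eps)
    est <- est * fft_convolve(ratio, bp$transfer)
  }
  est <- pmax(est, 0)
  out <- if (any(pads > 0L)) crop3(est, pads, d) else est
  attributes(out) <- attributes(stack)
  dim(out) <- d
  out
}
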