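# Back projector and accelerated Richardson-Lucy deconvolution.

bp_fixture <- function() {
  cached("bp_fixture", {
    optics <- small_optics(31L)
    psf <- generate_psf(525, optics, n_z = 5)
    shape <- c(64L, 64L, 8L)
    list(optics = optics, psf = psf, shape = shape,
         bp = build_back_projector(psf, back_projector_params(), shape))
  })
}

test_that("back projector transfer is the Wiener inverse times a Butterworth", {
  f <- bp_fixture()
  params <- back_projector_params()    # alpha 0.05, beta 0.1, n 20
  otf <- codexpp:::psf_otf(unclass(f$psf), f$shape,
                           center = c(16L, 16L, 3L))
  wiener <- Conj(otf) / (Mod(otf)^2 + params$alpha)
  ratio <- f$bp$transfer / wiener
  expect_lt(max(abs(Im(ratio))), 1e-9)        # Butterworth factor is real
  b <- Re(ratio)
  expect_true(all(b > 0 & b <= 1 + 1e-12))
  expect_true(all(is.finite(Mod(f$bp$transfer))))
  # amplitude at the lateral cutoff equals beta times the Wiener amplitude:
  # the Butterworth factor at normalized radius 1 is beta by construction
  ky <- codexpp:::fft_freqs(f$shape[1], f$optics$pixel_size_xy)
  kz <- codexpp:::fft_freqs(f$shape[3], f$optics$z_step)
  rho <- sqrt(outer(outer((ky / f$bp$cutoff["y"])^2,
                          (ky / f$bp$cutoff["x"])^2, "+"),
                    (kz / f$bp$cutoff["z"])^2, "+"))
  eps2 <- 1 / params$beta^2 - 1
  expect_equal(b, 1 / sqrt(1 + eps2 * rho^(2 * params$n)),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("Butterworth attenuation beyond cutoff matches the closed form", {
  params <- back_projector_params(beta = 0.1, n = 20)
  b <- codexpp:::butterworth_amplitude
  expect_equal(b(1, 0.1, 20), 0.1, tolerance = 1e-12)
  eps2 <- 1 / 0.1^2 - 1
  # attenuation ratio from 1x to 2x cutoff, against direct evaluation
  expect_equal(b(2, 0.1, 20) / b(1, 0.1, 20),
               sqrt((1 + eps2) / (1 + eps2 * 2^40)), tolerance = 1e-12)
  expect_equal(b(0, 0.1, 20), 1)
})

test_that("large alpha drives the transfer amplitude to zero", {
  f <- bp_fixture()
  bp_hi <- build_back_projector(f$psf,
                                back_projector_params(alpha = 1e8),
                                f$shape)
  expect_lt(max(Mod(bp_hi$transfer)), 1e-6)
})

test_that("a PSF larger than the target shape is rejected", {
  f <- bp_fixture()
  expect_error(build_back_projector(f$psf, back_projector_params(),
                                    c(16L, 16L, 3L)), "larger")
})

test_that("delta PSF with identity back projector is a fixed point", {
  optics <- small_optics(3L)
  delta <- array(0, c(3, 3, 3)); delta[2, 2, 2] <- 1
  psf <- structure(delta, wavelength = 525, optics = optics,
                   focal_plane = 2L, class = c("psf_model", "array"))
  set.seed(5)
  stack <- array(runif(16 * 16 * 3, 100, 1000), c(16, 16, 3))
  bp <- list(transfer = array(1 + 0i, c(16, 16, 3)),
             params = back_projector_params(), shape = c(16L, 16L, 3L))
  out <- deconvolve(stack, psf, bp = bp,
                    params = deconv_params(pad_mode = "periodic"))
  expect_equal(out, stack, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("one unmatched-projector iteration sharpens a blurred point source", {
  optics <- small_optics(31L)
  psf <- generate_psf(525, optics, n_z = 5)
  stack <- array(0, c(64, 64, 5)); stack[33, 33, 3] <- 1e4
  otf <- codexpp:::psf_otf(unclass(psf), c(64L, 64L, 5L),
                           center = c(16L, 16L, 3L))
  blurred <- pmax(codexpp:::fft_convolve(stack, otf), 0)
  dec <- deconvolve(blurred, psf,
                    params = deconv_params(pad_mode = "periodic"))
  expect_true(all(dec >= 0))
  expect_lt(lateral_fwhm(dec), lateral_fwhm(blurred))
  # classical 25-iteration Richardson-Lucy oracle: FWHM within 20%
  rl <- classical_rl(blurred, unclass(psf), center = c(16L, 16L, 3L),
                     iterations = 25L)
  expect_lt(abs(lateral_fwhm(dec) - lateral_fwhm(rl)) / lateral_fwhm(rl),
            0.20)
})

test_that("deconvolution is shift-equivariant under periodic boundaries", {
  optics <- small_optics(15L)
  psf <- generate_psf(595, optics, n_z = 3)
  set.seed(6)
  base <- array(0, c(32, 32, 3))
  for (i in 1:6)
    base[sample(8:24, 1), sample(8:24, 1), sample(1:3, 1)] <- runif(1, 5e3, 2e4)
  otf <- codexpp:::psf_otf(unclass(psf), c(32L, 32L, 3L),
                           center = c(8L, 8L, 2L))
  blurred <- pmax(codexpp:::fft_convolve(base, otf), 0)
  p <- deconv_params(pad_mode = "periodic")
  d1 <- deconvolve(blurred, psf, params = p)
  shifted <- codexpp:::circshift3(blurred, c(5L, -3L, 1L))
  d2 <- deconvolve(shifted, psf, params = p)
  expect_lt(max(abs(codexpp:::circshift3(d1, c(5L, -3L, 1L)) - d2)) /
              max(d1), 1e-6)
})

test_that("an all-zero stack is returned unchanged with a warning", {
  optics <- small_optics(15L)
  psf <- generate_psf(525, optics, n_z = 3)
  z <- array(0, c(16, 16, 3))
  expect_warning(out <- deconvolve(z, psf), "all-zero")
  expect_equal(out, z, ignore_attr = TRUE)
})

test_that("gpu backend requests fall back to the cpu implementation", {
  expect_message(p <- deconv_params(backend = "gpu"), "cpu")
  expect_equal(p$backend, "cpu")
})
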