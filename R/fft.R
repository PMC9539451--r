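# Internal n-dimensional FFT helpers built on stats::fft, which operates on
# every dimension of an array. All conventions: unnormalized forward
# transform, 1/N inverse.

fftn <- function(x) stats::fft(x)

ifftn <- function(x) stats::fft(x, inverse = TRUE) / length(x)

# Frequency coordinate of each FFT bin along an axis of length n, in cycles
# per sample-spacing unit d (the fftfreq convention: 0, 1/(nd), ...,
# -1/(nd)).
fft_freqs <- function(n, d = 1) {
  k <- c(seq.int(0L, floor((n - 1) / 2)), seq.int(-floor(n / 2), -1L))
  k / (n * d)
}

# Reflect-pad a 3-D array by pads = c(py, px, pz) on each side. Reflection
# excludes the edge sample (mirror about the boundary pixel).
pad_reflect3 <- function(x, pads) {
  d <- dim(x)
  idx <- lapply(1:3, function(i) {
    n <- d[i]; p <- pads[i]
    if (p == 0L) return(seq_len(n))
    if (n == 1L) return(rep(1L, n + 2L * p))
    ref <- function(j) {
      # reflect j into [1, n] with period 2(n-1), edge not duplicated
      j <- (j - 1L) %% (2L * (n - 1L))
      ifelse(j >= n, 2L * (n - 1L) - j, j) + 1L
    }
    ref(seq.int(1L - p, n + p))
  })
  x[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
}

crop3 <- function(x, pads, out_dim) {
  x[pads[1] + seq_len(out_dim[1]),
    pads[2] + seq_len(out_dim[2]),
    pads[3] + seq_len(out_dim[3]), drop = FALSE]
}

# Circularly shift a 3-D array by integer amounts s (can be negative).
circshift3 <- function(x, s) {
  d <- dim(x)
  idx <- lapply(1:3, function(i) {
    if (d[i] == 1L) return(1L)
    ((seq_len(d[i]) - 1L - s[i]) %% d[i]) + 1L
  })
  x[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
}

# Embed a centered kernel into an array of shape `shape` with the kernel
# center moved to the [1,1,1] origin (the ifftshift needed so that FFT
# convolution does not translate the image). `center` is the 1-based index
# of the kernel center in each axis.
kernel_to_origin <- function(kernel, shape, center = NULL) {
  kd <- dim(kernel)
  if (any(kd > shape)) stop("kernel larger than target shape")
  if (is.null(center)) center <- (kd - 1L) %/% 2L + 1L
  big <- array(0, dim = shape)
  big[seq_len(kd[1]), seq_len(kd[2]), seq_len(kd[3])] <- kernel
  circshift3(big, -(center - 1L))
}

# Optical transfer function of a centered PSF kernel at a target shape.
psf_otf <- function(psf, shape, center = NULL) {
  fftn(kernel_to_origin(psf, shape, center))
}

# Convolve (circularly) a real array with a frequency-domain transfer
# function of identical shape.
fft_convolve <- function(x, transfer) {
  Re(ifftn(fftn(x) * transfer))
}
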