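#' Construct a drift transform
#'
#' A similarity transform describing the drift of a moving image relative
#' to a reference: translation `(dy, dx)` in pixels (sub-pixel reals),
#' `rotation` in degrees (counter-clockwise about the image center) and
#' isotropic `scale`. `peak_quality` records the normalized phase-
#' correlation peak height in `[0, 1]`.
#'
#' @param dy,dx Translation in pixels.
#' @param rotation Rotation in degrees; `|rotation| < 90`.
#' @param scale Isotropic scale factor; `> 0`.
#' @param peak_quality Normalized correlation peak height.
#' @return An object of class `drift_transform`.
#' @export
drift_transform <- function(dy = 0, dx = 0, rotation = 0, scale = 1,
                            peak_quality = NA_real_) {
  stopifnot(scale > 0, abs(rotation) < 90, is.finite(dy), is.finite(dx))
  structure(list(dy = dy, dx = dx, rotation = rotation, scale = scale,
                 peak_quality = peak_quality),
            class = "drift_transform")
}

#' @export
print.drift_transform <- function(x, ...) {
  cat(sprintf("<drift_transform> dy=%.3f dx=%.3f rot=%.3f deg scale=%.4f (peak %.3f)\n",
              x$dy, x$dx, x$rotation, x$scale, x$peak_quality))
  invisible(x)
}

is_identity_transform <- function(tf, tol = 1e-12) {
  abs(tf$dy) < tol && abs(tf$dx) < tol && abs(tf$rotation) < tol &&
    abs(tf$scale - 1) < tol
}

hann2 <- function(nr, nc) {
  wy <- 0.5 - 0.5 * cos(2 * pi * (seq_len(nr) - 1) / (nr - 1))
  wx <- 0.5 - 0.5 * cos(2 * pi * (seq_len(nc) - 1) / (nc - 1))
  outer(wy, wx)
}

# Upsampled portion of the inverse DFT of `data` (matrix-multiply DFT):
# evaluates the cross-correlation surface on a grid of (nor x noc) samples
# with spacing 1/usfac px starting at (roff, coff) (in upsampled units).
dftups <- function(data, nor, noc, usfac, roff, coff) {
  nr <- nrow(data); nc <- ncol(data)
  kr <- c(seq.int(0L, floor((nr - 1) / 2)), seq.int(-floor(nr / 2), -1L))
  kc <- c(seq.int(0L, floor((nc - 1) / 2)), seq.int(-floor(nc / 2), -1L))
  wr <- exp(2i * pi / (nr * usfac) * outer((seq_len(nor) - 1) + roff, kr))
  wc <- exp(2i * pi / (nc * usfac) * outer(kc, (seq_len(noc) - 1) + coff))
  wr %*% data %*% wc
}

# Core translation estimator on the cross-power spectrum. Returns the shift
# (dy, dx) such that moving ~= reference circularly shifted by (dy, dx),
# plus the normalized correlation peak height.
phase_correlate <- function(reference, moving, upsample = 1L,
                            window = FALSE, reg = 0) {
  stopifnot(identical(dim(reference), dim(moving)))
  if (max(reference) == min(reference) || max(moving) == min(moving))
    stop("no signal: constant image")
  a <- reference - mean(reference)
  b <- moving - mean(moving)
  if (window) {
    w <- hann2(nrow(a), ncol(a))
    a <- a * w; b <- b * w
  }
  fa <- stats::fft(a); fb <- stats::fft(b)
  cross <- Conj(fa) * fb
  # reg > 0 floors the whitening magnitude, damping the noise that full
  # normalization amplifies on resampled or weakly textured inputs
  m <- Mod(cross)
  cross <- cross / pmax(m + reg * mean(m), .Machine$double.eps)
  surf <- Re(stats::fft(cross, inverse = TRUE)) / length(cross)
  peak <- which.max(surf)
  idx <- arrayInd(peak, dim(surf)) - 1L
  nr <- nrow(surf); nc <- ncol(surf)
  dy <- if (idx[1] > nr / 2) idx[1] - nr else idx[1]
  dx <- if (idx[2] > nc / 2) idx[2] - nc else idx[2]
  quality <- surf[peak]
  if (upsample > 1L) {
    # refine in a 1.5 px neighborhood of the integer peak
    us <- ceiling(upsample * 1.5)
    dftshift <- floor(us / 2)
    roff <- dftshift - dy * upsample
    coff <- dftshift - dx * upsample
    cc <- Mod(dftups(cross, us, us, upsample, -roff, -coff))
    p2 <- arrayInd(which.max(cc), dim(cc)) - 1L
    dy <- dy + (p2[1] - dftshift) / upsample
    dx <- dx + (p2[2] - dftshift) / upsample
  }
  list(dy = dy, dx = dx, peak_quality = max(min(quality, 1), 0))
}

#' Estimate between-cycle translation by phase correlation
#'
#' Locates the peak of the normalized cross-power spectrum of the two
#' images, optionally refined to `1/upsample` pixel by local matrix-
#' multiply DFT upsampling around the integer peak.
#'
#' @param reference,moving Numeric matrices of identical shape with
#'   non-constant content.
#' @param upsample Sub-pixel refinement factor (1 = integer-pixel).
#' @param window Apply a Hann window before the FFT to suppress edge
#'   spectral leakage (recommended for non-periodic tissue images).
#' @param reg Whitening regularization in `[0, 1]`; 0 is the classical
#'   fully normalized cross-power spectrum.
#' @return A [drift_transform()] with `rotation = 0`, `scale = 1`; `(dy,
#'   dx)` is the shift taking the reference onto the moving image.
#' @export
estimate_translation <- function(reference, moving, upsample = 20L,
                                 window = FALSE, reg = 0) {
  pc <- phase_correlate(reference, moving, upsample = upsample,
                        window = window, reg = reg)
  drift_transform(pc$dy, pc$dx, 0, 1, pc$peak_quality)
}

# Log-polar resampling of a (fftshifted) spectrum magnitude, used to turn
# rotation and scale into translations.
log_polar <- function(img, n_theta = 720L, n_r = NULL) {
  nr <- nrow(img); nc <- ncol(img)
  cy <- (nr + 1) / 2; cx <- (nc + 1) / 2
  r_max <- min(nr, nc) / 2 - 1
  if (is.null(n_r)) n_r <- 360L
  r_min <- 1
  theta <- (seq_len(n_theta) - 1) * pi / n_theta   # [0, pi)
  logr <- seq(log(r_min), log(r_max), length.out = n_r)
  r <- exp(logr)
  yy <- cy + outer(r, sin(theta))
  xx <- cx + outer(r, cos(theta))
  list(data = bilinear_sample(img, yy, xx),
       theta_step = 180 / n_theta,
       logr_step = (log(r_max) - log(r_min)) / (n_r - 1))
}

bilinear_sample <- function(img, yy, xx) {
  nr <- nrow(img); nc <- ncol(img)
  ok <- yy >= 1 & yy <= nr & xx >= 1 & xx <= nc
  yyc <- pmin(pmax(yy, 1), nr); xxc <- pmin(pmax(xx, 1), nc)
  y0 <- pmin(floor(yyc), nr - 1); x0 <- pmin(floor(xxc), nc - 1)
  fy <- as.vector(yyc - y0); fx <- as.vector(xxc - x0)
  i00 <- cbind(as.vector(y0), as.vector(x0))
  v <- (1 - fy) * (1 - fx) * img[i00] +
    (1 - fy) * fx * img[cbind(i00[, 1], i00[, 2] + 1L)] +
    fy * (1 - fx) * img[cbind(i00[, 1] + 1L, i00[, 2])] +
    fy * fx * img[cbind(i00[, 1] + 1L, i00[, 2] + 1L)]
  matrix(v * as.vector(ok), nrow(yy), ncol(yy))
}

# cosine-taper high-pass over the centered spectrum (1 - cos window product)
radial_highpass <- function(nr, nc) {
  ey <- cos(pi * (seq_len(nr) - (nr + 1) / 2) / nr)
  ex <- cos(pi * (seq_len(nc) - (nc + 1) / 2) / nc)
  x <- outer(ey, ex)
  (1 - x) * (2 - x)
}

fftshift2 <- function(x) {
  nr <- nrow(x); nc <- ncol(x)
  x[c((floor(nr / 2) + 1):nr, 1:floor(nr / 2)),
    c((floor(nc / 2) + 1):nc, 1:floor(nc / 2))]
}

#' Estimate a similarity transform (rotation, scale, translation)
#'
#' Rotation and log-scale are recovered by phase correlation of the
#' log-polar resampled Fourier magnitude spectra (rotation becomes a shift
#' along the angular axis and scale a shift along the log-radius axis);
#' the image is then de-rotated/de-scaled and the residual translation is
#' recovered by [estimate_translation()]. A rotation estimate above 45
#' degrees is flagged unreliable and the estimator falls back to
#' translation only.
#'
#' @inheritParams estimate_translation
#' @param upsample Sub-pixel/sub-bin refinement factor.
#' @return A [drift_transform()].
#' @export
estimate_similarity <- function(reference, moving, upsample = 20L) {
  stopifnot(identical(dim(reference), dim(moving)))
  w <- hann2(nrow(reference), ncol(reference))
  ma <- fftshift2(Mod(stats::fft((reference - mean(reference)) * w)))
  mb <- fftshift2(Mod(stats::fft((moving - mean(moving)) * w)))
  # radial high-pass: suppress the near-isotropic low-frequency core that
  # otherwise dominates the log-polar correlation
  hp <- radial_highpass(nrow(ma), ncol(ma))
  lp_estimate <- function(mov_img) {
    mm <- fftshift2(Mod(stats::fft((mov_img - mean(mov_img)) * w)))
    lpb <- log_polar(log1p(mm) * hp)
    pc <- phase_correlate(lpa$data, lpb$data, upsample = upsample)
    # rows = log-radius, cols = angle
    rot <- -pc$dx * lpa$theta_step
    if (rot > 90) rot <- rot - 180
    if (rot < -90) rot <- rot + 180
    list(rotation = rot, scale = exp(-pc$dy * lpa$logr_step),
         quality = pc$peak_quality)
  }
  lpa <- log_polar(log1p(ma) * hp)
  e1 <- lp_estimate(moving)
  rotation <- e1$rotation; scale <- e1$scale
  if (abs(rotation) > 45 || scale <= 0.5 || scale >= 2) {
    warning("similarity estimate unreliable; falling back to translation only")
    return(estimate_translation(reference, moving, upsample = upsample))
  }
  # refinement pass: estimate the residual rotation/scale left after
  # undoing the first estimate (halves the log-polar discretization bias)
  e2 <- lp_estimate(warp_similarity(moving, 0, 0, -rotation, 1 / scale))
  if (abs(e2$rotation) < 5 && abs(log(e2$scale)) < 0.05) {
    rotation <- rotation + e2$rotation
    scale <- scale * e2$scale
  }
  undone <- warp_similarity(moving, 0, 0, -rotation, 1 / scale)
  tr <- estimate_translation(reference, undone, upsample = upsample,
                             window = TRUE, reg = 0.1)
  drift_transform(tr$dy, tr$dx, rotation, scale,
                  min(e1$quality, tr$peak_quality, na.rm = TRUE))
}

# Sub-pixel translation by the Fourier shift theorem (sinc interpolation);
# the strips that wrap around circularly are zeroed to honor the
# out-of-frame-pixels-are-zero contract.
fourier_translate <- function(img, dy, dx) {
  n <- nrow(img); m <- ncol(img)
  ky <- fft_freqs(n); kx <- fft_freqs(m)
  ph <- exp(-2i * pi * (outer(ky * dy, rep(1, m)) +
                          outer(rep(1, n), kx * dx)))
  out <- Re(stats::fft(stats::fft(img) * ph, inverse = TRUE)) / (n * m)
  cy <- ceiling(abs(dy)); cx <- ceiling(abs(dx))
  if (cy > 0) {
    rows <- if (dy > 0) seq_len(min(cy, n)) else n + 1 - seq_len(min(cy, n))
    out[rows, ] <- 0
  }
  if (cx > 0) {
    cols <- if (dx > 0) seq_len(min(cx, m)) else m + 1 - seq_len(min(cx, m))
    out[, cols] <- 0
  }
  out
}

# Resample `img` under the forward similarity map: the output at pixel p
# takes the input value at A^{-1}(p), where
# A(p) = scale * R(rotation) (p - c) + c + (dy, dx).
warp_similarity <- function(img, dy, dx, rotation, scale) {
  nr <- nrow(img); nc <- ncol(img)
  if (rotation == 0 && scale == 1 &&
      dy == round(dy) && dx == round(dx)) {
    # integer translation fast path: exact, zero-filled
    out <- matrix(0, nr, nc)
    ys <- seq_len(nr) - dy; xs <- seq_len(nc) - dx
    okY <- ys >= 1 & ys <= nr; okX <- xs >= 1 & xs <= nc
    out[okY, okX] <- img[ys[okY], xs[okX]]
    return(out)
  }
  cy <- (nr + 1) / 2; cx <- (nc + 1) / 2
  th <- rotation * pi / 180
  R <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2, byrow = TRUE)
  # inverse map
  yy <- matrix(seq_len(nr), nr, nc) - cy - dy
  xx <- matrix(seq_len(nc), nr, nc, byrow = TRUE) - cx - dx
  sy <- (R[1, 1] * yy + R[2, 1] * xx) / scale + cy   # R^{-1} = t(R)
  sx <- (R[1, 2] * yy + R[2, 2] * xx) / scale + cx
  bilinear_sample(img, sy, sx)
}

#' Apply a drift transform to an image
#'
#' Resamples the image under the similarity map described by the transform
#' (rotation and scale about the image center, then translation); pixels
#' mapped from outside the frame are 0. An identity transform returns the
#' input unchanged; pure integer translations are applied exactly without
#' interpolation; pure sub-pixel translations use Fourier (sinc)
#' interpolation; rotation or scale falls back to bilinear resampling.
#'
#' @param image Numeric matrix.
#' @param transform A [drift_transform()].
#' @return Transformed matrix of the same shape.
#' @export
apply_transform <- function(image, transform) {
  stopifnot(inherits(transform, "drift_transform"))
  if (is_identity_transform(transform)) return(image)
  if (transform$rotation == 0 && transform$scale == 1 &&
      !(transform$dy == round(transform$dy) &&
          transform$dx == round(transform$dx)))
    return(fourier_translate(image, transform$dy, transform$dx))
  warp_similarity(image, transform$dy, transform$dx, transform$rotation,
                  transform$scale)
}

#' Invert a drift transform
#' @param transform A [drift_transform()].
#' @return The inverse [drift_transform()] (composition yields identity).
#' @export
invert_transform <- function(transform) {
  s <- 1 / transform$scale
  th <- -transform$rotation * pi / 180
  R <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2, byrow = TRUE)
  t_new <- -s * (R %*% c(transform$dy, transform$dx))
  drift_transform(t_new[1], t_new[2], -transform$rotation, s,
                  transform$peak_quality)
}

#' Estimate between-cycle transforms for every tile of a region
#'
#' For each cycle, the reference-channel best-focus plane of every tile is
#' registered against the same tile in the reference cycle; the resulting
#' transform is shared by all sibling channels of that cycle (recorded once
#' per (cycle, tile)). The reference cycle maps to the identity. Blank
#' cycles are registered like any other cycle so that background
#' subtraction operates on aligned images. Estimates whose correlation peak
#' falls below `quality_threshold` (e.g. empty tiles without tissue) are
#' replaced by the identity and flagged.
#'
#' @param ref_planes,moving_planes Lists of reference-channel planes per
#'   tile: `ref_planes[[tile]]` from the reference cycle,
#'   `moving_planes[[tile]]` from the cycle being registered.
#' @param mode `"translation"` (default) or `"similarity"`.
#' @param upsample Sub-pixel refinement factor.
#' @param quality_threshold Minimum peak quality before identity fallback.
#' @return List of [drift_transform()] per tile, each with attribute
#'   `fallback` when substituted.
#' @export
register_cycle_tiles <- function(ref_planes, moving_planes,
                                 mode = c("translation", "similarity"),
                                 upsample = 20L, quality_threshold = 0.03) {
  mode <- match.arg(mode)
  lapply(seq_along(ref_planes), function(t) {
    ref <- ref_planes[[t]]; mov <- moving_planes[[t]]
    tf <- tryCatch({
      if (mode == "translation")
        estimate_translation(ref, mov, upsample = upsample, window = TRUE)
      else estimate_similarity(ref, mov, upsample = upsample)
    }, error = function(e) NULL)
    if (is.null(tf) || !is.finite(tf$peak_quality) ||
        tf$peak_quality < quality_threshold) {
      warning(sprintf("tile %d: unreliable transform; identity substituted", t))
      tf <- drift_transform(0, 0, 0, 1,
                            if (is.null(tf)) 0 else tf$peak_quality)
      attr(tf, "fallback") <- TRUE
    }
    tf
  })
}

#' Serialize per-(cycle, tile) transforms to CSV
#' @param transforms Nested list: `transforms[[cycle]][[tile]]`.
#' @param path Destination CSV.
#' @return `path`, invisibly.
#' @export
write_transforms_csv <- function(transforms, path) {
  rows <- list()
  for (cyc in seq_along(transforms)) {
    tfs <- transforms[[cyc]]
    if (is.null(tfs)) next
    for (t in seq_along(tfs)) {
      tf <- tfs[[t]]
      rows[[length(rows) + 1L]] <- data.frame(
        cycle = cyc, tile = t, dy = tf$dy, dx = tf$dx,
        rotation = tf$rotation, scale = tf$scale,
        peak_quality = tf$peak_quality,
        fallback = isTRUE(attr(tf, "fallback")))
    }
  }
  df <- do.call(rbind, rows)
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(format(df, digits = 17, scientific = TRUE, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read transforms written by [write_transforms_csv()]
#' @param path CSV path.
#' @return Nested list `transforms[[cycle]][[tile]]` of
#'   [drift_transform()]s (lossless round trip).
#' @export
read_transforms_csv <- function(path) {
  df <- utils::read.csv(path)
  out <- list()
  for (i in seq_len(nrow(df))) {
    tf <- drift_transform(df$dy[i], df$dx[i], df$rotation[i], df$scale[i],
                          df$peak_quality[i])
    if (isTRUE(df$fallback[i])) attr(tf, "fallback") <- TRUE
    cyc <- df$cycle[i]
    if (length(out) < cyc || is.null(out[cyc][[1]])) out[[cyc]] <- list()
    out[[cyc]][[df$tile[i]]] <- tf
  }
  out
}
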