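# Shared fixture builders. Everything is generated in code at test time;
# expensive shared objects (synthetic experiments, pipeline runs) are
# cached once per test session.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

session_dir <- function(...) {
  root <- cached("session_root", {
    d <- file.path(tempdir(), "codexpp-tests")
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    d
  })
  file.path(root, ...)
}

# Smooth random texture with decent gradient content
make_textured <- function(n, seed = 1, smooth_sd = 1, amplitude = 40000) {
  set.seed(seed)
  g <- matrix(rnorm(n * n), n, n)
  k <- outer(dnorm(seq(-2, 2, length.out = 9), sd = smooth_sd),
             dnorm(seq(-2, 2, length.out = 9), sd = smooth_sd))
  k <- k / sum(k)
  gf <- stats::fft(g)
  kb <- matrix(0, n, n)
  kb[1:9, 1:9] <- k
  kb <- kb[c(5:n, 1:4), c(5:n, 1:4)]   # center kernel at origin
  out <- Re(stats::fft(gf * stats::fft(kb), inverse = TRUE)) / (n * n)
  (out - min(out)) / (max(out) - min(out)) * amplitude
}

# Exact sub-pixel shift by the Fourier shift theorem (independent of the
# package's resampling code)
fourier_shift <- function(img, dy, dx) {
  n <- nrow(img); m <- ncol(img)
  ky <- c(0:floor((n - 1) / 2), -(floor(n / 2):1)) / n
  kx <- c(0:floor((m - 1) / 2), -(floor(m / 2):1)) / m
  ph <- exp(-2i * pi * (outer(ky * dy, rep(1, m)) +
                          outer(rep(1, n), kx * dx)))
  Re(stats::fft(stats::fft(img) * ph, inverse = TRUE)) / (n * m)
}

roll2 <- function(img, dy, dx) {
  n <- nrow(img); m <- ncol(img)
  img[((seq_len(n) - 1 - dy) %% n) + 1, ((seq_len(m) - 1 - dx) %% m) + 1]
}

# Independent classical Richardson-Lucy deconvolution oracle: flipped-PSF
# back projector, periodic boundaries, written directly against stats::fft
# (no package helpers).
classical_rl <- function(raw, psf, center, iterations = 25L) {
  d <- dim(raw)
  big <- array(0, dim = d)
  kd <- dim(psf)
  big[seq_len(kd[1]), seq_len(kd[2]), seq_len(kd[3])] <- psf
  idx <- lapply(1:3, function(i)
    ((seq_len(d[i]) - 1 + (center[i] - 1)) %% d[i]) + 1)
  big <- big[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  H <- stats::fft(big)
  conv <- function(x, tf) Re(stats::fft(stats::fft(x) * tf,
                                        inverse = TRUE)) / length(x)
  eps <- 1e-6 * max(raw)
  est <- raw
  for (i in seq_len(iterations)) {
    ratio <- raw / pmax(conv(est, H), eps)
    est <- est * conv(ratio, Conj(H))
  }
  pmax(est, 0)
}

# Tissue-like scene: disk "cells" with sharp edges over a noisy background
make_cell_image <- function(n, seed = 1, n_cells = round(n * n / 900)) {
  set.seed(seed)
  img <- matrix(rnorm(n * n, 800, 60), n, n)
  yy <- matrix(seq_len(n), n, n); xx <- t(yy)
  for (i in seq_len(n_cells)) {
    r <- runif(1, 4, 8)
    cy <- runif(1, r, n - r); cx <- runif(1, r, n - r)
    m <- (yy - cy)^2 + (xx - cx)^2 <= r^2
    img[m] <- img[m] + runif(1, 1e4, 3e4)
  }
  img
}

put_disk <- function(img, cy, cx, r, value, add = FALSE) {
  yy <- matrix(seq_len(nrow(img)), nrow(img), ncol(img))
  xx <- matrix(seq_len(ncol(img)), nrow(img), ncol(img), byrow = TRUE)
  m <- (yy - cy)^2 + (xx - cx)^2 <= r^2
  if (add) img[m] <- img[m] + value else img[m] <- value
  img
}

small_optics <- function(psf_size = 31L)
  optical_config(psf_size_xy = psf_size)

# One small shared synthetic experiment + one processed run, reused by the
# io/synthsim/pipeline tests (128 px tiles keep it light).
shared_sim <- function() {
  cached("shared_sim", {
    root <- session_dir("sim_default")
    manifest <- simulate_experiment(
      root, layout = default_synth_layout(tile_px = 128L),
      optics = default_synth_optics(), degradations = degradation_spec(),
      seed = 101L)
    list(root = root, manifest = manifest)
  })
}

shared_run <- function() {
  cached("shared_run", {
    sim <- shared_sim()
    out <- session_dir("run_default")
    cfg <- pipeline_config(sim$root, out, workers = 1L)
    res <- process_region(cfg, 1L)
    list(sim = sim, out = out, cfg = cfg, res = res)
  })
}
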