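# Between-cycle registration: phase correlation, similarity estimation,
# transform application and serialization.

test_that("self-registration returns the origin with a full-height peak", {
  img <- make_textured(64, seed = 20)
  tf <- estimate_translation(img, img, upsample = 1)
  expect_equal(c(tf$dy, tf$dx), c(0, 0))
  expect_gt(tf$peak_quality, 0.95)
  expect_error(estimate_translation(matrix(5, 16, 16), img[1:16, 1:16]),
               "constant")
})

test_that("integer circular shifts are recovered exactly at upsample 1", {
  img <- make_textured(64, seed = 21)
  mov <- roll2(img, 5, -3)
  tf <- estimate_translation(img, mov, upsample = 1)
  expect_equal(c(tf$dy, tf$dx), c(5, -3))
})

test_that("sub-pixel shifts are recovered within 0.1 px at upsample 20", {
  img <- make_textured(96, seed = 22)
  for (s in list(c(2.25, -1.50), c(-0.75, 3.40))) {
    mov <- fourier_shift(img, s[1], s[2])
    tf <- estimate_translation(img, mov, upsample = 20)
    expect_lt(abs(tf$dy - s[1]), 0.1)
    expect_lt(abs(tf$dx - s[2]), 0.1)
  }
})

test_that("similarity mode recovers rotation and scale within tolerance", {
  img <- make_textured(192, seed = 23)
  rot <- estimate_similarity(img, codexpp:::warp_similarity(img, 0, 0, 2, 1))
  expect_lt(abs(rot$rotation - 2), 0.2)
  expect_lt(abs(rot$scale - 1), 0.005)
  scl <- estimate_similarity(img, codexpp:::warp_similarity(img, 0, 0, 0, 1.02))
  expect_lt(abs(scl$scale - 1.02), 0.005)
  expect_lt(abs(scl$rotation), 0.2)
  idn <- estimate_similarity(img, img)
  expect_equal(c(idn$dy, idn$dx, idn$rotation), c(0, 0, 0))
  expect_equal(idn$scale, 1)
})

test_that("estimator consistency holds over random similarity transforms", {
  img <- make_textured(192, seed = 24)
  set.seed(25)
  for (i in 1:20) {
    truth <- drift_transform(runif(1, -10, 10), runif(1, -10, 10),
                             runif(1, -5, 5), runif(1, 0.98, 1.02))
    mov <- apply_transform(img, truth)
    est <- estimate_similarity(img, mov)
    expect_lt(abs(est$dy - truth$dy), 0.5)
    expect_lt(abs(est$dx - truth$dx), 0.5)
    expect_lt(abs(est$rotation - truth$rotation), 0.3)
    expect_lt(abs(est$scale - truth$scale), 0.01)
  }
})

test_that("transform application is exact for identity and integer shifts", {
  img <- matrix(sample(0:65535, 48 * 48, replace = TRUE), 48, 48)
  expect_identical(apply_transform(img, drift_transform(0, 0)), img)
  shifted <- apply_transform(img, drift_transform(5, -3))
  back <- apply_transform(shifted, drift_transform(-5, 3))
  expect_equal(back[10:40, 10:40], img[10:40, 10:40] * 1.0)
})

test_that("apply then estimate round-trips within 0.1 px on smooth images", {
  img <- make_textured(128, seed = 26, smooth_sd = 2)
  tf <- drift_transform(3.3, -2.7)
  mov <- apply_transform(img, tf)
  # compare over the common interior so the zero-filled border of the
  # resampled image does not bias the spectrum
  core <- 17:112
  est <- estimate_translation(img[core, core], mov[core, core],
                              upsample = 20, window = TRUE)
  expect_lt(abs(est$dy - tf$dy), 0.1)
  expect_lt(abs(est$dx - tf$dx), 0.1)
})

test_that("transform inversion composes to the identity", {
  tf <- drift_transform(4.5, -2.25, rotation = 3, scale = 1.01)
  inv <- invert_transform(tf)
  expect_equal(inv$rotation, -3)
  expect_equal(inv$scale, 1 / 1.01)
  img <- make_textured(96, seed = 27, smooth_sd = 3)
  there_back <- apply_transform(apply_transform(img, tf), inv)
  diff <- abs(there_back[20:76, 20:76] - img[20:76, 20:76])
  expect_lt(mean(diff) / max(img), 0.02)    # double bilinear resampling
})

test_that("low-quality estimates fall back to the identity with a warning", {
  ref <- list(make_textured(48, seed = 28))
  empty <- list(matrix(500, 48, 48))   # featureless tile: no tissue
  expect_warning(tfs <- register_cycle_tiles(ref, empty), "identity")
  expect_equal(c(tfs[[1]]$dy, tfs[[1]]$dx), c(0, 0))
  expect_true(isTRUE(attr(tfs[[1]], "fallback")))
})

test_that("per-cycle transforms against the generator manifest are sub-pixel", {
  run <- shared_run()
  man <- run$sim$manifest
  tfs <- read_transforms_csv(file.path(run$out, "region_001",
                                       "transforms.csv"))
  layout <- default_synth_layout(tile_px = 128L)
  for (cyc in 2:4) for (tile in seq_len(n_tiles(layout))) {
    jc <- man$jitter[man$jitter$cycle == cyc & man$jitter$tile == tile, ]
    jr <- man$jitter[man$jitter$cycle == 1 & man$jitter$tile == tile, ]
    # the estimated transform tracks the scene content, i.e. the negative
    # of the stage-origin displacement recorded in the manifest
    true_dy <- -(man$drift$dy[cyc] + jc$dy - jr$dy)
    true_dx <- -(man$drift$dx[cyc] + jc$dx - jr$dx)
    expect_lt(abs(tfs[[cyc]][[tile]]$dy - true_dy), 0.5)
    expect_lt(abs(tfs[[cyc]][[tile]]$dx - true_dx), 0.5)
  }
})

test_that("transform CSV serialization is lossless", {
  set.seed(29)
  transforms <- lapply(1:3, function(cyc)
    lapply(1:4, function(t)
      drift_transform(runif(1, -8, 8), runif(1, -8, 8),
                      runif(1, -2, 2), runif(1, 0.99, 1.01),
                      runif(1))))
  path <- file.path(withr::local_tempdir(), "tf.csv")
  write_transforms_csv(transforms, path)
  back <- read_transforms_csv(path)
  for (cyc in 1:3) for (t in 1:4) {
    expect_identical(back[[cyc]][[t]]$dy, transforms[[cyc]][[t]]$dy)
    expect_identical(back[[cyc]][[t]]$dx, transforms[[cyc]][[t]]$dx)
    expect_identical(back[[cyc]][[t]]$scale, transforms[[cyc]][[t]]$scale)
  }
})
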