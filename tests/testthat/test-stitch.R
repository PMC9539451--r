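# Within-cycle stitching: pairwise offsets, stage model, global positions,
# linear-blended mosaics.

nuclear_channel <- list(channel_spec("DAPI", 425, is_nuclear = TRUE))

# Cut a grid of tiles out of one big textured image with exact overlaps
# (plus optional per-tile jitter); the construction offsets are the oracle.
crop_fixture <- function(rows, cols, tile = 96, overlap = 0.15, seed = 30,
                         jitter = 0) {
  step <- tile - round(overlap * tile)
  margin <- jitter + 1
  big <- make_cell_image((max(rows, cols) - 1) * step + tile + 2 * margin,
                         seed = seed)
  layout <- experiment_layout(rows, cols, n_z = 1,
                              channels = nuclear_channel, n_cycles = 1,
                              overlap_fraction = round(overlap * tile) / tile,
                              tile_shape = c(tile, tile))
  set.seed(seed + 1)
  tiles <- list(); truth <- matrix(0, rows * cols, 2)
  for (t in seq_len(rows * cols)) {
    rc <- tile_row_col(layout, t)
    y0 <- (rc["row"] - 1) * step + margin +
      if (jitter > 0) sample(-jitter:jitter, 1) else 0
    x0 <- (rc["col"] - 1) * step + margin +
      if (jitter > 0) sample(-jitter:jitter, 1) else 0
    tiles[[t]] <- big[y0 + seq_len(tile), x0 + seq_len(tile)]
    truth[t, ] <- c(y0, x0)
  }
  truth <- sweep(truth, 2, apply(truth, 2, min))
  list(big = big, layout = layout, tiles = tiles, truth = truth,
       step = step)
}

test_that("a single tile yields no pairs and anchors at the origin", {
  fx <- crop_fixture(1, 1)
  pairs <- pairwise_translations(fx$tiles, fx$layout)
  expect_equal(nrow(pairs), 0L)
  model <- fit_stage_model(pairs, fx$layout)
  pos <- solve_positions(model, fx$layout)
  expect_equal(unclass(pos), matrix(c(0, 0), 1, 2), ignore_attr = TRUE)
})

test_that("exact-overlap pairwise offsets are recovered with high ncc", {
  fx <- crop_fixture(2, 2)
  pairs <- pairwise_translations(fx$tiles, fx$layout)
  expect_equal(nrow(pairs), 4L)
  for (i in seq_len(nrow(pairs))) {
    expected <- fx$truth[pairs$tile_b[i], ] - fx$truth[pairs$tile_a[i], ]
    expect_equal(c(pairs$dy[i], pairs$dx[i]), unname(expected))
    expect_gt(pairs$ncc[i], 0.99)
  }
})

test_that("featureless tile pairs are marked invalid", {
  flat <- list(matrix(100, 64, 64), matrix(100, 64, 64))
  layout <- experiment_layout(1, 2, n_z = 1, channels = nuclear_channel,
                              n_cycles = 1, tile_shape = c(64, 64))
  pairs <- pairwise_translations(flat, layout)
  expect_false(any(pairs$valid))
})

test_that("the stage model flags outliers and falls back to nominal", {
  fx <- crop_fixture(3, 4, jitter = 2)
  pairs <- pairwise_translations(fx$tiles, fx$layout)
  # inject a 50 px error into one estimate
  pairs$dy[5] <- pairs$dy[5] + 50
  model <- fit_stage_model(pairs, fx$layout)
  dir5 <- pairs$direction[5]
  expect_true(model$pairs$flagged[5])
  expect_lt(abs(model$pairs$dy[5] - model[[dir5]]["dy"]), 1e-9)
  others <- pairs$dy[pairs$direction == dir5 & seq_len(nrow(pairs)) != 5]
  expect_lt(abs(model[[dir5]]["dy"] - median(others)), 3)
  # all pairs identical -> zero repeatability
  same <- pairs[pairs$direction == "west", ]
  same$dy <- 0; same$dx <- fx$step; same$ncc <- 1; same$valid <- TRUE
  m2 <- fit_stage_model(same, fx$layout)
  expect_equal(m2$repeatability, 0)
  expect_equal(unname(m2$west["dx"]), fx$step)
  # zero valid pairs -> nominal overlap model, everything flagged
  none <- pairs; none$valid <- FALSE
  m3 <- fit_stage_model(none, fx$layout)
  expect_true(all(m3$pairs$flagged))
  expect_equal(unname(m3$west["dx"]),
               fx$layout$tile_shape[2] * (1 - fx$layout$overlap_fraction))
})

test_that("global positions equal the construction truth exactly", {
  fx <- crop_fixture(2, 2)
  model <- fit_stage_model(pairwise_translations(fx$tiles, fx$layout),
                           fx$layout)
  pos <- solve_positions(model, fx$layout)
  expect_equal(unclass(pos), fx$truth, ignore_attr = TRUE)
})

test_that("jittered positions are recovered within 1 px", {
  fx <- crop_fixture(3, 3, jitter = 3, seed = 33)
  model <- fit_stage_model(pairwise_translations(fx$tiles, fx$layout),
                           fx$layout)
  pos <- solve_positions(model, fx$layout)
  expect_lt(max(abs(pos - fx$truth)), 1)
})

test_that("the spanning-tree solver matches a least-squares oracle", {
  fx <- crop_fixture(2, 3, jitter = 2, seed = 34)
  pairs <- pairwise_translations(fx$tiles, fx$layout)
  model <- fit_stage_model(pairs, fx$layout)
  pos <- solve_positions(model, fx$layout)
  # oracle: solve min sum ||p_b - p_a - d_ab||^2 by normal equations,
  # anchoring tile 1 (independent dense least squares per axis)
  nt <- 6
  A <- matrix(0, nrow(pairs) + 1, nt)
  for (i in seq_len(nrow(pairs))) {
    A[i, pairs$tile_a[i]] <- -1
    A[i, pairs$tile_b[i]] <- 1
  }
  A[nrow(pairs) + 1, 1] <- 1
  for (axis in c("dy", "dx")) {
    b <- c(pairs[[axis]], 0)
    ls <- qr.solve(A, b)
    col <- if (axis == "dy") 1 else 2
    expect_lt(max(abs((pos[, col] - pos[1, col]) - (ls - ls[1]))), 0.5)
  }
})

test_that("blending preserves constant tiles and forms a partition of unity", {
  fx <- crop_fixture(2, 2)
  const_tiles <- lapply(fx$tiles, function(t) matrix(777, nrow(t), ncol(t)))
  pos <- structure(fx$truth, class = c("tile_positions", "matrix"))
  mos <- compose_mosaic(const_tiles, pos, blend = "linear",
                        layout = fx$layout)
  expect_equal(max(abs(mos - 777)), 0)
  ws <- attr(mos, "weight_sum")
  expect_lt(max(abs(ws - 1)), 1e-9)
})

test_that("the overlap ramp follows hand-computed linear weights", {
  # two 1x2 tiles of constants 0 and 100 overlapping by 4 columns
  layout <- experiment_layout(1, 2, n_z = 1, channels = nuclear_channel,
                              n_cycles = 1, overlap_fraction = 4 / 16,
                              tile_shape = c(8, 16))
  tiles <- list(matrix(0, 8, 16), matrix(100, 8, 16))
  pos <- structure(matrix(c(0, 0, 0, 12), 2, 2, byrow = TRUE),
                   class = c("tile_positions", "matrix"))
  mos <- compose_mosaic(tiles, pos, blend = "linear", layout = layout)
  # overlap columns 13..16; tile-2 weight ramps 1/5, 2/5, 3/5, 4/5
  expect_equal(mos[4, 13], 100 * 1 / 5)
  expect_equal(mos[4, 15], 100 * 3 / 5)
  expect_equal(mos[4, 16], 100 * 4 / 5)
  expect_equal(mos[4, 20], 100)   # tile-2 interior
  mos_none <- compose_mosaic(tiles, pos, blend = "none", layout = layout)
  expect_equal(mos_none[4, 13], 100)   # last written wins
})

test_that("mosaics rebuilt from crop fixtures reproduce the source image", {
  fx <- crop_fixture(2, 2, seed = 35)
  model <- fit_stage_model(pairwise_translations(fx$tiles, fx$layout),
                           fx$layout)
  pos <- solve_positions(model, fx$layout)
  mos <- compose_mosaic(fx$tiles, pos, blend = "linear", layout = fx$layout)
  h <- nrow(mos); w <- ncol(mos)
  src <- fx$big[1 + seq_len(h), 1 + seq_len(w)]   # margin = 1 here
  expect_lt(max(abs(mos - src)), 1)
})
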