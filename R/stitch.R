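# Within-cycle lateral drift correction: pairwise phase-correlation
# translations between adjacent tiles, a mechanical stage model that
# repairs unreliable estimates, global tile positioning over a
# maximum-correlation spanning tree, and linear-blended mosaic composition.

ncc_overlap <- function(tile_a, tile_b, dy, dx, min_px = 2L) {
  # normalized cross-correlation of the overlap implied by
  # pos_b - pos_a = (dy, dx)
  nr <- nrow(tile_a); nc <- ncol(tile_a)
  ya <- max(1L, 1L + dy):min(nr, nr + dy)
  xa <- max(1L, 1L + dx):min(nc, nc + dx)
  if (length(ya) <= min_px || length(xa) <= min_px) return(NA_real_)
  a <- tile_a[ya, xa]
  b <- tile_b[ya - dy, xa - dx]
  sa <- stats::sd(a); sb <- stats::sd(b)
  if (sa == 0 || sb == 0) return(NA_real_)
  mean((a - mean(a)) * (b - mean(b))) / (sa * sb)
}

top_k_peaks <- function(surface, k) {
  ord <- order(surface, decreasing = TRUE)[seq_len(min(k, length(surface)))]
  arrayInd(ord, dim(surface)) - 1L
}

#' Pairwise translations between adjacent tiles
#'
#' For every horizontally ("west") and vertically ("north") adjacent tile
#' pair of the grid, computes the phase-correlation surface, tests the
#' top-`k` peaks (including their wrap-around interpretations), scores each
#' candidate by the normalized cross-correlation of the overlap it implies,
#' and keeps the best-scoring candidate. Pairs whose implied overlap is
#' degenerate (<= 2 px) or featureless are marked invalid.
#'
#' @param tiles List of 2-D tile images indexed by tile number (reference
#'   cycle, reference channel, best-focus plane).
#' @param layout An [experiment_layout()].
#' @param k Number of candidate correlation peaks tested per pair.
#' @return Data frame with columns `tile_a`, `tile_b`, `direction`
#'   (`"west"` = a is left neighbor, `"north"` = a is top neighbor), `dy`,
#'   `dx` (position of b minus position of a), `ncc`, `valid`.
#' @export
pairwise_translations <- function(tiles, layout, k = 8L) {
  rows <- list()
  dims <- dim(tiles[[1]])
  for (tile in seq_len(n_tiles(layout))) {
    rc <- tile_row_col(layout, tile)
    for (dir in c("west", "north")) {
      if (dir == "west" && rc["col"] == 1L) next
      if (dir == "north" && rc["row"] == 1L) next
      nb_rc <- if (dir == "west") c(rc[1], rc[2] - 1L) else c(rc[1] - 1L, rc[2])
      a <- grid_tile_index(layout, nb_rc[1], nb_rc[2])
      b <- tile
      nominal <- if (dir == "west")
        c(0, round(dims[2] * (1 - layout$overlap_fraction)))
      else c(round(dims[1] * (1 - layout$overlap_fraction)), 0)
      est <- pairwise_offset(tiles[[a]], tiles[[b]], nominal, k)
      rows[[length(rows) + 1L]] <- data.frame(
        tile_a = a, tile_b = b, direction = dir,
        dy = est$dy, dx = est$dx, ncc = est$ncc, valid = est$valid)
    }
  }
  if (!length(rows))
    return(data.frame(tile_a = integer(), tile_b = integer(),
                      direction = character(), dy = numeric(),
                      dx = numeric(), ncc = numeric(), valid = logical()))
  do.call(rbind, rows)
}

# 1-based tile index of grid cell (row, col) honoring serpentine order
grid_tile_index <- function(layout, row, col) {
  if (layout$serpentine && row %% 2L == 0L) col <- layout$grid_cols + 1L - col
  as.integer((row - 1L) * layout$grid_cols + col)
}

pairwise_offset <- function(tile_a, tile_b, nominal, k = 8L, reg = 0.1,
                            search_radius = 10L) {
  if (stats::sd(tile_a) == 0 || stats::sd(tile_b) == 0)
    return(list(dy = NA_real_, dx = NA_real_, ncc = NA_real_, valid = FALSE))
  a <- tile_a - mean(tile_a); b <- tile_b - mean(tile_b)
  fa <- stats::fft(a); fb <- stats::fft(b)
  cross <- Conj(fa) * fb
  # partially whitened cross-power: the magnitude floor keeps weak
  # (small-overlap) peaks above the noise the full whitening amplifies
  m <- Mod(cross)
  cross <- cross / pmax(m + reg * mean(m), .Machine$double.eps)
  surf <- Re(stats::fft(cross, inverse = TRUE)) / length(cross)
  nr <- nrow(tile_a); nc <- ncol(tile_a)
  # candidate offsets: the k strongest correlation peaks anywhere (in all
  # wrap-around interpretations), plus the strongest peaks inside the
  # stage-repeatability window around the nominal grid offset
  cand <- matrix(numeric(0), 0, 2)
  peaks <- top_k_peaks(surf, k)
  for (i in seq_len(nrow(peaks))) {
    py <- peaks[i, 1]; px <- peaks[i, 2]
    for (sy in unique(c(py, py - nr))) for (sx in unique(c(px, px - nc)))
      cand <- rbind(cand, c(-sy, -sx))
  }
  near <- expand.grid(dy = nominal[1] + (-search_radius):search_radius,
                      dx = nominal[2] + (-search_radius):search_radius)
  cand <- rbind(cand, as.matrix(near))
  best <- list(dy = NA_real_, dx = NA_real_, ncc = -Inf, valid = FALSE)
  for (i in seq_len(nrow(cand))) {
    # peak (sy, sx): tile_b ~= tile_a rolled by (sy, sx), so the scene
    # offset pos_b - pos_a is (-sy, -sx)
    ncc <- ncc_overlap(tile_a, tile_b, cand[i, 1], cand[i, 2])
    if (is.na(ncc)) next
    if (ncc > best$ncc) best <- list(dy = cand[i, 1], dx = cand[i, 2],
                                     ncc = ncc, valid = TRUE)
  }
  if (!is.finite(best$ncc)) {
    best$ncc <- NA_real_
    return(best)
  }
  # hill-climb refinement: walk the integer offset to the local ncc
  # maximum (repairs off-by-a-few-pixel peak picks)
  repeat {
    moved <- FALSE
    for (step in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1),
                      c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))) {
      cand <- ncc_overlap(tile_a, tile_b, best$dy + step[1],
                          best$dx + step[2])
      if (!is.na(cand) && cand > best$ncc) {
        best$dy <- best$dy + step[1]; best$dx <- best$dx + step[2]
        best$ncc <- cand
        moved <- TRUE
        break
      }
    }
    if (!moved) break
  }
  best
}

#' Fit the mechanical stage model
#'
#' Models the microscope stage as moving by a repeatable step per grid
#' direction: the per-direction robust center (median) of the valid
#' pairwise translations, with repeatability estimated as the scaled median
#' absolute deviation. Estimates farther than `3 * repeatability` from the
#' center or with `ncc < ncc_threshold` are replaced by the model value and
#' flagged. With no valid pair in a direction, the model falls back to the
#' nominal overlap fraction of the layout.
#'
#' @param pairs Data frame from [pairwise_translations()].
#' @param layout An [experiment_layout()].
#' @param ncc_threshold Minimum overlap correlation for a pair to be
#'   trusted.
#' @return A `stage_model` list: per-direction expected `(dy, dx)`,
#'   `repeatability` (px), and the `pairs` table with columns `model_dy`,
#'   `model_dx`, `flagged` added (flagged pairs carry model values).
#' @export
fit_stage_model <- function(pairs, layout, ncc_threshold = 0.5) {
  nominal <- list(
    west = c(dy = 0, dx = layout$tile_shape[2] *
               (1 - layout$overlap_fraction)),
    north = c(dy = layout$tile_shape[1] * (1 - layout$overlap_fraction),
              dx = 0))
  model <- list()
  rep_all <- 0
  for (dir in c("west", "north")) {
    sel <- pairs$direction == dir & pairs$valid &
      !is.na(pairs$ncc) & pairs$ncc >= ncc_threshold
    if (any(sel)) {
      ctr <- c(dy = stats::median(pairs$dy[sel]),
               dx = stats::median(pairs$dx[sel]))
      repe <- max(stats::mad(pairs$dy[sel], center = ctr["dy"]),
                  stats::mad(pairs$dx[sel], center = ctr["dx"]))
    } else {
      ctr <- nominal[[dir]]
      repe <- 0
    }
    model[[dir]] <- ctr
    rep_all <- max(rep_all, repe)
  }
  pairs$model_dy <- rep(NA_real_, nrow(pairs))
  pairs$model_dx <- rep(NA_real_, nrow(pairs))
  pairs$flagged <- rep(FALSE, nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    ctr <- model[[pairs$direction[i]]]
    pairs$model_dy[i] <- ctr["dy"]; pairs$model_dx[i] <- ctr["dx"]
    bad <- !isTRUE(pairs$valid[i]) || is.na(pairs$ncc[i]) ||
      pairs$ncc[i] < ncc_threshold ||
      abs(pairs$dy[i] - ctr["dy"]) > 3 * max(rep_all, 1e-9) ||
      abs(pairs$dx[i] - ctr["dx"]) > 3 * max(rep_all, 1e-9)
    if (bad) {
      pairs$flagged[i] <- TRUE
      pairs$dy[i] <- ctr["dy"]; pairs$dx[i] <- ctr["dx"]
    }
  }
  structure(list(west = model$west, north = model$north,
                 repeatability = rep_all, pairs = pairs,
                 ncc_threshold = ncc_threshold),
            class = "stage_model")
}

#' Solve global tile positions
#'
#' Positions tiles by accumulating pairwise offsets along a maximum-
#' correlation spanning tree (edges weighted by overlap ncc; repaired/
#' flagged pairs carry the stage-model offset and weight 0), anchored so
#' the minimum position is `(0, 0)`. A disconnected grid is completed with
#' nominal stage-model positions and a warning.
#'
#' @param model A `stage_model` from [fit_stage_model()] (carries the
#'   corrected pairs).
#' @param layout An [experiment_layout()].
#' @return A `tile_positions` matrix `(n_tiles x 2)` of `(y, x)` pixel
#'   offsets (real-valued).
#' @export
solve_positions <- function(model, layout) {
  nt <- n_tiles(layout)
  pairs <- model$pairs
  pos <- matrix(NA_real_, nt, 2)
  if (nt == 1L) {
    pos[1, ] <- c(0, 0)
  } else if (nrow(pairs)) {
    w <- ifelse(pairs$flagged | is.na(pairs$ncc), 0, pmax(pairs$ncc, 0))
    g <- igraph::graph_from_data_frame(
      data.frame(from = pairs$tile_a, to = pairs$tile_b,
                 weight = 1 - w + 1e-9, idx = seq_len(nrow(pairs))),
      directed = FALSE, vertices = data.frame(name = seq_len(nt)))
    tree <- igraph::mst(g)   # minimizes 1 - ncc == maximizes ncc
    pos[1, ] <- c(0, 0)
    # BFS over the tree accumulating offsets
    adj <- igraph::as_data_frame(tree, what = "edges")
    adj$from <- as.integer(adj$from); adj$to <- as.integer(adj$to)
    queue <- 1L
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      inc <- which(adj$from == v | adj$to == v)
      for (e in inc) {
        p <- pairs[adj$idx[e], ]
        other <- if (adj$from[e] == v) adj$to[e] else adj$from[e]
        if (!is.na(pos[other, 1])) next
        sgn <- if (p$tile_a == v) 1 else -1
        pos[other, ] <- pos[v, ] + sgn * c(p$dy, p$dx)
        queue <- c(queue, other)
      }
    }
  } else {
    pos[1, ] <- c(0, 0)
  }
  if (anyNA(pos)) {
    warning("tile grid not fully connected; placing remaining tiles at nominal positions")
    for (tile in seq_len(nt)) {
      if (!is.na(pos[tile, 1])) next
      rc <- tile_row_col(layout, tile)
      pos[tile, ] <- c((rc["row"] - 1) * model$north["dy"] +
                         (rc["col"] - 1) * model$west["dy"],
                       (rc["row"] - 1) * model$north["dx"] +
                         (rc["col"] - 1) * model$west["dx"])
    }
  }
  pos <- sweep(pos, 2, apply(pos, 2, min))
  colnames(pos) <- c("y", "x")
  structure(pos, class = c("tile_positions", "matrix"))
}

# Separable linear blending weight for one axis: ramps from 1/(ramp+1) at
# the tile edge to 1 over `ramp` pixels on the requested sides only
# (plateau elsewhere), complementary across an exact `ramp`-pixel overlap
# (the two tiles' weights sum to 1 there).
ramp_weights <- function(n, ramp, low = TRUE, high = TRUE) {
  w <- rep(1, n)
  ramp <- min(ramp, n)
  if (ramp > 0) {
    r <- seq_len(ramp) / (ramp + 1)
    if (low) w[seq_len(ramp)] <- pmin(w[seq_len(ramp)], r)
    if (high) w[n + 1L - seq_len(ramp)] <- pmin(w[n + 1L - seq_len(ramp)], r)
  }
  w
}

#' Compose a mosaic from positioned tiles
#'
#' Places each tile at its (rounded) global position and combines
#' overlapping pixels either by linear blending -- each tile weighted by a
#' separable ramp rising from its edges over the overlap width, weights
#' renormalized to sum to one wherever at least one tile contributes -- or
#' by last-written-wins (`blend = "none"`).
#'
#' @param tiles List of 2-D tile images.
#' @param positions A `tile_positions` matrix from [solve_positions()].
#' @param blend `"linear"` or `"none"`.
#' @param ramp Ramp width in pixels per axis `(y, x)`; defaults to the
#'   nominal overlap of `layout`.
#' @param layout An [experiment_layout()] (used only for the default ramp).
#' @return Numeric mosaic matrix covering the bounding box of all tiles.
#' @export
compose_mosaic <- function(tiles, positions, blend = c("linear", "none"),
                           ramp = NULL, layout = NULL) {
  blend <- match.arg(blend)
  th <- nrow(tiles[[1]]); tw <- ncol(tiles[[1]])
  if (is.null(ramp)) {
    if (is.null(layout)) stop("either ramp or layout must be given")
    ramp <- c(round(layout$overlap_fraction * th),
              round(layout$overlap_fraction * tw))
  }
  pr <- round(positions)
  H <- max(pr[, 1]) + th; W <- max(pr[, 2]) + tw
  acc <- matrix(0, H, W); wacc <- matrix(0, H, W)
  for (tile in seq_along(tiles)) {
    if (is.null(layout)) {
      wy <- ramp_weights(th, ramp[1]); wx <- ramp_weights(tw, ramp[2])
    } else {
      rc <- tile_row_col(layout, tile)
      wy <- ramp_weights(th, ramp[1], low = rc["row"] > 1L,
                         high = rc["row"] < layout$grid_rows)
      wx <- ramp_weights(tw, ramp[2], low = rc["col"] > 1L,
                         high = rc["col"] < layout$grid_cols)
    }
    wtile <- outer(wy, wx)
    ys <- pr[tile, 1] + seq_len(th); xs <- pr[tile, 2] + seq_len(tw)
    if (blend == "linear") {
      acc[ys, xs] <- acc[ys, xs] + tiles[[tile]] * wtile
      wacc[ys, xs] <- wacc[ys, xs] + wtile
    } else {
      acc[ys, xs] <- tiles[[tile]]
      wacc[ys, xs] <- 1
    }
  }
  out <- acc
  nz <- wacc > 0
  out[nz] <- acc[nz] / wacc[nz]
  attr(out, "weight_sum") <- wacc
  out
}

#' Write tile positions to CSV
#' @param positions A `tile_positions` matrix.
#' @param path Destination CSV.
#' @return `path`, invisibly.
#' @export
write_positions_csv <- function(positions, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  df <- data.frame(tile = seq_len(nrow(positions)),
                   y = positions[, 1], x = positions[, 2])
  utils::write.csv(format(df, digits = 17, trim = TRUE), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read tile positions written by [write_positions_csv()]
#' @param path CSV path.
#' @return A `tile_positions` matrix.
#' @export
read_positions_csv <- function(path) {
  df <- utils::read.csv(path)
  pos <- as.matrix(df[order(df$tile), c("y", "x")])
  dimnames(pos) <- list(NULL, c("y", "x"))
  structure(pos, class = c("tile_positions", "matrix"))
}
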