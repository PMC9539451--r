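# Focus-measure operators. All operate on a single 2-D plane and return a
# non-negative scalar that increases with sharpness; gradient-based metrics
# are invariant to a constant intensity offset.

#' @rdname focus_score
#' @export
focus_metrics <- c("tenengrad", "variance_of_laplacian", "brenner",
                   "normalized_variance")

conv2_full_valid <- function(img, kern) {
  # 2-D valid-region convolution by explicit shifts (kernels are 3x3)
  kr <- nrow(kern); kc <- ncol(kern)
  nr <- nrow(img) - kr + 1L; nc <- ncol(img) - kc + 1L
  out <- matrix(0, nr, nc)
  for (i in seq_len(kr)) for (j in seq_len(kc)) {
    if (kern[i, j] != 0)
      out <- out + kern[i, j] * img[i:(i + nr - 1L), j:(j + nc - 1L)]
  }
  out
}

sobel_y <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3, byrow = TRUE)
sobel_x <- t(sobel_y)
laplacian_k <- matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3, byrow = TRUE)

#' Score the sharpness of one image plane
#'
#' Focus-measure operators quantify the edge, variation, or texture content
#' of an image; focused planes score higher than defocused ones. Available
#' metrics: `tenengrad` (mean squared Sobel gradient magnitude),
#' `variance_of_laplacian`, `brenner` (mean squared 2-pixel horizontal
#' difference), and `normalized_variance` (variance over mean).
#'
#' @param plane Numeric matrix.
#' @param metric One of `focus_metrics`.
#' @return Non-negative scalar; larger means sharper.
#' @export
focus_score <- function(plane, metric = "tenengrad") {
  if (!is.matrix(plane) || !length(plane)) stop("plane must be a non-empty matrix")
  plane <- plane * 1.0
  switch(match.arg(metric, focus_metrics),
    tenengrad = {
      gy <- conv2_full_valid(plane, sobel_y)
      gx <- conv2_full_valid(plane, sobel_x)
      mean(gy^2 + gx^2)
    },
    variance_of_laplacian = {
      l <- conv2_full_valid(plane, laplacian_k)
      stats::var(as.vector(l))
    },
    brenner = {
      if (ncol(plane) < 3L) return(0)
      d <- plane[, 3:ncol(plane), drop = FALSE] -
        plane[, 1:(ncol(plane) - 2L), drop = FALSE]
      mean(d^2)
    },
    normalized_variance = {
      m <- mean(plane)
      if (m <= 0) return(0)
      stats::var(as.vector(plane)) / m
    })
}

#' Select the best-focus plane of a z-stack
#'
#' Scores every plane with `metric` and returns the argmax. Ties are broken
#' toward the plane nearest the stack center, then toward the lower index.
#'
#' @param stack Numeric array `(y, x, z)`.
#' @param metric One of `focus_metrics`.
#' @return List with `z` (1-based best plane index) and `scores`
#'   (per-plane score vector).
#' @export
select_best_plane <- function(stack, metric = "tenengrad") {
  nz <- dim(stack)[3]
  scores <- vapply(seq_len(nz), function(z) focus_score(stack[, , z], metric),
                   numeric(1))
  best <- max(scores)
  cand <- which(scores >= best - abs(best) * 1e-12)
  center <- (nz + 1) / 2
  cand <- cand[order(abs(cand - center), cand)]
  list(z = cand[1L], scores = scores)
}

#' Score focus for every tile, channel and cycle of a region
#'
#' Runs [select_best_plane()] independently for every (tile, channel,
#' cycle) address so that axial focus drift over the course of a multicycle
#' acquisition is compensated per address rather than inherited from a
#' single predefined cycle.
#'
#' @param root Experiment root.
#' @param layout An [experiment_layout()].
#' @param region Region index.
#' @param cycles Cycles to score (default all).
#' @param metric One of `focus_metrics`.
#' @return A `focus_selection` data frame: tile, channel, cycle, `z`
#'   (chosen plane), and one `score_z<k>` column per plane.
#' @export
select_focus_region <- function(root, layout, region = 1L,
                                cycles = seq_len(layout$n_cycles),
                                metric = "tenengrad") {
  rows <- list()
  for (cycle in cycles) for (tile in seq_len(n_tiles(layout)))
    for (channel in seq_along(layout$channels)) {
      stack <- read_tile(root, layout, region, cycle, tile, channel)
      sel <- select_best_plane(stack, metric)
      rows[[length(rows) + 1L]] <- c(tile = tile, channel = channel,
                                     cycle = cycle, z = sel$z, sel$scores)
    }
  df <- as.data.frame(do.call(rbind, rows))
  names(df) <- c("tile", "channel", "cycle", "z",
                 paste0("score_z", seq_len(layout$n_z)))
  df$metric <- metric
  class(df) <- c("focus_selection", "data.frame")
  df
}

#' Per-address focal plane assignment
#'
#' Validates that a focus selection covers every (tile, channel, cycle)
#' address of the layout and returns the plane assignment map. Each address
#' keeps its own independently selected best plane; no index is inherited
#' from the reference cycle.
#'
#' @param selection A `focus_selection` from [select_focus_region()].
#' @param layout An [experiment_layout()].
#' @param cycles Cycles the assignment must cover (default all).
#' @return Data frame (tile, channel, cycle, z).
#' @export
compensate_axial <- function(selection, layout,
                             cycles = seq_len(layout$n_cycles)) {
  need <- expand.grid(tile = seq_len(n_tiles(layout)),
                      channel = seq_along(layout$channels),
                      cycle = cycles)
  key <- function(d) paste(d$tile, d$channel, d$cycle)
  missing <- !(key(need) %in% key(selection))
  if (any(missing))
    stop("incomplete selection: ", sum(missing), " address(es) unscored")
  out <- merge(need, selection[, c("tile", "channel", "cycle", "z")],
               by = c("tile", "channel", "cycle"), sort = TRUE)
  if (any(out$z < 1L | out$z > layout$n_z))
    stop("focal plane index out of range")
  out
}

#' Write focus diagnostics to CSV
#' @param selection A `focus_selection`.
#' @param path Destination CSV path.
#' @return `path`, invisibly.
#' @export
write_focus_csv <- function(selection, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(as.data.frame(selection), path, row.names = FALSE)
  invisible(path)
}
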