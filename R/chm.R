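#' Color histogram of a block
#'
#' Per-channel counts of the block's pixels over `n_bins` equal-width bins
#' spanning `[0, 255]`, L1-normalized per channel (each channel's bins sum
#' to 1). Grayscale sources simply yield three identical channels.
#'
#' @param img `H x W x 3` RGB array on the `[0, 255]` scale.
#' @param origin_row,origin_col 0-based origin of the block window.
#' @param B Block side length.
#' @param n_bins Bins per channel (default 32, at least 2).
#' @return `n_bins x 3` matrix of class `chm_histogram`; columns are the R,
#'   G, B channels.
#' @export
color_histogram <- function(img, origin_row, origin_col, B = 8L,
                            n_bins = 32L) {
  validate_rgb_image(img)
  n_bins <- as.integer(n_bins)
  if (n_bins < 2L) stop("'n_bins' must be at least 2", call. = FALSE)
  B <- as.integer(B)
  if (origin_row < 0 || origin_col < 0 ||
      origin_row > dim(img)[1] - B || origin_col > dim(img)[2] - B)
    stop("block window falls outside the image", call. = FALSE)
  block_histogram(img, origin_row, origin_col, B, n_bins)
}

# color_histogram without the whole-image validation; the inner loop of
# expand_regions calls this thousands of times.
block_histogram <- function(img, origin_row, origin_col, B, n_bins) {
  rows <- origin_row + seq_len(B)
  cols <- origin_col + seq_len(B)
  h <- vapply(1:3, function(ch) {
    v <- img[rows, cols, ch]
    bin <- pmin(floor(v * n_bins / 256), n_bins - 1L) + 1L
    tabulate(bin, nbins = n_bins) / (B * B)
  }, numeric(n_bins))
  structure(h, class = "chm_histogram", n_bins = n_bins)
}

#' Euclidean distance between two block histograms
#'
#' The Euclidean norm of the difference of the concatenated per-channel bin
#' vectors. A metric: non-negative, symmetric, zero iff the histograms are
#' equal, and satisfying the triangle inequality.
#'
#' @param h1,h2 Histograms from [color_histogram()] with the same bin
#'   layout.
#' @return Non-negative real distance.
#' @export
histogram_distance <- function(h1, h2) {
  if (!identical(dim(h1), dim(h2)))
    stop("histograms have different bin layouts", call. = FALSE)
  sqrt(sum((unclass(h1) - unclass(h2))^2))
}

#' Eight-connected neighbor blocks of a block
#'
#' Neighbors sit one block-size step away at the eight compass angles (45,
#' 90, ..., 360 degrees; 90 = up, 45 = up-right, 360 = right, listed
#' counterclockwise), i.e. at origin offsets `(+/-B, 0)`, `(0, +/-B)`,
#' `(+/-B, +/-B)`. Neighbors whose window would leave the image are omitted.
#'
#' @param origin_row,origin_col 0-based origin of the center block.
#' @param H,W Image dimensions in pixels.
#' @param B Block side length.
#' @return `data.frame` with columns `angle`, `origin_row`, `origin_col`,
#'   at most 8 rows, in descending-angle-priority order
#'   (45, 90, 135, 180, 225, 270, 315, 360).
#' @export
neighbor_blocks <- function(origin_row, origin_col, H, W, B = 8L) {
  B <- as.integer(B)
  ang <- c(45L, 90L, 135L, 180L, 225L, 270L, 315L, 360L)
  dr <- c(-B, -B, -B, 0L, B, B, B, 0L)
  dc <- c(B, 0L, -B, -B, -B, 0L, B, B)
  r <- origin_row + dr
  c <- origin_col + dc
  keep <- r >= 0L & c >= 0L & r <= H - B & c <= W - B
  data.frame(angle = ang[keep], origin_row = r[keep], origin_col = c[keep])
}

#' Expand suspected blocks into full forged regions
#'
#' Region growing over the block lattice. Seed blocks are the grid blocks
#' whose window is at least half covered by suspected pixels of the
#' binarized map; they are processed in descending keypoint-count order
#' (ties by row-major origin). For each frontier block, the color histograms
#' of its in-image neighbors are compared with the block's own histogram and
#' the single minimum-distance neighbor is annexed if its distance does not
#' exceed `distance_threshold`; annexed blocks join the next frontier.
#' Expansion stops when a frontier empties or after `max_rounds` frontier
#' passes. The output mask always contains the input's suspected pixels.
#'
#' @param img `H x W x 3` RGB array on the `[0, 255]` scale.
#' @param suspicion A `suspicion_map` from [run_eom()] (or any list with a
#'   binarized 0/1 matrix in `$binarized`).
#' @param grid The `block_grid` with keypoint counts.
#' @param distance_threshold Maximum histogram distance for annexation
#'   (default 0.1 on L1-normalized histograms).
#' @param max_rounds Maximum frontier passes (default 50).
#' @param n_bins Histogram bins per channel (default 32).
#' @return Integer 0/1 forgery mask (`H x W`).
#' @export
expand_regions <- function(img, suspicion, grid, distance_threshold = 0.1,
                           max_rounds = 50L, n_bins = 32L) {
  validate_rgb_image(img)
  stopifnot(inherits(grid, "block_grid"))
  if (distance_threshold < 0)
    stop("'distance_threshold' must be non-negative", call. = FALSE)
  bin <- validate_mask(suspicion$binarized)
  H <- grid$H; W <- grid$W; B <- grid$B
  if (!identical(dim(bin), c(H, W)))
    stop("suspicion map and grid dimensions differ", call. = FALSE)
  mask <- bin
  cover <- window_count(bin, B)
  seeds <- which(cover >= (B * B) / 2)                 # column-major grid pos
  if (length(seeds) == 0L) return(mask)
  sr <- (seeds - 1L) %% grid$n_rows                    # 0-based origins
  sc <- (seeds - 1L) %/% grid$n_rows
  in_region <- matrix(FALSE, grid$n_rows, grid$n_cols)
  in_region[seeds] <- TRUE
  hist_cache <- new.env(parent = emptyenv())
  hist_of <- function(r0, c0) {
    key <- sprintf("%d_%d", r0, c0)
    h <- hist_cache[[key]]
    if (is.null(h)) {
      h <- block_histogram(img, r0, c0, B, n_bins)
      hist_cache[[key]] <- h
    }
    h
  }
  order_frontier <- function(r0, c0) {
    kp <- grid$kp[cbind(r0 + 1L, c0 + 1L)]
    order(-kp, r0, c0)
  }
  ord <- order_frontier(sr, sc)
  frontier <- cbind(sr, sc)[ord, , drop = FALSE]
  for (round in seq_len(max_rounds)) {
    nr0 <- integer(0); nc0 <- integer(0)
    for (k in seq_len(nrow(frontier))) {
      r0 <- frontier[k, 1L]; c0 <- frontier[k, 2L]
      nb <- neighbor_blocks(r0, c0, H, W, B)
      if (nrow(nb) == 0L) next
      h0 <- hist_of(r0, c0)
      d <- vapply(seq_len(nrow(nb)), function(i)
        histogram_distance(h0, hist_of(nb$origin_row[i], nb$origin_col[i])),
        numeric(1))
      best <- which.min(d)                             # first wins on ties
      if (d[best] > distance_threshold) next
      br <- nb$origin_row[best]; bc <- nb$origin_col[best]
      if (in_region[br + 1L, bc + 1L]) next
      in_region[br + 1L, bc + 1L] <- TRUE
      mask[br + seq_len(B), bc + seq_len(B)] <- 1L
      nr0 <- c(nr0, br); nc0 <- c(nc0, bc)
    }
    if (length(nr0) == 0L) break
    ord <- order_frontier(nr0, nc0)
    frontier <- cbind(nr0, nc0)[ord, , drop = FALSE]
  }
  mask
}

#' Morphological closing of a binary mask with a disk
#'
#' Dilation followed by erosion with a disk structuring element (pixels
#' within Euclidean distance `radius` of the center). The mask is padded
#' before the operations so that closing behaves as on an unbounded plane;
#' closing is therefore extensive (never removes mask pixels) and
#' idempotent.
#'
#' @param mask Binary 0/1 matrix.
#' @param radius Disk radius in pixels (default 5, at least 1).
#' @return Closed 0/1 integer mask of the same dimensions.
#' @export
morphological_close <- function(mask, radius = 5L) {
  mask <- validate_mask(mask)
  radius <- as.integer(radius)
  if (radius < 1L) stop("'radius' must be at least 1", call. = FALSE)
  kern <- disk_kernel(radius)
  H <- nrow(mask); W <- ncol(mask)
  pad <- matrix(0, H + 2L * radius, W + 2L * radius)
  pad[radius + seq_len(H), radius + seq_len(W)] <- mask
  closed <- EBImage::erode(EBImage::dilate(pad, kern), kern)
  out <- matrix(as.integer(closed[radius + seq_len(H), radius + seq_len(W)]),
                H, W)
  out
}

# Disk structuring element: 1 where x^2 + y^2 <= radius^2.
disk_kernel <- function(radius) {
  d <- -radius:radius
  k <- outer(d^2, d^2, "+") <= radius^2
  matrix(as.numeric(k), length(d), length(d))
}
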