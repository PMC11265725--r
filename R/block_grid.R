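#' Decompose a grayscale image into overlapping blocks
#'
#' Slides a `B x B` window over the image with a one-pixel stride, from the
#' top-left corner to the bottom-right, producing `(H-B+1) * (W-B+1)` blocks.
#' Block origins are 0-based `(row, col)` indices of the top-left corner and
#' the block order is row-major. Each block carries the population standard
#' deviation of its grayscale window; keypoint counts are filled in by
#' [assign_keypoints()].
#'
#' @param img Numeric `H x W` grayscale matrix on the `[0, 255]` scale.
#' @param B Block side length in pixels (default 8). Must satisfy
#'   `2 <= B <= min(H, W)`.
#' @return A `block_grid` object: list with `H`, `W`, `B`, `n_rows`
#'   (`H-B+1`), `n_cols` (`W-B+1`), `std` (`n_rows x n_cols` matrix of block
#'   standard deviations, `std[i, j]` for 0-based origin `(i-1, j-1)`), and
#'   `kp` (same shape, keypoint counts; zero until assigned).
#' @export
block_grid <- function(img, B = 8L) {
  validate_gray_image(img)
  B <- as.integer(B)
  H <- nrow(img); W <- ncol(img)
  if (B < 2L) stop("block size B must be at least 2", call. = FALSE)
  if (B > min(H, W))
    stop(sprintf("block size B = %d exceeds image dimensions %d x %d",
                 B, H, W), call. = FALSE)
  nr <- H - B + 1L
  nc <- W - B + 1L
  std <- matrix(block_std_map(img, B), nr, nc)
  structure(
    list(H = H, W = W, B = B, n_rows = nr, n_cols = nc,
         std = std, kp = matrix(0L, nr, nc)),
    class = "block_grid")
}

#' @export
print.block_grid <- function(x, ...) {
  cat(sprintf("block_grid: %d x %d image, B = %d, %d blocks (%d x %d)\n",
              x$H, x$W, x$B, x$n_rows * x$n_cols, x$n_rows, x$n_cols))
  cat(sprintf("  block std range: [%.3f, %.3f]; keypoint-bearing blocks: %d\n",
              min(x$std), max(x$std), sum(x$kp > 0L)))
  invisible(x)
}

#' Number of blocks in a grid
#'
#' @param grid A `block_grid`.
#' @return Integer block count, `(H-B+1) * (W-B+1)`.
#' @export
n_blocks <- function(grid) {
  stopifnot(inherits(grid, "block_grid"))
  grid$n_rows * grid$n_cols
}

# Column-major linear indices of every pixel of the B x B window whose
# 0-based origin is (r0, c0); origins may be vectors.
window_indices <- function(r0, c0, H, B) {
  offs <- as.vector(outer(seq_len(B) - 1L, (seq_len(B) - 1L) * H, "+"))
  base <- c0 * H + r0 + 1L
  outer(offs, base, "+")
}

# Per-block population standard deviation for all blocks, two-pass per block,
# vectorized over chunks of blocks to bound memory.
block_std_map <- function(img, B) {
  H <- nrow(img); W <- ncol(img)
  nr <- H - B + 1L; nc <- W - B + 1L
  n <- nr * nc
  # column-major block enumeration matches the std matrix layout
  r0 <- rep(seq_len(nr) - 1L, times = nc)
  c0 <- rep(seq_len(nc) - 1L, each = nr)
  out <- numeric(n)
  chunk <- 20000L
  for (lo in seq(1L, n, by = chunk)) {
    hi <- min(lo + chunk - 1L, n)
    idx <- window_indices(r0[lo:hi], c0[lo:hi], H, B)
    # index with a plain vector: a 2-column index matrix would be taken as
    # (row, col) pairs
    Wm <- matrix(img[as.vector(idx)], nrow = B * B)
    mu <- colMeans(Wm)
    out[lo:hi] <- sqrt(colMeans(sweep(Wm, 2L, mu)^2))
  }
  out
}

#' Population standard deviation of one block window
#'
#' Computes the standard deviation (divisor `n = B^2`, not `n - 1`) of the
#' grayscale values in the `B x B` window at the given 0-based origin. A
#' constant window yields exactly 0.
#'
#' @param img Numeric grayscale matrix.
#' @param origin_row,origin_col 0-based pixel indices of the window's
#'   top-left corner.
#' @param B Block side length.
#' @return Non-negative real number (at most 127.5 for 8-bit data).
#' @export
block_std <- function(img, origin_row, origin_col, B = 8L) {
  validate_gray_image(img)
  B <- as.integer(B)
  if (origin_row < 0 || origin_col < 0 ||
      origin_row > nrow(img) - B || origin_col > ncol(img) - B)
    stop("block window falls outside the image", call. = FALSE)
  w <- img[origin_row + seq_len(B), origin_col + seq_len(B)]
  mu <- mean(w)
  sqrt(mean((w - mu)^2))
}

#' Candidate blocks for the equilibrium-optimizer matcher
#'
#' Returns the blocks that contain at least one SIFT keypoint (after
#' [assign_keypoints()]), in row-major origin order. These blocks form the
#' particle population of [run_eom()]; keypoint-free blocks never enter the
#' matcher.
#'
#' @param grid A `block_grid` with keypoint counts assigned.
#' @return `data.frame` with columns `origin_row`, `origin_col` (0-based),
#'   `std`, `kp_count`, ordered by `origin_row` then `origin_col`.
#' @export
candidate_blocks <- function(grid) {
  stopifnot(inherits(grid, "block_grid"))
  sel <- which(grid$kp >= 1L)                   # column-major positions
  i <- (sel - 1L) %% grid$n_rows                # 0-based origin row
  j <- (sel - 1L) %/% grid$n_rows               # 0-based origin col
  ord <- order(i, j)                            # row-major block order
  data.frame(origin_row = i[ord], origin_col = j[ord],
             std = grid$std[sel][ord], kp_count = grid$kp[sel][ord])
}
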