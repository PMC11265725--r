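#' Detect SIFT keypoints on a grayscale image
#'
#' Runs the standard SIFT detector (difference-of-Gaussians extrema with
#' 128-dimensional gradient-histogram descriptors) on the image. Detection is
#' performed by scikit-image's `SIFT` class through a bundled Python helper;
#' the result is deterministic for a fixed image and fixed parameters.
#'
#' Keypoints act purely as suspicion seeds for the block matcher: no
#' descriptor matching (g2NN or otherwise) is performed by this package.
#'
#' @param img Numeric `H x W` grayscale matrix on the `[0, 255]` scale,
#'   at least 16 x 16 (minimum for a scale pyramid).
#' @param contrast_threshold DoG contrast threshold on the `[0, 1]` intensity
#'   scale (default 0.04, divided by the 3 scales per octave internally, the
#'   usual SIFT convention).
#' @param edge_threshold Edge-response (principal-curvature ratio) threshold,
#'   default 10.
#' @param python Python interpreter to invoke; defaults to
#'   `getOption("cmfd.python", "python")`.
#' @return A `keypoint_set`: list with `keypoints` (data.frame `row`, `col`
#'   subpixel 0-based coordinates, `scale`, `orientation` in degrees),
#'   `descriptors` (`n x 128` integer matrix), `H`, `W`.
#' @export
detect_sift <- function(img, contrast_threshold = 0.04, edge_threshold = 10,
                        python = getOption("cmfd.python", "python")) {
  validate_gray_image(img)
  H <- nrow(img); W <- ncol(img)
  if (H < 16L || W < 16L)
    stop("image must be at least 16 x 16 for SIFT's scale pyramid",
         call. = FALSE)
  script <- system.file("python", "sift_keypoints.py", package = "cmfd",
                        mustWork = TRUE)
  bin <- tempfile(fileext = ".f64")
  out <- tempfile(fileext = ".csv")
  on.exit(unlink(c(bin, out)), add = TRUE)
  # row-major float64 on the [0,1] scale, the helper's expected layout
  writeBin(as.double(t(img) / 255), bin, size = 8L)
  res <- suppressWarnings(system2(
    python,
    c(shQuote(script), shQuote(bin), H, W,
      format(contrast_threshold / 3, digits = 17),
      format(edge_threshold, digits = 17), shQuote(out)),
    stdout = TRUE, stderr = TRUE))
  status <- attr(res, "status")
  if (!is.null(status) && status != 0L)
    stop("SIFT helper failed:\n", paste(res, collapse = "\n"), call. = FALSE)
  kp <- utils::read.csv(out, colClasses = "numeric")
  desc <- as.matrix(kp[, grep("^d", names(kp)), drop = FALSE])
  storage.mode(desc) <- "integer"
  structure(
    list(keypoints = kp[, c("row", "col", "scale", "orientation")],
         descriptors = desc, H = H, W = W),
    class = "keypoint_set")
}

#' @export
print.keypoint_set <- function(x, ...) {
  cat(sprintf("keypoint_set: %d keypoints on a %d x %d image\n",
              nrow(x$keypoints), x$H, x$W))
  invisible(x)
}

#' Filter a keypoint set by detection scale
#'
#' Drops keypoints whose detection scale (sigma, in pixels) exceeds
#' `max_scale`. Suspicion seeding works at block granularity: a keypoint
#' detected at a scale far coarser than the block side marks a whole-organ
#' blob rather than block-level detail, and seeding a single 8x8 block with
#' it is noise. The pipeline filters at `max_scale = block_size` by default.
#'
#' @param kps A `keypoint_set`.
#' @param max_scale Maximum detection scale in pixels; `Inf` keeps all.
#' @return The filtered `keypoint_set`.
#' @export
filter_keypoints <- function(kps, max_scale) {
  stopifnot(inherits(kps, "keypoint_set"))
  keep <- kps$keypoints$scale <= max_scale
  kps$keypoints <- kps$keypoints[keep, , drop = FALSE]
  kps$descriptors <- kps$descriptors[keep, , drop = FALSE]
  kps
}

#' Write keypoints to CSV
#'
#' @param kps A `keypoint_set`.
#' @param path Output CSV path (columns `row`, `col`, `scale`,
#'   `orientation`).
#' @return Invisibly, `path`.
#' @export
write_keypoints_csv <- function(kps, path) {
  stopifnot(inherits(kps, "keypoint_set"))
  utils::write.csv(kps$keypoints, path, row.names = FALSE)
  invisible(path)
}

#' Assign keypoints to overlapping blocks as suspicion counts
#'
#' Each keypoint is binned into the integer pixel it falls in (floor of its
#' subpixel coordinates, 0-based); keypoints sharing a pixel are
#' deduplicated. A block's count is the number of distinct keypoint pixels
#' inside its `B x B` window, so every block covering a keypoint pixel is
#' incremented and no count can exceed `B^2`.
#'
#' @param kps A `keypoint_set` from [detect_sift()].
#' @param grid A `block_grid` built from the same image dimensions.
#' @return The grid with its `kp` count matrix filled in.
#' @export
assign_keypoints <- function(kps, grid) {
  stopifnot(inherits(kps, "keypoint_set"), inherits(grid, "block_grid"))
  if (kps$H != grid$H || kps$W != grid$W)
    stop(sprintf(
      "keypoint set (%d x %d) and grid (%d x %d) dimensions differ",
      kps$H, kps$W, grid$H, grid$W), call. = FALSE)
  ind <- matrix(0L, grid$H, grid$W)
  if (nrow(kps$keypoints) > 0L) {
    px <- unique(cbind(floor(kps$keypoints$row), floor(kps$keypoints$col)))
    ind[px + 1L] <- 1L
  }
  grid$kp <- window_count(ind, grid$B)
  grid
}

# Number of marked pixels inside every B x B window, via a padded integral
# image; returns an (H-B+1) x (W-B+1) integer matrix.
window_count <- function(ind, B) {
  H <- nrow(ind); W <- ncol(ind)
  S <- matrix(0L, H + 1L, W + 1L)
  S[-1L, -1L] <- apply(apply(ind, 2L, cumsum), 1L, cumsum) |> t()
  nr <- H - B + 1L; nc <- W - B + 1L
  i <- seq_len(nr); j <- seq_len(nc)
  cnt <- S[i + B, j + B, drop = FALSE] - S[i, j + B, drop = FALSE] -
    S[i + B, j, drop = FALSE] + S[i, j, drop = FALSE]
  storage.mode(cnt) <- "integer"
  cnt
}
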