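#' Generate a synthetic medical-like base image
#'
#' Produces a deterministic (per seed) near-grayscale image emulating a
#' soft-tissue scan: overlapping soft-edged ellipses on a dark background,
#' weak band-limited texture everywhere, and one feature-rich "lesion" — a
#' speckled patch whose fine-grained texture gives the SIFT detector dense
#' seeds and which is the natural target of a copy-move forgery. The
#' lesion's texture fills a soft-edged square aligned with the copy window
#' (rolling off a few pixels inside the window edge), emulating a forger
#' copying a window from within distinctive structure. The window is
#' recorded in the `"lesion"` attribute (`origin`, 0-based, and `size`) so
#' that [make_dataset()] can copy exactly that region. Intensities stay on
#' the dark side of the 8-bit range, as in soft-tissue windows.
#'
#' @param seed RNG seed; the same seed always yields the same image.
#' @param H,W Image dimensions in pixels (at least 64; default 256).
#' @param lesion_size Integer `(h, w)` of the lesion window (default
#'   `c(48, 48)`).
#' @return `H x W x 3` numeric array on the `[0, 255]` scale with a
#'   `"lesion"` attribute.
#' @export
generate_base_image <- function(seed, H = 256L, W = 256L,
                                lesion_size = c(48L, 48L)) {
  H <- as.integer(H); W <- as.integer(W)
  if (H < 64L || W < 64L)
    stop("base image must be at least 64 x 64", call. = FALSE)
  lh <- as.integer(lesion_size[1]); lw <- as.integer(lesion_size[2])
  margin <- 8L
  if (lh + 2L * margin > H || lw + 2L * margin > W)
    stop("lesion does not fit in the image", call. = FALSE)
  with_seed(seed, {
    ys <- matrix(seq_len(H), H, W)
    xs <- matrix(seq_len(W), H, W, byrow = TRUE)
    g <- matrix(18, H, W)
    for (e in seq_len(sample(4:6, 1))) {
      cr <- stats::runif(1, 0.2 * H, 0.8 * H)
      cc <- stats::runif(1, 0.2 * W, 0.8 * W)
      ar <- stats::runif(1, H / 7, H / 3)
      ac <- stats::runif(1, W / 7, W / 3)
      phi <- stats::runif(1, 0, pi)
      amp <- stats::runif(1, 20, 35)
      dy <- ys - cr; dx <- xs - cc
      u <- cos(phi) * dx + sin(phi) * dy
      v <- -sin(phi) * dx + cos(phi) * dy
      q <- (u / ac)^2 + (v / ar)^2
      g <- g + amp * exp(-3 * q)
    }
    g <- pmin(g, 100)
    g <- g + 4 * smooth_noise(H, W, sigma = 1.5)
    # speckled lesion filling a soft-edged square copy window: the texture
    # plateau extends to 78% of the half-size, so it rolls off a few pixels
    # inside the window edge
    r0 <- sample(margin:(H - lh - margin), 1) # 0-based origin
    c0 <- sample(margin:(W - lw - margin), 1)
    cr <- r0 + (lh - 1) / 2; cc <- c0 + (lw - 1) / 2
    qc <- pmax(abs(ys - 1 - cr) / (lh / 2), abs(xs - 1 - cc) / (lw / 2))
    wnd <- 1 / (1 + exp((qc - 0.78) * 40))
    g <- g + wnd * (22 + 45 * smooth_noise(H, W, sigma = 0.9))
    g <- pmin(pmax(g, 0), 124)
    img <- array(0, c(H, W, 3))
    img[, , 1] <- g
    img[, , 2] <- g * 0.985
    img[, , 3] <- g * 0.965
    attr(img, "lesion") <- list(origin = c(r0, c0), size = c(lh, lw))
    img
  })
}

# Band-limited unit-variance noise field: white noise smoothed with a
# Gaussian kernel (replicated edges), then standardized.
smooth_noise <- function(H, W, sigma) {
  n <- matrix(stats::rnorm(H * W), H, W)
  half <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-half:half, sd = sigma)
  k <- k / sum(k)
  pad_conv <- function(m, kern) {
    # convolve columns with replicated edge padding
    hp <- (length(kern) - 1L) / 2L
    mp <- rbind(m[rep(1L, hp), , drop = FALSE], m,
                m[rep(nrow(m), hp), , drop = FALSE])
    out <- apply(mp, 2L, function(col)
      stats::filter(col, kern, sides = 2L))[(hp + 1L):(hp + nrow(m)), ]
    out
  }
  s <- pad_conv(t(pad_conv(n, k)), k)
  s <- t(s)
  (s - mean(s)) / stats::sd(s)
}

#' Specification of a single copy-move forgery
#'
#' @param source_origin 0-based `(row, col)` of the copied window's top-left
#'   corner.
#' @param region_size `(h, w)` of the copied window in pixels.
#' @param dest_origin 0-based `(row, col)` where the copy is pasted.
#' @param rotation Paste rotation in degrees about the window center
#'   (0, 5, 10 or 15 typical).
#' @param noise_sigma Standard deviation of zero-mean Gaussian noise added
#'   to the whole forged image, on the `[0, 1]` intensity scale (so
#'   `noise_sigma * 255` in 8-bit units); 0 disables noise.
#' @param seed RNG seed for the noise draw.
#' @param allow_overlap Allow source and destination windows to overlap
#'   (default `FALSE`; overlapping regions make the ground truth ambiguous).
#' @return A `forgery_spec` list.
#' @export
forgery_spec <- function(source_origin, region_size, dest_origin,
                         rotation = 0, noise_sigma = 0, seed = 1L,
                         allow_overlap = FALSE) {
  spec <- list(source_origin = as.integer(source_origin),
               region_size = as.integer(region_size),
               dest_origin = as.integer(dest_origin),
               rotation = rotation, noise_sigma = noise_sigma,
               seed = as.integer(seed), allow_overlap = isTRUE(allow_overlap))
  if (any(spec$region_size < 1L))
    stop("region size must be positive", call. = FALSE)
  if (noise_sigma < 0) stop("'noise_sigma' must be non-negative", call. = FALSE)
  if (!spec$allow_overlap) {
    s <- spec$source_origin; d <- spec$dest_origin; z <- spec$region_size
    if (s[1] < d[1] + z[1] && d[1] < s[1] + z[1] &&
        s[2] < d[2] + z[2] && d[2] < s[2] + z[2])
      stop("source and destination windows overlap", call. = FALSE)
  }
  structure(spec, class = "forgery_spec")
}

#' Apply a copy-move forgery to an image
#'
#' Copies the source window, rotates it about its center (bilinear
#' interpolation), pastes the full rotated square at the destination (for
#' nonzero rotations the paste extends slightly past the axis-aligned
#' window), and optionally corrupts the whole image with zero-mean Gaussian
#' noise (clipped to `[0, 255]`). The returned ground-truth mask marks both
#' members of the duplicated pair: the axis-aligned source window and the
#' destination pixels whose rotated-window coverage is at least one half
#' (so the pasted area stays within 5% of `h * w` for small rotations).
#'
#' @param img `H x W x 3` array on the `[0, 255]` scale.
#' @param spec A [forgery_spec()].
#' @return List with `image` (forged array) and `mask` (0/1 matrix).
#' @export
apply_copy_move <- function(img, spec) {
  validate_rgb_image(img)
  stopifnot(inherits(spec, "forgery_spec"))
  H <- dim(img)[1]; W <- dim(img)[2]
  s <- spec$source_origin; d <- spec$dest_origin; z <- spec$region_size
  if (any(s < 0L) || any(d < 0L) ||
      s[1] + z[1] > H || s[2] + z[2] > W ||
      d[1] + z[1] > H || d[2] + z[2] > W)
    stop("source or destination window falls outside the image",
         call. = FALSE)
  out <- img
  mask <- matrix(0L, H, W)
  mask[s[1] + seq_len(z[1]), s[2] + seq_len(z[2])] <- 1L
  if (spec$rotation == 0) {
    out[d[1] + seq_len(z[1]), d[2] + seq_len(z[2]), ] <-
      img[s[1] + seq_len(z[1]), s[2] + seq_len(z[2]), ]
    mask[d[1] + seq_len(z[1]), d[2] + seq_len(z[2])] <- 1L
  } else {
    th <- spec$rotation * pi / 180
    # the rotated square extends past the h x w window: work on its
    # enlarged bounding box around the destination center
    ext <- ceiling((z * abs(cos(th)) + rev(z) * abs(sin(th)) - z) / 2) + 1L
    ctr_s <- s + (z - 1) / 2
    gr <- seq(-ext[1] + 1L, z[1] + ext[1]) - 1
    gc <- seq(-ext[2] + 1L, z[2] + ext[2]) - 1
    off_r <- rep(gr, times = length(gc)) - (z[1] - 1) / 2
    off_c <- rep(gc, each = length(gr)) - (z[2] - 1) / 2
    # back-rotate dest offsets into source coordinates (0-based, continuous)
    src_r <- ctr_s[1] + cos(th) * off_r - sin(th) * off_c
    src_c <- ctr_s[2] + sin(th) * off_r + cos(th) * off_c
    ind <- matrix(0, H, W)
    ind[s[1] + seq_len(z[1]), s[2] + seq_len(z[2])] <- 1
    cov <- bilinear_sample(ind, src_r, src_c)
    dst_r <- d[1] + rep(gr, times = length(gc)) + 1
    dst_c <- d[2] + rep(gc, each = length(gr)) + 1
    paste_sel <- cov >= 0.5
    if (any(dst_r[paste_sel] < 1) || any(dst_r[paste_sel] > H) ||
        any(dst_c[paste_sel] < 1) || any(dst_c[paste_sel] > W))
      stop("rotated paste leaves the image; move the destination window inward",
           call. = FALSE)
    if (any(src_r[paste_sel] < 0) || any(src_r[paste_sel] > H - 1) ||
        any(src_c[paste_sel] < 0) || any(src_c[paste_sel] > W - 1))
      stop("rotated source sampling leaves the image; move the source window inward",
           call. = FALSE)
    lin <- cbind(dst_r, dst_c)[paste_sel, , drop = FALSE]
    for (ch in 1:3) {
      vals <- bilinear_sample(img[, , ch], src_r, src_c)
      plane <- out[, , ch]
      plane[lin] <- clip255(vals[paste_sel])
      out[, , ch] <- plane
    }
    mask[lin] <- 1L
  }
  if (spec$noise_sigma > 0) {
    noise <- with_seed(spec$seed,
                       matrix(stats::rnorm(H * W, sd = spec$noise_sigma * 255),
                              H, W))
    for (ch in 1:3) out[, , ch] <- clip255(out[, , ch] + noise)
  }
  list(image = out, mask = mask)
}

# Bilinear interpolation of matrix m at continuous 0-based points (r, c),
# clamped to the image bounds.
bilinear_sample <- function(m, r, c) {
  H <- nrow(m); W <- ncol(m)
  r <- pmin(pmax(r, 0), H - 1)
  c <- pmin(pmax(c, 0), W - 1)
  r0 <- pmin(floor(r), H - 2); c0 <- pmin(floor(c), W - 2)
  fr <- r - r0; fc <- c - c0
  i00 <- cbind(r0 + 1, c0 + 1)
  m[i00] * (1 - fr) * (1 - fc) +
    m[cbind(r0 + 2, c0 + 1)] * fr * (1 - fc) +
    m[cbind(r0 + 1, c0 + 2)] * (1 - fr) * fc +
    m[cbind(r0 + 2, c0 + 2)] * fr * fc
}

#' Generate a synthetic copy-move forgery dataset with ground truth
#'
#' Writes `n_per_category` original images and, for each original, one
#' forged image per category — `simple` (plain paste), `rot5`/`rot10`/
#' `rot15` (paste rotated by 5/10/15 degrees) and `noise` (plain paste plus
#' global Gaussian noise with `noise_sigma = 0.1`) — together with exact
#' ground-truth masks and a CSV manifest. Copy-window sides are drawn
#' uniformly from `[32, 64]` pixels. Fully reproducible per seed.
#'
#' @param out_dir Output directory (created if missing).
#' @param n_per_category Number of originals (each spawns 5 forgeries).
#' @param base_size Image side length in pixels (default 256).
#' @param seed Master RNG seed.
#' @param noise_sigma Noise level of the `noise` category on the `[0, 1]`
#'   scale (default 0.1).
#' @return Invisibly, the manifest `data.frame`; the manifest is written to
#'   `file.path(out_dir, "manifest.csv")` with image paths relative to
#'   `out_dir`.
#' @export
make_dataset <- function(out_dir, n_per_category = 2L, base_size = 256L,
                         seed = 1L, noise_sigma = 0.1) {
  if (n_per_category < 1L)
    stop("'n_per_category' must be at least 1", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir))
    stop(sprintf("cannot create output directory '%s'", out_dir),
         call. = FALSE)
  H <- W <- as.integer(base_size)
  n <- as.integer(n_per_category)
  seeds <- derive_seeds(seed, 2L * n)
  cats <- c(simple = 0, rot5 = 5, rot10 = 10, rot15 = 15, noise = 0)
  # cap the copy-window side so that a disjoint destination always exists
  side_max <- min(64L, (H - 16L) %/% 3L)
  if (side_max < 32L)
    stop("base_size too small for 32-pixel copy windows", call. = FALSE)
  rows <- list()
  for (k in seq_len(n)) {
    sk <- seeds[k]
    side <- with_seed(seeds[n + k],
                      32L + sample.int(side_max - 31L, 2, replace = TRUE) - 1L)
    base <- generate_base_image(sk, H, W, lesion_size = side)
    les <- attr(base, "lesion")
    orig_name <- sprintf("original_%03d.png", k)
    png::writePNG(base / 255, file.path(out_dir, orig_name))
    rows[[length(rows) + 1L]] <- data.frame(
      path = orig_name, category = "original", mask_path = "",
      src_row = NA, src_col = NA, h = NA, w = NA,
      dst_row = NA, dst_col = NA, rotation = NA, noise_sigma = NA, seed = sk)
    for (ci in seq_along(cats)) {
      cat_name <- names(cats)[ci]
      fseed <- (sk + ci) %% .Machine$integer.max
      # margin 10: a 15-degree rotated paste of a 64-wide window can extend
      # 9 pixels past its axis-aligned bounding box
      dst <- with_seed(fseed,
                       sample_disjoint_dest(H, W, les$origin, les$size,
                                            margin = 10L))
      spec <- forgery_spec(
        source_origin = les$origin, region_size = les$size,
        dest_origin = dst, rotation = cats[[ci]],
        noise_sigma = if (cat_name == "noise") noise_sigma else 0,
        seed = fseed)
      fk <- apply_copy_move(base, spec)
      img_name <- sprintf("%s_%03d.png", cat_name, k)
      msk_name <- sprintf("%s_%03d_mask.png", cat_name, k)
      png::writePNG(fk$image / 255, file.path(out_dir, img_name))
      write_mask(fk$mask, file.path(out_dir, msk_name))
      rows[[length(rows) + 1L]] <- data.frame(
        path = img_name, category = cat_name, mask_path = msk_name,
        src_row = les$origin[1], src_col = les$origin[2],
        h = les$size[1], w = les$size[2],
        dst_row = dst[1], dst_col = dst[2], rotation = cats[[ci]],
        noise_sigma = if (cat_name == "noise") noise_sigma else 0,
        seed = fseed)
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

# Draw a destination origin whose window neither overlaps the source window
# nor leaves an 8-pixel border margin.
sample_disjoint_dest <- function(H, W, src, size, margin = 8L) {
  for (try in 1:200) {
    d <- c(sample(margin:(H - size[1] - margin), 1),
           sample(margin:(W - size[2] - margin), 1))
    overlap <- src[1] < d[1] + size[1] && d[1] < src[1] + size[1] &&
      src[2] < d[2] + size[2] && d[2] < src[2] + size[2]
    if (!overlap) return(d)
  }
  stop("could not place a disjoint destination window", call. = FALSE)
}
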