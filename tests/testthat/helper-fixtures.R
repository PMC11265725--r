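# Shared fixtures, built in code at test time.

# Small deterministic RGB array on the [0,255] scale.
fixture_rgb <- function(H = 24, W = 24, seed = 42) {
  cmfd:::with_seed(seed, array(stats::runif(H * W * 3, 0, 255), c(H, W, 3)))
}

# Deterministic grayscale matrix.
fixture_gray <- function(H = 24, W = 24, seed = 42) {
  cmfd:::with_seed(seed, matrix(stats::runif(H * W, 0, 255), H, W))
}

# A plain copy-move forgery fixture with its grayscale image, keypoint-backed
# grid and ground truth; cached per (seed, size) within a test run.
fixture_forgery_env <- new.env(parent = emptyenv())
fixture_forgery <- function(seed = 1, size = 256, rotation = 0,
                            region = c(48L, 48L)) {
  key <- paste(seed, size, rotation, paste(region, collapse = "x"), sep = "_")
  got <- fixture_forgery_env[[key]]
  if (!is.null(got)) return(got)
  base <- generate_base_image(seed, size, size, lesion_size = region)
  les <- attr(base, "lesion")
  dst <- cmfd:::with_seed(seed + 500,
                          cmfd:::sample_disjoint_dest(size, size, les$origin,
                                                      les$size))
  fk <- apply_copy_move(base, forgery_spec(les$origin, les$size, dst,
                                           rotation = rotation))
  gray <- to_gray(fk$image)
  out <- list(image = fk$image, mask = fk$mask, gray = gray,
              src = les$origin, dst = dst, region = les$size)
  fixture_forgery_env[[key]] <- out
  out
}

# The same fixture with SIFT keypoints assigned to the block grid (slow, so
# cached as well).
fixture_forgery_grid <- function(seed = 1, size = 256, rotation = 0) {
  key <- paste("grid", seed, size, rotation, sep = "_")
  got <- fixture_forgery_env[[key]]
  if (!is.null(got)) return(got)
  fx <- fixture_forgery(seed, size, rotation)
  kps <- detect_sift(fx$gray)
  fx$grid <- assign_keypoints(kps, block_grid(fx$gray, 8))
  fx$kps <- kps
  fixture_forgery_env[[key]] <- fx
  fx
}
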