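#' Detect copy-move forgery in an image
#'
#' Runs the full three-stage pipeline: grayscale conversion, SIFT keypoint
#' seeding, overlapping block decomposition, equilibrium-optimizer block
#' re-weighting, color-histogram region expansion, and morphological
#' closing. Returns the localization mask and the image-level verdict.
#'
#' @param img Path to an image file, or an `H x W x 3` array on the
#'   `[0, 255]` scale.
#' @param config A [run_config()].
#' @param verbose Log per-stage progress to standard error.
#' @return List of class `cmfd_detection` with `mask` (0/1 matrix),
#'   `verdict` (`"forged"`/`"original"`), `suspicion` (the EOM map),
#'   `n_keypoints`, `n_candidates`, and `timings` (seconds per stage).
#' @export
detect_forgery <- function(img, config = run_config(), verbose = FALSE) {
  if (is.character(img)) img <- read_image(img)
  validate_rgb_image(img)
  stopifnot(inherits(config, "run_config"))
  say <- function(fmt, ...) if (verbose) message(sprintf(fmt, ...))
  tick <- function() proc.time()[["elapsed"]]
  timings <- c()
  t0 <- tick()
  gray <- to_gray(img, variant = config$gray_variant)
  say("grayscale: %d x %d (variant %s)", nrow(gray), ncol(gray),
      config$gray_variant)
  kps <- detect_sift(gray, contrast_threshold = config$contrast_threshold,
                     edge_threshold = config$edge_threshold)
  n_detected <- nrow(kps$keypoints)
  kps <- filter_keypoints(kps, max_scale = config$sift_max_scale)
  timings["sift"] <- tick() - t0; t0 <- tick()
  say("sift: %d keypoints, %d kept at scale <= %.3g (contrast %.3g, edge %.3g)",
      n_detected, nrow(kps$keypoints), config$sift_max_scale,
      config$contrast_threshold, config$edge_threshold)
  grid <- block_grid(gray, B = config$block_size)
  grid <- assign_keypoints(kps, grid)
  timings["blocks"] <- tick() - t0; t0 <- tick()
  say("blocks: %d total, %d candidates (B = %d)", n_blocks(grid),
      sum(grid$kp > 0L), config$block_size)
  params <- eom_params(a1 = config$a1, a2 = config$a2, gp = config$gp,
                       max_iter = config$max_iter,
                       lambda_floor = config$lambda_floor,
                       seed = config$seed, threshold = config$threshold,
                       f_variant = config$f_variant,
                       member_rule = config$member_rule)
  susp <- run_eom(gray, grid, params)
  timings["eom"] <- tick() - t0; t0 <- tick()
  say("eom: %d candidates, %d suspected pixels (seed %d, max_iter %d)",
      susp$n_candidates, sum(susp$binarized), config$seed, config$max_iter)
  mask <- expand_regions(img, susp, grid,
                         distance_threshold = config$distance_threshold,
                         max_rounds = config$max_rounds,
                         n_bins = config$n_bins)
  mask <- morphological_close(mask, radius = config$closing_radius)
  timings["chm"] <- tick() - t0
  verdict <- image_verdict(mask, min_region_pixels = config$min_region_pixels)
  say("chm: %d mask pixels after closing (radius %d); verdict: %s",
      sum(mask), config$closing_radius, verdict)
  structure(
    list(mask = mask, verdict = verdict, suspicion = susp,
         n_keypoints = nrow(kps$keypoints),
         n_candidates = susp$n_candidates, timings = timings),
    class = "cmfd_detection")
}

#' @export
print.cmfd_detection <- function(x, ...) {
  cat(sprintf(
    "cmfd_detection: verdict %s; %d keypoints, %d candidate blocks, %d mask pixels\n",
    x$verdict, x$n_keypoints, x$n_candidates, sum(x$mask)))
  invisible(x)
}

#' Evaluate predicted masks against a dataset manifest
#'
#' For every manifest entry, loads the predicted mask, compares it with the
#' ground truth (an all-zero truth for originals), and accumulates pixel-
#' and image-level confusion counts. Produces per-image rows and the
#' Table-style per-category summary of [dataset_report()].
#'
#' @param manifest Manifest `data.frame` from [make_dataset()] (or the path
#'   of a manifest CSV).
#' @param predictions_dir Directory containing one predicted mask per
#'   manifest image, named `<image stem>_pred.png`.
#' @param data_dir Directory holding the dataset images/masks; defaults to
#'   the manifest's directory when `manifest` is a path.
#' @param min_region_pixels Image-verdict threshold (default 64).
#' @return List with `per_image` (data.frame), `pixel_summary` and
#'   `image_summary` (category tables from [dataset_report()]).
#' @export
evaluate_dataset <- function(manifest, predictions_dir, data_dir = NULL,
                             min_region_pixels = 64L) {
  if (is.character(manifest)) {
    if (is.null(data_dir)) data_dir <- dirname(manifest)
    manifest <- utils::read.csv(manifest)
  }
  if (is.null(data_dir)) data_dir <- "."
  pix <- list(); im <- list()
  for (i in seq_len(nrow(manifest))) {
    entry <- manifest[i, ]
    stem <- tools::file_path_sans_ext(entry$path)
    pred_path <- file.path(predictions_dir, paste0(stem, "_pred.png"))
    if (!file.exists(pred_path))
      stop(sprintf("missing prediction for manifest entry '%s' (expected '%s')",
                   entry$path, pred_path), call. = FALSE)
    pred <- read_mask(pred_path)
    truth <- if (nzchar(entry$mask_path) && !is.na(entry$mask_path))
      read_mask(file.path(data_dir, entry$mask_path))
    else matrix(0L, nrow(pred), ncol(pred))
    if (!identical(dim(pred), dim(truth)))
      stop(sprintf("prediction and truth dimensions differ for '%s'",
                   entry$path), call. = FALSE)
    cc <- confusion_counts(pred, truth)
    sc <- detection_scores(cc)
    pix[[i]] <- data.frame(
      path = entry$path, category = entry$category, level = "pixel",
      A1 = cc$A1, B1 = cc$B1, A2 = cc$A2, B2 = cc$B2,
      precision = sc$precision, recall = sc$recall, f1 = sc$f1,
      sensitivity = sc$sensitivity, specificity = sc$specificity)
    pred_lab <- image_verdict(pred, min_region_pixels) == "forged"
    true_lab <- sum(truth) > 0L
    im[[i]] <- data.frame(
      category = entry$category,
      A1 = as.integer(pred_lab && true_lab),
      B1 = as.integer(!pred_lab && true_lab),
      A2 = as.integer(!pred_lab && !true_lab),
      B2 = as.integer(pred_lab && !true_lab))
  }
  per_image <- do.call(rbind, pix)
  image_counts <- do.call(rbind, im)
  pixel_counts <- per_image[, c("category", "A1", "B1", "A2", "B2")]
  list(per_image = per_image,
       pixel_summary = dataset_report(pixel_counts),
       image_summary = dataset_report(image_counts))
}
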