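#' Confusion counts between predicted and true forgery labels
#'
#' Works at image level (vectors of binary verdicts) or pixel level (pairs
#' of masks). The positive class is "forged": `A1` true positives, `B1`
#' false negatives, `A2` true negatives, `B2` false positives.
#'
#' @param predicted Binary labels or 0/1 mask.
#' @param truth Same shape as `predicted`.
#' @return A `confusion_counts` list with integer fields `A1`, `B1`, `A2`,
#'   `B2`.
#' @export
confusion_counts <- function(predicted, truth) {
  if (!identical(dim(predicted), dim(truth)) ||
      length(predicted) != length(truth))
    stop("'predicted' and 'truth' must have identical shape", call. = FALSE)
  p <- as.logical(predicted)
  t <- as.logical(truth)
  if (anyNA(p) || anyNA(t))
    stop("labels must be binary with no missing values", call. = FALSE)
  structure(list(A1 = sum(p & t), B1 = sum(!p & t),
                 A2 = sum(!p & !t), B2 = sum(p & !t)),
            class = "confusion_counts")
}

#' Detection scores from confusion counts
#'
#' Computes the five-metric family as percentages: sensitivity = recall =
#' `A1 / (A1 + B1)`, specificity = `A2 / (A2 + B2)`, precision =
#' `A1 / (A1 + B2)`, and `F1 = 2 P R / (P + R)`. Ratios with a zero
#' denominator are undefined and reported as `NA` (never silently as 0), so
#' they drop out of downstream averages.
#'
#' @param counts A `confusion_counts` object, or a list with fields `A1`,
#'   `B1`, `A2`, `B2`.
#' @return A `detection_report` list: the counts plus `precision`, `recall`,
#'   `f1`, `sensitivity`, `specificity` in `[0, 100]` or `NA`.
#' @export
detection_scores <- function(counts) {
  A1 <- counts$A1; B1 <- counts$B1; A2 <- counts$A2; B2 <- counts$B2
  if (any(c(A1, B1, A2, B2) < 0)) stop("counts must be non-negative")
  if (A1 + B1 + A2 + B2 == 0)
    stop("cannot score an empty set of items", call. = FALSE)
  ratio <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  precision <- ratio(A1, A1 + B2)
  recall <- ratio(A1, A1 + B1)
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0)
    NA_real_ else 2 * precision * recall / (precision + recall)
  structure(list(A1 = A1, B1 = B1, A2 = A2, B2 = B2,
                 precision = precision, recall = recall, f1 = f1,
                 sensitivity = recall, specificity = ratio(A2, A2 + B2)),
            class = "detection_report")
}

#' @export
print.detection_report <- function(x, ...) {
  cat(sprintf("detection_report: A1=%d B1=%d A2=%d B2=%d\n",
              x$A1, x$B1, x$A2, x$B2))
  cat(sprintf(
    "  precision %.2f  recall %.2f  F1 %.2f  sensitivity %.2f  specificity %.2f\n",
    x$precision, x$recall, x$f1, x$sensitivity, x$specificity))
  invisible(x)
}

#' Image-level verdict from a localization mask
#'
#' An image is declared forged when its mask contains at least one
#' 8-connected component of at least `min_region_pixels` pixels; scattered
#' smaller responses count as authentic.
#'
#' @param mask Binary 0/1 mask.
#' @param min_region_pixels Minimum component size (default 64, one full
#'   8 x 8 block).
#' @return `"forged"` or `"original"`.
#' @export
image_verdict <- function(mask, min_region_pixels = 64L) {
  mask <- validate_mask(mask)
  if (sum(mask) < min_region_pixels) return("original")
  sizes <- component_sizes(mask)
  if (length(sizes) && max(sizes) >= min_region_pixels) "forged" else "original"
}

# Sizes of the 8-connected components of a binary mask. EBImage's bwlabel is
# 4-connected, so labels touching diagonally are merged with a union-find
# pass over the four diagonal shift directions.
component_sizes <- function(mask) {
  lab <- EBImage::bwlabel(mask)
  lab <- matrix(as.integer(lab), nrow(lab), ncol(lab))
  n <- max(lab)
  if (n == 0L) return(integer(0))
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  H <- nrow(lab); W <- ncol(lab)
  a <- lab[-H, -W]; b <- lab[-1, -1]          # down-right diagonal pairs
  pairs <- rbind(cbind(a[a > 0L & b > 0L], b[a > 0L & b > 0L]),
                 {a2 <- lab[-1, -W]; b2 <- lab[-H, -1]  # up-right diagonal
                  cbind(a2[a2 > 0L & b2 > 0L], b2[a2 > 0L & b2 > 0L])})
  pairs <- unique(pairs[pairs[, 1] != pairs[, 2], , drop = FALSE])
  for (k in seq_len(nrow(pairs))) {
    ra <- find(pairs[k, 1]); rb <- find(pairs[k, 2])
    if (ra != rb) parent[rb] <- ra
  }
  roots <- vapply(seq_len(n), find, integer(1))
  raw <- tabulate(lab[lab > 0L], nbins = n)
  as.integer(tapply(raw, roots, sum))
}

#' Per-category evaluation table with an average row
#'
#' Aggregates per-image confusion counts by forgery category, scores each
#' category ([detection_scores()]), and appends an unweighted "Average" row:
#' the arithmetic mean of the defined category values, computed at full
#' precision and then truncated (not rounded) to two decimals, the printed
#' convention of forgery-detection result tables.
#'
#' @param counts_df `data.frame` with columns `category`, `A1`, `B1`, `A2`,
#'   `B2` (one row per image, or already per category).
#' @return `data.frame` with one row per category plus the `Average` row and
#'   columns `category`, `precision`, `recall`, `f1`, `specificity`,
#'   `sensitivity`.
#' @export
dataset_report <- function(counts_df) {
  need <- c("category", "A1", "B1", "A2", "B2")
  if (!is.data.frame(counts_df) || !all(need %in% names(counts_df)) ||
      nrow(counts_df) == 0L)
    stop("'counts_df' must have rows and columns category, A1, B1, A2, B2",
         call. = FALSE)
  cats <- unique(counts_df$category)
  metric_cols <- c("precision", "recall", "f1", "specificity", "sensitivity")
  rows <- lapply(cats, function(cat) {
    sub <- counts_df[counts_df$category == cat, , drop = FALSE]
    sc <- detection_scores(list(A1 = sum(sub$A1), B1 = sum(sub$B1),
                                A2 = sum(sub$A2), B2 = sum(sub$B2)))
    data.frame(category = cat, precision = sc$precision, recall = sc$recall,
               f1 = sc$f1, specificity = sc$specificity,
               sensitivity = sc$sensitivity)
  })
  tab <- do.call(rbind, rows)
  avg <- vapply(metric_cols, function(cl)
    trunc2(mean(tab[[cl]], na.rm = TRUE)), numeric(1))
  rbind(tab, data.frame(category = "Average", as.list(avg)))
}

# Truncate (toward zero) to two decimals, the table-printing convention.
trunc2 <- function(x) trunc(x * 100) / 100
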