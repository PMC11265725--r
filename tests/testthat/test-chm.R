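test_that("block color histograms are L1-normalized per channel and deterministic", {
  img <- fixture_rgb(20, 20, seed = 31)
  h <- color_histogram(img, 2, 3, B = 8, n_bins = 32)
  expect_equal(dim(unclass(h)), c(32L, 3L))
  expect_equal(colSums(unclass(h)), rep(1, 3), tolerance = 1e-9)
  expect_true(all(unclass(h) >= 0))

  flat <- array(0, c(12, 12, 3))
  flat[, , 1] <- 10; flat[, , 2] <- 100; flat[, , 3] <- 250
  hf <- color_histogram(flat, 0, 0, B = 8, n_bins = 32)
  expect_equal(apply(unclass(hf), 2, max), rep(1, 3))   # one-hot per channel

  expect_identical(color_histogram(img, 2, 3, 8, 32),
                   color_histogram(img, 2, 3, 8, 32))
  expect_error(color_histogram(img, 15, 15, 8, 32), "outside")
})

test_that("histogram distance is a metric with the forced one-hot value", {
  img <- fixture_rgb(20, 20, seed = 32)
  h1 <- color_histogram(img, 0, 0, 8, 16)
  expect_equal(histogram_distance(h1, h1), 0)

  # two one-hot histograms in different bins of one channel: sqrt(2)
  a <- array(0, c(10, 10, 3)); a[, , 1] <- 5;   a[, , 2] <- 5;  a[, , 3] <- 5
  b <- array(0, c(10, 10, 3)); b[, , 1] <- 250; b[, , 2] <- 5;  b[, , 3] <- 5
  ha <- color_histogram(a, 0, 0, 8, 16)
  hb <- color_histogram(b, 0, 0, 8, 16)
  expect_equal(histogram_distance(ha, hb), sqrt(2))

  cmfd:::with_seed(33, for (k in 1:10) {
    o <- cbind(sample(0:12, 3, replace = TRUE), sample(0:12, 3, replace = TRUE))
    hs <- lapply(1:3, function(i)
      color_histogram(img, o[i, 1], o[i, 2], 8, 16))
    expect_equal(histogram_distance(hs[[1]], hs[[2]]),
                 histogram_distance(hs[[2]], hs[[1]]))
    expect_lte(histogram_distance(hs[[1]], hs[[3]]),
               histogram_distance(hs[[1]], hs[[2]]) +
                 histogram_distance(hs[[2]], hs[[3]]) + 1e-12)
    expect_gte(histogram_distance(hs[[1]], hs[[2]]), 0)
  })
  h32 <- color_histogram(img, 0, 0, 8, 32)
  expect_error(histogram_distance(h1, h32), "layout")
})

test_that("neighbor blocks sit one block-step away at the eight compass angles", {
  nb <- neighbor_blocks(100, 100, 256, 256, 8)
  expect_equal(nrow(nb), 8L)
  expect_setequal(nb$angle, c(45, 90, 135, 180, 225, 270, 315, 360))
  for (i in seq_len(8)) {
    dr <- nb$origin_row[i] - 100; dc <- nb$origin_col[i] - 100
    expect_true(dr %in% c(-8L, 0L, 8L) && dc %in% c(-8L, 0L, 8L))
    expect_false(dr == 0 && dc == 0)
  }
  expect_equal(nb$origin_row[nb$angle == 90], 92)    # 90 degrees = up
  expect_equal(nb$origin_col[nb$angle == 90], 100)
  expect_equal(nb$origin_row[nb$angle == 360], 100)  # 360 degrees = right
  expect_equal(nb$origin_col[nb$angle == 360], 108)

  corner <- neighbor_blocks(0, 0, 64, 64, 8)
  expect_equal(nrow(corner), 3L)                     # down, down-right, right
  # enumeration oracle over all valid offsets
  all_off <- expand.grid(dr = c(-8, 0, 8), dc = c(-8, 0, 8))
  all_off <- all_off[!(all_off$dr == 0 & all_off$dc == 0), ]
  valid <- sum(all_off$dr >= 0 & all_off$dc >= 0)
  expect_equal(nrow(corner), valid)
})

test_that("region expansion matches an independent BFS oracle and is threshold-monotone", {
  fx <- fixture_forgery(seed = 2, size = 128, region = c(32L, 32L))
  grid <- block_grid(fx$gray, 8)
  grid$kp[fx$src[1] + 9, fx$src[2] + 9] <- 3L
  grid$kp[fx$dst[1] + 9, fx$dst[2] + 9] <- 2L
  susp <- list(binarized = matrix(0L, 128, 128))
  susp$binarized[fx$src[1] + 9:20, fx$src[2] + 9:20] <- 1L
  susp$binarized[fx$dst[1] + 9:20, fx$dst[2] + 9:20] <- 1L

  empty <- expand_regions(fx$image, list(binarized = matrix(0L, 128, 128)),
                          grid)
  expect_equal(sum(empty), 0L)

  got <- expand_regions(fx$image, susp, grid, distance_threshold = 0.3,
                        max_rounds = 10)
  expect_true(all(got[susp$binarized == 1L] == 1L))  # mask contains its input

  # independent BFS oracle: plain double loop, no caching, same tie rules
  oracle <- local({
    B <- 8L; mask <- susp$binarized
    cover <- sapply(0:(128 - B), function(c0) sapply(0:(128 - B), function(r0)
      sum(susp$binarized[r0 + 1:B, c0 + 1:B])))
    seeds <- which(cover >= 32, arr.ind = TRUE) - 1L
    kp <- grid$kp[seeds + 1L]
    seeds <- seeds[order(-kp, seeds[, 1], seeds[, 2]), , drop = FALSE]
    seen <- matrix(FALSE, 121, 121)
    seen[seeds + 1L] <- TRUE
    frontier <- seeds
    hist_of <- function(r0, c0) color_histogram(fx$image, r0, c0, B, 32)
    for (round in 1:10) {
      nxt <- NULL
      for (k in seq_len(nrow(frontier))) {
        r0 <- frontier[k, 1]; c0 <- frontier[k, 2]
        nb <- neighbor_blocks(r0, c0, 128, 128, B)
        if (!nrow(nb)) next
        d <- sapply(seq_len(nrow(nb)), function(i)
          histogram_distance(hist_of(r0, c0),
                             hist_of(nb$origin_row[i], nb$origin_col[i])))
        b <- which.min(d)
        if (d[b] > 0.3) next
        br <- nb$origin_row[b]; bc <- nb$origin_col[b]
        if (seen[br + 1, bc + 1]) next
        seen[br + 1, bc + 1] <- TRUE
        mask[br + 1:B, bc + 1:B] <- 1L
        nxt <- rbind(nxt, c(br, bc))
      }
      if (is.null(nxt)) break
      kp <- grid$kp[nxt + 1L]
      frontier <- nxt[order(-kp, nxt[, 1], nxt[, 2]), , drop = FALSE]
    }
    mask
  })
  expect_identical(got, oracle)

  # monotone in the distance threshold
  m_small <- expand_regions(fx$image, susp, grid, distance_threshold = 0.05)
  m_mid <- expand_regions(fx$image, susp, grid, distance_threshold = 0.3)
  m_big <- expand_regions(fx$image, susp, grid, distance_threshold = 0.6)
  expect_true(all(m_mid[m_small == 1L] == 1L))
  expect_true(all(m_big[m_mid == 1L] == 1L))
})

test_that("disk closing is extensive, idempotent and bridges small gaps", {
  expect_equal(sum(morphological_close(matrix(0L, 30, 30), 5)), 0L)

  m <- matrix(0L, 40, 40)
  m[5:14, 5:14] <- 1L
  m[5:14, 18:27] <- 1L                      # 3-pixel gap between squares
  closed <- morphological_close(m, 5)
  expect_equal(length(cmfd:::component_sizes(closed)), 1L)

  cmfd:::with_seed(41, for (k in 1:5) {
    mk <- matrix(rbinom(900, 1, 0.2), 30, 30)
    ck <- morphological_close(mk, 3)
    expect_true(all(ck[mk == 1L] == 1L))               # extensivity
    expect_identical(morphological_close(ck, 3), ck)   # idempotence
  })
})
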