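test_that("fitness is the mean squared STD difference against the population", {
  expect_equal(eom_fitness(5, rep(5, 7)), 0)
  expect_equal(eom_fitness(1, c(1, 3)), 2)     # ((1-1)^2 + (1-3)^2) / 2
  loop_oracle <- function(s, pop) sum((s - pop)^2) / length(pop)
  cmfd:::with_seed(5, for (k in 1:20) {
    pop <- runif(sample(2:30, 1), 0, 120)
    s <- runif(1, 0, 120)
    expect_equal(eom_fitness(s, pop), loop_oracle(s, pop), tolerance = 1e-9)
    expect_gte(eom_fitness(s, pop), 0)
  })
  expect_error(eom_fitness(1, numeric(0)), "empty")
})

test_that("the equilibrium pool keeps the four best fitnesses with row-major ties", {
  win <- matrix(seq_len(4 * 5), 4, 5)
  pool <- eom_pool(win, c(9, 1, 5, 3, 7))
  expect_equal(pool$fitness, c(1, 3, 5, 7))
  expect_equal(pool$idx, c(2L, 4L, 3L, 5L))
  expect_equal(pool$avg, rowMeans(win[, c(2, 4, 3, 5)]))
  expect_true(all(diff(pool$fitness) >= 0))    # sorted invariant

  # four identical constant windows: the average is that window
  const <- matrix(7, 9, 4)
  p2 <- eom_pool(const, rep(0, 4))
  expect_equal(p2$avg, rep(7, 9))

  # tie at the minimum: the earlier (row-major) candidate becomes c_eq1
  p3 <- eom_pool(matrix(1:12, 2), c(4, 2, 2, 9, 3, 8))
  expect_equal(p3$idx[1], 2L)
  expect_error(eom_pool(matrix(1, 2, 3), c(1, 2, 3)), "at least 4")
})

test_that("exponential term follows the printed form with sign(0) = 0", {
  p <- eom_params()
  expect_equal(exponential_term(0.5, 0.3, 10, p), -1)    # sign(0) = 0
  expect_equal(exponential_term(0.9, 0, 99, p), 1)       # exp(0) = 1
  expect_equal(exponential_term(0.1, 1, 0, p), -3)
  pc <- eom_params(f_variant = "canonical")
  expect_equal(exponential_term(0.9, 0, 99, pc), 0)      # exp(0) - 1 = 0
  loop <- function(r, lam, s) 2 * sign(r - 0.5) * exp(-lam * s) - 1
  cmfd:::with_seed(6, for (k in 1:20) {
    r <- runif(1); lam <- runif(1); s <- runif(1, 0, 120)
    expect_equal(exponential_term(r, lam, s, p), loop(r, lam, s),
                 tolerance = 1e-12)
  })
})

test_that("generation rate and concentration update match element-wise loop oracles", {
  p <- eom_params()
  ceq1 <- matrix(1:16, 4, 4) * 3
  blk <- matrix(16:1, 4, 4) * 2
  # r2 below GP: the generation term sits out
  expect_equal(generation_rate(0.7, 0.2, 0.5, ceq1, blk, F = 1.2, p),
               matrix(0, 4, 4))
  # tie r2 == GP takes the 0.5 r1 branch
  expect_equal(generation_rate(1, 0.5, 0, ceq1, blk, F = 2, p),
               0.5 * ceq1 * 2)
  cmfd:::with_seed(7, for (k in 1:10) {
    r1 <- runif(1); r2 <- runif(1); lam <- runif(1); F <- runif(1, -3, 1)
    G <- generation_rate(r1, r2, lam, ceq1, blk, F, p)
    gcp <- if (r2 >= 0.5) 0.5 * r1 else 0
    for (i in 1:4) for (j in 1:4)
      expect_equal(G[i, j], gcp * (ceq1[i, j] - lam * blk[i, j]) * F,
                   tolerance = 1e-12)
    Cp <- update_concentration(blk, ceq1, F, G, lam, p)
    lam_eff <- max(lam, p$lambda_floor)
    for (i in 1:4) for (j in 1:4)
      expect_equal(Cp[i, j],
                   ceq1[i, j] + (ceq1[i, j] - blk[i, j]) * F +
                     G[i, j] / lam_eff * (1 - F),
                   tolerance = 1e-12)
  })
  # degenerate collapses
  expect_equal(update_concentration(blk, ceq1, 0, matrix(0, 4, 4), 0.5, p),
               ceq1)
  expect_equal(update_concentration(ceq1, ceq1, 0.7, matrix(0, 4, 4), 0.5, p),
               ceq1)
  expect_error(generation_rate(0.5, 0.9, 0.5, ceq1, matrix(0, 2, 2), 1, p),
               "shape")
})

test_that("re-weighting whitens members and darkens non-members with clipping", {
  p <- eom_params(member_rule = "pool")
  working <- matrix(100, 16, 16)
  win4 <- matrix(runif(64 * 4, 0, 255), 64, 4)
  pop <- c(50, 50, 50, 50)
  pool <- eom_pool(win4, rep(0, 4))            # membership cutoff 0
  # member: updated std 50 matches the population exactly -> fitness 0
  member_win <- c(rep(0, 32), rep(100, 32))    # std 50
  out <- classify_and_reweight(member_win, pool, working, 0, 0, pop, p)
  expect_true(out$member)
  expect_equal(out$factor, 50)
  expect_true(all(out$working[1:8, 1:8] == 255))        # 50 * 100 clipped
  # non-member: std 40 -> fitness > 0 -> darken by std / 100
  non_win <- c(rep(0, 32), rep(80, 32))        # std 40
  out2 <- classify_and_reweight(non_win, pool, working, 0, 0, pop, p)
  expect_false(out2$member)
  expect_true(all(out2$working[1:8, 1:8] == 40))        # (40/100) * 100
  # zero-variance update zeroes the window in either branch
  out3 <- classify_and_reweight(rep(5, 64), pool, working, 0, 0, pop, p)
  expect_true(all(out3$working[1:8, 1:8] == 0))
})

test_that("one vectorized matcher iteration equals the scalar-operation reference", {
  g <- fixture_gray(32, 32, seed = 17)
  grid <- block_grid(g, 8)
  grid$kp[cbind(c(3, 8, 14, 20, 24), c(5, 11, 2, 18, 9))] <- 1L
  params <- eom_params(max_iter = 1, seed = 99)
  got <- run_eom(g, grid, params)

  # reference: same draws, explicit loop over candidates using exported ops
  cand <- candidate_blocks(grid)
  working <- g
  stds <- mapply(function(r, c) block_std(g, r, c, 8),
                 cand$origin_row, cand$origin_col)
  fit <- vapply(stds, eom_fitness, numeric(1), population_stds = stds)
  wins <- sapply(seq_len(nrow(cand)), function(j)
    as.vector(g[cand$origin_row[j] + 1:8, cand$origin_col[j] + 1:8]))
  pool <- eom_pool(wins, fit)
  draws <- cmfd:::with_seed(99, matrix(stats::runif(4 * nrow(cand)), 4))
  for (j in seq_len(nrow(cand))) {
    lam <- draws[1, j]; r <- draws[2, j]; r1 <- draws[3, j]; r2 <- draws[4, j]
    F <- exponential_term(r, lam, stds[j], params)
    G <- generation_rate(r1, r2, lam, pool$windows[, 1], wins[, j], F, params)
    Cp <- update_concentration(wins[, j], pool$windows[, 1], F, G, lam, params)
    working <- classify_and_reweight(Cp, pool, working, cand$origin_row[j],
                                     cand$origin_col[j], stds, params)$working
  }
  expect_equal(got$working, working, tolerance = 1e-12)
  expect_identical(got$binarized,
                   matrix((working >= 127.5) + 0L, 32, 32))
})

test_that("the matcher is seed-deterministic, bounded and short-circuits tiny populations", {
  g <- fixture_gray(40, 40, seed = 21)
  grid <- block_grid(g, 8)
  grid$kp[cbind(c(2, 9, 17, 25, 30, 31), c(3, 12, 22, 5, 28, 14))] <- 1L
  p <- eom_params(max_iter = 4, seed = 7)
  a <- run_eom(g, grid, p)
  b <- run_eom(g, grid, p)
  expect_identical(a$working, b$working)
  expect_identical(a$binarized, b$binarized)
  expect_true(min(a$working) >= 0 && max(a$working) <= 255)
  c2 <- run_eom(g, grid, eom_params(max_iter = 4, seed = 8))
  expect_false(identical(a$working, c2$working))   # seed matters

  grid3 <- block_grid(g, 8)
  grid3$kp[cbind(c(2, 12, 22), c(2, 12, 22))] <- 1L
  expect_equal(nrow(candidate_blocks(grid3)), 3L)  # below the pool minimum
  empty <- run_eom(g, grid3, p)
  expect_equal(sum(empty$binarized), 0L)
  expect_equal(empty$n_candidates, 3L)
})

test_that("whitened pixels land on duplicated regions found by exhaustive STD matching", {
  hits <- 0L
  for (sd in 1:10) {
    # 64x64 smooth background with an exact duplicated 16x16 textured patch
    img <- cmfd:::with_seed(sd, {
      base <- matrix(40, 64, 64) +
        4 * cmfd:::smooth_noise(64, 64, 1.5)
      patch <- 60 + 35 * matrix(stats::rnorm(256), 16, 16)
      base[9:24, 9:24] <- patch
      base[41:56, 33:48] <- patch
      pmin(pmax(base, 0), 124)
    })
    grid <- block_grid(img, 8)
    # suspicion seeds on the textured areas, as SIFT would provide
    kp_px <- rbind(as.matrix(expand.grid(seq(10, 22, 4), seq(10, 22, 4))),
                   as.matrix(expand.grid(seq(42, 54, 4), seq(34, 46, 4))))
    grid$kp[kp_px] <- 1L
    s <- run_eom(img, grid, eom_params(seed = sd))
    # oracle: exhaustive all-pairs exact-window matching over the full grid
    r0 <- rep(0:56, times = 57); c0 <- rep(0:56, each = 57)
    idx <- cmfd:::window_indices(r0, c0, 64, 8)
    keys <- apply(matrix(img[idx], 64), 2, paste, collapse = ",")
    dup <- duplicated(keys) | duplicated(keys, fromLast = TRUE)
    oracle <- matrix(0L, 64, 64)
    for (j in which(dup)) oracle[r0[j] + 1:8, c0[j] + 1:8] <- 1L
    if (sum(s$binarized * oracle) > 0) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})
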