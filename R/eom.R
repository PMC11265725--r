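#' Parameters of the equilibrium-optimizer block matcher
#'
#' Bundles and validates the free parameters of [run_eom()]. `a1`, `a2` and
#' `GP` keep the standard equilibrium-optimizer values (2, 1, 0.5); the
#' remaining knobs are implementation choices documented in the methods
#' vignette.
#'
#' @param a1,a2 Exploration/exploitation constants of the exponential term
#'   (defaults 2 and 1).
#' @param gp Generation probability in `[0, 1]` (default 0.5); the
#'   generation-rate term participates only when the draw `r2 >= gp`.
#' @param max_iter Number of matcher iterations (default 20).
#' @param lambda_floor Lower guard for the random turnover rate `lambda`
#'   before it divides the generation-rate term (default 1e-6).
#' @param seed RNG seed for the matcher's random draws (default 1).
#' @param threshold Binarization threshold on the re-weighted working image,
#'   in `[0, 255]` (default 127.5): a pixel is suspected iff its working
#'   value is at least this.
#' @param f_variant `"printed"` (default) evaluates the exponential term as
#'   `a1 * sign(r - 0.5) * exp(-lambda * std) - a2`; `"canonical"` uses the
#'   classical equilibrium-optimizer form
#'   `a1 * sign(r - 0.5) * (exp(-lambda * std) - 1)`.
#' @param member_rule How an updated concentration qualifies as an
#'   equilibrium-pool member (the step that whitens a block): `"mean"`
#'   (default) admits it when its fitness is no worse than the population's
#'   average fitness; `"pool"` admits it only when its fitness is no worse
#'   than the pool's fourth-best member. See the methods vignette for why
#'   the population-average rule is the default.
#' @return An `eom_params` list.
#' @export
eom_params <- function(a1 = 2, a2 = 1, gp = 0.5, max_iter = 20L,
                       lambda_floor = 1e-6, seed = 1L, threshold = 127.5,
                       f_variant = c("printed", "canonical"),
                       member_rule = c("mean", "pool")) {
  f_variant <- match.arg(f_variant)
  member_rule <- match.arg(member_rule)
  for (nm in c("a1", "a2", "gp", "max_iter", "lambda_floor", "threshold"))
    stopifnot_scalar_number(get(nm), nm)
  if (a1 <= 0) stop("'a1' must be positive", call. = FALSE)
  if (gp < 0 || gp > 1) stop("'gp' must lie in [0, 1]", call. = FALSE)
  if (max_iter < 1) stop("'max_iter' must be at least 1", call. = FALSE)
  if (lambda_floor <= 0) stop("'lambda_floor' must be positive", call. = FALSE)
  if (threshold < 0 || threshold > 255)
    stop("'threshold' must lie in [0, 255]", call. = FALSE)
  structure(list(a1 = a1, a2 = a2, gp = gp, max_iter = as.integer(max_iter),
                 lambda_floor = lambda_floor, seed = as.integer(seed),
                 threshold = threshold, f_variant = f_variant,
                 member_rule = member_rule),
            class = "eom_params")
}

#' Fitness of a block against the candidate population
#'
#' The fitness of a block is the mean squared difference between its
#' standard deviation and the standard deviations of all population members
#' (the block itself included): `mean((std_u - std_i)^2)`. Blocks whose
#' texture statistics sit closest to the population's are the best
#' equilibrium candidates; exact duplicates have identical standard
#' deviations and therefore identical fitness.
#'
#' @param std_u Standard deviation(s) of the block(s) under evaluation
#'   (vectorized).
#' @param population_stds Standard deviations of the whole candidate
#'   population (non-empty).
#' @return Non-negative fitness value(s); 0 when every population standard
#'   deviation equals `std_u`.
#' @export
eom_fitness <- function(std_u, population_stds) {
  if (length(population_stds) == 0L)
    stop("candidate population is empty", call. = FALSE)
  m1 <- mean(population_stds)
  m2 <- mean(population_stds^2)
  std_u^2 - 2 * std_u * m1 + m2
}

#' Select the equilibrium pool from the candidate population
#'
#' Picks the four lowest-fitness candidates (ties broken by row-major block
#' order, i.e. by candidate index) and forms their element-wise average as
#' the fifth pool member.
#'
#' @param windows `B^2 x N` matrix whose columns are the candidate blocks'
#'   pixel windows.
#' @param fitnesses Length-`N` fitness vector aligned with the columns.
#' @return An `eom_pool`: list with `idx` (4 candidate indices by ascending
#'   fitness), `windows` (`B^2 x 4`), `fitness` (ascending, length 4), and
#'   `avg` (element-wise mean of the four windows).
#' @export
eom_pool <- function(windows, fitnesses) {
  if (!is.matrix(windows) || ncol(windows) != length(fitnesses))
    stop("'windows' must be a matrix with one column per fitness value",
         call. = FALSE)
  if (length(fitnesses) < 4L)
    stop("the equilibrium pool needs at least 4 candidates", call. = FALSE)
  ord <- order(fitnesses, seq_along(fitnesses))[1:4]
  structure(list(idx = ord,
                 windows = windows[, ord, drop = FALSE],
                 fitness = fitnesses[ord],
                 avg = rowMeans(windows[, ord, drop = FALSE])),
            class = "eom_pool")
}

#' Exponential term of the concentration update
#'
#' `F = a1 * sign(r - 0.5) * exp(-lambda * std) - a2` (with `sign(0) = 0`),
#' balancing exploration against exploitation. The `"canonical"` variant
#' multiplies `a1 * sign(r - 0.5)` by `exp(-lambda * std) - 1` instead.
#'
#' @param r,lam Random draws in `[0, 1]` (vectorized).
#' @param std Standard deviation of the current block (vectorized).
#' @param params An [eom_params()] object.
#' @return The exponential term `F` (same length as the inputs).
#' @export
exponential_term <- function(r, lam, std, params = eom_params()) {
  s <- sign(r - 0.5)
  if (params$f_variant == "printed")
    params$a1 * s * exp(-lam * std) - params$a2
  else
    params$a1 * s * (exp(-lam * std) - 1)
}

#' Generation-rate term of the concentration update
#'
#' `GCP = 0.5 * r1` when `r2 >= GP`, else 0 (the generation term sits out);
#' `G0 = GCP * (c_eq1 - lambda * block)`; `G = G0 * F`, element-wise.
#'
#' @param r1,r2 Random draws in `[0, 1]`.
#' @param lam Random turnover rate in `[0, 1]`.
#' @param c_eq1_values Best pool member's pixel window (`B x B` matrix or
#'   `B^2` vector).
#' @param block_values Current block's pixel window, same shape.
#' @param F Exponential term from [exponential_term()].
#' @param params An [eom_params()] object.
#' @return Generation-rate grid, same shape as the inputs.
#' @export
generation_rate <- function(r1, r2, lam, c_eq1_values, block_values, F,
                            params = eom_params()) {
  if (length(c_eq1_values) != length(block_values))
    stop("'c_eq1_values' and 'block_values' must have the same shape",
         call. = FALSE)
  gcp <- if (r2 >= params$gp) 0.5 * r1 else 0
  gcp * (c_eq1_values - lam * block_values) * F
}

#' Concentration update
#'
#' `C' = c_eq1 + (c_eq1 - block) * F + (G / lambda) * (1 - F)`, element-wise,
#' with `lambda` floored at `params$lambda_floor` before the division.
#'
#' @param block_values Current block's pixel window.
#' @param c_eq1_values Best pool member's pixel window, same shape.
#' @param F Exponential term.
#' @param G Generation-rate grid, same shape.
#' @param lam Random turnover rate in `[0, 1]`.
#' @param params An [eom_params()] object.
#' @return Updated concentration, same shape as the inputs.
#' @export
update_concentration <- function(block_values, c_eq1_values, F, G, lam,
                                 params = eom_params()) {
  if (!all(is.finite(block_values)) || !all(is.finite(c_eq1_values)) ||
      !all(is.finite(G)) || !is.finite(F) && length(F) == 1L)
    stop("non-finite inputs to the concentration update", call. = FALSE)
  lam_eff <- max(lam, params$lambda_floor)
  c_eq1_values + (c_eq1_values - block_values) * F + (G / lam_eff) * (1 - F)
}

#' Classify an updated concentration and re-weight its window
#'
#' An updated concentration counts as an equilibrium-pool member when its
#' fitness is no worse than the membership cutoff: the population's average
#' fitness (`member_rule = "mean"`, the default) or the pool's fourth
#' (worst) member (`member_rule = "pool"`). Member block windows in the
#' working image are multiplied by `STD(C')` ("convert to white");
#' non-members by `STD(C') / 100` ("convert to black"). Results are clipped
#' to `[0, 255]`.
#'
#' @param updated_values Updated concentration (`B x B` matrix or `B^2`
#'   vector).
#' @param pool An [eom_pool()].
#' @param working Working image (`H x W` matrix) to re-weight.
#' @param origin_row,origin_col 0-based origin of the block's window.
#' @param population_stds Standard deviations of the candidate population,
#'   against which the updated fitness is measured.
#' @param params An [eom_params()] object (supplies `member_rule`).
#' @return List with the modified `working` image, logical `member`, and the
#'   applied `factor`.
#' @export
classify_and_reweight <- function(updated_values, pool, working,
                                  origin_row, origin_col, population_stds,
                                  params = eom_params()) {
  stopifnot(inherits(pool, "eom_pool"))
  s <- sqrt(mean((updated_values - mean(updated_values))^2))
  member <- eom_fitness(s, population_stds) <=
    membership_cutoff(pool, population_stds, params$member_rule)
  factor <- if (member) s else s / 100
  B <- as.integer(sqrt(length(updated_values)))
  rows <- origin_row + seq_len(B)
  cols <- origin_col + seq_len(B)
  working[rows, cols] <- clip255(factor * working[rows, cols])
  list(working = working, member = member, factor = factor)
}

# Fitness cutoff below which an updated concentration counts as "in the
# equilibrium pool".
membership_cutoff <- function(pool, population_stds, member_rule) {
  if (member_rule == "pool") pool$fitness[4]
  else mean(eom_fitness(population_stds, population_stds))
}

#' Run the equilibrium-optimizer block matcher
#'
#' Iteratively re-weights keypoint-bearing blocks of the grayscale image
#' toward white (suspected forged) or black (authentic). Per iteration:
#' block windows and standard deviations are re-read from the current
#' working image; every candidate's fitness is evaluated against the
#' population ([eom_fitness()]); the equilibrium pool is re-selected
#' ([eom_pool()]); then, for each candidate in row-major order, the random
#' parameters `lambda, r, r1, r2` are drawn (in that fixed order from one
#' seeded stream), the exponential and generation-rate terms are formed, the
#' concentration is updated, and the block's window is re-weighted in place
#' ([classify_and_reweight()]), whitening pool members and darkening the
#' rest. After the final iteration the working image is binarized at
#' `params$threshold`.
#'
#' Images with fewer than four candidate blocks short-circuit to an
#' all-authentic (empty) map, since the equilibrium pool needs four members.
#'
#' @param img Numeric grayscale matrix on the `[0, 255]` scale.
#' @param grid A `block_grid` with keypoint counts assigned
#'   ([assign_keypoints()]).
#' @param params An [eom_params()] object.
#' @return A `suspicion_map`: list with `working` (re-weighted image),
#'   `binarized` (0/1 matrix), `n_candidates`, and `params`.
#' @export
run_eom <- function(img, grid, params = eom_params()) {
  validate_gray_image(img)
  stopifnot(inherits(grid, "block_grid"), inherits(params, "eom_params"))
  if (nrow(img) != grid$H || ncol(img) != grid$W)
    stop("image and grid dimensions differ", call. = FALSE)
  H <- grid$H; B <- grid$B
  cand <- candidate_blocks(grid)
  N <- nrow(cand)
  working <- img
  if (N >= 4L) {
    idx <- window_indices(cand$origin_row, cand$origin_col, H, B)
    B2 <- B * B
    with_seed(params$seed, {
      for (iter in seq_len(params$max_iter)) {
        Wm <- matrix(working[as.vector(idx)], B2, N)
        mu <- colMeans(Wm)
        stds <- sqrt(colMeans(sweep(Wm, 2L, mu)^2))
        fit <- eom_fitness(stds, stds)
        pool <- eom_pool(Wm, fit)
        ceq1 <- pool$windows[, 1L]
        cutoff <- membership_cutoff(pool, stds, params$member_rule)
        u <- matrix(stats::runif(4L * N), 4L, N)
        lam <- u[1L, ]; r <- u[2L, ]; r1 <- u[3L, ]; r2 <- u[4L, ]
        F <- exponential_term(r, lam, stds, params)
        gcp <- ifelse(r2 >= params$gp, 0.5 * r1, 0)
        lam_eff <- pmax(lam, params$lambda_floor)
        Gm <- (ceq1 - Wm * rep(lam, each = B2)) * rep(gcp * F, each = B2)
        Cp <- ceq1 + (ceq1 - Wm) * rep(F, each = B2) +
          Gm * rep((1 - F) / lam_eff, each = B2)
        muC <- colMeans(Cp)
        sC <- sqrt(colMeans(sweep(Cp, 2L, muC)^2))
        fitC <- eom_fitness(sC, stds)
        factor <- ifelse(fitC <= cutoff, sC, sC / 100)
        for (j in seq_len(N)) {
          w <- idx[, j]
          working[w] <- clip255(factor[j] * working[w])
        }
      }
    })
  }
  binarized <- if (N >= 4L)
    matrix((working >= params$threshold) + 0L, nrow(working), ncol(working))
  else matrix(0L, nrow(working), ncol(working))   # declared authentic
  structure(
    list(working = working, binarized = binarized,
         n_candidates = N, params = params),
    class = "suspicion_map")
}

#' @export
print.suspicion_map <- function(x, ...) {
  cat(sprintf(
    "suspicion_map: %d x %d, %d candidates, %d suspected pixels (%.2f%%)\n",
    nrow(x$binarized), ncol(x$binarized), x$n_candidates,
    sum(x$binarized), 100 * mean(x$binarized)))
  invisible(x)
}
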