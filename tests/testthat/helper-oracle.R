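# Independent oracles and small fixture builders used across the suite.
# The oracle code deliberately re-derives the partial-credit quantities from
# the defining formula (naive exponentials, no max-subtraction, grid search
# instead of Newton) so it shares no code path with the package internals.

# direct PCM evaluation: P(k) proportional to exp(sum_{j<=k}(theta - d_j))
naive_pcm_probs <- function(theta, thr) {
  num <- exp(c(0, cumsum(theta - thr)))
  num / sum(num)
}

naive_pcm_moments <- function(theta, thr) {
  p <- naive_pcm_probs(theta, thr)
  k <- 0:(length(p) - 1)
  e <- sum(k * p)
  c(expected = e, information = sum(k^2 * p) - e^2)
}

# log normalising constant of one item over a theta grid
oracle_item_logz <- function(grid, thr) {
  ks <- 0:length(thr)
  cd <- c(0, cumsum(thr))
  S <- outer(grid, ks) - matrix(cd, length(grid), length(ks), byrow = TRUE)
  log(rowSums(exp(S)))
}

# brute-force likelihood grid argmax.  Under the PCM the log-likelihood is
# sum(x)*theta - const - sum_i logZ_i(theta), so with the per-item logZ
# columns precomputed the argmax search is exact on the grid.
oracle_grid_mle <- function(x, ids, logz, grid) {
  ll <- sum(x) * grid - rowSums(logz[, ids, drop = FALSE])
  grid[which.max(ll)]
}

# compact ad-hoc bank builder for tests
make_bank <- function(difficulty, n_steps, item_id = seq_along(difficulty),
                      in_pool = TRUE, routes = NULL, spacing = 1.0) {
  item_bank(
    data.frame(item_id = item_id,
               text = paste("test item", item_id),
               n_steps = n_steps, difficulty = difficulty,
               in_pool = in_pool, stringsAsFactors = FALSE),
    routes = routes, threshold_spacing = spacing
  )
}

# draw one model-consistent response vector (naive sampler, independent of
# simulate_cohort)
oracle_draw_responses <- function(theta, thr_list) {
  vapply(thr_list, function(thr) {
    p <- naive_pcm_probs(theta, thr)
    sample(0:(length(p) - 1), 1L, prob = p)
  }, integer(1))
}
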