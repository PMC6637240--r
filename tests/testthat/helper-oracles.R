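# Independent oracles used across tests. These are deliberately naive
# (direct arithmetic, brute-force grids) and share no code with the
# package's estimators.

# Binomial mixture pmf by direct arithmetic.
naive_mixture <- function(y, n, p_e, p_c, pi) {
  (1 - pi) * dbinom(y, n, p_e) + pi * dbinom(y, n, p_c)
}

naive_loglik <- function(y, n, p_e, p_c, pi) {
  sum(log(naive_mixture(y, n, p_e, p_c, pi)))
}

# 1-D brute-force maximiser of the mixture log-likelihood over pi.
grid_argmax_pi <- function(y, n, p_e, p_c, npoints = 10001L) {
  grid <- seq(1e-6, 1 - 1e-6, length.out = npoints)
  agg <- aggregate(list(w = y), by = list(y = y, n = n), FUN = length)
  le <- dbinom(agg$y, agg$n, p_e)
  lc <- dbinom(agg$y, agg$n, p_c)
  ll <- vapply(grid, function(p)
    sum(agg$w * log((1 - p) * le + p * lc)), numeric(1))
  grid[which.max(ll)]
}

# 2-D brute-force maximiser of the mixture log-likelihood over (p_c, pi).
grid_argmax_pc_pi <- function(y, n, p_e, pc_grid, pi_grid) {
  agg <- aggregate(list(w = y), by = list(y = y, n = n), FUN = length)
  best <- c(NA, NA); best_ll <- -Inf
  for (pc in pc_grid) {
    le <- dbinom(agg$y, agg$n, p_e)
    lc <- dbinom(agg$y, agg$n, pc)
    for (pi in pi_grid) {
      ll <- sum(agg$w * log((1 - pi) * le + pi * lc))
      if (ll > best_ll) { best_ll <- ll; best <- c(pc, pi) }
    }
  }
  list(p_c = best[1], pi = best[2], loglik = best_ll)
}

# Two-stage brute force: coarse 2-D grid, then a fine grid around the
# coarse argmax (steps pc/10 and pi/10). Still exhaustive search, just
# closer to the true maximiser than one coarse pass.
grid_argmax_pc_pi_refined <- function(y, n, p_e, pc_grid, pi_grid) {
  g <- grid_argmax_pc_pi(y, n, p_e, pc_grid, pi_grid)
  pc_step <- diff(pc_grid)[1]; pi_step <- diff(pi_grid)[1]
  pc2 <- seq(max(p_e, g$p_c - pc_step), g$p_c + pc_step,
             by = pc_step / 10)
  pi2 <- seq(max(1e-4, g$pi - pi_step), min(1 - 1e-4, g$pi + pi_step),
             by = pi_step / 10)
  grid_argmax_pc_pi(y, n, p_e, pc2, pi2)
}

# Draw one cell's reads from the generative model (independent of
# simulate_records).
draw_reads <- function(n_reads, n_per_read, p_e, p_c, pi) {
  new <- runif(n_reads) < pi
  n <- rep_len(n_per_read, n_reads)
  y <- rbinom(n_reads, n, ifelse(new, p_c, p_e))
  data.frame(y = y, n = n, new = new)
}
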