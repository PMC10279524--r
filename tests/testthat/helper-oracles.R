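# Independent oracles and generators used across the suite.

# random valid four-group proportions with nonempty replicability null
rand_props <- function() {
  repeat {
    x <- stats::runif(4)
    x <- x / sum(x)
    if (x[1] + x[2] + x[3] > 1e-6) {
      return(four_group_proportions(x[1], x[2], x[3], x[4]))
    }
  }
}

# brute-force sup over a dense t-grid of the data-adaptive threshold:
# reject q_i <= largest grid t with FDR*(t) <= alpha
oracle_reject_grid <- function(q, props, alpha, grid_step = 1e-3) {
  tgrid <- sort(unique(c(q, seq(0, 1, by = grid_step))))
  m <- length(q)
  fdr <- vapply(tgrid, function(t) {
    r <- sum(q <= t)
    m * (props[["xi00"]] * t^2 +
           (props[["xi01"]] + props[["xi10"]]) * t) / max(r, 1)
  }, numeric(1))
  ok <- which(fdr <= alpha)
  if (!length(ok)) return(rep(FALSE, m))
  q <= tgrid[max(ok)]
}

# exhaustive-search BH oracle: largest i0 with p_(i0) <= alpha * i0 / m
oracle_bh_reject <- function(p, alpha) {
  m <- length(p)
  ps <- sort(p)
  ok <- which(ps <= alpha * seq_len(m) / m)
  if (!length(ok)) return(rep(FALSE, m))
  p <= ps[max(ok)]
}

# small default scenario for quick simulation-based tests
quick_scenario <- function(m = 2000, n_reps = 10, seed = 42,
                           xi = c(0.9, 0.025, 0.025, 0.05),
                           mu1 = 3, mu2 = 3, sigma1 = 1, sigma2 = 1) {
  simulation_scenario(
    m = m, props = four_group_proportions(xi[1], xi[2], xi[3], xi[4]),
    mu1 = mu1, mu2 = mu2, sigma1 = sigma1, sigma2 = sigma2,
    alpha = 0.05, n_reps = n_reps, seed = seed
  )
}
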