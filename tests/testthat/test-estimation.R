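test_that("storey_pi0 matches direct tail counts", {
  expect_equal(storey_pi0(c(0.01, 0.2, 0.6, 0.8), 0.5), 1.0)
  expect_equal(storey_pi0(c(0.1, 0.2, 0.3), 0.5), 0)
  expect_equal(storey_pi0(c(0.6, 0.7, 0.9, 0.95), 0.5), 2.0)  # raw, unclipped
  expect_error(storey_pi0(runif(5), 1), "in \\(0, 1\\)")
  expect_error(storey_pi0(runif(5), 0), "in \\(0, 1\\)")
})

test_that("estimate_xi00 matches direct joint-tail counts", {
  pp <- paired_pvalues(1:4,
                       c(0.6, 0.1, 0.2, 0.3),
                       c(0.7, 0.9, 0.1, 0.2))
  expect_equal(estimate_xi00(pp, 0.5), 1 / (4 * 0.25))
  low <- paired_pvalues(1:4, rep(0.1, 4), rep(0.9, 4))
  expect_equal(estimate_xi00(low, 0.5), 0)
  all_hi <- paired_pvalues(1:4, rep(0.8, 4), rep(0.9, 4))
  expect_equal(estimate_xi00(all_hi, 0.5), 4.0)  # raw, clipped downstream
})

test_that("smooth_select reproduces constant and linear trends", {
  grid <- seq(0.05, 0.95, by = 0.05)
  expect_equal(smooth_select(rep(0.7, length(grid)), grid), 0.7,
               tolerance = 1e-6)
  lin <- 0.2 + 0.5 * grid
  expect_equal(smooth_select(lin, grid), 0.2 + 0.5 * 0.95, tolerance = 1e-3)
  expect_warning(out <- smooth_select(c(0.4, 0.5, 0.6), c(0.25, 0.5, 0.75)),
                 "fewer than 4")
  expect_equal(out, 0.6)
  # output clipped to [0, 1]
  expect_equal(smooth_select(rep(1.8, length(grid)), grid), 1)
})

test_that("smoothed pi0 recovers 1 on pure-null uniform p-values", {
  set.seed(101)
  grid <- lambda_grid()
  p <- runif(10000)
  raw <- vapply(grid, function(l) storey_pi0(p, l), numeric(1))
  expect_equal(smooth_select(raw, grid), 1, tolerance = 0.05)
})

test_that("estimate_proportions recovers (1,0,0,0) on all-null data", {
  set.seed(7)
  pp <- paired_pvalues(1:10000, runif(10000), runif(10000))
  est <- estimate_proportions(pp)
  expect_equal(unname(est$joint[["xi00"]]), 1, tolerance = 0.05)
  expect_lt(est$joint[["xi11"]], 0.05)
  expect_equal(sum(est$joint), 1, tolerance = 1e-9)
})

test_that("xi00 is clipped to the Frechet-Hoeffding interval", {
  # 9 of 20 pairs jointly in the upper tail at lambda = 0.5:
  # pi0 estimates 0.9/0.9 but raw xi00 = 9/5 = 1.8 -> clipped to 0.9
  p_hi <- seq(0.5, 0.98, length.out = 9)
  p_lo <- seq(0.01, 0.49, length.out = 11)
  pp <- paired_pvalues(1:20, c(p_hi, p_lo), c(rev(p_hi), rev(p_lo)))
  est <- estimate_proportions(pp, fixed_lambda = 0.5)
  expect_equal(est$pi0_study1, 0.9)
  expect_equal(est$pi0_study2, 0.9)
  expect_equal(unname(est$joint[["xi00"]]), 0.9)
  expect_equal(unname(est$joint[["xi01"]]), 0)
  expect_equal(unname(est$joint[["xi10"]]), 0)
  expect_equal(unname(est$joint[["xi11"]]), 0.1)
})

test_that("joint estimates are always a valid four-group distribution", {
  set.seed(31)
  for (i in 1:10) {
    m <- 500
    pp <- paired_pvalues(1:m, runif(m)^runif(1, 0.3, 3),
                         runif(m)^runif(1, 0.3, 3))
    est <- estimate_proportions(pp)
    xi <- est$joint
    expect_true(all(xi >= 0 & xi <= 1))
    expect_equal(sum(xi), 1, tolerance = 1e-9)
    expect_lte(xi[["xi00"]], min(est$pi0_study1, est$pi0_study2) + 1e-12)
    expect_gte(xi[["xi00"]],
               max(0, est$pi0_study1 + est$pi0_study2 - 1) - 1e-12)
  }
})

test_that("estimated null mass is conservative under the generative model", {
  sc <- quick_scenario(m = 5000, n_reps = 20, seed = 314)
  true_null <- 1 - sc$props[["xi11"]]
  mass <- vapply(seq_len(sc$n_reps), function(r) {
    sim <- gen_pvalues(gen_states(sc, r), sc)
    est <- estimate_proportions(sim$pairs)
    1 - est$joint[["xi11"]]
  }, numeric(1))
  expect_gte(mean(mass), true_null - 3 * sd(mass) / sqrt(length(mass)))
})
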