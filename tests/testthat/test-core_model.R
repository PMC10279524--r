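test_that("paired_pvalues validates its inputs", {
  pp <- paired_pvalues(c("a", "b", "c"), c(0, 0.5, 1), c(1, 0.5, 0))
  expect_s3_class(pp, "paired_pvalues")
  expect_equal(length(pp), 3L)
  expect_error(paired_pvalues(c("a", "a"), c(0.1, 0.2), c(0.1, 0.2)),
               "duplicate")
  expect_error(paired_pvalues("a", 1.2, 0.5), "outside")
  expect_error(paired_pvalues("a", NA, 0.5), "missing")
  expect_error(paired_pvalues(c("a", "b"), 0.1, c(0.1, 0.2)), "length")
})

test_that("max_p is the elementwise maximum", {
  pp <- paired_pvalues(1:3, c(0.1, 0.5, 0.0), c(0.3, 0.5, 1.0))
  expect_equal(max_p(pp), c(0.3, 0.5, 1.0))
})

test_that("composite_null_cdf matches the closed form and its reductions", {
  pure_null <- four_group_proportions(1, 0, 0, 0)
  t <- seq(0, 1, by = 0.1)
  expect_equal(composite_null_cdf(t, pure_null), t^2)
  one_sided <- four_group_proportions(0, 0.3, 0.2, 0.5)
  expect_equal(composite_null_cdf(t, one_sided), t)
  mixed <- four_group_proportions(0.8, 0.05, 0.05, 0.1)
  expect_equal(composite_null_cdf(0.1, mixed), 0.02)
  empty <- four_group_proportions(0, 0, 0, 1)
  expect_error(composite_null_cdf(0.5, empty), "empty")
})

test_that("G is super-uniform with the exact deficiency identity", {
  t <- seq(0, 1, by = 0.001)
  set.seed(11)
  for (i in 1:20) {
    props <- rand_props()
    g <- composite_null_cdf(t, props)
    expect_true(all(g <= t + 1e-12))
    nm <- props[["xi00"]] + props[["xi01"]] + props[["xi10"]]
    expect_equal(g - t, props[["xi00"]] / nm * t * (t - 1))
    expect_true(all(diff(g) >= -1e-12))
    expect_equal(g[1], 0)
    expect_equal(g[length(g)], 1)
  }
})

test_that("fdr_star reproduces hand-computed values", {
  q <- c(0.01, 0.2, 0.5)
  pure_null <- four_group_proportions(1, 0, 0, 0)
  expect_equal(fdr_star(0.01, q, pure_null), 3 * 1e-4 / 1)
  expect_equal(fdr_star(0.2, q, pure_null), 3 * 0.04 / 2)
  # below all q: R(t) = 0 forces denominator 1
  props <- four_group_proportions(0.7, 0.1, 0.1, 0.1)
  t <- 0.005
  expect_equal(fdr_star(t, q, props),
               3 * (0.7 * t^2 + 0.2 * t) / 1)
})

test_that("find_threshold picks the largest qualifying order statistic", {
  q <- c(0.01, 0.2, 0.5)
  pure_null <- four_group_proportions(1, 0, 0, 0)
  expect_equal(find_threshold(q, pure_null, 0.05), 0.01)
  all_alt <- four_group_proportions(0, 0, 0, 1)
  expect_equal(find_threshold(q, all_alt, 0.05), max(q))
  expect_equal(find_threshold(rep(1, 50), pure_null, 0.05), 0)
})

test_that("jump_test matches the worked step-up example", {
  pp <- paired_pvalues(c("g1", "g2", "g3"),
                       c(0.01, 0.2, 0.5), c(0.005, 0.15, 0.45))
  res <- jump_test(pp, four_group_proportions(1, 0, 0, 0), alpha = 0.05)
  expect_equal(res$q, c(0.01, 0.2, 0.5))
  expect_equal(res$threshold, 0.01)
  expect_equal(res$rejected, c(TRUE, FALSE, FALSE))
  expect_equal(res$adjusted, c(0.0003, 0.06, 0.25))
  expect_equal(res$n_rejected, 1L)
})

test_that("jump_test honours result invariants on random instances", {
  set.seed(23)
  for (i in 1:50) {
    m <- sample(1:40, 1)
    q <- round(runif(m), 2)  # force ties
    props <- rand_props()
    alpha <- runif(1, 0.01, 0.3)
    res <- jump_test(props = props, alpha = alpha, q = q)
    expect_identical(res$rejected, res$q <= res$threshold)
    expect_identical(res$rejected, res$adjusted <= alpha)
    expect_true(all(diff(res$adjusted[order(res$q)]) >= -1e-12))
    expect_equal(res$threshold, find_threshold(q, props, alpha))
  }
})

test_that("step-up rule equals the dense-grid sup oracle", {
  set.seed(71)
  for (i in 1:400) {
    m <- sample(1:8, 1)
    q <- runif(m)
    props <- rand_props()
    alpha <- runif(1, 0.02, 0.4)
    res <- jump_test(props = props, alpha = alpha, q = q)
    expect_identical(res$rejected, oracle_reject_grid(q, props, alpha))
  }
})

test_that("rejections are a superset of BH on q when null mass <= 1", {
  set.seed(5)
  for (i in 1:50) {
    m <- sample(5:80, 1)
    q <- runif(m)^2
    props <- rand_props()  # sums to 1, so null mass <= 1 by construction
    alpha <- 0.1
    jump_rej <- jump_test(props = props, alpha = alpha, q = q)$rejected
    bh_rej <- bh_adjust(q, alpha)$rejected
    expect_true(all(jump_rej[bh_rej]))
  }
})

test_that("an extra feature at q = 1 only shrinks the rejection set", {
  # the plug-in estimate scales with m, so a null-looking extra feature
  # makes FDR* weakly larger at every t < 1: rejections cannot appear
  set.seed(9)
  for (i in 1:25) {
    q <- runif(sample(3:30, 1))^2
    props <- rand_props()
    before <- jump_test(props = props, alpha = 0.1, q = q)$rejected
    after <- jump_test(props = props, alpha = 0.1, q = c(q, 1))$rejected
    expect_true(all(before[after[seq_along(q)]]))
  }
})
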