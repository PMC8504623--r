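# Best-hit P-values, truncated-product combination, empirical P and FDR.

test_that("best-hit P-value is the order-1 statistic of the minimum", {
  expect_equal(best_hit_pvalue(0.5, 1), 0.5)
  expect_equal(best_hit_pvalue(0.01, 100), 1 - 0.99^100)
  expect_equal(best_hit_pvalue(0, 1000), 0)
  expect_equal(best_hit_pvalue(c(0.2, 0.05, 0.9), 1), 0.05)
  # tiny p_min survives the log-space route
  expect_equal(best_hit_pvalue(1e-12, 100), 1e-10, tolerance = 1e-6)
  expect_error(best_hit_pvalue(numeric(), 10), "no hits")
  expect_error(best_hit_pvalue(0.5, 0), "n_T")
  # nondecreasing in n_T, nonincreasing in p_min
  p <- vapply(c(1, 5, 50, 500), function(n) best_hit_pvalue(0.01, n), 0)
  expect_true(all(diff(p) > 0))
  q <- vapply(c(0.2, 0.1, 0.01), function(pm) best_hit_pvalue(pm, 20), 0)
  expect_true(all(diff(q) < 0))
})

test_that("best-hit P-value matches simulated minima of uniforms", {
  set.seed(99)
  n_draws <- 2e4
  for (n_T in c(1, 10, 100)) {
    p_min <- 0.01
    mins <- matrix(runif(n_draws * n_T), ncol = n_T)
    emp <- mean(apply(mins, 1, min) <= p_min)
    expected <- best_hit_pvalue(p_min, n_T)
    se <- sqrt(expected * (1 - expected) / n_draws)
    expect_lt(abs(emp - expected), 3 * se + 1e-12)
  }
})

test_that("truncated product concentrates evidence below tau", {
  expect_equal(combine_truncated_product(0.05), 0.05)
  expect_equal(combine_truncated_product(c(0.01, 0.02)), 0.002)
  expect_equal(combine_truncated_product(c(0.5, 0.9)), 0.5)  # fallback
  expect_error(combine_truncated_product(numeric()), "no P-values")
  set.seed(3)
  for (i in 1:50) {
    ps <- runif(sample(1:6, 1))
    tau <- runif(1, 0.05, 0.5)
    s <- combine_truncated_product(ps, tau)
    # permutation invariance
    expect_equal(combine_truncated_product(sample(ps), tau), s)
    # appending a significant p never increases the score
    extra <- runif(1, 0, tau)
    expect_lte(combine_truncated_product(c(ps, extra), tau), s + 1e-15)
    # with >= 2 significant p-values, s <= min(tau, smallest p)
    if (sum(ps <= tau) >= 2)
      expect_lte(s, min(tau, min(ps)))
  }
})

test_that("empirical P-value uses add-one smoothing and rank counts", {
  nulls <- sort(runif(999))
  expect_equal(empirical_pvalue(min(nulls) / 2, nulls, 999), 1 / 1000)
  expect_equal(empirical_pvalue(1, nulls, 999), 1)
  expect_equal(empirical_pvalue(stats::median(nulls), nulls, 999), 0.5,
               tolerance = 0.01)
  # nondecreasing in s, bounded in (0, 1]
  p <- empirical_pvalue(seq(0, 1, 0.01), nulls, 999)
  expect_true(all(diff(p) >= 0) && all(p > 0) && all(p <= 1))
  expect_error(empirical_pvalue(0.5, nulls, 0), "no comparisons")
})

test_that("FDR estimation counts nulls at each cutoff and monotonizes", {
  m <- data.frame(s_comb = c(1e-9, 1e-3))
  out <- estimate_fdr(m, null_scores = 1e-4, size_ratio = 1)
  expect_equal(out$fdr, c(0, 0.5))
  expect_equal(out$retained, c(TRUE, FALSE))
  # no null score below any real score: everything retained at FDR 0
  out2 <- estimate_fdr(data.frame(s_comb = c(0.1, 0.2, 0.3)),
                       null_scores = 0.9, size_ratio = 1)
  expect_equal(out2$fdr, rep(0, 3))
  expect_true(all(out2$retained))
  # monotonization: fdr is nondecreasing along increasing s_comb
  set.seed(8)
  m3 <- data.frame(s_comb = sort(runif(50)))
  out3 <- estimate_fdr(m3, null_scores = runif(50), size_ratio = 1)
  expect_true(all(diff(out3$fdr) >= 0))
  expect_true(all(out3$fdr <= 1))
})

test_that("identical real and null score distributions yield FDR ~ 1", {
  set.seed(12)
  scores <- runif(200)
  out <- estimate_fdr(data.frame(s_comb = scores), null_scores = scores,
                      size_ratio = 1)
  # self-vs-self: at any cutoff covering most matches the estimate is ~1
  expect_gt(stats::median(out$fdr), 0.9)
  expect_lte(sum(out$retained), 2L)
})
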