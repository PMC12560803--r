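test_that("Friedman statistic matches the textbook formula and base R", {
  set.seed(101)
  for (i in 1:10) {
    n <- sample(4:10, 1); k <- sample(3:6, 1)
    m <- matrix(rnorm(n * k), n, k)  # continuous, tie-free
    res <- friedman_test(m)
    r <- t(apply(m, 1, rank))
    Rj <- colSums(r)
    expect_equal(res$statistic,
                 12 / (n * k * (k + 1)) * sum((Rj - n * (k + 1) / 2)^2))
    base <- stats::friedman.test(m)
    expect_equal(res$statistic, unname(base$statistic))
    expect_equal(res$p.value, unname(base$p.value))
  }
})

test_that("Friedman handles degenerate and tied data", {
  m <- matrix(rep(c(1, 5, 2), each = 3), 3, 3)  # constant within block
  res <- friedman_test(t(m))
  expect_equal(res$statistic, 0)
  expect_equal(res$p.value, 1)
  # ties within blocks still agree with base R
  m2 <- rbind(c(1, 1, 2), c(3, 2, 2), c(5, 4, 5), c(1, 2, 3))
  expect_equal(friedman_test(m2)$p.value,
               unname(stats::friedman.test(m2)$p.value))
  expect_error(friedman_test(rbind(c(1, NA), c(2, 3))), "complete-block")
  expect_error(friedman_test(matrix(1:3, 1)), "blocks")
})

test_that("Friedman is invariant to strictly monotone within-block transforms", {
  set.seed(7)
  for (i in 1:20) {
    m <- matrix(rnorm(15), 5, 3)
    m2 <- m
    for (b in 1:5) {
      a <- runif(1, 0.5, 3)
      m2[b, ] <- exp(a * m[b, ]) + rnorm(1)
    }
    expect_equal(friedman_test(m2)$statistic, friedman_test(m)$statistic)
  }
})

test_that("exact Friedman equals independent permutation enumeration", {
  set.seed(3)
  m <- matrix(c(1.2, 0.4, 2.5, 0.7, 1.9, 0.1, 2.2, 0.3, 1.4), 3, 3)
  res <- friedman_test(m, exact = TRUE)
  expect_equal(res$p.value, oracle_block_permutation_p(m, oracle_friedman_stat))
  m4 <- matrix(rnorm(12), 4, 3)
  expect_equal(friedman_test(m4, exact = TRUE)$p.value,
               oracle_block_permutation_p(m4, oracle_friedman_stat))
})

test_that("Conover many-to-one behaves on degenerate and ordered data", {
  m <- matrix(5, 4, 3)
  res <- conover_many_to_one(m)
  expect_equal(res$statistic, c(0, 0))
  expect_equal(res$p.value, c(1, 1))
  # larger |rank-sum difference| gives smaller p, data held fixed
  m2 <- rbind(c(0, 1, 5), c(0, 2, 6), c(2, 1.5, 7), c(1, 0.5, 4))
  res2 <- conover_many_to_one(m2, control = 1)
  expect_lt(res2$p.value[2], res2$p.value[1])
  expect_equal(res2$df, rep(6L, 2))
  expect_error(conover_many_to_one(m2[, 1, drop = FALSE]), "2 conditions")
})

test_that("Conover p-values track the permutation null in rank order", {
  set.seed(11)
  m <- matrix(rnorm(12, sd = 2), 4, 3)
  m[, 3] <- m[, 3] + 2
  approx <- conover_many_to_one(m, control = 1)
  exact <- conover_many_to_one(m, control = 1, exact = TRUE)
  expect_equal(order(approx$p.value), order(exact$p.value))
  # exact mode agrees with the independently coded enumeration
  tstat <- function(mm) abs(conover_many_to_one(mm, control = 1)$statistic[1])
  expect_equal(exact$p.value[1],
               oracle_block_permutation_p(m, tstat))
})

test_that("BH adjustment follows the step-up formula and its bounds", {
  expect_equal(bh_adjust(0.05), 0.05)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(numeric(0)), "nonempty")
  set.seed(5)
  for (i in 1:20) {
    p <- runif(sample(1:12, 1))
    adj <- bh_adjust(p)
    expect_true(all(adj >= p - 1e-12))
    expect_true(all(adj <= 1))
    # direct step-up oracle: cummin (from the top) of sorted p * m / i
    m <- length(p)
    o <- order(p)
    q <- pmin(1, rev(cummin(rev(p[o] * m / seq_len(m)))))
    expect_equal(adj[o], q)
  }
})

test_that("exact Mann-Whitney matches full enumeration on small samples", {
  set.seed(21)
  for (n1 in 2:5) {
    for (n2 in 2:(10 - n1)) {
      x <- rnorm(n1); y <- rnorm(n2)
      res <- mann_whitney_exact(x, y)
      expect_equal(res$p.value, oracle_mw_exact_p(x, y),
                   info = sprintf("n1=%d n2=%d", n1, n2))
    }
  }
})

test_that("Mann-Whitney special cases behave", {
  expect_equal(mann_whitney_exact(c(3), c(3))$p.value, 1)
  # complete separation, 7 vs 6: two-sided p = 2 / choose(13, 6)
  res <- mann_whitney_exact(1:7, 8:13)
  expect_equal(res$p.value, 2 / choose(13, 6))
  expect_error(mann_whitney_exact(numeric(0), 1:3), "nonempty")
  # tied data falls back to the midrank approximation and matches wilcox.test
  x <- c(1, 2, 2, 3, 5); y <- c(2, 4, 4, 6, 7)
  res2 <- mann_whitney_exact(x, y)
  ref <- suppressWarnings(stats::wilcox.test(x, y, correct = TRUE))
  expect_equal(res2$p.value, unname(ref$p.value))
})

test_that("sample quantiles use linear interpolation on (k-1)/(n-1)", {
  expect_equal(sample_quantile(rep(4.2, 9), c(0, 0.3, 1)), rep(4.2, 3))
  expect_equal(sample_quantile(1:5, 0.5), 3)
  expect_equal(sample_quantile(1:40, 0.975), 39.025)
  expect_equal(sample_quantile(1:40, 0.025), 1.975)
  expect_error(sample_quantile(numeric(0), 0.5), "nonempty")
  expect_error(sample_quantile(1:5, 1.5), "\\[0, 1\\]")
})
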