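# Build an emm_set directly so the adjustment can be tested in isolation.
make_emm_set <- function(est, V, labels = paste0("c", seq_along(est))) {
  out <- data.frame(cell = labels, estimate = est, se = sqrt(diag(V)),
                    df = Inf)
  attr(out, "vcov") <- V
  attr(out, "factors") <- "cell"
  class(out) <- c("emm_set", "data.frame")
  out
}

test_that("identical estimates give adjusted p near 1, two cells give equality", {
  emms <- make_emm_set(c(1, 1, 1), diag(0.04, 3))
  res <- tukey_pairwise(emms)
  expect_true(all(res$adjusted_p > 0.999))
  emms2 <- make_emm_set(c(0, 1), diag(0.1, 2))
  res2 <- tukey_pairwise(emms2)
  expect_equal(res2$adjusted_p, res2$raw_p)
  expect_error(tukey_pairwise(make_emm_set(c(0, 1), matrix(c(1, 2, 2, 1), 2))),
               "positive semi-definite")
})

test_that("three-cell adjustment agrees with a Monte-Carlo max-|z| oracle", {
  emms <- make_emm_set(c(0, 0.5, 1.2), diag(0.09, 3))
  res <- tukey_pairwise(emms)
  # oracle: simulate cell-level noise directly and take the max |contrast z|
  set.seed(4242)
  B <- 2e5
  Z <- matrix(rnorm(3 * B), B, 3)
  cz <- cbind(Z[, 1] - Z[, 2], Z[, 1] - Z[, 3], Z[, 2] - Z[, 3]) / sqrt(2)
  maxz <- apply(abs(cz), 1, max)
  for (i in seq_len(nrow(res))) {
    expect_equal(res$adjusted_p[i], mean(maxz >= abs(res$z[i])),
                 tolerance = 0.02)
  }
})

test_that("adjusted p never falls below raw p and repeats are identical", {
  set.seed(77)
  for (i in 1:5) {
    k <- sample(3:6, 1)
    A <- matrix(rnorm(k * k), k)
    V <- crossprod(A) / k + diag(0.01, k)
    emms <- make_emm_set(rnorm(k), V)
    r1 <- tukey_pairwise(emms)
    expect_true(all(r1$adjusted_p >= r1$raw_p - 1e-12))
    r2 <- tukey_pairwise(emms)
    expect_identical(r1$adjusted_p, r2$adjusted_p)  # fixed internal seed
  }
})

test_that("letters separate exactly the significant pairs", {
  mk <- function(p, labels = c("A", "B", "C")) {
    pairs <- t(utils::combn(labels, 2))
    data.frame(cell_a = pairs[, 1], cell_b = pairs[, 2], adjusted_p = p,
               stringsAsFactors = FALSE)
  }
  # no significant pair
  expect_equal(unname(compact_letters(mk(c(0.9, 0.8, 0.7)), alpha = 0.05)),
               rep("a", 3))
  # only C differs from A and B
  lt <- compact_letters(mk(c(0.9, 0.01, 0.02)), alpha = 0.05)
  expect_equal(unname(lt), c("a", "a", "b"))
  # chain pattern over 4 cells: A=B, B=C, C=D but A!=C, A!=D, B!=D
  labels4 <- c("A", "B", "C", "D")
  pairs4 <- t(utils::combn(labels4, 2))
  p4 <- c(0.5, 0.01, 0.01, 0.5, 0.01, 0.5)  # AB, AC, AD, BC, BD, CD
  ct <- data.frame(cell_a = pairs4[, 1], cell_b = pairs4[, 2],
                   adjusted_p = p4, stringsAsFactors = FALSE)
  lt4 <- compact_letters(ct, alpha = 0.05, cells = labels4)
  sig_pairs <- paste(pairs4[p4 < 0.05, 1], pairs4[p4 < 0.05, 2])
  expect_true(oracle_letters_consistent(lt4, labels4, sig_pairs))
  expect_equal(unname(lt4), c("a", "ab", "bc", "c"))
})

test_that("letter displays stay consistent on random significance patterns", {
  set.seed(88)
  labels <- c("w", "x", "y", "z")
  pairs <- t(utils::combn(labels, 2))
  for (i in 1:25) {
    p <- runif(6)
    # only test patterns realizable by a transitive-ish difference structure:
    # consistency must hold for whatever pattern is supplied
    ct <- data.frame(cell_a = pairs[, 1], cell_b = pairs[, 2],
                     adjusted_p = p, stringsAsFactors = FALSE)
    lt <- compact_letters(ct, alpha = 0.4, cells = labels)
    sig <- paste(pairs[p < 0.4, 1], pairs[p < 0.4, 2])
    expect_true(oracle_letters_consistent(lt, labels, sig))
  }
})

test_that("a missing pair is an error", {
  ct <- data.frame(cell_a = "A", cell_b = "B", adjusted_p = 0.5)
  expect_error(compact_letters(ct, alpha = 0.05, cells = c("A", "B", "C")),
               "missing pair")
})
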