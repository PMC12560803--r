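mk_units <- function(counts, antagonist = "bicuculline") {
  n <- nrow(counts)
  d <- data.frame(unit = sprintf("u%03d", seq_len(n)),
                  well = "W01",
                  antagonist = rep_len(antagonist, n),
                  stringsAsFactors = FALSE)
  colnames(counts) <- paste0("seg", 1:11)
  cbind(d, as.data.frame(counts))
}

test_that("activity filter keeps exactly the units firing in both baselines", {
  cnt <- matrix(5L, 4, 11)
  cnt[1, 1] <- 0L          # silent initial baseline
  cnt[2, 4] <- 0L          # silent washout baseline
  u <- mk_units(cnt)
  kept <- filter_active_units(u)
  expect_setequal(kept$unit, c("u003", "u004"))
  expect_setequal(attr(kept, "dropped"), c("u001", "u002"))
  # randomized table equals the brute-force predicate, and is idempotent
  set.seed(9)
  cnt2 <- matrix(rpois(11 * 50, 3), 50, 11)
  u2 <- mk_units(cnt2)
  kept2 <- filter_active_units(u2)
  expect_setequal(kept2$unit, u2$unit[u2$seg1 > 0 & u2$seg4 > 0])
  expect_equal(filter_active_units(kept2)$unit, kept2$unit)
})

test_that("inclusion bounds are the 2.5th/97.5th interpolated percentiles", {
  cnt <- matrix(10L, 40, 11)
  cnt[, 1] <- 1:40
  cnt[, 4] <- 40:1
  b <- compute_inclusion_bounds(mk_units(cnt))
  expect_equal(unname(b$baseline1), c(1.975, 39.025))
  expect_equal(unname(b$baseline2), c(1.975, 39.025))
  cc <- matrix(7L, 5, 11)
  bc <- compute_inclusion_bounds(mk_units(cc))
  expect_equal(unname(bc$baseline1), c(7, 7))
  expect_error(compute_inclusion_bounds(mk_units(cnt[1, , drop = FALSE])),
               "at least 2")
})

test_that("the inclusion window is inclusive and matches the predicate", {
  cnt <- matrix(10L, 40, 11)
  cnt[, 1] <- 1:40
  u <- mk_units(cnt)
  b <- compute_inclusion_bounds(u)
  kept <- apply_inclusion(u, b)
  expect_setequal(kept$unit,
                  u$unit[u$seg1 >= 1.975 & u$seg1 <= 39.025])
  # a count exactly on an integer lower bound is retained
  cnt2 <- matrix(10L, 5, 11); cnt2[, 1] <- c(3L, 4L, 5L, 6L, 7L)
  u2 <- mk_units(cnt2)
  b2 <- list(baseline1 = c(lower = 3, upper = 6),
             baseline2 = c(lower = 0, upper = 100))
  class(b2) <- "inclusion_bounds"
  k2 <- apply_inclusion(u2, b2)
  expect_setequal(k2$seg1, 3:6)
})

test_that("pharmacological classification follows the strict two-step rule", {
  expect_equal(classify_unit(c(100, 40, 90), "bicuculline"), "GABA_A")
  expect_equal(classify_unit(c(80, 30, 60), "saclofen"), "GABA_B")
  expect_equal(classify_unit(c(100, 120, 200), "bicuculline"), "unclassified")
  expect_equal(classify_unit(c(100, 100, 200), "saclofen"), "unclassified")
  expect_equal(classify_unit(c(100, 40, 40), "bicuculline"), "unclassified")
  cnt <- rbind(c(100, 40, 90, rep(10, 8)),
               c(80, 30, 60, rep(10, 8)),
               c(50, 60, 70, rep(10, 8)))
  u <- mk_units(cnt, antagonist = c("bicuculline", "saclofen", "bicuculline"))
  cl <- classify_units(u)
  expect_equal(cl$class, c("GABA_A", "GABA_B", "unclassified"))
})

test_that("per-unit normalization produces fractions over analyzed segments", {
  expect_equal(normalize_unit(c(rep(0, 8), 10, 30, 60), segments = 9:11),
               c(0.1, 0.3, 0.6))
  v <- rep(0, 11); v[5] <- 42
  expect_equal(normalize_unit(v, segments = 4:11),
               c(0, 1, rep(0, 6)))
  expect_error(normalize_unit(rep(0, 11)), "zero total")
  set.seed(12)
  cnt <- matrix(rpois(11 * 30, 20), 30, 11)
  u <- mk_units(cnt)
  nm <- normalize_units(u)
  fr <- as.matrix(nm[, paste0("frac_seg", 4:11)])
  expect_equal(unname(rowSums(fr)), rep(1, nrow(fr)), tolerance = 1e-9)
  expect_equal(unname(fr), unname(cnt[, 4:11] / rowSums(cnt[, 4:11])))
  # zero-total units are excluded loudly, not silently
  cnt0 <- cnt; cnt0[3, 4:11] <- 0L
  expect_message(nm0 <- normalize_units(mk_units(cnt0)), "excluded")
  expect_equal(attr(nm0, "excluded_zero_total"), "u003")
})

test_that("identical profiles give a null concentration-response", {
  cnt <- matrix(rep(c(10L, 8L, 12L, rep(20L, 8)), each = 6), 6, 11)
  nm <- normalize_units(mk_units(cnt))
  res <- concentration_response(nm, class = "GABA_A")
  expect_equal(res$friedman$statistic, 0)
  expect_equal(res$friedman$p.value, 1)
  expect_true(all(res$comparisons$adjusted_p == 1))
  expect_equal(nrow(res$comparisons), 7L)
  expect_true(all(res$comparisons$adjusted_p >= res$comparisons$raw_p))
})

test_that("a top-concentration increase is detected with high power", {
  hits <- 0L
  nseed <- 25
  for (s in seq_len(nseed)) {
    cfg <- mea_sim_config(n_units = c(gabaA = 50, gabaB = 0,
                                      nonresponsive = 0, inactive = 0),
                          pfos_effects = c(1, 1, 1, 1, 1, 1.5, 1.5),
                          seed = 5000 + s)
    u <- simulate_paradigm(cfg)
    nm <- normalize_units(u)
    res <- concentration_response(nm, class = "GABA_A")
    top <- res$comparisons$adjusted_p[6:7]
    hits <- hits + (all(top < 0.05) &&
                      max(top) <= min(res$comparisons$adjusted_p[1:5]))
  }
  expect_gte(hits / nseed, 0.8)
})

test_that("the composed MEA analysis runs end to end", {
  u <- simulate_paradigm(mea_sim_config(seed = 77))
  res <- analyze_mea(u)
  expect_s3_class(res, "mea_analysis")
  expect_true(all(c("GABA_A", "GABA_B") %in% names(res$results)))
  expect_lte(res$counts["n_included"], res$counts["n_active"])
  expect_output(print(res), "Concentration-response")
})
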