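test_that("viability exclusions match the brute-force predicate", {
  cfg <- behavior_sim_config(n_per_group = 8, exclusion_rate = 0.5, seed = 71)
  tr <- simulate_trace(cfg)
  res <- exclude_invalid(tr)
  per <- stats::aggregate(tr[c("dead", "malformed", "uninflated")],
                          by = list(animal = tr$animal), FUN = any)
  bad <- per$animal[per$dead | per$malformed | per$uninflated]
  expect_setequal(unique(res$traces$animal), setdiff(per$animal, bad))
  expect_equal(unname(res$report["n_excluded"]), length(bad))

  ok <- exclude_invalid(simulate_trace(
    behavior_sim_config(n_per_group = 3, exclusion_rate = 0, seed = 1)))
  expect_equal(unname(ok$report["n_excluded"]), 0L)
  expect_equal(length(unique(ok$traces$animal)), 6L)
})

test_that("binning reproduces direct summation and conserves phase totals", {
  # constant 0.5 cm/s: every 120-s bin sums to 60 cm
  const <- expand.grid(animal = "a1", time_s = 0:3719,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  const$treatment <- "ctl"; const$distance_cm <- 0.5
  bc <- bin_distances(const)
  expect_equal(nrow(bc), 20L)
  expect_equal(bc$value, rep(60, 20))
  zc <- const; zc$distance_cm <- 0
  expect_equal(bin_distances(zc)$value, rep(0, 20))

  tr <- simulate_trace(behavior_sim_config(n_per_group = 3,
                                           exclusion_rate = 0, seed = 14))
  bins <- bin_distances(tr)
  phase_start <- c(L1 = 1200, L2 = 1800, D1 = 2400, D2 = 3000)
  for (r in sample(nrow(bins), 25)) {
    lo <- phase_start[[bins$phase[r]]] + (bins$bin[r] - 1) * 120
    sel <- tr$animal == bins$animal[r] & tr$time_s >= lo & tr$time_s < lo + 120
    expect_equal(bins$value[r], sum(tr$distance_cm[sel]), tolerance = 1e-9)
  }
  # per-phase totals conserved against direct summation
  for (a in unique(tr$animal)) {
    for (p in names(phase_start)) {
      sel <- tr$animal == a & tr$time_s >= phase_start[[p]] &
        tr$time_s < phase_start[[p]] + 600
      expect_equal(sum(bins$value[bins$animal == a & bins$phase == p]),
                   sum(tr$distance_cm[sel]), tolerance = 1e-9)
    }
  }
  # a missing second is a named error
  broken <- tr[!(tr$animal == tr$animal[1] & tr$time_s == 2500), ]
  expect_error(bin_distances(broken), "missing second\\(s\\) starting at 2500")
})

test_that("scaling constant and unit-interval mapping follow the 1.001 rule", {
  bins <- data.frame(animal = c("a1", "a1", "a2"), treatment = "ctl",
                     phase = "D1", bin = 1:3, value = c(120, 200, 80))
  expect_equal(compute_scale(bins), 200.2)
  expect_equal(compute_scale(bins[3, ]), 1.001 * 80)
  expect_error(compute_scale(bins[0, ]), "no bins")
  zero <- bins; zero$value <- 0
  expect_error(compute_scale(zero), "all bins are zero")

  sc <- scale_bins(bins, compute_scale(bins))
  expect_equal(max(sc$value_scaled), 1 / 1.001)
  expect_true(all(sc$value_scaled > 0 & sc$value_scaled < 1))
  expect_equal(order(sc$value_scaled), order(bins$value))
  z1 <- bins; z1$value[1] <- 0
  expect_equal(scale_bins(z1, 200.2)$value_scaled[1], 1e-6)
  expect_error(scale_bins(bins, 100), "exceeds")
  # per-larva alternative reading stays available
  Ml <- compute_scale(bins, per_larva = TRUE)
  expect_equal(unname(Ml), 1.001 * c(200, 80))
})

test_that("startle sums use the first three seconds after each transition", {
  tr <- simulate_trace(behavior_sim_config(n_per_group = 2,
                                           exclusion_rate = 0, seed = 3))
  vsr <- compute_vsr(tr)
  for (i in seq_len(nrow(vsr))) {
    secs <- if (vsr$startle_phase[i] == "VSR1") 1200:1202 else 2400:2402
    expect_equal(vsr$value[i],
                 sum(tr$distance_cm[tr$animal == vsr$animal[i] &
                                      tr$time_s %in% secs]),
                 tolerance = 1e-12)
  }
  expect_error(compute_vsr(tr[tr$time_s != 1201, ]), "VSR1 window")
})

test_that("phase analysis detects injected dark-phase hyperactivity", {
  hits <- 0L
  nseed <- 15
  for (s in seq_len(nseed)) {
    b <- sim_phase_bins(300 + s, n_per_group = 24, dark_shift = 1)
    res <- analyze_phases(b)
    lt <- res$letters
    distinct_dark <- all(
      vapply(c("D1", "D2"), function(p) {
        l1 <- lt$letters[lt$phase == p & lt$treatment == "PFOS"]
        l2 <- lt$letters[lt$phase == p & lt$treatment == "control"]
        !any(strsplit(l1, "")[[1]] %in% strsplit(l2, "")[[1]])
      }, logical(1)))
    hits <- hits + distinct_dark
  }
  expect_gte(hits / nseed, 0.8)
})

test_that("relabeling treatments leaves the analysis invariant", {
  b <- sim_phase_bins(401, n_per_group = 10, dark_shift = 0)
  res1 <- analyze_phases(b)
  b2 <- b
  levels(b2$treatment) <- c("groupX", "groupY")
  b2$animal <- sub("control", "groupX", sub("PFOS", "groupY", b2$animal))
  res2 <- analyze_phases(b2)
  expect_equal(unname(res1$letters$letters), unname(res2$letters$letters))
  expect_equal(res1$contrasts$adjusted_p, res2$contrasts$adjusted_p,
               tolerance = 1e-10)
})

test_that("startle analysis controls the familywise error under the null", {
  nseed <- 200
  any_sig <- logical(nseed)
  for (s in seq_len(nseed)) {
    v <- sim_vsr_records(6000 + s, n_per_group = 12)
    res <- analyze_vsr(v)
    any_sig[s] <- any(res$contrasts$adjusted_p < 0.05)
  }
  expect_lte(mean(any_sig), 0.09)
})

test_that("startle analysis detects a 3-cm shift and handles one group", {
  hits <- 0L
  nseed <- 25
  for (s in seq_len(nseed)) {
    v <- sim_vsr_records(7000 + s, n_per_group = 45, shift = 3, sigma_e = 2)
    res <- analyze_vsr(v)
    hits <- hits + all(res$contrasts$adjusted_p < 0.05)
  }
  expect_gte(hits / nseed, 0.8)

  v1 <- sim_vsr_records(3, treatments = "control")
  res1 <- suppressMessages(analyze_vsr(v1))
  expect_equal(nrow(res1$contrasts), 0L)
  expect_true(all(res1$letters$letters == "a"))
})
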