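# Independent oracles used across tests. These deliberately re-derive
# quantities by brute force (enumeration, direct summation, naive recursion)
# rather than calling package internals.

# All permutations of 1:k by naive recursion (distinct from the package's
# iterative generator).
oracle_perms <- function(k) {
  if (k == 1L) return(list(1L))
  out <- list()
  for (p in oracle_perms(k - 1L)) {
    for (pos in 0:(k - 1L)) {
      out[[length(out) + 1L]] <- append(p, k, after = pos)
    }
  }
  out
}

# Exhaustive within-block permutation p-value of a statistic on a blocks x
# conditions matrix.
oracle_block_permutation_p <- function(m, stat_fun, obs = stat_fun(m)) {
  k <- ncol(m); n <- nrow(m)
  perms <- oracle_perms(k)
  idx <- rep(1L, n)
  total <- length(perms)^n
  count <- 0L
  mm <- m
  repeat {
    for (i in seq_len(n)) mm[i, ] <- m[i, perms[[idx[i]]]]
    if (stat_fun(mm) >= obs - 1e-12) count <- count + 1L
    pos <- 1L
    while (pos <= n) {
      idx[pos] <- idx[pos] + 1L
      if (idx[pos] <= length(perms)) break
      idx[pos] <- 1L
      pos <- pos + 1L
    }
    if (pos > n) break
  }
  count / total
}

# Friedman chi-square statistic recomputed from first principles.
oracle_friedman_stat <- function(m) {
  r <- t(apply(m, 1, rank))
  n <- nrow(m); k <- ncol(m)
  ties <- unlist(lapply(seq_len(n), function(i) table(m[i, ])))
  denom <- n * k * (k + 1) - sum(ties^3 - ties) / (k - 1)
  if (denom <= 0) return(0)
  12 * sum((colSums(r) - n * (k + 1) / 2)^2) / denom
}

# Exact two-sided Mann-Whitney p by enumerating every label assignment.
oracle_mw_exact_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pool <- c(x, y)
  u_of <- function(sel) {
    r <- rank(pool)
    sum(r[sel]) - n1 * (n1 + 1) / 2
  }
  obs <- u_of(seq_len(n1))
  mu <- n1 * n2 / 2
  sels <- utils::combn(n1 + n2, n1)
  us <- apply(sels, 2, u_of)
  mean(abs(us - mu) >= abs(obs - mu) - 1e-9)
}

# Letter-display consistency: cells share a letter iff pair not significant.
oracle_letters_consistent <- function(letters, cells, sig_pairs) {
  share <- function(a, b) {
    la <- strsplit(letters[[a]], "")[[1]]
    lb <- strsplit(letters[[b]], "")[[1]]
    length(intersect(la, lb)) > 0L
  }
  for (i in seq_along(cells)) {
    for (j in seq_along(cells)) {
      if (i >= j) next
      is_sig <- paste(cells[i], cells[j]) %in% sig_pairs ||
        paste(cells[j], cells[i]) %in% sig_pairs
      if (is_sig == share(cells[i], cells[j])) return(FALSE)
    }
  }
  TRUE
}

# Small balanced beta-GAMM simulation reused by model tests.
sim_phase_bins <- function(seed, n_per_group = 24, dark_shift = 1,
                           treatments = c("control", "PFOS")) {
  eff <- matrix(0, length(treatments), 4,
                dimnames = list(treatments, c("L1", "L2", "D1", "D2")))
  if (length(treatments) > 1 && dark_shift != 0)
    eff[length(treatments), c("D1", "D2")] <- dark_shift
  b <- simulate_bins(behavior_sim_config(n_per_group = n_per_group,
                                         treatment_labels = treatments,
                                         logit_effects = eff, seed = seed))
  b$value_scaled <- b$value
  b
}

# Null VSR records: Gaussian startle values with a per-larva intercept.
sim_vsr_records <- function(seed, n_per_group = 12, shift = 0,
                            sigma_e = 2, sigma_b = 1,
                            treatments = c("control", "PFOS")) {
  set.seed(seed)
  animals <- paste0(rep(treatments, each = n_per_group), "_",
                    sequence(rep(n_per_group, length(treatments))))
  trt <- rep(treatments, each = n_per_group)
  b <- rnorm(length(animals), 0, sigma_b)
  out <- expand.grid(animal = animals, startle_phase = c("VSR1", "VSR2"),
                     stringsAsFactors = FALSE)
  out$treatment <- factor(trt[match(out$animal, animals)],
                          levels = treatments)
  mu <- 5 + b[match(out$animal, animals)] +
    ifelse(out$treatment == treatments[length(treatments)], shift, 0)
  out$value <- rnorm(nrow(out), mu, sigma_e)
  out[, c("animal", "treatment", "startle_phase", "value")]
}
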