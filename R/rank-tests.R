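#' Friedman test for complete randomized blocks
#'
#' Within-block midranks, tie-corrected chi-square statistic with
#' `df = k - 1`, and an upper-tail p-value. With fully tied blocks (no
#' information) the statistic is defined as 0 and p = 1. `exact = TRUE`
#' replaces the chi-square tail with the exact within-block permutation null
#' of the same statistic (all `k!^n` equally likely arrangements), feasible
#' for small designs only.
#'
#' @param y Numeric matrix, blocks (e.g. units) in rows, conditions in
#'   columns. Must be complete.
#' @param exact Logical; enumerate the within-block permutation null.
#' @return A list of class `rank_test` with `statistic`, `df`, `p.value`,
#'   `method`, `n` (blocks) and `k` (conditions).
#' @export
friedman_test <- function(y, exact = FALSE) {
  y <- as.matrix(y)
  if (!is.numeric(y)) stopf("'y' must be a numeric matrix")
  if (anyNA(y)) stopf("complete-block design required: 'y' contains missing cells")
  n <- nrow(y); k <- ncol(y)
  if (k < 2L) stopf("at least 2 conditions required")
  if (n < 2L) stopf("at least 2 complete blocks required")

  stat_fun <- function(m) {
    r <- t(apply(m, 1L, midrank))
    Rj <- colSums(r)
    ties <- unlist(lapply(seq_len(n), function(i) table(m[i, ])))
    denom <- n * k * (k + 1) - sum(ties^3 - ties) / (k - 1)
    if (denom <= 0) return(0)  # every block fully tied
    12 * sum((Rj - n * (k + 1) / 2)^2) / denom
  }
  stat <- stat_fun(y)
  if (exact) {
    perms <- all_permutations(k)
    n_arr <- nrow(perms)^n
    if (n_arr > 5e5) stopf("exact enumeration infeasible: %g arrangements", n_arr)
    idx <- rep(1L, n)
    count <- 0L
    m <- y
    repeat {
      for (i in seq_len(n)) m[i, ] <- y[i, perms[idx[i], ]]
      if (stat_fun(m) >= stat - 1e-12) count <- count + 1L
      pos <- 1L
      while (pos <= n) {
        idx[pos] <- idx[pos] + 1L
        if (idx[pos] <= nrow(perms)) break
        idx[pos] <- 1L
        pos <- pos + 1L
      }
      if (pos > n) break
    }
    p <- count / n_arr
    method <- "Friedman rank sum test (exact permutation null)"
  } else {
    p <- if (stat == 0 && all(apply(y, 1L, function(r) length(unique(r)) == 1L)))
      1 else stats::pchisq(stat, df = k - 1, lower.tail = FALSE)
    method <- "Friedman rank sum test (tie-corrected chi-square)"
  }
  structure(list(statistic = stat, df = k - 1L, p.value = min(p, 1),
                 method = method, n = n, k = k),
            class = "rank_test")
}

#' @export
print.rank_test <- function(x, ...) {
  cat(x$method, "\n")
  if (!is.null(x$df))
    cat(sprintf("statistic = %.4g, df = %s, p = %.4g\n",
                x$statistic, paste(x$df, collapse = ", "), x$p.value))
  else
    cat(sprintf("statistic = %.4g, p = %.4g\n", x$statistic, x$p.value))
  invisible(x)
}

#' Conover many-to-one post hoc test after Friedman
#'
#' Rank-based t statistics comparing each condition's rank sum to a
#' designated control column, with pooled tie-corrected variance and
#' `df = (n - 1) * (k - 1)`. Two-sided by default. `exact = TRUE` computes
#' per-comparison p-values from the within-block permutation null of |t|.
#'
#' @param y Numeric complete matrix, blocks x conditions.
#' @param control Index (or column name) of the control condition.
#' @param two_sided Logical; two-sided p-values (default).
#' @param exact Logical; permutation-null p-values for small designs.
#' @return Data frame with one row per non-control condition: `condition`,
#'   `statistic`, `df`, `p.value`.
#' @export
conover_many_to_one <- function(y, control = 1L, two_sided = TRUE,
                                exact = FALSE) {
  y <- as.matrix(y)
  if (!is.numeric(y) || anyNA(y)) stopf("'y' must be a complete numeric matrix")
  n <- nrow(y); k <- ncol(y)
  if (k < 2L) stopf("at least 2 conditions required")
  if (n < 2L) stopf("at least 2 complete blocks required")
  if (is.character(control)) control <- match(control, colnames(y))
  control <- as.integer(control)
  if (is.na(control) || control < 1L || control > k)
    stopf("'control' must index a column of 'y'")

  tstats <- function(m) {
    r <- t(apply(m, 1L, midrank))
    Rj <- colSums(r)
    A1 <- sum(r^2)
    C1 <- n * k * (k + 1)^2 / 4
    if (A1 - C1 <= 0) return(rep(0, k - 1L))  # fully tied blocks
    TT <- (k - 1) * sum((Rj - n * (k + 1) / 2)^2) / (A1 - C1)
    d2 <- 2 * n * (A1 - C1) * (1 - TT / (n * (k - 1))) / ((n - 1) * (k - 1))
    diffs <- Rj[-control] - Rj[control]
    if (d2 <= 0) return(ifelse(diffs == 0, 0, sign(diffs) * Inf))
    diffs / sqrt(d2)
  }
  tt <- tstats(y)
  df <- (n - 1L) * (k - 1L)
  if (exact) {
    perms <- all_permutations(k)
    n_arr <- nrow(perms)^n
    if (n_arr > 5e5) stopf("exact enumeration infeasible: %g arrangements", n_arr)
    idx <- rep(1L, n)
    count <- numeric(k - 1L)
    m <- y
    repeat {
      for (i in seq_len(n)) m[i, ] <- y[i, perms[idx[i], ]]
      tp <- tstats(m)
      count <- count + (abs(tp) >= abs(tt) - 1e-12)
      pos <- 1L
      while (pos <= n) {
        idx[pos] <- idx[pos] + 1L
        if (idx[pos] <= nrow(perms)) break
        idx[pos] <- 1L
        pos <- pos + 1L
      }
      if (pos > n) break
    }
    p <- count / n_arr
    if (!two_sided) p <- p / 2  # symmetric null
  } else {
    p <- if (two_sided) 2 * stats::pt(-abs(tt), df) else stats::pt(-abs(tt), df)
    p[tt == 0] <- if (two_sided) 1 else 0.5
  }
  conds <- colnames(y) %||% paste0("cond", seq_len(k))
  data.frame(condition = conds[-control], statistic = tt, df = df,
             p.value = pmin(p, 1), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Validating wrapper around `stats::p.adjust(method = "BH")`: inputs must
#' lie in `[0, 1]`; a single p-value is returned unchanged; the adjustment is
#' idempotent.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  check_prob(p, "p")
  stats::p.adjust(p, method = "BH")
}

#' Exact Mann-Whitney U test
#'
#' Exact two-sided p by enumeration of the null distribution of U
#' (`P(|U - n1 n2 / 2| >= observed)`, identical to the label-permutation
#' definition) when `n1 + n2 <= 20` and the pooled sample has no ties;
#' otherwise a midrank normal approximation with tie correction and
#' continuity correction.
#'
#' @param x,y Numeric samples (both nonempty).
#' @param two_sided Logical; if `FALSE`, the one-sided p in the direction of
#'   the observed shift.
#' @return A `rank_test` list with `statistic` (U for `x`), `n1`, `n2`,
#'   `p.value`, `method`.
#' @export
mann_whitney_exact <- function(x, y, two_sided = TRUE) {
  if (length(x) == 0L || length(y) == 0L) stopf("both groups must be nonempty")
  if (anyNA(c(x, y))) stopf("missing values not allowed")
  n1 <- length(x); n2 <- length(y)
  r <- midrank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  ties <- any(duplicated(c(x, y)))
  if (!ties && n1 + n2 <= 20L) {
    u_all <- 0:(n1 * n2)
    d <- stats::dwilcox(u_all, n1, n2)
    keep <- abs(u_all - mu) >= abs(U - mu) - 1e-9
    p2 <- sum(d[keep])
    p <- if (two_sided) p2 else
      sum(d[if (U >= mu) u_all >= U else u_all <= U])
    method <- "Mann-Whitney U test (exact enumeration)"
  } else {
    N <- n1 + n2
    tie_tab <- table(c(x, y))
    sigma2 <- n1 * n2 / 12 * ((N + 1) - sum(tie_tab^3 - tie_tab) / (N * (N - 1)))
    cc <- 0.5 * sign(U - mu)
    z <- if (sigma2 > 0) (U - mu - cc) / sqrt(sigma2) else 0
    p <- if (two_sided) 2 * stats::pnorm(-abs(z)) else stats::pnorm(-abs(z))
    method <- "Mann-Whitney U test (normal approximation, tie-corrected)"
  }
  structure(list(statistic = unname(U), n1 = n1, n2 = n2, df = NULL,
                 p.value = min(unname(p), 1), method = method),
            class = "rank_test")
}

#' Sample quantile by linear interpolation
#'
#' The plotting-position `p(k) = (k - 1)/(n - 1)` estimator (R's type 7),
#' used for the 2.5th/97.5th percentile inclusion bounds of the spike-count
#' pipeline.
#'
#' @param values Nonempty numeric vector.
#' @param q Probability (or vector of probabilities) in `[0, 1]`.
#' @return Numeric vector of quantiles.
#' @export
sample_quantile <- function(values, q) {
  if (length(values) == 0L) stopf("'values' must be nonempty")
  if (anyNA(values)) stopf("'values' must not contain NA")
  check_prob(q, "q")
  unname(stats::quantile(values, probs = q, type = 7, names = FALSE))
}
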