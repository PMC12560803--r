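#' Single-step Tukey-style pairwise contrasts of EMMs
#'
#' All pairwise differences (or a designated subset of pairs) between EMM
#' cells, with raw two-sided z p-values and a single-step familywise
#' adjustment: the adjusted p is the null probability that the maximum
#' absolute standardized contrast in the family exceeds the observed one,
#' computed by Monte-Carlo integration over the estimated contrast
#' correlation (1e5 draws under a fixed internal seed; the caller's RNG
#' state is untouched). Valid for unbalanced families where the classic
#' studentized-range shortcut is not. With a single pair the adjusted p
#' equals the raw p exactly.
#'
#' @param emms An `emm_set` from [estimate_emms()].
#' @param alpha Familywise significance level (stored on the result).
#' @param pairs Optional 2-column integer matrix of cell-row pairs defining
#'   the family; default all pairs.
#' @param nsim Monte-Carlo draws (default 1e5).
#' @return A `tukey_contrasts` data frame: `cell_a`, `cell_b`, `estimate`,
#'   `se`, `z`, `raw_p`, `adjusted_p` (always `>= raw_p`). Cell labels and
#'   `alpha` are attached as attributes.
#' @export
tukey_pairwise <- function(emms, alpha = 0.05, pairs = NULL, nsim = 1e5) {
  stopifnot(inherits(emms, "emm_set"))
  if (alpha <= 0 || alpha >= 1) stopf("'alpha' must be in (0, 1)")
  S <- attr(emms, "vcov")
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1))
    stopf("EMM covariance is not positive semi-definite")
  labels <- emm_cell_labels(emms)
  m <- nrow(emms)
  if (m < 2L && is.null(pairs)) stopf("at least 2 cells required")
  if (is.null(pairs)) pairs <- t(utils::combn(m, 2L))
  pairs <- matrix(as.integer(pairs), ncol = 2L)
  empty <- data.frame(cell_a = character(0), cell_b = character(0),
                      estimate = numeric(0), se = numeric(0), z = numeric(0),
                      raw_p = numeric(0), adjusted_p = numeric(0),
                      stringsAsFactors = FALSE)
  if (nrow(pairs) == 0L) {
    out <- empty
  } else {
    D <- matrix(0, nrow(pairs), m)
    D[cbind(seq_len(nrow(pairs)), pairs[, 1])] <- 1
    D[cbind(seq_len(nrow(pairs)), pairs[, 2])] <- -1
    est <- drop(D %*% emms$estimate)
    Vd <- D %*% S %*% t(D)
    se <- sqrt(pmax(diag(Vd), 0))
    z <- ifelse(se > 0, est / se, 0)
    raw <- 2 * stats::pnorm(-abs(z))
    if (nrow(pairs) == 1L) {
      adj <- raw
    } else {
      R <- stats::cov2cor(Vd + diag(1e-12 * max(diag(Vd), 1), nrow(Vd)))
      maxz <- with_seed(20240601L, max_abs_z_null(R, nsim))
      adj <- vapply(abs(z), function(zz) mean(maxz >= zz), numeric(1))
      adj <- pmin(pmax(adj, raw), 1)
    }
    out <- data.frame(cell_a = labels[pairs[, 1]], cell_b = labels[pairs[, 2]],
                      estimate = est, se = se, z = z, raw_p = raw,
                      adjusted_p = adj, stringsAsFactors = FALSE)
  }
  attr(out, "cells") <- labels
  attr(out, "alpha") <- alpha
  attr(out, "adjustment") <- "single-step max-|z| (Monte-Carlo, 1e5 draws)"
  class(out) <- c("tukey_contrasts", "data.frame")
  out
}

# Null distribution of the maximum absolute standardized contrast for a
# (possibly singular) correlation matrix R, via its eigendecomposition.
max_abs_z_null <- function(R, nsim) {
  e <- eigen(R, symmetric = TRUE)
  pos <- pmax(e$values, 0)
  A <- e$vectors %*% diag(sqrt(pos), length(pos))
  Z <- matrix(stats::rnorm(nsim * length(pos)), nsim)
  apply(abs(Z %*% t(A)), 1, max)
}

#' Compact letter display from adjusted pairwise contrasts
#'
#' Insert-and-absorb letter assignment: two cells share at least one letter
#' exactly when their adjusted p-value is `>= alpha`. Every unordered pair
#' of the requested cells must be present among the contrasts.
#'
#' @param contrasts A `tukey_contrasts` data frame (or any data frame with
#'   `cell_a`, `cell_b`, `adjusted_p`).
#' @param alpha Significance level; defaults to the level stored on
#'   `contrasts`, else 0.05.
#' @param cells Character vector of cell labels to letter; defaults to the
#'   labels appearing in `contrasts` (or stored on it).
#' @return Named character vector of letter strings, one per cell.
#' @export
compact_letters <- function(contrasts, alpha = NULL, cells = NULL) {
  alpha <- alpha %||% attr(contrasts, "alpha") %||% 0.05
  cells <- cells %||% unique(c(contrasts$cell_a, contrasts$cell_b))
  if (length(cells) == 0L) stopf("no cells to letter")
  if (length(cells) == 1L) return(stats::setNames("a", cells))
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  have <- key(contrasts$cell_a, contrasts$cell_b)
  need <- utils::combn(sort(cells), 2L)
  need_key <- key(need[1, ], need[2, ])
  missing <- setdiff(need_key, have)
  if (length(missing))
    stopf("missing pair(s): %s", paste(utils::head(missing, 5), collapse = "; "))
  padj <- stats::setNames(contrasts$adjusted_p, have)

  groups <- list(cells)
  sig <- need[, padj[need_key] < alpha, drop = FALSE]
  if (ncol(sig)) {
    for (j in seq_len(ncol(sig))) {
      a <- sig[1, j]; b <- sig[2, j]
      new_groups <- list()
      for (g in groups) {
        if (a %in% g && b %in% g) {
          new_groups <- c(new_groups, list(setdiff(g, a)), list(setdiff(g, b)))
        } else {
          new_groups <- c(new_groups, list(g))
        }
      }
      # absorb: drop any group contained in another
      keep <- rep(TRUE, length(new_groups))
      for (i in seq_along(new_groups)) {
        for (l in seq_along(new_groups)) {
          if (i != l && keep[i] &&
              all(new_groups[[i]] %in% new_groups[[l]]) &&
              (length(new_groups[[i]]) < length(new_groups[[l]]) || i > l)) {
            keep[i] <- FALSE
          }
        }
      }
      groups <- unique(new_groups[keep])
      groups <- groups[lengths(groups) > 0L]
    }
  }
  # order groups by the position of their first member for stable letters
  first_pos <- vapply(groups, function(g) min(match(g, cells)), numeric(1))
  groups <- groups[order(first_pos)]
  lab <- vapply(cells, function(cl) {
    paste(letters[which(vapply(groups, function(g) cl %in% g, logical(1)))],
          collapse = "")
  }, character(1))
  stats::setNames(lab, cells)
}
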