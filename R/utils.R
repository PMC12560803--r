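# Internal helpers shared across modules.

stopf <- function(...) stop(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the seed, evaluates `expr`, and restores the caller's RNG state so
#' package-internal randomization (e.g. the Monte-Carlo multiplicity
#' adjustment) never perturbs user-level reproducibility.
#'
#' @param seed Integer seed, or `NULL` to use the current RNG stream.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# All permutations of 1:k as a k! x k integer matrix (k small; used by the
# exact modes of the rank tests).
all_permutations <- function(k) {
  if (k == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(k - 1L)
  out <- matrix(0L, nrow(sub) * k, k)
  row <- 1L
  for (i in seq_len(k)) {
    for (j in seq_len(nrow(sub))) {
      rest <- seq_len(k)[-i]
      out[row, ] <- c(i, rest[sub[j, ]])
      row <- row + 1L
    }
  }
  out
}

# Midranks within a vector (average ranks for ties).
midrank <- function(x) rank(x, ties.method = "average")

check_prob <- function(p, what = "p") {
  if (length(p) == 0L) stopf("'%s' must be nonempty", what)
  if (anyNA(p) || !is.numeric(p)) stopf("'%s' must be numeric without NA", what)
  if (any(p < 0 | p > 1)) stopf("'%s' values must lie in [0, 1]", what)
  invisible(p)
}
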