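#' Estimated marginal means over the factor grid
#'
#' Evaluates the fitted linear predictor for every factor-level cell
#' (e.g. concentration x phase), with any time smooth averaged over the
#' observed time grid and the random intercept set to zero, and standard
#' errors by the delta method from the coefficient covariance. Inference
#' uses the normal (z) approximation, appropriate for penalized fits.
#'
#' @param fit A `beta_gamm` or `gaussian_lmm` object.
#' @param cells Optional data frame of factor-level combinations to
#'   evaluate; defaults to the full crossing of the fitted factor levels. A
#'   level absent from the design is an error.
#' @return An `emm_set` data frame: one row per cell with the factor
#'   columns, `estimate` (logit scale for the beta model, response scale for
#'   the Gaussian one), `se`, and `df` (`Inf`, z approximation). The full
#'   covariance of the EMM vector and the averaging matrix are attached as
#'   attributes for downstream contrasts.
#' @export
estimate_emms <- function(fit, cells = NULL) UseMethod("estimate_emms")

#' @export
estimate_emms.beta_gamm <- function(fit, cells = NULL) {
  spec <- fit$metadata$spec
  gam <- fit$engine_fit
  if (!fit$converged)
    warning("computing EMMs from a non-converged fit", call. = FALSE)
  xlev <- fit$metadata$xlevels
  grid <- build_grid(cells, xlev)

  smooth_var <- if (!is.null(spec$smooth)) names(spec$smooth)[1] else NULL
  times <- if (!is.null(smooth_var)) sort(unique(gam$model[[smooth_var]])) else 0
  nt <- length(times)

  L <- matrix(0, nrow(grid), length(stats::coef(gam)),
              dimnames = list(NULL, names(stats::coef(gam))))
  re_level <- levels(gam$model[[spec$random]])[1]
  for (i in seq_len(nrow(grid))) {
    nd <- grid[rep(i, nt), , drop = FALSE]
    if (!is.null(smooth_var)) nd[[smooth_var]] <- times
    nd[[spec$random]] <- factor(re_level, levels = levels(gam$model[[spec$random]]))
    Xp <- stats::predict(gam, newdata = nd, type = "lpmatrix",
                         exclude = sprintf("s(%s)", spec$random))
    L[i, ] <- colMeans(Xp)
  }
  finish_emms(grid, L, stats::coef(gam), fit$coef_covariance)
}

#' @export
estimate_emms.gaussian_lmm <- function(fit, cells = NULL) {
  spec <- fit$metadata$spec
  if (!fit$converged)
    warning("computing EMMs from a non-converged fit", call. = FALSE)
  xlev <- fit$metadata$xlevels
  grid <- build_grid(cells, xlev)
  for (f in names(xlev)) grid[[f]] <- factor(grid[[f]], levels = xlev[[f]])
  tt <- stats::delete.response(stats::terms(fit$metadata$fixed_formula))
  L <- stats::model.matrix(tt, grid,
                           xlev = xlev[intersect(names(xlev), all.vars(tt))])
  finish_emms(grid, L, fit$fixed_coefficients, fit$coef_covariance)
}

build_grid <- function(cells, xlev) {
  if (is.null(cells)) {
    grid <- expand.grid(xlev, stringsAsFactors = FALSE,
                        KEEP.OUT.ATTRS = FALSE)
  } else {
    grid <- as.data.frame(cells)
    missing <- setdiff(names(xlev), names(grid))
    if (length(missing))
      stopf("'cells' lacks factor column(s): %s", paste(missing, collapse = ", "))
    for (f in names(xlev)) {
      bad <- setdiff(unique(as.character(grid[[f]])), xlev[[f]])
      if (length(bad))
        stopf("cell level(s) absent from design for '%s': %s", f,
              paste(bad, collapse = ", "))
    }
  }
  for (f in names(xlev)) grid[[f]] <- factor(grid[[f]], levels = xlev[[f]])
  grid
}

finish_emms <- function(grid, L, beta, V) {
  beta <- beta[colnames(L)]
  Vs <- V[colnames(L), colnames(L), drop = FALSE]
  est <- drop(L %*% beta)
  Semm <- L %*% Vs %*% t(L)
  out <- cbind(grid,
               data.frame(estimate = est, se = sqrt(pmax(diag(Semm), 0)),
                          df = Inf))
  attr(out, "L") <- L
  attr(out, "vcov") <- Semm
  attr(out, "factors") <- names(grid)
  class(out) <- c("emm_set", "data.frame")
  out
}

#' Cell labels for an EMM grid
#' @param emms An `emm_set`.
#' @return Character vector, one label per cell (`level1.level2`).
#' @keywords internal
emm_cell_labels <- function(emms) {
  facs <- attr(emms, "factors")
  do.call(paste, c(lapply(facs, function(f) as.character(emms[[f]])),
                   sep = "."))
}
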