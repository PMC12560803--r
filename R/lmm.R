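#' Fit the Gaussian random-intercept model for startle responses
#'
#' REML fit of `response ~ factors (+ interactions) + (1 | group)` via
#' [lme4::lmer()]. Used for the visual startle response, where the summed
#' 3-s distances are modeled on their raw scale with a Gaussian error term.
#'
#' @param data Data frame with the response, fixed factors and grouping
#'   factor.
#' @param spec A [model_spec()] with `family = "gaussian"` and no smooth.
#' @return An object of class `gaussian_lmm` with fixed coefficients, the
#'   random-intercept SD, residual SD, fixed-coefficient covariance, a
#'   convergence flag, and metadata.
#' @details A rank-deficient fixed-effect design is an error that names the
#'   aliased columns rather than silently dropping them.
#' @export
fit_gaussian_lmm <- function(data, spec) {
  stopifnot(inherits(spec, "model_spec"))
  if (spec$family != "gaussian") stopf("spec family must be 'gaussian'")
  if (!is.null(spec$smooth))
    stopf("the Gaussian mixed model supports no smooth terms")
  data <- validate_model_data(data, spec)

  xlevels <- lapply(data[spec$factors], levels)
  fit_spec <- drop_constant_factors(spec, data)
  fixed_rhs <- c("1", fit_spec$factors,
                 vapply(fit_spec$interactions, paste, character(1),
                        collapse = ":"))
  fixed_fml <- stats::as.formula(
    paste(spec$response, "~", paste(fixed_rhs, collapse = " + ")),
    env = globalenv())
  X <- stats::model.matrix(fixed_fml, data)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stopf("singular fixed-effect design; aliased column(s): %s",
          paste(aliased, collapse = ", "))
  }

  fml <- spec_formula(fit_spec, "lme4")
  fit <- lme4::lmer(fml, data = data, REML = TRUE)
  converged <- is.null(fit@optinfo$conv$lme4$code) &&
    (fit@optinfo$conv$opt == 0)

  vc <- as.data.frame(lme4::VarCorr(fit))
  random_sd <- vc$sdcor[vc$grp == spec$random & vc$var1 == "(Intercept)"]

  structure(list(
    engine_fit = fit,
    fixed_coefficients = lme4::fixef(fit),
    random_sd = unname(random_sd),
    residual_sd = stats::sigma(fit),
    coef_covariance = as.matrix(stats::vcov(fit)),
    converged = converged,
    metadata = list(spec = spec, method = "REML", xlevels = xlevels,
                    dropped_factors = attr(fit_spec, "dropped_factors"),
                    fixed_formula = fixed_fml)),
    class = "gaussian_lmm")
}

#' @export
print.gaussian_lmm <- function(x, ...) {
  cat("Gaussian linear mixed model (REML)\n")
  cat(sprintf("  random-intercept SD: %.3f   residual SD: %.3f   converged: %s\n",
              x$random_sd, x$residual_sd, x$converged))
  cat("Fixed coefficients:\n")
  print(round(x$fixed_coefficients, 4))
  invisible(x)
}
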