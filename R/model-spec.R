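#' Specify a mixed model for assay responses
#'
#' Describes the model both pipelines fit: a response on the open unit
#' interval (beta family, logit link) or on the real line (Gaussian, identity
#' link), optional penalized smooths, categorical fixed factors with optional
#' two-way interactions, and exactly one random-intercept grouping factor
#' (the larva).
#'
#' @param response Name of the response column.
#' @param smooth Named list of smooth terms, e.g.
#'   `list(time = list(k = 10, m = 2))` for a cubic P-spline in `time` with
#'   basis size `k` and difference-penalty order `m`. `NULL` for no smooth.
#' @param factors Character vector of categorical fixed-effect column names
#'   (e.g. treatment/concentration and phase).
#' @param interactions List of character pairs naming two-way interactions;
#'   every factor in an interaction must appear in `factors`.
#' @param random Name of the random-intercept grouping factor (exactly one).
#' @param family `"beta"` (logit link, precision parameterization
#'   `y ~ Beta(mu * phi, (1 - mu) * phi)`) or `"gaussian"`.
#' @param ar1 Logical; apply an AR(1) working-correlation variance inflation
#'   to the coefficient covariance of a beta fit (default `FALSE`). Recorded
#'   in the fit metadata either way.
#'
#' @return An object of class `model_spec`.
#' @examples
#' model_spec("value_scaled",
#'   smooth = list(time = list(k = 10, m = 2)),
#'   factors = c("treatment", "phase"),
#'   interactions = list(c("treatment", "phase")),
#'   random = "animal", family = "beta")
#' @export
model_spec <- function(response, smooth = NULL, factors, interactions = list(),
                       random, family = c("beta", "gaussian"), ar1 = FALSE) {
  family <- match.arg(family)
  if (!is.character(response) || length(response) != 1L)
    stopf("'response' must be a single column name")
  if (!is.character(factors) || length(factors) < 1L)
    stopf("at least one fixed factor is required")
  if (!is.character(random) || length(random) != 1L)
    stopf("exactly one random-intercept factor is required")
  if (!is.null(smooth)) {
    if (!is.list(smooth) || is.null(names(smooth)) || any(names(smooth) == ""))
      stopf("'smooth' must be a named list of terms")
    for (nm in names(smooth)) {
      trm <- smooth[[nm]]
      k <- trm$k %||% 10L
      m <- trm$m %||% 2L
      if (k < 4) stopf("smooth basis size for '%s' must be >= 4 (got %s)", nm, k)
      if (m < 1) stopf("smooth penalty order for '%s' must be >= 1", nm)
      smooth[[nm]] <- list(k = as.integer(k), m = as.integer(m))
    }
  }
  if (length(interactions)) {
    for (ia in interactions) {
      if (!is.character(ia) || length(ia) != 2L)
        stopf("each interaction must name exactly two factors")
      missing <- setdiff(ia, factors)
      if (length(missing))
        stopf("interaction factor(s) not in 'factors': %s",
              paste(missing, collapse = ", "))
    }
  }
  structure(
    list(response = response, smooth = smooth, factors = factors,
         interactions = interactions, random = random, family = family,
         ar1 = isTRUE(ar1)),
    class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  sm <- if (is.null(x$smooth)) "none" else
    paste(vapply(names(x$smooth), function(nm)
      sprintf("s(%s, k=%d, m=%d)", nm, x$smooth[[nm]]$k, x$smooth[[nm]]$m),
      character(1)), collapse = " + ")
  ia <- if (!length(x$interactions)) "none" else
    paste(vapply(x$interactions, paste, character(1), collapse = ":"),
          collapse = ", ")
  cat("Model spec (", x$family, " family)\n",
      "  response:     ", x$response, "\n",
      "  smooth:       ", sm, "\n",
      "  factors:      ", paste(x$factors, collapse = ", "), "\n",
      "  interactions: ", ia, "\n",
      "  random:       (1 | ", x$random, ")\n", sep = "")
  invisible(x)
}

# Drop single-level factors (and interactions touching them) from a spec;
# a one-concentration run still fits, with the constant terms absorbed by
# the intercept. Returns the reduced spec with the dropped names attached.
drop_constant_factors <- function(spec, data) {
  keep <- vapply(spec$factors, function(f) nlevels(data[[f]]) >= 2L, logical(1))
  dropped <- spec$factors[!keep]
  if (length(dropped)) {
    spec$factors <- spec$factors[keep]
    spec$interactions <- Filter(function(ia) all(ia %in% spec$factors),
                                spec$interactions)
    if (!length(spec$factors)) spec$factors <- character(0)
  }
  attr(spec, "dropped_factors") <- dropped
  spec
}

# Right-hand side of the fixed/smooth part of the model formula.
spec_formula <- function(spec, engine = c("mgcv", "lme4")) {
  engine <- match.arg(engine)
  terms <- character(0)
  if (!is.null(spec$smooth) && engine == "mgcv") {
    terms <- c(terms, vapply(names(spec$smooth), function(nm)
      sprintf("s(%s, bs = \"ps\", k = %d, m = %d)",
              nm, spec$smooth[[nm]]$k, spec$smooth[[nm]]$m), character(1)))
  }
  terms <- c(terms, spec$factors)
  if (length(spec$interactions))
    terms <- c(terms, vapply(spec$interactions, paste, character(1),
                             collapse = ":"))
  rand <- switch(engine,
                 mgcv = sprintf("s(%s, bs = \"re\")", spec$random),
                 lme4 = sprintf("(1 | %s)", spec$random))
  rhs <- paste(c("1", terms, rand), collapse = " + ")
  stats::as.formula(paste(spec$response, "~", rhs), env = globalenv())
}
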