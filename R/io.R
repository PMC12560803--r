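#' Read a locomotion trace CSV
#'
#' Validates the long-format trace export: required columns, nonnegative
#' distances, no duplicated (animal, time) records; offending rows are
#' reported by line number (header = line 1).
#'
#' @param path CSV with columns `experiment, animal, treatment, time_s,
#'   distance_cm, dead, malformed, uninflated`.
#' @return Typed data frame of traces.
#' @export
read_trace_table <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("experiment", "animal", "treatment", "time_s", "distance_cm",
              "dead", "malformed", "uninflated")
  missing <- setdiff(needed, names(d))
  if (length(missing))
    stopf("%s: missing column(s): %s", path, paste(missing, collapse = ", "))
  if (!is.numeric(d$time_s) || !is.numeric(d$distance_cm))
    stopf("%s: 'time_s' and 'distance_cm' must be numeric", path)
  bad <- which(d$distance_cm < 0)
  if (length(bad))
    stopf("%s: negative distance at line %d", path, bad[1] + 1L)
  dup <- which(duplicated(d[, c("animal", "time_s")]))
  if (length(dup))
    stopf("%s: duplicated (animal, time) record at line %d", path, dup[1] + 1L)
  for (f in c("dead", "malformed", "uninflated")) d[[f]] <- as.logical(d[[f]])
  if (anyNA(d[, c("dead", "malformed", "uninflated")]))
    stopf("%s: viability flags must be TRUE/FALSE", path)
  d
}

#' Write a locomotion trace CSV
#' @param traces Trace data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trace_table <- function(traces, path) {
  utils::write.csv(traces, path, row.names = FALSE)
  invisible(path)
}

#' Read an MEA spike-count CSV
#'
#' Validates the post-sorting export: required columns, integer
#' nonnegative counts, known antagonist labels; offending rows are
#' reported by line number.
#'
#' @param path CSV with columns `unit, well, antagonist, seg1..seg11`.
#' @return Typed unit table.
#' @export
read_spike_table <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("unit", "well", "antagonist", seg_cols())
  missing <- setdiff(needed, names(d))
  if (length(missing))
    stopf("%s: missing column(s): %s", path, paste(missing, collapse = ", "))
  bad_lab <- which(!d$antagonist %in% c("bicuculline", "saclofen"))
  if (length(bad_lab))
    stopf("%s: unknown antagonist label at line %d", path, bad_lab[1] + 1L)
  for (sc in seg_cols()) {
    v <- d[[sc]]
    if (!is.numeric(v) || anyNA(v))
      stopf("%s: column '%s' must be numeric without NA", path, sc)
    bad <- which(v < 0 | v != round(v))
    if (length(bad))
      stopf("%s: non-integer or negative count in '%s' at line %d",
            path, sc, bad[1] + 1L)
    d[[sc]] <- as.integer(round(v))
  }
  d
}

#' Write an MEA spike-count CSV
#' @param units Unit table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spike_table <- function(units, path) {
  utils::write.csv(units, path, row.names = FALSE)
  invisible(path)
}

# ---- result serialization ------------------------------------------------

serialize_spec <- function(spec) {
  list(response = spec$response,
       smooth = lapply(spec$smooth, function(s) s[c("k", "m")]),
       factors = spec$factors,
       interactions = lapply(spec$interactions, identity),
       random = spec$random, family = spec$family, ar1 = spec$ar1)
}

results_payload <- function(x, ...) UseMethod("results_payload")

#' @export
results_payload.phase_analysis <- function(x, ...) {
  list(analysis = "light_dark_phases",
       model = serialize_spec(x$fit$metadata$spec),
       converged = x$converged,
       precision_phi = x$fit$precision,
       random_sd = x$fit$random_sd,
       rho_lag1 = x$fit$metadata$rho_lag1,
       ar1_applied = x$fit$metadata$ar1_applied,
       fixed_coefficients = as.list(x$fit$fixed_coefficients),
       emms = if (x$converged) as.data.frame(x$emms) else NULL,
       contrasts = if (x$converged) as.data.frame(x$contrasts) else NULL,
       letters = x$letters, alpha = x$alpha)
}

#' @export
results_payload.vsr_analysis <- function(x, ...) {
  list(analysis = "visual_startle_response",
       model = serialize_spec(x$fit$metadata$spec),
       converged = x$converged,
       random_sd = x$fit$random_sd,
       residual_sd = x$fit$residual_sd,
       fixed_coefficients = as.list(x$fit$fixed_coefficients),
       emms = as.data.frame(x$emms),
       contrasts = as.data.frame(x$contrasts),
       letters = x$letters, alpha = x$alpha)
}

#' @export
results_payload.mea_analysis <- function(x, ...) {
  list(analysis = "mea_concentration_response",
       bounds = lapply(unclass(x$bounds), as.list),
       unit_counts = as.list(x$counts),
       class_table = as.list(table(x$classified$class)),
       results = lapply(x$results, function(r)
         list(unit_class = r$unit_class, n_units = r$n_units,
              friedman = r$friedman[c("statistic", "df", "p.value")],
              comparisons = r$comparisons)))
}

#' Serialize an analysis result to JSON
#'
#' Writes the result with full provenance (package version, seed, run
#' configuration) so a run can be reproduced exactly. Output contains no
#' timestamps: identical inputs give byte-identical files.
#'
#' @param result A `phase_analysis`, `vsr_analysis` or `mea_analysis`.
#' @param path Output JSON path.
#' @param seed Seed used for the run (recorded).
#' @param config Optional named list of run configuration switches.
#' @return `path`, invisibly.
#' @export
save_results_json <- function(result, path, seed = NULL, config = NULL) {
  payload <- list(
    package = "larvastat",
    version = as.character(utils::packageVersion("larvastat")),
    seed = seed,
    config = config,
    result = results_payload(result))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
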