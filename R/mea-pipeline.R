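#' Annotated 11-segment recording paradigm
#'
#' @return Data frame with one row per recording segment: segment number,
#'   condition annotation, and the PFOS concentration (µM; 0 for the
#'   washout baseline that serves as the comparison reference, NA for the
#'   classification segments).
#' @export
recording_paradigm <- function() {
  data.frame(
    segment = 1:11,
    condition = c("baseline1", "GABA 10 uM", "antagonist", "baseline2 (0 uM)",
                  paste0("PFOS ", pfos_concentrations(), " uM")),
    pfos_uM = c(NA, NA, NA, 0, pfos_concentrations()),
    stringsAsFactors = FALSE)
}

seg_cols <- function() paste0("seg", 1:11)

check_unit_table <- function(units) {
  needed <- c("unit", "antagonist", seg_cols())
  missing <- setdiff(needed, names(units))
  if (length(missing))
    stopf("unit table lacks column(s): %s", paste(missing, collapse = ", "))
  invisible(units)
}

#' Drop units silent in either baseline
#'
#' A unit is retained only if it fired in both the initial baseline
#' (segment 1) and the post-washout baseline (segment 4), i.e.
#' `seg1 > 0 & seg4 > 0`.
#'
#' @param units Unit table (`unit`, `antagonist`, `seg1`..`seg11`).
#' @return The retained rows; dropped unit ids attached as attribute
#'   `"dropped"`.
#' @export
filter_active_units <- function(units) {
  check_unit_table(units)
  keep <- units$seg1 > 0 & units$seg4 > 0
  out <- units[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped") <- units$unit[!keep]
  out
}

#' Percentile inclusion bounds from baseline spike counts
#'
#' Nonparametric 95% inclusion window: the 2.5th and 97.5th sample
#' percentiles (linear interpolation, [sample_quantile()]) of the segment-1
#' and segment-4 counts of the activity-filtered units, computed
#' separately per baseline.
#'
#' @param units Activity-filtered unit table (>= 2 units).
#' @return An `inclusion_bounds` list with `baseline1` and `baseline2`,
#'   each `c(lower, upper)`.
#' @export
compute_inclusion_bounds <- function(units) {
  check_unit_table(units)
  if (nrow(units) < 2L) stopf("at least 2 retained units required")
  b1 <- sample_quantile(units$seg1, c(0.025, 0.975))
  b4 <- sample_quantile(units$seg4, c(0.025, 0.975))
  structure(list(baseline1 = c(lower = b1[1], upper = b1[2]),
                 baseline2 = c(lower = b4[1], upper = b4[2])),
            class = "inclusion_bounds")
}

#' @export
print.inclusion_bounds <- function(x, ...) {
  cat(sprintf("Inclusion window baseline 1 (seg1): [%.3f, %.3f]\n",
              x$baseline1[1], x$baseline1[2]))
  cat(sprintf("Inclusion window baseline 2 (seg4): [%.3f, %.3f]\n",
              x$baseline2[1], x$baseline2[2]))
  invisible(x)
}

#' Apply the percentile inclusion window
#'
#' Retains units whose segment-1 count lies inside the baseline-1 window
#' AND whose segment-4 count lies inside the baseline-2 window, both
#' inclusive; integer counts are compared to the interpolated bounds
#' without rounding.
#'
#' @param units Unit table.
#' @param bounds An [compute_inclusion_bounds()] result.
#' @return The retained rows.
#' @export
apply_inclusion <- function(units, bounds) {
  check_unit_table(units)
  stopifnot(inherits(bounds, "inclusion_bounds"))
  keep <- units$seg1 >= bounds$baseline1["lower"] &
    units$seg1 <= bounds$baseline1["upper"] &
    units$seg4 >= bounds$baseline2["lower"] &
    units$seg4 <= bounds$baseline2["upper"]
  out <- units[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify one unit by its agonist/antagonist response
#'
#' GABAergic pharmacological typing: spiking must strictly decrease from
#' the initial baseline to the GABA segment (`seg2 < seg1`) and strictly
#' increase from the GABA segment to the antagonist segment
#' (`seg3 > seg2`). A unit passing both in a bicuculline well is GABA_A,
#' in a saclofen well GABA_B; otherwise it is unclassified. Ties fail the
#' strict comparisons (conservative, deterministic).
#'
#' @param counts Numeric vector of at least the first three segment counts.
#' @param antagonist `"bicuculline"` or `"saclofen"`.
#' @return `"GABA_A"`, `"GABA_B"` or `"unclassified"`.
#' @export
classify_unit <- function(counts, antagonist) {
  if (length(counts) < 3L) stopf("segments 1-3 required for classification")
  antagonist <- match.arg(antagonist, c("bicuculline", "saclofen"))
  if (counts[2] < counts[1] && counts[3] > counts[2]) {
    if (antagonist == "bicuculline") "GABA_A" else "GABA_B"
  } else "unclassified"
}

#' Classify every unit of a table
#'
#' Vectorized [classify_unit()] over the rows of a unit table.
#'
#' @param units Unit table.
#' @return `units` with an added `class` column.
#' @export
classify_units <- function(units) {
  check_unit_table(units)
  bad <- setdiff(unique(units$antagonist), c("bicuculline", "saclofen"))
  if (length(bad))
    stopf("unknown antagonist label(s): %s", paste(bad, collapse = ", "))
  responsive <- units$seg2 < units$seg1 & units$seg3 > units$seg2
  units$class <- ifelse(!responsive, "unclassified",
                        ifelse(units$antagonist == "bicuculline",
                               "GABA_A", "GABA_B"))
  units
}

#' Normalize one unit's counts to per-unit fractions
#'
#' Divides each analyzed segment's count by the unit's total over the
#' analyzed segments (default 4-11: the washout baseline plus the seven
#' PFOS segments, the segments entering the statistical comparison).
#'
#' @param counts Numeric vector of the 11 segment counts.
#' @param segments Indices of the analyzed segments (default `4:11`).
#' @return Fractions summing to 1 over `segments`.
#' @export
normalize_unit <- function(counts, segments = 4:11) {
  if (length(counts) < max(segments)) stopf("count vector too short")
  tot <- sum(counts[segments])
  if (tot <= 0) stopf("zero total over analyzed segments: unit must be excluded")
  counts[segments] / tot
}

#' Normalize all units of a table
#'
#' Applies [normalize_unit()] per row; units with a zero total over the
#' analyzed segments are excluded with their ids recorded (never silently).
#'
#' @param units Unit table (typically classified and filtered).
#' @param segments Analyzed segment indices (default `4:11`).
#' @return Data frame with `unit`, `antagonist`, optional `class`, and one
#'   `frac_segK` column per analyzed segment; excluded unit ids attached as
#'   attribute `"excluded_zero_total"`.
#' @export
normalize_units <- function(units, segments = 4:11) {
  check_unit_table(units)
  cnt <- as.matrix(units[, seg_cols()])
  tot <- rowSums(cnt[, segments, drop = FALSE])
  keep <- tot > 0
  if (any(!keep))
    message(sum(!keep), " unit(s) excluded: zero total over analyzed segments")
  frac <- cnt[keep, segments, drop = FALSE] / tot[keep]
  colnames(frac) <- paste0("frac_seg", segments)
  meta_cols <- intersect(c("unit", "well", "antagonist", "true_type", "class"),
                         names(units))
  out <- cbind(units[keep, meta_cols, drop = FALSE], as.data.frame(frac))
  rownames(out) <- NULL
  attr(out, "segments") <- segments
  attr(out, "excluded_zero_total") <- units$unit[!keep]
  out
}

#' Concentration-response test on normalized counts
#'
#' Friedman test across the eight paired conditions (0 µM washout baseline
#' plus the seven PFOS concentrations) over the units of one
#' pharmacological class, followed by Conover many-to-one comparisons of
#' each concentration against 0 µM and Benjamini-Hochberg adjustment of
#' the seven control-comparison p-values.
#'
#' @param normalized Output of [normalize_units()] (segments must include
#'   4-11), restricted to one class, with >= 2 units.
#' @param class Label stored on the result (e.g. `"GABA_A"`).
#' @return A `concentration_response` list: `unit_class`, `n_units`,
#'   `friedman` (a `rank_test`), and `comparisons` (7 rows:
#'   `concentration_uM`, `statistic`, `df`, `raw_p`, `adjusted_p`).
#' @export
concentration_response <- function(normalized, class = "all") {
  segs <- attr(normalized, "segments") %||% 4:11
  if (!all(4:11 %in% segs))
    stopf("analysis needs segments 4-11 among the normalized segments")
  cols <- paste0("frac_seg", 4:11)
  missing <- setdiff(cols, names(normalized))
  if (length(missing))
    stopf("normalized table lacks column(s): %s", paste(missing, collapse = ", "))
  m <- as.matrix(normalized[, cols])
  if (nrow(m) < 2L) stopf("at least 2 units of class '%s' required", class)
  if (anyNA(m)) stopf("incomplete blocks: missing normalized values")
  colnames(m) <- c("0", as.character(pfos_concentrations()))
  fr <- friedman_test(m)
  cv <- conover_many_to_one(m, control = 1L, two_sided = TRUE)
  adj <- bh_adjust(cv$p.value)
  comparisons <- data.frame(concentration_uM = pfos_concentrations(),
                            statistic = cv$statistic, df = cv$df,
                            raw_p = cv$p.value, adjusted_p = adj,
                            stringsAsFactors = FALSE)
  structure(list(unit_class = class, n_units = nrow(m), friedman = fr,
                 comparisons = comparisons),
            class = "concentration_response")
}

#' @export
print.concentration_response <- function(x, ...) {
  cat(sprintf("Concentration-response (%s, %d units)\n",
              x$unit_class, x$n_units))
  cat(sprintf("  Friedman chi-square = %.3f, df = %d, p = %.4g\n",
              x$friedman$statistic, x$friedman$df, x$friedman$p.value))
  print(x$comparisons, digits = 4)
  invisible(x)
}

#' Full MEA analysis: filter, include, classify, test
#'
#' Composes the spike-count pipeline: activity filter, percentile
#' inclusion window, pharmacological classification, per-unit
#' normalization, and the concentration-response test per GABAergic class.
#'
#' @param units Raw unit table.
#' @param segments Analyzed segments for normalization (default `4:11`).
#' @return An `mea_analysis` list: `bounds`, `classified` (retained,
#'   classified units), `results` (named list of `concentration_response`
#'   per class with >= 2 units), and per-stage retention counts.
#' @export
analyze_mea <- function(units, segments = 4:11) {
  active <- filter_active_units(units)
  bounds <- compute_inclusion_bounds(active)
  included <- apply_inclusion(active, bounds)
  classified <- classify_units(included)
  results <- list()
  for (cl in c("GABA_A", "GABA_B")) {
    sub <- classified[classified$class == cl, , drop = FALSE]
    if (nrow(sub) >= 2L) {
      normed <- normalize_units(sub, segments)
      if (nrow(normed) >= 2L)
        results[[cl]] <- concentration_response(normed, class = cl)
    }
  }
  structure(list(bounds = bounds, classified = classified, results = results,
                 counts = c(n_input = nrow(units), n_active = nrow(active),
                            n_included = nrow(included))),
            class = "mea_analysis")
}

#' @export
print.mea_analysis <- function(x, ...) {
  cat("MEA concentration-response analysis\n")
  cat(sprintf("  units: %d input, %d active, %d within inclusion window\n",
              x$counts["n_input"], x$counts["n_active"], x$counts["n_included"]))
  print(x$bounds)
  tab <- table(x$classified$class)
  cat("  classes:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  for (r in x$results) print(r)
  invisible(x)
}
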