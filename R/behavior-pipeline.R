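#' Light-dark transition assay protocol
#'
#' Timing constants of the 62-min protocol: 20 min dark acclimation at
#' 0 lux, 20 min light at 13,238 lux (phases L1, L2), and 22 min dark at
#' 0 lux of which the first 20 min form phases D1 and D2 (the trailing
#' 120 s are recorded but not binned, since each phase contributes exactly
#' five 2-min sums). The startle windows are the first three full seconds
#' after each illumination transition.
#'
#' @return An `assay_protocol` list with phase windows (half-open, seconds),
#'   bin geometry and startle windows.
#' @export
assay_protocol <- function() {
  structure(list(
    total_seconds = 3720L,
    acclimation = c(0L, 1200L),
    phases = list(L1 = c(1200L, 1800L), L2 = c(1800L, 2400L),
                  D1 = c(2400L, 3000L), D2 = c(3000L, 3600L)),
    dark_tail = c(3600L, 3720L),
    bin_width = 120L, bins_per_phase = 5L,
    vsr_windows = list(VSR1 = 1200:1202, VSR2 = 2400:2402),
    light_lux = 13238),
    class = "assay_protocol")
}

#' Exclude non-viable larvae
#'
#' Removes every larva with any true viability flag (dead, malformed,
#' uninflated swim bladder) before analysis.
#'
#' @param traces Trace data frame with logical columns `dead`, `malformed`,
#'   `uninflated`.
#' @return List with `traces` (retained rows) and `report` (excluded counts
#'   per reason plus totals; larvae with several flags count under each).
#' @export
exclude_invalid <- function(traces) {
  flags <- c("dead", "malformed", "uninflated")
  missing <- setdiff(flags, names(traces))
  if (length(missing))
    stopf("traces lack viability flag(s): %s", paste(missing, collapse = ", "))
  per_animal <- stats::aggregate(traces[flags], by = list(animal = traces$animal),
                                 FUN = any)
  bad <- per_animal$animal[Reduce(`|`, per_animal[flags])]
  report <- c(vapply(flags, function(f) sum(per_animal[[f]]), integer(1)),
              n_excluded = length(bad),
              n_retained = nrow(per_animal) - length(bad))
  list(traces = traces[!(traces$animal %in% bad), , drop = FALSE],
       report = report)
}

#' Sum per-second distances into five 2-min bins per phase
#'
#' For each larva and each assay phase (L1, L2, D1, D2), sums the 1-s
#' distances into five consecutive 120-s bins. The acclimation period and
#' the final 120 s of the dark period are not binned. Any missing second
#' inside a phase is an error naming the gap.
#'
#' @param traces Trace data frame (`animal`, `treatment`, `time_s`,
#'   `distance_cm`, optional `experiment`).
#' @param protocol An [assay_protocol()].
#' @return Data frame `animal, treatment, phase, bin, time, value` (cm per
#'   2 min); `time` is the bin midpoint in seconds.
#' @export
bin_distances <- function(traces, protocol = assay_protocol()) {
  needed <- c("animal", "treatment", "time_s", "distance_cm")
  missing <- setdiff(needed, names(traces))
  if (length(missing))
    stopf("traces lack column(s): %s", paste(missing, collapse = ", "))
  span <- c(protocol$phases[[1]][1],
            protocol$phases[[length(protocol$phases)]][2])
  tr <- traces[traces$time_s >= span[1] & traces$time_s < span[2], , drop = FALSE]
  expected <- span[1]:(span[2] - 1L)
  for (a in unique(tr$animal)) {
    ts <- tr$time_s[tr$animal == a]
    gap <- setdiff(expected, ts)
    if (length(gap))
      stopf("larva '%s' is missing second(s) starting at %d within the binned window",
            a, min(gap))
    if (anyDuplicated(ts))
      stopf("larva '%s' has duplicated seconds in the binned window", a)
  }
  phase_names <- names(protocol$phases)
  starts <- vapply(protocol$phases, `[`, integer(1), 1L)
  phase_idx <- findInterval(tr$time_s, starts)
  bin <- (tr$time_s - starts[phase_idx]) %/% protocol$bin_width + 1L
  agg <- stats::aggregate(
    list(value = tr$distance_cm),
    by = list(animal = tr$animal, treatment = tr$treatment,
              phase = phase_names[phase_idx], bin = bin),
    FUN = sum)
  agg$phase <- factor(agg$phase, levels = phase_names)
  agg$time <- starts[as.character(agg$phase)] +
    (agg$bin - 1L) * protocol$bin_width + protocol$bin_width / 2
  agg <- agg[order(agg$animal, agg$time), ]
  if (!is.factor(agg$treatment))
    agg$treatment <- factor(agg$treatment, levels = unique(traces$treatment))
  rownames(agg) <- NULL
  agg
}

#' Experiment-wide scaling constant for the beta model
#'
#' `M = 1.001 x` the maximum 2-min sum observed across all larvae of the
#' experiment (one constant per experiment, so that scaled values stay
#' comparable across groups), or per larva when `per_larva = TRUE`.
#'
#' @param bins Output of [bin_distances()].
#' @param per_larva Alternative reading: one constant per larva.
#' @return The scalar `M` (cm), or a named per-larva vector.
#' @export
compute_scale <- function(bins, per_larva = FALSE) {
  if (!nrow(bins)) stopf("no bins supplied")
  if (per_larva) {
    mx <- c(tapply(bins$value, bins$animal, max))
    if (any(mx <= 0)) stopf("scale undefined: larva with all-zero bins")
    return(1.001 * mx)
  }
  mx <- max(bins$value)
  if (mx <= 0) stopf("scale undefined: all bins are zero")
  1.001 * mx
}

#' Map 2-min sums onto the open unit interval
#'
#' Divides each bin by the scaling constant; exact zeros are nudged to
#' `epsilon` so every value lies strictly inside (0, 1) as the beta model
#' requires. Values above `M` are an error.
#'
#' @param bins Output of [bin_distances()].
#' @param M Scaling constant from [compute_scale()] (scalar or per-larva
#'   named vector).
#' @param epsilon Replacement for exact zeros (default 1e-6).
#' @return `bins` with an added `value_scaled` column; `M` and `epsilon`
#'   attached as attributes.
#' @export
scale_bins <- function(bins, M = compute_scale(bins), epsilon = 1e-6) {
  if (epsilon <= 0 || epsilon >= 1) stopf("'epsilon' must be in (0, 1)")
  Mv <- if (length(M) == 1L) rep(M, nrow(bins)) else {
    if (!all(bins$animal %in% names(M)))
      stopf("per-larva scale missing for some larvae")
    unname(M[bins$animal])
  }
  if (any(bins$value > Mv))
    stopf("bin value exceeds the scaling constant M")
  sc <- bins$value / Mv
  sc[bins$value == 0] <- epsilon
  bins$value_scaled <- sc
  attr(bins, "M") <- M
  attr(bins, "epsilon") <- epsilon
  bins
}

#' Visual startle response: 3-s post-transition distance
#'
#' Sums the distance moved in the first three full seconds after the
#' dark-to-light transition (VSR1, seconds 1200-1202) and the
#' light-to-dark transition (VSR2, seconds 2400-2402).
#'
#' @param traces Trace data frame.
#' @param protocol An [assay_protocol()].
#' @return Data frame `animal, treatment, startle_phase, value` (cm over
#'   3 s), two rows per larva.
#' @export
compute_vsr <- function(traces, protocol = assay_protocol()) {
  out <- list()
  for (w in names(protocol$vsr_windows)) {
    secs <- protocol$vsr_windows[[w]]
    tr <- traces[traces$time_s %in% secs, , drop = FALSE]
    cnt <- table(tr$animal)
    bad <- names(cnt)[cnt != length(secs)]
    all_animals <- unique(traces$animal)
    bad <- union(bad, setdiff(all_animals, names(cnt)))
    if (length(bad))
      stopf("larva '%s' is missing seconds in the %s window", bad[1], w)
    agg <- stats::aggregate(list(value = tr$distance_cm),
                            by = list(animal = tr$animal,
                                      treatment = tr$treatment), FUN = sum)
    agg$startle_phase <- w
    out[[w]] <- agg[, c("animal", "treatment", "startle_phase", "value")]
  }
  res <- do.call(rbind, out)
  if (!is.factor(res$treatment))
    res$treatment <- factor(res$treatment, levels = unique(traces$treatment))
  res <- res[order(res$animal, res$startle_phase), ]
  rownames(res) <- NULL
  res
}

default_phase_spec <- function(ar1 = FALSE) {
  model_spec("value_scaled", smooth = list(time = list(k = 10, m = 2)),
             factors = c("treatment", "phase"),
             interactions = list(c("treatment", "phase")),
             random = "animal", family = "beta", ar1 = ar1)
}

default_vsr_spec <- function() {
  model_spec("value", factors = c("treatment", "startle_phase"),
             random = "animal", family = "gaussian")
}

# Between-treatment pairs within the same phase, as row indices into the
# EMM grid; the joint single-step adjustment runs over all of them at once.
treatment_pairs_within_phase <- function(emms, phase_col) {
  m <- nrow(emms)
  if (m < 2L) return(matrix(integer(0), 0, 2))
  cmb <- t(utils::combn(m, 2L))
  same_phase <- as.character(emms[[phase_col]])[cmb[, 1]] ==
    as.character(emms[[phase_col]])[cmb[, 2]]
  diff_trt <- as.character(emms$treatment)[cmb[, 1]] !=
    as.character(emms$treatment)[cmb[, 2]]
  cmb[same_phase & diff_trt, , drop = FALSE]
}

posthoc_letters <- function(emms, contrasts, phase_col, alpha) {
  labels <- emm_cell_labels(emms)
  phases <- as.character(emms[[phase_col]])
  out <- emms[, c("treatment", phase_col)]
  out$letters <- NA_character_
  for (p in unique(phases)) {
    cells_p <- labels[phases == p]
    if (length(cells_p) == 1L || nrow(contrasts) == 0L) {
      out$letters[phases == p] <- "a"
      next
    }
    sub <- contrasts[contrasts$cell_a %in% cells_p &
                       contrasts$cell_b %in% cells_p, , drop = FALSE]
    lt <- compact_letters(sub, alpha = alpha, cells = cells_p)
    out$letters[phases == p] <- unname(lt[cells_p])
  }
  rownames(out) <- NULL
  out
}

#' Phase analysis: beta GAMM, EMMs, adjusted contrasts, letters
#'
#' Fits the logit-beta mixed model to scaled 2-min bins, computes EMMs per
#' treatment x phase cell, tests all between-treatment differences within
#' each phase in one single-step max-|z| family, and assigns compact
#' letters per phase at level `alpha`. Post hoc results are only produced
#' from a converged fit; non-convergence is reported explicitly.
#'
#' @param scaled_bins Output of [scale_bins()].
#' @param alpha Familywise significance level (default 0.05, the level the
#'   assay's letter displays use).
#' @param spec Optional [model_spec()]; defaults to the assay model
#'   `logit(value) ~ s(time) + treatment * phase + (1 | animal)`.
#' @return A `phase_analysis` list: `fit`, `emms`, `contrasts`, `letters`
#'   (treatment x phase data frame), `alpha`, `converged`.
#' @export
analyze_phases <- function(scaled_bins, alpha = 0.05, spec = NULL) {
  spec <- spec %||% default_phase_spec()
  fit <- fit_beta_gamm(scaled_bins, spec)
  if (!fit$converged) {
    return(structure(list(fit = fit, emms = NULL, contrasts = NULL,
                          letters = NULL, alpha = alpha, converged = FALSE),
                     class = "phase_analysis"))
  }
  emms <- estimate_emms(fit)
  pairs <- treatment_pairs_within_phase(emms, "phase")
  contrasts <- tukey_pairwise(emms, alpha = alpha, pairs = pairs)
  letters <- posthoc_letters(emms, contrasts, "phase", alpha)
  structure(list(fit = fit, emms = emms, contrasts = contrasts,
                 letters = letters, alpha = alpha, converged = TRUE),
            class = "phase_analysis")
}

#' @export
print.phase_analysis <- function(x, ...) {
  cat("Light-dark phase analysis (beta GAMM)\n")
  if (!x$converged) {
    cat("  model did not converge; no post hoc results\n")
    return(invisible(x))
  }
  cat(sprintf("  alpha = %.3g; %d EMM cells, %d adjusted contrasts\n",
              x$alpha, nrow(x$emms), nrow(x$contrasts)))
  print(x$letters)
  invisible(x)
}

#' Startle analysis: Gaussian LMM, EMMs, adjusted contrasts, letters
#'
#' Same post hoc chain as [analyze_phases()] for the visual startle
#' response: `value ~ treatment + startle_phase + (1 | animal)` by REML,
#' EMMs per treatment x startle phase, between-treatment contrasts within
#' startle phase in one single-step family, compact letters per startle
#' phase. With a single treatment there are no contrasts and every cell is
#' lettered "a".
#'
#' @param vsr Output of [compute_vsr()].
#' @param alpha Familywise significance level.
#' @param spec Optional [model_spec()] (Gaussian family).
#' @return A `vsr_analysis` list mirroring `phase_analysis`.
#' @export
analyze_vsr <- function(vsr, alpha = 0.05, spec = NULL) {
  spec <- spec %||% default_vsr_spec()
  fit <- fit_gaussian_lmm(vsr, spec)
  emms <- estimate_emms(fit)
  pairs <- treatment_pairs_within_phase(emms, "startle_phase")
  contrasts <- tukey_pairwise(emms, alpha = alpha, pairs = pairs)
  letters <- posthoc_letters(emms, contrasts, "startle_phase", alpha)
  structure(list(fit = fit, emms = emms, contrasts = contrasts,
                 letters = letters, alpha = alpha, converged = fit$converged),
            class = "vsr_analysis")
}

#' @export
print.vsr_analysis <- function(x, ...) {
  cat("Visual startle response analysis (Gaussian LMM)\n")
  cat(sprintf("  alpha = %.3g; %d EMM cells, %d adjusted contrasts\n",
              x$alpha, nrow(x$emms), nrow(x$contrasts)))
  print(x$letters)
  invisible(x)
}
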