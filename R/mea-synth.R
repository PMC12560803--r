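#' PFOS concentration series of the 11-segment paradigm
#'
#' @return Numeric vector of the seven PFOS concentrations (µM) applied in
#'   recording segments 5-11.
#' @export
pfos_concentrations <- function() c(7.78, 14.05, 25.09, 44.80, 80, 100, 120)

#' Configuration for synthetic MEA spike-count tables
#'
#' Generative model for per-unit spike counts across the 11-segment
#' paradigm (baseline; GABA 10 µM; antagonist; washout baseline; seven
#' increasing PFOS concentrations). Each unit has a lognormal baseline rate
#' (spikes per 15-min segment) and negative-binomial counts
#' (`Var = mu + mu^2 / nb_dispersion`, the mean-dispersion
#' parameterization). GABA_A units are suppressed by the agonist and
#' rebound under bicuculline; GABA_B units rebound only under saclofen;
#' washout returns every unit to baseline; PFOS segments scale responsive
#' units by `pfos_effects`. Inactive units emit zero counts in the first
#' baseline to exercise the activity filter.
#'
#' @param n_units Named counts of units per type
#'   (`gabaA`, `gabaB`, `nonresponsive`, `inactive`).
#' @param baseline_median Median baseline rate (spikes / 15 min).
#' @param baseline_dispersion Lognormal sdlog of baseline rates.
#' @param nb_dispersion Negative-binomial dispersion (size/theta); `Inf`
#'   gives the Poisson limit.
#' @param gaba_effect Multiplicative rate factor under the agonist (< 1).
#' @param antagonist_effect Multiplicative rebound factor under the
#'   matching antagonist (> 1), applied on top of the agonist suppression.
#' @param pfos_effects Seven multiplicative factors for segments 5-11,
#'   applied to responsive (GABA_A/GABA_B) units; default all 1 (null).
#' @param units_per_well Units packed per well (wells carry one antagonist).
#' @param seed Integer seed, or `NULL`.
#' @return A validated `mea_sim_config`.
#' @export
mea_sim_config <- function(n_units = c(gabaA = 25L, gabaB = 25L,
                                       nonresponsive = 40L, inactive = 10L),
                           baseline_median = 200,
                           baseline_dispersion = 1,
                           nb_dispersion = 5,
                           gaba_effect = 0.3,
                           antagonist_effect = 2.5,
                           pfos_effects = rep(1, 7),
                           units_per_well = 8L,
                           seed = NULL) {
  types <- c("gabaA", "gabaB", "nonresponsive", "inactive")
  if (!all(types %in% names(n_units)))
    stopf("'n_units' must name %s", paste(types, collapse = ", "))
  n_units <- vapply(n_units[types], as.integer, integer(1))
  if (any(n_units < 0L)) stopf("unit counts must be >= 0")
  if (sum(n_units) < 1L) stopf("at least one unit required")
  if (baseline_median <= 0 || baseline_dispersion < 0)
    stopf("baseline rate parameters must be positive")
  if (nb_dispersion <= 0) stopf("'nb_dispersion' must be > 0 (Inf = Poisson)")
  if (gaba_effect <= 0 || gaba_effect >= 1)
    stopf("'gaba_effect' must lie in (0, 1)")
  if (antagonist_effect <= 1) stopf("'antagonist_effect' must be > 1")
  if (length(pfos_effects) != 7L || any(pfos_effects <= 0))
    stopf("'pfos_effects' must be 7 positive factors")
  structure(list(n_units = n_units, baseline_median = baseline_median,
                 baseline_dispersion = baseline_dispersion,
                 nb_dispersion = nb_dispersion, gaba_effect = gaba_effect,
                 antagonist_effect = antagonist_effect,
                 pfos_effects = pfos_effects,
                 units_per_well = as.integer(units_per_well),
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "mea_sim_config")
}

#' Simulate the 11-segment paradigm for a population of units
#'
#' @param config A [mea_sim_config()].
#' @return Data frame `unit, well, antagonist, true_type, seg1..seg11`
#'   (integer counts), deterministic given `config$seed`. `true_type` is
#'   the simulation truth label; the analysis pipeline ignores it.
#' @export
simulate_paradigm <- function(config) {
  stopifnot(inherits(config, "mea_sim_config"))
  with_seed(config$seed, {
    n <- config$n_units
    type <- rep(names(n), n)
    # responsive units sit in wells carrying their matching antagonist;
    # the remaining types are split across both antagonists
    antagonist <- character(length(type))
    antagonist[type == "gabaA"] <- "bicuculline"
    antagonist[type == "gabaB"] <- "saclofen"
    other <- which(!type %in% c("gabaA", "gabaB"))
    antagonist[other] <- rep(c("bicuculline", "saclofen"),
                             length.out = length(other))
    ord <- order(antagonist)
    type <- type[ord]; antagonist <- antagonist[ord]
    nunit <- length(type)
    well_of <- function(anta) {
      idx <- which(antagonist == anta)
      sprintf("%s%02d", toupper(substr(anta, 1, 1)),
              (seq_along(idx) - 1L) %/% config$units_per_well + 1L)
    }
    well <- character(nunit)
    well[antagonist == "bicuculline"] <- well_of("bicuculline")
    well[antagonist == "saclofen"] <- well_of("saclofen")

    lambda <- stats::rlnorm(nunit, meanlog = log(config$baseline_median),
                            sdlog = config$baseline_dispersion)
    mult <- matrix(1, nunit, 11L)
    resp <- type %in% c("gabaA", "gabaB")
    mult[resp, 2L] <- config$gaba_effect
    mult[resp, 3L] <- config$gaba_effect * config$antagonist_effect
    mult[resp, 5:11] <- rep(config$pfos_effects, each = sum(resp))
    inactive <- type == "inactive"
    lambda[inactive] <- pmin(lambda[inactive], 5)
    mult[inactive, 1L] <- 0

    mu <- lambda * mult
    counts <- if (is.infinite(config$nb_dispersion)) {
      stats::rpois(length(mu), mu)
    } else {
      stats::rnbinom(length(mu), mu = mu, size = config$nb_dispersion)
    }
    counts <- matrix(counts, nunit, 11L)
    colnames(counts) <- paste0("seg", 1:11)
    out <- data.frame(unit = sprintf("u%04d", seq_len(nunit)),
                      well = well, antagonist = antagonist,
                      true_type = type, stringsAsFactors = FALSE)
    out <- cbind(out, as.data.frame(counts))
    attr(out, "truth") <- config
    out
  })
}
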