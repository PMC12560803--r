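#' Configuration for synthetic larval locomotion data
#'
#' Defines the generative model both behavior simulators share: per-larva
#' random intercepts on the logit scale, a smooth time trend, phase and
#' treatment-by-phase shifts, and beta-distributed two-minute activity
#' fractions with precision `phi` (`y ~ Beta(mu * phi, (1 - mu) * phi)`).
#' Defaults mirror a typical light-dark transition experiment: two
#' treatment groups of 24 larvae (within the 21-45 replicate range such
#' assays run), markedly higher dark-phase activity, precision 20 and
#' intercept SD 0.5 on the logit scale, and a mild smooth drift through the
#' 62-minute protocol.
#'
#' @param n_per_group Larvae per treatment group.
#' @param treatment_labels Character vector of treatment labels; the first
#'   is the reference (control).
#' @param intercept Logit-scale intercept (control, light phase).
#' @param phase_effects Named logit shifts for phases L1, L2, D1, D2.
#' @param logit_effects Treatment x phase matrix of additional logit shifts
#'   (rows = treatments, columns = L1, L2, D1, D2); row one should be zero.
#'   Default all zero (null simulation).
#' @param time_trend Function of time (s) giving the smooth logit-scale
#'   trend; default a slow sinusoidal drift of amplitude 0.25.
#' @param random_sd Per-larva random-intercept SD (logit scale).
#' @param precision Beta precision `phi` (> 0).
#' @param startle_magnitude Distance (cm) of the 3-s post-transition burst
#'   in trace-level simulations.
#' @param trace_mean_cps Mean per-second distance (cm/s) by illumination
#'   context for trace-level simulations.
#' @param trace_gamma_shape Gamma shape of per-second distances
#'   (intermittent beat-and-glide swimming gives shape < 1).
#' @param exclusion_rate Probability a larva is flagged dead, malformed or
#'   with an uninflated swim bladder.
#' @param seed Integer seed, or `NULL`.
#' @return A validated `behavior_sim_config`.
#' @export
behavior_sim_config <- function(n_per_group = 24L,
                                treatment_labels = c("control", "PFOS"),
                                intercept = -1,
                                phase_effects = c(L1 = 0, L2 = -0.1,
                                                  D1 = 1, D2 = 0.8),
                                logit_effects = NULL,
                                time_trend = function(t) 0.25 * sin(2 * pi * t / 3600),
                                random_sd = 0.5,
                                precision = 20,
                                startle_magnitude = 6,
                                trace_mean_cps = c(acclimation = 0.4,
                                                   light = 0.3, dark = 0.9),
                                trace_gamma_shape = 0.6,
                                exclusion_rate = 0.05,
                                seed = NULL) {
  phases <- c("L1", "L2", "D1", "D2")
  if (n_per_group < 1L) stopf("'n_per_group' must be >= 1")
  if (length(treatment_labels) < 1L || anyDuplicated(treatment_labels))
    stopf("'treatment_labels' must be distinct and nonempty")
  if (!all(phases %in% names(phase_effects)))
    stopf("'phase_effects' must name L1, L2, D1, D2")
  if (is.null(logit_effects))
    logit_effects <- matrix(0, length(treatment_labels), 4L,
                            dimnames = list(treatment_labels, phases))
  logit_effects <- as.matrix(logit_effects)
  if (!identical(dim(logit_effects),
                 c(length(treatment_labels), 4L)))
    stopf("'logit_effects' must be a %d x 4 matrix", length(treatment_labels))
  dimnames(logit_effects) <- list(treatment_labels, phases)
  if (!is.function(time_trend)) stopf("'time_trend' must be a function")
  if (precision <= 0) stopf("'precision' (phi) must be > 0")
  if (random_sd < 0) stopf("'random_sd' must be >= 0")
  if (exclusion_rate < 0 || exclusion_rate > 1)
    stopf("'exclusion_rate' must be in [0, 1]")
  if (startle_magnitude < 0) stopf("'startle_magnitude' must be >= 0")
  if (!all(c("acclimation", "light", "dark") %in% names(trace_mean_cps)))
    stopf("'trace_mean_cps' must name acclimation, light, dark")
  if (any(trace_mean_cps < 0) || trace_gamma_shape <= 0)
    stopf("trace intensity parameters must be positive")
  structure(list(n_per_group = as.integer(n_per_group),
                 treatment_labels = treatment_labels,
                 intercept = intercept,
                 phase_effects = phase_effects[phases],
                 logit_effects = logit_effects,
                 time_trend = time_trend,
                 random_sd = random_sd, precision = precision,
                 startle_magnitude = startle_magnitude,
                 trace_mean_cps = trace_mean_cps,
                 trace_gamma_shape = trace_gamma_shape,
                 exclusion_rate = exclusion_rate,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "behavior_sim_config")
}

sim_animal_frame <- function(config) {
  treatments <- rep(config$treatment_labels, each = config$n_per_group)
  data.frame(
    animal = sprintf("%s_%02d", treatments,
                     sequence(rep(config$n_per_group,
                                  length(config$treatment_labels)))),
    treatment = treatments, stringsAsFactors = FALSE)
}

#' Simulate two-minute activity bins from the beta mixed model
#'
#' Draws scaled 2-min activity values directly at the level the phase
#' analysis models: `logit(mu) = intercept + trend(time) + phase +
#' treatment-by-phase shift + animal intercept`, `value ~ Beta(mu * phi,
#' (1 - mu) * phi)`. Bin times are the midpoints of the five 120-s bins of
#' each 600-s phase.
#'
#' @param config A [behavior_sim_config()].
#' @return Data frame `animal, treatment, phase, bin, time, value` with the
#'   generative truth attached as attribute `"truth"`. Reproducible given
#'   `config$seed`.
#' @export
simulate_bins <- function(config) {
  stopifnot(inherits(config, "behavior_sim_config"))
  with_seed(config$seed, {
    animals <- sim_animal_frame(config)
    b <- stats::rnorm(nrow(animals), 0, config$random_sd)
    phase_start <- c(L1 = 1200, L2 = 1800, D1 = 2400, D2 = 3000)
    grid <- expand.grid(bin = 1:5, phase = names(phase_start),
                        idx = seq_len(nrow(animals)),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    grid$time <- phase_start[grid$phase] + (grid$bin - 1) * 120 + 60
    trt <- animals$treatment[grid$idx]
    eta <- config$intercept + config$time_trend(grid$time) +
      config$phase_effects[grid$phase] +
      config$logit_effects[cbind(trt, grid$phase)] + b[grid$idx]
    mu <- stats::plogis(eta)
    phi <- config$precision
    val <- stats::rbeta(nrow(grid), mu * phi, (1 - mu) * phi)
    val <- pmin(pmax(val, 1e-12), 1 - 1e-12)
    out <- data.frame(animal = animals$animal[grid$idx],
                      treatment = factor(trt, levels = config$treatment_labels),
                      phase = factor(grid$phase,
                                     levels = c("L1", "L2", "D1", "D2")),
                      bin = grid$bin, time = grid$time,
                      value = val, stringsAsFactors = FALSE)
    out <- out[order(out$animal, out$time), ]
    rownames(out) <- NULL
    attr(out, "truth") <- list(intercept = config$intercept,
                               phase_effects = config$phase_effects,
                               logit_effects = config$logit_effects,
                               random_sd = config$random_sd,
                               precision = config$precision,
                               random_intercepts = stats::setNames(b, animals$animal))
    out
  })
}

#' Simulate per-second locomotion traces
#'
#' Second-level companion to [simulate_bins()]: 3720 nonnegative per-second
#' distances per larva with phase-dependent gamma-distributed activity, a
#' burst of `startle_magnitude` cm spread over the 3 s after each
#' illumination transition (1200 s and 2400 s), and viability flags drawn
#' with `exclusion_rate`. Exists to exercise binning, scaling and startle
#' extraction; second-level marginals are not meant to aggregate exactly to
#' the beta bin model.
#'
#' @param config A [behavior_sim_config()].
#' @return Data frame `experiment, animal, treatment, time_s, distance_cm,
#'   dead, malformed, uninflated` (3720 rows per larva).
#' @export
simulate_trace <- function(config) {
  stopifnot(inherits(config, "behavior_sim_config"))
  with_seed(config$seed, {
    animals <- sim_animal_frame(config)
    secs <- 0:3719
    ctx <- ifelse(secs < 1200, "acclimation",
                  ifelse(secs < 2400, "light", "dark"))
    phase_of_sec <- ifelse(secs < 1200, NA,
                    ifelse(secs < 1800, "L1",
                    ifelse(secs < 2400, "L2",
                    ifelse(secs < 3000, "D1", "D2"))))
    shape <- config$trace_gamma_shape
    out <- vector("list", nrow(animals))
    for (i in seq_len(nrow(animals))) {
      trt <- animals$treatment[i]
      mult <- ifelse(is.na(phase_of_sec), 1,
                     exp(config$logit_effects[trt, ifelse(is.na(phase_of_sec),
                                                          "L1", phase_of_sec)]))
      mu <- config$trace_mean_cps[ctx] * mult
      d <- ifelse(mu > 0, stats::rgamma(length(secs), shape = shape,
                                        scale = pmax(mu, 1e-12) / shape), 0)
      d[secs %in% c(1200:1202, 2400:2402)] <-
        d[secs %in% c(1200:1202, 2400:2402)] + config$startle_magnitude / 3
      flagged <- stats::runif(1) < config$exclusion_rate
      reason <- if (flagged) sample(c("dead", "malformed", "uninflated"), 1)
                else "none"
      out[[i]] <- data.frame(experiment = "E1", animal = animals$animal[i],
                             treatment = trt, time_s = secs, distance_cm = d,
                             dead = reason == "dead",
                             malformed = reason == "malformed",
                             uninflated = reason == "uninflated",
                             stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  })
}
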