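#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generators into one validated
#' list. Defaults reproduce the study conditions the analyses assume: a
#' 20-min post-injection window binned per minute, 7 experimental animals,
#' 120 taste trials (30 per taste) per session, a mu-power mean shift of
#' three noise SDs at 15 min, behavioral sickness onset at 12 min with an
#' 80 % drop in rearing durations, and condition effects that shrink
#' response magnitude, erode identity information and boost late-epoch
#' palatability polarization after LiCl.
#'
#' @param n_animals Animals in the experimental (saline--LiCl) group.
#' @param n_control Animals in the control (saline--saline) group.
#' @param session_minutes Length of the passive post-injection window (min).
#' @param power_noise_sd Gaussian noise SD of the per-minute power series (a.u.).
#' @param power_shift Absolute mean shift of mu power at `true_tau` (a.u.);
#'   the sign alternates across animals (both directions occur in vivo).
#' @param true_tau Planted change-point position (min), in `(0, session_minutes)`.
#' @param n_neurons Neurons per recorded ensemble.
#' @param n_trials_per_taste Trials per tastant (>= 6; the within-session
#'   decoder trains on 5 trials and needs at least one test trial).
#' @param bin_ms Spike-count bin width (ms).
#' @param baseline_rate Mean spontaneous firing rate (Hz).
#' @param identity_effect Taste-identity separation of middle-epoch firing
#'   (Hz per unit tuning weight).
#' @param palatability_gain Palatability-rank slope of late-epoch firing
#'   (Hz per centered rank unit).
#' @param illness_magnitude_shrink Fractional loss of evoked-response
#'   magnitude after LiCl, in `[0, 1]`.
#' @param illness_identity_loss Fractional loss of identity information after
#'   LiCl, in `[0, 1]`.
#' @param illness_palatability_boost Fractional gain of palatability signal
#'   after LiCl (>= 0).
#' @param frac_inhibitory Fraction of neurons whose taste response goes below
#'   baseline.
#' @param n_held Neurons flagged as held across both sessions
#'   (waveform-stable); default `min(12, n_neurons)`.
#' @param rearing_rate Rearing events per minute.
#' @param rearing_mean_duration Mean rearing duration (s), >= 0.5.
#' @param sickness_onset Planted behavioral sickness onset (min).
#' @param duration_drop Fractional drop of rearing durations after onset
#'   (LiCl sessions only), in `[0, 1]`.
#' @param seed Integer seed; each generator derives its own stream from it
#'   via a fixed offset table so stages can be regenerated independently.
#'
#' @return A list with class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(seed = 1)
#' cfg$true_tau
sim_config <- function(n_animals = 7,
                       n_control = 5,
                       session_minutes = 20,
                       power_noise_sd = 0.5,
                       power_shift = 1.5,
                       true_tau = 15,
                       n_neurons = 30,
                       n_trials_per_taste = 30,
                       bin_ms = 25,
                       baseline_rate = 6,
                       identity_effect = 3,
                       palatability_gain = 2,
                       illness_magnitude_shrink = 0.3,
                       illness_identity_loss = 0.5,
                       illness_palatability_boost = 0.5,
                       frac_inhibitory = 0.3,
                       n_held = NULL,
                       rearing_rate = 1.5,
                       rearing_mean_duration = 2.5,
                       sickness_onset = 12,
                       duration_drop = 0.8,
                       seed = 1L) {
  cfg <- as.list(environment())
  if (is.null(cfg$n_held)) cfg$n_held <- min(12, n_neurons)
  cfg$seed <- as.integer(seed)
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  num_pos <- c(
    "n_animals", "n_control", "session_minutes", "n_neurons",
    "n_trials_per_taste", "bin_ms", "baseline_rate"
  )
  for (f in num_pos) {
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1 || cfg[[f]] <= 0) {
      stop("'", f, "' must be a positive scalar")
    }
  }
  fracs <- c(
    "illness_magnitude_shrink", "illness_identity_loss",
    "frac_inhibitory", "duration_drop"
  )
  for (f in fracs) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) stop("'", f, "' must lie in [0, 1]")
  }
  if (cfg$illness_palatability_boost < 0) {
    stop("'illness_palatability_boost' must be >= 0")
  }
  for (f in c("true_tau", "sickness_onset")) {
    if (cfg[[f]] <= 0 || cfg[[f]] >= cfg$session_minutes) {
      stop("'", f, "' must lie strictly inside (0, ", cfg$session_minutes,
        ") minutes",
        call. = FALSE
      )
    }
  }
  if (cfg$n_trials_per_taste < 6) {
    stop("'n_trials_per_taste' must be >= 6 (5 training trials + 1 test trial)")
  }
  if (cfg$rearing_mean_duration < 0.5) {
    stop("'rearing_mean_duration' must be >= 0.5 s (scoring threshold)")
  }
  if (cfg$n_held > cfg$n_neurons) stop("'n_held' cannot exceed 'n_neurons'")
  invisible(cfg)
}

# Fixed per-generator seed offsets: one RNG stream per generator so each
# module's fixtures can be regenerated independently of the others.
SEED_OFFSETS <- c(
  lfp = 101L, ensemble = 211L, behavior = 307L,
  waveforms = 401L, within = 503L
)

seed_for <- function(cfg, stream) {
  (cfg$seed + SEED_OFFSETS[[stream]]) %% .Machine$integer.max
}
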