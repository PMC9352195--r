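#' Simulate per-minute mu-band power series with a planted change point
#'
#' One series per session per animal over the post-injection window.
#' Experimental animals contribute a saline and a LiCl session; the LiCl
#' series shifts its mean by `power_shift` at `true_tau` minutes, with the
#' sign of the shift alternating across animals (both an increase and a
#' decrease of mu power occur in vivo). Control animals contribute two
#' saline sessions and no shift. Both of an animal's sessions share a
#' slow sinusoidal power drift (amplitude twice the noise SD, random
#' phase), emulating the within-animal state fluctuations that make the
#' two same-day recordings comparable after per-session min-max
#' normalization; per-bin noise is independent between sessions.
#'
#' @param cfg A [sim_config()].
#' @return A list with class `sim_lfp`:
#'   * `power`: tibble `(animal_id, group, session, condition, minute, power)`,
#'     one row per 1-min bin;
#'   * `truth`: tibble `(animal_id, group, true_tau, shift)` (`NA` shift/tau
#'     for controls).
#' @export
#' @examples
#' sim <- sim_lfp_power(sim_config(seed = 2))
#' head(sim$power)
sim_lfp_power <- function(cfg) {
  validate_sim_config(cfg)
  set.seed(seed_for(cfg, "lfp"))
  mins <- seq_len(cfg$session_minutes)
  base_level <- 5

  animal_drift <- function() {
    phase <- runif(1, 0, 2 * pi)
    period <- runif(1, 15, 25)
    2 * cfg$power_noise_sd * sin(2 * pi * mins / period + phase)
  }

  one_series <- function(drift, shift, tau) {
    mu <- base_level + drift
    if (!is.na(shift) && shift != 0) {
      if (tau <= 0 || tau >= cfg$session_minutes) {
        stop("change-point position must lie in (0, ", cfg$session_minutes,
          ") minutes",
          call. = FALSE
        )
      }
      mu[mins >= tau] <- mu[mins >= tau] + shift
    }
    mu + rnorm(cfg$session_minutes, 0, cfg$power_noise_sd)
  }

  rows <- list()
  truth <- list()
  for (a in seq_len(cfg$n_animals)) {
    id <- sprintf("exp%02d", a)
    sign_a <- if (a %% 2 == 1) 1 else -1
    shift <- sign_a * cfg$power_shift
    drift <- animal_drift()
    rows[[length(rows) + 1]] <- tibble::tibble(
      animal_id = id, group = "experimental", session = "a",
      condition = "saline", minute = mins,
      power = one_series(drift, NA, NA)
    )
    rows[[length(rows) + 1]] <- tibble::tibble(
      animal_id = id, group = "experimental", session = "b",
      condition = "licl", minute = mins,
      power = one_series(drift, shift, cfg$true_tau)
    )
    truth[[length(truth) + 1]] <- tibble::tibble(
      animal_id = id, group = "experimental",
      true_tau = cfg$true_tau, shift = shift
    )
  }
  for (a in seq_len(cfg$n_control)) {
    id <- sprintf("ctl%02d", a)
    drift <- animal_drift()
    for (s in c("a", "b")) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        animal_id = id, group = "control", session = s,
        condition = "saline", minute = mins,
        power = one_series(drift, NA, NA)
      )
    }
    truth[[length(truth) + 1]] <- tibble::tibble(
      animal_id = id, group = "control", true_tau = NA_real_, shift = NA_real_
    )
  }
  structure(
    list(power = dplyr::bind_rows(rows), truth = dplyr::bind_rows(truth)),
    class = "sim_lfp"
  )
}

# Per-neuron latent parameters shared by both sessions of a pair.
draw_neuron_params <- function(cfg, tastes) {
  n <- cfg$n_neurons
  held <- seq_len(n) <= cfg$n_held
  cluster <- ifelse(held, rep_len(1:3, n), NA_integer_)
  tibble::tibble(
    neuron_id = sprintf("n%03d", seq_len(n)),
    baseline = rgamma(n, shape = 4, scale = cfg$baseline_rate / 4),
    magnitude = rgamma(n, shape = 4, scale = 0.8 * cfg$baseline_rate / 4),
    direction = ifelse(runif(n) < cfg$frac_inhibitory, -1, 1),
    pal_loading = rnorm(n),
    held = held,
    cluster = cluster
  )
}

# Rate (Hz) for one neuron in one condition at the bin start times `t_ms`,
# as a tastes x bins matrix. The first 200 ms post delivery carries no
# taste information; identity separation lives in the middle epoch
# (400-700 ms), palatability-rank-ordered firing in the late epoch
# (800-1100 ms). Condition effects are multiplicative on the epoch-specific
# components and leave the baseline untouched.
neuron_rate_matrix <- function(par_row, w_taste, cond, cfg, t_ms, tastes,
                               boost_cluster = NULL) {
  n_b <- length(t_ms)
  licl <- cond == "licl"
  dir <- par_row$direction
  mag <- par_row$magnitude
  if (isTRUE(par_row$held)) {
    cl <- par_row$cluster
    if (cl == 1) { # excitatory -> inhibitory
      dir <- if (licl) -1 else 1
    } else if (cl == 2) { # inhibitory -> excitatory
      dir <- if (licl) 1 else -1
    } else { # excitatory -> weaker excitatory
      dir <- 1
      if (licl) mag <- mag * (1 - max(cfg$illness_magnitude_shrink, 0.5))
    }
  } else if (licl) {
    mag <- mag * (1 - cfg$illness_magnitude_shrink)
  }
  ie <- cfg$identity_effect * if (licl) (1 - cfg$illness_identity_loss) else 1
  boost_ok <- is.null(boost_cluster) ||
    (isTRUE(par_row$held) && identical(par_row$cluster, boost_cluster))
  pg <- cfg$palatability_gain *
    if (licl && boost_ok) (1 + cfg$illness_palatability_boost) else 1

  resp_win <- t_ms >= 0 & t_ms < 1200
  mid_win <- t_ms >= 400 & t_ms < 700
  late_win <- t_ms >= 800 & t_ms < 1100
  p_rank <- palatability_ranks()[tastes]

  r <- matrix(par_row$baseline, nrow = length(tastes), ncol = n_b)
  r <- r + dir * mag * matrix(resp_win, length(tastes), n_b, byrow = TRUE)
  r <- r + ie * w_taste %o% as.numeric(mid_win)
  r <- r + pg * par_row$pal_loading * p_rank %o% as.numeric(late_win)
  pmax(r, 0.05)
}

ensemble_session <- function(cfg, params, w, cond, tastes, trial_taste,
                             boost_cluster = NULL) {
  t_ms <- seq(-1000, 1500 - cfg$bin_ms, by = cfg$bin_ms)
  n_b <- length(t_ms)
  bin_s <- cfg$bin_ms / 1000
  n_trials <- length(trial_taste)
  out <- vector("list", nrow(params))
  for (i in seq_len(nrow(params))) {
    rates <- neuron_rate_matrix(
      params[i, ], w[i, ], cond, cfg, t_ms, tastes, boost_cluster
    )
    lam <- rates[match(trial_taste, tastes), , drop = FALSE] * bin_s
    counts <- matrix(rpois(n_trials * n_b, as.vector(lam)), n_trials, n_b)
    out[[i]] <- tibble::tibble(
      neuron_id = params$neuron_id[i],
      trial = rep(seq_len(n_trials), times = n_b),
      taste = rep(trial_taste, times = n_b),
      time_ms = rep(t_ms, each = n_trials),
      count = as.integer(counts)
    )
  }
  df <- dplyr::bind_rows(out)
  df$condition <- cond
  attr(df, "bin_ms") <- cfg$bin_ms
  df[, c("neuron_id", "trial", "taste", "condition", "time_ms", "count")]
}

#' Simulate a saline/LiCl pair of ensemble recordings
#'
#' Trial spike counts are Poisson draws from an inhomogeneous rate with
#' three post-stimulus epochs: the first 200 ms carries no taste
#' information, the middle epoch (400--700 ms) carries identity separation
#' scaled by `identity_effect`, and late-epoch (800--1100 ms) firing is
#' monotone in palatability rank scaled by `palatability_gain`. A fraction
#' of neurons responds below baseline ("inhibitory"). The LiCl session
#' shrinks response magnitude, erodes identity information and boosts the
#' palatability component; baseline firing is untouched. The first
#' `n_held` neurons are flagged held with planted cluster motifs
#' (1 excitatory-to-inhibitory, 2 inhibitory-to-excitatory,
#' 3 excitatory-to-weaker-excitatory).
#'
#' @param cfg A [sim_config()].
#' @param tastes Character vector of tastants; must contain the four
#'   canonical tastes.
#' @param boost_cluster Optional integer in 1..3: restrict the LiCl
#'   palatability boost to held units of this planted cluster (all neurons
#'   receive it when `NULL`).
#' @return A list with class `sim_ensemble`: tibbles `saline` and `licl`
#'   in long trial-table form `(neuron_id, trial, taste, condition,
#'   time_ms, count)` with a `bin_ms` attribute, plus `truth` (per-neuron
#'   planted parameters and the palatability ranks).
#' @export
#' @examples
#' sim <- sim_ensemble_pair(sim_config(n_neurons = 4, n_held = 3, seed = 3))
#' dplyr::count(sim$saline, taste)
sim_ensemble_pair <- function(cfg, tastes = TASTES, boost_cluster = NULL) {
  validate_sim_config(cfg)
  if (length(unique(tastes)) < 4) {
    stop("at least the 4 canonical tastes are required")
  }
  if (!all(TASTES %in% tastes)) {
    stop("'tastes' must include sucrose, nacl, citric_acid and quinine")
  }
  set.seed(seed_for(cfg, "ensemble"))
  params <- draw_neuron_params(cfg, tastes)
  w <- matrix(rnorm(cfg$n_neurons * length(tastes)),
    nrow = cfg$n_neurons,
    dimnames = list(params$neuron_id, tastes)
  )
  # pseudo-random delivery order, balanced within blocks of one trial/taste
  order_block <- function() sample(tastes)
  trial_taste <- as.vector(replicate(cfg$n_trials_per_taste, order_block()))
  sal <- ensemble_session(cfg, params, w, "saline", tastes, trial_taste,
    boost_cluster = boost_cluster
  )
  trial_taste2 <- as.vector(replicate(cfg$n_trials_per_taste, order_block()))
  licl <- ensemble_session(cfg, params, w, "licl", tastes, trial_taste2,
    boost_cluster = boost_cluster
  )
  structure(
    list(
      saline = sal, licl = licl,
      truth = list(
        neurons = params, tuning = w,
        ranks = palatability_ranks()[tastes]
      )
    ),
    class = "sim_ensemble"
  )
}

#' Simulate a single within-session recording with sickness-driven drift
#'
#' Emulates a protocol in which tastes are delivered immediately after the
#' LiCl injection, so that identity information decays mid-session: trials
#' are delivered at `trials_per_min` and those after `sickness_onset`
#' minutes lose `illness_identity_loss` of their identity separation (and
#' `illness_magnitude_shrink` of their response magnitude).
#'
#' @param cfg A [sim_config()].
#' @param trials_per_min Delivery rate (trials/min).
#' @param drift If `FALSE`, the session is stationary (no illness drift);
#'   useful as a null fixture.
#' @return A list with class `sim_within`: `trials` (long trial table with
#'   an extra `trial_time_min` column) and `truth`.
#' @export
sim_ensemble_within <- function(cfg, trials_per_min = 3, drift = TRUE) {
  validate_sim_config(cfg)
  set.seed(seed_for(cfg, "within"))
  params <- draw_neuron_params(cfg, TASTES)
  w <- matrix(rnorm(cfg$n_neurons * 4),
    nrow = cfg$n_neurons,
    dimnames = list(params$neuron_id, TASTES)
  )
  trial_taste <- as.vector(replicate(cfg$n_trials_per_taste, sample(TASTES)))
  n_trials <- length(trial_taste)
  trial_time <- (seq_len(n_trials) - 0.5) / trials_per_min
  sick <- drift & trial_time >= cfg$sickness_onset

  t_ms <- seq(-1000, 1500 - cfg$bin_ms, by = cfg$bin_ms)
  bin_s <- cfg$bin_ms / 1000
  cfg_sick <- cfg
  out <- vector("list", nrow(params))
  for (i in seq_len(nrow(params))) {
    r_pre <- neuron_rate_matrix(params[i, ], w[i, ], "saline", cfg, t_ms, TASTES)
    r_post <- neuron_rate_matrix(params[i, ], w[i, ], "licl", cfg_sick, t_ms, TASTES)
    lam <- r_pre[match(trial_taste, TASTES), , drop = FALSE]
    lam[sick, ] <- r_post[match(trial_taste, TASTES), , drop = FALSE][sick, ]
    counts <- matrix(rpois(n_trials * length(t_ms), as.vector(lam * bin_s)),
      n_trials, length(t_ms)
    )
    out[[i]] <- tibble::tibble(
      neuron_id = params$neuron_id[i],
      trial = rep(seq_len(n_trials), times = length(t_ms)),
      taste = rep(trial_taste, times = length(t_ms)),
      trial_time_min = rep(trial_time, times = length(t_ms)),
      time_ms = rep(t_ms, each = n_trials),
      count = as.integer(counts)
    )
  }
  trials <- dplyr::bind_rows(out)
  trials$condition <- "licl"
  attr(trials, "bin_ms") <- cfg$bin_ms
  structure(
    list(
      trials = trials,
      truth = list(
        neurons = params, tuning = w,
        sickness_onset = if (drift) cfg$sickness_onset else NA_real_
      )
    ),
    class = "sim_within"
  )
}

#' Simulate rearing-event streams
#'
#' Rearing events (both forepaws off the floor for more than 0.5 s) are a
#' Poisson process at `rearing_rate` events/min; durations are
#' `0.5 + Exponential(rearing_mean_duration - 0.5)` seconds. In LiCl
#' sessions, events starting after `sickness_onset` minutes have their
#' durations scaled by `1 - duration_drop` (illness suppresses rearing).
#'
#' @param cfg A [sim_config()].
#' @return A list with class `sim_behavior`: `events` tibble
#'   `(animal_id, condition, onset_s, duration_s)` and `truth`.
#' @export
#' @examples
#' b <- sim_behavior(sim_config(seed = 4))
#' head(b$events)
sim_behavior <- function(cfg) {
  validate_sim_config(cfg)
  set.seed(seed_for(cfg, "behavior"))
  sess_s <- cfg$session_minutes * 60

  one_session <- function(id, cond) {
    n <- rpois(1, cfg$rearing_rate * cfg$session_minutes)
    if (n == 0) {
      return(tibble::tibble(
        animal_id = id, condition = cond,
        onset_s = numeric(0), duration_s = numeric(0)
      ))
    }
    onset <- sort(runif(n, 0, sess_s))
    dur <- 0.5 + rexp(n, rate = 1 / (cfg$rearing_mean_duration - 0.5))
    if (cond == "licl") {
      post <- onset >= cfg$sickness_onset * 60
      dur[post] <- dur[post] * (1 - cfg$duration_drop)
    }
    tibble::tibble(
      animal_id = id, condition = cond,
      onset_s = onset, duration_s = dur
    )
  }

  ev <- dplyr::bind_rows(
    purrr::map(seq_len(cfg$n_animals), function(a) {
      one_session(sprintf("exp%02d", a), "licl")
    }),
    purrr::map(seq_len(cfg$n_control), function(a) {
      one_session(sprintf("ctl%02d", a), "saline")
    })
  )
  structure(
    list(
      events = ev,
      truth = list(
        sickness_onset = cfg$sickness_onset,
        duration_drop = cfg$duration_drop,
        session_minutes = cfg$session_minutes
      )
    ),
    class = "sim_behavior"
  )
}

#' Simulate paired spike-waveform sets for held-unit screening
#'
#' Each unit gets a two-session pair of extracellular spike waveforms
#' (template plus Gaussian sample noise). A fraction of units changes its
#' template between sessions (amplitude scaling), providing planted
#' not-held cases.
#'
#' @param cfg A [sim_config()].
#' @param n_units Number of units (default `cfg$n_held`).
#' @param n_spikes Waveforms per session.
#' @param n_samples Samples per waveform.
#' @param frac_changed Fraction of units whose session-2 template is scaled
#'   in amplitude (planted not-held units).
#' @param noise_sd Sample noise SD, as a fraction of template amplitude.
#' @return A list with class `sim_waveforms`: `waveforms` tibble
#'   `(unit_id, session, spike, sample, voltage)` and `truth` with the
#'   planted held flag.
#' @export
sim_waveforms <- function(cfg, n_units = cfg$n_held, n_spikes = 150,
                          n_samples = 45, frac_changed = 0, noise_sd = 0.15) {
  validate_sim_config(cfg)
  set.seed(seed_for(cfg, "waveforms"))
  s <- seq_len(n_samples)
  template <- function(amp, trough, width) {
    -amp * exp(-((s - trough)^2) / (2 * width^2)) +
      0.35 * amp * exp(-((s - trough - 10)^2) / (2 * (1.8 * width)^2))
  }
  changed <- runif(n_units) < frac_changed
  rows <- vector("list", n_units * 2)
  truth <- tibble::tibble(
    unit_id = sprintf("u%03d", seq_len(n_units)),
    held = !changed
  )
  k <- 0
  for (u in seq_len(n_units)) {
    amp <- runif(1, 0.8, 1.5)
    trough <- runif(1, 14, 18)
    width <- runif(1, 2.2, 3.2)
    for (sess in 1:2) {
      amp_s <- if (sess == 2 && changed[u]) amp * 2 else amp
      tmpl <- template(amp_s, trough, width)
      wf <- matrix(rnorm(n_spikes * n_samples, 0, noise_sd * amp),
        n_spikes, n_samples,
        byrow = FALSE
      ) + matrix(tmpl, n_spikes, n_samples, byrow = TRUE)
      k <- k + 1
      rows[[k]] <- tibble::tibble(
        unit_id = truth$unit_id[u], session = sess,
        spike = rep(seq_len(n_spikes), times = n_samples),
        sample = rep(s, each = n_spikes),
        voltage = as.vector(wf)
      )
    }
  }
  structure(
    list(waveforms = dplyr::bind_rows(rows), truth = truth),
    class = "sim_waveforms"
  )
}

#' Write simulated fixtures to plain-text tables
#'
#' Writes the trials, events and power tables as CSV and the ground truth
#' as JSON, in the layout the analysis stages read back.
#'
#' @param lfp,ensemble,behavior Outputs of the corresponding simulators
#'   (any may be `NULL`).
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_fixtures <- function(dir, lfp = NULL, ensemble = NULL, behavior = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  put <- function(df, name) {
    f <- file.path(dir, name)
    write.csv(df, f, row.names = FALSE)
    written <<- c(written, f)
  }
  truth <- list()
  if (!is.null(lfp)) {
    put(lfp$power, "power.csv")
    truth$lfp <- lfp$truth
  }
  if (!is.null(ensemble)) {
    put(ensemble$saline, "trials_saline.csv")
    put(ensemble$licl, "trials_licl.csv")
    truth$ensemble <- ensemble$truth$neurons
  }
  if (!is.null(behavior)) {
    put(behavior$events, "events.csv")
    truth$behavior <- behavior$truth
  }
  if (length(truth)) {
    f <- file.path(dir, "ground_truth.json")
    jsonlite::write_json(truth, f, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    written <- c(written, f)
  }
  invisible(written)
}
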