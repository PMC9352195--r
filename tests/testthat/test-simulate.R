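test_that("config validation rejects out-of-range parameters", {
  expect_error(sim_config(true_tau = 25), "inside")
  expect_error(sim_config(true_tau = 0), "inside")
  expect_error(sim_config(sickness_onset = 20), "inside")
  expect_error(sim_config(duration_drop = 1.2), "\\[0, 1\\]")
  expect_error(sim_config(n_trials_per_taste = 4), "6")
  expect_error(sim_config(n_held = 40, n_neurons = 30), "n_held")
})

test_that("simulators are deterministic given config and seed", {
  cfg <- sim_config(n_neurons = 4, n_trials_per_taste = 6, seed = 42)
  expect_identical(sim_lfp_power(cfg), sim_lfp_power(cfg))
  expect_identical(sim_ensemble_pair(cfg), sim_ensemble_pair(cfg))
  expect_identical(sim_behavior(cfg), sim_behavior(cfg))
  expect_identical(
    sim_waveforms(cfg, n_units = 2, n_spikes = 60),
    sim_waveforms(cfg, n_units = 2, n_spikes = 60)
  )
})

test_that("power series carry the planted mean shift at the planted time", {
  cfg <- sim_config(
    n_animals = 20, power_shift = 1.5, power_noise_sd = 0.5,
    true_tau = 15, seed = 8
  )
  sim <- sim_lfp_power(cfg)
  # per animal and session: mean(bins 15..20) - mean(bins 1..14); the
  # saline session shares the animal's slow drift, so the session
  # difference isolates the planted signed shift
  est <- sim$power |>
    dplyr::filter(.data$group == "experimental") |>
    dplyr::group_by(animal_id, session) |>
    dplyr::summarise(
      d = mean(power[minute >= 15]) - mean(power[minute < 15]),
      .groups = "drop"
    ) |>
    tidyr::pivot_wider(names_from = session, values_from = d) |>
    dplyr::mutate(d = b - a) |>
    dplyr::left_join(sim$truth, by = "animal_id")
  # closed-form SE of a difference of two independent such contrasts
  se <- cfg$power_noise_sd * sqrt(2 * (1 / 6 + 1 / 14))
  expect_true(all(abs(est$d - est$shift) < 3.5 * se))
  expect_true(any(est$shift > 0) && any(est$shift < 0))
})

test_that("zero shift gives stationary noise and no detection downstream", {
  cfg <- sim_config(n_animals = 2, power_shift = 0, seed = 5)
  sim <- sim_lfp_power(cfg)
  s <- dplyr::filter(
    sim$power, .data$animal_id == "exp01", .data$condition == "licl"
  )
  res <- detect_changepoint(s, n_shuffles = 25, n_samples = 1000, seed = 1)
  expect_false(res$detected)
  expect_true(is.na(res$estimate))
})

test_that("baseline spike counts match the Poisson mean in a 250 ms bin", {
  cfg <- sim_config(
    n_neurons = 40, n_trials_per_taste = 10, baseline_rate = 6,
    frac_inhibitory = 0, n_held = 0, seed = 12
  )
  sim <- sim_ensemble_pair(cfg)
  # baseline window well before delivery; mean count per 250 ms
  base <- dplyr::filter(
    sim$saline, .data$time_ms >= -1000, .data$time_ms < -750
  )
  per_neuron <- base |>
    dplyr::group_by(neuron_id, trial) |>
    dplyr::summarise(n = sum(count), .groups = "drop") |>
    dplyr::group_by(neuron_id) |>
    dplyr::summarise(m = mean(n), n_tr = dplyr::n())
  expected <- sim$truth$neurons$baseline * 0.25
  se <- sqrt(expected / per_neuron$n_tr) # Poisson SE of the mean count
  expect_true(all(abs(per_neuron$m - expected) < 3.5 * se))
})

test_that("ensemble generator enforces the four-taste contract", {
  cfg <- sim_config(n_neurons = 2, seed = 1)
  expect_error(sim_ensemble_pair(cfg, tastes = c("sucrose", "nacl")), "4")
  sim <- sim_ensemble_pair(sim_config(n_neurons = 2, n_trials_per_taste = 6, seed = 1))
  counts <- dplyr::count(
    unique(sim$licl[, c("trial", "taste")]), taste
  )
  expect_setequal(counts$taste, c("sucrose", "nacl", "citric_acid", "quinine"))
  expect_true(all(counts$n == 6))
  expect_true(all(sim$saline$count >= 0))
})

test_that("LiCl shrinks evoked magnitude but leaves baseline untouched", {
  cfg <- sim_config(
    n_neurons = 40, n_trials_per_taste = 15, identity_effect = 0,
    palatability_gain = 0, illness_magnitude_shrink = 0.5,
    frac_inhibitory = 0, n_held = 0, seed = 3
  )
  sim <- sim_ensemble_pair(cfg)
  mag <- function(tr) {
    mean(abs(taste_magnitudes(tr)$magnitude))
  }
  expect_lt(mag(sim$licl), 0.75 * mag(sim$saline))
  base_rate <- function(tr) {
    mean(window_rates(tr, c(-1000, 0))$rate)
  }
  expect_lt(
    abs(base_rate(sim$licl) - base_rate(sim$saline)),
    0.05 * base_rate(sim$saline)
  )
})

test_that("rearing durations drop by the planted fraction after onset", {
  cfg <- sim_config(
    n_animals = 30, duration_drop = 0.8, sickness_onset = 12,
    rearing_rate = 3, seed = 21
  )
  b <- sim_behavior(cfg)
  licl <- dplyr::filter(b$events, .data$condition == "licl")
  pre <- licl$duration_s[licl$onset_s < 12 * 60]
  post <- licl$duration_s[licl$onset_s >= 12 * 60]
  expect_gt(length(post), 100)
  se <- sqrt(var(pre) * 0.04 / length(pre) + var(post) / length(post))
  expect_lt(abs(mean(post) - 0.2 * mean(pre)), 4 * se)
})

test_that("duration_drop = 0 leaves conditions identical in law", {
  cfg <- sim_config(
    n_animals = 25, n_control = 25, duration_drop = 0, seed = 31
  )
  b <- sim_behavior(cfg)
  ks <- suppressWarnings(ks.test(
    b$events$duration_s[b$events$condition == "licl"],
    b$events$duration_s[b$events$condition == "saline"]
  ))
  expect_gt(ks$p.value, 0.01)
})

test_that("zero rearing rate yields empty lists handled downstream", {
  cfg <- sim_config(rearing_rate = 0, seed = 2)
  b <- sim_behavior(cfg)
  expect_equal(nrow(b$events), 0)
  tr <- durations_per_bin(b$events, session_minutes = 20)
  expect_equal(sum(tr$seconds), 0)
})

test_that("fixtures round-trip through plain-text files", {
  cfg <- sim_config(n_animals = 2, n_control = 1, n_neurons = 2,
    n_trials_per_taste = 6, seed = 9
  )
  dir <- withr::local_tempdir()
  files <- write_fixtures(dir,
    lfp = sim_lfp_power(cfg), behavior = sim_behavior(cfg)
  )
  expect_true(all(file.exists(file.path(
    dir, c("power.csv", "events.csv", "ground_truth.json")
  ))))
  back <- read_power_csv(file.path(dir, "power.csv"))
  orig <- sim_lfp_power(cfg)$power
  expect_equal(nrow(back), nrow(orig))
  expect_equal(back$power, orig$power, tolerance = 1e-12)
})
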