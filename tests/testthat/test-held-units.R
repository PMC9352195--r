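test_that("stable templates are held, changed templates are rejected", {
  cfg <- sim_config(n_neurons = 30, seed = 51)
  wf_ok <- sim_waveforms(cfg, n_units = 10, frac_changed = 0)
  scr <- held_unit_screen(wf_ok$waveforms, seed = 1)
  expect_gte(mean(scr$held), 0.9)

  cfg2 <- sim_config(n_neurons = 30, seed = 52)
  wf_bad <- sim_waveforms(cfg2, n_units = 10, frac_changed = 1)
  scr2 <- held_unit_screen(wf_bad$waveforms, seed = 2)
  expect_lte(mean(scr2$held), 0.05)
})

test_that("a unit compared against itself is held", {
  cfg <- sim_config(seed = 53)
  wf <- sim_waveforms(cfg, n_units = 1, frac_changed = 0)
  m <- gustate:::wf_matrix(wf$waveforms[wf$waveforms$session == 1, ])
  dec <- held_unit_test(list(m, m), seed = 3)
  expect_true(dec$held)
  expect_equal(dec$between_stat, 0)
})

test_that("waveform contracts are enforced", {
  cfg <- sim_config(seed = 54)
  wf <- sim_waveforms(cfg, n_units = 1, n_spikes = 30)
  expect_error(held_unit_test(wf$waveforms), "50 waveforms")
  m1 <- matrix(rnorm(50 * 40), 50, 40)
  m2 <- matrix(rnorm(50 * 45), 50, 45)
  expect_error(held_unit_test(list(m1, m2)), "lengths differ")
})

test_that("RD vectors count held units times four and encode quadrants", {
  cfg <- sim_config(
    n_neurons = 12, n_held = 9, n_trials_per_taste = 10, seed = 55
  )
  sim <- sim_ensemble_pair(cfg)
  held <- sim$truth$neurons$neuron_id[sim$truth$neurons$held]
  rds <- response_difference_vectors(sim$saline, sim$licl, held_ids = held)
  expect_equal(nrow(rds), length(held) * 4)
  expect_true(all(rds$angle >= 0 & rds$angle < 360))
  expect_equal(rds$distance, sqrt(rds$saline_resp^2 + rds$licl_resp^2))
  # cluster 1 motif: excitatory under saline, inhibitory under LiCl ->
  # saline_resp > 0, licl_resp < 0 -> angle in (270, 360)
  cl1 <- sim$truth$neurons$neuron_id[which(sim$truth$neurons$cluster == 1)]
  q4 <- rds[rds$neuron_id %in% cl1, ]
  expect_gt(mean(q4$angle > 270 & q4$angle < 360), 0.8)
})

test_that("no condition change gives near-zero RD distances", {
  cfg <- sim_config(
    n_neurons = 8, n_held = 0, n_trials_per_taste = 20,
    illness_magnitude_shrink = 0, illness_identity_loss = 0,
    illness_palatability_boost = 0, identity_effect = 0,
    palatability_gain = 0, seed = 56
  )
  sim <- sim_ensemble_pair(cfg)
  rds <- response_difference_vectors(sim$saline, sim$licl)
  # responses equal in expectation: points hug the diagonal, not the axes
  expect_lt(median(abs(rds$saline_resp - rds$licl_resp)), 25)
})

test_that("BIC recovers three planted RD clusters and the partition", {
  set.seed(57)
  centers <- matrix(c(40, -40, -35, 35, 45, 12), 3, 2, byrow = TRUE)
  ok <- 0
  ari <- numeric(10)
  for (i in 1:10) {
    lab <- sample(rep(1:3, length.out = 60))
    pts <- centers[lab, ] + matrix(rnorm(120, sd = 3), 60, 2)
    rds <- tibble::tibble(
      neuron_id = paste0("n", seq_len(60)), taste = "sucrose",
      saline_resp = pts[, 1], licl_resp = pts[, 2],
      distance = sqrt(rowSums(pts^2)),
      angle = (atan2(pts[, 2], pts[, 1]) * 180 / pi) %% 360
    )
    cl <- gmm_cluster(rds)
    ok <- ok + (cl$k == 3)
    keep <- !is.na(cl$assignments$cluster)
    ari[i] <- mclust::adjustedRandIndex(
      cl$assignments$cluster[keep], lab[keep]
    )
  }
  expect_gte(ok, 9)
  expect_gt(mean(ari), 0.9)
})

test_that("a single Gaussian cloud selects one component", {
  set.seed(58)
  ok <- 0
  for (i in 1:10) {
    pts <- matrix(rnorm(120, sd = 10), 60, 2)
    rds <- tibble::tibble(
      neuron_id = paste0("n", 1:60), taste = "sucrose",
      saline_resp = pts[, 1], licl_resp = pts[, 2],
      distance = sqrt(rowSums(pts^2)),
      angle = (atan2(pts[, 2], pts[, 1]) * 180 / pi) %% 360
    )
    ok <- ok + (gmm_cluster(rds)$k == 1)
  }
  expect_gte(ok, 9)
})

test_that("the partition is invariant to rotation and translation", {
  set.seed(59)
  centers <- matrix(c(40, -40, -35, 35, 45, 12), 3, 2, byrow = TRUE)
  lab <- rep(1:3, each = 20)
  pts <- centers[lab, ] + matrix(rnorm(120, sd = 3), 60, 2)
  mk <- function(p) {
    tibble::tibble(
      neuron_id = paste0("n", 1:60), taste = "sucrose",
      saline_resp = p[, 1], licl_resp = p[, 2],
      distance = sqrt(rowSums(p^2)),
      angle = (atan2(p[, 2], p[, 1]) * 180 / pi) %% 360
    )
  }
  c0 <- gmm_cluster(mk(pts))
  th <- pi / 5
  rot <- pts %*% matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2)
  c1 <- gmm_cluster(mk(rot))
  shf <- pts + 15
  c2 <- gmm_cluster(mk(shf))
  keep <- !is.na(c0$assignments$cluster) & !is.na(c1$assignments$cluster)
  expect_gt(mclust::adjustedRandIndex(
    c0$assignments$cluster[keep], c1$assignments$cluster[keep]
  ), 0.95)
  keep2 <- !is.na(c0$assignments$cluster) & !is.na(c2$assignments$cluster)
  expect_gt(mclust::adjustedRandIndex(
    c0$assignments$cluster[keep2], c2$assignments$cluster[keep2]
  ), 0.95)
})

test_that("cluster-specific palatability boost yields the 3-way interaction", {
  cfg <- sim_config(
    n_neurons = 30, n_held = 24, n_trials_per_taste = 20,
    palatability_gain = 3, illness_palatability_boost = 2,
    illness_identity_loss = 0, illness_magnitude_shrink = 0, seed = 60
  )
  sim <- sim_ensemble_pair(cfg, boost_cluster = 1L)
  truth <- sim$truth$neurons
  held <- truth$neuron_id[truth$held]
  keep <- function(tr) {
    out <- dplyr::filter(tr, .data$neuron_id %in% held)
    attr(out, "bin_ms") <- attr(tr, "bin_ms")
    out
  }
  trs <- moving_spearman(keep(sim$saline), t_range = c(200, 1150))
  trl <- moving_spearman(keep(sim$licl), t_range = c(200, 1150))
  planted <- tibble::tibble(
    neuron_id = held, taste = "sucrose",
    saline_resp = 0, licl_resp = 0, distance = 0, angle = 0,
    cluster = truth$cluster[truth$held]
  )
  res <- cluster_palatability_anova(planted, trs, trl)
  expect_lt(res$anova$p.value, 0.05)
  fl1 <- res$followups[res$followups$cluster == 1, ]
  expect_lt(fl1$p.value, 0.05)
  expect_gt(fl1$estimate, 0)
})

test_that("the 3-way interaction depends on the true cluster labels", {
  # with an effect confined to one cluster, random label permutations
  # dilute (and usually remove) the interaction; with the boost applied
  # to every neuron, cluster labels are exchangeable and rejections sit
  # at the nominal level (full calibration is exercised elsewhere)
  p_true <- p_perm <- numeric(6)
  for (s in 1:6) {
    cfg <- sim_config(
      n_neurons = 30, n_held = 24, n_trials_per_taste = 15,
      palatability_gain = 3, illness_palatability_boost = 2,
      illness_identity_loss = 0, illness_magnitude_shrink = 0,
      seed = 600 + s
    )
    sim <- sim_ensemble_pair(cfg, boost_cluster = 1L)
    truth <- sim$truth$neurons
    held <- truth$neuron_id[truth$held]
    keep <- function(tr) {
      out <- dplyr::filter(tr, .data$neuron_id %in% held)
      attr(out, "bin_ms") <- attr(tr, "bin_ms")
      out
    }
    trs <- suppressMessages(moving_spearman(keep(sim$saline), t_range = c(200, 1150)))
    trl <- suppressMessages(moving_spearman(keep(sim$licl), t_range = c(200, 1150)))
    mk <- function(cl) {
      tibble::tibble(
        neuron_id = held, taste = "sucrose",
        saline_resp = 0, licl_resp = 0, distance = 0, angle = 0,
        cluster = cl
      )
    }
    p_true[s] <- cluster_palatability_anova(
      mk(truth$cluster[truth$held]), trs, trl
    )$anova$p.value
    set.seed(s)
    p_perm[s] <- cluster_palatability_anova(
      mk(sample(truth$cluster[truth$held])), trs, trl
    )$anova$p.value
  }
  expect_gt(mean(p_perm), mean(p_true))
  expect_gte(sum(p_true < 0.05), 4)
})

test_that("unchanged baselines pass both equivalence tests", {
  ok <- vapply(1:10, function(s) {
    cfg <- sim_config(
      n_neurons = 20, n_held = 20, n_trials_per_taste = 10, seed = 700 + s
    )
    sim <- sim_ensemble_pair(cfg)
    be <- baseline_equivalence(sim$saline, sim$licl)
    be$t_test$p.value > 0.05 && be$ks_test$p.value > 0.05
  }, logical(1))
  expect_gte(mean(ok), 0.9)
})

test_that("a planted baseline shift is caught by the paired t test", {
  cfg <- sim_config(n_neurons = 25, n_held = 25, n_trials_per_taste = 20,
    seed = 61
  )
  sim <- sim_ensemble_pair(cfg)
  shifted <- dplyr::mutate(sim$licl,
    count = count + rbinom(dplyr::n(), 1, 0.05)
  )
  attr(shifted, "bin_ms") <- attr(sim$licl, "bin_ms")
  be <- baseline_equivalence(sim$saline, shifted)
  expect_lt(be$t_test$p.value, 0.05)
})

test_that("zero-difference baselines give t = 0 and p = 1", {
  cfg <- sim_config(n_neurons = 6, n_held = 6, n_trials_per_taste = 8, seed = 62)
  sim <- sim_ensemble_pair(cfg)
  be <- baseline_equivalence(sim$saline, sim$saline)
  expect_equal(be$t_test$statistic, 0)
  expect_equal(be$t_test$p.value, 1)
})
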