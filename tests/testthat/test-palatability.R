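rank_locked_trials <- function(n_trials = 8, flip = FALSE, seed = 1) {
  # deterministic counts proportional to the palatability rank in every bin
  tastes <- c("sucrose", "nacl", "citric_acid", "quinine")
  lev <- c(sucrose = 8, nacl = 6, citric_acid = 4, quinine = 2)
  if (flip) lev <- setNames(rev(unname(lev)), names(lev))
  t_ms <- seq(-1000, 1475, 25)
  d <- tidyr::expand_grid(
    neuron_id = "n1",
    trial = seq_len(4 * n_trials),
    time_ms = t_ms
  )
  d$taste <- rep(rep(tastes, n_trials), each = length(t_ms))
  d$count <- lev[d$taste]
  attr(d, "bin_ms") <- 25
  d
}

test_that("rank-locked rates give |rho| = 1 in every window, sign included", {
  tr <- moving_spearman(rank_locked_trials())
  expect_true(all(abs(tr$rho$rho - 1) < 1e-9))
  anti <- moving_spearman(rank_locked_trials(flip = TRUE))
  expect_true(all(abs(anti$rho$rho + 1) < 1e-9))
})

test_that("taste-independent rates give mean rho near 0 and |rho| at its null level", {
  cfg <- sim_config(
    n_neurons = 60, n_trials_per_taste = 10, identity_effect = 0,
    palatability_gain = 0, n_held = 0, seed = 31
  )
  trials <- sim_ensemble_pair(cfg)$saline
  tr <- suppressMessages(moving_spearman(trials, t_range = c(800, 1100)))
  er <- gustate:::epoch_rho(tr)
  # near-silent (floored inhibitory) neurons have no defined correlation
  late <- er[er$epoch == "late" & !is.nan(er$abs_rho), ]
  expect_lt(abs(mean(tr$rho$rho, na.rm = TRUE)), 0.05)
  # permutation oracle for the null level of |rho| at these trial counts
  set.seed(2)
  rk <- palatability_ranks()[unique(trials[, c("trial", "taste")])$taste]
  null_abs <- mean(replicate(400, {
    abs(suppressWarnings(cor(rnorm(length(rk)), sample(rk),
      method = "spearman"
    )))
  }))
  expect_lt(abs(mean(late$abs_rho) - null_abs), 0.05)
})

test_that("zero-variance windows are excluded with a count", {
  tr <- rank_locked_trials()
  tr$count[tr$taste == "sucrose"] <- 0L
  tr$count[tr$taste == "nacl"] <- 0L
  tr$count[tr$taste == "citric_acid"] <- 0L
  tr$count[tr$taste == "quinine"] <- 0L
  attr(tr, "bin_ms") <- 25
  expect_message(res <- moving_spearman(tr), "zero-variance")
  expect_true(all(is.na(res$rho$rho)))
})

test_that("PPI matches a by-hand Euclidean computation on a two-bin toy", {
  # response vectors over 2 bins (rates in Hz, baseline 0):
  # suc (4,4), nacl (4,0), ca (0,4), qhcl (0,0)
  tastes <- c("sucrose", "nacl", "citric_acid", "quinine")
  t_ms <- seq(-1000, 1475, 25)
  d <- tidyr::expand_grid(neuron_id = "n1", trial = 1:8, time_ms = t_ms)
  d$taste <- rep(rep(tastes, 2), each = length(t_ms))
  d$count <- 0L
  # late epoch center: 950 ms; central 150 ms window = 6 bins at 875-1025
  ep <- epoch_def()
  mid <- mean(ep$late)
  sel_bins <- t_ms[t_ms + 12.5 >= mid - 75 & t_ms + 12.5 <= mid + 75]
  expect_length(sel_bins, 6)
  two <- sel_bins[1:2]
  # one count in a 25 ms bin = 40 Hz; plant a two-bin code
  d$count[d$time_ms == two[1]] <- ifelse(
    d$taste[d$time_ms == two[1]] %in% c("sucrose", "nacl"), 1L, 0L
  )
  d$count[d$time_ms == two[2]] <- ifelse(
    d$taste[d$time_ms == two[2]] %in% c("sucrose", "citric_acid"), 1L, 0L
  )
  attr(d, "bin_ms") <- 25
  ppi <- compute_ppi(d)
  late <- ppi[ppi$epoch == "late", ]
  # by hand: rate vectors over the 6 central bins (Hz):
  # suc = (40,40,0,0,0,0); nacl = (40,0,...); ca = (0,40,...); q = 0
  # D(s,n)=40, D(c,q)=40 -> d_sim = 40/sqrt(6)
  # D(s,c)=40*sqrt(2)... all four dissimilar pairs distance 40*sqrt(2)? no:
  # s-c = (40,0,..)-> 40? s-c = (40-0, 40-40) = (40,0) -> 40
  # s-q = (40,40) -> 40*sqrt(2); n-c = (40,-40) -> 40*sqrt(2); n-q = 40
  d_sim_hand <- 40 / sqrt(6)
  d_dis_hand <- mean(c(40, 40 * sqrt(2), 40 * sqrt(2), 40)) / sqrt(6)
  expect_equal(late$d_similar, d_sim_hand, tolerance = 1e-9)
  expect_equal(late$d_dissimilar, d_dis_hand, tolerance = 1e-9)
  expect_equal(late$ppi, d_dis_hand - d_sim_hand, tolerance = 1e-9)
})

test_that("a pure good/bad code maximizes the PPI", {
  # suc = nacl = +r, ca = qhcl = -r, no noise
  tastes <- c("sucrose", "nacl", "citric_acid", "quinine")
  t_ms <- seq(-1000, 1475, 25)
  d <- tidyr::expand_grid(neuron_id = "n1", trial = 1:8, time_ms = t_ms)
  d$taste <- rep(rep(tastes, 2), each = length(t_ms))
  good <- d$taste %in% c("sucrose", "nacl")
  d$count <- ifelse(d$time_ms >= 0 & good, 2L, 0L)
  attr(d, "bin_ms") <- 25
  ppi <- compute_ppi(d)
  expect_true(all(ppi$d_similar < 1e-9))
  expect_true(all(ppi$ppi > 0))
  ppi_n <- compute_ppi(d, mode = "normalized")
  expect_true(all(abs(ppi_n$ppi - 1) < 1e-9))
})

test_that("PPI is exactly zero under exchangeable tastes in expectation", {
  cfg <- sim_config(
    n_neurons = 80, n_trials_per_taste = 10, identity_effect = 0,
    palatability_gain = 0, n_held = 0, seed = 33
  )
  ppi <- compute_ppi(sim_ensemble_pair(cfg)$saline)
  late <- ppi[ppi$epoch == "late", ]
  se <- sd(late$ppi) / sqrt(nrow(late))
  expect_lt(abs(mean(late$ppi)), 2.5 * se + 1e-9)
})

test_that("PPI is translation invariant and scales linearly", {
  cfg <- sim_config(n_neurons = 6, n_trials_per_taste = 8, n_held = 0, seed = 34)
  trials <- sim_ensemble_pair(cfg)$saline
  p0 <- compute_ppi(trials)
  shifted <- dplyr::mutate(trials, count = count + 3L)
  attr(shifted, "bin_ms") <- attr(trials, "bin_ms")
  p1 <- compute_ppi(shifted)
  expect_equal(p0$ppi, p1$ppi, tolerance = 1e-9)
  scaled <- dplyr::mutate(trials, count = count * 2L)
  attr(scaled, "bin_ms") <- attr(trials, "bin_ms")
  p2 <- compute_ppi(scaled)
  expect_equal(p2$ppi, 2 * p0$ppi, tolerance = 1e-9)
  p2n <- compute_ppi(scaled, mode = "normalized")
  p0n <- compute_ppi(trials, mode = "normalized")
  expect_equal(p2n$ppi, p0n$ppi, tolerance = 1e-9)
})

test_that("identical inputs give between-condition p of 1", {
  cfg <- sim_config(n_neurons = 12, n_trials_per_taste = 8, n_held = 0, seed = 35)
  ppi <- compute_ppi(sim_ensemble_pair(cfg)$saline)
  pt <- ppi_tests(ppi, ppi)
  expect_true(all(pt$between$p.value == 1))
  expect_error(ppi_tests(ppi[1:9, ], ppi), "10 neurons")
})

test_that("a planted palatability boost raises the late-epoch PPI after LiCl", {
  cfg <- sim_config(
    n_neurons = 60, n_trials_per_taste = 20, palatability_gain = 3,
    illness_palatability_boost = 2, illness_identity_loss = 0,
    illness_magnitude_shrink = 0, n_held = 0, seed = 36
  )
  sim <- sim_ensemble_pair(cfg)
  pt <- ppi_tests(compute_ppi(sim$saline), compute_ppi(sim$licl))
  late <- pt$between[pt$between$epoch == "late", ]
  expect_lt(late$p.value, 0.05)
  vz <- pt$vs_zero
  expect_gt(
    vz$mean_ppi[vz$epoch == "late" & vz$condition == "licl"],
    vz$mean_ppi[vz$epoch == "late" & vz$condition == "saline"]
  )
})

test_that("the Kruskal-Wallis epoch comparison sees the palatability boost", {
  cfg <- sim_config(
    n_neurons = 50, n_trials_per_taste = 15, palatability_gain = 3,
    illness_palatability_boost = 1, illness_identity_loss = 0,
    illness_magnitude_shrink = 0, n_held = 0, seed = 37
  )
  sim <- sim_ensemble_pair(cfg)
  trs <- moving_spearman(sim$saline, t_range = c(200, 1150))
  trl <- moving_spearman(sim$licl, t_range = c(200, 1150))
  pct <- palatability_condition_test(trs, trl)
  late <- pct[pct$epoch == "late", ]
  expect_lt(late$p.value, 0.05)
  expect_gt(late$mean_licl, late$mean_saline)
  expect_equal(late$df, 1)
})
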