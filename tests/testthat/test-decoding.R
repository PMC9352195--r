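test_that("widely separated Gaussian clusters decode perfectly", {
  set.seed(1)
  tastes <- c("sucrose", "nacl", "citric_acid", "quinine")
  mu <- matrix(rnorm(4 * 6, sd = 10), 4, 6) # 10x the unit noise SD
  rows <- list()
  for (tr in 1:24) {
    tst <- tastes[(tr - 1) %% 4 + 1]
    for (n in 1:6) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        neuron_id = paste0("n", n), trial = tr, taste = tst,
        time_ms = seq(-1000, 1475, 25),
        count = rpois(100, 2)
      )
    }
  }
  d <- dplyr::bind_rows(rows)
  # plant separation in one post-delivery bin
  sel <- d$time_ms >= 250 & d$time_ms < 500
  d$count[sel] <- rpois(sum(sel), 5) +
    round(10 * mu[cbind(match(d$taste[sel], tastes),
      as.integer(sub("n", "", d$neuron_id[sel]))
    )]^0 * abs(mu[cbind(
      match(d$taste[sel], tastes),
      as.integer(sub("n", "", d$neuron_id[sel]))
    )]))
  attr(d, "bin_ms") <- 25
  res <- lda_loo_accuracy(d, t_range = c(250, 500), seed = 2)
  expect_equal(res$accuracy$accuracy, 1)
})

test_that("decisions match the closed-form Fisher discriminant on a 2-class toy", {
  set.seed(3)
  n <- 40
  p <- 3
  m_a <- c(1, 0, -1)
  m_b <- c(-1, 1, 0)
  X <- rbind(
    matrix(rnorm(n * p), n, p) + rep(m_a, each = n),
    matrix(rnorm(n * p), n, p) + rep(m_b, each = n)
  )
  y <- rep(c("a", "b"), each = n)
  model <- gustate:::lda_train(X, y)
  ours <- gustate:::lda_predict(model, X)
  # oracle uses the same pooled covariance estimate, closed form
  means <- rbind(colMeans(X[y == "a", ]), colMeans(X[y == "b", ]))
  Xc <- X - means[as.integer(factor(y)), ]
  S <- crossprod(Xc) / (2 * n - 2)
  oracle <- fisher_predict(means[1, ], means[2, ], S, X)
  expect_equal(ours, oracle)
})

test_that("our LOO-LDA agrees with an established implementation", {
  skip_if_not_installed("MASS")
  set.seed(4)
  n <- 15
  X <- rbind(
    matrix(rnorm(n * 2), n, 2),
    matrix(rnorm(n * 2, mean = 2), n, 2),
    matrix(rnorm(n * 2, mean = -2), n, 2)
  )
  y <- rep(c("a", "b", "c"), each = n)
  ref <- MASS::lda(X, grouping = y, CV = TRUE)$class
  ours <- vapply(seq_len(nrow(X)), function(i) {
    m <- gustate:::lda_train(X[-i, ], y[-i])
    gustate:::lda_predict(m, X[i, , drop = FALSE])
  }, character(1))
  expect_gt(mean(ours == as.character(ref)), 0.95)
})

test_that("label shuffling drives accuracy to the 25 % chance level", {
  cfg <- sim_config(
    n_neurons = 10, n_trials_per_taste = 10, identity_effect = 4,
    n_held = 0, seed = 21
  )
  trials <- sim_ensemble_pair(cfg)$saline
  tt <- unique(trials[, c("trial", "taste")])
  set.seed(9)
  relab <- setNames(sample(tt$taste), tt$trial)
  shuf <- dplyr::mutate(trials, taste = relab[as.character(trial)])
  attr(shuf, "bin_ms") <- attr(trials, "bin_ms")
  res <- lda_loo_accuracy(shuf, t_range = c(200, 1200), seed = 10)
  se <- sqrt(0.25 * 0.75 / res$n_trials)
  expect_true(all(abs(res$accuracy$accuracy - 0.25) < 3 * se))
})

test_that("accuracy is invariant to per-neuron affine rescaling", {
  cfg <- sim_config(
    n_neurons = 8, n_trials_per_taste = 8, identity_effect = 4,
    n_held = 0, seed = 22
  )
  trials <- sim_ensemble_pair(cfg)$saline
  r1 <- lda_loo_accuracy(trials, t_range = c(200, 700), seed = 1)
  scaled <- dplyr::mutate(trials, count = count * 3L)
  attr(scaled, "bin_ms") <- attr(trials, "bin_ms")
  r2 <- lda_loo_accuracy(scaled, t_range = c(200, 700), seed = 1)
  expect_equal(r1$accuracy$accuracy, r2$accuracy$accuracy)
})

test_that("more identity separation never hurts average decoding", {
  accs <- vapply(c(0, 2, 5), function(ie) {
    mean(vapply(1:4, function(s) {
      cfg <- sim_config(
        n_neurons = 8, n_trials_per_taste = 8, identity_effect = ie,
        n_held = 0, seed = 30 + s
      )
      tr <- sim_ensemble_pair(cfg)$saline
      r <- lda_loo_accuracy(tr, t_range = c(450, 700), seed = s)
      mean(r$accuracy$accuracy)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(accs) > -0.02))
})

test_that("identical condition inputs give corrected p of 1", {
  cfg <- sim_config(n_neurons = 6, n_trials_per_taste = 8, n_held = 0, seed = 23)
  tr <- sim_ensemble_pair(cfg)$saline
  r <- lda_loo_accuracy(tr, t_range = c(200, 1200), seed = 2)
  et <- epoch_condition_test(r, r)
  expect_true(all(et$p.adj == 1))
})

test_that("a LiCl identity loss shows up in middle and late epochs", {
  cfg <- sim_config(
    n_neurons = 25, n_trials_per_taste = 25, identity_effect = 3,
    illness_identity_loss = 0.8, n_held = 0, seed = 24
  )
  sim <- sim_ensemble_pair(cfg)
  rs <- lda_loo_accuracy(sim$saline, t_range = c(200, 1200), seed = 3)
  rl <- lda_loo_accuracy(sim$licl, t_range = c(200, 1200), seed = 4)
  et <- epoch_condition_test(rs, rl)
  expect_lt(et$p.adj[et$epoch == "middle"], 0.05)
  expect_gt(
    et$mean_saline[et$epoch == "middle"],
    et$mean_licl[et$epoch == "middle"]
  )
})

test_that("within-session blocks never test on training trials", {
  cfg <- sim_config(
    n_neurons = 10, n_trials_per_taste = 12, identity_effect = 4,
    n_held = 0, seed = 25
  )
  w <- sim_ensemble_within(cfg, drift = FALSE)
  res <- within_session_blocks(w$trials, n_iter = 2, seed = 5)
  tt <- unique(w$trials[, c("trial", "taste")])
  tt <- tt[order(tt$trial), ]
  first5 <- unlist(lapply(split(tt$trial, tt$taste), head, 5))
  expect_length(intersect(res$trial_correct$trial, first5), 0)
  expect_equal(sum(res$blocks$n_trials), 4 * (12 - 5))
  expect_error(
    within_session_blocks(w$trials, train_trials = 10, block_trials = 5),
    "at least"
  )
})

test_that("identity decay after sickness onset lowers late blocks", {
  cfg <- sim_config(
    n_neurons = 20, n_trials_per_taste = 30, identity_effect = 4,
    illness_identity_loss = 0.9, sickness_onset = 12, n_held = 0,
    seed = 26
  )
  w <- sim_ensemble_within(cfg, drift = TRUE)
  res <- within_session_blocks(w$trials, n_iter = 3, seed = 6)
  b <- res$blocks
  expect_lt(mean(b$accuracy[b$block >= 4]), mean(b$accuracy[b$block == 1]))
})

test_that("stationary sessions show no block effect across animals", {
  results <- lapply(1:6, function(s) {
    cfg <- sim_config(
      n_neurons = 10, n_trials_per_taste = 15, identity_effect = 3,
      n_held = 0, seed = 40 + s
    )
    w <- sim_ensemble_within(cfg, drift = FALSE)
    within_session_blocks(w$trials, n_iter = 2, seed = s)
  })
  names(results) <- paste0("animal", 1:6)
  ba <- block_accuracy_anova(results)
  expect_s3_class(ba, "block_anova")
  expect_true(is.finite(ba$anova$statistic))
})
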