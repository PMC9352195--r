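# Regularized linear discriminant classifier on pooled covariance.
# Shrinks toward the spherical average of the diagonal when the pooled
# covariance is ill-conditioned (or always, with shrinkage > 0).
lda_train <- function(X, y, shrinkage = NULL, quiet = FALSE) {
  y <- factor(y)
  classes <- levels(y)
  p <- ncol(X)
  n <- nrow(X)
  means <- t(vapply(
    classes, function(cl) colMeans(X[y == cl, , drop = FALSE]),
    numeric(p)
  ))
  Xc <- X - means[as.integer(y), , drop = FALSE]
  S <- crossprod(Xc) / (n - length(classes))
  applied <- FALSE
  lam <- if (is.null(shrinkage)) 0 else shrinkage
  target <- mean(diag(S)) * diag(p)
  Si <- NULL
  repeat {
    Sreg <- (1 - lam) * S + lam * target
    Si <- tryCatch(
      {
        if (rcond(Sreg) < 1e-10) NULL else solve(Sreg)
      },
      error = function(e) NULL
    )
    if (!is.null(Si)) break
    applied <- TRUE
    lam <- max(lam * 2, 0.1)
    if (lam >= 1) {
      Si <- solve(target + 1e-8 * diag(p))
      break
    }
  }
  if (applied && !quiet) {
    message("singular within-class covariance: shrinkage ", signif(lam, 2),
      " applied"
    )
  }
  W <- means %*% Si # classes x p
  b <- -0.5 * rowSums(W * means) # equal priors (balanced designs)
  list(W = W, b = b, classes = classes, shrinkage_applied = applied)
}

lda_predict <- function(model, X) {
  sc <- X %*% t(model$W) + rep(model$b, each = nrow(X))
  idx <- apply(sc, 1, function(r) {
    top <- which(r >= max(r) - 1e-12)
    if (length(top) > 1) sample(top, 1) else top
  })
  model$classes[idx]
}

# trials x neurons rate matrix for one time bin of width bin_ms starting
# at t0 (ms); rows ordered by trial index, with the taste labels attached.
bin_feature_matrix <- function(trials, t0, bin_ms) {
  d <- trials |>
    dplyr::filter(.data$time_ms >= t0, .data$time_ms < t0 + bin_ms) |>
    dplyr::group_by(.data$neuron_id, .data$trial, .data$taste) |>
    dplyr::summarise(n = sum(.data$count), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "neuron_id", values_from = "n")
  d <- d[order(d$trial), ]
  X <- as.matrix(d[, setdiff(names(d), c("trial", "taste"))])
  list(X = X * (1000 / bin_ms), y = d$taste, trial = d$trial)
}

#' Leave-one-out LDA taste decoding across time
#'
#' For each `bin_ms` time bin, an ensemble feature vector (one firing rate
#' per simultaneously recorded neuron) is built per trial and a linear
#' discriminant classifier with pooled covariance (shrinkage-regularized
#' when ill-conditioned) is fit on all trials but one and asked to
#' identify the held-out trial's taste; cycling over trials gives the
#' per-bin accuracy. Chance is 1/4 for the four-taste set.
#'
#' @param trials Long trial table for one session (simultaneous ensemble).
#' @param bin_ms Decoding bin width (ms).
#' @param t_range `c(start, end)` ms; bins start every `bin_ms` from
#'   `start`.
#' @param epochs An [epoch_def()] used for epoch summaries (a bin belongs
#'   to the epoch containing its center).
#' @param seed Seed for random tie-breaking.
#' @return Object of class `decoding_result`: `accuracy` tibble
#'   `(time_ms, accuracy, n_trials)` (bin start times), `correct` logical
#'   matrix trials x bins, `epoch_means` tibble, `n_neurons`, `n_trials`.
#' @export
#' @examples
#' cfg <- sim_config(n_neurons = 6, n_trials_per_taste = 8, seed = 5)
#' res <- lda_loo_accuracy(sim_ensemble_pair(cfg)$saline,
#'   t_range = c(200, 700)
#' )
#' res$epoch_means
lda_loo_accuracy <- function(trials, bin_ms = 250, t_range = c(-1000, 1500),
                             epochs = epoch_def(), seed = NULL) {
  validate_trials(trials)
  if (!is.null(seed)) set.seed(seed)
  starts <- seq(t_range[1], t_range[2] - bin_ms, by = bin_ms)
  per_taste <- table(unique(trials[, c("trial", "taste")])$taste)
  if (any(per_taste < 2)) stop("need at least 2 trials per taste")
  n_trials <- sum(per_taste)
  correct <- matrix(NA, n_trials, length(starts))
  n_shrunk <- 0L
  for (j in seq_along(starts)) {
    fm <- bin_feature_matrix(trials, starts[j], bin_ms)
    pred <- character(n_trials)
    for (i in seq_len(n_trials)) {
      m <- lda_train(fm$X[-i, , drop = FALSE], fm$y[-i], quiet = TRUE)
      n_shrunk <- n_shrunk + m$shrinkage_applied
      pred[i] <- lda_predict(m, fm$X[i, , drop = FALSE])
    }
    correct[, j] <- pred == fm$y
  }
  if (n_shrunk > 0) {
    message(
      "singular within-class covariance in ", n_shrunk, " of ",
      n_trials * length(starts), " fits: shrinkage applied"
    )
  }
  acc <- tibble::tibble(
    time_ms = starts, accuracy = colMeans(correct), n_trials = n_trials
  )
  centers <- starts + bin_ms / 2
  epoch_means <- purrr::imap_dfr(unclass(epochs), function(w, nm) {
    sel <- centers >= w[1] & centers < w[2]
    tibble::tibble(
      epoch = nm,
      accuracy = mean(correct[, sel, drop = FALSE]),
      n_bins = sum(sel)
    )
  })
  structure(
    list(
      accuracy = acc, correct = correct, epoch_means = epoch_means,
      epochs = epochs, bin_ms = bin_ms,
      n_neurons = dplyr::n_distinct(trials$neuron_id), n_trials = n_trials
    ),
    class = "decoding_result"
  )
}

#' @export
print.decoding_result <- function(x, ...) {
  cat(
    "LOO-LDA decoding:", x$n_neurons, "neurons,", x$n_trials,
    "trials,", nrow(x$accuracy), "bins\n"
  )
  print(x$epoch_means)
  invisible(x)
}

# Per-trial mean correctness within each epoch for one decoding_result.
epoch_trial_correct <- function(res) {
  centers <- res$accuracy$time_ms + res$bin_ms / 2
  purrr::imap_dfr(unclass(res$epochs), function(w, nm) {
    sel <- centers >= w[1] & centers < w[2]
    tibble::tibble(
      epoch = nm,
      trial_correct = rowMeans(res$correct[, sel, drop = FALSE])
    )
  })
}

#' Per-epoch condition comparison of decoding accuracy
#'
#' Compares conditions per epoch with a rank-based two-sample test
#' (Mann--Whitney U; a Welch t variant is available),
#' Bonferroni-corrected over epochs. When each side provides two or more
#' sessions, the statistical unit is the session's epoch accuracy (the
#' level at which decoding results are independent); with a single
#' session per side the test falls back to per-trial epoch-mean
#' correctness, which shares one fitted classifier per session and is
#' therefore only a within-ensemble comparison.
#'
#' @param saline,licl A `decoding_result` or list of them per condition.
#' @param method `"rank"` (two-sample Wilcoxon) or `"t"` (Welch t).
#' @return A tibble: `epoch, mean_saline, mean_licl, statistic, p.value,
#'   p.adj` (Bonferroni).
#' @export
epoch_condition_test <- function(saline, licl, method = c("rank", "t")) {
  method <- match.arg(method)
  as_list <- function(x) if (inherits(x, "decoding_result")) list(x) else x
  saline <- as_list(saline)
  licl <- as_list(licl)
  session_level <- length(saline) >= 2 && length(licl) >= 2
  pool <- function(results) {
    if (session_level) {
      dplyr::bind_rows(purrr::map(results, function(r) {
        dplyr::rename(r$epoch_means, trial_correct = "accuracy")
      }))
    } else {
      dplyr::bind_rows(purrr::map(results, epoch_trial_correct))
    }
  }
  ds <- pool(saline)
  dl <- pool(licl)
  eps <- unique(ds$epoch)
  out <- purrr::map_dfr(eps, function(ep) {
    a <- ds$trial_correct[ds$epoch == ep]
    b <- dl$trial_correct[dl$epoch == ep]
    if (isTRUE(all.equal(a, b))) {
      return(tibble::tibble(
        epoch = ep, mean_saline = mean(a), mean_licl = mean(b),
        statistic = NA_real_, p.value = 1
      ))
    }
    ht <- if (method == "rank") {
      suppressWarnings(wilcox.test(a, b))
    } else {
      t.test(a, b)
    }
    tibble::tibble(
      epoch = ep, mean_saline = mean(a), mean_licl = mean(b),
      statistic = unname(ht$statistic), p.value = ht$p.value
    )
  })
  out$p.adj <- pmin(out$p.value * length(eps), 1)
  out
}

#' Within-session block decoding against a pre-sickness baseline
#'
#' Trains the ensemble LDA once on the first `train_trials` trials per
#' taste (the pre-sickness baseline) and tests every later trial,
#' averaging correctness across post-stimulus decoding bins and across
#' `n_iter` random tie-breaking iterations. Tested trials are grouped
#' into consecutive `block_trials`-per-taste blocks. Analysis is
#' restricted to taste-responsive neurons. Training trials are never
#' tested.
#'
#' @param trials Long trial table with trials in delivery order.
#' @param train_trials Training trials per taste.
#' @param block_trials Tested trials per taste per block.
#' @param bin_ms Decoding bin width (ms).
#' @param post_window Post-stimulus window decoded, ms.
#' @param responsive_only Restrict to taste-responsive neurons.
#' @param n_iter Tie-breaking iterations averaged per tested trial.
#' @param seed Seed.
#' @return Object of class `block_decoding`: `blocks` tibble
#'   `(block, accuracy, n_trials)` and `trial_correct`
#'   `(trial, block, correct)`.
#' @export
within_session_blocks <- function(trials, train_trials = 5, block_trials = 5,
                                  bin_ms = 250, post_window = c(200, 1200),
                                  responsive_only = TRUE, n_iter = 10,
                                  seed = NULL) {
  validate_trials(trials)
  if (!is.null(seed)) set.seed(seed)
  if (responsive_only) {
    cls <- classify_responsiveness(trials)
    keep <- cls$neuron_id[cls$responsive]
    if (length(keep) < 2) {
      stop("fewer than 2 taste-responsive neurons in this session")
    }
    trials <- dplyr::filter(trials, .data$neuron_id %in% keep)
  }
  tt <- unique(trials[, c("trial", "taste")])
  tt <- tt[order(tt$trial), ]
  tt$within_taste <- stats::ave(seq_len(nrow(tt)), tt$taste, FUN = seq_along)
  per_taste <- max(tt$within_taste)
  if (per_taste < train_trials + block_trials) {
    stop(
      "need at least ", train_trials + block_trials,
      " trials per taste; have ", per_taste
    )
  }
  train_ids <- tt$trial[tt$within_taste <= train_trials]
  test_tt <- tt[tt$within_taste > train_trials, ]
  test_tt$block <- ceiling((test_tt$within_taste - train_trials) / block_trials)

  starts <- seq(post_window[1], post_window[2] - bin_ms, by = bin_ms)
  correct <- matrix(0, nrow(test_tt), length(starts))
  n_shrunk <- 0L
  for (j in seq_along(starts)) {
    fm <- bin_feature_matrix(trials, starts[j], bin_ms)
    tr <- fm$trial %in% train_ids
    model <- lda_train(fm$X[tr, , drop = FALSE], fm$y[tr], quiet = TRUE)
    n_shrunk <- n_shrunk + model$shrinkage_applied
    te <- match(test_tt$trial, fm$trial)
    for (it in seq_len(n_iter)) {
      pred <- lda_predict(model, fm$X[te, , drop = FALSE])
      correct[, j] <- correct[, j] + (pred == fm$y[te]) / n_iter
    }
  }
  if (n_shrunk > 0) {
    message(
      "singular within-class covariance in ", n_shrunk, " of ",
      length(starts), " training fits: shrinkage applied"
    )
  }
  test_tt$correct <- rowMeans(correct)
  blocks <- test_tt |>
    dplyr::group_by(.data$block) |>
    dplyr::summarise(
      accuracy = mean(.data$correct), n_trials = dplyr::n(),
      .groups = "drop"
    )
  structure(
    list(
      blocks = blocks,
      trial_correct = tibble::as_tibble(
        test_tt[, c("trial", "taste", "block", "correct")]
      )
    ),
    class = "block_decoding"
  )
}

#' Repeated-measures ANOVA on block decoding across sessions
#'
#' Block accuracies from several sessions are min-max normalized within
#' each session, then tested for a block effect with a repeated-measures
#' ANOVA (session as subject) and Bonferroni-corrected paired t follow-ups
#' of each later block against block 1.
#'
#' @param block_results Named list of `block_decoding` objects (or their
#'   `blocks` tibbles), one per session/animal.
#' @return List of class `block_anova`: `anova` tibble and `followups`.
#' @export
block_accuracy_anova <- function(block_results) {
  d <- purrr::imap_dfr(block_results, function(x, nm) {
    b <- if (inherits(x, "block_decoding")) x$blocks else x
    r <- range(b$accuracy)
    tibble::tibble(
      session = nm, block = b$block,
      accuracy = if (diff(r) > 0) (b$accuracy - r[1]) / diff(r) else
        rep(0.5, nrow(b))
    )
  })
  d$session <- factor(d$session)
  d$block_f <- factor(d$block)
  fit <- aov(accuracy ~ block_f + Error(session / block_f), data = d)
  tab <- summary(fit)[["Error: session:block_f"]][[1]]
  res <- tibble::tibble(
    term = "block",
    df = tab["block_f", "Df"], df_resid = tab["Residuals", "Df"],
    statistic = tab["block_f", "F value"], p.value = tab["block_f", "Pr(>F)"]
  )
  b1 <- d$accuracy[d$block == 1]
  later <- sort(unique(d$block[d$block > 1]))
  fl <- purrr::map_dfr(later, function(bk) {
    bb <- d$accuracy[d$block == bk]
    ht <- t.test(bb, b1, paired = TRUE)
    tibble::tibble(
      block = bk, estimate = unname(ht$estimate),
      statistic = unname(ht$statistic), p.value = ht$p.value
    )
  })
  fl$p.adj <- pmin(fl$p.value * nrow(fl), 1)
  structure(list(anova = res, followups = fl, data = d),
    class = "block_anova"
  )
}
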