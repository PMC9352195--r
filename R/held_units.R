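# Waveform dissimilarity: Euclidean distance between mean waveforms,
# normalized per sample by the pooled SD (a distribution-free scalar;
# the statistic is pluggable -- any function of two spike x sample
# matrices returning a scalar can be passed where `stat_fn` is accepted).
waveform_stat <- function(wf_a, wf_b) {
  if (ncol(wf_a) != ncol(wf_b)) {
    stop("waveform sample lengths differ (", ncol(wf_a), " vs ", ncol(wf_b), ")")
  }
  m1 <- colMeans(wf_a)
  m2 <- colMeans(wf_b)
  v1 <- apply(wf_a, 2, var)
  v2 <- apply(wf_b, 2, var)
  n1 <- nrow(wf_a)
  n2 <- nrow(wf_b)
  pooled_sd <- sqrt(((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2))
  pooled_sd[pooled_sd == 0] <- 1e-12
  sqrt(mean(((m1 - m2) / pooled_sd)^2))
}

wf_matrix <- function(wf_tbl) {
  tidyr::pivot_wider(wf_tbl[, c("spike", "sample", "voltage")],
    names_from = "sample", values_from = "voltage"
  ) |>
    dplyr::select(-"spike") |>
    as.matrix()
}

# Within-session null values: first third vs last third of each session's
# spikes, bootstrapped (resampling spikes within each third).
within_session_null <- function(wf_a, wf_b, n_boot, stat_fn) {
  one_session <- function(wf) {
    n <- nrow(wf)
    third <- floor(n / 3)
    first <- wf[seq_len(third), , drop = FALSE]
    last <- wf[(n - third + 1):n, , drop = FALSE]
    vapply(seq_len(n_boot), function(b) {
      stat_fn(
        first[sample(third, third, replace = TRUE), , drop = FALSE],
        last[sample(third, third, replace = TRUE), , drop = FALSE]
      )
    }, numeric(1))
  }
  c(one_session(wf_a), one_session(wf_b))
}

#' Decide whether a unit was stably held across two sessions
#'
#' Spike-shape analysis: the between-session dissimilarity (Euclidean
#' distance between mean waveforms normalized by the pooled per-sample
#' SD) is compared to a within-session null built by contrasting each
#' session's first-third and last-third waveforms (bootstrapped). The
#' unit is held when the between-session value falls below the 95th
#' percentile of the within-session null.
#'
#' @param wf Long waveform tibble for one unit
#'   `(session, spike, sample, voltage)` with two sessions, or a list of
#'   two spike-by-sample matrices.
#' @param n_boot Bootstrap resamples per session for the null.
#' @param percentile Null percentile defining the criterion.
#' @param stat_fn Dissimilarity statistic (two matrices -> scalar).
#' @param seed Seed for the bootstrap.
#' @return A one-row tibble: `between_stat, threshold, held` (class
#'   `held_decision`), with the null values as attribute `null`.
#' @export
held_unit_test <- function(wf, n_boot = 100, percentile = 95,
                           stat_fn = waveform_stat, seed = NULL) {
  if (is.data.frame(wf)) {
    sess <- sort(unique(wf$session))
    if (length(sess) != 2) stop("need exactly 2 sessions")
    wf <- list(
      wf_matrix(wf[wf$session == sess[1], ]),
      wf_matrix(wf[wf$session == sess[2], ])
    )
  }
  wf_a <- wf[[1]]
  wf_b <- wf[[2]]
  if (nrow(wf_a) < 50 || nrow(wf_b) < 50) {
    stop("need at least 50 waveforms per session")
  }
  if (!is.null(seed)) set.seed(seed)
  between <- stat_fn(wf_a, wf_b)
  null_vals <- within_session_null(wf_a, wf_b, n_boot, stat_fn)
  thr <- as.numeric(quantile(null_vals, percentile / 100))
  out <- tibble::tibble(
    between_stat = between, threshold = thr, held = between < thr
  )
  attr(out, "null") <- null_vals
  class(out) <- c("held_decision", class(out))
  out
}

#' Screen a population of units for stability across sessions
#'
#' Pools the within-session null across all units (the criterion the
#' population analysis uses) and flags each unit whose between-session
#' statistic falls below the pooled null's 95th percentile.
#'
#' @param wf_tbl Waveform tibble `(unit_id, session, spike, sample,
#'   voltage)` as from [sim_waveforms()].
#' @inheritParams held_unit_test
#' @return A tibble `(unit_id, between_stat, threshold, held)`.
#' @export
held_unit_screen <- function(wf_tbl, n_boot = 50, percentile = 95,
                             stat_fn = waveform_stat, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  units <- unique(wf_tbl$unit_id)
  per_unit <- purrr::map(units, function(u) {
    d <- wf_tbl[wf_tbl$unit_id == u, ]
    sess <- sort(unique(d$session))
    wf_a <- wf_matrix(d[d$session == sess[1], ])
    wf_b <- wf_matrix(d[d$session == sess[2], ])
    list(
      between = stat_fn(wf_a, wf_b),
      null = within_session_null(wf_a, wf_b, n_boot, stat_fn)
    )
  })
  pooled_null <- unlist(purrr::map(per_unit, "null"))
  thr <- as.numeric(quantile(pooled_null, percentile / 100))
  tibble::tibble(
    unit_id = units,
    between_stat = vapply(per_unit, `[[`, numeric(1), "between"),
    threshold = thr,
    held = .data$between_stat < thr
  )
}

#' Response-difference vectors for held units
#'
#' Per held unit and taste, the condition response is the mean
#' post-delivery (250 to 750 ms) firing rate minus the mean pre-delivery
#' (-750 to -250 ms) rate, computed on the unit's min-max-normalized
#' rates (as a percentage of its maximum responsiveness across both
#' sessions). Each unit x taste yields one response-difference (RD)
#' point (saline response, LiCl response), summarized by its distance
#' from the origin and its Cartesian angle (degrees in `[0, 360)`; the
#' quadrant encodes the excitatory/inhibitory nature of the response in
#' each condition). Units silent in both sessions are excluded with a
#' message. A set of `n` held units yields exactly `4 n` RDs.
#'
#' @param saline_trials,licl_trials Long trial tables for the two
#'   sessions (held units present in both).
#' @param held_ids Character vector of held unit ids; defaults to all
#'   neurons common to both sessions.
#' @param pre_win,post_win Windows in ms.
#' @return A tibble `(neuron_id, taste, saline_resp, licl_resp, distance,
#'   angle)`; responses in percent of maximum responsiveness.
#' @export
response_difference_vectors <- function(saline_trials, licl_trials,
                                        held_ids = NULL,
                                        pre_win = c(-750, -250),
                                        post_win = c(250, 750)) {
  if (is.null(held_ids)) {
    held_ids <- intersect(
      unique(saline_trials$neuron_id), unique(licl_trials$neuron_id)
    )
  }
  mean_win <- function(trials, win) {
    window_rates(trials, win) |>
      dplyr::group_by(.data$neuron_id, .data$taste) |>
      dplyr::summarise(rate = mean(.data$rate), .groups = "drop")
  }
  tab <- dplyr::bind_rows(
    dplyr::mutate(mean_win(saline_trials, pre_win),
      condition = "saline", window = "pre"
    ),
    dplyr::mutate(mean_win(saline_trials, post_win),
      condition = "saline", window = "post"
    ),
    dplyr::mutate(mean_win(licl_trials, pre_win),
      condition = "licl", window = "pre"
    ),
    dplyr::mutate(mean_win(licl_trials, post_win),
      condition = "licl", window = "post"
    )
  ) |>
    dplyr::filter(.data$neuron_id %in% held_ids)

  silent <- tab |>
    dplyr::group_by(.data$neuron_id) |>
    dplyr::summarise(silent = all(.data$rate == 0))
  if (any(silent$silent)) {
    message(
      sum(silent$silent), " unit(s) silent in both sessions excluded: ",
      paste(silent$neuron_id[silent$silent], collapse = ", ")
    )
    tab <- dplyr::filter(
      tab, !.data$neuron_id %in% silent$neuron_id[silent$silent]
    )
  }

  tab |>
    dplyr::group_by(.data$neuron_id) |>
    dplyr::mutate(
      norm = 100 * (.data$rate - min(.data$rate)) /
        (max(.data$rate) - min(.data$rate))
    ) |>
    dplyr::ungroup() |>
    dplyr::select(-"rate") |>
    tidyr::pivot_wider(
      names_from = c("condition", "window"), values_from = "norm"
    ) |>
    dplyr::mutate(
      saline_resp = .data$saline_post - .data$saline_pre,
      licl_resp = .data$licl_post - .data$licl_pre,
      distance = sqrt(.data$saline_resp^2 + .data$licl_resp^2),
      angle = (atan2(.data$licl_resp, .data$saline_resp) * 180 / pi) %% 360
    ) |>
    dplyr::select(
      "neuron_id", "taste", "saline_resp", "licl_resp", "distance", "angle"
    )
}

#' Gaussian-mixture clustering of response-difference vectors
#'
#' Fits full-covariance Gaussian mixtures with 1 to `k_max` components to
#' the RD points (saline response, LiCl response), selects the component
#' count by BIC, and assigns each point to its cluster only when it falls
#' inside the cluster's 95 % Mahalanobis confidence ellipse (otherwise it
#' is left unassigned). The number of peaks in the circular histogram of
#' RD angles is reported as a model-free cross-check.
#'
#' @param rds RD tibble from [response_difference_vectors()].
#' @param k_max Largest component count tried.
#' @param conf Confidence level of the membership ellipse.
#' @param angle_bin Bin width (degrees) of the angle histogram cross-check.
#' @return Object of class `rd_clusters`: `assignments` (the RD tibble
#'   plus `cluster`, `NA` when unassigned), `k`, `bic` tibble,
#'   `centroids`, `n_angle_peaks`, `model` (the mclust fit).
#' @export
gmm_cluster <- function(rds, k_max = 6, conf = 0.95, angle_bin = 30) {
  if (nrow(rds) < 10) stop("need at least 10 RD points")
  X <- as.matrix(rds[, c("saline_resp", "licl_resp")])
  fit <- mclust::Mclust(X, G = 1:k_max, modelNames = "VVV", verbose = FALSE)
  if (is.null(fit)) stop("Gaussian mixture fit failed")
  cl <- fit$classification
  lim <- qchisq(conf, df = 2)
  valid <- vapply(seq_len(nrow(X)), function(i) {
    k <- cl[i]
    S <- fit$parameters$variance$sigma[, , k] + diag(2) * 1e-6
    mu <- fit$parameters$mean[, k]
    mahalanobis(X[i, , drop = FALSE], mu, S) <= lim
  }, logical(1))
  out <- rds
  out$cluster <- ifelse(valid, cl, NA_integer_)

  # circular angle histogram peaks (strict local maxima over neighbors)
  br <- seq(0, 360, by = angle_bin)
  counts <- hist(rds$angle, breaks = br, plot = FALSE)$counts
  nb <- length(counts)
  left <- counts[c(nb, seq_len(nb - 1))]
  right <- counts[c(2:nb, 1)]
  n_peaks <- sum(counts > left & counts >= right & counts > 0)

  bic_tbl <- tibble::tibble(
    k = as.integer(rownames(fit$BIC)),
    bic = as.numeric(fit$BIC[, "VVV"])
  )
  structure(
    list(
      assignments = out, k = fit$G, bic = bic_tbl,
      centroids = t(fit$parameters$mean), n_angle_peaks = n_peaks,
      model = fit
    ),
    class = "rd_clusters"
  )
}

#' @export
print.rd_clusters <- function(x, ...) {
  cat(
    "RD clustering:", x$k, "clusters by BIC;",
    sum(is.na(x$assignments$cluster)), "of", nrow(x$assignments),
    "points unassigned;", x$n_angle_peaks, "angle-histogram peaks\n"
  )
  invisible(x)
}

#' Cluster-specific palatability ANOVA
#'
#' Tests whether the illness-related change in palatability coding
#' depends on the RD cluster a neuron belongs to. The response is each
#' neuron's saline - LiCl difference in epoch-mean Spearman rho^2 (the
#' condition dimension enters through this difference, which also
#' removes the neuron-specific palatability strength shared by both
#' sessions); an aligned-rank-transform mixed ANOVA with factors cluster
#' (between neurons) x epoch (within, neuron as subject) then reports
#' the cluster x epoch interaction -- the interaction between cluster,
#' epoch and condition, with (k-1)(e-1) numerator df. Per-cluster paired
#' Wilcoxon tests of the late-epoch condition effect follow. A neuron's
#' cluster is the majority vote over its assigned RD points; clusters
#' with fewer than 3 neurons are dropped with a message.
#'
#' Because cluster membership is a between-neuron label, its null
#' distribution is obtained exactly by permuting cluster labels across
#' neurons (`n_perm` label permutations of the ART F statistic), which
#' stays valid whatever the within-neuron covariance of the epoch
#' differences; `n_perm = 0` falls back to the parametric ART F test.
#'
#' @param clusters An `rd_clusters` object (or its `assignments` tibble).
#' @param saline_trace,licl_trace `palatability_trace` objects for the
#'   two sessions (held units).
#' @param epochs An [epoch_def()].
#' @param n_perm Cluster-label permutations for the interaction p-value.
#' @param seed Seed for the permutations.
#' @return List of class `cluster_anova`: `anova` (ART table with the
#'   three-way interaction), `followups` per cluster, `data`.
#' @export
cluster_palatability_anova <- function(clusters, saline_trace, licl_trace,
                                       epochs = epoch_def(), n_perm = 199,
                                       seed = NULL) {
  asg <- if (inherits(clusters, "rd_clusters")) {
    clusters$assignments
  } else {
    clusters
  }
  unit_cluster <- asg |>
    dplyr::filter(!is.na(.data$cluster)) |>
    dplyr::group_by(.data$neuron_id) |>
    dplyr::summarise(
      cluster = as.integer(names(which.max(table(.data$cluster))))
    )
  sizes <- dplyr::count(unit_cluster, .data$cluster)
  small <- sizes$cluster[sizes$n < 3]
  if (length(small)) {
    message(
      "dropping cluster(s) with < 3 units: ", paste(small, collapse = ", ")
    )
    unit_cluster <- dplyr::filter(unit_cluster, !.data$cluster %in% small)
  }
  if (dplyr::n_distinct(unit_cluster$cluster) < 2) {
    stop("need at least 2 clusters with >= 3 units")
  }
  d <- dplyr::bind_rows(
    dplyr::mutate(epoch_rho(saline_trace, epochs), condition = "saline"),
    dplyr::mutate(epoch_rho(licl_trace, epochs), condition = "licl")
  ) |>
    dplyr::inner_join(unit_cluster, by = "neuron_id")
  # the repeated-measures strata need balanced panels: drop neurons with
  # an undefined correlation in any epoch x condition cell
  n_cells <- dplyr::n_distinct(d$epoch) * 2
  complete_units <- d |>
    dplyr::filter(is.finite(.data$rho_sq)) |>
    dplyr::count(.data$neuron_id) |>
    dplyr::filter(.data$n == n_cells)
  dropped <- setdiff(unique(d$neuron_id), complete_units$neuron_id)
  if (length(dropped)) {
    message(
      length(dropped),
      " unit(s) without a defined correlation in every cell dropped"
    )
  }
  d <- dplyr::filter(d, .data$neuron_id %in% complete_units$neuron_id)

  dd <- d |>
    dplyr::select("neuron_id", "cluster", "epoch", "condition", "rho_sq") |>
    tidyr::pivot_wider(names_from = "condition", values_from = "rho_sq") |>
    dplyr::mutate(diff_rho_sq = .data$saline - .data$licl)
  res <- art_anova(
    dd, "diff_rho_sq", c("cluster", "epoch"),
    subject = "neuron_id", within = "epoch",
    effects = list(c("cluster", "epoch"))
  )
  if (n_perm > 0) {
    if (!is.null(seed)) set.seed(seed)
    units <- unique(dd$neuron_id)
    unit_lab <- dd$cluster[match(units, dd$neuron_id)]
    f_obs <- art_interaction_f(
      dd$diff_rho_sq, dd$neuron_id, unit_lab[match(dd$neuron_id, units)],
      dd$epoch
    )
    f_perm <- vapply(seq_len(n_perm), function(p) {
      perm <- sample(unit_lab)
      art_interaction_f(
        dd$diff_rho_sq, dd$neuron_id, perm[match(dd$neuron_id, units)],
        dd$epoch
      )
    }, numeric(1))
    res$p.value <- (1 + sum(f_perm >= f_obs)) / (n_perm + 1)
  }
  res$term <- "cluster:epoch:condition"
  late <- d |> dplyr::filter(.data$epoch == "late")
  fl <- late |>
    dplyr::group_by(.data$cluster) |>
    dplyr::group_modify(function(g, key) {
      w <- tidyr::pivot_wider(
        g[, c("neuron_id", "condition", "rho_sq")],
        names_from = "condition", values_from = "rho_sq"
      )
      w <- w[complete.cases(w), ]
      if (nrow(w) < 3 || isTRUE(all.equal(w$licl, w$saline))) {
        return(tibble::tibble(
          estimate = NA_real_, statistic = NA_real_, p.value = NA_real_
        ))
      }
      ht <- suppressWarnings(wilcox.test(w$licl, w$saline, paired = TRUE))
      tibble::tibble(
        estimate = mean(w$licl - w$saline),
        statistic = unname(ht$statistic), p.value = ht$p.value
      )
    }) |>
    dplyr::ungroup()
  structure(
    list(anova = res, followups = fl, data = d),
    class = "cluster_anova"
  )
}

# Closed-form ART F for the group x within interaction in a balanced
# mixed design (subject nested in group, one observation per subject x
# within level): align for the interaction, rank, then
# F = MS(group:within) / MS(within x subject-within-group). Used by the
# permutation loop, where refitting aov() per permutation would dominate
# the run time.
art_interaction_f <- function(y, subject, group, within) {
  m <- mean(y)
  m_g <- stats::ave(y, group)
  m_w <- stats::ave(y, within)
  r <- rank(y - m_g - m_w + m)
  rm_ <- mean(r)
  cell <- stats::ave(r, group, within)
  rg <- stats::ave(r, group)
  rw <- stats::ave(r, within)
  rs <- stats::ave(r, subject)
  ss_int <- sum((cell - rg - rw + rm_)^2)
  ss_err <- sum((r - cell - rs + rg)^2)
  k <- length(unique(group))
  e <- length(unique(within))
  n <- length(unique(subject))
  df1 <- (k - 1) * (e - 1)
  df2 <- (n - k) * (e - 1)
  (ss_int / df1) / (ss_err / df2)
}

#' Baseline-equivalence tests for held units
#'
#' Checks that pre-stimulus firing did not change between sessions: a
#' paired t test on per-unit baseline means, and a Kolmogorov--Smirnov
#' test of the saline - LiCl differences against a Gaussian centered at 0
#' with the sample SD (illness should leave spontaneous firing intact).
#'
#' @param saline_trials,licl_trials Long trial tables (held units).
#' @param held_ids Units to include (default: common to both sessions).
#' @param baseline_win Window in ms.
#' @return List of class `baseline_equivalence`: `t_test`, `ks_test`,
#'   `baselines` tibble.
#' @export
baseline_equivalence <- function(saline_trials, licl_trials, held_ids = NULL,
                                 baseline_win = c(-1000, 0)) {
  if (is.null(held_ids)) {
    held_ids <- intersect(
      unique(saline_trials$neuron_id), unique(licl_trials$neuron_id)
    )
  }
  mean_base <- function(trials) {
    window_rates(trials, baseline_win) |>
      dplyr::filter(.data$neuron_id %in% held_ids) |>
      dplyr::group_by(.data$neuron_id) |>
      dplyr::summarise(rate = mean(.data$rate))
  }
  b <- dplyr::inner_join(
    mean_base(saline_trials), mean_base(licl_trials),
    by = "neuron_id", suffix = c("_saline", "_licl")
  )
  diffs <- b$rate_saline - b$rate_licl
  if (all(diffs == 0)) {
    tt <- list(statistic = c(t = 0), parameter = c(df = nrow(b) - 1),
      p.value = 1
    )
  } else {
    tt <- t.test(b$rate_saline, b$rate_licl, paired = TRUE)
  }
  ks <- suppressWarnings(
    ks.test(diffs, "pnorm", mean = 0, sd = max(sd(diffs), 1e-12))
  )
  structure(
    list(
      t_test = tibble::tibble(
        statistic = unname(tt$statistic), df = unname(tt$parameter),
        p.value = tt$p.value,
        mean_saline = mean(b$rate_saline), mean_licl = mean(b$rate_licl)
      ),
      ks_test = tibble::tibble(
        statistic = unname(ks$statistic), p.value = ks$p.value
      ),
      baselines = b
    ),
    class = "baseline_equivalence"
  )
}
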