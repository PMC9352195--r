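# Long trial table -> list(counts [trial x bin x neuron], taste, t_ms).
ensemble_array <- function(trials) {
  bin_ms <- attr(trials, "bin_ms")
  t_ms <- sort(unique(trials$time_ms))
  if (is.null(bin_ms)) bin_ms <- min(diff(t_ms))
  neurons <- sort(unique(trials$neuron_id))
  tt <- unique(trials[, c("trial", "taste")])
  tt <- tt[order(tt$trial), ]
  arr <- array(0L, c(nrow(tt), length(t_ms), length(neurons)),
    dimnames = list(NULL, NULL, neurons)
  )
  ti <- match(trials$trial, tt$trial)
  bi <- match(trials$time_ms, t_ms)
  ni <- match(trials$neuron_id, neurons)
  arr[cbind(ti, bi, ni)] <- trials$count
  list(
    counts = arr, taste = tt$taste, trial = tt$trial,
    t_ms = t_ms, bin_ms = bin_ms, neurons = neurons
  )
}

#' Moving-window palatability rank correlation
#'
#' In a sliding window (250 ms wide, 25 ms steps by default), each
#' neuron's trial firing rates are Spearman-correlated with the canonical
#' palatability rank of the delivered taste
#' (sucrose > NaCl > citric acid > quinine). Windows with zero rate
#' variance yield an undefined correlation and are excluded (a count is
#' reported via `message`).
#'
#' @param trials Long trial table for one session.
#' @param window_ms,step_ms Window size and step (ms).
#' @param t_range Window start range, ms (defaults cover the pre-delivery
#'   baseline through the late epoch).
#' @param ranks Named palatability ranks (default [palatability_ranks()]).
#' @return Object of class `palatability_trace`: `rho` tibble
#'   `(neuron_id, t_center, rho, rho_sq)` and `summary` tibble with the
#'   across-neuron mean |rho| and mean rho^2 per window.
#' @export
#' @examples
#' cfg <- sim_config(n_neurons = 5, n_trials_per_taste = 10, seed = 6)
#' tr <- moving_spearman(sim_ensemble_pair(cfg)$saline)
#' head(tr$summary)
moving_spearman <- function(trials, window_ms = 250, step_ms = 25,
                            t_range = c(-250, 1250),
                            ranks = palatability_ranks()) {
  validate_trials(trials)
  ea <- ensemble_array(trials)
  starts <- seq(t_range[1], t_range[2] - window_ms, by = step_ms)
  rk <- ranks[ea$taste]
  if (anyNA(rk)) stop("trial tastes missing from 'ranks'")
  n_excluded <- 0L
  rows <- vector("list", length(ea$neurons))
  for (i in seq_along(ea$neurons)) {
    cmat <- ea$counts[, , i]
    rho <- vapply(starts, function(s) {
      sel <- ea$t_ms >= s & ea$t_ms < s + window_ms
      x <- rowSums(cmat[, sel, drop = FALSE])
      if (var(x) == 0) {
        n_excluded <<- n_excluded + 1L
        return(NA_real_)
      }
      suppressWarnings(cor(x, rk, method = "spearman"))
    }, numeric(1))
    rows[[i]] <- tibble::tibble(
      neuron_id = ea$neurons[i],
      t_center = starts + window_ms / 2,
      rho = rho, rho_sq = rho^2
    )
  }
  if (n_excluded > 0) {
    message(n_excluded, " zero-variance window(s) excluded")
  }
  rho_tbl <- dplyr::bind_rows(rows)
  summ <- rho_tbl |>
    dplyr::group_by(.data$t_center) |>
    dplyr::summarise(
      mean_abs_rho = mean(abs(.data$rho), na.rm = TRUE),
      mean_rho_sq = mean(.data$rho_sq, na.rm = TRUE),
      n_neurons = sum(!is.na(.data$rho)),
      .groups = "drop"
    )
  structure(
    list(rho = rho_tbl, summary = summ, window_ms = window_ms),
    class = "palatability_trace"
  )
}

# Per-neuron epoch means of |rho| and rho^2 (windows assigned by center).
epoch_rho <- function(trace, epochs = epoch_def()) {
  purrr::imap_dfr(unclass(epochs), function(w, nm) {
    trace$rho |>
      dplyr::filter(.data$t_center >= w[1], .data$t_center < w[2]) |>
      dplyr::group_by(.data$neuron_id) |>
      dplyr::summarise(
        abs_rho = mean(abs(.data$rho), na.rm = TRUE),
        rho_sq = mean(.data$rho_sq, na.rm = TRUE),
        .groups = "drop"
      ) |>
      dplyr::mutate(epoch = nm)
  })
}

#' Per-epoch condition comparison of palatability correlation
#'
#' Kruskal--Wallis test per epoch on per-neuron epoch-mean |rho| between
#' the saline and LiCl populations.
#'
#' @param saline,licl `palatability_trace` objects for the two conditions.
#' @param epochs An [epoch_def()].
#' @param measure `"abs_rho"` or `"rho_sq"`.
#' @return A tibble `(epoch, statistic, df, p.value, mean_saline,
#'   mean_licl)`.
#' @export
palatability_condition_test <- function(saline, licl, epochs = epoch_def(),
                                        measure = c("abs_rho", "rho_sq")) {
  measure <- match.arg(measure)
  es <- epoch_rho(saline, epochs)
  el <- epoch_rho(licl, epochs)
  purrr::map_dfr(unique(es$epoch), function(ep) {
    a <- es[[measure]][es$epoch == ep]
    b <- el[[measure]][el$epoch == ep]
    kt <- kruskal.test(list(a, b))
    tibble::tibble(
      epoch = ep, statistic = unname(kt$statistic),
      df = unname(kt$parameter), p.value = kt$p.value,
      mean_saline = mean(a, na.rm = TRUE), mean_licl = mean(b, na.rm = TRUE)
    )
  })
}

#' Pure palatability index (PPI)
#'
#' Contrasts the Euclidean distances between a neuron's trial-averaged
#' responses to tastes of different palatability (sucrose/citric acid,
#' sucrose/quinine, NaCl/citric acid, NaCl/quinine) against those of
#' similar palatability (sucrose/NaCl, citric acid/quinine). Responses
#' are baseline-normalized (the mean rate over the 500 ms before delivery
#' is subtracted) and taken over the central 150 ms of each epoch so that
#' epochs with different dynamics are not mixed; distances are divided by
#' the square root of the number of bins so the index is per-bin scaled.
#' With no palatability structure the index is 0; the more polarized the
#' response into good vs bad, the more positive it is. The default
#' `difference` mode is `D_dissimilar - D_similar`; the `normalized` mode
#' is `(D_dissimilar - D_similar) / (D_dissimilar + D_similar)`.
#'
#' @param trials Long trial table for one session.
#' @param epochs An [epoch_def()].
#' @param mode `"difference"` (default) or `"normalized"`.
#' @param baseline_win Baseline window (ms) for normalization.
#' @param center_ms Width of the central epoch slice used (ms).
#' @return A tibble `(neuron_id, epoch, d_similar, d_dissimilar, ppi)`.
#' @export
#' @examples
#' cfg <- sim_config(n_neurons = 5, n_trials_per_taste = 10, seed = 7)
#' ppi <- compute_ppi(sim_ensemble_pair(cfg)$saline)
#' head(ppi)
compute_ppi <- function(trials, epochs = epoch_def(),
                        mode = c("difference", "normalized"),
                        baseline_win = c(-500, 0), center_ms = 150) {
  mode <- match.arg(mode)
  validate_trials(trials)
  if (!all(TASTES %in% unique(trials$taste))) {
    stop("all four canonical tastes are required")
  }
  ea <- ensemble_array(trials)
  rate_scale <- 1000 / ea$bin_ms
  base_sel <- ea$t_ms >= baseline_win[1] & ea$t_ms < baseline_win[2]
  sim_p <- similar_pairs()
  dis_p <- dissimilar_pairs()

  purrr::map_dfr(seq_along(ea$neurons), function(i) {
    cmat <- ea$counts[, , i] * rate_scale
    base <- mean(cmat[, base_sel])
    purrr::imap_dfr(unclass(epochs), function(w, nm) {
      mid <- mean(w)
      sel <- ea$t_ms + ea$bin_ms / 2 >= mid - center_ms / 2 &
        ea$t_ms + ea$bin_ms / 2 <= mid + center_ms / 2
      nb <- sum(sel)
      vecs <- lapply(TASTES, function(tst) {
        colMeans(cmat[ea$taste == tst, sel, drop = FALSE]) - base
      })
      names(vecs) <- TASTES
      dist1 <- function(pr) {
        sqrt(sum((vecs[[pr[1]]] - vecs[[pr[2]]])^2)) / sqrt(nb)
      }
      d_sim <- mean(vapply(sim_p, dist1, numeric(1)))
      d_dis <- mean(vapply(dis_p, dist1, numeric(1)))
      ppi <- if (mode == "difference") {
        d_dis - d_sim
      } else if (d_dis + d_sim > 0) {
        (d_dis - d_sim) / (d_dis + d_sim)
      } else {
        0
      }
      tibble::tibble(
        neuron_id = ea$neurons[i], epoch = nm,
        d_similar = d_sim, d_dissimilar = d_dis, ppi = ppi
      )
    })
  })
}

#' Tests on pure palatability indices
#'
#' Per epoch: a one-sample t test of the PPI against 0 within each
#' condition, and an unpaired two-sample Wilcoxon rank test between
#' conditions with effect size r (|Z| divided by the square root of N).
#'
#' @param saline,licl PPI tibbles from [compute_ppi()].
#' @return List of class `ppi_tests`: `vs_zero` and `between` tibbles.
#' @export
ppi_tests <- function(saline, licl) {
  n_sal <- dplyr::n_distinct(saline$neuron_id)
  n_licl <- dplyr::n_distinct(licl$neuron_id)
  if (n_sal < 10 || n_licl < 10) {
    stop("need at least 10 neurons per condition")
  }
  eps <- unique(saline$epoch)
  vs_zero <- purrr::map_dfr(eps, function(ep) {
    purrr::map_dfr(
      list(saline = saline, licl = licl)[c("saline", "licl")] |>
        purrr::imap(function(d, cond) {
          x <- d$ppi[d$epoch == ep]
          ht <- t.test(x)
          tibble::tibble(
            epoch = ep, condition = cond, mean_ppi = mean(x),
            statistic = unname(ht$statistic), df = unname(ht$parameter),
            p.value = ht$p.value
          )
        }),
      identity
    )
  })
  between <- purrr::map_dfr(eps, function(ep) {
    a <- saline$ppi[saline$epoch == ep]
    b <- licl$ppi[licl$epoch == ep]
    if (isTRUE(all.equal(a, b))) {
      return(tibble::tibble(
        epoch = ep, statistic = NA_real_, p.value = 1, effect_r = 0
      ))
    }
    wt <- suppressWarnings(wilcox.test(b, a))
    z <- qnorm(pmax(wt$p.value / 2, .Machine$double.xmin), lower.tail = FALSE)
    tibble::tibble(
      epoch = ep, statistic = unname(wt$statistic), p.value = wt$p.value,
      effect_r = abs(z) / sqrt(length(a) + length(b))
    )
  })
  structure(list(vs_zero = vs_zero, between = between), class = "ppi_tests")
}

#' @export
print.ppi_tests <- function(x, ...) {
  cat("PPI vs zero:\n")
  print(x$vs_zero)
  cat("Between conditions (Wilcoxon):\n")
  print(x$between)
  invisible(x)
}
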