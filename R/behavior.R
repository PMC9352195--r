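#' Total rearing duration per time bin
#'
#' Sums event durations within consecutive bins; events spanning a bin
#' boundary are split proportionally, so the bin totals conserve the total
#' event duration exactly.
#'
#' @param events Data frame with `onset_s` and `duration_s` columns
#'   (one session).
#' @param session_minutes Session length (min).
#' @param bin_min Bin width (min); must divide `session_minutes`.
#' @return A tibble `(minute, seconds)` with `session_minutes / bin_min`
#'   rows (`minute` is the bin's end, in minutes).
#' @export
#' @examples
#' ev <- tibble::tibble(onset_s = 115, duration_s = 10)
#' durations_per_bin(ev, session_minutes = 20)
durations_per_bin <- function(events, session_minutes = 20, bin_min = 1) {
  if (session_minutes %% bin_min != 0) {
    stop("bin_min must divide session_minutes")
  }
  n_bins <- session_minutes / bin_min
  edges <- seq(0, session_minutes * 60, by = bin_min * 60)
  total <- numeric(n_bins)
  if (nrow(events)) {
    for (i in seq_len(nrow(events))) {
      s <- events$onset_s[i]
      e <- min(s + events$duration_s[i], session_minutes * 60)
      overlap <- pmax(0, pmin(e, edges[-1]) - pmax(s, edges[-length(edges)]))
      total <- total + overlap
    }
  }
  tibble::tibble(minute = seq_len(n_bins) * bin_min, seconds = total)
}

# Per-animal binned traces for a whole events table.
behavior_traces <- function(events, session_minutes = 20, bin_min = 1) {
  events |>
    dplyr::group_by(.data$animal_id, .data$condition) |>
    dplyr::group_modify(function(d, key) {
      durations_per_bin(d, session_minutes, bin_min)
    }) |>
    dplyr::ungroup()
}

#' Normalized LiCl - saline difference in rearing duration
#'
#' Each animal's per-bin duration trace is min-max normalized to `[0, 1]`;
#' the per-bin condition means are then subtracted (LiCl - saline) and
#' returned with the group SEM. Animals with an all-zero trace cannot be
#' normalized and are excluded with a warning.
#'
#' @param events Events table `(animal_id, condition, onset_s, duration_s)`
#'   with conditions `"licl"` and `"saline"` (separate cohorts).
#' @param session_minutes,bin_min Binning, as in [durations_per_bin()].
#' @return A tibble `(minute, difference, sem)`; `difference` lies in
#'   `[-1, 1]`.
#' @export
condition_difference <- function(events, session_minutes = 20, bin_min = 1) {
  traces <- behavior_traces(events, session_minutes, bin_min)
  norm <- traces |>
    dplyr::group_by(.data$animal_id, .data$condition) |>
    dplyr::filter({
      ok <- any(.data$seconds > 0)
      if (!ok) {
        warning("animal ", .data$animal_id[1], " has no rearing; excluded",
          call. = FALSE
        )
      }
      ok
    }) |>
    dplyr::mutate(
      norm = (.data$seconds - min(.data$seconds)) /
        (max(.data$seconds) - min(.data$seconds))
    ) |>
    dplyr::ungroup()
  by_cond <- norm |>
    dplyr::group_by(.data$condition, .data$minute) |>
    dplyr::summarise(
      m = mean(.data$norm),
      v = var(.data$norm) / dplyr::n(),
      .groups = "drop"
    ) |>
    tidyr::pivot_wider(names_from = "condition", values_from = c("m", "v"))
  tibble::tibble(
    minute = by_cond$minute,
    difference = by_cond$m_licl - by_cond$m_saline,
    sem = sqrt(by_cond$v_licl + by_cond$v_saline)
  )
}

#' Fit a four-parameter logistic to a difference trace
#'
#' `y(t) = lower + (upper - lower) / (1 + exp(-slope * (t - midpoint)))`,
#' fit by Levenberg--Marquardt nonlinear least squares with multi-start
#' initialization over a midpoint grid to avoid local minima. The sickness
#' onset readout is the time the curve approaches its lower asymptote.
#'
#' @param trace Data frame with `minute` and `difference` columns (or any
#'   single y column named `difference`), as from [condition_difference()].
#' @param midpoint_grid Starting values for the midpoint (min).
#' @return An object of class `sigmoid_fit`: parameters `lower`, `upper`,
#'   `midpoint`, `slope`, plus `r_squared`, `degenerate` flag and the
#'   underlying `nls` object.
#' @export
#' @examples
#' tr <- tibble::tibble(minute = 1:20, difference = -1 / (1 + exp(-(12 - 1:20))))
#' fit_sigmoid(tr)
fit_sigmoid <- function(trace, midpoint_grid = c(4, 8, 12, 16)) {
  if (nrow(trace) < 5) stop("need at least 5 bins to fit a sigmoid")
  t <- trace$minute
  y <- trace$difference
  if (diff(range(y)) < 1e-10) {
    # flat trace: nothing to fit; report the degenerate solution directly
    return(structure(
      list(
        lower = mean(y), upper = mean(y), midpoint = NA_real_, slope = 0,
        r_squared = 0, degenerate = TRUE, nls = NULL,
        trace = tibble::tibble(minute = t, difference = y)
      ),
      class = "sigmoid_fit"
    ))
  }
  best <- NULL
  best_rss <- Inf
  tried <- character(0)
  for (mid0 in midpoint_grid) {
    for (sl0 in c(-1, 1)) {
      fit <- tryCatch(
        minpack.lm::nlsLM(
          y ~ lower + (upper - lower) / (1 + exp(-slope * (t - midpoint))),
          start = list(
            lower = min(y), upper = max(y),
            midpoint = mid0, slope = sl0
          ),
          control = minpack.lm::nls.lm.control(maxiter = 200)
        ),
        error = function(e) {
          tried <<- c(tried, conditionMessage(e))
          NULL
        }
      )
      if (!is.null(fit)) {
        rss <- sum(resid(fit)^2)
        if (rss < best_rss) {
          best <- fit
          best_rss <- rss
        }
      }
    }
  }
  if (is.null(best)) {
    stop(
      "sigmoid fit failed to converge from any start; last errors: ",
      paste(utils::tail(unique(tried), 2), collapse = "; ")
    )
  }
  p <- as.list(coef(best))
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - best_rss / ss_tot else 0
  structure(
    list(
      lower = p$lower, upper = p$upper, midpoint = p$midpoint,
      slope = p$slope, r_squared = r2,
      degenerate = abs(p$slope) < 1e-3 || ss_tot == 0,
      nls = best, trace = tibble::tibble(minute = t, difference = y)
    ),
    class = "sigmoid_fit"
  )
}

#' @export
print.sigmoid_fit <- function(x, ...) {
  cat(sprintf(
    "Sigmoid fit: midpoint %.2f min, slope %.2f, asymptotes [%.2f, %.2f], r^2 = %.3f%s\n",
    x$midpoint, x$slope, x$lower, x$upper, x$r_squared,
    if (x$degenerate) " (degenerate)" else ""
  ))
  invisible(x)
}

#' Per-quartile rank test of rearing durations between conditions
#'
#' For each 5-min quartile, per-animal total rearing seconds are compared
#' between LiCl and saline cohorts with a Wilcoxon rank test (two-sample
#' rank-sum by default for separate cohorts; paired signed-rank available).
#' Exact small-sample p-values are used where no ties preclude them. The
#' rank-biserial-style effect size r (|Z| divided by the square root of
#' N) is reported.
#'
#' @param events Events table `(animal_id, condition, onset_s, duration_s)`.
#' @param session_minutes Session length (min).
#' @param quartile_min Quartile width (min).
#' @param paired Use a paired signed-rank test (animals matched by order).
#' @return A tibble with one row per quartile: `quartile, statistic,
#'   p.value, effect_r, n_licl, n_saline` (class `quartile_wilcoxon`).
#' @export
quartile_wilcoxon <- function(events, session_minutes = 20, quartile_min = 5,
                              paired = FALSE) {
  traces <- behavior_traces(events, session_minutes, bin_min = 1)
  q <- traces |>
    dplyr::mutate(quartile = ceiling(.data$minute / quartile_min)) |>
    dplyr::group_by(
      .data$animal_id, .data$condition, .data$quartile
    ) |>
    dplyr::summarise(seconds = sum(.data$seconds), .groups = "drop")
  out <- q |>
    dplyr::group_by(.data$quartile) |>
    dplyr::group_modify(function(d, key) {
      licl <- d$seconds[d$condition == "licl"]
      sal <- d$seconds[d$condition == "saline"]
      if (length(unique(c(licl, sal))) == 1) {
        warning("quartile ", key$quartile, ": all values tied; p = 1",
          call. = FALSE
        )
        return(tibble::tibble(
          statistic = NA_real_, p.value = 1, effect_r = 0,
          n_licl = length(licl), n_saline = length(sal)
        ))
      }
      wt <- suppressWarnings(
        wilcox.test(licl, sal, paired = paired, exact = NULL)
      )
      n_tot <- length(licl) + length(sal)
      z <- qnorm(pmax(wt$p.value / 2, .Machine$double.xmin), lower.tail = FALSE)
      tibble::tibble(
        statistic = unname(wt$statistic), p.value = wt$p.value,
        effect_r = abs(z) / sqrt(n_tot),
        n_licl = length(licl), n_saline = length(sal)
      )
    }) |>
    dplyr::ungroup()
  class(out) <- c("quartile_wilcoxon", class(out))
  out
}
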