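#' Firing rates within a time window, per trial
#'
#' Sums spike counts with bin start times in `[window[1], window[2])` ms
#' and divides by the window length, giving one rate (Hz) per neuron and
#' trial.
#'
#' @param trials Long trial table `(neuron_id, trial, taste, time_ms,
#'   count)`.
#' @param window `c(start, end)` in ms relative to taste delivery.
#' @return A tibble `(neuron_id, trial, taste, rate)`.
#' @export
window_rates <- function(trials, window) {
  dur_s <- (window[2] - window[1]) / 1000
  trials |>
    dplyr::filter(.data$time_ms >= window[1], .data$time_ms < window[2]) |>
    dplyr::group_by(.data$neuron_id, .data$trial, .data$taste) |>
    dplyr::summarise(rate = sum(.data$count) / dur_s, .groups = "drop")
}

validate_trials <- function(trials) {
  need <- c("neuron_id", "trial", "taste", "time_ms", "count")
  if (!all(need %in% names(trials))) {
    stop("trial table needs columns ", paste(need, collapse = ", "))
  }
  if (any(trials$count < 0)) stop("spike counts must be >= 0")
  if (!all(TASTES %in% unique(trials$taste))) {
    stop("all four canonical tastes must be present")
  }
  tspan <- range(trials$time_ms)
  if (tspan[1] > -1000 || tspan[2] < 1175) {
    stop("alignment must cover at least 1 s pre and 1.2 s post delivery")
  }
  invisible(trials)
}

#' Classify single-neuron taste responsiveness
#'
#' Per neuron, trial-wise firing rates in the pre-stimulus second
#' (`baseline_win`) are compared to rates in the evoked window
#' (`evoked_win`, which excludes the first 200 ms of post-delivery
#' activity because it is somatosensory rather than chemosensory) with a
#' Mann--Whitney U test, pooling trials across tastes. A neuron is
#' responsive when `p < alpha`; the response direction is the sign of the
#' mean baseline-subtracted evoked rate ("excitatory" above baseline,
#' "inhibitory" below -- a statement about firing direction only, not
#' about synaptic inhibition) and the magnitude is that mean (Hz).
#'
#' @param trials Long trial table for one session.
#' @param alpha Significance level.
#' @param baseline_win,evoked_win Windows in ms.
#' @return A tibble, one row per neuron: `neuron_id, statistic, p.value,
#'   responsive, direction, magnitude, flagged` (`flagged` marks all-zero
#'   neurons, which are non-responsive with undefined direction).
#' @export
classify_responsiveness <- function(trials, alpha = 0.05,
                                    baseline_win = c(-1000, 0),
                                    evoked_win = c(200, 1200)) {
  validate_trials(trials)
  n_tr <- dplyr::n_distinct(trials$trial)
  if (n_tr < 10) stop("need at least 10 trials")
  base <- window_rates(trials, baseline_win)
  evoked <- window_rates(trials, evoked_win)
  d <- dplyr::inner_join(base, evoked,
    by = c("neuron_id", "trial", "taste"), suffix = c("_base", "_evoked")
  )
  d |>
    dplyr::group_by(.data$neuron_id) |>
    dplyr::group_modify(function(g, key) {
      if (all(g$rate_base == 0) && all(g$rate_evoked == 0)) {
        return(tibble::tibble(
          statistic = NA_real_, p.value = NA_real_, responsive = FALSE,
          direction = NA_character_, magnitude = 0, flagged = TRUE
        ))
      }
      wt <- suppressWarnings(wilcox.test(g$rate_evoked, g$rate_base))
      mag <- mean(g$rate_evoked) - mean(g$rate_base)
      tibble::tibble(
        statistic = unname(wt$statistic), p.value = wt$p.value,
        responsive = wt$p.value < alpha,
        direction = if (mag >= 0) "excitatory" else "inhibitory",
        magnitude = mag, flagged = FALSE
      )
    }) |>
    dplyr::ungroup()
}

#' Per-neuron, per-taste response magnitudes
#'
#' Mean evoked rate minus across-trial mean baseline rate, separately for
#' each taste (Hz change from baseline).
#'
#' @inheritParams classify_responsiveness
#' @return A tibble `(neuron_id, taste, magnitude)`.
#' @export
taste_magnitudes <- function(trials, baseline_win = c(-1000, 0),
                             evoked_win = c(200, 1200)) {
  base <- window_rates(trials, baseline_win) |>
    dplyr::group_by(.data$neuron_id) |>
    dplyr::summarise(base = mean(.data$rate))
  window_rates(trials, evoked_win) |>
    dplyr::group_by(.data$neuron_id, .data$taste) |>
    dplyr::summarise(evoked = mean(.data$rate), .groups = "drop") |>
    dplyr::left_join(base, by = "neuron_id") |>
    dplyr::mutate(magnitude = .data$evoked - .data$base) |>
    dplyr::select("neuron_id", "taste", "magnitude")
}

#' Condition-by-direction ANOVA on response magnitudes
#'
#' Tests whether illness changes the magnitude of taste responses, and
#' whether the change differs for excitatory vs inhibitory responses.
#' Per-taste |magnitudes| are labelled with the session condition and the
#' neuron's response direction from [classify_responsiveness()]; a
#' two-way ANOVA (condition x direction) is followed by Tukey HSD
#' contrasts of condition within each direction. With `unit = "neuron"`
#' (the default) each neuron contributes its mean |magnitude| across the
#' four tastes, so observations are independent and the test holds its
#' nominal level; `unit = "taste"` keeps all four per-taste entries per
#' neuron (the pooled layout behind residual dfs of about 4 neurons - 4),
#' at the price of within-neuron correlation the F test does not model.
#'
#' @param saline_trials,licl_trials Long trial tables for the two sessions.
#' @param alpha Responsiveness level used for direction labelling.
#' @param responsive_only Restrict to taste-responsive neurons.
#' @param unit Observation unit: `"neuron"` (default) or `"taste"`.
#' @return An object of class `magnitude_anova`: `interaction` tibble
#'   (term, df, statistic, p.value), `main_effects`, `tukey` per-direction
#'   condition contrasts, `data` (the magnitudes used).
#' @export
magnitude_condition_anova <- function(saline_trials, licl_trials,
                                      alpha = 0.05, responsive_only = FALSE,
                                      unit = c("neuron", "taste")) {
  unit <- match.arg(unit)
  build <- function(trials, cond) {
    cls <- classify_responsiveness(trials, alpha = alpha)
    if (responsive_only) cls <- dplyr::filter(cls, .data$responsive)
    taste_magnitudes(trials) |>
      dplyr::inner_join(
        dplyr::select(cls, "neuron_id", "direction"),
        by = "neuron_id"
      ) |>
      dplyr::filter(!is.na(.data$direction)) |>
      dplyr::mutate(condition = cond, absmag = abs(.data$magnitude))
  }
  d <- dplyr::bind_rows(
    build(saline_trials, "saline"),
    build(licl_trials, "licl")
  )
  if (unit == "neuron") {
    d <- d |>
      dplyr::group_by(.data$neuron_id, .data$condition, .data$direction) |>
      dplyr::summarise(absmag = mean(.data$absmag), .groups = "drop")
  }
  cells <- dplyr::count(d, .data$condition, .data$direction)
  if (nrow(cells) < 4 || any(cells$n < 2)) {
    missing <- with(
      expand.grid(
        condition = c("saline", "licl"),
        direction = c("excitatory", "inhibitory")
      ),
      paste(condition, direction, sep = ":")
    )
    have <- paste(cells$condition[cells$n >= 2], cells$direction[cells$n >= 2],
      sep = ":"
    )
    stop(
      "condition x direction cell(s) with fewer than 2 observations: ",
      paste(setdiff(missing, have), collapse = ", ")
    )
  }
  d$condition <- factor(d$condition, levels = c("saline", "licl"))
  d$direction <- factor(d$direction)
  fit <- aov(absmag ~ condition * direction, data = d)
  tab <- anova(fit)
  row <- function(term) {
    tibble::tibble(
      term = term, df = tab[term, "Df"],
      df_resid = tab["Residuals", "Df"],
      statistic = tab[term, "F value"], p.value = tab[term, "Pr(>F)"]
    )
  }
  tk <- TukeyHSD(fit, "condition:direction")$`condition:direction`
  want <- c(
    "licl:excitatory-saline:excitatory",
    "licl:inhibitory-saline:inhibitory"
  )
  tk_tbl <- tibble::tibble(
    contrast = rownames(tk),
    estimate = tk[, "diff"], p.adj = tk[, "p adj"]
  ) |>
    dplyr::filter(.data$contrast %in% want)
  structure(
    list(
      interaction = row("condition:direction"),
      main_effects = dplyr::bind_rows(row("condition"), row("direction")),
      tukey = tk_tbl, data = d
    ),
    class = "magnitude_anova"
  )
}

#' @export
print.magnitude_anova <- function(x, ...) {
  i <- x$interaction
  cat(sprintf(
    "Condition x direction interaction: F(%d, %d) = %.2f, p = %.4g\n",
    i$df, i$df_resid, i$statistic, i$p.value
  ))
  print(x$tukey)
  invisible(x)
}
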