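#' Per-minute band power from a raw LFP trace
#'
#' Welch-style estimate: short-time Fourier transform with 1-s Hann
#' windows and 50 % overlap (via [signal::specgram()]), converted to a
#' one-sided power spectral density, integrated over `band`, and averaged
#' within each `bin_s`-second bin. Multi-channel input (matrix, channels
#' in columns) is averaged after per-channel power estimation.
#'
#' @param x Numeric vector, or matrix with one channel per column.
#' @param fs Sampling rate (Hz); must exceed twice the band's upper edge.
#' @param band Frequency interval `c(lo, hi)` in Hz (default mu, 7--12).
#' @param bin_s Output bin width in seconds (default 60).
#' @param window_s STFT window length in seconds.
#' @return A tibble `(minute, power)`, one row per bin, `power` in
#'   (input units)^2.
#' @export
#' @examples
#' fs <- 250
#' x <- sin(2 * pi * 10 * seq(0, 120, by = 1 / fs))
#' compute_band_power(x, fs)
compute_band_power <- function(x, fs, band = c(7, 12), bin_s = 60,
                               window_s = 1) {
  if (is.matrix(x) && ncol(x) > 1) {
    per_ch <- lapply(seq_len(ncol(x)), function(j) {
      compute_band_power(x[, j], fs, band, bin_s, window_s)
    })
    out <- per_ch[[1]]
    out$power <- rowMeans(do.call(cbind, lapply(per_ch, `[[`, "power")))
    return(out)
  }
  x <- as.numeric(x)
  if (anyNA(x) || any(!is.finite(x))) {
    stop("signal contains NA/non-finite at index ",
      which(!is.finite(x))[1],
      call. = FALSE
    )
  }
  if (band[2] >= fs / 2) stop("band upper edge must be below Nyquist (fs/2)")
  if (band[1] <= 0 || band[1] >= band[2]) stop("invalid band")
  n_win <- round(fs * window_s)
  if (length(x) < fs * bin_s) stop("signal shorter than one output bin")

  sp <- signal::specgram(x, n = n_win, Fs = fs, overlap = n_win %/% 2)
  w <- signal::hanning(n_win)
  # one-sided PSD per window: |S|^2 / (fs * sum(w^2)), doubled off DC/Nyquist
  scale <- 1 / (fs * sum(w^2))
  psd <- Mod(sp$S)^2 * scale
  one_sided <- rep(2, length(sp$f))
  one_sided[sp$f == 0 | abs(sp$f - fs / 2) < 1e-9] <- 1
  psd <- psd * one_sided
  in_band <- sp$f >= band[1] & sp$f <= band[2]
  df <- fs / n_win
  band_pow <- colSums(psd[in_band, , drop = FALSE]) * df

  bin_idx <- floor(sp$t / bin_s) + 1
  keep <- bin_idx <= floor(length(x) / (fs * bin_s))
  means <- tapply(band_pow[keep], bin_idx[keep], mean)
  tibble::tibble(
    minute = as.integer(names(means)) * (bin_s / 60),
    power = as.numeric(means)
  )
}

#' Min-max normalize a power series to `[0, 1]`
#'
#' Affine, order-preserving map across the entire session; the minimum
#' maps to 0 and the maximum to 1. Idempotent.
#'
#' @param x Numeric vector, or data frame with a `power` column (returned
#'   with `power` replaced).
#' @return Same shape as the input.
#' @export
#' @examples
#' normalize_power(c(2, 4, 6))
normalize_power <- function(x) {
  if (is.data.frame(x)) {
    x$power <- normalize_power(x$power)
    return(x)
  }
  r <- range(x)
  if (diff(r) == 0) stop("normalization undefined for a constant series")
  (x - r[1]) / diff(r)
}

#' Group-by-quartile test of session power differences
#'
#' Per animal, the mu-power values of both sessions are jointly min-max
#' normalized (one scale per animal, so the between-session shift is
#' preserved), the absolute between-session difference (|saline - LiCl| for
#' experimental animals, |saline - saline| for controls) is averaged
#' within 5-min quartiles, and a two-way mixed ANOVA (group x quartile,
#' animal as subject) tests whether the LiCl group's difference grows in
#' specific quartiles. One-way per-quartile follow-ups compare groups
#' within each quartile.
#'
#' @param power_df Tibble as produced by [sim_lfp_power()]: columns
#'   `animal_id, group, session, minute, power`, two sessions per animal.
#' @param quartile_min Quartile width in minutes.
#' @return An object of class `quartile_anova`: `interaction` (tibble with
#'   term, df, F, p), `per_quartile` follow-ups, and `differences` (the
#'   per-animal quartile means).
#' @export
quartile_power_anova <- function(power_df, quartile_min = 5) {
  need <- c("animal_id", "group", "session", "minute", "power")
  if (!all(need %in% names(power_df))) {
    stop("power_df needs columns ", paste(need, collapse = ", "))
  }
  counts <- dplyr::count(power_df, .data$animal_id, .data$session)
  if (length(unique(counts$n)) != 1) {
    stop("sessions have unequal bin counts; cannot pair series")
  }

  diffs <- power_df |>
    dplyr::group_by(.data$animal_id, .data$group) |>
    dplyr::arrange(.data$session, .data$minute, .by_group = TRUE) |>
    dplyr::mutate(norm = normalize_power(.data$power)) |>
    dplyr::ungroup() |>
    dplyr::select("animal_id", "group", "session", "minute", "norm") |>
    tidyr::pivot_wider(names_from = "session", values_from = "norm") |>
    dplyr::mutate(
      absdiff = abs(.data$a - .data$b),
      quartile = factor(ceiling(.data$minute / quartile_min))
    ) |>
    dplyr::group_by(.data$animal_id, .data$group, .data$quartile) |>
    dplyr::summarise(absdiff = mean(.data$absdiff), .groups = "drop")

  diffs$group <- factor(diffs$group)
  diffs$animal_id <- factor(diffs$animal_id)
  fit <- aov(absdiff ~ group * quartile + Error(animal_id / quartile),
    data = diffs
  )
  tabs <- summary(fit)
  within_tab <- tabs[["Error: animal_id:quartile"]][[1]]
  ix <- grep("group:quartile", rownames(within_tab))
  interaction <- tibble::tibble(
    term = "group:quartile",
    df = within_tab[ix, "Df"],
    df_resid = within_tab[nrow(within_tab), "Df"],
    statistic = within_tab[ix, "F value"],
    p.value = within_tab[ix, "Pr(>F)"]
  )

  per_q <- diffs |>
    dplyr::group_by(.data$quartile) |>
    dplyr::group_modify(function(d, key) {
      a <- anova(aov(absdiff ~ group, data = d))
      tibble::tibble(
        df = a$Df[1], df_resid = a$Df[2],
        statistic = a$`F value`[1], p.value = a$`Pr(>F)`[1]
      )
    }) |>
    dplyr::ungroup()

  structure(
    list(interaction = interaction, per_quartile = per_q, differences = diffs),
    class = "quartile_anova"
  )
}

#' @export
print.quartile_anova <- function(x, ...) {
  i <- x$interaction
  cat(sprintf(
    "Group x quartile interaction: F(%d, %d) = %.2f, p = %.4g\n",
    i$df, i$df_resid, i$statistic, i$p.value
  ))
  print(x$per_quartile)
  invisible(x)
}

#' Read a per-minute power table
#'
#' Reads a CSV with columns `animal_id, condition (or group/session),
#' minute, power` as written by [write_fixtures()] or exported from
#' external sources.
#'
#' @param path CSV file path.
#' @return A tibble.
#' @export
read_power_csv <- function(path) {
  df <- tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
  if (!all(c("minute", "power") %in% names(df))) {
    stop("power table needs at least 'minute' and 'power' columns")
  }
  df
}
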