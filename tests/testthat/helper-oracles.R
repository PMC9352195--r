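# Independent oracles used across the suite. These never call the code
# paths they check.

# Exhaustive discrete-change-position marginal for the two-state Gaussian
# model with mu1, mu2 ~ N(0,1), sigma ~ HalfCauchy(1): the state means are
# integrated in closed form (marginal likelihood of a Gaussian segment
# with unit-variance mean prior), sigma numerically on a log grid.
# Returns P(k) for k = 0..T-1, where bins 1..k precede the change.
discrete_tau_marginal <- function(z, n_sigma = 400) {
  T_ <- length(z)
  cy <- c(0, cumsum(z))
  cy2 <- c(0, cumsum(z^2))
  seg_logml <- function(n, Sy, Syy, sig2) {
    if (n == 0) return(rep(0, length(sig2)))
    -n / 2 * log(2 * pi) -
      ((n - 1) * log(sig2) + log(sig2 + n)) / 2 -
      0.5 * (Syy / sig2 - Sy^2 / (sig2 * (sig2 + n)))
  }
  lsig <- seq(log(0.02), log(20), length.out = n_sigma)
  sig <- exp(lsig)
  sig2 <- sig^2
  # HalfCauchy(1) density on sigma, times Jacobian for the log grid
  log_prior <- log(2 / pi) - log1p(sig2) + lsig
  dl <- lsig[2] - lsig[1]
  logpk <- vapply(0:(T_ - 1), function(k) {
    integrand <- log_prior +
      seg_logml(k, cy[k + 1], cy2[k + 1], sig2) +
      seg_logml(T_ - k, cy[T_ + 1] - cy[k + 1], cy2[T_ + 1] - cy2[k + 1], sig2)
    m <- max(integrand)
    m + log(sum(exp(integrand - m)) * dl)
  }, numeric(1))
  w <- exp(logpk - max(logpk))
  w / sum(w)
}

# Closed-form two-class Fisher discriminant with equal priors and a
# shared covariance known exactly: classify x to class 1 iff
# w'(x - (m1+m2)/2) > 0 with w = S^{-1}(m1 - m2).
fisher_predict <- function(m1, m2, S, X) {
  w <- solve(S, m1 - m2)
  mid <- (m1 + m2) / 2
  ifelse(as.vector((X - matrix(mid, nrow(X), length(mid), byrow = TRUE)) %*% w) > 0,
    "a", "b"
  )
}

# Direct one-sided FFT periodogram band power (no windowing, no averaging).
periodogram_band_power <- function(x, fs, band) {
  n <- length(x)
  p <- Mod(fft(x))^2 / (n * fs)
  f <- (seq_len(n) - 1) * fs / n
  keep <- f <= fs / 2
  p <- p[keep]
  f <- f[keep]
  one_sided <- rep(2, length(f))
  one_sided[f == 0 | abs(f - fs / 2) < 1e-9] <- 1
  sel <- f >= band[1] & f <= band[2]
  sum(p[sel] * one_sided[sel]) * fs / n
}

# Small balanced four-taste trial table built directly (no simulator):
# per-taste mean rates (Hz) per window segment, Poisson counts.
toy_trials <- function(n_trials = 10, bin_ms = 25,
                       base = 5, evoked = NULL, seed = 1) {
  set.seed(seed)
  tastes <- c("sucrose", "nacl", "citric_acid", "quinine")
  if (is.null(evoked)) evoked <- setNames(rep(base, 4), tastes)
  t_ms <- seq(-1000, 1500 - bin_ms, by = bin_ms)
  tt <- tibble::tibble(
    trial = seq_len(4 * n_trials),
    taste = rep(tastes, n_trials)
  )
  rows <- lapply(seq_len(nrow(tt)), function(i) {
    rate <- ifelse(t_ms >= 0, evoked[[tt$taste[i]]], base)
    tibble::tibble(
      neuron_id = "n1", trial = tt$trial[i], taste = tt$taste[i],
      time_ms = t_ms,
      count = rpois(length(t_ms), rate * bin_ms / 1000)
    )
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "bin_ms") <- bin_ms
  out
}
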