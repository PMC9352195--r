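#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.cp_fit <- function(x, conf_level = 0.95, ...) {
  a <- (1 - conf_level) / 2
  purrr::map_dfr(
    c("tau", "mu1", "mu2", "sigma"),
    function(p) {
      v <- as.vector(x[[p]])
      tibble::tibble(
        term = p, estimate = mean(v), std.error = sd(v),
        conf.low = quantile(v, a), conf.high = quantile(v, 1 - a)
      )
    }
  )
}

#' @export
glance.cp_fit <- function(x, ...) {
  tibble::tibble(
    tau_mean = mean(x$tau), rhat = x$rhat, reliable = x$reliable,
    n_draws = length(x$tau), n_chains = ncol(x$tau), n_bins = x$n_bins
  )
}

#' @export
tidy.cp_result <- function(x, ...) {
  d <- x$density
  d$threshold <- x$threshold
  d$marked <- d$height > x$threshold
  d
}

#' @export
glance.cp_result <- function(x, ...) {
  tibble::tibble(
    estimate = x$estimate, detected = x$detected,
    n_marked = length(x$marked_bins), threshold = x$threshold,
    rhat = x$fit$rhat
  )
}

#' @export
tidy.sigmoid_fit <- function(x, ...) {
  if (is.null(x$nls)) {
    return(tibble::tibble(
      term = c("lower", "upper", "midpoint", "slope"),
      estimate = c(x$lower, x$upper, x$midpoint, x$slope),
      std.error = NA_real_, statistic = NA_real_, p.value = NA_real_
    ))
  }
  s <- summary(x$nls)$coefficients
  tibble::tibble(
    term = rownames(s), estimate = s[, "Estimate"],
    std.error = s[, "Std. Error"], statistic = s[, "t value"],
    p.value = s[, "Pr(>|t|)"]
  )
}

#' @export
glance.sigmoid_fit <- function(x, ...) {
  tibble::tibble(
    r.squared = x$r_squared, midpoint = x$midpoint, slope = x$slope,
    lower = x$lower, upper = x$upper, degenerate = x$degenerate
  )
}

#' @export
tidy.rd_clusters <- function(x, ...) x$assignments

#' @export
glance.rd_clusters <- function(x, ...) {
  tibble::tibble(
    k = x$k, n_rds = nrow(x$assignments),
    n_unassigned = sum(is.na(x$assignments$cluster)),
    n_angle_peaks = x$n_angle_peaks,
    best_bic = max(x$bic$bic, na.rm = TRUE)
  )
}

#' @export
glance.coupling_test <- function(x, ...) {
  tibble::tibble(
    observed = x$observed, p.value = x$p, mode = x$mode, n_sims = x$n_sims
  )
}

#' @export
tidy.quartile_anova <- function(x, ...) {
  dplyr::bind_rows(
    x$interaction,
    dplyr::mutate(x$per_quartile, term = paste0("quartile_", .data$quartile))
  )
}

#' @export
tidy.magnitude_anova <- function(x, ...) {
  dplyr::bind_rows(x$interaction, x$main_effects)
}
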