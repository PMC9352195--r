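#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot per-minute power series by condition
#'
#' @param power_df Tibble with `animal_id, minute, power` and a
#'   `condition` or `session` column.
#' @return A ggplot object.
#' @export
plot_power_series <- function(power_df) {
  col <- if ("condition" %in% names(power_df)) "condition" else "session"
  ggplot2::ggplot(
    power_df,
    ggplot2::aes(
      .data$minute, .data$power,
      color = .data[[col]], group = interaction(
        power_df$animal_id, power_df[[col]]
      )
    )
  ) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::labs(
      x = "minute post-injection", y = "band power (a.u.)", color = col
    ) +
    ggplot2::theme_minimal()
}

#' @describeIn detect_changepoint Posterior change-position density with
#'   the shuffle threshold and marked bins.
#' @param object A `cp_result`.
#' @param ... Unused.
#' @export
autoplot.cp_result <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(.data$bin_center, .data$height)) +
    ggplot2::geom_col(ggplot2::aes(fill = .data$marked), width = 0.45) +
    ggplot2::geom_hline(
      yintercept = object$threshold, linetype = "dashed", color = "red"
    ) +
    ggplot2::scale_fill_manual(
      values = c(`FALSE` = "grey60", `TRUE` = "firebrick"), guide = "none"
    ) +
    ggplot2::labs(
      x = "change position tau (min)", y = "posterior mass",
      title = if (object$detected) {
        sprintf("change point at %.2f min", object$estimate)
      } else {
        "no change point detected"
      }
    ) +
    ggplot2::theme_minimal()
}

#' @describeIn lda_loo_accuracy Decoding accuracy across time with the
#'   25 % chance level.
#' @param object A `decoding_result`.
#' @param ... Unused.
#' @export
autoplot.decoding_result <- function(object, ...) {
  ggplot2::ggplot(
    object$accuracy,
    ggplot2::aes(.data$time_ms + object$bin_ms / 2, .data$accuracy)
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0.25, linetype = "dashed") +
    ggplot2::labs(x = "time from taste delivery (ms)", y = "LDA accuracy") +
    ggplot2::theme_minimal()
}

#' @describeIn moving_spearman Mean |rho| across neurons over time.
#' @param object A `palatability_trace`.
#' @param ... Unused.
#' @export
autoplot.palatability_trace <- function(object, ...) {
  ggplot2::ggplot(
    object$summary, ggplot2::aes(.data$t_center, .data$mean_abs_rho)
  ) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "window center (ms)", y = "mean |Spearman rho|"
    ) +
    ggplot2::theme_minimal()
}

#' @describeIn fit_sigmoid Difference trace with the fitted sigmoid.
#' @param object A `sigmoid_fit`.
#' @param ... Unused.
#' @export
autoplot.sigmoid_fit <- function(object, ...) {
  tr <- object$trace
  tr$fitted <- predict(object$nls)
  ggplot2::ggplot(tr, ggplot2::aes(.data$minute, .data$difference)) +
    ggplot2::geom_line(color = "black") +
    ggplot2::geom_line(
      ggplot2::aes(y = .data$fitted), color = "red", linetype = "dashed"
    ) +
    ggplot2::labs(
      x = "minute post-injection", y = "normalized LiCl - saline difference"
    ) +
    ggplot2::theme_minimal()
}

#' Polar plot of response-difference vectors by cluster
#'
#' @param clusters An `rd_clusters` object.
#' @return A ggplot object.
#' @export
plot_rd_polar <- function(clusters) {
  d <- clusters$assignments
  d$cluster <- factor(d$cluster, exclude = NULL)
  ggplot2::ggplot(
    d, ggplot2::aes(.data$angle, .data$distance, color = .data$cluster)
  ) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::coord_polar(start = -pi / 2, direction = -1) +
    ggplot2::scale_x_continuous(
      limits = c(0, 360), breaks = c(0, 90, 180, 270)
    ) +
    ggplot2::labs(
      x = "RD angle (deg)", y = "RD distance (% max responsiveness)"
    ) +
    ggplot2::theme_minimal()
}
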