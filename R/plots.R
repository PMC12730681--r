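#' Plot a growth trajectory
#'
#' Total wet weight (somatic plus ovary) and ovary mass against time, with
#' molt events marked as vertical lines. The stepwise jumps in wet weight
#' are the molts; the ovary curve shows the slow pre-puberty and rapid
#' post-puberty phases.
#'
#' @param object A `deb_trajectory`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @method autoplot deb_trajectory
autoplot.deb_trajectory <- function(object, ...) {
  long <- tidy.deb_trajectory(object, series = c("ww_total", "wo"))
  long$series <- factor(long$series, c("ww_total", "wo"),
                        c("total wet weight (g)", "ovary mass (g)"))
  molts <- molt_events(object)
  gg <- ggplot2::ggplot(long, ggplot2::aes(x = .data$day, y = .data$value)) +
    ggplot2::geom_line(colour = "#2c7fb8") +
    ggplot2::facet_wrap(ggplot2::vars(.data$series), ncol = 1,
                        scales = "free_y") +
    ggplot2::labs(x = "day", y = NULL)
  if (nrow(molts) > 0) {
    gg <- gg + ggplot2::geom_vline(data = molts,
                                   ggplot2::aes(xintercept = .data$day),
                                   linetype = "dotted", colour = "grey50")
  }
  gg
}

#' Plot a sensitivity table
#'
#' @param object A `deb_sensitivity` tibble.
#' @param ... Unused.
#' @return A ggplot bar chart of the sensitivity indices.
#' @export
#' @method autoplot deb_sensitivity
autoplot.deb_sensitivity <- function(object, ...) {
  d <- object[!is.na(object$si_pct), , drop = FALSE]
  d$parameter <- stats::reorder(d$parameter, d$si_pct)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$parameter, y = .data$si_pct)) +
    ggplot2::geom_col(fill = "#2c7fb8") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "sensitivity index (%)")
}

#' Plot observed against simulated values
#'
#' Scatter of paired values with the 1:1 line, the usual visual companion
#' of the goodness-of-fit statistics.
#'
#' @param data Data frame with the paired series.
#' @param observed,predicted Column names (tidy-eval).
#' @return A ggplot object.
#' @export
plot_obs_vs_sim <- function(data, observed, predicted) {
  o <- rlang::eval_tidy(rlang::enquo(observed), data)
  s <- rlang::eval_tidy(rlang::enquo(predicted), data)
  d <- tibble::tibble(observed = o, predicted = s)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$observed, y = .data$predicted)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    ggplot2::geom_point(colour = "#2c7fb8") +
    ggplot2::labs(x = "observed", y = "simulated")
}
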