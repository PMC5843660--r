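#' Plot a simulation result
#'
#' `autoplot()` draws, by panel: the population activity of each cell type
#' over time, the mean non-synaptic excitatory and inhibitory effects, or
#' the per-group mean connectivity traces.
#'
#' @param object A `dg_result`.
#' @param what `"activity"`, `"ns"` or `"connectivity"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dg_result <- function(object, what = c("activity", "ns",
                                                "connectivity"), ...) {
  what <- match.arg(what)
  steps <- object$steps
  if (what == "activity") {
    long <- tidyr::pivot_longer(
      steps, dplyr::any_of(c("s_gc", "s_gc_inverted", "s_mc", "s_in")),
      names_to = "population", values_to = "s")
    ggplot2::ggplot(long, ggplot2::aes(.data$time_days, .data$s)) +
      ggplot2::geom_line(linewidth = 0.3) +
      ggplot2::geom_hline(yintercept = c(object$config$rest_lo,
                                         object$config$rest_hi),
                          linetype = "dotted") +
      ggplot2::facet_wrap(~population, ncol = 1) +
      ggplot2::labs(x = "time (days)", y = "activity s") +
      ggplot2::theme_minimal()
  } else if (what == "ns") {
    long <- tidyr::pivot_longer(steps, c("nse", "nsi"),
                                names_to = "component",
                                values_to = "value")
    ggplot2::ggplot(long, ggplot2::aes(.data$time_days, .data$value,
                                       colour = .data$component)) +
      ggplot2::geom_line(linewidth = 0.3) +
      ggplot2::labs(x = "time (days)", y = "non-synaptic effect") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(object$groups,
                    ggplot2::aes(.data$time_days, .data$mean_c)) +
      ggplot2::geom_line(linewidth = 0.3) +
      ggplot2::facet_wrap(~group, scales = "free_y") +
      ggplot2::labs(x = "time (days)", y = "mean connectivity") +
      ggplot2::theme_minimal()
  }
}

#' Bar plot of 64-day connectivity changes per group
#'
#' @param result A `dg_result` (single run) or a tibble of per-replicate
#'   changes with columns `group` and `change` (mean and SEM are then drawn
#'   over replicates).
#' @return A ggplot object.
#' @export
plot_connectivity_change <- function(result) {
  df <- if (inherits(result, "dg_result")) connectivity_change(result)
  else tibble::as_tibble(result)
  summ <- df |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      mean = mean(.data$change),
      sem = if (dplyr::n() >= 2) stats::sd(.data$change) / sqrt(dplyr::n())
      else NA_real_,
      .groups = "drop")
  ggplot2::ggplot(summ, ggplot2::aes(.data$group, .data$mean)) +
    ggplot2::geom_col() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sem,
                                        ymax = .data$mean + .data$sem),
                           width = 0.3, na.rm = TRUE) +
    ggplot2::labs(x = "connectivity group",
                  y = "change at 64 d post-SE") +
    ggplot2::theme_minimal()
}

#' Occurrence / latency heat maps from a sweep table
#'
#' @param sweep Tibble from [run_sweep()] over `inverted_fraction` x
#'   `gabaa_duration_days`.
#' @param response `"n_events"` or `"latency_days"`.
#' @return A ggplot object.
#' @export
plot_sweep <- function(sweep, response = c("n_events", "latency_days")) {
  response <- match.arg(response)
  summ <- sweep |>
    dplyr::group_by(.data$inverted_fraction, .data$gabaa_duration_days) |>
    dplyr::summarise(value = mean(.data[[response]], na.rm = TRUE),
                     .groups = "drop")
  ggplot2::ggplot(summ,
                  ggplot2::aes(factor(.data$gabaa_duration_days),
                               factor(100 * .data$inverted_fraction),
                               fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::labs(x = "excitatory-GABAa duration (days)",
                  y = "inverted granule cells (%)",
                  fill = response) +
    ggplot2::theme_minimal()
}
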