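#' Plot a simulation result
#'
#' Faceted time-series view of the main pathway variables (external drive
#' context is not shown; pick variables with `vars`).
#'
#' @param object An `nvc_sim` tibble.
#' @param vars Character vector of columns to display.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.nvc_sim <- function(object,
                             vars = c("nu_e", "Glu", "Ca", "PG", "CBF_in",
                                      "BOLD"),
                             ...) {
  df <- tidyr::pivot_longer(as.data.frame(object)[, c("time", vars)],
                            -"time", names_to = "variable",
                            values_to = "value")
  df$variable <- factor(df$variable, levels = vars)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$variable),
                        scales = "free_y", switch = "y") +
    ggplot2::labs(x = "time (s)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a coding curve
#'
#' Calcium-spike frequency and amplitude and BOLD amplitude against the
#' steady excitatory rate, with the fitted logarithmic frequency model
#' overlaid.
#'
#' @param object An `nvc_coding` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.nvc_coding <- function(object, ...) {
  cu <- object$curve
  df <- tidyr::pivot_longer(
    cu[, c("nu_e", "f_ca", "a_ca", "bold_amp")], -"nu_e",
    names_to = "measure", values_to = "value")
  fit <- object$log_fit$fitted
  ggplot2::ggplot(df, ggplot2::aes(x = .data$nu_e, y = .data$value)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = data.frame(nu_e = fit$x, value = fit$fitted,
                                         measure = "f_ca"),
                       colour = "steelblue") +
    ggplot2::facet_wrap(~measure, scales = "free_y") +
    ggplot2::labs(x = "steady excitatory rate (Hz)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a canonical HRF fit
#'
#' @param object An `nvc_hrf_fit` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.nvc_hrf_fit <- function(object, ...) {
  df <- object$fitted
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$hrf), linewidth = 0.4) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "firebrick",
                       linetype = 2) +
    ggplot2::labs(x = "time from onset (s)", y = "normalized BOLD",
                  subtitle = paste0("double-gamma fit, R² = ",
                                    signif(object$r_squared, 3))) +
    ggplot2::theme_minimal()
}
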