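#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a trajectory
#'
#' Time evolution of the average expressed opinion \eqn{\langle\omega\rangle}
#' and the local opinion climate \eqn{r}, with the constant mean belief as a
#' reference line: the vertical gaps are the misperception components.
#'
#' @param object A `qn_trajectory`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot qn_trajectory
#' @export
autoplot.qn_trajectory <- function(object, ...) {
  d <- tibble::as_tibble(object) |>
    tidyr::pivot_longer(c("mean_omega", "r"), names_to = "quantity",
                        values_to = "value") |>
    dplyr::mutate(quantity = dplyr::recode(.data$quantity,
                                           mean_omega = "expressed <omega>",
                                           r = "local climate r"))
  ggplot2::ggplot(d, ggplot2::aes(.data$t, .data$value,
                                  colour = .data$quantity)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = attr(object, "mean_belief"),
                        linetype = "dotted") +
    ggplot2::labs(x = "time units", y = NULL, colour = NULL,
                  title = sprintf("%s dynamics", attr(object, "model")),
                  subtitle = "dotted line: constant mean belief <b>") +
    ggplot2::theme_minimal()
}

#' Plot an ensemble sweep
#'
#' Final mean belief, expressed opinion and local climate against the
#' hard-core degree \eqn{K_c}, with standard-error ribbons where available.
#'
#' @param object A `qn_ensemble` from [sweep_kc()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot qn_ensemble
#' @export
autoplot.qn_ensemble <- function(object, ...) {
  d <- tibble::as_tibble(object) |>
    dplyr::select("kc", "mean_b", "mean_omega_f", "r_f") |>
    tidyr::pivot_longer(-"kc", names_to = "quantity", values_to = "value") |>
    dplyr::mutate(quantity = dplyr::recode(.data$quantity,
                                           mean_b = "belief <b>",
                                           mean_omega_f = "expressed <omega_f>",
                                           r_f = "local climate r_f"))
  ggplot2::ggplot(d, ggplot2::aes(.data$kc, .data$value,
                                  colour = .data$quantity)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "hard-core degree K_c", y = "final value",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a power-law fit
#'
#' Points and fitted line on log-log axes.
#'
#' @param object A `qn_powerlaw_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot qn_powerlaw_fit
#' @export
autoplot.qn_powerlaw_fit <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(.data$kc, .data$y)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), linetype = "dashed") +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "K_c", y = "silenced per hard-core agent",
                  title = sprintf("power-law fit, exponent %.2f",
                                  object$exponent)) +
    ggplot2::theme_minimal()
}
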