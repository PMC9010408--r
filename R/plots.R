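# ggplot2 presentation layer: autoplot methods for the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an acceptance grid as a heat map
#'
#' @param object An [acceptance_grid()] tibble; multiple participants are
#'   averaged per cell.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.acceptance_grid <- function(object, ...) {
  cells <- object |>
    dplyr::group_by(.data$phi, .data$offer_pence) |>
    dplyr::summarise(p_accept = stats::weighted.mean(.data$p_accept,
                                                     .data$n_trials),
                     .groups = "drop")
  ggplot2::ggplot(cells, ggplot2::aes(x = .data$offer_pence, y = .data$phi,
                                      fill = .data$p_accept)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "#2c3e70", high = "#f3c911",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = "Offer (pence)", y = "Face valence",
                  fill = "P(accept)") +
    ggplot2::theme_minimal()
}

#' Plot a fitted valence weighting function
#'
#' Shows the fitted perceived-valence curve against the identity diagonal
#' and the (jittered) ratings it was fit to.
#'
#' @param object A [fit_weighting()] object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.weighting_fit <- function(object, ...) {
  curve <- tibble::tibble(
    phi = seq(0.01, 0.99, by = 0.01),
    epsilon = prelec_weight(seq(0.01, 0.99, by = 0.01),
                            object$delta, object$gamma)
  )
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$phi, y = .data$epsilon)) +
    ggplot2::geom_abline(linetype = "dashed", colour = "grey60") +
    ggplot2::geom_line(linewidth = 1) +
    ggplot2::geom_jitter(data = object$fitted,
                         ggplot2::aes(y = .data$rating),
                         width = 0.005, height = 0, alpha = 0.4) +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "True valence", y = "Perceived valence") +
    ggplot2::theme_minimal()
}

#' Plot generate-recover results
#'
#' True versus recovered parameter values, one panel per parameter, with
#' the identity line.
#'
#' @param object A [generate_recover()] report.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.recovery_report <- function(object, ...) {
  ggplot2::ggplot(object$draws,
                  ggplot2::aes(x = .data$true, y = .data$recovered)) +
    ggplot2::geom_abline(linetype = "dashed", colour = "grey60") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::facet_wrap(~parameter, scales = "free") +
    ggplot2::labs(x = "True value", y = "Recovered value") +
    ggplot2::theme_minimal()
}

#' Plot time-resolved pupil regression coefficients
#'
#' Coefficient time courses after offer onset, one line per regressor
#' (constant omitted by default).
#'
#' @param object A [timepoint_regression()] object.
#' @param terms Regressors to show; defaults to all but the constant.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pupil_regression <- function(object,
                                      terms = setdiff(object$terms,
                                                      "constant"),
                                      ...) {
  dat <- generics::tidy(object) |>
    dplyr::filter(.data$term %in% terms)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$time_s, y = .data$estimate,
                                    colour = .data$term)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Time after offer onset (s)", y = "Coefficient",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
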