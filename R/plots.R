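# ggplot2 quick-look plots for the main result types.

#' Plot a spectrum set
#'
#' Intensity versus energy transfer on a log scale, one panel per Q.
#'
#' @param object a [as_qens_spectra()] tibble.
#' @param q optional subset of Q values to show.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot qens_spectra
#' @export
autoplot.qens_spectra <- function(object, q = NULL, ...) {
  df <- as_tibble(object)
  if (!is.null(q)) df <- df[df$q %in% q, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$energy_meV, y = .data$intensity)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~q, labeller = ggplot2::label_both) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "energy transfer (meV)", y = "S(Q, ω) (1/meV)",
                  title = attr(object, "label")) +
    ggplot2::theme_minimal()
}

#' Plot a global fit
#'
#' Normalized data with the fitted four-component model overlaid, one panel
#' per Q.
#'
#' @param object a `qens_fit` from [fit_global()].
#' @param q optional subset of Q values to show.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot qens_fit
#' @export
autoplot.qens_fit <- function(object, q = NULL, ...) {
  df <- as_tibble(object$data)
  ft <- fitted_spectra(object)
  if (!is.null(q)) {
    df <- df[df$q %in% q, ]
    ft <- ft[ft$q %in% q, ]
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$energy_meV)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$intensity), size = 0.3,
                        alpha = 0.5) +
    ggplot2::geom_line(data = ft, ggplot2::aes(y = .data$fitted),
                       color = "firebrick", linewidth = 0.4) +
    ggplot2::facet_wrap(~q, labeller = ggplot2::label_both) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "energy transfer (meV)", y = "S(Q, ω) (1/meV)") +
    ggplot2::theme_minimal()
}

#' Plot a dispersion curve
#'
#' HWHM versus Q^2 with error bars; if a `qens_jump_fit` is supplied the
#' fitted jump-diffusion law is overlaid.
#'
#' @param object a `qens_dispersion` from [extract_dispersion()].
#' @param fit optional `qens_jump_fit` overlay.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot qens_dispersion
#' @export
autoplot.qens_dispersion <- function(object, fit = NULL, ...) {
  df <- as_tibble(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$q2, y = .data$hwhm_meV)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$hwhm_meV - .data$hwhm_err,
                                        ymax = .data$hwhm_meV + .data$hwhm_err),
                           width = 0) +
    ggplot2::labs(x = expression(Q^2 ~ (ring(A)^-2)), y = "HWHM (meV)",
                  title = attr(object, "component_label")) +
    ggplot2::theme_minimal()
  if (!is.null(fit)) {
    q2grid <- seq(0, max(df$q2) * 1.05, length.out = 200)
    line <- tibble(q2 = q2grid,
                   hwhm_meV = predict_jump_hwhm(fit, sqrt(q2grid)))
    p <- p + ggplot2::geom_line(data = line, color = "firebrick")
  }
  p
}
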