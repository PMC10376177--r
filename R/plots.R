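#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_vline
#'   geom_hline labs annotate theme_minimal
#' @export
ggplot2::autoplot

#' Plot an extracted ion chromatogram
#'
#' @param object An [extract_xic()] trace.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.xic <- function(object, ...) {
  p <- ggplot(object, aes(x = .data$rt, y = .data$intensity)) +
    geom_line(colour = "grey30") +
    labs(x = "Retention time (min)", y = "Intensity",
         title = sprintf("XIC m/z %.4f (+/- %g ppm)",
                         attr(object, "mz"), attr(object, "tol_ppm"))) +
    theme_minimal()
  apex <- attr(object, "apex_rt")
  if (!is.na(apex)) {
    p <- p + geom_vline(xintercept = apex, linetype = "dashed", colour = "firebrick")
  }
  p
}

#' Plot coelution evidence: one XIC trace per charge state
#'
#' @param object A [detect_coelution()] result.
#' @param ... Unused.
#' @return A ggplot faceted-free overlay, one colour per charge.
#' @exportS3Method ggplot2::autoplot
autoplot.coelution_evidence <- function(object, ...) {
  d <- dplyr::bind_rows(purrr::imap(object$xics, function(x, z) {
    tibble(z = z, rt = x$rt, intensity = x$intensity)
  }))
  p <- ggplot(d, aes(x = .data$rt, y = .data$intensity, colour = .data$z)) +
    geom_line() +
    labs(x = "Retention time (min)", y = "Intensity", colour = "Charge",
         title = if (object$accepted)
           sprintf("Coelution accepted: %d charges at %.2f min",
                   object$n_charges_found, object$apex_rt)
         else "No coelution detected") +
    theme_minimal()
  if (object$accepted) {
    p <- p + geom_vline(xintercept = object$apex_rt, linetype = "dashed",
                        colour = "grey40")
  }
  p
}

#' Plot a fitted kinetics trace
#'
#' @param object A [fit_linear_rate()] result.
#' @param trace The trace the fit was computed from.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.rate_fit <- function(object, trace, ...) {
  ggplot(trace, aes(x = .data$time_min, y = .data$absorbance)) +
    geom_point(size = 0.8, colour = "grey40") +
    annotate("segment",
             x = object$window[1], xend = object$window[2],
             y = object$intercept + object$slope * object$window[1],
             yend = object$intercept + object$slope * object$window[2],
             colour = "firebrick") +
    labs(x = "Time (min)", y = "Absorbance",
         title = sprintf("Initial rate %.4g dA/min (R^2 = %.4f)",
                         object$slope, object$r2)) +
    theme_minimal()
}

#' Plot a melting curve with its Tm and onset
#'
#' @param object A [melt_analysis()] result.
#' @param curve The curve the fit was computed from.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.melt_fit <- function(object, curve, ...) {
  p <- ggplot(curve, aes(x = .data$temperature, y = .data$ratio)) +
    geom_line(colour = "grey30") +
    geom_vline(xintercept = object$tm, colour = "firebrick", linetype = "dashed") +
    labs(x = "Temperature (deg C)", y = "Fluorescence ratio (350/330 nm)",
         title = sprintf("Tm = %.1f C, onset = %.1f C", object$tm, object$onset)) +
    theme_minimal()
  if (!is.na(object$onset)) {
    p <- p + geom_vline(xintercept = object$onset, colour = "steelblue",
                        linetype = "dotted")
  }
  p
}
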