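## ggplot2 displays for spectra, calibrations and latent-variable models.

#' Plot spectra
#'
#' Overlays spectra colored by an identity column.
#'
#' @param data A spectra table.
#' @param color Identity column used for the color aesthetic.
#' @return A ggplot object.
#' @export
plot_spectra <- function(data, color = "sample_id") {
  stopifnot(is.data.frame(data))
  grp <- interaction(data[spectrum_id_cols(data)], drop = TRUE)
  ggplot2::ggplot(dplyr::mutate(data, .spectrum = grp),
                  ggplot2::aes(.data$wavenumber, .data$intensity,
                               group = .data$.spectrum,
                               color = .data[[color]])) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = expression("Raman shift (cm"^-1 * ")"),
                  y = "Intensity (a.u.)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.ci_calibration <- function(object, pairs = NULL, ...) {
  p <- ggplot2::ggplot()
  if (!is.null(pairs)) {
    p <- p + ggplot2::geom_point(data = pairs,
                                 ggplot2::aes(.data$ci, .data$ratio))
  }
  p +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         color = "steelblue") +
    ggplot2::labs(x = "%CI (PXRD reference)", y = "380/1096 ratio",
                  title = sprintf("Calibration %s", object$label)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.nipals_pca <- function(object, color = NULL, components = c(1, 2), ...) {
  sc <- tidy(object, "scores")
  xs <- paste0("PC", components[1]); ys <- paste0("PC", components[2])
  aes <- if (!is.null(color) && color %in% names(sc)) {
    ggplot2::aes(.data[[xs]], .data[[ys]], color = .data[[color]])
  } else ggplot2::aes(.data[[xs]], .data[[ys]])
  ggplot2::ggplot(sc, aes) +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = sprintf("%s (%.1f%%)", xs, object$explained_variance[components[1]]),
      y = sprintf("%s (%.1f%%)", ys, object$explained_variance[components[2]]),
      title = "PCA scores") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.pls1_model <- function(object, n_factors = NULL, ...) {
  if (is.null(n_factors)) n_factors <- ncol(object$coefficients)
  df <- tibble(reference = object$y,
               predicted = object$fitted[, n_factors])
  ggplot2::ggplot(df, ggplot2::aes(.data$reference, .data$predicted)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, color = "grey50") +
    ggplot2::geom_point(color = "steelblue") +
    ggplot2::labs(x = "Reference %CI", y = "Predicted %CI",
                  title = sprintf("PLS1 calibration fit (%d factors)", n_factors)) +
    ggplot2::theme_minimal()
}

#' Correlation-loadings plot
#'
#' Per-wavenumber correlation with a latent factor, with the 50% and 100%
#' explained-variance bounds drawn as horizontal guides.
#'
#' @param corr Output of [correlation_loadings()].
#' @param factor Column to plot (e.g. `"PC1"` or `"Factor1"`).
#' @return A ggplot object.
#' @export
plot_correlation_loadings <- function(corr, factor = names(corr)[2]) {
  r50 <- attr(corr, "r50") %||% sqrt(0.5)
  ggplot2::ggplot(corr, ggplot2::aes(.data$variable, .data[[factor]])) +
    ggplot2::geom_hline(yintercept = c(-1, 1), color = "grey40") +
    ggplot2::geom_hline(yintercept = c(-r50, r50), linetype = 2, color = "grey60") +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::labs(x = expression("Raman shift (cm"^-1 * ")"),
                  y = sprintf("Correlation with %s", factor)) +
    ggplot2::ylim(-1, 1) +
    ggplot2::theme_minimal()
}
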