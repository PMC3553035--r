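#' @importFrom ggplot2 ggplot aes geom_line geom_point geom_hline geom_vline
#'   geom_abline labs theme_minimal scale_x_continuous
NULL

#' Plot a binned expression profile
#'
#' @param object A `binned_profile`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot binned_profile
#' @export
autoplot.binned_profile <- function(object, ...) {
  ggplot(as_tibble(object), aes(x = .data$start / 1e6, y = .data$value)) +
    geom_line(linewidth = 0.3) +
    labs(x = "Genome position (Mb)",
         y = "Mean expression (log10 pM)",
         title = if (isTRUE(attr(object, "smoothed")))
           sprintf("Smoothed profile (window %d bins)", attr(object, "window"))
         else "Binned expression profile") +
    theme_minimal()
}

#' Plot a periodogram with its significance threshold
#'
#' @param object A `periodogram`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot periodogram
#' @export
autoplot.periodogram <- function(object, ...) {
  thr <- attr(object, "threshold")
  pk <- attr(object, "major_peak_wavelength")
  p <- ggplot(as_tibble(object),
              aes(x = .data$wavelength / 1e3, y = .data$power)) +
    geom_line() +
    geom_vline(xintercept = pk / 1e3, linetype = "dashed", colour = "red") +
    labs(x = "Wavelength (kb)", y = "Spectral power",
         title = sprintf("Major peak at %.0f kb", pk / 1e3)) +
    theme_minimal()
  if (is.finite(thr)) {
    p <- p + geom_hline(yintercept = thr, linetype = "dotted",
                        colour = "blue")
  }
  p
}

#' Plot the additive-versus-simultaneous epistasis fit
#'
#' @param object An `epistasis_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot epistasis_fit
#' @export
autoplot.epistasis_fit <- function(object, ...) {
  df <- tibble(additive = object$additive,
               simultaneous = object$simultaneous)
  ggplot(df, aes(x = .data$additive, y = .data$simultaneous)) +
    geom_point(alpha = 0.3, size = 0.5) +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                colour = "grey50") +
    geom_abline(slope = object$slope, intercept = object$intercept,
                colour = "black") +
    labs(x = "Additive change (log10)", y = "Simultaneous change (log10)",
         title = sprintf("%s: k = %.2f, alpha = %.2f",
                         object$subset, object$slope, object$alpha)) +
    theme_minimal()
}

#' Plot rank-product results as fold change versus pfp
#'
#' @param object A `rank_product_tbl`.
#' @param fdr_cutoff Cutoff drawn as a horizontal guide.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot rank_product_tbl
#' @export
autoplot.rank_product_tbl <- function(object, fdr_cutoff = 0.001, ...) {
  df <- mutate(as_tibble(object),
               pfp = pmin(.data$pfp_up, .data$pfp_down))
  ggplot(df, aes(x = .data$fold_change,
                 y = -log10(pmax(.data$pfp, 1e-6)),
                 colour = .data$direction)) +
    geom_point(alpha = 0.5, size = 0.6) +
    geom_hline(yintercept = -log10(fdr_cutoff), linetype = "dotted") +
    labs(x = "Fold change (log10)", y = "-log10 pfp",
         colour = "Direction") +
    theme_minimal()
}
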