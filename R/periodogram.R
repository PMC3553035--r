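#' Fourier periodogram of a genome-position expression profile
#'
#' Computes the discrete Fourier power spectrum of the (mean-subtracted,
#' circular) binned profile. Power at frequency k is scaled so that the sum
#' over all positive frequencies equals the variance of the series
#' (Parseval); a pure sinusoid of amplitude A contributes power A^2/2 at its
#' frequency. Wavelengths are restricted to an analysis band; the 95%
#' significance threshold follows a chi-squared (2 d.f., i.e. exponential)
#' null for each normalized ordinate.
#'
#' @param profile A [bin_expression()] profile, normally smoothed first.
#' @param min_wavelength,max_wavelength Analysis band in bp. Defaults:
#'   100 kb and half the profile span.
#' @param confidence Confidence level for the significance threshold.
#' @return A tibble of class `periodogram` with columns `k` (cycles per
#'   chromosome), `wavelength` (bp), `power`, `significant`, and attributes
#'   `threshold`, `confidence`, `major_peak_wavelength`, `major_peak_power`,
#'   `span`, `total_power` (all positive frequencies, for Parseval checks).
#' @export
periodogram <- function(profile, min_wavelength = 1e5,
                        max_wavelength = NULL, confidence = 0.95) {
  n <- nrow(profile)
  span <- attr(profile, "span") %||% (n * (attr(profile, "bin_size") %||% 1))
  if (is.null(max_wavelength)) max_wavelength <- span / 2
  x <- profile$value - mean(profile$value)
  ft <- fft(x)
  kmax <- n %/% 2
  k <- seq_len(kmax)
  power <- 2 * Mod(ft[k + 1])^2 / n^2
  if (n %% 2 == 0) power[kmax] <- Mod(ft[kmax + 1])^2 / n^2
  wavelength <- span / k
  in_band <- wavelength >= min_wavelength & wavelength <= max_wavelength
  if (!any(in_band)) abort("empty analysis band: no Fourier wavelengths inside")

  out <- tibble(k = k[in_band], wavelength = wavelength[in_band],
                power = power[in_band])
  mean_power <- mean(out$power)
  threshold <- if (mean_power > 0) {
    -mean_power * log(1 - confidence)
  } else {
    NA_real_
  }
  out$significant <- if (is.na(threshold)) rep(FALSE, nrow(out)) else
    out$power > threshold
  i_max <- which.max(out$power)
  structure(
    out,
    threshold = threshold,
    confidence = confidence,
    mean_power = mean_power,
    major_peak_wavelength = out$wavelength[i_max],
    major_peak_power = out$power[i_max],
    major_peak_significant = out$significant[i_max],
    span = span,
    total_power = sum(power),
    class = c("periodogram", class(tibble()))
  )
}

#' Chi-squared significance threshold for periodogram ordinates
#'
#' Under a white-noise null, each periodogram ordinate divided by half the
#' mean power is chi-squared with 2 degrees of freedom — equivalently, the
#' ordinate itself is exponential with the mean in-band power as its mean.
#' The threshold exceeded with probability `1 - confidence` is therefore
#' `-mean_power * log(1 - confidence)`.
#'
#' @param pg A [periodogram()] (or numeric vector of in-band powers).
#' @param confidence Confidence level (default 0.95).
#' @return The per-frequency power threshold (a single number).
#' @export
periodogram_threshold <- function(pg, confidence = 0.95) {
  power <- if (is.numeric(pg)) pg else pg$power
  if (length(power) < 10) {
    warn("fewer than 10 in-band frequencies: threshold is unreliable")
  }
  m <- mean(power)
  if (!is.finite(m) || m <= 0) {
    abort("degenerate spectrum: mean in-band power is zero")
  }
  -m * log(1 - confidence)
}

#' Major peak of a periodogram
#' @param pg A [periodogram()].
#' @return One-row tibble with `wavelength`, `power`, `significant`.
#' @export
major_peak <- function(pg) {
  tibble(
    wavelength = attr(pg, "major_peak_wavelength"),
    power = attr(pg, "major_peak_power"),
    significant = attr(pg, "major_peak_significant")
  )
}

#' Number of periods of a wavelength around the chromosome
#'
#' @param genome_length Chromosome length in bp.
#' @param wavelength Wavelength in bp (positive).
#' @return Integer period count, `round(genome_length / wavelength)`.
#' @export
count_periods <- function(genome_length, wavelength) {
  if (any(wavelength <= 0)) abort("`wavelength` must be positive")
  as.integer(round(genome_length / wavelength))
}

#' Least-squares sinusoid fit at a fixed wavelength
#'
#' Fits `offset + amplitude * sin(2*pi*pos/wavelength + phase)` to the
#' profile by ordinary least squares (linear in the sine and cosine basis at
#' fixed wavelength, so the fit is exact, not iterative).
#'
#' @param profile A [bin_expression()] profile.
#' @param wavelength Wavelength in bp (positive), normally the major
#'   periodogram peak.
#' @return A list of class `sinusoid_fit`: `wavelength`, `amplitude`
#'   (non-negative), `phase` (radians), `offset`, `rss`, `fitted`.
#' @export
fit_sinusoid <- function(profile, wavelength) {
  if (wavelength <= 0) abort("`wavelength` must be positive")
  bin_size <- attr(profile, "bin_size") %||% 1
  pos <- (profile$bin - 0.5) * bin_size
  theta <- 2 * pi * pos / wavelength
  fit <- lm(profile$value ~ sin(theta) + cos(theta))
  a <- coef(fit)[2]
  b <- coef(fit)[3]
  amplitude <- sqrt(a^2 + b^2)
  phase <- atan2(b, a)
  structure(
    list(wavelength = wavelength,
         amplitude = unname(amplitude),
         phase = unname(phase),
         offset = unname(coef(fit)[1]),
         rss = sum(fit$residuals^2),
         fitted = unname(fit$fitted.values),
         position = pos),
    class = "sinusoid_fit"
  )
}

#' @export
print.sinusoid_fit <- function(x, ...) {
  cat(sprintf(
    "<sinusoid_fit> wavelength %.0f bp, amplitude %.4f, phase %.3f rad, offset %.4f, RSS %.4g\n",
    x$wavelength, x$amplitude, x$phase, x$offset, x$rss))
  invisible(x)
}

#' @rdname fit_sinusoid
#' @param x A `sinusoid_fit`.
#' @param ... Unused.
#' @method tidy sinusoid_fit
#' @export
tidy.sinusoid_fit <- function(x, ...) {
  tibble(term = c("offset", "amplitude", "phase"),
         estimate = c(x$offset, x$amplitude, x$phase))
}

#' @rdname fit_sinusoid
#' @method glance sinusoid_fit
#' @export
glance.sinusoid_fit <- function(x, ...) {
  tibble(wavelength = x$wavelength, amplitude = x$amplitude,
         phase = x$phase, offset = x$offset, rss = x$rss)
}

#' @rdname periodogram
#' @param x A `periodogram`.
#' @param ... Unused.
#' @method glance periodogram
#' @export
glance.periodogram <- function(x, ...) {
  tibble(
    major_peak_wavelength = attr(x, "major_peak_wavelength"),
    major_peak_power = attr(x, "major_peak_power"),
    major_peak_significant = attr(x, "major_peak_significant"),
    threshold = attr(x, "threshold"),
    n_significant = sum(x$significant),
    n_frequencies = nrow(x)
  )
}
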