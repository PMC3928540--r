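#' Parametric contrast sensitivity function
#'
#' A band-pass sensitivity curve over spatial frequency,
#' \deqn{S(f) = k \, (f/f_p)^a \exp\{(a/r)\,(1 - (f/f_p)^r)\},}
#' which peaks at `peak_frequency_cdeg` with value `peak_sensitivity`. The
#' exponent `a` sets the low-frequency attenuation (power-law rise towards
#' the peak, so S(0) = 0 for a > 0) and `r` the steepness of the exponential
#' high-frequency roll-off. Defaults approximate adult foveal sensitivity:
#' peak near 4 c/deg with S(30)/S(peak) about 0.01.
#'
#' @param peak_sensitivity sensitivity at the peak (arbitrary units; the
#'   filter is renormalized to unit peak gain before use).
#' @param peak_frequency_cdeg peak spatial frequency, cycles/degree.
#' @param low_frequency_attenuation power-law exponent below the peak (> 0
#'   gives a band-pass curve; 0 degenerates to a flat curve).
#' @param high_frequency_rolloff roll-off shape exponent (> 0).
#' @return An object of class `csf_spec`.
#' @export
#' @examples
#' csf <- default_csf()
#' csf_sensitivity(csf, c(0, 4, 30))
csf_spec <- function(peak_sensitivity = 200, peak_frequency_cdeg = 4,
                     low_frequency_attenuation = 1,
                     high_frequency_rolloff = 1) {
  p <- c(peak_sensitivity, peak_frequency_cdeg, low_frequency_attenuation,
         high_frequency_rolloff)
  if (any(!is.finite(p)) || any(p < 0) || peak_frequency_cdeg <= 0 ||
      peak_sensitivity <= 0 || high_frequency_rolloff <= 0)
    stop("CSF parameters must be non-negative (peak values strictly positive)")
  structure(list(peak_sensitivity = peak_sensitivity,
                 peak_frequency_cdeg = peak_frequency_cdeg,
                 low_frequency_attenuation = low_frequency_attenuation,
                 high_frequency_rolloff = high_frequency_rolloff),
            class = "csf_spec")
}

#' @rdname csf_spec
#' @param ... passed to [csf_spec()].
#' @export
default_csf <- function(...) csf_spec(...)

#' Evaluate a CSF at given spatial frequencies
#'
#' @param csf a [csf_spec()].
#' @param f spatial frequencies, cycles/degree (f >= 0).
#' @return Sensitivities S(f) (>= 0, -> 0 as f -> Inf for a band-pass curve).
#' @export
csf_sensitivity <- function(csf, f) {
  stopifnot(inherits(csf, "csf_spec"), all(f >= 0))
  a <- csf$low_frequency_attenuation
  r <- csf$high_frequency_rolloff
  fp <- csf$peak_frequency_cdeg
  x <- f / fp
  # a = 0 collapses the curve to a flat (all-pass) sensitivity, which is
  # useful as a degenerate control: filtering then becomes the identity.
  ifelse(f == 0 & a > 0, 0,
         csf$peak_sensitivity * x^a * exp((a / r) * (1 - x^r)))
}

# Unit-peak gain of the CSF on the FFT frequency grid of an N x N image.
csf_gain_grid <- function(csf, N, display) {
  p_deg <- pixels_to_degrees(1, display)
  k <- 0:(N - 1)
  s <- ifelse(k <= N / 2, k, N - k) / N        # cycles per pixel
  fr <- sqrt(outer(s^2, s^2, "+")) / p_deg     # cycles per degree
  peak <- csf_sensitivity(csf, csf$peak_frequency_cdeg)
  matrix(csf_sensitivity(csf, as.vector(fr)) / peak, N, N)
}

#' Filter an image through a contrast sensitivity function
#'
#' Multiplies the 2-D Fourier amplitude at radial frequency f (c/deg,
#' derived from the display's pixel pitch) by S(f)/max S, then inverse
#' transforms and returns the real part. The filter is linear and
#' shift-covariant and never amplifies (unit peak gain).
#'
#' @param image a [contrast_image()] or square numeric matrix.
#' @param csf a [csf_spec()]; a flat CSF gives the identity.
#' @param display a [display_spec()].
#' @return A [contrast_image()] with the same inducer mask as the input.
#' @export
csf_filter <- function(image, csf, display = default_display()) {
  v <- image_values(image)
  if (nrow(v) != ncol(v)) stop("csf_filter requires a square image")
  gain <- csf_gain_grid(csf, nrow(v), display)
  out <- Re(fft(fft(v) * gain, inverse = TRUE)) / length(v)
  contrast_image(out, image_mask(image))
}

#' @export
print.csf_spec <- function(x, ...) {
  cat(sprintf("<csf_spec> peak %.3g at %.3g c/deg, low-f exponent %.3g, roll-off %.3g\n",
              x$peak_sensitivity, x$peak_frequency_cdeg,
              x$low_frequency_attenuation, x$high_frequency_rolloff))
  invisible(x)
}
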