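#' Parametric dot-and-inducer stimulus specification
#'
#' Describes an Ebbinghaus-Titchener figure: a central dot inside a square
#' analysis window, surrounded by equally spaced noise-free inducer disks.
#' The two canonical conditions are `"small_inducers"` (12 disks of 15 px
#' diameter, ring radius 45 px) and `"large_inducers"` (5 disks of 55 px
#' diameter, ring radius 60 px); `"none"` renders the isolated dot.
#'
#' @param condition `"small_inducers"`, `"large_inducers"`, or `"none"`.
#' @param central_diameter_px diameter of the central dot, px.
#' @param inducer_diameter_px diameter of each inducer disk, px.
#' @param n_inducers number of inducer disks.
#' @param center_to_center_px radius of the inducer ring (dot midpoint to
#'   inducer midpoint), px.
#' @param window_px side of the square analysis window, px.
#' @param target_contrast Weber contrast of the central dot (non-positive).
#' @return An object of class `stimulus_spec`.
#' @export
#' @examples
#' stimulus_spec("small_inducers")
#' stimulus_spec("large_inducers")
stimulus_spec <- function(condition = c("small_inducers", "large_inducers",
                                        "none"),
                          central_diameter_px = 45,
                          inducer_diameter_px = NULL,
                          n_inducers = NULL,
                          center_to_center_px = NULL,
                          window_px = 200,
                          target_contrast = -0.87) {
  condition <- match.arg(condition)
  defaults <- switch(condition,
    small_inducers = list(d = 15, n = 12, r = 45),
    large_inducers = list(d = 55, n = 5, r = 60),
    none = list(d = 0, n = 0, r = 0))
  if (is.null(inducer_diameter_px)) inducer_diameter_px <- defaults$d
  if (is.null(n_inducers)) n_inducers <- defaults$n
  if (is.null(center_to_center_px)) center_to_center_px <- defaults$r
  if (condition == "none" && n_inducers != 0)
    stop("condition 'none' implies n_inducers = 0")
  if (window_px < 2 || central_diameter_px <= 0)
    stop("window and central dot must have positive extent")
  if (target_contrast > 0)
    stop("target_contrast must be non-positive (dark target)")
  if (n_inducers > 0 &&
      center_to_center_px + inducer_diameter_px / 2 > window_px / 2)
    stop("inducer disks would overlap the analysis-window border")
  structure(list(condition = condition,
                 central_diameter_px = central_diameter_px,
                 inducer_diameter_px = inducer_diameter_px,
                 n_inducers = n_inducers,
                 center_to_center_px = center_to_center_px,
                 window_px = window_px,
                 target_contrast = target_contrast),
            class = "stimulus_spec")
}

#' Contrast image container
#'
#' A square grid of Weber contrasts (`(L_pixel - L_bg)/L_bg`) plus a logical
#' mask marking the noise-free inducer pixels. The coordinate convention is
#' 0-based with the window center at `((N-1)/2, (N-1)/2)`.
#'
#' @param values numeric matrix of pixel contrasts.
#' @param inducer_mask logical matrix of the same shape (TRUE on inducer
#'   pixels); defaults to all-FALSE.
#' @return An object of class `contrast_image`.
#' @export
contrast_image <- function(values, inducer_mask = NULL) {
  values <- as.matrix(values)
  if (is.null(inducer_mask))
    inducer_mask <- matrix(FALSE, nrow(values), ncol(values))
  if (!all(dim(values) == dim(inducer_mask)))
    stop("values and inducer_mask must have identical dimensions")
  structure(list(values = values, inducer_mask = inducer_mask,
                 origin = "center"),
            class = "contrast_image")
}

image_values <- function(x) {
  if (inherits(x, "contrast_image") || inherits(x, "noise_field")) x$values
  else as.matrix(x)
}

image_mask <- function(x) {
  if (inherits(x, "contrast_image") || inherits(x, "noise_field"))
    x$inducer_mask
  else matrix(FALSE, nrow(as.matrix(x)), ncol(as.matrix(x)))
}

# Geometry shared by rendering, radial binning and the observers: disk
# masks, the integer radial bin of every pixel (0 = excluded: the center
# pixel area, radii beyond the profile, and inducer pixels), and per-bin
# pixel counts. 0-based coordinates, center at (N-1)/2.
window_geometry <- function(spec, display = default_display()) {
  N <- spec$window_px
  cx <- (N - 1) / 2
  off <- (0:(N - 1)) - cx
  dx <- matrix(off, N, N, byrow = TRUE)  # column offsets
  dy <- matrix(off, N, N)                # row offsets
  r <- sqrt(dx^2 + dy^2)
  dot_mask <- r <= spec$central_diameter_px / 2
  inducer_mask <- matrix(FALSE, N, N)
  if (spec$n_inducers > 0) {
    for (k in seq_len(spec$n_inducers) - 1) {
      theta <- pi / 2 + 2 * pi * k / spec$n_inducers  # first inducer on top
      icx <- cx + spec$center_to_center_px * cos(theta)
      icy <- cx - spec$center_to_center_px * sin(theta)
      dk <- sqrt((dx + cx - icx)^2 + (dy + cx - icy)^2)
      inducer_mask <- inducer_mask | dk <= spec$inducer_diameter_px / 2
    }
  }
  nbins <- as.integer(N / 2 - 1)
  bin_idx <- as.integer(round(r))
  bin_idx[bin_idx < 1L | bin_idx > nbins] <- 0L
  bin_idx[inducer_mask] <- 0L
  list(N = N, r = r, dot_mask = dot_mask, inducer_mask = inducer_mask,
       nbins = nbins, bin_idx = bin_idx,
       bin_counts = tabulate(bin_idx[bin_idx > 0L], nbins),
       dot_idx = which(dot_mask & !inducer_mask),
       n_dot = sum(dot_mask & !inducer_mask))
}

#' Render a stimulus specification as a contrast image
#'
#' The central disk is drawn at `spec$target_contrast` when `present` is
#' TRUE; inducer disks are always drawn at the display's maximum negative
#' contrast. A pixel belongs to a disk iff its center lies within the disk
#' radius (no anti-aliasing), so rendering is deterministic and energy
#' bookkeeping exact.
#'
#' @param spec a [stimulus_spec()].
#' @param display a [display_spec()].
#' @param present logical; draw the central dot?
#' @return A [contrast_image()] with its inducer mask populated.
#' @export
render_stimulus <- function(spec, display = default_display(),
                            present = TRUE) {
  geom <- window_geometry(spec, display)
  v <- matrix(0, geom$N, geom$N)
  if (spec$n_inducers > 0) v[geom$inducer_mask] <- display$max_neg_contrast
  if (present) v[geom$dot_mask & !geom$inducer_mask] <- spec$target_contrast
  contrast_image(v, geom$inducer_mask)
}

#' Contrast energy of an image
#'
#' The sum of squared pixel contrasts multiplied by the area of one pixel in
#' squared degrees. This is the stimulus intensity controlled by the
#' staircase.
#'
#' @param image a [contrast_image()] or plain numeric matrix.
#' @param display a [display_spec()].
#' @return Energy in deg^2 (non-negative, additive over disjoint pixel sets).
#' @export
contrast_energy <- function(image, display = default_display()) {
  v <- image_values(image)
  if (any(!is.finite(v))) stop("image contains non-finite contrasts")
  sum(v^2) * pixel_area_deg2(display)
}

#' Rescale the non-inducer region of an image to a target contrast energy
#'
#' Multiplies every non-inducer pixel by a single factor so the contrast
#' energy of that region equals `target_energy`; inducer pixels are left
#' untouched.
#'
#' @param image a [contrast_image()].
#' @param target_energy desired energy of the non-inducer region, deg^2.
#' @param display a [display_spec()].
#' @return The rescaled [contrast_image()].
#' @export
scale_to_energy <- function(image, target_energy,
                            display = default_display()) {
  stopifnot(target_energy >= 0)
  v <- image_values(image)
  m <- image_mask(image)
  e <- sum(v[!m]^2) * pixel_area_deg2(display)
  if (e <= 0) stop("image has zero energy in its scalable region")
  v[!m] <- v[!m] * sqrt(target_energy / e)
  contrast_image(v, m)
}

#' Sample a truncated Gaussian white-noise field
#'
#' Draws i.i.d. zero-mean Gaussian contrast deviates of variance `sigma2`;
#' samples exceeding `truncation_sd` standard deviations in magnitude are
#' discarded and replaced with fresh samples. Pixels under `inducer_mask`
#' are forced to zero (the inducers are always noise-free).
#'
#' @param sigma2 nominal noise variance (the experiments use 0.16). The
#'   truncation reduces the realised variance to about 0.774 * sigma2.
#' @param window_px side of the square field.
#' @param inducer_mask optional logical matrix of masked pixels.
#' @param seed optional integer; when given, the field is drawn under this
#'   seed without disturbing the caller's RNG stream.
#' @param truncation_sd rejection bound in standard deviations (default 2).
#' @return An object of class `noise_field` (fields `values`, `sigma2`,
#'   `truncation_sd`, `inducer_mask`).
#' @export
sample_noise_field <- function(sigma2, window_px, inducer_mask = NULL,
                               seed = NULL, truncation_sd = 2) {
  stopifnot(sigma2 >= 0, window_px >= 1)
  n <- as.integer(window_px)^2
  draw <- function() rtnorm_vec(n, sqrt(sigma2), truncation_sd)
  v <- if (is.null(seed)) draw() else local_seed(seed, draw())
  v <- matrix(v, window_px, window_px)
  if (is.null(inducer_mask))
    inducer_mask <- matrix(FALSE, window_px, window_px)
  v[inducer_mask] <- 0
  structure(list(values = v, sigma2 = sigma2, truncation_sd = truncation_sd,
                 inducer_mask = inducer_mask),
            class = "noise_field")
}

#' Add a noise field to a stimulus image
#'
#' Pixel-wise sum outside the inducer mask; inducer pixels keep the stimulus
#' value exactly (they are rendered noise-free).
#'
#' @param stimulus a [contrast_image()].
#' @param noise a `noise_field` (or matching `contrast_image`).
#' @return The composed [contrast_image()].
#' @export
compose_trial_image <- function(stimulus, noise) {
  sv <- image_values(stimulus)
  nv <- image_values(noise)
  if (!all(dim(sv) == dim(nv)))
    stop("stimulus and noise dimensions do not match")
  m <- image_mask(stimulus)
  out <- sv + nv
  out[m] <- sv[m]
  contrast_image(out, m)
}

#' @export
print.display_spec <- function(x, ...) {
  cat(sprintf("<display_spec> %d x %d px, %.2f cm wide at %.0f cm (%.5f deg/px)\n",
              x$width_px, x$height_px, x$width_cm, x$viewing_distance_cm,
              pixels_to_degrees(1, x)))
  invisible(x)
}

#' @export
print.stimulus_spec <- function(x, ...) {
  cat(sprintf("<stimulus_spec> %s: %d px dot, %d inducers (%d px) at ring %d px, window %d px\n",
              x$condition, x$central_diameter_px, x$n_inducers,
              x$inducer_diameter_px, x$center_to_center_px, x$window_px))
  invisible(x)
}

#' @export
print.contrast_image <- function(x, ...) {
  cat(sprintf("<contrast_image> %d x %d px, %d inducer px, contrast range [%.3f, %.3f]\n",
              nrow(x$values), ncol(x$values), sum(x$inducer_mask),
              min(x$values), max(x$values)))
  invisible(x)
}
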