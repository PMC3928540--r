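#' Simulated observers for the yes/no detection task
#'
#' Constructors for the decision models that can drive [run_staircase()]:
#'
#' * `ideal_observer()` - the maximum-posterior (equal-prior) likelihood
#'   decision in white Gaussian noise: respond *present* iff
#'   \eqn{\Lambda = (\langle x, s\rangle - \|s\|^2/2)/\sigma^2 > 0}, with the
#'   template s restricted to non-inducer pixels (the inducers are identical
#'   under both hypotheses and cancel).
#' * `csf_ideal_observer()` - ideal in all respects except that the
#'   noise-free signal (with inducers) and the noise-free template (without
#'   inducers) are first filtered by a contrast sensitivity function in the
#'   frequency domain; unfiltered noise is then added and the filtered
#'   template is used to compute the likelihoods.
#' * `template_observer()` - a linear template matcher with additive
#'   internal Gaussian noise and a response criterion; the configurable
#'   stand-in for human-like data.
#' * `oracle_observer()`, `random_observer()` - degenerate deciders (always
#'   correct / label-independent coin flip) used for calibration.
#'
#' @param csf a [csf_spec()].
#' @param template numeric matrix (window-sized linear template, normalized
#'   internally to unit norm over non-inducer pixels), or NULL for the
#'   default center-surround template of [center_surround_template()].
#' @param internal_sigma2 variance of the additive internal decision noise;
#'   NULL selects (sd of the external decision variable / 2)^2.
#' @param criterion decision criterion: the string `"midpoint"` (half the
#'   expected signal response, an unbiased criterion that tracks the
#'   staircase level) or a fixed number.
#' @param p_present probability that `random_observer()` responds "present".
#' @return An object of class `observer_model`.
#' @name observers
NULL

#' @rdname observers
#' @export
ideal_observer <- function() {
  structure(list(kind = "ideal"), class = "observer_model")
}

#' @rdname observers
#' @export
csf_ideal_observer <- function(csf = default_csf()) {
  stopifnot(inherits(csf, "csf_spec"))
  structure(list(kind = "csf_ideal", csf = csf), class = "observer_model")
}

#' @rdname observers
#' @export
template_observer <- function(template = NULL, internal_sigma2 = NULL,
                              criterion = "midpoint") {
  structure(list(kind = "template", template = template,
                 internal_sigma2 = internal_sigma2, criterion = criterion),
            class = "observer_model")
}

#' @rdname observers
#' @export
oracle_observer <- function() {
  structure(list(kind = "oracle"), class = "observer_model")
}

#' @rdname observers
#' @export
random_observer <- function(p_present = 0.5) {
  stopifnot(p_present >= 0, p_present <= 1)
  structure(list(kind = "random", p_present = p_present),
            class = "observer_model")
}

#' @export
print.observer_model <- function(x, ...) {
  cat(sprintf("<observer_model> kind = %s\n", x$kind))
  invisible(x)
}

#' Center-surround linear template
#'
#' A radially symmetric template with a (negative) central disk matched to
#' the target dot and an opposite-sign surrounding annulus, normalized to
#' unit norm over non-inducer pixels. This mimics the strategy reverse
#' correlation typically recovers from human observers in this task.
#'
#' @param spec a [stimulus_spec()] (fixes window, dot size and inducer mask).
#' @param display a [display_spec()].
#' @param center_gain weight inside the dot (negative for a dark target).
#' @param surround_gain weight in the annulus.
#' @param surround_outer_px outer radius of the annulus, px.
#' @return A unit-norm numeric matrix, zero on inducer pixels.
#' @export
center_surround_template <- function(spec, display = default_display(),
                                     center_gain = -1, surround_gain = 0.5,
                                     surround_outer_px = 35) {
  geom <- window_geometry(spec, display)
  tm <- matrix(0, geom$N, geom$N)
  tm[geom$r <= spec$central_diameter_px / 2] <- center_gain
  ann <- geom$r > spec$central_diameter_px / 2 & geom$r <= surround_outer_px
  tm[ann] <- surround_gain
  tm[geom$inducer_mask] <- 0
  tm / sqrt(sum(tm^2))
}

#' Ideal yes/no decision for a known additive signal in white noise
#'
#' Computes the log-likelihood ratio
#' \eqn{\Lambda = (\langle x, s\rangle - \|s\|^2/2)/\sigma^2} over
#' non-inducer pixels and responds "present" iff \eqn{\Lambda > 0} (ties go
#' to "absent"). \eqn{\Lambda} equals the difference of the two Gaussian
#' log-densities exactly.
#'
#' @param observation observed [contrast_image()] (or matrix).
#' @param signal_template noise-free signal [contrast_image()] (or matrix);
#'   its inducer mask, if any, marks pixels excluded from the likelihood.
#' @param sigma2 noise variance (> 0).
#' @return `"present"` or `"absent"`, with the log-likelihood ratio attached
#'   as attribute `"lambda"`.
#' @export
ideal_decide <- function(observation, signal_template, sigma2) {
  if (sigma2 <= 0) stop("sigma2 must be positive")
  x <- image_values(observation)
  s <- image_values(signal_template)
  if (!all(dim(x) == dim(s))) stop("observation/template shape mismatch")
  keep <- !(image_mask(observation) | image_mask(signal_template))
  lambda <- (sum(x[keep] * s[keep]) - sum(s[keep]^2) / 2) / sigma2
  structure(if (lambda > 0) "present" else "absent", lambda = lambda)
}

#' CSF-limited ideal decision
#'
#' Decides like [ideal_decide()] but with the CSF-filtered dot template
#' (computed without inducers); the known CSF-filtered inducer background is
#' subtracted from the observation first, since it is identical under both
#' hypotheses and carries no information.
#'
#' @param observation observed [contrast_image()], constructed as
#'   CSF-filtered noise-free stimulus (with inducers) plus raw noise.
#' @param spec a [stimulus_spec()] naming the condition; its
#'   `target_contrast` sets the dot contrast of the template.
#' @param csf a [csf_spec()].
#' @param display a [display_spec()].
#' @param sigma2 noise variance (> 0).
#' @return `"present"` or `"absent"` with attribute `"lambda"`.
#' @export
csf_ideal_decide <- function(observation, spec, csf,
                             display = default_display(), sigma2) {
  if (!inherits(spec, "stimulus_spec"))
    stop("no stimulus_spec supplied: cannot build condition templates")
  dot_spec <- spec
  dot_spec$condition <- "none"
  dot_spec$n_inducers <- 0
  tmpl <- csf_filter(render_stimulus(dot_spec, display, present = TRUE),
                     csf, display)
  bg_spec <- spec
  bg <- csf_filter(render_stimulus(bg_spec, display, present = FALSE),
                   csf, display)
  x <- image_values(observation)
  mask <- image_mask(observation) | window_geometry(spec, display)$inducer_mask
  xr <- x - image_values(bg)
  keep <- !mask
  s <- image_values(tmpl)
  lambda <- (sum(xr[keep] * s[keep]) - sum(s[keep]^2) / 2) / sigma2
  structure(if (lambda > 0) "present" else "absent", lambda = lambda)
}

#' Linear-template decision with internal noise
#'
#' Responds "present" iff `<x, template> + eps > criterion`, with
#' `eps ~ N(0, internal_sigma2)` drawn from the current RNG stream.
#'
#' @param observation observed [contrast_image()] (or matrix).
#' @param template unit-norm template matrix.
#' @param internal_sigma2 internal noise variance (>= 0).
#' @param criterion numeric decision criterion.
#' @return `"present"` or `"absent"` with attribute `"decision_variable"`.
#' @export
template_observer_decide <- function(observation, template,
                                     internal_sigma2 = 0, criterion = 0) {
  stopifnot(internal_sigma2 >= 0)
  x <- image_values(observation)
  tm <- image_values(template)
  if (!all(dim(x) == dim(tm))) stop("observation/template shape mismatch")
  d <- sum(x * tm) +
    if (internal_sigma2 > 0) rnorm(1, 0, sqrt(internal_sigma2)) else 0
  structure(if (d > criterion) "present" else "absent",
            decision_variable = d)
}

# ---- internal: fast per-trial deciders used by run_staircase ------------
#
# prepare_observer() precomputes everything that does not change across
# trials and returns decide(field, k, present): `field` is the masked noise
# field as a plain vector, `k` the dot contrast magnitude at the current
# staircase level (dot contrast = -k), `present` the trial's truth. The
# returned value is TRUE for a "present" response. Internal randomness
# (template observer's internal noise, random observer) is drawn from the
# main trial RNG stream, so runs are reproducible from (seed, config).
prepare_observer <- function(observer, spec, display, sigma2, geom) {
  stopifnot(inherits(observer, "observer_model"))
  if (sigma2 <= 0 && observer$kind %in% c("ideal", "csf_ideal"))
    stop("sigma2 must be positive for likelihood observers")
  switch(observer$kind,
    ideal = {
      nd <- geom$n_dot
      dot_idx <- geom$dot_idx
      function(field, k, present) {
        ip <- -k * sum(field[dot_idx]) + (if (present) k^2 * nd else 0)
        (ip - k^2 * nd / 2) / sigma2 > 0
      }
    },
    csf_ideal = {
      dot_spec <- spec
      dot_spec$condition <- "none"
      dot_spec$n_inducers <- 0
      dot_spec$target_contrast <- -1       # unit-contrast dot shape
      fd <- image_values(csf_filter(
        render_stimulus(dot_spec, display, present = TRUE), observer$csf,
        display))
      fd[geom$inducer_mask] <- 0           # likelihood over non-inducer px
      fd <- as.vector(fd)
      fd2 <- sum(fd^2)
      function(field, k, present) {
        ip <- k * sum(field * fd) + (if (present) k^2 * fd2 else 0)
        (ip - k^2 * fd2 / 2) / sigma2 > 0
      }
    },
    template = {
      tm <- observer$template
      if (is.null(tm)) tm <- center_surround_template(spec, display)
      tm <- image_values(tm)
      tm[geom$inducer_mask] <- 0
      tm <- as.vector(tm / sqrt(sum(tm^2)))
      dot_shape <- rep(0, geom$N^2)
      dot_shape[geom$dot_idx] <- -1        # unit-contrast dark dot
      tu <- sum(dot_shape * tm)
      sig2_int <- observer$internal_sigma2
      if (is.null(sig2_int)) {
        v_ext <- trunc_var_factor(2) * sigma2  # external decision variance
        sig2_int <- v_ext / 4
      }
      crit_fun <- if (identical(observer$criterion, "midpoint"))
        function(k) k * tu / 2 else function(k) observer$criterion
      function(field, k, present) {
        d <- sum(field * tm) + (if (present) k * tu else 0) +
          (if (sig2_int > 0) rnorm(1, 0, sqrt(sig2_int)) else 0)
        d > crit_fun(k)
      }
    },
    oracle = function(field, k, present) present,
    random = function(field, k, present) runif(1) < observer$p_present,
    stop("unknown observer kind: ", observer$kind)
  )
}

#' Variance retention factor of +/- c SD truncation
#'
#' The variance of a zero-mean Gaussian conditioned on |x| <= c standard
#' deviations, relative to the untruncated variance:
#' `1 - 2 c phi(c) / (2 Phi(c) - 1)`; about 0.774 at c = 2.
#'
#' @param c truncation bound in standard deviations.
#' @return The variance ratio in (0, 1).
#' @export
trunc_var_factor <- function(c = 2) {
  1 - 2 * c * stats::dnorm(c) / (2 * stats::pnorm(c) - 1)
}
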