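#' Fit a Weibull psychometric function to staircase data
#'
#' Maximum-likelihood fit of
#' \deqn{P(correct \mid E) = \gamma + (1-\gamma-\lambda)
#'   \left(1 - e^{-(E/\alpha)^\beta}\right)}
#' over contrast energy E, with the guess rate fixed at `gamma = 0.5`
#' (equal-prior yes/no chance) and the lapse rate fixed at `lambda = 0.01`.
#' Trials are pooled at their exact visited staircase levels.
#'
#' @param x a `detection_run` or a data frame with columns `energy` and
#'   `correct`.
#' @param gamma fixed guess rate.
#' @param lambda fixed lapse rate.
#' @return An object of class `psychometric_fit` with elements `alpha`,
#'   `beta`, `gamma`, `lambda`, `loglik`, `n_trials`, `levels`.
#' @export
fit_weibull <- function(x, gamma = 0.5, lambda = 0.01) {
  df <- if (inherits(x, "detection_run")) x$trials else x
  stopifnot(all(c("energy", "correct") %in% names(df)),
            gamma >= 0, lambda >= 0, gamma < 1 - lambda)
  if (any(df$energy <= 0)) stop("energies must be positive")
  agg <- stats::aggregate(cbind(k = df$correct, n = 1) ~ energy, data = df,
                          FUN = sum)
  agg <- agg[order(agg$energy), ]
  if (nrow(agg) < 2)
    stop("need at least 2 distinct staircase levels to fit")
  if (all(df$correct) || !any(df$correct))
    stop("degenerate data (all responses equally correct/incorrect): ",
         "Weibull fit cannot converge")
  fit <- weibull_mle(agg$energy, agg$k, agg$n, gamma, lambda)
  structure(list(alpha = fit$alpha, beta = fit$beta, gamma = gamma,
                 lambda = lambda, loglik = fit$loglik,
                 n_trials = sum(agg$n), levels = agg),
            class = "psychometric_fit")
}

# MLE over (log alpha, log beta) on aggregated (level, k correct of n).
weibull_mle <- function(energy, k, n, gamma, lambda) {
  nll <- function(par) {
    alpha <- exp(par[1]); beta <- exp(par[2])
    p <- gamma + (1 - gamma - lambda) * (1 - exp(-(energy / alpha)^beta))
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -sum(k * log(p) + (n - k) * log(1 - p))
  }
  start <- c(log(stats::weighted.mean(energy, n)), log(1.5))
  opt <- optim(start, nll, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-10))
  if (opt$convergence != 0)
    stop("Weibull fit did not converge (optim code ", opt$convergence,
         ", message: ", if (nzchar(opt$message %||% "")) opt$message else
           "none", ")")
  list(alpha = exp(opt$par[1]), beta = exp(opt$par[2]),
       loglik = -opt$value)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Predicted proportion correct of a Weibull fit
#'
#' @param fit a `psychometric_fit`.
#' @param energy contrast energies, deg^2.
#' @return Predicted proportions correct.
#' @export
predict_weibull <- function(fit, energy) {
  with(fit, gamma + (1 - gamma - lambda) *
         (1 - exp(-(energy / alpha)^beta)))
}

#' Interpolate the contrast energy at a criterion level of performance
#'
#' Closed-form inversion of the fitted Weibull:
#' `E = alpha * (-log((1 - lambda - criterion)/(1 - gamma - lambda)))^(1/beta)`.
#'
#' @param fit a `psychometric_fit`.
#' @param criterion proportion correct, strictly between `gamma` and
#'   `1 - lambda` (default 0.71).
#' @return Threshold energy in deg^2.
#' @export
threshold_at <- function(fit, criterion = 0.71) {
  if (criterion <= fit$gamma || criterion >= 1 - fit$lambda)
    stop("criterion must lie strictly between gamma and 1 - lambda")
  fit$alpha * (-log((1 - fit$lambda - criterion) /
                      (1 - fit$gamma - fit$lambda)))^(1 / fit$beta)
}

#' Bootstrap the threshold of a staircase run
#'
#' Resamples trials with replacement, refits the Weibull and re-interpolates
#' the criterion energy per replicate; the threshold standard deviation is
#' taken over replicates (error bars are conventionally reported as +/- 2
#' SD). Errors if more than 20% of replicates fail to converge.
#'
#' @param x a `detection_run` or data frame (see [fit_weibull()]).
#' @param criterion proportion correct defining the threshold.
#' @param n_boot number of bootstrap replicates (default 500).
#' @param seed RNG seed for resampling.
#' @param gamma,lambda fixed Weibull rates.
#' @return An object of class `threshold_estimate`: `threshold` (full-data
#'   fit), `sd`, `n_boot`, `criterion`, `boot` (replicate thresholds).
#' @export
bootstrap_threshold <- function(x, criterion = 0.71, n_boot = 500, seed = 1,
                                gamma = 0.5, lambda = 0.01) {
  df <- if (inherits(x, "detection_run")) x$trials else x
  fit <- fit_weibull(df, gamma, lambda)
  thr <- threshold_at(fit, criterion)
  boot <- local_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(nrow(df), replace = TRUE)
      tryCatch(threshold_at(fit_weibull(df[idx, , drop = FALSE],
                                        gamma, lambda), criterion),
               error = function(e) NA_real_)
    }, numeric(1))
  })
  fail <- mean(is.na(boot))
  if (fail > 0.2)
    stop(sprintf("%.0f%% of bootstrap replicates failed to converge",
                 100 * fail))
  structure(list(threshold = thr,
                 sd = if (n_boot > 1) sd(boot, na.rm = TRUE) else 0,
                 n_boot = n_boot, criterion = criterion,
                 fit = fit, boot = boot),
            class = "threshold_estimate")
}

#' Monte Carlo ideal-observer threshold
#'
#' Runs the full pipeline for the ideal observer: a 2-down/1-up staircase of
#' `n_trials` trials, a Weibull fit, criterion interpolation and a bootstrap
#' standard deviation. The staircase run is attached as attribute `"run"`
#' for reuse by the classification pipeline.
#'
#' @param spec a [stimulus_spec()].
#' @param display a [display_spec()].
#' @param sigma2 nominal noise variance.
#' @param n_trials trials to simulate (the reference experiments use 10000).
#' @param seed RNG seed.
#' @param n_boot bootstrap replicates.
#' @param criterion proportion correct defining the threshold.
#' @return A `threshold_estimate`.
#' @export
ideal_threshold_mc <- function(spec, display = default_display(),
                               sigma2 = 0.16, n_trials = 10000, seed = 1,
                               n_boot = 500, criterion = 0.71) {
  run <- run_staircase(ideal_observer(), spec, display, n_trials,
                       sigma2 = sigma2, seed = seed)
  est <- bootstrap_threshold(run, criterion, n_boot, seed = seed + 1L)
  attr(est, "run") <- run
  est
}

#' Efficiency: ratio of ideal to observer threshold
#'
#' @param ideal ideal-observer `threshold_estimate` (or number, deg^2).
#' @param observer observer `threshold_estimate` (or number, deg^2).
#' @return The efficiency, in (0, 1\] for any non-super-ideal observer up to
#'   sampling error.
#' @export
efficiency <- function(ideal, observer) {
  ti <- if (inherits(ideal, "threshold_estimate")) ideal$threshold else ideal
  to <- if (inherits(observer, "threshold_estimate")) observer$threshold
        else observer
  if (!is.finite(ti) || !is.finite(to) || ti <= 0 || to <= 0)
    stop("thresholds must be positive and finite")
  ti / to
}

#' @export
print.psychometric_fit <- function(x, ...) {
  cat(sprintf("<psychometric_fit> alpha = %.3g deg^2, beta = %.3g (gamma = %.2f, lambda = %.2f), logLik = %.2f\n",
              x$alpha, x$beta, x$gamma, x$lambda, x$loglik))
  invisible(x)
}

#' @export
print.threshold_estimate <- function(x, ...) {
  cat(sprintf("<threshold_estimate> %.3g deg^2 at %.0f%% correct (bootstrap sd %.2g, n_boot = %d)\n",
              x$threshold, 100 * x$criterion, x$sd, x$n_boot))
  invisible(x)
}
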