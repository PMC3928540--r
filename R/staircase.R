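#' 2-down/1-up staircase state
#'
#' Multiplicative staircase over contrast energy: after two consecutive
#' correct responses the level moves one step down, after every error one
#' step up. The step is `10^(step_db/10)` on energy (1 dB by default); the
#' convergence point (about 70.7% correct, the square root of one half) is
#' independent of the step size. Levels are tracked as an integer step
#' index, so every visited level is an exact multiple of the start level.
#'
#' @param start_level starting contrast energy, deg^2.
#' @param step_db step size in decibels of energy.
#' @param floor,ceiling clamps on the level, deg^2.
#' @return An object of class `staircase_state`.
#' @export
staircase_state <- function(start_level, step_db = 1,
                            floor = start_level * 1e-6,
                            ceiling = start_level * 1e4) {
  stopifnot(start_level > 0, step_db > 0, floor > 0, ceiling >= start_level)
  step <- 10^(step_db / 10)
  structure(list(start_level = start_level, step = step,
                 k = 0L,
                 k_min = as.integer(base::ceiling(log(floor / start_level) /
                                                    log(step))),
                 k_max = as.integer(base::floor(log(ceiling / start_level) /
                                                  log(step))),
                 consecutive_correct = 0L),
            class = "staircase_state")
}

staircase_level <- function(st) st$start_level * st$step^st$k

update_staircase <- function(st, correct) {
  if (correct) {
    st$consecutive_correct <- st$consecutive_correct + 1L
    if (st$consecutive_correct >= 2L) {
      st$k <- max(st$k - 1L, st$k_min)
      st$consecutive_correct <- 0L
    }
  } else {
    st$k <- min(st$k + 1L, st$k_max)
    st$consecutive_correct <- 0L
  }
  st
}

#' Analytic ideal-observer contrast-energy threshold
#'
#' Closed-form pilot value used to place the staircase start: the
#' equal-prior ideal yes/no observer has proportion correct
#' `Phi(d'/2)` with `d'^2 = E / (a * sigma2_eff)`, where `a` is the pixel
#' area and `sigma2_eff` the realised (truncated) noise variance. Inverting
#' at `criterion` gives the energy.
#'
#' @param display a [display_spec()].
#' @param sigma2 nominal noise variance.
#' @param criterion target proportion correct (default 0.71).
#' @param truncation_sd noise truncation bound in SD.
#' @return Contrast energy in deg^2.
#' @export
pilot_ideal_energy <- function(display = default_display(), sigma2 = 0.16,
                               criterion = 0.71, truncation_sd = 2) {
  dprime <- 2 * qnorm(criterion)
  dprime^2 * sigma2 * trunc_var_factor(truncation_sd) *
    pixel_area_deg2(display)
}

#' Run a staircase-controlled detection experiment
#'
#' Simulates `n_trials` yes/no trials: the target dot is present on a random
#' half of trials; the central-dot contrast is scaled so that its energy
#' equals the current 2-down/1-up staircase level; a fresh truncated noise
#' field is composed with the stimulus (inducer pixels stay noise-free); the
#' observer responds; the staircase updates on correctness.
#'
#' The returned `detection_run` carries, besides the trial log, everything
#' the classification pipeline needs: the per-trial radial average of the
#' raw noise field (bins 1..N/2-1 px from the window center, non-inducer
#' pixels only), the running per-pixel noise sums of the four
#' stimulus-response cells, and per-trial noise seeds from which any full
#' field can be regenerated exactly (see [get_noise_field()]).
#'
#' @param observer an [observers] model.
#' @param spec a [stimulus_spec()].
#' @param display a [display_spec()].
#' @param n_trials number of trials (>= 1).
#' @param sigma2 nominal noise variance (default 0.16).
#' @param stair a [staircase_state()]; by default starts at 20 times the
#'   analytic ideal threshold of [pilot_ideal_energy()].
#' @param seed integer seed for the trial stream (presence draws and any
#'   observer-internal noise).
#' @param noise_seed integer seed from which the per-trial noise seeds are
#'   drawn; two runs sharing `noise_seed` see identical noise deviates even
#'   if their conditions differ (paired-comparison support). Defaults to
#'   `seed`.
#' @param keep_noise logical; store the full noise fields in memory (only
#'   sensible for small runs).
#' @return An object of class `detection_run` with elements `trials` (data
#'   frame: index, condition, present, energy, response, correct,
#'   noise_ref), `radial` (n_trials x nbins matrix), `cells` (per-cell pixel
#'   sums and counts), `spec`, `display`, `sigma2`, `seeds`.
#' @export
run_staircase <- function(observer, spec, display = default_display(),
                          n_trials, sigma2 = 0.16, stair = NULL, seed = 1,
                          noise_seed = NULL, keep_noise = FALSE) {
  stopifnot(n_trials >= 1)
  if (is.null(stair))
    stair <- staircase_state(20 * pilot_ideal_energy(display, sigma2))
  if (is.null(noise_seed)) noise_seed <- seed
  geom <- window_geometry(spec, display)
  decide <- prepare_observer(observer, spec, display, sigma2, geom)
  a <- pixel_area_deg2(display)
  sdn <- sqrt(sigma2)
  npix <- geom$N^2
  ind_idx <- which(geom$inducer_mask)

  noise_seeds <- local_seed(noise_seed,
                            sample.int(2147483646L, n_trials, replace = TRUE))
  set.seed(seed)

  cells <- c("Sa_Ra", "Sa_Rp", "Sp_Ra", "Sp_Rp")
  cell_sums <- stats::setNames(
    lapply(cells, function(i) matrix(0, geom$N, geom$N)), cells)
  cell_counts <- stats::setNames(integer(4), cells)
  radial <- matrix(NA_real_, n_trials, geom$nbins)
  present <- logical(n_trials); response <- logical(n_trials)
  energy <- numeric(n_trials)
  noise_list <- if (keep_noise) vector("list", n_trials) else NULL

  for (t in seq_len(n_trials)) {
    pres <- runif(1) < 0.5
    lev <- staircase_level(stair)
    k <- sqrt(lev / (geom$n_dot * a))      # dot contrast magnitude
    field <- local_seed(noise_seeds[t], rtnorm_vec(npix, sdn, 2))
    if (length(ind_idx)) field[ind_idx] <- 0
    radial[t, ] <- bin_means_cpp(field, geom$bin_idx, geom$nbins)
    resp <- isTRUE(decide(field, k, pres))
    corr <- resp == pres
    cell <- paste0(if (pres) "Sp" else "Sa", "_", if (resp) "Rp" else "Ra")
    cell_sums[[cell]] <- cell_sums[[cell]] + matrix(field, geom$N, geom$N)
    cell_counts[cell] <- cell_counts[cell] + 1L
    present[t] <- pres; response[t] <- resp; energy[t] <- lev
    if (keep_noise) noise_list[[t]] <- matrix(field, geom$N, geom$N)
    stair <- update_staircase(stair, corr)
  }

  structure(list(
    trials = data.frame(index = seq_len(n_trials),
                        condition = spec$condition,
                        present = present, energy = energy,
                        response = ifelse(response, "present", "absent"),
                        correct = present == response,
                        noise_ref = noise_seeds,
                        stringsAsFactors = FALSE),
    radial = radial,
    cells = list(sums = cell_sums, counts = cell_counts),
    spec = spec, display = display, sigma2 = sigma2,
    observer_kind = observer$kind,
    seeds = list(seed = seed, noise_seed = noise_seed),
    noise = noise_list),
    class = "detection_run")
}

#' Regenerate (or fetch) the noise field of one trial
#'
#' Fields are reproduced exactly from the per-trial seed recorded in
#' `run$trials$noise_ref` using the same sampler as the original run, or
#' returned from memory when the run kept its fields.
#'
#' @param run a `detection_run`.
#' @param i trial index.
#' @return A `noise_field`.
#' @export
get_noise_field <- function(run, i) {
  stopifnot(inherits(run, "detection_run"),
            i >= 1, i <= nrow(run$trials))
  geom <- window_geometry(run$spec, run$display)
  if (!is.null(run$noise)) {
    v <- run$noise[[i]]
    return(structure(list(values = v, sigma2 = run$sigma2,
                          truncation_sd = 2,
                          inducer_mask = geom$inducer_mask),
                     class = "noise_field"))
  }
  ref <- run$trials$noise_ref[i]
  if (is.na(ref))
    stop("noise archive unavailable: trial ", i,
         " has no stored field and no noise seed")
  sample_noise_field(run$sigma2, geom$N, geom$inducer_mask, seed = ref)
}

#' @export
print.detection_run <- function(x, ...) {
  n <- nrow(x$trials)
  cat(sprintf("<detection_run> %s observer, %s, %d trials, %.1f%% correct\n",
              x$observer_kind, x$spec$condition, n,
              100 * mean(x$trials$correct)))
  invisible(x)
}

#' Pool trials of several runs of the same condition
#'
#' Concatenates trial logs, radial matrices and per-cell sums, so that
#' classification images of pooled data can be computed exactly as for a
#' single run (the "combined observer" pathway).
#'
#' @param ... `detection_run` objects sharing window, condition and sigma2.
#' @return A pooled `detection_run`.
#' @export
combine_runs <- function(...) {
  runs <- list(...)
  if (length(runs) == 1L && is.list(runs[[1]]) &&
      !inherits(runs[[1]], "detection_run")) runs <- runs[[1]]
  stopifnot(length(runs) >= 1, all(vapply(runs, inherits, TRUE,
                                          "detection_run")))
  r1 <- runs[[1]]
  for (r in runs[-1]) {
    if (!identical(r$spec$condition, r1$spec$condition) ||
        r$spec$window_px != r1$spec$window_px || r$sigma2 != r1$sigma2)
      stop("runs must share condition, window and sigma2 to be pooled")
  }
  out <- r1
  out$trials <- do.call(rbind, lapply(runs, `[[`, "trials"))
  out$trials$index <- seq_len(nrow(out$trials))
  out$radial <- do.call(rbind, lapply(runs, `[[`, "radial"))
  for (cell in names(out$cells$sums)) {
    out$cells$sums[[cell]] <- Reduce(`+`, lapply(runs, function(r)
      r$cells$sums[[cell]]))
    out$cells$counts[cell] <- sum(vapply(runs, function(r)
      r$cells$counts[cell], numeric(1)))
  }
  out$observer_kind <- paste(unique(vapply(runs, `[[`, "", "observer_kind")),
                             collapse = "+")
  out$noise <- NULL
  out
}
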