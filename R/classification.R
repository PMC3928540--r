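#' Classification image by stimulus-response sorting of the noise
#'
#' Averages the raw per-trial noise fields (the signal is never included)
#' within each of the four stimulus (present/absent) by response
#' (present/absent) cells and combines the cell means as
#' \deqn{C = (\bar N_{S^-R^+} + \bar N_{S^+R^+}) -
#'           (\bar N_{S^-R^-} + \bar N_{S^+R^-}),}
#' i.e. "noise that drew *present* responses minus noise that drew *absent*
#' responses", with unweighted cell means so unequal cell sizes do not bias
#' the combination.
#'
#' @param run a `detection_run` (see [run_staircase()]), possibly pooled
#'   with [combine_runs()].
#' @return An object of class `classification_image`: `weights` (window
#'   matrix), `counts` (trials per S-R cell), `inducer_mask`, `condition`,
#'   `n_trials`.
#' @export
classification_image <- function(run) {
  stopifnot(inherits(run, "detection_run"))
  counts <- run$cells$counts
  if (any(counts == 0))
    stop("empty stimulus-response cell(s): ",
         paste(names(counts)[counts == 0], collapse = ", "),
         " (need at least one trial in each of the four cells)")
  m <- lapply(names(counts), function(cell)
    run$cells$sums[[cell]] / counts[cell])
  names(m) <- names(counts)
  weights <- (m$Sa_Rp + m$Sp_Rp) - (m$Sa_Ra + m$Sp_Ra)
  geom <- window_geometry(run$spec, run$display)
  structure(list(weights = weights, counts = counts,
                 inducer_mask = geom$inducer_mask,
                 condition = run$spec$condition,
                 spec = run$spec, display = run$display,
                 sigma2 = run$sigma2,
                 n_trials = sum(counts)),
            class = "classification_image")
}

# Uniform box smoothing with renormalized partial kernels at the edges,
# via summed-area tables.
box_smooth_matrix <- function(m, k) {
  stopifnot(k %% 2 == 1, k >= 1)
  h <- (k - 1) / 2
  n <- nrow(m); p <- ncol(m)
  sat <- function(x) {
    s <- apply(x, 2, cumsum)
    t(apply(s, 1, cumsum))
  }
  S <- matrix(0, n + 1, p + 1)
  S[-1, -1] <- sat(m)
  Cn <- matrix(0, n + 1, p + 1)
  Cn[-1, -1] <- sat(matrix(1, n, p))
  i1 <- pmax(seq_len(n) - h, 1); i2 <- pmin(seq_len(n) + h, n)
  j1 <- pmax(seq_len(p) - h, 1); j2 <- pmin(seq_len(p) + h, p)
  win <- function(A) A[i2 + 1, j2 + 1, drop = FALSE] -
    A[i1, j2 + 1, drop = FALSE] - A[i2 + 1, j1, drop = FALSE] +
    A[i1, j1, drop = FALSE]
  win(S) / win(Cn)
}

#' Smooth a classification image with a uniform square kernel
#'
#' 2-D convolution with a normalized `kernel_px` x `kernel_px` uniform
#' kernel (the reference analysis uses 7 x 7 px, about 0.11 x 0.11 deg);
#' edges are handled by renormalized partial kernels, so a constant image is
#' unchanged.
#'
#' @param x a `classification_image` or numeric matrix.
#' @param kernel_px odd kernel side in pixels.
#' @return Same class as the input, smoothed.
#' @export
smooth_image <- function(x, kernel_px = 7) {
  if (inherits(x, "classification_image")) {
    x$weights <- box_smooth_matrix(x$weights, kernel_px)
    x$smoothed_px <- kernel_px
    x
  } else {
    box_smooth_matrix(as.matrix(x), kernel_px)
  }
}

#' Fill inducer regions with matched random noise for display
#'
#' Replaces the weights at inducer pixels with fresh Gaussian draws matched
#' to the mean and SD of the non-inducer weights, so that displayed
#' classification images blend into their background instead of showing
#' constant-valued inducer footprints (which could themselves induce the
#' size illusion). Analysis operations never consume in-filled images.
#'
#' @param x a `classification_image`.
#' @param seed optional seed for the in-fill draws.
#' @return The image with in-filled inducer pixels, tagged
#'   `display_only = TRUE`.
#' @export
infill_inducers <- function(x, seed = NULL) {
  stopifnot(inherits(x, "classification_image"))
  m <- x$inducer_mask
  if (any(m)) {
    w <- x$weights[!m]
    draw <- function() rnorm(sum(m), mean(w), sd(w))
    x$weights[m] <- if (is.null(seed)) draw() else local_seed(seed, draw())
  }
  x$display_only <- TRUE
  x
}

#' Radially average an image about the window center
#'
#' Bin `b` collects the non-inducer pixels whose Euclidean distance from the
#' window center (at `(N-1)/2` in 0-based coordinates) rounds to `b`; bins
#' run from 1 px to `N/2 - 1` px (99 bins for the 200-px window, matching
#' the numerator degrees of freedom of the profile-level tests). The center
#' pixel area (rounding to 0) is excluded.
#'
#' @param x a `classification_image`, or a numeric matrix (optionally with
#'   `mask`, a logical matrix of pixels to exclude).
#' @param mask optional exclusion mask when `x` is a matrix.
#' @return An object of class `radial_profile`: `values`, `radii` (px),
#'   `bin_counts`.
#' @export
radial_average <- function(x, mask = NULL) {
  if (inherits(x, "classification_image")) {
    geom <- window_geometry(x$spec, x$display)
    v <- x$weights
    bin_idx <- geom$bin_idx
    nbins <- geom$nbins
    counts <- geom$bin_counts
  } else {
    v <- as.matrix(x)
    N <- nrow(v)
    if (N != ncol(v)) stop("radial_average requires a square image")
    cx <- (N - 1) / 2
    off <- (0:(N - 1)) - cx
    r <- sqrt(outer(off^2, off^2, "+"))
    nbins <- as.integer(N / 2 - 1)
    bin_idx <- as.integer(round(r))
    bin_idx[bin_idx < 1L | bin_idx > nbins] <- 0L
    if (!is.null(mask)) bin_idx[mask] <- 0L
    counts <- tabulate(bin_idx[bin_idx > 0L], nbins)
  }
  if (any(counts == 0))
    stop("empty radial bin(s): ", paste(which(counts == 0), collapse = ", "))
  vals <- bin_means_cpp(as.vector(v), as.vector(bin_idx), nbins)
  structure(list(values = vals, radii = seq_len(nbins),
                 bin_counts = counts),
            class = "radial_profile")
}

#' Rotational power spectrum of a classification image
#'
#' 2-D FFT, squared modulus, averaged over annular frequency bins one DFT
#' sample wide; the frequency axis is converted to cycles/degree via the
#' display's pixel pitch and reported up to the Nyquist frequency
#' `1/(2 * pixel pitch)`. The total power `sum(|F|^2)/N^2` (equal to the sum
#' of squared pixel weights, Parseval) is attached as `total_power`.
#'
#' @param x a `classification_image` or square numeric matrix.
#' @param display a [display_spec()] (taken from `x` when available).
#' @return An object of class `spectral_profile`: `frequencies` (c/deg),
#'   `values` (mean squared amplitude per bin), `bin_counts`, `total_power`.
#' @export
spectral_profile <- function(x, display = NULL) {
  if (inherits(x, "classification_image")) {
    if (is.null(display)) display <- x$display
    v <- x$weights
  } else {
    v <- as.matrix(x)
    if (is.null(display)) display <- default_display()
  }
  N <- nrow(v)
  if (N != ncol(v)) stop("spectral_profile requires a square image")
  p_deg <- pixels_to_degrees(1, display)
  P <- Mod(fft(v))^2
  k <- 0:(N - 1)
  s <- ifelse(k <= N / 2, k, N - k)
  rad <- sqrt(outer(s^2, s^2, "+"))
  bin <- as.integer(round(rad))
  keep <- bin <= N / 2                    # up to Nyquist
  counts <- tabulate(bin[keep] + 1L, N / 2 + 1)
  sums <- as.vector(tapply(P[keep], bin[keep], sum))
  vals <- numeric(N / 2 + 1)
  vals[counts > 0] <- sums / counts[counts > 0]
  structure(list(frequencies = (0:(N / 2)) / (N * p_deg),
                 values = vals, bin_counts = counts,
                 total_power = sum(P) / N^2),
            class = "spectral_profile")
}

#' Frequency of the spectral peak
#'
#' @param profile a `spectral_profile`.
#' @param exclude_dc drop the zero-frequency bin before locating the peak.
#' @return Peak frequency in c/deg.
#' @export
peak_frequency <- function(profile, exclude_dc = TRUE) {
  stopifnot(inherits(profile, "spectral_profile"))
  f <- profile$frequencies
  v <- profile$values
  if (exclude_dc) { v <- v[-1]; f <- f[-1] }
  if (length(v) == 0) stop("empty profile")
  mx <- max(v)
  at <- which(v == mx)
  if (length(at) > 1)
    stop("spectral peak is tied across ", length(at), " bins")
  f[at]
}

# Eq.-style cell-mean combination of per-trial radial vectors for a subset
# of trials (used by the bootstrap and null replicates).
radial_cell_combo <- function(radial, present, resp_present, idx = NULL) {
  if (!is.null(idx)) {
    radial <- radial[idx, , drop = FALSE]
    present <- present[idx]; resp_present <- resp_present[idx]
  }
  cells <- list(Sa_Ra = !present & !resp_present,
                Sa_Rp = !present & resp_present,
                Sp_Ra = present & !resp_present,
                Sp_Rp = present & resp_present)
  if (any(vapply(cells, sum, 0L) == 0L)) return(NULL)
  mns <- lapply(cells, function(sel) colMeans(radial[sel, , drop = FALSE]))
  (mns$Sa_Rp + mns$Sp_Rp) - (mns$Sa_Ra + mns$Sp_Ra)
}

# 1-D uniform smoothing with renormalized edges.
smooth_vector <- function(v, width) {
  if (width <= 1) return(v)
  h <- (width - 1) / 2
  n <- length(v)
  cs <- c(0, cumsum(v))
  cn <- c(0, cumsum(rep(1, n)))
  i1 <- pmax(seq_len(n) - h, 1); i2 <- pmin(seq_len(n) + h, n)
  (cs[i2 + 1] - cs[i1]) / (cn[i2 + 1] - cn[i1])
}

#' Bootstrap band of the radial classification-image profile
#'
#' Per replicate, trials are resampled with replacement, the radial profile
#' is recomputed from the per-trial radial noise vectors via the
#' stimulus-response cell-mean combination, and smoothed with a 1-D uniform
#' kernel. The band is the pointwise mean +/- 2 SD across replicates.
#'
#' @param run a `detection_run`.
#' @param n_boot number of replicates (default 500).
#' @param smooth_px width of the 1-D smoothing kernel (default 5).
#' @param seed RNG seed.
#' @return An object of class `profile_band`: `mean`, `sd`, `radii`,
#'   `n_replicates`, `kind = "bootstrap"`.
#' @export
bootstrap_profiles <- function(run, n_boot = 500, smooth_px = 5, seed = 1) {
  stopifnot(inherits(run, "detection_run"))
  if (is.null(radial_cell_combo(run$radial, run$trials$present,
                                run$trials$response == "present")))
    stop("empty stimulus-response cell in the full data")
  n <- nrow(run$trials)
  present <- run$trials$present
  respp <- run$trials$response == "present"
  reps <- local_seed(seed, {
    out <- matrix(NA_real_, n_boot, ncol(run$radial))
    for (b in seq_len(n_boot)) {
      prof <- radial_cell_combo(run$radial, present, respp,
                                sample.int(n, replace = TRUE))
      if (!is.null(prof)) out[b, ] <- smooth_vector(prof, smooth_px)
    }
    out
  })
  fail <- mean(is.na(reps[, 1]))
  if (fail > 0.2)
    stop(sprintf("%.0f%% of bootstrap replicates had an empty cell",
                 100 * fail))
  ok <- !is.na(reps[, 1])
  sd_curve <- if (sum(ok) > 1) apply(reps[ok, , drop = FALSE], 2, sd)
              else rep(0, ncol(reps))
  structure(list(mean = colMeans(reps[ok, , drop = FALSE]),
                 sd = sd_curve,
                 radii = seq_len(ncol(run$radial)),
                 n_replicates = sum(ok), kind = "bootstrap",
                 smooth_px = smooth_px),
            class = "profile_band")
}

#' Randomization null band for radial profiles
#'
#' Keeps every trial's stimulus-response cell assignment but replaces its
#' noise with a freshly sampled truncated-noise field, recomputes the radial
#' profile, and repeats `n_rep` times; the band is the pointwise mean +/- 2
#' SD across replicates and is centered on zero for any observer, since
#' fresh noise is independent of the recorded labels.
#'
#' `method = "exact"` draws every pixel of every replicate field;
#' `method = "gaussian"` draws each bin-by-cell mean from its exact-variance
#' normal approximation (each such mean pools thousands of bounded i.i.d.
#' deviates, so the central-limit approximation is indistinguishable in
#' practice) and makes the band affordable for large runs. `"auto"` picks
#' `"gaussian"` when the exact method would need more than 2e8 draws.
#'
#' @param run a `detection_run`.
#' @param n_rep number of random classification images (default 200).
#' @param seed RNG seed.
#' @param method `"auto"`, `"exact"`, or `"gaussian"`.
#' @return A `profile_band` with `kind = "null"`.
#' @export
null_band <- function(run, n_rep = 200, seed = 1,
                      method = c("auto", "exact", "gaussian")) {
  stopifnot(inherits(run, "detection_run"))
  method <- match.arg(method)
  geom <- window_geometry(run$spec, run$display)
  present <- run$trials$present
  respp <- run$trials$response == "present"
  cells <- list(Sa_Ra = !present & !respp, Sa_Rp = !present & respp,
                Sp_Ra = present & !respp, Sp_Rp = present & respp)
  ncell <- vapply(cells, sum, 0L)
  if (any(ncell == 0L))
    stop("empty stimulus-response cell(s): ",
         paste(names(ncell)[ncell == 0L], collapse = ", "))
  n <- length(present)
  if (method == "auto") {
    draws <- as.double(n_rep) * n * sum(geom$bin_counts)
    method <- if (draws > 2e8) "gaussian" else "exact"
  }
  sgn <- c(Sa_Ra = -1, Sa_Rp = 1, Sp_Ra = -1, Sp_Rp = 1)
  reps <- local_seed(seed, {
    out <- matrix(NA_real_, n_rep, geom$nbins)
    if (method == "exact") {
      for (b in seq_len(n_rep)) {
        M <- null_bin_means_cpp(n, geom$bin_counts, sqrt(run$sigma2), 2)
        prof <- numeric(geom$nbins)
        for (cell in names(cells))
          prof <- prof + sgn[cell] *
            rowMeans(M[, cells[[cell]], drop = FALSE])
        out[b, ] <- prof
      }
    } else {
      # per-bin SD of each cell mean: sqrt(v_eff / (n_b * n_cell))
      v_eff <- trunc_var_factor(2) * run$sigma2
      for (b in seq_len(n_rep)) {
        prof <- numeric(geom$nbins)
        for (cell in names(cells)) {
          sds <- sqrt(v_eff / (geom$bin_counts * ncell[cell]))
          prof <- prof + sgn[cell] * rnorm(geom$nbins, 0, sds)
        }
        out[b, ] <- prof
      }
    }
    out
  })
  structure(list(mean = colMeans(reps), sd = apply(reps, 2, sd),
                 radii = seq_len(geom$nbins),
                 n_replicates = n_rep, kind = "null", method = method),
            class = "profile_band")
}

#' @export
print.classification_image <- function(x, ...) {
  cat(sprintf("<classification_image> %s, %d trials (cells: %s), window %d px%s\n",
              x$condition, x$n_trials,
              paste(x$counts, collapse = "/"), nrow(x$weights),
              if (isTRUE(x$display_only)) " [display only]" else ""))
  invisible(x)
}

#' @export
print.radial_profile <- function(x, ...) {
  cat(sprintf("<radial_profile> %d bins (1..%d px), range [%.3g, %.3g]\n",
              length(x$values), max(x$radii), min(x$values), max(x$values)))
  invisible(x)
}

#' @export
print.spectral_profile <- function(x, ...) {
  cat(sprintf("<spectral_profile> %d bins, 0..%.2f c/deg, total power %.3g\n",
              length(x$values), max(x$frequencies), x$total_power))
  invisible(x)
}

#' @export
print.profile_band <- function(x, ...) {
  cat(sprintf("<profile_band> %s band, %d replicates, %d bins\n",
              x$kind, x$n_replicates, length(x$mean)))
  invisible(x)
}
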