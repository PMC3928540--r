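#' Assemble a report bundle from analysed runs
#'
#' Writes a deterministic set of CSV tables, PNG figures and JSON metadata
#' for a collection of runs: per-observer thresholds (with bootstrap SD),
#' efficiencies relative to an `"ideal"` entry when present, raw and
#' smoothed classification-image panels (inducer regions in-filled with
#' matched noise for display only), radial profiles with bootstrap and
#' randomization bands, spectral profiles, and a Hotelling table mirroring
#' the one- and two-sample profile tests. All numbers in the figures come
#' from the CSV tables; nothing is recomputed at plot time.
#'
#' @param runs named list of `detection_run` objects; names label the
#'   observers (a name of `"ideal"` marks the efficiency reference).
#'   Two runs whose names differ only in a `_small`/`_large` suffix are
#'   paired for the two-sample test.
#' @param out_dir output directory.
#' @param n_boot bootstrap replicates for thresholds and profile bands.
#' @param n_null randomization replicates for the null band.
#' @param seed RNG seed for all resampling.
#' @return An object of class `report_bundle` listing the files written.
#' @export
build_report <- function(runs, out_dir, n_boot = 500, n_null = 200,
                         seed = 1) {
  if (inherits(runs, "detection_run")) runs <- list(run = runs)
  bad <- names(runs)[!vapply(runs, inherits, TRUE, "detection_run")]
  if (is.null(names(runs)) || any(!nzchar(names(runs))))
    stop("`runs` must be a named list of detection_run objects")
  if (length(bad))
    stop("not detection_run objects: ", paste(bad, collapse = ", "))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  put <- function(f) { files <<- c(files, f); f }

  # thresholds & efficiency ------------------------------------------------
  thr <- lapply(names(runs), function(nm) {
    est <- tryCatch(bootstrap_threshold(runs[[nm]], n_boot = n_boot,
                                        seed = seed),
                    error = function(e) NULL)
    if (is.null(est)) return(NULL)
    data.frame(observer = nm, condition = runs[[nm]]$spec$condition,
               threshold_deg2 = est$threshold, sd = est$sd,
               n_boot = est$n_boot, criterion = est$criterion)
  })
  thr <- do.call(rbind, thr[!vapply(thr, is.null, TRUE)])
  if (!is.null(thr)) {
    data.table::fwrite(thr, put(file.path(out_dir, "thresholds.csv")))
    ideal_rows <- grepl("^ideal", thr$observer)
    if (any(ideal_rows) && any(!ideal_rows)) {
      eff <- do.call(rbind, lapply(which(!ideal_rows), function(i) {
        ref <- thr[ideal_rows & thr$condition == thr$condition[i], ]
        if (!nrow(ref)) return(NULL)
        data.frame(observer = thr$observer[i],
                   condition = thr$condition[i],
                   efficiency = ref$threshold_deg2[1] /
                     thr$threshold_deg2[i])
      }))
      if (!is.null(eff) && nrow(eff))
        data.table::fwrite(eff, put(file.path(out_dir, "efficiency.csv")))
    }
  }

  # classification images, profiles, bands ---------------------------------
  hot <- list()
  for (nm in names(runs)) {
    run <- runs[[nm]]
    ci <- tryCatch(classification_image(run), error = function(e) NULL)
    if (is.null(ci)) next
    sm <- smooth_image(ci, 7)
    prof <- radial_average(ci)
    boot <- bootstrap_profiles(run, n_boot = n_boot, seed = seed)
    null <- null_band(run, n_rep = n_null, seed = seed)
    spec_prof <- spectral_profile(ci)
    dot_edge <- run$spec$central_diameter_px / 2

    data.table::fwrite(
      data.frame(radius_px = prof$radii, weight = prof$values,
                 boot_mean = boot$mean, boot_sd = boot$sd,
                 null_mean = null$mean, null_sd = null$sd),
      put(file.path(out_dir, paste0("radial_", nm, ".csv"))))
    data.table::fwrite(
      data.frame(freq_cdeg = spec_prof$frequencies,
                 mean_sq_amplitude = spec_prof$values),
      put(file.path(out_dir, paste0("spectral_", nm, ".csv"))))

    grDevices::png(put(file.path(out_dir, paste0("cimage_", nm, ".png"))),
                   width = 900, height = 480)
    op <- graphics::par(mfrow = c(1, 2), mar = c(2, 2, 3, 1))
    pal <- grDevices::hcl.colors(65, "Blue-Red 3")
    for (panel in list(list(img = infill_inducers(ci, seed = seed),
                            main = paste0(nm, " (raw)")),
                       list(img = infill_inducers(sm, seed = seed),
                            main = paste0(nm, " (smoothed 7 px)")))) {
      w <- panel$img$weights
      lim <- max(abs(w))                # symmetric diverging scale
      graphics::image(w, zlim = c(-lim, lim), col = pal, axes = FALSE,
                      main = panel$main, useRaster = TRUE)
    }
    graphics::par(op)
    grDevices::dev.off()

    grDevices::png(put(file.path(out_dir, paste0("radial_", nm, ".png"))),
                   width = 640, height = 480)
    graphics::plot(prof$radii, prof$values, pch = 16, cex = 0.6,
                   xlab = "distance from dot center (px)",
                   ylab = "mean noise weight", main = nm)
    graphics::polygon(c(null$radii, rev(null$radii)),
                      c(null$mean + 2 * null$sd,
                        rev(null$mean - 2 * null$sd)),
                      col = grDevices::gray(0.85), border = NA)
    graphics::points(prof$radii, prof$values, pch = 16, cex = 0.6)
    graphics::lines(boot$radii, boot$mean, lwd = 2)
    graphics::lines(boot$radii, boot$mean + 2 * boot$sd, lty = 3)
    graphics::lines(boot$radii, boot$mean - 2 * boot$sd, lty = 3)
    graphics::abline(v = dot_edge, lty = 2)  # edge of the central dot
    grDevices::dev.off()

    V <- trial_vectors(run)
    h <- tryCatch(hotelling_one_sample(V), error = function(e) NULL)
    if (!is.null(h))
      hot[[length(hot) + 1L]] <- data.frame(
        test = "one_sample", observer = nm,
        condition = run$spec$condition, df1 = h$df1, df2 = h$df2,
        F = h$f, p = format_p(h$p))
  }

  # two-sample tests for <name>_small / <name>_large pairs ------------------
  base_names <- unique(sub("_(small|large)$", "", names(runs)))
  for (bn in base_names) {
    a <- paste0(bn, "_small"); b <- paste0(bn, "_large")
    if (a %in% names(runs) && b %in% names(runs)) {
      h <- tryCatch(hotelling_two_sample(trial_vectors(runs[[a]]),
                                         trial_vectors(runs[[b]])),
                    error = function(e) NULL)
      if (!is.null(h))
        hot[[length(hot) + 1L]] <- data.frame(
          test = "two_sample", observer = bn,
          condition = "small_vs_large", df1 = h$df1, df2 = h$df2,
          F = h$f, p = format_p(h$p))
    }
  }
  if (length(hot))
    data.table::fwrite(do.call(rbind, hot),
                       put(file.path(out_dir, "hotelling.csv")))

  meta <- list(runs = lapply(runs, function(r)
    list(observer_kind = r$observer_kind, condition = r$spec$condition,
         n_trials = nrow(r$trials), seeds = r$seeds)),
    dot_edge_px = vapply(runs, function(r)
      r$spec$central_diameter_px / 2, numeric(1)),
    n_boot = n_boot, n_null = n_null, seed = seed)
  jsonlite::write_json(meta, put(file.path(out_dir, "metadata.json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  structure(list(files = files, out_dir = out_dir), class = "report_bundle")
}

#' @export
print.report_bundle <- function(x, ...) {
  cat(sprintf("<report_bundle> %d files in %s\n", length(x$files),
              x$out_dir))
  invisible(x)
}
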