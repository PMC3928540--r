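#' Write a detection run to a directory archive
#'
#' Persists a run as plain text: `trials.csv` (the trial log), `radial.csv`
#' (per-trial radial noise vectors), `cells.csv` (per-pixel noise sums of
#' the four stimulus-response cells) and `meta.json` (stimulus, display,
#' noise and seed metadata). Full noise fields are not stored: they are
#' regenerated exactly from the per-trial seeds in the trial log (fields are
#' additionally written to `noise.csv` when the run kept them in memory).
#'
#' @param run a `detection_run`.
#' @param dir target directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_run <- function(run, dir) {
  stopifnot(inherits(run, "detection_run"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  # doubles are written with 17 significant digits so archives round-trip
  # bit-exactly through text
  fwrite_exact <- function(x, path) {
    x <- data.table::as.data.table(x)
    for (col in names(x))
      if (is.double(x[[col]]))
        data.table::set(x, j = col, value = sprintf("%.17g", x[[col]]))
    data.table::fwrite(x, path)
  }
  fwrite_exact(run$trials, file.path(dir, "trials.csv"))
  fwrite_exact(run$radial, file.path(dir, "radial.csv"))
  fwrite_exact(lapply(run$cells$sums, as.vector),
               file.path(dir, "cells.csv"))
  if (!is.null(run$noise)) {
    noise <- stats::setNames(lapply(run$noise, as.vector),
                             paste0("trial_", seq_along(run$noise)))
    fwrite_exact(noise, file.path(dir, "noise.csv"))
  }
  meta <- list(package = "classim",
               observer_kind = run$observer_kind,
               sigma2 = run$sigma2,
               seeds = run$seeds,
               spec = unclass(run$spec),
               display = unclass(run$display),
               cell_counts = as.list(run$cells$counts),
               n_trials = nrow(run$trials),
               kept_noise = !is.null(run$noise))
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a detection run archive
#'
#' Reconstructs the `detection_run` written by [write_run()]. Errors with an
#' explicit message when any archive component is missing, so downstream
#' classification operations can never silently work from a zero image.
#'
#' @param dir archive directory.
#' @return A `detection_run`.
#' @export
read_run <- function(dir) {
  need <- c("trials.csv", "radial.csv", "cells.csv", "meta.json")
  missing <- need[!file.exists(file.path(dir, need))]
  if (length(missing))
    stop("incomplete run archive at '", dir, "': missing ",
         paste(missing, collapse = ", "))
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  trials <- as.data.frame(data.table::fread(file.path(dir, "trials.csv")))
  radial <- as.matrix(data.table::fread(file.path(dir, "radial.csv")))
  dimnames(radial) <- NULL
  cells_flat <- as.data.frame(data.table::fread(file.path(dir, "cells.csv")))
  N <- meta$spec$window_px
  sums <- lapply(cells_flat, function(v) matrix(v, N, N))
  counts <- unlist(meta$cell_counts)[names(sums)]
  noise <- NULL
  if (isTRUE(meta$kept_noise) && file.exists(file.path(dir, "noise.csv"))) {
    nz <- as.data.frame(data.table::fread(file.path(dir, "noise.csv")))
    noise <- lapply(nz, function(v) matrix(v, N, N))
    names(noise) <- NULL
  }
  spec <- do.call(stimulus_spec, meta$spec[c("condition",
                                             "central_diameter_px",
                                             "inducer_diameter_px",
                                             "n_inducers",
                                             "center_to_center_px",
                                             "window_px",
                                             "target_contrast")])
  display <- do.call(display_spec, meta$display)
  structure(list(trials = trials, radial = radial,
                 cells = list(sums = sums, counts = counts),
                 spec = spec, display = display, sigma2 = meta$sigma2,
                 observer_kind = meta$observer_kind,
                 seeds = meta$seeds, noise = noise),
            class = "detection_run")
}

#' Build a detection run from explicit noise fields and responses
#'
#' Constructs the same container as [run_staircase()] from user-supplied
#' per-trial noise fields, truth labels and responses, computing the radial
#' vectors and stimulus-response cell sums with the package conventions.
#' Useful for analysing externally generated (e.g. human) trial data and
#' for fixture construction.
#'
#' @param fields list of window-sized noise matrices (raw noise, zero at
#'   inducer pixels).
#' @param present logical vector of target-present truths.
#' @param response character (`"present"`/`"absent"`) or logical responses.
#' @param spec a [stimulus_spec()].
#' @param display a [display_spec()].
#' @param sigma2 nominal noise variance of the fields.
#' @param energy optional per-trial staircase energies (deg^2).
#' @return A `detection_run` (with fields kept in memory).
#' @export
as_detection_run <- function(fields, present, response, spec,
                             display = default_display(), sigma2 = 0.16,
                             energy = NA_real_) {
  n <- length(fields)
  stopifnot(n >= 1, length(present) == n, length(response) == n)
  if (is.logical(response))
    response <- ifelse(response, "present", "absent")
  geom <- window_geometry(spec, display)
  cells <- c("Sa_Ra", "Sa_Rp", "Sp_Ra", "Sp_Rp")
  cell_sums <- stats::setNames(
    lapply(cells, function(i) matrix(0, geom$N, geom$N)), cells)
  cell_counts <- stats::setNames(integer(4), cells)
  radial <- matrix(NA_real_, n, geom$nbins)
  for (t in seq_len(n)) {
    f <- as.matrix(fields[[t]])
    if (!all(dim(f) == geom$N)) stop("field ", t, " has the wrong shape")
    radial[t, ] <- bin_means_cpp(as.vector(f), geom$bin_idx, geom$nbins)
    cell <- paste0(if (present[t]) "Sp" else "Sa", "_",
                   if (response[t] == "present") "Rp" else "Ra")
    cell_sums[[cell]] <- cell_sums[[cell]] + f
    cell_counts[cell] <- cell_counts[cell] + 1L
  }
  structure(list(
    trials = data.frame(index = seq_len(n), condition = spec$condition,
                        present = present, energy = rep_len(energy, n),
                        response = response,
                        correct = present == (response == "present"),
                        noise_ref = NA_integer_, stringsAsFactors = FALSE),
    radial = radial,
    cells = list(sums = cell_sums, counts = cell_counts),
    spec = spec, display = display, sigma2 = sigma2,
    observer_kind = "external",
    seeds = list(seed = NA_integer_, noise_seed = NA_integer_),
    noise = lapply(fields, as.matrix)),
    class = "detection_run")
}
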