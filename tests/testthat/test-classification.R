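# A tiny run with hand-built fields, one or more trials in every
# stimulus-response cell.
make_fixture_run <- function(n = 12, seed = 91,
                             spec = stimulus_spec("small_inducers")) {
  set.seed(seed)
  geom <- classim:::window_geometry(spec)
  fields <- lapply(seq_len(n), function(i) {
    f <- matrix(rnorm(200^2, sd = 0.35), 200, 200)
    f[geom$inducer_mask] <- 0
    f
  })
  present <- rep(c(TRUE, FALSE), length.out = n)
  response <- rep(c(TRUE, TRUE, FALSE, FALSE), length.out = n)
  as_detection_run(fields, present, response, spec)
}

test_that("the classification image is the stated cell-mean combination", {
  run <- make_fixture_run()
  ci <- classification_image(run)
  # brute-force oracle straight from the definition
  pres <- run$trials$present
  resp <- run$trials$response == "present"
  cell_mean <- function(sel)
    Reduce(`+`, run$noise[sel]) / sum(sel)
  oracle <- (cell_mean(!pres & resp) + cell_mean(pres & resp)) -
    (cell_mean(!pres & !resp) + cell_mean(pres & !resp))
  expect_equal(ci$weights, oracle, tolerance = 1e-12)
  expect_identical(sum(ci$counts), 12L)
  # empty-cell error names the missing cell
  bad <- make_fixture_run(6)
  bad$cells$counts["Sp_Ra"] <- 0L
  expect_error(classification_image(bad), "Sp_Ra")
})

test_that("pooled sessions equal the cell-count-weighted combination", {
  r1 <- make_fixture_run(12, seed = 92)
  r2 <- make_fixture_run(8, seed = 93)
  pooled <- combine_runs(r1, r2)
  ci_pooled <- classification_image(pooled)
  # recompute from the concatenated records directly
  all_fields <- c(r1$noise, r2$noise)
  pres <- c(r1$trials$present, r2$trials$present)
  resp <- c(r1$trials$response, r2$trials$response) == "present"
  direct <- classification_image(
    as_detection_run(all_fields, pres, resp, r1$spec))
  expect_equal(ci_pooled$weights, direct$weights, tolerance = 1e-12)
  expect_equal(radial_average(ci_pooled)$values,
               radial_average(direct)$values, tolerance = 1e-12)
})

test_that("box smoothing is normalized, local and variance-reducing", {
  const <- matrix(3.7, 30, 30)
  expect_equal(smooth_image(const, 7), const, tolerance = 1e-12)
  imp <- matrix(0, 31, 31); imp[16, 16] <- 1
  sm <- smooth_image(imp, 7)
  expect_equal(sm[13:19, 13:19], matrix(1 / 49, 7, 7), tolerance = 1e-12)
  expect_equal(sum(sm[13:19, 13:19]), 1, tolerance = 1e-12)
  expect_true(all(sm[-(13:19), ] == 0))
  set.seed(94)
  wn <- matrix(rnorm(200^2), 200, 200)
  smw <- smooth_image(wn, 7)
  interior <- smw[20:180, 20:180]
  expect_equal(var(as.vector(interior)) * 49, 1, tolerance = 0.2)
  expect_error(smooth_image(wn, 6), "k")
})

test_that("inducer in-fill only touches masked pixels and leaves no flat footprint", {
  run <- make_fixture_run()
  ci <- classification_image(run)
  ci$weights[ci$inducer_mask] <- 0  # raw image: inducers are exactly zero
  filled <- infill_inducers(ci, seed = 5)
  expect_identical(filled$weights[!ci$inducer_mask],
                   ci$weights[!ci$inducer_mask])
  vals <- filled$weights[ci$inducer_mask]
  expect_identical(anyDuplicated(vals), 0L)
  expect_true(isTRUE(filled$display_only))
  # empty mask: identity
  m <- matrix(rnorm(25), 5, 5)
  ci2 <- ci; ci2$weights <- m; ci2$inducer_mask <- matrix(FALSE, 5, 5)
  expect_identical(infill_inducers(ci2)$weights, m)
})

test_that("radial averaging matches constants, an analytic bump, and has 99 bins", {
  const <- matrix(2.5, 200, 200)
  p <- radial_average(const)
  expect_identical(length(p$values), 99L)
  expect_identical(p$radii, 1:99)
  expect_true(all(abs(p$values - 2.5) < 1e-12))
  # radially symmetric Gaussian bump vs its generating function
  off <- (0:199) - 99.5
  r <- sqrt(outer(off^2, off^2, "+"))
  bump <- exp(-r^2 / (2 * 20^2))
  pb <- radial_average(bump)
  expect_lt(max(abs(pb$values - exp(-(1:99)^2 / 800))), 0.02)
  # rotation by 90 degrees leaves the profile unchanged
  set.seed(95)
  m <- matrix(rnorm(200^2), 200, 200)
  rot <- t(m)[, 200:1]
  expect_equal(radial_average(rot)$values, radial_average(m)$values,
               tolerance = 1e-12)
  # an all-masked bin errors
  mask <- r >= 49.5 & r < 50.5
  expect_error(radial_average(m, mask = mask), "empty radial bin")
})

test_that("spectral profiles localize gratings and satisfy Parseval", {
  d <- default_display()
  const <- matrix(4, 200, 200)
  sp <- spectral_profile(const, d)
  expect_identical(sp$frequencies[1], 0)
  # all energy in the DC bin (up to FFT roundoff)
  expect_gt(sp$values[1], 0)
  expect_true(all(sp$values[-1] < 1e-15 * sp$values[1]))
  # Parseval: total spectral power equals the pixel sum of squares
  set.seed(96)
  m <- matrix(rnorm(200^2), 200, 200)
  spm <- spectral_profile(m, d)
  expect_equal(spm$total_power, sum(m^2), tolerance = 1e-8)
  # gratings at the bins containing ~6 and ~9 c/deg
  p_deg <- pixels_to_degrees(1, d)
  for (f_target in c(6, 9)) {
    k0 <- round(f_target * 200 * p_deg)
    grating <- matrix(cos(2 * pi * k0 * (0:199) / 200), 200, 200,
                      byrow = TRUE)
    pk <- peak_frequency(spectral_profile(grating, d), exclude_dc = TRUE)
    expect_equal(pk, k0 / (200 * p_deg), tolerance = 1e-12)
    expect_identical(round(f_target / (1 / (200 * p_deg))), k0)
  }
  # rotation invariance of the spectral reduction
  rot <- t(m)[, 200:1]
  expect_equal(spectral_profile(rot, d)$values, spm$values,
               tolerance = 1e-9)
  # peak detection guards
  flat_prof <- sp; flat_prof$values <- rep(1, length(sp$values))
  expect_error(peak_frequency(flat_prof, exclude_dc = FALSE), "tied")
  mono <- sp; mono$values <- rev(sort(runif(101)))
  expect_equal(peak_frequency(mono, exclude_dc = TRUE),
               mono$frequencies[2])
  scaled <- mono; scaled$values <- scaled$values * 3.3
  expect_equal(peak_frequency(mono, exclude_dc = TRUE),
               peak_frequency(scaled, exclude_dc = TRUE))
})

test_that("bootstrap profile bands are seeded and degenerate at n = 1", {
  run <- make_fixture_run(40, seed = 97)
  b1 <- bootstrap_profiles(run, n_boot = 1, seed = 1)
  expect_true(all(b1$sd == 0))
  b2 <- bootstrap_profiles(run, n_boot = 30, seed = 2)
  b3 <- bootstrap_profiles(run, n_boot = 30, seed = 2)
  expect_identical(b2$mean, b3$mean)
  expect_identical(b2$sd, b3$sd)
  expect_identical(b2$kind, "bootstrap")
  # band width shrinks roughly as 1/sqrt(n_trials)
  big <- run_ideal_small()
  sub <- big
  sub$trials <- big$trials[1:2500, ]
  sub$radial <- big$radial[1:2500, ]
  w_small <- mean(bootstrap_profiles(sub, n_boot = 80, seed = 3)$sd)
  w_big <- mean(bootstrap_profiles(big, n_boot = 80, seed = 3)$sd)
  expect_equal(w_small / w_big, 2, tolerance = 0.25)
})

test_that("the randomization null band is centered on zero with the analytic width", {
  run <- make_fixture_run(60, seed = 98)
  nb <- null_band(run, n_rep = 120, seed = 4, method = "exact")
  expect_identical(nb$kind, "null")
  expect_true(all(abs(nb$mean) < 0.5 * nb$sd))
  ratio <- nb$sd / null_sd_analytic(run)
  expect_true(all(ratio > 0.7 & ratio < 1.3))
  expect_equal(mean(ratio), 1, tolerance = 0.1)
  # the fast gaussian path agrees with the literal resampling path
  ng <- null_band(run, n_rep = 120, seed = 5, method = "gaussian")
  ratio2 <- ng$sd / nb$sd
  expect_equal(mean(ratio2), 1, tolerance = 0.1)
  # seeded reproducibility
  expect_identical(null_band(run, n_rep = 20, seed = 6)$sd,
                   null_band(run, n_rep = 20, seed = 6)$sd)
})

test_that("ideal weights concentrate in the dot; random responding stays in the band", {
  run <- run_ideal_small()
  prof <- radial_average(classification_image(run))
  sdb <- null_sd_analytic(run)
  core <- 1:18   # inside the 22.5-px dot edge
  far <- 61:99
  expect_lt(mean(prof$values[core] / sdb[core]), -5)  # strongly negative
  expect_lt(mean(abs(prof$values[far] / sdb[far])), 2)
  # label-independent responses give a profile inside the null band almost
  # everywhere
  rnd <- run_rand_small()
  prnd <- radial_average(classification_image(rnd))
  z <- abs(prnd$values) / null_sd_analytic(rnd)
  expect_gt(mean(z < 2), 0.9)
})

test_that("the template observer's classification image recovers its template", {
  run <- run_tmpl_small()
  ci <- classification_image(run)
  tm <- center_surround_template(run$spec)
  keep <- !ci$inducer_mask
  # the raw per-pixel image is noise-limited even at 10^4 trials; the
  # pipeline's smoothed image is the quantitative recovery check
  r_raw <- cor(ci$weights[keep], tm[keep])
  expect_gt(r_raw, 0.2)
  sm <- smooth_image(ci, 7)
  tms <- classim:::box_smooth_matrix(tm, 7)
  expect_gt(cor(sm$weights[keep], tms[keep]), 0.8)
})
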