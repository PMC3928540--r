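test_that("pixel-to-degree conversion reproduces the printed stimulus sizes", {
  d <- default_display()
  printed <- c(`45` = 0.74, `15` = 0.25, `55` = 0.90, `60` = 0.98,
               `68` = 1.11)
  got <- pixels_to_degrees(as.numeric(names(printed)), d)
  # the reference values mix rounding and truncation; agreement at the
  # second decimal place means |difference| < 0.01
  expect_true(all(abs(got - printed) < 0.01))
  expect_identical(pixels_to_degrees(0, d), 0)
  expect_error(display_spec(viewing_distance_cm = -1), "positive")
  expect_error(display_spec(max_neg_contrast = -1.2), "max_neg_contrast")
})

test_that("pixel area behaves like an inverse-square small-angle quantity", {
  d <- default_display()
  expect_equal(pixel_area_deg2(d), 2.7103e-4, tolerance = 1e-4)
  d2 <- display_spec(viewing_distance_cm = 260)
  expect_equal(pixel_area_deg2(d2), pixel_area_deg2(d) / 4,
               tolerance = 1e-12)
  # a 1-cm pixel viewed from 57.29 cm subtends about 1 degree
  d3 <- display_spec(width_cm = 10, width_px = 10,
                     viewing_distance_cm = 180 / pi)
  expect_equal(pixel_area_deg2(d3), 1, tolerance = 1e-6)
})

test_that("contrast energy matches a brute-force pixel sum and its invariances", {
  d <- default_display()
  a <- pixel_area_deg2(d)
  expect_identical(contrast_energy(matrix(0, 20, 20), d), 0)
  one <- matrix(0, 20, 20); one[7, 13] <- 1
  expect_equal(contrast_energy(one, d), a, tolerance = 1e-15)
  # rasterized 45-px dot at the maximum negative contrast
  spec <- stimulus_spec("none", target_contrast = -0.87)
  img <- render_stimulus(spec, d, present = TRUE)
  n_dot <- sum(img$values != 0)
  expect_equal(contrast_energy(img, d), 0.7569 * a * n_dot,
               tolerance = 1e-12)
  expect_equal(contrast_energy(img, d),
               sum(img$values^2) * a, tolerance = 1e-15)
  # translation and global sign flip leave energy unchanged
  set.seed(1)
  m <- matrix(rnorm(400), 20, 20)
  shifted <- m[c(5:20, 1:4), c(11:20, 1:10)]
  expect_equal(contrast_energy(shifted, d), contrast_energy(m, d))
  expect_equal(contrast_energy(-m, d), contrast_energy(m, d))
  # additivity over disjoint pixel sets
  m1 <- m; m1[1:10, ] <- 0
  m2 <- m; m2[11:20, ] <- 0
  expect_equal(contrast_energy(m1, d) + contrast_energy(m2, d),
               contrast_energy(m, d), tolerance = 1e-12)
})

test_that("stimulus rendering places the printed inducer geometry", {
  d <- default_display()
  expect_equal(render_stimulus(stimulus_spec("none"), d,
                               present = FALSE)$values,
               matrix(0, 200, 200))
  small <- render_stimulus(stimulus_spec("small_inducers"), d,
                           present = FALSE)
  # 12 disjoint 15-px disks: the union pixel count equals the summed
  # per-disk counts, and every disk is non-empty
  disk_mask <- function(R, diam, n_ind, k) {
    th <- pi / 2 + 2 * pi * k / n_ind
    ctr <- c(99.5 - R * sin(th), 99.5 + R * cos(th))  # row, col, 0-based
    off <- 0:199
    outer(off, off, function(i, j)
      (i - ctr[1])^2 + (j - ctr[2])^2 <= (diam / 2)^2)
  }
  disks <- lapply(0:11, function(k) disk_mask(45, 15, 12, k))
  expect_true(all(vapply(disks, sum, 0L) > 0))
  expect_identical(sum(small$inducer_mask),
                   sum(vapply(disks, sum, 0L)))
  expect_identical(unname(which(small$inducer_mask)),
                   sort(unique(unlist(lapply(disks, which)))))
  expect_true(all(small$values[small$inducer_mask] == d$max_neg_contrast))
  large <- render_stimulus(stimulus_spec("large_inducers"), d,
                           present = FALSE)
  # 5 disks centered 60 px from the window center
  geom <- classim:::window_geometry(stimulus_spec("large_inducers"), d)
  comp <- which(large$inducer_mask, arr.ind = TRUE)
  centers <- t(vapply(seq_len(5) - 1, function(k) {
    th <- pi / 2 + 2 * pi * k / 5
    c(99.5 - 60 * sin(th), 99.5 + 60 * cos(th)) + 1  # row, col (1-based)
  }, numeric(2)))
  dmin <- apply(comp, 1, function(px)
    min(sqrt((px[1] - centers[, 1])^2 + (px[2] - centers[, 2])^2)))
  expect_true(all(dmin <= 55 / 2))
  # rendering is deterministic
  expect_identical(render_stimulus(stimulus_spec("small_inducers"), d, TRUE),
                   render_stimulus(stimulus_spec("small_inducers"), d, TRUE))
  # geometry that would cross the window border errors
  expect_error(stimulus_spec("large_inducers", center_to_center_px = 80),
               "border")
})

test_that("scale_to_energy rescales the non-inducer region exactly", {
  d <- default_display()
  spec <- stimulus_spec("small_inducers", target_contrast = -0.1)
  img <- render_stimulus(spec, d, present = TRUE)
  region_energy <- function(im)
    sum(im$values[!im$inducer_mask]^2) * pixel_area_deg2(d)
  e0 <- region_energy(img)
  expect_equal(scale_to_energy(img, e0, d)$values, img$values,
               tolerance = 1e-12)
  x4 <- scale_to_energy(img, 4 * e0, d)
  expect_equal(x4$values[!x4$inducer_mask],
               2 * img$values[!img$inducer_mask], tolerance = 1e-12)
  expect_identical(x4$values[x4$inducer_mask],
                   img$values[img$inducer_mask])
  for (target in c(0.3 * e0, 7 * e0)) {
    out <- scale_to_energy(img, target, d)
    expect_equal(region_energy(out), target, tolerance = 1e-10)
  }
  blank <- render_stimulus(spec, d, present = FALSE)
  expect_error(scale_to_energy(blank, 1e-5, d), "zero energy")
})

test_that("truncated noise fields have the stated bound, variance and law", {
  expect_identical(sample_noise_field(0, 32, seed = 1)$values,
                   matrix(0, 32, 32))
  f <- sample_noise_field(0.16, 200, seed = 2)
  expect_true(max(abs(f$values)) <= 2 * sqrt(0.16))
  # realised variance of +/-2 SD truncation: 0.774 * sigma^2
  x <- local({ set.seed(3); classim:::rtnorm_vec(1e6, sqrt(0.16), 2) })
  expect_equal(var(x), trunc_var_factor(2) * 0.16, tolerance = 0.005)
  expect_equal(trunc_var_factor(2), 0.7737, tolerance = 1e-4)
  # distributional check against the truncated normal CDF
  x5 <- local({ set.seed(4); classim:::rtnorm_vec(1e5, sqrt(0.16), 2) })
  ptrunc <- function(q) {
    lo <- pnorm(-2); hi <- pnorm(2)
    pmin(pmax((pnorm(q / 0.4) - lo) / (hi - lo), 0), 1)
  }
  expect_gt(suppressWarnings(ks.test(x5, ptrunc)$p.value), 0.01)
  # masked pixels stay zero; fixed seed reproduces the field
  mask <- matrix(FALSE, 64, 64); mask[10:20, 30:40] <- TRUE
  g1 <- sample_noise_field(0.16, 64, mask, seed = 9)
  g2 <- sample_noise_field(0.16, 64, mask, seed = 9)
  expect_identical(g1$values, g2$values)
  expect_true(all(g1$values[mask] == 0))
})

test_that("composition adds noise everywhere except the inducers", {
  d <- default_display()
  spec <- stimulus_spec("small_inducers", target_contrast = -0.3)
  stim <- render_stimulus(spec, d, present = TRUE)
  zero <- sample_noise_field(0, 200)
  expect_equal(compose_trial_image(stim, zero)$values, stim$values)
  noise <- sample_noise_field(0.16, 200, stim$inducer_mask, seed = 5)
  blank <- render_stimulus(spec, d, present = FALSE)
  blank$values[] <- 0; blank$inducer_mask[] <- FALSE
  expect_equal(compose_trial_image(blank, noise)$values, noise$values)
  comp <- compose_trial_image(stim, noise)
  expect_true(all(comp$values[stim$inducer_mask] == d$max_neg_contrast))
  expect_error(compose_trial_image(stim, sample_noise_field(0.16, 100)),
               "dimensions do not match")
})
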