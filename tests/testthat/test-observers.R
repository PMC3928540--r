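test_that("ideal decision rule equals the explicit Gaussian log-density difference", {
  set.seed(11)
  for (case in 1:50) {
    sigma2 <- runif(1, 0.05, 1)
    s <- matrix(rnorm(16, sd = 0.5), 4, 4)
    x <- matrix(rnorm(16, sd = sqrt(sigma2)), 4, 4) +
      if (runif(1) < 0.5) s else 0
    dec <- ideal_decide(x, s, sigma2)
    ll_present <- sum(dnorm(x, mean = s, sd = sqrt(sigma2), log = TRUE))
    ll_absent <- sum(dnorm(x, mean = 0, sd = sqrt(sigma2), log = TRUE))
    expect_equal(attr(dec, "lambda"), ll_present - ll_absent,
                 tolerance = 1e-9)
    expect_identical(as.character(dec),
                     if (ll_present - ll_absent > 0) "present" else "absent")
  }
  s <- matrix(c(0, 0.4, -0.2, 0.1), 2, 2)
  expect_identical(as.character(ideal_decide(s, s, 0.1)), "present")
  expect_identical(as.character(ideal_decide(0 * s, s, 0.1)), "absent")
  expect_error(ideal_decide(s, s, 0), "sigma2")
})

test_that("ideal yes/no accuracy matches the closed form Phi(d'/2)", {
  # template with ||s||^2 / sigma2 = 4, i.e. d' = 2 -> P(correct) = 0.841
  sigma2 <- 1
  s <- matrix(sqrt(4 / 64), 8, 8)
  n <- 1e4
  set.seed(21)
  correct <- logical(n)
  for (i in seq_len(n)) {
    pres <- i %% 2 == 0
    x <- matrix(rnorm(64), 8, 8) + if (pres) s else 0
    correct[i] <- (as.character(ideal_decide(x, s, sigma2)) == "present") ==
      pres
  }
  expect_equal(mean(correct), pnorm(1), tolerance = 0.01)
})

test_that("CSF filtering is linear, multiplicative and reduces to identity", {
  d <- default_display()
  flat <- csf_spec(low_frequency_attenuation = 0)
  set.seed(31)
  m <- matrix(rnorm(64^2), 64, 64)
  expect_equal(csf_filter(m, flat, d)$values, m, tolerance = 1e-10)
  csf <- default_csf()
  # impulse response equals the inverse transform of the gain (the PSF),
  # circularly centered on the impulse, and is center-surround shaped
  N <- 64
  imp <- matrix(0, N, N); imp[1, 1] <- 1
  out <- csf_filter(imp, csf, d)$values
  gain <- classim:::csf_gain_grid(csf, N, d)
  psf <- Re(fft(gain, inverse = TRUE)) / N^2
  expect_equal(out, psf, tolerance = 1e-10)
  expect_gt(out[1, 1], 0)
  expect_lt(min(out[1, ]), 0)  # opposite-sign surround lobe
  # filtering twice equals filtering once with the squared gain
  twice <- csf_filter(csf_filter(m, csf, d), csf, d)$values
  sq <- Re(fft(fft(m) * gain^2, inverse = TRUE)) / N^2
  expect_equal(twice, sq, tolerance = 1e-9)
})

test_that("the default CSF is band-pass with a steep high-frequency roll-off", {
  csf <- default_csf()
  fp <- csf$peak_frequency_cdeg
  expect_lt(csf_sensitivity(csf, 0), csf_sensitivity(csf, fp))
  f_hi <- seq(fp, 40, by = 0.5)
  expect_true(all(diff(csf_sensitivity(csf, f_hi)) < 0))
  expect_lt(csf_sensitivity(csf, 30) / csf_sensitivity(csf, fp), 0.05)
  expect_error(csf_spec(peak_frequency_cdeg = -2), "non-negative")
})

test_that("the CSF-limited ideal with a flat CSF reproduces the ideal observer", {
  spec <- stimulus_spec("small_inducers")
  flat <- csf_spec(low_frequency_attenuation = 0)
  r1 <- run_staircase(ideal_observer(), spec, n_trials = 400, seed = 7)
  r2 <- run_staircase(csf_ideal_observer(flat), spec, n_trials = 400,
                      seed = 7)
  expect_identical(r1$trials$response, r2$trials$response)
  expect_identical(r1$trials$energy, r2$trials$energy)
})

test_that("standalone CSF-ideal decisions behave sensibly", {
  d <- default_display()
  spec <- stimulus_spec("small_inducers", target_contrast = -0.05)
  csf <- default_csf()
  stim <- render_stimulus(spec, d, present = TRUE)
  obs_present <- csf_filter(stim, csf, d)  # zero-noise observation
  expect_identical(
    as.character(csf_ideal_decide(obs_present, spec, csf, d,
                                  sigma2 = 0.16)), "present")
  obs_absent <- csf_filter(render_stimulus(spec, d, present = FALSE),
                           csf, d)
  expect_identical(
    as.character(csf_ideal_decide(obs_absent, spec, csf, d,
                                  sigma2 = 0.16)), "absent")
  expect_error(csf_ideal_decide(obs_present, "small", csf, d, 0.16),
               "stimulus_spec")
})

test_that("the template observer responds to its criterion and internal noise", {
  spec <- stimulus_spec("small_inducers")
  tm <- center_surround_template(spec)
  expect_equal(sum(tm^2), 1, tolerance = 1e-12)
  x <- matrix(0, 200, 200)
  expect_identical(as.character(
    template_observer_decide(x, tm, 0, criterion = -Inf)), "present")
  expect_identical(as.character(
    template_observer_decide(x, tm, 0, criterion = Inf)), "absent")
  # with no internal noise the decision is deterministic in the stimulus
  set.seed(41)
  obs <- matrix(rnorm(200^2, sd = 0.4), 200, 200)
  d1 <- template_observer_decide(obs, tm, 0, criterion = 0.1)
  d2 <- template_observer_decide(obs, tm, 0, criterion = 0.1)
  expect_identical(as.character(d1), as.character(d2))
  # a far-positive criterion silences "present" responses
  set.seed(42)
  resp <- replicate(50, as.character(
    template_observer_decide(matrix(rnorm(400, sd = 0.4), 20, 20),
                             matrix(1 / 20, 20, 20), 0.01,
                             criterion = 50)))
  expect_true(all(resp == "absent"))
})

test_that("degenerate observers calibrate the staircase loop", {
  spec <- stimulus_spec("small_inducers")
  r <- run_staircase(oracle_observer(), spec, n_trials = 300, seed = 1)
  expect_true(all(r$trials$correct))
  # level decreases monotonically to the configured floor
  lev <- r$trials$energy
  expect_true(all(diff(lev) <= 0))
  st <- staircase_state(20 * pilot_ideal_energy())
  expect_equal(min(lev), st$start_level * st$step^st$k_min,
               tolerance = 1e-12)
  rc <- run_staircase(random_observer(), spec, n_trials = 2000, seed = 2)
  expect_equal(mean(rc$trials$correct), 0.5, tolerance = 0.04)
})
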