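---
title: "Methods: simulating and analysing detection-in-noise experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing detection-in-noise experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the model

The Ebbinghaus–Titchener figure — a central dot surrounded by a ring of
context ("inducer") disks — produces a robust size-contrast illusion: the
same central dot looks larger among small inducers than among large ones.
`classim` implements the information-processing side of this phenomenon: a
yes/no *detection* experiment in which the central dot, at low contrast, is
embedded in high-contrast pixel noise while the inducers remain noise-free,
and the reverse-correlation toolchain that turns thousands of such trials
into *classification images* — maps of the weight a decision process
assigns to each pixel.

All stimuli are defined as Weber contrast, $(L_{pixel}-L_{bg})/L_{bg}$, on
a square 200 × 200-px analysis window. The default display (38.25-cm-wide
1024 × 768 screen viewed from 130 cm) gives 0.01646 deg/px, so the 45-px
central dot subtends 0.74°, the 12 small inducers (15 px, ring radius
45 px) 0.25°, and the 5 large inducers (55 px, ring radius 60 px) 0.90°.
Stimulus intensity is **contrast energy**

$$E = \sum_i C_i^2\, a,$$

the sum of squared pixel contrasts times the pixel area $a$ in squared
degrees ($a \approx 2.71\times10^{-4}$ deg² here).

Pixel noise is zero-mean Gaussian with nominal variance $\sigma^2 = 0.16$;
samples beyond ±2 SD are rejected and redrawn, which keeps the noise
displayable and reduces the realised variance to
$1 - 2c\,\phi(c)/(2\Phi(c)-1) \approx 0.774\,\sigma^2$ at $c = 2$
(`trunc_var_factor()`). Inducer pixels are always noise-free at the
display's maximum negative contrast (−0.87).

## Observers

Three decision models drive the simulated trial loop:

* **Ideal observer.** With equal priors and known additive signal $s$ in
  white Gaussian noise, the posterior-maximizing rule is the likelihood
  ratio test $\Lambda = (\langle x, s\rangle - \|s\|^2/2)/\sigma^2 > 0$.
  The inducers are identical under both hypotheses, so the likelihood is
  restricted to non-inducer pixels. Ties ($\Lambda = 0$, a measure-zero
  event) respond "absent" for determinism. Its proportion correct has the
  closed form $\Phi(d'/2)$, $d'^2 = \|s\|^2/\sigma^2_{\mathrm{eff}}$, which
  the tests use as an oracle and `pilot_ideal_energy()` uses to place the
  staircase start.
* **CSF-limited ideal observer.** Identical, except that the noise-free
  signal (with inducers) and the noise-free dot template (without
  inducers) are first filtered in the frequency domain by a contrast
  sensitivity function; unfiltered noise is then added and the filtered
  template computes the likelihoods. The paper this design follows does not
  state how the (hypothesis-independent) filtered inducer background enters
  the likelihood; we subtract it before the decision, the exact analogue of
  the ideal observer's cancellation of the inducer pixels. Without the
  subtraction a constant bias $\langle b, s\rangle/\sigma^2$ would shift
  the criterion without changing the classification-image structure.
* **Linear template observer.** Responds "present" iff
  $\langle x, T\rangle + \varepsilon >$ criterion, with unit-norm template
  $T$ (default: a center-surround pattern, negative over the dot, positive
  in a surrounding annulus out to 35 px) and internal noise
  $\varepsilon \sim N(0, \sigma^2_{int})$. The default criterion is the
  "midpoint" rule (half the expected signal response at the current
  staircase level), which keeps the observer unbiased as the staircase
  moves; the default internal noise SD is half the external decision-
  variable SD, giving a human-like efficiency well below 1. This observer
  is the configurable stand-in for human data in parameter-recovery tests.

### The CSF parametric form

The exact sensitivity values of the adult foveal CSF are not reproduced in
the source material (it defers to a cited fit), and only qualitative
center-surround predictions are claimed, so `default_csf()` uses a
standard four-parameter band-pass form
$S(f) = k\,(f/f_p)^a \exp\{(a/r)(1-(f/f_p)^r)\}$ peaking at
$f_p = 4$ c/deg with $a = r = 1$: low-frequency attenuation ($S(0)=0$), a
steep roll-off ($S(30)/S(f_p) \approx 0.01$), all parameters overridable.
The filter is normalized to unit peak gain so it never amplifies; absolute
sensitivity folds into $\sigma^2$. Because $S(0) = 0$ the filtered dot is
mean-zero, which is what produces the opposite-sign annulus ("ringing")
outside the dot edge in the CSF-limited observer's templates and hence in
its classification image — the qualitative signature the acceptance suite
checks against the flat-CSF ideal.

## The trial loop and thresholds

`run_staircase()` draws target presence with probability 0.5 per trial,
scales the dot so the non-inducer region's contrast energy equals the
current staircase level, composes it with fresh truncated noise, queries
the observer, and updates a 2-down/1-up staircase. The source experiments
do not state the staircase's step rule; we use multiplicative 1-dB steps
on energy (down after two consecutive correct, up after each error),
starting at 20 × the analytic ideal threshold with a wide floor/ceiling.
The 2-down/1-up convergence point ($\sqrt{1/2} \approx 70.7\%$ correct,
printed as 71%) is independent of these choices, which is why thresholds
are step-rule-robust. Levels are tracked as an integer step index so every
visited level is exactly representable and trials pool exactly for the
fit.

Thresholds come from maximum-likelihood Weibull fits
$P(\mathrm{correct}\mid E) = \gamma + (1-\gamma-\lambda)
(1-e^{-(E/\alpha)^\beta})$ with $\gamma = 0.5$ (yes/no chance) and
$\lambda = 0.01$ fixed (the source states neither; these are standard),
inverted in closed form at 71% correct. Bootstrap SDs use 500 trial
resamples by default. **Efficiency** is the ratio of ideal to observer
threshold.

Absent trials carry the prevailing staircase level in their `energy`
field, so the trial log is complete and classification sorting is
well-defined.

## Classification images

With the four stimulus–response cells (S present/absent × R
present/absent), the classification image is the cell-mean combination

$$C = (\bar N_{S^-R^+} + \bar N_{S^+R^+}) -
      (\bar N_{S^-R^-} + \bar N_{S^+R^-}),$$

computed on the **raw noise fields only**. Whether the present-trial cells
should average noise or signal-plus-noise is not stated in the source; we
use noise alone, the standard practice consistent with "sorting the
noise", and the choice the staircase's varying signal contrast would
otherwise bias. Cell means are unweighted, so unequal cell sizes do not
bias the combination, and pooled sessions combine exactly
(`combine_runs()`).

Reductions and display:

* `radial_average()` — bins 1..99 px by integer-rounded Euclidean distance
  from the window center at $((N-1)/2, (N-1)/2)$, non-inducer pixels only.
  The 99-bin convention (center pixel excluded, radii beyond 99 dropped)
  is the only one consistent with the reference numerator degrees of
  freedom on a 200-px window.
* `spectral_profile()` — 2-D FFT, squared modulus, annular bins one DFT
  sample wide up to Nyquist (≈ 30.4 c/deg here), with the Parseval sum
  attached for verification; `peak_frequency()` locates the maximum.
* `smooth_image()` — 7 × 7 uniform kernel (≈ 0.11° × 0.11°) with
  renormalized partial kernels at edges.
* `infill_inducers()` — for display only, masked pixels are replaced with
  noise matched to the non-masked mean/SD, so the rendered image cannot
  itself induce the illusion; analysis never consumes in-filled images.

Error bands: `bootstrap_profiles()` resamples trials with replacement
(default 500 replicates) and smooths each replicate's radial profile with
a width-5 uniform kernel (the source says only "a convolution kernel");
`null_band()` keeps the recorded stimulus–response labels but redraws
every trial's noise (default 200 replicates), giving the ±2 SD gray band a
label-independent process would produce. The literal per-pixel
re-sampling is the default for small problems; for large runs a
`"gaussian"` method draws each bin-by-cell mean from its exact-variance
normal law — each such mean pools thousands of bounded i.i.d. deviates, so
the approximation error is far below the band's own Monte-Carlo error (the
two paths are compared in the test suite). At the reference scale (10⁴
trials × 200 replicates ≈ 6 × 10¹⁰ deviates) the literal path is not
affordable, which is why the fast path exists.

## Hotelling tests

Profile-level significance uses per-trial vectors: each trial's 99-bin
radial noise average signed by its response (+1 "present", −1 "absent").
The source does not spell this construction out; it follows the
classification-image testing literature, and its correctness anchor is the
exact identity that with equal cell sizes the vector mean is one quarter of
the radial classification profile (tested on fixtures). One-sample:
$T^2 = n\,\bar v' S^{-1} \bar v$, $F = T^2(n-p)/(p(n-1))$ on $(p, n-p)$
df — hence df₂ = 9901 for one 10⁴-trial session and 29901 for three pooled.
Two-sample: pooled covariance, $F = T^2(n_1+n_2-p-1)/(p(n_1+n_2-2))$ on
$(p, n_1+n_2-p-1)$ df — 19900 and 59900 for the corresponding comparisons.
Covariance solves are guarded by a reciprocal-condition-number check
(abort below 10⁻¹²).

## Synthetic data: what it does and does not establish

`generate_experiment()`/`generate_benchmark_suite()` produce complete
archived sessions with the reference trial structure: 10⁴ trials per
condition, σ² = 0.16, ±2 SD truncation, staircase-controlled energy,
half-present trials, and per-trial noise recoverable bit-exactly from
stored seeds. Archives are plain text (CSV + JSON).

The generator emulates the *statistical* structure human data would have
under a given decision model. It does not emulate sequential dependencies,
learning, lapses beyond the fixed rate, response times, or the unknown
human front end — so a green pipeline establishes that the analysis
recovers the properties of the stated observer models (and would recover a
human-like center-surround strategy if present), not that humans behave
like any of them. Human-scale numbers (thresholds ≈ 10× ideal, ~10%
efficiencies, the ~6 vs ~9 c/deg spectral peaks) require human data and are
deliberately not acceptance targets; the template observer is tuned only
to be qualitatively human-like (sub-ideal, center-surround).

## Numerical and design choices

* Small-angle pixel→degree conversion (arc length / distance): reproduces
  every printed stimulus size to within 0.01°; the arctangent form differs
  only in the fourth decimal at these sizes. The printed sizes themselves
  mix rounding and truncation (60 px → 0.9878° prints as 0.98), so exact
  printed-digit equality is not attainable for every value and agreement
  is defined as |difference| < 0.01°.
* Disk rasterization is binary (pixel center inside radius), keeping
  energy bookkeeping exact; no anti-aliasing.
* The first inducer sits at 90° (top); no statistic depends on the phase.
* The printed noise spectral density of the source (2.7e−4) is internally
  inconsistent with σ²·a and numerically equals the pixel area; σ² and a
  are stored separately and the printed NSD is never used.
* Rejection sampling of the truncated noise uses R's RNG inside C++, so
  every field is reproducible from a stored integer seed across platforms;
  run archives therefore store seeds, not fields (fields can additionally
  be kept with `keep_noise = TRUE`).
* Weibull fits are Nelder-Mead on (log α, log β) with explicit
  non-convergence errors; degenerate (all-correct) data error immediately.
* `radial_average()` errors on empty bins rather than returning NA, and
  `classification_image()` names any empty stimulus-response cell.

## Known limitations

* No luminance calibration, gamma, or monitor timing; contrasts below
  −0.87 are not clipped at extreme staircase levels (they do not occur in
  the shipped scenarios).
* No oriented (V1-like) front ends, parafoveal sensitivity variation, or
  cortical magnification in the CSF observer.
* The CSF parameter values are generic adult-foveal defaults, not a fit to
  any observer; only qualitative CSF signatures should be read from them.
* 2-D pixel-cluster significance maps are out of scope; inference on
  images is via the radial profiles.
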