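---
title: "Methods: spectral containers, preprocessing pipelines, and unmixing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spectral containers, preprocessing pipelines, and unmixing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ramanspec)
```

# The data model

Raman measurements arrive as single spectra, stacks of spectra, image scans,
or volumetric scans. `ramanspec` represents all of them with one container:
an intensity array whose **last** axis is spectral, paired with a wavenumber
axis in cm^-1^. The kind (`spectrum`, `spectra_stack`, `image`, `volume`) is
inferred from the number of leading spatial dimensions; at most three are
supported, since no common acquisition modality has more.

Two normalizations happen at construction and nowhere else:

* the wavenumber axis is stored strictly increasing — instruments that write
  descending axes are accommodated by reversing axis and intensities
  together, and the reversal is an involution;
* non-finite intensities are rejected, unless `nan_policy = "zero"` converts
  them (with a warning), which accommodates vendor exports with masked
  pixels.

Every analysis routine works on the flattened `N x B` matrix view
(`flatten_container()`), with spatial positions enumerated row-major. The
flatten/unflatten pair round-trips bit-exactly, so per-spectrum operations
applied to an image are identical to the same operations applied row-wise.

# Preprocessing methods and their parameters

All preprocessing maps container to container, independently per spectrum.
Parameters below are the package defaults; every one is recorded explicitly
in serialized pipelines so that a saved protocol is fully concrete.

**Cropping.** `crop_spectra(x, 700, 1800)` retains the biological
fingerprint region inclusively on both bounds.

**Cosmic-ray removal** (`despike_whitaker_hayes`). First differences of each
spectrum are scored with the modified z-score
$Z_i = 0.6745\,(d_i - \mathrm{med}(d))/\mathrm{MAD}(d)$; bands with
$|Z_i| > 6.5$ are replaced by the mean of unflagged neighbours within a
5-band window (linear interpolation if the window holds none). The default
threshold is deliberately conservative (low false-positive). Two numerical
edge cases are fixed: a zero MAD with non-constant differences falls back to
the mean absolute deviation, and a constant spectrum passes through
untouched. A known operating characteristic: on *noise-free* spectra the MAD
collapses toward the discretization scale and genuine band edges can be
flagged — the method's false-positive contract is only meaningful on data
with measurement noise, which is how the recall/false-alteration tests are
posed.

**Denoising.** Savitzky–Golay (`polyorder = 3`, `window = 7`) fits a
least-squares polynomial in a sliding window; edge samples come from the
one-sided polynomial fits, and polynomials up to the filter order are
reproduced exactly at interior points (this is tested to 1e-10). The
Gaussian filter (`sigma_bands = 1`) convolves with a unit-sum kernel
truncated at 4 sigma under reflect padding.

**Baseline correction.** Autofluorescence baselines are estimated by
penalized least squares on the Whittaker second-difference penalty,
$\sum_i w_i (y_i - z_i)^2 + \lambda \sum_i (\Delta^2 z)_i^2$, solved
sparsely per spectrum. ASLS iterates the asymmetric weights $w_i = p$ if
$y_i > z_i$, else $1 - p$ (defaults $\lambda = 10^5$, $p = 0.01$, at most 30
iterations, stopping when fewer than 0.1% of weights change). asPLS replaces
them with residual-driven logistic weights
$w_i = 1/(1 + e^{2(r_i - \sigma_-)/\sigma_-})$, where $\sigma_-$ is the
standard deviation of the negative residuals, plus a per-point penalty
scaling $\alpha_i = |r_i|/\max|r|$; a vanishing $\sigma_-$ terminates
(perfect fit). Lines lie in the null space of the penalty and are removed
essentially exactly; cubic baselines leave sub-percent residuals at
realistic spectral lengths (~1000 bands). Non-convergence at the iteration
cap returns the best iterate with a warning rather than failing. One
consequence worth knowing: with small $p$, the ASLS baseline tracks the
*lower envelope* of the noise, so baseline-corrected noisy spectra carry a
positive offset of roughly twice the residual noise level.

**Normalization** offers global min–max to [0, 1], per-spectrum min–max,
and per-spectrum area normalization (trapezoidal integral set to 1).
**Background subtraction** requires exact axis equality; resampling is out
of scope by design, so disagreement is an error and never silent.

# Pipelines

A pipeline is an ordered list of registered steps with parameters; applying
it is strict left-to-right composition, bit-identical to chaining the
operations manually, and deterministic. Pipelines serialize to JSON
(`format_version` "1", canonical key order, doubles at 17 significant
digits so round trips are bit-exact); custom steps serialize by registered
name only — shared protocol files can never carry executable code. Two
named protocols ship in the registry: `cell_phenotyping` (crop 700–1800,
despike, SG(3, 7), ASLS, global min–max) and `pipeline_I` (crop 700–1800,
despike, Gaussian, ASLS, per-spectrum area normalization). Protocols whose
step lists are not fully specified are deliberately not shipped; asking for
one is an error rather than a guess.

# Unmixing

The linear mixing model writes every pixel spectrum as a convex combination
of $K$ pure-component endmember spectra. `nfindr()` searches for the $K$
observed pixels whose simplex has maximal volume in the mean-centred PCA
projection to $K - 1$ dimensions (the projection method is the package's
choice; PCA is the standard one). The search makes full passes over
endmember slots and pixels, accepting only strictly volume-increasing swaps
(ties keep the incumbent, for determinism), iterates to convergence, and
keeps the best of `n_restarts = 10` seeded random starts — the search is
initialization-dependent, and on small instances the multi-restart optimum
matches exhaustive search (tested against a brute-force oracle). N-FINDR is
only correct under the pure-pixel assumption; the synthetic generator
therefore plants pure pixels by default, and the no-pure-pixel regime
should be read as expected degradation, not failure.

`fcls()` estimates abundances per pixel under nonnegativity and sum-to-one
constraints by augmenting the design with a heavy sum-to-one row
($\gamma = 10^3 \times$ the largest endmember column norm), solving with a
Lawson–Hanson active-set nonnegative least-squares solver implemented in
the package, and renormalizing exactly. On noiseless mixtures of
full-rank endmembers the recovered abundances are exact to machine
precision; the constraints hold on every pixel by construction.

# Spectral metrics

`mse`, `sad` (arccos of the normalized inner product, clamped; radians) and
`sid` (symmetrized KL divergence of sum-normalized spectra) support
denoiser and unmixing validation. SID uses natural logarithms (nats), an
`1e-12` floor under both normalized vectors, and a min-shift policy for
negative intensities (baseline-corrected spectra can dip below zero) — all
stated so reports are reproducible. `metric_report` reports per-spectrum
values, their mean, and the standard deviation of the sample mean, the
error-bar convention used in method-comparison figures.

# The synthetic scene generator

`gen_scene()` emulates what the analysis chain must survive:
peak-structured endmembers (sums of Gaussian and Lorentzian bands with
random centres in 700–1800 cm^-1^, widths 4–20 cm^-1^, resampled until all
pairwise spectral angles exceed 0.25 rad), symmetric-Dirichlet abundances
(concentration 0.5 — moderately sparse mixtures) with planted pure pixels,
a shared smooth polynomial baseline (degree 3, ±10% per-pixel scale
variation), Bernoulli cosmic spikes, and additive Gaussian noise. All
randomness flows from one seed.

Design choices worth making explicit:

* **Unit-area endmembers** (default). Under the mixing model, per-spectrum
  area normalization preserves abundance fractions only when endmember
  integrals are equal; unit-area pure components are the standard
  chemometrics convention and make generator ground truth directly
  comparable to abundances estimated from area-normalized data.
* **Amplitude scale.** Baseline amplitude (0.5), spike amplitudes (3–8) and
  noise sigma (0.05) are expressed as fractions of the clean scene's global
  intensity range, so one configuration means the same contamination at any
  absolute intensity scale.
* **Low-SNR emulation** (`paper_noise = TRUE`) reproduces the distinct
  contamination order used to build low signal-to-noise test sets:
  per-spectrum min–max to [0, 1] first, then Gaussian noise (0.15 there);
  the ground-truth bundle retains the pre-noise spectra so residual noise
  levels can be verified in distribution.
* The model is strictly linear (no nonlinear mixing, no instrument response,
  no Poisson shot noise) — intentionally, since N-FINDR and FCLS assume
  linearity; passing tests demonstrate correctness under the model, not
  robustness to physics the generator does not emulate.

# Validation scope and problem sizes

The test suite and the acceptance script validate on sizes chosen to
exercise the mathematics well while staying quick to rerun: 500-pixel FCLS
problems at K = 4, B = 300; twenty 33-pixel N-FINDR instances checked
against exhaustive search; a 20×20, 650-band contaminated scene for the
end-to-end chain; 1000-spectrum batches for despiking characteristics and
the noise-protocol check. One honest negative result is worth recording:
on the contaminated end-to-end scene, abundances are recovered within a
0.05 RMSE, but the mean spectral angle of recovered endmembers to the raw
ground truth stays near 0.22 rad — decomposition shows ~0.12 rad comes from
residual broadband noise that a 1-band Gaussian filter cannot remove from
sparse peaky spectra, and most of the rest from the ASLS lower-envelope
offset described above. That figure reflects the preprocessing defaults,
not the unmixing, and the corresponding check is left failing rather than
loosened.
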