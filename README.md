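# ramanspec

An R toolkit for integrative Raman spectroscopy data analysis, for
spectroscopists and chemometricians who need reproducible preprocessing
protocols and hyperspectral unmixing outside of vendor software.

Raman spectra carry molecular fingerprints (most biological information sits
in the 700–1800 cm⁻¹ region), but raw measurements are contaminated by
cosmic-ray spikes, autofluorescence baselines and detector noise, and every
lab tends to preprocess them differently. `ramanspec` addresses this with:

* **one spectral container** for single spectra, spectra stacks,
  hyperspectral images and volumetric scans — an intensity array with the
  wavenumber axis last, normalized to increasing wavenumbers at
  construction;
* **a preprocessing suite**: cropping, Whitaker–Hayes cosmic-ray removal
  (modified z-scores on first differences), Savitzky–Golay and Gaussian
  denoising, ASLS/asPLS baseline correction (penalized least squares with
  asymmetric or adaptive weights), min–max and area normalization,
  background subtraction;
* **serializable pipelines**: ordered, named steps with fully resolved
  parameters, saved as JSON and reapplied bit-identically; a registry of
  named protocols (`cell_phenotyping`, `pipeline_I`) plus user-registered
  custom steps;
* **spectral unmixing** under the linear mixing model
  `y = Σₖ aₖ eₖ` (`aₖ ≥ 0`, `Σ aₖ = 1`): N-FINDR endmember extraction
  (maximum simplex volume over observed pixels in a PCA projection, with
  seeded multi-restart search) and FCLS abundance estimation (Lawson–Hanson
  nonnegative least squares on a sum-to-one–augmented system);
* **metrics** — MSE, spectral angle distance (SAD), spectral information
  divergence (SID) — with per-spectrum reports (mean ± SEM);
* **I/O**: delimited text, MATLAB MAT-file (v5) exports, a native HDF5
  layout, pipeline JSON;
* **a synthetic scene generator** with full ground truth (peak-structured
  endmembers, Dirichlet abundances with planted pure pixels, smooth
  baselines, sparse spikes, Gaussian noise), so the whole chain is testable
  without instrument data;
* **a CLI** (`simulate`, `preprocess`, `unmix`, `metrics`, `slice`) whose
  every run writes a provenance sidecar sufficient to reproduce it.

## Worked example

Simulate a contaminated 20×20 Raman image, preprocess it with the shipped
`pipeline_I` protocol, unmix it, and compare against the generator's ground
truth:

```r
library(ramanspec)

scene <- gen_scene(scene_config(spatial_shape = c(20, 20), k = 4, seed = 7))
scene$container
#> <spectral_container: image, 20 x 20 x 650, 650 bands, 600.0-1900.0 cm^-1>

pre <- pipeline_apply(get_protocol("pipeline_I"), scene$container,
                      verbose = TRUE)
#> [1/5] crop: 20x20x650 -> 20x20x550 (0.059s)
#> [2/5] despike_wh: 20x20x550 -> 20x20x550 (0.106s)
#> [3/5] gaussian: 20x20x550 -> 20x20x550 (0.061s)
#> [4/5] asls: 20x20x550 -> 20x20x550 (7.262s)
#> [5/5] normalize: 20x20x550 -> 20x20x550 (0.029s)

res <- unmix_scene(pre, k = 4, seed = 7)
res$endmembers
#> <endmember_set: K=4, B=550, simplex volume 1.08183e-05>

keep <- scene$truth$axis >= 700 & scene$truth$axis <= 1800
m <- match_endmembers(res$endmembers, scene$truth$endmembers[, keep])
est <- apply(res$abundances, 3, function(s) as.numeric(t(s)))[, m$order]
tru <- apply(scene$truth$abundances, 3, function(s) as.numeric(t(s)))
sqrt(mean((est - tru)^2))
#> [1] 0.03354346   # per-pixel abundance RMSE vs ground truth
mean(m$sad)
#> [1] 0.2390689    # mean endmember spectral angle vs ground truth (rad)

band_slice(pre, 1008)$wavenumber   # protein-associated band
#> [1] 1008.6287
```

The abundance maps recover the ground truth within a few percent. The
endmember spectral angle is dominated by residual noise and the ASLS
baseline offset left by the preprocessing defaults — the methods vignette
(`vignettes/raman-analysis-methods.Rmd`) quantifies this decomposition and
documents every default and design choice.

The same chain is available from a shell:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "ramanspec.R", package = "ramanspec"))')" \
  preprocess --input scene.h5 --pipeline pipeline_I --out pre.h5
```

Each CLI command writes `<output>.provenance.json` (resolved parameters,
input checksums, tool version); rerunning from a sidecar reproduces the
output bit-exactly.

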