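---
title: "Label-free protein SERS diagnostics for NPC: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Label-free protein SERS diagnostics for NPC: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The problem

Blood-plasma proteins carry compositional and conformational signatures of
nasopharyngeal carcinoma (NPC). Label-free surface-enhanced Raman scattering
(SERS) of purified plasma protein produces a fingerprint spectrum
(400–1800 cm⁻¹) whose band intensities shift between healthy subjects and
NPC patients, and, for some bands, between the four TNM stages. `sersnpc`
implements the complete desk-scale analysis around this idea: a synthetic
cohort generator that emulates the statistical structure of such spectra,
the preprocessing chain used on real instruments, nonparametric per-band
statistics, and two classifiers — a one-dimensional convolutional neural
network (CNN) and a PCA-LDA chemometric baseline.

Because no clinical spectra are publicly deposited, everything here runs on
simulated cohorts; the generator is first-class, tested code and its
defaults *are* the study conditions.

## The synthetic cohort generator

A class mean is a sum of 24 Lorentzian bands
$L(\nu) = A\,\gamma^2/((\nu-\nu_0)^2+\gamma^2)$ at the fingerprint shifts
of plasma-protein SERS (490–1679 cm⁻¹), FWHM $2\gamma$ = 10 cm⁻¹ (slightly
above the 8 cm⁻¹ instrument resolution; Raman lines are near-Lorentzian).
Base amplitudes are chosen so the four strongest bands sit at 1003, 1266,
1449 and 1679 cm⁻¹, with the global maximum at the phenylalanine
ring-breathing band near 1003 cm⁻¹.

Class structure enters through two multiplicative rules:

* **screening shift** — every *affected* band (9 up-regulated, 13
  down-regulated, 2 unaffected) is scaled by $1 \pm e$ for any NPC class;
  default effect size $e = 0.15$;
* **stage trend** — the phenylalanine bands at 1003 and 1033 cm⁻¹ carry a
  linear trend $1 + 0.05\,s$ for stage $s \in \{1,2,3,4\}$, on top of the
  pooled shift.

A subject's spectrum is the class mean with per-band lognormal variation
(sdlog 0.10), plus a random non-negative 5th-order polynomial fluorescence
baseline (amplitude 0.5–2 × the maximum band height — fluorescence
typically dominates raw SERS counts), times a global lognormal scale
(sdlog 0.15, emulating laser-power and concentration variation), plus
additive Gaussian noise (sd 1% of the scaled maximum band height), clipped
at zero. The default cohort is 225 healthy / 120 + 249 + 291 + 279 staged
subjects = 1164 spectra, one per subject. Subject $i$ draws from substream
`seed + i`, so cohorts are reproducible and order-independent.

Where the underlying study reports only directions and significance stars,
the effect magnitudes above are the package's own choices, made once: they
are calibrated so that the configured directions are recovered with
p < 0.01 at n = 100/100 and the stage trend is visible in median ordering —
not so that any particular classifier accuracy is reached.

What the generator does *not* emulate: band-position (calibration) drift,
cosmic-ray spikes, heteroscedastic detector noise, correlated band
chemistry (each band varies independently), and any real biological overlap
structure between stages. Tests passing on these simulations therefore
validate the pipeline's mechanics and statistical calibration, not clinical
performance.

## Preprocessing

**Baseline.** The fluorescence background is removed with the iterative
*improved modified polynomial* fit (I-ModPoly): fit a 5th-order polynomial,
compute the residual standard deviation DEV, drop clear peak points
(intensity > fit + DEV) once, then repeatedly clamp the working data at
fit + DEV and refit until DEV changes by less than 1% (at most 100
iterations). The fit uses a shift axis rescaled to [−1, 1] (raw cm⁻¹ powers
up to 5 are badly conditioned). DEV uses the sample (n−1) standard
deviation; iteration counts and convergence are logged per spectrum.
Stopping constants (tol 0.01, max_iter 100) follow the algorithm's common
usage; the source method names no constants.

Negative residuals after subtraction are clipped to zero (spectra are
treated as non-negative relative intensities) and the number of clipped
points is logged.

One honest limitation, quantified in the acceptance tests: with 24
overlapping Lorentzian bands, the polynomial absorbs part of the band-tail
pedestal, so per-band areas after correction are typically within ~4% but
can be distorted by tens of percent for weak bands flanked by strong ones.
For an isolated band the recovered area is within 5%. This is a property of
polynomial baselines on dense spectra, not of the implementation — the
production fit matches an independently coded naive reference loop to
1e-12 in final DEV.

**Normalization.** Each corrected spectrum is divided by its trapezoidal
integral over 400–1800 cm⁻¹, so the area under every spectrum equals 1 and
"absolute" becomes "relative" intensity. This makes the pipeline exactly
invariant to global multiplicative scale.

A second preprocessing pass changes spectra by a further 1–2.5% in L1 (the
noise-floor polynomial is re-estimated and the area renormalized); the
pipeline applies it once.

## Per-band statistics

Band intensities are read as the local maximum within ±4 cm⁻¹ of the
nominal shift (robust to ≤ half-FWHM calibration offsets; window 0 reads
the nearest grid point). Healthy vs pooled-NPC contrasts use the two-sided
Mann-Whitney U test (exact when both groups ≤ 20 and tie-free, otherwise
the tie-corrected normal approximation); stage contrasts use Kruskal-Wallis
with tie correction. Stars follow the strict conventions ns / * / ** / ***
/ **** at 0.05 / 0.01 / 0.001 / 0.0001, left-closed (p = 0.05 is ns). No
multiple-testing correction is applied by default — stars are reported
per band — but a Bonferroni column is available. Repeatability is
summarized as RSD = 100·sd/mean over replicate spectra.

## The CNN

The five-block architecture: per block, two stacked 1-D convolutions
(kernel 3, stride 1, same padding, tanh) followed by max-pooling
(window 3), with 16/32/64/128/256 kernels across blocks; then flatten, one
fully connected tanh layer (width 64 — the source names no width; 64 is a
configurable choice), and a 5-way softmax. Training: Adam (lr 0.001,
β₁ 0.9, β₂ 0.999), cross-entropy, 100 epochs, batch 20, seeded shuffling.
Weights are Glorot-uniform; all randomness comes from R's RNG, so training
is bit-deterministic given the seed and thread count.

Two deliberate engineering choices:

* **Pooling stride.** The printed architecture pools with stride 1, which
  barely downsamples: the flattened layer is then 691 × 256 ≈ 177k wide
  (~11M parameters in the first dense layer), untrainable at desk scale on
  a CPU. The default `cnn_spec()` keeps stride 1 exactly as printed (and
  the architecture audit checks it); all *training experiments* in this
  package use the conventional non-overlapping variant `pool_stride = 3`,
  which yields a 2 × 256 flatten at 701 input points. The flag is part of
  the spec object so either variant can be requested.
* **Input scaling.** Unit-area spectra have O(10⁻³) intensities, which
  starves a ten-layer tanh stack of signal (training stalls at the
  class-prior solution). `train_cnn` therefore standardizes intensities
  with the training set's global mean and standard deviation, stores both
  in the model, and re-applies them at prediction time.

Training curves (per-epoch loss and accuracy over the training batches,
Keras-style running averages) are returned with the model. Evaluation
reports a 5×5 confusion matrix, class-wise recall ("per-class accuracy"),
and overall accuracy. Stratified seeded k-fold cross-validation is
provided. The backpropagation engine is RcppArmadillo; convolutions are
im2col + GEMM over mini-batches.

At the generator's default effect sizes the healthy class separates
essentially perfectly while the four stages overlap strongly — the only
stage information is the 5%-per-stage trend on two bands against 10%
per-band subject variation (adjacent-stage d′ ≈ 0.7). The acceptance suite
records both facts: healthy-class recall meets its bound, overall staging
accuracy is measured and compared against the design target it cannot
reach under these conditions, and a null-effect cohort drops the classifier
to chance (~20%).

## PCA-LDA comparator

Mean-centered PCA on the training spectra, retaining 20 components
(configurable; the source names no count), then multi-class LDA on the
scores via `MASS::lda`, with per-sample coordinates on the first two
discriminant axes exposed for plotting. The PCA basis is fitted on the
training set only. If the within-class scatter is singular (tiny cohorts,
constant score directions), the fit falls back to an LDA with a 1e-6 ridge
on the pooled within-class covariance; the fallback is flagged on the
model object.

## Pipeline and reproducibility

`stratified_split` draws seeded per-class samples without replacement; the
default plan reserves 45/24/48/57/54 test spectra (228) and trains on 936,
matching the study's 80/20 design (the printed per-class counts are taken
verbatim rather than recomputing "about 80%"). `run_all` chains
simulate → preprocess → split → statistics → CNN → PCA-LDA under one
master seed and writes every artifact (CSV/TSV/JSON) plus a run report
sufficient to re-run the analysis.

Problem sizes used by the shipped experiments: unit tests run on coarse
grids (4–8 cm⁻¹ spacing, tens of spectra); the acceptance experiments run
the full 1164-spectrum cohort at the default 2 cm⁻¹ grid, training 30
epochs (the 100-epoch run — the default of `analysis/04_classify.R` —
reaches 100% training accuracy by epoch 60 and the same test-set
conclusions); the statistical calibration checks use 200 null seeds
(type-I error), 20 seeds at n = 100/100 (direction recovery) and 100
seeds at n = 50/stage (trend ordering). Replicate seeds are spaced by
1000 because each subject draws from substream seed + index.

## Known limitations

* Simulated spectra only; no claim of clinical performance transfers.
* Per-band area fidelity after polynomial baseline removal degrades for
  weak bands in crowded regions (see above).
* The CNN is CPU-only and single-threaded deterministic; no early
  stopping, no hyperparameter search, no saliency tools.
* CSV is the only spectral format; vendor binary formats are out of scope.
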