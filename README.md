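# sersnpc

Desk-scale analysis of label-free blood-protein SERS spectra for cancer
screening and staging, built around a five-class design: healthy controls
plus nasopharyngeal carcinoma (NPC) stages I–IV.

Plasma-protein SERS spectra over the 400–1800 cm⁻¹ fingerprint region show
reproducible band-intensity shifts with NPC: tryptophan and phenylalanine
bands (e.g. 1003, 1033 cm⁻¹) rise, arginine/tyrosine/glutathione bands
(e.g. 490, 625, 1180 cm⁻¹) fall, and the phenylalanine bands trend upward
with stage. Since no clinical spectra are deposited anywhere, the package
ships a tested synthetic cohort generator with exactly this structure and
runs the full analysis chain on it:

* **Simulation** — 24 Lorentzian protein bands (FWHM 10 cm⁻¹), per-band
  class effects (±15% pooled NPC shift on 22 affected bands; +5% per stage
  on the two phenylalanine bands), lognormal subject variation, polynomial
  fluorescence baseline, lognormal intensity scale, additive noise.
  Default cohort: 225/120/249/291/279 subjects = 1164 spectra.
* **Preprocessing** — fifth-order iterative improved modified polynomial
  (I-ModPoly) background subtraction, then area normalization so each
  spectrum integrates to 1 over 400–1800 cm⁻¹:
  `Ĩ(ν) = I(ν) / ∫ I(ν) dν`.
* **Statistics** — per-band intensities (local max within ±4 cm⁻¹),
  two-sided Mann-Whitney U (healthy vs pooled NPC), Kruskal-Wallis across
  stages, significance stars, difference spectra, RSD repeatability.
* **Classification** — a 1-D CNN (5 blocks of two conv(3)+tanh layers with
  16/32/64/128/256 kernels and max-pooling, dense tanh layer, softmax;
  Adam, cross-entropy, 100 epochs, batch 20, lr 0.001) written in
  RcppArmadillo with full backpropagation, plus a PCA-LDA comparator
  (20 components, `MASS::lda`), both evaluated on a stratified 936/228
  train/test split with per-class recall and confusion matrices.

## Worked example

The repository is organised as a numbered workflow under `analysis/`
(large per-spectrum CSVs go to `scratch/`, small tables to `results/`):

```sh
Rscript analysis/01_simulate.R 1      # seed 1
Rscript analysis/02_preprocess.R
Rscript analysis/03_peak_statistics.R
Rscript analysis/04_classify.R 1 100  # seed 1, 100 epochs
```

which prints (seed 1):

```
simulated cohort (seed 1):
<spectrum_set> 1164 spectra, grid 400..1800 cm-1 (701 points)
  classes: normal=225 I=120 II=249 III=291 IV=279

unit-area check: max |area - 1| = 1.110223e-16
baseline iterations: median 14 max 16 ; converged: 1164 / 1164

NPC vs normal (Mann-Whitney, p < 0.01):
  higher in NPC: 548 756 1003 1033 1046 1124 1266 1553 1679
  lower in NPC:  490 625 645 740 836 851 881 936 1180 1209 1313 1449 1523 1616
stage trend at 1003 cm-1 (Kruskal-Wallis): p = 5.43e-34 ****
medians I-IV at 1003: 0.009419 0.009615 0.01008 0.01063
```

All 9 configured up-bands and 13 down-bands are recovered with the right
sign; the serine band at 1616 cm⁻¹ (configured neutral) also drops — the
closure effect of unit-area normalization: when affected bands rise, the
relative intensity of unaffected bands must fall slightly.

The classifier stage (script 04, seed 1) prints:

```
CNN training: final loss 0.146, final accuracy 95.0%

CNN test performance:
overall accuracy: 47.4%
per-class accuracy (recall):
normal      I     II    III     IV
 100.0   33.3   29.2   38.6   35.2

PCA-LDA test performance (20 components):
overall accuracy: 52.2%
per-class accuracy (recall):
normal      I     II    III     IV
 100.0    8.3   50.0   36.8   50.0
```

At the default effect sizes the healthy class separates perfectly for both
models (recall 100%) while the four stages overlap heavily — the stage
signal is a 5%-per-stage trend on two bands against 10% per-band subject
variation — so overall five-class accuracy sits near 50% for the CNN, for
PCA-LDA, and for an oracle classifier given the true per-band features
alike; see the methods vignette (`vignettes/sers-npc-methods.Rmd`) for
the separability analysis.

Equivalent programmatic use:

```r
library(sersnpc)
cohort <- simulate_cohort(simulation_config(seed = 1))
prep   <- preprocess_set(cohort)
sp     <- stratified_split(prep, split_plan(seed = 2))
fit    <- train_cnn(sp$train, cnn_spec(pool_stride = 3, seed = 3))
evaluate(fit, sp$test)
```

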