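---
title: "Methods: resting-state EEG connectivity features for epilepsy classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: resting-state EEG connectivity features for epilepsy classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epifc)
```

`epifc` turns a routine 19-channel resting-state EEG into a fixed vector of
784 quantitative features and trains classifiers that separate
epileptic-like from non-epileptic subjects. This vignette documents the
model assumptions, the tunable parameters, the synthetic-data generator that
stands in for clinical recordings, and the numerical and design choices a
user should know before trusting the output.

## Signal model and preprocessing

The pipeline assumes a monopolar 10–20 recording (19 standard labels,
128 or 256 Hz) in microvolts, resting state, without sleep segments. The
stage order is fixed: **filter → ICA → epoch**.

* **Band-pass filter.** A symmetric linear-phase FIR filter, Hamming design,
  window length `round(6.6 s × fs)` forced odd, pass band 1–40 Hz, applied
  with group-delay compensation. The long window gives narrow transitions;
  the coefficients are de-meaned so the DC response is exactly zero. Content
  above 40 Hz (including line noise) is outside the analysis band, so no
  notch filter is used.
* **EOG removal.** FastICA-style ICA (logcosh contrast, symmetric
  decorrelation, fixed internal seed) with 15 components. Components whose
  spatial topography correlates (absolute Pearson, strictly above 0.8) with
  a stored EOG template are subtracted from the signal. Matching on
  topographies rather than time courses makes the rule independent of
  recording length. The shipped template is *synthetic*: it was derived by
  running ICA on one simulated subject with strong planted blink activity
  (`inst/extdata/eog_template_synthetic.csv`).

  Convergence deserves a note. An ICA solution is only defined up to
  rotation inside any subspace whose sources have a rotation-invariant joint
  distribution — narrowband quadrature pairs are the canonical example, and
  near-Gaussian directions behave the same way in finite samples. In such
  data the per-component fixed-point residual can oscillate forever while
  the spanned subspace is fixed. `run_ica()` therefore declares convergence
  when every component's residual falls below `tol` (default 1e-3) **or**
  when the residual-violating components' subspace projector stops changing
  for three consecutive iterations; if neither happens within `maxit` it
  proceeds with the final iterate and a warning (set
  `on_nonconvergence = "error"` for the strict behaviour). The unmixing
  matrix is estimated on at most 8192 decimated time points — it is a
  spatial quantity and does not improve with minutes of extra samples — and
  the sources are then computed on the full signal.
* **Epoching.** Two non-overlapping epoch sets: 5 s at the native rate for
  band powers (frequency resolution) and 2.5 s at 128 Hz for connectivity
  (stationarity; decimation by an integer factor is safe because the signal
  is already limited to 40 Hz). Epochs whose maximum peak-to-peak amplitude
  across channels is below 1 µV are flagged as flat and excluded.
* **Epoch cleaning.** For each channel a peak-to-peak rejection threshold is
  selected from 40 log-spaced candidates between 10 and 500 µV by 10-fold
  cross-validation over epochs: the error is the RMS distance between the
  mean of the sub-threshold training epochs and the per-sample median of the
  validation epochs. The chosen threshold is the *largest* candidate within
  5 % of the minimum error — on artifact-free channels the error curve is
  flat above the data's peak-to-peak range and the strict argmin would chase
  noise-level dips and reject clean epochs. Per epoch, up to 3 channels above
  threshold are repaired by inverse-distance-weighted interpolation from the
  3 nearest clean electrodes (schematic 2-D positions); epochs with more bad
  channels are dropped, with a warning when more than half the epochs go.
* **Bipolar montage.** The 18 longitudinal derivations (anode − cathode) are
  grouped into AL, AR, PL, PR with five members each; Fz–Cz and Cz–Pz belong
  to both left and right groups of their row, since midline activity is not
  lateralized. Cleaning runs on monopolar epochs before the derivation.

## Epoch selection and band powers

Band powers come from Welch spectra (2 s Hamming segments, 50 % overlap)
corrected for the 1/f background by multiplying each bin's power by its
frequency; band membership is half-open (`lo ≤ f < hi`) so shared edges are
never double-counted. For each band the 50 highest-ranked epochs are used:
ranking is by channel-averaged relative power in that band, or, for
full-spectrum features, by the global band-power score
`GBP = TotalAbsolutePower / max(Var(rel. band powers), 1e-12)` — population
variance over the four channel-averaged relative powers, the epsilon
guarding the perfectly-even spectrum, which then ranks first. Relative
band powers were chosen over absolute ones inside the variance because the
score is meant to reward epochs that represent all bands evenly, which is a
statement about proportions. On the connectivity epoch set the delta and
global bands start at 2 Hz (2.5 s epochs need at least five cycles of the
lowest frequency for a usable spectral estimate).

## Connectivity estimators

All estimators operate on the selected 2.5 s bipolar epochs.

* **IMCOH** and **PLV** share multitaper cross-spectra (DPSS tapers,
  time-bandwidth 4, 7 tapers, 0.4 Hz bins). IMCOH is stored as an absolute
  value; its sign carries lead/lag information that the group summaries
  would average away. PLV is computed from the cross-spectral phase per
  epoch (not from an analytic-signal phase), bins averaged within the band
  after the epoch expectation.
* **MI** uses the Kraskov k-nearest-neighbour estimator (k = 3, max-norm,
  nats) on the raw amplitude series, global-band epochs only, with the
  median over epochs as the subject value (robust to outlier epochs) and
  negative estimates clipped at zero. The discrete joint-table formula is
  kept as `mi_discrete()` purely as a test oracle.
* **PDC** comes from one order-8 MVAR model per subject, fitted by least
  squares with normal equations accumulated per epoch, so no regression ever
  crosses an epoch boundary, and no ridge penalty. On the longitudinal
  bipolar montage the regressors are structurally rank-deficient (the two
  longitudinal chains of each hemisphere telescope to the same end-to-end
  difference: rank 16 of 18), so the solve is minimum-norm via an
  eigendecomposition with a relative tolerance — the same solution an
  lstsq-based toolbox returns. PDC is evaluated on a 0.25 Hz grid from 0.25
  to 30 Hz and is column-normalized: the squared entries of each column sum
  to exactly 1 at every frequency, which the test suite asserts to 1e-10.
  Entry (i, j) is the flow from channel j to channel i.

Matrices are summarized per scalp group by the mean and population standard
deviation of the within-group off-diagonal entries (20 directed entries for
PDC, 10 unique pairs otherwise).

## Graph measures, asymmetry, and the 784-feature vector

Node strength, Onnela weighted clustering (weights normalized by the graph
maximum, directed matrices symmetrized), and betweenness centrality (edge
lengths 1/weight, normalized by the pair count excluding the node) are
computed per node on the full 18-channel graph and summarized per group;
efficiency (mean inverse shortest path length) is computed on each 5-node
group subgraph; in/out-strength maxima are PDC-only. Asymmetry ratios
`max(left, right) / min(left, right)` compare AL vs AR and PL vs PR for each
graph summary; they are ≥ 1 by construction, insensitive to which side is
larger, and a non-positive summary (possible for betweenness on a sparse
graph) caps the ratio at 1e6 with `eps = 1e-12`.

The canonical enumeration — 40 band-power, 128 connectivity (IMCOH/PLV/PDC
across five bands, MI global only), 468 graph (degree maxima 40, strength
108 with PDC mean-only, clustering 128, betweenness 128, efficiency 64) and
148 asymmetry features (including efficiency ratios) — totals exactly 784.
The taxonomy (`feature_taxonomy()`) is the single source of truth for names
and order; `assemble_features()` fails loudly if any cell is missing.
Including efficiency in the asymmetry block is a deliberate reading: the
alternative taxonomies do not reach the fixed total, and efficiency is a
group-level summary exactly like the others being ratioed.

## Classification protocol

Subjects are split 80/20 with stratification; features are z-scored with
training-set mean and *population* standard deviation (zero-variance
features are dropped from both sets). Reductions: ANOVA-F top-k
(k ∈ {10, 25, 50, 100, 200}), PCA (component default 17), or deterministic
correlation pruning (canonical-order retention at |r| > 0.92 — the
deterministic rule replaces random victim selection for reproducibility)
followed by ANOVA. Models: SVM (C ∈ {0.01…100}, linear/RBF), single-layer
MLP (16/64/128 units, inputs additionally min-max scaled to [0, 1] with
training extrema), random forest (100/300 trees, depth ∅/5/10), and ridge
logistic regression with the C grid mapped to glmnet's λ = 1/(C·n).
Hyperparameters maximize mean AUC over stratified 5-fold CV; normalization
and reduction are refitted inside every fold, so no validation information
leaks into them (the test suite includes a leakage audit). Test evaluation
reports the ROC, the AUC, the confusion matrix at the Youden-J optimal
cut-off (ties resolved to the lower threshold), and a surrogate reference:
the 95th percentile of the AUC over 100 label permutations with a fixed
seed. Clinician fusion combines binarized model predictions with the
normal/abnormal EEG label by AND (specificity can only improve) or OR
(sensitivity can only improve).

## The synthetic cohort generator

No suitable public cohort exists, so `generate_cohort()` simulates one with
known ground truth; all distributional choices are stand-ins and are listed
here so their influence is explicit.

* **Connectivity backbone.** A stable order-8 MVAR process over the 19
  electrodes: diagonal AR(2) terms (0.45, −0.15) plus sparse off-diagonal
  coefficients (density 0.35, magnitude 0.05–0.15, random lag) restricted to
  within-scalp-group electrode pairs, rescaled until the companion spectral
  radius is ≤ 0.95. Subjects of the epileptic-like class have the planted
  group's coefficients multiplied by `1 + effect_size` (default group AL,
  default effect 2); an unstable combination is rejected with the spectral
  radius in the message.
* **Innovations and background.** MVAR innovations and the 1/f-shaped
  background noise are t(5)-distributed (unit variance). Heavy tails mimic
  the burstiness of real EEG and give ICA identifiable directions; with
  Gaussian innovations the ICA stage has nothing to estimate.
* **Oscillators.** Per-band rhythms at 2.5/6/10/20 Hz with a second harmonic
  locked to the fundamental (real cortical rhythms are arc-shaped, not
  sinusoidal) and a per-channel phase random walk decorrelating over about
  2.5 s. Fixed-phase sinusoids would keep a constant inter-channel lag for
  the whole recording, driving PLV towards 1 everywhere and masking the
  planted coupling.
* **Artifacts.** Blink-like biphasic transients (0.4 s, 80–150 µV) with a
  fixed frontal loading at a configurable rate (default 4/min), and, with
  probability `flat_prob`, one 5 s zero segment — long enough to blank a
  whole connectivity epoch, which exercises the flat-epoch filter.
* **Metadata.** Diagnoses are Bernoulli at the requested prevalence, with
  epileptic subjects assigned subtypes at the 219:24:48 imbalance of a
  first-seizure cohort; ages uniform on 16–98; sexes balanced; the clinician
  "EEG result" label is a Bernoulli draw with sensitivity 0.660 and
  specificity 0.629 against the true diagnosis. These marginals exist to
  exercise the subgroup and fusion machinery, not to model demography.

What passing tests on these cohorts shows: the pipeline recovers planted
directed coupling, stays calibrated under the null, and is numerically
correct. What they cannot show: performance on clinical EEG, whose artifact
structure, non-stationarity and pathology spectrum the generator does not
emulate.

## Problem sizes, numerical choices, determinism

* The acceptance-property tests use desk-scale sizes chosen once: the
  null-calibration check uses one 40-subject cohort with `effect_size = 0`
  and applies 10 run seeds to the split/CV/surrogate level, requiring the
  test AUC inside the surrogate band in at least 9; the recovery check uses
  one 120-subject cohort at `effect_size = 2` with 3 run seeds and requires
  test AUC ≥ 0.9; recordings are 60 s at 128 Hz (the generator's defaults
  remain 120 s at 256 Hz), and the end-to-end smoke test runs 12 subjects at
  120 s.
* Ties: epoch selection breaks score ties by earlier epoch index; ANOVA
  selection by lower feature index; the Youden cut-off takes the lowest
  maximizing threshold; grid search takes the first configuration attaining
  the maximal mean CV AUC.
* Degenerate inputs: zero-power channels give IMCOH 0 with a warning;
  constant channels give MI 0; a zero-weight graph has strength, clustering,
  betweenness and efficiency 0; `GBP` and asymmetry ratios carry explicit
  epsilon rules (1e-12, cap 1e6).
* Every stochastic step is seeded: cohorts from `cohort_spec(seed)` with
  per-subject seeds drawn once from it, ICA from a fixed internal seed, and
  splits/folds/surrogates from the run-level seed recorded in the report.
  RNG state is saved and restored around all internal seeding, so the
  package never perturbs a caller's random stream.

## Known limitations

* Sensor-space analysis only: the bipolar montage attenuates but does not
  remove volume conduction; no source modelling.
* The ICA template is synthetic and single-component; real blink/saccade
  archetypes differ and usually need two components.
* The clinical headline numbers of studies on hospital cohorts are not
  reproducible here — the data are not deposited — so the synthetic
  properties above are the package's acceptance surface.
* MI's kNN estimator is biased at strong dependence and short epochs; the
  median over epochs mitigates but does not remove this.
* The correlation-pruning order (canonical feature order) is a convention;
  a p-value-guided choice would likely retain more informative features.
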