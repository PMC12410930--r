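---
title: "Methods: simulation and analysis of nanopore O-glycopeptide recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulation and analysis of nanopore O-glycopeptide recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`glycopore` implements a complete desk-scale pipeline for single-molecule
nanopore analysis of mucin-type O-glycopeptides (MUC1 VNTR peptides carrying
the truncated glycans Tn, TF, STn, STF, plus the unmodified WT backbone):
a statistical simulator of ionic-current recordings, blockade-event
detection and feature extraction, population statistics, density-based
denoising and sub-population labeling, a supervised classification bench,
capture-corrected mixture quantification, and Eyring transition-state
kinetics. This vignette explains the models behind each stage, the
parameters that matter, and what the synthetic data can and cannot tell you
about real recordings.

## The measurement model

A single aerolysin (K238G) pore under a +160 mV bias passes an open-pore
current $I_0$ (about 100 pA in 1 M KCl at pH 3). A peptide entering the
pore blocks part of the ionic flux: the current drops to $I < I_0$ for the
dwell time of the molecule, then returns. Each such blockade event is
summarized by four features:

* **blockade ratio** $I/I_0$ — the fraction of current that still flows;
  bulkier glycans block more (smaller ratio). It is the dominant
  discriminating feature.
* **duration** (ms) — how long the molecule resides in the pore.
* **intra-event SD** (pA) — current fluctuation inside the event (also
  reported as $\mathrm{SD}/I_0$, which transfers across pores).
* **skewness** — asymmetry of the intra-event current distribution,
  computed as the population moment ratio
  $g_1 = \frac{n^{-1}\sum_i (x_i-\bar x)^3}{[n^{-1}\sum_i (x_i-\bar x)^2]^{3/2}}$
  (denominators $n$, not $n-1$).

## The synthetic-data generator

No raw recordings ship with the package, so every stage is exercised
against a simulator (`simulate_trace()`, `simulate_event_table()`) whose
defaults encode the study conditions at the reference point of +160 mV and
10 °C:

* **Blockade-ratio emission.** Each class draws $I/I_0$ from a Gaussian
  mixture. Peak centers are the Gaussian-fit values 0.45 (WT), 0.36 (Tn),
  0.33 (TF), 0.18 (STn), 0.10 (STF). The sialylated classes are
  two-component mixtures (weights 0.7/0.3): their secondary populations —
  attributed to electrostatic interaction of the sialic-acid carboxylate
  with pore arginines — sit at 0.26 (STn) and 0.24 (STF), deliberately
  overlapping *each other* so that they form the coherent "merging region"
  (MR) the labeling stage expects. Component SDs (0.02 single-population,
  0.025 sialylated) are calibration choices: no per-class SDs are published,
  and these values give the partial overlap of adjacent classes seen in
  real scatter data. They live in the presets and are never assumed by the
  analysis stages.
* **Dwell model.** Durations are log-normal (Gaussian in
  $\log_{10}$ duration), with reference statistical durations of about
  4.0, 3.2, 2.0, 1.4 and 1.1 ms (WT, Tn, TF, STn, STF; sialylated classes
  dwell shorter, consistent with their partial negative charge aiding
  transport). The spread (0.32–0.35 decades) is a calibration choice.
* **Temperature dependence.** The mean dwell scales with temperature by the
  Eyring factor
  $\tau(T)/\tau(T_{\mathrm{ref}}) = (T_{\mathrm{ref}}/T)\,
  e^{\Delta H^{\ddagger}/R\,(1/T - 1/T_{\mathrm{ref}})}$
  (`dwell_scale()`), shifting the log-mean and leaving the log-SD fixed.
  The WT and Tn activation enthalpies are calibrated with
  `delta_h_for_ratio()` so that cooling from 24 °C to 10 °C lengthens the
  statistical duration by exactly 1.5× (WT) and 1.8× (Tn), the observed
  cold-assist factors at +160 mV; TF (1.6×) and the sialylated classes
  (1.4×) are plausible interpolations, as their temperature series are not
  characterized. Note that these *dwell* enthalpies differ from the
  *interaction* thermodynamics in `thermo_constants` (ΔH‡ = 25.89 kJ/mol,
  ΔS‡ = −95.2 J/mol·K for WT; 47.74 kJ/mol, −20.3 J/mol·K for Tn), which
  derive from a different temperature–voltage series: an enthalpy of
  25.89 kJ/mol would imply a 1.76× ratio over this 14-degree span, not
  1.5×. The simulator treats the printed cold-assist factors as the
  condition to emulate and keeps the printed thermodynamics as the
  reference inputs for the Eyring-fit round trip. Each preset's ΔS is then
  derived so the absolute Eyring rate at 10 °C reproduces its reference
  dwell, making presets self-consistent inputs for kinetics tests.
* **Arrivals and capture.** Events arrive as a Poisson process with rate
  $\sum_c f_c [c]$ (capture rate × concentration), with the pore dead
  during an event. Capture rates per µM (0.30, 0.35, 0.80, 0.50, 0.70 for
  WT, Tn, TF, STn, STF) are synthetic: no per-class frequencies are
  published. They are deliberately *unequal* so that the
  capture-frequency correction in the quantification stage is genuinely
  exercised.
* **Trace texture.** The baseline is $I_0$ plus Gaussian white noise
  (default 2 pA SD) and an optional slow sinusoidal drift emulating
  bilayer-interaction wander. The 5 kHz recording bandwidth is emulated by
  convolving the rectangular pulse train with a Gaussian kernel of
  σ = 0.07 ms — a cheap monotone edge model that reproduces the
  attenuation of short events without a full filter cascade. Gating
  artifacts (uniform depth, exponential ~1 ms dwell) can be injected at a
  configurable rate to exercise denoising.

The shortcut generator `simulate_event_table()` emits feature rows directly
from these emission models (durations rejection-sampled above the 0.50 ms
detectability cutoff; intra-event SD drawn from the sampling distribution
of a Gaussian SD; skewness from its asymptotic null, variance $6/n$). Its
$I/I_0$ distribution is statistically indistinguishable from features
extracted off a full simulated trace (two-sample KS test in the suite);
its durations are the *model* durations, whereas trace extraction reports
the refined extent, which includes about +0.25 ms of band-limited edge
(see below). Trace-extracted skewness also has a wider spread than the
asymptotic null for short events, whose interiors retain some edge
curvature — the classifier is therefore always trained and evaluated on
features from one source, never across sources.

**What the simulator does not emulate:** correlated 1/f and capacitive
noise, voltage-dependent capture and dwell laws, multi-level sub-states
within events, competitive capture in mixtures, and bilayer-interaction
event clusters with structured (non-uniform) geometry. Passing tests on
synthetic data therefore validate the *pipeline's statistical machinery*,
not instrument-specific performance on real traces.

## Baseline estimation and event detection

`fit_baseline()` splits the trace into windows (default 10 s) and fits a
Gaussian to the all-points histogram restricted to the upper (open-pore)
mode, so blockades cannot drag $I_0$ down; a pore that never shows an
open-pore mode is an error, and a zero-variance trace gets its σ floored
at $10^{-6}$ pA with a warning. Segment values are interpolated linearly
between window centers, tracking slow drift.

`detect_events()` applies the one-sided existence threshold
$I_0 - 5\sigma$: a run of samples below threshold is an event. Two
refinements follow:

* **Extent.** Band-limited edges smear the crossing, so boundaries are
  extended outward to the nearest crossings of $I_0 - 1\sigma$: the
  5σ rule decides existence, the 1σ rule decides extent. With the 0.07 ms
  edge kernel, the 1σ crossings sit ≈ 0.12 ms outside each nominal edge,
  so reported durations carry a systematic positive margin of ≈ 0.25 ms —
  the price of not truncating genuine dwell. (A pure 5σ extent would
  underestimate dwell instead.)
* **Duration filter.** Events whose *threshold-crossing core* is shorter
  than 0.50 ms are excluded. Filtering on the core rather than the refined
  extent keeps the exclusion faithful: a 0.35 ms pulse must not sneak past
  the filter just because edge refinement widened it.

`i_mean` (and the intra-event SD/skewness in `extract_features()`) use the
interior of the refined extent after trimming max(10 % of the length,
0.35 ms) from each side; the 0.35 ms floor (≈ 5 edge-kernel sigmas) keeps
edge samples out of short events' interiors, which otherwise bias the
blockade ratio upward and inflate the SD. Events shorter than 3 interior
samples or with zero variance are flagged `degenerate` with SD/skewness 0.
The blockade ratio divides by the interpolated $I_0$ at the event
midpoint. At 5σ on a 60 s trace, Gaussian tails admit a handful of
sub-sample threshold crossings, all removed by the duration filter — the
false-positive rate of retained events is effectively zero.

## Population statistics

`fit_ratio_peak()` and `fit_duration_peak()` fit Gaussians to histograms
(Freedman–Diaconis binning with a floor of 40 bins) by least squares on bin
centers — deliberately mirroring how population peaks are read off
histograms of blockade data, rather than direct maximum likelihood.
Two-component fits are multi-start (the two most separated local maxima of
the smoothed histogram, quantile-based, and mirrored inits; best residual
sum wins) with component SDs bounded by the pooled sample SD — a component
broader than the whole sample signals an unresolved solution. A forced
second component on unimodal data is flagged (weight < 0.05 or centers
within one SD). The "statistical duration" is $10^{\hat\mu}$ of the
log-duration fit; `peak_separation()` of two ratio fits is the
$(I_a - I_b)/I_0$ metric used to justify cooling: narrower emission at low
temperature resolves otherwise-merged peaks.

## Denoising and the 6-class labeling

Events are clustered on the z-scored $(I/I_0, \log_{10}\mathrm{duration})$
plane — the plane in which event clouds are actually inspected; raw
duration spans decades and would otherwise dominate the metric.

`denoise()` is an in-package implementation of HDBSCAN (no R
implementation of the algorithm was available): core distances at
`min_samples` (default 10), mutual-reachability single linkage, condensed
tree at `min_cluster_size` (default 5 % of events), excess-of-mass cluster
selection. One flat-labeling choice deserves emphasis: plain
excess-of-mass labeling collapses on *single-population* clouds — the
standard single-cluster pathology, where most of a clean Gaussian blob is
labeled noise — and an absolute density floor (the
`cluster_selection_epsilon` device) cannot be made scale-free. The package
instead labels noise by a *cluster-relative persistence* rule: within each
selected cluster, a point whose detachment density is below
`relative_density_min` (default 0.2) of the cluster's median detachment
density is noise. Because densities are compared within the cluster, the
rule is invariant to sample size, feature scaling, and contamination
level; on a clean population it removes ≲ 1 % of events, while sparse
uniform contamination detaches at several-fold lower density and is
pruned. Both clustering stages are deterministic: no seeds, inputs
processed in event order.

The sialylated classes are each split in two by `split_sialylated()`
(agglomerative clustering, Ward linkage, k = 2 — the linkage is a package
choice; only the algorithm family is prescribed), with sub-population "-1"
the cluster nearer the class's primary fitted peak. The split is flagged
as dubious when a one-component Gaussian model of the blockade ratios
beats a two-component one by BIC — unimodal input; silhouette width was
evaluated for this role but its distributions for genuinely uni- and
bimodal clouds overlap too much to threshold, so it is attached only as a
diagnostic. The split is returned either way and the caller decides. `assign_mr()` merges STn-2 ∪ STF-2 into the MR
class: kept for classifier training (6 classes), excluded from all
proportion statistics. Count conservation — retained = labeled + MR,
input = retained + noise — is asserted in the suite.

## Classification bench

`glyco_dataset()` builds the n × 4 matrix (SD, skewness, duration, ratio),
makes a seeded stratified 80/20 split, and standardizes with
training-row statistics only. `train_bench()` trains seven families — SVM
(RBF), k-NN (k = 5), random forest (300 trees), multi-class AdaBoost
(SAMME on depth-≤3 CART trees, authored in-package as no AdaBoost
implementation ships with the stack), Gaussian naive Bayes, Gaussian
process (RBF), and an MLP (one hidden layer of 64 units, max 2000
iterations, weight decay $10^{-4}$, no early stopping) — with stratified
10-fold cross-validation, then reports held-out accuracy, per-class and
macro one-vs-rest AUC, average precision, and the confusion matrix.
Hyperparameters are the conventional defaults of each family and are
recorded in the report; none is searched. The Gaussian process's hard
labels come from its response output (its one-vs-all probability coupling
is poorly calibrated, while the labels are exact); probabilities still
feed its AUC. `select_model()` takes the highest macro AUC, ties broken by
test accuracy, then by the fixed family order. All randomness (split,
folds, initializations, permutations) flows from one seed; identical calls
reproduce reports exactly.

Permutation importance is the mean test-accuracy drop over permutations of
one feature, floored at zero and normalized to percentages summing to 100.
The learning curve re-trains on stratified subsamples of the training rows
and reports CV accuracy per size.

On synthetic data calibrated to the class peaks above, the selected MLP
typically reaches ~80–85 % held-out accuracy (macro AUC ≈ 0.96): the
Tn/TF pair (0.36 vs 0.33 at SD 0.02) overlaps genuinely. Benchmarks
reported for real recordings are not reproducible from synthetic data and
are treated as context only; the suite instead asserts the separable-limit
(≥ 99 % for every family) and chance-level (permuted labels) behaviors.

## Mixture quantification

Classes capture at different rates, so classified counts are corrected by
pure-sample capture frequencies (events·s⁻¹·µM⁻¹,
`estimate_capture_frequency()`):
$p_c = (n_c/f_c) / \sum_{c'} (n_{c'}/f_{c'})$, with MR and noise excluded
from numerator and denominator and STn-1/STF-1 standing for STn/STF. The
published workflow states only that quantification is "corrected based on
the capture frequency of pure peptide samples"; this count-over-frequency
normalization is the minimal reconstruction consistent with that statement
and with proportions summing to one. Two properties pin it down: equal
frequencies reduce it to raw count fractions, and uniform rescaling of all
frequencies leaves proportions unchanged. The package estimates pure-sample
frequencies from *classified* pure runs (counting the analyte's own
primary label), so the losses of the shared pipeline — denoising, MR
assignment, classifier confusion — hit numerator and reference alike and
largely cancel; the optional alternative of dividing sialylated counts by
their pure-sample "-1" fraction is thereby unnecessary and MR events stay
ignored, as prescribed. Excluding MR under-counts sialylated classes only
to the extent the "-1" fractions differ between pure samples and mixture.

The end-to-end experiment in the suite (and `run_mixture_experiment()` in
the test helpers) trains on ~350 events per pure class, quantifies a
~1000-event 2:2:1:3:3 (STF:STn:TF:Tn:WT) mixture at the pure-sample
concentrations of 10, 10, 2, 5 and 3 µM, and recovers every class
proportion within ±5 percentage points — the residual error is dominated
by Tn↔TF confusion, exactly as the class geometry predicts.

## Eyring kinetics

`eyring_fit()` is ordinary least squares of $\ln(k_{off}/T)$ on $1/T$ with
$k_{off} = 1/\tau_{off}$, giving $\Delta H^{\ddagger} = -R\,\mathrm{slope}$
and $\Delta S^{\ddagger} = R\,(\mathrm{intercept} - \ln(k_B/h))$. τ_off at
one temperature is the statistical duration converted to seconds
(`tau_from_durations()`; the arithmetic mean is available by flag, as the
two conventions differ for log-normal dwell). Noiseless series generated
from the Eyring relation are recovered to machine precision — including
the reference thermodynamics in `thermo_constants` — and the suite checks
that estimator bias vanishes as measurement noise shrinks. Bath
temperatures convert to kelvin by +273.15; the small pH drift of the
buffer with temperature is metadata only.

## Numerical and reproducibility choices

* Histogram fits use `minpack.lm`'s Levenberg–Marquardt on the residual
  function directly (no rank-gated model construction), with bounded
  parameters and multi-start for mixtures.
* Blockade-ratio draws are rejection-clamped to (0.01, 0.99); mixture
  component bookkeeping is kept so sub-population recovery can be scored.
* All index fields in public tables are 0-based half-open (start, end),
  matching the on-disk TSV formats; R-side code converts internally.
* Problem sizes in the suite — 500-event peak fits, 20–60 s traces,
  ~350-event-per-class training sets, a ~1000-event mixture — were chosen
  so that sampling error sits well inside the asserted tolerances while
  the whole suite stays desk-scale. The duration-ratio checks use common
  random numbers (the same seed at both temperatures), a standard
  variance-reduction design that cancels most sampling noise in a ratio
  of paired estimates.
* `sd(x) == 0` guards appear wherever a degenerate input would poison a
  fit; each degenerate path either errors informatively or flags the
  output, never silently.

## Known limitations

* The boundary-refinement margin (+≈0.25 ms) is visible in absolute
  durations; ratios of statistical durations are nearly unaffected, and
  the shortcut generator reports model durations.
* Denoising assumes outlier contamination is sparse relative to the
  population; structured contamination (a dense artifact cluster) would be
  *kept* as a cluster, by design.
* The quantification correction ignores competitive capture between
  analytes in a mixture.
* The classifier bench is a comparison harness, not a tuned production
  model; no hyperparameter search is performed.
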