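---
title: "Methods: simulating and analysing epidural field potentials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing epidural field potentials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Epidural field potentials (EFPs) are mesoscale brain signals recorded from
microelectrode arrays resting on the dura. Over primary visual cortex, their
broadband-gamma power (roughly 25–160 Hz after baseline normalisation)
carries information about where a visual object is, how large it is, its
shape, and — later in the response — its color. `efptools` implements the
complete analysis chain for such recordings: time–frequency decomposition,
trial screening, receptive-field mapping, data-driven selection of
informative time–frequency windows, feature-sensitivity indices, and
single-trial decoding. Because no public recordings of this kind are
available, the package is organised around a synthetic-data generator with
full ground truth, so every stage of the chain can be scored against known
parameters.

# The synthetic recording model

## What is emulated

* A hexagonal epidural array (202 electrodes, 1.8 mm pitch, 560 µm
  contacts; `array_geometry()`).
* One epidural receptive field (ERF) per electrode: a Gaussian sensitivity
  profile in visual space. ERF centers are drawn uniformly over the
  lower-right visual quadrant; equivalent diameters are drawn from
  N(3.0°, 0.46°). A diameter `D` maps to the Gaussian's full width at half
  maximum, `sigma = D / (2 sqrt(2 ln 2))`.
* A 5 × 3 × 5 × 5 factorial stimulus design: five locations at 3.5°, 5.8°
  and 8.2° eccentricity, three orbit diameters (1.0°, 1.2°, 1.4°), five
  shapes collapsing onto three angularity classes, five colors — 375
  conditions, typically 21–39 trials each.
* Trial epochs of 500 ms baseline + 800 ms stimulus at 1 kHz. Trials are
  independent; the three-object sequence structure of a behavioural trial
  is not simulated.

## Signal model

Each trial and electrode is the sum of

1. **1/f background** with standard deviation 20 µV,
2. an **early gamma burst**: band-limited (25–160 Hz) Gaussian noise with a
   raised-cosine envelope (latency 30 ms, 25 ms rise, plateau until 120 ms,
   60 ms decay) whose amplitude is
   `burst_amp × peak_gain × exp(−d²/(2σ²)) × g_size × g_angularity`,
   where `d` is the distance between the ERF center and the stimulus
   location, and
3. a **late sustained component** confined to ~110–180 ms carrying the
   same gains times a color gain.

Only band *power* is analysed downstream, so an amplitude-modulated noise
burst is a sufficient waveform model. Gains are amplitude gains; their
squares are the power ratios the model encodes:

* size — power ratios 1 : 1/1.8 : 1/3.5 for large : medium : small,
* angularity — amplitude 1 : 0.87 : 0.75 for circular : quadrangular :
  triangular (chosen to give clear but not extreme separation; the study
  reports strong angularity effects without quantifying the power ratio),
* color — the late component carries ×1.9 power for blue and red relative
  to brown, green and gray. The early burst carries **no** color
  preference: in this preparation the early transient shows no reliable
  electrode-level color information (detection at chance rates), and the
  color-sensitivity index is invariant to pattern magnitude, so any stable
  early pattern — however small — would saturate it. The ~10% early
  grand-average trend toward blue/red reported for this kind of data is
  therefore deliberately not encoded; this is a known limitation of the
  generator.

Per-trial log-normal gain noise (sdlog 0.25 on amplitude) models response
variability; a small per-electrode log-normal jitter (sdlog 0.05)
individualises the stable feature gains, except the early color gains (see
above). Orientation bias depth is |N(0.12, 0.08)|, matching a median
orientation index near 0.115.

Mapping sweeps move a 0.24° × 23.8° bar along a 19.1° trajectory centered
at (2.4°, −3.6°) in 12 directions (30° spacing), 1 s per sweep. The evoked
amplitude follows the closed-form line integral of the Gaussian ERF along
the bar, `exp(−d_perp²/(2σ²))`, times `1 + depth·cos(2(θ_bar − θ_pref))`.

## What is not emulated

Eye movements, fixation behaviour and reward, session-wise nonstationarity,
cortical geometry (ERF centers are assigned directly in visual
coordinates), hue-dependent shifts of the gamma peak frequency, and
feature-specific frequency bands (all features modulate one broadband
burst; only color has a distinct time course). Passing tests on this
generator therefore demonstrates the correctness of the analysis chain, not
that real EFPs behave this way.

## Artifacts

`inject_artifacts()` corrupts disjoint random trial subsets: clipping
(samples exactly at the ±1500 µV amplifier limit on a quarter of the
electrodes), power outliers (response window scaled ×4 in voltage across
the whole array), and correlated bursts (one shared 30–160 Hz burst of
100 µV added to 90% of electrodes, giving mean pairwise correlations well
above 0.5). Clean trials are left bit-exact.

# Preprocessing

Raw traces at an acquisition rate (e.g. 25 kHz) are low-passed with a
zero-phase FIR filter (150 Hz cutoff, forward–backward, odd-reflection
padding so edge transients cannot leak in, taps normalised to exact unit DC
gain) and decimated by an integer factor to 1 kHz. If a 50 Hz reference
trace is available, its in-phase and quadrature components are regressed
out — unlike a notch, this leaves neighbouring frequencies untouched.

The time–frequency transform uses Morlet wavelets of 7 cycles (a common
compromise between time and frequency resolution; configurable) on a 2
Hz-spaced grid from 10 to 160 Hz, implemented as one-sided Gaussian
multiplication in the frequency domain with reflection padding. Power is
scaled so a unit-amplitude sinusoid at a grid frequency has power 1. Bins
within the half support (3 σ_t) of an edge are reported per frequency and
treated as unreliable.

Baseline normalisation is per single trial: `WP(f,t) = (P(f,t) − B(f)) /
B(f)` with `B(f)` the mean power over the 500 ms pre-stimulus window
(excluding each frequency's edge region). WP is therefore invariant to any
multiplicative gain on the raw trace. A condition-level baseline is
available as a sensitivity analysis flag. Downstream analyses use 5 ms time
bins and the 26–175 ms × 25–160 Hz domain.

# Trial screening

Three stages run strictly in order on the surviving set:

1. **Clipping** — any sample at or beyond the amplifier limit rejects the
   trial.
2. **Power outliers** — per condition and electrode, broadband (30–160 Hz)
   power outside mean ± 4 SD. Two implementation choices matter here.
   First, the mean and SD are *jackknifed* (computed without the tested
   trial): with `n` trials, a single extreme trial can otherwise never
   exceed `(n−1)/√n` SDs of statistics it inflates itself, which is below 4
   for `n < 19`. Second, a trial is rejected when it is an outlier at a
   *majority* of electrodes: artifacts of this class are array-wide, and a
   rejected-anywhere rule would have a false-alarm rate growing with the
   electrode count (at 202 electrodes it would reject most clean trials).
   The stage is applied twice, so trials unmasked by a first-round
   rejection are caught. Several extreme trials inside one small condition
   can still mask one another — an intrinsic property of ± SD rules — and
   strictly single-electrode glitches pass this stage; both are accepted
   limitations.
3. **Correlated bursts** — trials above the 80th broadband-power percentile
   at a majority of electrodes are tested for unusually strong
   cross-electrode structure; mean pairwise Pearson correlation ≥ 0.5
   rejects.

All thresholds are configurable (`screen_params()`); an optional manual
exclusion list stands in for a final visual inspection.

# Receptive-field mapping

Per electrode and motion direction, broadband-gamma (60–150 Hz) power of
every sweep is accumulated onto the grid cells currently covered by the
bar and normalised by coverage counts. The accumulation is 1-D along the
motion axis (the bar spans the grid), uses nearest-bin assignment to avoid
a half-cell bias, and is lightly smoothed at the bar-width scale. Grid
resolution is 0.1°/cell, balancing the 0.24° bar against runtime.

Direction maps are combined by their geometric mean after min-shifting each
to be strictly positive (shift `min + 1e−6·range`); directions are sorted
before combining, so the result is exactly order-invariant. The combined
map is Z-scored against its own off-peak distribution (all cells outside
the top decile) and the largest contiguous region with Z ≥ 1 and area ≥ 1
square degree is extracted; the equivalent circular diameter is
`2√(area/π)`. The reported center is a sub-cell activation peak (weighted
centroid of the top 20% of the peak), which roughly halves the center error
relative to the argmax cell.

Thresholding a self-normalised map can never reject a pure-noise map on its
own, so validity additionally requires *significant modulation*: the
observed geometric-mean peak must exceed the peak of each of 19 surrogate
maps built by circularly shifting every direction profile along its motion
axis (≤ 5% false-valid rate under the null). The comparison is made on the
raw geometric-mean scale because shifting preserves profile values, making
surrogate and observed peaks directly comparable; the adaptive Z scale
would not be.

Note that the extracted Z ≥ 1 area depends on the map's signal-to-noise
ratio and is generally larger than the generator's diameter parameter
(which sets the FWHM of the sensitivity profile); center recovery, not area
recovery, is the accuracy contract.

Orientation bias uses the Michelson contrast between the most activating
bar orientation and its orthogonal, `OI = (WP_θ − WP_θ+90) / (WP_θ +
WP_θ+90)`, with reliability from a label-permutation test (default 1000
permutations, α = 0.05). Zero response latency is assumed in simulation; a
lag correction hook exists for real data.

# ROC window selection

Per electrode, category level and 5 ms × frequency bin, a one-vs-rest AUC
(midrank convention; identical to Mann–Whitney `U/(n₁n₂)`) measures how
well that level's single-trial WP separates from the category's remaining
trials. The grand-variance map is the variance of these AUCs over all
electrode × level series per bin.

The Z-transform of that variance is referenced to the *pre-response* bins
(t < 25 ms), where label exchangeability makes the AUC variance a pure
sampling quantity: `Z = (v − mean(v_ref)) / sd(v_ref)`. Referencing the map
to its own global mean instead would saturate whenever a large fraction of
the domain is informative — which is exactly the situation for location,
size and shape here — and was therefore rejected; it remains the fallback
when a map contains no pre-response bins. AUC maps start at 0 ms for this
reason, while selected windows are clipped to the 26–175 ms analysis
domain.

The selected window is the bounding rectangle of the contiguous region
with Z ≥ 2 containing the highest peak (ties: earlier time, then lower
frequency). A category with no supra-threshold region raises an error
prompting a manual window; the pipeline driver falls back to the full
analysis domain in that case and records the provenance. Multi-window
(disjoint-band) selection is intentionally not automated; manual windows
cover that case.

# Feature sensitivity

Per electrode, all trials are re-sorted by the level of the category under
analysis and WP is averaged over the category's window bins and trials per
level. The indices are

* `SPI = |WP(loc)_rnk1 − WP(loc)_rnk2|` (highest vs second-highest
  *response*; the spatial analyses rank locations by *distance* instead,
  and both rankings are exposed),
* `SZI = (|WP_l − WP_m| + |WP_m − WP_s|)/2`,
* `SHI = (|WP_c − WP_q| + |WP_q − WP_t|)/2` with quadrangular and
  triangular values averaged over their two shapes,
* `CSI = Σ_{i<j} |cWP_i − cWP_j| / mean(cWP)`, `cWP = WP(col) − min
  WP(col)`, over unordered pairs (ordered pairs would only double every
  value); all-equal color responses give CSI = 0 by convention, and
  `mean(cWP)` is taken over all five corrected values.

SPI, SZI and SHI scale with overall activation (exactly k-equivariant);
CSI is invariant under `WP → k·WP + c`.

Electrodes are assigned to the stimulus location closest to their ERF
center (ties to the lowest location id). Distance-binned statistics use
bins `[0, 0.75, 1.5, 2.25, 3]°`, a Kruskal–Wallis test, Tukey's honest
significant difference criterion applied to rank-transformed data for the
pairwise post-hocs, and `ω² = (H − k + 1)/(n − k)` (clamped at 0) as effect
size. For total n ≤ 10 the Kruskal–Wallis p-value is computed by complete
enumeration of group assignments and the paired Wilcoxon p-value by
complete sign-flip enumeration; asymptotic approximations take over above
that. The rank-distance profile re-sorts each electrode's per-location
means by distance rank, normalises to the per-electrode maximum, and
averages. The response fall-off with distance is summarised by a
half-Gaussian `r(d) = a·exp(−d²/(2σ²))` fitted by Levenberg–Marquardt
least squares with the peak pinned at d = 0 (note the *power* fall-off of
the generator has an effective width of `σ_amplitude/√2`). Early/late color
sensitivity compares per-electrode CSI in the 40–90 ms and 120–175 ms
windows with a paired signed-rank test.

# Single-trial classification

Each trial is collapsed to three numbers — its maximal WP inside the size,
shape and color windows — and pairs of conditions are decoded per
electrode with RBF-kernel SVMs in a leave-one-out procedure: balance the
classes by random subsampling, scale features to [0, 1], estimate C and
gamma by five-fold cross-validated grid search, train on all-but-one and
classify the held-out trial; ten repetitions per electrode and pair.
Shuffled-label repetitions estimate chance (50% by definition), and a
Mann–Whitney test of the ten true against the ten shuffled accuracies
declares significance at α ≤ 1%.

Three leakage/efficiency choices: scaling is computed on the training
portion of each leave-one-out split and applied to the held-out trial (a
scale-all variant reproduces the literal all-trials scaling); the grid
search runs once per repetition on the balanced set before the
leave-one-out loop — the hyperparameter estimate is nearly unchanged by one
held-out trial, and per-split tuning (available via `tune_per_split =
TRUE`) costs ~40× more; and the grid spans C ∈ 2^−5..2^15, gamma ∈
2^−15..2^3 with a stride of 2⁴ (6 × 5 points) — the classical coarse grid —
because a fine grid multiplies the cost of the repeated-runs procedure
without moving the accuracy of a 3-feature, ~40-trial problem. Class
assignment uses the SVM decision value. Subsampling and shuffling are
seeded per (electrode, run) so every accuracy is reproducible.

The gamma-contrast pair enumeration mirrors the classical high-vs-low set:
top size × top shape × top-two colors against bottom size × two
lowest-ranked shapes × three lowest-ranked colors (2 × 3 × 2 = 12
high-vs-low pairs), plus representative high-vs-medium and medium-vs-low
pairs.

# Pipeline, seeds and caching

`run_pipeline()` executes simulate → preprocess → screen → map-erf →
roc-select → sensitivity → classify from one validated configuration
(`efp_config()`, YAML round-trippable). A single master seed
deterministically derives independent per-stage and per-electrode streams
(`derive_seed()`, a 31-bit string hash), so identical configurations give
bit-identical outputs. Stage results are cached under the output directory
keyed by a hash of the relevant configuration subset; any stage re-runs
from cached upstream outputs. The summary reports the qualitative
pattern checks (index-vs-distance monotonicity, decreasing rank-distance
profile, late > early CSI, chance near 50%) as booleans it computes from
the run's own outputs.

# Problem sizes used by the test suite

The packaged tests exercise the chain at reduced sizes chosen to keep the
full suite within minutes while leaving every statistical check
well-powered: ERF recovery uses 50 electrodes at 3 sweeps per direction;
screening uses 6 electrodes × 20 conditions × 25 trials; window selection
uses 10 electrodes × 75 conditions (a balanced fraction of the factorial
design covering every level) × 10 trials; the qualitative-pattern checks
use 24 electrodes with the full 375-condition design at 6 trials per
condition and a 10 Hz frequency grid; chance-level estimation uses 50
electrodes × 10 shuffled repetitions. Full-scale defaults (202 electrodes,
21–39 trials, 2 Hz grid) remain the generator's and pipeline's defaults.

# Known limitations

* The generator's feature effects share one broadband carrier; real EFPs
  show feature-specific bands, which the ROC stage would localise further.
* The early color trend (a small grand-average bias toward blue/red) is
  not modelled, as discussed above.
* Stage-2 screening cannot separate several equally extreme trials within
  one condition, and ignores strictly single-electrode events.
* The extracted ERF area is SNR-dependent and not an estimator of the
  generator's diameter parameter.
* Decoding is per electrode only; no cross-electrode pooling or
  multi-class decoding is provided.
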