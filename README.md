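# efptools

Analysis of visually evoked **epidural field potentials (EFPs)** — mesoscale
signals recorded by microelectrode arrays resting on the dura over primary
visual cortex. EFPs are attractive for long-term recordings and
brain–computer interfacing because no durotomy is needed, but their
information content has to be established quantitatively. This package
implements the full analysis chain used to do that, together with a
ground-truth-annotated synthetic recording generator, so every stage can be
validated against known parameters:

* **Synthetic sessions** — hexagonal 202-electrode array, retinotopic
  receptive fields (~3° equivalent diameter in the lower-right quadrant),
  a 5 locations × 3 sizes × 5 shapes × 5 colors factorial design (375
  conditions), stimulus-locked broadband-gamma bursts whose amplitude
  follows `exp(−d²/2σ²) ×` size/angularity/color gains, moving-bar mapping
  sweeps, and controlled artifact injection (clipping, power outliers,
  correlated bursts).
* **Preprocessing** — zero-phase FIR low-pass + decimation to 1 kHz,
  regression-based 50 Hz removal against a socket reference, Morlet wavelet
  power (7 cycles), per-trial baseline normalisation
  `WP(f,t) = (P(f,t) − B(f)) / B(f)`.
* **Screening** — the three-stage semi-automatic trial rejection
  (amplifier limits; broadband power beyond ±4 SD per condition and
  electrode; correlated high-power trials with mean pairwise r ≥ 0.5).
* **Receptive-field mapping** — reverse-correlation back-projection of
  bar-evoked 60–150 Hz power, geometric-mean combination across 12 motion
  directions, Z ≥ 1 / ≥ 1 deg² extraction with a surrogate significance
  control, and the orientation index
  `OI = (WP_θ − WP_θ+90)/(WP_θ + WP_θ+90)`.
* **ROC window selection** — one-vs-rest AUC maps per electrode, condition
  and 5-ms × frequency bin; grand-variance maps Z-referenced to
  pre-response bins; automatic bounding-rectangle selection of the most
  informative time–frequency window per feature category.
* **Sensitivity indices** — `SPI = |WP_rnk1 − WP_rnk2|`,
  `SZI = (|WP_l − WP_m| + |WP_m − WP_s|)/2`,
  `SHI = (|WP_c − WP_q| + |WP_q − WP_t|)/2`,
  `CSI = Σ_{i<j}|cWP_i − cWP_j| / mean(cWP)` with
  `cWP = WP(col) − min WP(col)`; distance-binned Kruskal–Wallis tests with
  Tukey–Kramer post-hocs and ω² effect sizes; half-Gaussian response
  fall-off fits; early-vs-late color comparison.
* **Single-trial decoding** — trials collapsed to three numbers (maximal
  WP in the size, shape and color windows), balanced leave-one-out
  RBF-SVMs with five-fold cross-validated C/γ search, ten repetitions,
  shuffled-label chance estimation and Mann–Whitney significance at
  α ≤ 1%.
* **Pipeline** — `efp_config()` + `run_pipeline()` run everything from one
  seeded, YAML-serialisable configuration with per-stage caching; a thin
  CLI wrapper lives in `inst/scripts/efpmap.R`.

## Worked example

```r
library(efptools)

design <- efp_design(n_electrodes = 8)
truth  <- generate_ground_truth(design, seed = 42)
trials <- generate_object_trials(truth, n_trials_per_condition = 10,
                                 seed = 42, condition_ids = 1:75)
wp     <- compute_wp(trials, freqs = seq(20, 160, by = 10), t_keep = c(0, 200))

report <- screen_trials(trials, wp, screen_params())
#> kept 750 of 750 trials

mapping <- generate_mapping_trials(truth, sweeps_per_direction = 3, seed = 42)
erfs    <- map_erfs(mapping, seed = 42)
head(erfs$summary[, c("electrode", "valid", "diameter", "center_x", "center_y")], 3)
#>   electrode valid diameter center_x center_y
#> 1         1 TRUE      6.71     1.86    -6.71
#> 2         2 TRUE      6.68     1.26    -3.61
#> 3         3 TRUE      7.00     5.42    -5.36
truth$erfs[1, c("x", "y")]   # ground truth for electrode 1: (1.90, -6.58)

w <- select_window(grand_variance_map(auc_map(wp, "size")))
#> size window: 30-175 ms, 30-160 Hz (auto)

cmp <- category_mean_power(wp, "size", w)
apply(cmp, 1, function(v) compute_index(setNames(v, colnames(cmp)), "size"))
#> [1] 0.018 1.874 0.010 0.005 0.029 0.027 0.008 0.029
```

Reading the output: no trial hit the amplifier limit or the power/
correlation criteria, so all 750 survive screening. The mapped receptive
field of electrode 1 is recovered within ~0.1° of its true center (the
thresholded area, and hence the reported diameter, is larger than the
generator's FWHM parameter — see the methods vignette). The ROC stage
selects the early broadband window in which stimulus size is most
discriminable, and the per-electrode size-sensitivity index `SZI` is large
exactly for the electrode whose receptive field lies close to the
stimulated locations (electrode 2) and near zero for the others — the
distance dependence the index family is designed to expose.

The full chain — including sensitivity statistics and SVM decoding — runs
from one configuration:

```r
cfg <- efp_config(seed = 1, simulation = list(n_electrodes = 24, n_trials = 10),
                  output_dir = "efp_run")
res <- run_pipeline(cfg)
res$summary$pattern_checks
```

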