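# Shared fixtures, all generated in code.

# Balanced 75-condition fraction of the factorial design: every level of
# every category is present (Graeco-Latin style index constraint).
fractional_condition_ids <- function() {
  cond <- stimulus_conditions()
  li <- cond$location_id
  si <- match(cond$size_class, c("small", "medium", "large"))
  shi <- match(cond$shape, c("circle", "square", "diamond", "triangle",
                             "inverse_triangle"))
  ci <- match(cond$color, c("blue", "brown", "green", "red", "gray"))
  cond$condition_id[(li + si + shi + ci) %% 5 == 0]
}

# A design with every feature gain flat and no distance kernel (null model).
null_design <- function(n_electrodes = 2, ...) {
  efp_design(n_electrodes = n_electrodes,
             size_gain = c(small = 1, medium = 1, large = 1),
             angularity_gain = c(circular = 1, quadrangular = 1, triangular = 1),
             color_gain_early = c(blue = 1, brown = 1, green = 1, red = 1, gray = 1),
             color_gain_late = c(blue = 1, brown = 1, green = 1, red = 1, gray = 1),
             gain_jitter_sdlog = 0, use_distance_kernel = FALSE, ...)
}

# Per-trial evoked broadband power (30-180 ms window) minus baseline power,
# computed directly from the voltage traces.
evoked_power <- function(trials, electrode = 1) {
  on <- trials$onset_index
  fs <- trials$fs
  win <- on + seq(round(0.03 * fs), round(0.18 * fs))
  base <- seq_len(on - 1)
  apply(trials$voltage[, electrode, win, drop = FALSE], 1,
        function(v) var(as.vector(v))) -
    apply(trials$voltage[, electrode, base, drop = FALSE], 1,
          function(v) var(as.vector(v)))
}

# Small normalized tfp built from an object-trial simulation.
small_wp <- function(trials, freqs = seq(20, 160, by = 10), t_keep = c(0, 200)) {
  compute_wp(trials, freqs = freqs, bin_ms = 5, t_keep = t_keep)
}

# Full-domain analysis windows (used where ROC selection is not under test).
domain_windows <- function() {
  w <- function(cat, t0 = 26, t1 = 175, f0 = 25, f1 = 160) {
    structure(list(category = cat, t0 = t0, t1 = t1, f0 = f0, f1 = f1,
                   provenance = "manual"), class = "efp_window")
  }
  list(location = w("location"), size = w("size"), shape = w("shape"),
       color = w("color", t0 = 120, t1 = 175))
}
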