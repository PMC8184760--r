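# Controlled artifact injection into a clean trial set.

#' Artifact injection specification
#'
#' Fractions of trials to corrupt per failure mode. The three modes mirror
#' the stages of the screening procedure: amplifier clipping, broadband
#' power outliers, and high-power bursts shared across most electrodes.
#'
#' @param clip,power_outlier,correlated_burst fractions in [0, 1]; their sum
#'   must not exceed 1 (a trial receives at most one artifact).
#' @param burst_electrode_frac fraction of electrodes receiving the shared
#'   burst (>= 0.8 by construction of the failure mode).
#' @param outlier_scale voltage scaling factor applied during the response
#'   window of power-outlier trials (power scales with its square).
#' @param burst_amp amplitude (microvolts) of the shared broadband burst.
#' @return list of class `efp_artifact_spec`.
#' @export
artifact_spec <- function(clip = 0, power_outlier = 0, correlated_burst = 0,
                          burst_electrode_frac = 0.9, outlier_scale = 4,
                          burst_amp = 100) {
  fr <- c(clip, power_outlier, correlated_burst)
  if (any(fr < 0) || any(fr > 1)) stop("artifact fractions must be in [0, 1]")
  if (sum(fr) > 1) stop("artifact fractions must not sum to more than 1")
  if (burst_electrode_frac < 0.8 || burst_electrode_frac > 1) {
    stop("burst_electrode_frac must be in [0.8, 1]")
  }
  structure(list(clip = clip, power_outlier = power_outlier,
                 correlated_burst = correlated_burst,
                 burst_electrode_frac = burst_electrode_frac,
                 outlier_scale = outlier_scale, burst_amp = burst_amp),
            class = "efp_artifact_spec")
}

#' Inject artifacts into a trial set
#'
#' Corrupts disjoint random subsets of trials according to `spec` and updates
#' the ground-truth artifact labels. Clean trials are left bit-exactly
#' untouched.
#'
#' Modes: `clipped` trials have a subset of electrodes saturated at the
#' amplifier limit (samples exactly equal to +/- `amp_limit`);
#' `power_outlier` trials have their response window scaled by
#' `outlier_scale` (raising broadband power far beyond +6 SD of the
#' condition's distribution); `correlated_burst` trials receive one shared
#' broadband (30-160 Hz) burst added to >= 80% of electrodes, producing mean
#' pairwise correlations >= 0.5 across electrodes in the burst window.
#'
#' @param trials an `efp_trials` object.
#' @param spec an [artifact_spec()].
#' @param seed integer RNG seed.
#' @return the modified `efp_trials` object with updated `trials$artifact`.
#' @export
inject_artifacts <- function(trials, spec = artifact_spec(), seed = 1L) {
  stopifnot(inherits(trials, "efp_trials"), inherits(spec, "efp_artifact_spec"))
  n_trials <- nrow(trials$trials)
  n_elec <- dim(trials$voltage)[2]
  n_time <- dim(trials$voltage)[3]
  fs <- trials$fs
  onset <- trials$onset_index
  n_clip <- round(spec$clip * n_trials)
  n_out <- round(spec$power_outlier * n_trials)
  n_burst <- round(spec$correlated_burst * n_trials)
  if (n_clip + n_out + n_burst == 0) return(trials)

  with_seed(derive_seed(seed, "artifacts"), {
    picked <- sample(n_trials, n_clip + n_out + n_burst)
    idx_clip <- head(picked, n_clip)
    idx_out <- picked[seq_len(n_out) + n_clip]
    idx_burst <- tail(picked, n_burst)

    win <- onset:min(onset + round(0.15 * fs), n_time)
    for (i in idx_clip) {
      el <- sample(n_elec, max(1, ceiling(0.25 * n_elec)))
      for (e in el) {
        seg <- trials$voltage[i, e, win]
        peak <- max(abs(seg))
        if (peak == 0) peak <- 1
        trials$voltage[i, e, win] <- seg * (1.25 * trials$amp_limit / peak)
      }
      v <- trials$voltage[i, , ]
      trials$voltage[i, , ] <- pmin(pmax(v, -trials$amp_limit), trials$amp_limit)
      trials$trials$artifact[i] <- "clipped"
    }

    resp <- onset:min(onset + round(0.4 * fs), n_time)
    edge <- round(0.01 * fs)
    taper <- c(0.5 * (1 - cos(pi * seq_len(edge) / edge)),
               rep(1, length(resp) - 2 * edge),
               0.5 * (1 + cos(pi * seq_len(edge) / edge)))
    for (i in idx_out) {
      gain <- 1 + (spec$outlier_scale - 1) * taper
      trials$voltage[i, , resp] <- sweep(trials$voltage[i, , resp, drop = TRUE], 2, gain, "*")
      trials$trials$artifact[i] <- "power_outlier"
    }

    bwin <- (onset + round(0.02 * fs)):(onset + round(0.17 * fs))
    for (i in idx_burst) {
      common <- spec$burst_amp * band_noise(length(bwin), 1, fs, 30, 160)[, 1]
      el <- sample(n_elec, ceiling(spec$burst_electrode_frac * n_elec))
      for (e in el) {
        trials$voltage[i, e, bwin] <- trials$voltage[i, e, bwin] + common
      }
      trials$trials$artifact[i] <- "correlated_burst"
    }
    trials
  })
}
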