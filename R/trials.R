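# Synthetic trial generation: object flashes and moving-bar mapping sweeps.

#' Generate object-flash trials
#'
#' Simulates trial-segmented voltage traces for a set of stimulus conditions.
#' Each trial is a 500 ms pre-stimulus baseline followed by an 800 ms
#' stimulus epoch. The signal model is additive: a 1/f background plus a
#' stimulus-locked band-limited gamma burst (~25 ms rise) whose amplitude is
#' the product of the electrode's peak gain, the Gaussian ERF-stimulus
#' distance kernel `exp(-d^2 / (2 sigma^2))`, the size gain, the angularity
#' gain and the early color gain, plus an additive late-window component
#' carrying the late color gain. Per-trial log-normal gain noise models
#' response variability.
#'
#' @param truth an `efp_truth` object from [generate_ground_truth()].
#' @param n_trials_per_condition a single count, or a length-2 range from
#'   which per-condition counts are drawn uniformly (default `c(21, 39)`,
#'   the typical per-condition range for this kind of session).
#' @param seed integer RNG seed.
#' @param condition_ids optional subset of condition ids to simulate
#'   (default: all 375).
#' @param electrodes optional subset of electrode ids.
#' @param fs sampling rate in Hz (default 1000; use 25000 only to exercise
#'   the decimation stage on short snippets).
#' @param baseline_ms,stim_ms epoch structure in ms.
#' @return list of class `efp_trials`: `voltage` array
#'   (trial x electrode x time, microvolts), `fs`, `onset_index`,
#'   `baseline_index`, `trials` tibble (condition labels plus ground-truth
#'   artifact label, all `"clean"`), `electrodes`, `amp_limit`, `seed`.
#' @export
generate_object_trials <- function(truth, n_trials_per_condition = c(21, 39),
                                   seed = 1L, condition_ids = NULL,
                                   electrodes = NULL, fs = 1000,
                                   baseline_ms = 500, stim_ms = 800) {
  stopifnot(inherits(truth, "efp_truth"))
  if (length(n_trials_per_condition) < 1 || any(n_trials_per_condition < 1)) {
    stop("n_trials_per_condition must be >= 1")
  }
  conds <- truth$conditions
  if (!is.null(condition_ids)) {
    conds <- conds[conds$condition_id %in% condition_ids, , drop = FALSE]
  }
  if (nrow(conds) == 0) stop("condition list is empty")
  erfs <- truth$erfs
  if (!is.null(electrodes)) {
    erfs <- erfs[erfs$electrode_id %in% electrodes, , drop = FALSE]
  }
  des <- truth$design

  n_base <- round(baseline_ms * fs / 1000)
  n_stim <- round(stim_ms * fs / 1000)
  n_time <- n_base + n_stim
  onset_index <- n_base + 1L
  t_rel <- (seq_len(n_time) - onset_index) * 1000 / fs  # ms relative to onset

  # transient onset burst decaying into the sustained period, plus a
  # separate sustained component confined to the late window
  env_early <- ramp_env(t_rel, 30, 25, 120, 60)
  env_late <- ramp_env(t_rel, des$late_window[1] - 10, 15, des$late_window[2] + 5, 40)

  with_seed(derive_seed(seed, "object_trials"), {
    n_per <- if (length(n_trials_per_condition) == 1) {
      rep(n_trials_per_condition, nrow(conds))
    } else {
      sample(seq(n_trials_per_condition[1], n_trials_per_condition[2]),
             nrow(conds), replace = TRUE)
    }
    trials <- conds[rep(seq_len(nrow(conds)), n_per), , drop = FALSE]
    trials$trial_id <- seq_len(nrow(trials))
    trials$artifact <- "clean"
    trials <- trials[, c("trial_id", setdiff(names(trials), "trial_id"))]
    n_trials <- nrow(trials)
    n_elec <- nrow(erfs)

    voltage <- array(0, dim = c(n_trials, n_elec, n_time))
    for (e in seq_len(n_elec)) {
      erf <- erfs[e, ]
      d <- sqrt((trials$loc_x - erf$x)^2 + (trials$loc_y - erf$y)^2)
      kern <- if (des$use_distance_kernel) exp(-d^2 / (2 * erf$sigma^2)) else rep(1, n_trials)
      gtab <- unlist(erf[grep("^gain_", names(erf))])
      g_size <- gtab[paste0("gain_size_", trials$size_class)]
      g_ang <- gtab[paste0("gain_ang_", trials$angularity)]
      g_col_e <- gtab[paste0("gain_col_early_", trials$color)]
      g_col_l <- gtab[paste0("gain_col_late_", trials$color)]
      g <- erf$peak_gain * kern * g_size * g_ang
      amp_e <- des$burst_amp * g * g_col_e * exp(rnorm(n_trials, 0, erf$trial_noise_sdlog))
      amp_l <- des$late_amp * g * g_col_l * exp(rnorm(n_trials, 0, erf$trial_noise_sdlog))

      base <- des$baseline_sd * pink_noise(n_time, n_trials)
      b1 <- band_noise(n_time, n_trials, fs, des$burst_band[1], des$burst_band[2])
      b2 <- band_noise(n_time, n_trials, fs, des$burst_band[1], des$burst_band[2])
      v <- base + sweep(b1 * env_early, 2, amp_e, "*") + sweep(b2 * env_late, 2, amp_l, "*")
      voltage[, e, ] <- t(v)
    }
    structure(list(voltage = voltage, fs = fs, onset_index = onset_index,
                   baseline_index = c(1L, n_base), trials = trials,
                   electrodes = erfs$electrode_id, amp_limit = des$amp_limit,
                   seed = seed),
              class = "efp_trials")
  })
}

#' Generate moving-bar mapping sweeps
#'
#' Simulates the automated receptive-field mapping protocol: a thin gray bar
#' (0.24 x 23.8 degrees) moving along a 19.1-degree trajectory centered at
#' (2.4, -3.6) degrees, in one of 12 directions spaced by 30 degrees. The
#' bar-evoked gamma amplitude at every instant follows the line integral of
#' the electrode's Gaussian ERF along the bar (closed form
#' `exp(-d_perp^2 / (2 sigma^2))` for a bar much longer than sigma),
#' modulated by the orientation bias
#' `1 + depth * cos(2 * (theta_bar - theta_pref))`.
#'
#' @param truth an `efp_truth` object.
#' @param sweeps_per_direction sweeps per motion direction (>= 1).
#' @param seed integer RNG seed.
#' @param electrodes optional subset of electrode ids.
#' @param fs sampling rate (Hz).
#' @param sweep_s sweep duration in seconds (bar speed = 19.1 / `sweep_s`
#'   deg/s).
#' @param map_amp peak bar-evoked amplitude (microvolts) at unit gain.
#' @param map_band frequency band (Hz) of the bar-evoked activity.
#' @return list of class `efp_mapping`: `voltage` (sweep x electrode x time),
#'   `direction_deg` per sweep, `bar_pos` (position along the trajectory per
#'   sample, degrees), `traj_center`, `bar_width`, `bar_length`, `fs`,
#'   `electrodes`, `seed`.
#' @export
generate_mapping_trials <- function(truth, sweeps_per_direction = 3, seed = 1L,
                                    electrodes = NULL, fs = 1000, sweep_s = 1,
                                    map_amp = 45, map_band = c(60, 150)) {
  stopifnot(inherits(truth, "efp_truth"))
  if (sweeps_per_direction < 1) stop("sweeps_per_direction must be >= 1")
  erfs <- truth$erfs
  if (!is.null(electrodes)) erfs <- erfs[erfs$electrode_id %in% electrodes, , drop = FALSE]
  des <- truth$design
  traj_center <- c(2.4, -3.6)
  traj_len <- 19.1
  n_time <- round(sweep_s * fs)
  bar_pos <- seq(-traj_len / 2, traj_len / 2, length.out = n_time)
  directions <- rep(seq(0, 330, by = 30), each = sweeps_per_direction)
  n_sweep <- length(directions)
  n_elec <- nrow(erfs)

  with_seed(derive_seed(seed, "mapping_trials"), {
    voltage <- array(0, dim = c(n_sweep, n_elec, n_time))
    for (e in seq_len(n_elec)) {
      erf <- erfs[e, ]
      offs <- c(erf$x - traj_center[1], erf$y - traj_center[2])
      for (s in seq_len(n_sweep)) {
        phi <- directions[s] * pi / 180
        u <- c(cos(phi), sin(phi))                      # motion direction
        theta_bar <- (directions[s] + 90) %% 180        # bar orientation
        d_perp <- sum(offs * u) - bar_pos
        ori <- 1 + erf$ori_depth * cos(2 * (theta_bar - erf$theta_pref) * pi / 180)
        amp <- map_amp * erf$peak_gain * ori * exp(-d_perp^2 / (2 * erf$sigma^2))
        noise <- des$baseline_sd * pink_noise(n_time, 1)[, 1]
        burst <- band_noise(n_time, 1, fs, map_band[1], map_band[2])[, 1]
        voltage[s, e, ] <- noise + amp * burst
      }
    }
    structure(list(voltage = voltage, direction_deg = directions,
                   bar_pos = bar_pos, traj_center = traj_center,
                   bar_width = 0.24, bar_length = 23.8, fs = fs,
                   electrodes = erfs$electrode_id, seed = seed),
              class = "efp_mapping")
  })
}
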