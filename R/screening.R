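# Three-stage semi-automatic trial screening.

#' Mean pairwise Pearson correlation across electrodes
#'
#' Mean of the upper-triangle Pearson coefficients between electrode traces
#' of one trial segment. Electrodes with zero variance are excluded from the
#' pairs with a warning.
#'
#' @param segment numeric matrix, electrodes x time samples.
#' @return mean pairwise correlation (scalar).
#' @export
pairwise_correlation <- function(segment) {
  stopifnot(is.matrix(segment), nrow(segment) >= 2, ncol(segment) >= 3)
  v <- apply(segment, 1, var)
  if (any(v == 0)) {
    warning(sum(v == 0), " zero-variance electrode trace(s) excluded from correlation")
    segment <- segment[v > 0, , drop = FALSE]
    if (nrow(segment) < 2) return(NA_real_)
  }
  upper_tri_mean(cor(t(segment)))
}

#' Screening thresholds
#'
#' @param sd_limit stage-2 outlier bound in SDs of per-condition broadband
#'   power (default 4).
#' @param power_percentile stage-3 candidate percentile (default 0.8).
#' @param r_limit stage-3 mean pairwise correlation bound (default 0.5).
#' @param majority_frac fraction of electrodes that must exceed the
#'   percentile for a trial to become a stage-3 candidate (default 0.5,
#'   i.e. a majority).
#' @param broadband broadband frequency range (Hz) used for trial power.
#' @param window analysis window (ms post onset) over which power and
#'   correlations are evaluated.
#' @param manual_exclude optional integer vector of trial ids excluded
#'   up front (stands in for a final visual inspection).
#' @return list of class `efp_screen_params`.
#' @export
screen_params <- function(sd_limit = 4, power_percentile = 0.8, r_limit = 0.5,
                          majority_frac = 0.5, broadband = c(30, 160),
                          window = c(26, 175), manual_exclude = integer()) {
  structure(list(sd_limit = sd_limit, power_percentile = power_percentile,
                 r_limit = r_limit, majority_frac = majority_frac,
                 broadband = broadband, window = window,
                 manual_exclude = manual_exclude),
            class = "efp_screen_params")
}

#' Three-stage trial screening
#'
#' Applies the semi-automatic rejection cascade: (1) trials in which any
#' electrode reaches the amplifier limit; (2) trials whose broadband
#' (30-160 Hz) power lies outside the mean +/- 4 SD of the remaining trials
#' of the same stimulus condition at any analyzed electrode (mean and SD
#' are jackknifed, i.e. computed without the tested trial, so an extreme
#' trial cannot mask itself); (3) among the
#' remaining trials, those above the 80th power percentile at a majority of
#' electrodes are tested for unusually strong cross-electrode correlations
#' and rejected if the mean pairwise Pearson coefficient is >= 0.5. Stages
#' run strictly in order on the surviving set; stage-2 statistics are
#' computed once on the post-stage-1 set.
#'
#' @param trials an `efp_trials` object (provides raw voltage, amplifier
#'   limit, and condition labels).
#' @param tfp an `efp_tfp` computed from `trials`; broadband trial power is
#'   taken from it. Unnormalized power is accepted as well as WP.
#' @param params a [screen_params()] object.
#' @return tibble of class `efp_screening` with one row per trial:
#'   `trial_id`, `condition_id`, `decision` ("keep"/"reject"), `stage`
#'   (NA, 1, 2, 3 or "manual"), `broadband_power`, `mean_r`.
#' @export
screen_trials <- function(trials, tfp, params = screen_params()) {
  stopifnot(inherits(trials, "efp_trials"), inherits(tfp, "efp_tfp"))
  n_trials <- nrow(trials$trials)
  fsel <- tfp$freqs >= params$broadband[1] & tfp$freqs <= params$broadband[2]
  tsel <- tfp$time_ms >= params$window[1] & tfp$time_ms <= params$window[2]
  if (!any(fsel)) stop("broadband window outside the frequency grid")
  # [trial x electrode] broadband power in the analysis window
  bp <- apply(tfp$power[, , fsel, tsel, drop = FALSE], c(1, 2), mean)

  report <- tibble(trial_id = trials$trials$trial_id,
                   condition_id = trials$trials$condition_id,
                   decision = "keep", stage = NA_character_,
                   broadband_power = rowMeans(bp), mean_r = NA_real_)

  if (length(params$manual_exclude)) {
    hit <- report$trial_id %in% params$manual_exclude
    report$decision[hit] <- "reject"
    report$stage[hit] <- "manual"
  }

  # stage 1: amplifier limit
  alive <- report$decision == "keep"
  peak <- apply(abs(trials$voltage), 1, max)
  s1 <- alive & peak >= trials$amp_limit
  report$decision[s1] <- "reject"
  report$stage[s1] <- "1"

  # stage 2: per-condition, per-electrode +/- sd_limit SD; applied twice so
  # that trials unmasked by a first-round rejection are caught as well
  for (pass in 1:2) {
  alive <- report$decision == "keep"
  conds <- unique(report$condition_id[alive])
  for (cid in conds) {
    idx <- which(alive & report$condition_id == cid)
    if (length(idx) < 3) {
      if (pass == 1) {
        warning("condition ", cid, " has fewer than 3 trials; skipped in stage 2/3")
      }
      next
    }
    # jackknifed mean/SD: each trial is compared against the statistics of
    # the *other* trials of its condition, so a single extreme trial cannot
    # mask itself by inflating the SD it is tested against
    sub <- bp[idx, , drop = FALSE]
    n <- nrow(sub)
    tot <- colSums(sub)
    totsq <- colSums(sub^2)
    m_loo <- (matrix(tot, n, ncol(sub), byrow = TRUE) - sub) / (n - 1)
    ss_loo <- matrix(totsq, n, ncol(sub), byrow = TRUE) - sub^2
    v_loo <- pmax((ss_loo - (n - 1) * m_loo^2) / (n - 2), 0)
    out <- abs(sub - m_loo) > params$sd_limit * sqrt(v_loo)
    # a trial is rejected when it is an outlier at a majority of the
    # analyzed electrodes: artifacts of this kind are array-wide, and a
    # per-electrode union would scale its false-alarm rate with the
    # electrode count
    bad <- idx[rowMeans(out) > params$majority_frac]
    report$decision[bad] <- "reject"
    report$stage[bad] <- "2"
  }
  }

  # stage 3: high-power candidates tested for shared bursts
  alive <- report$decision == "keep"
  win <- trials$onset_index +
    seq(round(params$window[1] * trials$fs / 1000),
        round(params$window[2] * trials$fs / 1000))
  win <- win[win <= dim(trials$voltage)[3]]
  for (cid in unique(report$condition_id[alive])) {
    idx <- which(alive & report$condition_id == cid)
    if (length(idx) < 3) next
    thr <- apply(bp[idx, , drop = FALSE], 2, quantile, probs = params$power_percentile)
    high <- sweep(bp[idx, , drop = FALSE], 2, thr, ">")
    cand <- idx[rowMeans(high) > params$majority_frac]
    for (i in cand) {
      seg <- trials$voltage[i, , win, drop = TRUE]
      if (is.null(dim(seg))) seg <- matrix(seg, nrow = 1)
      r <- suppressWarnings(pairwise_correlation(seg))
      report$mean_r[i] <- r
      if (!is.na(r) && r >= params$r_limit) {
        report$decision[i] <- "reject"
        report$stage[i] <- "3"
      }
    }
  }
  class(report) <- c("efp_screening", class(report))
  report
}
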