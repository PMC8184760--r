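# Preprocessing: decimation, line-noise removal, Morlet wavelet power,
# baseline normalisation.

#' Zero-phase low-pass filtering, decimation and line-noise removal
#'
#' Applies a zero-phase FIR low-pass (cutoff 150 Hz, filtered forward and
#' backward) before integer decimation to the target rate. If a 50 Hz line
#' reference (e.g. a socket signal recorded alongside the data) is supplied,
#' its in-phase and quadrature components are regressed out of the signal by
#' least squares, which removes the line component without notching
#' neighbouring frequencies.
#'
#' @param x numeric vector (single trace) at the source rate.
#' @param fs_in source sampling rate (Hz); must be an integer multiple of
#'   `fs_out`.
#' @param fs_out output rate (default 1000 Hz).
#' @param line_ref optional line reference trace sampled at `fs_in`.
#' @param cutoff_hz FIR cutoff (default 150).
#' @return numeric vector at `fs_out`.
#' @export
decimate_and_denoise <- function(x, fs_in, fs_out = 1000, line_ref = NULL,
                                 cutoff_hz = 150) {
  ratio <- fs_in / fs_out
  if (abs(ratio - round(ratio)) > 1e-9) {
    stop("fs_in must be an integer multiple of fs_out (got ratio ", ratio, ")")
  }
  ratio <- as.integer(round(ratio))
  if (ratio > 1) {
    n_ord <- 2 * ceiling(3.3 * fs_in / cutoff_hz / 2)
    fir <- signal::fir1(n_ord, cutoff_hz / (fs_in / 2))
    fir <- fir / sum(fir)  # exact unit DC gain
    x <- filtfilt_padded(fir, x)
    if (!is.null(line_ref)) line_ref <- filtfilt_padded(fir, line_ref)
    keep <- seq(1, length(x), by = ratio)
    x <- x[keep]
    if (!is.null(line_ref)) line_ref <- line_ref[keep]
  }
  if (!is.null(line_ref)) {
    quad <- hilbert_quadrature(line_ref)
    X <- cbind(1, line_ref, quad)
    beta <- qr.coef(qr(X), x)
    x <- x - as.numeric(X %*% beta)
  }
  x
}

# Zero-phase FIR filtering with odd-reflection padding so that edge
# transients do not leak into the retained samples.
filtfilt_padded <- function(fir, x) {
  n <- length(x)
  pad <- min(3 * (length(fir) + 1), n - 1)
  left <- 2 * x[1] - x[(pad + 1):2]
  right <- 2 * x[n] - x[(n - 1):(n - pad)]
  y <- as.numeric(signal::filtfilt(fir, c(left, x, right)))
  y[pad + seq_len(n)]
}

# 90-degree phase-shifted copy via the analytic signal.
hilbert_quadrature <- function(x) {
  n <- length(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  Im(fft(fft(x) * h, inverse = TRUE) / n)
}

# Frequency-domain Morlet kernels: one-sided Gaussians around each target
# frequency. Returns matrix [padded-spectrum x freq].
morlet_kernels <- function(n_pad, fs, freqs, n_cycles) {
  f_axis <- (seq_len(n_pad) - 1) * fs / n_pad
  sapply(freqs, function(f0) {
    sigma_t <- n_cycles / (2 * pi * f0)
    h <- 2 * exp(-2 * pi^2 * sigma_t^2 * (f_axis - f0)^2)
    h[f_axis > fs / 2] <- 0
    h
  })
}

reflect_pad <- function(xmat, pad) {
  n <- nrow(xmat)
  pad <- min(pad, n - 1)
  rbind(xmat[(pad + 1):2, , drop = FALSE], xmat,
        xmat[(n - 1):(n - pad), , drop = FALSE])
}

# Batched Morlet power of columns of xmat [time x series]:
# array [freq x time x series]. Reflection padding at the edges.
morlet_power_mat <- function(xmat, fs, freqs, n_cycles = 7) {
  n <- nrow(xmat)
  sigma_max <- n_cycles / (2 * pi * min(freqs))
  support <- ceiling(3 * sigma_max * fs)
  if (n <= 2 * support / 3) {
    stop("signal shorter than the widest wavelet support (", support, " samples)")
  }
  pad <- min(support, n - 1)
  xp <- reflect_pad(xmat, pad)
  n2 <- 2^ceiling(log2(nrow(xp)))
  xp <- rbind(xp, matrix(0, n2 - nrow(xp), ncol(xmat)))
  spec <- mvfft(xp)
  kernels <- morlet_kernels(n2, fs, freqs, n_cycles)
  out <- array(0, dim = c(length(freqs), n, ncol(xmat)))
  idx <- pad + seq_len(n)
  for (k in seq_along(freqs)) {
    w <- mvfft(spec * kernels[, k], inverse = TRUE) / n2
    out[k, , ] <- abs(w[idx, , drop = FALSE])^2
  }
  out
}

#' Morlet wavelet power of a single trace
#'
#' Squared magnitude of the convolution with complex Morlet wavelets
#' (default 7 cycles), evaluated on a frequency grid. Scaled so that a unit
#' amplitude sinusoid at a grid frequency has power 1 at that frequency.
#' Edges are handled by reflection padding; bins within the half support
#' (3 sigma_t) of either edge are reported in the `"edge_ms"` attribute and
#' should be treated as unreliable.
#'
#' @param x numeric vector sampled at `fs`.
#' @param fs sampling rate (Hz).
#' @param freqs strictly increasing frequency grid (Hz), below Nyquist.
#' @param n_cycles Morlet width in cycles (default 7).
#' @return matrix [frequency x time] with attributes `freqs`, `fs`,
#'   `edge_ms` (per-frequency half support in ms).
#' @export
wavelet_power <- function(x, fs, freqs, n_cycles = 7) {
  stopifnot(is.numeric(x), is.numeric(freqs), length(freqs) >= 1)
  if (is.unsorted(freqs, strictly = TRUE)) stop("frequency grid must be strictly increasing")
  if (max(freqs) >= fs / 2) stop("frequency above Nyquist (", fs / 2, " Hz)")
  p <- morlet_power_mat(matrix(x, ncol = 1), fs, freqs, n_cycles)[, , 1, drop = FALSE]
  dim(p) <- dim(p)[1:2]
  structure(p, freqs = freqs, fs = fs,
            edge_ms = 3 * n_cycles / (2 * pi * freqs) * 1000)
}

#' Construct a time-frequency power object
#'
#' Wraps a power tensor as an `efp_tfp`. `power` may be a 4-d array
#' (trial x electrode x frequency x time) or a plain [frequency x time]
#' matrix (expanded to one trial and one electrode).
#'
#' @param power power tensor or matrix.
#' @param freqs frequency vector (Hz), strictly increasing.
#' @param time_ms time bin centers, ms relative to stimulus onset.
#' @param normalized whether `power` is already baseline-normalized.
#' @param baseline_ms baseline window `c(t0, t1)` in ms (t < 0 before onset).
#' @param bin_ms time bin width (ms).
#' @param labels optional tibble of per-trial condition labels.
#' @return object of class `efp_tfp`.
#' @export
as_tfp <- function(power, freqs, time_ms, normalized = FALSE,
                   baseline_ms = NULL, bin_ms = NULL, labels = NULL) {
  if (is.matrix(power)) {
    power <- array(power, dim = c(1, 1, nrow(power), ncol(power)))
  }
  stopifnot(length(dim(power)) == 4, dim(power)[3] == length(freqs),
            dim(power)[4] == length(time_ms))
  if (is.unsorted(freqs, strictly = TRUE)) stop("frequency grid must be strictly increasing")
  structure(list(power = power, freqs = freqs, time_ms = time_ms,
                 normalized = normalized, baseline_ms = baseline_ms,
                 bin_ms = bin_ms %||% diff(time_ms[1:2]), labels = labels),
            class = "efp_tfp")
}

#' Baseline-normalize wavelet power
#'
#' Per trial, electrode and frequency, computes the mean power `B(f)` over
#' the baseline time bins and rescales the whole series to
#' `WP(f, t) = (P(f, t) - B(f)) / B(f)`, i.e. power change relative to the
#' pre-stimulus baseline. This makes WP invariant to any multiplicative
#' gain on the raw trace.
#'
#' @param tfp an `efp_tfp` (unnormalized).
#' @param baseline_ms baseline window in ms relative to onset; defaults to
#'   the window stored in `tfp`.
#' @return the normalized `efp_tfp`.
#' @export
baseline_normalize <- function(tfp, baseline_ms = NULL) {
  stopifnot(inherits(tfp, "efp_tfp"))
  baseline_ms <- baseline_ms %||% tfp$baseline_ms
  if (is.null(baseline_ms)) stop("no baseline window given or stored")
  idx <- which(tfp$time_ms >= baseline_ms[1] & tfp$time_ms < baseline_ms[2])
  if (length(idx) == 0) stop("baseline window contains no time bins")
  dims <- dim(tfp$power)
  out <- tfp$power
  for (f in seq_len(dims[3])) {
    b <- apply(tfp$power[, , f, idx, drop = FALSE], c(1, 2), mean)
    if (any(b <= 0)) {
      stop(sprintf("non-positive baseline mean at %g Hz", tfp$freqs[f]))
    }
    barr <- array(rep(b, dims[4]), c(dims[1], dims[2], dims[4]))
    pf <- array(tfp$power[, , f, , drop = FALSE], c(dims[1], dims[2], dims[4]))
    out[, , f, ] <- (pf - barr) / barr
  }
  tfp$power <- out
  tfp$normalized <- TRUE
  tfp$baseline_ms <- baseline_ms
  tfp
}

#' Wavelet power tensor for a trial set
#'
#' Runs the Morlet transform over every trial and electrode of an
#' `efp_trials` object, optionally baseline-normalizes per single trial,
#' and averages power into time bins (default 5 ms) within a kept time
#' range. The per-trial baseline mean is computed at full resolution over
#' the pre-stimulus window, excluding samples inside the wavelet half
#' support of the trial edge at each frequency.
#'
#' @param trials an `efp_trials` object (1 kHz).
#' @param freqs frequency grid (Hz), default 2 Hz spacing from 10 to 160.
#' @param n_cycles Morlet width in cycles.
#' @param bin_ms output time bin width (ms).
#' @param t_keep time range (ms relative to onset) retained in the output.
#' @param baseline_ms baseline window for normalisation.
#' @param normalize if `TRUE` (default), return baseline-normalized WP.
#' @return an `efp_tfp` with power [trial x electrode x frequency x bin]
#'   and the trial label table attached as `labels`.
#' @export
compute_wp <- function(trials, freqs = seq(10, 160, by = 2), n_cycles = 7,
                       bin_ms = 5, t_keep = c(0, 250),
                       baseline_ms = NULL, normalize = TRUE) {
  stopifnot(inherits(trials, "efp_trials"))
  dims <- dim(trials$voltage)
  fs <- trials$fs
  if (max(freqs) >= fs / 2) stop("frequency above Nyquist (", fs / 2, " Hz)")
  t_rel <- (seq_len(dims[3]) - trials$onset_index) * 1000 / fs
  baseline_ms <- baseline_ms %||%
    c((trials$baseline_index[1] - trials$onset_index) * 1000 / fs, 0)
  edge_ms <- 3 * n_cycles / (2 * pi * freqs) * 1000
  t0 <- t_rel[1]

  keep <- which(t_rel >= t_keep[1] & t_rel < t_keep[2])
  bin_id <- floor((t_rel[keep] - t_keep[1]) / bin_ms)
  bins <- sort(unique(bin_id))
  time_ms <- t_keep[1] + (bins + 0.5) * bin_ms
  binner <- outer(bin_id, bins, "==")
  binner <- sweep(binner, 2, colSums(binner), "/")  # [kept-sample x bin]

  out <- array(NA_real_, dim = c(dims[1], dims[2], length(freqs), length(bins)))
  for (e in seq_len(dims[2])) {
    xmat <- t(trials$voltage[, e, , drop = TRUE])
    if (dims[1] == 1) xmat <- matrix(trials$voltage[1, e, ], ncol = 1)
    p <- morlet_power_mat(xmat, fs, freqs, n_cycles)  # [freq x time x trial]
    for (f in seq_along(freqs)) {
      pf <- p[f, , , drop = TRUE]
      if (dims[1] == 1) pf <- matrix(pf, ncol = 1)
      if (normalize) {
        bidx <- which(t_rel >= max(baseline_ms[1], t0 + edge_ms[f]) & t_rel < baseline_ms[2])
        if (length(bidx) == 0) stop("baseline window empty after edge exclusion at ",
                                    freqs[f], " Hz")
        b <- colMeans(pf[bidx, , drop = FALSE])
        if (any(b <= 0)) stop(sprintf("non-positive baseline mean at %g Hz", freqs[f]))
        pf <- sweep(sweep(pf, 2, b, "-"), 2, b, "/")
      }
      out[, e, f, ] <- crossprod(pf[keep, , drop = FALSE], binner)  # [trial x bin]
    }
  }
  structure(list(power = out, freqs = freqs, time_ms = time_ms,
                 normalized = normalize, baseline_ms = baseline_ms,
                 bin_ms = bin_ms, edge_ms = edge_ms,
                 labels = trials$trials),
            class = "efp_tfp")
}
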