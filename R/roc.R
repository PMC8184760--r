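# ROC-based selection of informative time-frequency windows.

#' One-vs-rest AUC maps per electrode and category level
#'
#' For each electrode, category level and time-frequency bin, computes the
#' area under the ROC curve separating the single-trial WP values of that
#' level's trials from the trials of all remaining levels of the same
#' category (midrank convention for ties).
#'
#' @param tfp normalized `efp_tfp` (5-ms bins) with attached labels.
#' @param category `"location"`, `"size"`, `"shape"` or `"color"`.
#' @param domain_t,domain_f analyzed time (ms) and frequency (Hz) ranges.
#'   The default time range starts at stimulus onset so that the
#'   pre-response bins provide a null reference for the grand-variance
#'   Z-transform; selected windows are later clipped to 26-175 ms.
#' @return list of class `efp_aucmap`: `auc` array [electrode x level x
#'   frequency x time], `levels`, `freqs`, `time_ms`, `category`.
#' @export
auc_map <- function(tfp, category, domain_t = c(0, 175), domain_f = c(25, 160)) {
  stopifnot(inherits(tfp, "efp_tfp"), !is.null(tfp$labels))
  col <- CATEGORY_COLUMNS[[match.arg(category, names(CATEGORY_COLUMNS))]]
  lab <- as.character(tfp$labels[[col]])
  lev <- sort(unique(lab))
  if (length(lev) < 2) stop("need >= 2 levels in category ", category)
  counts <- table(lab)
  drop <- names(counts)[counts < 2]
  if (length(drop)) {
    warning("level(s) with <2 trials skipped: ", paste(drop, collapse = ", "))
    lev <- setdiff(lev, drop)
  }
  fsel <- which(tfp$freqs >= domain_f[1] & tfp$freqs <= domain_f[2])
  tsel <- which(tfp$time_ms >= domain_t[1] & tfp$time_ms <= domain_t[2])
  dims <- dim(tfp$power)
  n_trials <- dims[1]
  out <- array(NA_real_, dim = c(dims[2], length(lev), length(fsel), length(tsel)))
  for (e in seq_len(dims[2])) {
    x <- tfp$power[, e, fsel, tsel, drop = FALSE]
    dim(x) <- c(n_trials, length(fsel) * length(tsel))
    r <- apply(x, 2, rank)
    for (li in seq_along(lev)) {
      pos <- lab == lev[li]
      n1 <- sum(pos); n2 <- n_trials - n1
      auc <- (colSums(r[pos, , drop = FALSE]) - n1 * (n1 + 1) / 2) / (n1 * n2)
      out[e, li, , ] <- matrix(auc, length(fsel), length(tsel))
    }
  }
  structure(list(auc = out, levels = lev, freqs = tfp$freqs[fsel],
                 time_ms = tfp$time_ms[tsel], category = category),
            class = "efp_aucmap")
}

#' Grand-variance map of AUC values
#'
#' Per time-frequency bin, the variance of the AUC over all electrode-level
#' series, Z-transformed across bins. Variance is high where one level
#' separates well from the others at many electrodes, and near zero where
#' AUCs all sit at 0.5. If the map contains pre-response bins (time below
#' `ref_t_max`), those provide the null reference for the Z-transform:
#' `Z = (v - mean(v_ref)) / sd(v_ref)`, so Z measures how far a bin's AUC
#' variance exceeds its label-exchangeable sampling level. Without such
#' bins the map is standardized against its own mean and SD.
#'
#' @param aucs an `efp_aucmap`.
#' @param ref_t_max latest time (ms) of the pre-response reference bins.
#' @return list of class `efp_zmap`: `z` matrix [frequency x time],
#'   `freqs`, `time_ms`, `category`.
#' @export
grand_variance_map <- function(aucs, ref_t_max = 25) {
  stopifnot(inherits(aucs, "efp_aucmap"))
  d <- dim(aucs$auc)
  if (d[3] * d[4] < 2) stop("need more than one time-frequency bin")
  if (d[1] * d[2] < 2) stop("need >= 2 electrode-level AUC series")
  flat <- aucs$auc
  dim(flat) <- c(d[1] * d[2], d[3] * d[4])
  v <- apply(flat, 2, var)
  vm <- matrix(v, d[3], d[4])
  ref <- vm[, aucs$time_ms < ref_t_max]
  if (length(ref) >= 2 && sd(ref) > 0) {
    z <- (vm - mean(ref)) / sd(ref)
  } else {
    s <- sd(v)
    z <- if (is.na(s) || s == 0) vm * 0 else (vm - mean(v)) / s
  }
  structure(list(z = z, freqs = aucs$freqs,
                 time_ms = aucs$time_ms, category = aucs$category),
            class = "efp_zmap")
}

#' Select the most informative time-frequency window
#'
#' Default method: among the contiguous regions with `Z >= z_sel`, returns
#' the bounding rectangle of the region containing the highest peak Z
#' (ties broken toward earlier time, then lower frequency). A manual
#' window can be supplied instead and is recorded as such.
#'
#' @param zmap an `efp_zmap`.
#' @param z_sel selection threshold (default 2).
#' @param manual optional list with `t0`, `t1`, `f0`, `f1` overriding the
#'   automatic selection.
#' @param clip_t time range (ms) the returned window is clipped to; the
#'   default keeps windows inside the 26-175 ms analysis domain.
#' @return list of class `efp_window`: `category`, `t0`, `t1` (ms), `f0`,
#'   `f1` (Hz), `provenance` ("auto"/"manual").
#' @export
select_window <- function(zmap, z_sel = 2, manual = NULL, clip_t = c(26, 175)) {
  stopifnot(inherits(zmap, "efp_zmap"))
  if (!is.null(manual)) {
    return(structure(list(category = zmap$category, t0 = manual$t0, t1 = manual$t1,
                          f0 = manual$f0, f1 = manual$f1, provenance = "manual"),
                     class = "efp_window"))
  }
  if (!all(is.finite(zmap$z))) stop("non-finite values in the Z map")
  mask <- zmap$z >= z_sel
  if (!any(mask)) {
    stop("no informative region: no bin reaches Z >= ", z_sel,
         "; supply a manual window")
  }
  lab <- EBImage::bwlabel(mask)
  regions <- sort(unique(lab[lab > 0]))
  best <- NULL
  for (rg in regions) {
    zr <- zmap$z
    zr[lab != rg] <- -Inf
    ij <- arrayInd(which.max(zr), dim(zr))
    # lexicographic key: higher peak Z, then earlier time, then lower frequency
    key <- c(-max(zr), zmap$time_ms[ij[2]], zmap$freqs[ij[1]])
    if (is.null(best) || lex_less(key, best$key)) best <- list(rg = rg, key = key)
  }
  ij <- which(lab == best$rg, arr.ind = TRUE)
  half <- if (length(zmap$time_ms) > 1) diff(zmap$time_ms[1:2]) / 2 else 2.5
  t0 <- max(min(zmap$time_ms[ij[, 2]]) - half, clip_t[1])
  t1 <- min(max(zmap$time_ms[ij[, 2]]) + half, clip_t[2])
  if (t0 >= t1) {
    stop("no informative region inside the analysis domain; supply a manual window")
  }
  structure(list(category = zmap$category, t0 = t0, t1 = t1,
                 f0 = min(zmap$freqs[ij[, 1]]),
                 f1 = max(zmap$freqs[ij[, 1]]),
                 provenance = "auto"),
            class = "efp_window")
}

lex_less <- function(a, b) {
  for (i in seq_along(a)) {
    if (a[i] < b[i] - 1e-12) return(TRUE)
    if (a[i] > b[i] + 1e-12) return(FALSE)
  }
  FALSE
}
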