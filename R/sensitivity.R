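# Feature-sensitivity indices and their statistics.

CATEGORY_COLUMNS <- c(location = "location_id", size = "size_class",
                      shape = "shape", color = "color")

#' Per-level mean power in a time-frequency window
#'
#' For each electrode, averages single-trial WP over the bins of the
#' category's time-frequency window and over all trials of each level of
#' the category (all trials are used, re-sorted by the level of interest).
#'
#' @param tfp normalized `efp_tfp` with an attached label table.
#' @param category one of `"location"`, `"size"`, `"shape"`, `"color"`.
#' @param window a window list with `t0`, `t1` (ms) and `f0`, `f1` (Hz),
#'   e.g. a [select_window()] result.
#' @return matrix [electrode x level] of mean WP, with trial counts in the
#'   `"n_trials"` attribute.
#' @export
category_mean_power <- function(tfp, category, window) {
  stopifnot(inherits(tfp, "efp_tfp"), !is.null(tfp$labels))
  col <- CATEGORY_COLUMNS[[match.arg(category, names(CATEGORY_COLUMNS))]]
  lab <- as.character(tfp$labels[[col]])
  fsel <- tfp$freqs >= window$f0 & tfp$freqs <= window$f1
  tsel <- tfp$time_ms >= window$t0 & tfp$time_ms <= window$t1
  if (!any(fsel) || !any(tsel)) stop("window outside the analyzed domain")
  per_trial <- apply(tfp$power[, , fsel, tsel, drop = FALSE], c(1, 2), mean)
  if (is.null(dim(per_trial))) per_trial <- matrix(per_trial, ncol = 1)
  lev <- sort(unique(lab))
  out <- sapply(lev, function(l) colMeans(per_trial[lab == l, , drop = FALSE]))
  out <- matrix(out, ncol = length(lev), dimnames = list(NULL, lev))
  attr(out, "n_trials") <- table(lab)[lev]
  out
}

#' Assign electrodes to their closest stimulus location
#'
#' Each electrode is assigned to the stimulus location with the smallest
#' Euclidean distance to its ERF center (ties broken toward the lowest
#' location id). Distances to all locations are returned rank-ordered.
#'
#' @param centers tibble with `electrode`, `center_x`, `center_y` (and
#'   optionally `valid`; invalid electrodes are dropped with a message).
#' @param locations tibble from [stimulus_locations()].
#' @return tibble with `electrode`, `assigned_location`, `dist_rnk1`,
#'   `dist_rnk2`, and `rank_order` (matrix column: location ids ordered by
#'   distance).
#' @export
assign_electrodes <- function(centers, locations = stimulus_locations()) {
  if ("valid" %in% names(centers)) {
    bad <- !centers$valid | !is.finite(centers$center_x)
    if (any(bad)) {
      message(sum(bad), " electrode(s) without a valid ERF excluded from assignment")
      centers <- centers[!bad, , drop = FALSE]
    }
  }
  n <- nrow(centers)
  d <- outer(centers$center_x, locations$x, "-")^2 +
    outer(centers$center_y, locations$y, "-")^2
  d <- sqrt(d)
  ord <- t(apply(d, 1, function(r) order(r, locations$location_id)))
  tibble(
    electrode = centers$electrode,
    assigned_location = locations$location_id[ord[, 1]],
    dist_rnk1 = d[cbind(seq_len(n), ord[, 1])],
    dist_rnk2 = d[cbind(seq_len(n), ord[, 2])],
    rank_order = I(lapply(seq_len(n), function(i) locations$location_id[ord[i, ]])),
    distances = I(lapply(seq_len(n), function(i) d[i, ]))
  )
}

#' Feature-sensitivity index from per-level mean power
#'
#' Computes the category's index from the per-level mean WP values:
#' \itemize{
#' \item location: `SPI = |WP_rnk1 - WP_rnk2|`, the absolute difference
#'   between the locations eliciting the highest and second-highest
#'   response;
#' \item size: `SZI = (|WP_l - WP_m| + |WP_m - WP_s|) / 2`;
#' \item shape: `SHI = (|WP_c - WP_q| + |WP_q - WP_t|) / 2`, where the
#'   quadrangular and triangular values are the means over their two
#'   constituent shapes;
#' \item color: `CSI = sum_{i<j} |cWP_i - cWP_j| / mean(cWP)` with
#'   `cWP = WP(col) - min(WP(col))`; defined as 0 when all five color
#'   responses are equal.
#' }
#' SPI, SZI and SHI scale with overall activation (k-equivariant under
#' `WP -> k WP`); CSI is invariant under `WP -> k WP + c` for `k > 0`.
#'
#' @param wp named numeric vector of per-level mean WP. Names must be
#'   location ids (location), `small/medium/large` (size), the five shape
#'   names (shape) or the five color names (color).
#' @param category category name.
#' @return the index value (scalar, >= 0).
#' @export
compute_index <- function(wp, category) {
  category <- match.arg(category, names(CATEGORY_COLUMNS))
  need <- switch(category,
    location = NULL,
    size = c("small", "medium", "large"),
    shape = SHAPES,
    color = COLORS)
  if (!is.null(need)) {
    miss <- setdiff(need, names(wp))
    if (length(miss)) stop("missing level(s): ", paste(miss, collapse = ", "))
  }
  switch(category,
    location = {
      if (length(wp) < 2) stop("need >= 2 locations")
      s <- sort(wp, decreasing = TRUE)
      unname(abs(s[1] - s[2]))
    },
    size = (abs(wp[["large"]] - wp[["medium"]]) + abs(wp[["medium"]] - wp[["small"]])) / 2,
    shape = {
      cq <- wp[["circle"]]
      q <- mean(c(wp[["square"]], wp[["diamond"]]))
      t3 <- mean(c(wp[["triangle"]], wp[["inverse_triangle"]]))
      (abs(cq - q) + abs(q - t3)) / 2
    },
    color = {
      cwp <- wp[COLORS] - min(wp[COLORS])
      if (all(cwp == 0)) return(0)
      pairs <- combn(length(cwp), 2)
      sum(abs(cwp[pairs[1, ]] - cwp[pairs[2, ]])) / mean(cwp)
    })
}

#' Sensitivity table over all electrodes and categories
#'
#' @param cmps named list of [category_mean_power()] matrices (names
#'   `location`, `size`, `shape`, `color`).
#' @param assignment tibble from [assign_electrodes()]; row order must
#'   match the electrode dimension of the matrices.
#' @return tibble with `electrode`, `category`, `index`,
#'   `assigned_location`, `dist_rnk1`, `dist_rnk2`.
#' @export
sensitivity_table <- function(cmps, assignment) {
  out <- list()
  for (cat in names(cmps)) {
    m <- cmps[[cat]]
    idx <- apply(m, 1, function(v) compute_index(setNames(v, colnames(m)), cat))
    out[[cat]] <- tibble(electrode = assignment$electrode, category = cat,
                         index = unname(idx),
                         assigned_location = assignment$assigned_location,
                         dist_rnk1 = assignment$dist_rnk1,
                         dist_rnk2 = assignment$dist_rnk2)
  }
  do.call(rbind, out)
}

#' Distance-binned index statistics
#'
#' Bins electrodes by the distance between their ERF center and assigned
#' stimulus location, then tests the index across bins with a
#' Kruskal-Wallis test, Tukey-Kramer-corrected pairwise post-hoc
#' comparisons on rank-transformed data, and an omega-squared effect size.
#' If paired rank-1/rank-2 responses are supplied, a Wilcoxon signed-rank
#' test of rnk1 vs rnk2 is run within each bin.
#'
#' @param values index values per electrode.
#' @param distances ERF-to-assigned-stimulus distance per electrode (deg).
#' @param edges bin edges in degrees (default `c(0, 0.75, 1.5, 2.25, 3)`).
#' @param paired optional list with `rnk1` and `rnk2` response vectors.
#' @return list of class `efp_stats`: `kruskal` (statistic/df/p), `omega2`,
#'   `posthoc` tibble, `bin_medians`, `bin_n`, and `paired_tests` (per bin).
#' @export
distance_binned_stats <- function(values, distances, edges = c(0, 0.75, 1.5, 2.25, 3),
                                  paired = NULL) {
  bin <- cut(distances, edges, include.lowest = TRUE, right = FALSE)
  keep <- !is.na(bin) & is.finite(values)
  values <- values[keep]; bin <- droplevels(bin[keep])
  n_per <- table(bin)
  if (any(n_per < 2)) {
    warning("bin(s) with <2 electrodes dropped: ",
            paste(names(n_per)[n_per < 2], collapse = ", "))
    ok <- bin %in% names(n_per)[n_per >= 2]
    values <- values[ok]; bin <- droplevels(bin[ok])
  }
  if (nlevels(bin) < 2) stop("need >= 2 non-empty distance bins")
  kw <- kw_test(values, bin)
  o2 <- omega_squared(kw$statistic, nlevels(bin), length(values))
  ph <- tukey_ranks(values, bin)
  paired_tests <- NULL
  if (!is.null(paired)) {
    r1 <- paired$rnk1[keep]; r2 <- paired$rnk2[keep]
    paired_tests <- lapply(levels(bin), function(b) {
      i <- bin == b
      if (sum(i) < 2) return(NULL)
      signed_rank_test(r1[i], r2[i])
    })
    names(paired_tests) <- levels(bin)
  }
  structure(list(kruskal = kw, omega2 = o2, posthoc = ph,
                 bin_medians = tapply(values, bin, median),
                 bin_n = table(bin), paired_tests = paired_tests),
            class = "efp_stats")
}

#' Mean normalized power by stimulus distance rank
#'
#' Re-sorts each electrode's per-location mean WP by the distance rank of
#' the locations (rank 1 = closest to the ERF center), normalizes per
#' electrode to its maximum, and averages across electrodes.
#'
#' @param cmp_location [category_mean_power()] matrix for the location
#'   category (columns named by location id).
#' @param assignment tibble from [assign_electrodes()] (same row order).
#' @return numeric vector of length 5: mean normalized power at ranks 1-5.
#' @export
rank_distance_profile <- function(cmp_location, assignment) {
  n <- nrow(cmp_location)
  stopifnot(n == nrow(assignment))
  prof <- matrix(NA_real_, n, 5)
  for (i in seq_len(n)) {
    ord <- as.character(assignment$rank_order[[i]])
    v <- cmp_location[i, ord]
    mx <- max(v)
    prof[i, ] <- if (mx > 0) v / mx else v
  }
  colMeans(prof, na.rm = TRUE)
}

#' Half-Gaussian fit of response versus distance
#'
#' Least-squares fit of `r(d) = a * exp(-d^2 / (2 sigma^2))` with the peak
#' pinned at `d = 0`, describing the fall-off of gamma responses with
#' ERF-stimulus distance.
#'
#' @param distances non-negative distances (deg).
#' @param responses responses at those distances.
#' @param sigma_max upper bound for sigma (deg); fits hitting it are
#'   flagged `flat`.
#' @return list of class `efp_halfgauss`: `a`, `sigma`, `r_squared`, `flat`.
#' @export
fit_half_gaussian <- function(distances, responses, sigma_max = 50) {
  stopifnot(length(distances) == length(responses), length(distances) >= 3,
            all(distances >= 0))
  df <- data.frame(d = distances, r = responses)
  if (sd(responses) == 0) {
    return(structure(list(a = mean(responses), sigma = sigma_max,
                          r_squared = 0, flat = TRUE),
                     class = "efp_halfgauss"))
  }
  start <- list(a = max(responses), s = max(median(distances), 0.5))
  fit <- tryCatch(
    minpack.lm::nlsLM(r ~ a * exp(-d^2 / (2 * s^2)), data = df, start = start,
                      lower = c(a = 0, s = 1e-6), upper = c(a = Inf, s = sigma_max),
                      control = minpack.lm::nls.lm.control(ftol = 1e-15,
                                                           ptol = 1e-15,
                                                           maxiter = 500)),
    error = function(e) stop("half-Gaussian fit failed to converge: ",
                             conditionMessage(e), "; residual sd ",
                             signif(sd(responses), 4)))
  a <- coef(fit)[["a"]]; s <- coef(fit)[["s"]]
  ss_res <- sum(resid(fit)^2)
  ss_tot <- sum((responses - mean(responses))^2)
  structure(list(a = a, sigma = s, r_squared = 1 - ss_res / ss_tot,
                 flat = s >= sigma_max * (1 - 1e-6)),
            class = "efp_halfgauss")
}

#' Early versus late color sensitivity
#'
#' Computes each electrode's CSI in an early and a late response window
#' (same frequency range) and compares them with a paired Wilcoxon
#' signed-rank test across electrodes.
#'
#' @param tfp normalized `efp_tfp` with labels.
#' @param freq_band frequency range (Hz) of the color window.
#' @param early,late time windows in ms (defaults 40-90 and 120-175).
#' @return list of class `efp_early_late`: `csi_early`, `csi_late`
#'   (per-electrode), `test` ([signed_rank_test()] result).
#' @export
early_late_color_comparison <- function(tfp, freq_band, early = c(40, 90),
                                        late = c(120, 175)) {
  if (early[2] > late[1]) warning("early and late windows overlap")
  w_early <- list(t0 = early[1], t1 = early[2], f0 = freq_band[1], f1 = freq_band[2])
  w_late <- list(t0 = late[1], t1 = late[2], f0 = freq_band[1], f1 = freq_band[2])
  cmp_e <- category_mean_power(tfp, "color", w_early)
  cmp_l <- category_mean_power(tfp, "color", w_late)
  csi_e <- apply(cmp_e, 1, function(v) compute_index(setNames(v, colnames(cmp_e)), "color"))
  csi_l <- apply(cmp_l, 1, function(v) compute_index(setNames(v, colnames(cmp_l)), "color"))
  structure(list(csi_early = csi_e, csi_late = csi_l,
                 test = signed_rank_test(csi_l, csi_e)),
            class = "efp_early_late")
}
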