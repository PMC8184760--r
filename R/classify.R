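# Single-trial decoding of stimulus pairs with leave-one-out SVMs.

#' Collapse a trial into its three-number feature representation
#'
#' Per trial, the maximal WP inside the size, shape and color
#' time-frequency windows.
#'
#' @param tfp normalized `efp_tfp`.
#' @param electrode electrode index (position in the tensor).
#' @param windows list of three windows (`size`, `shape`, `color`), each
#'   with `t0`, `t1`, `f0`, `f1`.
#' @return matrix [trial x 3] with columns named after the windows.
#' @export
extract_feature_triplet <- function(tfp, electrode, windows) {
  stopifnot(inherits(tfp, "efp_tfp"), length(windows) == 3)
  out <- sapply(windows, function(w) {
    fsel <- tfp$freqs >= w$f0 & tfp$freqs <= w$f1
    tsel <- tfp$time_ms >= w$t0 & tfp$time_ms <= w$t1
    if (!any(fsel) || !any(tsel)) stop("window outside the trial domain")
    apply(tfp$power[, electrode, fsel, tsel, drop = FALSE], 1, max)
  })
  out <- matrix(out, ncol = 3,
                dimnames = list(NULL, names(windows) %||% c("size", "shape", "color")))
  out
}

scale01 <- function(train, test = NULL) {
  lo <- apply(train, 2, min)
  hi <- apply(train, 2, max)
  rng <- hi - lo
  flat <- rng == 0
  if (any(flat)) {
    warning("degenerate feature(s) with zero range scaled to constant 0.5")
    rng[flat] <- 1
  }
  sc <- function(m) {
    m <- sweep(sweep(m, 2, lo, "-"), 2, rng, "/")
    m[, flat] <- 0.5
    m
  }
  if (is.null(test)) sc(train) else list(train = sc(train), test = sc(test))
}

svm_cv_tune <- function(X, y, cost_grid, gamma_grid, folds = 5) {
  n <- length(y)
  fold_id <- rep_len(seq_len(folds), n)[sample(n)]
  best <- NULL
  for (co in cost_grid) {
    for (ga in gamma_grid) {
      correct <- 0
      for (k in seq_len(folds)) {
        tr <- fold_id != k
        if (length(unique(y[tr])) < 2) next
        fit <- e1071::svm(X[tr, , drop = FALSE], y[tr], kernel = "radial",
                          cost = co, gamma = ga, scale = FALSE)
        correct <- correct + sum(predict(fit, X[!tr, , drop = FALSE]) == y[!tr])
      }
      if (is.null(best) || correct > best$correct) {
        best <- list(cost = co, gamma = ga, correct = correct)
      }
    }
  }
  best
}

#' Leave-one-out SVM decoding of a stimulus pair
#'
#' Repeated decoding runs with RBF-kernel SVMs: per run, the two classes
#' are balanced by random subsampling of the larger class, features are
#' scaled to [0, 1], `C` and `gamma` are estimated by five-fold
#' cross-validated grid search, and every trial is classified once by a
#' model trained on all remaining trials. Scaling (and, optionally, the
#' grid search) uses only the training portion of each leave-one-out split
#' so no information from the held-out trial leaks into training.
#'
#' @param X feature matrix [trial x feature] (e.g. triplets from
#'   [extract_feature_triplet()]).
#' @param y two-level class labels.
#' @param n_runs repetitions (default 10).
#' @param seed RNG seed; run `r` uses a seed derived from (`seed`, `r`).
#' @param shuffle if `TRUE`, class labels are randomly shuffled at the
#'   start of every run (chance estimation).
#' @param cost_grid,gamma_grid hyperparameter grids (powers of two spanning
#'   2^-5..2^15 and 2^-15..2^3).
#' @param tune_per_split if `TRUE`, re-run the grid search inside every
#'   leave-one-out split (much slower); default tunes once per run on the
#'   full balanced set before the leave-one-out loop.
#' @param scale_all if `TRUE`, scale all trials together before the
#'   leave-one-out loop instead of per training split.
#' @return numeric vector of `n_runs` accuracies in [0, 1].
#' @export
loocv_svm <- function(X, y, n_runs = 10, seed = 1L, shuffle = FALSE,
                      cost_grid = 2^seq(-5, 15, by = 4),
                      gamma_grid = 2^seq(-15, 3, by = 4),
                      tune_per_split = FALSE, scale_all = FALSE) {
  X <- as.matrix(X)
  y <- as.factor(y)
  if (nlevels(y) != 2) stop("need exactly 2 classes")
  if (min(table(y)) < 6) stop("need >= 6 trials per class after balancing")
  vapply(seq_len(n_runs), function(run) {
    with_seed(derive_seed(seed, paste0("run", run, if (shuffle) "s" else "")), {
      yy <- if (shuffle) sample(y) else y
      idx <- balanced_subsample(yy)
      Xs <- X[idx, , drop = FALSE]
      ys <- droplevels(yy[idx])
      n <- length(ys)
      if (any(apply(Xs, 2, function(col) diff(range(col))) == 0)) {
        warning("degenerate feature(s) with zero range scaled to constant 0.5")
      }
      if (scale_all) Xs <- suppressWarnings(scale01(Xs))
      tuned <- if (!tune_per_split) {
        sc <- if (scale_all) Xs else suppressWarnings(scale01(Xs))
        svm_cv_tune(sc, ys, cost_grid, gamma_grid)
      } else NULL
      correct <- 0
      for (i in seq_len(n)) {
        tr_x <- Xs[-i, , drop = FALSE]
        te_x <- Xs[i, , drop = FALSE]
        if (!scale_all) {
          sc <- suppressWarnings(scale01(tr_x, te_x))
          tr_x <- sc$train; te_x <- sc$test
        }
        par <- if (tune_per_split) {
          svm_cv_tune(tr_x, ys[-i], cost_grid, gamma_grid)
        } else tuned
        fit <- e1071::svm(tr_x, ys[-i], kernel = "radial",
                          cost = par$cost, gamma = par$gamma, scale = FALSE)
        correct <- correct + (predict(fit, te_x) == ys[i])
      }
      correct / n
    })
  }, numeric(1))
}

balanced_subsample <- function(y) {
  lv <- levels(droplevels(y))
  n_min <- min(table(y))
  unlist(lapply(lv, function(l) {
    i <- which(y == l)
    if (length(i) > n_min) sample(i, n_min) else i
  }))
}

#' Compare true-label and shuffled-label decoding runs
#'
#' Mann-Whitney U test of the true-label accuracies against the
#' shuffled-label (chance) accuracies; performance counts as significant
#' when `p <= alpha` and the true mean exceeds the chance mean.
#'
#' @param true_runs,shuffled_runs accuracy vectors from [loocv_svm()]
#'   (equal length, default 10 each).
#' @param alpha significance level (default 0.01).
#' @return list of class `efp_classification`: `mean_acc`, `chance_acc`,
#'   `p.value`, `significant`, `true_runs`, `shuffled_runs`.
#' @export
chance_and_significance <- function(true_runs, shuffled_runs, alpha = 0.01) {
  if (length(true_runs) != length(shuffled_runs)) {
    stop("need equally many true and shuffled runs")
  }
  if (length(true_runs) < 2) stop("fewer runs than configured")
  wt <- suppressWarnings(wilcox.test(true_runs, shuffled_runs))
  structure(list(mean_acc = mean(true_runs), chance_acc = mean(shuffled_runs),
                 p.value = wt$p.value, statistic = unname(wt$statistic),
                 significant = isTRUE(wt$p.value <= alpha) &&
                   mean(true_runs) > mean(shuffled_runs),
                 true_runs = true_runs, shuffled_runs = shuffled_runs),
            class = "efp_classification")
}

#' Enumerate gamma-contrast condition pairs
#'
#' Builds the condition pairs for high-vs-low, high-vs-medium and
#' medium-vs-low gamma contrasts from orderings of the size, shape and
#' color levels by expected gamma power (highest first). The high pool
#' combines the top size with the top shape and the top two colors; the
#' low pool combines the bottom size with the two lowest-ranked shapes and
#' the three lowest-ranked colors (so the default orderings give the
#' 2 x 3 x 2 = 12 classical high-vs-low combinations); the medium pool is
#' the middle size/shape/color.
#'
#' @param size_order,shape_order,color_order level names ordered from
#'   highest to lowest expected gamma power.
#' @return tibble with `contrast`, `size_a`, `shape_a`, `color_a`,
#'   `size_b`, `shape_b`, `color_b` (a = higher-gamma member).
#' @export
gamma_contrast_pairs <- function(size_order = c("large", "medium", "small"),
                                 shape_order = c("circle", "square", "diamond",
                                                 "triangle", "inverse_triangle"),
                                 color_order = c("blue", "red", "green", "gray",
                                                 "brown")) {
  if (length(unique(size_order)) < 3 || length(unique(shape_order)) < 2 ||
      length(unique(color_order)) < 2) {
    warning("degenerate level ordering; no contrast pairs")
    return(tibble(contrast = character(), size_a = character(),
                  shape_a = character(), color_a = character(),
                  size_b = character(), shape_b = character(),
                  color_b = character()))
  }
  high <- expand.grid(size = size_order[1], shape = shape_order[1],
                      color = color_order[1:2], stringsAsFactors = FALSE)
  low <- expand.grid(size = tail(size_order, 1), shape = tail(shape_order, 2),
                     color = tail(color_order, 3), stringsAsFactors = FALSE)
  mid <- expand.grid(size = size_order[2],
                     shape = shape_order[ceiling(length(shape_order) / 2)],
                     color = color_order[ceiling(length(color_order) / 2)],
                     stringsAsFactors = FALSE)
  cross <- function(a, b, label) {
    g <- expand.grid(i = seq_len(nrow(a)), j = seq_len(nrow(b)))
    tibble(contrast = label,
           size_a = a$size[g$i], shape_a = a$shape[g$i], color_a = a$color[g$i],
           size_b = b$size[g$j], shape_b = b$shape[g$j], color_b = b$color[g$j])
  }
  rbind(cross(high, low, "high_vs_low"),
        cross(high, mid, "high_vs_medium"),
        cross(mid, low, "medium_vs_low"))
}
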