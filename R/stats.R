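# Nonparametric statistics used across the analysis stages.

#' Area under the ROC curve for two samples
#'
#' Rank-based AUC with the midrank convention for ties:
#' `P(x > y) + 0.5 * P(x == y)`, identical to the Mann-Whitney
#' `U / (n1 * n2)`.
#'
#' @param x values of the positive class.
#' @param y values of the negative class.
#' @return AUC in [0, 1].
#' @export
auc_stat <- function(x, y) {
  nx <- length(x); ny <- length(y)
  stopifnot(nx >= 1, ny >= 1)
  r <- rank(c(x, y))
  (sum(r[seq_len(nx)]) - nx * (nx + 1) / 2) / (nx * ny)
}

# Kruskal-Wallis H (tie-corrected) from a rank vector and group index list.
kw_H <- function(r, groups, N) {
  mean_r <- (N + 1) / 2
  H <- 0
  for (g in groups) H <- H + length(g) * (mean(r[g]) - mean_r)^2
  H <- 12 / (N * (N + 1)) * H
  ties <- table(r)
  corr <- 1 - sum(ties^3 - ties) / (N^3 - N)
  if (corr > 0) H / corr else 0
}

#' Kruskal-Wallis test with small-sample permutation p-value
#'
#' For total n up to `exact_n_max` the p-value is computed by complete
#' enumeration of the distinct assignments of observations to groups;
#' otherwise the chi-square approximation is used.
#'
#' @param x numeric values.
#' @param g group labels.
#' @param exact_n_max enumeration threshold (default 10).
#' @return list with `statistic` (H), `df`, `p.value`, `method`.
#' @export
kw_test <- function(x, g, exact_n_max = 10) {
  g <- as.factor(g)
  keep <- is.finite(x)
  x <- x[keep]; g <- droplevels(g[keep])
  N <- length(x)
  k <- nlevels(g)
  if (k < 2) stop("need at least 2 groups")
  r <- rank(x)
  groups <- split(seq_len(N), g)
  H <- kw_H(r, groups, N)
  if (N <= exact_n_max) {
    sizes <- lengths(groups)
    perms <- group_assignments(N, sizes)
    Hs <- vapply(perms, function(p) kw_H(r, p, N), numeric(1))
    p <- mean(Hs >= H - 1e-12)
    method <- "exact permutation"
  } else {
    p <- stats::pchisq(H, k - 1, lower.tail = FALSE)
    method <- "chi-square approximation"
  }
  list(statistic = H, df = k - 1, p.value = p, method = method)
}

# All distinct assignments of 1:N into groups of the given sizes.
group_assignments <- function(N, sizes) {
  rec <- function(avail, sizes) {
    if (length(sizes) == 1) return(list(list(avail)))
    first <- combn(avail, sizes[1], simplify = FALSE)
    out <- list()
    for (f in first) {
      rest <- rec(setdiff(avail, f), sizes[-1])
      out <- c(out, lapply(rest, function(r) c(list(f), r)))
    }
    out
  }
  rec(seq_len(N), sizes)
}

#' Paired Wilcoxon signed-rank test
#'
#' Reports the large-sample Z statistic (tie- and zero-corrected) and a
#' p-value: sign-flip enumeration for `m <= exact_n_max` non-zero
#' differences, normal approximation otherwise. All differences equal to
#' zero gives `p = 1` by convention.
#'
#' @param x,y paired samples.
#' @param exact_n_max enumeration threshold (default 10).
#' @return list with `statistic` (Z), `W`, `n`, `p.value`, `method`.
#' @export
signed_rank_test <- function(x, y, exact_n_max = 10) {
  d <- x - y
  d <- d[is.finite(d)]
  nz <- d != 0
  m <- sum(nz)
  if (m == 0) {
    return(list(statistic = 0, W = 0, n = 0, p.value = 1, method = "all-zero differences"))
  }
  d <- d[nz]
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  mu <- m * (m + 1) / 4
  ties <- table(r)
  sigma2 <- m * (m + 1) * (2 * m + 1) / 24 - sum(ties^3 - ties) / 48
  Z <- (W - mu) / sqrt(sigma2)
  if (m <= exact_n_max) {
    signs <- expand.grid(rep(list(c(0, 1)), m))
    Ws <- as.matrix(signs) %*% r
    p <- mean(abs(Ws - mu) >= abs(W - mu) - 1e-12)
    method <- "exact sign-flip"
  } else {
    p <- 2 * stats::pnorm(-abs(Z))
    method <- "normal approximation"
  }
  list(statistic = Z, W = W, n = m, p.value = min(p, 1), method = method)
}

#' Omega-squared effect size for a Kruskal-Wallis comparison
#'
#' `omega^2 = (H - k + 1) / (n - k)`, clamped at zero.
#'
#' @param H Kruskal-Wallis statistic.
#' @param k number of groups.
#' @param n total observations.
#' @return effect size estimate.
#' @export
omega_squared <- function(H, k, n) {
  max(0, (H - k + 1) / (n - k))
}

#' Tukey-Kramer post-hoc comparisons on rank-transformed data
#'
#' Rank-transforms the pooled values and applies Tukey's honest significant
#' difference criterion to the group means of the ranks, correcting the
#' pairwise p-values for multiple comparisons.
#'
#' @param x numeric values.
#' @param g group labels.
#' @return tibble with `group1`, `group2`, `p.adj`.
#' @export
tukey_ranks <- function(x, g) {
  g <- droplevels(as.factor(g))
  r <- rank(x)
  fit <- aov(r ~ g, data = data.frame(r = r, g = g))
  tk <- TukeyHSD(fit)$g
  pairs <- strsplit(rownames(tk), "-", fixed = TRUE)
  tibble(group1 = vapply(pairs, `[`, "", 1),
         group2 = vapply(pairs, `[`, "", 2),
         p.adj = tk[, "p adj"])
}
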