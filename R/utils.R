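# Internal helpers: synthesis primitives, seeds, small numerics.

#' Derive a child seed from a master seed
#'
#' Deterministic integer hash of (seed, key) kept below 2^31 so downstream
#' stages and per-electrode streams get independent, reproducible RNG seeds.
#'
#' @param seed integer master seed.
#' @param key character or integer stream identifier.
#' @return a single integer seed.
#' @export
derive_seed <- function(seed, key) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  chars <- utf8ToInt(paste0(as.character(key), ":", format(seed, scientific = FALSE)))
  h <- 17
  for (ch in chars) h <- (h * 31 + ch) %% 2147483629
  as.integer(h)
}

assert_positive <- function(x, name) {
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop(sprintf("configuration error: '%s' must be positive and finite", name), call. = FALSE)
  }
  invisible(x)
}

# Columns of 1/f^alpha ("pink") noise, unit variance, length n.
pink_noise <- function(n, m = 1, alpha = 1) {
  nf <- n %/% 2
  f <- seq_len(nf)
  amp <- f^(-alpha / 2)
  re <- matrix(rnorm(nf * m), nf, m) * amp
  im <- matrix(rnorm(nf * m), nf, m) * amp
  spec <- matrix(0 + 0i, n, m)
  spec[2:(nf + 1), ] <- complex(real = re, imaginary = im)
  x <- Re(mvfft(spec, inverse = TRUE))
  x <- x[seq_len(n), , drop = FALSE]
  sweep(x, 2, apply(x, 2, sd), "/")
}

# Columns of band-limited Gaussian noise in [f1, f2] Hz, unit variance.
band_noise <- function(n, m, fs, f1, f2) {
  freqs <- seq(0, fs - fs / n, by = fs / n)
  freqs[freqs > fs / 2] <- freqs[freqs > fs / 2] - fs
  keep <- abs(freqs) >= f1 & abs(freqs) <= f2
  re <- matrix(rnorm(n * m), n, m)
  spec <- mvfft(re)
  spec[!keep, ] <- 0
  x <- Re(mvfft(spec, inverse = TRUE)) / n
  s <- apply(x, 2, sd)
  s[s == 0] <- 1
  sweep(x, 2, s, "/")
}

# Raised-cosine trapezoid envelope over time axis t (ms).
ramp_env <- function(t, t_on, rise, t_off, fall) {
  env <- numeric(length(t))
  up <- t >= t_on & t < t_on + rise
  env[up] <- 0.5 * (1 - cos(pi * (t[up] - t_on) / rise))
  env[t >= t_on + rise & t <= t_off] <- 1
  dn <- t > t_off & t < t_off + fall
  env[dn] <- 0.5 * (1 + cos(pi * (t[dn] - t_off) / fall))
  env
}

# Mean of the upper-triangle entries of a correlation matrix.
upper_tri_mean <- function(m) {
  mean(m[upper.tri(m)])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
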