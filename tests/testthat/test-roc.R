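test_that("AUC follows the Mann-Whitney midrank convention", {
  expect_equal(auc_stat(c(2, 4), c(1, 3)), 0.75)
  expect_equal(auc_stat(c(1, 3), c(2, 4)), 0.25)
  expect_equal(auc_stat(10:15, 1:6), 1)
  expect_equal(auc_stat(c(1, 1, 2), c(1, 1, 2)), 0.5)

  # exchangeable samples stay near 0.5
  withr::with_seed(4, {
    x <- rnorm(200); y <- rnorm(200)
    expect_lt(abs(auc_stat(x, y) - 0.5), 0.05)
  })
})

test_that("auc_map equals direct per-bin one-vs-rest AUCs", {
  withr::with_seed(7, {
    n_tr <- 24
    pw <- array(rnorm(n_tr * 1 * 3 * 4), dim = c(n_tr, 1, 3, 4))
    labels <- tibble::tibble(size_class = rep(c("small", "medium", "large"),
                                              each = 8))
    tfp <- as_tfp(pw, freqs = c(30, 60, 90), time_ms = c(30, 50, 70, 90),
                  normalized = TRUE, labels = labels)
    am <- auc_map(tfp, "size", domain_t = c(0, 100), domain_f = c(25, 100))
    for (li in seq_along(am$levels)) {
      pos <- labels$size_class == am$levels[li]
      for (f in 1:3) for (t in 1:4) {
        expect_equal(am$auc[1, li, f, t],
                     auc_stat(pw[pos, 1, f, t], pw[!pos, 1, f, t]))
      }
    }
  })
})

test_that("grand-variance maps standardize correctly and ignore duplication", {
  # all AUCs at 0.5: zero variance everywhere -> Z identically 0
  am <- structure(list(auc = array(0.5, dim = c(4, 2, 3, 5)), levels = c("a", "b"),
                       freqs = c(30, 60, 90), time_ms = seq(30, 70, 10),
                       category = "size"), class = "efp_aucmap")
  zm <- grand_variance_map(am)
  expect_true(all(zm$z == 0))

  withr::with_seed(1, {
    auc <- array(runif(4 * 2 * 3 * 5), dim = c(4, 2, 3, 5))
    am1 <- structure(list(auc = auc, levels = c("a", "b"), freqs = c(30, 60, 90),
                          time_ms = seq(30, 70, 10), category = "size"),
                     class = "efp_aucmap")
    am2 <- am1
    dup <- array(0, dim = c(4, 4, 3, 5))  # duplicate every electrode series
    dup[, 1:2, , ] <- auc
    dup[, 3:4, , ] <- auc
    am2$auc <- dup
    z1 <- grand_variance_map(am1)
    z2 <- grand_variance_map(am2)
    # duplicating series changes the variance denominator identically in
    # every bin, so the standardized map is unchanged
    expect_equal(z1$z, z2$z, tolerance = 1e-9)
  })
})

test_that("modulation confined to a known rectangle is found by the Z map", {
  withr::with_seed(12, {
    freqs <- seq(25, 100, by = 5)
    times <- seq(2.5, 172.5, by = 5)
    n_tr <- 40
    pw <- array(rnorm(n_tr * 2 * length(freqs) * length(times), sd = 0.1),
                dim = c(n_tr, 2, length(freqs), length(times)))
    labels <- tibble::tibble(size_class = rep(c("small", "large"), each = 20))
    fs <- freqs >= 40 & freqs <= 60
    ts <- times >= 50 & times <= 100
    pw[labels$size_class == "large", , fs, ts] <-
      pw[labels$size_class == "large", , fs, ts] + 1
    tfp <- as_tfp(pw, freqs, times, normalized = TRUE, labels = labels)
    zm <- grand_variance_map(auc_map(tfp, "size", domain_t = c(0, 175),
                                     domain_f = c(25, 160)))
    pk <- arrayInd(which.max(zm$z), dim(zm$z))
    expect_true(zm$freqs[pk[1]] >= 40 && zm$freqs[pk[1]] <= 60)
    expect_true(zm$time_ms[pk[2]] >= 50 && zm$time_ms[pk[2]] <= 100)

    w <- select_window(zm)
    expect_s3_class(w, "efp_window")
    expect_true(w$t0 >= 26 && w$t1 <= 175)
  })
})

make_zmap <- function(z, freqs, times) {
  structure(list(z = z, freqs = freqs, time_ms = times, category = "size"),
            class = "efp_zmap")
}

test_that("window selection returns bounding rectangles with the tie rules", {
  freqs <- seq(30, 80, by = 10)
  times <- seq(32.5, 122.5, by = 5)
  z <- matrix(0, length(freqs), length(times))
  z[2:3, 4:8] <- 3
  w <- select_window(make_zmap(z, freqs, times))
  expect_equal(c(w$f0, w$f1), c(40, 50))
  expect_equal(c(w$t0, w$t1), c(45, 70))
  expect_equal(w$provenance, "auto")

  # two disjoint regions: the higher peak wins even if smaller
  z2 <- matrix(0, length(freqs), length(times))
  z2[1:3, 1:6] <- 2.5
  z2[5, 15] <- 6
  w2 <- select_window(make_zmap(z2, freqs, times))
  expect_equal(c(w2$f0, w2$f1), c(70, 70))

  # equal peaks: earlier time wins, then lower frequency
  z3 <- matrix(0, length(freqs), length(times))
  z3[4, 15] <- 4
  z3[4, 2] <- 4
  w3 <- select_window(make_zmap(z3, freqs, times))
  expect_equal(w3$t1 - 2.5, 37.5)
  z4 <- matrix(0, length(freqs), length(times))
  z4[2, 5] <- 4
  z4[5, 5] <- 4
  w4 <- select_window(make_zmap(z4, freqs, times))
  expect_equal(w4$f0, 40)

  expect_error(select_window(make_zmap(z * 0, freqs, times)),
               "no informative region")
  wm <- select_window(make_zmap(z * 0, freqs, times),
                      manual = list(t0 = 40, t1 = 90, f0 = 30, f1 = 80))
  expect_equal(wm$provenance, "manual")
})
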