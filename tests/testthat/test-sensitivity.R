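test_that("sensitivity indices reproduce hand-computed values exactly", {
  expect_equal(compute_index(c("1" = 0.8, "2" = 0.3, "3" = 0.1, "4" = 0.05,
                               "5" = 0.02), "location"), 0.5)
  expect_equal(compute_index(c(large = 0.9, medium = 0.5, small = 0.3), "size"),
               0.3)
  expect_equal(compute_index(c(circle = 1.0, square = 0.4, diamond = 0.4,
                               triangle = 0.7, inverse_triangle = 0.7), "shape"),
               0.45)
  wp_col <- stats::setNames(1:5, c("blue", "brown", "green", "red", "gray"))
  expect_equal(compute_index(wp_col, "color"), 10)
  # CSI invariances by construction
  expect_equal(compute_index(3 * wp_col, "color"), 10)
  expect_equal(compute_index(wp_col + 7, "color"), 10)
  # all-equal colors: 0/0 convention
  expect_equal(compute_index(stats::setNames(rep(2, 5), names(wp_col)), "color"), 0)
  expect_error(compute_index(c(large = 1, medium = 0.5), "size"),
               "missing level")
})

test_that("CSI is affine invariant and SPI/SZI/SHI scale equivariant", {
  withr::with_seed(3, {
    for (i in 1:25) {
      k <- runif(1, 0.1, 10)
      cc <- runif(1, -5, 5)
      col <- stats::setNames(runif(5), c("blue", "brown", "green", "red", "gray"))
      expect_equal(compute_index(k * col + cc, "color"),
                   compute_index(col, "color"), tolerance = 1e-9)

      loc <- stats::setNames(runif(5), 1:5)
      sz <- stats::setNames(runif(3), c("small", "medium", "large"))
      sh <- stats::setNames(runif(5), c("circle", "square", "diamond",
                                        "triangle", "inverse_triangle"))
      expect_equal(compute_index(k * loc, "location"),
                   k * compute_index(loc, "location"), tolerance = 1e-12)
      expect_equal(compute_index(k * sz, "size"),
                   k * compute_index(sz, "size"), tolerance = 1e-12)
      expect_equal(compute_index(k * sh, "shape"),
                   k * compute_index(sh, "shape"), tolerance = 1e-12)
    }
  })
})

test_that("electrode assignment minimizes Euclidean distance with a stable tie rule", {
  loc <- stimulus_locations()
  centers <- tibble::tibble(electrode = 1, center_x = loc$x[1], center_y = loc$y[1])
  a <- assign_electrodes(centers)
  expect_equal(a$assigned_location, 1)
  expect_equal(a$dist_rnk1, 0)

  # equidistant point between locations 1 and 4: lowest id wins
  mid <- c(mean(loc$x[c(1, 4)]), mean(loc$y[c(1, 4)]))
  shift <- (loc$x[4] - loc$x[1]) * 0  # stay on the perpendicular bisector
  centers2 <- tibble::tibble(electrode = 1, center_x = mid[1], center_y = mid[2])
  d <- sqrt((loc$x - mid[1])^2 + (loc$y - mid[2])^2)
  if (abs(d[1] - d[4]) < 1e-12 && all(d[c(1, 4)] <= min(d[-c(1, 4)]))) {
    expect_equal(assign_electrodes(centers2)$assigned_location, 1)
  }

  withr::with_seed(9, {
    for (i in 1:20) {
      p <- c(runif(1, 0, 8), runif(1, -8, 0))
      got <- assign_electrodes(tibble::tibble(electrode = 1, center_x = p[1],
                                              center_y = p[2]))
      d <- sqrt((loc$x - p[1])^2 + (loc$y - p[2])^2)
      expect_equal(got$assigned_location, which.min(d))
      expect_equal(got$dist_rnk2, sort(d)[2])
    }
  })

  centers3 <- tibble::tibble(electrode = 1:2, center_x = c(2, NA),
                             center_y = c(-2, NA), valid = c(TRUE, FALSE))
  expect_message(a3 <- assign_electrodes(centers3), "excluded")
  expect_equal(nrow(a3), 1)
})

test_that("rank-distance profiles re-sort and normalize per electrode", {
  cmp <- matrix(c(4, 2, 1, 1, 0), nrow = 1, dimnames = list(NULL, as.character(1:5)))
  assignment <- tibble::tibble(electrode = 1, assigned_location = 1,
                               dist_rnk1 = 0.1, dist_rnk2 = 3,
                               rank_order = I(list(1:5)))
  expect_equal(rank_distance_profile(cmp, assignment), c(1, 0.5, 0.25, 0.25, 0))
})

test_that("half-Gaussian fits recover noiseless parameters to 1e-6", {
  d <- seq(0, 4, by = 0.25)
  r <- 2 * exp(-d^2 / (2 * 1.2^2))
  fit <- fit_half_gaussian(d, r)
  expect_equal(fit$a, 2, tolerance = 1e-6)
  expect_equal(fit$sigma, 1.2, tolerance = 1e-6)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  expect_false(fit$flat)

  flat <- fit_half_gaussian(d, rep(3, length(d)))
  expect_true(flat$flat)
  expect_equal(flat$r_squared, 0)
})

test_that("small-sample tests agree with their conventions", {
  # identical values in all groups: H = 0, p = 1
  kw <- kw_test(rep(5, 9), rep(1:3, each = 3))
  expect_equal(kw$statistic, 0)
  expect_equal(kw$p.value, 1)

  # identical paired samples: all-zero differences -> p = 1
  sr <- signed_rank_test(1:8, 1:8)
  expect_equal(sr$p.value, 1)

  # omega squared is clamped at 0
  expect_equal(omega_squared(0.5, 3, 30), 0)
  expect_gt(omega_squared(12, 3, 30), 0)
})

test_that("distance-binned statistics run the full nonparametric cascade", {
  withr::with_seed(5, {
    d <- runif(60, 0, 3)
    v <- exp(-d) + rnorm(60, sd = 0.05)
    st <- distance_binned_stats(v, d)
    expect_s3_class(st, "efp_stats")
    expect_lt(st$kruskal$p.value, 0.01)
    expect_gt(st$omega2, 0.1)
    expect_equal(nrow(st$posthoc), choose(4, 2))
    expect_true(all(st$posthoc$p.adj >= 0 & st$posthoc$p.adj <= 1))
    # medians decrease with distance for a decaying response
    expect_false(is.unsorted(rev(as.numeric(st$bin_medians))))

    paired <- list(rnk1 = v + 0.3, rnk2 = v)
    st2 <- distance_binned_stats(v, d, paired = paired)
    expect_true(all(vapply(st2$paired_tests, function(t) t$p.value, 1) < 0.05))
  })
})

test_that("identical early and late tensors give a signed-rank p of 1", {
  withr::with_seed(2, {
    pw <- array(abs(rnorm(40 * 2 * 3 * 30)) + 0.5, dim = c(40, 2, 3, 30))
    # make the late window a copy of the early window
    tm <- seq(2.5, 150, by = 5)
    early_idx <- tm >= 40 & tm <= 90
    late_idx <- tm >= 95 & tm <= 145
    pw[, , , late_idx] <- pw[, , , early_idx]
    labels <- tibble::tibble(color = rep(c("blue", "brown", "green", "red",
                                           "gray"), 8))
    tfp <- as_tfp(pw, freqs = c(30, 60, 90), time_ms = tm, normalized = TRUE,
                  labels = labels)
    res <- early_late_color_comparison(tfp, c(25, 100), early = c(40, 90),
                                       late = c(95, 145))
    expect_equal(res$test$p.value, 1)
    expect_equal(res$csi_early, res$csi_late)
  })
})
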