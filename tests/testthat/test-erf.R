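centered_truth <- function(x, y, diameter = 2.4, seed = 1, depth = NULL,
                           theta = NULL) {
  truth <- generate_ground_truth(efp_design(n_electrodes = 1), seed = seed)
  truth$erfs$x <- x
  truth$erfs$y <- y
  truth$erfs$diameter <- diameter
  truth$erfs$sigma <- diameter / (2 * sqrt(2 * log(2)))
  truth$erfs$peak_gain <- 1
  if (!is.null(depth)) truth$erfs$ori_depth <- depth
  if (!is.null(theta)) truth$erfs$theta_pref <- theta
  truth
}

test_that("back-projected direction maps ridge over the true ERF center", {
  truth <- centered_truth(2.4, -3.6)
  mp <- generate_mapping_trials(truth, sweeps_per_direction = 3, seed = 2)
  dm <- backproject(mp, 1)
  expect_length(dm$maps, 12)
  for (k in seq_along(dm$maps)) {
    ij <- arrayInd(which.max(dm$maps[[k]]), dim(dm$maps[[k]]))
    # the ridge runs along the bar; its crest must pass near the center,
    # i.e. the peak's projection onto the motion axis is close to the
    # center's projection
    phi <- dm$directions[k] * pi / 180
    u_pk <- (dm$x[ij[1]] - 2.4) * cos(phi) + (dm$y[ij[2]] + 3.6) * sin(phi)
    expect_lt(abs(u_pk), 0.5)
  }
})

test_that("accumulation is linear: a 2-sweep map equals the mean of 1-sweep maps", {
  truth <- centered_truth(3.0, -4.0)
  mp <- generate_mapping_trials(truth, sweeps_per_direction = 2, seed = 5)
  one <- function(k) {
    m <- mp
    sel <- which(mp$direction_deg == 0)[k]
    m$voltage <- mp$voltage[sel, , , drop = FALSE]
    m$direction_deg <- mp$direction_deg[sel]
    backproject(m, 1)$maps[[1]]
  }
  both <- backproject(mp, 1)$maps[[1]]
  expect_equal(both, (one(1) + one(2)) / 2, tolerance = 1e-10)
})

test_that("extraction is geometric-mean based and order invariant", {
  truth <- centered_truth(2.0, -3.0)
  mp <- generate_mapping_trials(truth, sweeps_per_direction = 2, seed = 3)
  dm <- backproject(mp, 1)
  erf <- combine_and_extract(dm)
  dm_perm <- dm
  perm <- c(5, 1, 12, 3, 8, 2, 11, 6, 9, 4, 10, 7)
  dm_perm$maps <- dm$maps[perm]
  dm_perm$directions <- dm$directions[perm]
  erf_perm <- combine_and_extract(dm_perm)
  expect_identical(erf$z, erf_perm$z)
  expect_identical(erf$center, erf_perm$center)

  # diameter-area consistency is exact
  expect_true(erf$valid)
  expect_equal(erf$diameter, 2 * sqrt(erf$area / pi))
})

test_that("electrodes without visual drive yield invalid ERFs", {
  truth <- centered_truth(60, 60)  # ERF far outside the mapped region
  mp <- generate_mapping_trials(truth, sweeps_per_direction = 2, seed = 4)
  hits <- 0
  for (s in 1:5) {
    mp_s <- generate_mapping_trials(truth, sweeps_per_direction = 2, seed = s)
    erf <- combine_and_extract(backproject(mp_s, 1))
    hits <- hits + erf$valid
  }
  expect_lte(hits, 1)
})

test_that("the orientation index is the Michelson contrast of Eq.-style responses", {
  resp <- tibble::tibble(
    orientation = rep(c(0, 30, 60, 90, 120, 150), each = 2),
    response = rep(c(3, 1, 1, 1, 1, 1), each = 2))
  ob <- orientation_bias(resp, n_permutations = 200, seed = 1)
  expect_equal(ob$oi, 0.5)  # (3 - 1) / (3 + 1)
  expect_equal(ob$theta, 0)

  flat <- tibble::tibble(orientation = rep(c(0, 30, 60, 90, 120, 150), each = 2),
                         response = rep(2, 12))
  ob0 <- orientation_bias(flat, n_permutations = 200, seed = 1)
  expect_equal(ob0$oi, 0)
  expect_gt(ob0$p.value, 0.5)

  neg <- flat; neg$response <- rep(-1, 12)
  expect_error(orientation_bias(neg), "positive")
  expect_error(orientation_bias(resp[resp$orientation < 90, ]), "6 orientation")
})

test_that("a simulated orientation bias is recovered within one 30-degree step", {
  hits <- 0
  for (s in 1:6) {
    truth <- centered_truth(2.4, -3.6, seed = s, depth = 0.4, theta = 60)
    mp <- generate_mapping_trials(truth, sweeps_per_direction = 3, seed = s)
    ob <- orientation_bias(orientation_responses(mp, 1), n_permutations = 50,
                           seed = s)
    d <- abs((ob$theta - 60 + 90) %% 180 - 90)
    hits <- hits + (d <= 30)
  }
  expect_gte(hits, 6 * 0.95 - 1)
})
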