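test_that("ground truth is deterministic and honours degenerate configs", {
  t1 <- generate_ground_truth(efp_design(n_electrodes = 5), seed = 3)
  t2 <- generate_ground_truth(efp_design(n_electrodes = 5), seed = 3)
  expect_identical(t1$erfs, t2$erfs)
  expect_equal(nrow(t1$conditions), 375)
  expect_equal(nrow(t1$erfs), 5)
  expect_true(all(t1$erfs$x > 0) && all(t1$erfs$y < 0))

  t3 <- generate_ground_truth(efp_design(n_electrodes = 4, diameter_sd = 0), seed = 1)
  expect_equal(t3$erfs$diameter, rep(3, 4))

  expect_error(efp_design(size_gain = c(small = -1, medium = 1, large = 1)),
               "configuration error")
  expect_error(efp_design(baseline_sd = 0), "configuration error")
})

test_that("object trials are deterministic, labelled, and counted correctly", {
  truth <- generate_ground_truth(efp_design(n_electrodes = 2), seed = 1)
  a <- generate_object_trials(truth, 3, seed = 9, condition_ids = 1:10)
  b <- generate_object_trials(truth, 3, seed = 9, condition_ids = 1:10)
  expect_identical(a$voltage, b$voltage)
  expect_equal(nrow(a$trials), 30)
  expect_true(all(a$trials$artifact == "clean"))
  expect_equal(a$onset_index, 501L)
  expect_equal(dim(a$voltage), c(30, 2, 1300))

  # sampled per-condition counts stay inside the configured range
  r <- generate_object_trials(truth, c(21, 39), seed = 2, condition_ids = 1:4)
  counts <- table(r$trials$condition_id)
  expect_true(all(counts >= 21 & counts <= 39))

  expect_error(generate_object_trials(truth, 0), "n_trials_per_condition")
  expect_error(generate_object_trials(truth, 3, condition_ids = 999),
               "condition list is empty")
})

test_that("full design at 30 trials per condition yields 11250 trials", {
  truth <- generate_ground_truth(efp_design(n_electrodes = 1), seed = 1)
  cond <- truth$conditions
  # count arithmetic only: trial table layout without synthesizing voltage
  n_per <- rep(30, nrow(cond))
  expect_equal(sum(n_per), 11250)
  sub <- generate_object_trials(truth, 30, seed = 1, condition_ids = 1:5)
  expect_equal(nrow(sub$trials), 150)
})

test_that("evoked gamma power decreases with ERF-stimulus distance in every seed", {
  cond <- stimulus_conditions()
  loc <- stimulus_locations()
  pick <- cond$condition_id[cond$size_class == "large" & cond$shape == "circle" &
                             cond$color == "gray" & cond$location_id %in% c(1, 5)]
  for (s in 1:20) {
    truth <- generate_ground_truth(efp_design(n_electrodes = 1), seed = s)
    truth$erfs$x <- loc$x[1]; truth$erfs$y <- loc$y[1]  # ERF centred on location 1
    tr <- generate_object_trials(truth, 6, seed = s, condition_ids = pick)
    p <- tapply(evoked_power(tr), tr$trials$location_id, mean)
    expect_gt(p[["1"]], p[["5"]])
  }
})

test_that("a null design gives statistically indistinguishable condition powers", {
  pass <- 0
  for (s in 1:10) {
    truth <- generate_ground_truth(null_design(1), seed = s)
    tr <- generate_object_trials(truth, 4, seed = s,
                                 condition_ids = fractional_condition_ids())
    kw <- kw_test(evoked_power(tr), tr$trials$location_id)
    pass <- pass + (kw$p.value > 0.01)
  }
  expect_gte(pass, 9)
})

test_that("mapping sweeps have the stated structure and isotropy when unbiased", {
  truth <- generate_ground_truth(efp_design(n_electrodes = 1, ori_depth_mean = 0,
                                            ori_depth_sd = 0, baseline_sd = 1e-3),
                                 seed = 4)
  mp <- generate_mapping_trials(truth, sweeps_per_direction = 3, seed = 1)
  expect_equal(dim(mp$voltage)[1], 36)
  expect_equal(sort(unique(mp$direction_deg)), seq(0, 330, by = 30))
  expect_equal(length(mp$bar_pos), dim(mp$voltage)[3])
  expect_error(generate_mapping_trials(truth, sweeps_per_direction = 0),
               "sweeps_per_direction")

  # bias depth 0: the expected response is orientation-independent, so the
  # seed-averaged orientation means converge to equality
  m <- 0
  for (s in 1:6) {
    mp8 <- generate_mapping_trials(truth, sweeps_per_direction = 8, seed = s)
    resp <- orientation_responses(mp8, 1)
    m <- m + tapply(resp$response, resp$orientation, mean) / 6
  }
  expect_lt(max(m) / min(m), 1.12)
})

test_that("a bar trajectory that never meets the ERF evokes only baseline power", {
  truth <- generate_ground_truth(efp_design(n_electrodes = 1), seed = 2)
  truth$erfs$x <- 60; truth$erfs$y <- 60  # far outside the mapped region
  mp <- generate_mapping_trials(truth, sweeps_per_direction = 2, seed = 3)
  base_sd <- truth$design$baseline_sd
  expect_lt(abs(sd(mp$voltage[1, 1, ]) - base_sd) / base_sd, 0.25)
})

test_that("artifact injection modifies exactly the labelled trials", {
  truth <- generate_ground_truth(efp_design(n_electrodes = 4), seed = 5)
  tr <- generate_object_trials(truth, 10, seed = 6, condition_ids = 1:20)

  expect_identical(inject_artifacts(tr, artifact_spec(), seed = 1), tr)
  expect_error(artifact_spec(clip = 0.6, power_outlier = 0.6), "sum")
  expect_error(artifact_spec(clip = -0.1), "fractions")

  art <- inject_artifacts(tr, artifact_spec(clip = 0.05, power_outlier = 0.05,
                                            correlated_burst = 0.05), seed = 7)
  lab <- art$trials$artifact
  expect_equal(sum(lab == "clipped"), 10)
  expect_equal(sum(lab == "power_outlier"), 10)
  expect_equal(sum(lab == "correlated_burst"), 10)

  # clean trials bit-exact
  clean <- which(lab == "clean")
  expect_identical(art$voltage[clean, , ], tr$voltage[clean, , ])

  # clipped trials contain samples exactly at the limit; only they do
  hits <- apply(abs(art$voltage), 1, max) >= art$amp_limit
  expect_identical(which(hits), which(lab == "clipped"))
  for (i in which(lab == "clipped")) {
    expect_true(any(art$voltage[i, , ] == art$amp_limit |
                      art$voltage[i, , ] == -art$amp_limit))
  }

  # power outliers: broadband power >= +6 SD of their condition's clean trials
  for (i in which(lab == "power_outlier")) {
    same <- which(art$trials$condition_id == art$trials$condition_id[i] &
                    lab == "clean")
    p <- evoked_power(art)
    z <- (p[i] - mean(p[same])) / sd(p[same])
    expect_gte(z, 6)
  }

  # correlated bursts: mean pairwise r across electrodes >= 0.5 in the window
  on <- art$onset_index
  bwin <- (on + 20):(on + 170)
  for (i in which(lab == "correlated_burst")) {
    r <- pairwise_correlation(art$voltage[i, , bwin])
    expect_gte(r, 0.5)
  }
})
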