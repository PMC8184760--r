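test_that("pairwise correlation matches hand-computed cases", {
  s <- rnorm(50)
  ident <- rbind(s, s, s)
  expect_equal(pairwise_correlation(ident), 1)

  mixed <- rbind(s, s, -s)  # pairs: (1, -1, -1) / 3
  expect_equal(pairwise_correlation(mixed), -1 / 3)

  withr::with_seed(1, {
    indep <- matrix(rnorm(4 * 1e4), nrow = 4)
    expect_lt(abs(pairwise_correlation(indep)), 0.05)
  })

  flat <- rbind(rep(1, 50), s, 2 * s)
  expect_warning(r <- pairwise_correlation(flat), "zero-variance")
  expect_equal(r, 1)
  expect_error(pairwise_correlation(matrix(1:3, 1)), "nrow")
})

make_screened_set <- function(spec, seed = 11) {
  truth <- generate_ground_truth(efp_design(n_electrodes = 6), seed = 5)
  tr <- generate_object_trials(truth, 25, seed = seed, condition_ids = seq(1, 96, by = 5))
  tr <- inject_artifacts(tr, spec, seed = seed + 1)
  tfp <- small_wp(tr)
  list(trials = tr, report = screen_trials(tr, tfp, screen_params()), tfp = tfp)
}

test_that("injected artifacts are rejected with the correct stage labels", {
  out <- make_screened_set(artifact_spec(clip = 0.02, correlated_burst = 0.03))
  lab <- out$trials$trials$artifact
  rep <- out$report

  clip_rows <- rep[lab == "clipped", ]
  expect_true(all(clip_rows$decision == "reject"))
  expect_true(all(clip_rows$stage == "1"))

  burst_rows <- rep[lab == "correlated_burst", ]
  expect_true(all(burst_rows$decision == "reject"))
  expect_true(all(burst_rows$stage %in% c("2", "3")))
  expect_true(any(burst_rows$stage == "3"))

  # every rejected trial carries exactly one stage label
  expect_true(all(!is.na(rep$stage[rep$decision == "reject"])))
  expect_true(all(is.na(rep$stage[rep$decision == "keep"])))
})

test_that("power outliers are caught by the 4-SD stage", {
  out <- make_screened_set(artifact_spec(power_outlier = 0.03), seed = 21)
  lab <- out$trials$trials$artifact
  rep <- out$report
  outlier <- which(lab == "power_outlier")
  # a lone outlier within its condition is always caught; several extreme
  # trials in the same small condition can mask one another under a +/- SD
  # rule, so overall recall is checked more loosely
  n_in_cond <- table(rep$condition_id[outlier])
  sole <- outlier[n_in_cond[as.character(rep$condition_id[outlier])] == 1]
  expect_true(all(rep$decision[sole] == "reject"))
  expect_true(all(rep$stage[sole] == "2"))
  expect_gte(mean(rep$decision[outlier] == "reject"), 0.6)
})

test_that("clean sets survive screening nearly untouched and stably", {
  out <- make_screened_set(artifact_spec(), seed = 31)
  rep <- out$report
  expect_equal(sum(rep$stage %in% "1"), 0)
  expect_lt(mean(rep$decision == "reject"), 0.05)

  # approximate fixed point: re-screening the kept set rejects <= 1% more
  keep <- which(rep$decision == "keep")
  tr2 <- out$trials
  tr2$voltage <- tr2$voltage[keep, , , drop = FALSE]
  tr2$trials <- tr2$trials[keep, , drop = FALSE]
  tfp2 <- out$tfp
  tfp2$power <- tfp2$power[keep, , , , drop = FALSE]
  tfp2$labels <- tfp2$labels[keep, , drop = FALSE]
  rep2 <- screen_trials(tr2, tfp2, screen_params())
  expect_lte(mean(rep2$decision == "reject"), 0.01)
})

test_that("sparse conditions are skipped with a warning, not an error", {
  truth <- generate_ground_truth(efp_design(n_electrodes = 2), seed = 1)
  tr <- generate_object_trials(truth, 2, seed = 2, condition_ids = 1:4)
  tfp <- small_wp(tr)
  w <- capture_warnings(rep <- screen_trials(tr, tfp, screen_params()))
  expect_true(length(w) > 0 && all(grepl("fewer than 3 trials", w)))
  expect_true(all(rep$decision == "keep"))
})
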