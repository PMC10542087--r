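test_that("Markov state sequences follow the transition structure", {
  # absorbing chain: identity transitions never leave the initial state
  tm_id <- diag(4)
  s <- generate_state_sequence(tm_id, 50, initial_distribution = c(0, 0, 1, 0),
                               seed = 5)
  expect_identical(s, rep(3L, 50))

  # uniform 2-state chain: stationary occupancy one half
  tm_u <- matrix(0.5, 2, 2)
  s <- generate_state_sequence(tm_u, 1e5, seed = 17)
  expect_equal(mean(s == 1), 0.5, tolerance = 0.01 / 0.5)

  # geometric dwell law: mean run length 1/(1 - p_self)
  tm_p <- matrix(c(0.8, 0.2, 0.2, 0.8), 2, 2)
  s <- generate_state_sequence(tm_p, 1e5, seed = 23)
  expect_equal(mean(rle(s)$lengths), 5, tolerance = 0.2 / 5)
})

test_that("state sequence validation and determinism hold", {
  bad <- matrix(c(0.9, 0.2, 0.2, 0.8), 2, 2)
  expect_error(generate_state_sequence(bad, 10, seed = 1), "sum to 1")
  expect_error(generate_state_sequence(matrix(1, 1, 1), 10, seed = 1),
               "K >= 2")
  a <- generate_state_sequence(matrix(0.5, 2, 2), 100, seed = 3)
  b <- generate_state_sequence(matrix(0.5, 2, 2), 100, seed = 3)
  d <- generate_state_sequence(matrix(0.5, 2, 2), 100, seed = 4)
  expect_identical(a, b)
  expect_false(identical(a, d))
})

test_that("block covariances follow the documented module scheme", {
  # no correlation anywhere: identity for every state
  covs0 <- default_block_covariances(12, within_r = 0, between_r = 0,
                                     n_states = 3)
  for (s in covs0) expect_equal(s, diag(12))

  # two modules, state 1: module 1 active at 0.6, module 2 at 0.06
  labs <- rep(c("A", "B"), each = 4)
  covs <- default_block_covariances(8, module_labels = labs, within_r = 0.6,
                                    between_r = 0, n_states = 2)
  want <- matrix(0, 8, 8)
  want[1:4, 1:4] <- 0.6
  want[5:8, 5:8] <- 0.06
  diag(want) <- 1
  expect_equal(covs[[1]], want)
  expect_true(all(eigen(covs[[1]], symmetric = TRUE)$values > 0))

  # PSD invariant over random parameter draws
  withr::with_seed(8, {
    for (i in 1:10) {
      cv <- default_block_covariances(15, within_r = runif(1, 0, 0.9),
                                      between_r = runif(1, 0, 0.3),
                                      n_states = sample(2:5, 1))
      for (s in cv) {
        expect_gte(min(eigen(s, symmetric = TRUE, only.values = TRUE)$values),
                   -1e-10)
        expect_equal(diag(s), rep(1, 15))  # shrinkage preserves the unit diagonal
        expect_equal(s, t(s))
      }
    }
  })
})

test_that("single-state cohorts converge to the planted correlation", {
  covs <- default_block_covariances(10, within_r = 0.5, n_states = 1)
  cfg <- cohort_config(n_patients = 1, n_controls = 1, n_regions = 10,
                       n_volumes = 5000, n_discard = 0, n_states = 1,
                       state_covariances = covs, noise_sd = 0, seed = 31)
  coh <- generate_cohort(cfg)
  r_hat <- stats::cor(coh$timeseries[[1]]$data)
  expect_lt(max(abs(r_hat - covs[[1]])), 0.05)
})

test_that("cohort generation is reproducible and metadata well-formed", {
  coh1 <- make_cohort(n_pat = 3, n_ctl = 3, n_regions = 8, seed = 11)
  coh2 <- make_cohort(n_pat = 3, n_ctl = 3, n_regions = 8, seed = 11)
  coh3 <- make_cohort(n_pat = 3, n_ctl = 3, n_regions = 8, seed = 12)
  expect_identical(coh1$timeseries[[1]]$data, coh2$timeseries[[1]]$data)
  expect_identical(coh1$meta, coh2$meta)
  expect_false(identical(coh1$timeseries[[1]]$data, coh3$timeseries[[1]]$data))

  meta <- coh1$meta
  ctl <- meta$group == "control"
  # clinical scores missing exactly for controls
  for (v in c("duration_months", "joa", "ndi")) {
    expect_true(all(is.na(meta[[v]][ctl])))
    expect_true(all(!is.na(meta[[v]][!ctl])))
  }
  # latent truth: retained length and label range
  lat <- coh1$truth$latent[[1]]
  expect_length(lat, 240 - 10)
  expect_true(all(lat %in% 1:4))
})

test_that("cohort files round-trip through the on-disk layout", {
  coh <- make_cohort(n_pat = 2, n_ctl = 2, n_regions = 6, seed = 21)
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  back <- load_cohort_dir(dir)
  expect_equal(back$meta$subject_id, coh$meta$subject_id)
  expect_equal(back$timeseries[[1]]$data, coh$timeseries[[1]]$data,
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(unlist(back$truth$latent[[1]]), coh$truth$latent[[1]],
               ignore_attr = TRUE)
})
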