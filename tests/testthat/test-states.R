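test_that("k-means separates a planted partition and is deterministic", {
  withr::with_seed(2, {
    z1 <- matrix(rnorm(40 * 10, 0, 0.01), 40, 10)
    z2 <- matrix(rnorm(40 * 10, 10, 0.01), 40, 10)
  })
  wfc <- list(fake_wfc(rbind(z1, z2), "S001", n_regions = 5))
  m <- fit_states(wfc, k = 2, n_restarts = 5, seed = 3)
  truth <- rep(1:2, each = 40)
  expect_equal(ari(m$labels$state, truth), 1)
  # centroids are the member means
  for (s in 1:2) {
    members <- rbind(z1, z2)[m$labels$state == s, ]
    expect_equal(unname(m$centroids[s, ]), unname(colMeans(members)),
                 tolerance = 1e-8)
  }
  # canonical ordering: descending occupancy
  expect_true(all(diff(m$occupancy) <= 0))

  m2 <- fit_states(wfc, k = 2, n_restarts = 5, seed = 3)
  expect_identical(m$labels, m2$labels)
  expect_identical(m$inertia, m2$inertia)
  expect_error(fit_states(wfc, k = 1, seed = 1), ">= 2")
})

test_that("K selection flags featureless inertia curves and inertia decreases", {
  one <- generate_cohort(cohort_config(
    n_patients = 8, n_controls = 8, n_regions = 30, n_states = 1,
    state_covariances = default_block_covariances(30, n_states = 1),
    seed = 71))
  wfc <- window_cohort(one)
  expect_warning(ks <- select_k(wfc, k_range = 2:6, n_restarts = 3, seed = 5),
                 "No elbow")
  expect_true(ks$flag)
  expect_equal(ks$k, 2)
  expect_true(all(diff(ks$curve$inertia) < 0))
})

test_that("temporal metrics match hand enumeration and conserve run lengths", {
  lab <- tibble::tibble(subject_id = "a", window = 1:6,
                        state = c(1L, 1L, 2L, 2L, 2L, 1L))
  tm <- temporal_metrics(lab, k = 2)
  expect_equal(tm$mean_dwell, c(1.5, 3))
  expect_equal(tm$frac_windows, c(0.5, 0.5))
  expect_equal(unique(tm$n_transitions), 2L)

  const <- tibble::tibble(subject_id = "b", window = 1:67, state = 2L)
  tm2 <- temporal_metrics(const, k = 3)
  expect_equal(tm2$mean_dwell, c(0, 67, 0))
  expect_equal(tm2$frac_windows, c(0, 1, 0))
  expect_equal(unique(tm2$n_transitions), 0L)
  expect_false("mean_dwell_s" %in% names(tm2))

  # seconds conversion: one window step = step * TR seconds
  tm3 <- temporal_metrics(const, k = 3, step = 3, tr_seconds = 2)
  expect_equal(tm3$mean_dwell_s, tm3$mean_dwell * 6)

  # run-length conservation: sum_k MDT_k * n_runs_k = W
  withr::with_seed(12, {
    for (i in 1:20) {
      st <- sample(1:4, 50, replace = TRUE)
      tmx <- temporal_metrics(tibble::tibble(subject_id = "s", window = 1:50,
                                             state = st), k = 4)
      runs <- rle(st)
      n_runs <- tabulate(runs$values, 4)
      expect_equal(sum(tmx$mean_dwell * n_runs), 50)
      expect_equal(sum(tmx$frac_windows), 1, tolerance = 1e-12)
      expect_lte(unique(tmx$n_transitions), 49)
    }
  })
})

test_that("truth-channel dwell times follow the geometric law at tick = step", {
  tm <- default_transition_matrices(4, p_self = 0.8, patient_p_self = 0.8)
  coh <- make_cohort(n_pat = 20, n_ctl = 20, n_regions = 8, seed = 81,
                     transition_patient = tm$patient,
                     transition_control = tm$control)
  wins <- enumerate_windows(230, window_spec())
  labs <- dplyr::bind_rows(lapply(names(coh$truth$latent), function(id) {
    tibble::tibble(subject_id = id, window = wins$window,
                   state = latent_window_labels(coh$truth$latent[[id]], wins))
  }))
  tmx <- temporal_metrics(labs, k = 4)
  mdt <- mean(tmx$mean_dwell[tmx$mean_dwell > 0])
  expect_equal(mdt, 5, tolerance = 0.1)
})

test_that("group contrasts reduce to the pooled t-test without covariates", {
  withr::with_seed(33, {
    y <- c(rnorm(10, 1), rnorm(8, 0))
    meta <- tibble::tibble(subject_id = sprintf("S%03d", 1:18),
                           group = rep(c("patient", "control"), c(10, 8)))
    metrics <- tibble::tibble(subject_id = meta$subject_id, state = 1L,
                              mean_dwell = y, frac_windows = 0.5,
                              n_transitions = 3L)
    out <- compare_temporal(metrics, meta, covariates = character(0))
    tt <- stats::t.test(y[1:10], y[11:18], var.equal = TRUE)
    row <- out[out$metric == "mean_dwell", ]
    expect_equal(row$t, unname(tt$statistic), tolerance = 1e-10)
    expect_equal(row$p, tt$p.value, tolerance = 1e-10)
    expect_equal(row$mean_patient_adj - row$mean_control_adj, row$estimate)
  })
})

test_that("state-mean connectivity respects visit structure and averages", {
  z <- rbind(c(0.2, 0, 0), c(0.4, 0, 0), c(1, 1, 1))
  wfc <- list(fake_wfc(z, "S001", n_regions = 3))
  model <- structure(list(
    k = 2, centroids = matrix(0, 2, 3),
    labels = tibble::tibble(subject_id = "S001", window = 1:3,
                            state = c(2L, 2L, 1L)),
    inertia = 0, occupancy = c(2 / 3, 1 / 3), seed = 1L,
    n_regions = 3L, region_labels = sprintf("R%03d", 1:3)),
    class = "dfc_state_model")
  s2 <- state_mean_fc(wfc, model, 2)
  expect_equal(s2$z[1, 1], 0.3)
  expect_true(s2$visited)
  # weighted mean of per-state means equals the grand mean
  s1 <- state_mean_fc(wfc, model, 1)
  grand <- (2 / 3) * s2$z[1, ] + (1 / 3) * s1$z[1, ]
  expect_equal(grand, colMeans(z), tolerance = 1e-10)

  # a subject never visiting a state is flagged, matrix row absent (NA)
  model$labels$state <- c(1L, 1L, 1L)
  model$occupancy <- c(1, 0)
  s2b <- state_mean_fc(wfc, model, 2)
  expect_false(s2b$visited)
  expect_true(all(is.na(s2b$z)))
})

test_that("tidy and glance summarise state models", {
  coh <- make_cohort(n_pat = 2, n_ctl = 2, n_regions = 10, seed = 14)
  wfc <- window_cohort(coh)
  m <- fit_states(wfc, k = 2, n_restarts = 2, seed = 15)
  td <- generics::tidy(m)
  expect_equal(nrow(td), 2 * choose(10, 2))
  expect_named(td, c("state", "region_a", "region_b", "z"))
  gl <- generics::glance(m)
  expect_equal(gl$k, 2)
  expect_equal(gl$n_subjects, 4)
  p <- ggplot2::autoplot(m)
  expect_s3_class(p, "ggplot")
})
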