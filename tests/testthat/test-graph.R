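test_that("sparsity binarization keeps the strongest edges deterministically", {
  withr::with_seed(55, {
    z <- sym_mat <- matrix(0, 5, 5)
    w <- rnorm(10)
    z[upper.tri(z)] <- w
    z <- z + t(z)
    g <- binarize_by_sparsity(z, 0.2)
    expect_equal(g$n_edges, 2)
    kept <- which(g$adjacency[upper.tri(g$adjacency)] == 1)
    absw <- abs(z[upper.tri(z)])
    expect_setequal(rank(-absw)[kept], 1:2)
  })

  # all-equal weights: ties resolved to lexicographically first pairs
  z1 <- matrix(1, 4, 4); diag(z1) <- 0
  g1 <- binarize_by_sparsity(z1, 0.5)          # floor(0.5*6) = 3 edges
  expect_equal(g1$n_edges, 3)
  expect_equal(g1$adjacency[1, 2:4], c(1, 1, 1), ignore_attr = TRUE)

  # near-complete graph at 90 regions
  zbig <- matrix(rnorm(90 * 90), 90, 90)
  zbig <- (zbig + t(zbig)) / 2; diag(zbig) <- 0
  expect_equal(binarize_by_sparsity(zbig, 0.9999)$n_edges, 4004)
  expect_error(binarize_by_sparsity(z1, 0.01), "zero edges")
})

test_that("graph metrics reproduce closed forms on canonical graphs", {
  k5 <- matrix(1, 5, 5); diag(k5) <- 0
  m <- graph_metrics(k5)
  expect_equal(unname(m$degree), rep(4, 5))
  expect_equal(unname(m$clustering), rep(1, 5))
  expect_equal(m$global_efficiency, 1)
  expect_equal(unname(m$betweenness), rep(0, 5))
  expect_equal(unname(m$local_efficiency), rep(1, 5))

  path <- matrix(0, 4, 4)
  path[cbind(1:3, 2:4)] <- 1
  path <- path + t(path)
  mp <- graph_metrics(path)
  expect_equal(unname(mp$betweenness[2]), 2 / 3)
  expect_equal(unname(mp$nodal_efficiency[1]), 11 / 18)
})

test_that("graph metrics match the exhaustive oracle on random graphs", {
  withr::with_seed(56, {
    for (i in 1:25) {
      n <- sample(4:8, 1)
      adj <- random_adjacency(n, runif(1, 0.2, 0.8))
      expect_metrics_equal(graph_metrics(adj), oracle_graph_metrics(adj))
    }
  })
})

test_that("AUC over sparsity is the trapezoid rule and is linear", {
  lad <- sparsity_ladder()
  expect_length(lad$values, 31)
  expect_equal(auc_over_sparsity(rep(1, 31), lad), 0.30)
  ramp <- seq(0, 1, length.out = 31)
  expect_equal(auc_over_sparsity(ramp, lad), 0.15, tolerance = 1e-12)
  withr::with_seed(57, {
    x <- rnorm(31); y <- rnorm(31)
    expect_equal(auc_over_sparsity(2 * x + 3 * y, lad),
                 2 * auc_over_sparsity(x, lad) + 3 * auc_over_sparsity(y, lad),
                 tolerance = 1e-12)
  })
  expect_error(auc_over_sparsity(c(ramp[-1], NA), lad), "Missing")
  expect_error(sparsity_ladder(0.4, 0.1), "s_min")
})

test_that("global efficiency never decreases along the sparsity ladder", {
  withr::with_seed(58, {
    z <- matrix(rnorm(20 * 20), 20, 20)
    z <- (z + t(z)) / 2; diag(z) <- 0
    lad <- sparsity_ladder()
    ge <- vapply(lad$values, function(s) {
      graph_metrics(binarize_by_sparsity(z, s))$global_efficiency
    }, numeric(1))
    expect_true(all(diff(ge) >= -1e-12))
  })
})

test_that("windowed metric AUCs respect the degree bound and variance forms", {
  withr::with_seed(59, {
    x <- matrix(rnorm(60 * 10), 60, 10)
    wfc <- windowed_fc(roi_ts(x), window_spec(20, 10))
    mets <- dyn_graph_metrics(wfc)
    expect_true(all(mets$auc >= 0))
    deg <- mets[mets$metric == "degree", ]
    expect_true(all(deg$auc <= 0.30 * 9 + 1e-12))

    v <- metric_variance(mets)
    expect_true(all(v$n_windows == nrow(wfc$z)))
    # closed forms
    expect_equal(stats::var(c(0.1, 0.3)), 0.02)
    same <- mets |> dplyr::mutate(auc = 1)
    expect_equal(max(metric_variance(same)$variance), 0)
  })
})

test_that("variance contrasts apply BH within nodal metric families", {
  withr::with_seed(60, {
    groups <- rep(c("patient", "control"), each = 8)
    meta <- fake_meta(groups)
    vtab <- tidyr::expand_grid(subject_id = meta$subject_id,
                               metric = c("global_efficiency", "degree"),
                               node = c(NA, sprintf("R%03d", 1:6))) |>
      dplyr::filter((metric == "global_efficiency") == is.na(node)) |>
      dplyr::mutate(variance = rnorm(dplyr::n(), 1, 0.2), n_windows = 10L)
    out <- compare_variance(vtab, meta, covariates = "age")
    deg <- out[out$metric == "degree", ]
    expect_equal(deg$q, oracle_bh(deg$p), tolerance = 1e-12)
    expect_true(is.na(out$q[out$metric == "global_efficiency"]))
  })
})
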