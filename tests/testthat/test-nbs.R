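test_that("edgewise GLM equals the pooled t-test without covariates", {
  withr::with_seed(44, {
    groups <- rep(c("patient", "control"), c(9, 7))
    z <- matrix(rnorm(16 * 10), 16, 10)
    sfc <- fake_state_fc(z, groups)
    meta <- fake_meta(groups)
    es <- edgewise_glm(sfc, meta, covariates = character(0))
    for (e in c(1, 5, 10)) {
      tt <- stats::t.test(z[1:9, e], z[10:16, e], var.equal = TRUE)
      expect_equal(unname(es$t[e]), unname(tt$statistic), tolerance = 1e-10)
      expect_equal(unname(es$p[e]), tt$p.value, tolerance = 1e-10)
    }
    expect_equal(es$df, 14)
    expect_equal(c(es$n_patients, es$n_controls), c(9, 7))
  })
})

test_that("edgewise GLM rejects collinear designs and tiny groups", {
  withr::with_seed(45, {
    groups <- rep(c("patient", "control"), each = 6)
    meta <- fake_meta(groups)
    meta$group_copy <- as.numeric(meta$group == "patient")
    sfc <- fake_state_fc(matrix(rnorm(12 * 3), 12, 3), groups)
    expect_error(edgewise_glm(sfc, meta, covariates = "group_copy"),
                 "collinear")

    visited <- c(TRUE, rep(FALSE, 5), rep(TRUE, 6))  # 1 patient visits
    sfc2 <- fake_state_fc(matrix(rnorm(12 * 3), 12, 3), groups,
                          visited = visited)
    expect_error(edgewise_glm(sfc2, meta, covariates = character(0)),
                 class = "dfc_state_skipped")
  })
})

test_that("a planted edge-block effect dominates the t map", {
  withr::with_seed(46, {
    groups <- rep(c("patient", "control"), each = 15)
    z <- matrix(rnorm(30 * 45), 30, 45)
    target <- 1:6
    z[1:15, target] <- z[1:15, target] + 3
    sfc <- fake_state_fc(z, groups)    # 10 regions -> 45 edges
    es <- edgewise_glm(sfc, fake_meta(groups),
                       covariates = c("age", "sex"))
    expect_setequal(order(abs(es$t), decreasing = TRUE)[1:6], target)
  })
})

test_that("NBS returns empty results on null data and respects monotone thresholds", {
  withr::with_seed(47, {
    groups <- rep(c("patient", "control"), each = 10)
    z <- matrix(rnorm(20 * 45, sd = 0.3), 20, 45)
    sfc <- fake_state_fc(z, groups)
    meta <- fake_meta(groups)
    r <- nbs(sfc, meta, covariates = character(0), edge_p = 1e-6,
             n_perm = 100, seed = 7)
    expect_length(r$components, 0)
    expect_equal(r$null_max_sizes >= 0, rep(TRUE, 100))

    # maximal suprathreshold component size is monotone in the threshold
    sizes <- vapply(c(0.001, 0.01, 0.05, 0.2, 0.5), function(ep) {
      rr <- nbs(sfc, meta, covariates = character(0), edge_p = ep,
                n_perm = 100, seed = 7)
      if (length(rr$component_sizes) == 0) 0L else max(rr$component_sizes)
    }, integer(1))
    expect_true(all(diff(sizes) >= 0))
  })
})

test_that("NBS family-wise p is invariant to group relabelling", {
  withr::with_seed(48, {
    groups <- rep(c("patient", "control"), each = 10)
    z <- matrix(rnorm(20 * 45, sd = 0.5), 20, 45)
    z[1:10, 1:9] <- z[1:10, 1:9] + 1.2
    meta <- fake_meta(groups)
    meta_flip <- meta
    meta_flip$group <- ifelse(meta$group == "patient", "control", "patient")
    r1 <- nbs(fake_state_fc(z, groups), meta, covariates = "age",
              n_perm = 200, seed = 9, edge_p = 0.01)
    r2 <- nbs(fake_state_fc(z, groups), meta_flip, covariates = "age",
              n_perm = 200, seed = 9, edge_p = 0.01)
    expect_equal(r1$component_sizes, r2$component_sizes)
    expect_equal(r1$fwe_p, r2$fwe_p)
    expect_equal(r1$edge_stats$t, -r2$edge_stats$t, tolerance = 1e-10)
  })
})

test_that("network-pair summaries count signed edges conservatively", {
  comps <- list(tibble::tibble(region_a = c("R001", "R001", "R002"),
                               region_b = c("R002", "R003", "R003"),
                               t = c(2.5, 3.1, 4.0)))
  fake_nbs <- structure(list(state = 1L, components = comps,
                             component_sizes = 3L, fwe_p = 0.01,
                             null_max_sizes = integer(0), edge_p = 0.001,
                             n_perm = 1000L, seed = 1L), class = "dfc_nbs")
  map <- tibble::tibble(region = c("R001", "R002", "R003"),
                        network = c("SMN", "SMN", "SMN"))
  s <- summarize_by_network(fake_nbs, map)
  expect_equal(nrow(s), 1)
  expect_equal(c(s$n_patient_gt_control, s$n_patient_lt_control), c(3, 0))

  # sign flip swaps the two counts; totals conserve component size
  fake_nbs$components[[1]]$t <- -fake_nbs$components[[1]]$t
  s2 <- summarize_by_network(fake_nbs, map)
  expect_equal(c(s2$n_patient_gt_control, s2$n_patient_lt_control), c(0, 3))
  expect_equal(sum(s$n_patient_gt_control + s$n_patient_lt_control), 3)

  # unmapped regions are reported, not dropped
  map2 <- map[1:2, ]
  expect_warning(s3 <- summarize_by_network(fake_nbs, map2), "unmapped")
  expect_equal(sum(s3$n_patient_gt_control + s3$n_patient_lt_control), 3)
})
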