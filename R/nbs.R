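# Design-matrix builder shared by the edgewise and nodal GLMs:
# intercept, group indicator (patient = 1), then covariates with
# treatment-coded dummies for character/factor columns.
build_design <- function(meta_rows, covariates) {
  g <- as.numeric(meta_rows$group == "patient")
  x <- cbind(`(Intercept)` = 1, group = g)
  for (cv in covariates) {
    v <- meta_rows[[cv]]
    if (is.character(v) || is.factor(v)) {
      lev <- levels(factor(v))
      for (l in lev[-1]) {
        x <- cbind(x, as.numeric(v == l))
        colnames(x)[ncol(x)] <- paste0(cv, l)
      }
    } else {
      x <- cbind(x, as.numeric(v))
      colnames(x)[ncol(x)] <- cv
    }
  }
  x
}

# Mass-univariate least squares of every column of Y on x; t and two-sided
# p for the group coefficient (column 2 of x).
fast_group_glm <- function(Y, x) {
  qr_x <- qr(x)
  if (qr_x$rank < ncol(x)) {
    dropped <- colnames(x)[qr_x$pivot[(qr_x$rank + 1):ncol(x)]]
    abort(sprintf("Rank-deficient design; collinear columns: %s",
                  paste(dropped, collapse = ", ")))
  }
  coef <- qr.coef(qr_x, Y)
  res <- Y - x %*% coef
  df <- nrow(x) - ncol(x)
  if (df < 1) abort("Not enough subjects for the requested design.")
  sigma2 <- colSums(res^2) / df
  v22 <- solve(crossprod(x))[2, 2]
  tval <- coef[2, ] / sqrt(sigma2 * v22)
  list(t = tval, p = 2 * stats::pt(-abs(tval), df), df = df,
       estimate = coef[2, ])
}

#' Edgewise covariate-adjusted group contrast of state connectivity
#'
#' Per off-diagonal edge, fits `z ~ group + covariates` over the subjects
#' that visit the state and reports the group coefficient's t (patient
#' minus control) with two-sided Student p.  Subjects that never visit the
#' state are excluded, with per-group visitor counts reported.
#'
#' @param state_fc A [state_mean_fc()] result.
#' @param meta Subject metadata tibble (`subject_id`, `group`, covariates).
#' @param covariates Covariate column names.
#' @return Object of class `dfc_edge_stats`: `state`, `t`, `p` (length-E
#'   vectors), `df`, `n_patients`, `n_controls`, region metadata.
#' @export
edgewise_glm <- function(state_fc, meta,
                         covariates = c("age", "sex", "education_years")) {
  stopifnot(inherits(state_fc, "dfc_state_fc"))
  keep <- state_fc$visited
  m <- meta[match(state_fc$subject_id[keep], meta$subject_id), , drop = FALSE]
  n_pat <- sum(m$group == "patient")
  n_ctl <- sum(m$group == "control")
  if (n_pat < 2 || n_ctl < 2) {
    abort(sprintf(
      "State %d skipped: fewer than 2 visiting subjects in a group (patients %d, controls %d).",
      state_fc$state, n_pat, n_ctl), class = "dfc_state_skipped")
  }
  x <- build_design(m, covariates)
  fit <- fast_group_glm(state_fc$z[keep, , drop = FALSE], x)
  structure(list(state = state_fc$state, t = fit$t, p = fit$p,
                 estimate = fit$estimate, df = fit$df,
                 n_patients = n_pat, n_controls = n_ctl,
                 covariates = covariates,
                 n_regions = state_fc$n_regions,
                 region_labels = state_fc$region_labels),
            class = "dfc_edge_stats")
}

#' @export
print.dfc_edge_stats <- function(x, ...) {
  cat(sprintf("<dfc_edge_stats> state %d: %d edges, df = %d (%d patients, %d controls)\n",
              x$state, length(x$t), x$df, x$n_patients, x$n_controls))
  invisible(x)
}

#' Materialise edge t or p values as an N x N matrix
#' @param stats A `dfc_edge_stats`.
#' @param what `"t"` or `"p"`.
#' @export
edge_stat_matrix <- function(stats, what = c("t", "p")) {
  what <- match.arg(what)
  sym_from_vec(stats[[what]], stats$n_regions, stats$region_labels)
}

# Size (edge count) of the largest connected component of a suprathreshold
# edge set, plus per-edge component membership.
supra_components <- function(edges_ij, n_regions) {
  if (nrow(edges_ij) == 0) {
    return(list(max_size = 0L, membership = integer(0), sizes = integer(0)))
  }
  g <- igraph::make_empty_graph(n = n_regions, directed = FALSE)
  g <- igraph::add_edges(g, t(edges_ij))
  comp <- igraph::components(g)$membership
  edge_comp <- comp[edges_ij[, 1L]]
  sizes <- as.integer(table(edge_comp))
  names(sizes) <- names(table(edge_comp))
  list(max_size = max(sizes), membership = edge_comp, sizes = sizes)
}

#' Network-based statistic (NBS)
#'
#' Family-wise-corrected test for connected components of suprathreshold
#' edges.  Edges with two-sided p below `edge_p` are retained; connected
#' components of the suprathreshold graph are measured by edge count; the
#' null distribution of the maximal component size is built by permutation
#' with identical thresholding.  With covariates the Freedman-Lane scheme
#' is used: residuals of the reduced (covariates-only) model are permuted
#' and added back to its fitted values before refitting the full model.
#' Component family-wise p is `(1 + #\{perm max >= size\}) / (n_perm + 1)`,
#' so p = 0 is impossible.
#'
#' @param state_fc A [state_mean_fc()] result.
#' @param meta Subject metadata tibble.
#' @param covariates Covariate column names (may be `character(0)`).
#' @param edge_p Edgewise two-sided p threshold (default 0.001).
#' @param n_perm Number of permutations (default 1000, minimum 100).
#' @param seed Integer seed.
#' @return Object of class `dfc_nbs`: `state`, `components` (list of
#'   tibbles with `region_a`, `region_b`, `t`), `component_sizes`,
#'   `fwe_p`, `null_max_sizes`, `edge_stats`, parameters.
#' @export
nbs <- function(state_fc, meta, covariates = c("age", "sex", "education_years"),
                edge_p = 0.001, n_perm = 1000L, seed) {
  if (missing(seed)) abort("`seed` is mandatory.")
  n_perm <- check_scalar_count(n_perm, "n_perm", min = 100L)
  obs <- edgewise_glm(state_fc, meta, covariates)
  idx <- edge_index(obs$n_regions)

  keep <- state_fc$visited
  m <- meta[match(state_fc$subject_id[keep], meta$subject_id), , drop = FALSE]
  x <- build_design(m, covariates)
  y <- state_fc$z[keep, , drop = FALSE]

  supra <- which(obs$p < edge_p)
  comp <- supra_components(idx[supra, , drop = FALSE], obs$n_regions)

  # Freedman-Lane: permute reduced-model residuals
  x0 <- x[, -2L, drop = FALSE]
  qr0 <- qr(x0)
  fitted0 <- x0 %*% qr.coef(qr0, y)
  res0 <- y - fitted0
  n <- nrow(y)
  null_max <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(n_perm), function(b) {
      perm <- sample.int(n)
      fit <- fast_group_glm(fitted0 + res0[perm, , drop = FALSE], x)
      s <- which(fit$p < edge_p)
      supra_components(idx[s, , drop = FALSE], obs$n_regions)$max_size
    }, integer(1))
  })

  comps <- list()
  sizes <- integer(0)
  fwe <- numeric(0)
  if (comp$max_size > 0) {
    for (cid in unique(comp$membership)) {
      sel <- supra[comp$membership == cid]
      sz <- length(sel)
      comps[[length(comps) + 1L]] <- tibble(
        region_a = obs$region_labels[idx[sel, 1L]],
        region_b = obs$region_labels[idx[sel, 2L]],
        t = obs$t[sel])
      sizes <- c(sizes, sz)
      fwe <- c(fwe, (1 + sum(null_max >= sz)) / (n_perm + 1))
    }
    ord <- order(sizes, decreasing = TRUE)
    comps <- comps[ord]; sizes <- sizes[ord]; fwe <- fwe[ord]
  }

  structure(list(state = state_fc$state, components = comps,
                 component_sizes = sizes, fwe_p = fwe,
                 null_max_sizes = null_max, edge_stats = obs,
                 edge_p = edge_p, n_perm = n_perm, seed = as.integer(seed)),
            class = "dfc_nbs")
}

#' @export
print.dfc_nbs <- function(x, ...) {
  cat(sprintf("<dfc_nbs> state %d: %d suprathreshold component(s) at edge p < %g\n",
              x$state, length(x$components), x$edge_p))
  if (length(x$components) > 0) {
    for (i in seq_along(x$components)) {
      cat(sprintf("  component %d: %d edges, FWE p = %.4g\n",
                  i, x$component_sizes[i], x$fwe_p[i]))
    }
  }
  invisible(x)
}

#' Summarise NBS components by network pair
#'
#' Counts suprathreshold edges in each (unordered) network pair, split by
#' the sign of the group effect (positive = patient > control).  Regions
#' absent from the map are counted under `"unmapped"` with a warning.
#'
#' @param nbs_result A [nbs()] result with at least one component.
#' @param network_map Tibble with columns `region`, `network`.
#' @param fwe_alpha Only components with `fwe_p` below this enter the
#'   summary (default 1, i.e. all).
#' @return Tibble: `network_a`, `network_b`, `n_patient_gt_control`,
#'   `n_patient_lt_control`.
#' @export
summarize_by_network <- function(nbs_result, network_map, fwe_alpha = 1) {
  stopifnot(inherits(nbs_result, "dfc_nbs"))
  keep <- which(nbs_result$fwe_p < fwe_alpha)
  if (length(nbs_result$components) == 0 || length(keep) == 0) {
    abort("No components to summarise.")
  }
  edges <- bind_rows(nbs_result$components[keep])
  net <- function(r) {
    out <- network_map$network[match(r, network_map$region)]
    if (anyNA(out)) {
      warn(sprintf("%d regions missing from the network map; counted as 'unmapped'.",
                   sum(is.na(out))))
      out[is.na(out)] <- "unmapped"
    }
    out
  }
  na <- net(edges$region_a)
  nb <- net(edges$region_b)
  lo <- pmin(na, nb)
  hi <- pmax(na, nb)
  tibble(network_a = lo, network_b = hi, t = edges$t) |>
    group_by(.data$network_a, .data$network_b) |>
    summarise(n_patient_gt_control = sum(.data$t > 0),
              n_patient_lt_control = sum(.data$t < 0), .groups = "drop")
}
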