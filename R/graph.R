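#' Sparsity ladder
#'
#' @param s_min,s_max,s_step Sparsity range and increment; defaults
#'   0.10-0.40 in steps of 0.01 (31 rungs).
#' @return Object of class `sparsity_ladder` with a `values` vector.
#' @export
sparsity_ladder <- function(s_min = 0.10, s_max = 0.40, s_step = 0.01) {
  if (!(s_min > 0 && s_min < s_max && s_max < 1 && s_step > 0)) {
    abort("Need 0 < s_min < s_max < 1 and s_step > 0.")
  }
  n <- round((s_max - s_min) / s_step)
  structure(list(s_min = s_min, s_max = s_max, s_step = s_step,
                 values = s_min + s_step * (0:n)),
            class = "sparsity_ladder")
}

#' Binarize a connectivity matrix at a target sparsity
#'
#' Ranks the strict upper-triangle entries by weight descending and keeps
#' the top `floor(s N(N-1)/2)` as unweighted, undirected edges.  Ties at
#' the cut are broken by (row, col) lexicographic order, so the result is
#' deterministic.  `rank = "abs"` (default) ranks by `|z|` so strong
#' negative coupling also counts; `rank = "positive"` ranks by signed z and
#' admits only positive entries.
#'
#' @param z Symmetric N x N matrix with zero diagonal (Fisher-Z weights).
#' @param s Target sparsity in (0, 1).
#' @param rank Edge ranking mode: `"abs"` or `"positive"`.
#' @return List of class `binary_graph`: `adjacency` (0/1 symmetric),
#'   `sparsity` (achieved edge fraction), `n_edges`.
#' @export
binarize_by_sparsity <- function(z, s, rank = c("abs", "positive")) {
  rank <- match.arg(rank)
  n <- nrow(z)
  if (max(abs(z - t(z))) > 1e-10) abort("Input matrix must be symmetric.")
  idx <- edge_index(n)
  w <- z[idx]
  e_total <- nrow(idx)
  m <- floor(s * e_total)
  if (m < 1) abort("Sparsity yields zero edges.")
  key <- if (rank == "abs") abs(w) else w
  ord <- order(-key, idx[, 1L], idx[, 2L])
  keep <- ord[seq_len(min(m, e_total))]
  if (rank == "positive") keep <- keep[w[keep] > 0]
  adj <- matrix(0L, n, n)
  adj[idx[keep, , drop = FALSE]] <- 1L
  adj[idx[keep, c(2L, 1L), drop = FALSE]] <- 1L
  dimnames(adj) <- dimnames(z)
  structure(list(adjacency = adj, sparsity = length(keep) / e_total,
                 n_edges = length(keep)),
            class = "binary_graph")
}

#' Graph-theoretic metrics of a binary graph
#'
#' Degree; nodal efficiency (harmonic mean of inverse shortest-path
#' lengths, unreachable pairs contributing 0); global efficiency (mean
#' nodal efficiency); clustering coefficient (`2 t_i / (k_i (k_i - 1))`, 0
#' when degree < 2); local efficiency (global efficiency of the subgraph
#' induced on each node's neighbours, 0 with < 2 neighbours); betweenness
#' centrality (shortest-path counting with multiplicity, normalised by
#' `(N-1)(N-2)/2`).
#'
#' @param g A [binarize_by_sparsity()] result or a 0/1 adjacency matrix.
#' @return List: `global_efficiency` (scalar) and per-node vectors
#'   `degree`, `nodal_efficiency`, `betweenness`, `clustering`,
#'   `local_efficiency`.
#' @export
graph_metrics <- function(g) {
  adj <- if (inherits(g, "binary_graph")) g$adjacency else g
  n <- nrow(adj)
  ig <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  d <- igraph::distances(ig)
  inv <- 1 / d
  diag(inv) <- 0
  nodal_eff <- rowSums(inv) / (n - 1)
  degree <- rowSums(adj)
  btw <- igraph::betweenness(ig, directed = FALSE, normalized = TRUE)
  cc <- igraph::transitivity(ig, type = "local", isolates = "zero")
  loc <- vapply(seq_len(n), function(i) {
    nb <- which(adj[i, ] == 1)
    if (length(nb) < 2) return(0)
    sub <- adj[nb, nb, drop = FALSE]
    ds <- igraph::distances(igraph::graph_from_adjacency_matrix(sub, mode = "undirected"))
    invs <- 1 / ds
    diag(invs) <- 0
    sum(invs) / (length(nb) * (length(nb) - 1))
  }, numeric(1))
  nm <- rownames(adj)
  named <- function(v) stats::setNames(as.numeric(v), nm)
  list(global_efficiency = mean(nodal_eff),
       degree = named(degree),
       nodal_efficiency = named(nodal_eff),
       betweenness = named(as.numeric(btw)),
       clustering = named(as.numeric(cc)),
       local_efficiency = named(loc))
}

#' Trapezoidal AUC of a metric over the sparsity ladder
#'
#' @param values One metric value per ladder rung (no missing values).
#' @param ladder A [sparsity_ladder()].
#' @return Scalar trapezoidal integral over sparsity.
#' @export
auc_over_sparsity <- function(values, ladder = sparsity_ladder()) {
  if (length(values) != length(ladder$values)) {
    abort("Need exactly one value per ladder rung.")
  }
  if (anyNA(values)) abort("Missing rung value.")
  pracma::trapz(ladder$values, values)
}

#' Per-window sparsity-integrated graph metrics
#'
#' For every sliding window: binarize the Fisher-Z matrix at each rung of
#' the sparsity ladder, compute all graph metrics, and integrate each
#' metric over sparsity by trapezoidal AUC.
#'
#' @param wfc A [windowed_fc()].
#' @param ladder A [sparsity_ladder()].
#' @param rank Edge ranking mode, see [binarize_by_sparsity()].
#' @param windows Optional window indices to restrict to (compute budget).
#' @param nodes Optional region-label subset for nodal metrics.
#' @return Long tibble: `subject_id`, `window`, `metric`, `node` (`NA` for
#'   the global metric), `auc`.
#' @export
dyn_graph_metrics <- function(wfc, ladder = sparsity_ladder(),
                              rank = c("abs", "positive"),
                              windows = NULL, nodes = NULL) {
  stopifnot(inherits(wfc, "windowed_fc"))
  rank <- match.arg(rank)
  wsel <- windows %||% seq_len(nrow(wfc$z))
  nodal_names <- c("degree", "nodal_efficiency", "betweenness",
                   "clustering", "local_efficiency")
  node_keep <- nodes %||% wfc$region_labels
  out <- vector("list", length(wsel))
  for (wi in seq_along(wsel)) {
    z <- fc_matrix(wfc, wsel[wi])
    per_rung <- lapply(ladder$values, function(s) {
      graph_metrics(binarize_by_sparsity(z, s, rank = rank))
    })
    glob <- auc_over_sparsity(vapply(per_rung, `[[`, numeric(1),
                                     "global_efficiency"), ladder)
    rows <- list(tibble(metric = "global_efficiency", node = NA_character_,
                        auc = glob))
    for (mn in nodal_names) {
      vals <- vapply(per_rung, `[[`, numeric(wfc$n_regions), mn)
      keep <- match(node_keep, wfc$region_labels)
      aucs <- apply(vals[keep, , drop = FALSE], 1L, auc_over_sparsity,
                    ladder = ladder)
      rows[[length(rows) + 1L]] <- tibble(metric = mn, node = node_keep,
                                          auc = aucs)
    }
    out[[wi]] <- bind_rows(rows) |>
      mutate(window = wsel[wi], .before = 1L)
  }
  bind_rows(out) |>
    mutate(subject_id = wfc$subject_id, .before = 1L)
}

#' Across-window variance of sparsity-integrated metrics
#'
#' Sample variance (denominator W - 1) of each metric's per-window AUC
#' across a subject's windows.
#'
#' @param metrics Long tibble from [dyn_graph_metrics()] (one or more
#'   subjects).
#' @return Tibble: `subject_id`, `metric`, `node`, `variance`, `n_windows`.
#' @export
metric_variance <- function(metrics) {
  out <- metrics |>
    group_by(.data$subject_id, .data$metric, .data$node) |>
    summarise(variance = stats::var(.data$auc),
              n_windows = dplyr::n(), .groups = "drop")
  if (any(out$n_windows < 2)) abort("Variance needs at least 2 windows.")
  out
}

#' Group contrast of metric variances with BH correction
#'
#' Covariate-adjusted linear model `variance ~ group + covariates` per
#' metric and node; Benjamini-Hochberg q-values across nodes within each
#' nodal-metric family.  Global metrics are tested without an FDR family
#' (`q = NA`).
#'
#' @param variances Output of [metric_variance()] for all subjects.
#' @param meta Subject metadata tibble.
#' @param covariates Covariate column names.
#' @param fdr_q Discovery threshold applied to q (default 0.05).
#' @return Tibble: `metric`, `node`, `estimate`, `t`, `p`, `q`,
#'   `significant`.
#' @export
compare_variance <- function(variances, meta,
                             covariates = c("age", "sex", "education_years"),
                             fdr_q = 0.05) {
  res <- variances |>
    group_by(.data$metric, .data$node) |>
    group_modify(function(df, key) {
      glm_group_contrast(df$variance, df$subject_id, meta, covariates) |>
        select("estimate", "t", "p")
    }) |>
    ungroup() |>
    group_by(.data$metric) |>
    mutate(q = if (all(is.na(.data$node))) NA_real_
               else stats::p.adjust(.data$p, method = "BH")) |>
    ungroup() |>
    mutate(significant = !is.na(.data$q) & .data$q < fdr_q)
  res
}
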