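#' Cluster windowed connectivity into recurring states
#'
#' K-means on the pooled upper-triangle Fisher-Z vectors of all subjects'
#' windows: squared-Euclidean distance, k-means++ initialisation, Lloyd
#' iterations, best of `n_restarts` by within-cluster sum of squares
#' (inertia).  An empty cluster is re-seeded at the point farthest from its
#' assigned centroid.  States are renumbered by descending pooled occupancy
#' so "state 2" is stable across runs.
#'
#' @param wfc_list List of [windowed_fc()] objects (one per subject).
#' @param k Number of states (>= 2).
#' @param n_restarts Independent k-means++ restarts (default 50).
#' @param seed Integer seed; the fit is deterministic given it.
#' @param iter_max Maximum Lloyd iterations per restart.
#' @return Object of class `dfc_state_model`: `k`, `centroids` (k x E),
#'   `labels` (tibble subject_id, window, state), `inertia`, `occupancy`,
#'   `seed`, `n_regions`, `region_labels`.
#' @export
fit_states <- function(wfc_list, k, n_restarts = 50L, seed, iter_max = 100L) {
  k <- check_scalar_count(k, "k", min = 2L)
  n_restarts <- check_scalar_count(n_restarts, "n_restarts")
  if (missing(seed)) abort("`seed` is mandatory.")
  x <- do.call(rbind, lapply(wfc_list, function(w) w$z))
  if (nrow(x) < k) abort("Pooled window count must be at least k.")
  subj <- rep(vapply(wfc_list, function(w) w$subject_id, character(1)),
              vapply(wfc_list, function(w) nrow(w$z), integer(1)))
  win <- unlist(lapply(wfc_list, function(w) w$windows$window), use.names = FALSE)

  best <- withr::with_seed(as.integer(seed), {
    out <- NULL
    for (r in seq_len(n_restarts)) {
      fit <- lloyd_kmeans(x, k, iter_max)
      if (is.null(out) || fit$inertia < out$inertia) out <- fit
    }
    out
  })

  # canonical ordering: descending occupancy, inertia-invariant relabelling
  ord <- order(tabulate(best$cluster, k), decreasing = TRUE)
  relabel <- match(seq_len(k), ord)
  cluster <- relabel[best$cluster]
  centroids <- best$centers[ord, , drop = FALSE]

  structure(list(
    k = k,
    centroids = centroids,
    labels = tibble(subject_id = subj, window = win, state = cluster),
    inertia = best$inertia,
    occupancy = as.numeric(tabulate(cluster, k)) / length(cluster),
    seed = as.integer(seed),
    n_regions = wfc_list[[1]]$n_regions,
    region_labels = wfc_list[[1]]$region_labels
  ), class = "dfc_state_model")
}

# k-means++ seeding followed by Lloyd iterations; empty clusters re-seeded
# at the farthest point from its current centroid.
lloyd_kmeans <- function(x, k, iter_max) {
  n <- nrow(x)
  xsq <- rowSums(x^2)
  centers <- matrix(0, k, ncol(x))
  centers[1L, ] <- x[sample.int(n, 1L), ]
  d2 <- pmax(xsq - 2 * drop(x %*% centers[1L, ]) + sum(centers[1L, ]^2), 0)
  for (c in seq_len(k - 1L) + 0L) {
    if (c >= 2L) {
      dc <- pmax(xsq - 2 * drop(x %*% centers[c, ]) + sum(centers[c, ]^2), 0)
      d2 <- pmin(d2, dc)
    }
    if (c < k) {
      p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
      centers[c + 1L, ] <- x[sample.int(n, 1L, prob = p), ]
    }
  }
  cluster <- integer(n)
  for (it in seq_len(iter_max)) {
    d <- outer(xsq, rowSums(centers^2), "+") - 2 * (x %*% t(centers))
    new_cluster <- max.col(-d, ties.method = "first")
    sizes <- tabulate(new_cluster, k)
    if (any(sizes == 0L)) {
      for (empty in which(sizes == 0L)) {
        far <- which.max(d[cbind(seq_len(n), new_cluster)])
        new_cluster[far] <- empty
        inform(sprintf("Empty cluster %d re-seeded at farthest point.", empty))
        sizes <- tabulate(new_cluster, k)
      }
    }
    if (it > 1L && all(new_cluster == cluster)) break
    cluster <- new_cluster
    for (c in seq_len(k)) {
      centers[c, ] <- colMeans(x[cluster == c, , drop = FALSE])
    }
  }
  d <- outer(xsq, rowSums(centers^2), "+") - 2 * (x %*% t(centers))
  inertia <- sum(pmax(d[cbind(seq_len(n), cluster)], 0))
  list(cluster = cluster, centers = centers, inertia = inertia)
}

#' @export
print.dfc_state_model <- function(x, ...) {
  cat(sprintf("<dfc_state_model> k = %d, %d windows, inertia = %.4g\n",
              x$k, nrow(x$labels), x$inertia))
  cat("occupancy:", paste(sprintf("%.1f%%", 100 * x$occupancy), collapse = " "), "\n")
  invisible(x)
}

#' Materialise one state's centroid as an N x N matrix
#' @param model A `dfc_state_model`.
#' @param state State index.
#' @export
centroid_matrix <- function(model, state) {
  sym_from_vec(model$centroids[state, ], model$n_regions, model$region_labels)
}

#' Choose the number of connectivity states
#'
#' Fits [fit_states()] over `k_range` and selects K.  The default criterion
#' is the elbow of the inertia curve, located by the chord rule: the K
#' whose inertia lies farthest below the straight line joining the curve's
#' endpoints.  This is invariant to the additive estimation-noise floor
#' that dominates windowed-connectivity inertia and would swamp a
#' curvature-of-log-inertia rule.  The elbow depth (chord distance divided
#' by the total inertia drop over the range) is reported per K; if the
#' maximum depth is below `elbow_tol` the curve is considered featureless:
#' the smallest K is returned with `flag = TRUE` and a warning.
#' `criterion = "silhouette"` instead picks the K with the highest mean
#' silhouette width (computed on a subsample of at most `silhouette_max`
#' windows for tractability).
#'
#' @param wfc_list List of [windowed_fc()] objects.
#' @param k_range Candidate K values (default 2:8).
#' @param criterion `"elbow"` (default) or `"silhouette"`.
#' @param n_restarts,seed,iter_max Passed to [fit_states()].
#' @param elbow_tol Minimum relative elbow depth counting as an elbow
#'   (default 0.2).
#' @param silhouette_max Subsample cap for the silhouette criterion.
#' @return Object of class `dfc_kselect`: `k`, `curve` (tibble k, inertia,
#'   criterion_value), `criterion`, `flag`, and `models` (fitted models).
#' @export
select_k <- function(wfc_list, k_range = 2:8,
                     criterion = c("elbow", "silhouette"),
                     n_restarts = 10L, seed, iter_max = 100L,
                     elbow_tol = 0.2, silhouette_max = 2000L) {
  criterion <- match.arg(criterion)
  if (missing(seed)) abort("`seed` is mandatory.")
  k_range <- sort(unique(as.integer(k_range)))
  if (any(k_range < 2)) abort("K candidates must be >= 2.")
  models <- lapply(k_range, function(k) {
    fit_states(wfc_list, k, n_restarts = n_restarts,
               seed = derive_seed(seed, paste0("k", k)), iter_max = iter_max)
  })
  inertia <- vapply(models, function(m) m$inertia, numeric(1))
  flag <- FALSE

  if (criterion == "elbow") {
    crit <- rep(NA_real_, length(k_range))
    total_drop <- inertia[1L] - inertia[length(inertia)]
    if (length(k_range) >= 3 && total_drop > 0) {
      tfrac <- (k_range - k_range[1L]) / (k_range[length(k_range)] - k_range[1L])
      chord <- inertia[1L] + tfrac * (inertia[length(inertia)] - inertia[1L])
      crit <- (chord - inertia) / total_drop
    }
    if (all(is.na(crit)) || max(crit, na.rm = TRUE) < elbow_tol) {
      flag <- TRUE
      warn("No elbow above tolerance in the inertia curve; returning smallest K.")
      k_star <- k_range[1L]
    } else {
      k_star <- k_range[which.max(crit)]
    }
  } else {
    x <- do.call(rbind, lapply(wfc_list, function(w) w$z))
    keep <- withr::with_seed(derive_seed(seed, "silhouette"), {
      if (nrow(x) > silhouette_max) sample.int(nrow(x), silhouette_max) else seq_len(nrow(x))
    })
    dx <- stats::dist(x[keep, , drop = FALSE])
    crit <- vapply(seq_along(k_range), function(i) {
      cl <- models[[i]]$labels$state[keep]
      if (length(unique(cl)) < 2) return(NA_real_)
      mean(cluster::silhouette(cl, dx)[, "sil_width"])
    }, numeric(1))
    if (all(is.na(crit))) {
      flag <- TRUE
      warn("Silhouette undefined for all K; returning smallest K.")
      k_star <- k_range[1L]
    } else {
      k_star <- k_range[which.max(crit)]
    }
  }

  structure(list(
    k = k_star,
    curve = tibble(k = k_range, inertia = inertia, criterion_value = crit),
    criterion = criterion, flag = flag, models = models
  ), class = "dfc_kselect")
}

#' @export
print.dfc_kselect <- function(x, ...) {
  cat(sprintf("<dfc_kselect> chosen K = %d (%s%s)\n", x$k, x$criterion,
              if (x$flag) ", flat-curve flag" else ""))
  invisible(x)
}

#' @rdname select_k
#' @param object A `dfc_kselect`.
#' @param ... Unused.
#' @export
autoplot.dfc_kselect <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(.data$k, .data$inertia)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$k, linetype = 2, colour = "red") +
    ggplot2::labs(x = "K", y = "Within-cluster sum of squares",
                  title = sprintf("K selection (%s): K = %d",
                                  object$criterion, object$k)) +
    ggplot2::theme_minimal()
}

#' Per-subject temporal state statistics
#'
#' Mean dwell time (mean length of maximal runs, in windows; 0 for states a
#' subject never visits), fractional windows (occupancy share) and the
#' number of transitions between consecutive windows.
#'
#' @param labels A `dfc_state_model`, or a tibble with columns
#'   `subject_id`, `window`, `state`.
#' @param k Number of states (taken from the model when given).
#' @param step,tr_seconds Optional window step (volumes) and TR; when both
#'   are supplied a `mean_dwell_s` column (seconds) is added.
#' @return Tibble: `subject_id`, `state`, `mean_dwell`, `frac_windows`,
#'   `n_transitions` (repeated within subject).
#' @export
temporal_metrics <- function(labels, k = NULL, step = NULL, tr_seconds = NULL) {
  if (inherits(labels, "dfc_state_model")) {
    k <- labels$k
    labels <- labels$labels
  }
  if (is.null(k)) abort("`k` is required when `labels` is a tibble.")
  if (nrow(labels) == 0) abort("Empty state sequence.")
  if (any(!labels$state %in% seq_len(k))) abort("States must lie in 1..k.")
  out <- labels |>
    arrange(.data$subject_id, .data$window) |>
    group_by(.data$subject_id) |>
    group_modify(function(df, key) {
      r <- rle(df$state)
      dwell <- vapply(seq_len(k), function(s) {
        runs <- r$lengths[r$values == s]
        if (length(runs) == 0) 0 else mean(runs)
      }, numeric(1))
      frac <- tabulate(df$state, k) / nrow(df)
      tibble(state = seq_len(k), mean_dwell = dwell, frac_windows = frac,
             n_transitions = sum(diff(df$state) != 0))
    }) |>
    ungroup()
  if (!is.null(step) && !is.null(tr_seconds)) {
    out$mean_dwell_s <- out$mean_dwell * step * tr_seconds
  }
  out
}

#' Covariate-adjusted group contrast of temporal metrics
#'
#' Fits `metric ~ group + covariates` by least squares for each temporal
#' metric (per-state mean dwell time and fractional windows, plus the
#' transition count) and reports the group coefficient's t and two-sided p.
#' With no covariates this is exactly the pooled-variance two-sample
#' t-test.  Adjusted group means are evaluated at the covariate means.
#'
#' @param metrics Output of [temporal_metrics()].
#' @param meta Subject metadata tibble with `subject_id`, `group` and the
#'   covariate columns.
#' @param covariates Character vector of covariate column names (default
#'   age, sex, education).
#' @return Tibble: `metric`, `state`, `estimate` (patient - control,
#'   adjusted), `t`, `p`, `df`, `mean_patient_adj`, `mean_control_adj`.
#' @export
compare_temporal <- function(metrics, meta,
                             covariates = c("age", "sex", "education_years")) {
  wide <- metrics |>
    tidyr::pivot_longer(c("mean_dwell", "frac_windows"),
                        names_to = "metric", values_to = "value") |>
    select("subject_id", "metric", "state", "value")
  trans <- metrics |>
    distinct(.data$subject_id, .data$n_transitions) |>
    mutate(metric = "n_transitions", state = NA_integer_,
           value = as.numeric(.data$n_transitions)) |>
    select("subject_id", "metric", "state", "value")
  long <- bind_rows(wide, trans)

  long |>
    group_by(.data$metric, .data$state) |>
    group_modify(function(df, key) {
      glm_group_contrast(df$value, df$subject_id, meta, covariates)
    }) |>
    ungroup() |>
    arrange(.data$metric, .data$state)
}

# Shared single-response covariate-adjusted group contrast.
glm_group_contrast <- function(y, subject_id, meta, covariates) {
  m <- meta[match(subject_id, meta$subject_id), , drop = FALSE]
  if (any(table(m$group) < 2)) abort("Need at least 2 subjects per group.")
  g <- as.numeric(m$group == "patient")
  x <- cbind(`(Intercept)` = 1, group = g)
  for (cv in covariates) {
    v <- m[[cv]]
    if (is.character(v) || is.factor(v)) {
      lev <- levels(factor(v))
      for (l in lev[-1]) x <- cbind(x, as.numeric(v == l))
      colnames(x)[(ncol(x) - length(lev) + 2):ncol(x)] <- paste0(cv, lev[-1])
    } else {
      x <- cbind(x, v)
      colnames(x)[ncol(x)] <- cv
    }
  }
  qr_x <- qr(x)
  if (qr_x$rank < ncol(x)) {
    dropped <- colnames(x)[qr_x$pivot[(qr_x$rank + 1):ncol(x)]]
    abort(sprintf("Rank-deficient design; collinear columns: %s",
                  paste(dropped, collapse = ", ")))
  }
  fit <- stats::lm.fit(x, y)
  df <- length(y) - ncol(x)
  sigma2 <- sum(fit$residuals^2) / df
  xtx_inv <- solve(crossprod(x))
  se <- sqrt(sigma2 * xtx_inv[2, 2])
  tval <- fit$coefficients["group"] / se
  pval <- 2 * stats::pt(-abs(tval), df)
  # adjusted means: evaluate at covariate means
  xbar <- colMeans(x)
  base <- sum(fit$coefficients * xbar) - fit$coefficients["group"] * xbar["group"]
  tibble(estimate = unname(fit$coefficients["group"]),
         t = unname(tval), p = unname(pval), df = df,
         mean_patient_adj = unname(base + fit$coefficients["group"]),
         mean_control_adj = unname(base))
}

#' Per-subject mean connectivity within one state
#'
#' @param wfc_list List of [windowed_fc()] objects.
#' @param model A `dfc_state_model` fitted on those subjects.
#' @param state State index.
#' @return Object of class `dfc_state_fc`: `state`, `subject_id`,
#'   `visited` (logical), `z` (S x E matrix, `NA` rows for subjects that
#'   never visit the state), `n_windows_in_state`, plus region metadata.
#' @export
state_mean_fc <- function(wfc_list, model, state) {
  stopifnot(inherits(model, "dfc_state_model"))
  if (!state %in% seq_len(model$k)) abort("`state` out of range.")
  ids <- vapply(wfc_list, function(w) w$subject_id, character(1))
  e <- ncol(wfc_list[[1]]$z)
  z <- matrix(NA_real_, length(ids), e)
  nw <- integer(length(ids))
  for (i in seq_along(ids)) {
    lab <- model$labels |> filter(.data$subject_id == ids[i])
    lab <- lab$state[order(lab$window)]
    sel <- which(lab == state)
    nw[i] <- length(sel)
    if (length(sel) > 0) {
      z[i, ] <- colMeans(wfc_list[[i]]$z[sel, , drop = FALSE])
    }
  }
  structure(list(state = state, subject_id = ids, visited = nw > 0, z = z,
                 n_windows_in_state = nw,
                 n_regions = wfc_list[[1]]$n_regions,
                 region_labels = wfc_list[[1]]$region_labels),
            class = "dfc_state_fc")
}

#' @export
print.dfc_state_fc <- function(x, ...) {
  cat(sprintf("<dfc_state_fc> state %d: %d/%d subjects visit\n",
              x$state, sum(x$visited), length(x$visited)))
  invisible(x)
}
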