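#' Sliding-window specification
#'
#' @param window_len Window length in volumes (default 30, i.e. 60 s at
#'   TR = 2 s).
#' @param step Step between window starts in volumes (default 3 TR).
#' @return An object of class `window_spec`.
#' @export
window_spec <- function(window_len = 30L, step = 3L) {
  window_len <- check_scalar_count(window_len, "window_len", min = 3L)
  step <- check_scalar_count(step, "step", min = 1L)
  structure(list(window_len = window_len, step = step), class = "window_spec")
}

#' Enumerate sliding windows
#'
#' Windows are 0-based, half-open intervals `[k step, k step + window_len)`
#' for `k = 0 .. W-1` with `W = floor((T - window_len)/step) + 1`.
#'
#' @param n_volumes Number of retained volumes T.
#' @param spec A [window_spec()].
#' @return Tibble with columns `window` (1-based index), `start`, `end`.
#' @export
enumerate_windows <- function(n_volumes, spec = window_spec()) {
  n_volumes <- check_scalar_count(n_volumes, "n_volumes", min = 1L)
  if (spec$window_len > n_volumes) {
    abort("`window_len` exceeds the number of volumes.")
  }
  w <- (n_volumes - spec$window_len) %/% spec$step + 1L
  start <- (seq_len(w) - 1L) * spec$step
  tibble(window = seq_len(w), start = start, end = start + spec$window_len)
}

#' Fisher Z transform of a correlation
#'
#' `z = arctanh(r)`, with `|r|` clamped at `1 - 1e-7` first so duplicate
#' time series cannot produce infinite values.
#'
#' @param r Correlation value(s) in `[-1, 1]`.
#' @return Fisher-Z value(s).
#' @export
fisher_z <- function(r) {
  r <- pmin(pmax(r, -(1 - 1e-7)), 1 - 1e-7)
  atanh(r)
}

#' Windowed Fisher-Z functional connectivity
#'
#' Pearson correlation between all region pairs within each sliding window,
#' Fisher-Z transformed.  Matrices are stored as a W x E matrix of strict
#' upper-triangle edge vectors (row-major pair order); the implied N x N
#' matrices are symmetric with zero diagonal (see [fc_matrix()]).  A region
#' with zero variance inside a window gets correlation 0 for all its edges
#' in that window, with a warning.
#'
#' @param ts A preprocessed [roi_ts()].
#' @param spec A [window_spec()].
#' @return An object of class `windowed_fc` with elements `subject_id`,
#'   `windows`, `z` (W x E), `region_labels`, `n_regions`, `spec`,
#'   `tr_seconds`.
#' @export
windowed_fc <- function(ts, spec = window_spec()) {
  stopifnot(inherits(ts, "roi_ts"))
  wins <- enumerate_windows(nrow(ts$data), spec)
  n <- ncol(ts$data)
  idx <- edge_index(n)
  z <- matrix(0, nrow(wins), nrow(idx))
  n_flat <- 0L
  for (w in seq_len(nrow(wins))) {
    seg <- ts$data[(wins$start[w] + 1L):wins$end[w], , drop = FALSE]
    sds <- apply(seg, 2L, stats::sd)
    flat <- sds == 0
    if (any(flat)) {
      n_flat <- n_flat + sum(flat)
      r <- matrix(0, n, n)
      ok <- !flat
      if (sum(ok) >= 2) r[ok, ok] <- stats::cor(seg[, ok, drop = FALSE])
      diag(r) <- 1
    } else {
      r <- stats::cor(seg)
    }
    z[w, ] <- fisher_z(r[idx])
  }
  if (n_flat > 0) {
    warn(sprintf("Subject %s: %d zero-variance region-window pairs; their correlations were set to 0.",
                 ts$subject_id, n_flat))
  }
  structure(list(subject_id = ts$subject_id, windows = wins, z = z,
                 region_labels = ts$region_labels, n_regions = n,
                 spec = spec, tr_seconds = ts$tr_seconds),
            class = "windowed_fc")
}

#' @export
print.windowed_fc <- function(x, ...) {
  cat(sprintf("<windowed_fc> subject %s: %d windows (len %d, step %d), %d regions\n",
              x$subject_id, nrow(x$z), x$spec$window_len, x$spec$step,
              x$n_regions))
  invisible(x)
}

#' Materialise one window's N x N Fisher-Z matrix
#'
#' @param wfc A [windowed_fc()].
#' @param window 1-based window index.
#' @return Symmetric N x N matrix with zero diagonal.
#' @export
fc_matrix <- function(wfc, window) {
  stopifnot(inherits(wfc, "windowed_fc"))
  sym_from_vec(wfc$z[window, ], wfc$n_regions, wfc$region_labels)
}

#' Across-window dFC variability map
#'
#' Entrywise sample standard deviation (denominator W - 1) of the windowed
#' Fisher-Z values: the per-edge variability of dynamic connectivity.
#'
#' @param wfc A [windowed_fc()].
#' @return Object of class `dfc_variability`: `subject_id`, `sd_z`
#'   (symmetric N x N, zero diagonal).
#' @export
variability_map <- function(wfc) {
  stopifnot(inherits(wfc, "windowed_fc"))
  if (nrow(wfc$z) < 2) abort("Variability needs at least 2 windows.")
  sds <- apply(wfc$z, 2L, stats::sd)
  structure(list(subject_id = wfc$subject_id,
                 sd_z = sym_from_vec(sds, wfc$n_regions, wfc$region_labels)),
            class = "dfc_variability")
}

#' @rdname variability_map
#' @param object A `dfc_variability`.
#' @param ... Unused.
#' @export
autoplot.dfc_variability <- function(object, ...) {
  df <- as_tibble(as.data.frame(as.table(object$sd_z)))
  names(df) <- c("region_a", "region_b", "sd_z")
  ggplot2::ggplot(df, ggplot2::aes(.data$region_a, .data$region_b,
                                   fill = .data$sd_z)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "SD(z)") +
    ggplot2::labs(title = sprintf("dFC variability: %s", object$subject_id),
                  x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}
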