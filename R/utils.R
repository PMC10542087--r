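#' @importFrom rlang abort warn inform .data
#' @importFrom tibble tibble as_tibble
#' @import dplyr
NULL

# Row-major upper-triangle index: pairs (i, j), i < j, ordered by i then j.
# This is the canonical edge order used for every vectorised connectivity
# matrix in the package (clustering space, edgewise GLMs, centroids).
edge_index <- function(n) {
  stopifnot(n >= 2)
  i <- rep.int(seq_len(n - 1L), times = (n - 1L):1L)
  j <- unlist(lapply(seq_len(n - 1L), function(a) seq.int(a + 1L, n)),
              use.names = FALSE)
  cbind(i = i, j = j)
}

# Vectorise the strict upper triangle of a symmetric matrix (row-major order).
ut_vec <- function(m) {
  m[edge_index(nrow(m))]
}

# Rebuild a symmetric N x N matrix (zero diagonal) from an edge vector.
sym_from_vec <- function(v, n, labels = NULL) {
  m <- matrix(0, n, n)
  idx <- edge_index(n)
  m[idx] <- v
  m[idx[, c(2L, 1L), drop = FALSE]] <- v
  if (!is.null(labels)) dimnames(m) <- list(labels, labels)
  m
}

# Deterministic per-stage seed derived from a master seed and a stage name,
# so adding a stage never perturbs earlier stages' randomness.
derive_seed <- function(master_seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(master_seed) * 69069 + h * 2654435) %% 2147483647) + 1L
}

check_scalar_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != round(x) || x < min) {
    abort(sprintf("`%s` must be a single integer >= %d.", name, min))
  }
  as.integer(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
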