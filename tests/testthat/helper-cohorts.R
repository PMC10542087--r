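# Small synthetic cohorts and alignment utilities shared across test files.

make_cohort <- function(n_pat = 6, n_ctl = 6, n_regions = 20, seed = 1, ...) {
  generate_cohort(cohort_config(n_patients = n_pat, n_controls = n_ctl,
                                n_regions = n_regions, seed = seed, ...))
}

window_cohort <- function(coh, spec = window_spec(), band = c(0.01, 0.08)) {
  lapply(lapply(coh$timeseries, preprocess_ts, band = band), windowed_fc,
         spec = spec)
}

# Latent state at each window midpoint, aligned row-by-row with model$labels.
aligned_truth <- function(coh, wfc_list, labels) {
  wins <- wfc_list[[1]]$windows
  tr <- lapply(coh$truth$latent, latent_window_labels, windows = wins)
  vapply(seq_len(nrow(labels)), function(i) {
    tr[[labels$subject_id[i]]][labels$window[i]]
  }, integer(1))
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# Hand-built windowed_fc carrying an explicit z matrix (W x E).
fake_wfc <- function(z, subject_id = "S000", n_regions = NULL) {
  e <- ncol(z)
  if (is.null(n_regions)) n_regions <- (1 + sqrt(1 + 8 * e)) / 2
  stopifnot(n_regions == round(n_regions))
  spec <- window_spec(3, 1)
  structure(list(subject_id = subject_id,
                 windows = tibble::tibble(window = seq_len(nrow(z)),
                                          start = seq_len(nrow(z)) - 1L,
                                          end = seq_len(nrow(z)) + 2L),
                 z = z, region_labels = sprintf("R%03d", seq_len(n_regions)),
                 n_regions = as.integer(n_regions), spec = spec,
                 tr_seconds = 2),
            class = "windowed_fc")
}

# Hand-built per-state mean FC container for the edgewise/NBS tests.
fake_state_fc <- function(z, groups, state = 1L, visited = NULL) {
  n <- nrow(z)
  e <- ncol(z)
  nr <- (1 + sqrt(1 + 8 * e)) / 2
  structure(list(state = state, subject_id = sprintf("S%03d", seq_len(n)),
                 visited = visited %||% rep(TRUE, n), z = z,
                 n_windows_in_state = rep(1L, n),
                 n_regions = as.integer(nr),
                 region_labels = sprintf("R%03d", seq_len(nr))),
            class = "dfc_state_fc")
}

fake_meta <- function(groups, seed = 99) {
  n <- length(groups)
  withr::with_seed(seed, tibble::tibble(
    subject_id = sprintf("S%03d", seq_len(n)),
    group = groups,
    age = round(rnorm(n, 47, 8), 1),
    sex = sample(c("M", "F"), n, replace = TRUE),
    education_years = round(rnorm(n, 12.8, 1.2), 1)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
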