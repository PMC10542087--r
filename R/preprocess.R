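#' ROI time-series container
#'
#' @param data Numeric T x N matrix (timepoints x regions).
#' @param region_labels Character vector of N unique labels.
#' @param subject_id Subject identifier.
#' @param tr_seconds Repetition time in seconds.
#' @return An object of class `roi_ts`.
#' @export
roi_ts <- function(data, region_labels = colnames(data), subject_id = "S000",
                   tr_seconds = 2) {
  data <- as.matrix(data)
  if (is.null(region_labels)) {
    region_labels <- sprintf("R%03d", seq_len(ncol(data)))
  }
  if (anyNA(data) || !is.numeric(data)) abort("Time series must be numeric with no missing values.")
  if (ncol(data) < 2) abort("Need at least 2 regions.")
  if (nrow(data) < 1) abort("Need at least 1 timepoint.")
  if (length(region_labels) != ncol(data)) abort("One label per region required.")
  if (anyDuplicated(region_labels)) abort("Region labels must be unique.")
  colnames(data) <- region_labels
  structure(list(subject_id = subject_id, data = data,
                 region_labels = as.character(region_labels),
                 tr_seconds = tr_seconds),
            class = "roi_ts")
}

#' @export
print.roi_ts <- function(x, ...) {
  cat(sprintf("<roi_ts> subject %s: %d volumes x %d regions, TR %g s\n",
              x$subject_id, nrow(x$data), ncol(x$data), x$tr_seconds))
  invisible(x)
}

#' @export
dim.roi_ts <- function(x) dim(x$data)

#' Read a parcellated ROI time series
#'
#' Tab-separated, T rows x N columns, header row of region labels.  Any
#' non-numeric cell raises a parse error naming its row and column;
#' duplicate labels raise a validation error.
#'
#' @param path File path.
#' @param tr_seconds Repetition time to attach, seconds.
#' @param subject_id Subject id; defaults to the file name stem.
#' @return A [roi_ts()].
#' @export
read_roi_timeseries <- function(path, tr_seconds = 2, subject_id = NULL) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  raw <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                           colClasses = "character")
  labels <- colnames(raw)
  if (anyDuplicated(labels)) {
    abort(sprintf("Duplicate region labels in %s: %s", path,
                  paste(unique(labels[duplicated(labels)]), collapse = ", ")))
  }
  num <- suppressWarnings(vapply(raw, as.numeric, numeric(nrow(raw))))
  if (nrow(raw) == 1L) num <- matrix(num, nrow = 1L)
  bad <- which(is.na(num) & !is.na(as.matrix(raw)), arr.ind = TRUE)
  if (anyNA(num)) {
    if (nrow(bad) == 0L) bad <- which(is.na(num), arr.ind = TRUE)
    abort(sprintf("Non-numeric value at row %d, column '%s' of %s.",
                  bad[1, 1], labels[bad[1, 2]], path))
  }
  roi_ts(num, region_labels = labels,
         subject_id = subject_id %||% sub("\\.[^.]*$", "", basename(path)),
         tr_seconds = tr_seconds)
}

#' Write a parcellated ROI time series
#'
#' @param ts A [roi_ts()].
#' @param path Output path (tab-separated, header of region labels).
#' @return `path`, invisibly.
#' @export
write_roi_timeseries <- function(ts, path) {
  stopifnot(inherits(ts, "roi_ts"))
  readr::write_tsv(as_tibble(as.data.frame(ts$data)), path, progress = FALSE)
  invisible(path)
}

#' Read a region-to-network map
#'
#' Two-column CSV (`region`, `network`).  Labels absent from
#' `atlas_labels` are reported; unmapped atlas labels are permitted.
#'
#' @param path CSV path.
#' @param atlas_labels Optional character vector of valid region labels.
#' @return Tibble with columns `region`, `network`.
#' @export
read_network_map <- function(path, atlas_labels = NULL) {
  map <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("region", "network") %in% names(map))) {
    abort("Network map must have columns `region` and `network`.")
  }
  if (!is.null(atlas_labels)) {
    missing_lab <- setdiff(map$region, atlas_labels)
    if (length(missing_lab) > 0) {
      abort(sprintf("Mapped regions not in atlas: %s",
                    paste(missing_lab, collapse = ", ")))
    }
    unmapped <- setdiff(atlas_labels, map$region)
    if (length(unmapped) > 0) {
      inform(sprintf("%d atlas regions are unmapped.", length(unmapped)))
    }
  }
  as_tibble(map[, c("region", "network")])
}

#' Discard leading volumes
#'
#' @param ts A [roi_ts()].
#' @param n_discard Number of initial volumes to drop.
#' @return A [roi_ts()] with the first `n_discard` rows removed.
#' @export
discard_initial <- function(ts, n_discard = 10L) {
  stopifnot(inherits(ts, "roi_ts"))
  n_discard <- check_scalar_count(n_discard, "n_discard", min = 0L)
  if (n_discard >= nrow(ts$data)) {
    abort("`n_discard` must be smaller than the number of volumes.")
  }
  if (n_discard == 0L) return(ts)
  roi_ts(ts$data[-seq_len(n_discard), , drop = FALSE],
         region_labels = ts$region_labels, subject_id = ts$subject_id,
         tr_seconds = ts$tr_seconds)
}

#' Remove per-region linear trends
#'
#' Subtracts the least-squares line over the 0-based volume index from each
#' column; residual means are 0 to numerical precision.  Idempotent.
#'
#' @param ts A [roi_ts()].
#' @return Detrended [roi_ts()].
#' @export
detrend_linear <- function(ts) {
  stopifnot(inherits(ts, "roi_ts"))
  x <- ts$data
  if (nrow(x) < 3) abort("Detrending requires at least 3 volumes.")
  tt <- seq_len(nrow(x)) - 1
  fit <- stats::lm.fit(cbind(1, tt), x)
  roi_ts(fit$residuals, region_labels = ts$region_labels,
         subject_id = ts$subject_id, tr_seconds = ts$tr_seconds)
}

#' Zero-phase band-pass filter
#'
#' Second-order Butterworth applied forward and backward
#' (zero phase, so state-transition timing is not shifted), identically to
#' every column.  Columns are demeaned before filtering, so the output of a
#' band (or high-pass) filter has zero DC component.
#'
#' @param ts A [roi_ts()].
#' @param low_hz,high_hz Pass band in Hz; requires
#'   `0 <= low_hz < high_hz < 1/(2 TR)`.  `low_hz = 0` gives a low-pass.
#' @return Filtered [roi_ts()].
#' @export
bandpass <- function(ts, low_hz = 0.01, high_hz = 0.08) {
  stopifnot(inherits(ts, "roi_ts"))
  nyq <- 1 / (2 * ts$tr_seconds)
  if (low_hz < 0 || low_hz >= high_hz) abort("Need 0 <= low_hz < high_hz.")
  if (high_hz >= nyq) {
    abort(sprintf("high_hz (%.3g) must be below the Nyquist frequency (%.3g Hz).",
                  high_hz, nyq))
  }
  x <- scale(ts$data, center = TRUE, scale = FALSE)
  filt <- if (low_hz > 0) {
    signal::butter(2, c(low_hz, high_hz) / nyq, type = "pass")
  } else {
    signal::butter(2, high_hz / nyq, type = "low")
  }
  y <- apply(x, 2L, function(col) signal::filtfilt(filt, col))
  roi_ts(y, region_labels = ts$region_labels, subject_id = ts$subject_id,
         tr_seconds = ts$tr_seconds)
}

#' Standard temporal preprocessing
#'
#' Fixed order: discard leading volumes, remove linear trends, band-pass.
#' Stages can be switched off but not reordered.
#'
#' @param ts A [roi_ts()].
#' @param n_discard Leading volumes to drop (0 disables).
#' @param detrend Apply linear detrending?
#' @param band Numeric length-2 pass band in Hz, or `NULL` to disable.
#' @return Preprocessed [roi_ts()].
#' @export
preprocess_ts <- function(ts, n_discard = 10L, detrend = TRUE,
                          band = c(0.01, 0.08)) {
  out <- discard_initial(ts, n_discard)
  if (isTRUE(detrend)) out <- detrend_linear(out)
  if (!is.null(band)) out <- bandpass(out, band[1], band[2])
  out
}
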