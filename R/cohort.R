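#' Default region-to-network map
#'
#' Assigns `n_regions` parcels to resting-state networks in contiguous,
#' near-equal blocks.  The default eight networks are those that dominate
#' connectivity-state switching in cervical myelopathy cohorts: sensorimotor
#' (SMN), default mode (DMN), executive control (ECN), salience (SN), visual
#' (VN), auditory (AN), language (LN) and precuneus (PN) networks.
#'
#' @param n_regions Number of parcels (default 90, an AAL-90-sized atlas).
#' @param networks Character vector of network names.
#' @return A tibble with columns `region` (label `R001`, ...) and `network`.
#' @export
default_network_map <- function(n_regions = 90L,
                                networks = c("SMN", "DMN", "ECN", "SN",
                                             "VN", "AN", "LN", "PN")) {
  n_regions <- check_scalar_count(n_regions, "n_regions", min = 2L)
  m <- length(networks)
  sizes <- rep(n_regions %/% m, m)
  extra <- n_regions %% m
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  tibble(
    region = sprintf("R%03d", seq_len(n_regions)),
    network = rep(networks, times = sizes)
  )
}

#' Block-structured state covariance matrices
#'
#' Builds one correlation (unit-diagonal covariance) matrix per latent
#' connectivity state.  State `k` activates the cyclic half of the modules
#' starting at offset `floor((k - 1) m / K)` (so consecutive states differ
#' in several modules and distant states in all of them): within-module
#' correlation is `within_r` for active modules and `within_r / 10` for
#' inactive ones; between-module correlation is `between_r` everywhere.
#' Matrices that are not positive semidefinite are shrunk toward the
#' identity in steps of 0.05 until they are.
#'
#' @param n_regions Number of regions.
#' @param module_labels Vector (length `n_regions`) of module assignments;
#'   defaults to [default_network_map()].
#' @param within_r Within-module correlation for active modules, in (-1, 1).
#' @param between_r Between-module correlation, in (-1, 1).
#' @param n_states Number of latent states (>= 1).
#' @return A list of `n_states` symmetric PSD matrices with unit diagonal.
#' @export
default_block_covariances <- function(n_regions = 90L,
                                      module_labels = NULL,
                                      within_r = 0.7,
                                      between_r = 0,
                                      n_states = 4L) {
  n_regions <- check_scalar_count(n_regions, "n_regions", min = 2L)
  n_states <- check_scalar_count(n_states, "n_states", min = 1L)
  if (abs(within_r) >= 1 || abs(between_r) >= 1) {
    abort("`within_r` and `between_r` must have absolute value < 1.")
  }
  if (is.null(module_labels)) {
    module_labels <- default_network_map(n_regions)$network
  }
  if (length(module_labels) != n_regions) {
    abort("`module_labels` must have one entry per region.")
  }
  mods <- unique(module_labels)
  m <- length(mods)
  mod_id <- match(module_labels, mods)
  n_active <- max(1L, ceiling(m / 2))

  lapply(seq_len(n_states), function(k) {
    shift <- floor((k - 1) * m / n_states)
    active <- ((seq_len(m) - 1 + shift) %% m) < n_active
    r_within <- ifelse(active, within_r, within_r / 10)
    sig <- matrix(between_r, n_regions, n_regions)
    for (mm in seq_len(m)) {
      in_mod <- mod_id == mm
      sig[in_mod, in_mod] <- r_within[mm]
    }
    diag(sig) <- 1
    lambda <- 0
    repeat {
      shrunk <- (1 - lambda) * sig + lambda * diag(n_regions)
      ev <- min(eigen(shrunk, symmetric = TRUE, only.values = TRUE)$values)
      if (ev >= -1e-10) break
      lambda <- lambda + 0.05
      if (lambda > 0.95) {
        abort("Covariance cannot be made PSD by shrinkage toward identity.")
      }
    }
    shrunk
  })
}

#' Default per-group Markov transition matrices
#'
#' Controls get self-transition probability `p_self` in every state; the
#' patient group gets an elevated self-transition in one state only
#' (`asym_state`), planting a longer mean dwell time there while leaving all
#' other dynamics identical.  Off-diagonal mass is spread uniformly.
#'
#' @param n_states Number of states.
#' @param p_self Baseline self-transition probability per dwell tick.
#' @param asym_state State receiving the patient-group dwell asymmetry.
#' @param patient_p_self Patient self-transition probability in `asym_state`.
#' @return List with row-stochastic matrices `patient` and `control`.
#' @export
default_transition_matrices <- function(n_states = 4L, p_self = 0.95,
                                        asym_state = 2L,
                                        patient_p_self = 0.985) {
  n_states <- check_scalar_count(n_states, "n_states", min = 2L)
  mk <- function(self_probs) {
    tm <- matrix(0, n_states, n_states)
    for (s in seq_len(n_states)) {
      tm[s, ] <- (1 - self_probs[s]) / (n_states - 1)
      tm[s, s] <- self_probs[s]
    }
    tm
  }
  ctrl <- mk(rep(p_self, n_states))
  pat_self <- rep(p_self, n_states)
  pat_self[asym_state] <- patient_p_self
  list(patient = mk(pat_self), control = ctrl)
}

#' Synthetic cohort configuration
#'
#' Bundles and validates every parameter of the covariance-switching cohort
#' generator.  Defaults emulate the study conditions the package targets:
#' 88 patients and 77 controls, 90 regions, 240 acquired volumes at
#' TR = 2 s with the first 10 discarded downstream, four latent
#' connectivity states, and a patient-only dwell-time elevation in state 2.
#'
#' @param n_patients,n_controls Group sizes.
#' @param n_regions Number of parcels.
#' @param n_volumes Acquired volumes per subject.
#' @param n_discard Leading volumes the downstream pipeline will discard
#'   (the latent ground truth is reported on the retained volumes).
#' @param tr_seconds Repetition time in seconds.
#' @param n_states Number of latent connectivity states.
#' @param state_covariances List of `n_states` symmetric PSD matrices; by
#'   default [default_block_covariances()].
#' @param transition_patient,transition_control Row-stochastic K x K
#'   matrices; by default [default_transition_matrices()].
#' @param state_switch_step Volumes per latent dwell tick (default 3, the
#'   sliding-window step, so latent dwells are commensurate with windows).
#' @param noise_sd Standard deviation of the AR(1) observation noise.
#' @param ar_phi AR(1) coefficient of the observation noise.
#' @param seed Integer seed (mandatory).
#' @return A validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 88L, n_controls = 77L,
                          n_regions = 90L, n_volumes = 240L,
                          n_discard = 10L, tr_seconds = 2,
                          n_states = 4L,
                          state_covariances = NULL,
                          transition_patient = NULL,
                          transition_control = NULL,
                          state_switch_step = 3L,
                          noise_sd = 0.3, ar_phi = 0.4,
                          seed) {
  if (missing(seed) || is.null(seed)) abort("`seed` is mandatory.")
  n_patients <- check_scalar_count(n_patients, "n_patients")
  n_controls <- check_scalar_count(n_controls, "n_controls")
  n_regions <- check_scalar_count(n_regions, "n_regions", min = 2L)
  n_volumes <- check_scalar_count(n_volumes, "n_volumes", min = 2L)
  n_discard <- check_scalar_count(n_discard, "n_discard", min = 0L)
  n_states <- check_scalar_count(n_states, "n_states", min = 1L)
  state_switch_step <- check_scalar_count(state_switch_step, "state_switch_step")
  if (n_volumes <= n_discard) abort("`n_volumes` must exceed `n_discard`.")
  if (noise_sd < 0) abort("`noise_sd` must be nonnegative.")

  if (is.null(state_covariances)) {
    state_covariances <- default_block_covariances(n_regions,
                                                   n_states = n_states)
  }
  if (length(state_covariances) != n_states) {
    abort("`state_covariances` must have one matrix per state.")
  }
  for (s in seq_along(state_covariances)) {
    sig <- state_covariances[[s]]
    if (!is.matrix(sig) || nrow(sig) != n_regions || ncol(sig) != n_regions) {
      abort(sprintf("State %d covariance is not %d x %d.", s, n_regions, n_regions))
    }
    if (max(abs(sig - t(sig))) > 1e-10) {
      abort(sprintf("State %d covariance is not symmetric.", s))
    }
    ev <- min(eigen(sig, symmetric = TRUE, only.values = TRUE)$values)
    if (ev < -1e-8) {
      abort(sprintf("State %d covariance is not positive semidefinite.", s))
    }
  }
  if (n_states >= 2) {
    if (is.null(transition_patient) || is.null(transition_control)) {
      tms <- default_transition_matrices(n_states)
      transition_patient <- transition_patient %||% tms$patient
      transition_control <- transition_control %||% tms$control
    }
    check_stochastic(transition_patient, n_states, "transition_patient")
    check_stochastic(transition_control, n_states, "transition_control")
  }

  structure(list(
    n_patients = n_patients, n_controls = n_controls,
    n_regions = n_regions, n_volumes = n_volumes, n_discard = n_discard,
    tr_seconds = tr_seconds, n_states = n_states,
    state_covariances = state_covariances,
    transition_patient = transition_patient,
    transition_control = transition_control,
    state_switch_step = state_switch_step,
    noise_sd = noise_sd, ar_phi = ar_phi,
    seed = as.integer(seed)
  ), class = "cohort_config")
}

check_stochastic <- function(tm, k, name) {
  if (!is.matrix(tm) || nrow(tm) != k || ncol(tm) != k) {
    abort(sprintf("`%s` must be %d x %d.", name, k, k))
  }
  if (any(tm < 0) || any(abs(rowSums(tm) - 1) > 1e-12)) {
    abort(sprintf("`%s` rows must be nonnegative and sum to 1 (+- 1e-12).", name))
  }
  invisible(tm)
}

#' Simulate a latent state sequence from a Markov chain
#'
#' @param transition_matrix K x K row-stochastic matrix.
#' @param n_ticks Length of the sequence.
#' @param initial_distribution Length-K probability vector for the first
#'   state; uniform by default.
#' @param seed Integer seed.
#' @return Integer vector of `n_ticks` states in `1..K`.
#' @export
generate_state_sequence <- function(transition_matrix, n_ticks,
                                    initial_distribution = NULL, seed) {
  k <- nrow(transition_matrix)
  if (is.null(k) || k < 2) abort("Need at least 2 states (K >= 2).")
  check_stochastic(transition_matrix, k, "transition_matrix")
  n_ticks <- check_scalar_count(n_ticks, "n_ticks")
  if (is.null(initial_distribution)) initial_distribution <- rep(1 / k, k)
  if (length(initial_distribution) != k || any(initial_distribution < 0) ||
      abs(sum(initial_distribution) - 1) > 1e-8) {
    abort("`initial_distribution` must be a length-K probability vector.")
  }
  withr::with_seed(as.integer(seed), {
    out <- integer(n_ticks)
    out[1L] <- sample.int(k, 1L, prob = initial_distribution)
    if (n_ticks > 1L) {
      u <- stats::runif(n_ticks - 1L)
      cum <- t(apply(transition_matrix, 1L, cumsum))
      for (t in 2L:n_ticks) {
        out[t] <- sum(u[t - 1L] > cum[out[t - 1L], ]) + 1L
      }
    }
    out
  })
}

#' Generate a synthetic two-group ROI time-series cohort
#'
#' Hidden-Markov covariance-switching model: each subject's latent state
#' advances once per `state_switch_step` volumes following that group's
#' transition matrix; within a dwell segment, volumes are drawn from a
#' zero-mean multivariate normal with the state's covariance; AR(1)
#' observation noise of standard deviation `noise_sd` is added.  Subject
#' metadata (age, sex, education, symptom duration, JOA, NDI) is drawn to
#' match the demographic moments of the target cohort; clinical scores are
#' missing for controls by construction.
#'
#' @param config A [cohort_config()].
#' @return List with `timeseries` (list of `roi_ts`), `meta` (tibble) and
#'   `truth` (per-subject retained-volume latent sequences, the true
#'   transition matrices, and the module labels).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  cfg <- config
  n_sub <- cfg$n_patients + cfg$n_controls
  group <- rep(c("patient", "control"), c(cfg$n_patients, cfg$n_controls))
  ids <- sprintf("S%03d", seq_len(n_sub))
  labels <- sprintf("R%03d", seq_len(cfg$n_regions))
  n_ticks <- ceiling(cfg$n_volumes / cfg$state_switch_step)
  chols <- lapply(cfg$state_covariances, function(s) chol(s + 1e-12 * diag(nrow(s))))

  withr::with_seed(cfg$seed, {
    latent_all <- vector("list", n_sub)
    ts_all <- vector("list", n_sub)
    for (i in seq_len(n_sub)) {
      if (cfg$n_states >= 2) {
        tm <- if (group[i] == "patient") cfg$transition_patient else cfg$transition_control
        seq_seed <- sample.int(2147483646L, 1L)
        ticks <- generate_state_sequence(tm, n_ticks, seed = seq_seed)
      } else {
        ticks <- rep(1L, n_ticks)
      }
      lat <- rep(ticks, each = cfg$state_switch_step)[seq_len(cfg$n_volumes)]
      z <- matrix(stats::rnorm(cfg$n_volumes * cfg$n_regions),
                  cfg$n_volumes, cfg$n_regions)
      x <- matrix(0, cfg$n_volumes, cfg$n_regions)
      for (s in unique(lat)) {
        rows <- which(lat == s)
        x[rows, ] <- z[rows, , drop = FALSE] %*% chols[[s]]
      }
      if (cfg$noise_sd > 0) {
        innov_sd <- cfg$noise_sd * sqrt(1 - cfg$ar_phi^2)
        e <- matrix(stats::rnorm(cfg$n_volumes * cfg$n_regions, sd = innov_sd),
                    cfg$n_volumes, cfg$n_regions)
        e <- apply(e, 2L, function(col) {
          as.numeric(stats::filter(col, cfg$ar_phi, method = "recursive"))
        })
        x <- x + e
      }
      latent_all[[i]] <- lat[(cfg$n_discard + 1L):cfg$n_volumes]
      ts_all[[i]] <- roi_ts(x, region_labels = labels, subject_id = ids[i],
                            tr_seconds = cfg$tr_seconds)
    }

    meta <- tibble(
      subject_id = ids,
      group = group,
      age = round(ifelse(group == "patient",
                         stats::rnorm(n_sub, 49.22, 7.91),
                         stats::rnorm(n_sub, 45.13, 8.76)), 1),
      sex = draw_sex(group),
      education_years = round(ifelse(group == "patient",
                                     stats::rnorm(n_sub, 12.91, 1.21),
                                     stats::rnorm(n_sub, 12.64, 1.20)), 1),
      duration_months = ifelse(group == "patient",
                               pmax(1, round(stats::rnorm(n_sub, 10.24, 6.10), 1)),
                               NA_real_),
      joa = ifelse(group == "patient",
                   pmin(17, pmax(0, round(stats::rnorm(n_sub, 11.10, 1.78), 1))),
                   NA_real_),
      ndi = ifelse(group == "patient",
                   pmin(1, pmax(0, round(stats::rnorm(n_sub, 0.32, 0.09), 2))),
                   NA_real_)
    )

    truth <- list(
      latent = stats::setNames(latent_all, ids),
      transition_patient = cfg$transition_patient,
      transition_control = cfg$transition_control,
      module_labels = default_network_map(cfg$n_regions)$network,
      n_discard = cfg$n_discard,
      state_switch_step = cfg$state_switch_step
    )
    list(timeseries = ts_all, meta = meta, truth = truth)
  })
}

# Deterministic sex counts per group (matching target proportions), shuffled.
draw_sex <- function(group) {
  out <- character(length(group))
  for (g in unique(group)) {
    idx <- which(group == g)
    p_male <- if (g == "patient") 45 / 88 else 39 / 77
    n_male <- round(length(idx) * p_male)
    sexes <- c(rep("M", n_male), rep("F", length(idx) - n_male))
    out[idx] <- sample(sexes)
  }
  out
}

#' Write a synthetic cohort to disk
#'
#' One TSV per subject (T rows x N regions, header = region labels),
#' metadata CSV and ground-truth JSON.
#'
#' @param cohort Output of [generate_cohort()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (ts in cohort$timeseries) {
    write_roi_timeseries(ts, file.path(dir, paste0(ts$subject_id, ".tsv")))
  }
  readr::write_csv(cohort$meta, file.path(dir, "meta.csv"))
  jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Latent state at each window midpoint
#'
#' Truth-channel utility: maps a subject's retained-volume latent sequence
#' onto sliding windows by reading the state at each window's midpoint
#' volume.
#'
#' @param latent Integer vector of per-volume latent states (retained
#'   volumes, i.e. after discard).
#' @param windows Tibble from [enumerate_windows()].
#' @return Integer vector, one state per window.
#' @export
latent_window_labels <- function(latent, windows) {
  mid <- floor((windows$start + windows$end) / 2)
  latent[mid + 1L]
}
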