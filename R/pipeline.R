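pipeline_stages <- c("simulate", "preprocess", "window", "cluster",
                     "temporal", "nbs", "graph", "clinical", "report")

default_run_config <- function() {
  list(
    seed = NULL,
    output_dir = NULL,
    input_dir = NULL,
    stages = pipeline_stages,
    cohort = list(n_patients = 88L, n_controls = 77L, n_regions = 90L,
                  n_volumes = 240L, n_discard = 10L, tr_seconds = 2,
                  n_states = 4L, state_switch_step = 3L, noise_sd = 0.3,
                  ar_phi = 0.4, within_r = 0.7, between_r = 0,
                  p_self = 0.95, asym_state = 2L, patient_p_self = 0.985),
    preprocess = list(n_discard = 10L, detrend = TRUE, band = c(0.01, 0.08)),
    window = list(window_len = 30L, step = 3L),
    cluster = list(k = "auto", k_range = c(2L, 8L), n_restarts = 10L,
                   criterion = "elbow"),
    nbs = list(edge_p = 0.001, component_p = 0.05, n_perm = 1000L,
               covariates = c("age", "sex", "education_years")),
    graph = list(s_min = 0.10, s_max = 0.40, s_step = 0.01, rank = "abs",
                 max_windows = NULL, nodes = NULL,
                 covariates = c("age", "sex", "education_years")),
    clinical = list(enabled = TRUE)
  )
}

#' Validate and normalise a pipeline configuration
#'
#' Accepts a YAML/JSON file path or a nested list, checks every key
#' against the known schema (unknown keys are an error listing the valid
#' ones), fills defaults, and enforces invariants (mandatory seed, window
#' and sparsity constraints, known stages).
#'
#' @param config File path (`.yaml`/`.yml`/`.json`) or nested list.
#' @return Normalised configuration of class `run_config`.
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.json$", config)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  if (!is.list(config)) abort("Config must be a list or a YAML/JSON path.")
  defaults <- default_run_config()

  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0) {
    abort(sprintf("Unknown config key(s): %s. Valid keys: %s.",
                  paste(unknown, collapse = ", "),
                  paste(names(defaults), collapse = ", ")))
  }
  for (sec in c("cohort", "preprocess", "window", "cluster", "nbs",
                "graph", "clinical")) {
    bad <- setdiff(names(config[[sec]]), names(defaults[[sec]]))
    if (length(bad) > 0) {
      abort(sprintf("Unknown key(s) in `%s`: %s. Valid keys: %s.",
                    sec, paste(bad, collapse = ", "),
                    paste(names(defaults[[sec]]), collapse = ", ")))
    }
    config[[sec]] <- utils::modifyList(defaults[[sec]], config[[sec]] %||% list())
  }
  for (top in c("stages")) {
    config[[top]] <- config[[top]] %||% defaults[[top]]
  }

  if (is.null(config$seed)) abort("`seed` is mandatory in pipeline configs.")
  bad_stage <- setdiff(config$stages, pipeline_stages)
  if (length(bad_stage) > 0) {
    abort(sprintf("Unknown stage(s): %s.", paste(bad_stage, collapse = ", ")))
  }
  config$stages <- pipeline_stages[pipeline_stages %in% config$stages]
  if (config$graph$s_min >= config$graph$s_max) {
    abort("Invalid `graph`: s_min must be below s_max.")
  }
  window_spec(config$window$window_len, config$window$step)  # validates
  sparsity_ladder(config$graph$s_min, config$graph$s_max, config$graph$s_step)
  config$seed <- as.integer(config$seed)
  structure(config, class = "run_config")
}

write_table <- function(df, path, seed) {
  writeLines(sprintf("# seed=%d dfcstates=%s", seed,
                     as.character(utils::packageVersion("dfcstates"))), path)
  readr::write_csv(df, path, append = TRUE, col_names = TRUE, progress = FALSE)
  invisible(path)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir Directory with per-subject TSVs and `meta.csv`.
#' @param tr_seconds TR to attach to the series.
#' @return List with `timeseries` and `meta` (and `truth` when present).
#' @export
load_cohort_dir <- function(dir, tr_seconds = 2) {
  meta <- readr::read_csv(file.path(dir, "meta.csv"), show_col_types = FALSE)
  ts <- lapply(meta$subject_id, function(id) {
    read_roi_timeseries(file.path(dir, paste0(id, ".tsv")),
                        tr_seconds = tr_seconds, subject_id = id)
  })
  truth <- NULL
  tp <- file.path(dir, "truth.json")
  if (file.exists(tp)) truth <- jsonlite::read_json(tp, simplifyVector = TRUE)
  list(timeseries = ts, meta = as_tibble(meta), truth = truth)
}

#' Run the end-to-end dynamic-connectivity pipeline
#'
#' Orchestrates simulate, preprocess, window, cluster, temporal, nbs, graph
#' and clinical stages in fixed order, writing every declared output table
#' (each with a seed/version comment header) plus a provenance report that
#' suffices to re-run the identical analysis.  Per-stage seeds are derived
#' from the master seed by stage-name hashing, so two runs with the same
#' config are identical and adding a stage never perturbs earlier ones.
#'
#' @param config A [validate_config()] result (or anything it accepts).
#' @param output_dir Output directory; overrides `config$output_dir`.
#' @return Object of class `run_report`: per-stage provenance and the
#'   headline tables.
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  if (!inherits(config, "run_config")) config <- validate_config(config)
  out_dir <- output_dir %||% config$output_dir
  if (is.null(out_dir)) abort("An output directory is required.")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  seed <- config$seed
  stages <- config$stages
  report <- list(seed = seed,
                 package_version = as.character(utils::packageVersion("dfcstates")),
                 config = unclass(config), stages = list(), tables = list())
  t_stage <- function(expr) {
    t0 <- proc.time()[["elapsed"]]
    v <- force(expr)
    list(value = v, wall_s = proc.time()[["elapsed"]] - t0)
  }
  cohort <- NULL; ts_pp <- NULL; wfc <- NULL; model <- NULL; metrics <- NULL

  if ("simulate" %in% stages) {
    st <- t_stage({
      cc <- config$cohort
      covs <- default_block_covariances(cc$n_regions,
                                        within_r = cc$within_r,
                                        between_r = cc$between_r,
                                        n_states = cc$n_states)
      tms <- default_transition_matrices(cc$n_states, p_self = cc$p_self,
                                         asym_state = cc$asym_state,
                                         patient_p_self = cc$patient_p_self)
      cfg <- cohort_config(
        n_patients = cc$n_patients, n_controls = cc$n_controls,
        n_regions = cc$n_regions, n_volumes = cc$n_volumes,
        n_discard = cc$n_discard, tr_seconds = cc$tr_seconds,
        n_states = cc$n_states, state_covariances = covs,
        transition_patient = tms$patient, transition_control = tms$control,
        state_switch_step = cc$state_switch_step, noise_sd = cc$noise_sd,
        ar_phi = cc$ar_phi, seed = derive_seed(seed, "simulate"))
      cohort <- generate_cohort(cfg)
      write_cohort(cohort, file.path(out_dir, "cohort"))
      cohort
    })
    cohort <- st$value
    report$stages$simulate <- list(seed = derive_seed(seed, "simulate"),
                                   n_subjects = length(cohort$timeseries),
                                   wall_s = st$wall_s)
  } else if (!is.null(config$input_dir)) {
    cohort <- load_cohort_dir(config$input_dir,
                              tr_seconds = config$cohort$tr_seconds)
  }

  if ("preprocess" %in% stages) {
    if (is.null(cohort)) abort("Stage `preprocess` failed: no cohort (simulate or input_dir required).")
    st <- t_stage(lapply(cohort$timeseries, preprocess_ts,
                         n_discard = config$preprocess$n_discard,
                         detrend = config$preprocess$detrend,
                         band = config$preprocess$band))
    ts_pp <- st$value
    report$stages$preprocess <- list(params = config$preprocess,
                                     wall_s = st$wall_s)
  }

  if ("window" %in% stages) {
    if (is.null(ts_pp)) abort("Stage `window` failed: no preprocessed series.")
    spec <- window_spec(config$window$window_len, config$window$step)
    st <- t_stage(lapply(ts_pp, windowed_fc, spec = spec))
    wfc <- st$value
    counts <- tibble(
      subject_id = vapply(wfc, function(w) w$subject_id, character(1)),
      n_windows = vapply(wfc, function(w) nrow(w$z), integer(1)))
    report$tables$window_counts <- counts
    report$n_windows_per_subject <- counts$n_windows[1]
    report$n_windowed_networks <- sum(counts$n_windows)
    write_table(counts, file.path(out_dir, "window_counts.csv"), seed)
    report$stages$window <- list(params = config$window, wall_s = st$wall_s,
                                 total_networks = sum(counts$n_windows))
  }

  if ("cluster" %in% stages) {
    if (is.null(wfc)) abort("Stage `cluster` failed: no windowed connectivity.")
    cl <- config$cluster
    st <- t_stage({
      if (identical(cl$k, "auto")) {
        ks <- select_k(wfc, k_range = seq(cl$k_range[1], cl$k_range[2]),
                       criterion = cl$criterion, n_restarts = cl$n_restarts,
                       seed = derive_seed(seed, "cluster"))
        write_table(ks$curve, file.path(out_dir, "k_selection.csv"), seed)
        list(model = ks$models[[match(ks$k, ks$curve$k)]], k_select = ks)
      } else {
        list(model = fit_states(wfc, as.integer(cl$k),
                                n_restarts = cl$n_restarts,
                                seed = derive_seed(seed, "cluster")),
             k_select = NULL)
      }
    })
    model <- st$value$model
    write_table(model$labels, file.path(out_dir, "state_labels.csv"), seed)
    centro <- as.data.frame(model$centroids)
    readr::write_tsv(centro, file.path(out_dir, "state_centroids.tsv"),
                     progress = FALSE)
    report$tables$states <- tibble(state = seq_len(model$k),
                                   occupancy = model$occupancy)
    report$k <- model$k
    report$stages$cluster <- list(seed = derive_seed(seed, "cluster"),
                                  k = model$k, inertia = model$inertia,
                                  wall_s = st$wall_s)
  }

  if ("temporal" %in% stages) {
    if (is.null(model)) abort("Stage `temporal` failed: no state model.")
    st <- t_stage({
      mets <- temporal_metrics(model, step = config$window$step,
                               tr_seconds = config$cohort$tr_seconds)
      contrasts <- compare_temporal(mets, cohort$meta,
                                    covariates = config$nbs$covariates)
      list(metrics = mets, contrasts = contrasts)
    })
    metrics <- st$value$metrics
    write_table(metrics, file.path(out_dir, "temporal_metrics.csv"), seed)
    write_table(st$value$contrasts,
                file.path(out_dir, "temporal_contrasts.csv"), seed)
    report$tables$temporal_contrasts <- st$value$contrasts
    report$stages$temporal <- list(wall_s = st$wall_s)
  }

  if ("nbs" %in% stages) {
    if (is.null(model)) abort("Stage `nbs` failed: no state model.")
    nb <- config$nbs
    st <- t_stage({
      res <- list(); skipped <- character(0)
      for (s in seq_len(model$k)) {
        sfc <- state_mean_fc(wfc, model, s)
        r <- tryCatch(
          nbs(sfc, cohort$meta, covariates = nb$covariates,
              edge_p = nb$edge_p, n_perm = nb$n_perm,
              seed = derive_seed(seed, paste0("nbs", s))),
          dfc_state_skipped = function(e) {
            skipped <<- c(skipped, conditionMessage(e))
            NULL
          })
        if (!is.null(r)) res[[as.character(s)]] <- r
      }
      list(results = res, skipped = skipped)
    })
    comp_tbl <- bind_rows(lapply(st$value$results, function(r) {
      if (length(r$components) == 0) return(NULL)
      tibble(state = r$state, component = seq_along(r$components),
             size = r$component_sizes, fwe_p = r$fwe_p,
             significant = r$fwe_p < nb$component_p)
    }))
    if (nrow(comp_tbl %||% tibble()) == 0) {
      comp_tbl <- tibble(state = integer(0), component = integer(0),
                         size = integer(0), fwe_p = numeric(0),
                         significant = logical(0))
    }
    write_table(comp_tbl, file.path(out_dir, "nbs_components.csv"), seed)
    jsonlite::write_json(
      lapply(st$value$results, function(r) {
        list(state = r$state, edge_p = r$edge_p, n_perm = r$n_perm,
             components = lapply(seq_along(r$components), function(i) {
               list(size = r$component_sizes[i], fwe_p = r$fwe_p[i],
                    edges = r$components[[i]])
             }))
      }), file.path(out_dir, "nbs_components.json"),
      auto_unbox = TRUE, digits = NA)
    report$tables$nbs_components <- comp_tbl
    report$stages$nbs <- list(params = nb, skipped = st$value$skipped,
                              wall_s = st$wall_s)
  }

  if ("graph" %in% stages) {
    if (is.null(wfc)) abort("Stage `graph` failed: no windowed connectivity.")
    gr <- config$graph
    st <- t_stage({
      ladder <- sparsity_ladder(gr$s_min, gr$s_max, gr$s_step)
      per_sub <- lapply(wfc, function(w) {
        wsel <- if (!is.null(gr$max_windows) && gr$max_windows < nrow(w$z)) {
          unique(round(seq(1, nrow(w$z), length.out = gr$max_windows)))
        } else NULL
        dyn_graph_metrics(w, ladder, rank = gr$rank, windows = wsel,
                          nodes = gr$nodes)
      })
      variances <- metric_variance(bind_rows(per_sub))
      contrasts <- compare_variance(variances, cohort$meta,
                                    covariates = gr$covariates)
      list(variances = variances, contrasts = contrasts)
    })
    write_table(st$value$variances, file.path(out_dir, "metric_variance.csv"),
                seed)
    write_table(st$value$contrasts,
                file.path(out_dir, "variance_contrasts.csv"), seed)
    report$tables$variance_contrasts <- st$value$contrasts
    report$stages$graph <- list(params = gr[c("s_min", "s_max", "s_step", "rank")],
                                wall_s = st$wall_s)
  }

  if ("clinical" %in% stages && isTRUE(config$clinical$enabled)) {
    if (is.null(cohort)) abort("Stage `clinical` failed: no cohort metadata.")
    st <- t_stage({
      summ <- describe_cohort(cohort$meta)
      corr <- NULL
      if (!is.null(metrics) && all(c("joa", "ndi") %in% names(cohort$meta))) {
        pat_metrics <- metrics |>
          filter(.data$state == 2) |>
          select("subject_id", dwell_state2 = "mean_dwell") |>
          inner_join(cohort$meta, by = "subject_id") |>
          filter(.data$group == "patient")
        corr <- correlate_clinical(pat_metrics, "dwell_state2")
      }
      list(summary = summ, corr = corr)
    })
    write_table(st$value$summary, file.path(out_dir, "cohort_summary.csv"), seed)
    if (!is.null(st$value$corr)) {
      write_table(st$value$corr, file.path(out_dir, "clinical_correlations.csv"),
                  seed)
    }
    report$tables$cohort_summary <- st$value$summary
    report$stages$clinical <- list(wall_s = st$wall_s)
  }

  report_path <- file.path(out_dir, "report.json")
  prov <- report
  prov$tables <- NULL  # tables live in their CSVs
  jsonlite::write_json(prov, report_path, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  structure(report, class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> seed %d, stages: %s\n", x$seed,
              paste(names(x$stages), collapse = ", ")))
  if (!is.null(x$n_windowed_networks)) {
    cat(sprintf("  %d windows/subject, %d windowed networks\n",
                x$n_windows_per_subject, x$n_windowed_networks))
  }
  if (!is.null(x$k)) cat(sprintf("  K = %d\n", x$k))
  invisible(x)
}
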