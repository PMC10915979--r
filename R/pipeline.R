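#' Default pipeline configuration
#'
#' A nested list mirroring every stage parameter; serialisable as YAML.
#' Every source of randomness has an explicit seed.
#'
#' @return Named list of stage configurations.
#' @export
default_config <- function() {
  list(
    input = list(mode = "synthetic", timecourses_dir = NULL),
    cohort = list(n_patients = 33, n_controls = 23, n_timepoints = 199,
                  tr_seconds = 2, n_components = 10, noise_sd = 0,
                  ar_phi = 0, seed = 1),
    dfnc = list(window_length = 30, sigma = 3, step = 1,
                lambda = 0.01, lambda_grid = as.numeric(10^seq(-2, 0, length.out = 10)),
                n_repetitions = 100, fc = "correlation", seed = 11,
                covariates = c("age", "gender")),
    states = list(k = NULL, k_candidates = 2:8, n_replicates = 100,
                  seed = 21),
    stats = list(test = "t", covariates = "gender",
                 clinical_correlations = FALSE, seed = 31),
    output = list(dir = "dynfnc-output")
  )
}

#' Read and validate a pipeline configuration from YAML
#'
#' Unknown keys are rejected; missing keys take defaults from
#' [default_config()].
#'
#' @param path Path to a YAML file.
#' @return Validated configuration list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  user <- yaml::read_yaml(path)
  base <- default_config()
  bad <- setdiff(names(user), names(base))
  if (length(bad)) abort(sprintf("unknown config section(s): %s",
                                 paste(bad, collapse = ", ")))
  for (sec in names(user)) {
    bad_keys <- setdiff(names(user[[sec]]), names(base[[sec]]))
    if (length(bad_keys)) {
      abort(sprintf("unknown key(s) in '%s': %s", sec,
                    paste(bad_keys, collapse = ", ")))
    }
    base[[sec]] <- modifyList(base[[sec]], user[[sec]])
  }
  validate_config(base)
}

#' @rdname read_run_config
#' @param config Configuration list to validate.
#' @export
validate_config <- function(config) {
  d <- config$dfnc
  if (d$window_length < 2) abort("window_length must be >= 2")
  if (d$sigma <= 0) abort("sigma must be > 0")
  if (d$step < 1) abort("step must be >= 1")
  if (!identical(d$lambda, "select") && d$lambda < 0) {
    abort("lambda must be >= 0 or \"select\"")
  }
  s <- config$states
  if (is.null(s[["k"]]) && length(s[["k_candidates"]]) < 3) {
    abort("either states$k or >= 3 k_candidates must be given")
  }
  for (sec in c("cohort", "dfnc", "states")) {
    if (is.null(config[[sec]]$seed)) abort(sprintf("missing seed in '%s'", sec))
  }
  config
}

.write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Stages in order: cohort input (synthetic generation or TSV ingest),
#' static FNC (component and network level), dynamic FNC (tapered windows,
#' graphical lasso, Fisher z, nuisance residualisation), state analysis
#' (k selection or fixed k, clustering, temporal-property metrics, per-group
#' centroids), temporal variability, and group statistics per family with
#' FDR control. All outputs are tidy TSV files; the run report carries
#' parameters, seeds, warnings and an md5 manifest of every file written.
#'
#' @param config Configuration list, as [default_config()] or
#'   [read_run_config()].
#' @param out_dir Output directory (overrides `config$output$dir`).
#' @return Invisibly, the run report (also written as `run_report.yaml`).
#' @export
run_pipeline <- function(config = default_config(), out_dir = NULL) {
  config <- validate_config(config)
  dir <- out_dir %||% config$output$dir
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  warnings <- character(0)
  note <- function(f) files <<- c(files, f)

  # --- input ---------------------------------------------------------------
  if (config$input$mode == "synthetic") {
    ch <- config$cohort
    design <- cohort_design(
      n_patients = ch$n_patients, n_controls = ch$n_controls,
      n_timepoints = ch$n_timepoints, tr_seconds = ch$tr_seconds,
      n_components = ch$n_components, noise_sd = ch$noise_sd,
      ar_phi = ch$ar_phi, seed = ch$seed)
    cohort <- simulate_cohort(design)
    subjects <- cohort$subjects
    clinical <- cohort$clinical
    note(.write_tsv(clinical, file.path(dir, "clinical.tsv")))
  } else if (config$input$mode == "timecourses") {
    if (is.null(config$input$timecourses_dir)) {
      abort("timecourses mode requires input$timecourses_dir")
    }
    subjects <- read_cohort(config$input$timecourses_dir)
    clin_path <- file.path(config$input$timecourses_dir, "clinical.tsv")
    clinical <- if (file.exists(clin_path)) as_tibble(read.delim(clin_path)) else NULL
  } else {
    abort(sprintf("unsupported input mode '%s'", config$input$mode))
  }
  note(.write_tsv(
    subjects %>% select(!dplyr::any_of(c("timecourses", "true_states"))),
    file.path(dir, "subjects.tsv")))

  # --- sFNC ----------------------------------------------------------------
  sf <- sfnc(subjects)
  sf_long <- tidy(sf)
  note(.write_tsv(sf_long, file.path(dir, "sfnc_long.tsv")))
  assignment <- default_networks()[seq_len(ncol(subjects$timecourses[[1]]))]
  names(assignment) <- colnames(subjects$timecourses[[1]])
  dom <- sfnc_domain(sf, assignment)
  dom_long <- bind_rows(lapply(seq_len(nrow(dom)), function(i) {
    m <- dom$domain[[i]]
    idx <- which(upper.tri(m, diag = TRUE), arr.ind = TRUE)
    tibble(subject_id = dom$subject_id[i],
           net_a = rownames(m)[idx[, 1]], net_b = colnames(m)[idx[, 2]],
           z = m[idx])
  }))
  note(.write_tsv(dom_long, file.path(dir, "sfnc_domain_long.tsv")))

  # --- dFNC ----------------------------------------------------------------
  d <- config$dfnc
  stack <- dfnc(subjects, window_length = d$window_length, sigma = d$sigma,
                step = d$step, lambda = d$lambda, lambda_grid = d$lambda_grid,
                n_repetitions = d$n_repetitions, seed = d$seed, fc = d$fc)
  covs <- intersect(d$covariates, names(stack))
  if (length(covs)) stack <- residualize_stack(stack, covs)
  note(.write_tsv(
    stack %>% select(!dplyr::all_of(c("z", "window_starts"))),
    file.path(dir, "dfnc_index.tsv")))

  # --- states --------------------------------------------------------------
  s <- config$states
  chosen_k <- s[["k"]]
  elbow_curve <- NULL
  if (is.null(chosen_k)) {
    sel <- withCallingHandlers(
      select_k_elbow(stack, s[["k_candidates"]], n_replicates = s$n_replicates,
                     seed = s$seed),
      warning = function(w) {
        warnings <<- c(warnings, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    chosen_k <- sel$k
    elbow_curve <- sel$curve
    note(.write_tsv(sel$curve, file.path(dir, "elbow_curve.tsv")))
  }
  model <- cluster_states(stack, k = chosen_k, n_replicates = s$n_replicates,
                          seed = s$seed)
  note(.write_tsv(tidy(model), file.path(dir, "state_labels.tsv")))
  for (st in seq_len(model$k)) {
    note(.write_tsv(as.data.frame(model$centroids[st, , ]),
                    file.path(dir, sprintf("state_centroid_%d.tsv", st))))
  }
  metrics <- state_metrics(model)
  note(.write_tsv(metrics, file.path(dir, "state_metrics.tsv")))
  if ("group" %in% names(stack)) {
    gsc <- group_state_centroids(stack, model)
    note(.write_tsv(gsc %>% select(!"centroid"),
                    file.path(dir, "state_occurrence.tsv")))
  }

  # --- temporal variability ------------------------------------------------
  vb <- temporal_variability(stack)
  note(.write_tsv(vb, file.path(dir, "variability.tsv")))

  # --- statistics ----------------------------------------------------------
  stats_tbl <- NULL
  if ("group" %in% names(subjects)) {
    covariate_cols <- intersect(config$stats$covariates, names(subjects))
    sf_feats <- sf_long %>%
      mutate(feature = paste(.data$comp_a, .data$comp_b, sep = "-")) %>%
      left_join(subjects %>% select("subject_id",
                                    dplyr::any_of(c("age", "gender"))),
                by = "subject_id")
    fam1 <- compare_groups(sf_feats, "z", "feature", "group",
                           covariate_cols = covariate_cols,
                           test = config$stats$test, family = "sfnc_pairs")
    dom_feats <- dom_long %>%
      filter(!is.na(.data$z)) %>%
      mutate(feature = paste(.data$net_a, .data$net_b, sep = "-")) %>%
      left_join(subjects %>% select("subject_id", "group",
                                    dplyr::any_of(c("age", "gender"))),
                by = "subject_id")
    fam2 <- compare_groups(dom_feats, "z", "feature", "group",
                           covariate_cols = covariate_cols,
                           test = config$stats$test, family = "sfnc_domain")
    met_long <- metrics %>%
      tidyr::pivot_longer(c("fraction_time", "mean_dwell_time"),
                          names_to = "metric", values_to = "value") %>%
      mutate(feature = paste(.data$metric, .data$state, sep = "_state"))
    trans <- metrics %>%
      group_by(.data$subject_id) %>%
      dplyr::slice(1) %>% ungroup() %>%
      mutate(feature = "n_transitions", value = .data$n_transitions)
    fam3 <- compare_groups(bind_rows(met_long, trans), "value", "feature",
                           "group", covariate_cols = covariate_cols,
                           test = config$stats$test, family = "state_metrics")
    vb_feats <- vb %>% mutate(feature = .data$component) %>%
      left_join(subjects %>% select("subject_id",
                                    dplyr::any_of(c("age", "gender"))),
                by = "subject_id")
    fam4 <- compare_groups(vb_feats, "V", "feature", "group",
                           covariate_cols = covariate_cols,
                           test = config$stats$test, family = "variability")
    stats_tbl <- bind_rows(fam1, fam2, fam3, fam4) %>%
      select(!dplyr::any_of("percent_change"))
    note(.write_tsv(stats_tbl, file.path(dir, "group_stats.tsv")))

    if (isTRUE(config$stats$clinical_correlations)) {
      if (is.null(clinical)) {
        abort(sprintf("clinical correlations requested but no clinical table at %s",
                      file.path(dir, "clinical.tsv")))
      }
      pre <- clinical %>% filter(.data$timepoint == "pre",
                                 .data$group == "patient")
      dwell <- metrics %>% filter(.data$group == "patient") %>%
        select("subject_id", "state", "mean_dwell_time") %>%
        tidyr::pivot_wider(names_from = "state",
                           values_from = "mean_dwell_time",
                           names_prefix = "dwell_state")
      feats <- left_join(pre, dwell, by = "subject_id")
      corr_rows <- list()
      for (sc in intersect(c("MMSE", "TUG", "iNPHGS_total"), names(feats))) {
        for (fv in grep("^dwell_state", names(feats), value = TRUE)) {
          if (sd(feats[[fv]]) == 0 || sd(feats[[sc]]) == 0) next
          corr_rows[[length(corr_rows) + 1]] <-
            correlate(feats[[fv]], feats[[sc]],
                      feature = paste(fv, sc, sep = "~"))
        }
      }
      if (length(corr_rows)) {
        corr_tbl <- bind_rows(corr_rows)
        corr_tbl$q_value <- bh_fdr(corr_tbl$p_value)
        note(.write_tsv(corr_tbl, file.path(dir, "clinical_correlations.tsv")))
      }
    }
  }

  # --- report --------------------------------------------------------------
  manifest <- tibble(file = basename(files),
                     md5 = unname(tools::md5sum(files)))
  report <- list(
    parameters = config[c("cohort", "dfnc", "states", "stats")],
    chosen_k = chosen_k,
    n_subjects = nrow(subjects),
    warnings = warnings,
    manifest = manifest
  )
  yaml::write_yaml(list(
    parameters = report$parameters, chosen_k = chosen_k,
    n_subjects = report$n_subjects, warnings = warnings,
    manifest = lapply(seq_len(nrow(manifest)), function(i) {
      list(file = manifest$file[i], md5 = manifest$md5[i])
    })
  ), file.path(dir, "run_report.yaml"))
  invisible(report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
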