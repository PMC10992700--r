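#' Pipeline configuration
#'
#' All knobs of the end-to-end analysis in one validated list: the cohort
#' spec used by the `simulate` stage, clustering parameters, marker-cutoff
#' overrides, and the maintenance-duration stratification toggle. A config
#' plus an input tree fully determines every artifact.
#'
#' @param n_patients,class_probs,seed Passed to [cohort_spec()] for the
#'   `simulate` stage; `seed` also drives the clustering initialisation.
#' @param k,max_iter Clustering parameters, see [shape_kmeans()].
#' @param cutoffs A [marker_cutoffs()] (use pinned values for
#'   replication-style runs).
#' @param stratify_by_maintenance Also refit the clustering within
#'   omalizumab maintenance-duration strata (<1 year vs >= 1 year)?
#' @param dose_params,omalizumab_params,lab_params,dropout_hazard Optional
#'   generator overrides, see [cohort_spec()].
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(n_patients = 300L,
                            class_probs = c(0.41, 0.37, 0.22),
                            seed = 1L,
                            k = 3L,
                            max_iter = 50L,
                            cutoffs = marker_cutoffs(),
                            stratify_by_maintenance = FALSE,
                            dose_params = default_dose_params(),
                            omalizumab_params = default_omalizumab_params(),
                            lab_params = default_lab_params(),
                            dropout_hazard = 0.02) {
  structure(
    list(n_patients = as.integer(n_patients), class_probs = class_probs,
         seed = as.integer(seed), k = as.integer(k),
         max_iter = as.integer(max_iter), cutoffs = cutoffs,
         stratify_by_maintenance = isTRUE(stratify_by_maintenance),
         dose_params = dose_params, omalizumab_params = omalizumab_params,
         lab_params = lab_params, dropout_hazard = dropout_hazard),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from a YAML file
#'
#' Recognised top-level keys mirror the arguments of [pipeline_config()]
#' (`n_patients`, `class_probs`, `seed`, `k`, `max_iter`,
#' `stratify_by_maintenance`, and a `cutoffs` mapping of pinned cutoff
#' values). Unspecified keys keep their defaults.
#'
#' @param path Path to a YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cutoffs <- do.call(marker_cutoffs, raw$cutoffs %||% list())
  args <- raw[intersect(names(raw),
                        c("n_patients", "class_probs", "seed", "k",
                          "max_iter", "stratify_by_maintenance",
                          "dropout_hazard"))]
  args$cutoffs <- cutoffs
  do.call(pipeline_config, args)
}

#' Run the analysis pipeline
#'
#' Orchestrates the stages end to end, writing plain-text artifacts under
#' `out_dir` plus a run manifest (`manifest.json` with the config hash,
#' seed, package version and per-stage record counts). Re-running with an
#' identical config reproduces byte-identical artifacts.
#'
#' Stages and their artifacts:
#' * `simulate` — `events.csv`, `labs.csv`, `latent.csv`;
#' * `score` — `scores.csv` (medication-score series);
#' * `classify` — `trajectories.csv`, `trajectories_wide.csv`,
#'   `responders.csv`;
#' * `cluster` — `clusters.csv`, `cluster_centers.csv`,
#'   `cluster_curves.csv` (and per-stratum versions when stratified);
#' * `survfit` — `survival.csv`, `logrank.json`;
#' * `predict` — `markers.csv`, `predictors.csv`, `kappa.json`,
#'   `crosstab.csv`;
#' * `report` — `report.json` summarising cluster sizes, cumulative
#'   response at 3/6/9 months, agreement and the OR table;
#' * `all` — chains every stage.
#'
#' Non-`simulate` stages read their inputs from `out_dir`, so each stage
#' requires its upstream artifacts; a missing one raises an error naming
#' the required file.
#'
#' @param command One of `"simulate"`, `"score"`, `"classify"`,
#'   `"cluster"`, `"survfit"`, `"predict"`, `"report"`, `"all"`.
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if absent).
#' @return `out_dir`, invisibly.
#' @export
#' @examples
#' \donttest{
#' out <- file.path(tempdir(), "omatraj-demo")
#' run_pipeline("all", pipeline_config(n_patients = 40, seed = 7), out)
#' list.files(out)
#' }
run_pipeline <- function(command, config, out_dir) {
  command <- match.arg(command,
                       c("all", "simulate", "score", "classify", "cluster",
                         "survfit", "predict", "report"))
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- if (command == "all") {
    c("simulate", "score", "classify", "cluster", "survfit", "predict",
      "report")
  } else {
    command
  }
  counts <- list()
  for (st in stages) {
    counts[[st]] <- switch(st,
      simulate = stage_simulate(config, out_dir),
      score = stage_score(config, out_dir),
      classify = stage_classify(config, out_dir),
      cluster = stage_cluster(config, out_dir),
      survfit = stage_survfit(config, out_dir),
      predict = stage_predict(config, out_dir),
      report = stage_report(config, out_dir)
    )
  }
  manifest <- list(
    config_hash = rlang::hash(unclass(config)),
    seed = config$seed,
    package = "omatraj",
    version = as.character(utils::packageVersion("omatraj")),
    stages = counts
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

require_artifact <- function(out_dir, file, stage) {
  path <- file.path(out_dir, file)
  if (!file.exists(path)) {
    stop("stage '", stage, "' requires the upstream artifact '", file,
         "' in ", out_dir, "; run the producing stage first.", call. = FALSE)
  }
  path
}

read_events_artifact <- function(out_dir, stage) {
  path <- require_artifact(out_dir, "events.csv", stage)
  events <- readr::read_csv(path, col_types = readr::cols(
    patient_id = readr::col_character(),
    drug_class = readr::col_character(),
    dose_mg_per_day = readr::col_double(),
    start_day = readr::col_integer(),
    duration_days = readr::col_integer()
  ))
  validate_events_file(events, path)
  events
}

stage_simulate <- function(config, out_dir) {
  spec <- cohort_spec(
    n_patients = config$n_patients, class_probs = config$class_probs,
    seed = config$seed, dropout_hazard = config$dropout_hazard,
    dose_params = config$dose_params,
    omalizumab_params = config$omalizumab_params,
    lab_params = config$lab_params
  )
  cohort <- generate_cohort(spec)
  write_cohort(cohort, out_dir)
  list(patients = nrow(cohort$latent), events = nrow(cohort$events))
}

stage_score <- function(config, out_dir) {
  events <- read_events_artifact(out_dir, "score")
  scores <- score_series(events)
  readr::write_csv(scores, file.path(out_dir, "scores.csv"))
  list(rows = nrow(scores))
}

stage_classify <- function(config, out_dir) {
  events <- read_events_artifact(out_dir, "classify")
  traj <- response_trajectories(events)
  readr::write_csv(traj, file.path(out_dir, "trajectories.csv"))
  readr::write_csv(trajectories_wide(traj),
                   file.path(out_dir, "trajectories_wide.csv"))
  readr::write_csv(responder_groups(traj),
                   file.path(out_dir, "responders.csv"))
  list(rows = nrow(traj))
}

read_trajectories_artifact <- function(out_dir, stage) {
  path <- require_artifact(out_dir, "trajectories.csv", stage)
  readr::read_csv(path, col_types = readr::cols(
    patient_id = readr::col_character(),
    month = readr::col_integer(),
    category = readr::col_character(),
    code = readr::col_integer()
  ))
}

stage_cluster <- function(config, out_dir) {
  traj <- read_trajectories_artifact(out_dir, "cluster")
  fit <- shape_kmeans(traj, k = config$k, seed = config$seed,
                      max_iter = config$max_iter)
  readr::write_csv(fit$assignments, file.path(out_dir, "clusters.csv"))
  readr::write_csv(fit$centers, file.path(out_dir, "cluster_centers.csv"))
  readr::write_csv(cluster_mean_curves(fit, traj),
                   file.path(out_dir, "cluster_curves.csv"))
  if (config$stratify_by_maintenance) {
    events <- read_events_artifact(out_dir, "cluster")
    strata <- maintenance_strata(events)
    fits <- stratify_and_refit(traj, strata, k = config$k,
                               seed = config$seed,
                               max_iter = config$max_iter)
    strat_assign <- purrr::imap_dfr(fits, function(f, s) {
      dplyr::mutate(f$assignments, stratum = s)
    })
    readr::write_csv(strat_assign,
                     file.path(out_dir, "clusters_by_maintenance.csv"))
  }
  list(patients = nrow(fit$assignments), objective = fit$objective)
}

stage_survfit <- function(config, out_dir) {
  traj <- read_trajectories_artifact(out_dir, "survfit")
  require_artifact(out_dir, "clusters.csv", "survfit")
  clusters <- readr::read_csv(
    file.path(out_dir, "clusters.csv"),
    col_types = readr::cols(patient_id = readr::col_character(),
                            cluster = readr::col_integer())
  )
  records <- first_complete_response(traj)
  km <- km_curve(records)
  readr::write_csv(tibble::as_tibble(km), file.path(out_dir, "survival.csv"))
  merged <- dplyr::inner_join(records, clusters, by = "patient_id")
  lr <- if (length(unique(merged$cluster)) >= 2L) {
    log_rank(merged, merged$cluster)
  } else {
    tibble::tibble(statistic = NA_real_, df = NA_integer_,
                   p_value = NA_real_)
  }
  jsonlite::write_json(as.list(lr), file.path(out_dir, "logrank.json"),
                       auto_unbox = TRUE, digits = NA)
  list(patients = nrow(records))
}

stage_predict <- function(config, out_dir) {
  labs <- read_cohort_artifact_labs(out_dir)
  events <- read_events_artifact(out_dir, "predict")
  responders <- readr::read_csv(
    require_artifact(out_dir, "responders.csv", "predict"),
    col_types = readr::cols(patient_id = readr::col_character(),
                            group = readr::col_character(),
                            first_cr_month = readr::col_integer())
  )
  clusters <- readr::read_csv(
    require_artifact(out_dir, "clusters.csv", "predict"),
    col_types = readr::cols(patient_id = readr::col_character(),
                            cluster = readr::col_integer())
  )

  markers <- derive_markers(labs, config$cutoffs) |>
    dplyr::left_join(om_start_flags(events), by = "patient_id") |>
    dplyr::left_join(responders, by = "patient_id")
  readr::write_csv(dplyr::select(markers, -"first_cr_month"),
                   file.path(out_dir, "markers.csv"))

  covs <- c("age_years", "om_start_300", "ige_low", "ige_high", "c4_high",
            "baso_high", "siri_high", "plr_high")
  models <- list()
  md <- dplyr::mutate(markers, nonresponder = .data$group == "NONRESPONDER")
  models$nonresponder <- try_fit(md, "nonresponder", covs)
  resp <- dplyr::filter(md, .data$group != "NONRESPONDER") |>
    dplyr::mutate(early = .data$group == "EARLY")
  models$early <- try_fit(resp, "early", covs)
  models <- models[!vapply(models, is.null, logical(1))]
  readr::write_csv(forest_table(models), file.path(out_dir, "predictors.csv"))

  # cluster (1~EARLY, 2~LATE, 3~NONRESPONDER) vs timing-group agreement
  joined <- dplyr::inner_join(clusters, responders, by = "patient_id")
  map <- c("EARLY", "LATE", "NONRESPONDER")
  kap <- if (nrow(joined) > 0L && max(joined$cluster) <= 3L) {
    fleiss_kappa(rating_matrix(map[joined$cluster], joined$group,
                               categories = map))
  } else {
    list(kappa = NA_real_, degenerate = TRUE)
  }
  jsonlite::write_json(kap, file.path(out_dir, "kappa.json"),
                       auto_unbox = TRUE, digits = NA)
  readr::write_csv(crosstab(clusters, responders),
                   file.path(out_dir, "crosstab.csv"))
  list(patients = nrow(markers), models = length(models))
}

# a degenerate covariate set (e.g. tiny demo cohorts) must not abort the
# pipeline; the failure is recorded in the manifest instead
try_fit <- function(data, outcome, covs) {
  usable <- covs[vapply(covs, function(v) {
    x <- data[[v]][!is.na(data[[v]])]
    length(unique(x)) > 1L
  }, logical(1))]
  if (length(usable) == 0L || length(unique(data[[outcome]])) < 2L) {
    return(NULL)
  }
  tryCatch(fit_logit(data, outcome, usable, model_name = outcome),
           error = function(e) NULL)
}

read_cohort_artifact_labs <- function(out_dir) {
  path <- require_artifact(out_dir, "labs.csv", "predict")
  readr::read_csv(path, col_types = readr::cols(
    patient_id = readr::col_character(),
    sex = readr::col_character(),
    .default = readr::col_double()
  ))
}

stage_report <- function(config, out_dir) {
  traj <- read_trajectories_artifact(out_dir, "report")
  clusters <- readr::read_csv(
    require_artifact(out_dir, "clusters.csv", "report"),
    col_types = readr::cols(patient_id = readr::col_character(),
                            cluster = readr::col_integer())
  )
  kappa <- jsonlite::read_json(require_artifact(out_dir, "kappa.json",
                                                "report"))
  predictors <- readr::read_csv(
    require_artifact(out_dir, "predictors.csv", "report"),
    col_types = readr::cols(.default = readr::col_guess())
  )
  responders <- readr::read_csv(
    require_artifact(out_dir, "responders.csv", "report"),
    col_types = readr::cols(patient_id = readr::col_character(),
                            group = readr::col_character(),
                            first_cr_month = readr::col_integer())
  )
  cum <- cumulative_response_rate(traj, months = c(3L, 6L, 9L))
  report <- list(
    n_patients = length(unique(traj$patient_id)),
    cluster_sizes = as.list(table(clusters$cluster)),
    responder_groups = as.list(table(responders$group)),
    cumulative_response = setNames(as.list(cum$rate),
                                   paste0("month_", cum$month)),
    fleiss_kappa = kappa$kappa,
    predictors = predictors
  )
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  list(written = 1L)
}
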