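#' Pipeline run configuration
#'
#' One object drives the whole analysis: simulate (or read) a cohort,
#' preprocess it into percent-reduction trajectories, cluster with the
#' multi-restart k-means engine scanned over a k range, and compare the
#' trajectory classification with the 50%-reduction threshold rule. Defaults
#' follow the study settings: k scanned over 2..6 with 20 restarts, 50%
#' inclusive cutoff, and the 1:1:1:1:1:1/2:1/2 arm weights inside the cohort
#' block.
#'
#' @param cohort A [cohort_config()] used when `input_csv` is `NULL`.
#' @param input_csv Optional path to an existing wide-format cohort CSV; when
#'   given, simulation is skipped.
#' @param winsorize,quantile_type,n_imputations,n_iterations Preprocessing
#'   options (see [preprocess_panss()]).
#' @param k_range,n_restarts Clustering options (see [select_k()]).
#' @param cutoff,strict,typical_arm_set Comparison options (see
#'   [compare_responses()]).
#' @param first_episode_only Restrict the analysis to first-episode patients?
#' @param arm_filter Optional single arm name: run the pipeline on that arm
#'   only (per-drug trajectory fit).
#' @param seed Master seed; stage seeds are derived from it and recorded in
#'   the provenance block.
#' @return A validated `run_config` list.
#' @export
run_config <- function(cohort = cohort_config(),
                       input_csv = NULL,
                       winsorize = TRUE, quantile_type = 7,
                       n_imputations = 5L, n_iterations = 20L,
                       k_range = 2:6, n_restarts = 20L,
                       cutoff = 50, strict = FALSE,
                       typical_arm_set = typical_arms(),
                       first_episode_only = FALSE,
                       arm_filter = NULL,
                       seed = 1L) {
  cfg <- list(cohort = cohort, input_csv = input_csv,
              winsorize = winsorize, quantile_type = quantile_type,
              n_imputations = as.integer(n_imputations),
              n_iterations = as.integer(n_iterations),
              k_range = as.integer(k_range), n_restarts = as.integer(n_restarts),
              cutoff = cutoff, strict = strict,
              typical_arm_set = typical_arm_set,
              first_episode_only = first_episode_only,
              arm_filter = arm_filter,
              seed = as.integer(seed))
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from YAML
#'
#' Fields mirror the arguments of [run_config()]; the `cohort:` block maps
#' onto [cohort_config()]. Missing fields take the defaults.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cohort_args <- raw$cohort %||% list()
  if (!is.null(cohort_args$class_proportions)) {
    cohort_args$class_proportions <- unlist(cohort_args$class_proportions)
  }
  if (!is.null(cohort_args$class_mean_curves)) {
    cohort_args$class_mean_curves <- lapply(cohort_args$class_mean_curves, unlist)
  }
  args <- raw[setdiff(names(raw), "cohort")]
  args$cohort <- do.call(cohort_config, cohort_args)
  do.call(run_config, args)
}

stage_seeds <- function(seed) {
  # fixed offsets keep every derived seed well below .Machine$integer.max
  list(simulate = seed, preprocess = seed + 10000L, cluster = seed + 20000L)
}

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = 10, pretty = TRUE,
                       na = "null")
}

#' Simulate a cohort and write it to disk
#'
#' Stage wrapper over [generate_cohort()] + [write_cohort()]; also emits a
#' provenance JSON recording the full configuration and seed so a re-run
#' reproduces the file byte for byte.
#'
#' @param config A `run_config`.
#' @param out_dir Output directory (created if needed).
#' @return Path of the cohort CSV, invisibly.
#' @export
run_simulate <- function(config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seeds <- stage_seeds(config$seed)
  cohort_cfg <- config$cohort
  cohort_cfg$seed <- seeds$simulate
  records <- generate_cohort(cohort_cfg)
  path <- file.path(out_dir, "cohort.csv")
  write_cohort(records, path, include_latent = FALSE)
  write_json_file(list(stage = "simulate", seed = seeds$simulate,
                       config = unclass(cohort_cfg),
                       n_patients = nrow(records)),
                  file.path(out_dir, "provenance_simulate.json"))
  invisible(path)
}

#' Run the full trajectory-analysis pipeline
#'
#' Executes simulate (or read) -> preprocess -> cluster -> compare and writes
#' the complete artifact bundle to `out_dir`: `cohort.csv`,
#' `trajectories.csv`, `model.json` (selected k, centroids, CH per k, restart
#' objectives, seeds), `assignments.csv` (patient, cluster, label),
#' `comparison.json` (all tables and tests with the decisions in force),
#' `report.md`, and one provenance JSON per stage. Outputs are a
#' deterministic function of the configuration: re-running the same config
#' reproduces every file byte-identically.
#'
#' @param config A `run_config`.
#' @param out_dir Output directory.
#' @return The bundle (list with `records`, `prep`, `selection`, `comparison`,
#'   `paths`), invisibly classed `trajresp_bundle`.
#' @export
run_pipeline <- function(config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seeds <- stage_seeds(config$seed)

  if (is.null(config$input_csv)) {
    cohort_cfg <- config$cohort
    cohort_cfg$seed <- seeds$simulate
    records <- generate_cohort(cohort_cfg)
    write_cohort(records, file.path(out_dir, "cohort.csv"), include_latent = FALSE)
    write_json_file(list(stage = "simulate", seed = seeds$simulate,
                         config = unclass(cohort_cfg)),
                    file.path(out_dir, "provenance_simulate.json"))
  } else {
    records <- read_cohort(config$input_csv)
  }

  if (isTRUE(config$first_episode_only)) {
    records <- dplyr::filter(records, .data$first_episode)
  }
  if (!is.null(config$arm_filter)) {
    records <- dplyr::filter(records, .data$arm %in% config$arm_filter)
  }
  if (nrow(records) == 0) {
    rlang::abort("stage `preprocess` failed: no records left after subset filters.",
                 class = "trajresp_stage_error")
  }

  prep <- preprocess_panss(records, winsorize = config$winsorize,
                           n_imputations = config$n_imputations,
                           n_iterations = config$n_iterations,
                           seed = seeds$preprocess,
                           quantile_type = config$quantile_type)
  readr::write_csv(prep$trajectories, file.path(out_dir, "trajectories.csv"))
  write_json_file(list(stage = "preprocess", seed = seeds$preprocess,
                       n_winsorized = sum(prep$audit$winsorized$n_winsorized),
                       n_imputed = sum(prep$audit$imputed_cells$n_imputed),
                       n_dropped_floor_baseline = prep$audit$n_dropped_floor_baseline),
                  file.path(out_dir, "provenance_preprocess.json"))

  selection <- cluster_trajectories(prep$trajectories,
                                    k_range = config$k_range,
                                    n_restarts = config$n_restarts,
                                    seed = seeds$cluster)
  model_json <- list(
    stage = "cluster", seed = seeds$cluster,
    selected_k = selection$selected_k,
    criteria = selection$criteria,
    centroids = as.data.frame(selection$best$centroids),
    restart_objectives = selection$best$restart_objectives
  )
  write_json_file(model_json, file.path(out_dir, "model.json"))
  readr::write_csv(selection$assignments, file.path(out_dir, "assignments.csv"))

  analysis <- selection$assignments |>
    dplyr::left_join(prep$trajectories, by = "patient_id") |>
    dplyr::left_join(dplyr::select(records, dplyr::any_of(
      c("patient_id", "arm", "first_episode"))), by = "patient_id")
  comparison <- compare_responses(analysis, cutoff = config$cutoff,
                                  strict = config$strict,
                                  typical_arm_set = config$typical_arm_set)
  comp_json <- list(
    stage = "compare",
    decisions = comparison$decisions,
    n = comparison$n,
    pct_high = comparison$pct_high,
    pct_responder = comparison$pct_responder,
    discordant = comparison$discordant,
    paired_counts = as.data.frame(comparison$paired$counts),
    composition_counts = as.data.frame(comparison$composition$counts),
    tests = tidy(comparison)
  )
  write_json_file(comp_json, file.path(out_dir, "comparison.json"))

  bundle <- structure(list(
    config = config, records = records, prep = prep,
    selection = selection, comparison = comparison,
    paths = list(out_dir = out_dir)
  ), class = "trajresp_bundle")

  writeLines(render_report(bundle), file.path(out_dir, "report.md"))
  invisible(bundle)
}

#' Render a human-readable pipeline report
#'
#' Markdown summary of a bundle: cluster sizes and percentages, mean percent
#' reduction per trajectory per week, discordance bookkeeping, and every test
#' with the decisions in force. Deterministic given the bundle.
#'
#' @param bundle Result of [run_pipeline()].
#' @return Character vector of markdown lines.
#' @export
render_report <- function(bundle) {
  sel <- bundle$selection
  cmp <- bundle$comparison
  if (is.null(sel) || is.null(cmp)) {
    rlang::abort("incomplete bundle: clustering and comparison stages are required.",
                 class = "trajresp_stage_error")
  }
  cl <- tidy(sel$best)
  n <- sum(cl$size)
  lines <- c(
    "# Treatment-response trajectory report",
    "",
    sprintf("Patients analysed: %d. Selected number of trajectories: k = %d (Calinski-Harabasz).",
            n, sel$selected_k),
    "",
    "## Trajectory clusters",
    "",
    "| cluster | label | n | % | mean pct w2 | mean pct w4 | mean pct w6 |",
    "|---|---|---|---|---|---|---|",
    sprintf("| %d | %s | %d | %.2f | %.2f | %.2f | %.2f |",
            cl$cluster, cl$label, cl$size, 100 * cl$size / n,
            cl$pct_w2, cl$pct_w4, cl$pct_w6),
    "",
    "## Trajectory vs threshold classification",
    "",
    sprintf("Threshold rule: responder iff week-6 percent reduction %s %g%%.",
            if (cmp$decisions$boundary == "strict (>)") ">" else ">=",
            cmp$decisions$cutoff),
    sprintf("High-trajectory: %.2f%% of patients; threshold responders: %.2f%%.",
            cmp$pct_high, cmp$pct_responder),
    sprintf("Discordantly classified patients: %d.", cmp$discordant),
    sprintf("Composition chi-squared = %.2f (df %d, p = %.3g); McNemar on discordant cells = %.2f (p = %.3g).",
            cmp$composition_test$statistic, cmp$composition_test$df,
            cmp$composition_test$p_value, cmp$mcnemar$statistic,
            cmp$mcnemar$p_value)
  )
  if (!is.null(cmp$arms)) {
    omni <- cmp$arms$omnibus
    top <- dplyr::arrange(cmp$arms$pairwise, .data$adjusted_p) |> utils::head(3)
    lines <- c(lines, "",
      "## Per-arm comparison",
      "",
      sprintf("Omnibus %s on arm x %s: statistic = %s, p = %.3g.",
              omni$method, omni$table,
              ifelse(is.na(omni$statistic), "-", sprintf("%.2f", omni$statistic)),
              omni$p_value),
      "",
      "Smallest BH-adjusted pairwise p-values:",
      sprintf("- %s vs %s: p_adj = %.3g", top$arm1, top$arm2, top$adjusted_p))
  }
  if (!is.null(cmp$episode)) {
    et <- cmp$episode$tests
    lines <- c(lines, "",
      "## First-episode vs relapse (by drug class)",
      "",
      sprintf("- %s arms: %s statistic = %s, p = %.3g",
              et$stratum, et$method,
              ifelse(is.na(et$statistic), "-", sprintf("%.2f", et$statistic)),
              et$p_value))
  }
  lines
}

#' @export
print.trajresp_bundle <- function(x, ...) {
  cat("<trajresp_bundle> written to", x$paths$out_dir, "\n")
  print(x$selection)
  print(x$comparison)
  invisible(x)
}
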