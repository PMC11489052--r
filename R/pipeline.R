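#' Default pipeline configuration
#'
#' Returns the full configuration list with documented defaults; any subset
#' can be overridden via `...` (or by passing a YAML file to
#' [run_pipeline()]). Numeric simulation parameters follow the standard
#' operating point (100 steps, 1000 repetitions).
#'
#' @param ... Named overrides merged over the defaults (nested lists are
#'   merged shallowly per top-level key).
#' @return Named list.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    seed = 1L,
    model_kind = "prkn_shape",      # gen_toy_network() kind ...
    model_path = NULL,              # ... or a .bnet / SBML-qual file
    scenario = list(),              # synthetic_scenario() overrides
    comorbidity_label = "T2DM",
    n_steps = 100L,
    n_reps = 1000L,
    n_stages = 3L,
    reference = "baseline",         # DTW comparator ("pairwise" allowed)
    correlation_threshold = 0.98,
    fdr_level = 0.05,
    cl_variant = "two_group",
    invert_repression = FALSE,
    default_p = 0.5,
    combine = "mean",
    max_breaks = 3L
  )
  overrides <- list(...)
  for (nm in names(overrides)) defaults[[nm]] <- overrides[[nm]]
  defaults
}

load_pipeline_model <- function(config) {
  if (!is.null(config$model_path)) {
    path <- config$model_path
    if (grepl("\\.(sbml|xml)$", path, ignore.case = TRUE)) {
      return(parse_sbml_qual(path))
    }
    return(read_bnet(path))
  }
  gen_toy_network(config$model_kind)
}

pipeline_gene_sets <- function(net, universe) {
  term <- identify_terminals(net)
  internal <- setdiff(net$nodes, c(term$inputs, term$outputs))
  sets <- list(model_inputs = term$inputs, model_nodes = net$nodes)
  if (length(internal) > 0L) sets$model_internal <- internal
  lapply(sets, intersect, y = universe)
}

#' Run the cohort-stratification pipeline end-to-end
#'
#' Orchestrates the full analysis: synthetic cohort generation (or
#' file-based inputs), per-cohort differential-expression and effect-size
#' statistics, evidence/tissue target filtering, literature-direction
#' screening, over-representation analysis, parameterization of the Boolean
#' model (cohort initial states; comorbidity point mutations), probabilistic
#' asynchronous simulation of every condition plus an unparameterized
#' baseline, staged DTW scoring against the comparator, Pearson correlation
#' of DTW profiles between condition pairs, and change-point detection on
#' endpoint trajectories. All randomness derives from `config$seed`;
#' re-running with the same configuration reproduces byte-identical outputs.
#'
#' @param config A [pipeline_config()] list or path to a YAML file with the
#'   same keys.
#' @param outdir Output directory (created if absent). When `NULL`, nothing
#'   is written and the results are only returned.
#' @return Invisibly, a `pipeline_result` list: `config`, `network`,
#'   `profiles`, `targets`, `literature_screen`, `enrichment`, `conditions`,
#'   `trajectories`, `dtw`, `correlations`, `change_points`, `manifest`
#'   (tibble when `outdir` given).
#' @export
run_pipeline <- function(config = pipeline_config(), outdir = NULL) {
  if (is.character(config) && length(config) == 1L) {
    config <- do.call(pipeline_config, yaml::read_yaml(config))
  }
  net <- load_pipeline_model(config)
  if (!is.null(config$scenario$cohort_sizes)) {
    # YAML maps arrive as named lists; the scenario wants a named vector
    config$scenario$cohort_sizes <- unlist(config$scenario$cohort_sizes)
  }
  scenario <- do.call(synthetic_scenario,
                      c(list(seed = config$seed), config$scenario))
  mats <- gen_counts(scenario)
  tables <- gen_interactions(scenario)
  degs <- gen_deg_table(scenario)
  forced <- deg_to_forced(net, degs)
  universe <- unique(c(scenario$genes, net$nodes))

  profiles <- list(); targets <- list(); screens <- list()
  enrichment <- list(); conditions <- list()
  for (cohort in names(mats)) {
    profile <- cohort_profile(mats[[cohort]], cl_variant = config$cl_variant)
    screen <- match_literature_direction(profile, tables$literature)
    de <- screen |>
      dplyr::filter(!is.na(.data$q_value),
                    .data$q_value <= config$fdr_level,
                    !.data$degenerate, !.data$excluded)
    filt <- filter_mirna_targets(tables$primary, tables$secondary,
                                 tables$tissue_genes, de$mirna)
    tgt <- profile_targets(profile, filt)
    enr <- enrich_hypergeometric(unique(tgt$gene),
                                 pipeline_gene_sets(net, universe), universe)
    spec <- build_initial_spec(net, tgt, default_p = config$default_p,
                               invert_repression = config$invert_repression,
                               combine = config$combine)
    profiles[[cohort]] <- profile
    targets[[cohort]] <- tgt
    screens[[cohort]] <- screen
    enrichment[[cohort]] <- enr
    conditions[[cohort]] <- merge_parameterizations(spec, NULL, cohort)
    comorbid <- merge_parameterizations(spec, forced, cohort,
                                        config$comorbidity_label)
    conditions[[paste(cohort, config$comorbidity_label, sep = "+")]] <-
      comorbid
  }
  conditions[["baseline"]] <- merge_parameterizations(
    initial_state_spec(default_probability = 0.5), NULL, "baseline")

  trajectories <- purrr::imap(conditions, function(cond, nm) {
    simulate_condition(net, cond, n_steps = config$n_steps,
                       n_reps = config$n_reps,
                       seed = derive_seed(config$seed, paste0("sim_", nm)))
  })

  endpoints <- identify_terminals(net)$outputs
  dtw_tab <- stage_dtw_table(trajectories, reference = config$reference,
                             endpoints = endpoints,
                             n_stages = config$n_stages)
  correlations <- if (identical(config$reference, "pairwise")) NULL else
    dtw_correlation_table(dtw_tab, threshold = config$correlation_threshold)

  change_points <- purrr::imap_dfr(trajectories, function(tr, nm) {
    purrr::map_dfr(endpoints, function(e) {
      fit <- detect_change_points(tr$prob[, e],
                                  max_breaks = config$max_breaks)
      tibble::tibble(condition = nm, endpoint = e,
                     n_breaks = fit$n_breaks,
                     breakpoints = paste(fit$breakpoints, collapse = ","),
                     rss = fit$rss, bic = fit$bic)
    })
  })

  result <- structure(
    list(config = config, network = net, profiles = profiles,
         targets = targets, literature_screen = screens,
         enrichment = enrichment, conditions = conditions,
         trajectories = trajectories, dtw = dtw_tab,
         correlations = correlations, change_points = change_points,
         manifest = NULL),
    class = "pipeline_result"
  )
  if (!is.null(outdir)) {
    result$manifest <- write_pipeline_outputs(result, outdir)
  }
  invisible(result)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result: ", length(x$profiles), " cohort(s), ",
      length(x$conditions), " simulated condition(s), ",
      nrow(x$dtw), " DTW rows>\n", sep = "")
  invisible(x)
}

write_pipeline_outputs <- function(result, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  save_tsv <- function(tab, name) {
    p <- file.path(outdir, name)
    readr::write_tsv(tibble::as_tibble(tab), p)
    paths <<- c(paths, p)
  }
  for (cohort in names(result$profiles)) {
    save_tsv(result$profiles[[cohort]],
             sprintf("profile_%s.tsv", cohort))
    save_tsv(result$targets[[cohort]], sprintf("targets_%s.tsv", cohort))
    save_tsv(result$enrichment[[cohort]],
             sprintf("enrichment_%s.tsv", cohort))
  }
  for (nm in names(result$conditions)) {
    cond <- result$conditions[[nm]]
    safe <- gsub("[^A-Za-z0-9_.-]", "_", nm)
    save_tsv(tibble::tibble(node = names(cond$spec$probabilities),
                            probability = unname(cond$spec$probabilities)),
             sprintf("init_%s.tsv", safe))
    save_tsv(tibble::tibble(node = names(cond$forced$forced),
                            value = unname(cond$forced$forced)),
             sprintf("forced_%s.tsv", safe))
    p <- file.path(outdir, sprintf("trajectory_%s.tsv", safe))
    write_trajectory_tsv(result$trajectories[[nm]], p)
    paths <- c(paths, p)
  }
  save_tsv(result$dtw, "dtw_stage_table.tsv")
  if (!is.null(result$correlations)) {
    save_tsv(result$correlations, "dtw_correlations.tsv")
  }
  save_tsv(result$change_points, "change_points.tsv")

  report <- c(
    "# Pipeline report",
    "",
    sprintf("- model: %s (%d nodes)",
            result$network$metadata$name %||% "custom",
            length(result$network$nodes)),
    sprintf("- cohorts: %s", paste(names(result$profiles), collapse = ", ")),
    sprintf("- conditions simulated: %s",
            paste(names(result$conditions), collapse = ", ")),
    sprintf("- steps=%d, repetitions=%d, seed=%d",
            result$config$n_steps, result$config$n_reps,
            result$config$seed),
    sprintf("- DTW reference: %s; stages: %d", result$config$reference,
            result$config$n_stages)
  )
  report_path <- file.path(outdir, "report.md")
  writeLines(report, report_path)
  paths <- c(paths, report_path)

  manifest <- tibble::tibble(
    file = basename(paths),
    md5 = unname(tools::md5sum(paths))
  ) |>
    dplyr::arrange(.data$file)
  manifest_payload <- list(
    parameters = result$config[order(names(result$config))],
    files = manifest
  )
  jsonlite::write_json(manifest_payload,
                       file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest
}
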