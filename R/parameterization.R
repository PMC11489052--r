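#' Join a cohort profile with its filtered target assignments
#'
#' Produces the per-target parameter table (one row per miRNA-gene
#' assignment, carrying that miRNA's effect-size probability), the tabular
#' bridge between the statistics stack and the simulator parameterization.
#' A miRNA's CL is constant across all of its targets.
#'
#' @param profile A [cohort_profile()] tibble.
#' @param assignments Tibble of (`mirna`, `gene`) rows, e.g. from
#'   [filter_mirna_targets()].
#' @return Tibble with `mirna`, `gene`, `cl`, `cohens_d`, `log2fc`,
#'   `q_value` and any evidence columns present in `assignments`.
#' @export
profile_targets <- function(profile, assignments) {
  tibble::as_tibble(assignments) |>
    dplyr::inner_join(
      tibble::as_tibble(profile) |>
        dplyr::select("mirna", "cl", "cohens_d", "log2fc", "q_value"),
      by = "mirna"
    )
}

#' Build simulator initial states from cohort effect sizes
#'
#' Every network node that is the target of at least one profile miRNA
#' receives that miRNA's common-language probability as its ON-probability
#' at step 0 (or `1 - CL` when `invert_repression = TRUE`, the biologically
#' motivated reading of miRNA repression). When several miRNAs target the
#' same node their CLs are combined by `combine` (default mean). All other
#' nodes get `default_p`. Gene identifiers are matched to node identifiers
#' exactly; unmatched genes are reported, not silently dropped.
#'
#' @param net A [boolean_network()].
#' @param targets Tibble with columns `gene` and `cl` (one row per
#'   miRNA-target assignment), e.g. from [profile_targets()].
#' @param default_p ON-probability for untargeted nodes (default 0.5).
#' @param invert_repression Assign `1 - CL` instead of CL (default FALSE).
#' @param combine Multi-miRNA combination rule: `"mean"`, `"max"` or
#'   `"min"`.
#' @return An [initial_state_spec()] with attribute `"mapping"`: a tibble of
#'   distinct target genes and whether each matched a network node.
#' @export
build_initial_spec <- function(net, targets, default_p = 0.5,
                               invert_repression = FALSE,
                               combine = c("mean", "max", "min")) {
  stopifnot(inherits(net, "boolean_network"))
  combine <- match.arg(combine)
  targets <- tibble::as_tibble(targets)
  if (!all(c("gene", "cl") %in% names(targets))) {
    stop("targets needs columns 'gene' and 'cl'", call. = FALSE)
  }
  if (any(!is.finite(targets$cl)) || any(targets$cl < 0 | targets$cl > 1)) {
    stop("CL probabilities must lie in [0, 1]", call. = FALSE)
  }
  mapping <- targets |>
    dplyr::distinct(.data$gene) |>
    dplyr::mutate(matched = .data$gene %in% net$nodes)
  comb_fun <- switch(combine, mean = mean, max = max, min = min)
  node_p <- targets |>
    dplyr::filter(.data$gene %in% net$nodes) |>
    dplyr::mutate(p = if (invert_repression) 1 - .data$cl else .data$cl) |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(p = comb_fun(.data$p), .groups = "drop")
  spec <- initial_state_spec(
    probabilities = stats::setNames(node_p$p, node_p$gene),
    default_probability = default_p
  )
  attr(spec, "mapping") <- mapping
  spec
}

#' Convert a differential-expression gene table into forced nodes
#'
#' Downregulated genes become knockouts (pinned to 0) and upregulated genes
#' become overexpressions (pinned to 1), encoding e.g. a comorbidity
#' transcriptomic profile as permanent point mutations. Genes absent from
#' the network are reported in the `"unmatched"` attribute, not errored.
#'
#' @param net A [boolean_network()].
#' @param degs Tibble with columns `gene` and `direction`
#'   (`"up"`/`"down"`); duplicate genes with conflicting directions raise an
#'   error.
#' @return A [forced_nodes()] object with attribute `"unmatched"` (character
#'   vector of genes not in the network).
#' @export
deg_to_forced <- function(net, degs) {
  stopifnot(inherits(net, "boolean_network"))
  degs <- tibble::as_tibble(degs)
  if (!all(c("gene", "direction") %in% names(degs))) {
    stop("degs needs columns 'gene' and 'direction'", call. = FALSE)
  }
  degs <- degs |> dplyr::mutate(direction = tolower(.data$direction))
  bad <- setdiff(unique(degs$direction), c("up", "down"))
  if (length(bad) > 0L) {
    stop("DEG directions must be 'up'/'down'; found: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  conflict <- degs |>
    dplyr::distinct(.data$gene, .data$direction) |>
    dplyr::count(.data$gene) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(conflict) > 0L) {
    stop("conflicting directions for gene(s): ",
         paste(conflict$gene, collapse = ", "), call. = FALSE)
  }
  degs <- degs |> dplyr::distinct(.data$gene, .data$direction)
  in_net <- degs |> dplyr::filter(.data$gene %in% net$nodes)
  out <- forced_nodes(stats::setNames(
    ifelse(in_net$direction == "up", 1L, 0L), in_net$gene))
  attr(out, "unmatched") <- setdiff(degs$gene, net$nodes)
  out
}

#' Combine a cohort initial-state spec with a forced-node set
#'
#' Bundles the miRNA-derived initial probabilities with comorbidity point
#' mutations into one simulation condition. Forced values take precedence
#' over initial probabilities for overlapping nodes (the forced value is
#' applied after initial-state sampling and the node never updates). The
#' condition carries provenance labels.
#'
#' @param spec An [initial_state_spec()].
#' @param forced A [forced_nodes()] (or NULL).
#' @param cohort,comorbidity Provenance labels; the condition label is
#'   `"cohort"` or `"cohort+comorbidity"`.
#' @return A `simulation_condition` object (list: `spec`, `forced`,
#'   `label`, `cohort`, `comorbidity`).
#' @export
merge_parameterizations <- function(spec, forced = NULL, cohort = NULL,
                                    comorbidity = NULL) {
  spec <- as_init_spec(spec)
  forced <- as_forced(forced)
  label <- paste(c(cohort %||% "condition",
                   if (length(forced$forced) > 0L) comorbidity),
                 collapse = "+")
  structure(
    list(spec = spec, forced = forced, label = label,
         cohort = cohort, comorbidity = comorbidity),
    class = "simulation_condition"
  )
}

#' @export
print.simulation_condition <- function(x, ...) {
  cat("<simulation_condition '", x$label, "': ",
      length(x$spec$probabilities), " parameterized node(s), ",
      length(x$forced$forced), " forced>\n", sep = "")
  invisible(x)
}

#' Simulate a parameterized condition
#'
#' Convenience wrapper running [simulate_ensemble()] with a
#' [merge_parameterizations()] condition, propagating its label.
#'
#' @param net A [boolean_network()].
#' @param condition A `simulation_condition`.
#' @inheritParams simulate_ensemble
#' @return A `trajectory_ensemble`.
#' @export
simulate_condition <- function(net, condition, n_steps = 100, n_reps = 1000,
                               seed = 1) {
  stopifnot(inherits(condition, "simulation_condition"))
  simulate_ensemble(net, condition$spec, condition$forced,
                    n_steps = n_steps, n_reps = n_reps, seed = seed,
                    label = condition$label)
}
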