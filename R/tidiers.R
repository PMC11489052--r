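# broom-style views of the package's result objects.

#' Tidy a Boolean network into its signed edge list
#'
#' @param x A [boolean_network()].
#' @param ... Unused.
#' @return Tibble (`source`, `sign`, `target`), as [to_sif()].
#' @method tidy boolean_network
#' @export
tidy.boolean_network <- function(x, ...) to_sif(x)

#' One-row summary of a Boolean network
#'
#' @param x A [boolean_network()].
#' @param ... Unused.
#' @return Tibble: `n_nodes`, `n_edges`, `n_inputs`, `n_outputs`.
#' @method glance boolean_network
#' @export
glance.boolean_network <- function(x, ...) {
  term <- identify_terminals(x)
  tibble::tibble(
    n_nodes = length(x$nodes),
    n_edges = nrow(to_sif(x)),
    n_inputs = length(term$inputs),
    n_outputs = length(term$outputs)
  )
}

#' Tidy a trajectory ensemble into long format
#'
#' @param x A `trajectory_ensemble`.
#' @param ... Unused.
#' @return Tibble (`step`, `node`, `probability`).
#' @method tidy trajectory_ensemble
#' @export
tidy.trajectory_ensemble <- function(x, ...) {
  tibble::tibble(
    step = rep(0:x$steps, times = length(x$nodes)),
    node = rep(x$nodes, each = x$steps + 1L),
    probability = as.vector(x$prob)
  )
}

#' One-row summary of a trajectory ensemble
#'
#' @param x A `trajectory_ensemble`.
#' @param ... Unused.
#' @return Tibble: `label`, `n_nodes`, `steps`, `n_reps`, `seed`,
#'   `n_forced`.
#' @method glance trajectory_ensemble
#' @export
glance.trajectory_ensemble <- function(x, ...) {
  tibble::tibble(
    label = x$label %||% NA_character_,
    n_nodes = length(x$nodes),
    steps = x$steps,
    n_reps = x$n_reps,
    seed = x$seed,
    n_forced = length(x$forced)
  )
}

#' Tidy a change-point fit into its segment table
#'
#' @param x A `change_point_fit`.
#' @param ... Unused.
#' @return Tibble (`segment`, `from`, `to`, `intercept`, `slope`).
#' @method tidy change_point_fit
#' @export
tidy.change_point_fit <- function(x, ...) x$segments

#' One-row summary of a change-point fit
#'
#' @param x A `change_point_fit`.
#' @param ... Unused.
#' @return Tibble: `n_breaks`, `rss`, `bic`.
#' @method glance change_point_fit
#' @export
glance.change_point_fit <- function(x, ...) {
  tibble::tibble(n_breaks = x$n_breaks, rss = x$rss, bic = x$bic)
}

#' Tidy a structural verification report
#'
#' @param x A `structure_verification`.
#' @param ... Unused.
#' @return Long tibble of per-edge findings with a `finding` column
#'   (`matched`, `sign_mismatch`, `network_only`, `reference_only`,
#'   `direction_conflict`).
#' @method tidy structure_verification
#' @export
tidy.structure_verification <- function(x, ...) {
  dplyr::bind_rows(
    x$matched |>
      dplyr::transmute(source = .data$source, target = .data$target,
                       sign = .data$sign_network, finding = "matched"),
    x$sign_mismatch |>
      dplyr::transmute(source = .data$source, target = .data$target,
                       sign = .data$sign_network, finding = "sign_mismatch"),
    x$network_only |>
      dplyr::mutate(finding = "network_only"),
    x$reference_only |>
      dplyr::transmute(source = .data$regulator, target = .data$target,
                       sign = .data$sign, finding = "reference_only"),
    x$direction_conflict |>
      dplyr::transmute(source = .data$regulator, target = .data$target,
                       sign = .data$sign, finding = "direction_conflict")
  )
}

#' One-row summary of a structural verification report
#'
#' @param x A `structure_verification`.
#' @param ... Unused.
#' @return The report's summary tibble.
#' @method glance structure_verification
#' @export
glance.structure_verification <- function(x, ...) x$summary
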