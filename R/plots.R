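# ggplot2 views of the package's result types.

#' Plot estimated ON-probability trajectories
#'
#' One line per node: estimated ON-probability across simulation steps.
#'
#' @param object A `trajectory_ensemble`.
#' @param nodes Optional subset of nodes to draw (default all).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot trajectory_ensemble
#' @export
autoplot.trajectory_ensemble <- function(object, nodes = NULL, ...) {
  long <- tidy(object)
  if (!is.null(nodes)) long <- long |> dplyr::filter(.data$node %in% nodes)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$step, y = .data$probability,
                                     colour = .data$node)) +
    ggplot2::geom_line() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "iteration step", y = "estimated ON-probability",
                  colour = NULL,
                  title = object$label) +
    ggplot2::theme_minimal()
}

#' Plot a staged DTW score table
#'
#' Bars of DTW score per condition, faceted by endpoint and stage; lower
#' bars mean the condition's dynamics track the comparator more closely.
#'
#' @param object A `dtw_stage_table`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot dtw_stage_table
#' @export
autoplot.dtw_stage_table <- function(object, ...) {
  tab <- tibble::as_tibble(object)
  if ("condition2" %in% names(tab)) {
    tab <- tab |>
      dplyr::mutate(condition = paste(.data$condition, .data$condition2,
                                      sep = " vs "))
  }
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$condition, y = .data$dtw,
                                    fill = .data$condition)) +
    ggplot2::geom_col() +
    ggplot2::facet_grid(endpoint ~ stage) +
    ggplot2::labs(x = NULL, y = "DTW score", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' Plot a change-point fit
#'
#' The series with its fitted piecewise-linear segments and dashed vertical
#' lines at the selected breakpoints.
#'
#' @param object A `change_point_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot change_point_fit
#' @export
autoplot.change_point_fit <- function(object, ...) {
  series <- tibble::tibble(index = seq_along(object$series),
                           value = object$series)
  seg_lines <- object$segments |>
    dplyr::rowwise() |>
    dplyr::reframe(index = .data$from:.data$to,
                   fitted = .data$intercept + .data$slope *
                     (.data$from:.data$to),
                   segment = .data$segment)
  p <- ggplot2::ggplot(series, ggplot2::aes(x = .data$index,
                                            y = .data$value)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_line(data = seg_lines,
                       ggplot2::aes(y = .data$fitted,
                                    group = .data$segment),
                       colour = "firebrick") +
    ggplot2::labs(x = "step", y = "value") +
    ggplot2::theme_minimal()
  if (length(object$breakpoints) > 0L) {
    p <- p + ggplot2::geom_vline(xintercept = object$breakpoints,
                                 linetype = "dashed", colour = "grey40")
  }
  p
}

#' Volcano-style plot of a cohort profile
#'
#' log2 fold change against -log10 q-value, colouring miRNAs passing the
#' FDR threshold.
#'
#' @param profile A [cohort_profile()] tibble.
#' @param fdr_level Significance threshold on the q-value (default 0.05).
#' @return A ggplot object.
#' @export
plot_cohort_profile <- function(profile, fdr_level = 0.05) {
  tab <- tibble::as_tibble(profile) |>
    dplyr::filter(!is.na(.data$q_value)) |>
    dplyr::mutate(significant = .data$q_value <= fdr_level)
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$log2fc,
                                    y = -log10(.data$q_value),
                                    colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "log2 fold change (case vs control)",
                  y = expression(-log[10] ~ "q-value"),
                  colour = paste0("FDR ≤ ", fdr_level)) +
    ggplot2::theme_minimal()
}
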