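# Readers/writers for the pipeline's tab-separated interchange formats.

#' Read a miRNA count matrix from TSV
#'
#' First column = miRNA identifier, remaining columns = samples.
#'
#' @param path TSV path.
#' @return Integer matrix with miRNA row names and sample column names.
#' @export
read_counts_matrix <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- as.character(tab[[1]])
  storage.mode(m) <- "integer"
  m
}

#' Read a sample sheet (sample, group, optional pair_id)
#'
#' @param path TSV path.
#' @return Tibble.
#' @export
read_sample_sheet <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(.default = readr::col_character()))
}

#' Read a miRNA-target interaction table
#'
#' Columns: `mirna`, `gene`, `evidence_level`, `n_supporting_studies`,
#' optional `source`, `target_score`.
#'
#' @param path TSV path.
#' @return Tibble.
#' @export
read_interaction_table <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' Read a one-per-line gene list
#'
#' @param path Text path.
#' @return Character vector.
#' @export
read_gene_list <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  x[nzchar(x)]
}

#' Read a literature direction table (`mirna`, `direction`)
#'
#' @param path TSV path.
#' @return Tibble.
#' @export
read_literature_table <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' Read a DEG table (`gene`, `direction`)
#'
#' @param path TSV path.
#' @return Tibble.
#' @export
read_deg_table <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' Write a trajectory ensemble as long-format TSV
#'
#' Columns `step`, `node`, `probability`.
#'
#' @param traj A `trajectory_ensemble`.
#' @param path Output path.
#' @export
write_trajectory_tsv <- function(traj, path) {
  readr::write_tsv(tidy(traj), path)
  invisible(path)
}

#' Read a long-format trajectory TSV back into a matrix form
#'
#' @param path TSV written by [write_trajectory_tsv()].
#' @return A `trajectory_ensemble`-like list with `prob`, `nodes`, `steps`
#'   (repetition count and seed are not stored in the TSV and come back
#'   `NA`).
#' @export
read_trajectory_tsv <- function(path) {
  long <- readr::read_tsv(path, show_col_types = FALSE)
  wide <- long |>
    tidyr::pivot_wider(names_from = "node", values_from = "probability") |>
    dplyr::arrange(.data$step)
  prob <- as.matrix(wide[, -1, drop = FALSE])
  rownames(prob) <- wide$step
  structure(
    list(prob = prob, nodes = colnames(prob), steps = nrow(prob) - 1L,
         n_reps = NA_integer_, seed = NA_integer_, forced = integer(0),
         label = NULL),
    class = "trajectory_ensemble"
  )
}
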