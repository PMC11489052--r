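#' Bundle a two-group miRNA count matrix with sample metadata
#'
#' @param counts Non-negative integer matrix (miRNAs x samples) with row and
#'   column names.
#' @param samples Data frame with columns `sample`, `group` (`"case"` /
#'   `"control"`) and optionally `pair_id` linking each case to its control.
#' @param cohort Optional cohort label.
#' @return An `expression_matrix` object.
#' @export
expression_matrix <- function(counts, samples, cohort = NULL) {
  samples <- tibble::as_tibble(samples)
  if (!all(c("sample", "group") %in% names(samples))) {
    stop("samples needs columns 'sample' and 'group'", call. = FALSE)
  }
  if (is.null(colnames(counts)) || is.null(rownames(counts))) {
    stop("counts must have miRNA row names and sample column names",
         call. = FALSE)
  }
  if (!setequal(colnames(counts), samples$sample)) {
    stop("every count column must be labeled in samples (and vice versa)",
         call. = FALSE)
  }
  bad <- setdiff(unique(samples$group), c("case", "control"))
  if (length(bad) > 0L) {
    stop("sample groups must be 'case'/'control'; found: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if ("pair_id" %in% names(samples)) {
    pairs <- samples |>
      dplyr::filter(!is.na(.data$pair_id)) |>
      dplyr::count(.data$pair_id, .data$group)
    ok <- pairs |>
      tidyr::pivot_wider(names_from = "group", values_from = "n",
                         values_fill = 0L)
    if (nrow(ok) == 0L ||
        !all(c("case", "control") %in% names(ok)) ||
        any(ok$case != 1L) || any(ok$control != 1L)) {
      stop("pair_id must link exactly one case to one control", call. = FALSE)
    }
  }
  structure(list(counts = counts, samples = samples, cohort = cohort),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("<expression_matrix", if (!is.null(x$cohort)) paste0(" '", x$cohort, "'"),
      ": ", nrow(x$counts), " miRNAs x ", ncol(x$counts), " samples (",
      sum(x$samples$group == "case"), " case / ",
      sum(x$samples$group == "control"), " control)>\n", sep = "")
  invisible(x)
}

#' Median-of-ratios size factors
#'
#' DESeq-style normalization: the reference profile is the per-miRNA
#' geometric mean over miRNAs with all-positive counts, and each sample's
#' size factor is the median of its count-to-reference ratios.
#'
#' @param counts miRNAs x samples count matrix.
#' @return Named numeric vector of size factors (one per sample).
#' @export
size_factors <- function(counts) {
  keep <- apply(counts > 0, 1L, all)
  if (!any(keep)) {
    stop("no miRNA with all-positive counts: cannot build the ",
         "median-of-ratios reference", call. = FALSE)
  }
  geo <- exp(rowMeans(log(counts[keep, , drop = FALSE])))
  sf <- apply(counts[keep, , drop = FALSE] / geo, 2L, stats::median)
  stats::setNames(sf, colnames(counts))
}

#' Per-miRNA log2 fold change (case vs control)
#'
#' Counts are normalized by median-of-ratios size factors, then
#' `log2FC = log2((mean case + pseudocount) / (mean control + pseudocount))`.
#'
#' @param mat An [expression_matrix()].
#' @param pseudocount Added to both group means before the ratio
#'   (default 0.5).
#' @return Tibble with columns `mirna`, `mean_case`, `mean_control`,
#'   `log2fc`.
#' @export
log2_fold_change <- function(mat, pseudocount = 0.5) {
  stopifnot(inherits(mat, "expression_matrix"))
  case <- mat$samples$sample[mat$samples$group == "case"]
  ctrl <- mat$samples$sample[mat$samples$group == "control"]
  if (length(case) == 0L || length(ctrl) == 0L) {
    stop("both groups need at least one sample", call. = FALSE)
  }
  sf <- size_factors(mat$counts)
  norm <- sweep(mat$counts, 2L, sf, "/")
  mean_case <- unname(rowMeans(norm[, case, drop = FALSE]))
  mean_ctrl <- unname(rowMeans(norm[, ctrl, drop = FALSE]))
  tibble::tibble(
    mirna = rownames(mat$counts),
    mean_case = mean_case,
    mean_control = mean_ctrl,
    log2fc = log2((mean_case + pseudocount) / (mean_ctrl + pseudocount))
  )
}

#' Paired t-test on matched case/control values
#'
#' Two-sided p-value from the t distribution on `n - 1` degrees of freedom
#' applied to the paired differences. Zero-variance differences are flagged
#' (`NA` statistics) rather than raised, so per-miRNA failures do not abort a
#' profile.
#'
#' @param x,y Equal-length paired value vectors (case, control).
#' @return Tibble with `statistic`, `p_value`, `df`, `mean_difference`,
#'   `degenerate` (TRUE when differences have zero variance).
#' @export
paired_t_test <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must be paired", call. = FALSE)
  if (length(x) < 2L) stop("need at least 2 pairs", call. = FALSE)
  d <- x - y
  if (stats::sd(d) == 0) {
    return(tibble::tibble(statistic = NA_real_, p_value = NA_real_,
                          df = length(d) - 1L, mean_difference = mean(d),
                          degenerate = TRUE))
  }
  fit <- stats::t.test(x, y, paired = TRUE)
  tibble::tibble(statistic = unname(fit$statistic),
                 p_value = fit$p.value,
                 df = unname(fit$parameter),
                 mean_difference = unname(fit$estimate),
                 degenerate = FALSE)
}

#' Welch two-sample t-test (unpaired fallback)
#'
#' Used when pairing metadata is absent.
#'
#' @inheritParams paired_t_test
#' @return Tibble as in [paired_t_test()].
#' @export
welch_t_test <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L) {
    stop("need at least 2 values per group", call. = FALSE)
  }
  if (stats::sd(c(x, y)) == 0) {
    return(tibble::tibble(statistic = NA_real_, p_value = NA_real_,
                          df = NA_real_, mean_difference = mean(x) - mean(y),
                          degenerate = TRUE))
  }
  fit <- stats::t.test(x, y)
  tibble::tibble(statistic = unname(fit$statistic),
                 p_value = fit$p.value,
                 df = unname(fit$parameter),
                 mean_difference = mean(x) - mean(y),
                 degenerate = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up false-discovery-rate adjustment; `NA` p-values propagate
#' as `NA`.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Numeric vector of q-values.
#' @export
bh_adjust <- function(p) {
  ok <- p[!is.na(p)]
  if (any(ok < 0 | ok > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Cohen's d standardized mean difference
#'
#' `d = (mean(x) - mean(y)) / s_pooled` with the pooled standard deviation
#' using `(n - 1)` weights.
#'
#' @param x Case values (>= 2).
#' @param y Control values (>= 2).
#' @return Numeric scalar; `NA` with a warning-free degenerate flag is not
#'   used here -- zero pooled variance raises an error (callers catch it
#'   per-miRNA).
#' @export
cohens_d <- function(x, y) {
  nx <- length(x); ny <- length(y)
  if (nx < 2L || ny < 2L) stop("each group needs >= 2 values", call. = FALSE)
  sp2 <- ((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) / (nx + ny - 2)
  if (sp2 <= 0) stop("zero pooled variance", call. = FALSE)
  (mean(x) - mean(y)) / sqrt(sp2)
}

#' Common-language effect size from Cohen's d
#'
#' Converts a standardized mean difference into the probability that a random
#' case observation exceeds a random control observation. The default is the
#' two-independent-normals form `CL = pnorm(d / sqrt(2))` (McGraw-Wong); the
#' one-sample variant `pnorm(d)` is available via `variant = "one_sample"`.
#'
#' @param d Cohen's d (finite; vectorized).
#' @param variant `"two_group"` (default) or `"one_sample"`.
#' @return CL probability in `[0, 1]`, strictly increasing in `d`.
#' @export
cl_from_d <- function(d, variant = c("two_group", "one_sample")) {
  variant <- match.arg(variant)
  if (variant == "two_group") stats::pnorm(d / sqrt(2)) else stats::pnorm(d)
}

#' Empirical probability of superiority
#'
#' Brute-force common-language effect size: the fraction of all (x_i, y_j)
#' pairs with `x_i > y_j`, ties counted as 1/2. Serves as the
#' distribution-free oracle for [cl_from_d()].
#'
#' @inheritParams cohens_d
#' @return Probability in `[0, 1]`.
#' @export
cl_empirical <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  # rank-based count of x_i > y_j pairs, ties as 1/2 (O(n log n))
  r <- rank(c(x, y), ties.method = "average")
  rx <- sum(r[seq_along(x)])
  wins <- rx - length(x) * (length(x) + 1) / 2
  wins / (length(x) * length(y))
}

#' Compute a full per-miRNA cohort profile
#'
#' Runs the differential-expression and effect-size stack on one cohort's
#' case/control matrix: median-of-ratios normalization, log2 fold change,
#' per-miRNA paired t-test (Welch fallback without pairing) on
#' log2-transformed normalized counts, Benjamini-Hochberg adjustment,
#' Cohen's d and its common-language probability.
#'
#' @param mat An [expression_matrix()].
#' @param pseudocount Pseudocount for log transforms (default 0.5).
#' @param cl_variant Passed to [cl_from_d()].
#' @return A `cohort_profile` tibble with columns `mirna`, `log2fc`,
#'   `p_value`, `q_value`, `cohens_d`, `cl`, `mean_case`, `mean_control`,
#'   `degenerate`, plus a `cohort` attribute.
#' @export
cohort_profile <- function(mat, pseudocount = 0.5,
                           cl_variant = c("two_group", "one_sample")) {
  stopifnot(inherits(mat, "expression_matrix"))
  cl_variant <- match.arg(cl_variant)
  sf <- size_factors(mat$counts)
  norm <- sweep(mat$counts, 2L, sf, "/")
  logn <- log2(norm + pseudocount)
  lfc <- log2_fold_change(mat, pseudocount)

  paired <- "pair_id" %in% names(mat$samples) &&
    !anyNA(mat$samples$pair_id)
  if (paired) {
    pairs <- mat$samples |>
      dplyr::select("sample", "group", "pair_id") |>
      tidyr::pivot_wider(names_from = "group", values_from = "sample")
    case_cols <- pairs$case
    ctrl_cols <- pairs$control
  } else {
    case_cols <- mat$samples$sample[mat$samples$group == "case"]
    ctrl_cols <- mat$samples$sample[mat$samples$group == "control"]
  }

  stats_tab <- purrr::map_dfr(seq_len(nrow(logn)), function(i) {
    x <- logn[i, case_cols]
    y <- logn[i, ctrl_cols]
    tt <- if (paired) paired_t_test(x, y) else welch_t_test(x, y)
    d <- tryCatch(cohens_d(x, y), error = function(e) NA_real_)
    tibble::tibble(p_value = tt$p_value, cohens_d = d,
                   degenerate = tt$degenerate || is.na(d))
  })

  out <- lfc |>
    dplyr::mutate(
      p_value = stats_tab$p_value,
      q_value = bh_adjust(stats_tab$p_value),
      cohens_d = stats_tab$cohens_d,
      cl = cl_from_d(stats_tab$cohens_d, cl_variant),
      degenerate = stats_tab$degenerate
    ) |>
    dplyr::select("mirna", "log2fc", "p_value", "q_value", "cohens_d", "cl",
                  "mean_case", "mean_control", "degenerate")
  attr(out, "cohort") <- mat$cohort
  attr(out, "paired") <- paired
  class(out) <- c("cohort_profile", class(out))
  out
}

#' Filter miRNA-target interactions by evidence, consensus and tissue
#'
#' Implements the evidence-driven target filter: keep (miRNA, gene) pairs
#' that carry the strongest experimental evidence level in the primary table
#' (`"A"`) or at least `min_studies` supporting studies in a secondary table;
#' optionally require the pair to appear in at least two of the supplied
#' tables (cross-database consensus); then keep only differentially expressed
#' miRNAs retaining at least one surviving target in the tissue expression
#' profile.
#'
#' @param primary Tibble (`mirna`, `gene`, `evidence_level`,
#'   `n_supporting_studies`, optional `source`).
#' @param secondary List of tibbles with the same columns (may be empty).
#' @param tissue_genes Character vector: genes expressed in the target
#'   tissue.
#' @param de_mirnas Character vector of differentially expressed miRNAs.
#' @param level_a_required Evidence level accepted from the primary table
#'   (default `"A"`).
#' @param min_studies Minimum supporting studies for a secondary-table pair
#'   (default 2).
#' @param require_consensus Require presence in >= 2 tables (default TRUE
#'   when secondary tables are supplied).
#' @return Tibble of surviving (`mirna`, `gene`) rows with evidence columns;
#'   attribute `"dropped"` records per-stage exclusion counts.
#' @export
filter_mirna_targets <- function(primary, secondary = list(), tissue_genes,
                                 de_mirnas, level_a_required = "A",
                                 min_studies = 2,
                                 require_consensus = length(secondary) > 0) {
  primary <- tibble::as_tibble(primary)
  tabs <- c(list(primary), lapply(secondary, tibble::as_tibble))
  all_pairs <- dplyr::bind_rows(tabs, .id = "table_id")

  evid_ok <- dplyr::bind_rows(
    primary |>
      dplyr::filter(.data$evidence_level %in% level_a_required) |>
      dplyr::select("mirna", "gene"),
    dplyr::bind_rows(lapply(secondary, tibble::as_tibble)) |>
      (\(d) if (nrow(d) == 0L) d else
        dplyr::filter(d, .data$n_supporting_studies >= min_studies))() |>
      dplyr::select(dplyr::any_of(c("mirna", "gene")))
  ) |>
    dplyr::distinct()

  consensus <- all_pairs |>
    dplyr::distinct(.data$table_id, .data$mirna, .data$gene) |>
    dplyr::count(.data$mirna, .data$gene) |>
    dplyr::filter(.data$n >= if (require_consensus) 2L else 1L) |>
    dplyr::select("mirna", "gene")

  kept <- evid_ok |>
    dplyr::inner_join(consensus, by = c("mirna", "gene"))
  n_after_evidence <- nrow(kept)

  kept_tissue <- kept |>
    dplyr::filter(.data$mirna %in% de_mirnas) |>
    dplyr::mutate(in_tissue = .data$gene %in% tissue_genes)
  surviving_mirnas <- kept_tissue |>
    dplyr::filter(.data$in_tissue) |>
    dplyr::pull("mirna") |>
    unique()
  out <- kept_tissue |>
    dplyr::filter(.data$mirna %in% surviving_mirnas, .data$in_tissue) |>
    dplyr::select("mirna", "gene") |>
    dplyr::left_join(
      primary |> dplyr::select(dplyr::any_of(
        c("mirna", "gene", "evidence_level", "n_supporting_studies",
          "source", "target_score"))),
      by = c("mirna", "gene")
    ) |>
    dplyr::distinct(.data$mirna, .data$gene, .keep_all = TRUE)

  attr(out, "dropped") <- tibble::tibble(
    n_input_pairs = nrow(dplyr::distinct(all_pairs, .data$mirna, .data$gene)),
    n_after_evidence_consensus = n_after_evidence,
    n_de_mirnas = length(unique(de_mirnas)),
    n_surviving_mirnas = length(surviving_mirnas),
    n_surviving_pairs = nrow(out)
  )
  out
}

#' Partition miRNAs by agreement with literature-reported direction
#'
#' A profile miRNA is `matched` when the sign of its log2 fold change agrees
#' with the direction reported in the literature table (`up` means positive
#' log2FC), `mismatched` otherwise, and `unreviewed` when absent from the
#' table. Mismatched miRNAs are flagged for exclusion from downstream
#' parameterization.
#'
#' @param profile A [cohort_profile()] tibble (needs `mirna`, `log2fc`).
#' @param literature Tibble (`mirna`, `direction` in `"up"`/`"down"`).
#' @return The profile with added `literature_direction`, `status`
#'   (`matched`/`mismatched`/`unreviewed`) and `excluded` columns.
#' @export
match_literature_direction <- function(profile, literature) {
  literature <- tibble::as_tibble(literature)
  bad <- setdiff(unique(tolower(literature$direction)), c("up", "down"))
  if (length(bad) > 0L) {
    stop("literature directions must be 'up'/'down'; found: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  literature <- literature |>
    dplyr::mutate(direction = tolower(.data$direction)) |>
    dplyr::distinct(.data$mirna, .keep_all = TRUE)
  tibble::as_tibble(profile) |>
    dplyr::left_join(literature |>
                       dplyr::select("mirna",
                                     literature_direction = "direction"),
                     by = "mirna") |>
    dplyr::mutate(
      status = dplyr::case_when(
        is.na(.data$literature_direction) ~ "unreviewed",
        .data$literature_direction == "up" & .data$log2fc > 0 ~ "matched",
        .data$literature_direction == "down" & .data$log2fc < 0 ~ "matched",
        TRUE ~ "mismatched"
      ),
      excluded = .data$status == "mismatched"
    )
}

#' Hypergeometric over-representation analysis
#'
#' One-sided hypergeometric p-value per gene set (probability of observing at
#' least the attained overlap between the query and the set, drawing from the
#' universe), Benjamini-Hochberg adjusted across sets.
#'
#' @param query_genes Character vector (subset of `universe`).
#' @param gene_sets Named list of character vectors (each a subset of
#'   `universe`).
#' @param universe Character vector of all considered genes.
#' @return Tibble sorted by ascending p with columns `set`, `n_set`,
#'   `n_query`, `n_overlap`, `p_value`, `q_value`.
#' @export
enrich_hypergeometric <- function(query_genes, gene_sets, universe) {
  universe <- unique(universe)
  if (length(universe) == 0L) stop("empty universe", call. = FALSE)
  query <- intersect(unique(query_genes), universe)
  out <- purrr::imap_dfr(gene_sets, function(set, nm) {
    set <- intersect(unique(set), universe)
    k <- length(intersect(query, set))
    p <- stats::phyper(k - 1, length(set), length(universe) - length(set),
                       length(query), lower.tail = FALSE)
    tibble::tibble(set = nm, n_set = length(set), n_query = length(query),
                   n_overlap = k, p_value = p)
  })
  out |>
    dplyr::mutate(q_value = bh_adjust(.data$p_value)) |>
    dplyr::arrange(.data$p_value)
}
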