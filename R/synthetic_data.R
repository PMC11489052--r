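#' Declare a synthetic cohort scenario
#'
#' One declarative object holds everything the generators need to emulate a
#' multi-cohort blood miRNA study: cohort sizes (defaults are the four
#' study cohorts -- clinical reference n=1430, prodromal n=223, SWEDD n=187,
#' parkinsonism n=81), negative-binomial count parameters, planted
#' standardized effects, miRNA-target map structure, literature agreement and
#' a comorbidity DEG plan. Everything downstream is reproducible from
#' `seed`.
#'
#' @param seed Integer master seed.
#' @param cohort_sizes Named vector: `clinical` (the control pool) plus case
#'   cohorts.
#' @param n_mirna Number of simulated miRNAs (default 500, the order of
#'   distinct miRNAs a whole-blood small-RNA assay detects).
#' @param planted_effects Tibble (`mirna`, `cohort`, `d`): standardized
#'   log-scale effects to plant. Default: `d = 1.2` in the first 20 miRNAs of
#'   every case cohort.
#' @param baseline_mean,dispersion Negative-binomial mean and dispersion of
#'   the unperturbed counts (recycled per miRNA).
#' @param size_factor_sd SD of per-sample log-normal size factors.
#' @param pair_effect_sd SD (log2 scale) of the shared subject effect that
#'   correlates a case with its paired control.
#' @param paired Emit case-control pairing metadata (default TRUE).
#' @param genes Gene symbol pool for target tables (default: PRKN-model
#'   vocabulary plus filler genes).
#' @param targets_per_mirna Targets drawn per DE miRNA.
#' @param frac_level_a Fraction of primary-table pairs at evidence level
#'   `"A"`.
#' @param frac_multi_study Fraction of secondary-table pairs with >= 2
#'   supporting studies.
#' @param tissue_overlap Fraction of target genes included in the tissue
#'   expression list.
#' @param literature_agreement Fraction of planted miRNAs whose literature
#'   direction agrees with the planted sign.
#' @param deg_plan Tibble (`gene`, `direction`) for the comorbidity DEG
#'   table. Default: the three knockouts SNCA, BCL2, BNIP3.
#' @return A `synthetic_scenario` object.
#' @export
synthetic_scenario <- function(
    seed = 1,
    cohort_sizes = c(clinical = 1430, prodromal = 223, swedd = 187,
                     parkinsonism = 81),
    n_mirna = 500,
    planted_effects = NULL,
    baseline_mean = 200,
    dispersion = 0.05,
    size_factor_sd = 0.15,
    pair_effect_sd = 0.25,
    paired = TRUE,
    genes = NULL,
    targets_per_mirna = 2,
    frac_level_a = 0.7,
    frac_multi_study = 0.7,
    tissue_overlap = 0.8,
    literature_agreement = 0.8,
    deg_plan = NULL) {
  if (any(cohort_sizes < 2)) stop("cohort sizes must be >= 2", call. = FALSE)
  if (!"clinical" %in% names(cohort_sizes)) {
    stop("cohort_sizes must include the 'clinical' control pool",
         call. = FALSE)
  }
  if (any(dispersion <= 0)) stop("dispersions must be > 0", call. = FALSE)
  mirnas <- sprintf("mir-%03d", seq_len(n_mirna))
  if (is.null(planted_effects)) {
    cases <- setdiff(names(cohort_sizes), "clinical")
    planted_effects <- tidyr::expand_grid(
      mirna = mirnas[seq_len(min(20L, n_mirna))],
      cohort = cases
    ) |>
      dplyr::mutate(d = 1.2)
  }
  planted_effects <- tibble::as_tibble(planted_effects)
  if (any(!is.finite(planted_effects$d))) {
    stop("planted effects must be finite", call. = FALSE)
  }
  if (is.null(genes)) {
    genes <- c("ATXN3", "BAG4", "FBXW7", "GABARAPL1", "TIMM17A", "ULK1",
               "VPS13C", "SNCA", "BCL2", "BNIP3",
               sprintf("GENE%03d", seq_len(60)))
  }
  if (is.null(deg_plan)) {
    deg_plan <- tibble::tibble(gene = c("SNCA", "BCL2", "BNIP3"),
                               direction = "down")
  }
  structure(
    list(seed = as.integer(seed), cohort_sizes = cohort_sizes,
         n_mirna = as.integer(n_mirna), mirnas = mirnas,
         planted_effects = planted_effects,
         baseline_mean = rep_len(baseline_mean, n_mirna),
         dispersion = rep_len(dispersion, n_mirna),
         size_factor_sd = size_factor_sd, pair_effect_sd = pair_effect_sd,
         paired = paired, genes = genes,
         targets_per_mirna = targets_per_mirna,
         frac_level_a = frac_level_a, frac_multi_study = frac_multi_study,
         tissue_overlap = tissue_overlap,
         literature_agreement = literature_agreement,
         deg_plan = tibble::as_tibble(deg_plan)),
    class = "synthetic_scenario"
  )
}

#' @export
print.synthetic_scenario <- function(x, ...) {
  cat("<synthetic_scenario: seed ", x$seed, ", ", x$n_mirna, " miRNAs, ",
      "cohorts ", paste(names(x$cohort_sizes), x$cohort_sizes, sep = "=",
                        collapse = " "), ">\n", sep = "")
  invisible(x)
}

# Exact sd of log2(X + pseudocount) for X ~ NB(mu, phi), by summing the pmf
# (the delta-method approximation sqrt(1/mu + phi)/ln2 underestimates the
# spread at moderate means).
nb_log2_sd <- function(mu, phi, pseudocount = 0.5) {
  mapply(function(m, p) {
    size <- 1 / p
    upper <- stats::qnbinom(1 - 1e-10, mu = m, size = size)
    x <- 0:upper
    w <- stats::dnbinom(x, mu = m, size = size)
    l <- log2(x + pseudocount)
    e <- sum(w * l)
    sqrt(max(sum(w * l^2) - e^2, 0))
  }, mu, phi)
}

# Effects are planted on the log2 mean so that Cohen's d measured on
# log2-normalized counts realizes the target: the per-observation log2
# spread is the exact NB log2 sd plus the shared subject effect's variance
# (present in both groups).
planted_log2_shift <- function(d, mu, phi, pair_sd = 0) {
  d * sqrt(nb_log2_sd(mu, phi)^2 + pair_sd^2)
}

#' Generate cohort count matrices with planted effects
#'
#' Draws negative-binomial counts for each case cohort and its paired
#' control samples (from the clinical reference pool). Case means are
#' shifted on the log2 scale so the planted standardized effect is realized
#' on log2-normalized counts. Per-sample log-normal size factors emulate
#' depth variation, and when pairing is requested a shared per-pair subject
#' effect correlates each case with its control.
#'
#' @param scenario A [synthetic_scenario()].
#' @return Named list of [expression_matrix()] objects, one per case
#'   cohort.
#' @export
gen_counts <- function(scenario) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  sc <- scenario
  cases <- setdiff(names(sc$cohort_sizes), "clinical")
  out <- list()
  for (cohort in cases) {
    withr_seed <- derive_seed(sc$seed, paste0("counts_", cohort))
    set.seed(withr_seed)
    n <- sc$cohort_sizes[[cohort]]
    n_ctrl <- min(n, sc$cohort_sizes[["clinical"]])
    n <- n_ctrl  # paired design: equal-sized matched subsets
    shift <- stats::setNames(rep(0, sc$n_mirna), sc$mirnas)
    pl <- sc$planted_effects[sc$planted_effects$cohort == cohort, ]
    if (nrow(pl) > 0L) {
      idx <- match(pl$mirna, sc$mirnas)
      shift[idx] <- planted_log2_shift(
        pl$d, sc$baseline_mean[idx], sc$dispersion[idx],
        if (sc$paired) sc$pair_effect_sd else 0)
    }
    sf <- exp(stats::rnorm(2L * n, 0, sc$size_factor_sd))
    pair_eff <- if (sc$paired) {
      matrix(stats::rnorm(sc$n_mirna * n, 0, sc$pair_effect_sd),
             sc$n_mirna, n)
    } else {
      matrix(0, sc$n_mirna, n)
    }
    mu_case <- (sc$baseline_mean * 2^shift) %o% sf[seq_len(n)] *
      2^pair_eff
    mu_ctrl <- sc$baseline_mean %o% sf[n + seq_len(n)] * 2^pair_eff
    draw <- function(mu) {
      matrix(stats::rnbinom(length(mu), mu = as.vector(mu),
                            size = rep(1 / sc$dispersion, ncol(mu))),
             nrow(mu), ncol(mu))
    }
    counts <- cbind(draw(mu_case), draw(mu_ctrl))
    rownames(counts) <- sc$mirnas
    colnames(counts) <- c(sprintf("%s_case_%03d", cohort, seq_len(n)),
                          sprintf("%s_ctrl_%03d", cohort, seq_len(n)))
    samples <- tibble::tibble(
      sample = colnames(counts),
      group = rep(c("case", "control"), each = n),
      pair_id = if (sc$paired) rep(sprintf("pair_%03d", seq_len(n)), 2L) else
        NA_character_
    )
    out[[cohort]] <- expression_matrix(counts, samples, cohort = cohort)
  }
  out
}

#' Generate interaction, tissue and literature tables
#'
#' Builds a primary evidence table, secondary tables, a tissue gene list and
#' a literature direction table whose filtering and matching outcomes are
#' known by construction: controlled fractions of level-A pairs, multi-study
#' pairs, tissue-overlapping targets and literature directions agreeing with
#' the planted effect signs.
#'
#' @param scenario A [synthetic_scenario()].
#' @return List: `primary` (tibble), `secondary` (list of 2 tibbles),
#'   `tissue_genes` (character), `literature` (tibble `mirna`,
#'   `direction`), `truth` (tibble of planted per-pair expectations).
#' @export
gen_interactions <- function(scenario) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  sc <- scenario
  set.seed(derive_seed(sc$seed, "interactions"))
  de_mirnas <- unique(sc$planted_effects$mirna)
  if (length(de_mirnas) == 0L) {
    empty <- tibble::tibble(mirna = character(), gene = character(),
                            evidence_level = character(),
                            n_supporting_studies = integer(),
                            source = character())
    return(list(primary = empty, secondary = list(empty, empty),
                tissue_genes = character(), literature = tibble::tibble(
                  mirna = character(), direction = character()),
                truth = tibble::tibble()))
  }
  pairs <- purrr::map_dfr(de_mirnas, function(m) {
    tibble::tibble(
      mirna = m,
      gene = sample(sc$genes, min(sc$targets_per_mirna, length(sc$genes)))
    )
  })
  k <- nrow(pairs)
  pairs <- pairs |>
    dplyr::mutate(
      level_a = seq_len(k) %in% sample.int(k, round(sc$frac_level_a * k)),
      multi_study = seq_len(k) %in%
        sample.int(k, round(sc$frac_multi_study * k))
    )
  primary <- pairs |>
    dplyr::transmute(
      .data$mirna, .data$gene,
      evidence_level = ifelse(.data$level_a, "A", "B"),
      n_supporting_studies = 1L,
      source = "primary_db",
      target_score = sample(90:100, k, replace = TRUE)
    )
  secondary1 <- pairs |>
    dplyr::transmute(
      .data$mirna, .data$gene,
      evidence_level = "predicted",
      n_supporting_studies = ifelse(.data$multi_study, 2L, 1L),
      source = "secondary_db1"
    )
  # a second secondary table covering a subset, for consensus structure
  keep2 <- sample.int(k, round(0.8 * k))
  secondary2 <- secondary1[keep2, ] |>
    dplyr::mutate(source = "secondary_db2")

  target_genes <- unique(pairs$gene)
  tissue_genes <- sample(target_genes,
                         round(sc$tissue_overlap * length(target_genes)))

  truth_dir <- sc$planted_effects |>
    dplyr::group_by(.data$mirna) |>
    dplyr::summarise(planted_sign = sign(mean(.data$d)), .groups = "drop")
  agree <- stats::runif(nrow(truth_dir)) < sc$literature_agreement
  literature <- truth_dir |>
    dplyr::mutate(
      direction = dplyr::if_else(
        xor(.data$planted_sign >= 0, !agree), "up", "down")
    ) |>
    dplyr::select("mirna", "direction")

  list(primary = primary, secondary = list(secondary1, secondary2),
       tissue_genes = tissue_genes, literature = literature,
       truth = pairs |> dplyr::left_join(truth_dir, by = "mirna"))
}

#' Generate a comorbidity DEG table
#'
#' Emits the planned up/down gene table used to force model nodes
#' (knockouts/overexpressions).
#'
#' @param scenario A [synthetic_scenario()].
#' @return Tibble (`gene`, `direction`).
#' @export
gen_deg_table <- function(scenario) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  plan <- scenario$deg_plan
  if (nrow(plan) == 0L) {
    return(tibble::tibble(gene = character(), direction = character()))
  }
  bad <- setdiff(unique(tolower(plan$direction)), c("up", "down"))
  if (length(bad) > 0L) {
    stop("DEG plan directions must be 'up'/'down'; found: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  plan |> dplyr::mutate(direction = tolower(.data$direction))
}

#' Catalogue of deterministic toy Boolean networks
#'
#' Fixture networks for testing and demonstration: `identity_input` (one
#' self-ruled node), `oscillator` (one negation node, a 2-cycle attractor),
#' `chain3` (A feeds B feeds C), `bistable` (mutual inhibition, two fixed
#' points), `prkn_shape` (a mitophagy-pathway-shaped model with the seven
#' canonical regulator inputs ATXN3, BAG4, FBXW7, GABARAPL1, TIMM17A, ULK1,
#' VPS13C and the four phenotype outputs Apoptosis, Mitophagy,
#' PRKN_ubiquitinated, PINK1_accumulation over synthetic internal rules --
#' including the comorbidity-perturbable nodes SNCA, BCL2 and BNIP3),
#' and `random` (seeded random rules over `n_nodes`).
#'
#' @param kind One of `"identity_input"`, `"oscillator"`, `"chain3"`,
#'   `"bistable"`, `"prkn_shape"`, `"random"`.
#' @param n_nodes Node count for `kind = "random"` (default 6).
#' @param seed Seed for `kind = "random"`.
#' @return A [boolean_network()].
#' @export
gen_toy_network <- function(kind, n_nodes = 6, seed = 1) {
  catalogue <- c("identity_input", "oscillator", "chain3", "bistable",
                 "prkn_shape", "random")
  if (!kind %in% catalogue) {
    stop("unknown network kind '", kind, "'; catalogue: ",
         paste(catalogue, collapse = ", "), call. = FALSE)
  }
  switch(kind,
    identity_input = boolean_network(c(A = "A"), name = kind),
    oscillator = boolean_network(c(A = "!A"), name = kind),
    chain3 = boolean_network(c(A = "A", B = "A", C = "B"), name = kind),
    bistable = boolean_network(c(A = "!B", B = "!A"), name = kind),
    prkn_shape = boolean_network(c(
      ATXN3 = "ATXN3", BAG4 = "BAG4", FBXW7 = "FBXW7",
      GABARAPL1 = "GABARAPL1", TIMM17A = "TIMM17A", ULK1 = "ULK1",
      VPS13C = "VPS13C",
      SNCA = "!ULK1",
      BCL2 = "BAG4",
      Mito_damage = "(ATXN3 | SNCA) & !VPS13C",
      BNIP3 = "Mito_damage",
      PRKN_activity = "BAG4 | (ULK1 & !FBXW7)",
      PINK1_accumulation = "Mito_damage & TIMM17A",
      PRKN_ubiquitinated = "PRKN_activity & Mito_damage",
      Mitophagy = "(PRKN_activity & GABARAPL1) | (ULK1 & BNIP3)",
      Apoptosis = "(Mito_damage | SNCA) & !PRKN_activity & !BCL2"
    ), name = kind),
    random = gen_random_network(n_nodes, seed)
  )
}

gen_random_network <- function(n_nodes, seed) {
  set.seed(seed)
  nodes <- paste0("N", seq_len(n_nodes))
  rules <- vapply(nodes, function(n) {
    k <- sample(1:min(3L, n_nodes), 1L)
    regs <- sample(nodes, k)
    lits <- ifelse(stats::runif(k) < 0.4, paste0("!", regs), regs)
    if (k == 1L) return(lits)
    ops <- sample(c(" & ", " | "), k - 1L, replace = TRUE)
    out <- lits[1]
    for (i in seq_len(k - 1L)) out <- paste0(out, ops[i], lits[i + 1L])
    out
  }, character(1))
  boolean_network(rules, name = sprintf("random_%d_%d", n_nodes, seed))
}
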