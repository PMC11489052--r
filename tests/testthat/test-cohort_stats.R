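make_mat <- function(counts, n_case, n_ctrl, paired = FALSE) {
  colnames(counts) <- c(sprintf("case_%d", seq_len(n_case)),
                        sprintf("ctrl_%d", seq_len(n_ctrl)))
  samples <- tibble::tibble(
    sample = colnames(counts),
    group = rep(c("case", "control"), c(n_case, n_ctrl))
  )
  if (paired) samples$pair_id <- rep(sprintf("p%d", seq_len(n_case)), 2)
  expression_matrix(counts, samples)
}

test_that("log2 fold change uses median-of-ratios normalization", {
  # stable majority keeps size factors at 1; case means exactly 2x control
  m <- rbind(mir1 = c(20, 20, 10, 10), mir2 = c(50, 50, 50, 50),
             mir3 = c(80, 80, 80, 80))
  mat <- make_mat(m, 2, 2)
  lfc <- log2_fold_change(mat, pseudocount = 0)
  expect_equal(lfc$log2fc, c(1, 0, 0), tolerance = 1e-10)

  # identical groups give zero log2FC
  m2 <- rbind(mir1 = c(13, 20, 13, 20))
  expect_equal(log2_fold_change(make_mat(rbind(m2, m2 + 5), 2, 2))$log2fc,
               c(0, 0), tolerance = 1e-10)

  # hand-computed fixture (size factors and ratios worked out externally)
  m3 <- rbind(mir1 = c(12, 25, 30, 41), mir2 = c(100, 180, 310, 420))
  lfc3 <- log2_fold_change(make_mat(m3, 2, 2))
  sf3 <- size_factors(m3)
  expect_equal(unname(sf3),
               c(0.470689033734, 0.9162153593, 1.31307108994, 1.78619808091),
               tolerance = 1e-9)
  expect_equal(lfc3$log2fc, c(0.20054971356, -0.204147238766),
               tolerance = 1e-9)

  expect_error(size_factors(matrix(0L, 2, 2)), "reference")
})

test_that("paired t-test matches the textbook formula and flags degeneracy", {
  x <- c(2, 4, 6, 8); y <- c(1, 2, 3, 4)  # differences 1,2,3,4
  tt <- paired_t_test(x, y)
  expect_equal(tt$statistic, 3.87298334621, tolerance = 1e-8)
  expect_equal(tt$p_value, 0.0304662916622, tolerance = 1e-8)
  expect_equal(tt$df, 3)

  # zero-variance differences are flagged, not raised
  same <- paired_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_true(same$degenerate)
  expect_true(is.na(same$p_value))

  # sign flip negates t, keeps p
  flipped <- paired_t_test(y, x)
  expect_equal(flipped$statistic, -tt$statistic)
  expect_equal(flipped$p_value, tt$p_value)

  expect_error(paired_t_test(1:3, 1:4), "paired")
})

test_that("BH adjustment is the standard step-up and order-invariant", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.42), 0.42)
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(11)
  p <- stats::runif(40)
  perm <- sample.int(40)
  expect_equal(bh_adjust(p)[perm], bh_adjust(p[perm]))
})

test_that("Cohen's d uses (n-1)-weighted pooled SD", {
  expect_equal(cohens_d(c(4, 5, 6), c(1, 2, 3)), 3)  # pooled SD is 1
  expect_equal(cohens_d(c(1, 2, 3), c(4, 5, 6)), -3) # antisymmetry
  expect_equal(cohens_d(c(5, 6, 7), c(5, 7, 6)), 0)
  expect_error(cohens_d(c(1, 1), c(1, 1)), "variance")
  expect_error(cohens_d(1, c(1, 2)), ">= 2")
})

test_that("CL transform is the two-normals form with exact symmetries", {
  expect_identical(cl_from_d(0), 0.5)
  expect_equal(cl_from_d(1), 0.760249938907, tolerance = 1e-10)
  for (d in c(-3, -0.7, 0.2, 1.5, 4)) {
    expect_equal(cl_from_d(d) + cl_from_d(-d), 1, tolerance = 1e-12)
  }
  expect_true(all(diff(cl_from_d(seq(-4, 4, by = 0.1))) > 0))
  expect_equal(cl_from_d(1, variant = "one_sample"), stats::pnorm(1))
})

test_that("empirical probability of superiority counts pairs with ties", {
  expect_equal(cl_empirical(c(5, 6), c(1, 2)), 1)
  expect_equal(cl_empirical(3, 3), 0.5)
  expect_equal(cl_empirical(c(1, 3), 2), 0.5)
  # exhaustive cross-check on a mixed example with ties
  x <- c(1, 2, 2, 5); y <- c(2, 3)
  wins <- sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  expect_equal(cl_empirical(x, y), wins / (length(x) * length(y)))
  expect_error(cl_empirical(numeric(0), 1), "non-empty")
})

test_that("normal-theory CL tracks the empirical oracle at large n", {
  set.seed(21)
  for (d in c(0, 0.5, 1, 2)) {
    x <- stats::rnorm(10000, mean = d)
    y <- stats::rnorm(10000)
    d_hat <- cohens_d(x, y)
    expect_lte(abs(cl_from_d(d_hat) - cl_empirical(x, y)), 0.02)
  }
})

test_that("paired t type-I error is nominal under the null", {
  set.seed(31)
  n_feat <- 2000
  p <- vapply(seq_len(n_feat), function(i) {
    x <- stats::rnorm(20)
    y <- stats::rnorm(20)
    paired_t_test(x, y)$p_value
  }, numeric(1))
  rate <- mean(p <= 0.05)
  expect_gte(rate, 0.035)
  expect_lte(rate, 0.065)
})

test_that("planted standardized effects are recovered without bias", {
  set.seed(41)
  d_hat <- replicate(500, cohens_d(stats::rnorm(100, mean = 1),
                                   stats::rnorm(100)))
  expect_lt(abs(mean(d_hat) - 1), 0.1)
})

test_that("cohort_profile assembles the full per-miRNA stack", {
  sc <- small_scenario(seed = 5)
  pr <- cohort_profile(gen_counts(sc)$swedd)
  expect_s3_class(pr, "cohort_profile")
  expect_true(all(c("mirna", "log2fc", "p_value", "q_value", "cohens_d",
                    "cl", "degenerate") %in% names(pr)))
  ok <- !is.na(pr$p_value)
  expect_true(all(pr$q_value[ok] >= pr$p_value[ok]))
  expect_true(all(pr$cl >= 0 & pr$cl <= 1, na.rm = TRUE))
  expect_equal(pr$cl, cl_from_d(pr$cohens_d))  # CL column is the transform
  # planted miRNAs dominate the smallest q-values
  planted <- unique(sc$planted_effects$mirna)
  top <- pr$mirna[order(pr$q_value)][seq_along(planted)]
  expect_gt(mean(top %in% planted), 0.9)
})

test_that("target filtering applies evidence, consensus and tissue rules", {
  primary <- tibble::tibble(
    mirna = c("m1", "m2", "m3"),
    gene = c("G1", "G2", "G3"),
    evidence_level = c("A", "B", "A"),
    n_supporting_studies = 1L
  )
  secondary <- list(tibble::tibble(
    mirna = c("m1", "m2", "m3"),
    gene = c("G1", "G2", "G3"),
    evidence_level = "predicted",
    n_supporting_studies = c(2L, 1L, 2L)
  ))
  # level-A + in tissue -> retained
  kept <- filter_mirna_targets(primary, secondary, tissue_genes = c("G1"),
                               de_mirnas = c("m1", "m2", "m3"))
  expect_equal(kept$mirna, "m1")
  expect_equal(kept$gene, "G1")
  # level B with one supporting study -> dropped even if in tissue
  kept2 <- filter_mirna_targets(primary, secondary,
                                tissue_genes = c("G1", "G2"),
                                de_mirnas = c("m2"))
  expect_equal(nrow(kept2), 0L)
  # DE miRNA whose only target is outside the tissue list -> dropped
  kept3 <- filter_mirna_targets(primary, secondary, tissue_genes = c("G9"),
                                de_mirnas = c("m1", "m3"))
  expect_equal(nrow(kept3), 0L)
  dropped <- attr(kept3, "dropped")
  expect_equal(dropped$n_surviving_mirnas, 0L)
})

test_that("literature direction matching partitions and excludes", {
  profile <- tibble::tibble(mirna = c("m1", "m2", "m3"),
                            log2fc = c(1.2, -0.8, 0.5))
  lit <- tibble::tibble(mirna = c("m1", "m2"), direction = c("Up", "Up"))
  out <- match_literature_direction(profile, lit)
  expect_equal(out$status, c("matched", "mismatched", "unreviewed"))
  expect_equal(out$excluded, c(FALSE, TRUE, FALSE))
  expect_error(
    match_literature_direction(profile,
                               tibble::tibble(mirna = "m1",
                                              direction = "sideways")),
    "up")
})

test_that("hypergeometric enrichment matches the exact tail", {
  universe <- paste0("g", 1:10)
  sets <- list(inside = universe[1:5], other = universe[6:10])
  res <- enrich_hypergeometric(universe[1:3], sets, universe)
  expect_equal(res$p_value[res$set == "inside"], 1 / 12, tolerance = 1e-12)
  expect_equal(res$p_value[res$set == "other"], 1)
  # set == universe is uninformative
  res2 <- enrich_hypergeometric(universe[1:3], list(all = universe),
                                universe)
  expect_equal(res2$p_value, 1)
  expect_error(enrich_hypergeometric("g1", sets, character(0)), "universe")
})

test_that("a miRNA's CL is constant across its targets", {
  sc <- small_scenario(seed = 6)
  pr <- cohort_profile(gen_counts(sc)$swedd)
  tabs <- gen_interactions(sc)
  tg <- profile_targets(pr, dplyr::bind_rows(tabs$primary)[, c("mirna", "gene")])
  multi <- tg |>
    dplyr::group_by(mirna) |>
    dplyr::filter(dplyr::n() > 1) |>
    dplyr::summarise(n_cl = dplyr::n_distinct(cl))
  expect_gt(nrow(multi), 0L)
  expect_true(all(multi$n_cl == 1L))
})
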