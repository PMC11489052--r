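test_that("parse_bnet handles identity rules, loops and error cases", {
  net <- parse_bnet("targets, factors\nA, A")
  expect_equal(net$nodes, "A")
  expect_identical(cohortpbn:::rule_text(net, "A"), "A")

  loop <- parse_bnet("targets, factors\nA, !B\nB, A")
  # hand-checked truth tables of the 2-node negative loop
  tt <- net_truth_tables(loop)
  # states in order (A,B) = 00, 10, 01, 11
  expect_equal(unname(tt[, "A"]), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(unname(tt[, "B"]), c(FALSE, TRUE, FALSE, TRUE))

  expect_error(parse_bnet("targets, factors\nA, C"), "undeclared")
  expect_error(parse_bnet("targets, factors\nA, A\nA, !A"), "duplicate")
  expect_error(parse_bnet("targets, factors\nA, "), "empty")
  expect_error(parse_bnet("wrong header\nA, A"), "header")
  expect_error(parse_bnet(""), "empty")
})

test_that("constants are allowed as rules and treated as inputs", {
  net <- parse_bnet("targets, factors\nA, 1\nB, A & !B")
  expect_equal(identify_terminals(net)$inputs, "A")
  ex <- exact_state_distribution(net, c(A = 0), n_steps = 3)
  expect_equal(unname(ex$marginals[4, "A"]), 1)  # constant-1 rule switches on
})

test_that("write_bnet round-trips node sets and truth tables exactly", {
  simple <- boolean_network(c(A = "A"))
  expect_match(write_bnet(simple), "A, A", fixed = TRUE)

  for (seed in 1:100) {
    n_nodes <- sample(2:8, 1)
    net <- rand_net(n_nodes, seed)
    back <- parse_bnet(write_bnet(net))
    expect_identical(back$nodes, net$nodes)
    expect_identical(net_truth_tables(back), net_truth_tables(net))
  }
})

test_that("minimal Boolean SBML-qual documents parse to the right rules", {
  qual_doc <- function(species, transitions) {
    paste0(
      '<?xml version="1.0" encoding="UTF-8"?>',
      '<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" ',
      'xmlns:qual="http://www.sbml.org/sbml/level3/version1/qual/version1" ',
      'level="3" version="1"><model id="toy">',
      '<qual:listOfQualitativeSpecies>', species,
      '</qual:listOfQualitativeSpecies>',
      '<qual:listOfTransitions>', transitions,
      '</qual:listOfTransitions></model></sbml>'
    )
  }
  sp <- function(id, maxlevel = 1) {
    sprintf('<qual:qualitativeSpecies qual:id="%s" qual:maxLevel="%d"/>',
            id, maxlevel)
  }
  trans <- function(out, inputs, math) {
    paste0('<qual:transition qual:id="tr_', out, '">',
           '<qual:listOfInputs>',
           paste(sprintf(
             '<qual:input qual:qualitativeSpecies="%s" qual:transitionEffect="none"/>',
             inputs), collapse = ""),
           '</qual:listOfInputs>',
           '<qual:listOfOutputs>',
           sprintf('<qual:output qual:qualitativeSpecies="%s" qual:transitionEffect="assignmentLevel"/>', out),
           '</qual:listOfOutputs>',
           '<qual:listOfFunctionTerms>',
           '<qual:defaultTerm qual:resultLevel="0"/>',
           '<qual:functionTerm qual:resultLevel="1">',
           '<math xmlns="http://www.w3.org/1998/Math/MathML">', math,
           '</math></qual:functionTerm></qual:listOfFunctionTerms>',
           '</qual:transition>')
  }
  eq1 <- function(id) {
    sprintf('<apply><eq/><ci>%s</ci><cn type="integer">1</cn></apply>', id)
  }

  # B := A; A has no incoming transition so it gets the identity self-rule
  doc <- qual_doc(paste0(sp("A"), sp("B")), trans("B", "A", eq1("A")))
  net <- parse_sbml_qual(doc)
  expect_setequal(net$nodes, c("A", "B"))
  expect_identical(cohortpbn:::rule_text(net, "A"), "A")
  expect_identical(cohortpbn:::rule_text(net, "B"), "A")

  # AND/NOT logic compiles to the equivalent rule
  doc2 <- qual_doc(
    paste0(sp("A"), sp("B"), sp("C")),
    trans("C", c("A", "B"),
          sprintf('<apply><and/>%s<apply><not/>%s</apply></apply>',
                  eq1("A"), eq1("B")))
  )
  net2 <- parse_sbml_qual(doc2)
  expect_identical(cohortpbn:::rule_text(net2, "C"), "A & !B")

  # multi-level species are outside the Boolean subset
  doc3 <- qual_doc(paste0(sp("A", 2), sp("B")),
                   trans("B", "A", eq1("A")))
  expect_error(parse_sbml_qual(doc3), "maxLevel")

  # no species at all
  doc4 <- qual_doc("", "")
  expect_error(parse_sbml_qual(doc4), "empty model")

  # unsupported math construct named in the error
  doc5 <- qual_doc(paste0(sp("A"), sp("B")),
                   trans("B", "A",
                         '<apply><plus/><ci>A</ci><cn>1</cn></apply>'))
  expect_error(parse_sbml_qual(doc5), "plus")
})

test_that("to_sif classifies literal occurrences by negation parity", {
  expect_equal(
    to_sif(boolean_network(c(A = "A", B = "!A"))),
    tibble::tibble(source = "A", sign = "inhibitory", target = "B")
  )
  both <- to_sif(boolean_network(c(A = "A", C = "A | !A")))
  expect_equal(nrow(both), 2L)
  expect_setequal(both$sign, c("stimulatory", "inhibitory"))
  expect_equal(nrow(to_sif(boolean_network(c(A = "A")))), 0L)
  expect_equal(nrow(to_sif(boolean_network(c(A = "1")))), 0L)
})

test_that("single-parity SIF signs agree with brute-force sensitivity", {
  for (seed in 1:25) {
    net <- rand_net(sample(2:6, 1), seed)
    sif <- to_sif(net)
    tts <- net_truth_tables(net)
    k <- length(net$nodes)
    grid <- expand.grid(rep(list(c(FALSE, TRUE)), k))
    names(grid) <- net$nodes
    for (r in seq_len(nrow(sif))) {
      src <- sif$source[r]; tgt <- sif$target[r]
      lits <- cohortpbn:::bool_expr_literals(net$rules[[tgt]])
      parities <- unique(lits$negated[lits$node == src])
      if (length(parities) != 1L) next  # mixed-sign regulators: two rows
      lo <- !grid[[src]]
      hi <- grid[[src]]
      # pair states differing only in src
      idx_lo <- which(lo); idx_hi <- which(hi)
      flip_bit <- 2L^(match(src, net$nodes) - 1L)
      partner <- idx_lo + flip_bit
      delta <- tts[partner, tgt] - tts[idx_lo, tgt]
      if (sif$sign[r] == "stimulatory") {
        expect_true(all(delta >= 0))
      } else {
        expect_true(all(delta <= 0))
      }
    }
  }
})

test_that("identify_terminals finds inputs/outputs and ignores node order", {
  prkn <- gen_toy_network("prkn_shape")
  term <- identify_terminals(prkn)
  expect_setequal(term$inputs, c("ATXN3", "BAG4", "FBXW7", "GABARAPL1",
                                 "TIMM17A", "ULK1", "VPS13C"))
  expect_setequal(term$outputs, c("Apoptosis", "Mitophagy",
                                  "PRKN_ubiquitinated",
                                  "PINK1_accumulation"))

  single <- boolean_network(c(A = "A"))
  expect_equal(identify_terminals(single),
               list(inputs = "A", outputs = "A"))

  chain <- gen_toy_network("chain3")
  expect_equal(identify_terminals(chain),
               list(inputs = "A", outputs = "C"))

  # invariance under node reordering
  rules <- vapply(prkn$nodes, function(n) cohortpbn:::rule_text(prkn, n),
                  character(1))
  perm <- rev(rules)
  term2 <- identify_terminals(boolean_network(perm))
  expect_setequal(term2$inputs, term$inputs)
  expect_setequal(term2$outputs, term$outputs)
})

test_that("verify_structure reports sign, presence and direction findings", {
  net <- boolean_network(c(A = "A", B = "!A"))
  ref_mismatch <- tibble::tibble(regulator = "A", target = "B",
                                 sign = "stimulatory")
  rep1 <- verify_structure(net, ref_mismatch)
  expect_equal(rep1$summary$n_sign_mismatch, 1L)
  expect_equal(rep1$summary$n_matched, 0L)

  ref_same <- tibble::tibble(regulator = "A", target = "B",
                             sign = "inhibitory")
  rep2 <- verify_structure(net, ref_same)
  expect_equal(rep2$summary$n_matched, 1L)
  expect_equal(rep2$summary$n_sign_mismatch, 0L)
  expect_equal(rep2$summary$n_network_only, 0L)
  expect_equal(rep2$summary$n_reference_only, 0L)

  ref_rev <- tibble::tibble(regulator = "B", target = "A",
                            sign = "inhibitory")
  rep3 <- verify_structure(net, ref_rev)
  expect_equal(rep3$summary$n_direction_conflict, 1L)

  ref_unknown <- tibble::tibble(regulator = "Z", target = "B",
                                sign = "stimulatory")
  rep4 <- verify_structure(net, ref_unknown)
  expect_equal(rep4$summary$n_unknown_reference_nodes, 1L)

  expect_error(
    verify_structure(net, tibble::tibble(regulator = "A", target = "B",
                                         sign = "activates")),
    "sign")
})

test_that("bnet and SIF files round-trip through disk", {
  net <- gen_toy_network("prkn_shape")
  path <- withr::local_tempfile(fileext = ".bnet")
  write_bnet_file(net, path)
  back <- read_bnet(path)
  expect_identical(net_truth_tables(back), net_truth_tables(net))

  sif_path <- withr::local_tempfile(fileext = ".sif")
  write_sif(net, sif_path)
  sif <- readr::read_tsv(sif_path, col_names = c("source", "sign", "target"),
                         show_col_types = FALSE)
  expect_equal(nrow(sif), nrow(to_sif(net)))
})
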