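#' Construct a Boolean network
#'
#' A Boolean network is an ordered set of named nodes, each carrying exactly
#' one update rule written over the node vocabulary with `!`, `&`, `|` and
#' parentheses. Input nodes carry the identity self-rule (`A, A`) or a
#' constant (`0`/`1`).
#'
#' @param rules Named character vector or list mapping node identifier to its
#'   rule expression. Names define the node order.
#' @param name Optional model name stored in the metadata.
#' @param metadata Optional named list of free-form annotations.
#' @return A `boolean_network` object.
#' @examples
#' net <- boolean_network(c(A = "A", B = "!A"))
#' net
#' @export
boolean_network <- function(rules, name = NULL, metadata = list()) {
  nodes <- names(rules)
  if (is.null(nodes) || any(!nzchar(nodes))) {
    stop("every rule must be named by a non-empty node identifier",
         call. = FALSE)
  }
  dup <- nodes[duplicated(nodes)]
  if (length(dup) > 0L) {
    stop("duplicate node identifier(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  asts <- vector("list", length(nodes))
  names(asts) <- nodes
  for (i in seq_along(nodes)) {
    txt <- as.character(rules[[i]])
    if (!nzchar(trimws(txt))) {
      stop("empty rule for node '", nodes[i], "'", call. = FALSE)
    }
    asts[[i]] <- parse_bool_expr(txt)
    refs <- bool_expr_vars(asts[[i]])
    unknown <- setdiff(refs, nodes)
    if (length(unknown) > 0L) {
      stop("rule for '", nodes[i], "' references undeclared node(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  if (!is.null(name)) metadata$name <- name
  structure(
    list(nodes = nodes, rules = asts, metadata = metadata),
    class = "boolean_network"
  )
}

#' @export
print.boolean_network <- function(x, ...) {
  nm <- x$metadata$name
  cat("<boolean_network", if (!is.null(nm)) paste0(" '", nm, "'"), ": ",
      length(x$nodes), " nodes>\n", sep = "")
  for (n in x$nodes) {
    cat("  ", n, " <- ", bool_expr_deparse(x$rules[[n]]), "\n", sep = "")
  }
  invisible(x)
}

rule_text <- function(net, node) bool_expr_deparse(net$rules[[node]])

is_identity_rule <- function(ast, node) {
  ast$op == "var" && ast$name == node
}

#' Parse a BoolNet-style rule file
#'
#' The dialect is the de-facto BoolNet convention: a header line
#' `targets, factors`, then one `node, expression` line per node with
#' operators `!`, `&`, `|`. Comment lines starting with `#` and blank lines
#' are skipped. Parsing is case-preserving.
#'
#' @param text Character scalar (file content) or character vector of lines.
#' @param name Optional model name.
#' @return A [boolean_network()].
#' @examples
#' parse_bnet("targets, factors\nA, A\nB, !A")
#' @export
parse_bnet <- function(text, name = NULL) {
  lines <- if (length(text) == 1L) strsplit(text, "\r?\n")[[1]] else text
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) stop("empty rule file", call. = FALSE)
  header <- tolower(gsub("\\s", "", lines[1]))
  if (!grepl("^targets[,\t]factors$", header)) {
    stop("expected header 'targets, factors', got: ", lines[1], call. = FALSE)
  }
  body <- lines[-1]
  if (length(body) == 0L) stop("rule file has no rules", call. = FALSE)
  rules <- character(0)
  for (i in seq_along(body)) {
    parts <- strsplit(body[i], "[,\t]", perl = TRUE)[[1]]
    if (length(parts) < 2L) {
      if (grepl("[,\t]\\s*$", body[i])) {
        stop("line ", i + 1L, ": empty rule for node '", trimws(parts[1]),
             "'", call. = FALSE)
      }
      stop("line ", i + 1L, ": expected 'target, factors', got: ", body[i],
           call. = FALSE)
    }
    target <- trimws(parts[1])
    expr <- trimws(paste(parts[-1], collapse = ","))
    if (!nzchar(target)) stop("line ", i + 1L, ": empty target", call. = FALSE)
    if (!nzchar(expr)) {
      stop("line ", i + 1L, ": empty rule for node '", target, "'",
           call. = FALSE)
    }
    if (target %in% names(rules)) {
      stop("line ", i + 1L, ": duplicate target '", target, "'", call. = FALSE)
    }
    rules[[target]] <- expr
  }
  net <- tryCatch(
    boolean_network(rules, name = name),
    error = function(e) stop("rule file invalid: ", conditionMessage(e),
                             call. = FALSE)
  )
  net
}

#' Serialize a Boolean network to BoolNet-style text
#'
#' Round-trip guarantee: `parse_bnet(write_bnet(net))` reproduces the node
#' set and per-node truth tables exactly.
#'
#' @param net A [boolean_network()].
#' @return Character scalar with the rule-file content.
#' @export
write_bnet <- function(net) {
  stopifnot(inherits(net, "boolean_network"))
  lines <- c("targets, factors",
             vapply(net$nodes, function(n) {
               paste0(n, ", ", rule_text(net, n))
             }, character(1)))
  paste0(paste(lines, collapse = "\n"), "\n")
}

#' Read / write Boolean networks on disk
#'
#' @param path File path.
#' @param net A [boolean_network()].
#' @inheritParams parse_bnet
#' @return `read_bnet()` returns a [boolean_network()]; `write_bnet_file()`
#'   invisibly returns `path`.
#' @export
read_bnet <- function(path, name = NULL) {
  parse_bnet(readLines(path, warn = FALSE),
             name = name %||% tools::file_path_sans_ext(basename(path)))
}

#' @rdname read_bnet
#' @export
write_bnet_file <- function(net, path) {
  writeLines(sub("\n$", "", write_bnet(net)), path)
  invisible(path)
}

# ---- SBML-qual (strict Boolean subset) --------------------------------------

qual_math_to_ast <- function(node, species_ids) {
  name <- xml2::xml_name(node)
  if (name == "math") {
    kids <- xml2::xml_children(node)
    if (length(kids) != 1L) stop("malformed <math> element", call. = FALSE)
    return(qual_math_to_ast(kids[[1]], species_ids))
  }
  if (name == "ci") {
    id <- trimws(xml2::xml_text(node))
    if (!id %in% species_ids) {
      stop("transition math references unknown species '", id, "'",
           call. = FALSE)
    }
    return(list(op = "var", name = id))
  }
  if (name == "cn") {
    v <- suppressWarnings(as.numeric(trimws(xml2::xml_text(node))))
    if (is.na(v) || !v %in% c(0, 1)) {
      stop("unsupported SBML-qual construct: numeric constant '",
           trimws(xml2::xml_text(node)), "' (only 0/1 allowed)",
           call. = FALSE)
    }
    return(list(op = "const", value = as.integer(v)))
  }
  if (name == "true") return(list(op = "const", value = 1L))
  if (name == "false") return(list(op = "const", value = 0L))
  if (name != "apply") {
    stop("unsupported SBML-qual construct: <", name, ">", call. = FALSE)
  }
  kids <- xml2::xml_children(node)
  op <- xml2::xml_name(kids[[1]])
  args <- kids[-1]
  if (op == "not") {
    if (length(args) != 1L) stop("<not> takes one operand", call. = FALSE)
    return(list(op = "not", x = qual_math_to_ast(args[[1]], species_ids)))
  }
  if (op %in% c("and", "or")) {
    if (length(args) < 1L) stop("<", op, "> needs operands", call. = FALSE)
    sub <- lapply(args, qual_math_to_ast, species_ids = species_ids)
    if (length(sub) == 1L) return(sub[[1]])
    return(list(op = op, args = sub))
  }
  if (op %in% c("eq", "geq", "leq")) {
    if (length(args) != 2L) stop("<", op, "> takes two operands", call. = FALSE)
    a <- qual_math_to_ast(args[[1]], species_ids)
    b <- qual_math_to_ast(args[[2]], species_ids)
    # normalize to (var, const)
    if (a$op == "const" && b$op == "var") {
      tmp <- a; a <- b; b <- tmp
      op <- switch(op, geq = "leq", leq = "geq", eq = "eq")
    }
    if (a$op != "var" || b$op != "const") {
      stop("unsupported SBML-qual construct: <", op,
           "> must compare a species to 0 or 1", call. = FALSE)
    }
    on <- switch(op,
      eq = b$value == 1L,
      geq = b$value == 1L,   # x >= 1  <=> active;  x >= 0 is tautology
      leq = b$value == 0L    # x <= 0  <=> inactive; x <= 1 is tautology
    )
    if (op == "geq" && b$value == 0L) return(list(op = "const", value = 1L))
    if (op == "leq" && b$value == 1L) return(list(op = "const", value = 1L))
    if (on) return(a)
    return(list(op = "not", x = a))
  }
  stop("unsupported SBML-qual construct: <", op, ">", call. = FALSE)
}

#' Parse a Boolean SBML-qual document
#'
#' Supports the strict Boolean subset emitted for logical pathway models:
#' every qualitative species has maximum level 1 and every transition's
#' function terms use `and`/`or`/`not` and equality-to-1 (or threshold)
#' comparisons. One network node is created per qualitative species; species
#' with no incoming transition get the identity self-rule. Anything outside
#' the subset (multi-level species, other MathML constructs) fails loudly.
#'
#' @param x Path to an SBML file, an XML string, or an `xml2` document.
#' @param name Optional model name (defaults to the SBML model id).
#' @return A [boolean_network()].
#' @export
parse_sbml_qual <- function(x, name = NULL) {
  doc <- if (inherits(x, "xml_document")) x else xml2::read_xml(x)
  ns <- c(q = "http://www.sbml.org/sbml/level3/version1/qual/version1")
  # attributes may carry the qual prefix or none, depending on the emitter
  qattr <- function(node, name) {
    v <- xml2::xml_attr(node, paste0("q:", name), ns = ns)
    miss <- is.na(v)
    if (any(miss)) v[miss] <- xml2::xml_attr(node[miss], name)
    v
  }
  species <- xml2::xml_find_all(doc, ".//q:qualitativeSpecies", ns)
  if (length(species) == 0L) stop("empty model: no qualitative species",
                                  call. = FALSE)
  ids <- qattr(species, "id")
  if (anyNA(ids)) stop("qualitative species without id", call. = FALSE)
  maxlev <- qattr(species, "maxLevel")
  bad <- !is.na(maxlev) & suppressWarnings(as.numeric(maxlev)) > 1
  if (any(bad)) {
    stop("unsupported feature: species with maxLevel > 1: ",
         paste(ids[bad], collapse = ", "), call. = FALSE)
  }

  rules <- stats::setNames(as.list(ids), ids)  # default: identity self-rule
  has_rule <- stats::setNames(rep(FALSE, length(ids)), ids)

  transitions <- xml2::xml_find_all(doc, ".//q:transition", ns)
  for (tr in transitions) {
    outs <- xml2::xml_find_all(tr, ".//q:output", ns)
    out_ids <- qattr(outs, "qualitativeSpecies")
    if (length(out_ids) == 0L) next
    terms <- xml2::xml_find_all(tr, ".//q:functionTerm", ns)
    lvls <- suppressWarnings(as.numeric(qattr(terms, "resultLevel")))
    if (any(!lvls %in% c(0, 1))) {
      stop("unsupported feature: functionTerm resultLevel outside {0,1}",
           call. = FALSE)
    }
    default <- xml2::xml_find_first(tr, ".//q:defaultTerm", ns)
    default_lvl <- if (inherits(default, "xml_missing")) 0 else
      suppressWarnings(as.numeric(qattr(default, "resultLevel")))
    if (is.na(default_lvl)) default_lvl <- 0
    asts <- lapply(terms, function(t) {
      math <- xml2::xml_find_first(t, ".//*[local-name() = 'math']")
      if (inherits(math, "xml_missing")) {
        stop("functionTerm without <math>", call. = FALSE)
      }
      qual_math_to_ast(math, ids)
    })
    keep <- if (default_lvl == 0) lvls == 1 else lvls == 0
    asts <- asts[keep]
    rule_ast <- if (length(asts) == 0L) {
      list(op = "const", value = as.integer(default_lvl))
    } else if (length(asts) == 1L) {
      asts[[1]]
    } else {
      list(op = "or", args = asts)
    }
    if (default_lvl == 1) rule_ast <- list(op = "not", x = rule_ast)
    for (oid in out_ids) {
      if (!oid %in% ids) {
        stop("transition output references unknown species '", oid, "'",
             call. = FALSE)
      }
      if (has_rule[[oid]]) {
        stop("species '", oid, "' has more than one incoming transition",
             call. = FALSE)
      }
      rules[[oid]] <- bool_expr_deparse(rule_ast)
      has_rule[[oid]] <- TRUE
    }
  }
  model_id <- xml2::xml_attr(
    xml2::xml_find_first(doc, ".//*[local-name() = 'model']"), "id")
  boolean_network(unlist(rules),
                  name = name %||% (if (!is.na(model_id)) model_id else NULL))
}

# ---- SIF export and structural verification ---------------------------------

#' Export the signed interaction structure of a network (SIF)
#'
#' Emits one row per (regulator literal-occurrence class, target): a
#' regulator appearing only un-negated in a target's rule is `stimulatory`,
#' only negated is `inhibitory`, and both produce two rows. Identity
#' self-rules of input nodes and constant rules emit no rows.
#'
#' @param net A [boolean_network()].
#' @return Tibble with columns `source`, `sign`
#'   (`"stimulatory"`/`"inhibitory"`), `target`.
#' @examples
#' to_sif(boolean_network(c(A = "A", B = "!A")))
#' @export
to_sif <- function(net) {
  stopifnot(inherits(net, "boolean_network"))
  rows <- purrr::map_dfr(net$nodes, function(n) {
    ast <- net$rules[[n]]
    if (is_identity_rule(ast, n)) return(NULL)
    lits <- bool_expr_literals(ast)
    if (nrow(lits) == 0L) return(NULL)
    lits |>
      dplyr::distinct(.data$node, .data$negated) |>
      dplyr::transmute(
        source = .data$node,
        sign = ifelse(.data$negated, "inhibitory", "stimulatory"),
        target = n
      )
  })
  if (nrow(rows) == 0L) {
    return(tibble::tibble(source = character(), sign = character(),
                          target = character()))
  }
  tibble::as_tibble(rows) |>
    dplyr::arrange(match(.data$target, net$nodes),
                   match(.data$source, net$nodes), .data$sign)
}

#' Write a network's interaction structure as a 3-column SIF file
#'
#' @param net A [boolean_network()].
#' @param path Output path (tab-separated: source, sign, target).
#' @export
write_sif <- function(net, path) {
  sif <- to_sif(net)
  readr::write_tsv(sif, path, col_names = FALSE)
  invisible(path)
}

#' Identify input and output nodes of a network
#'
#' Inputs are nodes whose rule depends on no other node (constants or the
#' identity self-rule); outputs are nodes that appear in no other node's
#' rule. An isolated node can be both.
#'
#' @param net A [boolean_network()].
#' @return List with character vectors `inputs` and `outputs`.
#' @export
identify_terminals <- function(net) {
  stopifnot(inherits(net, "boolean_network"))
  deps <- lapply(net$nodes, function(n) {
    setdiff(bool_expr_vars(net$rules[[n]]), n)
  })
  names(deps) <- net$nodes
  inputs <- net$nodes[lengths(deps) == 0L]
  referenced <- unique(unlist(deps, use.names = FALSE))
  outputs <- setdiff(net$nodes, referenced)
  list(inputs = inputs, outputs = outputs)
}

#' Read a signed-interaction reference table
#'
#' @param path TSV with columns `regulator`, `target`, `sign` (values
#'   `stimulatory`/`inhibitory`).
#' @return Validated tibble.
#' @export
read_signed_reference <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  validate_signed_reference(tab)
}

validate_signed_reference <- function(tab) {
  tab <- tibble::as_tibble(tab)
  need <- c("regulator", "target", "sign")
  missing <- setdiff(need, names(tab))
  if (length(missing) > 0L) {
    stop("signed reference table lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  bad <- setdiff(unique(tab$sign), c("stimulatory", "inhibitory"))
  if (length(bad) > 0L) {
    stop("invalid sign label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(tab[, c("regulator", "target")]) > 0L) {
    stop("duplicate (regulator, target) pair in signed reference",
         call. = FALSE)
  }
  tab
}

#' Verify a network's structure against a signed-interaction reference
#'
#' Compares the network's SIF edges against a reference table of known
#' regulator-target interactions with stimulatory/inhibitory signs (e.g. a
#' curated signed-interaction database export). Report-only: nothing errors;
#' sign mismatches, edges absent from either side, and reference edges whose
#' direction is reversed in the network are listed with summary counts.
#'
#' @param net A [boolean_network()].
#' @param ref Signed reference tibble (`regulator`, `target`, `sign`) or path
#'   readable by [read_signed_reference()].
#' @return A `structure_verification` object: list of tibbles `matched`,
#'   `sign_mismatch`, `network_only`, `reference_only`, `direction_conflict`,
#'   `unknown_reference_nodes`, plus a one-row `summary` tibble.
#' @export
verify_structure <- function(net, ref) {
  stopifnot(inherits(net, "boolean_network"))
  if (is.character(ref) && length(ref) == 1L) ref <- read_signed_reference(ref)
  ref <- validate_signed_reference(ref)

  net_edges <- to_sif(net)
  ref_nodes <- unique(c(ref$regulator, ref$target))
  unknown <- setdiff(ref_nodes, net$nodes)
  ref_known <- ref |>
    dplyr::filter(.data$regulator %in% net$nodes,
                  .data$target %in% net$nodes)

  joined <- net_edges |>
    dplyr::left_join(ref_known,
                     by = c(source = "regulator", target = "target"),
                     suffix = c("_network", "_reference"))
  matched <- joined |>
    dplyr::filter(!is.na(.data$sign_reference),
                  .data$sign_network == .data$sign_reference)
  sign_mismatch <- joined |>
    dplyr::filter(!is.na(.data$sign_reference),
                  .data$sign_network != .data$sign_reference)
  network_only <- joined |>
    dplyr::filter(is.na(.data$sign_reference)) |>
    dplyr::select("source", sign = "sign_network", "target")

  net_pairs <- paste(net_edges$source, net_edges$target, sep = "\r")
  ref_absent <- ref_known |>
    dplyr::filter(!paste(.data$regulator, .data$target, sep = "\r") %in%
                    net_pairs)
  direction_conflict <- ref_absent |>
    dplyr::filter(paste(.data$target, .data$regulator, sep = "\r") %in%
                    net_pairs)
  reference_only <- ref_absent |>
    dplyr::anti_join(direction_conflict, by = c("regulator", "target"))

  summary <- tibble::tibble(
    n_network_edges = nrow(net_edges),
    n_reference_edges = nrow(ref),
    n_matched = nrow(matched),
    n_sign_mismatch = nrow(sign_mismatch),
    n_network_only = nrow(network_only),
    n_reference_only = nrow(reference_only),
    n_direction_conflict = nrow(direction_conflict),
    n_unknown_reference_nodes = length(unknown)
  )
  structure(
    list(matched = matched, sign_mismatch = sign_mismatch,
         network_only = network_only, reference_only = reference_only,
         direction_conflict = direction_conflict,
         unknown_reference_nodes = unknown, summary = summary),
    class = "structure_verification"
  )
}

#' @export
print.structure_verification <- function(x, ...) {
  cat("<structure_verification>\n")
  print(x$summary)
  invisible(x)
}
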