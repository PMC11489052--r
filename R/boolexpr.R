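# Recursive-descent parser for Boolean rule expressions.
#
# Grammar (BoolNet-style, case-preserving identifiers):
#   expr   := term ('|' term)*
#   term   := factor ('&' factor)*
#   factor := '!' factor | '(' expr ')' | ident | '0' | '1'
#
# Identifiers may contain letters, digits, '_', '.', '-' and ':' (miRNA and
# gene symbols such as hsa-miR-96-5p), but must start with a letter or '_'.
# ASTs are nested lists: list(op = "var", name =), list(op = "const", value =),
# list(op = "not", x =), list(op = "and"/"or", args = list(...)).

bool_tokenize <- function(text) {
  pat <- "[A-Za-z_][A-Za-z0-9_.:-]*|[01]|[!&|()]|\\s+"
  m <- gregexpr(pat, text, perl = TRUE)[[1]]
  if (m[1] == -1L && nzchar(trimws(text))) {
    stop("cannot tokenize rule: ", text, call. = FALSE)
  }
  toks <- regmatches(text, gregexpr(pat, text, perl = TRUE))[[1]]
  covered <- sum(nchar(toks))
  if (covered != nchar(text)) {
    stop("unexpected character in rule: ", text, call. = FALSE)
  }
  toks <- toks[!grepl("^\\s+$", toks)]
  toks
}

parse_bool_expr <- function(text) {
  toks <- bool_tokenize(text)
  if (length(toks) == 0L) stop("empty rule expression", call. = FALSE)
  pos <- 1L

  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  advance <- function() {
    tok <- peek()
    pos <<- pos + 1L
    tok
  }

  parse_expr <- function() {
    args <- list(parse_term())
    while (!is.na(peek()) && peek() == "|") {
      advance()
      args <- c(args, list(parse_term()))
    }
    if (length(args) == 1L) args[[1]] else list(op = "or", args = args)
  }
  parse_term <- function() {
    args <- list(parse_factor())
    while (!is.na(peek()) && peek() == "&") {
      advance()
      args <- c(args, list(parse_factor()))
    }
    if (length(args) == 1L) args[[1]] else list(op = "and", args = args)
  }
  parse_factor <- function() {
    tok <- peek()
    if (is.na(tok)) stop("unexpected end of rule expression", call. = FALSE)
    if (tok == "!") {
      advance()
      return(list(op = "not", x = parse_factor()))
    }
    if (tok == "(") {
      advance()
      inner <- parse_expr()
      if (is.na(peek()) || peek() != ")") {
        stop("missing closing parenthesis in rule", call. = FALSE)
      }
      advance()
      return(inner)
    }
    if (tok %in% c("0", "1")) {
      advance()
      return(list(op = "const", value = as.integer(tok)))
    }
    if (grepl("^[A-Za-z_]", tok)) {
      advance()
      return(list(op = "var", name = tok))
    }
    stop("unexpected token '", tok, "' in rule", call. = FALSE)
  }

  ast <- parse_expr()
  if (!is.na(peek())) {
    stop("trailing input after rule expression: '", peek(), "'", call. = FALSE)
  }
  ast
}

# Nodes referenced by an expression (unique, in order of first appearance).
bool_expr_vars <- function(ast) {
  switch(ast$op,
    var = ast$name,
    const = character(),
    not = bool_expr_vars(ast$x),
    unique(unlist(lapply(ast$args, bool_expr_vars), use.names = FALSE))
  )
}

# Evaluate against a named logical/integer state vector.
bool_expr_eval <- function(ast, state) {
  switch(ast$op,
    var = as.logical(state[[ast$name]]),
    const = ast$value == 1L,
    not = !bool_expr_eval(ast$x, state),
    and = all(vapply(ast$args, bool_expr_eval, logical(1), state = state)),
    or = any(vapply(ast$args, bool_expr_eval, logical(1), state = state))
  )
}

# Deparse back to BoolNet-style text. Parenthesizes OR inside AND and any
# non-atomic operand of NOT, so parse(deparse(ast)) is truth-table identical.
bool_expr_deparse <- function(ast) {
  switch(ast$op,
    var = ast$name,
    const = as.character(ast$value),
    not = {
      inner <- bool_expr_deparse(ast$x)
      if (ast$x$op %in% c("and", "or")) inner <- paste0("(", inner, ")")
      paste0("!", inner)
    },
    and = paste(vapply(ast$args, function(a) {
      s <- bool_expr_deparse(a)
      if (a$op == "or") paste0("(", s, ")") else s
    }, character(1)), collapse = " & "),
    or = paste(vapply(ast$args, bool_expr_deparse, character(1)),
               collapse = " | ")
  )
}

# Literal occurrences with negation parity: tibble(node, negated).
bool_expr_literals <- function(ast, negated = FALSE) {
  switch(ast$op,
    var = tibble::tibble(node = ast$name, negated = negated),
    const = tibble::tibble(node = character(), negated = logical()),
    not = bool_expr_literals(ast$x, !negated),
    dplyr::bind_rows(lapply(ast$args, bool_expr_literals, negated = negated))
  )
}

# Compile to reverse-Polish integer code for the C++ engine.
# Tokens: >= 0 node index (0-based), -1 NOT, -2 AND, -3 OR, -4 FALSE, -5 TRUE.
bool_expr_rpn <- function(ast, node_index) {
  switch(ast$op,
    var = node_index[[ast$name]] - 1L,
    const = if (ast$value == 1L) -5L else -4L,
    not = c(bool_expr_rpn(ast$x, node_index), -1L),
    and = {
      out <- bool_expr_rpn(ast$args[[1]], node_index)
      for (a in ast$args[-1]) out <- c(out, bool_expr_rpn(a, node_index), -2L)
      out
    },
    or = {
      out <- bool_expr_rpn(ast$args[[1]], node_index)
      for (a in ast$args[-1]) out <- c(out, bool_expr_rpn(a, node_index), -3L)
      out
    }
  )
}

# Full truth table of one rule over a fixed variable ordering.
bool_expr_truth_table <- function(ast, vars) {
  k <- length(vars)
  if (k == 0L) {
    return(bool_expr_eval(ast, stats::setNames(logical(0), character(0))))
  }
  n <- 2L^k
  out <- logical(n)
  for (i in seq_len(n) - 1L) {
    bits <- as.logical(bitwAnd(i, bitwShiftL(1L, seq_len(k) - 1L)) > 0L)
    state <- stats::setNames(as.list(bits), vars)
    out[i + 1L] <- bool_expr_eval(ast, state)
  }
  out
}
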