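# Independent brute-force oracles. These deliberately avoid the package's
# compiled engine and igraph: rules are evaluated with the R expression
# walker, reachability is computed by Boolean matrix closure, and DTW by
# exhaustive path recursion.

rand_net <- function(n_nodes, seed) {
  gen_toy_network("random", n_nodes = n_nodes, seed = seed)
}

# truth table of every node over the full state space of the network
net_truth_tables <- function(net) {
  k <- length(net$nodes)
  grid <- expand.grid(rep(list(c(FALSE, TRUE)), k))
  names(grid) <- net$nodes
  vapply(net$nodes, function(nd) {
    apply(grid, 1L, function(row) {
      cohortpbn:::bool_expr_eval(net$rules[[nd]], row)
    })
  }, logical(nrow(grid)))
}

# exhaustive warping-path DTW (feasible for series of length <= 5)
brute_dtw <- function(a, b) {
  rec <- function(i, j) {
    c0 <- abs(a[i] - b[j])
    if (i == 1L && j == 1L) return(c0)
    best <- Inf
    if (i > 1L && j > 1L) best <- min(best, rec(i - 1L, j - 1L))
    if (i > 1L) best <- min(best, rec(i - 1L, j))
    if (j > 1L) best <- min(best, rec(i, j - 1L))
    c0 + best
  }
  rec(length(a), length(b))
}

# asynchronous-update flippable set of one full state, via the R evaluator
brute_flips <- function(net, state_logical, free_nodes) {
  flips <- character(0)
  for (nd in free_nodes) {
    if (cohortpbn:::bool_expr_eval(net$rules[[nd]], state_logical) !=
        state_logical[[nd]]) {
      flips <- c(flips, nd)
    }
  }
  flips
}

# terminal SCCs of the asynchronous state digraph by transitive closure
brute_attractors <- function(net, forced = NULL) {
  nodes <- net$nodes
  k <- length(nodes)
  fvec <- rep(NA_integer_, k)
  names(fvec) <- nodes
  if (!is.null(forced)) fvec[names(forced)] <- as.integer(forced)
  free <- which(is.na(fvec))
  m <- length(free)
  S <- 2L^m
  decode <- function(s) {
    st <- ifelse(is.na(fvec), 0L, fvec)
    if (m > 0L) st[free] <- bitwAnd(bitwShiftR(s - 1L, seq_len(m) - 1L), 1L)
    stats::setNames(st, nodes)
  }
  A <- matrix(FALSE, S, S)
  for (s in seq_len(S)) {
    st <- decode(s)
    lst <- as.logical(st)
    names(lst) <- nodes
    flips <- brute_flips(net, lst, nodes[free])
    if (length(flips) == 0L) {
      A[s, s] <- TRUE
    } else {
      for (nd in flips) {
        j <- match(match(nd, nodes), free)
        A[s, bitwXor(s - 1L, bitwShiftL(1L, j - 1L)) + 1L] <- TRUE
      }
    }
  }
  R <- A | diag(TRUE, S)
  repeat {
    R2 <- R | (R %*% R > 0)
    if (identical(R2, R)) break
    R <- R2
  }
  scc <- integer(S)
  nid <- 0L
  for (s in seq_len(S)) {
    if (scc[s] == 0L) {
      nid <- nid + 1L
      scc[which(R[s, ] & R[, s])] <- nid
    }
  }
  terminal <- integer(0)
  for (cc in seq_len(nid)) {
    mem <- which(scc == cc)
    reach <- which(colSums(R[mem, , drop = FALSE]) > 0)
    if (all(scc[reach] == cc)) terminal <- c(terminal, cc)
  }
  lapply(sort(terminal), function(cc) {
    states <- sort(which(scc == cc))
    vals <- vapply(states, decode, integer(k))
    mat <- if (is.matrix(vals)) t(vals) else matrix(vals, ncol = 1L)
    colnames(mat) <- nodes
    mat
  })
}

# canonical fingerprint of an attractor set (order- and type-insensitive)
attractor_fingerprint <- function(att_states) {
  sort(vapply(att_states, function(mat) {
    paste(sort(apply(mat, 1L, paste, collapse = "")), collapse = "|")
  }, character(1)))
}

small_scenario <- function(seed = 1, n = 60, ...) {
  synthetic_scenario(seed = seed,
                     cohort_sizes = c(clinical = n, swedd = n),
                     n_mirna = 120, ...)
}
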