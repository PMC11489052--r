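#' Specify probabilistic initial states
#'
#' Maps node identifiers to their ON-probability at step 0 of a simulation;
#' nodes not mentioned receive `default_probability`. This is the carrier of
#' the cohort parameterization: common-language effect-size probabilities of
#' the targeting miRNAs are assigned here.
#'
#' @param probabilities Named numeric vector of ON-probabilities in `[0, 1]`
#'   (may be empty).
#' @param default_probability ON-probability for unmapped nodes (default 0.5,
#'   maximum entropy).
#' @return An `initial_state_spec` object.
#' @export
initial_state_spec <- function(probabilities = numeric(0),
                               default_probability = 0.5) {
  probabilities <- unlist(probabilities)
  if (length(probabilities) > 0L && is.null(names(probabilities))) {
    stop("probabilities must be named by node", call. = FALSE)
  }
  p_all <- c(probabilities, default_probability)
  if (any(!is.finite(p_all)) || any(p_all < 0) || any(p_all > 1)) {
    stop("initial-state probabilities must lie in [0, 1]", call. = FALSE)
  }
  structure(list(probabilities = probabilities,
                 default_probability = default_probability),
            class = "initial_state_spec")
}

#' @export
print.initial_state_spec <- function(x, ...) {
  cat("<initial_state_spec: ", length(x$probabilities),
      " explicit node(s), default p = ", x$default_probability, ">\n",
      sep = "")
  invisible(x)
}

#' Pin nodes permanently to 0 or 1 (point mutations)
#'
#' Forced nodes encode permanent perturbations: a knockout pins a node to 0,
#' an overexpression pins it to 1. Forced nodes are set at initialization and
#' excluded from the asynchronous update set for the whole walk.
#'
#' @param forced Named integer/numeric vector with values 0 or 1 (may be
#'   empty).
#' @return A `forced_nodes` object.
#' @export
forced_nodes <- function(forced = integer(0)) {
  forced <- unlist(forced)
  if (length(forced) > 0L) {
    if (is.null(names(forced)) || any(!nzchar(names(forced)))) {
      stop("forced values must be named by node", call. = FALSE)
    }
    if (!all(forced %in% c(0, 1))) {
      stop("forced values must be 0 (knockout) or 1 (overexpression)",
           call. = FALSE)
    }
    if (anyDuplicated(names(forced)) > 0L) {
      stop("duplicate forced node", call. = FALSE)
    }
  }
  structure(list(forced = stats::setNames(as.integer(forced), names(forced))),
            class = "forced_nodes")
}

#' @export
print.forced_nodes <- function(x, ...) {
  cat("<forced_nodes: ", length(x$forced), " pinned>\n", sep = "")
  if (length(x$forced) > 0L) {
    print(x$forced)
  }
  invisible(x)
}

as_forced <- function(forced) {
  if (is.null(forced)) return(forced_nodes())
  if (inherits(forced, "forced_nodes")) return(forced)
  forced_nodes(forced)
}

as_init_spec <- function(spec) {
  if (is.null(spec)) return(initial_state_spec())
  if (inherits(spec, "initial_state_spec")) return(spec)
  if (is.numeric(spec) && length(spec) == 1L && is.null(names(spec))) {
    return(initial_state_spec(default_probability = spec))
  }
  initial_state_spec(spec)
}

check_nodes_known <- function(net, ids, what) {
  unknown <- setdiff(ids, net$nodes)
  if (length(unknown) > 0L) {
    stop(what, " name(s) absent from network: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
}

init_prob_vector <- function(net, spec) {
  spec <- as_init_spec(spec)
  check_nodes_known(net, names(spec$probabilities), "initial-state")
  p <- rep(spec$default_probability, length(net$nodes))
  names(p) <- net$nodes
  p[names(spec$probabilities)] <- spec$probabilities
  p
}

forced_vector <- function(net, forced) {
  forced <- as_forced(forced)
  check_nodes_known(net, names(forced$forced), "forced-node")
  f <- rep(-1L, length(net$nodes))
  names(f) <- net$nodes
  f[names(forced$forced)] <- forced$forced
  f
}

compile_network <- function(net) {
  idx <- stats::setNames(seq_along(net$nodes), net$nodes)
  rpn <- lapply(net$rules, bool_expr_rpn, node_index = idx)
  len <- lengths(rpn)
  list(code = as.integer(unlist(rpn, use.names = FALSE)),
       offset = as.integer(cumsum(c(0L, len[-length(len)]))),
       len = as.integer(len))
}

#' Sample one random initial state
#'
#' Each node is set to 1 independently with its specified ON-probability;
#' forced nodes are overridden afterwards. Uses R's RNG stream (set a seed
#' with [set.seed()] for reproducibility).
#'
#' @param net A [boolean_network()].
#' @param spec An [initial_state_spec()] (or named probability vector).
#' @param forced Optional [forced_nodes()].
#' @return Named integer vector of 0/1 states over the network's nodes.
#' @export
sample_initial_state <- function(net, spec = NULL, forced = NULL) {
  p <- init_prob_vector(net, spec)
  state <- as.integer(stats::runif(length(p)) < p)
  names(state) <- net$nodes
  f <- forced_vector(net, forced)
  state[f >= 0L] <- f[f >= 0L]
  state
}

#' Perform one asynchronous update step
#'
#' Computes the set U of non-forced nodes whose rule output disagrees with
#' their current value. If U is empty the state is a fixed point and is
#' returned unchanged; otherwise exactly one node of U, chosen uniformly at
#' random (R's RNG), is flipped.
#'
#' @param net A [boolean_network()].
#' @param state Named 0/1 vector over all nodes.
#' @param forced Optional [forced_nodes()].
#' @return The next state (named 0/1 vector).
#' @export
async_step <- function(net, state, forced = NULL) {
  stopifnot(inherits(net, "boolean_network"))
  if (is.null(names(state))) names(state) <- net$nodes
  if (!setequal(names(state), net$nodes)) {
    stop("state must assign every network node", call. = FALSE)
  }
  f <- forced_vector(net, forced)
  st <- as.logical(state[net$nodes])
  names(st) <- net$nodes
  targets <- vapply(net$nodes, function(n) {
    bool_expr_eval(net$rules[[n]], st)
  }, logical(1))
  flippable <- which(f < 0L & targets != st)
  if (length(flippable) == 0L) {
    return(stats::setNames(as.integer(st), net$nodes))
  }
  pick <- if (length(flippable) == 1L) flippable else
    flippable[sample.int(length(flippable), 1L)]
  st[pick] <- !st[pick]
  stats::setNames(as.integer(st), net$nodes)
}

#' Simulate an ensemble of asynchronous random walks
#'
#' Runs `n_reps` independent walks of `n_steps` asynchronous single-node
#' updates, each from an independently sampled initial state, and estimates
#' the per-step ON-probability of every node as the fraction of repetitions
#' in which it is ON. Defaults (100 steps, 1000 repetitions) are the standard
#' operating point; `n_reps = 100` is a lighter preset used for trajectory
#' figures. Randomness comes from a counter-based stream derived from `seed`,
#' so results are bit-reproducible and independent of R's RNG state.
#'
#' @param net A [boolean_network()].
#' @param spec An [initial_state_spec()], named probability vector, or a
#'   single default probability.
#' @param forced Optional [forced_nodes()] (knockouts/overexpressions).
#' @param n_steps Number of update steps (>= 1).
#' @param n_reps Number of repetitions (>= 1).
#' @param seed Integer master seed.
#' @param label Optional condition label carried in the result.
#' @return A `trajectory_ensemble`: list with `prob` ((n_steps+1) x nodes
#'   matrix of ON-probabilities), `nodes`, `steps`, `n_reps`, `seed`,
#'   `forced`, `label`.
#' @export
simulate_ensemble <- function(net, spec = NULL, forced = NULL,
                              n_steps = 100, n_reps = 1000, seed = 1,
                              label = NULL) {
  stopifnot(inherits(net, "boolean_network"))
  if (n_steps < 1 || n_reps < 1) {
    stop("n_steps and n_reps must be >= 1", call. = FALSE)
  }
  p <- init_prob_vector(net, spec)
  f <- forced_vector(net, forced)
  comp <- compile_network(net)
  prob <- pbn_simulate_cpp(comp$code, comp$offset, comp$len,
                           unname(p), unname(f),
                           as.integer(n_steps), as.integer(n_reps),
                           as.numeric(seed))
  dimnames(prob) <- list(step = 0:n_steps, node = net$nodes)
  structure(
    list(prob = prob, nodes = net$nodes, steps = as.integer(n_steps),
         n_reps = as.integer(n_reps), seed = as.integer(seed),
         forced = as_forced(forced)$forced, label = label),
    class = "trajectory_ensemble"
  )
}

#' @export
print.trajectory_ensemble <- function(x, ...) {
  cat("<trajectory_ensemble", if (!is.null(x$label)) paste0(" '", x$label, "'"),
      ": ", length(x$nodes), " nodes, ", x$steps, " steps, ", x$n_reps,
      " repetitions, seed ", x$seed, ">\n", sep = "")
  invisible(x)
}

free_node_setup <- function(net, forced) {
  f <- forced_vector(net, forced)
  free_idx <- which(f < 0L)
  if (length(free_idx) > 12L) {
    stop("exact state-space methods support at most 12 non-forced nodes ",
         "(network has ", length(free_idx), "); use simulate_ensemble()",
         call. = FALSE)
  }
  list(f = f, free_idx = free_idx)
}

# Flippable sets per enumerated free-node state (list of 0-based free-node
# positions), shared by the exact oracle and attractor enumeration.
transition_structure <- function(net, forced = NULL) {
  setup <- free_node_setup(net, forced)
  comp <- compile_network(net)
  flips <- pbn_transitions_cpp(comp$code, comp$offset, comp$len,
                               unname(setup$f),
                               as.integer(setup$free_idx - 1L))
  c(setup, list(flips = flips, n_states = length(flips)))
}

#' Exact state distribution of the asynchronous jump chain
#'
#' Builds the transition matrix of the embedded jump chain over the free-node
#' state space -- from state s each flippable node is chosen with probability
#' 1/|U(s)|, fixed points self-loop -- and propagates the exact
#' product-Bernoulli initial distribution for `n_steps` steps. Serves as the
#' independent oracle for the Monte-Carlo engine on small networks (at most
#' 12 non-forced nodes).
#'
#' @inheritParams simulate_ensemble
#' @return List with `marginals` ((n_steps+1) x nodes matrix of exact
#'   ON-probabilities) and `distribution` (final state-probability vector over
#'   the free-node state space).
#' @export
exact_state_distribution <- function(net, spec = NULL, forced = NULL,
                                     n_steps = 100) {
  ts <- transition_structure(net, forced)
  m <- length(ts$free_idx)
  S <- ts$n_states
  p <- init_prob_vector(net, spec)

  # transition triplets of the jump chain
  from <- integer(0); to <- integer(0); w <- numeric(0)
  for (s in seq_len(S)) {
    fl <- ts$flips[[s]]
    if (length(fl) == 0L) {
      from <- c(from, s); to <- c(to, s); w <- c(w, 1)
    } else {
      dest <- bitwXor(s - 1L, bitwShiftL(1L, fl)) + 1L
      from <- c(from, rep(s, length(fl)))
      to <- c(to, dest)
      w <- c(w, rep(1 / length(fl), length(fl)))
    }
  }
  P <- Matrix::sparseMatrix(i = from, j = to, x = w, dims = c(S, S))

  # product-Bernoulli initial distribution over free nodes
  dist <- rep(1, S)
  if (m > 0L) {
    pf <- p[ts$free_idx]
    for (j in seq_len(m)) {
      bit <- bitwAnd(bitwShiftR(seq_len(S) - 1L, j - 1L), 1L)
      dist <- dist * ifelse(bit == 1L, pf[j], 1 - pf[j])
    }
  }

  n_nodes <- length(net$nodes)
  marg <- matrix(0, n_steps + 1L, n_nodes,
                 dimnames = list(step = 0:n_steps, node = net$nodes))
  bit_on <- if (m > 0L) {
    vapply(seq_len(m), function(j) {
      bitwAnd(bitwShiftR(seq_len(S) - 1L, j - 1L), 1L) == 1L
    }, logical(S))
  } else {
    matrix(logical(0), nrow = S, ncol = 0)
  }
  if (m == 1L) bit_on <- matrix(bit_on, ncol = 1L)
  fill_marginals <- function(t, dist) {
    row <- ifelse(ts$f >= 0L, as.numeric(ts$f), 0)
    if (m > 0L) {
      row[ts$free_idx] <- vapply(seq_len(m), function(j) {
        sum(dist[bit_on[, j]])
      }, numeric(1))
    }
    marg[t, ] <<- pmin(pmax(row, 0), 1)  # guard sparse-arithmetic round-off
  }
  fill_marginals(1L, dist)
  for (t in seq_len(n_steps)) {
    dist <- as.numeric(Matrix::crossprod(P, dist))
    fill_marginals(t + 1L, dist)
  }
  list(marginals = marg, distribution = dist)
}

#' Enumerate attractors of the asynchronous state-transition graph
#'
#' Returns the terminal strongly-connected components of the asynchronous
#' transition digraph over the free-node state space (at most 12 non-forced
#' nodes). Singleton components whose state has an empty flippable set are
#' fixed points; larger components are complex (cyclic) attractors. Every
#' state of the graph reaches at least one returned attractor.
#'
#' @inheritParams simulate_ensemble
#' @return List of attractors. Each attractor is a list with `type`
#'   (`"fixed_point"` or `"cycle"`) and `states`, a 0/1 matrix with one row
#'   per attractor state and one column per network node.
#' @export
enumerate_attractors <- function(net, forced = NULL) {
  ts <- transition_structure(net, forced)
  S <- ts$n_states
  m <- length(ts$free_idx)

  edges <- integer(0)
  for (s in seq_len(S)) {
    fl <- ts$flips[[s]]
    dest <- if (length(fl) == 0L) s else
      bitwXor(s - 1L, bitwShiftL(1L, fl)) + 1L
    edges <- c(edges, rbind(rep(s, length(dest)), dest))
  }
  g <- igraph::make_graph(edges, n = S, directed = TRUE)
  comp <- igraph::components(g, mode = "strong")
  memb <- comp$membership
  # terminal SCCs: no edge leaves the component
  el <- igraph::as_edgelist(g, names = FALSE)
  leaving <- unique(memb[el[, 1]][memb[el[, 1]] != memb[el[, 2]]])
  terminal <- setdiff(seq_len(comp$no), leaving)

  decode <- function(s) {
    st <- ifelse(ts$f >= 0L, ts$f, 0L)
    if (m > 0L) {
      st[ts$free_idx] <- bitwAnd(bitwShiftR(s - 1L, seq_len(m) - 1L), 1L)
    }
    st
  }
  lapply(sort(terminal), function(cc) {
    states <- sort(which(memb == cc))
    vals <- vapply(states, decode, integer(length(net$nodes)))
    mat <- if (is.matrix(vals)) t(vals) else matrix(vals, ncol = 1L)
    colnames(mat) <- net$nodes
    type <- if (nrow(mat) == 1L && length(ts$flips[[states[1]]]) == 0L) {
      "fixed_point"
    } else {
      "cycle"
    }
    list(type = type, states = mat)
  })
}

#' Scan single-node forced perturbations
#'
#' For every node, simulates the ensemble with that node pinned to 0 and to
#' 1, and reports per output node (by default the network's terminal outputs)
#' the maximum absolute change in ON-probability relative to the unperturbed
#' ensemble across all steps.
#'
#' @inheritParams simulate_ensemble
#' @param outputs Nodes to read effects on (default: [identify_terminals()]
#'   outputs).
#' @return Tibble with columns `node`, `forced_value`, `output`,
#'   `max_abs_effect` (2 x nodes x outputs rows).
#' @export
perturbation_scan <- function(net, spec = NULL, n_steps = 100, n_reps = 1000,
                              seed = 1, outputs = NULL) {
  outputs <- outputs %||% identify_terminals(net)$outputs
  check_nodes_known(net, outputs, "output")
  baseline <- simulate_ensemble(net, spec, NULL, n_steps, n_reps, seed)
  purrr::map_dfr(net$nodes, function(node) {
    purrr::map_dfr(c(0L, 1L), function(v) {
      pert <- simulate_ensemble(net, spec,
                                forced_nodes(stats::setNames(v, node)),
                                n_steps, n_reps, seed)
      tibble::tibble(
        node = node,
        forced_value = v,
        output = outputs,
        max_abs_effect = vapply(outputs, function(o) {
          max(abs(pert$prob[, o] - baseline$prob[, o]))
        }, numeric(1))
      )
    })
  })
}
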