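#' Dynamic time warping distance between two series
#'
#' Classic dynamic-programming DTW with step pattern \{match, insert,
#' delete\}, boundary-aligned (first point to first, last to last), local
#' cost `|a_i - b_j|` by default. The score is the minimal cumulative local
#' cost over all admissible warping paths; lower means more similar.
#'
#' @param a,b Non-empty numeric series.
#' @param cost Local cost function of two scalars (default absolute
#'   difference).
#' @param window Optional Sakoe-Chiba band half-width (in steps); `NULL`
#'   (default) means unconstrained, appropriate for short series.
#' @return Non-negative numeric scalar.
#' @examples
#' dtw_distance(c(0, 1), c(0, 0, 1))  # warping absorbs the repeat: 0
#' @export
dtw_distance <- function(a, b, cost = function(x, y) abs(x - y),
                         window = NULL) {
  n <- length(a); m <- length(b)
  if (n == 0L || m == 0L) stop("series must be non-empty", call. = FALSE)
  D <- matrix(Inf, n + 1L, m + 1L)
  D[1L, 1L] <- 0
  for (i in seq_len(n)) {
    js <- if (is.null(window)) seq_len(m) else {
      seq(max(1L, i - window), min(m, i + window))
    }
    for (j in js) {
      D[i + 1L, j + 1L] <- cost(a[i], b[j]) +
        min(D[i, j], D[i, j + 1L], D[i + 1L, j])
    }
  }
  D[n + 1L, m + 1L]
}

#' Split a trajectory into contiguous simulation stages
#'
#' Divides the step axis into `n_stages` contiguous equal-length blocks
#' (remainder going to the last block) labeled `early`/`mid`/`late` for the
#' default three stages, or takes explicit stage boundaries (e.g. detected
#' change points): boundaries `c(b1, b2)` produce stages `[1, b1)`,
#' `[b1, b2)`, `[b2, end]` in 1-based series indices.
#'
#' @param n_points Length of the series being staged (e.g. `steps + 1` for a
#'   trajectory ensemble).
#' @param n_stages Number of stages (default 3).
#' @param breakpoints Optional strictly increasing interior 1-based indices
#'   overriding the equal split.
#' @return Tibble with columns `stage` (factor in temporal order), `from`,
#'   `to` (1-based inclusive series indices).
#' @export
stage_boundaries <- function(n_points, n_stages = 3, breakpoints = NULL) {
  if (n_stages < 1L) stop("n_stages must be >= 1", call. = FALSE)
  if (!is.null(breakpoints)) {
    breakpoints <- sort(unique(as.integer(breakpoints)))
    if (any(breakpoints <= 1L) || any(breakpoints > n_points)) {
      stop("breakpoints must be interior to the series", call. = FALSE)
    }
    from <- c(1L, breakpoints)
    to <- c(breakpoints - 1L, n_points)
  } else {
    if (n_points < n_stages) {
      stop("series shorter than the number of stages", call. = FALSE)
    }
    base <- n_points %/% n_stages
    sizes <- rep(base, n_stages)
    sizes[n_stages] <- sizes[n_stages] + n_points - base * n_stages
    to <- cumsum(sizes)
    from <- c(1L, utils::head(to, -1L) + 1L)
  }
  labels <- if (length(from) == 3L) c("early", "mid", "late") else
    paste0("stage", seq_along(from))
  tibble::tibble(stage = factor(labels, levels = labels),
                 from = as.integer(from), to = as.integer(to))
}

#' Extract per-stage sub-series of a trajectory ensemble
#'
#' @param traj A `trajectory_ensemble`.
#' @param n_stages Number of contiguous stages (default 3:
#'   early/mid/late).
#' @param breakpoints Optional explicit stage boundaries (see
#'   [stage_boundaries()]).
#' @return Long tibble: `node`, `stage`, `step`, `probability`.
#' @export
split_stages <- function(traj, n_stages = 3, breakpoints = NULL) {
  stopifnot(inherits(traj, "trajectory_ensemble"))
  bounds <- stage_boundaries(nrow(traj$prob), n_stages, breakpoints)
  purrr::pmap_dfr(bounds, function(stage, from, to) {
    sub <- traj$prob[from:to, , drop = FALSE]
    tibble::tibble(
      node = rep(colnames(sub), each = nrow(sub)),
      stage = stage,
      step = rep(as.integer(rownames(sub)), times = ncol(sub)),
      probability = as.vector(sub)
    )
  })
}

#' Staged DTW comparison of endpoint trajectories across conditions
#'
#' For every endpoint node and simulation stage, computes the DTW distance
#' between each condition's stage sub-series and a comparator: either a named
#' reference condition (default mode; typically an unparameterized baseline
#' simulated with all initial probabilities 0.5 and no forced nodes) or every
#' unordered pair of conditions (`reference = "pairwise"`). Lower scores mean
#' the condition's endpoint dynamics track the comparator more closely.
#'
#' @param conditions Named list of `trajectory_ensemble` objects sharing the
#'   network and step count.
#' @param reference Name of the reference condition in `conditions`, or
#'   `"pairwise"`.
#' @param endpoints Character vector of endpoint (output) nodes to score.
#' @param n_stages,breakpoints Passed to [stage_boundaries()].
#' @return A `dtw_stage_table` tibble: `endpoint`, `condition` (and
#'   `condition2` in pairwise mode), `stage`, `dtw`.
#' @export
stage_dtw_table <- function(conditions, reference = "pairwise", endpoints,
                            n_stages = 3, breakpoints = NULL) {
  if (is.null(names(conditions)) || any(!nzchar(names(conditions)))) {
    stop("conditions must be a named list", call. = FALSE)
  }
  steps <- unique(vapply(conditions, function(tr) nrow(tr$prob), integer(1)))
  if (length(steps) != 1L) {
    stop("all conditions must share the step count", call. = FALSE)
  }
  for (nm in names(conditions)) {
    missing <- setdiff(endpoints, conditions[[nm]]$nodes)
    if (length(missing) > 0L) {
      stop("endpoint(s) absent from condition '", nm, "': ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  bounds <- stage_boundaries(steps, n_stages, breakpoints)
  series <- function(cond, endpoint, from, to) {
    conditions[[cond]]$prob[from:to, endpoint]
  }
  cmp <- function(cond_a, cond_b) {
    purrr::pmap_dfr(bounds, function(stage, from, to) {
      tibble::tibble(
        endpoint = endpoints,
        stage = stage,
        dtw = unname(vapply(endpoints, function(e) {
          dtw_distance(series(cond_a, e, from, to),
                       series(cond_b, e, from, to))
        }, numeric(1)))
      )
    })
  }
  nms <- sort(names(conditions))
  out <- if (identical(reference, "pairwise")) {
    pairs <- utils::combn(nms, 2L)
    purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
      cmp(pairs[1L, k], pairs[2L, k]) |>
        dplyr::mutate(condition = pairs[1L, k], condition2 = pairs[2L, k])
    })
  } else {
    if (!reference %in% names(conditions)) {
      stop("reference condition '", reference, "' not supplied",
           call. = FALSE)
    }
    purrr::map_dfr(nms, function(nm) {
      cmp(nm, reference) |> dplyr::mutate(condition = nm)
    })
  }
  out <- out |>
    dplyr::select(dplyr::any_of(c("endpoint", "condition", "condition2",
                                  "stage", "dtw"))) |>
    dplyr::arrange(.data$stage, .data$endpoint)
  class(out) <- c("dtw_stage_table", class(out))
  attr(out, "reference") <- reference
  out
}

#' Pearson correlation of DTW score profiles between two conditions
#'
#' Correlates, across shared endpoints at one stage, the DTW score vectors
#' of two conditions. A coefficient at or above `threshold` (default 0.98)
#' flags the pair as highly similar in how their endpoint dynamics deviate
#' from the comparator.
#'
#' @param table A [stage_dtw_table()] result in reference mode.
#' @param pair Character vector of two condition names.
#' @param stage Stage label to correlate at.
#' @param threshold High-similarity flag threshold on r (default 0.98).
#' @return One-row tibble: `condition_a`, `condition_b`, `stage`,
#'   `n_endpoints`, `r`, `high_similarity` (`NA` r and `FALSE` flag when a
#'   score vector has zero variance).
#' @export
correlate_dtw_profiles <- function(table, pair, stage, threshold = 0.98) {
  stopifnot(length(pair) == 2L)
  stage_chr <- as.character(stage)
  wide <- tibble::as_tibble(table) |>
    dplyr::filter(.data$condition %in% pair,
                  as.character(.data$stage) == stage_chr) |>
    dplyr::select("endpoint", "condition", "dtw") |>
    tidyr::pivot_wider(names_from = "condition", values_from = "dtw") |>
    tidyr::drop_na()
  if (nrow(wide) < 2L || !all(pair %in% names(wide))) {
    stop("need >= 2 shared endpoints with scores for both conditions",
         call. = FALSE)
  }
  x <- wide[[pair[1]]]; y <- wide[[pair[2]]]
  r <- if (stats::sd(x) == 0 || stats::sd(y) == 0) NA_real_ else
    stats::cor(x, y)
  tibble::tibble(condition_a = pair[1], condition_b = pair[2],
                 stage = as.character(stage), n_endpoints = nrow(wide),
                 r = r,
                 high_similarity = !is.na(r) & r >= threshold)
}

#' Correlate DTW profiles for all condition pairs and stages
#'
#' @param table A [stage_dtw_table()] in reference mode.
#' @param threshold Passed to [correlate_dtw_profiles()].
#' @return Tibble with one row per condition pair and stage.
#' @export
dtw_correlation_table <- function(table, threshold = 0.98) {
  conds <- sort(unique(table$condition))
  ref <- attr(table, "reference")
  if (!is.null(ref) && !identical(ref, "pairwise")) {
    conds <- setdiff(conds, ref)  # the reference's self-scores are all zero
  }
  stages <- levels(table$stage) %||% unique(as.character(table$stage))
  if (length(conds) < 2L) {
    stop("need at least two conditions", call. = FALSE)
  }
  pairs <- utils::combn(conds, 2L)
  purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
    purrr::map_dfr(stages, function(st) {
      correlate_dtw_profiles(table, pairs[, k], st, threshold)
    })
  })
}

# O(1) residual sum of squares of a simple linear fit on y[i..j] given
# cumulative sums (x = 1-based index).
segment_rss_fun <- function(y) {
  n <- length(y)
  x <- seq_len(n)
  cy <- c(0, cumsum(y)); cyy <- c(0, cumsum(y^2))
  cx <- c(0, cumsum(x)); cxx <- c(0, cumsum(x^2))
  cxy <- c(0, cumsum(x * y))
  function(i, j) {
    k <- j - i + 1
    Sy <- cy[j + 1] - cy[i]; Syy <- cyy[j + 1] - cyy[i]
    Sx <- cx[j + 1] - cx[i]; Sxx <- cxx[j + 1] - cxx[i]
    Sxy <- cxy[j + 1] - cxy[i]
    syy <- Syy - Sy^2 / k
    sxx <- Sxx - Sx^2 / k
    sxy <- Sxy - Sx * Sy / k
    rss <- if (sxx <= 0) syy else syy - sxy^2 / sxx
    max(rss, 0)
  }
}

#' Detect change points by piecewise-linear regression
#'
#' Fits piecewise-linear least-squares models with 0..`max_breaks`
#' breakpoints by exact dynamic programming over all candidate break indices
#' and selects the number of segments by BIC. Residual sum of squares is
#' non-increasing in the number of allowed breaks; BIC penalizes the extra
#' two coefficients and one boundary per segment.
#'
#' @param series Numeric series (length >= 2 * (max_breaks + 1)).
#' @param max_breaks Maximum number of breakpoints (>= 0).
#' @param min_segment Minimum points per segment (default 3).
#' @return A `change_point_fit`: list with `breakpoints` (1-based indices
#'   where a new segment starts; empty when a single line suffices),
#'   `segments` tibble (`segment`, `from`, `to`, `intercept`, `slope`),
#'   `rss`, `bic`, `n_breaks`, `candidates` (per-k RSS/BIC table), `series`.
#' @export
detect_change_points <- function(series, max_breaks = 3, min_segment = 3) {
  if (max_breaks < 0) stop("max_breaks must be >= 0", call. = FALSE)
  n <- length(series)
  if (n < 2 * (max_breaks + 1)) {
    stop("series too short for ", max_breaks, " breakpoint(s)",
         call. = FALSE)
  }
  min_segment <- max(2L, as.integer(min_segment))
  rss_ij <- segment_rss_fun(series)
  kmax <- max_breaks + 1L

  # best[k, j]: minimal RSS of fitting y[1..j] with k segments
  best <- matrix(Inf, kmax, n)
  argmin <- matrix(NA_integer_, kmax, n)
  for (j in seq_len(n)) if (j >= min_segment) best[1L, j] <- rss_ij(1L, j)
  if (kmax > 1L) {
    for (k in 2L:kmax) {
      for (j in seq_len(n)) {
        if (j < k * min_segment) next
        is <- seq((k - 1L) * min_segment + 1L, j - min_segment + 1L)
        vals <- best[k - 1L, is - 1L] + vapply(is, function(i) rss_ij(i, j),
                                               numeric(1))
        w <- which.min(vals)
        best[k, j] <- vals[w]
        argmin[k, j] <- is[w]
      }
    }
  }

  bic_k <- vapply(seq_len(kmax), function(k) {
    rss <- best[k, n]
    p <- 2 * k + (k - 1)  # intercept+slope per segment, plus boundaries
    n * log(max(rss, 1e-300) / n) + p * log(n)
  }, numeric(1))
  k_sel <- which.min(bic_k)

  # backtrack segment starts
  starts <- integer(k_sel)
  j <- n
  for (k in rev(seq_len(k_sel))) {
    starts[k] <- if (k == 1L) 1L else argmin[k, j]
    j <- starts[k] - 1L
  }
  ends <- c(starts[-1L] - 1L, n)
  segments <- purrr::map_dfr(seq_len(k_sel), function(k) {
    idx <- starts[k]:ends[k]
    fit <- stats::lm.fit(cbind(1, idx), series[idx])
    tibble::tibble(segment = k, from = starts[k], to = ends[k],
                   intercept = unname(fit$coefficients[1]),
                   slope = unname(fit$coefficients[2]))
  })
  structure(
    list(breakpoints = starts[-1L], segments = segments,
         rss = best[k_sel, n], bic = bic_k[k_sel], n_breaks = k_sel - 1L,
         candidates = tibble::tibble(n_segments = seq_len(kmax),
                                     rss = best[, n], bic = bic_k),
         series = series),
    class = "change_point_fit"
  )
}

#' @export
print.change_point_fit <- function(x, ...) {
  cat("<change_point_fit: ", x$n_breaks, " breakpoint(s)",
      if (x$n_breaks > 0) paste0(" at ", paste(x$breakpoints, collapse = ", ")),
      ", BIC ", signif(x$bic, 5), ">\n", sep = "")
  invisible(x)
}
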