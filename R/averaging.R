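#' Bootstrap structure learning
#'
#' Learns one DAG per with-replacement resample of the rows (resample size =
#' n), each by [structural_em()] (which collapses to a single hill climb when
#' the resample is complete). Reproducible under `seed`: resample `b` uses
#' sub-seed `seed + b`.
#'
#' @param data data frame, possibly with missing values.
#' @param blacklist optional forbidden-arc matrix.
#' @param B number of bootstrap resamples (the conventional default for this
#'   analysis is 200).
#' @param seed optional integer seed.
#' @param ... further arguments to [structural_em()] (`max_iter`,
#'   `score_tol`, `restarts`, `max_parents`, `binary`).
#' @return list of `B` [dag] objects.
#' @export
bootstrap_structures <- function(data, blacklist = NULL, B = 200, seed = NULL, ...) {
  stopifnot(B >= 1)
  X <- as.data.frame(data)
  n <- nrow(X)
  lapply(seq_len(B), function(b) {
    sub_seed <- if (is.null(seed)) NULL else seed + b
    rows <- with_seed(sub_seed, sample.int(n, n, replace = TRUE))
    em_seed <- if (is.null(sub_seed)) NULL else (sub_seed * 7) %% 2147483647
    net <- structural_em(X[rows, , drop = FALSE], blacklist, seed = em_seed, ...)
    net$graph
  })
}

#' Arc strengths from a collection of DAGs
#'
#' The strength of a directed arc is the fraction of networks containing it.
#'
#' @param dags non-empty list of [dag] objects over a common node set.
#' @return data frame (`from`, `to`, `strength`) for every ordered node pair
#'   with positive strength, sorted by decreasing strength then names.
#' @export
arc_strengths <- function(dags) {
  if (!length(dags)) stop("need at least one network")
  nodes <- dags[[1]]$nodes
  for (g in dags) {
    if (!setequal(g$nodes, nodes)) stop("networks have inconsistent node sets")
  }
  counts <- matrix(0, length(nodes), length(nodes), dimnames = list(nodes, nodes))
  for (g in dags) {
    if (nrow(g$arcs)) counts[g$arcs] <- counts[g$arcs] + 1
  }
  idx <- which(counts > 0, arr.ind = TRUE)
  out <- data.frame(
    from = nodes[idx[, 1]],
    to = nodes[idx[, 2]],
    strength = counts[idx] / length(dags),
    stringsAsFactors = FALSE
  )
  out <- out[order(-out$strength, out$from, out$to), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Consensus DAG from an arc-strength table
#'
#' Keeps exactly the arcs with strength strictly greater than `threshold`.
#' The thresholded set is normally acyclic; if not, arcs are admitted in
#' decreasing strength order (ties broken lexicographically on parent then
#' child name), skipping any arc that would close a cycle.
#'
#' @param strengths data frame from [arc_strengths()].
#' @param threshold inclusion threshold in (0, 1); strictly-greater rule.
#' @param nodes optional node set (defaults to the names appearing in
#'   `strengths`).
#' @return a [dag].
#' @export
consensus_dag <- function(strengths, threshold = 0.5, nodes = NULL) {
  stopifnot(threshold > 0, threshold < 1)
  if (is.null(nodes)) nodes <- sort(unique(c(strengths$from, strengths$to)))
  keep <- strengths[strengths$strength > threshold, , drop = FALSE]
  keep <- keep[order(-keep$strength, keep$from, keep$to), , drop = FALSE]
  g <- dag(nodes)
  A <- adj_matrix(g)
  arcs <- NULL
  for (r in seq_len(nrow(keep))) {
    i <- match(keep$from[r], nodes)
    j <- match(keep$to[r], nodes)
    if (!reachable(A, j, i)) {
      A[i, j] <- TRUE
      arcs <- rbind(arcs, c(keep$from[r], keep$to[r]))
    }
  }
  dag(nodes, arcs)
}

#' Fit parameters on a fixed consensus structure
#'
#' With complete data this is one OLS fit per node. With missing cells a
#' parameter-only EM is run: impute with the current fit, refit on the
#' completed data, and iterate until the completed-data BIC of the fixed
#' structure moves by less than `score_tol`.
#'
#' @param data data frame, possibly with missing values.
#' @param g the consensus [dag].
#' @param max_iter,score_tol EM controls.
#' @param binary binary root nodes.
#' @return fitted [lgn].
#' @export
fit_consensus <- function(data, g, max_iter = 25, score_tol = 1e-3,
                          binary = character(0)) {
  X <- as.data.frame(data)[, g$nodes, drop = FALSE]
  if (!anyNA(X)) return(fit_lgn(X, g, binary = binary))
  params <- lapply(g$nodes, function(v) {
    x <- X[[v]][!is.na(X[[v]])]
    if (v %in% binary) {
      p <- mean(x)
      list(intercept = p, coefficients = stats::setNames(numeric(0), character(0)),
           sd = sqrt(max(p * (1 - p), 0)))
    } else {
      list(intercept = mean(x), coefficients = stats::setNames(numeric(0), character(0)),
           sd = max(stats::sd(x), 1e-6))
    }
  })
  names(params) <- g$nodes
  net <- lgn(dag(g$nodes), params, binary = binary)
  prev <- -Inf
  for (it in seq_len(max_iter)) {
    completed <- impute_lgn(net, X)
    net <- fit_lgn(completed, g, binary = binary)
    sc <- score_network(completed, g)
    if (abs(sc - prev) < score_tol) break
    prev <- sc
  }
  net
}
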