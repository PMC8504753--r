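#' Score-based DAG search by greedy hill climbing
#'
#' Best-improvement search over single-arc moves (add, delete, reverse),
#' starting from the empty graph. Blacklisted and cycle-creating arcs are
#' never proposed. Candidate gains are cached per (move, arc) and only the
#' columns touched by an accepted move are recomputed, so each step costs a
#' handful of small linear solves against the data's cross-product matrix.
#'
#' Ties between equal-gain moves are broken deterministically: move type
#' (add, delete, reverse), then parent name, then child name. With
#' `restarts > 1` the search is restarted from the incumbent perturbed by
#' random permitted arc insertions; the best-scoring result is returned,
#' reproducibly under `seed`.
#'
#' @param data complete numeric data frame or matrix (>= 10 rows).
#' @param blacklist optional two-column matrix of forbidden arcs (see
#'   [tier_blacklist()]).
#' @param restarts total number of climbs (default 1: a single climb from the
#'   empty graph).
#' @param seed optional integer seed used for restart perturbations.
#' @param max_parents optional cap on the in-degree of any node.
#' @return a [dag] whose total BIC is a local optimum, with attribute
#'   `"score"`.
#' @export
hill_climb <- function(data, blacklist = NULL, restarts = 1, seed = NULL,
                       max_parents = Inf) {
  X <- as.matrix(data)
  if (anyNA(X)) stop("data contains missing values; use structural_em() instead")
  if (nrow(X) < 3) stop("need at least 3 complete rows")
  cache <- score_cache(X)
  nodes <- colnames(X)
  F <- blacklist_matrix(blacklist, nodes)

  with_seed(seed, {
    res <- climb_from(cache, nodes, F, empty_state(cache, nodes), max_parents)
    if (restarts > 1) {
      for (r in seq_len(restarts - 1)) {
        st <- perturb_state(cache, nodes, F, res$state, max_parents)
        cand <- climb_from(cache, nodes, F, st, max_parents)
        if (cand$score > res$score + 1e-9) res <- cand
      }
    }
    g <- dag(nodes, adjacency_to_arcs(res$state$A, nodes))
    attr(g, "score") <- res$score
    g
  })
}

empty_state <- function(cache, nodes) {
  p <- length(nodes)
  s <- vapply(nodes, function(v) fit_node_cached(cache, v, character(0))$score, numeric(1))
  list(A = matrix(FALSE, p, p, dimnames = list(nodes, nodes)), s = s)
}

adjacency_to_arcs <- function(A, nodes) {
  idx <- which(A, arr.ind = TRUE)
  if (!nrow(idx)) return(NULL)
  cbind(from = nodes[idx[, 1]], to = nodes[idx[, 2]])
}

# gain matrices: G[i, j] = gain of adding i -> j to j's parents (ignoring
# legality), D[i, j] = gain of removing i -> j (only where the arc exists)
gain_matrices <- function(cache, nodes, st, max_parents) {
  p <- length(nodes)
  G <- matrix(-Inf, p, p, dimnames = list(nodes, nodes))
  D <- matrix(-Inf, p, p, dimnames = list(nodes, nodes))
  for (j in seq_len(p)) {
    cols <- refresh_child(cache, nodes, st, j, max_parents)
    G[, j] <- cols$G
    D[, j] <- cols$D
  }
  list(G = G, D = D)
}

# recompute the candidate-gain columns (adds and deletes) for child j
refresh_child <- function(cache, nodes, st, j, max_parents) {
  p <- length(nodes)
  gcol <- rep(-Inf, p)
  dcol <- rep(-Inf, p)
  pa <- nodes[st$A[, j]]
  for (i in seq_len(p)) {
    if (i == j) next
    if (st$A[i, j]) {
      dcol[i] <- fit_node_cached(cache, nodes[j], setdiff(pa, nodes[i]))$score - st$s[j]
    } else if (length(pa) < max_parents) {
      gcol[i] <- tryCatch(
        fit_node_cached(cache, nodes[j], c(pa, nodes[i]))$score - st$s[j],
        error = function(e) -Inf)
    }
  }
  list(G = gcol, D = dcol)
}

climb_from <- function(cache, nodes, F, st, max_parents) {
  p <- length(nodes)
  gm <- gain_matrices(cache, nodes, st, max_parents)
  G <- gm$G; D <- gm$D
  # structural masks for adds: no blacklisted arc, no existing arc either way
  repeat {
    addG <- G
    addG[F | st$A | t(st$A)] <- -Inf
    delG <- D
    revG <- matrix(-Inf, p, p, dimnames = list(nodes, nodes))
    has <- which(st$A & !t(F), arr.ind = TRUE)  # reversal target not blacklisted
    if (nrow(has)) {
      revG[has] <- D[has] + G[cbind(has[, 2], has[, 1])]
    }
    moved <- FALSE
    vetoed <- NULL
    repeat {
      best <- max(addG, delG, revG)
      if (!is.finite(best) || best <= 1e-9) break
      # deterministic pick among ties; score-equivalent orientations differ
      # only by float noise inherited from the score magnitude
      tie_tol <- 1e-7
      pick <- NULL
      ord <- order(nodes)
      for (kind in c("add", "del", "rev")) {
        M <- switch(kind, add = addG, del = delG, rev = revG)
        hit <- which(M >= best - tie_tol, arr.ind = TRUE)
        if (nrow(hit)) {
          hit <- hit[order(match(hit[, 1], ord), match(hit[, 2], ord)), , drop = FALSE]
          pick <- list(kind = kind, i = hit[1, 1], j = hit[1, 2], gain = M[hit[1, 1], hit[1, 2]])
          break
        }
      }
      i <- pick$i; j <- pick$j
      legal <- switch(pick$kind,
        add = !reachable(st$A, j, i),
        del = TRUE,
        rev = {
          A2 <- st$A; A2[i, j] <- FALSE
          !reachable(A2, i, j)
        })
      if (!legal) {
        # veto for this sweep only; legality can change after the next move
        if (pick$kind == "add") addG[i, j] <- -Inf else revG[i, j] <- -Inf
        next
      }
      # apply the move and refresh affected columns
      if (pick$kind == "add") {
        st$A[i, j] <- TRUE
        st$s[j] <- st$s[j] + G[i, j]
        cols <- refresh_child(cache, nodes, st, j, max_parents)
        G[, j] <- cols$G; D[, j] <- cols$D
      } else if (pick$kind == "del") {
        st$A[i, j] <- FALSE
        st$s[j] <- st$s[j] + D[i, j]
        cols <- refresh_child(cache, nodes, st, j, max_parents)
        G[, j] <- cols$G; D[, j] <- cols$D
      } else {
        st$A[i, j] <- FALSE
        st$s[j] <- st$s[j] + D[i, j]
        cols <- refresh_child(cache, nodes, st, j, max_parents)
        G[, j] <- cols$G; D[, j] <- cols$D
        st$A[j, i] <- TRUE
        gji <- fit_node_cached(cache, nodes[i], nodes[st$A[, i]])$score - st$s[i]
        st$s[i] <- st$s[i] + gji
        cols <- refresh_child(cache, nodes, st, i, max_parents)
        G[, i] <- cols$G; D[, i] <- cols$D
      }
      moved <- TRUE
      break
    }
    if (!moved) break
  }
  list(state = st, score = sum(st$s))
}

# random perturbation for restarts: insert up to two random permitted arcs
perturb_state <- function(cache, nodes, F, st, max_parents) {
  A <- st$A
  cand <- which(!F & !A & !t(A), arr.ind = TRUE)
  if (nrow(cand)) {
    for (k in sample(seq_len(nrow(cand)), min(2, nrow(cand)))) {
      i <- cand[k, 1]; j <- cand[k, 2]
      if (!reachable(A, j, i)) A[i, j] <- TRUE
    }
  }
  s <- vapply(seq_along(nodes), function(j) {
    fit_node_cached(cache, nodes[j], nodes[A[, j]])$score
  }, numeric(1))
  names(s) <- nodes
  list(A = A, s = s)
}

#' Globally optimal DAG by exhaustive enumeration
#'
#' Test oracle for small problems: enumerates all topological orders and, for
#' each node, the best-scoring subset of its predecessors (respecting the
#' blacklist), which covers every DAG. Refuses more than 5 nodes.
#'
#' @inheritParams hill_climb
#' @return the BIC-optimal [dag] with attribute `"score"`.
#' @export
exhaustive_search <- function(data, blacklist = NULL) {
  X <- as.matrix(data)
  if (anyNA(X)) stop("exhaustive_search requires complete data")
  nodes <- colnames(X)
  p <- length(nodes)
  if (p > 5) stop("exhaustive search is limited to 5 nodes")
  cache <- score_cache(X)
  F <- blacklist_matrix(blacklist, nodes)

  # score of every (node, parent-subset) pair, keyed by bitmask over nodes
  subset_score <- lapply(seq_len(p), function(j) {
    others <- setdiff(seq_len(p), j)
    out <- rep(-Inf, 2^p)
    for (m in 0:(2^length(others) - 1)) {
      pa <- others[bitwAnd(bitwShiftL(1, seq_along(others) - 1), m) > 0]
      if (any(F[pa, j])) next
      mask <- sum(bitwShiftL(1, pa - 1)) + 1
      out[mask] <- tryCatch(fit_node_cached(cache, nodes[j], nodes[pa])$score,
                            error = function(e) -Inf)
    }
    out
  })

  best <- list(score = -Inf, parents = NULL)
  perms <- permutations(p)
  for (r in seq_len(nrow(perms))) {
    ord <- perms[r, ]
    total <- 0
    pa_sets <- vector("list", p)
    for (k in seq_len(p)) {
      j <- ord[k]
      pred <- if (k > 1) ord[seq_len(k - 1)] else integer(0)
      sc <- subset_score[[j]]
      bs <- -Inf; bp <- integer(0)
      for (m in 0:(2^length(pred) - 1)) {
        pa <- pred[bitwAnd(bitwShiftL(1, seq_along(pred) - 1), m) > 0]
        mask <- sum(bitwShiftL(1, pa - 1)) + 1
        if (sc[mask] > bs) { bs <- sc[mask]; bp <- pa }
      }
      total <- total + bs
      pa_sets[[j]] <- bp
    }
    if (total > best$score + 1e-12) best <- list(score = total, parents = pa_sets)
  }
  arcs <- NULL
  for (j in seq_len(p)) {
    for (i in best$parents[[j]]) arcs <- rbind(arcs, c(nodes[i], nodes[j]))
  }
  g <- dag(nodes, arcs)
  attr(g, "score") <- best$score
  g
}

permutations <- function(p) {
  if (p == 1) return(matrix(1, 1, 1))
  sub <- permutations(p - 1)
  out <- matrix(0L, 0, p)
  for (k in seq_len(p)) {
    rest <- setdiff(seq_len(p), k)
    out <- rbind(out, cbind(k, matrix(rest[sub], nrow(sub))))
  }
  unname(out)
}
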