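#' @name scoring
#' @title Decomposable Gaussian BIC
#'
#' @description
#' Local node score: the maximized Gaussian log-likelihood of a node given an
#' OLS fit on its parents (ML residual variance, i.e. divide by n), penalized
#' by `(k/2) log(n)` with `k = |parents| + 2` (intercept, coefficients,
#' variance). Higher is better and the network score decomposes as the sum of
#' local scores, which is what makes greedy search cheap.
#'
#' All scores are computed from a single precomputed cross-product matrix of
#' the (complete) data, so each local fit is a small linear solve and never
#' touches the raw rows again.
NULL

# Build the sufficient statistics for scoring/fitting: C = crossprod([1 X]).
# data: numeric matrix or data frame with no missing values.
score_cache <- function(data) {
  X <- as.matrix(data)
  if (!is.numeric(X)) stop("data must be numeric")
  if (anyNA(X)) stop("scoring requires complete data (no missing values)")
  n <- nrow(X)
  C <- crossprod(cbind(`(const)` = 1, X))
  list(C = C, n = n, nodes = colnames(X))
}

# OLS fit of node ~ parents from the cache. Returns intercept, coefficients,
# ML residual variance (floored), and the local BIC score.
fit_node_cached <- function(cache, node, parents, floor_var = 1e-12) {
  C <- cache$C
  n <- cache$n
  idx <- c(1L, match(parents, cache$nodes) + 1L)
  j <- match(node, cache$nodes) + 1L
  Cxx <- C[idx, idx, drop = FALSE]
  Cxy <- C[idx, j]
  b <- tryCatch(solve(Cxx, Cxy), error = function(e) {
    stop("rank-deficient parent matrix for node '", node, "': ", conditionMessage(e))
  })
  rss <- max(C[j, j] - sum(b * Cxy), 0)
  s2 <- rss / n
  if (s2 < floor_var) {
    warning("degenerate fit for node '", node, "': residual variance floored")
    s2 <- floor_var
  }
  k <- length(parents) + 2
  logl <- -n / 2 * (log(2 * pi * s2) + 1)
  list(
    intercept = unname(b[1]),
    coefficients = stats::setNames(b[-1], parents),
    sd = sqrt(s2),
    logl = logl,
    score = logl - (k / 2) * log(n)
  )
}

#' Local BIC score of one node given a parent set
#'
#' @param data complete numeric data frame or matrix.
#' @param node node (column) name.
#' @param parents character vector of parent column names (possibly empty).
#' @return scalar score (higher is better).
#' @examples
#' d <- data.frame(x = c(-1, 1))
#' score_node(d, "x", character(0))  # -log(2*pi) - 1 - log(2)
#' @export
score_node <- function(data, node, parents = character(0)) {
  cache <- score_cache(data)
  if (nrow(as.matrix(data)) < length(parents) + 2) {
    stop("need at least |parents| + 2 complete rows")
  }
  fit_node_cached(cache, node, parents)$score
}

#' Total BIC score of a network structure
#'
#' Sum of [score_node()] over all nodes with their parent sets in `g`
#' (decomposability is exact by construction).
#'
#' @param data complete numeric data frame or matrix.
#' @param g a [dag] over the data's columns.
#' @return scalar score.
#' @export
score_network <- function(data, g) {
  cache <- score_cache(data)
  sum(vapply(g$nodes, function(v) {
    fit_node_cached(cache, v, parents(g, v))$score
  }, numeric(1)))
}

#' Fit linear-Gaussian parameters on a fixed structure
#'
#' OLS per node given its parents in `g` (ML residual variance). Binary roots
#' get their empirical rate as intercept and `sqrt(p(1-p))` as sd.
#'
#' @param data complete numeric data frame or matrix over `g`'s nodes.
#' @param g a [dag].
#' @param binary character vector of binary root nodes.
#' @return an [lgn].
#' @export
fit_lgn <- function(data, g, binary = character(0)) {
  cache <- score_cache(data[, g$nodes, drop = FALSE])
  params <- lapply(g$nodes, function(v) {
    if (v %in% binary) {
      if (length(parents(g, v))) stop("binary node '", v, "' must be a root in the structure")
      p <- mean(as.matrix(data)[, v])
      return(list(intercept = p, coefficients = stats::setNames(numeric(0), character(0)),
                  sd = sqrt(max(p * (1 - p), 0))))
    }
    f <- fit_node_cached(cache, v, parents(g, v))
    list(intercept = f$intercept, coefficients = f$coefficients, sd = f$sd)
  })
  names(params) <- g$nodes
  lgn(g, params, binary = binary)
}
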