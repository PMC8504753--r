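#' Linear-Gaussian Bayesian networks
#'
#' An `lgn` couples a [dag] with local linear-Gaussian models: every node is
#' `intercept + sum(beta_p * parent_p) + Normal(0, sd)`. The implied joint
#' distribution is multivariate normal, which gives exact expressions for
#' marginal and conditional moments (used as the oracle against which the
#' sampling-based queries are checked).
#'
#' A binary 0/1 treatment indicator can be declared via `binary`; such a node
#' must be a root. Its `intercept` is then the Bernoulli success rate and its
#' `sd` is `sqrt(p (1 - p))`, so first and second moments of the joint remain
#' exact even though the marginal is not normal.
#'
#' @param graph a [dag].
#' @param params named list, one entry per node, each a list with fields
#'   `intercept` (scalar), `coefficients` (named numeric over the node's
#'   parents; may be empty) and `sd` (residual standard deviation, >= 0).
#' @param binary character vector of binary root nodes (usually `"group"`).
#' @return an object of class `lgn`.
#' @examples
#' g <- dag(c("x", "y"), rbind(c("x", "y")))
#' net <- lgn(g, list(
#'   x = list(intercept = 0, coefficients = numeric(0), sd = 1),
#'   y = list(intercept = 1, coefficients = c(x = 2), sd = 0.5)
#' ))
#' implied_moments(net)$mean
#' @export
lgn <- function(graph, params, binary = character(0)) {
  stopifnot(inherits(graph, "dag"))
  if (!setequal(names(params), graph$nodes)) {
    stop("params must be supplied for exactly the graph's nodes")
  }
  for (v in graph$nodes) {
    p <- params[[v]]
    pa <- parents(graph, v)
    cf <- p$coefficients
    if (is.null(cf)) cf <- stats::setNames(numeric(0), character(0))
    if (!setequal(names(cf), pa)) {
      stop("coefficients of node '", v, "' must be named exactly by its parents")
    }
    if (is.na(p$sd) || p$sd < 0) stop("residual sd of node '", v, "' must be >= 0")
    params[[v]]$coefficients <- cf[pa]  # canonical parent order
  }
  for (v in binary) {
    if (!v %in% graph$nodes) stop("binary node '", v, "' not in graph")
    if (length(parents(graph, v))) stop("binary node '", v, "' must be a root")
  }
  topo_sort(graph)  # enforce acyclicity
  structure(list(graph = graph, params = params, binary = binary), class = "lgn")
}

#' @export
print.lgn <- function(x, ...) {
  cat("linear-Gaussian network:", length(x$graph$nodes), "nodes,",
      nrow(x$graph$arcs), "arcs\n")
  invisible(x)
}

# run expr with a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Exact first and second moments of the joint distribution
#'
#' Forward substitution in topological order: for each node,
#' `mu = a + B mu_pa` and the covariance row follows from
#' `cov(x_v, x) = beta' cov(x_pa, x)` plus the residual variance on the
#' diagonal.
#'
#' @param net an [lgn].
#' @return list with `mean` (named vector) and `cov` (symmetric matrix).
#' @export
implied_moments <- function(net) {
  ord <- topo_sort(net$graph)
  nodes <- net$graph$nodes
  p <- length(nodes)
  mu <- stats::setNames(numeric(p), nodes)
  S <- matrix(0, p, p, dimnames = list(nodes, nodes))
  for (v in ord) {
    pr <- net$params[[v]]
    pa <- names(pr$coefficients)
    if (length(pa)) {
      b <- pr$coefficients
      mu[v] <- pr$intercept + sum(b * mu[pa])
      cross <- as.numeric(b %*% S[pa, , drop = FALSE])  # cov(v, all) from parents
      S[v, ] <- cross
      S[, v] <- cross
      S[v, v] <- as.numeric(b %*% S[pa, pa, drop = FALSE] %*% b) + pr$sd^2
    } else {
      mu[v] <- pr$intercept
      S[v, v] <- pr$sd^2
    }
  }
  list(mean = mu, cov = S)
}

#' Exact conditional moments given evidence
#'
#' Standard Gaussian conditioning of [implied_moments()] on an evidence
#' block: `mu_a + S_ab S_bb^{-1} (e - mu_b)` with the Schur-complement
#' covariance. With a binary root among the evidence this is the best linear
#' predictor rather than the exact conditional, which is what conditional-mean
#' imputation requires.
#'
#' @param net an [lgn].
#' @param evidence named numeric vector or list of observed node values; may
#'   be empty.
#' @return list with `mean` and `cov` over the non-evidence nodes.
#' @export
conditional_moments <- function(net, evidence = numeric(0)) {
  evidence <- unlist(evidence)
  m <- implied_moments(net)
  if (!length(evidence)) return(m)
  ev <- names(evidence)
  if (!all(ev %in% net$graph$nodes)) {
    stop("unknown evidence node(s): ", paste(setdiff(ev, net$graph$nodes), collapse = ", "))
  }
  rest <- setdiff(net$graph$nodes, ev)
  Sbb <- m$cov[ev, ev, drop = FALSE]
  ok <- tryCatch(chol(Sbb), error = function(e) NULL)
  if (is.null(ok)) stop("singular evidence covariance: evidence block is degenerate")
  w <- backsolve(ok, forwardsolve(t(ok), evidence - m$mean[ev]))
  wS <- backsolve(ok, forwardsolve(t(ok), t(m$cov[rest, ev, drop = FALSE])))
  mu <- m$mean[rest] + as.numeric(m$cov[rest, ev, drop = FALSE] %*% w)
  S <- m$cov[rest, rest, drop = FALSE] - m$cov[rest, ev, drop = FALSE] %*% wS
  S <- (S + t(S)) / 2
  list(mean = stats::setNames(mu, rest), cov = S)
}

#' Ancestral (forward) sampling of a network
#'
#' Draws `n` joint samples in topological order; binary roots are drawn
#' Bernoulli with their stored rate, every other node normal around its
#' linear predictor. This is the Gaussian form of logic sampling.
#'
#' @param net an [lgn].
#' @param n number of rows to draw.
#' @param seed optional integer seed (the caller's RNG state is restored).
#' @return data frame of `n` rows in the network's node order.
#' @export
rlgn <- function(net, n, seed = NULL) {
  stopifnot(n >= 1)
  with_seed(seed, {
    ord <- topo_sort(net$graph)
    out <- matrix(NA_real_, n, length(net$graph$nodes),
                  dimnames = list(NULL, net$graph$nodes))
    for (v in ord) {
      pr <- net$params[[v]]
      if (v %in% net$binary) {
        out[, v] <- stats::rbinom(n, 1, pr$intercept)
        next
      }
      mu <- pr$intercept
      pa <- names(pr$coefficients)
      if (length(pa)) mu <- mu + as.numeric(out[, pa, drop = FALSE] %*% pr$coefficients)
      out[, v] <- if (pr$sd > 0) stats::rnorm(n, mu, pr$sd) else mu
    }
    as.data.frame(out)
  })
}

#' Serialize a network to JSON
#'
#' @param net an [lgn].
#' @param file optional path to write to.
#' @return JSON string (invisibly when `file` is given).
#' @export
lgn_to_json <- function(net, file = NULL) {
  obj <- list(
    nodes = net$graph$nodes,
    arcs = apply(net$graph$arcs, 1, function(a) list(from = a[1], to = a[2])),
    binary = net$binary,
    params = lapply(net$params, function(p) list(
      intercept = p$intercept,
      coefficients = as.list(p$coefficients),
      sd = p$sd
    ))
  )
  txt <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "list")
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}

#' Read a network from its JSON serialization
#' @param file path or JSON string produced by [lgn_to_json()].
#' @return an [lgn].
#' @export
lgn_from_json <- function(file) {
  obj <- jsonlite::fromJSON(file, simplifyVector = FALSE)
  arcs <- if (length(obj$arcs)) {
    do.call(rbind, lapply(obj$arcs, function(a) c(a$from, a$to)))
  } else NULL
  g <- dag(unlist(obj$nodes), arcs)
  params <- lapply(obj$params, function(p) list(
    intercept = p$intercept,
    coefficients = unlist(p$coefficients) %||% stats::setNames(numeric(0), character(0)),
    sd = p$sd
  ))
  binary <- if (length(obj$binary)) unlist(obj$binary) else character(0)
  lgn(g, params[g$nodes], binary = binary)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
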