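#' Directed graphs over named variables
#'
#' A `dag` object is a light container for a node set and a set of directed
#' arcs. Arcs are stored as a two-column character matrix (`from`, `to`).
#' Acyclicity is not enforced at construction time unless `check = TRUE`;
#' all learning functions in the package only ever return acyclic graphs.
#'
#' @param nodes character vector of variable names (unique, non-empty).
#' @param arcs two-column character matrix or data frame of directed arcs
#'   (`from`, `to`); may have zero rows.
#' @param check if `TRUE`, error when the graph contains a cycle.
#' @return an object of class `dag`.
#' @examples
#' g <- dag(c("a", "b", "c"), rbind(c("a", "b"), c("b", "c")))
#' topo_sort(g)
#' @export
dag <- function(nodes, arcs = NULL, check = FALSE) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) stop("duplicate node names")
  if (is.null(arcs) || NROW(arcs) == 0) {
    arcs <- matrix(character(0), 0, 2)
  } else {
    arcs <- as.matrix(arcs)
    if (ncol(arcs) != 2) stop("arcs must have two columns (from, to)")
    storage.mode(arcs) <- "character"
  }
  dimnames(arcs) <- list(NULL, c("from", "to"))
  if (nrow(arcs)) {
    bad <- !(arcs %in% nodes)
    if (any(bad)) stop("arc endpoint not among nodes: ", paste(unique(arcs[bad]), collapse = ", "))
    if (any(arcs[, 1] == arcs[, 2])) stop("self-arcs are not allowed")
    if (anyDuplicated(paste(arcs[, 1], arcs[, 2], sep = "\r"))) stop("duplicate arcs")
  }
  g <- structure(list(nodes = nodes, arcs = arcs), class = "dag")
  if (check) topo_sort(g)
  g
}

#' @export
print.dag <- function(x, ...) {
  cat("dag with", length(x$nodes), "nodes and", nrow(x$arcs), "arcs\n")
  if (nrow(x$arcs)) {
    cat(paste0("  ", x$arcs[, 1], " -> ", x$arcs[, 2]), sep = "\n")
  }
  invisible(x)
}

# adjacency matrix A[parent, child] = TRUE
adj_matrix <- function(g) {
  p <- length(g$nodes)
  A <- matrix(FALSE, p, p, dimnames = list(g$nodes, g$nodes))
  if (nrow(g$arcs)) A[g$arcs] <- TRUE
  A
}

#' Parents of a node
#' @param g a [dag].
#' @param node node name.
#' @return character vector of parent names.
#' @export
parents <- function(g, node) {
  if (!node %in% g$nodes) stop("unknown node: ", node)
  g$arcs[g$arcs[, 2] == node, 1]
}

#' Topological order of a DAG
#'
#' Kahn's algorithm; among nodes with no remaining parents the one earliest
#' in `g$nodes` is emitted first, so the order is deterministic.
#'
#' @param g a [dag].
#' @return character vector of all nodes with every parent before its children.
#' @export
topo_sort <- function(g) {
  A <- adj_matrix(g)
  indeg <- colSums(A)
  out <- character(0)
  active <- rep(TRUE, length(g$nodes))
  while (any(active)) {
    i <- which(active & indeg == 0)
    if (!length(i)) {
      cyc <- find_cycle(A[active, active, drop = FALSE])
      stop("not a DAG: cycle ", paste(cyc, collapse = " -> "))
    }
    i <- i[1]
    out <- c(out, g$nodes[i])
    indeg <- indeg - A[i, ]
    active[i] <- FALSE
  }
  out
}

# return one directed cycle (node names) in a graph known to contain one
find_cycle <- function(A) {
  nodes <- rownames(A)
  for (s in seq_along(nodes)) {
    stack <- list(list(v = s, path = s))
    while (length(stack)) {
      top <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (w in which(A[top$v, ])) {
        if (w == s) return(nodes[c(top$path, s)])
        if (!(w %in% top$path)) stack[[length(stack) + 1]] <- list(v = w, path = c(top$path, w))
      }
    }
  }
  nodes[1]
}

#' Test whether a graph is acyclic
#' @param g a [dag].
#' @return `TRUE` if `g` has no directed cycle.
#' @export
is_acyclic <- function(g) {
  ok <- TRUE
  tryCatch(topo_sort(g), error = function(e) ok <<- FALSE)
  ok
}

# TRUE if a directed path to_ ->* from_ exists, i.e. adding from_ -> to_
# would create a cycle. A is the logical adjacency matrix.
reachable <- function(A, from, to) {
  if (from == to) return(TRUE)
  seen <- logical(nrow(A))
  frontier <- from
  seen[from] <- TRUE
  while (length(frontier)) {
    nxt <- which(colSums(A[frontier, , drop = FALSE]) > 0 & !seen)
    if (to %in% nxt) return(TRUE)
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  FALSE
}

#' Compare the arc sets of two graphs
#' @param g1,g2 [dag] objects over any node sets.
#' @return `TRUE` when both node sets and directed arc sets coincide.
#' @export
same_graph <- function(g1, g2) {
  setequal(g1$nodes, g2$nodes) &&
    setequal(arc_keys(g1$arcs), arc_keys(g2$arcs))
}

arc_keys <- function(arcs) {
  if (!NROW(arcs)) return(character(0))
  paste(arcs[, 1], arcs[, 2], sep = "\r")
}

#' Render a graph in DOT format
#'
#' Optionally styles edges: width proportional to a bootstrap arc strength
#' and colour by the sign of a fitted coefficient (blue positive, red
#' negative), the conventional rendering of an averaged network.
#'
#' @param g a [dag].
#' @param strengths optional data frame (`from`, `to`, `strength`) as
#'   returned by [arc_strengths()].
#' @param net optional fitted [lgn] supplying coefficient signs.
#' @param file optional path; when given the DOT text is written there.
#' @return the DOT source as a character scalar, invisibly when `file` is set.
#' @export
as_dot <- function(g, strengths = NULL, net = NULL, file = NULL) {
  lines <- c("digraph G {", paste0("  \"", g$nodes, "\";"))
  if (nrow(g$arcs)) {
    for (i in seq_len(nrow(g$arcs))) {
      from <- g$arcs[i, 1]; to <- g$arcs[i, 2]
      attrs <- character(0)
      if (!is.null(strengths)) {
        s <- strengths$strength[strengths$from == from & strengths$to == to]
        if (length(s)) attrs <- c(attrs, sprintf("penwidth=%.2f", 0.5 + 4 * s[1]))
      }
      if (!is.null(net)) {
        b <- net$params[[to]]$coefficients[from]
        if (!is.na(b)) attrs <- c(attrs, sprintf("color=%s", if (b >= 0) "blue" else "red"))
      }
      tag <- if (length(attrs)) paste0(" [", paste(attrs, collapse = ", "), "]") else ""
      lines <- c(lines, sprintf("  \"%s\" -> \"%s\"%s;", from, to, tag))
    }
  }
  lines <- c(lines, "}")
  txt <- paste(lines, collapse = "\n")
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}
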