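# Fixture builders shared across the suite. All randomness is seeded by the
# caller so every test is reproducible.

# random DAG over p nodes (lower-triangular in node order) with edge
# probability `prob`, random coefficients in +-[0.5, 1.5], residual sd in
# [0.5, 1.5]
random_lgn <- function(p, seed, prob = 0.4) {
  set.seed(seed)
  nodes <- paste0("v", seq_len(p))
  arcs <- NULL
  if (p > 1) {
    for (j in 2:p) {
      for (i in seq_len(j - 1)) {
        if (stats::runif(1) < prob) arcs <- rbind(arcs, c(nodes[i], nodes[j]))
      }
    }
  }
  g <- dag(nodes, arcs)
  params <- lapply(nodes, function(v) {
    pa <- parents(g, v)
    list(
      intercept = stats::rnorm(1),
      coefficients = stats::setNames(
        stats::runif(length(pa), 0.5, 1.5) * sample(c(-1, 1), length(pa), TRUE), pa),
      sd = stats::runif(1, 0.5, 1.5)
    )
  })
  names(params) <- nodes
  lgn(g, params)
}

# tiny two-node network x -> y with configurable slope
chain_xy <- function(beta = 2, sd_y = 1, sd_x = 1) {
  g <- dag(c("x", "y"), rbind(c("x", "y")))
  lgn(g, list(
    x = list(intercept = 0, coefficients = stats::setNames(numeric(0), character(0)), sd = sd_x),
    y = list(intercept = 0, coefficients = c(x = beta), sd = sd_y)
  ))
}

# five-node benchmark network with well-identified arcs (the shielded a -> c
# arc is kept modest so the a/b/c triangle does not trap a greedy search in a
# misoriented local optimum):
# g (binary root) -> a -> b -> c, a -> c, plus isolated d
bench5 <- function() {
  nodes <- c("g", "a", "b", "c", "d")
  arcs <- rbind(c("g", "a"), c("a", "b"), c("b", "c"), c("a", "c"))
  none <- stats::setNames(numeric(0), character(0))
  lgn(dag(nodes, arcs), list(
    g = list(intercept = 0.5, coefficients = none, sd = 0.5),
    a = list(intercept = 0, coefficients = c(g = 2), sd = 1),
    b = list(intercept = 1, coefficients = c(a = 0.8), sd = 1),
    c = list(intercept = -1, coefficients = c(b = 0.7, a = 0.25), sd = 1),
    d = list(intercept = 0, coefficients = none, sd = 1)
  ), binary = "g")
}

# does a graph contain a specific directed arc?
has_arc <- function(g, from, to) {
  any(g$arcs[, 1] == from & g$arcs[, 2] == to)
}

# assert that no arc of `g` is in the blacklist
expect_no_blacklisted <- function(g, blacklist) {
  if (!NROW(blacklist) || !nrow(g$arcs)) return(invisible(TRUE))
  keys <- paste(g$arcs[, 1], g$arcs[, 2])
  bad <- keys %in% paste(blacklist[, 1], blacklist[, 2])
  testthat::expect_false(any(bad), label = paste(
    "blacklisted arcs present:", paste(keys[bad], collapse = ", ")))
}
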