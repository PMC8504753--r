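#' Fix arc coefficients to zero (mutilated network)
#'
#' Sets the named parent coefficients to exactly zero while leaving every
#' other parameter — including residual standard deviations — unchanged.
#' This is the "fix the regression coefficient to zero" intervention: the
#' arc is retained in the graph with a zero coefficient, which is
#' distributionally equivalent to dropping it.
#'
#' @param net an [lgn].
#' @param arcs two-column character matrix (or vector `c(from, to)`) of arcs
#'   to zero; every arc must exist in the network.
#' @return the mutilated [lgn].
#' @export
fix_arcs <- function(net, arcs) {
  if (is.null(dim(arcs))) arcs <- matrix(arcs, ncol = 2, byrow = TRUE)
  arcs <- as.matrix(arcs)
  for (r in seq_len(nrow(arcs))) {
    from <- arcs[r, 1]; to <- arcs[r, 2]
    if (!to %in% net$graph$nodes || !from %in% names(net$params[[to]]$coefficients)) {
      stop("arc ", from, " -> ", to, " not present in the network")
    }
    net$params[[to]]$coefficients[from] <- 0
  }
  net
}

#' Exact total effect by path tracing
#'
#' In a linear-Gaussian network the effect of a unit do-intervention on
#' `source` propagates additively: the total effect on `target` is the sum
#' over all directed paths of the product of arc coefficients. Computed by
#' dynamic programming in topological order (no path enumeration); zero when
#' no directed path exists.
#'
#' @param net an [lgn].
#' @param source,target distinct node names.
#' @return scalar total effect (target units per source unit).
#' @export
total_effect <- function(net, source, target) {
  stopifnot(source != target)
  if (!all(c(source, target) %in% net$graph$nodes)) stop("unknown node name")
  ord <- topo_sort(net$graph)
  eff <- stats::setNames(numeric(length(ord)), ord)
  eff[source] <- 1
  started <- FALSE
  for (v in ord) {
    if (v == source) { started <- TRUE; next }
    if (!started) next
    b <- net$params[[v]]$coefficients
    if (length(b)) eff[v] <- sum(b * eff[names(b)])
  }
  unname(eff[target])
}

#' Pathway decomposition of a total effect
#'
#' For each scenario (a set of arcs to zero), recomputes the total effect on
#' the mutilated network and reports the percentage of the full effect that
#' flowed through the severed arcs:
#' `contribution_pct = 100 * (beta_full - beta_fixed) / beta_full`.
#'
#' @param net an [lgn].
#' @param source,target node names with a non-zero full total effect.
#' @param scenarios list of arc sets, each a two-column matrix or a
#'   `c(from, to)` vector; list names label the scenarios.
#' @return list with `source`, `target`, `beta_full` and a data frame
#'   `scenarios` (`scenario`, `beta_fixed`, `contribution_pct`,
#'   `contribution_pct_rounded`).
#' @export
decompose_pathways <- function(net, source, target, scenarios) {
  beta_full <- total_effect(net, source, target)
  if (beta_full == 0) stop("total effect is zero: pathway percentages are undefined")
  labs <- names(scenarios)
  if (is.null(labs)) labs <- paste0("scenario_", seq_along(scenarios))
  rows <- lapply(seq_along(scenarios), function(k) {
    bf <- total_effect(fix_arcs(net, scenarios[[k]]), source, target)
    pct <- 100 * (beta_full - bf) / beta_full
    data.frame(scenario = labs[k], beta_fixed = bf, contribution_pct = pct,
               contribution_pct_rounded = round(pct), stringsAsFactors = FALSE)
  })
  list(source = source, target = target, beta_full = beta_full,
       scenarios = do.call(rbind, rows))
}

#' Residual group contrast after severing an arc
#'
#' Zeroes one arc and re-estimates the sampled group contrast on the target
#' ([group_effect()] on the mutilated network). Used to test whether a
#' treatment effect is fully mediated by the severed pathway: under full
#' mediation the remaining contrast is within Monte-Carlo error of zero.
#'
#' @param net an [lgn] containing the group indicator.
#' @param severed_arc `c(from, to)` arc to zero.
#' @param target target node.
#' @param n_samples,seed,group passed to [group_effect()].
#' @return list `beta`, `t`, `p`, `n_samples` from the mutilated network.
#' @export
mediation_check <- function(net, severed_arc, target, n_samples = 1e4,
                            seed = NULL, group = "group") {
  group_effect(fix_arcs(net, severed_arc), target, n_samples = n_samples,
               seed = seed, group = group)
}
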