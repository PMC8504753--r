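#' Sampling-based conditional probability query
#'
#' Forward ("logic") sampling of the network. Evidence on a binary root is
#' handled by rejection; evidence on continuous nodes is handled by
#' likelihood weighting (evidence nodes are clamped and each draw is weighted
#' by its Gaussian evidence likelihood), since exact-value rejection has
#' acceptance probability zero for continuous variables. Summary moments
#' converge to [conditional_moments()].
#'
#' @param net an [lgn].
#' @param targets character vector of query nodes (disjoint from evidence).
#' @param evidence named list / vector of clamped node values (may be empty).
#' @param n_samples number of draws (default 1e4).
#' @param seed optional integer seed.
#' @return list with `samples` (data frame over the targets), `weights`,
#'   `mean` and `sd` (weighted summaries per target), and `n_samples`.
#' @export
cp_query <- function(net, targets, evidence = list(), n_samples = 1e4,
                     seed = NULL) {
  stopifnot(n_samples >= 1)
  evidence <- unlist(evidence)
  ev <- names(evidence)
  if (length(intersect(targets, ev))) stop("targets must be disjoint from evidence")
  if (!all(targets %in% net$graph$nodes)) stop("unknown target node(s)")

  bin_ev <- intersect(ev, net$binary)
  cont_ev <- setdiff(ev, bin_ev)

  with_seed(seed, {
    if (length(bin_ev) && !length(cont_ev)) {
      # rejection on the binary root(s)
      draws <- rlgn(net, n_samples)
      keep <- rep(TRUE, n_samples)
      for (v in bin_ev) keep <- keep & draws[[v]] == evidence[[v]]
      if (!any(keep)) stop("rejection acceptance rate 0; use likelihood weighting")
      draws <- draws[keep, , drop = FALSE]
      w <- rep(1, nrow(draws))
    } else if (length(cont_ev) || length(bin_ev)) {
      # likelihood weighting with all evidence clamped
      ord <- topo_sort(net$graph)
      n <- n_samples
      out <- matrix(NA_real_, n, length(net$graph$nodes),
                    dimnames = list(NULL, net$graph$nodes))
      logw <- numeric(n)
      for (v in ord) {
        pr <- net$params[[v]]
        pa <- names(pr$coefficients)
        mu <- pr$intercept
        if (length(pa)) mu <- mu + as.numeric(out[, pa, drop = FALSE] %*% pr$coefficients)
        if (v %in% ev) {
          out[, v] <- evidence[[v]]
          if (v %in% net$binary) {
            p <- if (length(mu) == 1) rep(mu, n) else mu
            logw <- logw + log(ifelse(evidence[[v]] == 1, p, 1 - p))
          } else {
            if (pr$sd <= 0) stop("cannot weight evidence on a deterministic node")
            logw <- logw + stats::dnorm(evidence[[v]], mu, pr$sd, log = TRUE)
          }
        } else if (v %in% net$binary) {
          out[, v] <- stats::rbinom(n, 1, pr$intercept)
        } else {
          out[, v] <- if (pr$sd > 0) stats::rnorm(n, mu, pr$sd) else mu
        }
      }
      draws <- as.data.frame(out)
      w <- exp(logw - max(logw))
      if (sum(w) <= 0) stop("all likelihood weights are zero")
    } else {
      draws <- rlgn(net, n_samples)
      w <- rep(1, n_samples)
    }
    wm <- vapply(targets, function(v) stats::weighted.mean(draws[[v]], w), numeric(1))
    wv <- vapply(targets, function(v) {
      sum(w * (draws[[v]] - wm[v])^2) / sum(w)
    }, numeric(1))
    list(samples = draws[, targets, drop = FALSE], weights = w,
         mean = wm, sd = sqrt(wv), n_samples = n_samples)
  })
}

#' Sampled treatment-group contrast on a target variable
#'
#' Draws joint samples from the network and regresses the target on the 0/1
#' group indicator. The slope is the sampled group contrast; its t statistic
#' and two-sided p value (df = `n_samples - 2`) are diagnostics of the
#' sampled contrast, not trial-level inference — they scale with `n_samples`.
#'
#' @param net an [lgn] containing `group`.
#' @param target target node name.
#' @param n_samples number of draws (default 1e4).
#' @param seed optional integer seed.
#' @param group name of the binary treatment indicator.
#' @return list `beta`, `t`, `p`, `n_samples`.
#' @export
group_effect <- function(net, target, n_samples = 1e4, seed = NULL,
                         group = "group") {
  if (!group %in% net$graph$nodes) stop("no '", group, "' node in the network")
  d <- rlgn(net, n_samples, seed = seed)
  g <- d[[group]]
  if (stats::var(g) == 0) stop("group is constant in the samples")
  fit <- stats::lm.fit(cbind(1, g), d[[target]])
  beta <- unname(fit$coefficients[2])
  rss <- sum(fit$residuals^2)
  se <- sqrt(rss / (n_samples - 2) / sum((g - mean(g))^2))
  t <- beta / se
  list(beta = beta, t = t,
       p = 2 * stats::pt(-abs(t), df = n_samples - 2),
       n_samples = n_samples)
}
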