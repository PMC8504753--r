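#' Conditional-mean imputation under a fitted network
#'
#' Replaces every missing cell by the exact conditional mean of that variable
#' given the row's observed variables under the network's implied joint
#' moments. Rows are grouped by missingness pattern so each pattern costs one
#' Gaussian conditioning. Observed cells are never touched.
#'
#' @param net an [lgn] over the data's columns.
#' @param data data frame or matrix with `NA` for missing values.
#' @return a complete data frame.
#' @export
impute_lgn <- function(net, data) {
  X <- as.matrix(data[, net$graph$nodes, drop = FALSE])
  miss <- is.na(X)
  if (!any(miss)) return(as.data.frame(X))
  if (any(rowSums(!miss) == 0)) {
    stop("row(s) with all cells missing cannot be imputed; filter them first")
  }
  if (any(colSums(!miss) == 0)) {
    stop("variable(s) with no observed values: ",
         paste(colnames(X)[colSums(!miss) == 0], collapse = ", "))
  }
  m <- implied_moments(net)
  pat <- apply(miss, 1, function(r) paste(which(r), collapse = ","))
  for (key in unique(pat[pat != ""])) {
    rows <- which(pat == key)
    mis <- as.integer(strsplit(key, ",")[[1]])
    obs <- setdiff(seq_len(ncol(X)), mis)
    if (length(obs)) {
      Sbb <- m$cov[obs, obs, drop = FALSE]
      W <- tryCatch(solve(Sbb, t(m$cov[mis, obs, drop = FALSE])),
                    error = function(e) {
                      stop("singular observed-block covariance during imputation: ",
                           conditionMessage(e))
                    })
      dev <- sweep(X[rows, obs, drop = FALSE], 2, m$mean[obs])
      X[rows, mis] <- rep(m$mean[mis], each = length(rows)) + dev %*% W
    } else {
      X[rows, mis] <- rep(m$mean[mis], each = length(rows))
    }
  }
  as.data.frame(X)
}

#' Structure and parameter learning with missing data (Structural EM)
#'
#' Starts from the empty structure fitted on available-case marginals, then
#' alternates (E) conditional-mean imputation of the missing cells under the
#' current network with (M) hill-climbing structure search and OLS parameter
#' fitting on the completed data. Stops when the completed-data BIC improves
#' by less than `score_tol`, when the arc set repeats, or at `max_iter`.
#' With complete data this reduces to a single hill climb plus fit.
#'
#' @param data data frame with `NA` for missing cells.
#' @param blacklist optional forbidden-arc matrix.
#' @param max_iter maximum EM iterations (>= 1).
#' @param score_tol convergence tolerance on the completed-data BIC.
#' @param seed optional integer seed (passed to the structure search).
#' @param restarts,max_parents passed to [hill_climb()].
#' @param binary binary root nodes (see [lgn()]).
#' @return fitted [lgn] with attribute `"em_log"`: a data frame with one row
#'   per iteration (`iter`, `n_arcs`, `score`).
#' @export
structural_em <- function(data, blacklist = NULL, max_iter = 10,
                          score_tol = 1e-3, seed = NULL, restarts = 1,
                          max_parents = Inf, binary = character(0)) {
  stopifnot(max_iter >= 1, score_tol > 0)
  X <- as.data.frame(data)
  nodes <- colnames(X)

  # binary roots stay roots: forbid every arc into them
  if (length(binary)) {
    into_bin <- cbind(from = rep(setdiff(nodes, binary), times = length(binary)),
                      to = rep(binary, each = length(nodes) - length(binary)))
    blacklist <- rbind(blacklist, into_bin)
  }

  if (!anyNA(X)) {
    g <- hill_climb(X, blacklist, restarts = restarts, seed = seed,
                    max_parents = max_parents)
    net <- fit_lgn(X, g, binary = binary)
    attr(net, "em_log") <- data.frame(iter = 1L, n_arcs = nrow(g$arcs),
                                      score = attr(g, "score"))
    return(net)
  }

  n_obs <- colSums(!is.na(X))
  if (any(n_obs == 0)) {
    stop("variable(s) with no observed values: ",
         paste(nodes[n_obs == 0], collapse = ", "))
  }

  # initial model: empty structure, available-case marginals
  g0 <- dag(nodes)
  params <- lapply(nodes, function(v) {
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
  names(params) <- nodes
  net <- lgn(g0, params, binary = binary)

  log <- data.frame(iter = integer(0), n_arcs = integer(0), score = numeric(0))
  prev_score <- -Inf
  prev_arcs <- NULL
  for (it in seq_len(max_iter)) {
    completed <- impute_lgn(net, X)
    g <- hill_climb(completed, blacklist, restarts = restarts,
                    seed = if (is.null(seed)) NULL else seed + it - 1,
                    max_parents = max_parents)
    net <- fit_lgn(completed, g, binary = binary)
    sc <- attr(g, "score")
    log <- rbind(log, data.frame(iter = it, n_arcs = nrow(g$arcs), score = sc))
    arcs_now <- sort(arc_keys(g$arcs))
    if (!is.null(prev_arcs) &&
        (identical(arcs_now, prev_arcs) || abs(sc - prev_score) < score_tol)) break
    prev_score <- sc
    prev_arcs <- arcs_now
  }
  attr(net, "em_log") <- log
  net
}
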