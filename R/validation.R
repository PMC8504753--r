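#' Prediction-error metrics
#'
#' Mean absolute error, mean squared error, its square root, and the Pearson
#' correlation between observed and predicted values. When the observed
#' vector is constant the correlation is undefined; `NA` is returned for `r`
#' with a warning while the error metrics are still computed.
#'
#' @param observed,predicted numeric vectors of equal length (>= 2).
#' @return named list `mae`, `mse`, `rmse`, `r`.
#' @export
error_metrics <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted), length(observed) >= 2)
  d <- observed - predicted
  mse <- mean(d^2)
  r <- if (stats::sd(observed) == 0 || stats::sd(predicted) == 0) {
    warning("constant vector: Pearson correlation undefined")
    NA_real_
  } else {
    stats::cor(observed, predicted)
  }
  list(mae = mean(abs(d)), mse = mse, rmse = sqrt(mse), r = r)
}

#' Correlation-strength category
#'
#' Classifies `|r|` into the conventional bands: negligible (<= 0.30), low
#' (0.31-0.50), moderate (0.51-0.70), high (0.71-0.90), very high
#' (0.91-1). Values falling between the printed two-decimal band edges are
#' rounded half-up to two decimals first, so the classification is exhaustive.
#'
#' @param r correlation in [-1, 1] (vectorized).
#' @return character vector of category labels.
#' @examples
#' classify_correlation(c(0.72, -0.30, 0.68))
#' @export
classify_correlation <- function(r) {
  if (any(abs(r) > 1 + 1e-12, na.rm = TRUE)) stop("|r| must not exceed 1")
  a <- floor(abs(r) * 100 + 0.5) / 100  # round half-up to 2 decimals
  cut(a, breaks = c(-0.01, 0.30, 0.50, 0.70, 0.90, 1.001),
      labels = c("negligible", "low", "moderate", "high", "very high")) |>
    as.character()
}

#' Nested k-fold cross-validated predictive performance
#'
#' Rows are partitioned into `k` near-equal folds (seeded). For every fold the
#' full model-averaging pipeline — bootstrap resampling, Structural EM on each
#' resample, strength thresholding, parameter fitting — is run on the other
#' `k - 1` folds only, and each variable in the held-out fold is predicted
#' from its consensus parents' observed values through the fitted local
#' regression (parent-free variables are predicted by the training mean).
#' Held-out predictor values that are missing are replaced by training means;
#' held-out rows whose target value is missing are skipped for that variable.
#' Out-of-fold predictions are pooled before the per-variable metrics are
#' computed.
#'
#' @param data data frame, possibly with missing cells.
#' @param k number of folds (default 10).
#' @param blacklist optional forbidden-arc matrix.
#' @param B bootstrap resamples per training fold.
#' @param threshold consensus inclusion threshold.
#' @param seed integer seed controlling fold assignment and training.
#' @param binary binary root nodes, excluded from the metric table.
#' @param ... further arguments to [structural_em()].
#' @return data frame with one row per continuous variable: `variable`,
#'   `correlation`, `strength`, `rmse`, `mse`, `mae`. The pooled predictions
#'   are attached as attribute `"predictions"`.
#' @export
nested_cv <- function(data, k = 10, blacklist = NULL, B = 200, threshold = 0.5,
                      seed = NULL, binary = character(0), ...) {
  X <- as.data.frame(data)
  n <- nrow(X)
  stopifnot(n >= 2 * k)
  folds <- with_seed(seed, sample(rep_len(seq_len(k), n)))
  vars <- setdiff(colnames(X), binary)
  pred <- matrix(NA_real_, n, length(vars), dimnames = list(NULL, vars))

  for (f in seq_len(k)) {
    train <- X[folds != f, , drop = FALSE]
    test <- X[folds == f, , drop = FALSE]
    if (nrow(test) < 1 || nrow(train) < 3) stop("fold ", f, " too small for fitting")
    fold_seed <- if (is.null(seed)) NULL else (seed + 1000 * f) %% 2147483647
    dags <- bootstrap_structures(train, blacklist, B = B, seed = fold_seed,
                                 binary = binary, ...)
    cons <- consensus_dag(arc_strengths(dags), threshold, nodes = colnames(X))
    net <- fit_consensus(train, cons, binary = binary)
    train_means <- colMeans(train, na.rm = TRUE)
    for (v in vars) {
      pr <- net$params[[v]]
      pa <- names(pr$coefficients)
      if (length(pa)) {
        Z <- as.matrix(test[, pa, drop = FALSE])
        for (q in seq_along(pa)) Z[is.na(Z[, q]), q] <- train_means[pa[q]]
        pred[folds == f, v] <- pr$intercept + as.numeric(Z %*% pr$coefficients)
      } else {
        pred[folds == f, v] <- pr$intercept
      }
    }
  }

  rows <- lapply(vars, function(v) {
    ok <- !is.na(X[[v]])
    m <- error_metrics(X[[v]][ok], pred[ok, v])
    data.frame(variable = v, correlation = m$r,
               strength = classify_correlation(m$r),
               rmse = m$rmse, mse = m$mse, mae = m$mae,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "predictions") <- pred
  attr(out, "folds") <- folds
  out
}

#' Write a validation metric table as delimited text
#' @param metrics data frame from [nested_cv()].
#' @param file output path.
#' @export
write_metrics <- function(metrics, file) {
  utils::write.table(metrics, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
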