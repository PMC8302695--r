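#' Bray-Curtis similarity between two non-negative vectors
#'
#' 1 - sum(|u - v|) / sum(u + v), the community-ecology similarity used to
#' compare predicted and observed community profiles. Negative entries
#' (possible in unclipped model predictions) are clipped to 0 first, with a
#' warning, because the metric is undefined for negative masses. Two
#' all-zero vectors are defined as identical (similarity 1) with a warning.
#'
#' @param u,v numeric vectors of equal length.
#' @return a number in \[0, 1\].
#' @export
bray_curtis_similarity <- function(u, v) {
  stopifnot(length(u) == length(v))
  if (any(u < 0) || any(v < 0)) {
    warning("negative entries clipped to 0 for Bray-Curtis")
    u <- pmax(u, 0)
    v <- pmax(v, 0)
  }
  tot <- sum(u + v)
  if (tot == 0) {
    warning("both vectors all-zero; Bray-Curtis similarity defined as 1")
    return(1)
  }
  1 - sum(abs(u - v)) / tot
}

#' Relative root-mean-square error
#'
#' sqrt(mean((y - t)^2)) / max(y): the RMSE of the predictions scaled by the
#' maximum observed value, so it is invariant to jointly rescaling both
#' vectors.
#'
#' @param y observed values.
#' @param t predicted values (same length).
#' @return a non-negative number; 0 iff the vectors are equal.
#' @export
relative_rmse <- function(y, t) {
  stopifnot(length(y) == length(t), length(y) >= 1L)
  y_max <- max(y)
  if (y_max == 0) stop("relative RMSE undefined: max(y) = 0")
  sqrt(mean((y - t)^2)) / y_max
}

#' Squared correlation between observed and predicted values
#'
#' By default the squared Pearson correlation (the correlation-based
#' validation of predicted against observed values); the regression
#' coefficient of determination 1 - SS_res/SS_tot is available as
#' `method = "cod"` and can be negative for predictions worse than the mean.
#'
#' @param y observed values (non-constant).
#' @param t predicted values (non-constant for `method = "pearson"`).
#' @param method `"pearson"` (default) or `"cod"`.
#' @return a number (in \[0, 1\] for `"pearson"`).
#' @export
r_squared <- function(y, t, method = c("pearson", "cod")) {
  method <- match.arg(method)
  stopifnot(length(y) == length(t))
  if (stats::sd(y) == 0) stop("observed vector is constant")
  if (method == "pearson") {
    if (stats::sd(t) == 0) stop("predicted vector is constant")
    return(stats::cor(y, t)^2)
  }
  1 - sum((y - t)^2) / sum((y - mean(y))^2)
}

new_cv_result <- function(observed, predicted, targets, method, dropped,
                          provenance) {
  stopifnot(identical(dim(observed), dim(predicted)),
            !anyNA(predicted))
  structure(list(observed = observed, predicted = predicted,
                 targets = targets, method = method, dropped = dropped,
                 provenance = provenance),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %d folds x %d targets (%s prediction)\n",
              nrow(x$predicted), ncol(x$predicted), x$method))
  invisible(x)
}

#' Leave-one-out cross-validation of the network pipeline
#'
#' For every sample i, structure and parameters are learned on the other
#' n - 1 samples (hill climb + ML fit) and the targets of sample i are
#' predicted from the remaining columns as evidence. Columns that become
#' constant within a training fold are dropped for that fold (recorded in
#' the result) and predicted as their constant training value if they are
#' targets.
#'
#' @param data normalized `feature_table` (n >= 3).
#' @param constraints optional `edge_constraints`.
#' @param targets variables to predict for the held-out sample.
#' @param method prediction method, `"parents"` or `"joint"`; see
#'   [predict_nodes()].
#' @param max_iter hill-climb step budget per fold.
#' @param keep_models if TRUE, the per-fold fitted networks are retained
#'   (needed for evidence-only knockout).
#' @return a `cv_result` with observed and predicted matrices (one row per
#'   held-out sample).
#' @export
loo_cv <- function(data, constraints = NULL, targets,
                   method = c("parents", "joint"), max_iter = 500L,
                   keep_models = FALSE) {
  method <- match.arg(method)
  validate_feature_table(data)
  x <- data$values
  n <- nrow(x)
  if (n < 3L) stop("leave-one-out needs n >= 3")
  if (!all(targets %in% colnames(x))) stop("unknown target variable")
  constraints <- constraints %||% edge_constraints()
  predicted <- matrix(NA_real_, n, length(targets),
                      dimnames = list(rownames(x), targets))
  dropped <- vector("list", n)
  models <- if (keep_models) vector("list", n)
  pre <- precompute_search(colnames(x), constraints)
  for (i in seq_len(n)) {
    fold <- fit_fold(x[-i, , drop = FALSE], constraints, max_iter, pre)
    dropped[[i]] <- fold$dropped
    predicted[i, ] <- predict_fold(fold, x[i, ], targets, method)
    if (keep_models) models[[i]] <- fold
  }
  res <- new_cv_result(
    observed = x[, targets, drop = FALSE], predicted = predicted,
    targets = targets, method = method, dropped = dropped,
    provenance = list(model = "bn", constraints = constraints,
                      max_iter = max_iter, score = "gaussian-bic"))
  if (keep_models) res$models <- models
  res
}

# Precompute the search inputs shared by every fold over the same columns.
precompute_search <- function(nodes, constraints) {
  cm <- constraint_matrices(constraints, nodes)
  if (!dag_is_acyclic(cm$whitelist)) stop("whitelist alone contains a cycle")
  list(cm = cm, rank = as.integer(rank(nodes, ties.method = "first")),
       nodes = nodes)
}

# Learn structure + parameters on one training matrix, dropping constant
# columns first. `pre` caches the constraint matrices for the no-drop case.
fit_fold <- function(train, constraints, max_iter, pre = NULL) {
  rng <- apply(train, 2L, function(v) v[which.max(v)] - v[which.min(v)])
  keep <- colnames(train)[rng > 0]
  dropped <- setdiff(colnames(train), keep)
  if (length(dropped) || is.null(pre)) {
    pre <- precompute_search(keep, subset_constraints(constraints, keep))
    train_k <- train[, keep, drop = FALSE]
  } else {
    train_k <- train
  }
  res <- .hc_search(train_k, pre$cm$blacklist, pre$cm$whitelist,
                    pre$cm$whitelist, pre$rank, as.integer(max_iter))
  amat <- res$amat
  dimnames(amat) <- list(keep, keep)
  bn <- fit_amat(amat, train_k)
  const_values <- if (length(dropped)) {
    stats::setNames(train[1L, dropped], dropped)
  } else numeric(0)
  list(bn = bn, kept = keep, dropped = dropped, const_values = const_values)
}

# ML fit straight from an adjacency matrix (search output is guaranteed
# acyclic, so dag() revalidation is skipped in the fold hot path).
fit_amat <- function(amat, x) {
  nodes <- colnames(amat)
  n <- nrow(x)
  params <- stats::setNames(vector("list", length(nodes)), nodes)
  for (j in seq_along(nodes)) {
    pa <- nodes[amat[, j]]
    Z <- cbind(1, x[, pa, drop = FALSE])
    q <- qr(Z)
    if (q$rank < ncol(Z)) {
      stop(sprintf("collinear parents in family of node '%s'", nodes[j]))
    }
    beta <- qr.coef(q, x[, nodes[j]])
    res <- x[, nodes[j]] - Z %*% beta
    params[[j]] <- list(intercept = unname(beta[1L]),
                        coef = stats::setNames(unname(beta[-1L]), pa),
                        sigma2 = max(sum(res^2) / n, 1e-12))
  }
  idx <- which(amat, arr.ind = TRUE)
  g <- structure(list(nodes = nodes,
                      edges = canonical_edge_order(
                        data.frame(from = nodes[idx[, 1L]],
                                   to = nodes[idx[, 2L]],
                                   stringsAsFactors = FALSE), nodes)),
                 class = "bn_dag")
  structure(list(dag = g, params = params, n = n), class = "lgbn")
}

predict_fold <- function(fold, row, targets, method, zero_evidence = character(0)) {
  evidence <- row[setdiff(fold$kept, targets)]
  if (length(zero_evidence)) {
    z <- intersect(names(evidence), zero_evidence)
    evidence[z] <- 0
  }
  live <- intersect(targets, fold$kept)
  out <- stats::setNames(rep(NA_real_, length(targets)), targets)
  if (length(live)) {
    out[live] <- predict_nodes(fold$bn, evidence, live, method = method)
  }
  const <- intersect(targets, names(fold$const_values))
  out[const] <- fold$const_values[const]
  out
}

#' Average-abundance null model
#'
#' The baseline the network must beat: each target of the left-out sample is
#' predicted as the mean of that variable over the n - 1 training samples
#' (training-fold means, mirroring the leave-one-out discipline).
#'
#' @param data `feature_table` (n >= 2).
#' @param targets variables to predict.
#' @return a `cv_result`.
#' @export
null_model_predict <- function(data, targets) {
  validate_feature_table(data)
  x <- data$values
  n <- nrow(x)
  if (n < 2L) stop("null model needs n >= 2")
  if (!all(targets %in% colnames(x))) stop("unknown target variable")
  predicted <- vapply(seq_len(n), function(i) {
    colMeans(x[-i, targets, drop = FALSE])
  }, numeric(length(targets)))
  predicted <- matrix(predicted, nrow = n, byrow = TRUE,
                      dimnames = list(rownames(x), targets))
  new_cv_result(observed = x[, targets, drop = FALSE], predicted = predicted,
                targets = targets, method = "null-mean", dropped = NULL,
                provenance = list(model = "null"))
}

#' Community reconstruction report
#'
#' Compares network and null-model leave-one-out reconstructions: the mean
#' per-sample Bray-Curtis similarity between predicted and observed
#' community profiles for both models (negative predictions clipped to 0),
#' plus per-variable squared correlation and relative RMSE for both. All
#' quantities are computed on the normalized scale used for modeling.
#'
#' @param cv `cv_result` from [loo_cv()].
#' @param null `cv_result` from [null_model_predict()] over the same samples
#'   and targets.
#' @return object of class `validation_metrics`: `bray_curtis_mean`,
#'   `null_bray_curtis_mean`, a `per_variable` data.frame (variable, model,
#'   r_squared, relative_rmse) and provenance.
#' @export
community_reconstruction_report <- function(cv, null) {
  stopifnot(inherits(cv, "cv_result"), inherits(null, "cv_result"))
  if (!identical(dimnames(cv$predicted), dimnames(null$predicted))) {
    stop("cv and null results must cover the same samples and targets")
  }
  bc_mean <- function(res) {
    pred <- pmax(res$predicted, 0)
    mean(vapply(seq_len(nrow(pred)), function(i) {
      suppressWarnings(bray_curtis_similarity(res$observed[i, ], pred[i, ]))
    }, numeric(1)))
  }
  per_var <- do.call(rbind, lapply(cv$targets, function(v) {
    row <- function(res, model) {
      r2 <- tryCatch(r_squared(res$observed[, v], res$predicted[, v]),
                     error = function(e) NA_real_)
      data.frame(variable = v, model = model, r_squared = r2,
                 relative_rmse = relative_rmse(res$observed[, v],
                                               res$predicted[, v]),
                 stringsAsFactors = FALSE)
    }
    rbind(row(cv, "bn"), row(null, "null"))
  }))
  rownames(per_var) <- NULL
  structure(list(bray_curtis_mean = bc_mean(cv),
                 null_bray_curtis_mean = bc_mean(null),
                 per_variable = per_var,
                 prediction_method = cv$method,
                 provenance = cv$provenance),
            class = "validation_metrics")
}

#' @export
print.validation_metrics <- function(x, ...) {
  cat(sprintf("<validation_metrics> Bray-Curtis bn = %.3f, null = %.3f (%s prediction)\n",
              x$bray_curtis_mean, x$null_bray_curtis_mean,
              x$prediction_method))
  print(x$per_variable)
  invisible(x)
}

#' Write a validation report as TSV and JSON
#'
#' @param report a `validation_metrics`.
#' @param tsv_path,json_path output paths (either may be NULL to skip).
#' @return `report`, invisibly.
#' @export
write_validation_report <- function(report, tsv_path = NULL, json_path = NULL) {
  stopifnot(inherits(report, "validation_metrics"))
  if (!is.null(tsv_path)) {
    summary_rows <- data.frame(
      variable = "__community__", model = c("bn", "null"),
      r_squared = NA_real_,
      relative_rmse = NA_real_,
      bray_curtis_mean = c(report$bray_curtis_mean,
                           report$null_bray_curtis_mean),
      stringsAsFactors = FALSE)
    pv <- report$per_variable
    pv$bray_curtis_mean <- NA_real_
    write_tsv_exact(rbind(pv, summary_rows), tsv_path)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(bray_curtis_mean = report$bray_curtis_mean,
           null_bray_curtis_mean = report$null_bray_curtis_mean,
           prediction_method = report$prediction_method,
           per_variable = report$per_variable),
      json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(report)
}
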