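#' Gaussian BIC score of a DAG
#'
#' Decomposable network score maximized by the hill-climbing search: for each
#' node, the maximized Gaussian log-likelihood of the node given its parents
#' (ordinary least squares; ML residual variance RSS/n, floored at 1e-12)
#' minus the BIC penalty (k/2) * ln(n) with k = |parents| + 2 (intercept,
#' coefficients, variance). Higher is better. A singular family regression
#' (collinear parents) scores -Inf, which effectively forbids the edge.
#'
#' @param dag a `bn_dag`.
#' @param data `feature_table` or numeric matrix whose columns cover the DAG
#'   nodes; n must exceed the parameter count of the largest family.
#' @return a single number (sum of per-family scores).
#' @export
bic_score <- function(dag, data) {
  x <- if (inherits(data, "feature_table")) data$values else as.matrix(data)
  if (!all(dag$nodes %in% colnames(x))) stop("data columns must cover dag nodes")
  n <- nrow(x)
  total <- 0
  for (node in dag$nodes) {
    total <- total + family_score(x[, node], x[, dag_parents(dag, node),
                                              drop = FALSE], n)
    if (!is.finite(total)) return(-Inf)
  }
  total
}

# Score of one family (node given parents). X may have zero columns.
family_score <- function(y, X, n = length(y)) {
  k <- ncol(X) + 2L
  if (n < k) return(-Inf)  # family larger than the data can support
  Z <- cbind(1, X)
  q <- qr(Z)
  if (q$rank < ncol(Z)) return(-Inf)
  res <- qr.resid(q, y)
  sigma2 <- max(sum(res^2) / n, 1e-12)
  loglik <- -(n / 2) * (log(2 * pi * sigma2) + 1)
  loglik - (k / 2) * log(n)
}

#' Exhaustive BIC-optimal structure search (test oracle)
#'
#' Enumerates every labeled DAG over at most five nodes that honors the
#' constraints (all whitelisted edges present, no blacklisted edge) and
#' returns the BIC-maximal one. Ties are broken deterministically by a fixed
#' enumeration order in which sparser graphs are reached first (bitmask over
#' the sorted candidate-pair list starting from the whitelist-only graph).
#' Intended as an independent optimum against which [hill_climb()] is
#' checked; infeasible beyond five nodes.
#'
#' @param data `feature_table` or numeric matrix.
#' @param constraints optional `edge_constraints`.
#' @return list with `dag` (the optimal `bn_dag`), `score`, and `n_dags`
#'   (number of admissible DAGs enumerated).
#' @export
exhaustive_search <- function(data, constraints = NULL) {
  x <- if (inherits(data, "feature_table")) data$values else as.matrix(data)
  nodes <- colnames(x)
  p <- length(nodes)
  if (p > 5L) stop("exhaustive search supports at most 5 nodes")
  constraints <- constraints %||% edge_constraints()
  cm <- constraint_matrices(constraints, nodes)
  pairs <- which(!diag(TRUE, p) & !cm$blacklist & !cm$whitelist, arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1L], pairs[, 2L]), , drop = FALSE]
  m <- nrow(pairs)
  base <- cm$whitelist
  if (!dag_is_acyclic(base)) stop("whitelist alone contains a cycle")

  # cache family scores: per child, keyed by parent-set bitmask
  n <- nrow(x)
  cache <- lapply(seq_len(p), function(i) new.env(parent = emptyenv()))
  fam <- function(child, parents) {
    key <- paste0("p", paste(parents, collapse = ","))
    env <- cache[[child]]
    if (!is.null(env[[key]])) return(env[[key]])
    s <- family_score(x[, child], x[, parents, drop = FALSE], n)
    env[[key]] <- s
    s
  }
  score_amat <- function(A) {
    s <- 0
    for (j in seq_len(p)) s <- s + fam(j, which(A[, j]))
    s
  }

  best <- NULL
  best_score <- -Inf
  n_dags <- 0L
  for (mask in 0:(2^m - 1)) {
    A <- base
    if (m > 0 && mask > 0) {
      bits <- which(bitwAnd(mask, 2^(seq_len(m) - 1L)) > 0)
      A[pairs[bits, , drop = FALSE]] <- TRUE
    }
    if (!dag_is_acyclic(A)) next
    n_dags <- n_dags + 1L
    s <- score_amat(A)
    if (s > best_score) {
      best_score <- s
      best <- A
    }
  }
  list(dag = amat_to_dag(best, nodes), score = best_score, n_dags = n_dags)
}
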