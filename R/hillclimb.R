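#' Hill-climbing structure learning under edge constraints
#'
#' Greedy maximization of the Gaussian BIC score (see [bic_score()]) over
#' DAGs, starting from the whitelist-only graph and repeatedly applying the
#' single highest-scoring legal operator (add, delete or reverse an edge; an
#' operator is legal when the result is acyclic, contains no blacklisted
#' edge, and never deletes or reverses a whitelisted edge). The search stops
#' at a local optimum. Ties between operators are broken lexicographically on
#' (operator kind: add < delete < reverse, parent name, child name), so the
#' result is deterministic and independent of column order. Optional seeded
#' random restarts perturb the start graph with random legal edges and keep
#' the best-scoring local optimum.
#'
#' @param data `feature_table` or numeric matrix, already normalized and free
#'   of zero-variance columns.
#' @param constraints optional `edge_constraints`.
#' @param max_iter maximum number of greedy steps (default 500).
#' @param restarts number of additional random restarts (default 0: a single
#'   deterministic run).
#' @param seed integer seed for the restarts (ignored when `restarts = 0`).
#' @return list with `dag` (a `bn_dag`), `score` (its BIC), and `iterations`.
#' @export
hill_climb <- function(data, constraints = NULL, max_iter = 500L,
                       restarts = 0L, seed = 1L) {
  x <- if (inherits(data, "feature_table")) data$values else as.matrix(data)
  nodes <- colnames(x)
  if (is.null(nodes)) stop("data must have column names")
  sds <- apply(x, 2L, stats::sd)
  if (any(sds == 0)) {
    stop(sprintf("zero-variance column(s): %s; drop them first",
                 paste(nodes[sds == 0], collapse = ", ")))
  }
  constraints <- constraints %||% edge_constraints()
  cm <- constraint_matrices(constraints, nodes)
  if (!dag_is_acyclic(cm$whitelist)) stop("whitelist alone contains a cycle")
  rank <- as.integer(rank(nodes, ties.method = "first"))
  kmax <- max(colSums(cm$whitelist)) + 2L
  if (nrow(x) < kmax) stop("too few samples for the whitelisted families")

  run <- function(start) {
    res <- .hc_search(x, cm$blacklist, cm$whitelist, start, rank,
                      as.integer(max_iter))
    amat <- res$amat
    dimnames(amat) <- list(nodes, nodes)
    list(dag = amat_to_dag(amat, nodes), score = res$score,
         iterations = res$iterations)
  }

  best <- run(cm$whitelist)
  if (restarts > 0L) {
    p <- length(nodes)
    starts <- with_seed(seed, lapply(seq_len(restarts), function(r) {
      wl <- cm$whitelist
      free <- which(!diag(TRUE, p) & !cm$blacklist & !wl)
      for (e in free[sample.int(length(free), min(length(free), p))]) {
        cand <- wl
        cand[e] <- TRUE
        if (dag_is_acyclic(cand)) wl <- cand
      }
      wl
    }))
    for (st in starts) {
      # random start edges are ordinary (deletable) edges; only the true
      # whitelist is protected during search
      cand <- run(st)
      if (cand$score > best$score) best <- cand
    }
  }
  best
}
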