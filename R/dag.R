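#' Directed acyclic graphs over model variables
#'
#' Lightweight DAG container used throughout the network code: a node name
#' vector plus an edge data.frame. Construction enforces the invariants
#' (known nodes, no self-loops, no duplicate edges, acyclicity).
#'
#' @param nodes character vector of unique node names.
#' @param edges data.frame with character columns `from`, `to` (may have zero
#'   rows).
#' @return object of class `bn_dag`.
#' @export
dag <- function(nodes, edges = empty_edges()) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) stop("duplicate node names")
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (nrow(edges) == 0L) edges <- empty_edges()
  edges <- edges[, c("from", "to")]
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  unknown <- setdiff(unique(c(edges$from, edges$to)), nodes)
  if (length(unknown)) {
    stop(sprintf("edge references unknown node(s): %s",
                 paste(unknown, collapse = ", ")))
  }
  if (any(edges$from == edges$to)) stop("self-loops are not allowed")
  if (anyDuplicated(paste(edges$from, edges$to, sep = "\r"))) {
    stop("duplicate edges are not allowed")
  }
  g <- structure(list(nodes = nodes, edges = canonical_edge_order(edges, nodes)),
                 class = "bn_dag")
  if (!dag_is_acyclic(g)) stop("edge set contains a cycle")
  g
}

empty_edges <- function() {
  data.frame(from = character(0), to = character(0), stringsAsFactors = FALSE)
}

# Canonical edge order: by (child index, parent index) in node order, so that
# identical graphs always compare and serialize identically.
canonical_edge_order <- function(edges, nodes) {
  o <- order(match(edges$to, nodes), match(edges$from, nodes))
  ed <- edges[o, , drop = FALSE]
  rownames(ed) <- NULL
  ed
}

#' @export
print.bn_dag <- function(x, ...) {
  cat(sprintf("<bn_dag> %d nodes, %d edges\n", length(x$nodes), nrow(x$edges)))
  if (nrow(x$edges)) {
    cat(paste(sprintf("  %s -> %s", x$edges$from, x$edges$to), collapse = "\n"),
        "\n")
  }
  invisible(x)
}

#' Adjacency matrix of a DAG
#' @param g a `bn_dag`.
#' @return logical matrix A with A\[i, j\] = TRUE iff edge i -> j.
#' @export
dag_amat <- function(g) {
  p <- length(g$nodes)
  A <- matrix(FALSE, p, p, dimnames = list(g$nodes, g$nodes))
  if (nrow(g$edges)) {
    A[cbind(match(g$edges$from, g$nodes), match(g$edges$to, g$nodes))] <- TRUE
  }
  A
}

amat_to_dag <- function(A, nodes) {
  idx <- which(A, arr.ind = TRUE)
  dag(nodes, data.frame(from = nodes[idx[, 1L]], to = nodes[idx[, 2L]],
                        stringsAsFactors = FALSE))
}

#' Test a DAG (or adjacency matrix) for acyclicity
#' @param g a `bn_dag` or logical adjacency matrix.
#' @return TRUE iff no directed cycle exists.
#' @export
dag_is_acyclic <- function(g) {
  A <- if (inherits(g, "bn_dag")) dag_amat(g) else g
  # Kahn's algorithm
  indeg <- colSums(A)
  active <- rep(TRUE, ncol(A))
  repeat {
    src <- which(active & indeg == 0)
    if (!length(src)) break
    for (s in src) {
      indeg <- indeg - A[s, ]
      active[s] <- FALSE
    }
  }
  !any(active)
}

#' Topological order of a DAG
#' @param g a `bn_dag`.
#' @return node names, parents before children; ties resolved by node order.
#' @export
dag_topo_sort <- function(g) {
  A <- dag_amat(g)
  indeg <- colSums(A)
  out <- character(0)
  active <- rep(TRUE, ncol(A))
  while (any(active)) {
    s <- which(active & indeg == 0)[1L]
    if (is.na(s)) stop("graph contains a cycle")
    out <- c(out, g$nodes[s])
    indeg <- indeg - A[s, ]
    active[s] <- FALSE
  }
  out
}

#' Parents of a node
#' @param g a `bn_dag`.
#' @param node node name.
#' @return character vector of parent names in canonical node order.
#' @export
dag_parents <- function(g, node) {
  p <- g$edges$from[g$edges$to == node]
  g$nodes[sort(match(p, g$nodes))]
}
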