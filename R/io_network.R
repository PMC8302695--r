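#' Export a fitted network as a TSV pair
#'
#' Edge list (parent, child, coefficient) and node table (node, intercept,
#' residual_variance, tier, mechanism). Numbers are printed with 17
#' significant digits, so [read_bn()] reconstructs the object bit-exactly.
#'
#' @param bn an `lgbn`.
#' @param edge_path,node_path output paths.
#' @param metadata optional `feature_table` or metadata data.frame providing
#'   tier/mechanism columns; unknown nodes get NA.
#' @return `edge_path`, invisibly.
#' @export
write_bn <- function(bn, edge_path, node_path, metadata = NULL) {
  stopifnot(inherits(bn, "lgbn"))
  if (inherits(metadata, "feature_table")) metadata <- metadata$metadata
  ed <- bn$dag$edges
  coef <- vapply(seq_len(nrow(ed)), function(k) {
    bn$params[[ed$to[k]]]$coef[[ed$from[k]]]
  }, numeric(1))
  write_tsv_exact(data.frame(parent = ed$from, child = ed$to,
                             coefficient = coef, stringsAsFactors = FALSE),
                  edge_path)
  nodes <- bn$dag$nodes
  lookup <- function(col) {
    if (is.null(metadata)) return(rep(NA_character_, length(nodes)))
    as.character(metadata[[col]][match(nodes, metadata$variable)])
  }
  write_tsv_exact(data.frame(
    node = nodes,
    intercept = vapply(nodes, function(v) bn$params[[v]]$intercept, numeric(1)),
    residual_variance = vapply(nodes, function(v) bn$params[[v]]$sigma2,
                               numeric(1)),
    tier = lookup("tier"), mechanism = lookup("mechanism"),
    stringsAsFactors = FALSE), node_path)
  invisible(edge_path)
}

#' Import a network written by [write_bn()]
#'
#' @param edge_path,node_path the TSV pair.
#' @return an `lgbn`, bit-identical to the exported one.
#' @export
read_bn <- function(edge_path, node_path) {
  ed <- read_tsv_exact(edge_path)
  nd <- read_tsv_exact(node_path)
  g <- dag(as.character(nd$node),
           data.frame(from = as.character(ed$parent),
                      to = as.character(ed$child), stringsAsFactors = FALSE))
  params <- lapply(seq_len(nrow(nd)), function(i) {
    node <- nd$node[i]
    pa <- dag_parents(g, node)
    coef <- vapply(pa, function(p) {
      as.numeric(ed$coefficient[ed$parent == p & ed$child == node])
    }, numeric(1))
    list(intercept = as.numeric(nd$intercept[i]),
         coef = stats::setNames(coef, pa),
         sigma2 = as.numeric(nd$residual_variance[i]))
  })
  names(params) <- nd$node
  structure(list(dag = g, params = params, n = NA_integer_), class = "lgbn")
}

as_igraph <- function(x, metadata = NULL) {
  g <- if (inherits(x, "lgbn")) x$dag else x
  stopifnot(inherits(g, "bn_dag"))
  ig <- igraph::graph_from_data_frame(g$edges, directed = TRUE,
                                      vertices = data.frame(name = g$nodes))
  if (inherits(metadata, "feature_table")) metadata <- metadata$metadata
  if (!is.null(metadata)) {
    idx <- match(g$nodes, metadata$variable)
    igraph::V(ig)$tier <- as.character(metadata$tier[idx])
    igraph::V(ig)$mechanism <- as.character(metadata$mechanism[idx])
  }
  if (inherits(x, "lgbn") && nrow(g$edges)) {
    igraph::E(ig)$coefficient <- vapply(seq_len(nrow(g$edges)), function(k) {
      x$params[[g$edges$to[k]]]$coef[[g$edges$from[k]]]
    }, numeric(1))
  }
  ig
}

#' Export a network for visualization (GraphML or DOT)
#'
#' @param x an `lgbn` or `bn_dag`.
#' @param path output file; format chosen by `format`.
#' @param format `"graphml"` or `"dot"`.
#' @param metadata optional metadata supplying tier/mechanism node
#'   attributes.
#' @return `path`, invisibly.
#' @export
export_network <- function(x, path, format = c("graphml", "dot"),
                           metadata = NULL) {
  format <- match.arg(format)
  ig <- as_igraph(x, metadata)
  igraph::write_graph(ig, path, format = format)
  invisible(path)
}
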