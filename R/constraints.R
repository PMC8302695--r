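#' Edge constraint sets (blacklist / whitelist)
#'
#' A blacklist forbids directed edges during structure search; a whitelist
#' forces them. Constructor enforces that the two sets are disjoint and that
#' the whitelist alone is acyclic.
#'
#' @param blacklist data.frame with columns `from`, `to` (may be empty).
#' @param whitelist data.frame with columns `from`, `to` (may be empty).
#' @return object of class `edge_constraints`.
#' @export
edge_constraints <- function(blacklist = empty_edges(),
                             whitelist = empty_edges()) {
  norm <- function(x) {
    x <- as.data.frame(x, stringsAsFactors = FALSE)
    if (nrow(x) == 0L) return(empty_edges())
    x <- x[, c("from", "to")]
    x$from <- as.character(x$from)
    x$to <- as.character(x$to)
    unique(x)
  }
  bl <- norm(blacklist)
  wl <- norm(whitelist)
  key <- function(x) paste(x$from, x$to, sep = "\r")
  if (length(intersect(key(bl), key(wl)))) {
    stop("blacklist and whitelist overlap")
  }
  if (nrow(wl)) {
    nodes <- unique(c(wl$from, wl$to))
    if (!dag_is_acyclic(dag_amat(
      structure(list(nodes = nodes, edges = wl), class = "bn_dag")))) {
      stop("whitelist alone contains a cycle")
    }
  }
  structure(list(blacklist = bl, whitelist = wl), class = "edge_constraints")
}

#' @export
print.edge_constraints <- function(x, ...) {
  cat(sprintf("<edge_constraints> %d blacklisted, %d whitelisted\n",
              nrow(x$blacklist), nrow(x$whitelist)))
  invisible(x)
}

# Tier ranks encoding the inference direction
# {fermenter, geobacter} -> methanogen -> output. Environment is unranked:
# it may feed any tier but never receives an edge from the output node.
tier_rank <- function(tiers) {
  rank <- c(fermenter = 1, geobacter = 1, methanogen = 2, output = 3,
            environment = NA_real_)
  unknown <- setdiff(unique(tiers), names(rank))
  if (length(unknown)) {
    stop(sprintf("unknown tier label(s): %s", paste(unknown, collapse = ", ")))
  }
  unname(rank[tiers])
}

#' Build the tier blacklist
#'
#' Encodes the inference direction strictly from fermentative bacteria and
#' Geobacter over methanogens to CH4: every edge from a strictly later tier
#' to a strictly earlier tier is forbidden, as is every edge out of the
#' output node. Environment variables are unranked (free to point anywhere)
#' but never receive edges from the output. Fermenter and Geobacter form one
#' tier class, so edges between them are not backward edges.
#'
#' @param metadata data.frame with columns `variable` and `tier` (a
#'   `feature_table` is also accepted).
#' @param allow_within_tier if FALSE, edges within a tier class (fermenter +
#'   geobacter counted as one class, environment as another) are also
#'   blacklisted.
#' @return an `edge_constraints` with the blacklist filled and an empty
#'   whitelist.
#' @export
build_blacklist <- function(metadata, allow_within_tier = TRUE) {
  if (inherits(metadata, "feature_table")) metadata <- metadata$metadata
  vars <- metadata$variable
  tiers <- metadata$tier
  if (anyNA(tiers) || is.null(tiers)) stop("every variable needs a tier")
  rank <- tier_rank(tiers)
  p <- length(vars)
  from <- character(0)
  to <- character(0)
  for (i in seq_len(p)) {
    for (j in seq_len(p)) {
      if (i == j) next
      backward <- !is.na(rank[i]) && !is.na(rank[j]) && rank[i] > rank[j]
      from_output <- tiers[i] == "output"
      same_class <- (identical(rank[i], rank[j]) && !is.na(rank[i])) ||
        (tiers[i] == "environment" && tiers[j] == "environment")
      within <- !allow_within_tier && same_class
      if (backward || from_output || within) {
        from <- c(from, vars[i])
        to <- c(to, vars[j])
      }
    }
  }
  edge_constraints(blacklist = data.frame(from = from, to = to,
                                          stringsAsFactors = FALSE))
}

# Restrict a constraint set to the variables actually present (used when
# zero-variance columns were dropped within a CV fold).
subset_constraints <- function(constraints, vars) {
  keep <- function(x) x[x$from %in% vars & x$to %in% vars, , drop = FALSE]
  edge_constraints(blacklist = keep(constraints$blacklist),
                   whitelist = keep(constraints$whitelist))
}

# Logical p x p matrices for the C++ search.
constraint_matrices <- function(constraints, nodes) {
  p <- length(nodes)
  bl <- matrix(FALSE, p, p, dimnames = list(nodes, nodes))
  wl <- matrix(FALSE, p, p, dimnames = list(nodes, nodes))
  fill <- function(m, df) {
    df <- df[df$from %in% nodes & df$to %in% nodes, , drop = FALSE]
    if (nrow(df)) m[cbind(match(df$from, nodes), match(df$to, nodes))] <- TRUE
    m
  }
  list(blacklist = fill(bl, constraints$blacklist),
       whitelist = fill(wl, constraints$whitelist))
}
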