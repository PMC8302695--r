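#' Ground-truth structural equation models
#'
#' A linear-Gaussian SEM used as the generating model for synthetic
#' expression data: each node equals its intercept plus a weighted sum of
#' its parents plus Gaussian noise. Nodes carry tier and mechanism labels so
#' the generated tables feed directly into constraint building and the
#' knockout experiment. Construction enforces acyclicity, positive noise
#' scales, and the tier ordering (no edge may run from a strictly later
#' tier to a strictly earlier one; output never sends edges).
#'
#' @param nodes data.frame with columns `node`, `tier`, `mechanism`,
#'   `intercept`, `noise_sd`.
#' @param edges data.frame with columns `from`, `to`, `coef`.
#' @return object of class `ground_truth_sem`.
#' @export
ground_truth_sem <- function(nodes, edges) {
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (nrow(edges) == 0L) {
    edges <- data.frame(from = character(0), to = character(0),
                        coef = numeric(0), stringsAsFactors = FALSE)
  }
  stopifnot(all(c("node", "tier", "mechanism", "intercept", "noise_sd")
                %in% names(nodes)),
            all(c("from", "to", "coef") %in% names(edges)))
  if (any(nodes$noise_sd <= 0)) stop("all noise_sd must be > 0")
  g <- dag(nodes$node, edges[, c("from", "to")])  # checks acyclicity etc.
  rank <- tier_rank(nodes$tier)
  rk <- stats::setNames(rank, nodes$node)
  tier_of <- stats::setNames(nodes$tier, nodes$node)
  for (k in seq_len(nrow(edges))) {
    f <- edges$from[k]; t <- edges$to[k]
    if (tier_of[[f]] == "output") {
      stop(sprintf("tier constraint violation: output node '%s' sends an edge", f))
    }
    if (!is.na(rk[[f]]) && !is.na(rk[[t]]) && rk[[f]] > rk[[t]]) {
      stop(sprintf("tier constraint violation: edge %s (%s) -> %s (%s)",
                   f, tier_of[[f]], t, tier_of[[t]]))
    }
  }
  edges <- edges[order(match(edges$to, nodes$node),
                       match(edges$from, nodes$node)), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges, dag = g),
            class = "ground_truth_sem")
}

#' @export
print.ground_truth_sem <- function(x, ...) {
  cat(sprintf("<ground_truth_sem> %d nodes, %d edges\n",
              nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

# View a ground-truth SEM as a fitted-network object (same math, true
# parameters), so moment computations are shared.
sem_as_lgbn <- function(sem) {
  params <- lapply(seq_len(nrow(sem$nodes)), function(i) {
    node <- sem$nodes$node[i]
    ed <- sem$edges[sem$edges$to == node, , drop = FALSE]
    list(intercept = sem$nodes$intercept[i],
         coef = stats::setNames(ed$coef, ed$from),
         sigma2 = sem$nodes$noise_sd[i]^2)
  })
  names(params) <- sem$nodes$node
  structure(list(dag = sem$dag, params = params, n = NA_integer_),
            class = "lgbn")
}

#' Scenario configuration for the synthetic-data generator
#'
#' Bundles every tunable of the generator with validation. Defaults encode
#' the study conditions the pipeline is exercised under: 24 samples (the
#' metatranscriptomic design: 8 reactors x 3 replicates over two batches),
#' a strong hydrogen-transfer path (`iht_effect = 0.8`) against a weak
#' direct-electron-transfer path (`diet_effect = 0.2`), moderate noise
#' (`noise_sd = 0.2` on the unit-scaled latent variables), 22 core taxa and
#' 9 environmental parameters for the community tables, and 3 disconnected
#' distractor genes/taxa.
#'
#' @param n_samples number of samples (>= 3).
#' @param iht_effect path weight of H2-metabolism genes into methanogen
#'   genes (dimensionless, on the unit latent scale).
#' @param diet_effect path weight of EET genes (omc/pilA-like) into
#'   methanogen polyferredoxin genes.
#' @param noise_sd Gaussian noise scale for every endogenous node (> 0).
#' @param seed integer master seed; fully determines all draws.
#' @param n_distractor_taxa disconnected distractor genes/taxa (>= 0).
#' @param n_core_taxa core community size for [simulate_community()].
#' @param n_env number of environmental parameters (including CH4).
#' @param community_effect taxon -> taxon dependence strength in the
#'   community generator (0 gives mutually independent taxa).
#' @param env_effect taxon -> environment dependence strength (0 makes the
#'   environmental parameters pure noise).
#' @param n_genes,mean_gene_length,mean_depth knobs of [simulate_counts()].
#' @return validated list of class `scenario_config`.
#' @export
scenario_config <- function(n_samples = 24L, iht_effect = 0.8,
                            diet_effect = 0.2, noise_sd = 0.2, seed = 1L,
                            n_distractor_taxa = 3L, n_core_taxa = 22L,
                            n_env = 9L, community_effect = 0.8,
                            env_effect = 0.8, n_genes = 20L,
                            mean_gene_length = 1200, mean_depth = 2e6) {
  cfg <- list(n_samples = as.integer(n_samples), iht_effect = iht_effect,
              diet_effect = diet_effect, noise_sd = noise_sd,
              seed = as.integer(seed),
              n_distractor_taxa = as.integer(n_distractor_taxa),
              n_core_taxa = as.integer(n_core_taxa),
              n_env = as.integer(n_env),
              community_effect = community_effect, env_effect = env_effect,
              n_genes = as.integer(n_genes),
              mean_gene_length = mean_gene_length, mean_depth = mean_depth)
  if (cfg$n_samples < 3L) stop("n_samples must be >= 3")
  if (cfg$noise_sd <= 0) stop("noise_sd must be > 0")
  if (cfg$n_distractor_taxa < 0L) stop("n_distractor_taxa must be >= 0")
  if (cfg$n_core_taxa < 1L) stop("n_core_taxa must be >= 1")
  if (cfg$n_env < 1L) stop("n_env must be >= 1 (the CH4 column)")
  structure(cfg, class = "scenario_config")
}

#' Fixed-topology template SEM of the gene cascade
#'
#' Builds the generating analogue of the gene-level network: fermenter genes
#' for alcohol metabolism (adhE-, dhaT-like) feed H2-evolving hydrogenase
#' genes (hyaB-, hox-like) and Geobacter genes; Geobacter carries two
#' EET/DIET nodes (omcF-, pilA-like) and two hydrogen-cycling IHT nodes
#' (hnd-, ech-like); methanogen genes comprise the hydrogen-driven
#' electron-bifurcation complex (mvhADG-, hdrABC-like, mechanism IHT) and a
#' polyferredoxin node (mvhB-like, mechanism DIET, fed by the EET genes);
#' all three feed a single CH4-production output. Every IHT-labelled path
#' into the methanogen tier carries weight `iht_effect` and every
#' DIET-labelled path weight `diet_effect`; distractor genes are
#' disconnected.
#'
#' @param config a `scenario_config`.
#' @return a `ground_truth_sem`.
#' @export
build_template_sem <- function(config = scenario_config()) {
  stopifnot(inherits(config, "scenario_config"))
  s <- config$noise_sd
  node <- function(name, tier, mech) {
    data.frame(node = name, tier = tier, mechanism = mech, intercept = 0,
               noise_sd = s, stringsAsFactors = FALSE)
  }
  nodes <- rbind(
    node("gene_adhE", "fermenter", "other"),
    node("gene_dhaT", "fermenter", "other"),
    node("gene_hyaB", "fermenter", "IHT"),
    node("gene_hox",  "fermenter", "IHT"),
    node("gene_omcF", "geobacter", "DIET"),
    node("gene_pilA", "geobacter", "DIET"),
    node("gene_hnd",  "geobacter", "IHT"),
    node("gene_ech",  "geobacter", "IHT"),
    node("gene_mvhADG", "methanogen", "IHT"),
    node("gene_hdrABC", "methanogen", "IHT"),
    node("gene_mvhB",   "methanogen", "DIET"),
    node("ch4_production", "output", "other")
  )
  # Guild-level gene nodes (exogenous alcohol genes, hydrogen-cycling and
  # EET genes) carry unit intrinsic variability: each gene has substantial
  # regulation of its own beyond what upstream genes explain. noise_sd
  # controls only the residual noise of the integrating methanogen tier and
  # the output, so silencing a gene set removes information that cannot be
  # recovered from the remaining proxies.
  nodes$noise_sd[nodes$tier %in% c("fermenter", "geobacter")] <- 1
  if (config$n_distractor_taxa > 0L) {
    dis_tiers <- rep(c("fermenter", "geobacter", "methanogen"),
                     length.out = config$n_distractor_taxa)
    nodes <- rbind(nodes, do.call(rbind, lapply(
      seq_len(config$n_distractor_taxa),
      function(i) node(sprintf("gene_distractor_%d", i), dis_tiers[i], "other"))))
  }
  e <- function(from, to, coef) {
    data.frame(from = from, to = to, coef = coef, stringsAsFactors = FALSE)
  }
  iht <- config$iht_effect
  diet <- config$diet_effect
  edges <- rbind(
    # alcohol oxidation feeds hydrogen evolution and the Geobacter tier
    e("gene_adhE", "gene_hyaB", 0.7),
    e("gene_dhaT", "gene_hox",  0.7),
    e("gene_adhE", "gene_omcF", 0.6),
    e("gene_dhaT", "gene_pilA", 0.6),
    e("gene_adhE", "gene_hnd",  0.6),
    e("gene_dhaT", "gene_ech",  0.6),
    # IHT paths: hydrogen metabolism into the methanogen bifurcation complex
    e("gene_hyaB", "gene_mvhADG", iht),
    e("gene_hox",  "gene_mvhADG", iht),
    e("gene_hnd",  "gene_mvhADG", iht),
    e("gene_ech",  "gene_hdrABC", iht),
    e("gene_mvhADG", "gene_hdrABC", 0.7),
    # DIET paths: EET genes into the polyferredoxin node
    e("gene_omcF", "gene_mvhB", diet),
    e("gene_pilA", "gene_mvhB", diet),
    # downstream sub-network: methanogen genes to methane production
    e("gene_mvhADG", "ch4_production", 0.5),
    e("gene_hdrABC", "ch4_production", 0.5),
    e("gene_mvhB",   "ch4_production", 0.5)
  )
  ground_truth_sem(nodes, edges)
}

#' Total directed path weight between node sets
#'
#' Sum over all directed paths from any node in `from` to `to` of the
#' product of edge coefficients along the path; the standard path-tracing
#' quantity that determines how strongly a source set drives a sink in a
#' linear SEM.
#'
#' @param sem a `ground_truth_sem`.
#' @param from character vector of source nodes.
#' @param to single sink node.
#' @return a number (0 when no path exists).
#' @export
sem_path_weight <- function(sem, from, to) {
  # dynamic programming over the DAG: w[v] = total path weight v ~> to
  ord <- rev(dag_topo_sort(sem$dag))
  w <- stats::setNames(numeric(length(ord)), ord)
  w[to] <- 1
  for (v in ord) {
    if (v == to) next
    out <- sem$edges[sem$edges$from == v, , drop = FALSE]
    if (nrow(out)) w[v] <- sum(out$coef * w[out$to])
  }
  sum(w[intersect(from, names(w))])
}

#' Simulate gene-expression tables from a SEM
#'
#' Samples each node in topological order as intercept + sum(coef * parent)
#' + Gaussian(0, noise_sd), then shifts every column by a constant so all
#' values are non-negative (expression-like). Shifting rather than
#' truncating keeps the linear-Gaussian structure exact: covariances (and
#' hence everything the network learner sees beyond intercepts) are
#' untouched.
#'
#' @param sem a `ground_truth_sem`.
#' @param n number of samples (>= 1).
#' @param seed integer seed; the same (sem, n, seed) always yields the same
#'   table.
#' @return a `feature_table` with tier/mechanism metadata copied from the
#'   SEM (role `gene`, or `output` for the output-tier node).
#' @export
simulate_expression <- function(sem, n, seed = 1L) {
  stopifnot(inherits(sem, "ground_truth_sem"), n >= 1)
  nodes <- sem$nodes$node
  x <- with_seed(seed, {
    m <- matrix(0, n, length(nodes), dimnames = list(sprintf("s%02d", seq_len(n)),
                                                     nodes))
    for (v in dag_topo_sort(sem$dag)) {
      i <- match(v, nodes)
      ed <- sem$edges[sem$edges$to == v, , drop = FALSE]
      mu <- sem$nodes$intercept[i]
      if (nrow(ed)) mu <- mu + as.vector(m[, ed$from, drop = FALSE] %*% ed$coef)
      m[, v] <- mu + stats::rnorm(n, 0, sem$nodes$noise_sd[i])
    }
    m
  })
  shift <- pmax(0, -apply(x, 2L, min))
  x <- sweep(x, 2L, shift, "+")
  meta <- data.frame(
    variable = nodes,
    role = ifelse(sem$nodes$tier == "output", "output", "gene"),
    tier = sem$nodes$tier,
    mechanism = sem$nodes$mechanism,
    stringsAsFactors = FALSE
  )
  feature_table(x, meta)
}

#' Write / read a ground-truth SEM as a TSV pair
#'
#' Edge list (parent, child, coefficient) plus node table (node, intercept,
#' noise_sd, tier, mechanism); numbers use 17 significant digits so the
#' round trip is exact.
#'
#' @param sem a `ground_truth_sem`.
#' @param edge_path,node_path output paths.
#' @return `edge_path`, invisibly.
#' @export
write_sem <- function(sem, edge_path, node_path) {
  write_tsv_exact(data.frame(parent = sem$edges$from, child = sem$edges$to,
                             coefficient = sem$edges$coef,
                             stringsAsFactors = FALSE), edge_path)
  write_tsv_exact(sem$nodes[, c("node", "intercept", "noise_sd", "tier",
                                "mechanism")], node_path)
  invisible(edge_path)
}

#' @rdname write_sem
#' @export
read_sem <- function(edge_path, node_path) {
  ed <- read_tsv_exact(edge_path)
  nd <- read_tsv_exact(node_path)
  ground_truth_sem(nd, data.frame(from = as.character(ed$parent),
                                  to = as.character(ed$child),
                                  coef = as.numeric(ed$coefficient),
                                  stringsAsFactors = FALSE))
}
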