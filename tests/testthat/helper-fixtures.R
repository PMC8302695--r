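# Fixtures and independent oracles shared across the test files. Oracles are
# deliberately naive (enumeration, closed forms, stats::lm) so they stay
# independent of the implementation paths they check.

make_ft <- function(values, tiers = NULL, roles = NULL, mechanisms = NULL) {
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("s%03d", seq_len(nrow(values)))
  }
  vars <- colnames(values)
  feature_table(values, data.frame(
    variable = vars,
    role = roles %||% rep("gene", length(vars)),
    tier = tiers %||% rep("fermenter", length(vars)),
    mechanism = mechanisms %||% rep("other", length(vars)),
    stringsAsFactors = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

rand_mat <- function(n, p, seed, prefix = "v") {
  set.seed(seed)
  matrix(rnorm(n * p), n, p,
         dimnames = list(sprintf("s%03d", seq_len(n)),
                         sprintf("%s%02d", prefix, seq_len(p))))
}

# Oracle: maximized Gaussian log-likelihood of node given parents via lm()
# (stats::logLik.lm is the ML log-likelihood), minus the BIC penalty.
oracle_family_score <- function(y, X) {
  n <- length(y)
  df <- data.frame(y = y, X)
  fit <- if (ncol(X) == 0) lm(y ~ 1, df) else lm(y ~ ., df)
  as.numeric(logLik(fit)) - ((ncol(X) + 2) / 2) * log(n)
}

oracle_bic <- function(g, x) {
  sum(vapply(g$nodes, function(node) {
    oracle_family_score(x[, node], x[, dag_parents(g, node), drop = FALSE])
  }, numeric(1)))
}

# Oracle: total path weight by explicit recursive path enumeration.
oracle_path_weight <- function(sem, from, to) {
  paths_from <- function(v) {
    if (v == to) return(1)
    out <- sem$edges[sem$edges$from == v, , drop = FALSE]
    if (nrow(out) == 0L) return(0)
    sum(vapply(seq_len(nrow(out)), function(k) {
      out$coef[k] * paths_from(out$to[k])
    }, numeric(1)))
  }
  sum(vapply(from, paths_from, numeric(1)))
}

# Three-node linear-Gaussian generator with well-separated signal, used for
# the search-vs-oracle comparisons. Topology drawn among distinct shapes.
sim_three_node <- function(seed, n = 200) {
  set.seed(seed)
  shape <- sample(c("chain", "fork", "collider", "indep"), 1L)
  coef <- function() sample(c(-1, 1), 1L) * runif(1, 0.8, 1.2)
  sd_e <- runif(1, 0.1, 0.3)
  a <- rnorm(n)
  if (shape == "chain") {
    b <- coef() * a + rnorm(n, 0, sd_e)
    c <- coef() * b + rnorm(n, 0, sd_e)
    edges <- data.frame(from = c("A", "B"), to = c("B", "C"))
  } else if (shape == "fork") {
    b <- coef() * a + rnorm(n, 0, sd_e)
    c <- coef() * a + rnorm(n, 0, sd_e)
    edges <- data.frame(from = c("A", "A"), to = c("B", "C"))
  } else if (shape == "collider") {
    b <- rnorm(n)
    c <- coef() * a + coef() * b + rnorm(n, 0, sd_e)
    edges <- data.frame(from = c("A", "B"), to = c("C", "C"))
  } else {
    b <- rnorm(n)
    c <- rnorm(n)
    edges <- empty_edges_df()
  }
  list(x = cbind(A = a, B = b, C = c), shape = shape, edges = edges)
}

empty_edges_df <- function() {
  data.frame(from = character(0), to = character(0), stringsAsFactors = FALSE)
}

# Small normalized expression fixture from the template SEM.
template_fixture <- function(n = 60, seed = 5, iht = 0.8, diet = 0.2,
                             noise = 0.2) {
  cfg <- scenario_config(n_samples = max(n, 3), iht_effect = iht,
                         diet_effect = diet, noise_sd = noise, seed = seed)
  sem <- build_template_sem(cfg)
  expr <- simulate_expression(sem, n, seed = seed)
  nrm <- suppressWarnings(minmax_normalize(expr))$table
  list(sem = sem, raw = expr, norm = nrm,
       constraints = build_blacklist(nrm))
}
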