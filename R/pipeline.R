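#' Pipeline configuration
#'
#' Validates and fills in the configuration driving the end-to-end runs.
#' Configurations can be written in YAML ([read_pipeline_config()]); every
#' run writes a `provenance.json` (config + seed + package version)
#' sufficient to reproduce its outputs bit-exactly.
#'
#' @param ... named settings overriding the defaults: `seed`,
#'   `scenario` (a list of [scenario_config()] arguments), `min_abundance`,
#'   `min_occurrence`, `scope`, `allow_within_tier`, `max_iter`, `restarts`,
#'   `prediction` (`"parents"` or `"joint"`), `knockout_mode` (`"retrain"`
#'   or `"evidence_only"`), `extra_scenarios` (list of `name` +
#'   `silenced`).
#' @return validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  dots <- list(...)
  # modifyList mangles unnamed nested lists, so scenario lists are set aside
  extra <- dots$extra_scenarios %||% list()
  dots$extra_scenarios <- NULL
  cfg <- utils::modifyList(list(
    seed = 1L,
    scenario = list(),
    min_abundance = 0.005,
    min_occurrence = 0.5,
    scope = "both",
    allow_within_tier = TRUE,
    max_iter = 500L,
    restarts = 0L,
    prediction = "parents",
    community_prediction = "joint",
    knockout_mode = "retrain"
  ), dots)
  cfg$extra_scenarios <- extra
  stopifnot(length(cfg$seed) == 1L, cfg$seed == as.integer(cfg$seed))
  cfg$seed <- as.integer(cfg$seed)
  if (cfg$min_abundance <= 0 || cfg$min_abundance >= 1) {
    stop("min_abundance must be in (0, 1)")
  }
  if (cfg$min_occurrence <= 0 || cfg$min_occurrence >= 1) {
    stop("min_occurrence must be in (0, 1)")
  }
  cfg$scope <- match.arg(cfg$scope, c("both", "per_table"))
  cfg$prediction <- match.arg(cfg$prediction, c("parents", "joint"))
  cfg$community_prediction <- match.arg(cfg$community_prediction,
                                        c("joint", "parents"))
  cfg$knockout_mode <- match.arg(cfg$knockout_mode,
                                 c("retrain", "evidence_only"))
  scenario_args <- cfg$scenario
  scenario_args$seed <- scenario_args$seed %||% cfg$seed
  cfg$scenario <- do.call(scenario_config, scenario_args)
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file; keys as in [pipeline_config()].
#' @return a validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

write_provenance <- function(out_dir, cfg, stage, extra = list()) {
  payload <- c(list(
    stage = stage,
    package = "methanet",
    version = as.character(utils::packageVersion("methanet")),
    seed = cfg$seed,
    config = unclass_deep(cfg)
  ), extra)
  jsonlite::write_json(payload, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

unclass_deep <- function(x) {
  x <- unclass(x)
  if (is.list(x)) lapply(x, unclass_deep) else x
}

#' Generate and write all synthetic inputs
#'
#' Writes the DNA, RNA and environment community tables, the synthetic
#' expression table, their metadata sidecars, the ground-truth SEM (edge and
#' node TSVs) and a provenance file to `out_dir`. Outputs are a
#' deterministic function of the configuration: the same config and seed
#' give byte-identical files.
#'
#' @param config a `pipeline_config`.
#' @param out_dir output directory (created if needed).
#' @return invisible list of the generated objects.
#' @export
run_simulation <- function(config = pipeline_config(), out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  comm <- simulate_community(config$scenario)
  sem <- build_template_sem(config$scenario)
  expr <- simulate_expression(sem, config$scenario$n_samples,
                              seed = derive_seed(config$seed, "expression"))
  write_feature_table(comm$dna, file.path(out_dir, "dna.tsv"))
  write_feature_table(comm$rna, file.path(out_dir, "rna.tsv"))
  write_feature_table(comm$environment, file.path(out_dir, "environment.tsv"))
  write_feature_table(expr, file.path(out_dir, "expression.tsv"))
  write_sem(sem, file.path(out_dir, "sem_edges.tsv"),
            file.path(out_dir, "sem_nodes.tsv"))
  write_provenance(out_dir, config, "simulate")
  invisible(list(dna = comm$dna, rna = comm$rna,
                 environment = comm$environment, expression = expr,
                 sem = sem, core = comm$core))
}

#' Community network analysis (16S-based)
#'
#' The full community pipeline: select the core population (DNA + RNA
#' rule), assemble the RNA activities of the core taxa with the
#' environmental parameters into a single matrix, min-max normalize it,
#' build the tier blacklist, learn the network, and validate it by
#' leave-one-out cross-validation: community reconstruction (taxa predicted
#' from the environmental evidence, joint-Gaussian prediction) scored by
#' Bray-Curtis similarity against the average-abundance null model, plus
#' prediction of the output variable (methane production) from the taxa.
#' Writes the fitted network (TSV pair, GraphML, DOT), the metrics report
#' (TSV + JSON) and provenance.
#'
#' @param config a `pipeline_config`.
#' @param tables list with `dna`, `rna`, `environment` feature tables, e.g.
#'   from [run_simulation()]; if NULL they are read from `in_dir`.
#' @param out_dir output directory.
#' @param in_dir directory holding `dna.tsv`, `rna.tsv`, `environment.tsv`
#'   (used when `tables` is NULL).
#' @return invisible list: `network`, `report`, `core`, `performance`.
#' @export
run_community_network <- function(config = pipeline_config(), out_dir,
                                  tables = NULL, in_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(tables)) {
    stopifnot(!is.null(in_dir))
    tables <- list(dna = read_feature_table(file.path(in_dir, "dna.tsv")),
                   rna = read_feature_table(file.path(in_dir, "rna.tsv")),
                   environment = read_feature_table(
                     file.path(in_dir, "environment.tsv")))
  }
  core <- if (config$scope == "both") {
    select_core_taxa(tables$dna, tables$rna, config$min_abundance,
                     config$min_occurrence, scope = "both")
  } else {
    select_core_taxa(tables$rna, min_abundance = config$min_abundance,
                     min_occurrence = config$min_occurrence,
                     scope = "per_table")
  }
  if (!length(core)) {
    stop("core population is empty; relax min_abundance/min_occurrence")
  }
  model <- assemble_model_matrix(list(ft_subset(tables$rna, variables = core),
                                      tables$environment))
  norm <- suppressWarnings(minmax_normalize(model))
  pruned <- drop_zero_variance(norm$table)
  constraints <- build_blacklist(pruned$table,
                                 allow_within_tier = config$allow_within_tier)
  hc <- hill_climb(pruned$table, constraints, max_iter = config$max_iter,
                   restarts = config$restarts, seed = config$seed)
  bn <- fit_mle(hc$dag, pruned$table)

  taxa <- intersect(core, ft_variables(pruned$table))
  cv <- loo_cv(pruned$table, constraints, targets = taxa,
               method = config$community_prediction,
               max_iter = config$max_iter)
  null <- null_model_predict(pruned$table, taxa)
  report <- community_reconstruction_report(cv, null)

  outputs <- ft_variables(pruned$table)[pruned$table$metadata$role == "output"]
  performance <- NULL
  if (length(outputs)) {
    pcv <- loo_cv(pruned$table, constraints, targets = outputs,
                  method = config$prediction, max_iter = config$max_iter)
    performance <- do.call(rbind, lapply(outputs, function(v) {
      data.frame(variable = v,
                 r_squared = r_squared(pcv$observed[, v], pcv$predicted[, v]),
                 relative_rmse = relative_rmse(pcv$observed[, v],
                                               pcv$predicted[, v]),
                 method = config$prediction, stringsAsFactors = FALSE)
    }))
    write_tsv_exact(performance, file.path(out_dir, "performance.tsv"))
  }

  write_bn(bn, file.path(out_dir, "network_edges.tsv"),
           file.path(out_dir, "network_nodes.tsv"),
           metadata = pruned$table)
  export_network(bn, file.path(out_dir, "network.graphml"), "graphml",
                 metadata = pruned$table)
  export_network(bn, file.path(out_dir, "network.dot"), "dot",
                 metadata = pruned$table)
  write_validation_report(report, file.path(out_dir, "metrics.tsv"),
                          file.path(out_dir, "metrics.json"))
  write_provenance(out_dir, config, "community-network",
                   extra = list(core_taxa = core,
                                dropped_constant = pruned$dropped,
                                score = "gaussian-bic",
                                community_prediction = config$community_prediction,
                                performance_prediction = config$prediction))
  invisible(list(network = bn, report = report, core = core,
                 performance = performance))
}

#' Gene network analysis with in-silico knockout
#'
#' Normalizes the expression table, builds the fermenter/Geobacter ->
#' methanogen -> CH4 blacklist, and runs the knockout experiment over
#' `complete`, `delta_IHT` (all IHT-labelled genes silenced) and
#' `delta_DIET` (all DIET-labelled genes silenced), plus any extra
#' scenarios from the configuration. Writes the per-scenario networks, the
#' knockout results (TSV + JSON) and provenance recording the score
#' convention, prediction method and knockout mode.
#'
#' @param config a `pipeline_config`.
#' @param expression feature table of expression values plus the output
#'   column; if NULL, read from `in_dir/expression.tsv`.
#' @param out_dir output directory.
#' @param in_dir input directory (used when `expression` is NULL).
#' @param output_var output variable name (default: the single output-role
#'   column of the table).
#' @return invisible `knockout_result` data.frame.
#' @export
run_gene_network <- function(config = pipeline_config(), out_dir,
                             expression = NULL, in_dir = NULL,
                             output_var = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(expression)) {
    stopifnot(!is.null(in_dir))
    expression <- read_feature_table(file.path(in_dir, "expression.tsv"))
  }
  if (is.null(output_var)) {
    outs <- ft_variables(expression)[expression$metadata$role == "output"]
    if (length(outs) != 1L) stop("specify output_var (table has ",
                                 length(outs), " output columns)")
    output_var <- outs
  }
  norm <- suppressWarnings(minmax_normalize(expression))
  pruned <- drop_zero_variance(norm$table)
  constraints <- build_blacklist(pruned$table,
                                 allow_within_tier = config$allow_within_tier)
  scenarios <- default_knockout_scenarios(pruned$table)
  for (sc in config$extra_scenarios) {
    scenarios <- c(scenarios, list(knockout_scenario(sc$name, sc$silenced)))
  }
  results <- run_knockout_experiment(pruned$table, constraints, scenarios,
                                     output_var = output_var,
                                     mode = config$knockout_mode,
                                     method = config$prediction,
                                     max_iter = config$max_iter)
  # full-data network per scenario for inspection
  for (sc in scenarios) {
    tab <- drop_zero_variance(silence_genes(pruned$table, sc$silenced))$table
    cons <- subset_constraints(constraints, ft_variables(tab))
    hc <- hill_climb(tab, cons, max_iter = config$max_iter)
    bn <- fit_mle(hc$dag, tab)
    write_bn(bn, file.path(out_dir, sprintf("network_%s_edges.tsv", sc$name)),
             file.path(out_dir, sprintf("network_%s_nodes.tsv", sc$name)),
             metadata = tab)
    export_network(bn, file.path(out_dir, sprintf("network_%s.graphml",
                                                  sc$name)),
                   "graphml", metadata = tab)
  }
  write_tsv_exact(as.data.frame(results),
                  file.path(out_dir, "knockout_results.tsv"))
  jsonlite::write_json(as.data.frame(results),
                       file.path(out_dir, "knockout_results.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_provenance(out_dir, config, "gene-network",
                   extra = list(score = "gaussian-bic",
                                prediction_method = config$prediction,
                                knockout_mode = config$knockout_mode,
                                output_var = output_var,
                                dropped_constant = pruned$dropped))
  invisible(results)
}
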