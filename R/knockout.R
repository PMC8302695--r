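#' Silence genes in a feature table
#'
#' In-silico knockout: the listed columns are set to 0 in every sample (the
#' expression level of a silenced gene is zero); all other cells are
#' unchanged. Idempotent.
#'
#' @param table a `feature_table`.
#' @param genes character vector of variables to silence (may be empty).
#' @return a `feature_table`.
#' @export
silence_genes <- function(table, genes) {
  validate_feature_table(table)
  unknown <- setdiff(genes, ft_variables(table))
  if (length(unknown)) {
    stop(sprintf("unknown gene name(s): %s", paste(unknown, collapse = ", ")))
  }
  v <- table$values
  v[, genes] <- 0
  feature_table(v, table$metadata)
}

#' Select gene variables by mechanism label
#'
#' Returns all gene-role variables carrying the requested mechanism label
#' (IHT or DIET). Gene variables without a usable mechanism label raise an
#' error, since silent mislabeling would corrupt the knockout contrast.
#'
#' @param metadata a `feature_table` or its metadata data.frame.
#' @param mechanism `"IHT"` or `"DIET"`.
#' @return character vector of gene names (possibly empty).
#' @export
select_mechanism_genes <- function(metadata, mechanism = c("IHT", "DIET")) {
  mechanism <- match.arg(mechanism)
  if (inherits(metadata, "feature_table")) metadata <- metadata$metadata
  genes <- metadata[metadata$role == "gene", , drop = FALSE]
  bad <- is.na(genes$mechanism) | !(genes$mechanism %in% ft_mechanisms)
  if (any(bad)) {
    stop(sprintf("gene variable(s) without mechanism label: %s",
                 paste(genes$variable[bad], collapse = ", ")))
  }
  genes$variable[genes$mechanism == mechanism]
}

#' Define a knockout scenario
#'
#' @param name scenario name (the reference scenario must be named
#'   `"complete"` and have an empty silenced set).
#' @param silenced character vector of variables to silence.
#' @return object of class `knockout_scenario`.
#' @export
knockout_scenario <- function(name, silenced = character(0)) {
  structure(list(name = as.character(name),
                 silenced = as.character(silenced)),
            class = "knockout_scenario")
}

#' Default scenario set: complete, delta_IHT, delta_DIET
#'
#' @param metadata a `feature_table` or metadata data.frame with mechanism
#'   labels.
#' @return list of three `knockout_scenario`s.
#' @export
default_knockout_scenarios <- function(metadata) {
  list(knockout_scenario("complete"),
       knockout_scenario("delta_IHT", select_mechanism_genes(metadata, "IHT")),
       knockout_scenario("delta_DIET", select_mechanism_genes(metadata, "DIET")))
}

#' Run the in-silico knockout experiment
#'
#' Quantifies how much each gene set contributes to predicting the output
#' variable. In the default `"retrain"` mode each scenario silences its
#' genes in the data, drops the resulting zero-variance columns, reruns the
#' whole leave-one-out pipeline (structure learning + ML fit + prediction)
#' and scores predicted against observed output. In `"evidence_only"` mode
#' the complete scenario's per-fold models are reused and only the evidence
#' of silenced variables is zeroed at prediction time. Results carry the
#' drop in squared correlation relative to the complete scenario.
#'
#' @param data normalized `feature_table` including the output variable.
#' @param constraints optional `edge_constraints` (typically
#'   [build_blacklist()] on the table's tiers).
#' @param scenarios list of `knockout_scenario`s; must contain `"complete"`
#'   with an empty silenced set. Defaults to
#'   [default_knockout_scenarios()].
#' @param output_var name of the output variable (never silenced).
#' @param mode `"retrain"` (default) or `"evidence_only"`.
#' @param method prediction method passed to [loo_cv()].
#' @param max_iter hill-climb step budget per fold.
#' @return data.frame of class `knockout_result` with columns `scenario`,
#'   `mode`, `method`, `r_squared`, `relative_rmse`, `delta_r_squared`
#'   (scenario minus complete; 0 for complete by construction), ordered as
#'   given.
#' @export
run_knockout_experiment <- function(data, constraints = NULL,
                                    scenarios = NULL, output_var,
                                    mode = c("retrain", "evidence_only"),
                                    method = "parents", max_iter = 500L) {
  mode <- match.arg(mode)
  validate_feature_table(data)
  if (!(output_var %in% ft_variables(data))) stop("output_var not in table")
  scenarios <- scenarios %||% default_knockout_scenarios(data)
  names(scenarios) <- vapply(scenarios, `[[`, character(1), "name")
  if (!("complete" %in% names(scenarios)) ||
      length(scenarios[["complete"]]$silenced)) {
    stop("scenarios must include 'complete' with an empty silenced set")
  }
  for (sc in scenarios) {
    if (output_var %in% sc$silenced) {
      stop(sprintf("scenario '%s' silences the output variable", sc$name))
    }
    unknown <- setdiff(sc$silenced, ft_variables(data))
    if (length(unknown)) {
      stop(sprintf("scenario '%s' silences unknown variable(s): %s",
                   sc$name, paste(unknown, collapse = ", ")))
    }
  }
  constraints <- constraints %||% edge_constraints()

  score_cv <- function(cv) {
    obs <- cv$observed[, output_var]
    pred <- cv$predicted[, output_var]
    data.frame(r_squared = r_squared(obs, pred),
               relative_rmse = relative_rmse(obs, pred))
  }

  rows <- vector("list", length(scenarios))
  complete_cv <- NULL
  # process "complete" first so evidence_only scenarios can reuse its models;
  # output rows keep the caller's order
  proc <- order(names(scenarios) != "complete")
  for (k in proc) {
    sc <- scenarios[[k]]
    if (mode == "retrain" || sc$name == "complete") {
      silenced <- silence_genes(data, sc$silenced)
      pruned <- drop_zero_variance(silenced)
      if (!(output_var %in% ft_variables(pruned$table))) {
        stop("output variable became constant after silencing")
      }
      if (ncol(pruned$table$values) < 2L) {
        stop(sprintf("scenario '%s' silences all predictors", sc$name))
      }
      cons <- subset_constraints(constraints, ft_variables(pruned$table))
      cv <- loo_cv(pruned$table, cons, targets = output_var, method = method,
                   max_iter = max_iter,
                   keep_models = (sc$name == "complete" &&
                                    mode == "evidence_only"))
      if (sc$name == "complete") complete_cv <- cv
    } else {
      # evidence_only: reuse the complete fold models, zero the evidence
      stopifnot(!is.null(complete_cv))
      x <- data$values
      predicted <- complete_cv$predicted
      for (i in seq_len(nrow(x))) {
        predicted[i, ] <- predict_fold(complete_cv$models[[i]], x[i, ],
                                       output_var, method,
                                       zero_evidence = sc$silenced)
      }
      cv <- new_cv_result(observed = complete_cv$observed,
                          predicted = predicted, targets = output_var,
                          method = method, dropped = complete_cv$dropped,
                          provenance = complete_cv$provenance)
    }
    rows[[k]] <- cbind(data.frame(scenario = sc$name, mode = mode,
                                  method = method, stringsAsFactors = FALSE),
                       score_cv(cv))
  }
  out <- do.call(rbind, rows)
  out$delta_r_squared <- out$r_squared - out$r_squared[out$scenario == "complete"]
  rownames(out) <- NULL
  class(out) <- c("knockout_result", "data.frame")
  out
}
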