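#' Min-max normalization to \[0, 1\]
#'
#' Rescales each variable j to (v_ij - min(v_j)) / (max(v_j) - min(v_j)),
#' the transformation applied to the combined model matrix before network
#' learning. Constant columns (max = min) are mapped to 0 for every sample
#' — the same convention as a knocked-out gene — and reported via a warning;
#' [drop_zero_variance()] removes them if they should not enter the model.
#'
#' @param table a `feature_table`.
#' @return list with `table` (normalized `feature_table`) and `params`
#'   (class `normalization_params`: per-variable `min` and `max`, needed to
#'   back-transform predictions with [inverse_normalize()]).
#' @export
minmax_normalize <- function(table) {
  validate_feature_table(table)
  v <- table$values
  mins <- apply(v, 2L, min)
  maxs <- apply(v, 2L, max)
  rng <- maxs - mins
  const <- rng == 0
  if (any(const)) {
    warning(sprintf("constant column(s) normalized to 0: %s",
                    paste(colnames(v)[const], collapse = ", ")))
  }
  scaled <- sweep(v, 2L, mins, "-")
  scaled <- sweep(scaled, 2L, ifelse(const, 1, rng), "/")
  scaled[, const] <- 0
  params <- structure(list(min = mins, max = maxs),
                      class = "normalization_params")
  list(table = feature_table(scaled, table$metadata), params = params)
}

#' Invert a min-max normalization
#'
#' @param table normalized `feature_table` (or plain matrix with matching
#'   column names).
#' @param params the `normalization_params` returned by [minmax_normalize()].
#' @return object of the same kind on the original scale. Constant columns
#'   are restored to their constant value.
#' @export
inverse_normalize <- function(table, params) {
  v <- if (inherits(table, "feature_table")) table$values else as.matrix(table)
  idx <- match(colnames(v), names(params$min))
  if (anyNA(idx)) stop("normalization params lack some variables")
  rng <- (params$max - params$min)[idx]
  out <- sweep(sweep(v, 2L, rng, "*"), 2L, params$min[idx], "+")
  if (inherits(table, "feature_table")) feature_table(out, table$metadata) else out
}

#' Select the core population of taxa
#'
#' Retains taxa with mean relative abundance strictly above `min_abundance`
#' and presence (abundance > 0) in strictly more than `min_occurrence` of
#' the samples. With `scope = "both"` the rule is evaluated over the pooled
#' DNA + RNA samples (the criterion used to pick a joint core population);
#' with `scope = "per_table"` it is evaluated within the single table given
#' (the per-dataset variant).
#'
#' @param dna `feature_table` of taxon relative abundances (16S rRNA gene).
#' @param rna `feature_table` of taxon activities (16S rRNA); required when
#'   `scope = "both"`, must be absent otherwise.
#' @param min_abundance mean relative-abundance threshold (default 0.005,
#'   i.e. 0.5\%), strict inequality.
#' @param min_occurrence occurrence threshold as a fraction of samples
#'   (default 0.5), strict inequality; a sample counts as occupied when the
#'   abundance is > 0 exactly.
#' @param scope `"both"` or `"per_table"`.
#' @return character vector of retained taxon names (possibly empty), in the
#'   column order of `dna`.
#' @export
select_core_taxa <- function(dna, rna = NULL, min_abundance = 0.005,
                             min_occurrence = 0.5,
                             scope = c("both", "per_table")) {
  scope <- match.arg(scope)
  validate_feature_table(dna)
  if (scope == "both") {
    if (is.null(rna)) stop("scope = 'both' requires both a DNA and an RNA table")
    validate_feature_table(rna)
    if (!setequal(ft_variables(dna), ft_variables(rna))) {
      stop("DNA and RNA tables must share the same taxon namespace")
    }
    pooled <- rbind(dna$values, rna$values[, ft_variables(dna), drop = FALSE])
  } else {
    if (!is.null(rna)) stop("scope = 'per_table' takes a single table")
    pooled <- dna$values
  }
  mean_ab <- colMeans(pooled)
  occ <- colMeans(pooled > 0)
  ft_variables(dna)[mean_ab > min_abundance & occ > min_occurrence]
}

#' Reads per kilobase of transcript per million mapped reads
#'
#' RPKM = count / ((length_bp / 1000) * (library_size / 1e6)).
#'
#' @param counts numeric matrix of read counts, samples in rows, genes in
#'   columns (a `feature_table` is also accepted).
#' @param gene_lengths_bp positive lengths, one per gene (named or in column
#'   order).
#' @param library_sizes positive per-sample totals of mapped reads (named or
#'   in row order).
#' @param metadata optional per-gene metadata; defaults to role "gene",
#'   tier "fermenter" placeholder is NOT assumed — callers must supply real
#'   tiers when the result feeds network learning.
#' @return a `feature_table` of RPKM values with `length_bp` recorded.
#' @export
compute_rpkm <- function(counts, gene_lengths_bp, library_sizes,
                         metadata = NULL) {
  meta_in <- if (inherits(counts, "feature_table")) counts$metadata
  v <- if (inherits(counts, "feature_table")) counts$values else as.matrix(counts)
  if (!is.null(names(gene_lengths_bp))) {
    gene_lengths_bp <- gene_lengths_bp[colnames(v)]
  }
  if (!is.null(names(library_sizes))) {
    library_sizes <- library_sizes[rownames(v)]
  }
  stopifnot(length(gene_lengths_bp) == ncol(v),
            length(library_sizes) == nrow(v))
  if (any(!is.finite(gene_lengths_bp)) || any(gene_lengths_bp <= 0)) {
    stop("gene lengths must be positive")
  }
  if (any(!is.finite(library_sizes)) || any(library_sizes <= 0)) {
    stop("library sizes must be positive")
  }
  rpkm <- sweep(v, 2L, gene_lengths_bp / 1000, "/")
  rpkm <- sweep(rpkm, 1L, library_sizes / 1e6, "/")
  meta <- metadata %||% meta_in %||%
    data.frame(variable = colnames(v), role = "gene", tier = "fermenter",
               mechanism = "other", stringsAsFactors = FALSE)
  meta$length_bp <- as.double(gene_lengths_bp)
  feature_table(rpkm, meta)
}

#' Combine feature tables into one model matrix
#'
#' Column-wise concatenation of tables sharing the same samples, optionally
#' restricted to a variable selection; this is the "single matrix" that is
#' subsequently min-max normalized and fed to structure learning. Sample
#' order is canonicalized to that of the first table.
#'
#' @param tables list of `feature_table`s over identical sample sets.
#' @param variables optional character vector restricting the output columns
#'   (order preserved from the tables).
#' @return a `feature_table` with merged metadata.
#' @export
assemble_model_matrix <- function(tables, variables = NULL) {
  stopifnot(length(tables) >= 1L)
  lapply(tables, validate_feature_table)
  ids <- ft_samples(tables[[1L]])
  for (t in tables[-1L]) {
    if (!setequal(ids, ft_samples(t))) {
      off <- union(setdiff(ids, ft_samples(t)), setdiff(ft_samples(t), ids))
      stop(sprintf("tables do not share sample IDs; offending: %s",
                   paste(off, collapse = ", ")))
    }
  }
  all_vars <- unlist(lapply(tables, ft_variables))
  if (anyDuplicated(all_vars)) {
    stop(sprintf("variable name(s) appear in more than one table: %s",
                 paste(unique(all_vars[duplicated(all_vars)]), collapse = ", ")))
  }
  vals <- do.call(cbind, lapply(tables, function(t) t$values[ids, , drop = FALSE]))
  meta <- do.call(rbind, lapply(tables, function(t) t$metadata))
  ft <- feature_table(vals, meta)
  if (!is.null(variables)) {
    missing <- setdiff(variables, all_vars)
    if (length(missing)) {
      stop(sprintf("selected variable(s) not found: %s",
                   paste(missing, collapse = ", ")))
    }
    ft <- ft_subset(ft, variables = intersect(all_vars, variables))
  }
  ft
}

#' Drop zero-variance columns
#'
#' Removes variables that are constant across samples (e.g. genes silenced
#' by [silence_genes()]), which carry no likelihood information and break
#' Gaussian scoring.
#'
#' @param table a `feature_table`.
#' @return list with `table` (pruned) and `dropped` (character vector of
#'   removed variable names, possibly empty).
#' @export
drop_zero_variance <- function(table) {
  validate_feature_table(table)
  v <- table$values
  sds <- apply(v, 2L, stats::sd)
  const <- sds == 0 | nrow(v) < 2L
  if (all(const)) {
    return(list(table = ft_subset(table, variables = integer(0)),
                dropped = colnames(v)))
  }
  list(table = ft_subset(table, variables = colnames(v)[!const]),
       dropped = colnames(v)[const])
}
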