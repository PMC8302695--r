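#' Feature tables: the pipeline's universal data currency
#'
#' A feature table is a numeric samples-by-variables matrix plus per-variable
#' metadata. Every column carries a role (what was measured), a tier (its
#' position in the fermenter/Geobacter -> methanogen -> CH4 cascade used to
#' constrain network directionality) and a mechanism label (IHT, DIET or
#' other) used by the in-silico knockout. Gene columns may additionally carry
#' a transcript length in bp.
#'
#' @param values numeric matrix, samples in rows, variables in columns; both
#'   dimensions must be named, names unique, all values finite.
#' @param metadata data.frame with columns `variable`, `role`, `tier`,
#'   `mechanism` and optionally `length_bp`; one row per column of `values`.
#' @return an object of class `feature_table`.
#' @examples
#' vals <- matrix(runif(6), 2, 3,
#'                dimnames = list(c("s1", "s2"), c("a", "b", "ch4")))
#' meta <- data.frame(variable  = c("a", "b", "ch4"),
#'                    role      = c("gene", "gene", "output"),
#'                    tier      = c("fermenter", "methanogen", "output"),
#'                    mechanism = c("IHT", "other", "other"))
#' ft <- feature_table(vals, meta)
#' @export
feature_table <- function(values, metadata) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  metadata <- as.data.frame(metadata, stringsAsFactors = FALSE)
  if (is.null(metadata$length_bp)) metadata$length_bp <- NA_real_
  metadata$length_bp <- as.double(metadata$length_bp)
  metadata <- metadata[, c("variable", "role", "tier", "mechanism", "length_bp")]
  rownames(metadata) <- NULL
  ft <- structure(list(values = values, metadata = metadata),
                  class = "feature_table")
  validate_feature_table(ft)
  ft
}

ft_roles <- c("taxon_dna", "taxon_rna", "gene", "environment", "output")
ft_tiers <- c("fermenter", "geobacter", "methanogen", "environment", "output")
ft_mechanisms <- c("IHT", "DIET", "other")

#' Validate a feature table's invariants
#'
#' Checks unique sample/variable names, matrix-metadata agreement, finite
#' values, and that every variable has a known role, tier and mechanism.
#'
#' @param ft a `feature_table`.
#' @return `ft`, invisibly; errors name the offending variable.
#' @export
validate_feature_table <- function(ft) {
  stopifnot(inherits(ft, "feature_table"))
  v <- ft$values
  m <- ft$metadata
  if ((nrow(v) > 0L && is.null(rownames(v))) ||
      (ncol(v) > 0L && is.null(colnames(v)))) {
    stop("feature table values must have sample and variable names")
  }
  if (anyDuplicated(rownames(v))) stop("duplicate sample names")
  if (anyDuplicated(colnames(v))) stop("duplicate variable names")
  if (!all(is.finite(v))) stop("feature table values must be finite")
  if (!identical(as.character(m$variable),
                 as.character(colnames(v) %||% character(0)))) {
    stop("metadata rows must match value columns (same names, same order)")
  }
  allowed <- list(role = ft_roles, tier = ft_tiers, mechanism = ft_mechanisms)
  for (col in c("role", "tier", "mechanism")) {
    bad <- is.na(m[[col]]) | !(m[[col]] %in% allowed[[col]])
    if (any(bad)) {
      stop(sprintf("variable '%s' has missing or unknown %s '%s'",
                   m$variable[bad][1L], col, m[[col]][bad][1L]))
    }
  }
  invisible(ft)
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d samples x %d variables\n",
              nrow(x$values), ncol(x$values)))
  cat("roles:", paste(sprintf("%s=%d", names(table(x$metadata$role)),
                              table(x$metadata$role)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$values)

#' @export
as.matrix.feature_table <- function(x, ...) x$values

#' Subset a feature table by samples and/or variables
#'
#' @param ft a `feature_table`.
#' @param samples sample names or indices (default: all).
#' @param variables variable names or indices (default: all).
#' @return a `feature_table` with metadata subset accordingly.
#' @export
ft_subset <- function(ft, samples = NULL, variables = NULL) {
  v <- ft$values
  if (!is.null(samples)) v <- v[samples, , drop = FALSE]
  if (!is.null(variables)) v <- v[, variables, drop = FALSE]
  meta <- ft$metadata[match(colnames(v), ft$metadata$variable), , drop = FALSE]
  feature_table(v, meta)
}

#' Variable names of a feature table
#' @param ft a `feature_table`.
#' @return character vector.
#' @export
ft_variables <- function(ft) colnames(ft$values)

#' Sample names of a feature table
#' @param ft a `feature_table`.
#' @return character vector.
#' @export
ft_samples <- function(ft) rownames(ft$values)

#' Write a feature table as TSV plus a metadata sidecar
#'
#' The values file has a header row of variable names and the sample ID as
#' its first column (`sample_id`); the sidecar lists variable, role, tier,
#' mechanism and length_bp. Numbers are printed with 17 significant digits
#' so write -> read -> write is byte-identical.
#'
#' @param ft a `feature_table`.
#' @param path output TSV path for the values.
#' @param metadata_path sidecar path; defaults to `<path>.meta.tsv`.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(ft, path,
                                metadata_path = paste0(path, ".meta.tsv")) {
  validate_feature_table(ft)
  df <- data.frame(sample_id = rownames(ft$values), ft$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv_exact(df, path)
  write_tsv_exact(ft$metadata, metadata_path)
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#'
#' @param path TSV path of the values table.
#' @param metadata_path sidecar path; defaults to `<path>.meta.tsv`.
#' @return a validated `feature_table`; a tampered sidecar (e.g. a missing
#'   tier) raises an error naming the variable.
#' @export
read_feature_table <- function(path,
                               metadata_path = paste0(path, ".meta.tsv")) {
  df <- read_tsv_exact(path)
  if (colnames(df)[1L] != "sample_id") {
    stop("first column of a feature table file must be 'sample_id'")
  }
  vals <- as.matrix(df[, -1L, drop = FALSE])
  rownames(vals) <- df$sample_id
  meta <- read_tsv_exact(metadata_path)
  for (col in c("role", "tier", "mechanism")) {
    if (is.null(meta[[col]])) stop(sprintf("metadata sidecar lacks '%s'", col))
    meta[[col]] <- as.character(meta[[col]])
  }
  ord <- match(colnames(vals), meta$variable)
  if (anyNA(ord)) {
    stop(sprintf("metadata sidecar is missing variable '%s'",
                 colnames(vals)[is.na(ord)][1L]))
  }
  feature_table(vals, meta[ord, , drop = FALSE])
}
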