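# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a child seed from a global seed and a text tag
#'
#' One global integer seed drives a hierarchy of per-table seeds so that
#' regenerating one table never perturbs the random stream of another.
#' The derivation is a fixed polynomial hash of the tag mixed with the
#' parent seed, reduced modulo 2^31 - 1 (always a valid R integer seed).
#'
#' @param seed integer parent seed.
#' @param tag character tag naming the consumer (e.g. "dna", "expression").
#' @return a single integer in \[0, 2^31 - 2\].
#' @export
derive_seed <- function(seed, tag) {
  stopifnot(length(seed) == 1L, is.finite(seed), length(tag) == 1L)
  m <- 2147483647
  h <- as.double(seed %% m)
  for (code in utf8ToInt(as.character(tag))) {
    h <- (h * 131 + code) %% m
  }
  as.integer(h)
}

# Evaluate `code` under set.seed(seed), restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Format numbers so that write -> read -> write is byte-identical:
# %.17g round-trips every double exactly.
format_num <- function(x) sprintf("%.17g", x)

# Write a data.frame as deterministic TSV (no quoting, no row names).
write_tsv_exact <- function(df, path) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) df[[j]] <- format_num(df[[j]])
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

read_tsv_exact <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE, comment.char = "", quote = "")
}
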