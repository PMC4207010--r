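# Internal helpers shared across modules.

#' Evaluate an expression under a local RNG seed
#'
#' Saves and restores `.Random.seed` so seeded helpers do not disturb the
#' caller's RNG stream.
#' @noRd
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

# Derive a bounded child seed from a base seed and a stage label, so each
# pipeline stage draws from its own reproducible substream.
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483399) + 1L
}

stop_contract <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

check_gene_ids <- function(genes, what = "gene identifiers") {
  genes <- as.character(genes)
  if (anyNA(genes) || any(!nzchar(genes))) {
    stop_contract("%s must be non-empty strings", what)
  }
  if (any(grepl("[[:space:]]", genes))) {
    stop_contract("%s must not contain whitespace", what)
  }
  genes
}

# Write a data.frame as TSV with '#'-prefixed provenance header lines.
write_tsv_report <- function(df, path, header = character()) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (h in header) writeLines(paste0("# ", h), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
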