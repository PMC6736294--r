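# Internal helpers shared across modules.

#' @useDynLib wzscan, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats median rpois rbinom runif setNames filter pnorm complete.cases
#' @importFrom utils head tail
NULL

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
# Two calls with the same seed give identical draws; surrounding randomness
# is unaffected.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Reverse complement of DNA strings
#'
#' @param x Character vector of DNA sequences (A/C/G/T/N, either case).
#' @return Character vector of reverse-complemented sequences; names kept.
#' @examples
#' reverse_complement(c("ACGT", "AANT"))
#' @export
reverse_complement <- function(x) {
  stopifnot(is.character(x))
  revcomp_cpp(x)
}

# Random DNA string(s) of the given lengths.
random_dna <- function(lengths) {
  vapply(lengths, function(n) {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
  }, character(1))
}

# Validate a scaffold set: named uppercase character vector over {A,C,G,T,N}.
validate_scaffolds <- function(scaffolds, what = "scaffold set") {
  if (!is.character(scaffolds))
    stop(what, " must be a named character vector", call. = FALSE)
  ids <- names(scaffolds)
  if (is.null(ids) || any(is.na(ids)) || any(!nzchar(ids)))
    stop(what, ": every record needs a non-empty id", call. = FALSE)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop(what, ": duplicate scaffold id(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  empty <- ids[!nzchar(scaffolds)]
  if (length(empty))
    stop(what, ": empty sequence for record(s): ",
         paste(empty, collapse = ", "), call. = FALSE)
  bad <- grepl("[^ACGTN]", scaffolds)
  if (any(bad))
    stop(what, ": illegal character in record(s): ",
         paste(ids[bad], collapse = ", "), call. = FALSE)
  invisible(scaffolds)
}

scaffold_lengths <- function(scaffolds) {
  setNames(nchar(scaffolds), names(scaffolds))
}

# Binary-search lookup of sorted numeric key/value tables; 0 for absent keys.
lookup_sorted <- function(keys, table_keys, table_values) {
  if (!length(keys)) return(numeric(0))
  if (!length(table_keys)) return(numeric(length(keys)))
  idx <- findInterval(keys, table_keys)
  out <- numeric(length(keys))
  ok <- idx > 0L
  ok[ok] <- table_keys[idx[ok]] == keys[ok]
  out[ok] <- table_values[idx[ok]]
  out
}
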