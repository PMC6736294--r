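# YGS-style single-copy k-mer scan for W-linked scaffolds.
#
# All k-mers are stored canonically (the lexicographic minimum of a window
# and its reverse complement) as 2-bit integer codes, so reads need not be
# stranded. Windows containing N are skipped.

#' Count canonical k-mers
#'
#' @param x Character vector of sequences: a scaffold set or a read set.
#' @param k k-mer length (2--26); default 16.
#' @param source One of "assembly", "male_reads", "female_reads" (metadata
#'   used to guard downstream operations).
#' @return A `kmer_catalog`: list with `k`, `code` (sorted numeric 2-bit
#'   codes), `count`, `source`.
#' @examples
#' count_kmers(c(s1 = "ACGT"), k = 4)
#' @export
count_kmers <- function(x, k = 16L,
                        source = c("assembly", "male_reads", "female_reads")) {
  source <- match.arg(source)
  stopifnot(is.character(x), k >= 2, k <= 26)
  res <- kmer_count_cpp(x, as.integer(k))
  if (!length(res$code))
    warning("no k-mers counted: every sequence shorter than k or non-ACGT")
  structure(list(k = as.integer(k), code = res$code, count = res$count,
                 source = source),
            class = "kmer_catalog")
}

#' @export
print.kmer_catalog <- function(x, ...) {
  cat("kmer_catalog: k =", x$k, "| source =", x$source,
      "|", length(x$code), "distinct canonical k-mers\n")
  invisible(x)
}

#' k-mer multiplicity histogram
#'
#' @param catalog A `kmer_catalog`.
#' @return data.frame with `multiplicity` and `n_kmers` (number of distinct
#'   canonical k-mers seen that many times); rows sum to the catalogue size.
#' @export
kmer_histogram <- function(catalog) {
  stopifnot(inherits(catalog, "kmer_catalog"))
  if (!length(catalog$count)) stop("empty k-mer catalogue", call. = FALSE)
  tab <- table(catalog$count)
  data.frame(multiplicity = as.numeric(names(tab)),
             n_kmers = as.numeric(tab), row.names = NULL)
}

#' Single-copy k-mers of an assembly catalogue
#'
#' @param assembly_catalog A `kmer_catalog` with source "assembly".
#' @return Sorted numeric vector of canonical codes with assembly count 1.
#' @export
single_copy_kmers <- function(assembly_catalog) {
  stopifnot(inherits(assembly_catalog, "kmer_catalog"))
  if (assembly_catalog$source != "assembly")
    stop("single-copy k-mers are defined on the assembly catalogue, got '",
         assembly_catalog$source, "'", call. = FALSE)
  assembly_catalog$code[assembly_catalog$count == 1]
}

#' Decode canonical k-mer codes to strings
#'
#' @param codes Numeric vector of 2-bit codes.
#' @param k k-mer length.
#' @return Character vector of k-mers.
#' @export
decode_kmers <- function(codes, k) kmer_decode_cpp(codes, as.integer(k))

#' Encode k-mer strings to numeric codes
#'
#' @param kmers Character vector of equal-length DNA words.
#' @param canonical Encode the lexicographic minimum of the word and its
#'   reverse complement (default TRUE).
#' @return Numeric vector of 2-bit codes.
#' @export
encode_kmers <- function(kmers, canonical = TRUE)
  kmer_encode_cpp(kmers, canonical)

#' Write a k-mer catalogue as sorted text (kmer TAB count)
#'
#' @param catalog A `kmer_catalog`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_kmer_catalog <- function(catalog, path) {
  stopifnot(inherits(catalog, "kmer_catalog"))
  dt <- data.table::data.table(kmer = decode_kmers(catalog$code, catalog$k),
                               count = catalog$count)
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read a k-mer catalogue from text (kmer TAB count)
#'
#' @param path Input path.
#' @param source Catalogue source label.
#' @return A `kmer_catalog`.
#' @export
read_kmer_catalog <- function(path,
                              source = c("assembly", "male_reads",
                                         "female_reads")) {
  source <- match.arg(source)
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          col.names = c("kmer", "count"))
  k <- unique(nchar(dt$kmer))
  if (length(k) != 1)
    stop("k-mer catalogue '", path, "': unequal k-mer lengths", call. = FALSE)
  code <- encode_kmers(dt$kmer, canonical = TRUE)
  o <- order(code)
  structure(list(k = as.integer(k), code = code[o], count = dt$count[o],
                 source = source),
            class = "kmer_catalog")
}

#' YGS score for one scaffold
#'
#' Scored k-mers are the scaffold's distinct canonical k-mers that are
#' single-copy in the assembly (hence "present in the female genome"). A
#' scored k-mer is a hit when its pooled male read count is below
#' `min_read_count` and its pooled female read count is at least
#' `min_read_count`. The W call requires the hit percentage to exceed
#' `threshold_pct` strictly and at least `min_kmers` scored k-mers.
#'
#' @param scaffold Single sequence string.
#' @param scaffold_id Id used in the result row.
#' @param assembly_single_copy Sorted numeric codes from
#'   [single_copy_kmers()].
#' @param male_catalog,female_catalog Read `kmer_catalog`s sharing `k`.
#' @param k k-mer length (must match the catalogues).
#' @param min_read_count Read count at/above which a k-mer counts as present
#'   in a read pool (default 2; suppresses sequencing-error k-mers).
#' @param threshold_pct W-call threshold on the hit percentage (strict >,
#'   default 75).
#' @param min_kmers Minimum scored k-mers for a call (default 50).
#' @param denominator `"single_copy"` scores all assembly-single-copy
#'   k-mers of the scaffold; `"female_supported"` additionally restricts
#'   the denominator to female-read-supported k-mers.
#' @return One-row data.frame: scaffold_id, n_valid_single_copy,
#'   pct_unmatched_female_supported, w_call, flag.
#' @export
ygs_score <- function(scaffold, scaffold_id, assembly_single_copy,
                      male_catalog, female_catalog, k = 16L,
                      min_read_count = 2L, threshold_pct = 75,
                      min_kmers = 50L,
                      denominator = c("single_copy", "female_supported")) {
  denominator <- match.arg(denominator)
  stopifnot(threshold_pct > 0, threshold_pct <= 100)
  if (male_catalog$k != k || female_catalog$k != k)
    stop("catalogues do not share k = ", k, call. = FALSE)
  row <- function(n, pct, call, flag)
    data.frame(scaffold_id = scaffold_id, n_valid_single_copy = n,
               pct_unmatched_female_supported = pct, w_call = call,
               flag = flag, stringsAsFactors = FALSE)
  if (nchar(scaffold) < k)
    return(row(0L, NA_real_, FALSE, "shorter_than_k"))
  codes <- seq_kmer_codes_cpp(scaffold, as.integer(k))
  idx <- findInterval(codes, assembly_single_copy)
  in_sc <- idx > 0L
  in_sc[in_sc] <- assembly_single_copy[idx[in_sc]] == codes[in_sc]
  scored <- codes[in_sc]
  male_n <- lookup_sorted(scored, male_catalog$code, male_catalog$count)
  female_n <- lookup_sorted(scored, female_catalog$code, female_catalog$count)
  female_ok <- female_n >= min_read_count
  hit <- (male_n < min_read_count) & female_ok
  if (denominator == "female_supported") scored <- scored[female_ok]
  n_scored <- if (denominator == "female_supported") sum(female_ok)
              else length(scored)
  if (n_scored == 0L)
    return(row(0L, NA_real_, FALSE, "no_scored_kmers"))
  pct <- 100 * sum(hit) / n_scored
  if (n_scored < min_kmers)
    return(row(as.integer(n_scored), pct, FALSE, "too_few_kmers"))
  row(as.integer(n_scored), pct, pct > threshold_pct, "")
}

#' Run the YGS k-mer scan over all scaffolds
#'
#' @param scaffolds Scaffold set (named character vector).
#' @param male_reads,female_reads Read sets (character vectors) or pre-built
#'   `kmer_catalog`s of the pooled reads.
#' @param k k-mer length (default 16).
#' @param assembly_catalog Optional pre-built assembly `kmer_catalog`.
#' @param verbose Log summary counts (default FALSE).
#' @inheritParams ygs_score
#' @return data.frame with one YGS result row per scaffold.
#' @export
kmer_scan_all <- function(scaffolds, male_reads, female_reads, k = 16L,
                          min_read_count = 2L, threshold_pct = 75,
                          min_kmers = 50L,
                          denominator = c("single_copy", "female_supported"),
                          assembly_catalog = NULL, verbose = FALSE) {
  denominator <- match.arg(denominator)
  validate_scaffolds(scaffolds)
  as_cat <- function(x, source) {
    if (inherits(x, "kmer_catalog")) {
      if (x$k != k) stop("catalogue k mismatch", call. = FALSE)
      x
    } else count_kmers(x, k = k, source = source)
  }
  if (is.null(assembly_catalog))
    assembly_catalog <- count_kmers(scaffolds, k = k, source = "assembly")
  male_cat <- as_cat(male_reads, "male_reads")
  female_cat <- as_cat(female_reads, "female_reads")
  if (!length(male_cat$code))
    warning("male read catalogue is empty: every female-supported k-mer ",
            "will count as male-absent")
  sc <- single_copy_kmers(assembly_catalog)
  rows <- lapply(names(scaffolds), function(id)
    ygs_score(scaffolds[[id]], id, sc, male_cat, female_cat, k = k,
              min_read_count = min_read_count, threshold_pct = threshold_pct,
              min_kmers = min_kmers, denominator = denominator))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (verbose)
    message("kmer_scan_all: ", sum(out$w_call), "/", nrow(out),
            " scaffolds called W-linked (k = ", k, ", threshold > ",
            threshold_pct, "%, min ", min_kmers, " scored k-mers)")
  out
}
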