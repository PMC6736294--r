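# Readers/writers for the on-disk formats used throughout the pipeline,
# plus basic assembly statistics.
#
# Conventions: depth TSVs are 1-based inclusive on disk (samtools depth
# dialect); every internal coordinate in this package is 0-based half-open;
# conversion happens only at the I/O boundary.

#' Read a FASTA file into a scaffold set
#'
#' A scaffold set is a named character vector of uppercase sequences over
#' A/C/G/T/N. Record ids are the first whitespace-delimited token of each
#' header and must be unique; lowercase input is uppercased.
#'
#' @param path Path to a FASTA file (plain or gzip).
#' @return Named character vector of sequences, in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(set))
  ids <- sub("\\s.*$", "", names(seqs))
  names(seqs) <- ids
  validate_scaffolds(seqs, what = paste0("FASTA '", path, "'"))
}

#' Write a scaffold set to FASTA
#'
#' @param scaffolds Named character vector of sequences.
#' @param path Output path.
#' @param line_width Bases per sequence line (>= 1).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(scaffolds, path, line_width = 60L) {
  stopifnot(line_width >= 1)
  if (length(scaffolds)) validate_scaffolds(scaffolds)
  set <- Biostrings::DNAStringSet(scaffolds)
  Biostrings::writeXStringSet(set, filepath = path, width = as.integer(line_width))
  invisible(path)
}

#' Write reads to FASTQ
#'
#' Qualities are constant ("I" = Q40); read names come from the vector names.
#'
#' @param reads Named character vector of read sequences.
#' @param path Output path (".gz" suffix gzips).
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  if (length(reads)) {
    qual <- vapply(nchar(reads), function(n)
      paste(rep("I", n), collapse = ""), character(1))
    writeLines(paste0("@", names(reads), "\n", reads, "\n+\n", qual), con)
  }
  invisible(path)
}

#' Read a FASTQ file
#'
#' @param path Path to a FASTQ file (plain or gzip).
#' @return Named character vector of read sequences (uppercase).
#' @export
read_fastq <- function(path) {
  lines <- readLines(if (grepl("\\.gz$", path)) gzfile(path) else path)
  if (length(lines) %% 4L != 0L)
    stop("FASTQ '", path, "': line count not a multiple of 4", call. = FALSE)
  ids <- sub("^@", "", sub("\\s.*$", "", lines[seq(1, length(lines), by = 4)]))
  setNames(toupper(lines[seq(2, length(lines), by = 4)]), ids)
}

#' Read a samtools-depth style TSV into per-base depth arrays
#'
#' Rows are (scaffold_id, position, depth) with 1-based positions. In the
#' `all_positions` dialect every position of every listed scaffold must be
#' present; in the `sparse` dialect unlisted positions get depth 0.
#' Scaffolds absent from the file get all-zero arrays.
#'
#' @param path Path to the TSV (no header).
#' @param scaffolds Companion scaffold set (or named lengths) defining ids
#'   and lengths.
#' @param dialect `"all_positions"` or `"sparse"`.
#' @return Depth track: named list of integer vectors, one per scaffold,
#'   each of the scaffold's length.
#' @export
read_depth_tsv <- function(path, scaffolds,
                           dialect = c("all_positions", "sparse")) {
  dialect <- match.arg(dialect)
  lens <- if (is.character(scaffolds)) scaffold_lengths(scaffolds)
          else setNames(as.integer(scaffolds), names(scaffolds))
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          col.names = c("scaffold", "pos", "depth"),
                          colClasses = list(character = 1))
  if (nrow(dt)) {
    bad <- which(!dt$scaffold %in% names(lens))
    if (length(bad))
      stop("depth TSV '", path, "' line ", bad[1], ": unknown scaffold id '",
           dt$scaffold[bad[1]], "'", call. = FALSE)
    if (!is.numeric(dt$pos) || !is.numeric(dt$depth) ||
        any(dt$depth != floor(dt$depth)) || any(dt$pos != floor(dt$pos))) {
      bad <- which(dt$depth != floor(dt$depth) | dt$pos != floor(dt$pos))[1]
      stop("depth TSV '", path, "' line ", bad,
           ": non-integer position or depth", call. = FALSE)
    }
    out_of_range <- which(dt$pos < 1 | dt$pos > lens[dt$scaffold])
    if (length(out_of_range))
      stop("depth TSV '", path, "' line ", out_of_range[1],
           ": position out of range for scaffold '",
           dt$scaffold[out_of_range[1]], "'", call. = FALSE)
    if (any(dt$depth < 0))
      stop("depth TSV '", path, "' line ", which(dt$depth < 0)[1],
           ": negative depth", call. = FALSE)
  }
  track <- lapply(names(lens), function(id) integer(lens[[id]]))
  names(track) <- names(lens)
  if (nrow(dt)) {
    for (id in unique(dt$scaffold)) {
      sub <- dt[dt$scaffold == id, ]
      if (anyDuplicated(sub$pos))
        stop("depth TSV '", path, "': duplicate position for scaffold '",
             id, "'", call. = FALSE)
      if (dialect == "all_positions" && nrow(sub) != lens[[id]])
        stop("depth TSV '", path, "': scaffold '", id, "' lists ",
             nrow(sub), " of ", lens[[id]],
             " positions in all_positions dialect", call. = FALSE)
      v <- integer(lens[[id]])
      v[sub$pos] <- as.integer(sub$depth)
      track[[id]] <- v
    }
  }
  track
}

#' Write a depth track as samtools-depth style TSV
#'
#' @param track Depth track (named list of integer vectors).
#' @param path Output path.
#' @param dialect `"all_positions"` writes every base; `"sparse"` writes
#'   only non-zero depths.
#' @return `path`, invisibly.
#' @export
write_depth_tsv <- function(track, path,
                            dialect = c("all_positions", "sparse")) {
  dialect <- match.arg(dialect)
  parts <- lapply(names(track), function(id) {
    d <- track[[id]]
    pos <- seq_along(d)
    if (dialect == "sparse") {
      keep <- d > 0L
      pos <- pos[keep]; d <- d[keep]
    }
    if (!length(pos)) return(NULL)
    data.table::data.table(scaffold = id, pos = pos, depth = d)
  })
  dt <- data.table::rbindlist(parts)
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Assembly summary statistics
#'
#' N50 is the length L of the scaffold at which, scanning scaffold lengths
#' in descending order, the cumulative length first reaches at least half
#' the assembly total.
#'
#' @param scaffolds Scaffold set (named character vector) or a numeric
#'   vector of scaffold lengths.
#' @return List with `n_scaffolds`, `total_length`, `n50`.
#' @examples
#' assembly_stats(c(5, 4, 3, 2, 1))  # N50 = 4
#' @export
assembly_stats <- function(scaffolds) {
  lens <- if (is.character(scaffolds)) nchar(scaffolds) else as.numeric(scaffolds)
  if (!length(lens)) stop("empty scaffold set", call. = FALSE)
  stopifnot(all(lens >= 1))
  lens <- sort(lens, decreasing = TRUE)
  total <- sum(lens)
  n50 <- lens[which(cumsum(lens) >= total / 2)[1]]
  list(n_scaffolds = length(lens), total_length = total, n50 = n50)
}

#' Read a scaffold anchoring table
#'
#' Tab-separated with header columns scaffold_id, ref_chrom, order_index,
#' strand. (ref_chrom, order_index) must be unique; strand is "+" or "-".
#'
#' @param path Path to the TSV.
#' @param scaffolds Optional scaffold set; if given, every scaffold_id must
#'   be present in it.
#' @return data.frame of anchor rows.
#' @export
read_anchor_table <- function(path, scaffolds = NULL) {
  df <- as.data.frame(data.table::fread(path, header = TRUE, sep = "\t",
                                        colClasses = list(character = c(1, 2, 4))))
  validate_anchor_table(df, scaffolds)
}

validate_anchor_table <- function(df, scaffolds = NULL) {
  need <- c("scaffold_id", "ref_chrom", "order_index", "strand")
  if (!all(need %in% names(df)))
    stop("anchor table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(df[, c("ref_chrom", "order_index")]))
    stop("anchor table: duplicate (ref_chrom, order_index)", call. = FALSE)
  if (!all(df$strand %in% c("+", "-")))
    stop("anchor table: strand must be '+' or '-'", call. = FALSE)
  if (!is.null(scaffolds)) {
    missing <- setdiff(df$scaffold_id, names(scaffolds))
    if (length(missing))
      stop("anchor table: unknown scaffold id(s): ",
           paste(head(missing, 5), collapse = ", "), call. = FALSE)
  }
  df
}

#' Write an anchoring table
#'
#' @param anchors data.frame with scaffold_id, ref_chrom, order_index, strand.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_anchor_table <- function(anchors, path) {
  validate_anchor_table(anchors)
  data.table::fwrite(anchors, path, sep = "\t")
  invisible(path)
}

#' Read a simulation config from YAML
#'
#' Keys override the defaults of [sim_config()].
#'
#' @param path Path to a YAML file of scalar keys.
#' @return A validated `sim_config` object.
#' @export
read_sim_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(sim_config, vals)
}
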