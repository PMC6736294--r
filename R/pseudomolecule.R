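# Pseudomolecule construction from an anchoring table, depth lifting,
# windowed depth states, and the neo-sex chromosome report.
#
# Coordinates on pseudomolecules are 0-based half-open; scaffolds are
# separated by N-runs of `gap_size` bases. Gap positions carry no depth
# and are masked (NA) in lifted tracks so they never enter window means.

#' Build pseudomolecules from an anchoring table
#'
#' Scaffolds are concatenated per reference chromosome in `order_index`
#' order, reverse-complemented when the strand is "-", and separated by
#' N-runs of `gap_size`. Scaffolds whose label is in `exclude` are
#' dropped before building (this is how the neo-W and neo-Z versions of a
#' doubly-anchored chromosome are recovered: rebuild without Z-linked,
#' then without W-linked scaffolds).
#'
#' @param scaffolds Scaffold set (named character vector).
#' @param anchors Anchor table (scaffold_id, ref_chrom, order_index,
#'   strand).
#' @param gap_size N-run length between placements (default 100).
#' @param exclude Character vector of labels to drop (e.g. `c("Z")`).
#' @param labels Optional data.frame (scaffold_id, label) required when
#'   `exclude` is non-empty.
#' @return List with `seq` (named character vector, one pseudomolecule per
#'   ref_chrom) and `map` (data.frame: chrom, start, end, scaffold_id,
#'   strand) recording exact placements.
#' @export
build_pseudomolecule <- function(scaffolds, anchors, gap_size = 100L,
                                 exclude = character(0), labels = NULL) {
  validate_scaffolds(scaffolds)
  validate_anchor_table(anchors, scaffolds)
  stopifnot(gap_size >= 0)
  if (length(exclude)) {
    if (is.null(labels))
      stop("`labels` is required when `exclude` is non-empty", call. = FALSE)
    drop_ids <- labels$scaffold_id[labels$label %in% exclude]
    anchors <- anchors[!anchors$scaffold_id %in% drop_ids, , drop = FALSE]
  }
  gap <- paste(rep("N", gap_size), collapse = "")
  seqs <- character(0)
  maps <- list()
  for (chrom in unique(anchors$ref_chrom)) {
    sub <- anchors[anchors$ref_chrom == chrom, , drop = FALSE]
    if (anyDuplicated(sub$order_index))
      stop("duplicate order_index on ", chrom, call. = FALSE)
    sub <- sub[order(sub$order_index), , drop = FALSE]
    pieces <- scaffolds[sub$scaffold_id]
    minus <- sub$strand == "-"
    if (any(minus)) pieces[minus] <- revcomp_cpp(pieces[minus])
    lens <- nchar(pieces)
    starts <- cumsum(c(0, head(lens + gap_size, -1)))
    seqs[[chrom]] <- paste(pieces, collapse = gap)
    maps[[chrom]] <- data.frame(chrom = chrom, start = starts,
                                end = starts + lens,
                                scaffold_id = sub$scaffold_id,
                                strand = sub$strand,
                                row.names = NULL, stringsAsFactors = FALSE)
  }
  map <- do.call(rbind, maps)
  rownames(map) <- NULL
  list(seq = seqs, map = map, gap_size = as.integer(gap_size))
}

#' Lift per-scaffold depth onto pseudomolecule coordinates
#'
#' Depth is copied base-wise through the placements (reversed for "-"
#' strand); gap positions are NA so they are excluded from window means.
#'
#' @param track Depth track (named list of per-base vectors).
#' @param map Placement map from [build_pseudomolecule()].
#' @return Named list (one numeric vector per pseudomolecule) with NA at
#'   gap positions.
#' @export
lift_depth <- function(track, map) {
  missing <- setdiff(map$scaffold_id, names(track))
  if (length(missing))
    stop("depth track missing scaffold(s): ",
         paste(head(missing, 5), collapse = ", "), call. = FALSE)
  out <- list()
  for (chrom in unique(map$chrom)) {
    sub <- map[map$chrom == chrom, , drop = FALSE]
    total <- max(sub$end)
    v <- rep(NA_real_, total)
    for (i in seq_len(nrow(sub))) {
      d <- track[[sub$scaffold_id[i]]]
      if (length(d) != sub$end[i] - sub$start[i])
        stop("depth length mismatch for scaffold ", sub$scaffold_id[i],
             call. = FALSE)
      if (sub$strand[i] == "-") d <- rev(d)
      v[(sub$start[i] + 1L):sub$end[i]] <- d
    }
    out[[chrom]] <- v
  }
  out
}

#' Project lifted depth back to per-scaffold arrays
#'
#' Inverse of [lift_depth()] over the same map.
#'
#' @param lifted Named list of pseudomolecule depth vectors.
#' @param map Placement map.
#' @return Depth track (named list of per-scaffold vectors).
#' @export
project_depth <- function(lifted, map) {
  out <- list()
  for (i in seq_len(nrow(map))) {
    v <- lifted[[map$chrom[i]]][(map$start[i] + 1L):map$end[i]]
    if (map$strand[i] == "-") v <- rev(v)
    out[[map$scaffold_id[i]]] <- v
  }
  out
}

#' Mean depth per sex in non-overlapping windows
#'
#' Windows tile each pseudomolecule from 0; the final partial window keeps
#' its true extent. Gap (NA) positions are excluded from the mean's
#' denominator; all-gap windows get NaN means.
#'
#' @param male_lifted,female_lifted Lifted depth tracks from
#'   [lift_depth()].
#' @param window Window size in bp (default 1e5).
#' @return data.frame: chrom, start, end, male_mean, female_mean.
#' @export
window_depth <- function(male_lifted, female_lifted, window = 1e5) {
  stopifnot(window >= 1, identical(names(male_lifted), names(female_lifted)))
  rows <- list()
  for (chrom in names(male_lifted)) {
    n <- length(male_lifted[[chrom]])
    starts <- seq(0, n - 1, by = window)
    ends <- pmin(starts + window, n)
    wm <- vapply(seq_along(starts), function(i)
      mean(male_lifted[[chrom]][(starts[i] + 1):ends[i]], na.rm = TRUE),
      numeric(1))
    wf <- vapply(seq_along(starts), function(i)
      mean(female_lifted[[chrom]][(starts[i] + 1):ends[i]], na.rm = TRUE),
      numeric(1))
    rows[[chrom]] <- data.frame(chrom = chrom, start = starts, end = ends,
                                male_mean = wm, female_mean = wf,
                                row.names = NULL, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Classify one vector of window means against a diploid level.
classify_depth_state <- function(means, diploid, low_cut, tol) {
  haploid <- diploid / 2
  state <- rep("AMBIGUOUS", length(means))
  state[!is.nan(means) & means < low_cut] <- "ABSENT"
  hap <- !is.nan(means) & abs(means - haploid) <= tol * haploid &
    means >= low_cut
  dip <- !is.nan(means) & abs(means - diploid) <= tol * diploid &
    means >= low_cut
  state[hap] <- "HAPLOID"
  state[dip] <- "DIPLOID"
  state
}

#' Classify window depth states per sex
#'
#' Per sex a window is ABSENT below `low_cut`, HAPLOID within a relative
#' tolerance band around half the sex's diploid peak, DIPLOID within the
#' band around the diploid peak, otherwise AMBIGUOUS.
#'
#' @param rows Window table from [window_depth()].
#' @param peaks A `depth_peaks` object.
#' @param tol Relative tolerance of the bands (default 0.25).
#' @param low_cut Absent threshold (default 5).
#' @return `rows` with `male_state` and `female_state` columns added.
#' @export
classify_windows <- function(rows, peaks, tol = 0.25, low_cut = 5) {
  rows$male_state <- classify_depth_state(rows$male_mean,
                                          peaks$male_diploid, low_cut, tol)
  rows$female_state <- classify_depth_state(rows$female_mean,
                                            peaks$female_diploid, low_cut,
                                            tol)
  rows
}

# Joint window class from the per-sex states.
joint_window_class <- function(male_state, female_state) {
  ifelse(male_state == "ABSENT" & female_state == "HAPLOID", "W_LINKED",
  ifelse(male_state == "DIPLOID" & female_state == "HAPLOID", "Z_LINKED",
  ifelse(male_state == "DIPLOID" & female_state == "DIPLOID", "AUTOSOMAL",
         "OTHER")))
}

#' Neo-sex chromosome report
#'
#' Summarizes, per pseudomolecule, the fraction of sex-linked windows
#' (male-absent/female-haploid or male-diploid/female-haploid), the runs
#' of identical joint window state with their coordinates, and the length
#' inflation relative to a supplied reference chromosome length (a ratio
#' near 2 on a doubly-anchored chromosome is the signature of two fused
#' sex-linked versions).
#'
#' @param rows Classified window table from [classify_windows()].
#' @param maps Placement map (or list of maps) from
#'   [build_pseudomolecule()]; used for pseudomolecule lengths.
#' @param reference_lengths Optional named numeric vector of reference
#'   chromosome lengths keyed by ref_chrom.
#' @return List with `summary` (per chrom: n_windows, fraction_sex_linked,
#'   n_runs, pseudomolecule_length, inflation_ratio) and `runs` (per
#'   maximal run: chrom, start, end, male_state, female_state, class,
#'   n_windows).
#' @export
neo_report <- function(rows, maps, reference_lengths = NULL) {
  if (is.data.frame(maps)) maps <- list(maps)
  map <- do.call(rbind, maps)
  rows$class <- joint_window_class(rows$male_state, rows$female_state)
  runs_rows <- list()
  summary_rows <- list()
  for (chrom in unique(rows$chrom)) {
    sub <- rows[rows$chrom == chrom, , drop = FALSE]
    joint <- paste(sub$male_state, sub$female_state)
    r <- rle(joint)
    idx_end <- cumsum(r$lengths)
    idx_start <- idx_end - r$lengths + 1L
    runs_rows[[chrom]] <- data.frame(
      chrom = chrom,
      start = sub$start[idx_start], end = sub$end[idx_end],
      male_state = sub$male_state[idx_start],
      female_state = sub$female_state[idx_start],
      class = sub$class[idx_start],
      n_windows = r$lengths, row.names = NULL, stringsAsFactors = FALSE)
    plen <- max(map$end[map$chrom == chrom])
    ref_len <- if (!is.null(reference_lengths) &&
                   chrom %in% names(reference_lengths))
      reference_lengths[[chrom]] else NA_real_
    summary_rows[[chrom]] <- data.frame(
      chrom = chrom, n_windows = nrow(sub),
      fraction_sex_linked = mean(sub$class %in% c("W_LINKED", "Z_LINKED")),
      n_runs = length(r$lengths),
      pseudomolecule_length = plen,
      inflation_ratio = plen / ref_len,
      row.names = NULL, stringsAsFactors = FALSE)
  }
  runs <- do.call(rbind, runs_rows)
  rownames(runs) <- NULL
  summary <- do.call(rbind, summary_rows)
  rownames(summary) <- NULL
  list(summary = summary, runs = runs)
}
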