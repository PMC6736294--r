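# Differential-mapping classifier: per-scaffold median depth and coverage
# fraction per sex, pooled-histogram depth peaks, W/Z calls, per-individual
# in-silico sexing, and the two-method W-call comparison.

#' Classifier parameters
#'
#' @param w_cov_min Minimum female covered fraction for a depth W call
#'   (strict >, default 0.75).
#' @param z_cov_min Minimum covered fraction in both sexes for a Z call
#'   (strict >, default 0.75).
#' @param z_male_factor Multiplier on the male diploid peak giving the male
#'   median-depth floor for Z (default 0.75).
#' @param z_female_factor Multiplier on the female haploid peak giving the
#'   female median-depth ceiling for Z (default 1.5).
#' @return List of class `classifier_params`.
#' @export
classifier_params <- function(w_cov_min = 0.75, z_cov_min = 0.75,
                              z_male_factor = 0.75, z_female_factor = 1.5) {
  stopifnot(w_cov_min > 0, w_cov_min <= 1, z_cov_min > 0, z_cov_min <= 1,
            z_male_factor > 0, z_female_factor > 0)
  structure(list(w_cov_min = w_cov_min, z_cov_min = z_cov_min,
                 z_male_factor = z_male_factor,
                 z_female_factor = z_female_factor),
            class = "classifier_params")
}

#' Subsample a read table without replacement
#'
#' Used to equalize coverage across individuals before pooling. Original
#' order is preserved; when `n_target` is at least the table size all reads
#' are returned (with a warning if strictly greater).
#'
#' @param reads Vector or data.frame of reads.
#' @param n_target Number of reads to keep.
#' @param seed Integer seed making the draw reproducible.
#' @return Subsampled object of the same type.
#' @export
subsample_reads <- function(reads, n_target, seed = 1L) {
  n <- if (is.data.frame(reads)) nrow(reads) else length(reads)
  stopifnot(n_target >= 0)
  if (n_target >= n) {
    if (n_target > n)
      warning("n_target (", n_target, ") exceeds read count (", n,
              "); returning all reads")
    return(reads)
  }
  idx <- with_seed(seed, sort(sample.int(n, n_target)))
  if (is.data.frame(reads)) reads[idx, , drop = FALSE] else reads[idx]
}

#' Per-scaffold depth summary for one sex or individual
#'
#' Medians are over all bases, zeros included (an even-length median is the
#' mean of the central pair); the covered fraction is the proportion of
#' bases with depth >= 1.
#'
#' @param track Depth track (named list of per-base integer vectors).
#' @param scaffolds Scaffold set or named lengths; every scaffold must be
#'   present in the track.
#' @return data.frame: scaffold_id, length, median_depth, covered_fraction.
#' @export
scaffold_depth_summary <- function(track, scaffolds) {
  lens <- if (is.character(scaffolds)) scaffold_lengths(scaffolds)
          else setNames(as.numeric(scaffolds), names(scaffolds))
  missing <- setdiff(names(lens), names(track))
  if (length(missing))
    stop("depth track missing scaffold(s): ",
         paste(head(missing, 5), collapse = ", "), call. = FALSE)
  ids <- names(lens)
  data.frame(
    scaffold_id = ids,
    length = as.numeric(lens),
    median_depth = vapply(ids, function(id) median(track[[id]]), numeric(1)),
    covered_fraction = vapply(ids, function(id) mean(track[[id]] > 0L),
                              numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
}

# Merge male and female summaries into one table keyed by scaffold.
combine_depth_summaries <- function(male_summary, female_summary) {
  stopifnot(identical(male_summary$scaffold_id, female_summary$scaffold_id))
  data.frame(
    scaffold_id = male_summary$scaffold_id,
    length = male_summary$length,
    male_median = male_summary$median_depth,
    male_covered = male_summary$covered_fraction,
    female_median = female_summary$median_depth,
    female_covered = female_summary$covered_fraction,
    row.names = NULL, stringsAsFactors = FALSE)
}

# Local maxima of a numeric series (plateau-tolerant, interior points only).
local_maxima <- function(y) {
  n <- length(y)
  if (n < 3) return(integer(0))
  which(vapply(2:(n - 1), function(i)
    y[i] >= y[i - 1] && y[i] >= y[i + 1] &&
      (y[i] > y[i - 1] || y[i] > y[i + 1]), logical(1))) + 1L
}

#' Estimate diploid/haploid depth peaks from pooled per-base histograms
#'
#' Per-base depth histograms (bin width 1) are smoothed with a centred
#' moving average; the diploid peak per sex is the histogram argmax above
#' `low_cut`, and the female haploid peak is the best local maximum in the
#' open interval (`low_cut`, 0.75 x female diploid). If no local maximum
#' exists there the haploid peak falls back to half the diploid peak and
#' the result is flagged.
#'
#' @param male_track,female_track Depth tracks (named lists of per-base
#'   integer vectors).
#' @param low_cut Depth below which positions count as "absent" mass
#'   (default 5).
#' @param smooth_bw Moving-average width in bins (default 5).
#' @return List of class `depth_peaks`: male_diploid, female_diploid,
#'   female_haploid, male_low_mass, haploid_fallback.
#' @export
estimate_depth_peaks <- function(male_track, female_track, low_cut = 5,
                                 smooth_bw = 5) {
  md <- unlist(male_track, use.names = FALSE)
  fd <- unlist(female_track, use.names = FALSE)
  if (!length(md) || !length(fd)) stop("empty depth track", call. = FALSE)
  peak_scan <- function(d) {
    h <- tabulate(d + 1L)                       # h[i] = count of depth i-1
    sm <- as.numeric(stats::filter(h, rep(1 / smooth_bw, smooth_bw),
                                   sides = 2))
    sm[is.na(sm)] <- h[is.na(sm)]
    depth_axis <- seq_along(h) - 1L
    eligible <- depth_axis > low_cut
    if (!any(eligible)) stop("no depth mass above low_cut", call. = FALSE)
    dip <- depth_axis[eligible][which.max(sm[eligible])]
    list(h = h, sm = sm, axis = depth_axis, diploid = dip)
  }
  m <- peak_scan(md)
  f <- peak_scan(fd)
  hap_window <- f$axis > low_cut & f$axis < 0.75 * f$diploid
  lm_idx <- local_maxima(f$sm)
  lm_idx <- lm_idx[hap_window[lm_idx]]
  fallback <- length(lm_idx) == 0L
  female_haploid <- if (fallback) f$diploid / 2
                    else f$axis[lm_idx[which.max(f$sm[lm_idx])]]
  structure(list(male_diploid = m$diploid,
                 female_diploid = f$diploid,
                 female_haploid = female_haploid,
                 male_low_mass = mean(md < low_cut),
                 haploid_fallback = fallback),
            class = "depth_peaks")
}

#' Derive the Z-classification depth thresholds from the observed peaks
#'
#' The male floor is `z_male_factor` times the male diploid peak and the
#' female ceiling `z_female_factor` times the female haploid peak, each
#' rounded to the nearest integer (0.75 x 77 = 57.75 -> 58;
#' 1.5 x 41.5 = 62.25 -> 62).
#'
#' @param peaks A `depth_peaks` object (or list with male_diploid and
#'   female_haploid).
#' @param params A `classifier_params` object.
#' @return List with `z_male_min` and `z_female_max`.
#' @export
derive_thresholds <- function(peaks, params = classifier_params()) {
  stopifnot(peaks$male_diploid > 0, peaks$female_haploid > 0)
  list(z_male_min = round(params$z_male_factor * peaks$male_diploid),
       z_female_max = round(params$z_female_factor * peaks$female_haploid))
}

#' Depth-based W call
#'
#' W-linked scaffolds must show exactly zero median male depth and strictly
#' more than `w_cov_min` of their length covered by female reads.
#'
#' @param summary Combined per-scaffold summary with columns male_median
#'   and female_covered (see [combine_depth_summaries()]).
#' @param params A `classifier_params` object.
#' @return Logical vector, one call per row of `summary`.
#' @export
classify_w_by_depth <- function(summary, params = classifier_params()) {
  summary$male_median == 0 & summary$female_covered > params$w_cov_min
}

#' Depth-based Z call
#'
#' Z-linked scaffolds must exceed the male median floor, stay under the
#' female median ceiling, and have both sexes covering more than
#' `z_cov_min` of the scaffold. All inequalities strict.
#'
#' @param summary Combined per-scaffold summary (see
#'   [combine_depth_summaries()]).
#' @param thresholds Output of [derive_thresholds()].
#' @param params A `classifier_params` object.
#' @return Logical vector, one call per row of `summary`.
#' @export
classify_z_by_depth <- function(summary, thresholds,
                                params = classifier_params()) {
  summary$male_median > thresholds$z_male_min &
    summary$female_median < thresholds$z_female_max &
    summary$male_covered > params$z_cov_min &
    summary$female_covered > params$z_cov_min
}

#' Combine k-mer and depth-based calls
#'
#' The W call set is the union of the two approaches; Z comes from depth
#' only (a k-mer absence test cannot see Z, which both sexes carry). A
#' scaffold passing both the W and Z rules is labelled W and flagged.
#'
#' @param ygs YGS result table from [kmer_scan_all()] (columns scaffold_id,
#'   w_call).
#' @param depth data.frame with columns scaffold_id, depth_w, depth_z and
#'   optionally length (used for the per-category length breakdown).
#' @return List with `calls` (scaffold_id, kmer_w, depth_w, depth_z,
#'   final_label, evidence, flag) and `breakdown` (n/pct/length per
#'   evidence category plus the union).
#' @export
combine_calls <- function(ygs, depth) {
  if (!setequal(ygs$scaffold_id, depth$scaffold_id))
    stop("k-mer and depth tables cover different scaffolds", call. = FALSE)
  depth <- depth[match(ygs$scaffold_id, depth$scaffold_id), , drop = FALSE]
  kmer_w <- ygs$w_call
  depth_w <- depth$depth_w
  depth_z <- depth$depth_z
  w <- kmer_w | depth_w
  final <- ifelse(w, "W", ifelse(depth_z, "Z", "AUTO_OTHER"))
  flag <- ifelse(w & depth_z, "w_and_z_rules", "")
  evidence <- ifelse(kmer_w & depth_w, "both",
                     ifelse(kmer_w, "kmer_only",
                            ifelse(depth_w, "mapping_only", "none")))
  calls <- data.frame(scaffold_id = ygs$scaffold_id, kmer_w = kmer_w,
                      depth_w = depth_w, depth_z = depth_z,
                      final_label = final, evidence = evidence, flag = flag,
                      row.names = NULL, stringsAsFactors = FALSE)
  n_both <- sum(evidence == "both")
  n_kmer <- sum(evidence == "kmer_only")
  n_map <- sum(evidence == "mapping_only")
  n_union <- n_both + n_kmer + n_map
  lens <- if ("length" %in% names(depth)) depth$length else NULL
  len_of <- function(cat) {
    if (is.null(lens)) NA_real_ else sum(lens[evidence == cat])
  }
  breakdown <- data.frame(
    category = c("both", "kmer_only", "mapping_only", "union"),
    n = c(n_both, n_kmer, n_map, n_union),
    pct = if (n_union > 0) 100 * c(n_both, n_kmer, n_map, n_union) / n_union
          else rep(NA_real_, 4),
    length = c(len_of("both"), len_of("kmer_only"), len_of("mapping_only"),
               if (is.null(lens)) NA_real_
               else sum(lens[evidence != "none"])),
    row.names = NULL, stringsAsFactors = FALSE)
  list(calls = calls, breakdown = breakdown)
}

#' Verify the recorded sex of each individual from marker scaffolds
#'
#' Uses three marker scaffolds with known inheritance (a W fragment, a Z
#' fragment, an autosomal fragment). Females show haploid W and Z depth
#' (about half the autosomal median); males show near-zero W depth and
#' Z depth comparable to the autosomal median. Profiles matching neither
#' pattern are flagged inconsistent.
#'
#' @param summaries Named list (one per individual) of per-scaffold depth
#'   summaries from [scaffold_depth_summary()].
#' @param marker_ids List or named vector with entries `w_marker`,
#'   `z_marker`, `auto_marker` giving the three scaffold ids.
#' @param claimed_sex Optional named character vector ("male"/"female") of
#'   recorded sexes to compare against.
#' @param near_zero_cut W-marker median at/below which the W is absent
#'   (default 1).
#' @param z_female_ratio_max Z/autosomal median ratio at/below which Z
#'   depth is haploid (default 0.65).
#' @param z_male_ratio_min Z/autosomal median ratio at/above which Z depth
#'   is diploid (default 0.8).
#' @return data.frame: individual, w_median, z_median, auto_median,
#'   inferred_sex, consistent.
#' @export
verify_individual_sex <- function(summaries, marker_ids, claimed_sex = NULL,
                                  near_zero_cut = 1,
                                  z_female_ratio_max = 0.65,
                                  z_male_ratio_min = 0.8) {
  marker_ids <- as.list(marker_ids)
  rows <- lapply(names(summaries), function(ind) {
    s <- summaries[[ind]]
    get_med <- function(id) {
      i <- match(id, s$scaffold_id)
      if (is.na(i)) stop("individual '", ind, "': marker scaffold '", id,
                         "' missing from summary", call. = FALSE)
      s$median_depth[i]
    }
    wm <- get_med(marker_ids$w_marker)
    zm <- get_med(marker_ids$z_marker)
    am <- get_med(marker_ids$auto_marker)
    if (am <= 0) stop("individual '", ind, "': autosomal marker has zero ",
                      "median depth", call. = FALSE)
    ratio <- zm / am
    inferred <- if (wm > near_zero_cut && ratio <= z_female_ratio_max)
      "female"
    else if (wm <= near_zero_cut && ratio >= z_male_ratio_min)
      "male"
    else "inconsistent"
    consistent <- inferred != "inconsistent" &&
      (is.null(claimed_sex) || identical(unname(claimed_sex[ind]), inferred))
    data.frame(individual = ind, w_median = wm, z_median = zm,
               auto_median = am, inferred_sex = inferred,
               consistent = consistent, row.names = NULL,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
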