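# End-to-end synthetic study: simulate a ZW genome, run both W/Z
# classifiers, score them against truth, and profile the neo-sex
# chromosome signals.

precision_recall <- function(called, truth_pos) {
  tp <- sum(called %in% truth_pos)
  c(precision = if (length(called)) tp / length(called) else NA_real_,
    recall = if (length(truth_pos)) tp / length(truth_pos) else NA_real_)
}

#' Run the full synthetic classification study
#'
#' Simulates a genome and sex-pooled reads/depth tracks, runs the
#' single-copy k-mer scan and the differential-depth classifier, combines
#' the calls, scores them against the truth labels, and profiles the
#' anchored pseudomolecules for the neo-sex chromosome signature
#' (inflation of the doubly-anchored chromosome; sex-linked interior
#' window runs with autosomal termini).
#'
#' @param config A `sim_config`.
#' @param k,min_read_count,threshold_pct,min_kmers YGS scan parameters
#'   (see [kmer_scan_all()]).
#' @param params `classifier_params` for the depth rules.
#' @param window Depth-profile window size in bp. The default (2e4)
#'   keeps windows much smaller than the autosomal termini of the
#'   scaled-down neo chromosome, preserving the windows-to-termini ratio
#'   of full-scale profiles.
#' @param gap_size Pseudomolecule gap padding (default 100).
#' @param verbose Log stage progress.
#' @return List: sim truth table, ygs table, depth summary, peaks,
#'   thresholds, calls + breakdown, metrics (precision/recall for W and
#'   Z), window table and neo report.
#' @export
run_synthetic_study <- function(config = sim_config(), k = 16L,
                                min_read_count = 2L, threshold_pct = 75,
                                min_kmers = 50L,
                                params = classifier_params(),
                                window = 2e4, gap_size = 100L,
                                verbose = FALSE) {
  say <- function(...) if (verbose) message("[wzscan] ", ...)
  say("simulating genome (seed ", config$seed, ")")
  sim <- simulate_genome(config)
  st <- sim$truth$scaffolds

  say("simulating pooled reads and k-mer scan (k = ", k, ")")
  male_reads <- simulate_reads(sim$scaffolds, sim$truth, "male", config)
  female_reads <- simulate_reads(sim$scaffolds, sim$truth, "female", config)
  ygs <- kmer_scan_all(sim$scaffolds, male_reads, female_reads, k = k,
                       min_read_count = min_read_count,
                       threshold_pct = threshold_pct, min_kmers = min_kmers,
                       verbose = verbose)
  rm(male_reads, female_reads)
  gc(verbose = FALSE)

  say("simulating depth tracks and classifying by depth")
  male_track <- simulate_depth_tracks(sim$truth, config, "male")
  female_track <- simulate_depth_tracks(sim$truth, config, "female")
  summ <- combine_depth_summaries(
    scaffold_depth_summary(male_track, sim$scaffolds),
    scaffold_depth_summary(female_track, sim$scaffolds))
  peaks <- estimate_depth_peaks(male_track, female_track)
  thresholds <- derive_thresholds(peaks, params)
  depth_calls <- data.frame(
    scaffold_id = summ$scaffold_id, length = summ$length,
    depth_w = classify_w_by_depth(summ, params),
    depth_z = classify_z_by_depth(summ, thresholds, params),
    stringsAsFactors = FALSE)
  combined <- combine_calls(ygs, depth_calls)
  calls <- combined$calls

  truth_w <- st$scaffold_id[st$label %in% c("W", "NEO_W")]
  truth_z <- st$scaffold_id[st$label %in% c("Z", "NEO_Z")]
  metrics <- rbind(
    W = precision_recall(calls$scaffold_id[calls$final_label == "W"],
                         truth_w),
    Z = precision_recall(calls$scaffold_id[calls$final_label == "Z"],
                         truth_z))

  say("building pseudomolecules and windowed depth profile")
  anchors <- make_anchor_table(sim$truth)
  label_df <- data.frame(scaffold_id = calls$scaffold_id,
                         label = calls$final_label,
                         stringsAsFactors = FALSE)
  ps_all <- build_pseudomolecule(sim$scaffolds, anchors, gap_size = gap_size)
  ps_neow <- build_pseudomolecule(sim$scaffolds, anchors,
                                  gap_size = gap_size,
                                  exclude = "Z", labels = label_df)
  ps_neoz <- build_pseudomolecule(sim$scaffolds, anchors,
                                  gap_size = gap_size,
                                  exclude = "W", labels = label_df)
  profile_of <- function(ps) {
    wd <- window_depth(lift_depth(male_track, ps$map),
                       lift_depth(female_track, ps$map), window = window)
    classify_windows(wd, peaks)
  }
  windows_all <- profile_of(ps_all)
  windows_neow <- profile_of(ps_neow)
  windows_neoz <- profile_of(ps_neoz)
  ref_lengths <- c(stats::setNames(
    vapply(unique(st$source_chrom), function(ch)
      max(st$source_end[st$source_chrom == ch]), numeric(1)),
    sub("^chr", "ref", unique(st$source_chrom))))
  report_all <- neo_report(windows_all, ps_all$map, ref_lengths)
  report_neow <- neo_report(windows_neow, ps_neow$map, ref_lengths)
  report_neoz <- neo_report(windows_neoz, ps_neoz$map, ref_lengths)

  list(truth = sim$truth, scaffolds = sim$scaffolds, ygs = ygs,
       depth_summary = summ, peaks = peaks, thresholds = thresholds,
       calls = calls, breakdown = combined$breakdown, metrics = metrics,
       anchors = anchors,
       pseudomolecules = list(all = ps_all, neow = ps_neow, neoz = ps_neoz),
       windows = list(all = windows_all, neow = windows_neow,
                      neoz = windows_neoz),
       reports = list(all = report_all, neow = report_neow,
                      neoz = report_neoz))
}
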