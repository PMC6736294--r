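test_that("per-scaffold depth summaries use zero-inclusive medians", {
  track <- list(a = c(0L, 0L, 10L, 10L), b = rep(0L, 5), c = rep(80L, 3))
  s <- scaffold_depth_summary(track, c(a = 4, b = 5, c = 3))
  expect_equal(s$median_depth, c(5, 0, 80))
  expect_equal(s$covered_fraction, c(0.5, 0, 1))
  expect_error(scaffold_depth_summary(track["a"], c(a = 4, z = 2)),
               "missing")
})

test_that("read subsampling is deterministic, order-preserving and exact", {
  reads <- paste0("r", 1:1000)
  expect_identical(subsample_reads(reads, 1000, seed = 3), reads)
  expect_length(subsample_reads(reads, 0, seed = 3), 0)
  expect_warning(subsample_reads(reads, 2000, seed = 3), "exceeds")
  s1 <- subsample_reads(reads, 100, seed = 3)
  expect_identical(s1, subsample_reads(reads, 100, seed = 3))
  expect_length(s1, 100)
  expect_false(is.unsorted(match(s1, reads)))
})

test_that("subsampling includes each read at the expected rate", {
  reads <- seq_len(2000)
  hits <- numeric(length(reads))
  for (seed in 1:150) {
    idx <- subsample_reads(reads, 200, seed = seed)
    hits[idx] <- hits[idx] + 1
  }
  rates <- hits / 150
  expect_equal(mean(rates), 0.1, tolerance = 1e-9)
  expect_lt(max(abs(rates - 0.1)), 0.1)  # loose per-read band
})

test_that("depth peaks recover the diploid/haploid regime of pooled data", {
  with_seed_test(17, {
    # female: diploid regions at 83x, hemizygous at 41.5x
    female <- list(dip = rpois(4e5, 83), hap = rpois(1.2e5, 41.5))
    male <- list(dip = rpois(4e5, 77), hap = rpois(1.2e5, 77))
    pk <- estimate_depth_peaks(male, female)
    expect_lte(abs(pk$male_diploid - 77), 2)
    expect_lte(abs(pk$female_diploid - 83), 2)
    expect_lte(abs(pk$female_haploid - 41.5), 2)
    expect_lt(pk$male_low_mass, 0.01)
    expect_false(pk$haploid_fallback)
  })
})

test_that("a female track without a haploid peak falls back, flagged", {
  with_seed_test(18, {
    female <- list(a = rpois(2e5, 80))
    male <- list(a = rpois(2e5, 80))
    pk <- estimate_depth_peaks(male, female)
    expect_true(pk$haploid_fallback)
    expect_equal(pk$female_haploid, pk$female_diploid / 2)
  })
})

test_that("male low-depth mass flags W-absence", {
  with_seed_test(19, {
    male <- list(w = rpois(5e4, 0.2), a = rpois(5e4, 60))
    female <- list(w = rpois(5e4, 30), a = rpois(5e4, 60))
    pk <- estimate_depth_peaks(male, female)
    over_w <- mean(male$w < 5)
    expect_gt(over_w, 0.9)
    expect_gt(pk$male_low_mass, 0.45)
  })
})

test_that("threshold derivation reproduces the printed cut-offs", {
  pk <- structure(list(male_diploid = 77, female_diploid = 83,
                       female_haploid = 41.5), class = "depth_peaks")
  th <- derive_thresholds(pk)
  expect_equal(th$z_male_min, 58)    # 0.75 * 77 = 57.75
  expect_equal(th$z_female_max, 62)  # 1.5 * 41.5 = 62.25
  th1 <- derive_thresholds(pk, classifier_params(z_male_factor = 1,
                                                 z_female_factor = 1))
  expect_equal(th1$z_male_min, 77)
  expect_equal(th1$z_female_max, round(41.5))
})

test_that("W and Z depth rules apply their strict inequalities", {
  summ <- data.frame(
    scaffold_id = c("w_ok", "w_cov_boundary", "w_male_nonzero",
                    "z_ok", "z_male_boundary", "z_female_high"),
    male_median = c(0, 0, 1, 80, 58, 80),
    male_covered = c(0, 0, 0.2, 0.9, 0.9, 0.9),
    female_median = c(30, 30, 30, 40, 40, 70),
    female_covered = c(0.9, 0.75, 1.0, 0.9, 0.9, 0.9))
  expect_identical(classify_w_by_depth(summ),
                   c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE))
  th <- list(z_male_min = 58, z_female_max = 62)
  expect_identical(classify_z_by_depth(summ, th),
                   c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE))
})

test_that("combined calls reproduce the union breakdown arithmetic", {
  mk <- function(n_both, n_kmer, n_map, n_none = 5) {
    ids <- paste0("s", seq_len(n_both + n_kmer + n_map + n_none))
    kmer_w <- c(rep(TRUE, n_both + n_kmer),
                rep(FALSE, n_map + n_none))
    depth_w <- c(rep(TRUE, n_both), rep(FALSE, n_kmer),
                 rep(TRUE, n_map), rep(FALSE, n_none))
    list(ygs = data.frame(scaffold_id = ids, w_call = kmer_w),
         depth = data.frame(scaffold_id = ids, depth_w = depth_w,
                            depth_z = FALSE))
  }
  x <- mk(1952, 174, 246)
  res <- combine_calls(x$ygs, x$depth)
  bd <- res$breakdown
  expect_equal(bd$n[bd$category == "union"], 2372)
  expect_equal(round(bd$pct[1:3], 1), c(82.3, 7.3, 10.4))
  expect_equal(sum(res$calls$final_label == "W"), 2372)

  y <- mk(0, 1, 1)
  bd2 <- combine_calls(y$ygs, y$depth)$breakdown
  expect_equal(bd2$pct[1:3], c(0, 50, 50))

  z <- mk(3, 0, 0)
  bd3 <- combine_calls(z$ygs, z$depth)$breakdown
  expect_equal(bd3$pct[1:3], c(100, 0, 0))

  bad_depth <- x$depth; bad_depth$scaffold_id[1] <- "nope"
  expect_error(combine_calls(x$ygs, bad_depth), "different scaffolds")
})

test_that("Z calls never overlap W and labels partition the scaffolds", {
  ygs <- data.frame(scaffold_id = c("a", "b", "c"),
                    w_call = c(TRUE, FALSE, FALSE))
  depth <- data.frame(scaffold_id = c("a", "b", "c"),
                      depth_w = c(TRUE, FALSE, FALSE),
                      depth_z = c(TRUE, TRUE, FALSE))
  calls <- combine_calls(ygs, depth)$calls
  expect_identical(calls$final_label, c("W", "Z", "AUTO_OTHER"))
  expect_identical(calls$flag, c("w_and_z_rules", "", ""))
  expect_equal(sum(table(calls$final_label)), 3)
})

test_that("individual sexing recognizes the marker depth patterns", {
  mk_summary <- function(w, z, a)
    data.frame(scaffold_id = c("wm", "zm", "am"),
               length = c(1, 1, 1), median_depth = c(w, z, a),
               covered_fraction = 1)
  markers <- list(w_marker = "wm", z_marker = "zm", auto_marker = "am")
  summaries <- list(f1 = mk_summary(5, 5, 10),
                    m1 = mk_summary(0, 10, 10),
                    odd = mk_summary(5, 10, 10))
  res <- verify_individual_sex(summaries, markers)
  expect_identical(res$inferred_sex, c("female", "male", "inconsistent"))
  expect_identical(res$consistent, c(TRUE, TRUE, FALSE))

  res2 <- verify_individual_sex(summaries, markers,
                                claimed_sex = c(f1 = "male", m1 = "male",
                                                odd = "female"))
  expect_identical(res2$consistent, c(FALSE, TRUE, FALSE))
  expect_error(verify_individual_sex(summaries,
                                     list(w_marker = "missing",
                                          z_marker = "zm",
                                          auto_marker = "am")),
               "missing")
})

test_that("final labels are invariant to a common depth scale factor", {
  with_seed_test(23, {
    lens <- c(auto = 1.2e5, z = 2e4, w = 2e4)
    mk_tracks <- function(mult) {
      male <- list(auto = rpois(lens[1], 60 * mult),
                   z = rpois(lens[2], 60 * mult),
                   w = integer(lens[3]))
      female <- list(auto = rpois(lens[1], 60 * mult),
                     z = rpois(lens[2], 30 * mult),
                     w = rpois(lens[3], 30 * mult))
      list(male = male, female = female)
    }
    labels_of <- function(tr) {
      summ <- combine_depth_summaries(
        scaffold_depth_summary(tr$male, lens),
        scaffold_depth_summary(tr$female, lens))
      pk <- estimate_depth_peaks(tr$male, tr$female)
      th <- derive_thresholds(pk)
      dw <- classify_w_by_depth(summ)
      dz <- classify_z_by_depth(summ, th)
      ifelse(dw, "W", ifelse(dz, "Z", "AUTO"))
    }
    l1 <- labels_of(mk_tracks(1))
    l3 <- labels_of(mk_tracks(3))
    expect_identical(l1, c("AUTO", "Z", "W"))
    expect_identical(l1, l3)
  })
})
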