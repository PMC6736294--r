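toy_catalog <- function(kmers, counts, k, source = "male_reads") {
  code <- encode_kmers(kmers, canonical = TRUE)
  o <- order(code)
  structure(list(k = as.integer(k), code = code[o], count = counts[o],
                 source = source), class = "kmer_catalog")
}

test_that("canonical k-mer counting matches hand enumeration", {
  c1 <- count_kmers(c(s1 = "ACGT"), k = 4)
  expect_identical(decode_kmers(c1$code, 4), "ACGT")  # own revcomp
  expect_equal(c1$count, 1)

  c2 <- count_kmers(c(s1 = "AAAA"), k = 2)
  expect_identical(decode_kmers(c2$code, 2), "AA")
  expect_equal(c2$count, 3)

  c3 <- count_kmers(c(s1 = "ACNGT"), k = 2)  # GT canonicalizes to AC; N skipped
  expect_identical(decode_kmers(c3$code, 2), "AC")
  expect_equal(c3$count, 2)

  expect_warning(count_kmers(c(s1 = "ACG"), k = 16), "shorter than k")
})

test_that("k-mer counting matches the substring-enumeration oracle", {
  with_seed_test(101, {
    for (k in c(2L, 5L, 16L)) {
      seqs <- vapply(1:6, function(i)
        paste(sample(c("A", "C", "G", "T", "N"), sample(30:120, 1), TRUE,
                     prob = c(0.24, 0.24, 0.24, 0.24, 0.04)),
              collapse = ""), character(1))
      names(seqs) <- paste0("s", 1:6)
      got <- count_kmers(seqs, k = k)
      exp <- oracle_kmer_count(seqs, k)
      expect_identical(decode_kmers(got$code, k), names(exp))
      expect_equal(got$count, unname(exp))
    }
  })
})

test_that("k-mer histogram sums to catalogue size and is additive", {
  h <- kmer_histogram(toy_catalog("AA", 3, 2))
  expect_equal(h, data.frame(multiplicity = 3, n_kmers = 1))

  a <- count_kmers(c(x = "AAAAAAAA"), k = 3)   # AAA x6
  b <- count_kmers(c(y = "CGCGCGCG"), k = 3)   # disjoint k-mers
  merged <- count_kmers(c(x = "AAAAAAAA", y = "CGCGCGCG"), k = 3)
  ha <- kmer_histogram(a); hb <- kmer_histogram(b); hm <- kmer_histogram(merged)
  expect_equal(sum(hm$n_kmers), length(merged$code))
  both <- merge(ha, hb, by = "multiplicity", all = TRUE)
  both[is.na(both)] <- 0
  expect_equal(hm[order(hm$multiplicity), ],
               data.frame(multiplicity = both$multiplicity,
                          n_kmers = both$n_kmers.x + both$n_kmers.y),
               ignore_attr = TRUE)
})

test_that("single-copy extraction keeps exactly count-1 assembly k-mers", {
  cat <- count_kmers(c(s1 = "ACGTT", s2 = "ACGAA"), k = 4,
                     source = "assembly")
  sc <- single_copy_kmers(cat)
  expect_setequal(decode_kmers(sc, 4),
                  setdiff(decode_kmers(cat$code, 4),
                          decode_kmers(cat$code[cat$count > 1], 4)))
  expect_error(single_copy_kmers(count_kmers("ACGT", 4,
                                             source = "male_reads")),
               "assembly")
})

test_that("a planted duplicated block removes its k-mers from single-copy", {
  with_seed_test(55, {
    core <- paste(sample(c("A", "C", "G", "T"), 3000, TRUE), collapse = "")
    dup <- substr(core, 1001, 2000)
    asm <- c(s1 = paste0(core, dup))   # block present twice
    sc <- single_copy_kmers(count_kmers(asm, k = 16, source = "assembly"))
    inside <- vapply(1:(1000 - 15), function(i)
      substr(dup, i, i + 15), character(1))
    expect_length(intersect(encode_kmers(inside), sc), 0)
  })
})

test_that("YGS scoring reproduces extremes and the strict 75% boundary", {
  # scaffold with 4 distinct single-copy k-mers, 3 of them hits
  scaffold <- "ACGTA"                      # k=4 windows: ACGT, CGTA
  asm_sc <- encode_kmers(c("ACGT", "CGTA"))
  asm_sc <- sort(asm_sc)
  male <- toy_catalog(c("ACGT"), c(5), 4)           # ACGT present in males
  female <- toy_catalog(c("ACGT", "CGTA"), c(5, 5), 4, "female_reads")
  r <- ygs_score(scaffold, "s", asm_sc, male, female, k = 4, min_kmers = 1)
  expect_equal(r$pct_unmatched_female_supported, 50)
  expect_false(r$w_call)

  # all scored k-mers hits -> 100%, called
  male0 <- toy_catalog("AAAA", 1, 4)
  r <- ygs_score(scaffold, "s", asm_sc, male0, female, k = 4, min_kmers = 1)
  expect_equal(r$pct_unmatched_female_supported, 100)
  expect_true(r$w_call)

  # exactly 75% is NOT called (strict >): 4 scored k-mers, 3 hits
  scaffold4 <- with_seed_test(5, paste(sample(c("A", "C", "G", "T"), 30,
                                              TRUE), collapse = ""))
  all_kms <- decode_kmers(count_kmers(c(x = scaffold4), 4)$code, 4)
  kms <- all_kms[1:4]
  sc_codes <- sort(encode_kmers(kms))
  male1 <- toy_catalog(kms[1], 9, 4)
  femaleAll <- toy_catalog(kms, rep(9, 4), 4, "female_reads")
  r <- ygs_score(scaffold4, "s", sc_codes, male1, femaleAll, k = 4,
                 min_kmers = 1)
  expect_equal(r$pct_unmatched_female_supported, 75)
  expect_false(r$w_call)

  # too-short scaffold is flagged, not called
  r <- ygs_score("ACG", "tiny", sc_codes, male1, femaleAll, k = 4)
  expect_false(r$w_call)
  expect_identical(r$flag, "shorter_than_k")
  expect_equal(r$n_valid_single_copy, 0L)
})

test_that("YGS scoring matches brute-force enumeration on toys", {
  with_seed_test(77, {
    for (rep in 1:5) {
      asm <- setNames(vapply(1:3, function(i)
        paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = ""),
        character(1)), paste0("s", 1:3))
      reads_m <- vapply(1:30, function(i) {
        s <- asm[[sample(2, 1)]]       # males lack s3 ("W")
        a <- sample(nchar(s) - 11, 1); substr(s, a, a + 11)
      }, character(1))
      reads_f <- vapply(1:45, function(i) {
        s <- asm[[sample(3, 1)]]
        a <- sample(nchar(s) - 11, 1); substr(s, a, a + 11)
      }, character(1))
      k <- 4L
      cat_m <- count_kmers(reads_m, k, source = "male_reads")
      cat_f <- count_kmers(reads_f, k, source = "female_reads")
      sc <- single_copy_kmers(count_kmers(asm, k, source = "assembly"))
      for (id in names(asm)) {
        got <- ygs_score(asm[[id]], id, sc, cat_m, cat_f, k = k,
                         min_kmers = 1)
        exp <- oracle_ygs_pct(asm[[id]], asm, reads_m, reads_f, k)
        expect_equal(got$n_valid_single_copy, exp$n)
        expect_equal(got$pct_unmatched_female_supported, exp$pct)
      }
    }
  })
})

test_that("the scan is strand-invariant and monotone in its thresholds", {
  with_seed_test(88, {
    asm <- setNames(vapply(1:4, function(i)
      paste(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = ""),
      character(1)), paste0("s", 1:4))
    mk_reads <- function(ids, n) vapply(1:n, function(i) {
      s <- asm[[sample(ids, 1)]]
      a <- sample(nchar(s) - 29, 1); substr(s, a, a + 29)
    }, character(1))
    reads_m <- mk_reads(1:3, 300)     # s4 is female-limited
    reads_f <- mk_reads(1:4, 400)
    base <- kmer_scan_all(asm, reads_m, reads_f, k = 8, min_kmers = 10)
    flipped <- kmer_scan_all(reverse_complement(asm),
                             reverse_complement(reads_m),
                             reverse_complement(reads_f),
                             k = 8, min_kmers = 10)
    expect_equal(base, flipped)
    expect_true(base$w_call[base$scaffold_id == "s4"])
    expect_false(any(base$w_call[base$scaffold_id != "s4"]))

    strict <- kmer_scan_all(asm, reads_m, reads_f, k = 8, min_kmers = 10,
                            threshold_pct = 100)
    expect_true(all(strict$w_call <= base$w_call))
    expect_true(all(strict$w_call ==
                      (strict$pct_unmatched_female_supported == 100 &
                         strict$n_valid_single_copy >= 10)))
  })
})

test_that("an empty male read pool warns and calls everything supported", {
  with_seed_test(99, {
    asm <- c(s1 = paste(sample(c("A", "C", "G", "T"), 200, TRUE),
                        collapse = ""))
    reads_f <- vapply(1:60, function(i) {
      a <- sample(180, 1); substr(asm[[1]], a, a + 19)
    }, character(1))
    expect_warning(
      expect_warning(
        res <- kmer_scan_all(asm, character(0), reads_f, k = 6,
                             min_kmers = 5),
        "no k-mers"),
      "male")
    expect_true(res$w_call[1])
  })
})
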