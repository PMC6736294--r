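# Small configs keep these tests fast; statistical checks use wide
# (multi-sigma) bands around the configured generator parameters.

small_cfg <- function(...) {
  args <- list(seed = 5, autosome_length = 1.2e5, z_length = 6e4,
               w_length = 5e4, neo_length = 1e5, neo_autosomal_head = 1e4,
               neo_autosomal_tail = 1.5e4, scaffold_length_mean = 2e4,
               scaffold_length_min = 4e3)
  over <- list(...)
  args[names(over)] <- over
  do.call(sim_config, args)
}

test_that("the generator is deterministic and validates its config", {
  cfg <- small_cfg()
  s1 <- simulate_genome(cfg)
  s2 <- simulate_genome(cfg)
  expect_identical(s1, s2)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_fasta(s1$scaffolds, f1)
  write_fasta(s2$scaffolds, f2)
  expect_identical(readLines(f1), readLines(f2))

  expect_error(sim_config(neo_length = 1e5, neo_autosomal_head = 6e4,
                          neo_autosomal_tail = 6e4))
  expect_error(sim_config(strata_identities = c(0.9, 0.95)))
  expect_error(sim_config(read_error_rate = 2))
})

test_that("a degenerate config without W and neo yields only AUTO and Z", {
  cfg <- small_cfg(w_length = 0, neo_length = 0)
  sim <- simulate_genome(cfg)
  expect_setequal(unique(sim$truth$scaffolds$label), c("AUTO", "Z"))
})

test_that("scaffold records tile their source chromosomes exactly", {
  sim <- simulate_genome(small_cfg())
  st <- sim$truth$scaffolds
  expect_equal(st$source_end - st$source_start, st$length)
  expect_equal(nchar(sim$scaffolds), setNames(st$length, st$scaffold_id))
  expect_gte(min(st$length), 4e3)
  # within a (chromosome, label, copy) group, scaffolds are disjoint and
  # ordered (NEO_AUTO legitimately splits into a head and a tail block)
  grp <- paste(st$source_chrom, st$label, ifelse(is.na(st$copy), "", st$copy))
  for (g in unique(grp)) {
    iv <- st[grp == g, ]
    iv <- iv[order(iv$source_start), ]
    expect_true(nrow(iv) == 1 ||
                  all(iv$source_start[-1] >= head(iv$source_end, -1)))
  }
  cfg <- sim$truth$config
  mid <- cfg$neo_length - cfg$neo_autosomal_head - cfg$neo_autosomal_tail
  expect_equal(sum(st$length[st$source_chrom == "chr1A"]),
               cfg$neo_length + mid)
  expect_equal(sum(st$length[st$source_chrom == "chrZ"]), cfg$z_length)
})

test_that("neo-W/neo-Z identity matches the strata at non-repeat sites", {
  cfg <- small_cfg(strata_identities = c(1.0, 0.9),
                   neo_length = 2.2e5, neo_autosomal_head = 5e3,
                   neo_autosomal_tail = 1.5e4)
  sim <- simulate_genome(cfg)
  neo <- sim$truth$neo
  zc <- strsplit(neo$neo_z_mid, "")[[1]]
  wc <- strsplit(neo$neo_w_mid, "")[[1]]
  in_rep <- logical(length(zc))
  for (r in seq_len(nrow(neo$w_repeats)))
    in_rep[(neo$w_repeats$start[r] + 1):neo$w_repeats$end[r]] <- TRUE
  for (i in seq_len(nrow(sim$truth$strata))) {
    s <- sim$truth$strata[i, ]
    span <- (s$mid_start + 1):s$mid_end
    span <- span[!in_rep[span]]
    expect_lt(abs(mean(zc[span] == wc[span]) - s$identity), 0.01)
  }
})

test_that("male read sets carry no W material; error-free reads are exact", {
  cfg <- small_cfg(read_error_rate = 0)
  sim <- simulate_genome(cfg)
  rm_ <- simulate_reads(sim$scaffolds, sim$truth, "male", cfg)
  origin <- sub(":.*", "", names(rm_))
  w_ids <- sim$truth$scaffolds$scaffold_id[
    sim$truth$scaffolds$label %in% c("W", "NEO_W")]
  expect_length(intersect(origin, w_ids), 0)

  idx <- sample(length(rm_), 200)
  meta <- strsplit(names(rm_)[idx], ":")
  ok <- vapply(seq_along(idx), function(j) {
    m <- meta[[j]]
    src <- substr(sim$scaffolds[[m[1]]], as.integer(m[2]) + 1,
                  as.integer(m[2]) + nchar(rm_[idx[j]]))
    if (m[3] == "-") src <- reverse_complement(src)
    identical(unname(rm_[idx[j]]), src)
  }, logical(1))
  expect_true(all(ok))
})

test_that("female read depth on W scaffolds is half the autosomal depth", {
  cfg <- small_cfg(per_sex_diploid_depth = 20)
  sim <- simulate_genome(cfg)
  rf_ <- simulate_reads(sim$scaffolds, sim$truth, "female", cfg)
  st <- sim$truth$scaffolds
  origin <- sub(":.*", "", names(rf_))
  depth_of <- function(labels) {
    ids <- st$scaffold_id[st$label %in% labels]
    nr <- sum(origin %in% ids)
    nr * cfg$read_length / sum(st$length[st$label %in% labels])
  }
  d_auto <- depth_of("AUTO")
  d_w <- depth_of(c("W", "NEO_W"))
  # Poisson standard errors here are ~0.1-0.3x; 1x bands are >3 sigma
  expect_lt(abs(d_auto - 20), 1)
  expect_lt(abs(d_w - 10), 1)
  expect_gt(d_auto / d_w, 1.7)
  expect_lt(d_auto / d_w, 2.3)
})

test_that("depth tracks obey ploidy, dropout and the Poisson regime", {
  cfg <- small_cfg(per_sex_diploid_depth = 80)
  sim <- simulate_genome(cfg)
  st <- sim$truth$scaffolds
  tm <- simulate_depth_tracks(sim$truth, cfg, "male")
  tf <- simulate_depth_tracks(sim$truth, cfg, "female")
  w_ids <- st$scaffold_id[st$label %in% c("W", "NEO_W")]
  expect_true(all(vapply(w_ids, function(id) all(tm[[id]] == 0L),
                         logical(1))))
  auto_ids <- st$scaffold_id[st$label == "AUTO"]
  med <- median(unlist(tf[auto_ids]))
  expect_lte(abs(med - 80), 3)

  # dropout 0 zeroes repeat intervals, leaves the rest nominal
  cfg0 <- small_cfg(repeat_dropout = 0)
  sim0 <- simulate_genome(cfg0)
  t0 <- simulate_depth_tracks(sim0$truth, cfg0, "female")
  reps <- sim0$truth$repeats
  one <- reps[1, ]
  inside <- t0[[one$scaffold_id]][(one$start + 1):one$end]
  expect_true(all(inside == 0L))
  expect_gt(mean(t0[[one$scaffold_id]] > 0), 0.3)
})

test_that("anchor tables reproduce the double-anchoring signal", {
  sim <- simulate_genome(small_cfg())
  st <- sim$truth$scaffolds
  anchors <- make_anchor_table(sim$truth)
  expect_false(anyDuplicated(anchors[, c("ref_chrom", "order_index")]) > 0)
  on_1a <- anchors$scaffold_id[anchors$ref_chrom == "ref1A"]
  len_1a <- sum(st$length[match(on_1a, st$scaffold_id)])
  cfg <- sim$truth$config
  mid <- cfg$neo_length - cfg$neo_autosomal_head - cfg$neo_autosomal_tail
  expect_equal(len_1a, cfg$neo_length + mid)

  # first scaffold of an autosome gets order_index 1 on its reference
  first_a1 <- st$scaffold_id[st$source_chrom == "chrA1" &
                               st$source_start == 0]
  expect_equal(anchors$order_index[anchors$scaffold_id == first_a1], 1L)

  # no neo block -> no ref1A rows at all
  sim0 <- simulate_genome(small_cfg(neo_length = 0))
  expect_false("ref1A" %in% make_anchor_table(sim0$truth)$ref_chrom)
})

test_that("gametolog simulation is deterministic, stop-free and inert at
           zero divergence", {
  cfg <- small_cfg(n_gametolog_genes = 6, codons_per_gene = 40)
  g1 <- simulate_gametologs(cfg)
  g2 <- simulate_gametologs(cfg)
  expect_identical(g1, g2)
  for (s in g1$cds) expect_no_error(translate_cds(s))

  cfg0 <- small_cfg(n_gametolog_genes = 4, codons_per_gene = 30,
                    zw_divergence = 0, outgroup_divergence = 0)
  g0 <- simulate_gametologs(cfg0)
  expect_identical(unname(g0$cds[g0$pairs$z_id]),
                   unname(g0$cds[g0$pairs$w_id]))
  expect_identical(unname(g0$cds[g0$pairs$z_id]),
                   unname(g0$cds[g0$pairs$outgroup_id]))
})
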