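# Synthetic female (ZW) genome generator.
#
# Emulates the data structure the classifiers assume: a female-limited W,
# a Z at haploid female / diploid male depth, and a neo-sex chromosome --
# an ex-autosome ("chr1A") whose middle block exists as two diverged
# copies (neo-Z, neo-W) while its terminal head/tail keep recombining and
# behave autosomally. Repeats are length-preserving overwrites from a
# small fixed motif library; neo-W/neo-Z divergence follows configurable
# identity strata with no indels, so truth orthology is positional.

REPEAT_MOTIF_SEED <- 104729
BASES <- c("A", "C", "G", "T")

#' Simulation configuration
#'
#' Defaults define a desk-scale (~5.3 Mb) study: two 1.8-Mb autosomes, a
#' 0.35-Mb Z, a 0.25-Mb W, and a 0.6-Mb neo chromosome whose first 25 kb
#' and last 35 kb stay autosomal; pooled diploid depth 60x per sex;
#' identity strata 100/98/95/92%; repeat fractions 36.6% on W/neo-W and
#' 10% elsewhere. As in real genomes, autosomes carry most of the
#' sequence, so the pooled depth histogram peaks at the diploid level.
#'
#' @param seed Integer seed; every generator output is deterministic in it.
#' @param n_autosomes,autosome_length Number and length (bp) of autosomes.
#' @param z_length,w_length Z and W chromosome lengths (bp); `w_length`
#'   may be 0 (no W).
#' @param neo_length Length (bp) of the ancestral ex-autosomal chromosome;
#'   may be 0 (no neo system).
#' @param neo_autosomal_head,neo_autosomal_tail Terminal spans (bp) of the
#'   neo chromosome that remain autosomally inherited (single copy).
#' @param scaffold_length_mean,scaffold_length_min Scaffold fragmentation:
#'   geometric-like lengths with this mean, truncated below at the minimum.
#' @param per_sex_diploid_depth Target pooled diploid read depth per sex.
#' @param n_females,n_males Individuals per sex pool.
#' @param read_length,read_error_rate Simulated read length (bp) and
#'   per-base substitution error probability.
#' @param w_repeat_fraction,other_repeat_fraction Proportion of W/neo-W
#'   (resp. all other) sequence overwritten with repeat motifs.
#' @param repeat_dropout Mappability factor applied to simulated depth
#'   inside repeat intervals (models lost multi-mapped reads; default 0.5).
#' @param strata_identities Non-increasing neo-Z/neo-W per-base identities,
#'   one per stratum (equal-length blocks along the diverged middle).
#' @param n_gametolog_genes,codons_per_gene Gametolog CDS set size.
#' @param w_omega_multiplier Factor (> 0) on the nonsynonymous acceptance
#'   probability of the W gene copies.
#' @param zw_divergence Per-branch substitution proposal rate per site for
#'   the Z and W copies.
#' @param outgroup_divergence Proposal rate per site for the outgroup copy.
#' @param base_ns_accept Baseline acceptance probability of nonsynonymous
#'   changes (purifying selection; synonymous changes always accepted).
#' @return Validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_autosomes = 2L,
                       autosome_length = 1.8e6,
                       z_length = 3.5e5,
                       w_length = 2.5e5,
                       neo_length = 6e5,
                       neo_autosomal_head = 2.5e4,
                       neo_autosomal_tail = 3.5e4,
                       scaffold_length_mean = 5e4,
                       scaffold_length_min = 5e3,
                       per_sex_diploid_depth = 60,
                       n_females = 10L,
                       n_males = 9L,
                       read_length = 100L,
                       read_error_rate = 0.001,
                       w_repeat_fraction = 0.366,
                       other_repeat_fraction = 0.10,
                       repeat_dropout = 0.5,
                       strata_identities = c(1.00, 0.98, 0.95, 0.92),
                       n_gametolog_genes = 150L,
                       codons_per_gene = 300L,
                       w_omega_multiplier = 5,
                       zw_divergence = 0.04,
                       outgroup_divergence = 0.10,
                       base_ns_accept = 0.2) {
  cfg <- list(seed = as.integer(seed), n_autosomes = as.integer(n_autosomes),
              autosome_length = autosome_length, z_length = z_length,
              w_length = w_length, neo_length = neo_length,
              neo_autosomal_head = neo_autosomal_head,
              neo_autosomal_tail = neo_autosomal_tail,
              scaffold_length_mean = scaffold_length_mean,
              scaffold_length_min = scaffold_length_min,
              per_sex_diploid_depth = per_sex_diploid_depth,
              n_females = as.integer(n_females), n_males = as.integer(n_males),
              read_length = as.integer(read_length),
              read_error_rate = read_error_rate,
              w_repeat_fraction = w_repeat_fraction,
              other_repeat_fraction = other_repeat_fraction,
              repeat_dropout = repeat_dropout,
              strata_identities = strata_identities,
              n_gametolog_genes = as.integer(n_gametolog_genes),
              codons_per_gene = as.integer(codons_per_gene),
              w_omega_multiplier = w_omega_multiplier,
              zw_divergence = zw_divergence,
              outgroup_divergence = outgroup_divergence,
              base_ns_accept = base_ns_accept)
  with(cfg, {
    stopifnot(n_autosomes >= 1, autosome_length > 0, z_length > 0,
              w_length >= 0, neo_length >= 0,
              scaffold_length_min > 0,
              scaffold_length_mean >= scaffold_length_min,
              per_sex_diploid_depth > 0, n_females >= 1, n_males >= 1,
              read_length >= 20, read_error_rate >= 0, read_error_rate <= 1,
              w_repeat_fraction >= 0, w_repeat_fraction <= 1,
              other_repeat_fraction >= 0, other_repeat_fraction <= 1,
              repeat_dropout >= 0, repeat_dropout <= 1,
              all(strata_identities >= 0), all(strata_identities <= 1),
              all(diff(strata_identities) <= 0),
              n_gametolog_genes >= 1, codons_per_gene >= 10,
              w_omega_multiplier > 0, zw_divergence >= 0,
              outgroup_divergence >= 0,
              base_ns_accept > 0, base_ns_accept <= 1)
    if (neo_length > 0)
      stopifnot(neo_autosomal_head >= 0, neo_autosomal_tail >= 0,
                neo_autosomal_head + neo_autosomal_tail < neo_length)
  })
  structure(cfg, class = "sim_config")
}

# Fixed library of three 500-bp repeat motifs (constant across configs).
repeat_motifs <- function() {
  with_seed(REPEAT_MOTIF_SEED, random_dna(c(500, 500, 500)))
}

# Build a chromosome as a character vector of bases with `fraction` of its
# 500-bp slots overwritten by repeat motifs. Returns chars + repeat
# intervals (0-based half-open).
build_chrom_chars <- function(len, fraction, motifs) {
  chars <- sample(BASES, len, replace = TRUE)
  slot <- 500L
  n_slots <- len %/% slot
  n_rep <- min(n_slots, round(fraction * len / slot))
  rep_iv <- data.frame(start = integer(0), end = integer(0))
  if (n_rep > 0) {
    slots <- sort(sample.int(n_slots, n_rep))
    motif_chars <- lapply(motifs, function(m) strsplit(m, "")[[1]])
    picks <- sample.int(length(motifs), n_rep, replace = TRUE)
    for (i in seq_len(n_rep)) {
      a <- (slots[i] - 1L) * slot            # 0-based start
      chars[(a + 1L):(a + slot)] <- motif_chars[[picks[i]]]
    }
    rep_iv <- data.frame(start = (slots - 1L) * slot,
                         end = (slots - 1L) * slot + slot)
  }
  list(chars = chars, repeats = rep_iv)
}

# Intersect repeat intervals with [from, to) and shift to interval-local
# 0-based coordinates.
clip_intervals <- function(iv, from, to) {
  if (!nrow(iv)) return(iv)
  s <- pmax(iv$start, from)
  e <- pmin(iv$end, to)
  keep <- s < e
  data.frame(start = s[keep] - from, end = e[keep] - from)
}

# Geometric-like fragmentation of [0, len) into pieces with the configured
# mean, truncated below at the minimum; a short final remainder is merged
# into the previous piece.
fragment_lengths <- function(len, mean_len, min_len) {
  if (len <= min_len * 2) return(len)
  p <- 1 / max(1, mean_len - min_len + 1)
  out <- numeric(0)
  left <- len
  while (left > 0) {
    piece <- min(left, min_len + stats::rgeom(1, p))
    out <- c(out, piece)
    left <- left - piece
  }
  if (length(out) > 1 && tail(out, 1) < min_len) {
    out[length(out) - 1] <- out[length(out) - 1] + tail(out, 1)
    out <- head(out, -1)
  }
  out
}

#' Simulate a female (ZW) genome with truth labels
#'
#' Builds autosomes, Z, W and a neo chromosome whose middle exists as
#' diverged neo-Z and neo-W copies (identity per stratum from
#' `strata_identities`, no indels) while head/tail stay single-copy;
#' overwrites repeat motifs at the configured fractions (extra neo-W
#' repeats are placed outside the positions used to realize strata
#' identity, which is defined over non-repeat sites); fragments everything
#' into scaffolds and shuffles their order. Deterministic in
#' `config$seed`.
#'
#' @param config A `sim_config`.
#' @return List with `scaffolds` (named character vector) and `truth`
#'   (scaffold table with labels/source coordinates, per-scaffold repeat
#'   intervals, strata map, the neo-Z/neo-W middle sequences, and the
#'   config).
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  motifs <- repeat_motifs()
  with_seed(config$seed, {
    sources <- list()   # each: id-prefix-free record with seq chars etc.
    add_source <- function(label, chrom, copy, seq_chars, repeats,
                           offset = 0) {
      sources[[length(sources) + 1L]] <<-
        list(label = label, chrom = chrom, copy = copy, chars = seq_chars,
             repeats = repeats, offset = offset)
    }

    for (i in seq_len(config$n_autosomes)) {
      b <- build_chrom_chars(config$autosome_length,
                             config$other_repeat_fraction, motifs)
      add_source("AUTO", paste0("chrA", i), NA, b$chars, b$repeats)
    }
    bz <- build_chrom_chars(config$z_length, config$other_repeat_fraction,
                            motifs)
    add_source("Z", "chrZ", "Z", bz$chars, bz$repeats)
    if (config$w_length > 0) {
      bw <- build_chrom_chars(config$w_length, config$w_repeat_fraction,
                              motifs)
      add_source("W", "chrW", "W", bw$chars, bw$repeats)
    }

    strata_map <- NULL
    neo_seqs <- NULL
    if (config$neo_length > 0) {
      L <- config$neo_length
      h <- config$neo_autosomal_head
      t <- config$neo_autosomal_tail
      banc <- build_chrom_chars(L, config$other_repeat_fraction, motifs)
      if (h > 0)
        add_source("NEO_AUTO", "chr1A", NA, banc$chars[1:h],
                   clip_intervals(banc$repeats, 0, h))
      if (t > 0)
        add_source("NEO_AUTO", "chr1A", NA, banc$chars[(L - t + 1):L],
                   clip_intervals(banc$repeats, L - t, L), offset = L - t)

      mid_len <- L - h - t
      z_chars <- banc$chars[(h + 1):(L - t)]
      z_reps <- clip_intervals(banc$repeats, h, L - t)   # mid-relative

      # neo-W: inherit mid, add extra repeat slots, then diverge per stratum
      w_chars <- z_chars
      extra_frac <- max(0, config$w_repeat_fraction -
                          config$other_repeat_fraction)
      slot <- 500L
      n_slots <- mid_len %/% slot
      slot_free <- vapply(seq_len(n_slots), function(s) {
        a <- (s - 1L) * slot
        !nrow(z_reps) || !any(z_reps$start < a + slot & z_reps$end > a)
      }, logical(1))
      free_slots <- which(slot_free)
      n_extra <- min(length(free_slots), round(extra_frac * mid_len / slot))
      w_extra <- data.frame(start = integer(0), end = integer(0))
      if (n_extra > 0) {
        picks <- sort(sample(free_slots, n_extra))
        motif_chars <- lapply(motifs, function(m) strsplit(m, "")[[1]])
        which_motif <- sample.int(length(motifs), n_extra, replace = TRUE)
        for (i in seq_len(n_extra)) {
          a <- (picks[i] - 1L) * slot
          w_chars[(a + 1L):(a + slot)] <- motif_chars[[which_motif[i]]]
        }
        w_extra <- data.frame(start = (picks - 1L) * slot,
                              end = (picks - 1L) * slot + slot)
      }
      w_reps <- rbind(z_reps, w_extra)
      w_reps <- w_reps[order(w_reps$start), , drop = FALSE]

      # strata divergence on non-repeat sites of the mid block
      n_strata <- length(config$strata_identities)
      bounds <- round(seq(0, mid_len, length.out = n_strata + 1))
      in_repeat <- logical(mid_len)
      for (r in seq_len(nrow(w_reps)))
        in_repeat[(w_reps$start[r] + 1L):w_reps$end[r]] <- TRUE
      strata_map <- data.frame(
        stratum = seq_len(n_strata),
        mid_start = bounds[-(n_strata + 1)], mid_end = bounds[-1],
        anc_start = h + bounds[-(n_strata + 1)], anc_end = h + bounds[-1],
        identity = config$strata_identities)
      for (s in seq_len(n_strata)) {
        rate <- 1 - config$strata_identities[s]
        if (rate <= 0) next
        span <- (bounds[s] + 1L):bounds[s + 1]
        eligible <- span[!in_repeat[span]]
        n_sub <- rbinom(1, length(eligible), rate)
        if (n_sub == 0) next
        pos <- sample(eligible, n_sub)
        cur <- w_chars[pos]
        sub <- sample(BASES, n_sub, replace = TRUE)
        clash <- sub == cur
        while (any(clash)) {
          sub[clash] <- sample(BASES, sum(clash), replace = TRUE)
          clash <- sub == cur
        }
        w_chars[pos] <- sub
      }
      add_source("NEO_Z", "chr1A", "Z", z_chars, z_reps, offset = h)
      add_source("NEO_W", "chr1A", "W", w_chars, w_reps, offset = h)
      neo_seqs <- list(neo_z_mid = paste(z_chars, collapse = ""),
                       neo_w_mid = paste(w_chars, collapse = ""),
                       mid_offset = h,
                       z_repeats = z_reps, w_repeats = w_reps)
    }

    # fragment every source into scaffolds
    recs <- list()
    for (src in sources) {
      lens <- fragment_lengths(length(src$chars),
                               config$scaffold_length_mean,
                               config$scaffold_length_min)
      starts <- cumsum(c(0, head(lens, -1)))
      for (j in seq_along(lens)) {
        a <- starts[j]; b <- a + lens[j]
        recs[[length(recs) + 1L]] <- list(
          label = src$label, chrom = src$chrom, copy = src$copy,
          source_start = src$offset + a, source_end = src$offset + b,
          seq = paste(src$chars[(a + 1):b], collapse = ""),
          repeats = clip_intervals(src$repeats, a, b))
      }
    }
    recs <- recs[sample.int(length(recs))]
    ids <- sprintf("scf%05d", seq_along(recs))

    scaffolds <- setNames(vapply(recs, `[[`, character(1), "seq"), ids)
    truth_scaffolds <- data.frame(
      scaffold_id = ids,
      label = vapply(recs, `[[`, character(1), "label"),
      source_chrom = vapply(recs, `[[`, character(1), "chrom"),
      copy = vapply(recs, function(r)
        if (is.na(r$copy[1])) NA_character_ else r$copy, character(1)),
      source_start = vapply(recs, `[[`, numeric(1), "source_start"),
      source_end = vapply(recs, `[[`, numeric(1), "source_end"),
      length = nchar(scaffolds),
      row.names = NULL, stringsAsFactors = FALSE)
    repeat_rows <- lapply(seq_along(recs), function(i) {
      iv <- recs[[i]]$repeats
      if (!nrow(iv)) return(NULL)
      data.frame(scaffold_id = ids[i], start = iv$start, end = iv$end,
                 stringsAsFactors = FALSE)
    })
    truth <- list(scaffolds = truth_scaffolds,
                  repeats = do.call(rbind, repeat_rows),
                  strata = strata_map,
                  neo = neo_seqs,
                  config = config)
    list(scaffolds = scaffolds, truth = truth)
  })
}

# Chromosome copies carried per scaffold label for each sex.
copies_for_sex <- function(labels, sex) {
  stopifnot(sex %in% c("male", "female"))
  if (sex == "female") {
    c(AUTO = 2, NEO_AUTO = 2, Z = 1, NEO_Z = 1, W = 1, NEO_W = 1)[labels]
  } else {
    c(AUTO = 2, NEO_AUTO = 2, Z = 2, NEO_Z = 2, W = 0, NEO_W = 0)[labels]
  }
}

#' Simulate sex-pooled short reads
#'
#' Reads are sampled uniformly from the sex's chromosome complement:
#' females carry diploid autosomes plus one Z, one W, one neo-Z and one
#' neo-W; males carry diploid autosomes and two Z / neo-Z and no W. The
#' per-copy sampling rate is `per_sex_diploid_depth / 2`. Read names
#' encode the true origin as scaffold:start0:strand:serial.
#'
#' @param scaffolds Scaffold set from [simulate_genome()].
#' @param truth Matching truth object.
#' @param sex "male" or "female".
#' @param config The `sim_config` used for the genome.
#' @return Named character vector of read sequences.
#' @export
simulate_reads <- function(scaffolds, truth, sex, config) {
  sex <- match.arg(sex, c("male", "female"))
  st <- truth$scaffolds
  stopifnot(identical(st$scaffold_id, names(scaffolds)))
  rl <- config$read_length
  copies <- copies_for_sex(st$label, sex)
  with_seed(config$seed + if (sex == "female") 113L else 211L, {
    parts <- vector("list", nrow(st))
    for (i in seq_len(nrow(st))) {
      len <- st$length[i]
      if (copies[i] == 0 || len < rl) next
      lambda <- copies[i] * config$per_sex_diploid_depth / 2 * len / rl
      n <- rpois(1, lambda)
      if (n == 0) next
      starts <- sample.int(len - rl + 1L, n, replace = TRUE)
      seqs <- substring(scaffolds[[i]], starts, starts + rl - 1L)
      minus <- runif(n) < 0.5
      if (any(minus)) seqs[minus] <- revcomp_cpp(seqs[minus])
      names(seqs) <- paste0(st$scaffold_id[i], ":", starts - 1L, ":",
                            ifelse(minus, "-", "+"), ":", seq_len(n))
      parts[[i]] <- seqs
    }
    reads <- unlist(parts)
    if (is.null(reads)) reads <- setNames(character(0), character(0))
    mutate_seqs_cpp(reads, config$read_error_rate)
  })
}

#' Simulate per-base depth tracks
#'
#' Per-base depth is Poisson with mean `depth x copies / 2` for the sex's
#' copy number, multiplied by `repeat_dropout` inside repeat intervals
#' (mimicking multi-mapping loss). Deterministic in the seed.
#'
#' @param truth Truth object from [simulate_genome()].
#' @param config The `sim_config`.
#' @param sex "male" or "female".
#' @param depth Pooled diploid depth; defaults to
#'   `config$per_sex_diploid_depth` (set to ~10 for a single individual).
#' @param seed Seed; defaults to a sex-specific offset of `config$seed`.
#' @return Depth track: named list of per-base integer vectors.
#' @export
simulate_depth_tracks <- function(truth, config, sex, depth = NULL,
                                  seed = NULL) {
  sex <- match.arg(sex, c("male", "female"))
  st <- truth$scaffolds
  if (is.null(depth)) depth <- config$per_sex_diploid_depth
  if (is.null(seed))
    seed <- config$seed + if (sex == "female") 311L else 523L
  copies <- copies_for_sex(st$label, sex)
  reps <- truth$repeats
  with_seed(seed, {
    track <- vector("list", nrow(st))
    names(track) <- st$scaffold_id
    for (i in seq_len(nrow(st))) {
      len <- st$length[i]
      mu <- rep(depth * copies[i] / 2, len)
      if (!is.null(reps)) {
        iv <- reps[reps$scaffold_id == st$scaffold_id[i], , drop = FALSE]
        for (r in seq_len(nrow(iv)))
          mu[(iv$start[r] + 1L):iv$end[r]] <-
            mu[(iv$start[r] + 1L):iv$end[r]] * config$repeat_dropout
      }
      track[[i]] <- rpois(len, mu)
    }
    track
  })
}

#' Truth-based anchoring table
#'
#' Scaffolds are ordered along their true source chromosome ("refA1", ...,
#' "refZ", "refW", "ref1A"); neo-Z and neo-W scaffolds both anchor to
#' "ref1A" (at the same ancestral coordinates, Z copy first on ties),
#' reproducing the double-anchoring signal of a fused neo-sex chromosome.
#'
#' @param truth Truth object from [simulate_genome()].
#' @return data.frame: scaffold_id, ref_chrom, order_index, strand.
#' @export
make_anchor_table <- function(truth) {
  st <- truth$scaffolds
  ref <- sub("^chr", "ref", st$source_chrom)
  copy_rank <- ifelse(!is.na(st$copy) & st$copy == "W", 1L, 0L)
  o <- order(ref, st$source_start, copy_rank)
  st <- st[o, ]; ref <- ref[o]
  order_index <- stats::ave(seq_along(ref), ref, FUN = seq_along)
  data.frame(scaffold_id = st$scaffold_id, ref_chrom = ref,
             order_index = as.integer(order_index), strand = "+",
             row.names = NULL, stringsAsFactors = FALSE)
}
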