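# Independent brute-force oracles used to cross-check the implementation.
# These deliberately avoid the package's own code paths (no 2-bit codes,
# no banded DP, no cached NG86 tables).

oracle_revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTacgt", "TGCAtgca", s), "")[[1]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Canonical k-mer counting by plain substring enumeration.
oracle_kmer_count <- function(seqs, k) {
  counts <- new.env(parent = emptyenv())
  for (s in seqs) {
    s <- toupper(s)
    n <- nchar(s)
    if (n < k) next
    for (i in seq_len(n - k + 1)) {
      w <- substr(s, i, i + k - 1)
      if (grepl("[^ACGT]", w)) next
      canon <- min(w, oracle_revcomp(w))
      counts[[canon]] <- (if (is.null(counts[[canon]])) 0 else counts[[canon]]) + 1
    }
  }
  out <- unlist(as.list(counts))
  if (is.null(out)) return(setNames(numeric(0), character(0)))
  out[order(names(out))]
}

# YGS percentage for one scaffold by direct enumeration.
oracle_ygs_pct <- function(scaffold, assembly_seqs, male_reads, female_reads,
                           k, min_read_count = 2) {
  asm <- oracle_kmer_count(assembly_seqs, k)
  males <- oracle_kmer_count(male_reads, k)
  females <- oracle_kmer_count(female_reads, k)
  sc_names <- names(asm)[asm == 1]
  scaffold_kmers <- unique(names(oracle_kmer_count(scaffold, k)))
  scored <- intersect(scaffold_kmers, sc_names)
  if (!length(scored)) return(list(n = 0L, pct = NA_real_))
  getc <- function(tab, w) if (w %in% names(tab)) tab[[w]] else 0
  hits <- vapply(scored, function(w)
    getc(males, w) < min_read_count && getc(females, w) >= min_read_count,
    logical(1))
  list(n = length(scored), pct = 100 * sum(hits) / length(scored))
}

oracle_n50 <- function(lens) {
  lens <- sort(lens, decreasing = TRUE)
  half <- sum(lens) / 2
  cum <- cumsum(lens)
  lens[which(cum >= half)[1]]
}

# All global alignments of a and b as pairs of gapped strings.
oracle_all_alignments <- function(a, b) {
  rec <- function(i, j) {
    if (i > nchar(a) && j > nchar(b)) return(list(c("", "")))
    out <- list()
    if (i <= nchar(a) && j <= nchar(b)) {
      for (al in rec(i + 1, j + 1))
        out[[length(out) + 1]] <- c(paste0(substr(a, i, i), al[1]),
                                    paste0(substr(b, j, j), al[2]))
    }
    if (i <= nchar(a)) {
      for (al in rec(i + 1, j))
        out[[length(out) + 1]] <- c(paste0(substr(a, i, i), al[1]),
                                    paste0("-", al[2]))
    }
    if (j <= nchar(b)) {
      for (al in rec(i, j + 1))
        out[[length(out) + 1]] <- c(paste0("-", al[1]),
                                    paste0(substr(b, j, j), al[2]))
    }
    out
  }
  rec(1, 1)
}

# Score a gapped alignment pair with affine gaps: a gap run of length L
# costs gap_open + L * gap_extend (matching the package convention).
oracle_alignment_score <- function(a1, a2, subst, gap_open, gap_extend) {
  c1 <- strsplit(a1, "")[[1]]
  c2 <- strsplit(a2, "")[[1]]
  score <- 0
  in_gap1 <- FALSE; in_gap2 <- FALSE
  for (i in seq_along(c1)) {
    if (c1[i] == "-") {
      score <- score - gap_extend - if (in_gap1) 0 else gap_open
      in_gap1 <- TRUE; in_gap2 <- FALSE
    } else if (c2[i] == "-") {
      score <- score - gap_extend - if (in_gap2) 0 else gap_open
      in_gap2 <- TRUE; in_gap1 <- FALSE
    } else {
      score <- score + subst(c1[i], c2[i])
      in_gap1 <- FALSE; in_gap2 <- FALSE
    }
  }
  score
}

oracle_best_alignment_score <- function(a, b, subst, gap_open, gap_extend) {
  max(vapply(oracle_all_alignments(a, b), function(al)
    oracle_alignment_score(al[1], al[2], subst, gap_open, gap_extend),
    numeric(1)))
}

# ---- independent NG86 ------------------------------------------------------

oracle_genetic_code <- function() {
  # derived through seqinr, an independent source of the standard code
  codons <- apply(expand.grid(c("t", "c", "a", "g"), c("t", "c", "a", "g"),
                              c("t", "c", "a", "g")), 1, paste, collapse = "")
  aa <- vapply(codons, function(cod)
    seqinr::translate(strsplit(cod, "")[[1]]), character(1))
  setNames(aa, toupper(chartr("t", "T", codons)))
}

oracle_ng86 <- function(codons1, codons2) {
  code <- oracle_genetic_code()
  stops <- names(code)[code == "*"]
  bases <- c("A", "C", "G", "T")
  syn_sites <- function(cod) {
    s <- 0
    for (p in 1:3) {
      for (b in setdiff(bases, substr(cod, p, p))) {
        alt <- cod
        substr(alt, p, p) <- b
        if (!(alt %in% stops) && code[[alt]] == code[[cod]]) s <- s + 1 / 3
      }
    }
    s
  }
  perms_of <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms_of(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  pair_diff <- function(c1, c2) {
    if (c1 == c2) return(c(0, 0))
    pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
    count_path <- function(ord, allow) {
      cur <- c1; sd <- 0; nd <- 0
      for (p in ord) {
        nxt <- cur
        substr(nxt, p, p) <- substr(c2, p, p)
        if (nxt %in% stops) {
          if (!allow) return(NULL)
          cur <- nxt
          next
        }
        if (!(cur %in% stops)) {
          if (code[[nxt]] == code[[cur]]) sd <- sd + 1 else nd <- nd + 1
        }
        cur <- nxt
      }
      c(sd, nd)
    }
    paths <- Filter(Negate(is.null),
                    lapply(perms_of(pos), count_path, allow = FALSE))
    if (!length(paths)) paths <- lapply(perms_of(pos), count_path, allow = TRUE)
    colMeans(do.call(rbind, paths))
  }
  S <- (sum(vapply(codons1, syn_sites, numeric(1))) +
        sum(vapply(codons2, syn_sites, numeric(1)))) / 2
  N <- 3 * length(codons1) - S
  d <- rowSums(vapply(seq_along(codons1), function(i)
    pair_diff(codons1[i], codons2[i]), numeric(2)))
  pS <- if (S > 0) d[1] / S else 0
  pN <- if (N > 0) d[2] / N else 0
  jc <- function(p) if (p < 0.75) -3 / 4 * log(1 - 4 / 3 * p) else NA_real_
  list(S = S, N = N, Sd = d[1], Nd = d[2], pS = pS, pN = pN,
       dS = jc(pS), dN = jc(pN))
}

# Exact one-sided signed-rank p by enumeration of all sign patterns.
oracle_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  ranks <- rank(abs(d))
  w_obs <- sum(ranks[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), n))
  ws <- as.matrix(signs) %*% ranks
  mean(ws >= w_obs - 1e-9)
}

# Random sense-codon CDS helpers for dN/dS tests.
random_codons <- function(n, code = oracle_genetic_code()) {
  sense <- names(code)[code != "*"]
  sample(sense, n, replace = TRUE)
}

# Seed scoping for tests (save/restore the caller's RNG state).
with_seed_test <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (has_old) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}
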