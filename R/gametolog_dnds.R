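# Gametolog dN/dS: translation, protein-guided codon alignment with
# gap/stop-column removal, NG86 (Nei-Gojobori 1986) counting with
# Jukes-Cantor correction, and a paired signed-rank comparison of W vs Z
# omegas.

#' Translate a coding sequence
#'
#' Standard genetic code; a terminal stop is stripped. An internal stop is
#' an error unless `permissive`, in which case the residue is masked as X.
#'
#' @param cds Nucleotide string, length divisible by 3.
#' @param permissive Mask internal stops instead of failing.
#' @return Protein string.
#' @examples
#' translate_cds("ATGAAATAA")  # "MK"
#' @export
translate_cds <- function(cds, permissive = FALSE) {
  n <- nchar(cds)
  if (n %% 3L != 0L)
    stop("CDS length (", n, ") not divisible by 3", call. = FALSE)
  codons <- substring(cds, seq(1, n, 3), seq(3, n, 3))
  aa <- codon_aa(codons)
  if (any(is.na(aa)))
    stop("untranslatable codon(s): ",
         paste(unique(codons[is.na(aa)]), collapse = ", "), call. = FALSE)
  if (length(aa) && aa[length(aa)] == "*") aa <- aa[-length(aa)]
  internal <- which(aa == "*")
  if (length(internal)) {
    if (!permissive)
      stop("internal stop codon at codon ", internal[1], call. = FALSE)
    aa[internal] <- "X"
  }
  paste(aa, collapse = "")
}

#' Global protein alignment
#'
#' Needleman-Wunsch with affine gaps via Biostrings (BLOSUM62 by default;
#' a gap run of length L costs `gap_open + L * gap_extend`).
#'
#' @param p1,p2 Protein strings.
#' @param substitution_matrix Matrix name or matrix (default "BLOSUM62").
#' @param gap_open,gap_extend Gap penalties (positive costs; defaults
#'   10 and 1).
#' @return List with `aligned1`, `aligned2` (gapped strings) and `score`.
#' @export
align_proteins <- function(p1, p2, substitution_matrix = "BLOSUM62",
                           gap_open = 10, gap_extend = 1) {
  stopifnot(nzchar(p1), nzchar(p2))
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(p1), Biostrings::AAString(p2),
    substitutionMatrix = substitution_matrix,
    gapOpening = gap_open, gapExtension = gap_extend, type = "global")
  list(aligned1 = as.character(Biostrings::alignedPattern(pa)),
       aligned2 = as.character(Biostrings::alignedSubject(pa)),
       score = Biostrings::score(pa))
}

#' Back-translate a protein alignment to a codon alignment
#'
#' Each aligned residue pair maps to its codon pair; columns containing a
#' gap in either sequence are dropped, as are columns where either codon
#' is a stop (the "-nogap" convention of codon-alignment tools).
#'
#' @param alignment Protein alignment from [align_proteins()].
#' @param cds1,cds2 The coding sequences whose translations were aligned.
#' @return List with `codons1`, `codons2` (character vectors of paired
#'   codons) and `n_codons`.
#' @export
backtranslate_codon_alignment <- function(alignment, cds1, cds2) {
  chars1 <- strsplit(alignment$aligned1, "")[[1]]
  chars2 <- strsplit(alignment$aligned2, "")[[1]]
  stopifnot(length(chars1) == length(chars2))
  codon_of <- function(cds) {
    n <- nchar(cds)
    substring(cds, seq(1, n, 3), seq(3, n, 3))
  }
  cod1 <- codon_of(cds1); cod2 <- codon_of(cds2)
  res1 <- gsub("-", "", alignment$aligned1, fixed = TRUE)
  res2 <- gsub("-", "", alignment$aligned2, fixed = TRUE)
  if (res1 != translate_cds(cds1, permissive = TRUE) ||
      res2 != translate_cds(cds2, permissive = TRUE))
    stop("alignment does not match the translations of the CDSs",
         call. = FALSE)
  i1 <- cumsum(chars1 != "-")
  i2 <- cumsum(chars2 != "-")
  keep <- chars1 != "-" & chars2 != "-"
  c1 <- cod1[i1[keep]]
  c2 <- cod2[i2[keep]]
  stops <- stop_codons()
  ok <- !(c1 %in% stops) & !(c2 %in% stops)
  list(codons1 = c1[ok], codons2 = c2[ok], n_codons = sum(ok))
}

# ---- NG86 tables -----------------------------------------------------------

# Cached environment for the NG86 lookup tables.
.ng86_cache <- new.env(parent = emptyenv())

all_codons <- function() {
  as.vector(outer(outer(BASES, BASES, function(a, b) paste0(b, a)),
                  BASES, function(ab, c) paste0(ab, c)))
}

# Synonymous site count per codon: at each position, (number of the 3
# possible single-base changes that are synonymous) / 3. Changes to stop
# codons are not synonymous, so S + N = 3 per codon exactly.
ng86_site_table <- function() {
  codons <- all_codons()
  syn <- setNames(numeric(length(codons)), codons)
  for (cod in codons) {
    aa <- codon_aa(cod)
    s <- 0
    for (pos in 1:3) {
      cur <- substr(cod, pos, pos)
      for (b in setdiff(BASES, cur)) {
        alt <- cod
        substr(alt, pos, pos) <- b
        if (!is.na(codon_aa(alt)) && codon_aa(alt) == aa &&
            codon_aa(alt) != "*") s <- s + 1 / 3
      }
    }
    syn[cod] <- s
  }
  syn
}

# Per ordered codon pair: observed synonymous/nonsynonymous differences,
# averaged over all minimal mutational pathways that avoid stop codons
# (stop endpoints never occur in codon alignments). If every pathway
# crosses a stop, steps entering a stop are skipped and the pair flagged.
ng86_pair_diff <- function(c1, c2) {
  if (c1 == c2) return(c(sd = 0, nd = 0, flag = 0))
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  perms <- switch(as.character(length(pos)),
                  "1" = list(pos),
                  "2" = list(pos, rev(pos)),
                  "3" = {
                    p <- pos
                    list(p, p[c(1, 3, 2)], p[c(2, 1, 3)],
                         p[c(2, 3, 1)], p[c(3, 1, 2)], p[c(3, 2, 1)])
                  })
  stops <- stop_codons()
  walk <- function(order, allow_stops) {
    cur <- c1
    sd <- 0; nd <- 0
    for (p in order) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (nxt %in% stops) {
        if (!allow_stops) return(NULL)
        cur <- nxt          # step skipped from the counts
        next
      }
      if (!(cur %in% stops)) {
        if (codon_aa(nxt) == codon_aa(cur)) sd <- sd + 1 else nd <- nd + 1
      }
      cur <- nxt
    }
    c(sd, nd)
  }
  paths <- Filter(Negate(is.null), lapply(perms, walk, allow_stops = FALSE))
  flag <- 0
  if (!length(paths)) {
    paths <- lapply(perms, walk, allow_stops = TRUE)
    flag <- 1
  }
  m <- do.call(rbind, paths)
  c(sd = mean(m[, 1]), nd = mean(m[, 2]), flag = flag)
}

ng86_tables <- function() {
  if (!is.null(.ng86_cache$tables)) return(.ng86_cache$tables)
  codons <- all_codons()
  sense <- setdiff(codons, stop_codons())
  syn_sites <- ng86_site_table()
  n <- length(sense)
  sd_tab <- matrix(0, n, n, dimnames = list(sense, sense))
  nd_tab <- matrix(0, n, n, dimnames = list(sense, sense))
  flag_tab <- matrix(0, n, n, dimnames = list(sense, sense))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      r <- ng86_pair_diff(sense[i], sense[j])
      sd_tab[i, j] <- r["sd"]
      nd_tab[i, j] <- r["nd"]
      flag_tab[i, j] <- r["flag"]
    }
  }
  .ng86_cache$tables <- list(syn_sites = syn_sites, sd = sd_tab,
                             nd = nd_tab, flag = flag_tab, sense = sense)
  .ng86_cache$tables
}

#' NG86 dN/dS for one codon alignment
#'
#' Nei-Gojobori (1986) counting: expected synonymous sites per codon are
#' the fraction of the three possible changes per position that are
#' synonymous, averaged between the two sequences; observed differences
#' are averaged over all minimal stop-free mutational pathways; pS and pN
#' are Jukes-Cantor corrected to dS and dN. omega (dN/dS) is NA-flagged
#' when dS is 0 or a proportion is at/above 3/4 (uncorrectable).
#'
#' @param codons1,codons2 Paired codon vectors (no gaps, no stops), e.g.
#'   from [backtranslate_codon_alignment()].
#' @param gene_id,copy Optional identifiers carried into the record.
#' @return One-row data.frame: gene_id, copy, n_codons, S_sites, N_sites,
#'   Sd, Nd, pS, pN, dS, dN, omega, flag.
#' @export
ng86_dnds <- function(codons1, codons2, gene_id = NA_character_,
                      copy = NA_character_) {
  stopifnot(length(codons1) == length(codons2), length(codons1) >= 1)
  tabs <- ng86_tables()
  if (any(!codons1 %in% tabs$sense) || any(!codons2 %in% tabs$sense))
    stop("codon alignment contains stop or invalid codons", call. = FALSE)
  n_codons <- length(codons1)
  s1 <- sum(tabs$syn_sites[codons1])
  s2 <- sum(tabs$syn_sites[codons2])
  S <- (s1 + s2) / 2
  N <- 3 * n_codons - S
  idx <- cbind(match(codons1, tabs$sense), match(codons2, tabs$sense))
  Sd <- sum(tabs$sd[idx])
  Nd <- sum(tabs$nd[idx])
  flagged_paths <- sum(tabs$flag[idx]) > 0
  pS <- if (S > 0) Sd / S else 0
  pN <- if (N > 0) Nd / N else 0
  jc <- function(p) if (p < 0.75) -3 / 4 * log(1 - 4 / 3 * p) else NA_real_
  dS <- jc(pS)
  dN <- jc(pN)
  flag <- character(0)
  if (flagged_paths) flag <- c(flag, "stop_crossing_paths")
  omega <- NA_real_
  if (is.na(dS) || is.na(dN)) {
    flag <- c(flag, "saturated")
  } else if (dS == 0) {
    flag <- c(flag, "dS_zero")
  } else {
    omega <- dN / dS
  }
  data.frame(gene_id = gene_id, copy = copy, n_codons = n_codons,
             S_sites = S, N_sites = N, Sd = Sd, Nd = Nd, pS = pS, pN = pN,
             dS = dS, dN = dN, omega = omega,
             flag = paste(flag, collapse = ";"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' dN/dS records for a gametolog pair table
#'
#' For each gene, the Z copy and the W copy are each aligned to the
#' outgroup reference at the protein level, back-translated to codon
#' alignments (gap and stop columns dropped), and scored with
#' [ng86_dnds()].
#'
#' @param cds Named character vector of coding sequences.
#' @param pairs data.frame with gene_id, z_id, w_id, outgroup_id.
#' @return data.frame of per-copy records (two rows per gene).
#' @export
gametolog_dnds <- function(cds, pairs) {
  need <- c("gene_id", "z_id", "w_id", "outgroup_id")
  stopifnot(all(need %in% names(pairs)))
  missing <- setdiff(unique(c(pairs$z_id, pairs$w_id, pairs$outgroup_id)),
                     names(cds))
  if (length(missing))
    stop("CDS set missing sequence(s): ",
         paste(head(missing, 5), collapse = ", "), call. = FALSE)
  rows <- list()
  for (i in seq_len(nrow(pairs))) {
    out_cds <- cds[[pairs$outgroup_id[i]]]
    out_prot <- translate_cds(out_cds)
    for (copy in c("Z", "W")) {
      focal_cds <- cds[[if (copy == "Z") pairs$z_id[i] else pairs$w_id[i]]]
      aln <- align_proteins(translate_cds(focal_cds), out_prot)
      ca <- backtranslate_codon_alignment(aln, focal_cds, out_cds)
      rows[[length(rows) + 1L]] <-
        ng86_dnds(ca$codons1, ca$codons2, gene_id = pairs$gene_id[i],
                  copy = copy)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Exact null distribution tail P(W+ >= w_obs) of the signed-rank statistic
# for the given (possibly tied, averaged) ranks, by dynamic programming
# over doubled ranks.
signed_rank_exact_p <- function(ranks, w_obs) {
  r2 <- as.integer(round(2 * ranks))
  total <- sum(r2)
  f <- numeric(total + 1)
  f[1] <- 1
  for (r in r2) {
    g <- f
    g[(r + 1):(total + 1)] <- g[(r + 1):(total + 1)] + f[1:(total + 1 - r)]
    f <- g
  }
  w2 <- round(2 * w_obs)
  sum(f[(w2 + 1):(total + 1)]) / 2^length(r2)
}

#' Paired signed-rank test of W vs Z omegas
#'
#' Wilcoxon signed-rank on the per-gene differences omega_W - omega_Z
#' (zeros dropped, average ranks for ties); one-sided alternative
#' omega_W > omega_Z by default. Exact null enumeration for n <= 25
#' usable pairs, normal approximation with continuity and tie correction
#' otherwise. Pairs with an undefined omega are excluded and counted.
#'
#' @param records Record table from [gametolog_dnds()].
#' @param alternative "greater" (default) or "two.sided".
#' @return List of class `paired_test`: n_pairs, n_used, n_excluded,
#'   n_w_greater, statistic, p_value, method.
#' @export
paired_gametolog_test <- function(records,
                                  alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  wz <- merge(records[records$copy == "W", c("gene_id", "omega")],
              records[records$copy == "Z", c("gene_id", "omega")],
              by = "gene_id", suffixes = c("_w", "_z"))
  n_pairs <- nrow(wz)
  usable <- complete.cases(wz[, c("omega_w", "omega_z")])
  wz <- wz[usable, , drop = FALSE]
  d <- wz$omega_w - wz$omega_z
  n_w_greater <- sum(d > 0)
  d <- d[d != 0]
  n <- length(d)
  if (n < 2)
    stop("fewer than 2 usable non-tied pairs for the signed-rank test",
         call. = FALSE)
  ranks <- rank(abs(d))
  w_plus <- sum(ranks[d > 0])
  if (n <= 25) {
    method <- "exact"
    p_greater <- signed_rank_exact_p(ranks, w_plus)
    p_less <- signed_rank_exact_p(ranks, sum(ranks) - w_plus)
    p <- if (alternative == "greater") p_greater
         else min(1, 2 * min(p_greater, p_less))
  } else {
    method <- "normal-approximation"
    mu <- n * (n + 1) / 4
    ties <- table(ranks)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(ties^3 - ties) / 48
    z <- (w_plus - mu - 0.5 * sign(w_plus - mu)) / sqrt(sigma2)
    p <- if (alternative == "greater") pnorm(z, lower.tail = FALSE)
         else 2 * pnorm(abs(z), lower.tail = FALSE)
  }
  structure(list(n_pairs = n_pairs, n_used = n,
                 n_excluded = n_pairs - sum(usable),
                 n_w_greater = n_w_greater, statistic = w_plus,
                 p_value = p, method = method,
                 alternative = alternative),
            class = "paired_test")
}

#' @export
print.paired_test <- function(x, ...) {
  cat("Paired signed-rank test (", x$method, ", ", x$alternative, ")\n",
      "  pairs: ", x$n_pairs, " (", x$n_excluded, " excluded, ",
      x$n_used, " used)\n",
      "  W > Z in ", x$n_w_greater, " pairs; V = ", x$statistic,
      ", p = ", format(x$p_value, digits = 4), "\n", sep = "")
  invisible(x)
}
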