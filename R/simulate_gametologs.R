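# Gametolog CDS simulator: an ancestral coding sequence per gene, an
# outgroup copy, and Z/W copies evolved under a simple accept/reject
# substitution process in which synonymous changes are always accepted,
# nonsynonymous changes are accepted with a baseline probability
# (multiplied by w_omega_multiplier on the W branch), and stop codons are
# never emitted. No indels, so codon orthology is positional.

stop_codons <- function() c("TAA", "TAG", "TGA")

sense_codons <- function() {
  all64 <- as.vector(outer(outer(BASES, BASES, paste0), BASES, paste0))
  setdiff(all64, stop_codons())
}

codon_aa <- function(codons) {
  unname(Biostrings::GENETIC_CODE[codons])
}

# Cached mutation lookup tables: for codon index i, position p and
# alternative a (the 3 bases differing from the current one), the mutated
# codon index plus synonymy/stop flags.
.mut_cache <- new.env(parent = emptyenv())

mutation_tables <- function() {
  if (!is.null(.mut_cache$tab)) return(.mut_cache$tab)
  codons <- as.vector(outer(outer(BASES, BASES, paste0), BASES, paste0))
  aa <- codon_aa(codons)
  new_idx <- array(0L, c(64, 3, 3))
  is_syn <- array(FALSE, c(64, 3, 3))
  is_stop <- array(FALSE, c(64, 3, 3))
  for (i in 1:64) {
    for (p in 1:3) {
      alts <- setdiff(BASES, substr(codons[i], p, p))
      for (a in 1:3) {
        alt_cod <- codons[i]
        substr(alt_cod, p, p) <- alts[a]
        j <- match(alt_cod, codons)
        new_idx[i, p, a] <- j
        is_syn[i, p, a] <- aa[j] == aa[i]
        is_stop[i, p, a] <- aa[j] == "*"
      }
    }
  }
  .mut_cache$tab <- list(codons = codons, new_idx = new_idx,
                         is_syn = is_syn, is_stop = is_stop)
  .mut_cache$tab
}

# Evolve codon vectors: each site proposes a change with probability
# `rate`; acceptance depends on the effect (syn always, nonsyn with
# prob ns_accept, stop never). Proposals landing in the same codon are
# processed in successive vectorized rounds.
evolve_codons <- function(codons, rate, ns_accept) {
  if (rate <= 0) return(codons)
  tab <- mutation_tables()
  idx <- match(codons, tab$codons)
  n_sites <- 3L * length(codons)
  hits <- which(runif(n_sites) < rate)
  while (length(hits)) {
    cod_i <- (hits - 1L) %/% 3L + 1L
    first <- !duplicated(cod_i)
    h <- hits[first]; ci <- cod_i[first]
    pos <- (h - 1L) %% 3L + 1L
    alt <- sample.int(3L, length(h), replace = TRUE)
    sel <- cbind(idx[ci], pos, alt)
    ok <- !tab$is_stop[sel] &
      (tab$is_syn[sel] | runif(length(h)) < ns_accept)
    idx[ci[ok]] <- tab$new_idx[sel[ok, , drop = FALSE]]
    hits <- hits[!first]
  }
  tab$codons[idx]
}

#' Simulate gametolog coding sequences
#'
#' For each gene an ancestral CDS (sense codons only) is generated, then
#' evolved into an outgroup copy and into Z and W copies; the W branch's
#' nonsynonymous acceptance probability is `base_ns_accept *
#' w_omega_multiplier` (capped at 1). Deterministic in `config$seed`.
#'
#' @param config A `sim_config`; relevant fields: n_gametolog_genes,
#'   codons_per_gene, zw_divergence, outgroup_divergence, base_ns_accept,
#'   w_omega_multiplier.
#' @return List with `cds` (named character vector: <gene>_Z, <gene>_W,
#'   <gene>_out), `pairs` (data.frame gene_id, z_id, w_id, outgroup_id)
#'   and `truth` (acceptance probabilities used).
#' @export
simulate_gametologs <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  ns_z <- config$base_ns_accept
  ns_w <- min(1, config$base_ns_accept * config$w_omega_multiplier)
  sense <- sense_codons()
  with_seed(config$seed + 404L, {
    cds <- character(0)
    gene_ids <- sprintf("g%03d", seq_len(config$n_gametolog_genes))
    for (g in gene_ids) {
      anc <- sample(sense, config$codons_per_gene, replace = TRUE)
      out <- evolve_codons(anc, config$outgroup_divergence, ns_z)
      z <- evolve_codons(anc, config$zw_divergence, ns_z)
      w <- evolve_codons(anc, config$zw_divergence, ns_w)
      cds[paste0(g, "_Z")] <- paste(z, collapse = "")
      cds[paste0(g, "_W")] <- paste(w, collapse = "")
      cds[paste0(g, "_out")] <- paste(out, collapse = "")
    }
    pairs <- data.frame(gene_id = gene_ids,
                        z_id = paste0(gene_ids, "_Z"),
                        w_id = paste0(gene_ids, "_W"),
                        outgroup_id = paste0(gene_ids, "_out"),
                        stringsAsFactors = FALSE)
    list(cds = cds, pairs = pairs,
         truth = list(ns_accept_z = ns_z, ns_accept_w = ns_w,
                      zw_divergence = config$zw_divergence,
                      outgroup_divergence = config$outgroup_divergence))
  })
}
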