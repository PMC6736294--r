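---
title: "Methods: sex-linked scaffold discovery and neo-sex chromosome profiling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sex-linked scaffold discovery and neo-sex chromosome profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

In birds, females are the heterogametic sex (ZW) and males are ZZ. A
female genome assembly therefore contains W-derived scaffolds that should
receive **no** reads from male individuals and haploid-depth reads from
females, while Z-derived scaffolds sit at diploid depth in males and
haploid depth in females. `wzscan` classifies the scaffolds of a female
assembly into W-linked, Z-linked and other (autosome-like) classes from
sex-pooled short-read data, then uses reference anchoring to detect a
*neo-sex chromosome*: a formerly autosomal chromosome whose two haplotypes
have become W- and Z-inherited after fusion with the sex pair, leaving
recombining (autosomally behaving) blocks at its termini.

Two complementary classifiers are implemented.

**Single-copy k-mer scan (YGS-style).** Canonical k-mers (the
lexicographic minimum of each k-length window and its reverse complement;
k = 16 by default) are counted in the assembly and in the pooled reads of
each sex. For a scaffold, the *scored* k-mers are its distinct canonical
k-mers that occur exactly once in the assembly — restricting to
single-copy k-mers removes exact repeats that would otherwise match
spuriously across chromosomes, while unique variants of repeats remain
informative. A scored k-mer is a *hit* when it is effectively absent from
male reads and supported by female reads; a scaffold is called W-linked
when strictly more than 75% of at least 50 scored k-mers are hits.
"Present in a read pool" means a count of at least `min_read_count`
(default 2): in deeply pooled data a 1-count k-mer is overwhelmingly a
sequencing error, so presence at count 1 is not treated as support. The
denominator is all scored k-mers; an option restricts it to
female-supported k-mers, since the verbal rule leaves that choice open.

**Differential depth.** Per-base depth tracks per sex give per-scaffold
zero-inclusive median depths and covered fractions. Zero-inclusive
medians matter: a W scaffold must have male median exactly 0, which a
nonzero-only median would hide. Pooled per-base histograms (bin width 1,
moving-average smoothing over 5 bins) provide the male and female diploid
peaks and the female haploid peak; the haploid peak is the best local
maximum strictly inside (low_cut, 0.75 x diploid), with a flagged
fallback to diploid/2 when pooling leaves no such maximum. The Z rule is
male median > round(0.75 x male diploid peak) and female median <
round(1.5 x female haploid peak), plus both sexes covering > 75% of the
scaffold; with peaks of 77x and 41.5x this single rounding rule gives the
cut-offs 58 and 62. All classifier inequalities are strict. The W call
set is the union of the two methods; Z comes from depth only, because a
k-mer absence test cannot see a chromosome both sexes carry.

**Neo-sex profiling.** Scaffold anchoring to a reference is consumed as a
table (scaffold, reference chromosome, order, strand) — reference-guided
ordering itself is a solved problem handled by external tools and is not
re-implemented. Pseudomolecules are built by concatenating anchored
scaffolds with 100-N gaps; per-scaffold depth is lifted through the
placements (gaps masked), averaged in non-overlapping windows, and each
window is classified ABSENT / HAPLOID / DIPLOID / AMBIGUOUS per sex using
a single relative tolerance band (default 25%) around the sex's diploid
peak and its half. A chromosome anchored by two diverged haplotype sets
shows (a) a pseudomolecule nearly twice the reference length when built
from all scaffolds, and (b) after excluding Z-linked (resp. W-linked)
scaffolds, a chromosome whose interior windows are male-absent /
female-haploid (resp. male-diploid / female-haploid) with
diploid-diploid terminal runs.

**Identity strata.** Windowed neo-W/neo-Z identity (10-kb windows on
neo-Z coordinates, orthology from a paired-interval map) is segmented by
greedy recursive change-point splitting: a segment splits at the boundary
maximizing the between-segment mean difference while the difference
exceeds `merge_tol` (1.5 percentage points) and both sides keep
`min_windows` (3) windows; adjacent segments within the tolerance merge.
This formalizes what is usually a visual reading of clustered identity
zones (~100/98/95/92%) into explicit strata with coordinates.

**Gametolog dN/dS.** Each W and Z gene copy is compared with an outgroup
reference: proteins are globally aligned (BLOSUM62, affine gaps),
back-translated to codon alignments with gap and stop columns dropped,
and scored with the Nei–Gojobori (1986) counting method — synonymous site
fractions per codon position out of 3 possible changes (changes to stops
count as nonsynonymous sites, so S + N = 3 per codon exactly), observed
differences averaged over minimal stop-free mutational pathways, and
Jukes–Cantor correction of pS/pN. NG86 was chosen over maximum-likelihood
codon models deliberately: it is exact, dependency-free and auditable
against a brute-force reimplementation, and the scientific claim being
checked is a *paired inequality* (W above Z), not an absolute rate. The
paired comparison is a Wilcoxon signed-rank test (one-sided, W > Z) with
exact enumeration of the null for up to 25 usable pairs (dynamic
programming over doubled ranks, so tied average ranks stay exact) and a
tie- and continuity-corrected normal approximation beyond; pairs with an
undefined omega (dS = 0 or saturated proportions) are excluded and
counted.

## The synthetic genome generator

Every stage is testable without external data through `simulate_genome()`
and its companions. The generator emulates the statistical structure the
classifiers rely on, not sequence realism:

- autosomes, a Z, a female-limited W, and a neo chromosome whose middle
  block exists as diverged neo-Z and neo-W copies while head/tail
  intervals stay single-copy (recombining);
- neo-W/neo-Z divergence follows configurable identity strata with **no
  indels**, so truth orthology is positional and window-identity oracles
  are exact;
- repeats are length-preserving overwrites from a fixed library of three
  500-bp motifs placed on a 500-bp slot grid — shared motifs make their
  k-mers multi-copy genome-wide (exercising the single-copy filter) and
  depth inside repeats is multiplied by a mappability-dropout factor
  (default 0.5) to mimic multi-mapping losses without simulating a
  mapper. Extra neo-W repeat slots are placed outside the sites used to
  realize stratum identity, which is therefore defined over non-repeat
  positions;
- reads are sampled uniformly per chromosome copy (females: diploid
  autosomes + Z + W + neo-Z + neo-W; males: diploid autosomes + 2 Z +
  2 neo-Z, never W) at `per_sex_diploid_depth / 2` per copy, with iid
  substitution errors; read names encode the true origin;
- depth tracks are Poisson with mean depth x copies / 2 (dropout inside
  repeats), standing in for mapping followed by per-base depth
  extraction;
- gametolog coding sequences evolve by per-site proposals accepted always
  when synonymous, with probability `base_ns_accept` (default 0.2,
  purifying selection) when nonsynonymous — multiplied by
  `w_omega_multiplier` on the W branch — and never when creating a stop.

Everything is deterministic in `config$seed`; identical configs give
byte-identical FASTA output.

### Default study conditions

The defaults describe a desk-scale study of about 5.3 Mb: two 1.8-Mb
autosomes, a 0.35-Mb Z, a 0.25-Mb W, and a 0.6-Mb neo chromosome with
25-kb and 35-kb autosomal termini (10% of its length, keeping the
expected all-scaffold pseudomolecule inflation near 1.9); scaffolds
average 50 kb (minimum 5 kb); pooled diploid depth 60x per sex; 100-bp
reads at error rate 1e-3; repeat fractions 0.366 on W/neo-W versus 0.10
elsewhere; strata identities 1.00/0.98/0.95/0.92; 150 gametolog genes of
300 codons with W nonsynonymous acceptance multiplied by 5. Autosomes
dominate the genome so the pooled female histogram peaks at the diploid
level with a haploid shoulder — the regime the peak detector assumes, as
in real genomes where sex-linked sequence is a minority. The neo middle
(0.54 Mb) is much longer than any scaffold, the termini are several
profile windows long, and 60x leaves the Poisson haploid/diploid bands
(30x vs 60x) separated by many standard deviations.

Two deliberate deviations from the defaults appear in the studies that
the tests and `scripts/acceptance.R` run:

- the strata-recovery study uses a 1.04-Mb neo chromosome with 20-kb
  termini (so the diverged middle is exactly 100 ten-kb windows, 25 per
  stratum) and repeat fractions 0, isolating the divergence signal whose
  segmentation is under test;
- the 40-replicate null calibration of the paired dN/dS test uses 60
  genes of 150 codons per replicate — the test's level does not depend on
  the study size, and smaller replicates keep 40 of them tractable;
- depth profiles in the scaled study use 20-kb windows (the
  `window_depth()` default stays 100 kb): windows must be much smaller
  than the autosomal termini for terminal runs to be resolvable, the same
  windows-to-termini regime as a full-scale profile.

### What the generator does not emulate

Mapping artefacts beyond a uniform repeat dropout, quality-score and
error-profile structure, indels and structural variation, recombination
maps, GC bias, and assembly fragmentation pathologies (chimeras, gaps).
Passing tests therefore demonstrate that the *inference rules* recover
the planted structure under the stated noise model — they do not certify
performance on real libraries, where mappability and assembly errors add
failure modes a full-scale analysis handles with mapping-quality and
coverage filters.

## Numerical choices and degenerate inputs

- Coordinates are 0-based half-open internally; depth TSVs are 1-based on
  disk (the `samtools depth` convention) and converted only at I/O.
  Both an all-positions and a sparse depth dialect are supported, since
  depth extractors emit either.
- Derived depth thresholds round to the nearest integer (R's `round`);
  this one rule reproduces both printed cut-offs (57.75 -> 58,
  62.25 -> 62).
- N bases count toward scaffold lengths and depth arrays; k-mer windows
  containing N are skipped.
- The banded global DNA aligner (match +1, mismatch -1, gap open 4, gap
  extend 1; a length-L gap run costs open + L x extend, the same
  convention as the protein aligner) uses a 32-column corridor around the
  main diagonal, widened by the length difference so the corridor always
  reaches the terminal cell. Within paired orthologous windows of
  low-divergence, indel-free sequence the optimum lies on the diagonal;
  setting `band` to the window length gives the full quadratic DP, which
  the tests compare against exhaustive alignment enumeration.
- Ties in the N50 scan resolve to the scaffold that first reaches half
  the total, per the statistic's definition.
- `ygs_score` on a scaffold shorter than k, or with no scored k-mers,
  returns a flagged, uncalled row rather than an error; an empty male
  read pool degenerates to calling every female-supported scaffold and
  warns.
- Windows consisting only of gap padding have undefined means and are
  classified AMBIGUOUS; all-zero depth tracks yield median 0 and
  coverage 0.
- NG86 omega is flagged undefined when dS = 0 or a proportion reaches
  3/4 (Jukes–Cantor uncorrectable); codon pairs whose every minimal path
  crosses a stop fall back to averaging over unrestricted paths with
  stop-entering steps skipped, and are flagged.
- A scaffold passing both the W and Z depth rules (pathological input) is
  labelled W — the W rule's male-zero-median requirement is the more
  specific evidence — and flagged.

## Known limitations

- Lifting per-scaffold depth through the anchoring map is equivalent to
  re-mapping reads against the pseudomolecule only if mapping is
  position-stable; at junctions and in repeats the two differ slightly.
  The windowed profile treats this as acceptable because windows span
  many junctions.
- Stratum boundaries are constrained to window edges; sub-window
  boundaries blur into adjacent windows (hence the +-1-window recovery
  tolerance quoted in the tests).
- NG86 underestimates rates at high divergence relative to
  maximum-likelihood codon models; within the paired W-vs-Z design the
  bias is shared by both members of each pair.
- The exact signed-rank enumeration is used up to 25 usable pairs; beyond
  that the normal approximation (continuity- and tie-corrected) is
  standard but approximate.
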