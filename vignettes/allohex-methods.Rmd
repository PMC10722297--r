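---
title: "Detecting homoeologous exchanges and dating LTR insertions in a segmental allotetraploid"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting homoeologous exchanges and dating LTR insertions in a segmental allotetraploid}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allohex)
```

## The biological model

A segmental allotetraploid such as sour cherry carries two subgenomes,
here labelled *a* (sweet-cherry-derived) and *f* (ground-cherry-derived).
Because the homoeologous chromosomes still pair occasionally, segments of
one subgenome can be replaced by the corresponding segment of the other —
a duplication–deletion event that leaves the acceptor locus carrying two
near-identical copies of the donor haplotype and none of its own.  Such
homoeologous exchanges (HE) are directional, unbalanced, and leave three
independent footprints that this package measures and intersects:

* **Genomic**: hybrid whole-genome reads that align uniquely to one
  ancestor pile up on both copies of an exchanged segment, so windows of
  the acceptor subgenome become covered by reads unique to the *other*
  ancestor.
* **Transcriptomic**: RNA-seq of each ancestral species covers the hybrid
  genes derived from it; over an exchanged segment the donor species'
  reads take over.
* **Proteomic**: a protein encoded inside an exchanged segment is more
  similar (percent amino-acid identity, IAA) to the homoeologous ancestor
  than to its own.

A 250-kb window qualifies when all three flags agree; maximal runs of
adjacent qualifying windows merge into one directed region.  A fourth,
annotation-only signal computes the 70% quantile of the identity values in
1-Mb windows and confirms regions where the homoeologous quantile exceeds
the homologous one.  Confirmation is deliberately *not* a fourth AND
criterion: it summarises a coarser scale and would otherwise veto
exchanges shorter than the confirmation window.

## Window bookkeeping

All coordinates are 0-based, half-open, everywhere; SAM input is shifted
at the parsing boundary and BED/bedGraph output keeps the same convention,
so no stage ever re-interprets coordinates.  Window sizes follow the three
analysis scales: 100 kb for the genomic track, 250 kb for the RNA and
protein tracks, 1 Mb for quantile confirmation; "100k/250k/1M" are read as
exact decimal sizes.  Trailing partial windows are kept and normalised by
their true width — discarding them would blind the caller at chromosome
ends, and normalising keeps the fraction-covered statistic comparable.
The genomic track is harmonised onto the 250-kb grid by flagging a coarse
window when **any** overlapping 100-kb window is flagged (a configurable
policy; `"all"` is stricter and can only remove calls, never add them).
Equality of coverages or percentages never raises a flag: the footprints
are defined by strict inequalities, and flat windows carry no information.
Windows with no data in a track (no coverage from either read class, no
expression, no anchored protein) are marked `no_data` and cannot qualify.

## Read partitioning

Alignments are filtered exactly as `samtools view -f 3 -F 2304`: mapped in
a proper pair, neither secondary nor supplementary.  A *fragment* (read
pair) "matches" a genome when both mates pass that filter — the natural
fragment-level reading of a proper-pair filter — and the 2×2 match table
against the two ancestors gives the exhaustive partition into `UNIQUE_A`,
`UNIQUE_F`, `BOTH`, `NEITHER`.  Uniqueness is across genomes, not loci:
a read mapping to several positions of one genome still counts as
matching that genome through its primary alignment.

The built-in mapper exists so the synthetic universe needs no external
aligner; it is exact-match only (reads are simulated error-free) with a
k-mer seed on the first `k = 31` bases and full-length verification, which
is complete for exact matching.  One subtlety matters: after a
duplication–deletion exchange the donor and acceptor copies are literally
identical, so a read from either copy has two equally valid placements.
The mapper draws the primary placement uniformly at random (through R's
RNG, hence reproducible after `set.seed()`), as production short-read
aligners do; a deterministic tie-break would silently starve one copy of
coverage and hide every exchange on the lexicographically later
chromosome.  Real data are expected to arrive as SAM from a real aligner
via `read_sam()`.

## Protein identities

For synthetic data the identity of two proteins is computed from a global
Needleman–Wunsch alignment with match +1, mismatch 0 and a linear gap
penalty of −1, identity = 100 · matches / alignment columns; ties in the
traceback prefer the diagonal.  This scoring is a deliberately simple
stand-in for the homology-based identities real annotations provide; real
identity tables enter through a TSV reader, and when a protein has several
reference homologs the maximum identity per ancestor is kept ("more
similar to" compares best homologs).  Tied identities get their own
category with an exact-equality default (`tie_epsilon = 0`,
configurable), matching tables that report an explicit tie column.  A
protein belongs to the window containing its coding-region start —
unambiguous for genes spanning window boundaries.  The 70% quantile uses
linear interpolation between order statistics (R's default type 7); the
convention is pinned because quantile definitions differ across software.

## The LTR clock

The two long terminal repeats of a retrotransposon are identical at
insertion; their subsequent divergence K = 1 − identity dates the
insertion as T = K/(2µ) with µ = 7.7 × 10⁻⁹ substitutions per site per
generation, a *Prunus*-specific rate.  Identity comes from EDTA-style
pass-lists.  "Same type with the same insertion time in the same
positional order" is operationalised as: equal family, identities within
`identity_tolerance = 10⁻⁴` (≈ 6,500 generations at the default µ — the
tolerance is explicit because "same" is not quantifiable otherwise), and
membership in a maximum-cardinality order-preserving matching per
chromosome pair, computed by LCS-style dynamic programming.  Without the
order constraint a maximum bipartite matching is used instead, so
relaxing the constraint can never lose matches.  Generation counts are
converted to calendar ages by a sweep over 10–60 years per generation:
cherry generation times in natural habitats are unknown, and a sweep is
more honest than a point estimate.  Reported ages are rounded to one
decimal; full precision is kept internally.

## The synthetic universe

The generator's defaults are the study conditions the package is tested
under: two chromosomes of 5 Mb per subgenome; ancestors diverged by 3%
(1.5% per branch from a common random root); 0.2% drift between each
subgenome and its ancestor; six planted duplication–deletion exchanges of
0.5–2 Mb with boundaries snapped to 250-kb multiples (so expected flagged
window sets are exact rather than fuzzy at breakpoints); error-free
150-bp read pairs with Normal(550, 50) inserts at 20× coverage; one gene
per 50 kb (1.5 kb long, so genes never straddle a 250-kb boundary at the
defaults); genes expressed with probability 0.85 and captured by each RNA
dataset with probability 0.9; and an LTR table that plants shared
elements across every genome pair.  Substitution is the only mutational
process — no indels — which keeps exact-match mapping and identity
arithmetic closed-form; an indel mode would require a gapped mapper and
is out of scope.  Every stage seeds its RNG from `seed` plus a fixed
stage offset, so each output is byte-reproducible independently of call
order.

What the simulation does *not* emulate: sequencing errors, mapping bias,
assembly errors, repeat-induced multi-mapping beyond exchange duplicates,
transcript isoforms, uneven expression levels, or post-exchange
divergence of the duplicated copies.  Passing tests therefore demonstrate
that the statistics and the intersection logic are implemented correctly
and recover planted truth under clean conditions — not that the method is
robust to every artefact of real sequencing data.

## Numerical and design choices

* Strict inequalities for all three flags; ties and empty windows never
  qualify.
* Harmonisation default `"any"` favours sensitivity; precision is
  protected by the three-way AND.
* Fragment classification needs the universe of sequenced fragments to
  count `NEITHER`; the alignment files alone cannot supply it.
* `he_calls` regions are merged at window granularity; single qualifying
  windows stand as regions of one window.
* Truth comparison uses ≥ 50% reciprocal overlap, so a call must both
  cover and be covered by a planted segment.
* Problem sizes in the shipped tests (2 × 5 Mb chromosomes, 20× reads for
  the end-to-end check; 1–2 Mb universes for unit tests) were chosen as
  the smallest sizes at which every window statistic rests on hundreds of
  fragments and tens of genes, keeping the statistical behaviour of the
  full-size analysis while remaining quick to simulate.

## Known limitations

Breakpoints are resolved only to window boundaries; exchanges shorter
than one 250-kb window are invisible by construction.  The genomic track
loses power where the acceptor and donor copies have diverged after the
exchange (reads then map uniquely again) — dating the exchanges
themselves is the LTR module's job, not the coverage tracks'.  Whether a
called region reflects a true exchange or an assembly artefact cannot be
decided from these signals and is deliberately out of scope.

## A complete run

```{r, eval = FALSE}
res <- run_pipeline(sim_config(seed = 1), out_dir = "he_run")
print(res)
summary(res$calls)
plot(res$calls)
res$ltr_youngest
```

The run directory contains the three per-window evidence TSVs, the merged
region BED (round-trippable through `read_he_bed()`), the truth BED, the
dated LTR table and a JSON manifest with parameters and file checksums.
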