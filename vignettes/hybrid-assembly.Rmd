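---
title: "Hybrid assembly by consensus selection and comparative-contig filtering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid assembly by consensus selection and comparative-contig filtering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(hybridasm)
```

## The problem

Short-read assemblies of microbial genomes are limited by genomic repeats:
de Bruijn graph (DBG) assemblers resolve them differently, and each
assembler occasionally emits a *chimeric* contig that joins loci which are
not adjacent in the genome. Comparative (reference-guided) assembly can
produce longer contigs, but when the only available references are diverged
relatives (whole-genome similarity well below 100%), reference-biased
misassemblies appear wherever the reference's structure differs from the
target.

`hybridasm` reconciles the two sources in four stages:

1. **Consensus selection.** From two or more de novo assemblies of the same
   read set, a contig is kept only if it is identical to, or an exact
   substring of (either strand), contigs from at least `min_support = 2` of
   the assemblies, with candidates below `min_len = 500` bp never
   considered. The kept, containment-deduplicated set is called the *DBG
   contigs*. The logic: assemblers make *different* mistakes, so a chimera
   invented by one assembler is essentially never reproduced base-for-base
   by another, while correctly assembled sequence is.
2. **Comparative contigs.** Contigs built against each reference genome
   (*A-contigs*) are supplied as input; the package does not run the
   comparative assembler itself.
3. **Reliability filtering.** Each DBG contig is aligned to all pooled
   A-contigs and assigned to its single best hit. An A-contig is *reliable*
   iff (a) none of its assigned alignments contains an indel larger than
   `max_indel = 50` bp and (b) the fraction of its length covered by its
   assigned DBG contigs is at least `tau = 0.8`. Best-hit assignment is the
   crux: when reference A induces a chimeric copy of a region and reference
   B a faithful one, the DBG contigs pick the faithful copy, starving the
   chimera of coverage.
4. **Merging.** DBG contigs and reliable A-contigs are merged by a greedy
   exact-overlap layout (containments absorbed, then dovetails
   longest-first, each contig end used at most once) into the *hybrid
   assembly*.

## Alignment model

All alignment in the package is built on maximal exact matches (MEMs): an
exact match that cannot be extended on either side without a mismatch,
an `N`, or running off a sequence. MEMs of length ≥ `min_match` (default
20 bp) are found on both strands by a seeded scan (2-bit encoded k-mer
index, greedy extension, per-diagonal deduplication) and then chained by
sparse dynamic programming into colinear chains, maximizing matched bases.
Within a chain, adjacent matches may be separated by at most
`maxgap = 500` bp on either sequence, and a chain must reach
`mincluster = 100` matched bases to survive. The difference between the
query-side and target-side gap of adjacent matches is the chain's local
indel estimate; `max_indel` is its maximum over the chain.

Choices worth knowing:

* `N` matches nothing, including another `N`. An ambiguous base is absence
  of information, so no exact match may cover one.
* Containment ("identical to or a subsequence of") is tested exactly, which
  makes consensus voting byte-deterministic. A mismatch-tolerant mode
  (`is_contained(tol = )`, full-length chain identity) exists but is off by
  default.
* `min_match = 20` bp is the seed length commonly used by whole-genome
  exact-match aligners; it is exposed in `align_params()`.
* Overlapping chained matches are resolved by trimming the later match,
  which preserves exactness (an exact match shortened from its start on
  both coordinates is still exact).
* Target coordinates are always forward; the strand flag describes the
  query. Internal coordinates are 0-based half-open; TSV reports are
  1-based inclusive.
* In a declared self-comparison (repeat scanning) the identity diagonal is
  suppressed; two distinct but identical contigs still report their
  full-length match, which containment voting relies on.
* "Significant indel" is quantified as 50 bp: large enough to ignore
  chaining noise at the default `maxgap`, small enough to catch real
  structural disagreement. This number is a package decision, not an
  empirical constant, and is exposed in `reliability_params()`.
* Coverage of an A-contig counts only best-hit-assigned chains. Counting
  all alignments would let a chimera borrow coverage from DBG contigs that
  in fact belong to a faithful copy elsewhere, defeating the filter.
* Ties in best-hit assignment (several A-contigs containing a DBG contig
  in full) are broken toward the smaller maximal indel, then the longer
  A-contig, then the lexicographically smaller id — deterministic, and in
  practice it concentrates support on the longest faithful copy of each
  region.

## Evaluation metrics

* **Accuracy** of an assembly is the proportion of *bona fide* contigs: a
  contig whose best chain against the truth genome covers ≥ 95% of its
  length in matched bases with no indel above 50 bp. A chimera's junction
  splits every chain (its two loci are farther apart than `maxgap`), so no
  single chain can reach 95%.
* **Genome-relative N50** (`n50()`): after sorting contigs by descending
  length, the length of the first contig at which the running total
  reaches half the *genome* length; 0 if it never does (a boundary the
  definition leaves open; returning 0 makes under-assembly visible instead
  of flattering it).
* **Repeat complexity** (`complexity()`): the fraction of genome positions
  inside at least one non-identity maximal exact self-match ≥ 20 bp,
  counted once. Two planted copies of a 5 kb unit in a 100 kb genome give
  0.1.
* **Similarity** (`similarity()`): positions of each genome covered by
  MEMs (≥ 20 bp, both strands) against the other, unioned per genome, then
  `(covered_a + covered_b) / (len_a + len_b)`. Identical genomes score 1.
  A single-counted variant ("sum of match lengths over total length of
  both genomes", taken literally) would cap identical genomes at 0.5 and
  could not express the 0.80–0.92 working band for usable diverged
  references, so the double-counted form is used. Note that position-set
  similarity is insensitive to pure rearrangement: an inverted or
  translocated segment still matches exactly, on the other strand or
  another diagonal. Divergence is carried by point substitutions.
* **Weighted rank scores** (`rank_scores()`): for exactly four methods and
  four contiguity categories (average length, N50, longest, genome
  fraction covered by bona fide contigs), methods are ranked per dataset
  and category, weights 4 (best) to 1 (worst), ties sharing the mean of
  their tied weights, summed over datasets.
* **Proportion extended** (`proportion_extended()`): the fraction of de
  novo contigs whose best comparative hit protrudes ≥ 10 bp beyond at
  least one of their ends, or which share their best-hit comparative
  contig with another de novo contig (a merge opportunity).

## The synthetic study conditions

Everything is validated on seeded synthetic data; the generator
(`genome_fixture()`) fixes the study conditions:

* **Genome**: 100 kb of i.i.d. uniform bases with two planted copies of a
  400 bp repeat unit, giving repeat complexity 0.008 — above the 6e-3 floor
  that separates repeat-bearing genomes from trivial ones. 100 kb (vs. the
  megabase scale of real microbial genomes) keeps the full 20-genome suite
  within minutes on one CPU while leaving every length scale (reads ≪
  contigs ≪ genome) intact.
* **References**: three per genome, each produced by planting three block
  rearrangements (inversions in place, or translocations of 1.5–2.5 kb
  segments) and then bisecting the substitution rate until measured
  similarity lands in 0.80–0.92 — the band in which comparative assembly is
  still worth doing but misassembles. Rearrangement anchors are confined to
  disjoint genome zones per reference, so wherever one reference is
  structurally wrong, another is faithful: the geometry the best-hit filter
  is designed for.
* **DBG contigs** for the filtering suite: a bona fide tiling of the genome
  (mean 800 bp, adjacent contigs sharing 100 bp exact overlaps), with
  breakpoints kept out of planted repeats — emulating that consensus
  selection has already removed chimeras (validated separately) and that
  assemblers terminate contigs at repeat boundaries rather than inside
  them.
* **A-contigs**: per reference, a tiling of the genome (mean 8 kb) in which
  the contig over each divergent region is replaced by a chimera carrying
  the reference's structure there (inverted or translocated segment, plus
  substitutions at the reference's divergence rate), flanks capped at 1.4×
  the divergent segment so the divergent part is a substantial fraction of
  the contig. Genuine A-contigs are exact genome substrings: with
  error-free reads, a comparative assembler reconstructs target sequence,
  and read-level errors are a separate axis not modeled here.
* **De novo assemblies** for the consensus suite
  (`make_fixture_assemblies()`): three assemblies drawn as independent
  coarsenings of one shared breakpoint grid (so contigs of one assembly
  are frequently substrings of another's — the situation voting exploits),
  each contig replaced with probability 0.1 by a chimeric join of its own
  left half with a locus ≥ 15 kb away. Chimeras are drawn independently
  per assembly and never shared.
* **Reads** (`simulate_reads()`): given genome length G, fold coverage C,
  fragment length L and read length R, exactly ⌊G·C/(2R)⌋ fragments with
  uniform starts; each yields a forward read from the fragment's 5' end
  and the reverse complement of its 3' end (C = 60, L = 300, R = 75 by
  default). Reads carry no quality model; an optional uniform substitution
  error exists and defaults to 0, which is also what the validation suites
  use.

What these fixtures do *not* model: sequencing errors inside contigs,
collapsed-repeat misassemblies (chimeras here join distant loci or carry
reference structure), circular chromosomes (fragments never wrap), uneven
coverage, and contaminating sequence. Passing the suites therefore shows
the selection/filtering/merging logic is correct under its stated error
model, not that the thresholds are optimal for any particular real
dataset.

## What the validation suites measure

`validation_suite()` (20 seeded genomes) runs the reliability filter at
`tau = 0.8` and the merger, and reports per genome: planted and excluded
misassemblies, reliable-set accuracy, hybrid accuracy, and contig
counts/lengths before and after merging. `consensus_suite()` (20 seeded
genomes) runs consensus selection against three chimera-bearing assemblies
and reports the selected set's accuracy. `scripts/acceptance.R` wraps both
and writes the pooled exclusion rate and worst-genome accuracies as JSON.

```{r, eval = FALSE}
suite <- validation_suite(seeds = 1:3)
suite[, c("n_planted", "n_excluded", "acc_reliable", "acc_hybrid")]
```

Two structural facts make the filter effective under these conditions, and
they are worth understanding because they are the method, not the fixture:
a chimera's divergent middle is both diverged (so DBG contigs match the
faithful copy better) and longer than `maxgap` (so no chain bridges it),
which caps the chimera's attainable coverage by its flank fraction, below
`tau`; and junction-spanning DBG contigs are assigned to full-length
matches elsewhere, so the chimera is additionally starved of flank
coverage.

## Numerical and degenerate-input conventions

* All generators are bit-reproducible given their seed
  (`withr::with_seed`); the pipeline is byte-deterministic given config +
  seed, with output contigs always sorted by descending length then id.
* Empty cases are contracts, not accidents: empty FASTA, empty assembly
  for writing or accuracy, zero-length `t_len` in coverage, fewer than two
  assemblies for consensus — all raise errors; an empty DBG set excludes
  every A-contig with coverage 0; no overlaps means merging returns its
  input unchanged.
* Chain extraction is greedy best-first from a single dynamic-programming
  pass; a lower-scoring chain whose path touches an already-used match is
  skipped rather than re-optimized. The best chain — the only one the
  pipeline's decisions depend on — is exact.
* MEM seeding uses k = min(min_match, 31); matches shorter than
  `min_match` are discarded after extension, so the reported set is
  identical for any seed length ≤ the shortest true match.
* Pathological repeat structures are capped at 2000 blocks per chaining
  problem (longest kept); none of the study conditions comes near this.

## Known limitations

* Merging is greedy, not an overlap-graph traversal; on highly repetitive
  inputs a longest-first join could, in principle, preempt a better
  layout. The intended inputs are long, mostly unique contigs.
* The reliability filter inherits the resolution of exact-match chaining:
  a misassembly whose divergent region is shorter than `maxgap` and nearly
  identical to the target may pass; conversely a faithful A-contig whose
  region is tiled by DBG contigs that all best-match a longer duplicate is
  excluded (a sensitivity, not an accuracy, cost — and why at least two
  references per region are recommended).
* `rank_scores()` is defined for exactly four methods, matching the
  four-assembly comparison it mirrors.
* Scaffolding and gap filling are out of scope; only sequence-confirmed
  joins are made and no `N` bridges are ever written.
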