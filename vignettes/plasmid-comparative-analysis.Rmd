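---
title: "Methods: comparative CDS-level plasmid analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative CDS-level plasmid analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plasmidcomp)
```

`plasmidcomp` packages the computations behind comparative megaplasmid
studies: how similar is a query plasmid's gene content to each member of a
plasmid panel, how are its genes organized into operons, which transposable
elements does it carry and in what configuration, and which gene clusters
are syntenic with other replicons. This vignette documents the models,
parameter choices and their rationale, what the synthetic-data generator
does and does not emulate, and known limitations.

## Coordinates and records

All coordinates are 0-based, half-open, on the plus strand; GenBank's
1-based inclusive positions are converted only at the I/O boundary. A
`PlasmidRecord` holds the sequence, topology (circular records support
origin-wrapping features via a virtual end beyond the sequence length,
normalised on output), and the ordered CDS table. Translation uses the
bacterial genetic code (table 11); codons containing N give X; a CDS with an
internal stop is flagged pseudo and excluded from all protein-level
analyses. GenBank support is intentionally minimal (single record, source
and CDS features) — the subset this pipeline consumes and emits; round-trip
identity is enforced by tests, and coordinates/translations are cross-checked
against Biopython in the suite.

## The relative-similarity statistic

For query plasmid $Q$ with non-pseudo proteins $q_1,\dots,q_n$ and target
$T$, each $q_i$ receives at most one best hit: the target protein maximizing
the Smith–Waterman score $S(q_i, t)$ among those passing the acceptance
thresholds. The statistic is

$$\mathrm{RS}(Q,T) = 100 \times \frac{\sum_i \max_t S(q_i,t)\,[\text{hit accepted}]}{\sum_i S(q_i,q_i)}.$$

Because substitution matrices of the BLOSUM family are diagonally dominant,
$S(q,t) \le \min(S(q,q), S(t,t))$, so $\mathrm{RS} \in [0,100]$ and
$\mathrm{RS}(Q,Q) = 100.00$ exactly — the normalization anchor the test
suite asserts. Each query CDS is scored independently (the same semantics as
a per-CDS ring plot, where every query gene's wedge is independently filled
or blank); duplicated query genes may therefore hit the same target gene.
One consequence, verified in tests: a target carrying exact copies of half
the query's (distinct) genes scores 50.00%.

Alignment parameters (`alignment_params()`):

| parameter | default | rationale |
|---|---|---|
| matrix | BLOSUM62 | de-facto standard for protein search; X scores 0 against everything |
| gap open / extend | 11 / 1 | the standard protein-search affine penalty |
| min identity | 30% of aligned columns | conventional twilight-zone cutoff; exposed on the CLI |
| min query coverage | 50% of query residues | rejects short chance local hits; exposed on the CLI |

Raw Smith–Waterman scores (not bit scores) are summed: the normalization by
the query self-score makes the bit conversion nearly cancel, and raw scores
are aligner-independent. Alignment is performed by `Biostrings::pairwiseAlignment`;
the test suite checks it against an independently written plain-R Gotoh
dynamic program on exhaustive small cases. A k-mer prefilter (candidate
pairs must share at least two exact 4-mers) skips hopeless pairs; for
homologous pairs at the package's thresholds this never changes the selected
hit (a property the suite asserts over 50 random proteome pairs), and it can
be disabled.

Panel ranking sorts by relative similarity, breaking ties by raw total and
then target id, for fully deterministic output. The duplication census links
CDS pairs at ≥90% identity and ≥90% mutual coverage — thresholds chosen to
capture near-identical paralogs such as repeated transposases, not distant
gene families — and reports connected components as duplicate families.

## Operon calling

A putative operon is a maximal run of same-strand genes in which every
intergenic gap, measured between half-open intervals
(`start(next) − end(prev)`), is strictly below 20 bp. Adjacent or
overlapping same-strand genes (gap ≤ 0) always join; an opposite-strand gene
always breaks a run, even when it sits inside a permissive gap — "same
direction" is treated as a hard requirement. On circular records the first
and last CDS join across the origin when they satisfy the rule, which makes
the partition invariant under rotation of the sequence origin (tested over
20 random rotations). Pseudo genes participate: operon structure is a
coordinate property, not a protein property. The shipped keyword table for
functional labelling (~10 broad categories) is a convenience default, not a
curated annotation.

## Repeats and transposable elements

**Direct repeats (iterons).** The scanner searches unit lengths in a
configurable range (default 15–20, bracketing the 17-mer iterons typical of
large *Pseudomonas* plasmid origins), spacers up to 10 nt, and at most one
mismatch of any copy to the *first* copy. Arrays are maximal — not
extendable by a qualifying copy on either side, verified brute-force in the
tests — and each repeat region is reported once: among overlapping candidate
arrays the one with more copies wins, then fewer total mismatches to the
first unit, then the longer span. The mismatch tie-break matters: a unit
length that wrongly absorbs spacer bases tends to accrue one extra mismatch
per copy and loses to the true unit.

**Inverted-repeat pairs.** `find_ir_pairs()` scans every palindrome center:
for a fixed center the complementary-match profile along the arms is a
binary string, and candidate arms are exactly the maximal
match-bounded runs with at most `max_mismatch` (default 2) mismatches. This
is exhaustive — the suite checks exact agreement with a brute-force
enumeration — at cost O(n · max_span), fine at the tens-of-kilobases scale
this package targets. Mononucleotide runs ≥ 12 and dinucleotide runs ≥ 16
are masked first; unmasked search floods on AT-rich spacers. Arms longer
than `max_len` (default 48, generous for the 25–39 bp termini of Tn3-family
elements) are trimmed on the inner side. Maximal arms extend through chance
flanking complementarity, so planted-truth tests plant non-extendable arms.

**Target-site duplications.** A TSD must be exact — biologically the
duplication is created by a single insertion event — and lengths are tested
longest-first over 4–6 bp (5 bp is the canonical Tn5053-family DR length).

**Element delineation.** A descriptor per element family supplies terminal
IR sequence(s) and reference proteins with roles (transposase = anchor,
cargo). Every record CDS is matched against the descriptor proteome (so
multi-copy elements each anchor); boundaries are the nearest IR matches (≤ 2
substitutions) on either side of the anchor within a 100 kb window — sized
for composite elements of roughly 77 kb, and configurable. Equidistant IR
candidates resolve to the lower-mismatch one. If only one IR side is found
the call is truncated on the other side, and that boundary is set at the
outermost CDS matching the family's proteins — the same definition the
synthetic generator uses when it truncates an element, so planted truth and
calls agree exactly rather than approximately. Spans strictly contained in
another call become nested children (`parent`). Cargo is every CDS inside
the span that is not the element's own transposase machinery; a nested
child's genes therefore count toward the host's cargo, mirroring how
composite elements are described.

The shipped descriptor bundle is explicitly synthetic: IR lengths follow the
published Tn4656 (39 bp), Tn5053 (25 bp) and Tn5563 (38 bp) geometries, but
the sequences are fixed random stand-ins, because the real termini are not
reproducible without their source records. Analyses of real plasmids should
supply descriptors extracted from the reference transposons.

## Synteny

Gene-cluster synteny is order-consistency, not score: each cluster gene
takes its best hit in the target, and the chain is the longest strictly
monotone subsequence of hit positions in target coordinate order, computed
in both orientations (increasing = same, decreasing = inverted; ties go to
same). One homologue per query gene avoids the quadratic pair explosion of
multi-hit chaining; a gap-penalized collinear chainer was deliberately not
used because the quantity of interest is a gene count. The implementation is
checked against exhaustive subsequence enumeration on all permutations up to
length 5 and sampled shuffles up to length 12.

## In-silico PCR

Primer sites allow up to 2 substitutions but an exact 3-base 3' clamp and no
indels — a standard PCR-specificity heuristic. Product length runs from the
5' end of the forward site to the 5' end of the reverse site on the opposite
strand, inclusive of both primers. On circular records products may span the
origin (product lengths are rotation-invariant, tested); products above
20 kb, or longer than the circle, are suppressed.

## The synthetic-data generator

The generator is the package's stand-in for a curated plasmid panel: it
produces annotated circular plasmids whose *statistical structure* matches
what the analyses assume, with machine-readable ground truth validated
against the emitted record at generation time.

- **Geometry.** Genes are arranged in same-strand runs (mean ~4 genes/run,
  a realistic operon size for accessory regions), within-run gaps drawn from
  0–19 bp and between-run gaps from 25–150 bp, so the operon definition's
  boundary cases are exercised by construction. Default 50 genes of 60–200
  residues — large enough for stable alignment statistics, small enough that
  the full pipeline runs in seconds.
- **Divergence.** Targets copy a planned fraction of query genes mutated to
  a planned protein identity by amino-acid substitution followed by
  back-translation through uniform synonymous codons; indels are excluded so
  realized identity is exact to within rounding (±2 points asserted
  per gene). Remaining genes are unrelated randoms. Order can be shuffled
  with a recorded permutation, giving synteny tests an exact oracle.
- **Elements and iterons** are planted by insertion at intergenic positions,
  duplicating the insertion-site bases to create the TSD; nesting inserts
  into a host element's span and truncation drops one IR, cutting exactly at
  the element's outermost internal CDS. Insertions shift all recorded truth
  coordinates; planting elements invalidates the planted operon geometry, so
  configs combine one or the other.
- **Determinism.** One integer seed; per-gene and per-step sub-seeds are
  derived by counter, so extending a configuration never perturbs earlier
  genes, and identical configs give byte-identical GenBank output.

What it does **not** emulate: real codon usage and GC skew, insertion-
sequence proliferation, gene-length and intergenic-length distributions of
real plasmids, and homology relationships more tangled than one planted
partner per gene. Passing the planted-truth suite therefore demonstrates
correctness of the algorithms under their stated models, not recovery
performance on real, repeat-dense megaplasmids.

## Numerical and degenerate-input choices

Percentages are reported to 2 decimals. Best-hit ties break by higher
identity then lower target start; ranking ties by raw total then target id;
equidistant IR boundaries by mismatch count — every output is deterministic
given inputs and seed. Empty hit lists, clusters with no homologues
(chain_len 0 rows are retained in reports), primers with no binding site,
and proteome pairs sharing no 4-mers all return empty results rather than
errors; genuinely unusable inputs (empty sequences, a query with no usable
CDS, descriptors without IRs) raise errors.

## Limitations

- The element caller needs a descriptor (known transposase + IR); it is not
  a de-novo mobile-element finder, and same-family elements interleaved
  within one window can confuse boundary assignment.
- The GenBank reader handles the single-record CDS subset only.
- Relative-similarity values depend on the alignment parameterization;
  comparisons across runs must hold `alignment_params()` fixed.
- `find_ir_pairs()` is exhaustive and quadratic-ish; for whole-megaplasmid
  scans restrict `max_span` or search windows around anchors (as
  `delineate_elements()` does).

## Problem sizes used in the test suite

Synthetic plasmids of 8–50 genes (roughly 3–25 kb); 100 seeded plasmids with
1–3 planted elements for the recovery study; alignment-oracle cases up to
length 8 on a reduced alphabet plus longer spot checks; IR-oracle sequences
of 120 bp. These sizes give exact, fast, deterministic checks of every
algorithmic property; scaling to full megaplasmid panels is a matter of
runtime, not algorithm.
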