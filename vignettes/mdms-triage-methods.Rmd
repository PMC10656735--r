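---
title: "Triage and verification of microbial dark matter sequences: methods"
author: "mdmtriage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Triage and verification of microbial dark matter sequences: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

16S rRNA amplicon surveys routinely produce OTUs whose representative
sequences cannot be assigned to any known lineage. These "microbial dark
matter" sequences (MDMS) are usually rarefied out of community profiles,
although they can reach tens of percent of the reads in under-studied
environments (aquifers, desert rock surfaces) and are enriched for
candidate-phyla-radiation (Patescibacteria) lineages. `mdmtriage`
implements a desk-scale pipeline that keeps these sequences and asks, for
each one: how novel is it, is it an artifact, can its existence be
verified, and where does it sit on the tree?

The pipeline stages, in order:

1. **classify** — align every OTU representative to a 16S reference
   database; flag OTUs whose best-hit identity falls below the assignment
   threshold, and map best-hit identity to a taxonomic novelty rank.
2. **select** — retain OTUs with at least 50 total reads, convert counts
   to per-sample relative abundances, and keep unassigned OTUs whose
   relative-abundance summary exceeds 0.5%.
3. **chimera** — screen candidates with a reference-based two-parent
   (bimera) model; suspects are annotated, never removed.
4. **verify** — primer QC, in-silico PCR against template sequences, and
   comparison of the recovered amplicon to the original representative.
5. **magmatch** — screen candidates against metagenome contigs and
   quality-filtered bins.
6. **place** — mask a reference alignment by gap frequency, project the
   candidates in, and report each one's nearest reference lineage on a
   neighbor-joining tree.

## Identity bands and novelty ranks

Taxonomic novelty is inferred from best-hit percent identity using the
established 16S rank thresholds: an identity of 94.5% or lower indicates a
distinct genus, 86.5% a distinct family, 82% a distinct order, 78.5% a
distinct class and 75% a distinct phylum. Boundaries are inclusive on the
novel side (identity exactly 94.5 is called a new genus). Identities below
a configurable floor (default 60%) are flagged `BEYOND_PHYLUM`, which in
practice signals an artifact or a sequence outside the aligner's reliable
regime rather than deeper novelty. The transferred lineage is the best
hit's lineage truncated at the novelty rank: a new genus keeps the lineage
through family, a new phylum keeps only the domain.

An OTU is *unassigned* when its best-hit identity falls below
`assign_min_identity` (default 90%). The pipeline also reports pass/fail
at the two alignment screens of 75% (minimum to enter an alignment) and
90% (minimum to call a database match); the interesting dark fraction
typically lies between the two.

```{r}
library(mdmtriage)
refs <- read_fasta("refs.fasta")
lineages <- read_lineages("refs_lineage.tsv")
db <- reference_db(refs, lineages)
reps <- read_fasta("otus.fasta")
calls <- classify_otus(reps, db)
subset(calls, unassigned)
```

## Pairwise alignment and database search

The identity engine is an affine-gap Gotoh aligner (implemented in C++)
with two modes: *semiglobal* (global with free terminal gaps on both
sequences — the default for query-vs-reference comparisons) and *local*
(Smith–Waterman, used against contigs). Scoring defaults are +1/−1 with
gap open −2 and extension −1; a gap of length L costs
`gap_open + (L-1) * gap_extend`. Identity is computed over aligned columns
only, excluding terminal gaps, with internal gap columns counted in the
denominator (BLAST-like). Ambiguity codes, including N, never match — even
against themselves — so identity cannot be inflated by ambiguous bases.
Traceback tie-breaks (diagonal over gap-in-subject over gap-in-query;
closing a gap over extending it; end cell with the longest span) are part
of the documented contract and are mirrored by the independent
dynamic-programming oracle used in the tests.

The database search prefilters candidates by shared 8-mers (at least one
by default; correctness statements are made with the prefilter off, where
the search provably contains the best subject). Hits are ranked by
**alignment score, not identity**: under free-end-gap alignment a short
perfect end-overlap between unrelated sequences carries ~100% identity
over a handful of columns and would otherwise outrank a genuine
full-length 70%-identity hit. The identity of the best-scoring alignment
is what all threshold decisions consume. A practical corollary is that
best-hit identities below roughly the BEYOND_PHYLUM floor are not
meaningful — which is why the floor exists.

## Candidate selection

The "relative-abundance summary" of an OTU is, by default, the **sum**
across samples of its per-sample relative abundances, expressed in
percent. The aggregate is configurable (`sum`, `mean`, `max`) because the
choice is genuinely open: the sum mirrors pooling all samples of a survey,
the mean normalises for sample count, the max highlights single-sample
blooms. Selection keeps unassigned OTUs whose summary is *strictly*
greater than 0.5% — "higher than" is read literally, so a summary of
exactly 0.5% is excluded. The 50-read retention filter is applied first
and is inclusive (a 50-read OTU stays).

## Bimera model

Reference-based chimera screening models the query as a prefix of parent A
followed by a suffix of parent B. For each of the top-k candidate parents
(default 8), the semiglobal alignment is projected onto query coordinates
as a per-position match indicator (insertions in the query count as
mismatches). For every ordered parent pair and every breakpoint with at
least 50 bases on each side, the two-parent identity is the A-matches
before the breakpoint plus the B-matches after it. The query is CHIMERIC
when the best two-parent identity exceeds the best single-parent identity
by at least 2 percentage points (`min_delta`). Pairs with A = B are
included in the scan, so the gain is never negative.

The junction itself is only identifiable up to the run of breakpoints
between the flanking positions where the two parents differ; within that
run all breakpoints score identically. The scan therefore reports the
midpoint of the longest tied run, which is minimax-optimal: for parents at
10% mutual divergence the expected window is about ten bases, so the
reported junction is typically within ~5 bases of the true one, tighter
for more divergent parents. Flagged candidates are annotated, never
removed, since genuinely novel sequences can resemble bimeras of their
relatives.

## Verification

Primer QC covers GC content, nearest-neighbor melting temperature, the
longest self-complementary run, the 3'-terminal G/C clamp, and the Tm
difference within the pair. Acceptance windows (GC 40–60%, Tm 57–63 °C,
ΔTm ≤ 3 °C, self-dimer run ≤ 4) are conventional design defaults and are
configurable. Tm uses the unified nearest-neighbor parameter set of
Allawi & SantaLucia (1997), with duplex initiation terms, a symmetry
correction for self-complementary oligos,
Tm = ΔH / (ΔS + R ln k) − 273.15 with k = C_T/4 (C_T/1 when
self-complementary) at a total strand concentration of 0.5 µM, and the
salt correction ΔS + 0.368 (N−1) ln[Na+] at 50 mM monovalent salt. The
implementation was validated against an independently coded
nearest-neighbor oracle to within 0.1 °C; those values are frozen in the
test suite.

In-silico PCR matches the forward primer on the plus strand and the
reverse complement of the reverse primer downstream, tolerating at most 2
mismatches per site but requiring the 3 bases at each primer's 3' end to
match exactly. Amplification must be specific: zero or multiple products
mean no amplicon (non-specific amplifications are ignored). The recovered
amplicon passes verification when its identity to the original
representative exceeds 95% at exactly 100% query cover; identities in
(94.5, 95] at full cover are flagged REVIEW because they may still
represent the same genus (OTUs are 97% clusters, so a re-sequenced member
can legitimately differ from the representative).

## MAG cross-validation

Candidates are locally aligned to every contig sharing a k-mer; hits below
a minimal alignment score (default 40) are discarded as k-mer noise. A hit
*passes* when identity exceeds 96% and the contig belongs to a bin with
completeness ≥ 50% and contamination ≤ 10% (both inclusive). Hits to
unbinned contigs are retained as assembly-only evidence (ASSEMBLY_ONLY),
hits in failing bins carry BIN_QC, and hits covering less than half the
candidate carry LOW_COVER — flagged for human review rather than
auto-rejected, because partial overlaps can still be informative. The
report never claims an overlap longer than either sequence.

## Placement

Columns of the reference alignment whose gap fraction exceeds 0.70 are
masked. Each candidate is aligned to its best-identity reference in
ungapped coordinates and projected through that reference row's gap
pattern into the masked columns; candidate insertions relative to the
reference are discarded. This reference-coordinate projection mirrors
fragment-addition alignment and deliberately drops lineage-specific
inserts (such as the intervening sequences common in CPR 16S genes).
Distances are Jukes–Cantor over shared unambiguous columns; pairs sharing
fewer than 50 columns, or at p ≥ 0.75 (JC saturation), cannot be estimated
and are filled with 1.1 × the largest finite distance (and flagged) so
neighbor joining sees a complete matrix. Trees are canonical Saitou–Nei
neighbor joining via `ape::nj`, with tiny negative least-squares branch
lengths clamped to zero. "Located near lineage X" is operationalised as
the reference leaf minimising patristic distance; exact ties are broken
lexicographically and flagged AMBIGUOUS, and a PHYLUM_CONFLICT flag is
raised when the second-nearest reference disagrees at phylum level.
Neighbor joining replaces approximate-maximum-likelihood tree building
deliberately: the artifact needs placement adequate for taxonomic
attribution, not publication-grade phylogenetics.

## The synthetic community

`simulate_community()` generates every input the pipeline consumes, from a
single seed. It emulates:

- a rank-structured reference database (default 4 phyla × 2 classes × 2
  orders × 2 families × 2 genera = 64 references of 450 bases, the V3–V4
  amplicon scale) built by recursive substitution-only evolution with
  per-rank identity targets, which makes the reference alignment exact by
  construction; each phylum carries a private 12-base insert block whose
  columns are 75% gaps and therefore exercise the 0.70 mask;
- queries planted at controlled divergence bands: `evolve()` mutates until
  the identity *measured by the package's own aligner* is within ±1 point
  of target, and `plant_novel()` rejection-samples until the best database
  identity is at least 1 point inside the requested rank band — so band
  guarantees are definitionally true, not approximate;
- log-normal OTU counts across 8 samples at a depth of roughly 15–30k
  reads per sample, so that sub-percent planted OTUs can still clear the
  50-read retention filter, as they would at real survey depths;
- two-parent chimeras of cross-phylum references, contigs embedding the
  planted candidates (verbatim for primer targets, lightly mutated
  otherwise, one deliberately ~5% diverged), bins whose quality spectrum
  straddles both the 50% completeness and 10% contamination boundaries,
  and internal primer pairs for a subset of candidates.

Every generator writes machine-readable truth tables
(`truth/plants.tsv`, `truth/chimeras.tsv`, `truth/contigs.tsv`,
`truth/expected_mdms.tsv`); downstream tests read the truth, never
regenerate it. What the generator does **not** emulate: rRNA secondary
structure, sequencing error profiles and quality scores, PCR amplification
bias, variable 16S copy number, and the heterogeneity of real reference
databases. Passing tests therefore demonstrate that the pipeline's
decision rules are implemented exactly and recover planted structure under
idealised evolution; they do not certify performance on real amplicon
data.

## Numerical choices and problem sizes

- All thresholds live in `pipeline_config()` (the stage functions take
  them as arguments); the effective configuration is echoed into each
  report directory.
- The pipeline is deterministic: only the generator consumes random
  numbers, via R's global RNG, seeded once per simulation.
- Test and acceptance problem sizes were chosen to exercise every code
  path at seconds-to-minutes scale: a 64-reference community with ~31
  OTUs for end-to-end runs, a 16-reference database for the 100+100
  bimera sensitivity/specificity suite, 200 random pairs of length ≤ 40
  for the exact alignment-oracle comparison, and 50 additive 5-taxon
  matrices (verified against exhaustive search over all 15 topologies)
  for neighbor joining.

## Known limitations

- Best-hit identities below ~60% are dominated by alignment noise; the
  BEYOND_PHYLUM floor marks, rather than interprets, that regime.
- The k-mer prefilter can miss a true best hit for queries with no shared
  8-mer (prefilter-off search is the correctness surface).
- The bimera model considers exactly two parents and one breakpoint;
  multi-parent chimeras will usually, but not provably, still trip it.
- Placement quality degrades for fragments whose best reference is itself
  distant (new-phylum candidates); the PHYLUM_CONFLICT flag is the
  honest signal of that uncertainty.
- In-silico PCR is a string-matching model: primer thermodynamics beyond
  the QC report (hairpins, heterodimers, annealing kinetics) are out of
  scope.
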