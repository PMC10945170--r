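---
title: "Mining public sequences into a partitioned supermatrix: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining public sequences into a partitioned supermatrix: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(locusharvest)
```

`locusharvest` turns a local snapshot of heterogeneous sequence
records into a species-level concatenated matrix with contiguous
per-locus partitions. This vignette explains the model behind each
stage, the parameters that matter, the numerical and design choices
made where the procedure was genuinely open, and what the synthetic
test data can and cannot certify.

## The problem

Public archives hold, for a well-studied family such as the pierid
butterflies, thousands of sequence records deposited over decades:
under outdated names, as partial fragments, from multiple specimens
per species, and occasionally cross-contaminated between projects.
Target-capture datasets add a second shape of input — a small curated
locus kit (13 loci) nested inside a large one (425 loci, sharing ids
1–13). Building a defensible supermatrix requires explicit, auditable
rules for name validity, representative choice, fragment combination,
contamination, and concatenation. Each rule here is small; the value
is that all of them are deterministic, logged, and property-tested.

## Name resolution

A synonymy table (`published_name, valid_name, family`) is the single
authority for name validity; no live name service is consulted.  On
load the table is closed transitively (chains `A→B`, `B→C` become
`A→C`; cycles are an error), and a self-row is inserted for every
valid name, which makes resolution idempotent.  Lookup tries the exact
published string first, then a normalized form: case-fold, strip
parenthesized and 4-digit (authority/year) tokens, truncate to
genus + epithet.  Truncation collapses trinomials, i.e. subspecies are
merged into their species — the terminals of the output matrix are
species.  Unresolved names are a *value*, quarantined into the
exclusion report, never a silent drop: a mined dataset must be
auditable record by record.

## Hit filtering and pooling

Hits arrive as 12-column tabular search output with the bait locus as
the query. Coordinates are converted once, at ingestion, from 1-based
inclusive to 0-based half-open; minus-strand hits are normalized so
bait coordinates ascend; everything users see is emitted back as
1-based inclusive. Three thresholds gate a hit — `evalue_max` (1e−10),
`pident_min` (80%), `min_hit_len` (100 bp) — all configurable because
the procedure fixes none of them canonically; the defaults are
conventional for mining curated loci of congeneric taxa. Each subject
is then assigned to the single bait locus of its best bitscore (ties:
lowest locus id), and candidate pools are keyed by
(valid species × locus).

## Representative selection

"Longest with the most unambiguous content" admits two readings:
length first or ambiguity first. We operationalize the key as
**unambiguous base count desc, total length desc, accession asc**:
unambiguous positions are the ones that inform inference, so a 500 bp
clean sequence should beat a 600 bp sequence with 150 `N`s (it does:
500 > 450). The accession tie-break (C-locale byte order) makes
selection a total order, so permuting pool input can never change the
choice — a property the suite tests directly. When a self-search table
is supplied, the top-ranked candidate must have its best non-self hit
resolve to the same valid species (top-1 rule; a genus-rank relaxation
is a flag); a failure demotes to the next-ranked candidate and is
logged. With no table, verification is recorded `skipped` rather than
silently passed.

## Contamination screen

Any identity-table row pairing two snapshot records at ≥ 99% identity
over ≥ 100 bp whose species resolve to different families flags
contamination. The rule is symmetric — both members of such a pair are
"99% similar to a species in another family" — and it runs *before*
pooling, so a contaminant can never win a pool. Identity values are
consumed from a precomputed pairwise table (any local aligner's
output) to keep the toolkit self-contained; the fixture generator
computes its identities analytically from planted mutation counts.

## Tiling

When no single record spans a bait, fragments are combined. The
objective is lexicographic: **maximize covered bait positions, then
minimize the number of tiles**. On intervals this is solved exactly:
the union of all tiles fixes the attainable coverage; within each
maximal segment of that union, greedy farthest-reach interval covering
yields a minimum-cardinality cover, and any minimum cover is
automatically irredundant (a tile contained in the union of the others
could be deleted). Ties prefer the farther-reaching tile, then the
individually larger one, then the smaller accession. Tiling is applied
per locus. The suite checks the greedy solution against exhaustive
subset search (a bitmask DP over all 2ⁿ subsets) on hundreds of seeded
random tile sets.

Overlapping chosen tiles are stitched on the bait coordinate frame;
at overlaps the residue comes from the tile whose interval starts
first, and disagreements are counted and reported (mined records carry
no quality scores that could arbitrate). Placement uses the hit's
subject interval directly, i.e. it is indel-free; length mismatches
are trimmed or `N`-padded and logged. Real mined loci would be
re-aligned downstream (alignment itself is deliberately outside this
toolkit); the per-locus FASTA writer exists exactly for that handoff.

In the full pipeline the two rules compose as follows: the ranked
best sequence is the pool's representative whenever its own hit
intervals reach the pool's coverage ceiling; only otherwise is the
multi-specimen tiling solution used. This keeps single-record pools
under the selection key (where tiling's accession tie-break could
otherwise disagree with it) and reserves specimen-combination for the
case that motivates it — no available sequence fully covers the bait.

## Consensus, grafting, merging, concatenation

*Consensus.* Copies collapse column-wise to the minimal IUPAC code
covering the union of observed bases (`A`+`R` → `R`; `T`+`A` → `W`);
gaps are ignored unless a column is all-gap. Union rather than
majority: with no stated collapse rule, preserving every observed
state is the conservative choice, and union consensus is idempotent.

*Grafting.* A chimeric terminal adds one conspecific donor's COI
(locus id 1 by default; configurable, since the kit numbering does not
pin the barcode) to a recipient that has more loci but lacks COI.
Same-species is enforced, an existing COI is never overwritten, donor
non-COI loci are never copied, and per-locus provenance is recorded.
The default pipeline does not call this stage: its pools are keyed by
species, so conspecific specimens' loci already merge, with tiling
provenance recording every contributing accession; `build_chimera`
serves the specimen-keyed workflow.

*Merging.* The 13-locus kit's loci are the same loci, ids 1–13, of
the 425-locus kit, so the mapping is the identity; a species
contributed by both sets at one locus is resolved by the selection key
and logged.

*Concatenation.* Loci ascend by id, species rows sort in C-locale,
missing blocks fill with `-` (configurable to `?`; downstream
inference accepts both), partitions are prefix sums emitted 1-based
inclusive. Occupancy reports loci-present counts and the non-missing
site fraction per species (with `-` as the missing character,
within-locus alignment gaps count as missing too — a documented
conflation). Width conservation and partition-slicing round-trips are
property-tested over hundreds of random matrices.

The sampling-fraction helper is plain percent arithmetic
(`100·n/N`, default-rounded to integer for reporting, full precision
available for export): with 593 of 1,159 described species sampled it
prints 51, and 541 of 593 phylogeny species prints 91.

## The synthetic-data generator

`generate_snapshot()` emulates a mined snapshot with planted, provably
unique truths, from one seeded RNG stream (same spec + seed ⇒
byte-identical files):

* per-locus random reference baits of 450–750 bp; per-species true
  sequences at 2% substitution distance — typical congeneric
  divergence at conserved nuclear loci;
* per pool, one full-length fully-unambiguous intended best and
  decoys that are strictly dominated by construction (truncated to
  50–80%, or carrying ≥ 1 `N` at `ambiguity_rate`, default 0.1), so
  recovery must be 100% under the stated key at any ambiguity level;
* per bait, a 3-tile chain in which every chain tile covers at least
  one position privately, plus decoy tiles contained in chain tiles —
  making the chain the *unique* optimum of the tiling objective;
* organism strings drawn from valid names, generated synonyms,
  trinomials and authority-decorated forms, exercising resolution;
* contaminants as a cross-family cluster of near-identical (≈ 99.5%)
  copies of one bait reference, attached alternately to focal- and
  other-family species and linked pairwise in the identity table.
  Under the symmetric screen a *single* contaminant cannot be flagged
  without flagging its cross-family partner, so
  `contaminant_count = 1` is rejected as infeasible (use 0 or ≥ 2);
* threshold-failing and cross-locus junk hits, and occasional
  minus-strand fragments, so filtering, locus assignment and strand
  normalization are all load-bearing in end-to-end tests.

What passing on this generator shows: the selection, screening,
tiling, and concatenation rules are implemented exactly, and the
pipeline is deterministic and lossless in its accounting. What it does
not show: robustness to alignment error, indels, paralogy, or
mislabeled vouchers — real-data hazards that the generator
deliberately does not simulate (fragments are indel-free substrings;
identity values are exact; every name resolves).

## Problem sizes and numerical choices

The test suite and the acceptance script run at desk scale, chosen as
the package's own verification sizes: 500 random tile sets of ≤ 12
tiles against the exhaustive oracle, a 50-species × 20-locus snapshot
(≈ 3,000 records) end-to-end, 200 random fixtures per round-trip
property. Coordinates are integers throughout; no floating-point
comparison enters any decision rule except percent-identity
thresholds, which are compared with `>=` on the values as given. All
orderings that reach an output file are explicit radix (C-locale)
sorts, which is what makes byte-identical reruns a testable contract
rather than an aspiration.

## Known limitations

* Bait-frame placement is indel-free; loci from diverged taxa need
  downstream re-alignment before tree inference.
* The screen and verification trust their input tables; no aligner or
  search engine is bundled.
* Subspecies collapse to species; workflows needing infraspecific
  terminals must pre-edit the synonymy table.
* Occupancy's site fraction conflates missing blocks with within-locus
  gaps when the missing character is `-`.
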