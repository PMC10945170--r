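# locusharvest

Assembling a species-level, multilocus phylogenetic supermatrix from
public sequence archives is mostly bookkeeping, and the bookkeeping is
where datasets quietly go wrong: the same butterfly is deposited under
three historical names, a species has six partial COI fragments and one
full-length one, a capture library carries a read that is 99% identical
to a species in a different family, and two target-capture datasets
(a 13-locus kit and a 425-locus kit sharing those 13 loci) must be
merged without duplicating terminals. `locusharvest` implements that
pipeline as a tested R library with a thin command-line front end, for
systematists building concatenated matrices from heterogeneous local
snapshots of sequence records.

## What it computes

Given a snapshot (FASTA + tabular metadata), BLAST-style tabular hits
of the records against a set of *bait* loci, and a synonymy table, the
pipeline:

1. **Resolves names.** Published names (synonyms, trinomials, names
   with authorities) map to valid species through the synonymy table;
   chains collapse transitively, and resolution is idempotent.
2. **Screens contamination.** Any pair of records with pairwise
   identity ≥ 99% over ≥ 100 bp whose species lie in *different
   families* flags both records; flagged records never enter a pool.
3. **Filters hits** (e-value ≤ 1e−10, identity ≥ 80%, length ≥ 100 bp
   by default) and assigns each record to the single bait locus of its
   best bitscore.
4. **Selects representatives.** Per (species × locus) pool the chosen
   record maximizes the number of unambiguous bases
   `|{i : sᵢ ∈ {A,C,G,T}}|`, with ties broken by total length, then
   accession — a total deterministic order. An optional self-search
   check verifies that the best non-self hit of the chosen record is
   conspecific; failures demote to the next-ranked candidate.
5. **Tiles fragments.** When no single record spans a bait, fragments
   are tiled along it under the lexicographic objective
   *(maximize covered positions, then minimize tile count)*, solved
   exactly by greedy farthest-reach interval covering per coverable
   segment; one species may thus combine specimens.
6. **Concatenates.** Per-locus rows (bait coordinate frame) become a
   partitioned supermatrix: missing blocks filled with `-`, RAxML-style
   partition lines `DNA, L<id> = <start>-<end>`, per-species occupancy,
   per-accession provenance, and machine-readable exclusion reports, so
   `#input records = #records in provenance + #records excluded` always
   holds.

Also included: IUPAC union consensus for collapsing sequence copies
(`collapse_consensus`), COI grafting between conspecific specimens
(`build_chimera`), 13↔425 locus-set merging (`map_loci`), sampling-
fraction arithmetic for diversification analyses
(`sampling_fraction`), and a seeded synthetic-snapshot generator with
planted ground truth (`generate_snapshot`) that makes every stage
testable offline.

## Worked example

```r
library(locusharvest)

spec <- fixture_spec(n_species = 10, n_loci = 5,
                     contaminant_count = 3, seed = 11)
manifest <- generate_snapshot(spec, "fixture_demo")

rc <- run_config("fixture_demo/snapshot.fasta", "fixture_demo/metadata.tsv",
                 "fixture_demo/hits.tsv",       "fixture_demo/baits.tsv",
                 "fixture_demo/synonymy.csv",   "matrix_demo",
                 identity = "fixture_demo/identity.tsv")
res <- run_pipeline(rc)

res$supermatrix
#> supermatrix: 10 species x 2970 sites in 5 loci; mean non-missing fraction 1.000
table(res$exclusions$reason)
#> contamination  not_selected
#>             3           100
readLines("matrix_demo/partitions.txt")[1:2]
#> [1] "DNA, L1 = 1-699"    "DNA, L2 = 700-1182"
```

The three `contamination` exclusions are exactly the planted
cross-family contaminants; `not_selected` are pool candidates that
lost to the per-pool representative. The stage functions work alone,
too:

```r
select_best(data.frame(accession = c("AB1", "AB2"),
                       length_bp = c(500L, 600L),
                       unambiguous_count = c(500L, 450L)))
#> selection_result: chosen = AB1 of 2 candidate(s)   (500 > 450 unambiguous)

tile_select(data.frame(accession = c("a", "b", "c", "d"),
                       start = c(0, 39, 0, 69), end = c(60, 100, 30, 100)), 100)
#> tiling_solution: 2 tile(s) covering 100 bait position(s) from 2 specimen(s)

collapse_consensus(c("ACGT", "ACGA"))
#> [1] "ACGW"
sampling_fraction(593, 1159)   # clade coverage of a 593-species phylogeny
#> [1] 51
```

The command line mirrors this: `lh fixtures`, `lh run --config
run.yaml`, `lh resolve`, `lh tile` (script at
`system.file("cli/lh.R", package = "locusharvest")`).

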