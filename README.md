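# tecurate

Curation of DNA transposon families from a genome assembly: from seed
homology hits to family consensus sequences, element termini and target site
duplications (TSDs).

## The problem

Insertion-sequence-like DNA transposons in AT-rich protist genomes (the
*IS481EU* group found in parabasalids such as *Trichomonas vaginalis*) are
recognised by three structural diagnostics:

* **terminal signature** — elements begin with `TNT` and end with `AYA`
  (strictly `TGT..ACA`, the `TG..CA` pair shared with IS*3*/IS*481* and
  retroviral ends);
* **terminal inverted repeats (TIRs)** — reverse-complementary repeats at
  the two extremities, mostly shorter than 50 bp;
* **target site duplications** — the short direct repeat of host DNA created
  on both sides of an insertion. Unusually, this group produces TSDs of
  *discrete* lengths (~4 bp, ~15 bp or ~25 bp), and the different lengths
  co-occur within a single family.

Curating such families by hand means: search the genome with a transposase
protein, cluster the hits, build a majority-rule consensus, stretch it
outward through the flanks until the copies stop agreeing, and then decide
where the element really ends using the signature and the per-copy TSDs.
`tecurate` implements that workflow as reproducible, testable code, plus a
synthetic-genome generator that provides exact ground truth for every stage.

## The method

* **Seed-and-extend homology search** (`search_protein_seeds`,
  `search_nucleotide`): six-frame translation, exact k-mer seeding, ungapped
  X-drop extension (BLOSUM62 for protein, +1/−1 for nucleotide), gapped
  refinement, deterministic merging. Every parameter lives in
  `search_config()`.
* **Family building** (`cluster_sequences`, `majority_consensus`,
  `elongate_consensus`): single-linkage clustering at 75% identity / 75%
  coverage of the shorter sequence; per-column 50%-majority consensus
  (covering rows only, winning gap deletes the column, ties resolved in the
  fixed order `- > A > C > G > T`); iterative elongation that re-searches the
  genome and grows the consensus outward while ≥ 50% of covering copies
  agree and at least two copies cover the column.
* **Boundary determination** (`find_termini`, `call_tsd`, `detect_tir`):
  a TSD call is the largest L ≤ 35 for which the length-L suffix of the left
  flank matches the length-L prefix of the right flank within a mismatch
  budget (0 below 10 bp, ⌊L/8⌋ at 10 bp and above). Candidate termini are
  signature positions near the copy-flank divergence point; each candidate
  pair scores the number of copies with a supporting TSD (+1 for strict
  `TGT..ACA`, +0.5 for a detectable TIR). TSD lengths are binned into the
  discrete classes `~4` (2–6 bp), `~15` (14–17 bp), `~25` (24–29 bp).
* **Reporting** (`name_family`, `family_table`, `copy_boundary_listing`):
  the published naming convention (`IS481EU-7_TV`, non-autonomous partners
  `IS481EU-4N1_TV`, orphans `IS481EU-N1_TV`), a per-family distribution
  table, and plain-text boundary listings with bracketed TSDs (at most 5
  representative copies).
* **Simulation** (`simulation_config`, `simulate_genome`,
  `evaluate_calls`): genomes with implanted families exhibiting exactly the
  structure above, with exact per-copy truth and an evaluator.

## Worked example

```r
library(tecurate)

cfg <- simulation_config(genome_length = 60000L, n_families = 3L,
                         copies_per_family = 6L, seed = 1L)
sim <- simulate_genome(cfg)                      # genome + truth + seeds
res <- run_pipeline(sim$genome, sim$seeds, species_tag = "TV")
res$table
```

```
  species_tag        family       autonomy copies_with_both_termini  tsd_classes tir_length consensus_length
1          TV  IS481EU-1_TV     autonomous                        6   ~4:3,~15:2         25             1225
2          TV IS481EU-N1_TV non-autonomous                        5   ~4:2,~15:1         25             1457
3          TV IS481EU-N2_TV non-autonomous                        4 ~4:4,other:1         25             1217
```

Three implanted families are recovered; each row reports how many genomic
copies align to within 5 bp of both consensus ends, the census of TSD length
classes among those copies, the TIR length and the consensus length. (This
deliberately harsh little simulation — six copies per family, 5%
substitutions, indels, truncations, degenerate TSD copies — also shows the
failure modes: with so few copies a single consensus indel can frameshift
the transposase ORF, so two families are mis-labelled non-autonomous, and a
degenerate short TSD can surface as an off-class call. At ten or more copies
per family these artefacts largely disappear; see the methods vignette.)

A boundary listing for the first family (TSD copies bracketed):

```
chr1:9065-10526(+)  TATTATTAATCATGCT[GCTGAGTTAAGTTT] TGTATTGAAG...CTTCAATACA [GCTGCGTTAAGTTT]CGTCGTTTACCTATCT
chr1:23515-24972(+) GCTATCACTCACTACTTCTAGAGTC[TTAAA] TGTATTGAAG...CTTCAATACA [TTAAA]CTATGAATGCATTTTAAACACTGTC
```

The `analysis/` directory runs the same workflow as a five-stage narrative
(`01_simulate.R` … `05_report.R`), writing its tables under `results/`.

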