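---
title: "Curating transposon families: consensus building, termini and TSD classes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curating transposon families: consensus building, termini and TSD classes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(tecurate)
```

## The procedure and its assumptions

`tecurate` reconstructs DNA transposon families of the insertion-sequence
type found in parabasalid genomes. The curation loop mirrors how such
families are characterised by hand:

1. **Search.** Protein seeds (known or suspected transposases) are matched
   against a six-frame translation of the genome by exact k-mer seeding and
   ungapped X-drop extension under BLOSUM62; surviving extensions are mapped
   back to forward-strand nucleotide coordinates, chained and merged. The
   search is a transparent, fully parameterised stand-in for black-box
   repeat-detection tools: it assumes nothing beyond local sequence
   similarity, and identical inputs always produce byte-identical hit
   tables.
2. **Cluster.** Up to 10 copies per seed are extracted with 5 kb flanks and
   clustered by single linkage: two copies are linked when an end-gap-free
   global alignment reaches 75% identity over aligned columns *and* spans
   75% of the shorter sequence. Coverage on the shorter sequence means a
   truncated copy still joins its family; single linkage means a chain of
   intermediate copies can connect diverged ones.
3. **Consensus.** Members are aligned to the longest member (center-star,
   "once a gap, always a gap") and condensed by the 50% majority rule per
   column, counting only rows that cover the column.
4. **Elongate.** The consensus is re-searched against the genome and grown
   outward one column at a time while at least half of the covering copies
   agree on a single character and at least two copies cover the column.
   The procedure assumes element copies are embedded at unrelated sites, so
   flank agreement collapses right where the element ends.
5. **Boundaries.** The exact termini are chosen among signature positions
   (`TNT..AYA`, strictly `TGT..ACA`) near the point where copy flanks stop
   matching the consensus, scored by how many copies show a target site
   duplication there. TSD lengths are then binned into the discrete classes
   `~4` (2–6 bp), `~15` (14–17 bp), `~25` (24–29 bp) that are diagnostic for
   this group — including mixtures of classes within one family.
6. **Report.** Autonomy (a retained ≥ 300-codon ORF), the published naming
   convention (`IS481EU-{serial}_{tag}`, with `N` marking non-autonomous
   families), a per-family table and bracketed per-copy boundary listings.

## Parameters that matter

| parameter | default | unit | rationale |
|---|---|---|---|
| `min_identity`, `min_coverage` (clustering) | 0.75 / 0.75 | fraction | the standard coverage/identity thresholds for family-level clustering of element copies |
| majority threshold | 0.5 | fraction of covering rows | 50% majority rule; below it a column emits `N` |
| `flank` | 5000 | bp | flanking sequence kept per copy, enough to elongate a partially recovered consensus to full element length |
| `max_copies` | 10 | copies | copies used per family for consensus building; more adds little once the majority is stable |
| `max_tsd` | 35 | bp | longest candidate TSD; comfortably above the ~25 bp class |
| TSD mismatch budget | 0 below 10 bp, ⌊L/8⌋ above | mismatches | short TSDs must be exact (a 4-mer with one error is indistinguishable from chance), long ones may be degenerate — a 25 bp TSD tolerates 3 |
| `min_support_len` | 3 | bp | shortest TSD that counts as terminus support; 1–2 bp agreements arise at ~25%/6% of random junctions and, systematically, at candidate pairs shifted into the element |
| `window` | 30 | bp | candidate half-width around the copy-flank divergence point |
| `min_tir_len` / TIR identity | 8 / 0.8 | bp / fraction | below this, end-to-end self-similarity is indistinguishable from chance in a 100 bp scan |
| `min_orf_codons` | 300 | codons | a transposase-length ORF; the simulator embeds 350-codon ORFs, so the threshold separates intact from frameshifted consensi |
| elongation support | ≥ 50% agreement, ≥ 2 covering copies | — | the 2-copy floor prevents a single copy's flank from being promoted into the consensus |

## What the simulator emulates — and what it does not

`simulate_genome()` produces an AT-rich background (GC 0.33 by default, a
generic protist-like composition), implants per-family element templates
with the `TGT..ACA` signature, a 25 bp TIR (the reverse complement of the
element start, which automatically preserves the signature) and, for
autonomous families, an embedded 350-codon ORF. Copies receive: a TSD drawn
from the discrete regime (default weights 0.7/0.2/0.1 over jitter sets
{4,5}, {14,15,16}, {24,25}), a uniformly random strand, per-base
substitutions and single-base indels, optional degeneracy of the right TSD
copy, and truncation of 10–90% of one end with probability 0.2. Insertion
sites are mutually spaced (twice the longest TSD) so copies never nest.
Ground truth records every choice, and `evaluate_calls()` scores a pipeline
run against it.

What it does *not* model: nested insertions, other repeat families in the
background, compositional heterogeneity (isochores, low-complexity runs),
CpG-like mutation bias, segmental duplications, or assembly artefacts other
than `N` gaps. Passing tests on this substrate therefore certify the
*logic* of the pipeline — recovery of implanted structure under controlled
noise — not its performance on a real, repeat-rich assembly, where seed
choice and the background repeat landscape dominate.

## Numerical choices

* **Coordinates** are 1-based inclusive in memory (the R/Bioconductor
  convention); every on-disk TSV writes 0-based half-open intervals,
  converted at the boundary.
* **TSD scanning** runs from `max_len` down and returns the first length
  within budget. Suffix/prefix comparisons at different lengths are mutually
  shifted, so a true duplication of length L scores ~75% mismatches at any
  other candidate length — the top-down scan cannot over- or under-call a
  clean duplication.
* **Majority ties** break in the fixed order `- > A > C > G > T`; a winning
  gap deletes the column. Elongation requires a *unique* winning character.
* **Terminus scoring**: support count first, then (on ties) summed TSD
  length, then the smaller 5' position. Strict `TGT..ACA` adds 1, a
  detectable TIR adds 0.5 — copy evidence dominates, the bonuses only break
  near-ties. A side with no signature candidate in the window falls back to
  its divergence point while the other side is still optimised.
* **Anchoring slack**: an end-gap-free alignment trims terminal mismatches,
  so a noisy copy may "miss" the consensus end by a base or two; anchors
  extrapolate up to 3 bp without gaps. Likewise a copy only counts as
  "retaining both termini" when its alignment reaches within 5 bp of both
  consensus ends.
* **TIR detection** aligns the first 100 bases against the reverse
  complement of the last 100 locally and requires the alignment to start
  within 2 bp of both extremities; an ends-free global alignment cannot clip
  the non-repeat remainder of both windows at once and would bury a 25 bp
  TIR in ~75 forced random columns.
* **Assembly gaps**: hits and TSD windows never cross a run of ≥ 10 `N`;
  shorter runs count as mismatches.
* **Degenerate inputs**: empty flanks give a zero-length call, not an
  error; a single-copy family elongates nowhere (2-copy floor) and keeps
  unresolved termini; a consensus that no longer matches the genome raises
  a "family lost" error.

## Design choices where the procedure was genuinely open

* *Copies retaining both termini* is operationalised as: the copy's
  alignment reaches within 5 bp of both consensus ends. Some such copies
  still lack a callable TSD (degenerate short TSDs are rejected by design),
  so the census reports TSD-bearing copies separately from the count.
* Clustering is **not** repeated after elongation; families are fixed by the
  initial pass. Re-clustering elongated consensi could merge families that
  share termini but differ internally, which is exactly the distinction the
  census is meant to preserve.
* Non-autonomous families are assigned to an autonomous *parent* (for the
  `{k}N{j}` name) when their consensus aligns to the parent's at ≥ 75%
  identity over ≥ 50% of the shorter sequence; otherwise they are named as
  orphans (`N1`, `N2`, …).
* The TSD class bins are configurable; whether a 2–3 bp call reflects a real
  short duplication or noise cannot be decided from sequence alone, which is
  why `~4` extends down to 2 bp but terminus support starts at 3 bp.
* The `Hit` identity of a chained hit is the length-weighted mean of its
  parts; chaining repairs X-drop fragmentation across diverged patches
  (gap ≤ 90 bp on the same strand) without attempting intron-scale
  reconstruction.

## Problem sizes used by the tests

The test-suite simulations are sized for a desk-scale run: closure uses 10
families × 10 copies (≈ 330 kb of genome), noise recovery uses 10 families
× 30 copies at 5% substitutions in 3–5 seeded replicates (≈ 550 kb each),
the census fixture implants 31 copies of one family, and the
strand/determinism checks use 4 families × 8 copies. The acceptance script
re-runs the same computations from a caller-supplied seed.

## Known limitations

* Elongation votes are ungapped beyond each copy's anchor, so a copy
  desynchronises at its first indel past the current consensus end; rounds
  re-anchor, but with few copies (≤ 6) and truncation the covering set near
  one terminus can shrink until a voting error survives into the consensus.
  The README's worked example shows exactly this: one family's terminal
  bases corrupted, leaving an off-class TSD call.
* A consensus indel inside the ORF frameshifts the autonomy call; at 10+
  copies the majority rule removes such indels, at ≤ 6 copies it may not.
* The search is not a sensitivity-matched replacement for dedicated repeat
  annotators; its contract is transparency and determinism, not parity with
  tools whose settings are unpublished.
* Nested or tandem-inserted copies are out of scope (the simulator never
  generates them; on real data they would blur the divergence points that
  bound the terminus search window).
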