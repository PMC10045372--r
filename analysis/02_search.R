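#!/usr/bin/env Rscript
# Stage 2: translated homology search.
#
# Six-frame seed-and-extend search of the protein seeds against the genome;
# the resulting hit table (sorted, deterministic) is the input to family
# building.

library(tecurate)

genome <- read_fasta(file.path("results", "sim", "genome.fa"), "nucleotide")
seeds <- read_fasta(file.path("results", "sim", "seeds.fa"), "protein")
dir.create(file.path("results", "search"), showWarnings = FALSE)

cfg <- search_config()
hits <- search_protein_seeds(genome, seeds, cfg)
write_hits(hits, file.path("results", "search", "hits.tsv"))

cat(sprintf("%d hits from %d seeds on %d contig(s)\n",
            nrow(hits), length(seeds), length(genome)))
cat("hits per seed:\n")
print(table(hits$query_id))
cat(sprintf("median hit length %d bp, median identity %.3f\n",
            as.integer(median(hits$end - hits$start + 1)),
            median(hits$identity)))
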