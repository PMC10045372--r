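#!/usr/bin/env Rscript
# Stage 1: build the synthetic study genome.
#
# Ten transposon families (TGT..ACA termini, 25 bp TIRs, a transposase-length
# ORF), ten copies each, implanted with discrete-regime TSDs (~4 bp 70%,
# ~15 bp 20%, ~25 bp 10%), 5% substitutions, occasional indels, degenerate
# right TSD copies and 20% truncations — the realistic end of the conditions
# the pipeline is meant to survive. Writes the genome, the element templates,
# the protein seeds and the exact per-copy ground truth.

library(tecurate)

out <- file.path("results", "sim")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- simulation_config(seed = 42L)
sim <- simulate_genome(cfg)

write_fasta(sim$genome, file.path(out, "genome.fa"))
write_fasta(sim$templates, file.path(out, "templates.fa"))
write_fasta(sim$seeds, file.path(out, "seeds.fa"))
write_truth(sim$truth, file.path(out, "truth.tsv"))
writeLines(paste(names(unclass(cfg)),
                 vapply(unclass(cfg), function(x)
                   paste(deparse(x), collapse = ""), character(1)),
                 sep = " = "),
           file.path(out, "config.txt"))

cat(sprintf("genome: %d bp, %d contig(s)\n",
            nchar(sim$genome[[1]]$residues), length(sim$genome)))
cat(sprintf("implanted: %d copies across %d families\n",
            nrow(sim$truth), cfg$n_families))
cat(sprintf("truncated copies: %d; TSD length table:\n",
            sum(sim$truth$truncated_5 > 0 | sim$truth$truncated_3 > 0)))
print(table(sim$truth$tsd_length))
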