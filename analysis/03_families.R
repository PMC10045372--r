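#!/usr/bin/env Rscript
# Stage 3: cluster hit copies and build elongated consensus sequences.
#
# Up to 10 copies per seed are extracted with 5 kb flanks, clustered by
# single linkage at 75% identity / 75% coverage, turned into 50%-majority
# consensi, and iteratively elongated through the flanks until the copies
# stop agreeing (i.e. past both element ends).

library(tecurate)

genome <- read_fasta(file.path("results", "sim", "genome.fa"), "nucleotide")
hits <- read_hits(file.path("results", "search", "hits.tsv"))
out <- file.path("results", "families")
dir.create(out, showWarnings = FALSE)

cfg <- search_config()
copies <- list()
for (q in unique(hits$query_id)) {
  regs <- extract_hit_regions(genome, hits[hits$query_id == q, ],
                              flank = 5000L, max_copies = 10L)
  for (r in regs) copies[[r$copy_id]] <- r
}
cat(sprintf("extracted %d unique copy regions\n", length(copies)))

copy_seqs <- lapply(copies, function(r) named_seq(r$copy_id, r$copy,
                                                  "nucleotide"))
clusters <- cluster_sequences(unname(copy_seqs))
cat(sprintf("%d clusters (sizes: %s)\n", length(clusters),
            paste(vapply(clusters, function(cl) length(cl$member_ids),
                         integer(1)), collapse = ", ")))

members <- do.call(rbind, lapply(seq_along(clusters), function(i) {
  cl <- clusters[[i]]
  data.frame(member_id = cl$member_ids, cluster_id = sprintf("cluster%02d", i),
             representative = cl$member_ids == cl$representative)
}))
write.table(members, file.path(out, "members.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

nidx <- genome_index(genome, cfg, "nucleotide")
consensi <- list()
for (i in seq_along(clusters)) {
  cl <- clusters[[i]]
  cons0 <- consensus_record(sprintf("cluster%02d", i),
                            majority_consensus(align_members(cl)),
                            copy_support = length(cl$member_ids))
  el <- elongate_consensus(cons0, genome, cfg, index = nidx)
  cat(sprintf("%s: %d members, consensus %d -> %d bp in %d round(s)\n",
              cons0$name, length(cl$member_ids), nchar(cons0$residues),
              nchar(el$residues), el$rounds))
  consensi[[el$name]] <- named_seq(el$name, el$residues, "nucleotide")
}
write_fasta(consensi, file.path(out, "consensus_elongated.fa"))
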