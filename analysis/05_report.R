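#!/usr/bin/env Rscript
# Stage 5: autonomy, naming, the family table and the evaluation.
#
# Each trimmed consensus is classified autonomous when it retains a long
# (>= 300 codon) ATG-initiated ORF, families are named with the published
# convention (the letter N marks non-autonomous families), and because this
# genome is synthetic the whole run is scored against the implanted truth.

library(tecurate)

bdir <- file.path("results", "boundaries")
consensi <- read_fasta(file.path(bdir, "consensus_trimmed.fa"), "nucleotide")
term <- read.delim(file.path(bdir, "termini.tsv"))
truth <- read_truth(file.path("results", "sim", "truth.tsv"))
templates <- read_fasta(file.path("results", "sim", "templates.fa"),
                        "nucleotide")
out <- file.path("results", "report")
dir.create(out, showWarnings = FALSE)

read_calls <- function(nm) {
  df <- read.delim(file.path(bdir, paste0(nm, "_tsd_calls.tsv")),
                   colClasses = "character")
  lapply(seq_len(nrow(df)), function(i) {
    structure(list(copy_id = df$copy_id[i],
                   length = as.integer(df$tsd_length[i]),
                   mismatches = as.integer(df$mismatches[i]),
                   left_seq = ifelse(is.na(df$left_seq[i]), "",
                                     df$left_seq[i]),
                   right_seq = ifelse(is.na(df$right_seq[i]), "",
                                      df$right_seq[i]),
                   class_label = df$class_label[i]), class = "tsd_call")
  })
}

labels <- vapply(names(consensi), function(nm)
  classify_autonomy(consensi[[nm]]$residues)$label, character(1))

existing <- character(0)
families <- list()
calls_by <- list()
serial <- 0L
serial_of <- setNames(rep(NA_integer_, length(consensi)), names(consensi))
for (nm in names(consensi)[labels == "autonomous"]) {
  serial <- serial + 1L
  serial_of[nm] <- serial
  existing <- c(existing, name_family(serial, "SIM", "autonomous",
                                      existing = existing))
  names(existing)[length(existing)] <- nm
}
for (nm in names(consensi)[labels == "non-autonomous"]) {
  parent <- NULL; best <- 0
  for (an in names(consensi)[labels == "autonomous"]) {
    p <- pair_identity(consensi[[nm]]$residues, consensi[[an]]$residues)
    if (p$identity >= 0.75 && p$coverage >= 0.5 && p$identity > best) {
      best <- p$identity; parent <- serial_of[an]
    }
  }
  existing <- c(existing, name_family(1L, "SIM", "non-autonomous",
                                      parent = parent, existing = existing))
  names(existing)[length(existing)] <- nm
}

for (nm in names(consensi)) {
  fname <- unname(existing[names(existing) == nm])
  cons <- consensus_record(fname, consensi[[nm]]$residues)
  cons$termini_resolved <- TRUE
  cons$terminus_5 <- 1L
  cons$terminus_3 <- nchar(cons$residues)
  calls <- read_calls(nm)
  trow <- term[term$cluster == nm, ]
  tir <- structure(list(length = trow$tir_length, identity = NA,
                        present = trow$tir_present), class = "tir_report")
  families[[fname]] <- family_record(fname, "SIM", cons, labels[[nm]],
                                     trow$copies_both_termini,
                                     family_tsd_census(calls), tir)
  calls_by[[fname]] <- calls
}

write_family_report(families, calls_by, out)
cat("family table:\n")
print(family_table(families))

result <- structure(list(families = families, calls_by_family = calls_by),
                    class = "te_pipeline_result")
ev <- evaluate_calls(truth, result, unname(templates))
write.table(ev$per_family, file.path(out, "evaluation.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("\nevaluation against implanted truth:\n")
print(ev$per_family)
if (length(ev$missed))
  cat("missed templates:", paste(ev$missed, collapse = ", "), "\n")
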