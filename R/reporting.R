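#' Name a transposon family
#'
#' Families are named `IS481EU-{serial}_{tag}` when autonomous. Non-autonomous
#' families carry the letter N: `IS481EU-{k}N{j}_{tag}` when their autonomous
#' partner family `k` is known (`j` counts non-autonomous partners of `k`),
#' and `IS481EU-N{j}_{tag}` when no autonomous partner was found.
#'
#' @param serial family serial number (>= 1); for non-autonomous families
#'   with a parent this is ignored in favour of the parent's serial.
#' @param species_tag short species token, e.g. `"TV"`.
#' @param autonomy `"autonomous"` or `"non-autonomous"`.
#' @param parent serial of the autonomous partner family, or `NULL`.
#' @param existing character vector of names already assigned in this run
#'   (used for the per-parent / orphan counters and duplicate detection).
#' @return the new name token.
#' @export
name_family <- function(serial, species_tag, autonomy, parent = NULL,
                        existing = character(0)) {
  stopifnot(serial >= 1L)
  autonomy <- match.arg(autonomy, c("autonomous", "non-autonomous"))
  if (autonomy == "autonomous") {
    name <- sprintf("IS481EU-%d_%s", serial, species_tag)
  } else if (!is.null(parent)) {
    prefix <- sprintf("IS481EU-%dN", as.integer(parent))
    j <- sum(startsWith(existing, prefix) &
               endsWith(existing, paste0("_", species_tag))) + 1L
    name <- sprintf("%s%d_%s", prefix, j, species_tag)
  } else {
    pat <- sprintf("^IS481EU-N[0-9]+_%s$", species_tag)
    j <- sum(grepl(pat, existing)) + 1L
    name <- sprintf("IS481EU-N%d_%s", j, species_tag)
  }
  if (name %in% existing) stop("duplicate family name: ", name)
  name
}

#' Assemble a family record
#'
#' One row of the final family report: the named consensus with its autonomy
#' call, copy support, TSD census and TIR report.
#'
#' @param name family name from [name_family()].
#' @param species_tag species token.
#' @param consensus the family's [consensus_record()].
#' @param autonomy autonomy label.
#' @param copy_count_both_termini copies whose alignment reaches both
#'   consensus ends (within 5 bp).
#' @param census TSD census from [family_tsd_census()].
#' @param tir `tir_report` from [detect_tir()].
#' @return object of class `family_record`.
#' @export
family_record <- function(name, species_tag, consensus, autonomy,
                          copy_count_both_termini, census, tir) {
  stopifnot(copy_count_both_termini >= 0L)
  structure(list(name = name, species_tag = species_tag,
                 consensus = consensus, autonomy = autonomy,
                 copy_count_both_termini = as.integer(copy_count_both_termini),
                 census = census, tir = tir),
            class = "family_record")
}

format_census_classes <- function(census) {
  if (length(census$classes) == 0L) return("-")
  paste(sprintf("%s:%d", names(census$classes), census$classes),
        collapse = ",")
}

bracket_tsd <- function(flank, L, side, width = 30L) {
  n <- nchar(flank)
  if (side == "left") {
    tsd <- if (L > 0L) substr(flank, n - L + 1L, n) else ""
    pre <- substr(flank, max(1L, n - width + 1L), n - L)
    if (L > 0L) paste0(pre, "[", tsd, "]") else pre
  } else {
    tsd <- if (L > 0L) substr(flank, 1L, L) else ""
    post <- substr(flank, L + 1L, min(n, width))
    if (L > 0L) paste0("[", tsd, "]", post) else post
  }
}

#' Plain-text per-copy boundary listing
#'
#' One line per shown copy: the left-flank tail, the element's first 10 bp, an
#' ellipsis, the element's last 10 bp and the right-flank head, with each TSD
#' copy delimited by brackets (the plain-text stand-in for the red colouring
#' used in figure-style listings). Copies without a TSD are never shown; when
#' more than `max_shown` copies carry a TSD, the ones with the longest TSDs
#' are shown (ties by copy id).
#'
#' @param family a [family_record()].
#' @param calls list of `tsd_call`s for the family's copies (as produced by
#'   [find_termini()], which records each call's flank context).
#' @param max_shown listing cap, default 5 representative copies.
#' @return character vector, one line per shown copy.
#' @export
copy_boundary_listing <- function(family, calls, max_shown = 5L) {
  lens <- vapply(calls, `[[`, integer(1), "length")
  withtsd <- calls[lens > 0L]
  if (length(withtsd) == 0L) return(character(0))
  ids <- vapply(withtsd, `[[`, character(1), "copy_id")
  ord <- order(-vapply(withtsd, `[[`, integer(1), "length"), ids)
  shown <- withtsd[head(ord, max_shown)]
  el <- family$consensus$residues
  e5 <- substr(el, 1L, 10L)
  e3 <- substr(el, max(1L, nchar(el) - 9L), nchar(el))
  vapply(shown, function(cl) {
    lf <- if (!is.null(cl$left_ctx)) cl$left_ctx else cl$left_seq
    rf <- if (!is.null(cl$right_ctx)) cl$right_ctx else cl$right_seq
    sprintf("%-18s %s %s...%s %s", cl$copy_id,
            bracket_tsd(lf, cl$length, "left"),
            e5, e3,
            bracket_tsd(rf, cl$length, "right"))
  }, character(1))
}

family_serial <- function(name) {
  m <- regmatches(name, regexec("^IS481EU-([0-9]+)", name))[[1]]
  if (length(m) == 2L) as.integer(m[2]) else NA_integer_
}

#' Family distribution table
#'
#' @param families list of [family_record()]s.
#' @return data.frame with one row per family, sorted by species tag then
#'   family serial (orphan non-autonomous families last); rendering is
#'   deterministic for fixed input.
#' @export
family_table <- function(families) {
  if (length(families) == 0L) {
    return(data.frame(species_tag = character(0), family = character(0),
                      autonomy = character(0),
                      copies_with_both_termini = integer(0),
                      tsd_classes = character(0), tir_length = integer(0),
                      consensus_length = integer(0),
                      stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, lapply(families, function(f) {
    data.frame(species_tag = f$species_tag, family = f$name,
               autonomy = f$autonomy,
               copies_with_both_termini = f$copy_count_both_termini,
               tsd_classes = format_census_classes(f$census),
               tir_length = if (is.null(f$tir)) NA_integer_ else f$tir$length,
               consensus_length = nchar(f$consensus$residues),
               stringsAsFactors = FALSE)
  }))
  serial <- vapply(df$family, family_serial, integer(1))
  serial[is.na(serial)] <- .Machine$integer.max
  df <- df[order(df$species_tag, serial, df$family), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Write the family report
#'
#' Emits `families.tsv`, a fixed-width `families.txt` rendering, a
#' `listings.txt` boundary listing block per family, and the named consensus
#' FASTA.
#'
#' @param families list of [family_record()]s.
#' @param calls_by_family named list: per family name, its `tsd_call` list.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_family_report <- function(families, calls_by_family, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tab <- family_table(families)
  write.table(tab, file.path(out_dir, "families.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  txt <- c(paste(format(names(tab)), collapse = " "),
           apply(format(tab), 1L, paste, collapse = " "))
  writeLines(txt, file.path(out_dir, "families.txt"))
  lst <- unlist(lapply(families, function(f) {
    calls <- calls_by_family[[f$name]]
    c(sprintf("## %s", f$name),
      if (is.null(calls)) "(no TSD-bearing copies)"
      else copy_boundary_listing(f, calls), "")
  }))
  writeLines(lst, file.path(out_dir, "listings.txt"))
  cons <- lapply(families, function(f)
    named_seq(f$name, f$consensus$residues, "nucleotide"))
  if (length(cons)) write_fasta(cons, file.path(out_dir, "consensus.fa"))
  invisible(out_dir)
}
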