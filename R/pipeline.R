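#' Count copies retaining both termini
#'
#' A copy "retains both termini" when its alignment to the family consensus
#' reaches within `slack` bp of both consensus ends.
#'
#' @param consensus a terminus-trimmed [consensus_record()].
#' @param regions `hit_region` list for the family's copies.
#' @param slack tolerance in bp (default 5).
#' @return integer count.
#' @export
count_both_termini <- function(consensus, regions, slack = 5L) {
  R <- nchar(consensus$residues)
  sum(vapply(regions, function(rg) {
    aln <- overlap_align(consensus$residues, rg$copy)
    IRanges::start(aln@pattern@range) <= slack + 1L &&
      IRanges::end(aln@pattern@range) >= R - slack
  }, logical(1)))
}

#' Run the full family-characterisation pipeline
#'
#' Protein-seed homology search, per-seed extraction of the best copies with
#' flanks, single-linkage clustering, majority-rule consensus, iterative
#' elongation, terminus determination from signature + TSD support, TIR
#' detection, autonomy classification, family naming and TSD census.
#'
#' @param genome list of nucleotide [named_seq()] contigs.
#' @param seeds list of protein [named_seq()] seeds.
#' @param cfg a [search_config()].
#' @param species_tag token appended to family names.
#' @param flank flanking bp extracted around seed hits (curation default
#'   5000).
#' @param max_copies copies per family used for consensus building (curation
#'   default 10).
#' @param min_coverage,min_identity clustering thresholds.
#' @param min_orf_codons autonomy ORF threshold.
#' @param max_tsd longest TSD considered.
#' @param census_max_copies cap on copies re-collected for the family census.
#' @param bins TSD class bins.
#' @param max_rounds elongation round cap.
#' @return list of class `te_pipeline_result`: `families` (list of
#'   [family_record()]s), `calls_by_family`, `termini`, `table`
#'   ([family_table()] data.frame), `hits` (seed hit table) and
#'   `unresolved` (clusters whose termini could not be resolved).
#' @export
run_pipeline <- function(genome, seeds, cfg = search_config(),
                         species_tag = "SIM", flank = 5000L,
                         max_copies = 10L, min_coverage = 0.75,
                         min_identity = 0.75, min_orf_codons = 300L,
                         max_tsd = 35L, census_max_copies = 1000L,
                         bins = tsd_class_bins(), max_rounds = 10L) {
  if (inherits(genome, "named_seq")) genome <- list(genome)
  pidx <- genome_index(genome, cfg, "protein")
  nidx <- genome_index(genome, cfg, "nucleotide")
  hits <- search_protein_seeds(genome, seeds, cfg, pidx)
  copies <- list()
  for (q in unique(hits$query_id)) {
    regs <- extract_hit_regions(genome, hits[hits$query_id == q, ,
                                             drop = FALSE],
                                flank, max_copies)
    for (r in regs) copies[[r$copy_id]] <- r
  }
  copy_seqs <- lapply(copies, function(r)
    named_seq(r$copy_id, r$copy, "nucleotide"))
  clusters <- cluster_sequences(unname(copy_seqs), min_coverage,
                                min_identity)
  built <- list()
  for (i in seq_along(clusters)) {
    cl <- clusters[[i]]
    cons0 <- consensus_record(sprintf("cluster%02d", i),
                              majority_consensus(align_members(cl)),
                              copy_support = length(cl$member_ids))
    el <- tryCatch(
      elongate_consensus(cons0, genome, cfg, flank, max_copies, max_rounds,
                         nidx),
      error = function(e) NULL)
    if (is.null(el)) next
    fh <- el$last_hits
    if (is.null(fh))
      fh <- search_nucleotide(genome,
                              named_seq(el$name, el$residues, "nucleotide"),
                              cfg, nidx)
    regs <- extract_hit_regions(genome, fh, flank = max_tsd + 150L,
                                max_copies = census_max_copies)
    tc <- find_termini(el, regs, max_tsd = max_tsd)
    trimmed <- apply_termini(el, tc)
    aut <- classify_autonomy(trimmed, min_orf_codons)
    built[[length(built) + 1L]] <- list(
      cluster = cl, elongated = el, trimmed = trimmed, termini = tc,
      regions = regs, autonomy = aut$label,
      n_both = count_both_termini(trimmed, regs),
      census = family_tsd_census(tc$calls, bins))
  }
  # naming: autonomous families by decreasing copy number, then their
  # non-autonomous partners, then orphans
  existing <- character(0)
  families <- list()
  calls_by <- list()
  termini <- list()
  auto_idx <- which(vapply(built, `[[`, character(1), "autonomy") ==
                      "autonomous")
  serial_of <- integer(length(built))
  serial <- 0L
  for (i in auto_idx) {
    serial <- serial + 1L
    serial_of[i] <- serial
    nm <- name_family(serial, species_tag, "autonomous",
                      existing = existing)
    existing <- c(existing, nm)
    built[[i]]$name <- nm
  }
  for (i in seq_along(built)) {
    if (built[[i]]$autonomy == "autonomous") next
    parent <- NULL
    best <- 0
    for (j in auto_idx) {
      p <- pair_identity(built[[i]]$trimmed$residues,
                         built[[j]]$trimmed$residues)
      if (p$identity >= min_identity && p$coverage >= 0.5 &&
          p$identity > best) {
        best <- p$identity
        parent <- serial_of[j]
      }
    }
    nm <- name_family(1L, species_tag, "non-autonomous", parent = parent,
                      existing = existing)
    existing <- c(existing, nm)
    built[[i]]$name <- nm
  }
  for (b in built) {
    cons <- b$trimmed
    cons$name <- b$name
    cons$autonomy <- b$autonomy
    cons$tir <- b$termini$tir
    fam <- family_record(b$name, species_tag, cons, b$autonomy,
                         b$n_both, b$census, b$termini$tir)
    families[[b$name]] <- fam
    calls_by[[b$name]] <- b$termini$calls
    termini[[b$name]] <- b$termini
  }
  structure(list(families = families, calls_by_family = calls_by,
                 termini = termini, table = family_table(families),
                 hits = hits,
                 unresolved = character(0)),
            class = "te_pipeline_result")
}

parse_copy_interval <- function(copy_id) {
  m <- regmatches(copy_id,
                  regexec("^(.+):([0-9]+)-([0-9]+)\\(([+-])\\)$", copy_id))[[1]]
  if (length(m) != 5L) return(NULL)
  list(contig = m[2], start = as.integer(m[3]), end = as.integer(m[4]),
       strand = m[5])
}

#' Evaluate pipeline results against simulation ground truth
#'
#' Matches every reported family to its best template by consensus identity
#' and scores: signed terminus offsets (bp), consensus identity, per-copy TSD
#' length accuracy (exact and within 1 bp) over untruncated truth copies,
#' class-histogram L1 distance, and the copies-with-both-termini count versus
#' the truth untruncated count. Templates no family matched are listed under
#' `missed`.
#'
#' @param truth truth data.frame from [simulate_genome()].
#' @param result a [run_pipeline()] result.
#' @param templates list of template [named_seq()]s.
#' @param bins TSD class bins.
#' @return list with `per_family` (data.frame) and `missed` (template ids).
#' @export
evaluate_calls <- function(truth, result, templates, bins = tsd_class_bins()) {
  rows <- list()
  matched_templates <- character(0)
  for (fam in result$families) {
    cons <- fam$consensus$residues
    best_id <- 0; best_t <- NULL
    for (t in templates) {
      p <- pair_identity(cons, t$residues)
      if (p$identity * p$coverage > best_id) {
        best_id <- p$identity * p$coverage
        best_t <- t
      }
    }
    if (is.null(best_t)) next
    aln <- overlap_align(cons, best_t$residues)
    p0 <- IRanges::start(aln@pattern@range); p1 <- IRanges::end(aln@pattern@range)
    s0 <- IRanges::start(aln@subject@range); s1 <- IRanges::end(aln@subject@range)
    nm <- Biostrings::nmatch(aln); nmm <- Biostrings::nmismatch(aln)
    identity <- if (nm + nmm > 0) nm / (nm + nmm) else 0
    off5 <- s0 - p0
    off3 <- (nchar(best_t$residues) - s1) - (nchar(cons) - p1)
    tt <- truth[truth$family == best_t$id, , drop = FALSE]
    un <- tt[tt$truncated_5 == 0L & tt$truncated_3 == 0L, , drop = FALSE]
    calls <- result$calls_by_family[[fam$name]]
    called_len <- rep(0L, nrow(un))
    if (length(calls)) {
      ivs <- lapply(calls, function(cl) parse_copy_interval(cl$copy_id))
      for (r in seq_len(nrow(un))) {
        for (k in seq_along(calls)) {
          iv <- ivs[[k]]
          if (is.null(iv) || iv$contig != un$contig[r]) next
          ov <- min(iv$end, un$end[r]) - max(iv$start, un$start[r]) + 1L
          if (ov > 0.5 * (un$end[r] - un$start[r] + 1L)) {
            called_len[r] <- calls[[k]]$length
            break
          }
        }
      }
    }
    class_of <- function(v) vapply(v, classify_tsd_length, character(1),
                                   bins = bins)
    lv <- c(bins$label, "other", "none")
    h_truth <- table(factor(class_of(un$tsd_length), levels = lv))
    h_call <- table(factor(class_of(called_len), levels = lv))
    rows[[length(rows) + 1L]] <- data.frame(
      family = fam$name, template = best_t$id,
      consensus_identity = identity,
      terminus_offset_5 = off5, terminus_offset_3 = off3,
      tsd_exact = if (nrow(un)) mean(called_len == un$tsd_length) else NA,
      tsd_within1 = if (nrow(un)) mean(abs(called_len - un$tsd_length) <= 1L)
                    else NA,
      class_l1 = sum(abs(as.integer(h_truth) - as.integer(h_call))),
      copies_both_termini = fam$copy_count_both_termini,
      truth_untruncated = nrow(un),
      stringsAsFactors = FALSE)
    matched_templates <- c(matched_templates, best_t$id)
  }
  per_family <- if (length(rows)) do.call(rbind, rows) else NULL
  missed <- setdiff(vapply(templates, `[[`, character(1), "id"),
                    matched_templates)
  list(per_family = per_family, missed = missed)
}
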