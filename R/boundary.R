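#' TSD length class bins
#'
#' The discrete TSD length regimes characteristic of this transposon group:
#' around 4 bp (2-6), around 15 bp (14-17) and around 25 bp (24-29), matching
#' the three separate ranges reported for the related prokaryotic IS1202
#' group (5-6, 15-17, 24-29 bp) widened to the observed 4/5 bp calls.
#' Override to explore alternative binnings.
#'
#' @param bins data.frame with columns `label`, `min`, `max`; must be
#'   disjoint and ascending.
#' @return the validated bins.
#' @export
tsd_class_bins <- function(bins = data.frame(
    label = c("~4", "~15", "~25"),
    min = c(2L, 14L, 24L),
    max = c(6L, 17L, 29L), stringsAsFactors = FALSE)) {
  stopifnot(all(bins$min <= bins$max),
            all(diff(as.vector(rbind(bins$min, bins$max))) > 0))
  bins
}

#' Classify a TSD length into a discrete class
#'
#' @param length TSD length in bp (0 = none detected).
#' @param bins class bins from [tsd_class_bins()].
#' @return `"~4"`, `"~15"`, `"~25"`, `"other"` (positive length in no bin) or
#'   `"none"` (length 0).
#' @export
classify_tsd_length <- function(length, bins = tsd_class_bins()) {
  if (length < 0) stop("negative TSD length")
  if (length == 0) return("none")
  hit <- which(bins$min <= length & bins$max >= length)
  if (length(hit)) bins$label[hit[1]] else "other"
}

default_tsd_budget <- function(L) if (L < 10L) 0L else L %/% 8L

#' Call a target site duplication from a copy's flanks
#'
#' Compares, for candidate lengths from `max_len` down to 1, the length-L
#' suffix of the left flank against the length-L prefix of the right flank
#' (Hamming distance, N counting as a mismatch) and returns the largest L
#' whose mismatch count is within the budget: 0 mismatches below 10 bp,
#' floor(L/8) at 10 bp and above — short TSDs must be exact, long ones may be
#' degenerate. Candidate windows crossing a run of >= 10 N (an assembly gap)
#' are skipped. Suffix/prefix comparisons at different lengths are mutually
#' shifted, so a true duplication of length L scores ~75% mismatches at any
#' other candidate length; the top-down scan therefore returns the true
#' length, not an extension of it.
#'
#' @param left_flank,right_flank flanks in element orientation: `left_flank`
#'   ends at the base immediately 5' of the element, `right_flank` starts at
#'   the base immediately 3' of it.
#' @param max_len longest candidate TSD (default 35).
#' @param budget function of L giving the allowed mismatch count.
#' @param bins class bins for labelling.
#' @param copy_id optional id recorded in the call.
#' @return list of class `tsd_call`: `copy_id, length, mismatches, left_seq,
#'   right_seq, class_label`.
#' @export
call_tsd <- function(left_flank, right_flank, max_len = 35L,
                     budget = default_tsd_budget, bins = tsd_class_bins(),
                     copy_id = NA_character_) {
  none <- structure(list(copy_id = copy_id, length = 0L, mismatches = 0L,
                         left_seq = "", right_seq = "",
                         class_label = "none"), class = "tsd_call")
  nl <- nchar(left_flank); nr <- nchar(right_flank)
  lmax <- min(max_len, nl, nr)
  if (lmax < 1L) return(none)
  lc <- seq_chars(toupper(substr(left_flank, nl - lmax + 1L, nl)))
  rc <- seq_chars(toupper(substr(right_flank, 1L, lmax)))
  lruns <- n_runs(paste(lc, collapse = ""))
  rruns <- n_runs(paste(rc, collapse = ""))
  for (L in rev(seq_len(lmax))) {
    ls <- lc[(lmax - L + 1L):lmax]
    rs <- rc[1L:L]
    if (nrow(lruns) && any(lruns[, "end"] >= lmax - L + 1L)) next
    if (nrow(rruns) && any(rruns[, "start"] <= L)) next
    mism <- sum(ls != rs | ls == "N" | rs == "N")
    if (mism <= budget(L)) {
      return(structure(list(copy_id = copy_id, length = L,
                            mismatches = as.integer(mism),
                            left_seq = paste(ls, collapse = ""),
                            right_seq = paste(rs, collapse = ""),
                            class_label = classify_tsd_length(L, bins),
                            # flank context kept for boundary listings
                            left_ctx = substr(left_flank,
                                              max(1L, nl - 49L), nl),
                            right_ctx = substr(right_flank, 1L,
                                               min(nr, 50L))),
                       class = "tsd_call"))
    }
  }
  none
}

# subject position for every pattern position of a pairwise alignment,
# extrapolated without gaps beyond the aligned region; NA outside the subject
alignment_position_map <- function(aln, pattern_len, subject_len) {
  pa <- seq_chars(as.character(Biostrings::alignedPattern(aln)))
  sa <- seq_chars(as.character(Biostrings::alignedSubject(aln)))
  p0 <- IRanges::start(aln@pattern@range); p1 <- IRanges::end(aln@pattern@range)
  s0 <- IRanges::start(aln@subject@range)
  map <- rep(NA_integer_, pattern_len)
  pi <- p0 - 1L; si <- s0 - 1L
  for (k in seq_along(pa)) {
    if (sa[k] != "-") si <- si + 1L
    if (pa[k] != "-") {
      pi <- pi + 1L
      map[pi] <- si
    }
  }
  if (p0 > 1L) map[1:(p0 - 1L)] <- map[p0] - ((p0 - 1L):1L)
  if (p1 < pattern_len) map[(p1 + 1L):pattern_len] <-
      map[p1] + seq_len(pattern_len - p1)
  map[!is.na(map) & (map < 1L | map > subject_len)] <- NA_integer_
  map
}

#' Determine element termini from terminal signatures and TSD support
#'
#' Candidate 5' positions are consensus positions near the copy-flank
#' divergence point whose 3-mer matches the 5' signature (default degenerate
#' `TNT`, with the strict `TGT` subtype preferred); symmetrically `AYA`/`ACA`
#' at the 3' end. Every candidate pair is scored by the number of copies whose
#' implied flanks yield a positive TSD call, plus 1 for a strict signature
#' match at both ends and 0.5 for a detectable TIR between the candidate
#' termini — per-copy TSD evidence dominates, the signature and TIR break
#' near-ties. The winning pair, its per-copy TSD calls and the support count
#' are returned.
#'
#' @param elongated a [consensus_record()] after [elongate_consensus()].
#' @param copies list of `hit_region` objects for the family's copies.
#' @param signature degenerate IUPAC pair, default `c("TNT","AYA")`.
#' @param strict strict signature pair granting the score bonus.
#' @param window candidate search half-width (bp) around the divergence point.
#' @param max_tsd longest TSD considered.
#' @param min_support_len shortest TSD call that counts as copy support for a
#'   candidate pair (default 3): 1-2 bp suffix/prefix agreements arise by
#'   chance at a quarter of random junctions — and systematically, at every
#'   candidate pair shifted into the element, where the implied flanks share
#'   element-derived bases across all copies — so they carry no positional
#'   information.
#' @return list of class `terminus_call`: `terminus_5, terminus_3` (positions
#'   in the elongated consensus), `signature_matched`, `pattern_used`,
#'   `supporting_copies`, `candidate_score`, and `calls` (per-copy
#'   `tsd_call`s at the chosen pair).
#' @export
find_termini <- function(elongated, copies, signature = c("TNT", "AYA"),
                         strict = c("TGT", "ACA"), window = 30L,
                         max_tsd = 35L, min_support_len = 3L) {
  res <- elongated$residues
  R <- nchar(res)
  W <- window + max_tsd + 50L
  ctxs <- lapply(copies, function(rg) {
    lf <- rg$left_flank
    lf <- substr(lf, max(1L, nchar(lf) - W + 1L), nchar(lf))
    rf <- substr(rg$right_flank, 1L, W)
    list(context = paste0(lf, rg$copy, rf), left_kept = nchar(lf),
         copy_id = rg$copy_id)
  })
  anchors <- lapply(ctxs, function(cx) {
    aln <- overlap_align(res, cx$context)
    list(map = alignment_position_map(aln, R, nchar(cx$context)),
         p0 = IRanges::start(aln@pattern@range),
         p1 = IRanges::end(aln@pattern@range))
  })
  div5 <- round(stats::median(vapply(anchors, `[[`, numeric(1), "p0")))
  div3 <- round(stats::median(vapply(anchors, `[[`, numeric(1), "p1")))
  cand5 <- intersect(max(1L, div5 - window):min(R - 2L, div5 + window),
                     1:(R - 2L))
  cand5 <- cand5[vapply(cand5, function(p)
    iupac_match(signature[1], substr(res, p, p + 2L)), logical(1))]
  cand3 <- intersect(max(3L, div3 - window):min(R, div3 + window), 3:R)
  cand3 <- cand3[vapply(cand3, function(p)
    iupac_match(signature[2], substr(res, p - 2L, p)), logical(1))]

  score_pair <- function(p5, p3) {
    calls <- lapply(seq_along(copies), function(i) {
      m <- anchors[[i]]$map
      c5 <- m[p5]; c3 <- m[p3]
      # a copy whose alignment does not reach a terminus gives no evidence
      if (is.na(c5) || is.na(c3) ||
          anchors[[i]]$p0 > p5 + 3L || anchors[[i]]$p1 < p3 - 3L)
        return(call_tsd("", "", copy_id = ctxs[[i]]$copy_id))
      ctx <- ctxs[[i]]$context
      call_tsd(substr(ctx, 1L, c5 - 1L), substr(ctx, c3 + 1L, nchar(ctx)),
               max_len = max_tsd, copy_id = ctxs[[i]]$copy_id)
    })
    lens <- vapply(calls, `[[`, integer(1), "length")
    support <- sum(lens >= min_support_len)
    sc <- support
    strict_ok <- identical(substr(res, p5, p5 + 2L), strict[1]) &&
      identical(substr(res, p3 - 2L, p3), strict[2])
    if (strict_ok) sc <- sc + 1
    trial <- elongated
    trial$termini_resolved <- TRUE
    trial$terminus_5 <- p5; trial$terminus_3 <- p3
    tir <- detect_tir(trial)
    if (isTRUE(tir$present)) sc <- sc + 0.5
    list(score = sc, support = support, sum_len = sum(lens), calls = calls,
         tir = tir)
  }

  # a side without any signature candidate falls back to its divergence
  # point; the other side is still optimised by TSD support
  sig5 <- length(cand5) > 0L; sig3 <- length(cand3) > 0L
  if (!sig5) cand5 <- max(1L, min(div5, R - 1L))
  if (!sig3) cand3 <- max(3L, min(div3, R))
  pairs <- expand.grid(p5 = cand5, p3 = cand3)
  pairs <- pairs[pairs$p5 < pairs$p3, , drop = FALSE]
  if (nrow(pairs) == 0L) {
    pairs <- data.frame(p5 = max(1L, min(div5, R - 1L)))
    pairs$p3 <- max(pairs$p5 + 1L, min(div3, R))
    sig5 <- sig3 <- FALSE
  }
  scored <- lapply(seq_len(nrow(pairs)),
                   function(i) score_pair(pairs$p5[i], pairs$p3[i]))
  sc <- vapply(scored, `[[`, numeric(1), "score")
  sl <- vapply(scored, `[[`, numeric(1), "sum_len")
  best <- order(-sc, -sl, pairs$p5)[1]
  structure(list(
    terminus_5 = pairs$p5[best], terminus_3 = pairs$p3[best],
    signature_matched = sig5 && sig3,
    pattern_used = paste(signature, collapse = ".."),
    supporting_copies = scored[[best]]$support,
    candidate_score = sc[best],
    calls = scored[[best]]$calls,
    tir = scored[[best]]$tir), class = "terminus_call")
}

#' Record resolved termini on a consensus
#'
#' @param consensus a [consensus_record()].
#' @param termini a `terminus_call` from [find_termini()].
#' @param trim if `TRUE` (default) the residues are cut down to the element
#'   between the termini.
#' @return updated `consensus_record` with `termini_resolved = TRUE`.
#' @export
apply_termini <- function(consensus, termini, trim = TRUE) {
  stopifnot(termini$terminus_5 < termini$terminus_3)
  out <- consensus
  if (trim) {
    out$residues <- substr(consensus$residues, termini$terminus_5,
                           termini$terminus_3)
    out$terminus_5 <- 1L
    out$terminus_3 <- nchar(out$residues)
  } else {
    out$terminus_5 <- termini$terminus_5
    out$terminus_3 <- termini$terminus_3
  }
  out$termini_resolved <- TRUE
  out
}

#' Detect a terminal inverted repeat
#'
#' End-gap-free alignment of the element's first `max_scan` bases against the
#' reverse complement of its last `max_scan` bases. The repeat must be
#' anchored at both extremities (alignment starting within 2 bp of both
#' ends); it is reported present when the anchored span reaches `min_tir_len`
#' at identity >= 0.8.
#'
#' @param consensus_with_termini a `consensus_record` with resolved termini.
#' @param max_scan bases scanned from each end (default 100; TIRs here are
#'   expected well under 50 bp).
#' @param min_tir_len minimum length to call a TIR present.
#' @return list of class `tir_report`: `length`, `identity`, `present`.
#' @export
detect_tir <- function(consensus_with_termini, max_scan = 100L,
                       min_tir_len = 8L) {
  cr <- consensus_with_termini
  if (!isTRUE(cr$termini_resolved)) stop("termini not resolved")
  s <- substr(cr$residues, cr$terminus_5, cr$terminus_3)
  n <- nchar(s)
  scan <- min(max_scan, n %/% 2L)
  if (scan < 1L)
    return(structure(list(length = 0L, identity = 0, present = FALSE),
                     class = "tir_report"))
  head5 <- substr(s, 1L, scan)
  tail3 <- revcomp(substr(s, n - scan + 1L, n))
  # local alignment: an ends-free global alignment cannot clip the non-TIR
  # remainder of both scan windows at once, a local one can
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(head5), Biostrings::DNAString(tail3),
    type = "local", substitutionMatrix = member_submat(),
    gapOpening = 4, gapExtension = 1)
  p0 <- IRanges::start(aln@pattern@range); s0 <- IRanges::start(aln@subject@range)
  anchored <- p0 <= 2L && s0 <= 2L
  if (!anchored)
    return(structure(list(length = 0L, identity = 0, present = FALSE),
                     class = "tir_report"))
  span <- max(IRanges::width(aln@pattern@range),
              IRanges::width(aln@subject@range))
  nm <- Biostrings::nmatch(aln); nmm <- Biostrings::nmismatch(aln)
  ident <- if (nm + nmm > 0) nm / (nm + nmm) else 0
  structure(list(length = as.integer(span), identity = ident,
                 present = span >= min_tir_len && ident >= 0.8),
            class = "tir_report")
}

#' Write TSD calls as TSV
#'
#' Columns: `copy_id, contig, start, end, strand, tsd_length, mismatches,
#' left_seq, right_seq, class_label`; coordinates (parsed from the copy ids)
#' are written 0-based half-open like every on-disk interval.
#'
#' @param calls list of `tsd_call` objects.
#' @param path TSV path.
#' @param family optional family name column.
#' @export
write_tsd_calls <- function(calls, path, family = NA_character_) {
  rows <- lapply(calls, function(cl) {
    iv <- parse_copy_interval(cl$copy_id)
    data.frame(family = family, copy_id = cl$copy_id,
               contig = if (is.null(iv)) NA_character_ else iv$contig,
               start = if (is.null(iv)) NA_integer_ else iv$start - 1L,
               end = if (is.null(iv)) NA_integer_ else iv$end,
               strand = if (is.null(iv)) NA_character_ else iv$strand,
               tsd_length = cl$length, mismatches = cl$mismatches,
               left_seq = cl$left_seq, right_seq = cl$right_seq,
               class_label = cl$class_label, stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(family = character(0), copy_id = character(0),
               contig = character(0), start = integer(0), end = integer(0),
               strand = character(0), tsd_length = integer(0),
               mismatches = integer(0), left_seq = character(0),
               right_seq = character(0), class_label = character(0))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Census of a family's TSD calls
#'
#' @param calls list of `tsd_call` objects.
#' @param bins class bins from [tsd_class_bins()].
#' @return list with `exact` (named count vector per exact length), `classes`
#'   (count per class label among positive calls) and `none` (copies without
#'   a detectable TSD).
#' @export
family_tsd_census <- function(calls, bins = tsd_class_bins()) {
  lens <- vapply(calls, `[[`, integer(1), "length")
  pos <- lens[lens > 0L]
  exact <- table(pos)
  cls <- vapply(pos, classify_tsd_length, character(1), bins = bins)
  classes <- table(factor(cls, levels = c(bins$label, "other")))
  classes <- classes[classes > 0L]
  list(exact = setNames(as.integer(exact), names(exact)),
       classes = setNames(as.integer(classes), names(classes)),
       none = sum(lens == 0L))
}
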