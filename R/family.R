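#' @importFrom Biostrings pairwiseAlignment alignedPattern alignedSubject
#'   nmatch nmismatch nucleotideSubstitutionMatrix
NULL

# pairwise scoring used for member/cluster alignment: match +1, mismatch -1,
# gap open -4, gap extend -1, end gaps free
member_submat <- function() {
  Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                           baseOnly = FALSE)
}

overlap_align <- function(pattern, subject) {
  Biostrings::pairwiseAlignment(
    Biostrings::DNAString(pattern), Biostrings::DNAString(subject),
    type = "overlap", substitutionMatrix = member_submat(),
    gapOpening = 4, gapExtension = 1)
}

# identity over aligned non-gap columns and coverage of the shorter sequence
pair_identity <- function(a, b) {
  aln <- overlap_align(a, b)
  nm <- Biostrings::nmatch(aln)
  nmm <- Biostrings::nmismatch(aln)
  ident <- if (nm + nmm > 0) nm / (nm + nmm) else 0
  span <- min(IRanges::width(aln@pattern@range),
              IRanges::width(aln@subject@range))
  list(identity = ident, coverage = span / min(nchar(a), nchar(b)))
}

#' Cluster copy sequences by identity and coverage
#'
#' Single-linkage clustering in the style of BLASTCLUST: two sequences are
#' linked iff an end-gap-free global alignment reaches `min_identity` over
#' aligned non-gap columns *and* the aligned span covers `min_coverage` of the
#' shorter sequence (defaults 0.75/0.75). Clusters are the connected
#' components; the representative is the longest member (ties: smallest id).
#'
#' Pairs sharing no exact 12-mer are not aligned: any pair at >= 75% identity
#' over a few hundred bp shares one with overwhelming probability, and the
#' shortcut keeps all-vs-all clustering tractable.
#'
#' @param seqs list of nucleotide [named_seq()] copies.
#' @param min_coverage,min_identity linkage thresholds.
#' @return list of clusters, decreasing size; each a list with `member_ids`,
#'   `members` (the input records) and `representative` (an id).
#' @export
cluster_sequences <- function(seqs, min_coverage = 0.75,
                              min_identity = 0.75) {
  if (length(seqs) == 0L) return(list())
  ids <- vapply(seqs, `[[`, character(1), "id")
  res <- vapply(seqs, `[[`, character(1), "residues")
  if (any(nchar(res) == 0L)) stop("zero-length sequence in clustering input")
  names(seqs) <- ids
  n <- length(seqs)
  km <- lapply(res, function(s) unique(kmerize(s, min(12L, nchar(s)))))
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(max(0L, n - 1L))) {
    for (j in (i + 1L):n) {
      if (find(i) == find(j)) next
      if (!any(km[[i]] %in% km[[j]])) next
      p <- pair_identity(res[i], res[j])
      if (p$identity >= min_identity && p$coverage >= min_coverage) {
        parent[find(j)] <- find(i)
      }
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  groups <- split(seq_len(n), comp)
  clusters <- lapply(groups, function(g) {
    lens <- nchar(res[g])
    rep_i <- g[order(-lens, ids[g])][1]
    list(member_ids = ids[g], members = seqs[g], representative = ids[rep_i])
  })
  sizes <- vapply(clusters, function(cl) length(cl$member_ids), integer(1))
  reps <- vapply(clusters, `[[`, character(1), "representative")
  unname(clusters[order(-sizes, reps)])
}

#' Center-star multiple alignment of a cluster
#'
#' Each member is aligned end-gap-free to the representative; the pairwise
#' alignments are merged on the representative's coordinate frame under the
#' "once a gap, always a gap" rule. Member sequence beyond the aligned region
#' (overhangs) is kept in insertion blocks so that removing gaps from any row
#' reproduces the member exactly.
#'
#' @param cluster a cluster from [cluster_sequences()].
#' @return list of class `msa` with `ids`, `rows` (equal-length aligned
#'   strings), `ncol` and `rep_id`.
#' @export
align_members <- function(cluster) {
  stopifnot(length(cluster$members) >= 1L)
  rep_id <- cluster$representative
  rep_seq <- cluster$members[[rep_id]]$residues
  R <- nchar(rep_seq)
  ids <- cluster$member_ids
  parsed <- lapply(ids, function(id) {
    mem <- cluster$members[[id]]$residues
    if (id == rep_id) {
      return(list(votes = seq_chars(rep_seq),
                  ins = list(), covered = c(1L, R)))
    }
    aln <- overlap_align(mem, rep_seq)
    pa <- seq_chars(as.character(Biostrings::alignedPattern(aln)))
    sa <- seq_chars(as.character(Biostrings::alignedSubject(aln)))
    sr0 <- IRanges::start(aln@subject@range)
    sr1 <- IRanges::end(aln@subject@range)
    pr0 <- IRanges::start(aln@pattern@range)
    pr1 <- IRanges::end(aln@pattern@range)
    votes <- rep(NA_character_, R)
    ins <- list()
    r <- sr0 - 1L
    buf <- character(0)
    # left overhang: right-aligned insertion just before the first aligned col
    if (pr0 > 1L)
      ins[[as.character(sr0 - 1L)]] <-
        list(chars = seq_chars(substr(mem, 1L, pr0 - 1L)), side = "right")
    for (k in seq_along(sa)) {
      if (sa[k] != "-") {
        if (length(buf)) {
          ins[[as.character(r)]] <- list(chars = buf, side = "left")
          buf <- character(0)
        }
        r <- r + 1L
        votes[r] <- pa[k]
      } else {
        buf <- c(buf, pa[k])
      }
    }
    if (length(buf)) ins[[as.character(r)]] <- list(chars = buf, side = "left")
    if (pr1 < nchar(mem))
      ins[[as.character(sr1)]] <-
        list(chars = seq_chars(substr(mem, pr1 + 1L, nchar(mem))),
             side = "left")
    list(votes = votes, ins = ins, covered = c(sr0, sr1))
  })
  names(parsed) <- ids
  block_w <- integer(R + 1L)  # insertion block after rep position r (0..R)
  for (p in parsed) for (r in names(p$ins)) {
    ri <- as.integer(r) + 1L
    block_w[ri] <- max(block_w[ri], length(p$ins[[r]]$chars))
  }
  rows <- vapply(parsed, function(p) {
    out <- character(0)
    for (r in 0:R) {
      w <- block_w[r + 1L]
      if (w > 0L) {
        b <- p$ins[[as.character(r)]]
        chars <- if (is.null(b)) character(0) else b$chars
        pad <- rep("-", w - length(chars))
        out <- c(out, if (!is.null(b) && b$side == "right") c(pad, chars)
                 else c(chars, pad))
      }
      if (r < R) {
        v <- p$votes[r + 1L]
        out <- c(out, if (is.na(v)) "-" else v)
      }
    }
    paste(out, collapse = "")
  }, character(1))
  structure(list(ids = ids, rows = unname(rows), ncol = nchar(rows[[1]]),
                 rep_id = rep_id), class = "msa")
}

#' Majority-rule consensus of a multiple alignment
#'
#' Per column, characters over `{A,C,G,T,-}` are counted among the rows
#' covering the column (leading/trailing pad excluded). If the most frequent
#' character reaches `threshold` of the covering rows it is emitted (a winning
#' gap deletes the column); otherwise the column emits `N`. Ties break in the
#' fixed order `- > A > C > G > T`.
#'
#' @param msa an [align_members()] result.
#' @param threshold winning frequency, default 0.5 (the 50% majority rule).
#' @return consensus nucleotide string.
#' @export
majority_consensus <- function(msa, threshold = 0.5) {
  if (is.null(msa) || length(msa$rows) == 0L || msa$ncol == 0L)
    stop("empty alignment")
  mat <- do.call(rbind, strsplit(msa$rows, "", fixed = TRUE))
  nr <- nrow(mat); nc <- ncol(mat)
  first <- apply(mat != "-", 1L, function(x) which(x)[1])
  last <- apply(mat != "-", 1L, function(x) tail(which(x), 1))
  order_chars <- c("-", "A", "C", "G", "T")
  out <- character(0)
  for (j in seq_len(nc)) {
    cov <- which(first <= j & last >= j)
    if (!length(cov)) next
    v <- mat[cov, j]
    counts <- vapply(order_chars, function(ch) sum(v == ch), integer(1))
    win <- order_chars[which.max(counts)]  # which.max takes first on ties
    if (counts[win] / length(cov) >= threshold) {
      if (win != "-") out <- c(out, win)
    } else {
      out <- c(out, "N")
    }
  }
  paste(out, collapse = "")
}

#' Construct a family consensus record
#'
#' @param name family name token.
#' @param residues consensus nucleotide string.
#' @param copy_support number of copies behind the consensus.
#' @return object of class `consensus_record`; termini start unresolved.
#' @export
consensus_record <- function(name, residues, copy_support = 0L) {
  check_alphabet(toupper(residues), "nucleotide", name)
  structure(list(name = name, residues = toupper(residues),
                 termini_resolved = FALSE,
                 terminus_5 = NA_integer_, terminus_3 = NA_integer_,
                 tir = NULL, autonomy = NA_character_,
                 copy_support = as.integer(copy_support),
                 rounds = NA_integer_),
            class = "consensus_record")
}

#' @export
print.consensus_record <- function(x, ...) {
  cat(sprintf("<consensus_record> %s: %d bp, %d copies, termini %s\n",
              x$name, nchar(x$residues), x$copy_support,
              if (x$termini_resolved)
                sprintf("%d..%d", x$terminus_5, x$terminus_3)
              else "unresolved"))
  invisible(x)
}

# anchor a hit region to the consensus: where do consensus positions 1 and R
# fall inside the copy, and does the copy reach each consensus end? A few bp
# of slack with ungapped extrapolation, because an end-gap-free alignment
# trims terminal mismatches off a noisy copy.
anchor_region <- function(consensus_res, region, slack = 3L) {
  aln <- overlap_align(consensus_res, region$copy)
  R <- nchar(consensus_res)
  p0 <- IRanges::start(aln@pattern@range); p1 <- IRanges::end(aln@pattern@range)
  s0 <- IRanges::start(aln@subject@range); s1 <- IRanges::end(aln@subject@range)
  list(reaches_5 = p0 <= 1L + slack, reaches_3 = p1 >= R - slack,
       copy_pos_5 = s0 - (p0 - 1L), copy_pos_3 = s1 + (R - p1),
       p0 = p0, p1 = p1)
}

# outward extension votes: character d bases outside the consensus 5'/3' end
# in each copy's flanked context; NA when the copy does not reach that end or
# the context runs out
extension_votes <- function(consensus_res, regions, anchors, side, d) {
  vapply(seq_along(regions), function(i) {
    a <- anchors[[i]]; rg <- regions[[i]]
    if (side == "5") {
      if (!a$reaches_5) return(NA_character_)
      ctx <- nchar(rg$left_flank) + a$copy_pos_5 - d
      full <- paste0(rg$left_flank, rg$copy)
      if (ctx < 1L) return(NA_character_)
      substr(full, ctx, ctx)
    } else {
      if (!a$reaches_3) return(NA_character_)
      full <- paste0(rg$copy, rg$right_flank)
      ctx <- a$copy_pos_3 + d
      if (ctx > nchar(full)) return(NA_character_)
      substr(full, ctx, ctx)
    }
  }, character(1))
}

#' Iteratively elongate a consensus through flanking sequence
#'
#' Repeat-library curation loop: re-search the genome with the current
#' consensus, extract the best copies with flanks, anchor each copy to the
#' consensus, and grow the consensus outward one column at a time while at
#' least half of the covering copies agree on a single character and at least
#' two copies cover the column (the 2-copy floor prevents a lone copy's flank
#' from being promoted into the consensus). Terminates when neither end
#' extends or after `max_rounds` rounds.
#'
#' @param consensus a [consensus_record()].
#' @param genome list of nucleotide [named_seq()] contigs.
#' @param cfg a [search_config()].
#' @param flank flanking bp extracted around each copy.
#' @param max_copies copies used per round.
#' @param max_rounds safety cap on re-search rounds.
#' @param index optional prebuilt nucleotide [genome_index()].
#' @return the elongated `consensus_record` (with `rounds` recorded).
#' @export
elongate_consensus <- function(consensus, genome, cfg = search_config(),
                               flank = 5000L, max_copies = 10L,
                               max_rounds = 10L, index = NULL) {
  if (is.null(index)) index <- genome_index(genome, cfg, "nucleotide")
  res <- consensus$residues
  rounds <- 0L
  repeat {
    rounds <- rounds + 1L
    hits <- search_nucleotide(genome,
                              named_seq(consensus$name, res, "nucleotide"),
                              cfg, index)
    if (nrow(hits) == 0L) stop("family lost: no hits for ", consensus$name)
    regions <- extract_hit_regions(genome, hits, flank, max_copies)
    anchors <- lapply(regions, function(r) anchor_region(res, r))
    grow <- function(side) {
      added <- character(0)
      d <- 1L
      repeat {
        v <- extension_votes(res, regions, anchors, side, d)
        v <- v[!is.na(v)]
        if (length(v) < 2L) break
        counts <- table(v)
        top <- counts[which.max(counts)]
        if (sum(counts == top) > 1L) break          # no single winner
        if (top / length(v) < 0.5) break
        added <- c(added, names(top))
        d <- d + 1L
      }
      added
    }
    left <- grow("5")
    right <- grow("3")
    if (length(left)) res <- paste0(paste(rev(left), collapse = ""), res)
    if (length(right)) res <- paste0(res, paste(right, collapse = ""))
    if ((length(left) + length(right)) == 0L || rounds >= max_rounds) break
  }
  out <- consensus
  out$residues <- res
  out$copy_support <- length(regions)
  out$rounds <- rounds
  # when the last round did not extend, its hit table already describes the
  # final consensus and can be reused downstream
  out$last_hits <- if ((length(left) + length(right)) == 0L) hits else NULL
  out
}

#' Classify a consensus as autonomous or non-autonomous
#'
#' Scans both strands, three frames each, for the longest stop-free open
#' reading frame beginning at ATG. A family whose consensus retains a long
#' ORF (default >= 300 codons, enough to house a transposase) is called
#' autonomous.
#'
#' @param consensus a [consensus_record()] or nucleotide string.
#' @param min_orf_codons autonomy threshold in codons.
#' @return list with `label` (`"autonomous"`/`"non-autonomous"`) and
#'   `orf_codons` (longest qualifying ORF found).
#' @export
classify_autonomy <- function(consensus, min_orf_codons = 300L) {
  res <- if (inherits(consensus, "consensus_record")) consensus$residues
         else consensus
  best <- 0L
  if (nchar(res) >= 3L) {
    for (fr in translate_six_frames(res)) {
      aa <- seq_chars(fr$protein)
      if (!length(aa)) next
      stops <- c(which(aa == "*"), length(aa) + 1L)
      for (m in which(aa == "M")) {
        stop_at <- stops[stops > m][1]
        best <- max(best, stop_at - m)
      }
    }
  }
  list(label = if (best >= min_orf_codons) "autonomous" else "non-autonomous",
       orf_codons = best)
}
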