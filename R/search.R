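#' Search configuration
#'
#' All tunables of the seed-and-extend homology search. The search is a
#' transparent, deterministic replacement for black-box repeat-detection
#' tools: every parameter is explicit and serialisable, so a run can be
#' reproduced exactly.
#'
#' @param protein_seed_k exact k-mer seed length in protein mode.
#' @param nucleotide_seed_k exact k-mer seed length in nucleotide mode.
#' @param xdrop_protein,xdrop_nucleotide X-drop termination threshold for
#'   ungapped extension (score units).
#' @param min_score_protein,min_score_nucleotide minimum hit score.
#' @param min_hit_len minimum nucleotide hit length (bp), nucleotide mode.
#' @param matrix protein substitution matrix name (only `"BLOSUM62"`).
#' @param match,mismatch nucleotide scoring.
#' @param gap_open,gap_extend affine gap costs, subtracted, for the gapped
#'   refinement stage.
#' @param band extra width (bp) added around the ungapped core for gapped
#'   refinement.
#' @param chain_gap hits on the same strand for the same query separated by at
#'   most this many bp are chained into one (repairs X-drop fragmentation
#'   across diverged patches).
#' @return a list of class `search_config`.
#' @export
search_config <- function(protein_seed_k = 4L, nucleotide_seed_k = 11L,
                          xdrop_protein = 20, xdrop_nucleotide = 16,
                          min_score_protein = 50, min_score_nucleotide = 30,
                          min_hit_len = 90L, matrix = "BLOSUM62",
                          match = 1, mismatch = -1,
                          gap_open = 5, gap_extend = 1,
                          band = 15L, chain_gap = 90L) {
  stopifnot(protein_seed_k >= 2L, nucleotide_seed_k >= 2L,
            xdrop_protein > 0, xdrop_nucleotide > 0,
            min_score_protein > 0, min_score_nucleotide > 0)
  structure(as.list(environment()), class = "search_config")
}

blosum_env <- new.env(parent = emptyenv())
get_blosum62 <- function() {
  if (is.null(blosum_env$mat)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    blosum_env$mat <- e$BLOSUM62
  }
  blosum_env$mat
}

seq_chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

kmerize <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character(0))
  substring(s, 1:(n - k + 1L), k:n)
}

# all (text position, query position) pairs sharing an exact k-mer
kmer_match_pairs <- function(text_kmers, query_kmers) {
  if (!length(text_kmers) || !length(query_kmers)) return(NULL)
  uq <- unique(query_kmers)
  m <- match(text_kmers, uq)
  t_idx <- which(!is.na(m))
  if (!length(t_idx)) return(NULL)
  qpos_by <- split(seq_along(query_kmers), query_kmers)
  ql <- qpos_by[uq[m[t_idx]]]
  n_each <- lengths(ql)
  list(tpos = rep.int(t_idx, n_each), qpos = unlist(ql, use.names = FALSE))
}

# best-scoring prefix of an extension under X-drop termination
xdrop_best <- function(s, xdrop) {
  if (!length(s)) return(list(len = 0L, score = 0))
  cum <- cumsum(s)
  rmax <- cummax(cum)
  over <- which(rmax - cum > xdrop)
  lim <- if (length(over)) over[1L] else length(s)
  cuml <- cum[seq_len(lim)]
  best <- which.max(cuml)
  if (cuml[best] <= 0) list(len = 0L, score = 0)
  else list(len = best, score = cuml[best])
}

# Ungapped X-drop extension of every seed match, with per-diagonal skipping of
# seeds already covered by an earlier extension on the same diagonal.
ungapped_cores <- function(tchars, qchars, pairs, k, xdrop, scorer) {
  if (is.null(pairs)) return(NULL)
  d <- pairs$tpos - pairs$qpos
  ord <- order(d, pairs$tpos)
  tn <- length(tchars); qn <- length(qchars)
  out_t0 <- integer(0); out_t1 <- integer(0)
  out_q0 <- integer(0); out_q1 <- integer(0); out_sc <- numeric(0)
  last_d <- NA_integer_; last_end <- 0L
  for (i in ord) {
    tp <- pairs$tpos[i]; qp <- pairs$qpos[i]; di <- tp - qp
    if (!is.na(last_d) && di == last_d && tp <= last_end) next
    seed_sc <- sum(scorer(tchars[tp:(tp + k - 1L)], qchars[qp:(qp + k - 1L)]))
    limr <- min(tn - (tp + k - 1L), qn - (qp + k - 1L))
    r <- if (limr > 0L)
      xdrop_best(scorer(tchars[(tp + k):(tp + k - 1L + limr)],
                        qchars[(qp + k):(qp + k - 1L + limr)]), xdrop)
    else list(len = 0L, score = 0)
    liml <- min(tp - 1L, qp - 1L)
    l <- if (liml > 0L)
      xdrop_best(scorer(tchars[(tp - 1L):(tp - liml)],
                        qchars[(qp - 1L):(qp - liml)]), xdrop)
    else list(len = 0L, score = 0)
    out_t0 <- c(out_t0, tp - l$len); out_t1 <- c(out_t1, tp + k - 1L + r$len)
    out_q0 <- c(out_q0, qp - l$len); out_q1 <- c(out_q1, qp + k - 1L + r$len)
    out_sc <- c(out_sc, seed_sc + l$score + r$score)
    last_d <- di; last_end <- tp + k - 1L + r$len
  }
  if (!length(out_t0)) return(NULL)
  data.frame(tstart = out_t0, tend = out_t1, qstart = out_q0, qend = out_q1,
             score = out_sc)
}

protein_scorer <- function() {
  mat <- get_blosum62()
  function(a, b) {
    a[!a %in% rownames(mat)] <- "X"
    b[!b %in% rownames(mat)] <- "X"
    mat[cbind(a, b)]
  }
}

nuc_scorer <- function(match, mismatch) {
  function(a, b) {
    ifelse(a == b & a != "N", match, mismatch)
  }
}

empty_hits <- function() {
  data.frame(query_id = character(0), contig = character(0),
             start = integer(0), end = integer(0), strand = character(0),
             frame = integer(0), score = numeric(0), identity = numeric(0),
             stringsAsFactors = FALSE)
}

#' Precompute a k-mer index over a genome
#'
#' Built once and reused across searches against the same genome (the
#' iterative consensus-elongation loop re-searches repeatedly).
#'
#' @param genome list of nucleotide [named_seq()] contigs.
#' @param cfg a [search_config()].
#' @param mode `"protein"` (six-frame translated index) or `"nucleotide"`.
#' @return an opaque index object accepted by the search functions.
#' @export
genome_index <- function(genome, cfg = search_config(),
                         mode = c("nucleotide", "protein")) {
  mode <- match.arg(mode)
  if (inherits(genome, "named_seq")) genome <- list(genome)
  idx <- lapply(genome, function(ctg) {
    stopifnot(ctg$alphabet == "nucleotide")
    if (mode == "nucleotide") {
      list(id = ctg$id, len = nchar(ctg$residues),
           chars = seq_chars(ctg$residues),
           kmers = kmerize(ctg$residues, cfg$nucleotide_seed_k),
           nruns = n_runs(ctg$residues))
    } else {
      frames <- lapply(translate_six_frames(ctg$residues), function(fr) {
        list(frame = fr$frame, offset = fr$offset,
             chars = seq_chars(fr$protein),
             kmers = kmerize(fr$protein, cfg$protein_seed_k))
      })
      list(id = ctg$id, len = nchar(ctg$residues), frames = frames,
           nruns = n_runs(ctg$residues))
    }
  })
  names(idx) <- vapply(idx, `[[`, character(1), "id")
  structure(list(mode = mode, contigs = idx), class = "genome_index")
}

# clip an interval so it does not cross any >=10-N assembly-gap run; keeps the
# largest clean piece
clip_to_n_runs <- function(start, end, nruns) {
  if (is.null(nruns) || nrow(nruns) == 0L) return(c(start, end))
  cross <- nruns[nruns[, "start"] <= end & nruns[, "end"] >= start, ,
                 drop = FALSE]
  if (nrow(cross) == 0L) return(c(start, end))
  cuts <- sort(unique(c(start - 1L, pmax(start - 1L, cross[, "start"] - 1L),
                        pmin(end, cross[, "end"]), end)))
  best <- c(start, start - 1L)
  for (i in seq_len(length(cuts) - 1L)) {
    s <- cuts[i] + 1L; e <- cuts[i + 1L]
    inrun <- any(cross[, "start"] <= s & cross[, "end"] >= e)
    if (!inrun && (e - s) > (best[2] - best[1])) best <- c(s, e)
  }
  best
}

# chain same-strand hits for one query separated by <= chain_gap bp, then
# drop hits reciprocally overlapping an accepted better hit by >= 50%
merge_hits <- function(hits, chain_gap) {
  if (is.null(hits) || nrow(hits) == 0L) return(empty_hits())
  chained <- do.call(rbind, lapply(
    split(hits, list(hits$query_id, hits$contig, hits$strand), drop = TRUE),
    function(g) {
      g <- g[order(g$start, g$end), , drop = FALSE]
      grp <- cumsum(c(1L, ifelse(g$start[-1] - cummax(g$end)[-nrow(g)] - 1L >
                                   chain_gap, 1L, 0L)))
      do.call(rbind, lapply(split(g, grp), function(p) {
        len <- p$end - p$start + 1L
        data.frame(query_id = p$query_id[1], contig = p$contig[1],
                   start = min(p$start), end = max(p$end),
                   strand = p$strand[1],
                   frame = p$frame[which.max(p$score)],
                   score = sum(p$score),
                   identity = sum(p$identity * len) / sum(len),
                   stringsAsFactors = FALSE)
      }))
    }))
  rownames(chained) <- NULL
  ord <- order(-chained$score, chained$contig, chained$start, chained$end)
  chained <- chained[ord, , drop = FALSE]
  keep <- logical(nrow(chained))
  for (i in seq_len(nrow(chained))) {
    h <- chained[i, ]
    acc <- which(keep & chained$contig == h$contig &
                   chained$strand == h$strand)
    absorbed <- FALSE
    for (j in acc) {
      a <- chained[j, ]
      ov <- min(h$end, a$end) - max(h$start, a$start) + 1L
      if (ov > 0 && ov >= 0.5 * (h$end - h$start + 1L) &&
          ov >= 0.5 * (a$end - a$start + 1L)) { absorbed <- TRUE; break }
    }
    keep[i] <- !absorbed
  }
  out <- chained[keep, , drop = FALSE]
  out <- out[order(out$contig, out$start, out$end, out$query_id), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Search a genome with protein seeds
#'
#' Six-frame translated seed-and-extend: each contig is translated in all six
#' frames, exact protein k-mers shared with a seed are extended without gaps
#' under BLOSUM62 with X-drop termination, surviving extensions are mapped
#' back to forward-strand nucleotide coordinates, chained, and merged.
#' Deterministic for fixed input and configuration.
#'
#' @param genome list of nucleotide [named_seq()] contigs (ignored when `index`
#'   is supplied).
#' @param seeds list of protein [named_seq()] seeds.
#' @param cfg a [search_config()].
#' @param index optional prebuilt protein-mode [genome_index()].
#' @return hit table: `query_id, contig, start, end, strand, frame, score,
#'   identity`, 1-based inclusive coordinates, sorted by (contig, start).
#' @export
search_protein_seeds <- function(genome, seeds, cfg = search_config(),
                                 index = NULL) {
  if (inherits(seeds, "named_seq")) seeds <- list(seeds)
  if (length(seeds) == 0L) stop("no seeds supplied")
  for (s in seeds) if (s$alphabet != "protein")
    stop("protein-mode search requires protein seeds (got nucleotide: ",
         s$id, ")")
  if (is.null(index)) index <- genome_index(genome, cfg, "protein")
  stopifnot(index$mode == "protein")
  scorer <- protein_scorer()
  k <- cfg$protein_seed_k
  rows <- list()
  for (seed in seeds) {
    schars <- seq_chars(seed$residues)
    skmers <- kmerize(seed$residues, k)
    for (ctg in index$contigs) {
      for (fr in ctg$frames) {
        pairs <- kmer_match_pairs(fr$kmers, skmers)
        cores <- ungapped_cores(fr$chars, schars, pairs, k,
                                cfg$xdrop_protein, scorer)
        if (is.null(cores)) next
        cores <- cores[cores$score >= cfg$min_score_protein, , drop = FALSE]
        if (!nrow(cores)) next
        for (i in seq_len(nrow(cores))) {
          int0 <- codon_to_nuc(fr$frame, cores$tstart[i], ctg$len)
          int1 <- codon_to_nuc(fr$frame, cores$tend[i], ctg$len)
          lo <- min(int0, int1); hi <- max(int0, int1)
          cl <- clip_to_n_runs(lo, hi, ctg$nruns)
          if (cl[2] < cl[1]) next
          span <- cores$tend[i] - cores$tstart[i] + 1L
          ident <- sum(fr$chars[cores$tstart[i]:cores$tend[i]] ==
                         schars[cores$qstart[i]:cores$qend[i]]) / span
          rows[[length(rows) + 1L]] <- data.frame(
            query_id = seed$id, contig = ctg$id,
            start = cl[1], end = cl[2],
            strand = if (fr$frame > 0) "+" else "-",
            frame = fr$frame, score = cores$score[i], identity = ident,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  merge_hits(if (length(rows)) do.call(rbind, rows) else NULL, cfg$chain_gap)
}

#' Search a genome with a nucleotide query
#'
#' K-mer seeding on both strands, ungapped X-drop extension, then gapped
#' refinement of each core by affine local alignment of the query against the
#' core region widened by the unaligned query remainder plus `cfg$band` bp.
#' Hits below `min_hit_len` or `min_score_nucleotide` are dropped; overlapping
#' same-strand hits are merged keeping the best score.
#'
#' @inheritParams search_protein_seeds
#' @param query a nucleotide [named_seq()].
#' @param index optional prebuilt nucleotide-mode [genome_index()].
#' @return hit table as in [search_protein_seeds()] with `frame = 0`.
#' @export
search_nucleotide <- function(genome, query, cfg = search_config(),
                              index = NULL) {
  stopifnot(inherits(query, "named_seq"), query$alphabet == "nucleotide")
  k <- cfg$nucleotide_seed_k
  if (nchar(query$residues) < k)
    stop("query shorter than the seed k-mer length (", k, ")")
  if (is.null(index)) index <- genome_index(genome, cfg, "nucleotide")
  stopifnot(index$mode == "nucleotide")
  scorer <- nuc_scorer(cfg$match, cfg$mismatch)
  submat <- Biostrings::nucleotideSubstitutionMatrix(
    match = cfg$match, mismatch = cfg$mismatch, baseOnly = FALSE)
  oriented <- list(`+` = query$residues, `-` = revcomp(query$residues))
  qlen <- nchar(query$residues)
  rows <- list()
  for (strand in c("+", "-")) {
    qres <- oriented[[strand]]
    qchars <- seq_chars(qres)
    qkmers <- kmerize(qres, k)
    qdna <- Biostrings::DNAString(qres)
    for (ctg in index$contigs) {
      pairs <- kmer_match_pairs(ctg$kmers, qkmers)
      cores <- ungapped_cores(ctg$chars, qchars, pairs, k,
                              cfg$xdrop_nucleotide, scorer)
      if (is.null(cores)) next
      # chain cores along each diagonal (repairs X-drop breaks at diverged
      # patches), rescoring the chained run by direct comparison
      cores$diag <- cores$tstart - cores$qstart
      runs <- do.call(rbind, lapply(split(cores, cores$diag), function(g) {
        g <- g[order(g$tstart), , drop = FALSE]
        grp <- cumsum(c(1L, ifelse(g$tstart[-1] - cummax(g$tend)[-nrow(g)] -
                                     1L > cfg$chain_gap, 1L, 0L)))
        do.call(rbind, lapply(split(g, grp), function(p) {
          ts <- min(p$tstart); te <- max(p$tend)
          qs <- min(p$qstart); qe <- max(p$qend)
          nm <- sum(ctg$chars[ts:te] == qchars[qs:qe] &
                      qchars[qs:qe] != "N")
          len <- te - ts + 1L
          data.frame(tstart = ts, tend = te, qstart = qs, qend = qe,
                     diag = p$diag[1], score = 2L * nm - len,
                     identity = nm / len)
        }))
      }))
      rownames(runs) <- NULL
      # group diagonal runs whose genome intervals overlap: a single run is
      # an ungapped hit as-is; several diagonals mean indels, so refine by
      # affine local alignment over the banded window
      runs <- runs[order(-runs$score, runs$tstart), , drop = FALSE]
      taken <- rep(FALSE, nrow(runs))
      for (i in seq_len(nrow(runs))) {
        if (taken[i]) next
        ov <- pmin(runs$tend, runs$tend[i]) -
          pmax(runs$tstart, runs$tstart[i]) + 1L
        len_i <- runs$tend[i] - runs$tstart[i] + 1L
        len_all <- runs$tend - runs$tstart + 1L
        grp <- which(!taken & ov > 0 & ov >= 0.5 * pmin(len_i, len_all))
        grp <- setdiff(grp, i)
        taken[grp] <- TRUE
        if (length(grp) == 0L) {
          # ungapped fast path
          if (runs$score[i] < cfg$min_score_nucleotide) next
          cl <- clip_to_n_runs(runs$tstart[i], runs$tend[i], ctg$nruns)
          if (cl[2] - cl[1] + 1L < cfg$min_hit_len) next
          rows[[length(rows) + 1L]] <- data.frame(
            query_id = query$id, contig = ctg$id, start = cl[1],
            end = cl[2], strand = strand, frame = 0L,
            score = runs$score[i], identity = runs$identity[i],
            stringsAsFactors = FALSE)
          next
        }
        sub <- runs[c(i, grp), , drop = FALSE]
        w0 <- max(1L, min(sub$tstart - (sub$qstart - 1L)) - cfg$band)
        w1 <- min(ctg$len, max(sub$tend + (qlen - sub$qend)) + cfg$band)
        window <- paste(ctg$chars[w0:w1], collapse = "")
        aln <- Biostrings::pairwiseAlignment(
          qdna, Biostrings::DNAString(window), type = "local",
          substitutionMatrix = submat,
          gapOpening = cfg$gap_open, gapExtension = cfg$gap_extend)
        sc <- Biostrings::score(aln)
        if (sc < cfg$min_score_nucleotide) next
        srange <- aln@subject@range
        cl <- clip_to_n_runs(w0 + IRanges::start(srange) - 1L,
                             w0 + IRanges::end(srange) - 1L, ctg$nruns)
        if (cl[2] - cl[1] + 1L < cfg$min_hit_len) next
        nm <- Biostrings::nmatch(aln); nmm <- Biostrings::nmismatch(aln)
        rows[[length(rows) + 1L]] <- data.frame(
          query_id = query$id, contig = ctg$id, start = cl[1], end = cl[2],
          strand = strand, frame = 0L, score = sc,
          identity = if (nm + nmm > 0) nm / (nm + nmm) else 0,
          stringsAsFactors = FALSE)
      }
    }
  }
  merge_hits(if (length(rows)) do.call(rbind, rows) else NULL, cfg$chain_gap)
}

#' Extract hit regions with flanking sequence
#'
#' The top-scoring hits are pulled out of the genome together with flanking
#' sequence on both sides (default 5000 bp, up to 10 copies, following
#' standard repeat-curation practice). Minus-strand copies are
#' reverse-complemented so that every returned region is in element
#' orientation: the left flank precedes the element 5' end.
#'
#' @param genome list of nucleotide [named_seq()] contigs.
#' @param hits hit table from a search function.
#' @param flank flanking bp on each side.
#' @param max_copies maximum number of regions, best score first.
#' @return list of `hit_region` objects with fields `copy_id, copy,
#'   left_flank, right_flank, contig, start, end, strand, score, identity,
#'   trunc_left, trunc_right` (`trunc_*` flag flanks clipped at contig edges;
#'   coordinates are forward-strand, 1-based inclusive, element only).
#' @export
extract_hit_regions <- function(genome, hits, flank = 5000L,
                                max_copies = 10L) {
  stopifnot(flank >= 0L, max_copies >= 1L)
  if (inherits(genome, "named_seq")) genome <- list(genome)
  names(genome) <- vapply(genome, `[[`, character(1), "id")
  if (nrow(hits) == 0L) return(list())
  ord <- order(-hits$score, hits$contig, hits$start)
  hits <- hits[head(ord, max_copies), , drop = FALSE]
  lapply(seq_len(nrow(hits)), function(i) {
    h <- hits[i, ]
    ctg <- genome[[h$contig]]
    if (is.null(ctg)) stop("hit references unknown contig: ", h$contig)
    n <- nchar(ctg$residues)
    lf0 <- max(1L, h$start - flank)
    rf1 <- min(n, h$end + flank)
    copy <- substr(ctg$residues, h$start, h$end)
    left <- if (h$start > 1L) substr(ctg$residues, lf0, h$start - 1L) else ""
    right <- if (h$end < n) substr(ctg$residues, h$end + 1L, rf1) else ""
    tl <- nchar(left) < flank
    tr <- nchar(right) < flank
    if (h$strand == "-") {
      copy <- revcomp(copy)
      tmp <- left
      left <- if (nzchar(right)) revcomp(right) else ""
      right <- if (nzchar(tmp)) revcomp(tmp) else ""
      t2 <- tl; tl <- tr; tr <- t2
    }
    structure(list(
      copy_id = sprintf("%s:%d-%d(%s)", h$contig, h$start, h$end, h$strand),
      copy = copy, left_flank = left, right_flank = right,
      query_id = h$query_id, contig = h$contig, start = h$start, end = h$end,
      strand = h$strand, score = h$score, identity = h$identity,
      trunc_left = tl, trunc_right = tr), class = "hit_region")
  })
}

#' Write / read a hit table as TSV
#'
#' The on-disk interchange format uses 0-based half-open coordinates;
#' in-memory tables are 1-based inclusive. Conversion happens here, at the
#' boundary.
#'
#' @param hits hit table.
#' @param path TSV path.
#' @export
write_hits <- function(hits, path) {
  out <- hits
  out$start <- out$start - 1L
  names(out)[names(out) == "identity"] <- "identity_fraction"
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_hits
#' @export
read_hits <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE)
  x$start <- x$start + 1L
  names(x)[names(x) == "identity_fraction"] <- "identity"
  x
}
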