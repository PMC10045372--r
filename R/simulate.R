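#' Simulation configuration
#'
#' Describes a synthetic genome with implanted transposon families carrying
#' the structural features the analysis pipeline assumes: TGT..ACA terminal
#' signatures, terminal inverted repeats, an internal long ORF for autonomous
#' families, copies flanked by exact or degenerate TSDs drawn from discrete
#' length regimes (~4 / ~15 / ~25 bp), per-copy substitutions and indels, and
#' 5'/3' truncations.
#'
#' @param genome_length background genome length in bp (implanted copies add
#'   to it).
#' @param gc_fraction background GC content; the AT-rich default reflects the
#'   protist genomes this group of elements inhabits.
#' @param n_families number of independent element families.
#' @param copies_per_family copies implanted per family (scalar or range).
#' @param element_length template length range in bp.
#' @param tir_length terminal inverted repeat length in bp (under 50 here).
#' @param terminal_signature 5'/3' terminal 3-mers.
#' @param orf `"present"` (autonomous), `"absent"` or `"disrupted"`.
#' @param tsd_regime list of regimes, each `list(mean, weight, jitter)`;
#'   weights must sum to 1, lengths are drawn uniformly from `jitter`.
#' @param sub_rate,indel_rate per-base per-copy mutation rates.
#' @param tsd_degeneracy_rate per-base substitution rate in the right TSD
#'   copy only (the left copy stays the genomic original).
#' @param truncation_prob probability a copy loses 10-90% of one end.
#' @param seed RNG seed; identical configs give byte-identical output.
#' @return list of class `sim_config`.
#' @export
simulation_config <- function(genome_length = 200000L, gc_fraction = 0.33,
                              n_families = 10L, copies_per_family = 10L,
                              element_length = c(1000L, 1500L),
                              tir_length = 25L,
                              terminal_signature = c("TGT", "ACA"),
                              orf = c("present", "absent", "disrupted"),
                              tsd_regime = list(
                                list(mean = 4, weight = 0.7, jitter = c(4, 5)),
                                list(mean = 15, weight = 0.2,
                                     jitter = c(14, 15, 16)),
                                list(mean = 25, weight = 0.1,
                                     jitter = c(24, 25))),
                              sub_rate = 0.05, indel_rate = 0.005,
                              tsd_degeneracy_rate = 0.05,
                              truncation_prob = 0.2, seed = 42L) {
  orf <- match.arg(orf)
  w <- vapply(tsd_regime, `[[`, numeric(1), "weight")
  stopifnot(abs(sum(w) - 1) < 1e-9,
            sub_rate >= 0, sub_rate <= 1, indel_rate >= 0, indel_rate <= 1,
            tsd_degeneracy_rate >= 0, tsd_degeneracy_rate <= 1,
            truncation_prob >= 0, truncation_prob <= 1,
            tir_length < min(element_length) / 2)
  structure(list(genome_length = genome_length, gc_fraction = gc_fraction,
                 n_families = n_families,
                 copies_per_family = copies_per_family,
                 element_length = element_length, tir_length = tir_length,
                 terminal_signature = terminal_signature, orf = orf,
                 tsd_regime = tsd_regime, sub_rate = sub_rate,
                 indel_rate = indel_rate,
                 tsd_degeneracy_rate = tsd_degeneracy_rate,
                 truncation_prob = truncation_prob, seed = seed),
            class = "sim_config")
}

rand_bases <- function(n, gc) {
  sample(c("A", "T", "C", "G"), n, replace = TRUE,
         prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2))
}

random_orf_nt <- function(codons, stop_at = NA) {
  gc <- Biostrings::GENETIC_CODE
  ok <- names(gc)[gc != "*"]
  body <- sample(ok, codons - 1L, replace = TRUE)
  if (!is.na(stop_at)) body[stop_at - 1L] <- "TAA"
  paste0("ATG", paste(body, collapse = ""), "TAA")
}

#' Build an element template
#'
#' Random interior sequence at the configured GC, the terminal signature at
#' both extremities, a terminal inverted repeat (the first `tir_length` bases
#' reverse-complemented into the tail, which preserves the signature), and —
#' for autonomous templates — an embedded ATG-initiated stop-free ORF of 360
#' codons on the forward strand.
#'
#' @param cfg a [simulation_config()].
#' @param id template id.
#' @param seed optional seed; pass `NULL` to draw from the current RNG
#'   stream (as the multi-family generator does).
#' @return nucleotide [named_seq()].
#' @export
make_element_template <- function(cfg = simulation_config(), id = "template",
                                  seed = cfg$seed) {
  if (!is.null(seed)) set.seed(seed)
  rng <- range(cfg$element_length)
  orf_codons <- 350L
  orf_nt <- 3L * (orf_codons + 1L)
  reserved <- 2L * (cfg$tir_length + 10L)
  if (cfg$orf != "absent") {
    # autonomous templates cannot be shorter than TIRs + the ORF
    if (rng[2] < orf_nt + reserved)
      stop("element too short to hold the TIRs and a ", orf_codons,
           "-codon ORF")
    rng[1] <- max(rng[1], orf_nt + reserved)
  }
  L <- if (rng[1] == rng[2]) rng[1] else sample(rng[1]:rng[2], 1L)
  chars <- rand_bases(L, cfg$gc_fraction)
  chars[1:3] <- seq_chars(cfg$terminal_signature[1])
  tir <- cfg$tir_length
  if (tir > 0L) {
    chars[(L - tir + 1L):L] <-
      seq_chars(revcomp(paste(chars[1:tir], collapse = "")))
  }
  chars[(L - 2L):L] <- seq_chars(cfg$terminal_signature[2])
  if (cfg$orf != "absent") {
    orf <- random_orf_nt(orf_codons,
                         stop_at = if (cfg$orf == "disrupted") 150L else NA)
    at <- sample((tir + 11L):(L - tir - 10L - nchar(orf)), 1L)
    chars[at:(at + nchar(orf) - 1L)] <- seq_chars(orf)
  }
  named_seq(id, paste(chars, collapse = ""), "nucleotide")
}

#' Extract the template's transposase-like protein
#'
#' The longest ATG-initiated stop-free ORF across all six frames, translated;
#' used as the protein seed when running the pipeline on a simulated genome.
#'
#' @param template a nucleotide [named_seq()].
#' @param id id for the protein record.
#' @return protein [named_seq()], or `NULL` if no ORF of >= 100 codons.
#' @export
template_seed_protein <- function(template, id = paste0(template$id, "_p")) {
  best <- NULL; best_len <- 99L
  for (fr in translate_six_frames(template$residues)) {
    aa <- seq_chars(fr$protein)
    if (!length(aa)) next
    stops <- c(which(aa == "*"), length(aa) + 1L)
    for (m in which(aa == "M")) {
      stop_at <- stops[stops > m][1]
      if (stop_at - m > best_len) {
        best_len <- stop_at - m
        best <- paste(aa[m:(stop_at - 1L)], collapse = "")
      }
    }
  }
  if (is.null(best)) return(NULL)
  named_seq(id, best, "protein")
}

# mutate an element copy: substitutions then single-base indels
mutate_copy <- function(residues, sub_rate, indel_rate, gc) {
  ch <- seq_chars(residues)
  nsub <- stats::rbinom(1L, length(ch), sub_rate)
  if (nsub > 0L) {
    at <- sample(seq_along(ch), nsub)
    for (p in at) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
  }
  nind <- stats::rbinom(1L, length(ch), indel_rate)
  if (nind > 0L) {
    for (i in seq_len(nind)) {
      p <- sample(seq_along(ch), 1L)
      if (stats::runif(1) < 0.5 && length(ch) > 1L) ch <- ch[-p]
      else ch <- append(ch, rand_bases(1L, gc), after = p)
    }
  }
  list(residues = paste(ch, collapse = ""), substitutions = nsub,
       indels = nind)
}

draw_tsd_length <- function(regime) {
  w <- vapply(regime, `[[`, numeric(1), "weight")
  k <- sample(seq_along(regime), 1L, prob = w)
  jit <- regime[[k]]$jitter
  if (length(jit) == 1L) jit else sample(jit, 1L)
}

plan_copy <- function(template, cfg, copy_id) {
  mut <- mutate_copy(template$residues, cfg$sub_rate, cfg$indel_rate,
                     cfg$gc_fraction)
  res <- mut$residues
  t5 <- 0L; t3 <- 0L
  if (stats::runif(1) < cfg$truncation_prob) {
    cut <- round(stats::runif(1, 0.1, 0.9) * nchar(res))
    cut <- max(1L, min(cut, nchar(res) - 1L))
    if (stats::runif(1) < 0.5) {
      t5 <- cut
      res <- substr(res, cut + 1L, nchar(res))
    } else {
      t3 <- cut
      res <- substr(res, 1L, nchar(res) - cut)
    }
  }
  strand <- if (stats::runif(1) < 0.5) "+" else "-"
  list(copy_id = copy_id, element = if (strand == "+") res else revcomp(res),
       strand = strand, tsd_length = draw_tsd_length(cfg$tsd_regime),
       substitutions = mut$substitutions, indels = mut$indels,
       truncated_5 = t5, truncated_3 = t3)
}

degenerate_tsd <- function(tsd, rate) {
  if (nchar(tsd) == 0L || rate <= 0) return(tsd)
  ch <- seq_chars(tsd)
  n <- stats::rbinom(1L, length(ch), rate)
  if (n > 0L) {
    at <- sample(seq_along(ch), n)
    for (p in at) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
  }
  paste(ch, collapse = "")
}

# draw mutually spaced insertion sites in background coordinates
draw_sites <- function(n_bg, n_copies, max_tsd) {
  margin <- 2L * max_tsd
  lo <- margin + 1L; hi <- n_bg - margin
  if (hi - lo < n_copies * (margin + 1L))
    stop("genome too small for the requested copies")
  for (attempt in 1:50) {
    cand <- sort(sample(lo:hi, min(3L * n_copies, hi - lo)))
    # greedy spacing filter
    sel <- integer(0); last <- -Inf
    for (s in cand) {
      if (s - last >= margin) { sel <- c(sel, s); last <- s }
      if (length(sel) == n_copies) break
    }
    if (length(sel) == n_copies) return(sample(sel))  # random assignment
  }
  stop("genome too small for the requested copies")
}

#' Implant element copies into a genome
#'
#' Each copy duplicates the target site at its insertion point (left copy
#' upstream, right copy downstream of the element), inserts the — possibly
#' mutated, truncated, minus-strand — element between the two copies, and
#' optionally degenerates the right TSD copy. Ground truth is exact.
#'
#' @param genome a nucleotide [named_seq()] contig.
#' @param template element template from [make_element_template()].
#' @param cfg a [simulation_config()].
#' @param family family label recorded in truth.
#' @param sites optional pre-drawn insertion sites (background coordinates);
#'   drawn uniformly with mutual spacing when omitted.
#' @param n_copies number of copies when `sites` is omitted.
#' @param seed optional seed; `NULL` to use the current RNG stream.
#' @return list with `genome` (mutated contig) and `truth` (data.frame, one
#'   row per copy: final 1-based inclusive element interval, strand, TSD
#'   length and sequence, mutation and truncation counts).
#' @export
implant_copies <- function(genome, template, cfg = simulation_config(),
                           family = "fam1", sites = NULL,
                           n_copies = NULL, seed = cfg$seed) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(n_copies)) {
    rng <- range(cfg$copies_per_family)
    n_copies <- if (rng[1] == rng[2]) rng[1] else sample(rng[1]:rng[2], 1L)
  }
  max_tsd <- max(unlist(lapply(cfg$tsd_regime, `[[`, "jitter")))
  if (is.null(sites))
    sites <- draw_sites(nchar(genome$residues), n_copies, max_tsd)
  plans <- lapply(seq_len(n_copies), function(i)
    plan_copy(template, cfg, sprintf("%s_c%02d", family, i)))
  for (i in seq_along(plans)) {
    plans[[i]]$family <- family
    plans[[i]]$cfg_degen <- cfg$tsd_degeneracy_rate
  }
  splice_copies(genome, plans, sites)
}

# single splice pass over all planned insertions (possibly several families)
splice_copies <- function(genome, plans, sites) {
  stopifnot(length(plans) == length(sites))
  ord <- order(sites)
  plans <- plans[ord]; sites <- sites[ord]
  bg <- genome$residues
  pieces <- character(0)
  truth <- list()
  prev <- 1L
  offset <- 0L
  for (i in seq_along(plans)) {
    p <- plans[[i]]; s <- sites[i]
    L <- p$tsd_length
    target <- substr(bg, s, s + L - 1L)
    right_copy <- degenerate_tsd(target, p$cfg_degen %||% 0)
    pieces <- c(pieces, substr(bg, prev, s + L - 1L), p$element, right_copy)
    start <- s + L + offset
    truth[[i]] <- data.frame(
      family = p$family, copy_id = p$copy_id, contig = genome$id,
      insertion_site = s, start = start,
      end = start + nchar(p$element) - 1L, strand = p$strand,
      tsd_length = L, tsd_seq = target,
      substitutions = p$substitutions, indels = p$indels,
      truncated_5 = p$truncated_5, truncated_3 = p$truncated_3,
      stringsAsFactors = FALSE)
    offset <- offset + nchar(p$element) + nchar(right_copy)
    prev <- s + L
  }
  pieces <- c(pieces, substr(bg, prev, nchar(bg)))
  out <- genome
  out$residues <- paste(pieces, collapse = "")
  out$mask <- NULL
  list(genome = out, truth = do.call(rbind, truth))
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1L && is.na(a))) b else a

#' Simulate a genome with several implanted families
#'
#' Draws one template per family, plans mutually spaced insertion sites for
#' all copies jointly, and splices everything in a single deterministic pass.
#'
#' @param cfg a [simulation_config()].
#' @return list with `genome` (list of one contig), `truth` (data.frame over
#'   all copies), `templates` (per-family [named_seq()]s), `seeds` (per-family
#'   ORF proteins, autonomous configurations only) and `config`.
#' @export
simulate_genome <- function(cfg = simulation_config()) {
  set.seed(cfg$seed)
  bg <- named_seq("chr1",
                  paste(rand_bases(cfg$genome_length, cfg$gc_fraction),
                        collapse = ""), "nucleotide")
  templates <- lapply(seq_len(cfg$n_families), function(f)
    make_element_template(cfg, id = sprintf("fam%02d", f), seed = NULL))
  rngc <- range(cfg$copies_per_family)
  n_per <- if (rngc[1] == rngc[2]) rep(rngc[1], cfg$n_families)
           else sample(rngc[1]:rngc[2], cfg$n_families, replace = TRUE)
  max_tsd <- max(unlist(lapply(cfg$tsd_regime, `[[`, "jitter")))
  sites <- draw_sites(cfg$genome_length, sum(n_per), max_tsd)
  plans <- list()
  k <- 0L
  for (f in seq_len(cfg$n_families)) {
    for (i in seq_len(n_per[f])) {
      k <- k + 1L
      pl <- plan_copy(templates[[f]], cfg,
                      sprintf("fam%02d_c%02d", f, i))
      pl$family <- sprintf("fam%02d", f)
      plans[[k]] <- pl
    }
  }
  # degenerate the right TSD copies inside the splice via per-plan rate
  for (i in seq_along(plans)) plans[[i]]$cfg_degen <- cfg$tsd_degeneracy_rate
  spl <- splice_copies(bg, plans, sites)
  seeds <- if (cfg$orf == "present")
    Filter(Negate(is.null), lapply(templates, template_seed_protein))
  else list()
  list(genome = list(spl$genome), truth = spl$truth, templates = templates,
       seeds = seeds, config = cfg)
}

#' Simulate a family with a mixed TSD-length census
#'
#' The extreme mixed-regime case observed in this element group: one family
#' whose 11 full-length copies are flanked by 4 bp (7 copies), 5 bp (1), 15 bp
#' (2) and 24 bp (1) TSDs, plus 20 truncated copies that retain only one
#' terminus. Used to check that the census machinery reports discrete TSD
#' classes coexisting within a single family.
#'
#' @param seed RNG seed.
#' @param genome_length background length in bp.
#' @param full_lengths TSD lengths of the untruncated copies.
#' @param n_truncated number of additional truncated copies.
#' @return same structure as [simulate_genome()].
#' @export
simulate_mixed_census_family <- function(seed = 7L, genome_length = 120000L,
                                         full_lengths = c(rep(4L, 7L), 5L,
                                                          15L, 15L, 24L),
                                         n_truncated = 20L) {
  cfg <- simulation_config(genome_length = genome_length, n_families = 1L,
                           copies_per_family = length(full_lengths) +
                             n_truncated,
                           sub_rate = 0, indel_rate = 0,
                           tsd_degeneracy_rate = 0, truncation_prob = 0,
                           seed = seed)
  set.seed(seed)
  bg <- named_seq("chr1",
                  paste(rand_bases(genome_length, cfg$gc_fraction),
                        collapse = ""), "nucleotide")
  template <- make_element_template(cfg, id = "fam01", seed = NULL)
  n <- length(full_lengths) + n_truncated
  plans <- vector("list", n)
  for (i in seq_len(n)) {
    pl <- plan_copy(template, cfg, sprintf("fam01_c%02d", i))
    if (i <= length(full_lengths)) {
      pl$tsd_length <- full_lengths[i]
    } else {
      # force a truncation of 10-90% from one end
      cut <- round(stats::runif(1, 0.1, 0.9) * nchar(template$residues))
      cut <- max(100L, min(cut, nchar(template$residues) - 100L))
      res <- template$residues
      if (stats::runif(1) < 0.5) {
        pl$truncated_5 <- cut
        res <- substr(res, cut + 1L, nchar(res))
      } else {
        pl$truncated_3 <- cut
        res <- substr(res, 1L, nchar(res) - cut)
      }
      pl$element <- if (pl$strand == "+") res else revcomp(res)
    }
    pl$family <- "fam01"
    pl$cfg_degen <- 0
    plans[[i]] <- pl
  }
  sites <- draw_sites(genome_length, n, 35L)
  spl <- splice_copies(bg, plans, sites)
  list(genome = list(spl$genome), truth = spl$truth,
       templates = list(template),
       seeds = Filter(Negate(is.null),
                      list(template_seed_protein(template))),
       config = cfg)
}

#' Write / read a simulation truth table as TSV
#'
#' On disk the element interval is 0-based half-open (`start0`, `end`);
#' in memory it is 1-based inclusive.
#'
#' @param truth truth data.frame.
#' @param path TSV path.
#' @export
write_truth <- function(truth, path) {
  out <- truth
  names(out)[names(out) == "start"] <- "start0"
  out$start0 <- out$start0 - 1L
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE)
  x$start0 <- x$start0 + 1L
  names(x)[names(x) == "start0"] <- "start"
  x
}
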