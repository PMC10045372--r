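#' @importFrom Biostrings readBStringSet writeXStringSet BStringSet DNAString
#'   DNAStringSet AAString reverseComplement translate subseq IUPAC_CODE_MAP
#' @importFrom stats setNames
#' @importFrom utils head tail read.delim write.table
NULL

NUC_ALPHABET <- c("A", "C", "G", "T", "N")
PROT_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
                   "M", "F", "P", "S", "T", "W", "Y", "V", "X", "*")

#' Construct a named sequence record
#'
#' The basic unit handled by every stage: a contig, a protein seed, an element
#' copy or a consensus. Residues are stored uppercase; soft-masking (lowercase
#' in the source FASTA) is kept as a per-position logical flag but ignored by
#' all downstream computation.
#'
#' @param id identifier, non-empty, no whitespace.
#' @param residues sequence string; case-normalised to uppercase.
#' @param alphabet `"nucleotide"` or `"protein"`.
#' @param description optional free-text description.
#' @param mask optional logical vector, `TRUE` where the input was soft-masked.
#' @return An object of class `named_seq`.
#' @export
named_seq <- function(id, residues, alphabet = c("nucleotide", "protein"),
                      description = "", mask = NULL) {
  alphabet <- match.arg(alphabet)
  if (!is.character(id) || length(id) != 1L || !nzchar(id) || grepl("\\s", id))
    stop("sequence id must be a non-empty token without whitespace")
  raw <- as.character(residues)
  if (is.null(mask)) {
    chars <- strsplit(raw, "", fixed = TRUE)[[1]]
    mask <- chars %in% letters
  }
  res <- toupper(raw)
  if (alphabet == "nucleotide") res <- gsub("U", "T", res, fixed = TRUE)
  check_alphabet(res, alphabet, id)
  structure(list(id = id, residues = res, alphabet = alphabet,
                 description = description, mask = mask),
            class = "named_seq")
}

check_alphabet <- function(res, alphabet, id) {
  allowed <- if (alphabet == "nucleotide") NUC_ALPHABET else PROT_ALPHABET
  chars <- strsplit(res, "", fixed = TRUE)[[1]]
  bad <- which(!(chars %in% allowed))
  if (length(bad))
    stop(sprintf("illegal %s residue '%s' in record '%s' at position %d",
                 alphabet, chars[bad[1]], id, bad[1]))
  invisible(TRUE)
}

#' @export
print.named_seq <- function(x, ...) {
  cat(sprintf("<named_seq> %s [%s, %d residues]\n",
              x$id, x$alphabet, nchar(x$residues)))
  invisible(x)
}

seq_len_ns <- function(x) nchar(x$residues)

#' Read a FASTA file
#'
#' Records are returned in file order. Residues are normalised to uppercase
#' (with U mapped to T in nucleotide mode); lowercase soft-masking is recorded
#' in each record's `mask` but not otherwise interpreted.
#'
#' @param path FASTA file.
#' @param alphabet `"nucleotide"` or `"protein"`.
#' @return A named list of [named_seq()] records.
#' @export
read_fasta <- function(path, alphabet = c("nucleotide", "protein")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  full <- names(set)
  ids <- sub("\\s.*$", "", full)
  desc <- ifelse(grepl("\\s", full), sub("^\\S+\\s+", "", full), "")
  if (anyDuplicated(ids))
    stop("duplicate sequence id in ", path, ": ",
         ids[duplicated(ids)][1])
  if (any(!nzchar(ids))) stop("empty sequence id in ", path)
  recs <- lapply(seq_along(set), function(i) {
    named_seq(ids[i], as.character(set[[i]]), alphabet, desc[i])
  })
  setNames(recs, ids)
}

#' Write records to a FASTA file
#'
#' @param records list of [named_seq()] records; must be non-empty.
#' @param path output path.
#' @param width line-wrap width (default 60).
#' @export
write_fasta <- function(records, path, width = 60L) {
  if (inherits(records, "named_seq")) records <- list(records)
  if (length(records) == 0L) stop("refusing to write an empty FASTA file")
  stopifnot(width >= 1L)
  hdr <- vapply(records, function(r) {
    if (nzchar(r$description)) paste(r$id, r$description) else r$id
  }, character(1))
  set <- Biostrings::BStringSet(vapply(records, `[[`, character(1), "residues"))
  names(set) <- hdr
  Biostrings::writeXStringSet(set, filepath = path, width = width,
                              format = "fasta")
  invisible(path)
}

#' Reverse complement of a nucleotide string
#'
#' @param residues nucleotide string over A/C/G/T/N.
#' @return the reverse complement; `revcomp` is an involution and N maps to N.
#' @export
revcomp <- function(residues) {
  check_alphabet(toupper(residues), "nucleotide", "<revcomp input>")
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(residues)))
}

#' Translate a nucleotide string in all six frames
#'
#' Uses the standard genetic code; stop codons are rendered `*`; codons
#' containing N translate to `X`. Frames `+1,+2,+3` read the forward strand at
#' offsets 0..2, frames `-1,-2,-3` the reverse complement likewise.
#'
#' @param residues nucleotide string, length >= 3.
#' @return list keyed by frame label (`"+1"` .. `"-3"`), each element a list
#'   with `frame` (integer, signed), `protein` (string) and `offset` (0..2).
#'   Use [codon_to_nuc()] to map a protein position back to its codon's
#'   forward-strand nucleotide interval.
#' @export
translate_six_frames <- function(residues) {
  n <- nchar(residues)
  if (n < 3L) stop("need at least 3 nucleotides to translate")
  fwd <- Biostrings::DNAString(residues)
  rev <- Biostrings::reverseComplement(fwd)
  one <- function(dna, off) {
    w <- 3L * ((length(dna) - off) %/% 3L)
    if (w == 0L) return("")
    as.character(Biostrings::translate(
      Biostrings::subseq(dna, start = off + 1L, width = w),
      if.fuzzy.codon = "solve"))
  }
  out <- list()
  for (off in 0:2) {
    out[[sprintf("+%d", off + 1L)]] <-
      list(frame = off + 1L, protein = one(fwd, off), offset = off)
    out[[sprintf("-%d", off + 1L)]] <-
      list(frame = -(off + 1L), protein = one(rev, off), offset = off)
  }
  out
}

#' Map a translated position back to its codon on the forward strand
#'
#' @param frame signed frame in `{1,2,3,-1,-2,-3}`.
#' @param aa_index 1-based position in the frame's translation.
#' @param nuc_len length of the translated nucleotide sequence.
#' @return `c(start, end)`, the 1-based inclusive forward-strand interval of
#'   the codon.
#' @export
codon_to_nuc <- function(frame, aa_index, nuc_len) {
  stopifnot(frame %in% c(1:3, -(1:3)), aa_index >= 1L)
  off <- abs(frame) - 1L
  if (frame > 0) {
    start <- off + 3L * (aa_index - 1L) + 1L
    c(start, start + 2L)
  } else {
    # position on the reverse-complement strand, mapped back
    rc_start <- off + 3L * (aa_index - 1L) + 1L
    c(nuc_len - (rc_start + 2L) + 1L, nuc_len - rc_start + 1L)
  }
}

#' Match a window against an IUPAC degenerate pattern
#'
#' True iff every window position lies in the degeneracy set of the pattern
#' code at that position. An `N` in the *window* (an unknown base) matches only
#' the pattern code `N`: an unknown base is never accepted as evidence for a
#' specific-base requirement.
#'
#' @param pattern IUPAC nucleotide pattern (e.g. `"TNT"`, `"AYA"`).
#' @param window plain nucleotide window of the same length.
#' @return logical scalar.
#' @export
iupac_match <- function(pattern, window) {
  if (nchar(pattern) != nchar(window))
    stop("pattern and window must have equal length")
  p <- strsplit(toupper(pattern), "", fixed = TRUE)[[1]]
  w <- strsplit(toupper(window), "", fixed = TRUE)[[1]]
  codes <- Biostrings::IUPAC_CODE_MAP
  for (i in seq_along(p)) {
    if (!p[i] %in% names(codes)) stop("not an IUPAC code: ", p[i])
    if (w[i] == "N") {
      if (p[i] != "N") return(FALSE)
    } else {
      if (!grepl(w[i], codes[[p[i]]], fixed = TRUE)) return(FALSE)
    }
  }
  TRUE
}

# Runs of >= min_len consecutive N; returns a matrix with columns start,end
# (1-based inclusive). Hits and TSD calls must not cross such runs (assembly
# gaps); shorter N runs just count as mismatches.
n_runs <- function(residues, min_len = 10L) {
  r <- rle(strsplit(residues, "", fixed = TRUE)[[1]] == "N")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_len
  cbind(start = starts[keep], end = ends[keep])
}
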