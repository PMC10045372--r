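# Brute-force oracles and small fixture builders. These deliberately avoid
# the package's search/alignment code paths so they can serve as independent
# checks.

rand_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "T", "C", "G"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

rand_prot <- function(n) {
  aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  paste(sample(aa, n, replace = TRUE), collapse = "")
}

# deterministic reverse translation: lexicographically smallest codon per aa
encode_protein <- function(prot) {
  gc <- Biostrings::GENETIC_CODE
  tab <- vapply(split(names(gc), gc), function(x) sort(x)[1], character(1))
  paste(tab[strsplit(prot, "", fixed = TRUE)[[1]]], collapse = "")
}

# Smith-Waterman local alignment score, linear gap penalty, plain DP
sw_local_score <- function(a, b, scorer, gap = -6) {
  ac <- strsplit(a, "", fixed = TRUE)[[1]]
  bc <- strsplit(b, "", fixed = TRUE)[[1]]
  nb <- length(bc)
  prev <- numeric(nb + 1L)
  best <- 0
  for (i in seq_along(ac)) {
    cur <- numeric(nb + 1L)
    sub <- scorer(rep(ac[i], nb), bc)
    for (j in seq_len(nb)) {
      cur[j + 1L] <- max(0, prev[j] + sub[j], prev[j + 1L] + gap,
                         cur[j] + gap)
    }
    best <- max(best, max(cur))
    prev <- cur
  }
  best
}

blosum62_scorer <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  mat <- e$BLOSUM62
  function(a, b) mat[cbind(a, b)]
}

# global alignment identity by Needleman-Wunsch with match/mismatch/gap,
# identity over aligned non-gap columns
nw_identity <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  ac <- strsplit(a, "", fixed = TRUE)[[1]]
  bc <- strsplit(b, "", fixed = TRUE)[[1]]
  na <- length(ac); nb <- length(bc)
  S <- matrix(0, na + 1L, nb + 1L)
  S[, 1] <- gap * (0:na)
  S[1, ] <- gap * (0:nb)
  for (i in seq_len(na)) {
    for (j in seq_len(nb)) {
      d <- S[i, j] + if (ac[i] == bc[j]) match else mismatch
      S[i + 1L, j + 1L] <- max(d, S[i, j + 1L] + gap, S[i + 1L, j] + gap)
    }
  }
  # traceback counting matches and aligned columns
  i <- na; j <- nb; nm <- 0L; ncol <- 0L
  while (i > 0L && j > 0L) {
    d <- S[i, j] + if (ac[i] == bc[j]) match else mismatch
    if (S[i + 1L, j + 1L] == d) {
      nm <- nm + (ac[i] == bc[j]); ncol <- ncol + 1L
      i <- i - 1L; j <- j - 1L
    } else if (S[i + 1L, j + 1L] == S[i, j + 1L] + gap) {
      i <- i - 1L
    } else {
      j <- j - 1L
    }
  }
  nm / ncol
}

# exhaustive TSD oracle: for every candidate length, Hamming distance between
# the left-flank suffix and right-flank prefix; returns largest length within
# the budget rule (0 mismatches below 10 bp, floor(L/8) at >= 10 bp)
tsd_oracle <- function(left, right, max_len = 35L) {
  lmax <- min(max_len, nchar(left), nchar(right))
  for (L in rev(seq_len(lmax))) {
    ls <- strsplit(substr(left, nchar(left) - L + 1L, nchar(left)), "")[[1]]
    rs <- strsplit(substr(right, 1L, L), "")[[1]]
    mism <- sum(ls != rs | ls == "N" | rs == "N")
    budget <- if (L < 10L) 0L else L %/% 8L
    if (mism <= budget) return(list(length = L, mismatches = mism))
  }
  list(length = 0L, mismatches = 0L)
}

# flanks carrying an implanted exact duplication of length L that the
# exhaustive oracle confirms is the unique qualifying candidate (rejection
# sampling; without it a chance 1-2 bp suffix/prefix agreement would make the
# implanted length ill-defined)
tsd_fixture <- function(L, flank_len = 40L) {
  repeat {
    left <- rand_dna(flank_len)
    right <- rand_dna(flank_len)
    if (L > 0L) {
      t <- rand_dna(L)
      left <- paste0(substr(left, 1L, flank_len - L), t)
      right <- paste0(t, substr(right, L + 1L, flank_len))
    }
    if (tsd_oracle(left, right)$length == L)
      return(list(left = left, right = right))
  }
}

# exhaustive single-linkage components from a pairwise predicate matrix
sl_components <- function(link) {
  n <- nrow(link)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (link[i, j] && comp[j] != comp[i]) {
        comp[comp == max(comp[i], comp[j])] <- min(comp[i], comp[j])
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  match(comp, unique(comp))
}

# substitute a fraction of positions, never to the original character
mutate_seq <- function(s, rate, alphabet = c("A", "C", "G", "T")) {
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  k <- round(rate * length(ch))
  if (k == 0) return(list(seq = s, n = 0L, pos = integer(0)))
  pos <- sort(sample(seq_along(ch), k))
  for (p in pos) ch[p] <- sample(setdiff(alphabet, ch[p]), 1)
  list(seq = paste(ch, collapse = ""), n = k, pos = pos)
}
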