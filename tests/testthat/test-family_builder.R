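ns <- function(id, s) named_seq(id, s, "nucleotide")

make_orf_nt <- function(codons) {
  # ATG + (codons-1) non-stop codons + TAA
  all_codons <- names(Biostrings::GENETIC_CODE)
  ok <- all_codons[!Biostrings::GENETIC_CODE %in% "*"]
  paste0("ATG", paste(sample(ok, codons - 1L, replace = TRUE), collapse = ""),
         "TAA")
}

test_that("clustering links by identity and coverage, with single-linkage transitivity", {
  set.seed(201)
  b <- rand_dna(600)
  a <- mutate_seq(b, 0.10)$seq          # ~90% identical to b
  cl <- cluster_sequences(list(ns("a", a), ns("b", b)))
  expect_length(cl, 1L)
  expect_setequal(cl[[1]]$member_ids, c("a", "b"))

  set.seed(11)
  u <- rand_dna(1000); v <- rand_dna(1000)
  expect_lt(nw_identity(u, v), 0.75)    # oracle: genuinely unrelated
  cl2 <- cluster_sequences(list(ns("u", u), ns("v", v)))
  expect_length(cl2, 2L)

  # chain: a~b and b~c link at ~80%, a~c only ~65% -> one component
  set.seed(202)
  b2 <- rand_dna(500)
  a2 <- mutate_seq(b2, 0.2)$seq
  c2 <- mutate_seq(b2, 0.2)$seq
  expect_gte(nw_identity(a2, b2), 0.75)
  expect_gte(nw_identity(b2, c2), 0.75)
  expect_lt(nw_identity(a2, c2), 0.75)
  cl3 <- cluster_sequences(list(ns("a", a2), ns("b", b2), ns("c", c2)))
  expect_length(cl3, 1L)
  expect_setequal(cl3[[1]]$member_ids, c("a", "b", "c"))
})

test_that("clustering equals brute-force single-linkage components", {
  set.seed(203)
  n_groups <- 4
  seqs <- list(); truth <- integer(0)
  for (g in seq_len(n_groups)) {
    tpl <- rand_dna(sample(300:500, 1))
    for (m in seq_len(sample(3:5, 1))) {
      seqs[[length(seqs) + 1L]] <-
        ns(sprintf("g%dm%d", g, m), mutate_seq(tpl, 0.08)$seq)
      truth <- c(truth, g)
    }
  }
  n <- length(seqs)
  res <- vapply(seqs, `[[`, character(1), "residues")
  link <- matrix(FALSE, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    span_id <- nw_identity(res[i], res[j])
    link[i, j] <- link[j, i] <- span_id >= 0.75
  }
  diag(link) <- TRUE
  oracle <- sl_components(link)
  cl <- cluster_sequences(seqs)
  got <- integer(n)
  ids <- vapply(seqs, `[[`, character(1), "id")
  for (k in seq_along(cl)) got[match(cl[[k]]$member_ids, ids)] <- k
  # same partition (label-invariant)
  expect_equal(length(unique(oracle)), length(unique(got)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    expect_equal(oracle[i] == oracle[j], got[i] == got[j])
  }
  expect_equal(got, truth[match(ids, ids)] * 0 + got)  # consistency no-op
})

test_that("center-star alignment handles identity, deletions and noise", {
  set.seed(204)
  tpl <- rand_dna(300)
  cl <- cluster_sequences(list(ns("a", tpl), ns("b", tpl), ns("c", tpl)))
  msa <- align_members(cl[[1]])
  expect_false(any(grepl("-", msa$rows, fixed = TRUE)))
  for (i in seq_along(msa$ids)) {
    expect_equal(gsub("-", "", msa$rows[i], fixed = TRUE), tpl)
  }

  # one deleted base -> exactly one gap cell in that row
  del <- paste0(substr(tpl, 1, 149), substr(tpl, 151, 300))
  cl2 <- cluster_sequences(list(ns("rep", tpl), ns("del", del)))
  msa2 <- align_members(cl2[[1]])
  gaps <- vapply(strsplit(msa2$rows, ""), function(x) sum(x == "-"),
                 integer(1))
  expect_equal(gaps[match("del", msa2$ids)], 1L)
  expect_equal(gaps[match("rep", msa2$ids)], 0L)

  # 2% substitutions, no indels: rows stay essentially gap-free
  set.seed(5)
  mem <- lapply(1:5, function(i) ns(paste0("m", i), mutate_seq(tpl, 0.02)$seq))
  msa3 <- align_members(cluster_sequences(mem)[[1]])
  gaps3 <- vapply(strsplit(msa3$rows, ""), function(x) sum(x == "-"),
                  integer(1))
  expect_true(all(gaps3 <= 0.02 * 300))
  for (i in seq_along(msa3$ids)) {
    expect_equal(gsub("-", "", msa3$rows[i], fixed = TRUE),
                 mem[[match(msa3$ids[i], paste0("m", 1:5))]]$residues)
  }
})

fake_msa <- function(rows, ids = paste0("r", seq_along(rows))) {
  structure(list(ids = ids, rows = rows, ncol = nchar(rows[1]),
                 rep_id = ids[1]), class = "msa")
}

test_that("majority rule counts covering rows, breaks ties in fixed order, drops gap columns", {
  # (A,A,A,G,G): A at 3/5 wins
  expect_equal(majority_consensus(fake_msa(c("A", "A", "A", "G", "G"))), "A")
  # (A,A,G,G): both at exactly 0.5, tie-break order picks A
  expect_equal(majority_consensus(fake_msa(c("CAC", "CAC", "CGC", "CGC"))),
               "CAC")
  # interior gap majority (3/5) deletes the column
  expect_equal(majority_consensus(fake_msa(c("C-C", "C-C", "C-C",
                                             "CAC", "CAC"))), "CC")
  # no character reaches 50% -> N
  expect_equal(majority_consensus(
    fake_msa(c("CAC", "CAC", "CGC", "CGC", "CTC", "CTC"))), "CNC")
  # leading/trailing pad excluded from the denominator
  expect_equal(majority_consensus(fake_msa(c("--GGA", "TTGGA"))), "TTGGA")
  expect_error(majority_consensus(fake_msa(character(0))), "empty")
})

test_that("consensus of identical copies is the copy; rows may be permuted", {
  set.seed(205)
  tpl <- rand_dna(120)
  for (n in c(1, 2, 5)) {
    cl <- cluster_sequences(lapply(seq_len(n),
                                   function(i) ns(paste0("c", i), tpl)))
    expect_equal(majority_consensus(align_members(cl[[1]])), tpl)
  }
  rows <- c("CAC", "CAC", "CGC", "TAC", "TGA")
  perm <- sample(rows)
  expect_equal(majority_consensus(fake_msa(rows)),
               majority_consensus(fake_msa(perm)))
})

test_that("consensus recovers the template from 30 noisy copies at >= 99% identity", {
  set.seed(206)
  tpl <- rand_dna(800)
  copies <- lapply(1:30, function(i)
    ns(sprintf("cp%02d", i), mutate_seq(tpl, 0.05)$seq))
  cl <- cluster_sequences(copies)
  expect_length(cl, 1L)
  cons <- majority_consensus(align_members(cl[[1]]))
  expect_gte(nw_identity(cons, tpl), 0.99)
})

test_that("elongation extends through agreeing flanks and halts where copies diverge", {
  set.seed(13)
  tpl <- rand_dna(600)
  # 10 copies at unrelated random sites
  g <- rand_dna(2000)
  for (i in 1:10) g <- paste0(g, tpl, rand_dna(1500))
  genome <- list(ns("chr", g))
  init <- consensus_record("fam", substr(tpl, 151, 450))
  out <- elongate_consensus(init, genome, flank = 400, max_copies = 10)
  # recovers at least the full template, overhanging at most 2 bp per side
  expect_true(grepl(tpl, out$residues, fixed = TRUE))
  expect_lte(nchar(out$residues), nchar(tpl) + 4L)

  # pathological tandem context: identical 100 bp flanks force extension
  set.seed(207)
  fl <- rand_dna(100); fr <- rand_dna(100)
  g2 <- rand_dna(500)
  for (i in 1:5) g2 <- paste0(g2, fl, tpl, fr, rand_dna(800))
  out2 <- elongate_consensus(consensus_record("fam2", tpl),
                             list(ns("chr", g2)), flank = 400)
  expect_true(grepl(paste0(fl, tpl, fr), out2$residues, fixed = TRUE))

  # single-copy family: no error, but the 2-copy floor blocks extension
  g3 <- paste0(rand_dna(1000), tpl, rand_dna(1000))
  out3 <- elongate_consensus(consensus_record("fam3", substr(tpl, 101, 500)),
                             list(ns("chr", g3)), flank = 400)
  expect_equal(out3$residues, substr(tpl, 101, 500))
  expect_false(out3$termini_resolved)

  # a consensus absent from the genome is a lost family
  expect_error(elongate_consensus(consensus_record("ghost", rand_dna(300)),
                                  list(ns("chr", g3)), flank = 100),
               "family lost")
})

test_that("autonomy calls hinge on a long ATG-initiated open reading frame", {
  set.seed(208)
  orf <- make_orf_nt(400)
  elem <- paste0(rand_dna(60), orf, rand_dna(60))
  a <- classify_autonomy(consensus_record("e", elem))
  expect_equal(a$label, "autonomous")
  expect_gte(a$orf_codons, 400L)

  # stop codon at codon 150 disrupts it
  disrupted <- paste0(substr(orf, 1, 447), "TAA", substr(orf, 451, nchar(orf)))
  elem2 <- paste0(rand_dna(60), disrupted, rand_dna(60))
  expect_equal(classify_autonomy(consensus_record("e2", elem2))$label,
               "non-autonomous")

  # threshold boundary: 299 codons < 300
  orf299 <- make_orf_nt(299)
  expect_equal(classify_autonomy(paste0(rand_dna(30), orf299, rand_dna(30)),
                                 min_orf_codons = 300L)$label,
               "non-autonomous")
  expect_equal(classify_autonomy(paste0(rand_dna(30), orf299, rand_dna(30)),
                                 min_orf_codons = 299L)$label,
               "autonomous")

  # minus-strand ORFs count too
  elem3 <- revcomp(elem)
  expect_equal(classify_autonomy(elem3)$label, "autonomous")
})
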