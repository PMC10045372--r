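plant <- function(background, insert, at) {
  paste0(substr(background, 1, at - 1), insert,
         substr(background, at, nchar(background)))
}

test_that("protein search finds an exact in-frame planted copy on both strands", {
  set.seed(401)
  seed_prot <- named_seq("seedP", rand_prot(100), "protein")
  copy_nt <- encode_protein(seed_prot$residues)
  bg <- rand_dna(3000)
  g_fwd <- list(named_seq("c1", plant(bg, copy_nt, 1001), "nucleotide"))
  hits <- search_protein_seeds(g_fwd, list(seed_prot))
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$start, 1001L)
  expect_equal(hits$end, 1300L)
  expect_equal(hits$strand, "+")
  expect_equal(hits$identity, 1.0)

  g_rev <- list(named_seq("c1", plant(bg, revcomp(copy_nt), 1001),
                          "nucleotide"))
  hits_r <- search_protein_seeds(g_rev, list(seed_prot))
  expect_equal(nrow(hits_r), 1L)
  expect_equal(hits_r$strand, "-")
  expect_equal(c(hits_r$start, hits_r$end), c(1001L, 1300L))
  expect_equal(hits_r$identity, 1.0)
})

test_that("protein search tolerates 20% amino-acid substitutions (SW oracle check)", {
  set.seed(7)
  seed_prot <- named_seq("seedP", rand_prot(100), "protein")
  aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  mut <- mutate_seq(seed_prot$residues, 0.20, alphabet = aa)
  copy_nt <- encode_protein(mut$seq)
  genome <- list(named_seq("c1", plant(rand_dna(3000), copy_nt, 1501),
                           "nucleotide"))
  # the planted region must be findable in principle: brute-force local
  # alignment of the mutated protein vs the seed scores above min_score
  sw <- sw_local_score(mut$seq, seed_prot$residues, blosum62_scorer())
  expect_gte(sw, search_config()$min_score_protein)
  hits <- search_protein_seeds(genome, list(seed_prot))
  expect_gte(nrow(hits), 1L)
  planted <- c(1501L, 1800L)
  cov <- max(0, min(hits$end, planted[2]) - max(hits$start, planted[1]) + 1L)
  expect_gte(cov / 300, 0.8)
})

test_that("nucleotide search reports exact hits on both strands", {
  set.seed(402)
  q <- named_seq("q", rand_dna(300), "nucleotide")
  bg <- rand_dna(5000)
  g1 <- plant(bg, q$residues, 1001)
  g2 <- plant(g1, revcomp(q$residues), 4001)
  hits <- search_nucleotide(list(named_seq("c1", g2, "nucleotide")), q)
  expect_equal(nrow(hits), 2L)
  expect_setequal(hits$strand, c("+", "-"))
  fwd <- hits[hits$strand == "+", ]
  expect_equal(c(fwd$start, fwd$end), c(1001L, 1300L))
  expect_equal(fwd$identity, 1.0)
  expect_true(all(hits$frame == 0L))
})

test_that("nucleotide hit identity tracks the planted substitution level", {
  set.seed(3)
  q <- named_seq("q", rand_dna(400), "nucleotide")
  mut <- mutate_seq(q$residues, 0.05)
  genome <- list(named_seq("c1", plant(rand_dna(4000), mut$seq, 2001),
                           "nucleotide"))
  hits <- search_nucleotide(genome, q)
  expect_equal(nrow(hits), 1L)
  planted_identity <- 1 - mut$n / 400
  expect_lt(abs(hits$identity - planted_identity), 0.03)
  # independent check: global-alignment identity of the planted region
  expect_equal(nw_identity(q$residues, mut$seq), planted_identity)
})

test_that("planted-copy regions scoring above threshold are covered (SW oracle sweep)", {
  set.seed(404)
  cfg <- search_config()
  scorer <- blosum62_scorer()
  for (rep in 1:3) {
    seed_prot <- named_seq("s", rand_prot(80), "protein")
    mut <- mutate_seq(seed_prot$residues, sample(c(0, 0.1, 0.25), 1),
                      alphabet = strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]])
    at <- sample(500:2000, 1)
    genome <- list(named_seq("c1",
                             plant(rand_dna(3000), encode_protein(mut$seq), at),
                             "nucleotide"))
    sw <- sw_local_score(mut$seq, seed_prot$residues, scorer)
    hits <- search_protein_seeds(genome, list(seed_prot), cfg)
    if (sw >= cfg$min_score_protein) {
      planted <- c(at, at + 240 - 1L)
      cov <- if (nrow(hits)) max(0, min(hits$end, planted[2]) -
                                   max(hits$start, planted[1]) + 1L) else 0
      expect_gte(cov / 240, 0.8)
    }
  }
})

test_that("search is strand-invariant and deterministic", {
  set.seed(405)
  q <- named_seq("q", rand_dna(250), "nucleotide")
  g <- plant(plant(rand_dna(6000), q$residues, 1001),
             revcomp(q$residues), 500)
  genome <- list(named_seq("c1", g, "nucleotide"))
  flipped <- list(named_seq("c1", revcomp(g), "nucleotide"))
  h1 <- search_nucleotide(genome, q)
  h2 <- search_nucleotide(flipped, q)
  sig <- function(h) {
    x <- data.frame(len = h$end - h$start + 1L, score = h$score,
                    identity = h$identity)
    x[order(x$len, x$score, x$identity), ]
  }
  expect_equal(sig(h1), sig(h2), ignore_attr = TRUE)
  expect_setequal(h2$strand, chartr("+-", "-+", h1$strand))
  # byte-identical repeat run
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_hits(h1, f1)
  write_hits(search_nucleotide(genome, q), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("hit extraction caps copies, orients minus strands, flags clipped flanks", {
  set.seed(406)
  q <- named_seq("q", rand_dna(200), "nucleotide")
  bg <- rand_dna(12000)
  # 12 planted copies, increasingly mutated so scores differ
  sites <- seq(300, 11000, length.out = 12)
  g <- bg
  truth <- list()
  for (i in seq_along(sites)) {
    mut <- mutate_seq(q$residues, (i - 1) * 0.01)
    g <- plant(g, mut$seq, as.integer(sites[i]) + (i - 1L) * 200L)
    truth[[i]] <- mut
  }
  genome <- list(named_seq("c1", g, "nucleotide"))
  hits <- search_nucleotide(genome, q)
  expect_gte(nrow(hits), 12L)
  regions <- extract_hit_regions(genome, hits, flank = 500, max_copies = 10)
  expect_length(regions, 10L)
  # ranked by score descending
  scores <- vapply(regions, `[[`, numeric(1), "score")
  expect_equal(scores, sort(scores, decreasing = TRUE))
  expect_length(extract_hit_regions(genome, hits[1:3, ], flank = 500), 3L)

  # minus-strand orientation: copy comes back in query orientation
  g2 <- plant(rand_dna(2000), revcomp(q$residues), 901)
  gen2 <- list(named_seq("c1", g2, "nucleotide"))
  h2 <- search_nucleotide(gen2, q)
  r2 <- extract_hit_regions(gen2, h2, flank = 100)[[1]]
  expect_equal(r2$copy, q$residues)
  expect_equal(r2$left_flank, revcomp(substr(g2, 1101, 1200)))
  expect_equal(nchar(r2$right_flank), 100L)

  # flank clipped at the contig edge
  g3 <- plant(rand_dna(1000), q$residues, 101)
  gen3 <- list(named_seq("c1", g3, "nucleotide"))
  h3 <- search_nucleotide(gen3, q)
  r3 <- extract_hit_regions(gen3, h3, flank = 5000)[[1]]
  expect_equal(nchar(r3$left_flank), 100L)
  expect_true(r3$trunc_left)
})

test_that("hit tables round-trip through TSV with 0-based half-open coordinates", {
  h <- data.frame(query_id = "q", contig = "c1", start = 101L, end = 200L,
                  strand = "+", frame = 0L, score = 95, identity = 0.97,
                  stringsAsFactors = FALSE)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_hits(h, f)
  tab <- read.delim(f)
  expect_equal(tab$start, 100L)   # 0-based
  expect_equal(tab$end, 200L)     # half-open end == 1-based inclusive end
  expect_equal(read_hits(f), h, ignore_attr = TRUE)
})

test_that("search rejects degenerate inputs", {
  g <- list(named_seq("c1", rand_dna(100), "nucleotide"))
  expect_error(search_protein_seeds(g, list()), "no seeds")
  expect_error(search_protein_seeds(g, list(named_seq("x", "ACGT",
                                                      "nucleotide"))),
               "protein")
  expect_error(search_nucleotide(g, named_seq("q", "ACGT", "nucleotide")),
               "shorter than")
})
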