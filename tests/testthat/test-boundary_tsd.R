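mk_call <- function(len) {
  structure(list(copy_id = NA_character_, length = as.integer(len),
                 mismatches = 0L, left_seq = strrep("A", len),
                 right_seq = strrep("A", len),
                 class_label = classify_tsd_length(len)),
            class = "tsd_call")
}

test_that("call_tsd finds implanted duplications exactly and matches the brute-force oracle", {
  set.seed(2)
  for (L in 0:35) {
    for (trial in 1:3) {
      fx <- tsd_fixture(L)
      call <- call_tsd(fx$left, fx$right)
      o <- tsd_oracle(fx$left, fx$right)
      expect_equal(call$length, L)
      expect_equal(call$length, o$length)
      expect_equal(call$mismatches, o$mismatches)
      if (L > 0) {
        expect_equal(nchar(call$left_seq), L)
        expect_equal(nchar(call$right_seq), L)
      }
    }
  }
})

test_that("a shared 9-mer at the junction is called with zero mismatches", {
  set.seed(210)
  repeat {
    core <- "GGATCGATC"
    left <- paste0(rand_dna(15), core)
    right <- paste0(core, rand_dna(15))
    if (tsd_oracle(left, right)$length == 9L) break
  }
  call <- call_tsd(left, right)
  expect_equal(call$length, 9L)
  expect_equal(call$mismatches, 0L)
  expect_equal(call$left_seq, core)
})

test_that("degenerate long TSDs are callable within the mismatch budget", {
  set.seed(211)
  repeat {
    t <- rand_dna(25)
    mut <- mutate_seq(t, 2 / 25)          # 2 substitutions in the right copy
    if (mut$n == 2L && !1 %in% mut$pos && !25 %in% mut$pos) break
  }
  left <- paste0(rand_dna(15), t)
  right <- paste0(mut$seq, rand_dna(15))
  call <- call_tsd(left, right)
  expect_equal(call$length, 25L)
  expect_equal(call$mismatches, 2L)
  expect_equal(call$class_label, "~25")
})

test_that("independent random flanks almost never yield a long call (Monte-Carlo null)", {
  set.seed(1)
  lens <- integer(1000)
  for (i in 1:1000) lens[i] <- call_tsd(rand_dna(40), rand_dna(40))$length
  # false-positive control: calls of length >= 10 under the default budget
  expect_lt(mean(lens >= 10) , 0.01)
  # chance 1-3 bp suffix/prefix agreements occur at the expected
  # combinatorial rate (~ 1/4 + ...); nothing longer than a rare exact short
  # match should appear
  expect_lt(mean(lens >= 4), 0.02)
  expect_gt(mean(lens == 0), 0.60)
})

test_that("empty or N-gapped flanks give no call rather than an error", {
  expect_equal(call_tsd("", "ACGT")$length, 0L)
  expect_equal(call_tsd("ACGT", "")$length, 0L)
  # an assembly-gap run of >= 10 N may not be crossed
  left <- paste0(rand_dna(10), strrep("N", 12), "ACGTACGTACGTACG")
  right <- paste0(substr(left, 23, 37), strrep("N", 12), rand_dna(10))
  call <- call_tsd(left, right, max_len = 35)
  expect_lte(call$length, 15L)
})

test_that("TSD lengths classify into the discrete bins", {
  expect_equal(classify_tsd_length(4), "~4")
  expect_equal(classify_tsd_length(15), "~15")
  expect_equal(classify_tsd_length(24), "~25")
  expect_equal(classify_tsd_length(16), "~15")
  expect_equal(classify_tsd_length(5), "~4")
  expect_equal(classify_tsd_length(29), "~25")
  expect_equal(classify_tsd_length(10), "other")
  expect_equal(classify_tsd_length(0), "none")
  expect_error(classify_tsd_length(-1), "negative")
})

# hand-built family: element copies with given TSD lengths and clean flanks
region_family <- function(template, tsd_lens, flank = 100L,
                          truncate_5 = integer(0)) {
  lapply(seq_along(tsd_lens), function(i) {
    tsd <- rand_dna(tsd_lens[i])
    copy <- template
    if (i %in% truncate_5) copy <- substr(copy, 201L, nchar(copy))
    list(copy_id = paste0("cp", i), copy = copy,
         left_flank = paste0(rand_dna(flank), tsd),
         right_flank = paste0(tsd, rand_dna(flank)))
  })
}

test_that("find_termini recovers exact element bounds from signature plus TSD support", {
  set.seed(21)
  template <- paste0("TGT", rand_dna(594), "ACA")
  cons <- consensus_record("fam", paste0(rand_dna(5), template, rand_dna(5)))
  copies <- region_family(template, rep(15L, 10))
  tc <- find_termini(cons, copies)
  expect_equal(tc$terminus_5, 6L)
  expect_equal(tc$terminus_3, 5L + 600L)
  expect_equal(tc$supporting_copies, 10L)
  expect_true(tc$signature_matched)
  expect_equal(vapply(tc$calls, `[[`, integer(1), "length"), rep(15L, 10))

  # one 5'-truncated copy contributes no terminus evidence
  set.seed(21)
  copies2 <- region_family(template, rep(15L, 10), truncate_5 = 1L)
  tc2 <- find_termini(cons, copies2)
  expect_equal(tc2$terminus_5, 6L)
  expect_equal(tc2$terminus_3, 5L + 600L)
  expect_equal(tc2$supporting_copies, 9L)
})

test_that("degenerate TAT..ATA termini are recovered without the strict bonus", {
  set.seed(22)
  template <- paste0("TAT", rand_dna(594), "ATA")
  cons <- consensus_record("fam", paste0(rand_dna(4), template, rand_dna(4)))
  copies <- region_family(template, rep(4L, 8))
  tc <- find_termini(cons, copies)
  expect_equal(tc$terminus_5, 5L)
  expect_equal(tc$terminus_3, 4L + 600L)
  expect_true(tc$signature_matched)
  expect_gte(tc$supporting_copies, 7L)

  # same family, strict termini: strict bonus lifts the candidate score by 1
  set.seed(22)
  template_s <- paste0("TGT", substr(template, 4, 597), "ACA")
  cons_s <- consensus_record("fam", paste0(rand_dna(4), template_s,
                                           rand_dna(4)))
  copies_s <- region_family(template_s, rep(4L, 8))
  tc_s <- find_termini(cons_s, copies_s)
  expect_equal(tc_s$candidate_score - tc_s$supporting_copies -
                 ifelse(isTRUE(tc_s$tir$present), 0.5, 0), 1)
})

test_that("TIR detection anchors at both extremities", {
  set.seed(212)
  s25 <- rand_dna(25)
  mk_elem <- function(head, tail) {
    # interior chosen so the repeat cannot extend past 25 bp by chance
    repeat {
      mid <- rand_dna(400)
      if (substr(mid, 1, 1) != revcomp(substr(mid, 400, 400))) break
    }
    cr <- consensus_record("e", paste0(head, mid, tail))
    cr$termini_resolved <- TRUE
    cr$terminus_5 <- 1L
    cr$terminus_3 <- nchar(cr$residues)
    cr
  }
  tir <- detect_tir(mk_elem(s25, revcomp(s25)))
  expect_equal(tir$length, 25L)
  expect_equal(tir$identity, 1.0)
  expect_true(tir$present)

  # 2 mismatches in the 3' copy still detected
  mut <- mutate_seq(s25, 2 / 25)
  tir2 <- detect_tir(mk_elem(s25, revcomp(mut$seq)))
  expect_gte(tir2$length, 23L)
  # the local alignment may pick up a few chance columns past the repeat, so
  # the identity bound is the detector's own presence threshold
  expect_gte(tir2$identity, 0.8)
  expect_true(tir2$present)

  # random termini: spurious detections are rare
  set.seed(31)
  spurious <- 0L
  for (i in 1:100) {
    if (detect_tir(mk_elem(rand_dna(25), rand_dna(25)))$present)
      spurious <- spurious + 1L
  }
  expect_lte(spurious, 2L)

  expect_error(detect_tir(consensus_record("x", rand_dna(100))),
               "not resolved")
})

test_that("the family census reproduces exact-length and class histograms", {
  lens <- c(rep(4, 7), 5, 15, 15, 24)
  cen <- family_tsd_census(lapply(lens, mk_call))
  expect_equal(cen$exact, c("4" = 7L, "5" = 1L, "15" = 2L, "24" = 1L))
  expect_equal(cen$classes, c("~4" = 8L, "~15" = 2L, "~25" = 1L))
  expect_equal(cen$none, 0L)

  empty <- family_tsd_census(list())
  expect_length(empty$exact, 0L)
  expect_equal(empty$none, 0L)

  two <- family_tsd_census(lapply(c(15, 16), mk_call))
  expect_equal(two$classes, c("~15" = 2L))

  with_none <- family_tsd_census(lapply(c(4, 0, 0), mk_call))
  expect_equal(with_none$none, 2L)
  expect_equal(with_none$exact, c("4" = 1L))
})
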