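test_that("identical sequences score the sum of diagonal matrix entries", {
  # BLOSUM62 diagonal: A=4, C=9, D=6, E=5
  a <- smith_waterman("ACDE", "ACDE")
  expect_equal(a$score, 24)
  expect_equal(a$percent_identity, 100)
  expect_equal(c(a$query_start, a$query_end), c(1, 4))
  expect_false(a$gapped)
})

test_that("all-negative pair scores give score 0 and no coordinates", {
  a <- smith_waterman("AAAA", "WWWW")
  expect_equal(a$score, 0)
  expect_true(is.na(a$query_start))
})

test_that("smith_waterman equals exhaustive enumeration on short pairs", {
  withr::local_seed(101)
  ab <- c("A", "C", "D", "W")
  configs <- list(alignment_params(),                        # blastp-like
                  alignment_params(gap_open = 2L, gap_extend = 1L),  # gap-rich
                  alignment_params(ungapped = TRUE))
  for (p in configs) {
    for (i in 1:150) {
      q <- paste(sample(ab, sample(1:6, 1), TRUE), collapse = "")
      s <- paste(sample(ab, sample(1:6, 1), TRUE), collapse = "")
      expect_equal(smith_waterman(q, s, p)$score,
                   smith_waterman_exhaustive(q, s, p),
                   info = paste(q, s, p$gap_open, p$ungapped))
    }
  }
})

test_that("the aligner matches an independent local-alignment implementation", {
  withr::local_seed(7)
  aa <- rownames(trgstrat:::blosum62())[1:20]
  B62 <- trgstrat:::blosum62()
  for (i in 1:20) {
    q <- paste(sample(aa, 40, TRUE), collapse = "")
    s <- paste(sample(aa, 55, TRUE), collapse = "")
    ref <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(q), Biostrings::AAString(s), type = "local",
      substitutionMatrix = B62, gapOpening = 11, gapExtension = 1)
    expect_equal(smith_waterman(q, s)$score, Biostrings::score(ref))
  }
})

test_that("ambiguous residues score zero against everything", {
  # X contributes 0 even to itself: A-A + X-X + A-A = 4 + 0 + 4
  expect_equal(smith_waterman("AXA", "AXA")$score, 8)
  # ... and against any residue (A-A + W-X + A-A)
  expect_equal(smith_waterman("AWA", "AXA")$score, 8)
})

test_that("empty sequences and the seg flag are rejected", {
  expect_error(smith_waterman("", "ACDE"), "non-empty")
  expect_error(alignment_params(low_complexity_filter = TRUE),
               "not implemented")
})

test_that("E-values follow the Karlin-Altschul formula and monotonicities", {
  p <- alignment_params(lambda = 0.3, kappa = 0.1)
  expect_equal(evalue(50, 100, 1000, p), 0.1 * 100 * 1000 * exp(-0.3 * 50))
  # monotone decreasing in score
  s <- evalue(1:100, 100, 1000, p)
  expect_true(all(diff(s) < 0))
  # linear in n: doubling the database doubles E
  expect_equal(evalue(50, 100, 2000, p), 2 * evalue(50, 100, 1000, p))
  # vanishing at large scores
  expect_lt(evalue(1000, 100, 1000, p), 1e-100)
})

test_that("six-frame translation covers both strands with stops and partials", {
  tr <- translate_six_frames("ATGAAA")
  expect_equal(tr[["+1"]], "MK")
  expect_equal(translate_six_frames("TTTCAT")[["-1"]], "MK")
  # frame +3 of a 4 nt sequence has no full codon
  expect_equal(translate_six_frames("ATGA")[["+3"]], "")
  expect_equal(translate_six_frames("TAA")[["+1"]], "*")
  # reverse-complement symmetry: +1 of x equals -1 of revcomp(x)
  x <- "ATGGCCAAATTTGGG"
  expect_equal(translate_six_frames(x)[["+1"]],
               translate_six_frames(revcomp(x))[["-1"]])
})

test_that("tie-break picks the smallest query start, then subject start", {
  # two equal-scoring exact matches of "CC" in the subject
  a <- smith_waterman("CC", "AACCACC", alignment_params(ungapped = TRUE))
  expect_equal(a$subject_start, 3)
  b <- smith_waterman("AACCACC", "CC", alignment_params(ungapped = TRUE))
  expect_equal(b$query_start, 3)
})
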