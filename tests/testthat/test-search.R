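test_that("a query identical to one subject dominates the hit list", {
  withr::local_seed(1)
  q <- random_aa(80)
  proteome <- c(self = q, o1 = random_aa(90), o2 = random_aa(70))
  hits <- search_proteome(c(g1 = q), proteome)
  expect_true(nrow(hits) >= 1)
  expect_equal(hits$sseqid[1], "self")
  expect_equal(hits$evalue[1], min(hits$evalue))
})

test_that("unrelated random proteomes yield no hits at the strict cutoff", {
  withr::local_seed(2)
  q <- random_aa(60)
  proteome <- setNames(vapply(rep(80, 25), random_aa, character(1)),
                       paste0("r", 1:25))
  expect_equal(nrow(search_proteome(c(g1 = q), proteome)), 0)
})

test_that("a homolog of any isoform establishes presence", {
  withr::local_seed(3)
  isoA <- random_aa(70)
  isoB <- random_aa(70)
  gene <- fake_gene("g1", c(isoA, isoB))
  proteome <- c(hit_of_B = isoB, junk = random_aa(80))
  hits <- search_proteome(gene, proteome)
  expect_true("hit_of_B" %in% hits$sseqid)
})

test_that("translated genome search finds planted genes in the right frame", {
  withr::local_seed(4)
  prot <- random_aa(50)
  # uniform back-translation through the generator helper
  cds <- trgstrat:::back_translate(prot)
  genome <- c(scf1 = paste0("ACGTACG", cds, "TTACGGA"))
  hits <- search_genome_translated(prot, genome)
  expect_true(nrow(hits) >= 1)
  expect_true(hits$frame[1] > 0)
  # reverse complement: same score, negative frame
  rc <- c(scf1 = revcomp(genome[["scf1"]]))
  hits_rc <- search_genome_translated(prot, rc)
  expect_true(hits_rc$frame[1] < 0)
  expect_equal(hits_rc$bitscore[1], hits$bitscore[1])
  # random genome stays empty
  expect_equal(nrow(search_genome_translated(prot,
    c(r = paste(sample(c("A","C","G","T"), 600, TRUE), collapse = "")))), 0)
})

test_that("genome sequences shorter than a codon are skipped with a warning", {
  withr::local_seed(5)
  prot <- random_aa(40)
  genome <- c(tiny = "AC", ok = trgstrat:::back_translate(prot))
  expect_warning(hits <- search_genome_translated(prot, genome), "shorter")
  expect_true(nrow(hits) >= 1)
})

test_that("transcript support requires a word-seeded ungapped hit", {
  withr::local_seed(6)
  prot <- random_aa(60)
  gene <- fake_gene("g1", prot)
  # EST encoding 30 aa of the protein exactly: supported
  est30 <- substring(trgstrat:::back_translate(prot), 1, 90)
  expect_true(transcript_support(gene, c(e1 = est30)))
  # empty database: unsupported
  expect_false(transcript_support(gene, character(0)))
  # an EST encoding only a 10-aa exact match fails the 20-residue seed,
  # but passes when seeding is disabled
  est10 <- paste0(trgstrat:::back_translate(substring(prot, 1, 10)),
                  trgstrat:::back_translate(random_aa(25)))
  expect_false(transcript_support(gene, c(e1 = est10)))
  unseeded <- est_alignment_params(word_size = NULL)
  expect_true(transcript_support(gene, c(e1 = est10), unseeded))
})

test_that("EST mapping enforces the unique-gene rule and the length floor", {
  withr::local_seed(8)
  pA <- random_aa(120); pB <- random_aa(120)
  prots <- c(gA = pA, gB = pB)
  # EST encoding 60 aa of exactly one gene maps to it
  est <- substring(trgstrat:::back_translate(pA), 31, 210)
  expect_equal(as.character(map_est_to_genes(est, prots)), "gA")
  # EST matching two identical paralogs maps to none
  prots2 <- c(gA = pA, gB = pA)
  expect_true(is.na(map_est_to_genes(est, prots2)))
  # a short (< 33 aa) alignment is rejected
  est_short <- substring(trgstrat:::back_translate(pA), 1, 75)
  expect_true(is.na(map_est_to_genes(est_short, prots)))
})

test_that("hit tables are deterministic and order-independent", {
  withr::local_seed(9)
  q <- random_aa(60)
  hom <- trgstrat:::mutate_protein(q, 0.2)
  proteome <- c(a = hom, b = random_aa(60), c = q)
  h1 <- search_proteome(c(g = q), proteome)
  h2 <- search_proteome(c(g = q), proteome[c(3, 1, 2)])
  expect_equal(h1$sseqid, h2$sseqid)
  expect_equal(h1$evalue, h2$evalue)
})
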