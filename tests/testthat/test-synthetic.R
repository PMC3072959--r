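# A small world keeps the routine suite fast; the full-size study
# conditions are exercised by the acceptance suite.
small_config <- function(seed, ...) {
  synthetic_config(
    seed = seed,
    genes_per_class = c(orphan = 6, hymenoptera = 3, social_insect = 3,
                        hymenoptera_conserved = 3, insect = 4, metazoa = 8,
                        other = 3),
    background_proteins = 8L,
    ...)
}

dir_md5 <- function(dir) {
  files <- sort(list.files(dir, recursive = TRUE, full.names = TRUE))
  m <- tools::md5sum(files)
  names(m) <- sub(dir, "", names(m), fixed = TRUE)
  m
}

test_that("identical seeds produce byte-identical worlds", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  d3 <- withr::local_tempdir()
  generate_world(small_config(42), d1)
  generate_world(small_config(42), d2)
  expect_identical(dir_md5(d1), dir_md5(d2))
  generate_world(small_config(43), d3)
  expect_false(identical(unname(dir_md5(d1)), unname(dir_md5(d3))))
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(1234); before <- runif(3)
  set.seed(1234); invisible(runif(1))
  generate_world(small_config(42), withr::local_tempdir())
  after <- runif(2)
  expect_equal(after, before[2:3])
})

test_that("mutate_protein is identity at distance zero and Poisson-occupied", {
  withr::local_seed(60)
  p <- random_aa(200)
  expect_identical(mutate_protein(p, 0), p)
  # occupancy: expected substituted fraction is 1 - exp(-d)
  d <- 0.3
  frac <- replicate(300, {
    m <- mutate_protein(p, d)
    mean(strsplit(m, "")[[1]] != strsplit(p, "")[[1]])
  })
  expect_equal(mean(frac), 1 - exp(-d), tolerance = 0.02)
  # heavy divergence decays towards the score of unrelated sequences
  far <- mutate_protein(p, 8)
  null_score <- smith_waterman(random_aa(200), random_aa(200))$score
  expect_lt(smith_waterman(p, far)$score, 4 * null_score)
  expect_error(mutate_protein(p, -1))
})

test_that("planted truth round-trips at zero divergence on a small clade", {
  d <- withr::local_tempdir()
  w <- generate_world(small_config(7, divergence = 0), d)
  man <- read_species_manifest(file.path(d, "manifest.tsv"))
  prot <- read_fasta(file.path(d, "focal", "proteins.faa"))
  cds <- read_fasta(file.path(d, "focal", "cds.fna"))
  genes <- read_gff3(file.path(d, "focal", "genes.gff3"),
                     proteins = prot, cds = cds)
  expect_equal(length(genes), nrow(w$truth$genes))
  pa <- build_presence_absence(genes, man)
  rep <- classify_all(pa)
  truth <- setNames(w$truth$genes$class, w$truth$genes$gene_id)
  expect_equal(unname(rep$classes[names(truth)]), unname(truth))
  # per-class counts equal the plan
  expect_equal(unname(rep$counts[c("orphan", "metazoa")]), c(6L, 8L))
  # the genome-only homolog is recovered through the translated tier
  gonly <- w$truth$genes$gene_id[w$truth$genes$genome_only_species != ""]
  if (length(gonly) > 0)
    expect_true(all(pa$code[gonly, "ant1"] == "G"))
})

test_that("ESTs map back to their source genes", {
  d <- withr::local_tempdir()
  w <- generate_world(small_config(8, divergence = 0), d)
  prot <- read_fasta(file.path(d, "focal", "proteins.faa"))
  ests <- read_fasta(file.path(d, "ests.fna"))
  gene_of <- setNames(sub("\\.t\\d+$", "", names(prot)), names(prot))
  withr::local_seed(1)
  pick <- sample(names(ests), min(10, length(ests)))
  mapped <- vapply(pick, function(e)
    as.character(map_est_to_genes(ests[[e]], prot, gene_of = gene_of)),
    character(1))
  truth <- setNames(w$truth$ests$gene_id, w$truth$ests$est_id)
  ok <- !is.na(mapped)
  expect_gt(mean(ok), 0.6)  # some ESTs are legitimately ambiguous (paralogs)
  expect_equal(unname(mapped[ok]), unname(truth[pick][ok]))
})

test_that("expression planting validates its inputs", {
  classes <- c(g1 = "metazoa", g2 = "insect")
  plan <- list(weights = c(queen = 0.3, worker = 0.2, no_difference = 0.5),
               odds_ratio = 2)
  expect_error(plant_expression_bias(classes, plan), "orphan")
  plan$odds_ratio <- -1
  expect_error(plant_expression_bias(c(g1 = "orphan"), plan), "positive")
  # infeasible species plan is rejected up front
  expect_error(synthetic_config(seed = 1,
    species_plan = c(social_insect = 0, other_hymenoptera = 1,
                     other_insect = 2, other_metazoan = 1, outgroup = 1)),
    "social")
})

test_that("classification degrades gradually with divergence", {
  # same seed, increasing divergence: accuracy is monotone non-increasing
  accs <- vapply(c(0, 1.5, 6), function(dv) {
    d <- withr::local_tempdir()
    w <- generate_world(small_config(9, divergence = dv), d)
    man <- read_species_manifest(file.path(d, "manifest.tsv"))
    prot <- read_fasta(file.path(d, "focal", "proteins.faa"))
    genes <- read_gff3(file.path(d, "focal", "genes.gff3"), proteins = prot)
    rep <- classify_all(build_presence_absence(genes, man))
    truth <- setNames(w$truth$genes$class, w$truth$genes$gene_id)
    mean(rep$classes[names(truth)] == truth)
  }, numeric(1))
  expect_equal(accs[1], 1)
  expect_true(all(diff(accs) <= 0))
})
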