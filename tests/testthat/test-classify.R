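test_that("classification rules assign the documented classes", {
  m <- tiny_manifest()
  expect_equal(classify_gene(presence_row(character(0)), m), "orphan")
  # only the parasitoid wasp: restricted to Hymenoptera
  expect_equal(classify_gene(presence_row("wasp"), m), "hymenoptera")
  # all ants only: social insect
  expect_equal(classify_gene(presence_row(c("ant1", "ant2")), m),
               "social_insect")
  # all Hymenoptera, nothing else
  expect_equal(classify_gene(presence_row(c("ant1", "ant2", "wasp")), m),
               "hymenoptera_conserved")
  # all insects, no non-insect
  expect_equal(classify_gene(
    presence_row(c("ant1", "ant2", "wasp", "fly1", "fly2")), m), "insect")
  # all metazoans
  expect_equal(classify_gene(
    presence_row(c("ant1", "ant2", "wasp", "fly1", "fly2", "human")), m),
    "metazoa")
  # presence in yeast does not block the metazoan call
  expect_equal(classify_gene(
    presence_row(c("ant1", "ant2", "wasp", "fly1", "fly2", "human",
                   "yeast")), m), "metazoa")
  # one fly only: falls through every rule
  expect_equal(classify_gene(presence_row("fly1"), m), "other")
  # one ant + one fly: phylogenetically incoherent
  expect_equal(classify_gene(presence_row(c("ant1", "fly1")), m), "other")
})

test_that("classify_gene agrees with a brute-force rule oracle on all rows", {
  m <- tiny_manifest()
  sp <- m$id[!m$focal]
  hym <- c("ant1", "ant2", "wasp"); soc <- c("ant1", "ant2")
  ins <- c(hym, "fly1", "fly2"); met <- c(ins, "human")
  oracle <- function(present) {
    if (!any(present)) return("orphan")
    if (all(present[hym]) && !any(present[setdiff(sp, hym)]))
      return("hymenoptera_conserved")
    if (all(present[soc]) && !any(present[setdiff(sp, soc)]))
      return("social_insect")
    if (any(present[hym]) && !any(present[setdiff(sp, hym)]))
      return("hymenoptera")
    if (all(present[ins]) && !any(present[setdiff(sp, ins)]))
      return("insect")
    if (all(present[met])) return("metazoa")
    "other"
  }
  # all 2^7 presence vectors
  for (mask in 0:(2^7 - 1)) {
    present <- setNames(bitwAnd(mask, 2^(0:6)) > 0, sp)
    row <- setNames(ifelse(present, "P", "A"), sp)
    expect_equal(classify_gene(row, m), oracle(present), info = mask)
  }
})

test_that("precomputed hit tables drive the two-tier presence matrix", {
  m <- tiny_manifest()
  genes <- gene_set(fake_gene("g1", "MAAA"), fake_gene("g2", "MCCC"))
  hits <- function(q, e) data.frame(
    qseqid = q, sseqid = "s", pident = 100, length = 4L, mismatch = 0L,
    gapopen = 0L, qstart = 1L, qend = 4L, sstart = 1L, send = 4L,
    evalue = e, bitscore = 20, stringsAsFactors = FALSE)
  search <- list(
    ant1 = hits("g1", 1e-10),                       # protein tier
    ant2 = list(protein = NULL, genome = hits("g1", 1e-6)),  # genome tier
    wasp = hits("g1", 1e-2))                        # above cutoff
  pa <- build_presence_absence(genes, m, search = search)
  expect_equal(pa$code["g1", "ant1"], "P")
  expect_equal(pa$code["g1", "ant2"], "G")
  expect_equal(pa$code["g1", "wasp"], "A")
  expect_equal(unname(pa$code["g2", ]), rep("A", 7))
  # species outside the manifest are rejected
  expect_error(build_presence_absence(genes, m, search = list(mars = hits("g1", 1e-9))),
               "absent from manifest")
})

test_that("classes partition the gene set and counts sum to its size", {
  m <- tiny_manifest()
  withr::local_seed(20)
  sp <- m$id[!m$focal]
  code <- matrix(sample(c("A", "P"), 50 * 7, TRUE, prob = c(0.6, 0.4)),
                 50, 7, dimnames = list(sprintf("g%02d", 1:50), sp))
  rep <- classify_all(fake_pa(code, m))
  expect_equal(sum(rep$counts), 50)
  expect_true(all(rep$classes %in% trgstrat:::HOMOLOGY_CLASSES))
  expect_equal(rep$n, 50)
  # empty gene set gives an empty report
  rep0 <- classify_all(fake_pa(code[0, , drop = FALSE], m))
  expect_equal(rep0$n, 0)
  expect_equal(sum(rep0$counts), 0)
})

test_that("tightening the E-value cutoff never shrinks the orphan set", {
  m <- tiny_manifest()
  withr::local_seed(21)
  sp <- m$id[!m$focal]
  ev <- matrix(10^runif(60 * 7, -12, 0), 60, 7,
               dimnames = list(sprintf("g%02d", 1:60), sp))
  pa <- structure(list(code = NULL, evalue_protein = ev,
                       evalue_genome = matrix(Inf, 60, 7, dimnames = dimnames(ev)),
                       cutoff = 1e-4, manifest = m),
                  class = "presence_absence")
  cutoffs <- c(1e-2, 1e-4, 1e-6, 1e-8, 1e-10)
  orphans <- lapply(cutoffs, function(ct) {
    rep <- classify_all(recode_presence(pa, ct))
    names(rep$classes)[rep$classes == "orphan"]
  })
  for (i in seq_len(length(cutoffs) - 1)) {
    expect_true(all(orphans[[i]] %in% orphans[[i + 1]]),
                info = paste("cutoff", cutoffs[i], "->", cutoffs[i + 1]))
  }
})

test_that("external recheck moves genes out of over-restricted classes", {
  m <- tiny_manifest()
  code <- rbind(g1 = presence_row(character(0)),          # orphan
                g2 = presence_row("wasp"),                # hymenoptera
                g3 = presence_row(c("ant1", "ant2")))     # social_insect
  pa <- fake_pa(code, m)
  rep <- classify_all(pa)
  taxa <- data.frame(
    taxon = c("bombus", "chicken"),
    clades = c("hymenoptera,insect,metazoan", "metazoan"),
    stringsAsFactors = FALSE)
  # orphan with a bumble-bee hit becomes hymenoptera
  upd <- apply_external_recheck(rep, pa,
    data.frame(gene_id = "g1", taxon = "bombus"), taxa)
  expect_equal(unname(upd$classes["g1"]), "hymenoptera")
  expect_equal(upd$recheck$old_class, "orphan")
  # hymenoptera-class gene with a chicken hit falls through to other
  upd2 <- apply_external_recheck(rep, pa,
    data.frame(gene_id = "g2", taxon = "chicken"), taxa)
  expect_equal(unname(upd2$classes["g2"]), "other")
  # genes without extra hits are untouched
  expect_equal(unname(upd$classes["g3"]), "social_insect")
  # unmapped taxa are an error
  expect_error(apply_external_recheck(rep, pa,
    data.frame(gene_id = "g1", taxon = "martian"), taxa), "clade mapping")
})

test_that("recheck never moves a gene to a more restricted class", {
  m <- tiny_manifest()
  withr::local_seed(22)
  sp <- m$id[!m$focal]
  taxa <- data.frame(
    taxon = c("bombus", "polistes", "daphnia", "hydra", "chicken"),
    clades = c("hymenoptera,insect,metazoan", "hymenoptera,insect,metazoan",
               "metazoan", "metazoan", "metazoan"),
    stringsAsFactors = FALSE)
  for (i in 1:200) {
    code <- matrix(sample(c("A", "P"), 7, TRUE), 1, 7,
                   dimnames = list("g1", sp))
    pa <- fake_pa(code, m)
    rep <- classify_all(pa)
    hits <- data.frame(gene_id = "g1",
                       taxon = sample(taxa$taxon, sample(1:3, 1)))
    upd <- apply_external_recheck(rep, pa, hits, taxa)
    expect_gte(trgstrat:::restriction_rank(upd$classes[["g1"]]),
               trgstrat:::restriction_rank(rep$classes[["g1"]]))
  }
})
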