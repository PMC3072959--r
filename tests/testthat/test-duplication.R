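test_that("paralog search finds planted duplicates and excludes self", {
  withr::local_seed(40)
  p <- random_aa(80)
  universe <- gene_set(
    fake_gene("trg", p),
    fake_gene("dup", p),                       # verbatim duplicate
    fake_gene("far", random_aa(80)))           # unrelated
  par <- find_paralogs(universe[["trg"]], universe)
  expect_equal(as.character(par), "dup")
  # no similar gene: empty
  par2 <- find_paralogs(universe[["far"]], universe)
  expect_length(par2, 0)
})

test_that("isoforms of the same gene are excluded by identity, not score", {
  withr::local_seed(41)
  p <- random_aa(70)
  universe <- gene_set(fake_gene("trg", c(p, substring(p, 1, 50))),
                       fake_gene("other", random_aa(70)))
  expect_length(find_paralogs(universe[["trg"]], universe), 0)
})

test_that("the class-specific escape rules flag conserved paralogs", {
  m <- tiny_manifest()
  code <- rbind(
    trg_o   = presence_row(character(0)),                  # orphan TRG
    par_any = presence_row("fly1"),                        # present somewhere
    par_orp = presence_row(character(0)),                  # itself an orphan
    trg_i   = presence_row(c("ant1","ant2","wasp","fly1","fly2")),  # insect
    par_tick = presence_row(c("ant1","ant2","wasp","fly1","fly2","human")),
    par_hym = presence_row("wasp"))
  pa <- fake_pa(code, m)
  # orphan whose paralog is present in any other species: flagged
  r <- flag_conserved_paralogs("trg_o", "orphan", c("par_any"), pa)
  expect_true(r$conserved_paralog)
  expect_equal(r$evidence$species, "fly1")
  # orphan whose paralogs are all orphans: not flagged
  r2 <- flag_conserved_paralogs("trg_o", "orphan", c("par_orp"), pa)
  expect_false(r2$conserved_paralog)
  # insect-specific gene whose paralog reaches a non-insect: flagged
  r3 <- flag_conserved_paralogs("trg_i", "insect", c("par_tick"), pa)
  expect_true(r3$conserved_paralog)
  expect_true("human" %in% r3$evidence$species)
  # insect-specific gene whose paralog stays within insects: not flagged
  r4 <- flag_conserved_paralogs("trg_i", "insect", c("par_hym"), pa)
  expect_false(r4$conserved_paralog)
  # hymenoptera-restricted TRG needs evidence outside the Hymenoptera
  r5 <- flag_conserved_paralogs("trg_h", "hymenoptera", c("par_hym"), pa)
  expect_false(r5$conserved_paralog)
  r6 <- flag_conserved_paralogs("trg_h", "hymenoptera", c("par_any"), pa)
  expect_true(r6$conserved_paralog)
  # paralogs missing from presence data are an error
  expect_error(flag_conserved_paralogs("trg_o", "orphan", "ghost", pa),
               "missing from presence")
  # only restricted classes have a duplication-origin rule
  expect_error(flag_conserved_paralogs("x", "metazoa", character(0), pa),
               "restricted")
})

test_that("flagged fractions aggregate per class and tolerate extra genes", {
  m <- tiny_manifest()
  code <- rbind(a = presence_row(character(0)),
                b = presence_row(character(0)),
                p = presence_row("fly1"))
  pa <- fake_pa(code, m)
  recs <- list(
    flag_conserved_paralogs("a", "orphan", "p", pa),
    flag_conserved_paralogs("b", "orphan", character(0), pa))
  rates <- duplication_rate_by_class(recs)
  expect_equal(rates$fraction[rates$class == "orphan"], 0.5)
  # adding a paralog-free TRG of another class does not disturb the orphan rate
  recs2 <- c(recs, list(flag_conserved_paralogs("c", "insect",
                                                character(0), pa)))
  rates2 <- duplication_rate_by_class(recs2)
  expect_equal(rates2$fraction[rates2$class == "orphan"], 0.5)
  expect_equal(rates2$fraction[rates2$class == "insect"], 0)
})

test_that("near-cutoff paralogs match a direct E-value evaluation", {
  withr::local_seed(42)
  p <- random_aa(60)
  diverged <- trgstrat:::mutate_protein(p, 0.8)
  universe <- gene_set(fake_gene("trg", p), fake_gene("cand", diverged))
  params <- alignment_params()
  n_db <- sum(nchar(p)) + nchar(diverged)
  sc <- smith_waterman(p, diverged, params)$score
  direct <- evalue(sc, nchar(p), n_db, params)
  par <- find_paralogs(universe[["trg"]], universe, params)
  expect_equal("cand" %in% as.character(par), direct < params$evalue_cutoff)
})
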