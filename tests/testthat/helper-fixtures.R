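# Shared fixtures, all built in code.

# A small comparison panel: 2 ants (social), 1 wasp, 2 flies, 1 human-like
# metazoan, 1 yeast-like outgroup. Proteome paths are placeholders; tests
# that run the engine write real files instead.
tiny_manifest <- function() {
  species_manifest(data.frame(
    id = c("bee", "ant1", "ant2", "wasp", "fly1", "fly2", "human", "yeast"),
    proteome = c(NA, "x", "x", "x", "x", "x", "x", "x"),
    genome = NA_character_,
    clades = c("social_insect,hymenoptera,insect,metazoan",
               "social_insect,hymenoptera,insect,metazoan",
               "social_insect,hymenoptera,insect,metazoan",
               "hymenoptera,insect,metazoan",
               "insect,metazoan", "insect,metazoan",
               "metazoan", "outgroup_non_metazoan"),
    focal = c(TRUE, rep(FALSE, 7)),
    stringsAsFactors = FALSE))
}

# Presence row over the tiny manifest from the ids that are present.
presence_row <- function(present, manifest = tiny_manifest()) {
  sp <- manifest$id[!manifest$focal]
  setNames(ifelse(sp %in% present, "P", "A"), sp)
}

random_aa <- function(n, alphabet = c("A", "R", "N", "D", "C", "Q", "E",
                                      "G", "H", "I", "L", "K", "M", "F",
                                      "P", "S", "T", "W", "Y", "V")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Reverse-complement for strand tests.
revcomp <- function(nt) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(nt)))
}

# Minimal gene record as produced by read_gff3().
fake_gene <- function(id, proteins, cds = NA_character_, exons = 1L,
                      size = 1000L) {
  list(gene_id = id, seqid = "scf", start = 1L, end = size, strand = "+",
       gene_size = size, exon_number = exons,
       exons = matrix(numeric(0), ncol = 2), transcripts = character(0),
       proteins = setNames(proteins, paste0(id, ".t", seq_along(proteins))),
       cds = cds, official = TRUE)
}

gene_set <- function(...) {
  genes <- list(...)
  names(genes) <- vapply(genes, `[[`, character(1), "gene_id")
  structure(genes, class = "gene_model_set")
}

# A presence_absence object built directly from a code matrix.
fake_pa <- function(code, manifest = tiny_manifest(), cutoff = 1e-4) {
  ev <- matrix(Inf, nrow(code), ncol(code), dimnames = dimnames(code))
  ev[code != "A"] <- cutoff / 100
  structure(list(code = code,
                 evalue_protein = ifelse(code == "P", ev, Inf) * 1,
                 evalue_genome = ifelse(code == "G", ev, Inf) * 1,
                 cutoff = cutoff, manifest = manifest),
            class = "presence_absence")
}
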