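# Seeded synthetic comparative-genomics generator. Emits a complete input
# universe -- species manifest, focal gene models (GFF3 + protein + CDS
# FASTA), comparison proteomes (and genomes for the social-insect species,
# so the translated tier is exercised), ESTs, and expression contrast lists
# -- together with full ground truth for every record.
#
# Homologs are planted per class pattern with controlled divergence.
# Duplication-born TRGs are modelled as diverged copies of a
# lineage-specific extension of a conserved parent gene: the parent's core
# is present in every species (keeping the parent conserved) while the
# extension exists only in the species of the TRG's class, so the planted
# class and the planted duplication history are simultaneously true.

AA20 <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F","P","S",
          "T","W","Y","V")

# Codon table for back-translation (uniform synonymous choice).
CODONS_BY_AA <- local({
  code <- Biostrings::GENETIC_CODE
  split(names(code), unname(code))
})

random_protein <- function(len) {
  paste0("M", paste(sample(AA20, len - 1, replace = TRUE), collapse = ""))
}

back_translate <- function(prot) {
  aa <- strsplit(prot, "")[[1]]
  paste(vapply(aa, function(a) {
    cods <- CODONS_BY_AA[[a]]
    cods[sample.int(length(cods), 1)]
  }, character(1)), collapse = "")
}

random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

#' Mutate a protein by an expected substitution distance
#'
#' Draws `Poisson(length * distance)` substitution events at uniform
#' positions (with replacement, so per-site hits are Poisson(distance) and
#' the expected fraction of sites touched is `1 - exp(-distance)`). Each
#' event replaces the current residue by a different residue drawn with
#' probability proportional to `exp(BLOSUM62[current, r] / 2)`, so
#' divergence degrades alignment score gradually rather than stepwise.
#'
#' @param seq Amino-acid string.
#' @param distance Expected substitutions per site (>= 0).
#' @return Mutated amino-acid string of the same length.
#' @export
mutate_protein <- function(seq, distance) {
  stopifnot(distance >= 0)
  if (distance == 0) return(seq)
  aa <- strsplit(seq, "")[[1]]
  L <- length(aa)
  k <- rpois(1, L * distance)
  if (k == 0) return(seq)
  pos <- sample.int(L, k, replace = TRUE)
  mat <- blosum62()[AA20, AA20]
  for (p in pos) {
    cur <- aa[p]
    if (!cur %in% AA20) cur <- sample(AA20, 1)
    w <- exp(mat[cur, ] / 2)
    w[cur] <- 0
    aa[p] <- sample(AA20, 1, prob = w)
  }
  paste(aa, collapse = "")
}

#' Synthetic world configuration
#'
#' Defaults describe a scaled-down version of the study conditions: a focal
#' social bee compared against three social insects (ants), one solitary
#' wasp, four non-hymenopteran insects, two non-insect metazoans and a
#' non-metazoan outgroup; ~210 focal genes spread over all seven homology
#' classes; low per-branch divergence; class-specific protein lengths and
#' transcript-support probabilities following the qualitative pattern that
#' restricted genes are shorter and less supported; a caste contrast whose
#' group weights mirror the queen/worker/no-difference proportions of the
#' brain microarray data, with a configurable orphan odds ratio towards the
#' worker-like group.
#'
#' @param seed Integer seed (mandatory; full determinism under it).
#' @param species_plan Named integer vector: counts for `social_insect`,
#'   `other_hymenoptera`, `other_insect`, `other_metazoan`, `outgroup`.
#' @param genes_per_class Named integer vector over the seven classes.
#' @param divergence Expected substitutions per site per branch; planted
#'   orthologs sit at twice this distance from the focal copy.
#' @param duplication_fraction Named numeric: fraction of each restricted
#'   class born by duplication of a conserved parent.
#' @param dup_extra_divergence Additional divergence between a
#'   duplication-born gene and its parent's extension.
#' @param est_support_prob Named numeric: per-class probability that a gene
#'   has ESTs.
#' @param expression_plan List: `weights` (named queen/worker/no_difference
#'   group weights), `odds_ratio` (orphan odds towards the worker group).
#' @param protein_length_mean Named numeric: class-specific mean protein
#'   length (aa).
#' @param extension_length Length (aa) of the parent-specific extension
#'   used for duplication-born genes.
#' @param background_proteins Unrelated random proteins added per
#'   comparison proteome.
#' @param isoform_fraction Fraction of focal genes given a second
#'   (truncated) isoform.
#' @param genome_only_genes Number of social-insect-class genes whose
#'   homolog in one ant species is present only in its genome (exercising
#'   the translated tier).
#' @return Object of class `synthetic_config`.
#' @export
synthetic_config <- function(
    seed,
    species_plan = c(social_insect = 3, other_hymenoptera = 1,
                     other_insect = 4, other_metazoan = 2, outgroup = 1),
    genes_per_class = c(orphan = 40, hymenoptera = 25, social_insect = 25,
                        hymenoptera_conserved = 25, insect = 30,
                        metazoa = 45, other = 20),
    divergence = 0.15,
    duplication_fraction = c(orphan = 0.10, hymenoptera = 0.10,
                             social_insect = 0.10,
                             hymenoptera_conserved = 0.10, insect = 0.40),
    dup_extra_divergence = 0.25,
    est_support_prob = c(orphan = 0.45, hymenoptera = 0.51,
                         social_insect = 0.48, hymenoptera_conserved = 0.54,
                         insect = 0.81, metazoa = 0.92, other = 0.80),
    expression_plan = list(weights = c(queen = 0.215, worker = 0.175,
                                       no_difference = 0.610),
                           odds_ratio = 2.5),
    protein_length_mean = c(orphan = 90, hymenoptera = 110,
                            social_insect = 130,
                            hymenoptera_conserved = 140, insect = 150,
                            metazoa = 180, other = 140),
    extension_length = 60L,
    background_proteins = 25L,
    isoform_fraction = 0.1,
    genome_only_genes = 2L) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(all(genes_per_class >= 0), divergence >= 0,
            all(duplication_fraction >= 0 & duplication_fraction <= 1),
            all(est_support_prob >= 0 & est_support_prob <= 1),
            expression_plan$odds_ratio > 0)
  if (genes_per_class["social_insect"] > 0 && species_plan["social_insect"] == 0)
    stop("social_insect genes requested but no social-insect species planned")
  if (genes_per_class["hymenoptera"] > 0 &&
      species_plan["social_insect"] + species_plan["other_hymenoptera"] < 2)
    stop("hymenoptera class needs at least two Hymenopteran species")
  structure(list(seed = as.integer(seed), species_plan = species_plan,
                 genes_per_class = genes_per_class, divergence = divergence,
                 duplication_fraction = duplication_fraction,
                 dup_extra_divergence = dup_extra_divergence,
                 est_support_prob = est_support_prob,
                 expression_plan = expression_plan,
                 protein_length_mean = protein_length_mean,
                 extension_length = as.integer(extension_length),
                 background_proteins = as.integer(background_proteins),
                 isoform_fraction = isoform_fraction,
                 genome_only_genes = as.integer(genome_only_genes)),
            class = "synthetic_config")
}

# Species table implied by a plan. The focal species is a social insect
# (a honey-bee-like bee); ants are the non-focal social insects and carry
# genomes so the translated tier is exercised.
plan_species <- function(plan) {
  ids <- c("focal_bee",
           if (plan["social_insect"] > 0)
             paste0("ant", seq_len(plan["social_insect"])),
           if (plan["other_hymenoptera"] > 0)
             paste0("wasp", seq_len(plan["other_hymenoptera"])),
           if (plan["other_insect"] > 0)
             paste0("insectsp", seq_len(plan["other_insect"])),
           if (plan["other_metazoan"] > 0)
             paste0("metazoan", seq_len(plan["other_metazoan"])),
           if (plan["outgroup"] > 0)
             paste0("outgroup", seq_len(plan["outgroup"])))
  clades <- c("social_insect,hymenoptera,insect,metazoan",
              rep("social_insect,hymenoptera,insect,metazoan",
                  plan["social_insect"]),
              rep("hymenoptera,insect,metazoan", plan["other_hymenoptera"]),
              rep("insect,metazoan", plan["other_insect"]),
              rep("metazoan", plan["other_metazoan"]),
              rep("outgroup_non_metazoan", plan["outgroup"]))
  data.frame(id = ids, clades = clades,
             focal = c(TRUE, rep(FALSE, length(ids) - 1)),
             stringsAsFactors = FALSE)
}

# Species ids (non-focal) in which a gene of a given class is planted.
planted_pattern <- function(class, sp) {
  soc <- sp$id[grepl("social_insect", sp$clades) & !sp$focal]
  hym <- sp$id[grepl("hymenoptera", sp$clades) & !sp$focal]
  ins <- sp$id[grepl("insect,metazoan", sp$clades) & !sp$focal]  # all insects
  met <- sp$id[grepl("metazoan", sp$clades) & !sp$focal]
  non_hym_ins <- setdiff(ins, hym)
  switch(class,
    orphan = character(0),
    social_insect = soc,
    hymenoptera_conserved = hym,
    hymenoptera = {
      wasps <- setdiff(hym, soc)
      if (length(wasps) > 0) wasps[1] else soc[1]
    },
    insect = ins,
    metazoa = c(met, if (runif(1) < 0.5) sp$id[grepl("outgroup", sp$clades)]),
    other = {
      # a proper, nonempty subset of the non-hymenopteran insects: a
      # phylogenetically incoherent pattern
      k <- sample(seq_len(max(1, length(non_hym_ins) - 1)), 1)
      sample(non_hym_ins, k)
    })
}

#' Generate a synthetic comparative-genomics world
#'
#' Writes a self-contained fixture directory and returns the ground truth.
#' Identical seeds give byte-identical output.
#'
#' @param config A [synthetic_config()].
#' @param dir Output directory (created; must not pre-exist unless empty).
#' @return List of class `synthetic_world`: `dir`, `paths` (named list of
#'   every emitted file), and `truth` with `genes` (gene_id, class,
#'   dup_born, parent_id, expr_group, est_support), `presence` (logical
#'   matrix gene x comparison species of planted homologs), `ests`
#'   (est_id -> gene_id), and `expression` (per-EST group and p-value).
#' @export
generate_world <- function(config, dir) {
  stopifnot(inherits(config, "synthetic_config"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  with_seed(config$seed, generate_world_impl(config, dir))
}

generate_world_impl <- function(cfg, dir) {
  sp <- plan_species(cfg$species_plan)
  comparison <- sp$id[!sp$focal]
  classes <- rep(names(cfg$genes_per_class), cfg$genes_per_class)
  n_genes <- length(classes)
  gene_ids <- sprintf("g%04d", seq_len(n_genes))
  names(classes) <- gene_ids

  # -- focal sequences ------------------------------------------------------
  lens <- pmax(50L, round(rnorm(n_genes, cfg$protein_length_mean[classes],
                                cfg$protein_length_mean[classes] * 0.25)))
  focal_seq <- setNames(vapply(lens, random_protein, character(1)), gene_ids)

  # -- duplication-born genes ----------------------------------------------
  dup_born <- setNames(rep(FALSE, n_genes), gene_ids)
  parent_id <- setNames(rep(NA_character_, n_genes), gene_ids)
  parent_ext <- list()      # parent_id -> extension sequence (focal copy)
  met_ids <- gene_ids[classes == "metazoa" ]
  avail_parents <- met_ids
  for (cl in names(cfg$duplication_fraction)) {
    cand <- gene_ids[classes == cl]
    n_dup <- round(cfg$duplication_fraction[[cl]] * length(cand))
    if (n_dup == 0 || length(avail_parents) == 0) next
    chosen <- cand[seq_len(min(n_dup, length(avail_parents)))]
    for (g in chosen) {
      par <- avail_parents[1]; avail_parents <- avail_parents[-1]
      ext <- random_protein(cfg$extension_length)
      parent_ext[[par]] <- ext
      focal_seq[par] <- paste0(focal_seq[par], substring(ext, 2))
      # the TRG is a diverged copy of the parent's extension
      focal_seq[g] <- mutate_protein(ext, cfg$dup_extra_divergence)
      dup_born[g] <- TRUE
      parent_id[g] <- par
    }
  }

  # -- planted presence patterns -------------------------------------------
  presence <- matrix(FALSE, n_genes, length(comparison),
                     dimnames = list(gene_ids, comparison))
  pattern <- setNames(vector("list", n_genes), gene_ids)
  for (g in gene_ids) {
    pat <- planted_pattern(classes[[g]], sp)
    pattern[[g]] <- pat
    presence[g, pat] <- TRUE
  }
  # self-check: the planted pattern must imply the intended class
  chk_manifest <- species_manifest(
    data.frame(id = sp$id, proteome = ifelse(sp$focal, NA, "x"), genome = NA,
               clades = sp$clades, focal = sp$focal, stringsAsFactors = FALSE))
  for (g in gene_ids) {
    implied <- classify_gene(setNames(ifelse(presence[g, ], "P", "A"),
                                      comparison), chk_manifest)
    if (implied != classes[[g]])
      stop("infeasible plan: pattern for class ", classes[[g]],
           " implies ", implied)
  }

  # -- ortholog sequences per species --------------------------------------
  # For a duplication-born gene the "ortholog" material lives on the
  # parent's orthologs as an extension; ordinary genes get their own
  # diverged copies.
  d2 <- 2 * cfg$divergence
  proteomes <- setNames(vector("list", length(comparison)), comparison)
  for (s in comparison) proteomes[[s]] <- character(0)
  ext_carried <- list()  # parent -> species where its extension is planted
  for (g in gene_ids) {
    pat <- pattern[[g]]
    if (length(pat) == 0) next
    if (dup_born[[g]]) {
      par <- parent_id[[g]]
      ext_carried[[par]] <- union(ext_carried[[par]] %||% character(0), pat)
      next
    }
    for (s in pat) {
      proteomes[[s]][paste0(s, "_", g)] <- mutate_protein(focal_seq[[g]], d2)
    }
  }
  # parent orthologs: core everywhere (their own metazoa pattern), core +
  # extension where a dup-born child's class requires presence
  for (par in names(parent_ext)) {
    core_len <- nchar(focal_seq[[par]]) - (cfg$extension_length - 1L)
    core <- substring(focal_seq[[par]], 1, core_len)
    for (s in pattern[[par]]) {
      ortho <- mutate_protein(core, d2)
      if (s %in% (ext_carried[[par]] %||% character(0)))
        ortho <- paste0(ortho, substring(mutate_protein(parent_ext[[par]], d2), 2))
      proteomes[[s]][paste0(s, "_", par)] <- ortho
    }
    # a child's pattern may include species outside the parent's own
    # pattern; plant extension-only carriers there
    extra <- setdiff(ext_carried[[par]] %||% character(0), pattern[[par]])
    for (s in extra)
      proteomes[[s]][paste0(s, "_", par, "_ext")] <-
        mutate_protein(parent_ext[[par]], d2)
    # dup-born children inherit presence via the extension
    for (g in gene_ids[dup_born & !is.na(parent_id) & parent_id == par])
      presence[g, ] <- comparison %in% (ext_carried[[par]] %||% character(0))
  }

  # -- genome-only homologs (translated tier) ------------------------------
  ants <- sp$id[grepl("^ant", sp$id)]
  genome_only <- character(0)
  if (cfg$genome_only_genes > 0 && length(ants) > 0) {
    soc_genes <- gene_ids[classes == "social_insect" & !dup_born]
    genome_only <- head(soc_genes, cfg$genome_only_genes)
  }
  genomes <- setNames(vector("list", length(ants)), ants)
  for (a in ants) genomes[[a]] <- character(0)
  for (g in genome_only) {
    a <- ants[1]
    # drop the protein copy; the homolog survives only in the genome
    seqs <- mutate_protein(focal_seq[[g]], d2)
    proteomes[[a]] <- proteomes[[a]][names(proteomes[[a]]) != paste0(a, "_", g)]
    genomes[[a]][paste0(a, "_scf_", g)] <-
      paste0(random_dna(120), back_translate(seqs), random_dna(120))
  }
  for (a in ants) {
    genomes[[a]][paste0(a, "_scf_bg1")] <- random_dna(2000)
    genomes[[a]][paste0(a, "_scf_bg2")] <- random_dna(2000)
  }

  # -- background proteins --------------------------------------------------
  for (s in comparison) {
    bg <- vapply(pmax(60L, round(rnorm(cfg$background_proteins, 140, 35))),
                 random_protein, character(1))
    names(bg) <- sprintf("%s_bg%03d", s, seq_along(bg))
    proteomes[[s]] <- c(proteomes[[s]], bg)
  }

  # -- focal gene models ----------------------------------------------------
  two_iso <- runif(n_genes) < cfg$isoform_fraction
  cds <- setNames(vapply(focal_seq, back_translate, character(1)), gene_ids)
  gff <- character(0)
  prot_fa <- character(0)
  pos <- 1L
  scf <- "scf1"
  for (i in seq_along(gene_ids)) {
    g <- gene_ids[i]
    cds_len <- nchar(cds[[g]])
    n_ex <- sample(1:6, 1)
    cuts <- sort(sample(seq_len(cds_len - 1), n_ex - 1))
    ex_lens <- diff(c(0, cuts, cds_len))
    introns <- if (n_ex > 1) sample(50:200, n_ex - 1, replace = TRUE) else integer(0)
    starts <- integer(n_ex); ends <- integer(n_ex)
    cur <- pos
    for (e in seq_len(n_ex)) {
      starts[e] <- cur
      ends[e] <- cur + ex_lens[e] - 1L
      cur <- ends[e] + (if (e < n_ex) introns[e] else 0L) + 1L
    }
    gstart <- starts[1]; gend <- ends[n_ex]
    gff <- c(gff, sprintf("%s\tsynth\tgene\t%d\t%d\t.\t+\t.\tID=%s",
                          scf, gstart, gend, g))
    tx1 <- paste0(g, ".t1")
    gff <- c(gff, sprintf("%s\tsynth\tmRNA\t%d\t%d\t.\t+\t.\tID=%s;Parent=%s",
                          scf, gstart, gend, tx1, g))
    for (e in seq_len(n_ex))
      gff <- c(gff, sprintf("%s\tsynth\texon\t%d\t%d\t.\t+\t.\tParent=%s",
                            scf, starts[e], ends[e], tx1))
    prot_fa[tx1] <- focal_seq[[g]]
    if (two_iso[i] && nchar(focal_seq[[g]]) > 60) {
      tx2 <- paste0(g, ".t2")
      gff <- c(gff, sprintf("%s\tsynth\tmRNA\t%d\t%d\t.\t+\t.\tID=%s;Parent=%s",
                            scf, gstart, ends[max(1, n_ex - 1)], tx2, g))
      for (e in seq_len(max(1, n_ex - 1)))
        gff <- c(gff, sprintf("%s\tsynth\texon\t%d\t%d\t.\t+\t.\tParent=%s",
                              scf, starts[e], ends[e], tx2))
      prot_fa[tx2] <- substring(focal_seq[[g]], 1,
                                round(nchar(focal_seq[[g]]) * 0.7))
    }
    pos <- gend + sample(200:500, 1)
  }

  # -- ESTs and expression --------------------------------------------------
  supported <- runif(n_genes) < cfg$est_support_prob[classes]
  names(supported) <- gene_ids
  est_seq <- character(0)
  est_gene <- character(0)
  for (g in gene_ids[supported]) {
    n_est <- sample(1:2, 1)
    for (k in seq_len(n_est)) {
      cds_len <- nchar(cds[[g]])
      take <- min(300L, cds_len - (cds_len %% 3))
      max_start <- (cds_len - take) %/% 3
      off <- if (max_start > 0) 3L * sample.int(max_start, 1) else 0L
      id <- sprintf("E%05d", length(est_seq) + 1L)
      est_seq[id] <- substring(cds[[g]], off + 1, off + take)
      est_gene[id] <- g
    }
  }

  bias <- plant_expression_bias(classes[gene_ids[supported]],
                                cfg$expression_plan)
  expr_group <- setNames(rep(NA_character_, n_genes), gene_ids)
  expr_group[names(bias$groups)] <- bias$groups
  est_group <- expr_group[est_gene]
  est_p <- ifelse(is.na(est_group), NA_real_,
                  ifelse(est_group == "no_difference",
                         runif(length(est_group), 0.05, 1),
                         10^runif(length(est_group), -5, log10(0.049))))
  names(est_p) <- names(est_gene)

  # -- write everything -----------------------------------------------------
  p <- list()
  dir.create(file.path(dir, "species"), showWarnings = FALSE)
  dir.create(file.path(dir, "focal"), showWarnings = FALSE)
  dir.create(file.path(dir, "expr"), showWarnings = FALSE)
  dir.create(file.path(dir, "truth"), showWarnings = FALSE)

  p$gff <- file.path(dir, "focal", "genes.gff3")
  writeLines(c("##gff-version 3", gff), p$gff)
  p$proteins <- file.path(dir, "focal", "proteins.faa")
  write_fasta(prot_fa, p$proteins)
  p$cds <- file.path(dir, "focal", "cds.fna")
  write_fasta(cds, p$cds)
  p$ests <- file.path(dir, "ests.fna")
  write_fasta(est_seq, p$ests)

  man <- data.frame(
    id = sp$id,
    proteome = ifelse(sp$focal, "focal/proteins.faa",
                      file.path("species", paste0(sp$id, ".faa"))),
    genome = ifelse(sp$id %in% names(genomes),
                    file.path("species", paste0(sp$id, ".fna")), ""),
    clades = sp$clades, focal = sp$focal, stringsAsFactors = FALSE)
  p$manifest <- file.path(dir, "manifest.tsv")
  write.table(man, p$manifest, sep = "\t", quote = FALSE, row.names = FALSE)
  for (s in comparison)
    write_fasta(proteomes[[s]], file.path(dir, "species", paste0(s, ".faa")))
  for (a in names(genomes))
    write_fasta(genomes[[a]], file.path(dir, "species", paste0(a, ".fna")))

  write_list <- function(ids, pv, path) {
    writeLines(if (length(ids)) paste(ids, signif(pv, 6), sep = "\t")
               else character(0), path)
    path
  }
  q_idx <- !is.na(est_group) & est_group == "queen"
  w_idx <- !is.na(est_group) & est_group == "worker"
  p$expr_queen <- write_list(names(est_seq)[q_idx], est_p[q_idx],
                             file.path(dir, "expr", "queen.txt"))
  p$expr_worker <- write_list(names(est_seq)[w_idx], est_p[w_idx],
                              file.path(dir, "expr", "worker.txt"))
  p$expr_full <- write_list(names(est_seq), est_p,
                            file.path(dir, "expr", "all.txt"))

  truth_genes <- data.frame(
    gene_id = gene_ids, class = unname(classes[gene_ids]),
    dup_born = unname(dup_born), parent_id = unname(parent_id),
    est_support = unname(supported), expr_group = unname(expr_group),
    genome_only_species = ifelse(gene_ids %in% genome_only, ants[1], ""),
    stringsAsFactors = FALSE)
  p$truth_genes <- file.path(dir, "truth", "genes.tsv")
  write.table(truth_genes, p$truth_genes, sep = "\t", quote = FALSE,
              row.names = FALSE)
  p$truth_presence <- file.path(dir, "truth", "presence.tsv")
  write.table(data.frame(gene_id = gene_ids, presence, check.names = FALSE),
              p$truth_presence, sep = "\t", quote = FALSE, row.names = FALSE)
  p$truth_ests <- file.path(dir, "truth", "ests.tsv")
  write.table(data.frame(est_id = names(est_gene), gene_id = unname(est_gene),
                         group = unname(est_group),
                         p_value = unname(signif(est_p, 6))),
              p$truth_ests, sep = "\t", quote = FALSE, row.names = FALSE)

  structure(list(
    dir = dir, paths = p,
    truth = list(genes = truth_genes, presence = presence,
                 ests = data.frame(est_id = names(est_gene),
                                   gene_id = unname(est_gene),
                                   group = unname(est_group),
                                   p_value = unname(est_p),
                                   stringsAsFactors = FALSE))),
    class = "synthetic_world")
}

#' Plant a caste expression bias with a configured odds ratio
#'
#' Assigns each gene independently to one of the contrast groups with
#' probabilities proportional to the group weights, multiplying the
#' worker-like group's weight by `odds_ratio` for orphans. Under this
#' scheme the odds of an orphan landing in the worker group versus
#' elsewhere, relative to a non-orphan, equal the configured odds ratio
#' exactly in expectation.
#'
#' @param classes Named character vector gene_id -> class (must contain at
#'   least one orphan unless `odds_ratio` is 1).
#' @param plan List with `weights` (named numeric over the three groups,
#'   worker-like group named `worker`) and `odds_ratio` (> 0).
#' @return List with `groups` (named character vector gene -> group) and
#'   `odds_ratio` (the configured value).
#' @export
plant_expression_bias <- function(classes, plan) {
  w <- plan$weights
  or <- plan$odds_ratio
  if (or <= 0) stop("odds ratio must be positive")
  stopifnot(!is.null(names(w)), "worker" %in% names(w))
  if (or != 1 && !any(classes == "orphan"))
    stop("no orphan genes available to plant an enrichment effect")
  groups <- vapply(names(classes), function(g) {
    wg <- w
    if (classes[[g]] == "orphan") wg["worker"] <- wg["worker"] * or
    sample(names(w), 1, prob = wg)
  }, character(1))
  list(groups = groups, odds_ratio = or)
}
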