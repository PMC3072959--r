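# Two-tier presence/absence construction and the seven-way homology
# classification. Presence in a species means a protein-set hit below the
# E-value cutoff; genes with no protein hit are re-searched against the
# species' genome (translated), when one is available. Classification rules
# are applied most-specific-first so the logically overlapping definitions
# become a deterministic partition:
#   orphan > hymenoptera_conserved > social_insect > hymenoptera >
#   insect > metazoa > other.

#' Build the gene-by-species presence/absence matrix
#'
#' For every focal gene and every comparison species, records
#' `present_protein` ("P") when any isoform has a proteome hit with
#' E < cutoff, otherwise `present_genome` ("G") when the translated genome
#' yields a hit with E < cutoff (tier two, only run for genes absent at
#' tier one and only for species with a genome), otherwise `absent` ("A").
#' Best tier-one and tier-two E-values are retained so presence can be
#' recomputed at other cutoffs.
#'
#' @param focal_genes A `gene_model_set` (or named list of isoform vectors).
#' @param manifest A [species_manifest()].
#' @param search Either `NULL` (run the built-in engine on the manifest's
#'   FASTA files) or a named list of precomputed hit tables, one per
#'   comparison species id, each an outfmt-6 data.frame whose `qseqid`
#'   values are focal gene ids (or isoform ids resolvable via `gene_of`);
#'   optionally each species entry may be `list(protein =, genome =)` to
#'   separate the two tiers.
#' @param params [alignment_params()] for the built-in engine.
#' @param cutoff Homology E-value cutoff (default from `params`).
#' @param gene_of Optional named map from hit-table query ids to gene ids.
#' @return Object of class `presence_absence`: list with `code` (character
#'   matrix genes x species, values "A"/"P"/"G"), `evalue_protein`,
#'   `evalue_genome` (numeric matrices of best E-values, `Inf` when never
#'   searched or nothing aligned), `cutoff`, `manifest`.
#' @export
build_presence_absence <- function(focal_genes, manifest, search = NULL,
                                   params = alignment_params(),
                                   cutoff = params$evalue_cutoff,
                                   gene_of = NULL) {
  gene_ids <- names(focal_genes)
  sp <- comparison_ids(manifest)
  ev_p <- matrix(Inf, length(gene_ids), length(sp),
                 dimnames = list(gene_ids, sp))
  ev_g <- ev_p

  if (is.null(search)) {
    for (s in sp) {
      row <- manifest[manifest$id == s, ]
      proteome <- read_fasta(row$proteome)
      genome <- if (!is.na(row$genome) && nzchar(row$genome))
        read_fasta(row$genome) else NULL
      frames <- if (!is.null(genome))
        lapply(genome, translate_six_frames) else NULL
      n_genome <- if (!is.null(genome)) sum(nchar(genome)) else 0
      for (g in gene_ids) {
        hits <- search_proteome(focal_genes[[g]], proteome, params)
        if (nrow(hits) > 0) {
          ev_p[g, s] <- min(hits$evalue)
        } else if (!is.null(frames)) {
          best <- Inf
          for (p in query_isoforms(focal_genes[[g]])) {
            gh <- search_translated_frames(p, frames, n_genome, params)
            if (nrow(gh) > 0) best <- min(best, min(gh$evalue))
          }
          ev_g[g, s] <- best
        }
      }
    }
  } else {
    unknown <- setdiff(names(search), sp)
    if (length(unknown) > 0)
      stop("hit tables for species absent from manifest: ",
           paste(unknown, collapse = ", "))
    to_gene <- function(q) {
      if (is.null(gene_of)) q else unname(gene_of[q])
    }
    fill <- function(mat, hits) {
      if (is.null(hits) || nrow(hits) == 0) return(mat)
      g <- to_gene(hits$qseqid)
      bad <- is.na(g) | !(g %in% gene_ids)
      if (any(bad))
        stop("hit table query id(s) not resolvable to focal genes: ",
             paste(unique(hits$qseqid[bad])[1:min(3, sum(bad))], collapse = ", "))
      for (i in seq_len(nrow(hits)))
        mat[g[i], s] <- min(mat[g[i], s], hits$evalue[i])
      mat
    }
    for (s in names(search)) {
      entry <- search[[s]]
      if (is.data.frame(entry)) {
        ev_p <- fill(ev_p, entry)
      } else {
        ev_p <- fill(ev_p, entry$protein)
        ev_g <- fill(ev_g, entry$genome)
      }
    }
  }

  code <- presence_codes(ev_p, ev_g, cutoff)
  structure(list(code = code, evalue_protein = ev_p, evalue_genome = ev_g,
                 cutoff = cutoff, manifest = manifest),
            class = "presence_absence")
}

# Two-tier coding from stored E-values: protein tier wins; genome presence
# is only recorded where the protein tier is absent.
presence_codes <- function(ev_p, ev_g, cutoff) {
  code <- matrix("A", nrow(ev_p), ncol(ev_p), dimnames = dimnames(ev_p))
  code[ev_g < cutoff] <- "G"
  code[ev_p < cutoff] <- "P"
  code
}

#' Recompute presence/absence at a different E-value cutoff
#'
#' Recodes the matrix from the stored best E-values. Note the two-tier
#' asymmetry: genome-tier E-values exist only for gene/species pairs that
#' were absent at the original protein-tier cutoff, so re-coding at a
#' looser cutoff is exact for the protein tier and conservative for the
#' genome tier.
#'
#' @param pa A `presence_absence` object.
#' @param cutoff New E-value cutoff.
#' @return A `presence_absence` object at the new cutoff.
#' @export
recode_presence <- function(pa, cutoff) {
  pa$code <- presence_codes(pa$evalue_protein, pa$evalue_genome, cutoff)
  pa$cutoff <- cutoff
  pa
}

#' @export
print.presence_absence <- function(x, ...) {
  cat("presence_absence:", nrow(x$code), "genes x", ncol(x$code),
      "species at E <", format(x$cutoff), "\n")
  tab <- table(factor(x$code, levels = c("A", "P", "G")))
  cat(sprintf("  absent %d, present_protein %d, present_genome %d\n",
              tab["A"], tab["P"], tab["G"]))
  invisible(x)
}

#' Classify one presence/absence row
#'
#' Applies the seven-way decision sequence to a gene's presence vector over
#' the comparison species (most-specific rule first):
#' \enumerate{
#'   \item absent everywhere: `orphan`
#'   \item present in all Hymenoptera, absent outside: `hymenoptera_conserved`
#'   \item present in all (non-focal) social-insect species, absent in every
#'     non-social species: `social_insect`
#'   \item present in at least one Hymenopteran, absent outside the
#'     Hymenoptera: `hymenoptera`
#'   \item present in all insects, absent in all non-insects: `insect`
#'   \item present in all metazoans (non-metazoan outgroups ignored):
#'     `metazoa`
#'   \item otherwise: `other`
#' }
#' The focal species is trivially present in itself and does not take part.
#'
#' @param row Named character vector of codes ("A"/"P"/"G") or logical
#'   presence, covering every comparison species in the manifest.
#' @param manifest A [species_manifest()].
#' @return One of `r paste(HOMOLOGY_CLASSES, collapse = ", ")`.
#' @export
classify_gene <- function(row, manifest) {
  sp <- comparison_ids(manifest)
  if (!all(sp %in% names(row)))
    stop("presence row must cover all comparison species")
  present <- if (is.logical(row)) row[sp] else row[sp] != "A"

  hym <- species_with_tag(manifest, "hymenoptera")
  soc <- species_with_tag(manifest, "social_insect")
  ins <- species_with_tag(manifest, "insect")
  met <- species_with_tag(manifest, "metazoan")
  non_hym <- setdiff(sp, hym)
  non_soc <- setdiff(sp, soc)
  non_ins <- setdiff(sp, ins)

  all_in <- function(ids) length(ids) == 0 || all(present[ids])
  none_in <- function(ids) length(ids) == 0 || !any(present[ids])

  if (!any(present)) return("orphan")
  if (length(hym) > 0 && all_in(hym) && none_in(non_hym))
    return("hymenoptera_conserved")
  if (length(soc) > 0 && all_in(soc) && none_in(non_soc))
    return("social_insect")
  if (any(present[hym]) && none_in(non_hym)) return("hymenoptera")
  if (length(ins) > 0 && all_in(ins) && none_in(non_ins)) return("insect")
  if (length(met) > 0 && all_in(met)) return("metazoa")
  "other"
}

#' Classify every gene in a presence/absence matrix
#'
#' @param pa A `presence_absence` object from [build_presence_absence()].
#' @param manifest Defaults to the manifest stored in `pa`.
#' @return Object of class `classification_report`: list with `classes`
#'   (named character vector gene -> class), `counts` (named integer vector
#'   over the seven classes), `proportions`, `n`, and `recheck` (audit
#'   trail, initially empty).
#' @export
classify_all <- function(pa, manifest = pa$manifest) {
  gene_ids <- rownames(pa$code)
  classes <- vapply(gene_ids, function(g) classify_gene(pa$code[g, ], manifest),
                    character(1))
  new_classification_report(classes)
}

new_classification_report <- function(classes, recheck = NULL) {
  counts <- table(factor(classes, levels = HOMOLOGY_CLASSES))
  counts <- setNames(as.integer(counts), HOMOLOGY_CLASSES)
  structure(list(classes = classes, counts = counts,
                 proportions = if (length(classes) > 0)
                   counts / length(classes) else counts,
                 n = length(classes),
                 recheck = recheck %||% data.frame(
                   gene_id = character(0), old_class = character(0),
                   new_class = character(0), taxa = character(0),
                   stringsAsFactors = FALSE)),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat("classification_report over", x$n, "genes\n")
  print(x$counts)
  if (nrow(x$recheck) > 0)
    cat(nrow(x$recheck), "gene(s) moved by external recheck\n")
  invisible(x)
}

#' Re-check restricted genes against external hits
#'
#' Emulates the confirmation step in which candidate TRGs are searched
#' against a comprehensive external protein database: any extra hit in a
#' taxon outside a gene's class is folded into the presence vector (as a
#' pseudo-species carrying the taxon's clade tags) and the gene is
#' re-classified. Because extra hits only ever add presence, a gene can
#' only move to an equally or less restricted class. Every move is recorded
#' in the audit trail.
#'
#' @param report A `classification_report`.
#' @param pa The `presence_absence` matrix the report was built from.
#' @param extra_hits data.frame with columns `gene_id` and `taxon` (one row
#'   per external hit; genes without rows are untouched).
#' @param taxon_clades data.frame mapping `taxon` to comma-separated
#'   `clades` tags (same vocabulary as the manifest). Every taxon in
#'   `extra_hits` must be mapped.
#' @param manifest Defaults to the manifest stored in `pa`.
#' @return An updated `classification_report` with the audit trail in
#'   `$recheck`.
#' @export
apply_external_recheck <- function(report, pa, extra_hits, taxon_clades,
                                   manifest = pa$manifest) {
  if (nrow(extra_hits) == 0) return(report)
  stopifnot(all(c("gene_id", "taxon") %in% names(extra_hits)),
            all(c("taxon", "clades") %in% names(taxon_clades)))
  unmapped <- setdiff(unique(extra_hits$taxon), taxon_clades$taxon)
  if (length(unmapped) > 0)
    stop("extra-hit taxa without clade mapping: ",
         paste(unmapped, collapse = ", "))

  classes <- report$classes
  moves <- list()
  for (g in unique(extra_hits$gene_id)) {
    if (!g %in% names(classes)) stop("extra hits for unknown gene ", g)
    if (!classes[[g]] %in% TRG_CLASSES) next  # only TRGs were re-searched
    taxa <- unique(extra_hits$taxon[extra_hits$gene_id == g])
    aug <- manifest
    for (tx in taxa) {
      tags <- taxon_clades$clades[taxon_clades$taxon == tx][1]
      aug <- rbind(as.data.frame(aug)[, c("id", "proteome", "genome",
                                          "clades", "focal")],
                   data.frame(id = paste0(".extra.", tx), proteome = "x",
                              genome = NA, clades = tags, focal = FALSE,
                              stringsAsFactors = FALSE))
      aug <- species_manifest(aug)
    }
    row <- pa$code[g, ]
    row <- c(row, setNames(rep("P", length(taxa)), paste0(".extra.", taxa)))
    new_class <- classify_gene(row, aug)
    if (new_class != classes[[g]]) {
      moves[[length(moves) + 1]] <- data.frame(
        gene_id = g, old_class = classes[[g]], new_class = new_class,
        taxa = paste(taxa, collapse = ","), stringsAsFactors = FALSE)
      classes[[g]] <- new_class
    }
  }
  audit <- if (length(moves) > 0) do.call(rbind, moves) else
    report$recheck[0, , drop = FALSE]
  new_classification_report(classes,
                            recheck = rbind(report$recheck, audit))
}

# Restriction rank of a class (1 = most restricted). Used by tests of the
# recheck-monotonicity property.
restriction_rank <- function(class) match(class, HOMOLOGY_CLASSES)

#' Export a classification report as a data.frame
#' @param x A `classification_report`.
#' @param ... Unused.
#' @return data.frame with `gene_id` and `class`.
#' @export
as.data.frame.classification_report <- function(x, ...) {
  data.frame(gene_id = names(x$classes), class = unname(x$classes),
             row.names = NULL, stringsAsFactors = FALSE)
}
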