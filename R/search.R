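# Homology searches built on the local aligner: protein-vs-proteome
# (blastp-like), protein-vs-translated-genome (tblastn-like), EST transcript
# support, and EST-to-gene mapping (blastx-like). Database-level E-values
# use m = query residues and n = total database residues (nucleotides for
# nucleotide databases), the BLAST search-space convention.

query_isoforms <- function(gene) {
  if (is.list(gene) && !is.null(gene$proteins)) {
    prots <- gene$proteins
    if (length(prots) == 0) stop("gene ", gene$gene_id, " has no protein")
    prots
  } else {
    prots <- as.character(gene)
    if (is.null(names(prots))) names(prots) <- paste0("iso", seq_along(prots))
    prots
  }
}

#' Search a gene's isoforms against a species proteome
#'
#' Aligns every isoform of the query gene against every protein of the
#' comparison proteome and reports subjects whose best E-value (over
#' isoforms) is below the cutoff. An empty result means no detectable
#' homolog in that proteome. E-values use n = total proteome residues.
#'
#' @param query_gene A gene record from [read_gff3()] (all isoforms are
#'   searched) or a character vector of isoform proteins.
#' @param proteome Named character vector of subject proteins.
#' @param params [alignment_params()].
#' @return outfmt-6 style data.frame of passing hits (best isoform per
#'   subject), sorted by E-value.
#' @export
search_proteome <- function(query_gene, proteome, params = alignment_params()) {
  if (length(proteome) == 0) stop("proteome must be non-empty")
  prots <- query_isoforms(query_gene)
  gid <- if (is.list(query_gene) && !is.null(query_gene$gene_id))
    query_gene$gene_id else names(prots)[1]
  n_db <- sum(nchar(proteome))
  al <- params_alphabet(params)
  best_score <- rep(-1L, length(proteome))
  best_iso <- rep(NA_integer_, length(proteome))
  for (k in seq_along(prots)) {
    sc <- if (params$ungapped) {
      vapply(proteome, function(s)
        .cpp_ungapped_best(prots[[k]], s, params$substitution_matrix, al,
                           params$word_size %||% 0L)$score, integer(1))
    } else {
      .cpp_sw_score_vec(prots[[k]], unname(proteome),
                        params$substitution_matrix, al,
                        params$gap_open, params$gap_extend)
    }
    upd <- sc > best_score
    best_score[upd] <- sc[upd]
    best_iso[upd] <- k
  }
  ev <- vapply(seq_along(proteome), function(i)
    evalue(best_score[i], nchar(prots[[best_iso[i]]]), n_db, params),
    numeric(1))
  keep <- which(ev < params$evalue_cutoff & best_score > 0)
  if (length(keep) == 0) return(empty_hits())
  rows <- lapply(keep, function(i) {
    q <- prots[[best_iso[i]]]
    aln <- smith_waterman(q, proteome[[i]], params)
    hit_row(gid, names(proteome)[i], aln, ev[i],
            bit_score(best_score[i], params))
  })
  hits <- do.call(rbind, rows)
  hits[order(hits$evalue, hits$sseqid), , drop = FALSE]
}

#' Search a protein against a translated genome
#'
#' Aligns the query protein against all six reading frames of every genome
#' sequence (tblastn-like). E-values use n = total genome length in
#' nucleotides. Sequences shorter than 3 nt are skipped with a warning.
#'
#' @param query_protein Amino-acid string.
#' @param genome Named character vector of nucleotide sequences.
#' @param params [alignment_params()].
#' @param query_id Query identifier for the hit table.
#' @return outfmt-6 style data.frame with an extra `frame` column (+1..+3 /
#'   -1..-3); subject coordinates are amino-acid positions within the
#'   reported frame's translation.
#' @export
search_genome_translated <- function(query_protein, genome,
                                     params = alignment_params(),
                                     query_id = "query") {
  if (length(genome) == 0) stop("genome must be non-empty")
  short <- nchar(genome) < 3
  if (any(short)) {
    warning("skipping ", sum(short), " genome sequence(s) shorter than 3 nt")
    genome <- genome[!short]
    if (length(genome) == 0) return(cbind(empty_hits(), frame = integer(0)))
  }
  n_db <- sum(nchar(genome))
  frames <- lapply(genome, translate_six_frames)
  search_translated_frames(query_protein, frames, n_db, params, query_id)
}

# Shared core of the translated search: frames is a named list (per genome
# sequence) of six-frame translations, precomputed so that batch searches
# translate each genome only once.
search_translated_frames <- function(query_protein, frames, n_db, params,
                                     query_id = "query") {
  out <- list()
  for (si in seq_along(frames)) {
    tr <- frames[[si]]
    for (f in names(tr)) {
      if (!nzchar(tr[[f]])) next
      aln <- smith_waterman(query_protein, tr[[f]], params)
      if (aln$score <= 0) next
      ev <- evalue(aln$score, nchar(query_protein), n_db, params)
      if (ev < params$evalue_cutoff) {
        row <- hit_row(query_id, names(frames)[si], aln, ev,
                       bit_score(aln$score, params))
        row$frame <- as.integer(f)
        out[[length(out) + 1]] <- row
      }
    }
  }
  if (length(out) == 0) return(cbind(empty_hits(), frame = integer(0)))
  hits <- do.call(rbind, out)
  hits[order(hits$evalue, hits$sseqid, hits$frame), , drop = FALSE]
}

#' Transcript support for a gene
#'
#' A gene has transcript support when any EST in the database yields an
#' ungapped translated alignment to any of its isoforms with E below the
#' cutoff, after exact-word seeding (default word size 20). This mirrors an
#' ungapped tblastn of the protein against an EST database with
#' low-complexity filtering off.
#'
#' @param gene Gene record or character vector of isoform proteins.
#' @param est_db Named character vector of EST nucleotide sequences.
#' @param params [est_alignment_params()] by default.
#' @return Logical scalar. Use [transcript_support_evalue()] for the best
#'   E-value itself (needed for cutoff scans).
#' @export
transcript_support <- function(gene, est_db, params = est_alignment_params()) {
  transcript_support_evalue(gene, est_db, params) < params$evalue_cutoff
}

#' @rdname transcript_support
#' @param est_frames Optional precomputed list of six-frame translations of
#'   `est_db` (one [translate_six_frames()] result per EST), so batch
#'   callers translate the database only once.
#' @return `transcript_support_evalue()`: the best E-value over ESTs and
#'   isoforms (`Inf` when the database is empty or nothing aligns).
#' @export
transcript_support_evalue <- function(gene, est_db,
                                      params = est_alignment_params(),
                                      est_frames = NULL) {
  if (length(est_db) == 0) return(Inf)
  prots <- query_isoforms(gene)
  n_db <- sum(nchar(est_db))
  al <- params_alphabet(params)
  if (is.null(est_frames)) est_frames <- lapply(est_db, translate_six_frames)
  best <- 0L
  best_m <- 1L
  for (tr in est_frames) {
    for (fp in tr) {
      if (!nzchar(fp)) next
      for (p in prots) {
        r <- .cpp_ungapped_best(p, fp, params$substitution_matrix, al,
                                params$word_size %||% 0L)
        if (r$score > best) { best <- r$score; best_m <- nchar(p) }
      }
    }
  }
  if (best <= 0) return(Inf)
  evalue(best, best_m, n_db, params)
}

#' EST acceptance thresholds for gene mapping
#'
#' Quantifies "a large ungapped alignment to a single gene": the accepted
#' alignment must be ungapped, span at least `min_aa` aligned residues
#' (about 100 nt of a typical ~400 nt EST), reach E below `max_evalue`, and
#' the best gene must beat the runner-up by at least `min_bit_margin` bits
#' (otherwise the EST is ambiguous and mapped to no gene).
#'
#' @param min_aa Minimum ungapped aligned length in residues.
#' @param max_evalue E-value threshold.
#' @param min_bit_margin Required bit-score lead over the second-best gene.
#' @export
est_acceptance <- function(min_aa = 33L, max_evalue = 1e-4,
                           min_bit_margin = 5) {
  list(min_aa = as.integer(min_aa), max_evalue = max_evalue,
       min_bit_margin = min_bit_margin)
}

#' Map an EST to a unique focal gene
#'
#' Translated (blastx-like) ungapped alignment of the EST against the focal
#' protein set. Returns the single gene passing the acceptance thresholds,
#' or `NA` when no gene qualifies or the best two qualifying genes are
#' within the bit margin (the single-gene rule).
#'
#' @param est Nucleotide string.
#' @param focal_proteins Named character vector of proteins.
#' @param gene_of Named character vector mapping protein IDs to gene IDs
#'   (defaults to protein IDs themselves, i.e. one isoform per gene).
#' @param params [est_alignment_params()].
#' @param acceptance [est_acceptance()] thresholds.
#' @return Character gene ID or `NA_character_`; attributes `record` carries
#'   the per-gene alignment summary (gene, score, evalue, aligned length).
#' @export
map_est_to_genes <- function(est, focal_proteins,
                             gene_of = setNames(names(focal_proteins),
                                                names(focal_proteins)),
                             params = est_alignment_params(),
                             acceptance = est_acceptance()) {
  if (!params$ungapped)
    stop("EST mapping is defined for ungapped alignment only")
  if (length(focal_proteins) == 0) return(NA_character_)
  n_db <- sum(nchar(focal_proteins))
  al <- params_alphabet(params)
  tr <- translate_six_frames(est)
  tr <- tr[nzchar(tr)]
  per_prot <- lapply(names(focal_proteins), function(pid) {
    p <- focal_proteins[[pid]]
    best <- list(score = 0L, length = 0L)
    for (fp in tr) {
      r <- .cpp_ungapped_best(p, fp, params$substitution_matrix, al,
                              params$word_size %||% 0L)
      if (r$score > best$score) best <- r
    }
    data.frame(protein = pid, gene = unname(gene_of[pid]),
               score = best$score, aligned_aa = best$length,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, per_prot)
  # best isoform per gene
  tab <- tab[order(tab$gene, -tab$score), , drop = FALSE]
  tab <- tab[!duplicated(tab$gene), , drop = FALSE]
  tab$evalue <- evalue(tab$score, pmax(nchar(focal_proteins[tab$protein]), 1),
                       n_db, params)
  tab$bits <- bit_score(tab$score, params)
  tab$qualifies <- tab$score > 0 &
    tab$aligned_aa >= acceptance$min_aa &
    tab$evalue < acceptance$max_evalue
  tab <- tab[order(-tab$score), , drop = FALSE]
  qual <- tab[tab$qualifies, , drop = FALSE]
  result <- if (nrow(qual) == 0) {
    NA_character_
  } else if (nrow(qual) == 1) {
    qual$gene[1]
  } else if (qual$bits[1] - qual$bits[2] >= acceptance$min_bit_margin) {
    qual$gene[1]
  } else {
    NA_character_
  }
  structure(result, record = tab)
}
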