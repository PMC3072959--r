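# Duplication origin of restricted genes: a TRG that has a within-genome
# paralog whose homologs extend beyond the TRG's taxonomic class is a
# candidate for birth by duplication of a conserved parent followed by
# rapid divergence. Paralog detection reuses the homology cutoff; the
# escape rule is evaluated on each paralog's own presence row.

#' Find within-genome paralogs of a gene
#'
#' Aligns the gene's isoforms against the whole focal gene universe
#' (official set plus predictions) and returns the distinct genes with
#' E < cutoff. Self-hits and other isoforms of the same gene are excluded
#' by gene identity, not score. E-values use n = total universe residues.
#'
#' @param trg Gene record (or isoform vector with a `gene_id`-named first
#'   element).
#' @param universe A `gene_model_set` containing the focal gene universe,
#'   including `trg` itself.
#' @param params [alignment_params()].
#' @param cutoff E-value threshold (defaults to the homology cutoff).
#' @return Character vector of paralog gene ids (possibly empty), with the
#'   best E-value per paralog as the `evalues` attribute.
#' @export
find_paralogs <- function(trg, universe, params = alignment_params(),
                          cutoff = params$evalue_cutoff) {
  gid <- trg$gene_id
  subject_prots <- list()
  subject_gene <- character(0)
  for (g in universe) {
    if (g$gene_id == gid) next
    for (p in g$proteins) {
      subject_prots[[length(subject_prots) + 1]] <- p
      subject_gene <- c(subject_gene, g$gene_id)
    }
  }
  if (length(subject_prots) == 0) return(character(0))
  subjects <- unlist(subject_prots)
  n_db <- sum(vapply(universe, function(g) sum(nchar(g$proteins)), numeric(1)))
  al <- params_alphabet(params)
  best <- setNames(rep(Inf, length(unique(subject_gene))), unique(subject_gene))
  for (p in query_isoforms(trg)) {
    sc <- .cpp_sw_score_vec(p, subjects, params$substitution_matrix, al,
                            params$gap_open, params$gap_extend)
    ev <- evalue(sc, nchar(p), n_db, params)
    for (i in seq_along(ev)) {
      g2 <- subject_gene[i]
      if (ev[i] < best[[g2]]) best[[g2]] <- ev[i]
    }
  }
  hits <- best[best < cutoff]
  structure(names(hits), evalues = unname(hits))
}

#' Flag whether a TRG's paralogs reach outside its class
#'
#' Applies the class-specific escape rule: for an orphan, some paralog must
#' have a homolog in any other species; for the Hymenoptera-restricted
#' classes (`hymenoptera`, `hymenoptera_conserved`, `social_insect`), some
#' paralog must have a homolog outside the Hymenoptera; for an
#' insect-specific gene, outside the insects. Evidence is read off each
#' paralog's presence row.
#'
#' @param trg_id Gene id of the TRG.
#' @param trg_class Its homology class (one of the five restricted classes).
#' @param paralogs Character vector from [find_paralogs()].
#' @param pa The `presence_absence` matrix covering the paralogs.
#' @return Object of class `duplication_record`: list with `trg_id`,
#'   `trg_class`, `paralog_ids`, `conserved_paralog` (logical) and
#'   `evidence` (data.frame paralog x species of the escaping presences).
#' @export
flag_conserved_paralogs <- function(trg_id, trg_class, paralogs, pa) {
  if (!trg_class %in% TRG_CLASSES)
    stop("duplication origin is defined for restricted classes only, got ",
         trg_class)
  manifest <- pa$manifest
  sp <- comparison_ids(manifest)
  outside <- switch(trg_class,
    orphan = sp,
    hymenoptera = ,
    hymenoptera_conserved = ,
    social_insect = species_with_tag(manifest, "hymenoptera", negate = TRUE),
    insect = species_with_tag(manifest, "insect", negate = TRUE))
  evidence <- list()
  for (p in paralogs) {
    if (!p %in% rownames(pa$code))
      stop("paralog ", p, " missing from presence data")
    hit_sp <- outside[pa$code[p, outside] != "A"]
    if (length(hit_sp) > 0)
      evidence[[length(evidence) + 1]] <-
        data.frame(paralog = p, species = hit_sp, stringsAsFactors = FALSE)
  }
  evidence <- if (length(evidence) > 0) do.call(rbind, evidence) else
    data.frame(paralog = character(0), species = character(0),
               stringsAsFactors = FALSE)
  structure(list(trg_id = trg_id, trg_class = trg_class,
                 paralog_ids = as.character(paralogs),
                 conserved_paralog = nrow(evidence) > 0,
                 evidence = evidence),
            class = "duplication_record")
}

#' Duplication-origin analysis over all TRGs
#'
#' Runs [find_paralogs()] and [flag_conserved_paralogs()] for every gene in
#' a restricted class.
#'
#' @param universe A `gene_model_set` (the full focal gene universe).
#' @param report A `classification_report` over (at least) the TRGs.
#' @param pa The `presence_absence` matrix.
#' @param params,cutoff Passed to [find_paralogs()].
#' @return List of `duplication_record`, named by TRG id.
#' @export
duplication_origin_records <- function(universe, report, pa,
                                       params = alignment_params(),
                                       cutoff = params$evalue_cutoff) {
  trgs <- names(report$classes)[report$classes %in% TRG_CLASSES]
  out <- list()
  for (g in trgs) {
    par <- find_paralogs(universe[[g]], universe, params, cutoff)
    out[[g]] <- flag_conserved_paralogs(g, report$classes[[g]], par, pa)
  }
  out
}

#' Fraction of TRGs with duplication-origin evidence, per class
#'
#' @param records List of `duplication_record` (e.g. from
#'   [duplication_origin_records()]).
#' @return data.frame with `class`, `n`, `n_flagged`, `fraction`.
#' @export
duplication_rate_by_class <- function(records) {
  cls <- vapply(records, `[[`, character(1), "trg_class")
  flag <- vapply(records, `[[`, logical(1), "conserved_paralog")
  rows <- lapply(intersect(TRG_CLASSES, unique(cls)), function(k) {
    idx <- cls == k
    data.frame(class = k, n = sum(idx), n_flagged = sum(flag[idx]),
               fraction = if (sum(idx) > 0) mean(flag[idx]) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
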