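# Per-gene structural characteristics and per-class summaries: protein size
# (longest isoform), exon number, gene size, CDS GC content, transcript
# support. Summaries report mean +/- SE (sample sd over sqrt(n)) per class
# and transcript support as a percentage of the class.

#' GC content of a nucleotide sequence
#'
#' Percentage of G+C among unambiguous bases; ambiguity codes (anything
#' outside A/C/G/T) are excluded from both numerator and denominator.
#'
#' @param seq Nucleotide string.
#' @return Percent in [0, 100], or `NA` if no unambiguous base is present.
#' @export
gc_content <- function(seq) {
  if (is.na(seq) || !nzchar(seq)) return(NA_real_)
  chars <- strsplit(toupper(seq), "")[[1]]
  acgt <- chars %in% c("A", "C", "G", "T")
  if (!any(acgt)) return(NA_real_)
  100 * sum(chars[acgt] %in% c("G", "C")) / sum(acgt)
}

#' Compute the characteristics of one gene
#'
#' @param gene A gene record from [read_gff3()].
#' @param est_db Optional EST database for transcript support (named
#'   character vector); when `NULL`, support is `NA`.
#' @param params [est_alignment_params()] for the transcript-support search.
#' @return One-row data.frame: `gene_id`, `protein_size` (longest isoform),
#'   `exon_number`, `gene_size`, `gc_content` (NA when the CDS is missing,
#'   never silently zero), `transcript_support`.
#' @export
compute_characteristics <- function(gene, est_db = NULL,
                                    params = est_alignment_params()) {
  prot <- longest_protein(gene)
  data.frame(
    gene_id = gene$gene_id,
    protein_size = if (is.na(prot)) NA_integer_ else nchar(prot),
    exon_number = gene$exon_number,
    gene_size = gene$gene_size,
    gc_content = gc_content(gene$cds),
    transcript_support = if (is.null(est_db)) NA else
      transcript_support(gene, est_db, params),
    stringsAsFactors = FALSE
  )
}

#' Characteristics table for a gene set
#'
#' @param genes A `gene_model_set`.
#' @inheritParams compute_characteristics
#' @return data.frame, one row per gene.
#' @export
characteristics_table <- function(genes, est_db = NULL,
                                  params = est_alignment_params()) {
  est_frames <- if (!is.null(est_db) && length(est_db) > 0)
    lapply(est_db, translate_six_frames) else NULL
  rows <- lapply(genes, function(g) {
    row <- compute_characteristics(g, est_db = NULL, params = params)
    if (!is.null(est_db))
      row$transcript_support <-
        transcript_support_evalue(g, est_db, params, est_frames) <
          params$evalue_cutoff
    row
  })
  do.call(rbind, rows)
}

#' Per-class summary of gene characteristics
#'
#' Mean and standard error (sample sd / sqrt(n); 0 when n = 1) of each
#' numeric characteristic per homology class, plus the percentage of genes
#' with transcript support. Classes with no genes are omitted with a
#' message.
#'
#' @param characteristics data.frame from [characteristics_table()].
#' @param classes Named character vector gene_id -> class (e.g.
#'   `classification_report$classes`).
#' @return data.frame with one row per non-empty class: `class`, `n`, then
#'   `<var>_mean` and `<var>_se` for protein_size, exon_number, gene_size,
#'   gc_content, and `transcript_support_percent`.
#' @export
summarize_by_class <- function(characteristics, classes) {
  if (!all(characteristics$gene_id %in% names(classes)))
    stop("every gene needs a class")
  cls <- classes[characteristics$gene_id]
  vars <- c("protein_size", "exon_number", "gene_size", "gc_content")
  rows <- list()
  for (k in HOMOLOGY_CLASSES) {
    sub <- characteristics[cls == k, , drop = FALSE]
    if (nrow(sub) == 0) {
      message("class ", k, " has no genes; omitted from summary")
      next
    }
    row <- data.frame(class = k, n = nrow(sub), stringsAsFactors = FALSE)
    for (v in vars) {
      x <- sub[[v]][!is.na(sub[[v]])]
      row[[paste0(v, "_mean")]] <- if (length(x) > 0) mean(x) else NA_real_
      row[[paste0(v, "_se")]] <- if (length(x) > 1) sd(x) / sqrt(length(x))
        else if (length(x) == 1) 0 else NA_real_
    }
    supp <- sub$transcript_support[!is.na(sub$transcript_support)]
    row$transcript_support_percent <-
      if (length(supp) > 0) 100 * mean(supp) else NA_real_
    rows[[length(rows) + 1]] <- row
  }
  do.call(rbind, rows)
}

#' Transcript-support fractions across E-value cutoffs
#'
#' Recomputes per-class transcript-support fractions at each of several
#' E-value cutoffs from a single pass of best EST E-values per gene, and
#' tabulates between-class ratios, to check that tightening the cutoff
#' changes counts but not the ratios between classes.
#'
#' @param genes A `gene_model_set`.
#' @param classes Named character vector gene_id -> class.
#' @param est_db EST database (named character vector).
#' @param cutoffs Numeric vector of at least two E-value cutoffs.
#' @param params [est_alignment_params()].
#' @return List with `fractions` (matrix class x cutoff of supported
#'   fractions), `counts` (same shape, supported counts), `n_per_class`,
#'   and `ratios` (each cutoff's fractions normalised to the first class
#'   with support).
#' @export
cutoff_ratio_check <- function(genes, classes, est_db, cutoffs,
                               params = est_alignment_params()) {
  if (length(cutoffs) < 2) stop("need at least two cutoffs to compare")
  est_frames <- if (length(est_db) > 0)
    lapply(est_db, translate_six_frames) else NULL
  best_ev <- vapply(genes, transcript_support_evalue, numeric(1),
                    est_db = est_db, params = params,
                    est_frames = est_frames)
  cls <- classes[names(genes)]
  present_classes <- HOMOLOGY_CLASSES[HOMOLOGY_CLASSES %in% cls]
  frac <- matrix(NA_real_, length(present_classes), length(cutoffs),
                 dimnames = list(present_classes, format(cutoffs)))
  cnt <- frac
  for (j in seq_along(cutoffs)) {
    for (k in present_classes) {
      idx <- which(cls == k)
      cnt[k, j] <- sum(best_ev[idx] < cutoffs[j])
      frac[k, j] <- cnt[k, j] / length(idx)
    }
  }
  ref <- frac[1, , drop = TRUE]
  ratios <- sweep(frac, 2, ifelse(ref > 0, ref, NA_real_), "/")
  list(fractions = frac, counts = cnt,
       n_per_class = table(factor(cls, levels = present_classes)),
       ratios = ratios)
}
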