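# Gene models: GFF3 parsing (via rtracklayer) joined with protein and CDS
# FASTA into per-gene records. Coordinates are 1-based inclusive
# throughout, the GFF3 convention.

#' Read gene models from GFF3
#'
#' Parses `gene`, `mRNA`, `exon` and `CDS` features into one record per
#' gene. Gene size is `end - start + 1` (1-based inclusive span). The exon
#' number of a gene is the maximum exon count over its transcripts. Exon
#' intervals outside the gene span are a validation error.
#'
#' @param path Path to a GFF3 file.
#' @param proteins Optional named character vector of proteins (names are
#'   mRNA IDs, or gene IDs for single-isoform sets), attached per gene.
#' @param cds Optional named character vector of CDS nucleotide sequences
#'   keyed by gene ID or mRNA ID.
#' @param official Logical (recycled): whether each gene belongs to the
#'   official gene set as opposed to an ab-initio prediction set. Carried as
#'   an attribute; never used by classification.
#' @return An object of class `gene_model_set`: a named list of gene
#'   records, each with `gene_id`, `seqid`, `start`, `end`, `strand`,
#'   `gene_size`, `exon_number`, `exons` (two-column matrix), `transcripts`
#'   (character vector of mRNA IDs), `proteins` (named character vector, one
#'   per isoform), `cds` (string or NA), `official`.
#' @export
read_gff3 <- function(path, proteins = NULL, cds = NULL, official = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path)
  g <- as.data.frame(rtracklayer::readGFF(path,
                                          columns = c("seqid", "source", "type",
                                                      "start", "end", "strand"),
                                          tags = c("ID", "Parent")))
  g$Parent <- vapply(g$Parent, function(p)
    if (length(p) == 0) NA_character_ else as.character(p[[1]]), character(1))
  genes <- g[g$type == "gene", , drop = FALSE]
  if (nrow(genes) == 0) return(structure(list(), class = "gene_model_set"))
  if (anyNA(genes$ID)) stop("gene feature without ID in ", path)
  mrna <- g[g$type == "mRNA", , drop = FALSE]
  exons <- g[g$type == "exon", , drop = FALSE]
  mrna_gene <- setNames(mrna$Parent, mrna$ID)

  official <- rep_len(official, nrow(genes))
  out <- vector("list", nrow(genes))
  names(out) <- genes$ID
  for (i in seq_len(nrow(genes))) {
    gid <- genes$ID[i]
    tx <- mrna$ID[mrna$Parent == gid]
    ex_tx <- exons[exons$Parent %in% tx, , drop = FALSE]
    # single-transcript files may parent exons directly on the gene
    ex_direct <- exons[exons$Parent == gid & !is.na(exons$Parent), , drop = FALSE]
    ex_all <- rbind(ex_tx, ex_direct)
    if (nrow(ex_all) > 0) {
      bad <- ex_all$start < genes$start[i] | ex_all$end > genes$end[i]
      if (any(bad))
        stop("exon outside gene span for gene ", gid, ": ",
             paste(sprintf("%d-%d", ex_all$start[bad], ex_all$end[bad]),
                   collapse = ", "))
    }
    exon_number <- if (length(tx) > 0) {
      cnt <- vapply(tx, function(t) sum(ex_tx$Parent == t), integer(1))
      if (nrow(ex_direct) > 0) cnt <- c(cnt, nrow(ex_direct))
      max(c(cnt, 1L))
    } else max(nrow(ex_direct), 1L)

    prots <- character(0)
    if (!is.null(proteins)) {
      keys <- intersect(c(tx, gid), names(proteins))
      prots <- proteins[keys]
    }
    gene_cds <- NA_character_
    if (!is.null(cds)) {
      key <- intersect(c(gid, tx), names(cds))
      if (length(key) > 0) gene_cds <- unname(cds[key[1]])
    }
    out[[i]] <- list(
      gene_id = gid,
      seqid = as.character(genes$seqid[i]),
      start = genes$start[i], end = genes$end[i],
      strand = as.character(genes$strand[i]),
      gene_size = genes$end[i] - genes$start[i] + 1L,
      exon_number = exon_number,
      exons = as.matrix(ex_all[, c("start", "end"), drop = FALSE]),
      transcripts = tx,
      proteins = prots,
      cds = gene_cds,
      official = official[i]
    )
  }
  structure(out, class = "gene_model_set")
}

#' @export
print.gene_model_set <- function(x, ...) {
  cat("gene_model_set with", length(x), "genes\n")
  invisible(x)
}

#' @export
as.data.frame.gene_model_set <- function(x, ...) {
  data.frame(
    gene_id = vapply(x, `[[`, character(1), "gene_id"),
    seqid = vapply(x, `[[`, character(1), "seqid"),
    start = vapply(x, `[[`, numeric(1), "start"),
    end = vapply(x, `[[`, numeric(1), "end"),
    strand = vapply(x, `[[`, character(1), "strand"),
    gene_size = vapply(x, `[[`, numeric(1), "gene_size"),
    exon_number = vapply(x, `[[`, numeric(1), "exon_number"),
    n_isoforms = vapply(x, function(g) length(g$proteins), integer(1)),
    official = vapply(x, `[[`, logical(1), "official"),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

# Longest isoform of a gene record (Table-1-style characteristics use one
# protein per gene; homology search uses all isoforms).
longest_protein <- function(gene) {
  if (length(gene$proteins) == 0) return(NA_character_)
  unname(gene$proteins[which.max(nchar(gene$proteins))])
}
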