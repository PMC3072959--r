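# BLAST tabular (outfmt 6) reading/writing: the 12-column layout
# qseqid sseqid pident length mismatch gapopen qstart qend sstart send
# evalue bitscore. This is both the adapter for externally produced hit
# tables and the emission format of the built-in engine.

BLAST6_COLS <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                 "gapopen", "qstart", "qend", "sstart", "send",
                 "evalue", "bitscore")

empty_hits <- function() {
  df <- data.frame(qseqid = character(0), sseqid = character(0),
                   pident = numeric(0), length = integer(0),
                   mismatch = integer(0), gapopen = integer(0),
                   qstart = integer(0), qend = integer(0),
                   sstart = integer(0), send = integer(0),
                   evalue = numeric(0), bitscore = numeric(0),
                   stringsAsFactors = FALSE)
  df
}

#' Read a BLAST tabular (outfmt 6) hit table
#'
#' Expects exactly 12 tab-separated columns; E-values in scientific notation
#' are parsed as numerics. Lines starting with `#` are ignored.
#'
#' @param path Path to a tab-separated hit table.
#' @return data.frame with columns `qseqid sseqid pident length mismatch
#'   gapopen qstart qend sstart send evalue bitscore`.
#' @export
read_blast_tab <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) return(empty_hits())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nfld <- lengths(parts)
  if (any(nfld != 12L)) {
    bad <- which(nfld != 12L)[1]
    stop("malformed hit table ", path, ": expected 12 tab-separated columns, ",
         "got ", nfld[bad], " at line ", bad)
  }
  m <- matrix(unlist(parts), ncol = 12, byrow = TRUE)
  df <- data.frame(qseqid = m[, 1], sseqid = m[, 2],
                   pident = as.numeric(m[, 3]), length = as.integer(m[, 4]),
                   mismatch = as.integer(m[, 5]), gapopen = as.integer(m[, 6]),
                   qstart = as.integer(m[, 7]), qend = as.integer(m[, 8]),
                   sstart = as.integer(m[, 9]), send = as.integer(m[, 10]),
                   evalue = as.numeric(m[, 11]), bitscore = as.numeric(m[, 12]),
                   stringsAsFactors = FALSE)
  if (anyNA(df$evalue)) stop("unparseable E-value in ", path)
  df
}

#' Write hits in BLAST tabular (outfmt 6) layout
#'
#' E-values are formatted in scientific notation (`%.2e`, the BLAST+
#' convention of two significand digits), identities with one decimal,
#' bit scores with one decimal.
#'
#' @param hits data.frame as returned by [read_blast_tab()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_blast_tab <- function(hits, path) {
  stopifnot(all(BLAST6_COLS %in% names(hits)))
  lines <- sprintf("%s\t%s\t%.1f\t%d\t%d\t%d\t%d\t%d\t%d\t%d\t%.2e\t%.1f",
                   hits$qseqid, hits$sseqid, hits$pident,
                   as.integer(hits$length), as.integer(hits$mismatch),
                   as.integer(hits$gapopen), as.integer(hits$qstart),
                   as.integer(hits$qend), as.integer(hits$sstart),
                   as.integer(hits$send), hits$evalue, hits$bitscore)
  writeLines(lines, path)
  invisible(path)
}

# Assemble one outfmt-6 row from a local_alignment record.
hit_row <- function(qid, sid, aln, ev, bits) {
  data.frame(qseqid = qid, sseqid = sid,
             pident = aln$percent_identity %||% NA_real_,
             length = aln$length,
             mismatch = aln$length - aln$matches - (aln$gaps %||% 0L),
             gapopen = aln$gap_opens %||% 0L,
             qstart = aln$query_start, qend = aln$query_end,
             sstart = aln$subject_start, send = aln$subject_end,
             evalue = ev, bitscore = bits, stringsAsFactors = FALSE)
}
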