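# FASTA reading/writing. Parsing is delegated to Biostrings; a light
# pre-check gives a line-numbered error for the one malformation Biostrings
# accepts silently in some forms (sequence data before any header).

#' Read a FASTA file
#'
#' Returns sequences as an upper-cased named character vector, in file
#' order. Record identifiers are the first whitespace-delimited token of
#' each header; wrapped sequence lines are concatenated. Works for both
#' nucleotide and amino-acid FASTA (no alphabet validation). Transparent
#' gzip is supported.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector (possibly empty).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- gzfile(path, "r"); on.exit(close(con))
  first <- NULL; lineno <- 0L
  repeat {
    ln <- readLines(con, n = 1L)
    if (length(ln) == 0L) break
    lineno <- lineno + 1L
    if (grepl("^\\s*$", ln) || startsWith(ln, ";")) next
    first <- ln
    break
  }
  if (is.null(first)) return(setNames(character(0), character(0)))
  if (!startsWith(first, ">"))
    stop("malformed FASTA in ", path, ": sequence before header at line ",
         lineno)
  seqs <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(seqs))
  setNames(toupper(as.character(seqs)), ids)
}

#' Write sequences to FASTA
#'
#' One record per element of `seqs`, identifier from names, sequence on a
#' single unwrapped line (so that `read_fasta(write_fasta(x))` round-trips
#' byte-identically for upper-case input).
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (length(seqs) > 0 && (is.null(names(seqs)) || any(!nzchar(names(seqs)))))
    stop("all sequences must be named")
  lines <- if (length(seqs) == 0) character(0) else
    as.vector(rbind(paste0(">", names(seqs)), unname(seqs)))
  writeLines(lines, path)
  invisible(path)
}
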