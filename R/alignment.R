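# Local alignment engine: Smith-Waterman with affine gaps, an ungapped
# (single-diagonal) mode with optional exact-word seeding, and
# Karlin-Altschul E-value statistics. This is the package's stand-in for a
# protein BLAST workflow at synthetic scale; externally produced hit tables
# can be substituted anywhere downstream.

# Published Karlin-Altschul parameters for BLOSUM62. Ungapped values are the
# analytic ones; the gapped pair is the standard estimate for gap open 11 /
# extend 1.
KA_PARAMS <- list(
  ungapped = c(lambda = 0.3176, kappa = 0.134),
  gapped   = c(lambda = 0.267,  kappa = 0.041)
)

blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

#' Alignment and E-value parameters
#'
#' Bundles the scoring scheme used by the homology engine: substitution
#' matrix, affine gap penalties (a gap of length L costs
#' `gap_open + gap_extend * L`), whether alignment is ungapped, an optional
#' exact-word seeding size, the Karlin-Altschul scale `lambda` and prefactor
#' `kappa` used for `E = kappa * m * n * exp(-lambda * S)`, and the E-value
#' cutoff defining homology (default `1e-4`).
#'
#' `lambda`/`kappa` default to published BLOSUM62 values: the ungapped pair
#' when `ungapped = TRUE`, otherwise the gapped (11/1) pair. Ambiguous
#' residues (`X`, and anything outside the matrix alphabet) score 0 against
#' everything. Low-complexity filtering is not implemented; the flag exists
#' only so that configurations can state it explicitly, and setting it to
#' `TRUE` is an error.
#'
#' @param substitution_matrix Named square integer matrix (default BLOSUM62
#'   from Biostrings).
#' @param gap_open,gap_extend Non-negative gap penalties.
#' @param ungapped Logical; restrict alignments to a single diagonal.
#' @param word_size Integer or NULL; when set, ungapped alignment requires an
#'   exact identity word of this length on the diagonal before extension.
#' @param lambda,kappa Karlin-Altschul parameters (positive reals).
#' @param evalue_cutoff Positive E-value threshold defining homology.
#' @param low_complexity_filter Must be FALSE (present for explicitness).
#' @return An object of class `alignment_params`.
#' @examples
#' alignment_params()                      # gapped blastp-like defaults
#' est_alignment_params()                  # ungapped, word size 20
#' @export
alignment_params <- function(substitution_matrix = blosum62(),
                             gap_open = 11L, gap_extend = 1L,
                             ungapped = FALSE, word_size = NULL,
                             lambda = NULL, kappa = NULL,
                             evalue_cutoff = 1e-4,
                             low_complexity_filter = FALSE) {
  if (isTRUE(low_complexity_filter))
    stop("low-complexity filtering is not implemented; ",
         "low_complexity_filter must be FALSE")
  if (gap_open < 0 || gap_extend < 0) stop("gap penalties must be >= 0")
  if (!is.null(word_size) && word_size < 1) stop("word_size must be >= 1")
  if (evalue_cutoff <= 0) stop("evalue_cutoff must be positive")
  ka <- if (ungapped) KA_PARAMS$ungapped else KA_PARAMS$gapped
  lambda <- lambda %||% unname(ka["lambda"])
  kappa  <- kappa  %||% unname(ka["kappa"])
  if (lambda <= 0 || kappa <= 0) stop("lambda and kappa must be positive")
  if (is.null(rownames(substitution_matrix)))
    stop("substitution matrix must have a named alphabet")
  structure(list(substitution_matrix = substitution_matrix,
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 ungapped = isTRUE(ungapped),
                 word_size = if (is.null(word_size)) NULL else as.integer(word_size),
                 lambda = lambda, kappa = kappa,
                 evalue_cutoff = evalue_cutoff,
                 low_complexity_filter = FALSE),
            class = "alignment_params")
}

#' @rdname alignment_params
#' @param ... Overrides passed to [alignment_params()].
#' @details `est_alignment_params()` is the transcript-support / EST-mapping
#'   configuration: ungapped, exact-word seeding of 20 residues, no
#'   low-complexity filtering, E-value cutoff `1e-4`.
#' @export
est_alignment_params <- function(...) {
  args <- list(...)
  defaults <- list(ungapped = TRUE, word_size = 20L)
  do.call(alignment_params, utils::modifyList(defaults, args))
}

params_alphabet <- function(params) rownames(params$substitution_matrix)

#' Karlin-Altschul E-value
#'
#' Expected number of chance local alignments scoring at least `score`
#' between a query of length `m` and a database of total length `n`:
#' `E = kappa * m * n * exp(-lambda * score)`.
#'
#' @param score Raw alignment score (integer scale of the matrix).
#' @param m Query length (residues), >= 1.
#' @param n Database length (residues), >= 1.
#' @param params An [alignment_params()] object supplying lambda and kappa.
#' @return Non-negative numeric E-value.
#' @export
evalue <- function(score, m, n, params = alignment_params()) {
  stopifnot(m >= 1, n >= 1)
  params$kappa * m * n * exp(-params$lambda * score)
}

# Bit score under the same statistics; used for the EST single-gene margin
# rule.
bit_score <- function(score, params) {
  (params$lambda * score - log(params$kappa)) / log(2)
}

#' Optimal local alignment of two sequences
#'
#' Exact Smith-Waterman local alignment under affine gap costs, or best
#' single-diagonal segment when `params$ungapped` is TRUE. Ties on score are
#' broken deterministically in favour of the smallest query start, then the
#' smallest subject start. A score of 0 means no positive-scoring local
#' alignment exists; coordinates are then NA.
#'
#' @param query,subject Non-empty amino-acid strings.
#' @param params An [alignment_params()] object.
#' @return A list of class `local_alignment`: `score`, 1-based inclusive
#'   `query_start/query_end/subject_start/subject_end`, `length` (alignment
#'   columns), `percent_identity`, `gapped` (logical, whether the alignment
#'   itself contains gaps), and `evalue` computed against the subject alone
#'   (`m = nchar(query)`, `n = nchar(subject)`).
#' @examples
#' smith_waterman("ACDE", "ACDE")$score  # 24 under BLOSUM62
#' @export
smith_waterman <- function(query, subject, params = alignment_params()) {
  if (!nzchar(query) || !nzchar(subject)) stop("sequences must be non-empty")
  query <- toupper(query); subject <- toupper(subject)
  al <- params_alphabet(params)
  if (params$ungapped) {
    r <- .cpp_ungapped_best(query, subject, params$substitution_matrix, al,
                            params$word_size %||% 0L)
    gaps <- 0L; gap_opens <- 0L
  } else {
    r <- .cpp_sw_align(query, subject, params$substitution_matrix, al,
                       params$gap_open, params$gap_extend)
    gaps <- r$gaps; gap_opens <- r$gap_opens
  }
  structure(list(
    score = r$score,
    query_start = r$qstart, query_end = r$qend,
    subject_start = r$sstart, subject_end = r$send,
    length = r$length,
    percent_identity = if (r$length > 0) 100 * r$matches / r$length else NA_real_,
    matches = r$matches,
    gaps = gaps, gap_opens = gap_opens,
    gapped = gaps > 0,
    evalue = evalue(r$score, nchar(query), nchar(subject), params)
  ), class = "local_alignment")
}

#' Exhaustive local alignment score (reference implementation)
#'
#' Computes the optimal local alignment score by direct enumeration of every
#' monotone matching between residue positions of the two sequences (every
#' possible local alignment), applying the same affine gap cost
#' `gap_open + gap_extend * L` to each internal unaligned run. Exponential in
#' sequence length and intended purely as an independent check of
#' [smith_waterman()] on short sequences (<= ~8 residues).
#'
#' @inheritParams smith_waterman
#' @return Integer score (0 when no positive alignment exists).
#' @export
smith_waterman_exhaustive <- local({
  memo <- new.env(parent = emptyenv())
  matchings <- function(m, n) {
    key <- paste(m, n)
    if (!is.null(memo[[key]])) return(memo[[key]])
    out <- list()
    for (k in seq_len(min(m, n))) {
      qi <- utils::combn(m, k)
      sj <- utils::combn(n, k)
      # all pairs of k-subsets; indices as matrices (choose(m,k)*choose(n,k)) x k
      nq <- ncol(qi); ns <- ncol(sj)
      Q <- t(qi)[rep(seq_len(nq), times = ns), , drop = FALSE]
      S <- t(sj)[rep(seq_len(ns), each = nq), , drop = FALSE]
      out[[k]] <- list(Q = Q, S = S)
    }
    memo[[key]] <- out
    out
  }
  function(query, subject, params = alignment_params()) {
    query <- toupper(query); subject <- toupper(subject)
    mat <- params$substitution_matrix
    al <- rownames(mat)
    qc <- match(strsplit(query, "")[[1]], al)
    sc <- match(strsplit(subject, "")[[1]], al)
    # ambiguity rule: unmatched characters and X/* score 0
    zero <- function(idx, chars) ifelse(is.na(idx) | chars %in% c("X", "*"), NA, idx)
    qc <- zero(qc, strsplit(query, "")[[1]])
    sc <- zero(sc, strsplit(subject, "")[[1]])
    m <- length(qc); n <- length(sc)
    gfun <- function(d) ifelse(d > 0, params$gap_open + params$gap_extend * d, 0)
    best <- 0L
    for (mk in matchings(m, n)) {
      Q <- mk$Q; S <- mk$S
      if (params$ungapped) {
        keep <- rep(TRUE, nrow(Q))
        if (ncol(Q) > 1) {
          dq <- Q[, -1, drop = FALSE] - Q[, -ncol(Q), drop = FALSE]
          ds <- S[, -1, drop = FALSE] - S[, -ncol(S), drop = FALSE]
          keep <- rowSums(dq != 1 | ds != 1) == 0
        }
        if (!any(keep)) next
        Q <- Q[keep, , drop = FALSE]; S <- S[keep, , drop = FALSE]
      }
      a <- matrix(qc[Q], nrow = nrow(Q))
      b <- matrix(sc[S], nrow = nrow(S))
      sub <- matrix(0L, nrow(a), ncol(a))
      ok <- !is.na(a) & !is.na(b)
      sub[ok] <- mat[cbind(a[ok], b[ok])]
      sc_total <- rowSums(sub)
      if (ncol(Q) > 1 && !params$ungapped) {
        dq <- Q[, -1, drop = FALSE] - Q[, -ncol(Q), drop = FALSE] - 1L
        ds <- S[, -1, drop = FALSE] - S[, -ncol(S), drop = FALSE] - 1L
        sc_total <- sc_total - rowSums(gfun(dq)) - rowSums(gfun(ds))
      }
      best <- max(best, max(sc_total))
    }
    as.integer(best)
  }
})

#' Six-frame translation
#'
#' Translates a nucleotide sequence in all six reading frames under the
#' standard genetic code. Stops are rendered as `*`; codons containing
#' ambiguous bases translate to `X`; trailing partial codons are dropped.
#' Frames too short to contain a full codon yield an empty protein.
#'
#' @param nt Nucleotide string (length >= 3 for any non-empty frame).
#' @return Named character vector of six proteins, frames `+1 +2 +3 -1 -2 -3`.
#' @examples
#' translate_six_frames("ATGAAA")[["+1"]]  # "MK"
#' @export
translate_six_frames <- function(nt) {
  nt <- toupper(nt)
  rev <- reverse_complement(nt)
  code <- genetic_code_table()
  one <- function(s, off) {
    len <- nchar(s) - off
    len <- len - (len %% 3)
    if (len < 3) return("")
    starts <- seq(off + 1, off + len, by = 3)
    aa <- code[substring(s, starts, starts + 2)]
    aa[is.na(aa)] <- "X"  # codons containing ambiguous bases
    paste(aa, collapse = "")
  }
  c("+1" = one(nt, 0), "+2" = one(nt, 1), "+3" = one(nt, 2),
    "-1" = one(rev, 0), "-2" = one(rev, 1), "-3" = one(rev, 2))
}

# Standard genetic code as a codon -> residue lookup (stops as '*').
genetic_code_table <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- Biostrings::GENETIC_CODE
    cache
  }
})

reverse_complement <- function(nt) {
  paste(rev(strsplit(chartr("ACGTUNRYSWKMBDHV", "TGCAANYRSWMKVHDB",
                            toupper(nt)), "")[[1]]), collapse = "")
}
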